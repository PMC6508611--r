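# Profile-distance and efficiency metrics. The distance between two
# expression profiles is the mean absolute difference of their per-gene
# log2 fold-changes; against the all-zero profile it measures departure
# from the healthy state. The efficiency score of a treatment for a
# functional category is the log10 ratio of its mean absolute log2FC
# against the diseased baseline over that against the healthy baseline:
# positive scores move away from disease while staying near health.

#' Mean absolute log2FC difference between two profiles
#'
#' @param p1,p2 numeric vectors of per-gene log2 fold-changes, aligned on
#'   the same gene subset (N >= 1).
#' @return non-negative scalar: sum(|p1 - p2|) / N.
#' @examples
#' profileDistance(c(1, -1, 2), c(0, 0, 0))  # 4/3
#' @export
profileDistance <- function(p1, p2) {
    if (!length(p1)) stop("empty gene subset")
    if (length(p1) != length(p2))
        stop("profiles must be aligned on the same gene subset")
    mean(abs(p1 - p2))
}

#' Distance of a treatment profile from the healthy state
#'
#' [profileDistance()] of the treatment's vs-healthy log2FC vector against
#' the all-zero (healthy) profile, over a chosen gene subset; used as a
#' proxy for treatment efficiency.
#'
#' @param lfcVsWt named numeric vector of log2FC against the healthy
#'   control.
#' @param subset gene identifiers to evaluate over (default: all genes of
#'   the vector); must be present in \code{lfcVsWt}.
#' @return non-negative scalar.
#' @export
distanceFromWT <- function(lfcVsWt, subset = names(lfcVsWt)) {
    if (!length(subset)) stop("empty gene subset")
    bad <- setdiff(subset, names(lfcVsWt))
    if (length(bad))
        stop("subset genes absent from the profile: ",
             paste(utils::head(bad, 5), collapse = ", "))
    profileDistance(lfcVsWt[subset], rep(0, length(subset)))
}

#' Treatment efficiency score for a gene subset
#'
#' log10 of the ratio of aggregated |log2FC| against the disease control
#' over that against the healthy control. \code{"mean_of_abs"} (default)
#' aggregates as the mean of absolute values; \code{"abs_of_mean"} as the
#' absolute value of the mean (where opposite-sign changes cancel). The
#' denominator is guarded by \code{epsilon} and the score capped at
#' \code{+/- cap}.
#'
#' @param lfcVsTg,lfcVsWt aligned numeric log2FC vectors for the gene
#'   subset (vs disease and vs healthy control respectively).
#' @param mode "mean_of_abs" or "abs_of_mean".
#' @param epsilon positive divide-by-zero guard (default 1e-8).
#' @param cap reporting cap on |score| (default 12).
#' @return scalar efficiency score.
#' @examples
#' efficiencyScore(c(1, 1), c(0.1, 0.1))  # 1
#' @export
efficiencyScore <- function(lfcVsTg, lfcVsWt,
                            mode = c("mean_of_abs", "abs_of_mean"),
                            epsilon = 1e-8, cap = 12) {
    mode <- match.arg(mode)
    if (!length(lfcVsTg) || length(lfcVsTg) != length(lfcVsWt))
        stop("profiles must be non-empty and aligned")
    agg <- if (mode == "mean_of_abs") function(x) mean(abs(x))
           else function(x) abs(mean(x))
    score <- log10(agg(lfcVsTg) / max(agg(lfcVsWt), epsilon))
    min(max(score, -cap), cap)
}

#' Two-dimensional per-category treatment coordinates
#'
#' For every functional category with at least \code{minCategorySize} DE
#' genes, the treatment's mean log2FC against the healthy control (x) and
#' against the disease control (y) over the category's DE genes, plus the
#' [efficiencyScore()]. Displacement along y corresponds to desirable
#' distance from the diseased state; displacement along x to undesirable
#' distance from health. Categories with too few DE genes are skipped.
#'
#' @param lfcVsWt,lfcVsTg named per-gene log2FC vectors of one treatment
#'   (vs healthy and vs disease control), on a common gene universe.
#' @param annotation an [AnnotationSet-class].
#' @param deGenes character vector: the DE genes the evaluation is
#'   restricted to.
#' @param minCategorySize smallest usable category (default 3).
#' @param mode,epsilon,cap passed to [efficiencyScore()].
#' @return data.frame with columns \code{category}, \code{nGenes},
#'   \code{x}, \code{y}, \code{score}, one row per retained category.
#' @export
category2DCoordinates <- function(lfcVsWt, lfcVsTg, annotation, deGenes,
                                  minCategorySize = 3L,
                                  mode = c("mean_of_abs", "abs_of_mean"),
                                  epsilon = 1e-8, cap = 12) {
    mode <- match.arg(mode)
    stopifnot(is(annotation, "AnnotationSet"))
    universe <- intersect(names(lfcVsWt), names(lfcVsTg))
    evalSet <- intersect(deGenes, universe)
    rows <- list()
    for (id in categoryIds(annotation)) {
        genes <- intersect(geneSets(annotation)[[id]], evalSet)
        if (length(genes) < minCategorySize) next
        rows[[id]] <- data.frame(
            category = id, nGenes = length(genes),
            x = mean(lfcVsWt[genes]), y = mean(lfcVsTg[genes]),
            score = efficiencyScore(lfcVsTg[genes], lfcVsWt[genes],
                                    mode = mode, epsilon = epsilon,
                                    cap = cap),
            stringsAsFactors = FALSE)
    }
    out <- if (length(rows)) do.call(rbind, rows)
           else data.frame(category = character(), nGenes = integer(),
                           x = numeric(), y = numeric(), score = numeric(),
                           stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
}

#' Per-treatment efficiency records over an annotation
#'
#' Convenience wrapper running [category2DCoordinates()] for every
#' treatment arm of a dual-baseline result.
#'
#' @param study the [ExpressionStudy-class].
#' @param de result of [dualBaseline()].
#' @param annotation an [AnnotationSet-class].
#' @param geneSubset gene subset to evaluate over (e.g. the full-union DE
#'   set); default: union of DE genes in either contrast.
#' @param config a [FrameworkConfig-class] supplying mode, epsilon and
#'   minimum category size.
#' @return data.frame with a leading \code{treatment} column.
#' @export
efficiencyTable <- function(study, de, annotation, geneSubset = NULL,
                            config = frameworkConfig()) {
    if (is.null(geneSubset))
        geneSubset <- union(deGenes(de$vsHealthy), deGenes(de$vsDisease))
    out <- list()
    for (tr in treatmentArms(study)) {
        rec <- category2DCoordinates(
            de$vsHealthy@log2FC[, tr], de$vsDisease@log2FC[, tr],
            annotation, geneSubset,
            minCategorySize = config@minCategorySize,
            mode = config@efficiencyMode, epsilon = config@epsilon)
        if (nrow(rec))
            out[[tr]] <- cbind(treatment = tr, rec,
                               stringsAsFactors = FALSE)
    }
    res <- if (length(out)) do.call(rbind, out)
           else data.frame(treatment = character(), category = character(),
                           nGenes = integer(), x = numeric(), y = numeric(),
                           score = numeric(), stringsAsFactors = FALSE)
    rownames(res) <- NULL
    res
}
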
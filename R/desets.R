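# Disease / extended / full-union DE gene sets, the per-treatment
# restored / not-restored / altered trichotomy, and exclusive (UpSet-style)
# multi-set intersections.

#' Build the three nested DE gene sets from a dual-baseline run
#'
#' \code{diseaseSet}: genes DE in disease vs the healthy control (the
#' disease-associated profile). \code{extendedWtSet}: genes DE vs the
#' healthy control in disease or in at least one treatment.
#' \code{fullUnionSet}: additionally includes genes DE vs the disease
#' control in at least one treatment.
#'
#' @param vsWt [ContrastResult-class] with the healthy control as baseline.
#' @param vsTg [ContrastResult-class] with the disease control as baseline.
#' @return list of three sorted character vectors: \code{diseaseSet},
#'   \code{extendedWtSet}, \code{fullUnionSet} (nested by construction).
#' @export
buildDESets <- function(vsWt, vsTg) {
    stopifnot(is(vsWt, "ContrastResult"), is(vsTg, "ContrastResult"))
    if (!identical(sort(rownames(vsWt@de)), sort(rownames(vsTg@de))))
        stop("the two contrast results cover different gene universes")
    diseaseCond <- vsTg@baseline
    if (!diseaseCond %in% colnames(vsWt@de))
        stop("disease condition '", diseaseCond,
             "' absent from the vs-healthy contrast")
    diseaseSet <- deGenes(vsWt, diseaseCond)
    extendedWtSet <- deGenes(vsWt)
    treatments <- setdiff(colnames(vsTg@de), vsWt@baseline)
    fullUnionSet <- sort(union(extendedWtSet,
                               if (length(treatments))
                                   deGenes(vsTg, treatments)
                               else character()))
    list(diseaseSet = diseaseSet, extendedWtSet = extendedWtSet,
         fullUnionSet = fullUnionSet)
}

#' Restored / not-restored / altered trichotomy for one treatment
#'
#' Relative to the healthy baseline: \code{restored} are disease genes no
#' longer DE under the treatment; \code{notRestored} are disease genes
#' still DE; \code{altered} are genes DE under the treatment that are not
#' disease-associated (secondary, off-target effects).
#'
#' @param diseaseSet genes DE in disease vs healthy control.
#' @param treatmentDeVsWt genes DE in the treatment vs healthy control.
#' @param treatmentDeVsTg optional: genes DE in the treatment vs the
#'   disease control; when supplied, these are additionally counted as
#'   altered (the more inclusive reading of off-target effects).
#' @return list of three disjoint sorted character vectors
#'   (\code{restored}, \code{notRestored}, \code{altered});
#'   restored + notRestored partition the disease set.
#' @export
trichotomize <- function(diseaseSet, treatmentDeVsWt,
                         treatmentDeVsTg = NULL) {
    altered <- setdiff(treatmentDeVsWt, diseaseSet)
    if (!is.null(treatmentDeVsTg))
        altered <- union(altered, setdiff(treatmentDeVsTg, diseaseSet))
    list(restored = sort(setdiff(diseaseSet, treatmentDeVsWt)),
         notRestored = sort(intersect(diseaseSet, treatmentDeVsWt)),
         altered = sort(altered))
}

#' Trichotomy for every treatment arm of a study
#'
#' @param study the [ExpressionStudy-class] the contrasts came from.
#' @param vsWt [ContrastResult-class] against the healthy control.
#' @param vsTg optional [ContrastResult-class] against the disease control
#'   for the inclusive altered mode (default NULL: altered is defined
#'   against the healthy baseline only).
#' @return named list, treatment -> [trichotomize()] result.
#' @export
trichotomizeAll <- function(study, vsWt, vsTg = NULL) {
    diseaseSet <- deGenes(vsWt, diseaseControl(study))
    out <- lapply(treatmentArms(study), function(tr)
        trichotomize(diseaseSet, deGenes(vsWt, tr),
                     if (!is.null(vsTg)) deGenes(vsTg, tr)))
    names(out) <- treatmentArms(study)
    out
}

#' Exclusive multi-set intersections (UpSet semantics)
#'
#' For every non-empty combination of the input sets, counts the elements
#' belonging to exactly that combination; counts sum to the size of the
#' union.
#'
#' @param namedSets named list of character vectors (>= 1 set).
#' @return data.frame with columns \code{combination} (set names joined by
#'   "&"), \code{degree} and \code{count}, sorted by decreasing count then
#'   combination.
#' @export
exclusiveIntersections <- function(namedSets) {
    stopifnot(length(namedSets) >= 1L, !is.null(names(namedSets)))
    universe <- unique(unlist(namedSets, use.names = FALSE))
    if (!length(universe))
        return(data.frame(combination = character(), degree = integer(),
                          count = integer(), stringsAsFactors = FALSE))
    membership <- vapply(namedSets, function(s) universe %in% s,
                         logical(length(universe)))
    if (is.null(dim(membership)))
        membership <- matrix(membership, nrow = length(universe),
                             dimnames = list(NULL, names(namedSets)))
    sig <- apply(membership, 1, function(row)
        paste(names(namedSets)[row], collapse = "&"))
    counts <- table(sig)
    out <- data.frame(combination = names(counts),
                      degree = lengths(strsplit(names(counts), "&",
                                                fixed = TRUE)),
                      count = as.integer(counts),
                      stringsAsFactors = FALSE)
    out <- out[order(-out$count, out$combination), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Total (non-exclusive) pairwise-and-higher set overlaps
#'
#' Complements [exclusiveIntersections()]: for every combination of 2 or
#' more sets, the size of the plain intersection (a gene may contribute to
#' several combinations).
#'
#' @param namedSets named list of character vectors.
#' @param maxDegree largest combination size to report (default 2:
#'   pairwise overlaps).
#' @return data.frame with columns \code{combination}, \code{degree},
#'   \code{count}.
#' @export
setOverlaps <- function(namedSets, maxDegree = 2L) {
    nm <- names(namedSets)
    stopifnot(length(nm) >= 2L)
    out <- list()
    for (d in 2:min(maxDegree, length(nm))) {
        for (combo in utils::combn(nm, d, simplify = FALSE)) {
            count <- length(Reduce(intersect, namedSets[combo]))
            out[[length(out) + 1L]] <-
                data.frame(combination = paste(combo, collapse = "&"),
                           degree = d, count = count,
                           stringsAsFactors = FALSE)
        }
    }
    do.call(rbind, out)
}
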
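# Dual-baseline differential expression: one-way ANOVA across all
# conditions with Dunnett many-to-one comparisons against a chosen
# baseline, run per gene on the log2 matrix.

#' Per-gene log2 fold-change between two conditions
#'
#' Values are already log2-scale, so the fold-change of a condition over a
#' baseline is the difference of group means.
#'
#' @param study an [ExpressionStudy-class].
#' @param condition,baseline condition labels from the design.
#' @return named numeric vector (one value per gene).
#' @examples
#' sim <- generateStudy(antiTNFStudyTruth(), nGenes = 1200, seed = 1)
#' head(log2fcProfile(sim$study, diseaseControl(sim$study),
#'                    healthyControl(sim$study)))
#' @export
log2fcProfile <- function(study, condition, baseline) {
    cond <- sampleConditions(study)
    for (lab in c(condition, baseline))
        if (!lab %in% cond)
            stop("unknown condition label: ", lab)
    m <- assay(study, "log2expr")
    rowMeans(m[, cond == condition, drop = FALSE]) -
        rowMeans(m[, cond == baseline, drop = FALSE])
}

# Family-wise adjusted p-values for Dunnett many-to-one two-sided
# comparisons: P(max_j |T_j| >= t) under the multivariate t null with the
# design's correlation structure. A single comparison reduces exactly to
# the two-sided t distribution; otherwise the tail is evaluated with
# mvtnorm::pmvt on a |t| grid (quasi-Monte-Carlo tolerance 1e-5, run under
# a fixed local RNG state so results are reproducible) and interpolated.
# Grids are cached per (correlation, df) design within a session.
.dunnettGridCache <- new.env(parent = emptyenv())

.dunnettGrid <- function(corr, df, grid) {
    key <- paste(c(signif(corr, 12), df), collapse = ",")
    hit <- get0(key, envir = .dunnettGridCache)
    if (!is.null(hit)) return(hit)
    m <- ncol(corr)
    oldSeed <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(oldSeed))
        assign(".Random.seed", oldSeed, envir = globalenv()))
    set.seed(181081L)
    alg <- mvtnorm::GenzBretz(abseps = 1e-5, maxpts = 50000L)
    pGrid <- vapply(grid, function(tt) {
        if (tt == 0) return(1)
        1 - mvtnorm::pmvt(lower = rep(-tt, m), upper = rep(tt, m),
                          df = as.integer(df), corr = corr,
                          algorithm = alg)[1]
    }, numeric(1))
    pGrid <- pmin(pmax(cummin(pGrid), 0), 1)
    assign(key, pGrid, envir = .dunnettGridCache)
    pGrid
}

.dunnettAdjust <- function(tAbs, corr, df) {
    m <- ncol(corr)
    if (m == 1L)
        return(2 * stats::pt(-tAbs, df = df))
    tCap <- 12
    grid <- seq(0, tCap, by = 0.05)
    pGrid <- .dunnettGrid(corr, df, grid)
    out <- stats::approx(grid, pGrid, xout = pmin(tAbs, tCap),
                         rule = 2)$y
    out[tAbs > tCap] <- 0
    out
}

#' One-way ANOVA with Dunnett many-to-one contrasts per gene
#'
#' For every gene, all conditions are modelled with a common
#' (pooled-variance) one-way layout; each non-baseline condition is
#' compared against the baseline and the per-gene family of comparisons is
#' adjusted with Dunnett's two-sided many-to-one multivariate-t
#' correction. Genes with zero total variance are defined non-significant
#' (log2FC 0, p 1).
#'
#' @param study an [ExpressionStudy-class]; every condition needs >= 2
#'   samples.
#' @param baseline condition label used as the control of the comparisons.
#' @param config a [FrameworkConfig-class]; supplies the DE thresholds and
#'   the optional across-gene BH flag (\code{geneFDR}).
#' @return a [ContrastResult-class] with one column per non-baseline
#'   condition.
#' @examples
#' sim <- generateStudy(antiTNFStudyTruth(), nGenes = 1200, seed = 1)
#' res <- anovaDunnett(sim$study, baseline = healthyControl(sim$study))
#' res
#' @export
anovaDunnett <- function(study, baseline, config = frameworkConfig()) {
    cond <- sampleConditions(study)
    if (!baseline %in% cond)
        stop("unknown baseline condition: ", baseline)
    counts <- table(cond)
    tooFew <- names(counts)[counts < 2L]
    if (length(tooFew))
        stop("condition(s) with fewer than 2 samples: ",
             paste(tooFew, collapse = ", "))
    m <- assay(study, "log2expr")
    condLevels <- unique(cond)
    others <- setdiff(condLevels, baseline)
    k <- length(condLevels)
    N <- ncol(m)
    df <- N - k

    groupMeans <- vapply(condLevels, function(cn)
        rowMeans(m[, cond == cn, drop = FALSE]), numeric(nrow(m)))
    n <- as.numeric(counts[condLevels])
    names(n) <- condLevels
    # residual sum of squares of the one-way layout, vectorised over genes
    sse <- rowSums(m^2) - as.vector(groupMeans^2 %*% n)
    sse <- pmax(sse, 0)
    mse <- sse / df

    lfc <- groupMeans[, others, drop = FALSE] - groupMeans[, baseline]
    se <- sqrt(outer(mse, 1 / n[others] + 1 / n[[baseline]]))
    tStat <- lfc / se
    tStat[se == 0 & lfc == 0] <- 0
    tStat[se == 0 & lfc != 0] <- Inf

    rawP <- 2 * stats::pt(-abs(tStat), df = df)
    nO <- n[others]
    corr <- 1 / sqrt(outer(1 + n[[baseline]] / nO,
                           1 + n[[baseline]] / nO))
    diag(corr) <- 1
    adjP <- matrix(.dunnettAdjust(abs(as.vector(tStat)), corr, df),
                   nrow = nrow(tStat), dimnames = dimnames(tStat))
    adjP <- pmax(adjP, rawP)

    totVar <- rowSums((m - rowMeans(m))^2)
    zero <- totVar == 0
    if (any(zero)) {
        lfc[zero, ] <- 0
        rawP[zero, ] <- 1
        adjP[zero, ] <- 1
    }
    if (config@geneFDR)
        adjP <- apply(adjP, 2, stats::p.adjust, method = "BH")

    de <- abs(lfc) >= config@lfcThreshold & adjP <= config@pThreshold
    new("ContrastResult", baseline = baseline, log2FC = lfc, rawP = rawP,
        adjP = adjP, de = de, lfcThreshold = config@lfcThreshold,
        pThreshold = config@pThreshold)
}

#' Differential expression against both controls
#'
#' Runs [anovaDunnett()] twice on the same gene universe: once with the
#' healthy control as baseline (quantifying departure from the healthy
#' state, including the disease-vs-healthy contrast) and once with the
#' disease control as baseline (quantifying response relative to the
#' untreated diseased state).
#'
#' @param study an [ExpressionStudy-class] with both control roles.
#' @param config a [FrameworkConfig-class].
#' @return list with elements \code{vsHealthy} and \code{vsDisease}, both
#'   [ContrastResult-class].
#' @examples
#' sim <- generateStudy(antiTNFStudyTruth(), nGenes = 1200, seed = 1)
#' de <- dualBaseline(sim$study)
#' length(deGenes(de$vsHealthy, diseaseControl(sim$study)))
#' @export
dualBaseline <- function(study, config = frameworkConfig()) {
    list(vsHealthy = anovaDunnett(study, healthyControl(study), config),
         vsDisease = anovaDunnett(study, diseaseControl(study), config))
}
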
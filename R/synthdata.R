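# Synthetic treatment studies with planted ground truth. The generator
# emulates the design the framework targets: a healthy control arm, a
# diseased control arm with planted over-/under-expressed gene blocks, and
# several treatment arms that each restore a known fraction of the disease
# signature to healthy levels, reverse a known fraction to the opposite
# sign, and displace a treatment-specific "altered" block that is silent
# in disease.

#' Construct a SyntheticTruth
#'
#' @param diseaseUp,diseaseDown character vectors of planted disease-gene
#'   identifiers (disjoint).
#' @param altered named list, treatment -> character vector of
#'   treatment-specific altered genes (disjoint from the disease blocks).
#' @param restorationFraction numeric matrix treatments x c("up","down")
#'   in [0,1]: fraction of each disease block returned to the healthy mean.
#' @param reversalFraction named numeric per treatment: fraction of each
#'   disease block flipped to the opposite sign (restoration + reversal
#'   <= 1).
#' @param effectSize planted |log2FC| magnitude (default 2.5).
#' @param noiseSd residual standard deviation on log2 scale (default 0.25).
#' @param groupSizes named integer vector, condition -> replicates.
#' @param healthyControl,diseaseControl labels of the two control
#'   conditions within \code{groupSizes}.
#' @param timing named character per treatment, "prophylactic" or
#'   "therapeutic".
#' @return a validated [SyntheticTruth-class].
#' @export
syntheticTruth <- function(diseaseUp, diseaseDown, altered,
                           restorationFraction, reversalFraction,
                           effectSize = 2.5, noiseSd = 0.25,
                           groupSizes, healthyControl = "WT",
                           diseaseControl = "TG", timing = NULL) {
    trts <- rownames(restorationFraction)
    if (is.null(timing))
        timing <- stats::setNames(rep("therapeutic", length(trts)), trts)
    new("SyntheticTruth", diseaseUp = diseaseUp, diseaseDown = diseaseDown,
        altered = altered, restorationFraction = restorationFraction,
        reversalFraction = reversalFraction,
        effectSize = as.numeric(effectSize), noiseSd = as.numeric(noiseSd),
        groupSizes = stats::setNames(as.integer(groupSizes),
                                     names(groupSizes)),
        healthyControl = healthyControl, diseaseControl = diseaseControl,
        timing = timing)
}

#' A ready-made truth mirroring the reference study design
#'
#' Five anti-TNF-like arms against 10 healthy and 13 diseased controls:
#' four therapeutic arms of 10 replicates and one prophylactic arm of 3.
#' The disease signature has 404 over- and 463 under-expressed genes.
#' Restoration fractions are chosen so the expected per-arm counts of
#' non-restored disease genes are 3 (prophylactic), 25, 92, 106 and 175,
#' and treatment-specific altered blocks have sizes 170, 0, 30, 217 and
#' 175. The prophylactic arm carries the only non-zero reversal fraction
#' (its non-restored genes flip sign) and its altered block is displaced
#' opposite to the nominal direction, emulating the over-compensation seen
#' with early intervention.
#'
#' @param effectSize,noiseSd planted effect magnitude and residual noise
#'   (defaults 2.5 and 0.25 on log2 scale).
#' @return a [SyntheticTruth-class].
#' @examples
#' antiTNFStudyTruth()
#' @export
antiTNFStudyTruth <- function(effectSize = 2.5, noiseSd = 0.25) {
    up <- sprintf("dup%04d", seq_len(404))
    down <- sprintf("ddn%04d", seq_len(463))
    trts <- c("infliximab_p", "infliximab", "adalimumab", "etanercept",
              "certolizumab")
    notRestored <- c(infliximab_p = 3, infliximab = 25, adalimumab = 92,
                     etanercept = 106, certolizumab = 175)
    restore <- 1 - notRestored / (404 + 463)
    restorationFraction <- cbind(up = restore, down = restore)
    reversalFraction <- c(infliximab_p = 3 / (404 + 463), infliximab = 0,
                          adalimumab = 0, etanercept = 0, certolizumab = 0)
    alteredSizes <- c(infliximab_p = 170, infliximab = 0, adalimumab = 30,
                      etanercept = 217, certolizumab = 175)
    offset <- 0L
    altered <- lapply(trts, function(tr) {
        n <- alteredSizes[[tr]]
        ids <- if (n > 0) sprintf("alt%04d", offset + seq_len(n))
               else character()
        offset <<- offset + n
        ids
    })
    names(altered) <- trts
    syntheticTruth(
        diseaseUp = up, diseaseDown = down, altered = altered,
        restorationFraction = restorationFraction,
        reversalFraction = reversalFraction,
        effectSize = effectSize, noiseSd = noiseSd,
        groupSizes = c(WT = 10L, TG = 13L, infliximab_p = 3L,
                       infliximab = 10L, adalimumab = 10L,
                       etanercept = 10L, certolizumab = 10L),
        timing = c(infliximab_p = "prophylactic",
                   infliximab = "therapeutic", adalimumab = "therapeutic",
                   etanercept = "therapeutic",
                   certolizumab = "therapeutic"))
}

# deterministic subset of the first round(frac * n) elements of a
# pre-shuffled vector; the shuffle itself consumes the seeded stream
.takeFraction <- function(x, frac) x[seq_len(round(frac * length(x)))]

#' Generate a synthetic expression study from a planted truth
#'
#' Healthy-control samples draw around gene-specific baseline means
#' (Uniform(4, 12) on log2 scale) with independent Gaussian noise. The
#' disease control adds +/- \code{effectSize} on the disease blocks. Each
#' treatment arm returns a restoration fraction of each disease block to
#' the healthy mean, flips a reversal fraction to the opposite sign,
#' leaves the remainder at the diseased level, and displaces its own
#' altered block by \code{effectSize} (opposite direction for prophylactic
#' arms). The returned annotation contains one category per planted block
#' plus decoy categories of random genes. Identical inputs give identical
#' output.
#'
#' @param truth a [SyntheticTruth-class].
#' @param nGenes total genes (>= number of planted genes); non-planted
#'   genes are pure-noise background.
#' @param seed integer seed controlling all randomness.
#' @param nDecoys,decoySizeRange decoy categories: how many random gene
#'   sets and their size range (defaults 50 sets of 10..200 genes).
#' @return list with elements \code{study} ([ExpressionStudy-class]),
#'   \code{annotation} ([AnnotationSet-class]), \code{truth}, and
#'   \code{planted}: per-treatment lists of the realised restored /
#'   reversed / notRestored / altered gene sets.
#' @examples
#' sim <- generateStudy(antiTNFStudyTruth(), nGenes = 1500, seed = 7)
#' sim$study
#' @export
generateStudy <- function(truth, nGenes, seed, nDecoys = 50L,
                          decoySizeRange = c(10L, 200L)) {
    stopifnot(is(truth, "SyntheticTruth"))
    validObject(truth)
    planted <- c(truth@diseaseUp, truth@diseaseDown,
                 unlist(truth@altered, use.names = FALSE))
    if (anyDuplicated(c(truth@diseaseUp, truth@diseaseDown)))
        stop("overlapping disease blocks in truth")
    if (nGenes < length(planted))
        stop("nGenes must be >= number of planted genes (",
             length(planted), ")")
    genes <- c(planted,
               sprintf("bg%05d", seq_len(nGenes - length(planted))))

    oldSeed <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(oldSeed))
        assign(".Random.seed", oldSeed, envir = globalenv()))
    set.seed(as.integer(seed))

    mu <- stats::setNames(stats::runif(nGenes, 4, 12), genes)
    sgn <- stats::setNames(rep(0, nGenes), genes)
    sgn[truth@diseaseUp] <- 1
    sgn[truth@diseaseDown] <- -1

    conds <- names(truth@groupSizes)
    trts <- rownames(truth@restorationFraction)
    # per-arm realised gene fates, drawn once from the seeded stream
    plantedSets <- list()
    delta <- matrix(0, nGenes, length(conds),
                    dimnames = list(genes, conds))
    delta[truth@diseaseUp, truth@diseaseControl] <- truth@effectSize
    delta[truth@diseaseDown, truth@diseaseControl] <- -truth@effectSize
    for (tr in trts) {
        restored <- reversed <- character()
        for (dir in c("up", "down")) {
            block <- if (dir == "up") truth@diseaseUp else truth@diseaseDown
            shuffled <- sample(block)
            nRes <- round(truth@restorationFraction[tr, dir] * length(block))
            nRev <- round(truth@reversalFraction[[tr]] * length(block))
            restored <- c(restored, shuffled[seq_len(nRes)])
            if (nRev > 0)
                reversed <- c(reversed, shuffled[nRes + seq_len(nRev)])
        }
        stay <- setdiff(c(truth@diseaseUp, truth@diseaseDown),
                        c(restored, reversed))
        delta[stay, tr] <- truth@effectSize * sgn[stay]
        delta[reversed, tr] <- -truth@effectSize * sgn[reversed]
        alt <- truth@altered[[tr]]
        if (length(alt)) {
            altSign <- rep_len(c(1, -1), length(alt))
            if (identical(truth@timing[[tr]], "prophylactic"))
                altSign <- -altSign
            delta[alt, tr] <- truth@effectSize * altSign
        }
        plantedSets[[tr]] <- list(restored = sort(restored),
                                  reversed = sort(reversed),
                                  notRestored = sort(c(stay, reversed)),
                                  altered = sort(alt))
    }

    nTotal <- sum(truth@groupSizes)
    condOfSample <- rep(conds, times = truth@groupSizes[conds])
    sampleIds <- unlist(lapply(conds, function(cn)
        sprintf("%s_%02d", cn, seq_len(truth@groupSizes[[cn]]))))
    m <- mu + delta[, condOfSample, drop = FALSE] +
        matrix(stats::rnorm(nGenes * nTotal, sd = truth@noiseSd),
               nGenes, nTotal)
    colnames(m) <- sampleIds
    rownames(m) <- genes

    roles <- stats::setNames(rep("treatment", length(conds)), conds)
    roles[truth@healthyControl] <- "healthy_control"
    roles[truth@diseaseControl] <- "disease_control"
    timing <- stats::setNames(rep("none", length(conds)), conds)
    timing[names(truth@timing)] <- truth@timing
    design <- data.frame(sample = sampleIds, condition = condOfSample,
                         role = roles[condOfSample],
                         timing = timing[condOfSample],
                         stringsAsFactors = FALSE)
    study <- ExpressionStudy(m, design)

    sets <- list(disease_up = truth@diseaseUp,
                 disease_down = truth@diseaseDown)
    for (tr in trts)
        if (length(truth@altered[[tr]]))
            sets[[paste0("altered_", tr)]] <- truth@altered[[tr]]
    if (nDecoys > 0L) {
        decoySizes <- sample(decoySizeRange[1]:decoySizeRange[2], nDecoys,
                             replace = TRUE)
        decoySizes <- pmin(decoySizes, nGenes)
        for (i in seq_len(nDecoys))
            sets[[sprintf("decoy%03d", i)]] <- sort(sample(genes,
                                                           decoySizes[i]))
    }
    annotation <- AnnotationSet(sets, namespace = "planted")

    list(study = study, annotation = annotation, truth = truth,
         planted = plantedSets)
}
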
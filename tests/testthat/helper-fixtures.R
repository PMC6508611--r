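# Shared fixtures: tiny deterministic studies built in code, plus one
# lazily built emulated-design simulation reused across test files.

# 5 genes x 6 samples, two conditions per role, exact values
makeToyStudy <- function() {
    m <- rbind(
        g1 = c(1, 1, 3, 3, 2, 2),
        g2 = c(5, 5, 5, 5, 5, 5),
        g3 = c(2, 4, 1, 3, 2, 4),
        g4 = c(0, 0, 4, 4, 0, 0),
        g5 = c(8, 8, 6, 6, 7, 7))
    colnames(m) <- paste0("s", 1:6)
    design <- data.frame(
        sample = paste0("s", 1:6),
        condition = rep(c("WT", "TG", "TRT"), each = 2),
        role = rep(c("healthy_control", "disease_control", "treatment"),
                   each = 2),
        stringsAsFactors = FALSE)
    ExpressionStudy(m, design)
}

# noise-only or planted-shift study with arbitrary group sizes
makeNoiseStudy <- function(nGenes, groupSizes, noiseSd = 0.25, seed = 1,
                           shift = NULL) {
    set.seed(seed)
    conds <- names(groupSizes)
    condOf <- rep(conds, times = groupSizes)
    ids <- sprintf("g%04d", seq_len(nGenes))
    samples <- paste0("s", seq_along(condOf))
    m <- matrix(stats::rnorm(nGenes * length(condOf), mean = 8,
                             sd = noiseSd),
                nGenes, length(condOf), dimnames = list(ids, samples))
    if (!is.null(shift))
        for (cn in names(shift))
            m[shift[[cn]]$genes, condOf == cn] <-
                m[shift[[cn]]$genes, condOf == cn] + shift[[cn]]$delta
    roles <- stats::setNames(rep("treatment", length(conds)), conds)
    roles[conds[1]] <- "healthy_control"
    roles[conds[2]] <- "disease_control"
    design <- data.frame(sample = samples, condition = condOf,
                         role = roles[condOf], stringsAsFactors = FALSE)
    ExpressionStudy(m, design)
}

jaccard <- function(a, b) {
    u <- union(a, b)
    if (!length(u)) return(1)
    length(intersect(a, b)) / length(u)
}

# one moderate emulated-design simulation + its dual-baseline DE, shared
# across test files (built on first use)
.sharedEnv <- new.env()
sharedSim <- function() {
    if (is.null(.sharedEnv$sim))
        .sharedEnv$sim <- generateStudy(antiTNFStudyTruth(), nGenes = 1600,
                                        seed = 42)
    .sharedEnv$sim
}
sharedDE <- function() {
    if (is.null(.sharedEnv$de))
        .sharedEnv$de <- dualBaseline(sharedSim()$study)
    .sharedEnv$de
}
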
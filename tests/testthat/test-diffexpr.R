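# Dual-baseline differential expression: log2FC arithmetic, the
# ANOVA+Dunnett machinery and its oracles.

test_that("log2FC is the difference of group means on log2 scale", {
    study <- makeToyStudy()
    expect_equal(unname(log2fcProfile(study, "TG", "WT")["g1"]), 2)
    expect_equal(unname(log2fcProfile(study, "TG", "WT")["g4"]), 4)
    expect_equal(log2fcProfile(study, "WT", "WT"),
                 stats::setNames(rep(0, 5), rownames(study)))
    expect_error(log2fcProfile(study, "nope", "WT"), "unknown condition")
})

test_that("adding a constant to one condition shifts its log2FC exactly", {
    study <- makeToyStudy()
    base <- log2fcProfile(study, "TG", "WT")
    m <- assay(study)
    m[, sampleConditions(study) == "TG"] <-
        m[, sampleConditions(study) == "TG"] + 1.7
    shifted <- ExpressionStudy(m, data.frame(
        sample = colnames(study), condition = colData(study)$condition,
        role = colData(study)$role))
    expect_equal(log2fcProfile(shifted, "TG", "WT"), base + 1.7)
})

test_that("constant genes are defined non-significant", {
    m <- matrix(5, nrow = 3, ncol = 6,
                dimnames = list(paste0("g", 1:3), paste0("s", 1:6)))
    design <- data.frame(sample = paste0("s", 1:6),
                         condition = rep(c("WT", "TG", "A"), each = 2),
                         role = rep(c("healthy_control", "disease_control",
                                      "treatment"), each = 2))
    res <- anovaDunnett(ExpressionStudy(m, design), "WT")
    expect_true(all(res@adjP == 1))
    expect_true(all(res@log2FC == 0))
    expect_length(deGenes(res), 0L)
})

test_that("with a single comparison Dunnett reduces to the pooled t-test", {
    set.seed(11)
    study <- makeNoiseStudy(40, c(WT = 4L, TG = 5L), noiseSd = 1)
    res <- anovaDunnett(study, "WT")
    m <- assay(study)
    cond <- sampleConditions(study)
    pOracle <- vapply(rownames(m), function(g)
        stats::t.test(m[g, cond == "TG"], m[g, cond == "WT"],
                      var.equal = TRUE)$p.value, numeric(1))
    expect_equal(unname(res@adjP[, "TG"]), unname(pOracle),
                 tolerance = 1e-6)
    expect_equal(res@rawP, res@adjP)
})

test_that("Dunnett adjusted p agrees with the multcomp oracle", {
    skip_if_not_installed("multcomp")
    set.seed(7)
    study <- makeNoiseStudy(25, c(WT = 5L, TG = 4L, A = 6L, B = 3L),
                            noiseSd = 1)
    res <- anovaDunnett(study, "WT")
    m <- assay(study)
    grp <- factor(sampleConditions(study), levels = c("WT", "TG", "A", "B"))
    for (g in rownames(m)[1:10]) {
        fit <- stats::aov(m[g, ] ~ grp)
        glt <- multcomp::glht(fit, linfct = multcomp::mcp(grp = "Dunnett"))
        pOracle <- summary(glt)$test$pvalues
        expect_equal(unname(res@adjP[g, c("TG", "A", "B")]),
                     as.numeric(pOracle), tolerance = 1e-3)
    }
})

test_that("Dunnett adjustment matches a brute-force max-|t| null", {
    # 3 conditions x 4 replicates: estimate P(max |T_j| >= t) by
    # simulating the one-way null directly, and compare with the
    # multivariate-t evaluation at a few fixed t values
    groups <- rep(1:3, each = 4)
    nDraws <- 1e6L
    chunk <- 1e5L
    tRef <- c(1.5, 2.0, 2.5, 3.0)
    exceed <- matrix(0, length(tRef), 1)
    set.seed(99)
    done <- 0L
    while (done < nDraws) {
        nb <- min(chunk, nDraws - done)
        x <- matrix(stats::rnorm(nb * 12L), nb, 12L)
        gm <- vapply(1:3, function(g)
            rowMeans(x[, groups == g, drop = FALSE]), numeric(nb))
        sse <- rowSums(x^2) - 4 * rowSums(gm^2)
        mse <- sse / 9
        se <- sqrt(mse * (1 / 4 + 1 / 4))
        tmax <- pmax(abs(gm[, 2] - gm[, 1]), abs(gm[, 3] - gm[, 1])) / se
        exceed <- exceed + vapply(tRef, function(tt) sum(tmax >= tt),
                                  numeric(1))
        done <- done + nb
    }
    pMC <- as.numeric(exceed) / nDraws
    corr <- matrix(0.5, 2, 2); diag(corr) <- 1
    pPkg <- TxProfiler:::.dunnettAdjust(tRef, corr, df = 9)
    expect_lt(max(abs(pPkg - pMC)), 1e-3)
})

test_that("reversing condition and baseline negates log2FC, keeps p", {
    set.seed(3)
    study <- makeNoiseStudy(30, c(WT = 4L, TG = 4L), noiseSd = 1)
    a <- anovaDunnett(study, "WT")
    b <- anovaDunnett(study, "TG")
    expect_equal(a@log2FC[, "TG"], -b@log2FC[, "WT"])
    expect_equal(a@adjP[, "TG"], b@adjP[, "WT"], tolerance = 1e-12)
})

test_that("relaxing thresholds never shrinks the DE set", {
    de <- sharedDE()$vsHealthy
    strict <- deGenes(de)
    study <- sharedSim()$study
    lax <- anovaDunnett(study, "WT",
                        frameworkConfig(lfcThreshold = 0.5,
                                        pThreshold = 0.2))
    expect_true(all(strict %in% deGenes(lax)))
})

test_that("conditions with fewer than two samples are design errors", {
    m <- matrix(rnorm(15), 3, 5,
                dimnames = list(paste0("g", 1:3), paste0("s", 1:5)))
    design <- data.frame(sample = paste0("s", 1:5),
                         condition = c("WT", "WT", "TG", "TG", "A"),
                         role = c("healthy_control", "healthy_control",
                                  "disease_control", "disease_control",
                                  "treatment"))
    expect_error(anovaDunnett(ExpressionStudy(m, design), "WT"), "A")
})

test_that("swapping the control roles swaps the dual-baseline outputs", {
    study <- makeToyStudy()
    de <- dualBaseline(study)
    cd <- colData(study)
    swapped <- ExpressionStudy(assay(study), data.frame(
        sample = colnames(study), condition = cd$condition,
        role = ifelse(cd$role == "healthy_control", "disease_control",
                      ifelse(cd$role == "disease_control",
                             "healthy_control", cd$role))))
    deSwapped <- dualBaseline(swapped)
    expect_equal(de$vsHealthy@log2FC, deSwapped$vsDisease@log2FC)
    expect_equal(de$vsDisease@adjP, deSwapped$vsHealthy@adjP)
})

test_that("the optional across-gene BH correction only raises adjusted p", {
    set.seed(5)
    study <- makeNoiseStudy(50, c(WT = 3L, TG = 3L, A = 3L), noiseSd = 1)
    plain <- anovaDunnett(study, "WT")
    fdr <- anovaDunnett(study, "WT", frameworkConfig(geneFDR = TRUE))
    expect_true(all(fdr@adjP >= plain@adjP - 1e-12))
    expect_true(all(fdr@adjP >= fdr@rawP - 1e-12))
})
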
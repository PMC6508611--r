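# Feature construction, repeated random-forest selection, importance
# ranking and the PCA embedding.

separableFeatures <- function(seed = 1, nFeatures = 20L, nSignal = 5L,
                              shift = 6) {
    set.seed(seed)
    samples <- paste0("s", 1:20)
    labels <- stats::setNames(rep(c("A", "B"), each = 10), samples)
    x <- matrix(rnorm(nFeatures * 20), nFeatures, 20,
                dimnames = list(paste0("f", seq_len(nFeatures)), samples))
    signal <- paste0("f", seq_len(nSignal))
    x[signal, labels == "B"] <- x[signal, labels == "B"] + shift
    new("FeatureTable", level = "gene", values = x, labels = labels)
}

test_that("category features are mean expression over DE members", {
    m <- matrix(as.numeric(1:12), 3, 4,
                dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
    design <- data.frame(sample = paste0("s", 1:4),
                         condition = rep(c("WT", "TG"), each = 2),
                         role = rep(c("healthy_control", "disease_control"),
                                    each = 2))
    study <- ExpressionStudy(m, design)
    ann <- AnnotationSet(list(one = "g2", three = paste0("g", 1:3),
                              out = "gX"))
    ft <- categoryFeatures(study, ann, deGenes = paste0("g", 1:3),
                           minCategorySize = 1L)
    expect_identical(rownames(ft@values), c("one", "three"))
    expect_equal(ft@values["one", ], m["g2", ])
    expect_equal(ft@values["three", ], colMeans(m))
    # categories entirely outside the DE set never become features
    ftDE <- categoryFeatures(study, ann, deGenes = "g2",
                             minCategorySize = 1L)
    expect_identical(rownames(ftDE@values), c("one", "three"))
    expect_equal(ftDE@values["three", ], m["g2", ])
    expect_error(categoryFeatures(study, ann, deGenes = "g1",
                                  minCategorySize = 3L), "no category")
})

test_that("a planted separable class is classified perfectly", {
    ft <- separableFeatures(shift = 8)
    res <- rfSelect(ft, frameworkConfig(rfModels = 10L, rfTrees = 100L,
                                        rfMtry = 5L), seed = 1)
    expect_equal(res@oobError, 0)
    expect_equal(res@testAccuracy, 1)
    expect_identical(sum(res@confusionTest), 6L)  # 30% of 20
    expect_equal(sum(diag(res@confusionTest)), sum(res@confusionTest))
    expect_true(all(topImportant(res, 3L) %in% paste0("f", 1:5)))
})

test_that("repeated selection is reproducible and picks a sane winner", {
    ft <- separableFeatures(seed = 3, shift = 2)
    cfg <- frameworkConfig(rfModels = 8L, rfTrees = 80L, rfMtry = 4L)
    r1 <- rfSelect(ft, cfg, seed = 11)
    r2 <- rfSelect(ft, cfg, seed = 11)
    expect_identical(r1@oobErrors, r2@oobErrors)
    expect_identical(r1@importance, r2@importance)
    expect_identical(r1@modelIndex, r2@modelIndex)
    expect_equal(r1@oobError, min(r1@oobErrors))
    expect_lte(r1@oobError, stats::median(r1@oobErrors))
    # confusion rows sum to the per-condition test counts
    expect_identical(unname(rowSums(r1@confusionTest)), c(3, 3))
})

test_that("permuted labels drop accuracy to chance", {
    ft <- separableFeatures(seed = 5, shift = 8)
    accs <- vapply(1:10, function(s) {
        set.seed(1000 + s)
        perm <- ft
        perm@labels[] <- sample(ft@labels)
        names(perm@labels) <- names(ft@labels)
        rfSelect(perm, frameworkConfig(rfModels = 3L, rfTrees = 60L,
                                       rfMtry = 4L), seed = s)@testAccuracy
    }, numeric(1))
    expect_lt(mean(accs), 0.5 + 0.25)  # max class freq 0.5 +/- MC error
    expect_gt(mean(accs), 0.5 - 0.25)
})

test_that("a single informative feature among 99 noise features ranks first", {
    firsts <- vapply(1:10, function(s) {
        set.seed(3000 + s)
        samples <- paste0("s", 1:20)
        labels <- stats::setNames(rep(c("A", "B"), each = 10), samples)
        x <- matrix(rnorm(100 * 20), 100, 20,
                    dimnames = list(paste0("f", 1:100), samples))
        x["f1", labels == "B"] <- x["f1", labels == "B"] + 6
        ft <- new("FeatureTable", level = "gene", values = x,
                  labels = labels)
        res <- rfSelect(ft, frameworkConfig(rfModels = 3L, rfTrees = 200L,
                                            rfMtry = 10L), seed = s)
        topImportant(res, 1L) == "f1"
    }, logical(1))
    expect_gte(sum(firsts), 9L)
})

test_that("mtry is clamped to the feature count with a message", {
    ft <- separableFeatures(nFeatures = 4L, nSignal = 2L, shift = 8)
    expect_message(res <- rfSelect(ft, frameworkConfig(rfModels = 2L,
                                                       rfTrees = 50L,
                                                       rfMtry = 10L),
                                   seed = 1), "clamped")
    expect_equal(res@testAccuracy, 1)
})

test_that("single-sample classes are design errors", {
    x <- matrix(rnorm(15), 3, 5,
                dimnames = list(paste0("f", 1:3), paste0("s", 1:5)))
    labels <- stats::setNames(c("A", "A", "B", "B", "C"), paste0("s", 1:5))
    ft <- new("FeatureTable", level = "gene", values = x, labels = labels)
    expect_error(rfSelect(ft, frameworkConfig(rfModels = 2L)), "C")
})

test_that("topImportant ranks stably and checks its range", {
    ft <- separableFeatures(shift = 8)
    res <- rfSelect(ft, frameworkConfig(rfModels = 4L, rfTrees = 80L,
                                        rfMtry = 5L), seed = 2)
    all <- topImportant(res, length(res@importance))
    expect_identical(sort(all), sort(rownames(ft@values)))
    expect_error(topImportant(res, 0L), "topN")
    expect_error(topImportant(res, length(all) + 1L), "topN")
    # ties in importance break alphabetically by feature id, independent
    # of the order the features arrive in
    tied <- new("ForestResult", oobError = 0, testAccuracy = 1,
                confusionTest = matrix(1, 1, 1),
                confusionOOB = matrix(1, 1, 1),
                importance = sort(c(fB = 2, fA = 2, fC = 5),
                                  decreasing = TRUE)[c("fC", "fA", "fB")],
                modelIndex = 1L, oobErrors = 0, level = "gene",
                seed = 1L)
    expect_identical(topImportant(tied, 3L), c("fC", "fA", "fB"))
})

test_that("rank-1 data collapse onto one principal component", {
    base <- rnorm(10)
    x <- rbind(f1 = base, f2 = 2 * base, f3 = -base)
    colnames(x) <- paste0("s", 1:10)
    labels <- stats::setNames(rep(c("A", "B"), 5), colnames(x))
    ft <- new("FeatureTable", level = "gene", values = x, labels = labels)
    expect_warning(emb <- pcaEmbed(ft), "1 component")
    expect_equal(emb$explained[1], 1)
})

test_that("PCA separates planted sample groups and respects rotations", {
    ft <- separableFeatures(seed = 9, shift = 10)
    emb <- pcaEmbed(ft)
    pc1 <- emb$coordinates$PC1
    groups <- ft@labels[emb$coordinates$sample]
    expect_true(max(pc1[groups == "A"]) < min(pc1[groups == "B"]) ||
                min(pc1[groups == "A"]) > max(pc1[groups == "B"]))
    expect_equal(sum(emb$explained <= 1), 2L)
    # joint orthogonal rotation of the feature space preserves scores
    set.seed(2)
    q <- qr.Q(qr(matrix(rnorm(nrow(ft@values)^2), nrow(ft@values))))
    rot <- ft
    rot@values <- t(q) %*% ft@values
    rownames(rot@values) <- rownames(ft@values)
    embRot <- pcaEmbed(rot)
    expect_equal(abs(embRot$coordinates$PC1), abs(pc1), tolerance = 1e-6)
})

test_that("pathway-aggregated features classify planted block signal at least as well as genes", {
    # weak per-gene signal planted block-wise in category-aligned genes:
    # averaging within blocks boosts the signal-to-noise ratio
    set.seed(13)
    nPerBlock <- 10L; nBlocks <- 6L
    samples <- paste0("s", 1:24)
    classes <- stats::setNames(rep(c("A", "B", "C"), each = 8), samples)
    genes <- sprintf("g%03d", seq_len(nPerBlock * nBlocks))
    m <- matrix(rnorm(length(genes) * 24, mean = 8, sd = 1),
                length(genes), 24, dimnames = list(genes, samples))
    blockOf <- rep(seq_len(nBlocks), each = nPerBlock)
    shift <- matrix(c(0.8, 0, -0.8, 0, 0.8, 0,
                      0, 0.8, 0, -0.8, 0, 0.8,
                      -0.8, -0.8, 0.8, 0.8, 0, 0), nBlocks, 3)
    for (b in seq_len(nBlocks))
        for (ci in 1:3)
            m[blockOf == b, classes == c("A", "B", "C")[ci]] <-
                m[blockOf == b, classes == c("A", "B", "C")[ci]] +
                shift[b, ci]
    design <- data.frame(sample = samples, condition = classes,
                         role = ifelse(classes == "A", "healthy_control",
                                ifelse(classes == "B", "disease_control",
                                       "treatment")))
    study <- ExpressionStudy(m, design)
    ann <- AnnotationSet(split(genes, blockOf))
    cfg <- frameworkConfig(rfModels = 10L, rfTrees = 150L, rfMtry = 3L)
    geneAcc <- rfSelect(geneFeatures(study, genes), cfg,
                        seed = 21)@testAccuracy
    catAcc <- rfSelect(categoryFeatures(study, ann, genes), cfg,
                       seed = 21)@testAccuracy
    expect_gte(catAcc, geneAcc)
})
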
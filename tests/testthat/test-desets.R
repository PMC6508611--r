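# DE set algebra: nested set collections, the trichotomy partition and
# exclusive intersections.

# a ContrastResult holding prescribed DE sets, for set-algebra tests
fakeContrast <- function(universe, baseline, deSets) {
    conds <- names(deSets)
    de <- vapply(conds, function(cn) universe %in% deSets[[cn]],
                 logical(length(universe)))
    if (is.null(dim(de)))
        de <- matrix(de, nrow = length(universe))
    dimnames(de) <- list(universe, conds)
    lfc <- ifelse(de, 2, 0)
    p <- ifelse(de, 0.01, 1)
    new("ContrastResult", baseline = baseline, log2FC = lfc, rawP = p,
        adjP = p, de = de, lfcThreshold = 1, pThreshold = 0.05)
}

test_that("the three DE sets nest and follow the union definitions", {
    universe <- paste0("g", 1:10)
    vsWt <- fakeContrast(universe, "WT",
                         list(TG = c("g1", "g2"), A = c("g2", "g3")))
    vsTg <- fakeContrast(universe, "TG",
                         list(WT = c("g1", "g2"), A = "g4"))
    sets <- buildDESets(vsWt, vsTg)
    expect_identical(sets$diseaseSet, c("g1", "g2"))
    expect_identical(sets$extendedWtSet, c("g1", "g2", "g3"))
    expect_identical(sets$fullUnionSet, c("g1", "g2", "g3", "g4"))
    expect_true(all(sets$diseaseSet %in% sets$extendedWtSet))
    expect_true(all(sets$extendedWtSet %in% sets$fullUnionSet))
})

test_that("with no treatments all three sets equal the disease set", {
    universe <- paste0("g", 1:6)
    vsWt <- fakeContrast(universe, "WT", list(TG = c("g1", "g5")))
    vsTg <- fakeContrast(universe, "TG", list(WT = c("g1", "g5")))
    sets <- buildDESets(vsWt, vsTg)
    expect_identical(sets$diseaseSet, sets$extendedWtSet)
    expect_identical(sets$diseaseSet, sets$fullUnionSet)
})

test_that("mismatched universes are consistency errors", {
    vsWt <- fakeContrast(paste0("g", 1:5), "WT", list(TG = "g1"))
    vsTg <- fakeContrast(paste0("g", 2:6), "TG", list(WT = "g2"))
    expect_error(buildDESets(vsWt, vsTg), "universe")
})

test_that("the trichotomy is the stated partition", {
    tri <- trichotomize(c("g1", "g2", "g3"), c("g3", "g4"))
    expect_identical(tri$restored, c("g1", "g2"))
    expect_identical(tri$notRestored, "g3")
    expect_identical(tri$altered, "g4")
    triEmpty <- trichotomize(c("g1", "g2"), character())
    expect_identical(triEmpty$restored, c("g1", "g2"))
    expect_length(triEmpty$notRestored, 0L)
    expect_length(triEmpty$altered, 0L)
})

test_that("trichotomy sets are disjoint and partition the disease set", {
    set.seed(2)
    for (i in 1:20) {
        disease <- sample(paste0("g", 1:50), 20)
        trt <- sample(paste0("g", 1:50), 15)
        tri <- trichotomize(disease, trt)
        expect_length(intersect(tri$restored, tri$notRestored), 0L)
        expect_length(intersect(tri$restored, tri$altered), 0L)
        expect_length(intersect(tri$notRestored, tri$altered), 0L)
        expect_identical(sort(c(tri$restored, tri$notRestored)),
                         sort(disease))
    }
})

test_that("the inclusive altered mode adds vs-disease-only calls", {
    tri <- trichotomize(c("g1", "g2"), c("g2", "g3"),
                        treatmentDeVsTg = c("g1", "g4"))
    expect_identical(tri$altered, c("g3", "g4"))
})

test_that("disjoint sets have only first-order exclusive intersections", {
    res <- exclusiveIntersections(list(A = c("a1", "a2"), B = "b1",
                                       C = c("c1", "c2", "c3")))
    expect_identical(sort(res$combination), c("A", "B", "C"))
    expect_identical(res$count[res$combination == "C"], 3L)
    expect_true(all(res$degree == 1L))
})

test_that("exclusive counts match a brute-force membership tally", {
    set.seed(8)
    for (i in 1:10) {
        sets <- lapply(1:4, function(j) sample(paste0("g", 1:50),
                                               sample(5:25, 1)))
        names(sets) <- LETTERS[1:4]
        res <- exclusiveIntersections(sets)
        universe <- unique(unlist(sets))
        # oracle: per-gene membership signature tally
        oracle <- table(vapply(universe, function(g)
            paste(names(sets)[vapply(sets, function(s) g %in% s,
                                     logical(1))], collapse = "&"),
            character(1)))
        expect_identical(sum(res$count), length(universe))
        for (j in seq_len(nrow(res)))
            expect_identical(res$count[j],
                             as.integer(oracle[[res$combination[j]]]))
        expect_identical(nrow(res), length(oracle))
    }
})

test_that("total overlaps report plain intersections", {
    sets <- list(A = c("g1", "g2", "g3"), B = c("g2", "g3", "g4"),
                 C = c("g3", "g5"))
    ov <- setOverlaps(sets, maxDegree = 3L)
    expect_identical(ov$count[ov$combination == "A&B"], 2L)
    expect_identical(ov$count[ov$combination == "A&B&C"], 1L)
})

test_that("trichotomy over the shared simulation recovers planted fates", {
    sim <- sharedSim()
    de <- sharedDE()
    tri <- trichotomizeAll(sim$study, de$vsHealthy)
    for (tr in names(tri)) {
        expect_identical(sort(c(tri[[tr]]$restored, tri[[tr]]$notRestored)),
                         sort(deGenes(de$vsHealthy, "TG")))
        expect_gt(jaccard(tri[[tr]]$notRestored,
                          sim$planted[[tr]]$notRestored), 0.8)
    }
})
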
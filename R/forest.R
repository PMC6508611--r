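# Repeated random-forest classification of samples by condition, at gene
# or functional-category level. Many independently seeded forests are
# trained on fresh stratified 70/30 splits; the winner by out-of-bag error
# supplies the confusion matrices and the Gini importance ranking.

#' Gene-level feature table
#'
#' One feature per DE gene: its log2 expression row across all samples.
#'
#' @param study an [ExpressionStudy-class].
#' @param genes character vector of feature genes (e.g. a DE set).
#' @param samples optional sample subset (default: all).
#' @return a [FeatureTable-class] with level "gene".
#' @export
geneFeatures <- function(study, genes, samples = colnames(study)) {
    m <- assay(study, "log2expr")
    bad <- setdiff(genes, rownames(m))
    if (length(bad))
        stop("genes absent from the study: ",
             paste(utils::head(bad, 5), collapse = ", "))
    labels <- sampleConditions(study)[samples]
    new("FeatureTable", level = "gene",
        values = m[genes, samples, drop = FALSE], labels = labels)
}

#' Category-level feature table
#'
#' One feature per functional category holding at least
#' \code{minCategorySize} DE genes: the mean log2 expression over
#' (category intersect DE genes) per sample — the pathway-aggregated
#' representation of each sample.
#'
#' @param study an [ExpressionStudy-class].
#' @param annotation an [AnnotationSet-class].
#' @param deGenes non-empty character vector of DE genes.
#' @param minCategorySize smallest usable category (default 3).
#' @param samples optional sample subset (default: all).
#' @return a [FeatureTable-class] with level "category".
#' @export
categoryFeatures <- function(study, annotation, deGenes,
                             minCategorySize = 3L,
                             samples = colnames(study)) {
    stopifnot(is(annotation, "AnnotationSet"), length(deGenes) > 0L)
    m <- assay(study, "log2expr")
    rows <- list()
    for (id in categoryIds(annotation)) {
        genes <- intersect(geneSets(annotation)[[id]],
                           intersect(deGenes, rownames(m)))
        if (length(genes) < minCategorySize) next
        rows[[id]] <- colMeans(m[genes, samples, drop = FALSE])
    }
    if (!length(rows))
        stop("no category holds >= ", minCategorySize, " DE genes")
    values <- do.call(rbind, rows)
    labels <- sampleConditions(study)[samples]
    new("FeatureTable", level = "category", values = values,
        labels = labels)
}

# stratified split: per class, a rounded train fraction clamped so both
# sides keep at least one sample
.stratifiedSplit <- function(labels, trainFraction) {
    train <- character()
    for (cl in unique(labels)) {
        ids <- names(labels)[labels == cl]
        nTrain <- min(max(round(trainFraction * length(ids)), 1L),
                      length(ids) - 1L)
        train <- c(train, sample(ids, nTrain))
    }
    train
}

#' Repeated random-forest classification with OOB model selection
#'
#' Fits \code{config@rfModels} forests of \code{config@rfTrees} trees
#' (\code{mtry = config@rfMtry}, clamped to the feature count), each on a
#' fresh stratified split with \code{config@rfTrainFraction} of every
#' class in training. The model with the lowest out-of-bag error on its
#' training portion wins (ties to the lowest model index); its held-out
#' test accuracy, test and OOB confusion matrices and mean-decrease-in-
#' Gini importances are returned. Fully reproducible given \code{seed}.
#'
#' @param features a [FeatureTable-class]; every class needs >= 2 samples.
#' @param config a [FrameworkConfig-class].
#' @param seed integer master seed (default \code{config@seed}).
#' @param stratified set FALSE for a fully random (unstratified) split.
#' @return a [ForestResult-class].
#' @examples
#' sim <- generateStudy(antiTNFStudyTruth(), nGenes = 1200, seed = 1)
#' ft <- geneFeatures(sim$study, rownames(sim$study)[1:50])
#' rfSelect(ft, frameworkConfig(rfModels = 5), seed = 1)
#' @export
rfSelect <- function(features, config = frameworkConfig(),
                     seed = config@seed, stratified = TRUE) {
    stopifnot(is(features, "FeatureTable"))
    labels <- factor(features@labels)
    names(labels) <- names(features@labels)
    tooFew <- names(which(table(labels) < 2L))
    if (length(tooFew))
        stop("class(es) with a single sample (merge or drop them): ",
             paste(tooFew, collapse = ", "))
    x <- t(features@values)
    mtry <- min(config@rfMtry, ncol(x))
    if (mtry < config@rfMtry)
        message("mtry clamped to the feature count (", mtry, ")")

    oldSeed <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(oldSeed))
        assign(".Random.seed", oldSeed, envir = globalenv()))
    set.seed(as.integer(seed))
    modelSeeds <- sample.int(.Machine$integer.max - 1L, config@rfModels)

    fitOne <- function(i) {
        set.seed(modelSeeds[i])
        train <- if (stratified) .stratifiedSplit(labels,
                                                  config@rfTrainFraction)
                 else sample(names(labels),
                             min(max(round(config@rfTrainFraction *
                                           length(labels)), 1L),
                                 length(labels) - 1L))
        rf <- randomForest::randomForest(
            x = x[train, , drop = FALSE], y = labels[train],
            ntree = config@rfTrees, mtry = mtry, importance = FALSE)
        list(train = train, rf = rf,
             oob = unname(rf$err.rate[config@rfTrees, "OOB"]))
    }

    oobErrors <- numeric(config@rfModels)
    best <- NULL
    for (i in seq_len(config@rfModels)) {
        fit <- fitOne(i)
        oobErrors[i] <- fit$oob
        if (is.null(best) || fit$oob < best$oob)
            best <- c(fit, list(index = i))
    }

    test <- setdiff(names(labels), best$train)
    pred <- stats::predict(best$rf, x[test, , drop = FALSE])
    lev <- levels(labels)
    confusionTest <- table(actual = factor(labels[test], levels = lev),
                           predicted = factor(pred, levels = lev))
    oobPred <- best$rf$predicted
    confusionOOB <- table(actual = factor(labels[best$train], levels = lev),
                          predicted = factor(oobPred[best$train],
                                             levels = lev))
    imp <- randomForest::importance(best$rf, type = 2)[, 1]
    imp <- imp[order(-imp, names(imp))]

    new("ForestResult",
        oobError = best$oob,
        testAccuracy = mean(pred == labels[test]),
        confusionTest = unclass(as.matrix(confusionTest)),
        confusionOOB = unclass(as.matrix(confusionOOB)),
        importance = imp, modelIndex = as.integer(best$index),
        oobErrors = oobErrors, level = features@level,
        seed = as.integer(seed))
}

#' Top-ranked features of a forest result
#'
#' @param result a [ForestResult-class].
#' @param topN how many features (1 <= topN <= feature count).
#' @return character vector of the first \code{topN} feature ids by mean
#'   decrease in Gini (ties broken by feature id).
#' @export
topImportant <- function(result, topN) {
    stopifnot(is(result, "ForestResult"))
    if (topN < 1L || topN > length(result@importance))
        stop("topN must be in 1..", length(result@importance))
    names(result@importance)[seq_len(topN)]
}

#' Two-component PCA embedding of samples on selected features
#'
#' Column-centred singular value decomposition of the sample x feature
#' matrix restricted to a feature subset; returns the first two component
#' scores per sample and the explained-variance fractions. Data with
#' fewer than two effective dimensions yield a single component with a
#' warning.
#'
#' @param features a [FeatureTable-class].
#' @param subset non-empty character vector of feature ids (e.g. from
#'   [topImportant()]).
#' @return list with \code{coordinates} (data.frame: sample, condition,
#'   PC1[, PC2]) and \code{explained} (variance fractions).
#' @export
pcaEmbed <- function(features, subset = rownames(features@values)) {
    stopifnot(is(features, "FeatureTable"), length(subset) >= 1L)
    bad <- setdiff(subset, rownames(features@values))
    if (length(bad))
        stop("features absent from the table: ",
             paste(utils::head(bad, 5), collapse = ", "))
    x <- t(features@values[subset, , drop = FALSE])
    pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
    evFrac <- pc$sdev^2 / sum(pc$sdev^2)
    nComp <- sum(pc$sdev > max(pc$sdev) * 1e-8)
    if (nComp < 2L) {
        warning("fewer than 2 effective dimensions; returning 1 component")
        coords <- data.frame(sample = rownames(x),
                             condition = unname(features@labels[rownames(x)]),
                             PC1 = pc$x[, 1], stringsAsFactors = FALSE)
        return(list(coordinates = coords, explained = evFrac[1]))
    }
    coords <- data.frame(sample = rownames(x),
                         condition = unname(features@labels[rownames(x)]),
                         PC1 = pc$x[, 1], PC2 = pc$x[, 2],
                         stringsAsFactors = FALSE)
    rownames(coords) <- NULL
    list(coordinates = coords, explained = evFrac[1:2])
}
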
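#' @import methods
#' @import SummarizedExperiment
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

.ROLE_LEVELS <- c("healthy_control", "disease_control", "treatment")
.TIMING_LEVELS <- c("prophylactic", "therapeutic", "none")

#' ExpressionStudy: a log2 expression matrix with a dual-control design
#'
#' An \code{ExpressionStudy} extends
#' \link[SummarizedExperiment]{SummarizedExperiment} with a single
#' \code{"log2expr"} assay (genes in rows, samples in columns) and a column
#' design assigning every sample to a condition and every condition to a
#' role. Exactly one condition must be the healthy control (e.g. wild-type
#' littermates) and exactly one the disease control (e.g. untreated
#' transgenic animals); all remaining conditions are treatment arms. An
#' optional timing label distinguishes prophylactic from therapeutic
#' administration of the same agent.
#'
#' Values are assumed to be on log2 scale already (e.g. RMA-normalised
#' intensities summarised to gene level), so group differences of means are
#' log2 fold-changes directly.
#'
#' @slot .. see \link[SummarizedExperiment]{SummarizedExperiment}; colData
#'   carries \code{condition}, \code{role} and \code{timing} columns.
#'
#' @seealso [loadExpressionStudy()], [generateStudy()], [dualBaseline()]
#' @export
setClass("ExpressionStudy", contains = "SummarizedExperiment")

.validExpressionStudy <- function(object) {
    msg <- character()
    cd <- colData(object)
    if (!all(c("condition", "role") %in% colnames(cd)))
        return("colData must contain 'condition' and 'role' columns")
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "sample identifiers must be unique")
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "gene identifiers must be unique")
    if (!"log2expr" %in% assayNames(object))
        msg <- c(msg, "assay 'log2expr' is required")
    else if (anyNA(assay(object, "log2expr")))
        msg <- c(msg, "expression matrix must be complete (no missing values)")
    if (!all(cd$role %in% .ROLE_LEVELS))
        msg <- c(msg, sprintf("roles must be one of: %s",
                              paste(.ROLE_LEVELS, collapse = ", ")))
    role_by_cond <- unique(data.frame(condition = cd$condition,
                                      role = cd$role))
    if (anyDuplicated(role_by_cond$condition))
        msg <- c(msg, "each condition must map to exactly one role")
    for (r in c("healthy_control", "disease_control")) {
        n <- sum(role_by_cond$role == r)
        if (n != 1L)
            msg <- c(msg, sprintf("exactly one condition must have role '%s' (found %d)", r, n))
    }
    if ("timing" %in% colnames(cd) && !all(cd$timing %in% .TIMING_LEVELS))
        msg <- c(msg, sprintf("timing must be one of: %s",
                              paste(.TIMING_LEVELS, collapse = ", ")))
    if (length(msg)) msg else TRUE
}
setValidity("ExpressionStudy", .validExpressionStudy)

#' Construct an ExpressionStudy from a matrix and a sample design
#'
#' @param matrix numeric matrix of log2 expression values, genes in rows
#'   (unique rownames), samples in columns (unique colnames).
#' @param design data.frame with columns \code{sample}, \code{condition},
#'   \code{role} and optionally \code{timing}; one row per sample. Roles are
#'   given per condition (all samples of a condition share its role).
#' @return a validated [ExpressionStudy-class] with samples in matrix
#'   column order.
#' @examples
#' m <- matrix(rnorm(12, 8), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' d <- data.frame(sample = paste0("s", 1:4),
#'                 condition = rep(c("WT", "TG"), each = 2),
#'                 role = rep(c("healthy_control", "disease_control"), each = 2))
#' ExpressionStudy(m, d)
#' @export
ExpressionStudy <- function(matrix, design) {
    stopifnot(is.matrix(matrix), is.data.frame(design))
    if (!all(c("sample", "condition", "role") %in% colnames(design)))
        stop("design needs columns 'sample', 'condition', 'role'")
    dup <- design$sample[duplicated(design$sample)]
    if (length(dup))
        stop("duplicate sample in design: ", paste(unique(dup), collapse = ", "))
    missing_in_design <- setdiff(colnames(matrix), design$sample)
    if (length(missing_in_design))
        stop("sample missing from design: ",
             paste(missing_in_design, collapse = ", "))
    missing_in_matrix <- setdiff(design$sample, colnames(matrix))
    if (length(missing_in_matrix))
        stop("sample missing from matrix: ",
             paste(missing_in_matrix, collapse = ", "))
    design <- design[match(colnames(matrix), design$sample), , drop = FALSE]
    if (is.null(design$timing)) design$timing <- "none"
    cd <- DataFrame(condition = as.character(design$condition),
                    role = as.character(design$role),
                    timing = as.character(design$timing),
                    row.names = design$sample)
    new("ExpressionStudy",
        SummarizedExperiment(assays = list(log2expr = matrix), colData = cd))
}

#' AnnotationSet: named gene sets (GO/KEGG/TF-target style categories)
#'
#' Holds functional categories as character vectors of gene identifiers,
#' already intersected with a study's gene universe, plus per-category
#' display names and a free namespace label.
#'
#' @slot sets named list of character vectors (category id -> member genes).
#' @slot descriptions named character vector of display names.
#' @slot namespace single string, e.g. "GO", "KEGG" or "TF".
#' @seealso [loadGMT()], [hypergeomEnrich()], [categoryFeatures()]
#' @export
setClass("AnnotationSet",
         representation(sets = "list", descriptions = "character",
                        namespace = "character"))

setValidity("AnnotationSet", function(object) {
    msg <- character()
    if (is.null(names(object@sets)) || anyDuplicated(names(object@sets)))
        msg <- c(msg, "category identifiers must be unique and named")
    if (any(lengths(object@sets) == 0L))
        msg <- c(msg, "categories must be non-empty")
    if (!identical(names(object@sets), names(object@descriptions)))
        msg <- c(msg, "descriptions must be named like sets")
    if (length(object@namespace) != 1L)
        msg <- c(msg, "namespace must be a single string")
    if (length(msg)) msg else TRUE
})

#' @rdname AnnotationSet-class
#' @param sets named list of character vectors of gene ids.
#' @param descriptions optional named character vector of display names
#'   (defaults to the category ids).
#' @param namespace free label for the category source.
#' @export
AnnotationSet <- function(sets, descriptions = NULL, namespace = "custom") {
    if (is.null(descriptions))
        descriptions <- stats::setNames(names(sets), names(sets))
    new("AnnotationSet", sets = sets,
        descriptions = descriptions[names(sets)], namespace = namespace)
}

#' FrameworkConfig: analysis thresholds and random-forest settings
#'
#' Bundles every tunable of the pipeline. Defaults reproduce the standard
#' settings: |log2FC| >= 1 with adjusted p <= 0.05 for differential
#' expression, silhouette search over k = 2..15, 1000 forests of 500 trees
#' with 10 variables per split on a stratified 70/30 split.
#'
#' @slot lfcThreshold non-negative log2 fold-change cutoff (default 1).
#' @slot pThreshold adjusted p-value cutoff in (0, 1] (default 0.05).
#' @slot kRange integer c(lo, hi) silhouette search interval (default 2..15).
#' @slot efficiencyMode "mean_of_abs" (default) or "abs_of_mean"; see
#'   [efficiencyScore()].
#' @slot minCategorySize smallest usable category (default 3).
#' @slot epsilon positive guard against division by zero (default 1e-8).
#' @slot geneFDR logical; additionally apply Benjamini-Hochberg across genes
#'   on top of the per-gene Dunnett family-wise adjustment (default FALSE).
#' @slot rfModels,rfTrees,rfMtry,rfTrainFraction repeated random-forest
#'   settings (defaults 1000 / 500 / 10 / 0.7).
#' @slot seed integer master seed; every stochastic step derives its stream
#'   from it.
#' @export
setClass("FrameworkConfig",
         representation(lfcThreshold = "numeric", pThreshold = "numeric",
                        kRange = "integer", efficiencyMode = "character",
                        minCategorySize = "integer", epsilon = "numeric",
                        geneFDR = "logical", rfModels = "integer",
                        rfTrees = "integer", rfMtry = "integer",
                        rfTrainFraction = "numeric", seed = "integer"))

setValidity("FrameworkConfig", function(object) {
    msg <- character()
    if (object@lfcThreshold < 0) msg <- c(msg, "lfcThreshold must be >= 0")
    if (object@pThreshold <= 0 || object@pThreshold > 1)
        msg <- c(msg, "pThreshold must be in (0, 1]")
    if (length(object@kRange) != 2L || object@kRange[1] < 2L ||
        object@kRange[2] < object@kRange[1])
        msg <- c(msg, "kRange must be c(lo, hi) with 2 <= lo <= hi")
    if (!object@efficiencyMode %in% c("mean_of_abs", "abs_of_mean"))
        msg <- c(msg, "efficiencyMode must be 'mean_of_abs' or 'abs_of_mean'")
    if (object@minCategorySize < 1L) msg <- c(msg, "minCategorySize must be >= 1")
    if (object@epsilon <= 0) msg <- c(msg, "epsilon must be positive")
    if (object@rfTrainFraction <= 0 || object@rfTrainFraction >= 1)
        msg <- c(msg, "rfTrainFraction must be in (0, 1)")
    if (any(c(object@rfModels, object@rfTrees, object@rfMtry) < 1L))
        msg <- c(msg, "rfModels, rfTrees, rfMtry must be >= 1")
    if (length(msg)) msg else TRUE
})

#' @rdname FrameworkConfig-class
#' @param lfcThreshold,pThreshold,kRange,efficiencyMode,minCategorySize,epsilon,geneFDR,rfModels,rfTrees,rfMtry,rfTrainFraction,seed
#'   see the class slots.
#' @export
frameworkConfig <- function(lfcThreshold = 1, pThreshold = 0.05,
                            kRange = c(2L, 15L),
                            efficiencyMode = "mean_of_abs",
                            minCategorySize = 3L, epsilon = 1e-8,
                            geneFDR = FALSE, rfModels = 1000L,
                            rfTrees = 500L, rfMtry = 10L,
                            rfTrainFraction = 0.7, seed = 1L) {
    new("FrameworkConfig", lfcThreshold = as.numeric(lfcThreshold),
        pThreshold = as.numeric(pThreshold),
        kRange = as.integer(kRange),
        efficiencyMode = efficiencyMode,
        minCategorySize = as.integer(minCategorySize),
        epsilon = as.numeric(epsilon), geneFDR = isTRUE(geneFDR),
        rfModels = as.integer(rfModels), rfTrees = as.integer(rfTrees),
        rfMtry = as.integer(rfMtry),
        rfTrainFraction = as.numeric(rfTrainFraction),
        seed = as.integer(seed))
}

#' ContrastResult: per-gene statistics against one baseline condition
#'
#' One-way ANOVA + Dunnett many-to-one results for every non-baseline
#' condition against a common baseline. Matrices are genes x conditions.
#' \code{adjP} is the Dunnett family-wise adjusted p-value within each gene
#' (the family is the set of condition-vs-baseline comparisons); the
#' \code{de} flag is \code{|log2FC| >= lfcThreshold & adjP <= pThreshold}.
#'
#' @slot baseline baseline condition label.
#' @slot log2FC,rawP,adjP numeric matrices (genes x non-baseline conditions).
#' @slot de logical matrix of the same shape.
#' @slot lfcThreshold,pThreshold thresholds used for the flag.
#' @seealso [anovaDunnett()], [dualBaseline()], [deGenes()]
#' @export
setClass("ContrastResult",
         representation(baseline = "character", log2FC = "matrix",
                        rawP = "matrix", adjP = "matrix", de = "matrix",
                        lfcThreshold = "numeric", pThreshold = "numeric"))

setValidity("ContrastResult", function(object) {
    msg <- character()
    dm <- dim(object@log2FC)
    for (s in c("rawP", "adjP", "de"))
        if (!identical(dim(slot(object, s)), dm))
            msg <- c(msg, sprintf("slot '%s' must match log2FC dimensions", s))
    if (object@baseline %in% colnames(object@log2FC))
        msg <- c(msg, "baseline must not appear among contrast columns")
    if (any(object@adjP < object@rawP - 1e-12))
        msg <- c(msg, "adjP must be >= rawP")
    if (length(msg)) msg else TRUE
})

#' ClusterAssignment: Ward labels with the silhouette trace that chose k
#'
#' @slot k chosen number of clusters.
#' @slot labels named integer vector, gene -> cluster id in 1..k.
#' @slot silhouetteByK named numeric vector of mean silhouette widths for
#'   every candidate k (NA when undefined).
#' @slot featureColumns condition labels of the profile columns used.
#' @seealso [selectKSilhouette()], [wardCluster()]
#' @export
setClass("ClusterAssignment",
         representation(k = "integer", labels = "integer",
                        silhouetteByK = "numeric",
                        featureColumns = "character"))

setValidity("ClusterAssignment", function(object) {
    msg <- character()
    if (length(object@labels) &&
        !all(object@labels %in% seq_len(object@k)))
        msg <- c(msg, "labels must lie in 1..k")
    if (is.null(names(object@labels)))
        msg <- c(msg, "labels must be named by gene")
    if (length(msg)) msg else TRUE
})

#' SyntheticTruth: planted structure for a simulated treatment study
#'
#' Describes the generative ground truth of [generateStudy()]: which genes
#' are over-/under-expressed in disease, what fraction of each disease block
#' every treatment arm restores to healthy levels or reverses to the
#' opposite sign, which genes each arm alters despite being unchanged in
#' disease, the planted effect size and residual noise, and the replicate
#' count per condition.
#'
#' @slot diseaseUp,diseaseDown character vectors of planted disease genes.
#' @slot altered named list (treatment -> character vector) of
#'   treatment-specific altered genes, disjoint from the disease blocks.
#' @slot restorationFraction numeric matrix, treatments x c("up","down"),
#'   values in [0,1].
#' @slot reversalFraction named numeric vector per treatment, in [0,1];
#'   restoration + reversal <= 1 within each arm/direction.
#' @slot effectSize planted |log2FC| magnitude.
#' @slot noiseSd residual standard deviation on log2 scale.
#' @slot groupSizes named integer vector, condition -> replicate count.
#' @slot healthyControl,diseaseControl condition labels of the two controls.
#' @slot timing named character vector per treatment
#'   ("prophylactic"/"therapeutic").
#' @seealso [antiTNFStudyTruth()], [generateStudy()]
#' @export
setClass("SyntheticTruth",
         representation(diseaseUp = "character", diseaseDown = "character",
                        altered = "list",
                        restorationFraction = "matrix",
                        reversalFraction = "numeric",
                        effectSize = "numeric", noiseSd = "numeric",
                        groupSizes = "integer",
                        healthyControl = "character",
                        diseaseControl = "character",
                        timing = "character"))

setValidity("SyntheticTruth", function(object) {
    msg <- character()
    if (length(intersect(object@diseaseUp, object@diseaseDown)))
        msg <- c(msg, "diseaseUp and diseaseDown must be disjoint")
    disease <- c(object@diseaseUp, object@diseaseDown)
    for (tr in names(object@altered))
        if (length(intersect(object@altered[[tr]], disease)))
            msg <- c(msg, sprintf("altered set of '%s' overlaps disease genes", tr))
    trts <- rownames(object@restorationFraction)
    if (!identical(sort(trts), sort(names(object@reversalFraction))))
        msg <- c(msg, "restorationFraction rows and reversalFraction names must agree")
    rf <- object@restorationFraction
    if (any(rf < 0 | rf > 1)) msg <- c(msg, "restoration fractions must be in [0,1]")
    rv <- object@reversalFraction[rownames(rf)]
    if (any(rf + rv > 1 + 1e-12))
        msg <- c(msg, "restoration + reversal must be <= 1 per arm/direction")
    if (any(rv < 0 | rv > 1)) msg <- c(msg, "reversal fractions must be in [0,1]")
    need <- c(object@healthyControl, object@diseaseControl, trts)
    if (!all(need %in% names(object@groupSizes)))
        msg <- c(msg, "groupSizes must cover both controls and every treatment")
    if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
    if (length(msg)) msg else TRUE
})

#' ForestResult: the selected model of a repeated random-forest run
#'
#' @slot oobError out-of-bag error of the winning model (computed on its
#'   70\% training portion).
#' @slot testAccuracy accuracy on the winner's held-out 30\%.
#' @slot confusionTest actual x predicted count matrix on the test set.
#' @slot confusionOOB actual x predicted count matrix of OOB predictions on
#'   the training set.
#' @slot importance named numeric vector, mean decrease in Gini, sorted
#'   decreasing (ties by feature id).
#' @slot modelIndex index of the winner among the repeated models.
#' @slot oobErrors OOB error of every fitted model.
#' @slot level "gene" or "category".
#' @slot seed master seed used.
#' @seealso [rfSelect()], [topImportant()]
#' @export
setClass("ForestResult",
         representation(oobError = "numeric", testAccuracy = "numeric",
                        confusionTest = "matrix", confusionOOB = "matrix",
                        importance = "numeric", modelIndex = "integer",
                        oobErrors = "numeric", level = "character",
                        seed = "integer"))

setValidity("ForestResult", function(object) {
    msg <- character()
    if (any(object@importance < 0)) msg <- c(msg, "importances must be non-negative")
    if (object@oobError < 0 || object@oobError > 1)
        msg <- c(msg, "oobError must be in [0,1]")
    if (length(msg)) msg else TRUE
})

#' FeatureTable: sample-classification features at gene or category level
#'
#' @slot level "gene" or "category".
#' @slot values numeric feature x sample matrix (no missing values).
#' @slot labels named character vector, sample -> condition (>= 2 classes).
#' @seealso [categoryFeatures()], [geneFeatures()], [rfSelect()]
#' @export
setClass("FeatureTable",
         representation(level = "character", values = "matrix",
                        labels = "character"))

setValidity("FeatureTable", function(object) {
    msg <- character()
    if (anyNA(object@values)) msg <- c(msg, "feature values must be complete")
    if (!identical(colnames(object@values), names(object@labels)))
        msg <- c(msg, "labels must be named by the sample columns")
    if (length(unique(object@labels)) < 2L)
        msg <- c(msg, "at least two distinct condition labels are required")
    if (length(msg)) msg else TRUE
})
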
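#' Load an expression study from a matrix TSV and a sample sheet
#'
#' The matrix file is tab-separated with gene identifiers in the first
#' column and a header row of sample identifiers; values are log2-scale
#' expression. The sample sheet has columns \code{sample},
#' \code{condition}, \code{role} and optionally \code{timing}. Gene rows
#' containing any missing value are dropped (and counted in a message):
#' downstream statistics require genes measured in all samples.
#'
#' @param matrixPath path to the expression matrix TSV.
#' @param designPath path to the sample sheet TSV.
#' @param transpose set TRUE when the file stores samples in rows.
#' @return an [ExpressionStudy-class].
#' @export
loadExpressionStudy <- function(matrixPath, designPath, transpose = FALSE) {
    tab <- utils::read.delim(matrixPath, check.names = FALSE,
                             stringsAsFactors = FALSE)
    if (ncol(tab) < 2L)
        stop("matrix file needs a gene-id column plus >= 1 sample column")
    ids <- as.character(tab[[1L]])
    dup <- unique(ids[duplicated(ids)])
    if (length(dup))
        stop("duplicate gene identifier(s): ", paste(dup, collapse = ", "))
    m <- as.matrix(tab[, -1L, drop = FALSE])
    if (!is.numeric(m)) stop("non-numeric values in expression matrix")
    rownames(m) <- ids
    if (transpose) m <- t(m)
    dupS <- unique(colnames(m)[duplicated(colnames(m))])
    if (length(dupS))
        stop("duplicate sample identifier(s): ", paste(dupS, collapse = ", "))
    incomplete <- rowSums(is.na(m)) > 0L
    if (any(incomplete)) {
        message(sum(incomplete),
                " gene row(s) with missing values dropped at load")
        m <- m[!incomplete, , drop = FALSE]
    }
    design <- utils::read.delim(designPath, stringsAsFactors = FALSE)
    ExpressionStudy(m, design)
}

#' Write an expression study back to matrix + design TSVs
#'
#' @param study an [ExpressionStudy-class].
#' @param matrixPath,designPath output paths.
#' @return invisibly, the two paths.
#' @export
writeExpressionStudy <- function(study, matrixPath, designPath) {
    m <- assay(study, "log2expr")
    df <- data.frame(gene = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, matrixPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    cd <- colData(study)
    design <- data.frame(sample = rownames(cd), condition = cd$condition,
                         role = cd$role, timing = cd$timing)
    utils::write.table(design, designPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(c(matrixPath, designPath))
}

#' Load gene-set categories from a GMT file
#'
#' Standard GMT dialect: one category per line, tab-separated fields
#' \code{id}, \code{description}, then member genes. Members are
#' intersected with the study's gene universe; categories falling below
#' \code{minCategorySize} after intersection are dropped with a warning.
#'
#' @param path GMT file path.
#' @param universe character vector of measured gene identifiers.
#' @param minCategorySize smallest retained category (default 3).
#' @param namespace label stored on the returned set.
#' @return an [AnnotationSet-class].
#' @export
loadGMT <- function(path, universe, minCategorySize = 3L,
                    namespace = "custom") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(lines)]
    if (!length(lines)) {
        warning("empty GMT file: ", path)
        return(AnnotationSet(sets = stats::setNames(list(), character()),
                             descriptions = stats::setNames(character(), character()),
                             namespace = namespace))
    }
    fields <- strsplit(lines, "\t", fixed = TRUE)
    short <- which(lengths(fields) < 3L)
    if (length(short))
        stop("malformed GMT line ", short[1L],
             ": fewer than 3 tab-separated fields")
    ids <- vapply(fields, `[[`, character(1), 1L)
    dup <- unique(ids[duplicated(ids)])
    if (length(dup))
        stop("duplicate category identifier(s): ", paste(dup, collapse = ", "))
    desc <- vapply(fields, `[[`, character(1), 2L)
    sets <- lapply(fields, function(f) intersect(unique(f[-(1:2)]), universe))
    names(sets) <- ids
    small <- lengths(sets) < minCategorySize
    if (any(small)) {
        warning(sum(small), " categor",
                if (sum(small) == 1L) "y" else "ies",
                " below minimum size ", minCategorySize,
                " after intersecting with the universe; dropped")
        sets <- sets[!small]
        desc <- desc[!small]
    }
    AnnotationSet(sets = sets,
                  descriptions = stats::setNames(desc, names(sets)),
                  namespace = namespace)
}

#' Write an AnnotationSet as GMT
#'
#' @param annotation an [AnnotationSet-class].
#' @param path output file path.
#' @return invisibly, the path.
#' @export
writeGMT <- function(annotation, path) {
    sets <- geneSets(annotation)
    lines <- vapply(names(sets), function(id)
        paste(c(id, annotation@descriptions[[id]], sets[[id]]),
              collapse = "\t"), character(1))
    writeLines(lines, path)
    invisible(path)
}

#' Write a tabular result deterministically
#'
#' Tab-separated with header, numeric columns at 6 significant digits, rows
#' sorted by the first column (then subsequent columns on ties) so that
#' identical record sets produce byte-identical files regardless of
#' insertion order.
#'
#' @param records a data.frame with stable column names.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeResultTable <- function(records, path) {
    stopifnot(is.data.frame(records))
    if (nrow(records)) {
        ord <- do.call(order, unname(as.list(records)))
        records <- records[ord, , drop = FALSE]
        num <- vapply(records, is.numeric, logical(1))
        records[num] <- lapply(records[num], signif, digits = 6L)
    }
    utils::write.table(records, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read a table written by [writeResultTable()]
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
readResultTable <- function(path)
    utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)

#' Build a FrameworkConfig from a YAML file
#'
#' Keys mirror the configuration fields: \code{lfc_threshold},
#' \code{p_threshold}, \code{k_range} (two-element list), \code{efficiency_mode},
#' \code{min_category_size}, \code{epsilon}, \code{gene_fdr}, and an
#' \code{rf} block with \code{n_models}, \code{n_trees}, \code{mtry},
#' \code{train_fraction}, \code{seed}. Absent keys keep their defaults.
#'
#' @param path YAML file path.
#' @return a [FrameworkConfig-class].
#' @export
loadConfig <- function(path) {
    y <- yaml::read_yaml(path)
    if (is.null(y)) y <- list()
    rf <- if (is.null(y$rf)) list() else y$rf
    pick <- function(x, default) if (is.null(x)) default else x
    frameworkConfig(
        lfcThreshold = pick(y$lfc_threshold, 1),
        pThreshold = pick(y$p_threshold, 0.05),
        kRange = as.integer(unlist(pick(y$k_range, c(2, 15)))),
        efficiencyMode = pick(y$efficiency_mode, "mean_of_abs"),
        minCategorySize = pick(y$min_category_size, 3L),
        epsilon = pick(y$epsilon, 1e-8),
        geneFDR = pick(y$gene_fdr, FALSE),
        rfModels = pick(rf$n_models, 1000L),
        rfTrees = pick(rf$n_trees, 500L),
        rfMtry = pick(rf$mtry, 10L),
        rfTrainFraction = pick(rf$train_fraction, 0.7),
        seed = pick(rf$seed, 1L))
}

#' Tidy a ContrastResult into a long table
#'
#' One row per gene and contrast condition, with columns \code{gene},
#' \code{condition}, \code{log2FC}, \code{rawP}, \code{adjP}, \code{de};
#' the layout written by the command-line \code{de} step.
#'
#' @param x a [ContrastResult-class].
#' @return data.frame.
#' @export
contrastTable <- function(x) {
    stopifnot(is(x, "ContrastResult"))
    conds <- colnames(x@log2FC)
    genes <- rownames(x@log2FC)
    data.frame(
        gene = rep(genes, times = length(conds)),
        baseline = x@baseline,
        condition = rep(conds, each = length(genes)),
        log2FC = as.vector(x@log2FC),
        rawP = as.vector(x@rawP),
        adjP = as.vector(x@adjP),
        de = as.vector(x@de),
        stringsAsFactors = FALSE)
}

#' Serialise a synthetic study's planted truth to JSON
#'
#' Records the generator parameters and the realised per-treatment
#' restored / reversed / notRestored / altered gene sets, so a simulated
#' study can be scored later without regenerating it.
#'
#' @param sim the list returned by [generateStudy()].
#' @param path output JSON path.
#' @return invisibly, the path.
#' @export
writeTruthJSON <- function(sim, path) {
    truth <- sim$truth
    payload <- list(
        effectSize = truth@effectSize, noiseSd = truth@noiseSd,
        groupSizes = as.list(truth@groupSizes),
        healthyControl = truth@healthyControl,
        diseaseControl = truth@diseaseControl,
        diseaseUp = truth@diseaseUp, diseaseDown = truth@diseaseDown,
        restorationFraction = apply(truth@restorationFraction, 1, as.list),
        reversalFraction = as.list(truth@reversalFraction),
        timing = as.list(truth@timing),
        planted = sim$planted)
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}
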
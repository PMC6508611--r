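# Ward clustering of DE-gene log2FC profiles with silhouette-guided
# choice of the cluster number.

#' Cross-condition log2FC profile matrix for a gene set
#'
#' The clustering feature space: one row per gene, one column per
#' non-baseline condition of a vs-healthy contrast (disease plus each
#' treatment arm).
#'
#' @param vsWt [ContrastResult-class] against the healthy control.
#' @param genes character vector of genes to keep (default: all).
#' @return numeric matrix genes x conditions.
#' @export
profileMatrix <- function(vsWt, genes = NULL) {
    stopifnot(is(vsWt, "ContrastResult"))
    m <- vsWt@log2FC
    if (!is.null(genes)) {
        bad <- setdiff(genes, rownames(m))
        if (length(bad))
            stop("genes absent from the contrast: ",
                 paste(utils::head(bad, 5), collapse = ", "))
        m <- m[genes, , drop = FALSE]
    }
    m
}

#' Ward agglomerative clustering at a fixed k
#'
#' Hierarchical clustering by Ward's minimum-variance criterion on
#' Euclidean distances (\code{hclust} method \code{"ward.D2"}), cut at k
#' groups. Deterministic given the input.
#'
#' @param profiles numeric gene x condition matrix, no missing values.
#' @param k number of clusters (1 <= k <= nrow).
#' @return named integer vector of cluster labels in 1..k.
#' @export
wardCluster <- function(profiles, k) {
    profiles <- as.matrix(profiles)
    if (anyNA(profiles)) stop("profiles must not contain missing values")
    if (k > nrow(profiles))
        stop("k (", k, ") exceeds the number of genes (", nrow(profiles), ")")
    if (k == nrow(profiles))
        return(stats::setNames(seq_len(nrow(profiles)), rownames(profiles)))
    hc <- stats::hclust(stats::dist(profiles), method = "ward.D2")
    stats::cutree(hc, k = k)
}

#' Silhouette-guided selection of the cluster number
#'
#' Runs [wardCluster()] for every candidate k in the search range and
#' keeps the k maximising the mean silhouette width (Euclidean distances;
#' ties broken toward the smallest k). Degenerate input with all rows
#' identical yields k = 1 with a warning.
#'
#' @param profiles numeric gene x condition matrix.
#' @param kRange integer c(lo, hi), clamped into [2, nrow - 1].
#' @return a [ClusterAssignment-class].
#' @examples
#' x <- rbind(matrix(rnorm(60, 2, .1), 20), matrix(rnorm(60, -2, .1), 20))
#' rownames(x) <- paste0("g", 1:40)
#' selectKSilhouette(x)@k
#' @export
selectKSilhouette <- function(profiles, kRange = c(2L, 15L)) {
    profiles <- as.matrix(profiles)
    n <- nrow(profiles)
    if (is.null(rownames(profiles)))
        rownames(profiles) <- sprintf("row%d", seq_len(n))
    featCols <- if (is.null(colnames(profiles))) character()
                else colnames(profiles)
    d <- stats::dist(profiles)
    if (all(d < .Machine$double.eps^0.5)) {
        warning("all profiles identical; cluster number undefined, returning k = 1")
        return(new("ClusterAssignment", k = 1L,
                   labels = stats::setNames(rep(1L, n), rownames(profiles)),
                   silhouetteByK = stats::setNames(numeric(), character()),
                   featureColumns = featCols))
    }
    ks <- max(2L, kRange[1]):min(kRange[2], n - 1L)
    hc <- stats::hclust(d, method = "ward.D2")
    sil <- vapply(ks, function(k) {
        labels <- stats::cutree(hc, k = k)
        mean(cluster::silhouette(labels, d)[, "sil_width"])
    }, numeric(1))
    names(sil) <- ks
    kBest <- ks[which.max(sil)]   # which.max takes the first (smallest) tie
    new("ClusterAssignment", k = as.integer(kBest),
        labels = stats::cutree(hc, k = kBest),
        silhouetteByK = sil, featureColumns = featCols)
}

#' Per-cluster mean profiles and distance from the healthy state
#'
#' For every cluster: its size, the mean log2FC per condition, and the
#' mean-absolute-log2FC distance from the healthy (all-zero) profile per
#' condition — the aggregate view of how far each condition keeps each
#' cluster from healthy expression.
#'
#' @param assignment a [ClusterAssignment-class] (or named integer labels).
#' @param profiles the gene x condition log2FC matrix the labels refer to.
#' @return long-format data.frame with columns \code{cluster}, \code{size},
#'   \code{condition}, \code{meanLog2FC}, \code{distanceFromWT}.
#' @export
clusterSummaries <- function(assignment, profiles) {
    labels <- if (is(assignment, "ClusterAssignment")) assignment@labels
              else assignment
    profiles <- as.matrix(profiles)
    if (!all(names(labels) %in% rownames(profiles)))
        stop("assignment and profiles are not aligned")
    out <- list()
    for (cl in sort(unique(labels))) {
        genes <- names(labels)[labels == cl]
        sub <- profiles[genes, , drop = FALSE]
        out[[length(out) + 1L]] <- data.frame(
            cluster = cl, size = length(genes),
            condition = colnames(profiles),
            meanLog2FC = colMeans(sub),
            distanceFromWT = colMeans(abs(sub)),
            row.names = NULL, stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
}
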
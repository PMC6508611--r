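# Hypergeometric over-representation of a query gene set against
# functional categories, with Benjamini-Hochberg correction across the
# tested categories.

#' Hypergeometric gene-set over-representation test
#'
#' For each category of size K in a universe of M genes and a query of
#' size n with k query genes inside the category, the raw p-value is the
#' upper tail P[X >= k] with X ~ Hypergeometric(M, K, n). P-values are
#' corrected across all tested categories with Benjamini-Hochberg;
#' \code{strength} reports -log10(adjusted p).
#'
#' @param query character vector of genes, a subset of \code{universe}.
#' @param annotation an [AnnotationSet-class]; categories are intersected
#'   with the universe before testing.
#' @param universe character vector of all measured genes.
#' @return data.frame sorted by adjusted p then category id, with columns
#'   \code{category}, \code{name}, \code{k}, \code{K}, \code{n}, \code{M},
#'   \code{rawP}, \code{adjP}, \code{strength}.
#' @examples
#' ann <- AnnotationSet(list(A = c("g1", "g2", "g3"), B = c("g4", "g5")))
#' hypergeomEnrich(c("g1", "g2"), ann, paste0("g", 1:20))
#' @export
hypergeomEnrich <- function(query, annotation, universe) {
    stopifnot(is(annotation, "AnnotationSet"))
    universe <- unique(universe)
    query <- unique(query)
    outside <- setdiff(query, universe)
    if (length(outside))
        stop("query genes outside the universe: ",
             paste(utils::head(outside, 5), collapse = ", "),
             if (length(outside) > 5) sprintf(" (+%d more)",
                                              length(outside) - 5))
    M <- length(universe)
    n <- length(query)
    rows <- lapply(categoryIds(annotation), function(id) {
        members <- intersect(geneSets(annotation)[[id]], universe)
        K <- length(members)
        if (K == 0L) return(NULL)
        k <- length(intersect(members, query))
        rawP <- stats::phyper(k - 1L, K, M - K, n, lower.tail = FALSE)
        data.frame(category = id,
                   name = annotation@descriptions[[id]],
                   k = k, K = K, n = n, M = M, rawP = rawP,
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (is.null(out))
        return(data.frame(category = character(), name = character(),
                          k = integer(), K = integer(), n = integer(),
                          M = integer(), rawP = numeric(), adjP = numeric(),
                          strength = numeric(), stringsAsFactors = FALSE))
    out$adjP <- stats::p.adjust(out$rawP, method = "BH")
    out$strength <- -log10(out$adjP)
    out <- out[order(out$adjP, out$category), , drop = FALSE]
    rownames(out) <- NULL
    out
}
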
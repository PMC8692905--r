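#' Hypergeometric GO term enrichment
#'
#' For every annotation term with at least one query member, computes the
#' hypergeometric upper-tail probability of drawing at least \code{k}
#' term members in a query of size \code{n} from a universe of size
#' \code{N} containing \code{K} term members, i.e. \eqn{P(X \ge k)},
#' adjusts across tested terms by Benjamini-Hochberg, and retains rows
#' with \code{p < pMax} (set \code{all = TRUE} for every tested term).
#' The annotation is restricted to the universe before counting.
#'
#' @param query character vector of genes; must be a subset of
#'   \code{universe}.
#' @param annotation two-column data.frame (\code{gene}, \code{term}).
#' @param universe character vector, the gene background (genes surviving
#'   the gene filter by convention).
#' @param pMax unadjusted p-value threshold.
#' @param all return every tested term regardless of \code{pMax}?
#' @return data.frame \code{term}, \code{k}, \code{K}, \code{n}, \code{N},
#'   \code{p}, \code{q}, ordered by p.
#' @examples
#' ann <- data.frame(gene = paste0("g", 1:10),
#'                   term = rep(c("T1", "T2"), each = 5))
#' goEnrichment(paste0("g", 1:4), ann, paste0("g", 1:10), all = TRUE)
#' @export
goEnrichment <- function(query, annotation, universe, pMax = 0.05,
                         all = FALSE) {
    query <- unique(as.character(query))
    universe <- unique(as.character(universe))
    if (!all(query %in% universe))
        stop("query must be a subset of the universe")
    ann <- unique(annotation[, 1:2])
    names(ann) <- c("gene", "term")
    ann <- ann[ann$gene %in% universe, , drop = FALSE]
    N <- length(universe)
    n <- length(query)
    termK <- table(ann$term)
    inQuery <- ann$term[ann$gene %in% query]
    termk <- table(inQuery)
    terms <- names(termk)
    k <- as.integer(termk)
    K <- as.integer(termK[terms])
    p <- phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    q <- if (length(p)) bhAdjust(pmax(p, .Machine$double.xmin)) else numeric()
    out <- data.frame(term = terms, k = k, K = K, n = n, N = N, p = p,
                      q = q, stringsAsFactors = FALSE)
    if (all) {
        # untested terms (no query member): P(X >= 0) = 1 by convention
        rest <- setdiff(names(termK), terms)
        if (length(rest))
            out <- rbind(out, data.frame(
                term = rest, k = 0L, K = as.integer(termK[rest]), n = n,
                N = N, p = 1, q = 1, stringsAsFactors = FALSE))
    }
    out <- out[order(out$p, out$term), , drop = FALSE]
    if (!all) out <- out[out$p < pMax, , drop = FALSE]
    rownames(out) <- NULL
    out
}
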
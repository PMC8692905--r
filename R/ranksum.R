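# Wilcoxon-Mann-Whitney machinery. The scalar front-end switches between an
# exact permutation path (small samples) and a tie- and continuity-corrected
# normal approximation; the vectorized engine used by the marker functions
# applies the same approximation to every gene at once.

.EXACT_N_MAX <- 12L

# exact two-sided permutation p on pooled midranks: fraction of labelings
# whose rank-sum deviates from its null mean at least as much as observed
.rankSumExact <- function(ranks, nx) {
    n <- length(ranks)
    mu <- nx * (n + 1) / 2
    wObs <- sum(ranks[seq_len(nx)])
    dev <- abs(wObs - mu)
    combs <- combn(n, nx)
    w <- colSums(matrix(ranks[combs], nrow = nx))
    mean(abs(w - mu) >= dev - 1e-9)
}

# tie-corrected normal approximation with continuity correction
.rankSumApprox <- function(ranks, nx) {
    n <- length(ranks)
    ny <- n - nx
    w <- sum(ranks[seq_len(nx)])
    mu <- nx * (n + 1) / 2
    ties <- table(ranks)
    tieTerm <- sum(ties^3 - ties)
    sigma2 <- nx * ny / 12 * ((n + 1) - tieTerm / (n * (n - 1)))
    if (sigma2 <= 0) return(1)
    z <- max(abs(w - mu) - 0.5, 0) / sqrt(sigma2)
    min(1, 2 * pnorm(-z))
}

#' Wilcoxon rank-sum test for two groups
#'
#' Two-sided Wilcoxon-Mann-Whitney test. For total sample size at most 12
#' the p-value is computed by exhaustive enumeration of all labelings of
#' the pooled midranks (exact even under ties); larger samples use the
#' normal approximation with tie correction and continuity correction.
#'
#' @param x,y numeric vectors, each nonempty.
#' @param exact force (\code{TRUE}) or forbid (\code{FALSE}) the exact
#'   path; default switches at total n = 12.
#' @return list with \code{statistic} (the Mann-Whitney U of \code{x}) and
#'   \code{p.value}.
#' @examples
#' rankSumTest(c(1, 2, 3), c(4, 5, 6))$p.value  # 0.1, exact
#' @export
rankSumTest <- function(x, y, exact = NULL) {
    if (!length(x) || !length(y))
        stop("both groups must be nonempty")
    x <- as.numeric(x); y <- as.numeric(y)
    if (anyNA(x) || anyNA(y)) stop("NA values not allowed")
    n <- length(x) + length(y)
    if (is.null(exact)) exact <- n <= .EXACT_N_MAX
    ranks <- rank(c(x, y))
    nx <- length(x)
    w <- sum(ranks[seq_len(nx)])
    u <- w - nx * (nx + 1) / 2
    p <- if (exact) .rankSumExact(ranks, nx) else .rankSumApprox(ranks, nx)
    list(statistic = u, p.value = p)
}

# ---- vectorized engine ------------------------------------------------------

# midranks of every row of a matrix
.rowRanks <- function(m) {
    t(apply(m, 1L, rank))
}

# per-row sum of t^3 - t over tie groups
.rowTieTerm <- function(m) {
    apply(m, 1L, function(x) {
        tt <- tabulate(match(x, unique(x)))
        sum(tt^3 - tt)
    })
}

# vectorized two-sided normal-approximation p for one group vs the rest,
# given precomputed row ranks and tie terms over the full column set
.rowRankSumP <- function(ranks, tieTerm, inGroup) {
    n <- ncol(ranks)
    nx <- sum(inGroup)
    ny <- n - nx
    w <- rowSums(ranks[, inGroup, drop = FALSE])
    mu <- nx * (n + 1) / 2
    sigma2 <- nx * ny / 12 * ((n + 1) - tieTerm / (n * (n - 1)))
    z <- pmax(abs(w - mu) - 0.5, 0) / sqrt(sigma2)
    p <- 2 * pnorm(-z)
    p[sigma2 <= 0] <- 1
    pmin(p, 1)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Self-contained step-up procedure: the adjusted value of the i-th
#' smallest p is \eqn{\min_{j \ge i} p_{(j)} m / j}, capped at 1, returned
#' in input order.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return q-values, same length and order as \code{p}.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03))  # all 0.03
#' @export
bhAdjust <- function(p) {
    if (!length(p)) return(numeric())
    if (anyNA(p) || any(p <= 0 | p > 1))
        stop("p-values must lie in (0, 1]")
    m <- length(p)
    o <- order(p, decreasing = TRUE)
    ro <- order(o)
    pmin(1, cummin(p[o] * m / (m:1)))[ro]
}
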
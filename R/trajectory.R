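# Stand-in pseudotime: rank-normalized projection on the first principal
# axis of the variable-gene submatrix, oriented so non-AD cells precede AD
# cells, plus an entropy-minimizing three-segment state assignment.

#' Order cells of one lineage in pseudotime
#'
#' Pseudotime is the rank-normalized projection of each cell on the first
#' principal axis of the variable-gene submatrix, scaled to [0, 1] and
#' oriented so that the mean pseudotime of non-AD cells is at most that of
#' AD cells. This is a deliberately simple stand-in for a full trajectory
#' reconstruction: downstream computations need only an ordering, and an
#' externally computed pseudotime can be supplied instead (see
#' [readTrajectory()]).
#'
#' @param sce a \linkS4class{SingleCellExperiment} with \code{logcounts},
#'   or a log-normalized matrix.
#' @param cells cells of the lineage (identifiers or indices; default all).
#' @param varGenes variable genes to project on; default selects them from
#'   the lineage submatrix via [selectVariableGenes()].
#' @param condition per-cell condition labels for the selected cells
#'   (default: colData \code{condition}).
#' @return named numeric pseudotime in [0, 1].
#' @export
orderCells <- function(sce, cells = NULL, varGenes = NULL, condition = NULL) {
    m <- .exprMatrix(sce, if (is(sce, "SummarizedExperiment")) "logcounts" else NULL)
    if (is.null(cells)) cells <- colnames(m)
    if (is.character(cells)) cells <- match(cells, colnames(m))
    if (anyNA(cells)) stop("unknown cell identifiers")
    if (is.null(condition)) {
        condition <- as.character(colData(sce)$condition)[cells]
    }
    condition <- .checkCondition(condition)
    sub <- m[, cells, drop = FALSE]
    if (ncol(sub) < 10L)
        stop("need >= 10 cells to order")
    if (is.null(varGenes))
        varGenes <- selectVariableGenes(sub)
    varGenes <- intersect(varGenes, rownames(sub))
    if (length(varGenes) < 2L)
        stop("fewer than 2 variable genes")
    proj <- prcomp(t(sub[varGenes, , drop = FALSE]), center = TRUE,
                   scale. = FALSE, rank. = 1L)$x[, 1L]
    r <- rank(proj, ties.method = "average")
    pt <- (r - min(r)) / max(max(r) - min(r), 1)
    # canonical orientation: non-AD cells early, AD cells late
    if (mean(pt[condition == "nonAD"]) > mean(pt[condition == "AD"]))
        pt <- 1 - pt
    names(pt) <- colnames(sub)
    pt
}

# weighted two-class entropy of segments defined by cut positions
.segmentEntropy <- function(nAD, nTot) {
    p <- nAD / nTot
    h <- numeric(length(p))
    ok <- p > 0 & p < 1
    h[ok] <- -(p[ok] * log(p[ok]) + (1 - p[ok]) * log(1 - p[ok]))
    sum(nTot * h)
}

#' Assign condition-composition states along pseudotime
#'
#' Splits the pseudotime ordering into three contiguous segments by an
#' exact search over the two cut positions minimizing the size-weighted
#' within-segment condition-mixing entropy. A segment is labelled
#' \code{nonAD_enriched} (resp. \code{AD_enriched}) when more than
#' \code{enrichThreshold} of its cells come from the non-AD (resp. AD)
#' condition, and \code{transition} otherwise. The result depends on
#' pseudotime only through the cell ordering, so it is invariant to any
#' monotone transform of pseudotime.
#'
#' @param pt named numeric pseudotime (from [orderCells()] or external).
#' @param condition per-cell condition labels (\code{nonAD}/\code{AD}),
#'   parallel to \code{pt}.
#' @param enrichThreshold proportion above which a segment is called
#'   enriched for one condition.
#' @return a [TrajectoryAssignment-class].
#' @export
assignStates <- function(pt, condition, enrichThreshold = 0.6) {
    if (length(pt) < 3L) stop("need >= 3 cells")
    condition <- .checkCondition(condition)
    if (length(condition) != length(pt))
        stop("condition must be parallel to pseudotime")
    if (length(unique(condition)) < 2L)
        stop("both conditions must be present")
    cellIds <- names(pt)
    if (is.null(cellIds)) cellIds <- as.character(seq_along(pt))
    n <- length(pt)
    o <- order(pt, seq_len(n))
    isAD <- condition[o] == "AD"
    cumAD <- cumsum(isAD)
    best <- c(NA_integer_, NA_integer_)
    bestH <- Inf
    for (i in seq_len(n - 2L)) {
        j <- (i + 1L):(n - 1L)
        ad1 <- cumAD[i]
        ad2 <- cumAD[j] - ad1
        ad3 <- cumAD[n] - cumAD[j]
        h <- vapply(seq_along(j), function(jj) {
            .segmentEntropy(c(ad1, ad2[jj], ad3[jj]),
                            c(i, j[jj] - i, n - j[jj]))
        }, numeric(1))
        jm <- which.min(h)
        if (h[jm] < bestH - 1e-12) {
            bestH <- h[jm]
            best <- c(i, j[jm])
        }
    }
    seg <- rep(3L, n)
    seg[seq_len(best[2])] <- 2L
    seg[seq_len(best[1])] <- 1L
    labels <- vapply(1:3, function(s) {
        propNon <- mean(!isAD[seg == s])
        if (propNon > enrichThreshold) "nonAD_enriched"
        else if (1 - propNon > enrichThreshold) "AD_enriched"
        else "transition"
    }, character(1))
    ptSorted <- pt[o]
    cuts <- c(mean(ptSorted[best[1] + c(0L, 1L)]),
              mean(ptSorted[best[2] + c(0L, 1L)]))
    state <- factor(labels[seg], levels = .STATE_LEVELS)
    # back to input order
    ro <- order(o)
    new("TrajectoryAssignment", cellIds = cellIds,
        pseudotime = as.numeric(pt), state = state[ro], cutpoints = cuts)
}

#' Differential genes along the trajectory, grouped by peak state
#'
#' Screens genes for differential expression across the three states with
#' the one-vs-rest rank-sum machinery (per gene, the smallest of the three
#' one-vs-rest p-values), keeps the \code{topN} genes by p (constant genes
#' are never selected), and assigns each to the state where its mean
#' expression is maximal.
#'
#' @param sce expression source as in [findAllMarkers()] covering the
#'   trajectory cells.
#' @param traj a [TrajectoryAssignment-class]; all three states must have
#'   >= 3 cells.
#' @param topN number of genes to keep.
#' @return list with \code{table} (data.frame \code{gene}, \code{p},
#'   \code{block}) and \code{blocks} (state -> gene set).
#' @export
stateDEGs <- function(sce, traj, topN = 1000) {
    stopifnot(is(traj, "TrajectoryAssignment"))
    m <- .exprMatrix(sce, if (is(sce, "SummarizedExperiment")) "logcounts" else NULL)
    idx <- match(traj@cellIds, colnames(m))
    if (anyNA(idx)) stop("trajectory cells missing from the matrix")
    m <- m[, idx, drop = FALSE]
    states <- as.character(traj@state)
    sizes <- table(factor(states, levels = .STATE_LEVELS))
    if (any(sizes < 3L))
        stop("state(s) with < 3 cells: ",
             paste(names(sizes)[sizes < 3L], collapse = ", "))
    nonConstant <- .rowVars(m) > 0
    sub <- m[nonConstant, , drop = FALSE]
    ranks <- tieTerm <- NULL
    if (ncol(sub) > .EXACT_N_MAX) {
        ranks <- .rowRanks(sub)
        tieTerm <- .rowTieTerm(sub)
    }
    pMat <- vapply(.STATE_LEVELS, function(s) {
        .markerTest(sub, states == s, ranks, tieTerm)$p
    }, numeric(nrow(sub)))
    p <- apply(pMat, 1L, min)
    o <- order(p, seq_along(p))
    keep <- o[seq_len(min(topN, length(o)))]
    gm <- .groupMeans(sub[keep, , drop = FALSE], states)
    gm <- gm[, .STATE_LEVELS, drop = FALSE]
    block <- .STATE_LEVELS[max.col(gm, ties.method = "first")]
    tab <- data.frame(gene = rownames(sub)[keep], p = p[keep], block = block,
                      stringsAsFactors = FALSE)
    rownames(tab) <- NULL
    list(table = tab,
         blocks = lapply(stats::setNames(.STATE_LEVELS, .STATE_LEVELS),
                         function(s) tab$gene[tab$block == s]))
}
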
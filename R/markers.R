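# Marker and DEG detection: one-vs-rest and two-group Wilcoxon screens with
# Benjamini-Hochberg adjustment within each comparison's gene family.

.markerRow <- function(gene, group, logFC, p, meanIn, meanOut) {
    data.frame(gene = gene, group = group, log_fc = logFC, p = p,
               q = NA_real_, mean_in = meanIn, mean_out = meanOut,
               stringsAsFactors = FALSE)
}

# run one two-group comparison over all genes; exact per-gene path for tiny
# column sets, vectorized approximation otherwise
.markerTest <- function(m, inGroup, ranks = NULL, tieTerm = NULL) {
    n <- ncol(m)
    meanIn <- rowMeans(m[, inGroup, drop = FALSE])
    meanOut <- rowMeans(m[, !inGroup, drop = FALSE])
    if (n <= .EXACT_N_MAX) {
        p <- vapply(seq_len(nrow(m)), function(i) {
            rankSumTest(m[i, inGroup], m[i, !inGroup])$p.value
        }, numeric(1))
    } else {
        if (is.null(ranks)) ranks <- .rowRanks(m)
        if (is.null(tieTerm)) tieTerm <- .rowTieTerm(m)
        p <- .rowRankSumP(ranks, tieTerm, inGroup)
    }
    # p = 0 cannot occur (two-sided normal/enumeration p >= minimum mass),
    # but clamp defensively for bhAdjust's domain
    list(p = pmax(p, .Machine$double.xmin), logFC = meanIn - meanOut,
         meanIn = meanIn, meanOut = meanOut)
}

#' One-vs-rest cluster marker detection
#'
#' For every group with at least \code{minCells} cells, tests each gene
#' with the Wilcoxon rank-sum test (group vs all other cells), adjusts
#' p-values by Benjamini-Hochberg within the group's gene family, and
#' retains positive markers with \code{q <= qMax} and
#' \code{log_fc > minLogFC}. The log fold change is the difference of mean
#' natural-log normalized values.
#'
#' @param sce a \linkS4class{SingleCellExperiment} with \code{logcounts},
#'   or a log-normalized genes-by-cells matrix.
#' @param groups per-cell group labels (default: colData \code{cluster});
#'   cells with NA labels are ignored.
#' @param qMax q-value threshold.
#' @param minLogFC retain rows with \code{log_fc} strictly above this.
#' @param minCells groups below this size are skipped with a warning.
#' @param all return all tested rows (unfiltered) instead?
#' @return marker table: \code{gene}, \code{group}, \code{log_fc},
#'   \code{p}, \code{q}, \code{mean_in}, \code{mean_out}.
#' @export
findAllMarkers <- function(sce, groups = NULL, qMax = 0.05, minLogFC = 0,
                           minCells = 3, all = FALSE) {
    m <- .exprMatrix(sce, if (is(sce, "SummarizedExperiment")) "logcounts" else NULL)
    if (is.null(groups)) groups <- colData(sce)$cluster
    groups <- as.character(groups)
    if (length(groups) != ncol(m))
        stop("groups must be parallel to the cells")
    keep <- !is.na(groups)
    m <- m[, keep, drop = FALSE]
    groups <- groups[keep]
    lv <- sort(unique(groups))
    if (length(lv) < 2L)
        stop("need >= 2 groups")
    sizes <- table(groups)
    small <- names(sizes)[sizes < minCells]
    if (length(small)) {
        warning("skipping group(s) below ", minCells, " cells: ",
                paste(small, collapse = ", "))
        lv <- setdiff(lv, small)
    }
    ranks <- tieTerm <- NULL
    if (ncol(m) > .EXACT_N_MAX) {
        ranks <- .rowRanks(m)
        tieTerm <- .rowTieTerm(m)
    }
    res <- lapply(lv, function(g) {
        tst <- .markerTest(m, groups == g, ranks, tieTerm)
        tab <- .markerRow(rownames(m), g, tst$logFC, tst$p, tst$meanIn,
                          tst$meanOut)
        tab$q <- bhAdjust(tab$p)
        if (!all)
            tab <- tab[tab$q <= qMax & tab$log_fc > minLogFC, , drop = FALSE]
        tab
    })
    out <- do.call(rbind, res)
    rownames(out) <- NULL
    out
}

#' Differential expression between two cell groups
#'
#' Per-gene Wilcoxon rank-sum test of group A versus group B with
#' Benjamini-Hochberg adjustment; positive \code{log_fc} means up in A.
#'
#' @param sce expression source as in [findAllMarkers()].
#' @param cellsA,cellsB disjoint cell identifier vectors (or logical/
#'   integer indices), each of size >= 3.
#' @param qMax q-value threshold.
#' @param all return all tested rows instead of the q-filtered table?
#' @param label contrast label stored in the \code{group} column.
#' @return marker table as in [findAllMarkers()]; both signs retained.
#' @export
findMarkersBetween <- function(sce, cellsA, cellsB, qMax = 0.05,
                               all = FALSE, label = "A_vs_B") {
    m <- .exprMatrix(sce, if (is(sce, "SummarizedExperiment")) "logcounts" else NULL)
    toIdx <- function(cells) {
        if (is.character(cells)) match(cells, colnames(m))
        else if (is.logical(cells)) which(cells)
        else as.integer(cells)
    }
    ia <- toIdx(cellsA); ib <- toIdx(cellsB)
    if (anyNA(ia) || anyNA(ib))
        stop("unknown cell identifiers")
    if (length(intersect(ia, ib)))
        stop("groups overlap")
    if (length(ia) < 3L || length(ib) < 3L)
        stop("both groups need >= 3 cells")
    sub <- m[, c(ia, ib), drop = FALSE]
    inA <- c(rep(TRUE, length(ia)), rep(FALSE, length(ib)))
    tst <- .markerTest(sub, inA)
    tab <- .markerRow(rownames(m), label, tst$logFC, tst$p, tst$meanIn,
                      tst$meanOut)
    tab$q <- bhAdjust(tab$p)
    if (!all) tab <- tab[tab$q <= qMax, , drop = FALSE]
    rownames(tab) <- NULL
    tab
}

#' Tally differentially expressed genes per contrast
#'
#' @param tables a marker table from [findMarkersBetween()] or a named
#'   list of such tables (one per cluster).
#' @return data.frame with \code{group}, \code{n_up} (positive log_fc),
#'   \code{n_down}, \code{n_total}.
#' @export
countDEGs <- function(tables) {
    if (is.data.frame(tables)) tables <- list(tables)
    if (is.null(names(tables)))
        names(tables) <- vapply(tables, function(t) {
            if (nrow(t)) t$group[1] else "empty"
        }, character(1))
    out <- do.call(rbind, lapply(names(tables), function(nm) {
        t <- tables[[nm]]
        up <- sum(t$log_fc > 0)
        down <- sum(t$log_fc < 0)
        data.frame(group = nm, n_up = up, n_down = down,
                   n_total = up + down, stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    out
}
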
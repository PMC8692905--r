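#' Flag mitochondrial genes by name prefix
#'
#' @param sce a \linkS4class{SingleCellExperiment}.
#' @param prefix gene-name prefix identifying mitochondrial genes.
#' @return \code{sce} with a logical \code{is_mito} column in its rowData.
#' @export
flagMitoGenes <- function(sce, prefix = "MT-") {
    rowData(sce)$is_mito <- startsWith(rownames(sce), prefix)
    sce
}

.makeFilterReport <- function(nCellsIn, nCellsOut, nGenesIn, nGenesOut,
                              umiBounds = c(NA_real_, NA_real_),
                              removedCells = character(),
                              removedGenes = character(),
                              thresholds = list()) {
    new("FilterReport",
        nCellsIn = as.integer(nCellsIn), nCellsOut = as.integer(nCellsOut),
        nGenesIn = as.integer(nGenesIn), nGenesOut = as.integer(nGenesOut),
        umiBounds = as.numeric(umiBounds),
        removedCells = removedCells, removedGenes = removedGenes,
        thresholds = thresholds)
}

.appendReport <- function(sce, name, report) {
    qc <- metadata(sce)$qc
    if (is.null(qc)) qc <- list()
    qc[[name]] <- report
    metadata(sce)$qc <- qc
    sce
}

#' Filtering audit reports stored on an object
#'
#' @param sce a \linkS4class{SingleCellExperiment} that has passed through
#'   [filterCells()] and/or [filterGenes()].
#' @return named list of [FilterReport-class] objects (possibly empty).
#' @export
filterReports <- function(sce) {
    qc <- metadata(sce)$qc
    if (is.null(qc)) list() else qc
}

#' Filter cells by sequencing depth and detected genes
#'
#' Retains cells whose log10 total UMI count lies within
#' \code{sdWindow} sample standard deviations of the mean log10 UMI of all
#' input cells (inclusive bounds, computed once on the input population)
#' and which detect at least \code{minGenes} genes (count > 0).
#'
#' @param sce a \linkS4class{SingleCellExperiment} with a \code{counts}
#'   assay; every cell must have total UMI > 0.
#' @param sdWindow half-width of the log10-UMI window in s.d. units.
#' @param minGenes minimum number of detected genes per cell (inclusive).
#' @return filtered \code{sce}; the audit record is available via
#'   \code{filterReports(sce)$cells}.
#' @examples
#' sim <- generateCounts(simulationConfig(nClusters = 2,
#'     cellsPerClusterPerCondition = 10, nGenes = 100, nMitoGenes = 3,
#'     nSecreted = 5, nReceptors = 5, nPlantedPairs = 1,
#'     nMarkersPerCluster = 3, nStateGenes = 3, receiverCluster = 1,
#'     senderCluster = 2, seed = 1))
#' filtered <- filterCells(sim$sce, minGenes = 10)
#' filterReports(filtered)$cells
#' @export
filterCells <- function(sce, sdWindow = 2, minGenes = 1000) {
    if (ncol(sce) == 0L || nrow(sce) == 0L)
        stop("empty count matrix")
    .stopifnotScalar(sdWindow, "sdWindow", lower = 0)
    .stopifnotScalar(minGenes, "minGenes", lower = 0)
    m <- .exprMatrix(sce, "counts")
    totals <- colSums(m)
    if (any(totals <= 0))
        stop("cell(s) with zero total UMI: ",
             paste(colnames(m)[totals <= 0], collapse = ", "))
    l10 <- log10(totals)
    mu <- mean(l10)
    s <- if (length(l10) > 1L) sd(l10) else 0
    if (is.na(s)) s <- 0
    bounds <- c(mu - sdWindow * s, mu + sdWindow * s)
    # tolerance guards the degenerate all-identical case against fp jitter
    eps <- 1e-10 * max(1, abs(mu))
    inWindow <- l10 >= bounds[1] - eps & l10 <= bounds[2] + eps
    detected <- colSums(m > 0)
    keep <- inWindow & detected >= minGenes
    report <- .makeFilterReport(
        nCellsIn = ncol(m), nCellsOut = sum(keep),
        nGenesIn = nrow(m), nGenesOut = nrow(m),
        umiBounds = bounds,
        removedCells = colnames(m)[!keep],
        thresholds = list(sd_window = sdWindow, min_genes = minGenes))
    .appendReport(sce[, keep], "cells", report)
}

#' Filter genes by prevalence and mitochondrial status
#'
#' Retains genes detected (count > 0) in at least \code{minCells} cells;
#' when \code{dropMito} is TRUE, genes flagged mitochondrial are removed
#' regardless of prevalence. Mitochondrial status is taken from the
#' \code{is_mito} rowData column if present, else from \code{mitoPrefix}.
#'
#' @param sce a \linkS4class{SingleCellExperiment} with a \code{counts} assay.
#' @param minCells minimum number of cells a gene must be detected in.
#' @param dropMito remove mitochondrial genes?
#' @param mitoPrefix gene-name prefix used when no \code{is_mito} flag exists.
#' @return filtered \code{sce}; audit record under
#'   \code{filterReports(sce)$genes}.
#' @export
filterGenes <- function(sce, minCells = 10, dropMito = TRUE,
                        mitoPrefix = "MT-") {
    if (ncol(sce) == 0L || nrow(sce) == 0L)
        stop("empty count matrix")
    .stopifnotScalar(minCells, "minCells", lower = 0)
    m <- .exprMatrix(sce, "counts")
    isMito <- if ("is_mito" %in% names(rowData(sce))) rowData(sce)$is_mito
              else startsWith(rownames(m), mitoPrefix)
    detected <- rowSums(m > 0)
    keep <- detected >= minCells
    if (dropMito) keep <- keep & !isMito
    report <- .makeFilterReport(
        nCellsIn = ncol(m), nCellsOut = ncol(m),
        nGenesIn = nrow(m), nGenesOut = sum(keep),
        removedGenes = rownames(m)[!keep],
        thresholds = list(min_cells = minCells, drop_mito = dropMito))
    .appendReport(sce[keep, ], "genes", report)
}

#' Size-factor log normalization
#'
#' Within each cell, each gene's UMI count is divided by the cell's total
#' UMI count (over the genes present, i.e. after gene filtering),
#' multiplied by a size factor of 10,000 to give a TPM-like value, and
#' transformed as \code{ln(x + 1)}. The result satisfies, for every cell,
#' \eqn{\sum_g (e^{v_g} - 1) = 10{,}000} exactly.
#'
#' @param sce a \linkS4class{SingleCellExperiment} with a \code{counts}
#'   assay; every cell must have total UMI > 0.
#' @param sizeFactor the size factor (default 10,000).
#' @return \code{sce} with a \code{logcounts} assay added;
#'   \code{metadata(sce)$sizeFactor} records the factor.
#' @export
logNormalize <- function(sce, sizeFactor = 10000) {
    m <- .exprMatrix(sce, "counts")
    totals <- colSums(m)
    if (any(totals <= 0))
        stop("cell(s) with zero total UMI: ",
             paste(colnames(m)[totals <= 0], collapse = ", "))
    v <- log1p(sweep(m, 2, sizeFactor / totals, `*`))
    SummarizedExperiment::assay(sce, "logcounts") <- v
    metadata(sce)$sizeFactor <- sizeFactor
    sce
}

#' Select variable genes by mean and dispersion bounds
#'
#' A gene is variable when its mean log-normalized value lies in
#' \code{[meanLow, meanHigh]} and its dispersion exceeds
#' \code{minDispersion}, where dispersion is variance/mean of the
#' natural-scale values \eqn{e^v - 1}.
#'
#' @param sce a \linkS4class{SingleCellExperiment} with \code{logcounts}
#'   (or a plain log-normalized matrix).
#' @param meanLow,meanHigh inclusive bounds on the mean log value.
#' @param minDispersion exclusive lower bound on dispersion.
#' @return character vector of variable gene names.
#' @export
selectVariableGenes <- function(sce, meanLow = 0.01, meanHigh = 3,
                                minDispersion = 1) {
    v <- .exprMatrix(sce, if (is(sce, "SummarizedExperiment")) "logcounts" else NULL)
    if (ncol(v) == 0L) stop("empty matrix")
    meanLog <- rowMeans(v)
    nat <- expm1(v)
    mu <- rowMeans(nat)
    disp <- rep(0, nrow(v))
    ok <- mu > 0 & ncol(v) > 1L
    disp[ok] <- .rowVars(nat[ok, , drop = FALSE]) / mu[ok]
    rownames(v)[meanLog >= meanLow & meanLog <= meanHigh & disp > minDispersion]
}

#' Per-cell similarity to its cluster's average profile
#'
#' Pearson correlation of each cell's expression vector with the per-gene
#' mean vector of its own cluster; by default the cell is included in the
#' mean, with \code{excludeSelf = TRUE} as a sensitivity option.
#'
#' @param sce a \linkS4class{SingleCellExperiment} with \code{logcounts}
#'   (or a log-normalized matrix).
#' @param clusters per-cell cluster labels (default: colData
#'   \code{cluster}); every cluster needs >= 2 cells.
#' @param excludeSelf leave the cell out of its cluster centroid?
#' @return named numeric vector of correlations in [-1, 1].
#' @export
cellSimilarity <- function(sce, clusters = NULL, excludeSelf = FALSE) {
    v <- .exprMatrix(sce, if (is(sce, "SummarizedExperiment")) "logcounts" else NULL)
    if (is.null(clusters)) clusters <- colData(sce)$cluster
    clusters <- as.character(clusters)
    if (length(clusters) != ncol(v))
        stop("clusters must be parallel to the cells")
    sizes <- table(clusters)
    if (any(sizes < 2L))
        stop("every cluster needs >= 2 cells; too small: ",
             paste(names(sizes)[sizes < 2L], collapse = ", "))
    out <- numeric(ncol(v))
    names(out) <- colnames(v)
    for (cl in names(sizes)) {
        idx <- which(clusters == cl)
        sub <- v[, idx, drop = FALSE]
        centSum <- rowSums(sub)
        n <- length(idx)
        for (j in seq_len(n)) {
            cell <- sub[, j]
            cent <- if (excludeSelf) (centSum - cell) / (n - 1L) else centSum / n
            if (sd(cell) == 0)
                stop("constant expression vector for cell ", colnames(sub)[j])
            if (sd(cent) == 0)
                stop("constant centroid for cluster ", cl,
                     " (cell ", colnames(sub)[j], ")")
            out[idx[j]] <- cor(cell, cent)
        }
    }
    out
}

#' Correlation matrix of group average expression profiles
#'
#' Pearson correlation between the per-gene mean vectors of every pair of
#' groups (typically cluster-by-condition).
#'
#' @param sce a \linkS4class{SingleCellExperiment} with \code{logcounts}
#'   (or a log-normalized matrix).
#' @param groups per-cell group labels; every group needs >= 2 cells.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
clusterCorrelationMatrix <- function(sce, groups) {
    v <- .exprMatrix(sce, if (is(sce, "SummarizedExperiment")) "logcounts" else NULL)
    groups <- as.character(groups)
    sizes <- table(groups)
    if (length(sizes) < 2L)
        stop("need >= 2 groups")
    if (any(sizes < 2L))
        stop("every group needs >= 2 cells")
    gm <- .groupMeans(v, groups)
    constant <- apply(gm, 2, sd) == 0
    if (any(constant))
        stop("constant mean vector for group(s): ",
             paste(colnames(gm)[constant], collapse = ", "))
    cc <- cor(gm)
    diag(cc) <- 1
    cc
}
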
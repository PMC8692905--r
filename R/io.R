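# Readers/writers for the package's on-disk formats: MatrixMarket counts
# with gene/cell sidecars, dense TSV counts, ligand-receptor database TSVs
# (toy dialect and a CellPhoneDB-style dialect), two-column GO annotation,
# trajectory TSV, marker tables and ground-truth JSON.

#' Write a count matrix as MatrixMarket + sidecars
#'
#' Writes \code{matrix.mtx} (genes x cells, 1-based triplets),
#' \code{genes.tsv} (gene id plus gene flags) and \code{barcodes.tsv}
#' (cell id plus donor/condition/cluster metadata).
#'
#' @param sce a \linkS4class{SingleCellExperiment} with a \code{counts}
#'   assay.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeCountsMTX <- function(sce, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    m <- SummarizedExperiment::assay(sce, "counts")
    Matrix::writeMM(methods::as(methods::as(Matrix::Matrix(m, sparse = TRUE),
                                            "CsparseMatrix"), "generalMatrix"),
                    file.path(dir, "matrix.mtx"))
    genes <- data.frame(gene = rownames(sce),
                        as.data.frame(rowData(sce)),
                        check.names = FALSE)
    write.table(genes, file.path(dir, "genes.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    cells <- data.frame(cell = colnames(sce),
                        as.data.frame(colData(sce)),
                        check.names = FALSE)
    write.table(cells, file.path(dir, "barcodes.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    invisible(dir)
}

#' Read a count matrix from MatrixMarket + sidecars
#'
#' @param dir directory holding \code{matrix.mtx}, \code{genes.tsv} and
#'   \code{barcodes.tsv} as written by [writeCountsMTX()].
#' @param mitoPrefix prefix used to flag mitochondrial genes when the
#'   sidecar carries no \code{is_mito} column.
#' @return a \linkS4class{SingleCellExperiment}.
#' @export
readCountsMTX <- function(dir, mitoPrefix = "MT-") {
    m <- as.matrix(Matrix::readMM(file.path(dir, "matrix.mtx")))
    storage.mode(m) <- "integer"
    genes <- read.delim(file.path(dir, "genes.tsv"), stringsAsFactors = FALSE)
    cells <- read.delim(file.path(dir, "barcodes.tsv"), stringsAsFactors = FALSE)
    if (nrow(genes) != nrow(m) || nrow(cells) != ncol(m))
        stop("sidecar dimensions do not match the matrix")
    dimnames(m) <- list(genes$gene, cells$cell)
    rd <- genes[, setdiff(names(genes), "gene"), drop = FALSE]
    if (!"is_mito" %in% names(rd))
        rd$is_mito <- startsWith(genes$gene, mitoPrefix)
    cd <- cells[, setdiff(names(cells), "cell"), drop = FALSE]
    if ("condition" %in% names(cd))
        cd$condition <- factor(.checkCondition(cd$condition),
                               levels = .CONDITIONS)
    sce <- SingleCellExperiment(
        assays = list(counts = m),
        colData = DataFrame(cd, row.names = cells$cell),
        rowData = DataFrame(rd, row.names = genes$gene))
    sce
}

#' Read a dense TSV count matrix
#'
#' @param file TSV with genes as rows (first column gene ids) and cells as
#'   columns.
#' @param metaFile optional cell metadata TSV with a \code{cell} column
#'   matching the matrix columns.
#' @param mitoPrefix prefix used to flag mitochondrial genes.
#' @return a \linkS4class{SingleCellExperiment}.
#' @export
readCountsTSV <- function(file, metaFile = NULL, mitoPrefix = "MT-") {
    tab <- read.delim(file, check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(tab[, -1, drop = FALSE])
    storage.mode(m) <- "integer"
    rownames(m) <- tab[[1]]
    cd <- DataFrame(row.names = colnames(m))
    if (!is.null(metaFile)) {
        meta <- read.delim(metaFile, stringsAsFactors = FALSE)
        idx <- match(colnames(m), meta$cell)
        if (anyNA(idx)) stop("metadata missing for some cells")
        cd <- DataFrame(meta[idx, setdiff(names(meta), "cell"), drop = FALSE],
                        row.names = colnames(m))
        if ("condition" %in% names(cd))
            cd$condition <- factor(.checkCondition(cd$condition),
                                   levels = .CONDITIONS)
    }
    SingleCellExperiment(
        assays = list(counts = m), colData = cd,
        rowData = DataFrame(is_mito = startsWith(rownames(m), mitoPrefix),
                            row.names = rownames(m)))
}

#' Write a ligand-receptor database as TSV files
#'
#' Writes \code{secreted.tsv} (one column \code{gene}), \code{receptors.tsv}
#' (one column \code{gene}) and \code{pairs.tsv} (\code{ligand},
#' \code{receptor}).
#'
#' @param db a [LigandReceptorDB-class].
#' @param dir output directory.
#' @return \code{dir}, invisibly.
#' @export
writeLigandReceptorDB <- function(db, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write.table(data.frame(gene = secretedGenes(db)),
                file.path(dir, "secreted.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(data.frame(gene = receptorGenes(db)),
                file.path(dir, "receptors.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(lrPairs(db), file.path(dir, "pairs.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    invisible(dir)
}

#' Read a ligand-receptor database from TSV files
#'
#' @param dir directory with \code{secreted.tsv}, \code{receptors.tsv},
#'   \code{pairs.tsv} as written by [writeLigandReceptorDB()].
#' @return a [LigandReceptorDB-class].
#' @export
readLigandReceptorDB <- function(dir) {
    secreted <- read.delim(file.path(dir, "secreted.tsv"),
                           stringsAsFactors = FALSE)$gene
    receptors <- read.delim(file.path(dir, "receptors.tsv"),
                            stringsAsFactors = FALSE)$gene
    pairs <- read.delim(file.path(dir, "pairs.tsv"), stringsAsFactors = FALSE)
    ligandReceptorDB(secreted, receptors, pairs)
}

#' Read a CellPhoneDB-style database
#'
#' Minimal reader for the three-table dialect: \code{gene_input}
#' (\code{gene_name}, \code{uniprot}), \code{protein_input}
#' (\code{uniprot}, \code{secreted}, \code{receptor}) and
#' \code{interaction_input} (\code{partner_a}, \code{partner_b}; partner a
#' is taken as the ligand side). Interactions whose partners do not map to
#' gene names are dropped.
#'
#' @param geneFile,proteinFile,interactionFile paths to the three TSVs
#'   (CSV also accepted by extension).
#' @return a [LigandReceptorDB-class].
#' @export
readCellPhoneDB <- function(geneFile, proteinFile, interactionFile) {
    readAny <- function(f) {
        if (grepl("\\.csv$", f)) utils::read.csv(f, stringsAsFactors = FALSE)
        else read.delim(f, stringsAsFactors = FALSE)
    }
    genes <- readAny(geneFile)
    prot <- readAny(proteinFile)
    inter <- readAny(interactionFile)
    toLogical <- function(x) {
        if (is.logical(x)) x else tolower(as.character(x)) %in% c("true", "1", "yes")
    }
    gmap <- stats::setNames(genes$gene_name, genes$uniprot)
    secreted <- sort(unique(stats::na.omit(
        gmap[prot$uniprot[toLogical(prot$secreted)]])))
    receptors <- sort(unique(stats::na.omit(
        gmap[prot$uniprot[toLogical(prot$receptor)]])))
    lig <- unname(gmap[inter$partner_a])
    rec <- unname(gmap[inter$partner_b])
    ok <- !is.na(lig) & !is.na(rec) & lig %in% secreted & rec %in% receptors
    ligandReceptorDB(secreted, receptors,
                     data.frame(ligand = lig[ok], receptor = rec[ok],
                                stringsAsFactors = FALSE))
}

#' Write / read a two-column gene-to-term annotation
#'
#' @param annotation data.frame with columns \code{gene}, \code{term}.
#' @param file TSV path (header row \code{gene\tterm}).
#' @return [readGeneAnnotation()] returns the data.frame.
#' @export
writeGeneAnnotation <- function(annotation, file) {
    write.table(annotation[, c("gene", "term")], file, sep = "\t",
                quote = FALSE, row.names = FALSE)
    invisible(file)
}

#' @rdname writeGeneAnnotation
#' @export
readGeneAnnotation <- function(file) {
    ann <- read.delim(file, stringsAsFactors = FALSE)
    names(ann)[1:2] <- c("gene", "term")
    ann[, c("gene", "term")]
}

#' Write / read a trajectory assignment TSV
#'
#' Dialect: \code{cell_id}, \code{pseudotime}, \code{state}; the two cut
#' points are stored as a comment-free extra column repeated per row when
#' writing and recomputed as segment boundaries when reading an external
#' file without them.
#'
#' @param traj a [TrajectoryAssignment-class].
#' @param file TSV path.
#' @return [readTrajectory()] returns a [TrajectoryAssignment-class].
#' @export
writeTrajectory <- function(traj, file) {
    tab <- data.frame(cell_id = traj@cellIds, pseudotime = traj@pseudotime,
                      state = as.character(traj@state),
                      cut_low = cutpoints(traj)[1],
                      cut_high = cutpoints(traj)[2],
                      stringsAsFactors = FALSE)
    write.table(tab, file, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(file)
}

#' @rdname writeTrajectory
#' @export
readTrajectory <- function(file) {
    tab <- read.delim(file, stringsAsFactors = FALSE)
    cuts <- if (all(c("cut_low", "cut_high") %in% names(tab)))
        c(tab$cut_low[1], tab$cut_high[1])
    else {
        # infer boundaries between adjacent distinct states in pt order
        o <- order(tab$pseudotime)
        st <- tab$state[o]; pt <- tab$pseudotime[o]
        ch <- which(st[-1] != st[-length(st)])
        if (length(ch) != 2L)
            stop("cannot infer two cut points from the state labels")
        (pt[ch] + pt[ch + 1]) / 2
    }
    new("TrajectoryAssignment", cellIds = as.character(tab$cell_id),
        pseudotime = as.numeric(tab$pseudotime),
        state = factor(tab$state, levels = .STATE_LEVELS),
        cutpoints = as.numeric(cuts))
}

#' Write a marker table as TSV
#'
#' @param markers a marker table.
#' @param file TSV path.
#' @export
writeMarkerTable <- function(markers, file) {
    write.table(markers, file, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(file)
}

#' Write / read the simulation ground truth as JSON
#'
#' @param truth a [GroundTruth-class].
#' @param file JSON path.
#' @return [readGroundTruth()] returns a [GroundTruth-class].
#' @export
writeGroundTruth <- function(truth, file) {
    x <- list(planted_markers = truth@plantedMarkers,
              planted_pairs = truth@plantedPairs,
              planted_state_genes = truth@plantedStateGenes,
              shared_terms = truth@sharedTerms,
              cell_states = truth@cellStates,
              sender_cluster = truth@senderCluster,
              receiver_cluster = truth@receiverCluster)
    jsonlite::write_json(x, file, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    invisible(file)
}

#' @rdname writeGroundTruth
#' @export
readGroundTruth <- function(file) {
    x <- jsonlite::read_json(file, simplifyVector = TRUE)
    asList <- function(l) lapply(l, function(v) as.character(unlist(v)))
    new("GroundTruth",
        plantedMarkers = asList(x$planted_markers),
        plantedPairs = as.data.frame(x$planted_pairs),
        plantedStateGenes = asList(x$planted_state_genes),
        sharedTerms = asList(x$shared_terms),
        cellStates = as.data.frame(x$cell_states),
        senderCluster = x$sender_cluster,
        receiverCluster = x$receiver_cluster)
}

#' Stand-in cell clusterer
#'
#' Plumbing only: k-means on the leading principal components of the
#' variable-gene submatrix, for workflows where no cluster labels are
#' supplied. Real analyses should provide curated cluster labels as input.
#'
#' @param sce a \linkS4class{SingleCellExperiment} with \code{logcounts}.
#' @param k number of clusters.
#' @param nPCs principal components to use.
#' @param seed seed for the k-means restarts.
#' @return character vector of per-cell cluster labels ("K1"..."Kk").
#' @export
clusterCellsStandin <- function(sce, k, nPCs = 10, seed = 1) {
    m <- .exprMatrix(sce, "logcounts")
    vg <- selectVariableGenes(sce)
    if (length(vg) < 2L) stop("fewer than 2 variable genes")
    nPCs <- min(nPCs, length(vg) - 1L, ncol(m) - 1L)
    pcs <- prcomp(t(m[vg, , drop = FALSE]), center = TRUE,
                  scale. = FALSE, rank. = nPCs)$x
    set.seed(seed)
    km <- kmeans(pcs, centers = k, nstart = 10)
    paste0("K", km$cluster)
}
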
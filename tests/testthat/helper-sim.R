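# shared fixtures: a fast small design for unit tests and a memoized full
# reference analysis (default design) shared by the recovery tests

suppressPackageStartupMessages({
    library(SingleCellExperiment)
    library(SummarizedExperiment)
    library(S4Vectors)
})

tinyConfig <- function(seed = 1, ...) {
    args <- list(nClusters = 3, cellsPerClusterPerCondition = 20,
                 nGenes = 200, nMitoGenes = 6, nSecreted = 12,
                 nReceptors = 10, nPlantedPairs = 3,
                 nMarkersPerCluster = 5, nStateGenes = 8,
                 senderCluster = 2, receiverCluster = 3, seed = seed)
    args[names(list(...))] <- list(...)
    do.call(simulationConfig, args)
}

# SCE from a bare counts matrix (for hand-built QC toys)
makeSCE <- function(counts, condition = NULL, cluster = NULL) {
    counts <- as.matrix(counts)
    if (is.null(rownames(counts)))
        rownames(counts) <- sprintf("g%03d", seq_len(nrow(counts)))
    if (is.null(colnames(counts)))
        colnames(counts) <- sprintf("c%03d", seq_len(ncol(counts)))
    storage.mode(counts) <- "integer"
    cd <- DataFrame(row.names = colnames(counts))
    if (!is.null(condition))
        cd$condition <- factor(condition, levels = c("nonAD", "AD"))
    if (!is.null(cluster)) cd$cluster <- cluster
    SingleCellExperiment(assays = list(counts = counts), colData = cd)
}

# union of all genes planted as elevated in each cluster (markers plus the
# sender's ligands, the receiver's receptors and trajectory program genes)
plantedElevated <- function(truth) {
    elev <- plantedMarkers(truth)
    pp <- plantedPairs(truth)
    elev[[truth@senderCluster]] <-
        c(elev[[truth@senderCluster]], unique(pp$ligand))
    elev[[truth@receiverCluster]] <-
        c(elev[[truth@receiverCluster]], unique(pp$receptor),
          unlist(plantedStateGenes(truth), use.names = FALSE))
    elev
}

.refCache <- new.env(parent = emptyenv())

# full analysis of the reference design (4 clusters x 2 x 100 cells),
# computed once per session and shared across recovery tests
referenceAnalysis <- function(seed = 7) {
    key <- paste0("ref", seed)
    if (!is.null(.refCache[[key]])) return(.refCache[[key]])
    ds <- simulateDataset(simulationConfig(seed = seed))
    sce <- logNormalize(filterGenes(filterCells(ds$sce, minGenes = 100)))
    truth <- ds$truth
    recv <- colnames(sce)[colData(sce)$cluster == truth@receiverCluster]
    pt <- orderCells(sce, cells = recv)
    cond <- as.character(colData(sce)$condition)[match(recv, colnames(sce))]
    traj <- assignStates(pt, cond)
    blocks <- stateDEGs(sce, traj, topN = 200)
    stateTerms <- lapply(blocks$blocks, function(g) {
        if (!length(g)) character()
        else goEnrichment(g, ds$annotation, rownames(sce))$term
    })
    groups <- suppressWarnings(conditionGroups(sce))
    groupMarkers <- findAllMarkers(sce, groups)
    ligandSets <- extractClusterLigands(groupMarkers, ds$db)
    receptorSets <- extractClusterReceptors(groupMarkers, ds$db)
    recvGroups <- intersect(names(receptorSets),
                            paste0(c("n-", "d-"), truth@receiverCluster))
    capacity <- secretingCapacity(sce, groups, ligandSets)
    cross <- crossmatchLigands(ligandSets, ds$annotation, stateTerms)
    scores <- scoreLRPairs(sce, groups, ds$db, ligandSets,
                           receptorSets[recvGroups])
    out <- list(ds = ds, sce = sce, truth = truth, recv = recv, pt = pt,
                cond = cond, traj = traj, blocks = blocks,
                stateTerms = stateTerms, groups = groups,
                groupMarkers = groupMarkers, ligandSets = ligandSets,
                receptorSets = receptorSets, capacity = capacity,
                cross = cross, scores = scores)
    .refCache[[key]] <- out
    out
}
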
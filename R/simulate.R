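#' Build a simulation design
#'
#' Defaults describe the reference synthetic dataset used throughout the
#' package: four clusters (two fibroblast-like, one macrophage-like, one
#' SMC-like receiver) sampled from two conditions (non-dissected
#' \code{nonAD} and dissected \code{AD} aorta) across several donors, a
#' 37-gene mitochondrial panel, secreted and receptor panels with a handful
#' of planted ligand--receptor pairs from the sender (fibroblast-like)
#' cluster to the SMC-like receiver, and a three-program severity
#' trajectory inside the receiver cluster.
#'
#' @param nClusters,cellsPerClusterPerCondition,nGenes,nMitoGenes,nSecreted,nReceptors,nPlantedPairs,nMarkersPerCluster,nStateGenes,markerFoldChange,stateFoldChange,librarySizeMean,librarySizeSdLog,dispersion,nDonorsPerCondition,senderCluster,receiverCluster,seed
#'   see [SimulationConfig-class].
#' @return A validated [SimulationConfig-class] object.
#' @examples
#' simulationConfig(nClusters = 3, cellsPerClusterPerCondition = 20,
#'                  nGenes = 200, nMitoGenes = 5, nSecreted = 10,
#'                  nReceptors = 8, nPlantedPairs = 2, seed = 7)
#' @export
simulationConfig <- function(nClusters = 4,
                             cellsPerClusterPerCondition = 100,
                             nGenes = 1000,
                             nMitoGenes = 37,
                             nSecreted = 40,
                             nReceptors = 30,
                             nPlantedPairs = 6,
                             nMarkersPerCluster = 10,
                             nStateGenes = 20,
                             markerFoldChange = 4,
                             stateFoldChange = 4,
                             librarySizeMean = 10000,
                             librarySizeSdLog = 0.3,
                             dispersion = 0.5,
                             nDonorsPerCondition = 3,
                             senderCluster = 2,
                             receiverCluster = nClusters,
                             seed = 1) {
    new("SimulationConfig",
        nClusters = as.integer(nClusters),
        cellsPerClusterPerCondition = as.integer(cellsPerClusterPerCondition),
        nGenes = as.integer(nGenes),
        nMitoGenes = as.integer(nMitoGenes),
        nSecreted = as.integer(nSecreted),
        nReceptors = as.integer(nReceptors),
        nPlantedPairs = as.integer(nPlantedPairs),
        nMarkersPerCluster = as.integer(nMarkersPerCluster),
        nStateGenes = as.integer(nStateGenes),
        markerFoldChange = as.numeric(markerFoldChange),
        stateFoldChange = as.numeric(stateFoldChange),
        librarySizeMean = as.numeric(librarySizeMean),
        librarySizeSdLog = as.numeric(librarySizeSdLog),
        dispersion = as.numeric(dispersion),
        nDonorsPerCondition = as.integer(nDonorsPerCondition),
        senderCluster = as.integer(senderCluster),
        receiverCluster = as.integer(receiverCluster),
        seed = as.integer(seed))
}

# latent severity of receiver cells: three severity bands (healthy-like,
# intermediate, diseased-like) separated by gaps, emulating discrete
# trajectory branch states with a within-state continuum. Deterministic
# stratified grids give the bands a known condition composition: the low
# band is pure non-AD, the middle band an even mix, the high band pure AD.
.latentSeverity <- function(nPerCondition) {
    lo <- ceiling(nPerCondition / 2)
    hi <- nPerCondition - lo
    band <- function(a, b, n) if (n) seq(a, b, length.out = n) else numeric()
    list(nonAD = c(band(0, 0.28, lo), band(0.38, 0.62, hi)),
         AD = c(band(0.38, 0.62, lo), band(0.72, 1, hi)))
}

.severityState <- function(t) {
    ifelse(t < 1 / 3, "nonAD_enriched",
           ifelse(t > 2 / 3, "AD_enriched", "transition"))
}

#' Simulate a multi-donor two-condition UMI count matrix
#'
#' Gamma-Poisson (negative binomial) counts with per-cell log-normal
#' library sizes. Planted structure: per-cluster marker genes up-shifted by
#' \code{markerFoldChange}; for each planted ligand--receptor pair the
#' ligand is additionally up-shifted in the sender cluster's AD cells only
#' and the receptor up-shifted in the receiver cluster; receiver cells
#' carry a latent severity \code{t} in [0, 1] driving three smooth gene
#' programs (down-, transient- and up-regulated along \code{t}).
#' Mitochondrial genes carry the \code{"MT-"} name prefix.
#'
#' @param config a [SimulationConfig-class].
#' @return list with elements \code{sce} (a
#'   \linkS4class{SingleCellExperiment} with a \code{counts} assay, cell
#'   metadata \code{donor}/\code{condition}/\code{cluster} and gene flags
#'   \code{is_mito}/\code{is_secreted}/\code{is_receptor}) and \code{truth}
#'   (a [GroundTruth-class]).
#' @examples
#' sim <- generateCounts(simulationConfig(nClusters = 3,
#'     cellsPerClusterPerCondition = 15, nGenes = 150, nMitoGenes = 5,
#'     nSecreted = 8, nReceptors = 6, nPlantedPairs = 2,
#'     nMarkersPerCluster = 4, nStateGenes = 5, seed = 1))
#' dim(sim$sce)
#' @export
generateCounts <- function(config) {
    stopifnot(is(config, "SimulationConfig"))
    validObject(config)
    set.seed(config@seed)

    k <- config@nClusters
    cpc <- config@cellsPerClusterPerCondition
    nCells <- k * 2L * cpc
    nGenes <- config@nGenes
    clusters <- paste0("C", seq_len(k))
    sender <- clusters[config@senderCluster]
    receiver <- clusters[config@receiverCluster]

    cluster <- rep(clusters, each = 2L * cpc)
    condition <- rep(rep(.CONDITIONS, each = cpc), times = k)
    donor <- ifelse(condition == "nonAD",
                    paste0("N", rep_len(seq_len(config@nDonorsPerCondition), nCells)),
                    paste0("A", rep_len(seq_len(config@nDonorsPerCondition), nCells)))
    cellIds <- sprintf("cell%04d", seq_len(nCells))

    # gene panel: mito / secreted / receptor prefixes, generic remainder
    nGeneric <- nGenes - config@nMitoGenes - config@nSecreted - config@nReceptors
    geneIds <- c(if (config@nMitoGenes) paste0("MT-", seq_len(config@nMitoGenes)),
                 if (config@nSecreted) sprintf("SEC%03d", seq_len(config@nSecreted)),
                 if (config@nReceptors) sprintf("REC%03d", seq_len(config@nReceptors)),
                 sprintf("G%04d", seq_len(nGeneric)))
    isMito <- startsWith(geneIds, "MT-")
    isSecreted <- startsWith(geneIds, "SEC")
    isReceptor <- startsWith(geneIds, "REC")
    genericGenes <- geneIds[!(isMito | isSecreted | isReceptor)]

    # planted structure drawn from the generic pool (disjoint sets)
    pool <- sample(genericGenes)
    take <- function(n) {
        out <- pool[seq_len(n)]
        pool <<- pool[-seq_len(n)]
        out
    }
    markers <- stats::setNames(
        lapply(seq_len(k), function(i) sort(take(config@nMarkersPerCluster))),
        clusters)
    stateGenes <- list(nonAD_enriched = sort(take(config@nStateGenes)),
                       transition = sort(take(config@nStateGenes)),
                       AD_enriched = sort(take(config@nStateGenes)))

    lig <- sort(sample(geneIds[isSecreted], config@nPlantedPairs))
    rec <- sort(sample(geneIds[isReceptor], config@nPlantedPairs))
    pairs <- data.frame(sender = rep(sender, config@nPlantedPairs),
                        ligand = lig, receiver = rep(receiver, config@nPlantedPairs),
                        receptor = rec, stringsAsFactors = FALSE)

    # baseline relative propensities: long-tailed, mito-rich; planted genes
    # floored to mid-range expression so the planted signal is detectable
    base <- rlnorm(nGenes, meanlog = 0, sdlog = 1.2)
    names(base) <- geneIds
    base[isMito] <- base[isMito] * 5
    special <- c(unlist(markers), unlist(stateGenes), lig, rec)
    base[special] <- runif(length(special), 0.8, 1.5)

    # multiplicative fold-change matrix (genes x cells)
    fold <- matrix(1, nGenes, nCells, dimnames = list(geneIds, cellIds))
    fc <- config@markerFoldChange
    for (cl in clusters)
        fold[markers[[cl]], cluster == cl] <- fc
    recvCells <- cluster == receiver
    fold[rec, recvCells] <- fc
    fold[lig, cluster == sender & condition == "AD"] <- fc

    # receiver severity programs: smooth functions of the latent t
    tg <- .latentSeverity(cpc)
    tAll <- numeric(nCells)
    tAll[recvCells & condition == "nonAD"] <- tg$nonAD
    tAll[recvCells & condition == "AD"] <- tg$AD
    # programs are block-structured by state (like branch-DEG heatmap
    # blocks): full fold in the program's own state, an intermediate step
    # in the adjacent transition state. The transition program gets half
    # the (log) fold of the two monotone programs so the severity contrast
    # dominates the leading variance axis.
    sfc <- config@stateFoldChange
    recvIdx <- which(recvCells)
    tR <- tAll[recvIdx]
    stR <- .severityState(tR)
    wUp <- c(nonAD_enriched = 0, transition = 0.5, AD_enriched = 1)[stR]
    wMid <- c(nonAD_enriched = 0, transition = 0.5, AD_enriched = 0)[stR]
    fold[stateGenes$nonAD_enriched, recvIdx] <-
        rep(sfc^(1 - wUp), each = length(stateGenes$nonAD_enriched))
    fold[stateGenes$transition, recvIdx] <-
        rep(sfc^wMid, each = length(stateGenes$transition))
    fold[stateGenes$AD_enriched, recvIdx] <-
        rep(sfc^wUp, each = length(stateGenes$AD_enriched))

    # per-cell library sizes: log-normal around librarySizeMean with a mild
    # donor effect
    sdl <- config@librarySizeSdLog
    libSize <- rlnorm(nCells, meanlog = log(config@librarySizeMean) - sdl^2 / 2,
                      sdlog = sdl)
    donorEffect <- rlnorm(length(unique(donor)), 0, 0.05)
    names(donorEffect) <- unique(donor)
    libSize <- libSize * donorEffect[donor]

    prop <- base * fold
    mu <- sweep(prop, 2, libSize / colSums(prop), `*`)
    countsMat <- matrix(rnbinom(nGenes * nCells, mu = mu,
                                size = 1 / config@dispersion),
                        nGenes, nCells, dimnames = list(geneIds, cellIds))
    storage.mode(countsMat) <- "integer"

    sce <- SingleCellExperiment(
        assays = list(counts = countsMat),
        colData = DataFrame(donor = donor,
                            condition = factor(condition, levels = .CONDITIONS),
                            cluster = cluster, row.names = cellIds),
        rowData = DataFrame(is_mito = isMito, is_secreted = isSecreted,
                            is_receptor = isReceptor, row.names = geneIds))
    metadata(sce)$simulationConfig <- config

    truth <- new("GroundTruth",
                 plantedMarkers = markers,
                 plantedPairs = pairs,
                 plantedStateGenes = stateGenes,
                 sharedTerms = list(),
                 cellStates = data.frame(cell_id = cellIds[recvIdx], t = tR,
                                         state = .severityState(tR),
                                         stringsAsFactors = FALSE),
                 senderCluster = sender, receiverCluster = receiver)
    list(sce = sce, truth = truth)
}

#' Generate a toy ligand-receptor database
#'
#' The secreted and receptor panels of the simulation plus a directed pair
#' list containing every planted pair and a number of decoy pairs whose
#' members are expressed at baseline only.
#'
#' @param config the [SimulationConfig-class] used for [generateCounts()].
#' @param truth the matching [GroundTruth-class].
#' @param nDecoyPairs decoy pairs to add (capped at availability).
#' @return A [LigandReceptorDB-class].
#' @export
generateLRDB <- function(config, truth, nDecoyPairs = 20) {
    stopifnot(is(config, "SimulationConfig"), is(truth, "GroundTruth"))
    set.seed(config@seed + 1L)
    secreted <- if (config@nSecreted) sprintf("SEC%03d", seq_len(config@nSecreted))
                else character()
    receptors <- if (config@nReceptors) sprintf("REC%03d", seq_len(config@nReceptors))
                 else character()
    planted <- truth@plantedPairs
    decoyL <- setdiff(secreted, planted$ligand)
    decoyR <- setdiff(receptors, planted$receptor)
    grid <- expand.grid(ligand = decoyL, receptor = decoyR,
                        stringsAsFactors = FALSE)
    nDecoy <- min(nDecoyPairs, nrow(grid))
    decoys <- grid[sample(nrow(grid), nDecoy), , drop = FALSE]
    pairs <- rbind(planted[, c("ligand", "receptor")], decoys)
    ligandReceptorDB(secreted, receptors, pairs)
}

#' Generate a toy gene-to-GO-term annotation
#'
#' Every gene receives \code{termsPerGene} random terms from a common pool.
#' Genes of the planted AD-enriched trajectory program and the planted
#' ligands additionally receive one of a small set of shared "AD program"
#' terms (round-robin), so that the cross-match between sender ligands and
#' AD-state biology is recoverable; the term each ligand shares is recorded
#' in the returned ground truth.
#'
#' @param truth a [GroundTruth-class] from [generateCounts()].
#' @param geneIds genes to annotate (the simulated gene universe).
#' @param termsPerGene terms per gene (>= 1).
#' @param nTermsPool size of the random term pool.
#' @param nSharedTerms number of shared AD-program terms.
#' @param seed integer seed.
#' @return list with \code{annotation} (two-column data.frame \code{gene},
#'   \code{term}) and \code{truth} (input truth with \code{sharedTerms}
#'   filled in).
#' @export
generateGOAnnotation <- function(truth, geneIds, termsPerGene = 3,
                                 nTermsPool = 50, nSharedTerms = 3,
                                 seed = 1) {
    stopifnot(is(truth, "GroundTruth"))
    if (termsPerGene < 1)
        stop("termsPerGene must be >= 1")
    set.seed(as.integer(seed))
    pool <- sprintf("GO:T%03d", seq_len(nTermsPool))
    sharedPool <- sprintf("GO:AD%02d", seq_len(nSharedTerms))

    terms <- lapply(geneIds, function(g) sample(pool, termsPerGene))
    names(terms) <- geneIds

    adGenes <- intersect(truth@plantedStateGenes$AD_enriched, geneIds)
    ligands <- intersect(unique(truth@plantedPairs$ligand), geneIds)
    shared <- list()
    if (length(adGenes) && length(ligands)) {
        adAssign <- rep_len(sharedPool, length(adGenes))
        for (i in seq_along(adGenes))
            terms[[adGenes[i]]][1L] <- adAssign[i]
        ligAssign <- rep_len(sharedPool, length(ligands))
        for (i in seq_along(ligands)) {
            terms[[ligands[i]]][1L] <- ligAssign[i]
            shared[[ligands[i]]] <- ligAssign[i]
        }
    }
    annotation <- data.frame(
        gene = rep(geneIds, lengths(terms)),
        term = unlist(terms, use.names = FALSE),
        stringsAsFactors = FALSE)
    annotation <- unique(annotation)
    rownames(annotation) <- NULL
    truth@sharedTerms <- shared
    list(annotation = annotation, truth = truth)
}

#' Simulate a complete synthetic dataset
#'
#' Convenience wrapper running [generateCounts()], [generateLRDB()] and
#' [generateGOAnnotation()] from a single config.
#'
#' @inheritParams generateLRDB
#' @inheritParams generateGOAnnotation
#' @return list with \code{sce}, \code{truth}, \code{db}, \code{annotation}.
#' @export
simulateDataset <- function(config, nDecoyPairs = 20, termsPerGene = 3,
                            nTermsPool = 50, nSharedTerms = 3) {
    sim <- generateCounts(config)
    db <- generateLRDB(config, sim$truth, nDecoyPairs = nDecoyPairs)
    ann <- generateGOAnnotation(sim$truth, rownames(sim$sce),
                                termsPerGene = termsPerGene,
                                nTermsPool = nTermsPool,
                                nSharedTerms = nSharedTerms,
                                seed = config@seed + 2L)
    list(sce = sim$sce, truth = ann$truth, db = db,
         annotation = ann$annotation)
}
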
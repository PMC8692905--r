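#' @import methods
#' @importFrom stats cor mad median pnorm prcomp quantile rlnorm rnbinom runif
#'   sd var phyper kmeans
#' @importFrom utils head read.delim write.table combn
NULL

#' Simulation design for synthetic two-condition UMI data
#'
#' Holds the full design of the synthetic dataset: cluster layout, gene
#' panel sizes (mitochondrial, secreted, receptor), planted structure
#' (cluster markers, condition-specific ligand--receptor pairs, trajectory
#' programs) and the negative-binomial noise model.
#'
#' @slot nClusters number of cell clusters.
#' @slot cellsPerClusterPerCondition cells simulated per cluster per
#'   condition; a cluster has twice this many cells in total.
#' @slot nGenes total number of genes.
#' @slot nMitoGenes number of mitochondrial genes (named with the
#'   \code{"MT-"} prefix).
#' @slot nSecreted,nReceptors sizes of the secreted-gene and
#'   membrane-receptor panels.
#' @slot nPlantedPairs number of planted ligand--receptor pairs between the
#'   sender and receiver clusters.
#' @slot nMarkersPerCluster planted marker genes per cluster.
#' @slot nStateGenes genes per planted trajectory program (three programs).
#' @slot markerFoldChange multiplicative up-shift of planted markers,
#'   ligands and receptors in their home population (> 1).
#' @slot stateFoldChange maximal multiplicative up-shift of trajectory
#'   program genes along the planted severity axis.
#' @slot librarySizeMean mean per-cell library size (UMIs).
#' @slot librarySizeSdLog log-scale s.d. of the log-normal library sizes.
#' @slot dispersion negative-binomial overdispersion (variance =
#'   mu + dispersion * mu^2).
#' @slot nDonorsPerCondition donors simulated per condition.
#' @slot senderCluster,receiverCluster 1-based indices of the
#'   ligand-producing (fibroblast-like) and receiving (SMC-like) clusters.
#' @slot seed integer seed; one stream of pseudorandomness is derived from
#'   it.
#' @seealso [simulationConfig()], [generateCounts()]
#' @export
setClass("SimulationConfig", slots = c(
    nClusters = "integer",
    cellsPerClusterPerCondition = "integer",
    nGenes = "integer",
    nMitoGenes = "integer",
    nSecreted = "integer",
    nReceptors = "integer",
    nPlantedPairs = "integer",
    nMarkersPerCluster = "integer",
    nStateGenes = "integer",
    markerFoldChange = "numeric",
    stateFoldChange = "numeric",
    librarySizeMean = "numeric",
    librarySizeSdLog = "numeric",
    dispersion = "numeric",
    nDonorsPerCondition = "integer",
    senderCluster = "integer",
    receiverCluster = "integer",
    seed = "integer"
))

setValidity("SimulationConfig", function(object) {
    msg <- character()
    pos <- c(nClusters = object@nClusters,
             cellsPerClusterPerCondition = object@cellsPerClusterPerCondition,
             nGenes = object@nGenes,
             nDonorsPerCondition = object@nDonorsPerCondition)
    bad <- names(pos)[pos < 1L]
    if (length(bad))
        msg <- c(msg, paste0("non-positive dimension(s): ",
                             paste(bad, collapse = ", ")))
    nonneg <- c(nMitoGenes = object@nMitoGenes, nSecreted = object@nSecreted,
                nReceptors = object@nReceptors,
                nPlantedPairs = object@nPlantedPairs,
                nMarkersPerCluster = object@nMarkersPerCluster,
                nStateGenes = object@nStateGenes)
    bad <- names(nonneg)[nonneg < 0L]
    if (length(bad))
        msg <- c(msg, paste0("negative count(s): ", paste(bad, collapse = ", ")))
    if (object@nPlantedPairs > min(object@nSecreted, object@nReceptors))
        msg <- c(msg, "nPlantedPairs exceeds available ligand/receptor genes")
    nSpecial <- object@nMitoGenes + object@nSecreted + object@nReceptors
    if (nSpecial > object@nGenes)
        msg <- c(msg, "nMitoGenes + nSecreted + nReceptors exceeds nGenes")
    nGeneric <- object@nGenes - nSpecial
    if (object@nClusters * object@nMarkersPerCluster + 3L * object@nStateGenes >
        nGeneric)
        msg <- c(msg, "not enough generic genes for planted markers and state programs")
    if (object@markerFoldChange <= 1)
        msg <- c(msg, "markerFoldChange must be > 1")
    if (object@stateFoldChange <= 1)
        msg <- c(msg, "stateFoldChange must be > 1")
    if (object@librarySizeMean <= 0 || object@dispersion <= 0 ||
        object@librarySizeSdLog < 0)
        msg <- c(msg, "library size and dispersion parameters must be positive")
    if (object@senderCluster < 1L || object@senderCluster > object@nClusters ||
        object@receiverCluster < 1L || object@receiverCluster > object@nClusters)
        msg <- c(msg, "sender/receiver cluster index out of range")
    if (object@nClusters > 1L && object@senderCluster == object@receiverCluster)
        msg <- c(msg, "sender and receiver clusters must differ")
    if (length(msg)) msg else TRUE
})

#' Planted ground truth of a simulated dataset
#'
#' Records everything the simulator planted, so downstream recovery can be
#' scored: marker gene sets per cluster, ligand--receptor pairs, the three
#' trajectory gene programs, the per-cell latent severity/state of the
#' receiver cluster, and (once a GO annotation has been generated) the GO
#' terms each planted ligand shares with the AD-enriched program.
#'
#' @slot plantedMarkers named list, cluster -> character vector of marker
#'   genes (disjoint across clusters).
#' @slot plantedPairs data.frame with columns \code{sender}, \code{ligand},
#'   \code{receiver}, \code{receptor}.
#' @slot plantedStateGenes named list, state -> gene set, states
#'   \code{nonAD_enriched}, \code{transition}, \code{AD_enriched}.
#' @slot sharedTerms named list, ligand -> GO term(s) shared with the
#'   AD-enriched program (empty until [generateGOAnnotation()] runs).
#' @slot cellStates data.frame (\code{cell_id}, \code{t}, \code{state}) for
#'   receiver-cluster cells; \code{t} is the latent severity in [0, 1].
#' @slot senderCluster,receiverCluster cluster labels.
#' @export
setClass("GroundTruth", slots = c(
    plantedMarkers = "list",
    plantedPairs = "data.frame",
    plantedStateGenes = "list",
    sharedTerms = "list",
    cellStates = "data.frame",
    senderCluster = "character",
    receiverCluster = "character"
))

setValidity("GroundTruth", function(object) {
    msg <- character()
    mk <- unlist(object@plantedMarkers, use.names = FALSE)
    if (anyDuplicated(mk))
        msg <- c(msg, "planted marker sets are not disjoint across clusters")
    pp <- object@plantedPairs
    need <- c("sender", "ligand", "receiver", "receptor")
    if (nrow(pp) && !all(need %in% names(pp)))
        msg <- c(msg, "plantedPairs must have sender/ligand/receiver/receptor columns")
    if (length(msg)) msg else TRUE
})

#' Ligand-receptor interaction database
#'
#' A secreted-gene set, a membrane-receptor set, and a directed list of
#' ligand -> receptor pairs, in the style of curated interaction databases
#' such as CellPhoneDB.
#'
#' @slot secretedGenes character vector of secreted (ligand-capable) genes.
#' @slot receptorGenes character vector of membrane receptor genes.
#' @slot pairs data.frame with columns \code{ligand}, \code{receptor}.
#' @seealso [readLigandReceptorDB()], [scoreLRPairs()]
#' @export
setClass("LigandReceptorDB", slots = c(
    secretedGenes = "character",
    receptorGenes = "character",
    pairs = "data.frame"
))

setValidity("LigandReceptorDB", function(object) {
    msg <- character()
    p <- object@pairs
    if (!all(c("ligand", "receptor") %in% names(p)))
        return("pairs must have 'ligand' and 'receptor' columns")
    if (anyDuplicated(object@secretedGenes) || anyDuplicated(object@receptorGenes))
        msg <- c(msg, "duplicate genes in secreted or receptor set")
    if (nrow(p)) {
        if (!all(p$ligand %in% object@secretedGenes))
            msg <- c(msg, "pair ligand not in the secreted gene set")
        if (!all(p$receptor %in% object@receptorGenes))
            msg <- c(msg, "pair receptor not in the receptor gene set")
        if (anyDuplicated(paste(p$ligand, p$receptor)))
            msg <- c(msg, "duplicate ligand-receptor pairs")
    }
    if (length(msg)) msg else TRUE
})

#' Audit record of a filtering step
#'
#' Produced by [filterCells()] and [filterGenes()]; records input/output
#' dimensions, the thresholds applied, the log10-UMI window (cell filter
#' only) and the identifiers that were removed.
#'
#' @slot nCellsIn,nCellsOut,nGenesIn,nGenesOut dimensions before/after.
#' @slot umiBounds length-2 numeric, inclusive bounds on log10 total UMI
#'   (NA for gene filtering).
#' @slot removedCells,removedGenes identifiers removed by this step.
#' @slot thresholds named list of the thresholds used.
#' @export
setClass("FilterReport", slots = c(
    nCellsIn = "integer", nCellsOut = "integer",
    nGenesIn = "integer", nGenesOut = "integer",
    umiBounds = "numeric",
    removedCells = "character", removedGenes = "character",
    thresholds = "list"
))

setValidity("FilterReport", function(object) {
    msg <- character()
    if (object@nCellsOut != object@nCellsIn - length(object@removedCells))
        msg <- c(msg, "cell counts inconsistent with removed cell ids")
    if (object@nGenesOut != object@nGenesIn - length(object@removedGenes))
        msg <- c(msg, "gene counts inconsistent with removed gene ids")
    if (length(object@umiBounds) != 2L)
        msg <- c(msg, "umiBounds must have length 2")
    if (length(msg)) msg else TRUE
})

#' Pseudotime ordering with condition-composition states
#'
#' Per-cell pseudotime in [0, 1] plus a three-level state label obtained by
#' splitting the ordering into three contiguous segments and labelling each
#' by its condition composition: \code{nonAD_enriched}, \code{transition}
#' or \code{AD_enriched}.
#'
#' @slot cellIds cell identifiers.
#' @slot pseudotime numeric in [0, 1], parallel to \code{cellIds}.
#' @slot state factor with levels \code{nonAD_enriched}, \code{transition},
#'   \code{AD_enriched}.
#' @slot cutpoints the two pseudotime cut points separating the segments.
#' @seealso [orderCells()], [assignStates()]
#' @export
setClass("TrajectoryAssignment", slots = c(
    cellIds = "character",
    pseudotime = "numeric",
    state = "factor",
    cutpoints = "numeric"
))

.STATE_LEVELS <- c("nonAD_enriched", "transition", "AD_enriched")

setValidity("TrajectoryAssignment", function(object) {
    msg <- character()
    n <- length(object@cellIds)
    if (length(object@pseudotime) != n || length(object@state) != n)
        msg <- c(msg, "cellIds, pseudotime and state must be parallel")
    if (!identical(levels(object@state), .STATE_LEVELS))
        msg <- c(msg, "state levels must be nonAD_enriched/transition/AD_enriched")
    if (anyNA(object@state))
        msg <- c(msg, "every cell must have exactly one state")
    if (n && (min(object@pseudotime) < 0 || max(object@pseudotime) > 1))
        msg <- c(msg, "pseudotime must lie in [0, 1]")
    if (length(object@cutpoints) != 2L)
        msg <- c(msg, "cutpoints must have length 2")
    # contiguity: state must be constant within the intervals defined by cuts
    if (n >= 3L && !anyNA(object@cutpoints)) {
        seg <- findInterval(object@pseudotime, sort(object@cutpoints)) + 1L
        if (any(tapply(as.integer(object@state), seg,
                       function(s) length(unique(s))) > 1L))
            msg <- c(msg, "states are not contiguous in pseudotime")
    }
    if (length(msg)) msg else TRUE
})

setMethod("show", "SimulationConfig", function(object) {
    cat("SimulationConfig:", object@nClusters, "clusters x 2 conditions x",
        object@cellsPerClusterPerCondition, "cells;",
        object@nGenes, "genes (", object@nMitoGenes, "mito,",
        object@nSecreted, "secreted,", object@nReceptors, "receptors)\n")
    cat("  planted:", object@nMarkersPerCluster, "markers/cluster,",
        object@nPlantedPairs, "ligand-receptor pairs, 3 x",
        object@nStateGenes, "state genes\n")
    cat("  sender C", object@senderCluster, " -> receiver C",
        object@receiverCluster, "; fold change ", object@markerFoldChange,
        "; dispersion ", object@dispersion, "; seed ", object@seed, "\n",
        sep = "")
})

setMethod("show", "GroundTruth", function(object) {
    cat("GroundTruth:", length(object@plantedMarkers), "clusters with planted markers;",
        nrow(object@plantedPairs), "planted pairs (",
        object@senderCluster, "->", object@receiverCluster, ");",
        nrow(object@cellStates), "receiver cells with latent states\n")
})

setMethod("show", "LigandReceptorDB", function(object) {
    cat("LigandReceptorDB:", length(object@secretedGenes), "secreted genes,",
        length(object@receptorGenes), "receptor genes,",
        nrow(object@pairs), "directed pairs\n")
})

setMethod("show", "FilterReport", function(object) {
    cat("FilterReport: cells ", object@nCellsIn, " -> ", object@nCellsOut,
        "; genes ", object@nGenesIn, " -> ", object@nGenesOut, "\n", sep = "")
    if (!anyNA(object@umiBounds))
        cat(sprintf("  log10 UMI window [%.4f, %.4f]\n",
                    object@umiBounds[1], object@umiBounds[2]))
    if (length(object@thresholds))
        cat("  thresholds:", paste(names(object@thresholds),
                                   unlist(object@thresholds),
                                   sep = "=", collapse = ", "), "\n")
})

setMethod("show", "TrajectoryAssignment", function(object) {
    tab <- table(object@state)
    cat("TrajectoryAssignment:", length(object@cellIds), "cells;",
        paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
    cat(sprintf("  cut points at pseudotime %.3f and %.3f\n",
                object@cutpoints[1], object@cutpoints[2]))
})
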
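# End-to-end orchestration: synthetic or on-disk inputs -> QC -> markers ->
# trajectory -> interactome, with per-stage logging, on-disk stage outputs
# and a machine-readable JSON run report.

.DEFAULT_THRESHOLDS <- list(
    sd_window = 2, min_genes = 1000, min_cells = 10,
    q_max = 0.05, min_log_fc = 0,
    mean_low = 0.01, mean_high = 3, min_dispersion = 1,
    enrich_threshold = 0.6, p_max = 0.05, state_top_n = 1000,
    min_group_cells = 10)

#' Assemble a pipeline run configuration
#'
#' Exactly one of \code{simulation} (synthetic mode) or \code{countsDir} /
#' \code{countsTsv} (real-data mode) must be given. Every stage threshold
#' is surfaced as a named entry of \code{thresholds}; omitted entries take
#' the package defaults (2 s.d. UMI window, 1000 detected genes, 10 cells
#' per gene, q 0.05, variable-gene bounds 0.01/3/1, enrichment threshold
#' 0.6, p 0.05).
#'
#' @param simulation a [SimulationConfig-class] for synthetic mode.
#' @param countsDir MTX directory (see [readCountsMTX()]).
#' @param countsTsv,cellMetaTsv dense TSV matrix and cell metadata.
#' @param lrdbDir ligand-receptor database directory
#'   (see [readLigandReceptorDB()]); required in real-data mode.
#' @param annotationFile two-column gene-to-term TSV; required in
#'   real-data mode.
#' @param trajectoryTsv optional externally computed trajectory TSV
#'   (bypasses the stand-in ordering).
#' @param receiverCluster cluster label of the receiving (SMC-like)
#'   population; defaults to the simulation's receiver in synthetic mode.
#' @param thresholds named list overriding the default thresholds.
#' @param seed integer seed for the run.
#' @return a validated run-configuration list.
#' @export
runConfig <- function(simulation = NULL, countsDir = NULL, countsTsv = NULL,
                      cellMetaTsv = NULL, lrdbDir = NULL,
                      annotationFile = NULL, trajectoryTsv = NULL,
                      receiverCluster = NULL, thresholds = list(),
                      seed = 1) {
    synthetic <- !is.null(simulation)
    real <- !is.null(countsDir) || !is.null(countsTsv)
    if (synthetic == real)
        stop("exactly one of a simulation config or real-data paths must be set")
    if (synthetic && !is(simulation, "SimulationConfig"))
        stop("'simulation' must be a SimulationConfig")
    if (real && (is.null(lrdbDir) || is.null(annotationFile)))
        stop("real-data mode needs lrdbDir and annotationFile")
    unknown <- setdiff(names(thresholds), names(.DEFAULT_THRESHOLDS))
    if (length(unknown))
        stop("unknown threshold(s): ", paste(unknown, collapse = ", "))
    th <- utils::modifyList(.DEFAULT_THRESHOLDS, thresholds)
    list(simulation = simulation, countsDir = countsDir,
         countsTsv = countsTsv, cellMetaTsv = cellMetaTsv,
         lrdbDir = lrdbDir, annotationFile = annotationFile,
         trajectoryTsv = trajectoryTsv, receiverCluster = receiverCluster,
         thresholds = th, seed = as.integer(seed))
}

#' Read a pipeline configuration from YAML
#'
#' Recognized top-level keys: \code{simulation} (a mapping of
#' [simulationConfig()] arguments), \code{counts_dir}, \code{counts_tsv},
#' \code{cell_meta_tsv}, \code{lrdb_dir}, \code{annotation_file},
#' \code{trajectory_tsv}, \code{receiver_cluster}, \code{thresholds},
#' \code{seed}.
#'
#' @param file YAML path.
#' @return a run-configuration list (see [runConfig()]).
#' @export
readRunConfig <- function(file) {
    y <- yaml::read_yaml(file)
    sim <- if (!is.null(y$simulation)) do.call(simulationConfig, y$simulation)
    runConfig(simulation = sim, countsDir = y$counts_dir,
              countsTsv = y$counts_tsv, cellMetaTsv = y$cell_meta_tsv,
              lrdbDir = y$lrdb_dir, annotationFile = y$annotation_file,
              trajectoryTsv = y$trajectory_tsv,
              receiverCluster = y$receiver_cluster,
              thresholds = if (is.null(y$thresholds)) list() else y$thresholds,
              seed = if (is.null(y$seed)) 1L else y$seed)
}

.stage <- function(name, expr) {
    t0 <- Sys.time()
    message("[", name, "] starting")
    out <- tryCatch(expr, error = function(e) {
        stop("stage '", name, "' failed: ", conditionMessage(e),
             call. = FALSE)
    })
    message(sprintf("[%s] done in %.1fs", name,
                    as.numeric(Sys.time() - t0, units = "secs")))
    out
}

.reportFilter <- function(rep) {
    list(n_cells_in = rep@nCellsIn, n_cells_out = rep@nCellsOut,
         n_genes_in = rep@nGenesIn, n_genes_out = rep@nGenesOut,
         umi_bounds = if (anyNA(rep@umiBounds)) NULL else rep@umiBounds,
         thresholds = rep@thresholds)
}

#' Run the full crosstalk pipeline
#'
#' Executes simulation (synthetic mode) or loading, QC and normalization,
#' marker/DEG detection, the receiver-population trajectory with state
#' assignment and GO enrichment, and the interactome stage (ligand
#' extraction, secreting capacity, cross-match, ligand-receptor scoring).
#' Stage outputs are written under \code{outDir} as they are produced, so
#' partial results survive a failing stage; any stage error aborts with
#' the stage name and cause.
#'
#' @param config a run configuration from [runConfig()] or
#'   [readRunConfig()].
#' @param outDir output directory.
#' @return the run report (also written to \code{outDir/report.json}),
#'   invisibly.
#' @export
runPipeline <- function(config, outDir) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    th <- config$thresholds
    set.seed(config$seed)

    truth <- NULL
    inp <- .stage("input", {
        if (!is.null(config$simulation)) {
            ds <- simulateDataset(config$simulation)
            writeCountsMTX(ds$sce, file.path(outDir, "counts"))
            writeLigandReceptorDB(ds$db, file.path(outDir, "lrdb"))
            writeGeneAnnotation(ds$annotation,
                                file.path(outDir, "annotation.tsv"))
            writeGroundTruth(ds$truth, file.path(outDir, "ground_truth.json"))
            ds
        } else {
            sce <- if (!is.null(config$countsDir)) readCountsMTX(config$countsDir)
                   else readCountsTSV(config$countsTsv, config$cellMetaTsv)
            if (!"cluster" %in% names(colData(sce)))
                stop("cell metadata must provide a 'cluster' column")
            list(sce = sce, truth = NULL,
                 db = readLigandReceptorDB(config$lrdbDir),
                 annotation = readGeneAnnotation(config$annotationFile))
        }
    })
    sce <- inp$sce
    db <- inp$db
    annotation <- inp$annotation
    truth <- inp$truth
    receiver <- config$receiverCluster
    if (is.null(receiver) && !is.null(truth)) receiver <- truth@receiverCluster
    if (is.null(receiver))
        stop("stage 'input' failed: no receiver cluster specified")

    sce <- .stage("qc", {
        x <- filterCells(sce, sdWindow = th$sd_window,
                         minGenes = th$min_genes)
        x <- filterGenes(x, minCells = th$min_cells, dropMito = TRUE)
        x <- logNormalize(x)
        reps <- filterReports(x)
        jsonlite::write_json(lapply(reps, .reportFilter),
                             file.path(outDir, "filter_report.json"),
                             auto_unbox = TRUE, digits = NA, pretty = TRUE)
        x
    })

    mk <- .stage("markers", {
        clusters <- as.character(colData(sce)$cluster)
        condGroups <- suppressWarnings(
            conditionGroups(sce, minCells = th$min_group_cells))
        clusterMarkers <- findAllMarkers(sce, clusters, qMax = th$q_max,
                                         minLogFC = th$min_log_fc)
        groupMarkers <- findAllMarkers(sce, condGroups, qMax = th$q_max,
                                       minLogFC = th$min_log_fc)
        degs <- list()
        for (cl in sort(unique(clusters))) {
            a <- colnames(sce)[clusters == cl &
                               colData(sce)$condition == "AD"]
            b <- colnames(sce)[clusters == cl &
                               colData(sce)$condition == "nonAD"]
            if (length(a) >= 3L && length(b) >= 3L)
                degs[[cl]] <- findMarkersBetween(sce, a, b, qMax = th$q_max,
                                                 label = cl)
        }
        writeMarkerTable(clusterMarkers,
                         file.path(outDir, "cluster_markers.tsv"))
        writeMarkerTable(groupMarkers, file.path(outDir, "group_markers.tsv"))
        list(clusterMarkers = clusterMarkers, groupMarkers = groupMarkers,
             condGroups = condGroups, degCounts = countDEGs(degs))
    })

    tr <- .stage("trajectory", {
        recvCells <- colnames(sce)[colData(sce)$cluster == receiver]
        if (!is.null(config$trajectoryTsv)) {
            traj <- readTrajectory(config$trajectoryTsv)
        } else {
            pt <- orderCells(sce, cells = recvCells)
            cond <- as.character(colData(sce)$condition)[
                match(recvCells, colnames(sce))]
            traj <- assignStates(pt, cond,
                                 enrichThreshold = th$enrich_threshold)
        }
        writeTrajectory(traj, file.path(outDir, "trajectory.tsv"))
        blocks <- stateDEGs(sce, traj, topN = th$state_top_n)
        universe <- rownames(sce)
        stateTerms <- lapply(blocks$blocks, function(g) {
            if (!length(g)) return(character())
            goEnrichment(g, annotation, universe, pMax = th$p_max)$term
        })
        list(traj = traj, blocks = blocks, stateTerms = stateTerms,
             universe = universe)
    })

    ia <- .stage("interactome", {
        ligandSets <- extractClusterLigands(mk$groupMarkers, db)
        receptorSetsAll <- extractClusterReceptors(mk$groupMarkers, db)
        recvGroups <- intersect(names(receptorSetsAll),
                                paste0(c("n-", "d-"), receiver))
        receptorSets <- receptorSetsAll[recvGroups]
        capacity <- secretingCapacity(sce, mk$condGroups, ligandSets)
        cross <- crossmatchLigands(ligandSets, annotation, tr$stateTerms)
        scores <- scoreLRPairs(sce, mk$condGroups, db, ligandSets,
                               receptorSets)
        pairCounts <- countPairsPerGroup(scores)
        write.table(capacity, file.path(outDir, "secreting_capacity.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        write.table(scores, file.path(outDir, "interaction_scores.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        write.table(cross$matches, file.path(outDir, "crossmatch.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        list(ligandSets = ligandSets, receptorSets = receptorSets,
             capacity = capacity, cross = cross, scores = scores,
             pairCounts = pairCounts)
    })

    qcReps <- filterReports(sce)
    report <- list(
        mode = if (is.null(config$simulation)) "real" else "synthetic",
        seed = config$seed,
        thresholds = th,
        receiver_cluster = receiver,
        input = list(n_genes = qcReps$cells@nGenesIn,
                     n_cells = qcReps$cells@nCellsIn),
        qc = lapply(qcReps, .reportFilter),
        markers = list(
            n_cluster_marker_rows = nrow(mk$clusterMarkers),
            n_group_marker_rows = nrow(mk$groupMarkers),
            deg_counts = mk$degCounts),
        trajectory = list(
            n_cells = length(tr$traj@cellIds),
            cutpoints = cutpoints(tr$traj),
            state_sizes = as.list(table(stateLabels(tr$traj))),
            n_enriched_terms = lapply(tr$stateTerms, length)),
        interactome = list(
            secreting_capacity = ia$capacity,
            crossmatch_pair_counts = as.data.frame.table(
                ia$cross$pairCounts, responseName = "n",
                stringsAsFactors = FALSE),
            top_pairs = head(ia$scores, 10L),
            pair_counts = ia$pairCounts))
    jsonlite::write_json(report, file.path(outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(report)
}
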
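test_that("the simulator is deterministic and has the designed dimensions", {
    cfg <- simulationConfig(nClusters = 3, cellsPerClusterPerCondition = 50,
                            nGenes = 200, nMitoGenes = 6, nSecreted = 12,
                            nReceptors = 10, nPlantedPairs = 3,
                            nMarkersPerCluster = 5, nStateGenes = 8,
                            senderCluster = 2, receiverCluster = 3, seed = 42)
    a <- generateCounts(cfg)
    b <- generateCounts(cfg)
    expect_identical(counts(a$sce), counts(b$sce))
    expect_identical(plantedMarkers(a$truth), plantedMarkers(b$truth))
    # 3 clusters x 2 conditions x 50 cells
    expect_identical(dim(a$sce), c(200L, 300L))
    expect_true(all(counts(a$sce) >= 0))
    expect_identical(sum(rowData(a$sce)$is_mito), 6L)
    expect_true(all(startsWith(rownames(a$sce)[rowData(a$sce)$is_mito], "MT-")))
    expect_setequal(unique(colData(a$sce)$condition), c("nonAD", "AD"))
})

test_that("invalid simulation designs are rejected", {
    expect_error(simulationConfig(nClusters = 0), "non-positive")
    expect_error(simulationConfig(nSecreted = 2, nReceptors = 2,
                                  nPlantedPairs = 3),
                 "exceeds available")
    expect_error(simulationConfig(nGenes = 50, nMitoGenes = 30,
                                  nSecreted = 15, nReceptors = 15),
                 "exceeds nGenes")
    expect_error(simulationConfig(markerFoldChange = 1), "markerFoldChange")
})

test_that("planted markers are elevated in their home cluster", {
    cfg <- simulationConfig(nClusters = 3, cellsPerClusterPerCondition = 50,
                            nGenes = 300, nMitoGenes = 10, nSecreted = 12,
                            nReceptors = 10, nPlantedPairs = 3,
                            nMarkersPerCluster = 6, nStateGenes = 8,
                            markerFoldChange = 4, dispersion = 0.5,
                            senderCluster = 2, receiverCluster = 3,
                            seed = 3)
    sim <- generateCounts(cfg)
    m <- counts(sim$sce)
    cl <- colData(sim$sce)$cluster
    for (cluster in names(plantedMarkers(sim$truth))) {
        for (g in plantedMarkers(sim$truth)[[cluster]]) {
            expect_gt(mean(m[g, cl == cluster]), mean(m[g, cl != cluster]))
        }
    }
})

test_that("library sizes stay near the configured mean", {
    cfg <- tinyConfig(seed = 5)
    sim <- generateCounts(cfg)
    tot <- colSums(counts(sim$sce))
    # 5 s.d. band of the log-normal library-size distribution
    sdl <- cfg@librarySizeSdLog
    sdLib <- cfg@librarySizeMean * sqrt(exp(sdl^2) - 1)
    expect_true(all(tot > cfg@librarySizeMean - 5 * sdLib))
    expect_true(all(tot < cfg@librarySizeMean + 5 * sdLib))
})

test_that("ground truth invariants hold and pairs target sender -> receiver", {
    sim <- generateCounts(tinyConfig(seed = 2))
    truth <- sim$truth
    mk <- unlist(plantedMarkers(truth), use.names = FALSE)
    expect_false(anyDuplicated(mk) > 0)
    pp <- plantedPairs(truth)
    expect_true(all(startsWith(pp$ligand, "SEC")))
    expect_true(all(startsWith(pp$receptor, "REC")))
    expect_true(all(pp$sender == truth@senderCluster))
    expect_true(all(pp$receiver == truth@receiverCluster))
    st <- cellStates(truth)
    expect_setequal(unique(st$state),
                    c("nonAD_enriched", "transition", "AD_enriched"))
    expect_true(all(st$t >= 0 & st$t <= 1))
})

test_that("the ligand-receptor database contains planted pairs plus decoys", {
    cfg <- tinyConfig(seed = 9)
    sim <- generateCounts(cfg)
    db <- generateLRDB(cfg, sim$truth, nDecoyPairs = 8)
    expect_length(secretedGenes(db), cfg@nSecreted)
    expect_length(receptorGenes(db), cfg@nReceptors)
    pp <- plantedPairs(sim$truth)
    key <- function(p) paste(p$ligand, p$receptor)
    expect_true(all(key(pp) %in% key(lrPairs(db))))
    expect_identical(nrow(lrPairs(db)) - nrow(pp), 8L)
    # decoy members never coincide with planted ligands/receptors
    decoys <- lrPairs(db)[!key(lrPairs(db)) %in% key(pp), ]
    expect_false(any(decoys$ligand %in% pp$ligand))
    expect_false(any(decoys$receptor %in% pp$receptor))
    # no planted pairs -> decoys only
    cfg0 <- tinyConfig(seed = 9, nPlantedPairs = 0)
    sim0 <- generateCounts(cfg0)
    db0 <- generateLRDB(cfg0, sim0$truth, nDecoyPairs = 8)
    expect_identical(nrow(lrPairs(db0)), 8L)
})

test_that("the GO annotation links planted ligands to the AD program", {
    cfg <- tinyConfig(seed = 4)
    sim <- generateCounts(cfg)
    ann1 <- generateGOAnnotation(sim$truth, rownames(sim$sce), seed = 11)
    ann2 <- generateGOAnnotation(sim$truth, rownames(sim$sce), seed = 11)
    expect_identical(ann1$annotation, ann2$annotation)
    truth <- ann1$truth
    adTerms <- unique(ann1$annotation$term[
        ann1$annotation$gene %in% plantedStateGenes(truth)$AD_enriched])
    for (lig in plantedPairs(truth)$ligand) {
        st <- sharedTerms(truth)[[lig]]
        expect_gt(length(st), 0)
        ligTerms <- ann1$annotation$term[ann1$annotation$gene == lig]
        expect_true(all(st %in% ligTerms))
        expect_true(all(st %in% adTerms))
    }
    expect_error(generateGOAnnotation(sim$truth, rownames(sim$sce),
                                      termsPerGene = 0), "termsPerGene")
})
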
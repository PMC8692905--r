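test_that("pseudotime lies in [0, 1] and is oriented non-AD to AD", {
    ref <- referenceAnalysis()
    pt <- ref$pt
    expect_true(all(pt >= 0 & pt <= 1))
    expect_lte(mean(pt[ref$cond == "nonAD"]), mean(pt[ref$cond == "AD"]))
    # deterministic given the same input
    pt2 <- orderCells(ref$sce, cells = ref$recv)
    expect_identical(pt, pt2)
})

test_that("cell ordering validates its inputs", {
    sim <- generateCounts(tinyConfig(seed = 16))
    sce <- logNormalize(filterGenes(filterCells(sim$sce, minGenes = 10)))
    expect_error(orderCells(sce, cells = colnames(sce)[1:5]), ">= 10 cells")
    expect_error(orderCells(sce, varGenes = rownames(sce)[1]),
                 "fewer than 2 variable genes")
})

test_that("state segments follow the condition-composition rule", {
    # pure / balanced / pure blocks along a synthetic pseudotime
    pt <- seq(0, 1, length.out = 90)
    names(pt) <- paste0("c", 1:90)
    # middle block alternates starting with AD and ending with nonAD, so
    # the entropy optimum sits exactly at the block boundaries
    cond <- c(rep("nonAD", 30), rep(c("AD", "nonAD"), 15), rep("AD", 30))
    traj <- assignStates(pt, cond)
    st <- as.character(stateLabels(traj))
    expect_identical(unique(st[1:30]), "nonAD_enriched")
    expect_identical(unique(st[31:60]), "transition")  # 50/50 < 0.6
    expect_identical(unique(st[61:90]), "AD_enriched")
    expect_equal(sort(cutpoints(traj)),
                 unname(c(pt[30] + diff(pt[30:31]) / 2,
                          pt[60] + diff(pt[60:61]) / 2)),
                 tolerance = 1e-12)
    # invariance under a monotone transform of pseudotime
    traj2 <- assignStates(pt^3, cond)
    expect_identical(stateLabels(traj2), stateLabels(traj))
})

test_that("state assignment validates conditions and cell counts", {
    pt <- c(a = 0.1, b = 0.5)
    expect_error(assignStates(pt, c("nonAD", "AD")), ">= 3 cells")
    pt3 <- c(a = 0.1, b = 0.5, c = 0.9)
    expect_error(assignStates(pt3, rep("AD", 3)), "both conditions")
    expect_error(assignStates(pt3, c("nonAD", "AD", "weird")), "unknown")
})

test_that("planted trajectory states are recovered on simulated data", {
    ref <- referenceAnalysis()
    cs <- cellStates(ref$truth)
    cs <- cs[match(ref$recv, cs$cell_id), ]
    agree <- mean(as.character(stateLabels(ref$traj)) == cs$state)
    expect_gte(agree, 0.9)
})

test_that("state DEG blocks exclude constants and keep the bookkeeping", {
    ref <- referenceAnalysis()
    sub <- logcounts(ref$sce)[, ref$recv]
    constGenes <- rownames(sub)[apply(sub, 1, function(x) all(x == x[1]))]
    blocks <- ref$blocks
    expect_false(any(constGenes %in% blocks$table$gene))
    nTestable <- sum(apply(sub, 1, function(x) any(x != x[1])))
    expect_identical(nrow(blocks$table), min(200L, nTestable))
    expect_identical(sort(unlist(blocks$blocks, use.names = FALSE)),
                     sort(blocks$table$gene))
    # planted AD-program genes land in the AD-enriched block
    adGenes <- intersect(plantedStateGenes(ref$truth)$AD_enriched,
                         rownames(ref$sce))
    expect_gte(mean(adGenes %in% blocks$blocks$AD_enriched), 0.9)
})

test_that("state DEGs require all three states to be populated", {
    pt <- seq(0, 1, length.out = 30)
    ids <- paste0("c", 1:30)
    traj <- new("TrajectoryAssignment", cellIds = ids, pseudotime = pt,
                state = factor(c(rep("nonAD_enriched", 2),
                                 rep("transition", 14),
                                 rep("AD_enriched", 14)),
                               levels = c("nonAD_enriched", "transition",
                                          "AD_enriched")),
                cutpoints = c(mean(pt[2:3]), mean(pt[16:17])))
    m <- matrix(rnorm(10 * 30), 10, 30,
                dimnames = list(paste0("g", 1:10), ids))
    expect_error(stateDEGs(m, traj), "< 3 cells")
})

test_that("hypergeometric enrichment reproduces exact arithmetic", {
    # N=10, K=5, n=4, k=4: C(5,4) C(5,0) / C(10,4) = 5/210
    universe <- paste0("g", 1:10)
    ann <- data.frame(gene = universe,
                      term = rep(c("T1", "T2"), each = 5))
    res <- goEnrichment(paste0("g", 1:4), ann, universe, all = TRUE)
    expect_equal(res$p[res$term == "T1"], 5 / 210, tolerance = 1e-12)
    expect_identical(res$k[res$term == "T1"], 4L)
    # a term annotating every universe gene is certain: p = 1
    annAll <- data.frame(gene = universe, term = "ALL")
    resAll <- goEnrichment(paste0("g", 1:4), annAll, universe, all = TRUE)
    expect_equal(resAll$p, 1)
    # a term with no query member reports p = 1 when all rows are requested
    res0 <- goEnrichment("g1", ann, universe, all = TRUE)
    expect_equal(res0$p[res0$term == "T2"], 1)
    expect_error(goEnrichment("absent", ann, universe), "subset")
    expect_true(all(res$q >= res$p))
})

test_that("enriched AD-state terms include the planted shared terms", {
    ref <- referenceAnalysis()
    shared <- unique(unlist(sharedTerms(ref$truth)))
    expect_gt(length(shared), 0)
    expect_true(all(shared %in% ref$stateTerms$AD_enriched))
})
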
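test_that("condition-split groups drop small populations with a warning", {
    sim <- generateCounts(tinyConfig(seed = 18))
    g <- suppressWarnings(conditionGroups(sim$sce, minCells = 10))
    expect_setequal(unique(g), c(paste0("n-", c("C1", "C2", "C3")),
                                 paste0("d-", c("C1", "C2", "C3"))))
    expect_warning(conditionGroups(sim$sce, minCells = 25), "dropping")
})

test_that("ligand extraction intersects positive markers with the database", {
    db <- ligandReceptorDB(c("SEC1", "SEC2"), c("REC1"),
                           data.frame(ligand = "SEC1", receptor = "REC1"))
    mk <- data.frame(gene = c("SEC1", "G1", "REC1", "SEC2"),
                     group = c("A", "A", "A", "B"),
                     log_fc = c(1, 1, 1, -0.5), p = 0.01, q = 0.01,
                     mean_in = 1, mean_out = 0)
    ligs <- extractClusterLigands(mk, db)
    expect_identical(ligs$A, "SEC1")
    expect_identical(ligs$B, character())  # SEC2 is not a positive marker
    recs <- extractClusterReceptors(mk, db)
    expect_identical(recs$A, "REC1")
    expect_true(all(unlist(ligs) %in% secretedGenes(db)))
    emptyDb <- new("LigandReceptorDB", secretedGenes = character(),
                   receptorGenes = character(),
                   pairs = data.frame(ligand = character(),
                                      receptor = character()))
    expect_error(extractClusterLigands(mk, emptyDb), "empty")
})

test_that("secreting capacity z-scores group means across groups", {
    # one gene with group means 1, 2, 3 -> z = (-1, 0, 1)
    v <- matrix(c(1, 1, 2, 2, 3, 3), nrow = 1,
                dimnames = list("SEC1", paste0("c", 1:6)))
    groups <- rep(c("g1", "g2", "g3"), each = 2)
    cap <- secretingCapacity(v, groups, list(g3 = "SEC1"))
    expect_equal(cap$capacity[cap$group == "g3"], 1)
    expect_equal(cap$capacity[cap$group != "g3"], c(0, 0))
    expect_identical(cap$rank[cap$group == "g3"], 1L)
    z <- attr(cap, "zscores")
    expect_equal(unname(z["SEC1", ]), c(-1, 0, 1))
    # z-scores sum to zero and have unit sample s.d. per gene
    expect_equal(sum(z["SEC1", ]), 0)
    expect_equal(sd(z["SEC1", ]), 1)
    # degenerate across-group s.d. contributes zero everywhere
    v2 <- matrix(2, nrow = 1, ncol = 6,
                 dimnames = list("SEC1", paste0("c", 1:6)))
    cap2 <- secretingCapacity(v2, groups, list(g3 = "SEC1"))
    expect_equal(cap2$capacity, rep(0, 3))
})

test_that("the cross-match keeps ligands by term intersection", {
    ann <- data.frame(gene = c("L", "L", "D"), term = c("T1", "T2", "T9"))
    ligandSets <- list(grpA = "L", grpB = "D")
    stateTerms <- list(AD_enriched = c("T2", "T3"),
                       transition = character())
    res <- crossmatchLigands(ligandSets, ann, stateTerms)
    expect_identical(res$matches$ligand, "L")
    expect_identical(res$matches$term, "T2")
    expect_identical(res$pairCounts["grpA", "AD_enriched"], 1L)
    expect_identical(res$pairCounts["grpB", "AD_enriched"], 0L)
    # empty enriched-term set keeps nothing
    expect_identical(sum(res$pairCounts[, "transition"]), 0L)
    # unannotated ligand is treated as zero terms, with a message
    expect_message(
        crossmatchLigands(list(g = "UNSEEN"), ann, stateTerms),
        "without annotation")
    # monotone: enlarging a state's term set never removes a kept ligand
    bigger <- crossmatchLigands(ligandSets, ann,
                                list(AD_enriched = c("T2", "T3", "T9"),
                                     transition = character()))
    expect_true(all(res$matches$ligand %in% bigger$matches$ligand))
    expect_identical(bigger$ligandCounts["grpB", "AD_enriched"], 1L)
})

test_that("interaction scores are the product of group means", {
    v <- rbind(SEC1 = c(2, 2, 0, 0), REC1 = c(0, 0, 3, 3))
    colnames(v) <- paste0("c", 1:4)
    groups <- rep(c("s", "r"), each = 2)
    db <- ligandReceptorDB("SEC1", "REC1",
                           data.frame(ligand = "SEC1", receptor = "REC1"))
    tab <- scoreLRPairs(v, groups, db, list(s = "SEC1"), list(r = "REC1"))
    expect_equal(tab$score, 2 * 3)
    # ligand silent in the sender: score 0
    v0 <- v; v0["SEC1", 1:2] <- 0
    tab0 <- scoreLRPairs(v0, groups, db, list(s = "SEC1"), list(r = "REC1"))
    expect_equal(tab0$score, 0)
    # database gene missing from the matrix: pair skipped with a message
    db2 <- ligandReceptorDB(c("SEC1", "GHOST"), "REC1",
                            data.frame(ligand = c("SEC1", "GHOST"),
                                       receptor = c("REC1", "REC1")))
    expect_message(
        tab2 <- scoreLRPairs(v, groups, db2, list(s = c("SEC1", "GHOST")),
                             list(r = "REC1")),
        "absent")
    expect_identical(nrow(tab2), 1L)
    # identical sender/receiver groups are excluded by default
    tabSelf <- scoreLRPairs(v, groups, db, list(s = "SEC1"),
                            list(s = "REC1"))
    expect_identical(nrow(tabSelf), 0L)
})

test_that("scores are bilinear in the sender's ligand expression", {
    ref <- referenceAnalysis()
    sender <- paste0("d-", ref$truth@senderCluster)
    v <- logcounts(ref$sce)
    lig <- ref$ligandSets[[sender]]
    v2 <- v
    v2[lig, ref$groups == sender & !is.na(ref$groups)] <-
        2 * v2[lig, ref$groups == sender & !is.na(ref$groups)]
    s1 <- ref$scores
    s2 <- scoreLRPairs(v2, ref$groups, ref$ds$db, ref$ligandSets,
                       ref$receptorSets[intersect(
                           names(ref$receptorSets),
                           paste0(c("n-", "d-"), ref$truth@receiverCluster))])
    a <- s1[s1$sender == sender, ]
    b <- s2[s2$sender == sender, ]
    key <- function(d) paste(d$receiver, d$ligand, d$receptor)
    expect_equal(b$score[match(key(a), key(b))], 2 * a$score)
    # other senders are untouched
    oa <- s1[s1$sender != sender, ]
    ob <- s2[s2$sender != sender, ]
    expect_equal(ob$score[match(key(oa), key(ob))], oa$score)
})

test_that("pair counting respects the score threshold", {
    tab <- data.frame(sender = c("a", "a", "a", "b"),
                      receiver = c("r", "r", "r", "r"),
                      ligand = paste0("L", 1:4), receptor = paste0("R", 1:4),
                      score = c(5, 3, 0, 2))
    got <- countPairsPerGroup(tab)
    expect_identical(got$n_pairs[got$sender == "a"], 2L)  # score 0 excluded
    expect_identical(got$n_pairs[got$sender == "b"], 1L)
    got2 <- countPairsPerGroup(tab, minScore = 2.5)
    expect_identical(got2$n_pairs[got2$sender == "a"], 2L)
    expect_identical(got2$n_pairs[got2$sender == "b"], 0L)
    empty <- countPairsPerGroup(tab[0, ])
    expect_identical(nrow(empty), 0L)
})

test_that("condition-specific ligands surface only in the diseased group", {
    ref <- referenceAnalysis()
    truth <- ref$truth
    dSender <- paste0("d-", truth@senderCluster)
    nSender <- paste0("n-", truth@senderCluster)
    lig <- intersect(plantedPairs(truth)$ligand, rownames(ref$sce))
    expect_true(all(lig %in% ref$ligandSets[[dSender]]))
    expect_false(any(lig %in% ref$ligandSets[[nSender]]))
})
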
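test_that("the log10-UMI window removes depth outliers", {
    totals <- c(10000, 9500, 10500, 100, 9800, 10200)
    sce <- makeSCE(matrix(totals, nrow = 1))
    out <- filterCells(sce, sdWindow = 2, minGenes = 0)
    expect_identical(ncol(out), 5L)
    rep <- filterReports(out)$cells
    expect_identical(rep@removedCells, colnames(sce)[4])
    # brute-force recomputation of the window
    l10 <- log10(totals)
    expect_equal(rep@umiBounds,
                 c(mean(l10) - 2 * sd(l10), mean(l10) + 2 * sd(l10)))
    expect_equal(rep@umiBounds, c(2.0330, 5.2995), tolerance = 1e-4)
    expect_identical(rep@nCellsIn - length(rep@removedCells), rep@nCellsOut)
})

test_that("the detected-gene threshold is inclusive", {
    # one cell detecting exactly 3 genes, one detecting 2
    m <- cbind(c(5L, 5L, 5L, 0L), c(5L, 5L, 0L, 0L))
    sce <- makeSCE(m)
    out <- filterCells(sce, sdWindow = 100, minGenes = 3)
    expect_identical(colnames(out), "c001")
})

test_that("identical cells survive the degenerate zero-s.d. window", {
    sce <- makeSCE(matrix(7L, nrow = 4, ncol = 5))
    out <- filterCells(sce, sdWindow = 2, minGenes = 0)
    expect_identical(ncol(out), 5L)
})

test_that("cell filtering rejects empty input and zero-total cells", {
    expect_error(filterCells(makeSCE(matrix(integer(), 0, 0))), "empty")
    sce <- makeSCE(cbind(c(1L, 2L), c(0L, 0L)))
    expect_error(filterCells(sce), "zero total UMI")
})

test_that("re-applying the recorded window to the output is a no-op", {
    sim <- generateCounts(tinyConfig(seed = 6))
    once <- filterCells(sim$sce, minGenes = 10)
    rep <- filterReports(once)$cells
    l10 <- log10(colSums(counts(once)))
    expect_true(all(l10 >= rep@umiBounds[1] & l10 <= rep@umiBounds[2]))
    expect_true(all(colSums(counts(once) > 0) >= 10))
})

test_that("gene filtering applies the prevalence and mito rules", {
    # g1 in 10 cells, g2 in 9, mito gene in all
    n <- 12
    m <- rbind(g1 = c(rep(1L, 10), 0L, 0L),
               g2 = c(rep(1L, 9), 0L, 0L, 0L),
               `MT-1` = rep(5L, n),
               g3 = rep(1L, n))
    sce <- makeSCE(m)
    out <- filterGenes(sce, minCells = 10, dropMito = TRUE)
    expect_setequal(rownames(out), c("g1", "g3"))
    # mito retained when dropMito = FALSE
    out2 <- filterGenes(sce, minCells = 10, dropMito = FALSE)
    expect_true("MT-1" %in% rownames(out2))
    # no-op configuration is the identity
    out3 <- filterGenes(sce, minCells = 0, dropMito = FALSE)
    expect_identical(rownames(out3), rownames(sce))
    expect_identical(counts(out3), counts(sce))
})

test_that("normalization follows the ln(x/total * 1e4 + 1) formula", {
    m <- cbind(c(4L, 1996L), c(100L, 900L))
    sce <- logNormalize(makeSCE(m))
    v <- logcounts(sce)
    expect_equal(v[1, 1], log(4 / 2000 * 10000 + 1))  # ln(21)
    expect_equal(v[1, 1], 3.0445, tolerance = 1e-4)
    # zero counts map to zero exactly
    m2 <- cbind(c(0L, 10L), c(5L, 5L))
    v2 <- logcounts(logNormalize(makeSCE(m2)))
    expect_identical(v2[1, 1], 0)
    expect_error(logNormalize(makeSCE(cbind(c(1L, 1L), c(0L, 0L)))),
                 "zero total UMI")
})

test_that("every normalized cell conserves the size factor", {
    sim <- generateCounts(tinyConfig(seed = 8))
    sce <- logNormalize(filterGenes(filterCells(sim$sce, minGenes = 10)))
    back <- colSums(expm1(logcounts(sce)))
    expect_lt(max(abs(back - 10000)) / 10000, 1e-6)
})

test_that("variable-gene selection applies the mean and dispersion bounds", {
    # natural-scale toy values; verify membership by direct recomputation
    nat <- rbind(a = c(0, 0, 0, 6),      # dispersive, low mean
                 b = c(60, 60, 60, 60),  # high mean, zero dispersion
                 c = c(0, 0, 0, 0))      # constant zero
    colnames(nat) <- paste0("c", 1:4)
    v <- log1p(nat)
    got <- selectVariableGenes(v, meanLow = 0.01, meanHigh = 3,
                               minDispersion = 1)
    keep <- vapply(rownames(v), function(g) {
        mu <- mean(v[g, ]); nm <- mean(nat[g, ])
        disp <- if (nm > 0) var(nat[g, ]) / nm else 0
        mu >= 0.01 && mu <= 3 && disp > 1
    }, logical(1))
    expect_identical(got, rownames(v)[keep])
    expect_identical(got, "a")
    # mean log value above the upper bound is excluded
    hot <- matrix(rep(exp(3.5) - 1, 4), nrow = 1,
                  dimnames = list("hot", paste0("c", 1:4)))
    expect_length(selectVariableGenes(log1p(hot)), 0)
})

test_that("cell similarity behaves like Pearson against the centroid", {
    # identical cells: r = 1
    v <- cbind(a = c(1, 2, 3), b = c(1, 2, 3))
    rownames(v) <- paste0("g", 1:3)
    expect_equal(unname(cellSimilarity(v, c("x", "x"))), c(1, 1))
    # two-point anti-correlated toy with self excluded
    v2 <- cbind(a = c(1, 0), b = c(0, 1))
    rownames(v2) <- paste0("g", 1:2)
    r <- cellSimilarity(v2, c("x", "x"), excludeSelf = TRUE)
    expect_equal(unname(r), c(-1, -1))
    # all values within [-1, 1] on simulated data
    sim <- generateCounts(tinyConfig(seed = 3))
    sce <- logNormalize(filterGenes(filterCells(sim$sce, minGenes = 10)))
    rs <- cellSimilarity(sce)
    expect_true(all(rs >= -1 & rs <= 1))
    # planted structure: within-cluster similarity beats between-cluster
    cl <- colData(sce)$cluster
    swapped <- cellSimilarity(sce, c(cl[cl == "C2"], cl[cl != "C2"]))
    expect_gt(mean(rs), mean(swapped))
    expect_error(cellSimilarity(v, c("x", "y")), ">= 2 cells")
})

test_that("group correlation matrices are symmetric with unit diagonal", {
    sim <- generateCounts(tinyConfig(seed = 3))
    sce <- logNormalize(filterGenes(filterCells(sim$sce, minGenes = 10)))
    groups <- paste(colData(sce)$cluster, colData(sce)$condition, sep = ".")
    cc <- clusterCorrelationMatrix(sce, groups)
    expect_identical(cc, t(cc))
    expect_true(all(diag(cc) == 1))
    # the two condition halves of one cluster correlate more with each
    # other than with a different cluster (4x shifted markers)
    expect_gt(cc["C1.nonAD", "C1.AD"], cc["C1.nonAD", "C2.AD"])
})
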
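test_that("DE gene selection applies the strict min-p rule", {
    p <- rbind(g1 = c(0.20, 0.04),   # min 0.04 < 0.05 -> kept
               g2 = c(0.05, 0.06),   # min 0.05, strict inequality -> dropped
               g3 = c(NA, NA),       # never tested -> dropped
               g4 = c(NA, 0.001))
    colnames(p) <- c("c1", "c2")
    expect_equal(selectDEGenes(p, 0.05), c("g1", "g4"))
    expect_error(selectDEGenes(p[0, , drop = FALSE]), "empty")
    expect_error(selectDEGenes(p, alpha = 1.2), "alpha")
})

test_that("correlation matches identities and the textbook formula", {
    m <- rbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4),
               c = c(8, 6, 4, 2), d = c(5, 1, 9, 3))
    colnames(m) <- paste0("s", 1:4)
    r <- correlationValues(computeCorrelation(m, log2Transform = FALSE))
    expect_equal(r["a", "b"], 1)                   # duplicated profile
    expect_equal(r["a", "c"], -1)                  # exact negation
    # hand-computable 3x4 oracle check on the remaining pairs
    for (g1 in rownames(m)) for (g2 in rownames(m))
        expect_equal(r[g1, g2], oraclePearson(m[g1, ], m[g2, ]),
                     tolerance = 1e-12)
})

test_that("correlation equals the brute-force Pearson formula on random matrices", {
    for (seed in 1:25) {
        set.seed(seed)
        m <- matrix(rexp(60, 0.2), nrow = 10,
                    dimnames = list(sprintf("g%02d", 1:10),
                                    sprintf("s%d", 1:6)))
        r <- correlationValues(computeCorrelation(m, log2Transform = FALSE))
        for (i in 1:9) for (j in (i + 1):10)
            expect_equal(r[i, j], oraclePearson(m[i, ], m[j, ]),
                         tolerance = 1e-10)
    }
})

test_that("zero-variance genes are excluded and few samples rejected", {
    m <- rbind(a = c(1, 2, 3, 4), flat = c(5, 5, 5, 5), b = c(2, 1, 2, 9))
    colnames(m) <- paste0("s", 1:4)
    expect_message(corr <- computeCorrelation(m, log2Transform = FALSE),
                   "zero-variance")
    expect_equal(excludedGenes(corr), "flat")
    expect_equal(networkGenes(corr), c("a", "b"))
    expect_error(computeCorrelation(m[, 1:2]), "3 samples")
})

test_that("scale-free fit recovers an exact power law and rejects degeneracy", {
    # P(k) = c k^-2 at k in {1, 2, 4, 8}: collinear in log-log space
    deg <- rep(c(1, 2, 4, 8), times = c(64, 16, 4, 1))
    fit <- scaleFreeFit(deg)
    expect_equal(fit$r.squared, 1.0, tolerance = 1e-12)
    expect_equal(fit$lambda, 2.0, tolerance = 1e-12)

    # exponent 1.5 likewise recovered exactly
    deg2 <- rep(c(1, 4, 16), times = c(512, 64, 8))
    expect_equal(scaleFreeFit(deg2)$lambda, 1.5, tolerance = 1e-12)

    expect_error(scaleFreeFit(rep(3, 50)), "3 distinct")  # regular graph
})

test_that("threshold scan is monotone and flags undefined fits", {
    se <- simulateBlockExpression(
        blockDesign(nBlocks = 3, genesPerBlock = 25, nBackground = 25,
                    nSamples = 20, withinCorr = 0.85, seed = 13))
    corr <- computeCorrelation(se)
    scan <- scanThresholds(corr, seq(0.5, 0.99, 0.01))
    s <- scanTable(scan)
    expect_true(all(diff(s$n_edges) <= 0))
    expect_true(all(diff(s$mean_degree) <= 1e-9))
    # nestedness: edges at t2 > t1 are a subset of edges at t1
    for (pair in list(c(0.6, 0.8), c(0.7, 0.9))) {
        e1 <- networkEdges(buildNetwork(corr, pair[1]))
        e2 <- networkEdges(buildNetwork(corr, pair[2]))
        k1 <- paste(e1$from, e1$to)
        k2 <- paste(e2$from, e2$to)
        expect_true(all(k2 %in% k1))
    }
    # a grid so high that nothing survives
    rsmall <- correlationValues(corr)[1:5, 1:5]
    rsmall[upper.tri(rsmall)] <- 0.1
    rsmall[lower.tri(rsmall)] <- 0.1
    csmall <- new("CorrelationMatrix", r = rsmall, excluded = character())
    srow <- scanTable(scanThresholds(csmall, 0.95))
    expect_equal(srow$n_nodes, 0)
    expect_true(is.na(srow$r_squared))
    expect_error(scanThresholds(corr, numeric(0)), "empty")
})

test_that("threshold selection takes the argmax with ties toward density", {
    mkScan <- function(t, r2, n = 10) {
        new("ThresholdScan", scan = data.frame(
            threshold = t, n_nodes = n, n_edges = rev(seq_along(t)) * 5,
            mean_degree = rev(seq_along(t)), r_squared = r2,
            lambda = rep(2, length(t))))
    }
    expect_equal(selectThreshold(mkScan(c(0.80, 0.90, 0.95),
                                        c(0.70, 0.86, 0.60))), 0.90)
    expect_equal(selectThreshold(mkScan(c(0.85, 0.90), c(0.80, 0.80))), 0.85)
    expect_equal(selectThreshold(mkScan(0.7, 0.5)), 0.7)
    expect_error(selectThreshold(mkScan(c(0.8, 0.9), c(NA, NA))),
                 "defined")
})

test_that("network construction uses strict |r| > t with signs and weights", {
    r <- diag(3)
    dimnames(r) <- list(c("x", "y", "z"), c("x", "y", "z"))
    r["x", "y"] <- r["y", "x"] <- -0.95
    r["x", "z"] <- r["z", "x"] <- 0.90    # exactly t: no edge
    r["y", "z"] <- r["z", "y"] <- 0.10
    corr <- new("CorrelationMatrix", r = r, excluded = character())
    net <- buildNetwork(corr, 0.90)
    ed <- networkEdges(net)
    expect_equal(nrow(ed), 1)
    expect_equal(ed$weight, 0.95)
    expect_equal(ed$sign, -1L)
    expect_equal(networkGenes(net), c("x", "y"))  # z isolated -> excluded
})

test_that("planted blocks reappear as connected components at high threshold", {
    se <- simulateBlockExpression(
        blockDesign(nBlocks = 3, genesPerBlock = 20, nSamples = 24,
                    withinCorr = 0.95, seed = 21))
    corr <- computeCorrelation(se)
    net <- buildNetwork(corr, 0.8)
    comps <- connectedComponents(net)
    expect_gte(length(comps), 3)
    truth <- SummarizedExperiment::rowData(se)$block
    names(truth) <- rownames(se)
    # each of the three biggest components is pure w.r.t. the planted blocks
    for (comp in comps[1:3])
        expect_equal(length(unique(truth[comp])), 1)
    # node count can only shrink relative to the input gene set
    expect_lte(length(networkGenes(net)), nrow(se))
})
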
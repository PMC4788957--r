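test_that("dissimilarity is 1 - |r| with inherited symmetry", {
    r <- matrix(c(1, -1, 0, -1, 1, 0.5, 0, 0.5, 1), 3, 3,
                dimnames = list(letters[1:3], letters[1:3]))
    d <- dissimilarityFromCorrelation(r)
    expect_equal(d["a", "b"], 0)   # r = -1 -> perfectly similar
    expect_equal(d["a", "c"], 1)   # r = 0 -> maximally dissimilar
    expect_equal(d["b", "c"], 0.5)
    expect_equal(d, t(d))
    expect_equal(unname(diag(d)), rep(0, 3))
})

test_that("PAM recovers hand-checkable partitions", {
    d <- as.matrix(dist(c(a = 0, b = 1, c = 10, e = 11)))
    res <- clusterPAM(d, 2)
    lab <- clusterLabels(res)
    expect_equal(unname(lab["a"]), unname(lab["b"]))
    expect_equal(unname(lab["c"]), unname(lab["e"]))
    expect_false(lab[["a"]] == lab[["c"]])
    expect_length(res@medoids, 2)
    expect_error(clusterPAM(d, 4), "k must")
})

test_that("PAM agrees with exhaustive medoid enumeration on random instances", {
    for (seed in 1:30) {
        set.seed(seed)
        k <- sample(2:3, 1)
        sizes <- sample(2:4, k, replace = TRUE)
        # clusters drawn from disjoint intervals: BUILD+SWAP reaches the
        # same global optimum the oracle enumerates
        pts <- unlist(lapply(seq_len(k), function(b)
            runif(sizes[b], 10 * b, 10 * b + 1)))
        n <- length(pts)
        d <- as.matrix(dist(pts))
        dimnames(d) <- list(sprintf("g%d", 1:n), sprintf("g%d", 1:n))
        got <- clusterLabels(clusterPAM(d, k))
        want <- oraclePAMPartition(d, k)
        # same partition up to cluster relabeling, and same objective
        expect_equal(mclust::adjustedRandIndex(got, want), 1)
        objective <- function(labels) {
            sum(sapply(unique(labels), function(cl) {
                idx <- which(labels == cl)
                min(sapply(idx, function(m) sum(d[idx, m])))
            }))
        }
        expect_equal(objective(got), objective(want), tolerance = 1e-10)
    }
})

test_that("average-linkage hierarchical clustering cuts as expected", {
    d <- as.matrix(dist(c(a = 0, b = 1, c = 10, e = 11)))
    lab <- clusterLabels(clusterHclustAverage(d, 2))
    expect_equal(unname(lab["a"]), unname(lab["b"]))
    expect_equal(unname(lab["c"]), unname(lab["e"]))
    # duplicated points merge first
    d2 <- as.matrix(dist(c(p = 5, q = 5, r = 0, s = 9)))
    lab2 <- clusterLabels(clusterHclustAverage(d2, 3))
    expect_equal(unname(lab2["p"]), unname(lab2["q"]))
})

test_that("silhouette widths follow the (b-a)/max(a,b) definition", {
    d <- as.matrix(dist(c(a = 0, b = 1, c = 10, e = 11)))
    sil <- silhouetteWidths(c(a = 1, b = 1, c = 2, e = 2), d)
    # outer points: a=1, b=10.5; inner points: a=1, b=9.5
    expect_equal(unname(sil$widths),
                 c(9.5 / 10.5, 8.5 / 9.5, 8.5 / 9.5, 9.5 / 10.5))
    expect_equal(sil$overallMean, mean(sil$widths))
    # independent implementation agrees
    ref <- cluster::silhouette(c(1, 1, 2, 2), dmatrix = d)
    expect_equal(unname(sil$widths), ref[, "sil_width"], tolerance = 1e-12)

    # singleton cluster convention and a = b degeneracy
    sil2 <- silhouetteWidths(c(a = 1, b = 1, c = 2, e = 3), d)
    expect_equal(unname(sil2$widths[c("c", "e")]), c(0, 0))
    dEq <- matrix(1, 4, 4, dimnames = dimnames(d)); diag(dEq) <- 0
    silEq <- silhouetteWidths(c(a = 1, b = 1, c = 2, e = 2), dEq)
    expect_equal(unname(silEq$widths), rep(0, 4))   # a = b -> s = 0
    expect_error(silhouetteWidths(c(a = 1, b = 1), d[1:2, 1:2]), "2 clusters")
})

test_that("silhouette widths stay in [-1, 1] and beat permuted labels", {
    se <- simulateBlockExpression(
        blockDesign(nBlocks = 3, genesPerBlock = 15, nSamples = 16,
                    withinCorr = 0.85, seed = 5))
    d <- dissimilarityFromCorrelation(computeCorrelation(se))
    truth <- SummarizedExperiment::rowData(se)$block
    names(truth) <- rownames(se)
    sil <- silhouetteWidths(truth, d)
    expect_true(all(sil$widths >= -1 & sil$widths <= 1))
    set.seed(9)
    for (i in 1:5) {
        perm <- setNames(sample(truth), names(truth))
        expect_gt(sil$overallMean, silhouetteWidths(perm, d)$overallMean)
    }
})

test_that("model selection scans candidates and recovers planted k", {
    se <- simulateBlockExpression(
        blockDesign(nBlocks = 5, genesPerBlock = 30, nSamples = 24,
                    withinCorr = 0.9, seed = 42))
    d <- dissimilarityFromCorrelation(computeCorrelation(se))
    sel <- selectClustering(d, kRange = 2:8)
    expect_equal(nrow(sel$table), 2 * 7)   # one row per (algorithm, k)
    expect_equal(sel$best@k, 5L)
    truth <- SummarizedExperiment::rowData(se)$block
    names(truth) <- rownames(se)
    ari <- mclust::adjustedRandIndex(clusterLabels(sel$best),
                                     truth[names(clusterLabels(sel$best))])
    expect_gte(ari, 0.9)
    # the winning row attains the max silhouette
    expect_equal(max(sel$table$overall_mean_silhouette),
                 overallSilhouette(sel$best))
})

test_that("model selection handles degenerate ranges and fixed ties", {
    d <- as.matrix(dist(c(a = 0, b = 1, c = 10, e = 11, f = 20)))
    sole <- selectClustering(d, kRange = 2, algorithms = "pam")
    expect_equal(nrow(sole$table), 1)
    expect_equal(sole$best@algorithm, "pam")
    expect_equal(sole$best@k, 2L)
    expect_error(selectClustering(d, kRange = integer(0)), "empty")
    # pam and hclust tie on a clean instance -> pam preferred
    both <- selectClustering(d, kRange = 3, algorithms = c("pam",
                                                           "hclust_average"))
    if (abs(diff(both$table$overall_mean_silhouette)) < 1e-12)
        expect_equal(both$best@algorithm, "pam")
})

test_that("clustering is invariant to gene order up to relabeling", {
    se <- simulateBlockExpression(
        blockDesign(nBlocks = 3, genesPerBlock = 10, nSamples = 16,
                    withinCorr = 0.9, seed = 17))
    d <- dissimilarityFromCorrelation(computeCorrelation(se))
    set.seed(2)
    perm <- sample(nrow(d))
    dPerm <- d[perm, perm]
    for (fun in list(clusterPAM, clusterHclustAverage)) {
        l1 <- clusterLabels(fun(d, 3))
        l2 <- clusterLabels(fun(dPerm, 3))[names(l1)]
        expect_equal(mclust::adjustedRandIndex(l1, l2), 1)
    }
})
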
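test_that("clustering coefficient matches triangle enumeration", {
    expect_equal(unname(localClusteringCoefficient(
        fixtureGraph("triangle"))), rep(1, 3))
    expect_equal(unname(localClusteringCoefficient(
        fixtureGraph("path", 3), "v2")), 0)
    expect_error(localClusteringCoefficient(fixtureGraph("triangle"), "zz"),
                 "unknown gene")
    for (seed in 1:20) {
        net <- randomNetwork(15, 0.3, seed)
        expect_equal(unname(localClusteringCoefficient(net)),
                     oracleClustering(oracleAdjacency(net)))
    }
})

test_that("path lengths match the Floyd-Warshall oracle", {
    expect_equal(averagePathLength(fixtureGraph("complete", 4)), 1.0)
    expect_equal(averagePathLength(fixtureGraph("path", 3)), 4 / 3)
    for (seed in 1:15) {
        net <- randomNetwork(20, 0.25, seed)
        A <- oracleAdjacency(net)
        D <- oracleFloydWarshall(A)
        memb <- oracleComponents(A)
        big <- which(memb == names(sort(table(memb), decreasing = TRUE))[1])
        Dc <- D[big, big]
        expect_equal(averagePathLength(net), mean(Dc[upper.tri(Dc)]))
        expect_equal(networkDiameter(net), max(Dc))
    }
})

test_that("path lengths are hop counts, not |r|-weighted distances", {
    # a path with fractional edge weights: distances must still be 1 and 2
    net <- new("CoexpressionNetwork", nodes = c("a", "b", "c"),
               edges = data.frame(from = c("a", "b"), to = c("b", "c"),
                                  weight = c(0.92, 0.95), sign = 1L,
                                  stringsAsFactors = FALSE),
               threshold = 0.9)
    expect_equal(averagePathLength(net), 4 / 3)
    expect_equal(networkDiameter(net), 2)
    expect_setequal(neighborhoodAtDistance(net, "a", 1), "b")
    expect_setequal(neighborhoodAtDistance(net, "a", 2), c("b", "c"))
})

test_that("connected components agree with union-find", {
    two <- new("CoexpressionNetwork",
               nodes = c("a", "b", "c", "x", "y", "z"),
               edges = data.frame(
                   from = c("a", "a", "b", "x", "x", "y"),
                   to = c("b", "c", "c", "y", "z", "z"),
                   weight = 1, sign = 1L, stringsAsFactors = FALSE),
               threshold = 0)
    expect_equal(lengths(connectedComponents(two)), c(3L, 3L))
    expect_equal(connectedComponents(two)[[1]], c("a", "b", "c"))  # tie: id

    expect_equal(lengths(connectedComponents(fixtureGraph("star_k", 4))), 4L)

    for (seed in 1:15) {
        net <- randomNetwork(18, 0.1, seed)
        memb <- oracleComponents(oracleAdjacency(net))
        got <- connectedComponents(net)
        # identical partition: same component sets
        want <- lapply(split(networkGenes(net), memb), sort)
        expect_setequal(vapply(got, paste, "", collapse = "|"),
                        vapply(want, paste, "", collapse = "|"))
    }
})

test_that("HITS scores match the dense principal eigenvector", {
    expect_equal(unname(hitsScores(fixtureGraph("complete", 4))), rep(1, 4))
    star <- hitsScores(fixtureGraph("star_k", 4))
    expect_equal(unname(star["center"]), 1)
    expect_equal(unname(star[c("leaf1", "leaf2", "leaf3")]),
                 rep(1 / sqrt(3), 3), tolerance = 1e-8)
    for (seed in 1:20) {
        net <- randomNetwork(12, 0.4, seed)
        expect_equal(unname(hitsScores(net)),
                     oracleHits(oracleAdjacency(net)), tolerance = 1e-8)
    }
})

test_that("HITS scores are invariant under node relabeling", {
    net <- randomNetwork(14, 0.3, 4)
    scores <- hitsScores(net)
    set.seed(1)
    perm <- sample(length(networkGenes(net)))
    nodes2 <- networkGenes(net)[perm]
    net2 <- new("CoexpressionNetwork", nodes = nodes2,
                edges = coexnet:::.canonicalEdges(networkEdges(net), nodes2),
                threshold = 0)
    scores2 <- hitsScores(net2)
    expect_equal(scores2[names(scores)], scores, tolerance = 1e-8)
})

test_that("hub ranking breaks ties by HITS score then gene id", {
    star <- fixtureGraph("star_k", 4)
    expect_equal(rankHubs(star, 1), "center")
    expect_warning(all5 <- rankHubs(star, 10), "exceeds")
    expect_length(all5, 4)
    # complete graph: all degrees and scores tied -> lexicographic
    comp <- fixtureGraph("complete", 4)
    expect_equal(rankHubs(comp, 4), sort(networkGenes(comp)))
    # degree ties broken by hits score: barbell-ish fixture
    net <- new("CoexpressionNetwork",
               nodes = c("a", "b", "c", "d", "e"),
               edges = data.frame(
                   from = c("a", "a", "b", "c", "d"),
                   to = c("b", "c", "c", "d", "e"),
                   weight = 1, sign = 1L, stringsAsFactors = FALSE),
               threshold = 0)
    ht <- hubTable(net)
    tied <- ht[ht$degree == 2, ]
    expect_equal(tied$gene[order(tied$degree_rank)],
                 tied$gene[order(-tied$hits_score, tied$gene)])
})

test_that("handshake identity holds on constructed networks", {
    for (seed in 1:10) {
        net <- randomNetwork(16, 0.2, seed)
        deg <- tabulate(factor(c(networkEdges(net)$from,
                                 networkEdges(net)$to),
                               levels = networkGenes(net)))
        expect_equal(sum(deg), 2 * nrow(networkEdges(net)))
    }
})

test_that("null ensembles honour their model contracts", {
    # G(n, m): every replicate has exactly m edges -> with stat = mean
    # degree 2m/n the sample is constant
    ens <- generateNullEnsemble("erdos_renyi", 100, 300, nReplicates = 50,
                                statistic = "average_clustering", seed = 4)
    expect_length(ensembleSamples(ens), 50)
    # verify edge counts directly on regenerated graphs
    edges <- coexnet:::.withSeed(4L, vapply(1:50, function(i)
        igraph::ecount(igraph::sample_gnm(100, 300)), numeric(1)))
    expect_true(all(edges == 300))

    # edgeless ER: all clustering statistics are exactly 0
    ens0 <- generateNullEnsemble("erdos_renyi", 30, 0, nReplicates = 20,
                                 statistic = "average_clustering", seed = 1)
    expect_true(all(ensembleSamples(ens0) == 0))

    # BA: degree-sum identity gives mean degree ~ 2 m_attach
    ensBA <- generateNullEnsemble("barabasi_albert", 2000, 6000,
                                  nReplicates = 5,
                                  statistic = "scale_free_r2", seed = 2)
    expect_length(ensembleSamples(ensBA), 5)
    g <- coexnet:::.withSeed(2L, igraph::sample_pa(2000, power = 1, m = 3,
                                                   directed = FALSE))
    expect_lt(abs(mean(igraph::degree(g)) - 6) / 6, 0.05)

    expect_error(generateNullEnsemble("erdos_renyi", 5, 100), "exceeds")
    # reproducibility under the seed
    e1 <- generateNullEnsemble("erdos_renyi", 40, 60, nReplicates = 10,
                               statistic = "average_clustering", seed = 7)
    e2 <- generateNullEnsemble("erdos_renyi", 40, 60, nReplicates = 10,
                               statistic = "average_clustering", seed = 7)
    expect_identical(ensembleSamples(e1), ensembleSamples(e2))
})

test_that("ER ensemble clustering matches the G(n,m) expectation", {
    n <- 60; m <- 250
    ens <- generateNullEnsemble("erdos_renyi", n, m, nReplicates = 300,
                                statistic = "average_clustering", seed = 8)
    s <- ensembleSamples(ens)
    expected <- 2 * m / (n * (n - 1))   # edge density = P(neighbour pair linked)
    se3 <- 3 * sd(s) / sqrt(length(s))
    expect_lt(abs(mean(s) - expected), se3 + 0.01)
})

test_that("empirical p-values follow the (1+b)/(R+1) rule", {
    expect_equal(empiricalPvalue(5, (1:10) / 10, "greater"), 1 / 11)
    expect_equal(empiricalPvalue(0, (1:10) / 10, "greater"), 1.0)
    expect_equal(empiricalPvalue(0.3, 0.3, "greater"), 1.0)  # tie counts
    expect_equal(empiricalPvalue(0.05, (1:10) / 10, "less"), 1 / 11)
    expect_error(empiricalPvalue(1, numeric(0)), "empty")
    # monotone in the observation for direction = greater
    samples <- runif(50)
    ps <- sapply(c(0.1, 0.5, 0.9, 1.5), empiricalPvalue,
                 ensemble = samples, direction = "greater")
    expect_true(all(diff(ps) <= 0))
    expect_true(all(ps >= 1 / 51 & ps <= 1))
})

test_that("topology summary assembles consistent fields", {
    tri <- fixtureGraph("triangle")
    topo <- summarizeTopology(tri)
    expect_equal(topo$average_clustering, 1.0)
    expect_equal(topo$average_path_length, 1.0)
    expect_equal(topo$major_component_fraction, 100)

    net <- randomNetwork(20, 0.15, 3)
    topo <- summarizeTopology(net)
    expect_equal(sum(topo$component_sizes), topo$n_nodes)
    expect_equal(topo$major_component_fraction,
                 percentOf(max(topo$component_sizes), topo$n_nodes, 1))
    expect_equal(topo$average_clustering,
                 mean(oracleClustering(oracleAdjacency(net))))
})
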
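# Independent brute-force oracles. Each re-derives a quantity from first
# principles (textbook formula, exhaustive enumeration, dense linear
# algebra) so package results can be checked against a second route.

# textbook Pearson correlation of two vectors
oraclePearson <- function(x, y) {
    mx <- mean(x); my <- mean(y)
    sum((x - mx) * (y - my)) /
        sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# adjacency matrix of a CoexpressionNetwork (0/1, node order preserved)
oracleAdjacency <- function(net) {
    nodes <- networkGenes(net)
    ed <- networkEdges(net)
    A <- matrix(0, length(nodes), length(nodes),
                dimnames = list(nodes, nodes))
    for (i in seq_len(nrow(ed))) {
        A[ed$from[i], ed$to[i]] <- 1
        A[ed$to[i], ed$from[i]] <- 1
    }
    A
}

# O(n^3) triangle enumeration clustering coefficient
oracleClustering <- function(A) {
    n <- nrow(A)
    sapply(seq_len(n), function(v) {
        nb <- which(A[v, ] > 0)
        k <- length(nb)
        if (k < 2) return(0)
        tri <- 0
        for (i in seq_len(k - 1)) for (j in (i + 1):k)
            if (A[nb[i], nb[j]] > 0) tri <- tri + 1
        tri / (k * (k - 1) / 2)
    })
}

# Floyd-Warshall all-pairs shortest paths
oracleFloydWarshall <- function(A) {
    n <- nrow(A)
    D <- matrix(Inf, n, n)
    diag(D) <- 0
    D[A > 0] <- 1
    for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
    D
}

# union-find connected components; returns membership vector
oracleComponents <- function(A) {
    n <- nrow(A)
    parent <- seq_len(n)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    for (i in seq_len(n)) for (j in seq_len(n))
        if (A[i, j] > 0) {
            ri <- find(i); rj <- find(j)
            if (ri != rj) parent[ri] <- rj
        }
    sapply(seq_len(n), find)
}

# principal eigenvector of the adjacency, max-normalized, via dense eigen
oracleHits <- function(A) {
    e <- eigen(A, symmetric = TRUE)
    v <- e$vectors[, which.max(e$values)]
    if (sum(v) < 0) v <- -v
    v / max(v)
}

# exhaustive hypergeometric upper-tail sum with choose()
oracleFisherGreater <- function(a, b, c, d) {
    N <- a + b + c + d; K <- a + c; n <- a + b
    xs <- a:min(K, n)
    xs <- xs[n - xs <= N - K]
    sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}

# exhaustive PAM: best medoid set by total dissimilarity, ties by the
# lexicographically smallest index set; returns the induced partition
oraclePAMPartition <- function(d, k) {
    n <- nrow(d)
    sets <- utils::combn(n, k)
    cost <- apply(sets, 2, function(m) sum(apply(d[, m, drop = FALSE], 1, min)))
    best <- sets[, which.min(cost)]
    apply(d[, best, drop = FALSE], 1, which.min)
}

# one-sided Mann-Whitney U (x greater), normal approximation with tie and
# continuity correction: the classical large-sample formula
oracleWilcoxGreater <- function(x, y) {
    m <- length(x); n <- length(y)
    r <- rank(c(x, y))
    U <- sum(r[seq_len(m)]) - m * (m + 1) / 2
    ties <- table(r)
    sigma2 <- m * n / 12 *
        ((m + n + 1) - sum(ties^3 - ties) / ((m + n) * (m + n - 1)))
    z <- (U - m * n / 2 - 0.5) / sqrt(sigma2)
    pnorm(z, lower.tail = FALSE)
}

# random small network fixture
randomNetwork <- function(n, p, seed) {
    set.seed(seed)
    nodes <- sprintf("n%02d", seq_len(n))
    pairs <- t(utils::combn(n, 2))
    keep <- runif(nrow(pairs)) < p
    # ensure at least one edge
    if (!any(keep)) keep[1] <- TRUE
    ed <- data.frame(from = nodes[pairs[keep, 1]],
                     to = nodes[pairs[keep, 2]],
                     weight = 1, sign = 1L, stringsAsFactors = FALSE)
    used <- nodes[nodes %in% c(ed$from, ed$to)]
    new("CoexpressionNetwork", nodes = used,
        edges = ed, threshold = 0)
}

# write a small expression TSV and return its path
writeExprFixture <- function(m, path = tempfile(fileext = ".tsv")) {
    df <- data.frame(gene = rownames(m), m, check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
}
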
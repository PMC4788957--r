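## Topology statistics, hub/authority ranking and null-ensemble
## significance testing.

# largest connected component as an igraph subgraph
.majorComponent <- function(g) {
    comp <- igraph::components(g)
    keep <- which(comp$membership == which.max(comp$csize))
    igraph::induced_subgraph(g, keep)
}

#' Local clustering coefficient of a gene
#'
#' Fraction of a gene's co-expression neighbours that are themselves
#' connected: triangles through the gene divided by deg(deg-1)/2. Genes of
#' degree < 2 have coefficient 0 by convention.
#'
#' @param net a [CoexpressionNetwork].
#' @param gene gene id (omit for all genes).
#' @return named numeric vector of coefficients in \[0, 1\].
#' @examples
#' localClusteringCoefficient(fixtureGraph("triangle"))       # all 1
#' localClusteringCoefficient(fixtureGraph("path", 3), "v2")  # 0
#' @export
localClusteringCoefficient <- function(net, gene = NULL) {
    g <- .asIgraph(net)
    cc <- igraph::transitivity(g, type = "local", isolates = "zero")
    names(cc) <- net@nodes
    cc[is.na(cc)] <- 0   # degree-1 nodes
    if (is.null(gene)) return(cc)
    if (!all(gene %in% net@nodes)) stop("unknown gene: ",
                                        paste(setdiff(gene, net@nodes),
                                              collapse = ", "))
    cc[gene]
}

#' Average shortest-path length
#'
#' Mean unweighted BFS distance over all unordered pairs of the largest
#' connected component (the paper-style "network diameter"; the true
#' maximum eccentricity is available via [networkDiameter()]).
#'
#' @param net a [CoexpressionNetwork] with at least one edge.
#' @return numeric mean path length (>= 1).
#' @examples
#' averagePathLength(fixtureGraph("complete", 4))  # 1
#' averagePathLength(fixtureGraph("path", 3))      # 4/3
#' @export
averagePathLength <- function(net) {
    if (nrow(net@edges) == 0) stop("network has no edges")
    gc <- .majorComponent(.asIgraph(net))
    d <- igraph::distances(gc, weights = NA)
    mean(d[upper.tri(d)])
}

#' @rdname averagePathLength
#' @return `networkDiameter()`: the maximum shortest-path distance within
#'   the largest component.
#' @export
networkDiameter <- function(net) {
    if (nrow(net@edges) == 0) stop("network has no edges")
    gc <- .majorComponent(.asIgraph(net))
    max(igraph::distances(gc, weights = NA))
}

#' Connected components
#'
#' Partition of the genes into maximal connected sets, sorted by size
#' descending with ties broken by the smallest gene id.
#'
#' @param net a [CoexpressionNetwork].
#' @return list of character vectors (each sorted), largest first.
#' @export
connectedComponents <- function(net) {
    if (length(net@nodes) == 0) return(list())
    comp <- igraph::components(.asIgraph(net))
    parts <- split(net@nodes, comp$membership)
    parts <- lapply(parts, sort)
    ord <- order(-lengths(parts), vapply(parts, `[[`, "", 1))
    unname(parts[ord])
}

#' HITS authoritative-hub scores
#'
#' Scores genes by the principal eigenvector of the co-expression adjacency
#' matrix (for an undirected graph the HITS hub and authority vectors
#' coincide with this eigenvector). Computed by power iteration with a unit
#' diagonal shift, x <- (A + I) x with L2 normalization per step, which
#' leaves the eigenvectors of A unchanged while guaranteeing convergence on
#' bipartite graphs (where the unshifted iteration oscillates). Final
#' scores are rescaled so the maximum is 1. Genes in minor components
#' receive scores near 0.
#'
#' @param net a [CoexpressionNetwork] with at least one edge.
#' @param tol convergence tolerance on the L2 change per step (default
#'   1e-10).
#' @param maxIter maximum iterations (default 1000).
#' @return named numeric vector of max-normalized scores in \[0, 1\].
#' @examples
#' hitsScores(fixtureGraph("star_k", 4))  # center 1, leaves 1/sqrt(3)
#' @export
hitsScores <- function(net, tol = 1e-10, maxIter = 1000) {
    if (nrow(net@edges) == 0) stop("network has no edges")
    n <- length(net@nodes)
    A <- Matrix::sparseMatrix(
        i = c(match(net@edges$from, net@nodes),
              match(net@edges$to, net@nodes)),
        j = c(match(net@edges$to, net@nodes),
              match(net@edges$from, net@nodes)),
        x = 1, dims = c(n, n))
    x <- rep(1 / sqrt(n), n)
    res <- Inf
    for (it in seq_len(maxIter)) {
        y <- as.numeric(A %*% x) + x       # (A + I) x
        y <- y / sqrt(sum(y^2))
        res <- sqrt(sum((y - x)^2))
        if (res < tol) {
            y <- y / max(y)
            names(y) <- net@nodes
            return(y)
        }
        x <- y
    }
    stop(sprintf("HITS did not converge in %d iterations (residual %.3g)",
                 maxIter, res))
}

#' Per-gene hub table
#'
#' Degree, max-normalized HITS score, and the corresponding ranks for every
#' gene of the network. Degree ranks break ties by higher HITS score then
#' lexicographic gene id; HITS ranks break ties lexicographically.
#'
#' @param net a [CoexpressionNetwork] with at least one edge.
#' @param tol,maxIter passed to [hitsScores()].
#' @return data.frame with columns `gene`, `degree`, `hits_score`,
#'   `degree_rank`, `hits_rank`.
#' @export
hubTable <- function(net, tol = 1e-10, maxIter = 1000) {
    nodes <- net@nodes
    deg <- tabulate(c(match(net@edges$from, nodes),
                      match(net@edges$to, nodes)), nbins = length(nodes))
    hits <- hitsScores(net, tol = tol, maxIter = maxIter)
    degOrd <- order(-deg, -hits, nodes)
    hitsOrd <- order(-hits, nodes)
    out <- data.frame(gene = nodes, degree = deg,
                      hits_score = unname(hits),
                      degree_rank = NA_integer_, hits_rank = NA_integer_,
                      stringsAsFactors = FALSE)
    out$degree_rank[degOrd] <- seq_along(nodes)
    out$hits_rank[hitsOrd] <- seq_along(nodes)
    out
}

#' Top hub genes by degree
#'
#' The `nTop` genes with highest degree; ties are broken by higher HITS
#' score, then lexicographic gene id.
#'
#' @param hub a [CoexpressionNetwork] or a [hubTable()] data.frame.
#' @param nTop number of hubs to return (>= 1); truncated with a warning if
#'   larger than the network.
#' @return character vector of gene ids, best first.
#' @export
rankHubs <- function(hub, nTop = 1000) {
    if (is(hub, "CoexpressionNetwork")) hub <- hubTable(hub)
    if (nTop < 1) stop("nTop must be >= 1")
    if (nTop > nrow(hub)) {
        warning("nTop exceeds the number of genes; returning all")
        nTop <- nrow(hub)
    }
    hub$gene[order(hub$degree_rank)][seq_len(nTop)]
}

# statistic evaluated on an igraph object, by name
.topoStatistic <- function(name) {
    switch(name,
        average_clustering = function(g) {
            cc <- igraph::transitivity(g, type = "local",
                                       isolates = "zero")
            cc[is.na(cc)] <- 0
            mean(cc)
        },
        scale_free_r2 = function(g) {
            deg <- igraph::degree(g)
            tryCatch(scaleFreeFit(deg[deg >= 1])$r.squared,
                     error = function(e) NA_real_)
        },
        average_path_length = function(g) {
            gc <- .majorComponent(g)
            if (igraph::vcount(gc) < 2) return(NA_real_)
            d <- igraph::distances(gc, weights = NA)
            mean(d[upper.tri(d)])
        },
        stop("unknown statistic: ", name))
}

#' Generate a random-graph null ensemble
#'
#' Draws `nReplicates` random graphs with the observed node and edge counts
#' and evaluates a topology statistic on each, yielding the null
#' distribution against which the observed network is judged. Models:
#' `erdos_renyi` draws G(n, m) graphs with exactly `nEdges` edges chosen
#' uniformly; `barabasi_albert` grows preferential-attachment graphs with
#' attachment parameter m = max(1, round(nEdges/nNodes)) so the expected
#' edge count matches approximately.
#'
#' @param model `"erdos_renyi"` or `"barabasi_albert"`.
#' @param nNodes,nEdges node and edge counts to match.
#' @param nReplicates ensemble size (the package default of 10000 mirrors
#'   common practice; smaller values keep exploratory runs fast).
#' @param statistic one of `"average_clustering"`, `"scale_free_r2"`,
#'   `"average_path_length"`.
#' @param seed integer seed; the ensemble is reproducible.
#' @return a [NullEnsemble].
#' @examples
#' ens <- generateNullEnsemble("erdos_renyi", 50, 100, nReplicates = 20,
#'                             statistic = "average_clustering", seed = 1)
#' summary(ensembleSamples(ens))
#' @export
generateNullEnsemble <- function(model = c("erdos_renyi", "barabasi_albert"),
                                 nNodes, nEdges, nReplicates = 10000,
                                 statistic = "average_clustering",
                                 seed = 1) {
    model <- match.arg(model)
    if (nReplicates < 1) stop("nReplicates must be >= 1")
    if (nEdges > nNodes * (nNodes - 1) / 2)
        stop("nEdges exceeds the maximum for a simple graph")
    stat <- .topoStatistic(statistic)
    mAttach <- max(1, round(nEdges / nNodes))
    samples <- .withSeed(seed, vapply(seq_len(nReplicates), function(i) {
        g <- if (model == "erdos_renyi")
            igraph::sample_gnm(nNodes, nEdges)
        else
            igraph::sample_pa(nNodes, power = 1, m = mAttach,
                              directed = FALSE)
        stat(g)
    }, numeric(1)))
    new("NullEnsemble", model = model, statistic = statistic,
        samples = samples, nNodes = as.integer(nNodes),
        nEdges = as.integer(nEdges), seed = as.integer(seed))
}

#' Empirical p-value against a null ensemble
#'
#' p = (1 + number of null samples at least as extreme as the observation)
#' / (replicates + 1). Ties count as extreme; the smallest attainable value
#' is therefore 1/(R+1) and a network beating all R nulls never reports 0.
#'
#' @param observed observed statistic value.
#' @param ensemble a [NullEnsemble] (or numeric vector of null samples).
#' @param direction `"greater"` (observation high) or `"less"`.
#' @return empirical p-value in \[1/(R+1), 1\].
#' @examples
#' empiricalPvalue(5, 1:10 / 10, "greater")  # beats all 10 -> 1/11
#' @export
empiricalPvalue <- function(observed, ensemble,
                            direction = c("greater", "less")) {
    direction <- match.arg(direction)
    samples <- if (is(ensemble, "NullEnsemble")) ensemble@samples
               else as.numeric(ensemble)
    if (length(samples) == 0) stop("empty null ensemble")
    beat <- if (direction == "greater") sum(samples >= observed)
            else sum(samples <= observed)
    (1 + beat) / (length(samples) + 1)
}

#' Summarize network topology
#'
#' Assembles the headline topology report of a network: node and edge
#' counts, component sizes, the percentage of genes in the major connected
#' component (one decimal), the mean local clustering coefficient
#' (degree < 2 counting 0), mean shortest-path length and diameter of the
#' largest component, and the scale-free fit.
#'
#' @param net a [CoexpressionNetwork].
#' @return list with elements `n_nodes`, `n_edges`, `component_sizes`,
#'   `major_component_fraction`, `average_clustering`,
#'   `average_path_length`, `diameter`, `scale_free` (list: `r.squared`,
#'   `lambda`).
#' @export
summarizeTopology <- function(net) {
    comps <- connectedComponents(net)
    sizes <- lengths(comps)
    nN <- length(net@nodes)
    nE <- nrow(net@edges)
    deg <- tabulate(c(match(net@edges$from, net@nodes),
                      match(net@edges$to, net@nodes)), nbins = nN)
    fit <- tryCatch(scaleFreeFit(deg[deg >= 1]),
                    error = function(e) list(r.squared = NA_real_,
                                             lambda = NA_real_))
    list(n_nodes = nN,
         n_edges = nE,
         component_sizes = as.integer(sizes),
         major_component_fraction =
             if (nN > 0) percentOf(max(sizes), nN, 1) else NA_real_,
         average_clustering =
             if (nN > 0) mean(localClusteringCoefficient(net)) else NA_real_,
         average_path_length =
             if (nE > 0) averagePathLength(net) else NA_real_,
         diameter = if (nE > 0) networkDiameter(net) else NA_real_,
         scale_free = fit)
}
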
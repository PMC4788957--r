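## PAM and average-linkage hierarchical clustering over the 1 - |r|
## dissimilarity, with silhouette-based selection of algorithm and cluster
## number.

#' Dissimilarity from correlation
#'
#' The gene similarity measure is the absolute Pearson correlation between
#' expression profiles; the corresponding dissimilarity is d = 1 - |r|
#' (perfectly correlated and perfectly anticorrelated genes are both at
#' distance 0).
#'
#' @param corr a [CorrelationMatrix] or a plain symmetric correlation
#'   matrix with gene dimnames.
#' @return symmetric numeric matrix with zero diagonal, values in \[0, 1\].
#' @export
dissimilarityFromCorrelation <- function(corr) {
    r <- if (is(corr, "CorrelationMatrix")) corr@r else corr
    d <- 1 - abs(r)
    diag(d) <- 0
    d
}

# assemble a validated ClusteringResult from labels + dissimilarity
.clusteringResult <- function(algorithm, k, labels, d, medoids = character()) {
    sil <- silhouetteWidths(labels, d)
    new("ClusteringResult", algorithm = algorithm, k = as.integer(k),
        labels = stats::setNames(as.integer(labels), names(labels)),
        medoids = as.character(medoids),
        silWidths = sil$widths,
        clusterMeans = sil$clusterMeans,
        overallMean = sil$overallMean)
}

#' Partition around medoids (PAM) clustering
#'
#' Kaufman-Rousseeuw k-medoids over a precomputed dissimilarity: the BUILD
#' phase greedily seeds k medoids, the SWAP phase exchanges medoids with
#' non-medoids while the total dissimilarity to the nearest medoid
#' decreases, and every gene is labelled by its nearest medoid. The
#' procedure is deterministic for a given dissimilarity.
#'
#' @param d symmetric dissimilarity matrix with gene dimnames (e.g. from
#'   [dissimilarityFromCorrelation()]).
#' @param k number of clusters, 2 <= k < n.
#' @return a [ClusteringResult] (medoid gene ids in `@medoids`).
#' @export
clusterPAM <- function(d, k) {
    n <- nrow(d)
    if (k < 2 || k >= n) stop("k must satisfy 2 <= k < n")
    if (is.null(rownames(d))) stop("gene ids (dimnames) are required")
    fit <- cluster::pam(stats::as.dist(d), k = k, diss = TRUE,
                        keep.diss = FALSE)
    labels <- stats::setNames(as.integer(fit$clustering), rownames(d))
    .clusteringResult("pam", k, labels, d, medoids = fit$medoids)
}

#' Average-linkage hierarchical clustering
#'
#' Agglomerative UPGMA over a precomputed dissimilarity, cut into k groups.
#'
#' @inheritParams clusterPAM
#' @return a [ClusteringResult].
#' @export
clusterHclustAverage <- function(d, k) {
    n <- nrow(d)
    if (k < 2 || k >= n) stop("k must satisfy 2 <= k < n")
    if (is.null(rownames(d))) stop("gene ids (dimnames) are required")
    tree <- stats::hclust(stats::as.dist(d), method = "average")
    labels <- stats::cutree(tree, k = k)
    .clusteringResult("hclust_average", k, labels, d)
}

#' Silhouette widths of a partition
#'
#' For each gene i with cluster mates: a(i) is the mean dissimilarity to
#' its own cluster (excluding itself), b(i) the smallest mean dissimilarity
#' to any other cluster, and s(i) = (b - a) / max(a, b). Members of
#' singleton clusters get s(i) = 0, as do genes with a = b = 0.
#'
#' @param labels named integer vector (gene -> cluster index); at least 2
#'   clusters.
#' @param d symmetric dissimilarity matrix covering the labelled genes.
#' @return list with `widths` (named per-gene s(i)), `clusterMeans` (named
#'   by cluster) and `overallMean`.
#' @examples
#' d <- as.matrix(dist(c(a = 0, b = 1, c = 10, e = 11)))
#' labels <- c(a = 1, b = 1, c = 2, e = 2)
#' silhouetteWidths(labels, d)$overallMean   # ~0.9048
#' @export
silhouetteWidths <- function(labels, d) {
    if (length(unique(labels)) < 2)
        stop("silhouette requires at least 2 clusters")
    genes <- names(labels)
    if (is.null(genes)) stop("labels must be named by gene id")
    d <- d[genes, genes, drop = FALSE]
    ks <- sort(unique(labels))
    idxByCluster <- lapply(ks, function(k) which(labels == k))
    names(idxByCluster) <- ks
    widths <- vapply(seq_along(genes), function(i) {
        own <- idxByCluster[[as.character(labels[i])]]
        if (length(own) == 1) return(0)           # singleton convention
        a <- mean(d[i, setdiff(own, i)])
        b <- min(vapply(ks[ks != labels[i]], function(k) {
            mean(d[i, idxByCluster[[as.character(k)]]])
        }, numeric(1)))
        if (max(a, b) == 0) return(0)
        (b - a) / max(a, b)
    }, numeric(1))
    names(widths) <- genes
    clusterMeans <- vapply(ks, function(k) mean(widths[labels == k]),
                           numeric(1))
    names(clusterMeans) <- ks
    list(widths = widths, clusterMeans = clusterMeans,
         overallMean = mean(widths))
}

#' Select clustering algorithm and cluster number by silhouette
#'
#' Evaluates every (algorithm, k) candidate over the dissimilarity and
#' picks the one with the highest overall mean silhouette; ties are broken
#' toward smaller k, then PAM before hierarchical clustering.
#'
#' @param d symmetric dissimilarity matrix with gene dimnames.
#' @param kRange candidate cluster counts (default 4:20).
#' @param algorithms subset of `c("pam", "hclust_average")`.
#' @return list with `table` (data.frame: `algorithm`, `k`,
#'   `overall_mean_silhouette`, one row per candidate) and `best` (the
#'   winning [ClusteringResult]).
#' @export
selectClustering <- function(d, kRange = 4:20,
                             algorithms = c("pam", "hclust_average")) {
    if (length(kRange) == 0) stop("empty k range")
    algorithms <- match.arg(algorithms, several.ok = TRUE)
    kRange <- sort(unique(as.integer(kRange)))
    if (any(kRange < 2 | kRange >= nrow(d)))
        stop("every k must satisfy 2 <= k < n")
    fits <- list()
    rows <- list()
    for (alg in algorithms) {
        for (k in kRange) {
            fit <- if (alg == "pam") clusterPAM(d, k)
                   else clusterHclustAverage(d, k)
            key <- paste(alg, k)
            fits[[key]] <- fit
            rows[[key]] <- data.frame(algorithm = alg, k = k,
                                      overall_mean_silhouette =
                                          fit@overallMean)
        }
    }
    tab <- do.call(rbind, rows)
    rownames(tab) <- NULL
    # best: max silhouette, ties -> smaller k, then pam first
    algPref <- match(tab$algorithm, c("pam", "hclust_average"))
    ord <- order(-tab$overall_mean_silhouette, tab$k, algPref)
    bestRow <- tab[ord[1], ]
    list(table = tab,
         best = fits[[paste(bestRow$algorithm, bestRow$k)]])
}
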
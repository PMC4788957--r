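#' @import methods
#' @importFrom stats cor lm sd phyper wilcox.test p.adjust hclust cutree
#'   as.dist rnorm runif quantile median setNames
#' @importFrom utils read.delim write.table head
NULL

#' CorrelationMatrix: pairwise Pearson correlations between gene profiles
#'
#' Symmetric genes x genes matrix of Pearson correlation coefficients with
#' unit diagonal. Genes whose expression profile has zero variance (for which
#' Pearson correlation is undefined) are dropped from the matrix and recorded
#' in `excluded`.
#'
#' @slot r symmetric numeric matrix with gene ids as dimnames, values in
#'   \[-1, 1\], diagonal exactly 1.
#' @slot excluded character vector of gene ids removed for zero variance.
#'
#' @exportClass CorrelationMatrix
setClass("CorrelationMatrix",
         representation(r = "matrix", excluded = "character"))

setValidity("CorrelationMatrix", function(object) {
    r <- object@r
    if (!is.numeric(r)) return("r must be numeric")
    if (nrow(r) != ncol(r)) return("r must be square")
    if (is.null(rownames(r)) || !identical(rownames(r), colnames(r)))
        return("r must carry identical gene ids as row and column names")
    if (anyDuplicated(rownames(r))) return("duplicate gene ids")
    if (nrow(r) > 0) {
        if (max(abs(r - t(r))) > 1e-12) return("r must be symmetric (1e-12)")
        if (any(diag(r) != 1)) return("diagonal must be exactly 1")
        if (max(abs(r)) > 1 + 1e-12) return("|r| must not exceed 1")
    }
    TRUE
})

#' ThresholdScan: scale-free fit and density along a threshold grid
#'
#' One row per candidate absolute-correlation threshold, recording the node
#' and edge counts of the thresholded network (isolated genes dropped), its
#' mean degree, and the scale-free model fit (R-squared of the log-log degree
#' distribution regression, and the estimated power-law exponent lambda).
#' Undefined fits (fewer than 3 distinct degrees) are `NA`.
#'
#' @slot scan data.frame with columns `threshold`, `n_nodes`, `n_edges`,
#'   `mean_degree`, `r_squared`, `lambda`.
#'
#' @exportClass ThresholdScan
setClass("ThresholdScan", representation(scan = "data.frame"))

setValidity("ThresholdScan", function(object) {
    need <- c("threshold", "n_nodes", "n_edges", "mean_degree",
              "r_squared", "lambda")
    if (!all(need %in% names(object@scan)))
        return(paste("scan must have columns:", paste(need, collapse = ", ")))
    s <- object@scan
    if (is.unsorted(s$threshold, strictly = TRUE))
        return("thresholds must be strictly increasing")
    if (any(diff(s$n_edges) > 0))
        return("n_edges must be non-increasing in threshold")
    ok <- !is.na(s$r_squared)
    if (any(s$r_squared[ok] < -1e-12 | s$r_squared[ok] > 1 + 1e-12))
        return("defined r_squared values must lie in [0, 1]")
    TRUE
})

#' CoexpressionNetwork: a signed, weighted gene co-expression network
#'
#' Undirected graph in which nodes are genes and an edge joins two genes whose
#' expression profiles exceed an absolute Pearson correlation threshold. Each
#' edge carries the correlation magnitude as `weight` and the correlation
#' sign (+1/-1) as `sign`. Genes left isolated by the cut-off are not part of
#' the node set.
#'
#' @slot nodes character vector of gene ids (unique).
#' @slot edges data.frame with columns `from`, `to` (gene ids), `weight`
#'   (numeric, > threshold) and `sign` (integer, +1 or -1); one row per
#'   unordered pair, canonically ordered.
#' @slot threshold numeric scalar, the absolute-correlation cut-off.
#'
#' @exportClass CoexpressionNetwork
setClass("CoexpressionNetwork",
         representation(nodes = "character", edges = "data.frame",
                        threshold = "numeric"))

setValidity("CoexpressionNetwork", function(object) {
    nd <- object@nodes
    ed <- object@edges
    if (anyDuplicated(nd)) return("duplicate node ids")
    need <- c("from", "to", "weight", "sign")
    if (!all(need %in% names(ed)))
        return(paste("edges must have columns:", paste(need, collapse = ", ")))
    if (nrow(ed) > 0) {
        if (!all(ed$from %in% nd) || !all(ed$to %in% nd))
            return("edge endpoints must be nodes")
        if (any(ed$from == ed$to)) return("self-edges are not allowed")
        key <- paste(pmin(ed$from, ed$to), pmax(ed$from, ed$to))
        if (anyDuplicated(key)) return("duplicate edges")
        if (length(object@threshold) == 1 &&
            any(ed$weight <= object@threshold))
            return("every edge weight must exceed the threshold")
        if (!all(ed$sign %in% c(-1L, 1L))) return("edge sign must be +1 or -1")
        deg <- table(factor(c(ed$from, ed$to), levels = nd))
        if (any(deg == 0))
            return("isolated nodes are not part of a co-expression network")
    }
    TRUE
})

#' ClusteringResult: a gene partition with silhouette diagnostics
#'
#' Result of PAM or average-linkage hierarchical clustering over the
#' 1 - |r| dissimilarity, together with per-gene silhouette widths s(i),
#' per-cluster mean silhouettes and the overall mean silhouette used for
#' model selection.
#'
#' @slot algorithm character, `"pam"` or `"hclust_average"`.
#' @slot k integer, number of clusters.
#' @slot labels named integer vector mapping gene id to cluster index 1..k.
#' @slot medoids character vector of medoid gene ids (PAM only; empty for
#'   hierarchical clustering).
#' @slot silWidths named numeric vector of per-gene silhouette widths.
#' @slot clusterMeans numeric vector of per-cluster mean silhouettes, named
#'   by cluster index.
#' @slot overallMean numeric scalar, mean of `silWidths`.
#'
#' @exportClass ClusteringResult
setClass("ClusteringResult",
         representation(algorithm = "character", k = "integer",
                        labels = "integer", medoids = "character",
                        silWidths = "numeric", clusterMeans = "numeric",
                        overallMean = "numeric"))

setValidity("ClusteringResult", function(object) {
    if (!object@algorithm %in% c("pam", "hclust_average"))
        return("algorithm must be 'pam' or 'hclust_average'")
    lb <- object@labels
    if (is.null(names(lb))) return("labels must be named by gene id")
    if (!setequal(unique(lb), seq_len(object@k)))
        return("every cluster 1..k must be non-empty")
    if (!identical(names(lb), names(object@silWidths)))
        return("labels and silWidths must cover the same genes")
    if (any(object@silWidths < -1 - 1e-12 | object@silWidths > 1 + 1e-12))
        return("silhouette widths must lie in [-1, 1]")
    if (abs(object@overallMean - mean(object@silWidths)) > 1e-8)
        return("overallMean must equal mean(silWidths)")
    TRUE
})

#' BlockDesign: parameters of the planted-block expression generator
#'
#' Describes a synthetic genes x samples study: `nBlocks` co-expressed gene
#' modules of sizes `genesPerBlock` sharing a latent sample profile, plus
#' `nBackground` independent noise genes, observed over `nSamples` samples.
#' `withinCorr` is the target absolute pairwise correlation inside a block
#' (on the log scale); `antiFraction` of each block's genes receive a
#' sign-flipped loading so they anticorrelate with the rest of the block;
#' `noiseSd` is the per-gene Gaussian noise standard deviation (derived from
#' `withinCorr` when `NA`).
#'
#' @slot nBlocks integer.
#' @slot genesPerBlock integer vector of length `nBlocks`.
#' @slot nBackground integer.
#' @slot nSamples integer, at least 4.
#' @slot withinCorr numeric in (0, 1).
#' @slot antiFraction numeric in \[0, 1\].
#' @slot noiseSd numeric (NA to derive from `withinCorr`).
#' @slot seed integer.
#'
#' @exportClass BlockDesign
setClass("BlockDesign",
         representation(nBlocks = "integer", genesPerBlock = "integer",
                        nBackground = "integer", nSamples = "integer",
                        withinCorr = "numeric", antiFraction = "numeric",
                        noiseSd = "numeric", seed = "integer"))

setValidity("BlockDesign", function(object) {
    if (object@nBlocks < 1) return("nBlocks must be positive")
    if (length(object@genesPerBlock) != object@nBlocks)
        return("genesPerBlock must have one entry per block")
    if (any(object@genesPerBlock < 1))
        return("genesPerBlock entries must be positive")
    if (object@nBackground < 0) return("nBackground must be non-negative")
    if (object@nSamples < 4) return("nSamples must be at least 4")
    if (object@withinCorr <= 0 || object@withinCorr >= 1)
        return("withinCorr must lie strictly between 0 and 1")
    if (object@antiFraction < 0 || object@antiFraction > 1)
        return("antiFraction must lie in [0, 1]")
    if (!is.na(object@noiseSd) && object@noiseSd <= 0)
        return("noiseSd must be positive")
    TRUE
})

#' NullEnsemble: a simulated null distribution of a topology statistic
#'
#' Holds `nReplicates` values of one topology statistic evaluated on random
#' graphs with matched node and edge counts, drawn from the Erdos-Renyi
#' G(n, m) model or grown under Barabasi-Albert preferential attachment.
#'
#' @slot model character, `"erdos_renyi"` or `"barabasi_albert"`.
#' @slot statistic character, name of the statistic.
#' @slot samples numeric vector of length `nReplicates`.
#' @slot nNodes,nEdges integer, matched network size.
#' @slot seed integer used to seed the ensemble.
#'
#' @exportClass NullEnsemble
setClass("NullEnsemble",
         representation(model = "character", statistic = "character",
                        samples = "numeric", nNodes = "integer",
                        nEdges = "integer", seed = "integer"))

setValidity("NullEnsemble", function(object) {
    if (!object@model %in% c("erdos_renyi", "barabasi_albert"))
        return("model must be 'erdos_renyi' or 'barabasi_albert'")
    if (length(object@samples) < 1) return("ensemble must not be empty")
    TRUE
})

## -- show methods ----------------------------------------------------------

setMethod("show", "CorrelationMatrix", function(object) {
    cat(sprintf("CorrelationMatrix: %d genes", nrow(object@r)))
    if (length(object@excluded))
        cat(sprintf(" (%d excluded for zero variance)",
                    length(object@excluded)))
    cat("\n")
})

setMethod("show", "ThresholdScan", function(object) {
    s <- object@scan
    cat(sprintf("ThresholdScan: %d thresholds in [%.2f, %.2f]\n",
                nrow(s), min(s$threshold), max(s$threshold)))
    ok <- which(!is.na(s$r_squared) & s$n_nodes > 0)
    if (length(ok)) {
        b <- ok[which.max(s$r_squared[ok])]
        cat(sprintf("  best scale-free fit: R2 = %.3f at t = %.2f\n",
                    s$r_squared[b], s$threshold[b]))
    }
})

setMethod("show", "CoexpressionNetwork", function(object) {
    cat(sprintf(
        "CoexpressionNetwork: %d genes, %d edges (|r| > %s)\n",
        length(object@nodes), nrow(object@edges),
        if (length(object@threshold)) format(object@threshold) else "?"))
    if (nrow(object@edges) > 0)
        cat(sprintf("  %d positive, %d negative correlations\n",
                    sum(object@edges$sign > 0), sum(object@edges$sign < 0)))
})

setMethod("show", "ClusteringResult", function(object) {
    cat(sprintf("ClusteringResult: %s, k = %d, %d genes\n",
                object@algorithm, object@k, length(object@labels)))
    cat(sprintf("  overall mean silhouette: %.3f\n", object@overallMean))
})

setMethod("show", "BlockDesign", function(object) {
    cat(sprintf(
        "BlockDesign: %d blocks (%s genes) + %d background, %d samples\n",
        object@nBlocks, paste(object@genesPerBlock, collapse = "+"),
        object@nBackground, object@nSamples))
})

setMethod("show", "NullEnsemble", function(object) {
    cat(sprintf("NullEnsemble: %s, %d replicates of %s (n=%d, m=%d)\n",
                object@model, length(object@samples), object@statistic,
                object@nNodes, object@nEdges))
})

## -- accessors -------------------------------------------------------------

#' Accessors for pipeline objects
#'
#' Small accessor family for the package's S4 containers: gene ids, edge
#' tables, thresholds, scan tables, cluster labels and silhouette widths.
#'
#' @param x a `CoexpressionNetwork`, `CorrelationMatrix`, `ThresholdScan` or
#'   `ClusteringResult`.
#' @return the requested component (see each generic).
#' @name accessors
#' @examples
#' net <- fixtureGraph("triangle")
#' networkGenes(net)
#' networkEdges(net)
NULL

#' @describeIn accessors gene ids of a network or correlation matrix.
#' @export
setGeneric("networkGenes", function(x) standardGeneric("networkGenes"))

#' @export
setMethod("networkGenes", "CoexpressionNetwork", function(x) x@nodes)

#' @export
setMethod("networkGenes", "CorrelationMatrix", function(x) rownames(x@r))

#' @describeIn accessors edge table (`from`, `to`, `weight`, `sign`).
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' @export
setMethod("networkEdges", "CoexpressionNetwork", function(x) x@edges)

#' @describeIn accessors the absolute-correlation threshold of a network.
#' @export
setGeneric("networkThreshold", function(x) standardGeneric("networkThreshold"))

#' @export
setMethod("networkThreshold", "CoexpressionNetwork", function(x) x@threshold)

#' @describeIn accessors correlation matrix (genes x genes).
#' @export
setGeneric("correlationValues", function(x) standardGeneric("correlationValues"))

#' @export
setMethod("correlationValues", "CorrelationMatrix", function(x) x@r)

#' @describeIn accessors gene ids excluded from a correlation matrix.
#' @export
setGeneric("excludedGenes", function(x) standardGeneric("excludedGenes"))

#' @export
setMethod("excludedGenes", "CorrelationMatrix", function(x) x@excluded)

#' @describeIn accessors the per-threshold scan table.
#' @export
setGeneric("scanTable", function(x) standardGeneric("scanTable"))

#' @export
setMethod("scanTable", "ThresholdScan", function(x) x@scan)

#' @describeIn accessors named cluster labels of a clustering result.
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))

#' @export
setMethod("clusterLabels", "ClusteringResult", function(x) x@labels)

#' @describeIn accessors per-gene silhouette widths s(i).
#' @export
setGeneric("silhouetteValues", function(x) standardGeneric("silhouetteValues"))

#' @export
setMethod("silhouetteValues", "ClusteringResult", function(x) x@silWidths)

#' @describeIn accessors overall mean silhouette of a clustering.
#' @export
setGeneric("overallSilhouette", function(x) standardGeneric("overallSilhouette"))

#' @export
setMethod("overallSilhouette", "ClusteringResult", function(x) x@overallMean)

#' @describeIn accessors samples of a null ensemble.
#' @export
setGeneric("ensembleSamples", function(x) standardGeneric("ensembleSamples"))

#' @export
setMethod("ensembleSamples", "NullEnsemble", function(x) x@samples)
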
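## From expression to a signed, weighted co-expression network: DE
## prefiltering, Pearson correlation, the scale-free/density threshold scan
## and hard-threshold network construction.

#' Select differentially expressed genes
#'
#' A gene is retained iff its smallest adjusted p-value across the
#' condition-vs-control comparisons is strictly below `alpha`. Genes with no
#' tested comparison (all `NA`) are dropped.
#'
#' @param pvals numeric matrix of adjusted p-values (genes x comparisons),
#'   as returned by [readDEPvalues()].
#' @param alpha significance cut-off in (0, 1); default 0.05.
#' @return character vector of retained gene ids, in input order.
#' @examples
#' p <- rbind(g1 = c(0.20, 0.04), g2 = c(0.05, 0.06))
#' colnames(p) <- c("c1", "c2")
#' selectDEGenes(p)   # "g1": 0.04 < 0.05; g2 fails the strict inequality
#' @export
selectDEGenes <- function(pvals, alpha = 0.05) {
    if (!is.matrix(pvals) || nrow(pvals) == 0 || ncol(pvals) == 0)
        stop("empty p-value table")
    if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
    minp <- apply(pvals, 1, function(x) {
        if (all(is.na(x))) NA_real_ else min(x, na.rm = TRUE)
    })
    rownames(pvals)[!is.na(minp) & minp < alpha]
}

#' Compute the gene-gene Pearson correlation matrix
#'
#' Standard Pearson correlation between gene expression profiles across
#' samples. By default FPKM-like values are log2(v+1)-transformed first
#' (skipped automatically when the input assay is already on the log scale).
#' Genes with zero variance, for which the correlation is undefined, are
#' excluded and reported via [excludedGenes()].
#'
#' @param expr a `SummarizedExperiment` (first assay used) or numeric
#'   genes x samples matrix with at least 3 samples and 2 genes.
#' @param log2Transform apply log2(v + 1) before correlating (default TRUE
#'   for raw input; never reapplied to an assay read with
#'   `log2Transform = TRUE`).
#' @return a [CorrelationMatrix].
#' @examples
#' se <- simulateBlockExpression(blockDesign(nBlocks = 2, genesPerBlock = 5,
#'                                           nSamples = 8, seed = 1))
#' computeCorrelation(se)
#' @export
computeCorrelation <- function(expr, log2Transform = TRUE) {
    if (is(expr, "SummarizedExperiment")) {
        already <- isTRUE(S4Vectors::metadata(expr)$log2)
        m <- SummarizedExperiment::assay(expr, 1)
        if (already) log2Transform <- FALSE
    } else {
        m <- expr
    }
    stopifnot(is.matrix(m))
    if (ncol(m) < 3) stop("at least 3 samples are required for correlation")
    if (nrow(m) < 2) stop("at least 2 genes are required")
    if (is.null(rownames(m))) stop("gene ids (rownames) are required")
    if (log2Transform) m <- log2(m + 1)
    v <- apply(m, 1, stats::sd)
    excluded <- rownames(m)[v == 0]
    if (length(excluded) > 0)
        message(length(excluded), " zero-variance gene(s) excluded")
    m <- m[v > 0, , drop = FALSE]
    if (nrow(m) < 2) stop("fewer than 2 genes with non-zero variance")
    r <- stats::cor(t(m))
    r <- (r + t(r)) / 2
    r[r > 1] <- 1
    r[r < -1] <- -1
    diag(r) <- 1
    new("CorrelationMatrix", r = r, excluded = excluded)
}

#' Scale-free model fit of a degree sequence
#'
#' Estimates how well a degree sequence follows the power law
#' P(k) ~ k^-lambda: P(k) is the fraction of nodes with degree exactly k
#' (observed k >= 1, raw frequencies, no binning), and an ordinary
#' least-squares line is fitted to log10 P(k) versus log10 k. Returns the
#' R-squared of that fit and lambda = -slope. At least 3 distinct positive
#' degrees are required for the regression to be defined.
#'
#' @param degrees integer vector of node degrees (>= 1).
#' @return list with elements `r.squared` and `lambda`.
#' @examples
#' # exact power law P(k) = c * k^-2 sampled at k in {1,2,4,8}
#' deg <- rep(c(1, 2, 4, 8), c(64, 16, 4, 1))
#' scaleFreeFit(deg)   # r.squared = 1, lambda = 2
#' @export
scaleFreeFit <- function(degrees) {
    degrees <- degrees[degrees >= 1]
    if (length(degrees) == 0) stop("no positive degrees")
    tab <- table(degrees)
    if (length(tab) < 3)
        stop("scale-free fit undefined: fewer than 3 distinct degrees")
    k <- as.numeric(names(tab))
    pk <- as.numeric(tab) / length(degrees)
    fit <- stats::lm(log10(pk) ~ log10(k))
    list(r.squared = suppressWarnings(summary(fit))$r.squared,
         lambda = -unname(stats::coef(fit)[2]))
}

# Degrees of the |r| > t graph; isolated genes get 0.
.thresholdDegrees <- function(r, t) {
    a <- abs(r) > t
    diag(a) <- FALSE
    colSums(a)
}

# mean degree over ALL input genes (fixed denominator): with the
# denominator held fixed this density measure is guaranteed non-increasing
# in t, which the per-network 2E/N ratio (shrinking N) is not.

#' Scan correlation thresholds for scale-free fit and density
#'
#' For every threshold t of the grid, builds the edge set {|r| > t}, drops
#' isolated genes, and records node/edge counts, the mean degree, and the
#' scale-free fit R-squared and lambda (NA where undefined). The mean
#' degree (the density criterion) is computed over all input genes — with
#' a fixed denominator it is guaranteed to decrease as the cut-off rises,
#' whereas the within-network ratio 2E/N can fluctuate as isolated genes
#' drop out. Threshold selection trades the scale-free fit against this
#' density: the fit typically rises with t and then degrades once the
#' cut-off is so strict that the network deteriorates.
#'
#' @param corr a [CorrelationMatrix].
#' @param grid thresholds in (0, 1); default `seq(0.50, 0.99, by = 0.01)`.
#' @return a [ThresholdScan].
#' @export
scanThresholds <- function(corr, grid = seq(0.50, 0.99, by = 0.01)) {
    stopifnot(is(corr, "CorrelationMatrix"))
    if (length(grid) == 0) stop("empty threshold grid")
    if (any(grid <= 0 | grid >= 1)) stop("thresholds must lie in (0, 1)")
    grid <- sort(grid)
    r <- corr@r
    nGenes <- nrow(r)
    rows <- lapply(grid, function(t) {
        deg <- .thresholdDegrees(r, t)
        deg <- deg[deg > 0]
        nN <- length(deg)
        nE <- sum(deg) / 2
        fit <- tryCatch(scaleFreeFit(deg),
                        error = function(e) list(r.squared = NA_real_,
                                                 lambda = NA_real_))
        data.frame(threshold = t, n_nodes = nN, n_edges = nE,
                   mean_degree = 2 * nE / nGenes,
                   r_squared = fit$r.squared, lambda = fit$lambda)
    })
    new("ThresholdScan", scan = do.call(rbind, rows))
}

#' Select the correlation threshold from a scan
#'
#' Returns the threshold maximizing the scale-free fit R-squared among rows
#' with a non-empty network; ties are broken toward the smaller threshold
#' (the denser network, honouring the density criterion).
#'
#' @param scan a [ThresholdScan].
#' @return numeric threshold.
#' @examples
#' sc <- new("ThresholdScan", scan = data.frame(
#'   threshold = c(0.80, 0.90, 0.95), n_nodes = c(50, 40, 20),
#'   n_edges = c(400, 150, 30), mean_degree = c(16, 7.5, 3),
#'   r_squared = c(0.70, 0.86, 0.60), lambda = c(1.5, 2.1, 2.4)))
#' selectThreshold(sc)   # 0.9
#' @export
selectThreshold <- function(scan) {
    stopifnot(is(scan, "ThresholdScan"))
    s <- scan@scan
    ok <- !is.na(s$r_squared) & s$n_nodes > 0
    if (!any(ok)) stop("no threshold with a defined scale-free fit")
    s <- s[ok, , drop = FALSE]
    best <- which(s$r_squared == max(s$r_squared))
    s$threshold[best[which.min(s$threshold[best])]]
}

#' Build the co-expression network at a threshold
#'
#' Creates an edge for every gene pair with |r| strictly greater than `t`,
#' weighted by |r| and signed by the sign of r. Genes left without any edge
#' are excluded from the node set.
#'
#' @param corr a [CorrelationMatrix].
#' @param t absolute-correlation threshold in (0, 1).
#' @return a [CoexpressionNetwork].
#' @export
buildNetwork <- function(corr, t) {
    stopifnot(is(corr, "CorrelationMatrix"))
    if (t <= 0 || t >= 1) stop("threshold must lie in (0, 1)")
    r <- corr@r
    genes <- rownames(r)
    hit <- which(abs(r) > t & upper.tri(r), arr.ind = TRUE)
    edges <- data.frame(from = genes[hit[, 1]], to = genes[hit[, 2]],
                        weight = abs(r[hit]),
                        sign = ifelse(r[hit] >= 0, 1L, -1L),
                        stringsAsFactors = FALSE)
    nodes <- genes[genes %in% c(edges$from, edges$to)]
    .newNetwork(nodes, edges, t)
}
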
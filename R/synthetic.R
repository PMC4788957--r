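## Seeded generators: planted-block expression matrices with known ground
## truth, and small deterministic fixture graphs. These stand in for a real
## multi-study expression compendium so that every downstream stage
## (thresholding, topology, clustering, enrichment, validation) can be
## exercised against a known answer.

#' Construct a planted-block study design
#'
#' @param nBlocks number of co-expressed gene modules.
#' @param genesPerBlock integer vector (recycled to `nBlocks`) of module
#'   sizes.
#' @param nBackground number of independent background genes.
#' @param nSamples number of samples (>= 4).
#' @param withinCorr target absolute pairwise Pearson correlation between
#'   genes of the same block, on the log scale (0 < withinCorr < 1).
#' @param antiFraction fraction of each block's genes given a sign-flipped
#'   loading (they anticorrelate with the rest of the block).
#' @param noiseSd per-gene Gaussian noise sd; `NA` (default) derives it from
#'   `withinCorr` as sqrt(1/withinCorr - 1), which makes the expected
#'   within-block correlation equal withinCorr.
#' @param seed integer seed; identical seeds give bit-identical output.
#' @return a [BlockDesign].
#' @examples
#' blockDesign(nBlocks = 3, genesPerBlock = 50, nSamples = 24, seed = 7)
#' @export
blockDesign <- function(nBlocks = 3, genesPerBlock = 50, nBackground = 0,
                        nSamples = 24, withinCorr = 0.9, antiFraction = 0,
                        noiseSd = NA_real_, seed = 1) {
    new("BlockDesign",
        nBlocks = as.integer(nBlocks),
        genesPerBlock = rep_len(as.integer(genesPerBlock),
                                as.integer(nBlocks)),
        nBackground = as.integer(nBackground),
        nSamples = as.integer(nSamples),
        withinCorr = as.numeric(withinCorr),
        antiFraction = as.numeric(antiFraction),
        noiseSd = as.numeric(noiseSd),
        seed = as.integer(seed))
}

#' Generate a planted-block expression matrix
#'
#' Each block b has a latent standard-Gaussian sample profile; a member gene
#' g is alpha_g * latent_b + eps with eps ~ Normal(0, noiseSd) and alpha_g
#' sign-flipped for the `antiFraction` subset of the block. Background genes
#' are independent noise. Latent-scale values are exponentiated (base 2,
#' around a typical log2-FPKM level) so the returned matrix holds
#' non-negative FPKM-like abundances with lognormal marginals, floored at
#' 0.01; the log2(v+1) transform used before correlation therefore recovers
#' the planted structure. One seeded random stream is used per call and the
#' caller's RNG state is left untouched.
#'
#' @param design a [BlockDesign].
#' @return a `SummarizedExperiment` with assay `"fpkm"`; the planted block
#'   of each gene (0 = background) is in `rowData(se)$block` and as the
#'   attribute-free ground-truth labels in `metadata(se)$trueLabels`.
#' @examples
#' se <- simulateBlockExpression(blockDesign(seed = 7))
#' table(SummarizedExperiment::rowData(se)$block)
#' @export
simulateBlockExpression <- function(design) {
    stopifnot(is(design, "BlockDesign"))
    validObject(design)
    d <- design
    if (d@nSamples < 4) stop("at least 4 samples are required")
    sdNoise <- if (is.na(d@noiseSd)) sqrt(1 / d@withinCorr - 1) else d@noiseSd
    nGenes <- sum(d@genesPerBlock) + d@nBackground
    .withSeed(d@seed, {
        z <- matrix(0, nrow = nGenes, ncol = d@nSamples)
        labels <- integer(nGenes)
        # latent block profiles: centred and mutually orthogonalized so
        # between-block gene correlations are noise-driven, not inherited
        # from one chance correlation between latent draws
        L <- matrix(rnorm(d@nSamples * d@nBlocks), nrow = d@nSamples)
        L <- scale(L, center = TRUE, scale = FALSE)
        Q <- qr.Q(qr(L))[, seq_len(d@nBlocks), drop = FALSE]
        Q <- Q * sqrt(d@nSamples - 1)   # unit sample variance
        row <- 1L
        for (b in seq_len(d@nBlocks)) {
            latent <- Q[, b]
            nb <- d@genesPerBlock[b]
            nAnti <- floor(d@antiFraction * nb)
            for (gi in seq_len(nb)) {
                alpha <- runif(1, 0.8, 1.2)
                if (gi <= nAnti) alpha <- -alpha
                z[row, ] <- alpha * latent + rnorm(d@nSamples, sd = sdNoise)
                labels[row] <- b
                row <- row + 1L
            }
        }
        if (d@nBackground > 0) {
            z[row:nGenes, ] <- rnorm(d@nBackground * d@nSamples,
                                     sd = sqrt(1 + sdNoise^2))
            labels[row:nGenes] <- 0L
        }
        # lognormal FPKM-like marginals around ~2^5 FPKM, floored at 0.01
        fpkm <- pmax(2^(1.5 * z + 5), 0.01)
        genes <- sprintf("g%04d", seq_len(nGenes))
        dimnames(fpkm) <- list(genes,
                               sprintf("s%02d", seq_len(d@nSamples)))
        names(labels) <- genes
        se <- SummarizedExperiment::SummarizedExperiment(
            assays = list(fpkm = fpkm),
            rowData = S4Vectors::DataFrame(block = labels))
        S4Vectors::metadata(se)$trueLabels <- labels
        S4Vectors::metadata(se)$design <- d
        se
    })
}

#' Deterministic fixture graphs
#'
#' Small named graphs with unit edge weights and positive signs, used as
#' ground-truth fixtures: `star_k(n)` (one center, n leaves), `triangle`,
#' `path(n)`, `complete(n)`, and `planted_partition` (stochastic block
#' model with dense blocks and sparse inter-block edges; seeded).
#'
#' @param name one of `"star_k"`, `"triangle"`, `"path"`, `"complete"`,
#'   `"planted_partition"`.
#' @param n total number of nodes (`star_k(n)` has one center and n-1
#'   leaves); ignored for `triangle`.
#' @param blocks,blockSize,pIn,pOut,seed parameters of
#'   `planted_partition`: number of blocks, genes per block, within- and
#'   between-block edge probabilities, and the seed.
#' @return a [CoexpressionNetwork] with threshold 0.
#' @examples
#' fixtureGraph("star_k", n = 4)
#' fixtureGraph("path", n = 3)
#' @export
fixtureGraph <- function(name, n = 4, blocks = 3, blockSize = 10,
                         pIn = 0.9, pOut = 0.05, seed = 1) {
    edgesOf <- function(pairs, nodes) {
        data.frame(from = nodes[pairs[, 1]], to = nodes[pairs[, 2]],
                   weight = 1, sign = 1L, stringsAsFactors = FALSE)
    }
    if (name == "star_k") {
        if (n < 2) stop("star_k needs n >= 2")
        nodes <- c("center", sprintf("leaf%d", seq_len(n - 1)))
        pairs <- cbind(1L, 1L + seq_len(n - 1))
        return(.newNetwork(nodes, edgesOf(pairs, nodes), 0))
    }
    if (name == "triangle") {
        nodes <- c("a", "b", "c")
        pairs <- rbind(c(1, 2), c(1, 3), c(2, 3))
        return(.newNetwork(nodes, edgesOf(pairs, nodes), 0))
    }
    if (name == "path") {
        if (n < 2) stop("path needs n >= 2")
        nodes <- sprintf("v%d", seq_len(n))
        pairs <- cbind(seq_len(n - 1), seq_len(n - 1) + 1L)
        return(.newNetwork(nodes, edgesOf(pairs, nodes), 0))
    }
    if (name == "complete") {
        if (n < 2) stop("complete needs n >= 2")
        nodes <- sprintf("v%d", seq_len(n))
        pairs <- t(utils::combn(n, 2))
        return(.newNetwork(nodes, edgesOf(pairs, nodes), 0))
    }
    if (name == "planted_partition") {
        nTot <- blocks * blockSize
        lab <- rep(seq_len(blocks), each = blockSize)
        nodes <- sprintf("v%02d", seq_len(nTot))
        pairs <- .withSeed(seed, {
            all <- t(utils::combn(nTot, 2))
            p <- ifelse(lab[all[, 1]] == lab[all[, 2]], pIn, pOut)
            all[runif(nrow(all)) < p, , drop = FALSE]
        })
        net <- .newNetwork(nodes, edgesOf(pairs, nodes), 0)
        # drop any node left isolated by the draw (validity requirement)
        deg <- table(factor(c(net@edges$from, net@edges$to), levels = nodes))
        keep <- names(deg)[deg > 0]
        return(.newNetwork(keep, net@edges, 0))
    }
    stop("unknown fixture graph: ", name)
}
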
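## Cross-validation of network predictions: neighborhood extraction,
## fold-change shift testing, responsive-gene enrichment and correlation
## heatmap matrices. The underlying idea: perturbing a gene (mutation or
## overexpression) should shift the expression of its network neighbourhood,
## while distant genes remain unchanged.

#' Genes within a BFS distance of a focal gene
#'
#' All genes at shortest-path distance <= d from the focal gene. The focal
#' gene itself is excluded for d >= 1; d = 0 returns just the focal gene.
#'
#' @param net a [CoexpressionNetwork].
#' @param gene focal gene id (must be in the network).
#' @param d distance, one of 0, 1, 2, 3.
#' @return character vector of gene ids.
#' @examples
#' neighborhoodAtDistance(fixtureGraph("star_k", 4), "center", 1)
#' @export
neighborhoodAtDistance <- function(net, gene, d) {
    if (!gene %in% net@nodes) stop("gene not in network: ", gene)
    if (!d %in% 0:3) stop("d must be one of 0, 1, 2, 3")
    if (d == 0) return(gene)
    g <- .asIgraph(net)
    dist <- igraph::distances(g, v = gene, weights = NA)[1, ]
    members <- net@nodes[dist <= d]
    setdiff(members, gene)
}

#' Fold-change shift test for a neighbourhood
#'
#' Tests whether the fold changes of a member set (typically a perturbed
#' gene's distance-2 neighbourhood) are stochastically greater than those
#' of the remaining network genes, with a one-sided Mann-Whitney U test:
#' exact enumeration when both groups have at most 12 untied observations,
#' normal approximation with tie correction otherwise. Also reports the
#' mean fold change inside and outside the member set and the percentage
#' of members whose expression increased (ratio > 1, or log2 > 0 when the
#' fold changes carry `logScale = TRUE`).
#'
#' @param members character vector of member gene ids.
#' @param foldChanges named numeric vector (see [readFoldChanges()]).
#' @param networkGenes character vector delimiting the universe; non-member
#'   network genes form the comparison group.
#' @param method `"wilcox"` (default) or `"t"` (Welch's t on log2 fold
#'   changes, for users preferring a parametric test).
#' @return list with `n_members`, `mean_fc_in`, `mean_fc_out`,
#'   `fraction_increased` (percent) and `shift_p`.
#' @export
foldChangeShiftTest <- function(members, foldChanges, networkGenes,
                                method = c("wilcox", "t")) {
    method <- match.arg(method)
    logScale <- isTRUE(attr(foldChanges, "logScale"))
    members <- intersect(members, networkGenes)
    others <- setdiff(networkGenes, members)
    x <- foldChanges[intersect(members, names(foldChanges))]
    y <- foldChanges[intersect(others, names(foldChanges))]
    if (length(x) < 3 || length(y) < 3)
        stop("members and non-members each need >= 3 fold changes")
    neutral <- if (logScale) 0 else 1
    p <- if (length(unique(c(x, y))) == 1) {
        1   # all values identical: no evidence of any shift
    } else if (method == "t") {
        lx <- if (logScale) x else log2(x)
        ly <- if (logScale) y else log2(y)
        stats::t.test(lx, ly, alternative = "greater")$p.value
    } else {
        exact <- length(x) <= 12 && length(y) <= 12 &&
            !any(duplicated(c(x, y)))
        suppressWarnings(
            stats::wilcox.test(x, y, alternative = "greater",
                               exact = exact)$p.value)
    }
    list(n_members = length(x),
         mean_fc_in = mean(x),
         mean_fc_out = mean(y),
         fraction_increased = 100 * mean(x > neutral),
         shift_p = p)
}

#' Enrichment of strongly responsive genes in a target set
#'
#' Tests whether genes responding to a perturbation by at least
#' `fcCutoff`-fold are over-represented in a target gene set (a
#' neighbourhood or a cluster) relative to the rest of the network, by a
#' one-sided Fisher's exact test. The cut-off is inclusive (a gene at
#' exactly the cut-off counts as responsive); for `direction = "down"`,
#' responders satisfy fold change <= 1/`fcCutoff` (ratio scale).
#'
#' @param targetSet character vector of target gene ids (non-empty).
#' @param networkGenes universe of network gene ids.
#' @param foldChanges named numeric ratio-scale fold changes (used to
#'   derive the responder set when `responsive` is not given).
#' @param responsive optional character vector of responder ids supplied
#'   directly.
#' @param fcCutoff responder threshold, default 4.
#' @param direction `"up"` or `"down"`.
#' @return list with the 2x2 `counts` (a, b, c, d) and `p_value`.
#' @export
responsiveSetEnrichment <- function(targetSet, networkGenes,
                                    foldChanges = NULL, responsive = NULL,
                                    fcCutoff = 4,
                                    direction = c("up", "down")) {
    direction <- match.arg(direction)
    targetSet <- intersect(targetSet, networkGenes)
    if (length(targetSet) == 0) stop("empty target set")
    if (is.null(responsive)) {
        if (is.null(foldChanges))
            stop("supply foldChanges or an explicit responsive set")
        fc <- foldChanges[intersect(networkGenes, names(foldChanges))]
        responsive <- if (direction == "up") names(fc)[fc >= fcCutoff]
                      else names(fc)[fc <= 1 / fcCutoff]
    }
    responsive <- intersect(responsive, networkGenes)
    a <- length(intersect(targetSet, responsive))
    b <- length(targetSet) - a
    c <- length(responsive) - a
    d <- length(networkGenes) - length(targetSet) - c
    list(counts = c(a = a, b = b, c = c, d = d),
         p_value = fisherExactGreater(a, b, c, d))
}

#' Correlation heatmap matrix for a gene set
#'
#' Extracts the correlation submatrix of a gene set, optionally expanded by
#' the union of the genes' network neighbourhoods up to distance
#' `expandDistance`, with rows and columns ordered by the leaf order of an
#' average-linkage tree on 1 - |r| so co-expressed groups appear as blocks.
#'
#' @param genes character vector of gene ids of interest.
#' @param corr a [CorrelationMatrix].
#' @param net optional [CoexpressionNetwork] used for the expansion.
#' @param expandDistance 0 (no expansion), 1, 2 or 3.
#' @return ordered symmetric correlation submatrix.
#' @export
correlationHeatmapMatrix <- function(genes, corr, net = NULL,
                                     expandDistance = 0) {
    stopifnot(is(corr, "CorrelationMatrix"))
    if (!expandDistance %in% 0:3) stop("expandDistance must be 0..3")
    ids <- rownames(corr@r)
    present <- intersect(genes, ids)
    if (length(present) == 0) stop("none of the genes are in the matrix")
    sel <- present
    if (!is.null(net) && expandDistance > 0) {
        inNet <- intersect(present, net@nodes)
        nb <- unlist(lapply(inNet, function(g)
            neighborhoodAtDistance(net, g, expandDistance)))
        sel <- intersect(ids, union(present, nb))
    }
    sub <- corr@r[sel, sel, drop = FALSE]
    if (length(sel) > 2) {
        tree <- stats::hclust(stats::as.dist(1 - abs(sub)),
                              method = "average")
        sub <- sub[tree$order, tree$order, drop = FALSE]
    }
    sub
}
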
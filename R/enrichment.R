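## One-sided Fisher's exact test enrichment engine, the dual-annotation GO
## combination rule, and TF/TR cluster-membership enrichment.

#' One-sided (over-representation) Fisher's exact test
#'
#' Upper-tail hypergeometric probability for the 2x2 table
#' \[a, b; c, d\]: a study genes with the property, b study genes without,
#' c background-only genes with, d background-only without. The p-value is
#' P(X >= a) for X ~ Hypergeometric(N = a+b+c+d, K = a+c, n = a+b),
#' evaluated through the numerically stable log-space tail of
#' `stats::phyper`.
#'
#' @param a,b,c,d non-negative integer counts.
#' @return p-value in (0, 1\].
#' @examples
#' fisherExactGreater(2, 0, 0, 2)  # 1/6
#' fisherExactGreater(0, 5, 3, 7)  # 1: P(X >= 0)
#' @export
fisherExactGreater <- function(a, b, c, d) {
    counts <- c(a, b, c, d)
    if (any(counts < 0) || any(counts != floor(counts)))
        stop("counts must be non-negative integers")
    min(1, stats::phyper(a - 1, a + c, b + d, a + b, lower.tail = FALSE))
}

#' Term over-representation in a study set
#'
#' One-sided Fisher's exact test per annotation term, comparing the term's
#' frequency in the study set against the full background. Unannotated
#' background genes count as property-absent (the background is the entire
#' gene universe, not just annotated genes). One result row is produced per
#' term annotating at least one study gene.
#'
#' @param study character vector of study gene ids (must be a subset of
#'   `background`).
#' @param background character vector of background gene ids.
#' @param annotation gene -> term-set map from [readAnnotation()] (or any
#'   named list of character vectors).
#' @return data.frame with columns `term`, `a`, `b`, `c`, `d`, `p_value`
#'   and `source`, sorted by p ascending with ties broken by term id.
#' @export
termEnrichment <- function(study, background, annotation) {
    study <- unique(study)
    background <- unique(background)
    if (!all(study %in% background))
        stop("study genes must be a subset of the background")
    src <- attr(annotation, "source")
    if (is.null(src)) src <- NA_character_
    if (length(study) == 0) {
        return(data.frame(term = character(), a = integer(), b = integer(),
                          c = integer(), d = integer(), p_value = numeric(),
                          source = character(), stringsAsFactors = FALSE))
    }
    ann <- annotation[names(annotation) %in% background]
    gene <- rep(names(ann), lengths(ann))
    term <- unlist(ann, use.names = FALSE)
    inStudy <- gene %in% study
    studyTerms <- sort(unique(term[inStudy]))
    nStudy <- length(study)
    nBg <- length(background)
    rows <- lapply(studyTerms, function(tm) {
        withTerm <- unique(gene[term == tm])
        a <- sum(withTerm %in% study)
        b <- nStudy - a
        c <- length(withTerm) - a
        d <- nBg - nStudy - c
        data.frame(term = tm, a = a, b = b, c = c, d = d,
                   p_value = fisherExactGreater(a, b, c, d),
                   source = src, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out <- out[order(out$p_value, out$term), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Combine enrichment results from two annotation sources
#'
#' The sparse annotation of the organism is compensated by running the
#' same enrichment twice, once with ortholog-transferred terms and once
#' with protein-domain-derived terms. A term is called significant when it
#' is found by both approaches (both p < `alpha`) or by only one of them
#' with very high significance (p < `strictCutoff`).
#'
#' @param resOrtholog,resDomain results from [termEnrichment()] for the two
#'   sources (either may lack any given term).
#' @param alpha per-source threshold for the "both approaches" branch
#'   (default 0.05).
#' @param strictCutoff single-source threshold (default 1e-6).
#' @return data.frame with columns `term`, `p_ortholog`, `p_domain`
#'   (NA where the source lacks the term), `significant`, `rule_fired`
#'   (`"both"`, `"single_strict"` or NA).
#' @export
combineDualSource <- function(resOrtholog, resDomain, alpha = 0.05,
                              strictCutoff = 1e-6) {
    po <- stats::setNames(resOrtholog$p_value, resOrtholog$term)
    pd <- stats::setNames(resDomain$p_value, resDomain$term)
    terms <- sort(unique(c(names(po), names(pd))))
    pO <- unname(po[terms])
    pD <- unname(pd[terms])
    both <- !is.na(pO) & !is.na(pD) & pO < alpha & pD < alpha
    strict <- pmin(pO, pD, na.rm = TRUE) < strictCutoff
    rule <- ifelse(both, "both",
                   ifelse(strict, "single_strict", NA_character_))
    data.frame(term = terms, p_ortholog = pO, p_domain = pD,
               significant = both | strict, rule_fired = rule,
               stringsAsFactors = FALSE)
}

#' Enrichment of a marked gene set across clusters
#'
#' Tests each cluster for over-representation of a marked gene set (e.g.
#' transcription factors or transcriptional regulators) among the network
#' genes, by a one-sided Fisher's exact test on the 2x2 table (in-cluster
#' marked / in-cluster unmarked / out-of-cluster marked / out-of-cluster
#' unmarked).
#'
#' @param labels named integer vector (network gene -> cluster index) or a
#'   [ClusteringResult].
#' @param marked character vector of marked gene ids; ids outside the
#'   labelled genes are dropped with a warning.
#' @return data.frame with one row per cluster: `cluster`, `a`, `b`, `c`,
#'   `d`, `p_value`.
#' @export
clusterMembershipEnrichment <- function(labels, marked) {
    if (is(labels, "ClusteringResult")) labels <- clusterLabels(labels)
    if (length(labels) == 0) stop("empty cluster labels")
    genes <- names(labels)
    drop <- setdiff(marked, genes)
    if (length(drop) > 0)
        warning(length(drop), " marked gene(s) not in the network; dropped")
    marked <- intersect(marked, genes)
    nMarked <- length(marked)
    rows <- lapply(sort(unique(labels)), function(k) {
        inCl <- genes[labels == k]
        a <- sum(inCl %in% marked)
        b <- length(inCl) - a
        c <- nMarked - a
        d <- length(genes) - length(inCl) - c
        data.frame(cluster = k, a = a, b = b, c = c, d = d,
                   p_value = fisherExactGreater(a, b, c, d))
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Benjamini-Hochberg adjustment utility
#'
#' Thin wrapper over `stats::p.adjust(p, "BH")`, provided as an optional
#' utility; the enrichment routines report raw Fisher p-values by default.
#'
#' @param p numeric vector of p-values.
#' @return adjusted p-values.
#' @export
bhAdjust <- function(p) stats::p.adjust(p, method = "BH")
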
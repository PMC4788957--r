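## Readers and writers for the tabular and graph artifacts the pipeline
## touches. All tables are tab-separated UTF-8 with a single header line;
## lines starting with '#' are comments. Gene identifiers are opaque,
## case-sensitive strings.

.readTsv <- function(path) {
    utils::read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
                      check.names = FALSE, stringsAsFactors = FALSE,
                      quote = "")
}

#' Read a genes x samples expression matrix
#'
#' Parses a TSV whose header row holds sample ids and whose first column
#' holds gene ids, into a [SummarizedExperiment::SummarizedExperiment] with
#' one assay named `"fpkm"` (or `"log2fpkm"` when `log2Transform = TRUE`,
#' in which case every value v is replaced by log2(v + 1)). Values must be
#' finite and non-negative; duplicate gene or sample ids and missing cells
#' are rejected rather than repaired.
#'
#' @param path TSV file path.
#' @param log2Transform logical; apply log2(v + 1) on read.
#' @return a `SummarizedExperiment` with gene ids as rownames.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("gene\ts1\ts2\ts3", "g1\t1\t2\t3", "g2\t3\t2\t1"), f)
#' se <- readExpression(f)
#' dim(se)
#' @export
readExpression <- function(path, log2Transform = FALSE) {
    tab <- .readTsv(path)
    if (ncol(tab) < 3)
        stop("expression table needs a gene id column and at least 2 samples")
    genes <- as.character(tab[[1]])
    if (anyDuplicated(genes))
        stop("duplicate gene id(s): ",
             paste(unique(genes[duplicated(genes)]), collapse = ", "))
    samples <- colnames(tab)[-1]
    if (anyDuplicated(samples)) stop("duplicate sample id(s)")
    m <- as.matrix(tab[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    if (anyNA(m)) stop("missing values in expression matrix are not allowed")
    if (any(!is.finite(m))) stop("non-finite expression value")
    if (any(m < 0)) stop("negative expression value")
    rownames(m) <- genes
    assayName <- "fpkm"
    if (log2Transform) {
        m <- log2(m + 1)
        assayName <- "log2fpkm"
    }
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = stats::setNames(list(m), assayName))
    S4Vectors::metadata(se)$log2 <- log2Transform
    se
}

#' Write an expression matrix as TSV
#'
#' Inverse of [readExpression()] (for untransformed values): genes as rows,
#' samples as columns, first column `gene`.
#'
#' @param x a `SummarizedExperiment` (first assay is written) or numeric
#'   matrix with gene rownames and sample colnames.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeExpression <- function(x, path) {
    m <- if (is(x, "SummarizedExperiment"))
        SummarizedExperiment::assay(x, 1) else x
    stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
    out <- data.frame(gene = rownames(m), m, check.names = FALSE,
                      stringsAsFactors = FALSE)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read a per-gene, per-comparison adjusted p-value table
#'
#' TSV with gene ids in the first column and one column per condition-vs-
#' control comparison holding multiple-testing-adjusted p-values. Missing
#' cells mean "not tested in that comparison" and are kept as `NA`.
#'
#' @param path TSV file path.
#' @return numeric matrix (genes x comparisons), values in \[0, 1\] or `NA`.
#' @export
readDEPvalues <- function(path) {
    tab <- .readTsv(path)
    if (ncol(tab) < 2)
        stop("p-value table needs a gene id column and >= 1 comparison")
    genes <- as.character(tab[[1]])
    if (anyDuplicated(genes)) stop("duplicate gene id(s) in p-value table")
    m <- as.matrix(tab[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    ok <- is.na(m) | (m >= 0 & m <= 1)
    if (!all(ok)) stop("adjusted p-values must lie in [0, 1]")
    rownames(m) <- genes
    m
}

#' Read a gene-to-term annotation map
#'
#' Two-column TSV (gene id, term id), one pair per line, aggregated into a
#' gene -> term-set map. Duplicate pairs are deduplicated. The `source` tag
#' records which of the two complementary annotation routes produced the map
#' (GO terms transferred from putative orthologs, or GO terms attached to
#' conserved protein domains/families).
#'
#' @param path TSV file path (no header required; a `#` header line is
#'   ignored like any comment).
#' @param source one of `"ortholog"`, `"domain"`.
#' @return named list mapping gene id to a character vector of term ids,
#'   with attribute `source`.
#' @export
readAnnotation <- function(path, source = c("ortholog", "domain")) {
    source <- match.arg(source)
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    if (length(lines) == 0) {
        map <- stats::setNames(list(), character())
        attr(map, "source") <- source
        return(map)
    }
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(parts) != 2)
    if (length(bad))
        stop(sprintf("malformed annotation line %d: expected 2 columns",
                     bad[1]))
    gene <- vapply(parts, `[[`, "", 1)
    term <- vapply(parts, `[[`, "", 2)
    if (any(!nzchar(term))) stop("empty term id in annotation")
    map <- lapply(split(term, gene), function(x) sort(unique(x)))
    attr(map, "source") <- source
    map
}

#' Read a per-gene fold-change table
#'
#' Two-column TSV (`gene`, `fold_change`) with header. Fold changes are on
#' the ratio scale by default (strictly positive; 1 = unchanged); set
#' `logScale = TRUE` for log2 fold changes (0 = unchanged).
#'
#' @param path TSV file path.
#' @param logScale logical flag recording the scale of the values.
#' @return named numeric vector with attribute `logScale`.
#' @export
readFoldChanges <- function(path, logScale = FALSE) {
    tab <- .readTsv(path)
    if (ncol(tab) < 2) stop("fold-change table needs 2 columns")
    genes <- as.character(tab[[1]])
    if (anyDuplicated(genes)) stop("duplicate gene id(s) in fold changes")
    fc <- as.numeric(tab[[2]])
    if (anyNA(fc)) stop("missing fold-change value")
    if (!logScale && any(fc <= 0))
        stop("ratio-scale fold changes must be strictly positive")
    names(fc) <- genes
    attr(fc, "logScale") <- logScale
    fc
}

#' Write / read a cluster assignment table
#'
#' TSV with columns `gene`, `cluster`, `silhouette` — one row per gene of a
#' [ClusteringResult].
#'
#' @param result a `ClusteringResult`.
#' @param path file path.
#' @return `writeClusterTable()` returns `path` invisibly;
#'   `readClusterTable()` a data.frame with the three columns.
#' @export
writeClusterTable <- function(result, path) {
    stopifnot(is(result, "ClusteringResult"))
    out <- data.frame(gene = names(result@labels),
                      cluster = as.integer(result@labels),
                      silhouette = sprintf("%.6f", result@silWidths),
                      stringsAsFactors = FALSE)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @rdname writeClusterTable
#' @export
readClusterTable <- function(path) {
    tab <- .readTsv(path)
    need <- c("gene", "cluster", "silhouette")
    if (!all(need %in% names(tab)))
        stop("cluster table must have columns gene, cluster, silhouette")
    tab$gene <- as.character(tab$gene)
    tab$cluster <- as.integer(tab$cluster)
    tab$silhouette <- as.numeric(tab$silhouette)
    tab
}

## -- GML -------------------------------------------------------------------

.gmlQuote <- function(x) paste0('"', gsub('"', "'", x), '"')

#' Write a co-expression network in GML format
#'
#' Serializes a [CoexpressionNetwork] to GML with node attributes `label`
#' (gene id), `degree` and, when `clusters` is supplied, `cluster`; edge
#' attributes are `weight` (the |r| of the pair, written with 6 decimals)
#' and `sign` (+1 for positive, -1 for negative correlation). The graph
#' record carries the correlation `threshold`. The output is parseable by
#' any standard GML reader.
#'
#' @param net a `CoexpressionNetwork`.
#' @param path output file path.
#' @param clusters optional named integer vector (gene -> cluster index) or
#'   `ClusteringResult`; genes without an assignment get no `cluster` field.
#' @return `path`, invisibly.
#' @examples
#' f <- tempfile(fileext = ".gml")
#' writeNetworkGML(fixtureGraph("triangle"), f)
#' net2 <- readNetworkGML(f)
#' @export
writeNetworkGML <- function(net, path, clusters = NULL) {
    stopifnot(is(net, "CoexpressionNetwork"))
    if (is(clusters, "ClusteringResult")) clusters <- clusterLabels(clusters)
    nodes <- net@nodes
    ed <- net@edges
    deg <- tabulate(c(match(ed$from, nodes), match(ed$to, nodes)),
                    nbins = length(nodes))
    con <- file(path, open = "wt", encoding = "UTF-8")
    on.exit(close(con))
    w <- function(...) writeLines(sprintf(...), con)
    w("graph [")
    w("  directed 0")
    if (length(net@threshold) == 1 && is.finite(net@threshold))
        w("  threshold %.6f", net@threshold)
    for (i in seq_along(nodes)) {
        w("  node [")
        w("    id %d", i - 1L)
        w("    label %s", .gmlQuote(nodes[i]))
        w("    degree %d", deg[i])
        if (!is.null(clusters) && nodes[i] %in% names(clusters))
            w("    cluster %d", as.integer(clusters[[nodes[i]]]))
        w("  ]")
    }
    if (nrow(ed) > 0) {
        src <- match(ed$from, nodes) - 1L
        tgt <- match(ed$to, nodes) - 1L
        for (i in seq_len(nrow(ed))) {
            w("  edge [")
            w("    source %d", src[i])
            w("    target %d", tgt[i])
            w("    weight %.6f", ed$weight[i])
            w("    sign %d", ed$sign[i])
            w("  ]")
        }
    }
    w("]")
    invisible(path)
}

#' Read a co-expression network from GML
#'
#' Parses a GML file (via igraph's GML reader) into a
#' [CoexpressionNetwork]. Node `label` attributes become gene ids; edge
#' `weight` and `sign` attributes are restored (missing signs default to
#' +1, missing weights to 1). The threshold is taken from the graph-level
#' `threshold` field when present, else from the `threshold` argument.
#'
#' @param path GML file path.
#' @param threshold fallback threshold when the file carries none.
#' @return a `CoexpressionNetwork`.
#' @export
readNetworkGML <- function(path, threshold = NULL) {
    g <- igraph::read_graph(path, format = "gml")
    nodes <- if ("label" %in% igraph::vertex_attr_names(g))
        as.character(igraph::vertex_attr(g, "label"))
    else as.character(seq_len(igraph::vcount(g)))
    el <- igraph::as_edgelist(g, names = FALSE)
    weight <- if ("weight" %in% igraph::edge_attr_names(g))
        as.numeric(igraph::edge_attr(g, "weight")) else rep(1, nrow(el))
    sign <- if ("sign" %in% igraph::edge_attr_names(g))
        as.integer(igraph::edge_attr(g, "sign")) else rep(1L, nrow(el))
    thr <- igraph::graph_attr(g, "threshold")
    if (is.null(thr)) thr <- threshold
    if (is.null(thr)) {
        thr <- if (nrow(el) > 0) min(weight) - 1e-9 else 0
    }
    edges <- data.frame(from = nodes[el[, 1]], to = nodes[el[, 2]],
                        weight = weight, sign = sign,
                        stringsAsFactors = FALSE)
    .newNetwork(nodes, edges, as.numeric(thr))
}
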
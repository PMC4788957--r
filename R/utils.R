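## Internal helpers shared across modules.

# Run expr with a locally seeded RNG stream, restoring any pre-existing
# global .Random.seed afterwards (generators must not leak global state).
.withSeed <- function(seed, expr) {
    env <- globalenv()
    had <- exists(".Random.seed", envir = env, inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = env) else NULL
    on.exit({
        if (had) assign(".Random.seed", old, envir = env)
        else if (exists(".Random.seed", envir = env, inherits = FALSE))
            rm(".Random.seed", envir = env)
    })
    set.seed(as.integer(seed))
    force(expr)
}

# Canonical edge table: endpoints ordered by node index, rows sorted, so two
# networks with the same edge set compare identical().
.canonicalEdges <- function(edges, nodes) {
    if (nrow(edges) == 0) {
        return(data.frame(from = character(), to = character(),
                          weight = numeric(), sign = integer(),
                          stringsAsFactors = FALSE))
    }
    i <- match(edges$from, nodes)
    j <- match(edges$to, nodes)
    swap <- i > j
    from <- ifelse(swap, edges$to, edges$from)
    to <- ifelse(swap, edges$from, edges$to)
    ii <- pmin(i, j)
    jj <- pmax(i, j)
    ord <- order(ii, jj)
    data.frame(from = from[ord], to = to[ord],
               weight = as.numeric(edges$weight)[ord],
               sign = as.integer(edges$sign)[ord],
               stringsAsFactors = FALSE)
}

# Construct a validated CoexpressionNetwork from parts.
.newNetwork <- function(nodes, edges, threshold) {
    new("CoexpressionNetwork", nodes = as.character(nodes),
        edges = .canonicalEdges(edges, nodes),
        threshold = as.numeric(threshold))
}

# CoexpressionNetwork -> igraph (undirected, weight/sign edge attributes).
.asIgraph <- function(net) {
    stopifnot(is(net, "CoexpressionNetwork"))
    g <- igraph::make_empty_graph(n = length(net@nodes), directed = FALSE)
    g <- igraph::set_vertex_attr(g, "name", value = net@nodes)
    if (nrow(net@edges) > 0) {
        idx <- rbind(match(net@edges$from, net@nodes),
                     match(net@edges$to, net@nodes))
        g <- igraph::add_edges(g, as.vector(idx),
                               weight = net@edges$weight,
                               sign = net@edges$sign)
    }
    g
}

#' Percentage reporting
#'
#' Reports a count as a percentage of a total, rounded to a fixed number of
#' decimals: the convention used throughout the package's topology and
#' enrichment summaries (e.g. the fraction of the genome that is
#' differentially expressed, or the share of network genes in the major
#' connected component).
#'
#' @param x numerator count.
#' @param total denominator count (> 0).
#' @param digits decimals to round to (default 1).
#' @return `percentOf()` returns the rounded numeric percentage;
#'   `formatPercent()` the same value formatted as a string with a trailing
#'   `%` and exactly `digits` decimals.
#' @examples
#' percentOf(8443, 9171)        # 92.1
#' formatPercent(13699, 16624, 2)  # "82.40%"
#' @export
percentOf <- function(x, total, digits = 1) {
    if (total <= 0) stop("total must be positive")
    round(100 * x / total, digits)
}

#' @rdname percentOf
#' @export
formatPercent <- function(x, total, digits = 1) {
    sprintf(paste0("%.", digits, "f%%"), percentOf(x, total, digits))
}
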
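## End-to-end orchestration: a plain-text key=value configuration, staged
## execution (build -> topology -> cluster -> enrich -> validate) and a
## machine-readable run manifest. The thin command-line front end in
## inst/scripts/coexnet.R drives these functions.

.pipelineDefaults <- function() {
    list(expr = NULL, de_pvals = NULL, ann_ortholog = NULL,
         ann_domain = NULL, fold_changes = NULL, focal_gene = NULL,
         out_dir = ".",
         alpha_de = 0.05, threshold = NA_real_,
         grid_min = 0.50, grid_max = 0.99, grid_step = 0.01,
         k_min = 4L, k_max = 20L, algorithms = "pam,hclust_average",
         null_models = "erdos_renyi,barabasi_albert",
         null_replicates = 1000L, neighborhood_distance = 2L,
         fc_cutoff = 4, enrich_alpha = 0.05, strict_cutoff = 1e-6,
         seed = 1L)
}

#' Read / write a pipeline configuration
#'
#' Plain-text `key = value` format, one pair per line, `#` comments
#' allowed; keys mirror the command-line flags. Unset keys take the
#' documented defaults. The configuration round-trips through
#' serialization.
#'
#' @param path file path.
#' @param config named list (for the writer).
#' @return `readPipelineConfig()`: a complete named list of parameters.
#' @export
readPipelineConfig <- function(path) {
    lines <- readLines(path, warn = FALSE)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    cfg <- .pipelineDefaults()
    for (ln in lines) {
        m <- regmatches(ln, regexec("^([^=]+)=(.*)$", ln))[[1]]
        if (length(m) != 3) stop("malformed config line: ", ln)
        key <- trimws(m[2]); val <- trimws(m[3])
        if (!key %in% names(cfg)) stop("unknown config key: ", key)
        proto <- .pipelineDefaults()[[key]]
        cfg[[key]] <- if (is.integer(proto)) as.integer(val)
                      else if (is.numeric(proto)) as.numeric(val)
                      else val
    }
    .validateConfig(cfg)
}

#' @rdname readPipelineConfig
#' @export
writePipelineConfig <- function(config, path) {
    cfg <- utils::modifyList(.pipelineDefaults(), config)
    keep <- !vapply(cfg, is.null, logical(1))
    writeLines(sprintf("%s = %s", names(cfg)[keep],
                       vapply(cfg[keep], function(v) format(v, digits = 15),
                              character(1))),
               path)
    invisible(path)
}

.validateConfig <- function(cfg) {
    if (cfg$alpha_de <= 0 || cfg$alpha_de >= 1)
        stop("alpha_de must lie in (0, 1)")
    if (cfg$k_max < cfg$k_min) stop("k_max must be >= k_min")
    if (cfg$grid_min >= cfg$grid_max) stop("grid_min must be < grid_max")
    if (!is.na(cfg$threshold) && (cfg$threshold <= 0 || cfg$threshold >= 1))
        stop("threshold must lie in (0, 1)")
    if (cfg$null_replicates < 1) stop("null_replicates must be >= 1")
    cfg
}

.log <- function(quiet, fmt, ...) {
    if (!quiet)
        message(format(Sys.time(), "%Y-%m-%dT%H:%M:%S "),
                sprintf(fmt, ...))
}

#' Run the full co-expression pipeline
#'
#' Executes, in order: expression loading (with optional differential-
#' expression prefiltering), correlation, threshold scan and selection
#' (skipped when a fixed threshold is configured), network construction,
#' topology summary with null-ensemble significance, clustering model
#' selection, optional dual-source term enrichment and optional
#' neighbourhood validation. All declared outputs plus a machine-readable
#' manifest (package version, seeds, parameter values, output paths) are
#' written under `out_dir`. Identical configurations and seeds produce
#' byte-identical outputs.
#'
#' @param config named list as from [readPipelineConfig()]; missing keys
#'   take defaults. Must at least name `expr`.
#' @param quiet suppress progress logging (stderr).
#' @return the manifest, invisibly.
#' @export
runPipeline <- function(config = list(), quiet = FALSE) {
    cfg <- .validateConfig(utils::modifyList(.pipelineDefaults(), config))
    if (is.null(cfg$expr)) stop("config must name an expression table")
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    outPath <- function(f) file.path(cfg$out_dir, f)
    outputs <- list()

    .log(quiet, "reading expression from %s", cfg$expr)
    se <- readExpression(cfg$expr)
    if (!is.null(cfg$de_pvals)) {
        .log(quiet, "selecting DE genes (alpha = %g)", cfg$alpha_de)
        keep <- selectDEGenes(readDEPvalues(cfg$de_pvals), cfg$alpha_de)
        se <- se[intersect(rownames(se), keep), ]
        .log(quiet, "%d DE genes retained", nrow(se))
    }
    corr <- computeCorrelation(se)

    if (is.na(cfg$threshold)) {
        .log(quiet, "scanning thresholds %.2f..%.2f", cfg$grid_min,
             cfg$grid_max)
        scan <- scanThresholds(corr, seq(cfg$grid_min, cfg$grid_max,
                                         by = cfg$grid_step))
        st <- scanTable(scan)
        st$r_squared <- round(st$r_squared, 6)
        st$lambda <- round(st$lambda, 6)
        st$mean_degree <- round(st$mean_degree, 6)
        utils::write.table(st, outPath("threshold_scan.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        outputs$threshold_scan <- outPath("threshold_scan.tsv")
        threshold <- selectThreshold(scan)
        .log(quiet, "selected threshold %.2f", threshold)
    } else {
        threshold <- cfg$threshold
        .log(quiet, "using fixed threshold %.2f", threshold)
    }

    net <- buildNetwork(corr, threshold)
    .log(quiet, "network: %d genes, %d edges", length(networkGenes(net)),
         nrow(networkEdges(net)))

    topo <- summarizeTopology(net)
    nulls <- list()
    for (model in strsplit(cfg$null_models, ",")[[1]]) {
        ens <- generateNullEnsemble(
            trimws(model), topo$n_nodes, topo$n_edges,
            nReplicates = cfg$null_replicates,
            statistic = "average_clustering", seed = cfg$seed)
        nulls[[trimws(model)]] <- list(
            statistic = "average_clustering",
            replicates = cfg$null_replicates,
            p_value = empiricalPvalue(topo$average_clustering, ens,
                                      "greater"))
    }
    topoOut <- c(topo, list(null_ensembles = nulls))
    jsonlite::write_json(topoOut, outPath("topology.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    outputs$topology <- outPath("topology.json")

    d <- dissimilarityFromCorrelation(corr)
    d <- d[networkGenes(net), networkGenes(net)]
    .log(quiet, "clustering %d network genes, k = %d..%d", nrow(d),
         cfg$k_min, cfg$k_max)
    algs <- trimws(strsplit(cfg$algorithms, ",")[[1]])
    sel <- selectClustering(d, kRange = cfg$k_min:cfg$k_max,
                            algorithms = algs)
    selTab <- sel$table
    selTab$overall_mean_silhouette <-
        round(selTab$overall_mean_silhouette, 6)
    utils::write.table(selTab, outPath("silhouette_scan.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    writeClusterTable(sel$best, outPath("clusters.tsv"))
    outputs$silhouette_scan <- outPath("silhouette_scan.tsv")
    outputs$clusters <- outPath("clusters.tsv")

    writeNetworkGML(net, outPath("network.gml"), clusters = sel$best)
    outputs$network <- outPath("network.gml")

    if (!is.null(cfg$ann_ortholog) || !is.null(cfg$ann_domain)) {
        .log(quiet, "term enrichment per cluster")
        labels <- clusterLabels(sel$best)
        bg <- rownames(se)
        res <- list()
        for (k in sort(unique(labels))) {
            study <- names(labels)[labels == k]
            ro <- if (!is.null(cfg$ann_ortholog))
                termEnrichment(study, bg,
                               readAnnotation(cfg$ann_ortholog, "ortholog"))
            rd <- if (!is.null(cfg$ann_domain))
                termEnrichment(study, bg,
                               readAnnotation(cfg$ann_domain, "domain"))
            comb <- if (!is.null(ro) && !is.null(rd))
                combineDualSource(ro, rd, cfg$enrich_alpha,
                                  cfg$strict_cutoff)
            else {
                one <- if (!is.null(ro)) ro else rd
                data.frame(term = one$term,
                           p_ortholog = if (!is.null(ro)) one$p_value
                                        else NA_real_,
                           p_domain = if (!is.null(rd)) one$p_value
                                      else NA_real_,
                           significant = one$p_value < cfg$strict_cutoff,
                           rule_fired = ifelse(
                               one$p_value < cfg$strict_cutoff,
                               "single_strict", NA_character_),
                           stringsAsFactors = FALSE)
            }
            if (nrow(comb) > 0) comb <- cbind(cluster = k, comb)
            res[[as.character(k)]] <- comb
        }
        res <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
        utils::write.table(res, outPath("enrichment.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        outputs$enrichment <- outPath("enrichment.tsv")
    }

    if (!is.null(cfg$fold_changes) && !is.null(cfg$focal_gene)) {
        .log(quiet, "validating around %s at distance %d", cfg$focal_gene,
             cfg$neighborhood_distance)
        fc <- readFoldChanges(cfg$fold_changes)
        nb <- neighborhoodAtDistance(net, cfg$focal_gene,
                                     cfg$neighborhood_distance)
        shift <- foldChangeShiftTest(nb, fc, networkGenes(net))
        resp <- responsiveSetEnrichment(nb, networkGenes(net),
                                        foldChanges = fc,
                                        fcCutoff = cfg$fc_cutoff)
        val <- list(focal_gene = cfg$focal_gene,
                    distance = cfg$neighborhood_distance,
                    neighborhood = shift,
                    responsive_enrichment = list(
                        counts = as.list(resp$counts),
                        p_value = resp$p_value))
        jsonlite::write_json(val, outPath("validation.json"),
                             auto_unbox = TRUE, digits = NA, pretty = TRUE)
        outputs$validation <- outPath("validation.json")
    }

    manifest <- list(
        package = "coexnet",
        version = as.character(utils::packageVersion("coexnet")),
        parameters = cfg[!vapply(cfg, is.null, logical(1))],
        selected_threshold = threshold,
        best_clustering = list(algorithm = sel$best@algorithm,
                               k = sel$best@k,
                               overall_mean_silhouette =
                                   sel$best@overallMean),
        outputs = outputs)
    jsonlite::write_json(manifest, outPath("manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    .log(quiet, "done; manifest at %s", outPath("manifest.json"))
    invisible(manifest)
}
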
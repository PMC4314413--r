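#' Pipeline configuration
#'
#' One configuration object drives every stage. Either point the input
#' paths at existing files (expression/label TSVs, STRING-style edge
#' list, GMT pathways) or set \code{simulate = TRUE} to generate them
#' from the bundled synthetic-data module. Serialises losslessly to JSON
#' via \code{\link{write_pipeline_config}}.
#'
#' @param out_dir output directory for stage artifacts.
#' @param seed master seed; every stage derives its own substream.
#' @param simulate generate inputs with \code{\link{sim_config}}.
#' @param sim a \code{\link{sim_config}} (used when \code{simulate}).
#' @param expression_files,label_files parallel vectors of per-study
#'   expression and sample-label TSV paths (ignored when simulating).
#' @param network_file STRING-style edge list path.
#' @param gmt_file GMT pathway file path.
#' @param weights optional per-study weights (default equal).
#' @param fc_threshold,p_threshold signature selection thresholds.
#' @param score_cutoff optional edge confidence cutoff.
#' @param mcode an \code{\link{mcode_params}}.
#' @param enrich_p05,enrich_p01 enrichment tier thresholds.
#' @param top_k_pathways pathway cap for hub selection.
#' @param log_level "quiet" or "info".
#' @return an object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(out_dir = "hubnet_out", seed = 1L,
                            simulate = TRUE, sim = sim_config(seed = seed),
                            expression_files = NULL, label_files = NULL,
                            network_file = NULL, gmt_file = NULL,
                            weights = NULL, fc_threshold = 2,
                            p_threshold = 0.01, score_cutoff = NULL,
                            mcode = mcode_params(), enrich_p05 = 0.05,
                            enrich_p01 = 0.01, top_k_pathways = 2,
                            log_level = "info") {
  if (fc_threshold <= 0 || p_threshold <= 0)
    stopf("configuration error: thresholds must be positive")
  if (!simulate) {
    for (field in c("expression_files", "label_files", "network_file",
                    "gmt_file")) {
      val <- get(field)
      if (is.null(val))
        stopf("configuration error: %s is required when simulation is disabled",
              field)
    }
  }
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 simulate = simulate, sim = sim,
                 expression_files = expression_files,
                 label_files = label_files, network_file = network_file,
                 gmt_file = gmt_file, weights = weights,
                 fc_threshold = fc_threshold, p_threshold = p_threshold,
                 score_cutoff = score_cutoff, mcode = mcode,
                 enrich_p05 = enrich_p05, enrich_p01 = enrich_p01,
                 top_k_pathways = top_k_pathways, log_level = log_level),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config a \code{pipeline_config}.
#' @param path JSON file path.
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(unclass_deep(config), path, auto_unbox = TRUE,
                       pretty = TRUE, null = "null")
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  sim <- do.call(sim_config, raw$sim[names(raw$sim) %in% names(formals(sim_config))])
  mp <- do.call(mcode_params, raw$mcode[names(raw$mcode) %in% names(formals(mcode_params))])
  args <- raw[setdiff(names(raw), c("sim", "mcode"))]
  args <- args[names(args) %in% names(formals(pipeline_config))]
  args$sim <- sim; args$mcode <- mp
  do.call(pipeline_config, args)
}

plog <- function(config, fmt, ...) {
  if (!identical(config$log_level, "quiet"))
    message(sprintf(paste0("[hubnet] ", fmt), ...))
}

read_study_files <- function(expr_path, label_path, study_id) {
  tab <- utils::read.table(expr_path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  vals <- as.matrix(tab[, -1, drop = FALSE])
  rownames(vals) <- tab[[1]]
  lab <- utils::read.table(label_path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  groups <- lab$group[match(colnames(vals), lab$sample)]
  if (anyNA(groups)) stopf("sample labels missing for %s", expr_path)
  expression_study(study_id, vals, groups)
}

#' Run the whole hub-discovery pipeline
#'
#' Stages, in order: (optional) simulate inputs; cross-study gene scoring
#' and signature selection; network construction restricted to the
#' signatures, giant component, four centralities; MCODE clustering;
#' pathway enrichment; group comparison and hub-subnetwork extraction.
#' Every stage writes a TSV artifact into \code{out_dir} and a
#' \code{manifest.json} records the configuration, seed and row counts,
#' so a run is reproducible from its manifest.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @return invisibly, a list with every stage result (\code{scores},
#'   \code{signatures}, \code{network}, \code{centralities},
#'   \code{complexes}, \code{enrichment}, \code{selection}, \code{hub},
#'   \code{manifest}).
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  if (config$simulate) {
    plog(config, "stage simulate: writing synthetic inputs")
    simdir <- file.path(config$out_dir, "sim")
    write_simulation(config$sim, simdir)
    config$expression_files <-
      file.path(simdir, sprintf("study%d_expr.tsv", seq_len(config$sim$n_studies)))
    config$label_files <-
      file.path(simdir, sprintf("study%d_groups.tsv", seq_len(config$sim$n_studies)))
    config$network_file <- file.path(simdir, "network.tsv")
    config$gmt_file <- file.path(simdir, "pathways.gmt")
  }
  for (f in c(config$expression_files, config$label_files,
              config$network_file, config$gmt_file))
    if (!file.exists(f)) stopf("stage signatures: input missing: %s", f)

  plog(config, "stage signatures: scoring %d studies",
       length(config$expression_files))
  studies <- Map(read_study_files, config$expression_files,
                 config$label_files,
                 sprintf("study%d", seq_along(config$expression_files)))
  scores <- compute_gene_scores(studies, weights = config$weights,
                                fc_threshold = config$fc_threshold,
                                p_threshold = config$p_threshold)
  sig <- select_signatures(scores, config$fc_threshold, config$p_threshold)
  utils::write.table(scores, file.path(config$out_dir, "gene_scores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  plog(config, "stage network: %d signature genes", length(sig$genes))
  net_full <- build_network(config$network_file,
                            restrict_to_genes = sig$genes,
                            score_cutoff = config$score_cutoff)
  if (igraph::vcount(net_full) == 0)
    stopf("stage network: no interactions among the signature genes")
  net <- giant_component(net_full)
  ct <- centrality_table(net)
  write_centrality_table(ct, file.path(config$out_dir, "centralities.tsv"))

  plog(config, "stage mcode: giant component %d nodes / %d edges",
       igraph::vcount(net), igraph::ecount(net))
  cx <- predict_complexes(net, config$mcode)
  write_mcode_result(cx, file.path(config$out_dir, "complexes.tsv"))

  plog(config, "stage enrich: %d complexes found", nrow(cx))
  pathways <- read_gmt(config$gmt_file)
  universe <- scores$gene
  er <- enrich(sig$genes, pathways, universe = universe,
               p05 = config$enrich_p05, p01 = config$enrich_p01)
  write_enrichment_table(er, file.path(config$out_dir, "enrichment.tsv"))

  plog(config, "stage hub: %d enriched pathways", nrow(er))
  clusters <- attr(cx, "member_sets")
  names(clusters) <- if (length(clusters)) sprintf("cluster%d", seq_along(clusters))
  cluster_grp <- group_centralities(ct, clusters)
  pw_sets <- lapply(pathways, intersect, ct$node)
  pw_grp <- group_centralities(ct, pw_sets[lengths(pw_sets) > 0])
  comparisons <- pairwise_anova(cluster_grp)
  selection <- select_significant_groups(comparisons, cluster_grp$summary,
                                         pw_grp$summary, er,
                                         top_k_pathways = config$top_k_pathways)
  utils::write.table(rbind(cluster_grp$summary, pw_grp$summary),
                     file.path(config$out_dir, "group_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(comparisons,
                     file.path(config$out_dir, "group_comparisons.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  hub <- NULL
  hub_groups <- c(clusters[selection$cluster],
                  pathways[selection$pathways])
  if (length(hub_groups) >= 2) {
    hub <- hub_subnetwork(hub_groups, net)
    utils::write.table(data.frame(gene = hub$hub_genes),
                       file.path(config$out_dir, "hub_genes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(as.data.frame(hub$induced_edges),
                       file.path(config$out_dir, "hub_edges.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = c("node_a", "node_b"))
  } else {
    plog(config, "stage hub: fewer than two selected groups, no hub emitted")
  }

  manifest <- list(
    seed = config$seed,
    config_hash = config_hash(config),
    n_signature_genes = length(sig$genes),
    n_up = length(sig$up), n_down = length(sig$down),
    network_nodes = igraph::vcount(net), network_edges = igraph::ecount(net),
    n_complexes = nrow(cx), n_enriched = nrow(er),
    selected_cluster = selection$cluster,
    selected_pathways = selection$pathways,
    hub_genes = if (is.null(hub)) character(0) else hub$hub_genes)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(scores = scores, signatures = sig, network = net,
                 centralities = ct, complexes = cx, enrichment = er,
                 selection = selection, hub = hub, manifest = manifest))
}

# Stable short hash of the serialised configuration (no digest dependency).
# Path fields are excluded so runs into different directories hash alike.
config_hash <- function(config) {
  keep <- setdiff(names(config), c("out_dir", "expression_files",
                                   "label_files", "network_file", "gmt_file"))
  s <- jsonlite::toJSON(unclass_deep(unclass(config)[keep]), auto_unbox = TRUE,
                        null = "null", digits = NA)
  sprintf("%08x", sum(utf8ToInt(as.character(s)) *
                        (seq_len(nchar(as.character(s))) %% 97 + 1)) %% 4294967296)
}
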
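#' Simulation configuration for the synthetic multi-study benchmark
#'
#' Bundles every parameter of the synthetic world: \code{n_studies}
#' case/control expression studies over a shared universe of
#' \code{m_genes} genes with \code{n_de_genes} planted differentially
#' expressed genes (log2 shift \code{effect_size}, random sign per gene,
#' Gaussian noise \code{noise_sd}); a preferential-attachment background
#' interaction network with planted cliques (\code{clique_sizes}); and a
#' pathway collection with one planted enriched set. Planted genes are
#' placed preferentially inside the planted cliques and the planted
#' pathway so the signature-to-network-to-cluster chain carries signal.
#'
#' @param n_studies number of studies.
#' @param m_genes size of the shared gene universe.
#' @param samples_per_group samples per group (case and control) per study.
#' @param n_de_genes number of planted differential genes.
#' @param effect_size mean log2 shift of planted genes in cases; the sign
#'   is drawn per gene.
#' @param noise_sd Gaussian standard deviation of log2 values.
#' @param clique_sizes integer vector of planted-clique node counts
#'   (each >= 4); may be empty.
#' @param background_edge_param preferential-attachment parameter: edges
#'   added per new node in the background graph.
#' @param n_pathways number of pathway gene sets.
#' @param pathway_size_range length-2 vector (min, max) of pathway sizes.
#' @param planted_pathway_overlap planted DE genes placed in the planted
#'   pathway.
#' @param seed master random seed; fully determines all outputs.
#' @return an object of class \code{sim_config}.
#' @export
sim_config <- function(n_studies = 5, m_genes = 1000, samples_per_group = 10,
                       n_de_genes = 20, effect_size = 3, noise_sd = 0.5,
                       clique_sizes = c(8L, 6L), background_edge_param = 2,
                       n_pathways = 20, pathway_size_range = c(10L, 40L),
                       planted_pathway_overlap = min(10L, n_de_genes),
                       seed = 1L) {
  for (nm in c("n_studies", "m_genes", "samples_per_group"))
    if (!is_count(get(nm))) stopf("configuration error: %s must be a positive integer", nm)
  if (!is.numeric(n_de_genes) || n_de_genes < 0 || n_de_genes != floor(n_de_genes))
    stopf("configuration error: n_de_genes must be a non-negative integer")
  if (n_de_genes > m_genes)
    stopf("configuration error: n_de_genes (%d) exceeds m_genes (%d)",
          n_de_genes, m_genes)
  if (length(clique_sizes) && any(clique_sizes < 4))
    stopf("configuration error: every clique size must be >= 4")
  if (samples_per_group < 2)
    stopf("configuration error: need >= 2 samples per group")
  if (noise_sd <= 0) stopf("configuration error: noise_sd must be positive")
  if (length(pathway_size_range) != 2 || pathway_size_range[1] > pathway_size_range[2])
    stopf("configuration error: pathway_size_range must be (min, max)")
  if (planted_pathway_overlap > n_de_genes)
    stopf("configuration error: planted_pathway_overlap (%d) exceeds n_de_genes (%d)",
          planted_pathway_overlap, n_de_genes)
  if (n_pathways >= 1 && planted_pathway_overlap > pathway_size_range[2])
    stopf("configuration error: planted_pathway_overlap exceeds maximum pathway size")
  structure(list(
    n_studies = as.integer(n_studies), m_genes = as.integer(m_genes),
    samples_per_group = as.integer(samples_per_group),
    n_de_genes = as.integer(n_de_genes), effect_size = effect_size,
    noise_sd = noise_sd, clique_sizes = as.integer(clique_sizes),
    background_edge_param = background_edge_param,
    n_pathways = as.integer(n_pathways),
    pathway_size_range = as.integer(pathway_size_range),
    planted_pathway_overlap = as.integer(planted_pathway_overlap),
    seed = as.integer(seed)), class = "sim_config")
}

sim_gene_universe <- function(config) {
  sprintf("g%05d", seq_len(config$m_genes))
}

# Planted truth shared by all three generators. Drawn from its own
# sub-stream; clique members and the planted pathway take planted DE genes
# in a fixed order so their intersection (the eventual hub) is nonempty.
sim_truth <- function(config) {
  universe <- sim_gene_universe(config)
  set.seed(sub_seed(config$seed, 1L))
  de_idx <- sort(sample.int(config$m_genes, config$n_de_genes))
  de_genes <- universe[de_idx]
  signs <- sample(c(-1, 1), config$n_de_genes, replace = TRUE)
  names(signs) <- de_genes
  clique_members <- list()
  pool_de <- de_genes
  pool_bg <- setdiff(universe, de_genes)
  for (k in config$clique_sizes) {
    take_de <- utils::head(pool_de, k)
    need <- k - length(take_de)
    fill <- if (need > 0) pool_bg[seq_len(need)] else character(0)
    clique_members[[length(clique_members) + 1L]] <- c(take_de, fill)
    pool_de <- setdiff(pool_de, take_de)
    pool_bg <- setdiff(pool_bg, fill)
  }
  list(de_genes = de_genes, de_signs = signs,
       clique_members = clique_members,
       enriched_pathway = if (config$n_pathways >= 1) "PW_PLANTED" else NA_character_)
}

#' Generate synthetic case/control expression studies
#'
#' Simulates \code{n_studies} gene-by-sample log2 expression matrices over
#' a shared gene universe. Planted genes have their case-group mean
#' shifted by \code{effect_size} (sign fixed per gene across studies);
#' all other genes have zero shift. Values are independent Gaussians on
#' the log2 scale around a gene-specific baseline.
#'
#' @param config a \code{\link{sim_config}}.
#' @return list with \code{studies} (a list of
#'   \code{\link{expression_study}} objects, identical gene order) and
#'   \code{truth} (planted ground truth: \code{de_genes},
#'   \code{de_signs}, \code{clique_members}, \code{enriched_pathway}).
#' @export
generate_studies <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  truth <- sim_truth(config)
  universe <- sim_gene_universe(config)
  shift <- numeric(config$m_genes)
  names(shift) <- universe
  shift[truth$de_genes] <- config$effect_size * truth$de_signs
  set.seed(sub_seed(config$seed, 2L))
  baseline <- stats::runif(config$m_genes, 4, 10)
  nper <- config$samples_per_group
  studies <- lapply(seq_len(config$n_studies), function(j) {
    vals <- matrix(stats::rnorm(config$m_genes * 2 * nper,
                                mean = baseline, sd = config$noise_sd),
                   nrow = config$m_genes)
    vals[, seq_len(nper)] <- vals[, seq_len(nper)] + shift
    groups <- rep(c("case", "control"), each = nper)
    colnames(vals) <- sprintf("s%d_%s%02d", j, groups, c(seq_len(nper), seq_len(nper)))
    rownames(vals) <- universe
    expression_study(sprintf("study%d", j), vals, groups)
  })
  list(studies = studies, truth = truth)
}

#' Generate a synthetic interaction network with planted cliques
#'
#' Background is a preferential-attachment graph (each new node attaches
#' to \code{background_edge_param} existing nodes), giving the
#' heavy-tailed degree distribution protein-interaction hubs exhibit;
#' planted cliques (all within-clique edges) are then added on node sets
#' chosen preferentially among the planted differential genes.
#'
#' @param config a \code{\link{sim_config}}.
#' @param gene_universe character vector of node names; defaults to the
#'   configuration's universe.
#' @return list with \code{network} (an igraph, simple and undirected,
#'   with an integer \code{score} edge attribute in [0, 1000]) and
#'   \code{truth}.
#' @export
generate_network <- function(config, gene_universe = sim_gene_universe(config)) {
  stopifnot(inherits(config, "sim_config"))
  if (length(config$clique_sizes) && max(config$clique_sizes) > length(gene_universe))
    stopf("configuration error: clique size exceeds gene universe")
  truth <- sim_truth(config)
  set.seed(sub_seed(config$seed, 3L))
  n <- length(gene_universe)
  g <- igraph::sample_pa(n, m = config$background_edge_param, directed = FALSE)
  igraph::V(g)$name <- sample(gene_universe)  # detach hub age from gene id
  for (members in truth$clique_members) {
    members <- intersect(members, gene_universe)
    if (length(members) >= 2) {
      pairs <- utils::combn(members, 2)
      g <- igraph::add_edges(g, as.vector(pairs))
    }
  }
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  igraph::E(g)$score <- sample(400:1000, igraph::ecount(g), replace = TRUE)
  list(network = g, truth = truth)
}

#' Generate a synthetic pathway collection with one planted enriched set
#'
#' Builds \code{n_pathways} random gene sets; the planted pathway
#' (\code{PW_PLANTED}) contains exactly \code{planted_pathway_overlap}
#' planted differential genes (the same leading planted genes used to
#' seed the first clique), the rest filled uniformly at random from the
#' universe.
#'
#' @param config a \code{\link{sim_config}}.
#' @param gene_universe character vector; defaults to the configuration's.
#' @param truth ground truth from \code{\link{generate_studies}}; defaults
#'   to regenerating it from the configuration.
#' @return list with \code{pathways} (a named list of gene-id vectors,
#'   GMT-writable via \code{\link{write_gmt}}) and \code{truth}.
#' @export
generate_pathways <- function(config, gene_universe = sim_gene_universe(config),
                              truth = sim_truth(config)) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_pathways == 0)
    return(list(pathways = structure(list(), names = character(0)), truth = truth))
  set.seed(sub_seed(config$seed, 4L))
  sizes <- sample(config$pathway_size_range[1]:config$pathway_size_range[2],
                  config$n_pathways, replace = TRUE)
  sizes[1] <- max(sizes[1], config$planted_pathway_overlap)
  pws <- vector("list", config$n_pathways)
  # The planted pathway emulates the annotation of the first planted
  # complex: it prefers DE genes inside clique 1, then DE genes in no
  # clique, so it never straddles two planted complexes.
  in_c1 <- if (length(truth$clique_members))
    intersect(truth$de_genes, truth$clique_members[[1]]) else character(0)
  loose <- setdiff(truth$de_genes, unlist(truth$clique_members))
  ordered_de <- unique(c(in_c1, loose, truth$de_genes))
  planted <- utils::head(ordered_de, config$planted_pathway_overlap)
  fill_pool <- setdiff(gene_universe, truth$de_genes)  # exact overlap by construction
  pws[[1]] <- c(planted, sample(fill_pool, sizes[1] - length(planted)))
  if (config$n_pathways > 1)
    for (i in 2:config$n_pathways)
      pws[[i]] <- sample(gene_universe, sizes[i])
  names(pws) <- c("PW_PLANTED",
                  if (config$n_pathways > 1)
                    sprintf("PW%03d", seq_len(config$n_pathways - 1L)))
  list(pathways = pws, truth = truth)
}

#' Write a simulated scenario to plain-text files
#'
#' Writes each study as a genes-by-samples TSV plus a two-column sample
#' label TSV, the network as a three-column STRING-style edge list
#' (node, node, score in [0, 1000]), the pathways as GMT, and the ground
#' truth as a JSON file.
#'
#' @param config a \code{\link{sim_config}}.
#' @param dir output directory (created if missing).
#' @return invisibly, the list of written paths.
#' @export
write_simulation <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sim <- generate_studies(config)
  net <- generate_network(config)
  pw <- generate_pathways(config, truth = sim$truth)
  paths <- character(0)
  for (st in sim$studies) {
    ep <- file.path(dir, paste0(st$study_id, "_expr.tsv"))
    lp <- file.path(dir, paste0(st$study_id, "_groups.tsv"))
    df <- data.frame(gene = rownames(st$values), st$values, check.names = FALSE)
    utils::write.table(df, ep, sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(data.frame(sample = colnames(st$values), group = st$groups),
                       lp, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, ep, lp)
  }
  np <- file.path(dir, "network.tsv")
  el <- igraph::as_edgelist(net$network)
  utils::write.table(data.frame(protein1 = el[, 1], protein2 = el[, 2],
                                combined_score = igraph::E(net$network)$score),
                     np, sep = "\t", quote = FALSE, row.names = FALSE)
  gp <- file.path(dir, "pathways.gmt")
  write_gmt(pw$pathways, gp)
  tp <- file.path(dir, "truth.json")
  jsonlite::write_json(list(de_genes = sim$truth$de_genes,
                            de_signs = as.list(sim$truth$de_signs),
                            clique_members = sim$truth$clique_members,
                            enriched_pathway = sim$truth$enriched_pathway),
                       tp, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(paths, np, gp, tp))
}
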
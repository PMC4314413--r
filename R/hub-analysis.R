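CENTRALITIES <- c("degree", "stress", "betweenness", "closeness")

#' Per-group centrality summaries
#'
#' Aggregates a centrality table over named node groups (MCODE clusters,
#' enriched pathways, ...). Group members absent from the table are
#' dropped with a message; groups left empty are excluded with a warning.
#'
#' @param table a \code{\link{centrality_table}}.
#' @param groups named list of node-id vectors.
#' @return list with \code{summary} (data.frame: group, n, mean of each
#'   centrality) and \code{values} (per-group list of per-centrality
#'   value vectors).
#' @export
group_centralities <- function(table, groups) {
  values <- list()
  rows <- list()
  for (g in names(groups)) {
    members <- intersect(groups[[g]], table$node)
    missing <- setdiff(groups[[g]], table$node)
    if (length(missing))
      message(sprintf("group %s: %d members absent from centrality table",
                      g, length(missing)))
    if (length(members) == 0) {
      warning(sprintf("group %s empty after filtering; excluded", g),
              call. = FALSE)
      next
    }
    idx <- match(members, table$node)
    vals <- lapply(CENTRALITIES, function(ct) table[[ct]][idx])
    names(vals) <- CENTRALITIES
    values[[g]] <- vals
    rows[[g]] <- data.frame(group = g, n = length(members),
                            t(vapply(vals, mean, numeric(1))),
                            stringsAsFactors = FALSE)
  }
  if (length(rows)) {
    summary <- do.call(rbind, rows)
    names(summary)[-(1:2)] <- paste0("mean_", CENTRALITIES)
  } else {
    summary <- data.frame(group = character(0), n = integer(0),
                          mean_degree = numeric(0), mean_stress = numeric(0),
                          mean_betweenness = numeric(0),
                          mean_closeness = numeric(0))
  }
  rownames(summary) <- NULL
  list(summary = summary, values = values)
}

# Two-group one-way ANOVA: F equals the squared pooled-variance t.
anova_two_group <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2) return(c(F = NA_real_, p = NA_real_))
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / (n1 + n2 - 2)
  if (sp2 == 0) {
    if (mean(x) == mean(y)) return(c(F = 0, p = 1))
    return(c(F = Inf, p = 0))
  }
  Fs <- (mean(x) - mean(y))^2 / (sp2 * (1 / n1 + 1 / n2))
  c(F = Fs, p = stats::pf(Fs, 1, n1 + n2 - 2, lower.tail = FALSE))
}

#' Pairwise one-way ANOVA between groups, per centrality
#'
#' For every unordered pair of groups and each of the four centralities,
#' a two-group one-way ANOVA (F equal to the square of the
#' pooled-variance t statistic) with significance stars at the given
#' levels. An omnibus F across all groups per centrality is attached as
#' attribute \code{omnibus}. No multiplicity correction is applied.
#'
#' @param grouped result of \code{\link{group_centralities}}.
#' @param alpha significance levels for the star annotation.
#' @return data.frame with columns \code{group_a}, \code{group_b},
#'   \code{centrality}, \code{F}, \code{p}, \code{signif}.
#' @export
pairwise_anova <- function(grouped, alpha = c(0.05, 0.01, 1e-4)) {
  gs <- names(grouped$values)
  rows <- list()
  if (length(gs) >= 2) {
    for (i in seq_len(length(gs) - 1)) for (j in (i + 1):length(gs)) {
      for (ct in CENTRALITIES) {
        fp <- anova_two_group(grouped$values[[gs[i]]][[ct]],
                              grouped$values[[gs[j]]][[ct]])
        stars <- sum(fp["p"] < sort(alpha, decreasing = TRUE))
        rows[[length(rows) + 1L]] <- data.frame(
          group_a = gs[i], group_b = gs[j], centrality = ct,
          F = unname(fp["F"]), p = unname(fp["p"]),
          signif = paste(rep("*", stars), collapse = ""),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(group_a = character(0), group_b = character(0),
               centrality = character(0), F = numeric(0), p = numeric(0),
               signif = character(0))
  omnibus <- lapply(CENTRALITIES, function(ct) {
    vals <- lapply(grouped$values, `[[`, ct)
    ok <- lengths(vals) >= 2
    if (sum(ok) < 2) return(c(F = NA_real_, p = NA_real_))
    df <- data.frame(v = unlist(vals[ok]),
                     g = rep(names(vals)[ok], lengths(vals)[ok]))
    fit <- stats::oneway.test(v ~ g, df, var.equal = TRUE)
    c(F = unname(fit$statistic), p = unname(fit$p.value))
  })
  names(omnibus) <- CENTRALITIES
  attr(out, "omnibus") <- omnibus
  out
}

#' Select the significant cluster and pathways for hub extraction
#'
#' Default rule mirroring a typical hub analysis: the cluster with the
#' highest mean degree that is significant (p < \code{alpha} in degree)
#' against at least one other cluster — a lone cluster qualifies
#' vacuously — plus the top-tier (\code{p01}) enriched pathways with the
#' highest mean degree, capped at \code{top_k_pathways}.
#'
#' @param comparisons \code{\link{pairwise_anova}} over the clusters.
#' @param cluster_summary \code{\link{group_centralities}} summary of the
#'   clusters.
#' @param pathway_summary \code{\link{group_centralities}} summary of the
#'   enriched pathways (may have zero rows).
#' @param enrichment \code{\link{enrich}} result used for the tier
#'   filter.
#' @param top_k_pathways cap on selected pathways (default 2).
#' @param alpha cluster significance level (default 0.05).
#' @return list with \code{cluster} (name or NULL) and \code{pathways}
#'   (character vector, possibly empty).
#' @export
select_significant_groups <- function(comparisons, cluster_summary,
                                      pathway_summary, enrichment,
                                      top_k_pathways = 2, alpha = 0.05) {
  cluster <- NULL
  cs <- cluster_summary[order(-cluster_summary$mean_degree), ]
  for (g in cs$group) {
    cmp <- comparisons[comparisons$centrality == "degree" &
                         (comparisons$group_a == g | comparisons$group_b == g), ]
    if (nrow(cmp) == 0 && nrow(cs) == 1) { cluster <- g; break }
    if (nrow(cmp) > 0 && any(cmp$p < alpha, na.rm = TRUE)) { cluster <- g; break }
  }
  top_terms <- enrichment$term[enrichment$tier == "p01"]
  ps <- pathway_summary[pathway_summary$group %in% top_terms, , drop = FALSE]
  pathways <- utils::head(ps$group[order(-ps$mean_degree)], top_k_pathways)
  if (is.null(cluster) && length(pathways) == 0)
    warning("no qualifying groups; empty selection", call. = FALSE)
  list(cluster = cluster, pathways = as.character(pathways))
}

#' Hub subnetwork: intersection of the selected groups
#'
#' The hub gene set is the exact intersection of all group member sets
#' (order-invariant); the induced edges are taken from the network.
#' Pairwise intersections between groups are reported alongside.
#'
#' @param groups named list (>= 2) of node-id vectors.
#' @param net the interaction igraph.
#' @return list (class \code{hub_subnetwork}) with \code{source_groups},
#'   \code{hub_genes}, \code{induced_edges} (two-column matrix),
#'   \code{pairwise} (named list of pairwise intersections).
#' @export
hub_subnetwork <- function(groups, net) {
  if (length(groups) < 2) stopf("need >= 2 groups")
  hub <- sort(Reduce(intersect, groups))
  if (length(hub) == 0) message("empty hub intersection")
  present <- intersect(hub, igraph::V(net)$name)
  edges <- if (length(present) >= 2)
    igraph::as_edgelist(igraph::induced_subgraph(net, present))
  else matrix(character(0), ncol = 2)
  gs <- names(groups)
  pairwise <- list()
  if (length(gs) >= 2)
    for (i in seq_len(length(gs) - 1)) for (j in (i + 1):length(gs))
      pairwise[[paste(gs[i], gs[j], sep = "&")]] <-
        sort(intersect(groups[[i]], groups[[j]]))
  structure(list(source_groups = gs, hub_genes = hub,
                 induced_edges = edges, pairwise = pairwise),
            class = "hub_subnetwork")
}

#' Top-k nodes per centrality
#'
#' Four ranked lists (ties broken lexicographically) plus the genes
#' appearing in all four top-k lists. k larger than the node count
#' truncates.
#'
#' @param table a \code{\link{centrality_table}}.
#' @param k list length (>= 1).
#' @return list with one ranked character vector per centrality and
#'   \code{common} (genes in all four lists).
#' @export
top_hubs <- function(table, k = 5) {
  if (k < 1) stopf("k must be >= 1")
  k <- min(k, nrow(table))
  lists <- lapply(CENTRALITIES, function(ct)
    table$node[order(-table[[ct]], table$node)][seq_len(k)])
  names(lists) <- CENTRALITIES
  lists$common <- sort(Reduce(intersect, lists))
  lists
}
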
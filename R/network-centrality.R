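#' Build an interaction network from a STRING-style edge list
#'
#' Accepts a file path or a data.frame with two node columns and an
#' optional third confidence-score column (STRING export dialect:
#' \code{protein1 protein2 combined_score}; a header line is detected and
#' skipped automatically). The result is a simple undirected igraph:
#' self-loops and duplicate edges are dropped, edges below
#' \code{score_cutoff} removed, and the graph induced on
#' \code{restrict_to_genes} when given.
#'
#' @param edges path to a whitespace/tab-separated edge list, or a
#'   data.frame.
#' @param restrict_to_genes optional character vector; keep only edges
#'   with both endpoints in this set.
#' @param score_cutoff optional minimum confidence score (applies only
#'   when scores are present).
#' @return an undirected simple igraph with node names.
#' @export
build_network <- function(edges, restrict_to_genes = NULL, score_cutoff = NULL) {
  if (is.character(edges)) edges <- read_edge_list(edges)
  if (ncol(edges) < 2) stopf("edge list needs >= 2 columns")
  a <- as.character(edges[[1]]); b <- as.character(edges[[2]])
  score <- if (ncol(edges) >= 3) as.numeric(edges[[3]]) else NULL
  if (!is.null(score) && !is.null(score_cutoff)) {
    keep <- score >= score_cutoff
    a <- a[keep]; b <- b[keep]; score <- score[keep]
  }
  if (!is.null(restrict_to_genes)) {
    keep <- a %in% restrict_to_genes & b %in% restrict_to_genes
    a <- a[keep]; b <- b[keep]; if (!is.null(score)) score <- score[keep]
  }
  g <- igraph::graph_from_data_frame(
    if (is.null(score)) data.frame(a, b) else data.frame(a, b, score),
    directed = FALSE)
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE,
                   edge.attr.comb = "max")
}

read_edge_list <- function(path) {
  if (!file.exists(path)) stopf("edge list not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stopf("empty edge list: %s", path)
  parts <- strsplit(lines, "[\t ]+")
  nf <- lengths(parts)
  bad <- which(nf < 2)
  if (length(bad)) stopf("parse error in %s at line %d: fewer than 2 fields",
                         path, bad[1])
  # header: third field present but non-numeric, or STRING column names
  start <- 1L
  if (parts[[1]][1] %in% c("protein1", "node1", "source", "nodeA") ||
      (nf[1] >= 3 && is.na(suppressWarnings(as.numeric(parts[[1]][3])))))
    start <- 2L
  if (start > length(parts)) stopf("edge list %s has only a header", path)
  parts <- parts[start:length(parts)]
  df <- data.frame(a = vapply(parts, `[`, "", 1),
                   b = vapply(parts, `[`, "", 2))
  if (all(lengths(parts) >= 3)) {
    sc <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 3)))
    if (anyNA(sc))
      stopf("parse error in %s at line %d: non-numeric score",
            path, which(is.na(sc))[1] + start - 1L)
    df$score <- sc
  }
  df
}

#' Extract the giant (largest connected) component
#'
#' Ties on component size are broken by the lexicographically smallest
#' member, so the result is deterministic.
#'
#' @param net an igraph.
#' @return the induced subgraph on the largest component.
#' @export
giant_component <- function(net) {
  if (igraph::vcount(net) == 0) stopf("empty graph")
  comp <- igraph::components(net)
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1) {
    firsts <- vapply(best, function(k)
      min(igraph::V(net)$name[comp$membership == k]), "")
    best <- best[order(firsts)][1]
  }
  igraph::induced_subgraph(net, which(comp$membership == best))
}

# Adjacency list as integer indices, names preserved.
adj_list <- function(net) {
  lapply(igraph::as_adj_list(net, mode = "all"), as.integer)
}

# One Brandes-style pass per source: BFS shortest-path DAG with path
# counts sigma, then backward accumulation of
#   - betweenness dependencies  delta(v) += sigma_sv/sigma_sw * (1 + delta(w))
#   - stress continuations      g(v) = sum_{w in succ(v)} (1 + g(w)),
#     contributing sigma_sv * g(v) shortest s-* paths through v
#   - the distance row for closeness.
brandes_pass <- function(adj, s, n) {
  sigma <- numeric(n); sigma[s] <- 1
  dist <- rep(-1L, n); dist[s] <- 0L
  preds <- vector("list", n)
  order_seen <- integer(0)
  queue <- s; qh <- 1L
  while (qh <= length(queue)) {
    v <- queue[qh]; qh <- qh + 1L
    order_seen <- c(order_seen, v)
    for (w in adj[[v]]) {
      if (dist[w] < 0L) {
        dist[w] <- dist[v] + 1L
        queue <- c(queue, w)
      }
      if (dist[w] == dist[v] + 1L) {
        sigma[w] <- sigma[w] + sigma[v]
        preds[[w]] <- c(preds[[w]], v)
      }
    }
  }
  delta <- numeric(n)   # betweenness dependency
  gcont <- numeric(n)   # number of shortest-path continuations from v
  for (w in rev(order_seen)) {
    for (v in preds[[w]]) {
      delta[v] <- delta[v] + sigma[v] / sigma[w] * (1 + delta[w])
      gcont[v] <- gcont[v] + 1 + gcont[w]
    }
  }
  list(dist = dist, sigma = sigma, delta = delta, stress = sigma * gcont)
}

#' Degree, stress, betweenness and closeness centralities
#'
#' Computes all four on a connected graph (apply
#' \code{\link{giant_component}} first). Degree counts incident edges.
#' Stress \code{Cstr(v)} counts the shortest paths between other node
#' pairs whose interior contains v; by default each unordered pair's
#' paths are counted once (\code{stress_mode = "ordered"} doubles them,
#' for cross-checks against tools that sum over ordered pairs).
#' Betweenness sums \code{sigma_st(v)/sigma_st} over unordered pairs and
#' (when \code{normalized}) divides by \code{(N-1)(N-2)/2} so values lie
#' in [0, 1]. Closeness is \code{(N-1) / sum_t d(v, t)}, the reciprocal
#' average shortest-path length. Shortest paths are unweighted even when
#' edges carry confidence scores.
#'
#' @param net a connected igraph.
#' @param normalized normalise betweenness to [0, 1] (default TRUE).
#' @param stress_mode \code{"unordered"} (default) or \code{"ordered"}.
#' @return data.frame (class \code{centrality_table}) with columns
#'   \code{node}, \code{degree}, \code{stress}, \code{betweenness},
#'   \code{closeness}, sorted by degree descending (ties by node id).
#' @export
centrality_table <- function(net, normalized = TRUE,
                             stress_mode = c("unordered", "ordered")) {
  stress_mode <- match.arg(stress_mode)
  n <- igraph::vcount(net)
  if (n == 0) stopf("empty graph")
  if (igraph::components(net)$no > 1)
    stopf("graph is disconnected; extract the giant_component() first")
  adj <- adj_list(net)
  btw <- numeric(n); str_ <- numeric(n); dsum <- numeric(n)
  for (s in seq_len(n)) {
    bp <- brandes_pass(adj, s, n)
    bp$delta[s] <- 0; bp$stress[s] <- 0
    btw <- btw + bp$delta
    str_ <- str_ + bp$stress
    dsum[s] <- sum(bp$dist)
  }
  btw <- btw / 2                       # each unordered pair counted twice
  if (stress_mode == "unordered") str_ <- str_ / 2
  if (normalized) {
    norm <- if (n > 2) (n - 1) * (n - 2) / 2 else 1
    btw <- btw / norm
    if (n < 3) btw[] <- 0
  }
  clo <- if (n > 1) (n - 1) / dsum else rep(0, n)
  out <- data.frame(node = igraph::V(net)$name,
                    degree = as.integer(igraph::degree(net)),
                    stress = str_, betweenness = btw, closeness = clo,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$degree, out$node), ]
  rownames(out) <- NULL
  class(out) <- c("centrality_table", "data.frame")
  out
}

#' Write a centrality table as TSV
#' @param table a \code{\link{centrality_table}}.
#' @param path output file.
#' @export
write_centrality_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
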
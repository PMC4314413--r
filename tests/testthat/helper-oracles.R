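# Brute-force oracles, deliberately independent of the package's
# algorithms: plain BFS distance matrices and explicit enumeration of
# every shortest path.

rand_connected_graph <- function(n, p, seed) {
  set.seed(seed)
  repeat {
    m <- matrix(stats::runif(n * n) < p, n, n)
    m[lower.tri(m, diag = TRUE)] <- FALSE
    g <- igraph::graph_from_adjacency_matrix(m | t(m), mode = "undirected")
    igraph::V(g)$name <- sprintf("n%02d", seq_len(n))
    if (igraph::is_connected(g)) return(g)
  }
}

oracle_adj <- function(g) {
  nodes <- igraph::V(g)$name
  el <- igraph::as_edgelist(g)
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (i in seq_len(nrow(el))) {
    adj[[el[i, 1]]] <- c(adj[[el[i, 1]]], match(el[i, 2], nodes))
    adj[[el[i, 2]]] <- c(adj[[el[i, 2]]], match(el[i, 1], nodes))
  }
  adj
}

oracle_bfs_dist <- function(adj, s, n) {
  d <- rep(NA_integer_, n); d[s] <- 0L
  q <- s
  while (length(q)) {
    v <- q[1]; q <- q[-1]
    for (w in adj[[v]]) if (is.na(d[w])) { d[w] <- d[v] + 1L; q <- c(q, w) }
  }
  d
}

# All shortest s-t paths as a list of index vectors, by backward
# recursion over the BFS distance labelling from s.
oracle_paths <- function(adj, dist_s, t) {
  if (dist_s[t] == 0L) return(list(t))
  preds <- Filter(function(u) dist_s[u] == dist_s[t] - 1L, adj[[t]])
  out <- list()
  for (u in preds)
    for (p in oracle_paths(adj, dist_s, u))
      out[[length(out) + 1L]] <- c(p, t)
  out
}

# Exhaustive centralities: stress (unordered pairs), normalized
# betweenness, closeness, degree.
oracle_centralities <- function(g) {
  nodes <- igraph::V(g)$name
  n <- length(nodes)
  adj <- oracle_adj(g)
  dist <- t(sapply(seq_len(n), function(s) oracle_bfs_dist(adj, s, n)))
  stress <- numeric(n); btw <- numeric(n)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    paths <- oracle_paths(adj, dist[s, ], t)
    sigma <- length(paths)
    for (v in setdiff(seq_len(n), c(s, t))) {
      cv <- sum(vapply(paths, function(p) v %in% p, logical(1)))
      stress[v] <- stress[v] + cv
      btw[v] <- btw[v] + cv / sigma
    }
  }
  norm <- if (n > 2) (n - 1) * (n - 2) / 2 else 1
  data.frame(node = nodes, degree = lengths(adj)[nodes],
             stress = stress, betweenness = if (n > 2) btw / norm else 0,
             closeness = (n - 1) / rowSums(dist),
             stringsAsFactors = FALSE)
}

# Core numbers by direct definition: for each k, iteratively delete
# nodes of degree < k; survivors have core number >= k.
oracle_core_numbers <- function(g) {
  nodes <- igraph::V(g)$name
  core <- stats::setNames(integer(length(nodes)), nodes)
  for (k in seq_len(igraph::vcount(g))) {
    h <- g
    repeat {
      low <- igraph::V(h)$name[igraph::degree(h) < k]
      if (!length(low)) break
      h <- igraph::delete_vertices(h, low)
    }
    if (igraph::vcount(h) == 0) break
    core[igraph::V(h)$name] <- k
  }
  core
}

# Vertex weight straight from the definition, using the oracle cores.
oracle_vertex_weight <- function(g, v) {
  nbrs <- igraph::V(g)$name[igraph::neighbors(g, v)]
  if (!length(nbrs)) return(0)
  h0 <- igraph::induced_subgraph(g, c(v, nbrs))
  cores <- oracle_core_numbers(h0)
  kmax <- max(cores)
  h <- igraph::induced_subgraph(h0, names(cores)[cores == kmax])
  nh <- igraph::vcount(h)
  kmax * 2 * igraph::ecount(h) / (nh * (nh - 1))
}

# Shared small fixtures -------------------------------------------------

path_graph <- function(nodes) {
  igraph::graph_from_data_frame(
    data.frame(a = nodes[-length(nodes)], b = nodes[-1]), directed = FALSE)
}

star_graph <- function(center, leaves) {
  igraph::graph_from_data_frame(
    data.frame(a = center, b = leaves), directed = FALSE)
}

complete_graph <- function(nodes) {
  el <- t(utils::combn(nodes, 2))
  igraph::graph_from_data_frame(as.data.frame(el), directed = FALSE)
}

example_enrichment_path <- function() {
  system.file("extdata", "kegg_enrichment_example.tsv", package = "hubnet",
              mustWork = TRUE)
}

read_example_enrichment <- function() {
  utils::read.table(example_enrichment_path(), header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
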
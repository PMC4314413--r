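#' MCODE parameter set
#'
#' Defaults follow common practice for protein-interaction clustering:
#' complexes must reach a 4-core, the seed-expansion threshold keeps
#' nodes whose weight is within 30% of the seed's, nodes of degree < 2
#' never seed, expansion depth is effectively unbounded, and the haircut
#' (2-core trim) is on while fluff is off.
#'
#' @param k_core integer >= 2: discard complexes whose maximum internal
#'   core number is below this.
#' @param node_score_cutoff real in [0, 1): a neighbour joins a complex
#'   when its weight exceeds \code{(1 - node_score_cutoff)} times the
#'   seed's weight (strict).
#' @param degree_cutoff integer >= 2: minimum degree for seed nodes.
#' @param max_depth integer >= 1: maximum expansion depth from the seed.
#' @param haircut iteratively remove members with < 2 within-complex
#'   neighbours.
#' @param fluff add dense neighbouring vertices (complexes may overlap).
#' @param fluff_density_cutoff closed-neighbourhood density threshold for
#'   fluff (strict >).
#' @return an object of class \code{mcode_params}.
#' @export
mcode_params <- function(k_core = 4L, node_score_cutoff = 0.3,
                         degree_cutoff = 2L, max_depth = 100L,
                         haircut = TRUE, fluff = FALSE,
                         fluff_density_cutoff = 0.5) {
  if (k_core < 2) stopf("k_core must be >= 2")
  if (node_score_cutoff < 0 || node_score_cutoff >= 1)
    stopf("node_score_cutoff must be in [0, 1)")
  if (degree_cutoff < 2) stopf("degree_cutoff must be >= 2")
  if (max_depth < 1) stopf("max_depth must be >= 1")
  if (fluff_density_cutoff < 0 || fluff_density_cutoff > 1)
    stopf("fluff_density_cutoff must be in [0, 1]")
  structure(list(k_core = as.integer(k_core),
                 node_score_cutoff = node_score_cutoff,
                 degree_cutoff = as.integer(degree_cutoff),
                 max_depth = as.integer(max_depth),
                 haircut = haircut, fluff = fluff,
                 fluff_density_cutoff = fluff_density_cutoff),
            class = "mcode_params")
}

#' k-core decomposition
#'
#' The core number of a node is the largest k such that the node belongs
#' to a subgraph of minimum degree k. Computed by the standard peeling
#' iteration: repeatedly delete a minimum-degree node, recording the
#' running maximum of the minimum degree at deletion time.
#'
#' @param net an igraph.
#' @return named integer vector of core numbers.
#' @export
core_decomposition <- function(net) {
  n <- igraph::vcount(net)
  core <- integer(n)
  names(core) <- igraph::V(net)$name
  if (n == 0) return(core)
  adj <- adj_list(net)
  deg <- lengths(adj)
  alive <- rep(TRUE, n)
  k <- 0L
  for (step in seq_len(n)) {
    cand <- which(alive)
    v <- cand[which.min(deg[cand])]
    k <- max(k, deg[v])
    core[v] <- k
    alive[v] <- FALSE
    for (w in adj[[v]]) if (alive[w]) deg[w] <- deg[w] - 1L
  }
  core
}

#' MCODE vertex weight (core-clustering coefficient scaled by core level)
#'
#' Let H be the highest-k k-core of the subgraph induced by the closed
#' neighbourhood N[v]. The weight of v is \code{k(H) * density(H)} with
#' \code{density = 2E/(|H|(|H|-1))}; an isolated node weighs 0.
#'
#' @param net an igraph.
#' @param v node name (or names); default all nodes.
#' @return named numeric weight vector.
#' @export
vertex_weight <- function(net, v = igraph::V(net)$name) {
  vapply(v, function(nm) {
    nbrs <- igraph::neighbors(net, nm)
    if (length(nbrs) == 0) return(0)
    closed <- unique(c(nm, igraph::V(net)$name[nbrs]))
    h0 <- igraph::induced_subgraph(net, closed)
    cores <- core_decomposition(h0)
    kmax <- max(cores)
    members <- names(cores)[cores == kmax]
    h <- igraph::induced_subgraph(h0, members)
    kmax * graph_density(igraph::vcount(h), igraph::ecount(h))
  }, numeric(1))
}

#' MCODE complex score: density times node count
#'
#' \code{score = [2E/(V(V-1))] * V = 2E/(V-1)}; fewer than 2 nodes
#' scores 0 by convention. A complete graph on n nodes scores n.
#'
#' @param n_nodes,n_edges node and edge counts of the complex subgraph.
#' @return numeric score.
#' @export
complex_score <- function(n_nodes, n_edges) {
  ifelse(n_nodes < 2, 0, 2 * n_edges / (n_nodes - 1))
}

#' Haircut post-processing: trim to the 2-core of the complex
#'
#' Iteratively removes members with fewer than two within-complex
#' neighbours until stable; may return an empty set (e.g. a tree).
#'
#' @param members character vector of complex members.
#' @param net the parent igraph.
#' @return character vector of retained members.
#' @export
haircut <- function(members, net) {
  repeat {
    if (length(members) == 0) return(character(0))
    sub <- igraph::induced_subgraph(net, members)
    deg <- igraph::degree(sub)
    drop <- names(deg)[deg < 2]
    if (length(drop) == 0) return(sort(members))
    members <- setdiff(members, drop)
  }
}

#' Fluff post-processing: add dense neighbouring vertices
#'
#' One pass over the complex's outside neighbours: a neighbour u is added
#' when the density of the subgraph induced by its closed neighbourhood
#' N[u] exceeds \code{density_cutoff} (strict). Complexes may overlap
#' after fluffing.
#'
#' @param members character vector of complex members.
#' @param net the parent igraph.
#' @param density_cutoff real in [0, 1].
#' @return character vector of members (superset of the input).
#' @export
fluff <- function(members, net, density_cutoff = 0.5) {
  if (length(members) == 0) return(members)
  nbrs <- unique(unlist(lapply(members, function(v)
    igraph::V(net)$name[igraph::neighbors(net, v)])))
  cand <- setdiff(nbrs, members)
  add <- vapply(cand, function(u) {
    closed <- unique(c(u, igraph::V(net)$name[igraph::neighbors(net, u)]))
    h <- igraph::induced_subgraph(net, closed)
    graph_density(igraph::vcount(h), igraph::ecount(h)) > density_cutoff
  }, logical(1))
  sort(c(members, cand[add]))
}

#' MCODE complex prediction
#'
#' Full molecular-complex detection: vertices are weighted by the
#' core-clustering coefficient (\code{\link{vertex_weight}}), then seeds
#' are processed in descending weight order (ties by node id; nodes with
#' degree below \code{degree_cutoff} never seed). From each still-unused
#' seed, neighbours are included breadth-first when their weight exceeds
#' \code{(1 - node_score_cutoff)} times the seed weight, up to
#' \code{max_depth}; each node joins at most one complex. Complexes whose
#' maximum internal core number is below \code{k_core} are discarded;
#' survivors get the optional haircut/fluff and are scored with
#' \code{\link{complex_score}}.
#'
#' @param net an igraph.
#' @param params an \code{\link{mcode_params}}.
#' @return data.frame (class \code{mcode_result}) with one row per
#'   complex: \code{rank}, \code{score}, \code{n_nodes}, \code{n_edges},
#'   \code{seed}, \code{members} (comma-joined, sorted); ordered by
#'   score descending, ties by seed id. Attribute \code{member_sets}
#'   holds the member vectors.
#' @export
predict_complexes <- function(net, params = mcode_params()) {
  if (igraph::vcount(net) == 0) {
    out <- data.frame(rank = integer(0), score = numeric(0),
                      n_nodes = integer(0), n_edges = integer(0),
                      seed = character(0), members = character(0))
    attr(out, "member_sets") <- list()
    class(out) <- c("mcode_result", "data.frame")
    return(out)
  }
  w <- vertex_weight(net)
  nodes <- igraph::V(net)$name
  deg <- igraph::degree(net)
  adj <- igraph::as_adj_list(net, mode = "all")
  adj <- lapply(adj, function(x) nodes[as.integer(x)])
  names(adj) <- nodes
  seeds <- nodes[deg >= params$degree_cutoff & w > 0]
  seeds <- seeds[order(-w[seeds], seeds)]
  used <- character(0)
  complexes <- list()
  for (s in seeds) {
    if (s %in% used) next
    thr <- (1 - params$node_score_cutoff) * w[s]
    members <- s
    frontier <- s
    depth <- 0L
    while (length(frontier) > 0 && depth < params$max_depth) {
      nxt <- character(0)
      for (v in frontier) {
        for (u in adj[[v]]) {
          if (u %in% members || u %in% used) next
          if (w[u] > thr) {
            members <- c(members, u)
            nxt <- c(nxt, u)
          }
        }
      }
      frontier <- nxt
      depth <- depth + 1L
    }
    used <- c(used, members)
    sub <- igraph::induced_subgraph(net, members)
    if (max(core_decomposition(sub)) < params$k_core) next
    if (params$haircut) {
      members <- haircut(members, net)
      if (length(members) > 1) {
        # trimming can split the complex; keep the largest piece
        sub2 <- igraph::induced_subgraph(net, members)
        if (igraph::components(sub2)$no > 1)
          members <- igraph::V(giant_component(sub2))$name
      }
    }
    if (params$fluff) members <- fluff(members, net, params$fluff_density_cutoff)
    if (length(members) < 2) next
    complexes[[length(complexes) + 1L]] <- list(seed = s, members = sort(members))
  }
  if (length(complexes) == 0) {
    out <- data.frame(rank = integer(0), score = numeric(0),
                      n_nodes = integer(0), n_edges = integer(0),
                      seed = character(0), members = character(0))
    attr(out, "member_sets") <- list()
    class(out) <- c("mcode_result", "data.frame")
    return(out)
  }
  rows <- lapply(complexes, function(cx) {
    sub <- igraph::induced_subgraph(net, cx$members)
    nn <- igraph::vcount(sub); ne <- igraph::ecount(sub)
    data.frame(score = complex_score(nn, ne), n_nodes = nn, n_edges = ne,
               seed = cx$seed, members = paste(cx$members, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  ord <- order(-out$score, out$seed)
  out <- out[ord, ]
  out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  attr(out, "member_sets") <- lapply(complexes[ord], `[[`, "members")
  class(out) <- c("mcode_result", "data.frame")
  out
}

#' Write an MCODE result as TSV
#' @param result a \code{\link{predict_complexes}} result.
#' @param path output file.
#' @export
write_mcode_result <- function(result, path) {
  utils::write.table(as.data.frame(result), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
}
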
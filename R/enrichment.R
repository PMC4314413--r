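#' Read a GMT gene-set file
#'
#' One pathway per line: name, description, then member genes, all
#' tab-separated. Duplicate genes within a line are dropped.
#'
#' @param path GMT file.
#' @return named list of gene-id character vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stopf("GMT file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(structure(list(), names = character(0)))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3)
  if (length(bad)) stopf("parse error in %s at line %d: fewer than 3 fields",
                         path, bad[1])
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[`, "", 1)
  sets
}

#' Write a GMT gene-set file
#' @param pathways named list of gene-id vectors.
#' @param path output file.
#' @param descriptions optional per-pathway description column (defaults
#'   to the pathway name).
#' @export
write_gmt <- function(pathways, path, descriptions = names(pathways)) {
  lines <- vapply(seq_along(pathways), function(i)
    paste(c(names(pathways)[i], descriptions[i], pathways[[i]]),
          collapse = "\t"), "")
  writeLines(lines, path)
}

#' EASE score: jackknifed one-sided Fisher exact p-value
#'
#' For an overlap of \code{a} genes between a query list of size \code{L}
#' and a pathway of size \code{K} within a background of \code{N} genes,
#' the plain Fisher p is the upper hypergeometric tail
#' \code{P[X >= a]}, X ~ Hypergeom(N, K, L). The EASE score penalises
#' single-gene evidence by jackknifing one overlap gene: a is replaced by
#' a - 1 with margins preserved, giving \code{P[X >= a - 1]}; an overlap
#' of 0 or 1 scores exactly 1. EASE is therefore always >= the plain
#' Fisher p.
#'
#' @param a overlap count.
#' @param L query-list size.
#' @param K pathway size.
#' @param N background size.
#' @return list with \code{ease_p} and \code{fisher_p}.
#' @export
ease_p <- function(a, L, K, N) {
  if (a < 0 || L < 0 || K < 0 || N < 1 || a > min(L, K) || L > N || K > N)
    stopf("inconsistent 2x2 margins (a=%s, L=%s, K=%s, N=%s)", a, L, K, N)
  fisher <- stats::phyper(a - 1, K, N - K, L, lower.tail = FALSE)
  ease <- if (a <= 1) 1
          else stats::phyper(a - 2, K, N - K, L, lower.tail = FALSE)
  list(ease_p = min(ease, 1), fisher_p = min(fisher, 1))
}

#' Pathway enrichment of a gene set with the EASE score
#'
#' Tests the query set against every pathway in the collection. The
#' default background is the pathway-collection universe (union of all
#' pathway genes), optionally intersected with an analysis universe;
#' query genes outside the background are dropped with a message (they
#' are "unmapped"). One row per pathway with overlap >= 1, sorted by
#' EASE p ascending; tiers \code{p01} / \code{p05} / \code{none} use
#' strict thresholds. A Benjamini-Hochberg column over the tested
#' pathways is included for information only — tiers use the raw EASE p.
#'
#' @param gene_set character vector of query genes.
#' @param pathways named list of gene-id vectors (see
#'   \code{\link{read_gmt}}).
#' @param background optional character vector; default as described.
#' @param universe optional analysis universe intersected into the
#'   default background.
#' @param p05,p01 tier thresholds (strict <).
#' @return data.frame (class \code{enrichment_table}) with columns
#'   \code{term}, \code{count}, \code{ease_p}, \code{fisher_p},
#'   \code{bh_q}, \code{tier}, \code{genes} (comma-joined overlap).
#' @export
enrich <- function(gene_set, pathways, background = NULL, universe = NULL,
                   p05 = 0.05, p01 = 0.01) {
  if (is.null(background)) {
    background <- unique(unlist(pathways))
    if (!is.null(universe)) background <- intersect(background, universe)
  }
  if (length(background) == 0) stopf("empty background")
  gene_set <- unique(gene_set)
  unmapped <- setdiff(gene_set, background)
  if (length(unmapped))
    message(sprintf("%d genes were not mapped to the background and dropped",
                    length(unmapped)))
  gene_set <- intersect(gene_set, background)
  L <- length(gene_set); N <- length(background)
  rows <- lapply(names(pathways), function(term) {
    pw <- intersect(pathways[[term]], background)
    ov <- sort(intersect(gene_set, pw))
    if (length(ov) == 0) return(NULL)
    p <- ease_p(length(ov), L, length(pw), N)
    data.frame(term = term, count = length(ov), ease_p = p$ease_p,
               fisher_p = p$fisher_p, genes = paste(ov, collapse = ","),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) {
    out <- data.frame(term = character(0), count = integer(0),
                      ease_p = numeric(0), fisher_p = numeric(0),
                      bh_q = numeric(0), tier = character(0),
                      genes = character(0))
    class(out) <- c("enrichment_table", "data.frame")
    return(out)
  }
  out <- do.call(rbind, rows)
  out$bh_q <- stats::p.adjust(out$ease_p, method = "BH")
  out$tier <- ifelse(out$ease_p < p01, "p01",
                     ifelse(out$ease_p < p05, "p05", "none"))
  out <- out[order(out$ease_p, out$term),
             c("term", "count", "ease_p", "fisher_p", "bh_q", "tier", "genes")]
  rownames(out) <- NULL
  class(out) <- c("enrichment_table", "data.frame")
  out
}

#' Write an enrichment table as TSV
#' @param table an \code{\link{enrich}} result.
#' @param path output file.
#' @export
write_enrichment_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
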
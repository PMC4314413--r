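#' Construct an expression study
#'
#' A single case/control study: a gene-by-sample matrix of log2
#' expression values plus per-sample group labels. Studies carry an
#' optional relative weight used when combining rank scores across
#' studies; weights are normalised to sum to one over a study collection.
#'
#' @param study_id study label.
#' @param values numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns, log2 scale.
#' @param groups character vector of "case"/"control", one per column.
#' @param weight nonnegative relative weight (default 1: equal weights
#'   after normalisation).
#' @return an object of class \code{expression_study}.
#' @export
expression_study <- function(study_id, values, groups, weight = 1) {
  if (is.null(rownames(values))) stopf("values must have gene ids as rownames")
  if (length(groups) != ncol(values))
    stopf("groups length (%d) != number of samples (%d)", length(groups), ncol(values))
  if (!all(groups %in% c("case", "control")))
    stopf("groups must be 'case' or 'control'")
  if (sum(groups == "case") < 2 || sum(groups == "control") < 2)
    stopf("study %s: need >= 2 samples per group", study_id)
  if (weight < 0) stopf("negative study weight")
  structure(list(study_id = study_id, values = values,
                 groups = groups, weight = weight),
            class = "expression_study")
}

#' Collapse probe-level rows to gene level by per-sample maximum
#'
#' When a gene is measured by multiple probes, its expression in each
#' sample is the maximum over the gene's probes. Probes mapped to several
#' genes contribute to each; unmapped probes are dropped.
#'
#' @param probe_matrix numeric matrix, probes in rows (rownames = probe
#'   ids).
#' @param probe_to_gene_map data.frame with columns \code{probe},
#'   \code{gene} (one row per probe-gene assignment).
#' @return gene-by-sample matrix, rows sorted by gene id.
#' @export
collapse_probes <- function(probe_matrix, probe_to_gene_map) {
  if (nrow(probe_to_gene_map) == 0) stopf("empty probe-to-gene map")
  map <- probe_to_gene_map[probe_to_gene_map$probe %in% rownames(probe_matrix), ]
  genes <- sort(unique(map$gene))
  out <- matrix(NA_real_, nrow = length(genes), ncol = ncol(probe_matrix),
                dimnames = list(genes, colnames(probe_matrix)))
  for (g in genes) {
    probes <- map$probe[map$gene == g]
    sub <- probe_matrix[probes, , drop = FALSE]
    out[g, ] <- apply(sub, 2, max)
  }
  out
}

#' Restrict studies to their common genes
#'
#' A gene is kept only if present in every study (genes absent from any
#' one study are removed). The common list is returned in lexicographic
#' order and every study matrix is re-indexed to it.
#'
#' @param studies list of \code{\link{expression_study}} objects (>= 2).
#' @return list with \code{genes} (common gene ids) and \code{studies}
#'   (restricted studies, identical gene order).
#' @export
filter_common_genes <- function(studies) {
  if (length(studies) < 2) stopf("need >= 2 studies")
  common <- Reduce(intersect, lapply(studies, function(s) rownames(s$values)))
  if (length(common) == 0) stopf("no genes common to all studies")
  common <- sort(common)
  studies <- lapply(studies, function(s) {
    s$values <- s$values[common, , drop = FALSE]
    s
  })
  list(genes = common, studies = studies)
}

#' Per-gene log2 fold change of one study
#'
#' \code{log2FC_i = mean(case) - mean(control)} on the log2 scale.
#'
#' @param study an \code{\link{expression_study}}.
#' @return named numeric vector, one value per gene.
#' @export
fold_change <- function(study) {
  cs <- study$groups == "case"
  if (!any(cs) || all(cs)) stopf("a group has zero samples")
  rowMeans(study$values[, cs, drop = FALSE]) -
    rowMeans(study$values[, !cs, drop = FALSE])
}

#' Rank genes by absolute fold change
#'
#' Rank 1 is the largest \code{|log2FC|}; ranks are a permutation of
#' \code{1..m}. Ties are broken by smaller per-study p-value, then by
#' lexicographic gene id, so the ranking is deterministic.
#'
#' @param log2fc named numeric vector of per-gene log2 fold changes.
#' @param pvalues optional named numeric vector of per-study p-values
#'   used as the first tie-break.
#' @return named integer rank vector in the input gene order.
#' @export
rank_genes <- function(log2fc, pvalues = NULL) {
  if (is.null(names(log2fc))) stopf("log2fc must be named by gene id")
  if (!is.null(pvalues) && length(pvalues) != length(log2fc))
    stopf("pvalues length mismatch")
  p <- if (is.null(pvalues)) rep(0, length(log2fc)) else pvalues
  ord <- order(-abs(log2fc), p, names(log2fc))
  r <- integer(length(log2fc))
  r[ord] <- seq_along(log2fc)
  names(r) <- names(log2fc)
  r
}

#' Genome-wide relative significance (GWRS) of a rank
#'
#' \code{s = -2 * ln(r / m)}: strictly decreasing in the rank, zero at
#' the bottom rank, largest for rank 1.
#'
#' @param r rank(s), integer(s) in \code{1..m} (vectorised).
#' @param m number of common genes.
#' @return GWRS score(s), \code{>= 0}.
#' @export
gwrs <- function(r, m) {
  if (m < 1) stopf("m must be >= 1")
  if (any(r < 1 | r > m)) stopf("rank out of range 1..m")
  -2 * log(r / m)
}

#' Genome-wide global significance (GWGS): weighted GWRS combination
#'
#' \code{S_i = sum_j w_j * s_ij} with nonnegative weights summing to 1;
#' a convex combination, so \code{min_j s_ij <= S_i <= max_j s_ij}.
#'
#' @param scores numeric vector (one gene, one score per study) or a
#'   genes-by-studies matrix.
#' @param weights per-study weights; normalised to sum to 1.
#' @return the combined score (scalar or per-gene vector).
#' @export
gwgs <- function(scores, weights = NULL) {
  nstud <- if (is.matrix(scores)) ncol(scores) else length(scores)
  if (is.null(weights)) weights <- rep(1 / nstud, nstud)
  if (length(weights) != nstud) stopf("weight/score length mismatch")
  if (any(weights < 0)) stopf("negative weight")
  weights <- weights / sum(weights)
  if (is.matrix(scores)) drop(scores %*% weights) else sum(scores * weights)
}

#' Per-gene Welch t-test p-values for one study
#'
#' Two-sided Welch (unequal-variance) t-test of case vs control on log2
#' values, vectorised over genes. Genes with zero variance in both groups
#' and equal means get p = 1 by convention; p-values are clamped away
#' from exact zero.
#'
#' @param study an \code{\link{expression_study}}.
#' @return named numeric vector of p-values in (0, 1].
#' @export
per_study_pvalue <- function(study) {
  cs <- study$groups == "case"
  x <- study$values[, cs, drop = FALSE]
  y <- study$values[, !cs, drop = FALSE]
  n1 <- ncol(x); n2 <- ncol(y)
  if (n1 < 2 || n2 < 2) stopf("need >= 2 samples per group")
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- rowSums((x - m1)^2) / (n1 - 1)
  v2 <- rowSums((y - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  p[se2 == 0 & m1 == m2] <- 1       # degenerate: no variance, no difference
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  names(p) <- rownames(study$values)
  p
}

#' maxP meta-analytic p-value combination
#'
#' The combined p-value is the maximum of the per-study p-values, so a
#' gene is significant only if significant in every study.
#'
#' @param p numeric vector (one gene) or genes-by-studies matrix of
#'   per-study p-values.
#' @return combined p (scalar or per-gene vector), \code{>=} every input.
#' @export
maxp_combine <- function(p) {
  if (length(p) == 0) stopf("empty p-value vector")
  if (is.matrix(p)) apply(p, 1, max) else max(p)
}

#' Cross-study gene score table
#'
#' Runs the full scoring chain on a study collection restricted to its
#' common genes: per-study log2 fold change, absolute-fold-change ranks,
#' GWRS, weighted GWGS, per-study Welch p-values, maxP combination, mean
#' log2FC, and the signature-selection flag.
#'
#' @param studies list of \code{\link{expression_study}} objects.
#' @param weights per-study weights (default: the studies' own weights,
#'   normalised; equal by default).
#' @param fc_threshold,p_threshold selection thresholds (strict
#'   inequalities), defaults 2 and 0.01.
#' @return a data.frame (class \code{gene_score_table}) with one row per
#'   common gene: \code{gene}, per-study \code{log2fc_*}, \code{rank_*},
#'   \code{gwrs_*}, \code{p_*} columns, then \code{gwgs},
#'   \code{mean_log2fc}, \code{maxp}, \code{selected}, \code{direction};
#'   sorted by decreasing GWGS.
#' @export
compute_gene_scores <- function(studies, weights = NULL,
                                fc_threshold = 2, p_threshold = 0.01) {
  fc <- filter_common_genes(studies)
  studies <- fc$studies
  genes <- fc$genes
  m <- length(genes)
  n <- length(studies)
  if (is.null(weights)) weights <- vapply(studies, `[[`, numeric(1), "weight")
  weights <- weights / sum(weights)
  fcs <- sapply(studies, fold_change)
  ps <- sapply(studies, per_study_pvalue)
  ranks <- sapply(seq_len(n), function(j) rank_genes(fcs[, j], ps[, j]))
  scores <- gwrs(ranks, m)
  S <- gwgs(scores, weights)
  mean_fc <- rowMeans(fcs)
  maxp <- maxp_combine(ps)
  ids <- vapply(studies, `[[`, character(1), "study_id")
  out <- data.frame(gene = genes, stringsAsFactors = FALSE)
  for (j in seq_len(n)) {
    out[[paste0("log2fc_", ids[j])]] <- fcs[, j]
    out[[paste0("rank_", ids[j])]] <- ranks[, j]
    out[[paste0("gwrs_", ids[j])]] <- scores[, j]
    out[[paste0("p_", ids[j])]] <- ps[, j]
  }
  out$gwgs <- S
  out$mean_log2fc <- mean_fc
  out$maxp <- maxp
  out$selected <- abs(mean_fc) > fc_threshold & maxp < p_threshold
  out$direction <- ifelse(mean_fc > 0, "up", ifelse(mean_fc < 0, "down", "none"))
  out <- out[order(-out$gwgs, out$gene), ]
  rownames(out) <- NULL
  class(out) <- c("gene_score_table", "data.frame")
  out
}

#' Select signature genes from a score table
#'
#' A gene is selected iff \code{|mean_log2fc| > fc_threshold} and
#' \code{maxp < p_threshold} (both strict), and split into up- and
#' down-regulated sets by the sign of the mean log2 fold change.
#'
#' @param table a \code{\link{compute_gene_scores}} result (needs columns
#'   \code{gene}, \code{mean_log2fc}, \code{maxp}).
#' @param fc_threshold,p_threshold strict thresholds.
#' @return list with \code{genes}, \code{up}, \code{down}.
#' @export
select_signatures <- function(table, fc_threshold = 2, p_threshold = 0.01) {
  need <- c("gene", "mean_log2fc", "maxp")
  if (!all(need %in% names(table))) stopf("missing score-table columns")
  sel <- abs(table$mean_log2fc) > fc_threshold & table$maxp < p_threshold
  list(genes = table$gene[sel],
       up = table$gene[sel & table$mean_log2fc > 0],
       down = table$gene[sel & table$mean_log2fc < 0])
}
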
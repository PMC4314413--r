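toy_table <- function() {
  structure(data.frame(node = c("a", "b", "c", "d", "e", "f"),
                       degree = c(5L, 4L, 3L, 2L, 2L, 1L),
                       stress = c(10, 8, 6, 4, 2, 0),
                       betweenness = c(.5, .4, .3, .2, .1, 0),
                       closeness = c(.9, .8, .7, .6, .5, .4),
                       stringsAsFactors = FALSE),
            class = c("centrality_table", "data.frame"))
}

test_that("group_centralities aggregates means and filters absent members", {
  tab <- toy_table()
  expect_message(
    grp <- group_centralities(tab, list(g1 = c("a", "b", "zz"),
                                        g2 = c("c", "d", "e", "f"))),
    "absent")
  expect_equal(grp$summary$mean_degree[grp$summary$group == "g1"], 4.5)
  # partition identity: weighted mean of group means = global mean
  s <- grp$summary
  expect_equal(sum(s$n * s$mean_degree) / sum(s$n), mean(tab$degree))
  one <- group_centralities(tab, list(solo = "c"))
  expect_equal(one$summary$mean_stress, 6)
  expect_warning(group_centralities(tab, list(ghost = "nope")), "excluded")
})

test_that("two-group ANOVA F equals the squared pooled t", {
  tab <- toy_table()
  grp <- group_centralities(tab, list(g1 = c("a", "b", "c"),
                                      g2 = c("d", "e", "f")))
  cmp <- pairwise_anova(grp)
  for (ct in c("degree", "stress", "betweenness", "closeness")) {
    x <- grp$values$g1[[ct]]; y <- grp$values$g2[[ct]]
    tt <- stats::t.test(x, y, var.equal = TRUE)
    row <- cmp[cmp$centrality == ct, ]
    expect_equal(row$F, unname(tt$statistic)^2, tolerance = 1e-9)
    expect_equal(row$p, tt$p.value, tolerance = 1e-9)
  }
  set.seed(55)
  for (i in 1:20) {
    x <- rnorm(sample(3:10, 1)); y <- rnorm(sample(3:10, 1))
    g <- group_centralities(
      structure(data.frame(node = sprintf("n%02d", seq_along(c(x, y))),
                           degree = c(x, y), stress = c(x, y),
                           betweenness = c(x, y), closeness = c(x, y)),
                class = c("centrality_table", "data.frame")),
      list(A = sprintf("n%02d", seq_along(x)),
           B = sprintf("n%02d", length(x) + seq_along(y))))
    row <- pairwise_anova(g)
    tt <- stats::t.test(x, y, var.equal = TRUE)
    expect_equal(row$F[row$centrality == "degree"], unname(tt$statistic)^2,
                 tolerance = 1e-9)
  }
})

test_that("degenerate ANOVA inputs follow the stated conventions", {
  expect_equal(unname(hubnet:::anova_two_group(c(1, 2, 3), c(1, 2, 3))),
               c(0, 1))
  expect_lt(hubnet:::anova_two_group(c(1, 2, 3), c(101, 102, 103))["p"], 1e-6)
  expect_equal(unname(hubnet:::anova_two_group(c(2, 2, 2), c(2, 2, 2))),
               c(0, 1))
})

test_that("group selection follows the stated rule", {
  tab <- toy_table()
  grp <- group_centralities(tab, list(cluster1 = c("a", "b", "c"),
                                      cluster2 = c("d", "e", "f")))
  cmp <- pairwise_anova(grp)
  er <- structure(data.frame(term = c("pwA", "pwB", "pwC"),
                             count = c(3, 3, 3),
                             ease_p = c(1e-5, 2e-3, 0.2),
                             fisher_p = c(1e-6, 1e-3, 0.1),
                             bh_q = c(3e-5, 3e-3, 0.2),
                             tier = c("p01", "p01", "none"),
                             genes = "x", stringsAsFactors = FALSE),
                  class = c("enrichment_table", "data.frame"))
  pwsum <- group_centralities(tab, list(pwA = c("a", "c"), pwB = c("d", "e"),
                                        pwC = c("e", "f")))$summary
  sel <- select_significant_groups(cmp, grp$summary, pwsum, er)
  expect_equal(sel$cluster, "cluster1")
  expect_equal(sel$pathways, c("pwA", "pwB"))     # p01 tier, by mean degree
  sel1 <- select_significant_groups(cmp, grp$summary, pwsum, er,
                                    top_k_pathways = 1)
  expect_equal(sel1$pathways, "pwA")
  # identical groups: no significance anywhere -> empty selection
  same <- group_centralities(tab, list(c1 = c("d", "e"), c2 = c("d", "e")))
  expect_warning(
    sel0 <- select_significant_groups(pairwise_anova(same), same$summary,
                                      pwsum[0, ], er[er$tier == "none", ]),
    "empty")
  expect_null(sel0$cluster)
  # a lone cluster qualifies vacuously
  lone <- group_centralities(tab, list(only = c("a", "b")))
  sel2 <- select_significant_groups(pairwise_anova(lone), lone$summary,
                                    pwsum, er)
  expect_equal(sel2$cluster, "only")
})

test_that("hub subnetwork is the order-invariant intersection", {
  net <- complete_graph(c("B", "C", "Q"))
  gl <- list(g1 = c("A", "B", "C"), g2 = c("B", "C", "D"), g3 = c("C", "B"))
  hub <- hub_subnetwork(gl, net)
  expect_equal(hub$hub_genes, c("B", "C"))
  expect_equal(nrow(hub$induced_edges), 1)
  hub_rev <- hub_subnetwork(rev(gl), net)
  expect_equal(hub_rev$hub_genes, hub$hub_genes)
  same <- hub_subnetwork(list(a = c("B", "C"), b = c("B", "C")), net)
  expect_equal(same$hub_genes, c("B", "C"))
  expect_message(hub_subnetwork(list(a = "A", b = "Z"), net), "empty")
  expect_error(hub_subnetwork(list(a = "A"), net), ">= 2 groups")
})

test_that("pairwise intersection of the bundled pathway gene lists", {
  tab <- read_example_enrichment()
  sets <- lapply(strsplit(tab$genes, ",", fixed = TRUE), sort)
  names(sets) <- tab$term
  cc <- sets[["Cell cycle"]]
  om <- sets[["Oocyte meiosis"]]
  net <- complete_graph(union(cc, om))
  hub <- hub_subnetwork(list(cc = cc, om = om), net)
  # independent brute-force membership scan
  brute <- sort(cc[vapply(cc, function(g) any(om == g), logical(1))])
  expect_equal(hub$hub_genes, brute)
  expect_equal(hub$pairwise[["cc&om"]], brute)
  expect_true(all(c("CDK1", "CCNB1", "ESPL1", "CCNB2", "CDC20", "BUB1")
                  %in% brute))
})

test_that("top_hubs ranks each centrality with deterministic ties", {
  st <- centrality_table(star_graph("hub", sprintf("l%d", 1:5)))
  th <- top_hubs(st, 1)
  expect_true(all(vapply(th[c("degree", "stress", "betweenness", "closeness")],
                         function(x) x == "hub", logical(1))))
  tab <- toy_table()
  full <- top_hubs(tab, 99)   # k > N truncates
  expect_setequal(full$degree, tab$node)
  expect_equal(top_hubs(tab, 3)$common, c("a", "b", "c"))
  g <- rand_connected_graph(15, 0.25, 77)
  ct <- centrality_table(g)
  th3 <- top_hubs(ct, 3)
  or <- oracle_centralities(g)
  expect_equal(th3$stress, or$node[order(-or$stress, or$node)][1:3])
  expect_equal(th3$betweenness, or$node[order(-or$betweenness, or$node)][1:3])
})
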
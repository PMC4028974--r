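# The core score: summed target degree, ranking, quadrants, candidates.

test_that("sum_target_degree sums degrees of in-network targets", {
  star <- star_graph(4)
  deg <- degree_centrality(star)
  tab <- make_itab(rbind(c("miR-1", "HUB"), c("miR-2", "NOT_IN_GRAPH")))
  s1 <- sum_target_degree("miR-1", tab, deg)
  expect_equal(s1$sum_degree, 4)
  expect_equal(s1$n_targets_in_network, 1)
  s2 <- sum_target_degree("miR-2", tab, deg)
  expect_equal(s2$sum_degree, 0)
  expect_equal(s2$n_targets_in_network, 0)
  expect_equal(sum_target_degree("miR-none", tab, deg)$sum_degree, 0)

  # random interactions + random graph equal a lookup-and-sum oracle
  g <- random_test_graph(20, 0.2, seed = 31)
  deg <- degree_centrality(g)
  withr::with_seed(32, {
    pairs <- cbind(paste0("miR-", sample(1:6, 40, TRUE)),
                   sample(c(g$nodes, paste0("OUT", 1:5)), 40, TRUE))
  })
  tab <- make_itab(pairs)
  for (id in unique(tab$mirna)) {
    tg <- unique(tab$gene[tab$mirna == id])
    expect_equal(sum_target_degree(id, tab, deg)$sum_degree,
                 sum(deg[intersect(tg, names(deg))]))
  }
})

test_that("score is additive over disjoint target sets and degree-monotone", {
  g <- random_test_graph(15, 0.3, seed = 41)
  deg <- degree_centrality(g)
  a <- g$nodes[1:4]; b <- g$nodes[5:8]
  tab_ab <- make_itab(cbind("miR-x", c(a, b)))
  tab_a <- make_itab(cbind("miR-x", a))
  tab_b <- make_itab(cbind("miR-x", b))
  expect_equal(sum_target_degree("miR-x", tab_ab, deg)$sum_degree,
               sum_target_degree("miR-x", tab_a, deg)$sum_degree +
                 sum_target_degree("miR-x", tab_b, deg)$sum_degree)

  # raising one target's degree never lowers the score
  v <- a[1]
  g2 <- ppi_graph(edges = rbind(g$edges, c(v, "NEWNODE")), nodes = g$nodes)
  expect_gte(sum_target_degree("miR-x", tab_a, degree_centrality(g2))$sum_degree,
             sum_target_degree("miR-x", tab_a, deg)$sum_degree)
})

test_that("published fixture ranks as printed", {
  r <- replay_fixture(table3_fixture())
  expect_equal(nrow(r), 25)
  expect_equal(r$mirna[r$rank == 1], "hsa-miR-1")
  expect_equal(r$sum_degree[r$rank == 1], 1330)
  expect_equal(r$sum_degree[r$rank == 5], 1194)
  expect_equal(r$mirna[r$rank == 5], "hsa-miR-125b")

  # under a fixed threshold of 200, miR-21 (fold 0.26, degree 1302) falls in
  # the high-connectivity suppressor quadrant
  r200 <- replay_fixture(table3_fixture(), degree_threshold(200))
  expect_equal(r200$quadrant[r200$mirna == "hsa-miR-21"], "high-supp")
  expect_equal(r200$quadrant[r200$mirna == "hsa-miR-34a"], "high-onco")

  # equal sum_degree ties break by miRNA id ascending
  tied <- r$mirna[r$sum_degree == 263]
  expect_equal(tied, c("hsa-miR-27b", "hsa-miR-7"))
})

test_that("candidate selection is a strict threshold ordered by rank", {
  r <- replay_fixture(table3_fixture())
  top <- select_candidates(r, 1000)
  expect_equal(top, c("hsa-miR-1", "hsa-miR-21", "hsa-miR-124",
                      "hsa-miR-34a", "hsa-miR-125b"))
  expect_equal(select_candidates(r, 0), r$mirna[order(r$rank)])
  expect_equal(select_candidates(r, max(r$sum_degree)), character(0))
})

test_that("rank_mirnas scores only dysregulated miRNAs with mean threshold", {
  g <- star_graph(4)
  deg <- degree_centrality(g)
  tab <- make_itab(rbind(c("miR-1", "HUB"), c("miR-2", "LEAF1"),
                         c("miR-3", "LEAF2")))
  fct <- structure(
    data.frame(mirna = c("miR-1", "miR-2", "miR-3"),
               fc_consensus = c(4, 0.2, 1.2),
               log10_fc = log10(c(4, 0.2, 1.2)), n_replicates = 2,
               dysregulated = c(TRUE, TRUE, FALSE),
               reg_class = c("oncomiR", "suppressor", "oncomiR"),
               flag = "", stringsAsFactors = FALSE),
    class = c("fold_change_table", "data.frame"), fc_cap = 2^12)
  r <- rank_mirnas(fct, tab, deg)
  expect_equal(nrow(r), 2) # miR-3 not dysregulated
  expect_equal(r$mirna[r$rank == 1], "miR-1")
  expect_equal(attr(r, "threshold")$value, mean(c(4, 1)))
  expect_equal(r$quadrant, c("high-onco", "low-supp"))

  empty <- fct[fct$dysregulated == "never", ]
  expect_warning(r0 <- rank_mirnas(empty, tab, deg), "no dysregulated")
  expect_equal(nrow(r0), 0)
})

test_that("a fold floored at zero stays in the ranking at the capped log", {
  fx <- data.frame(mirna = c("hsa-miR-125b", "hsa-miR-1"),
                   fold = c(0, 8.53), mir2disease_flag = c("Yes", "No"),
                   sum_degree = c(1194, 1330))
  r <- replay_fixture(fx, degree_threshold(200))
  expect_equal(r$log10_fc[r$mirna == "hsa-miR-125b"], -log10(2^12))
  expect_equal(r$quadrant[r$mirna == "hsa-miR-125b"], "high-supp")
})

test_that("quadrant plot data carries the reference lines", {
  r <- replay_fixture(table3_fixture())
  qd <- export_quadrant_plot_data(r)
  expect_equal(nrow(qd), 25)
  expect_equal(attr(qd, "vline"), 0)
  expect_equal(attr(qd, "hline"), mean(r$sum_degree))
  expect_equal(attr(qd, "hline"), attr(r, "threshold")$value)

  r0 <- suppressWarnings(replay_fixture(fx <- data.frame(
    mirna = character(), fold = numeric(), mir2disease_flag = character(),
    sum_degree = numeric())))
  expect_equal(nrow(export_quadrant_plot_data(r0)), 0)

  pf <- tempfile(fileext = ".png")
  grDevices::png(pf)
  d <- plot_quadrants(r)
  grDevices::dev.off()
  expect_equal(nrow(d), 25)
})

test_that("hub-targeting miRNAs outscore uniform ones on synthetic truth", {
  spec <- synthetic_spec(n_nodes = 500, n_mirnas = 40, targets_per_mirna = 10,
                         seed = 77)
  g <- generate_ppi(spec)
  deg <- degree_centrality(g)
  hub <- assign_targets(g, spec, alpha = 1, mirna_prefix = "hub-miR-", seed = 78)
  uni <- assign_targets(g, spec, alpha = 0, mirna_prefix = "uni-miR-", seed = 79)
  score <- function(tab) {
    vapply(unique(tab$mirna), function(id) {
      sum_target_degree(id, tab, deg)$sum_degree
    }, numeric(1))
  }
  sh <- score(hub); su <- score(uni)
  expect_gt(mean(sh), mean(su))
  expect_lt(permutation_test(sh, su, n_perm = 999, seed = 80), 0.05)
})
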
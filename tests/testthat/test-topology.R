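# Network statistics: hand-checkable small graphs first, then equivalence
# against the brute-force oracles on seeded random instances.

path_graph <- function() {
  hon_graph(data.frame(from = c("a|", "b|"), to = c("b|", "c|"), weight = 1))
}

complete_graph <- function(n) {
  pairs <- expand.grid(from = seq_len(n), to = seq_len(n))
  pairs <- pairs[pairs$from != pairs$to, ]
  hon_graph(data.frame(from = sprintf("v%d|", pairs$from),
                       to = sprintf("v%d|", pairs$to), weight = 1))
}

test_that("degree records count distinct directed edges", {
  g <- hon_graph(data.frame(from = "a|", to = "b|", weight = 5))
  d <- degree_metrics(g)
  expect_equal(d$records[d$records$node == "a|", c("in_degree", "out_degree",
                                                   "all_degree")],
               data.frame(in_degree = 0, out_degree = 1, all_degree = 1),
               ignore_attr = TRUE)
  expect_equal(d$average_degree, 1)  # 2 * 1 / 2

  rules <- extract_rules(demo_chains())
  hon <- build_network(rules, attr(rules, "table"))
  rec <- degree_metrics(hon)$records
  a1h05 <- rec[rec$node == "A1|H05", ]
  expect_equal(c(a1h05$in_degree, a1h05$out_degree, a1h05$all_degree),
               c(1, 1, 2))
  # conservation: sum in = sum out = E
  expect_equal(sum(rec$in_degree), nrow(hon$edges))
  expect_equal(sum(rec$out_degree), nrow(hon$edges))
})

test_that("average degree follows the 2E/N convention", {
  g <- random_hon(243, 545, seed = 61)
  expect_equal(round(degree_metrics(g)$average_degree, 2), 4.49)
})

test_that("cumulative degree distribution is non-increasing from 1", {
  recs <- data.frame(node = letters[1:4], all_degree = c(1, 1, 2, 4))
  cd <- cumulative_degree_distribution(recs)
  expect_equal(cd$k, c(1, 2, 4))
  expect_equal(cd$p, c(1.0, 0.5, 0.25))

  one <- cumulative_degree_distribution(data.frame(node = "a", all_degree = 2))
  expect_equal(one, data.frame(k = 2, p = 1.0))

  g <- random_hon(40, 120, seed = 62)
  cd2 <- cumulative_degree_distribution(degree_metrics(g)$records)
  expect_equal(cd2$p[1], 1.0)
  expect_true(all(diff(cd2$p) <= 0))
})

test_that("power-law fit recovers an exact generating curve", {
  k <- 1:10
  fit <- fit_degree_distribution(data.frame(k = k, p = 2 * k^-1.5))
  expect_equal(fit$coefficient, 2, tolerance = 1e-9)
  expect_equal(fit$exponent, -1.5, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1.0, tolerance = 1e-9)
})

test_that("fit stays within contract on noisy and degenerate inputs", {
  set.seed(63)
  k <- 1:30
  p <- 1.8 * k^-1.2 * exp(rnorm(30, sd = 0.01))
  fit <- fit_degree_distribution(data.frame(k = k, p = p))
  expect_equal(fit$exponent, -1.2, tolerance = 0.05)
  expect_true(fit$r_squared >= 0 && fit$r_squared <= 1)
  expect_true(fit$exponential$r_squared >= 0 &&
              fit$exponential$r_squared <= 1)

  # a star exposes only two distinct degrees: not enough points to fit
  star <- hon_graph(data.frame(from = "hub|", to = sprintf("s%d|", 1:10),
                               weight = 1))
  cd <- cumulative_degree_distribution(degree_metrics(star)$records)
  expect_error(fit_degree_distribution(cd), "3 usable")
  # three distinct degrees suffice and keep R2 in range
  mixed <- random_hon(12, 30, seed = 630)
  cd2 <- cumulative_degree_distribution(degree_metrics(mixed)$records)
  fit2 <- fit_degree_distribution(cd2)
  expect_true(fit2$r_squared >= 0 && fit2$r_squared <= 1)
})

test_that("path metrics average over reachable ordered pairs", {
  pm <- path_metrics(path_graph())
  expect_equal(pm$average_path_length, 4 / 3)
  expect_equal(pm$diameter, 2)
  expect_equal(pm$reachable_pairs, 3L)

  k4 <- path_metrics(complete_graph(4))
  expect_equal(k4$average_path_length, 1)
  expect_equal(k4$diameter, 1)

  lonely <- hon_graph(data.frame(from = "a|", to = "b|", weight = 1))
  lonely$edges <- lonely$edges[0, ]
  expect_warning(pm0 <- path_metrics(lonely), "edgeless")
  expect_equal(pm0, list(average_path_length = 0, diameter = 0,
                         reachable_pairs = 0L))
})

test_that("clustering handles the canonical extremes", {
  tri <- hon_graph(data.frame(from = c("a|", "b|", "c|"),
                              to = c("b|", "c|", "a|"), weight = 1))
  expect_equal(clustering_coefficient(tri), 1.0)
  star <- hon_graph(data.frame(from = "hub|", to = sprintf("s%d|", 1:5),
                               weight = 1))
  expect_equal(clustering_coefficient(star), 0.0)
})

test_that("betweenness normalizes by (N-1)(N-2) with endpoints excluded", {
  bc <- betweenness_centrality(path_graph())
  expect_equal(bc$betweenness[bc$node == "b|"], 0.5)
  expect_equal(bc$betweenness[bc$node != "b|"], c(0, 0))
  expect_true(all(betweenness_centrality(complete_graph(4))$betweenness == 0))
})

test_that("k-core peeling matches hand-computed cluster values", {
  # triangle plus a pendant vertex
  g <- hon_graph(data.frame(from = c("a|", "b|", "c|", "c|"),
                            to = c("b|", "c|", "a|", "d|"), weight = 1))
  kc <- kcore_table(g)
  core <- setNames(kc$records$cluster_value, kc$records$node)
  expect_equal(core[c("a|", "b|", "c|", "d|")],
               c(`a|` = 2, `b|` = 2, `c|` = 2, `d|` = 1))
  tab <- kc$table
  expect_equal(tab$cluster, c(1, 2))
  expect_equal(tab$freq, c(1L, 3L))
  expect_equal(tab$freq_pct, c(25.00, 75.00))
  expect_equal(tab$cum_freq, c(1L, 4L))
  expect_equal(tab$cum_pct, c(25.00, 100.00))
})

test_that("cluster frequency table reproduces the published arithmetic", {
  tab <- cluster_frequency_table(c(`1` = 58L, `2` = 109L, `3` = 26L,
                                   `4` = 18L, `5` = 14L, `6` = 18L))
  expect_equal(tab$freq_pct[tab$cluster == 2], 44.86)
  expect_equal(tab$cum_freq[tab$cluster == 2], 167L)
  expect_equal(tab$cum_pct[tab$cluster == 2], 68.72)
  expect_equal(tab$freq_pct[tab$cluster == 6], 7.41)
  expect_equal(tab$cum_freq[nrow(tab)], 243L)
  expect_equal(tab$cum_pct[nrow(tab)], 100.00)
})

test_that("edgeless graphs get core number zero", {
  lonely <- hon_graph(data.frame(from = "a|", to = "b|", weight = 1))
  lonely$edges <- lonely$edges[0, ]
  kc <- kcore_table(lonely)
  expect_true(all(kc$records$cluster_value == 0))
  expect_equal(nrow(kc$table), 1L)
})

test_that("every reported K-core is internally K-connected", {
  g <- random_hon(40, 130, seed = 64)
  kc <- kcore_table(g)$records
  A <- hon_adjacency(g)
  U <- oracle_undirect(A)
  for (K in unique(kc$cluster_value)) {
    if (K == 0) next
    members <- kc$node[kc$cluster_value >= K]
    sub <- U[members, members, drop = FALSE]
    expect_true(all(rowSums(sub) >= K))
  }
})

test_that("random baseline is seeded, exact-size and reproducible", {
  b <- random_baseline(10, 90, seed = 65)
  expect_equal(b$paths$diameter, 1)           # forced complete digraph
  expect_equal(b$clustering_coefficient, 1.0)
  expect_equal(b$average_degree, 18)
  b2 <- random_baseline(50, 200, seed = 66)
  b3 <- random_baseline(50, 200, seed = 66)
  expect_identical(b2, b3)
  expect_error(random_baseline(5, 21, seed = 1), "ordered pairs")
})

test_that("baseline undirected density concentrates near M over the pair count", {
  dens <- sapply(1:50, function(s) {
    b <- random_baseline(243, 545, seed = 600 + s)
    b$n_undirected_edges / (243 * 242 / 2)
  })
  # reciprocal pairs are rare, so the undirected density sits just below
  # 545 / 29403 ~ 0.0185
  expect_equal(mean(dens), 0.0185, tolerance = 0.1)
  expect_true(mean(dens) <= 545 / (243 * 242 / 2))
})

test_that("implementation equals brute-force oracles on random graphs", {
  set.seed(67)
  sizes <- sample(30:50, 8, replace = TRUE)
  for (i in seq_along(sizes)) {
    n <- sizes[i]
    m <- sample(seq(2 * n, 4 * n), 1)
    g <- random_hon(n, m, seed = 670 + i)
    A <- hon_adjacency(g)

    pm <- path_metrics(g)
    om <- oracle_path_metrics(A)
    expect_equal(pm$average_path_length, om$average_path_length,
                 tolerance = 1e-9)
    expect_equal(pm$diameter, om$diameter)
    expect_equal(pm$reachable_pairs, om$reachable_pairs)

    expect_equal(clustering_coefficient(g), oracle_clustering(A),
                 tolerance = 1e-9)

    bc <- betweenness_centrality(g)
    expect_equal(bc$betweenness[match(rownames(A), bc$node)],
                 oracle_betweenness(A), tolerance = 1e-9)

    kc <- kcore_table(g)$records
    expect_equal(kc$cluster_value[match(rownames(A), kc$node)],
                 oracle_coreness(A))
  }
})

test_that("removing the top-degree node never raises another's degree", {
  g <- random_hon(40, 150, seed = 68)
  rec <- degree_metrics(g)$records
  top <- rec$node[1]
  keep <- g$edges[g$edges$from != top & g$edges$to != top, ]
  g2 <- hon_graph(keep)
  rec2 <- degree_metrics(g2)$records
  common <- intersect(rec$node, rec2$node)
  expect_true(all(rec2$all_degree[match(common, rec2$node)] <=
                  rec$all_degree[match(common, rec$node)]))
})

test_that("topology report assembles consistent counts", {
  g <- build_hon(demo_chains())
  rep <- topology_report(g, seed = 69, baseline_reps = 3)
  expect_equal(rep$n_nodes, 8L)
  expect_equal(rep$n_first_order, 6L)
  expect_equal(rep$n_higher_order, 2L)
  expect_equal(rep$n_edges, 6L)
  expect_equal(rep$average_degree, 2 * 6 / 8)
  kt <- rep$kcore$table
  expect_equal(kt$cum_freq[nrow(kt)], rep$n_nodes)
  expect_equal(kt$cum_pct[nrow(kt)], 100.00)
  expect_equal(rep$baseline$replicates, 3L)
})
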
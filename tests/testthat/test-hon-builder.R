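# Dependency extraction on the two demonstration chains has a fully
# hand-checkable answer: six first-order subpaths, two of them indefinite
# (P = 0.5 out of A1), and two second-order dependencies that resolve the
# ambiguity with probability 1.

test_that("subpath counting enumerates windows at every order", {
  tab <- count_subpaths(demo_chains(), 1)
  expect_s3_class(tab, "subpath_table")
  expect_equal(nrow(tab$counts), 6L)
  expect_true(all(tab$counts$count == 1L))
  expect_true(all(tab$counts$order == 1L))

  tab2 <- count_subpaths(demo_chains(), 2)
  second <- tab2$counts[tab2$counts$order == 2L, ]
  expect_true(any(second$context == "H05" & second$source == "A1" &
                  second$target == "A6" & second$count == 1L))
  expect_true(any(second$context == "H01" & second$source == "A1" &
                  second$target == "V04" & second$count == 1L))
  # order-1 entries are retained alongside
  expect_equal(sum(tab2$counts$order == 1L), 6L)

  expect_equal(nrow(count_subpaths(list(), 1)$counts), 0L)
  expect_error(count_subpaths(demo_chains(), 0), "order")
})

test_that("transfer probabilities implement the frequency ratio", {
  tab <- count_subpaths(demo_chains(), 2)
  base <- transfer_probability(tab, character(0), "A1")
  expect_equal(base$probs[["A6"]], 0.5)
  expect_equal(base$probs[["V04"]], 0.5)
  expect_equal(base$support, 2L)
  ext <- transfer_probability(tab, "H05", "A1")
  expect_equal(ext$probs, c(A6 = 1.0))
  expect_equal(ext$support, 1L)
  # every single-successor prefix normalizes to exactly 1
  for (src in c("H10", "H05", "H01", "V04")) {
    expect_equal(sum(transfer_probability(tab, character(0), src)$probs), 1.0)
    expect_length(transfer_probability(tab, character(0), src)$probs, 1L)
  }
  expect_error(transfer_probability(tab, character(0), "A6"), "A6")
  expect_error(transfer_probability(tab, "V04", "A1"), "A1\\|V04")
})

test_that("KL divergence in bits matches direct evaluation", {
  tab <- count_subpaths(demo_chains(), 2)
  base <- transfer_probability(tab, character(0), "A1")
  expect_equal(kl_divergence(base, base), 0)
  ext <- transfer_probability(tab, "H05", "A1")
  expect_equal(kl_divergence(ext, base), 1.0)

  mk <- function(probs, src = "x") structure(
    list(context = character(0), source = src, probs = probs, support = 10L),
    class = "transition_distribution")
  expect_equal(kl_divergence(mk(c(a = 0.9, b = 0.1)),
                             mk(c(a = 0.5, b = 0.5))),
               0.9 * log2(1.8) + 0.1 * log2(0.2))
  expect_error(kl_divergence(mk(c(zz = 1)), mk(c(a = 1))), "zz")
  expect_error(kl_divergence(mk(c(a = 1), src = "x"), mk(c(a = 1), src = "y")),
               "different sources")
})

test_that("dynamic threshold scales with order and shrinks with support", {
  expect_equal(dynamic_threshold(2, 1, alpha = 0.4), 0.8)
  expect_equal(dynamic_threshold(2, 3, alpha = 0.4), 0.4)
  # monotone: decreasing in support, increasing in order
  expect_true(all(diff(sapply(1:50, function(s) dynamic_threshold(2, s))) < 0))
  expect_lt(dynamic_threshold(2, 10), dynamic_threshold(3, 10))
  # the 1-bit jump at order 2, support 1 clears the default threshold
  expect_gt(1.0, dynamic_threshold(2, 1))
  expect_error(dynamic_threshold(1, 5), "order")
})

test_that("rule extraction reproduces the demonstration dependencies", {
  rules <- extract_rules(demo_chains())
  df <- as.data.frame(rules)
  first <- df[df$order == 1L, ]
  expect_equal(nrow(first), 4L)
  expect_setequal(paste(first$source, first$target),
                  c("H10 H05", "H05 A1", "H01 A1", "V04 A7"))
  expect_true(all(first$probability == 1.0))
  second <- df[df$order == 2L, ]
  expect_equal(nrow(second), 2L)
  expect_setequal(paste0(second$source, "|", second$context, ">", second$target),
                  c("A1|H05>A6", "A1|H01>V04"))
  expect_true(all(second$probability == 1.0))
  # the refined unconditioned transitions are fully superseded
  expect_false(any(first$source == "A1"))
})

test_that("max_order = 1 disables growth entirely", {
  rules <- extract_rules(demo_chains(), max_order = 1)
  expect_true(all(rules$order == 1L))
  expect_equal(nrow(rules), 6L)  # nothing superseded without growth
})

test_that("a purely first-order corpus yields no higher-order rules", {
  for (s in c(101, 102)) {
    chains <- generate_chains(example_chain_model(FALSE), 2000, seed = s)
    rules <- extract_rules(chains)
    expect_equal(sum(rules$order > 1L), 0L)
  }
})

test_that("raising alpha never increases the higher-order node count", {
  chains <- generate_chains(example_chain_model(TRUE), 800, seed = 31)
  counts <- sapply(c(0.05, 0.2, 0.4, 1, 2), function(a) {
    g <- build_hon(chains, alpha = a)
    sum(g$nodes$order > 1L)
  })
  expect_true(all(diff(counts) <= 0))
})

test_that("network wiring matches the demonstration construction", {
  rules <- extract_rules(demo_chains())
  g <- build_network(rules, attr(rules, "table"))
  expect_setequal(g$nodes$name[g$nodes$order == 1L],
                  c("H10|", "H05|", "A6|", "H01|", "V04|", "A7|"))
  expect_setequal(g$nodes$name[g$nodes$order > 1L], c("A1|H05", "A1|H01"))
  ek <- paste(g$edges$from, g$edges$to)
  expect_setequal(ek, c("H10| H05|", "H05| A1|H05", "A1|H05 A6|",
                        "H01| A1|H01", "A1|H01 V04|", "V04| A7|"))
  expect_true(all(g$edges$weight == 1))
})

test_that("rewiring redirects to the deepest context-matching variant", {
  g <- build_network(rewiring_rules())
  ek <- paste(g$edges$from, g$edges$to)
  expect_true("H12| A1|H12" %in% ek)           # into the higher-order variant
  expect_true("A1|H12 V04|A1" %in% ek)         # onward hop follows context
  expect_false("A1|" %in% g$nodes$name)        # isolated first-order node gone
  expect_false("V04|" %in% g$nodes$name)
  expect_true(all(c("V04|A1", "A6|", "A6V12|", "V03|") %in% g$nodes$name))
})

test_that("a rule set without higher-order entries builds the plain graph", {
  rules <- extract_rules(demo_chains(), max_order = 1)
  g <- build_network(rules, attr(rules, "table"))
  expect_true(all(g$nodes$order == 1L))
  proj <- project_first_order(g)
  expect_equal(proj$edges, g$edges)
})

test_that("first-order projection conserves edge weight", {
  rules <- extract_rules(demo_chains())
  g <- build_network(rules, attr(rules, "table"))
  proj <- project_first_order(g)
  ek <- paste(sub("\\|$", "", proj$edges$from),
              sub("\\|$", "", proj$edges$to))
  expect_setequal(ek, c("H10 H05", "H05 A1", "H01 A1", "A1 A6", "A1 V04",
                        "V04 A7"))
  expect_true(all(proj$edges$weight == 1))
  expect_equal(sum(proj$edges$weight), sum(g$edges$weight))

  g2 <- build_hon(generate_chains(example_chain_model(TRUE), 1000, seed = 41))
  expect_equal(sum(project_first_order(g2)$edges$weight),
               sum(g2$edges$weight))
})

test_that("extraction and wiring are deterministic for a fixed corpus", {
  chains <- generate_chains(example_chain_model(TRUE), 500, seed = 51)
  r1 <- extract_rules(chains)
  r2 <- extract_rules(chains)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  g1 <- build_network(r1, attr(r1, "table"))
  g2 <- build_network(r2, attr(r2, "table"))
  expect_identical(g1$nodes, g2$nodes)
  expect_identical(g1$edges, g2$edges)
})

test_that("rules referencing unobserved prefixes fail the consistency check", {
  rules <- extract_rules(demo_chains())
  fake <- as.data.frame(rules)
  fake$target[1] <- "A9"
  expect_error(build_network(fake, attr(rules, "table")), "absent")
})
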
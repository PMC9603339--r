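# Shared fixtures: the two demonstration chains, the rewiring fixture, and
# seeded random graphs for oracle comparisons.

demo_chains <- function() {
  list(parse_chain_line("H10→H05→A01→A06"),
       parse_chain_line("H01→A01→V04→A07"))
}

# Rule set exercising the rewiring steps: one first-order rule H12 -> A1 and
# two higher-order nodes (A1|H12 and V04|A1) with their outgoing rules.
rewiring_rules <- function() {
  data.frame(
    context = c("", "H12", "H12", "A1", "A1"),
    source = c("H12", "A1", "A1", "V04", "V04"),
    target = c("A1", "V03", "V04", "A6", "A6V12"),
    frequency = c(3, 2, 1, 1, 1),
    probability = c(1, 2 / 3, 1 / 3, 0.5, 0.5),
    order = c(1L, 2L, 2L, 2L, 2L),
    stringsAsFactors = FALSE)
}

# random directed simple graph as a hon_graph (all nodes first-order)
random_hon <- function(n, m, seed) {
  set.seed(seed)
  pairs <- expand.grid(from = seq_len(n), to = seq_len(n))
  pairs <- pairs[pairs$from != pairs$to, ]
  pick <- pairs[sample.int(nrow(pairs), m), ]
  hon_graph(data.frame(from = sprintf("n%03d|", pick$from),
                       to = sprintf("n%03d|", pick$to),
                       weight = 1),
            nodes = sprintf("n%03d|", seq_len(n)))
}

# dense adjacency matrix in the row/column order of graph$nodes
hon_adjacency <- function(graph) {
  nm <- graph$nodes$name
  A <- matrix(0L, length(nm), length(nm), dimnames = list(nm, nm))
  for (i in seq_len(nrow(graph$edges))) {
    A[graph$edges$from[i], graph$edges$to[i]] <- 1L
  }
  A
}
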
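# Topological diagnostics of a higher-order causation network: degree
# structure and scale-free fit, shortest-path metrics with a random-graph
# baseline, clustering, betweenness centrality and k-core decomposition.

.as_ig <- function(graph) {
  if (inherits(graph, "hon_graph")) as_igraph(graph) else graph
}

# undirected simple projection: reciprocal/parallel edges collapsed,
# self-loops removed (the convention of the small-world diagnostics)
.undirected_simple <- function(g) {
  igraph::simplify(igraph::as_undirected(g, mode = "collapse"),
                   remove.multiple = TRUE, remove.loops = TRUE)
}

#' Per-node degree metrics
#'
#' Degrees count distinct directed edges (weights are ignored): in-degree,
#' out-degree and their sum. The network-level average all-degree is 2E/N.
#'
#' @param graph A `hon_graph` or igraph object.
#' @return List with `records` (data frame `node`, `in_degree`, `out_degree`,
#'   `all_degree`, sorted by decreasing all-degree then node name) and
#'   `average_degree`.
#' @export
degree_metrics <- function(graph) {
  g <- .as_ig(graph)
  if (igraph::vcount(g) == 0) stop("empty graph", call. = FALSE)
  rec <- data.frame(node = igraph::V(g)$name,
                    in_degree = igraph::degree(g, mode = "in"),
                    out_degree = igraph::degree(g, mode = "out"),
                    stringsAsFactors = FALSE)
  rec$all_degree <- rec$in_degree + rec$out_degree
  rec <- rec[order(-rec$all_degree, rec$node), , drop = FALSE]
  rownames(rec) <- NULL
  list(records = rec,
       average_degree = 2 * igraph::ecount(g) / igraph::vcount(g))
}

#' Cumulative degree distribution
#'
#' For each observed all-degree k, the fraction of nodes whose all-degree is
#' at least k; non-increasing, equal to 1 at the smallest observed degree.
#'
#' @param records The `records` data frame from [degree_metrics()].
#' @return Data frame with columns `k` and `p` = P(K >= k).
#' @export
cumulative_degree_distribution <- function(records) {
  stopifnot(nrow(records) > 0)
  deg <- records$all_degree
  ks <- sort(unique(deg))
  data.frame(k = ks,
             p = vapply(ks, function(k) mean(deg >= k), 0))
}

#' Fit the cumulative degree distribution
#'
#' Primary fit is the power form P(K) ~ c * k^e via least squares on
#' log P against log k; an exponential (semilog) alternative
#' P(K) ~ a * exp(b k) is reported alongside so the better-supported model
#' can be quoted.
#'
#' @param cumdist A [cumulative_degree_distribution()] result (needs at least
#'   3 points with k > 0 and p > 0).
#' @return List of class `distribution_fit` with `coefficient`, `exponent`,
#'   `r_squared` (power fit) and `exponential` (list `coefficient`, `rate`,
#'   `r_squared`).
#' @export
fit_degree_distribution <- function(cumdist) {
  d <- cumdist[cumdist$k > 0 & cumdist$p > 0, , drop = FALSE]
  if (nrow(d) < 3) stop("need at least 3 usable points to fit", call. = FALSE)
  pow <- stats::lm(log(p) ~ log(k), data = d)
  expf <- stats::lm(log(p) ~ k, data = d)
  r2 <- function(m) {
    y <- m$model[[1]]
    sst <- sum((y - mean(y))^2)
    if (sst == 0) return(1)   # zero-variance response: perfect flat fit
    1 - sum(stats::residuals(m)^2) / sst
  }
  structure(list(coefficient = unname(exp(stats::coef(pow)[1])),
                 exponent = unname(stats::coef(pow)[2]),
                 r_squared = r2(pow),
                 exponential = list(
                   coefficient = unname(exp(stats::coef(expf)[1])),
                   rate = unname(stats::coef(expf)[2]),
                   r_squared = r2(expf))),
            class = "distribution_fit")
}

#' @export
print.distribution_fit <- function(x, ...) {
  cat(sprintf("P(K) ~ %.4f * k^%.4f (R2 = %.4f); exponential alt R2 = %.4f\n",
              x$coefficient, x$exponent, x$r_squared,
              x$exponential$r_squared))
  invisible(x)
}

#' Average shortest-path length and diameter
#'
#' Unweighted directed shortest paths over all ordered node pairs; pairs with
#' no connecting path are excluded from the average (their count is implied
#' by `reachable_pairs`), and the diameter is the longest finite shortest
#' path.
#'
#' @param graph A `hon_graph` or igraph object.
#' @return List with `average_path_length`, `diameter`, `reachable_pairs`.
#' @export
path_metrics <- function(graph) {
  g <- .as_ig(graph)
  if (igraph::vcount(g) == 0) stop("empty graph", call. = FALSE)
  if (igraph::ecount(g) == 0) {
    warning("edgeless graph: path metrics are 0", call. = FALSE)
    return(list(average_path_length = 0, diameter = 0, reachable_pairs = 0L))
  }
  d <- igraph::distances(g, mode = "out", weights = NA)
  diag(d) <- Inf
  finite <- d[is.finite(d)]
  list(average_path_length = mean(finite),
       diameter = max(finite),
       reachable_pairs = length(finite))
}

#' Mean local clustering coefficient
#'
#' Watts-Strogatz local clustering averaged over all nodes, computed on the
#' undirected simple projection (reciprocal and parallel edges collapsed,
#' self-loops removed); nodes with fewer than two neighbours contribute 0.
#'
#' @param graph A `hon_graph` or igraph object.
#' @return A number in \[0, 1\].
#' @export
clustering_coefficient <- function(graph) {
  g <- .undirected_simple(.as_ig(graph))
  if (igraph::vcount(g) == 0) stop("empty graph", call. = FALSE)
  mean(igraph::transitivity(g, type = "local", isolates = "zero"))
}

#' Betweenness centrality
#'
#' The share of geodesics between other node pairs that pass through each
#' node, normalized by (N-1)(N-2) for directed graphs (endpoints excluded)
#' so values are comparable across network sizes.
#'
#' @param graph A `hon_graph` or igraph object.
#' @param directed Treat edges as directed (default `TRUE`).
#' @return Data frame with `node`, `betweenness`, sorted by decreasing
#'   betweenness then node name.
#' @export
betweenness_centrality <- function(graph, directed = TRUE) {
  g <- .as_ig(graph)
  if (igraph::vcount(g) == 0) stop("empty graph", call. = FALSE)
  n <- igraph::vcount(g)
  if (!directed) g <- .undirected_simple(g)
  b <- igraph::betweenness(g, directed = directed, weights = NA)
  norm <- if (directed) (n - 1) * (n - 2) else (n - 1) * (n - 2) / 2
  rec <- data.frame(node = igraph::V(g)$name,
                    betweenness = if (n > 2) unname(b) / norm else 0,
                    stringsAsFactors = FALSE)
  rec <- rec[order(-rec$betweenness, rec$node), , drop = FALSE]
  rownames(rec) <- NULL
  rec
}

#' K-core decomposition and cluster-value frequency table
#'
#' Core numbers are obtained by iterative minimum-degree peeling on the
#' undirected simple projection: a node's cluster value K is the largest K
#' such that it belongs to a subgraph in which every node has at least K
#' neighbours. The frequency table lists, per cluster value in ascending
#' order, the node count, percentage (2 decimals), cumulative count and
#' cumulative percentage.
#'
#' @param graph A `hon_graph` or igraph object.
#' @return List with `records` (data frame `node`, `cluster_value`) and
#'   `table` (see [cluster_frequency_table()]).
#' @export
kcore_table <- function(graph) {
  g <- .undirected_simple(.as_ig(graph))
  if (igraph::vcount(g) == 0) stop("empty graph", call. = FALSE)
  core <- igraph::coreness(g)
  rec <- data.frame(node = igraph::V(g)$name, cluster_value = unname(core),
                    stringsAsFactors = FALSE)
  rec <- rec[order(-rec$cluster_value, rec$node), , drop = FALSE]
  rownames(rec) <- NULL
  freq <- table(rec$cluster_value)
  list(records = rec,
       table = cluster_frequency_table(
         stats::setNames(as.integer(freq), names(freq))))
}

#' Cluster-value frequency table
#'
#' @param freq Named integer vector: cluster value -> node count.
#' @return Data frame with columns `cluster`, `freq`, `freq_pct`, `cum_freq`,
#'   `cum_pct` in ascending cluster order; the last row's cumulative count is
#'   the node total and its cumulative percentage 100.00. Percentages are
#'   rounded to 2 decimals.
#' @export
cluster_frequency_table <- function(freq) {
  ord <- order(as.numeric(names(freq)))
  freq <- freq[ord]
  n <- sum(freq)
  cum <- cumsum(freq)
  data.frame(cluster = as.numeric(names(freq)),
             freq = as.integer(freq),
             freq_pct = round(100 * as.integer(freq) / n, 2),
             cum_freq = as.integer(cum),
             cum_pct = round(100 * as.integer(cum) / n, 2))
}

#' Random-network baseline
#'
#' Directed Erdos-Renyi G(N, M) graph — exactly `n_edges` distinct ordered
#' pairs without self-loops, drawn uniformly — matched in scale and average
#' degree to the observed network, with its path metrics, clustering
#' coefficient and average degree. Seeded and reproducible.
#'
#' @param n_nodes,n_edges Size of the graph; `n_edges` at most N(N-1).
#' @param seed Integer RNG seed.
#' @return List with `n_nodes`, `n_edges`, `average_degree`, `paths`,
#'   `clustering_coefficient`, `seed`.
#' @export
random_baseline <- function(n_nodes, n_edges, seed) {
  if (n_edges > n_nodes * (n_nodes - 1)) {
    stop("n_edges exceeds the number of ordered pairs", call. = FALSE)
  }
  set.seed(as.integer(seed))
  g <- igraph::sample_gnm(n_nodes, n_edges, directed = TRUE, loops = FALSE)
  igraph::V(g)$name <- paste0("r", seq_len(n_nodes))
  list(n_nodes = n_nodes, n_edges = n_edges,
       average_degree = 2 * n_edges / n_nodes,
       n_undirected_edges = igraph::ecount(.undirected_simple(g)),
       paths = path_metrics(g),
       clustering_coefficient = clustering_coefficient(g),
       seed = as.integer(seed))
}

#' Full topology report
#'
#' Assembles every network statistic into one report object: node/edge
#' counts split by order, degree records and the cumulative-distribution
#' fit, path metrics, clustering, betweenness, the k-core table, and a
#' random G(N, M) baseline averaged over `baseline_reps` seeded replicates.
#'
#' @param graph A `hon_graph`.
#' @param seed Seed for the baseline replicates.
#' @param baseline_reps Number of baseline graphs (default 10); 0 skips the
#'   baseline.
#' @param directed Directedness flag passed to [betweenness_centrality()].
#' @return An object of class `topology_report`.
#' @export
topology_report <- function(graph, seed = 1L, baseline_reps = 10L,
                            directed = TRUE) {
  stopifnot(inherits(graph, "hon_graph"))
  deg <- degree_metrics(graph)
  cum <- cumulative_degree_distribution(deg$records)
  fit <- tryCatch(fit_degree_distribution(cum), error = function(e) NULL)
  baseline <- NULL
  if (baseline_reps > 0) {
    reps <- lapply(seq_len(baseline_reps), function(i) {
      random_baseline(nrow(graph$nodes), nrow(graph$edges),
                      as.integer(seed) + i - 1L)
    })
    baseline <- list(
      replicates = baseline_reps,
      seed = as.integer(seed),
      average_path_length = mean(vapply(reps, function(r)
        r$paths$average_path_length, 0)),
      diameter = mean(vapply(reps, function(r) r$paths$diameter, 0)),
      clustering_coefficient = mean(vapply(reps, function(r)
        r$clustering_coefficient, 0)),
      average_degree = reps[[1]]$average_degree)
  }
  structure(list(
    n_nodes = nrow(graph$nodes),
    n_first_order = sum(graph$nodes$order == 1L),
    n_higher_order = sum(graph$nodes$order > 1L),
    n_edges = nrow(graph$edges),
    average_degree = deg$average_degree,
    degree_records = deg$records,
    cumulative_distribution = cum,
    fit = fit,
    paths = path_metrics(graph),
    clustering_coefficient = clustering_coefficient(graph),
    centralities = betweenness_centrality(graph, directed = directed),
    kcore = kcore_table(graph),
    baseline = baseline), class = "topology_report")
}

#' @export
print.topology_report <- function(x, ...) {
  cat(summary_text(x), sep = "\n")
  invisible(x)
}
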
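# Exporters and the end-to-end pipeline driver: Pajek .net, CSV tables,
# JSON topology report, deterministic run manifest.

#' Export a graph in Pajek .net format
#'
#' `*Vertices N` with 1-based ids and quoted node labels in the `base|context`
#' notation, then `*Arcs` lines `src dst weight`. Vertices are numbered in
#' sorted label order so output is byte-reproducible.
#'
#' @param graph A `hon_graph`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_pajek <- function(graph, path) {
  stopifnot(inherits(graph, "hon_graph"), nrow(graph$nodes) > 0)
  labels <- sort(graph$nodes$name)
  id <- stats::setNames(seq_along(labels), labels)
  lines <- c(sprintf("*Vertices %d", length(labels)),
             sprintf('%d "%s"', seq_along(labels), labels),
             "*Arcs",
             sprintf("%d %d %g", id[graph$edges$from], id[graph$edges$to],
                     graph$edges$weight))
  writeLines(lines, path)
  invisible(path)
}

#' Read a Pajek .net file back into a graph
#'
#' Supports the dialect written by [export_pajek()].
#'
#' @param path Path to a `.net` file.
#' @return A `hon_graph`.
#' @export
read_pajek <- function(path) {
  lines <- readLines(path, warn = FALSE)
  nv <- as.integer(sub("\\*Vertices\\s+", "", lines[1], ignore.case = TRUE))
  vlines <- lines[2:(1 + nv)]
  labels <- sub('^\\d+\\s+"(.*)"\\s*$', "\\1", vlines)
  arc_at <- which(tolower(trimws(lines)) == "*arcs")
  arcs <- lines[seq_len(length(lines) - arc_at) + arc_at]
  arcs <- arcs[nzchar(trimws(arcs))]
  if (length(arcs) == 0) stop("no arcs in Pajek file", call. = FALSE)
  parts <- do.call(rbind, strsplit(trimws(arcs), "\\s+"))
  hon_graph(data.frame(from = labels[as.integer(parts[, 1])],
                       to = labels[as.integer(parts[, 2])],
                       weight = as.numeric(parts[, 3]),
                       stringsAsFactors = FALSE))
}

#' Export the edge list as CSV
#'
#' @param graph A `hon_graph`.
#' @param path Output path; columns `from,to,weight`.
#' @return `path`, invisibly.
#' @export
export_edgelist <- function(graph, path) {
  utils::write.csv(graph$edges, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

.fmt_pct <- function(x) sprintf("%.2f", x)

#' Human-readable topology summary
#'
#' Deterministic narrative of a [topology_report()]: node and edge counts,
#' average degree, distribution fit, small-world comparison against the
#' random baseline, top-10 degree and betweenness nodes, and the
#' cluster-value table. Ranking ties are broken by node label.
#'
#' @param report A [topology_report()].
#' @return Character vector of lines.
#' @export
summary_text <- function(report) {
  stopifnot(inherits(report, "topology_report"))
  top <- function(df, col, n = 10) utils::head(df, n)
  lines <- c(
    sprintf("Nodes: %d (%d first-order, %d higher-order); edges: %d",
            report$n_nodes, report$n_first_order, report$n_higher_order,
            report$n_edges),
    sprintf("Average degree: %.2f", report$average_degree))
  if (!is.null(report$fit)) {
    lines <- c(lines, sprintf(
      "Cumulative degree distribution: P(K) ~ %.4f * k^%.4f (R2 = %.4f)",
      report$fit$coefficient, report$fit$exponent, report$fit$r_squared))
  }
  lines <- c(lines, sprintf(
    "Average path length: %.2f; diameter: %g (%d reachable pairs)",
    report$paths$average_path_length, report$paths$diameter,
    report$paths$reachable_pairs),
    sprintf("Clustering coefficient: %.4f", report$clustering_coefficient))
  if (is.null(report$baseline)) {
    lines <- c(lines, "Random baseline: not computed")
  } else {
    b <- report$baseline
    lines <- c(lines, sprintf(
      "Random baseline (%d reps, seed %d): path length %.2f, diameter %.1f, clustering %.4f",
      b$replicates, b$seed, b$average_path_length, b$diameter,
      b$clustering_coefficient))
  }
  dtop <- top(report$degree_records)
  lines <- c(lines, "Top degree nodes:",
             sprintf("  %s all=%d (in=%d, out=%d)", dtop$node,
                     dtop$all_degree, dtop$in_degree, dtop$out_degree))
  btop <- top(report$centralities)
  lines <- c(lines, "Top betweenness nodes:",
             sprintf("  %s %.4f", btop$node, btop$betweenness))
  kt <- report$kcore$table
  lines <- c(lines, "Cluster value table (cluster freq freq% cumfreq cum%):",
             sprintf("  %g %d %s %d %s", kt$cluster, kt$freq,
                     .fmt_pct(kt$freq_pct), kt$cum_freq, .fmt_pct(kt$cum_pct)))
  lines
}

#' Serialize a topology report to JSON
#'
#' @param report A [topology_report()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_topology_report <- function(report, path) {
  x <- unclass(report)
  if (!is.null(x$fit)) x$fit <- unclass(x$fit)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}

#' Run the full pipeline: chains in, report bundle out
#'
#' Loads (or generates) a chain corpus, extracts dependency rules, builds the
#' higher-order network, computes the topology report, and writes
#' `rules.csv`, `edges.csv`, `graph.net`, `topology.json`, `degrees.csv`,
#' `betweenness.csv`, `kcore.csv`, `summary.txt` and `manifest.json` under
#' `out_dir`. All randomness flows from `seed`; rerunning with the same
#' inputs produces byte-identical artifacts.
#'
#' @param input Path to a chain file (exactly one of `input` / `model` must
#'   be given).
#' @param model A [chain_model()] or path to a model spec YAML; requires
#'   `n_chains`.
#' @param n_chains Corpus size when generating from `model`.
#' @param out_dir Output directory (created if missing).
#' @param max_order,min_support,alpha Rule-extraction parameters, see
#'   [extract_rules()].
#' @param directed Directedness flag for betweenness.
#' @param baseline_reps Random-baseline replicates (default 10).
#' @param seed Seed for generation and the baseline.
#' @return The [topology_report()], invisibly; artifacts on disk.
#' @export
run_pipeline <- function(input = NULL, model = NULL, n_chains = NULL,
                         out_dir, max_order = 5L, min_support = 1L,
                         alpha = 0.4, directed = TRUE, baseline_reps = 10L,
                         seed = 1L) {
  if (is.null(input) == is.null(model)) {
    stop("exactly one of 'input' and 'model' must be supplied", call. = FALSE)
  }
  if (!is.null(input)) {
    chains <- load_chains(input)
    digest <- unname(tools::md5sum(input))
    source_desc <- input
  } else {
    if (is.character(model)) model <- read_chain_model(model)
    if (is.null(n_chains)) stop("n_chains required with a generator model",
                                call. = FALSE)
    chains <- generate_chains(model, n_chains, seed)
    digest <- sprintf("generated:%d chains, seed %d", n_chains,
                      as.integer(seed))
    source_desc <- "generator model"
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rules <- extract_rules(chains, max_order = max_order,
                         min_support = min_support, alpha = alpha)
  graph <- build_network(rules, attr(rules, "table"))
  report <- topology_report(graph, seed = seed,
                            baseline_reps = baseline_reps,
                            directed = directed)
  write_rules(rules, file.path(out_dir, "rules.csv"))
  export_edgelist(graph, file.path(out_dir, "edges.csv"))
  export_pajek(graph, file.path(out_dir, "graph.net"))
  write_topology_report(report, file.path(out_dir, "topology.json"))
  utils::write.csv(report$degree_records,
                   file.path(out_dir, "degrees.csv"), row.names = FALSE)
  utils::write.csv(report$centralities,
                   file.path(out_dir, "betweenness.csv"), row.names = FALSE)
  utils::write.csv(report$kcore$records,
                   file.path(out_dir, "kcore.csv"), row.names = FALSE)
  writeLines(summary_text(report), file.path(out_dir, "summary.txt"))
  manifest <- list(
    tool = "honcausal",
    version = as.character(utils::packageVersion("honcausal")),
    source = source_desc,
    input_digest = digest,
    n_chains = length(chains),
    parameters = list(max_order = max_order, min_support = min_support,
                      alpha = alpha, directed = directed,
                      baseline_reps = baseline_reps, seed = as.integer(seed)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(report)
}
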
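# Wiring validated dependency rules into the higher-order network: node
# creation, edge redirection to context-matching variants, projection back
# to the plain first-order transition graph.

.node_name <- function(base, context) {
  paste0(base, "|", .ctx_string(context))
}

#' Build the higher-order network from a dependency rule set
#'
#' Construction follows three steps: (a) every first-order rule i -> j
#' contributes nodes `i|`, `j|` and an edge weighted by the rule frequency;
#' (b) every higher-order context with accepted rules becomes one node
#' `i|g` carrying its rules as outgoing edges; (c) rewiring: every edge whose
#' target `j|` has a higher-order variant `j|g` such that `g` matches the
#' history known at the edge's origin (origin base, then origin context) is
#' redirected to the deepest matching variant. First-order nodes left without
#' any incident edge are dropped.
#'
#' @param rules An [extract_rules()] result (or a data frame with the same
#'   columns).
#' @param table Optional [count_subpaths()] table for consistency checking:
#'   every rule prefix must be observed in it.
#' @return An object of class `hon_graph`: list with `nodes` (data frame
#'   `name`, `base`, `context`, `order`) and `edges` (data frame `from`,
#'   `to`, `weight`), plus the provenance `rules`.
#' @export
build_network <- function(rules, table = NULL) {
  rules <- as.data.frame(rules)
  if (!is.null(table)) {
    stopifnot(inherits(table, "subpath_table"))
    key <- paste(table$counts$context, table$counts$source,
                 table$counts$target, sep = "\x1f")
    rk <- paste(rules$context, rules$source, rules$target, sep = "\x1f")
    if (!all(rk %in% key)) {
      stop("rule(s) reference subpaths absent from the frequency table",
           call. = FALSE)
    }
  }
  if (nrow(rules) == 0) {
    return(.hon_graph(data.frame(name = character(0), base = character(0),
                                 context = character(0), order = integer(0)),
                      data.frame(from = character(0), to = character(0),
                                 weight = numeric(0)), rules))
  }

  from <- ifelse(nzchar(rules$context),
                 paste0(rules$source, "|", rules$context),
                 paste0(rules$source, "|"))
  to <- paste0(rules$target, "|")
  edges <- data.frame(from = from, to = to, weight = rules$frequency,
                      stringsAsFactors = FALSE)

  # variant lookup: base factor -> list of context vectors (higher-order only)
  hi <- unique(rules[nzchar(rules$context), c("source", "context")])
  variants <- lapply(split(hi$context, hi$source),
                     function(cxs) lapply(cxs, .unsplit_ctx))

  # rewire each edge to the deepest variant of its target matching the
  # origin's known history (origin base first, then the origin's context)
  origin_ctx <- lapply(rules$context, .unsplit_ctx)
  origin_base <- rules$source
  for (i in seq_len(nrow(edges))) {
    tgt <- rules$target[i]
    vs <- variants[[tgt]]
    if (is.null(vs)) next
    hist <- c(origin_base[i], origin_ctx[[i]])
    best <- NULL
    for (g in vs) {
      if (length(g) <= length(hist) &&
          identical(g, hist[seq_along(g)]) &&
          (is.null(best) || length(g) > length(best))) {
        best <- g
      }
    }
    if (!is.null(best)) edges$to[i] <- .node_name(tgt, best)
  }

  # aggregate parallel edges created by rewiring
  ek <- paste(edges$from, edges$to, sep = "\x1f")
  agg <- tapply(edges$weight, ek, sum)
  parts <- strsplit(names(agg), "\x1f", fixed = TRUE)
  edges <- data.frame(from = vapply(parts, `[[`, "", 1L),
                      to = vapply(parts, `[[`, "", 2L),
                      weight = as.numeric(agg), stringsAsFactors = FALSE)

  node_names <- sort(unique(c(
    edges$from, edges$to,
    ifelse(nzchar(rules$context), paste0(rules$source, "|", rules$context),
           paste0(rules$source, "|")),
    paste0(rules$target, "|"))))
  nodes <- .parse_node_names(node_names)
  # drop first-order nodes with no incident edge after rewiring
  incident <- nodes$name %in% c(edges$from, edges$to)
  nodes <- nodes[incident | nodes$order > 1L, , drop = FALSE]
  nodes <- nodes[nodes$name %in% c(edges$from, edges$to), , drop = FALSE]
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(nodes) <- rownames(edges) <- NULL
  .hon_graph(nodes, edges, rules)
}

.parse_node_names <- function(node_names) {
  base <- sub("\\|.*$", "", node_names)
  ctx <- sub("^[^|]*\\|", "", node_names)
  data.frame(name = node_names, base = base, context = ctx,
             order = ifelse(nzchar(ctx),
                            lengths(strsplit(ctx, ".", fixed = TRUE)) + 1L, 1L),
             stringsAsFactors = FALSE)
}

.hon_graph <- function(nodes, edges, rules = NULL) {
  structure(list(nodes = nodes, edges = edges, rules = rules),
            class = "hon_graph")
}

#' Construct a higher-order graph directly from node/edge tables
#'
#' Mainly for tests and for re-reading exported graphs. Node names use the
#' `base|context` notation (`"A6|"`, `"A1|H05"`, `"A3|V11.V10"`).
#'
#' @param edges Data frame with columns `from`, `to` and optionally `weight`
#'   (default 1).
#' @param nodes Optional character vector of node names to include even when
#'   they have no incident edge.
#' @return A `hon_graph`.
#' @export
hon_graph <- function(edges, nodes = NULL) {
  edges <- as.data.frame(edges)
  if (is.null(edges$weight)) edges$weight <- 1
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  nodes <- .parse_node_names(sort(unique(c(edges$from, edges$to, nodes))))
  edges <- edges[order(edges$from, edges$to), c("from", "to", "weight")]
  rownames(nodes) <- rownames(edges) <- NULL
  .hon_graph(nodes, edges)
}

#' @export
print.hon_graph <- function(x, ...) {
  cat(sprintf("<hon_graph> %d nodes (%d first-order, %d higher-order), %d edges, total weight %g\n",
              nrow(x$nodes), sum(x$nodes$order == 1L),
              sum(x$nodes$order > 1L), nrow(x$edges), sum(x$edges$weight)))
  invisible(x)
}

#' Convert a higher-order graph to an igraph object
#'
#' @param graph A `hon_graph`.
#' @return A directed weighted [igraph::graph] with the same node names.
#' @export
as_igraph <- function(graph) {
  stopifnot(inherits(graph, "hon_graph"))
  igraph::graph_from_data_frame(graph$edges, directed = TRUE,
                                vertices = graph$nodes)
}

#' Project a higher-order graph onto base factors
#'
#' Collapses every node to its base factor and sums edge weights, recovering
#' the plain first-order (memoryless) transition graph. Total edge weight is
#' conserved, so the projection is the natural comparison point against a
#' conventional Markov causation network.
#'
#' @param graph A `hon_graph`.
#' @return A `hon_graph` whose nodes all have empty contexts.
#' @export
project_first_order <- function(graph) {
  stopifnot(inherits(graph, "hon_graph"))
  if (nrow(graph$edges) == 0) return(graph)
  base_of <- stats::setNames(graph$nodes$base, graph$nodes$name)
  from <- paste0(base_of[graph$edges$from], "|")
  to <- paste0(base_of[graph$edges$to], "|")
  key <- paste(from, to, sep = "\x1f")
  agg <- tapply(graph$edges$weight, key, sum)
  parts <- strsplit(names(agg), "\x1f", fixed = TRUE)
  hon_graph(data.frame(from = vapply(parts, `[[`, "", 1L),
                       to = vapply(parts, `[[`, "", 2L),
                       weight = as.numeric(agg), stringsAsFactors = FALSE))
}

#' End-to-end higher-order network construction
#'
#' Convenience wrapper: [extract_rules()] then [build_network()].
#'
#' @inheritParams extract_rules
#' @return A `hon_graph` (the rule set is attached as provenance).
#' @export
build_hon <- function(chains, max_order = 5L, min_support = 1L, alpha = 0.4) {
  rules <- extract_rules(chains, max_order = max_order,
                         min_support = min_support, alpha = alpha)
  build_network(rules, attr(rules, "table"))
}
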
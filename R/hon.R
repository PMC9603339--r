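# Path-dependency extraction: subpath frequencies, transfer probabilities
# (first-order and conditional), the Kullback-Leibler significance test with
# a dynamic threshold, and variable-order rule growth.
#
# Contexts are stored most-recent-predecessor-first, matching the node
# notation "A3|V11.V10" (A3 reached from V11, V11 reached from V10): the
# context vector for that node is c("V11", "V10") and is rendered "V11.V10".

.ctx_string <- function(ctx) paste(ctx, collapse = ".")
.unsplit_ctx <- function(s) if (nzchar(s)) strsplit(s, ".", fixed = TRUE)[[1]] else character(0)

#' Count subpath frequencies at all orders up to `order`
#'
#' Every window of `k + 1` consecutive factors in a chain (k = 1..`order`)
#' contributes one observation: the window's last element is the target, the
#' penultimate the source, and the preceding elements the context. Counts are
#' summed over all chains.
#'
#' @param chains List of [accident_chain()] objects.
#' @param order Maximum context length + 1 to tabulate (>= 1); `order = 1`
#'   counts plain adjacent pairs.
#' @return An object of class `subpath_table`: a list with `counts` (a data
#'   frame with columns `context` (dot-joined, most recent predecessor first,
#'   `""` for first order), `source`, `target`, `count`, `order`) and `order`.
#' @export
count_subpaths <- function(chains, order = 1L) {
  if (order < 1) stop("order must be >= 1", call. = FALSE)
  ctx <- character(0); src <- character(0); tgt <- character(0)
  for (ch in chains) {
    v <- unclass(ch)
    n <- length(v)
    for (k in seq_len(min(order, n - 1L))) {
      w <- k + 1L                       # window length
      for (s in seq_len(n - w + 1L)) {
        win <- v[s:(s + w - 1L)]
        ctx <- c(ctx, .ctx_string(rev(win[seq_len(w - 2L)])))
        src <- c(src, win[w - 1L])
        tgt <- c(tgt, win[w])
      }
    }
  }
  if (length(src) == 0) {
    counts <- data.frame(context = character(0), source = character(0),
                         target = character(0), count = integer(0),
                         order = integer(0), stringsAsFactors = FALSE)
  } else {
    key <- paste(ctx, src, tgt, sep = "\x1f")
    tab <- table(key)
    parts <- strsplit(names(tab), "\x1f", fixed = TRUE)
    parts <- lapply(parts, function(p) if (length(p) == 2L) c("", p) else p)
    counts <- data.frame(
      context = vapply(parts, `[[`, "", 1L),
      source = vapply(parts, `[[`, "", 2L),
      target = vapply(parts, `[[`, "", 3L),
      count = as.integer(tab),
      stringsAsFactors = FALSE)
    counts$order <- ifelse(nzchar(counts$context),
                           lengths(strsplit(counts$context, ".", fixed = TRUE)) + 1L,
                           1L)
    counts <- counts[order(counts$order, counts$context, counts$source,
                           counts$target), , drop = FALSE]
    rownames(counts) <- NULL
  }
  structure(list(counts = counts, order = as.integer(order)),
            class = "subpath_table")
}

#' @export
print.subpath_table <- function(x, ...) {
  cat(sprintf("<subpath_table> %d entries up to order %d\n",
              nrow(x$counts), x$order))
  invisible(x)
}

#' Transfer probability distribution of a (context, source) prefix
#'
#' With an empty context this is the first-order transfer probability
#' P(i -> j) = W(i -> j) / sum_h W(i -> h); with a non-empty context it is the
#' conditional transfer probability of the extended subpath, P(i|g -> j).
#'
#' @param table A [count_subpaths()] result.
#' @param context Character vector of predecessors, most recent first
#'   (`character(0)` for first order).
#' @param source Source factor code.
#' @return An object of class `transition_distribution`: list with `context`,
#'   `source`, `probs` (named, sums to 1) and `support` (total observations).
#' @export
transfer_probability <- function(table, context = character(0), source) {
  stopifnot(inherits(table, "subpath_table"))
  cs <- .ctx_string(context)
  rows <- table$counts[table$counts$context == cs &
                       table$counts$source == source, , drop = FALSE]
  if (nrow(rows) == 0) {
    pre <- if (nzchar(cs)) sprintf("%s|%s", source, cs) else source
    stop(sprintf("no observed successor for prefix '%s'", pre), call. = FALSE)
  }
  support <- sum(rows$count)
  structure(list(context = context, source = source,
                 probs = stats::setNames(rows$count / support, rows$target),
                 support = support),
            class = "transition_distribution")
}

#' @export
print.transition_distribution <- function(x, ...) {
  lab <- if (length(x$context)) paste0(x$source, "|", .ctx_string(x$context)) else x$source
  cat(sprintf("<transition_distribution> %s (support %d)\n", lab, x$support))
  print(round(x$probs, 4))
  invisible(x)
}

#' Kullback-Leibler divergence between transfer distributions (bits)
#'
#' D_KL(extended || base) = sum_j p_ext(j) log2(p_ext(j) / p_base(j)).
#' The extended distribution conditions on more history than the base, so its
#' support is a subset of the base support by construction; a target present
#' in `extended` but absent from `base` indicates a counting bug upstream.
#'
#' @param extended,base [transfer_probability()] results for the same source.
#' @return Non-negative divergence in bits.
#' @export
kl_divergence <- function(extended, base) {
  stopifnot(inherits(extended, "transition_distribution"),
            inherits(base, "transition_distribution"))
  if (!identical(extended$source, base$source)) {
    stop("distributions have different sources", call. = FALSE)
  }
  q <- base$probs[names(extended$probs)]
  if (anyNA(q)) {
    stop(sprintf("target(s) %s of the extended distribution missing from the base: inconsistent counts",
                 paste(names(extended$probs)[is.na(q)], collapse = ", ")),
         call. = FALSE)
  }
  max(0, sum(extended$probs * log2(extended$probs / q)))
}

#' Dynamic significance threshold for context extension
#'
#' delta = alpha * order / log2(1 + support): stricter for deeper contexts,
#' more permissive as the evidence behind the extended context grows. The
#' default scale `alpha = 0.4` accepts a 1-bit divergence at order 2 and
#' support 1 (delta = 0.8).
#'
#' @param order Candidate dependency order (>= 2).
#' @param support Observation count behind the extended context (>= 1).
#' @param alpha Positive scale factor.
#' @return The threshold delta.
#' @export
dynamic_threshold <- function(order, support, alpha = 0.4) {
  stopifnot(order >= 2, support >= 1, alpha > 0)
  alpha * order / log2(1 + support)
}

#' Extract first- and higher-order path-dependency rules
#'
#' First-order rules are the observed adjacent transitions. Contexts are then
#' grown one predecessor at a time: a candidate context of order k is accepted
#' when its support reaches `min_support` and the KL divergence of its
#' successor distribution from the distribution of its (accepted) parent
#' context exceeds [dynamic_threshold()]. Growth proceeds only from accepted
#' contexts and stops at `max_order`, when no extension is significant, or
#' when the accepted distribution is degenerate (a point mass diverges from
#' nothing deeper).
#'
#' Frequencies in the returned rules are residual: traversals captured by an
#' accepted deeper context are subtracted from its parent's rules, and rules
#' left with zero traversals (fully superseded by their refinements) are
#' dropped. Probabilities are the level's full conditional transfer
#' probabilities.
#'
#' @param chains List of [accident_chain()] objects.
#' @param max_order Maximum dependency order to consider (default 5).
#' @param min_support Minimum observation count for a rule (default 1).
#' @param alpha Threshold scale, see [dynamic_threshold()].
#' @return A data frame of class `dependency_rules` with columns `context`
#'   (dot-joined, most recent first, `""` for first order), `source`,
#'   `target`, `frequency`, `probability`, `order`, sorted by (order, source,
#'   context, target).
#' @export
extract_rules <- function(chains, max_order = 5L, min_support = 1L,
                          alpha = 0.4) {
  stopifnot(max_order >= 1, min_support >= 1)
  table <- count_subpaths(chains, max_order)
  cts <- table$counts
  first <- cts[cts$order == 1L, , drop = FALSE]
  rules <- list()
  add_rule <- function(ctx, src, tgt, freq, prob, ord) {
    rules[[length(rules) + 1L]] <<- data.frame(
      context = ctx, source = src, target = tgt, frequency = freq,
      probability = prob, order = ord, stringsAsFactors = FALSE)
  }
  # residual bookkeeping: counts to subtract from a parent's rules, keyed by
  # parent prefix "context\x1fsource" -> named vector of covered counts
  covered <- new.env(parent = emptyenv())
  note_covered <- function(parent_ctx, src, counts) {
    k <- paste(.ctx_string(parent_ctx), src, sep = "\x1f")
    prev <- if (!is.null(covered[[k]])) covered[[k]] else numeric(0)
    for (t in names(counts)) {
      prev[t] <- if (is.na(prev[t])) counts[t] else prev[t] + counts[t]
    }
    covered[[k]] <- prev
  }

  sources <- sort(unique(first$source))
  for (src in sources) {
    base <- transfer_probability(table, character(0), src)
    # first-order rules, min_support filter on the raw frequency
    f <- first[first$source == src & first$count >= min_support, , drop = FALSE]
    for (r in seq_len(nrow(f))) {
      add_rule("", src, f$target[r], f$count[r], base$probs[[f$target[r]]], 1L)
    }
    if (max_order < 2) next
    frontier <- list(list(context = character(0), dist = base))
    for (k in 2:max_order) {
      new_frontier <- list()
      for (node in frontier) {
        # degenerate accepted distribution: nothing deeper can diverge
        if (length(node$dist$probs) < 2L) next
        cand <- cts[cts$order == k & cts$source == src, , drop = FALSE]
        if (nrow(cand) == 0) next
        # candidate contexts extending node$context by one more predecessor
        pc <- .ctx_string(node$context)
        keep <- vapply(cand$context, function(cx) {
          v <- .unsplit_ctx(cx)
          identical(v[seq_len(k - 2L)], node$context) || (k == 2L)
        }, TRUE)
        cand <- cand[keep, , drop = FALSE]
        for (cx in sort(unique(cand$context))) {
          ext <- transfer_probability(table, .unsplit_ctx(cx), src)
          if (ext$support < min_support) next
          dkl <- kl_divergence(ext, node$dist)
          if (dkl > dynamic_threshold(k, ext$support, alpha)) {
            sub <- cand[cand$context == cx, , drop = FALSE]
            for (r in seq_len(nrow(sub))) {
              add_rule(cx, src, sub$target[r], sub$count[r],
                       ext$probs[[sub$target[r]]], k)
            }
            note_covered(node$context, src,
                         stats::setNames(sub$count, sub$target))
            new_frontier[[length(new_frontier) + 1L]] <-
              list(context = .unsplit_ctx(cx), dist = ext)
          }
        }
      }
      frontier <- new_frontier
      if (length(frontier) == 0) break
    }
  }

  out <- if (length(rules)) do.call(rbind, rules) else
    data.frame(context = character(0), source = character(0),
               target = character(0), frequency = integer(0),
               probability = numeric(0), order = integer(0))
  # subtract covered traversals; drop fully superseded rules
  if (nrow(out)) {
    for (i in seq_len(nrow(out))) {
      k <- paste(out$context[i], out$source[i], sep = "\x1f")
      cov <- covered[[k]]
      if (!is.null(cov) && !is.na(cov[out$target[i]])) {
        out$frequency[i] <- out$frequency[i] - cov[[out$target[i]]]
      }
    }
    out <- out[out$frequency > 0, , drop = FALSE]
    out <- out[order(out$order, out$source, out$context, out$target), ,
               drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "params") <- list(max_order = max_order,
                              min_support = min_support, alpha = alpha)
  attr(out, "table") <- table
  class(out) <- c("dependency_rules", "data.frame")
  out
}

#' Write a dependency rule set to CSV
#'
#' @param rules An [extract_rules()] result.
#' @param path Output path; columns `context,source,target,frequency,probability,order`.
#' @return `path`, invisibly.
#' @export
write_rules <- function(rules, path) {
  df <- as.data.frame(rules)[, c("context", "source", "target", "frequency",
                                 "probability", "order")]
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
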
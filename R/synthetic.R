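# Synthetic accident-chain corpora: a first-order Markov backbone with
# planted higher-order overrides, for validating dependency extraction.

.check_dist <- function(p, what) {
  if (length(p) == 0 || is.null(names(p)) || any(!nzchar(names(p)))) {
    stop(sprintf("%s must be a named probability vector", what), call. = FALSE)
  }
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
    stop(sprintf("%s must be non-negative and sum to 1 (got %.12f)",
                 what, sum(p)), call. = FALSE)
  }
  invisible(p)
}

#' Specify a chain-generating model
#'
#' A first-order Markov backbone (`transitions`) optionally overridden by
#' higher-order rules: an override replaces the base transition row whenever
#' the walker's recent history ends with the override's context. The context
#' is given in chronological order and includes the current state as its last
#' element, so `context = c("E02", "A1")` means "at A1, arrived from E02".
#' When several overrides match, the longest context wins — mirroring how
#' deeper dependency rules shadow shallower ones in the network builder.
#'
#' @param states Character vector of state labels (typically canonical factor
#'   codes).
#' @param start Named start-distribution over (a subset of) `states`.
#' @param transitions Row-stochastic matrix with `states` as dimnames; rows
#'   whose state is terminal-only may sum to 0.
#' @param overrides List of `list(context = <chr, length >= 2>, probs =
#'   <named distribution>)`.
#' @param lengths Either a plain integer vector (uniform over its values) or a
#'   named probability vector over lengths; minimum 2. Default uniform over
#'   3:6, matching typical report chain lengths.
#' @param terminals Optional absorbing states: sampling stops upon reaching
#'   one (never before the chain has 2 elements).
#' @return An object of class `chain_model`.
#' @export
chain_model <- function(states, start, transitions, overrides = list(),
                        lengths = 3:6, terminals = character(0)) {
  stopifnot(is.character(states), length(states) >= 2)
  .check_dist(start, "start distribution")
  if (!all(names(start) %in% states)) stop("start names outside states")
  stopifnot(is.matrix(transitions))
  if (is.null(rownames(transitions)) || is.null(colnames(transitions))) {
    stop("transitions must have state dimnames", call. = FALSE)
  }
  for (s in rownames(transitions)) {
    row <- transitions[s, ]
    row <- row[row > 0]
    if (length(row) > 0 && !(s %in% terminals)) {
      .check_dist(row, sprintf("transition row '%s'", s))
    }
  }
  for (ov in overrides) {
    if (length(ov$context) < 2) {
      stop("override contexts need length >= 2 (history incl. current state)",
           call. = FALSE)
    }
    if (!ov$context[length(ov$context)] %in% rownames(transitions)) {
      stop("override context must end in a state with a base transition row",
           call. = FALSE)
    }
    .check_dist(ov$probs, "override distribution")
  }
  if (is.null(names(lengths))) {
    lengths <- stats::setNames(rep(1 / length(lengths), length(lengths)),
                               as.character(lengths))
  }
  .check_dist(lengths, "length distribution")
  if (any(as.integer(names(lengths)) < 2)) stop("minimum chain length is 2")
  structure(list(states = states, start = start, transitions = transitions,
                 overrides = overrides, lengths = lengths,
                 terminals = terminals),
            class = "chain_model")
}

#' @export
print.chain_model <- function(x, ...) {
  cat(sprintf("<chain_model> %d states, %d override(s), %d terminal(s)\n",
              length(x$states), length(x$overrides), length(x$terminals)))
  invisible(x)
}

.sample_named <- function(p) {
  names(p)[sample.int(length(p), 1L, prob = p)]
}

# deepest matching override for the given chronological history, else NULL
.match_override <- function(model, history) {
  best <- NULL
  best_len <- 0L
  for (ov in model$overrides) {
    k <- length(ov$context)
    if (k > best_len && k <= length(history) &&
        identical(history[(length(history) - k + 1L):length(history)],
                  ov$context)) {
      best <- ov
      best_len <- k
    }
  }
  best
}

#' Generate a synthetic chain corpus
#'
#' Each chain draws its target length, a start state, and then iterates:
#' sample the next state from the deepest override whose context matches the
#' history so far, falling back to the base transition row. Sampling stops at
#' the target length, at a terminal state (once the chain has >= 2 elements),
#' or when the current state has no successors.
#'
#' @param model A [chain_model()].
#' @param n_chains Number of chains (>= 1).
#' @param seed Integer RNG seed; identical `(model, n_chains, seed)` yield an
#'   identical corpus.
#' @return List of [accident_chain()] objects.
#' @export
generate_chains <- function(model, n_chains, seed) {
  stopifnot(inherits(model, "chain_model"), n_chains >= 1)
  set.seed(as.integer(seed))
  len_vals <- as.integer(names(model$lengths))
  chains <- vector("list", n_chains)
  for (i in seq_len(n_chains)) {
    L <- len_vals[sample.int(length(len_vals), 1L, prob = model$lengths)]
    chain <- .sample_named(model$start)
    while (length(chain) < L) {
      cur <- chain[length(chain)]
      if (length(chain) >= 2L && cur %in% model$terminals) break
      ov <- .match_override(model, chain)
      row <- if (!is.null(ov)) ov$probs else {
        r <- model$transitions[cur, ]
        r[r > 0]
      }
      if (length(row) == 0) break
      chain <- c(chain, .sample_named(row))
    }
    if (length(chain) < 2L) {
      # start state with no successors: force one more draw from start row
      stop(sprintf("state '%s' cannot begin a chain (no successors)",
                   chain[1]), call. = FALSE)
    }
    chains[[i]] <- accident_chain(chain)
  }
  chains
}

#' Fit an empirical chain model to a corpus
#'
#' Maximum-likelihood start, length and first-order transition estimates;
#' for `order >= 2`, every observed context of length 2..`order` (history
#' including the current state) becomes an override carrying its empirical
#' successor distribution. Useful for simulation round-trips.
#'
#' @param chains Non-empty list of [accident_chain()] objects.
#' @param order Model order (>= 1).
#' @return A [chain_model()].
#' @export
model_from_chains <- function(chains, order = 1L) {
  if (length(chains) == 0) stop("no chains supplied", call. = FALSE)
  if (order < 1) stop("order must be >= 1", call. = FALSE)
  states <- sort(unique(unlist(lapply(chains, unclass))))
  starts <- vapply(chains, function(ch) ch[[1]], "")
  start <- table(starts) / length(starts)
  start <- stats::setNames(as.numeric(start), names(start))
  lens <- table(vapply(chains, length, 0L)) / length(chains)
  lengths <- stats::setNames(as.numeric(lens), names(lens))
  trans <- matrix(0, length(states), length(states),
                  dimnames = list(states, states))
  for (ch in chains) {
    v <- unclass(ch)
    for (j in seq_len(length(v) - 1L)) {
      trans[v[j], v[j + 1L]] <- trans[v[j], v[j + 1L]] + 1
    }
  }
  rs <- rowSums(trans)
  trans[rs > 0, ] <- trans[rs > 0, , drop = FALSE] / rs[rs > 0]
  overrides <- list()
  if (order >= 2) {
    tab <- count_subpaths(chains, order)
    cts <- tab$counts[tab$counts$order >= 2, , drop = FALSE]
    if (nrow(cts) > 0) {
      key <- paste(cts$context, cts$source, sep = "\x1f")
      for (k in unique(key)) {
        sub <- cts[key == k, , drop = FALSE]
        # stored context is most-recent-first; chronological = reverse
        ctx <- c(rev(.unsplit_ctx(sub$context[1])), sub$source[1])
        probs <- stats::setNames(sub$count / sum(sub$count), sub$target)
        overrides[[length(overrides) + 1L]] <-
          list(context = ctx, probs = probs)
      }
    }
  }
  chain_model(states, start, trans, overrides, lengths)
}

#' Read / write a chain-model specification file
#'
#' YAML with keys `states`, `start`, `transitions` (nested maps of positive
#' probabilities), `overrides` (list of `context` / `probs`), `lengths`, and
#' optional `terminals`.
#'
#' @param path File path.
#' @return For `read_chain_model`, a [chain_model()].
#' @export
read_chain_model <- function(path) {
  y <- yaml::read_yaml(path)
  states <- as.character(y$states)
  trans <- matrix(0, length(states), length(states),
                  dimnames = list(states, states))
  for (s in names(y$transitions)) {
    for (t in names(y$transitions[[s]])) {
      trans[s, t] <- y$transitions[[s]][[t]]
    }
  }
  overrides <- lapply(y$overrides, function(ov) {
    list(context = as.character(ov$context), probs = unlist(ov$probs))
  })
  chain_model(states,
              start = unlist(y$start),
              transitions = trans,
              overrides = if (is.null(overrides)) list() else overrides,
              lengths = if (is.null(y$lengths)) 3:6 else unlist(y$lengths),
              terminals = as.character(y$terminals))
}

#' @rdname read_chain_model
#' @param model A [chain_model()] to serialize.
#' @export
write_chain_model <- function(model, path) {
  trans <- apply(model$transitions, 1, function(r) as.list(r[r > 0]),
                 simplify = FALSE)
  trans <- trans[vapply(trans, length, 0L) > 0]
  y <- list(states = model$states,
            start = as.list(model$start),
            transitions = trans,
            overrides = lapply(model$overrides, function(ov) {
              list(context = ov$context, probs = as.list(ov$probs))
            }),
            lengths = as.list(model$lengths),
            terminals = model$terminals)
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Reference study models for validation corpora
#'
#' A small road-transport scenario over seven taxonomy codes: rain/snow
#' (E09) leads to slippery roads (E02); fast driving (H03) or a slippery road
#' leads to collision (A1); collisions damage the tank (V04), cause roll-over
#' (A3) or leakage (A6, absorbing). The planted variant adds one second-order
#' dependency: a collision arrived at from a slippery road overwhelmingly
#' rolls the vehicle over — `P(A3 | A1 from E02) = 0.9` versus the base
#' `P(A3 | A1) = 0.3`, a shift of about 1.1 bits of Kullback-Leibler
#' divergence from the corpus-level row. The planted context is kept to a
#' small share (~10%) of collision traffic so that the remaining contexts
#' stay close to the marginal row.
#'
#' @param planted If `TRUE`, include the planted second-order override; if
#'   `FALSE`, return the purely first-order (null) backbone.
#' @return A [chain_model()].
#' @export
example_chain_model <- function(planted = TRUE) {
  states <- c("E09", "E02", "H03", "A1", "A3", "V04", "A6")
  trans <- matrix(0, length(states), length(states),
                  dimnames = list(states, states))
  trans["E09", c("E02", "H03")] <- c(0.8, 0.2)
  trans["E02", "A1"] <- 1
  trans["H03", c("A1", "A3")] <- c(0.7, 0.3)
  trans["A1", c("V04", "A3", "A6")] <- c(0.5, 0.3, 0.2)
  trans["A3", c("V04", "A6")] <- c(0.7, 0.3)
  trans["V04", "A6"] <- 1
  overrides <- if (planted) {
    list(list(context = c("E02", "A1"), probs = c(A3 = 0.9, A6 = 0.1)))
  } else list()
  chain_model(states,
              start = c(H03 = 0.7, E09 = 0.1, A1 = 0.2),
              transitions = trans,
              overrides = overrides,
              lengths = 3:6,
              terminals = "A6")
}
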
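# Chain data model: factor codes, composites, accident chains and chain files.

.family_sizes <- c(H = 12L, V = 16L, HM = 9L, M = 8L, E = 13L, A = 9L)

# compact form: family letters + number without zero padding ("E3", "HM3", "A6")
.compact_code <- function(family, num) paste0(family, num)

.split_token <- function(token) {
  # one atomic token -> list(family, num) or NULL
  m <- regmatches(token, regexec("^(HM|H|V|M|E|A)([0-9]{1,2})$", token))[[1]]
  if (length(m) == 0) return(NULL)
  list(family = m[2], num = as.integer(m[3]))
}

#' Canonicalize a single atomic factor code
#'
#' Zero padding is normalized: accident-type codes canonicalize to the
#' single-digit form (`A01` becomes `A1`), all other families to two-digit
#' zero-padded form (`H1` becomes `H01`). Composite codes are handled by
#' [parse_factor()], not here.
#'
#' @param raw A single atomic factor code such as `"H01"`, `"A01"` or `"HM3"`.
#' @return The canonical registry code.
#' @examples
#' canonicalize_code("A01")  # "A1"
#' canonicalize_code("H1")   # "H01"
#' @export
canonicalize_code <- function(raw) {
  stopifnot(is.character(raw), length(raw) == 1L)
  raw <- trimws(raw)
  if (!nzchar(raw)) stop("empty factor code", call. = FALSE)
  p <- .split_token(raw)
  if (is.null(p)) {
    stop(sprintf("unrecognized factor code '%s'", raw), call. = FALSE)
  }
  if (p$num < 1L || p$num > .family_sizes[[p$family]]) {
    stop(sprintf("factor code '%s' out of range for family %s (1-%d)",
                 raw, p$family, .family_sizes[[p$family]]), call. = FALSE)
  }
  .format_code(p$family, p$num)
}

# Greedy left-to-right tokenizer over compact/padded atomic codes.
# "E3H3" -> c("E03","H03"); "A6HM3" -> c("A6","HM03"). Deterministic: the
# family prefix is matched longest-first (HM before H) and digits greedily.
.tokenize_composite <- function(code) {
  rest <- code
  parts <- character(0)
  while (nzchar(rest)) {
    m <- regmatches(rest, regexec("^(HM|H|V|M|E|A)([0-9]{1,2})", rest))[[1]]
    if (length(m) == 0) {
      stop(sprintf("cannot tokenize factor code '%s' (stuck at '%s')",
                   code, rest), call. = FALSE)
    }
    parts <- c(parts, canonicalize_code(m[1]))
    rest <- substr(rest, nchar(m[1]) + 1L, nchar(rest))
  }
  parts
}

#' Parse a factor code, atomic or composite
#'
#' Atomic codes resolve against the registry. Concatenated codes (used for
#' multi-factor causes acting simultaneously, e.g. `"E3H3"` for a turning road
#' combined with fast driving) yield a composite factor whose parts are the
#' atomic codes in input order. Composite factors are opaque: they are their
#' own network nodes and are never merged with their atomic parts.
#'
#' @param code Factor code string, e.g. `"V12"`, `"E3H3"`, `"A6HM3"`.
#' @return An object of class `causal_factor`: a list with `code` (canonical),
#'   `category` (registry family or `"COMPOSITE"`), `label`, and `parts`
#'   (canonical atomic codes; length 1 for atomic factors).
#' @examples
#' parse_factor("E3H3")$parts    # "E03" "H03"
#' parse_factor("V12")$label     # "Tire overheating"
#' @export
parse_factor <- function(code) {
  stopifnot(is.character(code), length(code) == 1L)
  code <- trimws(code)
  parts <- .tokenize_composite(code)
  reg <- factor_registry()
  if (length(parts) == 1L) {
    row <- reg[reg$code == parts, , drop = FALSE]
    out <- list(code = parts, category = row$category, label = row$label,
                parts = parts)
  } else {
    compact <- vapply(parts, function(p) {
      s <- .split_token(p)
      .compact_code(s$family, s$num)
    }, "")
    labels <- reg$label[match(parts, reg$code)]
    out <- list(code = paste0(compact, collapse = ""),
                category = "COMPOSITE",
                label = paste(labels, collapse = " + "),
                parts = unname(parts))
  }
  class(out) <- "causal_factor"
  out
}

#' @export
print.causal_factor <- function(x, ...) {
  cat(sprintf("<causal_factor> %s [%s] %s\n", x$code, x$category, x$label))
  invisible(x)
}

#' Construct an accident chain
#'
#' An accident chain is the ordered sequence of canonical factor codes that an
#' accident report attributes to one accident, from initiating cause to final
#' consequence. Chains must contain at least two factors (one subpath).
#'
#' @param codes Character vector of canonical factor codes (length >= 2).
#' @param source_id Optional identifier of the originating accident report.
#' @param validate Check codes against the registry/composite grammar
#'   (default `FALSE`: the sampler and internal callers supply pre-canonical
#'   or abstract state labels).
#' @return A character vector of class `accident_chain`.
#' @export
accident_chain <- function(codes, source_id = NULL, validate = FALSE) {
  codes <- as.character(codes)
  if (length(codes) < 2L) {
    stop("an accident chain needs at least 2 factors", call. = FALSE)
  }
  if (any(!nzchar(codes)) || anyNA(codes)) {
    stop("accident chain contains empty elements", call. = FALSE)
  }
  if (validate) codes <- vapply(codes, function(x) parse_factor(x)$code, "")
  structure(unname(codes), class = "accident_chain", source_id = source_id)
}

#' @export
print.accident_chain <- function(x, ...) {
  cat(paste(unclass(x), collapse = "→"), "\n")
  invisible(x)
}

#' Parse one chain line
#'
#' Splits a text line on the arrow delimiter (`→`; the ASCII `->` and
#' `,` dialects are also accepted), parses and canonicalizes every token.
#'
#' @param line A single line of text, e.g. `"H10→H05→A01→A06"`.
#' @return An [accident_chain()].
#' @export
parse_chain_line <- function(line) {
  stopifnot(is.character(line), length(line) == 1L)
  tokens <- strsplit(line, "→|->|,")[[1]]
  tokens <- trimws(tokens)
  tokens <- tokens[nzchar(tokens)]
  if (length(tokens) < 2L) {
    stop(sprintf("chain line '%s' has fewer than 2 factors", line),
         call. = FALSE)
  }
  accident_chain(vapply(tokens, function(t) parse_factor(t)$code, ""))
}

#' Load accident chains from a text file
#'
#' One chain per line, factors separated by arrows; empty lines and lines
#' starting with `#` are ignored.
#'
#' @param path Path to a UTF-8 chain file.
#' @param strict If `TRUE` (default) a malformed line aborts with its line
#'   number; if `FALSE`, malformed lines are skipped with a warning.
#' @return List of [accident_chain()] objects, in file order.
#' @export
load_chains <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop(sprintf("chain file '%s' not found", path),
                               call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#"))
  chains <- list()
  skipped <- 0L
  for (i in keep) {
    parsed <- tryCatch(parse_chain_line(lines[i]), error = function(e) e)
    if (inherits(parsed, "error")) {
      if (strict) {
        stop(sprintf("line %d of '%s': %s", i, path, conditionMessage(parsed)),
             call. = FALSE)
      }
      warning(sprintf("skipping line %d of '%s': %s",
                      i, path, conditionMessage(parsed)), call. = FALSE)
      skipped <- skipped + 1L
    } else {
      chains[[length(chains) + 1L]] <- parsed
    }
  }
  if (length(chains) == 0L) {
    warning(sprintf("no chains parsed from '%s'", path), call. = FALSE)
  }
  message(sprintf("loaded %d chain(s) from '%s' (%d line(s) skipped)",
                  length(chains), path, skipped))
  chains
}

#' Write accident chains to a text file
#'
#' @param chains List of [accident_chain()] objects.
#' @param path Output path; lines use the arrow delimiter.
#' @return `path`, invisibly.
#' @export
write_chains <- function(chains, path) {
  lines <- vapply(chains, function(ch) paste(unclass(ch), collapse = "→"), "")
  writeLines(lines, path, useBytes = FALSE)
  invisible(path)
}
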
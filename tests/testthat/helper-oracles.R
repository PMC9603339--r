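# Brute-force oracles, written independently of the package's igraph-backed
# implementations: Floyd-Warshall distances, explicit geodesic counting for
# betweenness, neighbour-pair triangle counting for clustering, and repeated
# minimum-degree peeling for core numbers. All take a dense 0/1 adjacency
# matrix (directed, no self-loops).

oracle_distances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  D[A == 1L] <- 1
  diag(D) <- 0
  for (k in seq_len(n)) {
    D <- pmin(D, outer(D[, k], D[k, ], "+"))
  }
  D
}

oracle_path_metrics <- function(A) {
  D <- oracle_distances(A)
  diag(D) <- Inf
  finite <- D[is.finite(D)]
  if (length(finite) == 0) {
    return(list(average_path_length = 0, diameter = 0, reachable_pairs = 0L))
  }
  list(average_path_length = mean(finite), diameter = max(finite),
       reachable_pairs = length(finite))
}

# number of geodesics sigma(s, t) for every ordered pair, by dynamic
# programming over increasing path length
oracle_geodesic_counts <- function(A, D) {
  n <- nrow(A)
  S <- matrix(0, n, n)
  diag(S) <- 1
  finite <- which(is.finite(D) & D > 0, arr.ind = TRUE)
  finite <- finite[order(D[finite]), , drop = FALSE]
  for (r in seq_len(nrow(finite))) {
    s <- finite[r, 1]; t <- finite[r, 2]
    w <- which(A[s, ] == 1L & D[, t] == D[s, t] - 1)
    S[s, t] <- sum(S[w, t])
  }
  S
}

oracle_betweenness <- function(A) {
  n <- nrow(A)
  D <- oracle_distances(A)
  S <- oracle_geodesic_counts(A, D)
  bc <- numeric(n)
  for (v in seq_len(n)) {
    for (s in seq_len(n)) {
      if (s == v) next
      for (t in seq_len(n)) {
        if (t == v || t == s || !is.finite(D[s, t])) next
        if (is.finite(D[s, v]) && is.finite(D[v, t]) &&
            D[s, v] + D[v, t] == D[s, t]) {
          bc[v] <- bc[v] + S[s, v] * S[v, t] / S[s, t]
        }
      }
    }
  }
  if (n > 2) bc / ((n - 1) * (n - 2)) else rep(0, n)
}

# undirected simple projection of a directed adjacency
oracle_undirect <- function(A) {
  U <- (A + t(A)) > 0
  diag(U) <- FALSE
  storage.mode(U) <- "integer"
  U
}

oracle_clustering <- function(A) {
  U <- oracle_undirect(A)
  n <- nrow(U)
  cc <- numeric(n)
  for (v in seq_len(n)) {
    nb <- which(U[v, ] == 1L)
    k <- length(nb)
    if (k < 2) next
    links <- sum(U[nb, nb]) / 2
    cc[v] <- 2 * links / (k * (k - 1))
  }
  mean(cc)
}

oracle_coreness <- function(A) {
  U <- oracle_undirect(A)
  n <- nrow(U)
  core <- integer(n)
  for (K in seq_len(n)) {
    alive <- rep(TRUE, n)
    repeat {
      deg <- rowSums(U[, alive, drop = FALSE]) * alive
      drop_v <- alive & deg < K
      if (!any(drop_v)) break
      alive[drop_v] <- FALSE
    }
    if (!any(alive)) break
    core[alive] <- K
  }
  core
}
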
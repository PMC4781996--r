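# Brute-force graph-metric oracles, written independently of the package
# implementation (and of igraph): direct definition-level enumeration,
# intended for small graphs only.

oracle_degree <- function(A) rowSums(A)

oracle_clustering <- function(A) {
  N <- nrow(A)
  Ci <- numeric(N)
  for (i in seq_len(N)) {
    nb <- which(A[i, ] == 1)
    k <- length(nb)
    if (k < 2) next
    e <- 0
    for (a in seq_len(k - 1)) {
      for (b in (a + 1):k) {
        e <- e + A[nb[a], nb[b]]
      }
    }
    Ci[i] <- 2 * e / (k * (k - 1))
  }
  Ci
}

# Floyd-Warshall all-pairs shortest paths
oracle_distances <- function(A) {
  N <- nrow(A)
  D <- matrix(Inf, N, N)
  D[A == 1] <- 1
  diag(D) <- 0
  for (k in seq_len(N)) {
    for (i in seq_len(N)) {
      for (j in seq_len(N)) {
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
      }
    }
  }
  D
}

oracle_path_length <- function(A) {
  D <- oracle_distances(A)
  diag(D) <- NA
  Li <- apply(D, 1, function(d) {
    d <- d[is.finite(d)]
    if (length(d) == 0) NA_real_ else mean(d)
  })
  list(local = Li, global = mean(Li, na.rm = TRUE),
       n_unreachable = sum(is.infinite(D), na.rm = TRUE) / 2)
}

# Enumerate every geodesic between j and k by depth-limited DFS and
# accumulate fractional interior-node counts.
oracle_betweenness <- function(A) {
  N <- nrow(A)
  D <- oracle_distances(A)
  BC <- numeric(N)
  paths_between <- function(from, to, depth) {
    if (from == to) return(list(to))
    if (depth == 0) return(list())
    out <- list()
    for (nb in which(A[from, ] == 1)) {
      if (D[nb, to] == depth - 1) {
        for (p in paths_between(nb, to, depth - 1)) {
          out[[length(out) + 1]] <- c(from, p)
        }
      }
    }
    out
  }
  for (j in seq_len(N - 1)) {
    for (k in (j + 1):N) {
      if (!is.finite(D[j, k]) || D[j, k] == 0) next
      geos <- paths_between(j, k, D[j, k])
      n_geo <- length(geos)
      for (p in geos) {
        interior <- setdiff(p, c(j, k))
        BC[interior] <- BC[interior] + 1 / n_geo
      }
    }
  }
  BC
}

# All labeled connected graphs on n nodes (n <= 5 is practical), as
# adjacency matrices.
enumerate_connected_graphs <- function(n) {
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  n_pairs <- nrow(pairs)
  out <- list()
  for (mask in seq_len(2^n_pairs) - 1L) {
    A <- matrix(0L, n, n)
    bits <- bitwAnd(bitwShiftR(mask, seq_len(n_pairs) - 1L), 1L)
    on <- which(bits == 1L)
    if (length(on)) {
      A[pairs[on, , drop = FALSE]] <- 1L
      A <- A + t(A)
    }
    if (is_connected_adj(A)) out[[length(out) + 1]] <- A
  }
  out
}

is_connected_adj <- function(A) {
  N <- nrow(A)
  seen <- logical(N)
  queue <- 1L
  seen[1] <- TRUE
  while (length(queue)) {
    v <- queue[1]
    queue <- queue[-1]
    nb <- which(A[v, ] == 1 & !seen)
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  all(seen)
}

random_connected_adj <- function(n, p = 0.4) {
  repeat {
    A <- matrix(0L, n, n)
    ut <- upper.tri(A)
    A[ut] <- stats::rbinom(sum(ut), 1L, p)
    A <- A + t(A)
    if (is_connected_adj(A)) return(A)
  }
}

# Wrap an adjacency matrix as the package's binary-graph type.
graph_fixture <- function(A, sparsity = sum(A) / (nrow(A) * (nrow(A) - 1))) {
  dimnames(A) <- list(sprintf("R%03d", seq_len(nrow(A))),
                      sprintf("R%03d", seq_len(nrow(A))))
  scnet:::.scn_graph(A, sparsity, rownames(A))
}

# Small named fixture graphs
adj_complete <- function(n) {
  A <- matrix(1L, n, n); diag(A) <- 0L; A
}
adj_star <- function(n) {
  A <- matrix(0L, n, n); A[1, 2:n] <- 1L; A[2:n, 1] <- 1L; A
}
adj_path <- function(n) {
  A <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) A[i, i + 1] <- A[i + 1, i] <- 1L
  A
}
adj_cycle <- function(n) {
  A <- adj_path(n); A[1, n] <- A[n, 1] <- 1L; A
}
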
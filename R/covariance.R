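#' Ledoit-Wolf shrinkage covariance estimate
#'
#' Computes the well-conditioned covariance estimator
#' \deqn{\hat\Sigma = (1-\lambda) S + \lambda \mu I,}
#' where `S` is the sample covariance (maximum-likelihood, divisor `n`),
#' `mu = trace(S)/P` the scaled-identity target level, and `lambda` the
#' analytically optimal shrinkage intensity clipped to `[0, 1]`.  With a
#' positive intensity the estimate is positive definite even when the
#' number of subjects is far below the number of regions ("small N, large
#' P"), which is the regime of group-level structural covariance networks.
#'
#' @param X Numeric matrix, subjects in rows, regions in columns (typically
#'   a residual matrix from [residualize()]).  Columns are centred
#'   internally.
#' @return A list with `sigma` (the shrunk covariance), `intensity`
#'   (`lambda` in `[0, 1]`), `mu`, and `sample_cov` (`S`).
#' @references Ledoit & Wolf (2004), "A well-conditioned estimator for
#'   large-dimensional covariance matrices", J. Multivariate Analysis 88.
#' @export
#' @examples
#' X <- matrix(rnorm(30 * 10), 30, 10)
#' lw <- ledoit_wolf(X)
#' lw$intensity
ledoit_wolf <- function(X) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  if (n < 2) stop("need at least 2 subjects for covariance estimation")
  Xc <- sweep(X, 2, colMeans(X))
  S <- crossprod(Xc) / n
  mu <- sum(diag(S)) / p
  # squared deviation of S from its shrinkage target, per coordinate
  d2 <- sum((S - diag(mu, p))^2) / p
  if (d2 <= .Machine$double.eps * max(mu^2, 1)) {
    warning("features have (near-)zero variance; returning unshrunk estimate",
            call. = FALSE)
    out <- list(sigma = S, intensity = 0, mu = mu, sample_cov = S)
    return(out)
  }
  # E||x x' - S||^2_F / p, averaged over subjects: uses
  # sum_k ||x_k x_k'||^2_F = sum_k (x_k . x_k)^2
  sq_norms <- rowSums(Xc^2)
  b2_bar <- (sum(sq_norms^2) - n * sum(S^2)) / (n^2 * p)
  b2 <- min(b2_bar, d2)
  lambda <- b2 / d2
  sigma <- (1 - lambda) * S + lambda * diag(mu, p)
  dimnames(sigma) <- dimnames(S)
  list(sigma = sigma, intensity = lambda, mu = mu, sample_cov = S)
}

#' Partial correlation matrix from a covariance estimate
#'
#' Inverts the covariance and standardizes the negative off-diagonal
#' precision entries:
#' `pcor_ij = -Omega_ij / sqrt(Omega_ii Omega_jj)` with `Omega` the
#' precision matrix.  Each entry is the correlation between two regions
#' after removing the linear influence of all other regions.
#'
#' @param sigma Positive-definite covariance matrix (e.g. from
#'   [ledoit_wolf()]).
#' @param labels Optional region labels for the result's dimnames.
#' @param group Optional group label, carried as an attribute.
#' @return An object of class `scn_assoc`: the partial-correlation matrix
#'   (diagonal 1) with attributes `labels` and `group`.
#' @export
partial_correlation <- function(sigma, labels = colnames(sigma),
                                group = NULL) {
  sigma <- as.matrix(sigma)
  omega <- tryCatch(solve(sigma), error = function(e) {
    stop("covariance is singular and cannot be inverted; ",
         "increase shrinkage (inspect the Ledoit-Wolf intensity) ",
         "or check for zero-variance regions", call. = FALSE)
  })
  d <- sqrt(diag(omega))
  pc <- -omega / outer(d, d)
  diag(pc) <- 1
  pc <- (pc + t(pc)) / 2
  if (!is.null(labels)) dimnames(pc) <- list(labels, labels)
  structure(pc, class = c("scn_assoc", "matrix"),
            labels = labels, group = group)
}

#' @export
print.scn_assoc <- function(x, ...) {
  cat(sprintf("Partial-correlation association matrix (%d regions%s)\n",
              nrow(x),
              if (!is.null(attr(x, "group")))
                paste0(", group ", attr(x, "group")) else ""))
  off <- x[upper.tri(x)]
  cat(sprintf("  off-diagonal range [%.3f, %.3f], mean |pcor| %.3f\n",
              min(off), max(off), mean(abs(off))))
  invisible(x)
}

# internal constructor for binary graphs
.scn_graph <- function(adj, sparsity, labels) {
  structure(list(adjacency = adj, sparsity = sparsity,
                 n_nodes = nrow(adj), n_edges = sum(adj) / 2L,
                 labels = labels),
            class = "scn_graph")
}

#' Binarize an association matrix at a given sparsity
#'
#' Ranks the `N(N-1)/2` region pairs by `|pcor|` (strongest first) and
#' keeps the top `floor(s * N(N-1)/2)` as edges of an undirected,
#' unweighted graph; all weaker connections are removed.  Ties at the
#' cut-off are broken deterministically in favour of the lexicographically
#' smaller `(i, j)` pair, so repeated runs give the identical graph.
#'
#' @param assoc An `scn_assoc` matrix (or any symmetric weight matrix).
#' @param s Sparsity in `(0, 1]`: the fraction of possible edges retained.
#' @param positive_only If `TRUE` rank by signed weight instead of
#'   magnitude, so negative partial correlations can never become edges.
#' @return An `scn_graph`: 0/1 adjacency matrix (zero diagonal), sparsity,
#'   node/edge counts, labels.
#' @export
#' @examples
#' S <- make_block_covariance(20, 2, 0.4, 0.02)
#' a <- partial_correlation(S)
#' g <- binarize_at_sparsity(a, 0.1)
#' g$n_edges   # floor(0.1 * 190) = 19
binarize_at_sparsity <- function(assoc, s, positive_only = FALSE) {
  W <- unclass(assoc)
  N <- nrow(W)
  stopifnot(N == ncol(W), s > 0, s <= 1)
  n_pairs <- N * (N - 1L) / 2L
  m <- floor(s * n_pairs)
  if (m < 1) {
    stop(sprintf(
      "sparsity %.4f yields 0 edges on %d nodes; below the estimable range",
      s, N))
  }
  ut <- which(upper.tri(W), arr.ind = TRUE)
  w <- W[upper.tri(W)]
  key <- if (positive_only) w else abs(w)
  ord <- order(-key, ut[, 1], ut[, 2])
  keep <- ord[seq_len(m)]
  adj <- matrix(0L, N, N)
  adj[ut[keep, , drop = FALSE]] <- 1L
  adj <- adj + t(adj)
  labels <- attr(assoc, "labels")
  if (is.null(labels)) labels <- colnames(W)
  if (is.null(labels)) labels <- sprintf("R%03d", seq_len(N))
  dimnames(adj) <- list(labels, labels)
  .scn_graph(adj, s, labels)
}

#' Sweep a range of sparsity thresholds
#'
#' Binarizes one association matrix at every sparsity in
#' `seq(s_min, s_max, by = step)`.  Because all graphs come from the same
#' deterministic edge ranking, edge sets are nested: the graph at a lower
#' sparsity is a subgraph of any graph at a higher sparsity.
#'
#' @inheritParams binarize_at_sparsity
#' @param s_min,s_max,step Sweep bounds and increment; the defaults give
#'   31 graphs from 5% to 35% in steps of 1%.
#' @return Named list of `scn_graph` objects (names are the sparsities).
#' @export
sparsity_sweep <- function(assoc, s_min = 0.05, s_max = 0.35, step = 0.01,
                           positive_only = FALSE) {
  stopifnot(s_min <= s_max, step > 0)
  ss <- seq(s_min, s_max, by = step)
  out <- lapply(ss, function(s)
    binarize_at_sparsity(assoc, s, positive_only = positive_only))
  names(out) <- formatC(ss, format = "f", digits = 4)
  out
}

#' Convert a binary graph to an igraph object
#' @param g An `scn_graph`.
#' @return An undirected `igraph` graph with vertex names.
#' @export
as_igraph <- function(g) {
  stopifnot(inherits(g, "scn_graph"))
  igraph::graph_from_adjacency_matrix(g$adjacency, mode = "undirected",
                                      diag = FALSE)
}

#' @export
print.scn_graph <- function(x, ...) {
  cat(sprintf("Binary graph: %d nodes, %d edges (sparsity %.2f%%)\n",
              x$n_nodes, x$n_edges, 100 * x$sparsity))
  invisible(x)
}
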
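# Graph-theoretic characterization of binary structural covariance
# networks: degree, clustering, characteristic path length, betweenness
# centrality, and betweenness-based hub detection.
#
# Conventions (stated once, used everywhere):
#  * C_i := 0 for nodes of degree < 2 (the defining ratio is 0/0 there).
#  * L_i averages finite distances only; unreachable pairs are excluded
#    and counted, never imputed.  L averages L_i over nodes with at least
#    one reachable partner.
#  * Betweenness uses fractional (Brandes) counting over unordered
#    endpoint pairs, endpoints excluded.

.adjacency_of <- function(g) {
  if (inherits(g, "scn_graph")) g$adjacency
  else if (is.matrix(g)) g
  else stop("expected an scn_graph or adjacency matrix")
}

#' Node degrees
#'
#' Degree of node *i* is the number of links attached to it,
#' `k_i = sum_j a_ij`.
#'
#' @param g An `scn_graph` or 0/1 adjacency matrix.
#' @return Named integer vector of degrees.
#' @export
graph_degree <- function(g) {
  A <- .adjacency_of(g)
  rowSums(A)
}

#' Clustering coefficients
#'
#' `C_i = 2 e_i / (k_i (k_i - 1))`, the fraction of realized links among
#' node *i*'s neighbours (`e_i` counted via the diagonal of `A^3`); the
#' network clustering coefficient `C` is the mean of `C_i` over all `N`
#' nodes.  Nodes with fewer than two neighbours get `C_i = 0`.
#'
#' @inheritParams graph_degree
#' @return List with `local` (per-node `C_i`) and `global` (`C`).
#' @export
graph_clustering <- function(g) {
  A <- .adjacency_of(g)
  k <- rowSums(A)
  # e_i = number of edges among neighbours of i = diag(A^3)/2
  e <- diag(A %*% A %*% A) / 2
  Ci <- ifelse(k < 2, 0, 2 * e / (k * (k - 1)))
  names(Ci) <- rownames(A)
  list(local = Ci, global = mean(Ci))
}

#' Shortest-path lengths
#'
#' Breadth-first (unweighted) shortest-path distances.  `L_i` is the mean
#' distance from node *i* to the nodes it can reach; the characteristic
#' path length `L` is the mean of `L_i` over nodes with at least one
#' reachable partner.  The number of unreachable (unordered) pairs is
#' always reported so that disconnectedness is visible rather than
#' silently absorbed.
#'
#' @inheritParams graph_degree
#' @param paper_denominator If `TRUE`, divide each node's distance sum by
#'   `N` (the full node count) instead of by the number of reachable
#'   partners — a strict reproduction of the printed 1/N scaling some
#'   studies use; the default divides by the number of terms.
#' @return List with `local` (`L_i`; `NA` for isolated nodes), `global`
#'   (`L`), and `n_unreachable_pairs`.
#' @export
graph_path_length <- function(g, paper_denominator = FALSE) {
  A <- .adjacency_of(g)
  N <- nrow(A)
  ig <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                            diag = FALSE)
  D <- igraph::distances(ig)
  diag(D) <- NA
  finite <- is.finite(D)
  n_unreachable <- sum(!finite & !is.na(D)) / 2
  reach <- rowSums(finite, na.rm = TRUE)
  if (all(reach == 0)) {
    stop("graph has no reachable node pairs; path length is undefined")
  }
  sums <- rowSums(ifelse(finite, D, 0), na.rm = TRUE)
  denom <- if (paper_denominator) rep(N, N) else reach
  Li <- ifelse(reach > 0, sums / denom, NA_real_)
  names(Li) <- rownames(A)
  list(local = Li, global = mean(Li, na.rm = TRUE),
       n_unreachable_pairs = n_unreachable)
}

#' Betweenness centrality and hub normalization
#'
#' `BC_i` sums, over all unordered pairs of other nodes, the fraction of
#' their shortest paths that pass through node *i* (fractional counting of
#' multiple geodesics; endpoints excluded).  For hub comparison the values
#' are normalized by the network average: `bc_i = BC_i / mean(BC)`.  When
#' every `BC_i` is zero (e.g. a complete graph) the normalization is
#' undefined and `bc` is returned as `NA` (no node can be a hub).
#'
#' @inheritParams graph_degree
#' @return List with `bc` (raw `BC_i`) and `bc_norm` (`bc_i`; `NA` when
#'   mean betweenness is zero).
#' @export
graph_betweenness <- function(g) {
  A <- .adjacency_of(g)
  ig <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                            diag = FALSE)
  bc <- igraph::betweenness(ig, directed = FALSE, weights = NULL)
  names(bc) <- rownames(A)
  m <- mean(bc)
  bc_norm <- if (m > 0) bc / m else rep(NA_real_, length(bc))
  names(bc_norm) <- rownames(A)
  list(bc = bc, bc_norm = bc_norm)
}

#' Identify betweenness hubs
#'
#' Hubs are nodes whose betweenness exceeds twice the network average:
#' normalized betweenness `bc_i > 2`, strict inequality.  If normalization
#' is undefined (all-zero betweenness) no node is a hub.
#'
#' @param x An `scn_graph`, or a data frame from [node_metrics()], or a
#'   numeric vector of normalized betweenness values.
#' @return Character vector of hub node labels.
#' @export
#' @examples
#' star <- binarize_at_sparsity(
#'   partial_correlation(diag(5) + 0), s = 0.4)  # degenerate example; see tests
identify_hubs <- function(x) {
  if (inherits(x, "scn_graph")) {
    bcn <- graph_betweenness(x)$bc_norm
  } else if (is.data.frame(x)) {
    bcn <- stats::setNames(x$betweenness_norm, x$node)
  } else {
    bcn <- x
  }
  if (all(is.na(bcn))) return(character(0))
  names(bcn)[!is.na(bcn) & bcn > 2]
}

#' Per-node metric table for one graph
#'
#' @inheritParams graph_degree
#' @return Data frame with one row per node: `node`, `degree`,
#'   `clustering`, `path_length`, `betweenness`, `betweenness_norm`,
#'   `hub`.
#' @export
node_metrics <- function(g) {
  A <- .adjacency_of(g)
  cl <- graph_clustering(g)
  pl <- graph_path_length(g)
  bt <- graph_betweenness(g)
  hub <- !is.na(bt$bc_norm) & bt$bc_norm > 2
  data.frame(
    node = rownames(A) %||% sprintf("R%03d", seq_len(nrow(A))),
    degree = graph_degree(g),
    clustering = cl$local,
    path_length = pl$local,
    betweenness = bt$bc,
    betweenness_norm = bt$bc_norm,
    hub = hub,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Network-level metric summary for one graph
#'
#' @inheritParams graph_degree
#' @return List with `C`, `L`, `n_edges`, `n_unreachable_pairs`, and
#'   `connected` (no unreachable pairs).
#' @export
global_metrics <- function(g) {
  cl <- graph_clustering(g)
  pl <- graph_path_length(g)
  A <- .adjacency_of(g)
  list(C = cl$global, L = pl$global, n_edges = sum(A) / 2,
       n_unreachable_pairs = pl$n_unreachable_pairs,
       connected = pl$n_unreachable_pairs == 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
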
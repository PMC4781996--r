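# Nonparametric group comparison: the relabeling permutation test that
# rebuilds the full network pipeline (residualize -> Ledoit-Wolf ->
# partial correlation -> binarize -> metric) under each random relabeling,
# plus the demographic two-sample t-tests.

# Rank region pairs once and binarize at several sparsities from the same
# ranking (cheap, and guarantees nested edge sets).
.binarize_many <- function(W, sparsities, positive_only = FALSE) {
  N <- nrow(W)
  ut <- which(upper.tri(W), arr.ind = TRUE)
  w <- W[upper.tri(W)]
  key <- if (positive_only) w else abs(w)
  ord <- order(-key, ut[, 1], ut[, 2])
  n_pairs <- length(w)
  lapply(sparsities, function(s) {
    m <- floor(s * n_pairs)
    if (m < 1) stop("sparsity yields 0 edges")
    adj <- matrix(0L, N, N)
    adj[ut[ord[seq_len(m)], , drop = FALSE]] <- 1L
    adj + t(adj)
  })
}

.metric_value <- function(A, metric) {
  switch(metric,
    C = {
      k <- rowSums(A)
      e <- diag(A %*% A %*% A) / 2
      mean(ifelse(k < 2, 0, 2 * e / (k * (k - 1))))
    },
    L = {
      ig <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                                diag = FALSE)
      D <- igraph::distances(ig)
      diag(D) <- NA
      finite <- is.finite(D)
      reach <- rowSums(finite, na.rm = TRUE)
      if (all(reach == 0)) stop("no reachable pairs")
      sums <- rowSums(ifelse(finite, D, 0), na.rm = TRUE)
      mean(ifelse(reach > 0, sums / reach, NA_real_), na.rm = TRUE)
    },
    bc = {
      ig <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                                diag = FALSE)
      bc <- igraph::betweenness(ig, directed = FALSE, weights = NULL)
      m <- mean(bc)
      if (m > 0) bc / m else rep(NA_real_, length(bc))
    },
    stop("unknown metric: ", metric))
}

# One pseudo-group's metric values across sparsities.  Returns a vector
# (global metrics) or matrix sparsity x node (bc).  Uncomputable entries
# are NA, never fabricated.
.group_metric_values <- function(Y, covdf, idx, covariates, sparsities,
                                 metric, positive_only) {
  blk <- .residualize_block(Y[idx, , drop = FALSE],
                            covdf[idx, , drop = FALSE], covariates)
  lw <- ledoit_wolf(blk$residuals)
  pc <- partial_correlation(lw$sigma, labels = colnames(Y))
  adjs <- .binarize_many(unclass(pc), sparsities, positive_only)
  vals <- lapply(adjs, function(A) {
    tryCatch(.metric_value(A, metric), error = function(e) {
      if (metric == "bc") rep(NA_real_, nrow(A)) else NA_real_
    })
  })
  if (metric == "bc") do.call(rbind, vals) else unlist(vals)
}

#' Permutation test for between-group network differences
#'
#' Tests group differences in the network clustering coefficient (`"C"`),
#' characteristic path length (`"L"`), or per-node normalized betweenness
#' (`"bc"`), at each sparsity in a sweep.  The null distribution is built
#' by relabeling: subjects from both groups are pooled, a pseudo-group of
#' the same size as the second group is drawn at random, the *entire*
#' network construction (per-group residualization, Ledoit-Wolf shrinkage,
#' partial correlation, binarization) is re-run for both pseudo-groups,
#' and the metric difference recorded.  This is repeated `n_perm` times;
#' the 95th and 5th percentiles of the null differences are the one-tailed
#' critical values for an increase and a decrease respectively (both
#' directions are reported; no multiplicity correction is applied, so on a
#' null dataset about 5% of comparisons per tail are expected to flag).
#'
#' The observed difference is computed by the same function (identical
#' code path) as the permuted ones, so no observed/null asymmetry can
#' arise.
#'
#' @param cohort A `cohort_table` with exactly two groups.
#' @param metric `"C"`, `"L"`, or `"bc"`.
#' @param sparsity Numeric vector of sparsities to test.
#' @param n_perm Number of relabelings (at least 20; the convention is
#'   1000).
#' @param seed Integer seed controlling the relabelings.
#' @param covariates Covariates removed within each (pseudo-)group before
#'   covariance estimation.
#' @param positive_only Passed to the binarization step.
#' @param alpha One-tailed level per direction (default 0.05, i.e. the
#'   95th percentile critical value).
#' @return An object of class `scn_permtest`: a tidy `$table` (one row per
#'   sparsity, and per node for `"bc"`, with observed difference, critical
#'   values, one-tailed empirical p-values and significance flags), the
#'   raw `$null` matrix (`n_perm` rows), and bookkeeping (`metric`,
#'   `groups` — the difference is `groups[1] - groups[2]` —, `n_perm`,
#'   `seed`).
#' @export
#' @examples
#' spec <- cohort_spec(n_subjects_per_group = 12, n_regions = 16, seed = 3)
#' pt <- scn_permtest(generate_cohort(spec), metric = "C",
#'                    sparsity = 0.2, n_perm = 50, seed = 9)
#' pt$table
scn_permtest <- function(cohort, metric = c("C", "L", "bc"),
                         sparsity = seq(0.05, 0.35, by = 0.01),
                         n_perm = 1000, seed = NULL,
                         covariates = c("age", "gender", "total_feature"),
                         positive_only = FALSE, alpha = 0.05) {
  metric <- match.arg(metric)
  if (n_perm < 20) {
    stop("n_perm < 20: tail percentiles of the null are meaningless")
  }
  stopifnot(is.data.frame(cohort))
  labels <- region_labels(cohort)
  Y <- as.matrix(cohort[, labels, drop = FALSE])
  covdf <- cohort[, intersect(names(cohort),
                              c("age", "gender", "total_feature")),
                  drop = FALSE]
  assign0 <- as.character(cohort$group)
  groups <- sort(unique(assign0))
  if (length(groups) != 2) stop("exactly two groups required")

  stat_fun <- function(assign) {
    vA <- .group_metric_values(Y, covdf, assign == groups[1], covariates,
                               sparsity, metric, positive_only)
    vB <- .group_metric_values(Y, covdf, assign == groups[2], covariates,
                               sparsity, metric, positive_only)
    as.vector(vA - vB)  # bc: column-major over (sparsity, node)
  }

  observed <- stat_fun(assign0)
  if (!is.null(seed)) set.seed(as.integer(seed))
  null <- matrix(NA_real_, n_perm, length(observed))
  for (b in seq_len(n_perm)) {
    null[b, ] <- suppressWarnings(stat_fun(sample(assign0)))
  }

  crit_high <- apply(null, 2, stats::quantile, probs = 1 - alpha,
                     na.rm = TRUE, names = FALSE)
  crit_low <- apply(null, 2, stats::quantile, probs = alpha,
                    na.rm = TRUE, names = FALSE)
  n_ok <- colSums(!is.na(null))
  p_inc <- colSums(sweep(null, 2, observed, ">="), na.rm = TRUE) / n_ok
  p_dec <- colSums(sweep(null, 2, observed, "<="), na.rm = TRUE) / n_ok

  if (metric == "bc") {
    grid <- expand.grid(sparsity = sparsity, node = labels,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  } else {
    grid <- data.frame(sparsity = sparsity, node = NA_character_,
                       stringsAsFactors = FALSE)
  }
  tab <- data.frame(
    metric = metric, grid,
    observed = observed, crit_low = crit_low, crit_high = crit_high,
    p_increase = p_inc, p_decrease = p_dec,
    significant = !is.na(observed) &
      (observed > crit_high | observed < crit_low),
    stringsAsFactors = FALSE
  )
  structure(list(table = tab, null = null, metric = metric,
                 sparsity = sparsity, nodes = if (metric == "bc") labels,
                 groups = groups, n_perm = n_perm, seed = seed,
                 alpha = alpha),
            class = "scn_permtest")
}

#' @export
print.scn_permtest <- function(x, ...) {
  cat(sprintf(
    "Permutation test: %s difference (%s - %s), %d permutations\n",
    x$metric, x$groups[1], x$groups[2], x$n_perm))
  nsig <- sum(x$table$significant, na.rm = TRUE)
  cat(sprintf("  %d of %d comparisons significant at one-tailed %.0f%%\n",
              nsig, nrow(x$table), 100 * x$alpha))
  cat(sprintf(
    "  (expected by chance per tail under the null: ~%.1f; no correction applied)\n",
    x$alpha * nrow(x$table)))
  invisible(x)
}

#' @export
summary.scn_permtest <- function(object, ...) {
  tab <- object$table
  sig <- tab[which(tab$significant), , drop = FALSE]
  cat(sprintf("Permutation test (%s), %d permutations, groups %s vs %s\n",
              object$metric, object$n_perm, object$groups[1],
              object$groups[2]))
  if (nrow(sig) == 0) {
    cat("  no significant differences\n")
  } else {
    print(sig, row.names = FALSE)
  }
  invisible(tab)
}

#' Nodal betweenness increase/decrease map
#'
#' Classifies every region at one sparsity as a significant increase,
#' significant decrease, or no change in normalized betweenness between
#' the two groups (two one-tailed tests against the permutation null).
#'
#' @param pt An `scn_permtest` run with `metric = "bc"`.
#' @param sparsity Which sparsity of the sweep to tabulate (default: the
#'   first).
#' @return Data frame with `node`, `observed`, `crit_low`, `crit_high`,
#'   `p_increase`, `p_decrease`, and `direction`
#'   (`"increase"`/`"decrease"`/`"ns"`).
#' @export
betweenness_difference_map <- function(pt, sparsity = pt$sparsity[1]) {
  stopifnot(inherits(pt, "scn_permtest"))
  if (pt$metric != "bc") {
    stop("betweenness_difference_map requires a permutation test on 'bc'")
  }
  tab <- pt$table[abs(pt$table$sparsity - sparsity) < 1e-12, , drop = FALSE]
  if (nrow(tab) == 0) stop("sparsity not found in the tested sweep")
  dir <- ifelse(!is.na(tab$observed) & tab$observed > tab$crit_high,
                "increase",
                ifelse(!is.na(tab$observed) & tab$observed < tab$crit_low,
                       "decrease", "ns"))
  data.frame(node = tab$node, observed = tab$observed,
             crit_low = tab$crit_low, crit_high = tab$crit_high,
             p_increase = tab$p_increase, p_decrease = tab$p_decrease,
             direction = dir, row.names = NULL, stringsAsFactors = FALSE)
}

#' Two-sample demographic t-test
#'
#' Pooled-variance two-sample t-test of a covariate between the two
#' groups, with `df = n_A + n_B - 2`.  A two-level categorical column
#' (e.g. gender) is automatically converted to a 0/1 dummy variable.
#'
#' @param cohort A `cohort_table` (any data frame with a 2-level `group`
#'   column works).
#' @param column Name of the column to test.
#' @return The `htest` object from [stats::t.test()] (`var.equal = TRUE`,
#'   two-tailed).
#' @export
#' @examples
#' demo <- data.frame(group = rep(c("A", "B"), each = 36),
#'                    gender = c(rep(1, 14), rep(0, 22),
#'                               rep(1, 15), rep(0, 21)))
#' demographics_ttest(demo, "gender")$p.value   # 0.813
demographics_ttest <- function(cohort, column) {
  stopifnot(column %in% names(cohort))
  v <- cohort[[column]]
  if (is.character(v) || is.factor(v)) {
    lev <- sort(unique(as.character(v)))
    if (length(lev) != 2) {
      stop("column '", column, "' must be numeric or 2-level categorical")
    }
    v <- as.integer(as.character(v) == lev[2])
  }
  g <- as.character(cohort$group)
  groups <- sort(unique(g))
  if (length(groups) != 2) stop("exactly two groups required")
  nA <- sum(g == groups[1]); nB <- sum(g == groups[2])
  if (nA < 2 || nB < 2) stop("each group needs at least 2 subjects")
  stats::t.test(v[g == groups[1]], v[g == groups[2]], var.equal = TRUE)
}
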
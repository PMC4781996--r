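#' Fit group-level structural covariance networks
#'
#' The central fitting function of the package.  For each group in a
#' cohort table it (1) regresses the chosen covariates out of every
#' regional feature, (2) estimates the region covariance with Ledoit-Wolf
#' shrinkage, (3) converts it to partial correlations, (4) binarizes the
#' association matrix across a sparsity sweep, and (5) computes per-node
#' and network-level graph metrics at every sparsity.  Optionally
#' (`n_rand > 0`) each graph is also compared against an ensemble of
#' degree-preserving rewired surrogates to obtain the small-world
#' coefficients gamma, lambda and sigma.
#'
#' @param data A `cohort_table` (see [generate_cohort()], [load_cohort()]).
#' @param covariates Covariates removed per region before covariance
#'   estimation.
#' @param sparsity Sparsity sweep (fractions of retained edges); default
#'   5%--35% in steps of 1%.
#' @param n_rand Size of the rewired null ensemble per sparsity; 0 (the
#'   default) skips the small-world normalization, which is by far the
#'   most expensive stage.
#' @param seed Seed for the null ensembles (required when `n_rand > 0`).
#' @param pooled Residualize across both groups jointly instead of per
#'   group.
#' @param positive_only Rank edges by signed instead of absolute partial
#'   correlation.
#' @param swaps_per_edge Rewiring intensity for the null ensemble.
#' @return An object of class `scnetwork` with components per group:
#'   `assoc` (partial-correlation matrix), `intensity` (Ledoit-Wolf
#'   shrinkage weight), `graphs` (list over sparsities), `global` (data
#'   frame of C, L, edge counts per sparsity), `nodes` (per-node metric
#'   table, all sparsities stacked), and `smallworld` (data frame of
#'   gamma/lambda/sigma per sparsity, when `n_rand > 0`); plus the call,
#'   residuals, and settings.
#' @seealso [scn_permtest()] for group inference, [small_world()],
#'   [node_metrics()].
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_spec(n_subjects_per_group = 15,
#'                                       n_regions = 30, seed = 7))
#' fit <- scnetwork(cohort, sparsity = seq(0.1, 0.2, 0.05))
#' summary(fit)
scnetwork <- function(data,
                      covariates = c("age", "gender", "total_feature"),
                      sparsity = seq(0.05, 0.35, by = 0.01),
                      n_rand = 0, seed = NULL, pooled = FALSE,
                      positive_only = FALSE, swaps_per_edge = 10) {
  cl <- match.call()
  if (!inherits(data, "cohort_table")) data <- as_cohort_table(data)
  if (n_rand > 0 && is.null(seed)) {
    stop("a seed is required when n_rand > 0")
  }
  res <- residualize(data, covariates = covariates, pooled = pooled)
  groups <- names(res$residuals)
  fit_g <- list()
  for (g in groups) {
    lw <- ledoit_wolf(res$residuals[[g]])
    assoc <- partial_correlation(lw$sigma, labels = res$labels, group = g)
    graphs <- sparsity_sweep(assoc, s_min = min(sparsity),
                             s_max = max(sparsity),
                             step = if (length(sparsity) > 1)
                               sparsity[2] - sparsity[1] else 1,
                             positive_only = positive_only)
    # honour an arbitrary (possibly non-uniform) sparsity vector
    if (length(sparsity) > 1 &&
        max(abs(diff(sparsity) - (sparsity[2] - sparsity[1]))) > 1e-9) {
      graphs <- lapply(sparsity, function(s)
        binarize_at_sparsity(assoc, s, positive_only = positive_only))
      names(graphs) <- formatC(sparsity, format = "f", digits = 4)
    }
    glb <- do.call(rbind, lapply(seq_along(graphs), function(i) {
      gm <- global_metrics(graphs[[i]])
      data.frame(sparsity = sparsity[i], C = gm$C, L = gm$L,
                 n_edges = gm$n_edges,
                 n_unreachable_pairs = gm$n_unreachable_pairs)
    }))
    nds <- do.call(rbind, lapply(seq_along(graphs), function(i) {
      nm <- node_metrics(graphs[[i]])
      cbind(sparsity = sparsity[i], nm)
    }))
    sw <- NULL
    if (n_rand > 0) {
      sw <- do.call(rbind, lapply(seq_along(graphs), function(i) {
        # one derived seed per (group, sparsity) cell
        s_i <- (as.integer(seed) + 7919L * i +
                  104729L * match(g, groups)) %% .Machine$integer.max
        r <- small_world(graphs[[i]], n_rand = n_rand, seed = s_i,
                         swaps_per_edge = swaps_per_edge)
        data.frame(sparsity = sparsity[i], C_p = r$C_p, L_p = r$L_p,
                   C_rand = r$C_rand, L_rand = r$L_rand,
                   gamma = r$gamma, lambda = r$lambda, sigma = r$sigma,
                   small_world = r$small_world)
      }))
    }
    fit_g[[g]] <- list(assoc = assoc, intensity = lw$intensity,
                       graphs = graphs, global = glb, nodes = nds,
                       smallworld = sw)
  }
  structure(list(groups = fit_g, call = cl, labels = res$labels,
                 residuals = res, covariates = covariates,
                 sparsity = sparsity, n_rand = n_rand, seed = seed,
                 pooled = pooled, positive_only = positive_only),
            class = "scnetwork")
}

#' @export
print.scnetwork <- function(x, ...) {
  cat("Structural covariance network fit\n")
  cat("  call: ", deparse(x$call), "\n", sep = "")
  cat(sprintf("  %d regions, sparsity %.0f%%-%.0f%% (%d thresholds)\n",
              length(x$labels), 100 * min(x$sparsity),
              100 * max(x$sparsity), length(x$sparsity)))
  for (g in names(x$groups)) {
    cat(sprintf("  group %s: shrinkage intensity %.3f\n",
                g, x$groups[[g]]$intensity))
  }
  if (x$n_rand > 0) {
    cat(sprintf("  small-world ensemble: %d rewired graphs per threshold\n",
                x$n_rand))
  }
  invisible(x)
}

#' @export
summary.scnetwork <- function(object, ...) {
  cat("Structural covariance networks\n\n")
  for (g in names(object$groups)) {
    fg <- object$groups[[g]]
    cat(sprintf("Group %s (Ledoit-Wolf intensity %.3f):\n",
                g, fg$intensity))
    tab <- fg$global
    if (!is.null(fg$smallworld)) {
      tab <- merge(tab, fg$smallworld[, c("sparsity", "gamma", "lambda",
                                          "sigma")], by = "sparsity")
    }
    show <- tab[round(seq(1, nrow(tab), length.out = min(nrow(tab), 7))), ]
    print(show, row.names = FALSE, digits = 4)
    cat("\n")
  }
  invisible(lapply(object$groups, `[[`, "global"))
}

#' @export
coef.scnetwork <- function(object, ...) {
  lapply(object$groups, function(g) g$assoc)
}

#' @export
residuals.scnetwork <- function(object, ...) {
  object$residuals$residuals
}

#' Plot network metrics across the sparsity sweep
#'
#' Base-graphics display of the clustering coefficient and characteristic
#' path length per group as a function of sparsity; when a small-world
#' ensemble was fitted, gamma, lambda and sigma are shown instead.
#'
#' @param x An `scnetwork` fit.
#' @param which `"metrics"` (C and L) or `"smallworld"` (gamma, lambda,
#'   sigma; requires `n_rand > 0` at fit time).
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.scnetwork <- function(x, which = c("metrics", "smallworld"), ...) {
  which <- match.arg(which)
  groups <- names(x$groups)
  op <- graphics::par(mfrow = c(1, if (which == "metrics") 2 else 3))
  on.exit(graphics::par(op))
  panel <- function(col, ylab) {
    m <- sapply(x$groups, function(g) {
      src <- if (which == "metrics") g$global else g$smallworld
      src[[col]]
    })
    graphics::matplot(x$sparsity, m, type = "b", pch = seq_along(groups),
                      lty = 1, xlab = "sparsity", ylab = ylab, ...)
    graphics::legend("topright", legend = groups, pch = seq_along(groups),
                     col = seq_along(groups), bty = "n")
  }
  if (which == "metrics") {
    panel("C", "clustering coefficient C")
    panel("L", "characteristic path length L")
  } else {
    if (is.null(x$groups[[1]]$smallworld)) {
      stop("fit was run with n_rand = 0; no small-world coefficients")
    }
    panel("gamma", expression(gamma))
    panel("lambda", expression(lambda))
    panel("sigma", expression(sigma))
  }
  invisible(x)
}

#' Hub regions of a fitted network
#'
#' @param fit An `scnetwork` fit.
#' @param group Group label (default: first group).
#' @param sparsity Sparsity at which to read hubs (default 0.11, the
#'   conventional single threshold for nodal analysis: high enough that
#'   all regions join the network, low enough to limit false-positive
#'   paths).
#' @return Character vector of hub region labels (normalized betweenness
#'   > 2).
#' @export
hubs <- function(fit, group = names(fit$groups)[1], sparsity = 0.11) {
  stopifnot(inherits(fit, "scnetwork"))
  nds <- fit$groups[[group]]$nodes
  sel <- nds[abs(nds$sparsity - sparsity) < 1e-9 & nds$hub, "node"]
  if (length(sel) == 0 &&
      !any(abs(fit$sparsity - sparsity) < 1e-9)) {
    stop("sparsity not part of the fitted sweep")
  }
  sel
}
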
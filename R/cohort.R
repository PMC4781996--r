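#' Load and validate a cohort table
#'
#' Reads a TSV/CSV cohort file (as written by [write_cohort()]): one row
#' per subject, covariate columns (`subject_id`, `group`, `age`, `gender`,
#' `total_feature`) followed by one numeric column per atlas region.
#'
#' @param path Path to a TSV or CSV file with a header row; the delimiter
#'   is inferred from the extension (`.csv` vs anything else = tab).
#' @param region_labels Expected region columns, in order.  `NULL` takes
#'   every non-covariate column as a region.
#' @return A `cohort_table` data frame (see [generate_cohort()]).
#' @export
load_cohort <- function(path, region_labels = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  as_cohort_table(df, region_labels = region_labels)
}

#' Validate a data frame as a cohort table
#'
#' @param df Data frame with the cohort-table columns.
#' @param region_labels Expected region columns; `NULL` to infer.
#' @return A validated `cohort_table`.
#' @export
as_cohort_table <- function(df, region_labels = NULL) {
  required <- c("subject_id", "group", "age", "gender", "total_feature")
  missing_cov <- setdiff(required, names(df))
  if (length(missing_cov)) {
    stop("missing covariate column(s): ", paste(missing_cov, collapse = ", "))
  }
  if (is.null(region_labels)) {
    region_labels <- setdiff(names(df), required)
  }
  missing_reg <- setdiff(region_labels, names(df))
  if (length(missing_reg)) {
    stop("missing region column(s): ", paste(missing_reg, collapse = ", "))
  }
  if (anyDuplicated(df$subject_id)) {
    dup <- unique(df$subject_id[duplicated(df$subject_id)])
    stop("duplicate subject_id: ", paste(dup, collapse = ", "))
  }
  grp <- unique(df$group)
  if (length(grp) != 2) {
    stop("group column must take exactly two values, found: ",
         paste(grp, collapse = ", "))
  }
  for (lab in region_labels) {
    v <- df[[lab]]
    if (is.character(v)) v <- suppressWarnings(as.numeric(v))
    bad <- which(!is.finite(v))
    if (length(bad)) {
      stop(sprintf("non-numeric or missing feature value at row %d, column '%s'",
                   bad[1], lab))
    }
    df[[lab]] <- v
  }
  df <- df[, c(required, region_labels)]
  attr(df, "region_labels") <- region_labels
  class(df) <- c("cohort_table", "data.frame")
  df
}

#' Region labels of a cohort table
#' @param cohort A `cohort_table`.
#' @return Character vector of region column names.
#' @export
region_labels <- function(cohort) {
  lab <- attr(cohort, "region_labels")
  if (is.null(lab)) {
    lab <- setdiff(names(cohort),
                   c("subject_id", "group", "age", "gender", "total_feature"))
  }
  lab
}

# Residualize one subjects x regions block against a covariate design.
# Rank-deficient designs (a covariate constant within the group, or
# collinear with earlier columns) drop the offending covariate with a
# warning rather than failing.  Returns list(residuals, used, dropped).
.residualize_block <- function(Y, covdf, covariates) {
  n <- nrow(Y)
  X <- matrix(1, n, 1, dimnames = list(NULL, "(intercept)"))
  used <- character(0)
  dropped <- character(0)
  for (cv in covariates) {
    cand <- cbind(X, as.numeric(covdf[[cv]]))
    if (qr(cand)$rank > qr(X)$rank) {
      X <- cand
      colnames(X)[ncol(X)] <- cv
      used <- c(used, cv)
    } else {
      warning(sprintf(
        "covariate '%s' dropped from residualization (constant or collinear)",
        cv), call. = FALSE)
      dropped <- c(dropped, cv)
    }
  }
  fit <- stats::lm.fit(X, Y)
  res <- as.matrix(fit$residuals)
  dimnames(res) <- dimnames(Y)
  list(residuals = res, used = used, dropped = dropped)
}

#' Remove covariate effects from regional features
#'
#' Fits, at every region, an ordinary least-squares regression of the
#' feature on the listed covariates (plus an intercept) and returns the
#' residuals, which replace the raw values in all downstream covariance
#' estimation.  By default the regression is fit within each group
#' separately, so group mean differences cannot leak into the group-level
#' covariance; `pooled = TRUE` fits across all subjects before splitting.
#'
#' @param cohort A `cohort_table`.
#' @param covariates Covariate column names regressed out, in order.
#'   An empty vector centres each region (intercept-only fit).
#' @param pooled Fit one regression across both groups (`TRUE`) or one per
#'   group (default).
#' @return An object of class `scn_residuals`: a list with one
#'   subjects-by-regions residual matrix per group (`$residuals`, a named
#'   list), the region labels, and the covariates used/dropped per group.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_spec(n_subjects_per_group = 10,
#'                                       n_regions = 12, seed = 1))
#' r <- residualize(cohort)
#' sapply(r$residuals, dim)
residualize <- function(cohort,
                        covariates = c("age", "gender", "total_feature"),
                        pooled = FALSE) {
  stopifnot(is.data.frame(cohort))
  labels <- region_labels(cohort)
  groups <- sort(unique(as.character(cohort$group)))
  miss <- setdiff(covariates, names(cohort))
  if (length(miss)) {
    stop("covariate column(s) not found: ", paste(miss, collapse = ", "))
  }
  Y_all <- as.matrix(cohort[, labels, drop = FALSE])

  res_list <- list()
  used <- list()
  dropped <- list()
  if (pooled) {
    blk <- .residualize_block(Y_all, cohort, covariates)
    for (g in groups) {
      idx <- cohort$group == g
      .check_group_size(sum(idx), length(blk$used), g)
      res_list[[g]] <- blk$residuals[idx, , drop = FALSE]
      used[[g]] <- blk$used
      dropped[[g]] <- blk$dropped
    }
  } else {
    for (g in groups) {
      idx <- cohort$group == g
      .check_group_size(sum(idx), length(covariates), g)
      blk <- .residualize_block(Y_all[idx, , drop = FALSE],
                                cohort[idx, , drop = FALSE], covariates)
      res_list[[g]] <- blk$residuals
      used[[g]] <- blk$used
      dropped[[g]] <- blk$dropped
    }
  }
  structure(list(residuals = res_list, labels = labels,
                 covariates = covariates, used = used, dropped = dropped,
                 pooled = pooled),
            class = "scn_residuals")
}

.check_group_size <- function(n, n_cov, g) {
  if (n < n_cov + 2) {
    stop(sprintf("group '%s' has %d subjects; need at least %d for %d covariate(s)",
                 g, n, n_cov + 2, n_cov))
  }
}

#' @export
print.scn_residuals <- function(x, ...) {
  cat("Covariate-residualized feature matrices\n")
  for (g in names(x$residuals)) {
    cat(sprintf("  group %s: %d subjects x %d regions (covariates: %s)\n",
                g, nrow(x$residuals[[g]]), ncol(x$residuals[[g]]),
                if (length(x$used[[g]])) paste(x$used[[g]], collapse = ", ")
                else "none"))
  }
  invisible(x)
}
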
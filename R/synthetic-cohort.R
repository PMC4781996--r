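#' Block-community covariance template
#'
#' Builds a region-by-region covariance matrix with community structure:
#' `variance` on the diagonal, `variance * r_in` between regions in the same
#' block and `variance * r_out` between blocks.  Regions are partitioned
#' into `n_blocks` contiguous blocks as evenly as possible (no block is
#' empty).  Positive definiteness is checked, not assumed: strongly negative
#' between-block correlations can make the compound-symmetry structure
#' indefinite.
#'
#' @param n_regions Number of regions (matrix dimension).
#' @param n_blocks Number of communities; must not exceed `n_regions`.
#' @param r_in Within-block correlation, in (-1, 1).
#' @param r_out Between-block correlation, in (-1, 1).
#' @param variance Common marginal variance (diagonal value).
#' @return A symmetric positive-definite `n_regions` x `n_regions` matrix
#'   with the block assignment attached as attribute `"blocks"`.
#' @export
#' @examples
#' S <- make_block_covariance(40, 4, r_in = 0.3, r_out = 0.05)
#' S[1:3, 1:3]
make_block_covariance <- function(n_regions, n_blocks, r_in, r_out,
                                  variance = 1) {
  stopifnot(n_regions >= 1, n_blocks >= 1, n_blocks <= n_regions,
            variance > 0)
  if (abs(r_in) >= 1 || abs(r_out) >= 1) {
    stop("r_in and r_out must lie strictly inside (-1, 1)")
  }
  blocks <- sort(rep_len(seq_len(n_blocks), n_regions))
  same <- outer(blocks, blocks, "==")
  S <- variance * ifelse(same, r_in, r_out)
  diag(S) <- variance
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10 * variance) {
    stop(sprintf(paste0(
      "block covariance is not positive definite ",
      "(smallest eigenvalue %.3g); try a smaller |r_out| or |r_in|"),
      min(ev)))
  }
  attr(S, "blocks") <- blocks
  S
}

#' Specify a synthetic two-group morphometric cohort
#'
#' Collects and validates all parameters of the generative model used by
#' [generate_cohort()].  Each subject's region vector is
#' `mean_value + age * age_slopes + gender * gender_slopes +
#' group_shift * 1[group B] + z`, with `z` multivariate normal with
#' covariance `covariance + noise_sd^2 I` (group B may use
#' `group_covariance` instead, to model covariance perturbations).
#'
#' Defaults emulate a two-group morphometric study: 36 subjects per group,
#' 148 atlas regions, ages uniform on 55--80 years, gender Bernoulli(0.5)
#' dummy-coded 0/1, and a block-community covariance template.
#'
#' @param n_subjects_per_group Subjects per group (both groups equal size).
#' @param n_regions Number of regions; region labels default to the
#'   Destrieux vocabulary when `n_regions` is 148, else `R001`, `R002`, ...
#' @param covariance Symmetric positive-definite region covariance template.
#'   `NULL` builds a block-community template from `n_blocks`, `r_in`,
#'   `r_out`, `variance`.
#' @param n_blocks,r_in,r_out,variance Parameters of the default
#'   block-community template (ignored when `covariance` is supplied).
#' @param mean_value Baseline regional mean (scalar or length-`n_regions`).
#' @param age_range Uniform sampling range for age, in years.
#' @param gender_prob Probability of gender code 1.
#' @param age_slopes Per-region linear age effect (scalar recycled).
#' @param gender_slopes Per-region additive gender effect (scalar recycled).
#' @param group_shift Additive mean shift applied to group B regions
#'   (scalar or length-`n_regions`); 0 gives a null configuration.
#' @param group_covariance Optional covariance template for group B only;
#'   `NULL` means both groups share `covariance`.
#' @param noise_sd Standard deviation of independent residual noise added
#'   on top of the covariance template.
#' @param total_feature How the `total_feature` covariate column is derived
#'   from the region values: `"sum"` (default) or `"mean"`.
#' @param region_labels Optional explicit label vector overriding the
#'   defaults.
#' @param seed Default seed used by [generate_cohort()] when none is given.
#' @return An object of class `cohort_spec`.
#' @seealso [generate_cohort()], [make_block_covariance()]
#' @export
cohort_spec <- function(n_subjects_per_group = 36,
                        n_regions = 148,
                        covariance = NULL,
                        n_blocks = 4, r_in = 0.3, r_out = 0.05, variance = 1,
                        mean_value = 2.5,
                        age_range = c(55, 80),
                        gender_prob = 0.5,
                        age_slopes = 0,
                        gender_slopes = 0,
                        group_shift = 0,
                        group_covariance = NULL,
                        noise_sd = 0,
                        total_feature = c("sum", "mean"),
                        region_labels = NULL,
                        seed = NULL) {
  stopifnot(n_subjects_per_group >= 2, n_regions >= 2, noise_sd >= 0,
            gender_prob >= 0, gender_prob <= 1,
            length(age_range) == 2, age_range[1] < age_range[2])
  total_feature <- match.arg(total_feature)
  if (is.null(covariance)) {
    covariance <- make_block_covariance(n_regions, n_blocks, r_in, r_out,
                                        variance)
  }
  .check_covariance_template(covariance, n_regions, "covariance")
  if (!is.null(group_covariance)) {
    .check_covariance_template(group_covariance, n_regions,
                               "group_covariance")
  }
  if (is.null(region_labels)) {
    region_labels <- if (n_regions == 148) destrieux_labels() else
      sprintf("R%03d", seq_len(n_regions))
  }
  stopifnot(length(region_labels) == n_regions,
            !anyDuplicated(region_labels))
  spec <- list(
    n_subjects_per_group = as.integer(n_subjects_per_group),
    n_regions = as.integer(n_regions),
    covariance = unname(covariance),
    group_covariance = if (is.null(group_covariance)) NULL else
      unname(group_covariance),
    mean_value = rep_len(mean_value, n_regions),
    age_range = age_range,
    gender_prob = gender_prob,
    age_slopes = rep_len(age_slopes, n_regions),
    gender_slopes = rep_len(gender_slopes, n_regions),
    group_shift = rep_len(group_shift, n_regions),
    noise_sd = noise_sd,
    total_feature = total_feature,
    region_labels = region_labels,
    seed = seed
  )
  class(spec) <- "cohort_spec"
  spec
}

.check_covariance_template <- function(S, n_regions, what) {
  if (!is.matrix(S) || nrow(S) != n_regions || ncol(S) != n_regions) {
    stop(sprintf("%s must be a %d x %d matrix", what, n_regions, n_regions))
  }
  if (max(abs(S - t(S))) > 1e-8 * max(abs(S), 1)) {
    stop(sprintf("%s must be symmetric", what))
  }
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    stop(sprintf("%s is not positive definite (smallest eigenvalue %.3g)",
                 what, min(ev)))
  }
  invisible(TRUE)
}

#' Generate a synthetic two-group cohort table
#'
#' Draws a subject-by-region feature table from the generative model in a
#' [cohort_spec()]: multivariate-normal regional values around a covariate-
#' and group-dependent mean.  Output is bit-identical for identical seeds.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed; defaults to `spec$seed`.  Required through one
#'   of the two routes.
#' @return A data frame of class `cohort_table` with columns `subject_id`,
#'   `group` (`"A"`/`"B"`), `age`, `gender` (0/1), `total_feature`, then one
#'   numeric column per region.
#' @export
#' @examples
#' spec <- cohort_spec(n_subjects_per_group = 10, n_regions = 20, seed = 1)
#' cohort <- generate_cohort(spec)
#' dim(cohort)
generate_cohort <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (is.null(seed)) stop("a seed is required (in the spec or as argument)")
  set.seed(as.integer(seed))
  n <- spec$n_subjects_per_group
  p <- spec$n_regions
  n_tot <- 2L * n
  group <- rep(c("A", "B"), each = n)
  age <- stats::runif(n_tot, spec$age_range[1], spec$age_range[2])
  gender <- stats::rbinom(n_tot, 1L, spec$gender_prob)

  draw_group <- function(S, m) {
    Sigma <- S + diag(spec$noise_sd^2, p)
    z <- matrix(stats::rnorm(m * p), m, p) %*% chol(Sigma)
    z
  }
  zA <- draw_group(spec$covariance, n)
  SB <- if (is.null(spec$group_covariance)) spec$covariance else
    spec$group_covariance
  zB <- draw_group(SB, n)

  base <- matrix(spec$mean_value, n_tot, p, byrow = TRUE) +
    outer(age, spec$age_slopes) +
    outer(as.numeric(gender), spec$gender_slopes)
  base[group == "B", ] <- sweep(base[group == "B", , drop = FALSE], 2,
                                spec$group_shift, "+")
  feat <- base + rbind(zA, zB)
  colnames(feat) <- spec$region_labels

  total <- switch(spec$total_feature,
                  sum  = rowSums(feat),
                  mean = rowMeans(feat))
  out <- data.frame(
    subject_id = sprintf("S%03d", seq_len(n_tot)),
    group = group,
    age = age,
    gender = gender,
    total_feature = total,
    stringsAsFactors = FALSE
  )
  out <- cbind(out, as.data.frame(feat))
  attr(out, "region_labels") <- spec$region_labels
  class(out) <- c("cohort_table", "data.frame")
  out
}

#' Write a cohort table as TSV
#'
#' @param cohort A `cohort_table` (or compatible data frame).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.table(cohort, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
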
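fit_fixture <- function(n_rand = 0, seed = NULL) {
  cohort <- generate_cohort(cohort_spec(n_subjects_per_group = 15,
                                        n_regions = 24, n_blocks = 3,
                                        r_in = 0.4, r_out = 0.05,
                                        seed = 41))
  scnetwork(cohort, sparsity = seq(0.1, 0.3, 0.1), n_rand = n_rand,
            seed = seed)
}

test_that("scnetwork fits one network per group across the sweep", {
  fit <- fit_fixture()
  expect_s3_class(fit, "scnetwork")
  expect_named(fit$groups, c("A", "B"))
  for (g in c("A", "B")) {
    fg <- fit$groups[[g]]
    expect_s3_class(fg$assoc, "scn_assoc")
    expect_length(fg$graphs, 3)
    expect_equal(fg$global$sparsity, c(0.1, 0.2, 0.3))
    expect_equal(fg$global$n_edges,
                 floor(c(0.1, 0.2, 0.3) * 24 * 23 / 2))
    expect_equal(nrow(fg$nodes), 3 * 24)
    expect_true(fg$intensity >= 0 && fg$intensity <= 1)
  }
})

test_that("methods print, summarize, plot and expose components", {
  fit <- fit_fixture(n_rand = 5, seed = 2)
  expect_output(print(fit), "shrinkage intensity")
  expect_output(summary(fit), "Group A")
  co <- coef(fit)
  expect_named(co, c("A", "B"))
  expect_equal(unname(diag(co$A)), rep(1, 24))
  rs <- residuals(fit)
  expect_equal(dim(rs$A), c(15, 24))
  pdf(NULL)
  expect_invisible(plot(fit))
  expect_invisible(plot(fit, which = "smallworld"))
  dev.off()
  # small-world table present and internally consistent
  sw <- fit$groups$A$smallworld
  expect_equal(sw$sigma, sw$gamma / sw$lambda)
})

test_that("plot of small-world coefficients requires an ensemble", {
  fit <- fit_fixture(n_rand = 0)
  pdf(NULL)
  expect_error(plot(fit, which = "smallworld"), "n_rand")
  dev.off()
  expect_error(scnetwork(generate_cohort(
    cohort_spec(n_subjects_per_group = 8, n_regions = 10, seed = 1)),
    sparsity = 0.2, n_rand = 3), "seed")
})

test_that("hubs accessor reads the nodal table at one sparsity", {
  fit <- fit_fixture()
  h <- hubs(fit, "A", sparsity = 0.1)
  nds <- fit$groups$A$nodes
  expect_identical(h, nds$node[nds$sparsity == 0.1 & nds$hub])
  expect_error(hubs(fit, "A", sparsity = 0.33), "not part")
})

test_that("configuration is materialized, validated, and rejects unknowns", {
  cfg <- scn_config()
  expect_s3_class(cfg, "scn_config")
  # every policy field explicit after loading
  expect_true(all(c("measures", "sparsity", "n_rand", "n_perm", "seed",
                    "covariates", "pooled_residualization",
                    "positive_only", "swaps_per_edge",
                    "nodal_sparsity", "schema_version") %in% names(cfg)))
  expect_error(scn_config(n_bogus = 3), "unknown configuration field")
  expect_error(scn_config(measures = "dti"), "unknown measure")

  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("measures:", "- thickness", "- sulc", "n_perm: 40",
               "sparsity:", "  min: 0.1", "  max: 0.2"), path)
  cfg2 <- scn_config(path)
  expect_equal(cfg2$measures, c("thickness", "sulc"))
  expect_equal(cfg2$n_perm, 40)
  expect_equal(cfg2$sparsity$min, 0.1)
  expect_equal(cfg2$sparsity$step, 0.01)  # default materialized
})

test_that("run_pipeline writes a complete, reproducible result bundle", {
  cohorts <- list(
    thickness = generate_cohort(cohort_spec(n_subjects_per_group = 12,
                                            n_regions = 16, seed = 51)),
    sulc = generate_cohort(cohort_spec(n_subjects_per_group = 12,
                                       n_regions = 16, seed = 52)))
  cfg <- scn_config(measures = c("thickness", "sulc"),
                    sparsity = list(min = 0.1, max = 0.2, step = 0.05),
                    nodal_sparsity = 0.15,
                    n_rand = 4L, n_perm = 25L, seed = 5L,
                    permutation_metrics = "C")
  out1 <- withr::local_tempdir()
  man <- run_pipeline(cfg, cohorts, out1)
  expect_named(man$measures, c("thickness", "sulc"))
  for (meas in c("thickness", "sulc")) {
    for (g in c("A", "B")) {
      for (suffix in c("assoc", "global", "nodes", "smallworld", "edges")) {
        expect_true(file.exists(file.path(
          out1, sprintf("%s_%s_%s.tsv", meas, g, suffix))))
      }
    }
    expect_true(file.exists(file.path(out1,
                                      paste0(meas, "_perm_C.tsv"))))
  }
  expect_true(file.exists(file.path(out1, "manifest.json")))

  # bookkeeping: 2 measures x 2 groups x 3 sparsities of graphs
  expect_equal(man$measures$thickness$n_sparsities, 3)

  # same config and seeds -> byte-identical outputs
  out2 <- withr::local_tempdir()
  run_pipeline(cfg, cohorts, out2)
  for (f in list.files(out1, pattern = "\\.tsv$")) {
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)), label = f)
  }
})

test_that("pipeline failures name the stage and measure", {
  cfg <- scn_config(measures = "thickness", n_rand = 0L,
                    run_permutation = FALSE)
  expect_error(run_pipeline(cfg, list(), tempdir()),
               "no cohort supplied.*thickness")
  # a cohort too small to residualize aborts with the stage name
  bad <- generate_cohort(cohort_spec(n_subjects_per_group = 3,
                                     n_regions = 10, seed = 1))
  expect_error(
    run_pipeline(cfg, list(thickness = bad), withr::local_tempdir()),
    "stage 'network' failed for measure 'thickness'")
})

test_that("atlas vocabulary is complete and bijective", {
  atlas <- destrieux_atlas()
  expect_equal(nrow(atlas), 74)
  expect_false(anyDuplicated(atlas$abbreviation) > 0)
  labels <- destrieux_labels()
  expect_length(labels, 148)
  expect_false(anyDuplicated(labels) > 0)
  expect_equal(sum(startsWith(labels, "lh_")), 74)
  expect_equal(sum(startsWith(labels, "rh_")), 74)
  expect_identical(destrieux_labels(hemispheres = FALSE),
                   atlas$abbreviation)
})
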
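test_that("noiseless one-site data is self-fit to 3 significant figures", {
  curve <- simulate_monotherapy(biphasic_params(1, 10), noise_sd = 0)
  fit <- fit_hill(curve)
  expect_true(fit$converged)
  expect_equal(fit$params$i_max, 1, tolerance = 1e-3)
  expect_equal(fit$params$ic50_nM, 10, tolerance = 1e-3)
  expect_equal(fit$params$n, 1, tolerance = 1e-3)
  expect_lt(fit$rmse, 1e-5)
})

test_that("noiseless biphasic data recovers its generating parameters", {
  truth <- biphasic_params(0.53, 17, 3050)
  curve <- simulate_monotherapy(truth, noise_sd = 0)
  fit <- fit_biphasic(curve)
  expect_equal(fit$params$f1, 0.53, tolerance = 1e-3)
  expect_equal(fit$params$kd1_nM, 17, tolerance = 1e-3)
  expect_equal(fit$params$kd2_nM, 3050, tolerance = 1e-3)
  expect_false(fit$params$second_phase_absent)
  expect_lt(fit$rmse, 1e-5)
})

test_that("monophasic data collapses to a single phase with Kd2 'None'", {
  curve <- simulate_monotherapy(biphasic_params(1, 9.1), noise_sd = 0)
  fit <- fit_biphasic(curve)
  expect_true(fit$params$second_phase_absent)
  expect_equal(fit$params$f1, 1)
  expect_equal(fit$params$kd1_nM, 9.1, tolerance = 1e-3)
})

test_that("a shallow Hill curve (n < 1) is the signature of biphasic truth", {
  curve <- simulate_monotherapy(biphasic_params(0.49, 29.9, 9300),
                                noise_sd = 0)
  fit <- fit_hill(curve)
  expect_lt(fit$params$n, 1)
  # and the biphasic model fits such data better
  bip <- fit_biphasic(curve)
  expect_lt(bip$rmse, fit$rmse)
})

test_that("fitting requires at least 5 distinct concentrations", {
  curve <- simulate_monotherapy(biphasic_params(1, 10),
                                grid = c(1, 10, 100, 1000), noise_sd = 0)
  expect_error(fit_hill(curve), ">= 5 distinct")
  expect_error(fit_biphasic(curve), ">= 5 distinct")
})

test_that("fitting is deterministic for identical input", {
  curve <- simulate_monotherapy(biphasic_params(0.49, 29.9, 9300),
                                noise_sd = 0.02, seed = 9)
  f1 <- fit_biphasic(curve)
  f2 <- fit_biphasic(curve)
  expect_identical(tidy(f1), tidy(f2))
  expect_identical(f1$rmse, f2$rmse)
})

test_that("optimizer never loses to the dense grid-search oracle", {
  truths <- list(biphasic_params(0.49, 29.9, 9300),
                 biphasic_params(1, 9.1))
  for (truth in truths) {
    for (sd_seed in list(c(0, 1), c(0.02, 3))) {
      curve <- simulate_monotherapy(truth, noise_sd = sd_seed[1],
                                    seed = sd_seed[2])
      m <- curve_means(curve)
      hill <- fit_hill(curve)
      bip <- fit_biphasic(curve)
      expect_lte(hill$rmse,
                 oracle_hill_rmse(m$conc_nM, m$mean_inhibition) + 1e-4)
      expect_lte(bip$rmse,
                 oracle_biphasic_rmse(m$conc_nM, m$mean_inhibition) + 1e-4)
    }
  }
})

test_that("replicate-level fitting is available as an option", {
  curve <- simulate_monotherapy(biphasic_params(0.53, 17, 3050),
                                noise_sd = 0.02, seed = 2)
  f_mean <- fit_biphasic(curve)
  f_rep <- fit_biphasic(curve, use_replicates = TRUE)
  expect_equal(f_rep$n_points, 48)
  expect_equal(f_mean$n_points, 16)
  # both see the same underlying truth
  expect_equal(f_rep$params$f1, f_mean$params$f1, tolerance = 0.1)
})

test_that("model comparison reports RMSE ratio and preference", {
  curve <- simulate_monotherapy(biphasic_params(0.49, 29.9, 9300),
                                noise_sd = 0)
  h <- fit_hill(curve)
  b <- fit_biphasic(curve)
  cmp <- compare_models(h, b)
  expect_equal(cmp$preferred, "biphasic")
  expect_equal(cmp$rmse_ratio, b$rmse / h$rmse)
  # published example: RMSE 0.018 (biphasic) vs 0.05 (Hill) -> ratio 0.36
  expect_equal(0.018 / 0.05, 0.36)
  # equal RMSEs are declared comparable
  h2 <- h; h2$rmse <- 0.03
  b2 <- b; b2$rmse <- 0.03
  expect_equal(compare_models(h2, b2)$preferred, "comparable")
  # mismatched curves are rejected
  other <- fit_biphasic(simulate_monotherapy(
    biphasic_params(0.5, 50, 5000), noise_sd = 0, treatment = "other"))
  expect_error(compare_models(h, other), "same curve")
})

test_that("well-separated biphasic truth beats Hill at low noise", {
  # Kd separation >= 100x with sigma = 0.01
  for (seed in 1:5) {
    curve <- simulate_monotherapy(biphasic_params(0.5, 20, 2000),
                                  noise_sd = 0.01, seed = seed)
    h <- fit_hill(curve)
    b <- fit_biphasic(curve)
    expect_lte(b$rmse, h$rmse)
  }
})

test_that("fit_panel returns one reporting row per curve", {
  curves <- dplyr::bind_rows(
    simulate_monotherapy(biphasic_params(0.49, 29.9, 9300), noise_sd = 0.02,
                         seed = 1, cell_line = "L", treatment = "d1"),
    simulate_monotherapy(biphasic_params(1, 9.1), noise_sd = 0.02,
                         seed = 2, cell_line = "L", treatment = "d2"))
  pan <- fit_panel(curves)
  expect_equal(nrow(pan), 2)
  expect_setequal(pan$drug, c("d1", "d2"))
  expect_true(all(c("hill_rmse", "i_max_pct", "ic50_star_nM", "hill_n",
                    "biphasic_rmse", "f1_pct", "f2_pct", "kd1_nM",
                    "kd2_uM") %in% names(pan)))
  expect_s3_class(pan$hill_fit[[1]], "hill_fit")
})

test_that("tidy and glance expose the fitted parameters", {
  curve <- simulate_monotherapy(biphasic_params(0.49, 29.9, 9300),
                                noise_sd = 0)
  b <- fit_biphasic(curve)
  td <- tidy(b)
  expect_setequal(td$term, c("f1", "f2", "kd1_nM", "kd2_nM"))
  expect_equal(td$estimate[td$term == "f1"], 0.49, tolerance = 1e-3)
  gl <- glance(b)
  expect_equal(gl$model, "biphasic")
  expect_equal(gl$n_points, 16)
  h <- fit_hill(curve)
  expect_setequal(tidy(h)$term, c("i_max", "ic50_star_nM", "n"))
})
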
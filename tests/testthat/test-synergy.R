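test_that("ic_x reads a dose passing exactly through the level", {
  curve <- tibble::tibble(
    cell_line = "L", treatment = "d", replicate = 1,
    conc_nM = c(10, 100, 1000), inhibition = c(0.2, 0.5, 0.8))
  est <- ic_x(curve, 0.5)
  expect_true(est$attainable)
  expect_equal(est$dose_nM, 100, tolerance = 1e-9)
})

test_that("levels above the curve plateau are flagged unattainable", {
  curve <- tibble::tibble(
    cell_line = "L", treatment = "AZD-like", replicate = 1,
    conc_nM = 10 ^ (0:4), inhibition = c(0.1, 0.25, 0.35, 0.40, 0.40))
  est <- ic_x(curve, 0.5)
  expect_false(est$attainable)
  expect_true(is.na(est$dose_nM))
})

test_that("interpolated and model-based IC50 agree within one grid step", {
  truth <- biphasic_params(0.49, 29.9, 9300)
  curve <- simulate_monotherapy(truth, noise_sd = 0)
  interp <- ic_x(curve, 0.5)
  model <- ic_x(curve, 0.5, method = "model_based", fit = truth)
  # one two-fold grid step on the log scale
  expect_lt(abs(log2(interp$dose_nM / model$dose_nM)), 1)
  # and the model route matches the analytic inverse
  expect_equal(model$dose_nM, inverse_dose(0.5, truth), tolerance = 1e-9)
})

test_that("ic_x is invariant to the input concentration unit", {
  curve_nM <- tibble::tibble(
    cell_line = "L", treatment = "d", replicate = 1,
    conc_nM = c(10, 100, 1000), inhibition = c(0.2, 0.5, 0.8))
  curve_uM <- dplyr::mutate(curve_nM, concentration = conc_nM / 1000,
                            unit = "uM", conc_nM = NULL)
  expect_equal(ic_x(curve_uM, 0.6)$dose_nM, ic_x(curve_nM, 0.6)$dose_nM,
               tolerance = 1e-12)
})

test_that("dose reduction index follows the Chou-Talalay 1:1 formula", {
  expect_equal(dose_reduction_index(200, 200, 10), 10)
  # additive case: combining at half each single-agent dose gives DRI 1
  expect_equal(dose_reduction_index(200, 200, 100), 1)
  # hand arithmetic with published single-agent/combination values
  expect_equal(dose_reduction_index(231, 9280, 22),
               (231 * 9280) / (22 * (231 + 9280)), tolerance = 1e-12)
  expect_error(dose_reduction_index(-1, 10, 5), "positive")
  expect_error(dose_reduction_index(10, 10, 0), "positive")
})

test_that("DRI and combination index are exact reciprocals", {
  set.seed(13)
  for (i in 1:50) {
    ic1 <- 10 ^ runif(1, 0, 4)
    ic2 <- 10 ^ runif(1, 0, 4)
    icc <- 10 ^ runif(1, -1, 3)
    expect_equal(dose_reduction_index(ic1, ic2, icc) *
                   combination_index(ic1, ic2, icc), 1, tolerance = 1e-12)
  }
})

test_that("isobologram coordinates and interaction index are correct", {
  iso <- isobologram_points(100, 400, 50, 200)  # half of each intercept
  expect_equal(iso$interaction_index, 1)
  expect_equal(isobologram_points(100, 400, 0, 0)$interaction_index, 0)
  # published dasatinib IC50 with a synthetic partner IC50
  iso2 <- isobologram_points(697, 5000, 73, 73)
  expect_equal(iso2$interaction_index, 73 / 697 + 73 / 5000,
               tolerance = 1e-12)
  expect_equal(iso2$intercepts$drug1_nM[1], 697)
  expect_error(isobologram_points(NA, 400, 10, 10), "unattainable")
})

test_that("combinations are ranked by coverage then weaker-phase potency", {
  fits <- tibble::tibble(
    drug = c("dasatinib", "AZD-6244"),
    f1 = c(0.49, 0.36), kd1_nM = c(29.9, 91))
  targets <- c(dasatinib = "Src", "AZD-6244" = "Mek")
  rk <- rank_combinations(fits, targets)
  expect_equal(nrow(rk), 1)
  expect_equal(rk$coverage, 0.85)
  expect_equal(rk$max_kd1_nM, 91)
  # same-target pairs are excluded
  fits2 <- tibble::tibble(drug = c("a", "b"), f1 = c(0.5, 0.5),
                          kd1_nM = c(10, 20))
  rk2 <- rank_combinations(fits2, c(a = "Src", b = "Src"))
  expect_equal(nrow(rk2), 0)
})

test_that("ranking matches brute-force enumeration on a toy panel", {
  fits <- tibble::tibble(
    drug = c("d1", "d2", "d3", "d4"),
    f1 = c(0.6, 0.5, 0.45, 0.3),
    kd1_nM = c(20, 300, 15, 40))
  targets <- c(d1 = "A", d2 = "B", d3 = "C", d4 = "A")
  rk <- rank_combinations(fits, targets)
  # brute force: enumerate, score, order
  brute <- list()
  for (i in 1:3) for (j in (i + 1):4) {
    if (targets[fits$drug[i]] == targets[fits$drug[j]]) next
    brute[[length(brute) + 1]] <- data.frame(
      drug1 = fits$drug[i], drug2 = fits$drug[j],
      coverage = min(fits$f1[i] + fits$f1[j], 1),
      max_kd1_nM = max(fits$kd1_nM[i], fits$kd1_nM[j]))
  }
  brute <- do.call(rbind, brute)
  brute <- brute[order(-brute$coverage, brute$max_kd1_nM), ]
  expect_equal(rk$drug1, brute$drug1)
  expect_equal(rk$drug2, brute$drug2)
  expect_equal(rk$coverage, brute$coverage)
})

test_that("specificity fold compares IC_x across cell lines with censoring", {
  truth <- biphasic_params(0.8, 50, 5000)
  a <- simulate_monotherapy(truth, noise_sd = 0, cell_line = "A")
  expect_equal(specificity_fold(a, a, 0.5)$fold, 1, tolerance = 1e-9)
  # constructed 10x potency shift
  shifted <- biphasic_params(0.8, 500, 50000)
  b <- simulate_monotherapy(shifted, grid = dilution_grid() * 10,
                            noise_sd = 0, cell_line = "B")
  sf <- specificity_fold(a, b, 0.5)
  expect_equal(sf$fold, 10, tolerance = 0.05)
  # resistant line that never reaches the level: reported as a lower bound
  resistant <- simulate_monotherapy(biphasic_params(0.3, 50, 1e5),
                                    noise_sd = 0, cell_line = "C")
  sf2 <- specificity_fold(a, resistant, 0.5)
  expect_true(sf2$lower_bound)
  expect_equal(sf2$fold, max(dilution_grid()) / sf2$ic_a_nM,
               tolerance = 1e-9)
  expect_error(specificity_fold(resistant, a, 0.5), "more-sensitive")
})

test_that("synergy report assembles per-level indices and notes", {
  t1 <- biphasic_params(0.8, 30, 3000)
  t2 <- biphasic_params(0.7, 90, 9000)
  c1 <- simulate_monotherapy(t1, noise_sd = 0, treatment = "d1")
  c2 <- simulate_monotherapy(t2, noise_sd = 0, treatment = "d2")
  cc <- simulate_combination(t1, t2, "independent_drivers", noise_sd = 0,
                             treatment = "both")
  rep_tbl <- synergy_report(c1, c2, cc, levels = c(0.5, 0.7, 0.99))
  expect_equal(nrow(rep_tbl), 3)
  r5 <- rep_tbl[rep_tbl$level == 0.5, ]
  expect_equal(r5$dri * r5$ci, 1, tolerance = 1e-12)
  expect_equal(r5$dri_drug1, r5$ic1_nM / r5$ic_combo_nM, tolerance = 1e-12)
  # unattainable level documented, not computed
  r99 <- rep_tbl[rep_tbl$level == 0.99, ]
  expect_true(is.na(r99$dri))
  expect_match(r99$note, "unattainable")
})
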
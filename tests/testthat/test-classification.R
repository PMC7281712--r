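test_that("a partial, shallow, potency-split response is called multi-driver", {
  # published MDA-MB-231 / dasatinib values: I_max 88%, n 0.49, IC50* 300 nM;
  # F1 49%, Kd1 30 nM
  hill <- tibble::tibble(cell_line = "MDA-MB-231", drug = "Dasatinib",
                         i_max_pct = 88, ic50_star_nM = 300, hill_n = 0.49)
  bip <- tibble::tibble(cell_line = "MDA-MB-231", drug = "Dasatinib",
                        f1_pct = 49, kd1_nM = 30)
  cls <- classify_response(hill, bip)
  expect_equal(cls$verdict, "multi")
  expect_true(cls$criterion_f1 && cls$criterion_n &&
                cls$criterion_potency_agreement)
})

test_that("a complete, steep, potency-agreeing response is called mono-driver", {
  # published CTV-1 / dasatinib values
  hill <- tibble::tibble(i_max_pct = 97, ic50_star_nM = 9.1, hill_n = 2.72)
  bip <- tibble::tibble(f1_pct = 100, kd1_nM = 9.1)
  cls <- classify_response(hill, bip)
  expect_equal(cls$verdict, "mono")
  expect_true(all(c(cls$criterion_f1, cls$criterion_n,
                    cls$criterion_potency_agreement)))
})

test_that("responses between the threshold bands are indeterminate", {
  hill <- tibble::tibble(i_max_pct = 90, ic50_star_nM = 20, hill_n = 0.95)
  bip <- tibble::tibble(f1_pct = 83, kd1_nM = 10)  # f1 between 0.80 and 0.85
  cls <- classify_response(hill, bip)
  expect_equal(cls$verdict, "indeterminate")
  expect_match(cls$reason, "between")
})

test_that("non-converged fits yield an indeterminate verdict with reason", {
  hill <- tibble::tibble(i_max_pct = 97, ic50_star_nM = 9.1, hill_n = 2.72,
                         converged = FALSE)
  bip <- tibble::tibble(f1_pct = 100, kd1_nM = 9.1)
  cls <- classify_response(hill, bip)
  expect_equal(cls$verdict, "indeterminate")
  expect_match(cls$reason, "converged")
})

test_that("thresholds are configurable and echoed in the output", {
  hill <- tibble::tibble(i_max_pct = 97, ic50_star_nM = 9.1, hill_n = 2.72)
  bip <- tibble::tibble(f1_pct = 100, kd1_nM = 9.1)
  th <- driver_thresholds(f1_hi = 0.99, f1_lo = 0.5)
  cls <- classify_response(hill, bip, thresholds = th)
  expect_equal(cls$threshold_f1_hi, 0.99)
  expect_equal(cls$threshold_f1_lo, 0.5)
  # invalid threshold orderings are rejected
  expect_error(driver_thresholds(f1_hi = 0.5, f1_lo = 0.9))
})

test_that("relaxing f1_hi can move indeterminate to mono but never multi to mono", {
  grid <- tidyr::expand_grid(f1 = seq(0.05, 1, by = 0.05),
                             n = c(0.5, 0.95, 2),
                             ratio = c(1, 2, 20))
  for (i in seq_len(nrow(grid))) {
    hill <- tibble::tibble(i_max_pct = 100,
                           ic50_star_nM = grid$ratio[i] * 10,
                           hill_n = grid$n[i])
    bip <- tibble::tibble(f1_pct = 100 * grid$f1[i], kd1_nM = 10)
    strict <- classify_response(hill, bip,
                                driver_thresholds(f1_hi = 0.95))$verdict
    relaxed <- classify_response(hill, bip,
                                 driver_thresholds(f1_hi = 0.85))$verdict
    if (strict != relaxed) {
      expect_equal(strict, "indeterminate")
      expect_equal(relaxed, "mono")
    }
    expect_false(strict == "multi" && relaxed == "mono")
  }
})

test_that("cell lines aggregate: one mono response suffices, multi needs two targets", {
  du <- classify_fit_table(read_fit_table(du4475_fits_path()))
  expect_equal(classify_cell_line(du)$verdict, "mono")

  m231 <- tibble::tibble(drug = c("Dasatinib", "AZD-6244"),
                         verdict = c("multi", "multi"))
  targets <- c(Dasatinib = "Src", "AZD-6244" = "Mek")
  expect_equal(classify_cell_line(m231, targets)$verdict, "multi")
  # two multi responses sharing a target do not establish multi-driver status
  same <- tibble::tibble(drug = c("a", "b"), verdict = "multi")
  expect_equal(classify_cell_line(same, c(a = "Src", b = "Src"))$verdict,
               "indeterminate")
  single <- tibble::tibble(drug = "x", verdict = "indeterminate")
  expect_equal(classify_cell_line(single)$verdict, "indeterminate")
  expect_error(classify_cell_line(single[0, ]), "no drug-level")
})

test_that("simulated mono and multi truths classify correctly across seeds", {
  verdicts <- vapply(1:10, function(s) {
    cv <- simulate_monotherapy(biphasic_params(1, 9.1), noise_sd = 0.02,
                               seed = s)
    classify_response(fit_hill(cv), fit_biphasic(cv))$verdict
  }, character(1))
  expect_gte(mean(verdicts == "mono"), 0.9)
  verdicts2 <- vapply(1:10, function(s) {
    cv <- simulate_monotherapy(biphasic_params(0.49, 29.9, 9300),
                               noise_sd = 0.02, seed = s)
    classify_response(fit_hill(cv), fit_biphasic(cv))$verdict
  }, character(1))
  expect_gte(mean(verdicts2 == "multi"), 0.9)
})
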
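#' Standard two-fold dilution series
#'
#' The screening design behind the analysis: 16 two-fold dilutions rising
#' from 0.6 nM, topping out at 0.6 x 2^15 ~ 19.66 uM (~20 uM).
#'
#' @param n_points Number of concentrations.
#' @param bottom_nM Lowest concentration (nM).
#' @param fold Dilution factor between consecutive doses.
#' @return Strictly increasing numeric vector of concentrations in nM.
#' @export
#' @examples
#' range(dilution_grid())  # 0.6 nM ... 19660.8 nM
dilution_grid <- function(n_points = 16, bottom_nM = 0.6, fold = 2) {
  stopifnot(n_points >= 2, bottom_nM > 0, fold > 1)
  bottom_nM * fold ^ (seq_len(n_points) - 1)
}

#' Simulate replicate monotherapy dose-response data
#'
#' The mean curve is the model evaluated on the grid; i.i.d. Gaussian
#' replicate noise (sd `noise_sd`) is added on the inhibition scale.  The
#' default noise level (0.02) brackets the residual magnitude typical of
#' triplicate MTT screens.  Deterministic under a fixed `seed`.
#'
#' @param truth A [biphasic_params()] or [hill_params()] object.
#' @param grid Concentration grid in nM (default [dilution_grid()]).
#' @param replicates Replicate wells per concentration (default 3).
#' @param noise_sd Gaussian noise sd on the inhibition scale (default 0.02).
#' @param seed Optional integer seed.
#' @param cell_line,treatment Identifiers stamped on the output.
#' @return Per-well response tibble (`cell_line`, `treatment`, `conc_nM`,
#'   `replicate`, `viability`, `inhibition`).
#' @export
#' @examples
#' simulate_monotherapy(biphasic_params(0.49, 29.9, 9300), seed = 1)
simulate_monotherapy <- function(truth, grid = dilution_grid(),
                                 replicates = 3, noise_sd = 0.02,
                                 seed = NULL, cell_line = "SIM",
                                 treatment = "drug") {
  check_grid(grid)
  stopifnot(replicates >= 1, noise_sd >= 0)
  if (!is.null(seed)) set.seed(seed)
  mean_curve <- model_inhibition(grid, truth)
  out <- tidyr::expand_grid(replicate = seq_len(replicates),
                            conc_nM = grid)
  out$inhibition <- rep(mean_curve, times = replicates) +
    rnorm(nrow(out), 0, noise_sd)
  out |>
    dplyr::mutate(cell_line = cell_line, treatment = treatment,
                  viability = 1 - .data$inhibition) |>
    dplyr::select("cell_line", "treatment", "conc_nM", "replicate",
                  "viability", "inhibition") |>
    dplyr::arrange(.data$conc_nM, .data$replicate)
}

#' Simulate a 1:1 two-drug combination response
#'
#' Two generative ground truths are available for a mixture dosed at equal
#' per-drug concentration `D`:
#'
#' * `"independent_drivers"`: each drug's target-specific phase removes its
#'   own driver's contribution independently, and off-target phases act
#'   independently too, so surviving viability is the product
#'   \deqn{V(D) = \prod_k (1 - f_k \tfrac{D}{D + K_k})}
#'   over all phases of both drugs.  This is a simulation assumption for a
#'   multi-driver cell, not a fitted quantity.
#' * `"loewe_additive"`: the Loewe dose-equivalence null. At each per-drug
#'   dose `D` the combination inhibition `I` solves
#'   `D/D1(I) + D/D2(I) = 1`, with `D1`, `D2` the single-agent inverse
#'   dose-response functions.  Used as the no-interaction reference for
#'   isobologram tests (interaction index 1 by construction).
#'
#' @param truth1,truth2 [biphasic_params()] for the two drugs.
#' @param scenario Generative model; see Details.
#' @inheritParams simulate_monotherapy
#' @return Per-well response tibble; `conc_nM` is the per-drug dose.
#' @export
simulate_combination <- function(truth1, truth2,
                                 scenario = c("independent_drivers",
                                              "loewe_additive"),
                                 grid = dilution_grid(), replicates = 3,
                                 noise_sd = 0.02, seed = NULL,
                                 cell_line = "SIM",
                                 treatment = "drug1+drug2") {
  scenario <- match.arg(scenario)
  if (!inherits(truth1, "biphasic_params") ||
      !inherits(truth2, "biphasic_params"))
    abort("both drug truths must be biphasic_params objects")
  check_grid(grid)
  if (!is.null(seed)) set.seed(seed)
  mean_curve <- if (scenario == "independent_drivers") {
    independent_action_inhibition(grid, truth1, truth2)
  } else {
    vapply(grid, loewe_inhibition, numeric(1),
           truth1 = truth1, truth2 = truth2)
  }
  out <- tidyr::expand_grid(replicate = seq_len(replicates),
                            conc_nM = grid)
  out$inhibition <- rep(mean_curve, times = replicates) +
    rnorm(nrow(out), 0, noise_sd)
  out |>
    dplyr::mutate(cell_line = cell_line, treatment = treatment,
                  viability = 1 - .data$inhibition) |>
    dplyr::select("cell_line", "treatment", "conc_nM", "replicate",
                  "viability", "inhibition") |>
    dplyr::arrange(.data$conc_nM, .data$replicate)
}

#' Simulate raw plate wells whose normalization recovers the curve
#'
#' Emits control and treated `WellRecord`-style rows (A490/A750) that,
#' passed through [normalize_plate()], reproduce exactly the inhibition
#' matrix that [simulate_monotherapy()] draws under the same seed: the
#' noise path is shared, so the round trip is exact, not just
#' distributional.
#'
#' @inheritParams simulate_monotherapy
#' @param control_wells Number of control wells (exact baseline, no noise).
#' @param baseline Corrected control absorbance (`a490 - a750`).
#' @param a750 Background absorbance added to every well.
#' @return Well tibble (`cell_line`, `treatment`, `conc_nM`, `replicate`,
#'   `a490`, `a750`, `is_control`).
#' @export
simulate_plate <- function(truth, grid = dilution_grid(), replicates = 3,
                           noise_sd = 0.02, seed = NULL,
                           cell_line = "SIM", treatment = "drug",
                           control_wells = 6, baseline = 1.0, a750 = 0.05) {
  stopifnot(control_wells >= 1, baseline > 0, a750 >= 0)
  resp <- simulate_monotherapy(truth, grid = grid, replicates = replicates,
                               noise_sd = noise_sd, seed = seed,
                               cell_line = cell_line, treatment = treatment)
  treated <- resp |>
    dplyr::mutate(a490 = .data$viability * baseline + a750, a750 = a750,
                  is_control = FALSE) |>
    dplyr::select("cell_line", "treatment", "conc_nM", "replicate",
                  "a490", "a750", "is_control")
  controls <- tibble::tibble(
    cell_line = cell_line, treatment = treatment, conc_nM = 0,
    replicate = seq_len(control_wells),
    a490 = baseline + a750, a750 = a750, is_control = TRUE)
  dplyr::bind_rows(controls, treated)
}

# --- internals --------------------------------------------------------------

check_grid <- function(grid) {
  if (length(grid) < 2 || any(!is.finite(grid)) || any(grid <= 0) ||
      any(diff(grid) <= 0))
    abort("`grid` must be a strictly increasing vector of positive doses")
  invisible(grid)
}

# Independent action across all phases of both drugs at per-drug dose d.
independent_action_inhibition <- function(d, truth1, truth2) {
  surv <- function(f, k) 1 - f * d / (d + k)
  v <- surv(truth1$f1, truth1$kd1_nM) * surv(truth2$f1, truth2$kd1_nM)
  if (!truth1$second_phase_absent) v <- v * surv(truth1$f2, truth1$kd2_nM)
  if (!truth2$second_phase_absent) v <- v * surv(truth2$f2, truth2$kd2_nM)
  1 - v
}

# Loewe-additive inhibition of the 1:1 mixture at per-drug dose d:
# solve d / D1(I) + d / D2(I) = 1 for I.
loewe_inhibition <- function(d, truth1, truth2) {
  amax <- min(model_asymptote(truth1), model_asymptote(truth2))
  g <- function(i) {
    d / inverse_dose(i, truth1) + d / inverse_dose(i, truth2) - 1
  }
  eps <- 1e-9
  if (g(amax - eps) > 0) return(amax - eps)  # beyond the joint asymptote
  uniroot(g, c(eps, amax - eps), tol = 1e-10)$root
}
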
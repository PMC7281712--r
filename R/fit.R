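#' Fit the Hill equation to a dose-response curve
#'
#' Minimizes the root-mean-square error (RMSE) between observed and
#' predicted inhibition over `I_max` in \[0, 1\], `IC50*` in
#' \[0.1 nM, 100 uM\] (optimized on a log10 scale) and `n` in \[0.1, 5\],
#' using bounded quasi-Newton (L-BFGS-B) local optimization from a fixed
#' multi-start grid (log-spaced IC50* starts crossed with n in
#' \{0.5, 1, 2\}; 12 starts).  The objective is the unweighted RMSE on the
#' per-concentration mean inhibition by default.
#'
#' @param data Per-well response tibble for a single (cell line, treatment)
#'   curve, or its [curve_means()] summary.
#' @param use_replicates If `TRUE`, fit all replicate points individually
#'   instead of the per-concentration means.
#' @return A `hill_fit` object: fields `params` ([hill_params()]), `rmse`,
#'   `n_points`, `converged`, `starts_tried`, and the fitted `means` table.
#'   [tidy()], [glance()] and [autoplot()] methods are provided.
#' @export
#' @examples
#' curve <- simulate_monotherapy(biphasic_params(1, 10), noise_sd = 0)
#' fit_hill(curve)
fit_hill <- function(data, use_replicates = FALSE) {
  pts <- fit_points(data, use_replicates, "fit_hill()")
  d <- pts$conc_nM
  y <- pts$y
  obj <- function(th) {
    pred <- th[1] * d ^ th[3] / ((10 ^ th[2]) ^ th[3] + d ^ th[3])
    sqrt(mean((pred - y) ^ 2))
  }
  i_max0 <- min(1, max(0.1, max(y)))
  starts <- expand.grid(
    i_max = i_max0,
    log_ic50 = seq(log10(KD_LOWER_NM) + 1, log10(KD2_BOUND_NM) - 1,
                   length.out = 4),
    n = c(0.5, 1, 2))
  best <- run_starts(starts, obj,
                     lower = c(0, log10(KD_LOWER_NM), 0.1),
                     upper = c(1, log10(KD2_BOUND_NM), 5))
  params <- hill_params(i_max = min(1, max(best$par[1], 1e-12)),
                        ic50_nM = 10 ^ best$par[2],
                        n = best$par[3])
  new_fit("hill_fit", params, best, pts)
}

#' Fit the biphasic two-site model to a dose-response curve
#'
#' Minimizes RMSE over `F1` in \[0, 1\], `Kd1` in \[0.1 nM, 100 uM\] and
#' `Kd2` in \[`Kd1`, 100 uM\] (both constants on a log10 scale; the ordering
#' constraint makes phase 1 the high-affinity phase and removes label
#' switching).  `F2 = 1 - F1` is always derived, never free.  Fixed
#' multi-start grid of 18 starts; unweighted RMSE on per-concentration
#' means by default, as in [fit_hill()].
#'
#' Two reporting conventions are applied to the optimum:
#' * `Kd2` at the 100 uM bound is flagged censored (printed ">100 uM");
#' * the second phase is dropped entirely (`F1 = 100%`, Kd2 "None") when a
#'   single-phase refit (`F1` fixed at 1) fits the data comparably well —
#'   within `collapse_tol` (default 10%) of the two-phase RMSE — or when
#'   the unconstrained `F1` exceeds 0.995.  The parsimony rule keeps noise
#'   from being absorbed into a spurious second phase on monophasic data.
#'
#' @inheritParams fit_hill
#' @param collapse_tol Relative RMSE slack under which the single-phase
#'   refit replaces the two-phase optimum.
#' @return A `biphasic_fit` object (same shape as [fit_hill()]'s result,
#'   with [biphasic_params()] in `params`).
#' @export
#' @examples
#' curve <- simulate_monotherapy(biphasic_params(0.49, 29.9, 9300),
#'                               noise_sd = 0)
#' fit_biphasic(curve)
fit_biphasic <- function(data, use_replicates = FALSE, collapse_tol = 0.10) {
  pts <- fit_points(data, use_replicates, "fit_biphasic()")
  d <- pts$conc_nM
  y <- pts$y
  lb <- log10(KD_LOWER_NM); ub <- log10(KD2_BOUND_NM)
  # th = (f1, log10 kd1, log10(kd2 / kd1)); kd2 clamped at the bound.
  obj <- function(th) {
    kd1 <- 10 ^ th[2]
    kd2 <- min(kd1 * 10 ^ th[3], KD2_BOUND_NM)
    pred <- th[1] * d / (d + kd1) + (1 - th[1]) * d / (d + kd2)
    sqrt(mean((pred - y) ^ 2))
  }
  starts <- expand.grid(f1 = c(0.4, 0.7, 1),
                        log_kd1 = c(0.5, 2, 3.5),
                        log_sep = c(1.5, 3))
  best <- run_starts(starts, obj,
                     lower = c(0, lb, 0), upper = c(1, ub, ub - lb))
  f1 <- best$par[1]
  kd1 <- 10 ^ best$par[2]
  kd2 <- min(kd1 * 10 ^ best$par[3], KD2_BOUND_NM)

  # Single-phase refit: I = f1 * D / (D + Kd1) with f1 = 1.
  obj1 <- function(th) {
    pred <- d / (d + 10 ^ th[1])
    sqrt(mean((pred - y) ^ 2))
  }
  best1 <- run_starts(data.frame(log_kd1 = c(0.5, 1.5, 2.5, 3.5)), obj1,
                      lower = lb, upper = ub)
  if (best1$value <= best$value * (1 + collapse_tol) || f1 >= 0.995) {
    collapse <- best1$value <= best$value * (1 + collapse_tol)
    params <- biphasic_params(
      f1 = 1,
      kd1_nM = if (collapse) 10 ^ best1$par[1] else kd1)
    chosen <- if (collapse) best1 else best
    chosen$starts_tried <- best$starts_tried + best1$starts_tried
    return(new_fit("biphasic_fit", params, chosen, pts))
  }
  params <- biphasic_params(
    f1 = f1, kd1_nM = kd1, kd2_nM = kd2,
    kd2_censored = kd2 >= KD2_BOUND_NM * (1 - 1e-6))
  best$starts_tried <- best$starts_tried + best1$starts_tried
  new_fit("biphasic_fit", params, best, pts)
}

#' Compare a Hill and a biphasic fit of the same curve
#'
#' @param hill A `hill_fit`.
#' @param biphasic A `biphasic_fit` of the same curve.
#' @param tie_tol Relative RMSE band within which the two models are
#'   declared `"comparable"` (default 10%).
#' @return A one-row tibble: both RMSEs, their ratio
#'   (`rmse_biphasic / rmse_hill`), and `preferred` in
#'   `c("hill", "biphasic", "comparable")`.
#' @export
compare_models <- function(hill, biphasic, tie_tol = 0.10) {
  stopifnot(inherits(hill, "hill_fit"), inherits(biphasic, "biphasic_fit"))
  same <- identical(dim(hill$means), dim(biphasic$means)) &&
    isTRUE(all.equal(hill$means$conc_nM, biphasic$means$conc_nM)) &&
    identical(hill$cell_line, biphasic$cell_line) &&
    identical(hill$treatment, biphasic$treatment)
  if (!same) abort("the two fits are not of the same curve")
  ratio <- biphasic$rmse / hill$rmse
  preferred <- if (is.nan(ratio) || abs(ratio - 1) <= tie_tol) "comparable"
  else if (ratio < 1) "biphasic" else "hill"
  tibble::tibble(
    cell_line = hill$cell_line, treatment = hill$treatment,
    rmse_hill = hill$rmse, rmse_biphasic = biphasic$rmse,
    rmse_ratio = ratio, preferred = preferred)
}

#' Fit both models to every curve of a panel
#'
#' Groups a per-well response tibble by (`cell_line`, `treatment`), fits
#' both the Hill and biphasic models to each curve, and returns one row per
#' curve in the conventional reporting layout with the fitted objects in
#' list-columns.
#'
#' @inheritParams fit_hill
#' @param collapse_tol Passed to [fit_biphasic()].
#' @return A tibble with columns `cell_line`, `drug`, `hill_rmse`,
#'   `i_max_pct`, `ic50_star_nM`, `hill_n`, `biphasic_rmse`, `f1_pct`,
#'   `f2_pct`, `kd1_nM`, `kd2_uM`, flags, `preferred`, and list-columns
#'   `hill_fit`, `biphasic_fit`.
#' @export
fit_panel <- function(data, use_replicates = FALSE, collapse_tol = 0.10) {
  data <- as_response_tbl(data)
  data |>
    dplyr::group_by(.data$cell_line, .data$treatment) |>
    dplyr::group_modify(function(g, key) {
      g$cell_line <- key$cell_line
      g$treatment <- key$treatment
      h <- fit_hill(g, use_replicates = use_replicates)
      b <- fit_biphasic(g, use_replicates = use_replicates,
                        collapse_tol = collapse_tol)
      cmp <- compare_models(h, b)
      tibble::tibble(
        hill_rmse = h$rmse,
        i_max_pct = 100 * h$params$i_max,
        ic50_star_nM = h$params$ic50_nM,
        hill_n = h$params$n,
        biphasic_rmse = b$rmse,
        f1_pct = 100 * b$params$f1,
        f2_pct = 100 * b$params$f2,
        kd1_nM = b$params$kd1_nM,
        kd2_uM = b$params$kd2_nM / 1e3,
        kd2_censored = b$params$kd2_censored,
        second_phase_absent = b$params$second_phase_absent,
        preferred = cmp$preferred,
        hill_fit = list(h), biphasic_fit = list(b))
    }) |>
    dplyr::ungroup() |>
    dplyr::rename(drug = "treatment")
}

# --- internals --------------------------------------------------------------

MIN_CONCENTRATIONS <- 5L

fit_points <- function(data, use_replicates, what) {
  if (!is.data.frame(data)) abort(paste0(what, " expects a data frame"))
  data <- tibble::as_tibble(data)
  if ("mean_inhibition" %in% names(data) && !"inhibition" %in% names(data)) {
    data <- dplyr::rename(data, inhibition = "mean_inhibition")
    if (isTRUE(use_replicates))
      abort("replicate-level fitting needs per-well data, not curve means")
  }
  data <- single_curve(data, what)
  means <- curve_means(data)
  means <- dplyr::filter(means, is.finite(.data$mean_inhibition),
                         .data$conc_nM > 0)
  if (nrow(means) < MIN_CONCENTRATIONS) {
    abort(sprintf(
      "%s needs >= %d distinct positive concentrations with finite mean inhibition; got %d",
      what, MIN_CONCENTRATIONS, nrow(means)))
  }
  if (use_replicates) {
    pts <- dplyr::filter(data, .data$conc_nM > 0,
                         is.finite(.data$inhibition))
    list(conc_nM = pts$conc_nM, y = pts$inhibition, means = means,
         cell_line = means$cell_line[1], treatment = means$treatment[1])
  } else {
    list(conc_nM = means$conc_nM, y = means$mean_inhibition, means = means,
         cell_line = means$cell_line[1], treatment = means$treatment[1])
  }
}

# Deterministic multi-start L-BFGS-B over a fixed start grid.
run_starts <- function(starts, obj, lower, upper) {
  best <- NULL
  n_ok <- 0L
  for (i in seq_len(nrow(starts))) {
    th0 <- pmin(pmax(as.numeric(starts[i, ]), lower), upper)
    o <- tryCatch(
      optim(th0, obj, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = 500)),
      error = function(e) NULL)
    if (is.null(o)) next
    if (o$convergence == 0) n_ok <- n_ok + 1L
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (is.null(best)) abort("all optimizer starts failed")
  best$converged <- n_ok > 0L
  best$starts_tried <- nrow(starts)
  best
}

new_fit <- function(class, params, best, pts) {
  structure(list(
    params = params,
    rmse = best$value,
    n_points = length(pts$y),
    converged = isTRUE(best$converged),
    starts_tried = best$starts_tried,
    means = pts$means,
    cell_line = pts$cell_line,
    treatment = pts$treatment),
    class = c(class, "dose_response_fit"))
}

#' @export
print.dose_response_fit <- function(x, ...) {
  model <- if (inherits(x, "hill_fit")) "Hill" else "Biphasic"
  cat(sprintf("%s fit of %s / %s\n", model, x$cell_line, x$treatment))
  print(x$params)
  cat(sprintf("RMSE = %.4g on %d points (%d starts%s)\n",
              x$rmse, x$n_points, x$starts_tried,
              if (x$converged) "" else "; NOT converged"))
  invisible(x)
}

#' @rdname fit_hill
#' @param x A fitted object.
#' @param ... Unused.
#' @export
tidy.hill_fit <- function(x, ...) {
  tibble::tibble(
    term = c("i_max", "ic50_star_nM", "n"),
    estimate = c(x$params$i_max, x$params$ic50_nM, x$params$n))
}

#' @rdname fit_biphasic
#' @param x A fitted object.
#' @param ... Unused.
#' @export
tidy.biphasic_fit <- function(x, ...) {
  tibble::tibble(
    term = c("f1", "f2", "kd1_nM", "kd2_nM"),
    estimate = c(x$params$f1, x$params$f2, x$params$kd1_nM,
                 x$params$kd2_nM))
}

#' @export
glance.dose_response_fit <- function(x, ...) {
  tibble::tibble(
    cell_line = x$cell_line, treatment = x$treatment,
    model = if (inherits(x, "hill_fit")) "hill" else "biphasic",
    rmse = x$rmse, n_points = x$n_points,
    converged = x$converged, starts_tried = x$starts_tried)
}

#' Plot a fitted dose-response curve
#'
#' Mean inhibition with standard-error bars on a log10 dose axis, overlaid
#' with the fitted model curve.
#'
#' @param object A `hill_fit` or `biphasic_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dose_response_fit <- function(object, ...) {
  means <- object$means
  grid <- 10 ^ seq(log10(min(means$conc_nM)), log10(max(means$conc_nM)),
                   length.out = 200)
  pred <- tibble::tibble(
    conc_nM = grid,
    inhibition = model_inhibition(grid, object$params))
  model <- if (inherits(object, "hill_fit")) "Hill" else "Biphasic"
  ggplot2::ggplot(means, ggplot2::aes(x = .data$conc_nM)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_inhibition - .data$sem,
                   ymax = .data$mean_inhibition + .data$sem),
      width = 0.05, na.rm = TRUE) +
    ggplot2::geom_point(ggplot2::aes(y = .data$mean_inhibition)) +
    ggplot2::geom_line(data = pred, ggplot2::aes(y = .data$inhibition),
                       colour = "steelblue") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "concentration (nM)", y = "inhibition of viability",
      title = sprintf("%s fit: %s / %s (RMSE %.3g)", model,
                      object$cell_line, object$treatment, object$rmse))
}
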
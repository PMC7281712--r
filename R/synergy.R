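#' Empirical IC_x from a dose-response curve
#'
#' The dose producing `level` inhibition is read from the mean curve by
#' linear interpolation of mean inhibition against log10(concentration)
#' between the first bracketing pair of grid points (the automated
#' counterpart of reading the value off the graph).  Mean inhibition is
#' clamped to \[0, 1\] before interpolation.  If the curve never reaches
#' `level`, the estimate is flagged unattainable.  Alternatively,
#' `method = "model_based"` inverts a fitted model via [inverse_dose()].
#'
#' @param data Per-well response tibble (or [curve_means()] summary) for a
#'   single curve.
#' @param level Target inhibition fraction in (0, 1); vectorized.
#' @param method `"interpolated"` (default) or `"model_based"`.
#' @param fit A fitted `hill_fit`/`biphasic_fit` or parameter object,
#'   required for `method = "model_based"`.
#' @return A tibble with one row per level: `level`, `dose_nM`,
#'   `attainable`, `method`.
#' @export
#' @examples
#' curve <- simulate_monotherapy(biphasic_params(1, 100), noise_sd = 0)
#' ic_x(curve, 0.5)  # ~100 nM
ic_x <- function(data, level, method = c("interpolated", "model_based"),
                 fit = NULL) {
  method <- match.arg(method)
  stopifnot(all(level > 0), all(level < 1))
  if (method == "model_based") {
    if (is.null(fit)) abort("model_based ic_x needs a `fit`")
    params <- if (inherits(fit, "dose_response_fit")) fit$params else fit
    amax <- model_asymptote(params)
    return(purrr::map_dfr(level, function(lv) {
      if (lv >= amax) {
        tibble::tibble(level = lv, dose_nM = NA_real_, attainable = FALSE,
                       method = "model_based")
      } else {
        tibble::tibble(level = lv, dose_nM = inverse_dose(lv, params),
                       attainable = TRUE, method = "model_based")
      }
    }))
  }
  means <- if ("mean_inhibition" %in% names(data)) {
    dplyr::arrange(tibble::as_tibble(data), .data$conc_nM)
  } else {
    curve_means(single_curve(data, "ic_x()"))
  }
  means <- dplyr::filter(means, .data$conc_nM > 0)
  if (nrow(means) < 2) abort("ic_x() needs >= 2 positive concentrations")
  y <- pmin(pmax(means$mean_inhibition, 0), 1)
  lg <- log10(means$conc_nM)
  purrr::map_dfr(level, function(lv) {
    if (max(y) < lv) {
      return(tibble::tibble(level = lv, dose_nM = NA_real_,
                            attainable = FALSE, method = "interpolated"))
    }
    crossings <- which(y[-length(y)] < lv & y[-1] >= lv)
    if (y[1] >= lv) {
      # already above the level at the lowest dose: report the lowest dose
      return(tibble::tibble(level = lv, dose_nM = means$conc_nM[1],
                            attainable = TRUE, method = "interpolated"))
    }
    if (length(crossings) > 1) {
      warn(sprintf(
        "inhibition crosses %.0f%% more than once; using the first crossing",
        100 * lv))
    }
    i <- crossings[1]
    frac <- (lv - y[i]) / (y[i + 1] - y[i])
    tibble::tibble(level = lv,
                   dose_nM = 10 ^ (lg[i] + frac * (lg[i + 1] - lg[i])),
                   attainable = TRUE, method = "interpolated")
  })
}

#' Dose-reduction index of a 1:1 drug combination
#'
#' For single-agent doses `ic1`, `ic2` and a per-drug combination dose
#' `ic_combo` all producing the same inhibition level,
#' \deqn{DRI = \frac{IC_1 \cdot IC_2}{IC_{combo} (IC_1 + IC_2)}}
#' which is the reciprocal of the Chou-Talalay combination index
#' \eqn{CI = IC_{combo}/IC_1 + IC_{combo}/IC_2} for a 1:1 mixture.
#' DRI > 1 indicates a synergy-driven dose reduction.
#'
#' @param ic1,ic2 Single-agent IC_x doses (nM), positive.
#' @param ic_combo Per-drug dose of the 1:1 combination at the same
#'   inhibition level (nM), positive.
#' @return Numeric vector of DRIs.
#' @export
#' @examples
#' dose_reduction_index(200, 200, 10)  # 10
dose_reduction_index <- function(ic1, ic2, ic_combo) {
  if (any(!is.finite(ic1) | ic1 <= 0) || any(!is.finite(ic2) | ic2 <= 0) ||
      any(!is.finite(ic_combo) | ic_combo <= 0))
    abort("all IC_x inputs must be positive")
  (ic1 * ic2) / (ic_combo * (ic1 + ic2))
}

#' Chou-Talalay combination index of a 1:1 mixture
#'
#' `CI = ic_combo/ic1 + ic_combo/ic2`; CI < 1 synergy, = 1 additivity,
#' > 1 antagonism.  Identically the reciprocal of
#' [dose_reduction_index()].
#'
#' @inheritParams dose_reduction_index
#' @return Numeric vector of CIs.
#' @export
combination_index <- function(ic1, ic2, ic_combo) {
  if (any(!is.finite(ic1) | ic1 <= 0) || any(!is.finite(ic2) | ic2 <= 0) ||
      any(!is.finite(ic_combo) | ic_combo <= 0))
    abort("all IC_x inputs must be positive")
  ic_combo / ic1 + ic_combo / ic2
}

#' Isobologram coordinates for one inhibition level
#'
#' Returns plot-ready coordinates: the single-agent intercepts
#' `(ic1, 0)` and `(0, ic2)`, the straight additivity line joining them,
#' the combination point `(d1, d2)`, and the interaction index
#' `d1/ic1 + d2/ic2` (< 1 synergy, = 1 additive, > 1 antagonism).
#'
#' @param ic1,ic2 Attainable single-agent IC_x doses (nM).
#' @param d1,d2 Doses of drug 1 and drug 2 in the combination achieving the
#'   same level (nM, >= 0).
#' @return A list of class `isobologram`: `intercepts`, `additivity_line`,
#'   `combination` tibbles and `interaction_index`.
#' @export
#' @examples
#' iso <- isobologram_points(697, 5000, 73, 73)
#' iso$interaction_index
isobologram_points <- function(ic1, ic2, d1, d2) {
  if (any(is.na(c(ic1, ic2))) || ic1 <= 0 || ic2 <= 0)
    abort("isobologram undefined at this level: unattainable single-agent IC_x")
  if (d1 < 0 || d2 < 0) abort("combination doses must be >= 0")
  structure(list(
    intercepts = tibble::tibble(drug1_nM = c(ic1, 0), drug2_nM = c(0, ic2)),
    additivity_line = tibble::tibble(
      drug1_nM = seq(ic1, 0, length.out = 50),
      drug2_nM = seq(0, ic2, length.out = 50)),
    combination = tibble::tibble(drug1_nM = d1, drug2_nM = d2),
    interaction_index = d1 / ic1 + d2 / ic2),
    class = "isobologram")
}

#' @export
print.isobologram <- function(x, ...) {
  verdict <- if (x$interaction_index < 1) "synergy"
  else if (x$interaction_index > 1) "antagonism" else "additive"
  cat(sprintf(
    "Isobologram: intercepts (%.4g, 0) / (0, %.4g) nM; combination (%.4g, %.4g) nM\n",
    x$intercepts$drug1_nM[1], x$intercepts$drug2_nM[2],
    x$combination$drug1_nM, x$combination$drug2_nM))
  cat(sprintf("Interaction index = %.3g (%s)\n", x$interaction_index, verdict))
  invisible(x)
}

#' Plot an isobologram
#'
#' @param object An `isobologram` from [isobologram_points()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.isobologram <- function(object, ...) {
  ggplot2::ggplot() +
    ggplot2::geom_line(
      data = object$additivity_line,
      ggplot2::aes(x = .data$drug1_nM, y = .data$drug2_nM),
      linetype = "dashed") +
    ggplot2::geom_point(
      data = object$intercepts,
      ggplot2::aes(x = .data$drug1_nM, y = .data$drug2_nM), shape = 1) +
    ggplot2::geom_point(
      data = object$combination,
      ggplot2::aes(x = .data$drug1_nM, y = .data$drug2_nM),
      colour = "firebrick", size = 3) +
    ggplot2::labs(x = "drug 1 dose (nM)", y = "drug 2 dose (nM)",
                  title = sprintf("Interaction index = %.3g",
                                  object$interaction_index))
}

#' Rank candidate 1:1 combinations from biphasic fits
#'
#' Drugs hitting distinct declared targets are paired; each pair is scored
#' by the combined target-specific coverage `min(F1_a + F1_b, 1)` (primary
#' key, descending) and by the weaker target-specific potency
#' `max(Kd1_a, Kd1_b)` (secondary key, ascending).  Pairs sharing a target
#' label are excluded: hitting the same driver twice adds no coverage.
#'
#' @param fits Tibble with columns `drug`, `f1` (fraction) or `f1_pct`, and
#'   `kd1_nM`; or a named list of [biphasic_params()].
#' @param targets Named character vector or data frame (`drug`, `target`).
#' @return A tibble of ranked pairs: `drug1`, `drug2`, `coverage`,
#'   `max_kd1_nM`, `rank`.  Empty (with a `note` attribute) when fewer than
#'   two annotated drugs are eligible.
#' @export
rank_combinations <- function(fits, targets) {
  if (is.list(fits) && !is.data.frame(fits) &&
      all(purrr::map_lgl(fits, inherits, "biphasic_params"))) {
    fits <- purrr::imap_dfr(fits, function(p, nm) {
      tibble::tibble(drug = nm, f1 = p$f1, kd1_nM = p$kd1_nM)
    })
  }
  fits <- tibble::as_tibble(fits)
  if (!"f1" %in% names(fits) && "f1_pct" %in% names(fits))
    fits$f1 <- fits$f1_pct / 100
  stopifnot(all(c("drug", "f1", "kd1_nM") %in% names(fits)))
  tgt <- normalize_targets(targets)
  fits <- dplyr::inner_join(fits, tgt, by = "drug")
  if (nrow(fits) < 2) {
    out <- tibble::tibble(drug1 = character(), drug2 = character(),
                          coverage = numeric(), max_kd1_nM = numeric(),
                          rank = integer())
    attr(out, "note") <- "fewer than 2 drugs with fits and target labels"
    return(out)
  }
  pairs <- utils::combn(seq_len(nrow(fits)), 2)
  out <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    a <- fits[pairs[1, j], ]; b <- fits[pairs[2, j], ]
    if (a$target == b$target) return(NULL)
    tibble::tibble(drug1 = a$drug, drug2 = b$drug,
                   coverage = min(a$f1 + b$f1, 1),
                   max_kd1_nM = max(a$kd1_nM, b$kd1_nM))
  })
  if (nrow(out) == 0) {
    attr(out, "note") <- "no pair with distinct target labels"
    return(out)
  }
  out <- dplyr::arrange(out, dplyr::desc(.data$coverage), .data$max_kd1_nM)
  out$rank <- seq_len(nrow(out))
  out
}

#' Fold-difference in sensitivity between two cell lines
#'
#' Ratio of the IC_x of the less sensitive curve (B) over the more
#' sensitive one (A) at a given inhibition level.  When the level is not
#' reached on curve B within the dose range, the fold is reported as a
#' lower bound using B's top dose.
#'
#' @param curve_a Response tibble for the sensitive cell line.
#' @param curve_b Response tibble for the comparison cell line.
#' @param level Inhibition level in (0, 1).
#' @return One-row tibble: `level`, `ic_a_nM`, `ic_b_nM`, `fold`,
#'   `lower_bound`.
#' @export
specificity_fold <- function(curve_a, curve_b, level = 0.5) {
  ia <- ic_x(curve_a, level)
  ib <- ic_x(curve_b, level)
  if (!ia$attainable)
    abort("level not attainable on the more-sensitive curve")
  if (!ib$attainable) {
    top <- max(as_response_tbl(tibble::as_tibble(curve_b))$conc_nM)
    return(tibble::tibble(level = level, ic_a_nM = ia$dose_nM,
                          ic_b_nM = NA_real_, fold = top / ia$dose_nM,
                          lower_bound = TRUE))
  }
  tibble::tibble(level = level, ic_a_nM = ia$dose_nM, ic_b_nM = ib$dose_nM,
                 fold = ib$dose_nM / ia$dose_nM, lower_bound = FALSE)
}

#' Per-level synergy report for a 1:1 combination
#'
#' Extracts IC_x for both single agents and the combination at each level,
#' then computes the pooled DRI (reciprocal CI), the CI, per-drug dose
#' reductions (`ic1/ic_combo`, `ic2/ic_combo`), and the isobologram
#' interaction index.  Levels at which any required IC_x is unattainable
#' carry `NA` indices and an explanatory note (e.g. a drug that plateaus
#' below the level).
#'
#' @param curve1,curve2 Single-agent response tibbles.
#' @param curve_combo Response tibble of the 1:1 combination (concentration
#'   = per-drug dose).
#' @param levels Inhibition levels (default 0.5, 0.7, 0.9).
#' @return A tibble with one row per level: `level`, `ic1_nM`, `ic2_nM`,
#'   `ic_combo_nM`, `dri`, `ci`, `dri_drug1`, `dri_drug2`,
#'   `interaction_index`, `note`.
#' @export
synergy_report <- function(curve1, curve2, curve_combo,
                           levels = c(0.5, 0.7, 0.9)) {
  i1 <- ic_x(curve1, levels)
  i2 <- ic_x(curve2, levels)
  ic <- ic_x(curve_combo, levels)
  purrr::map_dfr(seq_along(levels), function(k) {
    ok1 <- i1$attainable[k]; ok2 <- i2$attainable[k]; okc <- ic$attainable[k]
    if (ok1 && ok2 && okc) {
      d <- ic$dose_nM[k]
      tibble::tibble(
        level = levels[k],
        ic1_nM = i1$dose_nM[k], ic2_nM = i2$dose_nM[k], ic_combo_nM = d,
        dri = dose_reduction_index(i1$dose_nM[k], i2$dose_nM[k], d),
        ci = combination_index(i1$dose_nM[k], i2$dose_nM[k], d),
        dri_drug1 = i1$dose_nM[k] / d, dri_drug2 = i2$dose_nM[k] / d,
        interaction_index = d / i1$dose_nM[k] + d / i2$dose_nM[k],
        note = NA_character_)
    } else {
      missing <- c("drug1", "drug2", "combination")[!c(ok1, ok2, okc)]
      tibble::tibble(
        level = levels[k],
        ic1_nM = i1$dose_nM[k], ic2_nM = i2$dose_nM[k],
        ic_combo_nM = ic$dose_nM[k],
        dri = NA_real_, ci = NA_real_,
        dri_drug1 = NA_real_, dri_drug2 = NA_real_,
        interaction_index = NA_real_,
        note = paste0("DRI undefined: level unattainable for ",
                      paste(missing, collapse = ", ")))
    }
  })
}
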
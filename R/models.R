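#' Convert concentrations to the canonical nanomolar scale
#'
#' All concentrations inside the package are carried in nanomolar (nM).
#' Input tables may quote micromolar values; this helper converts them.
#'
#' @param value Numeric vector of concentrations (non-negative; 0 is allowed
#'   for control wells only).
#' @param unit Character vector (recycled) naming the unit of `value`.
#'   Accepted: `"nM"`, `"uM"` (also spelled `"µM"`/`"μM"`), `"mM"`, `"M"`.
#' @return Numeric vector in nM.
#' @export
#' @examples
#' as_nM(c(0.6, 20), c("nM", "uM"))
as_nM <- function(value, unit = "nM") {
  scale <- c(nM = 1, uM = 1e3, "µM" = 1e3, "μM" = 1e3,
             mM = 1e6, M = 1e9)
  unit <- as.character(unit)
  bad <- !(unit %in% names(scale))
  if (any(bad)) {
    abort(paste0("unknown concentration unit(s): ",
                 paste(unique(unit[bad]), collapse = ", "),
                 "; accepted units are: nM, uM, mM, M"))
  }
  if (any(value < 0, na.rm = TRUE)) {
    abort("concentrations must be non-negative (0 only for control wells)")
  }
  value * unname(scale[unit])
}

#' Hill model parameters
#'
#' Parameters of the three-parameter Hill equation
#' \deqn{I(D) = I_{max} \frac{D^n}{IC_{50}^{*n} + D^n}}
#' where `i_max` is the maximal inhibition (fraction of viability), `ic50_nM`
#' is the half-effect concentration of the drug-sensitive fraction (IC50*,
#' distinct from the empirical IC50), and `n` is the Hill coefficient.
#'
#' @param i_max Maximal inhibition, fraction in \[0, 1\].
#' @param ic50_nM IC50* in nM, positive.
#' @param n Hill coefficient, positive.
#' @return An object of class `hill_params`.
#' @export
#' @examples
#' p <- hill_params(0.88, 300, 0.49)
#' hill_inhibition(300, p)  # half of i_max at IC50*
hill_params <- function(i_max, ic50_nM, n) {
  stopifnot(length(i_max) == 1, length(ic50_nM) == 1, length(n) == 1)
  if (!is.finite(i_max) || i_max < 0 || i_max > 1)
    abort("`i_max` must be a fraction in [0, 1]")
  if (!is.finite(ic50_nM) || ic50_nM <= 0)
    abort("`ic50_nM` must be positive")
  if (!is.finite(n) || n <= 0)
    abort("`n` must be positive")
  structure(list(i_max = i_max, ic50_nM = ic50_nM, n = n),
            class = "hill_params")
}

#' Biphasic (two-site) model parameters
#'
#' Parameters of the biphasic inhibition model
#' \deqn{I(D) = F_1 \frac{D}{D + K_{d1}} + F_2 \frac{D}{D + K_{d2}}}
#' with a target-specific phase (`f1`, `kd1_nM`) and an off-target phase
#' (`f2 = 1 - f1`, `kd2_nM`).  `f2` is always derived, never free.
#'
#' Two reporting conventions are carried as flags: `kd2_censored` marks an
#' off-target constant at the 100 uM identifiability bound (printed
#' ">100 uM"), and `second_phase_absent` marks a monophasic response
#' (`f1 = 1`, printed "None") whose second term drops out of the model.
#'
#' @param f1 Target-specific fraction of viability, in \[0, 1\].
#' @param kd1_nM Dissociation constant of the first phase, nM.
#' @param kd2_nM Dissociation constant of the second phase, nM, or `NULL`
#'   when the second phase is absent.  Must satisfy `kd2_nM >= kd1_nM`.
#' @param kd2_censored Logical; `TRUE` when `kd2_nM` sits at the 100 uM
#'   reporting bound.
#' @return An object of class `biphasic_params` with fields `f1`, `f2`,
#'   `kd1_nM`, `kd2_nM`, `kd2_censored`, `second_phase_absent`.
#' @export
#' @examples
#' biphasic_params(0.49, 29.9, 9300)
#' biphasic_params(1, 9.1)  # mono-phasic: second phase absent
biphasic_params <- function(f1, kd1_nM, kd2_nM = NULL, kd2_censored = FALSE) {
  stopifnot(length(f1) == 1, length(kd1_nM) == 1)
  if (!is.finite(f1) || f1 < 0 || f1 > 1)
    abort("`f1` must be a fraction in [0, 1]")
  if (!is.finite(kd1_nM) || kd1_nM <= 0)
    abort("`kd1_nM` must be positive")
  absent <- is.null(kd2_nM)
  if (!absent) {
    stopifnot(length(kd2_nM) == 1)
    if (!is.finite(kd2_nM) || kd2_nM <= 0)
      abort("`kd2_nM` must be positive (or NULL when the phase is absent)")
    if (kd2_nM < kd1_nM)
      abort("`kd2_nM` must be >= `kd1_nM` (phase 1 is the high-affinity phase)")
  }
  structure(list(f1 = f1, f2 = 1 - f1, kd1_nM = kd1_nM,
                 kd2_nM = if (absent) NA_real_ else kd2_nM,
                 kd2_censored = isTRUE(kd2_censored) && !absent,
                 second_phase_absent = absent),
            class = "biphasic_params")
}

#' Hill inhibition at given concentrations
#'
#' @param conc_nM Numeric vector of concentrations in nM (>= 0).
#' @param params A [hill_params()] object.
#' @return Numeric vector of inhibition fractions.
#' @export
hill_inhibition <- function(conc_nM, params) {
  stopifnot(inherits(params, "hill_params"))
  if (any(conc_nM < 0, na.rm = TRUE)) abort("concentrations must be >= 0")
  dn <- conc_nM ^ params$n
  out <- params$i_max * dn / (params$ic50_nM ^ params$n + dn)
  out[conc_nM == 0] <- 0
  out
}

#' Biphasic inhibition at given concentrations
#'
#' @param conc_nM Numeric vector of concentrations in nM (>= 0).
#' @param params A [biphasic_params()] object.
#' @return Numeric vector of inhibition fractions.
#' @export
biphasic_inhibition <- function(conc_nM, params) {
  stopifnot(inherits(params, "biphasic_params"))
  if (any(conc_nM < 0, na.rm = TRUE)) abort("concentrations must be >= 0")
  out <- params$f1 * conc_nM / (conc_nM + params$kd1_nM)
  if (!params$second_phase_absent) {
    out <- out + params$f2 * conc_nM / (conc_nM + params$kd2_nM)
  }
  out
}

# Asymptotic maximal inhibition of a model as the dose grows without bound.
model_asymptote <- function(params) {
  if (inherits(params, "hill_params")) return(params$i_max)
  if (inherits(params, "biphasic_params")) {
    return(if (params$second_phase_absent) params$f1 else params$f1 + params$f2)
  }
  abort("`params` must be hill_params or biphasic_params")
}

# Forward model dispatch shared by inverse_dose() and plotting.
model_inhibition <- function(conc_nM, params) {
  if (inherits(params, "hill_params")) hill_inhibition(conc_nM, params)
  else biphasic_inhibition(conc_nM, params)
}

#' Invert a dose-response model for the dose at a target inhibition
#'
#' For the Hill model the closed form
#' \eqn{D = IC_{50}^* (I / (I_{max} - I))^{1/n}} is used; for the biphasic
#' model the monotone forward curve is inverted by bracketed root-finding on
#' a log-dose scale to a relative tolerance of 1e-9.
#'
#' @param target Target inhibition fraction, strictly between 0 and the
#'   model's asymptotic maximum.
#' @param params A [hill_params()] or [biphasic_params()] object.
#' @return Dose in nM.
#' @export
#' @examples
#' inverse_dose(0.5, hill_params(1, 100, 1))      # 100 nM
#' inverse_dose(0.5, biphasic_params(1, 10))      # 10 nM
inverse_dose <- function(target, params) {
  stopifnot(length(target) == 1, is.finite(target))
  amax <- model_asymptote(params)
  if (target <= 0) abort("`target` must be positive")
  if (target >= amax) {
    abort(sprintf(
      "unreachable inhibition level: target %.3f >= asymptotic maximum %.3f",
      target, amax))
  }
  if (inherits(params, "hill_params")) {
    return(params$ic50_nM * (target / (params$i_max - target)) ^ (1 / params$n))
  }
  f <- function(lg) biphasic_inhibition(10 ^ lg, params) - target
  lo <- -9; hi <- 12
  while (f(hi) < 0 && hi < 40) hi <- hi + 4
  root <- uniroot(f, c(lo, hi), tol = 1e-12)$root
  10 ^ root
}

#' @export
print.hill_params <- function(x, ...) {
  cat(sprintf("Hill parameters: I_max = %.1f%%, IC50* = %.4g nM, n = %.3g\n",
              100 * x$i_max, x$ic50_nM, x$n))
  invisible(x)
}

#' @export
print.biphasic_params <- function(x, ...) {
  kd2 <- if (x$second_phase_absent) "None"
  else if (x$kd2_censored) ">100 uM"
  else sprintf("%.4g nM", x$kd2_nM)
  cat(sprintf(
    "Biphasic parameters: F1/F2 = %.0f/%.0f, Kd1 = %.4g nM, Kd2 = %s\n",
    100 * x$f1, 100 * x$f2, x$kd1_nM, kd2))
  invisible(x)
}
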
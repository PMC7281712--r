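#' Threshold configuration for driver classification
#'
#' The mono/multi-driver signatures are qualitative (F1 "close to 100%",
#' n "significantly below 1", Kd1 "dramatically below" IC50*); these
#' numeric cut-offs operationalize them.  Defaults are calibrated on the
#' published seven-cell-line reference panel so that every panel response
#' reproduces its stated verdict, and every threshold is echoed in the
#' classification output so a report is self-describing.
#'
#' A response is **mono**-pattern when `f1 >= f1_hi` AND `n >= n_hi` AND
#' `ic50_star / kd1 <= r_lo` (Hill and biphasic potencies agree); it is
#' **multi**-pattern when `f1 <= f1_lo` AND `n <= n_lo` AND
#' `ic50_star / kd1 >= r_hi` (the apparent IC50* is inflated well above the
#' target-specific Kd1).  Anything else is indeterminate.
#'
#' @param f1_hi Minimum F1 (fraction) for the mono pattern.
#' @param f1_lo Maximum F1 for the multi pattern.
#' @param n_hi Minimum Hill coefficient for the mono pattern.
#' @param n_lo Maximum Hill coefficient for the multi pattern.
#' @param r_lo Maximum IC50*/Kd1 ratio for the mono pattern.
#' @param r_hi Minimum IC50*/Kd1 ratio for the multi pattern.
#' @return A named list of thresholds.
#' @export
driver_thresholds <- function(f1_hi = 0.85, f1_lo = 0.80,
                              n_hi = 0.9, n_lo = 0.85,
                              r_lo = 1.1, r_hi = 1.1) {
  stopifnot(f1_lo <= f1_hi, n_lo < n_hi, r_lo <= r_hi,
            f1_hi <= 1, f1_lo >= 0, n_lo > 0, r_lo > 0)
  list(f1_hi = f1_hi, f1_lo = f1_lo, n_hi = n_hi, n_lo = n_lo,
       r_lo = r_lo, r_hi = r_hi)
}

#' Classify a single drug response as mono- or multi-driver
#'
#' Joint interpretation of a Hill fit and a biphasic fit of the same curve.
#' Mono-driver responses show near-complete target-specific inhibition
#' (F1 near 100%), a steep curve (n > 1) and agreement between IC50* and
#' Kd1; multi-driver responses show partial F1, a shallow curve (n < 1)
#' and an IC50* inflated far above the low-nM Kd1.
#'
#' @param hill A `hill_fit` from [fit_hill()], or a one-row data frame with
#'   columns `i_max_pct` (or `i_max`), `ic50_star_nM`, `hill_n`.
#' @param biphasic A `biphasic_fit` from [fit_biphasic()], or a one-row data
#'   frame with columns `f1_pct` (or `f1`) and `kd1_nM`.
#' @param thresholds A [driver_thresholds()] list.
#' @return A one-row tibble: `verdict` in `c("mono", "multi",
#'   "indeterminate")`, the evaluated quantities (`f1`, `hill_n`,
#'   `potency_ratio`), per-criterion flags for both patterns, a `reason`
#'   for indeterminate verdicts, and the thresholds used.
#' @export
classify_response <- function(hill, biphasic,
                              thresholds = driver_thresholds()) {
  h <- extract_hill_row(hill)
  b <- extract_biphasic_row(biphasic)
  th <- thresholds
  th_tbl <- tibble::as_tibble(th)
  names(th_tbl) <- paste0("threshold_", names(th_tbl))

  if (!isTRUE(h$converged) || !isTRUE(b$converged)) {
    return(dplyr::bind_cols(
      tibble::tibble(
        cell_line = b$cell_line, drug = b$drug,
        verdict = "indeterminate",
        f1 = b$f1, hill_n = h$n, potency_ratio = h$ic50_nM / b$kd1_nM,
        criterion_f1 = NA, criterion_n = NA,
        criterion_potency_agreement = NA,
        reason = "fit not converged"),
      th_tbl))
  }
  ratio <- h$ic50_nM / b$kd1_nM
  mono_f1 <- b$f1 >= th$f1_hi
  mono_n <- h$n >= th$n_hi
  mono_r <- ratio <= th$r_lo
  multi_f1 <- b$f1 <= th$f1_lo
  multi_n <- h$n <= th$n_lo
  multi_r <- ratio >= th$r_hi
  verdict <- if (mono_f1 && mono_n && mono_r) "mono"
  else if (multi_f1 && multi_n && multi_r) "multi"
  else "indeterminate"
  # Criterion flags report agreement with the verdict's own pattern (for
  # indeterminate verdicts, with the mono pattern).
  use_mono <- verdict != "multi"
  dplyr::bind_cols(
    tibble::tibble(
      cell_line = b$cell_line, drug = b$drug,
      verdict = verdict,
      f1 = b$f1, hill_n = h$n, potency_ratio = ratio,
      criterion_f1 = if (use_mono) mono_f1 else multi_f1,
      criterion_n = if (use_mono) mono_n else multi_n,
      criterion_potency_agreement = if (use_mono) mono_r else multi_r,
      reason = if (verdict == "indeterminate") "between thresholds"
      else NA_character_),
    th_tbl)
}

#' Classify every row of a joint fit table
#'
#' Applies [classify_response()] to each row of a panel fit table (from
#' [fit_panel()] or [read_fit_table()]).
#'
#' @param fit_table Tibble with columns `cell_line`, `drug`, `i_max_pct`,
#'   `ic50_star_nM`, `hill_n`, `f1_pct`, `kd1_nM` (percent columns may be
#'   given as fractions `i_max`, `f1` instead).
#' @param thresholds A [driver_thresholds()] list.
#' @return A tibble with one classification row per input row.
#' @export
classify_fit_table <- function(fit_table, thresholds = driver_thresholds()) {
  stopifnot(is.data.frame(fit_table))
  purrr::map_dfr(seq_len(nrow(fit_table)), function(i) {
    row <- fit_table[i, ]
    classify_response(row, row, thresholds = thresholds)
  })
}

#' Aggregate drug-level classifications into a cell-line verdict
#'
#' A cell line is called **mono**-driver when at least one drug elicits a
#' mono-pattern response (one target's blockade suffices for full
#' inhibition).  It is called **multi**-driver when at least two drugs with
#' distinct declared targets each elicit a multi-pattern partial response.
#' Otherwise it is indeterminate.  Drug-to-target annotations are an
#' explicit input: targets are assigned from external binding data, never
#' inferred from the curves.
#'
#' @param classifications Tibble of drug-level rows from
#'   [classify_response()]/[classify_fit_table()] (needs `drug`, `verdict`).
#' @param targets Named character vector or data frame (`drug`, `target`)
#'   mapping drugs to target labels.  Optional for mono calls; required to
#'   establish a multi verdict.
#' @return A one-row tibble: `verdict`, `n_mono`, `n_multi`,
#'   `n_distinct_multi_targets`, `basis`.
#' @export
classify_cell_line <- function(classifications, targets = NULL) {
  cls <- tibble::as_tibble(classifications)
  if (nrow(cls) == 0) abort("no drug-level classifications supplied")
  if (!all(c("drug", "verdict") %in% names(cls)))
    abort("classifications need `drug` and `verdict` columns")
  tgt <- normalize_targets(targets)
  cls <- dplyr::left_join(cls, tgt, by = "drug")
  mono <- dplyr::filter(cls, .data$verdict == "mono")
  multi <- dplyr::filter(cls, .data$verdict == "multi")
  multi_targets <- unique(multi$target[!is.na(multi$target)])
  verdict <- if (nrow(mono) >= 1) "mono"
  else if (length(multi_targets) >= 2) "multi"
  else "indeterminate"
  basis <- switch(verdict,
    mono = paste0("mono-pattern response to: ",
                  paste(mono$drug, collapse = ", ")),
    multi = paste0("multi-pattern responses hitting distinct targets: ",
                   paste(multi_targets, collapse = ", ")),
    "no mono-pattern response and <2 distinct-target multi-pattern responses")
  tibble::tibble(
    verdict = verdict,
    n_mono = nrow(mono), n_multi = nrow(multi),
    n_distinct_multi_targets = length(multi_targets),
    basis = basis)
}

# --- internals --------------------------------------------------------------

# Column lookup that tolerates absent columns (no tibble warning).
col_or <- function(row, nm, default = NULL) {
  if (nm %in% names(row)) row[[nm]] else default
}

normalize_targets <- function(targets) {
  if (is.null(targets))
    return(tibble::tibble(drug = character(), target = character()))
  if (is.data.frame(targets)) {
    stopifnot(all(c("drug", "target") %in% names(targets)))
    return(tibble::as_tibble(targets)[, c("drug", "target")])
  }
  tibble::tibble(drug = names(targets), target = unname(targets))
}

extract_hill_row <- function(hill) {
  if (inherits(hill, "hill_fit")) {
    return(list(n = hill$params$n, ic50_nM = hill$params$ic50_nM,
                i_max = hill$params$i_max, converged = hill$converged,
                cell_line = hill$cell_line, drug = hill$treatment))
  }
  row <- tibble::as_tibble(hill)
  stopifnot(nrow(row) == 1)
  n <- col_or(row, "hill_n", col_or(row, "n"))
  i_max <- if ("i_max_pct" %in% names(row)) row$i_max_pct / 100
  else col_or(row, "i_max")
  list(n = n, ic50_nM = row$ic50_star_nM, i_max = i_max,
       converged = col_or(row, "converged", TRUE),
       cell_line = col_or(row, "cell_line", NA_character_),
       drug = col_or(row, "drug", col_or(row, "treatment", NA_character_)))
}

extract_biphasic_row <- function(biphasic) {
  if (inherits(biphasic, "biphasic_fit")) {
    return(list(f1 = biphasic$params$f1, kd1_nM = biphasic$params$kd1_nM,
                converged = biphasic$converged,
                cell_line = biphasic$cell_line, drug = biphasic$treatment))
  }
  row <- tibble::as_tibble(biphasic)
  stopifnot(nrow(row) == 1)
  f1 <- if ("f1_pct" %in% names(row)) row$f1_pct / 100
  else col_or(row, "f1")
  list(f1 = f1, kd1_nM = row$kd1_nM,
       converged = col_or(row, "converged", TRUE),
       cell_line = col_or(row, "cell_line", NA_character_),
       drug = col_or(row, "drug", col_or(row, "treatment", NA_character_)))
}
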
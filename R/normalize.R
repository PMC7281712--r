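#' Normalize raw plate absorbances to inhibition fractions
#'
#' MTT-style viability plates measure formazan absorbance at 490 nm with a
#' 750 nm background read; the corrected absorbance `a490 - a750` is the
#' viability signal.  Relative viability of a treated well is its corrected
#' absorbance divided by the mean corrected absorbance of the matching
#' control wells, and inhibition is `I = 1 - V`.
#'
#' Controls are matched within (`cell_line`, `treatment`); when a treated
#' group carries no controls of its own, cell-line-wide controls (any
#' treatment) are used.  A treated group with no usable controls is an error.
#'
#' Inhibition values are deliberately not clamped to \[0, 1\]: replicate
#' noise below 0 or above 1 is informative for fitting.  Clamping is applied
#' only at the interpolation/plotting boundary (see [ic_x()]).
#'
#' @param wells Data frame of wells with columns `cell_line`, `treatment`,
#'   `replicate`, `a490`, `a750`, `is_control`, and either `conc_nM` or
#'   `concentration` + `unit` (converted via [as_nM()]).  Control wells must
#'   have concentration 0.
#' @return A tibble of per-well responses with columns `cell_line`,
#'   `treatment`, `conc_nM`, `replicate`, `viability`, `inhibition`,
#'   ordered by ascending concentration within each curve.
#' @export
#' @examples
#' wells <- tibble::tibble(
#'   cell_line = "A", treatment = "drugX",
#'   conc_nM = c(0, 0, 10, 10), replicate = c(1, 2, 1, 2),
#'   a490 = c(1.05, 1.05, 0.55, 0.55), a750 = 0.05,
#'   is_control = c(TRUE, TRUE, FALSE, FALSE))
#' normalize_plate(wells)
normalize_plate <- function(wells) {
  wells <- as_well_tbl(wells)
  if (any(wells$a490 < 0, na.rm = TRUE) || any(wells$a750 < 0, na.rm = TRUE))
    abort("absorbances must be non-negative")
  wells$corrected <- wells$a490 - wells$a750
  if (any(wells$corrected < 0, na.rm = TRUE)) {
    warn(sprintf(
      "%d well(s) have negative corrected absorbance (a490 - a750); retained",
      sum(wells$corrected < 0, na.rm = TRUE)))
  }
  if (any(wells$is_control & wells$conc_nM != 0))
    abort("control wells must have concentration 0")

  ctrl <- dplyr::filter(wells, .data$is_control)
  ctrl_by_trt <- ctrl |>
    dplyr::group_by(.data$cell_line, .data$treatment) |>
    dplyr::summarise(ctrl_mean = mean(.data$corrected), .groups = "drop")
  ctrl_by_cell <- ctrl |>
    dplyr::group_by(.data$cell_line) |>
    dplyr::summarise(cell_ctrl_mean = mean(.data$corrected), .groups = "drop")

  out <- wells |>
    dplyr::filter(!.data$is_control) |>
    dplyr::left_join(ctrl_by_trt, by = c("cell_line", "treatment")) |>
    dplyr::left_join(ctrl_by_cell, by = "cell_line") |>
    dplyr::mutate(ctrl_mean = dplyr::coalesce(.data$ctrl_mean,
                                              .data$cell_ctrl_mean))
  if (any(is.na(out$ctrl_mean))) {
    missing <- out |>
      dplyr::filter(is.na(.data$ctrl_mean)) |>
      dplyr::distinct(.data$cell_line, .data$treatment)
    abort(paste0("no control wells for group(s): ",
                 paste(missing$cell_line, missing$treatment, sep = "/",
                       collapse = ", ")))
  }
  out |>
    dplyr::mutate(viability = .data$corrected / .data$ctrl_mean,
                  inhibition = 1 - .data$viability) |>
    dplyr::select("cell_line", "treatment", "conc_nM", "replicate",
                  "viability", "inhibition") |>
    dplyr::arrange(.data$cell_line, .data$treatment, .data$conc_nM,
                   .data$replicate)
}

#' Normalize a GDSC-style raw viability table
#'
#' Screening databases distribute raw per-well intensities with control
#' wells tagged in a `tag` column.  Relative viability is
#' `intensity / mean(control intensities)` within each (`cell_line`,
#' `treatment`) group (falling back to cell-line-wide controls), and
#' inhibition is `1 - viability`.
#'
#' @param raw Data frame with columns `cell_line`, `treatment` (or `drug`),
#'   `intensity`, `tag` (values `"control"` or `"treated"`), and either
#'   `conc_nM` or `concentration` + `unit`.
#' @return A tibble in the same per-well response layout as
#'   [normalize_plate()].
#' @export
normalize_gdsc <- function(raw) {
  raw <- tibble::as_tibble(raw)
  if ("drug" %in% names(raw) && !"treatment" %in% names(raw))
    raw <- dplyr::rename(raw, treatment = "drug")
  need <- c("cell_line", "treatment", "intensity", "tag")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    abort(paste0("missing column(s): ", paste(miss, collapse = ", ")))
  bad <- setdiff(unique(raw$tag), c("control", "treated"))
  if (length(bad))
    abort(paste0("`tag` must be 'control' or 'treated'; found: ",
                 paste(bad, collapse = ", ")))
  if (!any(raw$tag == "control"))
    abort("no control wells: every group needs a control designation")
  raw <- resolve_conc(raw, zero_ok = TRUE)
  if (!"replicate" %in% names(raw)) {
    raw <- raw |>
      dplyr::group_by(.data$cell_line, .data$treatment, .data$conc_nM,
                      .data$tag) |>
      dplyr::mutate(replicate = dplyr::row_number()) |>
      dplyr::ungroup()
  }

  ctrl <- dplyr::filter(raw, .data$tag == "control")
  ctrl_by_trt <- ctrl |>
    dplyr::group_by(.data$cell_line, .data$treatment) |>
    dplyr::summarise(ctrl_mean = mean(.data$intensity), .groups = "drop")
  ctrl_by_cell <- ctrl |>
    dplyr::group_by(.data$cell_line) |>
    dplyr::summarise(cell_ctrl_mean = mean(.data$intensity), .groups = "drop")

  out <- raw |>
    dplyr::filter(.data$tag == "treated") |>
    dplyr::left_join(ctrl_by_trt, by = c("cell_line", "treatment")) |>
    dplyr::left_join(ctrl_by_cell, by = "cell_line") |>
    dplyr::mutate(ctrl_mean = dplyr::coalesce(.data$ctrl_mean,
                                              .data$cell_ctrl_mean))
  if (any(is.na(out$ctrl_mean))) {
    missing <- out |>
      dplyr::filter(is.na(.data$ctrl_mean)) |>
      dplyr::distinct(.data$cell_line, .data$treatment)
    abort(paste0("no control wells for group(s): ",
                 paste(missing$cell_line, missing$treatment, sep = "/",
                       collapse = ", ")))
  }
  out |>
    dplyr::mutate(viability = .data$intensity / .data$ctrl_mean,
                  inhibition = 1 - .data$viability) |>
    dplyr::select("cell_line", "treatment", "conc_nM", "replicate",
                  "viability", "inhibition") |>
    dplyr::arrange(.data$cell_line, .data$treatment, .data$conc_nM,
                   .data$replicate)
}

#' Per-concentration summary of a dose-response curve
#'
#' Collapses replicate inhibition measurements to the per-concentration mean
#' and standard error used for fitting and interpolation.
#'
#' @param data Per-well response tibble (columns `cell_line`, `treatment`,
#'   `conc_nM`, `inhibition`; extra columns are ignored).
#' @return A tibble with one row per (`cell_line`, `treatment`, `conc_nM`):
#'   `mean_inhibition`, `sem`, `n_rep`, concentrations strictly ascending.
#' @export
curve_means <- function(data) {
  data <- as_response_tbl(data)
  data |>
    dplyr::group_by(.data$cell_line, .data$treatment, .data$conc_nM) |>
    dplyr::summarise(
      mean_inhibition = mean(.data$inhibition),
      sem = stats::sd(.data$inhibition) / sqrt(dplyr::n()),
      n_rep = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$cell_line, .data$treatment, .data$conc_nM)
}

# --- internal coercion helpers ---------------------------------------------

# Accept conc_nM directly, or concentration + unit columns.
resolve_conc <- function(df, zero_ok = TRUE) {
  if (!"conc_nM" %in% names(df)) {
    if (!all(c("concentration", "unit") %in% names(df)))
      abort("need a `conc_nM` column or `concentration` + `unit` columns")
    df$conc_nM <- as_nM(df$concentration, df$unit)
    df$concentration <- NULL
    df$unit <- NULL
  }
  if (!zero_ok && any(df$conc_nM <= 0))
    abort("dosed wells must have positive concentration")
  df
}

as_well_tbl <- function(wells) {
  wells <- tibble::as_tibble(wells)
  wells <- resolve_conc(wells, zero_ok = TRUE)
  need <- c("cell_line", "treatment", "conc_nM", "replicate",
            "a490", "a750", "is_control")
  miss <- setdiff(need, names(wells))
  if (length(miss))
    abort(paste0("missing column(s): ", paste(miss, collapse = ", ")))
  dup <- wells |>
    dplyr::filter(!.data$is_control) |>
    dplyr::count(.data$cell_line, .data$treatment, .data$conc_nM,
                 .data$replicate) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup))
    abort("replicate index must be unique within (cell_line, treatment, concentration)")
  wells
}

as_response_tbl <- function(data) {
  data <- tibble::as_tibble(data)
  data <- resolve_conc(data, zero_ok = TRUE)
  need <- c("cell_line", "treatment", "conc_nM", "inhibition")
  miss <- setdiff(need, names(data))
  if (length(miss))
    abort(paste0("missing column(s): ", paste(miss, collapse = ", ")))
  data
}

# Extract the single (cell_line, treatment) curve from a response tibble,
# erroring when several are present.
single_curve <- function(data, what = "this operation") {
  data <- as_response_tbl(data)
  ids <- dplyr::distinct(data, .data$cell_line, .data$treatment)
  if (nrow(ids) != 1) {
    abort(paste0(what, " expects a single (cell_line, treatment) curve; got ",
                 nrow(ids), ". Use fit_panel() or group explicitly."))
  }
  data
}
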
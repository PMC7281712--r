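CURVE_CSV_COLS <- c("cell_line", "drug", "concentration", "unit",
                    "replicate", "value", "value_type")
VALUE_TYPES <- c("absorbance_pair", "viability", "inhibition")

#' Read a long-format dose-response CSV
#'
#' Expected header: `cell_line, drug, concentration, unit, replicate, value,
#' value_type`.  `value_type` selects how `value` is interpreted per row:
#' `"inhibition"` (used as is), `"viability"` (inhibition is `1 - value`),
#' or `"absorbance_pair"` (`value` is the background-corrected absorbance
#' `a490 - a750`; rows with concentration 0 are the controls and the group
#' is normalized as in [normalize_plate()]).
#'
#' @param path Path to a CSV file.
#' @return A per-well response tibble (see [normalize_plate()]) with
#'   concentrations converted to nM.
#' @export
read_curve_csv <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  miss <- setdiff(CURVE_CSV_COLS, names(raw))
  if (length(miss))
    abort(paste0("missing column(s) in ", path, ": ",
                 paste(miss, collapse = ", ")))
  bad_type <- !(raw$value_type %in% VALUE_TYPES)
  if (any(bad_type)) {
    abort(sprintf(
      "line %d: unknown value_type '%s'; accepted values: %s",
      which(bad_type)[1] + 1L, raw$value_type[which(bad_type)[1]],
      paste(VALUE_TYPES, collapse = ", ")))
  }
  num <- function(col) suppressWarnings(as.numeric(raw[[col]]))
  conc <- num("concentration"); val <- num("value"); rep <- num("replicate")
  malformed <- is.na(conc) | is.na(val) | is.na(rep)
  if (any(malformed)) {
    i <- which(malformed)[1]
    bad_cols <- c("concentration", "value", "replicate")[
      c(is.na(conc[i]), is.na(val[i]), is.na(rep[i]))]
    abort(sprintf("line %d: malformed row (non-numeric %s)",
                  i + 1L, paste(bad_cols, collapse = ", ")))
  }
  tbl <- tibble::tibble(
    cell_line = raw$cell_line, treatment = raw$drug,
    conc_nM = as_nM(conc, raw$unit), replicate = rep,
    value = val, value_type = raw$value_type)

  parts <- list()
  direct <- dplyr::filter(tbl, .data$value_type != "absorbance_pair")
  if (nrow(direct)) {
    parts$direct <- direct |>
      dplyr::mutate(
        inhibition = ifelse(.data$value_type == "viability",
                            1 - .data$value, .data$value),
        viability = 1 - .data$inhibition)
  }
  absorb <- dplyr::filter(tbl, .data$value_type == "absorbance_pair")
  if (nrow(absorb)) {
    wells <- absorb |>
      dplyr::mutate(a490 = .data$value, a750 = 0,
                    is_control = .data$conc_nM == 0)
    if (!any(wells$is_control))
      abort("absorbance_pair rows need control rows at concentration 0")
    parts$absorb <- normalize_plate(wells)
  }
  dplyr::bind_rows(parts) |>
    dplyr::select("cell_line", "treatment", "conc_nM", "replicate",
                  "viability", "inhibition") |>
    dplyr::arrange(.data$cell_line, .data$treatment, .data$conc_nM,
                   .data$replicate)
}

#' Write a per-well response tibble as a long-format CSV
#'
#' Writes the schema read by [read_curve_csv()] (unit `nM`, value_type
#' `inhibition`), so write-then-read round-trips exactly.
#'
#' @param data Per-well response tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_curve_csv <- function(data, path) {
  data <- as_response_tbl(data)
  out <- tibble::tibble(
    cell_line = data$cell_line, drug = data$treatment,
    concentration = data$conc_nM, unit = "nM",
    replicate = data$replicate, value = data$inhibition,
    value_type = "inhibition")
  readr::write_csv(out, path)
  invisible(path)
}

#' Write a joint Hill/biphasic fit table
#'
#' Serializes a panel fit (see [fit_panel()]) in the conventional reporting
#' layout: per (cell line, drug) row the Hill RMSE, I_max (%), IC50* (nM)
#' and n, then the biphasic RMSE, F1/F2 (%), Kd1 (nM) and Kd2 (uM).
#' Censored Kd2 is written `">100"` and an absent second phase `"None"`.
#' Numeric columns keep at least six significant digits.
#'
#' @param fits Panel tibble from [fit_panel()], or any tibble with the flat
#'   columns produced by it.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_fit_table <- function(fits, path) {
  cols <- c("cell_line", "drug", "hill_rmse", "i_max_pct", "ic50_star_nM",
            "hill_n", "biphasic_rmse", "f1_pct", "f2_pct", "kd1_nM",
            "kd2_uM", "kd2_censored", "second_phase_absent")
  miss <- setdiff(cols, names(fits))
  if (length(miss))
    abort(paste0("missing column(s): ", paste(miss, collapse = ", ")))
  out <- fits |>
    dplyr::mutate(
      kd2_uM = dplyr::case_when(
        .data$second_phase_absent ~ "None",
        .data$kd2_censored ~ ">100",
        TRUE ~ formatC(.data$kd2_uM, digits = 6, format = "g")),
      dplyr::across(dplyr::where(is.numeric), \(x) signif(x, 7))) |>
    dplyr::select(dplyr::all_of(cols))
  readr::write_csv(out, path)
  invisible(path)
}

#' Read a fit table written by [write_fit_table()]
#'
#' Also reads externally prepared fitted-parameter tables in the same
#' layout (e.g. published panels used as classification fixtures).  The
#' `">100"` and `"None"` conventions in `kd2_uM` are parsed back into the
#' `kd2_censored` / `second_phase_absent` flags.
#'
#' @param path CSV path.
#' @return A tibble with numeric columns and logical reporting flags.
#' @export
read_fit_table <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  need <- c("cell_line", "drug", "hill_rmse", "i_max_pct", "ic50_star_nM",
            "hill_n", "biphasic_rmse", "f1_pct", "kd1_nM", "kd2_uM")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    abort(paste0("missing column(s) in ", path, ": ",
                 paste(miss, collapse = ", ")))
  kd2 <- trimws(raw$kd2_uM)
  absent <- kd2 %in% c("None", "none", "NA")
  censored <- grepl("^>", kd2)
  kd2_num <- suppressWarnings(as.numeric(gsub("^>", "", kd2)))
  kd2_num[absent] <- NA_real_
  tibble::tibble(
    cell_line = raw$cell_line, drug = raw$drug,
    hill_rmse = as.numeric(raw$hill_rmse),
    i_max_pct = as.numeric(raw$i_max_pct),
    ic50_star_nM = as.numeric(raw$ic50_star_nM),
    hill_n = as.numeric(raw$hill_n),
    biphasic_rmse = as.numeric(raw$biphasic_rmse),
    f1_pct = as.numeric(raw$f1_pct),
    f2_pct = if ("f2_pct" %in% names(raw)) as.numeric(raw$f2_pct)
             else 100 - as.numeric(raw$f1_pct),
    kd1_nM = as.numeric(raw$kd1_nM),
    kd2_uM = kd2_num,
    kd2_censored = censored,
    second_phase_absent = absent,
    target = if ("target" %in% names(raw)) raw$target else NA_character_)
}
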
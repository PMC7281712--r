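#' Run the fitting stage and write fit-table reports
#'
#' Fits both models to every curve in `data`, writes the fit table as CSV
#' (conventional layout, see [write_fit_table()]) and as JSON with run
#' metadata.  Reports embed the package version, the seed, and a hash of
#' the run configuration, so reruns with identical inputs are
#' byte-identical and self-describing.  Percentages appear only in report
#' columns; all internal computation is on fractions.
#'
#' @param data Per-well response tibble.
#' @param dir Output directory (created if needed).
#' @param seed Integer seed recorded in the report (and set before
#'   fitting, for reproducibility of any downstream stochastic step).
#' @param use_replicates,collapse_tol Passed to [fit_panel()].
#' @return Invisibly, a list with `fits` (the panel tibble) and the output
#'   `paths`.
#' @export
report_fits <- function(data, dir, seed = 1L, use_replicates = FALSE,
                        collapse_tol = 0.10) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  config <- list(stage = "fit", seed = seed,
                 use_replicates = use_replicates,
                 collapse_tol = collapse_tol)
  set.seed(seed)
  fits <- fit_panel(data, use_replicates = use_replicates,
                    collapse_tol = collapse_tol)
  csv <- file.path(dir, "fit_table.csv")
  write_fit_table(fits, csv)
  json <- file.path(dir, "fit_table.json")
  flat <- dplyr::select(fits, -"hill_fit", -"biphasic_fit")
  write_report_json(json, config, fits = flat)
  invisible(list(fits = fits, paths = c(csv = csv, json = json)))
}

#' Run the classification stage and write reports
#'
#' @param fit_table Panel fit tibble ([fit_panel()] or [read_fit_table()]).
#' @param targets Drug-to-target annotations (named vector or data frame).
#' @param dir Output directory.
#' @param thresholds A [driver_thresholds()] list.
#' @param seed Integer seed recorded in the report.
#' @return Invisibly, a list with `responses`, `cell_lines`, and `paths`.
#' @export
report_classification <- function(fit_table, targets = NULL, dir,
                                  thresholds = driver_thresholds(),
                                  seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  config <- list(stage = "classify", seed = seed, thresholds = thresholds)
  responses <- classify_fit_table(fit_table, thresholds = thresholds)
  cell_lines <- responses |>
    dplyr::group_by(.data$cell_line) |>
    dplyr::group_modify(\(g, key) classify_cell_line(g, targets)) |>
    dplyr::ungroup()
  csv <- file.path(dir, "classification.csv")
  readr::write_csv(responses, csv)
  json <- file.path(dir, "classification.json")
  write_report_json(json, config, responses = responses,
                    cell_lines = cell_lines)
  invisible(list(responses = responses, cell_lines = cell_lines,
                 paths = c(csv = csv, json = json)))
}

#' Run the synergy stage and write reports
#'
#' @param curve1,curve2,curve_combo Response tibbles for the two single
#'   agents and the 1:1 combination.
#' @param dir Output directory.
#' @param levels Inhibition levels for IC_x extraction.
#' @param seed Integer seed recorded in the report.
#' @return Invisibly, a list with the `report` tibble, `isobolograms`
#'   (per attainable level), and `paths`.
#' @export
report_synergy <- function(curve1, curve2, curve_combo, dir,
                           levels = c(0.5, 0.7, 0.9), seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  config <- list(stage = "synergy", seed = seed, levels = levels)
  rep_tbl <- synergy_report(curve1, curve2, curve_combo, levels = levels)
  isos <- rep_tbl |>
    dplyr::filter(!is.na(.data$interaction_index)) |>
    purrr::pmap(function(level, ic1_nM, ic2_nM, ic_combo_nM, ...) {
      isobologram_points(ic1_nM, ic2_nM, ic_combo_nM, ic_combo_nM)
    })
  csv <- file.path(dir, "synergy.csv")
  readr::write_csv(rep_tbl, csv)
  iso_csv <- file.path(dir, "isobologram_points.csv")
  iso_tbl <- purrr::map2_dfr(
    isos, rep_tbl$level[!is.na(rep_tbl$interaction_index)],
    function(iso, lv) {
      dplyr::bind_rows(
        dplyr::mutate(iso$additivity_line, part = "additivity_line"),
        dplyr::mutate(iso$combination, part = "combination")) |>
        dplyr::mutate(level = lv)
    })
  readr::write_csv(iso_tbl, iso_csv)
  json <- file.path(dir, "synergy.json")
  write_report_json(json, config, synergy = rep_tbl)
  invisible(list(report = rep_tbl, isobolograms = isos,
                 paths = c(csv = csv, iso_csv = iso_csv, json = json)))
}

#' Run the simulation stage and write fixture datasets
#'
#' Simulates a monotherapy plate for each supplied truth and writes the
#' well-level CSV (core long format) plus a JSON config echo with the
#' embedded seed.
#'
#' @param truths Named list of [biphasic_params()] (names = drug labels).
#' @param dir Output directory.
#' @param cell_line Cell-line label for the simulated wells.
#' @inheritParams simulate_monotherapy
#' @return Invisibly, a list with `curves` (named list of response
#'   tibbles) and `paths`.
#' @export
report_simulation <- function(truths, dir, cell_line = "SIM",
                              grid = dilution_grid(), replicates = 3,
                              noise_sd = 0.02, seed = 1L) {
  stopifnot(length(truths) >= 1, !is.null(names(truths)))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  config <- list(stage = "simulate", seed = seed, noise_sd = noise_sd,
                 replicates = replicates, grid_nM = grid,
                 drugs = names(truths))
  curves <- purrr::imap(truths, function(truth, nm) {
    simulate_monotherapy(truth, grid = grid, replicates = replicates,
                         noise_sd = noise_sd,
                         seed = seed + match(nm, names(truths)) - 1L,
                         cell_line = cell_line, treatment = nm)
  })
  csv <- file.path(dir, "simulated_curves.csv")
  write_curve_csv(dplyr::bind_rows(curves), csv)
  json <- file.path(dir, "simulation_config.json")
  write_report_json(json, config)
  invisible(list(curves = curves, paths = c(csv = csv, json = json)))
}

# Shared JSON writer: every report carries version, seed and config hash.
write_report_json <- function(path, config, ...) {
  payload <- list(
    package = "biphasr",
    version = as.character(utils::packageVersion("biphasr")),
    seed = config$seed,
    config = config,
    config_hash = rlang::hash(config),
    ...)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
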
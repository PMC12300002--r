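# Run orchestration and reporting: tidy CSV exports, a reproducibility
# manifest, and trajectory figures with action-level reference lines.
# The numeric CSVs are the contract surface; figures are a convenience.

#' Run a stochastic simulation and write its outputs
#'
#' Simulates the ensemble for each requested analyte and writes tidy
#' trajectory and summary CSVs plus a JSON manifest sufficient to
#' reproduce the run (seed, draw count, package version, file list).
#'
#' @param scn Scenario.
#' @param out_dir Output directory (created if needed).
#' @param analytes Analytes to simulate (default: all in the scenario).
#' @param n,seed As in [simulate_ensemble()].
#' @return Named list of `herdtk_ensemble`, invisibly.
#' @export
run_simulation <- function(scn, out_dir,
                           analytes = scn$analytes,
                           n = scn$params$simulation$n_draws,
                           seed = scn$params$simulation$seed) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  ensembles <- list()
  for (a in analytes) {
    ens <- simulate_ensemble(scn, a, n = n, seed = seed)
    ensembles[[a]] <- ens
    long <- tidyr::pivot_longer(
      ens$trajectories[, c("draw", "date", "serum", "muscle", "milk")],
      cols = c("serum", "muscle", "milk"),
      names_to = "matrix", values_to = "value")
    long$analyte <- a
    tr_path <- file.path(out_dir, sprintf("trajectories_%s.csv", a))
    readr::write_csv(long[, c("draw", "date", "matrix", "analyte", "value")],
                     tr_path, progress = FALSE)
    sm <- ens$summary
    sm$analyte <- a
    sm_path <- file.path(out_dir, sprintf("summary_%s.csv", a))
    readr::write_csv(sm, sm_path, progress = FALSE)
    ds_path <- file.path(out_dir, sprintf("doses_%s.csv", a))
    readr::write_csv(ens$dose_series, ds_path, progress = FALSE)
    written <- c(written, tr_path, sm_path, ds_path)
  }
  manifest <- list(
    package = "herdtk",
    version = as.character(utils::packageVersion("herdtk")),
    seed = seed, n_draws = n, analytes = analytes,
    outputs = basename(written)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(ensembles)
}

#' Evaluate a run against biomonitoring and write the report
#'
#' @param ensembles Named list of `herdtk_ensemble` (per analyte), as
#'   returned by [run_simulation()].
#' @param biomonitoring Biomonitoring tibble.
#' @param out_dir Output directory.
#' @param config Evaluation configuration.
#' @return Combined report tibble, invisibly.
#' @export
write_evaluation <- function(ensembles, biomonitoring, out_dir,
                             config = evaluation_config()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  reports <- lapply(ensembles, evaluate_scenario, biomonitoring = biomonitoring,
                    config = config)
  report <- dplyr::bind_rows(reports)
  readr::write_csv(report, file.path(out_dir, "evaluation.csv"),
                   progress = FALSE)
  mape_tbl <- dplyr::summarise(dplyr::group_by(report, .data$analyte),
                               mape = mape(.data$pct_error), .groups = "drop")
  readr::write_csv(mape_tbl, file.path(out_dir, "mape.csv"), progress = FALSE)
  invisible(report)
}

#' Plot an ensemble with action-level reference lines
#'
#' One panel per output matrix: all stochastic traces, the per-day
#' median, optional measured points, and horizontal reference lines at
#' the configured action levels (drawn only for matrix/analyte
#' combinations that have one; none exist for PFDA).
#'
#' @param ensemble A `herdtk_ensemble`.
#' @param matrix Output matrix to plot.
#' @param biomonitoring Optional biomonitoring tibble overlaid as points.
#' @param config Evaluation configuration providing action levels.
#' @return A ggplot object.
#' @export
plot_ensemble <- function(ensemble, matrix = "muscle", biomonitoring = NULL,
                          config = evaluation_config()) {
  tr <- ensemble$trajectories
  df <- tibble::tibble(draw = tr$draw, date = tr$date,
                       value = tr[[matrix]])
  med <- dplyr::summarise(dplyr::group_by(df, .data$date),
                          value = median(.data$value), .groups = "drop")
  unit <- if (matrix == "muscle") "ng/g" else "ng/mL"
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$date, y = .data$value)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$draw),
                       alpha = 0.2, colour = "steelblue") +
    ggplot2::geom_line(data = med, colour = "black", linewidth = 0.8) +
    ggplot2::labs(x = NULL,
                  y = sprintf("%s %s (%s)", ensemble$analyte, matrix, unit)) +
    ggplot2::theme_minimal()
  al <- config$action_levels
  al <- al[al$analyte == ensemble$analyte & al$matrix == matrix, ]
  if (nrow(al) > 0) {
    p <- p + ggplot2::geom_hline(yintercept = al$ng_g, linetype = "dashed")
  }
  if (!is.null(biomonitoring)) {
    bio <- biomonitoring[biomonitoring$analyte == ensemble$analyte &
                           biomonitoring$matrix == matrix, ]
    if (nrow(bio) > 0) {
      p <- p + ggplot2::geom_point(
        data = tibble::tibble(date = bio$date, value = bio$conc),
        colour = "red", shape = 17, size = 2)
    }
  }
  p
}
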
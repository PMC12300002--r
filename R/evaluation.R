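# Model evaluation against biomonitoring: agreement statistics,
# plasma-to-serum harmonization, partition-coefficient meta-analysis, and
# action-level exceedance.

#' Default evaluation configuration
#'
#' Action levels for PFOS in beef muscle (Maine action level 3.4 ng/g, EU
#' maximum limit 0.3 ng/g, USDA interim screening level 4.1 ng/g) and
#' serum/plasma harmonization ratios (PFOS 1.060, PFDA 1.047).
#'
#' @return List with `action_levels` (tibble `name, analyte, matrix,
#'   ng_g`) and `plasma_to_serum` (named vector).
#' @export
evaluation_config <- function() {
  list(
    action_levels = tibble::tibble(
      name = c("maine_beef", "eu_max", "usda_screen"),
      analyte = "PFOS",
      matrix = "muscle",
      ng_g = c(3.4, 0.3, 4.1)
    ),
    plasma_to_serum = c(PFOS = 1.060, PFDA = 1.047)
  )
}

#' Convert plasma concentrations to serum equivalents
#'
#' Multiplies plasma concentrations by the analyte's serum/plasma ratio.
#'
#' @param conc Plasma concentration(s), ng/mL.
#' @param analyte Analyte name(s), recycled against `conc`.
#' @param ratios Named vector of serum/plasma ratios.
#' @return Serum-equivalent concentration(s), ng/mL.
#' @export
plasma_to_serum <- function(conc, analyte,
                            ratios = evaluation_config()$plasma_to_serum) {
  stopifnot(all(conc >= 0))
  r <- ratios[analyte]
  if (anyNA(r)) {
    stop_validation(sprintf("no serum/plasma ratio for: %s",
                            paste(unique(analyte[is.na(r)]), collapse = ", ")))
  }
  unname(conc * r)
}

#' Percentage error of a modeled mean against a measured mean
#'
#' `100 (modeled - measured) / measured`.
#'
#' @param modeled,measured Mean concentrations (same units).
#' @return Signed percentage error.
#' @export
percentage_error <- function(modeled, measured) {
  if (any(measured <= 0)) {
    stop_validation("percentage error undefined for measured mean <= 0")
  }
  100 * (modeled - measured) / measured
}

#' Mean absolute percentage error
#'
#' @param errors Vector of signed percentage errors.
#' @return Mean of the absolute values, in percent.
#' @export
mape <- function(errors) {
  if (length(errors) == 0) stop_validation("mape of an empty error set")
  mean(abs(errors))
}

#' Fold ratio between modeled and measured means
#'
#' `max(modeled/measured, measured/modeled)`, always >= 1.
#'
#' @param modeled,measured Positive means.
#' @return Unitless fold ratio.
#' @export
fold_ratio <- function(modeled, measured) {
  stopifnot(all(modeled > 0), all(measured > 0))
  pmax(modeled / measured, measured / modeled)
}

#' Fraction of ensemble draws exceeding a threshold on a date
#'
#' @param ensemble A `herdtk_ensemble`.
#' @param matrix Output matrix (`serum`, `muscle`, `milk`).
#' @param threshold Concentration threshold (same units as the matrix).
#' @param date Calendar date within the simulated range.
#' @return Fraction of draws with value strictly above the threshold.
#' @export
exceedance_fraction <- function(ensemble, matrix, threshold, date) {
  date <- as.Date(date)
  tr <- ensemble$trajectories
  sel <- tr$date == date
  if (!any(sel)) {
    stop_validation(sprintf("date %s outside the simulated range", date))
  }
  mean(tr[[matrix]][sel] > threshold)
}

#' Meta-analysis of tissue/serum partition coefficients
#'
#' Computes per-pair tissue/serum ratios, per-dataset means, and a
#' meta-mean across datasets (weighted by dataset n by default, or
#' unweighted), with the between-dataset SD. Plasma-matrix blood values
#' are converted to serum equivalents first; pairs with zero serum are
#' excluded with a warning.
#'
#' @param pairs Tibble with columns `dataset`, `tissue`, `blood`, and
#'   optionally `blood_matrix` (`serum`/`plasma`) and `analyte` (needed
#'   for plasma conversion).
#' @param weights `"n"` (dataset size) or `"equal"`.
#' @param ratios Serum/plasma ratios for the conversion.
#' @return List with `meta_mean`, `meta_sd` (between-dataset SD),
#'   `dataset_means` tibble, and `n_excluded`.
#' @export
meta_pm <- function(pairs, weights = c("n", "equal"),
                    ratios = evaluation_config()$plasma_to_serum) {
  weights <- match.arg(weights)
  pairs <- tibble::as_tibble(pairs)
  blood <- pairs$blood
  if ("blood_matrix" %in% names(pairs)) {
    is_plasma <- pairs$blood_matrix == "plasma"
    if (any(is_plasma)) {
      blood[is_plasma] <- plasma_to_serum(blood[is_plasma],
                                          pairs$analyte[is_plasma], ratios)
    }
  }
  bad <- blood <= 0
  n_excluded <- sum(bad)
  if (n_excluded > 0) {
    warning(sprintf("%d pair(s) with non-positive serum excluded", n_excluded))
  }
  ok <- !bad
  ratio <- pairs$tissue[ok] / blood[ok]
  ds <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(dataset = pairs$dataset[ok], ratio = ratio),
                    .data$dataset),
    mean_ratio = mean(.data$ratio), n = dplyr::n(), .groups = "drop")
  w <- if (weights == "n") ds$n else rep(1, nrow(ds))
  meta_mean <- sum(w * ds$mean_ratio) / sum(w)
  meta_sd <- if (nrow(ds) > 1) sd(ds$mean_ratio) else 0
  list(meta_mean = meta_mean, meta_sd = meta_sd, dataset_means = ds,
       n_excluded = n_excluded)
}

#' Estimate an elimination half-life from depuration biomonitoring
#'
#' Log-linear (first-order) fit per animal over a zero-exposure window:
#' `log(conc) ~ days`, half-life `ln(2) / -slope`. Returns per-animal
#' estimates and their mean.
#'
#' @param records Tibble `animal_id, date, conc` with positive
#'   concentrations.
#' @return List with `dt50` (mean across animals) and `per_animal` tibble.
#' @export
fit_depuration_dt50 <- function(records) {
  records <- records[records$conc > 0, ]
  per <- dplyr::group_by(tibble::as_tibble(records), .data$animal_id)
  per <- dplyr::summarise(
    per,
    slope = coef(lm(log(.data$conc) ~ as.numeric(.data$date)))[2],
    .groups = "drop")
  per$dt50 <- log(2) / -per$slope
  list(dt50 = mean(per$dt50), per_animal = per)
}

#' Compare an ensemble to biomonitoring records
#'
#' Matches each biomonitoring (date, matrix, analyte) group to the
#' same-calendar-day ensemble summary (no interpolation) and reports
#' measured and modeled means/SDs, modeled range, percentage error, and
#' fold ratio. Plasma records are converted to serum equivalents and the
#' conversion is flagged.
#'
#' @param ensemble A `herdtk_ensemble`.
#' @param biomonitoring Tibble `animal_id, date, matrix, analyte, conc`.
#' @param config Evaluation configuration ([evaluation_config()]).
#' @return Tibble with one row per (date, matrix): measured/modeled
#'   means, SDs, modeled min/max, `pct_error`, `fold`, and
#'   `plasma_converted`.
#' @export
evaluate_scenario <- function(ensemble, biomonitoring,
                              config = evaluation_config()) {
  bio <- tibble::as_tibble(biomonitoring)
  bio <- bio[bio$analyte == ensemble$analyte, ]
  if (nrow(bio) == 0) {
    stop_validation(sprintf("no biomonitoring records for %s",
                            ensemble$analyte))
  }
  sim_dates <- unique(ensemble$trajectories$date)
  outside <- setdiff(as.character(bio$date), as.character(sim_dates))
  if (length(outside) > 0) {
    stop_validation(sprintf("biomonitoring date(s) outside simulation: %s",
                            paste(outside, collapse = ", ")))
  }
  converted <- bio$matrix == "plasma"
  bio$conc[converted] <- plasma_to_serum(bio$conc[converted],
                                         bio$analyte[converted],
                                         config$plasma_to_serum)
  bio$matrix[converted] <- "serum"
  bio$plasma_converted <- converted

  grp <- dplyr::summarise(
    dplyr::group_by(bio, .data$date, .data$matrix),
    measured_mean = mean(.data$conc),
    measured_sd = if (dplyr::n() > 1) sd(.data$conc) else NA_real_,
    n = dplyr::n(),
    plasma_converted = any(.data$plasma_converted),
    .groups = "drop")

  sm <- ensemble$summary
  out <- dplyr::left_join(grp, sm, by = c("date", "matrix"))
  out <- dplyr::rename(out, modeled_mean = "mean", modeled_sd = "sd",
                       modeled_min = "min", modeled_max = "max")
  out$pct_error <- percentage_error(out$modeled_mean, out$measured_mean)
  out$fold <- fold_ratio(out$modeled_mean, out$measured_mean)
  out$analyte <- ensemble$analyte
  out[, c("date", "analyte", "matrix", "n", "measured_mean", "measured_sd",
          "modeled_mean", "modeled_sd", "modeled_min", "modeled_max",
          "pct_error", "fold", "plasma_converted")]
}
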
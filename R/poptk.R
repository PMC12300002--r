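# Population toxicokinetics: first-order one-compartment kinetics driven by
# the daily dose series.
#
# The compartment tracks body burden (ng); serum concentration is burden /
# (Vd x BW x 1000 mL/L), so growth dilutes automatically as BW rises.
# Muscle and milk are constant-ratio partitions of serum (PM, Pmilk).
# Discrete daily stepping credits the dose at the end of each step:
# A' = A exp(-k dt) + dose.  At realistic rates (k <= 0.02/day) this stays
# within ~2% of the continuous ODE.

#' First-order elimination rate from a half-life
#'
#' `k = ln(2) / DT50`.
#'
#' @param dt50_days Serum elimination half-life, days.
#' @return Rate constant, per day.
#' @export
elimination_rate <- function(dt50_days) {
  stopifnot(all(dt50_days > 0))
  log(2) / dt50_days
}

#' One kinetic step
#'
#' `A' = A exp(-k dt) + dose`, dose credited at the end of the step.
#'
#' @param burden_ng Body burden at the start of the step, ng.
#' @param dose_ng Dose absorbed during the step, ng.
#' @param k Elimination rate, per day.
#' @param dt_days Step length, days.
#' @return Body burden at the end of the step, ng.
#' @export
tk_step <- function(burden_ng, dose_ng, k, dt_days = 1) {
  burden_ng * exp(-k * dt_days) + dose_ng
}

# Mean-parameter TK set for one analyte.
mean_tk_params <- function(scn, analyte) {
  tk <- scn$params$tk[[analyte]]
  if (is.null(tk)) {
    stop_validation(sprintf("no toxicokinetic parameters for %s", analyte))
  }
  list(DT50 = tk$DT50[1], Vd = tk$Vd[1], PM = tk$PM[1], Pmilk = tk$Pmilk[1])
}

#' Simulate one animal's trajectory
#'
#' Runs the daily kinetic recursion over a dose series and body-weight
#' series of equal length. Day 0 carries the maternal-transfer initial
#' condition (`serum0`); subsequent days apply [tk_step()]. Serum is
#' derived from burden through `Vd x BW`, and muscle/milk as `PM x serum`
#' and `Pmilk x serum`.
#'
#' @param dose_ng Numeric vector of daily absorbed doses (ng/day); the
#'   day-0 entry is ignored (the initial condition stands in for it).
#' @param bw_kg Numeric vector of daily body weights (kg), same length.
#' @param params List with `DT50` (days), `Vd` (L/kg), `PM`, `Pmilk`.
#' @param serum0 Initial serum concentration at day 0, ng/mL.
#' @param dates Optional Date vector for the output.
#' @return Tibble `date, burden, serum, muscle, milk`.
#' @export
simulate_trajectory <- function(dose_ng, bw_kg, params, serum0 = 0,
                                dates = NULL) {
  n <- length(dose_ng)
  if (length(bw_kg) != n) {
    stop_validation("dose and body-weight series must have equal length")
  }
  k <- elimination_rate(params$DT50)
  burden0 <- serum0 * params$Vd * bw_kg[1] * 1000
  burden <- if (n > 1) {
    c(burden0, as.numeric(stats::filter(dose_ng[-1], exp(-k),
                                        method = "recursive",
                                        init = burden0)))
  } else {
    burden0
  }
  serum <- burden / (params$Vd * bw_kg * 1000)
  tibble::tibble(
    date = if (is.null(dates)) seq_len(n) else dates,
    burden = burden,
    serum = serum,
    muscle = params$PM * serum,
    milk = params$Pmilk * serum
  )
}

#' Draw stochastic toxicokinetic parameter sets
#'
#' Independent normal draws per parameter (DT50, Vd, PM, Pmilk) using the
#' configured means and SDs, truncated below at 0.01 x mean by
#' resampling.
#'
#' @param n Number of draws.
#' @param tk Per-analyte parameter list: each of `DT50`, `Vd`, `PM`,
#'   `Pmilk` a `c(mean, sd)` pair.
#' @return Tibble `draw, DT50, Vd, PM, Pmilk`.
#' @export
draw_tk_params <- function(n, tk) {
  draw1 <- function(ms) {
    m <- ms[1]; s <- if (length(ms) > 1) ms[2] else 0
    stopifnot(m > 0, s >= 0)
    x <- rnorm(n, m, s)
    lo <- 0.01 * m
    while (any(x < lo)) {
      bad <- x < lo
      x[bad] <- rnorm(sum(bad), m, s)
    }
    x
  }
  tibble::tibble(draw = seq_len(n), DT50 = draw1(tk$DT50), Vd = draw1(tk$Vd),
                 PM = draw1(tk$PM), Pmilk = draw1(tk$Pmilk))
}

#' Simulate a stochastic ensemble
#'
#' Runs `n` stochastic trajectories for one analyte: each draw uses an
#' independent toxicokinetic parameter set and per-animal feed/water
#' intake factors (normal, mean 1, SD `intake_cv`). The milk pathway and
#' the maternal-transfer initial serum come from a single deterministic
#' dam run shared by all draws. A fixed seed reproduces the ensemble
#' exactly.
#'
#' @param scn Scenario.
#' @param analyte Analyte name.
#' @param n Number of stochastic draws (default from the scenario, 100).
#' @param seed RNG seed (default from the scenario).
#' @param tk_override Optional replacement for the analyte's TK parameter
#'   list (used by [vd_sensitivity()]).
#' @return A `herdtk_ensemble`: list with `trajectories` (tibble
#'   `draw, date, burden, serum, muscle, milk`), `draws` (parameters and
#'   intake factors per draw), `summary` (per day x matrix mean, sd,
#'   quantiles), and run metadata.
#' @export
simulate_ensemble <- function(scn, analyte,
                              n = scn$params$simulation$n_draws,
                              seed = scn$params$simulation$seed,
                              tk_override = NULL) {
  stopifnot(n >= 1)
  set.seed(seed)
  tk <- tk_override %||% scn$params$tk[[analyte]]
  mt <- scn$params$tk$maternal_transfer %||% 1.0

  schedule <- daily_schedule(scn)
  nursing_any <- any(schedule$nursing)
  dam_milk <- if (nursing_any || !is.null(scn$dam)) {
    build_dam_milk_series(scn, analyte)
  }
  doses <- build_dose_series(scn, analyte, dam_milk = dam_milk)
  body <- body_states(scn, schedule)
  serum0 <- mt * (dam_milk$serum_at_birth %||% 0)

  params <- draw_tk_params(n, tk)
  factors <- intake_perturbation(n, scn$params$intake$intake_cv %||% 0.30)

  # the feed factor scales everything the animal eats (stored feed, forage,
  # incidental soil, and milk for a nursing calf); the water factor scales
  # drinking water
  feedlike <- doses$dose_feed + doses$dose_pasture + doses$dose_soil +
    doses$dose_milk
  trajs <- vector("list", n)
  for (i in seq_len(n)) {
    dose_i <- factors$f_feed[i] * feedlike +
      factors$f_water[i] * doses$dose_water
    p <- list(DT50 = params$DT50[i], Vd = params$Vd[i],
              PM = params$PM[i], Pmilk = params$Pmilk[i])
    tr <- simulate_trajectory(dose_i, body$bw_kg, p, serum0 = serum0,
                              dates = schedule$date)
    tr$draw <- i
    trajs[[i]] <- tr
  }
  trajectories <- dplyr::bind_rows(trajs)[, c("draw", "date", "burden",
                                              "serum", "muscle", "milk")]
  structure(list(
    analyte = analyte,
    n = n,
    seed = seed,
    draws = dplyr::left_join(params, factors, by = "draw"),
    trajectories = trajectories,
    summary = ensemble_summary(trajectories),
    dose_series = doses,
    dam_milk = dam_milk,
    serum0 = serum0
  ), class = "herdtk_ensemble")
}

#' @export
print.herdtk_ensemble <- function(x, ...) {
  cat(sprintf("<herdtk_ensemble> %s, %d draws, %d days (seed %s)\n",
              x$analyte, x$n,
              length(unique(x$trajectories$date)), format(x$seed)))
  invisible(x)
}

#' Summarize an ensemble per day and output matrix
#'
#' @param trajectories Tibble `draw, date, serum, muscle, milk`.
#' @param probs Quantile probabilities to report.
#' @return Tibble `date, matrix, mean, sd, q05, q50, q95` (one quantile
#'   column per entry of `probs`).
#' @export
ensemble_summary <- function(trajectories, probs = c(0.05, 0.5, 0.95)) {
  long <- tidyr::pivot_longer(
    trajectories[, c("draw", "date", "serum", "muscle", "milk")],
    cols = c("serum", "muscle", "milk"),
    names_to = "matrix", values_to = "value")
  out <- dplyr::summarise(
    dplyr::group_by(long, .data$date, .data$matrix),
    mean = mean(.data$value), sd = sd(.data$value),
    min = min(.data$value), max = max(.data$value),
    .groups = "drop")
  qs <- dplyr::summarise(
    dplyr::group_by(long, .data$date, .data$matrix),
    q = list(quantile(.data$value, probs, names = FALSE)),
    .groups = "drop")
  qtbl <- as.data.frame(do.call(rbind, qs$q))
  names(qtbl) <- sprintf("q%02d", round(100 * probs))
  dplyr::bind_cols(out, qtbl)
}

#' Volume-of-distribution sensitivity analysis
#'
#' Reruns the ensemble with the Vd mean scaled by each factor and its SD
#' scaled identically (constant coefficient of variation), under the same
#' seed. At steady state serum is inversely proportional to Vd, so factor
#' 2 halves the plateau serum and factor 0.5 doubles it.
#'
#' @param scn Scenario.
#' @param analyte Analyte name.
#' @param factors Multiplicative factors for the Vd mean.
#' @param n,seed As in [simulate_ensemble()].
#' @return Named list of `herdtk_ensemble`, one per factor.
#' @export
vd_sensitivity <- function(scn, analyte, factors = c(0.5, 1, 2),
                           n = scn$params$simulation$n_draws,
                           seed = scn$params$simulation$seed) {
  stopifnot(all(factors > 0))
  out <- lapply(factors, function(f) {
    tk <- scn$params$tk[[analyte]]
    tk$Vd <- tk$Vd * f
    simulate_ensemble(scn, analyte, n = n, seed = seed, tk_override = tk)
  })
  names(out) <- as.character(factors)
  out
}

#' Deterministic (mean-parameter) run
#'
#' Single trajectory at the parameter means with unit intake factors;
#' the reference against which stochastic draws are compared and the
#' generator's ground truth for synthetic biomonitoring.
#'
#' @param scn Scenario.
#' @param analyte Analyte name.
#' @return Tibble `date, burden, serum, muscle, milk`.
#' @export
run_deterministic <- function(scn, analyte) {
  schedule <- daily_schedule(scn)
  dam_milk <- if (any(schedule$nursing) || !is.null(scn$dam)) {
    build_dam_milk_series(scn, analyte)
  }
  doses <- build_dose_series(scn, analyte, dam_milk = dam_milk)
  body <- body_states(scn, schedule)
  mt <- scn$params$tk$maternal_transfer %||% 1.0
  serum0 <- mt * (dam_milk$serum_at_birth %||% 0)
  simulate_trajectory(doses$dose_total, body$bw_kg,
                      mean_tk_params(scn, analyte), serum0 = serum0,
                      dates = schedule$date)
}
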
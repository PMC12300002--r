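# Daily absorbed-dose assembly.
#
# The absorbed dose (ng/day) per analyte is the sum over pathways:
# stored feed, pasture forage, incidental soil, drinking water, and dam
# milk for nursing calves.  Absorption fraction is 1 (administered dose =
# absorbed dose).  Mass-based concentrations are ng/g so doses multiply
# kg intakes by 1000; water is ng/L times L/day; milk uses 1 ng/mL = 1
# ng/g and kg = L at unit density.

#' Per-day drinking-water concentration
#'
#' Resolves the water segment active on each simulated day. Days after
#' filter installation are typically explicit 0 ng/L segments.
#'
#' @param scn Scenario.
#' @param analyte Analyte name.
#' @param schedule Daily schedule from [daily_schedule()].
#' @return Tibble `date, water_ng_L`.
#' @export
water_conc_timeline <- function(scn, analyte, schedule = daily_schedule(scn)) {
  seg <- scn$water[scn$water$analyte == analyte, ]
  out <- tibble::tibble(date = schedule$date, water_ng_L = NA_real_)
  for (i in seq_len(nrow(seg))) {
    sel <- out$date >= seg$start[i] & out$date <= seg$end[i]
    out$water_ng_L[sel] <- seg$ng_L[i]
  }
  if (anyNA(out$water_ng_L)) {
    stop_validation(sprintf(
      "water pathway unresolved for %s on %s", analyte,
      out$date[which(is.na(out$water_ng_L))[1]]))
  }
  out
}

#' One day's dose decomposition
#'
#' Pure unit arithmetic combining the day's concentrations and intakes
#' into absorbed-dose components (all ng/day). Vectorized over days.
#'
#' @param feed_ng_g,pasture_ng_g,soil_ng_g Concentrations in ng/g dry
#'   weight (feed applies to stored/clean/supplemental feed days, pasture
#'   to grazed forage).
#' @param water_ng_L Water concentration, ng/L.
#' @param milk_ng_mL Dam-milk concentration, ng/mL.
#' @param dmi_feed_kg,dmi_pasture_kg Dry-matter intake routed to stored
#'   feed and to pasture forage, kg/day.
#' @param soil_kg Soil ingested, kg/day.
#' @param water_L Water consumed, L/day.
#' @param milk_kg Milk consumed, kg/day.
#' @return Tibble of dose components and `dose_total` (ng/day).
#' @export
daily_dose <- function(feed_ng_g, pasture_ng_g, soil_ng_g, water_ng_L,
                       milk_ng_mL, dmi_feed_kg, dmi_pasture_kg, soil_kg,
                       water_L, milk_kg) {
  out <- tibble::tibble(
    dose_feed = feed_ng_g * dmi_feed_kg * 1000,
    dose_pasture = pasture_ng_g * dmi_pasture_kg * 1000,
    dose_soil = soil_ng_g * soil_kg * 1000,
    dose_water = water_ng_L * water_L,
    dose_milk = milk_ng_mL * milk_kg * 1000
  )
  out$dose_total <- out$dose_feed + out$dose_pasture + out$dose_soil +
    out$dose_water + out$dose_milk
  if (any(as.matrix(out) < 0, na.rm = TRUE)) {
    stop_validation("negative dose component; check input concentrations")
  }
  out
}

#' Dam milk concentration series
#'
#' Runs the deterministic (mean-parameter) kinetic model for a breeding
#' stock animal on the same farm calendar and derives daily milk
#' concentration as `Pmilk x dam serum`, aligned to the calf's nursing
#' window. The dam is an adult at constant body weight; her winters
#' (November-April) are fed the crop-year weighted first-cut average and
#' her summers acreage-weighted pasture.
#'
#' @param scn Scenario with a `dam` entry.
#' @param analyte Analyte name.
#' @return List with `milk` (tibble `date, milk_ng_mL` covering birth to
#'   weaning), `serum_at_birth` (ng/mL), and the dam `trajectory`.
#' @export
build_dam_milk_series <- function(scn, analyte) {
  if (is.null(scn$dam)) {
    stop_validation("scenario has no dam life history but the calf nurses")
  }
  lh <- scn$life_history
  days <- seq(scn$dam$start_date, lh$weaning_date, by = "day")
  yrs <- as.integer(format(days, "%Y"))
  mon <- as.integer(format(days, "%m"))
  # winter stored feed: Nov-Apr; crop year = year the winter started
  winter <- mon >= 11 | mon <= 4
  crop_year <- ifelse(mon >= 11, yrs, yrs - 1L)

  avail_years <- sort(unique(scn$feed_lots$year))
  if (length(avail_years) == 0) {
    stop_validation("no feed lots available for the dam's stored-feed winters")
  }
  nearest_year <- function(y) avail_years[which.min(abs(avail_years - y))]
  feed_conc_by_year <- vapply(
    sort(unique(vapply(crop_year[winter], nearest_year, numeric(1)))),
    function(y) weighted_feed_conc(scn, y, 1, analyte), numeric(1))
  names(feed_conc_by_year) <- as.character(
    sort(unique(vapply(crop_year[winter], nearest_year, numeric(1)))))

  # acreage-weighted pasture forage and soil over pasture/dual fields
  pf <- scn$fields[scn$fields$use %in% c("pasture", "dual") &
                     scn$fields$analyte == analyte, ]
  if (nrow(pf) == 0) stop_validation("no pasture fields for the dam")
  wts <- pf$acres / sum(pf$acres)
  forage <- sum(wts * vapply(pf$field_id,
                             function(f) pasture_forage_conc(scn, f, analyte),
                             numeric(1)))
  soil <- sum(wts * pf$soil_ng_g)

  # water: use the scenario segments, extending the first backwards in time
  seg <- dplyr::arrange(scn$water[scn$water$analyte == analyte, ], .data$start)
  water_conc <- rep(if (nrow(seg) > 0) seg$ng_L[1] else 0, length(days))
  for (i in seq_len(nrow(seg))) {
    water_conc[days >= seg$start[i] & days <= seg$end[i]] <- seg$ng_L[i]
  }

  bw <- rep(scn$dam$body_weight, length(days))
  dmi <- post_weaning_dmi(bw, scn$params$intake$post_weaning_dmi_fraction)
  water_L <- water_intake(bw, 15, scn$params$intake$water_a,
                          scn$params$intake$water_b, scn$params$intake$water_t0)
  soil_kg <- soil_ingestion(dmi, !winter,
                            scn$params$intake$soil_ingestion_fraction)

  feed_conc <- ifelse(
    winter,
    feed_conc_by_year[as.character(vapply(crop_year, nearest_year, numeric(1)))],
    0)
  doses <- daily_dose(
    feed_ng_g = feed_conc,
    pasture_ng_g = ifelse(winter, 0, forage),
    soil_ng_g = ifelse(winter, 0, soil),
    water_ng_L = water_conc,
    milk_ng_mL = 0,
    dmi_feed_kg = ifelse(winter, dmi, 0),
    dmi_pasture_kg = ifelse(winter, 0, dmi),
    soil_kg = soil_kg, water_L = water_L, milk_kg = 0)

  p <- mean_tk_params(scn, analyte)
  traj <- simulate_trajectory(doses$dose_total, bw, p, serum0 = 0,
                              dates = days)
  nursing <- seq(lh$birth_date, lh$weaning_date, by = "day")
  idx <- match(nursing, traj$date)
  list(
    milk = tibble::tibble(date = nursing, milk_ng_mL = traj$milk[idx]),
    serum_at_birth = traj$serum[match(lh$birth_date, traj$date)],
    trajectory = traj
  )
}

#' Dose components for the simulated animal
#'
#' Assembles the per-day dose decomposition over the whole life history,
#' with the milk pathway from the deterministic dam run. Supplemental-hay
#' episodes route the day's forage intake through the stored-feed pathway
#' at the configured hay concentration.
#'
#' @param scn Scenario.
#' @param analyte Analyte name.
#' @param dam_milk Optional precomputed result of [build_dam_milk_series()].
#' @return Tibble `date, analyte, dose_feed, dose_pasture, dose_soil,
#'   dose_water, dose_milk, dose_total` (ng/day).
#' @export
build_dose_series <- function(scn, analyte, dam_milk = NULL) {
  schedule <- daily_schedule(scn)
  body <- body_states(scn, schedule)
  feed <- feed_conc_timeline(scn, analyte, schedule)
  pasture <- pasture_conc_timeline(scn, analyte, schedule)
  water <- water_conc_timeline(scn, analyte, schedule)

  milk_conc <- rep(0, nrow(schedule))
  if (any(schedule$nursing)) {
    if (is.null(dam_milk)) dam_milk <- build_dam_milk_series(scn, analyte)
    idx <- match(schedule$date, dam_milk$milk$date)
    milk_conc <- ifelse(schedule$nursing & !is.na(idx),
                        dam_milk$milk$milk_ng_mL[ifelse(is.na(idx), 1, idx)], 0)
  }

  feed_day <- feed$source != "none"
  doses <- daily_dose(
    feed_ng_g = feed$feed_ng_g,
    pasture_ng_g = ifelse(feed$source == "supplemental", 0,
                          pasture$forage_ng_g),
    soil_ng_g = pasture$soil_ng_g,
    water_ng_L = water$water_ng_L,
    milk_ng_mL = milk_conc,
    dmi_feed_kg = ifelse(feed_day, body$dmi_forage, 0),
    dmi_pasture_kg = ifelse(!feed_day & schedule$grazing, body$dmi_forage, 0),
    soil_kg = body$soil_kg,
    water_L = body$water_L,
    milk_kg = body$milk_kg)
  dplyr::bind_cols(tibble::tibble(date = schedule$date, analyte = analyte),
                   doses)
}

#' Per-animal intake perturbation factors
#'
#' Draws one multiplicative factor pair (feed, water) per simulated
#' animal, constant across its days, from a normal with mean 1 and SD
#' `cv`, truncated below at 0.1. `cv = 0` returns exact 1s.
#'
#' @param n Number of animals (draws).
#' @param cv Coefficient of variation of intake (default 0.30).
#' @return Tibble `draw, f_feed, f_water`.
#' @export
intake_perturbation <- function(n, cv = 0.30) {
  stopifnot(cv >= 0)
  draw1 <- function() {
    if (cv == 0) return(rep(1, n))
    x <- rnorm(n, 1, cv)
    while (any(x < 0.1)) {
      bad <- x < 0.1
      x[bad] <- rnorm(sum(bad), 1, cv)
    }
    x
  }
  tibble::tibble(draw = seq_len(n), f_feed = draw1(), f_water = draw1())
}
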
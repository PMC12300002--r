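# Animal physiology: body weight, milk yield, dry-matter intake, water and
# incidental soil ingestion.
#
# Nursing calves consume milk (Wood lactation curve for the dam, converted
# to dry matter at 13%) plus an increasing amount of forage given by
# DMI_F = (0.0783 BW - 4.87 DMI_M) / DE_F, clamped at zero.  After weaning
# forage intake follows a proportional-to-body-weight rule and milk intake
# is zero.

#' Body weight from age (Brody growth curve)
#'
#' `BW(t) = W_inf - (W_inf - W_0) exp(-k t)`: monotone non-decreasing,
#' equal to the birth weight at age 0 and approaching the mature weight
#' asymptotically.
#'
#' @param age_days Age in days (vectorized).
#' @param params Growth parameter list: `birth_weight` (kg),
#'   `mature_weight` (kg), `rate` (1/day).
#' @return Body weight in kg.
#' @export
body_weight <- function(age_days, params) {
  stopifnot(params$birth_weight > 0,
            params$mature_weight > params$birth_weight,
            params$rate > 0)
  params$mature_weight -
    (params$mature_weight - params$birth_weight) * exp(-params$rate * age_days)
}

#' Daily milk yield of a beef cow (Wood curve)
#'
#' `MY(t) = A (t + 14)^b exp(-c (t + 14)) YP / 10`, where `t` is days
#' post-calving and `YP` is the breed-adjusted peak production rate. With
#' the defaults (A = 1.69, b = 0.57, c = 0.009, YP = 8.16 kg/day) the peak
#' falls on day `b/c - 14` (about day 49) post-calving.
#'
#' @param t_days Days after calving (vectorized).
#' @param params Lactation parameter list (`YP`, `A`, `b`, `c`).
#' @return Milk yield in kg/day.
#' @export
milk_yield <- function(t_days, params) {
  stopifnot(params$A > 0, params$b > 0, params$c > 0, params$YP > 0)
  params$A * (t_days + 14)^params$b * exp(-params$c * (t_days + 14)) *
    params$YP / 10
}

#' Calf milk dry-matter intake
#'
#' Converts consumed milk mass to dry matter (default dry-matter content
#' 13%).
#'
#' @param milk_kg_day Milk consumed, kg/day.
#' @param milk_dm_fraction Dry-matter fraction of whole milk.
#' @return kg dry weight per day.
#' @export
calf_milk_dmi <- function(milk_kg_day, milk_dm_fraction = 0.13) {
  milk_kg_day * milk_dm_fraction
}

#' Nursing-calf forage dry-matter intake
#'
#' `DMI_F = max(0, (0.0783 BW - 4.87 DMI_M) / DE_F)`: forage intake rises
#' with body weight and falls with milk intake; the interior is clamped at
#' zero because negative intake is physically impossible.
#'
#' @param bw_kg Calf body weight, kg.
#' @param dmi_milk Milk dry-matter intake, kg/day.
#' @param de_forage Forage digestible energy, Mcal/kg (default 2.895).
#' @return kg dry weight per day.
#' @export
calf_forage_dmi <- function(bw_kg, dmi_milk, de_forage = 2.895) {
  pmax(0, (0.0783 * bw_kg - 4.87 * dmi_milk) / de_forage)
}

#' Post-weaning dry-matter intake
#'
#' Proportional-to-body-weight rule (default 2.5% of BW per day), monotone
#' non-decreasing in body weight.
#'
#' @param bw_kg Body weight, kg.
#' @param fraction Intake as a fraction of body weight per day.
#' @return kg dry weight per day.
#' @export
post_weaning_dmi <- function(bw_kg, fraction = 0.025) {
  stopifnot(fraction >= 0)
  fraction * bw_kg
}

#' Daily water intake
#'
#' Affine rule `a BW + b max(0, T - T0)`: intake scales with body weight
#' with an optional warm-weather increment above a threshold temperature.
#'
#' @param bw_kg Body weight, kg.
#' @param tmean_c Daily mean temperature, degrees C.
#' @param a L per kg body weight per day.
#' @param b L per degree C above `t0` per day (0 disables the term).
#' @param t0 Threshold temperature, degrees C.
#' @return L per day.
#' @export
water_intake <- function(bw_kg, tmean_c = 15, a = 0.08, b = 0, t0 = 15) {
  a * bw_kg + b * pmax(0, tmean_c - t0)
}

#' Incidental soil ingestion while grazing
#'
#' Grazing cattle ingest soil at a fixed fraction of their forage
#' dry-matter intake (default 4%).
#'
#' @param dmi_forage Grazing-day forage dry-matter intake, kg/day.
#' @param grazing Logical; soil is only ingested on grazing days.
#' @param fraction Soil intake as a fraction of DMI.
#' @return kg soil per day.
#' @export
soil_ingestion <- function(dmi_forage, grazing = TRUE, fraction = 0.04) {
  stopifnot(fraction >= 0, fraction <= 0.2)
  ifelse(grazing, fraction * dmi_forage, 0)
}

#' Per-day body states over a life history
#'
#' Combines the growth, lactation, and intake rules on the daily schedule
#' into one row per day of body weight, milk/forage dry-matter intake,
#' water intake, and soil ingestion. Milk intake is the dam's daily yield
#' while nursing and zero afterwards (weaning is a hard switch).
#'
#' @param scn Scenario.
#' @param schedule Daily schedule from [daily_schedule()].
#' @return Tibble `date, age_days, bw_kg, milk_kg, dmi_milk, dmi_forage,
#'   water_L, soil_kg`.
#' @export
body_states <- function(scn, schedule = daily_schedule(scn)) {
  gp <- scn$params$growth
  lp <- scn$params$lactation
  ip <- scn$params$intake
  bw <- body_weight(schedule$age_days, gp)
  milk_kg <- ifelse(schedule$nursing, milk_yield(schedule$age_days, lp), 0)
  dmi_milk <- calf_milk_dmi(milk_kg, lp$milk_dm_fraction)
  dmi_forage <- ifelse(
    schedule$nursing,
    calf_forage_dmi(bw, dmi_milk, ip$de_forage),
    post_weaning_dmi(bw, ip$post_weaning_dmi_fraction)
  )
  water_L <- water_intake(bw, schedule$tmean_c, ip$water_a, ip$water_b,
                          ip$water_t0)
  soil_kg <- soil_ingestion(dmi_forage, schedule$grazing,
                            ip$soil_ingestion_fraction)
  tibble::tibble(
    date = schedule$date, age_days = schedule$age_days,
    bw_kg = bw, milk_kg = milk_kg, dmi_milk = dmi_milk,
    dmi_forage = dmi_forage, water_L = water_L, soil_kg = soil_kg
  )
}
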
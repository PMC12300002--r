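# Synthetic farm generator.
#
# Emulates a multi-field farm with a history of biosolids application on
# its hay fields: biosolids-field soils several-fold above the clean
# pastures (PFOS ~8-20 ng/g and PFDA ~65-111 ng/g versus <1 and <2.8
# ng/g), an annual calendar alternating ~6-month stored-feed winters
# with ~6-month grazing summers, and biomonitoring drawn with
# multiplicative lognormal noise from a known-parameter trajectory.

#' Synthetic-farm specification
#'
#' Defaults describe the study conditions: 14 fields of which 6 are
#' biosolids-amended hay fields and one a dual-use hay/pasture field,
#' truncated-lognormal soil concentrations within the observed field
#' ranges, seasonal winter/summer alternation, well water at 1.3 ng/L
#' PFOS (0 for PFDA) until filtration, and a 24-month life history.
#'
#' @param n_hay Number of biosolids-amended hay fields.
#' @param n_pasture Number of clean pasture fields.
#' @param soil_range Per-analyte, per-class truncation ranges (ng/g).
#' @param months Life-history length at sale/slaughter: 24 or 18.
#' @param birth_date Calf birth date.
#' @param dual_autumn Rotate the calf onto the dual-use hay/pasture field
#'   for six weeks in its first autumn (off by default: the default
#'   rotation keeps growing animals on the clean pastures).
#' @param maternal_transfer True calf-serum-at-birth / dam-serum ratio
#'   used by the generated scenario.
#' @param noise_cv Lognormal measurement-noise CV for biomonitoring.
#' @param n_animals Animals per biomonitoring sampling date.
#' @param seed RNG seed fixing all generator randomness.
#' @return List of class `synth_spec`.
#' @export
synth_spec <- function(n_hay = 6, n_pasture = 7,
                       soil_range = list(
                         PFOS = list(biosolids = c(8.2, 19.8),
                                     clean = c(0, 1.0)),
                         PFDA = list(biosolids = c(65.2, 111.0),
                                     clean = c(0, 2.8))),
                       months = 24, birth_date = as.Date("2021-05-01"),
                       dual_autumn = FALSE, maternal_transfer = 0.05,
                       noise_cv = 0.10, n_animals = 8, seed = 1) {
  stopifnot(months %in% c(18, 24), n_hay >= 1, n_pasture >= 1)
  structure(list(n_hay = n_hay, n_pasture = n_pasture,
                 soil_range = soil_range, months = months,
                 birth_date = as.Date(birth_date),
                 dual_autumn = isTRUE(dual_autumn),
                 maternal_transfer = maternal_transfer,
                 noise_cv = noise_cv,
                 n_animals = n_animals, seed = seed),
            class = "synth_spec")
}

# Lognormal draw truncated to [lo, hi] by resampling; meanlog targets the
# geometric midpoint of the range.
rlnorm_range <- function(n, lo, hi, sdlog = 0.3) {
  if (hi <= 0) return(rep(0, n))
  lo_pos <- max(lo, hi / 50)
  meanlog <- mean(log(c(lo_pos, hi)))
  x <- stats::rlnorm(n, meanlog, sdlog)
  while (any(x < lo | x > hi)) {
    bad <- x < lo | x > hi
    x[bad] <- stats::rlnorm(sum(bad), meanlog, sdlog)
  }
  x
}

#' Accumulation/depuration life-history template
#'
#' Builds the farm's calendar archetype for one animal: birth in spring,
#' summer pasture at the dam's side, weaning in late autumn at the start
#' of the first stored-feed winter (November-April), then alternating
#' seasons. The 24-month template has two stored-feed winters and ends in
#' late spring at slaughter; the 18-month template has one winter
#' followed by six months of grazing and ends at sale.
#'
#' @param birth_date Calf birth date (a spring date).
#' @param months 24 (slaughter) or 18 (live auction sale).
#' @return Life-history list as used by [farm_scenario()].
#' @export
accumulation_depuration_template <- function(birth_date, months = 24) {
  stopifnot(months %in% c(18, 24))
  birth_date <- as.Date(birth_date)
  yr <- as.integer(format(birth_date, "%Y"))
  w1_start <- as.Date(sprintf("%d-11-01", yr))
  w1_end <- as.Date(sprintf("%d-04-30", yr + 1))
  if (months == 24) {
    w2_start <- as.Date(sprintf("%d-11-01", yr + 1))
    w2_end <- as.Date(sprintf("%d-04-30", yr + 2))
    stored <- tibble::tibble(start = c(w1_start, w2_start),
                             end = c(w1_end, w2_end))
    end_date <- w2_end
  } else {
    stored <- tibble::tibble(start = w1_start, end = w1_end)
    end_date <- w1_end + 183
  }
  list(
    birth_date = birth_date,
    weaning_date = w1_start,
    end_date = end_date,
    stored_feed = stored,
    clean_feed = interval_tbl(NULL),
    supplemental = interval_tbl(NULL)
  )
}

#' Generate a complete synthetic farm scenario
#'
#' Draws field soils, bale inventories, grazing rotation, water and
#' weather series, and the life-history template from a [synth_spec()],
#' optionally writing the CSV/config bundle accepted by
#' [load_scenario()]. All randomness is fixed by the spec seed.
#'
#' @param spec A `synth_spec`.
#' @param dir Optional output directory for the file bundle.
#' @return A validated `farm_scenario`.
#' @export
generate_farm <- function(spec = synth_spec(), dir = NULL) {
  set.seed(spec$seed)
  analytes <- names(spec$soil_range)
  hay_ids <- sprintf("H%02d", seq_len(spec$n_hay))
  pas_ids <- sprintf("P%02d", seq_len(spec$n_pasture))
  dual_id <- "D01"

  soils <- list()
  for (a in analytes) {
    rng <- spec$soil_range[[a]]
    soils[[a]] <- c(
      setNames(rlnorm_range(spec$n_hay, rng$biosolids[1], rng$biosolids[2]),
               hay_ids),
      setNames(rlnorm_range(spec$n_pasture, rng$clean[1] + 0.05,
                            rng$clean[2] * 0.9), pas_ids),
      setNames(rlnorm_range(1, rng$biosolids[1], rng$biosolids[2]), dual_id))
  }
  all_ids <- c(hay_ids, pas_ids, dual_id)
  acres <- setNames(round(stats::runif(length(all_ids), 5, 20), 1), all_ids)
  use <- setNames(c(rep("hay", spec$n_hay), rep("pasture", spec$n_pasture),
                    "dual"), all_ids)
  biosolids <- setNames(c(rep(TRUE, spec$n_hay), rep(FALSE, spec$n_pasture),
                          TRUE), all_ids)
  fields <- dplyr::bind_rows(lapply(analytes, function(a) {
    tibble::tibble(field_id = all_ids, acres = unname(acres),
                   use = unname(use), biosolids = unname(biosolids),
                   analyte = a, soil_ng_g = round(unname(soils[[a]]), 2))
  }))

  lh <- accumulation_depuration_template(spec$birth_date, spec$months)
  yr0 <- as.integer(format(spec$birth_date, "%Y"))
  crop_years <- (yr0 - 3):(yr0 + spec$months %/% 12)

  # bale inventory: every hay field yields first-cut bales each crop year;
  # two fields also take a small second cut (6-14% of the crop)
  lot_rows <- list()
  for (y in crop_years) {
    b1 <- round(stats::runif(spec$n_hay, 60, 140))
    for (i in seq_len(spec$n_hay)) {
      for (a in analytes) {
        lot_rows[[length(lot_rows) + 1]] <- tibble::tibble(
          lot_id = sprintf("%s-%d-c1", hay_ids[i], y),
          field_id = hay_ids[i], year = y, cut = 1L, bales = b1[i],
          analyte = a, measured_ng_g = NA_real_, dm_fraction = 0.9)
      }
    }
    b2 <- round(stats::runif(2, 8, 18))
    for (i in 1:2) {
      for (a in analytes) {
        lot_rows[[length(lot_rows) + 1]] <- tibble::tibble(
          lot_id = sprintf("%s-%d-c2", hay_ids[i], y),
          field_id = hay_ids[i], year = y, cut = 2L, bales = b2[i],
          analyte = a, measured_ng_g = NA_real_, dm_fraction = 0.9)
      }
    }
  }
  feed_lots <- dplyr::bind_rows(lot_rows)

  # grazing: acreage-weighted rotation over the pastures each summer, with
  # a 6-week autumn window on the dual-use field for the under-one calf
  pas_acres <- acres[pas_ids]
  alloc <- unname(pas_acres / sum(pas_acres))
  summers <- list()
  yrs <- yr0:(yr0 + spec$months %/% 12)
  for (y in yrs) {
    s <- as.Date(sprintf("%d-05-01", y))
    e <- as.Date(sprintf("%d-10-31", y))
    if (s > lh$end_date) next
    summers[[length(summers) + 1]] <- tibble::tibble(
      start = s, end = min(e, lh$end_date), field_id = pas_ids,
      allocation = alloc)
  }
  grazing <- dplyr::bind_rows(summers)
  if (spec$dual_autumn) {
    # autumn on the dual field in year of birth (age < 1): Sep 15 - Oct 31
    dual_start <- as.Date(sprintf("%d-09-15", yr0))
    dual_end <- as.Date(sprintf("%d-10-31", yr0))
    keep <- !(grazing$start <= dual_end & grazing$end >= dual_start)
    first_summer <- tibble::tibble(
      start = as.Date(sprintf("%d-05-01", yr0)), end = dual_start - 1,
      field_id = pas_ids, allocation = alloc)
    dual_win <- tibble::tibble(start = dual_start, end = dual_end,
                               field_id = dual_id, allocation = 1)
    grazing <- dplyr::bind_rows(first_summer, dual_win, grazing[keep, ])
  }

  # water: 1.3 ng/L PFOS until the filter date, 0 after; PFDA non-detect
  filter_date <- as.Date(sprintf("%d-02-01", yr0 + 1))
  span_start <- min(lh$birth_date, as.Date(sprintf("%d-01-01", min(crop_years))))
  water <- dplyr::bind_rows(lapply(analytes, function(a) {
    pre <- if (a == "PFOS") 1.3 else 0
    tibble::tibble(
      start = c(span_start, filter_date),
      end = c(filter_date - 1, lh$end_date + 30),
      analyte = a, ng_L = c(pre, 0))
  }))

  # weather: sinusoidal annual temperature cycle with noise
  wx_days <- seq(span_start, lh$end_date + 30, by = "day")
  doy <- as.integer(format(wx_days, "%j"))
  weather <- tibble::tibble(
    date = wx_days,
    tmean_c = round(8 + 14 * sin(2 * pi * (doy - 110) / 365.25) +
                      stats::rnorm(length(wx_days), 0, 2), 1),
    precip_mm = round(pmax(0, stats::rnorm(length(wx_days), 3, 4)), 1))

  params <- default_params()
  params$transfer$second_cut_pasture_fields <- dual_id
  params$tk$maternal_transfer <- spec$maternal_transfer
  params$simulation$seed <- spec$seed

  scn <- farm_scenario(
    analytes = analytes, fields = fields, feed_lots = feed_lots,
    grazing = grazing, water = water, weather = weather,
    life_history = lh,
    dam = list(start_date = lh$birth_date - 3 * 365, body_weight = 600),
    params = params)
  if (!is.null(dir)) write_scenario(scn, dir)
  scn
}

#' Generate synthetic biomonitoring records
#'
#' Runs the deterministic model with the scenario's (true) parameters and
#' emits per-animal serum/muscle records at the sampling dates with
#' multiplicative lognormal noise of the given CV; `noise_cv = 0`
#' reproduces the model output exactly.
#'
#' @param scn Scenario (its TK parameters are the ground truth).
#' @param analyte Analyte name.
#' @param sampling_dates Dates within the simulated range.
#' @param matrices Matrices to report (`serum`, `muscle`).
#' @param n_animals Animals sampled per date.
#' @param noise_cv Lognormal measurement-noise CV.
#' @param seed RNG seed.
#' @return Tibble `animal_id, date, matrix, analyte, conc`.
#' @export
generate_biomonitoring <- function(scn, analyte, sampling_dates,
                                   matrices = c("serum", "muscle"),
                                   n_animals = 8, noise_cv = 0.10, seed = 1) {
  set.seed(seed)
  sampling_dates <- as.Date(sampling_dates)
  truth <- run_deterministic(scn, analyte)
  idx <- match(sampling_dates, truth$date)
  if (anyNA(idx)) {
    stop_validation("sampling dates outside the simulated range")
  }
  sdlog <- sqrt(log(1 + noise_cv^2))
  rows <- list()
  for (m in matrices) {
    base <- truth[[m]][idx]
    for (a in seq_len(n_animals)) {
      noise <- if (noise_cv > 0) {
        exp(rnorm(length(base), -sdlog^2 / 2, sdlog))
      } else rep(1, length(base))
      rows[[length(rows) + 1]] <- tibble::tibble(
        animal_id = sprintf("A%02d", a), date = sampling_dates, matrix = m,
        analyte = analyte, conc = base * noise)
    }
  }
  dplyr::bind_rows(rows)
}
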
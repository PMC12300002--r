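# Farm-scenario data model: construction, file IO, validation.
#
# A scenario is the complete declarative description of a farm simulation:
# fields and their soil concentrations, hay-bale inventories, grazing and
# feeding calendars, drinking-water history, daily weather, one animal's
# life history, and all model parameters.  Dates are calendar dates, the
# simulation clock is daily with day 0 = birth date, and intervals are
# closed on both ends.
#
# Units are fixed at this boundary: soil/feed/forage/muscle ng/g dry weight,
# serum/plasma/milk ng/mL, water ng/L.  For serum/tissue interconversion
# 1 ng/mL is treated as equivalent to 1 ng/g (unit density).

#' Default model parameters
#'
#' Returns the full parameter list used by a simulation when a scenario
#' config does not override a value. Defaults encode the study conditions:
#' Wood lactation curve with peak yield on day 48 post-calving, forage
#' digestible energy 2.895 Mcal/kg, 4% of dry-matter intake as incidental
#' soil while grazing, 30% between-animal intake variation, and per-analyte
#' toxicokinetic parameters (serum half-life DT50, volume of distribution
#' Vd, muscle and milk partition coefficients PM and Pmilk).
#'
#' @return Nested list with components `transfer`, `tk`, `growth`,
#'   `lactation`, `intake`, and `simulation`.
#' @export
default_params <- function() {
  list(
    transfer = list(
      tf = c(PFOS = 0.1, PFDA = 0.025),
      second_cut_multiplier = c(PFOS = 2.7, PFDA = 2.1),
      second_cut_pasture_fields = character(0)
    ),
    tk = list(
      maternal_transfer = 1.0,
      PFOS = list(DT50 = c(74.1, 13.4), Vd = c(0.085, 0.01),
                  PM = c(0.08, 0.02), Pmilk = c(0.015, 0.004)),
      # PFDA half-life is analyte-specific; Vd, Pmilk (and maternal transfer)
      # reuse the PFOS values in the absence of PFDA-specific cattle data.
      PFDA = list(DT50 = c(60.4, 10.4), Vd = c(0.085, 0.01),
                  PM = c(0.08, 0.02), Pmilk = c(0.015, 0.004))
    ),
    growth = list(birth_weight = 40, mature_weight = 600, rate = 0.004),
    lactation = list(YP = 8.16, A = 1.69, b = 0.57, c = 0.009,
                     milk_dm_fraction = 0.13),
    intake = list(de_forage = 2.895, post_weaning_dmi_fraction = 0.025,
                  water_a = 0.08, water_b = 0, water_t0 = 15,
                  soil_ingestion_fraction = 0.04, intake_cv = 0.30),
    simulation = list(n_draws = 100, seed = 1, clean_feed_conc = 0)
  )
}

#' Construct a farm scenario
#'
#' Assembles the tabular inputs and parameter lists into a validated
#' `farm_scenario` object. Most users will call [load_scenario()] or
#' [generate_farm()] instead of this constructor.
#'
#' @param analytes Character vector of analyte names (e.g. `c("PFOS","PFDA")`).
#' @param fields Tibble with columns `field_id, acres, use, biosolids,
#'   analyte, soil_ng_g` (long format, one row per field x analyte).
#' @param feed_lots Tibble with columns `lot_id, field_id, year, cut, bales,
#'   analyte, measured_ng_g, dm_fraction`.
#' @param grazing Tibble with columns `start, end, field_id, allocation`.
#' @param water Tibble with columns `start, end, analyte, ng_L`.
#' @param weather Tibble with columns `date, tmean_c, precip_mm`.
#' @param life_history List with `birth_date`, `weaning_date`, `end_date`
#'   (Dates) and interval tibbles `stored_feed`, `clean_feed`,
#'   `supplemental` (each with `start`, `end`; supplemental also per-analyte
#'   `ng_g` columns named after analytes).
#' @param dam List with `start_date` and `body_weight` describing the
#'   breeding-stock animal whose milk feeds the calf; `NULL` disables the
#'   milk pathway.
#' @param params Parameter list as returned by [default_params()]; missing
#'   entries are filled from the defaults.
#' @param feeding_order Optional tibble `year, cut, n_days` giving the order
#'   in which each crop year's cuts are fed out (`NA` n_days = remainder of
#'   the winter). Default: second cut first, for a number of days
#'   proportional to its bale share.
#' @param biomonitoring Optional tibble `animal_id, date, matrix, analyte,
#'   conc`.
#' @param validate Run [validate_scenario()] before returning?
#' @return A `farm_scenario` object.
#' @export
farm_scenario <- function(analytes, fields, feed_lots, grazing, water,
                          weather, life_history, dam = NULL,
                          params = default_params(), feeding_order = NULL,
                          biomonitoring = NULL, validate = TRUE) {
  params <- modify_defaults(default_params(), params)
  scn <- structure(list(
    analytes = analytes,
    fields = tibble::as_tibble(fields),
    feed_lots = tibble::as_tibble(feed_lots),
    grazing = tibble::as_tibble(grazing),
    water = tibble::as_tibble(water),
    weather = tibble::as_tibble(weather),
    life_history = life_history,
    dam = dam,
    params = params,
    feeding_order = if (!is.null(feeding_order)) tibble::as_tibble(feeding_order),
    biomonitoring = if (!is.null(biomonitoring)) tibble::as_tibble(biomonitoring)
  ), class = "farm_scenario")
  if (validate) validate_scenario(scn)
  scn
}

# Recursively overlay user-supplied parameter entries on the defaults.
modify_defaults <- function(defaults, user) {
  if (is.null(user)) return(defaults)
  for (nm in names(user)) {
    if (is.list(defaults[[nm]]) && is.list(user[[nm]])) {
      defaults[[nm]] <- modify_defaults(defaults[[nm]], user[[nm]])
    } else {
      defaults[[nm]] <- user[[nm]]
    }
  }
  defaults
}

#' @export
print.farm_scenario <- function(x, ...) {
  lh <- x$life_history
  cat("<farm_scenario>\n")
  cat("  analytes:", paste(x$analytes, collapse = ", "), "\n")
  cat("  fields:", length(unique(x$fields$field_id)),
      " feed lots:", length(unique(x$feed_lots$lot_id)), "\n")
  cat(sprintf("  life history: %s to %s (weaned %s)\n",
              lh$birth_date, lh$end_date, lh$weaning_date))
  invisible(x)
}

as_date_strict <- function(x, what) {
  out <- tryCatch(as.Date(x), error = function(e) NA)
  if (any(is.na(out))) {
    stop_validation(sprintf("invalid or missing date in %s", what))
  }
  out
}

interval_tbl <- function(x, extra = character(0)) {
  if (is.null(x) || (is.data.frame(x) && nrow(x) == 0) ||
      (is.list(x) && length(x) == 0)) {
    cols <- c(list(start = as.Date(character(0)), end = as.Date(character(0))),
              setNames(rep(list(numeric(0)), length(extra)), extra))
    return(tibble::as_tibble(cols))
  }
  if (!is.data.frame(x)) x <- dplyr::bind_rows(lapply(x, tibble::as_tibble))
  x$start <- as_date_strict(x$start, "interval start")
  x$end <- as_date_strict(x$end, "interval end")
  tibble::as_tibble(x)
}

#' Validate a farm scenario
#'
#' Checks every structural invariant a simulation relies on: positive
#' acreage, non-negative concentrations, complete analyte coverage per
#' field, resolvable field/lot references, ordered life-history dates,
#' non-overlapping stored/clean-feed intervals, grazing allocations that
#' sum to 1, water segments and weather covering the whole life history
#' (weather gaps up to 7 days are forward-filled, longer gaps are errors).
#'
#' @param scn A `farm_scenario`.
#' @return The scenario, invisibly, with weather forward-filled.
#' @export
validate_scenario <- function(scn) {
  f <- scn$fields
  req <- function(tbl, cols, name) {
    miss <- setdiff(cols, names(tbl))
    if (length(miss) > 0) {
      stop_validation(sprintf("%s is missing columns: %s", name,
                              paste(miss, collapse = ", ")))
    }
  }
  req(f, c("field_id", "acres", "use", "biosolids", "analyte", "soil_ng_g"),
      "fields")
  req(scn$feed_lots, c("lot_id", "field_id", "year", "cut", "bales", "analyte",
                       "measured_ng_g", "dm_fraction"), "feed_lots")
  req(scn$grazing, c("start", "end", "field_id", "allocation"), "grazing")
  req(scn$water, c("start", "end", "analyte", "ng_L"), "water")
  req(scn$weather, c("date", "tmean_c", "precip_mm"), "weather")

  if (any(f$acres <= 0)) stop_validation("field acres must be > 0")
  if (any(f$soil_ng_g < 0, na.rm = TRUE)) {
    stop_validation("soil concentrations must be >= 0")
  }
  if (!all(f$use %in% c("pasture", "hay", "dual"))) {
    stop_validation("field use must be one of pasture/hay/dual")
  }
  cover <- tapply(f$analyte, f$field_id, function(a) all(scn$analytes %in% a))
  if (!all(cover)) {
    stop_validation(sprintf(
      "fields missing soil entries for some analytes: %s",
      paste(names(cover)[!cover], collapse = ", ")))
  }
  if (any(is.na(f$soil_ng_g))) {
    stop_validation("soil concentration is NA; use 0 for non-detects")
  }

  fl <- scn$feed_lots
  if (nrow(fl) > 0) {
    if (!all(fl$cut %in% c(1, 2))) stop_validation("feed lot cut must be 1 or 2")
    if (any(fl$bales < 0)) stop_validation("bale counts must be >= 0")
    if (any(fl$measured_ng_g < 0, na.rm = TRUE)) {
      stop_validation("measured feed concentrations must be >= 0")
    }
    if (any(fl$dm_fraction <= 0 | fl$dm_fraction > 1)) {
      stop_validation("dm_fraction must be in (0, 1]")
    }
    dangling <- setdiff(fl$field_id, f$field_id)
    if (length(dangling) > 0) {
      stop_validation(sprintf("feed lot references unknown field(s): %s",
                              paste(dangling, collapse = ", ")))
    }
  }

  g <- scn$grazing
  if (nrow(g) > 0) {
    dangling <- setdiff(g$field_id, f$field_id)
    if (length(dangling) > 0) {
      stop_validation(sprintf("grazing interval references unknown field(s): %s",
                              paste(dangling, collapse = ", ")))
    }
    if (any(g$end < g$start)) stop_validation("grazing interval end < start")
    sums <- tapply(g$allocation, paste(g$start, g$end), sum)
    if (any(abs(sums - 1) > 1e-6)) {
      stop_validation("grazing allocations must sum to 1 within each interval")
    }
  }

  w <- scn$water
  if (any(w$ng_L < 0)) stop_validation("water concentrations must be >= 0")
  for (a in scn$analytes) {
    seg <- dplyr::arrange(w[w$analyte == a, ], .data$start)
    if (nrow(seg) > 1 && any(seg$start[-1] <= seg$end[-nrow(seg)])) {
      stop_validation(sprintf("overlapping water segments for %s", a))
    }
  }

  lh <- scn$life_history
  if (is.null(lh$birth_date) || is.null(lh$weaning_date) ||
      is.null(lh$end_date)) {
    stop_validation("life history needs birth_date, weaning_date, end_date")
  }
  if (!(lh$birth_date < lh$weaning_date && lh$weaning_date < lh$end_date)) {
    stop_validation("life-history dates must satisfy birth < weaning < end")
  }
  days <- seq(lh$birth_date, lh$end_date, by = "day")
  in_any <- function(d, tbl) {
    if (nrow(tbl) == 0) return(rep(FALSE, length(d)))
    Reduce(`|`, lapply(seq_len(nrow(tbl)),
                       function(i) d >= tbl$start[i] & d <= tbl$end[i]))
  }
  # clean-feed interventions may overlap stored-feed windows; clean feed
  # takes precedence in the daily schedule (an intervention replaces the
  # contaminated ration mid-winter)

  # water must cover every simulated day (0 is an explicit concentration)
  for (a in scn$analytes) {
    seg <- w[w$analyte == a, ]
    covered <- in_any(days, seg)
    if (!all(covered)) {
      stop_validation(sprintf(
        "water series for %s does not cover %s to %s (first gap %s)",
        a, lh$birth_date, lh$end_date, days[which(!covered)[1]]))
    }
  }

  # weather: forward-fill gaps up to 7 days, longer gaps are errors
  wx <- dplyr::arrange(scn$weather, .data$date)
  if (nrow(wx) == 0 || min(wx$date) > lh$birth_date ||
      max(wx$date) < lh$end_date) {
    stop_validation("weather series does not cover the life history")
  }
  gaps <- diff(as.integer(wx$date))
  if (any(gaps > 8)) {
    stop_validation(sprintf("weather gap of %d days exceeds the 7-day limit",
                            max(gaps) - 1))
  }
  invisible(scn)
}

#' Resolve a daily schedule for the simulated animal
#'
#' Expands the life history into one row per simulated day giving the
#' primary feeding mode (`nursing`, `pasture`, `stored_feed`, `clean_feed`),
#' whether the day is a grazing day, and the forward-filled weather.
#' Nursing days are pasture days before the weaning date (nursing calves
#' graze at the dam's side); weaning is a hard switch.
#'
#' @param scn A validated `farm_scenario`.
#' @return Tibble with columns `date, age_days, mode, nursing, grazing,
#'   tmean_c, precip_mm`.
#' @export
daily_schedule <- function(scn) {
  lh <- scn$life_history
  days <- seq(lh$birth_date, lh$end_date, by = "day")
  in_any <- function(d, tbl) {
    if (is.null(tbl) || nrow(tbl) == 0) return(rep(FALSE, length(d)))
    Reduce(`|`, lapply(seq_len(nrow(tbl)),
                       function(i) d >= tbl$start[i] & d <= tbl$end[i]))
  }
  sf <- in_any(days, lh$stored_feed)
  cf <- in_any(days, lh$clean_feed)
  mode <- ifelse(cf, "clean_feed", ifelse(sf, "stored_feed", "pasture"))
  nursing <- days < lh$weaning_date
  # forward-fill weather onto the simulation calendar
  wx <- dplyr::arrange(scn$weather, .data$date)
  idx <- findInterval(as.integer(days), as.integer(wx$date))
  idx[idx == 0] <- 1
  tibble::tibble(
    date = days,
    age_days = as.integer(days - lh$birth_date),
    mode = mode,
    nursing = nursing,
    grazing = mode == "pasture",
    tmean_c = wx$tmean_c[idx],
    precip_mm = wx$precip_mm[idx]
  )
}

#' Substitute non-detect concentrations
#'
#' Applies a deterministic substitution policy to values reported below a
#' method detection limit (MDL). The default policy treats non-detects as
#' 0, matching the handling of post-filtration drinking water.
#'
#' @param value Numeric reported value(s); ignored where `nondetect` is TRUE.
#' @param nondetect Logical vector marking non-detects.
#' @param mdl Detection limit(s), required for `half_mdl` and `mdl` policies.
#' @param policy One of `"zero"`, `"half_mdl"`, `"mdl"`.
#' @return Numeric vector of substituted concentrations.
#' @export
#' @examples
#' nondetect_conc(NA, nondetect = TRUE, mdl = 0.3)            # 0
#' nondetect_conc(NA, nondetect = TRUE, mdl = 0.2, policy = "half_mdl")
#' nondetect_conc(1.3, nondetect = FALSE)                     # unchanged
nondetect_conc <- function(value, nondetect = FALSE, mdl = NA_real_,
                           policy = c("zero", "half_mdl", "mdl")) {
  policy <- match.arg(policy)
  n <- max(length(value), length(nondetect), length(mdl))
  value <- rep_len(as.numeric(value), n)
  nondetect <- rep_len(nondetect, n)
  mdl <- rep_len(as.numeric(mdl), n)
  if (policy != "zero" && any(nondetect & is.na(mdl))) {
    stop_validation(sprintf("non-detect without an MDL under policy '%s'",
                            policy))
  }
  sub <- switch(policy, zero = rep(0, n), half_mdl = mdl / 2, mdl = mdl)
  ifelse(nondetect, sub, value)
}

# ---------------------------------------------------------------------------
# File IO

scenario_csv_cols <- list(
  fields = readr::cols(field_id = "c", acres = "d", use = "c",
                       biosolids = "l", analyte = "c", soil_ng_g = "d"),
  feed_lots = readr::cols(lot_id = "c", field_id = "c", year = "i", cut = "i",
                          bales = "d", analyte = "c", measured_ng_g = "d",
                          dm_fraction = "d"),
  grazing = readr::cols(start = "D", end = "D", field_id = "c",
                        allocation = "d"),
  water = readr::cols(start = "D", end = "D", analyte = "c", ng_L = "d"),
  weather = readr::cols(date = "D", tmean_c = "d", precip_mm = "d"),
  biomonitoring = readr::cols(animal_id = "c", date = "D", matrix = "c",
                              analyte = "c", conc = "d")
)

read_scenario_csv <- function(path, what) {
  if (!file.exists(path)) {
    stop(sprintf("scenario input file not found: %s", path), call. = FALSE)
  }
  readr::read_csv(path, col_types = scenario_csv_cols[[what]],
                  progress = FALSE, show_col_types = FALSE)
}

#' Load a farm scenario from a config file and data directory
#'
#' Reads a YAML scenario config plus the CSV tables it references
#' (`fields.csv`, `feed_lots.csv`, `grazing.csv`, `water.csv`,
#' `weather.csv`, optional `biomonitoring.csv`) and returns a validated
#' [farm_scenario()].
#'
#' @param config_path Path to the YAML config.
#' @param data_dir Directory containing the referenced CSVs; defaults to
#'   the config file's directory.
#' @return A validated `farm_scenario`.
#' @export
load_scenario <- function(config_path, data_dir = dirname(config_path)) {
  if (!file.exists(config_path)) {
    stop(sprintf("scenario config not found: %s", config_path), call. = FALSE)
  }
  cfg <- yaml::read_yaml(config_path)
  files <- cfg$files %||% list()
  path_of <- function(what, default) {
    file.path(data_dir, files[[what]] %||% default)
  }
  fields <- read_scenario_csv(path_of("fields", "fields.csv"), "fields")
  feed_lots <- read_scenario_csv(path_of("feed_lots", "feed_lots.csv"),
                                 "feed_lots")
  grazing <- read_scenario_csv(path_of("grazing", "grazing.csv"), "grazing")
  water <- read_scenario_csv(path_of("water", "water.csv"), "water")
  weather <- read_scenario_csv(path_of("weather", "weather.csv"), "weather")
  bio_path <- path_of("biomonitoring", "biomonitoring.csv")
  biomonitoring <- if (file.exists(bio_path)) {
    read_scenario_csv(bio_path, "biomonitoring")
  }

  lh_cfg <- cfg$life_history
  if (is.null(lh_cfg)) stop_validation("config has no life_history section")
  analytes <- as.character(cfg$analytes %||% c("PFOS", "PFDA"))
  supp_cols <- analytes
  life_history <- list(
    birth_date = as_date_strict(lh_cfg$birth_date, "life_history$birth_date"),
    weaning_date = as_date_strict(lh_cfg$weaning_date,
                                  "life_history$weaning_date"),
    end_date = as_date_strict(lh_cfg$end_date, "life_history$end_date"),
    stored_feed = interval_tbl(lh_cfg$stored_feed),
    clean_feed = interval_tbl(lh_cfg$clean_feed),
    supplemental = interval_tbl(lh_cfg$supplemental, extra = supp_cols)
  )
  dam <- if (!is.null(cfg$dam)) {
    list(start_date = as_date_strict(cfg$dam$start_date, "dam$start_date"),
         body_weight = as.numeric(cfg$dam$body_weight %||% 600))
  }
  params <- cfg[c("transfer", "tk", "growth", "lactation", "intake",
                  "simulation")]
  params <- lapply(params, function(x) x)  # drop NULL names cleanly
  params <- params[!vapply(params, is.null, logical(1))]
  # YAML maps come back as lists; transfer factor maps become named vectors
  if (!is.null(params$transfer)) {
    for (nm in c("tf", "second_cut_multiplier")) {
      if (!is.null(params$transfer[[nm]])) {
        params$transfer[[nm]] <- unlist(params$transfer[[nm]])
      }
    }
    if (!is.null(params$transfer$second_cut_pasture_fields)) {
      params$transfer$second_cut_pasture_fields <-
        as.character(unlist(params$transfer$second_cut_pasture_fields))
    }
  }
  if (!is.null(params$tk)) {
    for (a in analytes) {
      if (!is.null(params$tk[[a]])) {
        params$tk[[a]] <- lapply(params$tk[[a]], unlist)
      }
    }
  }
  feeding_order <- if (!is.null(cfg$feeding_order)) {
    fo <- dplyr::bind_rows(lapply(cfg$feeding_order, tibble::as_tibble))
    fo$n_days <- as.integer(fo$n_days)
    fo
  }
  farm_scenario(
    analytes = analytes, fields = fields, feed_lots = feed_lots,
    grazing = grazing, water = water, weather = weather,
    life_history = life_history, dam = dam, params = params,
    feeding_order = feeding_order, biomonitoring = biomonitoring
  )
}

#' Write a farm scenario to disk
#'
#' Emits the YAML config and CSV bundle accepted by [load_scenario()].
#' Writing then re-loading reproduces an equivalent scenario.
#'
#' @param scn A `farm_scenario`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(scn, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(tbl, name) {
    readr::write_csv(tbl, file.path(dir, paste0(name, ".csv")), progress = FALSE)
  }
  wr(scn$fields, "fields")
  wr(scn$feed_lots, "feed_lots")
  wr(scn$grazing, "grazing")
  wr(scn$water, "water")
  wr(scn$weather, "weather")
  if (!is.null(scn$biomonitoring)) wr(scn$biomonitoring, "biomonitoring")

  lh <- scn$life_history
  iv_list <- function(tbl) {
    if (nrow(tbl) == 0) return(list())
    lapply(seq_len(nrow(tbl)), function(i) {
      row <- as.list(tbl[i, ])
      row$start <- as.character(row$start)
      row$end <- as.character(row$end)
      row
    })
  }
  cfg <- list(
    analytes = as.list(scn$analytes),
    life_history = list(
      birth_date = as.character(lh$birth_date),
      weaning_date = as.character(lh$weaning_date),
      end_date = as.character(lh$end_date),
      stored_feed = iv_list(lh$stored_feed),
      clean_feed = iv_list(lh$clean_feed),
      supplemental = iv_list(lh$supplemental)
    ),
    transfer = list(
      tf = as.list(scn$params$transfer$tf),
      second_cut_multiplier = as.list(scn$params$transfer$second_cut_multiplier),
      second_cut_pasture_fields =
        as.list(scn$params$transfer$second_cut_pasture_fields)
    ),
    tk = c(list(maternal_transfer = scn$params$tk$maternal_transfer),
           lapply(scn$params$tk[scn$analytes],
                  function(p) lapply(p, as.list))),
    growth = scn$params$growth,
    lactation = scn$params$lactation,
    intake = scn$params$intake,
    simulation = scn$params$simulation
  )
  if (!is.null(scn$dam)) {
    cfg$dam <- list(start_date = as.character(scn$dam$start_date),
                    body_weight = scn$dam$body_weight)
  }
  if (!is.null(scn$feeding_order)) {
    cfg$feeding_order <- lapply(seq_len(nrow(scn$feeding_order)),
                                function(i) as.list(scn$feeding_order[i, ]))
  }
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}
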
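# Small scenarios built in code for the test suite.

# One hay field + one clean pasture, a single stored-feed winter, constant
# weather, and a dam so the milk pathway is exercised.
tiny_scenario <- function(analytes = c("PFOS", "PFDA"),
                          soil_hay = c(PFOS = 10, PFDA = 80),
                          soil_pasture = c(PFOS = 0.5, PFDA = 1),
                          water_ng_L = c(PFOS = 1.3, PFDA = 0),
                          params = list(), dam = TRUE,
                          clean_feed = NULL) {
  span_start <- as.Date("2018-01-01")
  span_end <- as.Date("2022-06-30")
  fields <- dplyr::bind_rows(lapply(analytes, function(a) {
    tibble::tibble(field_id = c("H1", "P1"), acres = c(10, 12),
                   use = c("hay", "pasture"), biosolids = c(TRUE, FALSE),
                   analyte = a,
                   soil_ng_g = c(soil_hay[[a]], soil_pasture[[a]]))
  }))
  feed_lots <- dplyr::bind_rows(lapply(2018:2021, function(y) {
    dplyr::bind_rows(lapply(analytes, function(a) {
      tibble::tibble(lot_id = sprintf("H1-%d-c1", y), field_id = "H1",
                     year = y, cut = 1L, bales = 100, analyte = a,
                     measured_ng_g = NA_real_, dm_fraction = 0.9)
    }))
  }))
  grazing <- tibble::tibble(start = as.Date("2021-05-01"),
                            end = as.Date("2021-10-31"),
                            field_id = "P1", allocation = 1)
  water <- dplyr::bind_rows(lapply(analytes, function(a) {
    tibble::tibble(start = span_start, end = span_end, analyte = a,
                   ng_L = water_ng_L[[a]])
  }))
  wx_days <- seq(span_start, span_end, by = "day")
  weather <- tibble::tibble(date = wx_days, tmean_c = 10, precip_mm = 2)
  life_history <- list(
    birth_date = as.Date("2021-05-01"),
    weaning_date = as.Date("2021-11-01"),
    end_date = as.Date("2022-04-30"),
    stored_feed = tibble::tibble(start = as.Date("2021-11-01"),
                                 end = as.Date("2022-04-30")),
    clean_feed = if (is.null(clean_feed)) {
      tibble::tibble(start = as.Date(character(0)), end = as.Date(character(0)))
    } else clean_feed,
    supplemental = tibble::tibble(start = as.Date(character(0)),
                                  end = as.Date(character(0)))
  )
  farm_scenario(
    analytes = analytes, fields = fields, feed_lots = feed_lots,
    grazing = grazing, water = water, weather = weather,
    life_history = life_history,
    dam = if (dam) list(start_date = as.Date("2019-05-01"), body_weight = 600),
    params = params
  )
}

# Constant-dose, constant-body-weight trajectory inputs for analytic checks.
constant_dose_setup <- function(n_days = 1500, dose = 10000, bw = 500,
                                dt50 = 50, vd = 0.085, pm = 0.08,
                                pmilk = 0.015) {
  list(dose = rep(dose, n_days), bw = rep(bw, n_days),
       params = list(DT50 = dt50, Vd = vd, PM = pm, Pmilk = pmilk))
}
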
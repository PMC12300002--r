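# Soil-to-plant transfer, bale-weighted mixing, feed timelines.

make_lot <- function(field_id = "H1", cut = 1L, measured = NA_real_) {
  tibble::tibble(lot_id = "L1", field_id = field_id, year = 2021L, cut = cut,
                 bales = 10, analyte = "PFOS", measured_ng_g = measured,
                 dm_fraction = 0.9)
}

test_that("lot feed concentration is soil x TF with a second-cut multiplier", {
  scn <- tiny_scenario(soil_hay = c(PFOS = 10, PFDA = 80))
  scn$params$transfer$tf <- c(PFOS = 0.1, PFDA = 0.025)
  expect_equal(lot_feed_conc(make_lot(cut = 1L), scn, "PFOS"), 1.0)
  expect_equal(lot_feed_conc(make_lot(cut = 2L), scn, "PFOS"), 2.7)
  # PFDA second-cut multiplier is 2.1
  lot <- make_lot(cut = 2L)
  expect_equal(lot_feed_conc(lot, scn, "PFDA"), 80 * 0.025 * 2.1)
  expect_error(lot_feed_conc(make_lot(field_id = "H9"), scn, "PFOS"), "H9",
               class = "herdtk_validation_error")
})

test_that("measured hay concentrations override the transfer estimate", {
  scn <- tiny_scenario()
  # sentinel: transfer factors must never be consulted for measured lots
  scn$params$transfer$tf <- c(PFOS = NaN, PFDA = NaN)
  expect_equal(lot_feed_conc(make_lot(measured = 6.89), scn, "PFOS"), 6.89)
  expect_error(lot_feed_conc(make_lot(), scn, "PFOS"),
               class = "herdtk_validation_error")
})

test_that("bale weighting averages lot concentrations", {
  scn <- tiny_scenario()
  mk <- function(concs, bales) {
    dplyr::bind_rows(lapply(seq_along(concs), function(i) {
      tibble::tibble(lot_id = sprintf("L%d", i), field_id = "H1", year = 2025L,
                     cut = 1L, bales = bales[i], analyte = "PFOS",
                     measured_ng_g = concs[i], dm_fraction = 0.9)
    }))
  }
  scn$feed_lots <- mk(c(1.0, 2.0), c(75, 25))
  expect_equal(weighted_feed_conc(scn, 2025, 1, "PFOS"), 1.25)
  scn$feed_lots <- mk(3.7, 40)
  expect_equal(weighted_feed_conc(scn, 2025, 1, "PFOS"), 3.7)
  scn$feed_lots <- mk(c(1, 2, 3), c(10, 10, 10))
  expect_equal(weighted_feed_conc(scn, 2025, 1, "PFOS"), 2.0)
  scn$feed_lots <- mk(c(1, 2), c(0, 0))
  expect_error(weighted_feed_conc(scn, 2025, 1, "PFOS"), "bales",
               class = "herdtk_validation_error")
})

test_that("weighted mixing is convex and monotone in soil concentration", {
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(2:6, 1)
    scn <- tiny_scenario()
    scn$fields <- dplyr::bind_rows(lapply(c("PFOS", "PFDA"), function(a) {
      tibble::tibble(field_id = sprintf("F%d", 1:n), acres = 10, use = "hay",
                     biosolids = TRUE, analyte = a,
                     soil_ng_g = round(stats::runif(n, 1, 30), 2))
    }))
    scn$feed_lots <- dplyr::bind_rows(lapply(1:n, function(i) {
      tibble::tibble(lot_id = sprintf("F%d-l", i), field_id = sprintf("F%d", i),
                     year = 2025L, cut = 1L, bales = sample(1:200, 1),
                     analyte = "PFOS", measured_ng_g = NA_real_,
                     dm_fraction = 0.9)
    }))
    concs <- vapply(seq_len(n), function(i)
      lot_feed_conc(scn$feed_lots[i, ], scn, "PFOS"), numeric(1))
    w <- weighted_feed_conc(scn, 2025, 1, "PFOS")
    expect_gte(w, min(concs) - 1e-12)
    expect_lte(w, max(concs) + 1e-12)
    # raising one field's soil never lowers the mix
    scn2 <- scn
    j <- sample(n, 1)
    sel <- scn2$fields$field_id == sprintf("F%d", j)
    scn2$fields$soil_ng_g[sel] <- scn2$fields$soil_ng_g[sel] + 5
    expect_gte(weighted_feed_conc(scn2, 2025, 1, "PFOS"), w)
  }
})

test_that("pasture forage follows soil x TF with optional second-cut flag", {
  scn <- tiny_scenario(soil_pasture = c(PFOS = 0.5, PFDA = 1))
  scn$params$transfer$tf <- c(PFOS = 0.1, PFDA = 0.025)
  expect_equal(pasture_forage_conc(scn, "P1", "PFOS"), 0.05)
  expect_equal(pasture_forage_conc(scn, "P1", "PFOS", as_second_cut = TRUE),
               0.5 * 0.1 * 2.7)
  scn0 <- tiny_scenario(soil_pasture = c(PFOS = 0, PFDA = 0))
  expect_equal(pasture_forage_conc(scn0, "P1", "PFOS"), 0)
  # fields flagged in the config are treated as second-cut by default
  scn$params$transfer$second_cut_pasture_fields <- "P1"
  expect_equal(pasture_forage_conc(scn, "P1", "PFOS"), 0.135)
})

test_that("the stored-feed timeline honours feeding order and interventions", {
  scn <- tiny_scenario()  # only first-cut lots
  tl <- feed_conc_timeline(scn, "PFOS")
  sch <- daily_schedule(scn)
  winter <- sch$mode == "stored_feed"
  expect_true(all(tl$source[winter] == "cut1"))
  expect_equal(unique(tl$feed_ng_g[winter]),
               weighted_feed_conc(scn, 2021, 1, "PFOS"))
  expect_true(all(tl$feed_ng_g[!winter] == 0))

  # add a second-cut lot and an explicit order: 30 days of cut 2 first
  scn2 <- scn
  extra <- dplyr::bind_rows(lapply(c("PFOS", "PFDA"), function(a) {
    tibble::tibble(lot_id = "H1-2021-c2", field_id = "H1", year = 2021L,
                   cut = 2L, bales = 20, analyte = a,
                   measured_ng_g = NA_real_, dm_fraction = 0.9)
  }))
  scn2$feed_lots <- dplyr::bind_rows(scn$feed_lots, extra)
  scn2$feeding_order <- tibble::tibble(year = 2021L, cut = c(2L, 1L),
                                       n_days = c(30L, NA))
  tl2 <- feed_conc_timeline(scn2, "PFOS")
  wdays <- which(winter)
  expect_true(all(tl2$source[wdays[1:30]] == "cut2"))
  expect_true(all(tl2$source[wdays[-(1:30)]] == "cut1"))
  expect_equal(tl2$feed_ng_g[wdays[1]],
               weighted_feed_conc(scn2, 2021, 2, "PFOS"))

  # clean-feed intervention zeroes the last 4 months of the winter
  scn3 <- tiny_scenario(clean_feed = tibble::tibble(
    start = as.Date("2022-01-01"), end = as.Date("2022-04-30")))
  tl3 <- feed_conc_timeline(scn3, "PFOS")
  iv <- tl3$date >= as.Date("2022-01-01")
  expect_true(all(tl3$feed_ng_g[iv] == 0))
  expect_true(all(tl3$source[iv] == "clean"))
  expect_true(all(tl3$feed_ng_g[tl3$source == "cut1"] > 0))
})
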
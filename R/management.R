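# Farm-management interventions and a simple per-animal economic
# comparison of holding to slaughter versus selling at live auction.
#
# Under linear first-order kinetics, a dose fed earlier decays for longer
# before the sale date, so feeding the highest-concentration bales first
# minimizes the terminal body burden of any permutation of the same lots
# (rearrangement inequality).  prioritize_feed() implements that
# highest-first schedule subject to bale availability.

#' Default economic configuration
#'
#' @param hanging_fraction Hanging (carcass) weight as a fraction of live
#'   weight (default 0.63).
#' @param bone_fraction Bone weight subtracted as a fraction of hanging
#'   weight (default 0.175).
#' @param retail_price USD per lb of ground beef.
#' @param auction_price USD per lb live weight.
#' @param feed_cost Purchased feed cost per animal, USD.
#' @param grain_cost Grain cost per animal, USD.
#' @return List of economic parameters.
#' @export
econ_config <- function(hanging_fraction = 0.63, bone_fraction = 0.175,
                        retail_price = NA_real_, auction_price = NA_real_,
                        feed_cost = 0, grain_cost = 0) {
  stopifnot(hanging_fraction > 0, hanging_fraction < 1,
            bone_fraction >= 0, bone_fraction < 1)
  list(hanging_fraction = hanging_fraction, bone_fraction = bone_fraction,
       retail_price = retail_price, auction_price = auction_price,
       feed_cost = feed_cost, grain_cost = grain_cost)
}

#' Sellable meat weight from live weight
#'
#' `live x hanging_fraction x (1 - bone_fraction)`.
#'
#' @param live_weight_lb Live weight, lb.
#' @param econ Economic configuration ([econ_config()]).
#' @return Sellable meat weight, lb.
#' @export
meat_weight <- function(live_weight_lb, econ = econ_config()) {
  stopifnot(all(live_weight_lb > 0))
  live_weight_lb * econ$hanging_fraction * (1 - econ$bone_fraction)
}

#' Net revenue per animal under a marketing option
#'
#' Slaughter: meat weight x retail price minus feed and grain costs.
#' Auction: live weight x auction price.
#'
#' @param option `"slaughter"` or `"auction"`.
#' @param live_weight_lb Live weight, lb.
#' @param econ Economic configuration with the relevant prices set.
#' @return Net revenue, USD.
#' @export
net_revenue <- function(option = c("slaughter", "auction"), live_weight_lb,
                        econ = econ_config()) {
  option <- match.arg(option)
  if (option == "slaughter") {
    if (is.na(econ$retail_price)) stop_validation("retail_price not configured")
    meat_weight(live_weight_lb, econ) * econ$retail_price -
      econ$feed_cost - econ$grain_cost
  } else {
    if (is.na(econ$auction_price)) {
      stop_validation("auction_price not configured")
    }
    live_weight_lb * econ$auction_price
  }
}

#' Highest-concentration-first feed plan
#'
#' Assigns lots to the daily feed demand in descending order of expected
#' concentration (ties broken by lot id), so the most contaminated feed
#' is fed earliest and decays longest before the end of the window.
#'
#' @param lots Tibble `lot_id, conc, kg_available` (expected ng/g and
#'   feedable mass per lot).
#' @param demand_kg Numeric vector of daily feed demand (kg/day) over the
#'   feeding window, in day order.
#' @param decreasing Feed highest concentration first (`TRUE`, the
#'   recommended plan) or lowest first.
#' @return Tibble `day, conc` with one row per day of the window, plus a
#'   `lot_id` column recording the lot fed each day (the lot providing
#'   the majority of that day's feed).
#' @export
prioritize_feed <- function(lots, demand_kg, decreasing = TRUE) {
  lots <- tibble::as_tibble(lots)
  stopifnot(all(c("lot_id", "conc", "kg_available") %in% names(lots)))
  if (sum(lots$kg_available) < sum(demand_kg) - 1e-9) {
    stop_validation(sprintf(
      "insufficient feed: %.1f kg available for %.1f kg demand",
      sum(lots$kg_available), sum(demand_kg)))
  }
  ord <- order(lots$conc * ifelse(decreasing, -1, 1), lots$lot_id)
  lots <- lots[ord, ]
  n <- length(demand_kg)
  day_conc <- numeric(n)
  day_lot <- character(n)
  lot_i <- 1L
  remaining <- lots$kg_available[1]
  for (d in seq_len(n)) {
    need <- demand_kg[d]
    got <- 0
    mix <- 0
    major_lot <- lots$lot_id[lot_i]
    major_kg <- 0
    while (need > 1e-12) {
      take <- min(need, remaining)
      mix <- mix + take * lots$conc[lot_i]
      if (take > major_kg) {
        major_kg <- take
        major_lot <- lots$lot_id[lot_i]
      }
      got <- got + take
      need <- need - take
      remaining <- remaining - take
      if (remaining <= 1e-12 && lot_i < nrow(lots)) {
        lot_i <- lot_i + 1L
        remaining <- lots$kg_available[lot_i]
      } else if (remaining <= 1e-12 && need > 1e-12) {
        stop_validation("feed plan ran out of lots mid-window")
      }
    }
    day_conc[d] <- if (got > 0) mix / got else 0
    day_lot[d] <- major_lot
  }
  tibble::tibble(day = seq_len(n), lot_id = day_lot, conc = day_conc)
}

#' Terminal burden of a feeding sequence
#'
#' Convenience kinetic roll-up for comparing feed plans: runs the daily
#' recursion over `conc x demand` doses and returns the body burden on
#' the final day.
#'
#' @param conc_ng_g Daily feed concentration sequence, ng/g.
#' @param demand_kg Daily feed intake, kg/day (recycled).
#' @param dt50 Elimination half-life, days.
#' @param burden0 Starting burden, ng.
#' @return Terminal burden, ng.
#' @export
terminal_burden <- function(conc_ng_g, demand_kg, dt50, burden0 = 0) {
  dose <- conc_ng_g * rep_len(demand_kg, length(conc_ng_g)) * 1000
  k <- elimination_rate(dt50)
  b <- burden0
  for (d in dose) b <- tk_step(b, d, k)
  b
}

#' Simulate a management variant
#'
#' Applies a farm-management intervention to the scenario, reruns the
#' stochastic ensemble, and reports the fraction of draws below each
#' action level at the end date (sale or slaughter).
#'
#' Variants: `baseline` (unchanged); `clean_feed` (the final
#' `clean_days` before the end date switch to purchased clean feed);
#' `prioritized_first_winter` / `prioritized_second_winter` (the chosen
#' winter feeds that crop year's lots highest-concentration-first
#' instead of the mixed weighted average).
#'
#' @param scn Scenario.
#' @param variant Management variant name.
#' @param analyte Analyte name.
#' @param clean_days Length of the clean-feed window for `clean_feed`.
#' @param n,seed As in [simulate_ensemble()].
#' @param config Evaluation configuration providing action levels.
#' @return List with the `ensemble`, the modified `scenario`, and
#'   `thresholds`, a tibble of below-threshold fractions at the end date.
#' @export
simulate_management <- function(scn,
                                variant = c("baseline", "clean_feed",
                                            "prioritized_first_winter",
                                            "prioritized_second_winter"),
                                analyte = "PFOS", clean_days = 120,
                                n = scn$params$simulation$n_draws,
                                seed = scn$params$simulation$seed,
                                config = evaluation_config()) {
  variant <- match.arg(variant)
  scn2 <- scn
  if (variant == "clean_feed") {
    end <- scn$life_history$end_date
    win <- tibble::tibble(start = end - clean_days + 1, end = end)
    scn2$life_history$clean_feed <-
      dplyr::bind_rows(scn$life_history$clean_feed, win)
  } else if (variant %in% c("prioritized_first_winter",
                            "prioritized_second_winter")) {
    sf <- scn$life_history$stored_feed
    idx <- if (variant == "prioritized_first_winter") 1 else nrow(sf)
    if (nrow(sf) < idx || idx < 1) {
      stop_validation("scenario lacks the requested stored-feed winter")
    }
    year <- as.integer(format(sf$start[idx], "%Y"))
    lots <- scn$feed_lots[scn$feed_lots$year == year &
                            scn$feed_lots$analyte == analyte, ]
    if (nrow(lots) == 0) {
      stop_validation(sprintf("no feed lots for crop year %d", year))
    }
    conc <- vapply(seq_len(nrow(lots)),
                   function(i) lot_feed_conc(lots[i, ], scn, analyte),
                   numeric(1))
    ndays <- as.integer(sf$end[idx] - sf$start[idx]) + 1L
    # uniform daily demand within the window; capacity split evenly per bale
    demand <- rep(1, ndays)
    kg <- lots$bales / sum(lots$bales) * ndays
    plan <- prioritize_feed(
      tibble::tibble(lot_id = lots$lot_id, conc = conc, kg_available = kg),
      demand)
    # encode the plan as per-day supplemental overrides on those days
    over <- tibble::tibble(start = seq(sf$start[idx], by = "day",
                                       length.out = ndays),
                           end = seq(sf$start[idx], by = "day",
                                     length.out = ndays))
    over[[analyte]] <- plan$conc
    for (a in setdiff(scn$analytes, analyte)) {
      # other analytes keep the same ordering by lot (co-sourced bales)
      conc_a <- vapply(seq_len(nrow(lots)), function(i) {
        row <- scn$feed_lots[scn$feed_lots$lot_id == lots$lot_id[i] &
                               scn$feed_lots$analyte == a, ]
        lot_feed_conc(row[1, ], scn, a)
      }, numeric(1))
      names(conc_a) <- lots$lot_id
      over[[a]] <- unname(conc_a[plan$lot_id])
    }
    scn2$life_history$supplemental <-
      dplyr::bind_rows(scn$life_history$supplemental, over)
  }
  ens <- simulate_ensemble(scn2, analyte, n = n, seed = seed)
  end <- scn2$life_history$end_date
  al <- config$action_levels[config$action_levels$analyte == analyte, ]
  thresholds <- tibble::tibble(
    name = al$name, matrix = al$matrix, ng_g = al$ng_g,
    below_fraction = vapply(seq_len(nrow(al)), function(i) {
      1 - exceedance_fraction(ens, al$matrix[i], al$ng_g[i], end)
    }, numeric(1)))
  list(variant = variant, ensemble = ens, scenario = scn2,
       thresholds = thresholds)
}
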
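# Feed and forage PFAS concentrations.
#
# Stored-feed concentrations come from each source field's soil level times
# a site-specific soil-to-plant transfer factor (TF), with second-cut hay
# carrying a higher TF (x2.7 for PFOS, x2.1 for PFDA by default).  When a
# lot has a measured hay concentration, the measurement overrides the
# soil-based estimate.  Annual crops are mixed as bale-fraction weighted
# averages because farm records rarely say when bales from individual
# fields were fed out.

field_soil <- function(scn, field_id, analyte) {
  rows <- scn$fields[scn$fields$field_id == field_id &
                       scn$fields$analyte == analyte, ]
  if (nrow(rows) == 0 || is.na(rows$soil_ng_g[1])) {
    stop_validation(sprintf("no soil concentration for field %s, analyte %s",
                            field_id, analyte))
  }
  rows$soil_ng_g[1]
}

#' Feed concentration for one hay lot
#'
#' Returns the lot's measured hay concentration when present; otherwise
#' estimates it as soil concentration x transfer factor, applying the
#' second-cut multiplier for cut-2 lots.
#'
#' @param lot One-row tibble (or list) with `field_id`, `cut`, and
#'   optionally `measured_ng_g`.
#' @param scn The scenario supplying field soil concentrations.
#' @param analyte Analyte name.
#' @param transfer Transfer-parameter list (`tf`, `second_cut_multiplier`);
#'   defaults to the scenario's.
#' @return Concentration in ng/g dry weight.
#' @export
lot_feed_conc <- function(lot, scn, analyte, transfer = scn$params$transfer) {
  measured <- lot$measured_ng_g
  if (!is.null(measured) && length(measured) == 1 && !is.na(measured)) {
    return(as.numeric(measured))
  }
  soil <- field_soil(scn, lot$field_id, analyte)
  tf <- transfer$tf[[analyte]]
  if (is.null(tf) || is.na(tf)) {
    stop_validation(sprintf("no transfer factor configured for %s", analyte))
  }
  mult <- if (lot$cut == 2) transfer$second_cut_multiplier[[analyte]] else 1
  soil * tf * mult
}

#' Bale-weighted average feed concentration for a crop year and cut
#'
#' Mixes the per-lot concentrations (measured where available, otherwise
#' soil x TF) weighted by each lot's share of the bales harvested. The
#' result always lies within the min-max envelope of the lot
#' concentrations.
#'
#' @param scn Scenario.
#' @param year Crop (harvest) year.
#' @param cut Cut number, 1 or 2.
#' @param analyte Analyte name.
#' @return Concentration in ng/g dry weight.
#' @export
weighted_feed_conc <- function(scn, year, cut, analyte) {
  lots <- scn$feed_lots[scn$feed_lots$year == year &
                          scn$feed_lots$cut == cut &
                          scn$feed_lots$analyte == analyte, ]
  if (nrow(lots) == 0 || sum(lots$bales) <= 0) {
    stop_validation(sprintf(
      "no bales available for crop year %s cut %d (%s)", year, cut, analyte))
  }
  conc <- vapply(seq_len(nrow(lots)),
                 function(i) lot_feed_conc(lots[i, ], scn, analyte),
                 numeric(1))
  sum(conc * lots$bales) / sum(lots$bales)
}

#' Pasture forage concentration for a field
#'
#' Forage on pasture is estimated as soil x TF. Dual-use hay fields grazed
#' after a cutting use the adjusted second-cut transfer factor.
#'
#' @param scn Scenario.
#' @param field_id Field identifier.
#' @param analyte Analyte name.
#' @param as_second_cut Apply the second-cut multiplier?
#' @return Concentration in ng/g dry weight.
#' @export
pasture_forage_conc <- function(scn, field_id, analyte,
                                as_second_cut = field_id %in%
                                  scn$params$transfer$second_cut_pasture_fields) {
  soil <- field_soil(scn, field_id, analyte)
  tf <- scn$params$transfer$tf[[analyte]]
  if (is.null(tf) || is.na(tf)) {
    stop_validation(sprintf("no transfer factor configured for %s", analyte))
  }
  mult <- if (isTRUE(as_second_cut)) {
    scn$params$transfer$second_cut_multiplier[[analyte]]
  } else 1
  soil * tf * mult
}

# Default feeding order for one winter: second cut first (if harvested that
# crop year), for a number of days proportional to its bale share, then
# first cut for the remainder.
default_feeding_order <- function(scn, year, n_days) {
  lots <- scn$feed_lots[scn$feed_lots$year == year &
                          scn$feed_lots$analyte == scn$analytes[1], ]
  b1 <- sum(lots$bales[lots$cut == 1])
  b2 <- sum(lots$bales[lots$cut == 2])
  if (b1 + b2 <= 0) {
    stop_validation(sprintf("no feed lots for crop year %s", year))
  }
  if (b2 > 0) {
    d2 <- max(1L, round(n_days * b2 / (b1 + b2)))
    tibble::tibble(year = year, cut = c(2L, 1L),
                   n_days = c(as.integer(d2), NA_integer_))
  } else {
    tibble::tibble(year = year, cut = 1L, n_days = NA_integer_)
  }
}

#' Per-day stored-feed concentration timeline
#'
#' Builds the daily stored-feed concentration an animal encounters over its
#' life: within each stored-feed interval the crop year is the calendar
#' year the interval starts in (hay is fed the winter after harvest), cuts
#' are fed out in the configured order (default: second cut first), and
#' clean-feed intervention days carry the configured clean-feed
#' concentration (default 0). Supplemental-hay episodes override pasture
#' days with their configured concentration.
#'
#' @param scn Scenario.
#' @param analyte Analyte name.
#' @param schedule Daily schedule from [daily_schedule()] (recomputed when
#'   omitted).
#' @return Tibble `date, feed_ng_g, source` where source is one of
#'   `none`, `cut1`, `cut2`, `clean`, `supplemental`.
#' @export
feed_conc_timeline <- function(scn, analyte, schedule = daily_schedule(scn)) {
  out <- tibble::tibble(date = schedule$date,
                        feed_ng_g = 0,
                        source = "none")
  clean_conc <- scn$params$simulation$clean_feed_conc %||% 0
  out$feed_ng_g[schedule$mode == "clean_feed"] <- clean_conc
  out$source[schedule$mode == "clean_feed"] <- "clean"

  sf <- scn$life_history$stored_feed
  if (nrow(sf) > 0) {
    for (i in seq_len(nrow(sf))) {
      idx <- which(schedule$mode == "stored_feed" &
                     schedule$date >= sf$start[i] & schedule$date <= sf$end[i])
      if (length(idx) == 0) next
      year <- as.integer(format(sf$start[i], "%Y"))
      order_tbl <- scn$feeding_order
      order_tbl <- if (!is.null(order_tbl) && any(order_tbl$year == year)) {
        order_tbl[order_tbl$year == year, ]
      } else {
        default_feeding_order(scn, year, length(idx))
      }
      pos <- 1L
      for (j in seq_len(nrow(order_tbl))) {
        if (pos > length(idx)) break
        nd <- order_tbl$n_days[j]
        take <- if (is.na(nd)) length(idx) - pos + 1L else min(nd, length(idx) - pos + 1L)
        if (take <= 0) next
        cut_j <- order_tbl$cut[j]
        conc <- weighted_feed_conc(scn, year, cut_j, analyte)
        sel <- idx[pos:(pos + take - 1L)]
        out$feed_ng_g[sel] <- conc
        out$source[sel] <- paste0("cut", cut_j)
        pos <- pos + take
      }
      if (pos <= length(idx)) {
        stop_validation(sprintf(
          "feeding order for crop year %s leaves %d stored-feed day(s) unassigned",
          year, length(idx) - pos + 1L))
      }
    }
  }

  supp <- scn$life_history$supplemental
  if (!is.null(supp) && nrow(supp) > 0 && analyte %in% names(supp)) {
    for (i in seq_len(nrow(supp))) {
      sel <- out$date >= supp$start[i] & out$date <= supp$end[i]
      out$feed_ng_g[sel] <- supp[[analyte]][i]
      out$source[sel] <- "supplemental"
    }
  }
  out
}

#' Per-day pasture forage and soil concentrations
#'
#' Resolves, for each grazing day, the allocation-weighted forage and soil
#' concentrations over the fields grazed that day.
#'
#' @param scn Scenario.
#' @param analyte Analyte name.
#' @param schedule Daily schedule from [daily_schedule()].
#' @return Tibble `date, forage_ng_g, soil_ng_g` (zero on non-grazing days).
#' @export
pasture_conc_timeline <- function(scn, analyte,
                                  schedule = daily_schedule(scn)) {
  out <- tibble::tibble(date = schedule$date, forage_ng_g = 0, soil_ng_g = 0)
  g <- scn$grazing
  if (nrow(g) == 0) return(out)
  # per-field concentrations, computed once
  fids <- unique(g$field_id)
  forage <- vapply(fids, function(f) pasture_forage_conc(scn, f, analyte),
                   numeric(1))
  soil <- vapply(fids, function(f) field_soil(scn, f, analyte), numeric(1))
  names(forage) <- names(soil) <- fids
  graze_days <- which(schedule$grazing)
  for (i in seq_len(nrow(g))) {
    sel <- graze_days[schedule$date[graze_days] >= g$start[i] &
                        schedule$date[graze_days] <= g$end[i]]
    if (length(sel) == 0) next
    out$forage_ng_g[sel] <- out$forage_ng_g[sel] +
      g$allocation[i] * forage[[g$field_id[i]]]
    out$soil_ng_g[sel] <- out$soil_ng_g[sel] +
      g$allocation[i] * soil[[g$field_id[i]]]
  }
  out
}
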
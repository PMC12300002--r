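# Agreement statistics, harmonization, meta-analysis, exceedance.

test_that("plasma concentrations convert by the serum/plasma ratio", {
  expect_equal(plasma_to_serum(10, "PFOS"), 10.60)
  expect_equal(plasma_to_serum(10, "PFDA"), 10.47)
  expect_equal(plasma_to_serum(0, "PFOS"), 0)
  expect_error(plasma_to_serum(1, "PFHxS"), class = "herdtk_validation_error")
})

test_that("percentage error and MAPE follow their definitions", {
  expect_equal(round(percentage_error(2.33, 2.87)), -19)
  expect_equal(round(percentage_error(256, 202)), 27)
  expect_equal(percentage_error(5, 5), 0)
  expect_error(percentage_error(1, 0), class = "herdtk_validation_error")
  expect_equal(mape(c(-19, -34, -29, 67, 68)), 43.4)
  expect_equal(mape(0), 0)
  expect_equal(mape(c(-12, 12)), 12)
  # invariant to sign flips and permutation
  e <- c(-5, 10, -15, 20)
  expect_equal(mape(e), mape(-e))
  expect_equal(mape(e), mape(sample(e)))
})

test_that("fold ratio is symmetric and agrees with percentage error", {
  expect_equal(fold_ratio(150, 89.1), 150 / 89.1)
  expect_equal(fold_ratio(89.1, 150), 150 / 89.1)
  expect_equal(fold_ratio(3, 3), 1)
  expect_equal(fold_ratio(1, 4), 4)
  for (pair in list(c(2.33, 2.87), c(256, 202), c(20.3, 12.2))) {
    pe <- percentage_error(pair[1], pair[2])
    r <- fold_ratio(pair[1], pair[2])
    expected <- if (pair[1] > pair[2]) 100 * (r - 1) else 100 * (1 - 1 / r)
    expect_equal(abs(pe), expected)
  }
})

# an ensemble-shaped object with prescribed values at one date
fake_ensemble <- function(values, date = as.Date("2021-12-01"),
                          analyte = "PFOS") {
  tr <- tibble::tibble(draw = seq_along(values), date = date,
                       burden = 0, serum = values / 0.08,
                       muscle = values, milk = 0.015 * values / 0.08)
  structure(list(analyte = analyte, n = length(values),
                 trajectories = tr, summary = ensemble_summary(tr)),
            class = "herdtk_ensemble")
}

test_that("exceedance fractions count draws above the threshold", {
  vals <- c(rep(4.0, 15), rep(1.0, 85))
  ens <- fake_ensemble(vals)
  d <- as.Date("2021-12-01")
  expect_equal(exceedance_fraction(ens, "muscle", 3.4, d), 0.15)
  expect_equal(exceedance_fraction(ens, "muscle", 0.1, d), 1.0)
  expect_equal(exceedance_fraction(ens, "muscle", 10, d), 0.0)
  # monotone non-increasing in the threshold
  ths <- seq(0, 5, by = 0.5)
  fr <- vapply(ths, function(t) exceedance_fraction(ens, "muscle", t, d),
               numeric(1))
  expect_true(all(diff(fr) <= 0))
  expect_error(exceedance_fraction(ens, "muscle", 1, as.Date("1990-01-01")),
               class = "herdtk_validation_error")
})

test_that("partition-coefficient meta-analysis averages dataset ratios", {
  one <- tibble::tibble(dataset = "a", tissue = c(2.0, 1.6),
                        blood = c(25.0, 20.0))
  m <- meta_pm(one)
  expect_equal(m$meta_mean, 0.08)
  expect_equal(m$meta_sd, 0)
  two <- tibble::tibble(
    dataset = rep(c("a", "b"), each = 10),
    tissue = c(rep(0.6, 10), rep(1.0, 10)),
    blood = rep(10, 20))
  m2 <- meta_pm(two)
  expect_equal(m2$meta_mean, 0.08)
  # dataset-size weighting differs from equal weighting when n differs
  three <- tibble::tibble(
    dataset = c(rep("a", 30), rep("b", 10)),
    tissue = c(rep(0.6, 30), rep(1.0, 10)),
    blood = rep(10, 40))
  expect_equal(meta_pm(three)$meta_mean, (30 * 0.06 + 10 * 0.10) / 40)
  expect_equal(meta_pm(three, weights = "equal")$meta_mean, 0.08)
  # plasma records are harmonized before forming ratios
  pl <- tibble::tibble(dataset = "a", tissue = c(2.0, 1.6),
                       blood = c(25.0, 20.0), blood_matrix = "plasma",
                       analyte = "PFOS")
  expect_equal(meta_pm(pl)$meta_mean, 0.08 / 1.060)
  # zero-serum pairs are dropped with a warning
  bad <- tibble::tibble(dataset = "a", tissue = c(2, 2), blood = c(25, 0))
  expect_warning(mb <- meta_pm(bad), "excluded")
  expect_equal(mb$meta_mean, 0.08)
  expect_equal(mb$n_excluded, 1)
})

test_that("log-linear depuration fits recover an exact exponential", {
  k <- elimination_rate(60)
  days <- as.Date("2022-01-01") + c(0, 30, 60, 90, 120)
  rec <- dplyr::bind_rows(lapply(1:3, function(i) {
    tibble::tibble(animal_id = as.character(i), date = days,
                   conc = 20 * exp(-k * as.numeric(days - days[1])))
  }))
  fit <- fit_depuration_dt50(rec)
  expect_equal(fit$dt50, 60, tolerance = 1e-8)
  expect_equal(nrow(fit$per_animal), 3)
})

test_that("scenario evaluation matches same-day summaries and flags plasma", {
  vals <- rep(c(2.0, 3.0), 5)
  ens <- fake_ensemble(vals)
  d <- as.Date("2021-12-01")
  bio <- tibble::tibble(animal_id = c("x", "y"), date = d,
                        matrix = "muscle", analyte = "PFOS",
                        conc = c(2.5, 2.5))
  rep1 <- evaluate_scenario(ens, bio)
  expect_equal(rep1$measured_mean, 2.5)
  expect_equal(rep1$modeled_mean, 2.5)
  expect_equal(rep1$pct_error, 0)
  expect_equal(rep1$fold, 1)
  expect_false(rep1$plasma_converted)

  bio_pl <- tibble::tibble(animal_id = "x", date = d, matrix = "plasma",
                           analyte = "PFOS", conc = 10)
  rep2 <- evaluate_scenario(ens, bio_pl)
  expect_true(rep2$plasma_converted)
  expect_equal(rep2$matrix, "serum")
  expect_equal(rep2$measured_mean, 10.6)

  bio_bad <- bio
  bio_bad$date <- as.Date("1999-01-01")
  expect_error(evaluate_scenario(ens, bio_bad), "1999",
               class = "herdtk_validation_error")
})
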
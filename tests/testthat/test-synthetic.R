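# Synthetic farm generator: ranges, reproducibility, known-truth records.

test_that("default farms respect the configured soil ranges by field class", {
  scn <- generate_farm(synth_spec(seed = 8))
  f <- scn$fields
  bios <- f$biosolids & f$analyte == "PFOS"
  past <- !f$biosolids & f$analyte == "PFOS"
  expect_true(all(f$soil_ng_g[bios] >= 8 & f$soil_ng_g[bios] <= 20))
  expect_true(all(f$soil_ng_g[past] < 1))
  biosd <- f$biosolids & f$analyte == "PFDA"
  pastd <- !f$biosolids & f$analyte == "PFDA"
  expect_true(all(f$soil_ng_g[biosd] >= 65 & f$soil_ng_g[biosd] <= 111))
  expect_true(all(f$soil_ng_g[pastd] < 2.8))
  # several-fold class separation
  expect_gt(min(f$soil_ng_g[bios]), 5 * max(f$soil_ng_g[past]))
})

test_that("the same seed yields a byte-identical scenario bundle", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  generate_farm(synth_spec(seed = 5), dir = d1)
  generate_farm(synth_spec(seed = 5), dir = d2)
  files <- list.files(d1)
  expect_true(length(files) >= 6)
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  # a different seed changes the bundle
  d3 <- withr::local_tempdir()
  generate_farm(synth_spec(seed = 6), dir = d3)
  expect_false(identical(readLines(file.path(d1, "fields.csv")),
                         readLines(file.path(d3, "fields.csv"))))
})

test_that("life-history templates carry the seasonal calendar archetype", {
  lh24 <- accumulation_depuration_template(as.Date("2021-05-01"), 24)
  expect_equal(nrow(lh24$stored_feed), 2)
  expect_equal(lh24$end_date, as.Date("2023-04-30"))
  lh18 <- accumulation_depuration_template(as.Date("2021-05-01"), 18)
  expect_equal(nrow(lh18$stored_feed), 1)
  # ~6 months of grazing after the single winter
  expect_equal(as.integer(lh18$end_date - lh18$stored_feed$end), 183)
  expect_error(accumulation_depuration_template(as.Date("2021-05-01"), 30))
})

test_that("synthetic biomonitoring carries known truth and calibrated noise", {
  scn <- generate_farm(synth_spec(seed = 12))
  dates <- as.Date(c("2022-04-01", "2022-08-01"))
  exact <- generate_biomonitoring(scn, "PFOS", dates, n_animals = 2,
                                  noise_cv = 0, seed = 1)
  truth <- run_deterministic(scn, "PFOS")
  for (i in seq_along(dates)) {
    sel <- exact$date == dates[i] & exact$matrix == "serum"
    expect_equal(unique(exact$conc[sel]),
                 truth$serum[truth$date == dates[i]])
  }
  # muscle and serum are linked by the true PM before noising
  pm <- scn$params$tk$PFOS$PM[1]
  serum <- exact$conc[exact$matrix == "serum"]
  muscle <- exact$conc[exact$matrix == "muscle"]
  expect_equal(muscle, pm * serum)
  # lognormal noise reproduces its CV
  noisy <- generate_biomonitoring(scn, "PFOS", dates[1],
                                  matrices = "serum", n_animals = 1000,
                                  noise_cv = 0.10, seed = 3)
  emp_cv <- sd(noisy$conc) / mean(noisy$conc)
  expect_gte(emp_cv, 0.08)
  expect_lte(emp_cv, 0.12)
  expect_error(generate_biomonitoring(scn, "PFOS", as.Date("1990-01-01")),
               class = "herdtk_validation_error")
})

test_that("default synthetic trajectories peak on stored feed in every draw", {
  scn <- generate_farm(synth_spec())
  ens <- simulate_ensemble(scn, "PFOS", n = 25, seed = 1)
  sf <- scn$life_history$stored_feed
  for (x in split(ens$trajectories, ens$trajectories$draw)) {
    mx <- x$date[which.max(x$serum)]
    expect_true(any(mx >= sf$start & mx <= sf$end))
  }
})

test_that("the full pipeline closes end to end on generated data", {
  scn <- generate_farm(synth_spec(seed = 21))
  dates <- as.Date(c("2022-03-15", "2022-09-15"))
  bio <- generate_biomonitoring(scn, "PFOS", dates, matrices = "serum",
                                n_animals = 4, noise_cv = 0.1, seed = 2)
  ens <- simulate_ensemble(scn, "PFOS", n = 20, seed = 3)
  report <- evaluate_scenario(ens, bio)
  expect_equal(nrow(report), 2)
  # the generator's truth is the ensemble's central tendency: modeled and
  # measured agree well within the stochastic spread
  expect_true(all(report$fold < 2))
  out <- withr::local_tempdir()
  run_simulation(scn, out, analytes = "PFOS", n = 5, seed = 4)
  expect_true(file.exists(file.path(out, "manifest.json")))
  expect_true(file.exists(file.path(out, "summary_PFOS.csv")))
  rep2 <- write_evaluation(list(PFOS = ens), bio, out)
  expect_true(file.exists(file.path(out, "evaluation.csv")))
  expect_true(file.exists(file.path(out, "mape.csv")))
  p <- plot_ensemble(ens, "muscle", biomonitoring = bio)
  expect_s3_class(p, "ggplot")
})
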
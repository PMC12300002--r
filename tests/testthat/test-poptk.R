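# One-compartment kinetics, stochastic ensembles, sensitivity.

test_that("elimination rate is ln2 over the half-life", {
  expect_equal(elimination_rate(74.1), log(2) / 74.1)
  expect_equal(elimination_rate(60.4), log(2) / 60.4)
  expect_equal(elimination_rate(log(2)), 1)
  expect_error(elimination_rate(0))
})

test_that("the daily step reproduces half-life, plateau, and no-loss limits", {
  k <- elimination_rate(50)
  b <- 1000
  for (i in 1:50) b <- tk_step(b, 0, k)
  expect_equal(b, 500, tolerance = 1e-9)
  # geometric steady state under constant dosing
  b <- 0
  for (i in 1:1500) b <- tk_step(b, 100, k)
  expect_equal(b, 100 / (1 - exp(-k)), tolerance = 1e-3)
  # k -> 0 accumulates linearly
  b <- 5
  for (i in 1:20) b <- tk_step(b, 10, 0)
  expect_equal(b, 5 + 20 * 10)
})

test_that("trajectories decay log-linearly and plateau at the analytic level", {
  setup <- constant_dose_setup(n_days = 600, dose = 0, dt50 = 74.1)
  tr <- simulate_trajectory(setup$dose, setup$bw, setup$params, serum0 = 30)
  expect_equal(tr$serum[1], 30)
  # log-linear fit over the decay recovers DT50 within 1%
  fit <- lm(log(serum) ~ I(0:599), data = tr)
  expect_equal(log(2) / -coef(fit)[[2]], 74.1, tolerance = 0.01)

  setup <- constant_dose_setup(n_days = 2000, dose = 10000, dt50 = 50)
  tr <- simulate_trajectory(setup$dose, setup$bw, setup$params)
  k <- elimination_rate(50)
  plateau_cont <- 10000 / (k * 0.085 * 500 * 1000)
  expect_equal(tail(tr$serum, 1), plateau_cont, tolerance = 0.02)
  # zero everything -> identically zero
  tr0 <- simulate_trajectory(rep(0, 100), rep(500, 100), setup$params)
  expect_true(all(tr0$serum == 0))
})

test_that("mass balance closes to numerical precision", {
  scn <- tiny_scenario()
  ds <- build_dose_series(scn, "PFOS")
  body <- body_states(scn)
  p <- list(DT50 = 74.1, Vd = 0.085, PM = 0.08, Pmilk = 0.015)
  tr <- simulate_trajectory(ds$dose_total, body$bw_kg, p, serum0 = 5)
  k <- elimination_rate(74.1)
  n <- nrow(tr)
  eliminated <- sum(tr$burden[-n] * (1 - exp(-k)))
  dosed <- sum(ds$dose_total[-1])
  expect_equal(tr$burden[n] - tr$burden[1], dosed - eliminated,
               tolerance = 1e-9)
})

test_that("serum scales linearly with dose and partitions are exact ratios", {
  scn <- tiny_scenario()
  ds <- build_dose_series(scn, "PFOS")
  body <- body_states(scn)
  p <- list(DT50 = 74.1, Vd = 0.085, PM = 0.08, Pmilk = 0.015)
  tr1 <- simulate_trajectory(ds$dose_total, body$bw_kg, p, serum0 = 2)
  tr2 <- simulate_trajectory(2 * ds$dose_total, body$bw_kg, p, serum0 = 4)
  expect_equal(tr2$serum, 2 * tr1$serum, tolerance = 1e-12)
  expect_equal(tr1$muscle, 0.08 * tr1$serum)
  expect_equal(tr1$milk, 0.015 * tr1$serum)
  # growth dilution: fixed burden, rising BW, falling serum
  grow <- seq(100, 500, length.out = 50)
  trg <- simulate_trajectory(rep(0, 50), grow, p, serum0 = 10)
  expect_true(all(diff(trg$serum) < 0))
})

test_that("parameter draws recover the configured distribution", {
  set.seed(5)
  tk <- default_params()$tk$PFOS
  d <- draw_tk_params(10000, tk)
  expect_equal(mean(d$DT50), 74.1, tolerance = 0.02)
  expect_equal(sd(d$DT50), 13.4, tolerance = 0.05)
  expect_true(all(d$DT50 > 0 & d$Vd > 0 & d$PM > 0 & d$Pmilk > 0))
})

test_that("ensembles degenerate to the deterministic run and are reproducible", {
  scn <- tiny_scenario()
  scn$params$intake$intake_cv <- 0
  tk0 <- scn$params$tk$PFOS
  for (nm in names(tk0)) tk0[[nm]][2] <- 0
  scn$params$tk$PFOS <- tk0
  ens <- simulate_ensemble(scn, "PFOS", n = 5, seed = 2)
  det <- run_deterministic(scn, "PFOS")
  for (i in 1:5) {
    expect_equal(ens$trajectories$serum[ens$trajectories$draw == i],
                 det$serum)
  }
  expect_true(all(ens$summary$sd[ens$summary$matrix == "serum"] < 1e-10))

  scn2 <- tiny_scenario()
  e1 <- simulate_ensemble(scn2, "PFOS", n = 8, seed = 31)
  e2 <- simulate_ensemble(scn2, "PFOS", n = 8, seed = 31)
  expect_identical(e1$summary, e2$summary)
  e3 <- simulate_ensemble(scn2, "PFOS", n = 8, seed = 32)
  expect_false(identical(e3$summary$mean, e1$summary$mean))
})

test_that("stored summaries equal summaries recomputed from members", {
  scn <- tiny_scenario()
  ens <- simulate_ensemble(scn, "PFOS", n = 10, seed = 4)
  expect_equal(ens$summary, ensemble_summary(ens$trajectories))
  sel <- ens$summary$matrix == "serum" &
    ens$summary$date == scn$life_history$end_date
  manual <- ens$trajectories$serum[ens$trajectories$date ==
                                     scn$life_history$end_date]
  expect_equal(ens$summary$mean[sel], mean(manual))
  expect_equal(ens$summary$sd[sel], sd(manual))
})

test_that("Vd scaling leaves CV constant and inverts plateau serum", {
  scn <- tiny_scenario()
  scn$params$intake$intake_cv <- 0
  scn$params$tk$maternal_transfer <- 0  # isolate the dose-driven signal
  tk0 <- scn$params$tk$PFOS
  for (nm in names(tk0)) tk0[[nm]][2] <- 0
  scn$params$tk$PFOS <- tk0
  sens <- vd_sensitivity(scn, "PFOS", factors = c(0.5, 1, 2), n = 2, seed = 9)
  base <- simulate_ensemble(scn, "PFOS", n = 2, seed = 9)
  expect_equal(sens[["1"]]$summary, base$summary)
  # deep-winter serum (near plateau of the exposure season) scales as 1/Vd
  probe_date <- as.Date("2022-04-15")
  get <- function(e) e$summary$mean[e$summary$matrix == "serum" &
                                      e$summary$date == probe_date]
  expect_equal(get(sens[["2"]]), get(sens[["1"]]) / 2, tolerance = 1e-6)
  expect_equal(get(sens[["0.5"]]), get(sens[["1"]]) * 2, tolerance = 1e-6)
})
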
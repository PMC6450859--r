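test_that("basal turnover is the steady-state tracer dilution F/Z", {
  expect_equal(basal_ra_steady_state(1.0, 0.02), 50)
  expect_equal(basal_ra_steady_state(0, 0.05), 0)
  expect_error(basal_ra_steady_state(1, 0), "positive")
  expect_error(basal_ra_steady_state(1, -0.01), "positive")
})

test_that("Steele Ra reduces to F/Z at steady enrichment and cancels by construction", {
  expect_equal(steele_total_ra(1.11, 5, 0, 0.0222, 220), 50)
  # numerator cancellation: V C dZ/dt constructed to equal F
  F <- 0.5; V <- 220; C <- 5
  dZdt <- F / (V * C)
  expect_equal(steele_total_ra(F, C, dZdt, 0.01, V), 0)
  expect_error(steele_total_ra(1, 5, 0, 0, 220, t = 95),
               "non-positive TTR.*95")
})

test_that("EGP subtracts the exogenous infusion and flags negatives", {
  expect_equal(endogenous_ra(50, 0)$egp, 50)
  expect_equal(endogenous_ra(40, 40)$egp, 0)
  neg <- endogenous_ra(30, 35)
  expect_equal(neg$egp, -5)
  expect_true("NEGATIVE_EGP" %in% neg$flags)
  expect_length(endogenous_ra(40, 40)$flags, 0)
})

test_that("Rd equals Ra under clamped glycaemia and subtracts pool change otherwise", {
  expect_equal(glucose_rd(50, 0, 220), 50)
  expect_equal(glucose_rd(50, 5 / 220, 220), 45)
})

test_that("window means use the sampled rates and fail on sparse windows", {
  expect_equal(window_mean_rate(rep(7, 4), c(210, 220, 230, 240),
                                c(210, 240))$mean, 7)
  r <- 0.1 * c(210, 220, 230, 240)
  expect_equal(window_mean_rate(r, c(210, 220, 230, 240),
                                c(210, 240))$mean, mean(r))
  expect_equal(window_mean_rate(c(1, 2, 3, 4), c(-30, -20, -10, 0),
                                c(-30, 0))$n, 4)
  expect_error(window_mean_rate(c(1, NA, NA, NA), c(210, 220, 230, 240),
                                c(210, 240)), "SPARSE_WINDOW")
})

test_that("glycerol Ra recovers F/Z on a constant series and refuses stage 2", {
  ser <- fixture_series_linear()   # glycerol TTR constant at 0.0485
  p <- default_protocol
  res <- glycerol_ra_window(ser, p, c(90, 120))
  expect_equal(res$mean, mg_to_umol(0.0067, "glycerol") / 0.0485,
               tolerance = 1e-6)
  expect_equal(round(res$mean, 2), 1.50)
  expect_error(glycerol_ra_window(ser, p, c(210, 240)),
               "stopped before stage 2")
})

test_that("noise-free simulated subject: basal rates recovered to float precision", {
  sim <- fixture_sim(noise = FALSE)
  kin <- subject_kinetics(sim$series, fixture_subject(), default_protocol)
  ts <- sim$truth_summary
  expect_equal(kin$basal_glucose_ra, ts$basal_glucose_ra,
               tolerance = 1e-6)
  expect_equal(kin$basal_glycerol_ra, ts$basal_glycerol_ra,
               tolerance = 1e-6)
  expect_equal(kin$basal_glucose_rd, kin$basal_glucose_ra)
})

test_that("noise-free simulated subject: clamp-window rates within 5% of truth", {
  sim <- fixture_sim(noise = FALSE)
  kin <- subject_kinetics(sim$series, fixture_subject(), default_protocol)
  ts <- sim$truth_summary
  expect_lt(abs(kin$clamp_glucose_ra / ts$clamp_glucose_ra - 1), 0.05)
  expect_lt(abs(kin$clamp_glucose_rd / ts$clamp_glucose_rd - 1), 0.05)
  expect_lt(abs(kin$clamp_glycerol_ra / ts$clamp_glycerol_ra - 1), 0.05)
})

test_that("mass balance closes at steady glycaemia: GIR + EGP = Rd within 2%", {
  sim <- fixture_sim(noise = FALSE)
  tr <- sim$truth_traj
  hw <- tr$t >= 210 & tr$t <= 240
  lhs <- mean(tr$gir[hw] + tr$egp[hw])
  rhs <- mean(tr$rd[hw])
  expect_lt(abs(lhs / rhs - 1), 0.02)
})

test_that("missing basal TTR samples abort with a sparse-window error", {
  sim <- fixture_sim(noise = FALSE)
  ser <- sim$series
  ser$samples$glucose_ttr[ser$samples$t <= 0] <- NA
  expect_error(subject_kinetics(ser, fixture_subject(), default_protocol),
               "SPARSE_WINDOW")
})
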
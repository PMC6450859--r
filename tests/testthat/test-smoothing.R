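sched <- c(-30, -20, -10, 0, 30, 60, 90, 100, 110, 120, 150, 180, 210,
           220, 230, 240)

test_that("exactly linear data collapse to a single exact segment", {
  y <- 2.5 - 0.01 * sched
  fit <- fit_optimal_segments(sched, y)
  expect_length(fit$knots, 0)
  expect_lt(max(abs(fit$fitted - y)), 1e-9)
  ev <- evaluate_curve(fit, c(-30, 0, 117.5, 240))
  expect_equal(ev$deriv, rep(-0.01, 4), tolerance = 1e-9)
})

test_that("a noise-free kink at a sample time is found exactly", {
  kink <- 120
  y <- ifelse(sched <= kink, 5 + 0.02 * sched, 5 + 0.02 * kink -
                0.03 * (sched - kink))
  fit <- fit_optimal_segments(sched, y)
  expect_equal(fit$knots, kink)
  expect_lt(max(abs(fit$fitted - y)), 1e-9)
  # right-derivative convention at the breakpoint; left on request
  expect_equal(evaluate_curve(fit, kink)$deriv, -0.03, tolerance = 1e-8)
  expect_equal(evaluate_curve(fit, kink, side = "left")$deriv, 0.02,
               tolerance = 1e-8)
})

test_that("values and derivatives are analytic on polynomial input", {
  t <- 0:10
  fit <- fit_optimal_segments(t, t^2)
  ev <- evaluate_curve(fit, 3)
  expect_equal(ev$value, 9, tolerance = 1e-9)
  expect_equal(ev$deriv, 6, tolerance = 1e-9)
  # constant input: zero derivative everywhere
  cfit <- fit_optimal_segments(sched, rep(7.25, length(sched)))
  evc <- evaluate_curve(cfit, seq(-30, 240, by = 10))
  expect_equal(evc$value, rep(7.25, 28), tolerance = 1e-9)
  expect_equal(evc$deriv, rep(0, 28), tolerance = 1e-9)
})

test_that("evaluation outside the fitted range is an error, never extrapolated", {
  fit <- fit_optimal_segments(sched, sin(sched / 50))
  expect_error(evaluate_curve(fit, 241), "outside fitted range")
  expect_error(evaluate_curve(fit, -31), "outside fitted range")
})

test_that("degenerate inputs are rejected", {
  expect_error(fit_optimal_segments(c(0, 10, 20), c(1, 2, 3)),
               "at least 4")
  expect_error(fit_optimal_segments(c(0, 0, 10, 20), c(1, 1, 2, 3)),
               "duplicate")
  expect_error(fit_optimal_segments(1:5, c(1, 2, NA, NA, 5)), "at least 4")
})

test_that("refitting the fitted values reproduces the curve with zero SSE", {
  set.seed(11)
  y <- 5 + 0.5 * sin(sched / 40) + rnorm(length(sched), 0, 0.1)
  fit <- fit_optimal_segments(sched, y)
  refit <- fit_optimal_segments(sched, fit$fitted)
  expect_lt(refit$rss, 1e-16)
  tt <- seq(-30, 240, by = 5)
  expect_equal(evaluate_curve(refit, tt)$value,
               evaluate_curve(fit, tt)$value, tolerance = 1e-7)
})

test_that("allowing one more breakpoint never increases the minimised SSE", {
  set.seed(12)
  for (rep in 1:5) {
    y <- 5 * exp(-sched / 80) + rnorm(length(sched), 0, 0.2)
    fit <- fit_optimal_segments(sched, y, max_segments = 4)
    rk <- fit$rss_by_knots
    expect_true(all(diff(rk[!is.na(rk)]) <= 1e-10))
  }
})

test_that("the derivative integrates back to the fitted curve", {
  set.seed(13)
  y <- 5 + 2 * sin(sched / 60) + rnorm(length(sched), 0, 0.05)
  fit <- fit_optimal_segments(sched, y)
  # fundamental theorem per segment; Simpson quadrature is exact for the
  # quadratic pieces
  edges <- c(-30, fit$knots, 240)
  for (i in seq_len(length(edges) - 1)) {
    a <- edges[i]; b <- edges[i + 1]
    m <- 200
    tt <- seq(a, b, length.out = 2 * m + 1)
    d <- evaluate_curve(fit, tt)$deriv
    # the right edge is a breakpoint: this segment's slope is the left one
    d[length(d)] <- evaluate_curve(fit, b, side = "left")$deriv
    h <- (b - a) / (2 * m)
    integral <- h / 3 * (d[1] + d[2 * m + 1] +
                           4 * sum(d[seq(2, 2 * m, by = 2)]) +
                           2 * sum(d[seq(3, 2 * m - 1, by = 2)]))
    dv <- diff(evaluate_curve(fit, c(a, b))$value)
    expect_lt(abs(integral - dv), 1e-8)
  }
})

test_that("required_spans forces breakpoints into the given intervals", {
  set.seed(14)
  y <- 5 * exp(-sched / 80) + rnorm(length(sched), 0, 0.2)
  fit <- fit_optimal_segments(sched, y, max_segments = 5,
                              required_spans = list(c(30, 120),
                                                    c(120, 230)))
  expect_true(any(fit$knots >= 30 & fit$knots <= 120))
  expect_true(any(fit$knots >= 120 & fit$knots <= 230))
})

test_that("noisy smooth signals are tracked within their residual bands", {
  # Monte-Carlo with known truth on the clamp sampling schedule
  truth <- function(t) 5 + 1.5 * sin(2 * pi * t / 400)
  set.seed(15)
  n_rep <- 150
  covered <- total <- 0
  for (r in seq_len(n_rep)) {
    y <- truth(sched) + rnorm(length(sched), 0, 0.08)
    fit <- fit_optimal_segments(sched, y)
    band <- 2 * max(fit$residual_sd, 0.08)
    covered <- covered + sum(abs(fit$fitted - truth(sched)) <= band)
    total <- total + length(sched)
  }
  expect_gt(covered / total, 0.93)
})
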
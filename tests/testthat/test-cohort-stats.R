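test_that("routing sends normal data down the normal route at the nominal rate", {
  set.seed(21)
  hits <- 0
  n_rep <- 500
  for (r in seq_len(n_rep)) {
    a <- rnorm(18); b <- rnorm(15)
    if (suppressWarnings(route_variable(a, b))$route == "normal") {
      hits <- hits + 1
    }
  }
  expect_gt(hits / n_rep, 0.90)
})

test_that("lognormal data are routed through the log10 transform", {
  set.seed(22)
  routes <- replicate(500, {
    a <- exp(rnorm(18, 0, 0.9)); b <- exp(rnorm(15, 0, 0.9))
    route_variable(a, b)$route
  })
  expect_gt(mean(routes == "lognormal"), 0.5)
})

test_that("non-positive values bypass the log route with a warning", {
  set.seed(23)
  a <- c(0, exp(rnorm(17, 0, 2)))
  b <- exp(rnorm(15, 0, 2))
  if (stats::shapiro.test(a)$p.value < 0.05 ||
      stats::shapiro.test(b)$p.value < 0.05) {
    expect_warning(r <- route_variable(a, b), "non-positive")
    expect_equal(r$route, "nonparametric")
  }
  expect_error(route_variable(c(1, 2), c(1, 2, 3)), ">= 3")
})

test_that("pooled-t difference matches its closed form and printed summaries", {
  # identical groups: zero difference, p = 1
  x <- c(1, 2, 3, 4, 5)
  same <- mean_difference_ci(x, x)
  expect_equal(same$estimate, 0)
  expect_equal(same$p, 1)
  # raw-data and summary-based routes agree exactly
  set.seed(24)
  a <- rnorm(18, 4.5, 2); b <- rnorm(15, 4.0, 1.7)
  raw <- mean_difference_ci(a, b)
  summ <- summary_mean_difference_ci(18, mean(a), sd(a), 15, mean(b), sd(b))
  expect_equal(raw$estimate, summ$estimate, tolerance = 1e-12)
  expect_equal(raw$ci, summ$ci, tolerance = 1e-10)
  expect_equal(raw$p, summ$p, tolerance = 1e-10)
  # equivariance: shifting group A shifts difference and CI by the shift
  shifted <- mean_difference_ci(a + 3, b)
  expect_equal(shifted$estimate, raw$estimate + 3, tolerance = 1e-10)
  expect_equal(shifted$ci, raw$ci + 3, tolerance = 1e-10)
})

test_that("whole-body insulin sensitivity contrast rebuilt from printed summaries", {
  a <- group_from_summary(18, 4.52, 2.07)
  b <- group_from_summary(15, 4.00, 1.70)
  expect_equal(mean(a), 4.52, tolerance = 1e-12)
  expect_equal(sd(a), 2.07, tolerance = 1e-12)
  res <- mean_difference_ci(a, b)
  expect_equal(res$estimate, 0.52, tolerance = 1e-12)
  expect_lt(abs(res$ci[1] - (-0.82)), 0.03)
  expect_lt(abs(res$ci[2] - 1.89), 0.03)
})

test_that("geometric-mean ratio is scale-invariant and matches printed ratio", {
  x <- c(1, 2, 4, 8, 16)
  expect_equal(geometric_ratio_ci(x, x)$estimate, 1)
  set.seed(25)
  a <- rlnorm(15, log(1.51), 0.3); b <- rlnorm(12, log(1.82), 0.3)
  r1 <- geometric_ratio_ci(a, b)
  r2 <- geometric_ratio_ci(7 * a, 7 * b)
  expect_equal(r1$estimate, r2$estimate, tolerance = 1e-10)
  expect_equal(r1$p, r2$p, tolerance = 1e-10)
  # groups constructed with exact printed geometric means
  ga <- 10^group_from_summary(15, log10(1.51), 0.05)
  gb <- 10^group_from_summary(12, log10(1.82), 0.05)
  expect_equal(round(geometric_ratio_ci(ga, gb)$estimate, 2), 0.83)
  expect_error(geometric_ratio_ci(c(1, -1, 2), c(1, 2, 3)), "positive")
})

test_that("Mann-Whitney exact p agrees with enumeration of all orderings", {
  a <- c(1, 2, 3); b <- c(4, 5, 6)
  # oracle: enumerate all choose(6,3) = 20 group assignments of the pooled
  # sample and count U statistics at least as extreme (two-sided)
  pool <- c(a, b)
  u_stat <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  u_obs <- u_stat(a, b)
  combos <- combn(6, 3)
  us <- apply(combos, 2, function(ix) u_stat(pool[ix], pool[-ix]))
  mu <- length(a) * length(b) / 2
  p_exact <- mean(abs(us - mu) >= abs(u_obs - mu))
  expect_equal(p_exact, 0.1)
  expect_equal(mann_whitney(a, b)$p, p_exact, tolerance = 1e-12)
  # symmetry and identity
  expect_equal(mann_whitney(b, a)$p, mann_whitney(a, b)$p)
  expect_equal(mann_whitney(c(1, 2, 3), c(1, 2, 3))$p, 1)
  expect_error(mann_whitney(numeric(0), 1:3), "empty")
})

test_that("Pearson correlation handles exact, degenerate and sampled cases", {
  x <- 1:10
  expect_equal(pearson_r(x, 2 * x + 1)$r, 1, tolerance = 1e-12)
  expect_equal(pearson_r(x, -x)$r, -1, tolerance = 1e-12)
  expect_warning(res <- pearson_r(x, rep(3, 10)), "zero variance")
  expect_true(is.na(res$r))
  set.seed(26)
  rhat <- replicate(1000, {
    z <- rnorm(12)
    e <- rnorm(12)
    x <- z
    y <- 0.78 * z + sqrt(1 - 0.78^2) * e
    pearson_r(x, y)$r
  })
  expect_lt(abs(mean(rhat) - 0.78), 0.05)
})

test_that("covariate adjustment leaves an unrelated covariate harmless", {
  set.seed(27)
  n <- 60
  g <- rep(c("BAM", "WEM"), each = n / 2)
  y <- 2 + 1.5 * (g == "BAM") + rnorm(n)
  cov_unrel <- rnorm(n)
  unadj <- mean_difference_ci(y[g == "BAM"], y[g == "WEM"])
  adj <- adjusted_group_effect(y, g, data.frame(c1 = cov_unrel))
  expect_lt(abs(adj$estimate - unadj$estimate), 0.5)
  # outcome identical to the covariate: zero group effect (the perfect fit
  # triggers a harmless numerical-precision warning in summary.lm)
  adj0 <- suppressWarnings(
    adjusted_group_effect(cov_unrel, g, data.frame(c1 = cov_unrel)))
  expect_equal(adj0$estimate, 0, tolerance = 1e-10)
  expect_error(
    adjusted_group_effect(y, g, data.frame(c1 = cov_unrel, c2 = cov_unrel)),
    "rank deficient")
})

test_that("interaction p-values are uniform under equal slopes", {
  set.seed(28)
  ps <- replicate(500, {
    g <- rep(c("BAM", "WEM"), c(15, 12))
    x <- rnorm(27)
    y <- 1 + 0.5 * x + rnorm(27)
    interaction_test(y, x, g)$p_interaction
  })
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("interaction test recovers group-specific slopes and symmetry", {
  set.seed(29)
  g <- rep(c("BAM", "WEM"), c(30, 30))
  x <- rnorm(60)
  slope <- ifelse(g == "BAM", 0.25, 0.78)
  y <- slope * x + rnorm(60, 0, 0.2)
  res <- interaction_test(y, x, g)
  expect_lt(abs(res$slopes[["BAM"]] - 0.25), 0.15)
  expect_lt(abs(res$slopes[["WEM"]] - 0.78), 0.15)
  # relabelling the groups leaves the interaction p unchanged
  res2 <- interaction_test(y, x, ifelse(g == "BAM", "WEM", "BAM"))
  expect_equal(res$p_interaction, res2$p_interaction, tolerance = 1e-10)
  expect_error(interaction_test(y, x, rep("BAM", 60)), "both groups")
})

test_that("route-then-test dispatches to the matching contrast type", {
  set.seed(30)
  a <- rnorm(18, 10, 2); b <- rnorm(15, 9, 2)
  row <- compare_groups(a, b, "demo")
  expect_equal(row$route, "normal")
  expect_equal(row$contrast, "mean_difference")
  expect_equal(row$estimate, mean(a) - mean(b), tolerance = 1e-10)
  al <- exp(rnorm(18, 0, 0.8)); bl <- exp(rnorm(15, 0.3, 0.8))
  rowl <- compare_groups(al, bl, "demo_log")
  expect_true(rowl$route %in% c("lognormal", "nonparametric"))
  if (rowl$route == "lognormal") {
    expect_equal(rowl$contrast, "geometric_mean_ratio")
  }
})

test_that("reference-summary recomputation flags the inconsistent printed CI", {
  rec <- recompute_reference_contrasts()
  vat <- rec[rec$variable == "vat_kg", ]
  expect_equal(vat$ci_flag, "CI_INCONSISTENT_WITH_PRINTED")
  clean <- rec[rec$variable %in% c("m_value", "clamp_glucose_rd",
                                   "basal_glucose_ra", "clamp_glucose_ra"), ]
  expect_true(all(clean$ci_flag == ""))
})
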
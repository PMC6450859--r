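test_that("Mosteller BSA matches the closed form, including edge values", {
  expect_equal(compute_bsa(160, 90), 2)
  expect_equal(compute_bsa(180, 80), 2)
  expect_equal(compute_bsa(175.6, 90.9), sqrt(175.6 * 90.9 / 3600),
               tolerance = 1e-12)
  expect_equal(round(compute_bsa(175.6, 90.9), 3), 2.106)
  # property: closed-form agreement over random anthropometry
  set.seed(7)
  h <- runif(1000, 140, 210)
  w <- runif(1000, 40, 160)
  expect_equal(compute_bsa(h, w), sqrt(h * w / 3600), tolerance = 1e-12)
  expect_error(compute_bsa(-1, 70), "positive")
  expect_error(compute_bsa(170, 0), "positive")
})

test_that("mass/mole conversions round-trip and match molar masses", {
  expect_equal(mg_to_umol(1, "glucose"), 1000 / 180.16, tolerance = 1e-12)
  expect_equal(mg_to_umol(1, "glycerol"), 1000 / 92.09, tolerance = 1e-12)
  x <- c(0.02, 0.0067, 1, 123.4)
  expect_equal(umol_to_mg(mg_to_umol(x, "glucose"), "glucose"), x,
               tolerance = 1e-12)
  expect_equal(umol_to_mg(mg_to_umol(x, "glycerol"), "glycerol"), x,
               tolerance = 1e-12)
  ctx <- conversion_context(90, v_frac = 0.22)
  expect_equal(ctx$V, 220)
  expect_error(conversion_context(-5), "positive")
  expect_error(conversion_context(80, v_frac = 1.2), "0, 1")
})

test_that("default protocol carries the reference infusion constants", {
  p <- clamp_protocol()
  expect_equal(p$glucose_tracer_prime, 2.0)
  expect_equal(p$glucose_tracer_rate, 0.02)
  expect_equal(p$glycerol_tracer_prime, 0.12)
  expect_equal(p$glycerol_tracer_rate, 0.0067)
  expect_equal(p$insulin_rate_low, 10)
  expect_equal(p$insulin_rate_high, 40)
  expect_equal(p$infusate_enrichment_low, 8)
  expect_equal(p$infusate_enrichment_high, 10)
  expect_equal(p$distribution_volume_fraction, 0.22)
  expect_equal(p$glycaemic_target, 5)
  expect_equal(p$basal_window, c(-30, 0))
  expect_equal(p$low_window, c(90, 120))
  expect_equal(p$high_window, c(210, 240))
  expect_equal(p$sample_times,
               c(-30, -20, -10, 0, 30, 60, 90, 100, 110, 120, 150, 180,
                 210, 220, 230, 240))
  expect_equal(infusate_enrichment_at(p, c(30, 120, 121, 240)),
               c(8, 8, 10, 10))
})

test_that("protocol validation rejects inconsistent windows and volumes", {
  expect_error(clamp_protocol(distribution_volume_fraction = 0), "0, 1")
  expect_error(clamp_protocol(low_window = c(100, 130)), "stage 1")
  expect_error(clamp_protocol(basal_window = c(-30, 10)), "basal")
})

test_that("protocol YAML round-trips field-for-field", {
  p <- clamp_protocol()
  f <- tempfile(fileext = ".yaml")
  write_protocol(p, f)
  p2 <- read_protocol(f)
  expect_equal(unclass(p2), unclass(p))
})

test_that("series CSV round-trips losslessly, preserving missingness", {
  ser <- fixture_series_linear()
  # knock out one glycerol TTR like a lost assay
  ser$samples$glycerol_ttr[ser$samples$t == 110] <- NA
  f <- tempfile(fileext = ".csv")
  write_series(ser, f)
  ser2 <- read_series(f)
  expect_equal(ser2$samples, ser$samples)
  expect_equal(ser2$gir, ser$gir)
})

test_that("series validation names the offending row", {
  expect_error(sample_series(t = c(0, 0), glucose_mmol_l = c(5, 5)),
               "duplicate sample time")
  expect_error(sample_series(t = c(0, 10), glucose_mmol_l = c(5, -1)),
               "negative value.*glucose_mmol_l")
  f <- tempfile(fileext = ".csv")
  writeLines("t_min,glucose_mmol_l,bogus\n0,5,1\n10,5,2", f)
  expect_error(read_series(f), "unknown column.*bogus")
})

test_that("GIR step function integrates exactly and respects side limits", {
  ser <- fixture_series_linear()   # 2 mg/kg/min from 0, 4 from 120
  expect_equal(gir_at(ser, c(-10, 0, 119, 120, 240)), c(0, 2, 2, 4, 4))
  expect_equal(gir_at(ser, 120, side = "left"), 2)
  expect_equal(gir_window_mean(ser, c(0, 240)), 3)
  expect_equal(gir_window_mean(ser, c(90, 120)), 2)
  expect_equal(gir_window_mean(ser, c(110, 130)), 3)  # straddles the step
  expect_equal(gir_window_mean(ser, c(-30, 0)), 0)
})

test_that("a written cohort loads back with channel-level missingness intact", {
  spec <- cohort_spec(n_bam = 2, n_wem = 2, seed = 5)
  ds <- generate_cohort(spec)
  dir <- tempfile()
  write_cohort(ds, dir)
  loaded <- load_subject_dataset(file.path(dir, "subjects.csv"), dir,
                                 default_protocol)
  expect_setequal(names(loaded$subjects), names(ds$subjects))
  id <- names(ds$subjects)[1]
  expect_equal(loaded$series[[id]]$samples, ds$series[[id]]$samples,
               tolerance = 1e-12)
  # glycerol TTR is absent after the tracer stops
  s <- loaded$series[[id]]$samples
  expect_true(all(is.na(s$glycerol_ttr[s$t > 120])))
  expect_length(loaded$warnings, 0)
})
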
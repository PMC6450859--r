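#' Ground-truth physiology for one simulated clamp subject
#'
#' The simulator embodies exactly the physiology the turnover estimator
#' assumes: a single glucose pool (V = 22% BW) fed by endogenous production
#' (EGP) and exogenous dextrose and drained by insulin-stimulated disposal
#' (Rd); a glycerol pool fed by lipolysis; prescribed insulin trajectories
#' (first-order approach to stage plateaus); and Hill dose-responses tying
#' EGP suppression, Rd stimulation and lipolysis suppression to the
#' prevailing insulin concentration, each normalised so the basal insulin
#' level reproduces the basal rate exactly.
#'
#' Defaults are calibrated to published clamp magnitudes in men with early
#' type 2 diabetes: basal EGP ~9 umol/kg/min, ~36% EGP suppression at the
#' low insulin dose and ~80% at the high dose, ~185% Rd stimulation at the
#' high dose, ~37% lipolysis suppression at the low dose, and basal
#' glucose ~5.9 mmol/l.
#'
#' @param basal_glucose_mmol_l Basal plasma glucose.
#' @param basal_egp Basal endogenous glucose production (umol kg-1 min-1).
#' @param basal_glycerol_ra Basal lipolysis (umol kg-1 min-1).
#' @param basal_glycerol_umol_l Basal plasma glycerol.
#' @param basal_insulin,insulin_low_plateau,insulin_high_plateau Serum
#'   insulin (pmol/l) at basal and the two stage plateaus.
#' @param insulin_tau First-order time constant of the insulin rise (min).
#' @param egp_i50,egp_hill EGP dose-response midpoint (pmol/l) and Hill
#'   coefficient.
#' @param rd_rmax,rd_i50,rd_hill Rd stimulation: maximal fold drive,
#'   midpoint, Hill coefficient.
#' @param gly_i50,gly_hill Lipolysis dose-response.
#' @param basal_nefa_mmol_l,nefa_i50,nefa_floor NEFA channel (AUC only).
#' @param cv_glucose,cv_ttr,cv_insulin,cv_nefa,cv_glycerol Multiplicative
#'   measurement noise CVs per channel.
#' @param controller_kp,controller_ki PI gains of the bedside dextrose
#'   controller (umol kg-1 min-1 per mmol/l of glucose error).
#' @return Object of class `simulation_truth`.
#' @export
simulation_truth <- function(basal_glucose_mmol_l = 5.9,
                             basal_egp = 9.0,
                             basal_glycerol_ra = 1.65,
                             basal_glycerol_umol_l = 70,
                             basal_insulin = 50,
                             insulin_low_plateau = 100,
                             insulin_high_plateau = 155,
                             insulin_tau = 8,
                             egp_i50 = 112, egp_hill = 4,
                             rd_rmax = 16, rd_i50 = 150, rd_hill = 2,
                             gly_i50 = 101, gly_hill = 2,
                             basal_nefa_mmol_l = 0.5,
                             nefa_i50 = 90, nefa_floor = 0.04,
                             cv_glucose = 0.02, cv_ttr = 0.015,
                             cv_insulin = 0.05, cv_nefa = 0.07,
                             cv_glycerol = 0.07,
                             controller_kp = 15, controller_ki = 10) {
  tr <- as.list(environment())
  rates <- c(tr$basal_egp, tr$basal_glycerol_ra, tr$basal_glucose_mmol_l,
             tr$basal_glycerol_umol_l, tr$basal_insulin,
             tr$insulin_low_plateau, tr$insulin_high_plateau)
  if (any(!is.finite(rates)) || any(rates <= 0)) {
    stop("truth rates and levels must be positive", call. = FALSE)
  }
  structure(tr, class = "simulation_truth")
}

# Hill activation normalised to 0 at basal insulin is handled by ratioing
# against the basal value inside each rate function.
hill_up <- function(I, i50, h) I^h / (I^h + i50^h)

truth_insulin <- function(truth, protocol, t) {
  sb <- protocol$stage_boundaries
  Ib <- truth$basal_insulin
  tau <- truth$insulin_tau
  t1 <- sb[["insulin_start"]]; t2 <- sb[["stage2_start"]]
  # value reached at end of stage 1 (start point of the stage-2 approach)
  I_t2 <- truth$insulin_low_plateau +
    (Ib - truth$insulin_low_plateau) * exp(-(t2 - t1) / tau)
  ifelse(t < t1, Ib,
         ifelse(t < t2,
                truth$insulin_low_plateau +
                  (Ib - truth$insulin_low_plateau) * exp(-(t - t1) / tau),
                truth$insulin_high_plateau +
                  (I_t2 - truth$insulin_high_plateau) *
                  exp(-(t - t2) / tau)))
}

truth_egp <- function(truth, I) {
  g <- function(I) 1 - hill_up(I, truth$egp_i50, truth$egp_hill)
  truth$basal_egp * g(I) / g(truth$basal_insulin)
}

# insulin-driven disposal at the basal glucose level; actual disposal
# scales linearly with glucose (mass action) so the clamp has a stable
# operating point
truth_rd_insulin <- function(truth, I) {
  f <- function(I) 1 + truth$rd_rmax * hill_up(I, truth$rd_i50,
                                               truth$rd_hill)
  truth$basal_egp * f(I) / f(truth$basal_insulin)
}

truth_glycerol_ra <- function(truth, I) {
  g <- function(I) 1 - hill_up(I, truth$gly_i50, truth$gly_hill)
  truth$basal_glycerol_ra * g(I) / g(truth$basal_insulin)
}

truth_nefa <- function(truth, I) {
  g <- function(I) 1 - hill_up(I, truth$nefa_i50, 2)
  truth$nefa_floor + (truth$basal_nefa_mmol_l - truth$nefa_floor) *
    g(I) / g(truth$basal_insulin)
}

#' Simulate one subject through the two-stage clamp
#'
#' Integrates the tracee and tracer mass balances
#' (V dC/dt = EGP + GIR - Rd and V d(CZ)/dt = F_pump + e_inf GIR - Rd Z for
#' glucose; the analogous pair without exogenous tracee for glycerol) with
#' a classical RK4 scheme in 5-min blocks. At each block boundary from
#' insulin start onward, a proportional-integral controller adjusts the
#' dextrose rate from the current (optionally noisy) glucose reading,
#' mimicking bedside titration against the glycaemic target. Tracer pools
#' start on their basal isotopic plateau (Z = F/Ra), the state the priming
#' bolus is designed to reach; the glycerol tracer is switched off at the
#' stage-2 boundary. Cumulative in/out fluxes are integrated with the same
#' RK4 stages as the pools, so mass-balance closure can be audited exactly.
#'
#' @param subj A [subject()].
#' @param protocol A [clamp_protocol()].
#' @param truth A [simulation_truth()].
#' @param noise Apply multiplicative Gaussian measurement noise to the
#'   sampled channels (and the controller's glucose readings)?
#' @param dt RK4 substep (min).
#' @param seed Optional integer seed (set once, before any draw).
#' @return List of class `clamp_simulation`: `series` (a
#'   [sample_series()]), `truth_traj` (5-min grid of true C, Z, I, EGP, Rd,
#'   glycerol Ra, GIR), `truth_summary` (window means of the true rates at
#'   scheduled sample times, plus true suppression/stimulation
#'   percentages), `conservation` (relative closure errors), `unstable`
#'   (logical).
#' @export
simulate_subject <- function(subj, protocol, truth = simulation_truth(),
                             noise = TRUE, dt = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  V <- protocol$distribution_volume_fraction * 1000      # ml/kg
  sb <- protocol$stage_boundaries
  t0 <- sb[["basal_start"]]; t_end <- sb[["end"]]
  t_ins <- sb[["insulin_start"]]; t_s2 <- sb[["stage2_start"]]
  target <- protocol$glycaemic_target

  f_pump <- mg_to_umol(protocol$glucose_tracer_rate, "glucose")
  f_gly <- mg_to_umol(protocol$glycerol_tracer_rate, "glycerol")

  C0 <- truth$basal_glucose_mmol_l
  Cg0 <- truth$basal_glycerol_umol_l
  E0 <- truth$basal_egp
  G0 <- truth$basal_glycerol_ra

  ## state: pools (umol/kg) + cumulative fluxes for conservation audit
  Qc <- C0 * V                       # mmol/l * ml/kg = umol/kg
  Qt <- (f_pump / E0) * Qc           # basal isotopic plateau
  Qg <- Cg0 * V / 1000
  Qtg <- (f_gly / G0) * Qg
  y <- c(Qc, Qt, Qg, Qtg, rep(0, 8))
  pool0 <- y[1:4]

  deriv <- function(t, y, u) {
    I <- truth_insulin(truth, protocol, t)
    C <- y[1] / V
    egp <- truth_egp(truth, I)
    rd <- truth_rd_insulin(truth, I) * C / C0
    Z <- y[2] / y[1]
    gir_mg <- umol_to_mg(u, "glucose")
    f_inf <- mg_to_umol(infusate_enrichment_at(protocol, t) * gir_mg / 1000,
                        "glucose")
    Cg <- y[3] * 1000 / V
    g_ra <- truth_glycerol_ra(truth, I)
    g_rd <- G0 * Cg / Cg0
    Zg <- y[4] / y[3]
    fg <- if (t < t_s2) f_gly else 0
    c(egp + u - rd,                  # glucose tracee
      f_pump + f_inf - rd * Z,       # glucose tracer
      g_ra - g_rd,                   # glycerol tracee
      fg - g_rd * Zg,                # glycerol tracer
      egp + u, rd,                   # cumulative tracee in/out
      f_pump + f_inf, rd * Z,        # cumulative tracer in/out
      g_ra, g_rd,
      fg, g_rd * Zg)
  }

  block_starts <- seq(t0, t_end - 5, by = 5)
  grid_t <- seq(t0, t_end, by = 5)
  n_grid <- length(grid_t)
  traj <- matrix(NA_real_, n_grid, 6,
                 dimnames = list(NULL, c("C", "Z", "Cg", "Zg", "gir", "I")))
  store <- function(i, t, y, u) {
    traj[i, ] <<- c(y[1] / V, y[2] / y[1], y[3] * 1000 / V, y[4] / y[3],
                    u, truth_insulin(truth, protocol, t))
  }

  u <- 0; e_prev <- 0
  gir_rec_t <- numeric(); gir_rec_rate <- numeric()
  unstable <- FALSE
  store(1, t0, y, u)
  for (bi in seq_along(block_starts)) {
    tb <- block_starts[bi]
    if (tb >= t_ins) {
      reading <- y[1] / V
      if (noise) reading <- reading * (1 + truth$cv_glucose * rnorm(1))
      e <- target - reading
      u <- max(0, u + truth$controller_kp * (e - e_prev) +
                 truth$controller_ki * e)
      e_prev <- e
      gir_rec_t <- c(gir_rec_t, tb)
      gir_rec_rate <- c(gir_rec_rate, umol_to_mg(u, "glucose"))
    }
    nstep <- max(1L, round(5 / dt))
    h <- 5 / nstep
    tt <- tb
    for (s in seq_len(nstep)) {
      k1 <- deriv(tt, y, u)
      k2 <- deriv(tt + h / 2, y + h / 2 * k1, u)
      k3 <- deriv(tt + h / 2, y + h / 2 * k2, u)
      k4 <- deriv(tt + h, y + h * k3, u)
      y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      tt <- tt + h
    }
    C_now <- y[1] / V
    if (C_now < 3 || C_now > 9) unstable <- TRUE
    store(bi + 1L, tb + 5, y, u)
  }

  cons_err <- function(inflow, outflow, pool_end, pool_start) {
    scale <- max(inflow, outflow, abs(pool_end), 1e-12)
    (inflow - outflow - (pool_end - pool_start)) / scale
  }
  conservation <- c(
    glucose_tracee = cons_err(y[5], y[6], y[1], pool0[1]),
    glucose_tracer = cons_err(y[7], y[8], y[2], pool0[2]),
    glycerol_tracee = cons_err(y[9], y[10], y[3], pool0[3]),
    glycerol_tracer = cons_err(y[11], y[12], y[4], pool0[4])
  )

  ## ---- sampling at the scheduled times ----
  st <- protocol$sample_times
  idx <- match(st, grid_t)
  if (anyNA(idx)) stop("sample times must fall on the 5-min grid",
                       call. = FALSE)
  nz <- function(x, cv) if (noise) x * (1 + cv * rnorm(length(x))) else x
  gly_ttr <- traj[idx, "Zg"]
  gly_ttr[st > t_s2] <- NA_real_        # tracer stopped before stage 2
  ser <- sample_series(
    t = st,
    glucose_mmol_l = nz(traj[idx, "C"], truth$cv_glucose),
    insulin_pmol_l = nz(traj[idx, "I"], truth$cv_insulin),
    nefa_mmol_l = nz(truth_nefa(truth, traj[idx, "I"]), truth$cv_nefa),
    glucose_ttr = nz(traj[idx, "Z"], truth$cv_ttr),
    glycerol_umol_l = nz(traj[idx, "Cg"], truth$cv_glycerol),
    glycerol_ttr = nz(gly_ttr, truth$cv_ttr),
    gir = data.frame(t = gir_rec_t, rate_mg_kg_min = gir_rec_rate)
  )

  ## ---- truth summaries at the estimator's window sample times ----
  I_grid <- traj[, "I"]
  egp_grid <- truth_egp(truth, I_grid)
  rd_grid <- truth_rd_insulin(truth, I_grid) * traj[, "C"] / C0
  gly_grid <- truth_glycerol_ra(truth, I_grid)
  wmean <- function(vals, window) {
    in_w <- st >= window[1] & st <= window[2]
    mean(vals[match(st[in_w], grid_t)])
  }
  low <- protocol$low_window; high <- protocol$high_window
  truth_summary <- list(
    basal_glucose_ra = E0,
    basal_glucose_rd = E0,
    basal_glycerol_ra = G0,
    clamp_glucose_ra = wmean(egp_grid, low),
    clamp_glucose_rd = wmean(rd_grid, high),
    clamp_glycerol_ra = wmean(gly_grid, low)
  )
  truth_summary$pct_supp_egp <-
    100 * (truth_summary$clamp_glucose_ra - E0) / E0
  truth_summary$pct_increase_rd <-
    100 * (truth_summary$clamp_glucose_rd - E0) / E0
  truth_summary$pct_supp_glycerol_ra <-
    100 * (truth_summary$clamp_glycerol_ra - G0) / G0

  structure(
    list(series = ser,
         truth_traj = data.frame(t = grid_t, C = traj[, "C"],
                                 Z = traj[, "Z"], Cg = traj[, "Cg"],
                                 Zg = traj[, "Zg"], gir = traj[, "gir"],
                                 insulin = I_grid, egp = egp_grid,
                                 rd = rd_grid, glycerol_ra = gly_grid),
         truth_summary = truth_summary,
         conservation = conservation,
         unstable = unstable),
    class = "clamp_simulation"
  )
}

#' @export
print.clamp_simulation <- function(x, ...) {
  cat("<clamp_simulation>",
      if (x$unstable) "[UNSTABLE]" else "", "\n")
  ts <- x$truth_summary
  cat(sprintf("  true basal EGP %.2f, clamp EGP %.2f (%.1f%%), Rd %.2f (%+.1f%%)\n",
              ts$basal_glucose_ra, ts$clamp_glucose_ra, ts$pct_supp_egp,
              ts$clamp_glucose_rd, ts$pct_increase_rd))
  cat(sprintf("  max |conservation error| %.2e\n", max(abs(x$conservation))))
  invisible(x)
}

#' Cohort-level specification for the simulator
#'
#' Group means and SDs for anthropometry, body composition and the
#' physiological truth parameters, emulating the magnitudes reported for
#' black West African (BAM) and white European (WEM) men with early type 2
#' diabetes: e.g. VAT 3.72 (1.07) vs 5.68 (2.43) kg, basal EGP
#' 8.82 (1.49) vs 9.25 (1.66) umol/kg/min, basal lipolysis geometric mean
#' 1.51 vs 1.82 umol/kg/min. Between-subject correlation between the
#' muscle and adipose sensitivity deviates is group-specific (default
#' scenario 0.25 in BAM, 0.78 in WEM, with a common 0.6 muscle-liver
#' correlation).
#'
#' @param n_bam,n_wem Group sizes.
#' @param seed Integer seed making the whole cohort reproducible.
#' @param bam,wem Named lists overriding group-level parameters (means/SDs);
#'   see `cohort_group_defaults()` for the names.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_bam = 18, n_wem = 15, seed = 1,
                        bam = list(), wem = list()) {
  g_bam <- utils::modifyList(cohort_group_defaults("BAM"), bam)
  g_wem <- utils::modifyList(cohort_group_defaults("WEM"), wem)
  structure(list(n_bam = n_bam, n_wem = n_wem, seed = seed,
                 bam = g_bam, wem = g_wem),
            class = "cohort_spec")
}

#' @rdname cohort_spec
#' @param group `"BAM"` or `"WEM"`.
#' @export
cohort_group_defaults <- function(group = c("BAM", "WEM")) {
  group <- match.arg(group)
  if (group == "BAM") {
    list(weight_mean = 90.9, weight_sd = 9.3,
         height_mean = 175.6, height_sd = 7.6,
         vat_mean = 3.72, vat_sd = 1.07,
         sat_mean = 11.8, sat_sd = 3.9,
         muscle_mean = 20.7, muscle_sd = 2.5,
         glucose_mean = 5.89, glucose_sd = 0.39,
         egp_mean = 8.82, egp_sd = 1.49,
         gly_meanlog = log(1.51), gly_sdlog = 0.26,
         insulin_meanlog = log(45.7), insulin_sdlog = 0.43,
         muscle_adipose_r = 0.25, muscle_liver_r = 0.6)
  } else {
    list(weight_mean = 94.2, weight_sd = 11.6,
         height_mean = 176.8, height_sd = 5.8,
         vat_mean = 5.68, vat_sd = 2.43,
         sat_mean = 11.8, sat_sd = 2.6,
         muscle_mean = 18.5, muscle_sd = 3.0,
         glucose_mean = 5.71, glucose_sd = 0.63,
         egp_mean = 9.25, egp_sd = 1.66,
         gly_meanlog = log(1.82), gly_sdlog = 0.26,
         insulin_meanlog = log(57.3), insulin_sdlog = 0.5,
         muscle_adipose_r = 0.78, muscle_liver_r = 0.6)
  }
}

# positive truncated normal by rejection; counts attempts beyond the first
rtnorm_pos <- function(n, mean, sd, lower = 0) {
  out <- numeric(n); rejected <- 0L
  for (i in seq_len(n)) {
    repeat {
      x <- rnorm(1, mean, sd)
      if (x > lower) { out[i] <- x; break }
      rejected <- rejected + 1L
      if (rejected > 10000L) stop("infeasible cohort spec: ",
                                  "rejection sampling not converging",
                                  call. = FALSE)
    }
  }
  attr(out, "rejected") <- rejected
  out
}

#' Generate a synthetic two-group clamp study
#'
#' Draws subject-level anthropometry and physiology from the group
#' distributions in `spec` (truncated at zero with rejection resampling),
#' simulates every subject with [simulate_subject()], and returns a dataset
#' in the same shape [load_subject_dataset()] produces, plus the per-subject
#' ground truth. Deterministic for a fixed `spec$seed`.
#'
#' @param spec A [cohort_spec()].
#' @param protocol A [clamp_protocol()].
#' @param noise Measurement noise on (default) or off.
#' @param dt RK4 substep (min).
#' @return List `subjects`, `series`, `truth` (per-subject
#'   `simulation_truth`), `sims` (full [simulate_subject()] results),
#'   `spec`; attribute `rejections` counts resampled draws.
#' @export
generate_cohort <- function(spec = cohort_spec(), protocol = clamp_protocol(),
                            noise = TRUE, dt = 0.5) {
  set.seed(spec$seed)
  rejections <- 0L
  draw_group <- function(g, n, prefix) {
    ids <- sprintf("%s%02d", prefix, seq_len(n))
    draw <- function(mean, sd) {
      x <- rtnorm_pos(n, mean, sd)
      rejections <<- rejections + attr(x, "rejected")
      as.numeric(x)
    }
    weight <- draw(g$weight_mean, g$weight_sd)
    height <- draw(g$height_mean, g$height_sd)
    vat <- draw(g$vat_mean, g$vat_sd)
    sat <- draw(g$sat_mean, g$sat_sd)
    muscle <- draw(g$muscle_mean, g$muscle_sd)
    glucose <- draw(g$glucose_mean, g$glucose_sd)
    egp <- draw(g$egp_mean, g$egp_sd)
    gly <- rlnorm(n, g$gly_meanlog, g$gly_sdlog)
    ins_b <- rlnorm(n, g$insulin_meanlog, g$insulin_sdlog)
    ## correlated sensitivity deviates: muscle, adipose, liver
    z_m <- rnorm(n)
    r_ma <- g$muscle_adipose_r; r_ml <- g$muscle_liver_r
    z_a <- r_ma * z_m + sqrt(1 - r_ma^2) * rnorm(n)
    z_l <- r_ml * z_m + sqrt(1 - r_ml^2) * rnorm(n)
    list(ids = ids, weight = weight, height = height, vat = vat, sat = sat,
         muscle = muscle, glucose = glucose, egp = egp, gly = gly,
         ins_b = ins_b, z_m = z_m, z_a = z_a, z_l = z_l)
  }

  mk <- function(d, group) {
    n <- length(d$ids)
    subs <- list(); series <- list(); truths <- list(); sims <- list()
    for (i in seq_len(n)) {
      subs[[i]] <- subject(d$ids[i], group, d$weight[i], d$height[i],
                           d$vat[i], d$sat[i], d$muscle[i])
      tr <- simulation_truth(
        basal_glucose_mmol_l = d$glucose[i],
        basal_egp = d$egp[i],
        basal_glycerol_ra = d$gly[i],
        basal_insulin = d$ins_b[i],
        insulin_low_plateau = max(d$ins_b[i] + 30,
                                  100 * exp(0.12 * rnorm(1))),
        insulin_high_plateau = max(d$ins_b[i] + 70,
                                   155 * exp(0.12 * rnorm(1))),
        egp_i50 = 112 * exp(-0.25 * d$z_l[i]),
        # median 14 (not the canonical-subject 16): lognormal spread and
        # insulin-plateau heterogeneity inflate the cohort mean, and 14
        # centres clamp Rd on the published group magnitudes
        rd_rmax = 14 * exp(0.4 * d$z_m[i]),
        gly_i50 = 101 * exp(-0.25 * d$z_a[i]))
      sim <- simulate_subject(subs[[i]], protocol, tr, noise = noise,
                              dt = dt)
      series[[i]] <- sim$series
      truths[[i]] <- tr
      sims[[i]] <- sim
    }
    names(subs) <- names(series) <- names(truths) <- names(sims) <- d$ids
    list(subjects = subs, series = series, truth = truths, sims = sims)
  }

  bam <- mk(draw_group(spec$bam, spec$n_bam, "BAM"), "BAM")
  wem <- mk(draw_group(spec$wem, spec$n_wem, "WEM"), "WEM")
  out <- list(subjects = c(bam$subjects, wem$subjects),
              series = c(bam$series, wem$series),
              truth = c(bam$truth, wem$truth),
              sims = c(bam$sims, wem$sims),
              spec = spec)
  attr(out, "rejections") <- rejections
  out
}

#' Write a simulated cohort to the on-disk study layout
#'
#' Emits `subjects.csv`, one `<id>.csv` series per subject, and a
#' `<id>_truth.json` per subject with the true rates and window means.
#'
#' @param dataset A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_subjects(dataset$subjects, file.path(dir, "subjects.csv"))
  for (id in names(dataset$series)) {
    write_series(dataset$series[[id]], file.path(dir, paste0(id, ".csv")))
    if (!is.null(dataset$sims[[id]])) {
      jsonlite::write_json(dataset$sims[[id]]$truth_summary,
                           file.path(dir, paste0(id, "_truth.json")),
                           auto_unbox = TRUE, digits = NA)
    }
  }
  invisible(dir)
}
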
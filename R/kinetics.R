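#' Basal turnover from the isotopic plateau
#'
#' During the basal period the tracer has equilibrated, so the single-pool
#' model reduces to its steady state: Ra = F / Z, with F the tracer infusion
#' rate (umol kg-1 min-1) and Z the plateau tracer-to-tracee ratio. At basal
#' steady state Rd = Ra.
#'
#' @param F_basal Tracer infusion rate, umol kg-1 min-1.
#' @param Z_basal Mean TTR over the basal window (> 0).
#' @return Ra in umol kg-1 min-1.
#' @examples
#' basal_ra_steady_state(1.0, 0.02)  # 50
#' @export
basal_ra_steady_state <- function(F_basal, Z_basal) {
  if (!is.finite(Z_basal) || Z_basal <= 0) {
    stop("basal TTR must be positive", call. = FALSE)
  }
  F_basal / Z_basal
}

#' Steele non-steady-state total rate of appearance
#'
#' Single-pool Steele equation adapted for stable isotopes:
#' Ra(t) = \[F(t) - V C(t) dZ/dt\] / Z(t), where F(t) is the total tracer
#' infusion rate (pump tracer plus any tracer carried by the labelled
#' dextrose infusate), C the smoothed tracee concentration, Z the smoothed
#' TTR, and V the distribution volume. When dZ/dt = 0 this reduces to the
#' steady-state F/Z.
#'
#' All inputs are per evaluation time and vectorised. Units must agree:
#' F in umol kg-1 min-1, C in umol/ml (i.e. mmol/l for glucose;
#' umol/l / 1000 for glycerol), V in ml/kg.
#'
#' @param F_tracer Total tracer infusion rate (umol kg-1 min-1).
#' @param C Tracee concentration (umol/ml).
#' @param dZdt TTR slope (1/min).
#' @param Z TTR (> 0).
#' @param V Distribution volume (ml/kg).
#' @param t Times, used only for error messages.
#' @return Ra in umol kg-1 min-1.
#' @export
steele_total_ra <- function(F_tracer, C, dZdt, Z, V, t = NULL) {
  bad <- which(!is.finite(Z) | Z <= 0)
  if (length(bad)) {
    where <- if (!is.null(t)) sprintf(" at t = %g min", t[bad[1]]) else ""
    stop("non-positive TTR in Steele equation", where, call. = FALSE)
  }
  (F_tracer - V * C * dZdt) / Z
}

#' Endogenous glucose production
#'
#' EGP = total glucose Ra minus the exogenous glucose infusion rate. A
#' negative result is physically impossible but can arise from measurement
#' error near-complete suppression; it is returned as-is and flagged, never
#' truncated.
#'
#' @param total_ra Total Ra (umol kg-1 min-1).
#' @param gir Exogenous glucose infusion rate (umol kg-1 min-1).
#' @return List `egp` (vector) and `flags` (character, `"NEGATIVE_EGP"`
#'   when any value is negative).
#' @export
endogenous_ra <- function(total_ra, gir) {
  egp <- total_ra - gir
  flags <- if (any(egp < 0, na.rm = TRUE)) "NEGATIVE_EGP" else character()
  list(egp = egp, flags = flags)
}

#' Rate of disappearance under changing glycaemia
#'
#' Rd(t) = Ra_total(t) - V dC/dt. With glucose clamped (dC/dt = 0),
#' Rd equals Ra.
#'
#' @param total_ra Total Ra (umol kg-1 min-1).
#' @param dCdt Tracee concentration slope (umol/ml/min).
#' @param V Distribution volume (ml/kg).
#' @return Rd in umol kg-1 min-1.
#' @export
glucose_rd <- function(total_ra, dCdt, V) {
  total_ra - V * dCdt
}

#' Mean of a rate over an analysis window
#'
#' Rates are computed at the protocol's scheduled sample times and averaged
#' over the window (never averaged first and then pushed through the model).
#'
#' @param rate Rate values at `times`.
#' @param times Times the rates were evaluated at (min).
#' @param window `[a, b]` min, inclusive.
#' @return List `mean`, `n`, `times`, `flags` (`"SPARSE_WINDOW"` with an
#'   error when fewer than 2 evaluable points fall in the window).
#' @export
window_mean_rate <- function(rate, times, window) {
  keep <- times >= window[1] & times <= window[2] & !is.na(rate)
  if (sum(keep) < 2) {
    stop(sprintf("SPARSE_WINDOW: %d evaluable point(s) in [%g, %g]",
                 sum(keep), window[1], window[2]), call. = FALSE)
  }
  list(mean = mean(rate[keep]), n = sum(keep), times = times[keep],
       flags = character())
}

# Total glucose tracer infusion at time t: constant pump tracer plus the
# tracer carried by the labelled dextrose (e_inf mg tracer per g glucose).
glucose_tracer_infusion <- function(series, protocol, t, side = "right") {
  f_pump <- mg_to_umol(protocol$glucose_tracer_rate, "glucose")
  gir_mg <- gir_at(series, t, side)                 # mg glucose kg-1 min-1
  e_inf <- infusate_enrichment_at(protocol, t)      # mg tracer / g glucose
  f_pump + mg_to_umol(e_inf * gir_mg / 1000, "glucose")
}

#' Full Steele analysis for one subject
#'
#' Computes basal and clamp-window turnover from a subject's sample series:
#' basal glucose Ra (= Rd) and glycerol Ra from the isotopic plateau
#' (steady-state F/Z on window-mean TTR); clamp-period EGP over the final
#' 30 min of the low-dose insulin stage; Rd over the final 30 min of the
#' high-dose stage; glycerol Ra over the low-dose window (the glycerol
#' tracer stops before stage 2, so only basal and low-dose windows are
#' legal). Concentration and TTR channels are smoothed with
#' [fit_optimal_segments()] before the non-steady-state equations are
#' applied; rates are evaluated at scheduled sample times inside each
#' window and then averaged.
#'
#' @param series A [sample_series()].
#' @param subj A [subject()] (provides the weight for V).
#' @param protocol A [clamp_protocol()].
#' @param max_segments,degree Smoothing controls (see
#'   [fit_optimal_segments()]). The glucose channels default to 5 segments:
#'   a full two-stage series traverses five regimes (basal plateau, the
#'   stage-1 transition, its plateau, the stage-2 transition, its plateau).
#'   The shorter glycerol channels use one fewer.
#' @return Object of class `kinetics_result`: basal/clamp rates
#'   (umol kg-1 min-1), `windows_used`, and `flags`.
#' @export
subject_kinetics <- function(series, subj, protocol, max_segments = 5,
                             degree = 2) {
  V <- protocol$distribution_volume_fraction * 1000  # ml/kg
  flags <- character()
  s <- series$samples

  ## ---- basal plateau (steady state) ----
  bw <- protocol$basal_window
  z_bas <- samples_in_window(series, "glucose_ttr", bw)
  if (nrow(z_bas) < 2) stop("SPARSE_WINDOW: basal glucose TTR", call. = FALSE)
  f_pump <- mg_to_umol(protocol$glucose_tracer_rate, "glucose")
  basal_glucose_ra <- basal_ra_steady_state(f_pump, mean(z_bas$y))

  zg_bas <- samples_in_window(series, "glycerol_ttr", bw)
  basal_glycerol_ra <- if (nrow(zg_bas) >= 2) {
    basal_ra_steady_state(mg_to_umol(protocol$glycerol_tracer_rate,
                                     "glycerol"),
                          mean(zg_bas$y))
  } else {
    flags <- c(flags, "SPARSE_BASAL_GLYCEROL")
    NA_real_
  }

  ## ---- smoothed clamp-period curves ----
  ## the insulin dose steps at the stage boundaries are known regime
  ## changes: require the breakpoint search to cover each insulin stage
  sb <- protocol$stage_boundaries
  st <- protocol$sample_times
  in_stage1 <- st[st > sb[["insulin_start"]] & st <= sb[["stage2_start"]]]
  in_stage2 <- st[st >= sb[["stage2_start"]] & st < sb[["end"]]]
  spans <- list(range(in_stage1), range(in_stage2))
  fit_ch <- function(channel) {
    ok <- !is.na(s[[channel]])
    fit_optimal_segments(s$t[ok], s[[channel]][ok],
                         max_segments = max_segments, degree = degree,
                         required_spans = spans)
  }
  cg_fit <- fit_ch("glucose_mmol_l")
  zg_fit <- fit_ch("glucose_ttr")

  ## ---- EGP over the low-dose window ----
  ## The smoothed tracer curves low-pass the bedside pump's 5-min rate
  ## staircase, so the exogenous terms use the exact window integral of the
  ## GIR step record rather than instantaneous rates. The window ends at
  ## the stage-2 boundary: left-hand derivatives there.
  lw <- protocol$low_window
  t_low <- protocol$sample_times[protocol$sample_times >= lw[1] &
                                   protocol$sample_times <= lw[2]]
  cg <- evaluate_curve(cg_fit, t_low, side = "left")
  zg <- evaluate_curve(zg_fit, t_low, side = "left")
  f_pump_mol <- mg_to_umol(protocol$glucose_tracer_rate, "glucose")
  gir_low_mg <- gir_window_mean(series, lw)
  e_low <- protocol$infusate_enrichment_low
  f_tot <- f_pump_mol + mg_to_umol(e_low * gir_low_mg / 1000, "glucose")
  ra_low <- steele_total_ra(rep(f_tot, length(t_low)), cg$value, zg$deriv,
                            zg$value, V, t_low)
  gir_mol <- mg_to_umol(gir_low_mg, "glucose")
  egp <- endogenous_ra(ra_low, gir_mol)
  flags <- c(flags, egp$flags)
  clamp_glucose_ra <- window_mean_rate(egp$egp, t_low, lw)$mean

  ## ---- Rd over the high-dose window ----
  hw <- protocol$high_window
  t_high <- protocol$sample_times[protocol$sample_times >= hw[1] &
                                    protocol$sample_times <= hw[2]]
  cgh <- evaluate_curve(cg_fit, t_high)
  zgh <- evaluate_curve(zg_fit, t_high)
  gir_high_mg <- gir_window_mean(series, hw)
  e_high <- protocol$infusate_enrichment_high
  f_toth <- f_pump_mol + mg_to_umol(e_high * gir_high_mg / 1000, "glucose")
  ra_high <- steele_total_ra(rep(f_toth, length(t_high)), cgh$value,
                             zgh$deriv, zgh$value, V, t_high)
  rd_high <- glucose_rd(ra_high, cgh$deriv, V)
  clamp_glucose_rd <- window_mean_rate(rd_high, t_high, hw)$mean

  ## ---- glycerol Ra over the low-dose window ----
  clamp_glycerol_ra <- tryCatch({
    gl_ra <- glycerol_ra_window(series, protocol, lw, V,
                                max_segments = max(2, max_segments - 1),
                                degree = degree)
    gl_ra$mean
  }, error = function(e) {
    flags <<- c(flags, "SPARSE_CLAMP_GLYCEROL")
    NA_real_
  })

  structure(
    list(basal_glucose_ra = basal_glucose_ra,
         basal_glucose_rd = basal_glucose_ra,   # basal steady state
         clamp_glucose_ra = clamp_glucose_ra,
         clamp_glucose_rd = clamp_glucose_rd,
         basal_glycerol_ra = basal_glycerol_ra,
         clamp_glycerol_ra = clamp_glycerol_ra,
         windows_used = list(basal = bw, low = lw, high = hw),
         flags = unique(flags)),
    class = "kinetics_result"
  )
}

#' Glycerol rate of appearance over a window
#'
#' Same Steele form as glucose, with the glycerol tracer infusion and no
#' exogenous tracee. The glycerol tracer is stopped just before the
#' high-dose stage, so requesting a window beyond the stage-2 boundary is a
#' protocol error.
#'
#' @param series A [sample_series()].
#' @param protocol A [clamp_protocol()].
#' @param window `[a, b]` min; must end at or before the stage-2 boundary.
#' @param V Distribution volume ml/kg (defaults to the protocol fraction).
#' @param max_segments,degree Smoothing controls.
#' @return As [window_mean_rate()].
#' @export
glycerol_ra_window <- function(series, protocol, window,
                               V = protocol$distribution_volume_fraction * 1000,
                               max_segments = 4, degree = 2) {
  if (window[2] > protocol$stage_boundaries[["stage2_start"]]) {
    stop("glycerol tracer is stopped before stage 2; ",
         "only basal and low-dose windows are legal", call. = FALSE)
  }
  s <- series$samples
  ok_c <- !is.na(s$glycerol_umol_l)
  ok_z <- !is.na(s$glycerol_ttr)
  c_fit <- fit_optimal_segments(s$t[ok_c], s$glycerol_umol_l[ok_c],
                                max_segments = max_segments, degree = degree)
  z_fit <- fit_optimal_segments(s$t[ok_z], s$glycerol_ttr[ok_z],
                                max_segments = max_segments, degree = degree)
  tt <- protocol$sample_times[protocol$sample_times >= window[1] &
                                protocol$sample_times <= window[2]]
  cc <- evaluate_curve(c_fit, tt, side = "left")
  zz <- evaluate_curve(z_fit, tt, side = "left")
  f_gly <- mg_to_umol(protocol$glycerol_tracer_rate, "glycerol")
  # glycerol concentration arrives in umol/l -> umol/ml
  ra <- steele_total_ra(rep(f_gly, length(tt)), cc$value / 1000,
                        zz$deriv, zz$value, V, tt)
  window_mean_rate(ra, tt, window)
}

#' @export
print.kinetics_result <- function(x, ...) {
  cat("<kinetics_result> (umol kg-1 min-1)\n")
  cat(sprintf("  glucose Ra : basal %.2f, low-dose EGP %.2f\n",
              x$basal_glucose_ra, x$clamp_glucose_ra))
  cat(sprintf("  glucose Rd : basal %.2f, high-dose %.2f\n",
              x$basal_glucose_rd, x$clamp_glucose_rd))
  cat(sprintf("  glycerol Ra: basal %.2f, low-dose %.2f\n",
              x$basal_glycerol_ra, x$clamp_glycerol_ra))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}
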
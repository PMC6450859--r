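#' Whole-body insulin sensitivity (M value)
#'
#' M is the mean glucose infusion rate over the final 30 min of the
#' high-dose insulin stage, corrected for any change in the glucose pool:
#' M = mean(GIR) - (C_end - C_start) * v_space / dt, with the pool-change
#' term converted from mmol/l to mg kg-1 min-1. The correction volume
#' defaults to the tracer distribution volume (0.22 l/kg) for internal
#' consistency with the turnover equations; the classical 0.19 l/kg glucose
#' space is available via `v_space_l_kg`.
#'
#' @param series A [sample_series()].
#' @param window `[a, b]` min (default the final high-dose half hour,
#'   210-240).
#' @param v_space_l_kg Correction volume, litres per kg body weight.
#' @return M in mg kg-1 min-1.
#' @examples
#' # constant GIR of 4 with constant glucose gives M = 4
#' @export
m_value <- function(series, window = c(210, 240), v_space_l_kg = 0.22) {
  gluc <- samples_in_window(series, "glucose_mmol_l", window)
  if (nrow(gluc) < 2) stop("window not covered by glucose samples",
                           call. = FALSE)
  mean_gir <- gir_window_mean(series, window)      # mg kg-1 min-1
  dC <- gluc$y[nrow(gluc)] - gluc$y[1]             # mmol/l
  dt <- gluc$t[nrow(gluc)] - gluc$t[1]             # min
  # mmol/l * l/kg = mmol/kg; * 180.16 mg/mmol; per minute
  correction <- dC * v_space_l_kg * MOLAR_MASS[["glucose"]] / dt
  mean_gir - correction
}

#' M adjusted for prevailing insulin (M/I)
#'
#' @param m M value (mg kg-1 min-1).
#' @param series A [sample_series()].
#' @param window `[a, b]` min over which insulin is averaged.
#' @return M/I in mg kg-1 min-1 per pmol/l.
#' @export
m_over_i <- function(m, series, window = c(210, 240)) {
  ins <- samples_in_window(series, "insulin_pmol_l", window)
  if (nrow(ins) < 1) stop("no insulin samples in window", call. = FALSE)
  mi <- mean(ins$y)
  if (mi <= 0) stop("mean insulin must be positive", call. = FALSE)
  m / mi
}

#' Percentage change from basal to clamp
#'
#' 100 * (clamp - basal) / basal: positive for insulin-stimulated increase
#' (glucose Rd), negative for suppression (EGP, glycerol Ra). Undefined for
#' a zero basal denominator.
#'
#' @param basal,clamp Rates on the same scale.
#' @return Percentage (may be negative); `NA` with a warning when basal is
#'   zero or missing.
#' @examples
#' pct_change(10, 5)    # -50
#' pct_change(10, 30)   # +200
#' @export
pct_change <- function(basal, clamp) {
  out <- 100 * (clamp - basal) / basal
  zero <- !is.na(basal) & basal == 0
  if (any(zero)) {
    warning("pct_change undefined for zero basal value", call. = FALSE)
    out[zero] <- NA_real_
  }
  out
}

#' Trapezium-rule area under the curve
#'
#' Samples are sorted by time and missing values dropped, so an unmeasured
#' interior point simply widens the trapezoid that spans it.
#'
#' @param t Times (min).
#' @param y Concentrations.
#' @return AUC in concentration-units x min.
#' @examples
#' auc_trapezium(c(0, 60, 120), c(0, 10, 0))   # 600
#' @export
auc_trapezium <- function(t, y) {
  keep <- !is.na(t) & !is.na(y)
  t <- t[keep]; y <- y[keep]
  if (length(t) < 2) stop("AUC needs at least 2 non-missing points",
                          call. = FALSE)
  ord <- order(t)
  pracma::trapz(t[ord], y[ord])
}

#' Tissue-specific insulin sensitivity indices for one subject
#'
#' Combines the turnover results with the raw series into the derived
#' measures: M, M/I, percentage increase in glucose Rd (skeletal muscle),
#' percentage suppression of EGP (liver), percentage suppression of
#' glycerol Ra (adipose tissue), and trapezium AUCs of glucose, insulin and
#' NEFA over the clamp.
#'
#' @param series A [sample_series()].
#' @param kin A [subject_kinetics()] result.
#' @param protocol A [clamp_protocol()].
#' @param v_space_l_kg M-value correction volume (l/kg).
#' @param auc_window AUC window, default the clamp period `c(0, 240)`.
#' @return Object of class `sensitivity_indices`.
#' @export
subject_indices <- function(series, kin, protocol,
                            v_space_l_kg = protocol$distribution_volume_fraction,
                            auc_window = c(0, 240)) {
  m <- m_value(series, protocol$high_window, v_space_l_kg)
  mi <- m_over_i(m, series, protocol$high_window)
  s <- series$samples
  in_auc <- s$t >= auc_window[1] & s$t <= auc_window[2]
  auc_of <- function(ch) {
    v <- s[[ch]][in_auc]
    if (sum(!is.na(v)) < 2) return(NA_real_)
    auc_trapezium(s$t[in_auc], v)
  }
  structure(
    list(m_value = m,
         m_over_i = mi,
         pct_increase_rd = pct_change(kin$basal_glucose_rd,
                                      kin$clamp_glucose_rd),
         pct_supp_egp = pct_change(kin$basal_glucose_ra,
                                   kin$clamp_glucose_ra),
         pct_supp_glycerol_ra = pct_change(kin$basal_glycerol_ra,
                                           kin$clamp_glycerol_ra),
         auc_glucose = auc_of("glucose_mmol_l"),
         auc_insulin = auc_of("insulin_pmol_l"),
         auc_nefa = auc_of("nefa_mmol_l"),
         auc_window = auc_window),
    class = "sensitivity_indices"
  )
}

#' @export
print.sensitivity_indices <- function(x, ...) {
  cat("<sensitivity_indices>\n")
  cat(sprintf("  M %.2f mg/kg/min, M/I %.4f per pmol/l\n", x$m_value,
              x$m_over_i))
  cat(sprintf("  Rd increase %+.1f%%, EGP suppression %+.1f%%, glycerol Ra %+.1f%%\n",
              x$pct_increase_rd, x$pct_supp_egp, x$pct_supp_glycerol_ra))
  cat(sprintf("  AUC (%g-%g min): glucose %.0f, insulin %.0f, NEFA %.1f\n",
              x$auc_window[1], x$auc_window[2], x$auc_glucose,
              x$auc_insulin, x$auc_nefa))
  invisible(x)
}

#' Run kinetics + indices over a whole study
#'
#' @param dataset List with `subjects` and `series` as returned by
#'   [load_subject_dataset()] or [generate_cohort()].
#' @param protocol A [clamp_protocol()].
#' @param ... Passed to [subject_kinetics()].
#' @return Data frame, one row per subject, with the turnover rates and
#'   indices (columns mirror the clamp-study reporting layout).
#' @export
analyze_cohort <- function(dataset, protocol = clamp_protocol(), ...) {
  rows <- lapply(names(dataset$subjects), function(id) {
    subj <- dataset$subjects[[id]]
    ser <- dataset$series[[id]]
    kin <- subject_kinetics(ser, subj, protocol, ...)
    ind <- subject_indices(ser, kin, protocol)
    data.frame(id = id, group = subj$group,
               weight_kg = subj$weight_kg,
               vat_kg = subj$vat_kg, muscle_kg = subj$muscle_kg,
               basal_glucose_ra = kin$basal_glucose_ra,
               clamp_glucose_ra = kin$clamp_glucose_ra,
               basal_glucose_rd = kin$basal_glucose_rd,
               clamp_glucose_rd = kin$clamp_glucose_rd,
               basal_glycerol_ra = kin$basal_glycerol_ra,
               clamp_glycerol_ra = kin$clamp_glycerol_ra,
               m_value = ind$m_value, m_over_i = ind$m_over_i,
               pct_increase_rd = ind$pct_increase_rd,
               pct_supp_egp = ind$pct_supp_egp,
               pct_supp_glycerol_ra = ind$pct_supp_glycerol_ra,
               auc_glucose = ind$auc_glucose,
               auc_insulin = ind$auc_insulin,
               auc_nefa = ind$auc_nefa,
               flags = paste(kin$flags, collapse = ";"))
  })
  do.call(rbind, rows)
}
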
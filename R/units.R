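#' Molar masses used throughout the package
#'
#' Glucose 180.16 g/mol, glycerol 92.09 g/mol. Tracer and tracee are treated
#' with the same molar mass; the isotopic mass excess (<2 g/mol) is far below
#' every other uncertainty in the pipeline.
#' @keywords internal
MOLAR_MASS <- c(glucose = 180.16, glycerol = 92.09)

#' Convert a mass infusion rate to a molar rate
#'
#' Tracer pump settings are recorded in mg per kg body weight per minute;
#' Steele's equations and all reported turnover rates work in
#' umol kg-1 min-1.
#'
#' @param mg Mass (mg) or mass rate (mg/kg/min).
#' @param analyte `"glucose"` or `"glycerol"`.
#' @return The corresponding amount in umol (or umol/kg/min).
#' @examples
#' mg_to_umol(1, "glucose")    # 5.5506 umol per mg glucose
#' mg_to_umol(0.0067, "glycerol")
#' @export
mg_to_umol <- function(mg, analyte = c("glucose", "glycerol")) {
  analyte <- match.arg(analyte)
  mg * 1000 / MOLAR_MASS[[analyte]]
}

#' @rdname mg_to_umol
#' @param umol Amount in umol (or umol/kg/min).
#' @export
umol_to_mg <- function(umol, analyte = c("glucose", "glycerol")) {
  analyte <- match.arg(analyte)
  umol * MOLAR_MASS[[analyte]] / 1000
}

#' Unit-conversion context for one subject
#'
#' Bundles the distribution volume and mass/mole bridges needed by the
#' kinetic equations: V in ml per kg body weight (`v_frac` of body weight,
#' 1 kg ~ 1000 ml), and conversion factors between the concentration units
#' the channels arrive in and the umol kg-1 min-1 the rates are reported in.
#'
#' @param weight Body weight in kg (> 0).
#' @param v_frac Distribution volume as a fraction of body weight
#'   (default 0.22).
#' @return An object of class `conversion_context` with elements
#'   `weight`, `v_frac`, `V` (ml/kg) and the molar masses.
#' @examples
#' ctx <- conversion_context(90)
#' ctx$V  # 220 ml/kg
#' @export
conversion_context <- function(weight, v_frac = 0.22) {
  if (!is.numeric(weight) || length(weight) != 1L || !is.finite(weight) ||
      weight <= 0) {
    stop("`weight` must be a single positive number (kg)", call. = FALSE)
  }
  if (!is.numeric(v_frac) || v_frac <= 0 || v_frac >= 1) {
    stop("`v_frac` must lie in (0, 1)", call. = FALSE)
  }
  structure(
    list(weight = weight, v_frac = v_frac,
         V = v_frac * 1000,           # ml per kg body weight
         molar_mass = MOLAR_MASS),
    class = "conversion_context"
  )
}

#' @export
print.conversion_context <- function(x, ...) {
  cat(sprintf("conversion context: weight %.1f kg, V = %.0f ml/kg (%.0f%% BW)\n",
              x$weight, x$V, 100 * x$v_frac))
  invisible(x)
}
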
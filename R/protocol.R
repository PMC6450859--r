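#' Describe a two-stage clamp infusion protocol
#'
#' Holds every rate, timing and enrichment the kinetic calculations need.
#' The defaults reproduce the reference protocol: a primed (2.0 mg/kg),
#' continuous (0.02 mg kg-1 min-1) D2-glucose infusion and a primed
#' (0.12 mg/kg), continuous (0.0067 mg kg-1 min-1) D5-glycerol infusion
#' started at -120 min; insulin at 10 mU m-2 min-1 over 0-120 min (stage 1)
#' and 40 mU m-2 min-1 over 120-240 min (stage 2); 20% dextrose labelled at
#' 8 mg tracer per g glucose during stage 1 and 10 mg/g during stage 2;
#' glycaemic target 5 mmol/l; Steele distribution volume 22% of body weight.
#' Analysis windows: basal -30..0 min, low-dose 90..120 min, high-dose
#' 210..240 min.
#'
#' @param glucose_tracer_prime mg/kg priming bolus of labelled glucose.
#' @param glucose_tracer_rate mg kg-1 min-1 continuous labelled glucose.
#' @param glycerol_tracer_prime mg/kg priming bolus of labelled glycerol.
#' @param glycerol_tracer_rate mg kg-1 min-1 continuous labelled glycerol.
#' @param insulin_rate_low,insulin_rate_high mU m-2 BSA min-1 per stage.
#' @param stage_boundaries Named numeric: basal start, insulin start, stage-2
#'   start, end (min).
#' @param infusate_enrichment_low,infusate_enrichment_high mg tracer per g
#'   glucose in the dextrose infusate, per stage.
#' @param distribution_volume_fraction Steele volume as fraction of body
#'   weight (in (0,1)).
#' @param basal_window,low_window,high_window Two-element numeric analysis
#'   windows (min).
#' @param glycaemic_target mmol/l held by the variable dextrose infusion.
#' @param sample_times Scheduled sampling times (min).
#' @return Object of class `clamp_protocol`.
#' @examples
#' p <- clamp_protocol()
#' p$glucose_tracer_rate
#' @export
clamp_protocol <- function(glucose_tracer_prime = 2.0,
                           glucose_tracer_rate = 0.02,
                           glycerol_tracer_prime = 0.12,
                           glycerol_tracer_rate = 0.0067,
                           insulin_rate_low = 10,
                           insulin_rate_high = 40,
                           stage_boundaries = c(basal_start = -120,
                                                insulin_start = 0,
                                                stage2_start = 120,
                                                end = 240),
                           infusate_enrichment_low = 8,
                           infusate_enrichment_high = 10,
                           distribution_volume_fraction = 0.22,
                           basal_window = c(-30, 0),
                           low_window = c(90, 120),
                           high_window = c(210, 240),
                           glycaemic_target = 5,
                           sample_times = c(-30, -20, -10, 0, 30, 60, 90,
                                            100, 110, 120, 150, 180, 210,
                                            220, 230, 240)) {
  p <- list(glucose_tracer_prime = glucose_tracer_prime,
            glucose_tracer_rate = glucose_tracer_rate,
            glycerol_tracer_prime = glycerol_tracer_prime,
            glycerol_tracer_rate = glycerol_tracer_rate,
            insulin_rate_low = insulin_rate_low,
            insulin_rate_high = insulin_rate_high,
            stage_boundaries = stage_boundaries,
            infusate_enrichment_low = infusate_enrichment_low,
            infusate_enrichment_high = infusate_enrichment_high,
            distribution_volume_fraction = distribution_volume_fraction,
            basal_window = basal_window,
            low_window = low_window,
            high_window = high_window,
            glycaemic_target = glycaemic_target,
            sample_times = sort(sample_times))
  validate_protocol(p)
  structure(p, class = "clamp_protocol")
}

validate_protocol <- function(p) {
  vf <- p$distribution_volume_fraction
  if (!is.numeric(vf) || vf <= 0 || vf >= 1) {
    stop("distribution_volume_fraction must lie in (0, 1)", call. = FALSE)
  }
  rates <- c(p$glucose_tracer_prime, p$glucose_tracer_rate,
             p$glycerol_tracer_prime, p$glycerol_tracer_rate,
             p$insulin_rate_low, p$insulin_rate_high,
             p$infusate_enrichment_low, p$infusate_enrichment_high,
             p$glycaemic_target)
  if (any(!is.finite(rates)) || any(rates < 0)) {
    stop("protocol rates and enrichments must be finite and >= 0",
         call. = FALSE)
  }
  sb <- p$stage_boundaries
  if (length(sb) != 4 || any(diff(sb) <= 0)) {
    stop("stage_boundaries must be 4 increasing times", call. = FALSE)
  }
  win_in <- function(w, a, b) length(w) == 2 && w[1] < w[2] &&
    w[1] >= a && w[2] <= b
  if (!win_in(p$basal_window, sb[[1]], sb[[2]])) {
    stop("basal_window must lie within the basal stage", call. = FALSE)
  }
  if (!win_in(p$low_window, sb[[2]], sb[[3]])) {
    stop("low_window must lie within stage 1", call. = FALSE)
  }
  if (!win_in(p$high_window, sb[[3]], sb[[4]])) {
    stop("high_window must lie within stage 2", call. = FALSE)
  }
  invisible(p)
}

#' @export
print.clamp_protocol <- function(x, ...) {
  cat("<clamp_protocol>\n")
  cat(sprintf("  glucose tracer : prime %.2f mg/kg + %.4f mg/kg/min\n",
              x$glucose_tracer_prime, x$glucose_tracer_rate))
  cat(sprintf("  glycerol tracer: prime %.2f mg/kg + %.4f mg/kg/min (off at %g min)\n",
              x$glycerol_tracer_prime, x$glycerol_tracer_rate,
              x$stage_boundaries[["stage2_start"]]))
  cat(sprintf("  insulin        : %g / %g mU m-2 min-1 (stages %g-%g / %g-%g min)\n",
              x$insulin_rate_low, x$insulin_rate_high,
              x$stage_boundaries[["insulin_start"]],
              x$stage_boundaries[["stage2_start"]],
              x$stage_boundaries[["stage2_start"]],
              x$stage_boundaries[["end"]]))
  cat(sprintf("  infusate label : %g / %g mg tracer per g glucose\n",
              x$infusate_enrichment_low, x$infusate_enrichment_high))
  cat(sprintf("  Steele volume  : %.0f%% BW; target %g mmol/l\n",
              100 * x$distribution_volume_fraction, x$glycaemic_target))
  invisible(x)
}

#' Infusate tracer enrichment in effect at time t
#'
#' mg tracer per g glucose in the dextrose infusate: the low-stage value up
#' to the stage-2 boundary, the high-stage value after.
#' @param protocol A [clamp_protocol()].
#' @param t Time (min), vectorised.
#' @return mg tracer per g infused glucose at each `t`.
#' @export
infusate_enrichment_at <- function(protocol, t) {
  ifelse(t <= protocol$stage_boundaries[["stage2_start"]],
         protocol$infusate_enrichment_low,
         protocol$infusate_enrichment_high)
}

#' Read / write a clamp protocol as YAML
#'
#' @param path YAML file path.
#' @return `read_protocol()`: a [clamp_protocol()].
#' @export
read_protocol <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y), names(formals(clamp_protocol)))]
  for (nm in c("stage_boundaries", "basal_window", "low_window",
               "high_window", "sample_times")) {
    if (!is.null(args[[nm]])) args[[nm]] <- unlist(args[[nm]])
  }
  if (!is.null(args$stage_boundaries) &&
      is.null(names(args$stage_boundaries))) {
    names(args$stage_boundaries) <- c("basal_start", "insulin_start",
                                      "stage2_start", "end")
  }
  do.call(clamp_protocol, args)
}

#' @rdname read_protocol
#' @param protocol A [clamp_protocol()].
#' @export
write_protocol <- function(protocol, path) {
  yaml::write_yaml(lapply(unclass(protocol), function(v) {
    if (!is.null(names(v)) && length(v) > 1) as.list(v) else v
  }), path)
  invisible(path)
}
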
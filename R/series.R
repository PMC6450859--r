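#' Construct a per-subject clamp sample series
#'
#' Irregularly sampled measurement channels on a shared time axis, plus the
#' dextrose (glucose infusion rate, GIR) record. Measurement channels may
#' contain `NA` for samples that were not assayed; the GIR is a separate
#' step function because the bedside pump is adjusted on its own 5-min
#' schedule, with each recorded rate in effect from its time until the next
#' change (right-continuous).
#'
#' @param t Sample times (min, strictly increasing). t = 0 is insulin start.
#' @param glucose_mmol_l Plasma glucose (mmol/l).
#' @param insulin_pmol_l Serum insulin (pmol/l).
#' @param nefa_mmol_l Plasma NEFA (mmol/l).
#' @param glucose_ttr Glucose tracer-to-tracee ratio (dimensionless).
#' @param glycerol_umol_l Plasma glycerol (umol/l).
#' @param glycerol_ttr Glycerol TTR (absent after the glycerol tracer stops).
#' @param gir Data frame `t, rate_mg_kg_min` recording every pump change, or
#'   `NULL` when no dextrose was given.
#' @return Object of class `sample_series`: a list with a `samples` data
#'   frame and a `gir` step table.
#' @export
sample_series <- function(t, glucose_mmol_l = NA, insulin_pmol_l = NA,
                          nefa_mmol_l = NA, glucose_ttr = NA,
                          glycerol_umol_l = NA, glycerol_ttr = NA,
                          gir = NULL) {
  samples <- data.frame(t = t,
                        glucose_mmol_l = rep_len(glucose_mmol_l, length(t)),
                        insulin_pmol_l = rep_len(insulin_pmol_l, length(t)),
                        nefa_mmol_l = rep_len(nefa_mmol_l, length(t)),
                        glucose_ttr = rep_len(glucose_ttr, length(t)),
                        glycerol_umol_l = rep_len(glycerol_umol_l, length(t)),
                        glycerol_ttr = rep_len(glycerol_ttr, length(t)))
  if (is.null(gir)) gir <- data.frame(t = numeric(), rate_mg_kg_min = numeric())
  obj <- structure(list(samples = samples, gir = gir),
                   class = "sample_series")
  validate_series(obj)
}

series_channels <- c("glucose_mmol_l", "insulin_pmol_l", "nefa_mmol_l",
                     "glucose_ttr", "glycerol_umol_l", "glycerol_ttr")

validate_series <- function(x) {
  s <- x$samples
  if (anyNA(s$t) || any(!is.finite(s$t))) {
    stop("sample times must be finite", call. = FALSE)
  }
  d <- diff(s$t)
  if (any(d == 0)) {
    stop(sprintf("duplicate sample time at t = %g (rows %s)",
                 s$t[which(d == 0)[1]], which(d == 0)[1]), call. = FALSE)
  }
  if (any(d < 0)) {
    stop(sprintf("non-monotone sample times at row %d", which(d < 0)[1] + 1L),
         call. = FALSE)
  }
  for (ch in series_channels) {
    bad <- which(!is.na(s[[ch]]) & s[[ch]] < 0)
    if (length(bad)) {
      stop(sprintf("negative value in channel %s at row %d (t = %g)",
                   ch, bad[1], s$t[bad[1]]), call. = FALSE)
    }
  }
  g <- x$gir
  if (nrow(g)) {
    if (any(diff(g$t) <= 0)) stop("GIR record times must increase",
                                  call. = FALSE)
    if (any(g$rate_mg_kg_min < 0)) stop("GIR rates must be >= 0",
                                        call. = FALSE)
  }
  x
}

#' @export
print.sample_series <- function(x, ...) {
  s <- x$samples
  cat(sprintf("<sample_series> %d samples, t in [%g, %g] min, %d GIR records\n",
              nrow(s), min(s$t), max(s$t), nrow(x$gir)))
  n_obs <- vapply(s[series_channels], function(v) sum(!is.na(v)), 0L)
  cat("  observed:", paste(sprintf("%s=%d", names(n_obs), n_obs),
                           collapse = " "), "\n")
  invisible(x)
}

#' GIR step function lookups
#'
#' `gir_at()` returns the pump rate in effect at each time (0 before the
#' first recorded change); `gir_window_mean()` integrates the step function
#' exactly over a window and divides by its length. The last recorded rate
#' is held beyond the final change time.
#'
#' @param series A [sample_series()].
#' @param t Times (min), vectorised.
#' @param side `"right"` (default): the rate newly in effect at a change
#'   time; `"left"`: the rate in effect just before it. The left limit is
#'   what a sample drawn at a stage boundary experienced.
#' @return mg glucose kg-1 min-1.
#' @export
gir_at <- function(series, t, side = c("right", "left")) {
  side <- match.arg(side)
  g <- series$gir
  if (!nrow(g)) return(rep(0, length(t)))
  idx <- findInterval(t, g$t, left.open = (side == "left"))
  ifelse(idx == 0, 0, g$rate_mg_kg_min[pmax(idx, 1L)])
}

#' @rdname gir_at
#' @param window Two-element numeric `[a, b]` (min).
#' @export
gir_window_mean <- function(series, window) {
  a <- window[1]; b <- window[2]
  if (b <= a) stop("window must have positive length", call. = FALSE)
  g <- series$gir
  if (!nrow(g)) return(0)
  brk <- sort(unique(c(a, b, g$t[g$t > a & g$t < b])))
  lefts <- head(brk, -1L)
  rates <- gir_at(series, lefts)
  sum(rates * diff(brk)) / (b - a)
}

#' Extract non-missing samples of one channel inside a window
#'
#' @param series A [sample_series()].
#' @param channel Channel name (one of the series measurement columns).
#' @param window `[a, b]` in min (inclusive).
#' @return Data frame `t, y` of the observed samples.
#' @export
samples_in_window <- function(series, channel, window) {
  channel <- match.arg(channel, series_channels)
  s <- series$samples
  keep <- s$t >= window[1] & s$t <= window[2] & !is.na(s[[channel]])
  data.frame(t = s$t[keep], y = s[[channel]][keep])
}

series_csv_cols <- c("t_min", "glucose_mmol_l", "insulin_pmol_l",
                     "nefa_mmol_l", "glucose_ttr", "glycerol_umol_l",
                     "glycerol_ttr", "gir_mg_kg_min")

#' Read / write one subject's time series CSV
#'
#' One row per time point, columns `t_min, glucose_mmol_l, insulin_pmol_l,
#' nefa_mmol_l, glucose_ttr, glycerol_umol_l, glycerol_ttr, gir_mg_kg_min`;
#' empty cells are missing. Rows carrying only a `gir_mg_kg_min` value
#' record pump-rate changes between blood samples; rows with measurements
#' are blood samples. The two interleave on the same time axis.
#'
#' @param path CSV path.
#' @return `read_series()`: a [sample_series()].
#' @export
read_series <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  unknown <- setdiff(names(df), series_csv_cols)
  if (length(unknown)) {
    stop("unknown column(s) in series CSV: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (!"t_min" %in% names(df)) stop("series CSV needs a t_min column",
                                    call. = FALSE)
  for (col in setdiff(series_csv_cols, names(df))) df[[col]] <- NA_real_
  df <- df[order(df$t_min), , drop = FALSE]
  meas <- df[rowSums(!is.na(df[series_csv_cols[2:7]])) > 0, , drop = FALSE]
  girr <- df[!is.na(df$gir_mg_kg_min), c("t_min", "gir_mg_kg_min")]
  sample_series(t = meas$t_min,
                glucose_mmol_l = meas$glucose_mmol_l,
                insulin_pmol_l = meas$insulin_pmol_l,
                nefa_mmol_l = meas$nefa_mmol_l,
                glucose_ttr = meas$glucose_ttr,
                glycerol_umol_l = meas$glycerol_umol_l,
                glycerol_ttr = meas$glycerol_ttr,
                gir = data.frame(t = girr$t_min,
                                 rate_mg_kg_min = girr$gir_mg_kg_min))
}

#' @rdname read_series
#' @param series A [sample_series()].
#' @export
write_series <- function(series, path) {
  s <- series$samples
  out <- data.frame(t_min = s$t, glucose_mmol_l = s$glucose_mmol_l,
                    insulin_pmol_l = s$insulin_pmol_l,
                    nefa_mmol_l = s$nefa_mmol_l,
                    glucose_ttr = s$glucose_ttr,
                    glycerol_umol_l = s$glycerol_umol_l,
                    glycerol_ttr = s$glycerol_ttr,
                    gir_mg_kg_min = NA_real_)
  g <- series$gir
  if (nrow(g)) {
    hit <- match(g$t, out$t_min)
    new <- is.na(hit)
    if (any(!new)) out$gir_mg_kg_min[hit[!new]] <- g$rate_mg_kg_min[!new]
    if (any(new)) {
      extra <- out[rep_len(NA_integer_, sum(new)), ]
      extra[] <- NA_real_
      extra$t_min <- g$t[new]
      extra$gir_mg_kg_min <- g$rate_mg_kg_min[new]
      out <- rbind(out, extra)
    }
    out <- out[order(out$t_min), ]
  }
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Load a whole study: subject table + per-subject series
#'
#' @param subjects_csv Path to the subject table (see [read_subjects()]).
#' @param series_dir Directory containing `<id>.csv` per subject.
#' @param protocol A [clamp_protocol()] used for validation (basal-window
#'   coverage warnings).
#' @return List with elements `subjects` (list of [subject()]), `series`
#'   (named list of [sample_series()]) and `warnings` (character).
#' @export
load_subject_dataset <- function(subjects_csv, series_dir, protocol) {
  subs <- read_subjects(subjects_csv)
  warnings <- character()
  series <- lapply(subs, function(s) {
    f <- file.path(series_dir, paste0(s$id, ".csv"))
    if (!file.exists(f)) stop("missing series file for subject ", s$id,
                              call. = FALSE)
    ser <- read_series(f)
    for (ch in c("glucose_mmol_l", "glucose_ttr")) {
      n_basal <- nrow(samples_in_window(ser, ch, protocol$basal_window))
      if (n_basal < 2) {
        warnings <<- c(warnings, sprintf(
          "subject %s: only %d basal %s samples", s$id, n_basal, ch))
      }
    }
    ser
  })
  list(subjects = subs, series = series, warnings = warnings)
}
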
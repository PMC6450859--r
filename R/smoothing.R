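#' Optimal-segments smoothing of clamp time courses
#'
#' Non-steady-state turnover calculations need smooth concentration and
#' enrichment curves with first derivatives. Tracer studies traditionally
#' smooth each channel with an "optimal segments" procedure: a piecewise
#' low-order polynomial whose breakpoints are chosen to minimise a penalised
#' weighted residual sum of squares. This implementation restricts
#' breakpoints to observed sample times, enforces continuity of the fitted
#' curve (the first derivative may jump at a breakpoint; the right-hand
#' derivative is reported there), and selects the number and position of
#' breakpoints by exhaustive search over all candidate sets, scored by a
#' small-sample information criterion (AICc by default; BIC available) on
#' the weighted RSS. The search is deterministic: ties favour fewer
#' segments, then the lexicographically first breakpoint set.
#'
#' When the sampled process is known to change regime at protocol times
#' (e.g. an insulin dose step), `required_spans` forces the accepted
#' breakpoint set to place at least one breakpoint inside each given
#' interval, so no single polynomial is asked to straddle a known
#' physiological transition.
#'
#' @param t Sample times (min), strictly increasing after removal of
#'   missing values.
#' @param y Observed values; pairs with `NA` in either vector are dropped.
#' @param weights Optional non-negative weights (default uniform);
#'   use 1/variance when the measurement noise model is known.
#' @param max_segments Maximum number of polynomial segments (default 4,
#'   sized for a 16-point clamp series).
#' @param degree Polynomial degree per segment, 1 (linear) or 2 (quadratic,
#'   default).
#' @param penalty `"aicc"` (default) or `"bic"`.
#' @param required_spans Optional list of closed intervals `c(a, b)`; each
#'   must contain at least one breakpoint.
#' @return Object of class `smoothed_curve` with fields `knots`,
#'   `coefficients`, `degree`, `range`, `residual_sd`, `fitted`, `data`,
#'   and `rss_by_knots` (the minimised weighted SSE per breakpoint count
#'   explored, ignoring `required_spans`).
#' @examples
#' t <- c(-30, -20, -10, 0, 30, 60, 90, 100, 110, 120)
#' fit <- fit_optimal_segments(t, 5 + 0.01 * t)
#' evaluate_curve(fit, 45)   # value and slope at 45 min
#' @export
fit_optimal_segments <- function(t, y, weights = NULL, max_segments = 4,
                                 degree = 2, penalty = c("aicc", "bic"),
                                 required_spans = NULL) {
  penalty <- match.arg(penalty)
  if (!degree %in% 1:2) stop("`degree` must be 1 or 2", call. = FALSE)
  keep <- !is.na(t) & !is.na(y)
  t <- t[keep]; y <- y[keep]
  w <- if (is.null(weights)) rep(1, length(t)) else weights[keep]
  ord <- order(t)
  t <- t[ord]; y <- y[ord]; w <- w[ord]
  n <- length(t)
  if (n < 4) stop("need at least 4 non-missing points to smooth",
                  call. = FALSE)
  if (any(diff(t) == 0)) stop("duplicate times in smoothing input",
                              call. = FALSE)
  if (diff(range(t)) == 0) stop("degenerate time axis", call. = FALSE)
  if (any(w < 0)) stop("weights must be >= 0", call. = FALSE)

  candidates <- t[seq(2L, n - 1L)]
  max_knots <- max(0L, min(max_segments - 1L, length(candidates)))

  # RSS floor so exact fits compare by parameter count, not log(0)
  rss_floor <- max(1e-20 * sum(w * y^2), 1e-300)
  best <- NULL
  rss_by_knots <- rep(NA_real_, max_knots + 1L)
  spans_ok <- function(knots) {
    is.null(required_spans) ||
      all(vapply(required_spans, function(sp) {
        any(knots >= sp[1] & knots <= sp[2])
      }, TRUE))
  }
  for (k in 0:max_knots) {
    sets <- if (k == 0) list(numeric(0)) else
      apply(utils::combn(length(candidates), k), 2,
            function(ix) candidates[ix], simplify = FALSE)
    for (knots in sets) {
      # every segment must hold enough points for its polynomial
      edges <- c(t[1], knots, t[n])
      counts <- vapply(seq_len(length(edges) - 1L), function(i) {
        sum(t >= edges[i] & t <= edges[i + 1L])
      }, 0L)
      if (any(counts < degree + 1L)) next
      X <- seg_basis(t, knots, degree)
      fit <- stats::lm.wfit(X, y, w)
      rss <- sum(w * fit$residuals^2)
      p <- ncol(X)
      if (is.na(rss_by_knots[k + 1L]) || rss < rss_by_knots[k + 1L]) {
        rss_by_knots[k + 1L] <- rss
      }
      if (!spans_ok(knots)) next
      pen <- if (penalty == "bic") p * log(n) else
        2 * p + 2 * p * (p + 1) / max(n - p - 1, 1)
      score <- n * log(max(rss, rss_floor) / n) + pen
      if (is.null(best) || score < best$score - 1e-12) {
        best <- list(score = score, knots = knots, coef = fit$coefficients,
                     rss = rss, p = p)
      }
    }
  }
  if (is.null(best)) stop("no admissible segmentation found", call. = FALSE)
  df_res <- max(n - best$p, 1L)
  fitted <- drop(seg_basis(t, best$knots, degree) %*% best$coef)
  structure(
    list(knots = best$knots, coefficients = unname(best$coef),
         degree = degree, range = range(t),
         residual_sd = sqrt(best$rss / df_res),
         rss = best$rss, rss_by_knots = rss_by_knots, fitted = fitted,
         data = data.frame(t = t, y = y, w = w)),
    class = "smoothed_curve"
  )
}

# C0 truncated-power basis: 1, t, ..., t^degree, then (t - k)_+^1..degree
# per interior knot. Derivative discontinuities are allowed at the knots.
seg_basis <- function(t, knots, degree) {
  cols <- lapply(0:degree, function(d) t^d)
  for (k in knots) {
    tp <- pmax(t - k, 0)
    for (d in 1:degree) cols <- c(cols, list(tp^d))
  }
  do.call(cbind, cols)
}

seg_basis_deriv <- function(t, knots, degree, side = "right") {
  cols <- lapply(0:degree, function(d) if (d == 0) rep(0, length(t))
                 else d * t^(d - 1))
  for (k in knots) {
    # at a breakpoint the derivative may jump; pick which segment's slope
    # to report there
    on <- if (side == "right") as.numeric(t >= k) else as.numeric(t > k)
    tp <- pmax(t - k, 0)
    for (d in 1:degree) cols <- c(cols, list(d * tp^(d - 1) * on))
  }
  do.call(cbind, cols)
}

#' Evaluate a smoothed curve and its first derivative
#'
#' Evaluation is only defined on the fitted time range; requests outside it
#' are an error (the segments carry no extrapolation guarantee). At an
#' interior breakpoint the right-hand derivative is returned.
#'
#' @param curve A [fit_optimal_segments()] result.
#' @param t Times (min), vectorised.
#' @param side Derivative convention at an interior breakpoint: `"right"`
#'   (default) or `"left"`. Use `"left"` when the evaluation time is the
#'   end of an analysis window that abuts a protocol stage change, so the
#'   slope belongs to the stage being analysed.
#' @return List with numeric vectors `value` and `deriv`.
#' @export
evaluate_curve <- function(curve, t, side = c("right", "left")) {
  side <- match.arg(side)
  r <- curve$range
  tol <- 1e-8 * max(1, diff(r))
  if (any(t < r[1] - tol | t > r[2] + tol)) {
    stop(sprintf("evaluation time outside fitted range [%g, %g]",
                 r[1], r[2]), call. = FALSE)
  }
  t <- pmin(pmax(t, r[1]), r[2])
  list(value = drop(seg_basis(t, curve$knots, curve$degree) %*%
                      curve$coefficients),
       deriv = drop(seg_basis_deriv(t, curve$knots, curve$degree, side) %*%
                      curve$coefficients))
}

#' @export
print.smoothed_curve <- function(x, ...) {
  cat(sprintf("<smoothed_curve> degree %d, %d segment(s) on [%g, %g], residual SD %.4g\n",
              x$degree, length(x$knots) + 1L, x$range[1], x$range[2],
              x$residual_sd))
  if (length(x$knots)) cat("  breakpoints at:", paste(x$knots, collapse = ", "), "\n")
  invisible(x)
}

#' @export
predict.smoothed_curve <- function(object, newdata = NULL, ...) {
  tt <- if (is.null(newdata)) object$data$t else newdata
  evaluate_curve(object, tt)$value
}
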
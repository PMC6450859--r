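#' Decide the analysis route for a variable
#'
#' Shapiro-Wilk at `alpha` per group: `"normal"` when both groups pass on
#' the raw scale; otherwise `"lognormal"` when all values are positive and
#' both groups pass after log10 transformation; otherwise
#' `"nonparametric"`. A lognormal candidate containing non-positive values
#' falls through to nonparametric with a warning.
#'
#' @param a,b Numeric vectors (>= 3 values each).
#' @param alpha Shapiro-Wilk significance level (default 0.05).
#' @return List `route` plus the Shapiro-Wilk p-values that produced it.
#' @export
route_variable <- function(a, b, alpha = 0.05) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 3 || length(b) < 3) {
    stop("need >= 3 values per group to assess normality", call. = FALSE)
  }
  sw <- c(a = stats::shapiro.test(a)$p.value,
          b = stats::shapiro.test(b)$p.value)
  if (all(sw >= alpha)) {
    return(list(route = "normal", shapiro_raw = sw, shapiro_log = NULL))
  }
  if (any(c(a, b) <= 0)) {
    warning("non-positive values: log transform skipped, ",
            "routing nonparametric", call. = FALSE)
    return(list(route = "nonparametric", shapiro_raw = sw,
                shapiro_log = NULL))
  }
  swl <- c(a = stats::shapiro.test(log10(a))$p.value,
           b = stats::shapiro.test(log10(b))$p.value)
  if (all(swl >= alpha)) {
    return(list(route = "lognormal", shapiro_raw = sw, shapiro_log = swl))
  }
  list(route = "nonparametric", shapiro_raw = sw, shapiro_log = swl)
}

#' Pooled-variance t mean difference with 95% CI
#'
#' Independent-samples Student's t (pooled variance, not Welch). The
#' contrast is ordered `a - b`.
#'
#' @param a,b Numeric vectors (n >= 2 each).
#' @param conf Confidence level (default 0.95).
#' @return List `estimate`, `ci` (length 2), `p`, `df`, `test`.
#' @export
mean_difference_ci <- function(a, b, conf = 0.95) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) {
    stop("need >= 2 values per group", call. = FALSE)
  }
  tt <- stats::t.test(a, b, var.equal = TRUE, conf.level = conf)
  ci <- tt$conf.int
  attributes(ci) <- NULL
  list(estimate = unname(tt$estimate[1] - tt$estimate[2]),
       ci = ci, p = tt$p.value,
       df = unname(tt$parameter), test = "student_t")
}

#' Pooled-t mean difference from printed group summaries
#'
#' Closed-form pooled-variance t contrast from (n, mean, SD) per group,
#' for re-deriving published contrasts when only summary statistics are
#' available.
#'
#' @param n1,m1,s1 Group A size, mean, SD.
#' @param n2,m2,s2 Group B size, mean, SD.
#' @param conf Confidence level.
#' @return As [mean_difference_ci()].
#' @export
summary_mean_difference_ci <- function(n1, m1, s1, n2, m2, s2,
                                       conf = 0.95) {
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  diff <- m1 - m2
  tcrit <- stats::qt(1 - (1 - conf) / 2, df)
  tstat <- diff / se
  list(estimate = diff, ci = c(diff - tcrit * se, diff + tcrit * se),
       p = 2 * stats::pt(-abs(tstat), df), df = df, test = "student_t")
}

#' Geometric-mean ratio with 95% CI
#'
#' Pooled t-interval on log10 values, back-transformed: ratio of geometric
#' means ordered `a / b`.
#'
#' @param a,b Positive numeric vectors.
#' @param conf Confidence level.
#' @return List `estimate` (ratio), `ci`, `p`, `geomean_a`, `geomean_b`,
#'   `test`.
#' @export
geometric_ratio_ci <- function(a, b, conf = 0.95) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (any(c(a, b) <= 0)) {
    stop("geometric ratio requires strictly positive values", call. = FALSE)
  }
  res <- mean_difference_ci(log10(a), log10(b), conf)
  list(estimate = 10^res$estimate, ci = 10^res$ci, p = res$p,
       geomean_a = 10^mean(log10(a)), geomean_b = 10^mean(log10(b)),
       test = "student_t_log10")
}

#' Mann-Whitney U test
#'
#' Two-sided; exact for small samples without ties, normal approximation
#' with continuity and tie correction otherwise (via [stats::wilcox.test()]).
#'
#' @param a,b Numeric vectors.
#' @return List `p`, `U`, `test`.
#' @export
mann_whitney <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (!length(a) || !length(b)) stop("empty group", call. = FALSE)
  wt <- suppressWarnings(stats::wilcox.test(a, b))
  list(p = wt$p.value, U = unname(wt$statistic), test = "mann_whitney")
}

#' Pearson correlation with t-based p-value
#'
#' @param x,y Numeric vectors, n >= 3, pairwise complete.
#' @return List `r`, `p`, `n`; `r = NA` with a warning when either input
#'   has zero variance.
#' @export
pearson_r <- function(x, y) {
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need >= 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance: correlation undefined", call. = FALSE)
    return(list(r = NA_real_, p = NA_real_, n = length(x)))
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Group effect adjusted for covariates
#'
#' Least-squares coefficient on the group indicator in
#' `outcome ~ group + covariates`, with t-based 95% CI. Complete-case
#' analysis; the indicator codes the first group level as 1, so the
#' contrast is first-level minus second-level.
#'
#' @param outcome Numeric outcome.
#' @param group Factor or character with exactly 2 levels.
#' @param covariates Data frame of numeric covariates.
#' @return List `estimate`, `ci`, `p`, `n`.
#' @export
adjusted_group_effect <- function(outcome, group, covariates) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) != 2) {
    stop("group must have exactly 2 levels", call. = FALSE)
  }
  covariates <- as.data.frame(covariates)
  dat <- data.frame(.y = outcome,
                    .g = as.numeric(group == levels(group)[1]),
                    covariates)
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  X <- stats::model.matrix(~ ., data = dat[, -1, drop = FALSE])
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("covariate matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  fit <- stats::lm(.y ~ ., data = dat)
  sm <- summary(fit)$coefficients[".g", ]
  tcrit <- stats::qt(0.975, fit$df.residual)
  list(estimate = unname(sm["Estimate"]),
       ci = unname(sm["Estimate"] + c(-1, 1) * tcrit * sm["Std. Error"]),
       p = unname(sm["Pr(>|t|)"]), n = nrow(dat))
}

#' Group-by-predictor interaction test
#'
#' p-value of the product term in
#' `outcome ~ predictor + group + predictor:group`, asking whether the
#' association differs between groups.
#'
#' @param outcome,predictor Numeric vectors.
#' @param group Two-level factor or character.
#' @return List `p_interaction`, `slopes` (per-group least-squares slopes),
#'   `n`.
#' @export
interaction_test <- function(outcome, predictor, group) {
  group <- droplevels(as.factor(group))
  if (nlevels(group) != 2) stop("need both groups represented",
                                call. = FALSE)
  dat <- data.frame(y = outcome, x = predictor, g = group)
  dat <- dat[stats::complete.cases(dat), ]
  if (!all(levels(group) %in% unique(dat$g))) {
    stop("need both groups represented after removing missing values",
         call. = FALSE)
  }
  fit <- stats::lm(y ~ x * g, data = dat)
  cf <- summary(fit)$coefficients
  inter_row <- grep(":", rownames(cf))
  slopes <- vapply(levels(group), function(l) {
    unname(stats::coef(stats::lm(y ~ x, data = dat[dat$g == l, ]))["x"])
  }, 0)
  list(p_interaction = unname(cf[inter_row, "Pr(>|t|)"]),
       slopes = slopes, n = nrow(dat))
}

#' Route-then-test comparison of one variable between two groups
#'
#' The full published procedure: Shapiro-Wilk routing, then Student's
#' pooled t (mean difference) on the normal route, pooled t on log10
#' values (geometric-mean ratio) on the lognormal route, or Mann-Whitney
#' (median difference reported descriptively) on the nonparametric route.
#'
#' @param a,b Numeric vectors; the contrast is `a - b` or `a / b`.
#' @param variable Label carried into the output.
#' @param alpha Shapiro-Wilk level for routing.
#' @return One-row data frame: variable, route, n per group, group
#'   summaries (formatted), contrast type, estimate, CI, p, test.
#' @export
compare_groups <- function(a, b, variable = "variable", alpha = 0.05) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  routing <- route_variable(a, b, alpha)
  route <- routing$route
  if (route == "normal") {
    res <- mean_difference_ci(a, b)
    sum_a <- sprintf("%.3g (%.3g)", mean(a), stats::sd(a))
    sum_b <- sprintf("%.3g (%.3g)", mean(b), stats::sd(b))
    contrast <- "mean_difference"
  } else if (route == "lognormal") {
    res <- geometric_ratio_ci(a, b)
    gci <- function(x) {
      l <- log10(x); m <- mean(l)
      hw <- stats::qt(0.975, length(x) - 1) * stats::sd(l) / sqrt(length(x))
      sprintf("%.3g (%.3g, %.3g)", 10^m, 10^(m - hw), 10^(m + hw))
    }
    sum_a <- gci(a); sum_b <- gci(b)
    contrast <- "geometric_mean_ratio"
  } else {
    res <- mann_whitney(a, b)
    res$estimate <- stats::median(a) - stats::median(b)
    res$ci <- c(NA_real_, NA_real_)
    iqr <- function(x) sprintf("%.3g (%.3g, %.3g)", stats::median(x),
                               stats::quantile(x, 0.25),
                               stats::quantile(x, 0.75))
    sum_a <- iqr(a); sum_b <- iqr(b)
    contrast <- "median_difference"
  }
  data.frame(variable = variable, route = route,
             n_a = length(a), n_b = length(b),
             summary_a = sum_a, summary_b = sum_b,
             contrast = contrast, estimate = res$estimate,
             ci_lo = res$ci[1], ci_hi = res$ci[2], p = res$p,
             test = res$test,
             shapiro_a = routing$shapiro_raw[["a"]],
             shapiro_b = routing$shapiro_raw[["b"]])
}

#' Compare every requested variable between the two study groups
#'
#' @param results Per-subject results data frame (as from
#'   [analyze_cohort()]) with a `group` column.
#' @param variables Columns to contrast (default: the standard turnover and
#'   index columns present in `results`).
#' @param group_col Name of the group column; the first level (or `"BAM"`
#'   if present) is the `a` side of every contrast.
#' @return Data frame, one row per variable (see [compare_groups()]).
#' @export
compare_cohort <- function(results, variables = NULL, group_col = "group") {
  g <- results[[group_col]]
  levels_ <- if ("BAM" %in% g) c("BAM", setdiff(unique(g), "BAM")) else
    unique(g)
  if (length(levels_) != 2) stop("need exactly 2 groups", call. = FALSE)
  if (is.null(variables)) {
    std <- c("basal_glucose_ra", "clamp_glucose_ra", "clamp_glucose_rd",
             "basal_glycerol_ra", "clamp_glycerol_ra", "m_value",
             "m_over_i", "pct_increase_rd", "pct_supp_egp",
             "pct_supp_glycerol_ra", "auc_glucose", "auc_insulin",
             "auc_nefa")
    variables <- intersect(std, names(results))
  }
  do.call(rbind, lapply(variables, function(v) {
    compare_groups(results[[v]][g == levels_[1]],
                   results[[v]][g == levels_[2]], variable = v)
  }))
}
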
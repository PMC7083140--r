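#' Univariate linear regression with F-test against the constant model
#'
#' Ordinary least squares of `y` on `x`, reporting the coefficient of
#' determination, the F-statistic of the fit against the intercept-only
#' model with its p-value, and pointwise 95% confidence bands for the
#' mean response.
#'
#' @param x predictor (not constant).
#' @param y response.
#' @param with_intercept include an intercept (default).
#' @return An object of class `regression_fit` with `coefficients`
#'   (data.frame: term, estimate, se), `r2`, `f_stat`, `p_value`, `rss`,
#'   `n`, and the underlying `lm` model.
#' @export
linear_fit <- function(x, y, with_intercept = TRUE) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete observations")
  if (diff(range(x)) == 0) stop("degenerate design: x is constant")
  dat <- data.frame(x = x, y = y)
  fit <- if (with_intercept) lm(y ~ x, data = dat)
         else lm(y ~ x + 0, data = dat)
  sm <- summary(fit)
  cf <- data.frame(term = rownames(sm$coefficients),
                   estimate = sm$coefficients[, 1],
                   se = sm$coefficients[, 2], row.names = NULL)
  rss <- sum(fit$residuals^2)
  if (is.null(sm$fstatistic)) {            # perfect fit edge case
    fs <- Inf; pv <- 0
  } else {
    fs <- unname(sm$fstatistic[1])
    pv <- pf(fs, sm$fstatistic[2], sm$fstatistic[3], lower.tail = FALSE)
  }
  if (rss == 0) { fs <- Inf; pv <- 0 }
  # zero-slope edge: F = 0, p = 1 exactly
  slope <- unname(coef(fit)[if (with_intercept) 2L else 1L])
  if (!is.na(slope) && slope == 0) { fs <- 0; pv <- 1 }
  structure(list(coefficients = cf, r2 = sm$r.squared, f_stat = fs,
                 p_value = pv, rss = rss, n = n,
                 with_intercept = with_intercept,
                 r2_type = if (with_intercept) "centered" else
                   "uncentered (no-intercept convention)",
                 model = fit),
            class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("regression_fit (n = %d): R2 = %.3f (%s), F = %.3g, p = %.3g\n",
              x$n, x$r2, x$r2_type, x$f_stat, x$p_value))
  print(x$coefficients, row.names = FALSE)
  invisible(x)
}

#' Pointwise confidence band for the mean response
#'
#' @param fit a [linear_fit()] (or [interaction_fit()]) result.
#' @param newdata data.frame of predictor values (column `x` for
#'   univariate fits).
#' @param level confidence level.
#' @return data.frame with `fit`, `lwr`, `upr`.
#' @export
confidence_band <- function(fit, newdata, level = 0.95) {
  stopifnot(inherits(fit, "regression_fit"))
  as.data.frame(predict(fit$model, newdata = newdata,
                        interval = "confidence", level = level))
}

#' No-intercept interaction model of relaxation time
#'
#' Least-squares fit of `TTR = b1 * dTT + b2 * (NCX1 * dTT)` without an
#' intercept, reported both as raw coefficients `(b1, b2)` and in the
#' factored form `TTR = b1 * (dTT - ratio * NCX1 * dTT)` with
#' `ratio = -b2 / b1`.  R-squared follows the uncentered (no-intercept)
#' convention.
#'
#' @param delta_tt t-tubule distance (um).
#' @param ncx1 NCX1 expression level (normalized).
#' @param ttr time to relaxation (s).
#' @return A `regression_fit` with extra fields `b1`, `b2`,
#'   `interaction_ratio`.
#' @export
interaction_fit <- function(delta_tt, ncx1, ttr) {
  stopifnot(length(delta_tt) == length(ncx1),
            length(delta_tt) == length(ttr))
  ok <- is.finite(delta_tt) & is.finite(ncx1) & is.finite(ttr)
  dat <- data.frame(dtt = delta_tt[ok], inter = (ncx1 * delta_tt)[ok],
                    ttr = ttr[ok])
  n <- nrow(dat)
  if (n < 4L) stop("need at least 4 complete observations")
  if (all(dat$dtt == 0)) stop("degenerate design: delta_tt is all zero")
  collin <- all(dat$inter == 0) ||
    (sd(dat$inter) > 0 && sd(dat$dtt) > 0 &&
     abs(cor(dat$dtt, dat$inter)) > 1 - 1e-12)
  if (collin && !all(dat$inter == 0))
    stop("degenerate design: predictors are collinear")
  fit <- if (all(dat$inter == 0)) lm(ttr ~ dtt + 0, data = dat)
         else lm(ttr ~ dtt + inter + 0, data = dat)
  sm <- summary(fit)
  cf <- data.frame(term = rownames(sm$coefficients),
                   estimate = sm$coefficients[, 1],
                   se = sm$coefficients[, 2], row.names = NULL)
  b1 <- unname(coef(fit)["dtt"])
  b2 <- if ("inter" %in% names(coef(fit))) unname(coef(fit)["inter"])
        else 0
  structure(list(coefficients = cf, r2 = sm$r.squared,
                 f_stat = if (is.null(sm$fstatistic)) Inf
                          else unname(sm$fstatistic[1]),
                 p_value = if (is.null(sm$fstatistic)) 0
                           else pf(sm$fstatistic[1], sm$fstatistic[2],
                                   sm$fstatistic[3], lower.tail = FALSE),
                 rss = sum(fit$residuals^2), n = n,
                 with_intercept = FALSE,
                 r2_type = "uncentered (no-intercept convention)",
                 b1 = b1, b2 = b2,
                 interaction_ratio = -b2 / b1,
                 model = fit),
            class = "regression_fit")
}

#' Likelihood-ratio test of nested least-squares models
#'
#' Gaussian-errors closed form: the statistic is
#' `n * log(RSS_reduced / RSS_full)`, referred to a chi-square
#' distribution with as many degrees of freedom as the difference in
#' coefficient count.
#'
#' @param full,reduced `regression_fit` objects on the same data, the
#'   reduced model nested in the full one.
#' @return List with `statistic`, `df`, `p_value`.
#' @export
likelihood_ratio_test <- function(full, reduced) {
  stopifnot(inherits(full, "regression_fit"),
            inherits(reduced, "regression_fit"))
  if (full$n != reduced$n)
    stop("models were fitted to different numbers of observations")
  df <- nrow(full$coefficients) - nrow(reduced$coefficients)
  if (df < 0) stop("the reduced model is not nested in the full model")
  if (full$rss > reduced$rss * (1 + 1e-10))
    stop("internal inconsistency: the full model fits worse than the ",
         "reduced model; the models are not nested least-squares fits")
  stat <- full$n * log(max(reduced$rss, .Machine$double.xmin) /
                       max(full$rss, .Machine$double.xmin))
  stat <- max(stat, 0)
  if (df == 0L)
    return(list(statistic = stat, df = 0L, p_value = 1))
  list(statistic = stat, df = df,
       p_value = pchisq(stat, df, lower.tail = FALSE))
}

#' Unpaired two-tailed t-test
#'
#' Classic equal-variance Student form by default (Welch available).
#' Two groups with zero pooled variance compare as `p = 1` when their
#' means are equal.
#'
#' @param group_a,group_b numeric vectors, each of length at least 2.
#' @param var_equal pooled-variance Student test (default) or Welch.
#' @return List with `statistic`, `df`, `p_value`.
#' @export
t_test_unpaired <- function(group_a, group_b, var_equal = TRUE) {
  group_a <- group_a[is.finite(group_a)]
  group_b <- group_b[is.finite(group_b)]
  if (length(group_a) < 2L || length(group_b) < 2L)
    stop("each group needs at least 2 observations")
  if (sd(group_a) == 0 && sd(group_b) == 0) {
    if (mean(group_a) == mean(group_b))
      return(list(statistic = 0, df = length(group_a) +
                    length(group_b) - 2L, p_value = 1))
    return(list(statistic = Inf, df = length(group_a) +
                  length(group_b) - 2L, p_value = 0))
  }
  tt <- t.test(group_a, group_b, var.equal = var_equal)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value)
}

#' Holm-Bonferroni step-down adjustment
#'
#' @param p_values numeric vector of raw p-values in \[0, 1\].
#' @return Adjusted p-values in the original order.
#' @export
holm_bonferroni <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p_values, method = "holm")
}

#' Dichotomize samples by t-tubule distance
#'
#' Splits records at the t-system remodeling threshold; the boundary
#' value belongs to the high (severe-loss) group.
#'
#' @param records data.frame with a `delta_tt_um` column (or a numeric
#'   vector).
#' @param threshold_um dichotomization threshold (um), default 1.05.
#' @return List with elements `low` (`dTT < threshold`) and `high`
#'   (`dTT >= threshold`).
#' @export
dichotomize_by_dtt <- function(records, threshold_um = 1.05) {
  vals <- if (is.data.frame(records)) records$delta_tt_um
          else as.numeric(records)
  if (anyNA(vals)) stop("delta_tt_um must be defined for every record")
  hi <- vals >= threshold_um
  if (is.data.frame(records))
    list(low = records[!hi, , drop = FALSE],
         high = records[hi, , drop = FALSE])
  else list(low = vals[!hi], high = vals[hi])
}

#' Densitometry normalization
#'
#' Band intensity divided by the geometric mean of the Ponceau and GAPDH
#' loading signals, then by the same-way-normalized inter-gel reference.
#'
#' @param raw band intensity.
#' @param ponceau,gapdh loading-control intensities for the same lane.
#' @param reference the reference lane's Ponceau/GAPDH-normalized
#'   intensity (use [normalize_densitometry()] with `reference = 1` on
#'   the reference lane itself to obtain it).
#' @return Normalized, dimensionless expression level (vectorized).
#' @export
normalize_densitometry <- function(raw, ponceau, gapdh, reference = 1) {
  vals <- c(raw, ponceau, gapdh, reference)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all densitometry inputs must be positive")
  (raw / sqrt(ponceau * gapdh)) / reference
}

#' Per-frequency group comparison of wall tension
#'
#' Splits the cohort at the t-tubule distance threshold and compares the
#' groups' wall tension at each pacing frequency with unpaired two-tailed
#' t-tests, Holm-adjusted across the frequencies.
#'
#' @param records data.frame with `delta_tt_um` and per-frequency value
#'   columns (`<value_prefix>_<frequency>hz`, e.g. `tension_0.5hz`).
#' @param frequencies pacing frequencies to compare (Hz).
#' @param threshold_um dichotomization threshold (um).
#' @param value_prefix prefix of the per-frequency columns.
#' @param var_equal passed to [t_test_unpaired()].
#' @return data.frame with per-frequency group means, SEMs, raw and
#'   Holm-adjusted p-values.
#' @export
frequency_group_comparison <- function(records,
                                       frequencies = c(0.2, 0.5, 1, 2),
                                       threshold_um = 1.05,
                                       value_prefix = "tension",
                                       var_equal = TRUE) {
  groups <- dichotomize_by_dtt(records, threshold_um)
  if (nrow(groups$low) == 0L || nrow(groups$high) == 0L)
    stop("both t-tubule distance groups must be non-empty")
  sem <- function(v) sd(v) / sqrt(length(v))
  rows <- lapply(frequencies, function(f) {
    col <- paste0(value_prefix, "_", f, "hz")
    if (!col %in% names(records))
      stop("missing column: ", col)
    a <- groups$low[[col]]; b <- groups$high[[col]]
    tt <- t_test_unpaired(a, b, var_equal = var_equal)
    data.frame(frequency_hz = f,
               mean_low = mean(a), sem_low = sem(a),
               mean_high = mean(b), sem_high = sem(b),
               n_low = length(a), n_high = length(b),
               p_raw = tt$p_value)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- holm_bonferroni(out$p_raw)
  out
}
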
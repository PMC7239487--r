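#' Root-mean-square error
#' @param pred,obs equal-length numeric vectors.
#' @return sqrt(mean((pred - obs)^2)).
#' @export
rmse <- function(pred, obs) {
  if (length(pred) != length(obs) || length(obs) < 1L)
    stop("`pred` and `obs` must be non-empty and of equal length")
  sqrt(mean((pred - obs)^2))
}

#' Mean absolute percent error
#'
#' mean(|pred - obs| / obs) x 100. Observations equal to zero are excluded
#' (percent error is undefined there); the number excluded is recorded in the
#' `"n_excluded"` attribute.
#'
#' @param pred,obs equal-length numeric vectors; `obs` non-negative.
#' @return percent error scalar.
#' @export
mape <- function(pred, obs) {
  if (length(pred) != length(obs) || length(obs) < 1L)
    stop("`pred` and `obs` must be non-empty and of equal length")
  keep <- obs != 0
  if (!any(keep)) stop("all observed values are zero")
  out <- mean(abs(pred[keep] - obs[keep]) / obs[keep]) * 100
  attr(out, "n_excluded") <- sum(!keep)
  out
}

#' Total session energy expenditure from a 10 s EE series
#'
#' Sum of kcal/min values times 10/60 min per bin.
#'
#' @param ee_kcal_min numeric vector of per-bin EE.
#' @param bin_s bin width in seconds (default 10).
#' @return total kcal.
#' @export
session_total <- function(ee_kcal_min, bin_s = 10) {
  if (length(ee_kcal_min) < 1L) stop("empty EE series")
  sum(ee_kcal_min) * bin_s / 60
}

#' Bland-Altman agreement with proportional-bias regression
#'
#' Differences are computed in percent-error form, (observed - predicted) /
#' observed x 100, following the convention of plotting percent error against
#' the observed session total. Reports the mean bias and 95% limits of
#' agreement (bias +/- 1.96 SD of differences) in percent and in raw kcal,
#' the proportional-bias correlation and OLS regression of percent error on
#' observed kcal, and regression-based 95% prediction limits at requested
#' observed-kcal magnitudes (fit +/- 1.96 residual SD).
#'
#' @param obs_total,pred_total per-subject observed and predicted session
#'   totals (kcal); at least 3 subjects, all `obs_total` > 0.
#' @param limits_at observed-kcal values at which to evaluate prediction
#'   limits (default: min, median, max of `obs_total`).
#' @return list of class `"ba_agreement"`: `mean_bias_pct`, `loa_pct`
#'   (low, high), `mean_bias_kcal`, `loa_kcal`, `prop_bias_r`, `fit_slope`,
#'   `fit_intercept`, `resid_sd`, `prediction_limits` (data.frame), `n`.
#' @export
bland_altman <- function(obs_total, pred_total, limits_at = NULL) {
  n <- length(obs_total)
  if (n < 3L || length(pred_total) != n)
    stop("need >= 3 paired subject totals")
  if (any(obs_total <= 0)) stop("observed totals must be positive")
  d_pct <- (obs_total - pred_total) / obs_total * 100
  d_kcal <- obs_total - pred_total
  mb <- mean(d_pct)
  sd_pct <- stats::sd(d_pct)
  fit <- stats::lm(d_pct ~ obs_total)
  co <- stats::coef(fit)
  rsd <- stats::sd(stats::residuals(fit))
  if (is.null(limits_at))
    limits_at <- c(min(obs_total), stats::median(obs_total), max(obs_total))
  pl <- data.frame(
    observed_kcal = limits_at,
    fit_pct = co[1] + co[2] * limits_at,
    lower_pct = co[1] + co[2] * limits_at - 1.96 * rsd,
    upper_pct = co[1] + co[2] * limits_at + 1.96 * rsd,
    row.names = NULL)
  structure(list(
    mean_bias_pct = mb,
    loa_pct = c(low = mb - 1.96 * sd_pct, high = mb + 1.96 * sd_pct),
    mean_bias_kcal = mean(d_kcal),
    loa_kcal = c(low = mean(d_kcal) - 1.96 * stats::sd(d_kcal),
                 high = mean(d_kcal) + 1.96 * stats::sd(d_kcal)),
    prop_bias_r = if (stats::sd(d_pct) == 0 || stats::sd(obs_total) == 0) 0
                  else stats::cor(d_pct, obs_total),
    fit_slope = unname(co[2]), fit_intercept = unname(co[1]),
    fit_slope_se = tryCatch(
      suppressWarnings(summary(fit)$coefficients[2, 2]),
      error = function(e) NA_real_),
    resid_sd = rsd, prediction_limits = pl, n = n), class = "ba_agreement")
}

#' One-way repeated-measures ANOVA across models with Fisher LSD
#'
#' Classic within-subject one-way ANOVA on a complete subjects x models error
#' matrix: subject is the blocking factor and the error term is the
#' model x subject interaction mean square, giving F on (m - 1, (m - 1)(n - 1))
#' degrees of freedom, uncorrected for sphericity. The decomposition is
#' obtained from `stats::aov(error ~ model + subject)`, whose residual stratum
#' is exactly the interaction in this unreplicated layout. Fisher LSD pairwise
#' comparisons (unadjusted t tests on the pooled error MS and its df) are
#' always computed; `significant` flags whether the omnibus test passed
#' `alpha`.
#'
#' @param error_matrix numeric matrix, subjects x models, complete.
#' @param alpha omnibus significance level (default 0.05).
#' @return list of class `"rm_anova"`: `f_stat`, `df_model`, `df_error`,
#'   `p_value`, `significant`, `ms_error`, `pairwise` (data.frame with
#'   `model_a`, `model_b`, `mean_diff`, `t`, `p`).
#' @export
rm_anova <- function(error_matrix, alpha = 0.05) {
  em <- as.matrix(error_matrix)
  if (anyNA(em)) stop("error matrix has missing cells")
  n <- nrow(em); m <- ncol(em)
  if (n < 2L || m < 2L) stop("need >= 2 subjects and >= 2 models")
  models <- colnames(em) %||% paste0("M", seq_len(m))
  subjects <- rownames(em) %||% paste0("S", seq_len(n))
  long <- data.frame(err = as.vector(em),
                     model = factor(rep(models, each = n), levels = models),
                     subject = factor(rep(subjects, m)))
  fit <- stats::aov(err ~ model + subject, data = long)
  tab <- summary(fit)[[1]]
  ms_model <- tab["model", "Mean Sq"]
  ms_err <- tab["Residuals", "Mean Sq"]
  df1 <- tab["model", "Df"]
  df2 <- tab["Residuals", "Df"]
  # degenerate layouts (identical model columns, or zero error variance)
  # carry no model effect: declare F = 0 rather than divide rounding dust
  ss_total <- sum((em - mean(em))^2)
  degenerate <- ms_err <= 0 ||
    ms_model * df1 <= 1e-10 * max(ss_total, .Machine$double.eps)
  f <- if (degenerate) 0 else ms_model / ms_err
  p <- if (degenerate) 1 else stats::pf(f, df1, df2, lower.tail = FALSE)
  means <- colMeans(em)
  pairs <- utils::combn(m, 2)
  lsd_se <- sqrt(2 * ms_err / n)
  pw <- data.frame(
    model_a = models[pairs[1, ]], model_b = models[pairs[2, ]],
    mean_diff = means[pairs[1, ]] - means[pairs[2, ]],
    row.names = NULL, stringsAsFactors = FALSE)
  pw$t <- if (lsd_se > 0) pw$mean_diff / lsd_se else 0
  pw$p <- if (lsd_se > 0) 2 * stats::pt(abs(pw$t), df2, lower.tail = FALSE)
          else rep(1, nrow(pw))
  structure(list(f_stat = f, df_model = df1, df_error = df2, p_value = p,
                 significant = p < alpha, ms_error = ms_err, pairwise = pw),
            class = "rm_anova")
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf("Repeated-measures ANOVA: F(%d, %d) = %.3f, p = %.3g\n",
              x$df_model, x$df_error, x$f_stat, x$p_value))
  invisible(x)
}

#' @export
print.ba_agreement <- function(x, ...) {
  cat(sprintf(paste0("Bland-Altman (n = %d): mean bias %.2f%% ",
                     "[LOA %.2f, %.2f]; proportional bias r = %.3f ",
                     "(slope %.3f %%/kcal)\n"),
              x$n, x$mean_bias_pct, x$loa_pct[1], x$loa_pct[2],
              x$prop_bias_r, x$fit_slope))
  invisible(x)
}
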
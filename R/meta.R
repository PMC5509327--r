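#' Heterogeneity statistics from Cochran's Q
#'
#' Computes I-squared, its test-based confidence interval, and two variants
#' of H-squared from Q and its degrees of freedom.
#'
#' `i2 = max(0, (Q - df)/Q) * 100`. The headline `h2` is the excess variant
#' `max(0, (Q - df)/df)`; the classical ratio `Q/df` is reported alongside as
#' `h2_classical`. The interval uses the test-based standard error of
#' `ln H` (`H = max(1, sqrt(Q/df))`):
#' `0.5 * (ln Q - ln df) / (sqrt(2 Q) - sqrt(2 df - 1))` when `Q > df + 1`,
#' and the small-Q form `sqrt(1/(2 (k-2)) * (1 - 1/(3 (k-2)^2)))` (with
#' `k = df + 1`) otherwise; the resulting interval for H is transformed to
#' the I-squared scale and clamped to `[0, 100]`. With `df = 1` and small Q
#' the small-Q form is undefined and the interval is returned as `NA`.
#'
#' @param Q Non-negative heterogeneity statistic.
#' @param df Degrees of freedom, `k - 1 >= 1`.
#' @param level Confidence level (default 0.95).
#' @return List with `i2`, `i2_ci`, `h2`, `h2_classical`.
#' @examples
#' heterogeneity(20, 9)
#' @export
heterogeneity <- function(Q, df, level = 0.95) {
  stopifnot(is.numeric(Q), length(Q) == 1L, is.numeric(df), length(df) == 1L)
  if (!is.finite(Q) || Q < 0) stop("`Q` must be non-negative", call. = FALSE)
  if (df < 1) stop("`df` must be at least 1", call. = FALSE)
  i2 <- if (Q > 0) max(0, (Q - df) / Q) * 100 else 0
  h2_classical <- Q / df
  h2 <- max(0, (Q - df) / df)
  k <- df + 1
  se_lnH <- if (Q > df + 1) {
    0.5 * (log(Q) - log(df)) / (sqrt(2 * Q) - sqrt(2 * df - 1))
  } else if (k > 2) {
    sqrt(1 / (2 * (k - 2)) * (1 - 1 / (3 * (k - 2)^2)))
  } else {
    NA_real_
  }
  i2_ci <- c(NA_real_, NA_real_)
  if (is.finite(se_lnH)) {
    lnH <- log(max(1, sqrt(Q / df)))
    zc <- stats::qnorm((1 + level) / 2)
    H_ci <- pmax(1, exp(c(lnH - zc * se_lnH, lnH + zc * se_lnH)))
    i2_ci <- pmin(100, pmax(0, 100 * (H_ci^2 - 1) / H_ci^2))
  }
  list(i2 = i2, i2_ci = i2_ci, h2 = h2, h2_classical = h2_classical)
}

build_meta_result <- function(effects, weights_raw, tau2, method,
                              Q, df, level, n_total = NA_real_) {
  w <- weights_raw / sum(weights_raw)
  estimate <- sum(w * effects$estimate)
  se <- 1 / sqrt(sum(weights_raw))
  scale <- effects$scale[1]
  zc <- stats::qnorm((1 + level) / 2)
  ci_est <- c(estimate - zc * se, estimate + zc * se)
  het <- if (df >= 1) {
    heterogeneity(Q, df, level = level)
  } else {
    list(i2 = NA_real_, i2_ci = c(NA_real_, NA_real_),
         h2 = NA_real_, h2_classical = NA_real_)
  }
  z <- estimate / se
  structure(
    list(k = nrow(effects), n_total = n_total,
         estimate = estimate, se = se, scale = scale, level = level,
         ci = if (scale == "log") exp(ci_est) else ci_est,
         z = z, p = 2 * stats::pnorm(-abs(z)),
         Q = Q, df = df, tau2 = tau2,
         i2 = het$i2, i2_ci = het$i2_ci,
         h2 = het$h2, h2_classical = het$h2_classical,
         weights = stats::setNames(w, effects$study_id),
         method = method),
    class = "meta_result"
  )
}

#' Inverse-variance fixed-effect pooling
#'
#' Weights each study by `1/se^2`. Also computes Cochran's Q about the
#' fixed-effect mean, the substrate for the DerSimonian-Laird estimator.
#' A single study is passed through unchanged (its own estimate and SE),
#' with heterogeneity fields undefined.
#'
#' @param effects An `effect_frame` (or data frame with columns `estimate`,
#'   `se`, optional `scale`, `study_id`, `n`), all on a common scale.
#' @param level Confidence level (default 0.95).
#' @return An object of class `meta_result`.
#' @examples
#' fixed_effect(data.frame(estimate = c(0, 2), se = c(1, 1)))
#' @export
fixed_effect <- function(effects, level = 0.95) {
  effects <- as_effect_frame(effects)
  w <- 1 / effects$se^2
  est <- sum(w * effects$estimate) / sum(w)
  Q <- sum(w * (effects$estimate - est)^2)
  build_meta_result(effects, w, tau2 = 0, method = "fixed",
                    Q = Q, df = nrow(effects) - 1L, level = level,
                    n_total = total_n(effects))
}

total_n <- function(effects) {
  if (!is.null(effects$n) && all(is.finite(effects$n))) sum(effects$n)
  else NA_real_
}

#' DerSimonian-Laird random-effects pooling
#'
#' Moment estimator of the between-study variance:
#' `tau2 = max(0, (Q - df) / (sum(w) - sum(w^2)/sum(w)))` with fixed-effect
#' weights `w = 1/se^2`, then re-pools with weights `1/(se^2 + tau2)`.
#' When `Q <= df` the estimator truncates at zero and the result coincides
#' with the fixed-effect pool.
#'
#' @inheritParams fixed_effect
#' @return An object of class `meta_result` with `method = "random"`.
#' @examples
#' dersimonian_laird(data.frame(estimate = c(0, 2), se = c(1, 1)))
#' @export
dersimonian_laird <- function(effects, level = 0.95) {
  effects <- as_effect_frame(effects)
  if (nrow(effects) < 2L) {
    stop("random-effects pooling needs at least 2 studies", call. = FALSE)
  }
  w <- 1 / effects$se^2
  est_fe <- sum(w * effects$estimate) / sum(w)
  Q <- sum(w * (effects$estimate - est_fe)^2)
  df <- nrow(effects) - 1L
  C <- sum(w) - sum(w^2) / sum(w)
  tau2 <- max(0, (Q - df) / C)
  w_star <- 1 / (effects$se^2 + tau2)
  build_meta_result(effects, w_star, tau2 = tau2, method = "random",
                    Q = Q, df = df, level = level, n_total = total_n(effects))
}

#' @export
print.meta_result <- function(x, digits = 4, ...) {
  natural <- if (x$scale == "log") exp(x$estimate) else x$estimate
  lab <- if (x$scale == "log") "pooled OR" else "pooled estimate"
  cat(sprintf("%s-effects meta-analysis of %d studies%s\n",
              if (x$method == "fixed") "Fixed" else "Random", x$k,
              if (is.finite(x$n_total)) sprintf(" (n = %s)", format(x$n_total)) else ""))
  cat(sprintf("  %s = %s [%s%% CI %s, %s], p = %s\n", lab,
              format(natural, digits = digits), format(100 * x$level),
              format(x$ci[1], digits = digits), format(x$ci[2], digits = digits),
              format(x$p, digits = digits)))
  if (isTRUE(x$df >= 1)) {
    cat(sprintf("  Q = %s (df = %d), tau^2 = %s, I^2 = %s%% [%s, %s], H^2 = %s\n",
                format(x$Q, digits = digits), x$df,
                format(x$tau2, digits = digits),
                format(x$i2, digits = digits),
                format(x$i2_ci[1], digits = digits),
                format(x$i2_ci[2], digits = digits),
                format(x$h2, digits = digits)))
  }
  invisible(x)
}

#' Leave-one-out sensitivity re-pooling
#'
#' Re-pools the collection with each study omitted in turn, using the same
#' method throughout.
#'
#' @inheritParams fixed_effect
#' @param method `"random"` (default) or `"fixed"`.
#' @return A named list of `meta_result` objects, one per omitted study,
#'   names giving the omitted `study_id`.
#' @export
leave_one_out <- function(effects, method = c("random", "fixed"),
                          level = 0.95) {
  method <- match.arg(method)
  effects <- as_effect_frame(effects)
  k <- nrow(effects)
  if (k < 3L) stop("leave-one-out needs at least 3 studies", call. = FALSE)
  pool <- if (method == "random") dersimonian_laird else fixed_effect
  out <- lapply(seq_len(k), function(i) pool(effects[-i, , drop = FALSE], level = level))
  names(out) <- effects$study_id
  out
}

#' Pooled risk-allele frequency across studies
#'
#' `method = "inverse_variance"` weights each study frequency by the
#' reciprocal of its binomial allele-count variance, i.e. `w = 2n / (f(1-f))`;
#' monomorphic studies (f of 0 or 1) have zero variance and are excluded
#' with a message. `method = "mean"` is the unweighted arithmetic mean.
#'
#' @param f Vector of per-study risk-allele frequencies in `[0, 1]`.
#' @param n Vector of per-study sample sizes (persons); recycled if scalar.
#'   Ignored by `method = "mean"`.
#' @param method `"inverse_variance"` or `"mean"`.
#' @return The pooled frequency (scalar in `[0, 1]`).
#' @examples
#' pooled_raf(c(0.971, 0.907, 0.82, 0.84), c(12035, 1114, 1274, 1988), "mean")
#' @export
pooled_raf <- function(f, n = NULL, method = c("inverse_variance", "mean")) {
  method <- match.arg(method)
  if (!length(f)) stop("no frequencies supplied", call. = FALSE)
  if (any(!is.finite(f)) || any(f < 0) || any(f > 1)) {
    stop("frequencies must lie in [0, 1]", call. = FALSE)
  }
  if (method == "mean") return(mean(f))
  if (is.null(n)) stop("inverse-variance pooling needs sample sizes `n`",
                       call. = FALSE)
  n <- rep_len(n, length(f))
  if (any(!is.finite(n)) || any(n <= 0)) {
    stop("sample sizes must be positive", call. = FALSE)
  }
  poly <- f > 0 & f < 1
  if (!any(poly)) stop("all studies are monomorphic", call. = FALSE)
  if (!all(poly)) {
    message(sum(!poly), " monomorphic study(ies) excluded from inverse-variance RAF pool")
  }
  w <- 2 * n[poly] / (f[poly] * (1 - f[poly]))
  sum(w * f[poly]) / sum(w)
}
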
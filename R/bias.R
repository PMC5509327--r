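#' Egger's regression test for funnel-plot asymmetry
#'
#' Classic form: ordinary least squares of the standardized effect
#' `z_i = y_i / se_i` on precision `1/se_i`. Small-study asymmetry shifts
#' the intercept away from zero; the intercept is tested with a t statistic
#' on `k - 2` degrees of freedom.
#'
#' @param effects An `effect_frame` (or data frame with `estimate`, `se`),
#'   k >= 3, with non-constant standard errors.
#' @return An object of class `bias_test_result` with `method = "egger"`,
#'   the `intercept`, its standard error, the t `statistic`, `df`, `p`,
#'   the `slope` (an estimate of the underlying pooled effect) and `k`.
#' @examples
#' egger_test(data.frame(estimate = c(0.1, 0.3, 0.2, 0.4),
#'                       se = c(0.1, 0.3, 0.2, 0.4)))
#' @export
egger_test <- function(effects) {
  effects <- as_effect_frame(effects)
  k <- nrow(effects)
  if (k < 3L) stop("Egger's test needs at least 3 studies", call. = FALSE)
  if (diff(range(effects$se)) == 0) {
    stop("degenerate design: all standard errors equal, precision is constant",
         call. = FALSE)
  }
  z <- effects$estimate / effects$se
  prec <- 1 / effects$se
  fit <- withCallingHandlers(
    summary(stats::lm(z ~ prec))$coefficients,
    warning = function(w) {
      # exact-fit constructions legitimately yield zero residual variance
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  intercept <- fit["(Intercept)", "Estimate"]
  se_int <- fit["(Intercept)", "Std. Error"]
  tval <- intercept / se_int
  structure(
    list(method = "egger", intercept = intercept, se_intercept = se_int,
         statistic = tval, df = k - 2L,
         p = 2 * stats::pt(-abs(tval), df = k - 2),
         slope = fit["prec", "Estimate"], k = k),
    class = "bias_test_result"
  )
}

#' Begg and Mazumdar's rank-correlation test for publication bias
#'
#' Kendall's tau between the variance-standardized deviations from the
#' fixed-effect pool, `(y_i - y_FE) / sqrt(se_i^2 - se_FE^2)`, and the
#' study variances `se_i^2`. The p-value uses the exact null distribution
#' for `k <= 8` (ties permitting) and the continuity-corrected normal
#' approximation otherwise; the reported `statistic` is the
#' continuity-corrected normal z in all cases. Studies whose variance does
#' not numerically exceed the pooled variance are guarded with a small
#' positive floor and reported via `message()`.
#'
#' @param effects An `effect_frame` (or data frame with `estimate`, `se`),
#'   k >= 3.
#' @return A `bias_test_result` with `method = "begg"`, Kendall's `tau`,
#'   the `statistic` (z), `p` and `k`.
#' @export
begg_test <- function(effects) {
  effects <- as_effect_frame(effects)
  k <- nrow(effects)
  if (k < 3L) stop("Begg's test needs at least 3 studies", call. = FALSE)
  v <- effects$se^2
  w <- 1 / v
  est_fe <- sum(w * effects$estimate) / sum(w)
  v_fe <- 1 / sum(w)
  v_dev <- v - v_fe
  if (any(v_dev <= 0)) {
    message(sum(v_dev <= 0),
            " study(ies) with variance <= pooled variance floored in Begg's test")
    v_dev <- pmax(v_dev, 1e-12)
  }
  dev <- (effects$estimate - est_fe) / sqrt(v_dev)
  dev_spread <- diff(range(dev))
  if (dev_spread <= 1e-10 * max(1, max(abs(dev))) || stats::sd(v) == 0) {
    return(structure(list(method = "begg", tau = 0, statistic = 0, p = 1, k = k),
                     class = "bias_test_result"))
  }
  # concordant-minus-discordant score for the z statistic
  S <- 0
  for (i in seq_len(k - 1)) {
    S <- S + sum(sign(dev[(i + 1):k] - dev[i]) * sign(v[(i + 1):k] - v[i]))
  }
  var0 <- k * (k - 1) * (2 * k + 5) / 18
  z <- if (S == 0) 0 else sign(S) * (abs(S) - 1) / sqrt(var0)
  ct <- suppressWarnings(
    stats::cor.test(dev, v, method = "kendall", exact = (k <= 8),
                    continuity = TRUE)
  )
  structure(
    list(method = "begg", tau = unname(ct$estimate), statistic = z,
         p = min(1, ct$p.value), k = k),
    class = "bias_test_result"
  )
}

#' @export
print.bias_test_result <- function(x, digits = 4, ...) {
  if (x$method == "egger") {
    cat(sprintf("Egger regression test (k = %d): intercept = %s (SE %s), t(%d) = %s, p = %s\n",
                x$k, format(x$intercept, digits = digits),
                format(x$se_intercept, digits = digits), x$df,
                format(x$statistic, digits = digits),
                format(x$p, digits = digits)))
  } else {
    cat(sprintf("Begg rank-correlation test (k = %d): tau = %s, z = %s, p = %s\n",
                x$k, format(x$tau, digits = digits),
                format(x$statistic, digits = digits),
                format(x$p, digits = digits)))
  }
  invisible(x)
}

#' Funnel-plot data export
#'
#' Per-study points plus the pseudo-confidence funnel boundary around the
#' pooled estimate, as plain data suitable for external plotting.
#'
#' @param effects An `effect_frame` (or data frame with `estimate`, `se`).
#' @param result The `meta_result` the funnel is centred on.
#' @param se_grid Standard errors at which to evaluate the boundary;
#'   defaults to an even grid from 0 to just past the largest study SE.
#' @param level Pseudo-CI level (default 0.95).
#' @return A list of class `funnel_data`: `studies` (study_id, estimate on
#'   the reporting scale, se) and `boundary` (se, lower, upper, center on
#'   the reporting scale).
#' @export
funnel_data <- function(effects, result, se_grid = NULL, level = 0.95) {
  effects <- as_effect_frame(effects)
  stopifnot(inherits(result, "meta_result"))
  to_report <- if (result$scale == "log") exp else identity
  if (is.null(se_grid)) {
    se_grid <- seq(0, max(effects$se) * 1.05, length.out = 41L)
  }
  zc <- stats::qnorm((1 + level) / 2)
  structure(
    list(
      studies = data.frame(study_id = effects$study_id,
                           estimate = to_report(effects$estimate),
                           se = effects$se, stringsAsFactors = FALSE),
      boundary = data.frame(se = se_grid,
                            lower = to_report(result$estimate - zc * se_grid),
                            upper = to_report(result$estimate + zc * se_grid),
                            center = to_report(result$estimate))
    ),
    class = "funnel_data"
  )
}
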
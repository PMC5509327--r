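#' Construct an effect size with its derived confidence interval, z and p
#'
#' An effect size is a point estimate with a standard error on a stated
#' estimation scale. Odds ratios are carried as log-OR (`scale = "log"`);
#' regression coefficients and standardized mean differences are carried
#' as-is (`scale = "identity"`). The confidence interval is reported on the
#' natural reporting scale (exponentiated for log-scale effects).
#'
#' @param estimate Point estimate on the estimation scale (log-OR for
#'   `scale = "log"`).
#' @param se Positive standard error on the estimation scale.
#' @param scale `"log"` or `"identity"`.
#' @param level Confidence level for the reported interval (default 0.95).
#' @param study_id Optional study label carried through to pooling output.
#' @return An object of class `effect_size`: a list with `estimate`, `se`,
#'   `scale`, `level`, `ci` (reporting scale), `z`, `p` and `study_id`.
#' @examples
#' effect_size(log(1.5), 0.2, scale = "log")
#' @export
effect_size <- function(estimate, se, scale = c("identity", "log"),
                        level = 0.95, study_id = NA_character_) {
  scale <- match.arg(scale)
  stopifnot(is.numeric(estimate), length(estimate) == 1L, is.finite(estimate))
  if (!is.numeric(se) || length(se) != 1L || !is.finite(se) || se <= 0) {
    stop("`se` must be a single positive number", call. = FALSE)
  }
  if (level <= 0 || level >= 1) stop("`level` must be in (0,1)", call. = FALSE)
  zc <- stats::qnorm((1 + level) / 2)
  ci_est <- c(estimate - zc * se, estimate + zc * se)
  ci <- if (scale == "log") exp(ci_est) else ci_est
  z <- estimate / se
  structure(
    list(estimate = estimate, se = se, scale = scale, level = level,
         ci = ci, z = z, p = 2 * stats::pnorm(-abs(z)),
         study_id = as.character(study_id)),
    class = "effect_size"
  )
}

#' @export
print.effect_size <- function(x, digits = 4, ...) {
  natural <- if (x$scale == "log") exp(x$estimate) else x$estimate
  lab <- if (x$scale == "log") "OR" else "estimate"
  cat(sprintf("%s %s = %s [%s%% CI %s, %s], se(%s) = %s, z = %s, p = %s\n",
              if (!is.na(x$study_id)) paste0("[", x$study_id, "] ") else "",
              lab, format(natural, digits = digits),
              format(100 * x$level),
              format(x$ci[1], digits = digits), format(x$ci[2], digits = digits),
              if (x$scale == "log") "log OR" else lab,
              format(x$se, digits = digits),
              format(x$z, digits = digits), format(x$p, digits = digits)))
  invisible(x)
}

#' Collect effect sizes into a pooling-ready data frame
#'
#' @param ... `effect_size` objects, or a single list of them.
#' @return A data frame of class `effect_frame` with columns `study_id`,
#'   `estimate`, `se`, `scale`.
#' @export
effect_frame <- function(...) {
  xs <- list(...)
  if (length(xs) == 1L && is.list(xs[[1]]) && !inherits(xs[[1]], "effect_size")) {
    xs <- xs[[1]]
  }
  if (!length(xs)) stop("no effect sizes supplied", call. = FALSE)
  ok <- vapply(xs, inherits, logical(1), "effect_size")
  if (!all(ok)) stop("all inputs must be `effect_size` objects", call. = FALSE)
  out <- data.frame(
    study_id = vapply(xs, function(e) e$study_id, character(1)),
    estimate = vapply(xs, function(e) e$estimate, numeric(1)),
    se = vapply(xs, function(e) e$se, numeric(1)),
    scale = vapply(xs, function(e) e$scale, character(1)),
    stringsAsFactors = FALSE
  )
  class(out) <- c("effect_frame", "data.frame")
  out
}

# Coerce pooling input: accepts an effect_frame, a plain data.frame with
# estimate/se (and optionally scale, study_id), or a list of effect_size.
as_effect_frame <- function(effects) {
  if (inherits(effects, "effect_size")) effects <- list(effects)
  if (is.list(effects) && !is.data.frame(effects)) {
    return(effect_frame(effects))
  }
  if (!is.data.frame(effects)) {
    stop("`effects` must be a data frame or list of effect_size objects",
         call. = FALSE)
  }
  if (!all(c("estimate", "se") %in% names(effects))) {
    stop("`effects` needs columns `estimate` and `se`", call. = FALSE)
  }
  if (is.null(effects$scale)) effects$scale <- "identity"
  if (is.null(effects$study_id)) {
    effects$study_id <- sprintf("study_%02d", seq_len(nrow(effects)))
  }
  if (length(unique(effects$scale)) > 1L) {
    stop("effects are on mixed scales; pool log and identity effects separately",
         call. = FALSE)
  }
  if (any(!is.finite(effects$se)) || any(effects$se <= 0)) {
    stop("all standard errors must be finite and positive", call. = FALSE)
  }
  effects
}

#' Recover a standard error from a reported confidence interval
#'
#' Inverts the usual Wald interval: `SE = (t(upper) - t(lower)) / (2 z)`,
#' where `t` is the log for ratio measures and the identity otherwise, and
#' `z` is the two-sided normal quantile at the stated level.
#'
#' @param lower,upper Reported interval bounds on the natural scale.
#' @param level Confidence level of the reported interval (default 0.95).
#' @param scale `"identity"` for differences/coefficients, `"log"` for ratio
#'   measures (both bounds must then be positive).
#' @return The standard error on the estimation scale (a positive scalar).
#' @examples
#' se_from_ci(0.060, 0.079)               # beta reported with 95% CI
#' se_from_ci(0.947, 0.981, scale = "log") # OR reported with 95% CI
#' @export
se_from_ci <- function(lower, upper, level = 0.95,
                       scale = c("identity", "log")) {
  scale <- match.arg(scale)
  stopifnot(is.numeric(lower), is.numeric(upper),
            length(lower) == 1L, length(upper) == 1L)
  if (!is.finite(lower) || !is.finite(upper) || lower >= upper) {
    stop("need finite `lower` < `upper`", call. = FALSE)
  }
  if (level <= 0 || level >= 1) stop("`level` must be in (0,1)", call. = FALSE)
  if (scale == "log" && lower <= 0) {
    stop("log-scale bounds must be positive", call. = FALSE)
  }
  tr <- if (scale == "log") log else identity
  (tr(upper) - tr(lower)) / (2 * stats::qnorm((1 + level) / 2))
}

#' Recover a standard error from an estimate and its two-sided p-value
#'
#' `SE = |estimate| / z`, with `z` the upper-tail normal quantile at `p/2`.
#' Undefined at `p = 1` (z = 0) and for a null estimate.
#'
#' @param estimate Non-zero point estimate on the estimation scale.
#' @param p Two-sided p-value in (0, 1).
#' @return The implied standard error.
#' @examples
#' se_from_p(0.075, 2 * pnorm(-0.075 / 0.003))  # recovers 0.003
#' @export
se_from_p <- function(estimate, p) {
  stopifnot(is.numeric(estimate), length(estimate) == 1L,
            is.numeric(p), length(p) == 1L)
  if (!is.finite(p) || p <= 0 || p >= 1) {
    stop("`p` must lie strictly between 0 and 1", call. = FALSE)
  }
  if (!is.finite(estimate) || estimate == 0) {
    stop("`estimate` must be non-zero to imply a standard error", call. = FALSE)
  }
  abs(estimate) / stats::qnorm(p / 2, lower.tail = FALSE)
}

#' Standardized mean difference between two genotype groups
#'
#' Pooled-SD standardization `d = (m1 - m0) / s_pooled` with the usual
#' large-sample standard error `sqrt(1/n1 + 1/n0 + d^2 / (2 (n1 + n0)))`.
#' `flavor = "hedges"` applies the small-sample correction
#' `J = 1 - 3 / (4 (n1 + n0 - 2) - 1)` to both the estimate and its SE.
#'
#' @param n1,m1,sd1 Size, mean and SD of the comparison group.
#' @param n0,m0,sd0 Size, mean and SD of the reference group.
#' @param flavor `"cohen"` (default) or `"hedges"`.
#' @param study_id Optional study label.
#' @return An `effect_size` on the identity scale.
#' @examples
#' smd(120, 5.31, 0.62, 300, 5.20, 0.60)
#' @export
smd <- function(n1, m1, sd1, n0, m0, sd0,
                flavor = c("cohen", "hedges"), study_id = NA_character_) {
  flavor <- match.arg(flavor)
  stopifnot(is.numeric(n1), is.numeric(n0))
  if (n1 < 2 || n0 < 2) stop("both groups need n >= 2", call. = FALSE)
  if (!is.finite(sd1) || !is.finite(sd0) || sd1 <= 0 || sd0 <= 0) {
    stop("group SDs must be positive", call. = FALSE)
  }
  s_pooled <- sqrt(((n1 - 1) * sd1^2 + (n0 - 1) * sd0^2) / (n1 + n0 - 2))
  d <- (m1 - m0) / s_pooled
  se <- sqrt(1 / n1 + 1 / n0 + d^2 / (2 * (n1 + n0)))
  if (flavor == "hedges") {
    j <- 1 - 3 / (4 * (n1 + n0 - 2) - 1)
    d <- j * d
    se <- j * se
  }
  effect_size(d, se, scale = "identity", study_id = study_id)
}
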
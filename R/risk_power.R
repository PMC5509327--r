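#' Population attributable risk under the multiplicative genotype model
#'
#' With risk-allele frequency `f` and per-allele odds ratio `gamma`, the
#' mean population relative risk is
#' `X = (1 - f)^2 + 2 f (1 - f) gamma + f^2 gamma^2 = (1 + f (gamma - 1))^2`
#' and `PAR = (X - 1) / X`. PAR is zero exactly when `gamma = 1` or
#' `f = 0`, and negative for a protective allele (`gamma < 1`).
#'
#' The formula presupposes that the named allele is the risk allele. With
#' `orient = TRUE` a `gamma < 1` input is re-expressed for the
#' complementary allele (`gamma -> 1/gamma`, `f -> 1 - f`) and the result
#' flags that the complement was treated as the risk allele.
#'
#' @param f Risk-allele frequency in `[0, 1]`.
#' @param gamma Per-allele odds ratio, positive.
#' @param orient If `TRUE`, flip to the complementary allele when
#'   `gamma < 1`.
#' @return An object of class `par_result`: list with `f`, `gamma`, `X`,
#'   `par` and `risk_is_complement`.
#' @examples
#' par_multiplicative(0.8845, 1.120)   # PAR ~ 18.3%
#' @export
par_multiplicative <- function(f, gamma, orient = FALSE) {
  stopifnot(is.numeric(f), length(f) == 1L, is.numeric(gamma),
            length(gamma) == 1L)
  if (!is.finite(f) || f < 0 || f > 1) {
    stop("`f` must lie in [0, 1]", call. = FALSE)
  }
  if (!is.finite(gamma) || gamma <= 0) {
    stop("`gamma` must be positive", call. = FALSE)
  }
  flipped <- FALSE
  if (orient && gamma < 1) {
    gamma <- 1 / gamma
    f <- 1 - f
    flipped <- TRUE
  }
  X <- (1 - f)^2 + 2 * f * (1 - f) * gamma + f^2 * gamma^2
  structure(
    list(f = f, gamma = gamma, X = X, par = (X - 1) / X,
         risk_is_complement = flipped),
    class = "par_result"
  )
}

#' @export
print.par_result <- function(x, digits = 4, ...) {
  cat(sprintf("PAR = %s%% (f = %s, per-allele OR = %s, X = %s)%s\n",
              format(100 * x$par, digits = digits),
              format(x$f, digits = digits), format(x$gamma, digits = digits),
              format(x$X, digits = digits),
              if (x$risk_is_complement) " [complementary allele taken as risk allele]" else ""))
  invisible(x)
}

#' Power of the per-allele case-control association test
#'
#' Closed-form normal approximation for the 1-df per-allele (allelic trend)
#' test. Expected genotype frequencies in cases and controls are derived
#' from the population risk-allele frequency `f`, the per-allele relative
#' risk `gamma` and the disease `prevalence` under the multiplicative model
#' and Hardy-Weinberg equilibrium; power is that of the Wald test of the
#' log allelic odds ratio at the implied allele counts.
#'
#' @param gamma Per-allele odds ratio (a protective allele, `gamma < 1`, is
#'   handled symmetrically).
#' @param f Population risk-allele frequency in `(0, 1)`.
#' @param n_case,n_control Numbers of cases and controls (persons).
#' @param prevalence Disease prevalence in `(0, 1)`.
#' @param alpha Two-sided significance level (default 0.05).
#' @return Power in `[alpha, 1]` (equals `alpha` at `gamma = 1`).
#' @examples
#' power_case_control(0.967, 0.70, 24278, 67043, prevalence = 0.088)
#' @export
power_case_control <- function(gamma, f, n_case, n_control, prevalence,
                               alpha = 0.05) {
  stopifnot(is.numeric(gamma), is.numeric(f), is.numeric(prevalence))
  if (gamma <= 0) stop("`gamma` must be positive", call. = FALSE)
  if (f <= 0 || f >= 1) stop("`f` must lie strictly in (0, 1)", call. = FALSE)
  if (prevalence <= 0 || prevalence >= 1) {
    stop("`prevalence` must lie in (0, 1)", call. = FALSE)
  }
  if (n_case <= 0 || n_control <= 0) {
    stop("sample sizes must be positive", call. = FALSE)
  }
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must lie in (0, 1)", call. = FALSE)
  pf <- genotype_freqs_from_raf(f)        # (hom-risk, het, hom-other)
  dose <- c(2, 1, 0)
  X <- sum(pf * gamma^dose)
  r0 <- prevalence / X                    # baseline penetrance
  if (r0 * max(gamma^dose) >= 1) {
    stop("implied genotype penetrance reaches 1; ",
         "prevalence/effect combination is infeasible", call. = FALSE)
  }
  p_case <- sum(dose / 2 * pf * gamma^dose / X)
  p_ctrl <- sum(dose / 2 * pf * (1 - r0 * gamma^dose) / (1 - prevalence))
  lnor <- log(p_case / (1 - p_case)) - log(p_ctrl / (1 - p_ctrl))
  v <- 1 / (2 * n_case * p_case * (1 - p_case)) +
       1 / (2 * n_control * p_ctrl * (1 - p_ctrl))
  za <- stats::qnorm(1 - alpha / 2)
  ncp <- abs(lnor) / sqrt(v)
  stats::pnorm(ncp - za) + stats::pnorm(-ncp - za)
}

#' Power of the per-allele quantitative-trait trend test
#'
#' Chi-square (1 df) power of the linear per-allele regression with
#' non-centrality `lambda = n * 2 f (1 - f) * beta^2 / sigma^2`, the allele
#' dose variance under Hardy-Weinberg equilibrium times the squared
#' standardized effect.
#'
#' @param beta Per-allele effect on the trait (e.g. mmol/l per allele).
#' @param f Risk-allele frequency in `(0, 1)`.
#' @param n Sample size (persons).
#' @param trait_sd Residual trait standard deviation (same units as the
#'   trait).
#' @param alpha Two-sided significance level (default 0.05).
#' @return Power in `[alpha, 1]` (equals `alpha` at `beta = 0`).
#' @examples
#' power_quantitative(0.075, 0.67, 13752, trait_sd = 0.8)
#' @export
power_quantitative <- function(beta, f, n, trait_sd, alpha = 0.05) {
  stopifnot(is.numeric(beta), is.numeric(f), is.numeric(n))
  if (f <= 0 || f >= 1) stop("`f` must lie strictly in (0, 1)", call. = FALSE)
  if (!is.numeric(trait_sd) || trait_sd <= 0) {
    stop("`trait_sd` must be positive", call. = FALSE)
  }
  if (n <= 0) stop("`n` must be positive", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must lie in (0, 1)", call. = FALSE)
  lambda <- n * 2 * f * (1 - f) * beta^2 / trait_sd^2
  crit <- stats::qchisq(1 - alpha, df = 1)
  stats::pchisq(crit, df = 1, ncp = lambda, lower.tail = FALSE)
}
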
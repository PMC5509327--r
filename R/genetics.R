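#' Hardy-Weinberg genotype frequencies from a risk-allele frequency
#'
#' Genotype triples throughout the package are ordered
#' (hom-risk, het, hom-other), i.e. carrying 2, 1 and 0 copies of the
#' risk allele.
#'
#' @param f Risk-allele frequency in `[0, 1]`.
#' @return Numeric triple `(f^2, 2 f (1 - f), (1 - f)^2)`.
#' @examples
#' genotype_freqs_from_raf(0.971)
#' @export
genotype_freqs_from_raf <- function(f) {
  stopifnot(is.numeric(f), length(f) == 1L)
  if (!is.finite(f) || f < 0 || f > 1) {
    stop("allele frequency must lie in [0, 1]", call. = FALSE)
  }
  c(hom_risk = f^2, het = 2 * f * (1 - f), hom_other = (1 - f)^2)
}

#' Expected genotype counts under Hardy-Weinberg equilibrium
#'
#' Returns `n` times the HWE genotype frequencies. Counts are kept
#' fractional: rounding would break exact recovery of `f` by allele
#' counting and is therefore never applied here.
#'
#' @param f Risk-allele frequency in `[0, 1]`.
#' @param n Positive sample size (persons).
#' @return Numeric triple of expected counts (hom-risk, het, hom-other).
#' @examples
#' reconstruct_counts(0.3, 1000)  # (90, 420, 490)
#' @export
reconstruct_counts <- function(f, n) {
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n <= 0) {
    stop("`n` must be a positive sample size", call. = FALSE)
  }
  n * genotype_freqs_from_raf(f)
}

#' Chi-square test for Hardy-Weinberg equilibrium
#'
#' Estimates the risk-allele frequency by allele counting and compares the
#' three observed genotype classes with their HWE expectation using a
#' 1-df chi-square statistic without continuity correction. A monomorphic
#' sample (estimated frequency 0 or 1) is reported as `chi2 = 0`, `p = 1`
#' with `monomorphic = TRUE`.
#'
#' @param counts Genotype triple (hom-risk, het, hom-other) of non-negative
#'   counts with a positive total.
#' @return An object of class `hwe_result`: list with `chi2`, `df`, `p`,
#'   `f_hat`, `monomorphic` and `hwe_ok` (`p >= 0.05`).
#' @examples
#' hwe_test(c(30, 30, 40))
#' @export
hwe_test <- function(counts) {
  counts <- check_genotype_triple(counts, "counts")
  n <- sum(counts)
  if (n <= 0) stop("total genotype count must be positive", call. = FALSE)
  f_hat <- (2 * counts[1] + counts[2]) / (2 * n)
  if (f_hat == 0 || f_hat == 1) {
    res <- list(chi2 = 0, df = 1L, p = 1, f_hat = unname(f_hat),
                monomorphic = TRUE, hwe_ok = TRUE)
    class(res) <- "hwe_result"
    return(res)
  }
  expected <- n * genotype_freqs_from_raf(unname(f_hat))
  chi2 <- sum((counts - expected)^2 / expected)
  res <- list(chi2 = unname(chi2), df = 1L,
              p = stats::pchisq(unname(chi2), df = 1, lower.tail = FALSE),
              f_hat = unname(f_hat), monomorphic = FALSE,
              hwe_ok = NA)
  res$hwe_ok <- res$p >= 0.05
  class(res) <- "hwe_result"
  res
}

#' @export
print.hwe_result <- function(x, digits = 4, ...) {
  cat(sprintf("HWE chi-square = %s (df = 1), p = %s, f_hat = %s%s\n",
              format(x$chi2, digits = digits), format(x$p, digits = digits),
              format(x$f_hat, digits = digits),
              if (x$monomorphic) " [monomorphic]" else ""))
  invisible(x)
}

check_genotype_triple <- function(x, what) {
  if (!is.numeric(x) || length(x) != 3L || any(!is.finite(x)) || any(x < 0)) {
    stop(sprintf("`%s` must be a non-negative numeric triple (hom-risk, het, hom-other)",
                 what), call. = FALSE)
  }
  x
}

# Collapse a genotype triple into the 2x2 margin (exposed, unexposed)
# implied by a genetic model. The allele and additive models count alleles
# (two per person), the dominant and recessive models count carriers.
collapse_genotypes <- function(counts, model) {
  switch(model,
    allele = ,
    additive = c(2 * counts[1] + counts[2], counts[2] + 2 * counts[3]),
    dominant = c(counts[1] + counts[2], counts[3]),
    recessive = c(counts[1], counts[2] + counts[3]),
    stop("unknown genetic model: ", model, call. = FALSE)
  )
}

#' Genetic-model odds ratio from genotype counts
#'
#' Collapses case and control genotype triples into a 2x2 table under the
#' requested genetic model and returns the crude odds ratio with the Woolf
#' standard error `sqrt(sum(1/cell))` on the log scale.
#'
#' Models: `"allele"` contrasts risk vs other alleles (two per person);
#' `"additive"` uses the same allele-count 2x2 as the crude per-allele OR;
#' `"dominant"` contrasts carriers (hom-risk + het) vs non-carriers;
#' `"recessive"` contrasts hom-risk vs the rest. Fractional counts (e.g.
#' HWE-reconstructed expectations) are accepted.
#'
#' @param case,control Genotype triples (hom-risk, het, hom-other).
#' @param model One of `"allele"`, `"dominant"`, `"recessive"`, `"additive"`.
#' @param correction Zero-cell handling: `"haldane"` (default) adds 0.5 to
#'   every cell of a collapsed 2x2 that contains a zero; `"none"` leaves the
#'   table as-is and errors on zero margins.
#' @param study_id Optional study label.
#' @return An `effect_size` on the log scale.
#' @examples
#' or_from_counts(c(30, 40, 30), c(10, 40, 50), model = "dominant")
#' @export
or_from_counts <- function(case, control,
                           model = c("allele", "dominant", "recessive", "additive"),
                           correction = c("haldane", "none"),
                           study_id = NA_character_) {
  model <- match.arg(model)
  correction <- match.arg(correction)
  case <- check_genotype_triple(case, "case")
  control <- check_genotype_triple(control, "control")
  if (sum(case) <= 0 || sum(control) <= 0) {
    stop("case and control totals must be positive", call. = FALSE)
  }
  tab <- rbind(case = collapse_genotypes(case, model),
               control = collapse_genotypes(control, model))
  if (correction == "haldane" && any(tab == 0)) tab <- tab + 0.5
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0) || any(tab == 0)) {
    stop("degenerate 2x2 table under the ", model,
         " model (zero cell or margin)", call. = FALSE)
  }
  log_or <- unname(log(tab[1, 1]) - log(tab[1, 2]) -
                     log(tab[2, 1]) + log(tab[2, 2]))
  se <- sqrt(sum(1 / tab))
  effect_size(log_or, se, scale = "log", study_id = study_id)
}
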
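#' Define a multi-study simulation scenario
#'
#' A scenario fixes the generative random-effects model for a collection of
#' studies: per-study true effects `theta_i ~ Normal(mu, tau^2)` (log-OR
#' for the case-control design, trait units per allele for the
#' quantitative design), risk-allele frequencies uniform over `raf_range`,
#' per-study sizes uniform over `n_range` (per group for case-control),
#' genotypes sampled multinomially under Hardy-Weinberg equilibrium.
#' Case-control studies derive case/control genotype distributions from
#' the multiplicative risk model at the stated `prevalence`; quantitative
#' studies draw per-subject traits `Normal(baseline + dose * theta_i,
#' trait_sd^2)`.
#'
#' The `seed` fully determines the output: each study uses its own
#' deterministic substream derived from `(seed, i)`, so growing `k`
#' extends a table without reshuffling earlier studies.
#'
#' @param design `"case_control"` or `"quantitative"`.
#' @param k Number of studies.
#' @param mu True pooled effect (log-OR or trait units per allele).
#' @param tau Between-study SD of true effects, `>= 0`.
#' @param raf_range Length-2 range of risk-allele frequencies in `(0, 1)`.
#' @param n_range Length-2 range of per-study sizes (per group for
#'   case-control).
#' @param prevalence Disease prevalence (case-control design).
#' @param trait_sd Residual trait SD (quantitative design).
#' @param baseline Trait mean at zero risk alleles (quantitative design).
#' @param seed Integer seed.
#' @param name Optional scenario label.
#' @return An object of class `sim_scenario`.
#' @export
sim_scenario <- function(design = c("case_control", "quantitative"),
                         k, mu, tau, raf_range, n_range,
                         prevalence = NA_real_, trait_sd = NA_real_,
                         baseline = 5.0, seed = 1L, name = NA_character_) {
  design <- match.arg(design)
  stopifnot(is.numeric(k), length(k) == 1L, k >= 1,
            is.numeric(mu), is.numeric(tau), length(raf_range) == 2L,
            length(n_range) == 2L)
  if (tau < 0) stop("`tau` must be non-negative", call. = FALSE)
  if (raf_range[1] > raf_range[2] || raf_range[1] <= 0 || raf_range[2] >= 1) {
    stop("`raf_range` must be an ordered range inside (0, 1)", call. = FALSE)
  }
  if (n_range[1] > n_range[2] || n_range[1] < 2) {
    stop("`n_range` must be an ordered range with lower bound >= 2",
         call. = FALSE)
  }
  if (design == "case_control" &&
      (!is.finite(prevalence) || prevalence <= 0 || prevalence >= 1)) {
    stop("case-control scenarios need a prevalence in (0, 1)", call. = FALSE)
  }
  if (design == "quantitative" && (!is.finite(trait_sd) || trait_sd < 0)) {
    stop("quantitative scenarios need a non-negative trait_sd", call. = FALSE)
  }
  structure(
    list(design = design, k = as.integer(k), mu = mu, tau = tau,
         raf_range = raf_range, n_range = n_range, prevalence = prevalence,
         trait_sd = trait_sd, baseline = baseline,
         seed = as.integer(seed), name = name),
    class = "sim_scenario"
  )
}

# Deterministic per-study substream seed; stays below 2^31 - 1.
substream_seed <- function(seed, i) {
  (((as.numeric(seed) %% 1000003) * 2039) + i * 9973) %% 2147483647
}

draw_study_params <- function(sc, i) {
  set.seed(substream_seed(sc$seed, i))
  list(theta = stats::rnorm(1, sc$mu, sc$tau),
       f = stats::runif(1, sc$raf_range[1], sc$raf_range[2]),
       n1 = as.integer(round(stats::runif(1, sc$n_range[1], sc$n_range[2]))),
       n2 = as.integer(round(stats::runif(1, sc$n_range[1], sc$n_range[2]))))
}

#' Simulate a multi-study case-control collection
#'
#' @param scenario A `sim_scenario` with `design = "case_control"`.
#' @return A case-control `study_table` of `k` studies with genotype
#'   counts, realized case/control risk-allele frequencies, and an HWE flag
#'   computed from the control genotypes.
#' @examples
#' sc <- scenario_library()$C
#' simulate_case_control_meta(sc)
#' @export
simulate_case_control_meta <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  if (scenario$design != "case_control") {
    stop("scenario design must be 'case_control'", call. = FALSE)
  }
  dose <- c(2, 1, 0)
  rows <- vector("list", scenario$k)
  for (i in seq_len(scenario$k)) {
    p <- draw_study_params(scenario, i)
    gam <- exp(p$theta)
    pf <- genotype_freqs_from_raf(p$f)
    X <- sum(pf * gam^dose)
    r0 <- scenario$prevalence / X
    if (r0 * max(gam^dose) >= 1) {
      stop("scenario implies genotype penetrance >= 1 in study ", i,
           call. = FALSE)
    }
    p_case <- pf * gam^dose / X
    p_ctrl <- pf * (1 - r0 * gam^dose) / (1 - scenario$prevalence)
    cc <- as.vector(stats::rmultinom(1, p$n1, p_case))
    kk <- as.vector(stats::rmultinom(1, p$n2, p_ctrl))
    hwe <- hwe_test(kk)
    rows[[i]] <- data.frame(
      study_id = sprintf("sim_cc_%03d", i), ethnicity = "simulated",
      snp_id = "rs_sim", risk_allele = "A",
      raf_case = (2 * cc[1] + cc[2]) / (2 * p$n1),
      raf_control = (2 * kk[1] + kk[2]) / (2 * p$n2),
      n_case = p$n1, n_control = p$n2,
      case_hom_risk = cc[1], case_het = cc[2], case_hom_other = cc[3],
      control_hom_risk = kk[1], control_het = kk[2], control_hom_other = kk[3],
      reported_or = NA_real_, or_ci_low = NA_real_, or_ci_high = NA_real_,
      hwe_ok = hwe$hwe_ok, stringsAsFactors = FALSE
    )
  }
  df <- do.call(rbind, rows)
  df$has_effect_pathway <- TRUE
  new_study_table(df, "case_control", "T2D")
}

#' Simulate a multi-study quantitative-trait collection
#'
#' Each study draws genotypes multinomially under HWE, subject traits
#' normally around `baseline + dose * theta_i`, and reports both the
#' per-genotype summaries (n, mean, SD) and the within-study per-allele
#' OLS slope with its standard error. If the genotype draw is degenerate
#' (zero allele-dose variance) it is redrawn, up to 100 attempts; if any
#' genotype class has fewer than 2 subjects the per-genotype summaries are
#' withheld (`NA`) and only the regression summary is emitted.
#'
#' @param scenario A `sim_scenario` with `design = "quantitative"`.
#' @return A quantitative `study_table` of `k` studies.
#' @export
simulate_quant_meta <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  if (scenario$design != "quantitative") {
    stop("scenario design must be 'quantitative'", call. = FALSE)
  }
  rows <- vector("list", scenario$k)
  for (i in seq_len(scenario$k)) {
    p <- draw_study_params(scenario, i)
    n <- p$n1
    pf <- genotype_freqs_from_raf(p$f)
    for (attempt in 1:100) {
      g <- as.vector(stats::rmultinom(1, n, pf))
      if (sum(g > 0) >= 2) break
    }
    if (sum(g > 0) < 2) {
      stop("degenerate genotype draw persisted in study ", i, call. = FALSE)
    }
    dose <- rep(c(2, 1, 0), g)
    y <- scenario$baseline + dose * p$theta +
      stats::rnorm(n, 0, scenario$trait_sd)
    xbar <- mean(dose)
    sxx <- sum((dose - xbar)^2)
    beta <- sum((dose - xbar) * (y - mean(y))) / sxx
    rss <- sum((y - mean(y) - beta * (dose - xbar))^2)
    se <- sqrt((rss / (n - 2)) / sxx)
    if (se == 0) se <- .Machine$double.eps  # noiseless limit
    per_geno <- rep(NA_real_, 9)
    if (all(g >= 2)) {
      stats_g <- function(d) c(sum(dose == d), mean(y[dose == d]),
                               stats::sd(y[dose == d]))
      per_geno <- c(stats_g(2), stats_g(1), stats_g(0))
      if (any(!is.finite(per_geno)) || any(per_geno[c(3, 6, 9)] <= 0)) {
        per_geno <- rep(NA_real_, 9)  # e.g. zero SD in the noiseless limit
      }
    }
    rows[[i]] <- data.frame(
      study_id = sprintf("sim_q_%03d", i), ethnicity = "simulated",
      snp_id = "rs_sim", risk_allele = "A",
      raf = (2 * g[1] + g[2]) / (2 * n), n = n, hwe_ok = hwe_test(g)$hwe_ok,
      beta = beta, beta_se = se,
      beta_ci_low = NA_real_, beta_ci_high = NA_real_, beta_p = NA_real_,
      n_hom_risk = per_geno[1], mean_hom_risk = per_geno[2],
      sd_hom_risk = per_geno[3],
      n_het = per_geno[4], mean_het = per_geno[5], sd_het = per_geno[6],
      n_hom_other = per_geno[7], mean_hom_other = per_geno[8],
      sd_hom_other = per_geno[9],
      stringsAsFactors = FALSE
    )
  }
  new_study_table(do.call(rbind, rows), "quantitative", "FG")
}

#' Named preset simulation scenarios
#'
#' `A` (`"g6pc2-fg-like"`): a quantitative collection shaped like the large
#' fasting-glucose meta-analyses (k = 32, mu = 0.07 mmol/l per allele,
#' tau = 0.01, allele frequencies 0.6-0.97). `B` (`"null-symmetric"`): a
#' null quantitative collection (mu = 0, tau = 0, k = 15) giving a
#' symmetric funnel, for type-I-error checks of the bias tests. `C`
#' (`"hetero-or"`): a heterogeneous case-control collection (k = 15,
#' mu = log 0.96, tau = 0.05, prevalence 8.8%).
#'
#' @param seed_A,seed_B,seed_C Seeds for the three presets.
#' @return A named list of `sim_scenario` objects (`A`, `B`, `C`).
#' @export
scenario_library <- function(seed_A = 101L, seed_B = 202L, seed_C = 303L) {
  list(
    A = sim_scenario("quantitative", k = 32, mu = 0.07, tau = 0.01,
                     raf_range = c(0.6, 0.97), n_range = c(300, 5000),
                     trait_sd = 0.8, baseline = 5.0, seed = seed_A,
                     name = "g6pc2-fg-like"),
    B = sim_scenario("quantitative", k = 15, mu = 0, tau = 0,
                     raf_range = c(0.3, 0.7), n_range = c(200, 2000),
                     trait_sd = 0.8, baseline = 5.0, seed = seed_B,
                     name = "null-symmetric"),
    C = sim_scenario("case_control", k = 15, mu = log(0.96), tau = 0.05,
                     raf_range = c(0.6, 0.9), n_range = c(1500, 3000),
                     prevalence = 0.088, seed = seed_C,
                     name = "hetero-or")
  )
}

#' Write a study table as delimited text
#'
#' Serializes numeric cells with 17 significant digits so that the matching
#' reader reproduces the table exactly.
#'
#' @param table A `study_table` of either kind.
#' @param path Output file path.
#' @param delim Field delimiter (default comma).
#' @return `path`, invisibly.
#' @export
write_study_table <- function(table, path, delim = ",") {
  stopifnot(inherits(table, "study_table"))
  kind <- attr(table, "kind")
  cols <- if (kind == "case_control") cc_columns else quant_columns
  out <- as.data.frame(table)[cols]
  for (col in names(out)) {
    if (is.numeric(out[[col]])) {
      out[[col]] <- ifelse(is.na(out[[col]]), "NA", sprintf("%.17g", out[[col]]))
    } else if (is.logical(out[[col]])) {
      out[[col]] <- ifelse(is.na(out[[col]]), "NA",
                           ifelse(out[[col]], "yes", "no"))
    }
  }
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.table(out, con, sep = delim, row.names = FALSE,
                     quote = FALSE, na = "NA")
  invisible(path)
}
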
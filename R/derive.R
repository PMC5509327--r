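#' Derive per-study effect sizes from a study table
#'
#' Turns each record of a `study_table` into an effect size, recording the
#' derivation pathway used.
#'
#' For case-control tables the pathways, in order of precedence, are:
#' `reported_or` (a published OR with its CI, SE recovered by
#' [se_from_ci()]), `counts` (genotype counts collapsed under the requested
#' genetic model by [or_from_counts()]), and `raf_reconstruction`
#' (Hardy-Weinberg expected counts from case and control allele
#' frequencies, then [or_from_counts()]). Published ORs are consumed as-is,
#' whatever covariate adjustment they carry; no regression is re-fit.
#'
#' For quantitative tables, `contrast = "beta"` takes the per-allele
#' regression coefficient with its SE recovered from `beta_se`, the CI or
#' the p-value (that precedence), falling back to a per-allele slope fit to
#' the per-genotype summaries by size-weighted least squares on allele dose
#' (residual variance approximated by the pooled within-genotype variance).
#' `contrast = "het_vs_ref"` / `"hom_vs_ref"` compute the standardized mean
#' difference of the het (resp. hom-risk) group against the hom-other
#' reference via [smd()].
#'
#' @param table A `study_table`.
#' @param model Genetic model for count-based case-control effects.
#' @param contrast Quantitative contrast (see Details).
#' @param correction Zero-cell handling passed to [or_from_counts()].
#' @param smd_flavor Passed to [smd()] for the SMD contrasts.
#' @return An `effect_frame` with extra columns `pathway`, `ethnicity` and
#'   `n`; records from which no effect can be derived are dropped, listed
#'   in `attr(, "skipped")` and reported via `message()`.
#' @export
derive_effects <- function(table,
                           model = c("allele", "dominant", "recessive", "additive"),
                           contrast = c("beta", "het_vs_ref", "hom_vs_ref"),
                           correction = c("haldane", "none"),
                           smd_flavor = c("cohen", "hedges")) {
  stopifnot(inherits(table, "study_table"))
  model <- match.arg(model)
  contrast <- match.arg(contrast)
  correction <- match.arg(correction)
  smd_flavor <- match.arg(smd_flavor)
  kind <- attr(table, "kind")
  rows <- vector("list", nrow(table))
  pathways <- character(nrow(table))
  for (i in seq_len(nrow(table))) {
    r <- table[i, ]
    d <- if (kind == "case_control") {
      derive_cc_effect(r, model, correction)
    } else {
      derive_quant_effect(r, contrast, smd_flavor)
    }
    pathways[i] <- d$pathway
    rows[[i]] <- d$row
  }
  skipped <- table$study_id[pathways == "none"]
  if (length(skipped)) {
    message(length(skipped), " record(s) without a derivable effect skipped: ",
            paste(skipped, collapse = ", "))
  }
  keep <- !vapply(rows, is.null, logical(1))
  if (!any(keep)) {
    out <- data.frame(study_id = character(0), estimate = numeric(0),
                      se = numeric(0), scale = character(0),
                      pathway = character(0), ethnicity = character(0),
                      n = numeric(0), stringsAsFactors = FALSE)
  } else {
    out <- do.call(rbind, rows[keep])
  }
  attr(out, "skipped") <- skipped
  class(out) <- c("effect_frame", "data.frame")
  out
}

effect_row <- function(e, pathway, ethnicity, n) {
  data.frame(study_id = e$study_id, estimate = e$estimate, se = e$se,
             scale = e$scale, pathway = pathway,
             ethnicity = ethnicity, n = n, stringsAsFactors = FALSE)
}

derive_cc_effect <- function(r, model, correction) {
  n <- r$n_case + r$n_control
  if (!is.na(r$reported_or) && !is.na(r$or_ci_low) && !is.na(r$or_ci_high)) {
    se <- se_from_ci(r$or_ci_low, r$or_ci_high, scale = "log")
    e <- effect_size(log(r$reported_or), se, scale = "log",
                     study_id = r$study_id)
    return(list(pathway = "reported_or",
                row = effect_row(e, "reported_or", r$ethnicity, n)))
  }
  case <- unlist(r[c("case_hom_risk", "case_het", "case_hom_other")])
  ctrl <- unlist(r[c("control_hom_risk", "control_het", "control_hom_other")])
  if (all(!is.na(case)) && all(!is.na(ctrl))) {
    e <- or_from_counts(case, ctrl, model = model, correction = correction,
                        study_id = r$study_id)
    return(list(pathway = "counts",
                row = effect_row(e, "counts", r$ethnicity, n)))
  }
  if (!is.na(r$raf_case) && !is.na(r$raf_control)) {
    e <- or_from_counts(reconstruct_counts(r$raf_case, r$n_case),
                        reconstruct_counts(r$raf_control, r$n_control),
                        model = model, correction = correction,
                        study_id = r$study_id)
    return(list(pathway = "raf_reconstruction",
                row = effect_row(e, "raf_reconstruction", r$ethnicity, n)))
  }
  list(pathway = "none", row = NULL)
}

derive_quant_effect <- function(r, contrast, smd_flavor) {
  if (contrast == "beta") {
    if (!is.na(r$beta)) {
      if (!is.na(r$beta_se)) {
        se <- r$beta_se; path <- "beta_se"
      } else if (!is.na(r$beta_ci_low) && !is.na(r$beta_ci_high)) {
        se <- se_from_ci(r$beta_ci_low, r$beta_ci_high)
        path <- "beta_ci"
      } else {
        se <- se_from_p(r$beta, r$beta_p); path <- "beta_p"
      }
      e <- effect_size(r$beta, se, scale = "identity", study_id = r$study_id)
      return(list(pathway = path, row = effect_row(e, path, r$ethnicity, r$n)))
    }
    fit <- genotype_ols(r)
    if (!is.null(fit)) {
      e <- effect_size(fit$beta, fit$se, scale = "identity",
                       study_id = r$study_id)
      return(list(pathway = "genotype_ols",
                  row = effect_row(e, "genotype_ols", r$ethnicity, r$n)))
    }
    return(list(pathway = "none", row = NULL))
  }
  # SMD contrasts against the hom-other (zero risk alleles) reference
  grp <- if (contrast == "het_vs_ref") "het" else "hom_risk"
  need <- c(paste0(c("n_", "mean_", "sd_"), grp),
            "n_hom_other", "mean_hom_other", "sd_hom_other")
  vals <- unlist(r[need])
  if (any(is.na(vals))) return(list(pathway = "none", row = NULL))
  e <- smd(vals[1], vals[2], vals[3], vals[4], vals[5], vals[6],
           flavor = smd_flavor, study_id = r$study_id)
  list(pathway = paste0("smd_", contrast),
       row = effect_row(e, paste0("smd_", contrast), r$ethnicity, r$n))
}

#' Subgroup meta-analysis of a study table
#'
#' Derives per-study effects with [derive_effects()] and pools them overall
#' and within each level of a grouping column. Levels with a single study
#' are passed through (the study's own estimate and SE) with heterogeneity
#' fields undefined; empty levels are skipped with a message.
#'
#' @inheritParams derive_effects
#' @param grouping Name of the grouping column (default `"ethnicity"`).
#' @param method `"random"` (default) or `"fixed"`.
#' @param level Confidence level.
#' @return A list with `overall` (a `meta_result`) and `subgroups` (a named
#'   list of `meta_result`, one per non-empty level).
#' @export
subgroup_meta <- function(table, grouping = "ethnicity",
                          model = "allele", contrast = "beta",
                          method = c("random", "fixed"), level = 0.95) {
  method <- match.arg(method)
  eff <- derive_effects(table, model = model, contrast = contrast)
  if (!nrow(eff)) stop("no derivable effects in this table", call. = FALSE)
  if (!grouping %in% names(eff)) {
    stop("grouping column '", grouping, "' not found", call. = FALSE)
  }
  pool1 <- function(sub) {
    if (nrow(sub) >= 2) {
      if (method == "random") dersimonian_laird(sub, level = level)
      else fixed_effect(sub, level = level)
    } else {
      fixed_effect(sub, level = level)  # k = 1 passthrough
    }
  }
  levels_seen <- unique(eff[[grouping]])
  subgroups <- list()
  for (lev in levels_seen) {
    sub <- eff[!is.na(eff[[grouping]]) & eff[[grouping]] == lev, , drop = FALSE]
    if (!nrow(sub)) {
      message("empty subgroup level skipped: ", lev)
      next
    }
    subgroups[[lev]] <- pool1(sub)
  }
  list(overall = pool1(eff), subgroups = subgroups)
}

# Size-weighted least-squares slope of group mean on allele dose (2, 1, 0),
# with residual variance approximated by the pooled within-genotype variance.
genotype_ols <- function(r) {
  ng <- unlist(r[c("n_hom_risk", "n_het", "n_hom_other")])
  mg <- unlist(r[c("mean_hom_risk", "mean_het", "mean_hom_other")])
  sg <- unlist(r[c("sd_hom_risk", "sd_het", "sd_hom_other")])
  if (any(is.na(c(ng, mg, sg))) || any(ng < 2)) return(NULL)
  dose <- c(2, 1, 0)
  n <- sum(ng)
  xbar <- sum(ng * dose) / n
  sxx <- sum(ng * (dose - xbar)^2)
  if (sxx <= 0) return(NULL)
  beta <- sum(ng * (dose - xbar) * mg) / sxx
  s2 <- sum((ng - 1) * sg^2) / (n - 3)
  list(beta = beta, se = sqrt(s2 / sxx))
}
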
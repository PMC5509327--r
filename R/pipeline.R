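#' Read a run configuration from YAML or JSON
#'
#' @param path Path to a YAML (or JSON) configuration file with the fields
#'   accepted by [run_analysis()].
#' @return The configuration as a named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
}

default_config <- function() {
  list(subgroup = "ethnicity", pooling = "random", alpha = 0.05,
       bias_tests = TRUE, sensitivity = TRUE,
       exclude_hwe_violations = FALSE, par = NULL,
       output_dir = NULL, seed = 1L)
}

#' Run the full meta-analysis pipeline from a configuration
#'
#' For each configured input cell (a study table restricted to one SNP and
#' outcome) and each genetic model or contrast, the pipeline derives
#' per-study effects (logging which pathway each study used), pools them
#' overall and within subgroups (random-effects by default), runs
#' leave-one-out sensitivity and the Egger/Begg bias tests where enough
#' studies exist, exports funnel data, and optionally computes the
#' population attributable risk from the pooled per-allele OR and pooled
#' risk-allele frequency. A failing cell is recorded and skipped; it does
#' not abort the run.
#'
#' The configuration is a list (or YAML/JSON file path) with entries:
#' `inputs` — a list of cells, each `list(label=, path=, kind=
#' "case_control"|"quantitative", snp=, models=|contrasts=)`;
#' `subgroup` (default `"ethnicity"`), `pooling` (`"random"`/`"fixed"`),
#' `alpha`, `bias_tests`, `sensitivity`, `exclude_hwe_violations`,
#' `par` (`list(f_method = "mean"|"inverse_variance", orient = TRUE)`),
#' `output_dir` (when set, CSV/JSON outputs are written there), `seed`.
#'
#' @param config A named list or path to a YAML/JSON file.
#' @return Invisibly, a result bundle: per-cell results (`effects`,
#'   `overall`, `subgroups`, `loo`, `bias`, `funnel`, `par`), the combined
#'   results table, the sensitivity table, cell-level `errors`, and the
#'   run `manifest`.
#' @export
run_analysis <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  cfg <- utils::modifyList(default_config(), config)
  if (is.null(cfg$inputs) || !length(cfg$inputs)) {
    stop("config must name at least one input cell", call. = FALSE)
  }
  set.seed(cfg$seed)
  level <- 1 - cfg$alpha
  pool <- if (identical(cfg$pooling, "fixed")) fixed_effect else dersimonian_laird
  cells <- list()
  errors <- list()
  result_rows <- list()
  sens_rows <- list()
  bias_rows <- list()
  pathway_rows <- list()

  for (cell in cfg$inputs) {
    label <- cell$label %||% paste0(cell$snp %||% "all", "_", cell$kind)
    out <- tryCatch(
      run_cell(cell, cfg, pool, level),
      error = function(e) e
    )
    if (inherits(out, "error")) {
      errors[[label]] <- conditionMessage(out)
      next
    }
    cells[[label]] <- out
    for (m in names(out$by_model)) {
      mm <- out$by_model[[m]]
      result_rows[[paste(label, m)]] <- mm$rows
      pathway_rows[[paste(label, m)]] <- mm$pathways
      if (!is.null(mm$sensitivity)) {
        sr <- mm$sensitivity
        sr <- cbind(cell = label, model = m, sr, stringsAsFactors = FALSE)
        sens_rows[[paste(label, m)]] <- sr
      }
      if (!is.null(mm$bias)) {
        bias_rows[[paste(label, m)]] <- data.frame(
          cell = label, model = m,
          egger_intercept = mm$bias$egger$intercept,
          egger_p = mm$bias$egger$p,
          begg_tau = mm$bias$begg$tau,
          begg_p = mm$bias$begg$p,
          k = mm$bias$egger$k,
          bias_suspected = mm$bias$egger$p <= 0.1 | mm$bias$begg$p <= 0.1,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!length(cells) && length(errors)) {
    warning("every cell failed; see $errors", call. = FALSE)
  }
  results_table <- if (length(result_rows)) do.call(rbind, unname(result_rows)) else NULL
  sensitivity_table <- if (length(sens_rows)) do.call(rbind, unname(sens_rows)) else NULL
  bias_table <- if (length(bias_rows)) do.call(rbind, unname(bias_rows)) else NULL
  pathway_table <- if (length(pathway_rows)) do.call(rbind, unname(pathway_rows)) else NULL

  manifest <- list(
    package = "genemeta",
    version = as.character(utils::packageVersion("genemeta")),
    seed = cfg$seed,
    config = cfg[setdiff(names(cfg), "output_dir")],
    config_md5 = config_hash(cfg[setdiff(names(cfg), "output_dir")])
  )
  bundle <- list(cells = cells, results = results_table,
                 sensitivity = sensitivity_table, bias = bias_table,
                 pathways = pathway_table, errors = errors,
                 manifest = manifest)
  class(bundle) <- "genemeta_bundle"
  if (!is.null(cfg$output_dir)) write_bundle(bundle, cfg$output_dir)
  invisible(bundle)
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA, null = "null")
  unname(tools::md5sum(tmp))
}

write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(bundle$results)) {
    write_results_table(bundle$results, file.path(dir, "results.csv"))
  }
  write_plain <- function(df, name) {
    if (is.null(df)) return(invisible(NULL))
    out <- df
    for (col in names(out)) {
      if (is.numeric(out[[col]])) {
        out[[col]] <- ifelse(is.na(out[[col]]), "NA", sprintf("%.17g", out[[col]]))
      }
    }
    utils::write.table(out, file.path(dir, name), sep = ",",
                       row.names = FALSE, quote = FALSE, na = "NA")
  }
  write_plain(bundle$sensitivity, "sensitivity.csv")
  write_plain(bundle$bias, "bias.csv")
  write_plain(bundle$pathways, "pathways.csv")
  funnel_rows <- list()
  for (label in names(bundle$cells)) {
    for (m in names(bundle$cells[[label]]$by_model)) {
      fd <- bundle$cells[[label]]$by_model[[m]]$funnel
      if (!is.null(fd)) {
        funnel_rows[[paste(label, m)]] <- cbind(cell = label, model = m,
                                                fd$studies,
                                                stringsAsFactors = FALSE)
      }
    }
  }
  if (length(funnel_rows)) {
    write_plain(do.call(rbind, unname(funnel_rows)), "funnel.csv")
  }
  jsonlite::write_json(bundle$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(dir)
}

run_cell <- function(cell, cfg, pool, level) {
  if (is.null(cell$kind)) stop("input cell lacks `kind`")
  tbl <- if (!is.null(cell$table)) {
    cell$table
  } else if (cell$kind == "case_control") {
    suppressWarnings(read_case_control_table(cell$path))
  } else {
    read_quant_table(cell$path)
  }
  if (!is.null(cell$snp)) {
    tbl <- if (cell$kind == "quantitative" &&
               any(grepl(";", tbl$snp_id, fixed = TRUE))) {
      quant_for_snp(tbl, cell$snp)
    } else {
      new_study_table(tbl[!is.na(tbl$snp_id) & tbl$snp_id == cell$snp, ,
                          drop = FALSE],
                      attr(tbl, "kind"), attr(tbl, "outcome"))
    }
  }
  if (isTRUE(cfg$exclude_hwe_violations)) {
    keep <- is.na(tbl$hwe_ok) | tbl$hwe_ok
    tbl <- new_study_table(tbl[keep, , drop = FALSE],
                           attr(tbl, "kind"), attr(tbl, "outcome"))
  }
  if (!nrow(tbl)) stop("no studies left for this cell")
  specs <- if (cell$kind == "case_control") {
    cell$models %||% "allele"
  } else {
    cell$contrasts %||% "beta"
  }
  by_model <- list()
  for (m in specs) {
    eff <- if (cell$kind == "case_control") {
      suppressMessages(derive_effects(tbl, model = m))
    } else {
      suppressMessages(derive_effects(tbl, contrast = m))
    }
    if (!nrow(eff)) stop("no derivable effects under '", m, "'")
    overall <- if (nrow(eff) >= 2) pool(eff, level = level) else
      fixed_effect(eff, level = level)
    rows <- meta_result_row(overall, snp = cell$snp %||% NA_character_,
                            subgroup = "overall", model = m)
    subgroups <- list()
    if (!is.null(cfg$subgroup) && cfg$subgroup %in% names(eff)) {
      for (lev in unique(eff[[cfg$subgroup]])) {
        sub <- eff[eff[[cfg$subgroup]] == lev, , drop = FALSE]
        if (!nrow(sub)) next
        res <- if (nrow(sub) >= 2) pool(sub, level = level) else
          fixed_effect(sub, level = level)
        subgroups[[lev]] <- res
        rows <- rbind(rows, meta_result_row(res, snp = cell$snp %||% NA_character_,
                                            subgroup = lev, model = m))
      }
    }
    sens <- if (isTRUE(cfg$sensitivity) && nrow(eff) >= 3) {
      sensitivity_report(eff, method = overall$method, level = level)
    } else NULL
    bias <- if (isTRUE(cfg$bias_tests) && nrow(eff) >= 3 &&
                diff(range(eff$se)) > 0) {
      list(egger = egger_test(eff), begg = suppressMessages(begg_test(eff)))
    } else NULL
    par_res <- NULL
    if (!is.null(cfg$par) && overall$scale == "log") {
      f_method <- cfg$par$f_method %||% "mean"
      fcol <- tbl$raf_control %||% tbl$raf
      fvals <- fcol[!is.na(fcol)]
      if (length(fvals)) {
        fpool <- pooled_raf(fvals, n = (tbl$n_case + tbl$n_control)[!is.na(fcol)],
                            method = f_method)
        par_res <- par_multiplicative(fpool, exp(overall$estimate),
                                      orient = isTRUE(cfg$par$orient))
      }
    }
    by_model[[m]] <- list(effects = eff, overall = overall,
                          subgroups = subgroups, rows = rows,
                          sensitivity = sens, bias = bias,
                          funnel = funnel_data(eff, overall, level = level),
                          par = par_res,
                          pathways = data.frame(study_id = eff$study_id,
                                                model = m,
                                                pathway = eff$pathway,
                                                stringsAsFactors = FALSE))
  }
  list(table = tbl, by_model = by_model)
}

#' Leave-one-out sensitivity table
#'
#' Re-pools the collection omitting each study in turn and flags omissions
#' whose study's own estimate lies outside the parent pooled confidence
#' interval (i.e. influential outliers).
#'
#' @param effects An `effect_frame` with at least 3 studies.
#' @param method `"random"` (default) or `"fixed"`, matching the parent
#'   pool.
#' @param level Confidence level.
#' @return A data frame with one row per omitted study: the re-pooled
#'   estimate and CI (reporting scale), p, tau2, the omitted study's own
#'   estimate, and `flagged`.
#' @export
sensitivity_report <- function(effects, method = c("random", "fixed"),
                               level = 0.95) {
  method <- match.arg(method)
  effects <- as_effect_frame(effects)
  parent <- if (method == "random") dersimonian_laird(effects, level = level)
            else fixed_effect(effects, level = level)
  loo <- leave_one_out(effects, method = method, level = level)
  to_report <- if (parent$scale == "log") exp else identity
  own <- to_report(effects$estimate)
  data.frame(
    omitted = effects$study_id,
    k = vapply(loo, function(x) x$k, numeric(1)),
    estimate = vapply(loo, function(x) to_report(x$estimate), numeric(1)),
    ci_low = vapply(loo, function(x) x$ci[1], numeric(1)),
    ci_high = vapply(loo, function(x) x$ci[2], numeric(1)),
    p = vapply(loo, function(x) x$p, numeric(1)),
    tau2 = vapply(loo, function(x) x$tau2, numeric(1)),
    study_estimate = own,
    flagged = own < parent$ci[1] | own > parent$ci[2],
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}
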
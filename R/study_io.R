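#' @name study_io
#' @title Study-table input and output
#'
#' @description
#' Study-level summary tables are delimited text (UTF-8, comma by default,
#' tab selectable) with a required header and the literal `NA` (or an empty
#' cell) for missing values. Parsing is locale-independent: decimal points
#' only, no thousands separators.
#'
#' Two schemas are supported. Case-control tables carry one row per study
#' with columns `study_id, ethnicity, snp_id, risk_allele, raf_case,
#' raf_control, n_case, n_control, case_hom_risk, case_het, case_hom_other,
#' control_hom_risk, control_het, control_hom_other, reported_or, or_ci_low,
#' or_ci_high, hwe_ok`. Quantitative-trait tables carry `study_id,
#' ethnicity, snp_id, risk_allele, raf, n, hwe_ok, beta, beta_se,
#' beta_ci_low, beta_ci_high, beta_p, n_hom_risk, mean_hom_risk,
#' sd_hom_risk, n_het, mean_het, sd_het, n_hom_other, mean_hom_other,
#' sd_hom_other`. Genotype triples are ordered (hom-risk, het, hom-other),
#' with the risk allele named per row. In quantitative tables a study typed
#' at several loci may carry semicolon-joined `snp_id`, `risk_allele` and
#' `raf` cells; [quant_for_snp()] expands these to a single-locus view.
#'
#' The packaged `G6PC2` tables (see [g6pc2_t2d_studies()] and
#' [g6pc2_fg_studies()]) transcribe published study characteristics; note
#' that their single per-study allele frequency is stored as `raf_control`
#' although the source tables do not state whether it is a case, control or
#' combined frequency.
NULL

cc_columns <- c("study_id", "ethnicity", "snp_id", "risk_allele",
                "raf_case", "raf_control", "n_case", "n_control",
                "case_hom_risk", "case_het", "case_hom_other",
                "control_hom_risk", "control_het", "control_hom_other",
                "reported_or", "or_ci_low", "or_ci_high", "hwe_ok")

quant_columns <- c("study_id", "ethnicity", "snp_id", "risk_allele", "raf",
                   "n", "hwe_ok", "beta", "beta_se", "beta_ci_low",
                   "beta_ci_high", "beta_p", "n_hom_risk", "mean_hom_risk",
                   "sd_hom_risk", "n_het", "mean_het", "sd_het",
                   "n_hom_other", "mean_hom_other", "sd_hom_other")

read_raw_table <- function(path, delim) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.table(path, header = TRUE, sep = delim, quote = "\"",
                    colClasses = "character", stringsAsFactors = FALSE,
                    na.strings = character(0), check.names = FALSE,
                    fileEncoding = "UTF-8", strip.white = TRUE)
}

# Strict numeric parser: decimal point only, no grouping separators.
parse_num <- function(x, column, integer = FALSE) {
  x[x == "" | x == "NA"] <- NA_character_
  pattern <- if (integer) "^[+-]?[0-9]+$" else
    "^[+-]?([0-9]+\\.?[0-9]*|\\.[0-9]+)([eE][+-]?[0-9]+)?$"
  bad <- !is.na(x) & !grepl(pattern, x)
  if (any(bad)) {
    stop(sprintf("malformed numeric cell in column '%s', row %d: '%s'",
                 column, which(bad)[1], x[which(bad)[1]]), call. = FALSE)
  }
  as.numeric(x)
}

parse_logical <- function(x, column) {
  x[x == "" | x == "NA"] <- NA_character_
  lx <- tolower(x)
  out <- rep(NA, length(x))
  out[lx %in% c("yes", "true", "1")] <- TRUE
  out[lx %in% c("no", "false", "0")] <- FALSE
  bad <- !is.na(x) & is.na(out)
  if (any(bad)) {
    stop(sprintf("unrecognized value in logical column '%s', row %d: '%s'",
                 column, which(bad)[1], x[which(bad)[1]]), call. = FALSE)
  }
  out
}

parse_char <- function(x) {
  x[x == "" | x == "NA"] <- NA_character_
  x
}

check_columns <- function(raw, expected, path) {
  missing <- setdiff(expected, names(raw))
  if (length(missing)) {
    stop("header of ", path, " lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
}

validation_error <- function(msgs) {
  stop("study table validation failed:\n  ",
       paste(msgs, collapse = "\n  "), call. = FALSE)
}

check_unique_ids <- function(ids) {
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    validation_error(paste0("duplicate study_id: ", paste(dup, collapse = ", ")))
  }
}

new_study_table <- function(df, kind, outcome) {
  rownames(df) <- NULL
  structure(df, kind = kind, outcome = outcome,
            class = c("study_table", "data.frame"))
}

#' Read a case-control study table
#'
#' See [study_io] for the schema. Structural violations (counts that do not
#' sum to the stated sample size, inverted confidence bounds, frequencies
#' outside `[0, 1]`) are errors naming the offending record; rows from which
#' no effect size can ever be derived (no genotype counts, no case+control
#' allele frequencies, no reported OR) are retained with
#' `has_effect_pathway = FALSE` and a warning, since published summary
#' tables legitimately defer per-study effects to figures.
#'
#' @param path Path to a delimited text file.
#' @param delim Field delimiter, `","` (default) or `"\t"`.
#' @return A `study_table` data frame (one validated row per study) with
#'   attributes `kind = "case_control"` and `outcome = "T2D"`.
#' @export
read_case_control_table <- function(path, delim = ",") {
  raw <- read_raw_table(path, delim)
  check_columns(raw, cc_columns, path)
  num_int <- c("n_case", "n_control")
  num_real <- c("raf_case", "raf_control", "case_hom_risk", "case_het",
                "case_hom_other", "control_hom_risk", "control_het",
                "control_hom_other", "reported_or", "or_ci_low", "or_ci_high")
  df <- data.frame(study_id = parse_char(raw$study_id),
                   ethnicity = parse_char(raw$ethnicity),
                   snp_id = parse_char(raw$snp_id),
                   risk_allele = parse_char(raw$risk_allele),
                   stringsAsFactors = FALSE)
  for (col in num_int) df[[col]] <- parse_num(raw[[col]], col, integer = TRUE)
  for (col in num_real) df[[col]] <- parse_num(raw[[col]], col)
  df$hwe_ok <- parse_logical(raw$hwe_ok, "hwe_ok")
  df <- df[cc_columns]
  if (!nrow(df)) return(new_study_table(df, "case_control", "T2D"))

  msgs <- character(0)
  rec <- function(i) sprintf("record %d (%s)", i, df$study_id[i])
  check_unique_ids(df$study_id)
  for (i in seq_len(nrow(df))) {
    r <- df[i, ]
    if (is.na(r$n_case) || r$n_case <= 0 || is.na(r$n_control) || r$n_control <= 0) {
      msgs <- c(msgs, paste0(rec(i), ": n_case and n_control must be positive"))
      next
    }
    for (fcol in c("raf_case", "raf_control")) {
      if (!is.na(r[[fcol]]) && (r[[fcol]] < 0 || r[[fcol]] > 1)) {
        msgs <- c(msgs, paste0(rec(i), ": ", fcol, " outside [0,1]"))
      }
    }
    cg <- unlist(r[c("case_hom_risk", "case_het", "case_hom_other")])
    kg <- unlist(r[c("control_hom_risk", "control_het", "control_hom_other")])
    for (side in list(list(g = cg, n = r$n_case, lab = "case"),
                      list(g = kg, n = r$n_control, lab = "control"))) {
      if (all(!is.na(side$g))) {
        if (any(side$g < 0)) {
          msgs <- c(msgs, paste0(rec(i), ": negative ", side$lab, " genotype count"))
        } else if (abs(sum(side$g) - side$n) > 1e-8) {
          msgs <- c(msgs, sprintf("%s: %s genotype counts sum to %s but n_%s = %s",
                                  rec(i), side$lab, format(sum(side$g)),
                                  side$lab, format(side$n)))
        }
      } else if (any(!is.na(side$g))) {
        msgs <- c(msgs, paste0(rec(i), ": incomplete ", side$lab, " genotype triple"))
      }
    }
    if (!is.na(r$reported_or) && r$reported_or <= 0) {
      msgs <- c(msgs, paste0(rec(i), ": reported_or must be positive"))
    }
    if (!is.na(r$or_ci_low) && !is.na(r$or_ci_high) && !is.na(r$reported_or)) {
      if (!(r$or_ci_low < r$reported_or && r$reported_or < r$or_ci_high)) {
        msgs <- c(msgs, paste0(rec(i), ": reported CI does not bracket the OR"))
      }
    }
  }
  if (length(msgs)) validation_error(msgs)

  has_counts <- stats::complete.cases(
    df[c("case_hom_risk", "case_het", "case_hom_other",
         "control_hom_risk", "control_het", "control_hom_other")])
  has_or <- !is.na(df$reported_or) &
    !is.na(df$or_ci_low) & !is.na(df$or_ci_high)
  has_raf <- !is.na(df$raf_case) & !is.na(df$raf_control)
  df$has_effect_pathway <- has_counts | has_or | has_raf
  if (any(!df$has_effect_pathway)) {
    warning(sum(!df$has_effect_pathway),
            " record(s) carry no derivable effect size ",
            "(no counts, no reported OR/CI, no case+control RAF)",
            call. = FALSE)
  }
  new_study_table(df, "case_control", "T2D")
}

#' Read a quantitative-trait study table
#'
#' See [study_io] for the schema. Rows reporting a per-allele regression
#' coefficient must carry at least one of `beta_se`, `beta_ci_*` or
#' `beta_p` (precedence in that order when several are present); rows may
#' instead (or additionally) report per-genotype summaries, whose group
#' sizes must sum to `n` and whose SDs must be positive.
#'
#' @inheritParams read_case_control_table
#' @return A `study_table` data frame with attributes
#'   `kind = "quantitative"` and `outcome = "FG"`.
#' @export
read_quant_table <- function(path, delim = ",") {
  raw <- read_raw_table(path, delim)
  check_columns(raw, quant_columns, path)
  df <- data.frame(study_id = parse_char(raw$study_id),
                   ethnicity = parse_char(raw$ethnicity),
                   snp_id = parse_char(raw$snp_id),
                   risk_allele = parse_char(raw$risk_allele),
                   raf = parse_char(raw$raf),  # may be semicolon-joined
                   stringsAsFactors = FALSE)
  df$n <- parse_num(raw$n, "n", integer = TRUE)
  df$hwe_ok <- parse_logical(raw$hwe_ok, "hwe_ok")
  for (col in c("beta", "beta_se", "beta_ci_low", "beta_ci_high", "beta_p",
                "n_hom_risk", "mean_hom_risk", "sd_hom_risk",
                "n_het", "mean_het", "sd_het",
                "n_hom_other", "mean_hom_other", "sd_hom_other")) {
    df[[col]] <- parse_num(raw[[col]], col)
  }
  # single-locus raf cells become numeric; multi-locus cells stay character
  multi <- !is.na(df$snp_id) & grepl(";", df$snp_id, fixed = TRUE)
  raf_num <- suppressWarnings(as.numeric(df$raf))
  if (any(!multi & !is.na(df$raf) & is.na(raf_num))) {
    bad <- which(!multi & !is.na(df$raf) & is.na(raf_num))[1]
    stop(sprintf("malformed numeric cell in column 'raf', row %d: '%s'",
                 bad, df$raf[bad]), call. = FALSE)
  }
  df <- df[quant_columns]
  if (!nrow(df)) return(new_study_table(df, "quantitative", "FG"))

  msgs <- character(0)
  rec <- function(i) sprintf("record %d (%s)", i, df$study_id[i])
  check_unique_ids(df$study_id)
  geno_n <- c("n_hom_risk", "n_het", "n_hom_other")
  geno_sd <- c("sd_hom_risk", "sd_het", "sd_hom_other")
  for (i in seq_len(nrow(df))) {
    r <- df[i, ]
    if (is.na(r$n) || r$n <= 0) {
      msgs <- c(msgs, paste0(rec(i), ": n must be positive"))
      next
    }
    fr <- raf_values(r$raf)
    if (any(!is.na(fr) & (fr < 0 | fr > 1))) {
      msgs <- c(msgs, paste0(rec(i), ": raf outside [0,1]"))
    }
    if (!is.na(r$beta)) {
      has_ci <- !is.na(r$beta_ci_low) && !is.na(r$beta_ci_high)
      if (is.na(r$beta_se) && !has_ci && is.na(r$beta_p)) {
        msgs <- c(msgs, paste0(rec(i),
          ": beta present but none of beta_se, beta_ci, beta_p supplied"))
      }
      if (!is.na(r$beta_se) && r$beta_se <= 0) {
        msgs <- c(msgs, paste0(rec(i), ": beta_se must be positive"))
      }
      if (has_ci && r$beta_ci_low >= r$beta_ci_high) {
        msgs <- c(msgs, paste0(rec(i), ": beta CI bounds out of order"))
      }
    }
    gn <- unlist(r[geno_n])
    if (all(!is.na(gn))) {
      if (any(gn < 0)) {
        msgs <- c(msgs, paste0(rec(i), ": negative genotype group size"))
      } else if (abs(sum(gn) - r$n) > 1e-8) {
        msgs <- c(msgs, sprintf("%s: genotype group sizes sum to %s but n = %s",
                                rec(i), format(sum(gn)), format(r$n)))
      }
      sds <- unlist(r[geno_sd])
      if (any(!is.na(sds) & sds <= 0)) {
        msgs <- c(msgs, paste0(rec(i), ": genotype SDs must be positive"))
      }
    } else if (any(!is.na(gn))) {
      msgs <- c(msgs, paste0(rec(i), ": incomplete genotype group sizes"))
    }
  }
  if (length(msgs)) validation_error(msgs)
  if (!any(multi)) df$raf <- raf_num  # single-locus table: numeric raf
  new_study_table(df, "quantitative", "FG")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

raf_values <- function(cell) {
  if (is.na(cell)) return(NA_real_)
  parts <- trimws(strsplit(cell, ";", fixed = TRUE)[[1]])
  parts[parts == "NA" | parts == ""] <- NA_character_
  suppressWarnings(as.numeric(parts))
}

#' Single-locus view of a (possibly multi-locus) quantitative table
#'
#' Selects the rows of a quantitative `study_table` typed at `snp` and
#' resolves semicolon-joined `snp_id`/`risk_allele`/`raf` cells to that
#' locus.
#'
#' @param table A quantitative `study_table`.
#' @param snp SNP identifier, e.g. `"rs560887"`.
#' @return A `study_table` with scalar `snp_id`, `risk_allele` and numeric
#'   `raf` columns.
#' @export
quant_for_snp <- function(table, snp) {
  stopifnot(inherits(table, "study_table"))
  ids <- strsplit(table$snp_id, ";", fixed = TRUE)
  hit <- vapply(ids, function(x) snp %in% trimws(x), logical(1))
  out <- table[hit, , drop = FALSE]
  if (!nrow(out)) {
    return(new_study_table(out, attr(table, "kind"), attr(table, "outcome")))
  }
  pos <- vapply(ids[hit], function(x) match(snp, trimws(x)), integer(1))
  pick <- function(cell, j) {
    parts <- trimws(strsplit(cell, ";", fixed = TRUE)[[1]])
    if (j <= length(parts)) parts[j] else NA_character_
  }
  out$snp_id <- snp
  out$risk_allele <- mapply(pick, out$risk_allele, pos, USE.NAMES = FALSE)
  raf_chr <- mapply(pick, out$raf, pos, USE.NAMES = FALSE)
  raf_chr[raf_chr %in% c("NA", "")] <- NA_character_
  out$raf <- as.numeric(raf_chr)
  new_study_table(out, attr(table, "kind"), attr(table, "outcome"))
}

#' Packaged G6PC2 type-2-diabetes case-control table
#'
#' Eighteen case-control studies of *G6PC2* variants (15 at rs560887, 3 at
#' rs16856187) transcribed from the published study-characteristics table:
#' sample sizes, the printed FG-raising-allele frequency (stored as
#' `raf_control`; the source does not state which group it refers to) and
#' the Hardy-Weinberg flag. Per-study odds ratios were published only in
#' forest-plot figures and are therefore absent.
#'
#' @return A case-control `study_table` with 18 rows.
#' @export
g6pc2_t2d_studies <- function() {
  path <- system.file("extdata", "g6pc2_t2d_studies.csv", package = "genemeta",
                      mustWork = TRUE)
  suppressWarnings(read_case_control_table(path))
}

#' Packaged G6PC2 fasting-glucose study table
#'
#' Thirty-five quantitative-trait studies (32 typed at rs560887, 5 of which
#' also at rs573225, and 3 at rs16856187) transcribed from the published
#' study-characteristics table: sample sizes, FG-raising alleles with their
#' frequencies, and Hardy-Weinberg flags. Per-study regression coefficients
#' and per-genotype glucose summaries were published only in figures and
#' are therefore absent.
#'
#' @return A quantitative `study_table` with 35 rows.
#' @export
g6pc2_fg_studies <- function() {
  path <- system.file("extdata", "g6pc2_fg_studies.csv", package = "genemeta",
                      mustWork = TRUE)
  read_quant_table(path)
}

results_columns <- c("snp", "subgroup", "model", "k", "n", "estimate",
                     "ci_low", "ci_high", "p", "Q", "i2", "i2_ci_low",
                     "i2_ci_high", "h2", "tau2")

#' One results-table row from a pooled result
#'
#' @param x A `meta_result`.
#' @param snp,subgroup,model Labels for the row.
#' @return A one-row data frame in the [write_results_table()] schema, with
#'   ratio estimates reported on the natural (OR) scale.
#' @export
meta_result_row <- function(x, snp = NA_character_, subgroup = "overall",
                            model = NA_character_) {
  stopifnot(inherits(x, "meta_result"))
  est <- if (x$scale == "log") exp(x$estimate) else x$estimate
  data.frame(snp = snp, subgroup = subgroup, model = model,
             k = x$k, n = x$n_total, estimate = est,
             ci_low = x$ci[1], ci_high = x$ci[2], p = x$p,
             Q = if (x$df >= 1) x$Q else NA_real_,
             i2 = x$i2, i2_ci_low = x$i2_ci[1], i2_ci_high = x$i2_ci[2],
             h2 = x$h2, tau2 = if (x$df >= 1) x$tau2 else NA_real_,
             stringsAsFactors = FALSE)
}

#' Write pooled results as delimited text
#'
#' Numbers are serialized with 17 significant digits so that
#' [read_results_table()] reproduces the written values bit-identically.
#'
#' @param results A data frame of [meta_result_row()] rows, or a list of
#'   `meta_result` objects (labels then default from list names).
#' @param path Output file path.
#' @param delim Field delimiter (default comma).
#' @return `path`, invisibly.
#' @export
write_results_table <- function(results, path, delim = ",") {
  if (is.list(results) && !is.data.frame(results)) {
    if (!length(results)) stop("`results` is empty", call. = FALSE)
    nm <- names(results) %||% rep(NA_character_, length(results))
    results <- do.call(rbind, Map(function(r, s) meta_result_row(r, subgroup = s),
                                  results, nm))
  }
  if (!is.data.frame(results) || !nrow(results)) {
    stop("`results` must be a non-empty data frame or list of meta_result",
         call. = FALSE)
  }
  missing <- setdiff(results_columns, names(results))
  if (length(missing)) {
    stop("results lack column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  out <- results[results_columns]
  for (col in names(out)) {
    if (is.numeric(out[[col]])) {
      out[[col]] <- ifelse(is.na(out[[col]]), "NA",
                           sprintf("%.17g", out[[col]]))
    }
  }
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.table(out, con, sep = delim, row.names = FALSE,
                     quote = FALSE, na = "NA")
  invisible(path)
}

#' Read back a results table written by [write_results_table()]
#'
#' @inheritParams read_case_control_table
#' @return A data frame with the [write_results_table()] columns.
#' @export
read_results_table <- function(path, delim = ",") {
  raw <- read_raw_table(path, delim)
  check_columns(raw, results_columns, path)
  df <- data.frame(snp = parse_char(raw$snp),
                   subgroup = parse_char(raw$subgroup),
                   model = parse_char(raw$model),
                   stringsAsFactors = FALSE)
  for (col in setdiff(results_columns, c("snp", "subgroup", "model"))) {
    df[[col]] <- parse_num(raw[[col]], col)
  }
  df[results_columns]
}
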
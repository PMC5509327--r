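test_that("packaged case-control table matches the published study accounting", {
  # reading the raw fixture warns that no per-study effects are derivable
  raw_path <- system.file("extdata", "g6pc2_t2d_studies.csv",
                          package = "genemeta")
  expect_warning(read_case_control_table(raw_path), "no derivable effect")
  tbl <- g6pc2_t2d_studies()
  expect_s3_class(tbl, "study_table")
  expect_equal(nrow(tbl), 18L)
  expect_equal(sum(tbl$snp_id == "rs560887"), 15L)
  expect_equal(sum(tbl$snp_id == "rs16856187"), 3L)
  expect_false(any(duplicated(tbl$study_id)))
  # printed NA cells stay missing, never zero
  expect_true(all(is.na(tbl$raf_control[tbl$study_id == "Prokopenko2009_DGI"])))
  expect_identical(tbl$hwe_ok[tbl$study_id == "Prokopenko2009_DGI"], NA)
})

test_that("packaged quantitative table carries 35 records across three loci", {
  tbl <- g6pc2_fg_studies()
  expect_equal(nrow(tbl), 35L)
  has <- function(snp) vapply(strsplit(tbl$snp_id, ";"),
                              function(x) snp %in% x, logical(1))
  expect_equal(sum(has("rs560887")), 32L)
  expect_equal(sum(has("rs573225")), 5L)
  expect_equal(sum(has("rs16856187")), 3L)
  # the rs573225 studies are a subset of the rs560887 ones
  expect_true(all(has("rs560887")[has("rs573225")]))

  r560 <- quant_for_snp(tbl, "rs560887")
  expect_equal(nrow(r560), 32L)
  expect_equal(unique(r560$snp_id), "rs560887")
  expect_true(is.numeric(r560$raf))
  expect_equal(as.vector(table(r560$ethnicity)[c("Caucasian", "Asian",
                                                 "African-American", "mixed")]),
               c(23L, 5L, 3L, 1L))
  r573 <- quant_for_snp(tbl, "rs573225")
  expect_equal(r573$raf[r573$study_id == "Baerenwald2013_DESIRCohort"], 0.670)
  expect_true(all(is.na(r573$raf[r573$study_id != "Baerenwald2013_DESIRCohort"])))
})

test_that("an empty table with only a header yields zero records", {
  tbl <- read_case_control_table(write_cc_csv(character(0)))
  expect_s3_class(tbl, "study_table")
  expect_equal(nrow(tbl), 0L)
  expect_equal(nrow(read_quant_table(write_quant_csv(character(0)))), 0L)
})

test_that("structural violations are reported as errors naming the record", {
  # genotype counts not summing to the stated sample size
  bad <- write_cc_csv(cc_row(counts_case = c("10", "20", "70"), n_case = "90"))
  expect_error(read_case_control_table(bad), "record 1 \\(s1\\).*sum to 100.*n_case = 90")
  # malformed numeric cell names row and column
  bad2 <- write_cc_csv(cc_row(n_case = "12x"))
  expect_error(read_case_control_table(bad2), "column 'n_case', row 1")
  # locale numerals (decimal comma) are rejected, not silently reinterpreted
  comma_file <- write_quant_csv(quant_row(beta = "0.5", beta_se = "0.01"))
  tsv <- tempfile(fileext = ".tsv")
  lines <- gsub(",", "\t", readLines(comma_file), fixed = TRUE)
  lines[2] <- sub("0\\.5", "0,5", lines[2])
  writeLines(lines, tsv)
  expect_error(read_quant_table(tsv, delim = "\t"), "column 'beta', row 1")
  # CI must bracket the reported OR
  bad4 <- write_cc_csv(cc_row(reported_or = "2.0", ci = c("0.5", "1.5")))
  expect_error(read_case_control_table(bad4), "bracket")
  # beta without any of se / ci / p
  bad5 <- write_quant_csv(quant_row(beta = "0.07"))
  expect_error(read_quant_table(bad5), "none of beta_se")
  # non-positive genotype SD
  bad6 <- write_quant_csv(quant_row(
    geno = c("90", "5.3", "0.6", "420", "5.2", "0", "490", "5.1", "0.6")))
  expect_error(read_quant_table(bad6), "SDs must be positive")
  # duplicated study ids
  bad7 <- write_cc_csv(c(cc_row(), cc_row()))
  expect_error(read_case_control_table(bad7), "duplicate study_id")
})

test_that("rows without any effect pathway are kept but flagged", {
  p <- write_cc_csv(c(
    cc_row(study_id = "a", counts_case = rep("NA", 3),
           counts_control = rep("NA", 3), raf_control = "NA"),
    cc_row(study_id = "b")
  ))
  expect_warning(tbl <- read_case_control_table(p), "1 record")
  expect_equal(tbl$has_effect_pathway, c(FALSE, TRUE))
})

test_that("beta rows and per-genotype rows are both accepted", {
  p <- write_quant_csv(c(
    quant_row(study_id = "a", beta = "0.075", beta_se = "0.003"),
    quant_row(study_id = "b", n = "1000",
              geno = c("90", "5.31", "0.62", "420", "5.25", "0.60",
                       "490", "5.20", "0.61"))
  ))
  tbl <- read_quant_table(p)
  expect_equal(nrow(tbl), 2L)
  expect_equal(tbl$beta[1], 0.075)
  expect_equal(tbl$n_hom_risk[2], 90)
})

test_that("results tables round-trip bit-identically through write and read", {
  res <- dersimonian_laird(make_effects(c(0.03, 0.11, 0.07, 0.05),
                                        c(0.011, 0.04, 0.02, 0.013)))
  row <- meta_result_row(res, snp = "rs1", subgroup = "overall", model = "additive")
  row2 <- meta_result_row(fixed_effect(make_effects(0.1, 0.02)),
                          snp = "rs1", subgroup = "Mexico", model = "additive")
  path <- tempfile(fileext = ".csv")
  write_results_table(rbind(row, row2), path)
  back <- read_results_table(path)
  expect_identical(back$estimate, c(row$estimate, row2$estimate))
  expect_identical(back$tau2[1], row$tau2)
  expect_identical(back$i2_ci_low[1], row$i2_ci_low)
  expect_true(is.na(back$Q[2]))  # k = 1 row has no heterogeneity
  # rewriting the re-read table reproduces the file byte for byte
  path2 <- tempfile(fileext = ".csv")
  write_results_table(back, path2)
  expect_identical(readLines(path), readLines(path2))
  expect_error(write_results_table(list(), tempfile()), "empty")
})

test_that("study tables round-trip through the writer and reader", {
  sc <- scenario_library()
  cc <- simulate_case_control_meta(sc$C)
  p <- tempfile(fileext = ".csv")
  write_study_table(cc, p)
  back <- read_case_control_table(p)
  expect_equal(as.data.frame(back), as.data.frame(cc)[names(back)],
               ignore_attr = TRUE)
  qt <- simulate_quant_meta(sc$B)
  p2 <- tempfile(fileext = ".csv")
  write_study_table(qt, p2)
  back2 <- read_quant_table(p2)
  expect_equal(as.data.frame(back2), as.data.frame(qt)[names(back2)],
               ignore_attr = TRUE)
})

test_that("tab-delimited input is supported via the dialect switch", {
  p <- tempfile(fileext = ".tsv")
  comma <- write_cc_csv(cc_row())
  writeLines(gsub(",", "\t", readLines(comma), fixed = TRUE), p)
  tbl <- read_case_control_table(p, delim = "\t")
  expect_equal(nrow(tbl), 1L)
  expect_equal(tbl$raf_control, 0.5)
})
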
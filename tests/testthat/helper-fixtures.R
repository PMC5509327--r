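# Shared builders for tiny in-code fixtures.

make_effects <- function(y, se, scale = "identity",
                         ids = sprintf("s%02d", seq_along(y))) {
  data.frame(study_id = ids, estimate = y, se = se, scale = scale,
             stringsAsFactors = FALSE)
}

# A minimal valid case-control CSV written to a temp file.
write_cc_csv <- function(rows, path = tempfile(fileext = ".csv")) {
  header <- paste("study_id,ethnicity,snp_id,risk_allele,raf_case,raf_control",
                  "n_case,n_control,case_hom_risk,case_het,case_hom_other",
                  "control_hom_risk,control_het,control_hom_other",
                  "reported_or,or_ci_low,or_ci_high,hwe_ok", sep = ",")
  writeLines(c(header, rows), path)
  path
}

# One fully-specified case-control row with overridable cells (in schema order).
cc_row <- function(study_id = "s1", ethnicity = "Caucasian",
                   snp_id = "rs1", risk_allele = "A",
                   raf_case = "NA", raf_control = "0.5",
                   n_case = "100", n_control = "100",
                   counts_case = c("25", "50", "25"),
                   counts_control = c("25", "50", "25"),
                   reported_or = "NA", ci = c("NA", "NA"), hwe_ok = "yes") {
  paste(study_id, ethnicity, snp_id, risk_allele, raf_case, raf_control,
        n_case, n_control, counts_case[1], counts_case[2], counts_case[3],
        counts_control[1], counts_control[2], counts_control[3],
        reported_or, ci[1], ci[2], hwe_ok, sep = ",")
}

write_quant_csv <- function(rows, path = tempfile(fileext = ".csv")) {
  header <- paste("study_id,ethnicity,snp_id,risk_allele,raf,n,hwe_ok",
                  "beta,beta_se,beta_ci_low,beta_ci_high,beta_p",
                  "n_hom_risk,mean_hom_risk,sd_hom_risk",
                  "n_het,mean_het,sd_het",
                  "n_hom_other,mean_hom_other,sd_hom_other", sep = ",")
  writeLines(c(header, rows), path)
  path
}

quant_row <- function(study_id = "q1", ethnicity = "Asian", snp_id = "rs1",
                      risk_allele = "A", raf = "0.3", n = "1000",
                      hwe_ok = "yes", beta = "NA", beta_se = "NA",
                      beta_ci = c("NA", "NA"), beta_p = "NA",
                      geno = rep("NA", 9)) {
  paste(study_id, ethnicity, snp_id, risk_allele, raf, n, hwe_ok,
        beta, beta_se, beta_ci[1], beta_ci[2], beta_p,
        paste(geno, collapse = ","), sep = ",")
}

# Random small genotype tables for brute-force OR checks.
random_genotype_triple <- function() {
  as.vector(stats::rmultinom(1, sample(40:200, 1),
                             prob = stats::runif(3, 0.1, 1)))
}
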
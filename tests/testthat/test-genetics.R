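test_that("HWE genotype frequencies follow f^2, 2f(1-f), (1-f)^2", {
  expect_equal(unname(genotype_freqs_from_raf(0.5)), c(0.25, 0.5, 0.25))
  expect_equal(unname(genotype_freqs_from_raf(0)), c(0, 0, 1))
  expect_equal(unname(genotype_freqs_from_raf(1)), c(1, 0, 0))
  # the published Japanese frequency, G = 0.971
  expect_equal(unname(genotype_freqs_from_raf(0.971)),
               c(0.942841, 0.056318, 0.000841))
  set.seed(1)
  for (f in runif(20)) expect_equal(sum(genotype_freqs_from_raf(f)), 1)
  expect_error(genotype_freqs_from_raf(1.2), "\\[0, 1\\]")
  expect_error(genotype_freqs_from_raf(-0.1), "\\[0, 1\\]")
})

test_that("reconstructed counts stay fractional and recover the frequency", {
  expect_equal(unname(reconstruct_counts(0.5, 100)), c(25, 50, 25))
  expect_equal(unname(reconstruct_counts(1, 50)), c(50, 0, 0))
  expect_equal(unname(reconstruct_counts(0.3, 1000)), c(90, 420, 490))
  set.seed(7)
  for (i in 1:30) {
    f <- runif(1); n <- sample(10:5000, 1)
    cts <- reconstruct_counts(f, n)
    expect_equal((2 * cts[[1]] + cts[[2]]) / (2 * n), f)
  }
})

test_that("odds ratios match hand-computed cross-products per model", {
  for (m in c("allele", "dominant", "recessive", "additive")) {
    e <- or_from_counts(c(25, 50, 25), c(25, 50, 25), model = m)
    expect_equal(e$estimate, 0)
  }
  # allele 2x2: case alleles 30/70, control alleles 10/90
  e <- or_from_counts(c(5, 20, 25), c(0, 10, 40), model = "allele",
                      correction = "none")
  expect_equal(exp(e$estimate), 2700 / 700)
  expect_equal(e$se, sqrt(1 / 30 + 1 / 70 + 1 / 10 + 1 / 90))
  # dominant collapse: carriers 90/10 vs 70/30
  e2 <- or_from_counts(c(70, 20, 10), c(30, 40, 30), model = "dominant",
                       correction = "none")
  expect_equal(exp(e2$estimate), (90 * 30) / (10 * 70))
  # additive is the crude per-allele (allele-count) OR
  e3 <- or_from_counts(c(5, 20, 25), c(0, 10, 40), model = "additive",
                       correction = "none")
  expect_equal(e3$estimate, e$estimate)
})

test_that("allele-model OR equals the brute-force 2x2 cross-product and inverts on swap", {
  set.seed(11)
  for (i in 1:60) {
    ca <- random_genotype_triple()
    co <- random_genotype_triple()
    a_ca <- c(2 * ca[1] + ca[2], ca[2] + 2 * ca[3])
    a_co <- c(2 * co[1] + co[2], co[2] + 2 * co[3])
    if (any(c(a_ca, a_co) == 0)) next
    e <- or_from_counts(ca, co, model = "allele", correction = "none")
    expect_equal(exp(e$estimate), (a_ca[1] * a_co[2]) / (a_ca[2] * a_co[1]))
    swapped <- or_from_counts(co, ca, model = "allele", correction = "none")
    expect_equal(swapped$estimate, -e$estimate)
    expect_equal(swapped$se, e$se)
  }
})

test_that("zero cells are Haldane-corrected by default and fatal when disabled", {
  e <- or_from_counts(c(0, 0, 50), c(10, 20, 20), model = "recessive")
  expect_true(is.finite(e$estimate))
  expect_error(
    or_from_counts(c(0, 0, 50), c(10, 20, 20), model = "recessive",
                   correction = "none"),
    "degenerate"
  )
})

test_that("the HWE chi-square test matches hand-worked expectations", {
  r <- hwe_test(c(25, 50, 25))
  expect_equal(r$chi2, 0)
  expect_equal(r$p, 1)
  expect_equal(r$f_hat, 0.5)
  expect_true(r$hwe_ok)
  expect_equal(hwe_test(c(90, 20, 90))$chi2, 128)
  r3 <- hwe_test(c(30, 30, 40))
  expect_equal(r3$f_hat, 0.45)
  expect_equal(r3$chi2, 15.51882, tolerance = 1e-6)
  expect_false(r3$hwe_ok)
  mono <- hwe_test(c(0, 0, 120))
  expect_true(mono$monomorphic)
  expect_equal(mono$chi2, 0)
  expect_equal(mono$p, 1)
  expect_error(hwe_test(c(0, 0, 0)), "positive")
  expect_error(hwe_test(c(-1, 5, 5)), "non-negative")
})
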
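test_that("simulation is fully determined by the seed", {
  sc <- scenario_library()$C
  expect_identical(simulate_case_control_meta(sc),
                   simulate_case_control_meta(sc))
  scB <- scenario_library()$B
  expect_identical(simulate_quant_meta(scB), simulate_quant_meta(scB))
  # different seed, different draw
  sc2 <- scenario_library(seed_C = 404L)$C
  expect_false(identical(simulate_case_control_meta(sc),
                         simulate_case_control_meta(sc2)))
})

test_that("earlier studies are unchanged when k grows", {
  base <- sim_scenario("quantitative", k = 5, mu = 0.05, tau = 0.02,
                       raf_range = c(0.3, 0.7), n_range = c(50, 200),
                       trait_sd = 0.5, seed = 42)
  bigger <- sim_scenario("quantitative", k = 9, mu = 0.05, tau = 0.02,
                         raf_range = c(0.3, 0.7), n_range = c(50, 200),
                         trait_sd = 0.5, seed = 42)
  t1 <- simulate_quant_meta(base)
  t2 <- simulate_quant_meta(bigger)
  expect_equal(as.data.frame(t1), as.data.frame(t2)[1:5, ],
               ignore_attr = TRUE)
})

test_that("the noiseless zero-tau limit reproduces mu exactly", {
  sc <- sim_scenario("quantitative", k = 6, mu = 0.07, tau = 0,
                     raf_range = c(0.4, 0.6), n_range = c(100, 200),
                     trait_sd = 0, seed = 11)
  tab <- simulate_quant_meta(sc)
  expect_equal(tab$beta, rep(0.07, 6))
})

test_that("generated tables pass study_io validation on both schemas", {
  lib <- scenario_library()
  cc <- simulate_case_control_meta(lib$C)
  p <- tempfile(fileext = ".csv")
  write_study_table(cc, p)
  expect_silent(suppressMessages(read_case_control_table(p)))
  qt <- simulate_quant_meta(lib$A)
  p2 <- tempfile(fileext = ".csv")
  write_study_table(qt, p2)
  expect_silent(suppressMessages(read_quant_table(p2)))
})

test_that("scenario presets encode the documented study conditions", {
  lib <- scenario_library()
  expect_equal(lib$A$k, 32L)
  expect_equal(lib$A$mu, 0.07)
  expect_equal(lib$B$mu, 0)
  expect_equal(lib$B$tau, 0)
  expect_equal(lib$C$design, "case_control")
  expect_equal(lib$C$mu, log(0.96))
  expect_equal(lib$C$tau, 0.05)
  expect_identical(scenario_library(), scenario_library())
})

test_that("control genotypes track HWE: flag rejects at about the 5% rate", {
  flags <- logical(0)
  for (r in 1:30) {
    sc <- scenario_library(seed_B = 500 + r)$B
    flags <- c(flags, simulate_quant_meta(sc)$hwe_ok)
  }
  rate <- mean(!flags)
  expect_gt(rate, 0.005)
  expect_lt(rate, 0.11)
})

test_that("per-study allele-model log-ORs are centred on mu (rare disease)", {
  lor <- c()
  for (r in 1:100) {
    sc <- sim_scenario("case_control", k = 15, mu = log(1.5), tau = 0.05,
                       raf_range = c(0.3, 0.7), n_range = c(1900, 2100),
                       prevalence = 0.01, seed = 7000 + r)
    tab <- simulate_case_control_meta(sc)
    eff <- suppressMessages(derive_effects(tab, model = "allele"))
    lor <- c(lor, eff$estimate)
  }
  expect_lt(abs(mean(lor) - log(1.5)), 0.02)
})

test_that("pooling preset-A simulations recovers the true mean effect", {
  est <- numeric(40)
  for (r in 1:40) {
    sc <- scenario_library(seed_A = 900 + r)$A
    eff <- suppressMessages(derive_effects(simulate_quant_meta(sc)))
    est[r] <- dersimonian_laird(eff)$estimate
  }
  mc_se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - 0.07), 3 * mc_se)
})

test_that("invalid scenarios are rejected up front", {
  expect_error(sim_scenario("case_control", k = 5, mu = 0, tau = -1,
                            raf_range = c(0.2, 0.8), n_range = c(10, 20),
                            prevalence = 0.1), "non-negative")
  expect_error(sim_scenario("case_control", k = 5, mu = 0, tau = 0,
                            raf_range = c(0.8, 0.2), n_range = c(10, 20),
                            prevalence = 0.1), "ordered")
  expect_error(sim_scenario("case_control", k = 5, mu = 0, tau = 0,
                            raf_range = c(0.2, 0.8), n_range = c(10, 20)),
               "prevalence")
  expect_error(sim_scenario("quantitative", k = 5, mu = 0, tau = 0,
                            raf_range = c(0.2, 0.8), n_range = c(10, 20)),
               "trait_sd")
  sc <- scenario_library()$B
  expect_error(simulate_case_control_meta(sc), "case_control")
})
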
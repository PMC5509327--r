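test_that("fixed-effect pooling matches hand-worked cases", {
  one <- fixed_effect(make_effects(0.3, 0.1))
  expect_equal(one$estimate, 0.3)
  expect_equal(one$se, 0.1)
  expect_true(is.na(one$i2))

  two <- fixed_effect(make_effects(c(0, 2), c(1, 1)))
  expect_equal(two$estimate, 1)
  expect_equal(two$se, 1 / sqrt(2))
  expect_equal(two$Q, 2)

  eq <- fixed_effect(make_effects(c(0.1, 0.4, 0.7), c(0.2, 0.2, 0.2)))
  expect_equal(eq$estimate, 0.4)  # equal weights -> arithmetic mean
})

test_that("DerSimonian-Laird matches full hand evaluation", {
  d <- dersimonian_laird(make_effects(c(0, 2), c(1, 1)))
  expect_equal(d$Q, 2)
  expect_equal(d$tau2, 1)        # (Q - df) / (sum w - sum w^2 / sum w) = 1/1
  expect_equal(d$estimate, 1)
  expect_equal(d$se, 1)          # 1 / sqrt(sum 1/(1 + 1))
  expect_equal(d$i2, 50)
  expect_equal(d$h2, 1)
  expect_equal(d$h2_classical, 2)

  d3 <- dersimonian_laird(make_effects(c(0, 1, 2), c(1, 1, 1)))
  expect_equal(d3$Q, 2)
  expect_equal(d3$df, 2L)
  expect_equal(d3$tau2, 0)       # truncation at zero
  f3 <- fixed_effect(make_effects(c(0, 1, 2), c(1, 1, 1)))
  expect_equal(d3$estimate, f3$estimate)
  expect_equal(d3$se, f3$se)

  same <- dersimonian_laird(make_effects(rep(0.4, 4), c(0.1, 0.2, 0.3, 0.4)))
  expect_equal(same$Q, 0)
  expect_equal(same$tau2, 0)
  expect_equal(same$estimate, 0.4)
  expect_error(dersimonian_laird(make_effects(0.1, 0.1)), "at least 2")
})

test_that("DL pooling agrees with metafor as an independent oracle", {
  set.seed(23)
  for (i in 1:10) {
    k <- sample(3:20, 1)
    y <- rnorm(k, 0.1, 0.3)
    se <- runif(k, 0.05, 0.5)
    mine <- dersimonian_laird(make_effects(y, se))
    ref <- metafor::rma(yi = y, sei = se, method = "DL")
    expect_equal(mine$estimate, as.numeric(ref$beta), tolerance = 1e-10)
    expect_equal(mine$se, ref$se, tolerance = 1e-10)
    expect_equal(mine$tau2, ref$tau2, tolerance = 1e-10)
    expect_equal(mine$Q, ref$QE, tolerance = 1e-10)
    expect_equal(mine$i2, ref$I2, tolerance = 1e-6)
  }
})

test_that("heterogeneity statistics and the ln-H interval are as derived", {
  h <- heterogeneity(2, 1)
  expect_equal(h$i2, 50)
  expect_equal(h$h2, 1)
  expect_equal(h$h2_classical, 2)
  expect_true(all(is.na(h$i2_ci)))  # small-Q SE undefined at df = 1

  expect_equal(heterogeneity(0.5, 3)$i2, 0)
  expect_equal(heterogeneity(0.5, 3)$h2, 0)

  h2 <- heterogeneity(20, 9)
  expect_equal(h2$i2, 55)
  # SE(lnH) = 0.5 (ln 20 - ln 9) / (sqrt(40) - sqrt(17)) = 0.18136
  expect_equal(h2$i2_ci, c(8.389, 77.896), tolerance = 1e-3)
  expect_error(heterogeneity(3, 0), "at least 1")
})

test_that("pooled estimates are convex combinations, order-invariant", {
  set.seed(5)
  for (i in 1:10) {
    k <- sample(2:12, 1)
    eff <- make_effects(rnorm(k), runif(k, 0.05, 1))
    res <- dersimonian_laird(eff)
    expect_equal(sum(res$weights), 1)
    expect_true(all(res$weights > 0))
    expect_gte(res$estimate, min(eff$estimate))
    expect_lte(res$estimate, max(eff$estimate))
    perm <- sample(k)
    res_p <- dersimonian_laird(eff[perm, ])
    expect_equal(res_p$estimate, res$estimate)
    expect_equal(res_p$se, res$se)
    expect_equal(res_p$tau2, res$tau2)
    expect_equal(res_p$weights[eff$study_id], res$weights)
  }
})

test_that("DL recovers the between-study variance for precise studies", {
  # k = 15 studies with tiny within-study error, tau = 0.05
  set.seed(99)
  tau <- 0.05
  est <- replicate(300, {
    y <- rnorm(15, 0.07, sqrt(tau^2 + 0.005^2))
    dersimonian_laird(make_effects(y, rep(0.005, 15)))$tau2
  })
  expect_lt(abs(mean(est) - tau^2) / tau^2, 0.25)
})

test_that("leave-one-out returns k re-pools consistent with the parent", {
  idfx <- make_effects(rep(0.5, 3), rep(0.1, 3))
  loo <- leave_one_out(idfx)
  expect_length(loo, 3L)
  for (x in loo) expect_equal(x$estimate, 0.5)
  three <- make_effects(c(0, 1, 2), c(1, 1, 1))
  loo3 <- leave_one_out(three)
  expect_equal(loo3[["s02"]]$estimate, 1)  # reduces to the two-study case
  expect_equal(names(loo3), three$study_id)
  expect_error(leave_one_out(make_effects(c(0, 1), c(1, 1))), "at least 3")
})

test_that("pooled allele frequencies behave under both weighting schemes", {
  expect_equal(pooled_raf(rep(0.3, 4), c(10, 100, 1000, 5), "inverse_variance"),
               0.3)
  expect_equal(pooled_raf(c(0.5, 0.5), c(10, 1000), "inverse_variance"), 0.5)
  # the four published Asian rs560887 frequencies, unweighted
  expect_equal(pooled_raf(c(0.971, 0.907, 0.82, 0.84), method = "mean"),
               0.8845)
  # inverse-variance pulls toward large, extreme-frequency studies
  iv <- pooled_raf(c(0.9, 0.5), c(10000, 100), "inverse_variance")
  expect_gt(iv, pooled_raf(c(0.9, 0.5), method = "mean"))
  expect_message(pooled_raf(c(1, 0.4), c(50, 50)), "monomorphic")
  expect_error(pooled_raf(numeric(0)), "no frequencies")
  expect_error(pooled_raf(c(0.2, 1.4), c(10, 10)), "\\[0, 1\\]")
})

test_that("subgroup pooling preserves totals and passes singletons through", {
  sc <- scenario_library()$C
  tab <- simulate_case_control_meta(sc)
  # one level: subgroup result identical to overall
  res <- suppressMessages(subgroup_meta(tab, model = "allele"))
  expect_named(res$subgroups, "simulated")
  expect_equal(res$subgroups$simulated$estimate, res$overall$estimate)
  # two disjoint levels partition the total sample size
  tab$ethnicity <- rep(c("g1", "g2"), length.out = nrow(tab))
  res2 <- suppressMessages(subgroup_meta(tab, model = "allele"))
  expect_equal(res2$subgroups$g1$n_total + res2$subgroups$g2$n_total,
               res2$overall$n_total)
  # a singleton level is passed through with undefined heterogeneity
  tab$ethnicity <- c("solo", rep("rest", nrow(tab) - 1))
  res3 <- suppressMessages(subgroup_meta(tab, model = "allele"))
  expect_equal(res3$subgroups$solo$k, 1L)
  expect_true(is.na(res3$subgroups$solo$i2))
})
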
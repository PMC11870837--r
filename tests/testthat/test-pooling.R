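test_that("Mantel-Haenszel pooling reduces to the single study", {
  d <- bdnf_aud_studies()
  ct <- build_contrast(d[1, ], "recessive")
  pooled <- pool_fixed_mh(ct)
  eff <- study_effects(ct)
  expect_equal(pooled$or, eff$or)
  expect_equal(pooled$ci_low, eff$ci_low, tolerance = 1e-10)
  expect_equal(pooled$ci_high, eff$ci_high, tolerance = 1e-10)
})

test_that("replicated tables pool to the common odds ratio with a tighter CI", {
  one <- make_dataset(c(30, 40, 12), c(50, 35, 8))
  k <- 5
  rep5 <- make_dataset(matrix(rep(c(30, 40, 12), k), ncol = 3, byrow = TRUE),
                       matrix(rep(c(50, 35, 8), k), ncol = 3, byrow = TRUE))
  ct1 <- build_contrast(one, "dominant")
  ctk <- build_contrast(rep5, "dominant")
  p1 <- pool_fixed_mh(ct1)
  pk <- pool_fixed_mh(ctk)
  expect_equal(pk$or, p1$or)
  expect_lt(pk$ci_high - pk$ci_low, p1$ci_high - p1$ci_low)

  # identical studies have tau2 = 0, so DL equals the fixed pooling
  effk <- study_effects(ctk)
  dl <- pool_random_dl(effk)
  expect_equal(dl$het$tau2, 0)
  expect_equal(dl$or, pk$or, tolerance = 1e-10)
  expect_equal(dl$ci_low, pk$ci_low, tolerance = 1e-8)
})

test_that("Mantel-Haenszel estimates match the reference implementation", {
  skip_if_not(has_metafor)
  d <- bdnf_aud_studies()
  for (m in c("recessive", "dominant", "homozygous")) {
    ct <- build_contrast(d, m)
    own <- pool_fixed_mh(ct)
    ref <- metafor::rma.mh(ai = ct$case_exposed, bi = ct$case_unexposed,
                           ci = ct$ctrl_exposed, di = ct$ctrl_unexposed,
                           measure = "OR", correct = FALSE)
    expect_equal(log(own$or), as.numeric(ref$beta), tolerance = 1e-10)
    expect_equal(log(own$ci_low), ref$ci.lb, tolerance = 1e-8)
    expect_equal(own$p_assoc, ref$pval, tolerance = 1e-8)
  }
})

test_that("DerSimonian-Laird estimates match the reference implementation", {
  skip_if_not(has_metafor)
  d <- bdnf_aud_studies()
  for (m in c("codominant", "dominant")) {
    eff <- study_effects(build_contrast(d, m))
    own <- pool_random_dl(eff)
    ref <- metafor::rma(yi = eff$log_or, sei = eff$se, method = "DL")
    expect_equal(log(own$or), as.numeric(ref$beta), tolerance = 1e-10)
    expect_equal(own$het$tau2, ref$tau2, tolerance = 1e-10)
    expect_equal(log(own$ci_low), ref$ci.lb, tolerance = 1e-8)
  }
})

test_that("heterogeneity statistics follow their definitions", {
  # identical effects: no dispersion at all
  eff0 <- make_effects(rep(0.4, 6), rep(0.2, 6))
  h0 <- heterogeneity(eff0$log_or, eff0$se)
  expect_equal(h0$q, 0)
  expect_equal(h0$i2, 0)
  expect_equal(h0$tau2, 0)

  # I2 is (Q - df)/Q on the percent scale
  d <- bdnf_aud_studies()
  eff <- study_effects(build_contrast(d, "codominant"))
  h <- heterogeneity(eff$log_or, eff$se)
  expect_equal(h$i2, max(0, (h$q - h$df) / h$q) * 100)
  expect_equal(h$p_het, pchisq(h$q, h$df, lower.tail = FALSE))
  expect_error(heterogeneity(0.5, 0.1), "at least 2")
})

test_that("two equal-precision opposite effects pool to the null", {
  eff <- make_effects(c(log(2), log(0.5)), c(0.25, 0.25))
  dl <- pool_random_dl(eff)
  expect_equal(dl$or, 1)
})

test_that("the heterogeneity gate selects the effects model", {
  d <- bdnf_aud_studies()
  rec <- select_and_pool(d, "recessive")
  expect_equal(rec$effects_model, "fixed")
  expect_gte(rec$het$p_het, 0.10)

  dom <- select_and_pool(d, "dominant")
  expect_equal(dom$effects_model, "random")
  expect_lt(dom$het$p_het, 0.10)

  # identical replicated tables have Q = 0, so the gate must pick fixed
  hom <- make_dataset(matrix(rep(c(90, 70, 20), 8), ncol = 3, byrow = TRUE),
                      matrix(rep(c(80, 75, 25), 8), ncol = 3, byrow = TRUE))
  expect_equal(select_and_pool(hom, "codominant")$effects_model, "fixed")
})

test_that("Bonferroni correction multiplies and caps", {
  expect_equal(bonferroni(0.0002, 19), 0.0038)
  expect_equal(bonferroni(0.2, 19), 1)
  expect_equal(bonferroni(0.5, 1), 0.5)
  expect_error(bonferroni(1.2, 3))
})

test_that("subgroup pooling partitions and degenerates correctly", {
  d <- bdnf_aud_studies()
  res <- run_subgroups(d, "ethnicity")
  expect_length(res, 8)
  cauc_hom <- res[["Caucasian.homozygous"]]
  expect_equal(cauc_hom$n, 14)
  expect_near(cauc_hom$or, 0.59, 0.01)

  asian_rec <- res[["Asian.recessive"]]
  expect_equal(asian_rec$effects_model, "fixed")
  expect_near(asian_rec$or, 0.95, 0.01)
  expect_true(asian_rec$ci_low < 1 && asian_rec$ci_high > 1)

  # one-level partition reproduces the overall analysis
  d1 <- d
  d1$ethnicity <- "other"
  one <- run_subgroups(d1, "ethnicity", models = "recessive")
  overall <- select_and_pool(d, "recessive")
  expect_equal(one[["other.recessive"]]$or, overall$or)
})

test_that("the pooled estimate stays inside the study odds-ratio hull", {
  for (r in 1:30) {
    ds <- simulate_dataset(sim_config(n_studies = 12, true_or = 0.8,
                                      tau = 0.2, seed = 400 + r))
    eff <- study_effects(build_contrast(ds, "codominant"),
                         zero_cell = "add_half")
    dl <- pool_random_dl(eff)
    expect_gte(log(dl$or), min(eff$log_or))
    expect_lte(log(dl$or), max(eff$log_or))
    mh <- pool_fixed_mh(build_contrast(ds, "codominant"))
    expect_gte(log(mh$or), min(eff$log_or) - 1e-8)
    expect_lte(log(mh$or), max(eff$log_or) + 1e-8)
  }
})
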
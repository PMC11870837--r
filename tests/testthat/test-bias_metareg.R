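test_that("Begg-Mazumdar matches the reference rank-correlation test", {
  skip_if_not(has_metafor)
  d <- bdnf_aud_studies()
  for (m in c("codominant", "recessive")) {
    eff <- study_effects(build_contrast(d, m))
    own <- begg_mazumdar(eff)
    ref <- metafor::ranktest(x = eff$log_or, vi = eff$se^2, exact = FALSE)
    expect_equal(own$tau, as.numeric(ref$tau), tolerance = 1e-10)
    expect_equal(own$p_value, ref$pval, tolerance = 1e-10)
  }
})

test_that("perfect concordance of deviation and variance gives tau = 1", {
  se <- sqrt(seq(0.1, 0.8, by = 0.1))
  log_or <- (1:8) * 2
  # precondition, via the standardization formula written out
  # independently: the standardized deviations must be strictly
  # increasing in the variances
  w <- 1 / se^2
  mu <- sum(w * log_or) / sum(w)
  t_std <- (log_or - mu) / sqrt(se^2 - 1 / sum(w))
  expect_true(all(diff(t_std) > 0))
  bm <- begg_mazumdar(make_effects(log_or, se))
  expect_equal(bm$tau, 1)
})

test_that("Begg-Mazumdar degrades gracefully on equal variances", {
  eff <- make_effects(c(0.1, 0.4, -0.2, 0.3), rep(0.2, 4))
  expect_warning(bm <- begg_mazumdar(eff), "equal")
  expect_equal(bm$tau, 0)
  expect_equal(bm$p_value, 1)
  expect_error(begg_mazumdar(eff[1:2, ]), "at least 3")
})

test_that("Egger intercept vanishes on an exactly symmetric funnel", {
  # pairs with matched precision and effects mirrored about a common mean
  mu <- -0.2
  se <- rep(c(0.1, 0.2, 0.3, 0.45), each = 2)
  delta <- rep(c(0.05, 0.12, 0.2, 0.3), each = 2) * c(1, -1)
  eff <- make_effects(mu + delta, se)
  eg <- egger_test(eff)
  expect_equal(eg$intercept, 0, tolerance = 1e-10)

  expect_error(egger_test(eff[1:2, ]), "at least 3")
  # minimum size runs and returns a finite p
  eg3 <- egger_test(eff[c(1, 3, 5), ])
  expect_true(is.finite(eg3$p_value))
})

test_that("Egger regression matches the reference implementation", {
  skip_if_not(has_metafor)
  d <- bdnf_aud_studies()
  eff <- study_effects(build_contrast(d, "codominant"))
  own <- egger_test(eff)
  ref <- metafor::regtest(x = eff$log_or, vi = eff$se^2, model = "lm",
                          predictor = "sei")
  expect_equal(own$p_value, ref$pval, tolerance = 1e-8)
})

test_that("publication bias routing follows the normality gate", {
  # right-skewed odds ratios route to the rank test
  cauc <- subset(bdnf_aud_studies(), ethnicity == "Caucasian")
  eff <- study_effects(build_contrast(cauc, "homozygous"))
  pb <- publication_bias(eff, label = "Caucasian homozygous")
  expect_false(pb$normal)
  expect_equal(pb$test_used, "begg_mazumdar")
  expect_false(pb$evidence)

  # near-normal synthetic odds ratios route to Egger
  set.seed(31)
  eff_n <- make_effects(rnorm(15, 0, 0.05), rep(0.3, 15))
  eff_n$or <- 1 + seq(-0.2, 0.2, length.out = 15)  # linear = normal-ish
  pb_n <- publication_bias(eff_n)
  expect_true(pb_n$normal)
  expect_equal(pb_n$test_used, "egger")
})

test_that("intercept-only meta-regression reproduces the random-effects pool", {
  d <- bdnf_aud_studies()
  eff <- study_effects(build_contrast(d, "codominant"))
  dl <- pool_random_dl(eff)
  mr <- meta_regression(d, "codominant", NULL)
  expect_equal(mr$coefficient, log(dl$or), tolerance = 1e-10)
  expect_equal(mr$tau2, dl$het$tau2, tolerance = 1e-10)
})

test_that("meta-regression matches the reference implementation", {
  skip_if_not(has_metafor)
  d <- bdnf_aud_studies()
  eff <- study_effects(build_contrast(d, "codominant"))
  for (cv in c("year", "quality_score")) {
    own <- meta_regression(d, "codominant", cv)
    ref <- metafor::rma(yi = eff$log_or, sei = eff$se,
                        mods = ~d[[cv]], method = "DL")
    expect_equal(own$coefficient, as.numeric(ref$beta[2]), tolerance = 1e-8)
    expect_equal(unname(own$se), unname(ref$se[2]), tolerance = 1e-8)
    expect_equal(unname(own$p_value), unname(ref$pval[2]), tolerance = 1e-8)
  }
  # categorical covariate, one-hot against the first level
  own_e <- meta_regression(d, "codominant", "ethnicity")
  ref_e <- metafor::rma(yi = eff$log_or, sei = eff$se,
                        mods = ~factor(d$ethnicity), method = "DL")
  expect_equal(own_e$coefficient, as.numeric(ref_e$beta[2]), tolerance = 1e-8)
})

test_that("meta-regression rejects degenerate designs and drops missing rows", {
  d <- bdnf_aud_studies()
  d2 <- as.data.frame(d)
  d2$constant <- 5
  expect_error(meta_regression(as_gene_dataset(d2), "codominant",
                               "constant"), "constant")
  expect_message(mr <- meta_regression(d, "codominant", "sex_ratio_m_to_f"),
                 "dropped")
  expect_lt(mr$n_studies, 20)
  expect_error(meta_regression(d, "codominant", "no_such"), "unknown")
})

test_that("meta-regression recovers a planted covariate slope", {
  # 40 studies whose true log odds ratio is 0.5 * x
  slope <- 0.5
  x <- seq(-0.6, 0.6, length.out = 40)
  rows <- lapply(seq_along(x), function(i) {
    cfg <- sim_config(n_studies = 1, true_or = exp(slope * x[i]), tau = 0,
                      n_cases_range = c(400, 800),
                      n_controls_range = c(400, 800), seed = 500 + i)
    as.data.frame(simulate_study(cfg, index = i))
  })
  df <- do.call(rbind, rows)
  df$xcov <- x
  ds <- as_gene_dataset(df)
  mr <- meta_regression(ds, "codominant", "xcov")
  expect_equal(mr$coefficient, slope, tolerance = 0.15)
  expect_lt(mr$p_value, 0.05)
})
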
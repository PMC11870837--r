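#' Begg-Mazumdar rank-correlation test for publication bias
#'
#' Kendall rank correlation between the variance-standardized deviations
#' of the study effects from the fixed-effects pooled effect,
#' `t_i = (log_or_i - mu) / sqrt(v_i - 1/sum(w))`, and the study variances
#' `v_i`. Small-study selection makes imprecise studies systematically
#' more extreme, which shows up as correlation. The p-value uses the
#' normal approximation with tie-corrected (tau-b) variance, two-sided.
#'
#' @param effects Output of [study_effects()]; at least 3 studies.
#' @return A list with `tau`, `p_value` and `n`.
#' @export
begg_mazumdar <- function(effects) {
  k <- nrow(effects)
  if (k < 3) stop("need at least 3 studies for the Begg-Mazumdar test")
  v <- effects$se^2
  w <- 1 / v
  mu <- sum(w * effects$log_or) / sum(w)
  vstar <- v - 1 / sum(w)
  if (all(abs(v - v[1]) < .Machine$double.eps^0.5)) {
    # equal variances: deviations cannot be standardized against a
    # variance ranking; rank correlation against a constant is undefined
    warning("all study variances equal; Begg-Mazumdar tau undefined, ",
            "returning tau = 0, p = 1")
    return(list(tau = 0, p_value = 1, n = k))
  }
  t_std <- (effects$log_or - mu) / sqrt(pmax(vstar, .Machine$double.eps))
  ct <- suppressWarnings(
    cor.test(t_std, v, method = "kendall", exact = FALSE, continuity = FALSE))
  list(tau = unname(ct$estimate), p_value = ct$p.value, n = k)
}

#' Egger regression test for funnel-plot asymmetry
#'
#' Ordinary least-squares regression of the standardized effect
#' `log_or/se` on the precision `1/se`. In a symmetric funnel the
#' intercept is zero; small-study effects push it away from zero. Returns
#' the intercept with its two-sided t test.
#'
#' @param effects Output of [study_effects()]; at least 3 studies.
#' @return A list with `intercept`, `se`, `t`, `p_value` and `n`.
#' @export
egger_test <- function(effects) {
  k <- nrow(effects)
  if (k < 3) stop("need at least 3 studies for the Egger test")
  y <- effects$log_or / effects$se
  x <- 1 / effects$se
  fit <- lm(y ~ x)
  sm <- summary(fit)$coefficients
  list(intercept = sm[1, 1], se = sm[1, 2], t = sm[1, 3],
       p_value = sm[1, 4], n = k)
}

#' Normality-gated publication-bias assessment
#'
#' Applies the Shapiro-Wilk test to the study odds ratios (on the OR
#' scale, not the log scale): normally distributed sets (`p > 0.05`) are
#' tested with [egger_test()], non-normal sets with [begg_mazumdar()].
#' Evidence of bias is declared at `p < 0.05` of the selected test.
#'
#' @param effects Output of [study_effects()]; at least 3 studies.
#' @param label Analysis label carried into the report.
#' @return A list with `label`, `n`, `shapiro_p`, `normal`, `test_used`
#'   (`"egger"` or `"begg_mazumdar"`), `statistic` (Egger intercept or
#'   Kendall tau), `p_value` and `evidence`.
#' @export
#' @examples
#' cauc <- subset(bdnf_aud_studies(), ethnicity == "Caucasian")
#' eff <- study_effects(build_contrast(cauc, "recessive"))
#' publication_bias(eff, label = "Caucasian recessive")
publication_bias <- function(effects, label = "overall") {
  sw <- shapiro_gate(effects$or)
  normal <- isTRUE(sw$normal)
  if (normal) {
    tst <- egger_test(effects)
    statistic <- tst$intercept
    test_used <- "egger"
  } else {
    tst <- begg_mazumdar(effects)
    statistic <- tst$tau
    test_used <- "begg_mazumdar"
  }
  list(label = label, n = nrow(effects), shapiro_p = sw$p_value,
       normal = normal, test_used = test_used, statistic = statistic,
       p_value = tst$p_value, evidence = !is.na(tst$p_value) && tst$p_value < 0.05)
}

#' Single-covariate random-effects meta-regression
#'
#' Weighted regression of study log odds ratios on one study-level
#' covariate, with a method-of-moments (DerSimonian-Laird type) residual
#' between-study variance: the fixed-weight residual dispersion `Q_E` is
#' compared with its expectation to estimate `tau2`, and the model is
#' refitted with weights `1/(se^2 + tau2)`. Categorical covariates are
#' one-hot encoded against their first level. Studies with a missing
#' covariate are dropped (a message reports how many). An intercept-only
#' regression (`covariate = NULL`) reproduces the DerSimonian-Laird
#' pooled estimate.
#'
#' @param dataset A `gene_dataset`.
#' @param model One of [genetic_models()].
#' @param covariate Column name of `dataset`, or `NULL` for intercept
#'   only.
#' @param k_bonferroni Number of covariates in the tested family, used
#'   for the corrected p-value (default 1, i.e. uncorrected).
#' @inheritParams study_effects
#' @return A list with `covariate`, `coefficient` (per-unit change in log
#'   odds ratio), `se`, `p_value`, `p_bc`, `tau2` and `n_studies`. For a
#'   categorical covariate with more than two levels, `coefficient` and
#'   `se` are `NA` and `p_value` is the Wald chi-square test of the whole
#'   covariate block.
#' @export
#' @examples
#' meta_regression(bdnf_aud_studies(), "codominant", "year")
meta_regression <- function(dataset, model = genetic_models(),
                            covariate = NULL, k_bonferroni = 1,
                            zero_cell = c("error", "add_half")) {
  model <- match.arg(model)
  d <- as.data.frame(dataset)
  if (!is.null(covariate)) {
    if (!covariate %in% names(d)) stop("unknown covariate: ", covariate)
    miss <- is.na(d[[covariate]])
    if (any(miss)) {
      message(sum(miss), " studies dropped for missing '", covariate, "'")
      d <- d[!miss, , drop = FALSE]
    }
  }
  if (nrow(d) < 4) stop("need at least 4 studies with the covariate present")
  eff <- study_effects(build_contrast(d, model), zero_cell)
  y <- eff$log_or
  v <- eff$se^2
  if (is.null(covariate)) {
    X <- matrix(1, nrow = length(y))
  } else {
    xval <- d[[covariate]]
    if (is.character(xval) || is.logical(xval) || is.factor(xval)) {
      xval <- factor(xval)
      if (nlevels(xval) < 2) stop("covariate '", covariate,
                                  "' is constant across studies")
      X <- stats::model.matrix(~xval)
    } else {
      if (diff(range(xval)) == 0) stop("covariate '", covariate,
                                       "' is constant across studies")
      X <- cbind(1, xval)
    }
  }
  k <- length(y)
  p <- ncol(X)
  W <- diag(1 / v, k)
  xtwx_inv <- solve(t(X) %*% W %*% X)
  H <- X %*% xtwx_inv %*% t(X) %*% W
  resid_fixed <- y - H %*% y
  qe <- sum((resid_fixed^2) / v)
  Pmat <- W - W %*% X %*% xtwx_inv %*% t(X) %*% W
  tau2 <- max(0, (qe - (k - p)) / sum(diag(Pmat)))
  wstar <- 1 / (v + tau2)
  Ws <- diag(wstar, k)
  vb <- solve(t(X) %*% Ws %*% X)
  beta <- vb %*% t(X) %*% Ws %*% y
  se_b <- sqrt(diag(vb))
  if (p == 1) {
    coefficient <- beta[1]
    se_c <- se_b[1]
    p_value <- 2 * pnorm(-abs(coefficient / se_c))
  } else if (p == 2) {
    coefficient <- beta[2]
    se_c <- se_b[2]
    p_value <- 2 * pnorm(-abs(coefficient / se_c))
  } else {
    # omnibus Wald test on the covariate block
    b2 <- beta[-1, , drop = FALSE]
    v2 <- vb[-1, -1, drop = FALSE]
    chi2 <- drop(t(b2) %*% solve(v2) %*% b2)
    coefficient <- NA_real_
    se_c <- NA_real_
    p_value <- pchisq(chi2, df = p - 1, lower.tail = FALSE)
  }
  list(covariate = covariate %||% "(intercept)", coefficient = coefficient,
       se = se_c, p_value = p_value,
       p_bc = bonferroni(p_value, k_bonferroni), tau2 = tau2,
       n_studies = k)
}
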
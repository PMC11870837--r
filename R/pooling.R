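#' Cochran Q heterogeneity statistics
#'
#' Q is the inverse-variance weighted dispersion of the study log odds
#' ratios around their fixed-effects (inverse-variance) pooled mean, with
#' `p_het` from the upper tail of chi-square on `n - 1` degrees of
#' freedom. `I2 = max(0, (Q - df)/Q) * 100` is the percentage of the
#' dispersion exceeding chance, and `tau2` is the DerSimonian-Laird
#' method-of-moments between-study variance
#' `max(0, (Q - df) / (sum(w) - sum(w^2)/sum(w)))`.
#'
#' @param log_or,se Per-study log odds ratios and standard errors.
#' @return A list with `q`, `df`, `p_het`, `i2` (percent) and `tau2`.
#' @export
#' @examples
#' eff <- study_effects(build_contrast(bdnf_aud_studies(), "codominant"))
#' heterogeneity(eff$log_or, eff$se)
heterogeneity <- function(log_or, se) {
  k <- length(log_or)
  if (k < 2) stop("need at least 2 studies for heterogeneity")
  w <- 1 / se^2
  mu <- sum(w * log_or) / sum(w)
  q <- sum(w * (log_or - mu)^2)
  df <- k - 1
  p_het <- pchisq(q, df, lower.tail = FALSE)
  i2 <- if (q > 0) max(0, (q - df) / q) * 100 else 0
  c_scale <- sum(w) - sum(w^2) / sum(w)
  tau2 <- max(0, (q - df) / c_scale)
  list(q = q, df = df, p_het = p_het, i2 = i2, tau2 = tau2)
}

new_pool_result <- function(label, model, studies_used, or, ci_low, ci_high,
                            p_assoc, het, effects_model, stage, p_bc = NA_real_) {
  structure(list(label = label, model = model, studies_used = studies_used,
                 n = length(studies_used), or = or, ci_low = ci_low,
                 ci_high = ci_high, p_assoc = p_assoc, p_bc = p_bc,
                 het = het, effects_model = effects_model, stage = stage),
            class = "pool_result")
}

#' @export
print.pool_result <- function(x, ...) {
  cat(sprintf("<pool_result> %s / %s (%s, %s)\n", x$label, x$model,
              x$effects_model, x$stage))
  cat(sprintf("  n = %d  OR = %.3f  95%% CI %.3f-%.3f  p = %.4g",
              x$n, x$or, x$ci_low, x$ci_high, x$p_assoc))
  if (!is.na(x$p_bc)) cat(sprintf("  p_bc = %.4g", x$p_bc))
  cat("\n")
  if (!is.null(x$het)) {
    cat(sprintf("  Q = %.2f (df %d), p_het = %.4g, I2 = %.0f%%, tau2 = %.4f\n",
                x$het$q, x$het$df, x$het$p_het, x$het$i2, x$het$tau2))
  }
  invisible(x)
}

#' Mantel-Haenszel fixed-effects pooled odds ratio
#'
#' Stratified fixed-effects pooling of 2x2 tables. The pooled odds ratio
#' is `sum(a_i d_i / n_i) / sum(b_i c_i / n_i)`; its log-scale variance is
#' the Robins-Breslow-Greenland estimator, which is consistent both with
#' many small strata and with few large ones. The association p-value is
#' the two-sided z test of the pooled log odds ratio.
#'
#' @param contrasts Output of [build_contrast()]; all rows must share one
#'   genetic model.
#' @param label Analysis label carried into the result.
#' @param stage `"preoutlier"` or `"postoutlier"`.
#' @param het Optional heterogeneity result to attach (computed from the
#'   study effects when `NULL` and at least two studies are present).
#' @return A `pool_result`.
#' @export
#' @examples
#' ct <- build_contrast(bdnf_aud_studies(), "recessive")
#' pool_fixed_mh(ct)
pool_fixed_mh <- function(contrasts, label = "overall",
                          stage = "preoutlier", het = NULL) {
  if (nrow(contrasts) < 1) stop("need at least one table")
  if (length(unique(contrasts$model)) != 1) {
    stop("all tables must share one genetic model")
  }
  a <- contrasts$case_exposed
  b <- contrasts$case_unexposed
  cc <- contrasts$ctrl_exposed
  dd <- contrasts$ctrl_unexposed
  n <- a + b + cc + dd
  R <- a * dd / n
  S <- b * cc / n
  if (sum(R) == 0 || sum(S) == 0) {
    stop("all tables degenerate: Mantel-Haenszel sums are zero")
  }
  log_or <- log(sum(R) / sum(S))
  # Robins-Breslow-Greenland variance
  P <- (a + dd) / n
  Q <- (b + cc) / n
  v <- sum(P * R) / (2 * sum(R)^2) +
    sum(P * S + Q * R) / (2 * sum(R) * sum(S)) +
    sum(Q * S) / (2 * sum(S)^2)
  se <- sqrt(v)
  p <- 2 * pnorm(-abs(log_or / se))
  if (is.null(het) && nrow(contrasts) >= 2) {
    eff <- study_effects(contrasts, zero_cell = "add_half")
    het <- heterogeneity(eff$log_or, eff$se)
  }
  new_pool_result(label, contrasts$model[1], contrasts$study_id,
                  or = exp(log_or), ci_low = exp(log_or - .ci_z * se),
                  ci_high = exp(log_or + .ci_z * se), p_assoc = p,
                  het = het, effects_model = "fixed", stage = stage)
}

#' DerSimonian-Laird random-effects pooled odds ratio
#'
#' Method-of-moments random-effects pooling: the between-study variance
#' `tau2` from [heterogeneity()] inflates each study variance, and the
#' pooled log odds ratio is the resulting inverse-variance weighted mean
#' with a Wald 95% confidence interval and two-sided z test.
#'
#' @param effects Output of [study_effects()] (needs `study_id`, `model`,
#'   `log_or`, `se`); at least two studies.
#' @inheritParams pool_fixed_mh
#' @return A `pool_result`.
#' @export
pool_random_dl <- function(effects, label = "overall",
                           stage = "preoutlier", het = NULL) {
  if (nrow(effects) < 2) stop("need at least 2 studies for random-effects pooling")
  if (is.null(het)) het <- heterogeneity(effects$log_or, effects$se)
  w <- 1 / (effects$se^2 + het$tau2)
  mu <- sum(w * effects$log_or) / sum(w)
  se <- sqrt(1 / sum(w))
  p <- 2 * pnorm(-abs(mu / se))
  new_pool_result(label, effects$model[1], effects$study_id,
                  or = exp(mu), ci_low = exp(mu - .ci_z * se),
                  ci_high = exp(mu + .ci_z * se), p_assoc = p,
                  het = het, effects_model = "random", stage = stage)
}

#' Heterogeneity-gated pooling
#'
#' Computes the Q test and pools with DerSimonian-Laird random effects
#' when `p_het < het_gate` (default 0.10), with Mantel-Haenszel fixed
#' effects otherwise. This is the standard model-selection rule of
#' two-stage genetic meta-analyses.
#'
#' @param dataset A `gene_dataset`.
#' @param model One of [genetic_models()].
#' @param het_gate Heterogeneity p-value threshold for switching to random
#'   effects.
#' @inheritParams pool_fixed_mh
#' @inheritParams study_effects
#' @return A `pool_result` whose `effects_model` records the choice.
#' @export
#' @examples
#' select_and_pool(bdnf_aud_studies(), "recessive")
select_and_pool <- function(dataset, model = genetic_models(),
                            label = "overall", stage = "preoutlier",
                            het_gate = 0.10,
                            zero_cell = c("error", "add_half")) {
  model <- match.arg(model)
  ct <- build_contrast(dataset, model)
  if (nrow(ct) == 1) {
    return(pool_fixed_mh(ct, label = label, stage = stage))
  }
  eff <- study_effects(ct, zero_cell)
  het <- heterogeneity(eff$log_or, eff$se)
  if (het$p_het < het_gate) {
    pool_random_dl(eff, label = label, stage = stage, het = het)
  } else {
    pool_fixed_mh(ct, label = label, stage = stage, het = het)
  }
}

#' Bonferroni correction
#'
#' `min(1, p * k)` for `k` comparisons.
#'
#' @param p P-value(s) in `[0, 1]`.
#' @param k Number of comparisons, `>= 1`.
#' @return Corrected p-value(s), capped at 1.
#' @export
#' @examples
#' bonferroni(0.0002, 19)
bonferroni <- function(p, k) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE), k >= 1, k == round(k))
  pmin(1, p * k)
}

#' Subgroup meta-analyses
#'
#' Runs [select_and_pool()] separately within each level of a study-level
#' partitioning covariate (typically `ethnicity`), for each requested
#' genetic model.
#'
#' @param dataset A `gene_dataset`.
#' @param partition_key Column of `dataset` to split on.
#' @param models Genetic models to run.
#' @inheritParams select_and_pool
#' @return A list of `pool_result`s labelled `<level>` per subgroup and
#'   model; subgroups with no studies are skipped with a message.
#' @export
#' @examples
#' res <- run_subgroups(bdnf_aud_studies(), "ethnicity",
#'                      models = "homozygous")
#' res[["Caucasian.homozygous"]]
run_subgroups <- function(dataset, partition_key = "ethnicity",
                          models = genetic_models(), het_gate = 0.10,
                          zero_cell = c("error", "add_half")) {
  if (!partition_key %in% names(dataset)) {
    stop("unknown partition key: ", partition_key)
  }
  key <- dataset[[partition_key]]
  if (anyNA(key)) stop("partition key missing for study ",
                       paste(dataset$study_id[is.na(key)], collapse = ", "))
  out <- list()
  for (lev in unique(key)) {
    sub <- dataset[key == lev, , drop = FALSE]
    if (nrow(sub) < 1) {
      message("subgroup ", lev, " has no studies; skipped")
      next
    }
    for (m in models) {
      out[[paste(lev, m, sep = ".")]] <-
        select_and_pool(sub, m, label = lev, het_gate = het_gate,
                        zero_cell = zero_cell)
    }
  }
  out
}

#' Flatten pool results into a results table
#'
#' One row per `pool_result`, shaped like the results table of a genetic
#' meta-analysis report (label, model, n, OR, CI, p, corrected p,
#' heterogeneity, effects model, stage).
#'
#' @param results A list of `pool_result`s.
#' @return A data frame.
#' @export
pool_results_table <- function(results) {
  rows <- lapply(results, function(r) {
    data.frame(label = r$label, model = r$model, stage = r$stage,
               n = r$n, or = r$or, ci_low = r$ci_low, ci_high = r$ci_high,
               p_assoc = r$p_assoc, p_bc = r$p_bc,
               q = if (is.null(r$het)) NA_real_ else r$het$q,
               p_het = if (is.null(r$het)) NA_real_ else r$het$p_het,
               i2 = if (is.null(r$het)) NA_real_ else r$het$i2,
               tau2 = if (is.null(r$het)) NA_real_ else r$het$tau2,
               effects_model = r$effects_model, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
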
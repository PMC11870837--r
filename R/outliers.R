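#' Galbraith (radial) plot outlier detection
#'
#' Plots each study at `x = 1/se` (precision) and `y = log_or/se`
#' (standardized effect). The reference slope is the fixed-effects
#' inverse-variance pooled log odds ratio, which equals the unweighted
#' least-squares slope of `y` on `x` through the origin. Studies whose
#' residual `y - slope * x` falls strictly outside the +/-2 band -- the
#' approximate 95% limits of a unit-variance residual -- are flagged as
#' heterogeneity-driving outliers. Flagging is single-pass: the slope is
#' not re-fitted after removal.
#'
#' @param effects Output of [study_effects()]; at least 3 studies.
#' @param threshold Residual band half-width (default 2).
#' @return A list with `points` (data frame `study_id`, `x`, `y`,
#'   `residual`, `flagged`, sufficient to re-draw the plot) and `flagged`
#'   (the flagged `study_id`s).
#' @export
#' @examples
#' eff <- study_effects(build_contrast(bdnf_aud_studies(), "codominant"))
#' galbraith_outliers(eff)$flagged
galbraith_outliers <- function(effects, threshold = 2) {
  if (nrow(effects) < 3) stop("need at least 3 studies for Galbraith analysis")
  stopifnot(threshold > 0)
  w <- 1 / effects$se^2
  slope <- sum(w * effects$log_or) / sum(w)
  x <- 1 / effects$se
  y <- effects$log_or / effects$se
  residual <- y - slope * x
  flagged <- abs(residual) > threshold
  points <- data.frame(study_id = effects$study_id, x = x, y = y,
                       residual = residual, flagged = flagged,
                       stringsAsFactors = FALSE)
  list(points = points, flagged = effects$study_id[flagged])
}

#' Pre/post outlier-treatment pooling
#'
#' Pools all studies, flags Galbraith outliers from the per-study effects,
#' removes them and re-pools the remainder, re-applying the heterogeneity
#' gate to the reduced set. When nothing is flagged the post result equals
#' the pre result.
#'
#' @param dataset A `gene_dataset`.
#' @param model One of [genetic_models()].
#' @inheritParams select_and_pool
#' @param galbraith_threshold Residual band half-width for
#'   [galbraith_outliers()].
#' @return A list with `pre` and `post` (`pool_result`s; `post` is `NULL`
#'   with a warning if no studies remain), `flagged` and `points`.
#' @export
#' @examples
#' tr <- outlier_treatment(bdnf_aud_studies(), "codominant")
#' tr$flagged
outlier_treatment <- function(dataset, model = genetic_models(),
                              label = "overall", het_gate = 0.10,
                              galbraith_threshold = 2,
                              zero_cell = c("error", "add_half")) {
  model <- match.arg(model)
  pre <- select_and_pool(dataset, model, label = label, stage = "preoutlier",
                         het_gate = het_gate, zero_cell = zero_cell)
  eff <- study_effects(build_contrast(dataset, model), zero_cell)
  gal <- galbraith_outliers(eff, threshold = galbraith_threshold)
  if (length(gal$flagged) == 0) {
    post <- pre
    post$stage <- "postoutlier"
    return(list(pre = pre, post = post, flagged = character(0),
                points = gal$points))
  }
  keep <- !(dataset$study_id %in% gal$flagged)
  if (!any(keep)) {
    warning("all studies flagged as outliers; no post-treatment pooling")
    return(list(pre = pre, post = NULL, flagged = gal$flagged,
                points = gal$points))
  }
  post <- select_and_pool(dataset[keep, , drop = FALSE], model,
                          label = label, stage = "postoutlier",
                          het_gate = het_gate, zero_cell = zero_cell)
  list(pre = pre, post = post, flagged = gal$flagged, points = gal$points)
}

#' Leave-one-out sensitivity analysis
#'
#' Re-pools the analysis set once per omitted study, re-applying the
#' heterogeneity gate each time. The full-set result is `robust` when
#' every leave-one-out result preserves both its significance status (the
#' 95% confidence interval excludes an odds ratio of 1; no multiplicity
#' correction is re-applied within the leave-one-out loop) and the
#' direction of the pooled effect.
#'
#' @inheritParams outlier_treatment
#' @return A list with `label`, `robust` and `loo_results` (data frame
#'   `omitted`, `or`, `ci_low`, `ci_high`, `significant`).
#' @export
#' @examples
#' cauc <- subset(bdnf_aud_studies(), ethnicity == "Caucasian")
#' leave_one_out(cauc, "homozygous", label = "Caucasian")$robust
leave_one_out <- function(dataset, model = genetic_models(),
                          label = "overall", het_gate = 0.10,
                          zero_cell = c("error", "add_half")) {
  model <- match.arg(model)
  if (nrow(dataset) < 2) stop("need at least 2 studies for sensitivity analysis")
  full <- select_and_pool(dataset, model, label = label,
                          het_gate = het_gate, zero_cell = zero_cell)
  full_sig <- full$ci_low > 1 || full$ci_high < 1
  full_dir <- sign(log(full$or))
  rows <- lapply(seq_len(nrow(dataset)), function(i) {
    r <- select_and_pool(dataset[-i, , drop = FALSE], model, label = label,
                         het_gate = het_gate, zero_cell = zero_cell)
    data.frame(omitted = dataset$study_id[i], or = r$or,
               ci_low = r$ci_low, ci_high = r$ci_high,
               significant = r$ci_low > 1 || r$ci_high < 1,
               stringsAsFactors = FALSE)
  })
  loo <- do.call(rbind, rows)
  robust <- all(loo$significant == full_sig) &&
    all(sign(log(loo$or)) == full_dir | log(loo$or) == 0)
  list(label = label, model = model, robust = robust,
       full_significant = full_sig, loo_results = loo)
}
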
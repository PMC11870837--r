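#' Build 2x2 contrast tables under a genetic model
#'
#' Collapses the 3x2 genotype table of each study into the 2x2 exposure
#' table of the requested genetic model:
#' \describe{
#'   \item{homozygous}{var-var vs wt-wt; heterozygotes are dropped.}
#'   \item{recessive}{var-var vs var-wt + wt-wt.}
#'   \item{dominant}{var-var + var-wt vs wt-wt.}
#'   \item{codominant}{variant vs wild-type allele counts; each subject
#'     contributes two alleles, so cells are `2*varvar + varwt` vs
#'     `2*wtwt + varwt` per arm. Within-subject allele dependence is
#'     ignored, as is conventional for the multiplicative model.}
#' }
#'
#' @param dataset A `gene_dataset`.
#' @param model One of [genetic_models()].
#' @return Data frame with columns `study_id`, `model`, `case_exposed`,
#'   `case_unexposed`, `ctrl_exposed`, `ctrl_unexposed`, `unit`
#'   (`"alleles"` for codominant, `"subjects"` otherwise).
#' @export
#' @examples
#' build_contrast(bdnf_aud_studies()[1, ], "codominant")
build_contrast <- function(dataset, model = genetic_models()) {
  model <- match.arg(model)
  d <- dataset
  cells <- switch(model,
    homozygous = data.frame(
      case_exposed = d$case_varvar, case_unexposed = d$case_wtwt,
      ctrl_exposed = d$ctrl_varvar, ctrl_unexposed = d$ctrl_wtwt),
    recessive = data.frame(
      case_exposed = d$case_varvar,
      case_unexposed = d$case_varwt + d$case_wtwt,
      ctrl_exposed = d$ctrl_varvar,
      ctrl_unexposed = d$ctrl_varwt + d$ctrl_wtwt),
    dominant = data.frame(
      case_exposed = d$case_varvar + d$case_varwt,
      case_unexposed = d$case_wtwt,
      ctrl_exposed = d$ctrl_varvar + d$ctrl_varwt,
      ctrl_unexposed = d$ctrl_wtwt),
    codominant = data.frame(
      case_exposed = 2L * d$case_varvar + d$case_varwt,
      case_unexposed = 2L * d$case_wtwt + d$case_varwt,
      ctrl_exposed = 2L * d$ctrl_varvar + d$ctrl_varwt,
      ctrl_unexposed = 2L * d$ctrl_wtwt + d$ctrl_varwt))
  out <- cbind(data.frame(study_id = d$study_id, model = model,
                          stringsAsFactors = FALSE),
               cells)
  out$unit <- if (model == "codominant") "alleles" else "subjects"
  rownames(out) <- NULL
  out
}

.ci_z <- qnorm(0.975)  # 1.959964; matches standard meta-analysis software

#' Per-study odds ratios from 2x2 contrast tables
#'
#' Cross-product odds ratio and Woolf log-scale standard error
#' (`sqrt` of the sum of reciprocal cells) per study, with 95% Wald
#' confidence intervals. Zero cells either raise an error (the default:
#' they signal that Laplace correction should have been applied to the
#' genotype counts upstream) or receive the 0.5 continuity correction on
#' all four cells of the affected table (`zero_cell = "add_half"`).
#'
#' @param contrasts Output of [build_contrast()].
#' @param zero_cell `"error"` or `"add_half"`.
#' @return Data frame with `study_id`, `model`, `log_or`, `se`, `or`,
#'   `ci_low`, `ci_high`, `continuity_added`.
#' @export
#' @examples
#' ct <- build_contrast(bdnf_aud_studies(), "recessive")
#' head(study_effects(ct))
study_effects <- function(contrasts, zero_cell = c("error", "add_half")) {
  zero_cell <- match.arg(zero_cell)
  # doubles: allele-count cross products overflow integer arithmetic
  a <- as.numeric(contrasts$case_exposed)
  b <- as.numeric(contrasts$case_unexposed)
  cc <- as.numeric(contrasts$ctrl_exposed)
  dd <- as.numeric(contrasts$ctrl_unexposed)
  zero <- a == 0 | b == 0 | cc == 0 | dd == 0
  if (any(zero)) {
    if (zero_cell == "error") {
      stop("zero cell in 2x2 table for study ",
           paste(contrasts$study_id[zero], collapse = ", "),
           "; apply laplace_correct() upstream or use zero_cell = \"add_half\"")
    }
    a[zero] <- a[zero] + 0.5
    b[zero] <- b[zero] + 0.5
    cc[zero] <- cc[zero] + 0.5
    dd[zero] <- dd[zero] + 0.5
  }
  log_or <- log(a * dd / (b * cc))
  se <- sqrt(1 / a + 1 / b + 1 / cc + 1 / dd)
  data.frame(study_id = contrasts$study_id, model = contrasts$model,
             log_or = log_or, se = se, or = exp(log_or),
             ci_low = exp(log_or - .ci_z * se),
             ci_high = exp(log_or + .ci_z * se),
             continuity_added = zero, stringsAsFactors = FALSE)
}

#' Forest-plot data for one genetic model
#'
#' Per-study 2x2 cells, odds ratios and confidence intervals in one table,
#' ready to draw a forest plot or export as TSV.
#'
#' @inheritParams build_contrast
#' @inheritParams study_effects
#' @return Data frame joining the contrast cells with the study effects.
#' @export
forest_data <- function(dataset, model = genetic_models(),
                        zero_cell = c("error", "add_half")) {
  model <- match.arg(model)
  ct <- build_contrast(dataset, model)
  eff <- study_effects(ct, zero_cell)
  cbind(ct, eff[, c("log_or", "se", "or", "ci_low", "ci_high",
                    "continuity_added")])
}
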
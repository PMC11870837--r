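#' Configuration for the synthetic study-set generator
#'
#' Defines the statistical structure of a simulated collection of
#' case-control genotype studies. Defaults emulate the scale of a typical
#' candidate-gene meta-analysis: 20 studies, control minor-allele
#' frequencies uniform on 0.14-0.52, per-arm sample sizes spanning small
#' to large cohorts, no true association, no between-study heterogeneity,
#' Hardy-Weinberg-distributed controls and no publication selection.
#'
#' @param n_studies Number of studies (>= 1).
#' @param maf_range Uniform bounds for the control minor-allele frequency.
#' @param true_or True odds ratio; its interpretation depends on
#'   `effect_model`: per variant allele (multiplicative, the default), or
#'   the genotype-level odds ratio of a dominant or recessive penetrance.
#' @param tau Between-study standard deviation of the study log odds
#'   ratios around `log(true_or)`.
#' @param n_cases_range,n_controls_range Integer ranges for per-arm
#'   subject counts, drawn uniformly.
#' @param hwe_violation_rate Proportion of studies whose control genotypes
#'   are distorted away from Hardy-Weinberg equilibrium.
#' @param hwe_inbreeding Inbreeding coefficient applied to violator
#'   studies' control genotype probabilities (`p^2 + Fpq`, `2pq(1-F)`,
#'   `q^2 + Fpq`).
#' @param selection_strength Non-negative publication-selection weight:
#'   candidate studies are resampled with acceptance probability
#'   `exp(-strength * p * se)`, where `p` is the one-sided allelic
#'   p-value in the risk direction (directional selection is what skews a
#'   funnel) and `se` the allelic log-OR standard error, and are always
#'   accepted when `p < 0.05`. Small null-or-protective studies are
#'   preferentially suppressed, creating funnel asymmetry. 0 disables
#'   selection.
#' @param effect_model `"multiplicative"`, `"dominant"` or `"recessive"`.
#' @param seed Integer seed; every draw of the generator flows from it.
#' @return A `sim_config` list.
#' @export
#' @examples
#' cfg <- sim_config(n_studies = 5, true_or = 0.7, seed = 1)
#' simulate_dataset(cfg)
sim_config <- function(n_studies = 20, maf_range = c(0.14, 0.52),
                       true_or = 1, tau = 0,
                       n_cases_range = c(30, 700),
                       n_controls_range = c(40, 920),
                       hwe_violation_rate = 0, hwe_inbreeding = 0.2,
                       selection_strength = 0,
                       effect_model = c("multiplicative", "dominant",
                                        "recessive"),
                       seed = 1L) {
  effect_model <- match.arg(effect_model)
  stopifnot(n_studies >= 1,
            length(maf_range) == 2, maf_range[1] > 0,
            maf_range[1] <= maf_range[2], maf_range[2] < 1,
            true_or > 0, tau >= 0,
            n_cases_range[1] >= 1, n_cases_range[1] <= n_cases_range[2],
            n_controls_range[1] >= 1,
            n_controls_range[1] <= n_controls_range[2],
            hwe_violation_rate >= 0, hwe_violation_rate <= 1,
            selection_strength >= 0)
  structure(list(n_studies = as.integer(n_studies), maf_range = maf_range,
                 true_or = true_or, tau = tau,
                 n_cases_range = as.integer(n_cases_range),
                 n_controls_range = as.integer(n_controls_range),
                 hwe_violation_rate = hwe_violation_rate,
                 hwe_inbreeding = hwe_inbreeding,
                 selection_strength = selection_strength,
                 effect_model = effect_model, seed = as.integer(seed)),
            class = "sim_config")
}

# genotype probabilities of one study arm
.control_genotype_probs <- function(maf, inbreeding = 0) {
  q <- maf
  p <- 1 - q
  f <- inbreeding
  pr <- c(wtwt = p^2 + f * p * q, varwt = 2 * p * q * (1 - f),
          varvar = q^2 + f * p * q)
  pr / sum(pr)
}

# tilt control genotype probabilities by the genotype odds ratios implied
# by the study log odds ratio under the configured penetrance model
.case_genotype_probs <- function(ctrl_probs, log_or, effect_model) {
  or <- exp(log_or)
  tilt <- switch(effect_model,
                 multiplicative = c(1, or, or^2),  # OR^(variant allele count)
                 dominant = c(1, or, or),
                 recessive = c(1, 1, or))
  pr <- ctrl_probs * tilt
  pr / sum(pr)
}

# draw one study; returns a one-row data frame (no class, no validation)
.draw_study <- function(config, index) {
  maf <- runif(1, config$maf_range[1], config$maf_range[2])
  violator <- runif(1) < config$hwe_violation_rate
  ctrl_pr <- .control_genotype_probs(
    maf, if (violator) config$hwe_inbreeding else 0)
  study_log_or <- log(config$true_or) + rnorm(1, 0, config$tau)
  case_pr <- .case_genotype_probs(ctrl_pr, study_log_or,
                                  config$effect_model)
  n_cases <- sample(config$n_cases_range[1]:config$n_cases_range[2], 1)
  n_controls <- sample(config$n_controls_range[1]:config$n_controls_range[2], 1)
  case_g <- drop(rmultinom(1, n_cases, case_pr))
  ctrl_g <- drop(rmultinom(1, n_controls, ctrl_pr))
  data.frame(study_id = sprintf("sim_%03d", index),
             author = sprintf("Sim%03d", index),
             year = 2000L + (index %% 25L),
             ethnicity = "other", snp = "simulated",
             case_wtwt = case_g[1], case_varwt = case_g[2],
             case_varvar = case_g[3],
             ctrl_wtwt = ctrl_g[1], ctrl_varwt = ctrl_g[2],
             ctrl_varvar = ctrl_g[3],
             n_cases = n_cases, n_controls = n_controls,
             true_maf = maf, true_log_or = study_log_or,
             hwe_violator = violator, stringsAsFactors = FALSE)
}

# crude allelic one-sided p (risk direction) for the selection filter;
# directional selection is what produces funnel asymmetry
.allelic_p <- function(row) {
  a <- 2 * row$case_varvar + row$case_varwt + 0.5
  b <- 2 * row$case_wtwt + row$case_varwt + 0.5
  cc <- 2 * row$ctrl_varvar + row$ctrl_varwt + 0.5
  dd <- 2 * row$ctrl_wtwt + row$ctrl_varwt + 0.5
  z <- log(a * dd / (b * cc)) / sqrt(1 / a + 1 / b + 1 / cc + 1 / dd)
  pnorm(-z)
}

#' Simulate one case-control genotype study
#'
#' Control genotypes are multinomial draws from Hardy-Weinberg
#' proportions at a minor-allele frequency drawn from the configured
#' range (optionally distorted by an inbreeding coefficient for
#' designated violator studies). The study-specific log odds ratio is
#' `log(true_or)` plus a `Normal(0, tau)` heterogeneity draw, and case
#' genotype probabilities are the control probabilities tilted by the
#' genotype odds ratios of the configured penetrance model, renormalized.
#'
#' @param config A [sim_config()].
#' @param index Study index (drives the study id and the position in the
#'   seeded random stream).
#' @return A one-row study data frame carrying the simulation truth in
#'   `true_maf`, `true_log_or` and `hwe_violator`.
#' @export
simulate_study <- function(config, index = 1L) {
  stopifnot(inherits(config, "sim_config"))
  with_sim_rng(config$seed + 1000L * index, .draw_study(config, index))
}

#' Simulate a complete study set
#'
#' Draws `n_studies` studies under the configuration; with
#' `selection_strength > 0` each candidate study must additionally pass a
#' publication filter whose acceptance probability decreases in the
#' product of its association p-value and its standard error, so small
#' null studies are preferentially suppressed and the surviving set shows
#' funnel asymmetry.
#'
#' @param config A [sim_config()].
#' @return A `gene_dataset` with the per-study truth columns attached and
#'   the configuration stored in the `sim_config` attribute.
#' @export
#' @examples
#' d <- simulate_dataset(sim_config(n_studies = 8, true_or = 0.7, seed = 42))
#' nrow(d)
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  rows <- with_sim_rng(config$seed, {
    out <- vector("list", config$n_studies)
    for (i in seq_len(config$n_studies)) {
      repeat {
        cand <- .draw_study(config, i)
        if (config$selection_strength == 0) break
        pv <- .allelic_p(cand)
        se <- sqrt(sum(1 / (c(2 * cand$case_varvar + cand$case_varwt,
                              2 * cand$case_wtwt + cand$case_varwt,
                              2 * cand$ctrl_varvar + cand$ctrl_varwt,
                              2 * cand$ctrl_wtwt + cand$ctrl_varwt) + 0.5)))
        accept <- pv < 0.05 ||
          runif(1) < exp(-config$selection_strength * pv * se)
        if (accept) break
      }
      out[[i]] <- cand
    }
    out
  })
  df <- do.call(rbind, rows)
  ds <- as_gene_dataset(df, name = "simulated")
  attr(ds, "sim_config") <- config
  ds
}

# evaluate expr under a temporary RNG state seeded with `seed`,
# restoring (or removing) the caller's .Random.seed afterwards
with_sim_rng <- function(seed, expr) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
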
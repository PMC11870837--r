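#' Minor (variant) allele frequency from genotype counts
#'
#' Frequency of the variant allele, `(2 * varvar + varwt) / (2 * total)`.
#' By convention it is computed on the control arm, where genotype
#' frequencies are not distorted by the disease association.
#'
#' @param wtwt,varwt,varvar Genotype counts (vectors recycle).
#' @return Numeric vector of allele frequencies in `[0, 1]`.
#' @export
#' @examples
#' minor_allele_frequency(106, 162, 68)  # 0.443
minor_allele_frequency <- function(wtwt, varwt, varvar) {
  total <- wtwt + varwt + varvar
  if (any(total <= 0)) stop("genotype total must be positive")
  (2 * varvar + varwt) / (2 * total)
}

#' Hardy-Weinberg equilibrium test
#'
#' Pearson goodness-of-fit chi-square test of observed genotype counts
#' against the Hardy-Weinberg expectations `p^2, 2pq, q^2` computed from
#' the sample allele frequency; 1 degree of freedom, no continuity
#' correction. Monomorphic samples are degenerate: `chi2 = 0`, `p = 1`.
#'
#' @param wtwt,varwt,varvar Genotype counts of one sample (usually
#'   controls).
#' @return A list with `chi2`, `p_value`, `compliant` (`p >= 0.05`) and
#'   `degenerate`.
#' @export
#' @examples
#' hwe_test(600, 263, 55)  # Hardy-Weinberg violation, p = 5e-4
hwe_test <- function(wtwt, varwt, varvar) {
  n <- wtwt + varwt + varvar
  if (n <= 0) stop("genotype total must be positive")
  q <- (2 * varvar + varwt) / (2 * n)
  if (q == 0 || q == 1) {
    return(list(chi2 = 0, p_value = 1, compliant = TRUE, degenerate = TRUE))
  }
  p <- 1 - q
  expected <- n * c(p^2, 2 * p * q, q^2)
  chi2 <- sum((c(wtwt, varwt, varvar) - expected)^2 / expected)
  pval <- pchisq(chi2, df = 1, lower.tail = FALSE)
  list(chi2 = chi2, p_value = pval, compliant = pval >= 0.05,
       degenerate = FALSE)
}

#' Approximate statistical power of a single association study
#'
#' Power of a two-sided two-proportion chi-square comparison of case and
#' control variant-allele frequencies to detect a given per-allele odds
#' ratio, using the normal approximation with the study's subject counts
#' as group sizes. This is an approximation to the genotypic-risk power
#' computations produced by dedicated power calculators; the `method`
#' string records the convention.
#'
#' @param n_cases,n_controls Subject counts per arm.
#' @param maf Control variant-allele frequency, strictly inside `(0, 1)`.
#' @param assumed_or Odds ratio to detect (default 1.5).
#' @param alpha Two-sided significance level (default 0.05).
#' @return A list with `power`, `powered` (`power >= 0.75`), `assumed_or`,
#'   `alpha` and `method`.
#' @export
#' @examples
#' study_power(377, 336, 0.443)$power
study_power <- function(n_cases, n_controls, maf, assumed_or = 1.5,
                        alpha = 0.05) {
  if (n_cases <= 0 || n_controls <= 0) stop("sample sizes must be positive")
  if (maf <= 0 || maf >= 1) stop("maf must be strictly between 0 and 1")
  p0 <- maf
  p1 <- assumed_or * p0 / (1 - p0 + assumed_or * p0)
  n1 <- n_cases
  n2 <- n_controls
  pbar <- (n1 * p1 + n2 * p0) / (n1 + n2)
  se0 <- sqrt(pbar * (1 - pbar) * (1 / n1 + 1 / n2))
  se1 <- sqrt(p1 * (1 - p1) / n1 + p0 * (1 - p0) / n2)
  za <- qnorm(1 - alpha / 2)
  d <- abs(p1 - p0)
  power <- pnorm((d - za * se0) / se1) + pnorm((-d - za * se0) / se1)
  list(power = power, powered = power >= 0.75, assumed_or = assumed_or,
       alpha = alpha,
       method = "two-proportion allele-frequency z test, subject counts")
}

#' Shapiro-Wilk normality gate
#'
#' Returns the Shapiro-Wilk p-value used to route downstream tests
#' (values are treated as normally distributed iff `p > 0.05`). A constant
#' vector has no defined test; it is reported as degenerate with `p = NA`.
#'
#' @param values Numeric vector, `3 <= length <= 5000`.
#' @return A list with `p_value`, `normal` and `degenerate`.
#' @export
shapiro_gate <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 3) stop("need at least 3 values for normality test")
  if (length(values) > 5000) stop("at most 5000 values supported")
  if (diff(range(values)) == 0) {
    return(list(p_value = NA_real_, normal = NA, degenerate = TRUE))
  }
  p <- shapiro.test(values)$p.value
  list(p_value = p, normal = p > 0.05, degenerate = FALSE)
}

#' Per-study descriptive statistics
#'
#' One row per study: control minor-allele frequency, Hardy-Weinberg
#' equilibrium test on controls, and approximate power to detect the
#' assumed odds ratio at the study's sample sizes.
#'
#' @param dataset A `gene_dataset`.
#' @param assumed_or,alpha Passed to [study_power()].
#' @return Data frame with columns `study_id`, `maf`, `hwe_chi2`, `hwe_p`,
#'   `hwe_compliant`, `power`, `powered`.
#' @export
#' @examples
#' head(descriptives_table(bdnf_aud_studies()))
descriptives_table <- function(dataset, assumed_or = 1.5, alpha = 0.05) {
  rows <- lapply(seq_len(nrow(dataset)), function(i) {
    s <- dataset[i, ]
    maf <- minor_allele_frequency(s$ctrl_wtwt, s$ctrl_varwt, s$ctrl_varvar)
    hwe <- hwe_test(s$ctrl_wtwt, s$ctrl_varwt, s$ctrl_varvar)
    nca <- if (!is.na(s$n_cases)) s$n_cases else
      s$case_wtwt + s$case_varwt + s$case_varvar
    nco <- if (!is.na(s$n_controls)) s$n_controls else
      s$ctrl_wtwt + s$ctrl_varwt + s$ctrl_varvar
    pw <- if (maf > 0 && maf < 1) {
      study_power(nca, nco, maf, assumed_or, alpha)
    } else {
      list(power = NA_real_, powered = NA)
    }
    data.frame(study_id = s$study_id, maf = maf, hwe_chi2 = hwe$chi2,
               hwe_p = hwe$p_value, hwe_compliant = hwe$compliant,
               power = pw$power, powered = pw$powered,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
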
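# builders and independent oracles shared across the test files

# minimal dataset from case/control genotype count matrices (k x 3 each)
make_dataset <- function(case, ctrl, ethnicity = "other",
                         ids = sprintf("s%02d", seq_len(nrow(case))),
                         ...) {
  case <- matrix(case, ncol = 3)
  ctrl <- matrix(ctrl, ncol = 3)
  df <- data.frame(study_id = ids, author = ids,
                   year = 2000L + seq_len(nrow(case)),
                   ethnicity = rep_len(ethnicity, nrow(case)),
                   snp = "rs0",
                   case_wtwt = case[, 1], case_varwt = case[, 2],
                   case_varvar = case[, 3],
                   ctrl_wtwt = ctrl[, 1], ctrl_varwt = ctrl[, 2],
                   ctrl_varvar = ctrl[, 3],
                   stringsAsFactors = FALSE, ...)
  as_gene_dataset(df, name = "test")
}

# effects data frame straight from log ORs and standard errors
make_effects <- function(log_or, se,
                         ids = sprintf("s%02d", seq_along(log_or)),
                         model = "codominant") {
  data.frame(study_id = ids, model = model, log_or = log_or, se = se,
             or = exp(log_or),
             ci_low = exp(log_or - qnorm(0.975) * se),
             ci_high = exp(log_or + qnorm(0.975) * se),
             continuity_added = FALSE, stringsAsFactors = FALSE)
}

# brute-force cross-product odds ratio of one 2x2 table
oracle_or <- function(a, b, cc, dd) (a * dd) / (b * cc)

# brute-force Pearson goodness-of-fit statistic against Hardy-Weinberg
# expectations, via the generic chi-square machinery
oracle_hwe_chi2 <- function(wtwt, varwt, varvar) {
  n <- wtwt + varwt + varvar
  q <- (2 * varvar + varwt) / (2 * n)
  suppressWarnings(
    chisq.test(c(wtwt, varwt, varvar),
               p = c((1 - q)^2, 2 * (1 - q) * q, q^2))$statistic)
}

has_metafor <- requireNamespace("metafor", quietly = TRUE)

# absolute-tolerance comparison (testthat's tolerance is relative)
expect_near <- function(actual, expected, tol, info = NULL) {
  expect_lt(abs(actual - expected), tol + 1e-12, label =
              paste0(info %||% "", " |", deparse(substitute(actual)), " = ",
                     format(actual), " vs ", format(expected), "|"))
}
`%||%` <- function(a, b) if (is.null(a)) b else a
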
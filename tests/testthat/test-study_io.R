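test_that("the bundled dataset loads with the documented composition", {
  d <- bdnf_aud_studies()
  expect_s3_class(d, "gene_dataset")
  expect_equal(nrow(d), 20)
  expect_equal(as.vector(table(d$ethnicity)[c("Asian", "Caucasian")]),
               c(6, 14))
  expect_equal(sum(d$laplace_applied), 4)
  expect_equal(sum(!is.na(d$duplicate_subjects_of)), 1)
})

test_that("subject totals exclude duplicate-sample studies", {
  d <- bdnf_aud_studies()
  tc <- total_counts(d)
  expect_equal(tc$cases, 4095)
  expect_equal(tc$controls, 4727)

  # permutation invariance
  tc2 <- total_counts(d[sample(nrow(d)), ])
  expect_equal(tc2, tc)

  one <- make_dataset(c(5, 3, 2), c(12, 6, 2))
  expect_equal(total_counts(one), list(cases = 10, controls = 20))

  # a row flagged as re-genotyping another study's subjects adds nothing
  two <- make_dataset(rbind(c(5, 3, 2), c(4, 4, 2)),
                      rbind(c(12, 6, 2), c(11, 7, 2)))
  two$duplicate_subjects_of[2] <- "s01"
  expect_equal(total_counts(two), list(cases = 10, controls = 20))
})

test_that("write/read round trip preserves every field", {
  d <- bdnf_aud_studies()
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp))
  write_studies(d, tmp)
  d2 <- read_studies(tmp)
  expect_equal(as.data.frame(d2), as.data.frame(d), ignore_attr = TRUE)

  csv <- tempfile(fileext = ".csv")
  on.exit(unlink(csv), add = TRUE)
  write_studies(d, csv, dialect = "csv")
  expect_equal(as.data.frame(read_studies(csv, dialect = "csv")),
               as.data.frame(d), ignore_attr = TRUE)
})

test_that("schema and validation errors name the offending field", {
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp))

  # header only
  writeLines(paste(c("study_id", "author", "year", "ethnicity", "snp",
                     "case_wtwt", "case_varwt", "case_varvar",
                     "ctrl_wtwt", "ctrl_varwt", "ctrl_varvar"),
                   collapse = "\t"), tmp)
  expect_error(read_studies(tmp), "empty dataset")

  d <- as.data.frame(bdnf_aud_studies())
  expect_error(as_gene_dataset(d[, setdiff(names(d), "ctrl_varvar")]),
               "ctrl_varvar")

  d_neg <- d
  d_neg$case_varvar[3] <- -1
  expect_error(as_gene_dataset(d_neg), "su_2011_rs6265")

  d_eth <- d
  d_eth$ethnicity[1] <- "Martian"
  expect_error(as_gene_dataset(d_eth), "ethnicity")

  d_dup <- d
  d_dup$study_id[2] <- d_dup$study_id[1]
  expect_error(as_gene_dataset(d_dup), "duplicate study_id")
})

test_that("unparseable covariates become NA, not zero", {
  d <- bdnf_aud_studies()
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp))
  raw <- as.data.frame(d)
  raw$quality_score[1] <- "high"
  write.table(raw, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  d2 <- read_studies(tmp)
  expect_true(is.na(d2$quality_score[1]))
  expect_false(any(d2$quality_score == 0, na.rm = TRUE))
})

test_that("Laplace correction adds one pseudocount to zero-cell studies only", {
  z <- make_dataset(c(0, 5, 10), c(3, 4, 5))
  z2 <- laplace_correct(z)
  expect_equal(unlist(z2[1, c("case_wtwt", "case_varwt", "case_varvar")],
                      use.names = FALSE), c(1, 6, 11))
  expect_equal(unlist(z2[1, c("ctrl_wtwt", "ctrl_varwt", "ctrl_varvar")],
                      use.names = FALSE), c(4, 5, 6))
  expect_true(z2$laplace_applied)
  # original untouched
  expect_equal(z$case_wtwt, 0L)

  nz <- make_dataset(c(2, 3, 4), c(5, 6, 7))
  expect_warning(nz2 <- laplace_correct(nz), "not applied")
  expect_equal(as.data.frame(nz2), as.data.frame(nz))

  # idempotent in effect: one application clears all zeros
  counts <- z2[, c("case_wtwt", "case_varwt", "case_varvar",
                   "ctrl_wtwt", "ctrl_varwt", "ctrl_varvar")]
  expect_true(all(counts >= 1))
  expect_warning(laplace_correct(z2), "not applied")
})

test_that("bundled Laplace-flagged rows round-trip through the correction", {
  # the flagged rows ship post-correction; subtracting the pseudocount
  # must expose a zero cell and re-applying the correction must restore
  # the shipped counts exactly
  d <- bdnf_aud_studies()
  cols <- c("case_wtwt", "case_varwt", "case_varvar",
            "ctrl_wtwt", "ctrl_varwt", "ctrl_varvar")
  lap <- d[d$laplace_applied, , drop = FALSE]
  expect_gt(nrow(lap), 0)
  pre <- lap
  pre[, cols] <- as.matrix(lap[, cols]) - 1L
  pre$laplace_applied <- FALSE
  expect_true(all(apply(pre[, cols], 1, function(r) any(r == 0))))
  redone <- laplace_correct(pre)
  expect_equal(as.matrix(redone[, cols]), as.matrix(lap[, cols]))
  expect_true(all(redone$laplace_applied))
})
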
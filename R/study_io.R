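#' Read a table of case-control genotype-count studies
#'
#' Reads a delimited file of per-study genotype counts into a validated
#' study dataset. The canonical header is `study_id`, `author`, `year`,
#' `ethnicity`, `snp`, `case_wtwt`, `case_varwt`, `case_varvar`,
#' `ctrl_wtwt`, `ctrl_varwt`, `ctrl_varvar`, optionally followed by
#' `n_cases`, `n_controls`, `laplace_applied`, `duplicate_subjects_of` and
#' the covariates `mean_age_case`, `mean_age_control`, `sex_ratio_m_to_f`,
#' `males_only`, `quality_score`. Header matching is case-insensitive.
#' Missing values are written as `.` or left empty; unparseable covariate
#' entries become `NA`, never zero.
#'
#' @param path Path to a TSV or CSV file with the canonical header.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @return A `gene_dataset`: a data frame with one validated study per row,
#'   in file order.
#' @seealso [write_studies()], [bdnf_aud_studies()], [validate_studies()]
#' @export
read_studies <- function(path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (dialect == "tsv") "\t" else ","
  raw <- read.delim(path, sep = sep, header = TRUE,
                    stringsAsFactors = FALSE, na.strings = c("NA", ".", ""),
                    check.names = FALSE)
  names(raw) <- tolower(names(raw))
  as_gene_dataset(raw, name = basename(path))
}

#' Assemble and validate a study dataset
#'
#' Turns a data frame with the canonical columns into a validated
#' `gene_dataset`. Counts must be non-negative integers; `ethnicity` must
#' be one of `Caucasian`, `Asian`, `other`; `study_id` must be unique.
#' Optional columns are filled with defaults (`laplace_applied = FALSE`,
#' covariates absent).
#'
#' @param df Data frame with at least the required columns.
#' @param name Dataset label.
#' @return A `gene_dataset` data frame.
#' @export
as_gene_dataset <- function(df, name = "dataset") {
  missing_cols <- setdiff(.required_cols, names(df))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(df) == 0) stop("empty dataset")

  df$study_id <- as.character(df$study_id)
  if (anyDuplicated(df$study_id)) {
    stop("duplicate study_id: ",
         paste(unique(df$study_id[duplicated(df$study_id)]), collapse = ", "))
  }

  for (cc in .count_cols) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    bad <- is.na(v) | v < 0 | v != round(v)
    if (any(bad)) {
      stop("invalid count in cell '", cc, "' for study ",
           paste(df$study_id[bad], collapse = ", "),
           " (counts must be non-negative integers)")
    }
    df[[cc]] <- as.integer(v)
  }

  bad_eth <- !(df$ethnicity %in% .ethnicity_levels)
  if (any(bad_eth)) {
    stop("ethnicity must be one of ",
         paste(.ethnicity_levels, collapse = "/"), "; offending study: ",
         paste(df$study_id[bad_eth], collapse = ", "))
  }
  df$year <- as.integer(df$year)

  if (is.null(df$laplace_applied)) df$laplace_applied <- FALSE
  df$laplace_applied <- as.logical(df$laplace_applied)
  df$laplace_applied[is.na(df$laplace_applied)] <- FALSE
  if (is.null(df$duplicate_subjects_of)) df$duplicate_subjects_of <- NA_character_
  df$duplicate_subjects_of <- as.character(df$duplicate_subjects_of)

  # covariates: absent stays absent (NA), never imputed
  for (cv in c("n_cases", "n_controls", "mean_age_case", "mean_age_control",
               "sex_ratio_m_to_f", "quality_score")) {
    if (is.null(df[[cv]])) df[[cv]] <- NA_real_
    df[[cv]] <- suppressWarnings(as.numeric(df[[cv]]))
  }
  if (is.null(df$males_only)) df$males_only <- NA
  df$males_only <- as.logical(df$males_only)

  lap_zero <- df$laplace_applied &
    apply(df[, .count_cols], 1, function(r) any(r == 0))
  if (any(lap_zero)) {
    stop("laplace_applied studies must have all genotype cells >= 1: ",
         paste(df$study_id[lap_zero], collapse = ", "))
  }

  dangling <- !is.na(df$duplicate_subjects_of) &
    !(df$duplicate_subjects_of %in% df$study_id)
  if (any(dangling)) {
    stop("duplicate_subjects_of refers to unknown study_id: ",
         paste(df$duplicate_subjects_of[dangling], collapse = ", "))
  }

  rownames(df) <- NULL
  structure(df, class = c("gene_dataset", "data.frame"), name = name)
}

#' @rdname as_gene_dataset
#' @param x Object to validate.
#' @export
validate_studies <- function(x) {
  as_gene_dataset(as.data.frame(x), name = attr(x, "name") %||% "dataset")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a study dataset back to delimited text
#'
#' Inverse of [read_studies()]: writes the canonical columns so that a
#' read/write round trip reproduces the dataset field for field. `NA` is
#' written as `.`.
#'
#' @param dataset A `gene_dataset`.
#' @param path Output file path.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_studies <- function(dataset, path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  out <- as.data.frame(dataset)
  write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE,
              na = ".")
  invisible(path)
}

#' Laplace zero-cell correction
#'
#' Adds a pseudocount of one to all six genotype cells of every study that
#' has at least one zero genotype cell, and marks it `laplace_applied`.
#' Studies without a zero cell are returned unchanged with a warning, since
#' the correction is conditional on the presence of zeros. The correction
#' is idempotent in effect: after one application no zero cell remains, so
#' a second call is a no-op.
#'
#' @param dataset A `gene_dataset` (or a single-row subset of one).
#' @return The corrected dataset; the input is not modified.
#' @export
#' @examples
#' d <- bdnf_aud_studies()
#' d$case_varvar[1] <- 0L
#' d2 <- laplace_correct(d[1, , drop = FALSE])
#' d2[, c("case_wtwt", "case_varvar", "laplace_applied")]
laplace_correct <- function(dataset) {
  counts <- as.matrix(dataset[, .count_cols])
  has_zero <- apply(counts, 1, function(r) any(r == 0))
  if (!any(has_zero)) {
    warning("no zero genotype cell present; Laplace correction not applied")
    return(dataset)
  }
  dataset[has_zero, .count_cols] <- counts[has_zero, , drop = FALSE] + 1L
  dataset$laplace_applied[has_zero] <- TRUE
  dataset
}

#' Total case and control subject counts
#'
#' Sums per-arm subject totals over studies. Studies whose
#' `duplicate_subjects_of` field points at another study contribute no
#' subjects (they re-genotype the same sample at a second marker, so their
#' subjects are already counted once). If explicit `n_cases`/`n_controls`
#' totals are present they are used (these stay faithful to the enrolled
#' sample when genotype cells carry pseudocounts); otherwise arms are
#' summed over genotype cells.
#'
#' @param dataset A `gene_dataset`.
#' @return A list with elements `cases` and `controls`.
#' @export
#' @examples
#' total_counts(bdnf_aud_studies())
total_counts <- function(dataset) {
  if (nrow(dataset) == 0) stop("empty dataset")
  keep <- is.na(dataset$duplicate_subjects_of)
  d <- dataset[keep, , drop = FALSE]
  n_cases <- d$n_cases
  n_controls <- d$n_controls
  gc_cases <- rowSums(d[, c("case_wtwt", "case_varwt", "case_varvar")])
  gc_ctrls <- rowSums(d[, c("ctrl_wtwt", "ctrl_varwt", "ctrl_varvar")])
  n_cases[is.na(n_cases)] <- gc_cases[is.na(n_cases)]
  n_controls[is.na(n_controls)] <- gc_ctrls[is.na(n_controls)]
  list(cases = sum(n_cases), controls = sum(n_controls))
}

#' The bundled BDNF / alcohol use disorder dataset
#'
#' Genotype counts, ethnicity, marker labels and study-level covariates for
#' 20 case-control studies (17 articles; 4095 cases, 4727 controls) of
#' BDNF polymorphisms (rs6265 and three markers in complete linkage
#' disequilibrium with it) and alcohol use disorder. Four studies with zero
#' genotype cells are stored after Laplace correction (`laplace_applied`);
#' the rs16917204 arm of the Su study shares its subjects with the rs6265
#' arm and is flagged `duplicate_subjects_of`.
#'
#' @return A `gene_dataset` of 20 studies.
#' @export
#' @examples
#' d <- bdnf_aud_studies()
#' table(d$ethnicity)
bdnf_aud_studies <- function() {
  path <- system.file("extdata", "bdnf_aud_studies.tsv", package = "genemeta",
                      mustWork = TRUE)
  read_studies(path, dialect = "tsv")
}

#' @export
print.gene_dataset <- function(x, ...) {
  cat("<gene_dataset> ", attr(x, "name") %||% "", ": ", nrow(x),
      " studies\n", sep = "")
  tc <- total_counts(x)
  cat("  cases ", tc$cases, ", controls ", tc$controls, "\n", sep = "")
  print.data.frame(x, ...)
  invisible(x)
}
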
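#' Pipeline run configuration
#'
#' Bundles every tunable of [run_pipeline()] with its default: the
#' heterogeneity gate for random effects (`p_het < 0.10`), the Galbraith
#' residual band (+/-2), the minimum number of studies for
#' publication-bias testing (more than 10), the Bonferroni multiplier
#' (`NULL` = the number of association tests the run performs) and the
#' covariates offered to the meta-regression.
#'
#' @param input Path to a study table readable by [read_studies()], or a
#'   `gene_dataset`.
#' @param models Genetic models to analyse.
#' @param subgroup_key Study column to subgroup on, or `NULL` to skip
#'   subgrouping.
#' @param bonferroni_k Fixed Bonferroni multiplier; `NULL` counts the
#'   association tests actually run.
#' @param het_gate Heterogeneity p-value threshold for random effects.
#' @param galbraith_threshold Galbraith residual band half-width.
#' @param bias_min_studies Minimum analysis size for publication-bias and
#'   sensitivity follow-up (default 11, i.e. more than 10 studies).
#' @param force_all Run sensitivity/bias follow-up for every analysis,
#'   not only Bonferroni-significant ones.
#' @param metareg_covariates Covariate columns for [meta_regression()];
#'   `sample_size` is derived from the per-arm totals.
#' @param zero_cell Zero-cell policy for [study_effects()].
#' @param seed Optional integer seed (recorded; the pipeline itself is
#'   deterministic).
#' @param output_dir Directory for the result bundle, or `NULL` to skip
#'   writing files.
#' @return A `run_config` list.
#' @export
run_config <- function(input, models = genetic_models(),
                       subgroup_key = "ethnicity", bonferroni_k = NULL,
                       het_gate = 0.10, galbraith_threshold = 2,
                       bias_min_studies = 11, force_all = FALSE,
                       metareg_covariates = c("year", "mean_age_case",
                                              "quality_score", "ethnicity",
                                              "sex_ratio_m_to_f",
                                              "sample_size"),
                       zero_cell = c("error", "add_half"),
                       seed = NULL, output_dir = NULL) {
  zero_cell <- match.arg(zero_cell)
  stopifnot(het_gate > 0, het_gate < 1, galbraith_threshold > 0,
            bias_min_studies >= 3)
  models <- match.arg(models, genetic_models(), several.ok = TRUE)
  structure(list(input = input, models = models,
                 subgroup_key = subgroup_key, bonferroni_k = bonferroni_k,
                 het_gate = het_gate,
                 galbraith_threshold = galbraith_threshold,
                 bias_min_studies = bias_min_studies, force_all = force_all,
                 metareg_covariates = metareg_covariates,
                 zero_cell = zero_cell, seed = seed,
                 output_dir = output_dir),
            class = "run_config")
}

.write_tsv <- function(df, dir, file) {
  if (is.null(dir)) return(invisible(NULL))
  write.table(df, file.path(dir, file), sep = "\t", quote = FALSE,
              row.names = FALSE, na = ".")
}

#' Run the full meta-analysis pipeline
#'
#' Executes the complete analysis on one study table: per-study
#' descriptives; pre-outlier pooling for every genetic model, overall and
#' within subgroups; Galbraith outlier treatment for every heterogeneous
#' (random-effects) analysis, with post-outlier re-pooling; Bonferroni
#' correction over the run's family of association tests; leave-one-out
#' sensitivity and normality-gated publication-bias testing for
#' qualifying results (Bonferroni-significant with more than
#' `bias_min_studies - 1` studies, or all with `force_all`); and
#' single-covariate random-effects meta-regression. When `output_dir` is
#' set, writes `descriptives.tsv`, `results.tsv`, `outliers.tsv`,
#' `sensitivity.tsv`, `bias.tsv`, `metareg.tsv`, per-model
#' `forest_<model>.tsv` and `galbraith_<model>.tsv`, `run.log` and a
#' `config.json` echo. Reruns with an identical configuration and input
#' are byte-identical.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `dataset`, `descriptives`, `results`
#'   (data frame), `pool_results` (the `pool_result` objects),
#'   `outliers`, `sensitivity`, `bias`, `metareg`, `bonferroni_k`.
#' @export
#' @examples
#' bundle <- run_pipeline(run_config(bdnf_aud_studies(),
#'                                   models = "recessive"))
#' bundle$results
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  log_lines <- character(0)
  say <- function(...) {
    msg <- paste0(...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }

  dataset <- if (inherits(config$input, "gene_dataset")) config$input
             else read_studies(config$input)
  say("loaded ", nrow(dataset), " studies")

  out_dir <- config$output_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }

  desc <- descriptives_table(dataset)
  .write_tsv(desc, out_dir, "descriptives.tsv")

  # analysis groups: overall + one per subgroup level
  groups <- list(overall = dataset)
  if (!is.null(config$subgroup_key)) {
    key <- dataset[[config$subgroup_key]]
    for (lev in unique(key)) {
      groups[[lev]] <- dataset[key == lev, , drop = FALSE]
    }
  }

  pool_results <- list()
  outlier_rows <- list()
  galb_points <- setNames(vector("list", length(config$models)),
                          config$models)
  for (m in config$models) {
    for (lab in names(groups)) {
      g <- groups[[lab]]
      pre <- select_and_pool(g, m, label = lab, stage = "preoutlier",
                             het_gate = config$het_gate,
                             zero_cell = config$zero_cell)
      pool_results[[paste(lab, m, "pre", sep = ".")]] <- pre
      # outlier treatment targets the analyses the Q test called
      # heterogeneous: that is where outliers have something to explain
      if (pre$effects_model == "random" && pre$n >= 3) {
        tr <- outlier_treatment(g, m, label = lab,
                                het_gate = config$het_gate,
                                galbraith_threshold =
                                  config$galbraith_threshold,
                                zero_cell = config$zero_cell)
        pts <- tr$points
        pts$label <- lab
        pts$model <- m
        galb_points[[m]] <- rbind(galb_points[[m]], pts)
        if (length(tr$flagged) > 0 && !is.null(tr$post)) {
          pool_results[[paste(lab, m, "post", sep = ".")]] <- tr$post
          outlier_rows[[paste(lab, m, sep = ".")]] <-
            data.frame(label = lab, model = m, study_id = tr$flagged,
                       stringsAsFactors = FALSE)
          say(lab, "/", m, ": flagged ", length(tr$flagged),
              " outlier(s): ", paste(tr$flagged, collapse = ", "))
        } else {
          say(lab, "/", m, ": heterogeneous but no Galbraith outlier")
        }
      }
    }
  }

  k <- config$bonferroni_k %||% length(pool_results)
  say("Bonferroni multiplier k = ", k)
  pool_results <- lapply(pool_results, function(r) {
    r$p_bc <- bonferroni(r$p_assoc, k)
    r
  })
  results <- pool_results_table(pool_results)
  .write_tsv(results, out_dir, "results.tsv")

  outliers <- if (length(outlier_rows)) do.call(rbind, outlier_rows)
              else data.frame(label = character(0), model = character(0),
                              study_id = character(0))
  rownames(outliers) <- NULL
  .write_tsv(outliers, out_dir, "outliers.tsv")

  # follow-up: sensitivity + publication bias for qualifying results
  sens_rows <- list()
  bias_rows <- list()
  for (nm in names(pool_results)) {
    r <- pool_results[[nm]]
    qualifies <- config$force_all ||
      (!is.na(r$p_bc) && r$p_bc <= 0.05 && r$n >= config$bias_min_studies)
    if (!qualifies) next
    g <- groups[[r$label]]
    g <- g[g$study_id %in% r$studies_used, , drop = FALSE]
    if (nrow(g) >= 2) {
      sens <- leave_one_out(g, r$model, label = r$label,
                            het_gate = config$het_gate,
                            zero_cell = config$zero_cell)
      sens_rows[[nm]] <- data.frame(label = r$label, model = r$model,
                                    stage = r$stage, n = r$n,
                                    robust = sens$robust,
                                    stringsAsFactors = FALSE)
    }
    if (nrow(g) >= 3) {
      eff <- study_effects(build_contrast(g, r$model), config$zero_cell)
      pb <- publication_bias(eff, label = r$label)
      bias_rows[[nm]] <- data.frame(label = r$label, model = r$model,
                                    stage = r$stage, n = r$n,
                                    shapiro_p = pb$shapiro_p,
                                    normal = pb$normal,
                                    test_used = pb$test_used,
                                    statistic = pb$statistic,
                                    p_value = pb$p_value,
                                    evidence = pb$evidence,
                                    stringsAsFactors = FALSE)
    }
  }
  sensitivity <- if (length(sens_rows)) do.call(rbind, sens_rows)
                 else data.frame()
  bias <- if (length(bias_rows)) do.call(rbind, bias_rows)
          else data.frame()
  rownames(sensitivity) <- rownames(bias) <- NULL
  .write_tsv(sensitivity, out_dir, "sensitivity.tsv")
  .write_tsv(bias, out_dir, "bias.tsv")

  # meta-regression on the full study set, one covariate at a time
  mr_data <- as.data.frame(dataset)
  mr_data$sample_size <- with(mr_data, ifelse(
    !is.na(n_cases) & !is.na(n_controls), n_cases + n_controls,
    case_wtwt + case_varwt + case_varvar +
      ctrl_wtwt + ctrl_varwt + ctrl_varvar))
  mr_ds <- as_gene_dataset(mr_data, name = "metareg")
  covs <- intersect(config$metareg_covariates, names(mr_ds))
  mr_rows <- list()
  for (m in config$models) {
    for (cv in covs) {
      res <- tryCatch(
        suppressMessages(
          meta_regression(mr_ds, m, cv, k_bonferroni = length(covs),
                          zero_cell = config$zero_cell)),
        error = function(e) NULL)
      if (is.null(res)) {
        say("meta-regression skipped for ", m, " ~ ", cv)
        next
      }
      mr_rows[[paste(m, cv, sep = ".")]] <-
        data.frame(model = m, covariate = cv,
                   coefficient = res$coefficient, se = res$se,
                   p_value = res$p_value, p_bc = res$p_bc,
                   n_studies = res$n_studies, stringsAsFactors = FALSE)
    }
  }
  metareg <- if (length(mr_rows)) do.call(rbind, mr_rows) else data.frame()
  rownames(metareg) <- NULL
  .write_tsv(metareg, out_dir, "metareg.tsv")

  for (m in config$models) {
    .write_tsv(forest_data(dataset, m, zero_cell = config$zero_cell),
               out_dir, paste0("forest_", m, ".tsv"))
    if (!is.null(galb_points[[m]])) {
      .write_tsv(galb_points[[m]], out_dir, paste0("galbraith_", m, ".tsv"))
    }
  }

  if (!is.null(out_dir)) {
    echo <- config
    echo$input <- if (is.character(config$input)) config$input
                  else "(in-memory dataset)"
    echo$bonferroni_k_effective <- k
    jsonlite::write_json(unclass(echo), file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, null = "null", digits = NA)
    writeLines(log_lines, file.path(out_dir, "run.log"))
  }

  invisible(list(dataset = dataset, descriptives = desc, results = results,
                 pool_results = pool_results, outliers = outliers,
                 sensitivity = sensitivity, bias = bias, metareg = metareg,
                 bonferroni_k = k))
}
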
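# End-to-end orchestration: cohort in (CSV path, cohort_spec, or tibble),
# biomarker panel, group comparison, correlations with ICG-R15, per-marker
# ROC with Youden cutoffs, DeLong comparisons, the refit logistic model and
# the frozen published model, inter-reader ICC, and a serializable report.

# marker -> direction ("higher": rises with dysfunction)
marker_directions <- function() {
  c(ecv = "higher", iwr = "lower", lv_bsa = "lower", spv_bsa = "higher",
    hh15 = "higher", lhl15 = "lower")
}

required_cohort_columns <- function() {
  c("id", "icg_r15", "age", "sex", "height", "weight", "hct",
    "attn_liver_pre", "attn_liver_pvp", "attn_liver_dp",
    "attn_aorta_pre", "attn_aorta_dp", "lv", "spv",
    "heart_c3", "heart_c15", "liver_c3", "liver_c15",
    "cr", "tbil", "inr")
}

#' Read a cohort from CSV
#'
#' One row per patient; the column schema is documented in the data
#' dictionary shipped at `inst/extdata/cohort_dictionary.csv`. Time--activity
#' curves are carried as flat count columns (`heart_c3`, `heart_c15`,
#' `liver_c3`, `liver_c15`), i.e. two-point TACs sampled at 3 and 15 min.
#'
#' @param path CSV file path.
#' @return A tibble; errors list any missing required columns.
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) {
    abort(paste("no such cohort file:", path), class = "hepafunc_input_error")
  }
  df <- as_tibble(read.csv(path, stringsAsFactors = FALSE))
  missing <- setdiff(required_cohort_columns(), names(df))
  if (length(missing)) {
    abort(paste("cohort CSV is missing columns:",
                paste(missing, collapse = ", ")),
          class = "hepafunc_input_error")
  }
  df
}

#' Write a cohort to CSV
#'
#' List-columns (full TACs) are dropped; the flat 3/15-min count columns
#' carry the scintigraphy information.
#'
#' @param cohort Cohort tibble.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_cohort_csv <- function(cohort, path) {
  flat <- cohort[, !vapply(cohort, is.list, logical(1))]
  write.csv(as.data.frame(flat), path, row.names = FALSE)
  invisible(path)
}

#' Score a cohort with the frozen combined model and evaluate its ROC
#'
#' Every patient is scored with [combined_model_probability()] (the published
#' coefficients, not a refit), classified at the published 0.472 threshold,
#' and the score's ROC against severe dysfunction (ICG-R15 >= 20%) is
#' returned.
#'
#' @param cohort Tibble with columns `iwr`, `spv_bsa`, `lv_bsa`, `icg_r15`.
#' @param icg_cutoff ICG-R15 cutoff (%) defining severe dysfunction.
#' @return A `roc_result` with extra fields `scores` and `classified`.
#' @export
#' @examples
#' coh <- add_biomarkers(sample_cohort(cohort_spec(), seed = 1))
#' evaluate_frozen_model(coh)$auc
evaluate_frozen_model <- function(cohort, icg_cutoff = 20) {
  need <- c("iwr", "spv_bsa", "lv_bsa", "icg_r15")
  missing <- setdiff(need, names(cohort))
  if (length(missing)) {
    abort(paste("cohort is missing columns:", paste(missing, collapse = ", ")),
          class = "hepafunc_input_error")
  }
  if (nrow(cohort) == 0) {
    abort("cohort is empty", class = "hepafunc_input_error")
  }
  scores <- combined_model_probability(cohort$iwr, cohort$spv_bsa,
                                       cohort$lv_bsa)
  severe <- cohort$icg_r15 >= icg_cutoff
  res <- roc_analysis(scores, severe, direction = "higher")
  res$scores <- scores
  res$classified <- classify_severe_dysfunction(scores)
  res
}

group_comparison_table <- function(panel, vars) {
  severe <- panel$severe
  rows <- map(vars, function(v) {
    a <- panel[[v]][!severe]
    b <- panel[[v]][severe]
    wt <- tryCatch(welch_test(a, b), error = function(e) NULL)
    tibble(
      variable = v,
      mean_low = mean(a), sd_low = sd(a),
      mean_high = if (length(b)) mean(b) else NA_real_,
      sd_high = if (length(b)) sd(b) else NA_real_,
      p = if (is.null(wt)) NA_real_ else wt$p
    )
  })
  tbl <- list_rbind(rows)
  if ("sex" %in% names(panel) && length(unique(severe)) == 2) {
    counts <- table(factor(panel$sex == "M", c(FALSE, TRUE)),
                    factor(severe, c(FALSE, TRUE)))
    tbl <- bind_rows(tbl, tibble(
      variable = "sex_male",
      mean_low = mean(panel$sex[!severe] == "M"), sd_low = NA_real_,
      mean_high = mean(panel$sex[severe] == "M"), sd_high = NA_real_,
      p = fisher_exact(t(counts))
    ))
  }
  tbl
}

correlation_table <- function(panel, vars) {
  list_rbind(map(vars, function(v) {
    sc <- tryCatch(spearman_ci(panel$icg_r15, panel[[v]]),
                   error = function(e) NULL)
    tibble(variable = v,
           r = if (is.null(sc)) NA_real_ else sc$r,
           ci_low = if (is.null(sc)) NA_real_ else sc$ci_low,
           ci_high = if (is.null(sc)) NA_real_ else sc$ci_high)
  }))
}

#' Run the full cohort analysis pipeline
#'
#' Computes the biomarker panel for every patient, binarizes severity at
#' ICG-R15 >= 20%, and emits: a group-comparison table (means +/- SD per
#' group with Welch p-values, Fisher exact for sex), a Spearman correlation
#' table against ICG-R15, a per-marker ROC table with Youden thresholds and
#' a combined-model row, DeLong comparisons of each CT marker against LHL15
#' and against the combined model, a refit logistic model on
#' (IWR, LV/BSA, SpV/BSA), the frozen published-model evaluation, inter-
#' reader ICCs when second-reader attenuations are present, and run
#' metadata. With a single-severity-class cohort the ROC/DeLong/logistic
#' stages are skipped with a warning.
#'
#' @param cohort A [cohort_spec()] (sampled with `seed`), a CSV path, or a
#'   cohort tibble with the raw measurement columns.
#' @param seed Seed used when `cohort` is a spec; recorded in the metadata.
#' @param icg_cutoff ICG-R15 cutoff (%) defining severe dysfunction.
#' @return An object of class `hepafunc_report`: a list of tibbles
#'   (`group_comparison`, `correlations`, `roc_table`, `delong_comparisons`,
#'   `icc`), fitted objects (`logistic_fit`, `frozen_model`, `roc_results`),
#'   the per-patient `panel`, and `metadata`.
#' @export
#' @examples
#' rep <- run_pipeline(cohort_spec(), seed = 1)
#' rep$roc_table
run_pipeline <- function(cohort, seed = NULL, icg_cutoff = 20) {
  if (inherits(cohort, "cohort_spec")) {
    seed <- if (is.null(seed)) cohort$seed else seed
    data <- sample_cohort(cohort, seed = seed, tacs = FALSE)
  } else if (is.character(cohort) && length(cohort) == 1) {
    data <- read_cohort_csv(cohort)
  } else if (is.data.frame(cohort)) {
    data <- as_tibble(cohort)
  } else {
    abort("`cohort` must be a cohort_spec, a CSV path, or a data frame",
          class = "hepafunc_input_error")
  }
  missing <- setdiff(setdiff(required_cohort_columns(), "liver_c3"),
                     names(data))
  if (length(missing)) {
    abort(paste("cohort is missing columns:", paste(missing, collapse = ", ")),
          class = "hepafunc_input_error")
  }

  panel <- add_biomarkers(data)
  panel$severe <- panel$icg_r15 >= icg_cutoff
  markers <- marker_directions()
  comp_vars <- c("age", "enh_pvp", "enh_dp", "ecv", "iwr",
                 "lv_bsa", "spv_bsa", "hh15", "lhl15", "meld")
  corr_vars <- c("enh_pvp", "enh_dp", names(markers))

  report <- list(
    group_comparison = group_comparison_table(panel, comp_vars),
    correlations = correlation_table(panel, corr_vars),
    panel = panel
  )

  two_class <- length(unique(panel$severe)) == 2
  if (!two_class) {
    warn("cohort contains a single severity class; ROC, DeLong and logistic stages skipped")
    report$roc_table <- NULL
    report$delong_comparisons <- NULL
    report$logistic_fit <- NULL
    report$frozen_model <- NULL
    report$roc_results <- NULL
  } else {
    roc_results <- imap(markers, function(dir, v) {
      roc_analysis(panel[[v]], panel$severe, direction = dir)
    })
    frozen <- evaluate_frozen_model(panel, icg_cutoff = icg_cutoff)
    roc_results$combined <- frozen
    report$roc_results <- roc_results
    report$frozen_model <- frozen
    report$roc_table <- list_rbind(imap(roc_results, function(r, v) {
      bind_cols(tibble(marker = v), tidy(r))
    }))

    ct_markers <- c("ecv", "iwr", "lv_bsa", "spv_bsa")
    combined_scores <- frozen$scores
    dl_rows <- list()
    for (v in ct_markers) {
      dl <- delong_compare(panel[[v]], panel$lhl15, panel$severe,
                           direction_a = markers[[v]],
                           direction_b = "lower")
      dl_rows[[paste0(v, "_vs_lhl15")]] <-
        tibble(comparison = paste0(v, " vs lhl15"),
               auc_a = dl$auc_a, auc_b = dl$auc_b, z = dl$z, p = dl$p)
      dl2 <- delong_compare(panel[[v]], combined_scores, panel$severe,
                            direction_a = markers[[v]],
                            direction_b = "higher")
      dl_rows[[paste0(v, "_vs_combined")]] <-
        tibble(comparison = paste0(v, " vs combined"),
               auc_a = dl2$auc_a, auc_b = dl2$auc_b, z = dl2$z, p = dl2$p)
    }
    report$delong_comparisons <- list_rbind(dl_rows)
    report$logistic_fit <- tryCatch(
      fit_logistic(panel, c("iwr", "lv_bsa", "spv_bsa"), "severe"),
      error = function(e) {
        warn(paste("logistic refit failed:", conditionMessage(e)))
        NULL
      })
  }

  # inter-reader reproducibility on the iodine-uptake chain
  if (all(paste0("reader2_", c("attn_liver_pre", "attn_liver_pvp",
                               "attn_liver_dp", "attn_aorta_pre",
                               "attn_aorta_dp")) %in% names(panel))) {
    r2_enh_pvp <- panel$reader2_attn_liver_pvp - panel$reader2_attn_liver_pre
    r2_enh_dp <- panel$reader2_attn_liver_dp - panel$reader2_attn_liver_pre
    r2_aorta <- panel$reader2_attn_aorta_dp - panel$reader2_attn_aorta_pre
    icc_tbl <- tibble(
      quantity = c("enh_pvp", "enh_dp", "ecv", "iwr"),
      icc = c(
        icc_agreement(panel$enh_pvp, r2_enh_pvp),
        icc_agreement(panel$enh_dp, r2_enh_dp),
        icc_agreement(panel$ecv,
                      compute_ecv(r2_enh_dp, pmax(r2_aorta, 1e-6), panel$hct)),
        icc_agreement(panel$iwr,
                      compute_iwr(pmax(r2_enh_pvp, 1e-6), r2_enh_dp))
      )
    )
    report$icc <- icc_tbl
  } else {
    report$icc <- NULL
  }

  report$metadata <- list(
    n = nrow(panel),
    n_severe = sum(panel$severe),
    icg_cutoff = icg_cutoff,
    seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
    config_hash = rlang::hash(list(
      if (inherits(cohort, "cohort_spec")) cohort else names(data), icg_cutoff)),
    package_version = as.character(utils::packageVersion("hepafunc"))
  )
  structure(report, class = "hepafunc_report")
}

#' @export
print.hepafunc_report <- function(x, ...) {
  cat(sprintf("<hepafunc_report> n = %d (%d severe), seed %s\n",
              x$metadata$n, x$metadata$n_severe, x$metadata$seed))
  if (!is.null(x$roc_table)) {
    cat("\nROC table:\n")
    print(select(x$roc_table, "marker", "auc", "auc_low", "auc_high",
                 "threshold", "threshold_direction", "sens", "spec"))
  }
  if (!is.null(x$logistic_fit)) {
    cat("\nRefit logistic model:\n")
    print(x$logistic_fit$odds_ratios)
  }
  invisible(x)
}

#' Serialize an analysis report to JSON
#'
#' All tables and scalars at full precision; given the same cohort and seed
#' the output is byte-identical.
#'
#' @param report A `hepafunc_report`.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return The JSON string (invisibly when written to a file).
#' @export
report_to_json <- function(report, path = NULL) {
  out <- list(
    metadata = report$metadata,
    group_comparison = report$group_comparison,
    correlations = report$correlations,
    roc_table = report$roc_table,
    delong_comparisons = report$delong_comparisons,
    icc = report$icc,
    logistic_fit = if (is.null(report$logistic_fit)) NULL else
      tidy(report$logistic_fit)
  )
  json <- jsonlite::toJSON(out, dataframe = "rows", auto_unbox = TRUE,
                           digits = NA, null = "null", na = "null")
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}

#' Plot the report's ROC curves
#'
#' One panel per marker plus the combined model, each annotated with its
#' AUC.
#'
#' @param object A `hepafunc_report` containing ROC results.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot hepafunc_report
#' @export
autoplot.hepafunc_report <- function(object, ...) {
  if (is.null(object$roc_results)) {
    abort("report has no ROC results (single-class cohort?)")
  }
  df <- list_rbind(imap(object$roc_results, function(r, v) {
    r$curve |>
      mutate(marker = sprintf("%s (AUC %.3f)", v, r$auc)) |>
      arrange(1 - .data$spec, .data$sens)
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = 1 - .data$spec, y = .data$sens)) +
    ggplot2::geom_step(color = "steelblue") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         color = "grey60") +
    ggplot2::facet_wrap(~marker) +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity") +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}
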
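#' Write / read a cohort as delimited text
#'
#' `write_cohort()` writes one CSV per subject (`<subject_id>.csv` with
#' columns `time_s, ml_g, v_g, ap_g`, header row, "." decimal), a cohort
#' score table `cohort.csv` (`subject_id` plus the score columns present)
#' and a JSON sidecar `spec.json` recording the full generator spec
#' including its seed. `read_cohort()` reads the directory back into a
#' `tug_cohort` (true groups are not part of the on-disk format and are
#' absent after reading). `read_recording()` reads a single recording file;
#' the axis column order is configurable.
#'
#' @param cohort A `tug_cohort`.
#' @param dir Output/input directory (created if needed).
#' @return `write_cohort()` returns `dir` invisibly; `read_cohort()` a
#'   `tug_cohort`; `read_recording()` a [tug_recording()].
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "tug_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in cohort$subjects) {
    rec <- s$recording
    n <- length(rec$axes$ML)
    df <- data.frame(time_s = (seq_len(n) - 1L) / rec$sampling_rate,
                     ml_g = rec$axes$ML, v_g = rec$axes$V, ap_g = rec$axes$AP)
    .write_table(df, file.path(dir, paste0(s$subject_id, ".csv")))
  }
  .write_table(cohort_scores(cohort), file.path(dir, "cohort.csv"))
  # named atomic vectors must become objects, not bare arrays, in JSON
  spec_list <- lapply(unclass(cohort$spec), function(x)
    if (!is.null(names(x))) as.list(x) else x)
  jsonlite::write_json(spec_list, file.path(dir, "spec.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

# full-precision delimited text so round-trips preserve the signal
.write_table <- function(df, path) {
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) format(x, digits = 15, trim = TRUE,
                                                scientific = FALSE))
  write.csv(df, path, row.names = FALSE, quote = TRUE)
}

#' @rdname write_cohort
#' @param axis_cols Names of the ML, V, AP columns in a recording file, in
#'   that order.
#' @param time_col Name of the time column (used to infer the sampling rate
#'   when `sampling_rate` is `NULL`).
#' @param sampling_rate Sampling rate in Hz; inferred from `time_col` when
#'   `NULL`.
#' @param file Path of one recording CSV.
#' @export
read_recording <- function(file, axis_cols = c("ml_g", "v_g", "ap_g"),
                           time_col = "time_s", sampling_rate = NULL) {
  df <- read.csv(file, check.names = FALSE)
  if (!all(axis_cols %in% names(df))) {
    stop("recording file ", file, " lacks axis columns: ",
         paste(setdiff(axis_cols, names(df)), collapse = ", "))
  }
  if (is.null(sampling_rate)) {
    if (!time_col %in% names(df) || nrow(df) < 2L) {
      stop("cannot infer sampling rate: no '", time_col, "' column in ", file)
    }
    sampling_rate <- 1 / mean(diff(df[[time_col]]))
  }
  tug_recording(df[[axis_cols[1L]]], df[[axis_cols[2L]]], df[[axis_cols[3L]]],
                sampling_rate)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir, axis_cols = c("ml_g", "v_g", "ap_g"),
                        time_col = "time_s") {
  scores <- read.csv(file.path(dir, "cohort.csv"), check.names = FALSE,
                     colClasses = c(subject_id = "character"))
  spec_path <- file.path(dir, "spec.json")
  spec <- if (file.exists(spec_path)) {
    raw <- jsonlite::read_json(spec_path, simplifyVector = TRUE)
    for (fld in c("faller_fraction", "score_noise_sd")) {
      if (!is.null(raw[[fld]])) raw[[fld]] <- unlist(raw[[fld]])
    }
    do.call(cohort_spec, raw[names(raw) %in% names(formals(cohort_spec))])
  } else NULL
  subjects <- lapply(seq_len(nrow(scores)), function(i) {
    id <- scores$subject_id[i]
    rec <- read_recording(file.path(dir, paste0(id, ".csv")),
                          axis_cols = axis_cols, time_col = time_col)
    sc <- as.list(scores[i, setdiff(names(scores), "subject_id"),
                         drop = FALSE])
    list(subject_id = id, recording = rec, scores = sc, true_group = NULL)
  })
  structure(list(subjects = subjects, spec = spec), class = "tug_cohort")
}

#' Write / read feature and label tables
#'
#' Delimited-text round-trip of the 27-column feature table (canonical
#' feature names preserved exactly, including spaces and parentheses) and
#' the 0/1 label table.
#'
#' @param x Data frame as produced by [extract_cohort_features()] or
#'   [label_cohort()].
#' @param path CSV path.
#' @return `write_feature_table()` returns `path` invisibly;
#'   `read_feature_table()` the data frame with original column names.
#' @export
write_feature_table <- function(x, path) {
  .write_table(x, path)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  read.csv(path, check.names = FALSE,
           colClasses = c(subject_id = "character"))
}

#' Pipeline configuration
#'
#' Bundles every stage's settings: the cohort generator spec, MSE and PE
#' parameters, the CV configuration, the top-k list, the combination rule
#' and the statistics options. All defaults materialise here so the config
#' echoed next to a run's outputs is complete.
#'
#' @param cohort A [cohort_spec()].
#' @param mse An [mse_params()].
#' @param pe A [pe_params()].
#' @param cv A [cv_config()].
#' @param k_list Top-k sizes evaluated per condition.
#' @param label_rule Combination rule for multifactor labels
#'   (see [label_combined()]).
#' @param ks_method Normality-test flavour (see [ks_normality()]).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_spec(), mse = mse_params(),
                            pe = pe_params(), cv = cv_config(),
                            k_list = c(15L, 10L, 5L), label_rule = "and",
                            ks_method = "lilliefors") {
  stopifnot(inherits(cohort, "cohort_spec"), inherits(mse, "mse_params"),
            inherits(pe, "pe_params"), inherits(cv, "cv_config"))
  structure(list(cohort = cohort, mse = mse, pe = pe, cv = cv,
                 k_list = as.integer(k_list), label_rule = label_rule,
                 ks_method = ks_method),
            class = "pipeline_config")
}

#' Run the full screening pipeline
#'
#' Executes simulate -> extract -> label -> train/compare -> stats and
#' writes all artifacts under `out_dir`: the cohort files, `features.csv`,
#' `labels.csv`, a `results.json` with per-condition with/without-MSE AUC,
#' precision, recall, importance rankings and the statistical report, the
#' effective configuration (`config.json`) and a human-readable
#' `summary.txt`. Deterministic under the config seeds: identical config
#' gives byte-identical `results.json`.
#'
#' Conditions with a single class (e.g. no fallers under some label) abort
#' with an error naming the offending label.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, a list with `features`, `labels`, `comparisons` (one
#'   `mse_comparison` per label condition) and `report` (one data frame per
#'   condition).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  message("stage 1/5: simulating cohort (n = ", config$cohort$n_subjects, ")")
  cohort <- simulate_cohort(config$cohort)
  write_cohort(cohort, file.path(out_dir, "cohort"))
  message("stage 2/5: extracting features")
  features <- extract_cohort_features(cohort, mse = config$mse, pe = config$pe)
  write_feature_table(features, file.path(out_dir, "features.csv"))
  message("stage 3/5: labeling")
  labels <- label_cohort(cohort_scores(cohort), rule = config$label_rule)
  write_feature_table(labels, file.path(out_dir, "labels.csv"))
  conditions <- setdiff(names(labels), "subject_id")
  comparisons <- list()
  reports <- list()
  for (cond in conditions) {
    y <- labels[[cond]]
    if (length(unique(y)) < 2L) {
      stop("training aborted: label '", cond, "' has a single class")
    }
    message("stage 4/5: training condition '", cond, "' (",
            sum(y), " fall risk / ", length(y), ")")
    cmp <- compare_with_without_mse(features, y, config = config$cv,
                                    k_list = config$k_list, condition = cond)
    comparisons[[cond]] <- cmp
    reports[[cond]] <- comparison_report(cmp, ks_method = config$ks_method)
  }
  message("stage 5/5: writing results")
  results <- lapply(comparisons, function(cmp) {
    per_k <- lapply(as.character(cmp$k_list), function(k) list(
      k = as.integer(k),
      with_mse = list(auc = cmp$with[[k]]$auc,
                      precision = cmp$with[[k]]$precision,
                      recall = cmp$with[[k]]$recall,
                      features = cmp$with[[k]]$subset),
      without_mse = list(auc = cmp$without[[k]]$auc,
                         precision = cmp$without[[k]]$precision,
                         recall = cmp$without[[k]]$recall,
                         features = cmp$without[[k]]$subset)))
    list(ranking_with_mse = cmp$importance_with$ranking,
         mean_importance_with_mse =
           as.list(cmp$importance_with$mean_importance),
         top_k = per_k,
         stats = reports[[cmp$condition]])
  })
  jsonlite::write_json(results, file.path(out_dir, "results.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE,
                       dataframe = "rows")
  jsonlite::write_json(.config_as_list(config), file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(.summary_text(comparisons, reports, labels),
             file.path(out_dir, "summary.txt"))
  invisible(list(features = features, labels = labels,
                 comparisons = comparisons, report = reports))
}

.config_as_list <- function(config) {
  lapply(unclass(config), function(x) if (is.list(x)) unclass(x) else x)
}

.summary_text <- function(comparisons, reports, labels) {
  out <- c("Fall-risk screening pipeline summary", "")
  counts <- vapply(setdiff(names(labels), "subject_id"),
                   function(cond) sum(labels[[cond]]), 0L)
  out <- c(out, "Label distribution (fall risk / total):",
           sprintf("  %-12s %3d / %d", names(counts), counts,
                   nrow(labels)), "")
  for (cond in names(comparisons)) {
    cmp <- comparisons[[cond]]
    out <- c(out, sprintf("Condition %s:", cond))
    top5 <- select_top_k(cmp$importance_with, min(5L, length(cmp$importance_with$ranking)))
    out <- c(out, paste0("  top-5 features: ", paste(top5, collapse = ", ")))
    rep <- reports[[cond]]
    for (i in seq_len(nrow(rep))) {
      out <- c(out, sprintf(
        "  top %2d: AUC with MSE %.3f | without %.3f | paired t p = %.4f",
        rep$k[i], rep$auc_with[i], rep$auc_without[i], rep$t_p[i]))
    }
    out <- c(out, "")
  }
  out
}
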
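#' Pipeline configuration
#'
#' Bundles the stage parameters. Defaults reproduce the published
#' constants of the indices (vitality weights 0.60/0.40 with boundary
#' 0.52; mental-activity weights 0.75/0.25 with boundary 0.426) and
#' conventional segmentation settings.
#'
#' @param segmentation A [segmentation_params()].
#' @param weights An [index_weights()].
#' @param alpha,target_power,cor_method,min_specificity Evaluation
#'   options, see [evaluate_cohort()].
#' @param seed Integer seed governing all randomness in a pipeline run.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(segmentation = segmentation_params(),
                            weights = index_weights(),
                            alpha = 0.05, target_power = 0.8,
                            cor_method = "pearson",
                            min_specificity = NULL, seed = 1L) {
  structure(
    list(segmentation = segmentation, weights = weights, alpha = alpha,
         target_power = target_power, cor_method = cor_method,
         min_specificity = min_specificity, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Join recording indices with subject metadata into a cohort table
#'
#' @param recordings Output of [recording_indices()].
#' @param subjects Data frame with `subject_id`, `cohort`, `hamd` (and
#'   optionally a precomputed `group`; otherwise [assign_groups()] is
#'   applied).
#' @return A per-recording cohort table with columns `subject_id`,
#'   `session_id`, `group`, `hamd`, `vitality`, `vitality_sd`.
#' @export
build_cohort_table <- function(recordings, subjects) {
  if (!"group" %in% names(subjects)) subjects <- assign_groups(subjects)
  missing_subj <- setdiff(recordings$subject_id, subjects$subject_id)
  if (length(missing_subj)) {
    stop(sprintf("no metadata for subject(s): %s",
                 paste(missing_subj, collapse = ", ")), call. = FALSE)
  }
  idx <- match(recordings$subject_id, subjects$subject_id)
  data.frame(subject_id = recordings$subject_id,
             session_id = recordings$session_id,
             group = subjects$group[idx], hamd = subjects$hamd[idx],
             vitality = recordings$vitality,
             vitality_sd = recordings$vitality_sd)
}

#' Run the full scoring and evaluation pipeline
#'
#' Chains the stages on tabular inputs: emotion scores -> per-recording
#' indices -> per-subject mental activity -> cohort evaluation, writing
#' `recording_indices.csv`, `subjects.csv`, `cohort.csv` and
#' `report.json` under `out_dir`. When WAV paths are supplied instead of
#' an emotion table, each file is segmented and scored with the proxy
#' scorer first (writing `spans.csv` and `emotions.csv`). Given the same
#' inputs, config and seed, the run is deterministic.
#'
#' @param out_dir Output directory (created if needed).
#' @param emotions Emotion table (data frame or CSV path), or `NULL` to
#'   derive one from `wav_paths`.
#' @param subjects Subject metadata (data frame or CSV path) with
#'   `subject_id`, `cohort`, `hamd`; optional — without it the
#'   evaluation stage is skipped.
#' @param wav_paths Character vector of WAV files (used when `emotions`
#'   is `NULL`).
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with `recordings`, `subjects_series`,
#'   `cohort` (or `NULL`) and `report` (or `NULL`).
#' @export
run_pipeline <- function(out_dir, emotions = NULL, subjects = NULL,
                         wav_paths = NULL, config = pipeline_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)

  if (is.null(emotions)) {
    if (is.null(wav_paths)) {
      stop("supply 'emotions' or 'wav_paths'", call. = FALSE)
    }
    all_spans <- list()
    all_scores <- list()
    for (p in wav_paths) {
      rec <- load_wav(p)
      spans <- segment_utterances(rec, config$segmentation)
      sp <- cbind(subject_id = rec$subject_id, session_id = rec$session_id,
                  spans)
      all_spans[[p]] <- sp
      all_scores[[p]] <- proxy_score(rec, spans)
    }
    spans_tbl <- do.call(rbind, all_spans)
    write.csv(spans_tbl, file.path(out_dir, "spans.csv"), row.names = FALSE)
    emotions <- validate_emotions(do.call(rbind, all_scores))
    write.csv(emotions, file.path(out_dir, "emotions.csv"),
              row.names = FALSE)
  } else if (is.character(emotions)) {
    emotions <- read_emotion_table(emotions)
  } else {
    emotions <- validate_emotions(emotions)
  }

  recs <- recording_indices(emotions, config$weights)
  write.csv(recs, file.path(out_dir, "recording_indices.csv"),
            row.names = FALSE)
  series <- subject_series(recs, config$weights)
  write.csv(series, file.path(out_dir, "subjects.csv"), row.names = FALSE)

  cohort <- NULL
  report <- NULL
  if (!is.null(subjects)) {
    if (is.character(subjects)) {
      subjects <- read.csv(subjects, stringsAsFactors = FALSE,
                           colClasses = c(subject_id = "character"))
    }
    cohort <- build_cohort_table(recs, subjects)
    write.csv(cohort, file.path(out_dir, "cohort.csv"), row.names = FALSE)
    report <- evaluate_cohort(cohort, alpha = config$alpha,
                              target_power = config$target_power,
                              cor_method = config$cor_method,
                              min_specificity = config$min_specificity)
    report_json <- report[c("pearson_r", "pearson_p", "n_cor", "auc",
                            "cutpoint", "sensitivity", "specificity",
                            "cohens_d", "power", "required_n")]
    report_json$tukey_p <- as.list(report$tukey_p)
    report_json$group_means <- as.list(report$group_means)
    report_json$group_n <- as.list(report$group_n)
    jsonlite::write_json(report_json, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(list(recordings = recs, subjects_series = series,
                 cohort = cohort, report = report))
}
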
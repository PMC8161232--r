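#' @keywords internal
emotion_components <- c("anger", "joy", "sorrow", "calmness", "excitement")

#' @keywords internal
emotion_columns <- c("subject_id", "session_id", "utterance_index",
                     emotion_components)

#' Validate an emotion-score table
#'
#' Enforces the external emotion recogniser's output contract: one row
#' per utterance; columns `subject_id`, `session_id`, `utterance_index`
#' and the five components `anger`, `joy`, `sorrow`, `calmness`,
#' `excitement`, each an integer in 0-10. Anger is carried through but
#' unused by the indices, which are built from the other four components.
#'
#' @param emotions A data frame.
#' @return The validated table, ordered by (subject, session, utterance),
#'   with component columns coerced to integer.
#' @export
validate_emotions <- function(emotions) {
  if (!is.data.frame(emotions)) stop("'emotions' must be a data frame",
                                     call. = FALSE)
  missing_cols <- setdiff(emotion_columns, names(emotions))
  if (length(missing_cols)) {
    stop(sprintf("emotion table lacks column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  for (comp in emotion_components) {
    v <- emotions[[comp]]
    bad <- which(!is.finite(v) | v != round(v) | v < 0 | v > 10)
    if (length(bad)) {
      stop(sprintf("column '%s', row %d: value %s violates the integer 0-10 contract",
                   comp, bad[1], format(v[bad[1]])), call. = FALSE)
    }
    emotions[[comp]] <- as.integer(v)
  }
  key <- paste(emotions$subject_id, emotions$session_id,
               emotions$utterance_index, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup)) {
    stop(sprintf("duplicate utterance: subject '%s', session '%s', index %s",
                 emotions$subject_id[dup[1]], emotions$session_id[dup[1]],
                 emotions$utterance_index[dup[1]]), call. = FALSE)
  }
  ord <- order(emotions$subject_id, emotions$session_id,
               emotions$utterance_index)
  emotions <- emotions[ord, , drop = FALSE]
  rownames(emotions) <- NULL
  emotions
}

#' Read an emotion-score table from CSV
#'
#' @param path CSV file with the schema described in
#'   [validate_emotions()].
#' @return The validated, ordered table.
#' @export
read_emotion_table <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("emotion table not found: '%s'", path), call. = FALSE)
  }
  validate_emotions(read.csv(path, stringsAsFactors = FALSE,
                             colClasses = c(subject_id = "character",
                                            session_id = "character")))
}

#' Write an emotion-score table to CSV
#'
#' @param emotions A table satisfying [validate_emotions()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_emotion_table <- function(emotions, path) {
  emotions <- validate_emotions(emotions)
  write.csv(emotions, path, row.names = FALSE)
  invisible(path)
}

# zero-crossing rate per sample pair, in [0, 1]
zcr <- function(x) {
  if (length(x) < 2L) return(0)
  mean(diff(sign(x)) != 0 & sign(x[-length(x)]) != 0)
}

#' Deterministic acoustic stand-in scorer
#'
#' Maps simple per-utterance acoustic features to the five 0-10 integer
#' emotion components so the audio-to-indices pipeline can be exercised
#' end to end. This scorer is a plumbing device, not a speech-emotion
#' model: scores are monotone binnings of RMS energy (excitement, and its
#' complement calmness), zero-crossing rate (joy), and the relative
#' energy slope across the utterance (sorrow falls with a rising energy
#' contour; anger tracks its magnitude). Identical input always yields
#' identical scores. Scientific evaluation should use scores from a real
#' recogniser ([read_emotion_table()]) or the synthetic generator.
#'
#' @param rec An [audio_recording()].
#' @param spans Utterance spans from [segment_utterances()] on `rec`.
#' @return An emotion table (see [validate_emotions()]), one row per span.
#' @export
proxy_score <- function(rec, spans) {
  stopifnot(inherits(rec, "audio_recording"))
  if (nrow(spans) == 0L) {
    out <- data.frame(subject_id = character(), session_id = character(),
                      utterance_index = integer(), anger = integer(),
                      joy = integer(), sorrow = integer(),
                      calmness = integer(), excitement = integer())
    return(out)
  }
  sr <- rec$sample_rate
  clip10 <- function(v) as.integer(pmax(0, pmin(10, round(v))))
  rows <- lapply(seq_len(nrow(spans)), function(i) {
    i0 <- max(1L, floor(spans$start_s[i] * sr) + 1L)
    i1 <- min(length(rec$samples), ceiling(spans$end_s[i] * sr))
    x <- rec$samples[i0:i1]
    r <- sqrt(mean(x^2))
    z <- zcr(x)
    # relative energy slope: RMS of second half vs first half, per second
    half <- length(x) %/% 2L
    r1 <- sqrt(mean(x[seq_len(half)]^2))
    r2 <- sqrt(mean(x[(half + 1L):length(x)]^2))
    dur <- (i1 - i0 + 1L) / sr
    slope <- if (r1 + r2 > 0) (r2 - r1) / ((r1 + r2) / 2) / dur else 0
    data.frame(subject_id = rec$subject_id, session_id = rec$session_id,
               utterance_index = spans$index[i],
               anger = clip10(2 * abs(slope)),
               joy = clip10(50 * z),
               sorrow = clip10(5 - 2 * slope),
               calmness = clip10(10 - 25 * r),
               excitement = clip10(25 * r))
  })
  validate_emotions(do.call(rbind, rows))
}
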
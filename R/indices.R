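#' Index weights and decision boundaries
#'
#' Constants of the mood indices. Vitality is the weighted mean
#' `w_viv * vivacity + w_rel * relaxation` of a recording's mean vivacity
#' and mean relaxation; the line `w_viv X + w_rel Y = vitality_boundary`
#' separates the healthy from the patient side in the
#' (vivacity, relaxation) plane. Mental activity is
#' `w_meanvit * mean(vitality) + w_sd * mean(vitality SD)` over a
#' subject's accumulated recordings, with its own separating boundary.
#' The defaults (0.60/0.40, boundary 0.52; 0.75/0.25, boundary 0.426)
#' are stored constants of the published algorithm, not refit at run
#' time; [fit_separating_weights()] reproduces the fitting procedure on
#' synthetic data.
#'
#' @param w_viv,w_rel Vitality weights; must sum to 1.
#' @param vitality_boundary Healthy/patient boundary for vitality.
#' @param w_meanvit,w_sd Mental-activity weights; must sum to 1.
#' @param activity_boundary Healthy/patient boundary for mental activity.
#' @param sd_denominator `"n-1"` (sample SD, default) or `"n"` for the
#'   per-recording vitality standard deviation.
#' @return An `index_weights` list.
#' @export
index_weights <- function(w_viv = 0.60, w_rel = 0.40,
                          vitality_boundary = 0.52,
                          w_meanvit = 0.75, w_sd = 0.25,
                          activity_boundary = 0.426,
                          sd_denominator = c("n-1", "n")) {
  if (abs(w_viv + w_rel - 1) > 1e-9) {
    stop("'w_viv' + 'w_rel' must equal 1", call. = FALSE)
  }
  if (abs(w_meanvit + w_sd - 1) > 1e-9) {
    stop("'w_meanvit' + 'w_sd' must equal 1", call. = FALSE)
  }
  structure(
    list(w_viv = w_viv, w_rel = w_rel, vitality_boundary = vitality_boundary,
         w_meanvit = w_meanvit, w_sd = w_sd,
         activity_boundary = activity_boundary,
         sd_denominator = match.arg(sd_denominator)),
    class = "index_weights"
  )
}

#' Per-utterance vivacity, relaxation and vitality
#'
#' For each utterance: `vivacity = joy / (joy + sorrow)`,
#' `relaxation = calmness / (calmness + excitement)`, and
#' `vitality = w_viv * vivacity + w_rel * relaxation`. A component whose
#' denominator is zero (e.g. joy = sorrow = 0) is undefined: the index is
#' `NA` and the utterance is excluded from the affected recording-level
#' mean rather than imputed, which would bias vitality toward 0.5.
#' Vitality is present only when both components are.
#'
#' @param emotions An emotion table (see [validate_emotions()]).
#' @param weights An [index_weights()].
#' @return `emotions` with columns `vivacity`, `relaxation`, `vitality`
#'   appended, each in \[0, 1\] or `NA`.
#' @export
#' @examples
#' e <- data.frame(subject_id = "s1", session_id = "v1", utterance_index = 1,
#'                 anger = 0, joy = 6, sorrow = 2, calmness = 4,
#'                 excitement = 4)
#' utterance_indices(e)  # vivacity 0.75, relaxation 0.5, vitality 0.65
utterance_indices <- function(emotions, weights = index_weights()) {
  emotions <- validate_emotions(emotions)
  js <- emotions$joy + emotions$sorrow
  ce <- emotions$calmness + emotions$excitement
  emotions$vivacity <- ifelse(js > 0, emotions$joy / js, NA_real_)
  emotions$relaxation <- ifelse(ce > 0, emotions$calmness / ce, NA_real_)
  emotions$vitality <- weights$w_viv * emotions$vivacity +
    weights$w_rel * emotions$relaxation
  emotions
}

#' Recording-level indices
#'
#' Aggregates utterances within each recording (a `subject_id` x
#' `session_id` pair): unweighted means of the defined per-utterance
#' vivacity and relaxation values, recording vitality as their weighted
#' combination, and `vitality_sd`, the standard deviation of
#' per-utterance vitality (sample SD with denominator n-1 by default; 0
#' for a single utterance). Utterances with an undefined vitality are
#' counted in `n_excluded` and reported with a notice.
#'
#' @inheritParams utterance_indices
#' @return A data frame with one row per recording: `subject_id`,
#'   `session_id`, `mean_vivacity`, `mean_relaxation`, `vitality`,
#'   `vitality_sd`, `n_utterances_used`, `n_utterances_excluded`.
#' @export
recording_indices <- function(emotions, weights = index_weights()) {
  ui <- utterance_indices(emotions, weights)
  if (nrow(ui) == 0L) stop("no utterances in emotion table", call. = FALSE)
  key <- interaction(ui$subject_id, ui$session_id, drop = TRUE, sep = "\r")
  pieces <- split(ui, key)
  out <- do.call(rbind, lapply(pieces, function(g) {
    vit <- g$vitality[!is.na(g$vitality)]
    if (length(vit) == 0L) {
      stop(sprintf("recording subject '%s' session '%s' has no utterance with defined vitality",
                   g$subject_id[1], g$session_id[1]), call. = FALSE)
    }
    n_excl <- sum(is.na(g$vitality))
    if (n_excl > 0L) {
      message(sprintf("subject '%s' session '%s': %d utterance(s) with undefined components excluded",
                      g$subject_id[1], g$session_id[1], n_excl))
    }
    mv <- mean(g$vivacity, na.rm = TRUE)
    mr <- mean(g$relaxation, na.rm = TRUE)
    vsd <- if (length(vit) > 1L) {
      if (identical(weights$sd_denominator, "n")) {
        sqrt(mean((vit - mean(vit))^2))
      } else {
        sd(vit)
      }
    } else 0
    data.frame(subject_id = g$subject_id[1], session_id = g$session_id[1],
               mean_vivacity = mv, mean_relaxation = mr,
               vitality = weights$w_viv * mv + weights$w_rel * mr,
               vitality_sd = vsd,
               n_utterances_used = length(vit),
               n_utterances_excluded = n_excl)
  }))
  rownames(out) <- NULL
  out[order(out$subject_id, out$session_id), , drop = FALSE]
}

#' Subject-level accumulation and mental activity
#'
#' Accumulates a subject's recordings: `mean_vitality` and
#' `mean_vitality_sd` are unweighted means over recordings (each
#' recording counts once regardless of its utterance count), and
#' `mental_activity = w_meanvit * mean_vitality + w_sd * mean_vitality_sd`.
#'
#' @param recordings Output of [recording_indices()].
#' @inheritParams utterance_indices
#' @return A data frame with one row per subject: `subject_id`,
#'   `n_recordings`, `mean_vitality`, `mean_vitality_sd`,
#'   `mental_activity`.
#' @export
subject_series <- function(recordings, weights = index_weights()) {
  if (!is.data.frame(recordings) || nrow(recordings) == 0L) {
    stop("'recordings' must be a non-empty data frame", call. = FALSE)
  }
  pieces <- split(recordings, recordings$subject_id)
  out <- do.call(rbind, lapply(pieces, function(g) {
    mv <- mean(g$vitality)
    ms <- mean(g$vitality_sd)
    data.frame(subject_id = g$subject_id[1], n_recordings = nrow(g),
               mean_vitality = mv, mean_vitality_sd = ms,
               mental_activity = weights$w_meanvit * mv + weights$w_sd * ms)
  }))
  rownames(out) <- NULL
  out[order(out$subject_id), , drop = FALSE]
}

#' Fit a separating line with weights constrained to sum to one
#'
#' Reproduces, on data you can generate, the procedure behind the stored
#' constants: over the grid `w_x` in 0, 0.01, ..., 1 (with
#' `w_y = 1 - w_x`), score each point `w_x x + w_y y`, place the boundary
#' at the midpoint of the split between sorted scores that maximizes
#' balanced accuracy against the two group labels (either side of the
#' boundary may be the "high" group), and return the grid point with the
#' highest balanced accuracy. Ties prefer `w_x` closest to 0.5, then the
#' smaller `w_x`.
#'
#' @param x,y Numeric coordinates in \[0, 1\] (e.g. vivacity and
#'   relaxation, or mean vitality and mean vitality SD).
#' @param group Two-level factor or character vector of group labels.
#' @param grid_step Weight grid resolution (default 0.01).
#' @return A list: `w_x`, `w_y`, `boundary`, `balanced_accuracy`.
#' @export
fit_separating_weights <- function(x, y, group, grid_step = 0.01) {
  stopifnot(length(x) == length(y), length(x) == length(group))
  group <- as.factor(group)
  if (nlevels(droplevels(group)) != 2L) {
    stop("'group' must contain exactly two non-empty groups", call. = FALSE)
  }
  group <- droplevels(group)
  is_a <- group == levels(group)[1]
  n_a <- sum(is_a)
  n_b <- sum(!is_a)

  best_split <- function(score) {
    ord <- order(score)
    s <- score[ord]
    a <- is_a[ord]
    # after split k: points 1..k below the boundary
    below_a <- cumsum(a)[-length(s)]
    below_b <- seq_len(length(s) - 1L) - below_a
    # orientation 1: group A below; orientation 2: group B below
    bal1 <- (below_a / n_a + (n_b - below_b) / n_b) / 2
    bal2 <- (below_b / n_b + (n_a - below_a) / n_a) / 2
    bal <- pmax(bal1, bal2)
    valid <- s[-length(s)] < s[-1L]   # splits between distinct scores only
    bal[!valid] <- -Inf
    if (!any(valid)) return(list(acc = 0.5, boundary = s[1]))
    k <- which.max(bal)
    list(acc = bal[k], boundary = (s[k] + s[k + 1L]) / 2)
  }

  grid <- seq(0, 1, by = grid_step)
  accs <- numeric(length(grid))
  bounds <- numeric(length(grid))
  for (i in seq_along(grid)) {
    sp <- best_split(grid[i] * x + (1 - grid[i]) * y)
    accs[i] <- sp$acc
    bounds[i] <- sp$boundary
  }
  top <- which(accs > max(accs) - 1e-12)
  pick <- top[order(abs(grid[top] - 0.5), grid[top])][1]
  list(w_x = grid[pick], w_y = 1 - grid[pick], boundary = bounds[pick],
       balanced_accuracy = accs[pick])
}
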
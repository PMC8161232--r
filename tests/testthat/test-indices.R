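test_that("per-utterance indices match hand calculations", {
  ui <- utterance_indices(emotion_rows(joy = 6, sorrow = 2, calmness = 4,
                                       excitement = 4))
  expect_equal(ui$vivacity, 0.75)
  expect_equal(ui$relaxation, 0.5)
  expect_equal(ui$vitality, 0.65)

  maxed <- utterance_indices(emotion_rows(joy = 10, sorrow = 0,
                                          calmness = 10, excitement = 0))
  expect_equal(maxed$vivacity, 1)
  expect_equal(maxed$relaxation, 1)
  expect_equal(maxed$vitality, 1)
})

test_that("zero-denominator components are missing, not imputed", {
  ui <- utterance_indices(emotion_rows(joy = 0, sorrow = 0, calmness = 5,
                                       excitement = 5))
  expect_true(is.na(ui$vivacity))
  expect_equal(ui$relaxation, 0.5)
  expect_true(is.na(ui$vitality))
})

test_that("recording aggregation matches hand calculations", {
  # two utterances engineered to vitality 0.65 and 0.25
  e <- emotion_rows(joy = c(6, 2), sorrow = c(2, 6), calmness = c(4, 2),
                    excitement = c(4, 6))
  ui <- utterance_indices(e)
  expect_equal(ui$vitality, c(0.65, 0.25))
  rec <- recording_indices(e)
  expect_equal(rec$vitality, 0.45)
  expect_equal(rec$vitality_sd, sd(c(0.65, 0.25)))
  expect_equal(rec$vitality_sd, 0.2828427, tolerance = 1e-6)
  expect_equal(rec$n_utterances_used, 2L)

  single <- recording_indices(emotion_rows(joy = 7, sorrow = 3,
                                           calmness = 7, excitement = 3))
  expect_equal(single$vitality, 0.7)
  expect_equal(single$vitality_sd, 0)

  same <- recording_indices(emotion_rows(joy = c(6, 6, 6), sorrow = c(2, 2, 2),
                                         calmness = c(4, 4, 4),
                                         excitement = c(4, 4, 4)))
  expect_equal(same$vitality_sd, 0)
})

test_that("undefined utterances are excluded with a notice and counted", {
  e <- emotion_rows(joy = c(6, 0), sorrow = c(2, 0), calmness = c(4, 5),
                    excitement = c(4, 5))
  expect_message(rec <- recording_indices(e), "excluded")
  expect_equal(rec$n_utterances_used, 1L)
  expect_equal(rec$n_utterances_excluded, 1L)
  # the defined relaxation of the excluded utterance still feeds its mean
  expect_equal(rec$mean_relaxation, 0.5)

  allbad <- emotion_rows(joy = 0, sorrow = 0, calmness = 0, excitement = 0)
  expect_error(recording_indices(allbad), "no utterance")
})

test_that("subject accumulation and mental activity match hand calculations", {
  e <- emotion_rows(joy = c(6, 2), sorrow = c(2, 6), calmness = c(4, 2),
                    excitement = c(4, 6))
  series <- subject_series(recording_indices(e))
  expect_equal(series$mental_activity, 0.75 * 0.45 + 0.25 * sd(c(0.65, 0.25)))
  expect_equal(series$mental_activity, 0.4082107, tolerance = 1e-6)

  # recordings with identical vitality v and zero SD: activity = 0.75 v
  e2 <- rbind(emotion_rows(joy = 7, sorrow = 3, calmness = 7, excitement = 3,
                           session_id = "v1"),
              emotion_rows(joy = 7, sorrow = 3, calmness = 7, excitement = 3,
                           session_id = "v2"))
  s2 <- subject_series(recording_indices(e2))
  expect_equal(s2$n_recordings, 2L)
  expect_equal(s2$mental_activity, 0.75 * 0.7)

  # mean vitality 0.5, mean SD 0.3 -> 0.45, on the healthy side of 0.426
  w <- index_weights()
  expect_equal(w$w_meanvit * 0.5 + w$w_sd * 0.3, 0.45)
  expect_gt(0.45, w$activity_boundary)
})

test_that("weights must sum to one and sd denominator is configurable", {
  expect_error(index_weights(w_viv = 0.7, w_rel = 0.4), "must equal 1")
  expect_error(index_weights(w_meanvit = 0.9, w_sd = 0.2), "must equal 1")
  e <- emotion_rows(joy = c(6, 2), sorrow = c(2, 6), calmness = c(4, 2),
                    excitement = c(4, 6))
  rec_n <- recording_indices(e, index_weights(sd_denominator = "n"))
  expect_equal(rec_n$vitality_sd, sqrt(mean((c(0.65, 0.25) - 0.45)^2)))
})

test_that("recording vitality equals the mean of utterance vitalities when none are missing", {
  set.seed(21)
  for (i in 1:20) {
    n <- sample(2:15, 1)
    e <- emotion_rows(joy = sample(1:10, n, TRUE), sorrow = sample(0:9, n, TRUE),
                      calmness = sample(1:10, n, TRUE),
                      excitement = sample(0:9, n, TRUE))
    ui <- utterance_indices(e)
    rec <- recording_indices(e)
    expect_equal(rec$vitality, mean(ui$vitality), tolerance = 1e-12)
    expect_true(rec$vitality >= 0 && rec$vitality <= 1)
    expect_gte(rec$vitality_sd, 0)
  }
})

test_that("indices are monotone and complement-symmetric in their components", {
  base <- utterance_indices(emotion_rows(joy = 5, sorrow = 3, calmness = 6,
                                         excitement = 2))
  for (j in 6:10) {
    up <- utterance_indices(emotion_rows(joy = j, sorrow = 3, calmness = 6,
                                         excitement = 2))
    expect_gte(up$vivacity, base$vivacity)
  }
  for (cm in 7:10) {
    up <- utterance_indices(emotion_rows(joy = 5, sorrow = 3, calmness = cm,
                                         excitement = 2))
    expect_gte(up$relaxation, base$relaxation)
  }
  # swapping (joy, sorrow) and (calmness, excitement) complements the indices
  swapped <- utterance_indices(emotion_rows(joy = 3, sorrow = 5,
                                            calmness = 2, excitement = 6))
  expect_equal(swapped$vivacity, 1 - base$vivacity)
  expect_equal(swapped$relaxation, 1 - base$relaxation)
})

test_that("separating-weight fit handles separable, null and noisy cases", {
  # perfectly separable along x alone
  set.seed(31)
  xa <- runif(30, 0.6, 0.9); xb <- runif(30, 0.1, 0.4)
  y <- runif(60, 0.4, 0.6)
  fit <- fit_separating_weights(c(xa, xb), y,
                                rep(c("a", "b"), each = 30))
  expect_equal(fit$balanced_accuracy, 1)

  # identical distributions: balanced accuracy near chance
  z <- runif(200)
  fit0 <- fit_separating_weights(z, runif(200),
                                 rep(c("a", "b"), each = 100))
  expect_lt(fit0$balanced_accuracy, 0.65)

  expect_error(fit_separating_weights(1:3, 1:3, rep("a", 3)), "two")
})

test_that("separating-weight fit recovers a 0.6/0.4 generating discriminant", {
  set.seed(41)
  n <- 200
  # group means differ along (0.6, 0.4): the optimal linear score direction
  xa <- rnorm(n, 0.60, 0.07); ya <- rnorm(n, 0.55, 0.07)
  xb <- rnorm(n, 0.60 - 0.6 * 0.22, 0.07); yb <- rnorm(n, 0.55 - 0.4 * 0.22, 0.07)
  fit <- fit_separating_weights(c(xa, xb), c(ya, yb),
                                rep(c("healthy", "patient"), each = n))
  expect_lte(abs(fit$w_x - 0.6), 0.1)
  expect_gt(fit$balanced_accuracy, 0.7)
})
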
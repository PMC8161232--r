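test_that("HAM-D grouping follows the Zimmerman cutoffs", {
  meta <- data.frame(subject_id = c("h1", "p1", "p2", "p3"),
                     cohort = c("healthy", "patient", "patient", "patient"),
                     hamd = c(NA, 7, 8, 0))
  out <- assign_groups(meta)
  expect_equal(as.character(out$group),
               c("healthy", "no_depression", "depression", "no_depression"))

  bad <- data.frame(subject_id = "p9", cohort = "patient", hamd = NA)
  expect_error(assign_groups(bad), "HAM-D")
})

test_that("correlation matches direct formula evaluation and handles edge cases", {
  x <- c(1, 2, 3)
  y <- c(0.5, 0.4, 0.36)
  res <- pearson_r(x, y)
  manual <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(res$r, manual)

  perfect <- pearson_r(1:10, -(1:10))
  expect_equal(perfect$r, -1)

  expect_error(pearson_r(1:5, rep(2, 5)), "zero variance")
  expect_error(pearson_r(1:2, 2:3), "at least 3")

  rk <- pearson_r(1:10, (1:10)^3, method = "spearman")
  expect_equal(rk$r, 1)
})

test_that("correlation p-values are uniform under the null", {
  set.seed(46)
  n <- 46
  pvals <- replicate(2000, pearson_r(rnorm(n), rnorm(n))$p)
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("Tukey-Kramer detects large shifts and not duplicated groups", {
  set.seed(52)
  a <- rnorm(20)
  b <- rnorm(20) + 5         # 5 pooled SDs apart
  dup <- a + rnorm(20, 0, 1e-8)
  p <- tukey_kramer(list(a = a, b = b, c = dup))
  expect_lt(p[["b-a"]], 0.001)
  expect_gt(p[["c-a"]], 0.95)

  expect_error(tukey_kramer(list(a = 1:5, b = 3)), ">= 2")
  expect_error(tukey_kramer(list(a = 1:5)), "two groups")
})

test_that("AUC equals the exhaustive Mann-Whitney pair count", {
  r <- roc_auc(c(0.9, 0.8), c(0.1, 0.2))
  expect_equal(r$auc, 1)

  same <- roc_auc(c(0.3, 0.5, 0.7), c(0.3, 0.5, 0.7))
  expect_equal(same$auc, 0.5)

  set.seed(61)
  for (i in 1:10) {
    n_pos <- sample(2:30, 1)
    n_neg <- sample(2:30, 1)
    pos <- round(runif(n_pos), 2)   # rounding forces ties
    neg <- round(runif(n_neg), 2)
    expect_equal(roc_auc(pos, neg)$auc, auc_pair_oracle(pos, neg))
  }
  expect_error(roc_auc(numeric(0), 1:3), "non-empty")
})

test_that("AUC agrees with pROC on seeded data", {
  skip_if_not_installed("pROC")
  set.seed(62)
  pos <- rnorm(25, 0.6, 0.1)
  neg <- rnorm(30, 0.5, 0.1)
  ours <- roc_auc(pos, neg)$auc
  ref <- as.numeric(pROC::auc(
    pROC::roc(response = rep(c(1, 0), c(25, 30)),
              predictor = c(pos, neg), quiet = TRUE, direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("operating point maximizes Youden's J over the exhaustive scan", {
  perfect <- best_cutpoint(roc_auc(c(0.8, 0.9), c(0.1, 0.2)))
  expect_equal(perfect$youden_j, 1)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)

  null_op <- best_cutpoint(roc_auc(c(0.3, 0.5), c(0.3, 0.5)))
  expect_lte(null_op$youden_j, 0.5 + 1e-9)

  set.seed(63)
  for (i in 1:8) {
    pos <- round(rnorm(15, 0.6, 0.1), 2)
    neg <- round(rnorm(20, 0.5, 0.1), 2)
    roc <- roc_auc(pos, neg)
    op <- best_cutpoint(roc)
    expect_equal(op$youden_j, youden_oracle(pos, neg), tolerance = 1e-12)
    # reported sensitivity/specificity are consistent with the cutpoint
    expect_equal(op$sensitivity, mean(pos > op$cutpoint))
    expect_equal(op$specificity, mean(neg <= op$cutpoint))
  }

  fixed <- best_cutpoint(roc_auc(c(0.6, 0.7, 0.8), c(0.1, 0.65, 0.75)),
                         min_specificity = 1)
  expect_equal(fixed$specificity, 1)
})

test_that("Cohen's d matches its pooled-SD definition", {
  set.seed(71)
  a <- rnorm(30)
  expect_equal(cohens_d(a, a), 0)
  b <- rnorm(200, 0, 2)
  shifted <- b + sd(b)
  expect_equal(cohens_d(shifted, b), 1, tolerance = 0.01)
  expect_error(cohens_d(rep(1, 5), rep(1, 5)), "zero pooled SD")

  # summary-statistic route with SE -> SD conversion (means/SEs as printed
  # in a screening study: healthy 0.60 +/- 0.027 SE, n = 14; depression
  # 0.49 +/- 0.022 SE, n = 22)
  d_sum <- cohens_d_summary(0.60, 0.027 * sqrt(14), 14,
                            0.49, 0.022 * sqrt(22), 22)
  expect_equal(d_sum, 1.08, tolerance = 0.01)
})

test_that("noncentral-t power matches a Monte-Carlo rejection rate", {
  set.seed(81)
  n <- 20
  reps <- 50000
  d <- 1.0
  x <- matrix(rnorm(n * reps, d, 1), nrow = n)
  y <- matrix(rnorm(n * reps, 0, 1), nrow = n)
  mx <- colMeans(x); my <- colMeans(y)
  vx <- colSums((x - rep(mx, each = n))^2) / (n - 1)
  vy <- colSums((y - rep(my, each = n))^2) / (n - 1)
  sp2 <- (vx + vy) / 2
  tstat <- (mx - my) / sqrt(sp2 * 2 / n)
  reject <- mean(abs(tstat) > qt(0.975, 2 * n - 2))
  expect_equal(power_two_sample_t(d, n, n), reject, tolerance = 0.01)
})

test_that("power obeys its boundary identities and monotonicities", {
  expect_equal(power_two_sample_t(0, 20, 20, alpha = 0.05), 0.05,
               tolerance = 1e-9)
  pow_d <- sapply(c(0.5, 1, 1.5, 2), power_two_sample_t, n1 = 15, n2 = 15)
  expect_true(all(diff(pow_d) > 0))
  pow_n <- sapply(c(5, 10, 20, 40), function(n) power_two_sample_t(0.8, n, 12))
  expect_true(all(diff(pow_n) > 0))
  pow_a <- sapply(c(0.01, 0.05, 0.1), function(a)
    power_two_sample_t(0.8, 12, 12, alpha = a))
  expect_true(all(diff(pow_a) > 0))
  expect_error(power_two_sample_t(1, 1, 10), ">= 2")
  expect_error(power_two_sample_t(1, 10, 10, alpha = 1.2), "alpha")
})

test_that("sample-size solver inverts the power function", {
  for (d in c(0.5, 1.0, 1.5, 2.0)) {
    n <- required_n_two_sample_t(d, n_fixed = 100, power = 0.8)
    expect_equal(power_two_sample_t(d, 100, n), 0.8, tolerance = 1e-6)
  }
  ns <- sapply(c(0.5, 1.0, 1.5, 2.0), required_n_two_sample_t,
               n_fixed = 100, power = 0.8)
  expect_true(all(diff(ns) < 0))
  expect_error(required_n_two_sample_t(0, 22, 0.8), "nonzero")
  # with one group held small, power plateaus below the target
  expect_error(required_n_two_sample_t(0.5, 22, 0.8), "unattainable")
  expect_error(required_n_two_sample_t(1, 22, 0.04), "alpha")
})

test_that("cohort evaluation assembles consistent statistics", {
  sim <- simulate_cohort(cohort_spec(seed = 91))
  recs <- suppressMessages(recording_indices(sim$emotions))
  cohort <- build_cohort_table(recs, sim$subjects)
  rep <- suppressMessages(evaluate_cohort(cohort))
  expect_true(rep$auc >= 0 && rep$auc <= 1)
  expect_equal(rep$sensitivity,
               mean(cohort$vitality[cohort$group == "healthy"] > rep$cutpoint))
  expect_equal(rep$specificity,
               mean(cohort$vitality[cohort$group == "depression"] <= rep$cutpoint))
  expect_named(rep$tukey_p, c("no_depression-healthy", "depression-healthy",
                              "depression-no_depression"))
  expect_lt(rep$pearson_r, 0)   # severity anticorrelates with vitality

  # single-row group is rejected with an informative error
  tiny <- cohort[c(which(cohort$group == "healthy")[1],
                   which(cohort$group == "no_depression")[1:2],
                   which(cohort$group == "depression")[1:2]), ]
  expect_error(suppressMessages(evaluate_cohort(tiny)), "healthy")
})

test_that("null cohorts evaluate near chance", {
  means <- list(healthy = c(joy = 5, sorrow = 4, calmness = 5,
                            excitement = 5, anger = 1))
  means$no_depression <- means$healthy
  means$depression <- means$healthy
  aucs <- numeric(6)
  sig <- 0
  for (i in seq_along(aucs)) {
    # one session per subject: rows are then truly independent, the
    # regime in which the nominal Tukey-Kramer error rate applies
    sim <- simulate_cohort(cohort_spec(emotion_means = means,
                                       sessions_per_subject = 1,
                                       seed = 100 + i))
    recs <- suppressMessages(recording_indices(sim$emotions))
    rep <- suppressMessages(evaluate_cohort(
      build_cohort_table(recs, sim$subjects)))
    aucs[i] <- rep$auc
    sig <- sig + (min(rep$tukey_p) < 0.05)
  }
  expect_lt(abs(mean(aucs) - 0.5), 0.12)
  expect_lte(sig, 2)   # at most a couple of spurious family rejections
})
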
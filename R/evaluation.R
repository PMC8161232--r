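#' Assign screening groups from HAM-D scores
#'
#' Patient rows are split at the Zimmerman cutoffs: HAM-D <= 7 is
#' `no_depression`, >= 8 is `depression`. Rows from the healthy cohort
#' (no HAM-D assessment) are labelled `healthy`.
#'
#' @param meta Data frame with columns `subject_id`, `cohort`
#'   (`"healthy"` or `"patient"`), and `hamd` (integer, `NA` allowed for
#'   healthy rows only).
#' @return `meta` with a `group` factor (`healthy`, `no_depression`,
#'   `depression`) appended.
#' @export
assign_groups <- function(meta) {
  stopifnot(is.data.frame(meta), all(c("cohort", "hamd") %in% names(meta)))
  if (!all(meta$cohort %in% c("healthy", "patient"))) {
    stop("'cohort' must be \"healthy\" or \"patient\"", call. = FALSE)
  }
  patient <- meta$cohort == "patient"
  bad <- which(patient & is.na(meta$hamd))
  if (length(bad)) {
    stop(sprintf("patient row %d (subject '%s') lacks a HAM-D score",
                 bad[1], meta$subject_id[bad[1]]), call. = FALSE)
  }
  if (any(meta$hamd[patient] < 0)) {
    stop("HAM-D scores must be nonnegative", call. = FALSE)
  }
  meta$group <- factor(
    ifelse(!patient, "healthy",
           ifelse(meta$hamd <= 7, "no_depression", "depression")),
    levels = c("healthy", "no_depression", "depression")
  )
  meta
}

#' Correlation between severity and an index
#'
#' Product-moment (default) or rank correlation with its two-sided
#' p-value, via [stats::cor.test()].
#'
#' @param x,y Numeric vectors of equal length >= 3 with nonzero variance.
#' @param method `"pearson"` or `"spearman"`.
#' @return A list: `r`, `p`, `n`, `method`.
#' @export
pearson_r <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0) {
    stop("correlation undefined: zero variance", call. = FALSE)
  }
  ct <- cor.test(x, y, method = method, exact = FALSE)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x),
       method = method)
}

#' Tukey-Kramer pairwise comparisons
#'
#' Studentized-range pairwise p-values with the Kramer adjustment for
#' unequal group sizes, via one-way [stats::aov()] +
#' [stats::TukeyHSD()].
#'
#' @param values Numeric vector of index values, or a named list of
#'   numeric vectors (one per group, in which case `group` is ignored).
#' @param group Group labels aligned with `values`.
#' @return Named numeric vector of adjusted p-values, one per group pair
#'   (names `"a-b"`).
#' @export
tukey_kramer <- function(values, group = NULL) {
  if (is.list(values) && !is.data.frame(values)) {
    group <- rep(names(values), lengths(values))
    values <- unlist(values, use.names = FALSE)
  }
  group <- factor(group)
  if (nlevels(group) < 2L) stop("need at least two groups", call. = FALSE)
  sizes <- table(group)
  if (any(sizes < 2L)) {
    stop(sprintf("every group needs >= 2 values (group '%s' has %d)",
                 names(sizes)[which.min(sizes)], min(sizes)), call. = FALSE)
  }
  fit <- aov(values ~ group, data = data.frame(values = values, group = group))
  tk <- TukeyHSD(fit)$group
  setNames(tk[, "p adj"], rownames(tk))
}

#' Empirical ROC curve and AUC
#'
#' ROC of a score that is higher in the positive group (here: vitality,
#' higher in the healthy group). The curve is evaluated at every cutpoint
#' between distinct pooled scores (midpoints, plus one below and one
#' above the range); a point is called positive when its score exceeds
#' the cutpoint. The AUC is the normalized Mann-Whitney statistic:
#' pairs with `pos > neg` count 1, ties count 1/2.
#'
#' @param scores_pos Scores of the positive group (healthy).
#' @param scores_neg Scores of the negative group (depression).
#' @return A list: `auc` and `curve`, a data frame with columns
#'   `cutpoint`, `sensitivity`, `specificity`.
#' @export
roc_auc <- function(scores_pos, scores_neg) {
  scores_pos <- scores_pos[!is.na(scores_pos)]
  scores_neg <- scores_neg[!is.na(scores_neg)]
  n_pos <- length(scores_pos)
  n_neg <- length(scores_neg)
  if (n_pos == 0L || n_neg == 0L) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  pooled <- c(scores_pos, scores_neg)
  r <- rank(pooled)
  auc <- (sum(r[seq_len(n_pos)]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)

  u <- sort(unique(pooled))
  cuts <- if (length(u) == 1L) c(u - 1, u + 1) else {
    c(u[1] - diff(range(u)) / 100 - 1e-9, (u[-length(u)] + u[-1]) / 2,
      u[length(u)] + diff(range(u)) / 100 + 1e-9)
  }
  sens <- vapply(cuts, function(cc) mean(scores_pos > cc), numeric(1))
  spec <- vapply(cuts, function(cc) mean(scores_neg <= cc), numeric(1))
  list(auc = auc,
       curve = data.frame(cutpoint = cuts, sensitivity = sens,
                          specificity = spec))
}

#' Youden-optimal operating point
#'
#' Selects the cutpoint maximizing Youden's J = sensitivity +
#' specificity - 1; ties are broken toward higher sensitivity, the
#' screening-oriented choice. A fixed-specificity mode picks the highest
#' sensitivity among cutpoints achieving at least the requested
#' specificity.
#'
#' @param roc Result of [roc_auc()].
#' @param min_specificity When non-`NULL`, require at least this
#'   specificity instead of maximizing J.
#' @return A list: `cutpoint`, `sensitivity`, `specificity`, `youden_j`.
#' @export
best_cutpoint <- function(roc, min_specificity = NULL) {
  cv <- roc$curve
  if (!is.null(min_specificity)) {
    ok <- cv$specificity >= min_specificity
    if (!any(ok)) stop("requested specificity is unattainable", call. = FALSE)
    cv <- cv[ok, , drop = FALSE]
    pick <- order(-cv$sensitivity, -cv$specificity)[1]
  } else {
    j <- cv$sensitivity + cv$specificity - 1
    pick <- order(-j, -cv$sensitivity)[1]
  }
  list(cutpoint = cv$cutpoint[pick], sensitivity = cv$sensitivity[pick],
       specificity = cv$specificity[pick],
       youden_j = cv$sensitivity[pick] + cv$specificity[pick] - 1)
}

#' Cohen's d from raw samples
#'
#' Standardized mean difference `(mean_a - mean_b) / s_pooled`, with
#' `s_pooled^2 = ((n_a - 1) s_a^2 + (n_b - 1) s_b^2) / (n_a + n_b - 2)`.
#'
#' @param a,b Numeric vectors with >= 2 values each.
#' @return Cohen's d (positive when `a` has the larger mean).
#' @export
cohens_d <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L) {
    stop("both groups need >= 2 values", call. = FALSE)
  }
  cohens_d_summary(mean(a), sd(a), length(a), mean(b), sd(b), length(b))
}

#' Cohen's d from summary statistics
#'
#' @param mean_a,sd_a,n_a,mean_b,sd_b,n_b Group means, standard
#'   deviations and sizes. (Convert a standard error with
#'   `sd = se * sqrt(n)`.)
#' @return Cohen's d.
#' @export
cohens_d_summary <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b) {
  sp2 <- ((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / (n_a + n_b - 2)
  if (sp2 <= 0) stop("effect size undefined: zero pooled SD", call. = FALSE)
  (mean_a - mean_b) / sqrt(sp2)
}

#' Power of the two-sided two-sample t-test
#'
#' Exact power from the noncentral t distribution with
#' `df = n1 + n2 - 2` and noncentrality `d * sqrt(n1 n2 / (n1 + n2))`.
#'
#' @param d Standardized effect size (Cohen's d).
#' @param n1,n2 Group sizes (>= 2; fractional sizes are allowed so the
#'   function can be inverted continuously).
#' @param alpha Two-sided significance level in (0, 1).
#' @return Power in (0, 1).
#' @export
#' @examples
#' power_two_sample_t(d = 1.03, n1 = 22, n2 = 14)
power_two_sample_t <- function(d, n1, n2, alpha = 0.05) {
  stopifnot(is.numeric(d), length(d) == 1L)
  if (n1 < 2 || n2 < 2) stop("group sizes must be >= 2", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must be in (0, 1)",
                                     call. = FALSE)
  df <- n1 + n2 - 2
  ncp <- d * sqrt(n1 * n2 / (n1 + n2))
  tc <- qt(1 - alpha / 2, df)
  pt(-tc, df, ncp) + pt(tc, df, ncp, lower.tail = FALSE)
}

#' Sample size for a target power
#'
#' Solves `power_two_sample_t(d, n_fixed, n, alpha) = power` for the
#' second group's (fractional) size by monotone root-finding on the
#' noncentral-t power function.
#'
#' @inheritParams power_two_sample_t
#' @param n_fixed Size of the group held fixed.
#' @param power Target power in (`alpha`, 1).
#' @return The required size of the free group, as a real number.
#' @export
#' @examples
#' required_n_two_sample_t(d = 1.03, n_fixed = 22, power = 0.8)
required_n_two_sample_t <- function(d, n_fixed, power, alpha = 0.05) {
  if (d == 0) stop("effect size must be nonzero", call. = FALSE)
  if (power <= alpha || power >= 1) {
    stop("target power must lie in (alpha, 1)", call. = FALSE)
  }
  f <- function(n) power_two_sample_t(d, n_fixed, n, alpha) - power
  upper <- 1e7
  if (f(upper) < 0) {
    stop(sprintf("power %.3g is unattainable with d = %.3g and n_fixed = %g",
                 power, d, n_fixed), call. = FALSE)
  }
  lo <- 2 + 1e-9
  if (f(lo) >= 0) return(lo)
  uniroot(f, c(lo, upper), tol = 1e-9)$root
}

#' Full screening evaluation of a cohort table
#'
#' Assembles the evaluation battery on a per-recording cohort table:
#' correlation of vitality with HAM-D over patient rows, Tukey-Kramer
#' comparison of the three groups, ROC/AUC of vitality for healthy vs
#' depression with its operating point, Cohen's d (healthy minus
#' depression), exact power of the observed comparison at `alpha`, and
#' the healthy-group size required for the target power with the
#' depression-group size held fixed. Rows from repeated sessions of one
#' subject are treated as independent data points (a notice flags this
#' clustering caveat when it occurs).
#'
#' @param cohort Data frame with columns `subject_id`, `session_id`,
#'   `group` (`healthy`/`no_depression`/`depression`), `hamd`, and
#'   `vitality`.
#' @param alpha Significance level.
#' @param target_power Target for the sample-size solver.
#' @param cor_method Passed to [pearson_r()].
#' @param min_specificity Optional fixed-specificity operating-point rule
#'   (see [best_cutpoint()]).
#' @return An `eval_report` list with elements `pearson_r`, `pearson_p`,
#'   `n_cor`, `tukey_p`, `auc`, `roc`, `cutpoint`, `sensitivity`,
#'   `specificity`, `cohens_d`, `power`, `required_n`, `group_means`,
#'   `group_n`.
#' @export
evaluate_cohort <- function(cohort, alpha = 0.05, target_power = 0.8,
                            cor_method = c("pearson", "spearman"),
                            min_specificity = NULL) {
  stopifnot(is.data.frame(cohort),
            all(c("subject_id", "group", "vitality") %in% names(cohort)))
  cor_method <- match.arg(cor_method)
  cohort$group <- factor(cohort$group,
                         levels = c("healthy", "no_depression", "depression"))
  if (any(is.na(cohort$group))) {
    stop("unknown group label in cohort table", call. = FALSE)
  }
  if (anyDuplicated(cohort$subject_id[!duplicated(paste(cohort$subject_id,
                                                        cohort$session_id))])) {
    message("note: repeated sessions per subject are treated as independent data points")
  }
  split_v <- split(cohort$vitality, cohort$group)
  n <- vapply(split_v, length, integer(1))
  if (any(n < 2L)) {
    stop(sprintf("group '%s' has %d row(s); every group needs >= 2",
                 names(n)[which.min(n)], min(n)), call. = FALSE)
  }

  patient <- cohort$group != "healthy"
  corr <- pearson_r(cohort$hamd[patient], cohort$vitality[patient],
                    method = cor_method)
  tk <- tukey_kramer(cohort$vitality, cohort$group)
  roc <- roc_auc(split_v$healthy, split_v$depression)
  op <- best_cutpoint(roc, min_specificity = min_specificity)
  d <- cohens_d(split_v$healthy, split_v$depression)
  pw <- power_two_sample_t(d, n[["depression"]], n[["healthy"]], alpha)
  rn <- tryCatch(
    required_n_two_sample_t(d, n[["depression"]], target_power, alpha),
    error = function(e) NA_real_
  )

  structure(
    list(pearson_r = corr$r, pearson_p = corr$p, n_cor = corr$n,
         tukey_p = tk, auc = roc$auc, roc = roc$curve,
         cutpoint = op$cutpoint, sensitivity = op$sensitivity,
         specificity = op$specificity, cohens_d = d, power = pw,
         required_n = rn,
         group_means = vapply(split_v, mean, numeric(1)), group_n = n,
         alpha = alpha, target_power = target_power),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat("Screening evaluation of vitality\n")
  cat(sprintf("  group means (n): %s\n",
              paste(sprintf("%s %.3f (%d)", names(x$group_means),
                            x$group_means, x$group_n), collapse = ", ")))
  cat(sprintf("  HAM-D correlation (patients): r = %.3f, p = %.3g, n = %d\n",
              x$pearson_r, x$pearson_p, x$n_cor))
  cat("  Tukey-Kramer p-values:\n")
  for (nm in names(x$tukey_p)) {
    cat(sprintf("    %-28s %.4f\n", nm, x$tukey_p[[nm]]))
  }
  cat(sprintf("  healthy vs depression: AUC = %.3f, d = %.3f\n",
              x$auc, x$cohens_d))
  cat(sprintf("  operating point: cutpoint %.3f, sensitivity %.2f, specificity %.2f\n",
              x$cutpoint, x$sensitivity, x$specificity))
  cat(sprintf("  power at observed d and n (alpha %.2g): %.3f\n",
              x$alpha, x$power))
  if (!is.na(x$required_n)) {
    cat(sprintf("  healthy n required for power %.2g: %.2f\n",
                x$target_power, x$required_n))
  }
  invisible(x)
}
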
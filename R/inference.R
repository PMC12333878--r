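#' Regress age out of subject summary statistics
#'
#' Ordinary least-squares fit of the summary values on age (with intercept),
#' computed once on the pooled two-group sample within a sex stratum; the
#' residuals are the age-adjusted measures used by the permutation test.
#' Residuals sum to zero and are orthogonal to centered age.
#'
#' @param values Numeric vector of per-subject summaries.
#' @param ages Numeric vector of ages in years, same length, non-constant.
#' @return Numeric vector of residuals.
#' @export
#' @examples
#' regress_out_age(c(1, 2, 4), c(60, 70, 80))  # (1/6, -1/3, 1/6)
regress_out_age <- function(values, ages) {
  values <- as.numeric(values)
  ages <- as.numeric(ages)
  if (length(values) != length(ages)) {
    stop("`values` and `ages` must have the same length", call. = FALSE)
  }
  if (length(values) < 3L) {
    stop("age residualization needs at least 3 subjects", call. = FALSE)
  }
  if (stats::var(ages) == 0) {
    stop("ages are constant; cannot regress out age", call. = FALSE)
  }
  fit <- stats::lm.fit(cbind(1, ages), values)
  as.numeric(fit$residuals)
}

#' Two-tailed permutation test for a difference in group means
#'
#' The observed statistic is the absolute difference in group means,
#' `T_obs = |mean(x) - mean(y)|`. The pooled values are randomly re-assigned
#' into groups of the original sizes B times, and the p-value is the
#' proportion of permuted statistics at least as large as the observed one
#' (`p = (1/B) * sum(T(b) >= T_obs)`, no smoothing by default, so p can be 0).
#' When the number of distinct assignments `choose(m+n, m)` is at most
#' `exhaustive_limit`, all assignments are enumerated instead of sampled,
#' giving the exact permutation p-value.
#'
#' @param x,y Numeric vectors for the two groups (non-empty).
#' @param n_permutations Number of Monte-Carlo permutations B (default 50000).
#' @param seed Optional integer seed; the caller's RNG state is preserved.
#' @param exhaustive `"auto"` (enumerate when feasible), `"never"`, or
#'   `"always"` (error if infeasible).
#' @param exhaustive_limit Largest `choose(m+n, m)` enumerated in auto mode.
#' @param smooth_p Use the (1 + count) / (1 + B) estimator, which is strictly
#'   positive; off by default (exhaustive mode never smooths: it is exact).
#' @return A `permutation_result`: list with `t_obs`, `p_value`,
#'   `n_permutations` (actual count used), `method` (`"sampled"` or
#'   `"exhaustive"`), `group_sizes` and `permuted_quantiles` (digest of the
#'   null distribution).
#' @export
#' @examples
#' permutation_test(c(10, 11), c(0, 1))  # exhaustive: p = 1/3
permutation_test <- function(x, y, n_permutations = 50000L, seed = NULL,
                             exhaustive = c("auto", "never", "always"),
                             exhaustive_limit = 10000L, smooth_p = FALSE) {
  exhaustive <- match.arg(exhaustive)
  x <- as.numeric(x)
  y <- as.numeric(y)
  m <- length(x)
  n <- length(y)
  if (m < 1L || n < 1L) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  n_permutations <- assert_count(n_permutations, "n_permutations", min = 1L)
  assert_flag(smooth_p, "smooth_p")
  z <- c(x, y)
  total <- sum(z)
  n_tot <- m + n
  n_assign <- choose(n_tot, m)
  do_exhaustive <- switch(exhaustive,
                          auto = n_assign <= exhaustive_limit,
                          never = FALSE,
                          always = {
                            if (n_assign > exhaustive_limit) {
                              stop(sprintf("exhaustive enumeration infeasible: choose(%d, %d) = %g assignments",
                                           n_tot, m, n_assign), call. = FALSE)
                            }
                            TRUE
                          })
  stat_from_idx <- function(idx) {
    sx <- sum(z[idx])
    abs(sx / m - (total - sx) / n)
  }
  # same arithmetic path as the permuted statistics, so the identity
  # assignment always satisfies T(b) >= T_obs exactly
  t_obs <- stat_from_idx(seq_len(m))
  if (do_exhaustive) {
    combos <- utils::combn(n_tot, m)
    stats <- apply(combos, 2L, stat_from_idx)
    p <- mean(stats >= t_obs)
    b_used <- ncol(combos)
    method <- "exhaustive"
  } else {
    stats <- with_seed(seed, {
      vapply(seq_len(n_permutations),
             function(b) stat_from_idx(sample.int(n_tot, m)),
             numeric(1))
    })
    count <- sum(stats >= t_obs)
    p <- if (smooth_p) (1 + count) / (1 + n_permutations) else count / n_permutations
    b_used <- n_permutations
    method <- "sampled"
  }
  structure(
    list(t_obs = t_obs, p_value = p, n_permutations = b_used, method = method,
         group_sizes = c(m = m, n = n),
         permuted_quantiles = stats::quantile(stats, c(0.5, 0.9, 0.95, 0.99))),
    class = "permutation_result"
  )
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("<permutation_result> T_obs = %.4g, p = %.4g (%s, B = %d, groups %d/%d)\n",
              x$t_obs, x$p_value, x$method, x$n_permutations,
              x$group_sizes[["m"]], x$group_sizes[["n"]]))
  invisible(x)
}

#' Bonferroni-corrected per-comparison threshold
#'
#' Divides the family-wise alpha by the number of tests in the family. The
#' default family of 8 is the experiment grid per metric: two diagnostic
#' contrasts x two sexes x two test types. Decisions use the exact value
#' (0.05 / 8 = 0.00625); display conventionally rounds to 3 decimals (0.006).
#'
#' @param family_alpha Family-wise significance level.
#' @param family_size Number of tests in the family.
#' @return The per-comparison threshold.
#' @export
bonferroni_threshold <- function(family_alpha = 0.05, family_size = 8L) {
  assert_scalar_number(family_alpha, "family_alpha")
  if (family_alpha <= 0 || family_alpha >= 1) {
    stop("`family_alpha` must be in (0, 1)", call. = FALSE)
  }
  family_size <- assert_count(family_size, "family_size", min = 1L)
  family_alpha / family_size
}

#' Comparison specification for one grid cell
#'
#' @param contrast Character vector of two distinct diagnosis labels, tested
#'   as group 1 vs group 2 (e.g. `c("NC", "DEMENTIA")`).
#' @param sex `"F"` or `"M"`: the stratum analyzed.
#' @param test_type `"mean_based"` or `"peak_based"`.
#' @param metric_name Metric whose summaries are tested.
#' @param n_permutations Permutation count B.
#' @param seed Root seed; the cell's own stream is derived from it and the
#'   cell labels, so results do not depend on execution order.
#' @param family_alpha,family_size Bonferroni family (default 0.05 over the
#'   8 tests per metric).
#' @return A `comparison_spec` object.
#' @export
comparison_spec <- function(contrast, sex, test_type = c("mean_based", "peak_based"),
                            metric_name = "frobenius", n_permutations = 50000L,
                            seed = 1L, family_alpha = 0.05, family_size = 8L) {
  test_type <- match.arg(test_type)
  contrast <- as.character(contrast)
  if (length(contrast) != 2L || contrast[1] == contrast[2]) {
    stop("`contrast` must be two distinct diagnosis labels", call. = FALSE)
  }
  sex <- match.arg(sex, c("F", "M"))
  metric_name <- match.arg(metric_name, METRIC_NAMES)
  structure(
    list(contrast = contrast, sex = sex, test_type = test_type,
         metric_name = metric_name,
         n_permutations = assert_count(n_permutations, "n_permutations"),
         seed = assert_count(seed, "seed", min = 0L),
         family_alpha = family_alpha,
         family_size = assert_count(family_size, "family_size")),
    class = "comparison_spec"
  )
}

#' Run one stratified, age-residualized group comparison
#'
#' Joins summaries to metadata, restricts to the requested sex stratum and the
#' two diagnosis groups of the contrast, picks the mean-based or peak-based
#' summary, regresses out age on the pooled two-group sample, and runs the
#' two-tailed permutation test. Significance is declared when
#' `p <= family_alpha / family_size` (non-strict, so a p-value equal to the
#' threshold is significant).
#'
#' @param summaries Data frame from [summarize_subjects()].
#' @param metadata Data frame with columns `subject_id`, `age`, `sex`,
#'   `diagnosis`.
#' @param spec A [comparison_spec()].
#' @param residualize_age Set to `FALSE` to skip age adjustment (ablation used
#'   for calibration studies; the default matches the analysis design).
#' @return A `comparison_result`: list with `spec`, `permutation`
#'   (a `permutation_result`), `bonferroni_threshold` and `significant`.
#' @export
run_comparison <- function(summaries, metadata, spec, residualize_age = TRUE) {
  stopifnot(inherits(spec, "comparison_spec"))
  needed <- c("subject_id", "age", "sex", "diagnosis")
  if (!all(needed %in% names(metadata))) {
    stop("`metadata` must have columns subject_id, age, sex, diagnosis", call. = FALSE)
  }
  df <- merge(summaries, metadata, by = "subject_id")
  df <- df[df$sex == spec$sex & df$diagnosis %in% spec$contrast, , drop = FALSE]
  counts <- table(factor(df$diagnosis, levels = spec$contrast))
  if (any(counts == 0L)) {
    stop(sprintf("empty group in stratum sex=%s: %s", spec$sex,
                 paste(sprintf("%s n=%d", names(counts), counts), collapse = ", ")),
         call. = FALSE)
  }
  value_col <- if (spec$test_type == "mean_based") "mean_value" else "peak_value"
  values <- df[[value_col]]
  adjusted <- if (residualize_age) regress_out_age(values, df$age) else values
  g1 <- adjusted[df$diagnosis == spec$contrast[1]]
  g2 <- adjusted[df$diagnosis == spec$contrast[2]]
  cell_seed <- derive_seed(spec$seed, spec$metric_name,
                           paste(spec$contrast, collapse = "_vs_"),
                           spec$sex, spec$test_type)
  perm <- permutation_test(g1, g2, n_permutations = spec$n_permutations,
                           seed = cell_seed)
  threshold <- bonferroni_threshold(spec$family_alpha, spec$family_size)
  structure(
    list(spec = spec, permutation = perm, bonferroni_threshold = threshold,
         significant = perm$p_value <= threshold),
    class = "comparison_result"
  )
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> %s | %s vs %s (%s) | %s: p = %.4g (threshold %.5g)%s\n",
              x$spec$metric_name, x$spec$contrast[1], x$spec$contrast[2],
              x$spec$sex, x$spec$test_type, x$permutation$p_value,
              x$bonferroni_threshold,
              if (x$significant) " *" else ""))
  invisible(x)
}
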
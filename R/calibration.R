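# Monte-Carlo calibration of the full pipeline on repeated synthetic cohorts.
# Used to check that the permutation test holds its nominal size under the
# exchangeable null and that the peak statistic out-powers the mean statistic
# for transient disruptions.

#' Default reduced cohort configuration for calibration studies
#'
#' A deliberately small cohort so hundreds of replicates are affordable: two
#' diagnosis groups (NC, DEMENTIA), one sex stratum, 8 subjects per cell,
#' 12 regions, 90 time points. All arguments of [sim_config()] can be
#' overridden.
#'
#' @param seed Master seed for the cohort.
#' @param ... Overrides passed to [sim_config()].
#' @return A [sim_config()].
#' @export
calibration_config <- function(seed = 1L, ...) {
  defaults <- list(n_per_cell = 8L, n_regions = 12L, n_timepoints = 90L,
                   latent_rank = 3L,
                   diagnoses = c("NC", "DEMENTIA"), sexes = "F", seed = seed)
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}

#' Rejection rates of the full pipeline over repeated synthetic cohorts
#'
#' For each of `n_cohorts` independently simulated cohorts, runs the complete
#' analysis path (simulate, build dFC, harmonize, distance series, summaries,
#' age-residualized permutation test) for one metric and one contrast, and
#' records the mean-based and peak-based p-values. With all injected effects
#' zero this estimates the empirical size of the test at `alpha`; with a
#' nonzero `peak_effect` or `sustained_effect` it estimates power.
#'
#' @param n_cohorts Number of simulated cohorts.
#' @param cfg Base [sim_config()] (default [calibration_config()]); each
#'   replicate gets a distinct seed derived from `seed` and the replicate
#'   index.
#' @param records Optional fixed metadata table (subject_id, age, sex,
#'   diagnosis) overriding the cohort's own records; lets calibration studies
#'   impose, for example, an age imbalance between diagnosis groups.
#' @param metric Metric name to analyze.
#' @param contrast Two diagnosis labels.
#' @param sex Sex stratum.
#' @param window A [window_spec()].
#' @param n_permutations Permutation count B per test.
#' @param alpha Rejection level applied to the p-values.
#' @param seed Root seed for the whole study.
#' @param residualize_age Passed to [run_comparison()]; `FALSE` gives the
#'   no-adjustment ablation.
#' @return A list with `p_mean` and `p_peak` (vectors of length `n_cohorts`),
#'   `reject_mean` and `reject_peak` (rejection rates at `alpha`), `alpha`
#'   and `n_cohorts`.
#' @export
estimate_rejection_rates <- function(n_cohorts = 500L, cfg = calibration_config(),
                                     records = NULL, metric = "frobenius",
                                     contrast = c("NC", "DEMENTIA"), sex = "F",
                                     window = window_spec(),
                                     n_permutations = 999L, alpha = 0.05,
                                     seed = 1L, residualize_age = TRUE) {
  n_cohorts <- assert_count(n_cohorts, "n_cohorts")
  p_mean <- numeric(n_cohorts)
  p_peak <- numeric(n_cohorts)
  for (r in seq_len(n_cohorts)) {
    cfg_r <- cfg
    cfg_r$seed <- derive_seed(seed, "cohort", r)
    cohort <- generate_cohort(cfg_r)
    if (!is.null(records)) {
      stopifnot(nrow(records) == nrow(cohort$records))
      cohort$records <- records
      names(cohort$series) <- records$subject_id
      # regenerate with the imposed metadata so age-dependent signal structure
      # reflects the fixed ages
      cohort$series <- lapply(seq_len(nrow(records)), function(i) {
        generate_subject_series(records[i, ], cfg_r,
                                stream = derive_seed(cfg_r$seed, "subject", i))
      })
      names(cohort$series) <- records$subject_id
    }
    series <- cohort_distance_series(cohort, window = window, metrics = metric)
    summaries <- summarize_subjects(series[[metric]])
    for (tt in c("mean_based", "peak_based")) {
      spec <- comparison_spec(contrast = contrast, sex = sex, test_type = tt,
                              metric_name = metric,
                              n_permutations = n_permutations,
                              seed = derive_seed(seed, "cell", r))
      res <- run_comparison(summaries, cohort$records, spec,
                            residualize_age = residualize_age)
      if (tt == "mean_based") {
        p_mean[r] <- res$permutation$p_value
      } else {
        p_peak[r] <- res$permutation$p_value
      }
    }
  }
  list(p_mean = p_mean, p_peak = p_peak,
       reject_mean = mean(p_mean <= alpha), reject_peak = mean(p_peak <= alpha),
       alpha = alpha, n_cohorts = n_cohorts)
}
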
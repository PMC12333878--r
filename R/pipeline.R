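#' Pipeline configuration
#'
#' Bundles everything one end-to-end run needs: exactly one data source
#' (a cohort directory on disk, an in-memory `cohort`, or a [sim_config()] to
#' simulate from), the windowing parameters, the metrics to evaluate, and the
#' testing design.
#'
#' @param data_dir Directory written by [write_cohort()] (mutually exclusive
#'   with `cohort` and `simulate_from`).
#' @param cohort An in-memory `cohort` object.
#' @param simulate_from A [sim_config()] to generate the cohort from.
#' @param window A [window_spec()].
#' @param metrics Character vector of metric names (default: all seven).
#' @param contrasts List of 2-vectors of diagnosis labels (default NC vs
#'   DEMENTIA and NC vs MCI).
#' @param sexes Sex strata to test.
#' @param n_permutations Permutation count B per test.
#' @param seed Root seed for all randomness in the run.
#' @param family_alpha,family_size Bonferroni family (0.05 over the 8 tests
#'   per metric).
#' @param wasserstein_order_p Order of the Wasserstein matching.
#' @param peak_k Number of peaks in the peak summary.
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(data_dir = NULL, cohort = NULL, simulate_from = NULL,
                            window = window_spec(), metrics = METRIC_NAMES,
                            contrasts = list(c("NC", "DEMENTIA"), c("NC", "MCI")),
                            sexes = c("F", "M"), n_permutations = 50000L,
                            seed = 1L, family_alpha = 0.05, family_size = 8L,
                            wasserstein_order_p = 2, peak_k = 5L) {
  sources <- c(!is.null(data_dir), !is.null(cohort), !is.null(simulate_from))
  if (sum(sources) != 1L) {
    stop("exactly one of `data_dir`, `cohort`, `simulate_from` must be given",
         call. = FALSE)
  }
  metrics <- match.arg(metrics, METRIC_NAMES, several.ok = TRUE)
  if (anyDuplicated(metrics)) {
    stop("duplicate metric names", call. = FALSE)
  }
  sexes <- match.arg(sexes, SEXES, several.ok = TRUE)
  structure(
    list(data_dir = data_dir, cohort = cohort, simulate_from = simulate_from,
         window = window, metrics = metrics, contrasts = contrasts,
         sexes = sexes,
         n_permutations = assert_count(n_permutations, "n_permutations"),
         seed = assert_count(seed, "seed", min = 0L),
         family_alpha = family_alpha,
         family_size = assert_count(family_size, "family_size"),
         wasserstein_order_p = wasserstein_order_p,
         peak_k = assert_count(peak_k, "peak_k")),
    class = "pipeline_config"
  )
}

resolve_cohort <- function(config) {
  if (!is.null(config$cohort)) {
    return(list(cohort = config$cohort,
                excluded = data.frame(subject_id = character(0),
                                      reason = character(0))))
  }
  if (!is.null(config$simulate_from)) {
    return(list(cohort = generate_cohort(config$simulate_from),
                excluded = data.frame(subject_id = character(0),
                                      reason = character(0))))
  }
  read_cohort(config$data_dir, spec = config$window)
}

#' Distance series for every subject and metric
#'
#' Builds each subject's dFC sequence, harmonizes lengths across the cohort,
#' and computes one distance series per (subject, metric). Persistence
#' summaries are computed once per connectivity matrix and shared by the two
#' Wasserstein metrics.
#'
#' @param cohort A `cohort`.
#' @param window A [window_spec()].
#' @param metrics Character vector of metric names.
#' @param wasserstein_order_p Wasserstein matching order.
#' @return Named list (by metric) of lists of `distance_series`.
#' @export
cohort_distance_series <- function(cohort, window = window_spec(),
                                   metrics = METRIC_NAMES,
                                   wasserstein_order_p = 2) {
  sequences <- lapply(names(cohort$series), function(id) {
    build_dfc(cohort$series[[id]], spec = window)
  })
  sequences <- harmonize_lengths(sequences, target = "min")
  needs_ph <- any(metrics %in% c("wasserstein0", "wasserstein1"))
  persistence <- if (needs_ph) {
    lapply(sequences, function(s) lapply(s$matrices, persistence_decompose))
  }
  out <- lapply(metrics, function(mname) {
    spec <- metric_spec(mname, wasserstein_order_p = wasserstein_order_p)
    lapply(seq_along(sequences), function(i) {
      distance_series(sequences[[i]], spec,
                      persistence = if (is.null(persistence)) NULL else persistence[[i]])
    })
  })
  names(out) <- metrics
  out
}

#' Long-format table of distance series
#'
#' Flattens the output of [cohort_distance_series()] into one row per
#' (subject, metric, transition), suitable for TSV export or plotting.
#'
#' @param series_by_metric Named list (by metric) of lists of
#'   `distance_series`, as returned by [cohort_distance_series()].
#' @return A data.frame with columns `subject_id`, `metric`, `transition`,
#'   `distance`.
#' @export
distance_series_table <- function(series_by_metric) {
  rows <- lapply(unlist(series_by_metric, recursive = FALSE), function(s) {
    data.frame(subject_id = s$subject_id, metric = s$metric_name,
               transition = seq_along(s$values), distance = s$values,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full experiment grid
#'
#' Executes the end-to-end analysis: obtain the cohort (read or simulate),
#' build dFC sequences, harmonize lengths, compute distance series for every
#' metric, summarize each subject by mean and peak statistics, and run the
#' sex-stratified, age-residualized permutation test for every
#' (metric x contrast x sex x test type) cell. A cell whose stratum is empty
#' (for example no MCI subjects of one sex in a small cohort) is reported with
#' an `error` message and `NA` p-value rather than aborting the grid.
#'
#' @param config A [pipeline_config()].
#' @return A `results_table`: data.frame with one row per grid cell (columns
#'   metric, contrast, sex, test_type, n_group1, n_group2, t_obs, p_value,
#'   threshold, significant, n_permutations, method, error) carrying the
#'   per-subject `summaries`, the `excluded` table, and provenance (seed,
#'   config) as attributes.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  src <- resolve_cohort(config)
  cohort <- src$cohort
  if (nrow(cohort$records) == 0L) {
    stop("cohort is empty after inclusion filtering", call. = FALSE)
  }
  series_by_metric <- cohort_distance_series(
    cohort, window = config$window, metrics = config$metrics,
    wasserstein_order_p = config$wasserstein_order_p)
  summaries <- do.call(rbind, lapply(config$metrics, function(mname) {
    summarize_subjects(series_by_metric[[mname]], k = config$peak_k)
  }))
  grid <- expand.grid(metric = config$metrics,
                      contrast_i = seq_along(config$contrasts),
                      sex = config$sexes,
                      test_type = c("mean_based", "peak_based"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    contrast <- config$contrasts[[g$contrast_i]]
    spec <- comparison_spec(contrast = contrast, sex = g$sex,
                            test_type = g$test_type, metric_name = g$metric,
                            n_permutations = config$n_permutations,
                            seed = config$seed,
                            family_alpha = config$family_alpha,
                            family_size = config$family_size)
    base <- data.frame(metric = g$metric,
                       contrast = paste(contrast, collapse = "_vs_"),
                       sex = g$sex, test_type = g$test_type,
                       stringsAsFactors = FALSE)
    res <- tryCatch(
      run_comparison(summaries[summaries$metric == g$metric, , drop = FALSE],
                     cohort$records, spec),
      error = function(e) e)
    if (inherits(res, "error")) {
      cbind(base, data.frame(n_group1 = NA_integer_, n_group2 = NA_integer_,
                             t_obs = NA_real_, p_value = NA_real_,
                             threshold = bonferroni_threshold(config$family_alpha,
                                                              config$family_size),
                             significant = NA, n_permutations = NA_integer_,
                             method = NA_character_,
                             error = conditionMessage(res),
                             stringsAsFactors = FALSE))
    } else {
      cbind(base, data.frame(n_group1 = res$permutation$group_sizes[["m"]],
                             n_group2 = res$permutation$group_sizes[["n"]],
                             t_obs = res$permutation$t_obs,
                             p_value = res$permutation$p_value,
                             threshold = res$bonferroni_threshold,
                             significant = res$significant,
                             n_permutations = res$permutation$n_permutations,
                             method = res$permutation$method,
                             error = NA_character_,
                             stringsAsFactors = FALSE))
    }
  })
  results <- do.call(rbind, rows)
  attr(results, "summaries") <- summaries
  attr(results, "excluded") <- src$excluded
  attr(results, "provenance") <- list(
    seed = config$seed, n_permutations = config$n_permutations,
    metrics = config$metrics, n_subjects = nrow(cohort$records),
    window = unclass(config$window),
    config_hash = derive_seed(config$seed, jsonlite::toJSON(
      list(metrics = config$metrics, window = unclass(config$window),
           B = config$n_permutations), auto_unbox = TRUE)))
  class(results) <- c("results_table", class(results))
  results
}

#' Write result tables and a machine-readable report
#'
#' Writes `results.tsv` (the full grid), `results.json` (the grid plus
#' provenance), and one `table_<metric>.tsv` per metric in the conventional
#' report layout (Comparison | Test type | p value), with significant cells
#' flagged against the Bonferroni threshold.
#'
#' @param results A `results_table` from [run_pipeline()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the vector of files written.
#' @export
report_results <- function(results, out_dir) {
  if (!inherits(results, "results_table") || nrow(results) == 0L) {
    stop("`results` must be a non-empty results_table", call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- file.path(out_dir, "results.tsv")
  utils::write.table(as.data.frame(results), files, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  json_path <- file.path(out_dir, "results.json")
  jsonlite::write_json(
    list(results = as.data.frame(results),
         provenance = attr(results, "provenance")),
    json_path, auto_unbox = TRUE, digits = NA)
  files <- c(files, json_path)
  for (mname in unique(results$metric)) {
    sub <- results[results$metric == mname, , drop = FALSE]
    tab <- data.frame(
      Comparison = sprintf("%s (%s)", gsub("_vs_", " versus ", sub$contrast),
                           ifelse(sub$sex == "F", "female", "male")),
      `Test type` = ifelse(sub$test_type == "mean_based", "Mean based",
                           "5 peak based"),
      `p value` = sub$p_value,
      Significant = ifelse(is.na(sub$significant), "",
                           ifelse(sub$significant, "*", "")),
      check.names = FALSE, stringsAsFactors = FALSE)
    path <- file.path(out_dir, sprintf("table_%s.tsv", mname))
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, path)
  }
  invisible(files)
}
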
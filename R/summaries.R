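#' Mean of a distance series
#'
#' The average distance between successive connectivity matrices: the
#' subject's overall temporal variability in connectivity, used by the
#' mean-based group test.
#'
#' @param series A `distance_series` or numeric vector.
#' @return Scalar mean.
#' @export
series_mean <- function(series) {
  v <- if (inherits(series, "distance_series")) series$values else as.numeric(series)
  if (length(v) == 0L) {
    stop("distance series is empty", call. = FALSE)
  }
  mean(v)
}

#' Mean of the k largest values of a distance series
#'
#' The 5-peak statistic (k = 5): the average of the k largest distance values,
#' sensitive to brief but pronounced disruptions of connectivity that a
#' whole-series mean dilutes. "Peaks" are the k largest values of the series,
#' not local maxima; ties at the k-th largest are resolved by taking exactly k
#' values in stable order.
#'
#' @param series A `distance_series` or numeric vector of length >= k.
#' @param k Number of peaks to average (default 5).
#' @return Scalar peak mean, always >= [series_mean()].
#' @export
#' @examples
#' top_k_peak_mean(1:10)  # 8
top_k_peak_mean <- function(series, k = 5L) {
  v <- if (inherits(series, "distance_series")) series$values else as.numeric(series)
  k <- assert_count(k, "k", min = 1L)
  if (length(v) < k) {
    stop(sprintf("series shorter than k (%d < %d)", length(v), k), call. = FALSE)
  }
  mean(sort(v, decreasing = TRUE)[seq_len(k)])
}

#' Per-subject summary table of distance series
#'
#' Reduces each subject's distance series to the two scalar group-test
#' statistics: the series mean and the k-peak mean.
#'
#' @param series_list List of `distance_series` objects (one per subject, all
#'   from the same metric).
#' @param k Number of peaks for the peak statistic.
#' @return A data.frame with columns `subject_id`, `metric`, `mean_value`,
#'   `peak_value`, `series_length`.
#' @export
summarize_subjects <- function(series_list, k = 5L) {
  if (length(series_list) == 0L) {
    stop("`series_list` must be non-empty", call. = FALSE)
  }
  rows <- lapply(series_list, function(s) {
    data.frame(subject_id = s$subject_id,
               metric = s$metric_name,
               mean_value = series_mean(s),
               peak_value = top_k_peak_mean(s, k = k),
               series_length = length(s$values),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
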
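#' Sliding-window specification
#'
#' Parameters of the sliding-window dFC construction: a window of
#' `window_size` consecutive samples is advanced by `step` samples, the
#' trailing partial window is discarded, and (by default) the first and last
#' complete windows are removed to avoid boundary artifacts. With the default
#' window of 5 samples at a 3-second sampling interval each window spans 15 s
#' and consecutive windows are offset by 6 s.
#'
#' @param window_size Samples per window (>= 3; correlations over fewer than
#'   3 points are unstable).
#' @param step Samples between consecutive window starts (>= 1).
#' @param drop_first_last Drop the first and last complete windows?
#' @param min_timepoints,max_timepoints Inclusion bounds on the raw series
#'   length; scans outside `[min_timepoints, max_timepoints]` are flagged as
#'   excluded by [read_time_series()].
#' @return A `window_spec` object.
#' @export
#' @examples
#' window_spec()                 # defaults: s = 5, c = 2, 90-600 time points
#' window_spec(window_size = 10, step = 5)
window_spec <- function(window_size = 5L, step = 2L, drop_first_last = TRUE,
                        min_timepoints = 90L, max_timepoints = 600L) {
  window_size <- assert_count(window_size, "window_size", min = 3L)
  step <- assert_count(step, "step", min = 1L)
  assert_flag(drop_first_last, "drop_first_last")
  min_timepoints <- assert_count(min_timepoints, "min_timepoints", min = 1L)
  max_timepoints <- assert_count(max_timepoints, "max_timepoints", min = 1L)
  if (min_timepoints > max_timepoints) {
    stop("`min_timepoints` must not exceed `max_timepoints`", call. = FALSE)
  }
  structure(
    list(window_size = window_size, step = step,
         drop_first_last = drop_first_last,
         min_timepoints = min_timepoints, max_timepoints = max_timepoints),
    class = "window_spec"
  )
}

#' @export
print.window_spec <- function(x, ...) {
  cat(sprintf(
    "<window_spec> size %d samples, step %d, drop first/last: %s, inclusion [%d, %d] time points\n",
    x$window_size, x$step, x$drop_first_last, x$min_timepoints, x$max_timepoints))
  invisible(x)
}

#' Regional time-series container
#'
#' One subject's brain activity as a time-by-region matrix with its sampling
#' interval. Rows are time points at a fixed interval, columns are atlas
#' regions.
#'
#' @param values Numeric T x M matrix, all values finite.
#' @param region_labels Character vector of M region labels; defaults to the
#'   column names of `values` or `R001..R<M>`.
#' @param sampling_interval_s Seconds between consecutive time points.
#' @param subject_id Optional subject identifier carried through the pipeline.
#' @return A `regional_ts` object.
#' @export
regional_ts <- function(values, region_labels = NULL, sampling_interval_s = 3,
                        subject_id = NA_character_) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (ncol(values) < 3L) {
    stop("a regional time series needs at least 3 regions", call. = FALSE)
  }
  if (!all(is.finite(values))) {
    stop("time-series values must all be finite", call. = FALSE)
  }
  assert_scalar_number(sampling_interval_s, "sampling_interval_s")
  if (is.null(region_labels)) {
    region_labels <- colnames(values)
  }
  if (is.null(region_labels)) {
    region_labels <- sprintf("R%03d", seq_len(ncol(values)))
  }
  if (length(region_labels) != ncol(values)) {
    stop("`region_labels` length must match the number of columns", call. = FALSE)
  }
  colnames(values) <- region_labels
  structure(
    list(values = values, region_labels = as.character(region_labels),
         sampling_interval_s = as.double(sampling_interval_s),
         subject_id = as.character(subject_id)),
    class = "regional_ts"
  )
}

#' @export
print.regional_ts <- function(x, ...) {
  cat(sprintf("<regional_ts> %s: %d time points x %d regions, interval %.3g s\n",
              x$subject_id, nrow(x$values), ncol(x$values), x$sampling_interval_s))
  invisible(x)
}

#' Read a regional time-series TSV file
#'
#' Parses a tab-separated file whose header row holds region labels and whose
#' data rows hold one time point each. The series is checked against the
#' inclusion range of `spec`: series outside `[min_timepoints,
#' max_timepoints]` are returned with `included = FALSE` and a human-readable
#' reason rather than being silently dropped, so callers can report exclusions.
#'
#' @param path Path to the TSV file.
#' @param spec A [window_spec()] providing the inclusion bounds.
#' @param sampling_interval_s Seconds between consecutive rows (not stored in
#'   the TSV itself; see [write_cohort()]'s sidecar).
#' @param subject_id Subject identifier; defaults to the file name stripped of
#'   the `_timeseries.tsv` suffix.
#' @return A list with elements `ts` (a [regional_ts()]), `included` (flag)
#'   and `reason` (`NA` when included).
#' @export
read_time_series <- function(path, spec = window_spec(), sampling_interval_s = 3,
                             subject_id = NULL) {
  if (!file.exists(path)) {
    stop(sprintf("time-series file not found: %s", path), call. = FALSE)
  }
  if (is.null(subject_id)) {
    subject_id <- sub("_timeseries\\.tsv$", "", basename(path))
  }
  lines <- readLines(path)
  if (length(lines) < 1L || !nzchar(lines[[1L]])) {
    stop(sprintf("%s: missing header row (line 1)", path), call. = FALSE)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  labels <- fields[[1L]]
  m <- length(labels)
  data_fields <- fields[-1L]
  n <- length(data_fields)
  values <- matrix(NA_real_, nrow = n, ncol = m)
  for (i in seq_len(n)) {
    row <- data_fields[[i]]
    if (length(row) != m) {
      stop(sprintf("%s: line %d has %d fields, expected %d",
                   path, i + 1L, length(row), m), call. = FALSE)
    }
    parsed <- suppressWarnings(as.numeric(row))
    if (anyNA(parsed)) {
      bad <- which(is.na(parsed))[1L]
      stop(sprintf("%s: non-numeric value '%s' at line %d, column %d",
                   path, row[bad], i + 1L, bad), call. = FALSE)
    }
    values[i, ] <- parsed
  }
  ts <- regional_ts(values, region_labels = labels,
                    sampling_interval_s = sampling_interval_s,
                    subject_id = subject_id)
  included <- TRUE
  reason <- NA_character_
  if (n < spec$min_timepoints) {
    included <- FALSE
    reason <- sprintf("too few time points (%d < %d)", n, spec$min_timepoints)
  } else if (n > spec$max_timepoints) {
    included <- FALSE
    reason <- sprintf("too many time points (%d > %d)", n, spec$max_timepoints)
  }
  list(ts = ts, included = included, reason = reason)
}

#' Windowed absolute-correlation connectivity matrix
#'
#' Computes the M x M connectivity matrix of one window: the absolute Pearson
#' correlation between every pair of regional segments, with a zero diagonal.
#' A region with zero variance inside the window has undefined correlations;
#' its edges are set to 0 (the conservative choice for downstream distances)
#' and a warning is raised.
#'
#' @param segment Numeric N x M matrix: the N within-window samples of M
#'   regions (N >= 3).
#' @param window_index Optional index of the window in its sequence, stored as
#'   an attribute.
#' @return An M x M symmetric hollow matrix with entries in `[0, 1]`.
#' @export
#' @examples
#' seg <- cbind(a = 1:5, b = c(2, 4, 6, 8, 10), c = c(5, 4, 3, 2, 1))
#' window_correlation(seg)   # |rho| = 1 for every pair
window_correlation <- function(segment, window_index = NA_integer_) {
  segment <- as.matrix(segment)
  if (nrow(segment) < 3L) {
    stop("window has fewer than 3 samples; correlation is undefined/unstable",
         call. = FALSE)
  }
  degenerate <- vapply(seq_len(ncol(segment)),
                       function(j) all(segment[, j] == segment[1L, j]),
                       logical(1))
  rho <- suppressWarnings(stats::cor(segment))
  cm <- abs(rho)
  if (any(degenerate)) {
    warning(sprintf("window %s: %d constant region(s); their edges set to 0",
                    window_index, sum(degenerate)), call. = FALSE)
  }
  cm[!is.finite(cm)] <- 0
  diag(cm) <- 0
  # guard against |rho| marginally exceeding 1 through floating point
  cm[cm > 1] <- 1
  attr(cm, "window_index") <- window_index
  cm
}

#' Build a dynamic functional connectivity sequence
#'
#' Slides a window of `spec$window_size` samples by `spec$step` samples over
#' the time series, computing one absolute-correlation connectivity matrix per
#' window. Trailing samples that do not fill a complete window are clipped,
#' and when `spec$drop_first_last` is on the first and last complete windows
#' are removed to avoid boundary artifacts. The fixed order of these steps
#' (clip, then drop ends) is part of the contract.
#'
#' @param ts A [regional_ts()].
#' @param spec A [window_spec()].
#' @return A `dfc_sequence`: list with `matrices` (ordered list of M x M
#'   connectivity matrices), `subject_id`, `region_labels` and the
#'   `window_spec` used.
#' @export
#' @examples
#' ts <- regional_ts(matrix(rnorm(90 * 4), 90, 4))
#' length(build_dfc(ts, window_spec())$matrices)  # 41 windows
build_dfc <- function(ts, spec = window_spec()) {
  stopifnot(inherits(ts, "regional_ts"), inherits(spec, "window_spec"))
  t_pts <- nrow(ts$values)
  s <- spec$window_size
  c_step <- spec$step
  if (t_pts < s) {
    stop("series too short for a single window", call. = FALSE)
  }
  starts <- seq.int(1L, t_pts - s + 1L, by = c_step)
  if (spec$drop_first_last) {
    if (length(starts) < 4L) {
      stop(sprintf("series too short after trimming: %d window(s) before dropping ends",
                   length(starts)), call. = FALSE)
    }
    starts <- starts[-c(1L, length(starts))]
  } else if (length(starts) < 2L) {
    stop("series too short after trimming: fewer than 2 windows", call. = FALSE)
  }
  matrices <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    seg <- ts$values[starts[i] + seq_len(s) - 1L, , drop = FALSE]
    matrices[[i]] <- window_correlation(seg, window_index = i)
  }
  structure(
    list(matrices = matrices, subject_id = ts$subject_id,
         region_labels = ts$region_labels, window_spec = spec),
    class = "dfc_sequence"
  )
}

#' @export
print.dfc_sequence <- function(x, ...) {
  cat(sprintf("<dfc_sequence> %s: %d windows of %d x %d\n", x$subject_id,
              length(x$matrices), length(x$region_labels), length(x$region_labels)))
  invisible(x)
}

#' Number of complete sliding windows before trimming
#'
#' `floor((t_pts - window_size) / step) + 1`, the count of complete windows a
#' series of `t_pts` samples yields before the first and last are dropped.
#'
#' @param t_pts Number of time points.
#' @param spec A [window_spec()].
#' @return Integer window count (0 when the series is shorter than one window).
#' @export
#' @examples
#' n_windows(90)  # 43
n_windows <- function(t_pts, spec = window_spec()) {
  t_pts <- assert_count(t_pts, "t_pts", min = 1L)
  if (t_pts < spec$window_size) {
    return(0L)
  }
  as.integer((t_pts - spec$window_size) %/% spec$step + 1L)
}

#' Truncate dFC sequences to a common length
#'
#' Scanner sessions differ in length, so subjects end up with different window
#' counts; group statistics on distance series require a consistent length.
#' Every sequence is truncated from the end to the cohort minimum (default) or
#' to an explicit target.
#'
#' @param sequences List of `dfc_sequence` objects.
#' @param target `"min"` (default) or an explicit window count no larger than
#'   the shortest sequence.
#' @return List of `dfc_sequence` objects, all of equal length.
#' @export
harmonize_lengths <- function(sequences, target = "min") {
  if (length(sequences) == 0L) {
    stop("`sequences` must be a non-empty list", call. = FALSE)
  }
  lengths <- vapply(sequences, function(s) length(s$matrices), integer(1))
  if (identical(target, "min")) {
    target_len <- min(lengths)
  } else {
    target_len <- assert_count(target, "target", min = 2L)
    if (any(lengths < target_len)) {
      short <- vapply(sequences[lengths < target_len], function(s) s$subject_id,
                      character(1))
      stop(sprintf("target %d exceeds sequence length for subject(s): %s",
                   target_len, paste(short, collapse = ", ")), call. = FALSE)
    }
  }
  lapply(sequences, function(s) {
    s$matrices <- s$matrices[seq_len(target_len)]
    s
  })
}
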
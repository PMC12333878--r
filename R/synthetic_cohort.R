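DIAGNOSES <- c("NC", "MCI", "DEMENTIA")
SEXES <- c("F", "M")

# Expand a per-diagnosis effect to a full named vector over `diagnoses`.
# A bare scalar applies to every diagnosis; a (partially) named vector fills
# unnamed diagnoses with 0.
normalize_effect <- function(x, diagnoses, name) {
  if (is.null(names(x))) {
    if (length(x) != 1L) {
      stop(sprintf("`%s` must be a scalar or a named per-diagnosis vector", name),
           call. = FALSE)
    }
    out <- stats::setNames(rep(as.double(x), length(diagnoses)), diagnoses)
  } else {
    unknown <- setdiff(names(x), diagnoses)
    if (length(unknown) > 0L) {
      stop(sprintf("`%s` names not in diagnoses: %s", name,
                   paste(unknown, collapse = ", ")), call. = FALSE)
    }
    out <- stats::setNames(rep(0, length(diagnoses)), diagnoses)
    out[names(x)] <- as.double(x)
  }
  if (!all(is.finite(out))) {
    stop(sprintf("`%s` must be finite", name), call. = FALSE)
  }
  out
}

#' Synthetic cohort configuration
#'
#' Parameters of the generative model used to emulate a resting-state fMRI
#' cohort: each subject's regional signal is a small number of smooth latent
#' signals mixed into regions through a mixing matrix that drifts slowly over
#' time, plus white noise. Group differences enter in two ways: the drift
#' magnitude is scaled by `(1 + sustained_effect[diagnosis]) *
#' (1 + age_effect * (age - mean age))` (sustained connectivity variability
#' and a linear age confound), and affected subjects additionally receive
#' `n_peak_events` short contiguous intervals during which the mixing is
#' abruptly perturbed with amplitude `peak_effect[diagnosis]` (transient
#' disruptions that surface as isolated maxima of the distance series).
#'
#' @param n_per_cell Subjects per (diagnosis x sex) cell.
#' @param n_regions Number of regions M (default 116, the AAL atlas size).
#' @param n_timepoints Either a single length or a `(min, max)` range (drawn
#'   uniformly per subject); must lie within the 90-600 inclusion range.
#' @param sampling_interval_s Seconds between time points (default 3).
#' @param age_range `(min, max)` age in years, drawn uniformly.
#' @param age_effect Slope of drift amplitude per year of age (0 = no
#'   confound).
#' @param sustained_effect Per-diagnosis multiplier on baseline drift; scalar
#'   or named vector (e.g. `c(DEMENTIA = 1)`), unnamed diagnoses get 0.
#' @param peak_effect Per-diagnosis amplitude of transient disruption events;
#'   scalar or named vector, unnamed diagnoses get 0.
#' @param n_peak_events Number of injected events per affected subject.
#' @param peak_event_len Event duration in samples (contiguous, long enough to
#'   span whole analysis windows at the default window size).
#' @param latent_rank Number of shared latent signals.
#' @param noise_sd Standard deviation of additive white noise.
#' @param drift_sd Innovation standard deviation of the mixing drift process,
#'   before group/age scaling.
#' @param drift_ar AR(1) coefficient of the mean-reverting mixing drift
#'   (closer to 1 = slower drift).
#' @param ar_coef AR(1) coefficient of the latent signals (temporal
#'   smoothness).
#' @param diagnoses,sexes Cells to generate (defaults: all three diagnoses,
#'   both sexes).
#' @param seed Master seed; per-subject streams are derived from it so subject
#'   generation order is irrelevant.
#' @return A `sim_config` object.
#' @export
#' @examples
#' cfg <- sim_config(n_per_cell = 2, n_regions = 8, n_timepoints = 90, seed = 7)
sim_config <- function(n_per_cell = 5L, n_regions = 116L, n_timepoints = c(90L, 200L),
                       sampling_interval_s = 3, age_range = c(45, 97),
                       age_effect = 0, sustained_effect = 0, peak_effect = 0,
                       n_peak_events = 3L, peak_event_len = 10L,
                       latent_rank = 5L, noise_sd = 1, drift_sd = 0.3,
                       drift_ar = 0.9, ar_coef = 0.8, diagnoses = DIAGNOSES,
                       sexes = SEXES, seed = 1L) {
  n_per_cell <- assert_count(n_per_cell, "n_per_cell")
  n_regions <- assert_count(n_regions, "n_regions", min = 3L)
  if (!length(n_timepoints) %in% c(1L, 2L)) {
    stop("`n_timepoints` must be a single count or a (min, max) range", call. = FALSE)
  }
  n_timepoints <- vapply(n_timepoints, assert_count, integer(1),
                         name = "n_timepoints")
  if (any(n_timepoints < 90L) || any(n_timepoints > 600L)) {
    stop("`n_timepoints` must lie within the inclusion range [90, 600]", call. = FALSE)
  }
  if (length(n_timepoints) == 2L && n_timepoints[1] > n_timepoints[2]) {
    stop("`n_timepoints` range must be increasing", call. = FALSE)
  }
  assert_scalar_number(sampling_interval_s, "sampling_interval_s")
  if (length(age_range) != 2L || age_range[1] >= age_range[2]) {
    stop("`age_range` must be an increasing (min, max) pair", call. = FALSE)
  }
  assert_scalar_number(age_effect, "age_effect")
  diagnoses <- match.arg(diagnoses, DIAGNOSES, several.ok = TRUE)
  sexes <- match.arg(sexes, SEXES, several.ok = TRUE)
  sustained_effect <- normalize_effect(sustained_effect, diagnoses, "sustained_effect")
  peak_effect <- normalize_effect(peak_effect, diagnoses, "peak_effect")
  structure(
    list(n_per_cell = n_per_cell, n_regions = n_regions,
         n_timepoints = n_timepoints,
         sampling_interval_s = as.double(sampling_interval_s),
         age_range = as.double(age_range), age_effect = as.double(age_effect),
         sustained_effect = sustained_effect, peak_effect = peak_effect,
         n_peak_events = assert_count(n_peak_events, "n_peak_events", min = 0L),
         peak_event_len = assert_count(peak_event_len, "peak_event_len"),
         latent_rank = assert_count(latent_rank, "latent_rank"),
         noise_sd = assert_scalar_number(noise_sd, "noise_sd"),
         drift_sd = assert_scalar_number(drift_sd, "drift_sd"),
         drift_ar = assert_scalar_number(drift_ar, "drift_ar"),
         ar_coef = assert_scalar_number(ar_coef, "ar_coef"),
         diagnoses = diagnoses, sexes = sexes,
         seed = assert_count(seed, "seed", min = 0L)),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> %d per cell (%d diagnoses x %d sexes), M = %d, T in [%s], seed %d\n",
    x$n_per_cell, length(x$diagnoses), length(x$sexes), x$n_regions,
    paste(x$n_timepoints, collapse = ", "), x$seed))
  invisible(x)
}

#' Generate one subject's regional time series
#'
#' Draws the subject's signal from the latent low-rank mixing model described
#' in [sim_config()]. Deterministic given `(record, cfg, stream)`.
#'
#' @param record A one-row data.frame (or list) with `subject_id`, `age`,
#'   `sex`, `diagnosis`.
#' @param cfg A [sim_config()].
#' @param stream Integer seed of the subject's private random stream; when
#'   `NULL` it is derived from `cfg$seed` and the subject id.
#' @return A [regional_ts()].
#' @export
generate_subject_series <- function(record, cfg, stream = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  diagnosis <- as.character(record$diagnosis)
  if (!diagnosis %in% cfg$diagnoses) {
    stop(sprintf("diagnosis '%s' not in the configured set", diagnosis), call. = FALSE)
  }
  age <- as.numeric(record$age)
  if (is.null(stream)) {
    stream <- derive_seed(cfg$seed, "subject", as.character(record$subject_id))
  }
  m <- cfg$n_regions
  k <- cfg$latent_rank
  age_center <- mean(cfg$age_range)
  scale <- (1 + cfg$sustained_effect[[diagnosis]]) *
    (1 + cfg$age_effect * (age - age_center))
  scale <- max(scale, 0)
  with_seed(stream, {
    t_pts <- if (length(cfg$n_timepoints) == 2L) {
      sample(cfg$n_timepoints[1]:cfg$n_timepoints[2], 1L)
    } else {
      cfg$n_timepoints[1]
    }
    # smooth latent signals: independent AR(1) processes
    z <- vapply(seq_len(k), function(j) {
      as.numeric(stats::filter(stats::rnorm(t_pts), cfg$ar_coef, method = "recursive"))
    }, numeric(t_pts))
    z <- matrix(z, nrow = t_pts, ncol = k)
    w0 <- matrix(stats::rnorm(m * k), m, k) / sqrt(k)
    # slowly drifting mixing: mean-reverting AR(1) fluctuation around w0 with
    # innovation sd drift_sd * scale, so the drift magnitude relative to the
    # base mixing is proportional to the group/age scale
    incr <- matrix(stats::rnorm(t_pts * m * k, sd = cfg$drift_sd * scale),
                   t_pts, m * k)
    drift <- stats::filter(incr, cfg$drift_ar, method = "recursive")
    drift <- matrix(as.numeric(drift), nrow = t_pts)
    # transient disruption events: abrupt mixing perturbations over short
    # contiguous intervals
    peak_amp <- cfg$peak_effect[[diagnosis]]
    event_pert <- vector("list", 0L)
    event_spans <- integer(0)
    event_of <- integer(t_pts)
    if (peak_amp != 0 && cfg$n_peak_events > 0L) {
      len <- min(cfg$peak_event_len, t_pts)
      starts <- sample.int(t_pts - len + 1L, cfg$n_peak_events, replace = TRUE)
      event_pert <- lapply(seq_len(cfg$n_peak_events), function(e) {
        peak_amp * matrix(stats::rnorm(m * k), m, k) / sqrt(k)
      })
      for (e in seq_along(starts)) {
        event_of[starts[e] + seq_len(len) - 1L] <- e
      }
    }
    noise <- matrix(stats::rnorm(t_pts * m, sd = cfg$noise_sd), t_pts, m)
    y <- matrix(0, t_pts, m)
    for (t in seq_len(t_pts)) {
      wt <- w0 + matrix(drift[t, ], m, k)
      if (event_of[t] > 0L) {
        wt <- wt + event_pert[[event_of[t]]]
      }
      y[t, ] <- wt %*% z[t, ]
    }
    y <- y + noise
    regional_ts(y, sampling_interval_s = cfg$sampling_interval_s,
                subject_id = as.character(record$subject_id))
  })
}

#' Generate a full synthetic cohort
#'
#' Creates `n_per_cell` subjects per (diagnosis x sex) cell with ages drawn
#' uniformly on the configured range, then one regional time series per
#' subject. Each subject has a private random stream derived from the master
#' seed, so the cohort is fully reproducible and independent of generation
#' order.
#'
#' @param cfg A [sim_config()].
#' @return A `cohort`: list with `records` (data.frame: subject_id, age, sex,
#'   diagnosis) and `series` (named list of [regional_ts()]).
#' @export
#' @examples
#' coh <- generate_cohort(sim_config(n_per_cell = 1, n_regions = 6,
#'                                   n_timepoints = 90, seed = 3))
#' nrow(coh$records)  # 6 cells x 1
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  cells <- expand.grid(diagnosis = cfg$diagnoses, sex = cfg$sexes,
                       idx = seq_len(cfg$n_per_cell),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  n <- nrow(cells)
  records <- with_seed(cfg$seed, {
    data.frame(
      subject_id = sprintf("sub-%04d", seq_len(n)),
      age = round(stats::runif(n, cfg$age_range[1], cfg$age_range[2]), 2),
      sex = cells$sex,
      diagnosis = cells$diagnosis,
      stringsAsFactors = FALSE
    )
  })
  series <- lapply(seq_len(n), function(i) {
    generate_subject_series(records[i, ], cfg)
  })
  names(series) <- records$subject_id
  structure(list(records = records, series = series, config = cfg),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d subjects: %s\n", nrow(x$records),
              paste(sprintf("%s=%d", names(table(x$records$diagnosis)),
                            table(x$records$diagnosis)), collapse = ", ")))
  invisible(x)
}

#' Write a cohort to a directory
#'
#' Emits `participants.tsv` (subject_id, age, sex, diagnosis), one
#' `<subject_id>_timeseries.tsv` per subject (header row of region labels,
#' one row per time point), and a `cohort.json` sidecar recording the
#' sampling interval. The files round-trip losslessly through
#' [read_time_series()] / [read_cohort()] up to text-serialization precision.
#'
#' @param cohort A `cohort`.
#' @param directory Output directory (created if missing).
#' @return Invisibly, the vector of files written.
#' @export
write_cohort <- function(cohort, directory) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  files <- file.path(directory, "participants.tsv")
  utils::write.table(cohort$records, files, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  interval <- if (length(cohort$series) > 0L) {
    cohort$series[[1L]]$sampling_interval_s
  } else {
    cohort$config$sampling_interval_s
  }
  for (id in names(cohort$series)) {
    path <- file.path(directory, paste0(id, "_timeseries.tsv"))
    ts <- cohort$series[[id]]
    df <- as.data.frame(ts$values)
    names(df) <- ts$region_labels
    utils::write.table(format(df, digits = 12, trim = TRUE, scientific = FALSE),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, path)
  }
  sidecar <- file.path(directory, "cohort.json")
  jsonlite::write_json(list(sampling_interval_s = interval,
                            n_subjects = nrow(cohort$records)),
                       sidecar, auto_unbox = TRUE)
  files <- c(files, sidecar)
  invisible(files)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param directory Directory with `participants.tsv` and per-subject series.
#' @param spec A [window_spec()] used for inclusion checks.
#' @return A list with `cohort` (records + series of included subjects) and
#'   `excluded` (data.frame of subject_id, reason).
#' @export
read_cohort <- function(directory, spec = window_spec()) {
  ppath <- file.path(directory, "participants.tsv")
  if (!file.exists(ppath)) {
    stop(sprintf("participants table not found: %s", ppath), call. = FALSE)
  }
  records <- utils::read.delim(ppath, stringsAsFactors = FALSE)
  sidecar <- file.path(directory, "cohort.json")
  interval <- if (file.exists(sidecar)) {
    jsonlite::read_json(sidecar)$sampling_interval_s
  } else {
    3
  }
  series <- list()
  excluded <- data.frame(subject_id = character(0), reason = character(0),
                         stringsAsFactors = FALSE)
  for (id in records$subject_id) {
    res <- read_time_series(file.path(directory, paste0(id, "_timeseries.tsv")),
                            spec = spec, sampling_interval_s = interval,
                            subject_id = id)
    if (res$included) {
      series[[id]] <- res$ts
    } else {
      excluded <- rbind(excluded, data.frame(subject_id = id, reason = res$reason,
                                             stringsAsFactors = FALSE))
    }
  }
  records <- records[records$subject_id %in% names(series), , drop = FALSE]
  cohort <- structure(list(records = records, series = series, config = NULL),
                      class = "cohort")
  list(cohort = cohort, excluded = excluded)
}
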
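test_that("window_correlation computes absolute Pearson correlations", {
  seg <- cbind(a = c(1, 2, 3, 4, 5),
               b = c(2, 4, 6, 8, 10),
               c = c(5, 4, 3, 2, 1))
  cm <- window_correlation(seg)
  expect_equal(cm["a", "b"], 1)          # perfect positive correlation
  expect_equal(cm["a", "c"], 1)          # |-1| = 1
  expect_equal(diag(cm), c(a = 0, b = 0, c = 0))
  expect_true(isSymmetric(unname(cm)))
})

test_that("constant regions give zero edges with a warning", {
  seg <- cbind(x = c(1, 2, 3, 7, 5), y = rep(2, 5), z = c(0, 1, 0, 1, 3))
  expect_warning(cm <- window_correlation(seg), "constant region")
  expect_equal(cm["y", "x"], 0)
  expect_equal(cm["y", "z"], 0)
  expect_gt(cm["x", "z"], 0)
})

test_that("windows with fewer than 3 samples are rejected", {
  expect_error(window_correlation(matrix(1:6, 2, 3)), "fewer than 3 samples")
})

test_that("90 time points give 43 windows, 41 after dropping ends", {
  set.seed(1)
  ts <- regional_ts(matrix(rnorm(90 * 4), 90, 4))
  expect_identical(n_windows(90), 43L)
  expect_length(build_dfc(ts, window_spec(drop_first_last = FALSE))$matrices, 43L)
  expect_length(build_dfc(ts)$matrices, 41L)
})

test_that("window placement matches direct correlation of the raw segment", {
  set.seed(2)
  ts <- regional_ts(matrix(rnorm(90 * 4), 90, 4))
  dfc <- build_dfc(ts)
  # after dropping the first window, the first surviving window starts at row 3
  seg <- ts$values[3:7, ]
  manual <- abs(stats::cor(seg))
  diag(manual) <- 0
  expect_equal(unname(dfc$matrices[[1]]), unname(manual), ignore_attr = TRUE)
})

test_that("window count before trimming matches explicit enumeration", {
  for (t_pts in c(90, 91, 100, 137, 600)) {
    for (s in c(3, 5, 8)) {
      for (c_step in c(1, 2, 3)) {
        starts <- seq(1, t_pts, by = c_step)
        starts <- starts[starts + s - 1 <= t_pts]
        spec <- window_spec(window_size = s, step = c_step)
        expect_identical(n_windows(t_pts, spec), length(starts))
      }
    }
  }
})

test_that("too-short series error after trimming", {
  ts9 <- regional_ts(matrix(rnorm(9 * 3), 9, 3))
  expect_error(build_dfc(ts9), "too short after trimming")
})

test_that("emitted matrices are symmetric, hollow, in [0, 1]", {
  set.seed(3)
  ts <- regional_ts(matrix(rnorm(95 * 6), 95, 6))
  dfc <- build_dfc(ts)
  for (cm in dfc$matrices) {
    expect_true(isSymmetric(unname(cm)))
    expect_equal(unname(diag(cm)), rep(0, 6))
    expect_true(all(cm >= 0 & cm <= 1))
  }
})

test_that("region relabeling permutes matrices consistently", {
  set.seed(4)
  x <- matrix(rnorm(90 * 5), 90, 5)
  perm <- c(3, 1, 5, 2, 4)
  d1 <- build_dfc(regional_ts(x))
  d2 <- build_dfc(regional_ts(x[, perm]))
  for (i in seq_along(d1$matrices)) {
    expect_equal(unname(d2$matrices[[i]]), unname(d1$matrices[[i]][perm, perm]),
                 ignore_attr = TRUE)
  }
})

test_that("time reversal reverses the window sequence", {
  set.seed(5)
  # 89 points, s = 5, c = 2: starts tile the series symmetrically
  x <- matrix(rnorm(89 * 4), 89, 4)
  spec <- window_spec(drop_first_last = FALSE)
  fwd <- build_dfc(regional_ts(x), spec)$matrices
  rev_ <- build_dfc(regional_ts(x[89:1, ]), spec)$matrices
  expect_length(rev_, length(fwd))
  for (i in seq_along(fwd)) {
    expect_equal(unname(rev_[[i]]), unname(fwd[[length(fwd) + 1 - i]]),
                 ignore_attr = TRUE)
  }
})

test_that("harmonize_lengths truncates from the end to the cohort minimum", {
  set.seed(6)
  seqs <- list(rand_dfc(4, 41, "a"), rand_dfc(4, 50, "b"), rand_dfc(4, 44, "c"))
  out <- harmonize_lengths(seqs)
  expect_equal(vapply(out, function(s) length(s$matrices), integer(1)),
               c(41L, 41L, 41L))
  # truncation keeps the leading matrices untouched
  expect_identical(out[[2]]$matrices, seqs[[2]]$matrices[1:41])

  single <- harmonize_lengths(seqs[1])
  expect_identical(single[[1]]$matrices, seqs[[1]]$matrices)

  out40 <- harmonize_lengths(seqs[1:2], target = 40)
  expect_equal(vapply(out40, function(s) length(s$matrices), integer(1)),
               c(40L, 40L))
  expect_error(harmonize_lengths(seqs, target = 45), "subject\\(s\\): a")
  expect_error(harmonize_lengths(list()), "non-empty")
})

test_that("read_time_series applies the 90-600 inclusion filter", {
  dir <- withr::local_tempdir()
  write_ts <- function(n) {
    path <- file.path(dir, sprintf("sub-%d_timeseries.tsv", n))
    m <- matrix(round(rnorm(n * 3), 4), n, 3)
    writeLines(c("R1\tR2\tR3", apply(m, 1, paste, collapse = "\t")), path)
    path
  }
  ok <- read_time_series(write_ts(90))
  expect_true(ok$included)
  expect_identical(nrow(ok$ts$values), 90L)

  short <- read_time_series(write_ts(89))
  expect_false(short$included)
  expect_match(short$reason, "too few time points")

  long <- read_time_series(write_ts(601))
  expect_false(long$included)
  expect_match(long$reason, "too many time points")
})

test_that("parse errors name the offending line", {
  dir <- withr::local_tempdir()
  ragged <- file.path(dir, "bad_timeseries.tsv")
  writeLines(c("R1\tR2\tR3", "1\t2\t3", "1\t2"), ragged)
  expect_error(read_time_series(ragged), "line 3")

  nonnum <- file.path(dir, "nn_timeseries.tsv")
  writeLines(c("R1\tR2\tR3", "1\t2\t3", "1\tx\t3"), nonnum)
  expect_error(read_time_series(nonnum), "non-numeric value 'x' at line 3")
})
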
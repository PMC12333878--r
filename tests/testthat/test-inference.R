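test_that("age residualization matches the normal-equations oracle", {
  expect_equal(regress_out_age(c(1, 2, 4), c(60, 70, 80)),
               c(1 / 6, -1 / 3, 1 / 6))
  # values unrelated to a zero fitted slope reduce to centering
  v <- c(2, 2, 5, 5)
  expect_equal(regress_out_age(v, c(60, 70, 60, 70)), v - mean(v))
  # perfect linear dependence leaves ~zero residuals
  ages <- c(55, 60, 72, 80, 91)
  expect_equal(regress_out_age(2 * ages, ages), rep(0, 5))
})

test_that("residuals are centered and orthogonal to age", {
  set.seed(40)
  for (i in 1:20) {
    n <- sample(5:30, 1)
    ages <- runif(n, 45, 97)
    values <- rnorm(n, sd = 3) + 0.05 * ages
    r <- regress_out_age(values, ages)
    expect_equal(sum(r), 0, tolerance = 1e-8)
    expect_equal(sum(r * (ages - mean(ages))), 0, tolerance = 1e-8)
  }
})

test_that("age residualization rejects degenerate inputs", {
  expect_error(regress_out_age(1:5, rep(70, 5)), "constant")
  expect_error(regress_out_age(1:4, 1:3), "same length")
  expect_error(regress_out_age(1:2, 1:2), "at least 3")
})

test_that("exhaustive permutation test matches the worked enumeration", {
  res <- permutation_test(c(10, 11), c(0, 1))
  expect_identical(res$method, "exhaustive")
  expect_equal(res$t_obs, 10)
  expect_equal(res$p_value, 1 / 3)
  expect_equal(res$n_permutations, 6L)
})

test_that("exhaustive p equals the bitmask enumeration oracle", {
  set.seed(41)
  for (i in 1:30) {
    m <- sample(1:5, 1)
    n <- sample(1:5, 1)
    # multiples of 2520 = lcm(1..9) keep every group mean an exact integer,
    # so ties are compared exactly in both the oracle and the implementation
    x <- sample(0:4, m, replace = TRUE) * 2520
    y <- sample(0:4, n, replace = TRUE) * 2520
    res <- permutation_test(x, y, exhaustive = "always")
    expect_equal(res$p_value, oracle_exact_perm_p(x, y))
  }
})

test_that("identical pooled values give T_obs = 0 and p = 1", {
  v <- c(3, 1, 4)
  res <- permutation_test(v, v)
  expect_equal(res$t_obs, 0)
  expect_equal(res$p_value, 1)
})

test_that("sampled permutation test is deterministic given a seed", {
  x <- rnorm(12)
  y <- rnorm(12, mean = 0.5)
  r1 <- permutation_test(x, y, n_permutations = 500, seed = 7, exhaustive = "never")
  r2 <- permutation_test(x, y, n_permutations = 500, seed = 7, exhaustive = "never")
  expect_identical(r1$p_value, r2$p_value)
  expect_identical(r1$method, "sampled")
})

test_that("p-value is invariant to group swap, shift, and positive scaling", {
  set.seed(42)
  x <- rnorm(8)
  y <- rnorm(6, mean = 1)
  base <- permutation_test(x, y, n_permutations = 400, seed = 3, exhaustive = "never")
  swap <- permutation_test(y, x, n_permutations = 400, seed = 3, exhaustive = "never")
  expect_equal(swap$t_obs, base$t_obs)
  shift <- permutation_test(x + 10, y + 10, n_permutations = 400, seed = 3,
                            exhaustive = "never")
  expect_equal(shift$t_obs, base$t_obs)
  expect_equal(shift$p_value, base$p_value)
  scaled <- permutation_test(3 * x, 3 * y, n_permutations = 400, seed = 3,
                             exhaustive = "never")
  expect_equal(scaled$t_obs, 3 * base$t_obs)
  expect_equal(scaled$p_value, base$p_value)
  # exhaustive p is sampling-free, so swap symmetry is exact there too
  expect_equal(permutation_test(y, x)$p_value, permutation_test(x, y)$p_value)
})

test_that("permutation test validates inputs and smoothing", {
  expect_error(permutation_test(numeric(0), 1:3), "non-empty")
  expect_error(permutation_test(rnorm(20), rnorm(20), exhaustive = "always"),
               "infeasible")
  sm <- permutation_test(1:4, 1:4 + 10, n_permutations = 100, seed = 1,
                         exhaustive = "never", smooth_p = TRUE)
  expect_gt(sm$p_value, 0)
})

test_that("bonferroni threshold divides alpha by the family size", {
  expect_equal(bonferroni_threshold(0.05, 8), 0.00625)
  expect_equal(round(bonferroni_threshold(0.05, 8), 3), 0.006)  # display convention
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  for (m in c(2, 5, 12)) {
    expect_equal(bonferroni_threshold(0.03, m) * m, 0.03)
  }
  expect_error(bonferroni_threshold(1.2, 8), "in \\(0, 1\\)")
})

make_fake_data <- function(n_per_group = 6, seed = 50) {
  set.seed(seed)
  meta <- data.frame(
    subject_id = sprintf("s%02d", 1:(4 * n_per_group)),
    age = runif(4 * n_per_group, 50, 90),
    sex = rep(c("F", "M"), each = 2 * n_per_group),
    diagnosis = rep(rep(c("NC", "DEMENTIA"), each = n_per_group), 2),
    stringsAsFactors = FALSE
  )
  summaries <- data.frame(
    subject_id = meta$subject_id,
    metric = "frobenius",
    mean_value = rnorm(nrow(meta)),
    peak_value = rnorm(nrow(meta), mean = 2),
    series_length = 40L,
    stringsAsFactors = FALSE
  )
  list(meta = meta, summaries = summaries)
}

test_that("run_comparison stratifies by sex and applies the decision rule", {
  d <- make_fake_data()
  spec <- comparison_spec(c("NC", "DEMENTIA"), "F", "mean_based",
                          n_permutations = 300, seed = 9)
  res <- run_comparison(d$summaries, d$meta, spec)
  expect_s3_class(res, "comparison_result")
  expect_equal(res$bonferroni_threshold, 0.00625)
  expect_identical(res$significant, res$permutation$p_value <= 0.00625)

  # manual recomputation of the same cell
  sel <- d$meta$sex == "F"
  vals <- d$summaries$mean_value[match(d$meta$subject_id[sel],
                                       d$summaries$subject_id)]
  resid <- regress_out_age(vals, d$meta$age[sel])
  g1 <- resid[d$meta$diagnosis[sel] == "NC"]
  g2 <- resid[d$meta$diagnosis[sel] == "DEMENTIA"]
  manual <- permutation_test(g1, g2, n_permutations = 300,
                             seed = derive_seed(9, "frobenius", "NC_vs_DEMENTIA",
                                                "F", "mean_based"))
  expect_equal(res$permutation$p_value, manual$p_value)
  expect_equal(res$permutation$t_obs, manual$t_obs)

  # altering the other stratum must not change the result
  d2 <- d
  d2$summaries$mean_value[d$meta$sex == "M"] <- 1000
  res2 <- run_comparison(d2$summaries, d2$meta, spec)
  expect_equal(res2$permutation$p_value, res$permutation$p_value)
})

test_that("run_comparison picks the summary column per test type", {
  d <- make_fake_data(seed = 51)
  for (tt in c("mean_based", "peak_based")) {
    spec <- comparison_spec(c("NC", "DEMENTIA"), "M", tt,
                            n_permutations = 200, seed = 2)
    res <- run_comparison(d$summaries, d$meta, spec)
    col <- if (tt == "mean_based") "mean_value" else "peak_value"
    sel <- d$meta$sex == "M"
    vals <- d$summaries[[col]][match(d$meta$subject_id[sel],
                                     d$summaries$subject_id)]
    resid <- regress_out_age(vals, d$meta$age[sel])
    expect_equal(res$permutation$t_obs,
                 abs(mean(resid[d$meta$diagnosis[sel] == "NC"]) -
                       mean(resid[d$meta$diagnosis[sel] == "DEMENTIA"])))
  }
})

test_that("run_comparison errors on an empty group with counts", {
  d <- make_fake_data()
  spec <- comparison_spec(c("NC", "MCI"), "F", "mean_based")
  expect_error(run_comparison(d$summaries, d$meta, spec), "MCI n=0")
})

test_that("derived cell seeds differ across cells but are reproducible", {
  s1 <- derive_seed(1, "frobenius", "NC_vs_DEMENTIA", "F", "mean_based")
  s2 <- derive_seed(1, "frobenius", "NC_vs_DEMENTIA", "F", "peak_based")
  s3 <- derive_seed(1, "manhattan", "NC_vs_DEMENTIA", "F", "mean_based")
  expect_true(s1 != s2 && s1 != s3)
  expect_identical(s1, derive_seed(1, "frobenius", "NC_vs_DEMENTIA", "F",
                                   "mean_based"))
  expect_true(all(c(s1, s2, s3) > 0 & c(s1, s2, s3) < 2^31))
})
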
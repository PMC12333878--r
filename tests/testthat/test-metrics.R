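make_pair2 <- function(a_off, b_off) {
  list(a = matrix(c(0, a_off, a_off, 0), 2),
       b = matrix(c(0, b_off, b_off, 0), 2))
}

test_that("element-wise distances match hand computations", {
  p <- make_pair2(0.8, 0.5)
  # both symmetric entries contribute, per the full-matrix sum convention
  expect_equal(elementwise_distance(p$a, p$b, "manhattan"), 0.6)
  expect_equal(elementwise_distance(p$a, p$b, "frobenius"), sqrt(0.18))
  expect_equal(elementwise_distance(p$a, p$b, "chebyshev"), 0.3)
  for (kind in c("manhattan", "frobenius", "chebyshev")) {
    expect_equal(elementwise_distance(p$a, p$a, kind), 0)
  }
})

test_that("nuclear distance is the sum of singular values of the difference", {
  p <- make_pair2(0.3, 0)
  expect_equal(nuclear_distance(p$a, p$b), 0.6)  # singular values {0.3, 0.3}
  expect_equal(nuclear_distance(p$a, p$a), 0)
})

test_that("spectral distance compares sorted eigenvalue spectra", {
  p <- make_pair2(0.5, 0.2)  # spectra {-0.5, 0.5} and {-0.2, 0.2}
  expect_equal(spectral_distance(p$a, p$b), sqrt(0.09 + 0.09))
  expect_equal(spectral_distance(p$a, p$a), 0)
})

test_that("distances reject mismatched dimensions", {
  a <- rand_conn(4)
  b <- rand_conn(5)
  expect_error(elementwise_distance(a, b, "manhattan"), "mismatched dimensions")
  expect_error(nuclear_distance(a, b), "mismatched dimensions")
  expect_error(spectral_distance(a, b), "mismatched dimensions")
  expect_error(wasserstein_distance(a, b), "unequal cardinality")
})

test_that("wasserstein distance uses the sorted bijection", {
  pa <- structure(list(births = c(0.5, 0.9), deaths = 0.3),
                  class = "persistence_summary")
  pb <- structure(list(births = c(0.4, 0.7), deaths = 0.6),
                  class = "persistence_summary")
  expect_equal(wasserstein_distance(pa, pb, dim = 0, p = 2), sqrt(0.01 + 0.04))
  expect_equal(wasserstein_distance(pa, pb, dim = 1, p = 2), 0.3)
  expect_equal(wasserstein_distance(pa, pa, dim = 0, p = 2), 0)
  expect_equal(wasserstein_distance(pa, pa, dim = 1, p = 7), 0)
  expect_error(wasserstein_distance(pa, pb, dim = 0, p = 0.5), ">= 1")
  expect_error(wasserstein_distance(pa, pb, dim = 2), "must be 0")
})

test_that("wasserstein with p = 1 on singletons is the absolute difference", {
  set.seed(8)
  for (i in 1:20) {
    v <- runif(2)
    pa <- structure(list(births = v[1], deaths = v[1]),
                    class = "persistence_summary")
    pb <- structure(list(births = v[2], deaths = v[2]),
                    class = "persistence_summary")
    expect_equal(wasserstein_distance(pa, pb, dim = 1, p = 1), abs(v[1] - v[2]))
  }
})

test_that("all seven metrics are nonnegative, symmetric, zero on identity", {
  set.seed(9)
  for (i in 1:25) {
    a <- rand_conn(6)
    b <- rand_conn(6)
    for (name in METRIC_NAMES) {
      spec <- metric_spec(name)
      f <- dfcdist:::metric_fun(spec)
      dab <- f(a, b)
      expect_gte(dab, 0)
      expect_equal(dab, f(b, a))
      expect_equal(f(a, a), 0)
    }
  }
})

test_that("norm orderings hold on random pairs", {
  set.seed(10)
  for (i in 1:200) {
    a <- rand_conn(6)
    b <- rand_conn(6)
    cheb <- elementwise_distance(a, b, "chebyshev")
    frob <- elementwise_distance(a, b, "frobenius")
    manh <- elementwise_distance(a, b, "manhattan")
    expect_lte(cheb, frob + 1e-12)
    expect_lte(frob, manh + 1e-12)
    expect_lte(frob, nuclear_distance(a, b) + 1e-12)        # Schatten ordering
    expect_lte(spectral_distance(a, b), frob + 1e-12)       # Hoffman-Wielandt
  }
})

test_that("element-wise, nuclear and spectral distances are homogeneous", {
  set.seed(11)
  a <- rand_conn(5)
  b <- rand_conn(5)
  for (alpha in c(0, 0.3, 2.5)) {
    for (kind in c("manhattan", "frobenius", "chebyshev")) {
      expect_equal(elementwise_distance(alpha * a, alpha * b, kind),
                   alpha * elementwise_distance(a, b, kind))
    }
    expect_equal(nuclear_distance(alpha * a, alpha * b),
                 alpha * nuclear_distance(a, b))
    expect_equal(spectral_distance(alpha * a, alpha * b),
                 alpha * spectral_distance(a, b))
  }
})

test_that("distance_series walks consecutive pairs in order", {
  set.seed(12)
  cm <- rand_conn(5)
  const_seq <- structure(list(matrices = replicate(6, cm, simplify = FALSE),
                              subject_id = "s", region_labels = letters[1:5],
                              window_spec = window_spec()),
                         class = "dfc_sequence")
  for (name in METRIC_NAMES) {
    ds <- distance_series(const_seq, name)
    expect_equal(ds$values, rep(0, 5))
  }

  seq41 <- rand_dfc(5, 41)
  ds <- distance_series(seq41, "frobenius")
  expect_length(ds$values, 40L)
  expect_equal(ds$values[7],
               elementwise_distance(seq41$matrices[[7]], seq41$matrices[[8]],
                                    "frobenius"))

  too_short <- rand_dfc(5, 1)
  expect_error(distance_series(too_short, "manhattan"), "at least 2")
})

test_that("distance series are invariant to simultaneous region relabeling", {
  set.seed(13)
  seq1 <- rand_dfc(5, 6)
  perm <- c(4, 2, 5, 1, 3)
  seq2 <- seq1
  seq2$matrices <- lapply(seq1$matrices, function(m) m[perm, perm])
  for (name in METRIC_NAMES) {
    expect_equal(distance_series(seq2, name)$values,
                 distance_series(seq1, name)$values,
                 tolerance = 1e-10)
  }
})
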
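#' Metric names understood by the pipeline
#' @export
METRIC_NAMES <- c("manhattan", "frobenius", "chebyshev", "nuclear", "spectral",
                  "wasserstein0", "wasserstein1")

#' Metric specification
#'
#' @param name One of `manhattan`, `frobenius`, `chebyshev`, `nuclear`,
#'   `spectral`, `wasserstein0`, `wasserstein1`.
#' @param wasserstein_order_p Order p >= 1 of the Wasserstein matching
#'   (used only by the two homology metrics). Default 2, the convention in the
#'   persistent-homology literature.
#' @return A `metric_spec` object.
#' @export
metric_spec <- function(name, wasserstein_order_p = 2) {
  name <- match.arg(name, METRIC_NAMES)
  assert_scalar_number(wasserstein_order_p, "wasserstein_order_p")
  if (wasserstein_order_p < 1) {
    stop("`wasserstein_order_p` must be >= 1", call. = FALSE)
  }
  structure(list(name = name, wasserstein_order_p = as.double(wasserstein_order_p)),
            class = "metric_spec")
}

check_pair <- function(a, b) {
  a <- as.matrix(a)
  b <- as.matrix(b)
  if (!all(dim(a) == dim(b))) {
    stop("connectivity matrices have mismatched dimensions", call. = FALSE)
  }
  list(a = a, b = b)
}

#' Element-wise matrix distances
#'
#' Manhattan, Frobenius and Chebyshev distances between two connectivity
#' matrices. Sums run over every entry of the full matrix, so each undirected
#' edge is counted twice (the diagonal contributes 0); permutation p-values
#' downstream are invariant to this constant factor.
#'
#' @param a,b Connectivity matrices of equal dimension.
#' @param kind `"manhattan"` (sum of absolute differences), `"frobenius"`
#'   (root sum of squared differences) or `"chebyshev"` (maximum absolute
#'   difference).
#' @return Nonnegative scalar distance.
#' @export
#' @examples
#' a <- matrix(c(0, .8, .8, 0), 2)
#' b <- matrix(c(0, .5, .5, 0), 2)
#' elementwise_distance(a, b, "manhattan")  # 0.6 (both symmetric entries)
elementwise_distance <- function(a, b, kind = c("manhattan", "frobenius", "chebyshev")) {
  kind <- match.arg(kind)
  p <- check_pair(a, b)
  d <- p$a - p$b
  switch(kind,
         manhattan = sum(abs(d)),
         frobenius = sqrt(sum(d * d)),
         chebyshev = max(abs(d)))
}

#' Nuclear-norm distance
#'
#' Sum of the singular values of the matrix difference; emphasizes changes in
#' the dominant low-rank structure of connectivity rather than in individual
#' edges.
#'
#' @inheritParams elementwise_distance
#' @return Nonnegative scalar distance.
#' @export
nuclear_distance <- function(a, b) {
  p <- check_pair(a, b)
  d <- p$a - p$b
  sum(svd(d, nu = 0, nv = 0)$d)
}

#' Spectral distance
#'
#' Euclidean norm of the difference between the eigenvalue spectra of two
#' symmetric matrices, each spectrum sorted ascending. Captures global network
#' reorganization (hubs, community structure) that element-wise comparisons
#' miss.
#'
#' @inheritParams elementwise_distance
#' @return Nonnegative scalar distance.
#' @export
spectral_distance <- function(a, b) {
  p <- check_pair(a, b)
  la <- sort(eigen(p$a, symmetric = TRUE, only.values = TRUE)$values)
  lb <- sort(eigen(p$b, symmetric = TRUE, only.values = TRUE)$values)
  sqrt(sum((la - lb)^2))
}

#' Persistence decomposition of a connectivity matrix
#'
#' Treats the matrix as a complete weighted graph on M nodes and summarizes
#' the graph filtration obtained by deleting edges whose weight falls at or
#' below an increasing threshold. As the threshold rises the number of
#' connected components grows monotonically and the number of independent
#' cycles shrinks, so the whole persistence diagram reduces to two multisets:
#'
#' * `births` — the M-1 filtration values at which connected components are
#'   born; these are exactly the edge weights of a maximum spanning tree.
#' * `deaths` — the 1 + M(M-3)/2 filtration values at which cycles die; these
#'   are the remaining (non-tree) edge weights.
#'
#' Both multisets are tie-break invariant: ties in edge weights may change
#' which spanning tree is found but never its weight multiset.
#'
#' @param cm A symmetric hollow connectivity matrix with M >= 3 rows.
#' @return A `persistence_summary`: list with sorted numeric vectors `births`
#'   (length M-1) and `deaths` (length 1 + M(M-3)/2).
#' @export
#' @examples
#' w <- matrix(0, 3, 3)
#' w[1, 2] <- w[2, 1] <- 0.9
#' w[1, 3] <- w[3, 1] <- 0.5
#' w[2, 3] <- w[3, 2] <- 0.3
#' persistence_decompose(w)  # births {0.5, 0.9}, deaths {0.3}
persistence_decompose <- function(cm) {
  cm <- as.matrix(cm)
  m <- nrow(cm)
  if (m < 3L || ncol(cm) != m) {
    stop("persistence decomposition needs a square matrix with M >= 3 (no cycle set otherwise)",
         call. = FALSE)
  }
  ut <- upper.tri(cm)
  w <- cm[ut]
  n_edges <- length(w)
  rows <- row(cm)[ut]
  cols <- col(cm)[ut]
  # Kruskal maximum spanning tree with stable index-order tie-breaking.
  ord <- order(-w, seq_len(n_edges))
  parent <- seq_len(m)
  find_root <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]] # path halving
      i <- parent[i]
    }
    i
  }
  in_tree <- logical(n_edges)
  accepted <- 0L
  for (e in ord) {
    ri <- find_root(rows[e])
    rj <- find_root(cols[e])
    if (ri != rj) {
      parent[ri] <- rj
      in_tree[e] <- TRUE
      accepted <- accepted + 1L
      if (accepted == m - 1L) break
    }
  }
  structure(
    list(births = sort(w[in_tree]), deaths = sort(w[!in_tree])),
    class = "persistence_summary"
  )
}

#' @export
print.persistence_summary <- function(x, ...) {
  cat(sprintf("<persistence_summary> %d component births, %d cycle deaths\n",
              length(x$births), length(x$deaths)))
  invisible(x)
}

#' p-Wasserstein distance between persistence summaries
#'
#' For connectivity matrices on the same region set the birth multisets (and
#' likewise the death multisets) have equal cardinality, so the optimal
#' matching pairs the l-th smallest value in one multiset with the l-th
#' smallest in the other and the distance is the p-norm of the sorted-vector
#' difference.
#'
#' @param a,b Connectivity matrices of equal dimension, or
#'   `persistence_summary` objects.
#' @param dim Homology dimension: 0 matches component births, 1 matches cycle
#'   deaths.
#' @param p Matching order, >= 1.
#' @return Nonnegative scalar distance.
#' @export
wasserstein_distance <- function(a, b, dim = 0, p = 2) {
  if (!dim %in% c(0, 1)) {
    stop("`dim` must be 0 (components) or 1 (cycles)", call. = FALSE)
  }
  assert_scalar_number(p, "p")
  if (p < 1) {
    stop("`p` must be >= 1", call. = FALSE)
  }
  pa <- if (inherits(a, "persistence_summary")) a else persistence_decompose(a)
  pb <- if (inherits(b, "persistence_summary")) b else persistence_decompose(b)
  xa <- if (dim == 0) pa$births else pa$deaths
  xb <- if (dim == 0) pb$births else pb$deaths
  if (length(xa) != length(xb)) {
    stop("persistence summaries have unequal cardinality (different region counts)",
         call. = FALSE)
  }
  # births/deaths are stored sorted; the sorted bijection is the optimal one
  sum(abs(xa - xb)^p)^(1 / p)
}

metric_fun <- function(spec) {
  p <- spec$wasserstein_order_p
  switch(spec$name,
         manhattan = function(a, b, ...) elementwise_distance(a, b, "manhattan"),
         frobenius = function(a, b, ...) elementwise_distance(a, b, "frobenius"),
         chebyshev = function(a, b, ...) elementwise_distance(a, b, "chebyshev"),
         nuclear = function(a, b, ...) nuclear_distance(a, b),
         spectral = function(a, b, ...) spectral_distance(a, b),
         wasserstein0 = function(a, b, pa = NULL, pb = NULL) {
           wasserstein_distance(if (is.null(pa)) a else pa,
                                if (is.null(pb)) b else pb, dim = 0, p = p)
         },
         wasserstein1 = function(a, b, pa = NULL, pb = NULL) {
           wasserstein_distance(if (is.null(pa)) a else pa,
                                if (is.null(pb)) b else pb, dim = 1, p = p)
         })
}

#' Distance series of a dFC sequence
#'
#' Applies one distance metric to every pair of consecutive connectivity
#' matrices, yielding the length T-1 series that quantifies how fast the
#' subject's connectivity pattern is changing over the scan. For the two
#' Wasserstein metrics each matrix's persistence summary is computed once and
#' reused for both of its adjacent transitions (and may be supplied
#' precomputed via `persistence`).
#'
#' @param seq A `dfc_sequence` with at least two matrices.
#' @param spec A [metric_spec()] (or metric name, taken with default options).
#' @param persistence Optional list of precomputed `persistence_summary`
#'   objects, one per matrix, to share across metrics.
#' @return A `distance_series`: list with numeric `values` (length T-1),
#'   `metric_name` and `subject_id`.
#' @export
distance_series <- function(seq, spec, persistence = NULL) {
  if (is.character(spec)) {
    spec <- metric_spec(spec)
  }
  mats <- seq$matrices
  n <- length(mats)
  if (n < 2L) {
    stop("a distance series needs at least 2 connectivity matrices", call. = FALSE)
  }
  f <- metric_fun(spec)
  needs_ph <- spec$name %in% c("wasserstein0", "wasserstein1")
  if (needs_ph && is.null(persistence)) {
    persistence <- lapply(mats, persistence_decompose)
  }
  values <- numeric(n - 1L)
  for (i in seq_len(n - 1L)) {
    values[i] <- if (needs_ph) {
      f(mats[[i]], mats[[i + 1L]], pa = persistence[[i]], pb = persistence[[i + 1L]])
    } else {
      f(mats[[i]], mats[[i + 1L]])
    }
  }
  structure(
    list(values = values, metric_name = spec$name, subject_id = seq$subject_id),
    class = "distance_series"
  )
}

#' @export
print.distance_series <- function(x, ...) {
  cat(sprintf("<distance_series> %s, %s: %d transitions, mean %.4g\n",
              x$subject_id, x$metric_name, length(x$values), mean(x$values)))
  invisible(x)
}
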
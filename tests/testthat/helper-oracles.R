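# Shared fixtures and independent oracles used across the test suite.

# Random symmetric hollow matrix with off-diagonal weights in [0, 1].
# `levels` > 0 draws weights from a discrete grid to force ties.
rand_conn <- function(m, levels = 0) {
  w <- if (levels > 0) {
    sample(seq(0, 1, length.out = levels), choose(m, 2), replace = TRUE)
  } else {
    stats::runif(choose(m, 2))
  }
  cm <- matrix(0, m, m)
  cm[upper.tri(cm)] <- w
  cm + t(cm)
}

# Small random dFC sequence (list of random connectivity matrices).
rand_dfc <- function(m, t_len, subject_id = "sub-test") {
  structure(list(matrices = replicate(t_len, rand_conn(m), simplify = FALSE),
                 subject_id = subject_id,
                 region_labels = sprintf("R%03d", seq_len(m)),
                 window_spec = window_spec()),
            class = "dfc_sequence")
}

# Brute-force graph-filtration oracle for the persistence decomposition.
# For every distinct edge weight v it counts connected components of the
# binary graphs with edges strictly above v and at-or-above v (via igraph,
# no spanning tree involved): the jump in component count is the number of
# component births at filtration value v, and the remaining edges of weight v
# are cycle deaths. Independent of the Kruskal implementation under test.
oracle_persistence <- function(cm) {
  m <- nrow(cm)
  ut <- upper.tri(cm)
  edges <- data.frame(from = row(cm)[ut], to = col(cm)[ut], w = cm[ut])
  n_components <- function(keep) {
    g <- igraph::graph_from_data_frame(edges[keep, c("from", "to")],
                                       directed = FALSE,
                                       vertices = data.frame(name = seq_len(m)))
    igraph::components(g)$no
  }
  births <- numeric(0)
  deaths <- numeric(0)
  for (v in sort(unique(edges$w))) {
    n_at <- sum(edges$w == v)
    n_births <- n_components(edges$w > v) - n_components(edges$w >= v)
    births <- c(births, rep(v, n_births))
    deaths <- c(deaths, rep(v, n_at - n_births))
  }
  list(births = sort(births), deaths = sort(deaths))
}

# Exact permutation p-value by bitmask enumeration of all C(m+n, m) group
# assignments; independent of the combn-based path in permutation_test().
oracle_exact_perm_p <- function(x, y) {
  z <- c(x, y)
  m <- length(x)
  n_tot <- length(z)
  t_obs <- abs(mean(x) - mean(y))
  stats <- c()
  for (mask in 0:(2^n_tot - 1)) {
    bits <- as.integer(intToBits(mask))[seq_len(n_tot)]
    if (sum(bits) != m) next
    g1 <- z[bits == 1]
    g2 <- z[bits == 0]
    stats <- c(stats, abs(mean(g1) - mean(g2)))
  }
  mean(stats >= t_obs - 1e-12)
}

# Tiny cohort configuration for fast end-to-end tests.
tiny_cfg <- function(...) {
  args <- utils::modifyList(
    list(n_per_cell = 2L, n_regions = 5L, n_timepoints = 90L,
         latent_rank = 2L, seed = 42L),
    list(...))
  do.call(sim_config, args)
}
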
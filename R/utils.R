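#' @keywords internal
"_PACKAGE"

# Internal input checks used across the package. Kept minimal and explicit so
# error messages identify the offending argument.

assert_scalar_number <- function(x, name, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("`%s` must be a single non-missing number", name), call. = FALSE)
  }
  if (finite && !is.finite(x)) {
    stop(sprintf("`%s` must be finite", name), call. = FALSE)
  }
  invisible(x)
}

assert_count <- function(x, name, min = 1L) {
  assert_scalar_number(x, name)
  if (x != as.integer(x) || x < min) {
    stop(sprintf("`%s` must be an integer >= %d", name, min), call. = FALSE)
  }
  invisible(as.integer(x))
}

assert_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("`%s` must be TRUE or FALSE", name), call. = FALSE)
  }
  invisible(x)
}

#' Derive a reproducible child seed from a root seed and string labels
#'
#' Hashes the labels with a polynomial rolling hash and folds the result into
#' the root seed modulo 2^31 - 1, so every (metric, contrast, sex, test type)
#' cell of the experiment grid gets its own deterministic random stream and
#' results do not depend on the order in which cells are run.
#'
#' @param root_seed Integer root seed.
#' @param ... Character scalars identifying the stream (labels are
#'   concatenated in order).
#' @return A single integer in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(42, "frobenius", "NC_vs_DEMENTIA", "F", "mean_based")
derive_seed <- function(root_seed, ...) {
  assert_scalar_number(root_seed, "root_seed")
  labels <- paste(vapply(list(...), as.character, character(1)), collapse = "|")
  modulus <- 2147483647 # 2^31 - 1, keeps the seed a valid 32-bit integer
  h <- as.double(root_seed) %% modulus
  for (code in utf8ToInt(labels)) {
    h <- (h * 131 + code) %% modulus
  }
  as.integer(max(1, h))
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards. With seed = NULL the current stream is used.
with_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(expr)
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
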
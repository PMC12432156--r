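# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

of_abort <- function(msg, class = "omicfuse_error") {
  rlang::abort(msg, class = class)
}

of_warn <- function(msg) {
  rlang::warn(msg)
}

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's RNG afterwards so package functions never perturb user randomness.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv(), inherits = FALSE)
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a stage seed from a root seed; keeps all values well inside the
# 32-bit integer range R requires.
derive_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 7919 + offset) %% 2147483647L)
}

is_count <- function(x) {
  length(x) == 1 && is.numeric(x) && is.finite(x) && x == as.integer(x) && x >= 1
}

is_fraction <- function(x) {
  length(x) == 1 && is.numeric(x) && is.finite(x) && x >= 0 && x <= 1
}

assert_matrix_like <- function(x, name = "x") {
  if (!is.matrix(x) || !is.numeric(x)) {
    of_abort(sprintf("`%s` must be a numeric matrix.", name))
  }
}

# Pairwise squared Euclidean distances between rows of a and rows of b.
pairwise_sqdist <- function(a, b = a) {
  an <- rowSums(a^2)
  bn <- rowSums(b^2)
  d <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  d[d < 0] <- 0
  d
}

of_log <- function(fmt, ...) {
  if (isTRUE(getOption("omicfuse.verbose", FALSE))) {
    message(sprintf(fmt, ...))
  }
  invisible(NULL)
}
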
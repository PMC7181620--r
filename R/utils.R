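# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  env <- globalenv()
  old <- if (exists(".Random.seed", envir = env, inherits = FALSE)) {
    get(".Random.seed", envir = env, inherits = FALSE)
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = env, inherits = FALSE)) {
        rm(".Random.seed", envir = env)
      }
    } else {
      assign(".Random.seed", old, envir = env)
    }
  })
  set.seed(seed)
  force(code)
}

# Derive a stream of child seeds from a master seed; keeps values < 2^31.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

stop_triconf <- function(...) stop(..., call. = FALSE)

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

# Coerce a position argument to an n x 2 matrix of (x, y) coordinates.
as_position_matrix <- function(x, arg = "x") {
  if (is.data.frame(x)) {
    if (all(c("x", "y") %in% names(x))) {
      x <- cbind(x$x, x$y)
    } else {
      x <- as.matrix(x[, 1:2])
    }
  } else if (is.null(dim(x))) {
    if (length(x) != 2L) {
      stop_triconf(sprintf("`%s` must be a length-2 (x, y) point or an n x 2 matrix", arg))
    }
    x <- matrix(x, nrow = 1L)
  } else {
    x <- as.matrix(x)
  }
  if (ncol(x) != 2L) {
    stop_triconf(sprintf("`%s` must have two columns (x, y)", arg))
  }
  if (!all(is.finite(x))) {
    stop_triconf(sprintf("`%s` contains non-finite coordinates", arg))
  }
  storage.mode(x) <- "double"
  x
}

# Simplex check used by posterior consumers.
check_simplex <- function(p, tol = 1e-10) {
  p <- as_posterior_matrix(p)
  ok <- apply(p, 1L, function(row) {
    all(row >= 0) && abs(sum(row) - 1) <= tol
  })
  if (!all(ok)) {
    stop_triconf("posterior must be a point on the 3-simplex (nonnegative, summing to 1)")
  }
  invisible(p)
}

as_posterior_matrix <- function(p) {
  if (is.null(dim(p))) {
    if (length(p) != 3L) stop_triconf("a posterior must have 3 components")
    p <- matrix(p, nrow = 1L)
  } else {
    p <- as.matrix(p)
    if (ncol(p) != 3L) stop_triconf("a posterior matrix must have 3 columns")
  }
  storage.mode(p) <- "double"
  p
}
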
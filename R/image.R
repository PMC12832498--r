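#' Validate a grayscale image matrix
#'
#' Images are plain numeric matrices with intensities in \[0, 1\]. Pipeline
#' entry points require at least 8 pixels along each side.
#'
#' @param x numeric matrix.
#' @param min_dim minimum allowed number of rows and columns.
#' @param range_check if `TRUE`, require all values in \[0, 1\].
#' @param arg name used in error messages.
#' @return `x`, invisibly, if valid; otherwise an error is thrown.
#' @export
assert_image <- function(x, min_dim = 8L, range_check = TRUE, arg = "x") {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(sprintf("`%s` must be a numeric matrix", arg), call. = FALSE)
  }
  if (nrow(x) < min_dim || ncol(x) < min_dim) {
    stop(sprintf("`%s` must be at least %dx%d, got %dx%d",
                 arg, min_dim, min_dim, nrow(x), ncol(x)), call. = FALSE)
  }
  if (anyNA(x) || any(!is.finite(x))) {
    stop(sprintf("`%s` contains non-finite values", arg), call. = FALSE)
  }
  if (range_check && (min(x) < 0 || max(x) > 1)) {
    stop(sprintf("`%s` has values outside [0, 1]", arg), call. = FALSE)
  }
  invisible(x)
}

#' Clip intensities to the unit interval
#' @param x numeric matrix or vector.
#' @return `x` with values clamped to \[0, 1\].
#' @export
clip01 <- function(x) {
  pmin(pmax(x, 0), 1)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. Keeps all stochastic operations
# bitwise reproducible without clobbering global state.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic fan-out of one global seed into per-subsystem seeds.
# Offsets are fixed so subsystems stay reproducible independently.
derive_seed <- function(seed, offset) {
  (as.integer(seed) + as.integer(offset)) %% 2147483647L
}
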
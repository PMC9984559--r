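#' @keywords internal
"_PACKAGE"

## Internal helpers shared across the package.

#' Evaluate an expression under a local RNG seed
#'
#' Runs `expr` with the global RNG seeded to `seed`, then restores the prior
#' RNG state, so package functions are reproducible without clobbering the
#' caller's stream. With `seed = NULL` the expression runs on the current
#' stream.
#'
#' @param seed Integer seed or `NULL`.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    # materialize a state so we can restore it
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

# Draw n child seeds (< 2^31) from a parent seed, for independent sub-streams.
derive_seeds <- function(seed, n) {
  if (is.null(seed)) return(rep(list(NULL), n))
  with_seed(seed, as.list(sample.int(.Machine$integer.max, n)))
}

#' Wrap angles into the half-open interval [-180, 180)
#'
#' @param x Numeric vector/matrix of angles in degrees.
#' @return Angles wrapped so that 185 becomes -175 and 180 becomes -180.
#' @examples
#' wrap_angle(c(185, -180, 180, 540))
#' @export
wrap_angle <- function(x) {
  ((x + 180) %% 360) - 180
}

# Round half away from zero at `digits` decimals (printed-table convention).
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

stop_dlrpmds <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x == as.integer(x)
}
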
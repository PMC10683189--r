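#' @keywords internal
#' @importFrom graphics abline legend lines
#' @importFrom grDevices hcl.colors
#' @importFrom stats var sd cor
"_PACKAGE"

## Internal argument checks and seed plumbing shared across the package.

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

check_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < min || x != round(x))
    stopf("`%s` must be a single integer >= %d (got %s)", name, min,
          paste(format(x), collapse = ","))
  as.integer(x)
}

check_fraction <- function(x, name, lo = 0, hi = 1, open_lo = FALSE,
                           open_hi = FALSE) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x))
    stopf("`%s` must be a single number", name)
  bad_lo <- if (open_lo) x <= lo else x < lo
  bad_hi <- if (open_hi) x >= hi else x > hi
  if (bad_lo || bad_hi)
    stopf("`%s` must lie in %s%g, %g%s (got %g)", name,
          if (open_lo) "(" else "[", lo, hi, if (open_hi) ")" else "]", x)
  as.numeric(x)
}

check_seed <- function(seed) {
  if (length(seed) != 1L || !is.numeric(seed) || is.na(seed) ||
      seed != round(seed))
    stopf("`seed` must be a single integer")
  as.integer(seed %% 2147483647L)
}

## Deterministic child seeds so every pipeline stage has its own stream.
## Linear-congruential step keeps values in 32-bit integer range.
child_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(check_seed(seed))
  for (k in idx) s <- (s * 48271 + as.double(k) + 1) %% 2147483587
  as.integer(s)
}

## Run an expression with a local RNG state so ops are pure in (inputs, seed).
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(check_seed(seed))
  expr
}
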
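#' Derive a reproducible sub-seed from a master seed and a key
#'
#' Cohort generation draws every file from its own RNG stream so that any
#' single recording can be regenerated without replaying the whole cohort.
#' The stream seed is a polynomial hash of the master seed concatenated with
#' the identifying key (animal, condition, frequency, ...), reduced modulo
#' the Mersenne prime 2^31 - 1 so it is always a valid \code{set.seed} value
#' and exactly representable in doubles on every platform.
#'
#' @param seed master integer seed.
#' @param ... key components (coerced to character).
#' @return an integer in [0, 2^31 - 2].
#' @export
seed_stream <- function(seed, ...) {
  key <- paste(c(format(seed), vapply(list(...), format, "")), collapse = "|")
  h <- 0
  for (b in utf8ToInt(key)) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

#' Wrap an angle in degrees to (-180, 180]
#' @param x angle(s) in degrees.
#' @return wrapped angle(s).
#' @export
wrap_degrees <- function(x) {
  w <- ((x %% 360) + 360) %% 360
  ifelse(w > 180, w - 360, w)
}

# stop() with the offending field named, for spec-style validation errors
check_that <- function(ok, field, msg) {
  if (!isTRUE(ok)) stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

# standard error of the mean
sem <- function(x) stats::sd(x) / sqrt(length(x))

# contiguous runs of TRUE in a logical vector -> matrix of (start, end) indices
true_runs <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}
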
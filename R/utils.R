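# Internal helpers shared across modules.

#' Wrap phase values into (-pi, pi]
#'
#' @param x Numeric vector, matrix or array of phases in radians.
#' @return Object of the same shape with every value wrapped into (-pi, pi].
#' @export
wrap_phase <- function(x) {
  w <- x - 2 * pi * round(x / (2 * pi))
  # round() maps exact half-integers to even, which can leave -pi; fold it up.
  w[w <= -pi] <- w[w <= -pi] + 2 * pi
  w
}

#' Circular correlation of two phase maps
#'
#' Magnitude of the mean resultant vector of the phase differences,
#' `|<exp(i(a - b))>|`. Equals 1 when `a - b` is constant.
#'
#' @param a,b Phase arrays in radians (same shape).
#' @param mask Optional logical mask selecting the pixels to average over.
#' @return Scalar in `[0, 1]`.
#' @export
circular_correlation <- function(a, b, mask = NULL) {
  d <- exp(1i * (a - b))
  if (!is.null(mask)) d <- d[mask]
  Mod(mean(d))
}

# Run code with a temporary RNG state seeded from `seed`; the caller's
# .Random.seed is restored on exit.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Complex standard normal array.
crnorm <- function(n, sd = 1) {
  complex(real = stats::rnorm(n, sd = sd / sqrt(2)),
          imaginary = stats::rnorm(n, sd = sd / sqrt(2)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar <- function(x, name, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      (positive && x <= 0)) {
    stop(sprintf("`%s` must be a finite%s numeric scalar", name,
                 if (positive) " positive" else ""), call. = FALSE)
  }
  invisible(x)
}
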
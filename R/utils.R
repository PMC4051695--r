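#' Evaluate code with a local, restorable random seed
#'
#' All stochastic generators in the package take an explicit `seed` argument
#' and must not disturb the caller's random-number state. This helper sets the
#' seed for the duration of `code` and then restores whatever `.Random.seed`
#' was present before (or removes it if there was none).
#'
#' @param seed Integer seed, or `NULL` to use the current random state.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- globalenv()
  had_seed <- exists(".Random.seed", envir = env, inherits = FALSE)
  old_seed <- if (had_seed) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old_seed, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Gaussian smoothing of a uniformly sampled signal
#'
#' Discrete convolution with a Gaussian kernel, reflecting the signal at the
#' boundaries so the ends are not darkened. `sigma` is in samples (pixels);
#' `sigma <= 0` returns the input unchanged.
#'
#' @param y Numeric vector.
#' @param sigma Kernel standard deviation in samples.
#' @return Smoothed numeric vector of the same length.
#' @keywords internal
gaussian_smooth <- function(y, sigma) {
  if (sigma <= 0) {
    return(y)
  }
  radius <- max(1L, ceiling(4 * sigma))
  k <- stats::dnorm(seq(-radius, radius), sd = sigma)
  k <- k / sum(k)
  n <- length(y)
  # reflect-pad so the convolution is defined up to the ends
  pad_l <- y[pmin(n, radius + 1L):2L]
  pad_r <- y[(n - 1L):pmax(1L, n - radius)]
  if (radius >= n) {
    # degenerate: kernel wider than signal; fall back to simple edge clamp
    pad_l <- rep(y[1L], radius)
    pad_r <- rep(y[n], radius)
  }
  yp <- c(pad_l, y, pad_r)
  out <- stats::filter(yp, k, method = "convolution", sides = 2)
  as.numeric(out[(radius + 1L):(radius + n)])
}

#' Significance star code
#'
#' Converts a p-value to the star convention used throughout the figures:
#' `***` for p < 0.0005, `**` for p < 0.005, `*` for p < 0.05, otherwise
#' `"ns"`.
#'
#' @param p P-value in \[0, 1\].
#' @return Character scalar: `"***"`, `"**"`, `"*"` or `"ns"`.
#' @export
#' @examples
#' star_code(0.01)   # "*"
#' star_code(0.001)  # "**"
#' star_code(1e-5)   # "***"
star_code <- function(p) {
  stopifnot(is.numeric(p), length(p) == 1L, !is.na(p), p >= 0, p <= 1)
  if (p < 0.0005) "***" else if (p < 0.005) "**" else if (p < 0.05) "*" else "ns"
}

`%||%` <- function(a, b) if (is.null(a)) b else a
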
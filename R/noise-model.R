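#' Gaussian spectral low-pass filter
#'
#' Smooths a real-valued sequence by multiplying its discrete Fourier
#' spectrum with a Gaussian envelope `exp(-omega^2 / (2 * sigma^2))`, where
#' `omega` runs over the two-sided discrete frequency index grid
#' `{0, 1, ..., floor(n/2), -(ceiling(n/2) - 1), ..., -1}` and
#' `sigma = n / cutoff_period`. Under this convention fluctuations with a
#' period shorter than `cutoff_period` time steps are suppressed, so the
#' output varies on a time scale of order `cutoff_period` or longer. The
#' envelope is symmetric in `omega`, hence the output is real, and the gain
#' at zero frequency is 1, so the mean of the sequence is preserved.
#'
#' The filter acts on the raw series with circular (periodic) boundary
#' handling and no detrending or windowing; sequences are assumed long
#' relative to `cutoff_period`.
#'
#' @param values Numeric vector, length at least 2.
#' @param cutoff_period Positive scalar; the cut-off period in time steps.
#' @return Numeric vector of the same length as `values`.
#' @examples
#' x <- rnorm(256)
#' y <- gaussian_lowpass_filter(x, cutoff_period = 32)
#' all.equal(mean(x), mean(y))
#' @export
gaussian_lowpass_filter <- function(values, cutoff_period) {
  if (!is.numeric(values) || length(values) < 2) {
    rlang::abort("`values` must be a numeric vector of length >= 2.",
                 class = "flockdual_invalid_input")
  }
  if (!is.numeric(cutoff_period) || length(cutoff_period) != 1 ||
      !is.finite(cutoff_period) || cutoff_period <= 0) {
    rlang::abort("`cutoff_period` must be a single positive number.",
                 class = "flockdual_invalid_input")
  }
  n <- length(values)
  sigma <- n / cutoff_period
  k <- 0:(n - 1)
  omega <- ifelse(k <= n / 2, k, k - n)
  envelope <- exp(-omega^2 / (2 * sigma^2))
  Re(stats::fft(stats::fft(values) * envelope, inverse = TRUE)) / n
}

#' Generate a temporally correlated random sequence
#'
#' Draws `n` i.i.d. values from a base distribution and applies
#' [gaussian_lowpass_filter()] with the given cut-off period. This is the
#' stochastic engine behind both the common path (speed and turning
#' fluctuations, uniform base on \[-0.5, 0.5\]) and the positional
#' displacement noise (standard normal base).
#'
#' When `seed` is supplied the RNG is seeded before drawing, so the same
#' `(n, cutoff_period, base_distribution, seed)` always reproduces the same
#' sequence. When `seed` is `NULL` the current RNG stream is consumed, which
#' is how the simulator allocates deterministic sub-streams from one
#' per-flight seed.
#'
#' @param n Integer, number of values (>= 2).
#' @param cutoff_period Positive scalar, cut-off period in time steps.
#' @param base_distribution `"uniform_half"` (uniform on \[-0.5, 0.5\]) or
#'   `"standard_normal"`.
#' @param seed Optional integer seed.
#' @return Numeric vector of length `n` with attributes `cutoff_period`,
#'   `base_distribution` and `seed` recording the generation parameters.
#' @export
correlated_sequence <- function(n, cutoff_period,
                                base_distribution = c("uniform_half",
                                                      "standard_normal"),
                                seed = NULL) {
  if (!is.numeric(n) || length(n) != 1 || n < 2) {
    rlang::abort("`n` must be a single integer >= 2.",
                 class = "flockdual_invalid_input")
  }
  base_distribution <- rlang::arg_match(base_distribution)
  if (!is.null(seed)) set.seed(seed)
  raw <- switch(base_distribution,
    uniform_half    = stats::runif(n, min = -0.5, max = 0.5),
    standard_normal = stats::rnorm(n)
  )
  out <- gaussian_lowpass_filter(raw, cutoff_period)
  attr(out, "cutoff_period") <- cutoff_period
  attr(out, "base_distribution") <- base_distribution
  attr(out, "seed") <- seed
  out
}

#' Normalize a sequence by its maximum absolute value
#'
#' Divides each value by `max(abs(values))`, so the result lies in
#' \[-1, 1\] and attains magnitude 1 at least once. Used to scale the
#' filtered noise sequences before multiplying by the speed and turning
#' amplitudes.
#'
#' @param values Numeric vector with at least one nonzero value.
#' @return Numeric vector of the same length.
#' @export
normalize_by_max_abs <- function(values) {
  m <- max(abs(values))
  if (!is.finite(m) || m == 0) {
    rlang::abort("All values are zero; normalization by max |x| is undefined.",
                 class = "flockdual_degenerate_input")
  }
  values / m
}

#' Rescale a sequence to a target sample standard deviation
#'
#' Multiplies the sequence by `target_std / sd(values)` (sample standard
#' deviation, n - 1 divisor). Scaling preserves the autocorrelation
#' structure; only the amplitude changes.
#'
#' @param values Numeric vector with nonzero sample standard deviation.
#' @param target_std Positive scalar.
#' @return Numeric vector of the same length with sample sd `target_std`.
#' @export
rescale_to_std <- function(values, target_std) {
  if (!is.numeric(target_std) || length(target_std) != 1 || target_std <= 0) {
    rlang::abort("`target_std` must be a single positive number.",
                 class = "flockdual_invalid_input")
  }
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0) {
    rlang::abort("Input has zero variance; rescaling is undefined.",
                 class = "flockdual_degenerate_input")
  }
  values * (target_std / s)
}
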
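#' Geometric mean
#'
#' @param x numeric vector, strictly positive.
#' @param na.rm drop NA values before averaging.
#' @return the geometric mean of `x`.
#' @export
geomean <- function(x, na.rm = FALSE) {
  if (na.rm) x <- x[!is.na(x)]
  if (any(x <= 0)) stop("geometric mean requires strictly positive values")
  exp(mean(log(x)))
}

#' Uncentered coefficient of determination
#'
#' R^2 = 1 - sum((model - data)^2) / sum(data^2).  The denominator is the
#' raw power of the data series (no mean subtraction), so R^2 can be
#' negative when the residual power exceeds the data power, and a model
#' that predicts all zeros scores exactly 0.
#'
#' @param model predicted series.
#' @param data observed series.
#' @return scalar R^2 (as a fraction, not percent).
#' @export
uncentered_r2 <- function(model, data) {
  stopifnot(length(model) == length(data))
  denom <- sum(data^2)
  if (denom == 0) return(NA_real_)
  1 - sum((model - data)^2) / denom
}

#' Low-pass decimation of a summary series
#'
#' Zero-phase low-pass filtering (Chebyshev Type I, order 3, 0.05 dB
#' passband ripple, cutoff 0.8 x Nyquist / factor) followed by taking every
#' `factor`-th sample starting from the first, so a series of length n
#' becomes length ceiling(n / factor).  The odd filter order gives exact
#' unit gain at DC, so a constant series passes through unchanged.
#'
#' @param x numeric series.
#' @param factor integer decimation factor (default 3).
#' @return decimated series of length `ceiling(length(x) / factor)`.
#' @export
decimate_series <- function(x, factor = 3) {
  stopifnot(factor >= 1, factor == round(factor))
  if (factor == 1) return(x)
  if (any(!is.finite(x))) stop("decimate_series requires finite input")
  filt <- signal::cheby1(3, Rp = 0.05, W = 0.8 / factor)
  # odd-reflection padding suppresses the zero-initial-condition edge
  # transient of filtfilt; 100 samples is ample for this filter
  n <- length(x)
  np <- min(n - 1, 100)
  xe <- c(2 * x[1] - x[(np + 1):2], x, 2 * x[n] - x[(n - 1):(n - np)])
  y <- signal::filtfilt(filt, xe)[(np + 1):(np + n)]
  y[seq(1, n, by = factor)]
}

#' Symmetric Hann window
#' @param n window length in samples.
#' @return numeric vector of window coefficients.
#' @keywords internal
hann_window <- function(n) {
  if (n == 1) return(1)
  0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))
}

# Gaussian-shaped band-limited noise and 1/f^chi noise, both built by
# shaping a white complex spectrum and inverting the FFT.  Deterministic
# given the RNG state; output is scaled to the requested RMS.
shaped_noise <- function(n, fs, amplitude_profile, rms = 1) {
  # generate on a highly composite length (fast FFT), then truncate
  m <- stats::nextn(n, c(2, 3, 5))
  nf <- m %/% 2
  f <- (1:nf) * fs / m
  amp <- amplitude_profile(f)
  z <- complex(real = stats::rnorm(nf), imaginary = stats::rnorm(nf)) * amp
  spec <- complex(real = rep(0, m))
  spec[2:(nf + 1)] <- z
  spec[seq(m, m - nf + 2)] <- Conj(z[1:(nf - 1)])
  x <- Re(stats::fft(spec, inverse = TRUE))[1:n] / m
  s <- stats::sd(x)
  if (s == 0) return(x)
  x / s * rms
}

one_over_f_noise <- function(n, fs, chi = 1.5, rms = 1) {
  shaped_noise(n, fs, function(f) f^(-chi / 2), rms = rms)
}

narrowband_noise <- function(n, fs, center, bw_sd = 1, rms = 1) {
  shaped_noise(n, fs, function(f) exp(-(f - center)^2 / (2 * bw_sd^2)),
               rms = rms)
}

#' Evaluate an expression under a local RNG seed
#'
#' Sets the seed, evaluates `expr`, and restores the caller's RNG state,
#' so seeded helpers do not perturb surrounding random draws.  All seeded
#' functions in this package draw their randomness this way.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_local_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  expr
}
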
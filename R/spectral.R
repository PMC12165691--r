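#' Welch power spectral density on a 1 Hz grid
#'
#' Averages periodograms of Hann-windowed 200 ms segments with 50%
#' overlap, each zero-padded to `nfft = sample_rate` samples so the
#' frequency grid has 1 Hz bins.  One-sided density normalisation
#' (power / Hz); with 200 ms windows adjacent 1 Hz bins are correlated
#' because the padding interpolates the underlying ~5 Hz resolution.
#'
#' @param x signal segment (numeric vector), typically the 0-500 ms
#'   stimulus window of an epoch.
#' @param sample_rate sampling rate, Hz.
#' @param window_sec Hann window length in seconds (0.2).
#' @param overlap fractional overlap between segments (0.5).
#' @param nfft FFT length (default `sample_rate`, giving 1 Hz bins).
#' @param detrend demean each segment before windowing (the standard
#'   Welch constant detrend).  Slow drift and unresolved sub-window
#'   frequencies otherwise leak through the ~5 Hz-wide Hann mainlobe
#'   directly into the 3-6 Hz bins used by the spectral decomposition.
#' @return list with `f` (0 ... nfft/2 Hz) and `psd` (same length).
#' @export
welch_psd <- function(x, sample_rate, window_sec = 0.2, overlap = 0.5,
                      nfft = NULL, detrend = TRUE) {
  fs <- sample_rate
  if (is.null(nfft)) nfft <- round(fs)
  win_n <- round(window_sec * fs)
  if (length(x) < win_n) stop("segment shorter than one Welch window")
  w <- hann_window(win_n)
  step <- max(1L, floor(win_n * (1 - overlap)))
  starts <- seq(1L, length(x) - win_n + 1L, by = step)
  scale <- 1 / (fs * sum(w^2))
  acc <- numeric(nfft %/% 2 + 1)
  for (s in starts) {
    seg <- x[s:(s + win_n - 1L)]
    if (detrend) seg <- seg - mean(seg)
    seg <- seg * w
    X <- stats::fft(c(seg, numeric(nfft - win_n)))
    acc <- acc + Mod(X[1:(nfft %/% 2 + 1)])^2
  }
  psd <- acc / length(starts) * scale
  psd[2:(nfft %/% 2)] <- 2 * psd[2:(nfft %/% 2)]   # one-sided, keep DC/Nyquist
  list(f = 0:(nfft %/% 2), psd = psd)
}

# Vectorised Welch over an epoch x time matrix (same conventions as
# welch_psd); returns epoch x frequency matrix.  Used by trial_spectra.
welch_psd_matrix <- function(X, sample_rate, window_sec = 0.2,
                             overlap = 0.5, nfft = NULL, detrend = TRUE) {
  fs <- sample_rate
  if (is.null(nfft)) nfft <- round(fs)
  win_n <- round(window_sec * fs)
  if (ncol(X) < win_n) stop("segment shorter than one Welch window")
  w <- hann_window(win_n)
  step <- max(1L, floor(win_n * (1 - overlap)))
  starts <- seq(1L, ncol(X) - win_n + 1L, by = step)
  scale <- 1 / (fs * sum(w^2))
  nb <- nfft %/% 2 + 1
  acc <- matrix(0, nrow(X), nb)
  pad <- matrix(0, nfft, nrow(X))
  for (s in starts) {
    seg <- t(X[, s:(s + win_n - 1L), drop = FALSE])
    if (detrend) seg <- sweep(seg, 2, colMeans(seg))
    pad[1:win_n, ] <- seg * w
    pad[(win_n + 1):nfft, ] <- 0
    Xf <- stats::mvfft(pad)
    acc <- acc + t(Mod(Xf[1:nb, , drop = FALSE])^2)
  }
  psd <- acc / length(starts) * scale
  psd[, 2:(nb - 1)] <- 2 * psd[, 2:(nb - 1)]
  psd
}

#' Per-trial stimulus-window power spectra
#'
#' Computes the Welch PSD of the 0-500 ms stimulus window of every epoch
#' for every electrode, retaining 1-250 Hz.
#'
#' @param epochs a `voltage_epochs` (normally after `regress_out_erp`).
#' @param fmax highest frequency retained, Hz.
#' @param stim_window seconds of the analysed window within the epoch.
#' @return object of class `spectrum_set`: list with `psd` (trial x
#'   electrode x frequency array), `f` (frequencies, Hz), `events`.
#' @export
trial_spectra <- function(epochs, fmax = 250, stim_window = c(0, 0.5)) {
  stopifnot(inherits(epochs, "voltage_epochs"))
  tsel <- epochs$time >= stim_window[1] & epochs$time < stim_window[2]
  fs <- epochs$sample_rate
  n_ep <- dim(epochs$data)[1]
  n_el <- dim(epochs$data)[2]
  f <- 1:fmax
  psd <- array(NA_real_, dim = c(n_ep, n_el, fmax))
  for (e in seq_len(n_el)) {
    M <- matrix(epochs$data[, e, tsel], nrow = n_ep)
    P <- welch_psd_matrix(M, fs)
    psd[, e, ] <- P[, f + 1L, drop = FALSE]
  }
  structure(list(psd = psd, f = f, events = epochs$events),
            class = "spectrum_set")
}

#' Baseline spectrum: geometric mean across blank epochs
#'
#' @param psd trial x frequency matrix (one electrode) or trial x
#'   electrode x frequency array of blank-epoch PSDs.
#' @return per-frequency geometric mean (vector, or electrode x frequency
#'   matrix for array input).
#' @export
baseline_spectrum <- function(psd) {
  check <- function(x) {
    bad <- which(!(x > 0))
    if (length(bad))
      stop("non-positive PSD value at bin ", bad[1])
  }
  if (is.matrix(psd)) {
    check(psd)
    exp(colMeans(log(psd)))
  } else if (length(dim(psd)) == 3) {
    check(psd)
    exp(apply(log(psd), c(2, 3), mean))
  } else {
    check(psd)
    psd
  }
}

#' Geometric mean of trial spectra across repeated runs
#'
#' Trial t of the output is the per-frequency geometric mean of trial t
#' across runs.  Trials excluded in some runs (NA) are averaged over the
#' runs in which they survive.
#'
#' @param runs list of trial x electrode x frequency arrays (identical
#'   dimensions), or of `spectrum_set` objects.
#' @return run-averaged array (or `spectrum_set` if given sets).
#' @export
average_across_runs <- function(runs) {
  is_set <- inherits(runs[[1]], "spectrum_set")
  arrs <- if (is_set) lapply(runs, `[[`, "psd") else runs
  dims <- lapply(arrs, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]])))
    stop("runs have mismatched trial/electrode/frequency dimensions")
  if (length(arrs) == 1) {
    out <- arrs[[1]]
  } else {
    logs <- lapply(arrs, log)
    sums <- Reduce(`+`, lapply(logs, function(a) ifelse(is.na(a), 0, a)))
    cnts <- Reduce(`+`, lapply(logs, function(a) !is.na(a)))
    out <- exp(sums / cnts)
    out[cnts == 0] <- NA_real_
  }
  if (is_set) {
    res <- runs[[1]]
    res$psd <- out
    res$run_averaged <- TRUE
    res
  } else out
}
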
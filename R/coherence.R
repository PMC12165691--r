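#' Welch-averaged cross- and auto-spectra of an epoch pair
#'
#' Cross power spectral density over the full epoch (nominally -200 to
#' 800 ms), computed in Hann-tapered 500 ms sliding windows with 75%
#' overlap, zero-padded to `nfft = sample_rate` samples (1 Hz bins) and
#' averaged across windows.  Epochs should have their ERPs regressed out
#' first, so that coherence does not merely reflect shared
#' stimulus-locked responses.  Averaging over several windows before
#' forming the coherence ratio is what keeps the magnitude-squared
#' coherence of a single epoch below 1.
#'
#' @param x,y equal-length voltage epochs (numeric vectors).
#' @param sample_rate sampling rate, Hz.
#' @param window_sec window length, seconds (0.5).
#' @param overlap fractional overlap (0.75).
#' @param nfft FFT length (default `sample_rate`).
#' @return list with `f`, `Pxy` (complex), `Pxx`, `Pyy`, `n_windows`.
#' @export
windowed_cpsd <- function(x, y, sample_rate, window_sec = 0.5,
                          overlap = 0.75, nfft = NULL) {
  stopifnot(length(x) == length(y))
  fs <- sample_rate
  if (is.null(nfft)) nfft <- round(fs)
  win_n <- round(window_sec * fs)
  if (length(x) < win_n) stop("epoch shorter than one window")
  w <- hann_window(win_n)
  step <- max(1L, floor(win_n * (1 - overlap)))
  starts <- seq(1L, length(x) - win_n + 1L, by = step)
  nb <- nfft %/% 2 + 1
  scale <- 1 / (fs * sum(w^2))
  Pxy <- complex(real = rep(0, nb))
  Pxx <- Pyy <- numeric(nb)
  for (s in starts) {
    idx <- s:(s + win_n - 1L)
    X <- stats::fft(c(x[idx] * w, numeric(nfft - win_n)))[1:nb]
    Y <- stats::fft(c(y[idx] * w, numeric(nfft - win_n)))[1:nb]
    Pxy <- Pxy + X * Conj(Y)
    Pxx <- Pxx + Mod(X)^2
    Pyy <- Pyy + Mod(Y)^2
  }
  K <- length(starts)
  one_sided <- function(p) { p[2:(nb - 1)] <- 2 * p[2:(nb - 1)]; p }
  list(f = 0:(nb - 1L),
       Pxy = one_sided(Pxy / K * scale),
       Pxx = one_sided(Pxx / K * scale),
       Pyy = one_sided(Pyy / K * scale),
       n_windows = K)
}

#' Magnitude-squared coherence averaged across runs
#'
#' MSC(f) = (1/N) sum over runs of |Pxy|^2 / (Pxx Pyy), each run's
#' spectra already Welch-averaged across windows.  Each run's ratio lies
#' in [0, 1]; bins with a zero auto-spectrum are masked (NA).
#'
#' @param cpsd_runs list of `windowed_cpsd` results, one per run.
#' @return list with `f` and `msc`.
#' @export
msc <- function(cpsd_runs) {
  stopifnot(length(cpsd_runs) >= 1)
  vals <- vapply(cpsd_runs, function(cp) {
    den <- cp$Pxx * cp$Pyy
    out <- Mod(cp$Pxy)^2 / den
    out[den == 0] <- NA_real_
    pmin(out, 1)
  }, numeric(length(cpsd_runs[[1]]$f)))
  list(f = cpsd_runs[[1]]$f, msc = rowMeans(as.matrix(vals)))
}

#' Alpha and broadband coherence summaries from an MSC spectrum
#'
#' Alpha coherence is the MSC at the (rounded) peak alpha frequency bin;
#' broadband coherence is the arithmetic mean of the MSC across
#' 70-180 Hz.
#'
#' @param msc_f MSC values over `f`.
#' @param f frequency grid, Hz.
#' @param alpha_peak peak alpha frequency, Hz.
#' @param band broadband range, Hz.
#' @return list with `alpha` and `broadband`.
#' @export
band_coherence <- function(msc_f, f, alpha_peak, band = c(70, 180)) {
  ai <- which(f == round(alpha_peak))
  if (length(ai) == 0) stop("alpha peak outside the frequency grid")
  sel <- f >= band[1] & f <= band[2]
  list(alpha = msc_f[ai], broadband = mean(msc_f[sel], na.rm = TRUE))
}

#' Pairwise coherence across a simulated grid
#'
#' Computes, for every electrode pair, the run-averaged MSC (one
#' windowed CPSD per epoch and run, MSC ratio per run, mean over runs,
#' then mean over the selected epochs) and the alpha / broadband
#' summaries.
#'
#' @param epochs_by_run list (one per run) of `voltage_epochs`, normally
#'   ERP-regressed.
#' @param alpha_peak alpha peak frequency used for the alpha summary, Hz.
#' @param epoch_subset optional indices of epochs to use (default: all).
#' @param band broadband range, Hz.
#' @return data frame with columns `el1`, `el2`, `alpha`, `broadband`.
#' @export
grid_pair_coherence <- function(epochs_by_run, alpha_peak = 10,
                                epoch_subset = NULL, band = c(70, 180)) {
  ep1 <- epochs_by_run[[1]]
  n_el <- dim(ep1$data)[2]
  n_ep <- dim(ep1$data)[1]
  if (is.null(epoch_subset)) epoch_subset <- seq_len(n_ep)
  fs <- ep1$sample_rate
  pairs <- which(upper.tri(matrix(0, n_el, n_el)), arr.ind = TRUE)
  out <- data.frame(el1 = pairs[, 1], el2 = pairs[, 2],
                    alpha = NA_real_, broadband = NA_real_)
  for (p in seq_len(nrow(pairs))) {
    i <- pairs[p, 1]; j <- pairs[p, 2]
    msc_acc <- NULL; nacc <- 0
    for (t in epoch_subset) {
      cps <- lapply(epochs_by_run, function(ep)
        windowed_cpsd(ep$data[t, i, ], ep$data[t, j, ], fs))
      m <- msc(cps)
      msc_acc <- if (is.null(msc_acc)) m$msc else msc_acc + m$msc
      nacc <- nacc + 1
    }
    bc <- band_coherence(msc_acc / nacc, m$f, alpha_peak, band)
    out$alpha[p] <- bc$alpha
    out$broadband[p] <- bc$broadband
  }
  out
}

#' Bin electrode-pair values by inter-electrode distance
#'
#' Euclidean distances are assigned to bins at multiples of `bin_width`
#' mm by rounding (`round(d / bin_width) * bin_width`), and the values
#' are averaged per bin.  Pairs whose seed electrode is masked out are
#' dropped; empty bins are omitted.
#'
#' @param values one value per pair (e.g. alpha coherence).
#' @param pairs two-column matrix/data frame of electrode indices.
#' @param positions electrode x 2 matrix of coordinates, mm.
#' @param bin_width bin spacing, mm (3).
#' @param seed_mask optional logical vector per electrode; a pair is kept
#'   when at least one member is an accepted seed.
#' @return data frame with `distance` (bin centre, mm), `mean`, `n`.
#' @export
bin_by_distance <- function(values, pairs, positions, bin_width = 3,
                            seed_mask = NULL) {
  pairs <- as.matrix(pairs)
  d <- sqrt(rowSums((positions[pairs[, 1], , drop = FALSE] -
                       positions[pairs[, 2], , drop = FALSE])^2))
  keep <- rep(TRUE, length(values))
  if (!is.null(seed_mask))
    keep <- seed_mask[pairs[, 1]] | seed_mask[pairs[, 2]]
  bin <- round(d / bin_width) * bin_width
  agg <- stats::aggregate(values[keep], list(distance = bin[keep]),
                          function(v) c(mean = mean(v), n = length(v)))
  data.frame(distance = agg$distance,
             mean = agg$x[, "mean"], n = agg$x[, "n"])
}

#' Fit an exponential decay to coherence vs distance
#'
#' Least-squares fit of c(d) = a exp(-d / lambda) + b, with a bootstrap
#' over distance bins (resampling with replacement) for parameter
#' uncertainty.  When the amplitude is indistinguishable from zero the
#' length constant is unidentifiable and flagged.
#'
#' @param distance bin distances, mm.
#' @param value mean coherence per bin.
#' @param n_boot bootstrap draws.
#' @param seed integer RNG seed.
#' @return object of class `decay_fit`: list with `a`, `lambda`, `b`,
#'   `draws` (per-bootstrap parameter matrix), `n_failed`,
#'   `lambda_identifiable`.
#' @export
fit_decay <- function(distance, value, n_boot = 1000, seed = 1) {
  stopifnot(length(distance) == length(value))
  if (length(unique(distance)) < 4) stop("need at least 4 distance bins")
  fit_one <- function(d, v) {
    a0 <- max(v) - min(v); b0 <- min(v); l0 <- max(stats::median(d), 1e-3)
    fit <- tryCatch(
      minpack.lm::nlsLM(v ~ a * exp(-d / lambda) + b,
                        start = list(a = max(a0, 1e-3), lambda = l0,
                                     b = b0),
                        lower = c(-Inf, 1e-6, 0),
                        upper = c(Inf, Inf, 1),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit))    # flat data: the constant model, amplitude 0
      return(c(a = 0, lambda = NA_real_, b = mean(v)))
    stats::coef(fit)
  }
  main <- fit_one(distance, value)
  draws <- matrix(NA_real_, n_boot, 3,
                  dimnames = list(NULL, c("a", "lambda", "b")))
  with_local_seed(seed, for (bi in seq_len(n_boot)) {
    take <- sample(length(distance), replace = TRUE)
    if (length(unique(distance[take])) < 3) next
    cf <- tryCatch(fit_one(distance[take], value[take]),
                   error = function(e) NULL)
    if (!is.null(cf)) draws[bi, ] <- cf
  })
  ok <- stats::complete.cases(draws)
  structure(list(a = unname(main["a"]), lambda = unname(main["lambda"]),
                 b = unname(main["b"]), draws = draws[ok, , drop = FALSE],
                 n_failed = sum(!ok),
                 lambda_identifiable = unname(abs(main["a"]) > 0.02)),
            class = "decay_fit")
}
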
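#' @name decompose
#' @title Spectral decomposition into broadband shift and alpha suppression
#'
#' @description
#' The stimulus-evoked change in low-frequency power is modelled, in the
#' log10-power / log10-frequency domain, as the sum of a linear broadband
#' elevation and a Gaussian alpha component:
#'
#'   log10(P_S(k) / P_B(k)) = (beta_broadband_low - n (k - mu))
#'                            + beta_alpha G(k | mu, sigma),
#'   k = log10(frequency),  G(k | mu, sigma) = exp(-(k - mu)^2 / (2 sigma^2)),
#'
#' with 8 Hz < 10^mu < 13 Hz.  beta_alpha is the trial's alpha response
#' (negative = suppression); beta_broadband_low is the broadband shift in
#' the low band.  An optional second Gaussian with 15 Hz < 10^mu2 < 30 Hz
#' absorbs a beta-band bump when one is present (fit range then extends
#' to 32 Hz).  The slope term is anchored at the alpha peak and mu is
#' shared between the line and the Gaussian during optimisation.
#'
#' Fitting is bounded least squares on the log10 ratio over integer-Hz
#' bins: the amplitudes (beta_broadband_low, n, beta_alpha, beta_beta)
#' are profiled out linearly for every candidate (mu, sigma [, mu2,
#' sigma2]), and the nonlinear parameters are optimised by multi-start
#' L-BFGS-B within bounds (sigma in [0.01, 0.2] log10-Hz; n in [-2, 3]).
NULL

spectral_gaussian <- function(k, mu, sigma) exp(-(k - mu)^2 / (2 * sigma^2))

# Profiled linear solve for the amplitude parameters given the nonlinear
# ones; clamps the slope n to its bounds (refitting the rest) if needed.
.spectral_inner_fit <- function(y, k, mu, sigma, mu2 = NULL, sigma2 = NULL,
                                n_bounds = c(-2, 3)) {
  X <- cbind(1, -(k - mu), spectral_gaussian(k, mu, sigma))
  if (!is.null(mu2)) X <- cbind(X, spectral_gaussian(k, mu2, sigma2))
  cf <- tryCatch(qr.coef(qr(X), y), error = function(e) rep(NA_real_, ncol(X)))
  if (any(is.na(cf))) cf[is.na(cf)] <- 0
  if (cf[2] < n_bounds[1] || cf[2] > n_bounds[2]) {
    n_fix <- min(max(cf[2], n_bounds[1]), n_bounds[2])
    y2 <- y + n_fix * (k - mu)
    X2 <- X[, -2, drop = FALSE]
    cf2 <- qr.coef(qr(X2), y2)
    cf <- append(cf2, n_fix, after = 1)
  }
  resid <- y - as.numeric(X %*% cf)
  list(coef = cf, sse = sum(resid^2))
}

.spectral_objective <- function(theta, y, k, beta_term, n_bounds) {
  if (beta_term)
    .spectral_inner_fit(y, k, theta[1], theta[2], theta[3], theta[4],
                        n_bounds)$sse
  else
    .spectral_inner_fit(y, k, theta[1], theta[2], n_bounds = n_bounds)$sse
}

#' Fit the spectral decomposition model to a log10 power ratio
#'
#' @param ratio log10(P_S / P_B) at the frequencies `f`.
#' @param f frequencies in Hz (integer bins).
#' @param mu_range_hz allowed range of the alpha peak 10^mu, Hz.
#' @param beta_term include the 15-30 Hz beta Gaussian.
#' @param sigma_bounds bounds on the Gaussian width, log10-Hz.
#' @param n_bounds bounds on the broadband slope.
#' @param n_starts_sigma number of sigma start values per mu start.
#' @param polish run a second, high-precision optimisation pass from the
#'   winning start (needed for exact inversion; per-trial fits skip it).
#' @return object of class `decomposition_fit`: list with
#'   `beta_broadband_low`, `n`, `beta_alpha`, `mu`, `sigma`,
#'   `alpha_peak_hz` (= 10^mu), optional `beta_beta`, `mu2`, `sigma2`,
#'   `rmse`, and `peak_pinned` (TRUE when the peak sits at a bound).
#' @export
fit_spectral_model <- function(ratio, f, mu_range_hz = c(8, 13),
                               beta_term = FALSE,
                               sigma_bounds = c(0.01, 0.2),
                               n_bounds = c(-2, 3),
                               n_starts_sigma = 3, polish = TRUE) {
  ok <- is.finite(ratio)
  if (!all(ok)) {
    message(sum(!ok), " non-finite ratio bin(s) dropped")
    ratio <- ratio[ok]
    f <- f[ok]
  }
  k <- log10(f)
  mu_lo <- log10(mu_range_hz[1])
  mu_hi <- log10(mu_range_hz[2])
  mu_starts <- if (mu_hi - mu_lo < 1e-9) mu_lo else
    seq(mu_lo, mu_hi, length.out = 5)
  sg_starts <- seq(sigma_bounds[1] + 0.01, sigma_bounds[2] - 0.02,
                   length.out = n_starts_sigma)
  lower <- c(mu_lo, sigma_bounds[1])
  upper <- c(mu_hi, sigma_bounds[2])
  if (beta_term) {
    lower <- c(lower, log10(15), sigma_bounds[1])
    upper <- c(upper, log10(30), sigma_bounds[2])
  }
  best <- NULL
  for (m0 in mu_starts) for (s0 in sg_starts) {
    theta0 <- c(m0, s0)
    if (beta_term) theta0 <- c(theta0, log10(22), 0.05)
    opt <- tryCatch(
      stats::optim(theta0, .spectral_objective, y = ratio, k = k,
                   beta_term = beta_term, n_bounds = n_bounds,
                   method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(factr = 1e2, maxit = 300,
                                  ndeps = rep(1e-5, length(theta0)))),
      error = function(e) NULL)
    if (!is.null(opt) && (is.null(best) || opt$value < best$value))
      best <- opt
  }
  # polish the winning start to high precision
  if (polish) {
    pol <- tryCatch(
      stats::optim(best$par, .spectral_objective, y = ratio, k = k,
                   beta_term = beta_term, n_bounds = n_bounds,
                   method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(factr = 1, pgtol = 1e-14, maxit = 500,
                                  ndeps = rep(1e-7, length(best$par)))),
      error = function(e) best)
    if (pol$value <= best$value) best <- pol
  }
  th <- best$par
  inner <- if (beta_term)
    .spectral_inner_fit(ratio, k, th[1], th[2], th[3], th[4], n_bounds)
  else .spectral_inner_fit(ratio, k, th[1], th[2], n_bounds = n_bounds)
  tol <- 1e-5
  out <- list(beta_broadband_low = unname(inner$coef[1]),
              n = unname(inner$coef[2]),
              beta_alpha = unname(inner$coef[3]),
              mu = th[1], sigma = th[2],
              alpha_peak_hz = 10^th[1],
              rmse = sqrt(inner$sse / length(ratio)),
              peak_pinned = (th[1] <= mu_lo + tol || th[1] >= mu_hi - tol))
  if (beta_term) {
    out$beta_beta <- unname(inner$coef[4])
    out$mu2 <- th[3]
    out$sigma2 <- th[4]
  }
  structure(out, class = "decomposition_fit")
}

#' Electrode-level alpha peak from the mean stimulus spectrum
#'
#' Fits the decomposition to the log10 ratio of the across-trial mean
#' stimulus PSD to the blank baseline over the fit range (3-26 Hz, or
#' 3-32 Hz with the beta term), with the alpha peak free in 8-13 Hz.
#'
#' @param mean_ps mean stimulus-trial PSD (vector over `f`).
#' @param p_b blank-baseline PSD (vector over `f`).
#' @param f frequency grid of the inputs, Hz.
#' @param fit_range fit range in Hz; default depends on `beta_term`.
#' @param beta_term include the beta-bump Gaussian.
#' @param exclude_hz integer frequencies to drop (e.g. line noise).
#' @return a `decomposition_fit`; its `alpha_peak_hz` is the electrode
#'   peak used to constrain per-trial fits.
#' @export
fit_electrode_alpha_peak <- function(mean_ps, p_b, f, fit_range = NULL,
                                     beta_term = FALSE, exclude_hz = NULL) {
  if (is.null(fit_range)) fit_range <- if (beta_term) c(3, 32) else c(3, 26)
  sel <- f >= fit_range[1] & f <= fit_range[2]
  if (!is.null(exclude_hz)) sel <- sel & !(f %in% exclude_hz)
  ratio <- log10(mean_ps[sel] / p_b[sel])
  fit_spectral_model(ratio, f[sel], mu_range_hz = c(8, 13),
                     beta_term = beta_term)
}

#' Per-trial spectral decomposition
#'
#' As `fit_electrode_alpha_peak`, but the alpha peak is constrained to
#' within 1 Hz of the electrode-level peak.  `beta_alpha` of the result
#' is the trial's alpha summary value (log10 power ratio).
#'
#' @param p_s trial PSD (vector over `f`).
#' @inheritParams fit_electrode_alpha_peak
#' @param electrode_peak electrode-level alpha peak, Hz.
#' @param peak_tol allowed deviation of the trial peak from the
#'   electrode peak, Hz.
#' @return a `decomposition_fit`.
#' @export
decompose_trial <- function(p_s, p_b, f, electrode_peak, fit_range = NULL,
                            beta_term = FALSE, exclude_hz = NULL,
                            peak_tol = 1) {
  if (is.null(fit_range)) fit_range <- if (beta_term) c(3, 32) else c(3, 26)
  sel <- f >= fit_range[1] & f <= fit_range[2]
  if (!is.null(exclude_hz)) sel <- sel & !(f %in% exclude_hz)
  ratio <- log10(p_s[sel] / p_b[sel])
  mu_range <- c(max(8, electrode_peak - peak_tol),
                min(13, electrode_peak + peak_tol))
  fit_spectral_model(ratio, f[sel], mu_range_hz = mu_range,
                     beta_term = beta_term, n_starts_sigma = 2,
                     polish = FALSE)
}

#' Harmonic line-noise exclusion bands by recording site
#'
#' @param site "nyu" (116-125 and 176-180 Hz) or "umcu" (96-105 and
#'   146-155 Hz).
#' @return integer vector of excluded frequencies, Hz.
#' @export
harmonic_exclusions <- function(site = c("nyu", "umcu")) {
  site <- match.arg(site)
  if (site == "nyu") c(116:125, 176:180) else c(96:105, 146:155)
}

#' High-frequency broadband power elevation
#'
#' The ratio of the geometric mean of the stimulus PSD to the geometric
#' mean of the blank PSD across 70-180 Hz in 1 Hz bins, with line-noise
#' harmonic bands excluded.
#'
#' @param p_s,p_b stimulus and blank PSD vectors over `f`.
#' @param f frequency grid, Hz.
#' @param band frequency band, Hz.
#' @param exclude_hz integer frequencies to exclude; use
#'   `harmonic_exclusions(site)` for the site presets.
#' @return broadband elevation as a (linear) power ratio.
#' @export
broadband_power <- function(p_s, p_b, f, band = c(70, 180),
                            exclude_hz = NULL) {
  sel <- f >= band[1] & f <= band[2]
  if (!is.null(exclude_hz)) sel <- sel & !(f %in% exclude_hz)
  if (!any(sel)) stop("no frequency bins left in the broadband band")
  geomean(p_s[sel]) / geomean(p_b[sel])
}

#' Low-frequency broadband power (alpha Gaussian removed)
#'
#' The broadband component of the 3-26 Hz response: 10^beta_broadband_low
#' from the trial's decomposition, i.e. the low-band power change with
#' the alpha Gaussian separated out.
#'
#' @param fit a `decomposition_fit`, or NULL to compute one from the
#'   spectra.
#' @inheritParams decompose_trial
#' @return power ratio 10^beta_broadband_low.
#' @export
low_frequency_broadband_power <- function(fit = NULL, p_s = NULL,
                                          p_b = NULL, f = NULL,
                                          electrode_peak = NULL, ...) {
  if (is.null(fit)) {
    stopifnot(!is.null(p_s), !is.null(p_b), !is.null(f),
              !is.null(electrode_peak))
    fit <- decompose_trial(p_s, p_b, f, electrode_peak, ...)
  }
  10^fit$beta_broadband_low
}

#' Alpha-band power without model-based correction
#'
#' The control analysis: geometric-mean power ratio within
#' [peak - halfwidth, peak + halfwidth], with no attempt to remove the
#' broadband shift.  When broadband power rises while the oscillation is
#' suppressed, the two changes cancel and this estimate stays near 1.
#'
#' @param p_s,p_b stimulus and blank PSD vectors over `f`.
#' @param f frequency grid, Hz.
#' @param peak electrode alpha peak, Hz.
#' @param halfwidth half-width of the band, Hz.
#' @return power ratio (1 = no change).
#' @export
alpha_band_power_no_correction <- function(p_s, p_b, f, peak,
                                           halfwidth = 1.5) {
  sel <- f >= peak - halfwidth & f <= peak + halfwidth
  geomean(p_s[sel]) / geomean(p_b[sel])
}

#' Build decimated alpha and broadband summary time courses
#'
#' Expresses both series as log10 power ratios relative to the mean
#' blank-trial value, low-pass filters and decimates them by `factor`
#' (Chebyshev Type I order 3, zero phase; see `decimate_series`), turning
#' 224 trials into 75 time points.
#'
#' @param beta_alpha per-trial alpha coefficients (log10 units).
#' @param broadband_ratio per-trial broadband elevation (linear ratio).
#' @param blank logical vector flagging blank trials.
#' @param factor decimation factor.
#' @return object of class `summary_timecourse`: list with `alpha`,
#'   `broadband` (decimated log10-ratio series), `n_original`, `factor`.
#' @export
build_summary_time_courses <- function(beta_alpha, broadband_ratio, blank,
                                       factor = 3) {
  stopifnot(length(beta_alpha) == length(broadband_ratio),
            length(blank) == length(beta_alpha))
  a <- beta_alpha - mean(beta_alpha[blank])
  b <- log10(broadband_ratio) - mean(log10(broadband_ratio[blank]))
  structure(list(alpha = decimate_series(a, factor),
                 broadband = decimate_series(b, factor),
                 n_original = length(a), factor = factor),
            class = "summary_timecourse")
}
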
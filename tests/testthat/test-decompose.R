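# helper: evaluate the decomposition model forward
model_ratio <- function(f, bb, n, ba, mu, sg, bbeta = 0, mu2 = log10(22),
                        sg2 = 0.05) {
  k <- log10(f)
  bb - n * (k - mu) + ba * exp(-(k - mu)^2 / (2 * sg^2)) +
    bbeta * exp(-(k - mu2)^2 / (2 * sg2^2))
}

test_that("noiseless spectra are inverted to high precision", {
  f <- 3:26
  cases <- list(
    c(bb = 0.3, n = 0.2, ba = -0.5, mu = log10(10), sg = 0.05),
    c(bb = 0.0, n = -0.3, ba = -0.2, mu = log10(8.7), sg = 0.12),
    c(bb = 0.6, n = 1.0, ba = 0.15, mu = log10(12.2), sg = 0.03))
  for (tr in cases) {
    y <- model_ratio(f, tr["bb"], tr["n"], tr["ba"], tr["mu"], tr["sg"])
    fit <- fit_spectral_model(y, f)
    err <- c(fit$beta_broadband_low - tr["bb"], fit$n - tr["n"],
             fit$beta_alpha - tr["ba"], fit$mu - tr["mu"],
             fit$sigma - tr["sg"])
    expect_lt(max(abs(err)), 1e-6)
  }
})

test_that("a pure broadband shift yields a near-zero alpha coefficient", {
  f <- 3:26
  y <- model_ratio(f, 0.4, 0.1, 0, log10(10), 0.05)
  fit <- fit_spectral_model(y, f)
  expect_lt(abs(fit$beta_alpha), 0.01)
  # with no alpha bump, mu is unidentified, so compare the fitted
  # broadband line pointwise rather than its (mu-anchored) offset
  k <- log10(f)
  line <- fit$beta_broadband_low - fit$n * (k - fit$mu)
  expect_equal(line, y, tolerance = 1e-3)
})

test_that("a planted 11.5 Hz peak is localised within a hertz", {
  f <- 3:26
  y <- model_ratio(f, 0.1, 0, -0.4, log10(11.5), 0.06)
  fit <- fit_spectral_model(y, f)
  expect_gte(fit$alpha_peak_hz, 10.5)
  expect_lte(fit$alpha_peak_hz, 12.5)
})

test_that("decomposition is scale-equivariant in stimulus power", {
  f <- 3:26
  y <- model_ratio(f, 0.2, 0.3, -0.5, log10(9.5), 0.07)
  ps <- 10^y
  pb <- rep(1, length(f))
  f0 <- fit_electrode_alpha_peak(ps, pb, f)
  for (cshift in c(-1, 0.5, 2)) {
    f1 <- fit_electrode_alpha_peak(ps * 10^cshift, pb, f)
    expect_equal(f1$beta_broadband_low - f0$beta_broadband_low, cshift,
                 tolerance = 1e-5)
    expect_equal(f1$beta_alpha, f0$beta_alpha, tolerance = 1e-5)
  }
})

test_that("per-trial fits keep the peak within 1 Hz of the electrode peak", {
  f <- 3:26
  pb <- rep(1, length(f))
  # electrode peak at 10; trial generated with a drifted peak at 12.5
  y <- model_ratio(f, 0.1, 0, -0.5, log10(12.5), 0.06)
  fit <- decompose_trial(10^y, pb, f, electrode_peak = 10)
  expect_lte(fit$alpha_peak_hz, 11 + 1e-9)
  expect_gte(fit$alpha_peak_hz, 9 - 1e-9)
})

test_that("cancellation: suppression is detected when raw band power is flat", {
  # background 1/f plus an alpha bump in the baseline; stimulus removes
  # the bump and raises broadband power by exactly the amount that keeps
  # the geometric-mean alpha-band power unchanged
  f <- 3:26
  bg <- 20 * f^-1.5
  bump <- 60 * exp(-(f - 10)^2 / (2 * 1.5^2))
  pb <- bg + bump
  band <- f >= 8.5 & f <= 11.5
  cshift <- mean(log10(pb[band]) - log10(bg[band]))
  ps <- bg * 10^cshift
  nc <- alpha_band_power_no_correction(ps, pb, f, 10)
  expect_equal(nc, 1.0, tolerance = 0.01)       # masked by construction
  fit <- fit_electrode_alpha_peak(ps, pb, f)
  expect_lt(fit$beta_alpha, -0.2)               # decomposition sees it
})

test_that("the beta-bump term shields the alpha estimate", {
  f <- 3:32
  base <- model_ratio(f, 0.2, 0.1, -0.5, log10(10), 0.06)
  with_beta <- model_ratio(f, 0.2, 0.1, -0.5, log10(10), 0.06,
                           bbeta = 0.3, mu2 = log10(24), sg2 = 0.04)
  f_nobump <- fit_spectral_model(base, f, beta_term = TRUE)
  f_bump <- fit_spectral_model(with_beta, f, beta_term = TRUE)
  expect_lt(abs(f_bump$beta_alpha - f_nobump$beta_alpha),
            0.05 * abs(f_nobump$beta_alpha))
  expect_gte(10^f_bump$mu2, 15)
  expect_lte(10^f_bump$mu2, 30)
})

test_that("broadband power is a geometric-mean ratio with exclusions", {
  f <- 1:250
  pb <- 100 * f^-1.2
  expect_equal(broadband_power(2 * pb, pb, f), 2.0)
  # contamination confined to an excluded band is ignored
  ps <- pb
  ps[f >= 116 & f <= 125] <- 10 * ps[f >= 116 & f <= 125]
  expect_equal(broadband_power(ps, pb, f,
                               exclude_hz = harmonic_exclusions("nyu")), 1.0)
  # log-linearity
  for (cs in c(-0.7, 0.3, 1.2))
    expect_equal(broadband_power(pb * 10^cs, pb, f), 10^cs)
  expect_error(broadband_power(pb, pb, f, band = c(70, 180),
                               exclude_hz = 1:250), "no frequency bins")
  expect_equal(harmonic_exclusions("umcu"), c(96:105, 146:155))
})

test_that("low-frequency broadband power isolates the shift from alpha", {
  f <- 3:26
  pb <- rep(1, length(f))
  y <- model_ratio(f, 0.3, 0.2, -0.5, log10(10), 0.05)
  expect_equal(low_frequency_broadband_power(
    p_s = 10^y, p_b = pb, f = f, electrode_peak = 10), 10^0.3,
    tolerance = 1e-4)
  # null trial
  expect_equal(low_frequency_broadband_power(
    p_s = pb, p_b = pb, f = f, electrode_peak = 10), 1.0, tolerance = 0.01)
  # invariant to the alpha amplitude
  vals <- vapply(c(-0.8, -0.4, 0), function(ba)
    low_frequency_broadband_power(
      p_s = 10^model_ratio(f, 0.3, 0.2, ba, log10(10), 0.05),
      p_b = pb, f = f, electrode_peak = 10), numeric(1))
  expect_lt(diff(range(vals)), 0.03 * 10^0.3)
})

test_that("uncorrected alpha power behaves as the control analysis", {
  f <- 3:26
  pb <- rep(1, length(f))
  # alpha fully removed with no broadband change: ratio < 1
  y <- model_ratio(f, 0, 0, -0.6, log10(10), 0.06)
  expect_lt(alpha_band_power_no_correction(10^y, pb, f, 10), 1)
  # with zero broadband shift the uncorrected and model-based estimates
  # agree on the direction and approximate size of the change
  fit <- fit_electrode_alpha_peak(10^y, pb, f)
  nc <- alpha_band_power_no_correction(10^y, pb, f, fit$alpha_peak_hz)
  expect_equal(sign(log10(nc)), sign(fit$beta_alpha))
})

test_that("trial spectrum equal to baseline gives near-zero amplitudes", {
  f <- 3:26
  pb <- 50 * f^-1.3
  fit <- decompose_trial(pb, pb, f, electrode_peak = 10)
  expect_lt(abs(fit$beta_alpha), 1e-6)
  expect_lt(abs(fit$beta_broadband_low), 1e-6)
})

test_that("summary time courses decimate 224 trials to 75 points", {
  set.seed(21)
  blank <- rep(FALSE, 224)
  blank[sample(224, 64)] <- TRUE
  ba <- rnorm(224, 0, 0.1)
  bb <- exp(rnorm(224, 0, 0.1))
  tc <- build_summary_time_courses(ba, bb, blank)
  expect_length(tc$alpha, 75)
  expect_length(tc$broadband, 75)
  # constant series pass through the decimator unchanged
  expect_equal(max(abs(decimate_series(rep(3, 224)) - 3)), 0,
               tolerance = 1e-10)
  # a +/- alternation (Nyquist) is attenuated by > 20 dB away from the
  # reflection-padded edges
  alt <- rep(c(1, -1), 112)
  expect_lt(max(abs(decimate_series(alt)[5:71])), 10^(-20 / 20))
  # blank normalisation: blank trials average to ~0 in both series
  dec_blank <- decimate_series(as.numeric(blank)) > 0.5
  expect_lt(abs(mean(tc$alpha[dec_blank])), 0.05)
})

test_that("log-domain noise leaves the alpha coefficient well estimated", {
  f <- 3:26
  set.seed(22)
  errs <- replicate(150, {
    tr <- c(bb = runif(1, 0, 0.5), n = runif(1, -0.5, 1),
            ba = runif(1, -0.8, 0), mu = log10(runif(1, 8.5, 12.5)),
            sg = runif(1, 0.03, 0.12))
    y <- model_ratio(f, tr["bb"], tr["n"], tr["ba"], tr["mu"], tr["sg"]) +
      rnorm(length(f), 0, 0.05)
    abs(fit_spectral_model(y, f)$beta_alpha - tr["ba"])
  })
  expect_lt(median(errs), 0.05)
})
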
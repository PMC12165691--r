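#' Ground-truth electrode for synthetic ECoG
#'
#' Bundles the generative parameters of one simulated recording site: a
#' positive Difference-of-Gaussians (DoG) pRF that multiplies broadband
#' (1/f^chi) power by 10^response while the bar is on, a second DoG pRF
#' whose response is applied with a negative sign to the amplitude of an
#' 8-13 Hz oscillation (alpha suppression), an evoked-potential template
#' added at stimulus onsets, and optional line noise and a beta bump.
#'
#' @param position electrode (x, y) position on the recording grid, mm.
#' @param bb_prf named/ordered vector (x, y, sigma, g1, g2): broadband pRF
#'   in degrees of visual angle and per-pixel gain units.
#' @param alpha_prf same layout; its response is applied with a negative
#'   sign to the oscillation amplitude, so positive g1 means suppression.
#' @param alpha_peak alpha oscillation peak frequency, Hz, in [8, 13].
#' @param noise_level RMS of the broadband background, arbitrary voltage
#'   units (think microvolts).
#' @param alpha_rms RMS of the unsuppressed alpha oscillation.
#' @param erp_amp peak amplitude of the evoked-potential template (a
#'   damped 10 Hz sinusoid over 0-300 ms); 0 disables it.
#' @param chi exponent of the 1/f^chi broadband background spectrum.
#' @param line_freq line-noise frequency in Hz, or NULL for none.
#' @param line_amp line-noise sinusoid amplitude.
#' @param beta_bump c(center_hz, rms) for a beta-band oscillation, or NULL.
#' @return object of class `gt_electrode`.
#' @export
gt_electrode <- function(position = c(0, 0),
                         bb_prf = c(x = 0, y = 0, sigma = 1, g1 = 0, g2 = 0),
                         alpha_prf = c(x = 0, y = 0, sigma = 2, g1 = 0, g2 = 0),
                         alpha_peak = 10, noise_level = 10, alpha_rms = 10,
                         erp_amp = 20, chi = 1.5,
                         line_freq = NULL, line_amp = 0, beta_bump = NULL) {
  stopifnot(alpha_peak >= 8, alpha_peak <= 13,
            bb_prf[3] > 0, alpha_prf[3] > 0,
            noise_level > 0, alpha_rms >= 0)
  structure(list(position = position,
                 bb_prf = unname(bb_prf), alpha_prf = unname(alpha_prf),
                 alpha_peak = alpha_peak, noise_level = noise_level,
                 alpha_rms = alpha_rms, erp_amp = erp_amp, chi = chi,
                 line_freq = line_freq, line_amp = line_amp,
                 beta_bump = beta_bump),
            class = "gt_electrode")
}

# Damped 10 Hz sinusoid over 0-300 ms, the default evoked-response shape.
erp_template <- function(fs, amp = 1, dur = 0.3) {
  t <- seq(0, dur, by = 1 / fs)
  amp * sin(2 * pi * 10 * t) * exp(-t / 0.1)
}

#' Calibrate DoG gains to a target peak response
#'
#' Per-pixel gains depend on the aperture grid resolution; this helper
#' chooses g1 so that the largest center-only response over the bar steps
#' equals `peak` (log10 power units downstream), and g2 so that the mean
#' surround term over non-blank steps equals `surround`.
#'
#' @param ap an `aperture_sequence`.
#' @param x,y,sigma DoG centre and size in degrees.
#' @param peak target maximal centre response.
#' @param surround target mean surround response magnitude.
#' @return vector c(x, y, sigma, g1, g2).
#' @export
calibrate_dog_gains <- function(ap, x, y, sigma, peak = 0.5, surround = 0.05) {
  am <- aperture_matrix(ap)
  g <- exp(-((am$xpix - x)^2 + (am$ypix - y)^2) / (2 * sigma^2))
  center <- as.numeric(am$S %*% g)
  npix <- rowSums(am$S)
  show <- npix > 0
  g1 <- peak / max(center[show])
  g2 <- surround / mean(npix[show])
  c(x = x, y = y, sigma = sigma, g1 = g1, g2 = g2)
}

#' Simulate a bar-sweep ECoG experiment with known ground truth
#'
#' For every step the broadband background power is multiplied by
#' 10^(STIM . bb_prf) and the alpha oscillation power by
#' 10^(-(STIM . alpha_prf)) while the bar is on; blank steps carry
#' baseline broadband and the full alpha oscillation.  An ERP is added at
#' non-blank stimulus onsets.  Identical seeds give identical output.
#'
#' @param design a `prf_design`.
#' @param electrodes list of `gt_electrode`.
#' @param n_runs number of identical runs (fresh noise per run).
#' @param sample_rate sampling rate in Hz (512 recommended minimum).
#' @param seed integer RNG seed.
#' @param ap optional precomputed `aperture_sequence(design)`.
#' @param alpha_signals optional externally generated unit-RMS alpha
#'   source signals: a list of length `n_runs` of electrode x sample
#'   matrices (used by `simulate_grid` to share alpha across electrodes).
#' @return object of class `ecog_sim`: list with `voltage` (list of
#'   electrode x sample matrices, one per run), `events`, `sample_rate`,
#'   `design`, `electrodes`, `apertures`, and the ground-truth per-step
#'   responses `bb_response`, `alpha_response` (electrode x step).
#' @export
simulate_experiment <- function(design, electrodes, n_runs = 1,
                                sample_rate = 512, seed = 1, ap = NULL,
                                alpha_signals = NULL) {
  stopifnot(inherits(design, "prf_design"), n_runs >= 1)
  if (length(electrodes) == 0) stop("electrode list must not be empty")
  if (inherits(electrodes, "gt_electrode")) electrodes <- list(electrodes)
  if (is.null(ap)) ap <- aperture_sequence(design)
  am <- aperture_matrix(ap)
  ev <- ap$events
  fs <- sample_rate
  n_samp <- round(run_duration(design) * fs)
  n_el <- length(electrodes)
  n_steps <- nrow(ev)

  resp_for <- function(prf) {
    g <- prf[4] * exp(-((am$xpix - prf[1])^2 + (am$ypix - prf[2])^2) /
                        (2 * prf[3]^2))
    as.numeric(am$S %*% g) - prf[5] * rowSums(am$S)
  }
  bb_resp <- t(vapply(electrodes, function(e) resp_for(e$bb_prf),
                      numeric(n_steps)))
  al_resp <- t(vapply(electrodes, function(e) resp_for(e$alpha_prf),
                      numeric(n_steps)))

  on_idx <- lapply(seq_len(n_steps), function(i) {
    i0 <- floor(ev$onset[i] * fs) + 1L
    i1 <- min(floor((ev$onset[i] + design$stim_on) * fs), n_samp)
    i0:i1
  })

  runs <- vector("list", n_runs)
  with_local_seed(seed, for (r in seq_len(n_runs)) {
    v <- matrix(0, n_el, n_samp)
    for (e in seq_len(n_el)) {
      el <- electrodes[[e]]
      bb <- one_over_f_noise(n_samp, fs, chi = el$chi, rms = el$noise_level)
      osc <- if (is.null(alpha_signals)) {
        narrowband_noise(n_samp, fs, center = el$alpha_peak,
                         bw_sd = 1, rms = el$alpha_rms)
      } else {
        alpha_signals[[r]][e, ] * el$alpha_rms
      }
      env_bb <- rep(1, n_samp)
      env_al <- rep(1, n_samp)
      x <- numeric(n_samp)
      erp <- erp_template(fs, amp = el$erp_amp)
      for (i in seq_len(n_steps)) {
        if (ev$blank[i]) next
        idx <- on_idx[[i]]
        env_bb[idx] <- 10^(bb_resp[e, i] / 2)
        env_al[idx] <- 10^(-al_resp[e, i] / 2)
        eidx <- idx[1] + seq_along(erp) - 1L
        eidx <- eidx[eidx <= n_samp]
        x[eidx] <- x[eidx] + erp[seq_along(eidx)]
      }
      x <- x + bb * env_bb + osc * env_al
      if (!is.null(el$line_freq) && el$line_amp > 0)
        x <- x + el$line_amp *
          sin(2 * pi * el$line_freq * (seq_len(n_samp) - 1) / fs)
      if (!is.null(el$beta_bump))
        x <- x + narrowband_noise(n_samp, fs, center = el$beta_bump[1],
                                  bw_sd = 1.5, rms = el$beta_bump[2])
      v[e, ] <- x
    }
    runs[[r]] <- v
  })
  structure(list(voltage = runs, events = ev, sample_rate = fs,
                 design = design, electrodes = electrodes, apertures = ap,
                 bb_response = bb_resp, alpha_response = al_resp),
            class = "ecog_sim")
}

#' Simulate a planar high-density grid with spatially correlated alpha
#'
#' Electrodes sit on a rows x cols grid with the given pitch.  Each
#' electrode's alpha oscillation is a weighted mixture of per-electrode
#' unit sources with weights exp(-distance / alpha_mixing_length)
#' (renormalised to preserve RMS), so mixing length 0 gives independent
#' alpha and a long mixing length gives near-identical alpha across the
#' grid.  Broadband noise is always independent per electrode.
#'
#' @param design a `prf_design`.
#' @param grid_shape c(rows, cols).
#' @param pitch centre-to-centre spacing, mm.
#' @param alpha_mixing_length spatial decay constant of alpha sharing, mm.
#' @param seed integer RNG seed.
#' @param electrodes optional list of `gt_electrode` (length rows*cols);
#'   defaults to zero-gain electrodes with a common 10 Hz alpha peak.
#' @param n_runs number of runs.
#' @param sample_rate sampling rate, Hz.
#' @return an `ecog_sim` with an extra element `positions` (electrode x 2
#'   matrix, mm).
#' @export
simulate_grid <- function(design, grid_shape = c(4, 4), pitch = 3,
                          alpha_mixing_length = 0, seed = 1,
                          electrodes = NULL, n_runs = 1, sample_rate = 512) {
  stopifnot(pitch > 0, alpha_mixing_length >= 0)
  n_el <- prod(grid_shape)
  pos <- cbind(x = rep(seq_len(grid_shape[2]) - 1, each = grid_shape[1]),
               y = rep(seq_len(grid_shape[1]) - 1, times = grid_shape[2])) * pitch
  if (is.null(electrodes))
    electrodes <- lapply(seq_len(n_el), function(i)
      gt_electrode(position = pos[i, ]))
  stopifnot(length(electrodes) == n_el)
  for (i in seq_len(n_el)) electrodes[[i]]$position <- pos[i, ]

  # spatially mixed unit-RMS alpha sources, generated up front so that
  # simulate_experiment can consume them in place of independent ones
  D <- as.matrix(stats::dist(pos))
  W <- if (alpha_mixing_length == 0) diag(n_el) else exp(-D / alpha_mixing_length)
  W <- W / sqrt(rowSums(W^2))
  n_samp <- round(run_duration(design) * sample_rate)
  alpha_signals <- with_local_seed(seed + 10^6L,
    lapply(seq_len(n_runs), function(r) {
      src <- t(vapply(seq_len(n_el), function(i)
        narrowband_noise(n_samp, sample_rate,
                         center = electrodes[[i]]$alpha_peak,
                         bw_sd = 1, rms = 1), numeric(n_samp)))
      W %*% src
    }))
  sim <- simulate_experiment(design, electrodes, n_runs = n_runs,
                             sample_rate = sample_rate, seed = seed,
                             alpha_signals = alpha_signals)
  sim$positions <- pos
  sim
}

#' Generate a synthetic electrode cohort with shared-centre DoG pRFs
#'
#' The study conditions for end-to-end validation: pRF centres drawn
#' uniformly in a disk of radius `ecc_max`, broadband sigma uniform in
#' `sigma_range`, alpha sigma a fixed multiple of broadband sigma
#' (default 2x) with the same centre, a strong broadband elevation (0.5
#' log10 units, about 3x power, at the best bar position) and a strong
#' alpha suppression (0.6 log10 units, about 75% power loss) with small
#' surrounds, over a 1/f^1.5 background.
#'
#' @param n number of electrodes.
#' @param ap an `aperture_sequence` (fixes the gain calibration grid).
#' @param seed integer RNG seed.
#' @param ecc_max maximal centre eccentricity, degrees.
#' @param sigma_range range of broadband pRF sigma, degrees.
#' @param alpha_sigma_factor alpha sigma / broadband sigma.
#' @param peak_bb peak broadband elevation, log10 power units.
#' @param peak_alpha peak alpha suppression, log10 power units.
#' @param surround surround response magnitude, log10 power units.
#' @param noise_level,alpha_rms see `gt_electrode`.
#' @return list of `gt_electrode` with an attribute `truth`: data frame of
#'   the generative parameters.
#' @export
synth_cohort <- function(n = 40, ap, seed = 1, ecc_max = 6,
                         sigma_range = c(0.8, 2), alpha_sigma_factor = 2,
                         peak_bb = 0.5, peak_alpha = 0.6, surround = 0.05,
                         noise_level = 10, alpha_rms = 10) {
  draws <- with_local_seed(seed, list(
    ecc = ecc_max * sqrt(stats::runif(n)),
    ang = stats::runif(n, 0, 2 * pi),
    sig = stats::runif(n, sigma_range[1], sigma_range[2]),
    peaks = stats::runif(n, 9, 12)))
  x <- draws$ecc * cos(draws$ang)
  y <- draws$ecc * sin(draws$ang)
  sig_bb <- draws$sig
  peaks <- draws$peaks
  els <- vector("list", n)
  for (i in seq_len(n)) {
    bb <- calibrate_dog_gains(ap, x[i], y[i], sig_bb[i],
                              peak = peak_bb, surround = surround)
    al <- calibrate_dog_gains(ap, x[i], y[i],
                              sig_bb[i] * alpha_sigma_factor,
                              peak = peak_alpha, surround = surround)
    els[[i]] <- gt_electrode(position = c((i - 1) %% 8, (i - 1) %/% 8) * 3,
                             bb_prf = bb, alpha_prf = al,
                             alpha_peak = peaks[i],
                             noise_level = noise_level,
                             alpha_rms = alpha_rms)
  }
  attr(els, "truth") <- data.frame(
    electrode = seq_len(n), x = x, y = y, sigma_bb = sig_bb,
    sigma_alpha = sig_bb * alpha_sigma_factor, alpha_peak = peaks)
  els
}
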
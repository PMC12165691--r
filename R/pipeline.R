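#' Run the full analysis pipeline on a synthetic experiment
#'
#' Chains every stage on an `ecog_sim`: common-average re-referencing,
#' epoching with baseline correction, ERP regression, noisy-epoch
#' exclusion, per-epoch Welch spectra, geometric run-averaging, blank
#' baseline, electrode-level alpha peak, per-trial spectral
#' decomposition, high-band broadband power, decimated summary time
#' courses, and DoG pRF fits with two-fold cross-validation for three
#' signal definitions: the decomposed alpha coefficient (negative-centre
#' convention), the 70-180 Hz broadband elevation (positive-centre
#' convention), and the uncorrected alpha-band power (free gains, the
#' control analysis).
#'
#' @param sim an `ecog_sim` from `simulate_experiment`.
#' @param rereference apply common-average re-referencing per run.
#' @param exclude_epochs apply inverse-Gaussian epoch exclusion.
#' @param signals subset of c("alpha", "broadband", "alpha_nocorr").
#' @param stim optional precomputed `prf_stimulus(sim$apertures)`.
#' @param decimate_factor decimation factor for the summary series.
#' @param verbose print progress messages.
#' @return list with `results` (data frame: electrode, signal, x, y,
#'   sigma, g1, g2, eccentricity, angle, r2_train, r2_cv), `fits`
#'   (nested list of `prf_fit`), `timecourses`, `spectra`
#'   (run-averaged `spectrum_set`), `baseline` (electrode x frequency),
#'   `electrode_peaks` (Hz), `excluded_epochs`.
#' @export
run_synthetic_pipeline <- function(sim, rereference = TRUE,
                                   exclude_epochs = TRUE,
                                   signals = c("alpha", "broadband",
                                               "alpha_nocorr"),
                                   stim = NULL, decimate_factor = 3,
                                   verbose = FALSE) {
  stopifnot(inherits(sim, "ecog_sim"))
  say <- function(...) if (verbose) message(...)
  fs <- sim$sample_rate
  n_runs <- length(sim$voltage)
  n_el <- length(sim$electrodes)

  say("epoching ", n_runs, " run(s)")
  spectra_runs <- vector("list", n_runs)
  blank_psd_runs <- vector("list", n_runs)
  n_excluded <- 0
  for (r in seq_len(n_runs)) {
    v <- sim$voltage[[r]]
    if (rereference && n_el > 1) v <- rereference_common_average(v)
    ep <- epoch_and_baseline_correct(v, sim$events, fs, run_id = r)
    keep <- NULL
    if (exclude_epochs && sum(!ep$events$blank) >= 20) {
      ex <- exclude_noisy_epochs(ep)
      keep <- ex$keep
      n_excluded <- n_excluded + ex$n_excluded
    }
    epr <- regress_out_erp(ep)
    sp <- trial_spectra(epr)
    if (!is.null(keep)) {
      for (e in seq_len(n_el)) sp$psd[!keep[, e], e, ] <- NA_real_
    }
    spectra_runs[[r]] <- sp
  }
  say("averaging spectra across runs")
  sp_avg <- average_across_runs(spectra_runs)
  blank <- sp_avg$events$blank
  f <- sp_avg$f

  # per-electrode blank baseline: geometric mean over blank epochs and runs
  p_b <- matrix(NA_real_, n_el, length(f))
  for (e in seq_len(n_el)) {
    logs <- do.call(rbind, lapply(spectra_runs, function(sp)
      log(sp$psd[blank, e, , drop = TRUE])))
    p_b[e, ] <- exp(colMeans(logs, na.rm = TRUE))
  }

  say("decomposing ", sum(!is.na(sp_avg$psd[, 1, 1])), " trial spectra x ",
      n_el, " electrodes")
  peaks <- numeric(n_el)
  n_trials <- dim(sp_avg$psd)[1]
  beta_alpha <- matrix(NA_real_, n_el, n_trials)
  bb_ratio <- matrix(NA_real_, n_el, n_trials)
  nocorr_ratio <- matrix(NA_real_, n_el, n_trials)
  for (e in seq_len(n_el)) {
    mean_ps <- exp(colMeans(log(sp_avg$psd[!blank, e, ]), na.rm = TRUE))
    efit <- fit_electrode_alpha_peak(mean_ps, p_b[e, ], f)
    peaks[e] <- efit$alpha_peak_hz
    for (t in seq_len(n_trials)) {
      ps <- sp_avg$psd[t, e, ]
      if (any(!is.finite(ps))) {           # fully excluded trial
        beta_alpha[e, t] <- 0
        bb_ratio[e, t] <- 1
        nocorr_ratio[e, t] <- 1
        next
      }
      dfit <- decompose_trial(ps, p_b[e, ], f, peaks[e])
      beta_alpha[e, t] <- dfit$beta_alpha
      bb_ratio[e, t] <- broadband_power(ps, p_b[e, ], f)
      nocorr_ratio[e, t] <- alpha_band_power_no_correction(
        ps, p_b[e, ], f, peaks[e])
    }
  }

  say("fitting pRFs")
  if (is.null(stim)) stim <- prf_stimulus(sim$apertures,
                                          factor = decimate_factor)
  fits <- vector("list", n_el)
  rows_list <- list()
  results <- list()
  for (e in seq_len(n_el)) {
    tc <- build_summary_time_courses(beta_alpha[e, ], bb_ratio[e, ],
                                     blank, factor = decimate_factor)
    nocorr_tc <- decimate_series(
      log10(nocorr_ratio[e, ]) -
        mean(log10(nocorr_ratio[e, ])[blank]), decimate_factor)
    series <- list(alpha = tc$alpha, broadband = tc$broadband,
                   alpha_nocorr = nocorr_tc)
    conv <- list(alpha = "negative", broadband = "positive",
                 alpha_nocorr = "free")
    fits[[e]] <- list(timecourse = tc)
    for (sg in signals) {
      fit <- fit_prf_cv(series[[sg]], stim, conv[[sg]])
      fits[[e]][[sg]] <- fit
      results[[length(results) + 1]] <- data.frame(
        electrode = e, signal = sg,
        x = fit$params["x"], y = fit$params["y"],
        sigma = fit$params["sigma"],
        g1 = fit$params["g1"], g2 = fit$params["g2"],
        eccentricity = fit$polar$eccentricity,
        angle = fit$polar$angle,
        r2_train = fit$r2_train, r2_cv = fit$r2_cv,
        alpha_peak_hz = peaks[e], row.names = NULL)
    }
  }
  list(results = do.call(rbind, results), fits = fits,
       spectra = sp_avg, baseline = p_b, f = f,
       electrode_peaks = peaks, excluded_epochs = n_excluded,
       stim = stim)
}
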
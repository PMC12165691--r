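#' Common-average re-referencing
#'
#' Subtracts, within each electrode group, the across-electrode mean at
#' every sample.  Groups mirror hardware families (standard grid,
#' high-density grid, strip, depth); a separate common average is computed
#' per group.  Idempotent.  A singleton group is left unchanged with a
#' warning.
#'
#' @param voltage electrode x sample matrix.
#' @param groups list of electrode index vectors (default: one group of
#'   all electrodes) or a factor/vector of group labels per electrode.
#' @return re-referenced voltage matrix.
#' @export
rereference_common_average <- function(voltage, groups = NULL) {
  stopifnot(is.matrix(voltage))
  if (is.null(groups)) groups <- list(seq_len(nrow(voltage)))
  if (!is.list(groups)) groups <- split(seq_along(groups), groups)
  out <- voltage
  for (g in groups) {
    if (length(g) < 2) {
      warning("singleton electrode group left unreferenced")
      next
    }
    out[g, ] <- sweep(voltage[g, , drop = FALSE], 2,
                      colMeans(voltage[g, , drop = FALSE]))
  }
  out
}

#' Estimate a clock/onset shift between two sites by ERP cross-correlation
#'
#' Finds the lag maximising the absolute cross-correlation between two
#' average evoked potentials.  A positive lag means `erp_b` is delayed
#' relative to `erp_a`.  When matrices are supplied (one ERP pair per
#' row), the point estimate uses the mean lag across pairs and a bootstrap
#' over pairs gives a confidence interval.
#'
#' @param erp_a,erp_b equal-length waveforms, or matrices with one
#'   waveform per row (paired by row).
#' @param sample_rate sampling rate, Hz.
#' @param max_lag maximal lag searched, in samples (default: half the
#'   waveform length).
#' @param n_boot bootstrap draws for the CI (matrix input only).
#' @param conf confidence level of the percentile interval.
#' @return list with `lag_ms`, `lag_samples`, `sign` (sign of the peak
#'   cross-correlation), and for matrix input `ci_ms` and `lags_ms`.
#' @export
estimate_onset_shift <- function(erp_a, erp_b, sample_rate,
                                 max_lag = NULL, n_boot = 1000,
                                 conf = 0.95) {
  one_lag <- function(a, b) {
    stopifnot(length(a) == length(b))
    if (stats::sd(a) == 0 || stats::sd(b) == 0)
      stop("flat waveform: lag undefined")
    L <- if (is.null(max_lag)) floor(length(a) / 2) else max_lag
    lags <- -L:L
    cc <- vapply(lags, function(k) {
      if (k >= 0) sum(a[1:(length(a) - k)] * b[(1 + k):length(b)])
      else sum(a[(1 - k):length(a)] * b[1:(length(b) + k)])
    }, numeric(1))
    i <- which.max(abs(cc))
    c(lag = lags[i], sign = sign(cc[i]))
  }
  if (is.matrix(erp_a)) {
    stopifnot(is.matrix(erp_b), nrow(erp_a) == nrow(erp_b))
    per_pair <- t(vapply(seq_len(nrow(erp_a)), function(i)
      one_lag(erp_a[i, ], erp_b[i, ]), c(lag = 0, sign = 0)))
    lag_samp <- mean(per_pair[, "lag"])
    boots <- vapply(seq_len(n_boot), function(b)
      mean(per_pair[sample(nrow(per_pair), replace = TRUE), "lag"]),
      numeric(1))
    a2 <- (1 - conf) / 2
    list(lag_ms = lag_samp / sample_rate * 1000,
         lag_samples = lag_samp,
         sign = sign(sum(per_pair[, "sign"])),
         ci_ms = stats::quantile(boots, c(a2, 1 - a2)) / sample_rate * 1000,
         lags_ms = per_pair[, "lag"] / sample_rate * 1000)
  } else {
    r <- one_lag(erp_a, erp_b)
    list(lag_ms = r[["lag"]] / sample_rate * 1000,
         lag_samples = r[["lag"]], sign = r[["sign"]])
  }
}

#' Epoch continuous voltage and baseline-correct
#'
#' Cuts `[-0.2, 0.8)` s epochs (a half-open window: `round(sample_rate)`
#' samples, 512 at 512 Hz) around each event onset and subtracts the mean
#' pre-stimulus (t < 0) amplitude per epoch per electrode.  Events whose
#' window falls outside the recording are dropped with a message.
#'
#' @param voltage electrode x sample matrix.
#' @param events data frame with columns onset (s), step, blank (and
#'   optionally more; carried through).
#' @param sample_rate sampling rate, Hz.
#' @param window epoch window in seconds relative to onset.
#' @param run_id identifier stored with the epochs.
#' @return object of class `voltage_epochs`: list with `data` (epoch x
#'   electrode x time array), `time` (seconds), `events`, `sample_rate`,
#'   `dropped` (indices of dropped events).
#' @export
epoch_and_baseline_correct <- function(voltage, events, sample_rate,
                                       window = c(-0.2, 0.8), run_id = 1L) {
  stopifnot(is.matrix(voltage))
  fs <- sample_rate
  n_time <- round(fs * diff(window))
  n_pre <- round(-window[1] * fs)
  # the sample at the event onset is the first post-stimulus (t = 0) sample
  start <- round(events$onset * fs) + 1L - n_pre
  ok <- start >= 1 & (start + n_time - 1L) <= ncol(voltage)
  if (any(!ok))
    message(sum(!ok), " event(s) dropped: epoch outside recording bounds")
  keep <- which(ok)
  n_el <- nrow(voltage)
  data <- array(0, dim = c(length(keep), n_el, n_time))
  for (j in seq_along(keep)) {
    idx <- start[keep[j]] + 0:(n_time - 1L)
    data[j, , ] <- voltage[, idx, drop = FALSE]
  }
  tvec <- ((0:(n_time - 1)) - n_pre) / fs
  base <- tvec < 0
  bl <- apply(data[, , base, drop = FALSE], c(1, 2), mean)
  data <- data - array(bl, dim = dim(data))
  ev <- events[keep, , drop = FALSE]
  ev$run <- run_id
  structure(list(data = data, time = tvec, events = ev,
                 sample_rate = fs, dropped = which(!ok)),
            class = "voltage_epochs")
}

#' Regress the event-related potential out of each epoch
#'
#' ERPs are computed separately for stimulus and blank epochs (per
#' electrode).  Each epoch's least-squares projection onto its matching
#' ERP is subtracted (`epoch - beta * ERP` with fitted scalar `beta`), so
#' residual power never exceeds the original power.  Set
#' `fitted_amplitude = FALSE` for plain subtraction (`beta = 1`).  A
#' zero-power ERP leaves the epochs unchanged.
#'
#' @param epochs a `voltage_epochs`.
#' @param fitted_amplitude fit the ERP amplitude per epoch (default) or
#'   subtract the ERP as is.
#' @return a `voltage_epochs` of residuals, with the ERPs in the `erps`
#'   element (list of electrode x time matrices `stimulus`, `blank`).
#' @export
regress_out_erp <- function(epochs, fitted_amplitude = TRUE) {
  stopifnot(inherits(epochs, "voltage_epochs"))
  blank <- epochs$events$blank
  if (sum(!blank) < 2 || sum(blank) < 2)
    stop("need at least 2 stimulus and 2 blank epochs")
  d <- epochs$data
  n_el <- dim(d)[2]
  erp_s <- apply(d[!blank, , , drop = FALSE], c(2, 3), mean)
  erp_b <- apply(d[blank, , , drop = FALSE], c(2, 3), mean)
  for (e in seq_len(n_el)) {
    for (cls in list(list(idx = which(!blank), erp = erp_s[e, ]),
                     list(idx = which(blank), erp = erp_b[e, ]))) {
      pw <- sum(cls$erp^2)
      if (pw == 0) next
      seg <- d[cls$idx, e, , drop = FALSE]
      beta <- if (fitted_amplitude) {
        as.numeric(matrix(seg, length(cls$idx), length(cls$erp)) %*%
                     cls$erp) / pw
      } else rep(1, length(cls$idx))
      d[cls$idx, e, ] <- seg - array(outer(beta, cls$erp),
                                     dim = dim(seg))
    }
  }
  out <- epochs
  out$data <- d
  out$erps <- list(stimulus = erp_s, blank = erp_b)
  out
}

#' Exclude epochs with outlier evoked power
#'
#' Per electrode: the maximum of squared voltage over the stimulus period
#' (0-500 ms) is taken for every non-blank epoch and an inverse-Gaussian
#' distribution is fitted to these maxima by closed-form maximum
#' likelihood.  The ERP is then regressed out, and any epoch whose
#' residual maximum power falls above the (1 - tail_prob) quantile of the
#' fitted distribution is excluded.  (The fit uses pre-removal maxima and
#' the test uses post-removal maxima; this asymmetry is intentional.)
#'
#' @param epochs a `voltage_epochs` (before ERP removal).
#' @param tail_prob upper-tail probability defining the exclusion
#'   threshold (default 1e-4, the upper 0.01% of the area under the curve).
#' @param stim_window seconds over which the maximum is taken.
#' @return list with `keep` (epoch x electrode logical matrix; blank
#'   epochs always TRUE), `params` (data frame with mu, lambda, threshold
#'   per electrode), `n_excluded`.
#' @export
exclude_noisy_epochs <- function(epochs, tail_prob = 1e-4,
                                 stim_window = c(0, 0.5)) {
  stopifnot(inherits(epochs, "voltage_epochs"))
  blank <- epochs$events$blank
  if (sum(!blank) < 20) stop("need at least 20 non-blank epochs")
  tsel <- epochs$time >= stim_window[1] & epochs$time < stim_window[2]
  n_el <- dim(epochs$data)[2]
  resid <- regress_out_erp(epochs)
  keep <- matrix(TRUE, dim(epochs$data)[1], n_el)
  params <- data.frame(electrode = seq_len(n_el), mu = NA_real_,
                       lambda = NA_real_, threshold = NA_real_)
  for (e in seq_len(n_el)) {
    mx <- apply(epochs$data[!blank, e, tsel]^2, 1, max)
    if (stats::sd(mx) == 0) {
      warning("zero-variance epoch maxima; no exclusions for electrode ", e)
      next
    }
    fit <- fit_invgauss(mx)
    thr <- qinvgauss(1 - tail_prob, fit$mu, fit$lambda)
    mx_res <- apply(resid$data[!blank, e, tsel]^2, 1, max)
    keep[which(!blank)[mx_res > thr], e] <- FALSE
    params$mu[e] <- fit$mu
    params$lambda[e] <- fit$lambda
    params$threshold[e] <- thr
  }
  list(keep = keep, params = params, n_excluded = sum(!keep))
}

#' Flag electrodes with unusually high trial variance
#'
#' An electrode is flagged when its across-trial variance exceeds the
#' across-electrode mean by more than three standard deviations.  Flags
#' are invariant to a common rescaling of all variances (z-scores are
#' unchanged by affine scaling).
#'
#' @param trial_variance numeric vector, one variance per electrode.
#' @param n_sd threshold in across-electrode standard deviations.
#' @return logical vector, TRUE = flagged.
#' @export
flag_high_variance_electrodes <- function(trial_variance, n_sd = 3) {
  if (length(trial_variance) < 4) stop("need at least 4 electrodes")
  s <- stats::sd(trial_variance)
  if (s == 0) return(rep(FALSE, length(trial_variance)))
  trial_variance > mean(trial_variance) + n_sd * s
}
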
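test_that("common-average re-referencing zeroes the group mean", {
  set.seed(1)
  v <- matrix(rnorm(4 * 100), 4, 100)
  out <- rereference_common_average(v)
  expect_lt(max(abs(colMeans(out))), 1e-12)
  # idempotent
  expect_equal(rereference_common_average(out), out)
  # +v / -v pair already has zero mean
  p <- rbind(v[1, ], -v[1, ])
  expect_equal(rereference_common_average(p), p)
  # shared offset removed
  vo <- v + 5
  expect_equal(rereference_common_average(vo), rereference_common_average(v))
  # groups are referenced separately; singletons warn
  out2 <- rereference_common_average(v, groups = list(1:2, 3:4))
  expect_lt(max(abs(colMeans(out2[1:2, ]))), 1e-12)
  expect_lt(max(abs(colMeans(out2[3:4, ]))), 1e-12)
  expect_warning(rereference_common_average(v, groups = list(1, 2:4)),
                 "singleton")
})

test_that("onset shift recovers constructed lags", {
  fs <- 512
  t <- (0:511) / fs
  a <- sin(2 * pi * 7 * t) * exp(-t / 0.2)
  shift <- round(0.072 * fs)              # 72 ms
  b <- c(numeric(shift), a[1:(length(a) - shift)])
  r <- estimate_onset_shift(a, b, fs)
  expect_lte(abs(r$lag_samples - shift), 1)
  expect_lt(abs(r$lag_ms - 72), 2.5)     # within ~1 sample of 72 ms
  # identical waveforms: zero lag
  expect_equal(estimate_onset_shift(a, a, fs)$lag_ms, 0)
  # sign-flipped and delayed: |xcorr| peak at the delay, negative sign
  b2 <- -c(numeric(10), a[1:(length(a) - 10)])
  r2 <- estimate_onset_shift(a, b2, fs)
  expect_equal(r2$lag_samples, 10)
  expect_equal(r2$sign, -1)
  expect_error(estimate_onset_shift(rep(0, 100), a[1:100], fs), "flat")
})

test_that("onset shift bootstrap CI brackets a common lag", {
  fs <- 512
  set.seed(2)
  n_pairs <- 12
  A <- t(replicate(n_pairs, {
    t <- (0:511) / fs
    sin(2 * pi * 7 * t) * exp(-t / 0.2) + rnorm(512, 0, 0.05)
  }))
  shift <- 37
  B <- cbind(matrix(0, n_pairs, shift), A[, 1:(512 - shift)]) +
    matrix(rnorm(n_pairs * 512, 0, 0.05), n_pairs)
  r <- estimate_onset_shift(A, B, fs, n_boot = 300)
  expect_lt(abs(r$lag_samples - shift), 3)
  expect_true(r$ci_ms[1] <= shift / fs * 1000 + 2 &&
                r$ci_ms[2] >= shift / fs * 1000 - 2)
})

test_that("epoching window, baseline and bounds behave as specified", {
  fs <- 512
  ev <- data.frame(onset = c(1, 2, 3), step = 1:3,
                   blank = c(FALSE, FALSE, TRUE))
  # constant signal -> all-zero epochs after baseline correction
  v <- matrix(7, 1, 4 * fs)
  ep <- epoch_and_baseline_correct(v, ev, fs)
  expect_equal(dim(ep$data), c(3, 1, 512))
  expect_true(all(ep$data == 0))
  expect_true(all(ep$time >= -0.2 & ep$time < 0.8))
  # step function rising at the second onset
  v2 <- matrix(0, 1, 4 * fs)
  v2[1, (2 * fs + 1):(4 * fs)] <- 3
  ep2 <- epoch_and_baseline_correct(v2, ev, fs)
  pre <- ep2$time < 0
  expect_equal(mean(ep2$data[2, 1, pre]), 0)
  expect_equal(mean(ep2$data[2, 1, ep2$time >= 0.1]), 3, tolerance = 1e-9)
  # event too close to the edge is dropped
  ev3 <- rbind(ev, data.frame(onset = 3.9, step = 4, blank = FALSE))
  expect_message(ep3 <- epoch_and_baseline_correct(v, ev3, fs), "dropped")
  expect_equal(dim(ep3$data)[1], 3)
})

test_that("a full synthetic run epochs into 224 x 512-sample trials", {
  d <- short_design()
  full <- prf_design(grid_resolution = 30)
  sim <- cached("sim1el", simulate_experiment(
    full, list(gt_electrode()), n_runs = 1, seed = 5))
  ep <- epoch_and_baseline_correct(sim$voltage[[1]], sim$events, 512)
  expect_equal(dim(ep$data), c(224, 1, 512))
})

test_that("ERP regression projects out the evoked component", {
  fs <- 512
  tvec <- -0.2 + (0:511) / fs
  w <- sin(2 * pi * 5 * pmax(tvec, 0)) * exp(-pmax(tvec, 0) / 0.15)
  # stimulus epochs: scaled copies of one waveform plus a pair whose mean
  # preserves the waveform while one member is orthogonal to it
  set.seed(3)
  orth <- cos(2 * pi * 40 * tvec)
  orth <- orth - sum(orth * w) / sum(w^2) * w
  n_blank <- 20
  data <- array(0, dim = c(4 + n_blank, 1, 512))
  data[1, 1, ] <- 0.5 * w
  data[2, 1, ] <- 1.5 * w
  data[3, 1, ] <- orth            # orthogonal to the ERP
  data[4, 1, ] <- 2 * w - orth    # keeps the stimulus ERP equal to w
  for (i in 5:(4 + n_blank)) data[i, 1, ] <- rnorm(512, 0, 0.1)
  ep <- structure(list(
    data = data, time = tvec,
    events = data.frame(onset = seq_len(4 + n_blank),
                        step = seq_len(4 + n_blank),
                        blank = c(rep(FALSE, 4), rep(TRUE, n_blank))),
    sample_rate = fs), class = "voltage_epochs")
  res <- regress_out_erp(ep)
  # the stimulus ERP is w itself, so epochs proportional to it vanish
  expect_equal(res$erps$stimulus[1, ], w, tolerance = 1e-12)
  expect_lt(max(abs(res$data[1:2, 1, ])), 1e-10)
  # the epoch orthogonal to the ERP is unchanged
  expect_equal(res$data[3, 1, ], orth, tolerance = 1e-8)
  # blank epochs with no evoked component are nearly untouched (their
  # ERP averages many noise epochs and is close to zero)
  expect_gt(stats::cor(ep$data[5, 1, ], res$data[5, 1, ]), 0.9)
})

test_that("ERP regression never increases epoch power", {
  set.seed(4)
  data <- array(rnorm(30 * 2 * 512), dim = c(30, 2, 512))
  data[1:20, 1, ] <- data[1:20, 1, ] +
    outer(runif(20, 0.5, 2), sin(2 * pi * 6 * (0:511) / 512))
  ep <- structure(list(
    data = data, time = -0.2 + (0:511) / 512,
    events = data.frame(onset = 1:30, step = 1:30,
                        blank = rep(c(FALSE, TRUE), c(20, 10))),
    sample_rate = 512), class = "voltage_epochs")
  res <- regress_out_erp(ep)
  p0 <- apply(ep$data^2, c(1, 2), sum)
  p1 <- apply(res$data^2, c(1, 2), sum)
  expect_true(all(p1 <= p0 + 1e-9))
})

test_that("inverse-Gaussian epoch screening excludes planted outliers only", {
  fs <- 512
  set.seed(6)
  n_ep <- 500
  data <- array(rnorm(n_ep * 1 * 512, 0, 1), dim = c(n_ep, 1, 512))
  outlier <- 123
  # a 100x power (10x amplitude) artifact within the stimulus window
  data[outlier, 1, 200:300] <- 10 * data[outlier, 1, 200:300]
  ep <- structure(list(
    data = data, time = -0.2 + (0:511) / fs,
    events = data.frame(onset = seq_len(n_ep), step = seq_len(n_ep),
                        blank = rep(c(FALSE, TRUE), c(450, 50))),
    sample_rate = fs), class = "voltage_epochs")
  ex <- exclude_noisy_epochs(ep)
  expect_false(ex$keep[outlier, 1])
  # homogeneous noise: expected false positives << 1 at tail_prob 1e-4
  expect_lte(ex$n_excluded, 2)
  # threshold equals the analytic quantile of the fitted distribution
  expect_equal(ex$params$threshold[1],
               qinvgauss(1 - 1e-4, ex$params$mu[1], ex$params$lambda[1]))
})

test_that("inverse-Gaussian quantile inverts the CDF (numeric oracle)", {
  for (par in list(c(2, 5), c(0.5, 0.1), c(10, 50))) {
    q <- qinvgauss(c(0.5, 0.99, 0.9999), par[1], par[2])
    # oracle: numerical integration of the density
    p <- vapply(q, function(qq)
      stats::integrate(dinvgauss, 0, qq, mu = par[1], lambda = par[2],
                       rel.tol = 1e-10)$value, numeric(1))
    expect_equal(p, c(0.5, 0.99, 0.9999), tolerance = 1e-6)
  }
  # closed-form ML fit matches moments on a large sample
  set.seed(7)
  x <- exp(rnorm(5000, 0, 0.4))          # positive, skewed
  fit <- fit_invgauss(x)
  expect_equal(fit$mu, mean(x))
})

test_that("high-variance electrode flagging uses the 3-SD rule", {
  v <- rep(1, 50)
  expect_false(any(flag_high_variance_electrodes(v)))
  v[7] <- 10
  flags <- flag_high_variance_electrodes(v)
  expect_true(flags[7])
  expect_equal(sum(flags), 1)
  # invariant to common scaling (z-scores unchanged)
  expect_equal(flag_high_variance_electrodes(v * 1e6), flags)
  expect_error(flag_high_variance_electrodes(c(1, 2, 3)), "4 electrodes")
})
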
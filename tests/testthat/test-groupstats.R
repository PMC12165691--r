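# small synthetic cohort of series + predictions for null-threshold tests
make_fit_cohort <- function(n = 12, noise = 0.05, seed = 41) {
  stim <- test_stim()
  set.seed(seed)
  truths <- lapply(seq_len(n), function(i)
    c(x = runif(1, -5, 5), y = runif(1, -5, 5),
      sigma = runif(1, 0.8, 2.5), g1 = 0.005, g2 = 1e-5))
  series <- sapply(truths, function(tr)
    dog_series(tr) + rnorm(stim$n_dec, 0, noise * 0.005 * 50))
  preds <- sapply(seq_len(n), function(i)
    fit_prf(series[, i], stim, "positive")$pred)
  list(series = series, preds = preds, truths = truths, stim = stim)
}

test_that("shuffle-null thresholds separate matched from mismatched pRFs", {
  co <- cached("fit_cohort", make_fit_cohort())
  out <- shuffle_null_threshold(co$series, co$preds, n_shuffles = 300,
                                seed = 1)
  real_r2 <- vapply(seq_len(ncol(co$series)), function(i)
    uncentered_r2(co$preds[, i], co$series[, i]), numeric(1))
  # heterogeneous pRFs: null far below matched accuracy
  expect_lt(out$threshold, min(real_r2))
  expect_lt(median(out$null_r2), 0.5)
  # deterministic under a fixed seed
  out2 <- shuffle_null_threshold(co$series, co$preds, n_shuffles = 300,
                                 seed = 1)
  expect_identical(out$threshold, out2$threshold)
  # exchangeable case: identical series/predictions give null ~ real
  S <- co$series[, rep(1, 10)]
  P <- co$preds[, rep(1, 10)]
  out3 <- shuffle_null_threshold(S, P, n_shuffles = 100, seed = 2)
  expect_equal(out3$threshold, uncentered_r2(P[, 1], S[, 1]),
               tolerance = 1e-9)
})

test_that("electrode selection applies strict thresholds and extent", {
  rec <- data.frame(
    r2_cv_bb = c(0.6, 0.6, 0.25, 0.6, NA),
    r2_cv_alpha = c(0.5, 0.5, 0.5, 0.22, 0.5),
    ecc_bb = c(2, 9, 2, 2, 2),
    ecc_alpha = c(3, 3, 3, 3, 3))
  thr <- c(broadband = 0.31, alpha = 0.22)
  out <- select_electrodes(rec, thr)
  expect_equal(out$keep, c(TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_equal(out$reason[2], "eccentricity")
  expect_equal(out$reason[3], "broadband accuracy")
  expect_equal(out$reason[4], "alpha accuracy")  # exactly at threshold
  expect_equal(out$reason[5], "missing fit")
  # monotone: raising thresholds never adds electrodes
  out_hi <- select_electrodes(rec, c(broadband = 0.5, alpha = 0.4))
  expect_true(all(out$keep | !out_hi$keep))
})

test_that("pair normalisation puts the broadband centre at (0, 1)", {
  set.seed(42)
  for (i in 1:10) {
    bb <- c(x = runif(1, -5, 5), y = runif(1, -5, 5),
            sigma = runif(1, 0.5, 3))
    if (sqrt(bb[1]^2 + bb[2]^2) < 0.1) next
    al <- c(x = bb[1] + rnorm(1, 0, 0.5), y = bb[2] + rnorm(1, 0, 0.5),
            sigma = 2 * bb[3])
    nm <- normalize_prf_pair(bb, al)
    expect_equal(unname(nm$bb[c("x", "y")]), c(0, 1), tolerance = 1e-12)
    # rotation+scaling preserves the centre distance / bb eccentricity
    ecc <- sqrt(bb[1]^2 + bb[2]^2)
    d0 <- unname(sqrt(sum((bb[1:2] - al[1:2])^2)) / ecc)
    d1 <- unname(sqrt(sum((nm$bb[1:2] - nm$alpha[1:2])^2)))
    expect_equal(d1, d0, tolerance = 1e-12)
  }
  # alpha == bb lands on (0, 1) too, with the size ratio preserved
  bb <- c(x = 3, y = 4, sigma = 1)
  nm <- normalize_prf_pair(bb, bb)
  expect_equal(unname(nm$alpha[c("x", "y")]), c(0, 1), tolerance = 1e-12)
  expect_equal(nm$alpha[["sigma"]] / nm$bb[["sigma"]], 1)
  expect_error(normalize_prf_pair(c(0, 0, 1), bb), "zero")
})

test_that("pRF overlap matches geometry and a Monte-Carlo oracle", {
  a <- c(x = 0, y = 0, sigma = 1)
  expect_equal(prf_overlap_percent(a, a), 100)
  far <- c(x = 5, y = 0, sigma = 1)
  expect_equal(prf_overlap_percent(a, far), 0)
  # lens case: inner r=1 at origin, outer r=2 at (0, 0.5)
  outer_prf <- c(x = 0, y = 0.5, sigma = 2)
  got <- prf_overlap_percent(a, outer_prf)
  set.seed(43)
  pts <- matrix(runif(2e6, -1, 1), ncol = 2)
  pts <- pts[rowSums(pts^2) <= 1, ]           # uniform in the inner disk
  inside <- (pts[, 1] - 0)^2 + (pts[, 2] - 0.5)^2 <= 4
  expect_equal(got, 100 * mean(inside), tolerance = 0.1)
  # containment case
  expect_equal(prf_overlap_percent(a, c(x = 0, y = 0, sigma = 3)), 100)
})

test_that("shuffled pairing collapses overlap for scattered cohorts", {
  # co-centred pairs scattered across the field
  set.seed(44)
  n <- 10
  bb <- cbind(x = runif(n, -6, 6), y = runif(n, -6, 6),
              sigma = runif(n, 0.5, 1))
  al <- bb; al[, "sigma"] <- 2 * bb[, "sigma"]
  matched <- mean(vapply(seq_len(n), function(i)
    prf_overlap_percent(bb[i, ], al[i, ]), numeric(1)))
  ctrl <- shuffled_overlap_control(bb, al, n_shuffles = 200, seed = 3)
  expect_equal(matched, 100)
  expect_lt(ctrl$mean_overlap, matched / 2)
  # identical electrodes: shuffling changes nothing
  bb1 <- bb[rep(1, 5), ]; al1 <- al[rep(1, 5), ]
  ctrl1 <- shuffled_overlap_control(bb1, al1, n_shuffles = 20, seed = 4)
  expect_equal(ctrl1$mean_overlap,
               prf_overlap_percent(bb1[1, ], al1[1, ]))
  # two records: the only derangement is the swap
  ctrl2 <- shuffled_overlap_control(bb[1:2, ], al[1:2, ],
                                    n_shuffles = 5, seed = 5)
  swap <- mean(c(prf_overlap_percent(bb[1, ], al[2, ]),
                 prf_overlap_percent(bb[2, ], al[1, ])))
  expect_equal(ctrl2$mean_overlap, swap)
})

test_that("circular correlation and the 68% ellipse behave correctly", {
  ang <- runif(20, 0, 360)
  expect_equal(circ_corr(ang, ang), 1)
  # wrap-around: adding 360 changes nothing
  expect_equal(circ_corr(ang, ang + 360), 1)
  set.seed(45)
  xy <- MASS::mvrnorm(4000, c(1, 2),
                      matrix(c(1, 0.6, 0.6, 2), 2))
  el <- covariance_ellipse_68(xy)
  # ~68% of samples fall inside the ellipse (Mahalanobis check)
  m <- stats::mahalanobis(xy, el$center, el$cov)
  expect_equal(mean(m <= stats::qchisq(0.68, 2)), 0.68, tolerance = 0.03)
})

test_that("probabilistic area bootstrap reduces to known cases", {
  set.seed(46)
  n <- 30
  rec <- data.frame(
    angle_bb = runif(n, 0, 360), ecc_bb = runif(n, 1, 6),
    size_bb = runif(n, 0.5, 2))
  rec$angle_alpha <- rec$angle_bb
  rec$ecc_alpha <- rec$ecc_bb * 1.1
  rec$size_alpha <- rec$size_bb * 2
  # degenerate probabilities: everything lands in one area every draw
  probs <- matrix(c(1, 0), n, 2, byrow = TRUE,
                  dimnames = list(NULL, c("V1-V3", "dorsolateral")))
  out <- bootstrap_area_comparison(rec, probs, n_boot = 60, seed = 6)
  expect_equal(nrow(out$per_group[["V1-V3"]]), 60)
  expect_null(out$per_group[["dorsolateral"]])
  expect_equal(mean(out$per_group[["V1-V3"]]$n), n, tolerance = 1e-9)
  # identical angles across signals: circular correlation 1
  expect_equal(out$correlations[["V1-V3"]]$angle, 1, tolerance = 1e-9)
  # 50/50 probabilities: mean group size ~ n/2 within a few binomial SDs
  probs2 <- matrix(0.5, n, 2,
                   dimnames = list(NULL, c("V1-V3", "dorsolateral")))
  out2 <- bootstrap_area_comparison(rec, probs2, n_boot = 120, seed = 7)
  expect_equal(mean(out2$per_group[["V1-V3"]]$n), n / 2,
               tolerance = 3 * sqrt(n * 0.25) / sqrt(120) * 3 + 0.5)
})

test_that("size-eccentricity regression recovers slopes and bands", {
  # exact line: slope recovered with a zero-width band
  ecc <- seq(1, 8, length.out = 12)
  size <- 0.5 + 0.3 * ecc
  out <- size_eccentricity_regression(ecc, size, n_boot = 50, seed = 8)
  expect_equal(out$slope, 0.3, tolerance = 1e-9)
  expect_lt(max(out$band[2, ] - out$band[1, ]), 1e-9)
  # alpha slope 3x broadband slope, 20% noise: ratio lands in [2, 4]
  set.seed(48)
  n <- 50
  e2 <- runif(n, 1, 8)
  s_bb <- (0.2 + 0.15 * e2) * (1 + rnorm(n, 0, 0.2))
  s_al <- (0.2 + 0.45 * e2) * (1 + rnorm(n, 0, 0.2))
  sl_bb <- size_eccentricity_regression(e2, s_bb, n_boot = 200, seed = 9)
  sl_al <- size_eccentricity_regression(e2, s_al, n_boot = 200, seed = 9)
  expect_gt(sl_al$slope / sl_bb$slope, 2)
  expect_lt(sl_al$slope / sl_bb$slope, 4)
  # slope invariant to the ordering of points
  perm <- sample(length(ecc))
  out_p <- size_eccentricity_regression(ecc[perm], size[perm],
                                        n_boot = 50, seed = 8)
  expect_equal(out_p$slope, out$slope, tolerance = 1e-9)
})
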
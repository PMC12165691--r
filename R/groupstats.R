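#' Shuffle-null threshold for pRF model accuracy
#'
#' Builds a null distribution of model accuracy by scoring each
#' electrode's time series against the pRF model prediction of a
#' different electrode (no refitting), and returns the stated percentile
#' of the pooled null R^2 values.  Electrodes whose real cross-validated
#' accuracy exceeds this threshold are considered to have reliable pRFs.
#'
#' @param series time-point x electrode matrix of observed summary series.
#' @param predictions time-point x electrode matrix of fitted model
#'   predictions (same order).
#' @param n_shuffles number of shuffles.
#' @param percentile percentile of the null distribution (95).
#' @param seed integer RNG seed.
#' @return list with `threshold` (as a fraction), `null_r2` (pooled null
#'   values).
#' @export
shuffle_null_threshold <- function(series, predictions, n_shuffles = 5000,
                                   percentile = 95, seed = 1) {
  stopifnot(ncol(series) == ncol(predictions),
            nrow(series) == nrow(predictions))
  n <- ncol(series)
  if (n < 10) stop("need at least 10 electrodes for a shuffle null")
  # R^2 of electrode j's prediction against electrode i's series, i != j
  r2 <- matrix(NA_real_, n, n)
  denom <- colSums(series^2)
  for (j in seq_len(n)) {
    res <- series - predictions[, j]
    r2[, j] <- 1 - colSums(res^2) / denom
  }
  null_r2 <- numeric(n_shuffles * n)
  with_local_seed(seed, {
    idx <- 1L
    for (s in seq_len(n_shuffles)) {
      partner <- vapply(seq_len(n), function(i)
        sample(setdiff(seq_len(n), i), 1L), integer(1))
      null_r2[idx:(idx + n - 1L)] <- r2[cbind(seq_len(n), partner)]
      idx <- idx + n
    }
  })
  list(threshold = unname(stats::quantile(null_r2, percentile / 100)),
       null_r2 = null_r2)
}

#' Select electrodes for the alpha/broadband pRF comparison
#'
#' Keeps electrodes whose cross-validated accuracy strictly exceeds the
#' per-signal thresholds for both broadband and alpha and whose fitted
#' pRF centres lie within the maximal stimulus extent for both signals.
#' Accuracy exactly at a threshold is excluded (strict inequality).
#'
#' @param records data frame with columns `r2_cv_bb`, `r2_cv_alpha`,
#'   `ecc_bb`, `ecc_alpha` (NA = missing fit).
#' @param thresholds list or vector with `broadband` and `alpha` R^2
#'   thresholds (fractions).
#' @param ecc_limit maximal pRF centre eccentricity, degrees (8.3).
#' @return list with `keep` (logical) and `reason` (character, "" when
#'   kept).
#' @export
select_electrodes <- function(records, thresholds, ecc_limit = 8.3) {
  thr_bb <- thresholds[["broadband"]]
  thr_al <- thresholds[["alpha"]]
  n <- nrow(records)
  keep <- rep(TRUE, n)
  reason <- rep("", n)
  for (i in seq_len(n)) {
    r <- records[i, ]
    if (any(is.na(c(r$r2_cv_bb, r$r2_cv_alpha, r$ecc_bb, r$ecc_alpha)))) {
      keep[i] <- FALSE; reason[i] <- "missing fit"; next
    }
    if (!(r$r2_cv_bb > thr_bb)) {
      keep[i] <- FALSE; reason[i] <- "broadband accuracy"; next
    }
    if (!(r$r2_cv_alpha > thr_al)) {
      keep[i] <- FALSE; reason[i] <- "alpha accuracy"; next
    }
    if (r$ecc_bb > ecc_limit || r$ecc_alpha > ecc_limit) {
      keep[i] <- FALSE; reason[i] <- "eccentricity"; next
    }
  }
  list(keep = keep, reason = reason)
}

#' Normalise an alpha/broadband pRF pair to the broadband centre
#'
#' Rotates both pRFs by minus the broadband polar angle and divides both
#' eccentricities and both sizes by the broadband eccentricity, which
#' places the broadband centre at (0, 1) exactly.  Undefined when the
#' broadband eccentricity is 0.
#'
#' @param bb,alpha vectors/lists with x, y, sigma.
#' @return list with `bb` and `alpha`, each c(x, y, sigma) normalised.
#' @export
normalize_prf_pair <- function(bb, alpha) {
  bb <- unlist(bb)[1:3]; alpha <- unlist(alpha)[1:3]
  ecc <- sqrt(bb[1]^2 + bb[2]^2)
  if (ecc == 0) stop("broadband eccentricity is zero: normalisation undefined")
  # rotate so the broadband centre lands on the positive y axis
  theta <- pi / 2 - atan2(bb[2], bb[1])
  rot <- function(p) c(cos(theta) * p[1] - sin(theta) * p[2],
                       sin(theta) * p[1] + cos(theta) * p[2])
  b2 <- rot(bb[1:2]) / ecc
  a2 <- rot(alpha[1:2]) / ecc
  list(bb = c(x = unname(b2[1]), y = unname(b2[2]),
              sigma = unname(bb[3] / ecc)),
       alpha = c(x = unname(a2[1]), y = unname(a2[2]),
                 sigma = unname(alpha[3] / ecc)))
}

#' Percent overlap of two pRFs truncated at one sigma
#'
#' Treats each pRF as a disk of radius `truncation x sigma` and returns
#' the exact circle-circle intersection (lens) area as a percentage of
#' the inner disk's area.
#'
#' @param inner,outer vectors/lists with x, y, sigma.
#' @param truncation disk radius in units of sigma.
#' @return percent of the inner disk contained in the outer disk.
#' @export
prf_overlap_percent <- function(inner, outer, truncation = 1) {
  inner <- unname(unlist(inner)[1:3]); outer <- unname(unlist(outer)[1:3])
  r1 <- truncation * inner[3]
  r2 <- truncation * outer[3]
  stopifnot(r1 > 0, r2 > 0)
  d <- sqrt((inner[1] - outer[1])^2 + (inner[2] - outer[2])^2)
  if (d >= r1 + r2) return(0)
  if (d <= abs(r2 - r1)) {
    lens <- pi * min(r1, r2)^2
  } else {
    a1 <- r1^2 * acos((d^2 + r1^2 - r2^2) / (2 * d * r1))
    a2 <- r2^2 * acos((d^2 + r2^2 - r1^2) / (2 * d * r2))
    tri <- 0.5 * sqrt((-d + r1 + r2) * (d + r1 - r2) *
                        (d - r1 + r2) * (d + r1 + r2))
    lens <- a1 + a2 - tri
  }
  100 * lens / (pi * r1^2)
}

# random permutation with no fixed points (derangement by rejection;
# for n = 2 the swap is the only derangement)
.derangement <- function(n) {
  if (n < 2) stop("derangement needs n >= 2")
  repeat {
    p <- sample(n)
    if (!any(p == seq_len(n))) return(p)
  }
}

#' Mean pRF overlap under shuffled alpha/broadband pairing
#'
#' Recomputes the alpha-in-broadband overlap after randomly re-pairing
#' alpha pRFs with broadband pRFs from other electrodes (derangements,
#' so the identity pairing never occurs) and averages across shuffles.
#'
#' @param bb,alpha data frames / matrices with columns x, y, sigma (one
#'   row per electrode, paired by row).
#' @param n_shuffles number of random re-pairings.
#' @param seed integer RNG seed.
#' @param truncation disk radius in sigmas.
#' @return list with `mean_overlap` (percent), `per_shuffle` means.
#' @export
shuffled_overlap_control <- function(bb, alpha, n_shuffles = 1000,
                                     seed = 1, truncation = 1) {
  bb <- as.matrix(bb); alpha <- as.matrix(alpha)
  n <- nrow(bb)
  if (n < 2) stop("need at least 2 records")
  per <- with_local_seed(seed, vapply(seq_len(n_shuffles), function(s) {
    p <- .derangement(n)
    mean(vapply(seq_len(n), function(i)
      prf_overlap_percent(bb[i, ], alpha[p[i], ], truncation), numeric(1)))
  }, numeric(1)))
  list(mean_overlap = mean(per), per_shuffle = per)
}

#' Circular (Fisher-Lee) correlation of two angle vectors
#' @param a,b angles in degrees.
#' @return correlation in [-1, 1].
#' @export
circ_corr <- function(a, b) {
  a <- a * pi / 180; b <- b * pi / 180
  num <- sum(sin(a - mean_angle(a)) * sin(b - mean_angle(b)))
  den <- sqrt(sum(sin(a - mean_angle(a))^2) * sum(sin(b - mean_angle(b))^2))
  if (den == 0) return(NA_real_)
  num / den
}

mean_angle <- function(x) atan2(mean(sin(x)), mean(cos(x)))

#' 68% covariance ellipse of a bivariate sample
#'
#' Chi-square(2)-scaled sample covariance: the returned ellipse contains
#' 68% of the probability mass of the fitted bivariate normal.
#'
#' @param xy n x 2 matrix.
#' @param n_points points on the returned outline.
#' @return list with `center`, `cov`, `outline` (n_points x 2).
#' @export
covariance_ellipse_68 <- function(xy, n_points = 100) {
  xy <- as.matrix(xy)
  ctr <- colMeans(xy)
  S <- stats::cov(xy)
  sc <- stats::qchisq(0.68, df = 2)
  eg <- eigen(S)
  t <- seq(0, 2 * pi, length.out = n_points)
  circ <- rbind(cos(t), sin(t))
  pts <- t(eg$vectors %*% (sqrt(sc * pmax(eg$values, 0)) * circ)) +
    matrix(ctr, n_points, 2, byrow = TRUE)
  list(center = ctr, cov = S, outline = pts)
}

#' Bootstrap comparison of pRF parameters with probabilistic area labels
#'
#' Resamples electrodes with replacement and, within each draw, assigns
#' every sampled electrode to a visual-area group at random according to
#' its area probability vector (probabilities may sum to < 1; the
#' remainder is "none").  Per draw and group, circular means of polar
#' angles and plain means of eccentricity and size are accumulated for
#' both signals; angle differences are wrapped to (-180, 180].
#'
#' @param records data frame with columns `angle_bb`, `ecc_bb`,
#'   `size_bb`, `angle_alpha`, `ecc_alpha`, `size_alpha`.
#' @param area_probs electrode x group matrix of assignment
#'   probabilities (row sums <= 1), with column names naming the groups.
#' @param n_boot bootstrap draws.
#' @param seed integer RNG seed.
#' @return list with `per_group` (named list of data frames, one row per
#'   bootstrap draw in which the group was non-empty), `ellipses`
#'   (68% covariance ellipses of the (bb, alpha) eccentricity pairs per
#'   group), and `correlations` (circular correlation of angles, Pearson
#'   correlations of eccentricity and size per group).
#' @export
bootstrap_area_comparison <- function(records, area_probs, n_boot = 5000,
                                      seed = 1) {
  stopifnot(nrow(records) == nrow(area_probs))
  if (any(rowSums(area_probs) > 1 + 1e-9))
    stop("area probabilities must sum to at most 1 per electrode")
  groups <- colnames(area_probs)
  n <- nrow(records)
  acc <- stats::setNames(
    replicate(length(groups), list(), simplify = FALSE), groups)
  labels_all <- c(groups, "none")
  with_local_seed(seed, for (b in seq_len(n_boot)) {
    take <- sample(n, n, replace = TRUE)
    lab <- vapply(take, function(i) {
      p <- c(area_probs[i, ], 1 - sum(area_probs[i, ]))
      sample(labels_all, 1, prob = pmax(p, 0))
    }, character(1))
    for (g in groups) {
      sel <- take[lab == g]
      if (length(sel) == 0) next
      r <- records[sel, , drop = FALSE]
      wrap <- ((r$angle_alpha - r$angle_bb + 180) %% 360) - 180
      acc[[g]][[b]] <- data.frame(
        boot = b, n = length(sel),
        angle_bb = mean_angle(r$angle_bb * pi / 180) * 180 / pi,
        angle_alpha = mean_angle(r$angle_alpha * pi / 180) * 180 / pi,
        angle_diff = mean(wrap),
        ecc_bb = mean(r$ecc_bb), ecc_alpha = mean(r$ecc_alpha),
        size_bb = mean(r$size_bb), size_alpha = mean(r$size_alpha))
    }
  })
  per_group <- lapply(acc, function(l) do.call(rbind, l))
  ellipses <- lapply(per_group, function(df) {
    if (is.null(df) || nrow(df) < 3) return(NULL)
    covariance_ellipse_68(cbind(df$ecc_bb, df$ecc_alpha))
  })
  correlations <- lapply(per_group, function(df) {
    if (is.null(df) || nrow(df) < 3) return(NULL)
    list(angle = circ_corr(df$angle_bb, df$angle_alpha),
         eccentricity = stats::cor(df$ecc_bb, df$ecc_alpha),
         size = stats::cor(df$size_bb, df$size_alpha))
  })
  list(per_group = per_group, ellipses = ellipses,
       correlations = correlations)
}

#' Bootstrapped pRF size vs eccentricity regression
#'
#' Ordinary least-squares lines fitted to (eccentricity, size) pairs in
#' each bootstrap draw; reports the mean slope and intercept, the mean
#' line and a 16-84% percentile band on an eccentricity grid.
#'
#' @param ecc,size numeric vectors (one pair per electrode).
#' @param n_boot bootstrap draws.
#' @param seed integer RNG seed.
#' @param grid eccentricity grid for the band (default: range of `ecc`).
#' @return list with `slope`, `intercept` (means), `slope_draws`,
#'   `intercept_draws`, `grid`, `band` (2 x length(grid): 16% and 84%
#'   percentiles of the fitted line).
#' @export
size_eccentricity_regression <- function(ecc, size, n_boot = 1000,
                                         seed = 1, grid = NULL) {
  stopifnot(length(ecc) == length(size), length(ecc) >= 5)
  if (is.null(grid)) grid <- seq(min(ecc), max(ecc), length.out = 25)
  slopes <- intercepts <- rep(NA_real_, n_boot)
  lines <- matrix(NA_real_, n_boot, length(grid))
  with_local_seed(seed, for (b in seq_len(n_boot)) {
    take <- sample(length(ecc), replace = TRUE)
    if (length(unique(ecc[take])) < 2) next   # singular design: discard
    cf <- stats::coef(stats::lm(size[take] ~ ecc[take]))
    intercepts[b] <- cf[1]; slopes[b] <- cf[2]
    lines[b, ] <- cf[1] + cf[2] * grid
  })
  ok <- !is.na(slopes)
  list(slope = mean(slopes[ok]), intercept = mean(intercepts[ok]),
       slope_draws = slopes[ok], intercept_draws = intercepts[ok],
       grid = grid,
       band = apply(lines[ok, , drop = FALSE], 2, stats::quantile,
                    probs = c(0.16, 0.84)),
       n_discarded = sum(!ok))
}
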
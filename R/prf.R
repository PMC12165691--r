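#' DoG population receptive field response to aperture masks
#'
#' The predicted response to each step is the dot product of the
#' binarised stimulus aperture with the pRF,
#' `STIM . (g1 G1(x, y, sigma) - g2)`: a circular Gaussian centre
#' (amplitude 1 at its peak, per-pixel units) minus a spatially constant
#' surround, so a mask far from the centre yields approximately
#' `-g2 * (number of mask pixels)`.
#'
#' @param stim an `aperture_sequence`, or a list with `S` (steps x pixels
#'   matrix), `xpix`, `ypix` as from `aperture_matrix`.
#' @param params vector or list with x, y, sigma, g1, g2 (degrees and
#'   per-pixel gains).
#' @return numeric vector, one predicted value per step.
#' @export
dog_response <- function(stim, params) {
  if (inherits(stim, "aperture_sequence")) stim <- aperture_matrix(stim)
  p <- unname(unlist(params)[1:5])
  g <- exp(-((stim$xpix - p[1])^2 + (stim$ypix - p[2])^2) / (2 * p[3]^2))
  as.numeric(stim$S %*% g) * p[4] - p[5] * rowSums(stim$S)
}

#' Precompute a stimulus object for pRF fitting
#'
#' Flattens the aperture sequence, stores the decimated surround
#' regressor, and scores a coarse (x, y, sigma) start lattice so that
#' each subsequent fit only refines a handful of candidate starts.  The
#' aperture time series is decimated with the same filter as the summary
#' time courses; by linearity, decimating the per-pixel apertures and
#' taking the dot product equals decimating the dot product.
#'
#' @param ap an `aperture_sequence`.
#' @param factor decimation factor (3: 224 steps -> 75 time points).
#' @param sigma_grid coarse start values for sigma, degrees.
#' @param n_xy number of coarse start values per spatial axis.
#' @return object of class `prf_stimulus`.
#' @export
prf_stimulus <- function(ap, factor = 3,
                         sigma_grid = c(0.5, 1, 2, 4, 8), n_xy = 7) {
  stopifnot(inherits(ap, "aperture_sequence"))
  am <- aperture_matrix(ap)
  r <- ap$design$field_radius
  rs <- rowSums(am$S)
  xy <- seq(-r, r, length.out = n_xy)
  grid <- expand.grid(x = xy, y = xy, sigma = sigma_grid)
  G <- matrix(0, length(am$xpix), nrow(grid))
  for (j in seq_len(nrow(grid)))
    G[, j] <- exp(-((am$xpix - grid$x[j])^2 + (am$ypix - grid$y[j])^2) /
                    (2 * grid$sigma[j]^2))
  B <- am$S %*% G
  n_dec <- length(decimate_series(rs, factor))
  Bd <- matrix(0, n_dec, nrow(grid))
  for (j in seq_len(nrow(grid))) Bd[, j] <- decimate_series(B[, j], factor)
  structure(list(S = am$S, xpix = am$xpix, ypix = am$ypix,
                 rowsum = rs, rowsum_dec = decimate_series(rs, factor),
                 grid = grid, basis_dec = Bd, factor = factor,
                 n_steps = nrow(am$S), n_dec = n_dec,
                 field_radius = r),
            class = "prf_stimulus")
}

# Least-squares gains for pred = g1 * b1 - g2 * b0 under the sign
# convention; small active-set enumeration over the 2 constraints.
.solve_gains <- function(y, b1, b0, sign_convention) {
  cand <- list()
  X <- cbind(b1, -b0)
  cf <- tryCatch(qr.coef(qr(X), y), error = function(e) c(NA, NA))
  if (!any(is.na(cf))) cand[[length(cand) + 1]] <- cf
  g1_only <- sum(y * b1) / sum(b1^2)
  g2_only <- -sum(y * b0) / sum(b0^2)
  cand[[length(cand) + 1]] <- c(g1_only, 0)
  cand[[length(cand) + 1]] <- c(0, g2_only)
  cand[[length(cand) + 1]] <- c(0, 0)
  clamp <- switch(sign_convention,
                  positive = function(g) pmax(g, 0),
                  negative = function(g) pmin(g, 0),
                  free = identity)
  best <- NULL
  for (g in cand) {
    if (any(!is.finite(g))) next      # degenerate regressor (e.g. b1 ~ 0)
    g <- unname(clamp(g))
    pred <- g[1] * b1 - g[2] * b0
    sse <- sum((y - pred)^2)
    if (is.finite(sse) && (is.null(best) || sse < best$sse))
      best <- list(g = g, sse = sse, pred = pred)
  }
  if (is.null(best))
    best <- list(g = c(0, 0), sse = sum(y^2), pred = rep(0, length(y)))
  best
}

.prf_objective <- function(theta, y, stim, rows, sign_convention,
                           want_fit = FALSE) {
  g <- exp(-((stim$xpix - theta[1])^2 + (stim$ypix - theta[2])^2) /
             (2 * theta[3]^2))
  b1 <- decimate_series(as.numeric(stim$S %*% g), stim$factor)[rows]
  b0 <- stim$rowsum_dec[rows]
  sol <- .solve_gains(y, b1, b0, sign_convention)
  if (want_fit) sol else sol$sse
}

#' Fit a DoG pRF to a summary time course
#'
#' Bounded nonlinear least squares over (x, y, sigma, g1, g2): the gains
#' are profiled out linearly under the sign convention, and (x, y, sigma)
#' is optimised by L-BFGS-B from the best coarse-lattice starts.  Centre
#' bounds are +/- 2 x field radius; sigma in [0.1, 25] degrees.  Model
#' accuracy is the uncentered R^2 (denominator = raw power of the data
#' series), which can be negative.
#'
#' Sign conventions: `"positive"` (g1 >= 0, g2 >= 0; broadband: positive
#' centre, negative surround via the `-g2` term), `"negative"` (g1 <= 0,
#' g2 <= 0; alpha: negative centre, positive surround), `"free"`
#' (unconstrained gains; the no-correction control analysis).
#'
#' @param series decimated summary time course (length `stim$n_dec`).
#' @param stim a `prf_stimulus`.
#' @param sign_convention one of "positive", "negative", "free".
#' @param rows optional subset of time points to fit on (used for
#'   cross-validation).
#' @param n_refine number of coarse starts refined by L-BFGS-B.
#' @return object of class `prf_fit`: list with `params` (x, y, sigma,
#'   g1, g2), `r2_train`, `pred` (model series on all time points),
#'   `data`, `polar` (angle, eccentricity), `degenerate`.
#' @export
fit_prf <- function(series, stim, sign_convention = c("positive",
                    "negative", "free"), rows = NULL, n_refine = 2) {
  sign_convention <- match.arg(sign_convention)
  stopifnot(inherits(stim, "prf_stimulus"),
            length(series) == stim$n_dec)
  if (is.null(rows)) rows <- seq_len(stim$n_dec)
  y <- series[rows]
  if (all(y == 0)) {
    pred <- rep(0, stim$n_dec)
    return(structure(list(params = c(x = 0, y = 0, sigma = 1, g1 = 0, g2 = 0),
                          r2_train = NA_real_, pred = pred, data = series,
                          polar = to_polar(0, 0), degenerate = TRUE,
                          sign_convention = sign_convention),
                     class = "prf_fit"))
  }
  # coarse scoring on the precomputed lattice
  sse <- vapply(seq_len(nrow(stim$grid)), function(j) {
    .solve_gains(y, stim$basis_dec[rows, j], stim$rowsum_dec[rows],
                 sign_convention)$sse
  }, numeric(1))
  starts <- order(sse)[seq_len(n_refine)]
  bound <- 2 * stim$field_radius
  lower <- c(-bound, -bound, 0.1)
  upper <- c(bound, bound, 25)
  best <- NULL
  for (j in starts) {
    th0 <- as.numeric(stim$grid[j, ])
    opt <- tryCatch(
      stats::optim(th0, .prf_objective, y = y, stim = stim, rows = rows,
                   sign_convention = sign_convention,
                   method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(factr = 1e4, maxit = 200)),
      error = function(e) NULL)
    if (!is.null(opt) && (is.null(best) || opt$value < best$value))
      best <- opt
  }
  th <- best$par
  sol <- .prf_objective(th, y, stim, rows, sign_convention, want_fit = TRUE)
  # full-series prediction with the fitted parameters
  g <- exp(-((stim$xpix - th[1])^2 + (stim$ypix - th[2])^2) / (2 * th[3]^2))
  pred_full <- sol$g[1] *
    decimate_series(as.numeric(stim$S %*% g), stim$factor) -
    sol$g[2] * stim$rowsum_dec
  params <- c(x = th[1], y = th[2], sigma = th[3],
              g1 = sol$g[1], g2 = sol$g[2])
  structure(list(params = params,
                 r2_train = uncentered_r2(pred_full[rows], y),
                 pred = pred_full, data = series,
                 polar = to_polar(th[1], th[2]),
                 degenerate = FALSE,
                 sign_convention = sign_convention),
            class = "prf_fit")
}

#' Two-fold cross-validated pRF model accuracy
#'
#' Splits the decimated series into its first 38 and last 37 time points
#' (each half contains a full horizontal and a full vertical sweep by
#' construction of the sweep order), fits the pRF on each half, predicts
#' the held-out half, concatenates the predictions in temporal order and
#' scores them with the uncentered R^2 against the full series.
#'
#' @inheritParams fit_prf
#' @return list with `r2_cv`, `pred` (concatenated out-of-fold
#'   predictions), and the two half-fits (`fit1`, `fit2`).
#' @export
crossvalidate_prf <- function(series, stim,
                              sign_convention = c("positive", "negative",
                                                  "free")) {
  sign_convention <- match.arg(sign_convention)
  n <- stim$n_dec
  h1 <- seq_len(ceiling(n / 2))
  h2 <- setdiff(seq_len(n), h1)
  f1 <- fit_prf(series, stim, sign_convention, rows = h1)
  f2 <- fit_prf(series, stim, sign_convention, rows = h2)
  pred <- numeric(n)
  pred[h2] <- f1$pred[h2]
  pred[h1] <- f2$pred[h1]
  list(r2_cv = uncentered_r2(pred, series), pred = pred,
       fit1 = f1, fit2 = f2, halves = c(length(h1), length(h2)))
}

#' Full pRF fit plus cross-validated accuracy
#'
#' Parameters are reported from the fit to the complete series; accuracy
#' from the two-fold split.
#'
#' @inheritParams fit_prf
#' @return a `prf_fit` with an added `r2_cv` element.
#' @export
fit_prf_cv <- function(series, stim,
                       sign_convention = c("positive", "negative",
                                           "free")) {
  sign_convention <- match.arg(sign_convention)
  fit <- fit_prf(series, stim, sign_convention)
  cv <- crossvalidate_prf(series, stim, sign_convention)
  fit$r2_cv <- cv$r2_cv
  fit$cv_pred <- cv$pred
  fit
}

#' Cartesian pRF centre to polar coordinates
#'
#' Eccentricity is sqrt(x^2 + y^2); polar angle is measured from the
#' right horizontal meridian, counterclockwise, in [0, 360) degrees.  At
#' the origin the angle is undefined and reported as 0 with
#' `angle_defined = FALSE`.
#'
#' @param x,y pRF centre, degrees of visual angle.
#' @return list with `eccentricity`, `angle`, `angle_defined`.
#' @export
to_polar <- function(x, y) {
  ecc <- sqrt(x^2 + y^2)
  if (ecc == 0)
    return(list(eccentricity = 0, angle = 0, angle_defined = FALSE))
  ang <- atan2(y, x) * 180 / pi
  if (ang < 0) ang <- ang + 360
  list(eccentricity = ecc, angle = ang, angle_defined = TRUE)
}

#' Polar pRF coordinates to Cartesian
#' @param angle polar angle, degrees counterclockwise from the right
#'   horizontal meridian.
#' @param eccentricity distance from fixation, degrees.
#' @return list with `x`, `y`.
#' @export
from_polar <- function(angle, eccentricity) {
  list(x = eccentricity * cos(angle * pi / 180),
       y = eccentricity * sin(angle * pi / 180))
}
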
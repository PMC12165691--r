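#' Bar-sweep pRF stimulus design
#'
#' Describes the mapping stimulus: a contrast bar swept across a circular
#' visual field in eight directions (two horizontal, two vertical, four
#' diagonal), 28 discrete steps per sweep, 850 ms per step (500 ms stimulus
#' on, 350 ms blank), with 3 s of blank before and after the sweeps.  On
#' the diagonal sweeps the bar travels from one side to the centre in 12
#' steps and the remaining 16 steps are blanks, giving 64 blank steps per
#' run that serve as the spectral baseline.
#'
#' @param n_sweeps number of sweep directions (8).
#' @param steps_per_sweep discrete bar positions per sweep (28).
#' @param step_duration seconds per step (0.85).
#' @param stim_on seconds the bar is displayed within a step (0.5).
#' @param stim_off seconds of blank closing each step (0.35).
#' @param pre_post_blank seconds of blank at run start and end (3).
#' @param field_radius radius of the stimulated field, degrees (8.3).
#' @param bar_width bar aperture width, degrees (2).
#' @param grid_resolution pixels per side of each aperture mask (100).
#' @param diagonal_truncation trailing blank steps on diagonal sweeps (16).
#' @return an object of class `prf_design`.
#' @export
prf_design <- function(n_sweeps = 8, steps_per_sweep = 28,
                       step_duration = 0.85, stim_on = 0.5, stim_off = 0.35,
                       pre_post_blank = 3.0, field_radius = 8.3,
                       bar_width = 2.0, grid_resolution = 100,
                       diagonal_truncation = 16) {
  if (grid_resolution < 16) stop("grid_resolution must be at least 16")
  if (bar_width <= 0 || bar_width > 2 * field_radius)
    stop("bar_width must be positive and no wider than the field diameter")
  if (step_duration <= 0 || stim_on <= 0 || pre_post_blank < 0)
    stop("durations must be positive (pre_post_blank may be zero)")
  if (diagonal_truncation < 0 || diagonal_truncation >= steps_per_sweep)
    stop("diagonal_truncation must lie in [0, steps_per_sweep)")
  structure(list(
    n_sweeps = n_sweeps, steps_per_sweep = steps_per_sweep,
    step_duration = step_duration, stim_on = stim_on, stim_off = stim_off,
    pre_post_blank = pre_post_blank, field_radius = field_radius,
    bar_width = bar_width, grid_resolution = grid_resolution,
    diagonal_truncation = diagonal_truncation
  ), class = "prf_design")
}

#' Total run duration
#'
#' Steps x step duration plus the leading and trailing blank periods;
#' 224 x 0.85 s + 2 x 3 s = 196.4 s for the default design.
#'
#' @param design a `prf_design`.
#' @return run duration in seconds.
#' @export
run_duration <- function(design) {
  stopifnot(inherits(design, "prf_design"))
  design$n_sweeps * design$steps_per_sweep * design$step_duration +
    2 * design$pre_post_blank
}

# Sweep motion directions (unit vectors), interleaved so that the first
# and second halves of the run each contain one full horizontal and one
# full vertical sweep (required by the temporal split used for
# cross-validation), with the second half in reversed directions.
sweep_directions <- function() {
  s2 <- 1 / sqrt(2)
  list(
    list(u = c(1, 0),    type = "horizontal"),
    list(u = c(s2, s2),  type = "diagonal"),
    list(u = c(0, 1),    type = "vertical"),
    list(u = c(s2, -s2), type = "diagonal"),
    list(u = c(-1, 0),   type = "horizontal"),
    list(u = c(-s2, -s2), type = "diagonal"),
    list(u = c(0, -1),   type = "vertical"),
    list(u = c(-s2, s2), type = "diagonal")
  )
}

#' Generate the aperture mask sequence for a design
#'
#' Rasterises one binary mask per step on a square pixel grid spanning
#' [-field_radius, field_radius] in both x (rightward) and y (upward),
#' origin at fixation.  Cardinal sweeps cross the full field; diagonal
#' sweeps travel from one side to the centre in
#' `steps_per_sweep - diagonal_truncation` steps and then show blanks.
#'
#' @param design a `prf_design`.
#' @return an `aperture_sequence`: list with `masks` (array
#'   resolution x resolution x n_steps, values 0/1), `events` (data frame
#'   with onset, duration, step, sweep, sweep_type, blank), and pixel
#'   centre coordinate vectors `x`, `y` in degrees.
#' @export
aperture_sequence <- function(design) {
  stopifnot(inherits(design, "prf_design"))
  res <- design$grid_resolution
  r <- design$field_radius
  px <- -r + (seq_len(res) - 0.5) * (2 * r / res)
  xg <- matrix(px, res, res)          # x varies along rows
  yg <- matrix(px, res, res, byrow = TRUE)
  disk <- xg^2 + yg^2 <= r^2
  dirs <- sweep_directions()
  n_steps <- design$n_sweeps * design$steps_per_sweep
  masks <- array(0, dim = c(res, res, n_steps))
  sweep_id <- integer(n_steps)
  sweep_type <- character(n_steps)
  blank <- logical(n_steps)
  step <- 0L
  for (s in seq_len(design$n_sweeps)) {
    d <- dirs[[((s - 1L) %% 8L) + 1L]]
    if (d$type == "diagonal") {
      n_show <- design$steps_per_sweep - design$diagonal_truncation
      centers <- -r + (seq_len(n_show) - 0.5) * (r / n_show)
    } else {
      n_show <- design$steps_per_sweep
      centers <- -r + (seq_len(n_show) - 0.5) * (2 * r / n_show)
    }
    proj <- xg * d$u[1] + yg * d$u[2]
    for (i in seq_len(design$steps_per_sweep)) {
      step <- step + 1L
      sweep_id[step] <- s
      sweep_type[step] <- d$type
      if (i <= n_show) {
        m <- (abs(proj - centers[i]) <= design$bar_width / 2) & disk
        masks[, , step] <- m * 1
        blank[step] <- !any(m)
      } else {
        blank[step] <- TRUE
      }
    }
  }
  events <- data.frame(
    onset = design$pre_post_blank + (seq_len(n_steps) - 1) * design$step_duration,
    duration = design$stim_on,
    step = seq_len(n_steps),
    sweep = sweep_id,
    sweep_type = sweep_type,
    blank = blank
  )
  structure(list(masks = masks, events = events, x = px, y = px,
                 design = design),
            class = "aperture_sequence")
}

#' Flatten an aperture sequence into a step-by-pixel matrix
#'
#' @param ap an `aperture_sequence`.
#' @return list with `S` (n_steps x n_pixels matrix), `xpix`, `ypix`
#'   (degree coordinates of each pixel column).
#' @export
aperture_matrix <- function(ap) {
  stopifnot(inherits(ap, "aperture_sequence"))
  d <- dim(ap$masks)
  S <- t(matrix(ap$masks, d[1] * d[2], d[3]))
  list(S = S,
       xpix = rep(ap$x, times = d[2]),
       ypix = rep(ap$y, each = d[1]))
}

#' Write / read a BIDS-iEEG style events table
#'
#' Tab-separated columns onset, duration, step, sweep, sweep_type, blank.
#' @param events events data frame (as in `aperture_sequence()$events`).
#' @param path file path.
#' @return `read_events_tsv` returns the events data frame.
#' @export
write_events_tsv <- function(events, path) {
  utils::write.table(events, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
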
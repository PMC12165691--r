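# Shared fixtures, built in code at test time.

# full-size design on a coarse pixel grid (fast masks, same geometry)
test_design <- function(res = 50) prf_design(grid_resolution = res)

# short design for simulation-heavy tests: 8 sweeps x 7 steps
short_design <- function(res = 30)
  prf_design(steps_per_sweep = 7, diagonal_truncation = 3,
             grid_resolution = res)

# cache expensive objects across tests within a run
.cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

test_apertures <- function() cached("ap50", aperture_sequence(test_design()))
test_stim <- function() cached("stim50", prf_stimulus(test_apertures()))

# noiseless DoG summary series for a given truth on the cached stimulus
dog_series <- function(truth, stim = test_stim()) {
  resp <- dog_response(list(S = stim$S, xpix = stim$xpix,
                            ypix = stim$ypix), truth)
  decimate_series(resp, stim$factor)
}
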
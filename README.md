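# alphaprf

Model-based separation of alpha-oscillatory and broadband responses in
intracranial (ECoG) recordings, with population receptive field (pRF)
mapping of both signal components and distance-resolved inter-electrode
coherence.

## The problem

Visual stimulation has two spectral signatures in human visual cortex:
a broadband power elevation spanning a wide frequency range, and a
suppression of the ~8–13 Hz alpha oscillation. Both are spatially
tuned, but they overlap below ~30 Hz, so power in a fixed alpha band
confounds them — a stimulus can raise broadband power and silence the
oscillation while raw alpha-band power stays flat. This package:

1. **decomposes** each trial's spectral change (3–26 Hz, log–log) into
   a broadband shift plus an alpha Gaussian:

   `log10(P_S/P_B) = (β_bb_low − n·(k−μ)) + β_alpha · G(k|μ,σ)`,
   `k = log10(f)`, `8 < 10^μ < 13 Hz`,

   with an optional second Gaussian (15–30 Hz) for beta bumps;
2. quantifies high-frequency broadband power as the 70–180 Hz
   geometric-mean power ratio (line-noise harmonics excluded);
3. fits a **Difference-of-Gaussians pRF** to each signal's 75-point
   decimated summary time course, `RESP = STIM · (g1·G1(x,y,σ) − g2)`,
   with two-fold cross-validated uncentered R²;
4. selects electrodes against a **shuffle-null** accuracy threshold and
   runs the pRF comparison statistics (pair normalisation, lens
   overlap, probabilistic-area bootstraps, size–eccentricity
   regression);
5. computes **magnitude-squared coherence** per electrode pair
   (Welch-averaged 500 ms windows, 75% overlap), bins it by electrode
   distance and fits `a·exp(−d/λ) + b`;
6. ships a **synthetic bar-sweep ECoG generator** (224-trial, 196.4 s
   runs; 1/f background modulated by a positive DoG field; alpha
   oscillation suppressed by a larger negative DoG field; ERPs, line
   noise, beta bumps, spatially correlated alpha sources) so the whole
   pipeline is validated against known ground truth.

## Worked example

The central methodological point in one construction — a stimulus that
removes the alpha rhythm while raising broadband power so that raw
alpha-band power is unchanged:

```r
library(alphaprf)
f <- 3:26
background <- 20 * f^-1.5
bump <- 60 * exp(-(f - 10)^2 / (2 * 1.5^2))      # alpha rhythm at 10 Hz
p_blank <- background + bump
shift <- mean(log10(p_blank / background)[f >= 8.5 & f <= 11.5])
p_stim <- background * 10^shift                   # rhythm gone, broadband up

alpha_band_power_no_correction(p_stim, p_blank, f, peak = 10)
#> [1] 1
fit <- fit_electrode_alpha_peak(p_stim, p_blank, f)
round(c(beta_alpha = fit$beta_alpha, peak_hz = fit$alpha_peak_hz), 3)
#> beta_alpha    peak_hz
#>     -2.126      9.877
```

Band power reports "no change" (ratio 1.0); the decomposition reports a
strongly negative alpha coefficient — the suppression that the
broadband elevation masked.

End to end on synthetic data with known ground truth (alpha fields
twice the size of broadband fields, same centres):

```r
design   <- prf_design(grid_resolution = 50)
apertures <- aperture_sequence(design)
cohort   <- synth_cohort(6, apertures, seed = 42)
sim      <- simulate_experiment(design, cohort, n_runs = 3, seed = 43,
                                ap = apertures)
out      <- run_synthetic_pipeline(sim)   # ~1 minute
subset(out$results, signal %in% c("alpha", "broadband"),
       select = c(electrode, signal, x, y, sigma, g1, r2_cv))
#>  electrode    signal     x    y sigma      g1 r2_cv
#>          1     alpha -1.14 -5.5  2.33 -0.0083  0.77
#>          1 broadband -0.45 -5.4  1.88  0.0052  0.94
#>          2     alpha  3.74  4.6  1.69 -0.0096  0.59
#>          2 broadband  3.88  4.2  0.99  0.0080  0.82
#>          3     alpha -1.71 -3.0  2.22 -0.0092  0.71
#>          3 broadband -1.80 -2.7  1.39  0.0070  0.93
#>          ...
```

Alpha pRFs come out with negative centre gains (`g1 < 0`: power falls
when the bar covers the field), at the same centres as the broadband
pRFs, and larger — fitted alpha sizes run somewhat below the generative
2x ratio for reasons analysed in the methods vignette
(`vignettes/alpha-prf-methods.Rmd`), which also documents every model,
parameter and numerical choice.

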
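# rodspt

Single-molecule localization and dynamics analysis for rod-shaped
bacteria.

`rodspt` is for microbiologists and biophysicists doing
single-particle-tracking PALM (sptPALM) in bacteria such as *E. coli*,
who need to answer, from localization tables and cell outlines: what
fraction of a protein is membrane-bound, how fast does it diffuse, does
it cluster, and how do these connect to function (here, mRNA decay
kinetics). The motivating system is RNase E, the principal *E. coli*
endoribonuclease, whose membrane attachment via an amphipathic helix
tunes co-transcriptional mRNA degradation — but every stage is generic.

## What it computes

**Membrane-bound percentage (MB%).** Localizations are converted into
normalized cell coordinates: `yNorm` along the cell axis and `xNorm`
across it (signed distance to the centerline over the half-width *R*).
For spots in the cylindrical part of the cell, the distribution of
|xNorm| is a mixture of a projected membrane circle and a projected
cytoplasmic disk,

    P(x) = m * P_memb(x) + (1 - m) * P_cyto(x)

whose raw marginals are the arcsine law `1 / (pi sqrt(r^2 - x^2))` and
the semicircle law `2 sqrt(r^2 - x^2) / (pi r^2)` at the inner-membrane
radius `r = R / dilF`, modified by defocus weighting
`Phi((f + z) / sigma)` (with `f = R - fCut`) and Gaussian localization
blur (`sigma = locErr / 1000` um). The four parameters
`(m, dilF, locErr, fCut)` are estimated from the binned |xNorm| histogram
by adaptive Markov chain Monte Carlo with uniform priors; MB% = 100 m is
reported with a 95% credible interval.

**Diffusion.** Per-track time-averaged MSD,
`MSD(tau) = 4 D tau + b` fit over the first three lags, with the
intercept `b = -4 D dt / 3 + 4 sigma^2` separating motion-blur (dynamic)
and localization-noise (static) errors; ensemble means with SEM,
ensemble-averaged MSD curves, one/two-population Gaussian fits of D
histograms, and the adaptive tracker linking radius
`ceiling(2 sqrt(4 D dt) / pixel)`.

**Clustering.** Ripley `K`, `L = sqrt(K/pi)` and `H = L - r` per cell,
referenced against complete spatial randomness simulated on the same
spherocylinder surface and projected to 2D, summarized as the integral
over r of `H_data - H_CSR`.

**Decay kinetics.** Windowed log-linear exponential fits giving
co-transcriptional (`k_d1`, default window 150–210 s) and
post-transcriptional (`k_d2`, 300–600 s) rates, compared across strains
with pooled-variance t-tests.

**Synthetic data.** A Brownian-dynamics simulator of spherocylindrical
cells (membrane diffusion on the cylinder surface, cytoplasmic diffusion
inside, motion blur, localization noise, defocus-dependent detection,
photobleaching) plus two-phase decay curves, so every stage is testable
by parameter recovery. See the methods vignette
(`vignettes/rodspt-methods.Rmd`) for the models, defaults and known
limitations.

## Worked example

Simulate a membrane-enriched protein (true membrane fraction 0.93,
membrane D = 0.0184 um²/s), run the localization pipeline, and fit MB%:

```r
library(rodspt)

cfg   <- sim_config(n_cells = 60, m_true = 0.93, seed = 7,
                    spots_per_cell = 1700)
cells <- simulate_cells(cfg)
sim   <- simulate_tracks(cells, cfg)

spots <- apply_drift(sim$tracks, estimate_drift(sim$tracks, cells))
ns    <- cylinder_filter(normalize_spots(assign_spots(spots, cells),
                                         cells), cells)
hist  <- build_xnorm_histogram(ns, n_boot = 100)
hist
#> xnorm_histogram: 25 bins of width 0.04 (absolute) | 29444 spots from 7361 tracks

R_um <- mean(vapply(cells, function(c) c$R_px, numeric(1))) * cfg$pixel_size
fit  <- fit_mb(hist, R_um, mb_fit_settings(n_iter = 6000, seed = 1))
fit
#> MB% = 93.2 [88.7, 97.0] (95% CI)
#>   acceptance 0.28, split-chain diagnostic 1.000
```

The point estimate recovers the simulated 93% membrane-bound fraction;
the interval is the central 95% of the posterior. Diffusion and decay
from the same objects:

```r
ed <- ensemble_D(split_tracks(sim$tracks, cfg$pixel_size))
sprintf("D = %.4f +/- %.4f um^2/s over %d tracks", ed$mean, ed$sem, ed$n)
#> "D = 0.0190 +/- 0.0004 um^2/s over 3147 tracks"
adaptive_link_radius(ed$mean)
#> 1

d <- simulate_decay(cfg, seq(0, 600, 15), n_replicates = 3)
attr(decay_rates(d), "mean")
#>       k_d1       k_d2
#> 0.01951069 0.01007274
```

The ensemble D sits slightly above the membrane coefficient because the
track mix includes the fast cytoplasmic subpopulation; the decay rates
recover the simulated 0.02/s and 0.01/s within a few percent. (The
apparent D of pure membrane tracks in the image plane is *below* the
surface coefficient — projection compresses the transverse component; see
the vignette.)

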
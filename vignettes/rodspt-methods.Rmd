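---
title: "rodspt: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{rodspt: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rodspt)
```

# Scope

`rodspt` analyzes single-particle-tracking PALM data from rod-shaped
bacteria: it converts localizations into normalized cell coordinates,
estimates the membrane-bound percentage (MB%) of a protein from the
transverse-position histogram by fitting a cylindrical-projection mixture
model with MCMC, quantifies per-track diffusion from time-averaged
mean-squared displacements, measures spatial clustering with Ripley
statistics against complete spatial randomness (CSR) simulated on the cell
surface, and fits windowed exponential mRNA decay rates. A
Brownian-dynamics simulator of spherocylindrical cells provides ground
truth for validating every stage by parameter recovery.

This vignette documents the models, the tunable parameters, the numerical
choices, and the known limitations.

# Normalized cell coordinates

Spots (one localization per molecule per frame, from a tracking program)
are assigned to cells by polygon containment against segmentation
outlines; a track is assigned as a whole to the cell holding the majority
of its spots, and tracks straddling cells are dropped. Stage drift
between the bright-field outlines and the fluorescence data is estimated
from the mean offset between per-cell spot centroids and outline
centroids, attributing spots to the nearest cell rather than by
containment so a drifted cloud is not truncated at the polygon boundary;
the correction is applied only above 0.5 px.

Each spot is projected onto the cell centerline. `yNorm` is the
arc-length position divided by the cell length $L$; `xNorm` is the signed
perpendicular distance divided by the half-width $R$, the sign taken from
the cross product of the local centerline tangent with the spot offset
(positive to the left of the direction of increasing `yNorm`; only
$|x_{\mathrm{Norm}}|$ enters the MB% fit, so the convention is
cosmetic). Spots with $|x_{\mathrm{Norm}}| > 1$ or `yNorm` outside
$[0, 1]$ are *rejected*, not clipped: clipping would pile noise-displaced
mass into the outermost bin and bias MB% upward. Only spots in the
cylindrical part of the cell, $R < y < L - R$ along the axis (strict
inequalities), enter transverse-position histograms, because the 2D
projection model below assumes a cylinder.

Histograms use bins of width 0.04 and only the first four localizations
of each track, so each track contributes equally; tracks shorter than
four frames are dropped. The SEM of each bin is estimated by
bootstrapping *tracks* (not spots), which respects the within-track
dependence of the four contributed points; with at least 30 bootstrap
replicates the full bin covariance is retained for the fit below.

# The projection mixture model for MB%

A cell is modeled as a cylinder with its circular cross-section in the
$x$–$z$ plane; molecules are either uniform on the inner-membrane circle
of radius $r$ or uniform in the enclosed disk. The transverse marginals
are, for $|x| < r$ with $z(x) = \sqrt{r^2 - x^2}$,

$$P^0_{\mathrm{memb}}(x) = \frac{1}{\pi z(x)}, \qquad
  P^0_{\mathrm{cyto}}(x) = \frac{2 z(x)}{\pi r^2},$$

the arcsine and semicircle laws. Imaging effects enter as:

* **Defocus.** The sample is illuminated so that depths $z < -f$ are out
  of focus; with localization uncertainty $\sigma$ the detection weight at
  depth $z$ is $\Phi((f + z)/\sigma)$. The membrane component carries the
  weight $\Phi((f+z)/\sigma) + \Phi((f-z)/\sigma)$ at its two depth
  branches $\pm z(x)$; the cytoplasm component is weighted by
  $\int_{-z}^{z} \Phi((f+u)/\sigma)\,du$, which has the closed form
  $G(z) - G(-z)$ with $G(u) = \sigma\,(v\Phi(v) + \phi(v))$,
  $v = (f+u)/\sigma$. (The alternative reading in which the integrand is
  constant in the depth variable is available via
  `literal_defocus = TRUE` in `predicted_marginal()`; it multiplies the
  disk density by $2z\,\Phi((f+z)/\sigma)$ instead. The depth-dependent
  integrand is the default because it is the one consistent with
  weighting each depth by its own detection probability.)
* **Localization error.** Each component is convolved with a Gaussian of
  SD $\sigma$ in $x$. The blur is applied in 1D after depth integration;
  the axial ($z$) uncertainty has almost no effect on the $x$ marginal,
  so both are set to the lateral value.
* **Scaling.** $r = R/\mathrm{dilF}$, where $R$ is the bright-field
  half-width and dilF $\ge 1$ accounts for the membrane sitting inside
  the detected cell boundary; $f = R - \mathrm{fCut}$, so fCut $= 0$
  means an unobstructed view; $\sigma = \mathrm{locErr}/1000$ with locErr
  in nm.

The observed distribution is the mixture
$P(x) = m\,P_{\mathrm{memb}}(x) + (1 - m)\,P_{\mathrm{cyto}}(x)$ of the
*individually renormalized* components; $m$ is the membrane-bound
fraction and MB% $= 100\,m$.

## Numerics

The model is evaluated on a uniform grid of step $h$ (default $R/400$;
the MCMC uses $R/200$) symmetric about $x = 0$, so folding to $|x|$ is
exact. Membrane bin masses are integrated in the circle angle — with
$x = r\cos\theta$ the arcsine edge singularity disappears — using
composite Simpson with five nodes per grid cell; the cytoplasm depth
integral uses the closed form above. The blur is a discrete convolution
(FFT) with a kernel truncated at $5\sigma$. Halving $h$ changes every
0.04-wide bin probability by less than $10^{-4}$. With $\sigma = 0$ the
defocus weight is the indicator of the *closed* half-space $z \ge -f$, so
that fCut $= 0$ leaves the whole cell in view (the open convention would
put spurious half-weight on the single tangent point $z = -f = -r$).
Model bin probabilities are conditioned on $|x_{\mathrm{Norm}}| \le 1$,
mirroring the rejection rule applied to data.

# MCMC estimation of MB%

`fit_mb()` fits the absolute-`xNorm` histogram. The objective is the
squared misfit between observed and model bin probabilities; when the
histogram carries a bootstrap bin covariance $\hat\Sigma$ the residuals
are whitened by it (Mahalanobis misfit), which accounts for both the
multinomial constraint and the within-track correlation of the
contributed points. The inverse of a covariance estimated from $B$
bootstrap replicates overstates precision by $(B-1)/(B-p-2)$ for $p$
bins, so $\hat\Sigma$ is scaled by that factor and ridged by 5% of its
mean diagonal before inversion; without the correction the credible
intervals are systematically narrow. The observation variance is treated
as an unknown scale with a conjugate inverse-gamma update (prior anchored
at unit whitened variance with weight equal to the number of bins), so
the likelihood is Gaussian with a sampled scale.

Priors are uniform on a box: $m \in [0,1]$, dilF $\in [1, 1.6]$, locErr
$\in [0, 80]$ nm, fCut $\in [0, R]$ — bounds that contain plausible
microscope and geometry values. The sampler is adaptive random-walk
Metropolis: the proposal covariance is re-estimated every 100 iterations
from the second half of the chain history, scaled by $2.38^2/4$. The
chain is seeded at the best of nine Nelder–Mead minimizations started on
a grid over $(m, \mathrm{fCut})$, because the posterior can be multimodal
along the $m$–fCut trade-off: for data without a defocus signature,
fCut $= 0$ and fCut $= R$ produce *identical* marginals (the defocus
weight sums to a constant in both limits), with genuinely different
shapes in between. MB% is reported as the posterior mean of $m$ with a
central 95% credible interval; convergence is checked by a split-chain
scale-reduction diagnostic on $m$ (flagged above 1.05) and acceptance
rates outside [0.05, 0.95] are flagged. `posterior_predictive_band()`
evaluates the model density over posterior draws and returns the
pointwise envelope; `check_hyperparameter_insensitivity()` refits under
alternative settings (bin width, bounds, chain length) and flags MB%
spreads above two percentage points, e.g. a bound that pins the
posterior.

# Diffusion analysis

For a track $\vec r(t_i)$ the time-averaged MSD at lag $\tau = k\,\Delta t$
is the overlapping-window average
$\mathrm{MSD}(\tau) = \frac{1}{N_\tau}\sum_i [\vec r(t_i) -
\vec r(t_i + \tau)]^2$ with $N_\tau = \mathrm{len} - k$. The diffusion
coefficient comes from ordinary least squares over the first three lags,

$$\mathrm{MSD}(\tau) = 4 D \tau + b, \qquad
  b = -\tfrac{4 D \Delta t}{3} + 4\sigma^2,$$

where the intercept collects the dynamic error (motion blur during the
exposure $\Delta t$) and the static error (localization noise
$\sigma$). Three lags keep the fit on short delays where the per-track
statistics are best. Only gapless tracks of at least 12 frames qualify;
negative fitted $D$ values are *retained* in ensemble means (truncation
would bias them), and the stationary-emitter simulation shows the
resulting noise floor. Ensemble results are mean $\pm$ SEM (SD over
tracks divided by $\sqrt{n}$); `eata_msd()` averages per-track curves.

$D$ histograms (probability densities with Freedman–Diaconis bins) are
fit with one- or two-population Gaussian shapes by Levenberg–Marquardt;
the slow-population fraction can be fixed, e.g. to an independently
estimated MB%. With the fraction fixed at 0 or 1 the fit reduces exactly
to the one-population form.

The adaptive tracker linking radius is
$\lceil 2\sqrt{4 D_{\mathrm{5pix}} \Delta t} / \mathrm{pixel} \rceil$
pixels (at least 1): twice the per-frame RMS displacement implied by a
preliminary coefficient estimated with a loose 5-pixel radius. With
$\Delta t = 0.0217$ s and 0.160 um pixels the switch points fall at
0.0737 and 0.295 um²/s.

# Clustering

Ripley's $\hat K(r) = \frac{A}{n(n-1)} \sum_{i \ne j} 1(d_{ij} \le r)$,
$L = \sqrt{K/\pi}$, $H = L - r$, with $A$ the projected cell footprint
$2R(L-2R) + \pi R^2$. No analytic edge correction is applied: the null
reference is CSR simulated *on the same cell* — points uniform by area on
the spherocylinder surface (cylindrical body plus caps), projected to the
imaging plane — so edge and projection effects cancel in the comparison.
The per-cell clustering score is the trapezoidal integral over $r$ of
$H_{\mathrm{data}} - \bar H_{\mathrm{CSR}}$, with the CSR mean taken over
20 replicates and $r$ from 0 to $R$ in 50 steps by default (both
exposed); positive values indicate clustering, and the spread of the same
statistic across the CSR replicates provides the null scale. Patterns
need at least 300 points (configurable).

# Decay kinetics

Relative-abundance time courses are fit by least squares of
$\log(\mathrm{abundance})$ against time inside a window (edges
inclusive); the rate is minus the slope. Log-linear fitting is exact for
noiseless exponentials and standard for this assay. Default windows are
[150, 210] s for the co-transcriptional rate $k_{d1}$ and [300, 600] s
for the post-transcriptional rate $k_{d2}$, both exposed as arguments.
Strains are compared with the pooled-variance two-sample $t$-test
(two-tailed by default, left-tailed option); degenerate zero-variance
inputs with equal means return $p = 1$.

# The synthetic-data generator

`simulate_cells()` draws straight, axis-aligned spherocylinders with
lengths and half-widths from truncated normals, laid out on a
non-overlapping grid; `simulate_tracks()` populates them with molecules
and `simulate_decay()` produces two-phase decay curves. What is
emulated, with defaults in parentheses:

* cell geometry: $L$ (3.0 ± 0.4 um), $R$ (0.45 ± 0.03 um), pixel size
  (0.160 um) — typical *E. coli* dimensions;
* the membrane at radius $R/\mathrm{dilF_{true}}$ (dilF$_\mathrm{true}$ =
  1.2): segmentation outlines sit outside the membrane, so the true
  dilation factor is interior to the fit bounds;
* compartment assignment with membrane probability `m_true` (0.93);
* diffusion: membrane molecules move on the cylinder surface in the
  flattened (arc-length, axial) chart with $D_{\mathrm{mem}}$
  (0.0184 um²/s), reflecting at the cap junctions; cytoplasmic molecules
  move in 3D with $D_{\mathrm{cyto}}$ (0.1 um²/s, the measured scale of
  the fast cytoplasmic population) inside the membrane-bounded
  spherocylinder, reflecting at the wall via folding of the
  distance-to-spine;
* motion blur: the recorded position is the average of `n_sub` (10)
  substep positions per 21.7 ms frame;
* localization error: isotropic Gaussian noise (`sigma_loc` = 0.02 um) in
  the image plane;
* detection: a frame is recorded with probability
  $\Phi((f_{\mathrm{depth}} + z)/\sigma_z)$ on the frame-mean depth, with
  $\sigma_z$ = 0.02 um set equal to the lateral error — the same
  equal-uncertainty simplification the projection model makes. The
  default $f_{\mathrm{depth}} = 0.45$ um $= R$ leaves the whole cell in
  view, so detection is equal for both compartments, the condition the
  MB% analysis assumes (a focal plane cutting the cell makes detection
  compartment-differential through track splitting of fast molecules);
  missed frames split trajectories into separate tracks;
* photobleaching: geometric lifetimes with `p_bleach` (0.1) per frame;
  minimum emitted track length is 1 — length filters belong downstream;
* decay: $A e^{-k_{d1} t}$ before the switch time (255 s), continuing
  continuously at rate $k_{d2}$ after, with unit-mean lognormal noise of
  CV `cv_noise` (0.1); defaults $k_{d1} = 0.02$/s (fast co-transcriptional
  decay of a cytoplasmic-nuclease regime; rates much below ~0.016/s are
  not resolvable in a 60 s window at 10% noise regardless of method) and
  $k_{d2} = 0.01$/s.

Not emulated: camera noise (the localization error is the abstraction),
blinking and other photophysics beyond single-step bleaching, cell
curvature (the projection model itself assumes a cylinder), nucleoid
exclusion, and PSF broadening of fast molecules.

# What recovery tests do and do not show

Because the generator implements the physics rather than the model,
passing tests validate the inference machinery under realistic
conditions, and two deliberate physical effects mark the model's
boundaries:

* **Projection of surface diffusion.** Membrane motion projected to the
  image plane compresses the transverse component by $\cos\theta$, so
  image-plane tracks of membrane molecules show an apparent $D$ about 25%
  below the surface coefficient — a property test documents this.
  Diffusion-recovery tests therefore use planar Brownian tracks
  (`simulate_point_tracks()`), the chart representation of membrane
  motion, which also provides the stationary-emitter control.
* **Motion-blur compression of fast cytoplasm.** Frame-averaging pulls
  positions of fast cytoplasmic molecules away from the reflecting
  membrane, shrinking their transverse marginal support by roughly
  $\sqrt{2 D_{\mathrm{cyto}} \Delta t}$-scale boundary layers. The
  projection model has no such term. At $D_{\mathrm{cyto}} =
  0.1$ um²/s this inflates MB% by ~10 points for all-cytoplasm data and
  costs
  credible-interval coverage at high membrane fractions, where the
  misfit opens a spurious lower-$m$/intermediate-fCut mode. With blur
  disabled (`n_sub = 1`) the all-cytoplasm fit returns ~2.7%, showing
  the machinery itself is unbiased. MB% estimates for
  membrane-enriched proteins (the regime the method targets) recover
  truth within a few points at realistic spot counts (~10⁵).

Test problem sizes: recovery fits use ~10⁵ histogram spots (about 100
cells at 4200 localizations each); the interval-coverage study uses 20
replicates of ~1.1×10⁴ histogram spots; Ripley nulls use 10⁴-point
patterns; diffusion ensembles use 2000–5000 tracks.

# Known limitations

* The MB% model is as published: no nucleoid-exclusion term (cytoplasmic
  constructs with strong exclusion will misfit near $x = 0$), no
  motion-blur compression term, single global dilF for both components.
* fCut is unidentifiable when the data carry no defocus signature (see
  above); the posterior then spreads over its equivalent values, which is
  harmless for MB% at large spot counts but adds variance at small ones.
* Recovery degrades if the instrument's axial detection response is much
  broader than the lateral localization error, since the model ties the
  defocus softness to locErr.
* The drift model is a single movie-wide translation; rotation and
  per-frame drift are out of scope.
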
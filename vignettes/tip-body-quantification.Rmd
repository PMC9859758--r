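---
title: "Quantifying +TIP-body dynamics and condensate biophysics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying +TIP-body dynamics and condensate biophysics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tipquant)
```

## Scope

Plus-end tracking proteins (+TIPs) such as Kar9, Bim1 and Bik1 in budding
yeast concentrate into a micrometre-scale body at the growing end of astral
microtubules. The body behaves in many respects like a liquid condensate:
it fuses, it partitions proteins, and in vitro the purified components
phase separate into droplets. `tipquant` implements the quantitative
analyses this behaviour calls for:

* annotation of microtubule **growth and shrinkage phases** from trajectories
  of the distance between a fluorescent punctum and the spindle pole body
  (SPB);
* **joint rate estimation** across strains by linear mixed-effects models;
* **intensity statistics**: spindle asymmetry index, cumulative intensity,
  punctum-loss frequency with binomial confidence intervals, and
  fluorescence **stoichiometry calibration**;
* **droplet coalescence** analysis: aspect-parameter relaxation, fusion-time
  fits, inverse capillary velocity, and the underlying hydrodynamic
  relations;
* **FRAP normalization** and **partition coefficients**;
* approximate **binodal construction** from concentration-salt screening
  grids;
* a **synthetic-data generator** that produces every input the pipeline
  consumes, with the statistical structure the analyses assume.

Everything operates on plain tab-separated tables; conventions are fixed
package-wide (frames 0-based, time in seconds, lengths in micrometres,
intensities in arbitrary units, segment endpoints inclusive).

## Phase annotation

A punctum-SPB distance trajectory is annotated in four steps.

1. **Smoothing.** A Savitzky-Golay filter (polynomial order 1, window 5
   frames) is applied to the length series. With order 1 and a symmetric
   window this is exactly the centered moving average; the test suite
   asserts that identity. Near the series ends the window shrinks
   symmetrically to the available points; we deliberately do not reflect or
   pad, which would fabricate data. The smoothed series feeds **only**
   changepoint detection; all statistics are computed on raw data.
2. **Changepoint detection.** For each candidate number of changepoints
   $k \in \{0, \dots, 5\}$ we find, by exact dynamic programming, the
   segmentation minimizing the total residual sum of squares of per-segment
   least-squares lines, with every segment at least 5 frames long. The
   number of changepoints is then chosen by a Bayesian information
   criterion, $n\ln(\mathrm{RSS}_k/n) + (3k + 2)\ln n$, counting two line
   parameters per segment plus one location per breakpoint; the penalty
   multiplier is configurable. The stopping rule is a genuine design
   choice: a maximum count and a minimum spacing constrain the search but
   do not select $k$, and a penalized RSS criterion is the standard,
   reproducible way to do so. Ties prefer fewer changepoints, and among
   equal-cost placements the earliest ones, so results are deterministic.
   An RSS below the double-precision resolution of the series' sum of
   squares is treated as an exact fit, which keeps exactly-linear inputs at
   $k = 0$.
3. **Extremum refinement.** Each changepoint is moved to the nearest local
   maximum or minimum of the *unfiltered* series whose topographic
   prominence is at least 25% of the raw series' full range (minima are
   found on the negated series). Changepoints with no qualifying extremum
   anywhere stay where they are. Equidistant candidates resolve to the
   earlier frame.
4. **Classification.** Boundaries (shared by adjacent segments) partition
   the trajectory into inclusive frame intervals. Each interval with at
   least 3 frames - the minimum leaving one residual degree of freedom -
   gets an ordinary least-squares line against time on the raw data, and is
   labelled growth (shrinkage) when the slope is significantly positive
   (negative) by a two-sided $t$-test at $\alpha = 0.05$; otherwise it is
   indeterminate. A perfect fit makes the $t$ statistic degenerate; by the
   limiting behaviour we assign $p = 0$ for a nonzero slope and $p = 1$ for
   a zero one.

Annotation runs on the longest prefix of non-missing length values (after
punctum loss the series ends), is invariant to adding a constant, swaps
labels under negation, and is equivariant under time rescaling; these are
property tests. Whether a boundary frame belongs to the preceding or
following segment is not decidable from the data; segments share the frame,
and per-frame expansion (`frame_phases()`) assigns it to the earlier
segment.

A separate `display_smooth()` (moving average over three frames) exists
purely to reproduce the figure convention for displayed trajectories and
never feeds analysis.

## Rate models

Growth and shrinkage segments become *partial trajectories* with time
measured from the phase start, so intercepts are initial lengths (or
intensities). Indeterminate segments are excluded. For each response
(length, intensity) and phase, the strains are modelled jointly:

$$y_{ij} = \beta_{0,s(j)} + \beta_{1,s(j)} t_{ij} + b_{0j} + b_{1j} t_{ij}
+ \varepsilon_{ij},$$

with per-strain fixed intercepts and slopes (cell-means coding), random
intercept and slope per partial trajectory with shared covariance $\Psi$,
and a single residual variance across strains. Estimation is by maximum
likelihood (`lme4::lmer`, `REML = FALSE`). Fixed-effect $t$-tests and
confidence intervals use residual degrees of freedom
$n_{\mathrm{obs}} - n_{\mathrm{fixed}}$, the convention of the MATLAB
mixed-model tooling this analysis style descends from; we deliberately do
not use Satterthwaite approximations. Between-strain contrasts are Wald
tests on the fixed-effect covariance block.

Two degenerate regimes are handled explicitly. A singular fitted $\Psi$ is
refitted with independent (diagonal) random effects, with a warning. Data
whose pooled per-strain OLS fit is exact (zero residuals, hence no
between-group variability at all) collapse analytically to that OLS
solution - the limit the mixed model approaches - rather than being pushed
through an optimizer that cannot represent zero variance. `psi = "none"`
fixes $\Psi = 0$ outright, reducing the model to pooled per-strain OLS with
the Gaussian ML log-likelihood; the mixed-model log-likelihood can never
fall below it (nesting), which is asserted in tests.

With maximum likelihood, variance components are slightly biased downward
in small samples, so per-strain confidence intervals are mildly
anti-conservative below roughly 20 groups; calibration tests therefore run
at the 40-groups-per-strain design where coverage is nominal.

## Intensity statistics

The asymmetry index $|I_{\mathrm{bud}} - I_{\mathrm{mother}}| /
(I_{\mathrm{bud}} + I_{\mathrm{mother}})$ maps a fully symmetric
distribution to 0 and a fully one-sided one to 1; it is symmetric in its
arguments and scale-invariant. Background subtraction is the caller's
responsibility: input tables carry a `background` column and the convention
used to measure it, because slide- versus cell-background conventions
differ between assay types and the package does not segment images.

Stoichiometry calibration divides a reference punctum intensity of known
composition by its molecule number (sites x copies per site) to obtain a
per-molecule brilliance, then divides query intensities by that brilliance.
The aggregator is explicit - the kinetochore reference uses a median,
query puncta a mean - since both conventions occur. Intensities measured
at different exposure times are rescaled by the exposure ratio
(`exposure_scale_factor()`).

Punctum loss is consumed as a per-trajectory flag (with loss time when
known); frequencies over an observation window get Wilson score 95%
confidence intervals. We implement the plain Wilson interval; whether the
"Wilson/Brown" label used in this literature implies any further
modification is unclear, and the plain score interval is the defensible
default. Proportions are compared with the pooled two-proportion $z$-test
(degenerate pooled proportions 0 or 1 give $z = 0$, $p = 1$), continuous
samples with Welch's $t$-test via `stats::t.test`.

## Droplet coalescence and hydrodynamics

A fusing droplet's shape is summarized by the aspect parameter
$A = (L - W)/(L + W)$ of its moment-equivalent ellipse. During relaxation
$A(t) = A_0 e^{-t/\tau}$; the fusion time $\tau$ is obtained by nonlinear
least squares with **no offset term** ($A \to 0$ at full relaxation by
definition), started from a log-linear fit. Measured axes can dip below
each other near relaxation, so the fitting path tolerates slightly negative
$A$; the exported `aspect_parameter()` enforces $L \ge W > 0$. Events whose
aspect series does not decay are flagged and excluded downstream.

The final radius $R$ is, by definition, the radius "in the spherical
state"; with no prescribed estimator we average $(L + W)/4$ over the frames
in the last 10% of the series with $A < 0.05$ (bias $< 0.15\%$ at that
threshold), falling back to the area-based $\sqrt{LW}/2$ when relaxation is
incomplete.

Across events, $\tau$ is regressed on $R$ **through the origin** - physics
forces $\tau(0) = 0$ - giving the inverse capillary velocity $\tau/R
\propto \eta/\gamma$; an intercept option exists for sensitivity checks.
We report $\tau/R$ in s/um: with micrometre-scale droplets and
second-scale fusion times this is the only unit consistent with the
magnitudes encountered, even though s/m labels appear in parts of the
literature.

The full two-viscosity relation is implemented as

$$\tau = \frac{(2\lambda + 3)(19\lambda + 16)}{40(\lambda + 1)}
\frac{\eta_{\mathrm{ext}} R}{\gamma}, \qquad
\lambda = \eta_{\mathrm{int}}/\eta_{\mathrm{ext}},$$

whose high-internal-viscosity limit is $\tau = \tfrac{19}{20}
\eta_{\mathrm{int}} R / \gamma$. The constant 16 is the classical value
and the only one consistent with that $19/20$ limit; a variant coefficient
(169) circulating in print does not reproduce the limit, so we treat it as
typographic and make the constant configurable. Tests assert convergence
of the two forms to within $10^{-3}$ for $\lambda \ge 10^4$.

Ellipse axes can be extracted from binary masks via second central moments
(axis length $4\sqrt{\lambda_i}$ of the coordinate-covariance eigenvalues,
which reproduces the diameter of a disc); the mask must contain a single
connected region.

FRAP traces are corrected in four steps: background-subtract all traces,
normalize each unbleached reference to its pre-bleach mean, divide the
target by the per-frame average of the normalized references, and finally
normalize the corrected target to its own pre-bleach mean, so full recovery
is 1. Partition coefficients are background-subtracted inside/outside
density ratios; a denominator at or below zero means enrichment is
unquantifiable and raises an error rather than returning a misleading
number.

## Phase diagrams

Screening grids record, per (protein concentration, salt) well, whether the
mixture phase separated. Phase separation occurs at *lower* ionic
strength, so for each concentration we take the contiguous separated block
starting from the lowest tested salt and place the boundary at the
**arithmetic midpoint** in salt between the last separated and first
soluble condition. (Midpoints "between the tested conditions" could also
be geometric; arithmetic is the plain reading and is what we implement.)
Columns separated everywhere or nowhere are censored (`above_max`,
`below_min`) rather than extrapolated. Separation reappearing at higher
salt can only arise from classification noise; the lowest-salt block is
used and a warning raised. The recovered boundary is within half the salt
grid spacing of the truth by construction when calls are noise-free, which
is asserted on simulated grids. `critical_concentration()` applies the
same bracketing logic along the concentration axis at fixed salt, and
`compare_binodals()` pairs two boundary sets on common concentrations,
propagating censoring.

## The synthetic-data generator

No microscopy data ship with the package; the generator produces inputs
with the statistical structure the analyses assume, under the acquisition
conditions of the motivating experiments.

* **Trajectories** follow two-state dynamic instability: growth at
  $v_g$ and shrinkage at $v_s$ switch after exponential waiting times with
  catastrophe and rescue rates $f_c$, $f_r$ (a continuous-time Markov
  model). Defaults - $v_g = v_s = 0.02$ um/s, $f_c = f_r = 0.01$/s,
  50 frames at $dt = 3.5$ s - match the scale of the plus-end tracking
  movies (about 3-minute observations with one to three phase switches);
  they are fixture choices, not measured claims. A microtubule shrinking
  to zero length restarts a growth phase by default (puncta re-assemble
  near the SPB and track the next microtubule); this reflection is
  configurable off. Measurement noise on length is additive Gaussian
  (default SD 0.05 um, about a quarter of a pixel-scale step per frame);
  the intensity drifts linearly with phase-dependent rates plus Gaussian
  frame noise, and during shrinkage a constant hazard can delete the
  punctum, after which intensity is missing and the trajectory is flagged
  lost. Gaussian noise is an assumption - the real error distribution of
  spot localization is unknown to us - and is stated as such.
* **Fusion events** conserve cross-sectional area (two equal parents of
  radius $r$ give $R = \sqrt{2} r$, $LW = 4R^2$ exactly) and relax with
  $A(t) = A_0 e^{-t/\tau}$, $\tau = (\text{capillary slope}) \times R$.
  Axis noise is multiplicative, the only reading consistent with a
  dimensionless noise SD.
* **Phase grids** separate below a supplied boundary (function, constant,
  or interpolated table) with independent call-flipping noise.
* **Spindle pairs** split a per-cell total intensity so the noiseless
  asymmetry index equals the requested level, with the bright side chosen
  at random, then add background and noise.

Every generator is seed-deterministic, and seeds restore the caller's RNG
state. What the generator does **not** emulate: 2-D projection of 3-D
distances, point-spread functions or any raster image formation,
photophysics (blinking, bleaching) beyond the FRAP module's needs, tracking
and linking errors, and non-Gaussian measurement noise. Tests passing on
synthetic data therefore validate the estimators against their assumed
model, not the upstream measurement process.

## Numerical choices and problem sizes

All seeds are explicit. The changepoint DP is exact, $O(k n^2)$, sized for
trajectories of tens to hundreds of frames. Exact-fit degeneracies use a
relative floor of $10^{-12}$ times the data's sum of squares. The
nonlinear fusion fit uses Levenberg-Marquardt (`minpack.lm`) with
analytic-free starts from the log-linear fit. Test and verification
problem sizes are chosen to make sampling bands decisive: $\ge 10^4$
completed phases for the waiting-time law (a 5% band at $10^4$ frames
would be narrower than the sampling error and meaningless), 100-200
random fixtures for the exhaustive changepoint oracle ($n \le 60$, $k \le
2$), 100 seeded replicates for fusion-time, annotation-agreement and
mixed-model recovery, and 1000 replicates for the Welch type-I rate.

## Limitations

The package analyses tables, not images: spot detection, tracking, ROI
measurement and phase-state calling from micrographs are upstream of it.
Loss events are consumed as flags, mirroring manual classification; the
optional intensity-threshold heuristic is labelled as a synthetic-data
convenience. The changepoint count selection (BIC) is our choice where
the original tooling's stopping rule is undocumented; the penalty
multiplier is exposed for sensitivity analysis. Mixed models assume
Gaussian residuals, a shared residual variance across strains, and
independent partial trajectories - segments from the same cell are treated
as distinct groups. No multiple-testing correction is applied anywhere;
tests are reported raw.
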
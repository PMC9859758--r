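# tipquant

Quantitative analysis of microtubule **+TIP bodies** — the condensed
assemblies of plus-end tracking proteins (in budding yeast: Kar9, Bim1,
Bik1) that ride the growing ends of astral microtubules — and of the
liquid droplets their purified components form in vitro.

The package is for microscopists and quantitative cell biologists who have
already measured things (punctum–spindle-pole distances, punctum
intensities, droplet ellipse axes, FRAP traces, phase-separation screens)
and need the downstream statistics, fits and phase annotations, all on
plain TSV tables. A seed-deterministic synthetic-data generator produces
every input type with the statistical structure the analyses assume, so
the whole pipeline is testable without any imaging data.

## What it computes

**Growth/shrinkage annotation.** Trajectories of punctum–SPB distance are
annotated in four steps: Savitzky–Golay smoothing (order 1, window 5 — the
centered moving average), exact dynamic-programming changepoint detection
(≤ 5 changepoints, segments ≥ 5 frames, BIC-selected count), refinement of
changepoints to raw-series extrema with topographic prominence ≥ 25% of
the range, and per-segment OLS slope tests at α = 0.05 labelling each
segment growth, shrinkage, or indeterminate.

**Joint rate models.** Per response (length or intensity) and phase, all
strains are fitted jointly by maximum likelihood with the linear
mixed-effects model

&nbsp;&nbsp;&nbsp;&nbsp;y = β₀,strain + β₁,strain·t + b₀ + b₁·t + ε,

random intercept/slope per partial trajectory, Wald t-tests on fixed
effects with residual degrees of freedom, and between-strain contrasts.

**Intensity statistics.** Asymmetry index |I_bud − I_mother| / (I_bud +
I_mother), cumulative intensity, punctum-loss frequency with Wilson 95%
CIs, two-proportion z- and Welch t-tests, exposure-time rescaling, and
stoichiometry calibration: a reference punctum of known composition gives
the brilliance (a.u. per molecule), which converts punctum intensity into
molecule counts.

**Droplet fluidity.** Aspect parameter A = (L − W)/(L + W) of a fusing
droplet decays as A₀·e^(−t/τ); τ is fitted per event, and τ-vs-R through
the origin gives the inverse capillary velocity τ/R ∝ η/γ (s/μm). The
full two-viscosity relaxation relation
τ = (2λ+3)(19λ+16)/(40(λ+1)) · η_ext·R/γ and its high-viscosity limit
τ = (19/20)·η_int·R/γ are provided, plus FRAP reference-droplet
normalization, partition coefficients, and ellipse axes from binary masks.

**Phase diagrams.** Binodal boundaries are built from
concentration × salt screening grids as arithmetic midpoints between the
last phase-separated and first soluble salt per concentration, with
censoring; critical-concentration brackets and binodal comparisons
included.

## Worked example

```r
library(tipquant)

## stoichiometry: kinetochore reference (16 sites x 17 molecules, median
## punctum intensity 912 a.u.) calibrates a.u. per molecule, then converts
## a metaphase punctum of 244 a.u. into a molecule count
br <- brilliance_per_molecule(912, 16, 17)
sprintf("brilliance: %.2f a.u. per molecule", br)
#> "brilliance: 3.35 a.u. per molecule"
sprintf("molecules per punctum: %.1f", molecule_count(244, br))
#> "molecules per punctum: 72.8"

## annotate a simulated punctum-SPB distance trajectory (50 frames, 3.5 s)
tr  <- simulate_trajectory(mt_sim_params(seed = 8, init_length = 1.5),
                           intensity_sim_params(seed = 108))
ann <- annotate_trajectory(tr)
ann$segments
#>   start_frame end_frame      kind   slope intercept  slope_p n_points
#> 1           0        24    growth  0.0193      1.53 3.46e-25       25
#> 2          24        32 shrinkage -0.0212      3.18 7.39e-05        9
#> 3          32        49    growth  0.0188      2.57 5.59e-19       18
```

The trajectory grew at ~0.019 μm/s, suffered a catastrophe at frame 24,
shrank at ~0.021 μm/s, and was rescued at frame 32 (true rates 0.02 μm/s).
Segments feed `extract_partials()` and `fit_lme()` for joint per-strain
rates, or the whole thing runs at once with `run_pipeline()`.

```r
## droplet coalescence: fit one simulated fusion event
ev <- simulate_fusion_event(fusion_sim_params(parent_radius = 1,
        capillary_slope = 11.34, A0 = 0.5, shape_noise_sd = 0.02,
        n_frames = 250, dt = 0.5, seed = 5))
f  <- fit_fusion_time(ev)
sprintf("tau = %.2f s, R = %.2f um, tau/R = %.2f s/um",
        f$tau, f$R, f$tau / f$R)
#> "tau = 16.01 s, R = 1.41 um, tau/R = 11.37 s/um"

## and the slope implied by known material constants
inverse_capillary_velocity(18.2, 7e-6)   # Pa s, N/m -> s/um
#> [1] 2.47
```

The fitted τ/R (11.37 s/μm) recovers the generator's inverse capillary
velocity (11.34 s/μm); 18.2 Pa·s over 7 μN/m predicts 2.47 s/μm.

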
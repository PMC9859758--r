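Package: tipquant
Title: Quantitative Analysis of Microtubule +TIP-Body Dynamics and Condensate Biophysics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify the behaviour of microtubule plus-end tracking
    protein (+TIP) bodies and their in vitro condensates. Annotates growth and
    shrinkage phases of astral microtubules from punctum-to-spindle-pole
    distance trajectories (Savitzky-Golay smoothing, exact piecewise-linear
    changepoint detection, prominence-filtered extremum refinement,
    significance-tested segment slopes), estimates length and intensity change
    rates jointly across strains with linear mixed-effects models, computes
    fluorescence asymmetry and stoichiometry statistics with Wilson binomial
    confidence intervals, fits droplet coalescence relaxation times and
    inverse capillary velocities, normalizes FRAP traces, constructs
    approximate binodal phase boundaries from concentration-salt screening
    grids, and generates synthetic data with the statistical structure the
    analyses assume.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    minpack.lm,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    signal
Config/testthat/edition: 3
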
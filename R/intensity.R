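#' Spindle asymmetry index
#'
#' Absolute difference of the background-subtracted intensities on the two
#' ends of the spindle divided by their sum: `|I_bud - I_mother| /
#' (I_bud + I_mother)`. 0 means a fully symmetric distribution, 1 a fully
#' one-sided one. Symmetric in its arguments and invariant to joint scaling.
#'
#' @param I_bud,I_mother Background-subtracted intensities, a.u. (>= 0, not
#'   both zero). Vectorized.
#' @return Asymmetry index in \[0, 1\].
#' @export
asymmetry_index <- function(I_bud, I_mother) {
  if (any(I_bud < 0 | I_mother < 0)) stop_invalid("intensities must be >= 0")
  s <- I_bud + I_mother
  if (any(s == 0)) stop_invalid("asymmetry index undefined when both intensities are zero")
  abs(I_bud - I_mother) / s
}

#' Cumulative spindle intensity
#'
#' Sum of the background-subtracted intensities on both sides of the spindle.
#'
#' @param I_bud,I_mother Intensities, a.u. Vectorized.
#' @return `I_bud + I_mother`.
#' @export
cumulative_intensity <- function(I_bud, I_mother) I_bud + I_mother

#' Brilliance of a single fluorophore-tagged molecule
#'
#' Calibrates intensity per molecule from a reference punctum of known
#' stoichiometry: the reference punctum intensity divided by the number of
#' sites times the copies per site (e.g. a kinetochore cluster of 16
#' kinetochores with 17 molecules each). Returned at full precision; display
#' convention is two decimals.
#'
#' @param ref_punctum_intensity Aggregate reference punctum intensity, a.u.
#'   (> 0).
#' @param n_sites Number of sites in the reference structure (> 0).
#' @param copies_per_site Molecules per site (> 0).
#' @return Brilliance in a.u. per molecule.
#' @export
brilliance_per_molecule <- function(ref_punctum_intensity, n_sites,
                                    copies_per_site) {
  if (ref_punctum_intensity <= 0 || n_sites <= 0 || copies_per_site <= 0)
    stop_invalid("all calibration inputs must be > 0")
  ref_punctum_intensity / (n_sites * copies_per_site)
}

#' Molecule count from punctum intensity
#'
#' @param punctum_intensity Punctum intensity, a.u. (>= 0).
#' @param brilliance Intensity per molecule, a.u. (> 0); see
#'   [brilliance_per_molecule()].
#' @return Estimated number of molecules.
#' @export
molecule_count <- function(punctum_intensity, brilliance) {
  if (brilliance <= 0) stop_invalid("brilliance must be > 0")
  punctum_intensity / brilliance
}

#' Exposure-time scale factor
#'
#' Factor rescaling intensities acquired at a shorter exposure to a
#' reference exposure (e.g. 250 ms reference over 100 ms measured gives
#' 2.5).
#'
#' @param reference_ms Reference exposure time, ms (> 0).
#' @param measured_ms Exposure time of the measurement, ms (> 0).
#' @return `reference_ms / measured_ms`.
#' @export
exposure_scale_factor <- function(reference_ms, measured_ms) {
  if (reference_ms <= 0 || measured_ms <= 0)
    stop_invalid("exposure times must be > 0")
  reference_ms / measured_ms
}

#' Wilson score confidence interval for a binomial proportion
#'
#' @param successes Number of successes (0 <= successes <= n).
#' @param n Number of trials (>= 1).
#' @param level Confidence level (default 0.95).
#' @return Named numeric vector `c(lo, hi)`.
#' @export
wilson_ci <- function(successes, n, level = 0.95) {
  if (n < 1 || successes < 0 || successes > n)
    stop_invalid("invalid binomial counts")
  if (level <= 0 || level >= 1) stop_invalid("level must be in (0, 1)")
  z <- qnorm(1 - (1 - level) / 2)
  p <- successes / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(lo = max(0, center - hw), hi = min(1, center + hw))
}

#' Punctum-loss frequency with Wilson confidence interval
#'
#' Fraction of trajectories that lose their punctum within an observation
#' window, with the Wilson 95% binomial confidence interval. Loss is
#' consumed as a per-trajectory flag (plus loss time when available); the
#' package does not detect loss from images.
#'
#' @param trajectories Either a list of trajectory `data.frame`s carrying a
#'   `lost` column (and, from the simulator, a `loss_time_s` attribute), or
#'   a logical vector of per-trajectory loss-within-window flags.
#' @param window_s Observation window, s (used when loss times are
#'   available; a loss counts if its time is <= `window_s`). Default 175 s.
#' @param level Confidence level (default 0.95).
#' @return A list of class `"loss_summary"`: `n_lost`, `n_total`,
#'   `window_s`, `fraction`, `ci_lo`, `ci_hi`.
#' @export
loss_frequency <- function(trajectories, window_s = 175, level = 0.95) {
  if (is.logical(trajectories)) {
    lost <- trajectories
  } else {
    lost <- vapply(trajectories, function(tr) {
      fl <- isTRUE(tr$lost[1])
      lt <- attr(tr, "loss_time_s")
      if (fl && !is.null(lt) && !is.na(lt)) lt <= window_s else fl
    }, logical(1))
  }
  n <- length(lost)
  if (n == 0) stop_invalid("no trajectories")
  k <- sum(lost)
  ci <- wilson_ci(k, n, level)
  structure(list(n_lost = k, n_total = n, window_s = window_s,
                 fraction = k / n, ci_lo = ci[["lo"]], ci_hi = ci[["hi"]]),
            class = "loss_summary")
}

#' Two-proportion z-test (pooled)
#'
#' Two-tailed z-test of equality of two binomial proportions using the
#' pooled standard error. When the pooled proportion is 0 or 1 the statistic
#' is degenerate; z is set to 0 and p to 1.
#'
#' @param x1,n1 Successes and trials in group 1 (n1 >= 1).
#' @param x2,n2 Successes and trials in group 2 (n2 >= 1).
#' @return A list: `z`, `p` (two-sided).
#' @export
two_proportion_z <- function(x1, n1, x2, n2) {
  if (n1 < 1 || n2 < 1) stop_invalid("group sizes must be >= 1")
  if (x1 < 0 || x1 > n1 || x2 < 0 || x2 > n2) stop_invalid("invalid counts")
  p1 <- x1 / n1; p2 <- x2 / n2
  pp <- (x1 + x2) / (n1 + n2)
  if (pp <= 0 || pp >= 1) return(list(z = 0, p = 1))
  z <- (p1 - p2) / sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  list(z = z, p = 2 * pnorm(-abs(z)))
}

#' Welch's two-sample t-test
#'
#' Two-tailed Welch t-test (unequal variances, Welch-Satterthwaite degrees
#' of freedom), as used for continuous comparisons between strains or
#' treatments. Delegates to [stats::t.test()]; the degenerate case of two
#' zero-variance samples returns t = 0, p = 1 when the means agree and
#' p = 0 otherwise.
#'
#' @param sample_a,sample_b Numeric samples of at least 2 values each.
#' @return A list: `t`, `df`, `p` (two-sided).
#' @export
welch_t <- function(sample_a, sample_b) {
  if (length(sample_a) < 2 || length(sample_b) < 2)
    stop_invalid("each sample needs >= 2 values")
  if (var(sample_a) + var(sample_b) == 0) {
    eq <- mean(sample_a) == mean(sample_b)
    return(list(t = if (eq) 0 else Inf * sign(mean(sample_a) - mean(sample_b)),
                df = NA_real_, p = if (eq) 1 else 0))
  }
  ht <- t.test(sample_a, sample_b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}
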
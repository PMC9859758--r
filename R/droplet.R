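#' Aspect parameter of a deformed droplet
#'
#' `A = (L - W) / (L + W)` for major axis `L` and minor axis `W` of the
#' moment-equivalent ellipse of a fusing droplet. 0 for a sphere; decays
#' exponentially with the fusion time during coalescence relaxation.
#'
#' @param L Major axis, um (L >= W). Vectorized.
#' @param W Minor axis, um (> 0).
#' @return Aspect parameter in \[0, 1).
#' @export
aspect_parameter <- function(L, W) {
  if (any(W <= 0)) stop_invalid("minor axis must be > 0")
  if (any(L < W)) stop_invalid("major axis must be >= minor axis")
  (L - W) / (L + W)
}

# Noise-tolerant aspect parameter used for fitting: measured L can dip
# below W near full relaxation, giving small negative A values.
aspect_raw <- function(L, W) (L - W) / (L + W)

#' Fit the fusion time of a coalescence event
#'
#' Computes the aspect parameter per frame and fits `A(t) = A0 * exp(-t /
#' tau)` by nonlinear least squares (no offset: A relaxes to 0 by
#' definition). The final spherical radius `R` is estimated as the mean of
#' `(L + W) / 4` over the frames in the last 10% of the series that are
#' relaxed (`A < 0.05`); if none qualify, the area-based fallback
#' `sqrt(L * W) / 2` averaged over the last 10% of frames is used.
#'
#' Non-decaying events (no positive-slope decay, fitted `tau <= 0`, or
#' optimizer failure) are returned with `ok = FALSE` and should be excluded
#' downstream.
#'
#' @param event A `data.frame` with columns `time_s`, `L_um`, `W_um` (and
#'   optionally `event_id`), e.g. from [simulate_fusion_event()] or
#'   [read_fusion_events()].
#' @param min_frames Minimum frames required (default 5).
#' @return A list of class `"fusion_fit"`: `event_id`, `A0`, `tau`, `R`,
#'   `rss`, `n_frames`, `ok` (and `message` when `ok` is `FALSE`).
#' @export
fit_fusion_time <- function(event, min_frames = 5) {
  n <- nrow(event)
  if (n < min_frames) stop_invalid("need >= ", min_frames, " frames")
  id <- if (!is.null(event$event_id)) as.character(event$event_id[1]) else NA_character_
  t <- event$time_s
  A <- aspect_raw(event$L_um, event$W_um)
  fail <- function(msg) structure(
    list(event_id = id, A0 = NA_real_, tau = NA_real_, R = NA_real_,
         rss = NA_real_, n_frames = n, ok = FALSE, message = msg),
    class = "fusion_fit")

  # starting values from a log-linear fit on clearly positive A
  pos <- A > max(A, 0) * 1e-3 & A > 0
  if (sum(pos) < 3) return(fail("too few positive aspect values"))
  st <- lm(log(A[pos]) ~ t[pos])
  if (coef(st)[2] >= 0) return(fail("aspect parameter does not decay"))
  start <- list(A0 = exp(unname(coef(st)[1])), tau = -1 / unname(coef(st)[2]))

  fit <- tryCatch(
    minpack.lm::nlsLM(A ~ A0 * exp(-t / tau), start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error")) return(fail(conditionMessage(fit)))
  cf <- coef(fit)
  if (!is.finite(cf[["tau"]]) || cf[["tau"]] <= 0 || cf[["A0"]] <= 0)
    return(fail("non-physical fit"))

  tail_idx <- seq.int(n - ceiling(0.1 * n) + 1L, n)
  relaxed <- tail_idx[A[tail_idx] < 0.05]
  R <- if (length(relaxed) > 0)
    mean((event$L_um[relaxed] + event$W_um[relaxed]) / 4)
  else
    mean(sqrt(pmax(event$L_um[tail_idx] * event$W_um[tail_idx], 0)) / 2)

  structure(list(event_id = id, A0 = unname(cf[["A0"]]),
                 tau = unname(cf[["tau"]]), R = R,
                 rss = sum(stats::resid(fit)^2), n_frames = n, ok = TRUE),
            class = "fusion_fit")
}

#' Inverse capillary velocity from a collection of fusion fits
#'
#' Least-squares fit of fusion time on final radius through the origin
#' (physically tau(0) = 0): the slope is the inverse capillary velocity
#' tau/R in s/um, proportional to the ratio of condensed-phase viscosity to
#' surface tension. An intercept can be allowed for sensitivity checks.
#'
#' @param fits A list of `"fusion_fit"` objects (failed fits are dropped),
#'   or a `data.frame` with columns `tau` and `R`.
#' @param intercept If `TRUE`, fit `tau ~ R` with an intercept instead of
#'   through the origin (default `FALSE`).
#' @return A list of class `"capillary_fit"`: `slope` (s/um), `stderr` (`NA`
#'   with a single droplet), `intercept` (0 unless requested), `n_droplets`.
#' @export
fit_capillary_slope <- function(fits, intercept = FALSE) {
  if (is.data.frame(fits)) {
    d <- fits
  } else {
    if (inherits(fits, "fusion_fit")) fits <- list(fits)
    ok <- vapply(fits, function(f) isTRUE(f$ok), logical(1))
    d <- data.frame(tau = vapply(fits[ok], `[[`, numeric(1), "tau"),
                    R = vapply(fits[ok], `[[`, numeric(1), "R"))
  }
  if (nrow(d) == 0) stop_invalid("no successful fusion fits")
  if (nrow(d) == 1 && !intercept) {
    return(structure(list(slope = d$tau / d$R, stderr = NA_real_,
                          intercept = 0, n_droplets = 1L),
                     class = "capillary_fit"))
  }
  fit <- if (intercept) lm(tau ~ R, data = d) else lm(tau ~ 0 + R, data = d)
  sm <- suppressWarnings(summary(fit))$coefficients  # exact data warns harmlessly
  structure(list(slope = sm["R", "Estimate"],
                 stderr = if (nrow(d) > (1 + intercept)) sm["R", "Std. Error"]
                          else NA_real_,
                 intercept = if (intercept) sm["(Intercept)", "Estimate"] else 0,
                 n_droplets = nrow(d)),
            class = "capillary_fit")
}

#' Hydrodynamic parameters of a droplet two-phase system
#'
#' @param eta_int Condensed (internal) phase viscosity, Pa s (> 0).
#' @param eta_ext Dilute (external) phase viscosity, Pa s (> 0).
#' @param gamma Surface tension, N/m (> 0).
#' @return A list of class `"hydrodynamic_params"` with the viscosity ratio
#'   `lambda = eta_int / eta_ext`.
#' @export
hydrodynamic_params <- function(eta_int, eta_ext, gamma) {
  if (eta_int <= 0 || eta_ext <= 0 || gamma <= 0)
    stop_invalid("all hydrodynamic parameters must be > 0")
  structure(list(eta_int = eta_int, eta_ext = eta_ext,
                 lambda = eta_int / eta_ext, gamma = gamma),
            class = "hydrodynamic_params")
}

#' Fusion time from the full two-viscosity relaxation relation
#'
#' Coalescence relaxation time of a droplet of final radius `R` suspended in
#' a medium of viscosity `eta_ext`, from the Navier-Stokes small-deformation
#' result `tau = (2 lambda + 3)(19 lambda + 16) / (40 (lambda + 1)) *
#' eta_ext * R / gamma`, with `lambda = eta_int / eta_ext`. In the high
#' internal-viscosity limit this reduces to [eq2_fusion_time()],
#' `tau = (19/20) eta_int R / gamma`. The constant 16 in the second factor
#' is configurable; it is the value consistent with that limit.
#'
#' @param h A [hydrodynamic_params()] object.
#' @param R_um Final droplet radius, um (> 0). Vectorized.
#' @param second_factor_const Constant in the `(19 lambda + c)` factor
#'   (default 16).
#' @return Fusion time tau, s.
#' @export
eq1_fusion_time <- function(h, R_um, second_factor_const = 16) {
  stopifnot(inherits(h, "hydrodynamic_params"))
  if (any(R_um <= 0)) stop_invalid("R must be > 0")
  l <- h$lambda
  pref <- (2 * l + 3) * (19 * l + second_factor_const) / (40 * (l + 1))
  pref * h$eta_ext * (R_um * 1e-6) / h$gamma
}

#' Fusion time in the high internal-viscosity limit
#'
#' `tau = (19/20) * eta_int * R / gamma`, valid when the condensed-phase
#' viscosity greatly exceeds the dilute-phase viscosity.
#'
#' @param eta_int Condensed-phase viscosity, Pa s (> 0).
#' @param R_um Final droplet radius, um (> 0). Vectorized.
#' @param gamma Surface tension, N/m (> 0).
#' @return Fusion time tau, s.
#' @export
eq2_fusion_time <- function(eta_int, R_um, gamma) {
  if (eta_int <= 0 || gamma <= 0 || any(R_um <= 0))
    stop_invalid("inputs must be > 0")
  (19 / 20) * eta_int * (R_um * 1e-6) / gamma
}

#' Inverse capillary velocity from material parameters
#'
#' The slope tau/R implied by the high internal-viscosity limit:
#' `(19/20) * eta_int / gamma`, reported in s/um.
#'
#' @param eta_int Condensed-phase viscosity, Pa s (> 0).
#' @param gamma Surface tension, N/m (> 0).
#' @return Inverse capillary velocity, s/um.
#' @export
inverse_capillary_velocity <- function(eta_int, gamma) {
  if (eta_int <= 0 || gamma <= 0) stop_invalid("inputs must be > 0")
  (19 / 20) * eta_int / gamma * 1e-6
}

# Vectorized flood fill: number of 8-connected foreground components.
count_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  comp <- 0L
  shift <- function(m, dr, dc) {
    out <- matrix(FALSE, nrow(m), ncol(m))
    r <- seq_len(nrow(m)); c <- seq_len(ncol(m))
    rs <- r + dr; cs <- c + dc
    keep_r <- rs >= 1 & rs <= nrow(m); keep_c <- cs >= 1 & cs <= ncol(m)
    out[r[keep_r], c[keep_c]] <- m[rs[keep_r], cs[keep_c]]
    out
  }
  todo <- mask
  while (any(todo)) {
    comp <- comp + 1L
    seedidx <- which(todo)[1]
    cur <- matrix(FALSE, nrow(mask), ncol(mask)); cur[seedidx] <- TRUE
    repeat {
      grown <- cur
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        grown <- grown | shift(cur, dr, dc)
      }
      grown <- grown & mask
      if (!any(grown & !cur)) break
      cur <- grown
    }
    lab[cur] <- comp
    todo <- todo & !cur
  }
  comp
}

#' Ellipse axes of a binary mask region
#'
#' Major and minor axis lengths of the moment-equivalent ellipse of a single
#' connected foreground region, from the eigenvalues of the second central
#' moments of the pixel coordinates: axis length `= 4 * sqrt(eigenvalue)`,
#' reproducing the diameter for a disc.
#'
#' @param mask A logical or 0/1 numeric matrix with a single 8-connected
#'   foreground region.
#' @param check_connectivity If `TRUE` (default), error when the foreground
#'   has more than one connected component.
#' @return Named numeric vector `c(L, W)` in pixels, `L >= W`.
#' @export
ellipse_axes_from_mask <- function(mask, check_connectivity = TRUE) {
  m <- mask != 0
  if (!any(m)) stop_invalid("empty mask")
  if (check_connectivity && count_components(m) > 1)
    stop_invalid("mask contains more than one connected region")
  idx <- which(m, arr.ind = TRUE)
  x <- idx[, 2]; y <- idx[, 1]
  mu20 <- mean((x - mean(x))^2)
  mu02 <- mean((y - mean(y))^2)
  mu11 <- mean((x - mean(x)) * (y - mean(y)))
  tr <- mu20 + mu02
  det <- mu20 * mu02 - mu11^2
  disc <- sqrt(max(tr^2 / 4 - det, 0))
  ev <- c(tr / 2 + disc, tr / 2 - disc)
  c(L = 4 * sqrt(max(ev[1], 0)), W = 4 * sqrt(max(ev[2], 0)))
}

#' Reference-corrected FRAP normalization
#'
#' Corrects a bleached droplet's recovery trace for acquisition bleaching
#' and focus drift using unbleached reference droplets: all traces are
#' background-subtracted; each reference is normalized to its own
#' pre-bleach mean; the target is divided by the per-frame average of the
#' normalized references; finally the corrected target is normalized to its
#' own pre-bleach mean, so full recovery corresponds to 1.
#'
#' @param target Numeric intensity trace of the bleached droplet.
#' @param references A numeric vector (one reference), a matrix with one
#'   column per reference, or a list of vectors; all on the target's time
#'   base.
#' @param bleach_frame Index of the last pre-bleach frame (>= 1); frames
#'   `1..bleach_frame` are pre-bleach.
#' @param background Background intensity subtracted from every trace
#'   (scalar or per-frame vector; default 0).
#' @return Normalized target trace (pre-bleach mean 1).
#' @export
frap_normalize <- function(target, references, bleach_frame, background = 0) {
  n <- length(target)
  if (is.list(references)) references <- do.call(cbind, references)
  refs <- as.matrix(references)
  if (nrow(refs) != n) stop_invalid("references must share the target's time base")
  if (bleach_frame < 1 || bleach_frame >= n)
    stop_invalid("no pre-bleach (or no post-bleach) frames")
  pre <- seq_len(bleach_frame)
  tgt <- target - background
  refs <- refs - background
  if (any(refs <= 0)) stop_invalid("zero or negative reference intensity after background subtraction")
  refn <- sweep(refs, 2, colMeans(refs[pre, , drop = FALSE]), `/`)
  corr <- tgt / rowMeans(refn)
  pre_mean <- mean(corr[pre])
  if (pre_mean <= 0) stop_invalid("non-positive pre-bleach target intensity")
  corr / pre_mean
}

#' Droplet partition coefficient
#'
#' Background-subtracted ratio of integrated density inside versus outside
#' droplets: `(inside - background) / (outside - background)`. The same
#' background convention (unlabelled protein mixture) must be used for all
#' three inputs.
#'
#' @param inside_density Integrated density inside droplets, a.u.
#' @param outside_density Integrated density outside droplets, a.u.
#' @param background_density Background integrated density, a.u. (default 0).
#' @return Enrichment ratio (vectorized).
#' @export
partition_coefficient <- function(inside_density, outside_density,
                                  background_density = 0) {
  denom <- outside_density - background_density
  if (any(denom <= 0))
    stop_invalid("outside density must exceed background (enrichment unquantifiable)")
  (inside_density - background_density) / denom
}
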
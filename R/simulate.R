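#' Parameters for the dynamic-instability trajectory simulator
#'
#' Bundles the kinetic and acquisition parameters of the two-state
#' (growth/shrinkage) microtubule model used by [simulate_trajectory()].
#' Catastrophes (growth to shrinkage) and rescues (shrinkage to growth)
#' occur after exponential waiting times with rates `f_cat` and `f_res`.
#'
#' @param v_growth Growth speed, um/s (> 0).
#' @param v_shrink Shrinkage speed, um/s (> 0).
#' @param f_cat Catastrophe rate, 1/s (>= 0).
#' @param f_res Rescue rate, 1/s (>= 0).
#' @param len_noise_sd SD of additive Gaussian measurement noise on length, um.
#' @param n_frames Number of acquired frames (>= 2).
#' @param dt Frame interval, s. Default 3.5 s, the acquisition interval of the
#'   plus-end tracking movies this simulator emulates.
#' @param init_length Initial microtubule length, um (>= 0).
#' @param init_state Initial phase, `"growth"` or `"shrinkage"`.
#' @param reflect If `TRUE` (default), a microtubule shrinking to length 0
#'   immediately restarts a growth phase (puncta re-assembling next to the
#'   spindle pole body and tracking the next emerging microtubule). If
#'   `FALSE`, length stays at 0 until the rescue clock fires.
#' @param seed Integer seed for reproducibility, or `NULL`.
#' @return A list of class `"mt_sim_params"`.
#' @export
mt_sim_params <- function(v_growth = 0.02, v_shrink = 0.02,
                          f_cat = 0.01, f_res = 0.01,
                          len_noise_sd = 0.05, n_frames = 50, dt = 3.5,
                          init_length = 0.5, init_state = c("growth", "shrinkage"),
                          reflect = TRUE, seed = NULL) {
  init_state <- match.arg(init_state)
  if (n_frames < 2) stop_invalid("n_frames must be >= 2")
  if (dt <= 0) stop_invalid("dt must be > 0")
  if (v_growth <= 0 || v_shrink <= 0) stop_invalid("speeds must be > 0")
  if (f_cat < 0 || f_res < 0) stop_invalid("switch rates must be >= 0")
  if (len_noise_sd < 0) stop_invalid("len_noise_sd must be >= 0")
  if (init_length < 0) stop_invalid("init_length must be >= 0")
  structure(list(v_growth = v_growth, v_shrink = v_shrink, f_cat = f_cat,
                 f_res = f_res, len_noise_sd = len_noise_sd,
                 n_frames = as.integer(n_frames), dt = dt,
                 init_length = init_length, init_state = init_state,
                 reflect = reflect, seed = seed),
            class = "mt_sim_params")
}

#' Parameters for the punctum-intensity simulator
#'
#' Intensity drifts linearly with phase-dependent rates (the punctum brightens
#' while the microtubule grows and dims while it shrinks), with additive
#' Gaussian frame noise. During shrinkage the punctum can be lost
#' (constant hazard); intensity is missing from the loss time onwards.
#'
#' @param base_intensity Intensity at time 0, a.u. (> 0).
#' @param drift_growth Intensity change rate during growth, a.u./s.
#' @param drift_shrink Intensity change rate during shrinkage, a.u./s.
#' @param noise_sd SD of additive Gaussian frame noise, a.u. (>= 0).
#' @param loss_hazard_shrink Punctum-loss hazard during shrinkage, 1/s (>= 0).
#' @param seed Integer seed, or `NULL`.
#' @return A list of class `"intensity_sim_params"`.
#' @export
intensity_sim_params <- function(base_intensity = 100, drift_growth = 0.2,
                                 drift_shrink = -0.4, noise_sd = 5,
                                 loss_hazard_shrink = 0.004, seed = NULL) {
  if (base_intensity <= 0) stop_invalid("base_intensity must be > 0")
  if (noise_sd < 0) stop_invalid("noise_sd must be >= 0")
  if (loss_hazard_shrink < 0) stop_invalid("loss_hazard_shrink must be >= 0")
  structure(list(base_intensity = base_intensity, drift_growth = drift_growth,
                 drift_shrink = drift_shrink, noise_sd = noise_sd,
                 loss_hazard_shrink = loss_hazard_shrink, seed = seed),
            class = "intensity_sim_params")
}

#' Parameters for the droplet-coalescence simulator
#'
#' Two equal parent droplets of radius `parent_radius` fuse; cross-sectional
#' area is conserved, so the final spherical radius is `sqrt(2) *
#' parent_radius`. The aspect parameter A = (L - W)/(L + W) relaxes as
#' `A0 * exp(-t / tau)` with `tau = capillary_slope * R` (inverse capillary
#' velocity times final radius).
#'
#' @param parent_radius Radius of each parent droplet, um (> 0).
#' @param capillary_slope Inverse capillary velocity tau/R, s/um (> 0).
#' @param A0 Initial aspect parameter, in (0, 1).
#' @param shape_noise_sd SD of multiplicative Gaussian noise applied
#'   independently to the measured major and minor axes (dimensionless, >= 0).
#' @param n_frames Number of frames (>= 2).
#' @param dt Frame interval, s (> 0).
#' @param seed Integer seed, or `NULL`.
#' @return A list of class `"fusion_sim_params"`.
#' @export
fusion_sim_params <- function(parent_radius = 1, capillary_slope = 2.25,
                              A0 = 0.5, shape_noise_sd = 0,
                              n_frames = 60, dt = 1, seed = NULL) {
  if (parent_radius <= 0) stop_invalid("parent_radius must be > 0")
  if (capillary_slope <= 0) stop_invalid("capillary_slope must be > 0")
  if (A0 <= 0 || A0 >= 1) stop_invalid("A0 must lie strictly in (0, 1)")
  if (shape_noise_sd < 0) stop_invalid("shape_noise_sd must be >= 0")
  if (n_frames < 2 || dt <= 0) stop_invalid("need n_frames >= 2 and dt > 0")
  structure(list(parent_radius = parent_radius,
                 capillary_slope = capillary_slope, A0 = A0,
                 shape_noise_sd = shape_noise_sd,
                 n_frames = as.integer(n_frames), dt = dt, seed = seed),
            class = "fusion_sim_params")
}

# Continuous-time two-state trajectory: returns a data.frame of phase
# segments (t_start, t_end, state, len_start) covering [0, t_end_total].
simulate_phase_path <- function(mt, t_end_total) {
  state <- mt$init_state
  len <- mt$init_length
  cur_t <- 0
  seg_start <- numeric(0); seg_end <- numeric(0)
  seg_state <- character(0); seg_len0 <- numeric(0)
  while (cur_t < t_end_total) {
    rate <- if (state == "growth") mt$f_cat else mt$f_res
    dwell <- if (rate <= 0) Inf else rexp(1L, rate)
    if (state == "shrinkage") {
      t_zero <- len / mt$v_shrink
      if (t_zero < dwell) {
        # microtubule fully depolymerizes before rescue
        seg_start <- c(seg_start, cur_t); seg_end <- c(seg_end, cur_t + t_zero)
        seg_state <- c(seg_state, "shrinkage"); seg_len0 <- c(seg_len0, len)
        cur_t <- cur_t + t_zero
        len <- 0
        if (mt$reflect) {
          state <- "growth"
        } else {
          # hold at zero (still shrinkage-labelled) until the rescue fires
          hold <- dwell - t_zero
          seg_start <- c(seg_start, cur_t); seg_end <- c(seg_end, cur_t + hold)
          seg_state <- c(seg_state, "paused"); seg_len0 <- c(seg_len0, 0)
          cur_t <- cur_t + hold
          state <- "growth"
        }
        next
      }
    }
    seg_start <- c(seg_start, cur_t); seg_end <- c(seg_end, cur_t + dwell)
    seg_state <- c(seg_state, state); seg_len0 <- c(seg_len0, len)
    len <- len + dwell * if (state == "growth") mt$v_growth else -mt$v_shrink
    cur_t <- cur_t + dwell
    state <- if (state == "growth") "shrinkage" else "growth"
  }
  seg_end[length(seg_end)] <- min(seg_end[length(seg_end)], t_end_total)
  data.frame(t_start = seg_start, t_end = seg_end, state = seg_state,
             len_start = seg_len0)
}

#' Simulate a punctum--SPB distance and intensity trajectory
#'
#' Generates one trajectory of microtubule length (the distance between a
#' fluorescent +TIP punctum and the spindle pole body) and punctum intensity
#' under the two-state dynamic-instability model of [mt_sim_params()] and the
#' phase-dependent intensity drift model of [intensity_sim_params()].
#'
#' The true length is piecewise linear in time (slope `+v_growth` during
#' growth, `-v_shrink` during shrinkage); observed length adds Gaussian noise.
#' Intensity drifts linearly with phase-dependent rates plus frame noise;
#' during shrinkage a loss event (constant hazard `loss_hazard_shrink`)
#' truncates the intensity record, which is missing (`NA`) thereafter, and
#' flags the trajectory as lost.
#'
#' @param mt An [mt_sim_params()] object.
#' @param inten An [intensity_sim_params()] object.
#' @param cell_id,punctum_id,strain Labels attached to every frame.
#' @return A `data.frame` with columns `cell_id`, `punctum_id`, `strain`,
#'   `frame` (0-based), `time_s`, `true_phase` (`"growth"`/`"shrinkage"`),
#'   `length_true_um`, `length_um`, `intensity_au` (NA after punctum loss) and
#'   `lost` (same value on all rows). Attributes: `loss_time_s` (NA if not
#'   lost) and `phase_segments` (the continuous-time ground-truth path).
#' @export
simulate_trajectory <- function(mt, inten = intensity_sim_params(),
                                cell_id = "cell1", punctum_id = "p1",
                                strain = "wt") {
  stopifnot(inherits(mt, "mt_sim_params"),
            inherits(inten, "intensity_sim_params"))
  n <- mt$n_frames
  t_frames <- (seq_len(n) - 1) * mt$dt
  t_total <- t_frames[n]

  path <- with_seed(mt$seed, {
    p <- simulate_phase_path(mt, t_total)
    attr(p, "frame_noise") <-
      if (mt$len_noise_sd > 0) rnorm(n, 0, mt$len_noise_sd) else numeric(n)
    p
  })
  frame_noise <- attr(path, "frame_noise")

  # locate each frame's segment; frames at a switch time belong to the new one
  idx <- findInterval(t_frames, path$t_start)
  slope_of <- function(state) switch(state, growth = mt$v_growth,
                                     shrinkage = -mt$v_shrink, paused = 0)
  seg_slope <- vapply(path$state, slope_of, numeric(1))
  len_true <- path$len_start[idx] + seg_slope[idx] * (t_frames - path$t_start[idx])
  len_true <- pmax(len_true, 0)
  phase <- ifelse(path$state[idx] == "paused", "shrinkage", path$state[idx])

  # intensity: integrate the drift over segments, then add frame noise
  drift_of <- function(state) switch(state, growth = inten$drift_growth,
                                     shrinkage = inten$drift_shrink, paused = inten$drift_shrink)
  seg_drift <- vapply(path$state, drift_of, numeric(1))
  seg_dur <- path$t_end - path$t_start
  i_start <- inten$base_intensity + c(0, cumsum(seg_drift * seg_dur))[seq_len(nrow(path))]
  inten_true <- i_start[idx] + seg_drift[idx] * (t_frames - path$t_start[idx])

  loss_time <- NA_real_
  inten_obs <- with_seed(inten$seed, {
    obs <- inten_true +
      if (inten$noise_sd > 0) rnorm(n, 0, inten$noise_sd) else 0
    if (inten$loss_hazard_shrink > 0) {
      shr <- which(path$state %in% c("shrinkage", "paused"))
      for (s in shr) {
        cand <- rexp(1L, inten$loss_hazard_shrink)
        if (cand <= seg_dur[s]) { loss_time <- path$t_start[s] + cand; break }
      }
    }
    obs
  })
  lost <- !is.na(loss_time)
  if (lost) inten_obs[t_frames >= loss_time] <- NA_real_

  out <- data.frame(cell_id = cell_id, punctum_id = punctum_id, strain = strain,
                    frame = seq_len(n) - 1L, time_s = t_frames,
                    true_phase = phase, length_true_um = len_true,
                    length_um = len_true + frame_noise,
                    intensity_au = inten_obs, lost = lost)
  attr(out, "loss_time_s") <- loss_time
  attr(out, "phase_segments") <- path
  out
}

#' Simulate a droplet coalescence event
#'
#' Generates a time series of major (`L`) and minor (`W`) ellipse axes of a
#' relaxing fused droplet. Cross-sectional area is conserved
#' (`L * W = 4 R^2` at every frame before noise, with `R = sqrt(2) *
#' parent_radius`), and the aspect parameter `A = (L - W)/(L + W)` decays as
#' `A0 * exp(-t / tau)` with `tau = capillary_slope * R`.
#'
#' @param p A [fusion_sim_params()] object.
#' @param event_id Label for the event.
#' @return A `data.frame` with columns `event_id`, `frame`, `time_s`, `L_um`,
#'   `W_um`, and attributes `tau_true`, `R_true`, `A0` (ground truth).
#' @export
simulate_fusion_event <- function(p, event_id = "event1") {
  stopifnot(inherits(p, "fusion_sim_params"))
  R <- sqrt(2) * p$parent_radius
  tau <- p$capillary_slope * R
  t <- (seq_len(p$n_frames) - 1) * p$dt
  A <- p$A0 * exp(-t / tau)
  s <- (1 + A) / (1 - A)              # axis ratio L/W
  L <- 2 * R * sqrt(s)
  W <- 2 * R / sqrt(s)
  if (p$shape_noise_sd > 0) {
    eps <- with_seed(p$seed, rnorm(2L * p$n_frames, 0, p$shape_noise_sd))
    L <- L * (1 + eps[seq_len(p$n_frames)])
    W <- W * (1 + eps[p$n_frames + seq_len(p$n_frames)])
  }
  out <- data.frame(event_id = event_id, frame = seq_len(p$n_frames) - 1L,
                    time_s = t, L_um = L, W_um = W)
  attr(out, "tau_true") <- tau
  attr(out, "R_true") <- R
  attr(out, "A0") <- p$A0
  out
}

#' Simulate a phase-separation screening grid
#'
#' Emulates a concentration-by-salt droplet-formation screen: a well phase
#' separates when its salt concentration lies below the binodal boundary at
#' its protein concentration, and each call is then flipped independently
#' with probability `flip_prob` (classification noise).
#'
#' @param binodal_salt_of_conc Boundary salt (mM) as a function of protein
#'   concentration (uM): an R function, a single number (flat boundary), or a
#'   two-column `data.frame`/matrix (conc, salt) interpolated linearly and
#'   extended flat beyond its range.
#' @param conc_list Protein concentrations to test, uM.
#' @param salt_list Salt concentrations to test, mM.
#' @param flip_prob Probability of flipping each call, in \[0, 1\].
#' @param seed Integer seed, or `NULL`.
#' @return A `data.frame` with columns `protein_uM`, `nacl_mM`, `separated`
#'   (logical), one row per grid point.
#' @export
simulate_phase_grid <- function(binodal_salt_of_conc, conc_list, salt_list,
                                flip_prob = 0, seed = NULL) {
  if (flip_prob < 0 || flip_prob > 1) stop_invalid("flip_prob must be in [0, 1]")
  f <- binodal_salt_of_conc
  if (is.numeric(f) && length(f) == 1L) {
    b <- f; f <- function(conc) rep(b, length(conc))
  } else if (is.data.frame(f) || is.matrix(f)) {
    tab <- as.data.frame(f)
    f <- stats::approxfun(tab[[1]], tab[[2]], rule = 2)
  }
  stopifnot(is.function(f))
  g <- expand.grid(protein_uM = conc_list, nacl_mM = salt_list,
                   KEEP.OUT.ATTRS = FALSE)
  sep <- g$nacl_mM < f(g$protein_uM)
  if (flip_prob > 0) {
    flip <- with_seed(seed, runif(nrow(g)) < flip_prob)
    sep <- xor(sep, flip)
  }
  data.frame(protein_uM = g$protein_uM, nacl_mM = g$nacl_mM, separated = sep)
}

#' Simulate paired bud/mother spindle-end intensities
#'
#' Draws per-cell total punctum intensity, splits it between the bud- and
#' mother-proximal ends of the spindle so that the noiseless asymmetry index
#' `|I_bud - I_mother| / (I_bud + I_mother)` equals `asym_level` (the brighter
#' side is chosen at random), then adds background and measurement noise.
#'
#' @param n_cells Number of cells.
#' @param asym_level Target asymmetry index, in \[0, 1\].
#' @param total_intensity_mean,total_intensity_sd Mean and SD of the per-cell
#'   total (background-free) intensity, a.u.
#' @param background Background level added to each side, a.u.
#' @param noise_sd SD of additive measurement noise per side, a.u.
#' @param seed Integer seed, or `NULL`.
#' @return A `data.frame` with columns `cell_id`, `I_bud`, `I_mother`,
#'   `background` (as-measured; subtract `background` before computing
#'   indices).
#' @export
simulate_spindle_intensities <- function(n_cells, asym_level,
                                         total_intensity_mean = 200,
                                         total_intensity_sd = 0,
                                         background = 0, noise_sd = 0,
                                         seed = NULL) {
  if (asym_level < 0 || asym_level > 1) stop_invalid("asym_level must be in [0, 1]")
  if (n_cells < 1) stop_invalid("n_cells must be >= 1")
  with_seed(seed, {
    total <- rnorm(n_cells, total_intensity_mean, total_intensity_sd)
    total <- pmax(total, 0)
    hi <- total * (1 + asym_level) / 2
    lo <- total * (1 - asym_level) / 2
    bud_is_hi <- runif(n_cells) < 0.5
    I_bud <- ifelse(bud_is_hi, hi, lo)
    I_mother <- ifelse(bud_is_hi, lo, hi)
    if (noise_sd > 0) {
      I_bud <- I_bud + rnorm(n_cells, 0, noise_sd)
      I_mother <- I_mother + rnorm(n_cells, 0, noise_sd)
    }
    data.frame(cell_id = sprintf("cell%03d", seq_len(n_cells)),
               I_bud = I_bud + background, I_mother = I_mother + background,
               background = background)
  })
}
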
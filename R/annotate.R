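#' Configuration for growth/shrinkage phase annotation
#'
#' Parameters of the four-step annotation of microtubule length trajectories:
#' (1) Savitzky-Golay smoothing, (2) piecewise-linear changepoint detection on
#' the smoothed series, (3) refinement of changepoints to nearby
#' prominence-filtered extrema of the raw series, (4) classification of the
#' resulting segments by the sign and significance of their OLS slopes.
#'
#' @param sg_polyorder Savitzky-Golay polynomial order (default 1).
#' @param sg_window Savitzky-Golay window length in frames, odd (default 5).
#' @param max_changes Maximum number of changepoints per trajectory (default 5).
#' @param min_distance Minimum segment length in frames between changepoints,
#'   also enforced at the trajectory ends (default 5).
#' @param prominence_frac Minimum topographic prominence of a refining
#'   extremum, as a fraction of the raw series' full range (default 0.25).
#' @param alpha Significance level of the two-sided slope t-test (default 0.05).
#' @param min_segment_points Minimum frames for a segment to be classified;
#'   shorter segments are indeterminate (default 3, the minimum leaving one
#'   residual degree of freedom for the slope t-test).
#' @param bic_penalty Multiplier on the BIC complexity penalty used to select
#'   the number of changepoints (default 1).
#' @return A list of class `"annotation_config"`.
#' @export
annotation_config <- function(sg_polyorder = 1, sg_window = 5, max_changes = 5,
                              min_distance = 5, prominence_frac = 0.25,
                              alpha = 0.05, min_segment_points = 3,
                              bic_penalty = 1) {
  if (sg_window < 3 || sg_window %% 2 == 0) stop_invalid("sg_window must be odd and >= 3")
  if (sg_polyorder < 0 || sg_polyorder >= sg_window) stop_invalid("invalid sg_polyorder")
  if (alpha <= 0 || alpha >= 1) stop_invalid("alpha must be in (0, 1)")
  if (prominence_frac <= 0 || prominence_frac > 1) stop_invalid("prominence_frac must be in (0, 1]")
  if (min_distance < 1 || max_changes < 0) stop_invalid("invalid changepoint constraints")
  if (min_segment_points < 2) stop_invalid("min_segment_points must be >= 2")
  structure(list(sg_polyorder = sg_polyorder, sg_window = as.integer(sg_window),
                 max_changes = as.integer(max_changes),
                 min_distance = as.integer(min_distance),
                 prominence_frac = prominence_frac, alpha = alpha,
                 min_segment_points = as.integer(min_segment_points),
                 bic_penalty = bic_penalty),
            class = "annotation_config")
}

#' Savitzky-Golay smoothing with shrink-window edge handling
#'
#' Central-point least-squares polynomial smoothing. With polynomial order 1
#' and a symmetric window this is exactly the centered moving average. Near
#' the edges the window is shrunk symmetrically to the available points
#' rather than padding or reflecting the data.
#'
#' @param y Numeric series (no missing values).
#' @param config An [annotation_config()]; `sg_polyorder` and `sg_window` are
#'   used.
#' @return Smoothed numeric series of the same length. A series shorter than
#'   the window is returned unchanged with a warning.
#' @export
smooth_trajectory <- function(y, config = annotation_config()) {
  n <- length(y)
  if (anyNA(y)) stop_invalid("smooth_trajectory requires a series without missing values")
  if (n < config$sg_window) {
    warning("series shorter than the smoothing window; returned unchanged")
    return(y)
  }
  h <- (config$sg_window - 1L) %/% 2L
  out <- numeric(n)
  for (i in seq_len(n)) {
    hh <- min(h, i - 1L, n - i)           # symmetric shrink near edges
    j <- (i - hh):(i + hh)
    ord <- min(config$sg_polyorder, length(j) - 1L)
    if (ord == 0L) {
      out[i] <- mean(y[j])
    } else {
      x <- j - i                           # centered: fitted value = intercept
      X <- outer(x, 0:ord, `^`)
      out[i] <- qr.solve(X, y[j])[1L]
    }
  }
  out
}

#' Display-only moving average
#'
#' Centered moving average used purely for display of trajectories (the
#' figure convention of a moving average over three timeframes); it never
#' feeds the annotation, which smooths with [smooth_trajectory()].
#'
#' @param y Numeric series.
#' @param window Odd window length (default 3).
#' @return Smoothed series (shrink-window at the edges).
#' @export
display_smooth <- function(y, window = 3) {
  smooth_trajectory(y, annotation_config(sg_polyorder = 0, sg_window = window))
}

# RSS of the least-squares line through points i..j (1-based) of y,
# from precomputed prefix sums. Returns a closure cost(i, j).
make_segment_cost <- function(y) {
  n <- length(y)
  x <- as.numeric(seq_len(n))
  c1 <- c(0, cumsum(x)); c2 <- c(0, cumsum(x * x))
  cy <- c(0, cumsum(y)); cyy <- c(0, cumsum(y * y)); cxy <- c(0, cumsum(x * y))
  function(i, j) {
    m <- j - i + 1
    sx <- c1[j + 1] - c1[i]; sxx <- c2[j + 1] - c2[i]
    sy <- cy[j + 1] - cy[i]; syy <- cyy[j + 1] - cyy[i]
    sxy <- cxy[j + 1] - cxy[i]
    Sxx <- sxx - sx * sx / m
    Syy <- syy - sy * sy / m
    Sxy <- sxy - sx * sy / m
    rss <- if (Sxx <= 0) Syy else Syy - Sxy * Sxy / Sxx
    max(rss, 0)
  }
}

#' Detect changepoints of a piecewise-linear series
#'
#' Exact dynamic-programming segmentation: for each candidate number of
#' changepoints k in `0..max_changes`, finds the segmentation minimizing the
#' total residual sum of squares of per-segment least-squares lines, subject
#' to every segment (including the first and last) spanning at least
#' `min_distance` frames. The returned k minimizes the penalized criterion
#' `n*log(RSS_k/n) + bic_penalty*(3k + 2)*log(n)` (two line parameters per
#' segment plus one location parameter per breakpoint); ties prefer fewer
#' changepoints, and among equal-cost placements the earliest breakpoints.
#'
#' @param y Numeric series, typically the output of [smooth_trajectory()].
#' @param config An [annotation_config()].
#' @return Integer vector of 0-based indices of the first frame of each new
#'   segment, in increasing order (empty if no changepoint is selected or
#'   none is feasible).
#' @export
detect_changepoints <- function(y, config = annotation_config()) {
  n <- length(y)
  m <- config$min_distance
  kmax_feasible <- max(0L, n %/% m - 1L)
  kmax <- min(config$max_changes, kmax_feasible)
  if (n < 2L * m || kmax == 0L) return(integer(0))
  cost <- make_segment_cost(y)

  # F[k+1, j]: best RSS of y[1..j] split into k+1 segments of length >= m
  F <- matrix(Inf, nrow = kmax + 1L, ncol = n)
  B <- matrix(NA_integer_, nrow = kmax + 1L, ncol = n)  # start of last segment
  for (j in m:n) F[1L, j] <- cost(1L, j)
  for (k in seq_len(kmax)) {
    lo <- k * m + 1L                      # earliest start of the last segment
    for (j in ((k + 1L) * m):n) {
      best <- Inf; argi <- NA_integer_
      for (i in lo:(j - m + 1L)) {
        v <- F[k, i - 1L] + cost(i, j)
        if (v < best) { best <- v; argi <- i }
      }
      F[k + 1L, j] <- best; B[k + 1L, j] <- argi
    }
  }
  rss <- F[, n]
  feasible <- which(is.finite(rss))
  # numerical noise floor: RSS below double-precision resolution of the
  # data's sum of squares counts as an exact fit
  floor_rss <- max(1e-12 * sum(y^2), 1e-300)
  ks <- feasible - 1L
  bic <- n * log(pmax(rss[feasible], floor_rss) / n) +
    config$bic_penalty * (3 * ks + 2) * log(n)
  k_sel <- ks[which.min(bic)]
  if (k_sel == 0L) return(integer(0))
  # backtrack
  cps <- integer(k_sel)
  j <- n
  for (k in seq(k_sel, 1L)) {
    i <- B[k + 1L, j]
    cps[k] <- i
    j <- i - 1L
  }
  cps - 1L                                # 0-based first-frame-of-new-segment
}

# Local extrema (interior, first index of any plateau) and topographic
# prominences of a series. kind = "max" or "min" (minima via sign inversion).
local_extrema <- function(y, kind = c("max", "min")) {
  kind <- match.arg(kind)
  z <- if (kind == "min") -y else y
  n <- length(z)
  if (n < 3) return(data.frame(index = integer(0), prominence = numeric(0)))
  idx <- which(z[2:(n - 1)] > z[1:(n - 2)] & z[2:(n - 1)] >= z[3:n]) + 1L
  prom <- vapply(idx, function(i) {
    h <- z[i]
    left <- if (i == 1L) h else {
      jj <- i - 1L
      lo <- h
      while (jj >= 1L && z[jj] <= h) { lo <- min(lo, z[jj]); jj <- jj - 1L }
      lo
    }
    right <- if (i == n) h else {
      jj <- i + 1L
      lo <- h
      while (jj <= n && z[jj] <= h) { lo <- min(lo, z[jj]); jj <- jj + 1L }
      lo
    }
    h - max(left, right)
  }, numeric(1))
  data.frame(index = idx, prominence = prom)
}

#' Refine changepoints to prominent extrema of the raw series
#'
#' Moves each changepoint to the nearest local maximum or minimum of the
#' unfiltered series whose topographic prominence is at least
#' `prominence_frac` times the full range of the raw series. Changepoints
#' with no qualifying extremum anywhere in the series are kept as boundaries
#' themselves. Ties between equidistant extrema take the earlier frame.
#'
#' @param y Raw (unfiltered) numeric series.
#' @param changepoints 0-based changepoint indices from
#'   [detect_changepoints()].
#' @param config An [annotation_config()].
#' @return Sorted, deduplicated 0-based boundary indices.
#' @export
refine_extrema <- function(y, changepoints, config = annotation_config()) {
  if (length(changepoints) == 0) return(integer(0))
  rng <- max(y) - min(y)
  if (rng == 0) return(sort(unique(as.integer(changepoints))))
  thr <- config$prominence_frac * rng
  ex <- rbind(local_extrema(y, "max"), local_extrema(y, "min"))
  ex <- ex[ex$prominence >= thr, , drop = FALSE]
  cand <- sort(ex$index - 1L)             # 0-based
  bnd <- vapply(as.integer(changepoints), function(cp) {
    if (length(cand) == 0) return(cp)
    d <- abs(cand - cp)
    cand[which.min(d)]                    # which.min takes the earliest tie
  }, integer(1))
  sort(unique(bnd))
}

#' Classify inter-boundary segments as growth, shrinkage or indeterminate
#'
#' Segments are the maximal inclusive frame intervals between consecutive
#' boundaries (boundary frames are shared by adjacent segments), extended to
#' the trajectory ends. Each segment with at least `min_segment_points`
#' frames gets an ordinary least-squares line fitted to the unfiltered data
#' against time; it is labelled growth (shrinkage) when the slope is
#' significantly positive (negative) at level `alpha` by a two-sided t-test,
#' and indeterminate otherwise. Shorter segments are indeterminate with
#' missing statistics. A perfect fit (zero residuals) gets p = 0 for a
#' nonzero slope and p = 1 for a zero slope.
#'
#' @param y Raw numeric series.
#' @param time Time of each frame, s (same length as `y`).
#' @param boundaries Sorted 0-based boundary indices.
#' @param config An [annotation_config()].
#' @return A `data.frame` with columns `start_frame`, `end_frame` (0-based,
#'   inclusive), `kind`, `slope`, `intercept` (value at segment start),
#'   `slope_p`, `n_points`.
#' @export
classify_phases <- function(y, time, boundaries, config = annotation_config()) {
  n <- length(y)
  stopifnot(length(time) == n)
  pts <- sort(unique(c(0L, as.integer(boundaries), n - 1L)))
  pts <- pts[pts >= 0L & pts <= n - 1L]
  if (length(pts) < 2L) pts <- c(0L, n - 1L)
  out <- data.frame(start_frame = pts[-length(pts)], end_frame = pts[-1])
  out$kind <- "indeterminate"
  out$slope <- NA_real_; out$intercept <- NA_real_; out$slope_p <- NA_real_
  out$n_points <- out$end_frame - out$start_frame + 1L
  for (r in seq_len(nrow(out))) {
    i0 <- out$start_frame[r] + 1L; i1 <- out$end_frame[r] + 1L
    if (i1 - i0 + 1L < config$min_segment_points) next
    fit <- fit_phase_ols(time[i0:i1] - time[i0], y[i0:i1])
    out$slope[r] <- fit$slope; out$intercept[r] <- fit$intercept
    out$slope_p[r] <- fit$p_slope
    if (fit$p_slope < config$alpha) {
      if (fit$slope > 0) out$kind[r] <- "growth"
      else if (fit$slope < 0) out$kind[r] <- "shrinkage"
    }
  }
  out
}

#' Annotate growth and shrinkage phases of a trajectory
#'
#' Runs the four-step annotation on a trajectory's length series:
#' Savitzky-Golay smoothing (feeding only changepoint detection), exact
#' piecewise-linear changepoint detection, refinement to prominent raw-series
#' extrema, and slope-significance classification of the resulting segments
#' on the unfiltered data. Annotation operates on the longest prefix of
#' frames with non-missing length. The returned segments are also the frame
#' windows used to slice the intensity series for intensity-rate models.
#'
#' @param traj A trajectory `data.frame` with columns `frame`, `time_s` and
#'   `length_um` (as produced by [simulate_trajectory()] or [read_tracks()]),
#'   or a bare numeric length series (then `dt` supplies the time base).
#' @param config An [annotation_config()].
#' @param dt Frame interval in seconds, used only when `traj` is a bare
#'   numeric series (default 3.5).
#' @return A list of class `"tip_annotation"`: `changepoints` and
#'   `boundaries` (0-based indices), `segments` (see [classify_phases()]),
#'   `n_frames_used`, and the `config`.
#' @export
annotate_trajectory <- function(traj, config = annotation_config(), dt = 3.5) {
  if (is.numeric(traj)) {
    traj <- data.frame(frame = seq_along(traj) - 1L,
                       time_s = (seq_along(traj) - 1) * dt, length_um = traj)
  }
  ok <- !is.na(traj$length_um)
  n_use <- if (all(ok)) nrow(traj) else which(!ok)[1] - 1L
  y <- traj$length_um[seq_len(n_use)]
  tm <- traj$time_s[seq_len(n_use)]
  if (n_use < config$min_segment_points) {
    segs <- data.frame(start_frame = 0L, end_frame = max(n_use - 1L, 0L),
                       kind = "indeterminate", slope = NA_real_,
                       intercept = NA_real_, slope_p = NA_real_,
                       n_points = n_use)
    return(structure(list(changepoints = integer(0), boundaries = integer(0),
                          segments = segs, n_frames_used = n_use,
                          config = config),
                     class = "tip_annotation"))
  }
  sm <- if (n_use >= config$sg_window) smooth_trajectory(y, config) else y
  cps <- detect_changepoints(sm, config)
  bnds <- refine_extrema(y, cps, config)
  segs <- classify_phases(y, tm, bnds, config)
  structure(list(changepoints = cps, boundaries = bnds, segments = segs,
                 n_frames_used = n_use, config = config),
            class = "tip_annotation")
}

#' Per-frame phase labels of an annotation
#'
#' Expands the segment table to one label per frame. A boundary frame shared
#' by two segments is assigned to the preceding segment. Frames beyond the
#' annotated prefix (missing length) are `NA`.
#'
#' @param ann A `"tip_annotation"` object.
#' @param n_frames Total number of frames to label (default: annotated
#'   frames).
#' @return Character vector of `"growth"`, `"shrinkage"`, `"indeterminate"`
#'   or `NA`.
#' @export
frame_phases <- function(ann, n_frames = ann$n_frames_used) {
  lab <- rep(NA_character_, n_frames)
  for (r in seq_len(nrow(ann$segments))) {
    i0 <- ann$segments$start_frame[r] + 1L
    i1 <- min(ann$segments$end_frame[r] + 1L, n_frames)
    if (i0 > n_frames) next
    fill <- which(is.na(lab[i0:i1])) + i0 - 1L  # shared frame keeps earlier label
    lab[fill] <- ann$segments$kind[r]
  }
  lab
}
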
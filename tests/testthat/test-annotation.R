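test_that("order-1 smoothing preserves constants and lines, averages impulses", {
  expect_equal(smooth_trajectory(rep(5, 7)), rep(5, 7))
  y <- 0.1 * (0:10)
  expect_equal(smooth_trajectory(y), y, tolerance = 1e-12)
  # affine idempotence
  ya <- 2 - 0.3 * (0:19)
  expect_equal(smooth_trajectory(smooth_trajectory(ya)), ya, tolerance = 1e-12)
  imp <- c(0, 0, 0, 0, 1, 0, 0, 0, 0)
  expect_equal(smooth_trajectory(imp)[5], 0.2)
  expect_warning(out <- smooth_trajectory(c(1, 2, 3)), "shorter")
  expect_equal(out, c(1, 2, 3))
})

test_that("order-1 symmetric-window smoothing equals the centered moving average", {
  set.seed(1)
  y <- cumsum(rnorm(40))
  sm <- smooth_trajectory(y, annotation_config(sg_window = 5))
  ma <- stats::filter(y, rep(1 / 5, 5), sides = 2)
  interior <- 3:38
  expect_equal(sm[interior], as.numeric(ma[interior]), tolerance = 1e-12)
  # and matches signal's Savitzky-Golay filter away from the edges
  sg <- signal::sgolayfilt(y, p = 1, n = 5)
  expect_equal(sm[interior], sg[interior], tolerance = 1e-10)
})

test_that("changepoint detection solves the constrained RSS problem", {
  # exact line: no changepoints regardless of length
  expect_identical(detect_changepoints(0.1 * (0:39)), integer(0))
  expect_identical(detect_changepoints(rep(2, 25)), integer(0))
  # noiseless tent: apex frame starts the new segment
  tent <- tent_series(rise = 20, slope = 0.1)
  expect_identical(detect_changepoints(tent[1:40]), 20L)
  # infeasible: 8 frames cannot host two segments of >= 5 frames
  expect_identical(detect_changepoints(c(1, 2, 3, 4, 5, 4, 3, 2)), integer(0))
})

test_that("DP segmentation matches exhaustive enumeration on random fixtures", {
  set.seed(20)
  cfg <- annotation_config(max_changes = 2)
  for (rep in 1:40) {
    n <- sample(12:60, 1)
    y <- random_piecewise(n, sample(0:2, 1), runif(1, 0.05, 0.2))
    cps <- detect_changepoints(y, cfg)
    rf <- oracle_rss_fun(y)
    k_oracle <- oracle_select_k(y, 2, 5, rss_fun = rf)
    expect_identical(length(cps), as.integer(k_oracle))
    b <- oracle_best_segmentation(y, length(cps), 5, rf)
    edges <- c(1L, cps + 1L, n + 1L)
    rss_dp <- sum(vapply(seq_len(length(edges) - 1), function(s)
      oracle_seg_rss(y, edges[s], edges[s + 1] - 1L), numeric(1)))
    expect_equal(rss_dp, b$rss, tolerance = 1e-9)
  }
})

test_that("extremum refinement snaps to prominent peaks and keeps others", {
  tent <- tent_series(rise = 20, slope = 0.1)[1:40]
  expect_identical(refine_extrema(tent, 19L), 20L)
  expect_identical(refine_extrema(tent, 22L), 20L)
  # a 10%-of-range bump does not qualify; the changepoint stands
  y <- c(rep(0, 10), 0.1, rep(0, 9), 1)   # range 1, bump prominence 0.1
  expect_identical(refine_extrema(y, 12L), 12L)
  expect_identical(refine_extrema(numeric(20) + 3, integer(0)), integer(0))
  # flat series: changepoints returned unchanged
  expect_identical(refine_extrema(rep(1, 30), c(10L, 20L)), c(10L, 20L))
  # prominences agree with the brute-force definition
  set.seed(4)
  z <- cumsum(rnorm(50))
  ex <- tipquant:::local_extrema(z, "max")
  for (r in seq_len(nrow(ex)))
    expect_equal(ex$prominence[r], oracle_prominence(z, ex$index[r]))
})

test_that("segment classification follows slope sign and significance", {
  cfg <- annotation_config()
  # noiseless positive slope: growth with degenerate p = 0
  segs <- classify_phases(0.05 * (0:9), 0:9, integer(0), cfg)
  expect_identical(segs$kind, "growth")
  expect_identical(segs$slope_p, 0)
  expect_equal(segs$slope, 0.05)
  # zero-slope noise: indeterminate in >= 90% of replicates (type I <= alpha)
  set.seed(30)
  ind <- vapply(1:400, function(i) {
    s <- classify_phases(rnorm(20, 0, 0.05), (0:19) * 3.5, integer(0), cfg)
    s$kind == "indeterminate"
  }, logical(1))
  expect_gte(mean(ind), 0.9)
  # clear negative slope: shrinkage with power ~ 1
  set.seed(31)
  shr <- vapply(1:100, function(i) {
    y <- 2 - 0.02 * (0:19) * 3.5 + rnorm(20, 0, 0.01)
    classify_phases(y, (0:19) * 3.5, integer(0), cfg)$kind == "shrinkage"
  }, logical(1))
  expect_gte(mean(shr), 0.99)
  # segments shorter than min_segment_points stay indeterminate
  s2 <- classify_phases(c(0, 1, 0.9, 0.5, 0.1), 0:4, c(1L), cfg)
  expect_identical(s2$kind[1], "indeterminate")
  expect_true(is.na(s2$slope[1]))
})

test_that("end-to-end annotation recovers a noiseless alternating tent wave", {
  y <- tent_series(rise = 12, n_apex = 3, slope = 0.1)
  ann <- annotate_trajectory(y, dt = 1)
  segs <- ann$segments
  expect_identical(segs$kind,
                   c("growth", "shrinkage", "growth", "shrinkage",
                     "growth", "shrinkage"))
  expect_identical(segs$start_frame[-1], segs$end_frame[-nrow(segs)])
  apexes <- 12 * (1:5)
  expect_identical(ann$boundaries, as.integer(apexes))
})

test_that("degenerate trajectories annotate as a single indeterminate segment", {
  ann <- annotate_trajectory(rep(1.4, 30), dt = 3.5)
  expect_identical(nrow(ann$segments), 1L)
  expect_identical(ann$segments$kind, "indeterminate")
  tiny <- annotate_trajectory(c(1, 2), dt = 3.5)
  expect_identical(tiny$segments$kind, "indeterminate")
})

test_that("annotation is shift-invariant, negation-antisymmetric, unit-equivariant", {
  set.seed(40)
  mt <- mt_sim_params(seed = 7, init_length = 1.5)
  tr <- simulate_trajectory(mt, intensity_sim_params(loss_hazard_shrink = 0))
  y <- tr$length_um; tm <- tr$time_s
  base <- annotate_trajectory(y, dt = 3.5)
  shifted <- annotate_trajectory(y + 5, dt = 3.5)
  expect_identical(base$segments$kind, shifted$segments$kind)
  expect_equal(base$segments$slope, shifted$segments$slope)
  neg <- annotate_trajectory(-y, dt = 3.5)
  swap <- c(growth = "shrinkage", shrinkage = "growth",
            indeterminate = "indeterminate")
  expect_identical(unname(swap[base$segments$kind]), neg$segments$kind)
  # rescaling time scales slopes, leaves labels and boundaries unchanged
  resc <- annotate_trajectory(
    data.frame(frame = tr$frame, time_s = tm / 60, length_um = y),
    dt = 3.5 / 60)
  expect_identical(base$segments$kind, resc$segments$kind)
  expect_equal(resc$segments$slope, base$segments$slope * 60)
  expect_identical(base$boundaries, resc$boundaries)
})

test_that("annotation runs on the longest prefix before punctum loss", {
  y <- c(0.1 * (0:20), rep(NA_real_, 10))
  tr <- data.frame(frame = 0:30, time_s = (0:30) * 3.5, length_um = y)
  ann <- annotate_trajectory(tr)
  expect_identical(ann$n_frames_used, 21L)
  expect_identical(ann$segments$end_frame[nrow(ann$segments)], 20L)
  expect_identical(ann$segments$kind, "growth")
})
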
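test_that("aspect parameter arithmetic and simulator round-trip", {
  expect_equal(aspect_parameter(2, 2), 0)
  expect_equal(aspect_parameter(3, 1), 0.5)
  expect_error(aspect_parameter(1, 0), "> 0")
  expect_error(aspect_parameter(1, 2), ">=")
  # algebraic inverse: (L, W) built from A at fixed area return A exactly
  A <- c(0.01, 0.1, 0.5, 0.9); R <- 1.7
  s <- (1 + A) / (1 - A)
  L <- 2 * R * sqrt(s); W <- 2 * R / sqrt(s)
  expect_equal(aspect_parameter(L, W), A, tolerance = 1e-14)
  expect_equal(L * W, rep(4 * R^2, length(A)), tolerance = 1e-12)
})

test_that("fusion-time fit inverts the simulator exactly at zero noise", {
  p <- fusion_sim_params(parent_radius = 10 / (2 * sqrt(2)),
                         capillary_slope = 10 / (10 / 2), A0 = 0.5,
                         n_frames = 120, dt = 0.5)
  ev <- simulate_fusion_event(p)      # tau = 10 s by construction
  f <- fit_fusion_time(ev)
  expect_true(f$ok)
  expect_equal(f$tau, 10, tolerance = 1e-6)
  expect_equal(f$A0, 0.5, tolerance = 1e-6)
  expect_equal(f$R, attr(ev, "R_true"), tolerance = 2e-3)
})

test_that("non-decaying aspect series are flagged as failures", {
  flat <- data.frame(event_id = "x", time_s = 0:19,
                     L_um = rep(3, 20), W_um = rep(2, 20))
  f <- fit_fusion_time(flat)
  expect_false(f$ok)
  expect_true(is.na(f$tau))
  grow <- data.frame(event_id = "y", time_s = 0:19,
                     L_um = 2 + (0:19) * 0.05, W_um = rep(2, 20))
  expect_false(fit_fusion_time(grow)$ok)
  expect_error(fit_fusion_time(flat[1:3, ]), ">=")
})

test_that("noisy fusion events recover tau within a few percent (median)", {
  errs <- vapply(1:30, function(i) {
    p <- fusion_sim_params(parent_radius = runif(1, 0.7, 1.8),
                           capillary_slope = 4, A0 = 0.5,
                           shape_noise_sd = 0.02, n_frames = 150, dt = 0.33,
                           seed = 500 + i)
    ev <- simulate_fusion_event(p)
    f <- fit_fusion_time(ev)
    abs(f$tau - attr(ev, "tau_true")) / attr(ev, "tau_true")
  }, numeric(1))
  expect_lte(median(errs), 0.05)
})

test_that("capillary slope: exact fit, single point, weighted-mean identity", {
  d <- data.frame(R = c(0.8, 1.5, 2.4), tau = 2.25 * c(0.8, 1.5, 2.4))
  cf <- fit_capillary_slope(d)
  expect_equal(cf$slope, 2.25)
  expect_lt(cf$stderr, 1e-10)
  one <- fit_capillary_slope(data.frame(R = 2, tau = 9))
  expect_equal(one$slope, 4.5)
  expect_true(is.na(one$stderr))
  expect_error(fit_capillary_slope(data.frame(R = numeric(0),
                                              tau = numeric(0))), "no successful")
  # through-origin LS slope = mean(tau/R) weighted by R^2
  set.seed(80)
  d2 <- data.frame(R = runif(15, 0.5, 3))
  d2$tau <- 5 * d2$R + rnorm(15, 0, 0.5)
  cf2 <- fit_capillary_slope(d2)
  expect_equal(cf2$slope,
               sum((d2$tau / d2$R) * d2$R^2) / sum(d2$R^2), tolerance = 1e-12)
})

test_that("relaxation-time relations: value, limit, monotonicity", {
  h <- hydrodynamic_params(1, 1, 1)   # lambda = 1
  expect_equal(eq1_fusion_time(h, 1), (5 * 35 / 80) * 1e-6)
  expect_equal(eq2_fusion_time(18.2, 2, 7e-6) / eq2_fusion_time(18.2, 1, 7e-6), 2)
  expect_equal(eq2_fusion_time(1, 1, 1e6), 0.95 * 1e-12)    # gamma -> inf: tau -> 0
  expect_equal(inverse_capillary_velocity(18.2, 7e-6), 2.47, tolerance = 1e-9)
  # eq1 converges to eq2 for large viscosity contrast
  for (lam in c(1e4, 1e5, 1e6)) {
    hh <- hydrodynamic_params(lam * 0.01, 0.01, 5e-6)
    ratio <- eq1_fusion_time(hh, 1.3) / eq2_fusion_time(lam * 0.01, 1.3, 5e-6)
    expect_lt(abs(ratio - 1), 1e-3)
  }
  # monotone increasing in R
  expect_true(all(diff(eq1_fusion_time(h, c(1, 2, 4))) > 0))
})

test_that("ellipse axes from binary masks match moment formulas", {
  grid_mask <- function(nr, nc, f) {
    m <- matrix(FALSE, nr, nc)
    for (r in seq_len(nr)) for (cc in seq_len(nc)) m[r, cc] <- f(r, cc)
    m
  }
  disc <- grid_mask(121, 121, function(r, c) (r - 61)^2 + (c - 61)^2 <= 50^2)
  ax <- ellipse_axes_from_mask(disc)
  expect_equal(unname(ax["L"]), 100, tolerance = 0.02)
  expect_equal(unname(ax["W"]), 100, tolerance = 0.02)
  ell <- grid_mask(61, 141, function(r, c)
    ((c - 71) / 60)^2 + ((r - 31) / 20)^2 <= 1)
  ax2 <- ellipse_axes_from_mask(ell)
  expect_equal(unname(ax2["L"]), 120, tolerance = 0.02)
  expect_equal(unname(ax2["W"]), 40, tolerance = 0.02)
  th <- 30 * pi / 180
  rot <- grid_mask(141, 141, function(r, c) {
    x <- c - 71; y <- r - 71
    u <- cos(th) * x + sin(th) * y; v <- -sin(th) * x + cos(th) * y
    (u / 60)^2 + (v / 20)^2 <= 1
  })
  ax3 <- ellipse_axes_from_mask(rot)
  expect_equal(unname(ax3), unname(ax2), tolerance = 0.02)
  expect_error(ellipse_axes_from_mask(matrix(FALSE, 5, 5)), "empty")
  two <- matrix(FALSE, 9, 9); two[2:3, 2:3] <- TRUE; two[7:8, 7:8] <- TRUE
  expect_error(ellipse_axes_from_mask(two), "more than one")
})

test_that("FRAP normalization corrects acquisition bleaching", {
  n <- 100; bleach <- 5; bg <- 10
  # constant references: output is the target's own pre-bleach normalization
  tgt <- c(rep(100, bleach), 20 + 80 * (1 - exp(-(1:(n - bleach)) / 15)))
  refs <- matrix(80, n, 3)
  out <- frap_normalize(tgt + bg, refs + bg, bleach, bg)
  expect_equal(out, tgt / mean(tgt[1:bleach]))
  # references decayed to 50%: corrected target doubles there
  half <- matrix(rep(c(rep(80, 50), rep(40, 50)), 2), n, 2)
  out2 <- frap_normalize(tgt + bg, half + bg, bleach, bg)
  expect_equal(out2[51:100], 2 * tgt[51:100] / mean(tgt[1:bleach]))
  # 20% linear acquisition bleaching on all traces: plateau recovers to 1
  acq <- 1 - 0.2 * (seq_len(n) - 1) / (n - 1)
  out3 <- frap_normalize(tgt * acq + bg, refs * acq + bg, bleach, bg)
  expect_equal(mean(out3[(n - 9):n]), 1, tolerance = 0.02)
  expect_error(frap_normalize(tgt, refs, 0, 0), "pre-bleach")
  expect_error(frap_normalize(tgt, matrix(0, n, 2), bleach, 0), "reference")
})

test_that("partition coefficient arithmetic and conventions", {
  expect_equal(partition_coefficient(50, 50, 0), 1)
  expect_equal(partition_coefficient(280, 20, 10), 27)
  expect_error(partition_coefficient(10, 5, 5), "background")
  # shifting all three inputs jointly preserves the ratio
  expect_equal(partition_coefficient(280 + 7, 20 + 7, 10 + 7),
               partition_coefficient(280, 20, 10))
})
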
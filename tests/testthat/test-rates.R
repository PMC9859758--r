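test_that("phase OLS handles exact, flat and degenerate inputs", {
  f <- fit_phase_ols(c(0, 1, 2), c(0, 1, 2))
  expect_equal(f$intercept, 0)
  expect_equal(f$slope, 1)
  expect_equal(f$sigma2, 0)
  expect_identical(f$p_slope, 0)
  flat <- fit_phase_ols(c(0, 1, 2), c(1, 1, 1))
  expect_equal(flat$slope, 0)
  expect_identical(flat$p_slope, 1)
  expect_error(fit_phase_ols(c(0, 1), c(1, 2)), "3")
  expect_error(fit_phase_ols(rep(1, 5), 1:5), "degenerate")
})

test_that("OLS slope estimate falls within its sampling spread", {
  set.seed(50)
  for (i in 1:20) {
    t <- (0:49) * 3.5
    y <- 0.6 + 0.02 * t + rnorm(50, 0, 0.05)
    f <- fit_phase_ols(t, y)
    expect_lt(abs(f$slope - 0.02), 3 * f$se_slope + 1e-12)
  }
  # agreement with lm as an independent route
  set.seed(51)
  t <- (0:29) * 2; y <- 1 + 0.01 * t + rnorm(30, 0, 0.1)
  f <- fit_phase_ols(t, y)
  lf <- summary(lm(y ~ t))
  expect_equal(f$slope, lf$coefficients["t", "Estimate"])
  expect_equal(f$se_slope, lf$coefficients["t", "Std. Error"])
  expect_equal(f$p_slope, lf$coefficients["t", "Pr(>|t|)"])
})

make_partials <- function(strains, slopes, n_groups, n_obs = 15, dt = 3.5,
                          sd_int = 0.1, sd_slope = 0.005, sd_noise = 0.05,
                          b0 = 0.5) {
  do.call(rbind, lapply(seq_along(strains), function(s)
    do.call(rbind, lapply(seq_len(n_groups), function(g) {
      t <- (seq_len(n_obs) - 1) * dt
      data.frame(partial_id = paste0(strains[s], "_", g),
                 strain = strains[s], phase = "growth", response = "length",
                 t_rel = t,
                 y = (b0 + rnorm(1, 0, sd_int)) +
                   (slopes[s] + rnorm(1, 0, sd_slope)) * t +
                   rnorm(n_obs, 0, sd_noise))
    }))))
}

test_that("identical exactly-linear partials collapse to the pooled OLS line", {
  p <- do.call(rbind, lapply(1:6, function(g)
    data.frame(partial_id = paste0("g", g), strain = "wt",
               t_rel = (0:9) * 3.5, y = 1.2 + 0.015 * (0:9) * 3.5)))
  fit <- fit_lme(p)
  expect_true(fit$converged)
  expect_equal(fit$Psi, matrix(0, 2, 2), ignore_attr = TRUE)
  expect_equal(fit$sigma2, 0)
  expect_equal(fit$fixed$estimate[fit$fixed$term == "intercept"], 1.2)
  expect_equal(fit$fixed$estimate[fit$fixed$term == "slope"], 0.015)
})

test_that("Psi = 'none' reduces to pooled OLS with the Gaussian log-likelihood", {
  set.seed(60)
  t <- 0:20
  y <- 1 + 0.02 * t + rnorm(21, 0, 0.05)
  p <- data.frame(partial_id = "a", strain = "wt", t_rel = t, y = y)
  fit <- fit_lme(p, psi = "none")
  ols <- lm(y ~ t)
  expect_equal(fit$fixed$estimate[fit$fixed$term == "intercept"],
               unname(coef(ols)[1]))
  expect_equal(fit$fixed$estimate[fit$fixed$term == "slope"],
               unname(coef(ols)[2]))
  n <- length(y); rss <- sum(resid(ols)^2)
  expect_equal(fit$logLik, -n / 2 * (log(2 * pi * rss / n) + 1))
})

test_that("mixed-model log-likelihood is never below the pooled-OLS one", {
  set.seed(61)
  for (i in 1:5) {
    p <- make_partials(c("wt", "mut"), c(0.02, 0.01), 10)
    fit <- suppressWarnings(fit_lme(p))
    ols <- lm(y ~ 0 + strain + strain:t_rel,
              data = transform(p, strain = factor(strain)))
    ll0 <- {
      n <- nrow(p); rss <- sum(resid(ols)^2)
      -n / 2 * (log(2 * pi * rss / n) + 1)
    }
    expect_gte(fit$logLik, ll0 - 1e-6)
  }
})

test_that("fixed effects are equivariant under unit rescaling", {
  set.seed(62)
  p <- make_partials("wt", 0.02, 12)
  f1 <- suppressWarnings(fit_lme(p))
  p2 <- transform(p, t_rel = t_rel / 60, y = y * 1000)  # minutes, nm
  f2 <- suppressWarnings(fit_lme(p2))
  s1 <- f1$fixed$estimate[f1$fixed$term == "slope"]
  s2 <- f2$fixed$estimate[f2$fixed$term == "slope"]
  expect_equal(s2, s1 * 1000 * 60, tolerance = 1e-4)
  i1 <- f1$fixed$estimate[f1$fixed$term == "intercept"]
  i2 <- f2$fixed$estimate[f2$fixed$term == "intercept"]
  expect_equal(i2, i1 * 1000, tolerance = 1e-4)
})

test_that("between-strain Wald contrasts behave at the null and under power", {
  set.seed(63)
  p <- make_partials(c("wt", "mut"), c(0.02, 0.01), 25, sd_noise = 0.03)
  fit <- suppressWarnings(fit_lme(p))
  self <- compare_fixed_effects(fit, "wt", "wt", "slope")
  expect_identical(self$p, 1)
  expect_identical(self$difference, 0)
  gap <- compare_fixed_effects(fit, "wt", "mut", "slope")
  expect_gt(abs(gap$t), 5)          # a 2x rate difference at this SNR
  expect_lt(gap$p, 0.001)
  expect_error(compare_fixed_effects(fit, "wt", "nosuch", "slope"), "unknown")
})

test_that("parameter recovery: strain slopes inside their own 95% CIs", {
  set.seed(64)
  hits <- 0L
  n_rep <- 15
  for (i in seq_len(n_rep)) {
    p <- make_partials(c("wt", "mut"), c(0.02, 0.01), 30)
    fit <- suppressWarnings(fit_lme(p))
    fx <- fit$fixed[fit$fixed$term == "slope", ]
    truth <- c(mut = 0.01, wt = 0.02)[fx$strain]
    hits <- hits + as.integer(all(fx$ci_lo <= truth & truth <= fx$ci_hi))
  }
  expect_gte(hits, round(0.8 * n_rep)) # nominal ~0.95^2 joint coverage
})

test_that("extract_partials slices annotated phases with time from phase start", {
  y <- tent_series(rise = 12, n_apex = 1, slope = 0.1)
  tr <- data.frame(cell_id = "c1", punctum_id = "p1", strain = "wt",
                   frame = seq_along(y) - 1L, time_s = (seq_along(y) - 1) * 3.5,
                   length_um = y, intensity_au = 100 + seq_along(y), lost = FALSE)
  p <- extract_partials(list(tr), response = "length")
  expect_setequal(unique(p$phase), c("growth", "shrinkage"))
  expect_true(all(tapply(p$t_rel, p$partial_id, min) == 0))
  pint <- extract_partials(list(tr), response = "intensity")
  expect_equal(nrow(pint), nrow(p))
  # missing intensity after loss is dropped
  tr2 <- tr; tr2$intensity_au[15:25] <- NA
  p2 <- extract_partials(list(tr2), response = "intensity")
  expect_true(all(!is.na(p2$y)))
})
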
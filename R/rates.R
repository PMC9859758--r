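#' Ordinary least-squares fit of one partial trajectory
#'
#' Closed-form simple linear regression of a response (length or intensity)
#' on time within one growth or shrinkage phase, with a two-sided t-test on
#' the slope (n - 2 degrees of freedom). With `t` measured from the phase
#' start, the intercept is the initial length (or intensity) of the phase.
#' A perfect fit (zero residuals) is degenerate for the t statistic and gets
#' `p_slope = 0` for a nonzero slope and `p_slope = 1` for a zero slope.
#'
#' @param t Times from phase start, s (>= 3 values, not all equal).
#' @param y Response values (um or a.u.).
#' @return A list: `intercept`, `slope`, `se_intercept`, `se_slope`,
#'   `t_slope`, `p_slope`, `sigma2` (residual variance, n - 2 df), `rss`,
#'   `n`, `df`.
#' @export
fit_phase_ols <- function(t, y) {
  n <- length(t)
  if (n < 3 || length(y) != n) stop_invalid("fit_phase_ols needs >= 3 paired observations")
  if (anyNA(t) || anyNA(y)) stop_invalid("missing values in OLS input")
  tb <- mean(t); yb <- mean(y)
  Sxx <- sum((t - tb)^2)
  if (Sxx <= 0) stop_invalid("degenerate design: zero time variance")
  Sxy <- sum((t - tb) * (y - yb))
  Syy <- sum((y - yb)^2)
  slope <- Sxy / Sxx
  intercept <- yb - slope * tb
  rss <- max(Syy - slope * Sxy, 0)
  df <- n - 2L
  tol <- 1e-12 * (Syy + yb^2 * n) + 1e-290
  if (rss <= tol) {
    p <- if (slope == 0) 1 else 0
    return(list(intercept = intercept, slope = slope, se_intercept = 0,
                se_slope = 0, t_slope = if (slope == 0) 0 else Inf * sign(slope),
                p_slope = p, sigma2 = 0, rss = rss, n = n, df = df))
  }
  sigma2 <- rss / df
  se_slope <- sqrt(sigma2 / Sxx)
  se_int <- sqrt(sigma2 * (1 / n + tb^2 / Sxx))
  tstat <- slope / se_slope
  list(intercept = intercept, slope = slope, se_intercept = se_int,
       se_slope = se_slope, t_slope = tstat,
       p_slope = 2 * pt(-abs(tstat), df), sigma2 = sigma2, rss = rss,
       n = n, df = df)
}

#' Extract partial trajectories from annotated segments
#'
#' Slices growth and shrinkage segments out of trajectories to produce the
#' long-format observation table the rate models consume. Time is measured
#' from each phase start, so model intercepts are initial values.
#' Indeterminate segments are excluded; intensity observations that are
#' missing (after punctum loss) are dropped; partials with fewer than
#' `min_points` remaining observations are discarded.
#'
#' @param trajectories A list of trajectory `data.frame`s (see
#'   [read_tracks()] / [simulate_trajectory()]).
#' @param annotations A list of `"tip_annotation"` objects, parallel to
#'   `trajectories` (default: annotate each with `config`).
#' @param response `"length"` or `"intensity"`.
#' @param config An [annotation_config()] used when annotations are computed
#'   here.
#' @param min_points Minimum observations per partial (default
#'   `config$min_segment_points`).
#' @return A `data.frame` with columns `partial_id`, `strain`, `phase`,
#'   `response`, `t_rel`, `y`.
#' @export
extract_partials <- function(trajectories, annotations = NULL,
                             response = c("length", "intensity"),
                             config = annotation_config(),
                             min_points = config$min_segment_points) {
  response <- match.arg(response)
  col <- if (response == "length") "length_um" else "intensity_au"
  if (is.null(annotations))
    annotations <- lapply(trajectories, annotate_trajectory, config = config)
  out <- vector("list", 0L)
  for (i in seq_along(trajectories)) {
    tr <- trajectories[[i]]
    segs <- annotations[[i]]$segments
    segs <- segs[segs$kind %in% c("growth", "shrinkage"), , drop = FALSE]
    if (nrow(segs) == 0) next
    key <- paste(tr$cell_id[1], tr$punctum_id[1], sep = "/")
    for (r in seq_len(nrow(segs))) {
      idx <- (segs$start_frame[r] + 1L):(segs$end_frame[r] + 1L)
      yv <- tr[[col]][idx]
      keep <- !is.na(yv)
      if (sum(keep) < min_points) next
      tt <- tr$time_s[idx][keep]
      out[[length(out) + 1L]] <- data.frame(
        partial_id = paste0(key, "/seg", r),
        strain = tr$strain[1], phase = segs$kind[r], response = response,
        t_rel = tt - tt[1], y = yv[keep])
    }
  }
  if (length(out) == 0)
    return(data.frame(partial_id = character(0), strain = character(0),
                      phase = character(0), response = character(0),
                      t_rel = numeric(0), y = numeric(0)))
  do.call(rbind, out)
}

# Gaussian maximum-likelihood log-likelihood of a pooled per-strain OLS fit.
pooled_ols_loglik <- function(rss, n) {
  s2 <- rss / n
  if (s2 <= 0) return(Inf)
  -n / 2 * (log(2 * pi * s2) + 1)
}

#' Joint mixed-effects rate model across strains
#'
#' Fits, by maximum likelihood, the linear mixed-effects model
#' `y = b0_strain + b1_strain * t + u0_partial + u1_partial * t + e`, where
#' each strain has its own fixed intercept (initial value) and slope (rate),
#' and intercept and slope vary randomly by partial trajectory with a shared
#' 2x2 covariance `Psi`; residuals are iid Gaussian. This is the joint
#' estimation used to pool growth (or shrinkage) phases over all strains for
#' one response. Fixed-effect t-tests use residual degrees of freedom
#' `n_obs - n_fixed`.
#'
#' Estimation is delegated to [lme4::lmer()] with `REML = FALSE`. A singular
#' full covariance is refitted with a diagonal `Psi` (independent random
#' intercept and slope) with a warning. Data whose pooled per-strain OLS fit
#' is exact (zero residuals, hence no between-partial variability) are
#' handled directly by the OLS reduction, to which the model collapses.
#'
#' @param partials Long-format `data.frame` from [extract_partials()]
#'   (columns `partial_id`, `strain`, `t_rel`, `y`; `phase`/`response`
#'   columns, when present, must be homogeneous).
#' @param psi Random-effect structure: `"full"` (correlated intercept and
#'   slope), `"diagonal"`, or `"none"` (Psi fixed at zero; reduces to pooled
#'   per-strain OLS, single-group data allowed).
#' @return A list of class `"tip_lme"`: `fixed` (data.frame with `strain`,
#'   `term`, `estimate`, `se`, `t`, `p`, `ci_lo`, `ci_hi`), `vcov_fixed`,
#'   `Psi`, `sigma2`, `logLik`, `n_obs`, `n_groups`, `df`, `converged`,
#'   `singular`, `psi`.
#' @export
fit_lme <- function(partials, psi = c("full", "diagonal", "none")) {
  psi <- match.arg(psi)
  d <- data.frame(y = partials$y, t_rel = partials$t_rel,
                  strain = factor(partials$strain),
                  partial_id = factor(partials$partial_id))
  if (anyNA(d)) stop_invalid("missing values in mixed-model input")
  for (col in c("phase", "response"))
    if (!is.null(partials[[col]]) && length(unique(partials[[col]])) > 1)
      stop_invalid("fit one model per phase/response; got mixed ", col)
  n_groups <- nlevels(d$partial_id)
  if (psi != "none" && n_groups < 2)
    stop_invalid("need >= 2 partial trajectories (or psi = 'none')")
  n_fixed <- 2L * nlevels(d$strain)
  n_obs <- nrow(d)
  df_t <- n_obs - n_fixed
  single <- nlevels(d$strain) == 1L
  # cell-means coding: every strain gets its own intercept and slope
  fx <- if (single) y ~ t_rel else y ~ 0 + strain + strain:t_rel
  rename_single <- function(nms) {
    if (!single) return(nms)
    lev <- levels(d$strain)
    nms[nms == "(Intercept)"] <- paste0("strain", lev)
    nms[nms == "t_rel"] <- paste0("strain", lev, ":t_rel")
    nms
  }

  # pooled per-strain OLS (also the Psi = 0 reduction and the logLik floor)
  ols <- lm(fx, data = d)
  rss <- sum(ols$residuals^2)
  scale2 <- sum(d$y^2) + 1e-290
  exact <- rss <= 1e-12 * scale2

  if (psi == "none" || exact) {
    sm <- suppressWarnings(summary(ols))  # exact fits warn harmlessly
    beta <- coef(ols)
    names(beta) <- rename_single(names(beta))
    V <- sm$sigma^2 * sm$cov.unscaled
    rownames(V) <- colnames(V) <- names(beta)
    fixed <- fixed_table(beta, sqrt(diag(V)), d, df_t, exact)
    return(structure(list(fixed = fixed, vcov_fixed = V,
                          Psi = matrix(0, 2, 2,
                                       dimnames = list(c("(Intercept)", "t_rel"),
                                                       c("(Intercept)", "t_rel"))),
                          sigma2 = if (exact) 0 else sm$sigma^2,
                          logLik = pooled_ols_loglik(rss, n_obs),
                          n_obs = n_obs, n_groups = n_groups, df = df_t,
                          converged = TRUE, singular = FALSE,
                          psi = if (exact) "collapsed" else psi),
                     class = "tip_lme"))
  }

  form_full <- stats::update(fx, . ~ . + (1 + t_rel | partial_id))
  form_diag <- stats::update(fx, . ~ . + (1 + t_rel || partial_id))
  # optimizer chatter (gradient-check notes) is stored as diagnostics instead
  quiet_lmer <- function(f) tryCatch(
    suppressMessages(suppressWarnings(lme4::lmer(f, data = d, REML = FALSE))),
    error = function(e) e)
  fit <- quiet_lmer(if (psi == "full") form_full else form_diag)
  if (psi == "full" &&
      (inherits(fit, "error") || lme4::isSingular(fit, tol = 1e-5))) {
    warning("singular random-effect covariance; refitting with diagonal Psi")
    fit <- quiet_lmer(form_diag)
  }
  if (inherits(fit, "error"))
    return(structure(list(converged = FALSE, message = conditionMessage(fit)),
                     class = "tip_lme"))
  Psi <- matrix(0, 2, 2, dimnames = list(c("(Intercept)", "t_rel"),
                                         c("(Intercept)", "t_rel")))
  for (vc in lme4::VarCorr(fit)) {     # one block, or two for diagonal fits
    m <- as.matrix(vc)
    Psi[rownames(m), colnames(m)] <- Psi[rownames(m), colnames(m)] + m
  }
  beta <- lme4::fixef(fit)
  names(beta) <- rename_single(names(beta))
  V <- as.matrix(vcov(fit))
  rownames(V) <- colnames(V) <- names(beta)
  fixed <- fixed_table(beta, sqrt(diag(V)), d, df_t, FALSE)
  structure(list(fixed = fixed, vcov_fixed = V, Psi = Psi,
                 sigma2 = stats::sigma(fit)^2, logLik = as.numeric(logLik(fit)),
                 n_obs = n_obs, n_groups = n_groups, df = df_t,
                 converged = TRUE, singular = lme4::isSingular(fit, tol = 1e-5),
                 psi = psi,
                 diagnostics = unlist(fit@optinfo$conv$lme4$messages)),
            class = "tip_lme")
}

# Assemble the per-strain fixed-effect table from coefficient and SE vectors
# named in cell-means coding ("strainX", "strainX:t_rel").
fixed_table <- function(beta, se, d, df_t, exact) {
  levs <- levels(d$strain)
  rows <- list()
  for (s in levs) {
    for (term in c("intercept", "slope")) {
      nm <- if (term == "intercept") paste0("strain", s)
            else paste0("strain", s, ":t_rel")
      b <- unname(beta[nm]); e <- unname(se[nm])
      if (exact) {
        tt <- if (b == 0) 0 else Inf * sign(b)
        p <- if (b == 0) 1 else 0
        e <- 0
      } else {
        tt <- b / e
        p <- 2 * pt(-abs(tt), df_t)
      }
      q <- if (df_t > 0) stats::qt(0.975, df_t) else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        strain = s, term = term, estimate = b, se = e, t = tt, p = p,
        ci_lo = b - q * e, ci_hi = b + q * e)
    }
  }
  do.call(rbind, rows)
}

#' Wald contrast between two strains' fixed effects
#'
#' Tests the difference of one fixed-effect coefficient (intercept or slope)
#' between two strains of a joint mixed-model fit, using the fixed-effect
#' covariance block and the fit's residual degrees of freedom.
#'
#' @param fit A `"tip_lme"` object.
#' @param strain_a,strain_b Strain labels present in the fit.
#' @param which `"slope"` (rate) or `"intercept"` (initial value).
#' @return A list: `difference` (a minus b), `se`, `t`, `p` (two-sided),
#'   `df`.
#' @export
compare_fixed_effects <- function(fit, strain_a, strain_b,
                                  which = c("slope", "intercept")) {
  which <- match.arg(which)
  if (!isTRUE(fit$converged)) stop_invalid("fit did not converge")
  levs <- unique(fit$fixed$strain)
  if (!strain_a %in% levs || !strain_b %in% levs)
    stop_invalid("unknown strain in contrast")
  nm <- function(s) if (which == "intercept") paste0("strain", s)
                    else paste0("strain", s, ":t_rel")
  if (strain_a == strain_b)
    return(list(difference = 0, se = 0, t = 0, p = 1, df = fit$df))
  V <- fit$vcov_fixed
  ia <- match(nm(strain_a), rownames(V)); ib <- match(nm(strain_b), rownames(V))
  ea <- fit$fixed$estimate[fit$fixed$strain == strain_a &
                             fit$fixed$term == which]
  eb <- fit$fixed$estimate[fit$fixed$strain == strain_b &
                             fit$fixed$term == which]
  diff <- ea - eb
  se <- sqrt(V[ia, ia] + V[ib, ib] - 2 * V[ia, ib])
  if (se == 0) {
    p <- if (diff == 0) 1 else 0
    return(list(difference = diff, se = 0,
                t = if (diff == 0) 0 else Inf * sign(diff), p = p, df = fit$df))
  }
  tt <- diff / se
  list(difference = diff, se = se, t = tt, p = 2 * pt(-abs(tt), fit$df),
       df = fit$df)
}
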
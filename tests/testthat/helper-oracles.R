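# Independent oracles used across tests. These deliberately avoid the
# package's internal code paths (prefix sums, DP): segments are refit with
# QR least squares and placements enumerated exhaustively.

# RSS of a least-squares line on y[i..j] (1-based inclusive), via QR,
# memoized per series (the cache only avoids recomputation; every value
# still comes from an independent QR fit).
oracle_rss_fun <- function(y) {
  cache <- new.env(parent = emptyenv())
  function(i, j) {
    key <- paste0(i, "_", j)
    got <- cache[[key]]
    if (!is.null(got)) return(got)
    x <- i:j
    r <- .lm.fit(cbind(1, x), y[x])$residuals
    cache[[key]] <- sum(r^2)
    cache[[key]]
  }
}

oracle_seg_rss <- function(y, i, j) {
  x <- i:j
  r <- .lm.fit(cbind(1, x), y[x])$residuals
  sum(r^2)
}

# Exhaustive minimum-RSS segmentation of y with exactly k changepoints
# (k <= 2) and minimum segment length m. Changepoints are 1-based first
# indices of new segments. Returns list(rss, cps) or NULL if infeasible.
oracle_best_segmentation <- function(y, k, m, rss_fun = oracle_rss_fun(y)) {
  n <- length(y)
  if ((k + 1) * m > n) return(NULL)
  if (k == 0) return(list(rss = rss_fun(1, n), cps = integer(0)))
  best <- Inf; bcp <- NULL
  if (k == 1) {
    for (c1 in (m + 1):(n - m + 1)) {
      r <- rss_fun(1, c1 - 1) + rss_fun(c1, n)
      if (r < best) { best <- r; bcp <- c1 }
    }
  } else if (k == 2) {
    for (c1 in (m + 1):(n - 2 * m + 1)) {
      left <- rss_fun(1, c1 - 1)
      for (c2 in (c1 + m):(n - m + 1)) {
        r <- left + rss_fun(c1, c2 - 1) + rss_fun(c2, n)
        if (r < best) { best <- r; bcp <- c(c1, c2) }
      }
    }
  } else stop("oracle supports k <= 2")
  list(rss = best, cps = bcp)
}

# BIC model selection mirroring the documented criterion, applied to the
# oracle's exhaustive per-k optima. Returns the selected k.
oracle_select_k <- function(y, kmax, m, penalty = 1,
                            rss_fun = oracle_rss_fun(y)) {
  n <- length(y)
  rss <- vapply(0:kmax, function(k) {
    b <- oracle_best_segmentation(y, k, m, rss_fun)
    if (is.null(b)) Inf else b$rss
  }, numeric(1))
  feas <- which(is.finite(rss))
  fl <- max(1e-12 * sum(y^2), 1e-300)
  ks <- feas - 1L
  bic <- n * log(pmax(rss[feas], fl) / n) + penalty * (3 * ks + 2) * log(n)
  ks[which.min(bic)]
}

# Brute-force topographic prominence of position i (1-based) of series z,
# straight from the definition: walk out to the nearest higher point on
# each side, take the minimum on the way, prominence is height above the
# higher of the two minima.
oracle_prominence <- function(z, i) {
  n <- length(z); h <- z[i]
  side_min <- function(idx) {
    lo <- h
    for (j in idx) {
      if (z[j] > h) return(lo)
      lo <- min(lo, z[j])
    }
    lo
  }
  left <- if (i > 1) side_min((i - 1):1) else h
  right <- if (i < n) side_min((i + 1):n) else h
  h - max(left, right)
}

# Piecewise-linear series with noise, for changepoint fixtures.
random_piecewise <- function(n, n_breaks, noise_sd, min_len = 5) {
  n_breaks <- min(n_breaks, n %/% min_len - 1L)   # keep placement feasible
  if (n_breaks <= 0) {
    bks <- integer(0)
  } else {
    repeat {
      bks <- sort(sample(seq(min_len + 1, n - min_len + 1), n_breaks))
      if (n_breaks < 2 || all(diff(bks) >= min_len)) break
    }
  }
  edges <- c(1, bks, n + 1)
  y <- numeric(n); lev <- 0
  for (s in seq_len(length(edges) - 1)) {
    idx <- edges[s]:(edges[s + 1] - 1)
    slope <- sample(c(-1, 1), 1) * runif(1, 0.05, 0.2)
    y[idx] <- lev + slope * (seq_along(idx) - 1)
    lev <- y[idx[length(idx)]] + slope
  }
  y + rnorm(n, 0, noise_sd)
}

# Symmetric triangular wave ("tent") used as a noiseless annotation truth.
tent_series <- function(rise = 20, n_apex = 1, slope = 0.1) {
  half <- slope * (0:rise)
  y <- half
  for (k in seq_len(n_apex)) {
    y <- c(y, rev(half)[-1])
    if (k < n_apex) y <- c(y, half[-1])
  }
  y
}
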
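# Independent oracles used to cross-check package computations.

# brute-force random-intercept Bernoulli-logit log-likelihood: numerical
# integration of each group's integral over +-8 SD (adaptive quadrature via
# integrate()), independent of lme4's adaptive Gauss-Hermite path
bruteforce_melr_loglik <- function(y, X, group, beta, sd_b) {
  eta <- as.numeric(X %*% beta)
  ll <- 0
  for (g in unique(group)) {
    sel <- group == g
    f <- function(b) {
      sapply(b, function(bi) {
        p <- stats::plogis(eta[sel] + bi)
        exp(sum(stats::dbinom(y[sel], 1, p, log = TRUE))) *
          stats::dnorm(bi, 0, sd_b)
      })
    }
    v <- stats::integrate(f, -8 * sd_b, 8 * sd_b, rel.tol = 1e-12)$value
    ll <- ll + log(v)
  }
  ll
}

# direct grid evaluation of the unnormalized refinement posterior for a tiny
# problem (used against the MCMC marginals)
grid_posterior <- function(pairs, calib, move, mask, lat_grid, lon_grid,
                           fixed_states = NULL) {
  stopifnot(nrow(pairs) == 1 || !is.null(fixed_states))
  logpost <- matrix(NA_real_, length(lat_grid), length(lon_grid))
  for (i in seq_along(lat_grid)) for (j in seq_along(lon_grid)) {
    la <- lat_grid[i]; lo <- lon_grid[j]
    lp <- wheatrack:::.twilight_loglik(pairs$date[1], la, lo, pairs$rise[1],
                                       pairs$set[1], calib) +
      wheatrack:::.mask_logw(mask, la, lo)
    if (!is.null(fixed_states)) {
      for (k in seq_len(nrow(fixed_states))) {
        spd <- gc_distance_km(la, lo, fixed_states$lat[k], fixed_states$lon[k]) /
          fixed_states$dt_h[k]
        lp <- lp + stats::dgamma(max(spd, 1e-12), move$shape, move$rate, log = TRUE)
      }
    }
    logpost[i, j] <- lp
  }
  logpost
}
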
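# Standardization, VIF, mixed-model fits, posterior simulation, R-squared.

sim_binary_table <- function(n, beta, ranef_sd = 0, ngroups = 4, seed = 1) {
  set.seed(seed)
  df <- data.frame(x1 = rnorm(n), x2 = rnorm(n),
                   year = sample(ngroups, n, replace = TRUE))
  b <- rnorm(ngroups, 0, ranef_sd)
  eta <- beta[1] + beta[2] * df$x1 + beta[3] * df$x2 + b[df$year]
  df$y <- rbinom(n, 1, plogis(eta))
  df
}

sim_gauss_table <- function(n, beta, sigma = 1, ranef_sd = 0, ngroups = 4,
                            seed = 1) {
  set.seed(seed)
  df <- data.frame(x1 = rnorm(n), x2 = rnorm(n),
                   year = sample(ngroups, n, replace = TRUE))
  b <- rnorm(ngroups, 0, ranef_sd)
  df$y <- beta[1] + beta[2] * df$x1 + beta[3] * df$x2 + b[df$year] +
    rnorm(n, 0, sigma)
  df
}

bin_spec <- model_spec("y", fixed = c("x1", "x2"), interactions = character(),
                       moderator = "x2", family = "binomial")
gau_spec <- model_spec("y", fixed = c("x1", "x2"), interactions = character(),
                       moderator = "x2", family = "gaussian")

test_that("z_transform centres and scales exactly, and is idempotent", {
  set.seed(2)
  df <- data.frame(a = rnorm(50, 5, 3), b = runif(50))
  z <- z_transform(df, c("a", "b"))
  for (cl in c("a", "b")) {
    expect_lt(abs(mean(z[[cl]])), 1e-12)
    expect_lt(abs(sd(z[[cl]]) - 1), 1e-12)
  }
  z2 <- z_transform(z, "a")
  expect_equal(z2$a, z$a, tolerance = 1e-12)
  expect_error(z_transform(data.frame(c = rep(1, 5)), "c"), "zero variance")
  expect_named(attr(z, "z_scaling"), c("a", "b"))
})

test_that("VIF matches the closed form and screens iteratively", {
  set.seed(3)
  n <- 400
  x1 <- rnorm(n); x2 <- rnorm(n)   # orthogonal in expectation
  v0 <- vif_screen(data.frame(x1 = x1, x2 = x2), c("x1", "x2"))
  expect_lt(max(v0$vif), 1.1)
  expect_length(v0$dropped, 0)
  # closed form for any 2-predictor design: VIF = 1/(1-r^2)
  x3 <- 0.9 * x1 + sqrt(1 - 0.81) * rnorm(n)
  r2 <- cor(x1, x3)^2
  v1 <- vif_screen(data.frame(x1 = x1, x3 = x3), c("x1", "x3"), threshold = 2)
  expect_equal(unname(v1$history[[1]]["x1"]), 1 / (1 - r2), tolerance = 1e-9)
  expect_equal(v1$dropped, "x3")   # tie on 2 predictors: later-listed drops
  # perfect collinearity: deterministic drop with warning
  expect_warning(v2 <- vif_screen(data.frame(a = x1, b = 2 * x1), c("a", "b")),
                 "perfect collinearity")
  expect_equal(v2$dropped, "b")
})

test_that("temperature collinear with remaining distance is screened out", {
  set.seed(4)
  n <- 300
  remdist <- seq(8000, 100, length.out = n) + rnorm(n, 0, 200)
  temperature <- 25 - 0.0025 * remdist + rnorm(n, 0, 1.5)  # r ~ -0.95
  press <- rnorm(n)
  v <- vif_screen(data.frame(temperature = temperature,
                             remaining_distance = remdist, pressure = press),
                  c("temperature", "remaining_distance", "pressure"),
                  threshold = 2)
  expect_true("temperature" %in% v$dropped ||
                "remaining_distance" %in% v$dropped)
  expect_false("pressure" %in% v$dropped)
})

test_that("MELR recovers known coefficients within 3 SE", {
  df <- sim_binary_table(5000, c(-0.5, 0.8, -0.4), ranef_sd = 0.3,
                         ngroups = 6, seed = 10)
  fit <- fit_melr(df, bin_spec)
  se <- sqrt(diag(fit$vcov))
  truth <- c(-0.5, 0.8, -0.4)
  for (k in 1:3) expect_lt(abs(fit$coef[k] - truth[k]), 3 * se[k])
  expect_gt(fit$scale_parameter, 0.75)
  expect_lt(fit$scale_parameter, 1.4)
})

test_that("a near-zero random-intercept variance is recovered at the boundary", {
  df <- sim_binary_table(3000, c(0.2, 0.5, 0), ranef_sd = 0, ngroups = 2,
                         seed = 11)
  fit <- fit_melr(df, bin_spec)
  expect_lt(fit$random_sd, 0.01)
})

test_that("MELR likelihood matches the brute-force quadrature oracle", {
  df <- sim_binary_table(50, c(0, 0.7, -0.3), ranef_sd = 0.6, ngroups = 5,
                         seed = 12)
  fit <- fit_melr(df, bin_spec, nAGQ = 25)
  X <- model.matrix(~ x1 + x2, fit$data)
  ll <- bruteforce_melr_loglik(fit$data$y, X, fit$data$year, fit$coef,
                               max(fit$random_sd, 1e-8))
  expect_lt(abs(ll - fit$loglik), 1e-6)
})

test_that("LMM recovers slopes; equal weights match the unweighted fit", {
  df <- sim_gauss_table(4000, c(1, 0.5, -0.25), sigma = 0.8, ranef_sd = 0.2,
                        ngroups = 6, seed = 13)
  fit <- fit_lmm(df, gau_spec)
  se <- sqrt(diag(fit$vcov))
  truth <- c(1, 0.5, -0.25)
  for (k in 1:3) expect_lt(abs(fit$coef[k] - truth[k]), 3 * se[k])

  df$wcol <- rep(2, nrow(df))
  spec_w <- model_spec("y", fixed = c("x1", "x2"), moderator = "x2",
                       weights = "wcol", family = "gaussian")
  fit_w <- fit_lmm(df, spec_w)
  expect_equal(unname(fit_w$coef), unname(fit$coef), tolerance = 1e-8)
})

test_that("a noise-free constructed regression returns its analytic slope", {
  # total speed = c / duration exactly: log10(speed) on log10(duration)
  # has slope -1 and intercept log10(c)
  dur <- c(20, 25, 32, 40, 50, 64, 80, 100)
  df <- data.frame(y = 4000 / dur, ld = log10(dur),
                   year = rep(1:2, 4))
  spec <- model_spec("y", transform = "log10", fixed = "ld", moderator = "ld",
                     family = "gaussian")
  fit <- suppressWarnings(fit_lmm(df, spec))
  expect_equal(unname(fit$coef["ld"]), -1, tolerance = 1e-8)
  expect_equal(unname(fit$coef["(Intercept)"]), log10(4000), tolerance = 1e-8)
})

test_that("posterior simulation is centred on the fit and converges to the normal interval", {
  df <- sim_gauss_table(800, c(0.3, 0.5, -0.2), sigma = 1, ranef_sd = 0.2,
                        seed = 14)
  fit <- fit_lmm(df, gau_spec)
  cri <- posterior_sim(fit, n = 100000, seed = 1)
  se <- sqrt(diag(fit$vcov))
  for (k in seq_along(fit$coef)) {
    expect_lt(abs(cri$estimate[k] - fit$coef[k]), 3 * se[k] / sqrt(1000))
    # large-n draws approach the normal-approximation interval
    expect_equal(unname(cri$upper[k] - cri$lower[k]),
                 unname(2 * qnorm(0.975) * se[k]), tolerance = 0.05)
  }
  expect_true(all(cri$lower <= cri$estimate & cri$estimate <= cri$upper))
  expect_error(posterior_sim(fit, n = 100), "at least 1000")
})

test_that("credible-interval coverage is nominal across replicates", {
  # all true effects zero: every 95% CrI should contain 0 in ~95% of
  # replicates (pooled over the two slope terms, both families)
  hits <- 0; total <- 0
  for (r in 1:60) {
    dfb <- sim_binary_table(250, c(0, 0, 0), ranef_sd = 0.2, seed = 2000 + r)
    fb <- fit_melr(dfb, bin_spec, nAGQ = 9)
    cb <- posterior_sim(fb, n = 1000, seed = r)
    dfg <- sim_gauss_table(200, c(0, 0, 0), sigma = 1, ranef_sd = 0.2,
                           seed = 3000 + r)
    fg <- fit_lmm(dfg, gau_spec)
    cg <- posterior_sim(fg, n = 1000, seed = r)
    for (cri in list(cb, cg)) {
      sl <- cri$term %in% c("x1", "x2")
      hits <- hits + sum(cri$lower[sl] < 0 & cri$upper[sl] > 0)
      total <- total + sum(sl)
    }
  }
  expect_gte(hits / total, 0.92)
  expect_lte(hits / total, 0.98)
})

test_that("R-squared partitions variance as expected", {
  # no random variance: marginal equals conditional
  df <- sim_gauss_table(2000, c(0, 0.8, -0.5), sigma = 0.5, ranef_sd = 0,
                        seed = 15)
  fit <- suppressWarnings(fit_lmm(df, gau_spec))
  r2 <- r_squared(fit)
  expect_equal(unname(r2["marginal"]), unname(r2["conditional"]),
               tolerance = 0.02)
  # pure noise: both near zero
  df0 <- sim_gauss_table(5000, c(0, 0, 0), sigma = 1, ranef_sd = 0, seed = 16)
  r20 <- r_squared(suppressWarnings(fit_lmm(df0, gau_spec)))
  expect_lt(r20["conditional"], 0.05)
  # fixed effects explain (nearly) everything as sigma -> 0
  df1 <- sim_gauss_table(1000, c(0, 1, 1), sigma = 0.01, ranef_sd = 0, seed = 17)
  r21 <- r_squared(suppressWarnings(fit_lmm(df1, gau_spec)))
  expect_gt(r21["marginal"], 0.99)
})

test_that("scale equivariance: fitted probabilities agree on raw vs z-scored covariates", {
  df <- sim_binary_table(1500, c(-0.2, 0.6, -0.3), ranef_sd = 0.2, seed = 18)
  df$x1 <- 5 + 3 * df$x1; df$x2 <- -2 + 0.5 * df$x2   # un-standardized
  fit_raw <- fit_melr(df, bin_spec)
  zdf <- z_transform(df, c("x1", "x2"))
  fit_z <- fit_melr(zdf, bin_spec)
  p_raw <- fitted(fit_raw$model)
  p_z <- fitted(fit_z$model)
  expect_equal(as.numeric(p_raw), as.numeric(p_z), tolerance = 1e-5)
})

test_that("effect predictions flatten without an interaction and flip with one", {
  set.seed(19)
  n <- 4000
  df <- data.frame(x1 = rnorm(n), remaining_distance = rnorm(n),
                   year = sample(3, n, replace = TRUE))
  # sign-flipping interaction: slope +1 at high distance, -1 at low
  eta <- 0 + 0 * df$x1 + 1.0 * df$x1 * df$remaining_distance
  df$y <- rbinom(n, 1, plogis(eta))
  spec <- model_spec("y", fixed = c("x1", "remaining_distance"),
                     interactions = "x1", family = "binomial")
  fit <- fit_melr(df, spec)
  ep <- effect_predictions(fit, "x1", bins = 5, seed = 1)
  # slope of predictions across x1 within the lowest and highest moderator bin
  for (side in c(min(ep$moderator_value), max(ep$moderator_value))) {
    sel <- ep$moderator_value == side
    slope <- unname(coef(lm(fit ~ term_value, ep[sel, ]))[2])
    expect_equal(sign(slope), sign(side))
  }
  # intercept-only prediction at covariate means equals inverse-link intercept
  df0 <- df; df0$y <- rbinom(n, 1, plogis(0.7 + 0 * df0$x1))
  fit0 <- fit_melr(df0, spec)
  ep0 <- effect_predictions(fit0, "x1", bins = 3, seed = 1)
  centre <- ep0[which.min(abs(ep0$term_value) + abs(ep0$moderator_value)), ]
  expect_equal(centre$fit, plogis(sum(fit0$coef * c(1, mean(df0$x1),
                                                    mean(df0$remaining_distance),
                                                    centre$term_value * centre$moderator_value))),
               tolerance = 0.02)
})
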
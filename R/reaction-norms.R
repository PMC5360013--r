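# The statistical layer: z-transformation, VIF collinearity screening,
# mixed-effects logistic regression for departure probability, weighted
# linear mixed models for travel speed and total speed of migration,
# flat-prior posterior simulation for credible intervals, effect
# predictions over binned interaction grids, and variance-partition
# R-squared.

#' z-transform columns of a table
#'
#' Centres and scales each named column to unit SD, storing the scalings
#' (for back-transformation of effect plots) in the `z_scaling` attribute.
#'
#' @param table A data.frame.
#' @param columns Character vector of numeric column names.
#' @return The table with transformed columns and a `z_scaling` attribute
#'   (named list of `c(mean, sd)`).
#' @export
z_transform <- function(table, columns) {
  scaling <- list()
  for (cl in columns) {
    x <- table[[cl]]
    if (!is.numeric(x)) stop(sprintf("column '%s' is not numeric", cl))
    m <- mean(x, na.rm = TRUE); s <- stats::sd(x, na.rm = TRUE)
    if (!is.finite(s) || s == 0)
      stop(sprintf("column '%s' has zero variance; cannot z-transform", cl))
    table[[cl]] <- (x - m) / s
    scaling[[cl]] <- c(mean = m, sd = s)
  }
  attr(table, "z_scaling") <- scaling
  table
}

#' Variance-inflation-factor screening
#'
#' VIF_i = 1 / (1 - R^2_i) from regressing predictor i on the others;
#' the largest-VIF predictor is dropped iteratively until all VIFs fall
#' below the threshold. A perfectly collinear pair drops the later-listed
#' predictor deterministically, with a warning.
#'
#' @param table Data with the predictor columns.
#' @param predictors Character vector (>= 2) of predictor names.
#' @param threshold VIF threshold (> 1), default 2.
#' @return List: `retained`, `dropped`, `vif` (final values), `history`.
#' @export
vif_screen <- function(table, predictors, threshold = 2) {
  if (threshold <= 1) stop("'threshold' must exceed 1")
  if (length(predictors) < 2) stop("need at least 2 predictors")
  X <- stats::na.omit(as.data.frame(table)[predictors])
  dropped <- character()
  history <- list()
  repeat {
    keep <- setdiff(predictors, dropped)
    if (length(keep) < 2) break
    vif <- vapply(keep, function(p) {
      fit <- stats::lm.fit(cbind(1, as.matrix(X[setdiff(keep, p)])), X[[p]])
      r2 <- 1 - sum(fit$residuals^2) / sum((X[[p]] - mean(X[[p]]))^2)
      if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
    }, numeric(1))
    history[[length(history) + 1]] <- vif
    if (all(vif < threshold)) break
    worst <- which(vif == max(vif))
    # deterministic tie-break: drop the later-listed predictor
    drop_this <- keep[worst[length(worst)]]
    if (is.infinite(max(vif)))
      warning(sprintf("perfect collinearity: dropping '%s'", drop_this))
    dropped <- c(dropped, drop_this)
  }
  keep <- setdiff(predictors, dropped)
  final_vif <- if (length(history)) history[[length(history)]] else NULL
  list(retained = keep, dropped = dropped, vif = final_vif,
       history = history)
}

#' Model specification for the reaction-norm fits
#'
#' @param response Response column name.
#' @param transform "identity" or "log10" applied to the response (and
#'   recorded for back-transformation).
#' @param fixed Main-effect covariate names.
#' @param interactions Covariates interacting with `moderator`.
#' @param moderator Moderating covariate (default "remaining_distance").
#' @param random Random-intercept factor column (default "year").
#' @param weights Optional weights column name (for latitude-SD weighting
#'   use the precomputed inverse SD).
#' @param family "binomial" (logit) or "gaussian".
#' @return List of class `model_spec`.
#' @export
model_spec <- function(response, transform = c("identity", "log10"),
                       fixed = character(), interactions = character(),
                       moderator = "remaining_distance",
                       random = "year", weights = NULL,
                       family = c("binomial", "gaussian")) {
  transform <- match.arg(transform)
  family <- match.arg(family)
  if (length(interactions) && !all(interactions %in% fixed))
    stop("every interaction's main effect must be among the fixed terms")
  structure(list(response = response, transform = transform, fixed = fixed,
                 interactions = interactions, moderator = moderator,
                 random = random, weights = weights, family = family),
            class = "model_spec")
}

.spec_formula <- function(spec, random = TRUE) {
  rhs <- spec$fixed
  if (length(spec$interactions))
    rhs <- c(rhs, paste0(spec$interactions, ":", spec$moderator))
  if (!length(rhs)) rhs <- "1"
  rhs <- paste(rhs, collapse = " + ")
  if (random && !is.null(spec$random))
    rhs <- paste0(rhs, " + (1 | ", spec$random, ")")
  stats::as.formula(paste(".response ~", rhs))
}

.prep_model_frame <- function(table, spec) {
  df <- as.data.frame(table)
  y <- df[[spec$response]]
  if (spec$transform == "log10") {
    if (any(y <= 0, na.rm = TRUE))
      stop("log10 transform needs a strictly positive response")
    y <- log10(y)
  }
  df$.response <- y
  need <- c(".response", spec$fixed, spec$moderator, spec$random, spec$weights)
  need <- intersect(unique(need), names(df))
  ok <- stats::complete.cases(df[need])
  list(df = df[ok, , drop = FALSE], dropped = sum(!ok))
}

#' Mixed-effects logistic regression (departure probability)
#'
#' Binary response with one random intercept, fitted by maximum likelihood
#' with adaptive Gauss-Hermite quadrature (`lme4::glmer`, `nAGQ` nodes;
#' a single scalar grouping factor makes the quadrature exact to high
#' order). With fewer than 2 grouping levels the model falls back to a
#' fixed-intercept logistic regression with a warning. The overdispersion
#' scale parameter is the sum of squared Pearson residuals over the
#' residual degrees of freedom.
#'
#' @param table A bird-day table (stopover rows) or any data.frame.
#' @param spec A [model_spec()] with `family = "binomial"`.
#' @param nAGQ Quadrature nodes (default 15).
#' @return A list of class `fit_result`; see [posterior_sim()] for the
#'   credible intervals.
#' @export
fit_melr <- function(table, spec, nAGQ = 15) {
  stopifnot(spec$family == "binomial")
  pp <- .prep_model_frame(table, spec)
  df <- pp$df
  ngroups <- length(unique(df[[spec$random]]))
  if (ngroups < 2) {
    warning("fewer than 2 grouping levels: falling back to fixed-intercept logistic")
    fit <- stats::glm(.spec_formula(spec, random = FALSE), data = df,
                      family = stats::binomial())
    beta <- stats::coef(fit)
    V <- stats::vcov(fit)
    ransd <- NA_real_
    pearson <- stats::residuals(fit, type = "pearson")
    scale_par <- sum(pearson^2) / stats::df.residual(fit)
    ll <- as.numeric(stats::logLik(fit))
  } else {
    df[[spec$random]] <- factor(df[[spec$random]])
    fit <- lme4::glmer(.spec_formula(spec), data = df,
                       family = stats::binomial(), nAGQ = nAGQ)
    if (any(abs(lme4::fixef(fit)) > 15))
      stop("complete separation suspected: |coefficient| > 15 for ",
           paste(names(which(abs(lme4::fixef(fit)) > 15)), collapse = ", "))
    beta <- lme4::fixef(fit)
    V <- as.matrix(stats::vcov(fit))
    ransd <- sqrt(unlist(lme4::VarCorr(fit))[[1]])
    pearson <- stats::residuals(fit, type = "pearson")
    scale_par <- sum(pearson^2) / (nrow(df) - length(beta) - 1)
    ll <- as.numeric(stats::logLik(fit))
  }
  structure(list(model = fit, spec = spec, coef = beta, vcov = V,
                 random_sd = ransd, resid_sd = NA_real_,
                 scale_parameter = scale_par, loglik = ll,
                 n = nrow(df), n_dropped = pp$dropped, data = df,
                 family = "binomial"),
            class = "fit_result")
}

#' Weighted linear mixed model (travel speed, total speed of migration)
#'
#' REML fit with one random intercept and optional observation weights
#' (e.g. inverse latitude-SD). A singular random effect is retained with
#' its SD reported as ~0 and flagged.
#'
#' @param table Data.
#' @param spec A [model_spec()] with `family = "gaussian"`.
#' @return A `fit_result`.
#' @export
fit_lmm <- function(table, spec) {
  stopifnot(spec$family == "gaussian")
  pp <- .prep_model_frame(table, spec)
  df <- pp$df
  w <- if (!is.null(spec$weights)) df[[spec$weights]] else rep(1, nrow(df))
  if (any(w <= 0)) stop("weights must be positive")
  df$.w <- w
  ngroups <- length(unique(df[[spec$random]]))
  singular <- FALSE
  if (ngroups < 2) {
    warning("fewer than 2 grouping levels: falling back to weighted least squares")
    fit <- stats::lm(.spec_formula(spec, random = FALSE), data = df, weights = .w)
    beta <- stats::coef(fit)
    V <- stats::vcov(fit)
    ransd <- NA_real_
    sigma <- summary(fit)$sigma
    dfres <- stats::df.residual(fit)
  } else {
    df[[spec$random]] <- factor(df[[spec$random]])
    fit <- suppressMessages(lme4::lmer(.spec_formula(spec), data = df,
                                       weights = .w, REML = TRUE))
    singular <- lme4::isSingular(fit)
    beta <- lme4::fixef(fit)
    V <- as.matrix(stats::vcov(fit))
    ransd <- sqrt(unlist(lme4::VarCorr(fit))[[1]])
    sigma <- stats::sigma(fit)
    dfres <- nrow(df) - length(beta) - 1
  }
  structure(list(model = fit, spec = spec, coef = beta, vcov = V,
                 random_sd = ransd, resid_sd = sigma, resid_df = dfres,
                 scale_parameter = NA_real_, loglik = as.numeric(stats::logLik(fit)),
                 n = nrow(df), n_dropped = pp$dropped, data = df,
                 family = "gaussian", singular = singular),
            class = "fit_result")
}

#' Posterior simulation for credible intervals
#'
#' Simulates from the joint posterior under improper flat priors,
#' p(beta) ~ 1 and p(sigma) ~ 1/sigma: for gaussian fits sigma^2 is drawn
#' from its scaled inverse-chi-square distribution and the coefficients
#' from a multivariate normal around the estimates scaled by the drawn
#' sigma; for binomial fits the coefficients are drawn from the asymptotic
#' normal on the link scale. The estimate is the median of the draws; the
#' 95% credible interval the 2.5% and 97.5% quantiles; an effect is
#' significant when its interval excludes zero.
#'
#' @param fit A `fit_result`.
#' @param n Number of draws (>= 1000; default 2000).
#' @param seed Optional integer seed.
#' @return data.frame of class `cri_table`: term, estimate, lower, upper,
#'   significant; the draws are in the `draws` attribute.
#' @export
posterior_sim <- function(fit, n = 2000, seed = NULL) {
  if (n < 1000) stop("need at least 1000 posterior draws")
  if (!is.null(seed)) set.seed(seed)
  V <- (V <- fit$vcov)
  V <- (V + t(V)) / 2
  ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) stop("non-positive-definite coefficient covariance")
  if (fit$family == "gaussian") {
    dfres <- fit$resid_df
    sig2 <- fit$resid_sd^2 * dfres / stats::rchisq(n, dfres)
    scale <- sig2 / fit$resid_sd^2
    Z <- MASS::mvrnorm(n, mu = rep(0, length(fit$coef)), Sigma = V)
    draws <- sweep(Z * sqrt(scale), 2, -fit$coef)
    sigma_draws <- sqrt(sig2)
  } else {
    draws <- MASS::mvrnorm(n, mu = fit$coef, Sigma = V)
    sigma_draws <- NULL
  }
  colnames(draws) <- names(fit$coef)
  est <- apply(draws, 2, stats::median)
  lo <- apply(draws, 2, stats::quantile, 0.025)
  hi <- apply(draws, 2, stats::quantile, 0.975)
  out <- data.frame(term = names(fit$coef), estimate = est, lower = lo,
                    upper = hi, significant = lo > 0 | hi < 0,
                    row.names = NULL)
  attr(out, "draws") <- draws
  attr(out, "sigma_draws") <- sigma_draws
  class(out) <- c("cri_table", "data.frame")
  out
}

#' Marginal and conditional R-squared (variance partition)
#'
#' Fixed-effects variance over total variance (marginal) and fixed plus
#' random over total (conditional), with the distribution-specific
#' residual variance pi^2/3 on the latent scale for the logit family.
#'
#' @param fit A `fit_result`.
#' @return c(marginal, conditional).
#' @export
r_squared <- function(fit) {
  X <- stats::model.matrix(stats::as.formula(
    paste("~", paste(labels(stats::terms(.spec_formula(fit$spec, random = FALSE))),
                     collapse = "+"))), fit$data)
  eta <- as.numeric(X %*% fit$coef[colnames(X)])
  var_f <- stats::var(eta)
  var_r <- if (is.na(fit$random_sd)) 0 else fit$random_sd^2
  var_e <- if (fit$family == "binomial") pi^2 / 3 else fit$resid_sd^2
  tot <- var_f + var_r + var_e
  c(marginal = var_f / tot, conditional = (var_f + var_r) / tot)
}

#' Effect predictions over a binned interaction grid
#'
#' Summarizes the two interacting covariates into five categories each
#' (quantile bins, represented by their within-bin means), fixes all other
#' covariates at their means, and predicts the response (inverse link) with
#' 95% intervals from the posterior draws. Cells outside the jointly
#' observed covariate envelope are marked unsupported rather than
#' extrapolated.
#'
#' @param fit A `fit_result` whose spec contains the interaction.
#' @param term The covariate interacting with the spec's moderator.
#' @param bins Number of categories per axis (default 5).
#' @param n_draws Posterior draws for the intervals.
#' @param seed Optional seed.
#' @return data.frame: term value, moderator value, fit, lower, upper,
#'   supported.
#' @export
effect_predictions <- function(fit, term, bins = 5, n_draws = 2000,
                               seed = NULL) {
  spec <- fit$spec
  if (!(term %in% spec$interactions))
    stop(sprintf("'%s' does not interact with '%s' in this fit", term,
                 spec$moderator))
  df <- fit$data
  binmeans <- function(x) {
    br <- unique(stats::quantile(x, seq(0, 1, length.out = bins + 1)))
    cut_i <- cut(x, br, include.lowest = TRUE)
    as.numeric(tapply(x, cut_i, mean))
  }
  tv <- binmeans(df[[term]]); mv <- binmeans(df[[spec$moderator]])
  grid <- expand.grid(tv = tv, mv = mv)

  newdata <- df[rep(1, nrow(grid)), , drop = FALSE]
  for (cl in c(spec$fixed, spec$moderator))
    newdata[[cl]] <- mean(df[[cl]])
  newdata[[term]] <- grid$tv
  newdata[[spec$moderator]] <- grid$mv

  X <- stats::model.matrix(stats::as.formula(
    paste("~", paste(labels(stats::terms(.spec_formula(spec, random = FALSE))),
                     collapse = "+"))), newdata)
  sims <- posterior_sim(fit, n = max(n_draws, 1000), seed = seed)
  draws <- attr(sims, "draws")
  eta <- draws[, colnames(X)] %*% t(X)
  inv <- if (fit$family == "binomial") stats::plogis else identity
  pred <- inv(X %*% fit$coef[colnames(X)])

  # supported = some observation falls in the joint cell
  tcut <- cut(df[[term]], unique(stats::quantile(df[[term]], seq(0, 1, length.out = bins + 1))),
              include.lowest = TRUE)
  mcut <- cut(df[[spec$moderator]], unique(stats::quantile(df[[spec$moderator]], seq(0, 1, length.out = bins + 1))),
              include.lowest = TRUE)
  occupied <- table(tcut, mcut) > 0
  ti <- rep(seq_along(tv), times = length(mv))
  mi <- rep(seq_along(mv), each = length(tv))

  data.frame(term = term, term_value = grid$tv,
             moderator_value = grid$mv,
             fit = as.numeric(pred),
             lower = inv(apply(eta, 2, stats::quantile, 0.025)),
             upper = inv(apply(eta, 2, stats::quantile, 0.975)),
             supported = occupied[cbind(ti, mi)])
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> %s, n = %d (%d rows dropped), random SD = %s\n",
              x$family, x$n, x$n_dropped,
              if (is.na(x$random_sd)) "NA" else sprintf("%.4f", x$random_sd)))
  print(round(cbind(estimate = x$coef), 3))
  invisible(x)
}
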
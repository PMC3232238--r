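#' Model configuration for the four-model ladder
#'
#' The ladder adds spatial structure step by step:
#' \describe{
#'   \item{model 1}{independent per-zone regressions of log density on year
#'     ("no pooling"); diffuse independent priors, no shared hyperparameters.}
#'   \item{model 2}{hierarchical zone-specific intercepts and year slopes
#'     with shared hyper-mean and hyper-SDs; independent residuals.}
#'   \item{model 3}{model 2 plus the standardized elevation covariate.}
#'   \item{model 4}{model 3 plus zone-specific exponential spatial
#'     covariance (partial sill, decay, nugget) on the residuals, as in
#'     stratified kriging.}
#' }
#'
#' Priors follow the conventional diffuse scheme: coefficient hyper-SDs
#' uniform(0, 100); variances (partial sill, nugget, residual) inverse
#' gamma(0.1, 0.1); decay `phi_k` uniform between data-driven bounds from
#' [phi_prior_bounds()]; hyper-means normal(0, `mu_prior_sd`).
#'
#' @param model ladder rung, 1-4.
#' @param include_elevation logical; default `FALSE` for models 1-2,
#'   `TRUE` for models 3-4. Set `FALSE` explicitly for reference-site fits.
#' @param offset additive constant `c` in the log response
#'   `log(count + c)` (default 1), making zero counts representable.
#' @param sd_beta_max upper bound of the uniform prior on hyper-SDs.
#' @param ig_shape,ig_rate inverse-gamma hyperparameters for variances.
#' @param mu_prior_sd SD of the normal prior on hyper-means (and on the
#'   independent per-zone coefficients in model 1).
#' @return An object of class `zt_config`.
#' @export
model_config <- function(model = 4, include_elevation = NULL, offset = 1,
                         sd_beta_max = 100, ig_shape = 0.1, ig_rate = 0.1,
                         mu_prior_sd = 1000) {
  if (!model %in% 1:4) stopf("model must be 1, 2, 3 or 4")
  include_elevation <- include_elevation %||% (model >= 3)
  if (model == 2 && include_elevation)
    stopf("model 2 excludes the elevation covariate")
  if (offset <= 0) stopf("offset must be > 0")
  structure(list(model = as.integer(model),
                 include_elevation = include_elevation,
                 offset = offset, sd_beta_max = sd_beta_max,
                 ig_shape = ig_shape, ig_rate = ig_rate,
                 mu_prior_sd = mu_prior_sd),
            class = "zt_config")
}

#' Per-zone design matrices with the standard centering rules
#'
#' Builds `X_k = [1, year - mean(year), (elev - mean(elev))/sd(elev)]`
#' (elevation column only when the configuration includes it), plus the
#' centering rules needed to invert the transforms at reporting time.
#' Intercepts therefore read as log median density at mean elevation in
#' the middle of the study period. Plot coordinates are centered on the
#' site centroid (distances are unaffected; this mirrors standard
#' geostatistical practice for numerical stability).
#'
#' @param data plot table with `zone`, `x`, `y`, `year`, `count` and
#'   (if used) `elevation`.
#' @param cfg a [model_config()].
#' @return List with `zones`, per-zone row indices `idx`, design matrices
#'   `X`, coordinates `coords`, and `centering` (year center, elevation
#'   mean/sd, coordinate centroid).
#' @export
build_design <- function(data, cfg = model_config()) {
  if (!nrow(data)) stopf("data is empty")
  need <- c("zone", "x", "y", "year", "count")
  if (!all(need %in% names(data))) stopf("data needs columns zone,x,y,year,count")
  zones <- sort(unique(as.character(data$zone)))
  cnt <- table(data$zone)
  if (any(cnt < 2)) stopf("every zone needs at least 2 rows")
  year_center <- mean(data$year)
  centroid <- c(x = mean(data$x), y = mean(data$y))
  elev_mean <- NA_real_; elev_sd <- NA_real_
  if (cfg$include_elevation) {
    if (!"elevation" %in% names(data)) stopf("data needs an elevation column")
    elev_mean <- mean(data$elevation)
    elev_sd <- stats::sd(data$elevation)
    if (!is.finite(elev_sd) || elev_sd == 0)
      stopf("elevation has zero variance; cannot standardize (drop the covariate)")
  }
  idx <- lapply(zones, function(z) which(data$zone == z))
  names(idx) <- zones
  X <- lapply(idx, function(i) {
    x <- cbind(intercept = 1, year = data$year[i] - year_center)
    if (cfg$include_elevation)
      x <- cbind(x, elevation = (data$elevation[i] - elev_mean) / elev_sd)
    x
  })
  coords <- lapply(idx, function(i)
    cbind(x = data$x[i] - centroid["x"], y = data$y[i] - centroid["y"]))
  list(zones = zones, idx = idx, X = X, coords = coords,
       centering = list(year_center = year_center, elev_mean = elev_mean,
                        elev_sd = elev_sd, centroid = centroid))
}

#' Log-scale response from counts
#'
#' `log(count + c)` with offset `c` (default 1), the minimal device for
#' carrying zero counts into a lognormal model; exactly invertible via
#' `exp(y) - c`.
#'
#' @param counts non-negative integer vector.
#' @param cfg a [model_config()] or a numeric offset.
#' @return Numeric log-scale response.
#' @export
log_response <- function(counts, cfg = model_config()) {
  offset <- if (inherits(cfg, "zt_config")) cfg$offset else cfg
  if (any(counts < 0)) stopf("counts must be non-negative")
  log(counts + offset)
}

# multivariate normal log density given an upper Cholesky factor of Sigma
.ll_mvn_chol <- function(r, U) {
  z <- backsolve(U, r, transpose = TRUE)
  -0.5 * length(r) * log(2 * pi) - sum(log(diag(U))) - 0.5 * sum(z^2)
}

# Sigma = sigma2 exp(-phi D) + (tau2 + jitter) I, jitter = 1e-8 (sigma2+tau2)
.zone_chol <- function(D, sigma2, phi, tau2) {
  n <- nrow(D)
  S <- sigma2 * exp(-phi * D) + diag(tau2 + 1e-8 * (sigma2 + tau2), n)
  tryCatch(chol(S), error = function(e)
    stopf("covariance factorization failed after jitter (sigma2=%.3g, phi=%.3g, tau2=%.3g)",
          sigma2, phi, tau2))
}

#' Log likelihood of a parameter set
#'
#' Model 4: sum over zones of the multivariate normal log density of the
#' log response with mean `X_k beta_k` and covariance
#' `sigma2_k exp(-phi_k D_k) + tau2_k I` (the spatial random effect is
#' marginalized into the covariance). Models 1-3: independent normal
#' errors with per-zone residual variance. Zones contribute additively
#' (independent blocks).
#'
#' @param data plot table.
#' @param params list with `beta` (named list or matrix of per-zone
#'   coefficient vectors) and, for model 4, named vectors `sigma2`, `phi`,
#'   `tau2` per zone; for models 1-3 a named vector `resid_var`.
#' @param cfg a [model_config()].
#' @return Scalar log likelihood.
#' @export
log_likelihood <- function(data, params, cfg = model_config()) {
  des <- build_design(data, cfg)
  y <- log_response(data$count, cfg)
  ll <- 0
  for (z in des$zones) {
    i <- des$idx[[z]]
    b <- if (is.matrix(params$beta)) params$beta[, z] else params$beta[[z]]
    r <- y[i] - drop(des$X[[z]] %*% b)
    if (cfg$model == 4) {
      D <- as.matrix(stats::dist(des$coords[[z]]))
      U <- .zone_chol(D, params$sigma2[[z]], params$phi[[z]], params$tau2[[z]])
      ll <- ll + .ll_mvn_chol(r, U)
    } else {
      v <- params$resid_var[[z]]
      ll <- ll + sum(stats::dnorm(r, 0, sqrt(v), log = TRUE))
    }
  }
  ll
}

#' Log prior of a parameter set
#'
#' Models 2-4: zone coefficients are normal around the hyper-mean with the
#' hyper-SDs; hyper-means normal(0, `mu_prior_sd`); hyper-SDs
#' uniform(0, `sd_beta_max`). Model 1: independent normal(0, `mu_prior_sd`)
#' per zone coefficient, no hyper terms. Variances (residual, partial
#' sill, nugget) are inverse-gamma(`ig_shape`, `ig_rate`); decay `phi_k`
#' uniform within `phi_bounds`. Returns `-Inf` outside support.
#'
#' @param params as in [log_likelihood()].
#' @param hyper list with `mu` and `sd_beta` (ignored for model 1).
#' @param cfg a [model_config()].
#' @param phi_bounds named list (per zone) of `c(phi_min, phi_max)`, or a
#'   single bounds vector recycled; required for model 4.
#' @return Scalar log prior density (possibly `-Inf`).
#' @export
log_prior <- function(params, hyper = NULL, cfg = model_config(),
                      phi_bounds = NULL) {
  beta <- if (is.matrix(params$beta)) params$beta
          else do.call(cbind, params$beta)
  zones <- colnames(beta)
  p <- nrow(beta)
  lp <- 0
  if (cfg$model == 1) {
    lp <- lp + sum(stats::dnorm(beta, 0, cfg$mu_prior_sd, log = TRUE))
  } else {
    mu <- hyper$mu; sdb <- hyper$sd_beta
    if (any(sdb <= 0) || any(sdb >= cfg$sd_beta_max)) return(-Inf)
    for (j in seq_len(p))
      lp <- lp + sum(stats::dnorm(beta[j, ], mu[j], sdb[j], log = TRUE))
    lp <- lp + sum(stats::dnorm(mu, 0, cfg$mu_prior_sd, log = TRUE))
    lp <- lp + sum(stats::dunif(sdb, 0, cfg$sd_beta_max, log = TRUE))
  }
  if (cfg$model == 4) {
    lp <- lp + sum(dinvgamma_log(unlist(params$sigma2), cfg$ig_shape, cfg$ig_rate))
    lp <- lp + sum(dinvgamma_log(unlist(params$tau2), cfg$ig_shape, cfg$ig_rate))
    if (is.null(phi_bounds)) stopf("model 4 needs phi_bounds")
    if (!is.list(phi_bounds))
      phi_bounds <- stats::setNames(rep(list(phi_bounds), length(zones)), zones)
    for (z in zones) {
      b <- phi_bounds[[z]]
      lp <- lp + stats::dunif(params$phi[[z]], b[1], b[2], log = TRUE)
    }
  } else {
    lp <- lp + sum(dinvgamma_log(unlist(params$resid_var), cfg$ig_shape,
                                 cfg$ig_rate))
  }
  lp
}

#' Log posterior (likelihood + prior)
#'
#' @inheritParams log_likelihood
#' @inheritParams log_prior
#' @param data plot table.
#' @return Scalar; finite whenever all parameters are in support and the
#'   data are finite.
#' @export
log_posterior <- function(data, params, hyper = NULL, cfg = model_config(),
                          phi_bounds = NULL) {
  lp <- log_prior(params, hyper, cfg, phi_bounds)
  if (!is.finite(lp)) return(lp)
  lp + log_likelihood(data, params, cfg)
}
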
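#' Pairwise Euclidean distances and their summary
#'
#' @param coords two-column matrix or data frame of x/y coordinates in
#'   metres (at least 2 points).
#' @return A list of class `distance_summary`: `D` (symmetric distance
#'   matrix with zero diagonal), `d_min` (minimum strictly positive
#'   distance; distinct locations are required somewhere in the set) and
#'   `d_max`.
#' @export
pairwise_distances <- function(coords) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 2L) stopf("need at least 2 points")
  D <- as.matrix(stats::dist(coords[, 1:2, drop = FALSE]))
  dimnames(D) <- NULL
  pos <- D[upper.tri(D)]
  pos <- pos[pos > 0]
  if (!length(pos)) stopf("all points coincide; d_min is undefined")
  structure(list(D = D, d_min = min(pos), d_max = max(D)),
            class = "distance_summary")
}

#' Exponential covariance with nugget
#'
#' `Sigma = sigma2 * exp(-phi * D) + tau2 * I`: stationary exponential
#' decay with partial sill `sigma2`, decay rate `phi` (1/m) and nugget
#' `tau2` added on the diagonal (zero-lag variance `sigma2 + tau2`).
#'
#' @param D distance matrix (metres) or a `distance_summary`.
#' @param sigma2 partial sill (variance, log scale).
#' @param phi decay parameter, 1/m.
#' @param tau2 nugget variance.
#' @return Covariance matrix of the same dimension as `D`.
#' @export
exponential_covariance <- function(D, sigma2, phi, tau2 = 0) {
  if (inherits(D, "distance_summary")) D <- D$D
  if (!all(is.finite(c(sigma2, phi, tau2)))) stopf("parameters must be finite")
  if (sigma2 < 0 || tau2 < 0 || phi <= 0)
    stopf("need sigma2 >= 0, tau2 >= 0, phi > 0")
  sigma2 * exp(-phi * D) + diag(tau2, nrow(D))
}

#' Effective range of the exponential correlation
#'
#' The lag distance beyond which residual spatial correlation falls to 5%:
#' `xi = -log(0.05) / phi`, so `exp(-phi * xi) = 0.05` exactly.
#'
#' @param phi decay parameter(s), 1/m; must be positive.
#' @return Effective range(s) in metres.
#' @export
effective_range <- function(phi) {
  if (any(!is.finite(phi)) || any(phi <= 0)) stopf("phi must be positive")
  -log(0.05) / phi
}

#' Data-driven prior bounds for the decay parameter
#'
#' Uniform-prior bounds for `phi` built from the observed plot geometry:
#' the lower bound allows at most a correlation of 0.5 at the maximum
#' inter-plot distance (`phi_min = -log(0.5)/d_max`) and the upper bound a
#' correlation of at least 0.01 at the minimum positive distance
#' (`phi_max = -log(0.01)/d_min`).
#'
#' A layout whose positive inter-plot distances are all equal (e.g. two
#' points) is rejected: the bounds would be formally computable but carry
#' no information about decay.
#'
#' @param ds a [pairwise_distances()] summary, or a coordinate matrix.
#' @return Named numeric `c(phi_min, phi_max)` in 1/m.
#' @export
phi_prior_bounds <- function(ds) {
  if (!inherits(ds, "distance_summary")) ds <- pairwise_distances(ds)
  if (ds$d_min >= ds$d_max * (1 - 1e-12))
    stopf(paste("degenerate geometry: all inter-plot distances are equal",
                "(d_min = d_max = %.4g m), so the decay bounds carry no",
                "information - widen the layout or pool more locations"),
          ds$d_max)
  phi_min <- -log(0.5) / ds$d_max
  phi_max <- -log(0.01) / ds$d_min
  c(phi_min = phi_min, phi_max = phi_max)
}

#' Empirical semivariogram
#'
#' Bins pairwise squared (or root-absolute) differences by separation
#' distance. The classical (Matheron) estimator is the mean of half squared
#' differences per bin; the robust Hawkins-Cressie estimator is
#' `[mean |z_i - z_j|^(1/2)]^4 / (2 * (0.457 + 0.494 / N(h)))`, which
#' resists heavy-tailed contamination.
#'
#' @param values numeric vector, one value per location.
#' @param coords matrix/data frame of x/y coordinates (metres).
#' @param n_bins number of equal-width lag bins (default 15).
#' @param max_lag maximum lag considered; default half the maximum
#'   inter-point distance.
#' @param estimator `"robust"` (Hawkins-Cressie, default) or `"classical"`.
#' @return Data frame of class `semivariogram` with columns `lag` (bin
#'   midpoint, m), `gamma` (semivariance; `NA` for empty bins), `npairs`
#'   and `estimator`.
#' @export
empirical_semivariogram <- function(values, coords, n_bins = 15,
                                    max_lag = NULL,
                                    estimator = c("robust", "classical")) {
  estimator <- match.arg(estimator)
  coords <- as.matrix(coords)
  if (length(values) != nrow(coords)) stopf("values and coords lengths differ")
  if (length(values) < 2L) stopf("need at least 2 locations")
  if (n_bins < 1) stopf("n_bins must be positive")
  d <- stats::dist(coords[, 1:2, drop = FALSE])
  dz <- stats::dist(matrix(values, ncol = 1))
  d <- as.vector(d); dz <- as.vector(dz)
  max_lag <- max_lag %||% (max(d) / 2)
  if (max_lag <= 0) stopf("max_lag must be positive")
  keep <- d <= max_lag & d > 0
  brk <- seq(0, max_lag, length.out = n_bins + 1L)
  bin <- cut(d[keep], brk, include.lowest = TRUE, labels = FALSE)
  mid <- (brk[-1] + brk[-length(brk)]) / 2
  gamma <- rep(NA_real_, n_bins)
  npairs <- integer(n_bins)
  for (b in seq_len(n_bins)) {
    j <- which(bin == b)
    npairs[b] <- length(j)
    if (!length(j)) next
    gamma[b] <- if (estimator == "classical") {
      mean(0.5 * dz[keep][j]^2)
    } else {
      mean(sqrt(abs(dz[keep][j])))^4 / (2 * (0.457 + 0.494 / length(j)))
    }
  }
  structure(data.frame(lag = mid, gamma = gamma, npairs = npairs,
                       estimator = estimator),
            class = c("semivariogram", "data.frame"))
}

#' Weighted least-squares fit of an exponential semivariogram model
#'
#' Fits `gamma(h) = tau2 + sigma2 * (1 - exp(-phi * h))` to an empirical
#' semivariogram by minimising the weighted sum of squared deviations.
#' Default weights are Cressie's `N(h) / gamma(h; theta)^2`; `"npairs"`
#' and `"equal"` are also available.
#'
#' @param sv a [empirical_semivariogram()] result (>= 3 nonempty bins).
#' @param weights `"cressie"`, `"npairs"` or `"equal"`.
#' @param init optional `c(tau2, sigma2, phi)` starting values.
#' @return List of class `semivariogram_fit`: `tau2`, `sigma2`, `phi`,
#'   `converged`, `objective`, `note` (e.g. flags an unidentifiable range
#'   when the empirical semivariogram is flat) and the input `sv`.
#' @export
fit_exponential_semivariogram <- function(sv,
                                          weights = c("cressie", "npairs",
                                                      "equal"),
                                          init = NULL) {
  weights <- match.arg(weights)
  ok <- is.finite(sv$gamma) & sv$npairs > 0
  if (sum(ok) < 3L) stopf("need at least 3 nonempty bins")
  h <- sv$lag[ok]; g <- sv$gamma[ok]; n <- sv$npairs[ok]
  model <- function(p) p[1] + p[2] * (1 - exp(-p[3] * h))
  obj <- function(p) {
    m <- model(p)
    w <- switch(weights,
                cressie = n / pmax(m, 1e-12)^2,
                npairs = n,
                equal = rep(1, length(h)))
    sum(w * (g - m)^2)
  }
  gtop <- mean(g[h >= stats::quantile(h, 2 / 3)])
  p0 <- init %||% c(max(min(g), 1e-6), max(gtop - min(g), 1e-6),
                    3 / max(h))
  lo <- c(0, 0, 1e-10)
  hi <- c(Inf, Inf, 1e3 / min(h))
  pen <- function(p) {
    if (any(p < lo) || p[3] > hi[3]) return(1e12)
    obj(p)
  }
  fit <- stats::optim(p0, obj, method = "L-BFGS-B", lower = lo, upper = hi)
  # a second start helps when the first lands on a flat ridge
  fit2 <- stats::optim(c(mean(g) / 2, mean(g) / 2, 10 / max(h)), obj,
                       method = "L-BFGS-B", lower = lo, upper = hi)
  if (fit2$value < fit$value) fit <- fit2
  conv <- fit$convergence == 0
  conv_msg <- fit$message
  # best-effort simplex polish from the box-constrained solution
  fit3 <- stats::optim(fit$par, pen, method = "Nelder-Mead",
                       control = list(maxit = 2000, reltol = 1e-12))
  if (fit3$value <= fit$value) {
    fit <- fit3
    conv <- conv || fit3$convergence == 0
  }
  p <- pmax(fit$par, lo)
  note <- character()
  tot <- p[1] + p[2]
  if (tot > 0 && p[2] < 1e-4 * tot)
    note <- c(note, "flat semivariogram: sill ~ 0, range unidentifiable")
  if (p[3] >= hi[3] * (1 - 1e-6))
    note <- c(note, "decay at upper bound: range unidentifiable")
  if (!conv)
    warning(sprintf("semivariogram WLS did not converge: %s",
                    conv_msg %||% "optimizer reported failure"),
            call. = FALSE)
  structure(list(tau2 = p[1], sigma2 = p[2], phi = p[3],
                 converged = conv,
                 objective = fit$value, weights = weights,
                 note = if (length(note)) paste(note, collapse = "; ") else NA_character_,
                 sv = sv),
            class = "semivariogram_fit")
}

#' @export
print.semivariogram_fit <- function(x, ...) {
  cat(sprintf("Exponential semivariogram fit (%s weights)\n", x$weights))
  cat(sprintf("  nugget tau2   = %.4g\n  partial sill  = %.4g\n  decay phi     = %.4g (1/m)\n",
              x$tau2, x$sigma2, x$phi))
  if (x$phi > 0)
    cat(sprintf("  effective range = %.4g m\n", effective_range(x$phi)))
  if (!is.na(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' Export a semivariogram estimate as CSV
#'
#' Columns `lag,gamma,npairs,estimator`, one row per bin.
#' @param sv a `semivariogram`.
#' @param path file path.
#' @export
write_semivariogram <- function(sv, path) {
  utils::write.csv(sv[, c("lag", "gamma", "npairs", "estimator")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
plot.semivariogram <- function(x, fit = NULL, ...) {
  graphics::plot(x$lag, x$gamma, pch = 19, xlab = "lag (m)",
                 ylab = "semivariance", ...)
  if (!is.null(fit)) {
    hh <- seq(0, max(x$lag), length.out = 200)
    graphics::lines(hh, fit$tau2 + fit$sigma2 * (1 - exp(-fit$phi * hh)))
  }
  invisible(x)
}
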
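#' @export
print.zonetrend <- function(x, ...) {
  cat(sprintf("Hierarchical %strend model (model %d), %d zone(s)\n",
              if (x$model == 4) "spatial " else "", x$model,
              length(x$zones)))
  cat(sprintf("  %d chain(s) x %d retained draws (burn-in %d, thin %d)\n",
              x$chain_config$n_chains, n_retained(x$chain_config, TRUE),
              x$chain_config$burn_in, x$chain_config$thin))
  if (x$prior_only) cat("  prior-only run (likelihood switched off)\n")
  cat("Posterior median trend (per year, log scale):\n")
  tr <- coef(x)["year", , drop = TRUE]
  print(round(tr, 3))
  if (length(x$failed_blocks))
    cat("  WARNING: failed Metropolis blocks:",
        paste(x$failed_blocks, collapse = ", "), "\n")
  invisible(x)
}

#' Posterior-median coefficients
#'
#' @param object a [zonetrend()] fit.
#' @param ... unused.
#' @return Matrix of posterior median coefficients, terms in rows, zones
#'   in columns.
#' @export
coef.zonetrend <- function(object, ...) {
  pooled <- do.call(rbind, object$draws)
  out <- matrix(NA_real_, length(object$terms), length(object$zones),
                dimnames = list(object$terms, object$zones))
  for (z in object$zones)
    out[, z] <- apply(pooled[, sprintf("beta_%s[%s]", object$terms, z),
                             drop = FALSE], 2, stats::median)
  out
}

#' Residuals on the log scale
#'
#' Observed log response minus the posterior-median marginal mean
#' `X beta`.
#' @param object a [zonetrend()] fit.
#' @param ... unused.
#' @return Numeric vector aligned with the rows of the fitted data.
#' @export
residuals.zonetrend <- function(object, ...) {
  fd <- .prep_fit_data(object$data, object$config)
  b <- coef(object)
  r <- numeric(nrow(object$data))
  for (k in seq_along(fd$zones)) {
    z <- fd$zones[k]
    r[fd$idx[[z]]] <- fd$y[[k]] - drop(fd$X[[k]] %*% b[, z])
  }
  r
}

#' Posterior-predictive simulation of counts
#'
#' Draws replicate data sets from the fitted model: for each simulation a
#' retained posterior draw is selected, a log response replicated from its
#' marginal model (multivariate normal per zone for model 4), and counts
#' recovered by inverting the log offset (rounded, floored at zero).
#'
#' @param object a [zonetrend()] fit.
#' @param nsim number of replicate data sets.
#' @param seed integer seed.
#' @param ... unused.
#' @return Data frame with `nsim` columns (`sim_1`, ...), one row per
#'   observation of the fitted data.
#' @export
simulate.zonetrend <- function(object, nsim = 1, seed = 1L, ...) {
  fd <- .prep_fit_data(object$data, object$config)
  cfg <- object$config
  pooled <- do.call(rbind, object$draws)
  with_seed(seed, {
    pick <- sample.int(nrow(pooled), nsim, replace = nsim > nrow(pooled))
    out <- matrix(NA_real_, nrow(object$data), nsim)
    for (s in seq_len(nsim)) {
      th <- pooled[pick[s], ]
      for (k in seq_along(fd$zones)) {
        z <- fd$zones[k]
        b <- th[sprintf("beta_%s[%s]", fd$terms, z)]
        mu <- drop(fd$X[[k]] %*% b)
        n <- length(mu)
        yrep <- if (cfg$model == 4) {
          U <- .zone_chol(fd$D[[k]], th[sprintf("sigma2[%s]", z)],
                          th[sprintf("phi[%s]", z)], th[sprintf("tau2[%s]", z)])
          mu + drop(crossprod(U, stats::rnorm(n)))
        } else {
          mu + stats::rnorm(n, 0, sqrt(th[sprintf("resid_var[%s]", z)]))
        }
        out[fd$idx[[z]], s] <- pmax(round(exp(yrep) - cfg$offset), 0)
      }
    }
    out <- as.data.frame(out)
    names(out) <- paste0("sim_", seq_len(nsim))
    out
  })
}

#' Trace and credible-interval plot for a fitted model
#'
#' @param x a [zonetrend()] fit.
#' @param which `"ci"` (default; posterior medians and 95% intervals for
#'   trend coefficients) or `"trace"` (trace of the trend draws).
#' @param ... passed to the underlying plot call.
#' @export
plot.zonetrend <- function(x, which = c("ci", "trace"), ...) {
  which <- match.arg(which)
  pars <- grep("^beta_year\\[|^mu_year$", x$parameters, value = TRUE)
  if (which == "trace") {
    pooled <- lapply(x$draws, function(m) m[, pars[1]])
    graphics::plot(pooled[[1]], type = "l",
                   ylim = range(unlist(pooled)),
                   xlab = "retained draw", ylab = pars[1], ...)
    if (length(pooled) > 1)
      for (i in 2:length(pooled)) graphics::lines(pooled[[i]], col = i)
    return(invisible(x))
  }
  s <- summary(x)$table
  s <- s[s$parameter %in% pars, ]
  yy <- seq_len(nrow(s))
  graphics::plot(s$median, yy, xlim = range(s$lower, s$upper, 0),
                 yaxt = "n", pch = 19, xlab = "trend (log scale, per year)",
                 ylab = "", ...)
  graphics::segments(s$lower, yy, s$upper, yy)
  graphics::abline(v = 0, lty = 3)
  graphics::axis(2, at = yy,
                 labels = sub("^beta_year\\[(.*)\\]$", "\\1",
                              sub("^mu_year$", "site", s$parameter)),
                 las = 1)
  invisible(x)
}
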
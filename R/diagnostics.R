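#' Gelman-Rubin potential scale reduction factor
#'
#' Split-chain R-hat: each chain is halved, and the between/within variance
#' ratio `sqrt(((n-1)/n * W + B/n) / W)` computed over the resulting
#' half-chains. Values near 1 indicate convergence; the split version also
#' detects trends within chains. Invariant to affine reparameterization.
#'
#' @param x a [zonetrend()] fit or a list of per-chain draw matrices.
#' @param parameter parameter name(s); default all.
#' @return Named numeric vector of R-hat values.
#' @export
gelman_rubin <- function(x, parameter = NULL) {
  ch <- if (inherits(x, "zonetrend")) x$draws else x
  if (length(ch) < 2L) stopf("R-hat needs at least 2 chains")
  if (nrow(ch[[1]]) < 10L) stopf("R-hat needs at least 10 draws per chain")
  parameter <- parameter %||% colnames(ch[[1]])
  vapply(parameter, function(pp) {
    halves <- unlist(lapply(ch, function(m) {
      v <- m[, pp]
      n2 <- floor(length(v) / 2)
      list(v[seq_len(n2)], v[seq_len(n2) + n2])
    }), recursive = FALSE)
    n <- length(halves[[1]]); m <- length(halves)
    means <- vapply(halves, mean, 0)
    vars <- vapply(halves, stats::var, 0)
    W <- mean(vars)
    B <- n * stats::var(means)
    if (W == 0) return(if (B == 0) 1 else Inf)
    sqrt(((n - 1) / n * W + B / n) / W)
  }, 0)
}

# effective sample size via Geyer's initial positive sequence (per chain,
# pooled): ESS = m*n / (1 + 2 sum rho_t)
.ess_one <- function(ch, pp) {
  m <- length(ch); n <- nrow(ch[[1]])
  # pooled autocorrelation estimate using within-chain acf
  rho <- rowMeans(vapply(ch, function(mm) {
    v <- mm[, pp]
    if (stats::var(v) == 0) return(rep(0, min(n - 1, 100)))
    a <- stats::acf(v, lag.max = min(n - 1, 100), plot = FALSE)$acf[-1]
    as.vector(a)
  }, numeric(min(n - 1, 100))))
  # sum consecutive pairs until a pair sum goes negative
  s <- 0
  t <- 1
  while (t + 1 <= length(rho)) {
    pair <- rho[t] + rho[t + 1]
    if (pair < 0) break
    s <- s + pair
    t <- t + 2
  }
  max(m * n / (1 + 2 * s), 1)
}

#' Convergence report for a fitted model
#'
#' Per-parameter split-chain R-hat and effective sample size, with a
#' pass/fail flag against `threshold` (default 1.1).
#'
#' @param fit a [zonetrend()] fit with >= 2 chains.
#' @param threshold R-hat pass threshold.
#' @return Data frame of class `convergence_report` with columns
#'   `parameter`, `rhat`, `ess`, `pass`.
#' @export
convergence_report <- function(fit, threshold = 1.1) {
  rh <- gelman_rubin(fit)
  ess <- vapply(names(rh), function(pp) .ess_one(fit$draws, pp), 0)
  out <- data.frame(parameter = names(rh), rhat = unname(rh),
                    ess = unname(ess), pass = unname(rh) < threshold,
                    stringsAsFactors = FALSE)
  structure(out, class = c("convergence_report", "data.frame"),
            threshold = threshold)
}

#' Export a convergence report as CSV
#' @param x a [convergence_report()].
#' @param path file path.
#' @export
write_convergence <- function(x, path) {
  utils::write.csv(x[, c("parameter", "rhat", "ess", "pass")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Posterior-predictive Bayesian P-value
#'
#' Model-fit check from the discrepancy in the sum of squared residuals
#' between observed and replicated data: for each sampled parameter set,
#' replicate log responses are simulated from the fitted model, and
#' `D(y) = sum((y - X beta)^2)` is compared with the same discrepancy on
#' the replicate. The P-value is the fraction of replicates whose
#' discrepancy is at least the observed one; values near 0.5 indicate an
#' adequate model, values near 0 or 1 systematic misfit. The discrepancy
#' uses the marginal mean `X beta` on the log scale (tagged
#' `"ss_residual_marginal"`), matching the marginalized model
#' representation.
#'
#' @param fit a [zonetrend()] fit.
#' @param n_replicates posterior draws used (default 500; < 50 warns).
#' @param seed integer seed (replicate draws are deterministic given it).
#' @param data optional plot table to evaluate instead of the training
#'   data (same layout).
#' @return List of class `ppc_report`: `p_value`, `n_replicates`,
#'   `discrepancy`.
#' @export
bayesian_p_value <- function(fit, n_replicates = 500, seed = 1L,
                             data = NULL) {
  stopifnot(inherits(fit, "zonetrend"))
  if (n_replicates < 50)
    warning("fewer than 50 replicates: P-value estimate is unstable",
            call. = FALSE)
  data <- data %||% fit$data
  cfg <- fit$config
  fd <- .prep_fit_data(data, cfg)
  all_draws <- do.call(rbind, fit$draws)
  idx <- if (n_replicates >= nrow(all_draws)) seq_len(nrow(all_draws))
         else round(seq(1, nrow(all_draws), length.out = n_replicates))
  with_seed(seed, {
    exceed <- 0L
    for (dd in idx) {
      th <- all_draws[dd, ]
      d_obs <- 0; d_rep <- 0
      for (k in seq_along(fd$zones)) {
        z <- fd$zones[k]
        b <- th[sprintf("beta_%s[%s]", fd$terms, z)]
        mu <- drop(fd$X[[k]] %*% b)
        r <- fd$y[[k]] - mu
        d_obs <- d_obs + sum(r^2)
        n <- length(mu)
        if (cfg$model == 4) {
          U <- .zone_chol(fd$D[[k]], th[sprintf("sigma2[%s]", z)],
                          th[sprintf("phi[%s]", z)],
                          th[sprintf("tau2[%s]", z)])
          yrep <- mu + drop(crossprod(U, stats::rnorm(n)))
        } else {
          yrep <- mu + stats::rnorm(n, 0, sqrt(th[sprintf("resid_var[%s]", z)]))
        }
        d_rep <- d_rep + sum((yrep - mu)^2)
      }
      if (d_rep >= d_obs) exceed <- exceed + 1L
    }
    structure(list(p_value = exceed / length(idx),
                   n_replicates = length(idx),
                   discrepancy = "ss_residual_marginal"),
              class = "ppc_report")
  })
}

#' @export
print.ppc_report <- function(x, ...) {
  cat(sprintf("Posterior-predictive check (%s, %d replicates): P = %.3f\n",
              x$discrepancy, x$n_replicates, x$p_value))
  invisible(x)
}

#' Export a posterior-predictive report as a single-line CSV record
#' @param x a `ppc_report`.
#' @param path file path.
#' @export
write_ppc <- function(x, path) {
  utils::write.csv(data.frame(p_value = x$p_value,
                              n_replicates = x$n_replicates,
                              discrepancy = x$discrepancy),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
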
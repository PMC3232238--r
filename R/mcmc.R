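#' MCMC chain configuration
#'
#' Defaults follow the conventional long-run scheme for spatial
#' hierarchical fits: 3 chains, 1000 burn-in iterations, 40,000 post
#' burn-in iterations thinned by 10, retaining 4000 draws per chain
#' (12,000 in total). Desk-scale fits should shrink `n_iter`.
#'
#' @param n_chains number of chains (default 3).
#' @param burn_in burn-in iterations discarded per chain (default 1000).
#' @param n_iter post-burn-in iterations per chain (default 40000); must be
#'   divisible by `thin`.
#' @param thin thinning factor (default 10).
#' @param seeds optional integer vector of per-chain seeds; derived from
#'   the fit's master seed when `NULL`.
#' @return An object of class `chain_config`.
#' @export
chain_config <- function(n_chains = 3, burn_in = 1000, n_iter = 40000,
                         thin = 10, seeds = NULL) {
  if (n_chains < 1 || burn_in < 0 || n_iter < 1 || thin < 1)
    stopf("invalid chain configuration")
  if (n_iter %% thin != 0) stopf("n_iter must be divisible by thin")
  if (!is.null(seeds) && length(seeds) != n_chains)
    stopf("need one seed per chain")
  structure(list(n_chains = as.integer(n_chains),
                 burn_in = as.integer(burn_in),
                 n_iter = as.integer(n_iter), thin = as.integer(thin),
                 seeds = seeds),
            class = "chain_config")
}

#' Retained draws implied by a chain configuration
#'
#' `n_chains * n_iter / thin` in total; the per-chain count is
#' `n_iter / thin` exactly.
#' @param chains a [chain_config()].
#' @param per_chain return the per-chain count instead of the total.
#' @return Integer number of retained posterior draws.
#' @export
n_retained <- function(chains, per_chain = FALSE) {
  per <- chains$n_iter %/% chains$thin
  if (per_chain) per else chains$n_chains * per
}

# ---- internal sampler machinery ----

# per-zone sufficient pieces shared by all updates
.prep_fit_data <- function(data, cfg) {
  des <- build_design(data, cfg)
  y <- log_response(data$count, cfg)
  K <- length(des$zones)
  fd <- list(zones = des$zones, centering = des$centering, cfg = cfg,
             p = ncol(des$X[[1]]), terms = colnames(des$X[[1]]),
             y = lapply(des$idx, function(i) y[i]), X = des$X,
             idx = des$idx)
  if (cfg$model == 4) {
    fd$D <- lapply(des$coords, function(cc) {
      D <- as.matrix(stats::dist(cc)); dimnames(D) <- NULL; D
    })
    fd$phi_bounds <- lapply(des$zones, function(z) {
      ds <- pairwise_distances(des$coords[[z]])
      phi_prior_bounds(ds)
    })
    names(fd$phi_bounds) <- des$zones
  }
  fd
}

#' Overdispersed per-chain starting states
#'
#' Coefficients start at per-zone least squares plus a random jitter scaled
#' by the coefficient standard errors (so noise-free data start at the
#' exact solution); variances start from residual moments; the decay
#' parameter starts uniform within its prior bounds. Rank-deficient
#' designs fall back to draws from a unit normal. States are distinct
#' across chains.
#'
#' @param data plot table.
#' @param cfg a [model_config()].
#' @param n_chains number of states to produce.
#' @param seed integer seed.
#' @return List of starting states (one per chain).
#' @export
initialize_chains <- function(data, cfg = model_config(), n_chains = 3,
                              seed = 1L) {
  fd <- .prep_fit_data(data, cfg)
  with_seed(seed, lapply(seq_len(n_chains), function(ch) .init_state(fd)))
}

.init_state <- function(fd) {
  cfg <- fd$cfg
  K <- length(fd$zones); p <- fd$p
  beta <- matrix(0, p, K, dimnames = list(fd$terms, fd$zones))
  rv <- numeric(K); names(rv) <- fd$zones
  for (k in seq_len(K)) {
    X <- fd$X[[k]]; y <- fd$y[[k]]
    ft <- stats::lm.fit(X, y)
    if (any(is.na(ft$coefficients)) || ft$rank < p) {
      beta[, k] <- stats::rnorm(p)
      rv[k] <- max(stats::var(y), 0.1)
    } else {
      dfree <- max(length(y) - p, 1)
      v <- sum(ft$residuals^2) / dfree
      se <- sqrt(pmax(diag(chol2inv(qr.R(ft$qr))) * v, 0))
      beta[, k] <- ft$coefficients + stats::rnorm(p) * 2 * se
      rv[k] <- max(v, 1e-8)
    }
  }
  st <- list(beta = beta)
  if (cfg$model == 4) {
    st$sigma2 <- rv * stats::runif(K, 0.3, 0.7)
    st$tau2 <- rv - st$sigma2
    st$phi <- vapply(fd$zones, function(z)
      stats::runif(1, fd$phi_bounds[[z]][1], fd$phi_bounds[[z]][2]), 0)
    names(st$sigma2) <- names(st$tau2) <- names(st$phi) <- fd$zones
  } else {
    st$resid_var <- rv
  }
  if (cfg$model >= 2) {
    st$mu <- rowMeans(beta) + stats::rnorm(p, 0, 0.1)
    sdb <- apply(beta, 1, stats::sd)
    sdb[!is.finite(sdb)] <- 1  # single-zone fits: no spread to estimate
    st$sd_beta <- pmin(pmax(sdb * stats::runif(p, 0.5, 2), 0.05),
                       cfg$sd_beta_max * 0.9)
    names(st$mu) <- names(st$sd_beta) <- fd$terms
  }
  st
}

# adaptive scalar random-walk Metropolis bookkeeping
.mh_new <- function(names) {
  list(logstep = stats::setNames(rep(log(0.5), length(names)), names),
       batch_acc = stats::setNames(integer(length(names)), names),
       batch_n = stats::setNames(integer(length(names)), names),
       batch_i = stats::setNames(integer(length(names)), names),
       burn_acc = stats::setNames(integer(length(names)), names),
       burn_n = stats::setNames(integer(length(names)), names),
       post_acc = stats::setNames(integer(length(names)), names),
       post_n = stats::setNames(integer(length(names)), names))
}

.mh_record <- function(mh, nm, accepted, adapting) {
  if (adapting) {
    mh$burn_n[nm] <- mh$burn_n[nm] + 1L
    mh$burn_acc[nm] <- mh$burn_acc[nm] + accepted
    mh$batch_n[nm] <- mh$batch_n[nm] + 1L
    mh$batch_acc[nm] <- mh$batch_acc[nm] + accepted
    if (mh$batch_n[nm] >= 50L) {
      mh$batch_i[nm] <- mh$batch_i[nm] + 1L
      delta <- min(0.05, 1 / sqrt(mh$batch_i[nm]))
      rate <- mh$batch_acc[nm] / mh$batch_n[nm]
      mh$logstep[nm] <- mh$logstep[nm] + if (rate > 0.44) delta else -delta
      mh$batch_n[nm] <- 0L; mh$batch_acc[nm] <- 0L
    }
  } else {
    mh$post_n[nm] <- mh$post_n[nm] + 1L
    mh$post_acc[nm] <- mh$post_acc[nm] + accepted
  }
  mh
}

#' Fit a hierarchical spatial trend model by MCMC
#'
#' The fitting function of the package: draws posterior samples for any
#' rung of the four-model ladder with a bespoke Gibbs-within-Metropolis
#' sampler on the marginalized model. Coefficients, hyper-means and
#' (models 1-3) residual variances have conjugate conditional draws;
#' hyper-SDs, partial sills, nuggets and decay parameters use adaptive
#' scalar random-walk Metropolis (log scale for variances, logit scale
#' within the prior bounds for the decay), with adaptation targeting 44%
#' acceptance and frozen after burn-in. The covariance Cholesky factor per
#' zone is cached and only recomputed when a covariance parameter proposal
#' is evaluated or accepted. Runs are deterministic given `seed`.
#'
#' @param data plot table (`zone, x, y, elevation, year, count`), e.g. from
#'   [sim_camas()] or [read_plot_table()].
#' @param model ladder rung 1-4 (see [model_config()]).
#' @param config optional [model_config()]; overrides `model`.
#' @param chains a [chain_config()]. The default is the full long-run
#'   scheme; pass something smaller for desk-scale work.
#' @param seed master integer seed; per-chain seeds are derived from it
#'   unless `chains$seeds` is set.
#' @param prior_only logical; if `TRUE` the likelihood is switched off and
#'   the sampler targets the joint prior (for prior-recovery checks).
#' @param fixed named list fixing parameters at given values and skipping
#'   their updates: any of `sigma2`, `tau2`, `phi`, `resid_var` (scalar or
#'   per-zone vector), `mu`, `sd_beta`.
#' @param init optional list of per-chain starting states (as from
#'   [initialize_chains()]).
#' @param verbose print per-chain progress.
#' @return An object of class `zonetrend`: retained draws per chain,
#'   resolved configuration (prior bounds, centering rules), acceptance
#'   rates, and the data. Methods: `print`, `summary`, `coef`, `plot`,
#'   `simulate`, `residuals`.
#' @export
zonetrend <- function(data, model = 4, config = NULL,
                      chains = chain_config(), seed = 1L,
                      prior_only = FALSE, fixed = list(), init = NULL,
                      verbose = FALSE) {
  cl <- match.call()
  cfg <- config %||% model_config(model)
  stopifnot(inherits(chains, "chain_config"))
  fd <- .prep_fit_data(data, cfg)
  chain_seeds <- chains$seeds %||% (as.integer(seed) + 7919L * seq_len(chains$n_chains))
  out <- with_seed(seed, {
    states <- init %||% initialize_chains(data, cfg, chains$n_chains,
                                          seed = as.integer(seed) + 104729L)
    lapply(seq_len(chains$n_chains), function(ch) {
      if (verbose) message(sprintf("chain %d/%d", ch, chains$n_chains))
      set.seed(chain_seeds[ch])
      .run_chain(fd, states[[ch]], chains, prior_only, fixed)
    })
  })
  draws <- lapply(out, `[[`, "draws")
  mh <- lapply(out, `[[`, "mh")
  failed <- unique(unlist(lapply(mh, function(m) {
    names(m$burn_n)[m$burn_n > 0 & m$burn_acc == 0]
  })))
  if (length(failed))
    warning(sprintf("Metropolis block(s) %s accepted nothing during burn-in; run flagged as failed",
                    paste(failed, collapse = ", ")), call. = FALSE)
  acc <- NULL
  if (length(mh[[1]]$post_n) && any(mh[[1]]$post_n > 0)) {
    acc <- Reduce(`+`, lapply(mh, `[[`, "post_acc")) /
      pmax(Reduce(`+`, lapply(mh, `[[`, "post_n")), 1)
  }
  structure(list(call = cl, model = cfg$model, config = cfg,
                 chain_config = chains, seed = seed,
                 chain_seeds = chain_seeds,
                 draws = draws, parameters = colnames(draws[[1]]),
                 acceptance = acc, failed_blocks = failed,
                 phi_bounds = fd$phi_bounds,
                 centering = fd$centering, terms = fd$terms,
                 zones = fd$zones, prior_only = prior_only,
                 data = data),
            class = "zonetrend")
}

# parameter vector layout for recording
.param_names <- function(fd) {
  cfg <- fd$cfg
  nm <- c(outer(paste0("beta_", fd$terms), fd$zones,
                function(a, z) sprintf("%s[%s]", a, z)))
  if (cfg$model == 4) {
    for (w in c("sigma2", "tau2", "phi"))
      nm <- c(nm, sprintf("%s[%s]", w, fd$zones))
  } else {
    nm <- c(nm, sprintf("resid_var[%s]", fd$zones))
  }
  if (cfg$model >= 2)
    nm <- c(nm, paste0("mu_", fd$terms), paste0("sigma_beta_", fd$terms))
  nm
}

.flatten_state <- function(st, fd) {
  v <- c(st$beta)
  if (fd$cfg$model == 4) v <- c(v, st$sigma2, st$tau2, st$phi)
  else v <- c(v, st$resid_var)
  if (fd$cfg$model >= 2) v <- c(v, st$mu, st$sd_beta)
  v
}

.run_chain <- function(fd, st, chains, prior_only, fixed) {
  cfg <- fd$cfg
  K <- length(fd$zones); p <- fd$p
  zones <- fd$zones
  spatial <- cfg$model == 4 && !prior_only

  # apply fixed values
  for (nm in c("sigma2", "tau2", "phi", "resid_var")) {
    if (!is.null(fixed[[nm]]))
      st[[nm]] <- stats::setNames(rep_len(fixed[[nm]], K), zones)
  }
  for (nm in c("mu", "sd_beta")) {
    if (!is.null(fixed[[nm]]))
      st[[nm]] <- stats::setNames(rep_len(fixed[[nm]], p), fd$terms)
  }

  mh_names <- character()
  if (cfg$model == 4 && !prior_only) {
    if (is.null(fixed$phi)) mh_names <- c(mh_names, sprintf("phi[%s]", zones))
    if (is.null(fixed$sigma2)) mh_names <- c(mh_names, sprintf("sigma2[%s]", zones))
    if (is.null(fixed$tau2)) mh_names <- c(mh_names, sprintf("tau2[%s]", zones))
  }
  if (cfg$model >= 2 && is.null(fixed$sd_beta))
    mh_names <- c(mh_names, paste0("sigma_beta_", fd$terms))
  mh <- .mh_new(mh_names)

  # cached per-zone Cholesky and log-likelihood (spatial model only)
  U <- vector("list", K); ll <- numeric(K)
  if (spatial) {
    for (k in seq_len(K)) {
      U[[k]] <- .zone_chol(fd$D[[k]], st$sigma2[k], st$phi[k], st$tau2[k])
      r <- fd$y[[k]] - drop(fd$X[[k]] %*% st$beta[, k])
      ll[k] <- .ll_mvn_chol(r, U[[k]])
    }
  }

  n_keep <- chains$n_iter %/% chains$thin
  pn <- .param_names(fd)
  draws <- matrix(NA_real_, n_keep, length(pn), dimnames = list(NULL, pn))
  total <- chains$burn_in + chains$n_iter
  keep_i <- 0L

  for (it in seq_len(total)) {
    adapting <- it <= chains$burn_in

    if (cfg$model == 4) {
      for (k in seq_len(K)) {
        z <- zones[k]
        if (prior_only) {
          if (is.null(fixed$sigma2))
            st$sigma2[k] <- rinvgamma(1, cfg$ig_shape, cfg$ig_rate)
          if (is.null(fixed$tau2))
            st$tau2[k] <- rinvgamma(1, cfg$ig_shape, cfg$ig_rate)
          if (is.null(fixed$phi))
            st$phi[k] <- stats::runif(1, fd$phi_bounds[[z]][1],
                                      fd$phi_bounds[[z]][2])
        } else {
          # decay: random walk on the logit of the rescaled phi
          if (is.null(fixed$phi)) {
            nm <- sprintf("phi[%s]", z)
            b <- fd$phi_bounds[[z]]
            u <- (st$phi[k] - b[1]) / (b[2] - b[1])
            eta <- stats::qlogis(u) + stats::rnorm(1, 0, exp(mh$logstep[nm]))
            u2 <- stats::plogis(eta)
            phi2 <- b[1] + (b[2] - b[1]) * u2
            U2 <- .zone_chol(fd$D[[k]], st$sigma2[k], phi2, st$tau2[k])
            r <- fd$y[[k]] - drop(fd$X[[k]] %*% st$beta[, k])
            ll2 <- .ll_mvn_chol(r, U2)
            lr <- ll2 - ll[k] + log(u2 * (1 - u2)) - log(u * (1 - u))
            ok <- is.finite(lr) && log(stats::runif(1)) < lr
            if (ok) { st$phi[k] <- phi2; U[[k]] <- U2; ll[k] <- ll2 }
            mh <- .mh_record(mh, nm, ok, adapting)
          }
          # partial sill and nugget: random walk on the log scale
          for (w in c("sigma2", "tau2")) {
            if (!is.null(fixed[[w]])) next
            nm <- sprintf("%s[%s]", w, z)
            cur <- st[[w]][k]
            prop <- cur * exp(stats::rnorm(1, 0, exp(mh$logstep[nm])))
            s2 <- if (w == "sigma2") prop else st$sigma2[k]
            t2 <- if (w == "tau2") prop else st$tau2[k]
            U2 <- tryCatch(.zone_chol(fd$D[[k]], s2, st$phi[k], t2),
                           error = function(e) NULL)
            if (!is.null(U2)) {
              r <- fd$y[[k]] - drop(fd$X[[k]] %*% st$beta[, k])
              ll2 <- .ll_mvn_chol(r, U2)
              lr <- ll2 - ll[k] +
                dinvgamma_log(prop, cfg$ig_shape, cfg$ig_rate) -
                dinvgamma_log(cur, cfg$ig_shape, cfg$ig_rate) +
                log(prop) - log(cur)
              ok <- is.finite(lr) && log(stats::runif(1)) < lr
            } else ok <- FALSE
            if (ok) { st[[w]][k] <- prop; U[[k]] <- U2; ll[k] <- ll2 }
            mh <- .mh_record(mh, nm, ok, adapting)
          }
        }
      }
    } else if (!prior_only) {
      # conjugate inverse-gamma draw for per-zone residual variance
      if (is.null(fixed$resid_var)) for (k in seq_len(K)) {
        r <- fd$y[[k]] - drop(fd$X[[k]] %*% st$beta[, k])
        st$resid_var[k] <- rinvgamma(1, cfg$ig_shape + length(r) / 2,
                                     cfg$ig_rate + sum(r^2) / 2)
      }
    } else if (is.null(fixed$resid_var) && cfg$model < 4) {
      st$resid_var[] <- rinvgamma(K, cfg$ig_shape, cfg$ig_rate)
    }

    # coefficients: conjugate normal conditional per zone
    pr_mu <- if (cfg$model >= 2) st$mu else rep(0, p)
    pr_sd <- if (cfg$model >= 2) st$sd_beta else rep(cfg$mu_prior_sd, p)
    for (k in seq_len(K)) {
      if (prior_only) {
        st$beta[, k] <- stats::rnorm(p, pr_mu, pr_sd)
        next
      }
      X <- fd$X[[k]]; y <- fd$y[[k]]
      if (spatial) {
        W <- backsolve(U[[k]], X, transpose = TRUE)
        v <- backsolve(U[[k]], y, transpose = TRUE)
        XtSiX <- crossprod(W); XtSiy <- crossprod(W, v)
      } else {
        XtSiX <- crossprod(X) / st$resid_var[k]
        XtSiy <- crossprod(X, y) / st$resid_var[k]
      }
      P <- XtSiX + diag(1 / pr_sd^2, p)
      Up <- chol(P)
      m <- backsolve(Up, backsolve(Up, XtSiy + pr_mu / pr_sd^2,
                                   transpose = TRUE))
      st$beta[, k] <- drop(m) + drop(backsolve(Up, stats::rnorm(p)))
      if (spatial) {
        r <- y - drop(X %*% st$beta[, k])
        ll[k] <- .ll_mvn_chol(r, U[[k]])
      }
    }

    if (cfg$model >= 2) {
      # hyper-means: conjugate normal conditional
      if (is.null(fixed$mu)) {
        prec <- K / st$sd_beta^2 + 1 / cfg$mu_prior_sd^2
        mm <- (rowSums(st$beta) / st$sd_beta^2) / prec
        st$mu <- stats::rnorm(p, mm, sqrt(1 / prec))
        names(st$mu) <- fd$terms
      }
      # hyper-SDs: random walk on the log scale, uniform(0, max) prior
      if (is.null(fixed$sd_beta)) for (j in seq_len(p)) {
        nm <- paste0("sigma_beta_", fd$terms[j])
        cur <- st$sd_beta[j]
        prop <- cur * exp(stats::rnorm(1, 0, exp(mh$logstep[nm])))
        if (prop < cfg$sd_beta_max) {
          dev <- st$beta[j, ] - st$mu[j]
          lr <- sum(stats::dnorm(dev, 0, prop, log = TRUE)) -
            sum(stats::dnorm(dev, 0, cur, log = TRUE)) +
            log(prop) - log(cur)
          ok <- is.finite(lr) && log(stats::runif(1)) < lr
        } else ok <- FALSE
        if (ok) st$sd_beta[j] <- prop
        mh <- .mh_record(mh, nm, ok, adapting)
      }
    }

    if (!adapting) {
      j <- it - chains$burn_in
      if (j %% chains$thin == 0L) {
        keep_i <- keep_i + 1L
        draws[keep_i, ] <- .flatten_state(st, fd)
      }
    }
  }
  list(draws = draws, mh = mh)
}
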
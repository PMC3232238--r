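test_that("design matrices apply the centering rules and return them for inversion", {
  dat <- sim_camas(small_design(years = 2005:2010), seed = 1)
  des <- build_design(dat, model_config(4))
  # 6 years 2005-2010: centered values symmetric about 0 with mean exactly 0
  yc <- unlist(lapply(des$X, function(x) x[, "year"]))
  expect_equal(mean(yc), 0, tolerance = 1e-12)
  expect_setequal(round(sort(unique(yc)), 6), c(-2.5, -1.5, -0.5, 0.5, 1.5, 2.5))
  # an observation at mid-study year has centered year 0
  expect_equal(des$centering$year_center, 2007.5)
  # a plot at mean elevation standardizes to 0
  ec <- unlist(lapply(des$X, function(x) x[, "elevation"]))
  expect_equal(mean(ec), 0, tolerance = 1e-12)
  expect_equal(sd(ec), 1, tolerance = 1e-12)

  flat <- dat
  flat$elevation <- 900
  expect_error(build_design(flat, model_config(4)), "zero variance")
})

test_that("the log response handles zeros, closed forms and inversion", {
  expect_equal(log_response(0, 1), 0)
  expect_equal(log_response(exp(1) - 1, 1), 1)
  set.seed(4)
  counts <- rpois(50, 5)
  expect_equal(exp(log_response(counts, 1)) - 1, counts, tolerance = 1e-12)
  expect_error(log_response(c(3, -1), 1), "non-negative")
})

test_that("the spatial log likelihood matches a hand-coded dense MVN density", {
  des <- study_design(zones = c("A", "B"), plots_per_zone_per_year = 3,
                      years = 2005,
                      zone_extents = list(A = c(0, 50, 0, 50),
                                          B = c(60, 110, 0, 50)))
  dat <- sim_camas(des, seed = 21)
  cfg <- model_config(4)
  params <- list(beta = matrix(c(1, 0.1, -0.5, 0.8, 0.05, -0.3), 3, 2,
                               dimnames = list(c("intercept", "year",
                                                 "elevation"), c("A", "B"))),
                 sigma2 = c(A = 0.9, B = 1.2), phi = c(A = 0.04, B = 0.08),
                 tau2 = c(A = 0.3, B = 0.2))
  ll <- log_likelihood(dat, params, cfg)

  # oracle: explicit inverse and determinant, including the documented jitter
  d2 <- build_design(dat, cfg)
  y <- log_response(dat$count, 1)
  oracle <- 0
  for (z in c("A", "B")) {
    i <- d2$idx[[z]]
    r <- y[i] - drop(d2$X[[z]] %*% params$beta[, z])
    D <- matrix(0, 3, 3)
    for (a in 1:3) for (b in 1:3)
      D[a, b] <- sqrt(sum((d2$coords[[z]][a, ] - d2$coords[[z]][b, ])^2))
    S <- params$sigma2[z] * exp(-params$phi[z] * D) +
      diag(params$tau2[z] + 1e-8 * (params$sigma2[z] + params$tau2[z]), 3)
    oracle <- oracle - 0.5 * (3 * log(2 * pi) + log(det(S)) +
                                drop(t(r) %*% solve(S) %*% r))
  }
  expect_equal(ll, oracle, tolerance = 1e-10)
})

test_that("the ladder nests: model 4 at zero sill collapses to model 3", {
  dat <- sim_camas(small_design(), seed = 22)
  beta <- matrix(c(1, 0.1, -0.5), 3, 3,
                 dimnames = list(c("intercept", "year", "elevation"),
                                 c("A", "B", "C")))
  tau2 <- c(A = 0.4, B = 0.6, C = 0.5)
  ll4 <- log_likelihood(dat, list(beta = beta,
                                  sigma2 = c(A = 0, B = 0, C = 0),
                                  phi = c(A = 1, B = 1, C = 1),
                                  tau2 = tau2),
                        model_config(4))
  ll3 <- log_likelihood(dat, list(beta = beta, resid_var = tau2),
                        model_config(3))
  expect_equal(ll4, ll3, tolerance = 1e-5)
})

test_that("the likelihood is additive over independent zone blocks", {
  # identical year multisets per zone keep the centering constants equal
  # between pooled and per-zone builds (no elevation covariate)
  des <- study_design(zones = c("A", "B"), plots_per_zone_per_year = 4,
                      years = 2005:2006,
                      zone_extents = list(A = c(0, 100, 0, 100),
                                          B = c(150, 250, 0, 100)))
  dat <- sim_camas(des, seed = 30)
  cfg <- model_config(4, include_elevation = FALSE)
  params <- list(beta = matrix(c(1, 0.1, 0.7, 0.2), 2, 2,
                               dimnames = list(c("intercept", "year"),
                                               c("A", "B"))),
                 sigma2 = c(A = 1, B = 0.5), phi = c(A = 0.05, B = 0.02),
                 tau2 = c(A = 0.2, B = 0.4))
  whole <- log_likelihood(dat, params, cfg)
  parts <- vapply(c("A", "B"), function(z) {
    sub <- dat[dat$zone == z, ]
    pz <- list(beta = params$beta[, z, drop = FALSE],
               sigma2 = params$sigma2[z], phi = params$phi[z],
               tau2 = params$tau2[z])
    log_likelihood(sub, pz, cfg)
  }, 0)
  expect_equal(whole, sum(parts), tolerance = 1e-10)
})

test_that("priors return -Inf outside support and match density formulas", {
  cfg <- model_config(4)
  beta <- matrix(c(1, 0.1, -0.5), 3, 1,
                 dimnames = list(c("intercept", "year", "elevation"), "A"))
  params <- list(beta = beta, sigma2 = c(A = 1), phi = c(A = 0.05),
                 tau2 = c(A = 0.3))
  bounds <- c(0.01, 0.1)
  hyper_ok <- list(mu = c(0, 0, 0), sd_beta = c(1, 1, 1))
  lp <- log_prior(params, hyper_ok, cfg, phi_bounds = bounds)
  expect_true(is.finite(lp))

  # hyper-SD outside uniform(0,100)
  expect_identical(log_prior(params, list(mu = c(0, 0, 0),
                                          sd_beta = c(1, 150, 1)),
                             cfg, bounds), -Inf)
  # decay below its lower bound
  p2 <- params; p2$phi <- c(A = 0.001)
  expect_identical(log_prior(p2, hyper_ok, cfg, bounds), -Inf)

  # inverse-gamma term vs an independent density implementation
  ig_oracle <- function(x, a, b) dgamma(1 / x, shape = a, rate = b) / x^2
  for (v in c(0.05, 0.3, 1, 4, 20)) {
    pv <- params; pv$sigma2 <- c(A = v)
    diff_pkg <- log_prior(pv, hyper_ok, cfg, bounds) -
      log_prior(params, hyper_ok, cfg, bounds)
    diff_ora <- log(ig_oracle(v, 0.1, 0.1)) - log(ig_oracle(1, 0.1, 0.1))
    expect_equal(diff_pkg, diff_ora, tolerance = 1e-10)
  }
})

test_that("the log posterior is the sum of its parts and peaks at noise-free truth", {
  dat <- sim_camas(small_design(), seed = 23)
  cfg <- model_config(4)
  beta <- matrix(rep(c(1.5, 0.1, -0.6), 3), 3, 3,
                 dimnames = list(c("intercept", "year", "elevation"),
                                 c("A", "B", "C")))
  params <- list(beta = beta, sigma2 = c(A = 1, B = 1, C = 1),
                 phi = c(A = 0.05, B = 0.05, C = 0.05),
                 tau2 = c(A = 0.3, B = 0.3, C = 0.3))
  hyper <- list(mu = c(1.5, 0.1, -0.6), sd_beta = c(1, 0.2, 0.2))
  bounds <- c(0.001, 1)
  expect_equal(log_posterior(dat, params, hyper, cfg, bounds),
               log_prior(params, hyper, cfg, bounds) +
                 log_likelihood(dat, params, cfg))

  # noise-free data: perturbing beta away from truth never helps
  tb <- matrix(rep(c(2, 0.1, -0.3), 3), 3, 3,
               dimnames = list(c("intercept", "year", "elevation"),
                               c("A", "B", "C")))
  nf <- noise_free_data(tb)
  cfg1 <- model_config(1, include_elevation = TRUE)
  at_truth <- log_posterior(nf, list(beta = tb,
                                     resid_var = c(A = 0.01, B = 0.01,
                                                   C = 0.01)),
                            cfg = cfg1)
  set.seed(6)
  for (rep in 1:5) {
    pb <- tb + matrix(rnorm(9, 0, 0.1), 3, 3)
    off <- log_posterior(nf, list(beta = pb,
                                  resid_var = c(A = 0.01, B = 0.01,
                                                C = 0.01)),
                         cfg = cfg1)
    expect_lte(off, at_truth)
  }
})

test_that("the no-pooling posterior factorizes over zones", {
  des <- study_design(zones = c("A", "B"), plots_per_zone_per_year = 4,
                      years = 2005:2006,
                      zone_extents = list(A = c(0, 100, 0, 100),
                                          B = c(150, 250, 0, 100)))
  dat <- sim_camas(des, seed = 31)
  cfg <- model_config(1)
  beta <- matrix(c(1, 0.1, 0.5, 0.2), 2, 2,
                 dimnames = list(c("intercept", "year"), c("A", "B")))
  p1 <- list(beta = beta, resid_var = c(A = 0.5, B = 0.5))
  p2 <- p1
  p2$beta[, "A"] <- c(3, -0.4)
  p2$resid_var["A"] <- 2
  delta_joint <- log_posterior(dat, p2, cfg = cfg) -
    log_posterior(dat, p1, cfg = cfg)
  subA <- dat[dat$zone == "A", ]
  delta_A <- log_posterior(subA, list(beta = p2$beta[, "A", drop = FALSE],
                                      resid_var = p2$resid_var["A"]),
                           cfg = cfg) -
    log_posterior(subA, list(beta = p1$beta[, "A", drop = FALSE],
                             resid_var = p1$resid_var["A"]), cfg = cfg)
  expect_equal(delta_joint, delta_A, tolerance = 1e-9)
})

test_that("shifting all years by a constant leaves the likelihood unchanged", {
  dat <- sim_camas(small_design(), seed = 24)
  cfg <- model_config(3)
  beta <- matrix(rep(c(1, 0.1, -0.5), 3), 3, 3,
                 dimnames = list(c("intercept", "year", "elevation"),
                                 c("A", "B", "C")))
  params <- list(beta = beta, resid_var = c(A = 0.5, B = 0.5, C = 0.5))
  shifted <- dat
  shifted$year <- dat$year + 7
  expect_equal(log_likelihood(shifted, params, cfg),
               log_likelihood(dat, params, cfg), tolerance = 1e-12)
})

test_that("all four models build on the single-zone reference design", {
  dat <- sim_camas(reference_design(plots_per_year = 6, years = 2006:2007),
                   seed = 40)
  for (m in 1:4) {
    cfg <- model_config(m, include_elevation = FALSE)
    expect_silent(build_design(dat, cfg))
  }
})
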
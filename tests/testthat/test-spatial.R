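test_that("pairwise distances match closed forms and a brute-force oracle", {
  ds <- pairwise_distances(rbind(c(0, 0), c(3, 4)))
  expect_equal(ds$D[1, 2], 5)
  expect_equal(ds$d_min, 5)
  expect_equal(ds$d_max, 5)

  sq <- pairwise_distances(rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1)))
  expect_equal(sq$d_min, 1)
  expect_equal(sq$d_max, sqrt(2))

  set.seed(42)
  pts <- cbind(runif(20, 0, 100), runif(20, 0, 100))
  D <- pairwise_distances(pts)$D
  oracle <- matrix(0, 20, 20)
  for (i in 1:20) for (j in 1:20)
    oracle[i, j] <- sqrt((pts[i, 1] - pts[j, 1])^2 + (pts[i, 2] - pts[j, 2])^2)
  expect_equal(D, oracle, tolerance = 1e-12)

  expect_error(pairwise_distances(rbind(c(0, 0))), "2 points")
  expect_error(pairwise_distances(rbind(c(1, 1), c(1, 1))), "coincide")
})

test_that("exponential covariance has the right diagonal, limits and half-distance", {
  D <- pairwise_distances(rbind(c(0, 0), c(10, 0), c(0, 25)))$D
  S <- exponential_covariance(D, sigma2 = 2, phi = 0.05, tau2 = 0.7)
  expect_equal(diag(S), rep(2.7, 3))
  expect_true(isSymmetric(S))

  Snn <- exponential_covariance(D, sigma2 = 0, phi = 1, tau2 = 0.7)
  expect_equal(Snn, diag(0.7, 3))

  phi <- 0.13
  d_half <- -log(0.5) / phi
  Dh <- matrix(c(0, d_half, d_half, 0), 2)
  Sh <- exponential_covariance(Dh, sigma2 = 2, phi = phi, tau2 = 0)
  expect_equal(Sh[1, 2], 0.5 * 2, tolerance = 1e-12)

  expect_error(exponential_covariance(D, sigma2 = NA, phi = 1), "finite")
})

test_that("covariance matrices are positive definite after the standard jitter", {
  set.seed(7)
  pts <- cbind(runif(300, 0, 50), runif(300, 0, 50))
  D <- pairwise_distances(pts)$D
  for (pars in list(c(1, 0.001, 0), c(5, 10, 0.01), c(0.1, 0.5, 2))) {
    S <- pars[1] * exp(-pars[2] * D) +
      diag(pars[3] + 1e-8 * (pars[1] + pars[3]), nrow(D))
    expect_silent(chol(S))
  }
})

test_that("effective range satisfies its defining identity and monotonicity", {
  expect_equal(effective_range(-log(0.05) / 78), 78, tolerance = 1e-12)
  set.seed(3)
  phis <- 10^runif(20, -4, 1)
  expect_equal(exp(-phis * effective_range(phis)), rep(0.05, 20),
               tolerance = 1e-12)
  xr <- effective_range(sort(phis))
  expect_true(all(diff(xr) < 0))
  expect_gt(effective_range(1e6), 0)
  expect_lt(effective_range(1e6), 1e-4)
  expect_error(effective_range(0), "positive")
})

test_that("decay prior bounds hit the stated correlations at the extreme distances", {
  set.seed(11)
  pts <- cbind(runif(40, 0, 1000), runif(40, 0, 1000))
  ds <- pairwise_distances(pts)
  b <- phi_prior_bounds(ds)
  expect_equal(exp(-b["phi_min"] * ds$d_max), c(phi_min = 0.5),
               tolerance = 1e-12)
  expect_equal(exp(-b["phi_max"] * ds$d_min), c(phi_max = 0.01),
               tolerance = 1e-12)
  expect_lt(b[1], b[2])

  # two points only: d_min = d_max, so the bounds cross
  expect_error(phi_prior_bounds(rbind(c(0, 0), c(10, 0))), "degenerate")
})

test_that("empirical semivariogram matches trivial cases and a brute-force oracle", {
  pts <- cbind(runif(30, 0, 10), runif(30, 0, 10))
  sv0 <- empirical_semivariogram(rep(3.7, 30), pts)
  expect_true(all(sv0$gamma[sv0$npairs > 0] == 0))
  sv0c <- empirical_semivariogram(rep(3.7, 30), pts, estimator = "classical")
  expect_true(all(sv0c$gamma[sv0c$npairs > 0] == 0))

  sv2 <- empirical_semivariogram(c(0, 2), rbind(c(0, 0), c(1, 0)),
                                 n_bins = 1, max_lag = 2,
                                 estimator = "classical")
  expect_equal(sv2$gamma, 2)  # 0.5 * (0-2)^2

  set.seed(5)
  pts <- cbind(runif(50, 0, 100), runif(50, 0, 100))
  U <- chol(exp(-0.05 * pairwise_distances(pts)$D) + diag(1e-8, 50))
  vals <- drop(crossprod(U, rnorm(50)))  # a Gaussian-field realization
  sv <- empirical_semivariogram(vals, pts, n_bins = 10,
                                estimator = "classical")
  # independent double-loop recomputation
  max_lag <- max(pairwise_distances(pts)$D) / 2
  brk <- seq(0, max_lag, length.out = 11)
  g <- rep(NA_real_, 10); n <- integer(10)
  for (i in 1:49) for (j in (i + 1):50) {
    d <- sqrt(sum((pts[i, ] - pts[j, ])^2))
    if (d > max_lag || d == 0) next
    b <- findInterval(d, brk, rightmost.closed = TRUE)
    n[b] <- n[b] + 1L
    g[b] <- sum(0.5 * (vals[i] - vals[j])^2, g[b], na.rm = TRUE)
  }
  g <- ifelse(n > 0, g / n, NA)
  expect_equal(sv$npairs, n)
  expect_equal(sv$gamma, g, tolerance = 1e-12)
})

test_that("robust and classical estimators agree on Gaussian data; robust resists outliers", {
  set.seed(9)
  pts <- cbind(runif(400, 0, 100), runif(400, 0, 100))
  vals <- rnorm(400)  # iid: flat semivariogram at variance 1
  svr <- empirical_semivariogram(vals, pts, n_bins = 8)
  svc <- empirical_semivariogram(vals, pts, n_bins = 8,
                                 estimator = "classical")
  ok <- svr$npairs > 500
  expect_true(all(abs(svr$gamma[ok] / svc$gamma[ok] - 1) < 0.10))

  cont <- vals
  bad <- sample(400, 20)
  cont[bad] <- 10 * vals[bad]
  svr2 <- empirical_semivariogram(cont, pts, n_bins = 8)
  svc2 <- empirical_semivariogram(cont, pts, n_bins = 8,
                                  estimator = "classical")
  pert_r <- mean(abs(svr2$gamma[ok] - svr$gamma[ok]))
  pert_c <- mean(abs(svc2$gamma[ok] - svc$gamma[ok]))
  expect_lt(pert_r, pert_c)
})

test_that("weighted least squares recovers exact exponential semivariograms", {
  h <- seq(5, 200, length.out = 12)
  tau2 <- 0.4; sigma2 <- 1.6; phi <- 0.03
  sv <- structure(data.frame(lag = h,
                             gamma = tau2 + sigma2 * (1 - exp(-phi * h)),
                             npairs = rep(100L, 12),
                             estimator = "classical"),
                  class = c("semivariogram", "data.frame"))
  fit <- fit_exponential_semivariogram(sv, weights = "equal")
  expect_equal(fit$tau2, tau2, tolerance = 0.01)
  expect_equal(fit$sigma2, sigma2, tolerance = 0.01)
  expect_equal(fit$phi, phi, tolerance = 0.02)
  expect_true(fit$converged)
})

test_that("flat semivariograms are flagged and WLS beats the generating parameters", {
  h <- seq(5, 200, length.out = 12)
  flat <- structure(data.frame(lag = h, gamma = rep(1, 12),
                               npairs = rep(50L, 12),
                               estimator = "classical"),
                    class = c("semivariogram", "data.frame"))
  ff <- fit_exponential_semivariogram(flat, weights = "equal")
  expect_lt(ff$sigma2, 0.01 * (ff$sigma2 + ff$tau2 + 1))
  expect_false(is.na(ff$note))

  set.seed(13)
  tau2 <- 0.4; sigma2 <- 1.6; phi <- 0.03
  noisy <- structure(data.frame(
    lag = h,
    gamma = pmax(tau2 + sigma2 * (1 - exp(-phi * h)) + rnorm(12, 0, 0.1),
                 0.01),
    npairs = rep(100L, 12), estimator = "classical"),
    class = c("semivariogram", "data.frame"))
  fit <- fit_exponential_semivariogram(noisy, weights = "equal")
  sse <- function(p) sum((noisy$gamma - (p[1] + p[2] * (1 - exp(-p[3] * h))))^2)
  expect_lte(sse(c(fit$tau2, fit$sigma2, fit$phi)),
             sse(c(tau2, sigma2, phi)) + 1e-10)
})

test_that("semivariogram CSV export keeps the lag/gamma/npairs columns", {
  set.seed(2)
  pts <- cbind(runif(20), runif(20))
  sv <- empirical_semivariogram(rnorm(20), pts, n_bins = 5)
  f <- tempfile(fileext = ".csv")
  write_semivariogram(sv, f)
  back <- read.csv(f)
  expect_equal(names(back), c("lag", "gamma", "npairs", "estimator"))
  expect_equal(back$npairs, sv$npairs)
  unlink(f)
})
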
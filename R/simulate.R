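#' Generating parameters for synthetic density counts
#'
#' The "truth" for the synthetic-data generator: per-zone regression
#' coefficients on the log-density scale (intercept, year slope, elevation
#' slope), per-zone spatial covariance parameters (partial sill `sigma2`,
#' exponential decay `phi` in 1/m, nugget `tau2`), and the shared hyper-mean
#' `mu_beta` and hyper-SDs `sd_beta` of the coefficient hierarchy. Defaults
#' reproduce the qualitative structure of a grazed-then-rested wet prairie:
#' a positive log-linear time trend (~0.09/yr at the site level), a negative
#' density-elevation association (~ -0.8 per SD of elevation), zone-varying
#' intercepts spanning near-zero to high density, and spatial decay ranging
#' from long-range correlation to essentially none (zone E).
#'
#' @param beta numeric matrix, one column per zone, rows named
#'   `intercept`, `year`, `elevation` (the elevation row may be omitted for
#'   designs without an elevation covariate).
#' @param sigma2,phi,tau2 numeric vectors, one value per zone: partial sill,
#'   decay (1/m) and nugget on the log scale.
#' @param mu_beta,sd_beta hyper-mean and hyper-SD per coefficient.
#' @param zones zone labels; default from `beta` column names.
#' @return An object of class `true_params`.
#' @export
true_params <- function(beta = NULL, sigma2 = NULL, phi = NULL, tau2 = NULL,
                        mu_beta = c(intercept = 1.42, year = 0.09,
                                    elevation = -0.79),
                        sd_beta = c(intercept = 1.2, year = 0.05,
                                    elevation = 0.1),
                        zones = NULL) {
  if (is.null(beta)) {
    beta <- rbind(intercept = c(1.97, 0.95, 1.50, 3.02, -0.06),
                  year      = c(0.10, 0.08, 0.15, 0.04, 0.07),
                  elevation = c(-0.71, -0.81, -0.81, -0.75, -0.85))
    colnames(beta) <- LETTERS[1:5]
  }
  beta <- as.matrix(beta)
  K <- ncol(beta)
  zones <- zones %||% colnames(beta) %||% LETTERS[seq_len(K)]
  colnames(beta) <- zones
  # effective ranges ~ (185, 285, 578, 226, 0.64) m -> phi = 3/xi
  if (is.null(phi)) phi <- rep_len(c(0.016, 0.011, 0.005, 0.013, 4.7), K)
  if (is.null(sigma2)) sigma2 <- rep_len(1.0, K)
  if (is.null(tau2)) tau2 <- rep_len(0.5, K)
  sigma2 <- rep_len(sigma2, K); phi <- rep_len(phi, K); tau2 <- rep_len(tau2, K)
  names(sigma2) <- names(phi) <- names(tau2) <- zones
  if (any(sigma2 < 0) || any(tau2 < 0)) stopf("sigma2 and tau2 must be >= 0")
  if (any(phi <= 0)) stopf("phi must be > 0")
  if (any(sd_beta < 0)) stopf("sd_beta components must be >= 0")
  structure(list(beta = beta, sigma2 = sigma2, phi = phi, tau2 = tau2,
                 mu_beta = mu_beta, sd_beta = sd_beta, zones = zones),
            class = "true_params")
}

#' @export
print.true_params <- function(x, ...) {
  cat("Generating parameters for", length(x$zones), "zone(s)\n")
  cat("beta (log scale):\n"); print(round(x$beta, 3))
  print(round(rbind(sigma2 = x$sigma2, phi = x$phi, tau2 = x$tau2), 4))
  invisible(x)
}

#' Simulate counts over a plot layout
#'
#' Draws, independently per zone, a latent log-density vector from the
#' multivariate normal with mean `X_k beta_k` and exponential-with-nugget
#' covariance `sigma2_k exp(-phi_k D_k) + tau2_k I` over all plot-years in
#' the zone (spatial correlation spans years), exponentiates it to a
#' density, and converts to integer counts. The design matrix uses the same
#' centering rules as model fitting: year centered at its mean, elevation
#' standardized. With lognormal latent densities the count marginal is
#' zero-heavy with a long positive tail.
#'
#' @param layout data frame with `zone`, `x`, `y`, `year` and (unless the
#'   truth has no elevation row) `elevation` columns, e.g. from
#'   [generate_layout()] plus an [generate_elevation_surface()] evaluation.
#' @param truth a [true_params()] object covering every zone in `layout`.
#' @param seed integer seed.
#' @param discretize `"poisson"` (default; counts are Poisson with the
#'   latent density as mean, preserving zeros and long tails) or `"round"`
#'   (deterministic rounding of the latent density).
#' @return `layout` with an integer `count` column appended.
#' @export
simulate_counts <- function(layout, truth, seed = 1L,
                            discretize = c("poisson", "round")) {
  discretize <- match.arg(discretize)
  stopifnot(inherits(truth, "true_params"))
  need <- c("zone", "x", "y", "year")
  if (!all(need %in% names(layout))) stopf("layout needs columns zone, x, y, year")
  p <- nrow(truth$beta)
  has_elev <- "elevation" %in% rownames(truth$beta)
  if (has_elev && !"elevation" %in% names(layout))
    stopf("layout needs an elevation column for an elevation-covariate truth")
  zs <- unique(layout$zone)
  if (!all(zs %in% truth$zones)) stopf("truth lacks parameters for some zones")

  yr_c <- layout$year - mean(layout$year)
  if (has_elev) {
    es <- stats::sd(layout$elevation)
    el_s <- if (es > 0) (layout$elevation - mean(layout$elevation)) / es
            else rep(0, nrow(layout))
  }
  with_seed(seed, {
    count <- integer(nrow(layout))
    for (z in zs) {
      i <- which(layout$zone == z)
      X <- cbind(1, yr_c[i])
      if (has_elev) X <- cbind(X, el_s[i])
      mu <- drop(X %*% truth$beta[seq_len(p), z])
      s2 <- truth$sigma2[[z]]; t2 <- truth$tau2[[z]]; ph <- truth$phi[[z]]
      n <- length(i)
      if (s2 + t2 == 0) {
        w <- mu
      } else {
        D <- as.matrix(stats::dist(cbind(layout$x[i], layout$y[i])))
        S <- s2 * exp(-ph * D) + diag(t2 + 1e-8 * (s2 + t2), n)
        U <- tryCatch(chol(S), error = function(e)
          stopf("zone '%s': covariance not positive definite after jitter", z))
        w <- mu + drop(crossprod(U, stats::rnorm(n)))
      }
      lam <- exp(w)
      count[i] <- if (discretize == "poisson") stats::rpois(n, lam)
                  else as.integer(round(lam))
    }
    out <- layout
    out$count <- count
    out
  })
}

#' One-call synthetic monitoring data set
#'
#' Convenience wrapper: draws a layout, evaluates a synthetic elevation
#' surface at the plot locations (restoration designs), and simulates
#' counts. The result is a complete plot-observation table ready for
#' [zonetrend()].
#'
#' @param design a [study_design()].
#' @param truth a [true_params()]; for reference designs a 2-row (no
#'   elevation) truth is derived from it automatically.
#' @param relief_m,wavelength_m passed to [generate_elevation_surface()].
#' @param seed integer seed; sub-seeds for layout, surface and counts are
#'   derived from it.
#' @param discretize passed to [simulate_counts()].
#' @return Data frame `zone, x, y, elevation, year, count` with attributes
#'   `truth` and `design`.
#' @export
sim_camas <- function(design = study_design(), truth = NULL,
                      relief_m = 15, wavelength_m = 120, seed = 1L,
                      discretize = c("poisson", "round")) {
  discretize <- match.arg(discretize)
  stopifnot(inherits(design, "study_design"))
  if (is.null(truth)) {
    truth <- if (design$site_kind == "reference")
      true_params(beta = rbind(intercept = 0.55, year = 0.03),
                  sigma2 = 0.8, phi = -log(0.05) / 78, tau2 = 0.4,
                  zones = design$zones)
    else true_params()
  }
  if (!all(design$zones %in% truth$zones)) {
    if (length(design$zones) <= length(truth$zones)) {
      keep <- seq_along(design$zones)
      truth <- true_params(beta = truth$beta[, keep, drop = FALSE],
                           sigma2 = unname(truth$sigma2[keep]),
                           phi = unname(truth$phi[keep]),
                           tau2 = unname(truth$tau2[keep]),
                           mu_beta = truth$mu_beta, sd_beta = truth$sd_beta,
                           zones = design$zones)
    } else stopf("truth does not cover the design's zones")
  }
  layout <- generate_layout(design, seed = seed)
  if (design$site_kind == "reference" && !"elevation" %in% rownames(truth$beta)) {
    layout$elevation <- 0
  } else {
    surf <- generate_elevation_surface(design, relief_m = relief_m,
                                       wavelength_m = wavelength_m,
                                       seed = seed + 1L)
    layout$elevation <- surf(layout$x, layout$y)
  }
  tab <- simulate_counts(layout, truth, seed = seed + 2L,
                         discretize = discretize)
  tab <- tab[, c("zone", "x", "y", "elevation", "year", "count")]
  attr(tab, "truth") <- truth
  attr(tab, "design") <- design
  tab
}

#' Read and write plot-observation tables
#'
#' Plain-CSV round trip for the `zone,x,y,elevation,year,count` table.
#' @param x a plot table data frame.
#' @param path file path.
#' @return `read_plot_table` returns the data frame; `write_plot_table`
#'   returns `path` invisibly.
#' @export
write_plot_table <- function(x, path) {
  utils::write.csv(x[, c("zone", "x", "y", "elevation", "year", "count")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_plot_table
#' @export
read_plot_table <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("zone", "x", "y", "elevation", "year", "count")
  if (!all(need %in% names(out)))
    stopf("plot table must have columns %s", paste(need, collapse = ","))
  if (any(out$count < 0) || any(out$count != round(out$count)))
    stopf("counts must be non-negative integers")
  out
}

#' Flat key=value serialization of generating parameters
#'
#' Writes a [true_params()] object as `key=value` lines (e.g.
#' `beta.year.A=0.10`) so simulation truths round-trip into
#' parameter-recovery checks.
#' @param truth a [true_params()].
#' @param path file path.
#' @export
write_params <- function(truth, path) {
  stopifnot(inherits(truth, "true_params"))
  kv <- c()
  for (z in truth$zones) for (r in rownames(truth$beta))
    kv[sprintf("beta.%s.%s", r, z)] <- truth$beta[r, z]
  for (nm in c("sigma2", "phi", "tau2"))
    for (z in truth$zones) kv[sprintf("%s.%s", nm, z)] <- truth[[nm]][[z]]
  for (j in names(truth$mu_beta)) kv[sprintf("mu_beta.%s", j)] <- truth$mu_beta[[j]]
  for (j in names(truth$sd_beta)) kv[sprintf("sd_beta.%s", j)] <- truth$sd_beta[[j]]
  writeLines(sprintf("%s=%.17g", names(kv), kv), path)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  ln <- readLines(path)
  ln <- ln[nzchar(trimws(ln))]
  kv <- strsplit(ln, "=", fixed = TRUE)
  vals <- stats::setNames(vapply(kv, function(p) as.numeric(p[2]), 0),
                          vapply(kv, `[`, "", 1))
  parts <- strsplit(names(vals), ".", fixed = TRUE)
  bet <- parts[vapply(parts, `[`, "", 1) == "beta"]
  zones <- unique(vapply(bet, `[`, "", 3))
  terms <- unique(vapply(bet, `[`, "", 2))
  beta <- matrix(NA_real_, length(terms), length(zones),
                 dimnames = list(terms, zones))
  for (p in bet) beta[p[2], p[3]] <- vals[paste(p, collapse = ".")]
  pull <- function(nm) stats::setNames(
    vals[sprintf("%s.%s", nm, zones)], zones)
  hyp <- function(nm) {
    idx <- grep(sprintf("^%s\\.", nm), names(vals))
    stats::setNames(vals[idx], sub(sprintf("^%s\\.", nm), "", names(vals)[idx]))
  }
  true_params(beta = beta, sigma2 = unname(pull("sigma2")),
              phi = unname(pull("phi")), tau2 = unname(pull("tau2")),
              mu_beta = hyp("mu_beta"), sd_beta = hyp("sd_beta"),
              zones = zones)
}
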
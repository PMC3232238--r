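#' Stratified monitoring study design
#'
#' Describes the sampling layout of a zone-structured monitoring study: a set
#' of disjoint rectangular zones, a fixed number of plots drawn by simple
#' random sampling within each zone each year, and the years surveyed. The
#' default emulates a wet-prairie restoration site: 5 zones (A-E) covering
#' 100 ha, 70 plots per zone per year (350 annually), surveyed over six years.
#'
#' @param zones character vector of zone labels.
#' @param plots_per_zone_per_year number of plots sampled in each zone each
#'   year; must be at least 2 so inter-plot distances exist.
#' @param years integer vector of calendar years surveyed.
#' @param zone_extents named list of rectangles `c(xmin, xmax, ymin, ymax)`
#'   in metres, one per zone, pairwise disjoint. Default: side-by-side
#'   200 m x 1000 m strips (zones separated by zero-width boundaries such as
#'   roads and ditches; disconnection is expressed by independent covariance
#'   blocks, not by gaps).
#' @param site_kind `"restoration"` (multi-zone) or `"reference"`
#'   (single-zone control site).
#' @return An object of class `study_design`.
#' @seealso [reference_design()], [generate_layout()]
#' @export
study_design <- function(zones = LETTERS[1:5],
                         plots_per_zone_per_year = 70,
                         years = 2005:2010,
                         zone_extents = NULL,
                         site_kind = c("restoration", "reference")) {
  site_kind <- match.arg(site_kind)
  zones <- as.character(zones)
  if (length(zones) < 1L || anyDuplicated(zones))
    stopf("zones must be a non-empty set of distinct labels")
  if (length(years) < 1L) stopf("years must be non-empty")
  if (!is.numeric(plots_per_zone_per_year) || plots_per_zone_per_year < 2)
    stopf("plots_per_zone_per_year must be >= 2 (distances must be computable)")
  if (is.null(zone_extents)) {
    w <- 200
    zone_extents <- lapply(seq_along(zones) - 1L,
                           function(i) c(i * w, (i + 1) * w, 0, 1000))
    names(zone_extents) <- zones
  }
  if (!setequal(names(zone_extents), zones))
    stopf("zone_extents must be named by zone label")
  zone_extents <- zone_extents[zones]
  for (z in zones) {
    e <- zone_extents[[z]]
    if (length(e) != 4L || e[2] <= e[1] || e[4] <= e[3])
      stopf("zone extent for '%s' must be c(xmin, xmax, ymin, ymax) with positive area", z)
  }
  if (length(zones) > 1L) {
    for (i in seq_along(zones)[-1L]) for (j in seq_len(i - 1L)) {
      a <- zone_extents[[i]]; b <- zone_extents[[j]]
      overlap <- (min(a[2], b[2]) > max(a[1], b[1])) &&
                 (min(a[4], b[4]) > max(a[3], b[3]))
      if (overlap) stopf("zone extents '%s' and '%s' overlap", zones[i], zones[j])
    }
  }
  structure(list(zones = zones,
                 plots_per_zone_per_year = as.integer(plots_per_zone_per_year),
                 years = as.integer(years),
                 zone_extents = zone_extents,
                 site_kind = site_kind),
            class = "study_design")
}

#' Single-zone reference-site design
#'
#' A quasi-pristine control site monitored alongside the restoration site:
#' one zone, 150 plots per year, no zone stratification. Fits of
#' reference-site data conventionally drop the elevation covariate.
#'
#' @param plots_per_year plots sampled each year (default 150).
#' @param years calendar years surveyed.
#' @param extent site rectangle in metres (default 450 m x 450 m, ~20 ha).
#' @return A `study_design` with `site_kind = "reference"`.
#' @export
reference_design <- function(plots_per_year = 150, years = 2006:2010,
                             extent = c(0, 450, 0, 450)) {
  study_design(zones = "R", plots_per_zone_per_year = plots_per_year,
               years = years, zone_extents = list(R = extent),
               site_kind = "reference")
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf("Study design (%s site): %d zone(s) x %d plots/zone/year x %d year(s)\n",
              x$site_kind, length(x$zones), x$plots_per_zone_per_year,
              length(x$years)))
  cat("  zones:", paste(x$zones, collapse = ", "), "\n")
  cat("  years:", paste(range(x$years), collapse = "-"), "\n")
  invisible(x)
}

#' Draw random plot locations for every zone and year
#'
#' Simple random sampling of plot locations: coordinates are uniform within
#' each zone's extent, drawn independently for every year (plots are not
#' permanent; repeat coordinates across years never occur with continuous
#' draws). Deterministic given `seed`.
#'
#' @param design a [study_design()].
#' @param seed integer seed.
#' @return A data frame with columns `zone`, `x`, `y`, `year`, one row per
#'   plot observation (`|zones| * plots_per_zone_per_year * |years|` rows).
#' @export
generate_layout <- function(design, seed = 1L) {
  stopifnot(inherits(design, "study_design"))
  n <- design$plots_per_zone_per_year
  with_seed(seed, {
    rows <- list()
    for (yr in design$years) for (z in design$zones) {
      e <- design$zone_extents[[z]]
      rows[[length(rows) + 1L]] <- data.frame(
        zone = z,
        x = stats::runif(n, e[1], e[2]),
        y = stats::runif(n, e[3], e[4]),
        year = yr,
        stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Synthetic low-relief elevation surface
#'
#' Builds a smooth "swale and ridge" elevation surface: a superposition of
#' sinusoids with random orientations and phases (dominant wavelength plus
#' shorter-wavelength, lower-amplitude components standing in for micro-
#' topographic noise). Amplitudes are calibrated on a dense grid over the
#' site so the site-wide standard deviation is `sd_m` (default 1 m, the
#' conventional reporting unit for standardized elevation) and the total
#' relief (max - min) never exceeds `relief_m`.
#'
#' @param design a [study_design()]; its zone extents define the site.
#' @param relief_m maximum topographic relief in metres (default 15).
#' @param wavelength_m dominant swale wavelength in metres (default 120).
#' @param sd_m target site-wide standard deviation in metres (default 1).
#' @param mean_m mean site elevation in metres (default 916.8).
#' @param seed integer seed.
#' @return A function `f(x, y)` returning elevation in metres, with class
#'   `elevation_surface`.
#' @export
generate_elevation_surface <- function(design, relief_m = 15,
                                       wavelength_m = 120, sd_m = 1,
                                       mean_m = 916.8, seed = 1L) {
  stopifnot(inherits(design, "study_design"))
  if (!is.numeric(relief_m) || relief_m <= 0) stopf("relief_m must be > 0")
  if (!is.numeric(wavelength_m) || wavelength_m <= 0) stopf("wavelength_m must be > 0")
  ext <- do.call(rbind, design$zone_extents)
  xr <- range(ext[, 1:2]); yr <- range(ext[, 3:4])
  # 4 dominant swale components + 4 short-wavelength low-amplitude ones
  wl <- wavelength_m * c(1, 0.8, 0.55, 0.4, 0.22, 0.16, 0.11, 0.08)
  amp <- c(1, 0.8, 0.6, 0.45, 0.12, 0.1, 0.08, 0.06)
  comps <- with_seed(seed, data.frame(
    wl = wl, amp = amp,
    theta = stats::runif(length(wl), 0, pi),
    phase = stats::runif(length(wl), 0, 2 * pi)))
  raw <- function(x, y) {
    z <- 0
    for (i in seq_len(nrow(comps))) {
      u <- x * cos(comps$theta[i]) + y * sin(comps$theta[i])
      z <- z + comps$amp[i] * sin(2 * pi * u / comps$wl[i] + comps$phase[i])
    }
    z
  }
  g <- expand.grid(x = seq(xr[1], xr[2], length.out = 60),
                   y = seq(yr[1], yr[2], length.out = 60))
  zg <- raw(g$x, g$y)
  s <- stats::sd(zg)
  scale <- if (s > 0) sd_m / s else 0
  rng <- diff(range(zg)) * scale
  if (rng > relief_m) scale <- scale * relief_m / rng
  f <- function(x, y) mean_m + scale * raw(x, y)
  structure(f, class = c("elevation_surface", "function"),
            relief_m = relief_m, sd_m = sd_m, mean_m = mean_m)
}
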
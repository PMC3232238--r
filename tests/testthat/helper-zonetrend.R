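# shared fixtures, built in code; a small model-4 fit is cached so several
# test files can reuse it without refitting

small_design <- function(zones = c("A", "B", "C"), plots = 15,
                         years = 2005:2006, width = 150, height = 300) {
  ext <- lapply(seq_along(zones) - 1L,
                function(i) c(i * width, (i + 1) * width, 0, height))
  names(ext) <- zones
  study_design(zones = zones, plots_per_zone_per_year = plots,
               years = years, zone_extents = ext)
}

.zt_cache <- new.env(parent = emptyenv())

shared_fit4 <- function() {
  if (is.null(.zt_cache$fit4)) {
    dat <- sim_camas(small_design(), seed = 420)
    .zt_cache$fit4 <- suppressWarnings(zonetrend(
      dat, model = 4,
      chains = chain_config(n_chains = 2, burn_in = 200, n_iter = 800,
                            thin = 4),
      seed = 99))
  }
  .zt_cache$fit4
}

# counts constructed so log(count + 1) equals the linear predictor exactly
# (continuous "counts"; the log response is invertible with offset 1)
noise_free_data <- function(beta, design = small_design(), seed = 7) {
  layout <- generate_layout(design, seed = seed)
  surf <- generate_elevation_surface(design, seed = seed + 1)
  layout$elevation <- surf(layout$x, layout$y)
  yr <- layout$year - mean(layout$year)
  el <- (layout$elevation - mean(layout$elevation)) / sd(layout$elevation)
  mu <- numeric(nrow(layout))
  for (z in unique(layout$zone)) {
    i <- layout$zone == z
    mu[i] <- cbind(1, yr[i], el[i]) %*% beta[, z]
  }
  stopifnot(all(mu > 0))
  layout$count <- exp(mu) - 1
  layout
}
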
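#' Posterior summary table
#'
#' Pooled-chain posterior medians, SDs and equal-tailed 95% credible
#' intervals for every parameter, plus derived effective-range rows
#' (`xi[zone]`, metres) obtained by transforming the decay draws draw-wise
#' before taking quantiles. A per-zone raw-density summary (mean and SD of
#' plants per square metre, using the 0.6 m^2 quadrat area) accompanies
#' the table.
#'
#' @param object a [zonetrend()] fit.
#' @param probs lower/upper credible probabilities (default 2.5%/97.5%).
#' @param quadrat_area_m2 quadrat area used for the raw density summary.
#' @param ... unused.
#' @return An object of class `summary.zonetrend` with components `table`
#'   (parameter, median, sd, lower, upper) and `density` (zone, mean_m2,
#'   sd_m2, n).
#' @export
summary.zonetrend <- function(object, probs = c(0.025, 0.975),
                              quadrat_area_m2 = 0.6, ...) {
  pooled <- do.call(rbind, object$draws)
  tab <- summarize_draws(pooled, probs = probs)
  phis <- grep("^phi\\[", colnames(pooled), value = TRUE)
  if (length(phis)) {
    xi <- effective_range(pooled[, phis, drop = FALSE])
    colnames(xi) <- sub("^phi", "xi", phis)
    tab <- rbind(tab, summarize_draws(xi, probs = probs))
  }
  dens <- do.call(rbind, lapply(split(object$data, object$data$zone),
    function(d) data.frame(zone = d$zone[1],
                           mean_m2 = mean(d$count) / quadrat_area_m2,
                           sd_m2 = stats::sd(d$count) / quadrat_area_m2,
                           n = nrow(d), stringsAsFactors = FALSE)))
  rownames(dens) <- NULL
  structure(list(table = tab, density = dens, model = object$model,
                 n_draws = nrow(pooled), probs = probs),
            class = "summary.zonetrend")
}

#' Summarize a matrix of posterior draws
#'
#' @param draws numeric matrix, draws in rows, parameters in columns.
#' @param probs lower/upper quantile probabilities.
#' @return Data frame with `parameter`, `median`, `sd`, `lower`, `upper`.
#' @export
summarize_draws <- function(draws, probs = c(0.025, 0.975)) {
  draws <- as.matrix(draws)
  if (!nrow(draws)) stopf("no draws to summarize")
  qs <- apply(draws, 2, stats::quantile, probs = probs, names = FALSE)
  data.frame(parameter = colnames(draws),
             median = apply(draws, 2, stats::median),
             sd = apply(draws, 2, stats::sd),
             lower = qs[1, ], upper = qs[2, ],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @export
print.summary.zonetrend <- function(x, digits = 3, ...) {
  cat(sprintf("Posterior summary (model %d, %d pooled draws; %g%% / %g%% equal-tailed CI)\n",
              x$model, x$n_draws, 100 * x$probs[1], 100 * x$probs[2]))
  tt <- x$table
  tt[, -1] <- round(tt[, -1], digits)
  print(tt, row.names = FALSE)
  cat("\nRaw density by zone (plants per m^2):\n")
  dd <- x$density
  dd[, c("mean_m2", "sd_m2")] <- round(dd[, c("mean_m2", "sd_m2")], 1)
  print(dd, row.names = FALSE)
  invisible(x)
}

#' Percent change per unit of a log-scale coefficient
#'
#' `(exp(beta) - 1) * 100`: the percent change in median density per unit
#' of the covariate (per year for the trend, per SD for elevation).
#' Negative values are percent decreases of magnitude
#' `(1 - exp(beta)) * 100`; the sign convention is carried in the value
#' itself, positive = increase.
#'
#' @param beta log-scale coefficient(s) or draws.
#' @return Percent change, same shape as `beta`.
#' @export
percent_change <- function(beta) {
  if (any(!is.finite(beta))) stopf("beta must be finite")
  (exp(beta) - 1) * 100
}

#' Export and re-import a posterior summary table
#'
#' Writes the `table` component as CSV at full double precision so the
#' round trip reproduces the values exactly.
#' @param x a `summary.zonetrend` or a data frame shaped like its table.
#' @param path file path.
#' @export
write_summary <- function(x, path) {
  tt <- if (inherits(x, "summary.zonetrend")) x$table else x
  out <- data.frame(parameter = tt$parameter,
                    median = sprintf("%.17g", tt$median),
                    sd = sprintf("%.17g", tt$sd),
                    lower = sprintf("%.17g", tt$lower),
                    upper = sprintf("%.17g", tt$upper))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_summary
#' @export
read_summary <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (nm in c("median", "sd", "lower", "upper")) out[[nm]] <- as.numeric(out[[nm]])
  out
}

#' Fit the whole model ladder and compare trend estimates
#'
#' Fits models 1-4 on the same data with a shared master seed (expanded
#' per model, so cross-model differences are attributable to structure)
#' and collects per-model, per-zone summaries of the year and elevation
#' coefficients, the site-level hyper-means (models 2-4 only; model 1
#' generates no site estimate), credible-interval widths, and the
#' shrinkage distance of each zone trend from the pooled model-1 mean. A
#' model that fails is recorded per-model without aborting the ladder.
#'
#' @param data plot table.
#' @param chains a [chain_config()] reused for every model.
#' @param seed master seed.
#' @param ... further arguments passed to [zonetrend()].
#' @return An object of class `zonetrend_ladder`: `fits` (list, possibly
#'   with `NULL` for failures), `comparison` (long data frame with one row
#'   per model/parameter), `errors`.
#' @export
run_ladder <- function(data, chains = chain_config(), seed = 1L, ...) {
  fits <- vector("list", 4); errors <- rep(NA_character_, 4)
  comp <- list()
  for (m in 1:4) {
    ft <- tryCatch(zonetrend(data, model = m, chains = chains,
                             seed = seed * 10L + m, ...),
                   error = function(e) e)
    if (inherits(ft, "error")) { errors[m] <- conditionMessage(ft); next }
    fits[[m]] <- ft
    s <- summary(ft)$table
    keep <- grepl("^beta_(year|elevation)\\[|^mu_(year|elevation)$",
                  s$parameter)
    s <- s[keep, , drop = FALSE]
    s$model <- m
    s$ci_width <- s$upper - s$lower
    comp[[length(comp) + 1L]] <- s
  }
  comp <- do.call(rbind, comp)
  # shrinkage: distance of zone trends from the pooled model-1 mean
  if (!is.null(fits[[1]])) {
    m1 <- comp[comp$model == 1 & grepl("^beta_year", comp$parameter), ]
    pooled <- mean(m1$median)
    comp$shrinkage <- ifelse(grepl("^beta_year", comp$parameter),
                             abs(comp$median - pooled), NA_real_)
    attr(comp, "pooled_trend") <- pooled
  }
  structure(list(fits = fits, comparison = comp, errors = errors,
                 seed = seed),
            class = "zonetrend_ladder")
}

#' @export
print.zonetrend_ladder <- function(x, digits = 3, ...) {
  cat("Model ladder comparison (trend and elevation coefficients)\n")
  cc <- x$comparison
  cc[, c("median", "sd", "lower", "upper", "ci_width")] <-
    round(cc[, c("median", "sd", "lower", "upper", "ci_width")], digits)
  print(cc[, c("model", "parameter", "median", "lower", "upper",
               "ci_width")], row.names = FALSE)
  if (any(!is.na(x$errors)))
    cat("failed models:",
        paste(which(!is.na(x$errors)), x$errors[!is.na(x$errors)],
              collapse = "; "), "\n")
  invisible(x)
}

#' @export
plot.zonetrend_ladder <- function(x, parameter = "year", ...) {
  cc <- x$comparison
  pat <- sprintf("^beta_%s\\[|^mu_%s$", parameter, parameter)
  cc <- cc[grepl(pat, cc$parameter), ]
  if (!nrow(cc)) stopf("no '%s' rows in the comparison", parameter)
  labs <- unique(cc$parameter)
  ypos <- seq_along(labs)
  names(ypos) <- labs
  off <- (cc$model - 2.5) * 0.15
  graphics::plot(cc$median, ypos[cc$parameter] + off, yaxt = "n",
                 xlim = range(cc$lower, cc$upper, 0),
                 xlab = sprintf("%s coefficient (log scale)", parameter),
                 ylab = "", pch = 19, col = cc$model, ...)
  graphics::segments(cc$lower, ypos[cc$parameter] + off,
                     cc$upper, ypos[cc$parameter] + off, col = cc$model)
  graphics::abline(v = 0, lty = 3)
  graphics::axis(2, at = ypos, labels = sub("^beta_[a-z]+\\[(.*)\\]$", "\\1",
                                            sub("^mu_.*$", "site", labs)),
                 las = 1)
  graphics::legend("topright", legend = paste("model", sort(unique(cc$model))),
                   col = sort(unique(cc$model)), pch = 19, bty = "n")
  invisible(x)
}
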
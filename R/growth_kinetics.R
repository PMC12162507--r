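# Specific growth-rate estimation from cell-count time series.
#
# The specific growth rate mu (h^-1) is the slope of ln(cell density)
# against time over the exponential phase. The estimator slides every
# contiguous window of at least `min_window` points over the log-counts,
# keeps windows whose linear fit reaches the R^2 floor, drops windows
# strictly contained in an equally-or-better-fitting qualifying window
# (sub-stretches of one linear phase, whose steepest noisy sub-slopes
# would otherwise bias the estimate upward) and windows shorter than half
# the best-supported phase, and reports the maximum slope among the
# remaining candidates -- lag and plateau points drop out because windows
# covering them fit worse than the pure exponential stretch.

#' Construct a growth curve
#'
#' @param times Sampling times in hours, strictly increasing.
#' @param counts Cell densities in cells/mL, positive.
#' @param strain Strain label.
#' @param condition Optional [condition()] describing pressure and sulfur.
#' @param replicate_id Replicate label.
#' @return A `growth_curve` object.
#' @export
growth_curve <- function(times, counts, strain = "", condition = NULL,
                         replicate_id = "") {
  assert_that(length(times) == length(counts),
              "times and counts must have equal length")
  assert_that(all(is.finite(times)) && all(diff(times) > 0),
              "times must be strictly increasing")
  assert_that(all(is.finite(counts)) && all(counts > 0),
              "counts must be positive (log-linear fitting is undefined ",
              "otherwise)")
  structure(list(times = as.numeric(times), counts = as.numeric(counts),
                 strain = strain, condition = condition,
                 replicate_id = replicate_id),
            class = "growth_curve")
}

#' Experimental condition: hydrostatic pressure and sulfur regime
#'
#' The study's levels are 0.1, 40 and 70 MPa with colloidal sulfur at
#' 0.25 g/L when present (0.5 or 2 g/L for induction experiments), but the
#' fields are free-valued.
#'
#' @param pressure_MPa Hydrostatic pressure in MPa.
#' @param sulfur `TRUE`/`FALSE` for elemental sulfur present/absent.
#' @param sulfur_conc_g_per_L Sulfur concentration; must be positive iff
#'   sulfur is present (default 0.25 when present, 0 when absent).
#' @return A `condition` object.
#' @export
condition <- function(pressure_MPa, sulfur,
                      sulfur_conc_g_per_L = if (sulfur) 0.25 else 0) {
  assert_that(isTRUE(sulfur) || isFALSE(sulfur), "sulfur must be TRUE/FALSE")
  assert_that((sulfur_conc_g_per_L > 0) == sulfur,
              "sulfur_conc_g_per_L must be > 0 exactly when sulfur is present")
  structure(list(pressure_MPa = pressure_MPa, sulfur = sulfur,
                 sulfur_conc_g_per_L = sulfur_conc_g_per_L),
            class = "condition")
}

# Slope, intercept and R^2 of y ~ x by least squares; R^2 is NA when y is
# constant (flat curves have an undefined fit quality, not a perfect one).
loglinear_fit <- function(x, y) {
  vx <- stats::var(x)
  vy <- stats::var(y)
  if (vy == 0) return(list(slope = 0, r2 = NA_real_))
  slope <- stats::cov(x, y) / vx
  list(slope = slope, r2 = stats::cor(x, y)^2)
}

#' Fit the specific growth rate of one curve
#'
#' Among all contiguous windows of at least `min_window` points whose
#' log-linear fit reaches `min_r2`, returns the maximum slope of
#' ln(counts) versus time after two pruning steps: windows strictly
#' contained in an equally-or-better-fitting qualifying window are
#' dropped (they are sub-stretches of the same linear phase, and
#' selecting the steepest noisy sub-stretch would bias the estimate
#' upward), as are windows shorter than half the longest remaining
#' candidate (short chance alignments). On fully exponential data the
#' full series is therefore fitted; curves with lag or plateau phases
#' keep the pure exponential stretch, which fits strictly better than
#' any window crossing a kink. If no window reaches the floor the
#' best-R^2 window's slope is returned with `low_quality = TRUE`. A
#' perfectly flat curve yields `mu = 0` with `r_squared = NA` and the
#' low-quality flag.
#'
#' @param curve A [growth_curve()] (or data frame with `time_h` and
#'   `cells_per_mL` columns).
#' @param min_window Minimum window size in points (default 4).
#' @param min_r2 R^2 floor for an acceptable exponential-phase window
#'   (default 0.95).
#' @return A `growth_rate_estimate`: `mu` (h^-1), `window` (index span
#'   used), `r_squared`, `doubling_time` (h), `low_quality`, `n_points`.
#' @export
fit_growth_rate <- function(curve, min_window = 4L, min_r2 = 0.95) {
  if (is.data.frame(curve))
    curve <- growth_curve(curve$time_h, curve$cells_per_mL)
  assert_that(inherits(curve, "growth_curve"), "curve must be a growth_curve")
  n <- length(curve$times)
  assert_that(min_window >= 2L, "min_window must be >= 2")
  assert_that(n >= min_window, "curve has ", n, " points; at least ",
              min_window, " are required for fitting")
  y <- log(curve$counts)
  x <- curve$times
  qualifying <- list()
  fallback <- NULL   # best-R^2 window overall
  for (i in seq_len(n - min_window + 1L)) {
    for (j in seq(i + min_window - 1L, n)) {
      fit <- loglinear_fit(x[i:j], y[i:j])
      cand <- list(mu = fit$slope, window = c(i, j), r_squared = fit$r2)
      if (!is.na(fit$r2) && fit$r2 >= min_r2)
        qualifying[[length(qualifying) + 1L]] <- cand
      if (is.null(fallback) ||
          (!is.na(fit$r2) && (is.na(fallback$r_squared) ||
                              fit$r2 > fallback$r_squared)))
        fallback <- cand
    }
  }
  best <- NULL
  if (length(qualifying)) {
    win <- t(vapply(qualifying, function(q) as.integer(q$window), integer(2)))
    r2s <- vapply(qualifying, `[[`, 1, "r_squared")
    # a window strictly contained in an equally-or-better-fitting
    # qualifying window is an arbitrary sub-stretch of the same phase,
    # not a distinct candidate (its steeper noisy sub-slopes would bias
    # the estimate upward); candidates far shorter than the
    # best-supported phase are likewise noise artifacts
    undominated <- vapply(seq_len(nrow(win)), function(k)
      !any(win[, 1] <= win[k, 1] & win[, 2] >= win[k, 2] &
           (win[, 1] != win[k, 1] | win[, 2] != win[k, 2]) &
           r2s >= r2s[[k]]), TRUE)
    cand <- qualifying[undominated]
    lens <- vapply(cand, function(q) diff(q$window) + 1L, 1L)
    cand <- cand[lens >= max(lens) / 2]
    for (c in cand) if (is.null(best) || c$mu > best$mu) best <- c
  }
  est <- if (!is.null(best)) c(best, low_quality = FALSE)
         else c(fallback, low_quality = TRUE)
  est$doubling_time <- if (est$mu > 0) log(2) / est$mu else Inf
  est$n_points <- n
  class(est) <- "growth_rate_estimate"
  est
}

#' @export
print.growth_rate_estimate <- function(x, ...) {
  cat(sprintf(
    "<growth_rate_estimate> mu = %.4g h^-1 (doubling %.3g h), window %d..%d, R^2 = %s%s\n",
    x$mu, x$doubling_time, x$window[1], x$window[2],
    if (is.na(x$r_squared)) "NA" else sprintf("%.4f", x$r_squared),
    if (x$low_quality) " [low quality]" else ""))
  invisible(x)
}

#' Read a cell-count table
#'
#' Tab-separated with columns `strain`, `pressure_MPa`, `sulfur`,
#' `sulfur_conc_g_per_L`, `replicate`, `time_h`, `cells_per_mL`.
#'
#' @param path TSV path.
#' @return Data frame of counts.
#' @export
read_growth_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("strain", "pressure_MPa", "sulfur", "sulfur_conc_g_per_L",
            "replicate", "time_h", "cells_per_mL")
  missing_cols <- setdiff(need, names(df))
  assert_that(length(missing_cols) == 0L, "count table lacks column(s): ",
              paste(missing_cols, collapse = ", "))
  df$sulfur <- as.logical(df$sulfur)
  df
}

#' Growth-rate grid by strain and condition
#'
#' Fits each replicate curve and aggregates per strain x condition cell:
#' mean and SD of mu over biological replicates (SD is `NA` for single
#' replicates), plus a pooled estimate from the fit to all replicate
#' points of the cell combined.
#'
#' @param counts Long data frame as returned by [read_growth_tsv()].
#' @param min_window,min_r2 Passed to [fit_growth_rate()].
#' @return Data frame with one row per strain x condition: `n_replicates`,
#'   `mu_mean`, `mu_sd`, `mu_pooled`, plus per-replicate fits as attribute
#'   `fits`.
#' @export
rate_grid <- function(counts, min_window = 4L, min_r2 = 0.95) {
  assert_that(is.data.frame(counts) && nrow(counts) > 0,
              "empty count table")
  cell_key <- interaction(counts$strain, counts$pressure_MPa, counts$sulfur,
                          counts$sulfur_conc_g_per_L, drop = TRUE)
  fits <- list()
  rows <- lapply(split(counts, cell_key), function(cell) {
    reps <- split(cell, cell$replicate)
    mus <- vapply(reps, function(r) {
      r <- r[order(r$time_h), ]
      fit_growth_rate(growth_curve(r$time_h, r$cells_per_mL),
                      min_window, min_r2)$mu
    }, 1)
    pooled <- pooled_rate(cell, min_window, min_r2)
    data.frame(strain = cell$strain[[1]],
               pressure_MPa = cell$pressure_MPa[[1]],
               sulfur = cell$sulfur[[1]],
               sulfur_conc_g_per_L = cell$sulfur_conc_g_per_L[[1]],
               n_replicates = length(mus), mu_mean = mean(mus),
               mu_sd = if (length(mus) > 1L) stats::sd(mus) else NA_real_,
               mu_pooled = pooled, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$strain, out$pressure_MPa, !out$sulfur), , drop = FALSE]
}

# Pooled fit: average log-counts per time point across replicates (when
# replicates share time points), then the standard window search. Cells
# with unshared time grids fall back to NA.
pooled_rate <- function(cell, min_window, min_r2) {
  byt <- split(log(cell$cells_per_mL), cell$time_h)
  times <- as.numeric(names(byt))
  means <- vapply(byt, mean, 1)
  o <- order(times)
  if (length(times) < min_window) return(NA_real_)
  fit_growth_rate(growth_curve(times[o], exp(means[o])),
                  min_window, min_r2)$mu
}

#' Qualitative growth class relative to the parental strain
#'
#' Classifies a mutant's growth under one condition against the parental
#' strain measured under the same condition: `"-"` when mu falls below the
#' absolute floor (severely impaired growth, well under the ~0.1 h^-1
#' regime) or the final-density ratio collapses; `"+++"` when both the
#' rate and the final density reach 80% of parental; `"++"` at 40% of the
#' parental rate; `"+"` otherwise. Thresholds are configurable.
#'
#' @param estimate Mutant [fit_growth_rate()] result or a numeric mu.
#' @param parental_estimate Parental estimate or numeric mu (> 0).
#' @param final_density_ratio Mutant/parental final cell-density ratio
#'   (default 1 when only rates are available).
#' @param mu_floor Absolute mu floor for `"-"` (default 0.05 h^-1).
#' @param density_floor Final-density ratio floor for `"-"` (default 0.1).
#' @param frac_high,density_high Parental fractions for `"+++"`
#'   (default 0.8 both).
#' @param frac_mid Parental fraction for `"++"` (default 0.4).
#' @return One of `"-"`, `"+"`, `"++"`, `"+++"`.
#' @export
classify_growth <- function(estimate, parental_estimate,
                            final_density_ratio = 1, mu_floor = 0.05,
                            density_floor = 0.1, frac_high = 0.8,
                            density_high = 0.8, frac_mid = 0.4) {
  mu <- if (inherits(estimate, "growth_rate_estimate")) estimate$mu
        else estimate
  mu_p <- if (inherits(parental_estimate, "growth_rate_estimate"))
            parental_estimate$mu else parental_estimate
  assert_that(is.finite(mu_p) && mu_p > 0, "parental mu must be positive")
  if (mu < mu_floor || final_density_ratio < density_floor) return("-")
  if (mu >= frac_high * mu_p && final_density_ratio >= density_high)
    return("+++")
  if (mu >= frac_mid * mu_p) return("++")
  "+"
}

#' Class matrix for a fitted rate grid
#'
#' Applies [classify_growth()] to every non-parental row of a rate grid,
#' pairing each with the parental strain's rate under the same condition.
#'
#' @param grid A [rate_grid()] result or any data frame with `strain`,
#'   `pressure_MPa`, `sulfur` and a rate column `mu_mean`.
#' @param parental_strain Name of the parental/reference strain.
#' @param density_ratios Optional data frame (`strain`, `pressure_MPa`,
#'   `sulfur`, `ratio`) of final-density ratios; defaults to 1 everywhere.
#' @param ... Threshold overrides passed to [classify_growth()].
#' @return The grid restricted to mutant rows with a `growth_class` column.
#' @export
classify_grid <- function(grid, parental_strain, density_ratios = NULL, ...) {
  assert_that(parental_strain %in% grid$strain,
              "parental strain '", parental_strain, "' absent from grid")
  par_rows <- grid[grid$strain == parental_strain, , drop = FALSE]
  mut <- grid[grid$strain != parental_strain, , drop = FALSE]
  cls <- vapply(seq_len(nrow(mut)), function(i) {
    p <- par_rows[par_rows$pressure_MPa == mut$pressure_MPa[[i]] &
                  par_rows$sulfur == mut$sulfur[[i]], , drop = FALSE]
    assert_that(nrow(p) == 1L, "no unique parental rate for condition ",
                mut$pressure_MPa[[i]], " MPa, sulfur=", mut$sulfur[[i]])
    ratio <- 1
    if (!is.null(density_ratios)) {
      dr <- density_ratios[density_ratios$strain == mut$strain[[i]] &
                           density_ratios$pressure_MPa == mut$pressure_MPa[[i]] &
                           density_ratios$sulfur == mut$sulfur[[i]], ,
                           drop = FALSE]
      if (nrow(dr) == 1L) ratio <- dr$ratio
    }
    classify_growth(mut$mu_mean[[i]], p$mu_mean[[1]], ratio, ...)
  }, "")
  mut$growth_class <- cls
  rownames(mut) <- NULL
  mut
}
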
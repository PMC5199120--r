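# Robustness classification of parameter points, scan aggregation,
# 2D-histogram matrices and pairwise restriction mining.

#' Configuration for robustness classification
#'
#' A parameter point is classified by simulating its steady-state
#' dose-response curve at each receptor-abundance multiplier and comparing
#' amplitudes and EC50s across multipliers:
#' \itemize{
#'   \item normal amplitude: amplitude at the reference abundance at least
#'     `amplitude_floor` (normalized output units);
#'   \item robust amplitude: normal amplitude, all amplitudes positive, and
#'     max/min amplitude ratio at most `amplitude_tol`;
#'   \item robust EC50: normal amplitude, all EC50s defined, and max/min
#'     EC50 ratio at most `ec50_tol`;
#'   \item robust response: both;
#'   \item DoRA: output EC50 within `dora_band` of the occupancy EC50 at the
#'     reference abundance.
#' }
#'
#' @param multipliers receptor-abundance multipliers; must include 1.
#' @param amplitude_tol max/min amplitude ratio across multipliers.
#' @param ec50_tol max/min EC50 ratio across multipliers.
#' @param amplitude_floor normal-amplitude threshold (normalized output).
#' @param dora_band EC50-ratio band for dose-response alignment.
#' @param abundances reference abundances (multiplied on `R_tot`).
#' @param grid_points number of non-zero ligand-grid points per curve.
#' @param grid_decades half-width of the ligand grid around each point's
#'   `Kd_LR`, decades (the grid adapts to the sampled affinity so its top
#'   saturates the receptor for every draw).
#' @param tol steady-state solver tolerance.
#' @return A list of class `robustness_config`.
#' @export
robustness_config <- function(multipliers = c(0.1, 1, 10),
                              amplitude_tol = 1.5,
                              ec50_tol = 3,
                              amplitude_floor = 0.05,
                              dora_band = c(1 / 3, 3),
                              abundances = carousel_abundances(),
                              grid_points = 20,
                              grid_decades = 4,
                              tol = 1e-9) {
  if (!any(multipliers == 1)) stop("multipliers must include 1")
  if (amplitude_tol <= 1 || ec50_tol <= 1) stop("tolerances must exceed 1")
  structure(list(multipliers = multipliers, amplitude_tol = amplitude_tol,
                 ec50_tol = ec50_tol, amplitude_floor = amplitude_floor,
                 dora_band = dora_band, abundances = abundances,
                 grid_points = grid_points, grid_decades = grid_decades,
                 tol = tol),
            class = "robustness_config")
}

#' Classify one parameter point for robustness to receptor abundance
#'
#' @param params a [carousel_params()] object or coercible named list/row.
#' @param config a [robustness_config()].
#' @return A one-row data frame with logical columns `normal_amplitude`,
#'   `robust_amplitude`, `robust_ec50`, `robust_response`, `dora`,
#'   `any_failure` plus the per-multiplier amplitudes/EC50s as attributes
#'   `detail`.
#' @export
classify_point <- function(params, config = robustness_config()) {
  params <- as_carousel_params(params)
  grid <- kd_centered_grid(params$Kd_LR, config$grid_decades,
                           config$grid_points)
  m <- config$multipliers
  ref_i <- which(m == 1)[1]
  ab_i <- lapply(m, function(mi) {
    carousel_abundances(config$abundances$R_tot * mi,
                        config$abundances$G_tot, config$abundances$V_cyt)
  })

  # stage 1: endpoint steady states (L = 0 and saturating top) suffice for
  # the amplitude flags; the full grid is only needed for EC50-based flags
  endpoints <- grid[c(1, length(grid))]
  amps <- numeric(length(m))
  fail <- FALSE
  for (i in seq_along(m)) {
    cv <- simulate_dor(params, ab_i[[i]], endpoints, tol = config$tol)
    if (any(!cv$converged)) fail <- TRUE
    amps[i] <- amplitude(cv)
  }
  normal_amp <- !fail && is.finite(amps[ref_i]) &&
    amps[ref_i] >= config$amplitude_floor
  robust_amp <- normal_amp && all(is.finite(amps)) && all(amps > 0) &&
    max(amps) / min(amps) <= config$amplitude_tol

  # stage 2: EC50s (and DoRA at the reference abundance), only where the
  # amplitude gate allows them to be defined at all
  ecs <- rep(NA_real_, length(m))
  dora <- FALSE
  ratio <- NA_real_
  if (normal_amp) {
    need <- which(is.finite(amps) & amps >= config$amplitude_floor)
    need <- union(ref_i, need)
    for (i in need) {
      cv <- simulate_dor(params, ab_i[[i]], grid, tol = config$tol)
      if (any(!cv$converged)) fail <- TRUE
      ecs[i] <- ec50(cv, floor = config$amplitude_floor)
      if (i == ref_i) {
        dr <- dora_ratio(cv, band = config$dora_band,
                         floor = config$amplitude_floor)
        dora <- isTRUE(dr$dora)
        ratio <- dr$ratio
      }
    }
    normal_amp <- normal_amp && !fail
    robust_amp <- robust_amp && !fail
  }
  robust_ec <- normal_amp && all(is.finite(ecs)) &&
    max(ecs) / min(ecs) <= config$ec50_tol
  out <- data.frame(
    normal_amplitude = normal_amp,
    robust_amplitude = robust_amp,
    robust_ec50 = robust_ec,
    robust_response = robust_amp && robust_ec,
    dora = dora && !fail,
    dora_ratio = ratio,
    any_failure = fail
  )
  attr(out, "detail") <- list(amplitudes = amps, ec50s = ecs,
                              multipliers = m)
  out
}

#' Run a robustness scan over sampled parameter points
#'
#' Classifies every draw and aggregates class fractions. Failed
#' (non-converged) points count as non-robust and stay in the denominator.
#'
#' @param draws data frame of parameter draws from [lhs_sample()] (one row
#'   per point, one column per kinetic parameter).
#' @param config a [robustness_config()].
#' @param progress print a progress line every `progress` points (0 = quiet).
#' @return A list of class `scan_result`: `labels` (per-point logical data
#'   frame), `fractions` (percent, over all points), `n`, `n_failed`,
#'   `draws`, `config`.
#' @export
run_scan <- function(draws, config = robustness_config(), progress = 0) {
  n <- nrow(draws)
  labs <- vector("list", n)
  for (i in seq_len(n)) {
    labs[[i]] <- classify_point(as.list(draws[i, kinetic_parameter_names()]),
                                config)
    if (progress > 0 && i %% progress == 0) {
      message("classified ", i, "/", n, " points")
    }
  }
  labels <- do.call(rbind, labs)
  fr <- function(v) 100 * mean(v, na.rm = FALSE)
  fractions <- c(
    normal_amplitude = fr(labels$normal_amplitude),
    robust_amplitude = fr(labels$robust_amplitude),
    robust_ec50 = fr(labels$robust_ec50),
    robust_response = fr(labels$robust_response),
    dora_among_robust = if (any(labels$robust_response)) {
      100 * mean(labels$dora[labels$robust_response])
    } else NA_real_
  )
  structure(list(labels = labels, fractions = fractions, n = n,
                 n_failed = sum(labels$any_failure), draws = draws,
                 config = config),
            class = "scan_result")
}

#' @export
print.scan_result <- function(x, ...) {
  cat("Carousel robustness scan: ", x$n, " points, ", x$n_failed,
      " solver failures\n", sep = "")
  print(round(x$fractions, 2))
  invisible(x)
}

#' Matrix of pairwise 2D log10 histograms
#'
#' For each ordered pair of sampled parameters, counts of the points in
#' log10 bins of `decades_per_bin` decades; the diagonal holds the 1D
#' histograms. Bin edges span each parameter's sampled range.
#'
#' @param points data frame of parameter values (a subset of scan draws).
#' @param sampled parameter names to include.
#' @param ranges named list of c(lo, hi) sampling ranges per parameter
#'   (defaults to the observed range, expanded to whole bins).
#' @param decades_per_bin bin width, decades.
#' @return A list of class `histogram_matrix`: `panels[[x]][[y]]` count
#'   matrices (rows = y bins, cols = x bins), `breaks` per parameter, and
#'   `panel_id` labels ("Rxy" by row-major position).
#' @export
histogram_matrix <- function(points, sampled = colnames(points),
                             ranges = NULL, decades_per_bin = 1) {
  if (!nrow(points)) stop("points subset is empty")
  breaks <- lapply(sampled, function(nm) {
    if (!is.null(ranges) && nm %in% names(ranges)) {
      lo <- log10(ranges[[nm]][1]); hi <- log10(ranges[[nm]][2])
    } else {
      lo <- floor(min(log10(points[[nm]])))
      hi <- ceiling(max(log10(points[[nm]])))
    }
    seq(floor(lo), ceiling(hi), by = decades_per_bin)
  })
  names(breaks) <- sampled
  bin <- function(nm) {
    b <- breaks[[nm]]
    cut(pmin(pmax(log10(points[[nm]]), b[1]), b[length(b)]),
        breaks = b, include.lowest = TRUE)
  }
  bins <- lapply(sampled, bin)
  names(bins) <- sampled
  panels <- list()
  ids <- character(0)
  for (xi in seq_along(sampled)) {
    xnm <- sampled[xi]
    panels[[xnm]] <- list()
    for (yi in seq_along(sampled)) {
      ynm <- sampled[yi]
      panels[[xnm]][[ynm]] <- if (xi == yi) {
        table(bins[[xnm]])
      } else {
        table(bins[[ynm]], bins[[xnm]])
      }
      ids <- c(ids, sprintf("R%d%d", yi - 1L, xi - 1L))
    }
  }
  structure(list(panels = panels, breaks = breaks, sampled = sampled,
                 panel_id = ids, n = nrow(points)),
            class = "histogram_matrix")
}

#' Mine pairwise parameter restrictions
#'
#' For every ordered pair of parameters (x, y), the fraction of points in
#' the subset satisfying `log10(x) + margin < log10(y)`. Pairs whose
#' fraction reaches `threshold` are reported as restrictions ("x << y");
#' a fraction of exactly 1 is flagged as a necessary restriction.
#'
#' @param points data frame of parameter values (e.g. the robust-response
#'   subset of scan draws).
#' @param sampled parameter names to consider.
#' @param threshold minimum satisfaction fraction to report.
#' @param margin log10 margin (decades) tightening the inequality.
#' @param min_points refuse subsets smaller than this.
#' @return Data frame with columns `x`, `y`, `fraction`, `necessary`,
#'   sorted by decreasing fraction.
#' @export
mine_restrictions <- function(points, sampled = colnames(points),
                              threshold = 0.95, margin = 0,
                              min_points = 50) {
  if (nrow(points) < min_points) {
    stop("subset has ", nrow(points), " points; at least ", min_points,
         " required for restriction mining")
  }
  lg <- log10(as.matrix(points[, sampled, drop = FALSE]))
  out <- list()
  for (xi in seq_along(sampled)) for (yi in seq_along(sampled)) {
    if (xi == yi) next
    frac <- mean(lg[, xi] + margin < lg[, yi])
    if (frac >= threshold) {
      out[[length(out) + 1L]] <- data.frame(
        x = sampled[xi], y = sampled[yi], fraction = frac,
        necessary = frac == 1)
    }
  }
  if (!length(out)) {
    return(data.frame(x = character(), y = character(),
                      fraction = numeric(), necessary = logical()))
  }
  res <- do.call(rbind, out)
  res[order(-res$fraction, res$x, res$y), , drop = FALSE]
}

#' DoRA sub-analysis of the robust-response subset
#'
#' Among parameter points with a robust response: the DoRA fraction, the
#' partition into collision-coupling-limited (`koff_RG > koff_LR`) and
#' ligand-limited (`koff_RG < koff_LR`) groups, and for the DoRA points the
#' proximity of the occupied-receptor hydrolysis rate to the larger of the
#' two off-rates (on DoRA points roughly one hydrolysis event occurs per
#' ternary-complex lifetime, so `kH_LRGt ~ max(koff_LR, koff_RG)`).
#'
#' @param scan a `scan_result`, or a data frame of robust-response draws
#'   paired with `labels`.
#' @param labels per-point labels when `scan` is a draws data frame.
#' @param proximity_decades half-width (decades) of the "close to" band.
#' @return A list: `n_robust`, `dora_fraction` (percent), `groups` (per-point
#'   group factor), `prox_fraction` (fraction of DoRA points with
#'   `kH_LRGt` within the band of `max(koff_LR, koff_RG)`), and the
#'   per-point ratio table.
#' @export
dora_subanalysis <- function(scan, labels = NULL, proximity_decades = 1) {
  if (inherits(scan, "scan_result")) {
    draws <- scan$draws
    labels <- scan$labels
  } else {
    draws <- scan
    if (is.null(labels)) stop("labels required")
  }
  rob <- which(labels$robust_response)
  if (!length(rob)) stop("no robust-response points in the subset")
  d <- draws[rob, , drop = FALSE]
  dora <- labels$dora[rob]
  grp <- factor(ifelse(d$koff_RG > d$koff_LR, "koff_RG>koff_LR",
                       "koff_RG<koff_LR"))
  ref_rate <- pmax(d$koff_LR, d$koff_RG)
  prox <- abs(log10(d$kH_LRGt) - log10(ref_rate)) <= proximity_decades
  list(
    n_robust = length(rob),
    dora_fraction = 100 * mean(dora),
    groups = grp,
    prox_fraction = if (any(dora)) mean(prox[dora]) else NA_real_,
    table = data.frame(
      dora = dora, group = grp,
      log10_kH_LRGt = log10(d$kH_LRGt),
      log10_max_off = log10(ref_rate),
      within_band = prox)
  )
}
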
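# Steady-state dose-response curves, amplitude/EC50 summaries, DoRA scoring,
# and the classical receptor-theory baseline.

#' Default ligand grid
#'
#' Zero plus `n` log-spaced concentrations. The default span (1e-3 to 1e5 nM)
#' brackets the reference ligand-receptor Kd of 5.6 nM by about four decades
#' on each side, so the top of the grid saturates the receptor.
#'
#' @param lo,hi grid limits, nM.
#' @param n number of non-zero points.
#' @return Sorted numeric vector starting at 0.
#' @export
default_l_grid <- function(lo = 1e-3, hi = 1e5, n = 25) {
  c(0, 10^seq(log10(lo), log10(hi), length.out = n))
}

# grid centered on a sampled Kd so that the saturating-top precondition holds
# for every draw in an 8-decade scan
kd_centered_grid <- function(Kd, decades = 4, n = 20) {
  c(0, 10^seq(log10(Kd) - decades, log10(Kd) + decades, length.out = n))
}

#' Simulate a steady-state dose-response curve
#'
#' One steady state per grid ligand concentration. The output is free
#' Gbetagamma normalized to total G protein; occupancy is
#' ligand-bound receptor normalized to total receptor (equal to the Langmuir
#' fraction `L / (Kd_LR + L)` at steady state, a consequence of the
#' coupling-state-independent ligand affinity).
#'
#' @param params a [carousel_params()] object, or a prebuilt
#'   `carousel_network` (any variant).
#' @param abundances a [carousel_abundances()] object. For a network input,
#'   totals other than `R_tot`/`G_tot` (RGS, a second receptor pool) are
#'   taken from `extra_totals`.
#' @param l_grid ligand grid, nM; must be sorted and should contain 0 and a
#'   saturating top (>= 1e4 x Kd_LR by default).
#' @param tol steady-state tolerance, see [solve_steady_state()].
#' @param method solver method, see [solve_steady_state()].
#' @param extra_totals named list of additional conserved totals (nM) for
#'   the extended (`RGS_tot`) or two-pool (`R2_tot`) variants.
#' @return A data frame of class `dor_curve` with columns `L`, `output`,
#'   `occupancy`, `converged`, `residual`; the full species matrix is in
#'   `attr(, "states")`.
#' @export
simulate_dor <- function(params, abundances = carousel_abundances(),
                         l_grid = default_l_grid(), tol = 1e-9,
                         method = "hybrid", extra_totals = list()) {
  if (is.unsorted(l_grid)) stop("l_grid must be sorted ascending")
  if (any(l_grid < 0)) stop("l_grid must be non-negative")
  if (inherits(params, "carousel_network")) {
    net <- params
  } else {
    net <- build_network("simplified", as_carousel_params(params))
  }
  Rt <- abundances$R_tot; Gt <- abundances$G_tot

  if (net$variant == "simplified" && method == "hybrid") {
    k <- with(net$params,
              c(kon_LR, koff_LR, kon_RG, koff_RG, kA_Gd, koff_GdGbg,
                kE_G, kE_RG, kE_LRG, kH_Gt, kH_RGt, kH_LRGt))
    out <- .css_curve(k, Rt, Gt, l_grid, tol, 400L)
    states <- out$states
    rownames(states) <- net$species
    conv <- as.logical(out$converged)
    resid <- out$residual
  } else {
    totals <- stats::setNames(numeric(nrow(net$cons)), rownames(net$cons))
    totals["R_tot"] <- Rt
    totals[intersect(c("Ga_tot", "Gbg_tot"), names(totals))] <- Gt
    for (nm in names(extra_totals)) {
      if (!nm %in% names(totals)) stop("unknown extra total: ", nm)
      totals[nm] <- extra_totals[[nm]]
    }
    x <- naive_state(net, as.list(totals))
    states <- matrix(0, length(net$species), length(l_grid),
                     dimnames = list(net$species, NULL))
    conv <- logical(length(l_grid)); resid <- numeric(length(l_grid))
    # pre-equilibrate at L = 0, then walk up the grid with warm starts
    ss <- solve_steady_state(net, 0, x, tol = tol, method = method)
    x0 <- ss$state
    x <- x0
    for (i in seq_along(l_grid)) {
      if (l_grid[i] == 0) {
        states[, i] <- x0; conv[i] <- ss$converged; resid[i] <- ss$residual
        next
      }
      si <- solve_steady_state(net, l_grid[i], x, tol = tol, method = method)
      states[, i] <- si$state; conv[i] <- si$converged
      resid[i] <- si$residual
      x <- si$state
    }
  }

  occ_species <- grep("^L", rownames(states), value = TRUE)
  Rt_all <- Rt + if (net$variant == "two_pool")
    sum(states[grep("^L?R2", rownames(states)), 1]) else 0
  occupied <- if (net$variant == "two_pool") {
    colSums(states[grep("^LR($|G|_)", rownames(states)), , drop = FALSE]) +
      colSums(states[grep("^LR2", rownames(states)), , drop = FALSE])
  } else {
    colSums(states[occ_species, , drop = FALSE])
  }
  curve <- data.frame(
    L = l_grid,
    output = if (Gt > 0) states["Gbg", ] / Gt else rep(0, length(l_grid)),
    occupancy = if (Rt_all > 0) occupied / Rt_all else rep(0, length(l_grid)),
    converged = conv,
    residual = resid
  )
  attr(curve, "states") <- states
  attr(curve, "params") <- net$params
  attr(curve, "abundances") <- abundances
  attr(curve, "variant") <- net$variant
  class(curve) <- c("dor_curve", "data.frame")
  curve
}

#' Dose-response amplitude
#'
#' Difference in normalized output between the top of the ligand grid and
#' zero ligand. `NA` if either endpoint failed to converge.
#'
#' @param curve a `dor_curve` from [simulate_dor()].
#' @param column which series to use.
#' @return Dimensionless amplitude in `[-1, 1]`.
#' @export
amplitude <- function(curve, column = "output") {
  n <- nrow(curve)
  if (!isTRUE(curve$converged[1]) || !isTRUE(curve$converged[n])) return(NA_real_)
  curve[[column]][n] - curve[[column]][1]
}

#' EC50 by log-linear interpolation
#'
#' Concentration at which the baseline-subtracted, amplitude-normalized
#' series crosses one half, interpolated linearly in log10(L). Undefined
#' (`NA`) when the amplitude is below `floor`.
#'
#' @param L ligand grid (nM) or a `dor_curve`.
#' @param y response series (ignored when `L` is a `dor_curve`).
#' @param column series to summarize when `L` is a `dor_curve`.
#' @param floor minimum amplitude below which the EC50 is undefined.
#' @return EC50 in nM, or `NA_real_`.
#' @export
ec50 <- function(L, y = NULL, column = "output", floor = 0.05) {
  if (inherits(L, "dor_curve")) {
    curve <- L
    y <- curve[[column]]
    L <- curve$L
  }
  stopifnot(length(L) == length(y))
  amp <- y[length(y)] - y[1]
  if (!is.finite(amp) || amp < floor) return(NA_real_)
  s <- (y - y[1]) / amp
  pos <- which(L > 0)
  Lp <- L[pos]; sp <- s[pos]
  hit <- which(sp >= 0.5)
  if (!length(hit)) return(NA_real_)
  i <- hit[1]
  # half-max reached at (or below) the lowest non-zero concentration: the
  # EC50 lies outside the grid support and cannot be measured
  if (i == 1L) return(NA_real_)
  # linear in log10(L)
  f <- (0.5 - sp[i - 1]) / (sp[i] - sp[i - 1])
  10^(log10(Lp[i - 1]) + f * (log10(Lp[i]) - log10(Lp[i - 1])))
}

#' Dose-response alignment (DoRA) ratio
#'
#' Ratio of the output EC50 to the occupancy EC50. A system with dose-response
#' alignment transmits fractional occupancy linearly, so the ratio is close
#' to 1; a sensitized (signal-amplifying) system has a ratio below 1.
#'
#' @param curve a `dor_curve`, or the output EC50 (nM).
#' @param occupancy_ec50 occupancy EC50 (nM) when `curve` is a scalar.
#' @param band DoRA acceptance band on the ratio.
#' @param floor minimum-amplitude floor passed to [ec50()].
#' @return List with `ratio`, `dora` (logical flag; `NA` when either EC50 is
#'   undefined), `ec50_output`, `ec50_occupancy`.
#' @export
dora_ratio <- function(curve, occupancy_ec50 = NULL, band = c(1 / 3, 3),
                       floor = 0.05) {
  if (inherits(curve, "dor_curve")) {
    e_out <- ec50(curve, column = "output", floor = floor)
    e_occ <- ec50(curve, column = "occupancy", floor = floor)
  } else {
    e_out <- curve
    e_occ <- occupancy_ec50
  }
  if (!is.finite(e_out) || !is.finite(e_occ)) {
    return(list(ratio = NA_real_, dora = NA, ec50_output = e_out,
                ec50_occupancy = e_occ))
  }
  ratio <- e_out / e_occ
  list(ratio = ratio, dora = ratio >= band[1] && ratio <= band[2],
       ec50_output = e_out, ec50_occupancy = e_occ)
}

#' Classical receptor-theory dose-response baseline
#'
#' The textbook operational model: stimulus `S = eps * R0 * L / (Kd + L)`
#' (intrinsic efficacy times occupied receptor) passed through the
#' hyperbolic transducer `E/Em = S / (Ke + S)`. Under this model any change
#' in receptor abundance `R0` shifts the amplitude and/or EC50 of the
#' response, which is the behaviour the carousel model escapes.
#'
#' @param L ligand concentrations.
#' @param R0 receptor abundance (arbitrary concentration units).
#' @param Kd ligand-receptor dissociation constant (same units as `L`).
#' @param eps intrinsic efficacy.
#' @param Ke transducer constant (units of `S`).
#' @return `E/Em`, dimensionless in `[0, 1)`.
#' @export
receptor_theory_effect <- function(L, R0 = 1, Kd = 10, eps = 1, Ke = 0.1) {
  stopifnot(R0 > 0, Kd > 0, eps > 0, Ke > 0, all(L >= 0))
  S <- eps * R0 * L / (Kd + L)
  S / (Ke + S)
}
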
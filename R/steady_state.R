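# Steady-state computation for carousel networks.
#
# The workhorse is a damped pseudo-transient continuation (PTC): implicit
# Euler with a geometrically growing pseudo-time step that turns into full
# Newton as the step grows. The rate equations are rank-deficient (the
# conservation laws), so one equation per conserved total is replaced by the
# conservation constraint, which also pins the totals exactly. The simplified
# variant dispatches to a compiled kernel; all variants are covered by the R
# implementation, and an independent stiff-integrator path (deSolve) is
# available as `method = "integrate"`.

# forward and backward flux parts, for turnover-scaled residuals
flux_parts <- function(network, state, L) {
  nr <- length(network$kf)
  vf <- numeric(nr); vb <- numeric(nr)
  for (j in seq_len(nr)) {
    f <- network$kf[j] * prod(state[network$fwd[[j]]])
    if (network$lig[j]) f <- f * L
    vf[j] <- f
    if (network$kr[j] > 0) vb[j] <- network$kr[j] * prod(state[network$rev[[j]]])
  }
  list(vf = vf, vb = vb)
}

#' Residual norm of a candidate steady state
#'
#' Maximum over species of `|dx_i/dt| / max(x_i, floor)`, the
#' concentration-scaled rate of change (units 1/s).
#'
#' @param network a `carousel_network`.
#' @param state named concentration vector (nM).
#' @param L clamped ligand concentration, nM.
#' @param floor residual scale floor, nM.
#' @return The residual norm (1/s).
#' @export
verify_steady_state <- function(network, state, L, floor = 1e-12) {
  d <- rhs(network, state, L)
  max(abs(d) / pmax(state, floor))
}

turnover_residual <- function(network, state, L) {
  vp <- flux_parts(network, state, L)
  net <- as.numeric(network$S %*% (vp$vf - vp$vb))
  gross <- as.numeric(abs(network$S) %*% (vp$vf + vp$vb))
  max(abs(net) / (gross + 1e-300))
}

# choose one species per conservation row whose rate equation the constraint
# replaces; prefer species appearing in as few conservation rows as possible
# (e.g. free R, Gt, Gbg, RGS), which keeps the constrained system
# well-conditioned
constraint_rows <- function(network) {
  involvement <- colSums(network$cons != 0)
  taken <- integer(0)
  vapply(seq_len(nrow(network$cons)), function(r) {
    supp <- setdiff(which(network$cons[r, ] != 0), taken)
    pick <- supp[which.min(involvement[supp])]
    taken <<- c(taken, pick)
    pick
  }, integer(1))
}

# generic damped PTC / Newton on the conservation-constrained system
ptc_steady_state <- function(network, totals, x0, L, tol = 1e-9,
                             maxit = 400L, pure_newton = FALSE) {
  ns <- length(network$species)
  crow <- constraint_rows(network)
  x <- pmax(as.numeric(x0), 0)
  kmax <- max(c(network$kf * ifelse(network$lig, max(L, 1), 1) *
                  max(1, sum(totals)), network$kr), 1e-12)
  dt <- if (pure_newton) Inf else 0.1 / kmax
  dtmax <- 1e18 / kmax

  resid <- function(x) {
    names(x) <- network$species
    c(conc = verify_steady_state(network, x, L),
      turn = turnover_residual(network, x, L))
  }
  r <- resid(x)
  it_used <- maxit
  for (it in seq_len(maxit)) {
    if (r["conc"] <= tol || r["turn"] <= 1e-11) { it_used <- it - 1L; break }
    names(x) <- network$species
    J <- network_jacobian(network, x, L)
    f <- rhs(network, x, L)
    B <- -J
    rhs_v <- as.numeric(f)
    if (is.finite(dt)) {
      diag(B)[-crow] <- diag(B)[-crow] + 1 / dt
    }
    B[crow, ] <- network$cons
    rhs_v[crow] <- totals - as.numeric(network$cons %*% x)
    dx <- tryCatch(solve(B, rhs_v), error = function(e) NULL)
    if (is.null(dx) || any(!is.finite(dx))) {
      dt <- dt * 0.2
      if (dt < 1e-30 / kmax) break
      next
    }
    xn <- pmax(x + dx, 0)
    rn <- resid(xn)
    if (any(!is.finite(rn))) {
      dt <- dt * 0.2
      if (dt < 1e-30 / kmax) break
      next
    }
    # conservation rows plus clipping keep iterates bounded; steps are
    # accepted and the step size scales with the improvement ratio of the
    # bounded turnover residual (neutral to noise near the fixed point)
    fac <- if (rn["turn"] <= 0.3 * r["turn"]) 10
           else if (rn["turn"] <= r["turn"]) 3
           else max(r["turn"] / rn["turn"], 0.3)
    x <- xn; r <- rn
    dt <- min(max(dt * fac, 1e-25 / kmax), dtmax)
  }
  r <- resid(x)
  names(x) <- network$species
  list(state = x, residual = unname(r["conc"]),
       converged = r["conc"] <= tol || r["turn"] <= 1e-11,
       iterations = it_used)
}

# deSolve-based path: integrate the ODEs until the residual falls below tol
# (root-triggered early exit) or the horizon is reached
integrate_steady_state <- function(network, x0, L, tol = 1e-9,
                                   horizon = 1e8, times = NULL) {
  # the turnover exit threshold scales down with a stricter tol so that a
  # tight comparison against the Newton path is not cut short by the root
  turn_tol <- min(1e-11, max(tol, 1e-14))
  func <- function(t, y, parms) {
    y <- pmax(y, 0)
    names(y) <- network$species
    list(rhs(network, y, L))
  }
  jac <- function(t, y, parms) {
    y <- pmax(y, 0)
    names(y) <- network$species
    network_jacobian(network, y, L)
  }
  rootf <- function(t, y, parms) {
    y <- pmax(y, 0)
    names(y) <- network$species
    min(verify_steady_state(network, y, L) - tol,
        turnover_residual(network, y, L) - turn_tol)
  }
  if (is.null(times)) times <- c(0, 10^seq(0, log10(horizon), length.out = 60))
  out <- deSolve::lsodar(y = as.numeric(x0), times = times, func = func,
                         jacfunc = jac, jactype = "fullusr",
                         rootfunc = rootf, rtol = 1e-10, atol = 1e-12,
                         maxsteps = 1e5)
  x <- pmax(out[nrow(out), -1], 0)
  names(x) <- network$species
  res <- verify_steady_state(network, x, L)
  list(state = x, residual = res,
       converged = res <= tol ||
         turnover_residual(network, x, L) <= turn_tol,
       trajectory = out)
}

#' Solve the steady state of a carousel network
#'
#' Finds the fixed point of the mass-action dynamics at a clamped ligand
#' concentration, preserving the conserved totals of the initial state
#' exactly.
#'
#' @param network a `carousel_network`.
#' @param L clamped ligand concentration, nM.
#' @param init initial state (named concentration vector); its conserved
#'   totals define the totals of the solution.
#' @param tol convergence tolerance on the concentration-scaled residual
#'   (1/s). A turnover-scaled residual below 1e-11 (net flux a negligible
#'   fraction of gross flux, i.e. a fixed point at machine precision) is also
#'   accepted, which matters for extreme parameter draws whose gross fluxes
#'   cancel below `tol` only in exact arithmetic.
#' @param method "hybrid" (pseudo-transient continuation into Newton; the
#'   default, compiled for the simplified variant), "newton" (pure damped
#'   Newton from `init`), or "integrate" (stiff ODE integration via
#'   deSolve with residual-triggered early exit).
#' @param maxit iteration cap for the hybrid/newton methods.
#' @return A list of class `carousel_steady_state`: `state`, `residual`,
#'   `converged`, `method`.
#' @export
solve_steady_state <- function(network, L, init, tol = 1e-9,
                               method = c("hybrid", "newton", "integrate"),
                               maxit = 400L) {
  method <- match.arg(method)
  check_state(network, init, L)
  totals <- as.numeric(network$cons %*% init[network$species])
  res <- if (method == "integrate") {
    integrate_steady_state(network, init[network$species], L, tol = tol)
  } else if (network$variant == "simplified" && method == "hybrid" &&
             abs(totals[2] - totals[3]) <= 1e-9 * max(totals[2], 1)) {
    k <- with(network$params,
              c(kon_LR, koff_LR, kon_RG, koff_RG, kA_Gd, koff_GdGbg,
                kE_G, kE_RG, kE_LRG, kH_Gt, kH_RGt, kH_LRGt))
    out <- .css_solve(k, totals[1], totals[2], L,
                      as.numeric(init[network$species]), tol, maxit)
    st <- out$state
    names(st) <- network$species
    list(state = st, residual = out$residual, converged = out$converged,
         iterations = out$iterations)
  } else {
    ptc_steady_state(network, totals, init[network$species], L, tol = tol,
                     maxit = maxit, pure_newton = (method == "newton"))
  }
  res$method <- method
  res$L <- L
  class(res) <- "carousel_steady_state"
  res
}

#' @export
print.carousel_steady_state <- function(x, ...) {
  cat("Carousel steady state (", x$method, "), L = ", x$L, " nM: ",
      if (isTRUE(x$converged)) "converged" else "NOT converged",
      ", residual ", format(x$residual, digits = 3), " /s\n", sep = "")
  print(signif(x$state, 4))
  invisible(x)
}

#' Pre-equilibrated unliganded initial state
#'
#' The steady state of the simplified model at `L = 0`, computed from the
#' naive start (all receptor free, all G protein as free heterotrimer).
#' Degenerate inputs have closed forms: with no G protein the state is all
#' free receptor; with all exchange rates zero there is no activation flux
#' and the state is the receptor-G coupling equilibrium with every active
#' species exactly zero.
#'
#' @param params a [carousel_params()] object.
#' @param abundances a [carousel_abundances()] object.
#' @param tol solver tolerance passed to [solve_steady_state()].
#' @return Named concentration vector (nM) over the 12 simplified species.
#' @export
initial_state <- function(params, abundances = carousel_abundances(),
                          tol = 1e-9) {
  params <- as_carousel_params(params)
  Rt <- abundances$R_tot; Gt <- abundances$G_tot
  x <- stats::setNames(numeric(12L), SIMPLIFIED_SPECIES)
  if (Gt == 0) {
    x["R"] <- Rt
    return(x)
  }
  if (params$kE_G == 0 && params$kE_RG == 0 && params$kE_LRG == 0) {
    # no activation flux: receptor-trimer binding equilibrium, closed form
    Kd <- params$Kd_RG
    s <- Rt + Gt + Kd
    RG <- (s - sqrt(s^2 - 4 * Rt * Gt)) / 2
    x["RG"] <- RG; x["R"] <- Rt - RG; x["G"] <- Gt - RG
    return(x)
  }
  net <- build_network("simplified", params)
  x["R"] <- Rt; x["G"] <- Gt
  ss <- solve_steady_state(net, 0, x, tol = tol)
  ss$state
}

naive_state <- function(network, totals) {
  x <- stats::setNames(numeric(length(network$species)), network$species)
  switch(network$variant,
    simplified = { x["R"] <- totals[["R_tot"]]; x["G"] <- totals[["Ga_tot"]] },
    extended = {
      x["R"] <- totals[["R_tot"]]; x["G"] <- totals[["Ga_tot"]]
      x["RGS"] <- totals[["RGS_tot"]]
    },
    two_pool = {
      x["R"] <- totals[["R_tot"]]; x["R2"] <- totals[["R2_tot"]]
      x["G"] <- totals[["Ga_tot"]]
    })
  x
}
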
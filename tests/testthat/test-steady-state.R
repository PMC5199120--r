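test_that("steady-state occupancy obeys the Langmuir isotherm across parameter draws", {
  # the coupling-state-independent ligand affinity forces occupancy to
  # L/(Kd+L) at any fixed point, a whole-solver oracle
  for (seed in 1:8) {
    p <- random_params(seed)
    cv <- simulate_dor(p, carousel_abundances(),
                       c(0, p$Kd_LR * c(0.1, 1, 10)))
    expect_true(all(cv$converged))
    expect_equal(cv$occupancy, cv$L / (p$Kd_LR + cv$L), tolerance = 1e-9)
  }
})

test_that("hybrid solver agrees with independent stiff integration", {
  p <- carousel_params()
  net <- build_network("simplified", p)
  st <- initial_state(p)
  # the integrator is run to a much stricter residual than the comparison
  # tolerance so that its own truncation error does not mask disagreement
  for (L in c(0.5, 100)) {
    hy <- solve_steady_state(net, L, st, method = "hybrid")
    it <- solve_steady_state(net, L, st, method = "integrate", tol = 1e-12)
    expect_true(hy$converged)
    expect_equal(unname(hy$state["Gbg"]), unname(it$state["Gbg"]),
                 tolerance = 1e-6)
  }
  for (seed in 1:6) {
    pp <- random_params(seed, span = 4)
    netp <- build_network("simplified", pp)
    x0 <- stats::setNames(numeric(12), netp$species)
    x0["R"] <- 1400; x0["G"] <- 860
    hy <- solve_steady_state(netp, 10, x0, method = "hybrid")
    it <- solve_steady_state(netp, 10, x0, method = "integrate", tol = 1e-12)
    expect_true(hy$converged)
    expect_equal(unname(hy$state["Gbg"]), unname(it$state["Gbg"]),
                 tolerance = 1e-6)
  }
})

test_that("conserved totals are preserved along integrated trajectories", {
  p <- carousel_params()
  net <- build_network("simplified", p)
  x0 <- stats::setNames(numeric(12), net$species)
  x0["R"] <- 1400; x0["G"] <- 860
  out <- carousel:::integrate_steady_state(net, x0, 50)$trajectory
  tot <- t(apply(out[, -1], 1, function(r) {
    conserved_totals(stats::setNames(pmax(r, 0), net$species))
  }))
  expect_equal(tot[, "R_tot"] / 1400, rep(1, nrow(tot)), tolerance = 1e-9)
  expect_equal(tot[, "Ga_tot"] / 860, rep(1, nrow(tot)), tolerance = 1e-9)
  expect_equal(tot[, "Gbg_tot"] / 860, rep(1, nrow(tot)), tolerance = 1e-9)
})

test_that("degenerate inputs have exact closed-form steady states", {
  # no G protein: all receptor free; half occupancy exactly at L = Kd
  p <- carousel_params()
  st0 <- initial_state(p, carousel_abundances(G_tot = 0))
  expect_identical(unname(st0["R"]), 1400)
  expect_identical(sum(st0[-1]), 0)
  cv <- simulate_dor(p, carousel_abundances(G_tot = 0), c(0, 5.6))
  expect_equal(cv$occupancy[2], 0.5, tolerance = 1e-9)
  expect_identical(cv$output, c(0, 0))
  # no exchange flux anywhere: no active species can ever form
  pz <- carousel_params(kE_G = 0, kE_RG = 0, kE_LRG = 0)
  stz <- initial_state(pz)
  expect_identical(unname(stz[c("Gbg", "Gt", "Gd")]), c(0, 0, 0))
  expect_equal(unname(conserved_totals(stz)), c(1400, 860, 860),
               tolerance = 1e-12)
})

test_that("the basal unliganded state has small positive activation", {
  st <- initial_state(carousel_params())
  basal <- st[["Gbg"]] / 860
  expect_gt(basal, 0)
  expect_lt(basal, 0.05)
})

test_that("steady state is independent of the initial condition", {
  p <- carousel_params()
  net <- build_network("simplified", p)
  naive <- stats::setNames(numeric(12), net$species)
  naive["R"] <- 1400; naive["G"] <- 860
  pre <- initial_state(p)
  for (L in c(0.2, 5.6, 1000)) {
    a <- solve_steady_state(net, L, naive)
    b <- solve_steady_state(net, L, pre)
    expect_equal(a$state, b$state, tolerance = 1e-6)
  }
})

test_that("residual verification flags perturbed fixed points", {
  p <- carousel_params()
  net <- build_network("simplified", p)
  ss <- solve_steady_state(net, 10, initial_state(p))
  expect_lt(verify_steady_state(net, ss$state, 10), 1e-8)
  bumped <- ss$state
  bumped["Gbg"] <- bumped["Gbg"] * 1.01
  expect_gt(verify_steady_state(net, bumped, 10), 1e-9)
})
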
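test_that("simplified network has the canonical structure", {
  net <- build_network("simplified", carousel_params())
  expect_length(net$species, 12)
  expect_length(net$kf, 19)
  expect_identical(sum(net$lig), 4L)                       # ligand binding
  expect_identical(sum(net$kr > 0 & !net$lig), 9L)         # coupling + reassoc
  expect_identical(sum(net$kr == 0), 6L)                   # exchange + hydrolysis
  expect_identical(nrow(net$cons), 3L)
})

test_that("extended network duplicates receptor forms and adds 8 RGS associations", {
  net <- build_network("extended", carousel_params(), rgs = rgs_params())
  expect_length(net$species, 21)
  expect_identical(sum(grepl("^RGS\\+", net$reaction)), 8L)
  expect_identical(nrow(net$cons), 4L)
  # GAP acceleration only on RGS-bound receptor complexes
  expect_equal(net$kf[net$reaction == "hyd_RGt"], rgs_params()$kH_noRGS_RGt)
  expect_equal(net$kf[net$reaction == "hyd_RGt_RGS"], 0.11)
  expect_error(build_network("extended", carousel_params()), "rgs")
})

test_that("two-pool network gives the non-binder pool coupling but no ligand binding", {
  net <- build_network("two_pool", carousel_params())
  expect_true(all(c("R2", "R2G", "R2Gt", "R2Gd") %in% net$species))
  pool2_rxn <- grepl("R2", net$reaction)
  expect_false(any(net$lig & pool2_rxn))
  expect_identical(sum(grepl("^R2\\+", net$reaction)), 3L)
  expect_identical(nrow(net$cons), 4L)
  # a ligand-binding second pool gets the full receptor reaction set
  netb <- build_network("two_pool", carousel_params(),
                        pool2 = list(binds_ligand = TRUE))
  expect_identical(sum(netb$lig), 8L)
})

test_that("conservation vectors annihilate the stoichiometry exactly", {
  for (net in list(
    build_network("simplified", carousel_params()),
    build_network("extended", carousel_params(), rgs = rgs_params()),
    build_network("two_pool", carousel_params())
  )) {
    expect_true(all(net$cons %*% net$S == 0))
  }
})

test_that("rhs matches a hand-assembled flux-by-flux oracle", {
  p <- carousel_params()
  net <- build_network("simplified", p)
  expect_equal(rhs(net, stats::setNames(numeric(12), net$species), 10),
               stats::setNames(numeric(12), net$species))
  # single-molecule arithmetic: only free trimer present, so the only
  # fluxes are its exchange (kE_G) and its dissociation into GalphaGDP +
  # Gbetagamma (reverse of the reassociation reaction, koff_GdGbg)
  x <- stats::setNames(numeric(12), net$species)
  x["G"] <- 1
  d <- rhs(net, x, 0)
  expect_equal(unname(d["Gt"]), 0.00062)
  expect_equal(unname(d["Gbg"]), 0.00062 + p$koff_GdGbg)
  expect_equal(unname(d["G"]), -(0.00062 + p$koff_GdGbg))
  expect_equal(unname(d["Gd"]), p$koff_GdGbg)
  # random states and parameters against the independent oracle
  for (seed in 1:5) {
    pp <- random_params(seed)
    netp <- build_network("simplified", pp)
    x <- random_state(seed)
    expect_equal(rhs(netp, x, 7.3), oracle_rhs(pp, x, 7.3),
                 tolerance = 1e-10)
  }
})

test_that("rhs rejects invalid states", {
  net <- build_network("simplified", carousel_params())
  x <- stats::setNames(numeric(12), net$species)
  xb <- x; xb[1] <- -1
  expect_error(rhs(net, xb, 0), "non-negative")
  expect_error(rhs(net, x, -1), "non-negative")
  expect_error(rhs(net, x[1:5], 0), "species")
})

test_that("closed binding/coupling loops are thermodynamically consistent", {
  p <- random_params(3)
  net <- build_network("simplified", p)
  keq <- function(name) {
    j <- match(name, net$reaction)
    net$kf[j] / net$kr[j]
  }
  # R -> LR -> LRG -> RG -> R: the product of equilibrium constants around
  # the loop is 1 (ligand affinity independent of coupling state and vice
  # versa)
  loop <- keq("L+R") * keq("LR+G") / (keq("R+G") * keq("L+RG"))
  expect_equal(loop, 1, tolerance = 1e-12)
  loop_t <- keq("L+R") * keq("LR+Gt") / (keq("R+Gt") * keq("L+RGt"))
  expect_equal(loop_t, 1, tolerance = 1e-12)
})

test_that("conserved totals recover the configured abundances", {
  z <- stats::setNames(numeric(12), simplified_species)
  expect_equal(unname(conserved_totals(z)), c(0, 0, 0))
  st <- initial_state(carousel_params(), carousel_abundances())
  expect_equal(conserved_totals(st),
               c(R_tot = 1400, Ga_tot = 860, Gbg_tot = 860),
               tolerance = 1e-9)
})
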
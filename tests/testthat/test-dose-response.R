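test_that("receptor-theory baseline evaluates its closed form", {
  expect_identical(receptor_theory_effect(0), 0)
  # hyperbolic transducer saturates at R0/(Ke+R0)
  expect_equal(receptor_theory_effect(1e9, R0 = 1, Kd = 10, eps = 1,
                                      Ke = 0.1),
               1 / 1.1, tolerance = 1e-6)
  # closed-form EC50 of the composite curve: Kd*Ke/(Ke+eps*R0),
  # which decreases as receptor abundance rises
  for (R0 in c(0.3, 1, 3, 10)) {
    ec <- ec50(c(0, 10^seq(-5, 4, length.out = 200)),
               receptor_theory_effect(c(0, 10^seq(-5, 4, length.out = 200)),
                                      R0 = R0),
               floor = 1e-6)
    expect_equal(ec, 10 * 0.1 / (0.1 + R0), tolerance = 0.02)
  }
})

test_that("EC50 interpolation recovers known half-saturation points", {
  L <- c(0, 10^seq(-2, 4, length.out = 40))
  expect_equal(ec50(L, L / (10 + L), floor = 0.01), 10, tolerance = 0.02)
  # occupancy series of a simulated curve lands on the ligand Kd
  cv <- simulate_dor(carousel_params())
  expect_equal(ec50(cv, column = "occupancy"), 5.6, tolerance = 0.05)
  # amplitude below the floor leaves the EC50 undefined
  expect_true(is.na(ec50(L, 0.01 * L / (10 + L), floor = 0.05)))
  # half-max below the lowest non-zero concentration is unmeasurable
  expect_true(is.na(ec50(c(0, 1, 10, 100), c(0, 0.9, 0.95, 1))))
})

test_that("amplitude is the endpoint difference and degenerate curves are flat", {
  cv <- simulate_dor(carousel_params())
  expect_equal(amplitude(cv), cv$output[nrow(cv)] - cv$output[1])
  expect_gt(amplitude(cv), 0.9)
  # equal exchange rates on all receptor states: ligand cannot change the
  # activation flux, so the response is flat
  pfl <- carousel_params(kE_RG = 0.00062, kE_LRG = 0.00062)
  cfl <- simulate_dor(pfl, l_grid = c(0, 10^seq(-2, 5, length.out = 10)))
  expect_lt(abs(amplitude(cfl)), 1e-6)
  # unconverged endpoints poison the amplitude
  cvb <- cv
  cvb$converged[1] <- FALSE
  expect_true(is.na(amplitude(cvb)))
})

test_that("curve invariants hold: bounded output, Langmuir occupancy, monotone occupancy", {
  cv <- simulate_dor(carousel_params())
  expect_true(all(cv$output >= 0 & cv$output <= 1))
  expect_true(all(diff(cv$occupancy) >= -1e-12))
  expect_equal(cv$occupancy, cv$L / (5.6 + cv$L), tolerance = 1e-9)
  expect_true(all(cv$converged))
})

test_that("dose-response alignment ratio behaves at its fixed points", {
  cv <- simulate_dor(carousel_params())
  # identical series compared with themselves give a ratio of exactly 1
  e <- ec50(cv, column = "output")
  expect_equal(dora_ratio(e, e)$ratio, 1)
  expect_true(dora_ratio(e, e)$dora)
  dr <- dora_ratio(cv)
  expect_equal(dr$ec50_occupancy, 5.6, tolerance = 0.05)
  expect_true(dr$dora)
  # undefined EC50 propagates to an undefined flag
  expect_true(is.na(dora_ratio(NA_real_, 5)$dora))
})

test_that("grid validation rejects malformed inputs", {
  expect_error(simulate_dor(carousel_params(), l_grid = c(10, 1)), "sorted")
  expect_error(simulate_dor(carousel_params(), l_grid = c(-1, 10)),
               "non-negative")
})
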
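# The regime anchors: reference parameters are robust with alignment;
# precoupling loses robustness to receptor decrease but keeps alignment;
# delocalized GAP activity loses robustness; fast uncoupling sensitizes.

test_that("reference parameters classify as a robust, aligned response", {
  lab <- classify_point(carousel_params())
  expect_true(lab$normal_amplitude)
  expect_true(lab$robust_amplitude)
  expect_true(lab$robust_ec50)
  expect_true(lab$robust_response)
  expect_true(lab$dora)
  expect_false(lab$any_failure)
})

test_that("precoupling regime loses robustness to receptor decrease, keeps DoRA", {
  lab <- classify_point(carousel_params(koff_RG = 0.001))
  det <- attr(lab, "detail")
  expect_false(lab$robust_response)
  # amplitude collapses when receptors drop below the G-protein pool,
  # but a receptor excess changes nothing
  expect_lt(det$amplitudes[1], 0.5 * det$amplitudes[2])
  expect_equal(det$amplitudes[3], det$amplitudes[2], tolerance = 0.02)
  expect_true(lab$dora)
  expect_equal(lab$dora_ratio, 1, tolerance = 0.15)
})

test_that("delocalized GAP activity loses robustness to receptor decrease", {
  lab <- classify_point(carousel_params(kH_Gt = 0.11, kH_RGt = 0.11))
  det <- attr(lab, "detail")
  expect_false(lab$robust_response)
  expect_lt(det$amplitudes[1], 0.5 * det$amplitudes[2])
  expect_equal(det$amplitudes[3], det$amplitudes[2], tolerance = 0.02)
})

test_that("fast receptor-G uncoupling sensitizes the output", {
  lab <- classify_point(carousel_params(koff_RG = 10))
  expect_lt(lab$dora_ratio, 1 / 3)
  expect_false(lab$dora)
})

test_that("scan fractions aggregate labels deterministically", {
  draws <- do.call(rbind, replicate(15, as.data.frame(
    carousel_params()[kinetic_parameter_names()]), simplify = FALSE))
  scan <- run_scan(draws)
  expect_identical(unname(scan$fractions["robust_response"]), 100)
  expect_identical(unname(scan$fractions["dora_among_robust"]), 100)
  deloc <- draws
  deloc$kH_Gt <- 0.11; deloc$kH_RGt <- 0.11; deloc$kH_LRGt <- 0.11
  scan0 <- run_scan(deloc)
  expect_identical(unname(scan0$fractions["robust_response"]), 0)
  # determinism: identical draws and config give identical results
  scan2 <- run_scan(draws)
  expect_identical(scan$labels, scan2$labels)
  expect_identical(scan$fractions, scan2$fractions)
})

test_that("class hierarchy holds on sampled scans", {
  d <- lhs_sample(lhs_spec(n = 120, seed = 17))
  scan <- run_scan(d)
  lb <- scan$labels
  expect_true(all(!lb$robust_response | lb$robust_amplitude))
  expect_true(all(!lb$robust_response | lb$robust_ec50))
  expect_true(all(!lb$robust_amplitude | lb$normal_amplitude))
  expect_true(all(!lb$robust_ec50 | lb$normal_amplitude))
  expect_lte(sum(lb$robust_response),
             min(sum(lb$robust_amplitude), sum(lb$robust_ec50)))
})

test_that("restriction mining counts directed inequalities exactly", {
  set.seed(42)
  n <- 400
  pts <- data.frame(
    kH_Gt = 10^stats::runif(n, -4, 0),
    kH_LRGt = 10^stats::runif(n, 1, 3),    # always above kH_Gt
    kE_G = 10^stats::runif(n, -4, 4),
    kE_LRG = 10^stats::runif(n, -4, 4)     # independent of kE_G
  )
  r <- mine_restrictions(pts, threshold = 0.95)
  hit <- r[r$x == "kH_Gt" & r$y == "kH_LRGt", ]
  expect_identical(nrow(hit), 1L)
  expect_identical(hit$fraction, 1)
  expect_true(hit$necessary)
  # independent log-uniform clouds produce no reported restriction
  expect_false(any(r$x == "kE_G" & r$y == "kE_LRG"))
  expect_false(any(r$x == "kE_LRG" & r$y == "kE_G"))
  frac_indep <- mean(log10(pts$kE_G) < log10(pts$kE_LRG))
  expect_lt(abs(frac_indep - 0.5), 0.1)
  expect_error(mine_restrictions(pts[1:10, ]), "at least")
})

test_that("histogram matrix is consistent with its marginals", {
  set.seed(7)
  pts <- data.frame(a = 10^stats::runif(100, -2, 2),
                    b = 10^stats::runif(100, -3, 1))
  hm <- histogram_matrix(pts)
  panel <- hm$panels[["a"]][["b"]]
  expect_identical(sum(panel), 100L)
  expect_identical(as.integer(colSums(panel)),
                   as.integer(hm$panels[["a"]][["a"]]))
  expect_identical(as.integer(rowSums(panel)),
                   as.integer(hm$panels[["b"]][["b"]]))
  single <- histogram_matrix(pts[3, , drop = FALSE])
  expect_identical(sum(single$panels[["a"]][["b"]] > 0), 1L)
  expect_error(histogram_matrix(pts[0, ]), "empty")
})

test_that("the DoRA sub-analysis partitions the robust subset", {
  draws <- do.call(rbind, replicate(12, as.data.frame(
    carousel_params()[kinetic_parameter_names()]), simplify = FALSE))
  scan <- run_scan(draws)
  sub <- dora_subanalysis(scan)
  expect_identical(sub$n_robust, 12L)
  expect_identical(sub$dora_fraction, 100)
  # reference point: koff_RG (0.1) > koff_LR (0.001), kH_LRGt = 0.11 within
  # a decade of koff_RG
  expect_identical(as.character(unique(sub$groups)), "koff_RG>koff_LR")
  expect_identical(sub$prox_fraction, 1)
})

test_that("the two-receptor-pool mixture halves the signal only with receptor-coupled GAP", {
  p <- carousel_params()
  ab_half <- carousel_abundances(700, 860)
  mix <- simulate_dor(build_network("two_pool", p), ab_half, c(0, 1e5),
                      extra_totals = list(R2_tot = 700))
  all_b <- simulate_dor(p, carousel_abundances(1400, 860), c(0, 1e5))
  ratio <- mix$output[2] / all_b$output[2]
  # half occupancy maps onto the transfer curve at half occupancy
  expect_equal(ratio, 0.646, tolerance = 0.02)
  # removing receptor-localized hydrolysis abolishes the non-binder
  # pool's inhibition
  pd <- carousel_params(kH_RGt = 0.002, kH_LRGt = 0.11)
  mixd <- simulate_dor(build_network("two_pool", pd), ab_half, c(0, 1e5),
                       extra_totals = list(R2_tot = 700))
  alld <- simulate_dor(pd, carousel_abundances(1400, 860), c(0, 1e5))
  expect_gt(mixd$output[2] / alld$output[2], 0.9)
})
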
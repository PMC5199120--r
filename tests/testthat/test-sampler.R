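test_that("Latin hypercube draws stratify every sampled dimension", {
  spec <- lhs_spec(n = 10, seed = 3)
  d <- lhs_sample(spec)
  for (nm in spec$sampled) {
    u <- (log10(d[[nm]]) - log10(spec$center[[nm]])) / spec$span + 0.5
    # exactly one point per equal-width stratum
    expect_identical(as.integer(sort(ceiling(u * 10))), 1:10)
  }
})

test_that("draws are reproducible under a fixed seed and differ across seeds", {
  a <- lhs_sample(lhs_spec(n = 25, seed = 11))
  b <- lhs_sample(lhs_spec(n = 25, seed = 11))
  c <- lhs_sample(lhs_spec(n = 25, seed = 12))
  expect_identical(a, b)
  expect_false(isTRUE(all.equal(a$Kd_LR, c$Kd_LR)))
  # the caller's RNG stream is left untouched
  set.seed(99); before <- stats::runif(1)
  set.seed(99); invisible(lhs_sample(lhs_spec(n = 5, seed = 1)))
  expect_identical(stats::runif(1), before)
})

test_that("an 8-decade span is centered on the reference value", {
  spec <- lhs_spec(n = 200, span = 8, seed = 5)
  d <- lhs_sample(spec)
  expect_true(all(d$kE_G >= 6.2e-8 & d$kE_G <= 62))
  expect_true(all(d$Kd_LR >= 5.6e-4 & d$Kd_LR <= 5.6e4))
  # non-sampled parameters stay fixed at the reference
  spec2 <- lhs_spec(n = 50, sampled = c("koff_RG", "kH_Gt"), seed = 5)
  d2 <- lhs_sample(spec2)
  expect_identical(unique(d2$Kd_LR), 5.6)
  expect_identical(unique(d2$kE_LRG), 1.5)
})

test_that("log10 marginals are uniform (Kolmogorov-Smirnov at alpha 0.01)", {
  spec <- lhs_spec(n = 1e4, seed = 1)
  d <- lhs_sample(spec)
  for (nm in c("Kd_LR", "koff_RG", "kE_LRG", "kH_Gt")) {
    lo <- log10(spec$center[[nm]]) - 4
    pval <- stats::ks.test(log10(d[[nm]]), "punif", lo, lo + 8)$p.value
    expect_gt(pval, 0.01)
  }
})

test_that("the manifest round-trips to identical draws", {
  spec <- lhs_spec(n = 30, seed = 21)
  d <- lhs_sample(spec)
  man <- sample_manifest(spec, d)
  expect_identical(length(man$centers), 12L)
  expect_equal(man$centers$Kd_LR, 5.6)
  expect_identical(man$sampled, kinetic_parameter_names())
  # through JSON and back
  f <- tempfile(fileext = ".json")
  jsonlite::write_json(man, f, auto_unbox = TRUE, digits = NA)
  man2 <- jsonlite::read_json(f, simplifyVector = TRUE)
  d2 <- draws_from_manifest(man2)
  expect_equal(as.matrix(d2), as.matrix(d), tolerance = 1e-12)
})

test_that("invalid sample specs are rejected", {
  expect_error(lhs_spec(n = 0), "n")
  expect_error(lhs_spec(span = -2), "span")
  expect_error(lhs_spec(sampled = character()), "non-empty")
  expect_error(lhs_spec(sampled = "nope"), "unknown")
})
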
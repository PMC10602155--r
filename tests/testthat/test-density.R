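test_that("CVC cubes count bead volume correctly", {
  p <- model_params(1.15, 0.12)
  # one bead near the grid centre, rest of the grid empty
  cfg <- as_chain_config(rbind(c(3, 1, 2), c(700, 700, 700)), p)
  cvc <- cvc_distribution(cfg, center = c(0, 0, 0))
  expect_length(cvc$values, 216)
  vbead <- 4 / 3 * pi * 4.9^3 / 120^3
  expect_equal(sum(cvc$values), vbead)      # far bead ignored
  expect_equal(max(cvc$values), vbead, tolerance = 1e-12)
  expect_equal(vbead, 2.85e-4, tolerance = 0.01)
  expect_equal(sum(cvc$counts == 0), 215)
})

test_that("G(r) is zero at the origin and non-decreasing", {
  cfg <- small_relaxed()
  g <- cumulative_pair_correlation(cfg, analysis_radius = 50, r_max = 60)
  expect_true(all(diff(g$values) >= 0))
  expect_gte(g$values[1], 0)
})

test_that("G(r) slope is 3 for uniform density and 2 on a plane", {
  ball <- as_chain_config(make_fixture("uniform_ball", n = 1e5, seed = 61,
                                       R = 300))
  g <- cumulative_pair_correlation(ball, analysis_radius = 150, r_max = 130)
  expect_equal(packing_exponent(g)$exponent, 3, tolerance = 0.05)

  plane <- as_chain_config(make_fixture("plane", n = 3e4, seed = 62, L = 800))
  gp <- cumulative_pair_correlation(plane, analysis_radius = 150, r_max = 130)
  expect_equal(packing_exponent(gp)$exponent, 2, tolerance = 0.05)
})

test_that("packing exponent recovers power-law point clouds", {
  for (D0 in c(2.2, 2.5, 2.8)) {
    pts <- make_fixture("power_law_blob", n = 8e4, seed = round(100 * D0),
                        R = 400, D0 = D0)
    blob <- as_chain_config(rbind(c(0, 0, 0), pts))
    g <- cumulative_pair_correlation(blob, analysis_radius = 1e-6,
                                     r_max = 130, center = c(0, 0, 0))
    # single reference bead at the blob centre sees G ~ r^D0
    expect_equal(packing_exponent(g)$exponent, D0, tolerance = 0.05)
  }
})

test_that("cell-list G(r) equals the brute-force oracle", {
  cfg <- small_relaxed()
  expect_lte(nrow(cfg$coords), 2000)
  a <- cumulative_pair_correlation(cfg, analysis_radius = 60, r_max = 80,
                                   method = "cell")
  b <- cumulative_pair_correlation(cfg, analysis_radius = 60, r_max = 80,
                                   method = "brute")
  expect_identical(a$values, b$values)
})

test_that("local volume fraction counts beads in the analysis sphere", {
  p <- model_params(1.15, 0.12)
  far <- matrix(rep(c(1e4, 0, 0), 5), ncol = 3, byrow = TRUE)
  cfg <- as_chain_config(far, p)
  expect_equal(local_volume_fraction(cfg, center = c(0, 0, 0)), 0)
  inside <- make_fixture("uniform_ball", n = 1000, seed = 63, R = 200)
  cfg2 <- as_chain_config(inside, p)
  expect_equal(local_volume_fraction(cfg2, radius = 240,
                                     center = c(0, 0, 0)),
               1000 * (4.9 / 240)^3)
  expect_equal(1000 * (4.9 / 240)^3, 8.51e-3, tolerance = 0.01)
})

test_that("block averaging of D_i contracts the variance tenfold", {
  expect_equal(resample_di(rep(2.7, 10)), 2.7)
  expect_equal(resample_di(1:10), 5.5)
  expect_error(resample_di(1:5, group = 10))
  expect_length(resample_di(1:25, group = 10), 2)
  set.seed(64)
  di <- rnorm(5e4, mean = 2.7, sd = 0.3)
  ratio <- var(resample_di(di)) / var(di)
  expect_equal(ratio, 0.1, tolerance = 0.02)
})
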
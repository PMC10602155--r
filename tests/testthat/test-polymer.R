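test_that("end-to-end curve reduces to the bond length for two beads", {
  p <- model_params(1.15, 0.12)
  cfg <- as_chain_config(rbind(c(0, 0, 0), c(19, 0, 0)), p)
  ann <- annotate(cfg)
  # single pair at separation 147 + 27 bp = 174 bp
  cv <- end_to_end_curve(cfg, ann, bins = c(150, 200), seed = 1)
  expect_equal(cv$values, 19)
  expect_equal(cv$pair_counts, 1)
})

test_that("an ideal chain shows Flory exponent 1/2", {
  # several chains: single-chain <R^2(s)> estimates at large s have few
  # independent segments, so the ensemble mean is the meaningful curve
  curves <- lapply(1:8, function(s) {
    cfg <- as_chain_config(make_fixture("ideal_chain", n = 2e4,
                                        seed = 40 + s, bond = 10))
    end_to_end_curve(cfg, annotate(cfg), max_pairs = 2e4, seed = 140 + s)
  })
  # bonds of 10 nm carry 1 bp of linker: 148 bp per bead
  fit <- fit_power_law(average_curves(curves), 148 * c(1e1, 1e3))
  expect_equal(fit$exponent, 0.5, tolerance = 0.02 / 0.5)
  expect_gt(fit$r_squared, 0.99)
})

test_that("contacts respect the cutoff threshold", {
  p <- model_params(1.15, 0.12)
  bins <- c(150, 300)
  for (gap in c(30, 36)) {
    cfg <- as_chain_config(rbind(c(0, 0, 0), c(gap, 0, 0)), p)
    ann <- annotate(cfg)
    cp <- contact_probability(cfg, ann, cutoff = 35, bins = bins)
    expect_equal(cp$values, as.numeric(gap < 35))
  }
})

test_that("cell-list contacts equal the O(N^2) enumeration", {
  cfg <- small_relaxed()
  sub <- as_chain_config(cfg$coords[1:500, ], cfg$params)
  ann <- annotate(sub)
  bins <- log_bins(1e2, 1e6, per_decade = 10)
  a <- contact_probability(sub, ann, bins = bins, method = "cell")
  b <- contact_probability(sub, ann, bins = bins, method = "brute")
  expect_identical(a$meta$contact_counts, b$meta$contact_counts)
  expect_equal(a$values, b$values)
})

test_that("contact probability normalises to 1 at infinite cutoff", {
  cfg <- small_relaxed()
  sub <- as_chain_config(cfg$coords[1:300, ], cfg$params)
  ann <- annotate(sub)
  cp <- contact_probability(sub, ann, cutoff = 1e9,
                            bins = log_bins(1e2, 1e6, per_decade = 5))
  pop <- cp$pair_counts > 0
  expect_true(any(pop))
  expect_true(all(cp$values[pop] == 1))
  expect_true(all(cp$values[pop] >= 0 & cp$values[pop] <= 1))
  expect_error(contact_probability(sub, ann, cutoff = -1))
})

test_that("power-law fits recover exact exponents", {
  x <- 10^seq(0, 2, length.out = 30)
  cubic <- new_curve_for_test(x, x^3)
  expect_equal(fit_power_law(cubic, c(1, 100))$exponent, 3, tolerance = 1e-10)
  flat <- new_curve_for_test(x, rep(2.5, 30))
  expect_equal(fit_power_law(flat, c(1, 100))$exponent, 0, tolerance = 1e-10)
  expect_error(fit_power_law(cubic, c(200, 300)), "3 populated")
})

test_that("curve averaging pools mean-squared distances", {
  p <- model_params(1.15, 0.12)
  bins <- c(100, 200)
  cfgs <- list(as_chain_config(rbind(c(0, 0, 0), c(10, 0, 0)), p),
               as_chain_config(rbind(c(0, 0, 0), c(20, 0, 0)), p))
  curves <- lapply(cfgs, function(cf)
    end_to_end_curve(cf, annotate(cf), bins = bins, seed = 1))
  avg <- average_curves(curves)
  expect_equal(avg$values, sqrt(mean(c(10^2, 20^2))))
})
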
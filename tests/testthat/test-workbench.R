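test_that("child seeds are deterministic, distinct and 32-bit safe", {
  s1 <- child_seed(123456789, 3, 7)
  expect_identical(s1, child_seed(123456789, 3, 7))
  expect_lt(s1, 2^31)
  grid <- expand.grid(c = 1:12, r = 1:5)
  seeds <- mapply(child_seed, 42, grid$c, grid$r)
  expect_identical(length(unique(seeds)), nrow(grid))
})

test_that("fixture generators match their ground truths", {
  # lattice: first neighbours at the lattice spacing
  lat <- as_chain_config(make_fixture("lattice", a = 20, m = 8))
  g <- cumulative_pair_correlation(lat, analysis_radius = 30, r_max = 60,
                                   dr = 1, center = c(90, 90, 90))
  expect_equal(g$values[g$bin_centers <= 19], rep(0, 19))
  expect_gt(g$values[g$bin_centers == 21], 0)
  # uniform ball radius: no point outside R
  b <- make_fixture("uniform_ball", n = 5000, seed = 83, R = 120)
  expect_lte(max(sqrt(rowSums(b^2))), 120)
  # ideal chain: fixed bond length
  ch <- make_fixture("ideal_chain", n = 500, seed = 84, bond = 10)
  bl <- sqrt(rowSums(diff(ch)^2))
  expect_equal(bl, rep(10, 499))
  expect_error(make_fixture("nonesuch"))
})

test_that("ensembles run, summarise and re-run idempotently", {
  out <- withr::local_tempdir()
  man <- run_manifest(alphas = c(1.10, 1.20), phis = c(0.16),
                      replicates = 2, master_seed = 5, Rc = 100,
                      outdir = out)
  res <- run_ensemble(man, curves = "gofr")
  expect_identical(nrow(res$summary), 4L)
  expect_identical(length(res$curves), 2L)
  expect_true(all(is.finite(res$summary$D_i)))
  expect_true(all(res$summary$return_fraction > 0.3 &
                  res$summary$return_fraction < 0.6))
  # a second run reuses the completed replicates and reproduces the tables
  res2 <- run_ensemble(man, curves = "gofr")
  expect_equal(res2$summary[order(res2$summary$seed), ],
               res$summary[order(res$summary$seed), ],
               ignore_attr = TRUE)
  # deterministic contract: fresh in-memory run with the same manifest
  man3 <- run_manifest(alphas = c(1.10, 1.20), phis = c(0.16),
                       replicates = 2, master_seed = 5, Rc = 100)
  res3 <- run_ensemble(man3, curves = "gofr")
  expect_equal(res3$summary$D_i, res$summary$D_i)
  expect_equal(res3$summary$mean_linker, res$summary$mean_linker)
})

test_that("failed replicates are recorded without sinking the ensemble", {
  # an impossible relaxation budget fails every replicate
  man <- run_manifest(alphas = 1.15, phis = 0.16, replicates = 1,
                      master_seed = 2, Rc = 100,
                      settings = relaxation_settings(max_sweeps = 1))
  expect_error(run_ensemble(man), "all replicates failed")
})
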
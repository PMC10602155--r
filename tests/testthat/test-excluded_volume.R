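test_that("a star motif expands to a linear 15-bead chain", {
  tr <- star_traj(k = 7)
  cfg <- expand_overlaps(tr, seed = 12)
  expect_identical(nrow(cfg$coords), 15L)
  expect_identical(length(cfg$bond_lengths), 14L)
  # the 8 revisits of the central site no longer coincide
  d <- as.matrix(dist(cfg$coords))
  diag(d) <- Inf
  expect_gt(min(d), 0)
  # perturbations stay within 0.1 r0 of the original site
  ctr_rows <- seq(1, 15, by = 2)
  expect_lt(max(sqrt(rowSums(cfg$coords[ctr_rows, ]^2))), 0.1 * 4.9 + 1e-9)
})

test_that("return-free trajectories expand to the nm-scaled vertices", {
  p <- model_params(1.15, 0.12)
  v <- cbind(seq(0, 5), 0, 0)
  tr <- make_traj(v, rep("jump", 5), p)
  cfg <- expand_overlaps(tr, seed = 1)
  expect_identical(cfg$coords, v * p$b)
  expect_equal(cfg$bond_lengths, rep(10, 5))
})

test_that("a coincident non-bonded pair is pushed to bead contact", {
  p <- model_params(1.15, 0.12)
  # jump out and return: beads 1 and 3 coincide and are non-bonded
  tr <- make_traj(rbind(c(0, 0, 0), c(1.5, 0, 0), c(0, 0, 0)),
                  c("jump", "return"), p)
  cfg <- relax_excluded_volume(expand_overlaps(tr, seed = 3), seed = 4)
  d13 <- sqrt(sum((cfg$coords[1, ] - cfg$coords[3, ])^2))
  expect_gte(d13, 2 * p$r0 * (1 - 1e-3))
})

test_that("relaxed configurations are overlap-free by the O(N^2) oracle", {
  cfg <- small_relaxed()
  expect_lte(nrow(cfg$coords), 2000)
  bmin <- brute_min_nonbonded(cfg$coords)
  cmin <- srev:::.min_nonbonded_cpp(cfg$coords, 2 * cfg$params$r0)$min_dist
  expect_equal(cmin, bmin, tolerance = 1e-12)
  expect_gte(bmin, 9.8 * (1 - 1e-3))
})

test_that("relaxation preserves bead count and drifts the centre < 1 nm", {
  p <- model_params(alpha = 1.12, phi = 0.16, Rc = 100)
  set.seed(91)
  tr <- generate_srrw(p, n_steps = p$n - 1)
  pre <- expand_overlaps(tr)
  post <- relax_excluded_volume(pre, seed = 92)
  expect_identical(nrow(post$coords), nrow(pre$coords))
  expect_identical(length(post$bond_lengths), length(pre$bond_lengths))
  drift <- sqrt(sum((colMeans(post$coords) - colMeans(pre$coords))^2))
  expect_lt(drift, 1)
})

test_that("repulsive energy is non-increasing without noise", {
  p <- model_params(1.15, 0.12)
  tr <- star_traj(k = 6, len = 1.3, params = p)
  pre <- expand_overlaps(tr, seed = 8)
  post <- relax_excluded_volume(
    # noise-free gradient descent: a loose tolerance because the residual
    # overlap at the force balance is only squeezed out by noise/boost
    pre, relaxation_settings(noise_amp = 0, stall_boost = 1, step = 0.05,
                             max_sweeps = 5000, tol = 1e-2),
    record_energy = TRUE)
  e <- post$provenance$relaxation$energy_trace
  expect_gt(length(e), 1)
  expect_true(all(diff(e) <= 1e-9 * max(e)))
})

test_that("relaxation is a near no-op for walks without returns", {
  p <- model_params(1.15, 0.12, Rc = 300)
  set.seed(55)
  n <- 400
  # build an all-jump walk directly: bonded beads are >= 10 nm apart, so
  # only accidental non-bonded spatial encounters could overlap
  len <- sample_jump_length(n, p$alpha, p$Umax)
  dir <- make_fixture("uniform_ball", n = n, seed = 56, R = 1)
  dir <- dir / sqrt(rowSums(dir^2))
  verts <- rbind(c(0, 0, 0), apply(dir * len, 2, cumsum))
  tr <- make_traj(verts, rep("jump", n), p)
  pre <- expand_overlaps(tr)
  if (brute_min_nonbonded(pre$coords) >= 2 * p$r0) {
    post <- relax_excluded_volume(pre)
    expect_lt(max(abs(post$coords - pre$coords)), 1e-9)
  } else succeed("walk had spatial encounters; no-op case not exercised")
})

test_that("verify_configuration reports overlaps with the offending pair", {
  cfg <- small_relaxed()
  rep1 <- verify_configuration(cfg)
  expect_true(rep1$overlap$pass)
  expect_true(rep1$connectivity$pass)
  expect_true(rep1$finite$pass)
  # inject a coincident non-bonded pair
  bad <- cfg
  bad$coords[10, ] <- bad$coords[100, ]
  rep2 <- verify_configuration(bad)
  expect_false(rep2$overlap$pass)
  expect_setequal(rep2$overlap$worst_pair, c(10L, 100L))
  # report min distance agrees with the O(N^2) oracle
  expect_equal(rep2$overlap$min_dist, brute_min_nonbonded(bad$coords),
               tolerance = 1e-12)
})
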
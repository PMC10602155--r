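test_that("return probability follows the closed form", {
  expect_equal(return_probability(1, 1.25), 0.8)
  expect_equal(return_probability(2, 1.1), 2^(-1.1) / 1.1, tolerance = 1e-12)
  # vanishes for long backbone steps
  expect_lt(return_probability(1e6, 1.1), 1e-6)
  # never a valid probability above 1/alpha
  expect_true(all(return_probability(seq(1, 50, by = 0.5), 1.3) <= 1 / 1.3))
  expect_error(return_probability(0.5, 1.2))
  expect_error(return_probability(2, 1.0))
})

test_that("jump lengths follow the heavy-tailed pdf", {
  set.seed(21)
  u <- sample_jump_length(1e5, alpha = 1.15, Umax = Inf)
  expect_true(all(u >= 1))
  # Kolmogorov-Smirnov distance against the analytic CDF 1 - U^-(alpha+1)
  ks <- suppressWarnings(
    stats::ks.test(u, function(q) 1 - q^(-(1.15 + 1))))
  expect_lt(unname(ks$statistic), 0.01)
  # analytic mean (alpha+1)/alpha without cutoff
  set.seed(22)
  m <- mean(sample_jump_length(1e6, alpha = 1.1, Umax = Inf))
  expect_equal(m, (1.1 + 1) / 1.1, tolerance = 0.01)
  # local cutoff respected
  set.seed(23)
  expect_true(all(sample_jump_length(1e4, alpha = 1.1, Umax = 5) <= 5))
})

test_that("trajectories obey the stack and cutoff rules", {
  p <- model_params(alpha = 1.12, phi = 0.12, Rc = 400)
  tr <- generate_srrw(p, n_steps = 5000, seed = 17)
  v <- tr$vertices
  expect_identical(nrow(v), 5001L)
  expect_identical(v[1, ], c(0, 0, 0))
  steps <- diff(v)
  len <- sqrt(rowSums(steps^2))
  jumps <- tr$step_kind == "jump"
  # jump lengths within [1, Umax]
  expect_true(all(len[jumps] >= 1 - 1e-9))
  expect_true(all(len[jumps] <= p$Umax + 1e-9))
  # every return exactly reverses the step on top of the backbone stack
  stack <- list()
  ok <- TRUE
  for (i in seq_len(tr$n_steps)) {
    if (jumps[i]) {
      stack[[length(stack) + 1L]] <- steps[i, ]
    } else {
      top <- stack[[length(stack)]]
      if (max(abs(steps[i, ] + top)) > 1e-9) { ok <- FALSE; break }
      stack[[length(stack)]] <- NULL
    }
  }
  expect_true(ok)
  # the walk grows: fewer returns than jumps
  expect_lt(sum(!jumps), sum(jumps))
  # jump vertices respect the confinement about the running centre of mass
  com <- apply(v, 2, cumsum) / seq_len(nrow(v))
  prop <- v[-1, ] - com[-nrow(v), ]
  d <- sqrt(rowSums(prop^2))
  expect_true(all(d[jumps] <= p$Rc / p$b + 1e-9))
})

test_that("one-step walks are a single forced jump", {
  p <- model_params(alpha = 1.3, phi = 0.12)
  tr <- generate_srrw(p, n_steps = 1, seed = 5)
  expect_identical(tr$step_kind, "jump")
  expect_identical(tr$return_fraction, 0)
})

test_that("trajectories are seed-deterministic and alpha-ordered", {
  p <- model_params(alpha = 1.15, phi = 0.12, Rc = 400)
  a <- generate_srrw(p, n_steps = 2000, seed = 31)
  b <- generate_srrw(p, n_steps = 2000, seed = 31)
  expect_identical(a$vertices, b$vertices)
  expect_identical(a$step_kind, b$step_kind)
  # return fraction strictly decreasing in alpha
  rf <- vapply(c(1.10, 1.15, 1.20), function(al) {
    generate_srrw(model_params(al, 0.12, Rc = 400),
                  n_steps = 2e4, seed = 77)$return_fraction
  }, numeric(1))
  expect_true(all(diff(rf) < 0))
})
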
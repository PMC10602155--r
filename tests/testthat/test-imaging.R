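test_that("voxelization conserves mass and is symmetric", {
  p <- model_params(1.15, 0.12)
  # bead exactly at a voxel centre of a fixed grid
  bead <- c(2.5, 2.5, 2.5)
  cfg <- matrix(bead, 1, 3)
  st <- voxelize(cfg, voxel_edge = 5, sigma = 4.9, pad = 42.5)
  expect_equal(sum(st$data), 1, tolerance = 1e-3)
  # stamp maximum at the containing voxel, symmetric about it
  top <- which(st$data == max(st$data), arr.ind = TRUE)[1, ]
  ctr <- floor((bead - st$origin) / 5) + 1
  expect_equal(unname(top), unname(ctr))
  # many-bead mass conservation to 0.1%
  pts <- make_fixture("uniform_ball", n = 300, seed = 71, R = 100)
  st2 <- voxelize(pts, voxel_edge = 5)
  expect_equal(sum(st2$data), 300, tolerance = 1e-3)
  expect_true(all(st2$data >= 0))
  expect_error(voxelize(pts, voxel_edge = -1))
})

test_that("stamp values match dense numerical quadrature", {
  bead <- c(1.3, -2.1, 0.7)
  st <- voxelize(matrix(bead, 1, 3), voxel_edge = 5, sigma = 4.9, pad = 30)
  # midpoint quadrature of the 3-D Gaussian over two probe voxels
  quad <- function(lo) {
    m <- 40
    g <- function(a, x0) {
      xs <- lo[a] + (seq_len(m) - 0.5) * 5 / m
      sum(exp(-0.5 * ((xs - x0) / 4.9)^2)) * (5 / m) / (4.9 * sqrt(2 * pi))
    }
    g(1, bead[1]) * g(2, bead[2]) * g(3, bead[3])
  }
  for (probe in list(c(1, 1, 1), c(3, 4, 2))) {
    lo <- st$origin + (probe - 1) * 5
    expect_equal(st$data[probe[1], probe[2], probe[3]], quad(lo),
                 tolerance = 1e-6)
  }
})

test_that("domain centres are found at synthetic blob peaks", {
  # two separated Gaussian blobs
  n <- 80
  ax <- seq_len(n) * 5
  mk <- function(c0, amp) {
    d2 <- outer(outer((ax - c0[1])^2, (ax - c0[2])^2, `+`), (ax - c0[3])^2, `+`)
    amp * exp(-d2 / (2 * 25^2))
  }
  arr <- array(mk(c(120, 120, 120), 1) + mk(c(280, 280, 280), 0.8),
               dim = c(n, n, n))
  st <- srev:::new_stack(arr, 5, c(0, 0, 0))
  ctrs <- find_domain_centers(st, smoothing_sigma = 2, min_separation = 50)
  expect_identical(nrow(ctrs), 2L)
  ord <- order(ctrs[, 1])
  expect_lt(max(abs(ctrs[ord[1], ] - 120)), 6)   # within ~1 voxel
  expect_lt(max(abs(ctrs[ord[2], ] - 280)), 6)
  # constant stack has no strict maxima
  flat <- srev:::new_stack(array(1, dim = c(20, 20, 20)), 5, c(0, 0, 0))
  expect_identical(nrow(find_domain_centers(flat, smoothing_sigma = 0)), 0L)
  # blobs closer than min_separation merge to the brighter one
  arr2 <- array(mk(c(150, 200, 200), 1) + mk(c(190, 200, 200), 0.6),
                dim = c(n, n, n))
  st2 <- srev:::new_stack(arr2, 5, c(0, 0, 0))
  ctr2 <- find_domain_centers(st2, smoothing_sigma = 2, min_separation = 80)
  expect_identical(nrow(ctr2), 1L)
  expect_lt(abs(ctr2[1, 1] - 150), 11)
})

test_that("mass scaling recovers uniform and power-law exponents", {
  flat <- srev:::new_stack(array(1, dim = c(61, 61, 61)), 5,
                           rep(-152.5, 3))
  m <- mass_scaling(flat, c(0, 0, 0), window = 3, r_max = 120)
  expect_true(all(diff(m$values) >= 0))
  fit <- fit_power_law(m, c(30, 110))
  expect_equal(fit$exponent, 3, tolerance = 0.02)

  blob <- blob_stack(D0 = 2.5, R = 200, n = 101)
  mb <- mass_scaling(blob, c(0, 0, 0), window = 3, r_max = 120)
  expect_equal(fit_power_law(mb, c(20, 100))$exponent, 2.5,
               tolerance = 0.05)
})

test_that("domain radii stop at the right criterion", {
  # power-law blob of radius 60 nm in near-empty background: the
  # mass curve flattens past 60 nm and the deviation criterion fires
  st <- blob_stack(D0 = 2.5, R = 60, n = 131, edge = 2.5, bg = 1e-6)
  m <- mass_scaling(st, c(0, 0, 0), window = 3, r_max = 150)
  rec <- domain_radius(m, fit_window = c(10, 30))
  expect_false(is.null(rec))
  expect_equal(rec$radius, 60, tolerance = 5 / 60)
  # uniform ball: local slope is already 3 inside the fit window
  flat <- srev:::new_stack(array(1, dim = c(121, 121, 121)), 2.5,
                           rep(-151.25, 3))
  mf <- mass_scaling(flat, c(0, 0, 0), window = 3, r_max = 120)
  rf <- domain_radius(mf, fit_window = c(10, 30))
  expect_identical(rf$criterion, "D=3")
  # denser shell beyond a sparse gap: radial CVC minimum fires in the gap
  sh <- blob_stack(D0 = 2.2, R = 45, n = 131, edge = 2.5, bg = 1e-4,
                   shell = c(90, 120, 1))
  ms <- mass_scaling(sh, c(0, 0, 0), window = 3, r_max = 150)
  rs <- domain_radius(ms, fit_window = c(10, 30), dev_tol = 10)
  expect_identical(rs$criterion, "radial-CVC-minimum")
  expect_gt(rs$radius, 45)
  expect_lt(rs$radius, 95)
})

test_that("domain calling is translation-equivariant on the voxel grid", {
  st <- blob_stack(D0 = 2.5, R = 60, n = 81, bg = 1e-6)
  shift <- c(3L, -2L, 1L)
  arr2 <- array(1e-6, dim = dim(st$data))
  src <- list(1:(81 - 3), 3:81, 1:(81 - 1))
  dst <- list(4:81, 1:79, 2:81)
  arr2[dst[[1]], dst[[2]], dst[[3]]] <- st$data[src[[1]], src[[2]], src[[3]]]
  st2 <- srev:::new_stack(arr2, st$voxel_edge, st$origin)
  c1 <- find_domain_centers(st, smoothing_sigma = 2,
                            prominence = 0.05)
  c2 <- find_domain_centers(st2, smoothing_sigma = 2,
                            prominence = 0.05)
  expect_identical(nrow(c1), nrow(c2))
  expect_equal(c2[1, ] - c1[1, ], shift * st$voxel_edge)
})

test_that("projection and CLAHE preprocessing feed the 2-D pipeline", {
  st <- blob_stack(D0 = 2.5, R = 60, n = 81, bg = 1e-6)
  flat <- project_stack(st)
  expect_identical(dim(flat$data)[3], 1L)
  expect_equal(sum(flat$data), sum(st$data))
  expect_error(find_domain_centers(st, clahe = TRUE), "2-D")
  skip_if_not_installed("EBImage")
  ctr <- find_domain_centers(flat, smoothing_sigma = 2, prominence = 1e-3,
                             clahe = TRUE, clahe_block = 20)
  expect_gte(nrow(ctr), 1)
  # the blob centre projects to the plane centre
  expect_lt(max(abs(ctr[1, 1:2])), 11)
})

test_that("domain statistics summarise radii", {
  one <- data.frame(x = 0, y = 0, z = 0, radius = 55,
                    criterion = "deviation", exponent = 2.5)
  expect_equal(domain_statistics(one)$mean_radius, 55)
  two <- rbind(one, transform(one, radius = 70))
  s <- domain_statistics(two)
  expect_equal(s$mean_radius, 62.5)
  expect_identical(s$n, 2L)
})

test_that("find_domains ties centres, curves and radii together", {
  st <- blob_stack(D0 = 2.5, R = 60, n = 131, edge = 2.5, bg = 1e-6)
  recs <- find_domains(st, smoothing_sigma = 2, prominence = 0.05,
                       window = 3, r_max = 150)
  expect_gte(nrow(recs), 1)
  expect_equal(recs$radius[1], 60, tolerance = 0.15)
})
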
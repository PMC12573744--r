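test_that("a small CC2 grid scan produces converged records", {
  cfg <- scan_config(function(x, y) make_h2_geometry(x),
                     xgrid = c(0.70, 0.74), ygrid = c(0, 1),
                     method = "cc2", n_states = 1L, threshold = 1e-8)
  rec <- run_scan(cfg)
  expect_equal(nrow(rec), 4L)
  expect_true(all(rec$converged))
  expect_true(all(abs(rec$im_omega_1) == 0))
  # 1 x N degenerate grid reduces to a curve scan
  cfg1 <- scan_config(function(x, y) make_h2_geometry(y),
                      xgrid = 0, ygrid = c(0.7, 0.75, 0.8),
                      method = "cc2", n_states = 1L)
  rec1 <- run_scan(cfg1)
  expect_equal(nrow(rec1), 3L)
  expect_true(all(diff(rec1$e0) != 0))
})

test_that("complex-region detection flags conjugate pairs and groups regions", {
  rec <- data.frame(x = rep(1:3, each = 3), y = rep(1:3, 3),
                    e0 = 0, converged = TRUE, zeta = NA_real_,
                    re_omega_1 = 0.3, im_omega_1 = 0,
                    re_omega_2 = 0.31, im_omega_2 = 0)
  out <- detect_complex_region(rec)
  expect_false(any(out$mask))
  expect_equal(out$n_regions, 0L)
  rec$im_omega_1[5] <- 1e-4; rec$im_omega_2[5] <- -1e-4
  out2 <- detect_complex_region(rec)
  expect_equal(sum(out2$mask), 1L)
  expect_equal(out2$n_regions, 1L)
  # two disconnected flagged points -> two regions
  rec$im_omega_1[1] <- 5e-5
  out3 <- detect_complex_region(rec)
  expect_equal(out3$n_regions, 2L)
})

test_that("pattern search recovers the apex of a synthetic cone", {
  gapc <- function(x, y) 0.8 * sqrt((x - 0.3)^2 + (y + 0.2)^2)
  loc <- locate_intersection(gapc, start = c(0, 0), step = 0.1, tol = 1e-8)
  expect_false(loc$complex_collapse)
  expect_lt(abs(loc$point[1] - 0.3), 1e-6)
  expect_lt(abs(loc$point[2] + 0.2), 1e-6)
  expect_lt(loc$gap, 1e-6)
})

test_that("linearity metrics distinguish conical from sublinear lifting", {
  cone <- function(x, y) 0.5 * sqrt(x^2 + y^2)
  lin <- linearity_metric(cone, c(0, 0), radii = seq(0.002, 0.01, length.out = 5))
  expect_true(all(lin$r_squared > 1 - 1e-12))
  expect_true(all(abs(lin$slope - 0.5) < 1e-10))
  sqrtlike <- function(x, y) 0.05 * (x^2 + y^2)^(1 / 4)
  lin2 <- linearity_metric(sqrtlike, c(0, 0), radii = seq(0.002, 0.01, length.out = 5))
  expect_true(all(lin2$r_squared < lin$r_squared))
  expect_error(linearity_metric(cone, c(0, 0), radii = 0.01), "two radii")
})

test_that("gh-plane displacement generators add Cartesian vectors", {
  base <- make_hof_geometry(1.1, 1.33, 90.5)
  gv <- matrix(0, 3, 3); gv[1, 1] <- 1
  hv <- matrix(0, 3, 3); hv[3, 2] <- 1
  fn <- gh_plane_geometry(base, gv, hv)
  g <- fn(0.02, -0.01)
  expect_equal(g$coordinates[1, 1], base$coordinates[1, 1] + 0.02)
  expect_equal(g$coordinates[3, 2], base$coordinates[3, 2] - 0.01)
  expect_identical(fn(0, 0)$coordinates, base$coordinates)
})
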
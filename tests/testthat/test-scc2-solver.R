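test_that("with the orthogonality equation removed the solver reproduces CC2", {
  s <- sys_h4()
  gs <- solve_cc2_ground(s$mo, threshold = 1e-10)
  sol <- solve_scc2(s$mo, select = c(1, 2), threshold = 1e-9, constrain = FALSE)
  expect_identical(sol$zeta, 0)
  expect_equal(sol$energy, gs$energy, tolerance = 1e-10)
  expect_lt(max(abs(sol$t1 - gs$t1)), 1e-8)
})

test_that("an already-orthogonal pair converges with zeta = 0 at CC2 energies", {
  s <- sys_h4()
  gs <- solve_cc2_ground(s$mo, threshold = 1e-10)
  model <- jacobian_model(gs$dressed, gs$t2)
  sts <- solve_right_states(model, 2, method = "dense", spin = "singlet",
                            eta = gs$eta)
  sol <- solve_scc2(s$mo, select = c(1, 2), threshold = 1e-8)
  expect_equal(sol$zeta, 0)
  expect_equal(sol$energy, gs$energy, tolerance = 1e-10)
  expect_equal(sol$omega_A, Re(sts[[1]]$omega), tolerance = 1e-8)
  expect_equal(sol$omega_B, Re(sts[[2]]$omega), tolerance = 1e-8)
})

test_that("the coupled solve near a defect yields real states meeting all residuals", {
  # near-degenerate same-symmetry pair of HOF inside the CC2 defect region
  tube <- hof_tube()
  x <- list(mo = tube$mo)
  sol <- tube$sol
  expect_true(is.numeric(sol$omega_A) && is.numeric(sol$omega_B))
  expect_gt(abs(sol$zeta), 1e-3)                      # constraint active
  expect_lte(sol$orthogonality_residual, 1e-8)
  expect_lte(sol$singles_residual_norm, 1e-8)
  # eigen-residuals of both states against the Jacobian at SCC2 amplitudes
  model <- jacobian_model(sol$dressed, sol$t2)
  for (st in list(sol$state_A, sol$state_B)) {
    app <- jacobian_apply(model, st$r1, st$r2)
    res <- sqrt(sum((app$rho1 - st$omega * st$r1)^2) +
                  sum((app$rho2 - st$omega * st$r2)^2) / 4)
    expect_lt(res, 1e-7)
  }
  # the plain CC2 pair is complex here; SCC2 lifted the defect
  gs <- solve_cc2_ground(x$mo, threshold = 1e-8)
  cc2_sts <- solve_right_states(jacobian_model(gs$dressed, gs$t2), 2,
                                method = "dense", spin = "singlet")
  expect_true(any(abs(Im(sapply(cc2_sts, function(s) s$omega))) > 1e-6))
})

test_that("a symmetry-inert state pair fails fast with a clear diagnostic", {
  g <- make_h4_geometry(1.0, 1.4, skew = 0, top_scale = 1.4)
  x <- mo_for(g)
  expect_error(solve_scc2(x$mo, select = c(1, 2), threshold = 1e-8,
                          max_zeta_iter = 12L),
               "no leverage|not converged|unresponsive")
})

test_that("SCC2 restarts chain across neighboring geometries", {
  tube <- hof_tube()
  sol <- tube$sol
  mo1 <- tube$mo
  maps <- scc2:::so_maps(mo1$n_mo, mo1$n_occ)
  guess <- list(t1 = sol$t1, zeta = sol$zeta,
                refA = scc2:::singlet_extract(sol$state_A$r1, maps),
                refB = scc2:::singlet_extract(sol$state_B$r1, maps),
                omegaA = sol$omega_A, omegaB = sol$omega_B)
  x2 <- mo_for(make_hof_geometry(1.4405, 1.5600, 90.5))
  sol2 <- solve_scc2(x2$mo, threshold = 1e-8, guess = guess)
  expect_lte(sol2$orthogonality_residual, 1e-8)
  expect_lt(abs(sol2$zeta - sol$zeta), 0.1)
  expect_lt(abs(sol2$omega_A - sol$omega_A), 5e-3)
})
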
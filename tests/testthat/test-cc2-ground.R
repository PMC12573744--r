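test_that("t1 = 0 doubles are the canonical MP2 amplitudes and E0 = EHF + EMP2", {
  s <- sys_h2o()
  mo <- s$mo
  d0 <- dress_integrals(mo, matrix(0, mo$n_occ, mo$n_mo - mo$n_occ))
  t2 <- compute_t2(d0)$t2
  expect_lt(max(abs(t2 - aperm(t2, c(2, 1, 4, 3)))), 1e-12)  # pair symmetry
  # closed-form spatial MP2 correlation energy
  occ <- seq_len(mo$n_occ); vir <- (mo$n_occ + 1):mo$n_mo
  eps <- mo$orbital_energies
  emp2 <- 0
  for (i in occ) for (j in occ) for (a in vir) for (b in vir) {
    iajb <- mo$g_mo[i, a, j, b]; ibja <- mo$g_mo[i, b, j, a]
    emp2 <- emp2 + iajb * (2 * iajb - ibja) / (eps[i] + eps[j] - eps[a] - eps[b])
  }
  expect_equal(ground_energy(d0, t2), mo$hf_energy + emp2, tolerance = 1e-10)
  expect_equal(mp2_energy(mo), emp2, tolerance = 1e-10)
})

test_that("degenerate denominators abort with a diagnostic", {
  s <- sys_h2()
  mo <- s$mo
  mo$orbital_energies <- c(0.3, 0.3)   # engineered zero gap
  mo$fock_mo <- diag(mo$orbital_energies)
  d <- dress_integrals(mo, matrix(0, 1, 1))
  expect_error(compute_t2(d), "degenerate occupied/virtual gap")
})

test_that("working-equation residual, energy and eta match the determinant oracle", {
  for (tag in c("h2", "h4")) {
    ctx <- det_context(tag)
    mo <- ctx$mo
    t1 <- random_t1(mo, sd = 0.05, seed = 2)
    dressed <- dress_integrals(mo, t1)
    lab <- ctx$lab
    t2 <- random_r2(lab, sd = 0.05, seed = 4)
    ref <- det_cc2_residuals(ctx, t1, t2)
    expect_lt(max(abs(singles_residual(dressed, t2) - ref$omega1)), 1e-10)
    expect_equal(ground_energy(dressed, t2), ref$energy, tolerance = 1e-10)
    eta <- eta_vector(dressed)
    expect_lt(max(abs(eta$eta1 - ref$eta1)), 1e-10)
    eta2v <- eta$eta2[cbind(lab$doubles$a, lab$doubles$b,
                            lab$doubles$i, lab$doubles$j)]
    expect_lt(max(abs(eta2v - ref$eta2v)), 1e-10)
    # truncated doubles residual: <mu2|H~|HF> + eps * t2
    sov <- scc2:::so_view(dressed)
    eps2v <- scc2:::r2_to_vec(-scc2:::doubles_denominator(sov), lab)
    om2_prod <- scc2:::r2_to_vec(sov$g_vvoo, lab) +
      eps2v * scc2:::r2_to_vec(t2, lab)
    expect_lt(max(abs(om2_prod - (ref$omega2_Ht + eps2v * scc2:::r2_to_vec(t2, lab)))),
              1e-10)
  }
})

test_that("the folded ground-state solve agrees with the determinant-space solve", {
  for (tag in c("h2", "h4")) {
    ctx <- det_context(tag)
    gs <- solve_cc2_ground(ctx$mo, threshold = 1e-10)
    det <- det_solve_cc2(ctx$mo, ctx$basis, ctx$lab, threshold = 1e-10)
    expect_equal(gs$energy, det$energy, tolerance = 1e-9)
  }
})

test_that("folded and simultaneous amplitude iterations reach the same point", {
  s <- sys_h4()
  mo <- s$mo
  gs <- solve_cc2_ground(mo, threshold = 1e-10)
  # simultaneous quasi-Newton on (t1, t2) without folding
  o <- mo$n_occ; v <- mo$n_mo - o
  lab <- labels_for(mo)
  eps <- mo$orbital_energies
  D1 <- outer(eps[seq_len(o)], eps[o + seq_len(v)], "-")
  t1 <- matrix(0, o, v)
  d0 <- dress_integrals(mo, t1)
  t2 <- array(0, dim(compute_t2(d0)$t2))
  st <- scc2:::diis_new(8)
  for (it in 1:200) {
    dressed <- dress_integrals(mo, t1)
    sov <- scc2:::so_view(dressed)
    D2 <- scc2:::doubles_denominator(sov)
    om2 <- sov$g_vvoo - D2 * t2
    om1_so <- singles_residual(dressed, t2)
    om1 <- scc2:::so_collapse_singles(om1_so, sov$maps)
    res <- sqrt(sum(om1_so^2) + sum(om2^2) / 4)
    if (res < 1e-10) break
    par <- c(as.numeric(t1 + om1 / D1), as.numeric(t2 + om2 / D2))
    par <- scc2:::diis_update(st, par, c(as.numeric(om1), as.numeric(om2) / 2))
    t1 <- matrix(par[seq_len(o * v)], o, v)
    t2 <- array(par[-seq_len(o * v)], dim(t2))
  }
  expect_lt(res, 1e-10)
  expect_equal(t1, gs$t1, tolerance = 1e-9)
  expect_lt(max(abs(t2 - gs$t2)), 1e-8)
})

test_that("restarting from a converged solution takes one iteration", {
  s <- sys_h4()
  gs <- solve_cc2_ground(s$mo, threshold = 1e-9)
  gs2 <- solve_cc2_ground(s$mo, threshold = 1e-9, t1_init = gs$t1)
  expect_equal(gs2$iterations, 1L)
  expect_equal(gs2$energy, gs$energy, tolerance = 1e-12)
})

test_that("CC2 energy is size-extensive over noninteracting fragments", {
  gA <- make_h2_geometry(0.74)
  eA <- solve_cc2_ground(mo_for(gA)$mo, threshold = 1e-10)$energy
  gAB <- combine_geometries(gA, gA, offset = c(0, 0, 100))
  eAB <- solve_cc2_ground(mo_for(gAB)$mo, threshold = 1e-10)$energy
  expect_lt(abs(eAB - 2 * eA), 1e-8)
})
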
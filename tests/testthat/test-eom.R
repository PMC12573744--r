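test_that("dense Jacobian columns equal the operator action on unit vectors", {
  s <- sys_h2()
  gs <- solve_cc2_ground(s$mo, threshold = 1e-9)
  model <- jacobian_model(gs$dressed, gs$t2)
  A <- build_dense_jacobian(model)
  lb <- model$labels
  set.seed(9)
  for (k in sample(ncol(A), min(4L, ncol(A)))) {
    x <- replace(numeric(ncol(A)), k, 1)
    r1 <- scc2:::vec_to_r1(x[seq_len(lb$n1)], lb)
    r2 <- scc2:::vec_to_r2(x[lb$n1 + seq_len(lb$n2)], lb)
    rho <- jacobian_apply(model, r1, r2)
    expect_equal(A[, k], c(scc2:::r1_to_vec(rho$rho1, lb),
                           scc2:::r2_to_vec(rho$rho2, lb)), tolerance = 1e-13)
  }
  # real matrix: spectrum closed under conjugation
  ev <- eigen(A, only.values = TRUE)$values
  for (lam in ev[abs(Im(ev)) > 1e-10])
    expect_true(min(abs(ev - Conj(lam))) < 1e-9)
})

test_that("Jacobian action matches the determinant-space Jacobian", {
  for (tag in c("h2", "h4")) {
    ctx <- det_context(tag)
    mo <- ctx$mo
    t1 <- random_t1(mo, sd = 0.05, seed = 6)
    dressed <- dress_integrals(mo, t1)
    t2 <- compute_t2(dressed)$t2
    model <- jacobian_model(dressed, t2)
    A <- build_dense_jacobian(model)
    maps <- scc2:::so_maps(mo$n_mo, mo$n_occ)
    t1so <- scc2:::so_expand_singles(t1, maps)
    T1m <- scc2:::det_r1_matrix(ctx$basis, mo$n_occ, t1so)
    Ht <- det_similarity_transform(ctx$H, T1m)
    T2m <- scc2:::det_r2_matrix(ctx$basis, mo$n_occ, t2)
    eps2v <- scc2:::r2_to_vec(model$eps2, ctx$lab)
    Aorc <- det_cc2_jacobian(Ht, T2m, ctx$basis, mo$n_occ, ctx$lab, eps2v)
    expect_lt(max(abs(A - Aorc)), 1e-10)
  }
})

test_that("Fock-only limit reduces to orbital-energy differences", {
  # fluctuation potential artificially zeroed: diagonal h, no two-electron part
  n <- 4; nocc <- 2L
  eps <- c(-1.2, -0.7, 0.4, 0.9)
  ao <- ao_integral_set(diag(n), diag(eps), array(0, rep(n, 4)), 0, 4L)
  ref <- list(mo_coefficients = diag(n), orbital_energies = eps,
              n_occ = nocc, hf_energy = 2 * sum(eps[1:2]))
  mo <- transform_mo_integrals(ao, ref)
  d0 <- dress_integrals(mo, matrix(0, nocc, n - nocc))
  t2 <- compute_t2(d0)$t2
  expect_identical(max(abs(t2)), 0)
  eta <- eta_vector(d0)
  expect_identical(max(abs(eta$eta1)), 0)
  expect_identical(max(abs(eta$eta2)), 0)
  model <- jacobian_model(d0, t2)
  A <- build_dense_jacobian(model)
  expect_lt(max(abs(A - t(A))), 1e-12)  # symmetric in the Fock-only limit
  ev <- sort(Re(eigen(A, only.values = TRUE)$values))
  diffs <- sort(c(outer(eps[3:4], eps[1:2], "-")))
  expect_equal(min(ev), min(diffs), tolerance = 1e-10)
})

test_that("transpose action satisfies the adjoint identity", {
  s <- sys_h4()
  gs <- solve_cc2_ground(s$mo, threshold = 1e-9)
  model <- jacobian_model(gs$dressed, gs$t2)
  lab <- model$labels
  for (k in 1:20) {
    u <- random_state(lab, seed = 100 + k)
    w <- random_state(lab, seed = 200 + k)
    rho <- jacobian_apply(model, w$r1, w$r2)
    tr <- jacobian_apply_transpose(model, u$r1, u$r2)
    lhs <- scc2:::dot_state(u$r1, u$r2, rho$rho1, rho$rho2)
    rhs <- scc2:::dot_state(tr$sigma1, tr$sigma2, w$r1, w$r2)
    expect_equal(lhs, rhs, tolerance = 1e-10)
  }
})

test_that("folded eigenpairs unfold to eigenvectors of the full Jacobian", {
  s <- sys_h2o()
  gs <- solve_cc2_ground(s$mo, threshold = 1e-9)
  model <- jacobian_model(gs$dressed, gs$t2)
  sts <- solve_right_states(model, 2, method = "davidson", eta = gs$eta,
                            threshold = 1e-10)
  for (st in sts) {
    rho <- jacobian_apply(model, st$r1, st$r2)
    res <- sqrt(sum((rho$rho1 - st$omega * st$r1)^2) +
                  sum((rho$rho2 - st$omega * st$r2)^2) / 4)
    expect_lt(res, 1e-8)
  }
})

test_that("Davidson and dense eigensolvers agree on water", {
  s <- sys_h2o()
  gs <- solve_cc2_ground(s$mo, threshold = 1e-10)
  model <- jacobian_model(gs$dressed, gs$t2)
  den <- solve_right_states(model, 3, method = "dense", spin = "singlet",
                            eta = gs$eta)
  dav <- solve_right_states(model, 3, method = "davidson", eta = gs$eta,
                            threshold = 1e-10)
  for (k in 1:3)
    expect_equal(dav[[k]]$omega, Re(den[[k]]$omega), tolerance = 1e-8)
})

test_that("left states are biorthonormal to the right states with l0 = 0", {
  s <- sys_h2o()
  gs <- solve_cc2_ground(s$mo, threshold = 1e-9)
  model <- jacobian_model(gs$dressed, gs$t2)
  rights <- solve_right_states(model, 3, method = "dense", spin = "singlet",
                               eta = gs$eta)
  lefts <- solve_left_states(model, rights)
  for (k in seq_along(lefts)) {
    expect_identical(lefts[[k]]$r0, 0)
    for (l in seq_along(rights)) {
      ov <- sum(lefts[[k]]$r1 * rights[[l]]$r1) +
        0.25 * sum(lefts[[k]]$r2 * rights[[l]]$r2)
      expect_equal(ov, as.numeric(k == l), tolerance = 1e-8)
    }
  }
})

test_that("ground-state contributions behave as eta'r/omega", {
  s <- sys_h2()
  gs <- solve_cc2_ground(s$mo, threshold = 1e-10)
  model <- jacobian_model(gs$dressed, gs$t2)
  st <- solve_right_states(model, 1, method = "dense", spin = "singlet",
                           eta = gs$eta)[[1]]
  # linearity in r
  r0a <- ground_contribution(gs$eta, st$r1, st$r2, Re(st$omega))
  r0b <- ground_contribution(gs$eta, 3 * st$r1, 3 * st$r2, Re(st$omega))
  expect_equal(r0b, 3 * r0a, tolerance = 1e-12)
  expect_error(ground_contribution(gs$eta, st$r1, st$r2, 0), "omega too small")
  # orthogonal eta: r0 = 0
  eta0 <- list(eta1 = matrix(0, nrow(st$r1), ncol(st$r1)),
               eta2 = array(0, dim(st$r2)))
  expect_identical(ground_contribution(eta0, st$r1, st$r2, 0.5), 0)
  # assembled (r0, r) is an eigenvector of the full Hbar matrix including
  # the reference row/column
  ctx <- det_context("h2")
  mo <- ctx$mo
  maps <- scc2:::so_maps(mo$n_mo, mo$n_occ)
  t1so <- scc2:::so_expand_singles(gs$t1, maps)
  Smat <- det_cluster_matrix(ctx$basis, mo$n_occ, t1so, gs$t2)
  lm <- scc2:::oracle_label_map(ctx$basis, mo$n_occ, ctx$lab)
  # truncated-model Hbar over {ref, singles, doubles}: E0 and eta in the
  # reference row, the CC2 Jacobian plus E0*I in the excited block
  T1m <- scc2:::det_r1_matrix(ctx$basis, mo$n_occ, t1so)
  Ht <- det_similarity_transform(ctx$H, T1m)
  T2m <- scc2:::det_r2_matrix(ctx$basis, mo$n_occ, gs$t2)
  eps2v <- scc2:::r2_to_vec(-scc2:::doubles_denominator(scc2:::so_view(gs$dressed)),
                            ctx$lab)
  A <- det_cc2_jacobian(Ht, T2m, ctx$basis, mo$n_occ, ctx$lab, eps2v)
  etav <- c(scc2:::r1_to_vec(gs$eta$eta1, ctx$lab),
            gs$eta$eta2[cbind(ctx$lab$doubles$a, ctx$lab$doubles$b,
                              ctx$lab$doubles$i, ctx$lab$doubles$j)])
  N <- 1 + nrow(A)
  Hbar <- rbind(c(gs$energy, etav),
                cbind(0, A + gs$energy * diag(nrow(A))))
  vec <- c(st$r0, scc2:::r1_to_vec(st$r1, ctx$lab),
           scc2:::r2_to_vec(st$r2, ctx$lab))
  resid <- Hbar %*% vec - (gs$energy + Re(st$omega)) * vec
  expect_lt(max(abs(resid)), 1e-9)
})

test_that("eigenvalues are invariant under the r-normalization convention", {
  s <- sys_h4()
  gs <- solve_cc2_ground(s$mo, threshold = 1e-9)
  model <- jacobian_model(gs$dressed, gs$t2)
  st <- solve_right_states(model, 1, method = "dense", spin = "singlet")[[1]]
  # rescaled vector still an eigenvector with the same eigenvalue
  rho <- jacobian_apply(model, 2.5 * st$r1, 2.5 * st$r2)
  expect_lt(max(abs(rho$rho1 - Re(st$omega) * 2.5 * st$r1)), 1e-7)
})
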
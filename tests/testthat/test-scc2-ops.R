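test_that("X3 is antisymmetric in the two states and vanishes when they coincide", {
  s <- sys_h4()
  gs <- solve_cc2_ground(s$mo, threshold = 1e-9)
  lab <- labels_for(s$mo)
  A <- random_state(lab, seed = 31)
  B <- random_state(lab, seed = 32)
  dOm_AB <- scc_singles_correction(gs$dressed, build_x3(A, B), 0.2)
  dOm_BA <- scc_singles_correction(gs$dressed, build_x3(B, A), 0.2)
  expect_lt(max(abs(dOm_AB + dOm_BA)), 1e-13)
  dOm_AA <- scc_singles_correction(gs$dressed, build_x3(A, A), 0.2)
  expect_identical(max(abs(dOm_AA)), 0)
  expect_identical(max(abs(scc_singles_correction(gs$dressed, build_x3(A, B), 0))), 0)
})

test_that("X3 amplitudes materialized in determinant space match the bilinear formula", {
  ctx <- det_context("h4")
  mo <- ctx$mo
  lab <- ctx$lab
  A <- random_state(lab, seed = 41)
  B <- random_state(lab, seed = 42)
  x3 <- build_x3(A, B)
  X3m <- det_cluster_matrix(ctx$basis, mo$n_occ, zeta = 1, x3 = x3)
  # pick a few (mu1, mu2) label pairs, build tau_mu1 tau_mu2 |HF> and compare
  # the coefficient against r^A_mu1 r^B_mu2 - r^B_mu1 r^A_mu2 summed over
  # all label pairs producing that determinant
  e0 <- numeric(length(ctx$basis$masks)); e0[1] <- 1
  v <- X3m %*% e0
  # reconstruct independently by looping over label pairs
  vref <- numeric(length(v))
  for (k1 in seq_len(lab$n1)) {
    cfA <- scc2:::r1_to_vec(A$r1, lab)[k1]
    cfB <- scc2:::r1_to_vec(B$r1, lab)[k1]
    w1 <- scc2:::tau_apply_vec(ctx$basis, mo$n_occ, lab, "s", k1, e0)
    for (k2 in seq_len(lab$n2)) {
      xa <- cfA * scc2:::r2_to_vec(A$r2, lab)[k2]
      xb <- cfB * scc2:::r2_to_vec(B$r2, lab)[k2]
      cf <- cfA * scc2:::r2_to_vec(B$r2, lab)[k2] -
        cfB * scc2:::r2_to_vec(A$r2, lab)[k2]
      if (abs(cf) < 1e-14) next
      vref <- vref + cf * scc2:::tau_apply_vec(ctx$basis, mo$n_occ, lab, "d", k2, w1)
    }
  }
  expect_lt(max(abs(v - vref)), 1e-12)
})

test_that("similarity-constraint correction matches the determinant oracle", {
  ctx <- det_context("h4")
  mo <- ctx$mo
  lab <- ctx$lab
  t1 <- random_t1(mo, sd = 0.05, seed = 51)
  dressed <- dress_integrals(mo, t1)
  t2 <- compute_t2(dressed)$t2
  A <- random_state(lab, seed = 52)
  B <- random_state(lab, seed = 53)
  zeta <- 0.1
  dOm <- scc_singles_correction(dressed, build_x3(A, B), zeta)
  maps <- scc2:::so_maps(mo$n_mo, mo$n_occ)
  t1so <- scc2:::so_expand_singles(t1, maps)
  Smat <- det_cluster_matrix(ctx$basis, mo$n_occ, t1so, t2, zeta, build_x3(A, B))
  Tmat <- det_cluster_matrix(ctx$basis, mo$n_occ, t1so, t2)
  HS <- det_similarity_transform(ctx$H, Smat)
  HT <- det_similarity_transform(ctx$H, Tmat)
  prS <- det_projections(HS, ctx$basis, mo$n_occ, lab)
  prT <- det_projections(HT, ctx$basis, mo$n_occ, lab)
  expect_lt(max(abs(dOm - (prS$omega1 - prT$omega1))), 1e-10)
})

test_that("q and Q reproduce exp(S)|HF> and <mu|exp(S)|nu> in determinant space", {
  ctx <- det_context("h4")
  mo <- ctx$mo
  lab <- ctx$lab
  t1 <- random_t1(mo, sd = 0.07, seed = 61)
  maps <- scc2:::so_maps(mo$n_mo, mo$n_occ)
  t1so <- scc2:::so_expand_singles(t1, maps)
  dressed <- dress_integrals(mo, t1)
  t2 <- compute_t2(dressed)$t2
  Smat <- det_cluster_matrix(ctx$basis, mo$n_occ, t1so, t2)
  eS <- scc2:::matexp_nilpotent(Smat)
  lm <- scc2:::oracle_label_map(ctx$basis, mo$n_occ, lab)
  e0 <- numeric(length(ctx$basis$masks)); e0[lm$ref] <- 1
  vq <- eS %*% e0
  q <- overlap_q(t1so, t2)
  expect_lt(max(abs(scc2:::r1_to_vec(q$q1, lab) - lm$s_ph * vq[lm$s_idx])), 1e-10)
  expect_lt(max(abs(scc2:::r2_to_vec(q$q2, lab) - lm$d_ph * vq[lm$d_idx])), 1e-10)
  # all amplitudes zero -> q = 0
  q0 <- overlap_q(0 * t1so, 0 * t2)
  expect_identical(max(abs(q0$q1)), 0)
  expect_identical(max(abs(q0$q2)), 0)
  # t2 = 0: doubles part is the symmetrized t1 (x) t1 contribution only
  q1only <- overlap_q(t1so, 0 * t2)
  tt <- scc2:::tc(t(t1so), t(t1so), integer(0), integer(0))
  tt <- aperm(tt, c(1, 3, 2, 4))
  expect_lt(max(abs(q1only$q2 - (tt - aperm(tt, c(1, 2, 4, 3))))), 1e-13)
  # Q action on unit vectors matches columns of <mu|exp(S)|nu>, and is linear
  v <- random_state(lab, seed = 62)
  Qv <- overlap_Q_apply(t1so, v$r1, v$r2)
  vec_full <- numeric(length(e0))
  vec_full[lm$s_idx] <- lm$s_ph * scc2:::r1_to_vec(v$r1, lab)
  vec_full[lm$d_idx] <- vec_full[lm$d_idx] + lm$d_ph * scc2:::r2_to_vec(v$r2, lab)
  w <- eS %*% vec_full
  expect_lt(max(abs(scc2:::r1_to_vec(Qv$w1, lab) - lm$s_ph * w[lm$s_idx])), 1e-10)
  expect_lt(max(abs(scc2:::r2_to_vec(Qv$w2, lab) - lm$d_ph * w[lm$d_idx])), 1e-10)
  u <- random_state(lab, seed = 63)
  Qu <- overlap_Q_apply(t1so, u$r1, u$r2)
  Qlin <- overlap_Q_apply(t1so, 2 * v$r1 - u$r1, 2 * v$r2 - u$r2)
  expect_lt(max(abs(Qlin$w2 - (2 * Qv$w2 - Qu$w2))), 1e-12)
})

test_that("the spin-adapted configuration Gram matches determinant expansion", {
  ctx <- det_context("h4")
  mo <- ctx$mo
  nocc <- mo$n_occ; nvir <- mo$n_mo - nocc
  S <- configuration_overlap_matrix(nocc, nvir, basis = "spin-adapted")
  labs <- attr(S, "labels")
  ev <- eigen((S + t(S)) / 2, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-12)  # positive semidefinite
  # determinant expansion of E_ai E_bj |HF>
  nb <- length(ctx$basis$masks)
  E_op <- function(a, i) {
    # singlet excitation operator as a determinant-space matrix
    pa <- scc2:::prod_so_index(mo$n_mo, nocc, "vir", a)
    pb <- scc2:::prod_so_index(mo$n_mo, nocc, "vir", a + nvir)
    qa <- scc2:::prod_so_index(mo$n_mo, nocc, "occ", i)
    qb <- scc2:::prod_so_index(mo$n_mo, nocc, "occ", i + nocc)
    scc2:::op_matrix_pq(ctx$basis, pa, qa) + scc2:::op_matrix_pq(ctx$basis, pb, qb)
  }
  e0 <- numeric(nb); e0[1] <- 1
  dec <- function(p) c((p - 1L) %/% nvir + 1L, (p - 1L) %% nvir + 1L) # (i, a)
  ns <- nrow(labs$singles)
  set.seed(71)
  pick <- sample(nrow(labs$pairs), 6)
  for (x in pick) for (y in pick) {
    px <- dec(labs$pairs$p[x]); qx <- dec(labs$pairs$q[x])
    py <- dec(labs$pairs$p[y]); qy <- dec(labs$pairs$q[y])
    vx <- E_op(px[2], px[1]) %*% (E_op(qx[2], qx[1]) %*% e0)
    vy <- E_op(py[2], py[1]) %*% (E_op(qy[2], qy[1]) %*% e0)
    expect_equal(S[ns + x, ns + y], sum(vx * vy), tolerance = 1e-12)
  }
  # singles block and determinant-basis mode
  expect_equal(unname(diag(S)[1]), 2)
  expect_identical(configuration_overlap_matrix(basis = "determinant",
                                                n_labels = 5L), diag(5))
})

test_that("the orthogonality value reproduces <RA|P|RB> in determinant space", {
  ctx <- det_context("h4")
  mo <- ctx$mo
  lab <- ctx$lab
  t1 <- random_t1(mo, sd = 0.06, seed = 81)
  maps <- scc2:::so_maps(mo$n_mo, mo$n_occ)
  t1so <- scc2:::so_expand_singles(t1, maps)
  dressed <- dress_integrals(mo, t1)
  t2 <- compute_t2(dressed)$t2
  A <- random_state(lab, seed = 82)
  B <- random_state(lab, seed = 83)
  Smat <- det_cluster_matrix(ctx$basis, mo$n_occ, t1so, t2)
  O_prod <- orthogonality_value(t1so, t2, A, B)
  O_det <- det_overlap_value(ctx$basis, mo$n_occ, Smat, A, B)
  expect_equal(O_prod, O_det, tolerance = 1e-10)
  # with no cluster operator the overlap collapses to the plain projected
  # inner product, and O(A, A) is a norm under the projector
  O_plain <- orthogonality_value(0 * t1so, 0 * t2, A, B)
  expect_equal(O_plain,
               A$r0 * B$r0 + sum(A$r1 * B$r1) + 0.25 * sum(A$r2 * B$r2),
               tolerance = 1e-12)
  expect_gte(orthogonality_value(t1so, t2, A, A), 0)
})

test_that("the constraint correction is invariant under compensating rescalings", {
  s <- sys_h4()
  gs <- solve_cc2_ground(s$mo, threshold = 1e-9)
  lab <- labels_for(s$mo)
  A <- random_state(lab, seed = 91)
  B <- random_state(lab, seed = 92)
  cscale <- 2.7
  As <- list(r1 = cscale * A$r1, r2 = cscale * A$r2)
  Bs <- list(r1 = B$r1 / cscale, r2 = B$r2 / cscale)
  d1 <- scc_singles_correction(gs$dressed, build_x3(A, B), 0.37)
  d2 <- scc_singles_correction(gs$dressed, build_x3(As, Bs), 0.37)
  expect_lt(max(abs(d1 - d2)), 1e-12)
})
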
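test_that("AO integrals satisfy their structural invariants", {
  s <- sys_h2o()
  ao <- s$ao
  eri <- ao$eri
  expect_lt(max(abs(ao$overlap - t(ao$overlap))), 1e-12)
  expect_gt(min(eigen(ao$overlap, symmetric = TRUE, only.values = TRUE)$values), 0)
  # 8-fold permutational symmetry, spot-checked over random index quads
  set.seed(7)
  for (k in 1:50) {
    ix <- sample(ao$n_ao, 4, replace = TRUE)
    p <- ix[1]; q <- ix[2]; r <- ix[3]; sdx <- ix[4]
    v <- eri[p, q, r, sdx]
    expect_equal(eri[q, p, r, sdx], v, tolerance = 1e-12)
    expect_equal(eri[p, q, sdx, r], v, tolerance = 1e-12)
    expect_equal(eri[r, sdx, p, q], v, tolerance = 1e-12)
  }
})

test_that("nuclear repulsion is the point-charge Coulomb sum", {
  g <- geometry(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, 100)))
  ao <- compute_ao_integrals(g, "sto-3g")
  expect_equal(ao$nuclear_repulsion, 1 / (100 / 0.52917721092), tolerance = 1e-12)
})

test_that("a single normalized function gives a 1x1 identity overlap", {
  ao <- compute_ao_integrals(geometry("He", matrix(0, 1, 3)), "sto-3g")
  expect_equal(ao$overlap, matrix(1, 1, 1), tolerance = 1e-12)
})

test_that("RHF solves the one-orbital closed forms and stays orthonormal", {
  ao <- compute_ao_integrals(geometry("He", matrix(0, 1, 3)), "sto-3g")
  ref <- solve_rhf(ao)
  expect_equal(ref$hf_energy,
               2 * ao$core_hamiltonian[1, 1] + ao$eri[1, 1, 1, 1],
               tolerance = 1e-12)

  s <- sys_h2o()
  C <- s$ref$mo_coefficients
  expect_lt(max(abs(t(C) %*% s$ao$overlap %*% C - diag(ncol(C)))), 1e-8)
  expect_false(is.unsorted(s$ref$orbital_energies))
})

test_that("RHF matches an independently coded Roothaan SCF on water", {
  s <- sys_h2o()
  ao <- s$ao
  n <- ao$n_ao; nocc <- ao$n_electrons %/% 2L
  se <- eigen(ao$overlap, symmetric = TRUE)
  X <- se$vectors %*% diag(1 / sqrt(se$values)) %*% t(se$vectors)
  C <- X  # core guess happens after first Fock build below
  D <- matrix(0, n, n)
  E_old <- 0; E <- NA
  for (it in 1:300) {
    Fm <- ao$core_hamiltonian
    for (p in 1:n) for (q in 1:n)
      Fm[p, q] <- Fm[p, q] + sum((2 * ao$eri[p, q, , ] -
                                    ao$eri[p, , , q]) * D)
    E <- sum(D * (ao$core_hamiltonian + Fm)) + ao$nuclear_repulsion
    ev <- eigen(t(X) %*% Fm %*% X, symmetric = TRUE)
    ord <- order(ev$values)
    C <- X %*% ev$vectors[, ord]
    D <- C[, 1:nocc] %*% t(C[, 1:nocc])
    if (abs(E - E_old) < 1e-12 && it > 2) break
    E_old <- E
  }
  expect_equal(s$ref$hf_energy, E, tolerance = 1e-8)
})

test_that("MO transformation matches the brute-force four-index loop (H2)", {
  s <- sys_h2()
  C <- s$ref$mo_coefficients
  n <- 2
  g_ref <- array(0, rep(n, 4))
  for (p in 1:n) for (q in 1:n) for (r in 1:n) for (ss in 1:n) {
    acc <- 0
    for (a in 1:n) for (b in 1:n) for (cc in 1:n) for (d in 1:n)
      acc <- acc + C[a, p] * C[b, q] * C[cc, r] * C[d, ss] * s$ao$eri[a, b, cc, d]
    g_ref[p, q, r, ss] <- acc
  }
  expect_lt(max(abs(s$mo$g_mo - g_ref)), 1e-12)
})

test_that("identity coefficients leave an orthonormal toy basis unchanged", {
  set.seed(11)
  n <- 3
  h <- crossprod(matrix(rnorm(n * n), n))
  eri <- array(rnorm(n^4, sd = 0.1), rep(n, 4))
  # impose the 8-fold symmetry
  eri <- (eri + aperm(eri, c(2, 1, 3, 4)) + aperm(eri, c(1, 2, 4, 3)) +
            aperm(eri, c(2, 1, 4, 3)) + aperm(eri, c(3, 4, 1, 2)) +
            aperm(eri, c(4, 3, 1, 2)) + aperm(eri, c(3, 4, 2, 1)) +
            aperm(eri, c(4, 3, 2, 1))) / 8
  ao <- ao_integral_set(diag(n), h, eri, 0, 2L)
  ref <- list(mo_coefficients = diag(n), orbital_energies = 1:3, n_occ = 1L,
              hf_energy = 0)
  mo <- transform_mo_integrals(ao, ref)
  expect_equal(mo$g_mo, eri, tolerance = 1e-13)
  expect_equal(mo$h_mo, h, tolerance = 1e-13)
})

test_that("MO Fock matrix is diagonal at the canonical orbitals", {
  s <- sys_h2o()
  f <- s$mo$fock_mo
  expect_lt(max(abs(f - diag(diag(f)))), 1e-7)
  expect_equal(diag(f), s$ref$orbital_energies, tolerance = 1e-7)
})

test_that("energies are invariant under rigid rotation and translation", {
  g <- make_hof_geometry(1.1, 1.33, 90.5)
  th <- 0.61
  R <- rbind(c(1, 0, 0), c(0, cos(th), -sin(th)), c(0, sin(th), cos(th)))
  g2 <- transform_geometry(g, R, c(0.3, -1.2, 2.0))
  e1 <- local({ x <- mo_for(g); solve_cc2_ground(x$mo, threshold = 1e-9)$energy })
  e2 <- local({ x <- mo_for(g2); solve_cc2_ground(x$mo, threshold = 1e-9)$energy })
  expect_equal(e1, e2, tolerance = 1e-9)
})

test_that("unknown basis/element combinations are rejected cleanly", {
  expect_error(compute_ao_integrals(make_h2_geometry(), "cc-pvdz"), "not bundled")
  g <- geometry(c("F", "H"), rbind(c(0, 0, 0), c(0, 0, 0.9)))
  expect_error(compute_ao_integrals(g, "6-31g"), "not available for element")
})
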
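# Shared fixture systems, computed once per test session and cached.
# Everything is generated in code; geometries are the package's own
# constructors at fixed parameters.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- builder()
  .fixture_cache[[name]]
}

mo_for <- function(geom, basis = "sto-3g") {
  ao <- compute_ao_integrals(geom, basis)
  ref <- solve_rhf(ao)
  list(ao = ao, ref = ref, mo = transform_mo_integrals(ao, ref))
}

sys_h2 <- function() fixture("h2", function() mo_for(make_h2_geometry(0.74)))

sys_h4 <- function() fixture("h4", function() {
  mo_for(make_h4_geometry(1.0, 1.2, skew = 0.1))
})

sys_h2o <- function() fixture("h2o", function() {
  g <- read_xyz(paste("3", "water",
                      "O 0.0 0.0 0.1173",
                      "H 0.0 0.7572 -0.4692",
                      "H 0.0 -0.7572 -0.4692", sep = "\n"))
  mo_for(g)
})

# determinant bases (cached; H2O has 441 determinants)
basis_for <- function(tag) {
  fixture(paste0("basis_", tag), function() {
    mo <- switch(tag, h2 = sys_h2()$mo, h4 = sys_h4()$mo, h2o = sys_h2o()$mo)
    det_basis(mo$n_mo, mo$n_occ, mo$n_occ)
  })
}

labels_for <- function(mo) scc2:::sz_labels(scc2:::so_maps(mo$n_mo, mo$n_occ))

# random Sz = 0 amplitudes / states in production storage
random_t1 <- function(mo, sd = 0.05, seed = 1) {
  set.seed(seed)
  matrix(rnorm(mo$n_occ * (mo$n_mo - mo$n_occ), sd = sd), mo$n_occ)
}

random_r2 <- function(lab, sd = 0.1, seed = 1) {
  set.seed(seed)
  scc2:::vec_to_r2(rnorm(lab$n2, sd = sd), lab)
}

random_state <- function(lab, seed = 1) {
  set.seed(seed)
  r1 <- scc2:::vec_to_r1(rnorm(lab$n1, sd = 0.3), lab)
  r2 <- scc2:::vec_to_r2(rnorm(lab$n2, sd = 0.2), lab)
  n <- sqrt(sum(r1^2) + sum(r2^2) / 4)
  list(r1 = r1 / n, r2 = r2 / n, r0 = rnorm(1))
}

# determinant-space context: Hamiltonian + label map for a fixture
det_context <- function(tag) {
  fixture(paste0("detctx_", tag), function() {
    mo <- switch(tag, h2 = sys_h2()$mo, h4 = sys_h4()$mo, h2o = sys_h2o()$mo)
    basis <- basis_for(tag)
    list(mo = mo, basis = basis, H = det_hamiltonian(mo, basis),
         lab = labels_for(mo))
  })
}

# projections of the truncated model in determinant space for given
# amplitudes: returns omega1 (so matrix), energy
det_cc2_residuals <- function(ctx, t1_sp, t2) {
  mo <- ctx$mo
  maps <- scc2:::so_maps(mo$n_mo, mo$n_occ)
  t1so <- scc2:::so_expand_singles(t1_sp, maps)
  T1m <- scc2:::det_r1_matrix(ctx$basis, mo$n_occ, t1so)
  Ht <- det_similarity_transform(ctx$H, T1m)
  T2m <- scc2:::det_r2_matrix(ctx$basis, mo$n_occ, t2)
  M <- Ht + (Ht %*% T2m - T2m %*% Ht)
  pr <- det_projections(M, ctx$basis, mo$n_occ, ctx$lab)
  prH <- det_projections(Ht, ctx$basis, mo$n_occ, ctx$lab)
  list(omega1 = pr$omega1, energy = pr$energy, eta1 = pr$eta1,
       eta2v = pr$eta2v, omega2_Ht = prH$omega2_full, Htilde = Ht, M = M)
}

# converged SCC2 solution inside the HOF defect region (expensive; shared)
hof_tube <- function() fixture("hof_tube", function() {
  x <- mo_for(make_hof_geometry(1.441, 1.560, 90.5))
  list(mo = x$mo, sol = solve_scc2(x$mo, select = c(1, 2), threshold = 1e-8))
})
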
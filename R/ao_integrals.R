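# AO integral acquisition: the backend contract plus the bundled Gaussian
# backend.  All quantities are in atomic units (bohr, hartree); the ERI
# tensor is stored in chemist notation (pq|rs) with its full eight-fold
# permutational symmetry.

#' Compute AO-basis integrals for a geometry
#'
#' Evaluates overlap, core Hamiltonian (kinetic + nuclear attraction),
#' two-electron repulsion integrals and the nuclear repulsion energy over
#' contracted Cartesian Gaussians, using the bundled basis-set library.
#'
#' @param geom a [geometry()].
#' @param basis basis-set name, e.g. `"sto-3g"` or `"6-31g"`.
#' @return an object of class `"ao_integrals"`: a list with `n_ao`,
#'   `overlap`, `core_hamiltonian`, `kinetic`, `eri` (4-d array, chemist
#'   notation), `nuclear_repulsion`, `n_electrons`.
#' @examples
#' ao <- compute_ao_integrals(make_h2_geometry(0.74), "sto-3g")
#' ao$n_ao
#' @export
compute_ao_integrals <- function(geom, basis = "sto-3g") {
  shells <- basis_shells(geom, basis)
  xyz <- ang_to_bohr(geom$coordinates)
  z <- as.numeric(ELEMENTS[geom$elements])
  out <- cpp_ao_integrals(shells, xyz, z)
  n <- out$n_ao
  S <- out$overlap
  # renormalize each contracted function to unit self-overlap
  nrm <- 1 / sqrt(diag(S))
  D <- outer(nrm, nrm)
  S <- S * D
  T_ <- out$kinetic * D
  V <- out$nuclear * D
  eri <- array(out$eri, rep(n, 4))
  for (axis in 1:4) {
    perm <- c(axis, setdiff(1:4, axis))
    eri <- aperm(aperm(eri, perm) * nrm, order(perm))
  }
  structure(list(n_ao = n, overlap = S, core_hamiltonian = T_ + V,
                 kinetic = T_, eri = eri,
                 nuclear_repulsion = out$nuclear_repulsion,
                 n_electrons = n_electrons(geom),
                 basis = tolower(basis), geometry = geom),
            class = "ao_integrals")
}

#' @export
print.ao_integrals <- function(x, ...) {
  cat(sprintf("ao_integrals: %d basis functions (%s), %d electrons, E_nuc = %.10f\n",
              x$n_ao, x$basis, x$n_electrons, x$nuclear_repulsion))
  invisible(x)
}

#' Construct an AO integral set directly from matrices
#'
#' Backend contract entry point: any source of AO integrals (an orthonormal
#' toy basis, an external program's output) can be wrapped for use with
#' [solve_rhf()] and everything downstream.
#'
#' @param overlap symmetric positive-definite overlap matrix.
#' @param core_hamiltonian symmetric one-electron matrix.
#' @param eri rank-4 ERI array in chemist notation.
#' @param nuclear_repulsion scalar (hartree).
#' @param n_electrons electron count.
#' @export
ao_integral_set <- function(overlap, core_hamiltonian, eri,
                            nuclear_repulsion = 0, n_electrons = 2L) {
  n <- nrow(overlap)
  ev <- eigen(overlap, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("overlap matrix is not positive definite")
  structure(list(n_ao = n, overlap = overlap,
                 core_hamiltonian = core_hamiltonian, kinetic = NULL,
                 eri = eri, nuclear_repulsion = nuclear_repulsion,
                 n_electrons = as.integer(n_electrons), basis = "custom",
                 geometry = NULL),
            class = "ao_integrals")
}
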
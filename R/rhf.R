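# Restricted Hartree-Fock: Roothaan-Hall with DIIS convergence acceleration.

#' Solve restricted Hartree-Fock
#'
#' Canonical closed-shell SCF by repeated diagonalization of the Fock matrix
#' in a symmetrically orthogonalized basis, accelerated with DIIS on the
#' `FDS - SDF` commutator.
#'
#' @param aoints an [ao_integral_set()] / [compute_ao_integrals()] result.
#' @param n_electrons electron count; defaults to the one stored in
#'   `aoints`.  Must be even.
#' @param threshold convergence threshold on the orbital-gradient
#'   (commutator) norm, hartree.
#' @param max_iter iteration cap.
#' @return an object of class `"rhf"`: `mo_coefficients` (AO x MO),
#'   `orbital_energies` (ascending, hartree), `n_occ`, `hf_energy`,
#'   `iterations`, `residual`.
#' @examples
#' ao <- compute_ao_integrals(make_h2_geometry(0.74), "sto-3g")
#' ref <- solve_rhf(ao)
#' ref$hf_energy
#' @export
solve_rhf <- function(aoints, n_electrons = NULL, threshold = 1e-9,
                      max_iter = 200L) {
  nel <- as.integer(n_electrons %||% aoints$n_electrons)
  if (nel %% 2L != 0L) stop("RHF requires an even electron count")
  n <- aoints$n_ao
  nocc <- nel %/% 2L
  if (nocc > n) stop("more electron pairs than basis functions")
  S <- aoints$overlap
  H <- aoints$core_hamiltonian
  eri <- aoints$eri
  se <- eigen(S, symmetric = TRUE)
  X <- se$vectors %*% diag(1 / sqrt(se$values), n) %*% t(se$vectors)

  fock_build <- function(Dm) {
    # J_pq = (pq|rs) D_rs ; K_pq = (pr|qs) D_rs   (chemist notation)
    J <- tc(eri, Dm, c(3, 4), c(1, 2))
    K <- tc(aperm(eri, c(1, 3, 2, 4)), Dm, c(3, 4), c(1, 2))
    H + 2 * J - K
  }

  C <- {
    Fp <- t(X) %*% H %*% X
    ev <- eigen(Fp, symmetric = TRUE)
    X %*% ev$vectors[, order(ev$values), drop = FALSE]  # aufbau occupation
  }
  energy <- NA_real_
  res <- Inf
  st <- diis_new(8)
  for (it in seq_len(max_iter)) {
    Cocc <- C[, seq_len(nocc), drop = FALSE]
    D <- Cocc %*% t(Cocc)
    Fm <- fock_build(D)
    energy <- sum(D * (H + Fm)) + aoints$nuclear_repulsion
    err <- Fm %*% D %*% S - S %*% D %*% Fm
    res <- max(abs(err))
    if (res <= threshold) break
    Fm <- matrix(diis_update(st, as.numeric(Fm), as.numeric(t(X) %*% err %*% X)), n, n)
    Fp <- t(X) %*% Fm %*% X
    Fp <- (Fp + t(Fp)) / 2
    ev <- eigen(Fp, symmetric = TRUE)
    ord <- order(ev$values)
    C <- X %*% ev$vectors[, ord, drop = FALSE]
  }
  if (res > threshold)
    stop(sprintf("SCF did not converge in %d iterations (residual %.3e)",
                 max_iter, res))
  # final canonicalization: diagonalize the converged Fock exactly
  Cocc <- C[, seq_len(nocc), drop = FALSE]
  D <- Cocc %*% t(Cocc)
  Fm <- fock_build(D)
  Fp <- t(X) %*% Fm %*% X
  Fp <- (Fp + t(Fp)) / 2
  ev <- eigen(Fp, symmetric = TRUE)
  ord <- order(ev$values)
  C <- X %*% ev$vectors[, ord, drop = FALSE]
  eps <- ev$values[ord]
  Cocc <- C[, seq_len(nocc), drop = FALSE]
  D <- Cocc %*% t(Cocc)
  energy <- sum(D * (H + fock_build(D))) + aoints$nuclear_repulsion
  structure(list(mo_coefficients = C, orbital_energies = eps, n_occ = nocc,
                 hf_energy = energy, iterations = it, residual = res,
                 aoints = aoints),
            class = "rhf")
}

#' @export
print.rhf <- function(x, ...) {
  cat(sprintf("RHF: E = %.10f hartree (%d iterations, residual %.2e)\n",
              x$hf_energy, x$iterations, x$residual))
  cat(sprintf("  %d occupied / %d virtual orbitals; HOMO-LUMO gap %.4f\n",
              x$n_occ, length(x$orbital_energies) - x$n_occ,
              if (x$n_occ < length(x$orbital_energies))
                x$orbital_energies[x$n_occ + 1] - x$orbital_energies[x$n_occ]
              else NA_real_))
  invisible(x)
}
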
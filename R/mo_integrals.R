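# Transformation of AO integrals to the canonical MO basis, and the
# spin-orbital views used by the correlated solvers.  The Hamiltonian is
# split as H = F + U: F is the (diagonal, canonical) Fock operator and the
# fluctuation potential U = H - F carries everything else.

#' Transform AO integrals to the MO basis
#'
#' Quarter-transformation chain producing the MO-basis one-electron matrix,
#' the rank-4 MO ERI tensor (chemist notation) and the diagonal canonical
#' Fock matrix.
#'
#' @param aoints an [ao_integral_set()].
#' @param ref a converged [solve_rhf()] reference.
#' @return an object of class `"mo_integrals"`: `h_mo`, `g_mo`, `fock_mo`,
#'   `orbital_energies`, `n_occ`, `n_mo`, `nuclear_repulsion`, `hf_energy`.
#' @export
transform_mo_integrals <- function(aoints, ref) {
  C <- ref$mo_coefficients
  n <- ncol(C)
  if (nrow(C) != aoints$n_ao) stop("dimension mismatch between C and AO set")
  h <- t(C) %*% aoints$core_hamiltonian %*% C
  g <- aoints$eri
  for (k in 1:4) {
    g <- array(crossprod(C, matrix(g, n, n^3)), rep(n, 4))
    g <- aperm(g, c(2, 3, 4, 1))
  }
  nocc <- ref$n_occ
  occ <- seq_len(nocc)
  # canonical Fock in MO basis: h + sum_i [2 (pq|ii) - (pi|iq)]
  Jm <- apply(g[, , occ, occ, drop = FALSE], c(1, 2), function(b) sum(diag(as.matrix(b))))
  Km <- apply(g[, occ, occ, , drop = FALSE], c(1, 4), function(b) sum(diag(as.matrix(b))))
  f <- h + 2 * Jm - Km
  structure(list(h_mo = h, g_mo = g, fock_mo = f,
                 orbital_energies = ref$orbital_energies,
                 n_occ = nocc, n_mo = n,
                 nuclear_repulsion = aoints$nuclear_repulsion,
                 hf_energy = ref$hf_energy),
            class = "mo_integrals")
}

#' @export
print.mo_integrals <- function(x, ...) {
  cat(sprintf("mo_integrals: %d MOs, %d occupied; max |F_offdiag| = %.2e\n",
              x$n_mo, x$n_occ, max(abs(x$fock_mo - diag(diag(x$fock_mo))))))
  invisible(x)
}

# ---- spin-orbital machinery -------------------------------------------------
# Spin orbitals are ordered: all alpha (spatial 1..n), then all beta
# (spatial 1..n).  Occupied spin orbitals are the alpha then beta occupied
# spatial orbitals; likewise for virtuals.

so_maps <- function(n_mo, n_occ) {
  n_so <- 2L * n_mo
  spat <- rep(seq_len(n_mo), 2L)
  spin <- rep(c(1L, 2L), each = n_mo)
  occ <- seq_len(n_occ)
  vir <- seq.int(n_occ + 1L, n_mo)
  list(n_so = n_so, spat = spat, spin = spin,
       occ_so = c(occ, n_mo + occ), vir_so = c(vir, n_mo + vir),
       o = 2L * n_occ, v = 2L * (n_mo - n_occ))
}

# antisymmetrized spin-orbital integrals <pq||rs> from a spatial chemist
# tensor g (possibly T1-dressed, hence without bra-ket symmetry):
# <pq|rs> = (pr|qs) d(sp,sr) d(sq,ss)
.so_cache <- new.env(parent = emptyenv())

so_antisymmetrize <- function(g, n_mo) {
  n_so <- 2L * n_mo
  key <- as.character(n_mo)
  cache <- get0(key, envir = .so_cache)
  if (is.null(cache)) {
    spat <- rep(seq_len(n_mo), 2L)
    spin <- rep(c(1L, 2L), each = n_mo)
    idx <- expand.grid(p = seq_len(n_so), q = seq_len(n_so),
                       r = seq_len(n_so), s = seq_len(n_so))
    p <- idx$p; q <- idx$q; r <- idx$r; s <- idx$s
    n <- n_mo
    lin <- function(a, b, c_, d_) ((d_ - 1L) * n + c_ - 1L) * n * n + (b - 1L) * n + a
    cache <- list(
      coul_idx = lin(spat[p], spat[r], spat[q], spat[s]),
      coul_mask = as.numeric((spin[p] == spin[r]) & (spin[q] == spin[s])),
      exch_idx = lin(spat[p], spat[s], spat[q], spat[r]),
      exch_mask = as.numeric((spin[p] == spin[s]) & (spin[q] == spin[r])))
    assign(key, cache, envir = .so_cache)
  }
  array(g[cache$coul_idx] * cache$coul_mask -
          g[cache$exch_idx] * cache$exch_mask, rep(n_so, 4L))
}

# one-electron spatial matrix -> spin-orbital block-diagonal matrix
so_expand_1e <- function(m) {
  n <- nrow(m)
  out <- matrix(0, 2 * n, 2 * n)
  out[seq_len(n), seq_len(n)] <- m
  out[n + seq_len(n), n + seq_len(n)] <- m
  out
}
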
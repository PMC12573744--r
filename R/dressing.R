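# T1-transformed (dressed) integrals.  With the singles cluster operator
# T1 = sum_ai t_ai E_ai, every operator V is replaced by
# exp(-T1) V exp(T1).  Because T1 is a nilpotent one-particle operator this
# is an exact two-sided transformation of the integrals:
#   h~ = L h R,  (pq|rs)~ = L x R x L x R applied index-wise,
# with L = I - kappa, R = I + kappa, kappa[virt, occ] = t(t1).

#' Dress MO integrals with singles amplitudes
#'
#' Builds the T1-transformed one- and two-electron integrals, the effective
#' Fock matrix constructed from the dressed integrals with the reference
#' density, and the dressed reference energy.  With `t1 = 0` the result
#' equals the undressed MO integrals exactly.
#'
#' @param moints a [transform_mo_integrals()] result.
#' @param t1 occupied x virtual matrix of spatial singles amplitudes.
#' @return an object of class `"dressed_integrals"`: `h`, `g` (chemist,
#'   spatial), `fock` (dressed effective Fock), `eref` (dressed reference
#'   energy), plus dimensions and the bare `orbital_energies` used for all
#'   denominators.
#' @export
dress_integrals <- function(moints, t1) {
  n <- moints$n_mo
  nocc <- moints$n_occ
  t1 <- matrix(t1, nocc, n - nocc)
  kappa <- matrix(0, n, n)
  kappa[(nocc + 1L):n, seq_len(nocc)] <- t(t1)
  L <- diag(n) - kappa
  R <- diag(n) + kappa
  h <- L %*% moints$h_mo %*% R
  g <- moints$g_mo
  mats <- list(L, t(R), L, t(R))  # bra indices pick up L, ket indices R
  for (k in 1:4) {
    g <- array(mats[[k]] %*% matrix(g, n, n^3), rep(n, 4))
    g <- aperm(g, c(2, 3, 4, 1))
  }
  occ <- seq_len(nocc)
  Jm <- apply(g[, , occ, occ, drop = FALSE], c(1, 2), function(b) sum(diag(as.matrix(b))))
  Km <- apply(g[, occ, occ, , drop = FALSE], c(1, 4), function(b) sum(diag(as.matrix(b))))
  fock <- h + 2 * Jm - Km
  eref <- moints$nuclear_repulsion + sum(diag(h)[occ] + diag(fock)[occ])
  obj <- structure(list(h = h, g = g, fock = fock, eref = eref,
                        n_mo = n, n_occ = nocc,
                        orbital_energies = moints$orbital_energies,
                        t1 = t1),
                   class = "dressed_integrals")
  obj$.so <- so_view(obj)
  obj
}

# cached spin-orbital views of a dressed set (computed once at construction)
so_view <- function(dressed) {
  if (!is.null(dressed$.so)) return(dressed$.so)
  n <- dressed$n_mo
  m <- so_maps(n, dressed$n_occ)
  g_so <- so_antisymmetrize(dressed$g, n)
  f_so <- so_expand_1e(dressed$fock)
  eps_so <- dressed$orbital_energies[m$spat]
  list(maps = m,
       f_oo = f_so[m$occ_so, m$occ_so, drop = FALSE],
       f_ov = f_so[m$occ_so, m$vir_so, drop = FALSE],
       f_vo = f_so[m$vir_so, m$occ_so, drop = FALSE],
       f_vv = f_so[m$vir_so, m$vir_so, drop = FALSE],
       g_vvoo = g_so[m$vir_so, m$vir_so, m$occ_so, m$occ_so, drop = FALSE],
       g_oovv = g_so[m$occ_so, m$occ_so, m$vir_so, m$vir_so, drop = FALSE],
       g_ovvv = g_so[m$occ_so, m$vir_so, m$vir_so, m$vir_so, drop = FALSE],
       g_oovo = g_so[m$occ_so, m$occ_so, m$vir_so, m$occ_so, drop = FALSE],
       g_vvvo = g_so[m$vir_so, m$vir_so, m$vir_so, m$occ_so, drop = FALSE],
       g_ovoo = g_so[m$occ_so, m$vir_so, m$occ_so, m$occ_so, drop = FALSE],
       g_voov = g_so[m$vir_so, m$occ_so, m$occ_so, m$vir_so, drop = FALSE],
       eps_o = eps_so[m$occ_so], eps_v = eps_so[m$vir_so])
}
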
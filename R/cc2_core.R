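# CC2 working equations in the spin-orbital basis with T1-dressed integrals.
#
# Storage conventions:
#   t1 (user level): occupied x virtual spatial matrix (singlet amplitudes)
#   t1 (spin-orbital): occ_so x vir_so matrix, alpha and beta blocks equal
#   t2: rank-4 array t2[a, b, i, j] over (vir_so, vir_so, occ_so, occ_so),
#       antisymmetric in (a,b) and in (i,j)
# Inner products over excitation labels: singles sum(x * y); doubles
# sum(x * y) / 4 (each unique label appears four times in the tensor).

so_expand_singles <- function(m_spatial, maps) {
  o2 <- maps$o; v2 <- maps$v
  o <- o2 %/% 2L; v <- v2 %/% 2L
  out <- matrix(0, o2, v2)
  out[seq_len(o), seq_len(v)] <- m_spatial
  out[o + seq_len(o), v + seq_len(v)] <- m_spatial
  out
}

so_collapse_singles <- function(m_so, maps) {
  o <- maps$o %/% 2L; v <- maps$v %/% 2L
  m_so[seq_len(o), seq_len(v), drop = FALSE]
}

dot_doubles <- function(x, y) sum(x * y) / 4
dot_state <- function(x1, x2, y1, y2) sum(x1 * y1) + dot_doubles(x2, y2)

doubles_denominator <- function(sov) {
  eo <- sov$eps_o; ev <- sov$eps_v
  o <- length(eo); v <- length(ev)
  d <- outer(-ev, -ev, "+")
  D <- array(0, c(v, v, o, o))
  eij <- outer(eo, eo, "+")
  for (i in seq_len(o)) for (j in seq_len(o))
    D[, , i, j] <- d + eij[i, j]
  D
}

#' Closed-form CC2 doubles amplitudes
#'
#' With the doubles-doubles Jacobian diagonal in the canonical orbital-energy
#' differences, the doubles equations have the closed-form solution
#' `t2 = <ab||ij>~ / (e_i + e_j - e_a - e_b)` in terms of the T1-dressed
#' two-electron integrals.  With `t1 = 0` these are the MP2 amplitudes.
#'
#' @param dressed a [dress_integrals()] result.
#' @return list with `t2` (spin-orbital rank-4 array) and `denominators`.
#' @export
compute_t2 <- function(dressed) {
  sov <- so_view(dressed)
  D <- doubles_denominator(sov)
  small <- abs(D) < 1e-8
  if (any(small)) {
    idx <- which(small, arr.ind = TRUE)[1, ]
    stop(sprintf(paste0("degenerate occupied/virtual gap: |e_i+e_j-e_a-e_b| < 1e-8 ",
                        "for (a=%d, b=%d, i=%d, j=%d)"),
                 idx[1], idx[2], idx[3], idx[4]))
  }
  list(t2 = sov$g_vvoo / D, denominators = D)
}

# <mu1| [H~, X2] |HF> for any doubles-like tensor x2: the linear map shared
# by the singles residual (x2 = t2) and the singles-doubles Jacobian block
# (x2 = r2).  Returns an occ_so x vir_so matrix.
singles_from_doubles <- function(sov, x2) {
  term2 <- t(tc(x2, sov$f_ov, c(4, 2), c(1, 2)))              # [i,a]
  term3 <- -0.5 * t(tc(sov$g_ovvv, x2, c(1, 3, 4), c(4, 1, 2)))
  term4 <- -0.5 * tc(sov$g_oovo, x2, c(1, 2, 3), c(3, 4, 1))
  term2 + term3 + term4
}

# <mu1| [[U~, X2], Y1] |HF>: the double-commutator patterns coupling a
# doubles-like tensor x2 and a singles-like matrix y1 through the
# pure de-excitation integrals <kl||cd>~.  Used in the singles-singles
# Jacobian block (x2 = t2) and in the similarity-constraint correction
# (x2 = r2 of one state, y1 = r1 of the other).
singles_double_commutator <- function(sov, x2, y1) {
  g <- sov$g_oovv
  Fvv <- -0.5 * tc(x2, g, c(3, 4, 2), c(1, 2, 4))   # [a, b]
  Foo <- 0.5 * tc(g, x2, c(2, 3, 4), c(4, 1, 2))    # [j, i]
  W <- tc(g, x2, c(2, 4), c(4, 2))                  # [j, b, i?]: see below
  # W indices: g[j,k,b,c] x2[a,c,i,k] contracted over (k,c) -> [j, b, a, i]
  term_w <- tc(W, y1, c(1, 2), c(1, 2))             # sum_jb y1[j,b] -> [a, i]
  y1 %*% t(Fvv) - crossprod(Foo, y1) + t(term_w)
}

#' CC2 singles residual
#'
#' Evaluates `Omega_ai = <ai| H~ + [H~, T2] |HF>` for all single
#' excitations, with all reference to T1 absorbed in the dressed integrals.
#'
#' @param dressed a [dress_integrals()] result (carries t1).
#' @param t2 spin-orbital doubles array from [compute_t2()].
#' @return occ_so x vir_so residual matrix.
#' @export
singles_residual <- function(dressed, t2) {
  sov <- so_view(dressed)
  t(sov$f_vo) + singles_from_doubles(sov, t2)
}

#' CC2 ground-state energy
#'
#' `E0 = <HF| H~ + [H~, T2] |HF>`: the dressed reference energy plus the
#' doubles contraction with the de-excitation integrals.
#'
#' @inheritParams singles_residual
#' @return energy in hartree.
#' @export
ground_energy <- function(dressed, t2) {
  sov <- so_view(dressed)
  dressed$eref + 0.25 * sum(sov$g_oovv * aperm(t2, c(3, 4, 1, 2)))
}

#' The eta vector coupling the reference to excited configurations
#'
#' `eta_nu = <HF| [Hbar, tau_nu] |HF>`; its singles block is the
#' occupied-virtual block of the dressed Fock matrix and its doubles block
#' the dressed de-excitation integrals.  Used for the ground-state
#' contribution `r0 = eta' r / omega` of every excited state.
#'
#' @inheritParams singles_residual
#' @return list with `eta1` (occ_so x vir_so) and `eta2` (rank-4, indexed
#'   like t2).
#' @export
eta_vector <- function(dressed, t2 = NULL) {
  sov <- so_view(dressed)
  list(eta1 = sov$f_ov, eta2 = aperm(sov$g_oovv, c(3, 4, 1, 2)))
}

#' Solve the CC2 ground state
#'
#' DIIS-accelerated solution of the folded CC2 amplitude equations: only the
#' singles are iterated, the doubles being recomputed in closed form from
#' the current T1-dressed integrals at every iteration.
#'
#' @param moints a [transform_mo_integrals()] result.
#' @param threshold convergence threshold on the spin-orbital singles
#'   residual norm.
#' @param max_iter iteration cap.
#' @param t1_init optional starting amplitudes (occupied x virtual spatial
#'   matrix), e.g. from a neighboring geometry.
#' @param extra_residual optional function(dressed, t2) returning an
#'   additional occ_so x vir_so residual contribution (used by the
#'   similarity-constrained solver); `NULL` for plain CC2.
#' @return object of class `"cc2_ground"`: `t1` (spatial), `t2`
#'   (spin-orbital), `energy`, `eta`, `dressed`, `iterations`, `residual`,
#'   `residual_history`.
#' @export
solve_cc2_ground <- function(moints, threshold = 1e-8, max_iter = 100L,
                             t1_init = NULL, extra_residual = NULL) {
  o <- moints$n_occ; v <- moints$n_mo - moints$n_occ
  eps <- moints$orbital_energies
  D1 <- outer(eps[seq_len(o)], eps[o + seq_len(v)], "-")  # e_i - e_a
  t1 <- if (is.null(t1_init)) matrix(0, o, v) else matrix(t1_init, o, v)
  st <- diis_new(8)
  hist <- numeric(0)
  for (it in seq_len(max_iter)) {
    dressed <- dress_integrals(moints, t1)
    sov <- so_view(dressed)
    t2 <- compute_t2(dressed)$t2
    om_so <- t(sov$f_vo) + singles_from_doubles(sov, t2)
    if (!is.null(extra_residual)) om_so <- om_so + extra_residual(dressed, t2)
    om_sp <- so_collapse_singles(om_so, sov$maps)
    res <- sqrt(sum(om_so^2))
    hist <- c(hist, res)
    if (res <= threshold) break
    t1_new <- t1 + om_sp / D1
    t1 <- matrix(diis_update(st, as.numeric(t1_new), as.numeric(om_sp)), o, v)
  }
  if (res > threshold)
    stop(sprintf("CC2 ground state did not converge in %d iterations; residual history: %s",
                 max_iter, paste(sprintf("%.2e", utils::tail(hist, 8)), collapse = " ")))
  dressed <- dress_integrals(moints, t1)
  t2 <- compute_t2(dressed)$t2
  structure(list(t1 = t1, t2 = t2, energy = ground_energy(dressed, t2),
                 eta = eta_vector(dressed), dressed = dressed,
                 iterations = it, residual = res, residual_history = hist,
                 moints = moints),
            class = "cc2_ground")
}

#' @export
print.cc2_ground <- function(x, ...) {
  cat(sprintf("CC2 ground state: E0 = %.10f hartree (%d iterations, residual %.2e)\n",
              x$energy, x$iterations, x$residual))
  invisible(x)
}

#' Closed-form MP2 correlation energy
#'
#' Convenience reference: the canonical MP2 correlation energy from bare MO
#' integrals, equal to the CC2 correlation energy at `t1 = 0`.
#'
#' @param moints a [transform_mo_integrals()] result.
#' @return MP2 correlation energy in hartree.
#' @export
mp2_energy <- function(moints) {
  dressed <- dress_integrals(moints, matrix(0, moints$n_occ,
                                            moints$n_mo - moints$n_occ))
  t2 <- compute_t2(dressed)$t2
  ground_energy(dressed, t2) - moints$hf_energy
}
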
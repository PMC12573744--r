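# Similarity-constrained layer: the X3 constraint operator, the
# zeta-scaled singles-residual correction, and the natural-projection
# overlap O(A,B) with its q / Q / S machinery.

#' Build the X3 constraint operator
#'
#' `X3 = sum (r^A_mu1 r^B_mu2 - r^B_mu1 r^A_mu2) tau_mu1 tau_mu2`, stored in
#' factorized form through the two states' singles and doubles blocks; the
#' implied triples amplitudes are never materialized.  Antisymmetric under
#' exchange of the states and identically zero when they coincide.
#'
#' @param rA,rB right `"eom_state"` objects (or lists with `r1`, `r2`).
#' @return object of class `"x3_operator"`.
#' @export
build_x3 <- function(rA, rB) {
  if (!all(dim(rA$r1) == dim(rB$r1)) || !all(dim(rA$r2) == dim(rB$r2)))
    stop("state dimension mismatch in X3 construction")
  structure(list(r1A = rA$r1, r2A = rA$r2, r1B = rB$r1, r2B = rB$r2),
            class = "x3_operator")
}

#' Similarity-constraint correction to the singles residual
#'
#' `Delta Omega_mu1 = zeta <mu1| [H~, X3] |HF>`, evaluated through the
#' factorized double-commutator contractions (no triples tensor is formed):
#' for each ordered state pair, the three de-excitation patterns coupling
#' `<kl||cd>~` to (r1, r2) plus the fully contracted scalar term.
#'
#' @param dressed a [dress_integrals()] result.
#' @param x3 an [build_x3()] operator.
#' @param zeta constraint strength (dimensionless).
#' @return occ_so x vir_so singles contribution.
#' @export
scc_singles_correction <- function(dressed, x3, zeta) {
  if (zeta == 0) return(matrix(0, nrow(x3$r1A), ncol(x3$r1A)))
  sov <- so_view(dressed)
  half <- function(r1x, r2y) {
    sc <- 0.25 * sum(sov$g_oovv * aperm(r2y, c(3, 4, 1, 2)))
    singles_double_commutator(sov, r2y, r1x) + r1x * sc
  }
  zeta * (half(x3$r1A, x3$r2B) - half(x3$r1B, x3$r2A))
}

#' Projection-space representation of exp(S)|HF>
#'
#' The q vector of the orthogonality machinery: `q_mu = <mu|exp(S)|HF>`
#' over the singles and doubles labels.  Exact within the projection space
#' (the exponential of nilpotent excitation operators terminates);
#' `zeta X3` starts at the triples and does not contribute.
#'
#' @param t1_so occ_so x vir_so spin-orbital singles amplitudes.
#' @param t2 rank-4 doubles array.
#' @return list `q1` (occ_so x vir_so), `q2` (rank-4 array).
#' @export
overlap_q <- function(t1_so, t2) {
  # q2[a,b,i,j] = t2 + t1[i,a] t1[j,b] - t1[j,a] t1[i,b]
  tt <- tc(t(t1_so), t(t1_so), integer(0), integer(0))  # [a,i,b,j]
  tt <- aperm(tt, c(1, 3, 2, 4))                        # [a,b,i,j]
  q2 <- t2 + tt - aperm(tt, c(1, 2, 4, 3))
  list(q1 = t1_so, q2 = q2)
}

#' Apply the Q matrix of the orthogonality machinery
#'
#' `Q_munu = <mu|exp(S)|nu>` applied to a projection-space vector without
#' materializing Q: the identity plus the T1-mediated singles-to-doubles
#' coupling (higher cluster components leave the projection space).
#'
#' @param t1_so spin-orbital singles amplitudes.
#' @param v1,v2 vector blocks in production storage.
#' @return list `(w1, w2)`.
#' @export
overlap_Q_apply <- function(t1_so, v1, v2) {
  cross <- tc(t(t1_so), t(v1), integer(0), integer(0))  # [a,i,b,j] = t1[i,a]v1[j,b]
  cross <- aperm(cross, c(1, 3, 2, 4))
  z <- cross + aperm(cross, c(2, 1, 4, 3))              # + v1[i,a] t1[j,b]
  w2 <- v2 + z - aperm(z, c(1, 2, 4, 3))
  list(w1 = v1, w2 = w2)
}

#' Gram matrix of projection-space configurations
#'
#' `S_munu = <mu|nu>`.  In the default orthonormal spin-orbital determinant
#' basis this is the identity; for the spin-adapted configuration basis
#' `{E_ai|HF>, E_ai E_bj|HF>}` the doubles blocks are non-trivial and the
#' closed-form Gram is returned over composite pair labels `(ai) <= (bj)`.
#'
#' @param n_occ,n_virt spatial occupied / virtual counts (spin-adapted
#'   mode).
#' @param basis `"determinant"` or `"spin-adapted"`.
#' @param n_labels label count for the determinant mode.
#' @return symmetric positive semidefinite matrix; for the spin-adapted
#'   mode, an attribute `"labels"` carries the pair labels.
#' @export
configuration_overlap_matrix <- function(n_occ = NULL, n_virt = NULL,
                                         basis = c("determinant", "spin-adapted"),
                                         n_labels = NULL) {
  basis <- match.arg(basis)
  if (basis == "determinant") {
    if (is.null(n_labels)) stop("n_labels required for determinant basis")
    return(diag(n_labels))
  }
  # spin-adapted: singles then doubles pair labels
  sing <- expand.grid(i = seq_len(n_occ), a = seq_len(n_virt))
  pair_id <- function(i, a) (i - 1L) * n_virt + a
  pairs <- expand.grid(p = seq_len(n_occ * n_virt), q = seq_len(n_occ * n_virt))
  pairs <- pairs[pairs$p <= pairs$q, , drop = FALSE]
  ns <- nrow(sing); npr <- nrow(pairs)
  S <- matrix(0, ns + npr, ns + npr)
  diag(S)[seq_len(ns)] <- 2  # <HF|E_ia E_ai|HF> = 2
  dec <- function(p) c(i = (p - 1L) %/% n_virt + 1L, a = (p - 1L) %% n_virt + 1L)
  for (x in seq_len(npr)) {
    px <- dec(pairs$p[x]); qx <- dec(pairs$q[x])
    a <- px["a"]; i <- px["i"]; b <- qx["a"]; j <- qx["i"]
    for (y in x:npr) {
      py <- dec(pairs$p[y]); qy <- dec(pairs$q[y])
      c_ <- py["a"]; k <- py["i"]; d_ <- qy["a"]; l <- qy["i"]
      val <- 0
      # aligned pairing {(a,i),(b,j)} == {(c,k),(d,l)}
      if ((a == c_ && i == k && b == d_ && j == l) ||
          (a == d_ && i == l && b == c_ && j == k)) {
        val <- val + if (a != b && i != j) 4 else if (a == b && i == j) 4 else 2
      }
      # crossed pairing {(a,j),(b,i)} == {(c,k),(d,l)} contributes -2
      if (a != b && i != j) {
        if ((a == c_ && j == k && b == d_ && i == l) ||
            (a == d_ && j == l && b == c_ && i == k)) val <- val - 2
      }
      S[ns + x, ns + y] <- S[ns + y, ns + x] <- val
    }
  }
  attr(S, "labels") <- list(singles = sing, pairs = pairs)
  S
}

#' Orthogonality value O(A,B) under the natural projection
#'
#' Evaluates `O(A,B) = r0A r0B (1 + q'Sq) + r0A q'S Q rB + (rA)'Q'S q r0B +
#' (rA)'Q'S Q rB` in the orthonormal spin-orbital determinant representation
#' (S = identity), where q and Q carry the cluster operator
#' `S = T1 + T2 + zeta X3`.
#'
#' @param t1_so spin-orbital singles amplitudes.
#' @param t2 doubles amplitudes.
#' @param stateA,stateB lists/states with `r0`, `r1`, `r2`.
#' @return scalar overlap.
#' @export
orthogonality_value <- function(t1_so, t2, stateA, stateB) {
  q <- overlap_q(t1_so, t2)
  QA <- overlap_Q_apply(t1_so, stateA$r1, stateA$r2)
  QB <- overlap_Q_apply(t1_so, stateB$r1, stateB$r2)
  qq <- dot_state(q$q1, q$q2, q$q1, q$q2)
  stateA$r0 * stateB$r0 * (1 + qq) +
    stateA$r0 * dot_state(q$q1, q$q2, QB$w1, QB$w2) +
    stateB$r0 * dot_state(QA$w1, QA$w2, q$q1, q$q2) +
    dot_state(QA$w1, QA$w2, QB$w1, QB$w2)
}
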
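# Determinant-space oracle: brute-force full-configuration algebra for
# small systems.  Hamiltonians, excitation operators, nilpotent cluster
# exponentials, similarity transforms, Jacobians and overlaps are built as
# explicit matrices over a complete Sz-conserving determinant basis and
# serve as the independent reference for every working equation in the
# package.  Dense matrices only; deliberately simple code.
#
# Spin-orbital convention (matches the production tensors): spatial orbital
# p as alpha -> index p, as beta -> index n_mo + p.  A determinant is the
# ordered product of creation operators with ascending spin-orbital index
# applied to the vacuum, stored as a bitmask (bit p-1 <-> spin orbital p).

#' Enumerate a full determinant basis at fixed Sz
#'
#' Complete set of determinants for given electron counts per spin,
#' deterministically ordered: reference (aufbau) first, then by excitation
#' level relative to the reference, then lexicographically by bitmask.
#'
#' @param n_spatial number of spatial orbitals (<= 15).
#' @param n_alpha,n_beta electron counts per spin.
#' @param cap refuse bases larger than this.
#' @return object of class `"det_basis"`: `masks` (integer bitmasks),
#'   `ref` (mask of the reference), `n_so`, `levels`, lookup environment.
#' @export
det_basis <- function(n_spatial, n_alpha, n_beta, cap = 20000L) {
  if (n_spatial > 15L) stop("determinant oracle limited to 15 spatial orbitals")
  ndet <- choose(n_spatial, n_alpha) * choose(n_spatial, n_beta)
  if (ndet > cap) stop("determinant basis size ", ndet, " exceeds cap ", cap)
  combos <- function(n, k) {
    if (k == 0L) return(list(integer(0)))
    cols <- utils::combn(n, k)
    lapply(seq_len(ncol(cols)), function(j) cols[, j])
  }
  am <- vapply(combos(n_spatial, n_alpha),
               function(ix) sum(bitwShiftL(1L, ix - 1L)), integer(1))
  bm <- vapply(combos(n_spatial, n_beta),
               function(ix) sum(bitwShiftL(1L, ix - 1L)), integer(1))
  grid <- expand.grid(a = am, b = bm)
  masks <- bitwOr(grid$a, bitwShiftL(grid$b, n_spatial))
  ref <- bitwOr(sum(bitwShiftL(1L, seq_len(n_alpha) - 1L)),
                bitwShiftL(sum(bitwShiftL(1L, seq_len(n_beta) - 1L)), n_spatial))
  pc <- popcount32(bitwAnd(masks, bitwNot(ref)))
  ord <- order(pc, masks)
  masks <- masks[ord]
  lookup <- new.env(parent = emptyenv(), size = length(masks))
  for (k in seq_along(masks)) assign(as.character(masks[k]), k, envir = lookup)
  structure(list(masks = masks, ref = ref, n_so = 2L * n_spatial,
                 n_spatial = n_spatial, n_alpha = n_alpha, n_beta = n_beta,
                 levels = pc[ord], lookup = lookup),
            class = "det_basis")
}

#' @export
print.det_basis <- function(x, ...) {
  cat(sprintf("det_basis: %d determinants, %d spatial orbitals, (%d alpha, %d beta)\n",
              length(x$masks), x$n_spatial, x$n_alpha, x$n_beta))
  invisible(x)
}

popcount32 <- function(x) {
  n <- integer(length(x))
  for (s in 0:31) n <- n + bitwAnd(bitwShiftR(x, s), 1L)
  n
}

det_index <- function(basis, mask) {
  get0(as.character(mask), envir = basis$lookup, ifnotfound = NA_integer_)
}

occ_list <- function(mask, n_so) which(bitwAnd(bitwShiftR(mask, 0:(n_so - 1L)), 1L) == 1L)

# apply a'_p a_q to a determinant; returns list(mask, sign) or NULL
apply_pq <- function(mask, p, q) {
  bq <- bitwShiftL(1L, q - 1L)
  if (bitwAnd(mask, bq) == 0L) return(NULL)
  s1 <- popcount32(bitwAnd(mask, bq - 1L))
  m1 <- bitwXor(mask, bq)
  bp <- bitwShiftL(1L, p - 1L)
  if (bitwAnd(m1, bp) != 0L) return(NULL)
  s2 <- popcount32(bitwAnd(m1, bp - 1L))
  list(mask = bitwOr(m1, bp), sign = if ((s1 + s2) %% 2L == 0L) 1 else -1)
}

# independent antisymmetrized spin-orbital integrals from spatial MO
# integrals (direct index formula; kept separate from the production path)
oracle_so_ints <- function(moints) {
  n <- moints$n_mo; n_so <- 2L * n
  spat <- function(p) ((p - 1L) %% n) + 1L
  spin <- function(p) ((p - 1L) %/% n) + 1L
  h_so <- matrix(0, n_so, n_so)
  for (p in seq_len(n_so)) for (q in seq_len(n_so))
    if (spin(p) == spin(q)) h_so[p, q] <- moints$h_mo[spat(p), spat(q)]
  g_abij <- array(0, rep(n_so, 4))  # <pq||rs>
  for (p in seq_len(n_so)) for (q in seq_len(n_so))
    for (r in seq_len(n_so)) for (s in seq_len(n_so)) {
      coul <- if (spin(p) == spin(r) && spin(q) == spin(s))
        moints$g_mo[spat(p), spat(r), spat(q), spat(s)] else 0
      exch <- if (spin(p) == spin(s) && spin(q) == spin(r))
        moints$g_mo[spat(p), spat(s), spat(q), spat(r)] else 0
      g_abij[p, q, r, s] <- coul - exch
    }
  list(h = h_so, g = g_abij, n_so = n_so)
}

#' Hamiltonian matrix over a determinant basis
#'
#' Slater-Condon construction from MO integrals; Hermitian, and its lowest
#' eigenvalue is the FCI energy of the system.
#'
#' @param moints a [transform_mo_integrals()] result.
#' @param basis a [det_basis()].
#' @return dense symmetric matrix (hartree), nuclear repulsion included.
#' @export
det_hamiltonian <- function(moints, basis) {
  so <- oracle_so_ints(moints)
  nd <- length(basis$masks)
  n_so <- basis$n_so
  H <- matrix(0, nd, nd)
  occs <- lapply(basis$masks, occ_list, n_so = n_so)
  # diagonal
  for (I in seq_len(nd)) {
    oI <- occs[[I]]
    e <- sum(diag(so$h)[oI])
    for (ii in oI) for (jj in oI) e <- e + 0.5 * so$g[ii, jj, ii, jj]
    H[I, I] <- e + moints$nuclear_repulsion
  }
  # off-diagonal: classify by excitation distance (vectorized per row)
  for (I in seq_len(nd)) {
    mI <- basis$masks[I]; oI <- occs[[I]]
    xall <- bitwXor(mI, basis$masks)
    nxall <- popcount32(xall)
    for (J in which(nxall == 2L | nxall == 4L)) {
      mJ <- basis$masks[J]
      x <- xall[J]
      nx <- nxall[J]
      if (nx == 2L) {
        p <- occ_list(bitwAnd(x, mJ), n_so)   # created in J
        q <- occ_list(bitwAnd(x, mI), n_so)   # removed from I
        ph <- excitation_phase(mI, q, p)
        common <- occ_list(bitwAnd(mI, mJ), n_so)
        val <- so$h[p, q]
        for (k in common) val <- val + so$g[p, k, q, k]
        H[J, I] <- H[J, I] + ph * val
      } else if (nx == 4L) {
        pp <- occ_list(bitwAnd(x, mJ), n_so)  # p < r created
        qq <- occ_list(bitwAnd(x, mI), n_so)  # q < s removed
        ph <- excitation_phase2(mI, qq, pp)
        H[J, I] <- H[J, I] + ph * so$g[pp[1], pp[2], qq[1], qq[2]]
      }
    }
  }
  H
}

# phase for single replacement q -> p on mask mI
excitation_phase <- function(mI, q, p) {
  lo <- min(p, q); hi <- max(p, q)
  between <- popcount32(bitwAnd(mI, bitwAnd(bitwShiftL(1L, hi - 1L) - 1L,
                                            bitwNot(bitwShiftL(1L, lo) - 1L))))
  if (between %% 2L == 0L) 1 else -1
}

# phase for double replacement {q1<q2} -> {p1<p2}: apply q2->p2 then q1->p1
excitation_phase2 <- function(mI, qq, pp) {
  s1 <- excitation_phase(mI, qq[2], pp[2])
  m1 <- bitwOr(bitwXor(mI, bitwShiftL(1L, qq[2] - 1L)), bitwShiftL(1L, pp[2] - 1L))
  s2 <- excitation_phase(m1, qq[1], pp[1])
  s1 * s2
}


# vectorized a'_p a_q over all determinants at once: returns target index
# (NA where annihilated) and sign, using hashed mask lookup
apply_pq_vec <- function(basis, p, q) {
  masks <- basis$masks
  bq <- bitwShiftL(1L, q - 1L); bp <- bitwShiftL(1L, p - 1L)
  ok <- bitwAnd(masks, bq) != 0L
  m1 <- bitwXor(masks, bq)
  ok <- ok & (bitwAnd(m1, bp) == 0L)
  s1 <- popcount32(bitwAnd(masks, bq - 1L))
  s2 <- popcount32(bitwAnd(m1, bp - 1L))
  newmask <- bitwOr(m1, bp)
  J <- match(newmask, masks)
  J[!ok] <- NA_integer_
  list(J = J, sign = 1 - 2 * ((s1 + s2) %% 2L), mask = newmask, ok = ok)
}
# matrix of a'_p a_q over the basis
op_matrix_pq <- function(basis, p, q) {
  nd <- length(basis$masks)
  M <- matrix(0, nd, nd)
  for (I in seq_len(nd)) {
    r <- apply_pq(basis$masks[I], p, q)
    if (!is.null(r)) {
      J <- det_index(basis, r$mask)
      if (!is.na(J)) M[J, I] <- r$sign
    }
  }
  M
}

# so index helpers matching the production occ/vir ordering
prod_so_index <- function(n_mo, n_occ, kind, k) {
  # kind "occ": k in 1..2*n_occ -> spin orbital index; kind "vir" similar
  if (kind == "occ") {
    o <- n_occ
    if (k <= o) k else n_mo + (k - o)
  } else {
    v <- n_mo - n_occ
    if (k <= v) n_occ + k else n_mo + n_occ + (k - v)
  }
}

#' Cluster / excited-state operator matrix
#'
#' Builds the determinant-space matrix of `S = T1 + T2 + zeta X3` (or any
#' sub-combination) from production-storage amplitudes.  The result is
#' strictly excitation-raising and nilpotent.
#'
#' @param basis a [det_basis()].
#' @param n_occ number of occupied spatial orbitals.
#' @param t1_so occ_so x vir_so singles matrix (or NULL).
#' @param t2 rank-4 doubles array (or NULL).
#' @param zeta scalar weight of `x3`.
#' @param x3 an [build_x3()] operator (or NULL).
#' @return dense matrix over the basis.
#' @export
det_cluster_matrix <- function(basis, n_occ, t1_so = NULL, t2 = NULL,
                               zeta = 0, x3 = NULL) {
  n_mo <- basis$n_spatial
  M <- matrix(0, length(basis$masks), length(basis$masks))
  if (!is.null(t1_so)) M <- M + det_r1_matrix(basis, n_occ, t1_so)
  if (!is.null(t2)) M <- M + det_r2_matrix(basis, n_occ, t2)
  if (zeta != 0 && !is.null(x3)) {
    MA1 <- det_r1_matrix(basis, n_occ, x3$r1A)
    MA2 <- det_r2_matrix(basis, n_occ, x3$r2A)
    MB1 <- det_r1_matrix(basis, n_occ, x3$r1B)
    MB2 <- det_r2_matrix(basis, n_occ, x3$r2B)
    M <- M + zeta * (MA1 %*% MB2 - MB1 %*% MA2)
  }
  M
}

# matrix of R1 = sum r1[i,a] a'_a a_i
det_r1_matrix <- function(basis, n_occ, r1) {
  n_mo <- basis$n_spatial
  nd <- length(basis$masks)
  M <- matrix(0, nd, nd)
  o2 <- nrow(r1); v2 <- ncol(r1)
  for (i in seq_len(o2)) for (a in seq_len(v2)) {
    cf <- r1[i, a]
    if (cf == 0) next
    ap <- apply_pq_vec(basis, prod_so_index(n_mo, n_occ, "vir", a),
                       prod_so_index(n_mo, n_occ, "occ", i))
    keep <- which(ap$ok & !is.na(ap$J))
    M[cbind(ap$J[keep], keep)] <- M[cbind(ap$J[keep], keep)] +
      cf * ap$sign[keep]
  }
  M
}

# matrix of R2 = (1/4) sum r2[a,b,i,j] a'_a a'_b a_j a_i, via unique labels
det_r2_matrix <- function(basis, n_occ, r2) {
  n_mo <- basis$n_spatial
  nd <- length(basis$masks)
  M <- matrix(0, nd, nd)
  d <- dim(r2); v2 <- d[1]; o2 <- d[3]
  for (a in seq_len(v2)) for (b in seq_len(v2)) if (b > a)
    for (i in seq_len(o2)) for (j in seq_len(o2)) if (j > i) {
      cf <- r2[a, b, i, j]
      if (cf == 0) next
      s1 <- apply_pq_vec(basis, prod_so_index(n_mo, n_occ, "vir", a),
                         prod_so_index(n_mo, n_occ, "occ", i))
      ok1 <- which(s1$ok & !is.na(s1$J))
      if (length(ok1) == 0) next
      # second replacement applied to the intermediate masks
      pb <- bitwShiftL(1L, prod_so_index(n_mo, n_occ, "vir", b) - 1L)
      qj <- bitwShiftL(1L, prod_so_index(n_mo, n_occ, "occ", j) - 1L)
      m1 <- s1$mask[ok1]
      ok2 <- bitwAnd(m1, qj) != 0L
      m2 <- bitwXor(m1, qj)
      ok2 <- ok2 & (bitwAnd(m2, pb) == 0L)
      sA <- popcount32(bitwAnd(m1, qj - 1L))
      sB <- popcount32(bitwAnd(m2, pb - 1L))
      m3 <- bitwOr(m2, pb)
      J <- match(m3, basis$masks)
      keep <- which(ok2 & !is.na(J))
      if (length(keep) == 0) next
      rows <- J[keep]; cols <- ok1[keep]
      sgn <- s1$sign[ok1][keep] * (1 - 2 * ((sA[keep] + sB[keep]) %% 2L))
      M[cbind(rows, cols)] <- M[cbind(rows, cols)] + cf * sgn
    }
  M
}

#' Exact similarity transform by a nilpotent operator
#'
#' `Hbar = exp(-S) H exp(S)` with the exponentials evaluated as terminating
#' series (S is strictly excitation-raising).
#'
#' @param H dense Hamiltonian matrix.
#' @param S dense nilpotent cluster matrix.
#' @return dense non-symmetric matrix.
#' @export
det_similarity_transform <- function(H, S) {
  eS <- matexp_nilpotent(S)
  eSm <- matexp_nilpotent(-S)
  eSm %*% H %*% eS
}

matexp_nilpotent <- function(S, cap = 40L) {
  out <- diag(nrow(S))
  term <- diag(nrow(S))
  for (k in seq_len(cap)) {
    term <- term %*% S / k
    if (max(abs(term)) == 0) break
    out <- out + term
  }
  out
}

# label index maps: position of each production singles/doubles label in
# the determinant basis, with the phase of tau_mu |HF>
oracle_label_map <- function(basis, n_occ, labels) {
  n_mo <- basis$n_spatial
  ref <- basis$ref
  s_idx <- integer(labels$n1); s_ph <- numeric(labels$n1)
  for (k in seq_len(labels$n1)) {
    i <- labels$singles$i[k]; a <- labels$singles$a[k]
    r <- apply_pq(ref, prod_so_index(n_mo, n_occ, "vir", a),
                  prod_so_index(n_mo, n_occ, "occ", i))
    s_idx[k] <- det_index(basis, r$mask); s_ph[k] <- r$sign
  }
  d_idx <- integer(labels$n2); d_ph <- numeric(labels$n2)
  for (k in seq_len(labels$n2)) {
    a <- labels$doubles$a[k]; b <- labels$doubles$b[k]
    i <- labels$doubles$i[k]; j <- labels$doubles$j[k]
    r1 <- apply_pq(ref, prod_so_index(n_mo, n_occ, "vir", a),
                   prod_so_index(n_mo, n_occ, "occ", i))
    r2 <- apply_pq(r1$mask, prod_so_index(n_mo, n_occ, "vir", b),
                   prod_so_index(n_mo, n_occ, "occ", j))
    d_idx[k] <- det_index(basis, r2$mask); d_ph[k] <- r1$sign * r2$sign
  }
  list(s_idx = s_idx, s_ph = s_ph, d_idx = d_idx, d_ph = d_ph,
       ref = det_index(basis, ref))
}

#' Determinant-space CC residuals, energy and eta
#'
#' Projections of a similarity-transformed Hamiltonian matrix onto the
#' reference and the production singles/doubles labels.  `truncated = TRUE`
#' reproduces the model's truncations symbolically: the doubles residual is
#' evaluated as `<mu2|H~|HF> + eps_mu2 t_mu2` (diagonal Fock commutator)
#' rather than from the full Hbar.
#'
#' @param Hbar matrix from [det_similarity_transform()].
#' @param basis a [det_basis()].
#' @param n_occ occupied spatial orbitals.
#' @param labels an `sz_labels()` label set (from a [jacobian_model()] or
#'   built directly).
#' @return list: `energy`, `omega1` (occ_so x vir_so), `omega2_full`
#'   (vector over doubles labels), `eta1`, `eta2v`.
#' @export
det_projections <- function(Hbar, basis, n_occ, labels) {
  lm <- oracle_label_map(basis, n_occ, labels)
  col0 <- Hbar[, lm$ref]
  row0 <- Hbar[lm$ref, ]
  omega1 <- matrix(0, labels$o, labels$v)
  omega1[cbind(labels$singles$i, labels$singles$a)] <- lm$s_ph * col0[lm$s_idx]
  eta1 <- matrix(0, labels$o, labels$v)
  eta1[cbind(labels$singles$i, labels$singles$a)] <- lm$s_ph * row0[lm$s_idx]
  list(energy = Hbar[lm$ref, lm$ref],
       omega1 = omega1,
       omega2_full = lm$d_ph * col0[lm$d_idx],
       eta1 = eta1,
       eta2v = lm$d_ph * row0[lm$d_idx],
       label_map = lm)
}

#' Determinant-space CC2 Jacobian
#'
#' Dense Jacobian over the production label ordering, built from the
#' T1-transformed Hamiltonian matrix with the CC2 block structure: the
#' singles rows include the `[[H~,T2],tau]` terms, the doubles rows are
#' `<mu2|[H~,tau_nu1]|HF>` and the diagonal orbital-energy differences.
#'
#' @param Htilde determinant-space matrix of the T1-transformed Hamiltonian.
#' @param T2mat determinant-space matrix of T2.
#' @param basis,n_occ,labels as in [det_projections()].
#' @param eps2 vector of doubles-label orbital-energy differences.
#' @return dense matrix dim `n1 + n2`.
#' @export
det_cc2_jacobian <- function(Htilde, T2mat, basis, n_occ, labels, eps2) {
  lm <- oracle_label_map(basis, n_occ, labels)
  n1 <- labels$n1; n2 <- labels$n2
  A <- matrix(0, n1 + n2, n1 + n2)
  M11 <- Htilde + (Htilde %*% T2mat - T2mat %*% Htilde)
  h0_11 <- M11[, lm$ref]
  h0_1 <- Htilde[, lm$ref]
  # columns over nu1
  for (k in seq_len(n1)) {
    colv <- M11[, lm$s_idx[k]] * lm$s_ph[k] -
      tau_apply_vec(basis, n_occ, labels, "s", k, h0_11)
    colv2 <- Htilde[, lm$s_idx[k]] * lm$s_ph[k] -
      tau_apply_vec(basis, n_occ, labels, "s", k, h0_1)
    A[seq_len(n1), k] <- lm$s_ph * colv[lm$s_idx]
    A[n1 + seq_len(n2), k] <- lm$d_ph * colv2[lm$d_idx]
  }
  # columns over nu2: singles rows from Htilde, doubles rows diagonal eps
  for (k in seq_len(n2)) {
    colv <- Htilde[, lm$d_idx[k]] * lm$d_ph[k] -
      tau_apply_vec(basis, n_occ, labels, "d", k, h0_1)
    A[seq_len(n1), n1 + k] <- lm$s_ph * colv[lm$s_idx]
  }
  A[cbind(n1 + seq_len(n2), n1 + seq_len(n2))] <- eps2
  A
}

# apply tau_mu (single or double label k) to a coefficient vector
tau_apply_vec <- function(basis, n_occ, labels, kind, k, vec) {
  n_mo <- basis$n_spatial
  nd <- length(basis$masks)
  out <- numeric(nd)
  if (kind == "s") {
    p <- prod_so_index(n_mo, n_occ, "vir", labels$singles$a[k])
    q <- prod_so_index(n_mo, n_occ, "occ", labels$singles$i[k])
    for (I in which(vec != 0)) {
      r <- apply_pq(basis$masks[I], p, q)
      if (!is.null(r)) {
        J <- det_index(basis, r$mask)
        if (!is.na(J)) out[J] <- out[J] + r$sign * vec[I]
      }
    }
  } else {
    pa <- prod_so_index(n_mo, n_occ, "vir", labels$doubles$a[k])
    pb <- prod_so_index(n_mo, n_occ, "vir", labels$doubles$b[k])
    qi <- prod_so_index(n_mo, n_occ, "occ", labels$doubles$i[k])
    qj <- prod_so_index(n_mo, n_occ, "occ", labels$doubles$j[k])
    for (I in which(vec != 0)) {
      r1 <- apply_pq(basis$masks[I], pa, qi)
      if (is.null(r1)) next
      r2 <- apply_pq(r1$mask, pb, qj)
      if (is.null(r2)) next
      J <- det_index(basis, r2$mask)
      if (!is.na(J)) out[J] <- out[J] + r1$sign * r2$sign * vec[I]
    }
  }
  out
}

#' Determinant-space natural-projection overlap
#'
#' `O(A,B) = <R^A| P |R^B>` with `P` the projector onto the
#' reference + singles + doubles determinants and
#' `|R^K> = (r0 + R1 + R2) exp(S) |HF>` assembled explicitly.
#'
#' @param basis a [det_basis()].
#' @param n_occ occupied spatial orbitals.
#' @param Smat determinant-space cluster matrix (T1 + T2 + zeta X3).
#' @param stateA,stateB lists with `r0`, `r1`, `r2` in production storage.
#' @return scalar.
#' @export
det_overlap_value <- function(basis, n_occ, Smat, stateA, stateB) {
  eS <- matexp_nilpotent(Smat)
  e0 <- numeric(length(basis$masks)); e0[det_index(basis, basis$ref)] <- 1
  mk <- function(st) {
    R <- det_r1_matrix(basis, n_occ, st$r1) + det_r2_matrix(basis, n_occ, st$r2)
    (st$r0 * diag(nrow(R)) + R) %*% (eS %*% e0)
  }
  vA <- mk(stateA); vB <- mk(stateB)
  keep <- basis$levels <= 2L
  sum(vA[keep] * vB[keep])
}

#' Determinant-space CC2 ground-state solve
#'
#' Direct fixed-point solution of the CC2 equations using only
#' determinant-space projections (no production working equations):
#' `t2` from the T1-transformed doubles projections with diagonal
#' denominators, `t1` from the singles projections of
#' `H~ + [H~, T2]`.
#'
#' @param moints a [transform_mo_integrals()] result.
#' @param basis a [det_basis()].
#' @param labels label set matching the system.
#' @param threshold residual norm threshold.
#' @param max_iter cap.
#' @param damping step fraction for the quasi-Newton update.
#' @return list `t1_so`, `t2v` (doubles-label vector), `energy`.
#' @export
det_solve_cc2 <- function(moints, basis, labels, threshold = 1e-10,
                          max_iter = 500L, damping = 0.6) {
  n_occ <- moints$n_occ
  H <- det_hamiltonian(moints, basis)
  eps <- moints$orbital_energies
  epso <- eps[seq_len(n_occ)]; epsv <- eps[-seq_len(n_occ)]
  o <- labels$o; v <- labels$v
  eps_so_o <- c(epso, epso); eps_so_v <- c(epsv, epsv)
  d <- labels$doubles
  eps2 <- eps_so_v[d$a] + eps_so_v[d$b] - eps_so_o[d$i] - eps_so_o[d$j]
  eps1 <- outer(eps_so_o, eps_so_v, function(ei, ea) ea - ei)
  t1 <- matrix(0, o, v)
  t2v <- numeric(labels$n2)
  st <- diis_new(8)
  for (it in seq_len(max_iter)) {
    T1m <- det_r1_matrix(basis, n_occ, t1)
    Ht <- det_similarity_transform(H, T1m)
    pr <- det_projections(Ht, basis, n_occ, labels)
    t2v <- -pr$omega2_full / eps2
    T2m <- det_r2_matrix(basis, n_occ, vec_to_r2(t2v, labels))
    M <- Ht + (Ht %*% T2m - T2m %*% Ht)
    pr2 <- det_projections(M, basis, n_occ, labels)
    om1 <- pr2$omega1
    if (sqrt(sum(om1^2)) <= threshold) break
    t1_new <- t1 - damping * om1 / eps1
    t1 <- matrix(diis_update(st, as.numeric(t1_new), as.numeric(om1)), o, v)
  }
  T1m <- det_r1_matrix(basis, n_occ, t1)
  Ht <- det_similarity_transform(H, T1m)
  T2m <- det_r2_matrix(basis, n_occ, vec_to_r2(t2v, labels))
  M <- Ht + (Ht %*% T2m - T2m %*% Ht)
  list(t1_so = t1, t2v = t2v, energy = M[det_index(basis, basis$ref),
                                         det_index(basis, basis$ref)],
       hamiltonian = H)
}
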
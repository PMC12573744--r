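# The coupled SCC2 solver.
#
# Structure of the problem: the doubles equations and the excited-state
# equations are identical to CC2 at the SCC2 ground amplitudes, and the
# constraint operator zeta*X3 enters only the singles amplitude equation.
# The orthogonality O(A,B) depends on zeta solely through the converged
# t1.  The solver exploits this: the two constrained eigenpairs are
# re-solved exactly (dense folded solve in the singlet singles space) at
# every amplitude iteration, the singles equation is converged by DIIS at
# fixed zeta, and the scalar orthogonality condition is driven to zero by
# a secant iteration in zeta.  At convergence all four residual classes
# (singles residual, two eigen-residuals, orthogonality) are below
# threshold.

# Matrix realization of the folded singlet problem:
# M(omega) = A11 + A12 diag(1/(omega - eps)) A21 over the spatial singlet
# singles basis, with A12/A21 stored as dense (small) matrices over the
# Sz = 0 doubles labels so that each omega update is a single product.
folded_workspace <- function(model) {
  maps <- model$sov$maps
  lb <- model$labels
  sov <- model$sov
  o <- maps$o %/% 2L; v <- maps$v %/% 2L
  o2 <- maps$o; v2 <- maps$v
  n <- o * v
  # A11 over the spin-orbital singles, assembled directly from tensors:
  # Z[i,a,j,b] = <ai|[H~ + [[U~,T2],.], tau_bj]|HF>
  g <- sov$g_oovv
  Fvv <- sov$f_vv - 0.5 * tc(model$t2, g, c(3, 4, 2), c(1, 2, 4))
  Foo <- sov$f_oo + 0.5 * tc(g, model$t2, c(2, 3, 4), c(4, 1, 2))
  W <- tc(g, model$t2, c(2, 4), c(4, 2))            # [j,b,a,i]
  Z <- aperm(sov$g_voov, c(3, 1, 2, 4)) + aperm(W, c(4, 3, 1, 2))
  for (i in seq_len(o2)) Z[i, , i, ] <- Z[i, , i, ] + Fvv
  for (a in seq_len(v2)) Z[, a, , a] <- Z[, a, , a] - t(Foo)
  io <- seq_len(o); iv <- seq_len(v)
  A11arr <- 0.5 * (Z[io, iv, io, iv, drop = FALSE] +
                     Z[io, iv, o + io, v + iv, drop = FALSE] +
                     Z[o + io, v + iv, io, iv, drop = FALSE] +
                     Z[o + io, v + iv, o + io, v + iv, drop = FALSE])
  A11 <- matrix(A11arr, n, n)
  A21m <- matrix(0, lb$n2, n)
  A12m <- matrix(0, n, lb$n2)
  for (k in seq_len(n)) {
    e <- matrix(0, o, v); e[k] <- 1
    e_so <- singlet_embed(e, maps)
    A21m[, k] <- r2_to_vec(a21_apply(sov, e_so), lb)
    A12m[k, ] <- r2_to_vec(sfd_transpose(sov, e_so), lb)
  }
  eps2v <- r2_to_vec(model$eps2, lb)
  list(A11 = A11, A12 = A12m, A21 = A21m, eps2v = eps2v,
       o = o, v = v, maps = maps)
}

folded_matrix <- function(ws, model, omega) {
  ws$A11 + ws$A12 %*% (ws$A21 / (omega - ws$eps2v))
}

# self-consistent folded root followed by overlap with ref_vec (spatial).
# `exclude` (eigenvalue + vector of an already-assigned root) prevents two
# tracked states from collapsing onto the same eigenvector near a
# degeneracy: a candidate duplicating the excluded root is passed over for
# the next-best overlap.
sc_folded_root <- function(ws, model, omega0, ref_vec, relax = 0.5,
                           tol = 1e-9, max_cycle = 50L, exclude = NULL) {
  omega <- omega0
  vec <- as.numeric(ref_vec)
  lambda <- omega0
  pick <- function(ed) {
    ov <- abs(t(Conj(ed$vectors)) %*% vec)
    ord <- order(ov, decreasing = TRUE)
    for (k in ord) {
      if (!is.null(exclude)) {
        dup <- abs(ed$values[k] - exclude$lambda) < 1e-9 &&
          abs(sum(Conj(ed$vectors[, k]) * exclude$vec)) > 0.9999
        if (dup) next
      }
      return(k)
    }
    ord[1]
  }
  v <- NULL
  for (cyc in seq_len(max_cycle)) {
    M <- folded_matrix(ws, model, omega)
    ed <- eigen(M)
    k <- pick(ed)
    lambda <- ed$values[k]
    v <- ed$vectors[, k]
    omega_new <- Re(lambda)
    if (abs(omega_new - omega) < tol) {
      return(list(omega = lambda, vec = v, cycles = cyc, converged = TRUE))
    }
    omega <- omega + relax * (omega_new - omega)
    if (max(abs(Im(v))) < 1e-10) vec <- Re(v) / sqrt(sum(Re(v)^2))
  }
  list(omega = lambda, vec = v, cycles = max_cycle, converged = FALSE)
}

# assemble a full production state from a folded singlet singles vector
unfold_state <- function(model, omega_re, vec_sp, eta) {
  maps <- model$sov$maps
  r1_sp <- matrix(vec_sp, maps$o %/% 2L, maps$v %/% 2L)
  r1_so <- singlet_embed(r1_sp, maps)
  r2 <- a21_apply(model$sov, r1_so) / (omega_re - model$eps2)
  nrm <- state_norm(r1_so, r2)
  r1_so <- r1_so / nrm; r2 <- r2 / nrm
  pf <- phase_fix(r1_so, r2)
  r0 <- ground_contribution(eta, pf$r1, pf$r2, omega_re)
  structure(list(omega = omega_re, r1 = pf$r1, r2 = pf$r2, r0 = r0,
                 side = "right", spin = "singlet",
                 norm_convention = "unit-2-norm"),
            class = "eom_state")
}

# solve the two tracked constrained states for the current amplitudes;
# complex pairs are realified onto the invariant subspace (transient
# situation inside a CC2 defect region: the converged SCC2 states are real)
solve_pair <- function(model, ws, track, eta) {
  sA <- sc_folded_root(ws, model, track$omegaA, track$refA)
  sB <- sc_folded_root(ws, model, track$omegaB, track$refB,
                       exclude = list(lambda = sA$omega,
                                      vec = sA$vec / sqrt(sum(abs(sA$vec)^2))))
  complex_pair <- (abs(Im(sA$omega)) > 1e-9) || (abs(Im(sB$omega)) > 1e-9)
  if (complex_pair) {
    v <- if (abs(Im(sA$omega)) > 1e-9) sA$vec else sB$vec
    om <- if (abs(Im(sA$omega)) > 1e-9) Re(sA$omega) else Re(sB$omega)
    vr <- Re(v); vi <- Im(v)
    vr <- vr / sqrt(sum(vr^2))
    vi <- vi - vr * sum(vr * vi)
    vi <- vi / sqrt(sum(vi^2))
    # align the realified pair with the tracked references
    if (abs(sum(vr * as.numeric(track$refB))) > abs(sum(vr * as.numeric(track$refA)))) {
      tmp <- vr; vr <- vi; vi <- tmp
    }
    stA <- unfold_state(model, om, vr, eta)
    stB <- unfold_state(model, om, vi, eta)
  } else {
    stA <- unfold_state(model, Re(sA$omega), Re(sA$vec), eta)
    stB <- unfold_state(model, Re(sB$omega), Re(sB$vec), eta)
  }
  list(A = stA, B = stB, complex_pair = complex_pair,
       convergedA = sA$converged, convergedB = sB$converged)
}

#' Solve the coupled SCC2 equations
#'
#' Simultaneous solution of the SCC2 ground-state amplitude equations, the
#' two constrained right eigenproblems and the orthogonality condition
#' `O(A,B) = 0` under the natural projection.  Starting from a CC2 solution
#' the constraint strength is initialized at `zeta = 0`; restarts from a
#' neighboring geometry pass amplitudes, `zeta` and tracking vectors
#' through `guess`.
#'
#' @param moints a [transform_mo_integrals()] result.
#' @param select indices (among singlet CC2 states, ascending energy) of
#'   the two states to constrain, used at the initial geometry.
#' @param threshold residual threshold applied to all residual classes.
#' @param max_iter cap for the singles DIIS loop (per zeta value).
#' @param max_zeta_iter cap for the secant iteration on zeta.
#' @param guess optional restart: list with `t1`, `zeta`, `refA`, `refB`,
#'   `omegaA`, `omegaB`.
#' @param constrain set `FALSE` to drop the orthogonality equation (the
#'   solver then reproduces plain CC2 with `zeta = 0`).
#' @return object of class `"scc2_solution"`.
#' @export
solve_scc2 <- function(moints, select = c(1L, 2L), threshold = 1e-8,
                       max_iter = 200L, max_zeta_iter = 30L,
                       guess = NULL, constrain = TRUE) {
  o <- moints$n_occ; v <- moints$n_mo - moints$n_occ
  eps <- moints$orbital_energies
  D1 <- outer(eps[seq_len(o)], eps[o + seq_len(v)], "-")

  # --- initial CC2 solution and state selection ------------------------------
  if (is.null(guess)) {
    cc <- solve_cc2_ground(moints, threshold = threshold)
    t1 <- cc$t1
    model0 <- jacobian_model(cc$dressed, cc$t2)
    sts <- solve_right_states(model0, n_states = max(select) + 2L,
                              method = "dense", spin = "singlet",
                              eta = cc$eta)
    if (length(sts) < max(select))
      stop("fewer singlet states available than requested by `select`")
    stA0 <- sts[[select[1]]]; stB0 <- sts[[select[2]]]
    maps <- model0$sov$maps
    track <- list(refA = singlet_extract(Re(stA0$r1), maps),
                  refB = singlet_extract(Re(stB0$r1), maps),
                  omegaA = Re(stA0$omega), omegaB = Re(stB0$omega))
    zeta <- 0
  } else {
    t1 <- guess$t1
    zeta <- guess$zeta %||% 0
    track <- list(refA = guess$refA, refB = guess$refB,
                  omegaA = guess$omegaA, omegaB = guess$omegaB)
  }
  nrmz <- function(m) m / sqrt(sum(m^2))
  track$refA <- nrmz(track$refA); track$refB <- nrmz(track$refB)

  # --- inner solve: converge t1 at fixed zeta --------------------------------
  inner_threshold <- max(min(threshold, threshold * 1e-3), 1e-12)
  state_env <- new.env(parent = emptyenv())
  inner_solve <- function(t1_init, zeta) {
    t1 <- t1_init
    st <- diis_new(8)
    hist <- numeric(0)
    tr <- track   # local homing state: follows the pair within this solve
    for (it in seq_len(max_iter)) {
      dressed <- dress_integrals(moints, t1)
      t2 <- compute_t2(dressed)$t2
      model <- jacobian_model(dressed, t2)
      ws <- folded_workspace(model)
      eta <- eta_vector(dressed)
      pair <- solve_pair(model, ws, tr, eta)
      maps <- model$sov$maps
      # enforce assignment continuity: near a degeneracy the two homing
      # targets can legitimately rotate past each other between iterations;
      # an alternating A/B swap flips the antisymmetric X3 and stalls the
      # solve, so keep whichever permutation overlaps the previous iterate
      vA <- singlet_extract(pair$A$r1, maps); vB <- singlet_extract(pair$B$r1, maps)
      if (abs(sum(vA * tr$refB)) + abs(sum(vB * tr$refA)) >
          abs(sum(vA * tr$refA)) + abs(sum(vB * tr$refB))) {
        tmp <- pair$A; pair$A <- pair$B; pair$B <- tmp
      }
      # sign-align both states with the running references: the absolute
      # phase convention can flip when the dominant amplitude migrates,
      # which would flip X3 and destabilize the iteration near a seam
      for (nm in c("A", "B")) {
        ref <- if (nm == "A") tr$refA else tr$refB
        if (sum(singlet_extract(pair[[nm]]$r1, maps) * ref) < 0) {
          pair[[nm]]$r1 <- -pair[[nm]]$r1
          pair[[nm]]$r2 <- -pair[[nm]]$r2
          pair[[nm]]$r0 <- -pair[[nm]]$r0
        }
      }
      # adaptive rotation damping: within ~1e-4 hartree of a degeneracy the
      # eigenvectors rotate strongly under tiny amplitude updates, which
      # makes the residual map stiff; blending the new state with the
      # previous iterate removes the oscillation without moving the fixed
      # point (at convergence the rotation vanishes and the states are the
      # exact eigenvectors)
      for (nm in c("A", "B")) {
        ref <- if (nm == "A") tr$refA else tr$refB
        vnew <- nrmz(singlet_extract(pair[[nm]]$r1, maps))
        ov <- sum(vnew * ref)
        if (it > 1L && ov < 0.995) {
          alpha <- max(0.25, ov)
          vb <- nrmz((1 - alpha) * ref + alpha * vnew)
          pair[[nm]] <- unfold_state(model, pair[[nm]]$omega, vb, eta)
        }
      }
      tr$refA <- nrmz(singlet_extract(pair$A$r1, maps))
      tr$refB <- nrmz(singlet_extract(pair$B$r1, maps))
      tr$omegaA <- pair$A$omega
      tr$omegaB <- pair$B$omega
      x3 <- build_x3(pair$A, pair$B)
      om_so <- singles_residual(dressed, t2)
      if (zeta != 0) om_so <- om_so + scc_singles_correction(dressed, x3, zeta)
      om_sp <- so_collapse_singles(om_so, maps)
      res <- sqrt(sum(om_so^2))
      hist <- c(hist, res)
      state_env$last <- list(dressed = dressed, t2 = t2, model = model,
                             eta = eta, pair = pair, t1 = t1,
                             residual = res, iterations = it,
                             history = hist)
      if (res <= inner_threshold) break
      t1_new <- t1 + om_sp / D1
      t1 <- matrix(diis_update(st, as.numeric(t1_new), as.numeric(om_sp)), o, v)
    }
    if (res > inner_threshold)
      stop(sprintf("SCC2 singles equations did not converge (zeta = %.6g); residual history: %s",
                   zeta, paste(sprintf("%.2e", utils::tail(hist, 6)), collapse = " ")))
    last <- state_env$last
    maps <- last$model$sov$maps
    t1_so <- so_expand_singles(last$t1, maps)
    O <- orthogonality_value(t1_so, last$t2, last$pair$A, last$pair$B)
    list(t1 = last$t1, O = O, last = last,
         complex_pair = last$pair$complex_pair)
  }

  # --- outer iteration on zeta -----------------------------------------------
  # The orthogonality value is only meaningful on the branch where the
  # tracked pair is real.  Inside a CC2 defect region the pair at zeta = 0
  # is complex; zeta is then marched outward until it splits real (past the
  # exceptional point) before the root of O(zeta) is bracketed and refined
  # by secant/bisection steps restricted to the real branch.
  zeta0_init <- zeta
  sol <- inner_solve(t1, zeta)
  history <- data.frame(zeta = zeta, O = sol$O,
                        complex = sol$complex_pair,
                        residual = sol$last$residual)
  record <- function(z, s) history <<- rbind(history,
    data.frame(zeta = z, O = s$O, complex = s$complex_pair,
               residual = s$last$residual))
  try_eval <- function(z, t1_start) {
    out <- tryCatch(inner_solve(t1_start, z), error = function(e) NULL)
    if (!is.null(out)) {
      # propagate homing state only from converged solves, so transient
      # wrong-root picks cannot ratchet the tracking onto another state
      pair <- out$last$pair
      maps <- out$last$model$sov$maps
      track$refA <<- nrmz(singlet_extract(pair$A$r1, maps))
      track$refB <<- nrmz(singlet_extract(pair$B$r1, maps))
      track$omegaA <<- pair$A$omega
      track$omegaB <<- pair$B$omega
    }
    out
  }
  if (constrain && (sol$complex_pair || abs(sol$O) > threshold)) {
    # march to the real branch if needed
    pts <- list(list(zeta = zeta, s = sol))
    if (sol$complex_pair) {
      # continuation march: warm-start each zeta from the last converged
      # amplitudes, halving the step whenever the inner solve fails (the
      # region around the exceptional point is the delicate part)
      found <- FALSE
      for (dir in c(-1, 1)) {
        step <- 0.2; z <- zeta; cur <- sol
        for (m in 1:16) {
          z <- z + dir * step
          step <- step * 1.5
          cand <- try_eval(z, cur$t1)
          if (is.null(cand)) next  # jump over inner-solve failure bands
          cur <- cand
          record(z, cand)
          pts[[length(pts) + 1L]] <- list(zeta = z, s = cand)
          if (!cand$complex_pair) { found <- TRUE; break }
          if (abs(z) > 30) break
        }
        if (found) break
      }
      if (!found)
        stop("SCC2: no real-branch zeta found within the search window")
      # keep only real-branch points for the root search
      pts <- Filter(function(p) !p$s$complex_pair, pts)
    }
    # root refinement on the real branch: adaptive secant with bracket
    # safeguards.  Warm restarts (small |O|) take a small probe step and
    # converge in two or three evaluations; cold starts march until a sign
    # change brackets the root.  If one search direction dead-ends against
    # a complex pocket, the mirror direction is tried (solutions come in
    # (zeta, A, B) <-> (-zeta, B, A) pairs).
    base <- pts[[length(pts)]]
    sol <- base$s; zeta <- base$zeta
    if (abs(sol$O) > threshold) {
      refine <- function(dir0) {
        lo <- NULL; hi <- NULL   # bracket endpoints (opposite O signs)
        upd_bracket <- function(pnew) {
          if (pnew$s$complex_pair) return()
          if (is.null(lo)) { lo <<- pnew; return() }
          if (sign(pnew$s$O) == sign(lo$s$O)) lo <<- pnew
          else if (is.null(hi)) hi <<- pnew
          else if (sign(pnew$s$O) == sign(hi$s$O)) hi <<- pnew
        }
        upd_bracket(base)
        delta <- dir0 * max(1e-3, min(0.1, 0.02 * abs(base$zeta)))
        p1 <- base
        cand <- try_eval(base$zeta + delta, base$s$t1)
        if (is.null(cand))
          stop("SCC2: inner solve failed while probing the orthogonality slope")
        record(base$zeta + delta, cand)
        p2 <- list(zeta = base$zeta + delta, s = cand)
        upd_bracket(p2)
        best <- if (base$s$complex_pair) NULL else base
        for (zit in seq_len(max_zeta_iter)) {
          if (!p2$s$complex_pair &&
              (is.null(best) || abs(p2$s$O) < abs(best$s$O))) best <- p2
          if (!p2$s$complex_pair && abs(p2$s$O) <= threshold) break
          zs <- NA_real_
          if (!p1$s$complex_pair && !p2$s$complex_pair && p2$s$O != p1$s$O)
            zs <- p2$zeta - p2$s$O * (p2$zeta - p1$zeta) / (p2$s$O - p1$s$O)
          if (is.finite(zs)) {
            # cap the step; keep inside the bracket when one exists
            zs <- p2$zeta + sign(zs - p2$zeta) * min(abs(zs - p2$zeta), 0.5)
            if (!is.null(lo) && !is.null(hi) &&
                (zs <= min(lo$zeta, hi$zeta) || zs >= max(lo$zeta, hi$zeta)))
              zs <- (lo$zeta + hi$zeta) / 2
          } else if (!is.null(lo) && !is.null(hi)) {
            zs <- (lo$zeta + hi$zeta) / 2
          } else {
            zs <- p2$zeta + dir0 * 0.15 * 1.4^zit  # no slope yet: march
          }
          # evaluate; when the proposal lands in a complex pocket or the
          # inner solve fails, first try jumping past the pocket, then back
          # off toward the last good real point
          cand <- NULL
          zs_jump <- zs
          for (attempt in 1:8) {
            cand <- try_eval(zs, p2$s$t1)
            if (!is.null(cand) && !cand$complex_pair) break
            if (!is.null(cand)) record(zs, cand)
            if (attempt <= 2 && is.null(hi)) {
              zs_jump <- zs_jump + (zs_jump - p2$zeta)   # double away
              zs <- zs_jump
            } else if (!is.null(lo) && !is.null(hi)) {
              zs <- (lo$zeta + hi$zeta) / 2
            } else {
              zs <- (zs + p2$zeta) / 2
            }
          }
          if (is.null(cand) || cand$complex_pair)
            stop("SCC2: refinement dead-ended against a complex pocket")
          record(zs, cand)
          pnew <- list(zeta = zs, s = cand)
          upd_bracket(pnew)
          if (abs(zs) > 100 && abs(cand$O - base$s$O) < 1e-10 * (1 + abs(base$s$O)))
            stop(sprintf(paste0("orthogonality condition unresponsive to zeta ",
                                "(O = %.3e flat out to zeta = %.3g): the constraint ",
                                "operator has no leverage on this state pair"),
                         cand$O, zs))
          p1 <- p2; p2 <- pnew
        }
        if (!is.null(best) && abs(best$s$O) <= threshold)
          return(list(sol = best$s, zeta = best$zeta))
        stop(sprintf("orthogonality condition not converged: |O| = %.3e after %d zeta iterations; recent (zeta, O, complex): %s",
                     if (is.null(best)) NA_real_ else abs(best$s$O), max_zeta_iter,
                     paste(apply(utils::tail(history, 8), 1, function(r)
                       sprintf("(%.4g, %.2e, %s)", as.numeric(r[1]),
                               as.numeric(r[2]), r[3])), collapse = " ")))
      }
      dir0 <- sign(base$zeta - zeta0_init); if (dir0 == 0) dir0 <- 1
      res1 <- tryCatch(refine(dir0), error = function(e) e)
      if (inherits(res1, "error"))
        res1 <- tryCatch(refine(-dir0), error = function(e) e)
      if (inherits(res1, "error")) stop(res1)
      sol <- res1$sol; zeta <- res1$zeta
    }
  }

  last <- sol$last
  structure(list(t1 = sol$t1, t2 = last$t2, zeta = zeta,
                 state_A = last$pair$A, state_B = last$pair$B,
                 energy = ground_energy(last$dressed, last$t2),
                 omega_A = last$pair$A$omega, omega_B = last$pair$B$omega,
                 orthogonality_residual = abs(sol$O),
                 singles_residual_norm = last$residual,
                 convergence = history,
                 dressed = last$dressed, eta = last$eta,
                 moints = moints),
            class = "scc2_solution")
}

#' @export
print.scc2_solution <- function(x, ...) {
  cat("SCC2 solution\n")
  cat(sprintf("  E0      = %.10f hartree\n", x$energy))
  cat(sprintf("  omega_A = %.8f hartree (%.4f eV)\n",
              x$omega_A, x$omega_A * HARTREE_EV))
  cat(sprintf("  omega_B = %.8f hartree (%.4f eV)\n",
              x$omega_B, x$omega_B * HARTREE_EV))
  cat(sprintf("  zeta    = %.8g   |O(A,B)| = %.3e   |Omega1| = %.3e\n",
              x$zeta, x$orthogonality_residual, x$singles_residual_norm))
  invisible(x)
}
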
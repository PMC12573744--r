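# High-level fitting interface: one call from a geometry to a converged
# CC2 or SCC2 calculation, returning a classed object with the usual
# accessor methods.

#' Fit the CC2 model to a molecule
#'
#' Runs SCF, MO transformation, the CC2 ground-state solve and (optionally)
#' the EOM-CC2 excited states in one call.
#'
#' @param geom a [geometry()].
#' @param basis basis-set name (see [available_bases()]).
#' @param n_states number of excited states to compute (0 for ground state
#'   only).
#' @param method eigensolver path, `"dense"` or `"davidson"`.
#' @param spin which excited states to report (dense path).
#' @param threshold residual convergence threshold.
#' @return object of class `"cc2"` with components `scf`, `moints`,
#'   `ground` (class `"cc2_ground"`), `states` (list of `"eom_state"`).
#' @examples
#' \donttest{
#' fit <- cc2(make_h2_geometry(0.74), "sto-3g", n_states = 2)
#' summary(fit)
#' }
#' @export
cc2 <- function(geom, basis = "sto-3g", n_states = 0L,
                method = c("dense", "davidson"), spin = "singlet",
                threshold = 1e-8) {
  method <- match.arg(method)
  ao <- compute_ao_integrals(geom, basis)
  ref <- solve_rhf(ao, threshold = min(1e-9, threshold))
  mo <- transform_mo_integrals(ao, ref)
  gs <- solve_cc2_ground(mo, threshold = threshold)
  states <- list()
  if (n_states > 0L) {
    model <- jacobian_model(gs$dressed, gs$t2)
    states <- solve_right_states(model, n_states = n_states, method = method,
                                 spin = spin, eta = gs$eta)
  }
  structure(list(geometry = geom, basis = basis, scf = ref, moints = mo,
                 ground = gs, states = states, threshold = threshold),
            class = "cc2")
}

#' Fit the SCC2 model to a molecule
#'
#' As [cc2()], but solves the similarity-constrained equations for two
#' target states whose orthogonality under the natural projection is
#' enforced, yielding real excitation energies with correct intersection
#' topology.
#'
#' @inheritParams cc2
#' @param select indices of the two constrained singlet states at this
#'   geometry.
#' @param guess restart information from a neighboring geometry (see
#'   [solve_scc2()]).
#' @return object of class `"scc2"` with `solution` (class
#'   `"scc2_solution"`).
#' @export
scc2 <- function(geom, basis = "sto-3g", select = c(1L, 2L),
                 threshold = 1e-8, guess = NULL) {
  ao <- compute_ao_integrals(geom, basis)
  ref <- solve_rhf(ao, threshold = min(1e-9, threshold))
  mo <- transform_mo_integrals(ao, ref)
  sol <- solve_scc2(mo, select = select, threshold = threshold, guess = guess)
  structure(list(geometry = geom, basis = basis, scf = ref, moints = mo,
                 solution = sol, threshold = threshold),
            class = "scc2")
}

#' @export
print.cc2 <- function(x, ...) {
  cat(sprintf("CC2/%s fit\n", x$basis))
  cat(sprintf("  E(HF)  = %.10f hartree\n", x$scf$hf_energy))
  cat(sprintf("  E(CC2) = %.10f hartree\n", x$ground$energy))
  for (k in seq_along(x$states)) {
    om <- x$states[[k]]$omega
    if (is.complex(om) && abs(Im(om)) > 1e-10)
      cat(sprintf("  omega_%d = %.6f %+.6fi hartree (complex pair)\n",
                  k, Re(om), Im(om)))
    else
      cat(sprintf("  omega_%d = %.6f hartree = %.4f eV\n",
                  k, Re(om), Re(om) * HARTREE_EV))
  }
  invisible(x)
}

#' @export
summary.cc2 <- function(object, ...) {
  x <- object
  cat(sprintf("CC2/%s: %d AOs, %d electrons\n", x$basis, x$moints$n_mo,
              2L * x$moints$n_occ))
  cat(sprintf("  E(HF)   = %16.10f hartree\n", x$scf$hf_energy))
  cat(sprintf("  E(corr) = %16.10f hartree\n", x$ground$energy - x$scf$hf_energy))
  cat(sprintf("  E(CC2)  = %16.10f hartree  (%d iterations)\n",
              x$ground$energy, x$ground$iterations))
  if (length(x$states) > 0) {
    cat("  excited states:\n")
    for (k in seq_along(x$states)) {
      st <- x$states[[k]]
      if (is.complex(st$omega) && abs(Im(st$omega)) > 1e-10)
        cat(sprintf("    %d: %.6f %+.6fi hartree  COMPLEX  [%s]\n",
                    k, Re(st$omega), Im(st$omega), st$spin %||% "?"))
      else
        cat(sprintf("    %d: %10.6f hartree = %8.4f eV  [%s]  r0 = %.3g\n",
                    k, Re(st$omega), Re(st$omega) * HARTREE_EV,
                    st$spin %||% "?", st$r0 %||% NA_real_))
    }
  }
  invisible(x)
}

#' @export
print.scc2 <- function(x, ...) {
  cat(sprintf("SCC2/%s fit\n", x$basis))
  print(x$solution)
  invisible(x)
}

#' @export
coef.cc2 <- function(object, ...) {
  list(t1 = object$ground$t1, t2 = object$ground$t2)
}

#' @export
coef.scc2 <- function(object, ...) {
  list(t1 = object$solution$t1, t2 = object$solution$t2,
       zeta = object$solution$zeta)
}

#' Excitation energies of a fit
#'
#' @param object a `"cc2"` or `"scc2"` fit.
#' @param unit `"hartree"` or `"ev"`.
#' @param ... unused.
#' @return complex (CC2, possibly with nonzero imaginary parts) or numeric
#'   vector of excitation energies.
#' @export
excitation_energies <- function(object, unit = c("hartree", "ev"), ...) {
  unit <- match.arg(unit)
  fac <- if (unit == "ev") HARTREE_EV else 1
  if (inherits(object, "cc2"))
    return(vapply(object$states, function(s) as.complex(s$omega), complex(1)) * fac)
  if (inherits(object, "scc2"))
    return(c(A = object$solution$omega_A, B = object$solution$omega_B) * fac)
  stop("unsupported object")
}
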
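# internal helpers: unit constants, tensor contraction, DIIS

BOHR <- 0.52917721092       # Angstrom per bohr
HARTREE_EV <- 27.211386245988

ang_to_bohr <- function(x) x / BOHR
bohr_to_ang <- function(x) x * BOHR

#' General pairwise tensor contraction
#'
#' Contracts the axes `axA` of array `A` against the axes `axB` of array `B`
#' (matched in order).  The result carries the free axes of `A` followed by
#' the free axes of `B`.  This is the only contraction primitive used by the
#' working equations.
#'
#' @param A,B numeric arrays (vectors and matrices are promoted).
#' @param axA,axB integer vectors of axes to contract, equal lengths.
#' @return numeric array of the free dimensions (a scalar if none remain).
#' @keywords internal
#' @noRd
tc <- function(A, B, axA, axB) {
  dA <- dim(A); if (is.null(dA)) dA <- length(A)
  dB <- dim(B); if (is.null(dB)) dB <- length(B)
  freeA <- setdiff(seq_along(dA), axA)
  freeB <- setdiff(seq_along(dB), axB)
  Ap <- aperm(array(A, dA), c(freeA, axA))
  Bp <- aperm(array(B, dB), c(axB, freeB))
  m <- prod(dA[freeA]); k <- prod(dA[axA]); n <- prod(dB[freeB])
  stopifnot(k == prod(dB[axB]))
  M <- matrix(Ap, m, k) %*% matrix(Bp, k, n)
  dout <- c(dA[freeA], dB[freeB])
  if (length(dout) == 0) return(as.numeric(M))
  array(M, dout)
}

# Pulay DIIS extrapolation over flattened parameter/error vectors.
# Subspace capped at `size`; restarts when the B matrix becomes
# ill-conditioned (condition number > 1e12).
diis_new <- function(size = 8) {
  env <- new.env(parent = emptyenv())
  env$size <- size
  env$params <- list()
  env$errors <- list()
  env
}

diis_update <- function(st, param, error) {
  st$params[[length(st$params) + 1L]] <- param
  st$errors[[length(st$errors) + 1L]] <- error
  if (length(st$params) > st$size) {
    st$params <- st$params[-1L]
    st$errors <- st$errors[-1L]
  }
  n <- length(st$params)
  if (n < 2L) return(param)
  B <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(i)) {
    B[i, j] <- B[j, i] <- sum(st$errors[[i]] * st$errors[[j]])
  }
  A <- rbind(cbind(B, -1), c(rep(-1, n), 0))
  rhs <- c(rep(0, n), -1)
  kap <- tryCatch(kappa(A, exact = FALSE), error = function(e) Inf)
  if (!is.finite(kap) || kap > 1e12) {
    keep <- n
    st$params <- st$params[keep]
    st$errors <- st$errors[keep]
    return(param)
  }
  cf <- tryCatch(solve(A, rhs), error = function(e) NULL)
  if (is.null(cf)) return(param)
  w <- cf[seq_len(n)]
  out <- 0
  for (i in seq_len(n)) out <- out + w[i] * st$params[[i]]
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
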
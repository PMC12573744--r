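# Surface scans and intersection topology: grid drivers over internal
# coordinates or branching-plane displacements, complex-region detection,
# derivative-free intersection location and linear-lifting metrics.

#' Configure a potential-energy-surface scan
#'
#' A scan is defined by a geometry-generating function over two grid
#' variables (internal coordinates, or dimensionless multipliers of two
#' Cartesian displacement vectors for gh-plane scans) and a method.
#'
#' @param geometry_fn function `(x, y) -> geometry`.
#' @param xgrid,ygrid numeric grid vectors (length >= 1).
#' @param method `"cc2"` or `"scc2"`.
#' @param basis basis-set name.
#' @param n_states states of interest (cc2) / constrained pair indices
#'   (scc2, length 2).
#' @param threshold residual threshold for all solvers.
#' @param restart `"chain"` to warm-start each point from its converged
#'   neighbor (with MO-sign alignment), `"cold"` otherwise.
#' @return object of class `"scan_config"`.
#' @export
scan_config <- function(geometry_fn, xgrid, ygrid, method = c("cc2", "scc2"),
                        basis = "sto-3g", n_states = c(1L, 2L),
                        threshold = 1e-8, restart = c("chain", "cold")) {
  method <- match.arg(method)
  restart <- match.arg(restart)
  if (length(xgrid) < 1L || length(ygrid) < 1L) stop("empty grid")
  structure(list(geometry_fn = geometry_fn, xgrid = xgrid, ygrid = ygrid,
                 method = method, basis = basis, n_states = n_states,
                 threshold = threshold, restart = restart),
            class = "scan_config")
}

#' Run a two-dimensional surface scan
#'
#' One record per grid point: ground-state energy, real and imaginary
#' excitation-energy components per tracked state, `zeta` for SCC2 runs and
#' a convergence flag.  Failures at individual points are recorded, not
#' fatal; the run errors only if no point converges.
#'
#' @param config a [scan_config()].
#' @param verbose print per-point progress.
#' @return data.frame of class `"scan_records"`.
#' @export
run_scan <- function(config, verbose = FALSE) {
  rows <- list()
  guess <- NULL
  n_st <- if (config$method == "scc2") 2L else max(config$n_states)
  for (ix in seq_along(config$xgrid)) {
    guess_row <- NULL
    for (iy in seq_along(config$ygrid)) {
      x <- config$xgrid[ix]; y <- config$ygrid[iy]
      g <- config$geometry_fn(x, y)
      use_guess <- if (config$restart == "chain") {
        if (iy == 1L) guess_row else guess
      } else NULL
      rec <- tryCatch(
        scan_point(g, config, use_guess),
        error = function(e) list(error = conditionMessage(e)))
      if (is.null(rec$error)) {
        guess <- rec$guess
        if (iy == 1L) guess_row <- rec$guess
        row <- data.frame(x = x, y = y, e0 = rec$e0,
                          converged = TRUE, zeta = rec$zeta %||% NA_real_)
        for (k in seq_len(n_st)) {
          row[[paste0("re_omega_", k)]] <- Re(rec$omega[k])
          row[[paste0("im_omega_", k)]] <- Im(rec$omega[k])
        }
        if (verbose)
          message(sprintf("(%g, %g): E0 = %.8f, omega = %s", x, y, rec$e0,
                          paste(sprintf("%.6f%+.2ei", Re(rec$omega),
                                        Im(rec$omega)), collapse = " ")))
      } else {
        row <- data.frame(x = x, y = y, e0 = NA_real_,
                          converged = FALSE, zeta = NA_real_)
        for (k in seq_len(n_st)) {
          row[[paste0("re_omega_", k)]] <- NA_real_
          row[[paste0("im_omega_", k)]] <- NA_real_
        }
        if (verbose) message(sprintf("(%g, %g): FAILED (%s)", x, y, rec$error))
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  if (!any(out$converged)) stop("scan failed: no grid point converged")
  class(out) <- c("scan_records", "data.frame")
  attr(out, "method") <- config$method
  out
}

scan_point <- function(geom, config, guess) {
  ao <- compute_ao_integrals(geom, config$basis)
  ref <- solve_rhf(ao, threshold = min(1e-9, config$threshold))
  mo <- transform_mo_integrals(ao, ref)
  if (config$method == "cc2") {
    gs <- solve_cc2_ground(mo, threshold = config$threshold,
                           t1_init = guess$t1)
    model <- jacobian_model(gs$dressed, gs$t2)
    sts <- solve_right_states(model, n_states = max(config$n_states),
                              method = "dense", spin = "singlet",
                              eta = gs$eta)
    om <- vapply(sts, function(s) as.complex(s$omega), complex(1))
    list(e0 = gs$energy, omega = om[config$n_states],
         guess = list(t1 = gs$t1), zeta = NA_real_)
  } else {
    sol <- solve_scc2(mo, select = config$n_states,
                      threshold = config$threshold, guess = guess$scc2)
    maps <- so_maps(mo$n_mo, mo$n_occ)
    list(e0 = sol$energy,
         omega = complex(real = c(sol$omega_A, sol$omega_B), imaginary = 0),
         zeta = sol$zeta,
         guess = list(t1 = sol$t1,
                      scc2 = list(t1 = sol$t1, zeta = sol$zeta,
                                  refA = singlet_extract(sol$state_A$r1, maps),
                                  refB = singlet_extract(sol$state_B$r1, maps),
                                  omegaA = sol$omega_A,
                                  omegaB = sol$omega_B)))
  }
}

#' Detect complex-eigenvalue regions in scan records
#'
#' Flags grid points where the tracked pair carries a nonzero imaginary
#' component and groups flagged points into 4-connected regions.
#'
#' @param records a [run_scan()] result (cc2).
#' @param threshold imaginary-part magnitude (hartree) above which a point
#'   is inside the defect region.
#' @return list `mask` (logical vector over records), `regions` (integer
#'   region id per record, 0 outside), `n_regions`.
#' @export
detect_complex_region <- function(records, threshold = 1e-8) {
  imcols <- grep("^im_omega_", names(records), value = TRUE)
  immax <- do.call(pmax, c(lapply(records[imcols], abs), list(na.rm = FALSE)))
  immax[is.na(immax)] <- 0
  mask <- immax > threshold
  xs <- sort(unique(records$x)); ys <- sort(unique(records$y))
  ix <- match(records$x, xs); iy <- match(records$y, ys)
  region <- integer(nrow(records))
  nid <- 0L
  for (s in seq_len(nrow(records))) {
    if (!mask[s] || region[s] != 0L) next
    nid <- nid + 1L
    queue <- s
    while (length(queue) > 0) {
      cur <- queue[1]; queue <- queue[-1]
      if (region[cur] != 0L) next
      region[cur] <- nid
      nb <- which(mask & region == 0L &
                    ((abs(ix - ix[cur]) == 1L & iy == iy[cur]) |
                       (ix == ix[cur] & abs(iy - iy[cur]) == 1L)))
      queue <- c(queue, nb)
    }
  }
  list(mask = mask, regions = region, n_regions = nid, im_max = immax)
}

#' Locate an intersection point by minimizing the excitation-energy gap
#'
#' Derivative-free pattern search of `|omega_B - omega_A|` over the 2-d
#' scan plane for a real-spectrum method (SCC2).  For CC2 inside a defect
#' region the gap collapses to a complex pair and the search reports the
#' complex-collapse flag instead of a minimum.
#'
#' @param gap_fn function `(x, y) -> list(gap =, complex =)` or a numeric
#'   gap; see [make_gap_fn()].
#' @param start length-2 starting point.
#' @param step initial pattern-search step size.
#' @param tol gap tolerance (hartree) for declaring degeneracy located.
#' @param bounds list `(x = c(lo, hi), y = c(lo, hi))` or NULL.
#' @param max_eval evaluation budget.
#' @return list `point`, `gap`, `complex_collapse`, `evaluations`,
#'   `boundary`.
#' @export
locate_intersection <- function(gap_fn, start, step = 0.02, tol = 1e-6,
                                bounds = NULL, max_eval = 400L) {
  evalf <- function(p) {
    r <- gap_fn(p[1], p[2])
    if (is.numeric(r)) r <- list(gap = r, complex = FALSE)
    if (is.null(r$failed)) r$failed <- FALSE
    r
  }
  inb <- function(p) {
    if (is.null(bounds)) return(TRUE)
    p[1] >= bounds$x[1] && p[1] <= bounds$x[2] &&
      p[2] >= bounds$y[1] && p[2] <= bounds$y[2]
  }
  p <- start
  f <- evalf(p)
  nev <- 1L
  if (f$failed) stop("gap evaluation failed at the starting point")
  if (f$complex)
    return(list(point = p, gap = NA_real_, complex_collapse = TRUE,
                evaluations = nev, boundary = FALSE))
  h <- step
  while (nev < max_eval) {
    if (f$gap <= tol && h <= 1e-5) break
    cand <- list(c(p[1] + h, p[2]), c(p[1] - h, p[2]),
                 c(p[1], p[2] + h), c(p[1], p[2] - h))
    improved <- FALSE
    for (q in cand) {
      if (!inb(q)) next
      fq <- evalf(q); nev <- nev + 1L
      if (fq$failed) next
      if (fq$complex)
        return(list(point = q, gap = NA_real_, complex_collapse = TRUE,
                    evaluations = nev, boundary = FALSE))
      if (fq$gap < f$gap) { p <- q; f <- fq; improved <- TRUE; break }
    }
    if (!improved) {
      h <- h / 2
      if (h < 1e-7) break
    }
  }
  boundary <- !is.null(bounds) &&
    (min(abs(p[1] - bounds$x)) < 1e-10 || min(abs(p[2] - bounds$y)) < 1e-10)
  list(point = p, gap = f$gap, complex_collapse = FALSE,
       evaluations = nev, boundary = boundary)
}

#' Build a gap function over a scan plane
#'
#' Returns a memoizing closure `(x, y) -> list(gap, complex)` evaluating
#' the excitation-energy gap of the tracked state pair with chained
#' restarts, suitable for [locate_intersection()] and
#' [linearity_metric()].
#'
#' @param geometry_fn function `(x, y) -> geometry`.
#' @param method `"cc2"` or `"scc2"`.
#' @param basis basis name.
#' @param states tracked pair indices.
#' @param threshold solver threshold.
#' @return closure with attribute `"detail_env"` caching last solutions.
#' @export
make_gap_fn <- function(geometry_fn, method = "scc2", basis = "sto-3g",
                        states = c(1L, 2L), threshold = 1e-8,
                        signed = FALSE) {
  env <- new.env(parent = emptyenv())
  env$guess <- NULL
  cfg <- scan_config(geometry_fn, 0, 0, method = method, basis = basis,
                     n_states = states, threshold = threshold)
  fn <- function(x, y) {
    g <- geometry_fn(x, y)
    rec <- tryCatch(scan_point(g, cfg, env$guess),
                    error = function(e) list(error = conditionMessage(e)))
    if (!is.null(rec$error))
      return(list(gap = NA_real_, complex = FALSE, failed = TRUE))
    env$guess <- rec$guess
    om <- rec$omega
    if (any(abs(Im(om)) > 1e-8))
      return(list(gap = NA_real_, complex = TRUE, failed = FALSE))
    gp <- Re(om[2]) - Re(om[1])
    if (!signed) gp <- abs(gp)
    list(gap = gp, complex = FALSE, failed = FALSE)
  }
  attr(fn, "detail_env") <- env
  fn
}

#' Quadratic refinement of an intersection point
#'
#' Near a (correctly described) conical intersection the squared gap is a
#' smooth positive-semidefinite quadratic form of the in-plane displacement
#' with its minimum at the apex.  This routine fits that form to a small
#' stencil of gap evaluations and jumps to its minimizer, converging in a
#' few rounds where the pattern search of [locate_intersection()] only
#' halves its step.
#'
#' @param gap_fn a [make_gap_fn()] closure (absolute gap).
#' @param start length-2 starting point (ideally a small-gap point).
#' @param h stencil half-width.
#' @param tol target on the gap (hartree).
#' @param max_rounds fit/jump rounds.
#' @return list `point`, `gap`, `evaluations`.
#' @export
refine_intersection <- function(gap_fn, start, h = 3e-4, tol = 1e-6,
                                max_rounds = 4L) {
  evalg <- function(p) {
    r <- gap_fn(p[1], p[2])
    if (is.numeric(r)) r
    else if (isTRUE(r$failed) || isTRUE(r$complex)) NA_real_
    else r$gap
  }
  nev <- 0L
  best <- list(point = start, gap = Inf)
  consider <- function(p, g) {
    if (is.finite(g) && g < best$gap) best <<- list(point = p, gap = g)
  }
  g0 <- evalg(start); nev <- nev + 1L
  consider(start, g0)
  p <- start
  for (round in seq_len(max_rounds)) {
    if (best$gap <= tol) break
    offs <- rbind(c(0, 0), c(h, 0), c(-h, 0), c(0, h), c(0, -h),
                  c(h, h), c(-h, h))
    pts <- sweep(offs, 2, p, "+")
    gs <- apply(pts, 1, evalg); nev <- nev + nrow(pts) - 1L
    for (k in seq_len(nrow(pts))) consider(pts[k, ], gs[k])
    ok <- is.finite(gs)
    if (sum(ok) < 6L) { h <- h / 2; next }
    dx <- pts[ok, 1] - p[1]; dy <- pts[ok, 2] - p[2]
    X <- cbind(1, dx, dy, dx^2, dx * dy, dy^2)
    beta <- tryCatch(qr.solve(X, gs[ok]^2), error = function(e) NULL)
    if (is.null(beta)) { h <- h / 2; next }
    Hm <- matrix(c(2 * beta[4], beta[5], beta[5], 2 * beta[6]), 2, 2)
    ev <- eigen(Hm, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) { h <- h / 2; next }
    d <- -solve(Hm, beta[2:3])
    if (sqrt(sum(d^2)) > 4 * h) d <- d * (4 * h / sqrt(sum(d^2)))
    pn <- p + d
    gn <- evalg(pn); nev <- nev + 1L
    consider(pn, gn)
    if (is.finite(gn)) p <- pn
    h <- h / 2
  }
  list(point = best$point, gap = best$gap, evaluations = nev)
}

#' Linear-lifting metric around a located intersection
#'
#' Samples the gap along rays from the intersection point and fits
#' `gap = slope * distance` per ray; a first-order (conical) degeneracy
#' shows slopes stable under radius and R^2 near 1, while a defective
#' intersection lifts sublinearly.
#'
#' @param gap_fn as in [locate_intersection()].
#' @param center intersection point (length 2).
#' @param directions matrix of unit ray directions (rows), default 4 rays.
#' @param radii sampling distances (>= 5 recommended).
#' @return data.frame per ray: `angle`, `slope`, `r_squared`.
#' @export
linearity_metric <- function(gap_fn, center,
                             directions = rbind(c(1, 0), c(-1, 0),
                                                c(0, 1), c(0, -1)),
                             radii = seq(0.002, 0.01, length.out = 5)) {
  if (length(radii) < 2L) stop("need at least two radii per ray")
  evalg <- function(p) {
    g <- gap_fn(p[1], p[2])
    if (is.numeric(g)) g else g$gap
  }
  # chained gap functions carry restart state; snapshot it at the center so
  # every ray starts from the same solution rather than from the far end of
  # the previous ray (which would cross the seam in one large jump)
  env <- attr(gap_fn, "detail_env")
  snapshot <- NULL
  if (!is.null(env)) {
    if (is.null(env$guess)) {
      # establish a restart chain by approaching the center from outside
      # (the center itself may sit too close to the seam to solve cold)
      for (w in c(0.004, 0.002, 0.001))
        invisible(evalg(center + c(w, 0)))
    }
    invisible(evalg(center))
    snapshot <- env$guess
  }
  out <- list()
  for (d in seq_len(nrow(directions))) {
    if (!is.null(env)) env$guess <- snapshot
    u <- directions[d, ] / sqrt(sum(directions[d, ]^2))
    # warm the restart chain up to the first radius in fractional steps
    if (!is.null(env))
      for (w in radii[1] * c(0.4, 0.8))
        invisible(evalg(center + w * u))
    gaps <- vapply(radii, function(r) evalg(center + r * u), numeric(1))
    # a chained evaluation can occasionally converge onto a different
    # solution branch, visible as a gross upward break from the cone trend
    # (the spurious branch pairs a different state, with a far larger gap).
    # Reference the smallest observed slopes, retry flagged points from a
    # fresh chain walked out in small steps, and drop any that persist.
    slopes <- gaps / radii
    ssl <- sort(slopes[is.finite(slopes)])
    med <- stats::median(utils::head(ssl, max(3L, ceiling(length(ssl) / 2))))
    bad <- which(!is.finite(gaps) | abs(slopes / med - 1) > 0.5)
    if (length(bad) > 0 && length(bad) < length(radii) && !is.null(env)) {
      for (k in utils::head(sort(bad), 2L)) {   # bounded retry budget
        env$guess <- snapshot
        for (f in c(0.25, 0.5, 0.75))
          invisible(evalg(center + f * radii[k] * u))
        gaps[k] <- evalg(center + radii[k] * u)
      }
      slopes <- gaps / radii
      bad <- which(!is.finite(gaps) | abs(slopes / med - 1) > 0.5)
      if (length(bad) > 0) gaps[bad] <- NA_real_
    }
    ok <- is.finite(gaps)
    fit <- stats::lm(gaps[ok] ~ 0 + radii[ok])
    ss_tot <- sum(gaps[ok]^2)
    r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else NA_real_
    out[[d]] <- data.frame(angle = atan2(u[2], u[1]),
                           slope = unname(stats::coef(fit)[1]),
                           r_squared = r2, n = sum(ok))
  }
  do.call(rbind, out)
}

#' Displaced geometry generator for gh-plane scans
#'
#' Returns `(x, y) -> geometry` adding `x * gvec + y * hvec` (Angstrom) to
#' a base geometry's coordinates.
#'
#' @param base a [geometry()].
#' @param gvec,hvec displacement matrices (atoms x 3, Angstrom).
#' @export
gh_plane_geometry <- function(base, gvec, hvec) {
  force(base); force(gvec); force(hvec)
  function(x, y) {
    geometry(base$elements,
             base$coordinates + x * gvec + y * hvec,
             base$charge)
  }
}
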
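# Molecular geometries: construction, XYZ input/output, internal coordinates

ELEMENTS <- c(H = 1, He = 2, Li = 3, Be = 4, B = 5, C = 6, N = 7, O = 8,
              F = 9, Ne = 10, Ar = 18)

#' Construct a molecular geometry
#'
#' A geometry holds element symbols and Cartesian coordinates in Angstrom,
#' together with total charge.  Only closed-shell (even electron count,
#' singlet) systems are accepted, matching the restricted reference used by
#' all solvers in this package.
#'
#' @param elements character vector of element symbols.
#' @param coordinates numeric matrix, one row per atom, columns x, y, z in
#'   Angstrom.
#' @param charge integer total charge (default 0).
#' @return an object of class `"geometry"`.
#' @examples
#' geometry("He", matrix(0, 1, 3))
#' @export
geometry <- function(elements, coordinates, charge = 0L) {
  coordinates <- matrix(as.numeric(coordinates), nrow = length(elements))
  if (length(elements) < 1L) stop("geometry needs at least one atom")
  if (ncol(coordinates) != 3L) stop("coordinates must have 3 columns")
  if (any(!is.finite(coordinates))) stop("non-finite coordinates")
  unknown <- setdiff(elements, names(ELEMENTS))
  if (length(unknown) > 0L)
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  nel <- sum(ELEMENTS[elements]) - charge
  if (nel %% 2L != 0L)
    stop("odd electron count (", nel, "): only closed-shell systems supported")
  structure(list(elements = as.character(elements),
                 coordinates = coordinates,
                 charge = as.integer(charge),
                 multiplicity = 1L),
            class = "geometry")
}

#' @export
print.geometry <- function(x, ...) {
  cat(sprintf("geometry: %d atoms, charge %d\n", length(x$elements), x$charge))
  for (i in seq_along(x$elements))
    cat(sprintf("  %-2s %12.6f %12.6f %12.6f\n", x$elements[i],
                x$coordinates[i, 1], x$coordinates[i, 2], x$coordinates[i, 3]))
  invisible(x)
}

n_electrons <- function(geom) {
  sum(ELEMENTS[geom$elements]) - geom$charge
}

#' Read a geometry from XYZ-format text
#'
#' Standard XYZ: an atom-count line, a comment line, then one
#' `element x y z` line per atom with coordinates in Angstrom.
#'
#' @param text a single string or character vector of lines, or a file path
#'   (when `is_file = TRUE`).
#' @param charge total charge to attach (XYZ does not carry one).
#' @param is_file read `text` as a path.
#' @return a [geometry()].
#' @export
read_xyz <- function(text, charge = 0L, is_file = FALSE) {
  lines <- if (is_file) readLines(text) else unlist(strsplit(text, "\n", fixed = TRUE))
  lines <- lines[nzchar(trimws(lines)) | seq_along(lines) == 2L]
  if (length(lines) < 3L && length(lines) >= 1L) {
    # allow a bare "El x y z" one-liner for convenience in examples
    fields <- strsplit(trimws(lines[1]), "\\s+")[[1]]
    if (length(fields) == 4L && is.na(suppressWarnings(as.integer(fields[1])))) {
      return(geometry(fields[1], matrix(as.numeric(fields[2:4]), 1, 3), charge))
    }
  }
  nat <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(nat)) stop("XYZ parse error: line 1 is not an atom count")
  if (length(lines) < 2L + nat)
    stop("XYZ parse error: expected ", nat, " atom lines, found ",
         max(0L, length(lines) - 2L))
  els <- character(nat); xyz <- matrix(NA_real_, nat, 3)
  for (k in seq_len(nat)) {
    fields <- strsplit(trimws(lines[2L + k]), "\\s+")[[1]]
    if (length(fields) < 4L)
      stop("XYZ parse error at atom line ", k, ": need 'element x y z'")
    els[k] <- fields[1]
    v <- suppressWarnings(as.numeric(fields[2:4]))
    if (any(is.na(v))) stop("XYZ parse error at atom line ", k, ": bad coordinate")
    xyz[k, ] <- v
  }
  geometry(els, xyz, charge)
}

#' Write a geometry as XYZ-format text
#'
#' @param geom a [geometry()].
#' @param comment comment line content.
#' @return a single string in XYZ format (Angstrom).
#' @export
write_xyz <- function(geom, comment = "") {
  lines <- c(as.character(length(geom$elements)), comment,
             vapply(seq_along(geom$elements), function(i) {
               sprintf("%s %.17g %.17g %.17g", geom$elements[i],
                       geom$coordinates[i, 1], geom$coordinates[i, 2],
                       geom$coordinates[i, 3])
             }, character(1)))
  paste(lines, collapse = "\n")
}

#' Planar HOF geometry from internal coordinates
#'
#' Places O at the origin, F along +x at the given O-F distance, and H in the
#' xy-plane at the given O-H distance and H-O-F angle.
#'
#' @param r_oh O-H bond length in Angstrom.
#' @param r_of O-F bond length in Angstrom.
#' @param theta H-O-F angle in degrees, in (0, 180).
#' @return a [geometry()] with atoms ordered H, O, F.
#' @examples
#' make_hof_geometry(1.1, 1.33, 90.5)
#' @export
make_hof_geometry <- function(r_oh = 1.1, r_of = 1.33, theta = 90.5) {
  if (r_oh <= 0 || r_of <= 0) stop("bond lengths must be positive")
  if (theta <= 0 || theta >= 180) stop("angle must lie in (0, 180) degrees")
  th <- theta * pi / 180
  xyz <- rbind(H = c(r_oh * cos(th), r_oh * sin(th), 0),
               O = c(0, 0, 0),
               F = c(r_of, 0, 0))
  geometry(c("H", "O", "F"), xyz)
}

#' H2 molecule along the z axis
#' @param r bond length in Angstrom.
#' @return a [geometry()].
#' @export
make_h2_geometry <- function(r = 0.7414) {
  geometry(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, r)))
}

#' Rectangular / trapezoidal H4 model systems
#'
#' Four hydrogens at `(+-a/2, +-b/2, 0)` for the rectangle; the trapezoid
#' shifts the upper edge horizontally by `skew` and scales its width by
#' `top_scale`.  Distorted H4 arrangements are the standard minimal testbed
#' for same-symmetry excited-state near-degeneracies in coupled cluster
#' models.
#'
#' @param a,b horizontal and vertical edge lengths in Angstrom.
#' @param skew horizontal displacement of the upper edge (Angstrom).
#' @param top_scale width scaling of the upper edge.
#' @return a [geometry()].
#' @export
make_h4_geometry <- function(a = 1.2, b = 1.2, skew = 0, top_scale = 1) {
  w <- a * top_scale / 2
  xyz <- rbind(c(-a / 2, -b / 2, 0),
               c( a / 2, -b / 2, 0),
               c(-w + skew, b / 2, 0),
               c( w + skew, b / 2, 0))
  geometry(rep("H", 4), xyz)
}

#' Combine two geometries into one system
#'
#' Useful for size-extensivity checks with fragments at noninteracting
#' separations.
#'
#' @param g1,g2 geometries.
#' @param offset length-3 displacement (Angstrom) applied to `g2`.
#' @return a [geometry()].
#' @export
combine_geometries <- function(g1, g2, offset = c(0, 0, 100)) {
  geometry(c(g1$elements, g2$elements),
           rbind(g1$coordinates,
                 sweep(g2$coordinates, 2, offset, "+")),
           charge = g1$charge + g2$charge)
}

#' Bond length between two atoms (Angstrom)
#' @param geom a [geometry()].
#' @param i,j atom indices.
#' @export
bond_length <- function(geom, i, j) {
  sqrt(sum((geom$coordinates[i, ] - geom$coordinates[j, ])^2))
}

#' Bond angle i-j-k in degrees
#' @param geom a [geometry()].
#' @param i,j,k atom indices; `j` is the vertex.
#' @export
bond_angle <- function(geom, i, j, k) {
  u <- geom$coordinates[i, ] - geom$coordinates[j, ]
  v <- geom$coordinates[k, ] - geom$coordinates[j, ]
  acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))) * 180 / pi
}

#' Rigidly transform a geometry
#'
#' Applies a proper rotation followed by a translation; all observables
#' computed downstream are invariant under this map.
#'
#' @param geom a [geometry()].
#' @param rotation 3x3 rotation matrix.
#' @param translation length-3 shift in Angstrom.
#' @export
transform_geometry <- function(geom, rotation = diag(3), translation = c(0, 0, 0)) {
  xyz <- geom$coordinates %*% t(rotation)
  xyz <- sweep(xyz, 2, translation, "+")
  geometry(geom$elements, xyz, geom$charge)
}
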
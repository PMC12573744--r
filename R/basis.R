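# Bundled Gaussian basis sets.  STO-3G is carried for H-Ne; 6-31G for H and
# O.  Exponents and contraction coefficients are the standard published
# values; coefficients refer to normalized primitives and each contracted
# function is renormalized to unit self-overlap when integrals are built.

.sto3g_s_coef <- c(0.15432897, 0.53532814, 0.44463454)
.sto3g_sp_scoef <- c(-0.09996723, 0.39951283, 0.70115470)
.sto3g_sp_pcoef <- c(0.15591627, 0.60768372, 0.39195739)

.basis_data <- list(
  "sto-3g" = list(
    H  = list(list(l = 0, e = c(3.42525091, 0.62391373, 0.16885540), c = .sto3g_s_coef)),
    He = list(list(l = 0, e = c(6.36242139, 1.15892300, 0.31364979), c = .sto3g_s_coef)),
    Li = list(list(l = 0, e = c(16.1195750, 2.9362007, 0.7946505), c = .sto3g_s_coef),
              list(l = 0, e = c(0.6362897, 0.1478601, 0.0480887), c = .sto3g_sp_scoef),
              list(l = 1, e = c(0.6362897, 0.1478601, 0.0480887), c = .sto3g_sp_pcoef)),
    Be = list(list(l = 0, e = c(30.1678710, 5.4951153, 1.4871927), c = .sto3g_s_coef),
              list(l = 0, e = c(1.3148331, 0.3055389, 0.0993707), c = .sto3g_sp_scoef),
              list(l = 1, e = c(1.3148331, 0.3055389, 0.0993707), c = .sto3g_sp_pcoef)),
    B  = list(list(l = 0, e = c(48.7911130, 8.8873622, 2.4052670), c = .sto3g_s_coef),
              list(l = 0, e = c(2.2369561, 0.5198205, 0.1690618), c = .sto3g_sp_scoef),
              list(l = 1, e = c(2.2369561, 0.5198205, 0.1690618), c = .sto3g_sp_pcoef)),
    C  = list(list(l = 0, e = c(71.6168370, 13.0450960, 3.5305122), c = .sto3g_s_coef),
              list(l = 0, e = c(2.9412494, 0.6834831, 0.2222899), c = .sto3g_sp_scoef),
              list(l = 1, e = c(2.9412494, 0.6834831, 0.2222899), c = .sto3g_sp_pcoef)),
    N  = list(list(l = 0, e = c(99.1061690, 18.0523120, 4.8856602), c = .sto3g_s_coef),
              list(l = 0, e = c(3.7804559, 0.8784966, 0.2857144), c = .sto3g_sp_scoef),
              list(l = 1, e = c(3.7804559, 0.8784966, 0.2857144), c = .sto3g_sp_pcoef)),
    O  = list(list(l = 0, e = c(130.7093200, 23.8088610, 6.4436083), c = .sto3g_s_coef),
              list(l = 0, e = c(5.0331513, 1.1695961, 0.3803890), c = .sto3g_sp_scoef),
              list(l = 1, e = c(5.0331513, 1.1695961, 0.3803890), c = .sto3g_sp_pcoef)),
    F  = list(list(l = 0, e = c(166.6791300, 30.3608120, 8.2168207), c = .sto3g_s_coef),
              list(l = 0, e = c(6.4648032, 1.5022812, 0.4885885), c = .sto3g_sp_scoef),
              list(l = 1, e = c(6.4648032, 1.5022812, 0.4885885), c = .sto3g_sp_pcoef)),
    Ne = list(list(l = 0, e = c(207.0156100, 37.7081510, 10.2052970), c = .sto3g_s_coef),
              list(l = 0, e = c(8.2463151, 1.9162662, 0.6232293), c = .sto3g_sp_scoef),
              list(l = 1, e = c(8.2463151, 1.9162662, 0.6232293), c = .sto3g_sp_pcoef))
  ),
  "6-31g" = list(
    H = list(list(l = 0, e = c(18.7311370, 2.8253937, 0.6401217),
                  c = c(0.03349460, 0.23472695, 0.81375733)),
             list(l = 0, e = 0.1612778, c = 1.0)),
    O = list(list(l = 0,
                  e = c(5484.6717, 825.23495, 188.04696, 52.964500, 16.897570, 5.7996353),
                  c = c(0.0018311, 0.0139501, 0.0684451, 0.2327143, 0.4701930, 0.3585209)),
             list(l = 0, e = c(15.539616, 3.5999336, 1.0137618),
                  c = c(-0.1107775, -0.1480263, 1.1307670)),
             list(l = 1, e = c(15.539616, 3.5999336, 1.0137618),
                  c = c(0.0708743, 0.3397528, 0.7271586)),
             list(l = 0, e = 0.2700058, c = 1.0),
             list(l = 1, e = 0.2700058, c = 1.0))
  )
)

#' List bundled basis sets
#' @return named list: basis name -> element symbols covered.
#' @export
available_bases <- function() {
  lapply(.basis_data, names)
}

# Expand a geometry + basis name into the primitive shell list consumed by
# the integral backend.  Coordinates are converted to bohr here.
basis_shells <- function(geom, basis_name) {
  basis_name <- tolower(basis_name)
  bs <- .basis_data[[basis_name]]
  if (is.null(bs))
    stop("basis '", basis_name, "' not bundled; available: ",
         paste(names(.basis_data), collapse = ", "))
  missing <- setdiff(unique(geom$elements), names(bs))
  if (length(missing) > 0L)
    stop("basis '", basis_name, "' not available for element(s): ",
         paste(missing, collapse = ", "))
  shells <- list()
  for (at in seq_along(geom$elements)) {
    el <- geom$elements[at]
    center <- ang_to_bohr(geom$coordinates[at, ])
    for (sh in bs[[el]]) {
      norms <- cpp_prim_norms(sh$e, sh$l)
      shells[[length(shells) + 1L]] <- list(
        l = as.integer(sh$l), center = as.numeric(center),
        exponents = as.numeric(sh$e),
        coefficients = as.numeric(sh$c * norms))
    }
  }
  shells
}
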
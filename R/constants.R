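#' Physical constants and element tables
#'
#' All internal energy arithmetic is done in hartree and all internal
#' distances in bohr; user-facing interfaces take angstrom and report
#' kJ/mol.
#'
#' @name constants
#' @keywords internal
NULL

#: unit conversions (CODATA)
BOHR_PER_ANGSTROM <- 1.8897259886
KJMOL_PER_HARTREE <- 2625.4996

.ELEMENTS <- data.frame(
  symbol = c("H", "HE", "LI", "BE", "B", "C", "N", "O", "F", "NE",
             "NA", "MG", "AL", "SI", "P", "S", "CL", "AR", "K", "CA",
             "FE", "ZN", "SE", "BR", "I"),
  Z = c(1L, 2L, 3L, 4L, 5L, 6L, 7L, 8L, 9L, 10L,
        11L, 12L, 13L, 14L, 15L, 16L, 17L, 18L, 19L, 20L,
        26L, 30L, 34L, 35L, 53L),
  # single-bond covalent radii, angstrom (Cordero et al. 2008 values)
  rcov = c(0.31, 0.28, 1.28, 0.96, 0.84, 0.76, 0.71, 0.66, 0.57, 0.58,
           1.66, 1.41, 1.21, 1.11, 1.07, 1.05, 1.02, 1.06, 2.03, 1.76,
           1.32, 1.22, 1.20, 1.20, 1.39),
  stringsAsFactors = FALSE
)

#' Resolve element symbols to nuclear charges
#'
#' @param element character vector of element symbols (case-insensitive).
#' @return integer vector of nuclear charges Z.
#' @examples
#' element_to_Z(c("O", "h", "Cl"))
#' @export
element_to_Z <- function(element) {
  idx <- match(toupper(trimws(element)), .ELEMENTS$symbol)
  if (anyNA(idx)) {
    stop("unknown element symbol(s): ",
         paste(unique(element[is.na(idx)]), collapse = ", "))
  }
  .ELEMENTS$Z[idx]
}

#' Covalent radii for elements
#'
#' @param element character vector of element symbols.
#' @return numeric vector of single-bond covalent radii in angstrom.
#' @export
covalent_radius <- function(element) {
  idx <- match(toupper(trimws(element)), .ELEMENTS$symbol)
  if (anyNA(idx)) {
    stop("no covalent radius for element(s): ",
         paste(unique(element[is.na(idx)]), collapse = ", "))
  }
  .ELEMENTS$rcov[idx]
}

# number of core electrons for a neutral atom (by period), used by the
# element-spherical fallback in parameter transfer
.core_electrons <- function(Z) {
  ifelse(Z <= 2L, 0L,
  ifelse(Z <= 10L, 2L,
  ifelse(Z <= 18L, 10L,
  ifelse(Z <= 36L, 18L, 36L))))
}
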
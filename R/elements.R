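# Element symbols and standard atomic weights, Z = 1..100.
# Weights are the conventional (abridged) CIAAW values; radioelements carry
# the mass number of the most stable isotope.

.element_symbols <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne",
  "Na", "Mg", "Al", "Si", "P", "S", "Cl", "Ar", "K", "Ca",
  "Sc", "Ti", "V", "Cr", "Mn", "Fe", "Co", "Ni", "Cu", "Zn",
  "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr", "Y", "Zr",
  "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe", "Cs", "Ba", "La", "Ce", "Pr", "Nd",
  "Pm", "Sm", "Eu", "Gd", "Tb", "Dy", "Ho", "Er", "Tm", "Yb",
  "Lu", "Hf", "Ta", "W", "Re", "Os", "Ir", "Pt", "Au", "Hg",
  "Tl", "Pb", "Bi", "Po", "At", "Rn", "Fr", "Ra", "Ac", "Th",
  "Pa", "U", "Np", "Pu", "Am", "Cm", "Bk", "Cf", "Es", "Fm"
)

.atomic_weights <- c(
  1.008, 4.0026, 6.94, 9.0122, 10.81, 12.011, 14.007, 15.999, 18.998, 20.180,
  22.990, 24.305, 26.982, 28.085, 30.974, 32.06, 35.45, 39.948, 39.098, 40.078,
  44.956, 47.867, 50.942, 51.996, 54.938, 55.845, 58.933, 58.693, 63.546, 65.38,
  69.723, 72.630, 74.922, 78.971, 79.904, 83.798, 85.468, 87.62, 88.906, 91.224,
  92.906, 95.95, 98, 101.07, 102.91, 106.42, 107.87, 112.41, 114.82, 118.71,
  121.76, 127.60, 126.90, 131.29, 132.91, 137.33, 138.91, 140.12, 140.91, 144.24,
  145, 150.36, 151.96, 157.25, 158.93, 162.50, 164.93, 167.26, 168.93, 173.05,
  174.97, 178.49, 180.95, 183.84, 186.21, 190.23, 192.22, 195.08, 196.97, 200.59,
  204.38, 207.2, 208.98, 209, 210, 222, 223, 226, 227, 232.04,
  231.04, 238.03, 237, 244, 243, 247, 247, 251, 252, 257
)

#' Resolve element identifiers to atomic numbers
#'
#' Accepts element symbols (case-insensitive) or integer atomic numbers
#' (possibly as strings) and returns atomic numbers.
#'
#' @param x Character or numeric vector of element symbols or atomic numbers.
#' @return Integer vector of atomic numbers in `[1, 100]`.
#' @examples
#' element_z(c("H", "ca", "8", 26))
#' @export
element_z <- function(x) {
  out <- integer(length(x))
  xs <- trimws(as.character(x))
  is_num <- grepl("^[0-9]+$", xs)
  out[is_num] <- as.integer(xs[is_num])
  if (any(!is_num)) {
    idx <- match(toupper(xs[!is_num]), toupper(.element_symbols))
    if (anyNA(idx)) {
      bad <- xs[!is_num][is.na(idx)]
      stop("unknown element symbol: ", paste(unique(bad), collapse = ", "))
    }
    out[!is_num] <- idx
  }
  if (any(out < 1L | out > 100L)) {
    stop("atomic number outside [1, 100]: ",
         paste(out[out < 1L | out > 100L], collapse = ", "))
  }
  out
}

#' Element symbol for an atomic number
#'
#' @param z Integer vector of atomic numbers in `[1, 100]`.
#' @return Character vector of element symbols.
#' @export
element_symbol <- function(z) {
  stopifnot(all(z >= 1L), all(z <= 100L))
  .element_symbols[z]
}

#' Standard atomic weight
#'
#' @param z Integer vector of atomic numbers in `[1, 100]`.
#' @return Numeric vector of relative atomic masses (g/mol).
#' @export
atomic_weight <- function(z) {
  stopifnot(all(z >= 1L), all(z <= 100L))
  .atomic_weights[z]
}
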
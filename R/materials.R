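#' Construct a material from an element composition
#'
#' A material is a named set of elements with their fractions by weight.
#' Raw fractions must sum to 1 within `sum_tol` (printed compositions carry
#' rounding); [normalize_material()] rescales them to sum to 1 exactly.
#'
#' @param name Material name.
#' @param z Vector of element symbols or atomic numbers (see [element_z()]).
#' @param weight_fraction Numeric vector of fractions by weight, all > 0.
#' @param normalize Rescale fractions to sum to 1 (default `TRUE`).
#' @param sum_tol Maximum allowed deviation of the raw fraction sum from 1.
#' @return An object of class `material`: a list with elements `name`,
#'   `z` (integer atomic numbers) and `weight_fraction`.
#' @examples
#' material("water", c("H", "O"), c(0.111898, 0.888102))
#' @seealso [parse_composition()], [tissue_registry()]
#' @export
material <- function(name, z, weight_fraction, normalize = TRUE,
                     sum_tol = 2e-3) {
  z <- element_z(z)
  weight_fraction <- as.numeric(weight_fraction)
  if (length(z) != length(weight_fraction) || length(z) == 0L)
    stop("'z' and 'weight_fraction' must be nonempty and of equal length")
  if (anyNA(weight_fraction) || any(weight_fraction <= 0))
    stop("weight fractions must be positive numbers")
  if (anyDuplicated(z))
    stop("duplicate element in composition: ",
         paste(element_symbol(z[duplicated(z)]), collapse = ", "))
  s <- sum(weight_fraction)
  if (abs(s - 1) > sum_tol)
    stop(sprintf("weight fractions sum to %.6f, outside 1 +/- %g", s, sum_tol))
  m <- structure(
    list(name = as.character(name), z = z, weight_fraction = weight_fraction),
    class = "material"
  )
  if (normalize) normalize_material(m) else m
}

#' Rescale a material's weight fractions to sum exactly to one
#'
#' @param m A [material()].
#' @return The material with fractions divided by their sum; order preserved.
#' @export
normalize_material <- function(m) {
  stopifnot(inherits(m, "material"))
  m$weight_fraction <- m$weight_fraction / sum(m$weight_fraction)
  m
}

#' @export
print.material <- function(x, ...) {
  cat(sprintf("<material> %s (%d elements)\n", x$name, length(x$z)))
  print(data.frame(element = element_symbol(x$z), Z = x$z,
                   weight_fraction = x$weight_fraction), row.names = FALSE)
  invisible(x)
}

#' @export
format.material <- function(x, ...) {
  paste0(element_symbol(x$z), " ", format(x$weight_fraction, digits = 15),
         collapse = ", ")
}

#' Parse a composition from text
#'
#' Accepts either a one-line composition such as
#' `"H 0.101174, C 0.111, N 0.026, O 0.761826"` or CSV text / a CSV file
#' with header `element,weight_fraction`.  Elements may be symbols
#' (case-insensitive) or atomic numbers; lines starting with `#` are
#' comments.
#'
#' @param source Composition text, or the path of a CSV file.
#' @param name Name for the material (defaults to the file name or
#'   `"material"`).
#' @inheritParams material
#' @return A [material()] (normalized by default).
#' @examples
#' parse_composition("H 0.111898, O 0.888102", name = "water")
#' @export
parse_composition <- function(source, name = NULL, normalize = TRUE,
                              sum_tol = 2e-3) {
  is_file <- length(source) == 1L && !grepl("[,\n]", source) &&
    file.exists(source)
  if (is_file) {
    if (is.null(name))
      name <- sub("\\.[^.]*$", "", basename(source))
    lines <- readLines(source, encoding = "UTF-8")
  } else {
    lines <- unlist(strsplit(source, "\n", fixed = TRUE))
    if (is.null(name)) name <- "material"
  }
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop("empty composition")
  if (length(lines) == 1L && grepl(",", lines) &&
      !grepl("element", lines, ignore.case = TRUE)) {
    # one-line "SYM frac, SYM frac, ..." form
    lines <- trimws(unlist(strsplit(lines, ",", fixed = TRUE)))
  }
  lines <- lines[!grepl("^element[ ,\t]", lines, ignore.case = TRUE)]
  parts <- strsplit(lines, "[ ,\t:]+")
  bad <- vapply(parts, length, 1L) != 2L
  if (any(bad)) stop("cannot parse composition record: ",
                     lines[bad][1L])
  sym <- vapply(parts, `[`, "", 1L)
  frac <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2L)))
  if (anyNA(frac)) stop("non-numeric weight fraction for element: ",
                        paste(sym[is.na(frac)], collapse = ", "))
  material(name, sym, frac, normalize = normalize, sum_tol = sum_tol)
}

#' Serialize a material to composition CSV text
#'
#' Inverse of [parse_composition()]: writes one `element,weight_fraction`
#' record per constituent, full precision.
#'
#' @param m A [material()].
#' @param path Optional file to write; when `NULL` the CSV text is returned.
#' @return The CSV text, invisibly when written to a file.
#' @export
write_composition <- function(m, path = NULL) {
  stopifnot(inherits(m, "material"))
  txt <- c("element,weight_fraction",
           sprintf("%s,%.17g", element_symbol(m$z), m$weight_fraction))
  if (is.null(path)) return(paste(txt, collapse = "\n"))
  writeLines(txt, path)
  invisible(paste(txt, collapse = "\n"))
}

# compositions by weight of twelve reference human organs/tissues (ICRU-44
# style compilations) plus water (2:1 H2O stoichiometry, standard weights)
.tissue_compositions <- list(
  adipose_tissue = list(
    z = c("H", "C", "N", "O", "Na", "S", "Cl"),
    w = c(0.114, 0.598, 0.007, 0.278, 0.001, 0.001, 0.001)),
  blood_whole = list(
    z = c("H", "C", "N", "O", "Na", "P", "S", "Cl", "K", "Fe"),
    w = c(0.102, 0.110, 0.033, 0.745, 0.001, 0.001, 0.002, 0.003, 0.002,
          0.001)),
  cortical_bone = list(
    z = c("H", "C", "N", "O", "Na", "Mg", "P", "S", "Ca"),
    w = c(0.034, 0.155, 0.042, 0.435, 0.001, 0.002, 0.103, 0.003, 0.225)),
  brain = list(
    z = c("H", "C", "N", "O", "Na", "P", "S", "Cl", "K"),
    w = c(0.107, 0.145, 0.022, 0.712, 0.002, 0.004, 0.002, 0.003, 0.003)),
  breast_tissue = list(
    z = c("H", "C", "N", "O", "Na", "P", "S", "Cl"),
    w = c(0.106, 0.332, 0.030, 0.527, 0.001, 0.001, 0.002, 0.001)),
  eye_lens = list(
    z = c("H", "C", "N", "O", "Na", "P", "S", "Cl"),
    w = c(0.096, 0.195, 0.057, 0.646, 0.001, 0.001, 0.003, 0.001)),
  lung_tissue = list(
    z = c("H", "C", "N", "O", "Na", "P", "S", "Cl", "K"),
    w = c(0.103, 0.105, 0.031, 0.749, 0.002, 0.002, 0.003, 0.003, 0.002)),
  skeletal_muscle = list(
    z = c("H", "C", "N", "O", "Na", "P", "S", "Cl", "K"),
    w = c(0.102, 0.143, 0.034, 0.710, 0.001, 0.002, 0.003, 0.001, 0.004)),
  ovary = list(
    z = c("H", "C", "N", "O", "Na", "P", "S", "Cl", "K"),
    w = c(0.105, 0.093, 0.024, 0.768, 0.002, 0.002, 0.002, 0.002, 0.002)),
  testis = list(
    z = c("H", "C", "N", "O", "Na", "P", "S", "Cl", "K"),
    w = c(0.106, 0.099, 0.020, 0.766, 0.002, 0.001, 0.002, 0.002, 0.002)),
  soft_tissue = list(
    z = c("H", "C", "N", "O", "Na", "P", "S", "Cl", "K"),
    w = c(0.102, 0.143, 0.034, 0.708, 0.002, 0.003, 0.003, 0.002, 0.003)),
  soft_tissue_4component = list(
    z = c("H", "C", "N", "O"),
    w = c(0.101174, 0.111, 0.026, 0.761826)),
  water = list(
    z = c("H", "O"),
    w = c(0.111898, 0.888102))
)

#' Built-in registry of reference human organs/tissues and water
#'
#' Twelve reference organ and tissue compositions (adipose tissue, whole
#' blood, cortical bone, brain grey/white matter, breast tissue, eye lens,
#' lung tissue, skeletal muscle, ovary, testis, soft tissue and 4-component
#' soft tissue) plus water, as fractions by weight.
#'
#' @param name Optional canonical name; when given, the single matching
#'   material is returned.
#' @return A named list of [material()] objects (13 entries), or one
#'   material when `name` is supplied.
#' @examples
#' names(tissue_registry())
#' tissue_registry("cortical_bone")
#' @export
tissue_registry <- function(name = NULL) {
  reg <- lapply(names(.tissue_compositions), function(nm) {
    comp <- .tissue_compositions[[nm]]
    material(nm, comp$z, comp$w)
  })
  names(reg) <- names(.tissue_compositions)
  if (is.null(name)) return(reg)
  if (!name %in% names(reg))
    stop("unknown material '", name, "'; registry has: ",
         paste(names(reg), collapse = ", "))
  reg[[name]]
}
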
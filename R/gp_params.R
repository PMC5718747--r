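# Elemental geometric-progression (GP) fitting parameter libraries in the
# ANSI/ANS-6.4.3-1991 style, and their interpolation to a material's
# equivalent atomic number.

.gp_columns <- c("Z", "energy_MeV", "a", "b", "c", "d", "Xk")
.gp_param_names <- c("a", "b", "c", "d", "Xk")

#' Validate an elemental GP fitting parameter library
#'
#' Each element must carry a complete set of rows on the 25-point
#' [standard_energy_grid()]; a missing (Z, energy) cell is an error.
#'
#' @param df Data frame with columns `Z,energy_MeV,a,b,c,d,Xk`.
#' @return The validated library, sorted by (Z, energy), with class
#'   `gp_library`.
#' @export
as_gp_library <- function(df) {
  df <- as.data.frame(df)
  missing <- setdiff(.gp_columns, names(df))
  if (length(missing) > 0L)
    stop("GP library is missing column(s): ", paste(missing, collapse = ", "))
  df <- df[, .gp_columns]
  for (cc in .gp_columns[-1L]) df[[cc]] <- as.numeric(df[[cc]])
  if (anyNA(df)) stop("GP library contains missing/non-numeric values")
  if (any(df$Z != round(df$Z))) stop("'Z' must be integer atomic numbers")
  df$Z <- as.integer(df$Z)
  if (any(df$Xk <= 0)) stop("'Xk' must be positive")
  grid <- standard_energy_grid()
  for (z in unique(df$Z)) {
    e <- df$energy_MeV[df$Z == z]
    if (anyDuplicated(e) || length(e) != length(grid) ||
        !isTRUE(all.equal(sort(e), grid, tolerance = 1e-9))) {
      miss <- setdiff(signif(grid, 10), signif(e, 10))
      stop(sprintf(
        "element Z=%d does not cover the 25-point standard grid (missing/extra near: %s)",
        z, paste(utils::head(c(miss, setdiff(signif(e, 10), signif(grid, 10))), 3L),
                 collapse = ", ")))
    }
  }
  df <- df[order(df$Z, df$energy_MeV), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("gp_library", "data.frame")
  df
}

#' Read an elemental GP parameter library
#'
#' CSV schema: header `Z,energy_MeV,a,b,c,d,Xk`, one row per
#' (element, energy), `#` comments allowed.  The column order `a,b,c,d,Xk`
#' is fixed regardless of the ordering used by the source tabulation.
#'
#' @param path CSV file path.
#' @return A `gp_library` (see [as_gp_library()]).
#' @export
read_gp_library <- function(path) {
  as_gp_library(utils::read.csv(path, comment.char = "#",
                                strip.white = TRUE))
}

#' Write a GP library to CSV
#'
#' @param lib A `gp_library`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gp_library <- function(lib, path) {
  stopifnot(inherits(lib, "gp_library"))
  utils::write.csv(as.data.frame(lib), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Interpolate GP fitting parameters to a fractional atomic number
#'
#' Each of the five parameters P in (a, b, c, d, Xk) is interpolated
#' independently between the integer floor/ceiling elements of `zeq` on
#' the logarithm of the atomic number:
#' `P = (P1 (log Z2 - log zeq) + P2 (log zeq - log Z1)) / (log Z2 - log Z1)`.
#' An integer `zeq` returns that element's library row exactly.
#'
#' @param zeq Equivalent atomic number (scalar).
#' @param energy One of the 25 grid energies (MeV); GP parameters are not
#'   interpolated in energy.
#' @param lib A `gp_library` containing the floor and ceiling elements.
#' @return One-row data frame `energy_MeV,a,b,c,d,Xk`.
#' @examples
#' lib <- synthetic_gp_library()
#' interpolate_gp(13.40, 0.03, lib)
#' @export
interpolate_gp <- function(zeq, energy, lib) {
  stopifnot(inherits(lib, "gp_library"), length(zeq) == 1L,
            length(energy) == 1L)
  if (!isTRUE(any(abs(standard_energy_grid() - energy) < 1e-9)))
    stop("energy ", energy, " MeV is not on the 25-point standard grid")
  z1 <- floor(zeq); z2 <- ceiling(zeq)
  row_for <- function(z) {
    r <- lib[lib$Z == z & abs(lib$energy_MeV - energy) < 1e-9, , drop = FALSE]
    if (nrow(r) != 1L)
      stop(sprintf("GP library has no row for Z=%d at E=%g MeV", z, energy))
    r
  }
  p1 <- row_for(z1)
  if (z1 == z2) {
    out <- p1[, c("energy_MeV", .gp_param_names)]
    rownames(out) <- NULL
    return(out)
  }
  p2 <- row_for(z2)
  w <- (log(zeq) - log(z1)) / (log(z2) - log(z1))
  vals <- (1 - w) * unlist(p1[.gp_param_names]) +
    w * unlist(p2[.gp_param_names])
  out <- data.frame(energy_MeV = energy, as.list(vals))
  names(out) <- c("energy_MeV", .gp_param_names)
  out
}

#' GP fitting parameters of a material over the standard grid
#'
#' Composes [zeq_curve()] with [interpolate_gp()]: for each of the 25 grid
#' energies the material's equivalent atomic number is computed from the
#' attenuation dataset, then the elemental GP parameters are interpolated
#' to it.
#'
#' @param m A [material()].
#' @param ds An `attenuation_dataset`.
#' @param lib A `gp_library`.
#' @param grid Energies (must be a subset of the standard grid).
#' @param zrange,convention Passed to [zeq_curve()].
#' @return Data frame of class `gp_table` with columns
#'   `material,energy_MeV,Zeq,a,b,c,d,Xk`.
#' @export
material_gp_table <- function(m, ds, lib, grid = standard_energy_grid(),
                              zrange = 4:30,
                              convention = c("without_coherent",
                                             "with_coherent")) {
  convention <- match.arg(convention)
  zc <- zeq_curve(m, ds, grid, zrange, convention)
  rows <- lapply(seq_len(nrow(zc)), function(i) {
    p <- interpolate_gp(zc$Zeq[i], zc$energy_MeV[i], lib)
    cbind(data.frame(material = m$name, energy_MeV = zc$energy_MeV[i],
                     Zeq = zc$Zeq[i]),
          p[, .gp_param_names])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("gp_table", "data.frame")
  out
}
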
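# Equivalent atomic number: match a material's Compton-to-total ratio R
# against pure-element ratios and interpolate logarithmically between the
# bracketing elements.

#' Bracket a ratio between adjacent elements
#'
#' Finds the adjacent-Z pair whose Compton-to-total ratios enclose `R`.
#' An exact match returns a degenerate bracket (the element twice).  When
#' the elemental ratio sequence is non-monotone (possible above ~1 MeV,
#' where R is nearly flat in Z) more than one adjacent pair may enclose
#' `R`; the pair with the smallest `Z1` is chosen, deterministically.
#'
#' @param R The material's ratio at one energy.
#' @param ratios Data frame with columns `Z` (adjacent coverage not
#'   required, but pairs are taken between consecutive rows) and `ratio`,
#'   sorted by `Z`; see [elemental_ratios()].
#' @return List with `Z1`, `R1`, `Z2`, `R2`.
#' @examples
#' r <- data.frame(Z = 13:14, ratio = c(0.1438, 0.1145))
#' bracket_ratio(0.1313, r)
#' @export
bracket_ratio <- function(R, ratios) {
  stopifnot(is.data.frame(ratios), all(c("Z", "ratio") %in% names(ratios)),
            nrow(ratios) >= 1L, length(R) == 1L, is.finite(R))
  if (is.unsorted(ratios$Z, strictly = TRUE))
    stop("'ratios' must be sorted by strictly increasing Z")
  hit <- which(ratios$ratio == R)
  if (length(hit) > 0L) {
    i <- hit[1L]
    return(list(Z1 = ratios$Z[i], R1 = R, Z2 = ratios$Z[i], R2 = R))
  }
  if (nrow(ratios) == 1L)
    stop(sprintf("ratio R=%g not matched by the single element available", R))
  r <- ratios$ratio
  lo <- pmin(r[-length(r)], r[-1L])
  hi <- pmax(r[-length(r)], r[-1L])
  enclosing <- which(R >= lo & R <= hi)
  if (length(enclosing) == 0L)
    stop(sprintf(
      "ratio R=%g lies outside the span [%g, %g] of the elemental ratios",
      R, min(r), max(r)))
  i <- enclosing[1L]
  list(Z1 = ratios$Z[i], R1 = r[i], Z2 = ratios$Z[i + 1L], R2 = r[i + 1L])
}

#' Logarithmic interpolation of the equivalent atomic number
#'
#' Interpolates Zeq between the two bracketing elements on the logarithm of
#' the Compton-to-total ratio:
#' `Zeq = (Z1 (log R2 - log R) + Z2 (log R - log R1)) / (log R2 - log R1)`.
#' The logarithm base cancels; natural logs are used.  A degenerate
#' bracket (`Z1 == Z2`) returns `Z1`.
#'
#' @param R Material ratio, within the closed interval bounded by `R1` and
#'   `R2`; all ratios must be positive.
#' @param Z1,Z2 Bracketing atomic numbers.
#' @param R1,R2 The bracketing elements' ratios.
#' @return The equivalent atomic number, in `[Z1, Z2]`.
#' @examples
#' interpolate_zeq(0.1313, 13, 0.1438, 14, 0.1145)  # 13.40
#' @export
interpolate_zeq <- function(R, Z1, R1, Z2, R2) {
  if (any(c(R, R1, R2) <= 0)) stop("ratios must be positive")
  if (Z1 == Z2) return(as.numeric(Z1))
  if (R1 == R2)
    stop("R1 == R2 with distinct bracketing elements: cannot interpolate")
  if (R < min(R1, R2) || R > max(R1, R2))
    stop(sprintf("R=%g outside the bracket [%g, %g]", R, min(R1, R2),
                 max(R1, R2)))
  (Z1 * (log(R2) - log(R)) + Z2 * (log(R) - log(R1))) / (log(R2) - log(R1))
}

#' Equivalent atomic number of a material over an energy grid
#'
#' For each grid energy: compute the material's Compton-to-total ratio,
#' compute the same ratio for all elements in `zrange`, bracket, and
#' interpolate with [interpolate_zeq()].
#'
#' @param m A [material()].
#' @param ds An `attenuation_dataset` covering `zrange` and the grid.
#' @param grid Energies in MeV (default [standard_energy_grid()]).
#' @param zrange Elements available for bracketing (default 4:30; ratios
#'   outside their span are an error, not an extrapolation).
#' @param convention Total-coefficient convention (see
#'   [interpolate_coefficient()]).
#' @return Data frame of class `zeq_curve` with columns `material`,
#'   `energy_MeV`, `R`, `Z1`, `R1`, `Z2`, `R2`, `Zeq`.
#' @export
zeq_curve <- function(m, ds, grid = standard_energy_grid(), zrange = 4:30,
                      convention = c("without_coherent", "with_coherent")) {
  stopifnot(inherits(m, "material"))
  convention <- match.arg(convention)
  rows <- lapply(grid, function(e) {
    R <- compton_ratio(m, ds, e, convention)
    ratios <- elemental_ratios(ds, e, zrange, convention)
    br <- tryCatch(bracket_ratio(R, ratios), error = function(err)
      stop("at E=", e, " MeV: ", conditionMessage(err), call. = FALSE))
    data.frame(material = m$name, energy_MeV = e, R = R,
               Z1 = br$Z1, R1 = br$R1, Z2 = br$Z2, R2 = br$R2,
               Zeq = interpolate_zeq(R, br$Z1, br$R1, br$Z2, br$R2))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("zeq_curve", "data.frame")
  out
}
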
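# Effective atomic number for total photon interaction by the
# cross-section-ratio method, and tissue-equivalence band screening.

#' Effective atomic number of a material over an energy grid
#'
#' Cross-section-ratio method: `Zeff = sigma_a / sigma_e`, where the
#' average atomic cross section is
#' `sigma_a = (mu/rho)_m / (N_A sum_i w_i / A_i)` and the average
#' electronic cross section is
#' `sigma_e = (1/N_A) sum_i f_i (A_i / Z_i) (mu/rho)_i`, with `w_i` weight
#' fractions, `f_i` number (mole) fractions and `A_i` atomic weights.
#' A pure element returns its own Z at every energy.
#'
#' @param m A [material()].
#' @param ds An `attenuation_dataset` covering the constituents and grid.
#' @param grid Energies in MeV (default [standard_energy_grid()]).
#' @param convention Total-coefficient convention; the customary choice
#'   for Zeff of total photon interaction is `"with_coherent"` (default
#'   here, unlike the buildup-oriented ratio R).
#' @return Data frame of class `zeff_curve` with columns `material`,
#'   `energy_MeV`, `Zeff`.
#' @export
zeff_curve <- function(m, ds, grid = standard_energy_grid(),
                       convention = c("with_coherent", "without_coherent")) {
  stopifnot(inherits(m, "material"))
  convention <- match.arg(convention)
  m <- normalize_material(m)
  A <- atomic_weight(m$z)
  moles <- m$weight_fraction / A          # mol of atoms per gram, by element
  f <- moles / sum(moles)                 # number fractions
  mu_el <- vapply(m$z, function(z)
    interpolate_coefficient(ds, z, "total", grid, convention),
    numeric(length(grid)))
  if (length(grid) == 1L) mu_el <- matrix(mu_el, nrow = 1L)
  mu_mat <- as.numeric(mu_el %*% m$weight_fraction)
  sigma_a <- mu_mat / sum(moles)          # N_A cancels in the ratio
  sigma_e <- as.numeric(mu_el %*% (f * A / m$z))
  out <- data.frame(material = m$name, energy_MeV = grid,
                    Zeff = sigma_a / sigma_e)
  class(out) <- c("zeff_curve", "data.frame")
  out
}

#' Energy bands where two Zeff curves agree within tolerance
#'
#' Scans two curves sharing an energy grid and reports maximal runs of
#' consecutive grid energies where the substitute's Zeff matches the
#' organ's within `tol`, as `[first, last]` energy intervals.  This is the
#' screening step for tissue-equivalent phantom materials: a good
#' substitute matches the organ's Zeff over the energy band of interest.
#'
#' @param organ,substitute `zeff_curve` data frames (or any with columns
#'   `energy_MeV` and `Zeff`) on identical grids.
#' @param tol Tolerance on the Zeff difference (default 0.05 relative).
#' @param mode `"relative"` compares `|dZ| / Zeff_organ`; `"absolute"`
#'   compares `|dZ|` (symmetric in the two curves).
#' @return Data frame of class `equivalence_bands` with columns `organ`,
#'   `substitute`, `E_from_MeV`, `E_to_MeV`, `n_points`; zero rows when
#'   the curves never agree.
#' @export
equivalence_bands <- function(organ, substitute, tol = 0.05,
                              mode = c("relative", "absolute")) {
  mode <- match.arg(mode)
  stopifnot(all(c("energy_MeV", "Zeff") %in% names(organ)),
            all(c("energy_MeV", "Zeff") %in% names(substitute)),
            tol > 0)
  o <- organ[order(organ$energy_MeV), ]
  s <- substitute[order(substitute$energy_MeV), ]
  if (nrow(o) != nrow(s) ||
      !isTRUE(all.equal(o$energy_MeV, s$energy_MeV, tolerance = 1e-9)))
    stop("the two curves must share the same energy grid")
  dz <- abs(s$Zeff - o$Zeff)
  ok <- if (mode == "relative") dz / o$Zeff <= tol else dz <= tol
  runs <- rle(ok)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values
  organ_name <- if ("material" %in% names(o)) o$material[1L] else "organ"
  sub_name <- if ("material" %in% names(s)) s$material[1L] else "substitute"
  n_bands <- sum(keep)
  out <- data.frame(
    organ = rep(organ_name, n_bands),
    substitute = rep(sub_name, n_bands),
    E_from_MeV = o$energy_MeV[starts[keep]],
    E_to_MeV = o$energy_MeV[ends[keep]],
    n_points = runs$lengths[keep]
  )
  rownames(out) <- NULL
  class(out) <- c("equivalence_bands", "data.frame")
  out
}
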
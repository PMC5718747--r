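# Elemental photon-interaction data: partial and total mass attenuation
# coefficients (cm^2/g) per element and energy, energy interpolation,
# the weight-fraction mixture rule, the Compton-to-total ratio R, and
# process-crossover energies.

.atten_columns <- c("Z", "energy_MeV", "photoelectric", "incoherent",
                    "coherent", "pair_nuclear", "pair_electron",
                    "total_with_coherent", "total_without_coherent")

.partial_processes <- c("photoelectric", "incoherent", "coherent",
                        "pair_nuclear", "pair_electron")

#' The 25-point standard energy grid
#'
#' Energies (MeV) at which elemental GP fitting parameter libraries in the
#' ANSI/ANS-6.4.3-1991 style are tabulated, spanning 0.015-15 MeV.
#'
#' @return Numeric vector of 25 energies in MeV, increasing.
#' @export
standard_energy_grid <- function() {
  c(0.015, 0.02, 0.03, 0.04, 0.05, 0.06, 0.08, 0.1, 0.15, 0.2,
    0.3, 0.4, 0.5, 0.6, 0.8, 1, 1.5, 2, 3, 4, 5, 6, 8, 10, 15)
}

#' Validate a data frame of elemental attenuation coefficients
#'
#' Checks the schema (see [read_attenuation()]), non-negativity,
#' consistency of the totals with the sum of their partials (1e-6
#' relative), and strictly increasing energies per element; rows are
#' returned grouped by `Z` and sorted by energy.
#'
#' @param df Data frame with columns `Z`, `energy_MeV`, `photoelectric`,
#'   `incoherent`, `coherent`, `pair_nuclear`, `pair_electron`,
#'   `total_with_coherent`, `total_without_coherent` (all cm^2/g except
#'   the first two).
#' @return The validated data frame with class `attenuation_dataset`.
#' @export
as_attenuation_dataset <- function(df) {
  df <- as.data.frame(df)
  missing <- setdiff(.atten_columns, names(df))
  if (length(missing) > 0L)
    stop("attenuation table is missing column(s): ",
         paste(missing, collapse = ", "))
  df <- df[, .atten_columns]
  num <- .atten_columns[-1L]
  for (cc in num) df[[cc]] <- as.numeric(df[[cc]])
  if (anyNA(df)) stop("attenuation table contains missing/non-numeric values")
  if (any(df$Z != round(df$Z)) || any(df$Z < 1) || any(df$Z > 100))
    stop("'Z' must be integer atomic numbers in [1, 100]")
  df$Z <- as.integer(df$Z)
  coef_cols <- setdiff(num, "energy_MeV")
  if (any(df$energy_MeV <= 0)) stop("energies must be positive")
  if (any(df[, coef_cols] < 0)) stop("negative attenuation coefficient")
  sum_wo <- rowSums(df[, c("photoelectric", "incoherent", "pair_nuclear",
                           "pair_electron")])
  sum_wc <- sum_wo + df$coherent
  rel <- function(a, b) abs(a - b) / pmax(abs(b), .Machine$double.xmin)
  if (any(rel(df$total_without_coherent, sum_wo) > 1e-6))
    stop("'total_without_coherent' does not equal the sum of its partials")
  if (any(rel(df$total_with_coherent, sum_wc) > 1e-6))
    stop("'total_with_coherent' does not equal the sum of its partials")
  df <- df[order(df$Z, df$energy_MeV), , drop = FALSE]
  dup <- unlist(tapply(df$energy_MeV, df$Z, function(e) diff(e) <= 0))
  if (any(dup))
    stop("energy grid not strictly increasing for some element")
  rownames(df) <- NULL
  class(df) <- c("attenuation_dataset", "data.frame")
  df
}

#' Read an elemental attenuation coefficient table
#'
#' CSV schema: header
#' `Z,energy_MeV,photoelectric,incoherent,coherent,pair_nuclear,pair_electron,total_with_coherent,total_without_coherent`,
#' one row per (element, energy), coefficients in cm^2/g, `#` comments
#' allowed.  Tables exported from XCOM/WinXCom can be reshaped to this
#' schema.
#'
#' @param path CSV file path.
#' @return An `attenuation_dataset` (see [as_attenuation_dataset()]).
#' @export
read_attenuation <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", strip.white = TRUE)
  as_attenuation_dataset(df)
}

#' Write an attenuation dataset to CSV
#'
#' @param ds An `attenuation_dataset`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_attenuation <- function(ds, path) {
  stopifnot(inherits(ds, "attenuation_dataset"))
  utils::write.csv(as.data.frame(ds), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# map a process name (+ convention for "total") to a dataset column
.process_column <- function(process,
                            convention = c("without_coherent",
                                           "with_coherent")) {
  convention <- match.arg(convention)
  known <- c(.partial_processes, "pair", "total")
  process <- match.arg(process, known)
  if (process == "total")
    return(if (convention == "with_coherent") "total_with_coherent"
           else "total_without_coherent")
  process
}

#' Log-log linear interpolation
#'
#' Interpolates linearly in (ln x, ln y): the standard scheme for photon
#' cross sections versus energy.  Exact at grid points and exact for
#' power-law curves.
#'
#' @param x Increasing positive abscissae (e.g. energies in MeV).
#' @param y Positive ordinates tabulated at `x`.
#' @param xout Query points, all within `range(x)`.
#' @return Interpolated values at `xout`.
#' @export
loglog_interpolate <- function(x, y, xout) {
  if (length(x) != length(y) || length(x) < 1L)
    stop("'x' and 'y' must have equal, positive length")
  if (any(xout < min(x)) || any(xout > max(x)))
    stop(sprintf("query point outside tabulated span [%g, %g]",
                 min(x), max(x)))
  if (length(x) == 1L) return(rep(y, length(xout)))
  # grid points are returned verbatim; zero/negative tabulated values are
  # only fatal if a query actually needs them
  node <- match(xout, x)
  at_node <- !is.na(node)
  out <- numeric(length(xout))
  out[at_node] <- y[node[at_node]]
  k <- !at_node
  if (any(k)) {
    idx <- findInterval(xout[k], x, rightmost.closed = TRUE)
    lo <- y[idx]; hi <- y[idx + 1L]
    if (any(lo <= 0) || any(hi <= 0))
      stop("log-log interpolation requires positive tabulated values at the bracketing grid points")
    t <- (log(xout[k]) - log(x[idx])) / (log(x[idx + 1L]) - log(x[idx]))
    out[k] <- exp((1 - t) * log(lo) + t * log(hi))
  }
  out
}

#' Interpolate an elemental coefficient in energy
#'
#' Picks the per-element curve for one interaction process out of an
#' attenuation dataset and evaluates it at arbitrary energies by log-log
#' interpolation.
#'
#' @param ds An `attenuation_dataset`.
#' @param z Atomic number (or element symbol).
#' @param process One of `"photoelectric"`, `"incoherent"`, `"coherent"`,
#'   `"pair_nuclear"`, `"pair_electron"`, `"pair"` (nuclear + electron
#'   field) or `"total"`.
#' @param energy Energies in MeV, within the element's tabulated span.
#' @param convention Which total to use: `"without_coherent"` (default;
#'   coherent scattering does not remove photons from a beam in the
#'   buildup sense) or `"with_coherent"`.
#' @return Mass attenuation coefficients in cm^2/g at `energy`.
#' @export
interpolate_coefficient <- function(ds, z, process, energy,
                                    convention = c("without_coherent",
                                                   "with_coherent")) {
  stopifnot(inherits(ds, "attenuation_dataset"))
  z <- element_z(z)
  stopifnot(length(z) == 1L)
  rows <- ds[ds$Z == z, , drop = FALSE]
  if (nrow(rows) == 0L)
    stop("element Z=", z, " not present in the attenuation dataset")
  col <- .process_column(process, match.arg(convention))
  y <- if (col == "pair") rows$pair_nuclear + rows$pair_electron
       else rows[[col]]
  loglog_interpolate(rows$energy_MeV, y, energy)
}

#' Mixture-rule mass attenuation coefficient
#'
#' Weight-fraction additivity: the coefficient of a multi-element material
#' is `sum_i w_i (mu/rho)_i(E)` with normalized weight fractions `w_i`.
#'
#' @param m A [material()].
#' @inheritParams interpolate_coefficient
#' @return Coefficients in cm^2/g at `energy`.
#' @export
mixture_coefficient <- function(m, ds, process, energy,
                                convention = c("without_coherent",
                                               "with_coherent")) {
  stopifnot(inherits(m, "material"))
  convention <- match.arg(convention)
  m <- normalize_material(m)
  per_el <- vapply(seq_along(m$z), function(i) {
    interpolate_coefficient(ds, m$z[i], process, energy, convention)
  }, numeric(length(energy)))
  as.numeric(if (length(energy) == 1L) sum(per_el * m$weight_fraction)
             else per_el %*% m$weight_fraction)
}

#' Compton-to-total attenuation ratio R
#'
#' The ratio `(mu/rho)_Compton / (mu/rho)_total` of a material or element,
#' the matching quantity of the equivalent-atomic-number method.
#'
#' @param x A [material()], or an atomic number / element symbol.
#' @inheritParams interpolate_coefficient
#' @return Ratios in (0, 1] at `energy`.
#' @export
compton_ratio <- function(x, ds, energy,
                          convention = c("without_coherent",
                                         "with_coherent")) {
  convention <- match.arg(convention)
  if (inherits(x, "material")) {
    inc <- mixture_coefficient(x, ds, "incoherent", energy, convention)
    tot <- mixture_coefficient(x, ds, "total", energy, convention)
  } else {
    inc <- interpolate_coefficient(ds, x, "incoherent", energy, convention)
    tot <- interpolate_coefficient(ds, x, "total", energy, convention)
  }
  if (any(tot <= 0)) stop("total attenuation coefficient is zero")
  inc / tot
}

#' Compton-to-total ratios of all elements at one energy
#'
#' @inheritParams interpolate_coefficient
#' @param zrange Atomic numbers to evaluate (default 4:30, the span of
#'   elemental GP parameter libraries).
#' @return Data frame with columns `Z` and `ratio`, sorted by `Z`.
#' @export
elemental_ratios <- function(ds, energy, zrange = 4:30,
                             convention = c("without_coherent",
                                            "with_coherent")) {
  stopifnot(length(energy) == 1L)
  convention <- match.arg(convention)
  data.frame(
    Z = as.integer(zrange),
    ratio = vapply(zrange, function(z)
      compton_ratio(z, ds, energy, convention), numeric(1))
  )
}

#' Crossover energy of two interaction processes
#'
#' Finds the energy at which the mixture coefficients of two processes are
#' equal, i.e. the root of `ln muA(E) - ln muB(E)` under log-log energy
#' interpolation, located by bisection to a relative energy tolerance.
#' The sign of the difference must change exactly once across the grid
#' energies inside the bracket.
#'
#' @param m A [material()].
#' @param ds An `attenuation_dataset`.
#' @param process_a,process_b Process names (see
#'   [interpolate_coefficient()]); the result is symmetric in the two.
#' @param bracket Length-2 numeric `(Elo, Ehi)` in MeV.
#' @param convention Total-coefficient convention, used when either
#'   process is `"total"`.
#' @param tol Relative tolerance on the energy (default 1e-6).
#' @return Crossover energy in MeV.
#' @examples
#' ds <- synthetic_attenuation()
#' crossover_energy(tissue_registry("water"), ds,
#'                  "photoelectric", "incoherent", c(0.015, 0.2))
#' @export
crossover_energy <- function(m, ds, process_a, process_b, bracket,
                             convention = c("without_coherent",
                                            "with_coherent"),
                             tol = 1e-6) {
  stopifnot(inherits(m, "material"), length(bracket) == 2L,
            bracket[1] < bracket[2])
  convention <- match.arg(convention)
  mu <- function(p, e) mixture_coefficient(m, ds, p, e, convention)
  grid <- sort(unique(ds$energy_MeV))
  grid <- grid[grid >= bracket[1] & grid <= bracket[2]]
  nodes <- sort(unique(c(bracket, grid)))
  g <- function(e) {
    a <- mu(process_a, e); b <- mu(process_b, e)
    if (any(a <= 0) || any(b <= 0))
      stop("process coefficient nonpositive inside the bracket; shrink it")
    log(a) - log(b)
  }
  gv <- g(nodes)
  # count distinct roots along the nodes: an exact zero at a node is one
  # root (a sign flip straddling it belongs to that same root); a sign
  # flip between two consecutive nonzero nodes is one root
  zero_nodes <- which(gv == 0)
  nz <- which(gv != 0)
  flips <- integer(0)
  if (length(nz) >= 2L) {
    for (j in seq_len(length(nz) - 1L)) {
      i1 <- nz[j]; i2 <- nz[j + 1L]
      if (sign(gv[i1]) != sign(gv[i2]) && i2 == i1 + 1L)
        flips <- c(flips, i1)  # flip with no zero node in between
    }
  }
  n_roots <- length(zero_nodes) + length(flips)
  if (n_roots == 0L)
    stop("no crossover inside the bracket [",
         bracket[1], ", ", bracket[2], "] MeV")
  if (n_roots > 1L) stop("multiple crossovers inside the bracket")
  if (length(zero_nodes) == 1L) return(nodes[zero_nodes])
  lo <- nodes[flips]; hi <- nodes[flips + 1L]
  glo <- gv[flips]
  while ((hi - lo) / lo > tol) {
    mid <- sqrt(lo * hi)  # bisect in log energy, matching the interpolant
    gm <- g(mid)
    if (gm == 0) return(mid)
    if (sign(gm) == sign(glo)) {
      lo <- mid; glo <- gm
    } else hi <- mid
  }
  sqrt(lo * hi)
}

#' Photoelectric/Compton and Compton/pair crossover energies
#'
#' Convenience wrapper computing `E_pe` (photoelectric = Compton) and
#' `E_pp` (Compton = pair production) for a material.  These delimit the
#' Compton-dominated regime in which photon buildup is largest.  `E_pp`
#' is `NA` when the dataset does not extend past the crossover.
#'
#' @inheritParams crossover_energy
#' @return Data frame with columns `material`, `Epe_MeV`, `Epp_MeV`.
#' @export
crossover_summary <- function(m, ds,
                              convention = c("without_coherent",
                                             "with_coherent"),
                              tol = 1e-6) {
  convention <- match.arg(convention)
  span <- range(ds$energy_MeV)
  epe <- crossover_energy(m, ds, "photoelectric", "incoherent",
                          c(span[1], min(1, span[2])), convention, tol)
  # pair production is zero below threshold; search above 1.1 MeV only
  epp <- tryCatch(
    crossover_energy(m, ds, "incoherent", "pair",
                     c(1.1, span[2]), convention, tol),
    error = function(e) NA_real_
  )
  data.frame(material = m$name, Epe_MeV = epe, Epp_MeV = epp)
}
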
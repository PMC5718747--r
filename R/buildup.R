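# The five-parameter geometric-progression buildup formula (Harima et al.):
#   B(E, x) = 1 + (b - 1) (K^x - 1) / (K - 1)   for K != 1
#   B(E, x) = 1 + (b - 1) x                     for K  = 1
#   K(E, x) = c x^a + d [tanh(x/Xk - 2) - tanh(-2)] / [1 - tanh(-2)]
# valid for penetration depths x <= 40 mfp.  b is the buildup factor at
# 1 mfp; K is the per-mfp dose-multiplication factor.

.as_gp_row <- function(p) {
  if (is.data.frame(p)) {
    stopifnot(nrow(p) == 1L)
    p <- as.list(p)
  }
  need <- c("a", "b", "c", "d", "Xk")
  if (!all(need %in% names(p)))
    stop("GP parameter set must provide a, b, c, d, Xk")
  lapply(p[need], as.numeric)
}

#' Dose-multiplication factor K of the GP formula
#'
#' `K = c x^a + d (tanh(x/Xk - 2) - tanh(-2)) / (1 - tanh(-2))`.
#'
#' @param x Penetration depths in mean free paths, `0 < x <= 40`
#'   (`x^a` diverges at 0 for the common case `a < 0`).
#' @param p GP parameter set: a one-row data frame or list with fields
#'   `a`, `b`, `c`, `d`, `Xk` (`Xk > 0`).
#' @return K at each depth.  An evaluation yielding `K <= 0` (unphysical
#'   parameters) is an error.
#' @export
dose_multiplication_k <- function(x, p) {
  p <- .as_gp_row(p)
  if (p$Xk <= 0) stop("'Xk' must be positive")
  if (any(x <= 0) || any(x > 40))
    stop("depths must satisfy 0 < x <= 40 mfp")
  k <- p$c * x^p$a +
    p$d * (tanh(x / p$Xk - 2) - tanh(-2)) / (1 - tanh(-2))
  if (any(k <= 0))
    stop("K <= 0 at some depth: unphysical GP parameter set")
  k
}

#' GP buildup factor
#'
#' Evaluates the geometric-progression buildup formula.  `x = 0` returns 1
#' by the algebraic limit without evaluating K; `x = 1` returns `b`
#' exactly, since `(K^1 - 1)/(K - 1) = 1` identically (evaluating the
#' formula instead would re-round `1 + (b - 1)` by one ulp); `|K - 1| <
#' 1e-8` uses the removable-singularity branch `1 + (b - 1) x`; otherwise
#' `1 + (b - 1)(K^x - 1)/(K - 1)`.
#'
#' @param x Penetration depths in mean free paths, in `[0, 40]`.
#' @inheritParams dose_multiplication_k
#' @return Buildup factors at each depth (dimensionless, >= 1 for
#'   physical parameter sets).
#' @examples
#' buildup_factor(c(0, 1, 5), list(a = -0.1, b = 2.5, c = 1.7, d = 0.05,
#'                                 Xk = 14.2))
#' @export
buildup_factor <- function(x, p) {
  pl <- .as_gp_row(p)
  if (any(x < 0) || any(x > 40))
    stop("depths must satisfy 0 <= x <= 40 mfp")
  out <- numeric(length(x))
  zero <- x == 0
  one <- x == 1
  out[zero] <- 1
  out[one] <- pl$b
  rest <- !zero & !one
  if (any(rest)) {
    xs <- x[rest]
    k <- dose_multiplication_k(xs, pl)
    b1 <- pl$b - 1
    lin <- abs(k - 1) < 1e-8
    v <- numeric(length(xs))
    v[lin] <- 1 + b1 * xs[lin]
    v[!lin] <- 1 + b1 * (k[!lin]^xs[!lin] - 1) / (k[!lin] - 1)
    out[rest] <- v
  }
  out
}

#' Buildup factors on an energy x depth grid
#'
#' Evaluates [buildup_factor()] for every row of a GP parameter table at
#' every requested depth.
#'
#' @param gp_table Data frame with columns `energy_MeV,a,b,c,d,Xk` (one
#'   row per energy), e.g. from [material_gp_table()] or
#'   [reference_gp_params()]; an optional `material` column is carried
#'   through.
#' @param depths Depths in mean free paths, all in `(0, 40]` (default:
#'   the customary reporting set 1-8, 10, 15, 20, 25, 30, 35, 40).
#' @return Long-format data frame of class `buildup_grid` with columns
#'   `material` (if present), `energy_MeV`, `depth_mfp`, `K`, `B`.
#' @export
buildup_grid <- function(gp_table,
                         depths = c(1:8, 10, 15, 20, 25, 30, 35, 40)) {
  stopifnot(is.data.frame(gp_table), nrow(gp_table) >= 1L)
  if (any(depths <= 0) || any(depths > 40))
    stop("depths must lie in (0, 40] mfp")
  if (!"energy_MeV" %in% names(gp_table))
    stop("'gp_table' must have an 'energy_MeV' column")
  depths <- sort(unique(depths))
  rows <- lapply(seq_len(nrow(gp_table)), function(i) {
    p <- .as_gp_row(gp_table[i, ])
    df <- data.frame(energy_MeV = gp_table$energy_MeV[i],
                     depth_mfp = depths,
                     K = dose_multiplication_k(depths, p),
                     B = buildup_factor(depths, p))
    if ("material" %in% names(gp_table))
      df <- cbind(data.frame(material = gp_table$material[i]), df)
    df
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("buildup_grid", "data.frame")
  out
}

#' Energy of maximal buildup at a fixed depth
#'
#' Returns the grid energy at which the buildup factor is largest at the
#' requested depth (the broad Compton-regime maximum).  Ties are broken
#' toward the lower energy.
#'
#' @param grid A `buildup_grid` from [buildup_grid()].
#' @param depth A depth present in the grid (mfp).
#' @return List with `depth_mfp`, `Epeak_MeV` and `B_peak` (and `material`
#'   when the grid carries one).
#' @export
peak_energy <- function(grid, depth) {
  stopifnot(inherits(grid, "buildup_grid"), length(depth) == 1L)
  sub <- grid[grid$depth_mfp == depth, , drop = FALSE]
  if (nrow(sub) == 0L)
    stop("depth ", depth, " mfp is not a column of the grid")
  sub <- sub[order(sub$energy_MeV), , drop = FALSE]
  i <- which.max(sub$B)  # first maximum = lowest energy on ties
  out <- list(depth_mfp = depth, Epeak_MeV = sub$energy_MeV[i],
              B_peak = sub$B[i])
  if ("material" %in% names(sub)) out <- c(list(material = sub$material[1L]), out)
  out
}

#' Percent differences between a buildup grid and a reference tabulation
#'
#' Cell-wise `100 |B - B_ref| / B_ref` over identical (energy, depth)
#' index sets, with signed differences and summary statistics.
#'
#' @param grid A `buildup_grid` (or any data frame with `energy_MeV`,
#'   `depth_mfp` and `B`).
#' @param reference Data frame with columns `energy_MeV`, `depth_mfp` and
#'   `B` holding the reference values on the same index set.
#' @return List with `table` (columns `energy_MeV, depth_mfp, B, B_ref,
#'   percent_diff, abs_percent_diff`, ordered by energy then depth) and
#'   `min`, `max`, `mean` of the absolute percent differences.
#' @export
compare_to_reference <- function(grid, reference) {
  need <- c("energy_MeV", "depth_mfp", "B")
  stopifnot(all(need %in% names(grid)), all(need %in% names(reference)))
  g <- as.data.frame(grid)[, need]
  r <- as.data.frame(reference)[, need]
  names(r)[3] <- "B_ref"
  key <- function(d) paste(signif(d$energy_MeV, 10), signif(d$depth_mfp, 10))
  if (nrow(g) != nrow(r) || !setequal(key(g), key(r)))
    stop("grid and reference do not share the same (energy, depth) cells")
  tab <- merge(g, r, by = c("energy_MeV", "depth_mfp"))
  tab <- tab[order(tab$energy_MeV, tab$depth_mfp), , drop = FALSE]
  tab$percent_diff <- 100 * (tab$B - tab$B_ref) / tab$B_ref
  tab$abs_percent_diff <- abs(tab$percent_diff)
  rownames(tab) <- NULL
  list(table = tab,
       min = min(tab$abs_percent_diff),
       max = max(tab$abs_percent_diff),
       mean = mean(tab$abs_percent_diff))
}
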
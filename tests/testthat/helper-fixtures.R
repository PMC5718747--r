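# Shared in-code fixtures.  Everything is generated at test time; no
# binary files.

# a hand-rolled two-element dataset whose curves are exact power laws:
#   photoelectric = A_pe * E^-3,  incoherent = A_inc * E^-0.3
# (coherent/pair zero), so every interpolation has a closed form.
powerlaw_atten <- function(z = c(8L, 13L), grid = c(0.01, 0.03, 0.1, 0.3,
                                                    1, 3, 10, 30, 100),
                           A_pe = NULL, A_inc = NULL) {
  if (is.null(A_pe)) A_pe <- 1e-6 * z^3
  if (is.null(A_inc)) A_inc <- rep(0.15, length(z))
  rows <- lapply(seq_along(z), function(i) {
    pe <- A_pe[i] * grid^-3
    inc <- A_inc[i] * grid^-0.3
    data.frame(Z = z[i], energy_MeV = grid, photoelectric = pe,
               incoherent = inc, coherent = 0, pair_nuclear = 0,
               pair_electron = 0, total_with_coherent = pe + inc,
               total_without_coherent = pe + inc)
  })
  as_attenuation_dataset(do.call(rbind, rows))
}

# a minimal valid GP library built by hand (constant in Z unless slopes
# are given): handy for pass-through and constant-interpolation checks
flat_gp_library <- function(z = c(7L, 8L), a = 0.05, b = 2, c = 1.3,
                            d = 0.02, Xk = 14) {
  grid <- standard_energy_grid()
  rows <- lapply(z, function(zz)
    data.frame(Z = zz, energy_MeV = grid, a = a, b = b, c = c, d = d,
               Xk = Xk))
  as_gp_library(do.call(rbind, rows))
}

expect_rel_equal <- function(object, expected, tol) {
  expect_true(all(abs(object - expected) <= tol * abs(expected)),
              label = sprintf("max rel err %.3g vs tol %.3g",
                              max(abs(object - expected) / abs(expected)),
                              tol))
}
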
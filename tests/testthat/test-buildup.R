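# Frozen oracle values below were computed with an independent
# 50-digit evaluation of the GP formula (mpmath), not with this package.

test_that("the dose-multiplication factor K matches hand arithmetic", {
  # constant case: c = 1, a = 0, d = 0 -> K = 1 for every depth
  p <- list(a = 0, b = 2, c = 1, d = 0, Xk = 14)
  expect_equal(dose_multiplication_k(c(0.5, 1, 17, 40), p), rep(1, 4))

  # at x = 2*Xk the tanh term reduces to w = tanh(2)/(1 + tanh(2))
  p2 <- list(a = 0.157, b = 1.332, c = 0.509, d = -0.0780, Xk = 14.48)
  w <- 0.49084218055563291
  expect_equal(dose_multiplication_k(2 * 14.48, p2),
               0.509 * (2 * 14.48)^0.157 - 0.0780 * w, tolerance = 1e-14)
  expect_equal(dose_multiplication_k(2 * 14.48, p2),
               0.82513043624614029, tolerance = 1e-14)

  expect_error(dose_multiplication_k(0, p2), "0 < x")
  expect_error(dose_multiplication_k(41, p2), "<= 40")
  # unphysical parameters driving K <= 0 are flagged
  expect_error(dose_multiplication_k(1, list(a = 0, b = 2, c = -1, d = 0,
                                             Xk = 14)), "unphysical")
})

test_that("the buildup factor honours its algebraic identities", {
  p <- list(a = 0.157, b = 1.332, c = 0.509, d = -0.0780, Xk = 14.48)
  # x = 0 -> 1 without evaluating K (a > 0 here, but also for a < 0)
  expect_identical(buildup_factor(0, p), 1)
  expect_identical(buildup_factor(0, list(a = -0.2, b = 2, c = 1.5,
                                          d = 0.05, Xk = 14)), 1)
  # x = 1 -> exactly b
  expect_equal(buildup_factor(1, p), 1.332)
  # forced K = 1: linear branch 1 + (b-1) x
  plin <- list(a = 0, b = 2, c = 1, d = 0, Xk = 14)
  expect_equal(buildup_factor(10, plin), 11)
  # frozen arbitrary-precision oracle at x = 5
  expect_equal(buildup_factor(5, p), 1.8446613221954581, tolerance = 1e-14)
  expect_error(buildup_factor(-1, p), "0 <= x")
  expect_error(buildup_factor(41, p), "<= 40")
})

test_that("the K -> 1 branches join continuously", {
  x <- 1:40
  for (eps in c(1e-9, -1e-9)) {
    p <- list(a = 0, b = 2.7, c = 1 + eps, d = 0, Xk = 14)  # K = 1 + eps
    expect_true(all(abs(buildup_factor(x, p) - (1 + 1.7 * x)) < 1e-6))
  }
})

test_that("published parameter rows give physical buildup curves", {
  gp <- reference_gp_params()
  expect_equal(nrow(gp), 300)
  x <- 1:40
  for (i in seq_len(nrow(gp))) {
    B <- buildup_factor(x, gp[i, ])
    expect_true(B[1] == gp$b[i],
                label = sprintf("%s at %g MeV: B(1) == b",
                                gp$material[i], gp$energy_MeV[i]))
    expect_true(all(B >= 1) && all(diff(B) >= 0),
                label = sprintf("%s at %g MeV: B >= 1 and nondecreasing",
                                gp$material[i], gp$energy_MeV[i]))
  }
})

test_that("buildup grids are complete matrices with the 1-mfp identity", {
  muscle <- reference_gp_params("skeletal_muscle")
  g <- buildup_grid(muscle, depths = c(1, 5, 40))
  expect_s3_class(g, "buildup_grid")
  expect_equal(nrow(g), 75)
  expect_equal(g$B[g$depth_mfp == 1], muscle$b)

  one <- buildup_grid(muscle[1, ], depths = 7)
  expect_equal(nrow(one), 1)

  expect_error(buildup_grid(muscle, depths = c(1, 41)), "40")
  expect_error(buildup_grid(muscle, depths = 0), "40|0")
})

test_that("peak energies land on the published grid energies", {
  muscle <- buildup_grid(reference_gp_params("skeletal_muscle"),
                         depths = 40)
  expect_equal(peak_energy(muscle, 40)$Epeak_MeV, 0.1)

  bone <- buildup_grid(reference_gp_params("cortical_bone"), depths = 40)
  expect_equal(peak_energy(bone, 40)$Epeak_MeV, 0.2)

  # ties break toward the lower energy
  flat <- buildup_grid(data.frame(energy_MeV = c(0.1, 0.2), a = 0, b = 2,
                                  c = 1, d = 0, Xk = 14), depths = 10)
  expect_equal(peak_energy(flat, 10)$Epeak_MeV, 0.1)

  single <- buildup_grid(data.frame(energy_MeV = 0.3, a = 0, b = 2, c = 1,
                                    d = 0, Xk = 14), depths = 10)
  expect_equal(peak_energy(single, 10)$Epeak_MeV, 0.3)
  expect_error(peak_energy(muscle, 39), "not a column")
})

test_that("low-energy buildup ordering reverses at high energy and depth", {
  # deep Compton regime: the lower-Zeq tissue builds up more at 0.05 MeV,
  # the higher-Zeq tissue more at 15 MeV (pair-production regime)
  adipose <- reference_gp_params("adipose_tissue")
  bone <- reference_gp_params("cortical_bone")
  b_at <- function(gp, e) buildup_factor(40, gp[gp$energy_MeV == e, ])
  expect_gt(b_at(adipose, 0.05), b_at(bone, 0.05))
  expect_gt(b_at(bone, 15), b_at(adipose, 15))
})

test_that("grid comparison computes per-cell percent differences", {
  muscle <- buildup_grid(reference_gp_params("skeletal_muscle"),
                         depths = c(1, 10, 40))
  self <- compare_to_reference(muscle, muscle)
  expect_equal(self$max, 0)
  expect_equal(self$table$percent_diff, rep(0, nrow(self$table)))

  doubled <- transform(as.data.frame(muscle), B = 2 * B)
  cmp <- compare_to_reference(muscle, doubled)
  expect_equal(cmp$table$abs_percent_diff, rep(50, nrow(cmp$table)))
  expect_equal(cmp$table$percent_diff, rep(-50, nrow(cmp$table)))

  other <- buildup_grid(reference_gp_params("skeletal_muscle"),
                        depths = c(1, 10))
  expect_error(compare_to_reference(muscle, other), "same \\(energy, depth\\)")
})
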
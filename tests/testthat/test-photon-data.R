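test_that("log-log interpolation is exact at nodes and on power laws", {
  grid <- c(0.01, 0.05, 0.2, 1, 5, 20)
  mu <- 2.5 * grid^-3
  expect_identical(loglog_interpolate(grid, mu, grid), mu)

  # power-law recovery at arbitrary interior points (closed form)
  set.seed(11)
  q <- exp(runif(50, log(0.01), log(20)))
  expect_rel_equal(loglog_interpolate(grid, mu, q), 2.5 * q^-3, 1e-12)

  # geometric midpoint of two nodes -> geometric mean of the values
  em <- sqrt(grid[2] * grid[3])
  expect_equal(loglog_interpolate(grid, mu, em), sqrt(mu[2] * mu[3]),
               tolerance = 1e-14)

  expect_error(loglog_interpolate(grid, mu, 100), "outside")
  expect_error(loglog_interpolate(c(1, 2), c(0, 1), 1.5), "positive")
})

test_that("the attenuation loader validates schema and physics", {
  ds <- powerlaw_atten()
  expect_s3_class(ds, "attenuation_dataset")
  expect_equal(sort(unique(ds$Z)), c(8L, 13L))

  bad <- as.data.frame(ds)
  bad$incoherent[3] <- -1
  bad$total_with_coherent <- NULL  # recompute would be needed anyway
  expect_error(as_attenuation_dataset(bad), "missing column")

  bad2 <- as.data.frame(ds)
  bad2$incoherent[3] <- -bad2$incoherent[3]
  expect_error(as_attenuation_dataset(bad2), "negative|does not equal")

  bad3 <- as.data.frame(ds)
  bad3$total_without_coherent[1] <- bad3$total_without_coherent[1] * 1.01
  expect_error(as_attenuation_dataset(bad3), "does not equal the sum")

  bad4 <- rbind(as.data.frame(ds), as.data.frame(ds)[1, ])
  expect_error(as_attenuation_dataset(bad4), "strictly increasing")

  # CSV round-trip through the declared schema
  f <- withr::local_tempfile(fileext = ".csv")
  write_attenuation(ds, f)
  back <- read_attenuation(f)
  expect_equal(as.data.frame(back), as.data.frame(ds), tolerance = 1e-12)
})

test_that("the mixture rule is weight-fraction additivity", {
  ds <- powerlaw_atten()
  e <- c(0.04, 0.7, 9)

  # single-element material returns the element's own coefficient
  o <- material("oxygen", "O", 1)
  expect_equal(mixture_coefficient(o, ds, "total", e),
               interpolate_coefficient(ds, 8, "total", e))

  # 50/50 mix -> arithmetic mean of the two elements
  mix <- material("mix", c("O", "Al"), c(0.5, 0.5))
  expect_equal(
    mixture_coefficient(mix, ds, "photoelectric", e),
    (interpolate_coefficient(ds, 8, "photoelectric", e) +
       interpolate_coefficient(ds, 13, "photoelectric", e)) / 2,
    tolerance = 1e-14)

  # mixing a material with itself leaves coefficients unchanged
  # (linearity in the weight fractions)
  mix2 <- material("mix2", c("O", "Al"), c(0.25 + 0.25, 0.5))
  expect_equal(mixture_coefficient(mix2, ds, "incoherent", e),
               mixture_coefficient(mix, ds, "incoherent", e))

  expect_error(mixture_coefficient(material("m", "Fe", 1), ds, "total", e),
               "not present")
})

test_that("the Compton ratio lies in (0,1] and decreases in Z", {
  ds <- synthetic_attenuation()
  grid <- standard_energy_grid()
  for (e in grid) {
    r <- elemental_ratios(ds, e, 4:30)$ratio
    expect_true(all(r > 0 & r <= 1))
    expect_true(all(diff(r) < 0))  # strictly decreasing in Z
  }

  # a dataset with only Compton interaction has R = 1 everywhere
  pure <- powerlaw_atten(A_pe = c(1e-300, 1e-300))
  expect_equal(compton_ratio(8, pure, c(0.02, 1, 50)), rep(1, 3),
               tolerance = 1e-12)
})

test_that("crossover energies are found by bisection on log-coefficients", {
  # curves mu_pe = E^-2 and mu_inc = E^-1 cross at exactly E = 1
  grid <- exp(seq(log(0.1), log(10), length.out = 7))
  pe <- grid^-2
  inc <- grid^-1
  ds <- as_attenuation_dataset(data.frame(
    Z = 8L, energy_MeV = grid, photoelectric = pe, incoherent = inc,
    coherent = 0, pair_nuclear = 0, pair_electron = 0,
    total_with_coherent = pe + inc, total_without_coherent = pe + inc))
  o <- material("oxygen", "O", 1)
  e_cross <- crossover_energy(o, ds, "photoelectric", "incoherent",
                              range(grid))
  expect_equal(e_cross, 1, tolerance = 1e-6)

  # invariant under swapping the two processes
  expect_equal(crossover_energy(o, ds, "incoherent", "photoelectric",
                                range(grid)), e_cross, tolerance = 1e-9)

  # closed-form oracle on the synthetic element family
  spec <- synthetic_spec()
  ds2 <- synthetic_attenuation(spec)
  for (z in c(6L, 13L, 26L)) {
    el <- material(paste0("Z", z), z, 1)
    expect_equal(
      crossover_energy(el, ds2, "photoelectric", "incoherent", c(0.011, 1)),
      synthetic_epe(spec, z), tolerance = 1e-5)
  }

  expect_error(crossover_energy(o, ds, "photoelectric", "incoherent",
                                c(2, max(grid))), "no crossover")
})

test_that("crossover at a grid node and multiple crossings are handled", {
  grid <- c(0.5, 1, 2)
  pe <- grid^-2
  inc <- grid^-1  # equal exactly at the node E = 1
  ds <- as_attenuation_dataset(data.frame(
    Z = 8L, energy_MeV = grid, photoelectric = pe, incoherent = inc,
    coherent = 0, pair_nuclear = 0, pair_electron = 0,
    total_with_coherent = pe + inc, total_without_coherent = pe + inc))
  o <- material("oxygen", "O", 1)
  expect_equal(crossover_energy(o, ds, "photoelectric", "incoherent",
                                c(0.5, 2)), 1)

  # a wiggly curve crossing twice inside the bracket is refused
  grid2 <- c(0.5, 1, 2, 4)
  a <- c(2, 0.5, 2, 2)     # crosses b = 1 twice
  b <- rep(1, 4)
  ds2 <- as_attenuation_dataset(data.frame(
    Z = 8L, energy_MeV = grid2, photoelectric = a, incoherent = b,
    coherent = 0, pair_nuclear = 0, pair_electron = 0,
    total_with_coherent = a + b, total_without_coherent = a + b))
  expect_error(crossover_energy(o, ds2, "photoelectric", "incoherent",
                                c(0.5, 4)), "multiple")
})

test_that("crossover_summary reports Epe (and NA Epp when out of span)", {
  ds <- synthetic_attenuation()
  w <- tissue_registry("water")
  cs <- crossover_summary(w, ds)
  expect_equal(cs$material, "water")
  expect_gt(cs$Epe_MeV, min(ds$energy_MeV))
  expect_lt(cs$Epe_MeV, 1)
  # with the default synthetic pair-production strength the Compton/pair
  # crossover lies beyond 100 MeV
  expect_true(is.na(cs$Epp_MeV))

  # a pair-heavy spec brings Epp inside the span
  spec <- synthetic_spec(c_ppn = 0.02, c_ppe = 2e-3)
  cs2 <- crossover_summary(w, synthetic_attenuation(spec))
  expect_false(is.na(cs2$Epp_MeV))
  expect_gt(cs2$Epp_MeV, cs2$Epe_MeV)
})
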
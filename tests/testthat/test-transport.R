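# Closed-form transport operations: Peclet numbers, partitioning, sieving,
# rejection equations and layer fluxes.

test_that("Peclet numbers are flux/coefficient ratios with guarded domains", {
  expect_equal(peclet_membrane(7.34e-6, 7.34e-6), 1)
  expect_equal(peclet_membrane(0, 1e-6), 0)
  expect_equal(peclet_membrane(2e-5, 2e-6), 10) # advection-dominated regime
  expect_equal(peclet_polarization(7.34e-6, 7.34e-6), 1)
  expect_equal(peclet_polarization(0, 7.34e-6), 0)
  expect_equal(peclet_polarization(1.468e-5, 7.34e-6), 2)
  expect_error(peclet_membrane(1e-6, 0), "positive")
  expect_error(peclet_polarization(1e-6, -1e-6), "positive")
  expect_error(peclet_membrane(-1e-6, 1e-6), "non-negative")
})

test_that("sieving coefficient combines hindrance and partitioning", {
  expect_equal(sieving_coefficient(1, 0), 1)
  expect_equal(sieving_coefficient(1, 1), 0)
  # partitioning from the Ferry worked example implies sigma ~ 0.8491
  phi <- ferry_partition(3.48e-9, 5.69e-9)
  expect_equal(sieving_coefficient(1, phi), 0.8491, tolerance = 1e-4)
  expect_warning(out <- sieving_coefficient(1.5, 0.9), "negative")
  expect_equal(out, 1 - 1.35)
  expect_error(sieving_coefficient(-1, 0.5), "non-negative")
})

test_that("Ferry partitioning handles the full radius range", {
  expect_equal(ferry_partition(3.48e-9, 5.69e-9), 0.1509, tolerance = 1e-3)
  expect_equal(ferry_partition(0, 1e-9), 1)
  expect_equal(ferry_partition(1e-9, 1e-9), 0)
  # an oversized solute cannot enter; the squared form must not recover
  expect_equal(ferry_partition(3e-9, 1e-9), 0)
  expect_error(ferry_partition(-1e-9, 1e-9), "non-negative")
  expect_error(ferry_partition(1e-9, 0), "positive")
})

test_that("interaction-energy partitioning reduces to Ferry at E_T = 0", {
  set.seed(1)
  for (i in 1:20) {
    r_s <- runif(1, 0, 6e-9); r_p <- runif(1, 1e-9, 8e-9)
    expect_identical(smith_deen_partition(r_s, r_p, E_T = 0),
                     ferry_partition(r_s, r_p))
  }
  kT <- 1.380649e-23 * 298.15
  expect_equal(smith_deen_partition(3.48e-9, 5.69e-9, E_T = kT, kT = kT),
               ferry_partition(3.48e-9, 5.69e-9) * exp(-1))
  expect_equal(smith_deen_partition(3.48e-9, 5.69e-9, E_T = Inf), 0)
  expect_error(smith_deen_partition(1e-9, 2e-9, kT = 0), "positive")
})

test_that("observed rejection follows the concentration ratio", {
  expect_equal(observed_rejection(1, 0), 1)
  expect_equal(observed_rejection(1, 1), 0)
  expect_equal(observed_rejection(5, 1.75), 0.65)
  expect_error(observed_rejection(0, 1), "positive")
  expect_warning(out <- observed_rejection(1, 1.2), "negative rejection")
  expect_equal(out, -0.2, tolerance = 1e-12)
})

test_that("rejection equations hit their frozen reference values", {
  # frozen from the numerical boundary-value oracle (and plain arithmetic)
  expect_equal(rejection_general(0.9, 2, 1), 0.4350072, tolerance = 1e-6)
  expect_equal(rejection_advection(0.9, 2), 0.5491469, tolerance = 1e-6)
})

test_that("rejection equations honor their analytic corners", {
  for (s in c(0, 0.3, 0.85, 1)) {
    # infinitely diffusive membrane passes everything
    expect_equal(rejection_general(s, 1.3, 0), 0)
    # vanishing flux: observed rejection equals the sieving coefficient
    expect_equal(rejection_advection(s, 0), s)
    expect_equal(rejection_general(s, 0, Inf), s)
  }
  expect_equal(rejection_general(1, 2, 0.5), 1)
  expect_equal(rejection_advection(1, 5), 1)
  expect_equal(rejection_advection(0, 3), 0)
  # vanishing rejection at extreme polarization, stable past exp underflow
  expect_equal(rejection_advection(0.97, 800), 0)
  expect_equal(rejection_general(0.97, 800, 800), 0)
  expect_error(rejection_advection(1.2, 1, strict = TRUE), "sigma")
  expect_warning(rejection_advection(1.2, 1), "sigma")
})

test_that("general equation collapses onto the advection equation as Pe_m grows", {
  sig <- seq(0, 1, by = 0.1)
  ped <- seq(0, 10, by = 1)
  grid <- expand.grid(s = sig, p = ped)
  adv <- rejection_advection(grid$s, grid$p)
  gaps <- sapply(c(2, 5, 10, 20), function(pm)
    max(abs(rejection_general(grid$s, grid$p, pm) - adv)))
  expect_true(all(diff(gaps) <= 0)) # monotone collapse
  expect_lt(gaps[[4]], 1e-8)        # numerically indistinguishable at 20
})

test_that("rejection is monotone in polarization and sieving", {
  ped <- seq(0, 8, length.out = 40)
  for (s in c(0.2, 0.6, 0.95)) {
    expect_true(all(diff(rejection_advection(s, ped)) < 0))
  }
  sig <- seq(0.01, 0.99, length.out = 40)
  for (p in c(0.5, 2, 6)) {
    expect_true(all(diff(rejection_advection(sig, p)) > 0))
  }
})

test_that("layer flux expressions collapse and flag their singular limits", {
  expect_equal(solute_flux_membrane(0, 0, 1e-5, 1, 0.2, 2), 0)
  # pure advection of the internal concentration at large Pe_m
  expect_equal(solute_flux_membrane(3, 3, 1e-5, 1, 0.2, 1e4), 1 * 0.2 * 1e-5 * 3)
  expect_warning(out <- solute_flux_membrane(2, 2, 1e-5, 1, 0.2, 0), "pe_m = 0")
  expect_equal(out, 1 * 0.2 * 1e-5 * 2)
  expect_warning(out <- solute_flux_membrane(2, 1, 1e-5, 1, 0.2, 0), "pe_m = 0")
  expect_identical(out, Inf)

  # equal concentrations make the polarization ratio collapse for any Pe_d
  for (p in c(0.3, 1, 6)) {
    expect_equal(solute_flux_polarization(1.7, 1.7, 1e-5, p), 1e-5 * 1.7)
  }
  expect_equal(solute_flux_polarization(0, 0, 1e-5, 1), 0)
  expect_warning(out <- solute_flux_polarization(1, 2, 1e-5, 0), "pe_d = 0")
  expect_identical(out, -Inf)
  expect_error(solute_flux_polarization(1, 2, 1e-5, -1), "non-negative")
})
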
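# Least-squares estimation, confidence intervals and nested-model comparison.

test_that("residual_ss is zero at the generating parameters and permutation-invariant", {
  v <- ref_fluxes(8)
  d <- make_advection_dataset(0.9, 7.34e-6, v)
  tp <- transport_parameters(0.9, 7.34e-6)
  expect_equal(residual_ss(tp, d, "advection"), 0)
  expect_equal(residual_ss(transport_parameters(0, 1e-6),
                           make_dataset(v, rep(0, 8)), "advection"), 0)
  set.seed(3)
  d2 <- make_dataset(v, rejection_advection(0.9, v / 7.34e-6) + rnorm(8, 0, 0.05))
  tp2 <- transport_parameters(0.8, 5e-6)
  perm <- sample(8)
  expect_equal(residual_ss(tp2, d2, "advection"),
               residual_ss(tp2, rejection_data(as.data.frame(d2)[perm, ]),
                           "advection"))
  expect_error(residual_ss(tp2, d2, "general"), "k_m")
})

test_that("noise-free data regenerate their parameters (advection model)", {
  d <- make_advection_dataset(0.97, 7.34e-6, ref_fluxes(5))
  f <- fit_condition(d, "advection")
  expect_true(f$converged)
  expect_equal(f$estimate[["sigma"]], 0.97, tolerance = 1e-6)
  expect_equal(f$estimate[["k_dbl"]], 7.34e-6, tolerance = 1e-6)
  expect_lt(f$ss_res, 1e-12)
  expect_equal(f$df, 3)
  expect_equal(f$adj_r2, 1, tolerance = 1e-6)
})

test_that("noise-free data regenerate their parameters (general model)", {
  v <- ref_fluxes(8)
  r <- rejection_general(0.95, v / 7.34e-6, v / 2e-5)
  f <- fit_condition(make_dataset(v, r), "general")
  expect_equal(f$estimate[["sigma"]], 0.95, tolerance = 1e-5)
  expect_equal(f$estimate[["k_dbl"]], 7.34e-6, tolerance = 1e-4)
  expect_equal(f$estimate[["k_m"]], 2e-5, tolerance = 1e-4)
  expect_lt(f$ss_res, 1e-12)
})

test_that("flat rejection data pin sigma at its vanishing-flux limit", {
  v <- ref_fluxes(6)
  # huge k_dbl puts Pe_d ~ 0 everywhere, so R_obs = sigma identically
  f <- fit_fixed_kdbl(make_dataset(v, rep(0.88, 6)), k_dbl = 1e3)
  expect_equal(f$estimate[["sigma"]], 0.88, tolerance = 1e-8)
  f1 <- fit_fixed_kdbl(make_dataset(v, rep(1, 6)), k_dbl = 7.34e-6)
  expect_equal(f1$estimate[["sigma"]], 1, tolerance = 1e-8)
})

test_that("freezing k_dbl low biases sigma upward, matching a grid-search oracle", {
  v <- ref_fluxes(10)
  d <- make_advection_dataset(0.95, 7.34e-6, v)
  f_true <- fit_fixed_kdbl(d, 7.34e-6)
  expect_equal(f_true$estimate[["sigma"]], 0.95, tolerance = 1e-8)
  f_half <- fit_fixed_kdbl(d, 7.34e-6 / 2)
  expect_gt(f_half$estimate[["sigma"]], 0.95)
  # independent dense-grid oracle over sigma at the frozen k_dbl
  grid <- seq(0.9, 1.1, by = 1e-4)
  ss <- suppressWarnings(vapply(grid, function(s)
    sum((d$r_obs - rejection_advection(s, v / (7.34e-6 / 2)))^2), numeric(1)))
  expect_gt(grid[which.min(ss)], 0.95)
  expect_equal(f_half$estimate[["sigma"]], grid[which.min(ss)],
               tolerance = 2e-4)
})

test_that("shared-k_dbl fitting recovers a common coefficient exactly", {
  design <- default_design()
  truth <- default_ground_truth(noise_sd_conc = 0)
  sim <- simulate_dataset(design, truth)
  sf <- fit_shared_kdbl(sim)
  expect_true(sf$converged)
  expect_equal(unname(sf$sigma), truth$sigma, tolerance = 1e-6)
  expect_equal(sf$k_dbl, truth$k_dbl, tolerance = 1e-6)
  expect_lt(sf$ss_res, 1e-12)
})

test_that("shared-k_dbl fit on a single condition equals fit_condition", {
  set.seed(5)
  v <- ref_fluxes(10)
  d <- make_dataset(v, rejection_advection(0.96, v / 7.34e-6) +
                      rnorm(10, 0, 0.01))
  fc <- fit_condition(d, "advection")
  sf <- fit_shared_kdbl(d)
  expect_equal(unname(sf$sigma), fc$estimate[["sigma"]], tolerance = 1e-8)
  expect_equal(sf$k_dbl, fc$estimate[["k_dbl"]], tolerance = 1e-8)
  expect_equal(sf$ss_res, fc$ss_res, tolerance = 1e-10)
})

test_that("conditions generated with different k_dbl leave detectable misfit", {
  v <- ref_fluxes(10)
  d1 <- make_advection_dataset(0.95, 5e-6, v, id = "a")
  d2 <- make_advection_dataset(0.98, 1.2e-5, v, id = "b")
  sf <- fit_shared_kdbl(list(d1, d2))
  expect_gt(sf$ss_res, 1e-6)
  # grid-search oracle: no shared k_dbl can fit both noise-free curves
  kgrid <- exp(seq(log(1e-6), log(5e-5), length.out = 60))
  sgrid <- seq(0.85, 1.05, by = 1e-3)
  best <- min(vapply(kgrid, function(k) {
    ss <- 0
    for (d in list(d1, d2)) {
      pred <- suppressWarnings(
        vapply(sgrid, function(s)
          sum((d$r_obs - rejection_advection(s, d$flux_m_per_s / k))^2),
          numeric(1)))
      ss <- ss + min(pred)
    }
    ss
  }, numeric(1)))
  expect_gt(best, 1e-6)
  expect_lte(sf$ss_res, best * 1.001) # optimizer at least matches the grid
})

test_that("F statistic and p value follow the printed formula", {
  mk <- function(ss, df, n) structure(list(ss_res = ss, df = df, n_obs = n),
                                      class = "uf_fit")
  ft <- f_test(mk(10, 5, 7), mk(8, 4, 7))
  expect_equal(ft$F, 1)
  expect_equal(ft$p, stats::pf(1, 1, 4, lower.tail = FALSE))
  # equal sums of squares: no improvement, p = 1
  ft0 <- f_test(mk(3, 5, 7), mk(3, 4, 7))
  expect_equal(ft0$F, 0); expect_equal(ft0$p, 1)
  # negative F reported as computed, p clamped to 1
  ftn <- f_test(mk(2.9, 5, 7), mk(3, 4, 7))
  expect_lt(ftn$F, 0); expect_equal(ftn$p, 1)
  fti <- f_test(mk(1, 5, 7), mk(0, 4, 7))
  expect_identical(fti$F, Inf); expect_equal(fti$p, 0)
  expect_error(f_test(mk(1, 4, 7), mk(2, 5, 7)), "degrees of freedom")
  expect_error(f_test(mk(1, 5, 7), mk(0.5, 4, 9)), "same dataset")
})

test_that("adjusted r2 is 1 for perfect fits, 0 for the mean, negative for worse", {
  d <- make_advection_dataset(0.95, 7.34e-6, ref_fluxes(8))
  f <- fit_condition(d, "advection")
  expect_equal(adjusted_r2(f, d), 1, tolerance = 1e-9)
  # definitional anchor: a 1-parameter model reproducing the mean scores 0
  r <- c(0.9, 0.95, 0.85, 0.92)
  ss_mean <- sum((r - mean(r))^2)
  expect_equal(ufreject:::.adj_r2(ss_mean, r, 1L), 0)
  # a fit worse than the mean goes negative
  f_bad <- fit_fixed_kdbl(d, 1e-7)
  expect_lt(adjusted_r2(f_bad, d), 0)
  expect_warning(adjusted_r2(f, make_dataset(ref_fluxes(4), rep(0.9, 4))),
                 "zero total variance")
})

test_that("interior-truth nested F test calibrates at the nominal level", {
  # null: advection model with (sigma, k_dbl) truth; small model freezes
  # k_dbl at its true value (interior point), large model fits it
  set.seed(202)
  v <- ref_fluxes(10)
  rtrue <- rejection_advection(0.97, v / 7.34e-6)
  n_rej <- 0
  n_mc <- 1000
  for (i in seq_len(n_mc)) {
    d <- make_dataset(v, rtrue + rnorm(10, 0, 0.01))
    ft <- f_test(fit_fixed_kdbl(d, 7.34e-6), fit_condition(d, "advection"))
    if (ft$p <= 0.05) n_rej <- n_rej + 1
  }
  expect_gte(n_rej / n_mc, 0.03)
  expect_lte(n_rej / n_mc, 0.07)
})

test_that("fits validate their inputs", {
  v <- ref_fluxes(3)
  d <- make_advection_dataset(0.9, 7e-6, v)
  expect_error(fit_condition(d, "general"), "observations")
  two <- rbind(as.data.frame(d),
               as.data.frame(make_advection_dataset(0.9, 7e-6, v, id = "c2")))
  expect_error(fit_condition(rejection_data(two)), "single condition")
  expect_error(fit_fixed_kdbl(d, -1), "positive")
  expect_error(fit_shared_kdbl(make_advection_dataset(0.9, 7e-6, ref_fluxes(2))),
               "observations")
})

test_that("fit results print their estimates and diagnostics", {
  d <- make_advection_dataset(0.95, 7.34e-6, ref_fluxes(6))
  expect_output(print(fit_condition(d)), "sigma")
  expect_output(print(fit_shared_kdbl(d)), "k_dbl")
  mk <- function(ss, df, n) structure(list(ss_res = ss, df = df, n_obs = n),
                                      class = "uf_fit")
  expect_output(print(f_test(mk(10, 5, 7), mk(8, 4, 7))), "F test")
})
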
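fast_cfg <- inversion_config(seed = 7)

test_that("residual vector is the windowed model-minus-measurement stack", {
  obs <- forward_model(test_truth, test_lib)
  res <- spectral_residuals(test_truth, obs, test_lib, fast_cfg)
  expect_equal(length(res), 2 * nrow(obs))
  expect_equal(max(abs(res)), 0)
  shifted <- obs
  shifted$reflectance <- shifted$reflectance + 0.01
  res2 <- spectral_residuals(test_truth, shifted, test_lib, fast_cfg)
  half <- length(res2) / 2
  expect_equal(res2[seq_len(half)], rep(-0.01, half))
  expect_equal(res2[-seq_len(half)], rep(0, half))
})

test_that("noiseless spectra are inverted back to their generating leaf", {
  set.seed(71)
  n_truths <- 25
  worst_rel <- 0
  worst_cx <- 0
  for (i in seq_len(n_truths)) {
    truth <- random_truth(c(4.5, 6.3))
    obs <- forward_model(truth, test_lib)
    fit <- invert_spectrum(obs, test_lib, fast_cfg)
    est <- fit$estimate
    rel <- vapply(c("Cab", "Ccar", "Canth"), function(nm) {
      abs(est[[nm]] - truth[[nm]]) / max(truth[[nm]], 1e-9)
    }, numeric(1))
    worst_rel <- max(worst_rel, rel)
    worst_cx <- max(worst_cx, abs(est$Cx - truth$Cx))
    expect_true(fit$converged)
  }
  expect_lt(worst_rel, 0.01)
  expect_lt(worst_cx, 0.02)
})

test_that("the ratio constraint binds when the true ratio is outside the band", {
  truth <- leaf_biophysics(N = 1.6, Cab = 48, Ccar = 6, Canth = 1, Cx = 0.2)
  expect_equal(truth$Cab / truth$Ccar, 8)
  obs <- forward_model(truth, test_lib)
  fit <- invert_spectrum(obs, test_lib, fast_cfg)
  expect_equal(fit$chl_car_ratio, 6.4, tolerance = 1e-8)
  expect_true(fit$active_constraints[["ratio_upper"]])
  # grid-search oracle over the (Cab, ratio) feasible plane with the other
  # parameters fixed at truth: the best feasible residual sits on the
  # upper ratio boundary and is no better than the optimiser's solution
  grid <- tidyr::expand_grid(Cab = seq(40, 56, by = 0.5),
                             rho = seq(4.4, 6.4, by = 0.1))
  ssr <- purrr::pmap_dbl(grid, function(Cab, rho) {
    p <- leaf_biophysics(N = 1.6, Cab = Cab, Ccar = Cab / rho, Canth = 1,
                         Cx = 0.2)
    sum(spectral_residuals(p, obs, test_lib, fast_cfg)^2)
  })
  expect_equal(grid$rho[which.min(ssr)], 6.4)
  expect_lte(fit$residual_norm, min(ssr))
})

test_that("the returned optimum beats every multistart initial point", {
  obs <- forward_model(test_truth, test_lib)
  fit <- invert_spectrum(obs, test_lib, fast_cfg)
  expect_true(all(fit$residual_norm <= fit$start_residuals))
})

test_that("inversion is deterministic given inputs and seed", {
  obs <- forward_model(test_truth, test_lib)
  f1 <- invert_spectrum(obs, test_lib, fast_cfg)
  f2 <- invert_spectrum(obs, test_lib, fast_cfg)
  expect_identical(unclass(f1$estimate), unclass(f2$estimate))
  expect_identical(f1$residual_norm, f2$residual_norm)
  expect_identical(f1$start_index, f2$start_index)
})

test_that("estimates under measurement noise stay close to the truth", {
  set.seed(72)
  n_rep <- 50
  rel_err <- numeric(n_rep)
  obs0 <- forward_model(test_truth, test_lib)
  for (i in seq_len(n_rep)) {
    noisy <- obs0
    nw <- nrow(noisy)
    noisy$reflectance <- pmin(noisy$reflectance * (1 + rnorm(nw, 0, 0.01)), 1)
    noisy$transmittance <- pmin(noisy$transmittance * (1 + rnorm(nw, 0, 0.01)), 1)
    over <- noisy$reflectance + noisy$transmittance > 1
    if (any(over)) {
      sc <- 1 / (noisy$reflectance[over] + noisy$transmittance[over])
      noisy$reflectance[over] <- noisy$reflectance[over] * sc
      noisy$transmittance[over] <- noisy$transmittance[over] * sc
    }
    fit <- invert_spectrum(noisy, test_lib, fast_cfg)
    rel_err[i] <- abs(fit$estimate$Cab - test_truth$Cab) / test_truth$Cab
  }
  expect_lt(median(rel_err), 0.05)
})

test_that("degenerate and incomplete inputs are refused", {
  zero <- tibble::tibble(wavelength_nm = 400:900, reflectance = 0,
                         transmittance = 0)
  expect_error(invert_spectrum(zero, test_lib, fast_cfg), "Degenerate")
  narrow <- forward_model(test_truth, test_lib)
  narrow <- narrow[narrow$wavelength_nm <= 600, ]
  expect_error(invert_spectrum(narrow, test_lib, fast_cfg), "fit window")
})

test_that("batch inversion preserves order and tolerates failing records", {
  set.seed(73)
  specs <- purrr::map_dfr(c("a", "b", "c"), function(id) {
    dplyr::mutate(forward_model(random_truth(), test_lib), sample_id = id)
  })
  out <- invert_batch(specs, test_lib, fast_cfg)
  expect_equal(out$sample_id, c("a", "b", "c"))
  expect_true(all(out$converged))
  # batch row equals the single-spectrum fit
  single <- invert_spectrum(specs[specs$sample_id == "b", ], test_lib, fast_cfg)
  expect_equal(out$Cab[out$sample_id == "b"], single$estimate$Cab)
  # a degenerate record is flagged, not fatal
  degen <- tibble::tibble(wavelength_nm = 400:900, reflectance = 0,
                          transmittance = 0, sample_id = "dead")
  out2 <- invert_batch(dplyr::bind_rows(specs, degen), test_lib, fast_cfg)
  expect_equal(nrow(out2), 4)
  expect_false(out2$converged[out2$sample_id == "dead"])
  expect_equal(sum(out2$converged), 3)
  expect_error(invert_batch(specs[0, ], test_lib, fast_cfg), "mpty")
})

test_that("tidy, glance and augment expose the fit in broom form", {
  obs <- forward_model(test_truth, test_lib)
  fit <- invert_spectrum(obs, test_lib, fast_cfg)
  td <- tidy(fit)
  expect_equal(td$term, c("N", "Cab", "Ccar", "Canth", "Cx", "Cbrown",
                          "Cw", "Cm"))
  expect_true(all(td$estimate >= td$lower - 1e-9, na.rm = TRUE))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_true(gl$converged)
  expect_gte(gl$chl_car_ratio, 4.4)
  expect_lte(gl$chl_car_ratio, 6.4)
  aug <- augment(fit)
  expect_equal(aug$.resid_reflectance,
               aug$reflectance - aug$.fitted_reflectance)
})

test_that("the soft-penalty ratio method also returns feasible estimates", {
  truth <- leaf_biophysics(N = 1.6, Cab = 48, Ccar = 6, Canth = 1, Cx = 0.2)
  obs <- forward_model(truth, test_lib)
  cfg <- inversion_config(seed = 7, ratio_method = "penalty",
                          penalty_weight = 50)
  fit <- invert_spectrum(obs, test_lib, cfg)
  expect_gte(fit$chl_car_ratio, 4.4)
  expect_lte(fit$chl_car_ratio, 6.4)
})
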
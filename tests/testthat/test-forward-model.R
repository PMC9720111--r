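test_that("plate transmissivity matches the hemispheric quadrature oracle", {
  expect_equal(plate_transmissivity(0), 1)
  ks <- c(0.01, 0.05, 0.1, 0.3, 0.5, 1, 2, 3, 5, 10)
  expect_lt(max(abs(plate_transmissivity(ks) - theta_quadrature(ks))), 1e-8)
  # asymptote and strict monotonicity
  expect_lt(plate_transmissivity(50), 1e-10)
  th <- plate_transmissivity(seq(0, 8, by = 0.05))
  expect_true(all(diff(th) < 0))
  expect_error(plate_transmissivity(-0.1), "non-negative")
})

test_that("exponential integral agrees with direct quadrature", {
  e1_quad <- function(k) {
    stats::integrate(function(t) exp(-t) / t, k, Inf, rel.tol = 1e-12)$value
  }
  expect_equal(leafpigments:::expint_e1(1), e1_quad(1), tolerance = 1e-12)
  expect_equal(leafpigments:::expint_e1(1), 0.21938, tolerance = 1e-4)
  for (k in c(0.001, 0.7, 1.999, 2.001, 25)) {
    expect_equal(leafpigments:::expint_e1(k), e1_quad(k), tolerance = 1e-12)
  }
})

test_that("average Fresnel transmissivity matches angular integration", {
  expect_equal(fresnel_tav(40, 1), 1)
  expect_equal(fresnel_tav(72.3, 1), 1)
  for (case in list(c(90, 1.5), c(40, 1.4), c(40, 1.3), c(40, 1.6))) {
    got <- fresnel_tav(case[1], case[2])
    expect_gt(got, 0)
    expect_lt(got, 1)
    expect_equal(got, tav_quadrature(case[1], case[2]), tolerance = 1e-9)
  }
  # decreasing in refractive index
  expect_gt(fresnel_tav(40, 1.3), fresnel_tav(40, 1.6))
  expect_error(fresnel_tav(0, 1.4), "alpha")
  expect_error(fresnel_tav(40, 0.9), ">= 1")
})

test_that("carotenoid absorption mixes the two end-members convexly", {
  k0 <- carotenoid_absorption(test_lib, Ccar = 8, Cx = 0)
  k1 <- carotenoid_absorption(test_lib, Ccar = 8, Cx = 1)
  kh <- carotenoid_absorption(test_lib, Ccar = 8, Cx = 0.5)
  expect_equal(k0$absorption, 8 * test_lib$K_car_V)
  expect_equal(k1$absorption, 8 * test_lib$K_car_Z)
  expect_equal(kh$absorption, (k0$absorption + k1$absorption) / 2)
  expect_error(carotenoid_absorption(test_lib, 8, 1.2), "Cx")
})

test_that("total absorption is a linear constituent sum scaled by 1/N", {
  zero <- leaf_biophysics(N = 2, Cab = 0, Ccar = 0, Canth = 0, Cx = 0,
                          Cw = 0, Cm = 0)
  expect_true(all(total_absorption(zero, test_lib)$absorption == 0))
  p1 <- leaf_biophysics(N = 2, Cab = 30, Ccar = 6, Canth = 1, Cx = 0.4,
                        Cbrown = 0.1, Cw = 0.01, Cm = 0.004)
  p2 <- leaf_biophysics(N = 2, Cab = 60, Ccar = 12, Canth = 2, Cx = 0.4,
                        Cbrown = 0.2, Cw = 0.02, Cm = 0.008)
  expect_equal(total_absorption(p2, test_lib)$absorption,
               2 * total_absorption(p1, test_lib)$absorption)
  only_chl <- leaf_biophysics(N = 1.7, Cab = 25, Ccar = 0, Canth = 0,
                              Cx = 0, Cw = 0, Cm = 0)
  expect_equal(total_absorption(only_chl, test_lib)$absorption,
               25 * test_lib$K_ab / 1.7)
})

test_that("transparent slab with unit refractive index transmits everything", {
  lib1 <- test_lib
  lib1$n_refr <- rep(1, nrow(lib1))
  zero <- leaf_biophysics(N = 1.8, Cab = 0, Ccar = 0, Canth = 0, Cx = 0,
                          Cw = 0, Cm = 0)
  spec <- forward_model(zero, lib1)
  expect_equal(spec$reflectance, rep(0, nrow(lib1)))
  expect_equal(spec$transmittance, rep(1, nrow(lib1)))
})

test_that("zero absorber with a real interface conserves energy exactly", {
  zero <- leaf_biophysics(N = 2.2, Cab = 0, Ccar = 0, Canth = 0, Cx = 0,
                          Cw = 0, Cm = 0)
  spec <- forward_model(zero, test_lib)
  expect_lt(max(abs(1 - spec$reflectance - spec$transmittance)), 1e-9)
})

test_that("energy is conserved for random valid parameter draws", {
  set.seed(402)
  for (i in 1:200) {
    spec <- forward_model(random_truth(c(3, 9)), test_lib)
    expect_true(all(spec$reflectance >= 0))
    expect_true(all(spec$transmittance >= 0))
    expect_true(all(spec$reflectance + spec$transmittance <= 1 + 1e-12))
  }
})

test_that("single-plate output matches an independent one-plate implementation", {
  p <- leaf_biophysics(N = 1, Cab = 35, Ccar = 7, Canth = 1.5, Cx = 0.25,
                       Cbrown = 0.05, Cw = 0.01, Cm = 0.004)
  spec <- forward_model(p, test_lib)
  # direct evaluation of the one-plate interface algebra, written out
  # independently of the package internals
  k <- (35 * test_lib$K_ab +
          7 * (0.75 * test_lib$K_car_V + 0.25 * test_lib$K_car_Z) +
          1.5 * test_lib$K_anth + 0.05 * test_lib$K_brown +
          0.01 * test_lib$K_w + 0.004 * test_lib$K_m) / 1
  theta <- theta_quadrature(k)
  n <- test_lib$n_refr
  talf <- vapply(n, function(nn) tav_quadrature(40, nn), numeric(1))
  t12 <- vapply(n, function(nn) tav_quadrature(90, nn), numeric(1))
  t21 <- t12 / n^2
  r21 <- 1 - t21
  Ta <- talf * theta * t21 / (1 - r21^2 * theta^2)
  Ra <- (1 - talf) + r21 * theta * Ta
  expect_equal(spec$transmittance, Ta, tolerance = 1e-7)
  expect_equal(spec$reflectance, Ra, tolerance = 1e-7)
})

test_that("spectra vary monotonically and continuously with the parameters", {
  lib <- test_lib
  peak <- lib$wavelength_nm[which.max(lib$K_ab)]
  t_at_peak <- vapply(c(10, 20, 40, 60, 90), function(cab) {
    p <- leaf_biophysics(N = 1.6, Cab = cab, Ccar = cab / 5.4, Canth = 0,
                         Cx = 0.2)
    spec <- forward_model(p, lib)
    spec$transmittance[spec$wavelength_nm == peak]
  }, numeric(1))
  expect_true(all(diff(t_at_peak) < 0))

  nir <- lib$wavelength_nm > 780
  r_nir <- vapply(c(1, 1.5, 2, 2.5, 3), function(nn) {
    p <- leaf_biophysics(N = nn, Cab = 40, Ccar = 8, Canth = 0, Cx = 0.2)
    mean(forward_model(p, lib)$reflectance[nir])
  }, numeric(1))
  expect_true(all(diff(r_nir) > 0))

  p1 <- leaf_biophysics(N = 1.999, Cab = 40, Ccar = 8, Canth = 1, Cx = 0.3)
  p2 <- leaf_biophysics(N = 2.001, Cab = 40, Ccar = 8, Canth = 1, Cx = 0.3)
  s1 <- forward_model(p1, lib)
  s2 <- forward_model(p2, lib)
  expect_lt(max(abs(s1$reflectance - s2$reflectance)), 1e-3)
  expect_lt(max(abs(s1$transmittance - s2$transmittance)), 1e-3)
})
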
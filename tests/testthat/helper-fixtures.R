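# Shared fixtures, built once per test run.

test_lib <- build_synthetic_library(seed = 1)

# A mid-range leaf used across forward-model and inversion tests.
test_truth <- leaf_biophysics(
  N = 1.6, Cab = 45, Ccar = 45 / 5.2, Canth = 2, Cx = 0.3,
  Cbrown = 0.05, Cw = 0.012, Cm = 0.0045
)

# Draw a random valid leaf with the chl/car ratio inside (or spanning)
# the admissible band, using the current RNG stream.
random_truth <- function(ratio_range = c(4.5, 6.3)) {
  Cab <- runif(1, 20, 80)
  leaf_biophysics(
    N = runif(1, 1.2, 2.5), Cab = Cab,
    Ccar = Cab / runif(1, ratio_range[1], ratio_range[2]),
    Canth = runif(1, 0, 8), Cx = runif(1, 0, 0.8),
    Cbrown = runif(1, 0, 0.3), Cw = runif(1, 0.005, 0.02),
    Cm = runif(1, 0.002, 0.008)
  )
}

# Independent quadrature oracle for the elementary-plate transmissivity:
# exponential attenuation exp(-k/mu) averaged over an isotropic
# (cosine-weighted) hemisphere, theta(k) = 2 * int_0^1 mu exp(-k/mu) dmu.
theta_quadrature <- function(k) {
  vapply(k, function(kk) {
    2 * stats::integrate(function(mu) mu * exp(-kk / mu), 0, 1,
                         rel.tol = 1e-12)$value
  }, numeric(1))
}

# Independent oracle for the average Fresnel transmissivity: unpolarised
# interface transmissivity integrated over the incidence cone with
# sin(t)cos(t) weighting.
tav_quadrature <- function(alpha_deg, n) {
  fresnel_t <- function(theta_i) {
    sin_t <- sin(theta_i) / n
    cos_i <- cos(theta_i)
    cos_t <- sqrt(pmax(1 - sin_t^2, 0))
    rs <- ((cos_i - n * cos_t) / (cos_i + n * cos_t))^2
    rp <- ((cos_t - n * cos_i) / (cos_t + n * cos_i))^2
    1 - (rs + rp) / 2
  }
  a <- alpha_deg * pi / 180
  num <- stats::integrate(function(t) fresnel_t(t) * sin(t) * cos(t), 0, a,
                          rel.tol = 1e-10)$value
  den <- stats::integrate(function(t) sin(t) * cos(t), 0, a,
                          rel.tol = 1e-10)$value
  num / den
}
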
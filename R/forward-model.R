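# Generalized-plate leaf optical forward model.
#
# The leaf is represented as N identical absorbing plates with rough
# air-cell interfaces. A single elementary plate combines the Fresnel
# transmissivities of its two interfaces with the internal beam
# transmissivity theta(k); the stack of N (possibly non-integer) plates is
# solved analytically with the Stokes recurrences.

# Vectorised exponential integral E1(x) for x > 0.
# Power series for x <= 1, modified-Lentz continued fraction for x > 1;
# both branches reach double precision, avoiding the cancellation that a
# naive evaluation of theta(k) would suffer near k ~ 0.
expint_e1 <- function(x) {
  if (any(x < 0)) stop("expint_e1() requires x >= 0.", call. = FALSE)
  out <- rep(Inf, length(x))   # E1(0+) diverges
  small <- x > 0 & x <= 2
  if (any(small)) {
    xs <- x[small]
    s <- -0.5772156649015328606 - log(xs)
    term <- rep(1, length(xs))
    for (n in 1:50) {
      term <- term * (-xs) / n
      s <- s - term / n
      if (max(abs(term)) / n < 1e-17) break
    }
    out[small] <- s
  }
  large <- x > 2
  if (any(large)) {
    xl <- x[large]
    b <- xl + 1
    c0 <- 1 / 1e-300
    d <- 1 / b
    h <- d
    for (i in 1:40) {
      a <- -i * i
      b <- b + 2
      d <- 1 / (a * d + b)
      c0 <- b + a / c0
      del <- c0 * d
      h <- h * del
      if (max(abs(del - 1)) < 1e-15) break
    }
    out[large] <- h * exp(-xl)
  }
  out
}

#' Elementary-plate beam transmissivity
#'
#' Fraction of radiation entering an elementary plate that reaches the
#' opposite face, integrated over all internal propagation directions:
#' `theta(k) = (1 - k) exp(-k) + k^2 E1(k)` with `E1` the exponential
#' integral. `theta(0) = 1`, and `theta` decreases strictly to 0 as the
#' plate absorption `k` grows.
#'
#' @param k Non-negative per-plate absorption (dimensionless optical depth).
#' @return Numeric vector of transmissivities in (0, 1].
#' @examples
#' plate_transmissivity(c(0, 0.5, 1, 5))
#' @export
plate_transmissivity <- function(k) {
  if (any(!is.finite(k)) || any(k < 0)) {
    stop("`k` must be finite and non-negative.", call. = FALSE)
  }
  theta <- numeric(length(k))
  zero <- k == 0
  theta[zero] <- 1
  pos <- !zero
  if (any(pos)) {
    kp <- k[pos]
    theta[pos] <- (1 - kp) * exp(-kp) + kp^2 * expint_e1(kp)
  }
  # underflow guard: the expression is exact but may round to tiny negatives
  pmin(pmax(theta, 0), 1)
}

#' Average Fresnel transmissivity of a leaf interface
#'
#' Transmissivity of a dielectric interface of refractive index `n`,
#' averaged over an incidence cone of half-angle `alpha` degrees
#' (Stern's analytic solution as used throughout the plate-model
#' literature). `alpha = 90` gives the isotropic average used for the
#' internal interfaces; `alpha = 40` is the conventional cone for the
#' upper leaf surface.
#'
#' @param alpha Incidence cone half-angle in degrees, in (0, 90].
#' @param n Refractive index (vectorised), >= 1.
#' @return Numeric vector of average transmissivities in (0, 1].
#' @examples
#' fresnel_tav(40, 1.4)
#' fresnel_tav(90, c(1, 1.3, 1.5))
#' @export
fresnel_tav <- function(alpha, n) {
  if (length(alpha) != 1L || !is.finite(alpha) || alpha <= 0 || alpha > 90) {
    stop("`alpha` must be a single angle in (0, 90] degrees.", call. = FALSE)
  }
  if (any(n < 1)) stop("`n` must be >= 1.", call. = FALSE)
  out <- numeric(length(n))
  unity <- abs(n - 1) < 1e-12
  out[unity] <- 1
  if (all(unity)) return(out)
  nr <- n[!unity]
  rd <- pi / 180
  n2 <- nr^2
  np <- n2 + 1
  nm <- n2 - 1
  a <- (nr + 1)^2 / 2
  k <- -(n2 - 1)^2 / 4
  sa <- sin(alpha * rd)
  b1 <- if (alpha != 90) sqrt(pmax((sa^2 - np / 2)^2 + k, 0)) else 0
  b2 <- sa^2 - np / 2
  b <- b1 - b2
  b3 <- b^3
  a3 <- a^3
  ts <- (k^2 / (6 * b3) + k / b - b / 2) - (k^2 / (6 * a3) + k / a - a / 2)
  tp1 <- -2 * n2 * (b - a) / np^2
  tp2 <- -2 * n2 * np * log(b / a) / nm^2
  tp3 <- n2 * (1 / b - 1 / a) / 2
  tp4 <- 16 * n2^2 * (n2^2 + 1) * log((2 * np * b - nm^2) / (2 * np * a - nm^2)) /
    (np^3 * nm^2)
  tp5 <- 16 * n2^3 * (1 / (2 * np * b - nm^2) - 1 / (2 * np * a - nm^2)) / np^3
  tp <- tp1 + tp2 + tp3 + tp4 + tp5
  out[!unity] <- (ts + tp) / (2 * sa^2)
  out
}

#' Carotenoid absorption with the xanthophyll-cycle extension
#'
#' Total carotenoid specific absorption is modelled as a mixture of a
#' violaxanthin-dominated and a zeaxanthin-dominated end-member spectrum,
#' weighted by the de-epoxidation state `Cx = (Z+A)/(Z+A+V)`. The default
#' `"convex"` rule expresses that fraction directly,
#' `Ccar * ((1 - Cx) K_V + Cx K_Z)`; the `"difference"` rule instead adds a
#' fixed difference spectrum scaled by `Cx` at a reference carotenoid
#' content of 10 ug cm-2, mirroring the additive formulation used in
#' fluorescence-capable extensions of the plate model.
#'
#' @param lib An `absorption_library`.
#' @param Ccar Total carotenoid content (ug cm-2), >= 0.
#' @param Cx Zeaxanthin fraction in [0, 1].
#' @param method Mixing rule, `"convex"` (default) or `"difference"`.
#' @return A tibble with columns `wavelength_nm` and `absorption`.
#' @export
carotenoid_absorption <- function(lib, Ccar, Cx, method = c("convex", "difference")) {
  method <- match.arg(method)
  if (Ccar < 0) stop("`Ccar` must be >= 0.", call. = FALSE)
  if (Cx < 0 || Cx > 1) stop("`Cx` must lie in [0, 1].", call. = FALSE)
  k <- if (method == "convex") {
    Ccar * ((1 - Cx) * lib$K_car_V + Cx * lib$K_car_Z)
  } else {
    Ccar * lib$K_car_V + Cx * 10 * (lib$K_car_Z - lib$K_car_V)
  }
  tibble::tibble(wavelength_nm = lib$wavelength_nm, absorption = pmax(k, 0))
}

#' Total per-plate absorption spectrum
#'
#' Sums the constituent absorptions (contents times specific coefficients)
#' and divides by the structure parameter `N`, giving the optical depth of
#' one elementary plate at each wavelength.
#'
#' @param p A [leaf_biophysics()] parameter set.
#' @param lib An `absorption_library`.
#' @param cx_method Carotenoid mixing rule, see [carotenoid_absorption()].
#' @return A tibble with columns `wavelength_nm` and `absorption`.
#' @export
total_absorption <- function(p, lib, cx_method = "convex") {
  kcar <- carotenoid_absorption(lib, p$Ccar, p$Cx, method = cx_method)$absorption
  k <- (p$Cab * lib$K_ab + kcar + p$Canth * lib$K_anth +
          p$Cbrown * lib$K_brown + p$Cw * lib$K_w + p$Cm * lib$K_m) / p$N
  tibble::tibble(wavelength_nm = lib$wavelength_nm, absorption = k)
}

# Precompute the parameter-independent pieces of the forward model for a
# library: coefficient matrix and interface transmissivities. Re-used
# across the thousands of evaluations an inversion performs.
prepare_library <- function(lib, alpha = 40, cx_method = "convex") {
  n <- lib$n_refr
  talf <- fresnel_tav(alpha, n)
  t12 <- fresnel_tav(90, n)
  t21 <- t12 / n^2
  list(
    wl = lib$wavelength_nm,
    K = cbind(ab = lib$K_ab, carV = lib$K_car_V, carZ = lib$K_car_Z,
              anth = lib$K_anth, brown = lib$K_brown, w = lib$K_w, m = lib$K_m),
    cx_method = cx_method,
    talf = talf, ralf = 1 - talf,
    t12 = t12, r12 = 1 - t12,
    t21 = t21, r21 = 1 - t21
  )
}

# Fast core: leaf_biophysics (or plain list) + prepared library -> list(R, T).
forward_rt <- function(p, prep) {
  carw <- if (prep$cx_method == "convex") {
    c(p$Ccar * (1 - p$Cx), p$Ccar * p$Cx)
  } else {
    c(p$Ccar - 10 * p$Cx, 10 * p$Cx)
  }
  contents <- c(p$Cab, carw[1], carw[2], p$Canth, p$Cbrown, p$Cw, p$Cm)
  k <- pmax(drop(prep$K %*% contents), 0) / p$N
  theta <- plate_transmissivity(k)

  # single elementary plate with an alpha-cone upper interface
  r21 <- prep$r21
  denom1 <- 1 - r21^2 * theta^2
  Ta <- prep$talf * theta * prep$t21 / denom1
  Ra <- prep$ralf + r21 * theta * Ta
  t <- prep$t12 * theta * prep$t21 / denom1
  r <- prep$r12 + r21 * theta * t

  # Stokes stack of the remaining N - 1 plates (isotropic illumination)
  Nm1 <- p$N - 1
  Rsub <- numeric(length(r))
  Tsub <- numeric(length(r))
  conservative <- (r + t) >= 1 - 1e-9
  if (any(conservative)) {
    tc <- t[conservative]
    Tsub[conservative] <- tc / (tc + (1 - tc) * Nm1)
    Rsub[conservative] <- 1 - Tsub[conservative]
  }
  gen <- !conservative
  if (any(gen)) {
    rg <- r[gen]; tg <- t[gen]
    D <- sqrt(pmax((1 + rg + tg) * (1 + rg - tg) * (1 - rg + tg) * (1 - rg - tg), 0))
    a <- (1 + rg^2 - tg^2 + D) / (2 * rg)
    b <- (1 - rg^2 + tg^2 + D) / (2 * tg)
    bNm1 <- b^Nm1
    bN2 <- bNm1^2
    a2 <- a^2
    denom2 <- a2 * bN2 - 1
    Rsub[gen] <- a * (bN2 - 1) / denom2
    Tsub[gen] <- bNm1 * (a2 - 1) / denom2
  }
  denom3 <- 1 - Rsub * r
  Tleaf <- Ta * Tsub / denom3
  Rleaf <- Ra + Ta * Rsub * t / denom3
  if (any(!is.finite(Rleaf)) || any(!is.finite(Tleaf))) {
    stop("Non-finite reflectance/transmittance: pathological parameters ",
         "or absorption coefficients.", call. = FALSE)
  }
  list(reflectance = Rleaf, transmittance = Tleaf)
}

#' Simulate leaf reflectance and transmittance
#'
#' Runs the generalized-plate forward model: per-plate absorption from the
#' constituent contents, elementary-plate reflectance/transmittance from
#' the beam transmissivity and the Fresnel interface terms (40 degree cone
#' at the upper surface, isotropic internally), and the analytic Stokes
#' solution for a stack of `N` plates, with non-integer `N` handled
#' continuously.
#'
#' @param p A [leaf_biophysics()] parameter set.
#' @param lib An `absorption_library`.
#' @param alpha Incidence cone half-angle (degrees) for the upper surface.
#' @param cx_method Carotenoid mixing rule, see [carotenoid_absorption()].
#' @return A tibble with columns `wavelength_nm`, `reflectance`,
#'   `transmittance`; satisfies `0 <= R`, `0 <= T`, `R + T <= 1`.
#' @examples
#' lib <- build_synthetic_library()
#' spec <- forward_model(leaf_biophysics(Cab = 40, Ccar = 8), lib)
#' summary(spec$reflectance + spec$transmittance)
#' @export
forward_model <- function(p, lib, alpha = 40, cx_method = "convex") {
  stopifnot(inherits(p, "leaf_biophysics"))
  prep <- prepare_library(lib, alpha = alpha, cx_method = cx_method)
  rt <- forward_rt(p, prep)
  tibble::tibble(
    wavelength_nm = lib$wavelength_nm,
    reflectance = rt$reflectance,
    transmittance = rt$transmittance
  )
}
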
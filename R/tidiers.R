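# broom-style accessors for fitted inversion objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics augment
#' @export
generics::augment

#' Tidy a leaf spectral fit
#'
#' @param x A `leaf_fit` from [invert_spectrum()].
#' @param ... Unused.
#' @return One row per estimated parameter: `term`, `estimate`, `lower`,
#'   `upper`, `at_lower`, `at_upper`.
#' @export
tidy.leaf_fit <- function(x, ...) {
  if (is.null(x$estimate)) {
    return(tibble::tibble(term = character(), estimate = numeric(),
                          lower = numeric(), upper = numeric(),
                          at_lower = logical(), at_upper = logical()))
  }
  cfg <- x$config
  terms <- biophysics_names
  est <- unlist(unclass(x$estimate))[terms]
  bnd <- purrr::map(terms, function(nm) cfg$bounds[[nm]] %||% c(NA, NA))
  act <- x$active_constraints
  fit_nms <- fit_par_names(cfg)
  at <- function(nm, side) {
    key <- paste0(nm, "_", side)
    if (key %in% names(act)) unname(act[key]) else NA
  }
  tibble::tibble(
    term = terms,
    estimate = unname(est),
    lower = purrr::map_dbl(bnd, 1),
    upper = purrr::map_dbl(bnd, 2),
    at_lower = purrr::map_lgl(terms, at, side = "lower"),
    at_upper = purrr::map_lgl(terms, at, side = "upper")
  )
}

#' Glance at a leaf spectral fit
#'
#' @param x A `leaf_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `residual_norm`, `rmse`, `n_obs`,
#'   `n_iterations`, `converged`, `start_index`, `chl_car_ratio`,
#'   `ratio_active`, `anth_detectable`.
#' @method glance leaf_fit
#' @export
glance.leaf_fit <- function(x, ...) {
  tibble::tibble(
    residual_norm = x$residual_norm,
    rmse = if (is.na(x$residual_norm)) NA_real_ else
      sqrt(x$residual_norm / (2 * x$n_obs)),
    n_obs = x$n_obs,
    n_iterations = x$n_iterations,
    converged = x$converged,
    start_index = x$start_index,
    chl_car_ratio = x$chl_car_ratio,
    ratio_active = if (length(x$active_constraints)) {
      any(x$active_constraints[c("ratio_lower", "ratio_upper")])
    } else NA,
    anth_detectable = if (is.null(x$estimate)) NA else
      x$estimate$Canth >= x$config$detection_limit
  )
}

#' Augment the observed spectrum with fitted values
#'
#' @param x A `leaf_fit`.
#' @param ... Unused.
#' @return The in-window observations with `.fitted_reflectance`,
#'   `.fitted_transmittance`, `.resid_reflectance`,
#'   `.resid_transmittance`.
#' @method augment leaf_fit
#' @export
augment.leaf_fit <- function(x, ...) {
  if (is.null(x$fitted)) return(x$observed)
  dplyr::mutate(
    x$observed,
    .fitted_reflectance = x$fitted$reflectance,
    .fitted_transmittance = x$fitted$transmittance,
    .resid_reflectance = .data$reflectance - x$fitted$reflectance,
    .resid_transmittance = .data$transmittance - x$fitted$transmittance
  )
}
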
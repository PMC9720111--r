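# Spectrophotometric pigment quantification of ethanol leaf extracts.
#
# Freeze-dried leaf powder is extracted in 95% ethanol and the combined
# extract read at 470, 649 and 664 nm in a 1 cm pathlength against a
# solvent blank. Concentrations follow the standard linear pigment
# equations for that solvent; contents per dry mass follow from extract
# volume and weighed-in tissue mass.

#' Pigment-equation coefficient table
#'
#' Linear coefficients of the classical spectrophotometric pigment
#' equations, keyed by solvent so further solvent systems can be added.
#' For 95% ethanol (1 cm pathlength, ug mL-1):
#' `chl_a = 13.36 A664 - 5.19 A649`,
#' `chl_b = 27.43 A649 - 8.12 A664`,
#' `car = (1000 A470 - 2.13 chl_a - 97.64 chl_b) / 209`.
#'
#' @return A tibble with one row per solvent.
#' @export
pigment_equation_coefficients <- function() {
  tibble::tibble(
    solvent = "ethanol_95",
    ca_664 = 13.36, ca_649 = -5.19,
    cb_649 = 27.43, cb_664 = -8.12,
    car_470 = 1000, car_ca = -2.13, car_cb = -97.64, car_denom = 209
  )
}

#' Pigment concentrations of an extract from its absorbance triplet
#'
#' Applies the solvent-specific linear pigment equations to blank-corrected
#' absorbances at 470, 649 and 664 nm (1 cm pathlength). Readings above the
#' photometric linear range (~1.2) trigger a warning; assays yielding a
#' concentration below -0.01 ug mL-1 are flagged invalid (`valid = FALSE`)
#' and small negative round-off values are clipped to zero.
#'
#' @param assays Tibble with columns `A470`, `A649`, `A664` (one row per
#'   reading); other columns are carried through.
#' @param solvent Solvent key into [pigment_equation_coefficients()].
#' @return The input with columns `chl_a_conc`, `chl_b_conc`, `car_conc`
#'   (ug mL-1) and `valid` appended.
#' @examples
#' extract_concentrations(tibble::tibble(A470 = 0.3, A649 = 0.2, A664 = 0.5))
#' @export
extract_concentrations <- function(assays, solvent = "ethanol_95") {
  need <- c("A470", "A649", "A664")
  missing <- setdiff(need, names(assays))
  if (length(missing)) {
    stop("Assay table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(assays$A470 < 0 | assays$A649 < 0 | assays$A664 < 0)) {
    stop("Absorbances must be non-negative.", call. = FALSE)
  }
  if (any(c(assays$A470, assays$A649, assays$A664) > 1.2)) {
    warning("Absorbance readings above ~1.2 are outside the photometric ",
            "linear range.", call. = FALSE)
  }
  k <- pigment_equation_coefficients()
  k <- k[k$solvent == solvent, ]
  if (!nrow(k)) stop("Unknown solvent `", solvent, "`.", call. = FALSE)
  ca <- k$ca_664 * assays$A664 + k$ca_649 * assays$A649
  cb <- k$cb_649 * assays$A649 + k$cb_664 * assays$A664
  car <- (k$car_470 * assays$A470 + k$car_ca * ca + k$car_cb * cb) / k$car_denom
  valid <- ca > -0.01 & cb > -0.01 & car > -0.01
  dplyr::mutate(
    tibble::as_tibble(assays),
    chl_a_conc = pmax(ca, 0), chl_b_conc = pmax(cb, 0),
    car_conc = pmax(car, 0), valid = valid
  )
}

#' Convert extract concentration to content per leaf dry mass
#'
#' `content = concentration * extract_volume / dry_mass`; with
#' concentration in ug mL-1, volume in mL and mass in mg the result is in
#' ug mg-1, numerically equal to mg per g dry weight.
#'
#' @param conc Concentration (ug mL-1).
#' @param volume_ml Total extract volume (mL). The study default of 2.3 mL
#'   is the initial 0.6 mL plus the three washes of 0.6, 0.6 and 0.5 mL.
#' @param mass_mg Weighed-in tissue dry mass (mg).
#' @return Content in mg per g dry weight.
#' @examples
#' content_per_dry_mass(10, 2.3, 2.0)
#' @export
content_per_dry_mass <- function(conc, volume_ml = 2.3, mass_mg) {
  if (any(volume_ml <= 0) || any(mass_mg <= 0)) {
    stop("Extract volume and dry mass must be positive.", call. = FALSE)
  }
  conc * volume_ml / mass_mg
}

#' Full wet-chemistry chain for an assay table
#'
#' Applies [extract_concentrations()] and [content_per_dry_mass()] to every
#' reading of an assay table with columns `sample_id`, `replicate`, `A470`,
#' `A649`, `A664`, `extract_volume_ml`, `dry_mass_mg`.
#'
#' @param assays Assay tibble as above.
#' @param solvent Solvent key.
#' @return The input with per-replicate contents (mg g-1 dry weight):
#'   `chl_a`, `chl_b`, `chl_total`, `car_total`, plus `valid`.
#' @export
assay_contents <- function(assays, solvent = "ethanol_95") {
  need <- c("extract_volume_ml", "dry_mass_mg")
  missing <- setdiff(need, names(assays))
  if (length(missing)) {
    stop("Assay table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  out <- extract_concentrations(assays, solvent = solvent)
  dplyr::mutate(
    out,
    chl_a = content_per_dry_mass(.data$chl_a_conc, .data$extract_volume_ml,
                                 .data$dry_mass_mg),
    chl_b = content_per_dry_mass(.data$chl_b_conc, .data$extract_volume_ml,
                                 .data$dry_mass_mg),
    chl_total = .data$chl_a + .data$chl_b,
    car_total = content_per_dry_mass(.data$car_conc, .data$extract_volume_ml,
                                     .data$dry_mass_mg)
  )
}

#' Average extraction replicates into per-sample pigment contents
#'
#' Means of the per-replicate contents across the (typically three)
#' extraction replicates of each sample, after dropping replicates flagged
#' invalid. The chlorophyll/carotenoid ratio is undefined (NA, flagged)
#' when the carotenoid content is zero.
#'
#' @param contents Output of [assay_contents()].
#' @return One row per `sample_id`: `chl_a`, `chl_b`, `chl_total`,
#'   `car_total` (mg g-1 DW), `chl_car_ratio`, `n_replicates`,
#'   `n_dropped`, `ratio_defined`.
#' @export
summarize_replicates <- function(contents) {
  if (is.null(contents$sample_id)) {
    stop("`contents` needs a `sample_id` column.", call. = FALSE)
  }
  contents |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      n_replicates = sum(.data$valid),
      n_dropped = sum(!.data$valid),
      chl_a = mean(.data$chl_a[.data$valid]),
      chl_b = mean(.data$chl_b[.data$valid]),
      chl_total = mean(.data$chl_total[.data$valid]),
      car_total = mean(.data$car_total[.data$valid]),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      chl_car_ratio = dplyr::if_else(.data$car_total > 0,
                                     .data$chl_total / .data$car_total,
                                     NA_real_),
      ratio_defined = .data$car_total > 0
    )
}
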
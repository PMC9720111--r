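# Spectral records and the experiment design table.
#
# A spectrum is an ordinary tibble with columns `wavelength_nm`,
# `reflectance`, `transmittance`, plus any metadata columns (`sample_id`,
# `side`, `cultivar`, `pfd`, `spectrum`, `day`, ...). Collections of leaves
# are simply tall tibbles with a `sample_id` column, so all spectral
# operations compose with dplyr verbs.

#' Validate a measured spectrum
#'
#' Checks the invariants every calibrated reflectance/transmittance record
#' must satisfy: strictly increasing wavelengths, both quantities inside
#' \[0, 1\], and elementwise `R + T <= 1` up to a calibration tolerance.
#'
#' @param spectrum A tibble with `wavelength_nm`, `reflectance`,
#'   `transmittance` columns (one sample).
#' @param rt_tol Tolerance on `R + T - 1` beyond which the record is
#'   treated as a calibration error (default 0.01).
#' @return The input, invisibly, if valid; otherwise an error.
#' @export
check_spectrum <- function(spectrum, rt_tol = 0.01) {
  need <- c("wavelength_nm", "reflectance", "transmittance")
  missing <- setdiff(need, names(spectrum))
  if (length(missing)) {
    stop("Spectrum lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(spectrum) < 2) stop("Spectrum needs at least 2 rows.", call. = FALSE)
  if (is.unsorted(spectrum$wavelength_nm, strictly = TRUE)) {
    stop("Wavelengths must be strictly increasing.", call. = FALSE)
  }
  r <- spectrum$reflectance
  t <- spectrum$transmittance
  if (any(!is.finite(r)) || any(!is.finite(t))) {
    stop("Non-finite reflectance/transmittance values.", call. = FALSE)
  }
  if (any(r < 0 | r > 1) || any(t < 0 | t > 1)) {
    stop("Reflectance and transmittance must lie in [0, 1].", call. = FALSE)
  }
  bad <- r + t > 1 + rt_tol
  if (any(bad)) {
    stop("Calibration error: R + T > 1 + ", rt_tol, " at ", sum(bad),
         " wavelength(s), first at ", spectrum$wavelength_nm[which(bad)[1]],
         " nm.", call. = FALSE)
  }
  invisible(spectrum)
}

#' Read a leaf spectrum from disk
#'
#' Supports two dialects: `"combined"`, a CSV with header
#' `wavelength_nm,reflectance,transmittance`; and `"two_column"`,
#' instrument-style two-column wavelength/value exports, one file for
#' reflectance (`path`) and one for transmittance (`transmittance_path`).
#'
#' @param path File with the spectrum (combined) or the reflectance
#'   (two-column dialect).
#' @param dialect `"combined"` (default) or `"two_column"`.
#' @param transmittance_path Second file for the two-column dialect.
#' @param resample_to Optional target wavelength grid (nm); when given the
#'   record is linearly interpolated onto it.
#' @param rt_tol Calibration tolerance passed to [check_spectrum()].
#' @param metadata Named list of metadata values added as columns
#'   (e.g. `sample_id`, `cultivar`).
#' @return A validated spectrum tibble.
#' @export
read_spectrum <- function(path, dialect = c("combined", "two_column"),
                          transmittance_path = NULL, resample_to = NULL,
                          rt_tol = 0.01, metadata = list()) {
  dialect <- match.arg(dialect)
  if (dialect == "combined") {
    df <- readr::read_csv(path, show_col_types = FALSE)
    need <- c("wavelength_nm", "reflectance", "transmittance")
    if (!all(need %in% names(df))) {
      stop("Combined spectrum file must have header ",
           "`wavelength_nm,reflectance,transmittance`.", call. = FALSE)
    }
    df <- df[need]
  } else {
    if (is.null(transmittance_path)) {
      stop("Two-column dialect needs `transmittance_path`.", call. = FALSE)
    }
    rd <- function(f) {
      x <- utils::read.table(f, header = FALSE, sep = "", comment.char = "#",
                             col.names = c("wavelength_nm", "value"))
      tibble::as_tibble(x)
    }
    rr <- rd(path)
    tt <- rd(transmittance_path)
    if (!isTRUE(all.equal(rr$wavelength_nm, tt$wavelength_nm))) {
      stop("Reflectance and transmittance files are on different grids.",
           call. = FALSE)
    }
    df <- tibble::tibble(wavelength_nm = rr$wavelength_nm,
                         reflectance = rr$value, transmittance = tt$value)
  }
  if (!is.null(resample_to)) df <- resample_spectrum(df, resample_to)
  for (nm in names(metadata)) df[[nm]] <- metadata[[nm]]
  check_spectrum(df, rt_tol = rt_tol)
  df
}

#' Write a spectrum tibble to CSV
#'
#' @param spectrum A spectrum tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path) {
  readr::write_csv(spectrum, path)
  invisible(path)
}

#' Resample a spectrum onto a target wavelength grid
#'
#' Linear interpolation of reflectance and transmittance; exact (no change)
#' where target wavelengths coincide with measured ones. Extrapolation is
#' refused.
#'
#' @param spectrum A spectrum tibble (one sample).
#' @param grid Target wavelengths in nm, strictly increasing.
#' @return The resampled spectrum; metadata columns are carried over.
#' @export
resample_spectrum <- function(spectrum, grid) {
  if (is.unsorted(grid, strictly = TRUE)) {
    stop("Target grid must be strictly increasing.", call. = FALSE)
  }
  wl <- spectrum$wavelength_nm
  if (min(grid) < min(wl) || max(grid) > max(wl)) {
    stop("Target grid extends beyond the measured range [", min(wl), ", ",
         max(wl), "] nm.", call. = FALSE)
  }
  out <- tibble::tibble(
    wavelength_nm = as.numeric(grid),
    reflectance = stats::approx(wl, spectrum$reflectance, xout = grid)$y,
    transmittance = stats::approx(wl, spectrum$transmittance, xout = grid)$y
  )
  meta <- setdiff(names(spectrum), names(out))
  for (nm in meta) out[[nm]] <- spectrum[[nm]][1]
  out
}

#' Average the two midrib-side measurements of a leaf
#'
#' Each leaf is measured once on either side of the midrib; the package
#' combines the two records by the elementwise arithmetic mean of
#' reflectance and of transmittance, marking the result `side =
#' "averaged"`. Raw sides should be retained by the caller.
#'
#' @param left,right Spectrum tibbles on the identical wavelength grid and
#'   with the same `sample_id` (when present).
#' @return The averaged spectrum.
#' @export
average_sides <- function(left, right) {
  if (nrow(left) != nrow(right) ||
      !isTRUE(all.equal(left$wavelength_nm, right$wavelength_nm))) {
    stop("Side records are on different wavelength grids.", call. = FALSE)
  }
  if (!is.null(left$sample_id) && !is.null(right$sample_id) &&
      !identical(left$sample_id[1], right$sample_id[1])) {
    stop("Side records belong to different samples.", call. = FALSE)
  }
  out <- left
  out$reflectance <- (left$reflectance + right$reflectance) / 2
  out$transmittance <- (left$transmittance + right$transmittance) / 2
  out$side <- "averaged"
  out
}

#' Factorial experiment design
#'
#' Describes the growth-chamber light-quality experiment: two cultivars
#' (a green one without and a red one with anthocyanins), two photon flux
#' densities, two white-light spectra differing in their blue percentage,
#' and three sampling days, grown at a fixed plant density.
#'
#' @param growing_area_m2 Area of one growing compartment (m2).
#' @param plants_per_area Plants hosted per compartment.
#' @param cultivars Cultivar labels; first is the anthocyanin-free one.
#' @param pfd_levels Photon flux densities (umol m-2 s-1).
#' @param days Sampling days after treatment start.
#' @param bands Per-spectrum waveband percentages: a tibble with columns
#'   `spectrum`, `white`, `blue`, `green`, `red`, `far_red`, where `white`
#'   is the printed white-total column and the last four are the channel
#'   percentages.
#' @return A list of class `experiment_design`.
#' @export
experiment_design <- function(growing_area_m2 = 0.27, plants_per_area = 12,
                              cultivars = c("CV_g", "CV_r"),
                              pfd_levels = c(160, 240), days = c(1, 7, 14),
                              bands = default_band_table()) {
  stopifnot(growing_area_m2 > 0, plants_per_area > 0)
  structure(
    list(growing_area_m2 = growing_area_m2, plants_per_area = plants_per_area,
         cultivars = cultivars, pfd_levels = pfd_levels, days = days,
         bands = tibble::as_tibble(bands)),
    class = "experiment_design"
  )
}

#' @rdname experiment_design
#' @export
default_band_table <- function() {
  tibble::tibble(
    spectrum = c("B15", "B40"),
    white = c(75, 60),
    blue = c(15, 40),
    green = c(40, 35),
    red = c(29, 16),
    far_red = c(16, 9)
  )
}

#' Validate an experiment design
#'
#' Computes the plant density and, per light spectrum, the sum of the four
#' waveband percentages (which must total 100) and the consistency between
#' the printed white-total column and the sum of its green/red/far-red
#' constituents. Inconsistencies are flagged in the report, never raised
#' as errors.
#'
#' @param design An [experiment_design()].
#' @return A tibble with columns `check`, `spectrum`, `value`, `ok`,
#'   `note`.
#' @examples
#' validate_design(experiment_design())
#' @export
validate_design <- function(design) {
  stopifnot(inherits(design, "experiment_design"))
  density <- design$plants_per_area / design$growing_area_m2
  rows <- list(tibble::tibble(
    check = "plant_density_per_m2", spectrum = NA_character_,
    value = density, ok = TRUE,
    note = sprintf("%d plants / %.2f m2", design$plants_per_area,
                   design$growing_area_m2)
  ))
  b <- design$bands
  for (i in seq_len(nrow(b))) {
    total <- b$blue[i] + b$green[i] + b$red[i] + b$far_red[i]
    rows <- c(rows, list(tibble::tibble(
      check = "band_percentages_sum", spectrum = b$spectrum[i],
      value = total, ok = total == 100,
      note = if (total == 100) "bands sum to 100" else
        sprintf("bands sum to %g, expected 100", total)
    )))
    bracket <- b$green[i] + b$red[i] + b$far_red[i]
    rows <- c(rows, list(tibble::tibble(
      check = "white_total_vs_bracket", spectrum = b$spectrum[i],
      value = bracket, ok = bracket == b$white[i],
      note = if (bracket == b$white[i]) "white column consistent" else
        sprintf("white column %g but green+red+far_red = %g",
                b$white[i], bracket)
    )))
  }
  dplyr::bind_rows(rows)
}

#' Plant density of a growing area
#'
#' @param plants Number of plants.
#' @param area_m2 Growing area in m2.
#' @return Plants per m2.
#' @examples
#' plant_density(12, 0.27)
#' @export
plant_density <- function(plants, area_m2) {
  if (any(area_m2 <= 0)) stop("`area_m2` must be > 0.", call. = FALSE)
  plants / area_m2
}
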
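# Light-adapted chlorophyll a fluorescence quenching indices.
#
# The indices operate on trace level summaries extracted upstream by the
# imaging fluorometer protocol: F_M_Lss (steady-state maximum fluorescence
# in light), F_t_Lss (steady-state fluorescence in light), F_P (peak of
# the initial Kautsky phase) and F_M_D3 (instantaneous maximum during dark
# relaxation), all in instrument counts.

#' Chlorophyll fluorescence quenching indices
#'
#' Computes, per row of a level-summary table:
#' * `QY` (phiPSII), the steady-state PSII quantum yield,
#'   `(F_M_Lss - F_t_Lss) / F_M_Lss`;
#' * `Rfd`, the fluorescence-decline vitality index,
#'   `(F_P - F_t_Lss) / F_t_Lss`;
#' * `qE`, the energy-dependent quenching,
#'   `(F_M_D3 - F_M_Lss) / F_M_D3`.
#'
#' A zero denominator makes only the affected index `NA` (flagged in
#' `qc_flags`); the remaining indices are still returned.
#'
#' @param traces Tibble with columns `F_M_Lss`, `F_t_Lss`, `F_P`,
#'   `F_M_D3`; other columns are carried through.
#' @return The input with `QY`, `Rfd`, `qE` and `qc_flags` appended.
#' @examples
#' fluorescence_indices(tibble::tibble(
#'   F_M_Lss = 1000, F_t_Lss = 600, F_P = 900, F_M_D3 = 1200
#' ))
#' @export
fluorescence_indices <- function(traces) {
  need <- c("F_M_Lss", "F_t_Lss", "F_P", "F_M_D3")
  missing <- setdiff(need, names(traces))
  if (length(missing)) {
    stop("Trace table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(unlist(traces[need]) < 0)) {
    stop("Fluorescence levels must be non-negative.", call. = FALSE)
  }
  out <- tibble::as_tibble(traces)
  qy_ok <- out$F_M_Lss > 0
  rfd_ok <- out$F_t_Lss > 0
  qe_ok <- out$F_M_D3 > 0
  out$QY <- ifelse(qy_ok, (out$F_M_Lss - out$F_t_Lss) / out$F_M_Lss, NA_real_)
  out$Rfd <- ifelse(rfd_ok, (out$F_P - out$F_t_Lss) / out$F_t_Lss, NA_real_)
  out$qE <- ifelse(qe_ok, (out$F_M_D3 - out$F_M_Lss) / out$F_M_D3, NA_real_)
  out$qc_flags <- purrr::pmap_chr(
    list(qy_ok, rfd_ok, qe_ok),
    function(a, b, c) {
      bad <- c("QY", "Rfd", "qE")[!c(a, b, c)]
      if (length(bad)) paste0("undefined: ", paste(bad, collapse = ",")) else ""
    }
  )
  out
}

#' Classify photosynthetic vitality from the Rfd index
#'
#' Rfd values below a critical threshold of 1.0 indicate impaired
#' photosynthetic activity; values reaching 3.0 indicate high
#' photosynthetic efficiency; everything in between is normal. Both
#' thresholds are configurable.
#'
#' @param rfd Numeric vector of Rfd values.
#' @param critical Lower threshold (default 1.0).
#' @param high Upper threshold (default 3.0).
#' @return Factor with levels `below_critical`, `normal`, `high`.
#' @examples
#' classify_vitality(c(0.8, 2, 3.5))
#' @export
classify_vitality <- function(rfd, critical = 1.0, high = 3.0) {
  if (any(!is.finite(rfd))) stop("`rfd` must be finite.", call. = FALSE)
  cut(rfd, breaks = c(-Inf, critical, high, Inf), right = FALSE,
      labels = c("below_critical", "normal", "high"))
}
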
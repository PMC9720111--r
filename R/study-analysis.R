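# Downstream study computations: unit conversion between area- and
# mass-based pigment contents, modelled-vs-measured correlation by
# grouping factor, pigment-ratio time series, and growth-effect summaries
# of the photon-flux-density treatments.

#' Convert area-based pigment content to dry-mass basis
#'
#' The inversion estimates contents per leaf area (ug cm-2) while the wet
#' chemistry reports them per dry mass (mg g-1 DW); dividing by the leaf
#' mass per area (LMA, g cm-2) and by 1000 converts the former to the
#' latter.
#'
#' @param content_area Content per area (ug cm-2).
#' @param lma Leaf mass per area (g cm-2), > 0.
#' @return Content in mg per g dry weight.
#' @examples
#' area_to_mass(50, 0.004)
#' @export
area_to_mass <- function(content_area, lma) {
  if (any(!is.finite(lma)) || any(lma <= 0)) {
    stop("`lma` must be positive; missing LMA for a treatment cell.",
         call. = FALSE)
  }
  content_area / lma / 1000
}

#' @rdname area_to_mass
#' @param content_mass Content in mg per g dry weight.
#' @export
mass_to_area <- function(content_mass, lma) {
  if (any(!is.finite(lma)) || any(lma <= 0)) {
    stop("`lma` must be positive.", call. = FALSE)
  }
  content_mass * lma * 1000
}

#' Join treatment-level LMA onto estimates and convert named columns
#'
#' LMA is usually known only at the treatment level, so the LMA table maps
#' treatment cells (any subset of `cultivar`, `pfd`, `spectrum`, `day`) to
#' `lma_g_cm2`. Every estimate row must match exactly one LMA row.
#'
#' @param estimates Tibble of per-leaf estimates with treatment columns.
#' @param lma_table Tibble with the treatment key columns and `lma_g_cm2`.
#' @param cols Names of area-based content columns (ug cm-2) to convert;
#'   converted columns are suffixed `_mass` (mg g-1 DW).
#' @return The estimates with `lma_g_cm2` and converted columns appended.
#' @export
convert_area_to_mass <- function(estimates, lma_table,
                                 cols = c("Cab", "Ccar", "Canth")) {
  key <- intersect(names(lma_table), names(estimates))
  if (!length(key)) stop("No shared treatment columns.", call. = FALSE)
  if (any(lma_table$lma_g_cm2 <= 0)) {
    stop("LMA values must be positive.", call. = FALSE)
  }
  out <- dplyr::left_join(estimates, lma_table, by = key)
  if (any(is.na(out$lma_g_cm2))) {
    stop("Missing LMA for ", sum(is.na(out$lma_g_cm2)), " row(s).",
         call. = FALSE)
  }
  for (cl in cols) {
    out[[paste0(cl, "_mass")]] <- area_to_mass(out[[cl]], out$lma_g_cm2)
  }
  out
}

#' Pearson correlation of modelled vs measured contents, by group
#'
#' Pairs the two tables by `sample_id`, computes the Pearson correlation
#' coefficient and the least-squares regression line (measured on
#' modelled) within each level of a grouping factor, plus a pooled
#' `overall` row. Groups whose vectors are constant get `r = NA` with a
#' flag; groups with fewer than 3 pairs are refused.
#'
#' @param modelled,measured Tibbles with `sample_id` and the value column.
#' @param value Name of the value column in both tables.
#' @param group Name of the grouping column in `modelled` (use `NULL` for
#'   pooled only).
#' @return Tibble with `group`, `level`, `n`, `r`, `slope`, `intercept`,
#'   `flag`.
#' @export
grouped_correlation <- function(modelled, measured, value = "chl_total",
                                group = NULL) {
  paired <- dplyr::inner_join(
    dplyr::select(modelled, dplyr::all_of(c("sample_id", value, group))),
    dplyr::select(measured, dplyr::all_of(c("sample_id", value))),
    by = "sample_id", suffix = c("_modelled", "_measured")
  )
  x_col <- paste0(value, "_modelled")
  y_col <- paste0(value, "_measured")
  one <- function(df, level) {
    x <- df[[x_col]]
    y <- df[[y_col]]
    if (length(x) < 3) {
      stop("Fewer than 3 pairs in group `", level, "`.", call. = FALSE)
    }
    constant <- stats::sd(x) == 0 || stats::sd(y) == 0
    if (constant) {
      return(tibble::tibble(level = level, n = length(x), r = NA_real_,
                            slope = NA_real_, intercept = NA_real_,
                            flag = "constant vector"))
    }
    fit <- stats::lm(y ~ x)
    tibble::tibble(level = level, n = length(x),
                   r = stats::cor(x, y),
                   slope = unname(stats::coef(fit)[2]),
                   intercept = unname(stats::coef(fit)[1]),
                   flag = "")
  }
  rows <- list(one(paired, "overall"))
  if (!is.null(group)) {
    for (lev in unique(paired[[group]])) {
      rows <- c(rows, list(one(paired[paired[[group]] == lev, ],
                               as.character(lev))))
    }
  }
  dplyr::bind_rows(rows) |>
    dplyr::mutate(group = group %||% "pooled", .before = 1)
}

#' Group-mean time series of a pigment ratio
#'
#' Computes a per-sample ratio of two content columns, then its mean,
#' standard deviation and count per treatment cell and day. Samples with a
#' non-positive denominator are flagged and excluded from the means.
#'
#' @param estimates Tibble of per-sample contents with treatment columns.
#' @param numerator,denominator Content column names.
#' @param group_by Character vector of grouping columns
#'   (default `c("cultivar", "pfd", "spectrum", "day")`).
#' @return Grouped tibble with `mean_ratio`, `sd_ratio`, `n`,
#'   `n_undefined`.
#' @export
pigment_ratio_series <- function(estimates, numerator = "Canth",
                                 denominator = "Cab",
                                 group_by = c("cultivar", "pfd", "spectrum",
                                              "day")) {
  group_by <- intersect(group_by, names(estimates))
  den <- estimates[[denominator]]
  num <- estimates[[numerator]]
  ok <- is.finite(den) & den > 0 & is.finite(num)
  estimates$.ratio <- ifelse(ok, num / den, NA_real_)
  estimates |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group_by))) |>
    dplyr::summarise(
      mean_ratio = mean(.data$.ratio, na.rm = TRUE),
      sd_ratio = stats::sd(.data$.ratio, na.rm = TRUE),
      n = sum(!is.na(.data$.ratio)),
      n_undefined = sum(is.na(.data$.ratio)),
      .groups = "drop"
    )
}

#' Growth response to the higher photon flux density
#'
#' Pools the two spectral treatments within each PFD level by the
#' arithmetic mean of the printed treatment means, then reports the
#' percent change of the pooled high-PFD mean relative to itself:
#' `100 * (pooled_high - pooled_low) / pooled_high`, rounded to integer
#' percent. Expressing the change relative to the higher-PFD mean is the
#' convention that reproduces the published growth summaries from their
#' treatment-mean table.
#'
#' @param treatment_means Tibble with columns `cultivar`, `pfd`,
#'   `spectrum`, and one column per trait (e.g. `fresh_weight_g`).
#' @param traits Trait column names to summarise.
#' @return Tibble with `cultivar`, `trait`, `pooled_low`, `pooled_high`,
#'   `pct_change`.
#' @examples
#' tbl <- growth_table()
#' pfd_effect_summary(tbl)
#' @export
pfd_effect_summary <- function(treatment_means, traits = NULL) {
  need <- c("cultivar", "pfd", "spectrum")
  missing <- setdiff(need, names(treatment_means))
  if (length(missing)) {
    stop("Means table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(traits)) {
    traits <- setdiff(names(treatment_means), need)
  }
  pfds <- sort(unique(treatment_means$pfd))
  if (length(pfds) != 2) stop("Need exactly two PFD levels.", call. = FALSE)
  rows <- list()
  for (cv in unique(treatment_means$cultivar)) {
    for (tr in traits) {
      pooled <- vapply(pfds, function(p) {
        cell <- treatment_means[treatment_means$cultivar == cv &
                                  treatment_means$pfd == p, ]
        if (nrow(cell) < 2) {
          stop("Missing treatment cell for cultivar ", cv, " at PFD ", p,
               ".", call. = FALSE)
        }
        mean(cell[[tr]])
      }, numeric(1))
      rows <- c(rows, list(tibble::tibble(
        cultivar = cv, trait = tr,
        pooled_low = pooled[1], pooled_high = pooled[2],
        pct_change = round(100 * (pooled[2] - pooled[1]) / pooled[2])
      )))
    }
  }
  dplyr::bind_rows(rows)
}

#' Published growth-response treatment means
#'
#' Fresh and dry rosette weights (g per head, treatment means) of the two
#' lettuce cultivars under the four light treatments at harvest, as used
#' by the worked growth-summary example.
#'
#' @return A tibble with columns `cultivar`, `pfd`, `spectrum`,
#'   `fresh_weight_g`, `dry_weight_g`.
#' @export
growth_table <- function() {
  tibble::tibble(
    cultivar = rep(c("CV_g", "CV_r"), each = 4),
    pfd = rep(c(160, 160, 240, 240), 2),
    spectrum = rep(c("B15", "B40"), 4),
    fresh_weight_g = c(11.14, 10.18, 24.89, 23.08,
                       14.72, 13.53, 25.83, 22.95),
    dry_weight_g = c(0.63, 0.49, 1.16, 1.07,
                     0.83, 0.77, 1.17, 1.07)
  )
}
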
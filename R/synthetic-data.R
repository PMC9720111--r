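# Synthetic cohort generator.
#
# Emulates the statistical structure of the two-cultivar light-quality
# experiment: a 2 cultivars x 2 PFDs x 2 spectra x 3 sampling-days
# factorial with replicate leaves, cultivar-specific anthocyanin presence
# (red cultivar only), treatment effect multipliers on the pigment pools,
# replicate-level lognormal scatter, and instrument noise on spectra,
# assay absorbances and fluorescence levels. Ground truth is stored for
# every simulated record so each pipeline stage can be verified.

#' Synthetic study design
#'
#' Bundles the factorial structure, per-cultivar baseline leaf properties,
#' treatment effect multipliers, treatment-level leaf mass per area, the
#' noise model and the seed. The default effect calibration mirrors the
#' direction and magnitude of the published treatment responses (blue
#' enrichment raising chlorophylls ~13%/12% at day 1 under the two PFDs,
#' carotenoids ~15% at day 1, anthocyanin increases up to +50% at the low
#' and +19% at the high PFD in the red cultivar, the
#' chlorophyll/carotenoid ratio drifting up over days at the low PFD and
#' down at the high one, and the zeaxanthin fraction lowered by blue
#' enrichment at the low PFD but raised at the high one).
#'
#' @param replicates Leaves per treatment cell per day (default 3).
#' @param seed Generator seed.
#' @param baselines Per-cultivar baseline biophysics: tibble with
#'   `cultivar` and the [leaf_biophysics()] fields. The green cultivar
#'   carries zero anthocyanin.
#' @param effects Effect-multiplier table from [default_effect_table()]:
#'   one multiplier per (parameter, pfd, spectrum, day).
#' @param lma_table Treatment-level leaf mass per area (g cm-2).
#' @param noise List with `rt_mult_sd` (multiplicative sd on R and T,
#'   default 0.01), `absorbance_sd` (additive sd on assay absorbances,
#'   default 0.005), `fluor_mult_sd` (multiplicative sd on fluorescence
#'   levels, default 0.02), `scatter_sdlog` (replicate lognormal scatter
#'   on pigment pools, default 0.06).
#' @return A list of class `synthetic_design`.
#' @export
synthetic_design <- function(replicates = 3L, seed = 1L,
                             baselines = default_baselines(),
                             effects = default_effect_table(),
                             lma_table = default_lma_table(),
                             noise = list()) {
  noise <- utils::modifyList(
    list(rt_mult_sd = 0.01, absorbance_sd = 0.005, fluor_mult_sd = 0.02,
         scatter_sdlog = 0.06),
    noise
  )
  stopifnot(replicates >= 1)
  ratio <- baselines$Cab / baselines$Ccar
  if (any(ratio <= 4.4 | ratio >= 6.4)) {
    stop("Baseline Cab/Ccar must lie strictly inside (4.4, 6.4).",
         call. = FALSE)
  }
  if (any(effects$multiplier <= 0)) {
    stop("Effect multipliers must be positive.", call. = FALSE)
  }
  structure(
    list(replicates = as.integer(replicates), seed = as.integer(seed),
         cultivars = baselines$cultivar, pfd_levels = c(160, 240),
         spectra = c("B15", "B40"), days = c(1, 7, 14),
         baselines = baselines, effects = effects, lma_table = lma_table,
         noise = noise),
    class = "synthetic_design"
  )
}

#' @rdname synthetic_design
#' @export
default_baselines <- function() {
  tibble::tibble(
    cultivar = c("CV_g", "CV_r"),
    N = c(1.5, 1.6),
    Cab = c(45, 42),
    Ccar = c(45 / 5.4, 42 / 5.2),
    Canth = c(0, 3),
    Cx = c(0.25, 0.3),
    Cbrown = c(0.05, 0.05),
    Cw = c(0.012, 0.012),
    Cm = c(0.0045, 0.0048)
  )
}

#' @rdname synthetic_design
#' @export
default_effect_table <- function() {
  grid <- tidyr::expand_grid(
    parameter = c("Cab", "Ccar", "Canth", "Cx"),
    pfd = c(160, 240), spectrum = c("B15", "B40"), day = c(1, 7, 14)
  )
  day_idx <- function(day) match(day, c(1, 7, 14))
  # time trends applied to every spectrum within a PFD
  trend <- list(
    Cab = list(`160` = c(1, 1.02, 1.06), `240` = c(1, 1.05, 1.10)),
    Ccar = list(`160` = c(1, 1.00, 1.00), `240` = c(1, 1.06, 1.14)),
    Canth = list(`160` = c(1, 1.05, 1.10), `240` = c(1, 1.15, 1.30)),
    Cx = list(`160` = c(1, 1, 1), `240` = c(1, 1, 1))
  )
  # additional blue-enrichment (B40 vs B15) effects
  blue <- list(
    Cab = list(`160` = c(1.13, 1.04, 1.02), `240` = c(1.12, 1.04, 1.02)),
    Ccar = list(`160` = c(1.15, 1.07, 1.00), `240` = c(1.15, 1.02, 1.00)),
    Canth = list(`160` = c(1.20, 1.35, 1.50), `240` = c(1.10, 1.15, 1.19)),
    Cx = list(`160` = c(0.85, 0.80, 0.75), `240` = c(1.10, 1.20, 1.27))
  )
  grid$multiplier <- purrr::pmap_dbl(grid, function(parameter, pfd, spectrum, day) {
    i <- day_idx(day)
    m <- trend[[parameter]][[as.character(pfd)]][i]
    if (spectrum == "B40") m <- m * blue[[parameter]][[as.character(pfd)]][i]
    m
  })
  grid
}

#' @rdname synthetic_design
#' @export
default_lma_table <- function() {
  tidyr::expand_grid(cultivar = c("CV_g", "CV_r"),
                     pfd = c(160, 240), spectrum = c("B15", "B40")) |>
    dplyr::mutate(lma_g_cm2 = ifelse(.data$pfd == 240, 0.0050, 0.0040) *
                    ifelse(.data$cultivar == "CV_r", 1.05, 1))
}

cell_multipliers <- function(design, pfd, spectrum, day) {
  e <- design$effects
  sel <- e[e$pfd == pfd & e$spectrum == spectrum & e$day == day, ]
  stats::setNames(sel$multiplier, sel$parameter)
}

#' Draw leaf biophysics for one treatment cell
#'
#' Baseline times the cell's effect multipliers times lognormal replicate
#' scatter, truncated to the valid parameter space; anthocyanin is forced
#' to zero for the anthocyanin-free (first) cultivar by its zero baseline.
#' Draws come from the current RNG stream; wrap in `set.seed()` (or use
#' [generate_cohort()], which seeds internally) for reproducibility.
#'
#' @param design A [synthetic_design()].
#' @param cultivar,pfd,spectrum,day Treatment cell.
#' @param n Number of leaves to draw.
#' @return Tibble of `n` rows with the [leaf_biophysics()] fields.
#' @export
sample_biophysics <- function(design, cultivar, pfd, spectrum, day, n = 1L) {
  base <- design$baselines[design$baselines$cultivar == cultivar, ]
  if (!nrow(base)) stop("Unknown cultivar `", cultivar, "`.", call. = FALSE)
  mult <- cell_multipliers(design, pfd, spectrum, day)
  sdl <- design$noise$scatter_sdlog
  scatter <- function(n, sd = sdl) stats::rlnorm(n, -sd^2 / 2, sd)
  cx0 <- min(base$Cx * (mult[["Cx"]] %||% 1), 0.95)
  # chlorophylls and carotenoids share one pool-size scatter factor: the
  # chl/car ratio varies far less between leaves than either pool does
  pool <- scatter(n)
  ratio_jitter <- scatter(n, sdl / 4)
  tibble::tibble(
    N = pmax(base$N * scatter(n, sdl / 2), 1),
    Cab = base$Cab * (mult[["Cab"]] %||% 1) * pool,
    Ccar = base$Ccar * (mult[["Ccar"]] %||% 1) * pool / ratio_jitter,
    Canth = base$Canth * (mult[["Canth"]] %||% 1) * scatter(n),
    Cx = pmin(pmax(cx0 + stats::rnorm(n, 0, sdl / 2), 0), 1),
    Cbrown = base$Cbrown * scatter(n),
    Cw = base$Cw * scatter(n, 0.8 * sdl),
    Cm = base$Cm * scatter(n, 0.8 * sdl)
  )
}

# Invert the wet-chemistry linear system: concentrations -> absorbances.
concentrations_to_absorbances <- function(ca, cb, ccar) {
  k <- pigment_equation_coefficients()
  m <- matrix(c(k$ca_664, k$ca_649, k$cb_664, k$cb_649), nrow = 2,
              byrow = TRUE)  # rows: ca, cb; cols: A664, A649
  inv <- solve(m)
  a <- inv %*% rbind(ca, cb)
  A470 <- (k$car_denom * ccar - k$car_ca * ca - k$car_cb * cb) / k$car_470
  tibble::tibble(A470 = as.numeric(A470), A649 = a[2, ], A664 = a[1, ])
}

#' Generate a full synthetic cohort
#'
#' For every leaf of the factorial design: draws true biophysics, renders
#' its reflectance/transmittance spectrum through the forward model with
#' multiplicative instrument noise (clipped so `R + T <= 1`), derives
#' assay absorbance triplets by inverting the wet-chemistry equations from
#' the true mass-based contents (using the treatment LMA and a 3:1
#' chlorophyll a:b split) with additive noise, and draws fluorescence
#' level summaries whose Rfd and qE rise with day and blue fraction.
#'
#' @param design A [synthetic_design()].
#' @param lib An `absorption_library` (default the synthetic one).
#' @return A list of class `synthetic_cohort` with tibbles `truth`,
#'   `spectra` (tall), `assays`, `fluorescence`, the `design`, and the
#'   spectral noise `clip_rate`.
#' @examples
#' cohort <- generate_cohort(synthetic_design(replicates = 1, seed = 3))
#' nrow(cohort$truth)
#' @export
generate_cohort <- function(design, lib = build_synthetic_library()) {
  stopifnot(inherits(design, "synthetic_design"))
  seeded(design$seed, generate_cohort_impl(design, lib))
}

generate_cohort_impl <- function(design, lib) {
  cells <- tidyr::expand_grid(
    cultivar = design$cultivars, pfd = design$pfd_levels,
    spectrum = design$spectra, day = design$days
  )
  prep <- prepare_library(lib)
  noise <- design$noise
  truth <- list(); spectra <- list(); assays <- list(); fluor <- list()
  n_clipped <- 0L; n_wl <- 0L
  for (i in seq_len(nrow(cells))) {
    cell <- cells[i, ]
    draws <- sample_biophysics(design, cell$cultivar, cell$pfd,
                               cell$spectrum, cell$day,
                               n = design$replicates)
    lma <- design$lma_table
    lma <- lma$lma_g_cm2[lma$cultivar == cell$cultivar &
                           lma$pfd == cell$pfd &
                           lma$spectrum == cell$spectrum]
    for (r in seq_len(design$replicates)) {
      id <- sprintf("%s_%d_%s_D%d_r%d", cell$cultivar, cell$pfd,
                    cell$spectrum, cell$day, r)
      p <- row_to_biophysics(as.list(draws[r, ]))
      truth[[id]] <- dplyr::bind_cols(
        tibble::tibble(sample_id = id), cell, replicate = r,
        tibble::as_tibble(unclass(p)), lma_g_cm2 = lma
      )
      # spectrum with multiplicative noise, clipped to R + T <= 1
      rt <- forward_rt(unclass(p), prep)
      nr <- length(rt$reflectance)
      R <- rt$reflectance * (1 + stats::rnorm(nr, 0, noise$rt_mult_sd))
      Tt <- rt$transmittance * (1 + stats::rnorm(nr, 0, noise$rt_mult_sd))
      R <- pmin(pmax(R, 0), 1)
      Tt <- pmin(pmax(Tt, 0), 1)
      over <- R + Tt > 1
      if (any(over)) {
        sc <- 1 / (R[over] + Tt[over])
        R[over] <- R[over] * sc
        Tt[over] <- Tt[over] * sc
      }
      n_clipped <- n_clipped + sum(over); n_wl <- n_wl + nr
      spectra[[id]] <- dplyr::bind_cols(
        tibble::tibble(wavelength_nm = lib$wavelength_nm, reflectance = R,
                       transmittance = Tt, sample_id = id, side = "averaged"),
        cell
      )
      # assay triplet: true mass-based contents -> concentrations ->
      # absorbances (+ additive noise); chlorophyll a:b split 3:1
      chl_mass <- area_to_mass(p$Cab, lma)   # mg g-1 == ug mg-1
      car_mass <- area_to_mass(p$Ccar, lma)
      mass <- stats::runif(3, 1.6, 2.8)
      vol <- 2.3
      ca <- 0.75 * chl_mass * mass / vol
      cb <- 0.25 * chl_mass * mass / vol
      cc <- car_mass * mass / vol
      ab <- concentrations_to_absorbances(ca, cb, cc)
      ab <- dplyr::mutate(ab, dplyr::across(
        dplyr::everything(),
        ~ pmax(.x + stats::rnorm(3, 0, noise$absorbance_sd), 0)
      ))
      assays[[id]] <- dplyr::bind_cols(
        tibble::tibble(sample_id = id, replicate = 1:3), ab,
        extract_volume_ml = vol, dry_mass_mg = mass, cell
      )
      # fluorescence levels engineered so Rfd and qE rise with day and
      # with the blue fraction
      di <- match(cell$day, design$days)
      blue <- cell$spectrum == "B40"
      qy <- 0.55
      rfd <- c(1.4, 2.0, 2.8)[di] + (if (blue) c(0.1, 0.3, 0.5)[di] else 0) +
        (cell$pfd - 160) / 80 * 0.15
      qe <- c(0.12, 0.18, 0.24)[di] + (if (blue) c(0.02, 0.05, 0.08)[di] else 0)
      ft <- 500 * (1 + stats::rnorm(1, 0, noise$fluor_mult_sd))
      fm <- ft / (1 - qy) * (1 + stats::rnorm(1, 0, noise$fluor_mult_sd / 2))
      fp <- ft * (1 + rfd) * (1 + stats::rnorm(1, 0, noise$fluor_mult_sd / 2))
      fmd3 <- fm / (1 - qe) * (1 + stats::rnorm(1, 0, noise$fluor_mult_sd / 2))
      fluor[[id]] <- dplyr::bind_cols(
        tibble::tibble(sample_id = id, F_M_Lss = fm, F_t_Lss = min(ft, fm),
                       F_P = fp, F_M_D3 = max(fmd3, fm)), cell
      )
    }
  }
  clip_rate <- n_clipped / n_wl
  if (clip_rate > 0.05) {
    stop("Spectral noise clipping rate ", round(100 * clip_rate, 1),
         "% exceeds 5%: noise configuration infeasible.", call. = FALSE)
  }
  structure(
    list(truth = dplyr::bind_rows(truth), spectra = dplyr::bind_rows(spectra),
         assays = dplyr::bind_rows(assays),
         fluorescence = dplyr::bind_rows(fluor),
         design = design, clip_rate = clip_rate),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort>\n")
  cat("  leaves:", nrow(x$truth), " (", x$design$replicates,
      "replicates per cell )\n")
  cat("  spectral clip rate:", signif(x$clip_rate, 3), "\n")
  invisible(x)
}

#' Write a synthetic cohort to a directory of CSV files
#'
#' Emits `truth.csv`, `assays.csv`, `fluorescence.csv`, `library.csv` and
#' one combined-dialect spectrum CSV per leaf under `spectra/`.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @param lib The absorption library used to render the cohort.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, lib = build_synthetic_library()) {
  dir.create(file.path(dir, "spectra"), recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(cohort$truth, file.path(dir, "truth.csv"))
  readr::write_csv(cohort$assays, file.path(dir, "assays.csv"))
  readr::write_csv(cohort$fluorescence, file.path(dir, "fluorescence.csv"))
  write_absorption_library(lib, file.path(dir, "library.csv"))
  for (id in unique(cohort$spectra$sample_id)) {
    one <- cohort$spectra[cohort$spectra$sample_id == id,
                          c("wavelength_nm", "reflectance", "transmittance")]
    readr::write_csv(one, file.path(dir, "spectra", paste0(id, ".csv")))
  }
  invisible(dir)
}
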
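test_that("the synthetic absorption library is deterministic and well formed", {
  l1 <- build_synthetic_library(seed = 4)
  l2 <- build_synthetic_library(seed = 4)
  expect_identical(l1, l2)
  kcols <- c("K_ab", "K_car_V", "K_car_Z", "K_anth", "K_brown", "K_w", "K_m")
  expect_true(all(vapply(l1[kcols], function(v) all(v >= 0), logical(1))))
  expect_true(all(l1$n_refr >= 1))
  # the zeaxanthin-like end-member is red-shifted against violaxanthin-like
  expect_gt(l1$wavelength_nm[which.max(l1$K_car_Z)],
            l1$wavelength_nm[which.max(l1$K_car_V)])
})

test_that("library CSV round-trips", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_absorption_library(test_lib, path)
  back <- read_absorption_library(path)
  expect_equal(back$K_ab, test_lib$K_ab, tolerance = 1e-9)
})

test_that("cell draws honour the design rules and calibrated multipliers", {
  design <- synthetic_design(seed = 2)
  set.seed(21)
  green <- sample_biophysics(design, "CV_g", 160, "B40", 1, n = 50)
  expect_true(all(green$Canth == 0))
  expect_true(all(green$N >= 1))
  expect_true(all(green$Cx >= 0 & green$Cx <= 1))

  # Monte-Carlo mean approaches baseline x multiplier
  set.seed(22)
  draws <- sample_biophysics(design, "CV_r", 160, "B40", 1, n = 1000)
  base <- design$baselines[design$baselines$cultivar == "CV_r", ]
  mult <- design$effects$multiplier[design$effects$parameter == "Cab" &
                                      design$effects$pfd == 160 &
                                      design$effects$spectrum == "B40" &
                                      design$effects$day == 1]
  expect_equal(mean(draws$Cab), base$Cab * mult, tolerance = 0.01)

  # zero scatter gives exactly baseline x multipliers
  exact <- synthetic_design(seed = 2, noise = list(scatter_sdlog = 0))
  one <- sample_biophysics(exact, "CV_r", 160, "B40", 1, n = 2)
  expect_equal(one$Cab, rep(base$Cab * mult, 2))
  expect_equal(one$Ccar[1], one$Ccar[2])
})

test_that("cohorts have factorial cardinality, valid spectra and determinism", {
  c1 <- generate_cohort(synthetic_design(replicates = 3, seed = 11))
  expect_equal(nrow(c1$truth), 2 * 2 * 2 * 3 * 3)
  expect_equal(dplyr::n_distinct(c1$spectra$sample_id), 72)
  expect_equal(nrow(c1$assays), 72 * 3)
  expect_lte(c1$clip_rate, 0.05)
  for (id in unique(c1$spectra$sample_id)[c(1, 30, 72)]) {
    expect_no_error(check_spectrum(c1$spectra[c1$spectra$sample_id == id, ]))
  }
  c2 <- generate_cohort(synthetic_design(replicates = 3, seed = 11))
  expect_identical(c1$truth, c2$truth)
  expect_identical(c1$spectra, c2$spectra)
  expect_identical(c1$assays, c2$assays)
  expect_identical(c1$fluorescence, c2$fluorescence)
  # infeasible noise is refused
  expect_error(
    generate_cohort(synthetic_design(replicates = 1, seed = 1,
                                     noise = list(rt_mult_sd = 0.6))),
    "clipping rate"
  )
})

test_that("simulated assays recover the true contents within assay noise", {
  cohort <- generate_cohort(synthetic_design(replicates = 2, seed = 9))
  wc <- summarize_replicates(assay_contents(cohort$assays))
  j <- dplyr::inner_join(
    wc,
    dplyr::mutate(cohort$truth,
                  chl_true = area_to_mass(Cab, lma_g_cm2),
                  car_true = area_to_mass(Ccar, lma_g_cm2)),
    by = "sample_id"
  )
  expect_lt(max(abs(j$chl_total - j$chl_true) / j$chl_true), 0.05)
  expect_lt(max(abs(j$car_total - j$car_true) / j$car_true), 0.10)
})

test_that("noiseless cohorts are inverted back to the stored ground truth", {
  design <- synthetic_design(
    replicates = 1, seed = 13,
    noise = list(rt_mult_sd = 0, absorbance_sd = 0, fluor_mult_sd = 0)
  )
  cohort <- generate_cohort(design)
  day1 <- dplyr::filter(cohort$truth, day == 1)
  cfg <- inversion_config(seed = 5)
  for (id in day1$sample_id) {
    spec <- cohort$spectra[cohort$spectra$sample_id == id, ]
    fit <- invert_spectrum(spec, test_lib, cfg)
    truth <- day1[day1$sample_id == id, ]
    expect_lt(abs(fit$estimate$Cab - truth$Cab) / truth$Cab, 0.01)
  }
})

test_that("fluorescence summaries rise with day and blue fraction", {
  cohort <- generate_cohort(synthetic_design(replicates = 3, seed = 17))
  idx <- fluorescence_indices(cohort$fluorescence)
  by_day <- idx |>
    dplyr::group_by(day) |>
    dplyr::summarise(rfd = mean(Rfd), qe = mean(qE), .groups = "drop") |>
    dplyr::arrange(day)
  expect_true(all(diff(by_day$rfd) > 0))
  expect_true(all(diff(by_day$qe) > 0))
  by_spec <- idx |>
    dplyr::group_by(spectrum) |>
    dplyr::summarise(rfd = mean(Rfd), .groups = "drop")
  expect_gt(by_spec$rfd[by_spec$spectrum == "B40"],
            by_spec$rfd[by_spec$spectrum == "B15"])
})

test_that("the injected day-1 blue effect is recovered from the generator", {
  design <- synthetic_design(replicates = 3)
  eff <- design$effects
  injected <- eff |>
    dplyr::filter(parameter == "Cab", day == 1) |>
    tidyr::pivot_wider(names_from = spectrum, values_from = multiplier) |>
    dplyr::summarise(pct = mean(100 * (B40 / B15 - 1))) |>
    dplyr::pull(pct)
  diffs <- vapply(1:50, function(s) {
    set.seed(s)
    cells <- tidyr::expand_grid(cultivar = c("CV_g", "CV_r"),
                                pfd = c(160, 240), spectrum = c("B15", "B40"))
    draws <- purrr::pmap_dfr(cells, function(cultivar, pfd, spectrum) {
      dplyr::mutate(
        sample_biophysics(design, cultivar, pfd, spectrum, day = 1, n = 3),
        spectrum = spectrum
      )
    })
    means <- draws |>
      dplyr::group_by(spectrum) |>
      dplyr::summarise(cab = mean(Cab), .groups = "drop")
    100 * (means$cab[means$spectrum == "B40"] /
             means$cab[means$spectrum == "B15"] - 1)
  }, numeric(1))
  expect_lt(abs(mean(diffs) - injected), 3)
})

test_that("end-to-end estimation preserves the day-1 blue effect", {
  design <- synthetic_design(replicates = 3, seed = 29)
  cohort <- generate_cohort(design)
  day1 <- dplyr::filter(cohort$spectra, day == 1)
  est <- invert_batch(day1, test_lib, inversion_config(seed = 3))
  # treatment metadata columns are carried through from the spectra
  expect_true(all(c("cultivar", "pfd", "spectrum", "day") %in% names(est)))
  est <- dplyr::left_join(est, dplyr::select(cohort$truth, sample_id,
                                             Cab_true = Cab),
                          by = "sample_id")
  pct <- function(v, s) {
    m <- tapply(v, s, mean)
    100 * (m[["B40"]] / m[["B15"]] - 1)
  }
  expect_true(all(est$converged))
  expect_lt(abs(pct(est$Cab, est$spectrum) - pct(est$Cab_true, est$spectrum)),
            3)
})

test_that("cohorts write to a directory of plain CSV files", {
  dir <- withr::local_tempdir()
  cohort <- generate_cohort(synthetic_design(replicates = 1, seed = 3))
  write_cohort(cohort, dir)
  expect_true(file.exists(file.path(dir, "truth.csv")))
  expect_equal(length(list.files(file.path(dir, "spectra"))), 24)
  back <- read_spectrum(list.files(file.path(dir, "spectra"),
                                   full.names = TRUE)[1])
  expect_no_error(check_spectrum(back))
})
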
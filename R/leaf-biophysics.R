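#' Leaf biophysical parameter vector
#'
#' Constructs the parameter set the plate-model forward simulation consumes
#' and the spectral inversion estimates: leaf structure plus per-area pigment
#' and matter contents.
#'
#' @param N Leaf structure parameter: the effective number of elementary
#'   absorbing plates (dimensionless, >= 1). Thicker, more mesophyll-layered
#'   leaves have larger N.
#' @param Cab Total chlorophyll a+b content per leaf area (ug cm-2).
#' @param Ccar Total carotenoid content per leaf area (ug cm-2).
#' @param Canth Anthocyanin content per leaf area (ug cm-2).
#' @param Cx Zeaxanthin(+antheraxanthin) fraction of the total xanthophyll
#'   pool, (Z+A)/(Z+A+V), in [0, 1]. Controls the de-epoxidation state of
#'   the xanthophyll cycle via convex mixing of the two carotenoid
#'   absorption end-members.
#' @param Cbrown Brown-pigment content (arbitrary units, >= 0).
#' @param Cw Equivalent water thickness (cm).
#' @param Cm Dry matter per area (g cm-2).
#'
#' @return A named list of class `leaf_biophysics`.
#' @examples
#' p <- leaf_biophysics(N = 1.5, Cab = 40, Ccar = 8, Canth = 2, Cx = 0.2)
#' unlist(p)
#' @export
leaf_biophysics <- function(N = 1.5, Cab = 40, Ccar = Cab / 5.4, Canth = 0,
                            Cx = 0, Cbrown = 0, Cw = 0.01, Cm = 0.004) {
  p <- list(N = N, Cab = Cab, Ccar = Ccar, Canth = Canth, Cx = Cx,
            Cbrown = Cbrown, Cw = Cw, Cm = Cm)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("`", nm, "` must be a single finite number.", call. = FALSE)
    }
  }
  if (p$N < 1) stop("`N` must be >= 1.", call. = FALSE)
  if (p$Cx < 0 || p$Cx > 1) stop("`Cx` must lie in [0, 1].", call. = FALSE)
  neg <- vapply(p[c("Cab", "Ccar", "Canth", "Cbrown", "Cw", "Cm")],
                function(v) v < 0, logical(1))
  if (any(neg)) {
    stop("Contents must be non-negative: ",
         paste(names(neg)[neg], collapse = ", "), call. = FALSE)
  }
  structure(p, class = "leaf_biophysics")
}

#' @export
print.leaf_biophysics <- function(x, ...) {
  cat("<leaf_biophysics>\n")
  v <- unlist(x)
  cat(paste0("  ", format(names(v), width = 7), " ",
             formatC(v, digits = 5, format = "g")), sep = "\n")
  invisible(x)
}

#' Coerce per-leaf parameter rows to a tibble
#'
#' @param x A `leaf_biophysics` or a list of them.
#' @param ... Unused.
#' @return A tibble with one row per parameter set.
#' @export
as_biophysics_tbl <- function(x, ...) {
  if (inherits(x, "leaf_biophysics")) x <- list(x)
  purrr::map_dfr(x, ~ tibble::as_tibble(unclass(.x)))
}

biophysics_names <- c("N", "Cab", "Ccar", "Canth", "Cx", "Cbrown", "Cw", "Cm")

# Row of a data frame -> leaf_biophysics (used by batch simulation)
row_to_biophysics <- function(row) {
  do.call(leaf_biophysics, as.list(row[biophysics_names]))
}
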
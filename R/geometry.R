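#' Multi-leaf collimator geometry
#'
#' Describes the leaf-pair layout of an MLC as the ascending y-coordinates of
#' the pair boundaries at the isocenter plane. Pair `n` spans
#' `boundaries[n]..boundaries[n + 1]`; pairs are indexed from the most
#' negative y boundary upward.
#'
#' @param boundaries Numeric vector of `n_pairs + 1` strictly increasing
#'   y-coordinates (mm at isocenter).
#' @return An object of class `mlc_geometry` with fields `n_pairs`,
#'   `boundaries` and derived `widths`.
#' @examples
#' g <- mlc_geometry(c(-10, -5, 0, 5, 10))
#' g$n_pairs
#' @export
mlc_geometry <- function(boundaries) {
  boundaries <- as.numeric(boundaries)
  if (length(boundaries) < 2L) {
    stopf("mlc_geometry: need at least 2 boundaries")
  }
  if (any(!is.finite(boundaries)) || any(diff(boundaries) <= 0)) {
    stopf("mlc_geometry: boundaries must be finite and strictly increasing")
  }
  structure(
    list(
      n_pairs = length(boundaries) - 1L,
      boundaries = boundaries,
      widths = diff(boundaries)
    ),
    class = "mlc_geometry"
  )
}

#' Varian HD-120-style MLC geometry
#'
#' 60 leaf pairs spanning -110..+110 mm: 14 outer 5 mm pairs, 32 central
#' 2.5 mm pairs, 14 outer 5 mm pairs (widths at the isocenter plane).
#'
#' @return An `mlc_geometry` with 60 pairs.
#' @examples
#' mlc_hd120()$n_pairs  # 60
#' @export
mlc_hd120 <- function() {
  b <- c(
    seq(-110, -40, by = 5),   # 14 outer pairs
    seq(-37.5, 40, by = 2.5), # 32 central pairs
    seq(45, 110, by = 5)      # 14 outer pairs
  )
  mlc_geometry(b)
}

#' Simple uniform-width geometry (testing convenience)
#'
#' @param n_pairs number of leaf pairs
#' @param width_mm leaf width (mm), identical for every pair
#' @param center_mm y-coordinate of the geometry center
#' @return An `mlc_geometry`.
#' @export
mlc_uniform <- function(n_pairs, width_mm = 5, center_mm = 0) {
  half <- n_pairs * width_mm / 2
  mlc_geometry(seq(-half, half, by = width_mm) + center_mm)
}

#' @export
print.mlc_geometry <- function(x, ...) {
  cat(sprintf(
    "<mlc_geometry> %d pairs, y %g..%g mm, widths %s mm\n",
    x$n_pairs, x$boundaries[1], x$boundaries[x$n_pairs + 1L],
    paste(unique(x$widths), collapse = "/")
  ))
  invisible(x)
}

geometry_equal <- function(a, b, tol = 1e-6) {
  a$n_pairs == b$n_pairs && all(abs(a$boundaries - b$boundaries) <= tol)
}
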
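#' Per-control-point aperture geometry
#'
#' Derives every geometric quantity the complexity metrics consume from one
#' control point: which leaf pairs are inside the jaw window and open, the
#' jaw-clipped gaps, aperture and jaw areas, the exposed leaf-side perimeter,
#' the full aperture perimeter, per-bank position spreads and per-pair
#' aperture midpoints.
#'
#' A pair is *in field* when its y-span overlaps the jaw y-window with
#' positive measure and its opening overlaps the jaw x-window; it is *open*
#' when additionally its jaw-clipped gap exceeds `open_gap_tol` (default
#' 0.5 mm, the dosimetrically-closed tolerance of an HD-style MLC). All
#' positions entering perimeters, spreads and midpoints are clipped to the
#' jaws, so `area <= jaw_area` and `0 <= aaja <= 1` always hold.
#'
#' `side_perimeter` is the exposed MLC leaf-side edge length: for each pair
#' boundary strictly inside the jaw y-window, adjacent open pairs contribute
#' `|left_n - left_{n+1}| + |right_n - right_{n+1}|` (clipped positions) and
#' an open pair abutting a closed pair contributes its full clipped gap.
#' Boundaries lying on or outside the jaw edges are shielded by the jaws and
#' contribute nothing. `full_perimeter` is the total boundary length of the
#' jaw-clipped open region (leaf sides + leaf tip faces + jaw caps).
#'
#' @param cp a [control_point()].
#' @param geom the beam's [mlc_geometry()].
#' @param open_gap_tol gap (mm) at or below which a pair counts as closed.
#' @return A list of class `aperture_state`; see Details for fields.
#' @export
aperture_state <- function(cp, geom, open_gap_tol = 0.5) {
  b <- geom$boundaries
  np <- geom$n_pairs
  x1 <- cp$jaw_x[1]; x2 <- cp$jaw_x[2]
  y1 <- cp$jaw_y[1]; y2 <- cp$jaw_y[2]

  lo <- pmax(b[seq_len(np)], y1)
  hi <- pmin(b[seq_len(np) + 1L], y2)
  width_clip <- pmax(0, hi - lo)

  lc <- pmin(pmax(cp$left, x1), x2)
  rc <- pmin(pmax(cp$right, x1), x2)
  gap <- pmax(0, rc - lc)

  in_field <- width_clip > 0 & gap > 0
  open <- in_field & gap > open_gap_tol

  area <- sum(gap[open] * width_clip[open])
  jaw_area <- (x2 - x1) * (y2 - y1)

  # leaf-side edges at pair boundaries strictly inside the jaw y-window
  side <- 0
  full_side <- 0 # geometric horizontal boundary at interior pair boundaries
  for (n in seq_len(np + 1L)) {
    yb <- b[n]
    if (yb <= y1 || yb >= y2) next
    below <- if (n > 1L) n - 1L else 0L
    above <- if (n <= np) n else 0L
    open_below <- below > 0L && open[below]
    open_above <- above > 0L && open[above]
    if (open_below && open_above) {
      side <- side + abs(lc[below] - lc[above]) + abs(rc[below] - rc[above])
      ov <- max(0, min(rc[below], rc[above]) - max(lc[below], lc[above]))
      full_side <- full_side + gap[below] + gap[above] - 2 * ov
    } else if (open_below) {
      side <- side + gap[below]
      full_side <- full_side + gap[below]
    } else if (open_above) {
      side <- side + gap[above]
      full_side <- full_side + gap[above]
    }
  }

  # caps where the jaw lines cut the open region
  cap <- 0
  for (yj in c(y1, y2)) {
    p <- findInterval(yj, b, rightmost.closed = FALSE, all.inside = FALSE)
    if (yj == y2) p <- findInterval(yj - 1e-12, b)
    if (p >= 1L && p <= np && open[p]) cap <- cap + gap[p]
  }
  end_perimeter <- 2 * sum(width_clip[open])
  full_perimeter <- full_side + cap + end_perimeter

  n_open <- sum(open)
  spread_left <- if (n_open > 0) max(lc[open]) - min(lc[open]) else 0
  spread_right <- if (n_open > 0) max(rc[open]) - min(rc[open]) else 0
  midpoint_x <- (lc[open] + rc[open]) / 2

  structure(
    list(
      in_field = in_field, open = open, gap = gap,
      left_clip = lc, right_clip = rc, width_clip = width_clip,
      area = area, jaw_area = jaw_area, aaja = area / jaw_area,
      side_perimeter = side, end_perimeter = end_perimeter,
      full_perimeter = full_perimeter,
      spread_left = spread_left, spread_right = spread_right,
      midpoint_x = midpoint_x, n_open = n_open
    ),
    class = "aperture_state"
  )
}

beam_aperture_states <- function(beam, open_gap_tol = 0.5) {
  lapply(beam$cps, aperture_state, geom = beam$geometry, open_gap_tol = open_gap_tol)
}

raster_axes <- function(bbox, pixel_mm) {
  # pixel centers covering [bbox] with spacing pixel_mm
  nx <- max(1L, ceiling((bbox[2] - bbox[1]) / pixel_mm - 1e-9))
  ny <- max(1L, ceiling((bbox[4] - bbox[3]) / pixel_mm - 1e-9))
  list(
    x = bbox[1] + (seq_len(nx) - 0.5) * pixel_mm,
    y = bbox[3] + (seq_len(ny) - 0.5) * pixel_mm
  )
}

beam_bbox <- function(beam) {
  jx <- range(unlist(lapply(beam$cps, function(cp) cp$jaw_x)))
  jy <- range(unlist(lapply(beam$cps, function(cp) cp$jaw_y)))
  c(jx[1], jx[2], jy[1], jy[2])
}

#' Rasterize one control point's aperture
#'
#' Binary mask over a pixel grid covering the jaw rectangle (or an explicit
#' bounding box); a pixel is open when its center lies inside the jaw-clipped
#' aperture.
#'
#' @param cp a [control_point()].
#' @param geom the [mlc_geometry()].
#' @param pixel_mm pixel spacing (> 0).
#' @param bbox optional `c(x_min, x_max, y_min, y_max)` grid extent; defaults
#'   to the control point's jaw rectangle.
#' @param open_gap_tol closed-pair tolerance (mm).
#' @return A list with `mask` (logical matrix, rows = y), `x`, `y` pixel
#'   center coordinates and `pixel_mm`.
#' @export
rasterize_aperture <- function(cp, geom, pixel_mm, bbox = NULL, open_gap_tol = 0.5) {
  if (!is.numeric(pixel_mm) || pixel_mm <= 0) stopf("invalid resolution: pixel_mm must be > 0")
  st <- aperture_state(cp, geom, open_gap_tol)
  if (is.null(bbox)) bbox <- c(cp$jaw_x[1], cp$jaw_x[2], cp$jaw_y[1], cp$jaw_y[2])
  ax <- raster_axes(bbox, pixel_mm)
  mask <- aperture_mask(st, cp, geom, ax)
  list(mask = mask, x = ax$x, y = ax$y, pixel_mm = pixel_mm)
}

aperture_mask <- function(st, cp, geom, ax) {
  pair <- findInterval(ax$y, geom$boundaries)
  pair[pair < 1L | pair > geom$n_pairs] <- NA_integer_
  inside_y <- !is.na(pair) & ax$y > cp$jaw_y[1] & ax$y < cp$jaw_y[2]
  lrow <- rep(Inf, length(ax$y))
  rrow <- rep(-Inf, length(ax$y))
  ok <- inside_y & st$open[ifelse(is.na(pair), 1L, pair)]
  lrow[ok] <- st$left_clip[pair[ok]]
  rrow[ok] <- st$right_clip[pair[ok]]
  # mask[iy, ix]
  outer(lrow, ax$x, `<=`) & outer(rrow, ax$x, `>=`)
}

#' Geometric union area of a beam's apertures
#'
#' Rasterizes every control point on a shared grid covering the beam's jaw
#' extent and counts pixels open in at least one control point.
#'
#' @param beam a [beam_record()].
#' @param pixel_mm pixel spacing (default 0.5 mm).
#' @param open_gap_tol closed-pair tolerance (mm).
#' @param states optional precomputed [aperture_state()] list.
#' @return Union area in mm^2.
#' @export
union_area <- function(beam, pixel_mm = 0.5, open_gap_tol = 0.5, states = NULL) {
  if (!is.numeric(pixel_mm) || pixel_mm <= 0) stopf("invalid resolution: pixel_mm must be > 0")
  bbox <- beam_bbox(beam)
  ax <- raster_axes(bbox, pixel_mm)
  acc <- matrix(FALSE, length(ax$y), length(ax$x))
  states <- states %||% beam_aperture_states(beam, open_gap_tol)
  for (k in seq_along(beam$cps)) {
    acc <- acc | aperture_mask(states[[k]], beam$cps[[k]], beam$geometry, ax)
  }
  sum(acc) * pixel_mm^2
}

#' Unweighted sum of per-control-point aperture areas
#'
#' @param beam a [beam_record()].
#' @param open_gap_tol closed-pair tolerance (mm).
#' @return Sum of analytic aperture areas over control points, mm^2.
#' @export
area_sum <- function(beam, open_gap_tol = 0.5) {
  sum(vapply(
    beam_aperture_states(beam, open_gap_tol),
    function(s) s$area, numeric(1)
  ))
}

#' Leaf travel bookkeeping for a beam
#'
#' Active leaves are both bank leaves of every pair that is open at one or
#' more control points. Travel uses the raw (unclipped) leaf positions.
#'
#' @param beam a [beam_record()].
#' @param open_gap_tol closed-pair tolerance (mm).
#' @param states optional precomputed [aperture_state()] list.
#' @return A list with `per_leaf` (named vector, total |travel| in mm per
#'   active leaf) and `per_transition` (mean |travel| over active leaves for
#'   each of the `N_cp - 1` transitions).
#' @export
leaf_travel_table <- function(beam, open_gap_tol = 0.5, states = NULL) {
  states <- states %||% beam_aperture_states(beam, open_gap_tol)
  ever_open <- Reduce(`|`, lapply(states, function(s) s$open))
  if (!any(ever_open)) stopf("empty beam: no pair is ever open")
  act <- which(ever_open)
  left <- vapply(beam$cps, function(cp) cp$left[act], numeric(length(act)))
  right <- vapply(beam$cps, function(cp) cp$right[act], numeric(length(act)))
  left <- matrix(left, nrow = length(act))
  right <- matrix(right, nrow = length(act))
  dl <- abs(left[, -1L, drop = FALSE] - left[, -ncol(left), drop = FALSE])
  dr <- abs(right[, -1L, drop = FALSE] - right[, -ncol(right), drop = FALSE])
  per_leaf <- c(rowSums(dl), rowSums(dr))
  names(per_leaf) <- c(paste0("L", act - 1L), paste0("R", act - 1L))
  per_transition <- (colSums(dl) + colSums(dr)) / (2 * length(act))
  list(per_leaf = per_leaf, per_transition = per_transition)
}

#' Accumulated fluence map of a beam
#'
#' Sums each control point's binary aperture mask weighted by its meterset
#' share ([cp_mu_weights()]); units are MU per pixel.
#'
#' @param beam a [beam_record()].
#' @param pixel_mm bixel spacing (default 1 mm).
#' @param open_gap_tol closed-pair tolerance (mm).
#' @param states optional precomputed [aperture_state()] list.
#' @return A list of class `fluence_map` with `values` (matrix, rows = y),
#'   `x`, `y`, `pixel_mm`, `origin`.
#' @export
fluence_map <- function(beam, pixel_mm = 1, open_gap_tol = 0.5, states = NULL) {
  if (!is.numeric(pixel_mm) || pixel_mm <= 0) stopf("invalid resolution: pixel_mm must be > 0")
  bbox <- beam_bbox(beam)
  ax <- raster_axes(bbox, pixel_mm)
  w <- cp_mu_weights(beam)
  vals <- matrix(0, length(ax$y), length(ax$x))
  states <- states %||% beam_aperture_states(beam, open_gap_tol)
  for (k in seq_along(beam$cps)) {
    if (w[k] == 0) next
    vals <- vals + w[k] * aperture_mask(states[[k]], beam$cps[[k]], beam$geometry, ax)
  }
  structure(
    list(
      values = vals, x = ax$x, y = ax$y, pixel_mm = pixel_mm,
      origin = c(ax$x[1], ax$y[1])
    ),
    class = "fluence_map"
  )
}

# Exact area of the Chebyshev erosion of a control point's jaw-clipped
# aperture by radius `band`. Exploits the row structure of an MLC aperture:
# a point is in the eroded region iff its (2*band) window in y stays inside
# the jaws and meets only open pairs, and its x lies in the shrunk
# intersection of those pairs' intervals.
eroded_area <- function(st, cp, geom, band) {
  if (band <= 0) {
    return(st$area)
  }
  y1 <- cp$jaw_y[1]; y2 <- cp$jaw_y[2]
  if (y2 - y1 <= 2 * band) {
    return(0)
  }
  b <- geom$boundaries
  np <- geom$n_pairs
  lo <- pmax(b[seq_len(np)], y1)
  hi <- pmin(b[seq_len(np) + 1L], y2)
  keep <- st$width_clip > 0
  brk <- sort(unique(c(
    y1 + band, y2 - band,
    pmax(lo[keep] - band, y1 + band), pmin(lo[keep] + band, y2 - band),
    pmax(hi[keep] - band, y1 + band), pmin(hi[keep] + band, y2 - band)
  )))
  brk <- brk[brk >= y1 + band - 1e-12 & brk <= y2 - band + 1e-12]
  if (length(brk) < 2L) {
    return(0)
  }
  total <- 0
  for (i in seq_len(length(brk) - 1L)) {
    ym <- (brk[i] + brk[i + 1L]) / 2
    wlo <- ym - band
    whi <- ym + band
    touch <- which(keep & hi > wlo + 1e-12 & lo < whi - 1e-12)
    if (length(touch) == 0L || any(!st$open[touch])) next
    xlen <- max(0, min(st$right_clip[touch]) - max(st$left_clip[touch]) - 2 * band)
    total <- total + xlen * (brk[i + 1L] - brk[i])
  }
  total
}
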
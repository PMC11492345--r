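#' Configuration of the complexity-metric constants
#'
#' All tunables of the 27-metric vector with their defaults. Units are mm
#' unless stated otherwise.
#'
#' @param lt_max clamp (mm) on per-transition mean leaf travel inside LAAM
#'   (default 30 mm).
#' @param lt_norm normalization (mm) of total mean leaf travel inside LTMCS
#'   (default 1000 mm).
#' @param sas_thresholds small-aperture gap thresholds (mm), ascending.
#' @param eam_band edge band width (mm) of the edge area metric.
#' @param mi_bixel fluence bixel size (mm) for the modulation index.
#' @param mi_F upper integration limit (in units of the fluence SD).
#' @param mi_df integration step for the modulation index.
#' @param em_c1,em_c2 weights of the leaf-end and leaf-side perimeter
#'   components of the edge metric.
#' @param jaw_move_tol jaw movement (mm) above which a transition counts as
#'   jaw tracking.
#' @param union_mode `"geometric"` (raster union of apertures) or
#'   `"summed"` (sum of per-control-point areas) for the UnionArea metric.
#' @param raster_px pixel size (mm) of the union raster.
#' @param open_gap_tol gap (mm) at or below which a leaf pair is closed.
#' @return A list of class `metric_config`.
#' @export
metric_config <- function(lt_max = 30, lt_norm = 1000,
                          sas_thresholds = c(2, 5, 10, 20),
                          eam_band = 2, mi_bixel = 1, mi_F = 1, mi_df = 0.01,
                          em_c1 = 0, em_c2 = 1, jaw_move_tol = 0.1,
                          union_mode = c("geometric", "summed"),
                          raster_px = 0.5, open_gap_tol = 0.5) {
  union_mode <- match.arg(union_mode)
  stopifnot(
    lt_max > 0, lt_norm > 0, all(sas_thresholds > 0),
    !is.unsorted(sas_thresholds), eam_band >= 0, mi_bixel > 0,
    mi_df > 0, raster_px > 0
  )
  structure(
    list(
      lt_max = lt_max, lt_norm = lt_norm, sas_thresholds = sas_thresholds,
      eam_band = eam_band, mi_bixel = mi_bixel, mi_F = mi_F, mi_df = mi_df,
      em_c1 = em_c1, em_c2 = em_c2, jaw_move_tol = jaw_move_tol,
      union_mode = union_mode, raster_px = raster_px,
      open_gap_tol = open_gap_tol
    ),
    class = "metric_config"
  )
}

states_or <- function(beam, cfg, states) {
  states %||% beam_aperture_states(beam, cfg$open_gap_tol)
}

# normalized per-CP meterset shares; computed from the cumulative weights so
# results are bitwise invariant under MU rescaling
norm_weights <- function(beam) {
  dw <- diff(cum_weights(beam))
  w <- (c(dw, 0) + c(0, dw)) / 2
  w / sum(w)
}

# normalized per-transition meterset shares
transition_weights <- function(beam) {
  dw <- diff(cum_weights(beam))
  dw / sum(dw)
}

require_open <- function(states) {
  if (!any(vapply(states, function(s) s$n_open > 0L, logical(1)))) {
    stopf("empty beam: no open leaf pair at any control point")
  }
}

#' Meterset bookkeeping metrics
#'
#' @param plan the owning [plan_record()] (PMU is plan-level and copied onto
#'   every beam of the plan).
#' @param beam a [beam_record()].
#' @return Named vector `TotalMU`, `PMU` (plan MU normalized to a 2 Gy
#'   fraction), `NumSegments` (control point count).
#' @export
mu_metrics <- function(plan, beam) {
  if (!is.finite(plan$fraction_dose_gy) || plan$fraction_dose_gy <= 0) {
    stopf("invalid prescription: fraction_dose_gy must be > 0")
  }
  plan_mu <- sum(vapply(plan$beams, function(b) b$total_mu, numeric(1)))
  c(
    TotalMU = beam$total_mu,
    PMU = plan_mu * 2 / plan$fraction_dose_gy,
    NumSegments = length(beam$cps)
  )
}

#' Leaf-gap metrics: average gap and small aperture scores
#'
#' `AvgLeafGap` is the unweighted mean of the jaw-clipped gaps of all open
#' in-field pairs across all control points. `SASx` is the MU-weighted
#' fraction of open pairs with gap strictly below `x` mm (control points with
#' no open pair are skipped and the weights renormalized).
#'
#' @param beam a [beam_record()].
#' @param cfg a [metric_config()].
#' @param states optional precomputed [aperture_state()] list.
#' @return Named vector `AvgLeafGap`, `SAS2`, `SAS5`, `SAS10`, `SAS20`.
#' @export
gap_metrics <- function(beam, cfg = metric_config(), states = NULL) {
  states <- states_or(beam, cfg, states)
  require_open(states)
  w <- norm_weights(beam)
  gaps <- unlist(lapply(states, function(s) s$gap[s$open]))
  open_cp <- vapply(states, function(s) s$n_open > 0L, logical(1))
  wsum <- sum(w[open_cp])
  sas <- vapply(cfg$sas_thresholds, function(th) {
    frac <- vapply(states, function(s) {
      if (s$n_open == 0L) {
        return(0)
      }
      mean(s$gap[s$open] < th)
    }, numeric(1))
    sum(w[open_cp] * frac[open_cp]) / wsum
  }, numeric(1))
  c(
    AvgLeafGap = mean(gaps),
    setNames(sas, paste0("SAS", cfg$sas_thresholds))
  )
}

#' Jaw metrics: aperture/jaw area ratio, jaw opening, jaw tracking
#'
#' @inheritParams gap_metrics
#' @return Named vector `AAJA` (MU-weighted mean of per-control-point
#'   aperture area over jaw area), `MAXJ` (largest jaw opening, mm),
#'   `JawTrackingPct` (fraction of transitions in which any jaw coordinate
#'   moves by more than `jaw_move_tol`).
#' @export
jaw_metrics <- function(beam, cfg = metric_config(), states = NULL) {
  states <- states_or(beam, cfg, states)
  w <- norm_weights(beam)
  aaja <- sum(w * vapply(states, function(s) s$aaja, numeric(1)))
  jaws <- t(vapply(
    beam$cps,
    function(cp) c(cp$jaw_x, cp$jaw_y), numeric(4)
  ))
  maxj <- max(jaws[, 2] - jaws[, 1], jaws[, 4] - jaws[, 3])
  moved <- abs(diff(jaws)) > cfg$jaw_move_tol
  c(
    AAJA = aaja, MAXJ = maxj,
    JawTrackingPct = mean(apply(moved, 1L, any))
  )
}

lsv_cp <- function(st) {
  o <- which(st$open)
  if (length(o) < 2L) {
    return(1)
  }
  factor_bank <- function(pos) {
    pos_max <- max(pos) - min(pos)
    if (pos_max <= 0) {
      return(1)
    }
    sum(pos_max - abs(diff(pos))) / ((length(pos) - 1L) * pos_max)
  }
  factor_bank(st$left_clip[o]) * factor_bank(st$right_clip[o])
}

#' Modulation complexity score family
#'
#' Per control point, `LSV` is the product over both banks of the mean
#' normalized positional agreement of adjacent open in-field leaves (bank
#' spread as normalizer; degenerate banks score 1), and `AAV` is the
#' aperture opening summed over pairs relative to the per-pair maximum
#' opening of the beam. Beam-level `LSV`/`AAV` are MU-weighted means;
#' `MCS` is the MU-weighted mean of the per-control-point product, and
#' `MCSv` averages the factors over control-point transitions weighted by
#' transition MU.
#'
#' @inheritParams gap_metrics
#' @return Named vector `LSV`, `AAV`, `MCS`, `MCSv`, all in `[0, 1]`.
#' @export
mcs_family <- function(beam, cfg = metric_config(), states = NULL) {
  states <- states_or(beam, cfg, states)
  require_open(states)
  w <- norm_weights(beam)
  lsv_k <- vapply(states, lsv_cp, numeric(1))

  open_gap <- vapply(states, function(s) ifelse(s$open, s$gap, 0),
    numeric(beam$geometry$n_pairs)
  )
  open_gap <- matrix(open_gap, nrow = beam$geometry$n_pairs)
  max_gap <- apply(open_gap, 1L, max)
  denom <- sum(max_gap)
  aav_k <- if (denom > 0) colSums(open_gap) / denom else rep(0, length(states))

  wt <- transition_weights(beam)
  n <- length(states)
  mcsv <- sum(wt * (lsv_k[-n] + lsv_k[-1]) / 2 * (aav_k[-n] + aav_k[-1]) / 2)
  c(
    LSV = sum(w * lsv_k), AAV = sum(w * aav_k),
    MCS = sum(w * lsv_k * aav_k), MCSv = mcsv
  )
}

#' Leaf travel metrics
#'
#' `LT` is the mean total travel (mm) over active leaves; `LTMCS` combines
#' it with `MCSv` as `(1 - min(LT, lt_norm) / lt_norm) * MCSv`.
#'
#' @inheritParams gap_metrics
#' @return Named vector `LT`, `LTMCS`.
#' @export
travel_metrics <- function(beam, cfg = metric_config(), states = NULL,
                           .mcsv = NULL) {
  states <- states_or(beam, cfg, states)
  lt <- mean(leaf_travel_table(beam, cfg$open_gap_tol, states)$per_leaf)
  mcsv <- .mcsv %||% mcs_family(beam, cfg, states)[["MCSv"]]
  c(LT = lt, LTMCS = (1 - min(lt, cfg$lt_norm) / cfg$lt_norm) * mcsv)
}

#' Aperture shape metrics: area, irregularity, modulation, union area
#'
#' `BA` is the MU-weighted mean aperture area in cm^2; `BI` the MU-weighted
#' aperture irregularity `perimeter^2 / (4 pi area)` (1 for a disc, 4/pi for
#' a square); `UnionArea` the union footprint of all apertures (mm^2,
#' geometric raster union by default, or the summed per-control-point areas
#' under `union_mode = "summed"`); `BM` the beam modulation
#' `1 - weighted_area / UnionArea`.
#'
#' @inheritParams gap_metrics
#' @return Named vector `BA`, `BI`, `BM`, `UnionArea`.
#' @export
du_metrics <- function(beam, cfg = metric_config(), states = NULL) {
  states <- states_or(beam, cfg, states)
  require_open(states)
  w <- norm_weights(beam)
  areas <- vapply(states, function(s) s$area, numeric(1))
  wa <- sum(w * areas)
  pos <- areas > 0
  bi <- sum(w[pos] * vapply(
    states[pos],
    function(s) s$full_perimeter^2 / (4 * pi * s$area), numeric(1)
  ))
  ua <- if (cfg$union_mode == "summed") {
    sum(areas)
  } else {
    union_area(beam, cfg$raster_px, cfg$open_gap_tol, states)
  }
  bm <- if (ua > 0) min(1, max(0, 1 - wa / ua)) else 0
  c(BA = wa / 100, BI = bi, BM = bm, UnionArea = ua)
}

#' Edge metrics
#'
#' `EM` is the MU-weighted exposed-edge length per aperture area
#' (`(c2 * side + c1 * end) / area`, 1/mm); `EAM` the MU-weighted percentage
#' of aperture area lying within `eam_band` mm (Chebyshev distance) of the
#' aperture boundary, computed by exact erosion of the jaw-clipped aperture.
#'
#' @inheritParams gap_metrics
#' @return Named vector `EM` (1/mm), `EAM` (percent).
#' @export
edge_metrics <- function(beam, cfg = metric_config(), states = NULL) {
  states <- states_or(beam, cfg, states)
  require_open(states)
  w <- norm_weights(beam)
  em <- 0
  eam <- 0
  for (k in seq_along(states)) {
    s <- states[[k]]
    if (s$area <= 0) next
    em <- em + w[k] * (cfg$em_c2 * s$side_perimeter + cfg$em_c1 * s$end_perimeter) / s$area
    er <- eroded_area(s, beam$cps[[k]], beam$geometry, cfg$eam_band)
    eam <- eam + w[k] * 100 * (s$area - er) / s$area
  }
  c(EM = em, EAM = eam)
}

#' Mean asymmetry distance
#'
#' MU-weighted mean over open pairs of the absolute aperture midpoint
#' x-offset from the isocenter axis.
#'
#' @inheritParams gap_metrics
#' @return `MAD` in mm.
#' @export
asymmetry_metric <- function(beam, cfg = metric_config(), states = NULL) {
  states <- states_or(beam, cfg, states)
  require_open(states)
  w <- norm_weights(beam)
  mad_k <- vapply(states, function(s) {
    if (s$n_open == 0L) {
      return(0)
    }
    mean(abs(s$midpoint_x))
  }, numeric(1))
  c(MAD = sum(w * mad_k))
}

#' Fluence modulation index
#'
#' Accumulates the MU fluence map, takes the standard deviation `sigma` of
#' the bixel values inside the union footprint, and integrates (trapezoid,
#' step `mi_df`) the fraction of adjacent same-row bixel pairs whose
#' absolute fluence difference exceeds `f * sigma` for `f` in `[0, mi_F]`.
#' A uniform fluence (or footprint smaller than 2 bixels) scores 0.
#'
#' @inheritParams gap_metrics
#' @return `M`, unitless.
#' @export
modulation_index <- function(beam, cfg = metric_config(), states = NULL) {
  fm <- fluence_map(beam, cfg$mi_bixel, cfg$open_gap_tol, states)
  v <- fm$values
  fp <- v > 0
  if (sum(fp) < 2L) {
    return(c(M = 0))
  }
  sigma <- sd(v[fp])
  if (!is.finite(sigma) || sigma == 0) {
    return(c(M = 0))
  }
  both <- fp[, -ncol(fp), drop = FALSE] & fp[, -1L, drop = FALSE]
  if (!any(both)) {
    return(c(M = 0))
  }
  dif <- abs(v[, -1L, drop = FALSE] - v[, -ncol(v), drop = FALSE])[both]
  fs <- seq(0, cfg$mi_F, by = cfg$mi_df)
  z <- vapply(fs, function(f) mean(dif > f * sigma), numeric(1))
  c(M = sum((z[-1] + z[-length(z)]) / 2) * cfg$mi_df)
}

#' Aperture perimeter variability
#'
#' Per control point, `APV = 1 - side_perimeter / ((n_open - 1) *
#' (spread_left + spread_right))`; degenerate states (at most one open pair,
#' or both bank spreads zero) score 1. Aligned leaf banks give APV 1 and
#' maximally staggered banks approach 0. Values are clamped to `[0, 1]`
#' (exact for contiguous apertures by the side-perimeter bound). The beam
#' value is the MU-weighted mean.
#'
#' @inheritParams gap_metrics
#' @return `APV` in `[0, 1]`.
#' @export
apv_metric <- function(beam, cfg = metric_config(), states = NULL) {
  states <- states_or(beam, cfg, states)
  require_open(states)
  w <- norm_weights(beam)
  c(APV = sum(w * vapply(states, apv_cp, numeric(1))))
}

apv_cp <- function(st) {
  denom <- (st$n_open - 1L) * (st$spread_left + st$spread_right)
  if (st$n_open <= 1L || denom <= 0) {
    return(1)
  }
  min(1, max(0, 1 - st$side_perimeter / denom))
}

#' LAAM: MU-weighted leaf-travel / aperture-area / perimeter-variability score
#'
#' The proposed composite deliverability score. For each control-point
#' transition `k -> k+1`:
#' `(1 - min(LT_k, lt_max) / lt_max) * (AAJA_k + AAJA_{k+1}) / 2 *
#'  (APV_k + APV_{k+1}) / 2`,
#' where `LT_k` is the mean leaf travel of the transition over the beam's
#' active leaves; the terms are weighted by the transition's share of the
#' beam meterset and summed. A static field scores exactly 1; heavy
#' modulation drives the score toward 0.
#'
#' @inheritParams gap_metrics
#' @return `LAAM` in `[0, 1]`.
#' @export
laam_metric <- function(beam, cfg = metric_config(), states = NULL) {
  states <- states_or(beam, cfg, states)
  require_open(states)
  tt <- leaf_travel_table(beam, cfg$open_gap_tol, states)$per_transition
  aaja_k <- vapply(states, function(s) s$aaja, numeric(1))
  apv_k <- vapply(states, apv_cp, numeric(1))
  wt <- transition_weights(beam)
  n <- length(states)
  lt_factor <- 1 - pmin(tt, cfg$lt_max) / cfg$lt_max
  c(LAAM = sum(
    wt * lt_factor *
      (aaja_k[-n] + aaja_k[-1]) / 2 * (apv_k[-n] + apv_k[-1]) / 2
  ))
}

#' Compute the full 27-metric complexity vector of one beam
#'
#' @param plan the owning [plan_record()].
#' @param beam a [beam_record()] of that plan.
#' @param cfg a [metric_config()].
#' @return Named numeric vector of the 27 metrics in [metric_names()] order.
#' @examples
#' b <- toy_beam_T1()
#' p <- plan_record("P1", list(b), fraction_dose_gy = 10)
#' round(compute_all(p, b)[c("MCS", "MCSv", "APV", "LAAM")], 5)
#' @export
compute_all <- function(plan, beam, cfg = metric_config()) {
  states <- beam_aperture_states(beam, cfg$open_gap_tol)
  mcs <- mcs_family(beam, cfg, states)
  out <- c(
    mu_metrics(plan, beam),
    gap_metrics(beam, cfg, states),
    jaw_metrics(beam, cfg, states),
    modulation_index(beam, cfg, states),
    mcs,
    travel_metrics(beam, cfg, states, .mcsv = mcs[["MCSv"]]),
    du_metrics(beam, cfg, states),
    edge_metrics(beam, cfg, states),
    asymmetry_metric(beam, cfg, states),
    apv_metric(beam, cfg, states),
    laam_metric(beam, cfg, states)
  )
  # SAS columns are named after the configured thresholds
  out[metric_names()]
}

#' Compute complexity vectors for every beam of one or more plans
#'
#' @param plans a [plan_record()] or list of them.
#' @param cfg a [metric_config()].
#' @return data.frame with `plan_id`, `beam_id` and the 27 metric columns.
#' @export
compute_plan_metrics <- function(plans, cfg = metric_config()) {
  if (inherits(plans, "plan_record")) plans <- list(plans)
  rows <- list()
  for (plan in plans) {
    for (beam in plan$beams) {
      v <- compute_all(plan, beam, cfg)
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(
          plan_id = plan$plan_id, beam_id = beam$beam_id,
          stringsAsFactors = FALSE
        ),
        as.data.frame(as.list(v))
      )
    }
  }
  do.call(rbind, rows)
}
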
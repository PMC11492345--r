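#' Control point of a VMAT beam
#'
#' One sampled machine state: MLC bank positions, jaw positions, gantry angle
#' and the cumulative meterset weight. All positions are mm at the isocenter
#' plane in the IEC beam-limiting-device frame; bank `left` closes from -x,
#' bank `right` from +x, so `right >= left` pairwise. Opposing positions that
#' overlap by at most 0.01 mm are clamped to their midpoint; larger overlaps
#' are kept and flagged by [validate_plan()].
#'
#' @param index 0-based control point index.
#' @param cum_weight cumulative meterset weight in `[0, 1]`.
#' @param left,right numeric vectors of `n_pairs` leaf positions (mm).
#' @param jaw_x,jaw_y length-2 numeric `(x1, x2)` / `(y1, y2)` jaw positions (mm).
#' @param gantry_deg gantry angle (degrees).
#' @return A `control_point` object.
#' @export
control_point <- function(index, cum_weight, left, right, jaw_x, jaw_y,
                          gantry_deg = 0) {
  left <- as.numeric(left)
  right <- as.numeric(right)
  if (length(left) != length(right)) {
    stopf("control_point: left/right banks must have equal length")
  }
  overlap <- right < left & right >= left - 0.01
  if (any(overlap)) {
    mid <- (left[overlap] + right[overlap]) / 2
    left[overlap] <- mid
    right[overlap] <- mid
  }
  structure(
    list(
      index = as.integer(index),
      cum_weight = as.numeric(cum_weight),
      left = left,
      right = right,
      jaw_x = as.numeric(jaw_x),
      jaw_y = as.numeric(jaw_y),
      gantry_deg = as.numeric(gantry_deg)
    ),
    class = "control_point"
  )
}

#' A treatment beam as an ordered control-point sequence
#'
#' @param beam_id beam identifier (string).
#' @param total_mu beam meterset in monitor units (> 0).
#' @param cps list of [control_point()] objects, ordered by cumulative weight.
#' @param geometry the [mlc_geometry()] shared by every control point.
#' @param energy_label e.g. `"6X-FFF"`.
#' @param site_label optional treatment-site label.
#' @return A `beam_record` object.
#' @export
beam_record <- function(beam_id, total_mu, cps, geometry,
                        energy_label = "6X-FFF", site_label = NA_character_) {
  stopifnot(inherits(geometry, "mlc_geometry"), is.list(cps))
  structure(
    list(
      beam_id = as.character(beam_id),
      total_mu = as.numeric(total_mu),
      cps = cps,
      geometry = geometry,
      energy_label = as.character(energy_label),
      site_label = as.character(site_label)
    ),
    class = "beam_record"
  )
}

#' A treatment plan (one or more beams plus prescription bookkeeping)
#'
#' @param plan_id plan identifier.
#' @param beams list of [beam_record()] objects.
#' @param fraction_dose_gy prescribed dose per fraction (Gy, > 0); used to
#'   normalize plan MU to a 2 Gy fraction (PMU).
#' @param n_fractions number of planned fractions.
#' @return A `plan_record` object.
#' @export
plan_record <- function(plan_id, beams, fraction_dose_gy, n_fractions = 1L) {
  structure(
    list(
      plan_id = as.character(plan_id),
      beams = beams,
      fraction_dose_gy = as.numeric(fraction_dose_gy),
      n_fractions = as.integer(n_fractions)
    ),
    class = "plan_record"
  )
}

#' @export
print.beam_record <- function(x, ...) {
  cat(sprintf(
    "<beam_record> %s: %d control points, %.1f MU, %d leaf pairs\n",
    x$beam_id, length(x$cps), x$total_mu, x$geometry$n_pairs
  ))
  invisible(x)
}

#' @export
print.plan_record <- function(x, ...) {
  cat(sprintf(
    "<plan_record> %s: %d beam(s), %.3g Gy x %d fractions\n",
    x$plan_id, length(x$beams), x$fraction_dose_gy, x$n_fractions
  ))
  invisible(x)
}

#' A measured patient-specific QA outcome for one beam
#'
#' @param plan_id,beam_id identifiers joining the record to a plan/beam.
#' @param gpr_percent gamma passing rate in percent, `[0, 100]`.
#' @param criterion_label the gamma criterion, e.g. `"2%/2mm, 5% threshold, global"`.
#' @param site_label optional treatment-site label.
#' @return A one-row `data.frame` with the record fields.
#' @export
qa_record <- function(plan_id, beam_id, gpr_percent,
                      criterion_label = "2%/2mm, 5% threshold, global",
                      site_label = NA_character_) {
  gpr_percent <- as.numeric(gpr_percent)
  if (is.na(gpr_percent) || gpr_percent < 0 || gpr_percent > 100) {
    stopf("invalid GPR: %s (must lie in [0, 100])", format(gpr_percent))
  }
  data.frame(
    plan_id = as.character(plan_id), beam_id = as.character(beam_id),
    site = as.character(site_label), gpr_percent = gpr_percent,
    criterion = as.character(criterion_label),
    stringsAsFactors = FALSE
  )
}

#' Validate a plan against the control-point invariants
#'
#' Checks, for every beam: at least two control points; a shared MLC
#' geometry; positive meterset; jaw ordering; per-pair bank ordering
#' (beyond the 0.01 mm clamp tolerance); and cumulative meterset weights
#' that start at 0, end at 1 and never decrease.
#'
#' @param plan a [plan_record()].
#' @return A character vector of human-readable violations; empty when the
#'   plan is valid. Violations name the beam, control point and rule.
#' @export
validate_plan <- function(plan) {
  v <- character(0)
  note <- function(fmt, ...) v <<- c(v, sprintf(fmt, ...))
  if (!inherits(plan, "plan_record")) {
    return("not a plan_record")
  }
  if (!is.finite(plan$fraction_dose_gy) || plan$fraction_dose_gy <= 0) {
    note("plan %s: fraction_dose_gy must be > 0", plan$plan_id)
  }
  for (beam in plan$beams) {
    id <- beam$beam_id
    if (!is.finite(beam$total_mu) || beam$total_mu <= 0) {
      note("beam %s: invalid meterset (total_mu must be > 0)", id)
    }
    n <- length(beam$cps)
    if (n < 2L) {
      note("beam %s: fewer than 2 control points", id)
      next
    }
    np <- beam$geometry$n_pairs
    w <- vapply(beam$cps, function(cp) cp$cum_weight, numeric(1))
    if (abs(w[1]) > 1e-9) note("beam %s: first cum_weight is %g, not 0", id, w[1])
    if (abs(w[n] - 1) > 1e-9) note("beam %s: last cum_weight is %g, not 1", id, w[n])
    bad <- which(diff(w) < -1e-12)
    for (k in bad) {
      note("beam %s CP %d: cum_weight decreases (%g -> %g)", id, k, w[k], w[k + 1])
    }
    for (k in seq_len(n)) {
      cp <- beam$cps[[k]]
      if (length(cp$left) != np) {
        note("beam %s CP %d: %d leaf pairs, geometry has %d", id, k, length(cp$left), np)
        next
      }
      neg <- which(cp$right < cp$left - 0.01)
      for (p in neg) {
        note("beam %s CP %d pair %d: right < left - 0.01 mm", id, k, p - 1L)
      }
      if (cp$jaw_x[1] >= cp$jaw_x[2]) note("beam %s CP %d: jaw x1 >= x2", id, k)
      if (cp$jaw_y[1] >= cp$jaw_y[2]) note("beam %s CP %d: jaw y1 >= y2", id, k)
      if (!all(is.finite(c(cp$left, cp$right, cp$jaw_x, cp$jaw_y, cp$cum_weight)))) {
        note("beam %s CP %d: non-finite positions", id, k)
      }
    }
  }
  v
}

cum_weights <- function(beam) {
  vapply(beam$cps, function(cp) cp$cum_weight, numeric(1))
}

#' Meterset delivered in each control-point transition
#'
#' @param beam a [beam_record()].
#' @return Numeric vector of `N_cp - 1` MU values,
#'   `total_mu * diff(cum_weight)`; sums to `total_mu`.
#' @examples
#' b <- toy_beam_T1()
#' transition_mu(b)  # 50 50
#' @export
transition_mu <- function(beam) {
  beam$total_mu * diff(cum_weights(beam))
}

#' Meterset attributed to each control point (half-transition rule)
#'
#' Each control point receives half of every adjacent transition's MU; the
#' first and last control points border a single transition and receive one
#' half only. Conserves `total_mu` exactly.
#'
#' @param beam a [beam_record()].
#' @return Numeric vector of `N_cp` MU values summing to `total_mu`.
#' @examples
#' cp_mu_weights(toy_beam_T1())  # 25 50 25
#' @export
cp_mu_weights <- function(beam) {
  mu_t <- transition_mu(beam)
  (c(mu_t, 0) + c(0, mu_t)) / 2
}
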
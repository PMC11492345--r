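# Deterministic synthetic plans and cohorts.
#
# The generator emulates the *shape* of a stereotactic VMAT QA cohort --
# jaw-tracked arcs on an HD-120-style MLC, 50-180 control points, sites with
# different target sizes, and gamma passing rates produced as a noisy
# monotone function of beam complexity -- not its dosimetry. GPR here is a
# statistical stand-in: a linear link on LAAM plus Gaussian noise, clipped
# to 100, which reproduces the ceiling-limited GPR distributions QA
# programs see in practice.

#' Static rectangular field (the LAAM verification fixture)
#'
#' Two identical control points with cumulative weights 0 and 1, jaws
#' exactly at the field edge, and open pairs exactly those whose y-span lies
#' within `+/- h/2`; remaining pairs are parked closed at the axis. The
#' 100 mm x 100 mm, 100 MU field on the HD-120 geometry ("fixture S1") is
#' the canonical correctness check: every normalized complexity score
#' (LSV, AAV, MCS, MCSv, LTMCS, APV, AAJA, LAAM) equals 1 and every
#' modulation score 0.
#'
#' @param size_mm `c(width, height)` of the field (mm).
#' @param mu beam meterset (MU).
#' @param geom an [mlc_geometry()] (default HD-120).
#' @param beam_id,site_label identification.
#' @return A [beam_record()].
#' @export
static_field_beam <- function(size_mm = c(100, 100), mu = 100,
                              geom = mlc_hd120(), beam_id = "S1",
                              site_label = NA_character_) {
  w <- size_mm[1]
  h <- size_mm[2]
  span <- range(geom$boundaries)
  if (h > span[2] - span[1] || -h / 2 < span[1] || h / 2 > span[2]) {
    stopf("field height %g mm exceeds the %g mm MLC span", h, span[2] - span[1])
  }
  np <- geom$n_pairs
  lo <- geom$boundaries[seq_len(np)]
  hi <- geom$boundaries[seq_len(np) + 1L]
  open <- lo >= -h / 2 & hi <= h / 2
  left <- ifelse(open, -w / 2, 0)
  right <- ifelse(open, w / 2, 0)
  cps <- lapply(0:1, function(i) {
    control_point(
      index = i, cum_weight = i, left = left, right = right,
      jaw_x = c(-w / 2, w / 2), jaw_y = c(-h / 2, h / 2), gantry_deg = 0
    )
  })
  beam_record(beam_id, mu, cps, geom, site_label = site_label)
}

#' Hand-computable three-control-point toy beam ("fixture T1")
#'
#' Two 5 mm pairs, jaws x(-10, 10) y(-5, 5), 100 MU over cumulative weights
#' (0, 0.5, 1). The leaf banks slide apart symmetrically so every metric is
#' tractable by hand; this is the worked oracle used throughout the tests.
#'
#' @return A [beam_record()].
#' @export
toy_beam_T1 <- function() {
  geom <- mlc_uniform(2L, 5)
  pos <- list(
    list(left = c(-10, -10), right = c(10, 10)),
    list(left = c(-5, -10), right = c(10, 5)),
    list(left = c(0, -10), right = c(10, 0))
  )
  cps <- lapply(seq_along(pos), function(k) {
    control_point(
      index = k - 1L, cum_weight = c(0, 0.5, 1)[k],
      left = pos[[k]]$left, right = pos[[k]]$right,
      jaw_x = c(-10, 10), jaw_y = c(-5, 5), gantry_deg = 0
    )
  })
  beam_record("T1", 100, cps, geom)
}

#' Synthetic jaw-tracked VMAT arc beam
#'
#' Projects a superellipse target outline (half-widths `a_x`, `a_y`,
#' squareness exponent `shape_exp`) onto the MLC, adds a slow sinusoidal
#' lateral drift and size breathing over the arc, and perturbs each leaf
#' outward by a smoothed uniform staircase of the given amplitude (smoothing
#' over three adjacent pairs; draws are independent across control points,
#' so the amplitude drives both leaf travel and aperture irregularity).
#' Jaws track each control point's aperture bounding box with `jaw_margin`
#' added in x; the y jaws sit on the outermost open pair boundary so the
#' leaf-side perimeter stays jaw-shielded at the field ends, as physical
#' jaw tracking does.
#'
#' @param n_cp number of control points (>= 2).
#' @param mu beam meterset (MU).
#' @param a_x,a_y target half-width/half-height (mm).
#' @param shape_exp superellipse exponent (2 = ellipse, large = rectangle).
#' @param amplitude staircase noise amplitude (mm, >= 0).
#' @param drift_mm lateral drift amplitude over the arc (mm).
#' @param jaw_margin x jaw margin beyond the leaf tips (mm).
#' @param geom an [mlc_geometry()].
#' @param beam_id,site_label,energy_label identification.
#' @param seed optional seed; `NULL` draws from the current RNG stream.
#' @return A [beam_record()] that passes [validate_plan()].
#' @export
modulated_arc_beam <- function(n_cp = 100, mu = 1100, a_x = 25, a_y = 30,
                               shape_exp = 8, amplitude = 1, drift_mm = 2,
                               jaw_margin = 1, geom = mlc_hd120(),
                               beam_id = "A1", site_label = NA_character_,
                               energy_label = "6X-FFF", seed = NULL) {
  if (n_cp < 2L) stopf("modulated_arc_beam: need n_cp >= 2")
  if (amplitude < 0 || a_x <= 0 || a_y <= 0) stopf("modulated_arc_beam: parameter out of range")
  build <- function() {
    np <- geom$n_pairs
    lo <- geom$boundaries[seq_len(np)]
    hi <- geom$boundaries[seq_len(np) + 1L]
    y_c <- (lo + hi) / 2
    phi1 <- runif(1, 0, 2 * pi)
    phi2 <- runif(1, 0, 2 * pi)
    dw <- runif(n_cp - 1L, 0.25, 1.75)
    cum <- c(0, cumsum(dw) / sum(dw))
    cum[n_cp] <- 1
    gantry <- seq(181, 181 + 358, length.out = n_cp) %% 360

    inside <- abs(y_c) < a_y
    cps <- vector("list", n_cp)
    for (k in seq_len(n_cp)) {
      ph <- (k - 1) / max(1L, n_cp - 1L)
      x_c <- drift_mm * sin(2 * pi * ph + phi1)
      scale <- 1 + 0.05 * sin(4 * pi * ph + phi2)
      chord <- rep(0, np)
      rel <- pmin(1, abs(y_c[inside]) / a_y)
      chord[inside] <- if (is.infinite(shape_exp)) {
        a_x * scale # rectangular target: constant chord, conformal-arc like
      } else {
        a_x * scale * (1 - rel^shape_exp)^(1 / shape_exp)
      }
      noise_l <- amplitude * smooth3(runif(np))
      noise_r <- amplitude * smooth3(runif(np))
      left <- ifelse(inside, x_c - chord - noise_l, x_c)
      right <- ifelse(inside, x_c + chord + noise_r, x_c)
      open <- inside & (right - left) > 0.5
      if (!any(open)) { # degenerate draw: force the central pair open
        center <- which.min(abs(y_c))
        left[center] <- x_c - max(1, a_x / 2)
        right[center] <- x_c + max(1, a_x / 2)
        open[center] <- TRUE
      }
      jaw_x <- c(min(left[open]) - jaw_margin, max(right[open]) + jaw_margin)
      jaw_y <- c(min(lo[open]), max(hi[open]))
      left[!open] <- x_c
      right[!open] <- x_c
      cps[[k]] <- control_point(
        index = k - 1L, cum_weight = cum[k], left = left, right = right,
        jaw_x = jaw_x, jaw_y = jaw_y, gantry_deg = gantry[k]
      )
    }
    beam_record(beam_id, mu, cps, geom,
      energy_label = energy_label,
      site_label = site_label
    )
  }
  if (is.null(seed)) build() else with_seed(seed, build())
}

# moving average over three adjacent leaf pairs (reflected ends): keeps the
# staircase but correlates neighbors, as deliverable leaf sequences do
smooth3 <- function(u) {
  n <- length(u)
  if (n < 3L) {
    return(u)
  }
  (u[c(1, 1:(n - 1))] + u + u[c(2:n, n)]) / 3
}

#' Cohort generator specification
#'
#' The default cohort emulates a 594-beam stereotactic QA dataset
#' qualitatively: ~300 plans of 2 beams, five treatment sites with realistic
#' mixture weights, a conformal-arc/modulated-arc mixture controlling the
#' complexity spread, and GPR linked linearly to LAAM with Gaussian noise
#' and a ceiling at 100.
#'
#' @param n_beams cohort size (default 600).
#' @param n_cp_range inclusive range of control points per beam.
#' @param sites named mixture weights (must sum to 1).
#' @param p_conformal probability that a beam is a conformal arc
#'   (rectangular target profile, zero staircase: the low-complexity mode).
#' @param amplitude_conformal,amplitude_modulated staircase amplitude ranges
#'   (mm) of the two mixture components.
#' @param exponent_conformal,exponent_modulated superellipse exponent ranges;
#'   an infinite value means an exactly rectangular profile.
#' @param gpr_intercept,gpr_slopes GPR link: `intercept + sum(slopes *
#'   metric)` with `gpr_slopes` a named vector over metric columns.
#' @param noise_sd GPR noise SD (percent).
#' @param seed integer seed; the whole cohort is a pure function of the spec.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_beams = 600L, n_cp_range = c(50L, 180L),
                        sites = c(
                          brain = 0.34, lung = 0.31, spine = 0.24,
                          liver = 0.04, other = 0.07
                        ),
                        p_conformal = 0.6,
                        amplitude_conformal = c(0, 0),
                        amplitude_modulated = c(0.5, 6),
                        exponent_conformal = c(Inf, Inf),
                        exponent_modulated = c(5, 14),
                        gpr_intercept = 78, gpr_slopes = c(LAAM = 20),
                        noise_sd = 1, seed = 42L) {
  stopifnot(
    n_beams >= 2, noise_sd >= 0,
    abs(sum(sites) - 1) < 1e-9, length(n_cp_range) == 2L
  )
  structure(
    list(
      n_beams = as.integer(n_beams), n_cp_range = as.integer(n_cp_range),
      sites = sites, p_conformal = p_conformal,
      amplitude_conformal = amplitude_conformal,
      amplitude_modulated = amplitude_modulated,
      exponent_conformal = exponent_conformal,
      exponent_modulated = exponent_modulated,
      gpr_intercept = gpr_intercept, gpr_slopes = gpr_slopes,
      noise_sd = noise_sd, seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
}

site_size_ranges <- function(site) {
  switch(site,
    brain = list(a_x = c(12, 30), a_y = c(15, 35)),
    lung = list(a_x = c(15, 35), a_y = c(18, 38)),
    spine = list(a_x = c(18, 40), a_y = c(20, 38)),
    liver = list(a_x = c(20, 40), a_y = c(22, 38)),
    other = list(a_x = c(15, 38), a_y = c(18, 38)),
    list(a_x = c(15, 35), a_y = c(18, 38))
  )
}

#' Generate a synthetic QA cohort (plans + metrics + GPRs)
#'
#' Draws plans of two beams each until `n_beams` beams exist, extracts the
#' 27-metric vector of every beam, and assigns
#' `GPR = clip(intercept + sum(slopes * metric) + N(0, noise_sd), 0, 100)`.
#' Regeneration from the same spec is bitwise identical.
#'
#' @param spec a [cohort_spec()].
#' @param cfg a [metric_config()] used for metric extraction.
#' @return A list with `plans` (list of [plan_record()]), `metrics`
#'   (data.frame, [metric_names()] columns) and `qa` (data.frame of QA
#'   records).
#' @export
make_cohort <- function(spec = cohort_spec(), cfg = metric_config()) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    plans <- list()
    n_done <- 0L
    plan_i <- 0L
    site_names <- names(spec$sites)
    while (n_done < spec$n_beams) {
      plan_i <- plan_i + 1L
      site <- sample(site_names, 1L, prob = spec$sites)
      sz <- site_size_ranges(site)
      n_in_plan <- min(2L, spec$n_beams - n_done)
      fraction_dose <- sample(c(5, 6, 7.5, 8, 10), 1L)
      beams <- lapply(seq_len(n_in_plan), function(j) {
        conformal <- runif(1) < spec$p_conformal
        amp_r <- if (conformal) spec$amplitude_conformal else spec$amplitude_modulated
        exp_r <- if (conformal) spec$exponent_conformal else spec$exponent_modulated
        shape_exp <- if (any(is.infinite(exp_r))) Inf else runif(1, exp_r[1], exp_r[2])
        modulated_arc_beam(
          n_cp = sample(seq(spec$n_cp_range[1], spec$n_cp_range[2]), 1L),
          mu = min(2400, max(200, rnorm(1, 1134, 339))),
          a_x = runif(1, sz$a_x[1], sz$a_x[2]),
          a_y = runif(1, sz$a_y[1], sz$a_y[2]),
          shape_exp = shape_exp,
          amplitude = runif(1, amp_r[1], amp_r[2]),
          drift_mm = runif(1, 0.5, 8),
          jaw_margin = 0.5 + 2.5 * runif(1)^2,
          beam_id = sprintf("B%d", j),
          site_label = site
        )
      })
      plans[[plan_i]] <- plan_record(
        sprintf("P%03d", plan_i), beams,
        fraction_dose_gy = fraction_dose, n_fractions = 6L
      )
      n_done <- n_done + n_in_plan
    }
    metrics <- compute_plan_metrics(plans, cfg)
    eps <- rnorm(nrow(metrics), 0, spec$noise_sd)
    link <- spec$gpr_intercept
    for (m in names(spec$gpr_slopes)) {
      link <- link + spec$gpr_slopes[[m]] * metrics[[m]]
    }
    gpr <- pmin(100, pmax(0, link + eps))
    sitecol <- unlist(lapply(plans, function(p) {
      vapply(p$beams, function(b) b$site_label, character(1))
    }))
    qa <- data.frame(
      plan_id = metrics$plan_id, beam_id = metrics$beam_id,
      site = sitecol, gpr_percent = gpr,
      criterion = "2%/2mm, 5% threshold, global",
      stringsAsFactors = FALSE
    )
    list(plans = plans, metrics = metrics, qa = qa)
  })
}
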
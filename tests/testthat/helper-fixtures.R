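# Shared fixtures and independent oracles for the test suite.

s1_plan <- function() {
  b <- static_field_beam()
  plan_record("P-S1", list(b), fraction_dose_gy = 2, n_fractions = 1L)
}

t1_plan <- function() {
  b <- toy_beam_T1()
  plan_record("P-T1", list(b), fraction_dose_gy = 10, n_fractions = 1L)
}

# random jaw-tracked control point (contiguous aperture) for geometry
# property tests; drawn from the arc generator so it matches the package's
# stated world
random_arc_cp <- function() {
  b <- modulated_arc_beam(
    n_cp = 2, a_x = runif(1, 5, 40), a_y = runif(1, 8, 38),
    shape_exp = runif(1, 2, 14), amplitude = runif(1, 0, 6),
    drift_mm = runif(1, 0, 5), jaw_margin = runif(1, 0.5, 3)
  )
  list(cp = b$cps[[1]], geom = b$geometry)
}

# small fast synthetic beam for bulk metric property tests
tiny_arc_beam <- function(n_cp = 5, ...) {
  modulated_arc_beam(
    n_cp = n_cp, a_x = runif(1, 6, 25), a_y = runif(1, 8, 25),
    shape_exp = runif(1, 2, 12), amplitude = runif(1, 0, 5),
    drift_mm = runif(1, 0, 4), ...
  )
}

# --- independent oracles ------------------------------------------------------

# brute-force Spearman: explicit mid-ranking + Pearson on the ranks
oracle_spearman <- function(x, y) {
  rank_mid <- function(v) {
    s <- sort(v)
    vapply(v, function(z) mean(which(abs(s - z) < 1e-12)), numeric(1))
  }
  rx <- rank_mid(x)
  ry <- rank_mid(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# brute-force AUC: loop over all positive-negative pairs, half credit ties
oracle_auc <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
    }
  }
  total / (length(pos) * length(neg))
}

# trapezoidal AUC over the full ROC polygon (threshold sweep with ties)
trapezoid_auc <- function(scores, labels) {
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- c(0, vapply(thr, function(t) mean(scores[labels] >= t), numeric(1)))
  fpr <- c(0, vapply(thr, function(t) mean(scores[!labels] >= t), numeric(1)))
  sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
}

# brute-force fluence modulation index (double loop over f grid and rows)
oracle_modulation_index <- function(values, F = 1, df = 0.01) {
  fp <- values > 0
  sigma <- sd(values[fp])
  if (!is.finite(sigma) || sigma == 0) {
    return(0)
  }
  fs <- seq(0, F, by = df)
  z <- numeric(length(fs))
  for (i in seq_along(fs)) {
    hits <- 0
    pairs <- 0
    for (r in seq_len(nrow(values))) {
      for (cc in seq_len(ncol(values) - 1L)) {
        if (fp[r, cc] && fp[r, cc + 1L]) {
          pairs <- pairs + 1
          if (abs(values[r, cc + 1L] - values[r, cc]) > fs[i] * sigma) hits <- hits + 1
        }
      }
    }
    z[i] <- if (pairs > 0) hits / pairs else 0
  }
  sum((z[-1] + z[-length(z)]) / 2) * df
}

# raster-based erosion oracle for the edge area metric: Chebyshev (square)
# structuring element, applied separably (row min then column min)
oracle_eroded_area <- function(cp, geom, band, px = 0.1) {
  r <- rasterize_aperture(cp, geom, px)
  k <- ceiling(band / px - 1e-9)
  m <- r$mask
  erode_1d <- function(mat, k, along_rows) {
    out <- mat
    for (d in seq_len(k)) {
      if (along_rows) { # shift along y (rows), pad with FALSE
        up <- rbind(mat[-seq_len(d), , drop = FALSE], matrix(FALSE, d, ncol(mat)))
        dn <- rbind(matrix(FALSE, d, ncol(mat)), mat[seq_len(nrow(mat) - d), , drop = FALSE])
      } else {
        up <- cbind(mat[, -seq_len(d), drop = FALSE], matrix(FALSE, nrow(mat), d))
        dn <- cbind(matrix(FALSE, nrow(mat), d), mat[, seq_len(ncol(mat) - d), drop = FALSE])
      }
      out <- out & up & dn
    }
    out
  }
  er <- erode_1d(erode_1d(m, k, TRUE), k, FALSE)
  sum(er) * px^2
}

# default acceptance cohort, built once per test run
cohort_cache <- new.env(parent = emptyenv())
get_default_cohort <- function() {
  if (is.null(cohort_cache$default)) {
    cohort_cache$default <- make_cohort(cohort_spec())
  }
  cohort_cache$default
}
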
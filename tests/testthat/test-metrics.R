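test_that("MU metrics follow the definitions", {
  expect_equal(
    unname(mu_metrics(s1_plan(), s1_plan()$beams[[1]])),
    c(100, 100, 2)
  )
  expect_equal(
    unname(mu_metrics(t1_plan(), t1_plan()$beams[[1]])),
    c(100, 20, 3)
  )
  # plan MU 1200, fraction dose 8 -> PMU 300
  b <- toy_beam_T1()
  b$total_mu <- 1200
  p <- plan_record("P", list(b), 8)
  expect_equal(mu_metrics(p, b)[["PMU"]], 300)
  p$fraction_dose_gy <- -1
  expect_error(mu_metrics(p, b), "invalid prescription")
})

test_that("gap metrics: average gap and small aperture scores", {
  g1 <- gap_metrics(static_field_beam())
  expect_equal(unname(g1), c(100, 0, 0, 0, 0))

  g2 <- gap_metrics(toy_beam_T1())
  expect_equal(g2[["AvgLeafGap"]], 15)
  expect_equal(g2[["SAS20"]], 0.75)
  expect_equal(g2[["SAS10"]], 0)

  # strict inequality at the boundary: all gaps exactly 5
  geom <- mlc_uniform(2L, 5)
  cp <- function(i, w) {
    control_point(i, w, c(-2.5, -2.5), c(2.5, 2.5), c(-5, 5), c(-5, 5))
  }
  b <- beam_record("B", 100, list(cp(0, 0), cp(1, 1)), geom)
  g3 <- gap_metrics(b)
  expect_equal(g3[["SAS5"]], 0)
  expect_equal(g3[["SAS10"]], 1)
})

test_that("jaw metrics match the fixtures", {
  j1 <- jaw_metrics(static_field_beam())
  expect_equal(unname(j1), c(1, 100, 0))

  j2 <- jaw_metrics(toy_beam_T1())
  expect_equal(j2[["AAJA"]], 0.75)
  expect_equal(j2[["MAXJ"]], 20)
  expect_equal(j2[["JawTrackingPct"]], 0)

  # jaws move at every transition
  geom <- mlc_uniform(2L, 5)
  mk <- function(i, w, jx) control_point(i, w, c(-8, -8), c(8, 8), jx, c(-5, 5))
  b <- beam_record(
    "B", 100,
    list(mk(0, 0, c(-10, 10)), mk(1, 0.5, c(-9, 10)), mk(2, 1, c(-9, 9))), geom
  )
  expect_equal(jaw_metrics(b)[["JawTrackingPct"]], 1)
})

test_that("MCS family matches the hand enumeration", {
  m1 <- mcs_family(static_field_beam())
  expect_equal(unname(m1), c(1, 1, 1, 1))

  t1 <- toy_beam_T1()
  states <- lapply(t1$cps, aperture_state, geom = t1$geometry)
  lsv_k <- vapply(states, vmatqa:::lsv_cp, numeric(1))
  expect_equal(lsv_k, c(1, 0, 0))
  m2 <- mcs_family(t1)
  expect_equal(m2[["MCS"]], 0.25)
  expect_equal(m2[["MCSv"]], 0.21875)
  # per-CP AAV: (1, 0.75, 0.5) -> weighted mean 0.75
  expect_equal(m2[["AAV"]], 0.75)
  expect_equal(m2[["LSV"]], 0.25)

  set.seed(31)
  for (i in 1:25) {
    v <- mcs_family(tiny_arc_beam(5))
    expect_true(all(v >= 0 & v <= 1 + 1e-12))
  }
})

test_that("travel metrics and the LTMCS clamp", {
  tv1 <- travel_metrics(static_field_beam())
  expect_equal(unname(tv1), c(0, 1))

  tv2 <- travel_metrics(toy_beam_T1())
  expect_equal(tv2[["LT"]], 5)
  expect_equal(tv2[["LTMCS"]], 0.995 * 0.21875)

  # LT >= lt_norm clamps LTMCS to 0
  cfg <- metric_config(lt_norm = 4)
  expect_equal(travel_metrics(toy_beam_T1(), cfg)[["LTMCS"]], 0)
})

test_that("area/irregularity/modulation metrics match closed forms", {
  d1 <- du_metrics(static_field_beam())
  expect_equal(d1[["BA"]], 100)
  expect_equal(d1[["BI"]], 400^2 / (4 * pi * 1e4))
  expect_equal(d1[["UnionArea"]], 10000, tolerance = 0.005)
  expect_equal(d1[["BM"]], 0)

  d2 <- du_metrics(toy_beam_T1(), metric_config(raster_px = 0.1))
  expect_equal(d2[["BA"]], 1.5)
  expect_equal(d2[["UnionArea"]], 200, tolerance = 0.005)
  expect_equal(d2[["BM"]], 0.25, tolerance = 0.005)

  # BI of any rectangle exceeds 1 (isoperimetric)
  set.seed(41)
  for (i in 1:20) {
    b <- tiny_arc_beam(4)
    expect_gt(du_metrics(b)[["BI"]], 1)
  }

  # summed union mode returns the area sum
  cfgs <- metric_config(union_mode = "summed")
  expect_equal(du_metrics(toy_beam_T1(), cfgs)[["UnionArea"]], 450)
})

test_that("edge metrics: EM constants and EAM closed form", {
  e1 <- edge_metrics(static_field_beam())
  expect_equal(e1[["EM"]], 0)
  expect_equal(e1[["EAM"]], 100 * (10000 - 96^2) / 10000)

  # single-CP beam built from T1 CP2: EM = 10 / 150
  t1 <- toy_beam_T1()
  cp2 <- t1$cps[[2]]
  cps <- list(cp2, cp2)
  cps[[1]]$index <- 0L
  cps[[1]]$cum_weight <- 0
  cps[[2]]$index <- 1L
  cps[[2]]$cum_weight <- 1
  b <- beam_record("B", 100, cps, t1$geometry)
  expect_equal(edge_metrics(b)[["EM"]], 10 / 150)
  # with c1 = 1, c2 = 0 the tip perimeter (2 * 10 mm) is scored instead
  expect_equal(
    edge_metrics(b, metric_config(em_c1 = 1, em_c2 = 0))[["EM"]],
    20 / 150
  )

  # aperture thinner than twice the band everywhere erodes away completely
  geom <- mlc_uniform(1L, 3)
  mk <- function(i, w) control_point(i, w, -20, 20, c(-25, 25), c(-1.5, 1.5))
  thin <- beam_record("B", 10, list(mk(0, 0), mk(1, 1)), geom)
  expect_equal(edge_metrics(thin)[["EAM"]], 100)
})

test_that("asymmetry distance is translation-equivariant", {
  expect_equal(asymmetry_metric(static_field_beam())[["MAD"]], 0)
  expect_equal(asymmetry_metric(toy_beam_T1())[["MAD"]], 2.5)

  b <- static_field_beam()
  shifted <- b
  shifted$cps <- lapply(b$cps, function(cp) {
    cp$left <- cp$left + 10
    cp$right <- cp$right + 10
    cp$jaw_x <- cp$jaw_x + 10
    cp
  })
  expect_equal(
    asymmetry_metric(shifted)[["MAD"]],
    asymmetry_metric(b)[["MAD"]] + 10
  )
})

test_that("modulation index matches the brute-force oracle", {
  expect_equal(modulation_index(static_field_beam())[["M"]], 0)

  # alternating two-level fluence: implementation vs double-loop oracle
  geom <- mlc_uniform(4L, 5)
  mk <- function(i, w, l, r) control_point(i, w, l, r, c(-10, 10), c(-10, 10))
  wide <- rep(-10, 4)
  b <- beam_record("B", 100, list(
    mk(0, 0, wide, rep(10, 4)),
    mk(1, 0.5, wide, rep(0, 4)),
    mk(2, 1, wide, rep(10, 4))
  ), geom)
  fm <- fluence_map(b, 1)
  expect_equal(
    modulation_index(b)[["M"]],
    oracle_modulation_index(fm$values),
    tolerance = 1e-9
  )

  set.seed(51)
  for (i in 1:5) {
    bb <- tiny_arc_beam(5)
    fmb <- fluence_map(bb, 1)
    expect_equal(
      modulation_index(bb)[["M"]],
      oracle_modulation_index(fmb$values),
      tolerance = 1e-9
    )
    # MU rescaling leaves M unchanged
    b10 <- bb
    b10$total_mu <- bb$total_mu * 10
    expect_equal(modulation_index(b10)[["M"]], modulation_index(bb)[["M"]])
  }
})

test_that("APV and LAAM match the fixtures and stay in [0, 1]", {
  expect_equal(apv_metric(static_field_beam())[["APV"]], 1)
  expect_equal(laam_metric(static_field_beam())[["LAAM"]], 1)

  t1 <- toy_beam_T1()
  states <- lapply(t1$cps, aperture_state, geom = t1$geometry)
  expect_equal(vapply(states, vmatqa:::apv_cp, numeric(1)), c(1, 0, 0))
  expect_equal(apv_metric(t1)[["APV"]], 0.25)
  expect_equal(
    laam_metric(t1)[["LAAM"]],
    0.5 * (1 - 2.5 / 30) * 0.875 * 0.5,
    tolerance = 1e-12
  )

  # transitions with mean travel >= lt_max contribute zero
  cfg <- metric_config(lt_max = 2)
  expect_equal(laam_metric(t1, cfg)[["LAAM"]], 0)

  set.seed(61)
  for (i in 1:50) {
    rc <- random_arc_cp()
    st <- aperture_state(rc$cp, rc$geom)
    apv <- vmatqa:::apv_cp(st)
    expect_gte(apv, 0)
    expect_lte(apv, 1)
  }
})

test_that("compute_all is deterministic and scale/range invariant", {
  t1 <- toy_beam_T1()
  p <- t1_plan()
  v1 <- compute_all(p, t1)
  v2 <- compute_all(p, t1)
  expect_identical(v1, v2) # bitwise

  expect_identical(names(v1), metric_names())

  # MU scale invariance: everything except TotalMU/PMU unchanged
  set.seed(71)
  b <- tiny_arc_beam(5, mu = 500)
  pb <- plan_record("P", list(b), 8)
  b2 <- b
  b2$total_mu <- b$total_mu * 3.7
  pb2 <- plan_record("P", list(b2), 8)
  va <- compute_all(pb, b)
  vb <- compute_all(pb2, b2)
  keep <- setdiff(metric_names(), c("TotalMU", "PMU"))
  expect_identical(va[keep], vb[keep])
  expect_equal(vb[["TotalMU"]], va[["TotalMU"]] * 3.7)
})

test_that("range invariants hold on a bank of random synthetic beams", {
  set.seed(81)
  unit <- c(
    "LSV", "AAV", "MCS", "MCSv", "LTMCS", "APV", "AAJA", "LAAM", "BM",
    "SAS2", "SAS5", "SAS10", "SAS20", "JawTrackingPct"
  )
  nonneg <- c(
    "LT", "AvgLeafGap", "MAXJ", "MAD", "BA", "UnionArea", "EM", "EAM",
    "M", "TotalMU", "PMU", "NumSegments"
  )
  cfg <- metric_config(raster_px = 1, mi_bixel = 2) # coarse grids for speed
  for (i in 1:1000) {
    b <- tiny_arc_beam(4)
    p <- plan_record("P", list(b), 8)
    v <- compute_all(p, b, cfg)
    expect_true(all(is.finite(v)))
    expect_true(all(v[unit] >= -1e-12 & v[unit] <= 1 + 1e-12))
    expect_true(all(v[nonneg] >= 0))
  }
})

test_that("metrics degrade monotonically with leaf-end noise", {
  perturb <- function(beam, sigma) {
    beam$cps <- lapply(beam$cps, function(cp) {
      open <- cp$right - cp$left > 0.5
      nl <- rnorm(length(cp$left), 0, sigma) * open
      nr <- rnorm(length(cp$right), 0, sigma) * open
      cp$left <- cp$left + nl
      cp$right <- pmax(cp$right + nr, cp$left + nl * 0) # keep banks ordered
      cp$right <- pmax(cp$right, cp$left)
      cp
    })
    beam
  }
  sigmas <- c(0, 0.5, 1, 2, 3.5, 5)
  n_seeds <- 20
  med <- matrix(NA_real_, length(sigmas), 7,
    dimnames = list(NULL, c("LSV", "APV", "MCSv", "LAAM", "EM", "BI", "LT"))
  )
  for (si in seq_along(sigmas)) {
    vals <- matrix(NA_real_, n_seeds, 7)
    for (s in seq_len(n_seeds)) {
      set.seed(1000 + s)
      base <- modulated_arc_beam(
        n_cp = 20, a_x = 20, a_y = 20, shape_exp = 6,
        amplitude = 0.5, drift_mm = 2
      )
      set.seed(5000 + s)
      b <- perturb(base, sigmas[si])
      states <- lapply(b$cps, aperture_state, geom = b$geometry)
      mcs <- mcs_family(b, states = states)
      vals[s, ] <- c(
        mcs[["LSV"]],
        apv_metric(b, states = states)[["APV"]],
        mcs[["MCSv"]],
        laam_metric(b, states = states)[["LAAM"]],
        edge_metrics(b, states = states)[["EM"]],
        du_metrics(b, metric_config(union_mode = "summed"), states)[["BI"]],
        travel_metrics(b, states = states, .mcsv = mcs[["MCSv"]])[["LT"]]
      )
    }
    med[si, ] <- apply(vals, 2, median)
  }
  trend <- function(col) suppressWarnings(cor(seq_along(sigmas), med[, col], method = "spearman"))
  for (col in c("LSV", "APV", "MCSv", "LAAM")) expect_lte(trend(col), -0.9)
  for (col in c("EM", "BI", "LT")) expect_gte(trend(col), 0.9)
})
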
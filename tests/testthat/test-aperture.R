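test_that("aperture_state matches the hand-derived fixtures", {
  s1 <- static_field_beam()
  st <- aperture_state(s1$cps[[1]], s1$geometry)
  expect_equal(st$n_open, 36L)
  expect_equal(unique(st$gap[st$open]), 100)
  expect_equal(st$area, 10000)
  expect_equal(st$jaw_area, 10000)
  expect_equal(st$aaja, 1)
  expect_equal(st$side_perimeter, 0)
  expect_equal(st$spread_left, 0)
  expect_equal(st$spread_right, 0)
  expect_equal(st$full_perimeter, 400)

  t1 <- toy_beam_T1()
  st2 <- aperture_state(t1$cps[[2]], t1$geometry)
  expect_equal(st2$gap[st2$open], c(15, 15))
  expect_equal(st2$area, 150)
  expect_equal(st2$aaja, 0.75)
  expect_equal(st2$side_perimeter, 10)
  expect_equal(st2$spread_left, 5)
  expect_equal(st2$spread_right, 5)
  expect_equal(st2$full_perimeter, 60)
  expect_equal(sort(st2$midpoint_x), c(-2.5, 2.5))

  # all pairs closed
  geom <- mlc_uniform(4L, 5)
  cp <- control_point(0, 0, rep(0, 4), rep(0, 4), c(-10, 10), c(-10, 10))
  st3 <- aperture_state(cp, geom)
  expect_equal(st3$n_open, 0L)
  expect_equal(st3$area, 0)
  expect_equal(st3$aaja, 0)
  expect_equal(st3$side_perimeter, 0)
})

test_that("raster area agrees with the analytic area on random apertures", {
  set.seed(101)
  worst <- 0
  for (i in 1:200) {
    rc <- random_arc_cp()
    st <- aperture_state(rc$cp, rc$geom)
    r <- rasterize_aperture(rc$cp, rc$geom, 0.1)
    raster_area <- sum(r$mask) * 0.1^2
    rel <- abs(raster_area - st$area) / st$area
    worst <- max(worst, rel)
  }
  expect_lt(worst, 0.005)
})

test_that("side_perimeter bound holds exactly on random control points", {
  set.seed(202)
  for (i in 1:1000) {
    rc <- random_arc_cp()
    st <- aperture_state(rc$cp, rc$geom)
    if (st$n_open >= 2L) {
      bound <- (st$n_open - 1L) * (st$spread_left + st$spread_right)
      expect_lte(st$side_perimeter, bound + 1e-9)
    }
  }
})

test_that("union area brackets and fixture values hold", {
  s1 <- static_field_beam()
  expect_equal(union_area(s1, 0.5), 10000, tolerance = 0.005)
  expect_equal(area_sum(s1), 20000)

  t1 <- toy_beam_T1()
  expect_equal(union_area(t1, 0.1), 200, tolerance = 0.005)
  expect_equal(area_sum(t1), 450)
  expect_error(union_area(t1, -1), "invalid resolution")

  set.seed(303)
  for (i in 1:20) {
    b <- tiny_arc_beam(6)
    states <- lapply(b$cps, aperture_state, geom = b$geometry)
    areas <- vapply(states, function(s) s$area, numeric(1))
    ua <- union_area(b, 0.5)
    expect_gte(ua, max(areas) * 0.995)
    expect_lte(ua, sum(areas) * 1.005)
  }
})

test_that("leaf travel table matches hand enumeration", {
  s1 <- static_field_beam()
  tt <- leaf_travel_table(s1)
  expect_true(all(tt$per_leaf == 0))
  expect_equal(tt$per_transition, 0)

  t1 <- toy_beam_T1()
  tt1 <- leaf_travel_table(t1)
  expect_equal(unname(tt1$per_leaf), c(10, 0, 0, 10))
  expect_equal(tt1$per_transition, c(2.5, 2.5))

  # one moving leaf: 7 mm out, 3 mm back over 4 active leaves
  geom <- mlc_uniform(2L, 5)
  mk_cp <- function(i, w, l1) {
    control_point(i, w, c(l1, -10), c(10, 10), c(-12, 12), c(-5, 5))
  }
  b <- beam_record(
    "B", 100,
    list(mk_cp(0, 0, -10), mk_cp(1, 0.5, -3), mk_cp(2, 1, -6)), geom
  )
  tt2 <- leaf_travel_table(b)
  expect_equal(unname(tt2$per_leaf), c(10, 0, 0, 0))
  expect_equal(tt2$per_transition, c(7 / 4, 3 / 4))
})

test_that("fluence map accumulates MU and conserves integral", {
  s1 <- static_field_beam()
  fm <- fluence_map(s1, 1)
  inside <- fm$values[fm$values > 0]
  expect_equal(unique(inside), 100)
  expect_equal(sum(fm$values > 0) * 1, 10000, tolerance = 0.01)

  # T1 staircase: 25/75/150 pattern of overlapping apertures, max 100 at core
  t1 <- toy_beam_T1()
  fmt <- fluence_map(t1, 0.5)
  expect_equal(max(fmt$values), 100)

  # fluence conservation against MU-weighted analytic areas
  set.seed(404)
  for (i in 1:10) {
    b <- tiny_arc_beam(6)
    fmb <- fluence_map(b, 0.5)
    states <- lapply(b$cps, aperture_state, geom = b$geometry)
    target <- sum(cp_mu_weights(b) * vapply(states, function(s) s$area, numeric(1)))
    expect_equal(sum(fmb$values) * 0.25, target, tolerance = 0.02)
  }

  # a zero-MU transition leaves the fluence unchanged
  geom <- mlc_uniform(2L, 5)
  mk <- function(i, w) {
    control_point(i, w, c(-8, -8), c(8, 8), c(-10, 10), c(-5, 5))
  }
  b2 <- beam_record("B", 100, list(mk(0, 0), mk(1, 0.25), mk(2, 0.25), mk(3, 1)), geom)
  b3 <- beam_record("B", 100, list(mk(0, 0), mk(1, 0.25), mk(3, 1)), geom)
  expect_equal(fluence_map(b2, 0.5)$values, fluence_map(b3, 0.5)$values)
})

test_that("exact erosion matches the raster erosion oracle", {
  set.seed(505)
  for (i in 1:10) {
    b <- modulated_arc_beam(
      n_cp = 2, a_x = runif(1, 8, 20), a_y = runif(1, 8, 20),
      shape_exp = runif(1, 2, 10), amplitude = runif(1, 0, 4)
    )
    cp <- b$cps[[1]]
    st <- aperture_state(cp, b$geometry)
    band <- sample(c(1, 2), 1)
    exact <- vmatqa:::eroded_area(st, cp, b$geometry, band)
    raster <- oracle_eroded_area(cp, b$geometry, band, px = 0.1)
    expect_equal(exact, raster, tolerance = 0.03)
  }
  # closed form: rectangle erodes to (w - 2b)(h - 2b)
  s1 <- static_field_beam()
  st <- aperture_state(s1$cps[[1]], s1$geometry)
  expect_equal(vmatqa:::eroded_area(st, s1$cps[[1]], s1$geometry, 2), 96^2)
})
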
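test_that("transition MU and per-CP MU weights follow the definitions", {
  mk <- function(weights, mu) {
    cps <- lapply(seq_along(weights), function(k) {
      control_point(k - 1L, weights[k],
        left = c(-10, -10), right = c(10, 10),
        jaw_x = c(-10, 10), jaw_y = c(-5, 5)
      )
    })
    beam_record("B", mu, cps, mlc_uniform(2L, 5))
  }
  expect_equal(transition_mu(mk(c(0, 0.5, 1), 100)), c(50, 50))
  expect_equal(transition_mu(mk(c(0, 1), 250)), 250)
  expect_equal(transition_mu(mk(c(0, 0.25, 0.25, 1), 100)), c(25, 0, 75))
  expect_equal(cp_mu_weights(mk(c(0, 0.5, 1), 100)), c(25, 50, 25))
  expect_equal(cp_mu_weights(mk(c(0, 1), 100)), c(50, 50))
  expect_equal(cp_mu_weights(toy_beam_T1()), c(25, 50, 25))

  # MU conservation over random valid weight vectors
  set.seed(11)
  for (i in 1:1000) {
    n <- sample(2:40, 1)
    w <- c(0, sort(runif(n - 2L)), 1)
    mu <- runif(1, 10, 3000)
    b <- mk(w, mu)
    expect_equal(sum(transition_mu(b)), mu, tolerance = 1e-9)
    expect_equal(sum(cp_mu_weights(b)), mu, tolerance = 1e-9)
  }
})

test_that("validate_plan reports violations as data", {
  expect_identical(validate_plan(s1_plan()), character(0))
  expect_identical(validate_plan(t1_plan()), character(0))

  b <- toy_beam_T1()
  b$cps[[2]]$right[2] <- b$cps[[2]]$left[2] - 0.02
  v <- validate_plan(plan_record("P", list(b), 10))
  expect_length(v, 1L)
  expect_match(v, "pair 1")
  expect_match(v, "right < left")

  b1 <- toy_beam_T1()
  b1$cps <- b1$cps[1]
  expect_match(
    validate_plan(plan_record("P", list(b1), 10)),
    "fewer than 2 control points"
  )

  b2 <- toy_beam_T1()
  b2$total_mu <- 0
  expect_match(validate_plan(plan_record("P", list(b2), 10)), "invalid meterset")
})

test_that("control_point clamps sub-tolerance overlaps only", {
  cp <- control_point(0, 0,
    left = c(0, 5), right = c(-0.008, 4),
    jaw_x = c(-10, 10), jaw_y = c(-5, 5)
  )
  expect_equal(cp$left[1], cp$right[1]) # clamped to midpoint
  expect_equal(cp$right[2], 4) # larger overlap untouched
})

test_that("JSON plan dialect round-trips field-by-field", {
  plan <- plan_record(
    "RT", list(toy_beam_T1(), static_field_beam(), tiny_arc_beam(8)),
    fraction_dose_gy = 7.5, n_fractions = 6L
  )
  path <- tempfile(fileext = ".json")
  write_rtplan(plan, path)
  back <- read_rtplan(path)
  expect_equal(back, plan, tolerance = 1e-9)
})

test_that("reader rejects invariant violations with named errors", {
  mk_file <- function(mutate) {
    plan <- t1_plan()
    plan <- mutate(plan)
    path <- tempfile(fileext = ".json")
    write_plan_json(plan, path)
    path
  }
  # non-monotone cumulative weights: [0, 0.7, 0.6, 1]
  p1 <- mk_file(function(plan) {
    b <- plan$beams[[1]]
    cps <- lapply(1:4, function(k) {
      cp <- b$cps[[min(k, 3)]]
      cp$cum_weight <- c(0, 0.7, 0.6, 1)[k]
      cp$index <- k - 1L
      cp
    })
    plan$beams[[1]]$cps <- cps
    plan
  })
  expect_error(read_rtplan(p1), "corrupt control points")

  p2 <- mk_file(function(plan) {
    plan$beams[[1]]$total_mu <- 0
    plan
  })
  expect_error(read_rtplan(p2), "invalid meterset")

  # property: every injected ControlPoint corruption is rejected
  set.seed(21)
  mutators <- list(
    function(plan) { # jaw ordering
      plan$beams[[1]]$cps[[2]]$jaw_x <- c(10, -10)
      plan
    },
    function(plan) { # bank ordering beyond tolerance
      plan$beams[[1]]$cps[[3]]$right[1] <- plan$beams[[1]]$cps[[3]]$left[1] - 5
      plan
    },
    function(plan) { # first weight not 0
      plan$beams[[1]]$cps[[1]]$cum_weight <- 0.2
      plan
    },
    function(plan) { # last weight not 1
      plan$beams[[1]]$cps[[3]]$cum_weight <- 0.9
      plan
    }
  )
  for (m in mutators) expect_error(read_rtplan(mk_file(m)))
})

test_that("QA table IO validates GPR and joins to metrics", {
  qa <- rbind(
    qa_record("P1", "B1", 97.3, "2%/2mm"),
    qa_record("P1", "B2", 91.8, "2%/2mm")
  )
  expect_equal(qa$gpr_percent[1], 97.3)
  expect_error(qa_record("P1", "B1", 103), "invalid GPR")

  path <- tempfile(fileext = ".csv")
  write_qa_table(qa, path)
  back <- read_qa_table(path)
  expect_equal(back$gpr_percent, qa$gpr_percent)

  bad <- qa
  bad$gpr_percent[2] <- 103
  write.csv(bad, path, row.names = FALSE)
  expect_error(read_qa_table(path), "invalid GPR")

  metrics <- compute_plan_metrics(list(s1_plan(), t1_plan()))
  qa2 <- rbind(
    qa_record("P-S1", "S1", 99), qa_record("P-T1", "T1", 92)
  )
  merged <- join_metrics_qa(metrics, qa2)
  expect_equal(nrow(merged), 2L)
  expect_error(
    join_metrics_qa(metrics, qa_record("P-X", "B9", 95)),
    "unmatched record"
  )
})

test_that("metrics CSV round-trips in the fixed column order", {
  metrics <- compute_plan_metrics(list(s1_plan(), t1_plan()))
  path <- tempfile(fileext = ".csv")
  write_metrics_csv(metrics, path)
  back <- read_metrics_csv(path)
  expect_identical(names(back), c("plan_id", "beam_id", metric_names()))
  for (m in metric_names()) expect_equal(back[[m]], metrics[[m]], tolerance = 1e-12)
})
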
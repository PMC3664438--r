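test_that("rates portrait differentiates the stored series", {
  n <- 2001
  t <- seq(0, 20, length.out = n)
  # injected harmonic pair: the portrait is an ellipse traced repeatedly
  tr <- synthetic_trajectory(t, s = 0.1 * sin(t) + 0.5, y2 = cos(t))
  pt <- rates_portrait(tr, contact_s = 0.4)
  expect_equal(length(pt$ds_dt), n - 2)
  i <- 2:(n - 1)
  expect_equal(pt$ds_dt, 0.1 * cos(t[i]), tolerance = 1e-3)
  expect_equal(pt$dm_dt, -sin(t[i]), tolerance = 1e-3)
  # quiescent agent in a flat world: everything at the origin
  tr0 <- synthetic_trajectory(t, s = rep(0, n), y2 = rep(0, n))
  pt0 <- rates_portrait(tr0)
  expect_true(all(pt0$ds_dt == 0 & pt0$dm_dt == 0))
  expect_false(detect_limit_cycle(pt0)$cycle_detected)
})

test_that("limit-cycle detection recovers the period of a pure oscillation", {
  period <- 4
  dt <- 0.01
  t <- seq(0, 60, by = dt)
  tr <- synthetic_trajectory(t, s = 0.2 + 0.1 * sin(2 * pi * t / period),
                             y2 = cos(2 * pi * t / period))
  res <- detect_limit_cycle(rates_portrait(tr, contact_s = 0.05))
  expect_true(res$cycle_detected)
  expect_equal(res$period, period, tolerance = 2 * dt / period)
  expect_gt(res$n_returns, 3)
})

test_that("decaying transients are not reported as cycles", {
  dt <- 0.01
  t <- seq(0, 60, by = dt)
  decay <- exp(-0.2 * t)
  tr <- synthetic_trajectory(t, s = 0.2 + 0.1 * decay * sin(3 * t),
                             y2 = decay * cos(3 * t))
  res <- detect_limit_cycle(rates_portrait(tr, contact_s = 0.05))
  expect_false(res$cycle_detected)
})

test_that("coordination verdict requires both reliability and functionality", {
  cyc <- function(det, per = 4) list(cycle_detected = det, period = per,
                                     amplitude = 1, n_returns = 5)
  out <- function(lab) structure(list(label = lab), class = "smc_outcome")
  # reliable cycle + task success on every trial
  v1 <- classify_coordination(rep(list(cyc(TRUE)), 10),
                              rep(list(out("approach")), 10), "approach",
                              "cycle")
  expect_true(v1$is_sm_coordination)
  expect_equal(v1$reliability, 1)
  # reliable cycle but the task fails: stable yet not efficacious
  v2 <- classify_coordination(rep(list(cyc(TRUE)), 10),
                              rep(list(out("undecided")), 10), "approach",
                              "cycle")
  expect_false(v2$is_sm_coordination)
  expect_true(v2$reliability >= 0.9 && !v2$functional)
  # pattern in 1 of 20 trials: below any reasonable reliability
  v3 <- classify_coordination(c(list(cyc(TRUE)), rep(list(cyc(FALSE)), 19)),
                              rep(list(out("approach")), 20), "approach",
                              "cycle")
  expect_false(v3$is_sm_coordination)
  # reliable avoidance transients co-occurring with avoid success qualify
  v4 <- classify_coordination(rep(list(TRUE), 10),
                              rep(list(out("avoid")), 10), "avoid",
                              "transient")
  expect_true(v4$is_sm_coordination)
  expect_error(classify_coordination(list(cyc(TRUE)), list(), "approach"),
               "aligned")
})

test_that("category map handles degenerate grids and reports flips", {
  a <- inert_agent()   # stationary: every cell undecided, no boundary
  cm <- category_map(a, width_grid = 1, height_grid = 0.8, T = 5)
  expect_equal(dim(cm$label), c(1, 1))
  expect_equal(cm$label[1, 1], "undecided")
  expect_true(is.na(cm$boundaries$boundary_width))
  expect_equal(cm$boundaries$n_flips, 0)
})
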
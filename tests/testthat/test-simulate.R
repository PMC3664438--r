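test_that("inert agent stays put and the loop is deterministic", {
  w <- single_shape_world(1)
  tr <- run_trial(w, inert_agent(), sim_state(5), T = 10)
  expect_true(all(tr$p == 5))
  expect_true(all(tr$v == 0))
  a <- bistable_agent()
  t1 <- run_trial(w, a, sim_state(12.3, 0.1, -0.2), T = 50)
  t2 <- run_trial(w, a, sim_state(12.3, 0.1, -0.2), T = 50)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
})

test_that("clamped velocity gives the ballistic closed form", {
  w <- unit_gaussian_world(h = 0.9, w = 1.5, center = 20)
  v0 <- 0.37
  tr <- run_trial(w, inert_agent(), sim_state(10), T = 60,
                  clamp_velocity = v0)
  expect_equal(tr$s, sense(w, 10 + v0 * tr$t), tolerance = 1e-9)
  expect_true(all(tr$v == v0))
})

test_that("the stored coupling invariant ds = v * gradient holds exactly", {
  w <- single_shape_world(1, 0.8)
  tr <- run_trial(w, bistable_agent(), sim_state(12), T = 100)
  expect_lt(max(abs(tr$ds - tr$v * sense_gradient(w, tr$p))), 1e-12)
  expect_true(all(tr$s >= 0 & tr$s <= 1))
  expect_true(all(tr$p >= 0 & tr$p < 40))
})

test_that("finite-difference sensing mode tracks the analytic coupling", {
  w <- single_shape_world(1, 0.8)
  a <- bistable_agent()
  tr_fd <- run_trial(w, a, sim_state(12), T = 50, ds_mode = "finite")
  # backward difference of the stored s equals the stored ds (by definition)
  expect_equal(tr_fd$ds[-1], diff(tr_fd$s) / tr_fd$dt, tolerance = 1e-12)
  # the midpoint-rule oracle matches the analytic coupling to second order
  tr <- run_trial(w, a, sim_state(12), T = 50)
  fd <- trajectory_ds_fd(tr)
  expect_lt(max(abs(fd$ds_analytic - fd$ds_fd)), 1e-3)
  # sample-centred differencing carries the first-order Euler-path bias
  fd_c <- trajectory_ds_fd(tr, scheme = "central")
  expect_lt(max(abs(fd_c$ds_analytic - fd_c$ds_fd)), 1e-2)
})

test_that("run_trial validates its controls and reports divergence", {
  w <- single_shape_world(1)
  expect_error(run_trial(w, inert_agent(), sim_state(0), T = -1), "T")
  expect_error(run_trial(w, inert_agent(), sim_state(0), dt = 0.1), "dt")
})

test_that("behavior outcomes label dwelling, fleeing and undecided runs", {
  w <- single_shape_world(1, 0.8)
  target <- w$objects[[1]]
  n <- 1001
  t <- seq(0, 10, length.out = n)
  # dwelling at the peak with small oscillation
  dwell <- synthetic_trajectory(t, s = rep(0.8, n), y2 = rep(0, n),
                                p = 20 + 0.3 * sin(5 * t),
                                v = 0.15 * cos(5 * t), world = w)
  o <- behavior_outcome(dwell, target)
  expect_equal(o$label, "approach")
  expect_true(o$oscillation)
  # monotone escape past 4 widths
  flee <- synthetic_trajectory(t, s = pmax(0, 0.8 - 0.1 * t),
                               y2 = rep(0, n), p = 22 + 1.4 * t,
                               v = rep(1.4, n), world = w)
  o2 <- behavior_outcome(flee, target)
  expect_equal(o2$label, "avoid")
  expect_false(o2$oscillation)
  # parked at middle distance: neither
  park <- synthetic_trajectory(t, s = rep(0.2, n), y2 = rep(0, n),
                               p = rep(23, n), v = rep(0, n), world = w)
  expect_equal(behavior_outcome(park, target)$label, "undecided")
})

test_that("halving dt barely moves the final position (integration sanity)", {
  w <- single_shape_world(1, 0.8)
  a <- bistable_agent()
  p1 <- run_trial(w, a, sim_state(12), T = 50, dt = 0.01)
  p2 <- run_trial(w, a, sim_state(12), T = 50, dt = 0.005)
  d <- abs(wrapped_distance(p1$p[length(p1$p)], p2$p[length(p2$p)], 40))
  expect_lt(d, 0.05)
})
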
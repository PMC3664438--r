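test_that("fixed points of the clamped interneuron match closed forms and uniroot", {
  # linear leak: single fixed point at y1 = I
  a0 <- agent_params(0, 2, 0, 0, 1, 1, 5)
  for (I in c(-3, 0, 1.7)) {
    fp <- solve_fixed_points(a0, I)
    expect_equal(nrow(fp), 1)
    expect_equal(fp$y1, I, tolerance = 1e-10)
    expect_true(fp$stable)
  }
  # bistable symmetric case: middle root exactly at 3, outer roots from an
  # independent root finder on the closed form
  a <- bistable_agent()
  fp <- solve_fixed_points(a, 0)
  expect_equal(nrow(fp), 3)
  expect_equal(fp$y1[2], 3, tolerance = 1e-10)
  expect_false(fp$stable[2])                     # slope 6/4 > 1 at center
  F <- function(y) -y + 6 / (1 + exp(-(y - 3)))
  lo <- uniroot(F, c(0, 1), tol = 1e-14)$root
  hi <- uniroot(F, c(5, 6), tol = 1e-14)$root
  expect_equal(fp$y1[c(1, 3)], c(lo, hi), tolerance = 1e-9)
  expect_true(all(fp$stable[c(1, 3)]))
  # outer roots symmetric about 3 for this symmetric wiring
  expect_equal(fp$y1[1] + fp$y1[3], 6, tolerance = 1e-9)
  # derived quantities
  sig <- 1 / (1 + exp(-(fp$y1 - 3)))
  expect_equal(fp$y2, 4 * sig, tolerance = 1e-9)
  expect_equal(fp$v, motor_velocity(a, fp$y2))
})

test_that("w11 <= 4 implies a unique fixed point for every input", {
  set.seed(123)
  for (rep in 1:200) {
    a <- random_params_draw()
    if (a$w11 > 4) a$w11 <- runif(1, -16, 4)
    for (I in c(-10, -3, 0, 3, 10))
      expect_equal(nrow(solve_fixed_points(a, I)), 1)
  }
})

test_that("stable fixed points are endpoints of clamped integrations", {
  a <- bistable_agent()
  for (I in c(-0.8, 0, 0.8)) {
    fp <- solve_fixed_points(a, I)
    st <- fp[fp$stable, ]
    unst <- fp$y1[!fp$stable]
    for (k in seq_len(nrow(st))) {
      # 10 spread starts inside the basin (bounded by the unstable root)
      basin <- if (nrow(st) == 1) c(st$y1[k] - 5, st$y1[k] + 5)
      else if (st$y1[k] < min(unst)) c(st$y1[k] - 5, min(unst) - 0.05)
      else c(max(unst) + 0.05, st$y1[k] + 5)
      for (y0 in seq(basin[1], basin[2], length.out = 10)) {
        res <- tendency(a, agent_state(y1 = y0), I, T_max = 500)
        expect_equal(res$y1_end, st$y1[k], tolerance = 1e-3)
      }
    }
  }
})

test_that("a state on the basin boundary is flagged as non-convergent", {
  a <- bistable_agent()
  fp <- solve_fixed_points(a, 0)
  expect_warning(res <- tendency(a, agent_state(y1 = fp$y1[2]), 0,
                                 T_max = 50),
                 "converge")
  expect_null(res)
  # monostable input: the unique attractor regardless of state
  am <- monostable_agent()
  for (y0 in c(-8, 0, 8))
    expect_equal(tendency(am, agent_state(y1 = y0), 1.2)$y1_end,
                 solve_fixed_points(am, 1.2)$y1, tolerance = 1e-3)
})

test_that("bifurcation diagram finds the saddle-node fold pair", {
  # monostable wiring: one branch, no folds
  bif0 <- bifurcation_diagram(monostable_agent(), c(-3, 3), 0.05)
  expect_equal(length(bif0$bifurcations), 0)
  expect_equal(length(unique(bif0$points$branch_id)), 1)
  # bistable wiring: two folds, symmetric about I = 0 by the symmetry
  # (y1, I) -> (6 - y1, -I) of this parameterization
  a <- bistable_agent()
  bif <- bifurcation_diagram(a, c(-3, 3), 0.01)
  expect_equal(length(bif$bifurcations), 2)
  expect_equal(sum(bif$bifurcations), 0, tolerance = 0.02)
  # fold locations match the analytic tangency condition
  disc <- sqrt(1 - 4 / 6)
  u <- c((1 - disc) / 2, (1 + disc) / 2)
  ycrit <- log(u / (1 - u)) + 3
  Ifold <- sort(ycrit - 6 * u)
  expect_equal(sort(bif$bifurcations), Ifold, tolerance = 0.011)
  # large |I|: single branch tracking saturation y1 ~ I + w11 * {0 or 1}
  big <- solve_fixed_points(a, 30)
  expect_equal(nrow(big), 1)
  expect_equal(big$y1, 30 + 6, tolerance = 1e-3)
  small <- solve_fixed_points(a, -30)
  expect_equal(small$y1, -30, tolerance = 1e-3)
})

test_that("attractor landscape classification is consistent with the root solver", {
  set.seed(5)
  w <- single_shape_world(1, 0.8)
  for (a in list(bistable_agent(), monostable_agent())) {
    land <- attractor_landscape(w, a,
                                p_grid = symmetric_grid(20, 3, 0.2),
                                v_grid = symmetric_grid(0, 1, 0.1))
    cells <- cbind(sample(length(land$p), 30, TRUE),
                   sample(length(land$v), 30, TRUE))
    for (k in 1:30) {
      I <- land$I[cells[k, 1], cells[k, 2]]
      fp <- solve_fixed_points(a, I)
      vs <- fp$v[fp$stable]
      want <- if (all(vs >= 0)) "positive"
      else if (all(vs < 0)) "negative" else "bistable"
      expect_equal(land$class[cells[k, 1], cells[k, 2]], want)
      # bistable cells carry exactly two stable velocities
      if (want == "bistable")
        expect_equal(sort(c(land$v_lower[cells[k, 1], cells[k, 2]],
                            land$v_upper[cells[k, 1], cells[k, 2]])),
                     sort(vs), tolerance = 1e-4)
    }
  }
})

test_that("landscape inherits the surface symmetry and is empty-world uniform", {
  a <- bistable_agent()
  land0 <- attractor_landscape(world(40), a, p_grid = seq(0, 39, 1),
                               v_grid = symmetric_grid(0, 1, 0.25))
  expect_equal(length(unique(as.vector(land0$class))), 1)
  land <- attractor_landscape(single_shape_world(1, 0.8), a)
  mirrored <- land$class[rev(seq_along(land$p)), rev(seq_along(land$v))]
  expect_identical(land$class, mirrored)
})

test_that("landscape classes are stable under grid refinement away from boundaries", {
  a <- bistable_agent()
  w <- single_shape_world(1, 0.8)
  coarse <- attractor_landscape(w, a, p_grid = symmetric_grid(20, 3, 0.1),
                                v_grid = symmetric_grid(0, 1, 0.1))
  fine <- attractor_landscape(w, a, p_grid = symmetric_grid(20, 3, 0.05),
                              v_grid = symmetric_grid(0, 1, 0.05))
  # coarse cell (i, j) sits at fine cell (2i-1, 2j-1)
  fi <- 2 * seq_along(coarse$p) - 1
  fj <- 2 * seq_along(coarse$v) - 1
  same <- coarse$class == fine$class[fi, fj]
  # interior cells: all 4-neighbors share the coarse class
  nb_same <- matrix(TRUE, nrow(same), ncol(same))
  cl <- coarse$class
  n <- nrow(cl); m <- ncol(cl)
  nb_same[2:(n-1), ] <- nb_same[2:(n-1), ] &
    cl[2:(n-1), ] == cl[1:(n-2), ] & cl[2:(n-1), ] == cl[3:n, ]
  nb_same[, 2:(m-1)] <- nb_same[, 2:(m-1)] &
    cl[, 2:(m-1)] == cl[, 1:(m-2)] & cl[, 2:(m-1)] == cl[, 3:m]
  expect_true(all(same[nb_same]))
})

test_that("habitat ensembles are sized and reproducible as specified", {
  a <- bistable_agent()
  spec <- list(n = 4, width = c(1, 1), offset = c(6, 10))
  e1 <- sample_habitat(a, spec, seed = 9, T = 20)
  e2 <- sample_habitat(a, spec, seed = 9, T = 20)
  expect_equal(length(e1$trajectories), 4)
  expect_identical(e1$draws, e2$draws)
  expect_identical(lapply(e1$trajectories, as.data.frame),
                   lapply(e2$trajectories, as.data.frame))
  e3 <- sample_habitat(a, spec, seed = 10, T = 20)
  expect_false(identical(e1$draws, e3$draws))
  expect_error(sample_habitat(a, list(n = 0), seed = 1), "n")
})
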
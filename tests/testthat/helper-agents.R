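# Hand-built fixtures used across the suite (all generated in code).

# bistable clamped dynamics: w11 > 4, folds symmetric about I = 0
bistable_agent <- function() agent_params(w11 = 6, w21 = 4, theta1 = -3,
                                          theta2 = 0, tau1 = 1, tau2 = 1,
                                          g_s = 10)

# monostable clamped dynamics for every input (w11 <= 4)
monostable_agent <- function(w11 = 3) agent_params(w11 = w11, w21 = 2,
                                                   theta1 = 0, theta2 = 0,
                                                   tau1 = 1, tau2 = 1,
                                                   g_s = 5)

# all-zero weights: pure leak, stationary from zero state
inert_agent <- function() agent_params(0, 0, 0, 0, 1, 1, 0)

unit_gaussian_world <- function(h = 1, w = 1, center = 0, L = 40)
  world(L, list(gaussian_object(center, h, w)))

# a synthetic trajectory object carrying prescribed series (for portrait
# and outcome tests that need closed-form signals)
synthetic_trajectory <- function(t, s, y2, p = NULL, v = NULL,
                                 world = unit_gaussian_world(),
                                 ds = NULL) {
  dt <- t[2] - t[1]
  n <- length(t)
  structure(list(t = t, p = if (is.null(p)) rep(0, n) else p, s = s,
                 ds = if (is.null(ds)) rep(0, n) else ds, y1 = rep(0, n),
                 y2 = y2, v = if (is.null(v)) rep(0, n) else v,
                 world = world, params = inert_agent(),
                 init = sim_state(0), dt = dt, motor_sign = 1,
                 ds_mode = "analytic"),
            class = "smc_trajectory")
}

random_params_draw <- function() {
  agent_params(w11 = runif(1, -16, 16), w21 = runif(1, -16, 16),
               theta1 = runif(1, -16, 16), theta2 = runif(1, -16, 16),
               tau1 = runif(1, 0.1, 10), tau2 = runif(1, 0.1, 10),
               g_s = runif(1, -50, 50))
}
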
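#' Initial condition of a closed-loop trial
#'
#' @param p initial body position, world units.
#' @param y1,y2 initial neuron activations.
#' @return a `sim_state` (named list).
#' @export
sim_state <- function(p, y1 = 0, y2 = 0) {
  stopifnot(is.finite(p), is.finite(y1), is.finite(y2))
  structure(list(p = p, y1 = y1, y2 = y2), class = "sim_state")
}

#' Run one closed-loop trial
#'
#' Integrates the coupled agent-environment system with forward Euler on a
#' uniform time grid.  At each stored sample `s = sense(p)`,
#' `ds = v * sense_gradient(p)` (analytic mode), the neuron states advance
#' by one Euler step driven by `ds`, and the body moves by `dt * v`.  The
#' run is fully deterministic: identical inputs give bit-identical
#' trajectories.
#'
#' `ds_mode = "finite"` replaces the analytic sensor derivative with the
#' backward difference `(s_t - s_{t-dt}) / dt` (zero at the first sample);
#' it exists as a numerical cross-check of the analytic coupling, not as a
#' default.  `clamp_velocity` forces the velocity to a constant, opening
#' the loop (a test hook; the neuron states still integrate).
#' `motor_sign = -1` negates the motor mapping, the lesion used to probe
#' the mirror symmetry of the behavior.
#'
#' @param world an [world()] object.
#' @param params an [agent_params()] object.
#' @param init a [sim_state()].
#' @param T trial duration, time units, `> 0`.
#' @param dt Euler step, time units, in `(0, 0.05]`.
#' @param ds_mode `"analytic"` (default) or `"finite"`.
#' @param clamp_velocity `NULL`, or a constant commanded velocity.
#' @param motor_sign `+1` or `-1`.
#' @return an `smc_trajectory`: list with numeric series `t`, `p`, `s`,
#'   `ds`, `y1`, `y2`, `v` (all the same length) plus metadata fields
#'   `world`, `params`, `init`, `dt`, `motor_sign`, `ds_mode`.
#' @export
#' @examples
#' w <- single_shape_world(width = 1, height = 0.8)
#' a <- agent_params(6, 4, -3, 0, 1, 1, 10)
#' tr <- run_trial(w, a, sim_state(p = 12), T = 20)
#' range(tr$s)
run_trial <- function(world, params, init, T = 100, dt = 0.01,
                      ds_mode = c("analytic", "finite"),
                      clamp_velocity = NULL, motor_sign = 1) {
  stopifnot(inherits(world, "smc_world"), inherits(params, "smc_agent"))
  if (!is.finite(T) || T <= 0) stop("'T' must be > 0")
  if (!is.finite(dt) || dt <= 0 || dt > 0.05)
    stop("'dt' must be in (0, 0.05]")
  ds_mode <- match.arg(ds_mode)
  stopifnot(motor_sign %in% c(-1, 1))
  v <- .world_vecs(world)
  clamped <- !is.null(clamp_velocity)
  raw <- cpp_run_trial(init$p, init$y1, init$y2, v$c, v$h, v$w,
                       world$circumference, params$w11, params$w21,
                       params$theta1, params$theta2, params$tau1,
                       params$tau2, params$g_s, params$v_max, T, dt,
                       if (ds_mode == "analytic") 0L else 1L,
                       if (clamped) clamp_velocity else 0.0, clamped,
                       motor_sign, TRUE)
  structure(c(raw, list(world = world, params = params, init = init,
                        dt = dt, motor_sign = motor_sign,
                        ds_mode = ds_mode)),
            class = "smc_trajectory")
}

# final-sample-only run used by the fitness battery (no series storage)
.run_final <- function(world, params, init, T, dt, motor_sign = 1) {
  v <- .world_vecs(world)
  cpp_run_trial(init$p, init$y1, init$y2, v$c, v$h, v$w,
                world$circumference, params$w11, params$w21, params$theta1,
                params$theta2, params$tau1, params$tau2, params$g_s,
                params$v_max, T, dt, 0L, 0.0, FALSE, motor_sign, FALSE)
}

#' @export
print.smc_trajectory <- function(x, ...) {
  cat(sprintf("<smc_trajectory> %d samples, dt = %g, T = %g\n",
              length(x$t), x$dt, x$t[length(x$t)]))
  cat(sprintf("  p in [%.3g, %.3g], s in [%.3g, %.3g], v in [%.3g, %.3g]\n",
              min(x$p), max(x$p), min(x$s), max(x$s), min(x$v), max(x$v)))
  invisible(x)
}

#' @export
as.data.frame.smc_trajectory <- function(x, ...) {
  data.frame(t = x$t, p = x$p, s = x$s, ds = x$ds,
             y1 = x$y1, y2 = x$y2, v = x$v)
}

#' Finite-difference sensor derivative along a stored trajectory
#'
#' Recomputes `ds/dt` from the stored `s(t)` series, as an independent
#' check of the analytic coupling `ds = v * sense_gradient(p)`.
#'
#' The `"midpoint"` scheme compares like with like for an Euler path: the
#' difference of `s` across one step is matched against the analytic
#' coupling evaluated at the spatial midpoint of that step
#' (`v_k * sense_gradient(p_k + dt v_k / 2)`), which agrees to second
#' order in `dt`.  `"central"` and `"backward"` difference the stored
#' series at the samples themselves and carry the first-order bias of the
#' piecewise-linear body path.
#'
#' @param traj an `smc_trajectory`.
#' @param scheme `"midpoint"` (second order, default), `"central"` or
#'   `"backward"`.
#' @return data frame with columns `t`, `ds_analytic`, `ds_fd`.
#' @export
trajectory_ds_fd <- function(traj,
                             scheme = c("midpoint", "central", "backward")) {
  scheme <- match.arg(scheme)
  s <- traj$s; dt <- traj$dt; n <- length(s)
  if (scheme == "midpoint") {
    i <- 1:(n - 1)
    fd <- (s[i + 1] - s[i]) / dt
    pm <- traj$p[i] + dt * traj$v[i] / 2
    ana <- traj$v[i] * sense_gradient(traj$world, pm)
    return(data.frame(t = traj$t[i] + dt / 2, ds_analytic = ana,
                      ds_fd = fd))
  }
  if (scheme == "central") {
    i <- 2:(n - 1)
    fd <- (s[i + 1] - s[i - 1]) / (2 * dt)
  } else {
    i <- 2:n
    fd <- (s[i] - s[i - 1]) / dt
  }
  data.frame(t = traj$t[i], ds_analytic = traj$ds[i], ds_fd = fd)
}

#' Outcome thresholds
#'
#' Tunables of [behavior_outcome()].  `approach_mult` and `avoid_mult`
#' scale the target width into distance thresholds; `tail_frac` is the
#' final fraction of the trial scored; `contact_s` defines first contact
#' for the oscillation flag; `min_sign_changes` is the oscillation
#' criterion.
#'
#' @param approach_mult,avoid_mult,tail_frac,contact_s,min_sign_changes
#'   numeric scalars; see Description.
#' @export
outcome_thresholds <- function(approach_mult = 2, avoid_mult = 4,
                               tail_frac = 0.2, contact_s = 0.05,
                               min_sign_changes = 3) {
  list(approach_mult = approach_mult, avoid_mult = avoid_mult,
       tail_frac = tail_frac, contact_s = contact_s,
       min_sign_changes = min_sign_changes)
}

# number of velocity sign changes from sample `from` on, ignoring zeros
.sign_changes <- function(v, from = 1) {
  sg <- sign(v[from:length(v)])
  sg <- sg[sg != 0]
  if (length(sg) < 2) return(0L)
  sum(diff(sg) != 0)
}

#' Score the behavioral outcome of a trial
#'
#' Labels a trajectory relative to a target shape: `approach` when the mean
#' absolute wrapped distance to the peak over the final fraction of the
#' trial is below `approach_mult * width`; `avoid` when the final distance
#' both exceeds the initial distance and `avoid_mult * width`; otherwise
#' `undecided`.  The oscillation flag is set when the velocity changes sign
#' at least `min_sign_changes` times after first contact (first sample with
#' `s > contact_s`).
#'
#' @param traj an `smc_trajectory`.
#' @param target a [gaussian_object()] present in the trajectory's world.
#' @param thresholds see [outcome_thresholds()].
#' @return an `smc_outcome`: list with `label`, `final_distance`,
#'   `initial_distance`, `mean_tail_distance`, `oscillation`,
#'   `sign_changes`, `dwell_side` (sign of the mean signed wrapped distance
#'   over the tail; which side of the peak the agent dwells on).
#' @export
behavior_outcome <- function(traj, target, thresholds = outcome_thresholds()) {
  stopifnot(inherits(traj, "smc_trajectory"), length(traj$p) > 0)
  L <- traj$world$circumference
  d <- wrapped_distance(traj$p, target$center, L)
  ad <- abs(d)
  n <- length(ad)
  tail_i <- seq.int(max(1L, n - floor(thresholds$tail_frac * n) + 1L), n)
  mean_tail <- mean(ad[tail_i])
  d0 <- ad[1]; dT <- ad[n]
  label <- if (mean_tail < thresholds$approach_mult * target$width) {
    "approach"
  } else if (dT > d0 && dT > thresholds$avoid_mult * target$width) {
    "avoid"
  } else "undecided"
  contact <- which(traj$s > thresholds$contact_s)[1]
  nsc <- if (is.na(contact)) 0L else .sign_changes(traj$v, contact)
  structure(list(label = label, final_distance = dT, initial_distance = d0,
                 mean_tail_distance = mean_tail,
                 oscillation = nsc >= thresholds$min_sign_changes,
                 sign_changes = nsc,
                 dwell_side = sign(mean(d[tail_i])),
                 contact_index = contact),
            class = "smc_outcome")
}

#' @export
print.smc_outcome <- function(x, ...) {
  cat(sprintf(
    "<smc_outcome> %s (final dist %.3g, tail mean %.3g, %d sign changes%s)\n",
    x$label, x$final_distance, x$mean_tail_distance, x$sign_changes,
    if (x$oscillation) ", oscillatory" else ""))
  invisible(x)
}

#' Run the canonical single-shape trial
#'
#' The canonical protocol: one shape of the given width and height at
#' mid-circle on a 40-unit track, the agent starting at a wrapped offset
#' from the peak with zeroed neurons, integrated for `T` time units.
#'
#' @param params an [agent_params()] object.
#' @param width,height shape parameters.
#' @param offset signed start offset from the peak, world units (default 8).
#' @param T,dt integration controls, as in [run_trial()].
#' @param motor_sign passed to [run_trial()].
#' @param L,center world geometry.
#' @return list with elements `trajectory`, `outcome`, `target`.
#' @export
canonical_trial <- function(params, width, height = 0.8, offset = 8,
                            T = 100, dt = 0.01, motor_sign = 1,
                            L = 40, center = 20) {
  w <- single_shape_world(width, height, center, L)
  tr <- run_trial(w, params, sim_state(wrap_position(center + offset, L)),
                  T = T, dt = dt, motor_sign = motor_sign)
  list(trajectory = tr, outcome = behavior_outcome(tr, w$objects[[1]]),
       target = w$objects[[1]])
}
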
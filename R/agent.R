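#' Construct agent parameters
#'
#' The controller is a two-neuron continuous-time recurrent neural network
#' (CTRNN) in the standard leaky-integrator form: a self-connected
#' interneuron driven by the time derivative of the sensor signal, feeding
#' a motor neuron that sets the agent's velocity.
#'
#' The dynamics are
#' \deqn{\tau_1 \dot y_1 = -y_1 + w_{11}\,\sigma(y_1+\theta_1) + g_s\,\Delta s}
#' \deqn{\tau_2 \dot y_2 = -y_2 + w_{21}\,\sigma(y_1+\theta_1)}
#' with \eqn{\sigma(x) = 1/(1+e^{-x})}, and the motor mapping
#' \eqn{v = v_{max}(2\sigma(y_2+\theta_2) - 1)}, so both movement
#' directions are reachable and `v` is strictly increasing in `y2`.
#'
#' Parameter ranges are the conventional CTRNN evolution box and double as
#' the genome bounds (see [genome_decode()]).
#'
#' @param w11 interneuron self-weight, in `[-16, 16]`.
#' @param w21 interneuron-to-motor weight, in `[-16, 16]`.
#' @param theta1,theta2 neuron biases, in `[-16, 16]`.
#' @param tau1,tau2 time constants, time units, in `[0.1, 10]`.
#' @param g_s sensor input gain, in `[-50, 50]`.
#' @param v_max speed scale, world units per time unit, `> 0` (fixed at 1
#'   for evolved agents to remove a scaling degeneracy).
#' @return an `smc_agent` object (named list of the parameters).
#' @export
#' @examples
#' a <- agent_params(w11 = 6, w21 = 4, theta1 = -3, theta2 = 0,
#'                   tau1 = 1, tau2 = 1, g_s = 10)
agent_params <- function(w11, w21, theta1, theta2, tau1, tau2, g_s,
                         v_max = 1) {
  chk <- function(x, lo, hi, nm) {
    if (!is.finite(x) || x < lo || x > hi)
      stop(sprintf("'%s' must be in [%g, %g], got %g", nm, lo, hi, x))
  }
  chk(w11, -16, 16, "w11"); chk(w21, -16, 16, "w21")
  chk(theta1, -16, 16, "theta1"); chk(theta2, -16, 16, "theta2")
  chk(tau1, 0.1, 10, "tau1"); chk(tau2, 0.1, 10, "tau2")
  chk(g_s, -50, 50, "g_s")
  if (!is.finite(v_max) || v_max <= 0) stop("'v_max' must be > 0")
  structure(list(w11 = w11, w21 = w21, theta1 = theta1, theta2 = theta2,
                 tau1 = tau1, tau2 = tau2, g_s = g_s, v_max = v_max),
            class = "smc_agent")
}

#' @export
print.smc_agent <- function(x, ...) {
  cat("<smc_agent> two-neuron CTRNN\n")
  cat(sprintf("  w11 %- .4g  w21 %- .4g  theta1 %- .4g  theta2 %- .4g\n",
              x$w11, x$w21, x$theta1, x$theta2))
  cat(sprintf("  tau1 %- .4g  tau2 %- .4g  g_s %- .4g  v_max %- .4g\n",
              x$tau1, x$tau2, x$g_s, x$v_max))
  invisible(x)
}

#' Agent internal state
#'
#' @param y1 interneuron activation.
#' @param y2 motor neuron activation.
#' @return an `agent_state` (named list).
#' @export
agent_state <- function(y1 = 0, y2 = 0) {
  stopifnot(is.finite(y1), is.finite(y2))
  structure(list(y1 = y1, y2 = y2), class = "agent_state")
}

#' Logistic activation
#' @param x numeric.
#' @return `1 / (1 + exp(-x))`.
#' @export
logistic <- function(x) 1 / (1 + exp(-x))

#' CTRNN state derivatives
#'
#' The right-hand side of the controller ODEs for a given sensory input
#' `ds` (the sensor time derivative).
#'
#' @param params an [agent_params()] object.
#' @param state an [agent_state()].
#' @param input sensor derivative `ds` driving the interneuron.
#' @return named numeric vector `c(dy1, dy2)`.
#' @export
internal_derivatives <- function(params, state, input) {
  stopifnot(is.finite(input))
  sig <- logistic(state$y1 + params$theta1)
  c(dy1 = (-state$y1 + params$w11 * sig + params$g_s * input) / params$tau1,
    dy2 = (-state$y2 + params$w21 * sig) / params$tau2)
}

#' Motor mapping
#'
#' Maps the motor neuron activation to velocity:
#' `v = v_max * (2 * logistic(y2 + theta2) - 1)`, an odd function of
#' `y2 + theta2` with range `(-v_max, v_max)`.
#'
#' @param params an [agent_params()] object.
#' @param state an [agent_state()], or a numeric `y2` value.
#' @return velocity, world units per time unit.
#' @export
motor_velocity <- function(params, state) {
  y2 <- if (is.list(state)) state$y2 else state
  params$v_max * (2 * logistic(y2 + params$theta2) - 1)
}

#' Read / write agent parameters
#'
#' Agents are stored as flat JSON documents, one key per parameter.  A file
#' missing the optional `v_max` key gets the default 1 (reported with a
#' message).  Numbers are written with 17 significant digits so that
#' save/load round-trips are exact.
#'
#' @param path file path.
#' @return [read_agent()] returns an `smc_agent`; [write_agent()] returns
#'   `path` invisibly.
#' @export
read_agent <- function(path) {
  x <- jsonlite::fromJSON(path)
  need <- c("w11", "w21", "theta1", "theta2", "tau1", "tau2", "g_s")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("agent file ", path, " is missing field(s): ",
         paste(miss, collapse = ", "))
  if (is.null(x$v_max)) {
    message("agent file has no 'v_max'; using default 1")
    x$v_max <- 1
  }
  agent_params(x$w11, x$w21, x$theta1, x$theta2, x$tau1, x$tau2, x$g_s,
               x$v_max)
}

#' @param agent an `smc_agent`.
#' @rdname read_agent
#' @export
write_agent <- function(agent, path) {
  stopifnot(inherits(agent, "smc_agent"))
  jsonlite::write_json(unclass(agent), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
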
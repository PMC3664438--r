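#' Combined sensorimotor-contingency report for one agent
#'
#' Runs the full analysis stack on one agent and bundles the verdicts:
#' the open-loop environment extrema, the quasi-static attractor-landscape
#' structure, the coordination verdicts for the approach and avoidance
#' conditions, and an (empty) sensorimotor-strategy slot.  The strategy
#' analysis requires a normative comparison among coordination
#' repertoires that this minimal task does not support, so the slot is a
#' placeholder by design.
#'
#' @param params an [agent_params()] object.
#' @param seed master seed; split into per-component streams.
#' @param n_battery trials per condition in the coordination battery.
#' @param narrow_width,wide_width the two category widths.
#' @param T,dt trial integration controls.
#' @return an `smc_report`: nested list ready for JSON serialization.
#' @export
smc_report <- function(params, seed = 1, n_battery = 10, narrow_width = 1,
                       wide_width = 3, T = 100, dt = 0.01) {
  stopifnot(inherits(params, "smc_agent"))
  streams <- split_seed(seed, 2)

  env <- lapply(c(narrow = narrow_width, wide = wide_width), function(wd) {
    surf <- smc_surface(single_shape_world(wd, height = 0.8))
    ex <- surface_extrema(surf)
    list(n_peaks = sum(ex$kind == "peak"),
         n_troughs = sum(ex$kind == "trough"),
         max_abs_value = max(abs(surf$value)),
         symmetry_residual = check_symmetry(surf, 20))
  })

  land <- attractor_landscape(single_shape_world(narrow_width,
                                                 height = 0.8), params)
  reg <- count_landscape_regions(land)
  st <- .swept_fixed_points(params, land)

  coord <- list(
    approach = .condition_coordination(params, narrow_width, "approach",
                                       "cycle", streams[1], n_battery, T,
                                       dt),
    avoid = .condition_coordination(params, wide_width, "avoid",
                                    "transient", streams[2], n_battery, T,
                                    dt))

  cfg <- list(seed = seed, n_battery = n_battery,
              narrow_width = narrow_width, wide_width = wide_width,
              T = T, dt = dt, params = unclass(params))
  structure(list(
    provenance = provenance(cfg, seed),
    agent = unclass(params),
    sm_environment = env,
    sm_habitat = list(
      n_regions_positive = reg$n_positive,
      n_regions_negative = reg$n_negative,
      n_regions_monostable = reg$n_monostable,
      n_bistable_cells = sum(land$class == "bistable"),
      min_abs_stable_velocity = st$min_abs_v,
      swept_input_range = st$I_range),
    sm_coordination = coord,
    sm_strategy = NULL), class = "smc_report")
}

# stable fixed points over the input range the landscape actually sweeps
.swept_fixed_points <- function(params, land) {
  I_range <- range(land$I)
  Is <- seq(I_range[1], I_range[2], length.out = 201)
  vs <- unlist(lapply(Is, function(I) {
    fp <- solve_fixed_points(params, I)
    fp$v[fp$stable]
  }))
  list(min_abs_v = min(abs(vs)), I_range = I_range)
}

.condition_coordination <- function(params, width, success_label, pattern,
                                    seed, n, T, dt) {
  ens <- sample_habitat(params,
                        list(n = n, width = c(width, width),
                             offset = c(6, 10), height = c(0.5, 1)),
                        seed = seed, T = T, dt = dt)
  reports <- if (pattern == "cycle")
    lapply(ens$trajectories,
           function(tr) detect_limit_cycle(rates_portrait(tr)))
  else lapply(ens$trajectories, transient_signature)
  verdict <- classify_coordination(reports, ens$outcomes, success_label,
                                   pattern)
  unclass(verdict)
}

#' Write an SMC report as JSON
#'
#' @param report an [smc_report()].
#' @param path output path.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}
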
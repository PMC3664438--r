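# Genome layout: 7 genes in [0,1], affinely mapped onto the parameter box.
# v_max is fixed at 1 and excluded to remove a scaling degeneracy between
# speed scale and time constants.
.gene_names <- c("w11", "w21", "theta1", "theta2", "tau1", "tau2", "g_s")
.gene_lo <- c(-16, -16, -16, -16, 0.1, 0.1, -50)
.gene_hi <- c( 16,  16,  16,  16, 10,  10,   50)

#' Decode / encode a genome
#'
#' A genome is a vector of 7 reals in `[0, 1]`, mapped affinely onto the
#' parameter ranges of [agent_params()] in the order `w11, w21, theta1,
#' theta2, tau1, tau2, g_s` (with `v_max` fixed at 1).  `genome_encode()`
#' inverts the map; the round trip is exact to 1e-12.
#'
#' @param genome numeric vector of 7 genes in `[0, 1]`.
#' @return [genome_decode()] returns an `smc_agent`; [genome_encode()] a
#'   genome vector.
#' @export
genome_decode <- function(genome) {
  if (length(genome) != 7 || any(!is.finite(genome)) ||
      any(genome < 0 | genome > 1))
    stop("genome must be 7 reals in [0, 1]")
  p <- as.list(.gene_lo + genome * (.gene_hi - .gene_lo))
  names(p) <- .gene_names
  agent_params(p$w11, p$w21, p$theta1, p$theta2, p$tau1, p$tau2, p$g_s,
               v_max = 1)
}

#' @param agent an `smc_agent` (with parameters inside the genome box).
#' @rdname genome_decode
#' @export
genome_encode <- function(agent) {
  p <- unlist(agent[.gene_names])
  (p - .gene_lo) / (.gene_hi - .gene_lo)
}

#' Build a discrimination trial battery
#'
#' The task battery: narrow (`w = 1`) shapes to approach and wide
#' (`w = 3`) shapes to avoid, with peak heights drawn uniformly from
#' `[0.5, 1]` and start offsets cycled through `{+-6, +-8, +-10}`, so that
#' within each trial the shapes can be told apart only by their steepness
#' and horizontal extent.  Deterministic given `seed`.
#'
#' @param seed integer seed for the height draws.
#' @param n_narrow,n_wide trial counts per class.
#' @param narrow_width,wide_width the two category widths.
#' @param height_range range of peak heights.
#' @param offsets pool of signed start offsets, world units.
#' @return data frame with columns `width`, `height`, `offset`, `kind`.
#' @export
fitness_battery <- function(seed = 1, n_narrow = 6, n_wide = 6,
                            narrow_width = 1, wide_width = 3,
                            height_range = c(0.5, 1),
                            offsets = c(6, 8, 10, -6, -8, -10)) {
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  n <- n_narrow + n_wide
  data.frame(
    width = c(rep(narrow_width, n_narrow), rep(wide_width, n_wide)),
    height = stats::runif(n, height_range[1], height_range[2]),
    offset = c(rep_len(offsets, n_narrow), rep_len(offsets, n_wide)),
    kind = c(rep("narrow", n_narrow), rep("wide", n_wide)))
}

#' Discrimination fitness of a genome
#'
#' Each trial runs the canonical single-shape protocol (track length 40,
#' shape at mid-circle, zeroed initial neurons, `T = 100`, `dt = 0.01`).
#' Narrow trials score `1 - min(1, d_final / d_start)` (full marks for
#' ending on the peak); wide trials score
#' `min(1, d_final / (L/2 - d_start))` (full marks for gaining the
#' maximum possible distance).  Fitness is the mean over trials, in
#' `[0, 1]`, and is deterministic given the battery.
#'
#' @param genome a 7-gene vector (see [genome_decode()]) or an
#'   `smc_agent`.
#' @param battery a [fitness_battery()] data frame.
#' @param T,dt trial integration controls.
#' @param motor_sign passed to the simulator (mirror-symmetry checks).
#' @return fitness in `[0, 1]`.
#' @export
fitness <- function(genome, battery = fitness_battery(), T = 100,
                    dt = 0.01, motor_sign = 1) {
  params <- if (inherits(genome, "smc_agent")) genome else
    genome_decode(genome)
  L <- 40; center <- 20
  scores <- vapply(seq_len(nrow(battery)), function(i) {
    w <- single_shape_world(battery$width[i], battery$height[i], center, L)
    fin <- .run_final(w, params,
                      sim_state(wrap_position(center + battery$offset[i], L)),
                      T, dt, motor_sign)
    d_final <- abs(wrapped_distance(fin$p, center, L))
    d_start <- abs(battery$offset[i])
    if (battery$kind[i] == "narrow") 1 - min(1, d_final / d_start)
    else min(1, d_final / (L / 2 - d_start))
  }, 0)
  mean(scores)
}

#' Evolution configuration
#'
#' @param pop population size, `>= 10`.
#' @param generations maximum generations, `>= 1`.
#' @param target early-stop fitness.
#' @param mut_sigma per-gene Gaussian mutation s.d. (reflected at the
#'   `[0, 1]` bounds).
#' @param cx_rate probability of uniform crossover per offspring.
#' @param battery_args arguments forwarded to [fitness_battery()] (the
#'   battery seed is derived from the evolution seed).
#' @export
evolve_config <- function(pop = 60, generations = 300, target = 1,
                          mut_sigma = 0.05, cx_rate = 0.5,
                          battery_args = list()) {
  if (pop < 10) stop("'pop' must be >= 10")
  if (generations < 1) stop("'generations' must be >= 1")
  list(pop = pop, generations = generations, target = target,
       mut_sigma = mut_sigma, cx_rate = cx_rate,
       battery_args = battery_args)
}

.reflect01 <- function(x) {
  while (any(x < 0 | x > 1)) {
    x <- ifelse(x < 0, -x, x)
    x <- ifelse(x > 1, 2 - x, x)
  }
  x
}

#' Evolve discrimination agents
#'
#' Generational real-valued genetic algorithm over the 7-gene genome:
#' rank-proportional parent selection, elitism of one, uniform crossover
#' at rate `cx_rate`, per-gene Gaussian mutation (`sd = mut_sigma`,
#' reflected into `[0, 1]`).  The fitness battery is drawn once from the
#' run seed and held fixed, so the best-so-far fitness is non-decreasing
#' and the whole run is reproducible from `seed`.
#'
#' @param config an [evolve_config()].
#' @param seed integer master seed.
#' @param verbose print per-generation progress.
#' @param trace_elites also record the elite genome of every generation
#'   (useful for harvesting diverse solvers from one run).
#' @return an `smc_evolution`: list with `best_genome`, `best_fitness`,
#'   `best_agent`, `history` (data frame `generation`, `best`, `mean`),
#'   `seed`, `config`, `battery`; plus `elites` (matrix, one row per
#'   generation) when `trace_elites = TRUE`.
#' @export
evolve_agents <- function(config = evolve_config(), seed = 1,
                          verbose = FALSE, trace_elites = FALSE) {
  old <- .save_rng(); on.exit(.restore_rng(old))
  streams <- split_seed(seed, 2)
  battery <- do.call(fitness_battery,
                     utils::modifyList(list(seed = streams[1]),
                                       config$battery_args))
  set.seed(streams[2])
  pop <- matrix(stats::runif(config$pop * 7), config$pop, 7)
  fit <- apply(pop, 1, fitness, battery = battery)
  hist <- data.frame(generation = 0L, best = max(fit), mean = mean(fit))
  elites <- if (trace_elites) pop[which.max(fit), , drop = FALSE]
  for (gen in seq_len(config$generations)) {
    if (max(fit) >= config$target) break
    rk <- rank(fit, ties.method = "first")
    probs <- rk / sum(rk)
    elite <- which.max(fit)
    newpop <- matrix(0, config$pop, 7)
    newpop[1, ] <- pop[elite, ]
    for (i in 2:config$pop) {
      par <- sample.int(config$pop, 2, prob = probs, replace = TRUE)
      child <- pop[par[1], ]
      if (stats::runif(1) < config$cx_rate) {
        mask <- stats::runif(7) < 0.5
        child[mask] <- pop[par[2], mask]
      }
      newpop[i, ] <- .reflect01(child + stats::rnorm(7, 0, config$mut_sigma))
    }
    pop <- newpop
    fit <- c(fit[elite], apply(pop[-1, , drop = FALSE], 1, fitness,
                               battery = battery))
    hist <- rbind(hist, data.frame(generation = gen, best = max(fit),
                                   mean = mean(fit)))
    if (trace_elites) elites <- rbind(elites, pop[which.max(fit), ])
    if (verbose && gen %% 10 == 0)
      message(sprintf("gen %d: best %.4f mean %.4f", gen, max(fit),
                      mean(fit)))
  }
  best <- which.max(fit)
  out <- list(best_genome = pop[best, ], best_fitness = fit[best],
              best_agent = genome_decode(pop[best, ]), history = hist,
              seed = seed, config = config, battery = battery)
  if (trace_elites) out$elites <- elites
  structure(out, class = "smc_evolution")
}

#' @export
print.smc_evolution <- function(x, ...) {
  cat(sprintf(
    "<smc_evolution> seed %d: best fitness %.4f after %d generation(s)\n",
    x$seed, x$best_fitness, max(x$history$generation)))
  invisible(x)
}

#' Load the shipped reference evolved agent
#'
#' The package ships one frozen evolved genome, selected among successful
#' GA runs for matching the qualitative solution class of the task:
#' oscillatory approach to narrow shapes, transient avoidance of wide
#' ones, a four-region attractor landscape on the narrow shape, and no
#' near-zero-velocity attractor.  All habitat and coordination analyses in
#' the documentation and tests use this agent.
#'
#' @return an `smc_agent` with attributes `genome`, `fitness` (on the
#'   freeze battery), `seed` (the evolution seed that produced it).
#' @export
reference_agent <- function() {
  path <- system.file("extdata", "reference_agent.json",
                      package = "smcagent")
  if (path == "" || !file.exists(path))
    stop("reference agent fixture is missing from the installation")
  x <- jsonlite::fromJSON(path)
  if (is.null(x$genome) || length(x$genome) != 7)
    stop("reference agent fixture is corrupt (no 7-gene genome)")
  a <- genome_decode(as.numeric(x$genome))
  attr(a, "genome") <- as.numeric(x$genome)
  attr(a, "fitness") <- x$fitness
  attr(a, "seed") <- x$seed
  a
}

#' Write a genome file
#'
#' Genome files carry the genes plus the evolution seed and the fitness
#' achieved, as flat JSON.
#'
#' @param genome 7-gene numeric vector.
#' @param path output path.
#' @param seed,fitness provenance fields.
#' @export
write_genome <- function(genome, path, seed = NA, fitness = NA) {
  stopifnot(length(genome) == 7)
  jsonlite::write_json(list(genome = as.numeric(genome), seed = seed,
                            fitness = fitness),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_genome
#' @export
read_genome <- function(path) {
  x <- jsonlite::fromJSON(path)
  if (is.null(x$genome) || length(x$genome) != 7)
    stop("genome file must contain a 7-gene 'genome' field")
  x$genome <- as.numeric(x$genome)
  x
}

#' Split a master seed into component streams
#'
#' Derives `n` independent 31-bit child seeds from one master seed, so
#' that a single invocation seed reproducibly controls every stochastic
#' component (battery draws, population initialization, habitat
#' sampling).
#'
#' @param seed non-negative integer master seed.
#' @param n number of streams.
#' @return integer vector of `n` seeds.
#' @export
split_seed <- function(seed, n) {
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}
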
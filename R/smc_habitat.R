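#' Fixed points of the clamped internal dynamics
#'
#' Quasi-static analysis clamps the sensory drive `I = g_s * ds` as a fixed
#' parameter and asks where the interneuron would settle: the roots of
#' `F(y1) = -y1 + w11 * logistic(y1 + theta1) + I`.  Roots are located by a
#' dense sign-change scan over `y1 in [-|I| - 20, |I| + 20]` (step 1e-3)
#' followed by bisection to 1e-12, and classified stable when
#' `F'(y1*) < 0`; near-tangent roots (`|F'| < 1e-8`) are flagged
#' non-stable.  For `w11 <= 4` the logistic slope bound
#' (`w11 * sigma' <= w11/4 <= 1`) guarantees a single root for every `I`;
#' for `w11 > 4` there is a saddle-node pair and up to three roots.
#'
#' The motor neuron has no feedback, so each interneuron root carries
#' `y2* = w21 * logistic(y1* + theta1)` and the steady-state velocity
#' `v* = motor_velocity(y2*)`.
#'
#' @param params an [agent_params()] object.
#' @param I clamped input drive (the product `g_s * ds`), finite scalar.
#' @return data frame with one row per fixed point: `I`, `y1`, `y2`, `v`,
#'   `stable`; ordered by `y1`.
#' @export
#' @examples
#' a <- agent_params(6, 4, -3, 0, 1, 1, 10)
#' solve_fixed_points(a, 0)   # bistable: three roots, outer two stable
solve_fixed_points <- function(params, I) {
  stopifnot(is.finite(I))
  w11 <- params$w11; th1 <- params$theta1
  F <- function(y) -y + w11 * logistic(y + th1) + I
  lim <- abs(I) + 20
  ys <- seq(-lim, lim, by = 1e-3)
  fv <- F(ys)
  roots <- ys[fv == 0]
  sw <- which(fv[-1] * fv[-length(fv)] < 0)
  for (i in sw) {
    r <- stats::uniroot(F, c(ys[i], ys[i + 1]), tol = 1e-12)
    roots <- c(roots, r$root)
  }
  roots <- sort(unique(roots))
  if (length(roots) == 0)
    stop("no fixed point found in scan range (should not happen)")
  sig <- logistic(roots + th1)
  Fp <- -1 + w11 * sig * (1 - sig)
  y2 <- params$w21 * sig
  data.frame(I = I, y1 = roots, y2 = y2,
             v = motor_velocity(params, y2),
             stable = Fp < 0 & abs(Fp) >= 1e-8)
}

# Saddle-node fold inputs of the clamped interneuron.  For w11 > 4 the map
# G(y1) = y1 - w11 * logistic(y1 + theta1) (roots of F <=> G(y1) = I) has a
# local max I_hi at y_lo and local min I_lo at y_hi; bistable for
# I in (I_lo, I_hi).  NULL when monostable for all I (w11 <= 4).
.fold_points <- function(params) {
  w11 <- params$w11; th1 <- params$theta1
  if (w11 <= 4) return(NULL)
  disc <- sqrt(1 - 4 / w11)
  u <- c((1 - disc) / 2, (1 + disc) / 2)     # sigma values at criticality
  x <- log(u / (1 - u))
  y_crit <- sort(x - th1)                    # y_lo (local max of G), y_hi
  G <- function(y) y - w11 * logistic(y + th1)
  list(y_lo = y_crit[1], y_hi = y_crit[2],
       I_hi = G(y_crit[1]), I_lo = G(y_crit[2]))
}

#' Bifurcation diagram of the clamped interneuron
#'
#' Sweeps the clamped input `I` and assembles the fixed-point branches,
#' matching roots across consecutive `I` values by nearest-`y1`
#' continuity.  Where the branch count changes, a bifurcation (saddle-node
#' fold) point is recorded at the midpoint of the bracketing `I` step;
#' folds come in pairs or are absent.
#'
#' @param params an [agent_params()] object.
#' @param I_range length-2 numeric, the swept input interval.
#' @param I_step sweep step, `> 0`.
#' @return an `smc_bifurcation`: list with `points` (data frame `I`, `y1`,
#'   `v`, `stable`, `branch_id`), `bifurcations` (numeric vector of fold
#'   `I` values, located to within `I_step`), `I_range`, `I_step`.
#' @export
bifurcation_diagram <- function(params, I_range = c(-5, 5), I_step = 0.01) {
  stopifnot(length(I_range) == 2, all(is.finite(I_range)), I_step > 0)
  Is <- seq(I_range[1], I_range[2], by = I_step)
  rows <- vector("list", length(Is))
  branch_y <- numeric(0)          # last y1 of each open branch
  branch_ids <- integer(0)
  next_id <- 1L
  bif <- numeric(0)
  prev_count <- NA_integer_
  for (k in seq_along(Is)) {
    fp <- solve_fixed_points(params, Is[k])
    ids <- integer(nrow(fp))
    used <- logical(length(branch_y))
    for (r in order(fp$y1)) {
      if (length(branch_y)) {
        d <- abs(branch_y - fp$y1[r])
        d[used] <- Inf
        j <- which.min(d)
      }
      if (length(branch_y) && is.finite(d[j]) && d[j] < 1) {
        ids[r] <- branch_ids[j]; branch_y[j] <- fp$y1[r]; used[j] <- TRUE
      } else {
        ids[r] <- next_id
        branch_ids <- c(branch_ids, next_id)
        branch_y <- c(branch_y, fp$y1[r])
        used <- c(used, TRUE)
        next_id <- next_id + 1L
      }
    }
    keep <- used
    branch_y <- branch_y[keep]; branch_ids <- branch_ids[keep]
    if (!is.na(prev_count) && nrow(fp) != prev_count)
      bif <- c(bif, Is[k] - I_step / 2)
    prev_count <- nrow(fp)
    rows[[k]] <- cbind(fp, branch_id = ids)
  }
  structure(list(points = do.call(rbind, rows), bifurcations = bif,
                 I_range = I_range, I_step = I_step),
            class = "smc_bifurcation")
}

#' @export
print.smc_bifurcation <- function(x, ...) {
  nb <- length(unique(x$points$branch_id))
  cat(sprintf("<smc_bifurcation> I in [%g, %g] step %g: %d branch(es), %d fold point(s)",
              x$I_range[1], x$I_range[2], x$I_step, nb,
              length(x$bifurcations)))
  if (length(x$bifurcations))
    cat(" at I ~", paste(signif(x$bifurcations, 4), collapse = ", "))
  cat("\n")
  invisible(x)
}

# Vectorized stable-root lookup used by the landscape: inverts the
# monotone branches of G(y1) = y1 - w11*logistic(y1+theta1) by linear
# interpolation on dense tables.  Returns a list of functions of I.
.branch_inverters <- function(params, I_max) {
  w11 <- params$w11; th1 <- params$theta1
  G <- function(y) y - w11 * logistic(y + th1)
  lim <- I_max + abs(w11) + 5
  fold <- .fold_points(params)
  step <- 1e-3
  if (is.null(fold)) {
    ys <- seq(-lim, lim, by = step)
    tab <- list(x = G(ys), y = ys)
    list(fold = NULL,
         lower = function(I) stats::approx(tab$x, tab$y, xout = I,
                                           rule = 2)$y)
  } else {
    y_lower <- seq(-lim, fold$y_lo, by = step)
    y_upper <- seq(fold$y_hi, lim, by = step)
    tl <- list(x = G(y_lower), y = y_lower)
    tu <- list(x = G(y_upper), y = y_upper)
    list(fold = fold,
         lower = function(I) stats::approx(tl$x, tl$y, xout = I, rule = 2)$y,
         upper = function(I) stats::approx(tu$x, tu$y, xout = I, rule = 2)$y)
  }
}

#' Quasi-static attractor landscape over position and velocity
#'
#' For every grid cell the sensory drive the agent would receive while
#' commanding velocity `v` at position `p` is clamped
#' (`I = g_s * v * sense_gradient(p)`) and the stable steady states of the
#' internal dynamics are computed.  Cells are classified by the signs of
#' the stable steady-state velocities: `"positive"`, `"negative"`, or
#' `"bistable"` when two stable states of opposite velocity sign coexist
#' (two stable states of equal sign classify by that sign).
#'
#' @param world an [world()] object.
#' @param params an [agent_params()] object.
#' @param p_grid,v_grid grids; defaults `center +/- 3 * width` step 0.05
#'   and `[-1, 1]` step 0.02 for single-object worlds.
#' @return an `smc_landscape`: list with `p`, `v`, `class` (character
#'   matrix), `v_lower`, `v_upper` (stable steady-state velocity matrices;
#'   `v_upper` is `NA` where only one stable state exists), `I` (drive
#'   matrix), `params`, `world`.
#' @export
attractor_landscape <- function(world, params, p_grid = NULL,
                                v_grid = NULL) {
  stopifnot(inherits(world, "smc_world"), inherits(params, "smc_agent"))
  if (is.null(p_grid)) {
    if (length(world$objects) != 1)
      stop("default grids require a single-object world; pass p_grid")
    o <- world$objects[[1]]
    p_grid <- symmetric_grid(o$center, 3 * o$width, 0.05)
  }
  if (is.null(v_grid)) v_grid <- symmetric_grid(0, 1, 0.02)
  I <- params$g_s * outer(sense_gradient(world, p_grid), v_grid)
  inv <- .branch_inverters(params, max(abs(I)))
  vel <- function(y1) motor_velocity(params,
                                     params$w21 * logistic(y1 + params$theta1))
  v_lower <- matrix(vel(inv$lower(as.vector(I))), nrow(I), ncol(I))
  v_upper <- matrix(NA_real_, nrow(I), ncol(I))
  cls <- matrix(ifelse(v_lower >= 0, "positive", "negative"),
                nrow(I), ncol(I))
  if (!is.null(inv$fold)) {
    bist <- I > inv$fold$I_lo & I < inv$fold$I_hi
    if (any(bist)) {
      vu <- vel(inv$upper(I[bist]))
      v_upper[bist] <- vu
      vl <- v_lower[bist]
      cls[bist] <- ifelse(sign(vl) == sign(vu),
                          ifelse(vl >= 0, "positive", "negative"),
                          "bistable")
    }
    mono_hi <- I >= inv$fold$I_hi   # only the upper branch survives
    if (any(mono_hi)) {
      vu <- vel(inv$upper(I[mono_hi]))
      v_lower[mono_hi] <- vu
      cls[mono_hi] <- ifelse(vu >= 0, "positive", "negative")
    }
  }
  structure(list(p = p_grid, v = v_grid, class = cls, v_lower = v_lower,
                 v_upper = v_upper, I = I, params = params, world = world),
            class = "smc_landscape")
}

#' @export
print.smc_landscape <- function(x, ...) {
  tab <- table(factor(x$class, c("positive", "negative", "bistable")))
  cat(sprintf("<smc_landscape> %d x %d grid: %d positive, %d negative, %d bistable cells\n",
              length(x$p), length(x$v), tab[1], tab[2], tab[3]))
  invisible(x)
}

# 4-connected component labelling of a logical matrix (iterative BFS)
.label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  idx <- which(mask)
  for (start in idx) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    stack <- start
    lab[start] <- cur
    while (length(stack)) {
      cell <- stack[length(stack)]
      stack <- stack[-length(stack)]
      r <- (cell - 1L) %% nr + 1L
      cl <- (cell - 1L) %/% nr + 1L
      nb <- c(if (r > 1L) cell - 1L, if (r < nr) cell + 1L,
              if (cl > 1L) cell - nr, if (cl < nc) cell + nr)
      nb <- nb[mask[nb] & lab[nb] == 0L]
      lab[nb] <- cur
      stack <- c(stack, nb)
    }
  }
  list(labels = lab, n = cur)
}

#' Count connected monostable regions of a landscape
#'
#' 4-connected components of the monostable cells, counted separately for
#' positive- and negative-velocity classes (bistable cells act as
#' separators).  For an evolved discriminator on a single narrow shape the
#' landscape resolves the four smooth extrema of the sensorimotor
#' environment into four discrete regions of attraction (two positive, two
#' negative).
#'
#' @param landscape an [attractor_landscape()].
#' @return list with `n_positive`, `n_negative`, `n_monostable` (their
#'   sum) and the label matrices.
#' @export
count_landscape_regions <- function(landscape) {
  pos <- .label_components(landscape$class == "positive")
  neg <- .label_components(landscape$class == "negative")
  list(n_positive = pos$n, n_negative = neg$n,
       n_monostable = pos$n + neg$n,
       labels_positive = pos$labels, labels_negative = neg$labels)
}

#' Attractor a state converges to under clamped input
#'
#' Integrates the clamped internal dynamics from the given state for up to
#' `T_max` time units and returns the stable fixed point the endpoint
#' matches (within `tol` in `y1`).  In this one-dimensional clamped system
#' the basin boundary is the unstable fixed point; a state started on it
#' (or failing to converge) is flagged by returning `NULL` with a warning.
#'
#' @param params an [agent_params()] object.
#' @param state an [agent_state()].
#' @param I clamped input drive.
#' @param T_max integration budget, time units.
#' @param dt Euler step.
#' @param tol matching tolerance in `y1`.
#' @return one row of [solve_fixed_points()] output with extra columns
#'   `y1_end`, `y2_end` (the raw integration endpoint, for oracle
#'   comparisons), or `NULL` if non-convergent within budget.
#' @export
tendency <- function(params, state, I, T_max = 200, dt = 0.01, tol = 1e-3) {
  fp <- solve_fixed_points(params, I)
  if (!any(fp$stable)) stop("no stable fixed point at I = ", I)
  y1 <- state$y1; y2 <- state$y2
  n <- ceiling(T_max / dt)
  for (k in seq_len(n)) {
    sig <- logistic(y1 + params$theta1)
    y1 <- y1 + dt * (-y1 + params$w11 * sig + I) / params$tau1
    y2 <- y2 + dt * (-y2 + params$w21 * sig) / params$tau2
  }
  st <- fp[fp$stable, , drop = FALSE]
  d <- abs(st$y1 - y1)
  if (min(d) > tol) {
    warning("state did not converge to a stable fixed point within budget ",
            "(basin boundary?)")
    return(NULL)
  }
  out <- st[which.min(d), , drop = FALSE]
  out$y1_end <- y1
  out$y2_end <- y2
  out
}

#' Sample a sensorimotor habitat ensemble
#'
#' The habitat is the set of trajectories the closed-loop system actually
#' produces over ranges of the relevant boundary conditions.  This draws a
#' battery of canonical single-shape trials with start offsets, shape
#' widths/heights and initial neuron states sampled uniformly from the
#' given ranges, deterministically under `seed`.
#'
#' @param params an [agent_params()] object.
#' @param spec sampling specification: list with `n` (number of trials)
#'   and ranges `offset` (length-2, world units; a sign is drawn
#'   separately), `width`, `height`, `y1`, `y2` (each length-2; degenerate
#'   ranges allowed).  Missing entries default to the canonical protocol
#'   (`offset c(6,10)`, `width c(1,1)`, `height c(0.5,1)`, zero states).
#' @param seed integer seed; same seed, same ensemble.
#' @param T,dt integration controls.
#' @return an `smc_ensemble`: list with `trajectories`, `targets`,
#'   `outcomes`, `draws` (data frame of sampled values), `spec`, `seed`.
#' @export
sample_habitat <- function(params, spec = list(), seed = 1, T = 100,
                           dt = 0.01) {
  if (!length(spec) && !is.list(spec)) stop("empty sampling spec")
  dflt <- list(n = 10, offset = c(6, 10), width = c(1, 1),
               height = c(0.5, 1), y1 = c(0, 0), y2 = c(0, 0),
               signed_offsets = TRUE)
  spec <- utils::modifyList(dflt, spec)
  if (!is.numeric(spec$n) || spec$n < 1) stop("spec$n must be >= 1")
  n <- as.integer(spec$n)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  ru <- function(rng) stats::runif(n, rng[1], rng[2])
  draws <- data.frame(
    offset = ru(spec$offset) *
      (if (isTRUE(spec$signed_offsets)) sample(c(-1, 1), n, TRUE) else 1),
    width = ru(spec$width), height = ru(spec$height),
    y1 = ru(spec$y1), y2 = ru(spec$y2))
  trials <- lapply(seq_len(n), function(i) {
    w <- single_shape_world(draws$width[i], draws$height[i])
    tr <- run_trial(w, params,
                    sim_state(wrap_position(20 + draws$offset[i], 40),
                              draws$y1[i], draws$y2[i]),
                    T = T, dt = dt)
    list(trajectory = tr, target = w$objects[[1]],
         outcome = behavior_outcome(tr, w$objects[[1]]))
  })
  structure(list(trajectories = lapply(trials, `[[`, "trajectory"),
                 targets = lapply(trials, `[[`, "target"),
                 outcomes = lapply(trials, `[[`, "outcome"),
                 draws = draws, spec = spec, seed = seed),
            class = "smc_ensemble")
}

#' @export
print.smc_ensemble <- function(x, ...) {
  labs <- vapply(x$outcomes, `[[`, "", "label")
  cat(sprintf("<smc_ensemble> %d trajectories (seed %d): %s\n",
              length(x$trajectories), x$seed,
              paste(names(table(labs)), table(labs), collapse = ", ",
                    sep = ":")))
  invisible(x)
}

.save_rng <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
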
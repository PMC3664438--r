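#' Symmetric grid about a center
#'
#' Builds a uniform grid whose points come in exact floating-point mirror
#' pairs about `center`, which keeps symmetry residuals of analytically
#' symmetric surfaces at zero.
#'
#' @param center grid center.
#' @param halfwidth half extent, `> 0`.
#' @param step grid step, `> 0`.
#' @export
symmetric_grid <- function(center, halfwidth, step) {
  stopifnot(halfwidth > 0, step > 0)
  offs <- seq(0, halfwidth, by = step)
  center + c(-rev(offs[-1]), offs)
}

#' Compute the open-loop sensorimotor environment surface
#'
#' The sensorimotor environment treats the motor command as a free
#' variable: with the loop cut at the motor neuron, the sensory change
#' produced by commanding velocity `v` at position `p` is
#' `value(p, v) = v * sense_gradient(world, p)`.  The surface depends only
#' on the world and the sensor interface, never on the agent's internal
#' parameters or state.
#'
#' @param world an [world()] object.
#' @param p_grid,v_grid uniform, nonempty grids of positions (world units)
#'   and commanded velocities.  Defaults cover `center +/- 3 * max(width)`
#'   at step 0.01 and `v` in `[-1, 1]` at step 0.01 (single-object worlds
#'   only; pass grids explicitly otherwise).
#' @return an `smc_surface`: list with `p`, `v`, `value` (a
#'   `length(p) x length(v)` matrix, sensor units per time unit) and
#'   `world`.
#' @export
#' @examples
#' w <- single_shape_world(width = 1, height = 1)
#' s <- smc_surface(w)
#' max(abs(s$value))
smc_surface <- function(world, p_grid = NULL, v_grid = NULL) {
  stopifnot(inherits(world, "smc_world"))
  if (is.null(p_grid)) {
    if (length(world$objects) != 1)
      stop("default grids require a single-object world; pass p_grid")
    o <- world$objects[[1]]
    p_grid <- symmetric_grid(o$center, 3 * o$width, 0.01)
  }
  if (is.null(v_grid)) v_grid <- symmetric_grid(0, 1, 0.01)
  stopifnot(length(p_grid) > 0, length(v_grid) > 0)
  g <- sense_gradient(world, p_grid)
  structure(list(p = p_grid, v = v_grid, value = outer(g, v_grid),
                 world = world),
            class = "smc_surface")
}

#' @export
print.smc_surface <- function(x, ...) {
  cat(sprintf(
    "<smc_surface> %d x %d grid, p in [%.3g, %.3g], v in [%.3g, %.3g]\n",
    length(x$p), length(x$v), min(x$p), max(x$p), min(x$v), max(x$v)))
  cat(sprintf("  |value| max %.4g\n", max(abs(x$value))))
  invisible(x)
}

#' Grid-local extrema of a sensorimotor surface
#'
#' Finds local maxima (peaks) and minima (troughs) of the surface value by
#' strict 8-neighbor comparison, boundary cells included (missing
#' neighbors are ignored).  Cells on the zero plateau (value exactly 0,
#' e.g. the `v = 0` row and empty regions) are excluded, so the flat
#' background never yields spurious extrema.  For a single Gaussian shape
#' the surface has exactly two peaks and two troughs, at the points of
#' greatest slope of the bell (`p = center +/- width`) on the velocity
#' boundary.
#'
#' @param surface an [smc_surface()].
#' @return data frame with columns `p`, `v`, `value`, `kind`
#'   (`"peak"`/`"trough"`), possibly empty.
#' @export
surface_extrema <- function(surface) {
  stopifnot(inherits(surface, "smc_surface"))
  m <- surface$value
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(NA_real_, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- m
  shifts <- expand.grid(dr = -1:1, dc = -1:1)
  shifts <- shifts[!(shifts$dr == 0 & shifts$dc == 0), ]
  is_max <- matrix(TRUE, nr, nc); is_min <- matrix(TRUE, nr, nc)
  for (k in seq_len(nrow(shifts))) {
    nb <- pad[2:(nr + 1) + shifts$dr[k], 2:(nc + 1) + shifts$dc[k]]
    cmp_max <- m > nb; cmp_max[is.na(cmp_max)] <- TRUE
    cmp_min <- m < nb; cmp_min[is.na(cmp_min)] <- TRUE
    is_max <- is_max & cmp_max
    is_min <- is_min & cmp_min
  }
  nonzero <- m != 0
  res <- rbind(
    if (any(is_max & nonzero)) {
      idx <- which(is_max & nonzero, arr.ind = TRUE)
      data.frame(p = surface$p[idx[, 1]], v = surface$v[idx[, 2]],
                 value = m[idx], kind = "peak")
    },
    if (any(is_min & nonzero)) {
      idx <- which(is_min & nonzero, arr.ind = TRUE)
      data.frame(p = surface$p[idx[, 1]], v = surface$v[idx[, 2]],
                 value = m[idx], kind = "trough")
    })
  if (is.null(res))
    res <- data.frame(p = numeric(), v = numeric(), value = numeric(),
                      kind = character())
  res[order(res$p, res$v), , drop = FALSE]
}

#' Symmetry residual of a sensorimotor surface
#'
#' For an isolated symmetric object the surface obeys the two-fold
#' symmetry `S(center + d, v) = S(center - d, -v)` (one fold from the
#' bell shape, one from the agent's ability to move either way).  Returns
#' the worst-case violation `max |S(c+d, v) - S(c-d, -v)|` over the grid;
#' exactly 0 for a single object on a mirror-symmetric grid.
#'
#' @param surface an [smc_surface()] computed on grids symmetric about
#'   `center` (positions) and 0 (velocities); asymmetric grids are a usage
#'   error.
#' @param center the symmetry center (an object's peak position).
#' @return the maximum absolute asymmetry, `>= 0`.
#' @export
check_symmetry <- function(surface, center) {
  stopifnot(inherits(surface, "smc_surface"))
  p_off <- surface$p - center
  if (max(abs(p_off + rev(p_off))) > 1e-9 ||
      max(abs(surface$v + rev(surface$v))) > 1e-9)
    stop("grids must be symmetric about 'center' (positions) and 0 ",
         "(velocities); see symmetric_grid()")
  mirrored <- surface$value[rev(seq_along(surface$p)),
                            rev(seq_along(surface$v)), drop = FALSE]
  max(abs(surface$value - mirrored))
}

#' Clamped-velocity finite-difference oracle for the surface
#'
#' Recomputes surface values from the sensor alone: moving at commanded
#' velocity `v` for a short time `delta` changes the sensor by about
#' `(sense(p + v * delta) - sense(p - v * delta)) / (2 * delta)`.  Used to
#' cross-check [smc_surface()] values independently of the analytic
#' gradient.
#'
#' @param world an [world()] object.
#' @param p,v equal-length vectors of positions and velocities.
#' @param delta half time step of the central difference.
#' @return numeric vector of approximate `ds/dt` values.
#' @export
surface_fd_oracle <- function(world, p, v, delta = 1e-4) {
  (sense(world, p + v * delta) - sense(world, p - v * delta)) / (2 * delta)
}

#' Export a surface as long-format CSV
#'
#' @param surface an [smc_surface()].
#' @param path output CSV path (columns `p`, `v`, `value`).
#' @export
write_surface <- function(surface, path) {
  df <- data.frame(p = rep(surface$p, times = length(surface$v)),
                   v = rep(surface$v, each = length(surface$p)),
                   value = as.vector(surface$value))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
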
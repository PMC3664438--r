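#' Construct a Gaussian object
#'
#' A bell-shaped gradient on the circular track, the stimulus of the
#' categorical perception task.  The sensor field it generates at wrapped
#' distance `d` from its center is `height * exp(-d^2 / (2 * width^2))`.
#'
#' @param center position of the peak, in world units, in `[0, L)`.
#' @param height peak sensor value, in normalized sensor units, in `(0, 1]`.
#' @param width standard-deviation-like horizontal scale, world units, `> 0`.
#' @return a `gaussian_object`: a named list with fields `center`, `height`,
#'   `width`.
#' @export
#' @examples
#' gaussian_object(center = 20, height = 0.8, width = 1)
gaussian_object <- function(center, height, width) {
  if (!is.finite(height) || height <= 0 || height > 1)
    stop("'height' must be in (0, 1], got ", height)
  if (!is.finite(width) || width <= 0)
    stop("'width' must be > 0, got ", width)
  if (!is.finite(center))
    stop("'center' must be finite")
  structure(list(center = center, height = height, width = width),
            class = "gaussian_object")
}

#' Construct a circular 1-D world
#'
#' The environment is a circle of circumference `circumference` carrying a
#' static sensor field built from Gaussian bumps (see [gaussian_object()]).
#' Object centers are wrapped into `[0, circumference)`.
#'
#' Analyses that treat the field near an object as a single isolated shape
#' (surface symmetry, extremum location) assume objects do not overlap; a
#' warning is issued when any pair of centers is closer than six times the
#' largest width.
#'
#' @param circumference length of the circular track, world units, `> 0`.
#'   The default of 40 leaves narrow (`w = 1`) and wide (`w = 3`) shapes
#'   well separated from their own wrap-around tails.
#' @param objects a list of [gaussian_object()]s (or of plain lists with
#'   fields `center`, `height`, `width`).
#' @return an `smc_world` object.
#' @export
#' @examples
#' w <- world(40, list(gaussian_object(20, 0.8, 1)))
#' sense(w, 20)
world <- function(circumference = 40, objects = list()) {
  if (!is.finite(circumference) || circumference <= 0)
    stop("'circumference' must be > 0")
  objects <- lapply(objects, function(o) {
    gaussian_object(wrap_position(o$center, circumference), o$height, o$width)
  })
  w <- structure(list(circumference = circumference, objects = objects),
                 class = "smc_world")
  .check_separation(w)
  w
}

.check_separation <- function(w) {
  n <- length(w$objects)
  if (n < 2) return(invisible(TRUE))
  wmax <- max(vapply(w$objects, `[[`, 0, "width"))
  cs <- vapply(w$objects, `[[`, 0, "center")
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- abs(wrapped_distance(cs[i], cs[j], w$circumference))
    if (d < 6 * wmax)
      warning(sprintf(
        "objects %d and %d are separated by %.3g < 6 * max width (%.3g); ",
        i, j, d, 6 * wmax),
        "single-shape analyses (symmetry, extrema) may not apply",
        call. = FALSE)
  }
  invisible(TRUE)
}

.world_vecs <- function(w) {
  list(c = vapply(w$objects, `[[`, 0, "center"),
       h = vapply(w$objects, `[[`, 0, "height"),
       w = vapply(w$objects, `[[`, 0, "width"))
}

#' @export
print.smc_world <- function(x, ...) {
  cat(sprintf("<smc_world> circumference %g, %d object(s)\n",
              x$circumference, length(x$objects)))
  for (o in x$objects)
    cat(sprintf("  center %g  height %g  width %g\n",
                o$center, o$height, o$width))
  invisible(x)
}

#' Normalized proximity sensor
#'
#' The sensor reads the height of the summed Gaussian field at the agent's
#' own position, clipped at 1 ("normalized proximity"): `s = min(1,
#' sum_j h_j exp(-d(p, c_j)^2 / (2 w_j^2)))` with `d` the signed minimal
#' wrapped distance.  Pure and vectorized over `p`.
#'
#' @param world an [world()] object.
#' @param p position(s), world units (any finite value; wrapped internally).
#' @return sensor value(s) in `[0, 1]`.
#' @export
sense <- function(world, p) {
  stopifnot(inherits(world, "smc_world"), all(is.finite(p)))
  v <- .world_vecs(world)
  cpp_sense(as.numeric(p), v$c, v$h, v$w, world$circumference)
}

#' Spatial gradient of the sensor field
#'
#' Analytic derivative `ds/dp` of the summed field, with wrapped distances;
#' zero wherever the summed field reaches the clip level 1.  The agent's
#' input is the time derivative `ds/dt = v * sense_gradient(p)`, so this
#' gradient is the spatial factor of everything the agent senses.
#'
#' @inheritParams sense
#' @return gradient value(s), sensor units per world unit.
#' @export
sense_gradient <- function(world, p) {
  stopifnot(inherits(world, "smc_world"), all(is.finite(p)))
  v <- .world_vecs(world)
  cpp_sense_gradient(as.numeric(p), v$c, v$h, v$w, world$circumference)
}

#' Wrap a position onto the circle
#'
#' @param p position(s), world units.
#' @param L circumference, `> 0`.
#' @return position(s) in `[0, L)`.
#' @export
wrap_position <- function(p, L) {
  if (!is.finite(L) || L <= 0) stop("'L' must be > 0")
  ((p %% L) + L) %% L
}

#' Signed minimal wrapped distance
#'
#' Returns `d = p1 - p2` reduced modulo `L` into `(-L/2, L/2]`; the sign at
#' the exact antipode is fixed positive by convention.  Antisymmetric:
#' `wrapped_distance(a, b) == -wrapped_distance(b, a)` except at the
#' antipode.
#'
#' @param p1,p2 positions, world units.
#' @param L circumference, `> 0`.
#' @return signed distance(s) in `(-L/2, L/2]`.
#' @export
wrapped_distance <- function(p1, p2, L) {
  if (!is.finite(L) || L <= 0) stop("'L' must be > 0")
  d <- wrap_position(p1 - p2, L)
  ifelse(d > L / 2, d - L, d)
}

#' Single-shape trial world
#'
#' Convenience constructor for the canonical one-shape trial: a world of
#' circumference `L` with one Gaussian object at `center`.
#'
#' @param width,height shape parameters (see [gaussian_object()]).
#' @param center peak position; default mid-circle.
#' @param L circumference.
#' @return an `smc_world` with a single object.
#' @export
single_shape_world <- function(width, height = 0.8, center = 20, L = 40) {
  world(L, list(gaussian_object(center, height, width)))
}

#' Two-shape demonstration world
#'
#' One narrow and one wide shape on opposite sides of the circle, the
#' configuration used for demonstration runs of the discrimination task.
#'
#' @param narrow_width,wide_width widths of the two shapes.
#' @param heights length-2 vector of peak heights.
#' @param L circumference.
#' @export
two_shape_world <- function(narrow_width = 1, wide_width = 3,
                            heights = c(0.8, 0.8), L = 40) {
  world(L, list(gaussian_object(L / 4, heights[1], narrow_width),
                gaussian_object(3 * L / 4, heights[2], wide_width)))
}

#' Export a field profile
#'
#' Writes the sensor field sampled on a position grid as a two-column CSV
#' (`position`, `sensor_value`).
#'
#' @param world an `smc_world`.
#' @param path output CSV path.
#' @param step grid step, world units.
#' @return the data frame, invisibly.
#' @export
write_field_profile <- function(world, path, step = 0.01) {
  p <- seq(0, world$circumference, by = step)
  df <- data.frame(position = p, sensor_value = sense(world, p))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
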
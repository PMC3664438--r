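# Base-graphics views of the analysis products.

#' @export
plot.smc_trajectory <- function(x, ...) {
  op <- graphics::par(mfrow = c(3, 1), mar = c(2.5, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$t, x$p, type = "l", xlab = "", ylab = "position p")
  graphics::plot(x$t, x$s, type = "l", xlab = "", ylab = "sensor s")
  graphics::plot(x$t, x$v, type = "l", xlab = "time", ylab = "velocity v")
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' @export
plot.smc_surface <- function(x, ...) {
  graphics::image(x$p, x$v, x$value,
                  col = grDevices::hcl.colors(64, "Blue-Red 3"),
                  xlab = "position p", ylab = "commanded velocity v",
                  main = "sensorimotor environment ds/dt", ...)
  graphics::contour(x$p, x$v, x$value, add = TRUE, drawlabels = FALSE,
                    col = "gray30")
  invisible(x)
}

#' @export
plot.smc_landscape <- function(x, ...) {
  code <- matrix(match(x$class, c("negative", "bistable", "positive")),
                 nrow(x$class), ncol(x$class))
  graphics::image(x$p, x$v, code, col = c("black", "gray70", "white"),
                  zlim = c(1, 3), xlab = "position p",
                  ylab = "commanded velocity v",
                  main = "attractor landscape", ...)
  invisible(x)
}

#' @export
plot.smc_bifurcation <- function(x, ...) {
  pts <- x$points
  graphics::plot(range(pts$I), range(pts$y1), type = "n",
                 xlab = "clamped input I",
                 ylab = expression(y[1] * "*"), ...)
  for (b in unique(pts$branch_id)) {
    seg <- pts[pts$branch_id == b, ]
    st <- seg[seg$stable, ]; un <- seg[!seg$stable, ]
    if (nrow(st)) graphics::lines(st$I, st$y1, lwd = 2)
    if (nrow(un)) graphics::lines(un$I, un$y1, lty = 2)
  }
  if (length(x$bifurcations))
    graphics::abline(v = x$bifurcations, lty = 3, col = "gray50")
  invisible(x)
}

#' @export
plot.smc_portrait <- function(x, ...) {
  pre <- seq_len(x$transient_end)
  post <- seq.int(x$transient_end + 1L, length(x$t))
  graphics::plot(x$dm_dt, x$ds_dt, type = "n", xlab = "dm/dt",
                 ylab = "ds/dt", ...)
  graphics::lines(x$dm_dt[pre], x$ds_dt[pre], col = "gray75")
  graphics::lines(x$dm_dt[post], x$ds_dt[post])
  graphics::points(0, 0, pch = 3)
  invisible(x)
}
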
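#' Sensorimotor rates portrait
#'
#' Projects a trajectory into the plane of sensorimotor rates of change:
#' `dm/dt` (central difference of the motor neuron activation `y2`)
#' against `ds/dt` (central difference of the sensor signal `s`).  A
#' sustained closed orbit in this plane is the signature of a
#' sensorimotor coordination pattern; collapse toward the origin is the
#' signature of a transient encounter.
#'
#' The transient prefix is marked as the first 30% of the trial or
#' everything up to first contact (`s > contact_s`), whichever is later.
#'
#' @param traj an `smc_trajectory` with at least 3 samples.
#' @param contact_s first-contact sensor threshold.
#' @return an `smc_portrait`: list with `t`, `ds_dt`, `dm_dt` (endpoints
#'   of the source dropped by the differencing), `transient_end` (index
#'   into these series of the last transient sample), `dt`.
#' @export
rates_portrait <- function(traj, contact_s = 0.05) {
  stopifnot(inherits(traj, "smc_trajectory"), length(traj$t) >= 3)
  n <- length(traj$t); i <- 2:(n - 1); dt <- traj$dt
  ds_dt <- (traj$s[i + 1] - traj$s[i - 1]) / (2 * dt)
  dm_dt <- (traj$y2[i + 1] - traj$y2[i - 1]) / (2 * dt)
  contact <- which(traj$s > contact_s)[1]
  cut_src <- max(floor(0.3 * n), if (is.na(contact)) n else contact)
  transient_end <- min(max(cut_src - 1L, 1L), length(i))
  structure(list(t = traj$t[i], ds_dt = ds_dt, dm_dt = dm_dt,
                 transient_end = transient_end, dt = dt),
            class = "smc_portrait")
}

#' @export
print.smc_portrait <- function(x, ...) {
  post <- seq.int(x$transient_end + 1L, length(x$t))
  r <- sqrt(x$ds_dt^2 + x$dm_dt^2)
  cat(sprintf(
    "<smc_portrait> %d samples (%d post-transient), max radius %.3g (post: %.3g)\n",
    length(x$t), length(post), max(r),
    if (length(post)) max(r[post]) else NA))
  invisible(x)
}

#' Detect a limit cycle in a rates portrait
#'
#' Recurrence test on the post-transient orbit.  The reference is the
#' point farthest from the origin within the *third quarter* of the
#' post-transient segment: the scanning oscillation settles with
#' decreasing amplitude, so anchoring on the settled part of the orbit
#' (rather than its early, still-shrinking extreme) is what makes the
#' recurrence ball revisitable at all, and capping the search at 75%
#' leaves at least a quarter of the segment in which returns can be
#' observed.  Every re-entry into a tolerance
#' ball around the reference with a consistent crossing direction
#' (positive projection of the local motion onto the motion at the
#' reference) counts as a return.  A cycle is detected when there are at least 3 returns,
#' the inter-return times vary by less than 10% of their median, and the
#' orbit is not drifting away from the reference (mean entry distance over
#' the later returns no larger than over the earlier ones plus half the
#' tolerance).
#'
#' @param portrait an [rates_portrait()].
#' @param tol radius of the recurrence ball; default 5% of the
#'   post-transient maximum radius.
#' @return list with `cycle_detected` (logical), `period` (median
#'   inter-return time; `NA` when not detected), `amplitude` (max radial
#'   extent of the post-transient orbit), `n_returns`.
#' @export
detect_limit_cycle <- function(portrait, tol = NULL) {
  stopifnot(inherits(portrait, "smc_portrait"))
  post <- seq.int(portrait$transient_end + 1L, length(portrait$t))
  if (length(post) < 10)
    return(list(cycle_detected = FALSE, period = NA_real_,
                amplitude = NA_real_, n_returns = 0L))
  x <- portrait$dm_dt[post]; y <- portrait$ds_dt[post]
  tt <- portrait$t[post]
  r <- sqrt(x^2 + y^2)
  amplitude <- max(r)
  if (amplitude == 0)
    return(list(cycle_detected = FALSE, period = NA_real_,
                amplitude = 0, n_returns = 0L))
  if (is.null(tol)) tol <- 0.05 * amplitude
  late <- seq.int(ceiling(length(r) / 2), ceiling(3 * length(r) / 4))
  ref <- late[which.max(r[late])]
  d <- sqrt((x - x[ref])^2 + (y - y[ref])^2)
  n <- length(d)
  # local motion direction at the reference
  dir_ref <- c(x[min(ref + 1, n)] - x[max(ref - 1, 1)],
               y[min(ref + 1, n)] - y[max(ref - 1, 1)])
  inside <- d < tol
  entries <- which(!inside[-n] & inside[-1]) + 1L
  entries <- entries[entries > ref]
  if (length(entries)) {
    proj <- (x[pmin(entries + 1L, n)] - x[pmax(entries - 1L, 1L)]) * dir_ref[1] +
            (y[pmin(entries + 1L, n)] - y[pmax(entries - 1L, 1L)]) * dir_ref[2]
    entries <- entries[proj > 0]
  }
  if (length(entries) < 3)
    return(list(cycle_detected = FALSE, period = NA_real_,
                amplitude = amplitude, n_returns = length(entries)))
  gaps <- diff(c(tt[ref], tt[entries]))
  med <- stats::median(gaps)
  regular <- max(abs(gaps - med)) < 0.1 * med
  ed <- d[entries]
  half <- ceiling(length(ed) / 2)
  no_drift <- mean(ed[(length(ed) - half + 1):length(ed)]) <=
    mean(ed[1:half]) + tol / 2
  detected <- regular && no_drift
  list(cycle_detected = detected,
       period = if (detected) med else NA_real_,
       amplitude = amplitude, n_returns = length(entries))
}

#' Reliable-transient signature of an avoidance encounter
#'
#' The avoidance pattern is a pure transient: the agent meets the shape
#' and leaves without ever reversing.  The signature holds when the
#' velocity sign after first contact never changes and equals the sign at
#' contact.
#'
#' @param traj an `smc_trajectory`.
#' @param contact_s first-contact sensor threshold.
#' @return logical.
#' @export
transient_signature <- function(traj, contact_s = 0.05) {
  contact <- which(traj$s > contact_s)[1]
  if (is.na(contact)) return(FALSE)
  .sign_changes(traj$v, contact) == 0
}

#' Aggregate a coordination verdict over a trial battery
#'
#' A sensorimotor pattern counts as a sensorimotor coordination when it is
#' reliable (present in at least `r_min` of the battery) and functional
#' (the trials exhibiting it succeed at the task label).  Cyclic patterns
#' (approach) and reliable transients (avoidance) both qualify.
#'
#' @param reports list of per-trial pattern reports: for
#'   `pattern = "cycle"`, outputs of [detect_limit_cycle()]; for
#'   `pattern = "transient"`, logicals from [transient_signature()].
#' @param outcomes list of [behavior_outcome()] results, same length and
#'   order as `reports`.
#' @param success_label task-success label for these trials
#'   (`"approach"` or `"avoid"`).
#' @param pattern `"cycle"` or `"transient"`.
#' @param r_min reliability threshold, in `[0, 1]` (default 0.9).
#' @return an `smc_coordination`: list with `pattern`, `cycle_detected`
#'   (whether the pattern is present reliably), `period` (median over
#'   pattern trials; cycles only), `period_spread` (max relative deviation
#'   from the median), `amplitude` (median), `reliability`, `functional`,
#'   `is_sm_coordination`, `n`.
#' @export
classify_coordination <- function(reports, outcomes,
                                  success_label = c("approach", "avoid"),
                                  pattern = c("cycle", "transient"),
                                  r_min = 0.9) {
  pattern <- match.arg(pattern)
  success_label <- match.arg(success_label)
  if (length(reports) != length(outcomes) || !length(reports))
    stop("'reports' and 'outcomes' must be nonempty and aligned")
  present <- if (pattern == "cycle")
    vapply(reports, `[[`, TRUE, "cycle_detected") else
    vapply(reports, isTRUE, TRUE)
  labels <- vapply(outcomes, `[[`, "", "label")
  reliability <- mean(present)
  functional <- any(present) && all(labels[present] == success_label)
  periods <- if (pattern == "cycle")
    vapply(reports, `[[`, 0, "period")[present] else numeric(0)
  med <- if (length(periods)) stats::median(periods) else NA_real_
  structure(list(
    pattern = pattern,
    cycle_detected = pattern == "cycle" && reliability >= r_min,
    period = med,
    period_spread = if (length(periods))
      max(abs(periods - med)) / med else NA_real_,
    amplitude = if (pattern == "cycle" && any(present))
      stats::median(vapply(reports, `[[`, 0, "amplitude")[present])
      else NA_real_,
    reliability = reliability, functional = functional,
    is_sm_coordination = reliability >= r_min && functional,
    n = length(reports)), class = "smc_coordination")
}

#' @export
print.smc_coordination <- function(x, ...) {
  cat(sprintf(
    "<smc_coordination> %s pattern: reliability %.2f, functional %s -> %s\n",
    x$pattern, x$reliability, x$functional,
    if (x$is_sm_coordination) "SM coordination" else "not an SM coordination"))
  if (!is.na(x$period))
    cat(sprintf("  period %.3g (spread %.1f%%)\n", x$period,
                100 * x$period_spread))
  invisible(x)
}

#' Map behavioral categories over shape parameters
#'
#' Runs one canonical trial per (width, height) cell and records the
#' behavioral label, exposing the categorical boundary of the evolved
#' discrimination: within each height row the boundary width is the
#' midpoint between the last approach and the first avoid along the width
#' axis.  `n_flips` counts changes along the approach/avoid subsequence
#' of the row (the boundary is between those two categories; `undecided`
#' cells are no-calls, not category reversals); rows whose boundary flips
#' more than once are reported as-is with a multiplicity flag.
#'
#' @param params an [agent_params()] object.
#' @param width_grid,height_grid shape parameter grids.
#' @param offset,T,dt canonical trial protocol controls.
#' @return an `smc_category_map`: list with `width`, `height`, `label`
#'   (character matrix, widths x heights), `boundaries` (data frame
#'   `height`, `boundary_width`, `n_flips`, `multiple_flips`).
#' @export
category_map <- function(params, width_grid = seq(0.5, 4, by = 0.25),
                         height_grid = seq(0.5, 1, by = 0.1),
                         offset = 8, T = 100, dt = 0.01) {
  lab <- matrix(NA_character_, length(width_grid), length(height_grid))
  for (j in seq_along(height_grid)) for (i in seq_along(width_grid)) {
    tr <- canonical_trial(params, width_grid[i], height_grid[j],
                          offset = offset, T = T, dt = dt)
    lab[i, j] <- tr$outcome$label
  }
  bnd <- do.call(rbind, lapply(seq_along(height_grid), function(j) {
    l <- lab[, j]
    cat_seq <- l[l %in% c("approach", "avoid")]
    flips <- if (length(cat_seq) < 2) 0L
    else sum(cat_seq[-1] != cat_seq[-length(cat_seq)])
    appr <- which(l == "approach"); avd <- which(l == "avoid")
    bw <- if (length(appr) && length(avd) && max(appr) < min(avd))
      (width_grid[max(appr)] + width_grid[min(avd)]) / 2 else NA_real_
    data.frame(height = height_grid[j], boundary_width = bw,
               n_flips = flips, multiple_flips = flips > 1)
  }))
  structure(list(width = width_grid, height = height_grid, label = lab,
                 boundaries = bnd),
            class = "smc_category_map")
}

#' @export
print.smc_category_map <- function(x, ...) {
  cat(sprintf("<smc_category_map> %d widths x %d heights\n",
              length(x$width), length(x$height)))
  print(x$boundaries, row.names = FALSE)
  invisible(x)
}
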
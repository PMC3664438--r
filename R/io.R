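#' Read / write world configurations
#'
#' Worlds are stored as JSON or YAML documents (chosen by file extension)
#' with keys `circumference` and `objects`, the latter a list of
#' `{center, height, width}` records.  Invariants are enforced on load;
#' violations report the offending key.
#'
#' @param path file path ending in `.json`, `.yaml` or `.yml`.
#' @return [read_world()] returns an `smc_world`; [write_world()] returns
#'   `path` invisibly.
#' @export
read_world <- function(path) {
  x <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
       else jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  if (is.null(x$circumference)) stop("world file missing 'circumference'")
  objs <- lapply(x$objects, function(o) {
    for (k in c("center", "height", "width"))
      if (is.null(o[[k]])) stop("world object missing '", k, "'")
    gaussian_object(o$center, o$height, o$width)
  })
  world(x$circumference, objs)
}

#' @param w an `smc_world`.
#' @rdname read_world
#' @export
write_world <- function(w, path) {
  stopifnot(inherits(w, "smc_world"))
  x <- list(circumference = w$circumference,
            objects = lapply(w$objects, unclass))
  if (grepl("\\.ya?ml$", path)) yaml::write_yaml(x, path)
  else jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Export a trajectory as CSV plus metadata sidecar
#'
#' Writes the series as CSV (`t,p,s,ds,y1,y2,v`) and a JSON sidecar
#' (`<path>.meta.json`) with the world, agent parameters, initial state,
#' step size and provenance stamp, so the run is regenerable from its own
#' metadata.
#'
#' @param traj an `smc_trajectory`.
#' @param path output CSV path.
#' @param seed optional seed to record.
#' @export
write_trajectory <- function(traj, path, seed = NA) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  meta <- list(world = list(circumference = traj$world$circumference,
                            objects = lapply(traj$world$objects, unclass)),
               params = unclass(traj$params),
               init = unclass(traj$init),
               dt = traj$dt, motor_sign = traj$motor_sign,
               ds_mode = traj$ds_mode, seed = seed)
  meta <- c(meta, provenance(meta, seed))
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Export a bifurcation diagram as CSV
#'
#' Columns `I`, `y1`, `stable`, `branch_id`.
#'
#' @param bif an [bifurcation_diagram()] result.
#' @param path output CSV path.
#' @export
write_bifurcation <- function(bif, path) {
  utils::write.csv(bif$points[c("I", "y1", "stable", "branch_id")], path,
                   row.names = FALSE)
  invisible(path)
}

#' Export an attractor landscape as long-format CSV
#'
#' Columns `p`, `v`, `class`, `v_stable_1`, `v_stable_2` (`v_stable_2`
#' empty where the cell is monostable).
#'
#' @param landscape an [attractor_landscape()] result.
#' @param path output CSV path.
#' @export
write_landscape <- function(landscape, path) {
  df <- data.frame(p = rep(landscape$p, times = length(landscape$v)),
                   v = rep(landscape$v, each = length(landscape$p)),
                   class = as.vector(landscape$class),
                   v_stable_1 = as.vector(landscape$v_lower),
                   v_stable_2 = as.vector(landscape$v_upper))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Configuration hash and provenance stamp
#'
#' `config_hash()` is a 32-bit FNV-1a hash of the canonical JSON encoding
#' of an R object, printed as 8 hex digits; `provenance()` bundles the
#' package version, the hash and the seed.  Every artifact the CLI writes
#' embeds this stamp so any output is regenerable from its own metadata.
#'
#' @param x an R object (list of configuration values).
#' @return `config_hash()`: an 8-hex-digit string.
#' @export
config_hash <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null")
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b %% 256))
    # 32-bit modular multiply by the FNV prime, split to stay exact
    h1 <- h %/% 65536; h0 <- h %% 65536
    h <- (h0 * 16777619 + ((h1 * 16777619) %% 65536) * 65536) %% 2^32
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' @param seed the seed used for the run (`NA` when deterministic).
#' @rdname config_hash
#' @export
provenance <- function(x, seed = NA) {
  list(package_version =
         as.character(utils::packageVersion("smcagent")),
       config_hash = config_hash(x), seed = seed)
}

#' Export a surface as a JSON header plus dense matrix CSV
#'
#' Companion to [write_surface()] for consumers that prefer a dense
#' layout: `<basename>.json` carries the grids and provenance,
#' `<basename>.csv` the value matrix (rows = positions, columns =
#' velocities).
#'
#' @param surface an [smc_surface()].
#' @param basename output path without extension.
#' @export
write_surface_dense <- function(surface, basename) {
  jsonlite::write_json(
    c(list(p = surface$p, v = surface$v,
           world = list(circumference = surface$world$circumference,
                        objects = lapply(surface$world$objects, unclass))),
      provenance(list(p = surface$p, v = surface$v), NA)),
    paste0(basename, ".json"), digits = NA, auto_unbox = TRUE)
  utils::write.table(surface$value, paste0(basename, ".csv"),
                     sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(basename)
}

#' Export a habitat ensemble as a directory of trajectory CSVs
#'
#' Writes `trajectory_<k>.csv` for every member plus `manifest.json`
#' holding the sampling specification, the seed, the drawn values and the
#' provenance stamp, so the whole ensemble is regenerable.
#'
#' @param ensemble an [sample_habitat()] result.
#' @param dir output directory (created if needed).
#' @export
write_ensemble <- function(ensemble, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (k in seq_along(ensemble$trajectories))
    utils::write.csv(as.data.frame(ensemble$trajectories[[k]]),
                     file.path(dir, sprintf("trajectory_%03d.csv", k)),
                     row.names = FALSE)
  jsonlite::write_json(
    c(list(spec = ensemble$spec, seed = ensemble$seed,
           draws = ensemble$draws,
           labels = vapply(ensemble$outcomes, `[[`, "", "label")),
      provenance(ensemble$spec, ensemble$seed)),
    file.path(dir, "manifest.json"), digits = NA, auto_unbox = TRUE,
    dataframe = "columns")
  invisible(dir)
}

#' Export a category map as long-format CSV
#'
#' One row per (width, height) cell with the behavioral label, plus the
#' per-height boundary table as a second file when `boundary_path` is
#' given.
#'
#' @param cm an [category_map()] result.
#' @param path output CSV path.
#' @param boundary_path optional CSV path for the boundary table.
#' @export
write_category_map <- function(cm, path, boundary_path = NULL) {
  df <- data.frame(width = rep(cm$width, times = length(cm$height)),
                   height = rep(cm$height, each = length(cm$width)),
                   label = as.vector(cm$label))
  utils::write.csv(df, path, row.names = FALSE)
  if (!is.null(boundary_path))
    utils::write.csv(cm$boundaries, boundary_path, row.names = FALSE)
  invisible(path)
}
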
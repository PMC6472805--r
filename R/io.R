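# Configuration files, run containers, and snapshot export.

#' Load a simulation or continuum configuration from a YAML file
#'
#' Keys mirror the arguments of \code{\link{sim_config}} (or
#' \code{\link{continuum_config}} when \code{type = "continuum"}); every
#' default can be overridden. Unknown keys are an error listing them.
#' Assumed-default parameters that the file does not override are reported
#' in a warning so runs relying on them are visible.
#'
#' @param path YAML file path. An empty file yields all defaults.
#' @param type \code{"network"} or \code{"continuum"}.
#' @param quiet Suppress the assumed-parameter warning.
#' @return A \code{sim_config} or \code{continuum_config}.
#' @export
load_config <- function(path, type = c("network", "continuum"),
                        quiet = FALSE) {
  type <- match.arg(type)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  ctor <- if (type == "network") sim_config else continuum_config
  known <- names(formals(ctor))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (type == "network" && !quiet) {
    assumed <- setdiff(.assumed_params, names(vals))
    if (length(assumed) > 0)
      warning("using assumed defaults for: ", paste(assumed, collapse = ", "),
              call. = FALSE)
  }
  do.call(ctor, vals)
}

#' Save a configuration to YAML
#'
#' Writes every field so that \code{load_config} round-trips to an identical
#' configuration.
#'
#' @param config A \code{sim_config} or \code{continuum_config}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
save_config <- function(config, path) {
  ctor <- if (inherits(config, "sim_config")) sim_config else continuum_config
  keep <- intersect(names(config), names(formals(ctor)))
  vals <- unclass(config)[keep]
  yaml::write_yaml(vals, path)
  invisible(path)
}

#' Write network geometry as CSV
#'
#' Two files: \code{<stem>_nodes.csv} (node id, x, y, z, fixed) and
#' \code{<stem>_segments.csv} (a, b, rest, fiber), plus
#' \code{<stem>_crosslinks.csv} when crosslinks exist.
#'
#' @param network A \code{fiber_network}.
#' @param stem Output path stem.
#' @return Character vector of the files written, invisibly.
#' @export
write_network_csv <- function(network, stem) {
  nodes <- data.frame(id = seq_len(nrow(network$pos)),
                      x = network$pos[, 1], y = network$pos[, 2],
                      z = network$pos[, 3], fixed = network$fixed)
  files <- paste0(stem, c("_nodes.csv", "_segments.csv"))
  write.csv(nodes, files[1], row.names = FALSE)
  write.csv(network$segments, files[2], row.names = FALSE)
  if (nrow(network$crosslinks) > 0) {
    f3 <- paste0(stem, "_crosslinks.csv")
    write.csv(network$crosslinks, f3, row.names = FALSE)
    files <- c(files, f3)
  }
  invisible(files)
}

#' Write network fibers as a legacy-VTK polyline file
#'
#' ASCII legacy VTK (POLYDATA with LINES), one polyline per fiber, for
#' visualization in ParaView and similar tools.
#'
#' @param network A \code{fiber_network}.
#' @param path Output file path (.vtk).
#' @return \code{path}, invisibly.
#' @export
write_network_vtk <- function(network, path) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(network$pos)
  writeLines(c("# vtk DataFile Version 3.0",
               "fiber network snapshot", "ASCII",
               "DATASET POLYDATA",
               sprintf("POINTS %d float", n)), con)
  writeLines(apply(network$pos, 1, function(p)
    sprintf("%.6f %.6f %.6f", p[1], p[2], p[3])), con)
  fibers <- split(network$segments, network$segments$fiber)
  sizes <- vapply(fibers, function(f) nrow(f) + 1L, 1L)
  writeLines(sprintf("LINES %d %d", length(fibers),
                     sum(sizes) + length(fibers)), con)
  for (f in fibers) {
    chain <- c(f$a[1], f$b) - 1L
    writeLines(paste(c(length(chain), chain), collapse = " "), con)
  }
  invisible(path)
}

#' Write a run container
#'
#' Persists a \code{network_time_series} as a directory container:
#' \code{profiles.csv} (per-snapshot concentration profiles),
#' \code{stress.csv}, \code{accumulation.csv}, \code{events.csv},
#' \code{energy.csv}, \code{meta.json} (config snapshot, seed, versions),
#' and a \code{manifest.json} listing every payload.
#'
#' @param series A \code{network_time_series}.
#' @param dir Output directory (created if missing).
#' @param bin_width Profile bin width, um.
#' @param region_depth Accumulation region depth, um.
#' @return The manifest as a list, invisibly.
#' @export
write_run_container <- function(series, dir, bin_width = 1, region_depth = 3) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  prof <- profile_series(series, bin_width)
  edges <- attr(prof, "edges")
  prof_df <- data.frame(t_norm = rep(series$t_norm, each = ncol(prof)),
                        z_lo = rep(edges[-length(edges)], length(series$t_norm)),
                        concentration = as.vector(t(prof)))
  st <- stress_series(series)
  acc <- accumulation_timeseries(series, region_depth)
  en <- data.frame(t_norm = series$t_norm, energy = series$energy,
                   ext_work = series$ext_work,
                   bound_crosslinks = series$bound_count,
                   segments_in_zone = series$n_in_zone)
  payloads <- c("profiles.csv", "stress.csv", "accumulation.csv",
                "events.csv", "energy.csv", "meta.json")
  write.csv(prof_df, file.path(dir, "profiles.csv"), row.names = FALSE)
  write.csv(st, file.path(dir, "stress.csv"), row.names = FALSE)
  write.csv(acc, file.path(dir, "accumulation.csv"), row.names = FALSE)
  write.csv(series$events, file.path(dir, "events.csv"), row.names = FALSE)
  write.csv(en, file.path(dir, "energy.csv"), row.names = FALSE)
  meta <- list(
    config = unclass(series$config)[!vapply(series$config, is.function, TRUE)],
    seed = series$seed,
    max_kudt = series$max_kudt,
    package_version = as.character(utils::packageVersion("ecmremodel")),
    n_snapshots = length(series$time))
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  manifest <- run_manifest(dir, payloads, meta)
  invisible(manifest)
}

#' Write a run manifest
#'
#' Records the config snapshot, seed, package version, and the output files
#' of a run; errors if a listed output is missing.
#'
#' @param dir Run directory.
#' @param files Payload file names relative to \code{dir}.
#' @param meta Metadata list (config snapshot, seed, ...).
#' @return The manifest list, invisibly.
#' @export
run_manifest <- function(dir, files, meta) {
  missing <- files[!file.exists(file.path(dir, files))]
  if (length(missing) > 0)
    stop("manifest lists missing output file(s): ",
         paste(missing, collapse = ", "))
  manifest <- list(created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                   files = files, meta = meta)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Read a run container
#'
#' @param dir Directory written by \code{\link{write_run_container}}.
#' @return List of data frames (\code{profiles}, \code{stress},
#'   \code{accumulation}, \code{events}, \code{energy}) plus \code{meta}.
#' @export
read_run_container <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  out <- list(
    profiles = read.csv(file.path(dir, "profiles.csv")),
    stress = read.csv(file.path(dir, "stress.csv")),
    accumulation = read.csv(file.path(dir, "accumulation.csv")),
    events = read.csv(file.path(dir, "events.csv")),
    energy = read.csv(file.path(dir, "energy.csv")),
    meta = jsonlite::read_json(file.path(dir, "meta.json"),
                               simplifyVector = TRUE))
  out$manifest <- manifest
  out
}

#' Write a displacement field or intensity volume as flat CSV
#'
#' Columns \code{x, y, z, ux, uy, uz} for fields; \code{x, y, z, I, mask}
#' for volumes.
#'
#' @param obj A \code{displacement_field} or \code{intensity_volume}.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_grid_csv <- function(obj, path) {
  if (inherits(obj, "displacement_field")) {
    dims <- dim(obj$u)[1:3]
    cc <- voxel_coords(dims, obj$spacing, obj$origin)
    g <- expand.grid(x = cc[[1]], y = cc[[2]], z = cc[[3]])
    df <- data.frame(g, ux = as.vector(obj$u[, , , 1]),
                     uy = as.vector(obj$u[, , , 2]),
                     uz = as.vector(obj$u[, , , 3]))
  } else if (inherits(obj, "intensity_volume")) {
    dims <- dim(obj$I)
    cc <- voxel_coords(dims, obj$spacing, obj$origin)
    g <- expand.grid(x = cc[[1]], y = cc[[2]], z = cc[[3]])
    df <- data.frame(g, I = as.vector(obj$I), mask = as.vector(obj$mask))
  } else stop("unsupported object")
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
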
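# File formats, run configuration, and the end-to-end pipeline.
#
# Formats: plain-text CSV for traces, wall-motion fields, metrics and
# convergence logs; JSON for configuration, sidecars and manifests; ASCII
# VTU (+ a .pvd series index) for fields, readable by ParaView.

#' Read boundary traces from CSV
#'
#' Expected columns: `frame, time_s, point_index, x_cm, y_cm, tag` (one
#' header line).  Coordinates are multiplied by `pixel_size_cm` on ingest,
#' so traces digitized in pixels can be scaled to CGS at load time.
#'
#' @param path CSV file
#' @param pixel_size_cm scale factor applied to x and y (default 1)
#' @return list of [boundary_trace()] objects, ordered by frame
#' @export
read_traces <- function(path, pixel_size_cm = 1) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame", "time_s", "point_index", "x_cm", "y_cm", "tag")
  if (!all(need %in% names(d)))
    stop("trace file must have columns: ", paste(need, collapse = ", "))
  lapply(split(d, d$frame), function(fd) {
    fd <- fd[order(fd$point_index), ]
    boundary_trace(cbind(fd$x_cm, fd$y_cm) * pixel_size_cm, fd$tag,
                   frame = fd$frame[1], time = fd$time_s[1])
  })
}

#' Write boundary traces to CSV
#' @param traces list of [boundary_trace()]
#' @param path output CSV
#' @export
write_traces <- function(traces, path) {
  rows <- lapply(traces, function(tr)
    data.frame(frame = tr$frame, time_s = tr$time,
               point_index = seq_len(nrow(tr$points)),
               x_cm = tr$points[, 1], y_cm = tr$points[, 2],
               tag = tr$tags))
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Write a wall-motion field (CSV + JSON sidecar)
#' @param field a `wall_motion_field`
#' @param path output CSV; the sidecar is written at `<path>.json`
#' @export
write_motion <- function(field, path) {
  rows <- lapply(seq_along(field$times), function(k)
    data.frame(time_s = field$times[k],
               node_index = seq_len(field$node_count),
               x_cm = field$positions[, 1, k],
               y_cm = field$positions[, 2, k],
               tag = field$tags))
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  jsonlite::write_json(list(n_nodes = field$node_count,
                            sample_rate_hz = field$sample_rate,
                            units = "CGS"),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a wall-motion field written by [write_motion()]
#' @param path CSV path (sidecar `<path>.json` must exist)
#' @return a `wall_motion_field`
#' @export
read_motion <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"))
  d <- read.csv(path, stringsAsFactors = FALSE)
  times <- sort(unique(d$time_s))
  frames <- lapply(times, function(t) {
    fd <- d[d$time_s == t, ]
    fd <- fd[order(fd$node_index), ]
    cbind(fd$x_cm, fd$y_cm)
  })
  tags <- d$tag[d$time_s == times[1]][order(d$node_index[d$time_s == times[1]])]
  interpolate_motion(frames, times, target_rate = meta$sample_rate_hz,
                     tags = tags)
}

# --- configuration ----------------------------------------------------------

#' Default run configuration
#'
#' Nested list mirroring the simulation protocol: embryonic-blood fluid
#' properties (rho = 1.06 g/cm^3, mu = 0.07 P), 2 ms steps for 5 s,
#' Newton tolerance 1e-3 with at most 5 iterations, backflow beta = 0.2.
#'
#' @return nested configuration list
#' @export
default_config <- function() {
  list(
    fluid = list(density = 1.06, viscosity = 0.07),
    time = list(dt = 0.002, t_end = 5, rho_inf = 0.5,
                newton_tol = 1e-3, max_newton = 5L),
    stabilization = list(ci = 36, lsic = TRUE),
    backflow_beta = 0.2,
    mesh = list(edge_length = 0.004),
    synthetic = list(kind = "peristaltic", n_cycles = 2),
    metrics = list(k = 10L, av_window = 0.02),
    seed = 1L
  )
}

merge_config <- function(cfg, defaults, prefix = "") {
  for (key in names(cfg)) {
    full <- paste0(prefix, key)
    if (!key %in% names(defaults))
      stop(sprintf("unknown configuration key: '%s'", full))
    if (is.list(defaults[[key]]) && !is.list(cfg[[key]]))
      stop(sprintf("configuration key '%s' must be a section", full))
    if (is.list(defaults[[key]]))
      cfg[[key]] <- merge_config(cfg[[key]], defaults[[key]],
                                 paste0(full, "."))
  }
  out <- defaults
  for (key in names(cfg)) out[[key]] <- cfg[[key]]
  out
}

validate_config <- function(cfg, defaults = default_config()) {
  out <- merge_config(cfg, defaults)
  positive <- list(c("fluid", "density"), c("fluid", "viscosity"),
                   c("time", "dt"), c("time", "t_end"),
                   c("time", "newton_tol"), c("mesh", "edge_length"))
  for (k in positive) {
    v <- out[[k[1]]][[k[2]]]
    if (!is.numeric(v) || v <= 0)
      stop(sprintf("configuration key '%s.%s' must be positive", k[1], k[2]))
  }
  out
}

#' Load a run configuration from JSON
#'
#' Missing keys are filled from [default_config()]; unknown keys are
#' rejected with the offending key named; physical values are checked for
#' positivity.  An empty file yields the full default configuration.
#'
#' @param path JSON file
#' @return validated configuration list
#' @export
load_config <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  cfg <- if (nchar(trimws(txt)) == 0) list() else
    jsonlite::fromJSON(txt, simplifyVector = TRUE)
  validate_config(cfg)
}

#' Save a run configuration to JSON
#' @param cfg configuration list (validated before writing)
#' @param path output JSON file
#' @export
save_config <- function(cfg, path) {
  cfg <- validate_config(cfg)
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

# --- VTK output -------------------------------------------------------------

#' Write one flow state as ASCII VTU
#'
#' Unstructured-grid XML with point data `velocity`, `pressure`,
#' `mesh_velocity`, `displacement` (current minus reference coordinates)
#' and `boundary_tag` (0 interior, 1 wall, 2 inlet, 3 outlet).
#'
#' @param state a `flow_state`
#' @param mesh the `mesh2d`
#' @param path output `.vtu` file
#' @export
write_vtu <- function(state, mesh, path) {
  n <- nrow(state$coords); m <- nrow(mesh$tri)
  num <- function(x) paste(format(x, digits = 17, scientific = TRUE,
                                  trim = TRUE), collapse = " ")
  tagv <- integer(n)
  tagv[mesh$loop] <- match(mesh$loop_tags, VALID_TAGS)
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w('<?xml version="1.0"?>')
  w('<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">')
  w('<UnstructuredGrid>')
  w(sprintf('<Piece NumberOfPoints="%d" NumberOfCells="%d">', n, m))
  w('<Points><DataArray type="Float64" NumberOfComponents="3" format="ascii">')
  w(num(as.vector(rbind(t(state$coords), 0))))
  w('</DataArray></Points>')
  w('<Cells><DataArray type="Int32" Name="connectivity" format="ascii">')
  w(paste(as.vector(t(mesh$tri)) - 1L, collapse = " "))
  w('</DataArray><DataArray type="Int32" Name="offsets" format="ascii">')
  w(paste(3L * seq_len(m), collapse = " "))
  w('</DataArray><DataArray type="UInt8" Name="types" format="ascii">')
  w(paste(rep(5L, m), collapse = " "))
  w('</DataArray></Cells>')
  w('<PointData>')
  arr <- function(name, vals, ncomp) {
    w(sprintf('<DataArray type="Float64" Name="%s" NumberOfComponents="%d" format="ascii">',
              name, ncomp))
    w(num(vals)); w('</DataArray>')
  }
  arr("velocity", as.vector(rbind(t(state$u), 0)), 3)
  arr("pressure", state$p, 1)
  arr("mesh_velocity", as.vector(rbind(t(state$umesh), 0)), 3)
  arr("displacement", as.vector(rbind(t(state$coords - mesh$coords), 0)), 3)
  w(sprintf('<DataArray type="Int32" Name="boundary_tag" NumberOfComponents="1" format="ascii">'))
  w(paste(tagv, collapse = " ")); w('</DataArray>')
  w('</PointData>')
  w('</Piece></UnstructuredGrid></VTKFile>')
  invisible(path)
}

#' Read point data back from a VTU written by [write_vtu()]
#' @param path `.vtu` file
#' @return list: `coords` (N x 2), `u`, `p`, `umesh`, `tri`
#' @export
read_vtu <- function(path) {
  if (!requireNamespace("xml2", quietly = TRUE))
    stop("read_vtu needs the xml2 package")
  doc <- xml2::read_xml(path)
  getv <- function(xp) {
    nd <- xml2::xml_find_first(doc, xp)
    as.numeric(strsplit(trimws(xml2::xml_text(nd)), "\\s+")[[1]])
  }
  pts <- matrix(getv("//Points/DataArray"), ncol = 3, byrow = TRUE)
  u <- matrix(getv("//PointData/DataArray[@Name='velocity']"),
              ncol = 3, byrow = TRUE)
  um <- matrix(getv("//PointData/DataArray[@Name='mesh_velocity']"),
               ncol = 3, byrow = TRUE)
  p <- getv("//PointData/DataArray[@Name='pressure']")
  tri <- matrix(getv("//Cells/DataArray[@Name='connectivity']") + 1,
                ncol = 3, byrow = TRUE)
  list(coords = pts[, 1:2], u = u[, 1:2], p = p, umesh = um[, 1:2],
       tri = tri)
}

#' Write a simulation as a VTU time series with a .pvd index
#'
#' One VTU per stored state plus a ParaView `.pvd` collection enumerating
#' the state times in order.
#'
#' @param sim a `cardio_sim`
#' @param out_dir output directory (created)
#' @param basename file stem (default "step")
#' @return tibble: `time`, `file`
#' @export
write_field_series <- function(sim, out_dir, basename = "step") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  times <- vapply(sim$states, function(s) s$time, numeric(1))
  if (is.unsorted(times, strictly = TRUE))
    stop("state times are not strictly increasing")
  files <- sprintf("%s_%04d.vtu", basename, seq_along(times) - 1L)
  for (k in seq_along(times))
    write_vtu(sim$states[[k]], sim$mesh, file.path(out_dir, files[k]))
  pvd <- file.path(out_dir, paste0(basename, ".pvd"))
  con <- file(pvd, "w")
  writeLines('<?xml version="1.0"?>', con)
  writeLines('<VTKFile type="Collection" version="0.1"><Collection>', con)
  for (k in seq_along(times))
    writeLines(sprintf('<DataSet timestep="%.10g" file="%s"/>',
                       times[k], files[k]), con)
  writeLines('</Collection></VTKFile>', con)
  close(con)
  tibble::tibble(time = times, file = files)
}

# --- pipeline ---------------------------------------------------------------

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
}

#' Run the full motion -> mesh -> simulation -> metrics pipeline
#'
#' Drives every stage from one configuration (see [default_config()]):
#' generates (or loads) the wall motion, triangulates the most-contracted
#' configuration, runs the moving-domain simulation, and writes the
#' metrics CSV, convergence log, VTU series and a provenance manifest to
#' `out_dir`.  Deterministic under a fixed config and seed.
#'
#' @param config configuration list or path to a JSON config
#' @param out_dir output directory
#' @param motion optional precomputed `wall_motion_field` (otherwise the
#'   `synthetic` section chooses the generator)
#' @param write_fields also write the VTU series (default TRUE)
#' @return invisible list of artifact paths and the `cardio_sim`
#' @export
pipeline_run <- function(config = default_config(), out_dir, motion = NULL,
                         write_fields = TRUE) {
  cfg <- if (is.character(config)) load_config(config) else
    validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(cfg$seed)
  t0 <- Sys.time()
  if (is.null(motion))
    motion <- run_stage("wall_motion", {
      if (cfg$synthetic$kind == "peristaltic")
        generate_peristaltic_motion(
          peristaltic_spec(n_cycles = cfg$synthetic$n_cycles))
      else if (cfg$synthetic$kind == "two_chamber")
        generate_two_chamber_motion(
          two_chamber_spec(n_cycles = cfg$synthetic$n_cycles))
      else stop(sprintf("unknown synthetic kind '%s'", cfg$synthetic$kind))
    })
  mesh <- run_stage("meshgen", {
    areas <- vapply(seq_along(motion$times), function(k)
      abs(polygon_area(motion$positions[, , k])), numeric(1))
    kref <- which.min(areas)
    triangulate(motion$positions[, , kref], cfg$mesh$edge_length,
                motion$tags)
  })
  props <- blood_properties(cfg$fluid$density, cfg$fluid$viscosity)
  tcfg <- time_config(dt = cfg$time$dt,
                      t_end = motion$times[1] +
                        min(cfg$time$t_end,
                            motion$times[length(motion$times)] -
                              motion$times[1]),
                      rho_inf = cfg$time$rho_inf,
                      newton_tol = cfg$time$newton_tol,
                      max_newton = cfg$time$max_newton,
                      ci = cfg$stabilization$ci,
                      lsic = cfg$stabilization$lsic)
  bc <- flow_bc(inlet_type = "traction", beta = cfg$backflow_beta)
  sim <- run_stage("ale_solver",
                   run_simulation(mesh, props, bc, tcfg, motion = motion))
  metrics <- run_stage("hemodynamics",
                       hemodynamics_series(sim, k = cfg$metrics$k,
                                           av_window = cfg$metrics$av_window))
  paths <- list(metrics = file.path(out_dir, "metrics.csv"),
                log = file.path(out_dir, "convergence_log.csv"),
                config = file.path(out_dir, "config.json"),
                manifest = file.path(out_dir, "manifest.json"))
  write.csv(metrics, paths$metrics, row.names = FALSE)
  write.csv(sim$log, paths$log, row.names = FALSE)
  save_config(cfg, paths$config)
  if (write_fields)
    paths$fields <- write_field_series(sim, file.path(out_dir, "fields"))
  manifest <- list(
    package = "cardioflow2d",
    version = as.character(utils::packageVersion("cardioflow2d")),
    seed = cfg$seed,
    config_file = "config.json",
    n_steps = nrow(sim$log),
    all_converged = all(sim$log$converged),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(c(paths, list(sim = sim, metrics = metrics)))
}
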
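#' Read and write force-profile CSV files
#'
#' CSV dialect: comma-separated, '.' decimal, UTF-8, mandatory header with
#' columns `position_mm`, `depth_mm`, `force_N_per_mm`, `source`.  One row
#' per (position, indentation depth); the round trip is lossless to 12
#' significant digits.
#'
#' @param profiles list of [force_profile()] objects.
#' @param path CSV file path.
#' @return `read_profiles`: a list of [force_profile()]s (one per
#'   indentation depth); `write_profiles`: `path`, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  stopifnot(is.list(profiles))
  rows <- do.call(rbind, lapply(profiles, function(p) {
    stopifnot(inherits(p, "force_profile"))
    data.frame(position_mm = sprintf("%.12g", p$positions),
               depth_mm = sprintf("%.12g", p$indentation_depth),
               force_N_per_mm = sprintf("%.12g", p$forces),
               source = p$source)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_profiles
#' @export
read_profiles <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("position_mm", "depth_mm", "force_N_per_mm", "source")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("profile CSV is missing column(s): ", paste(miss, collapse = ", "))
  for (col in c("position_mm", "depth_mm", "force_N_per_mm")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (anyNA(v))
      stop("non-numeric value in column ", col, " at row ",
           which(is.na(v))[1])
    df[[col]] <- v
  }
  bad <- which(df$force_N_per_mm < 0)
  if (length(bad))
    stop("negative force at row ", bad[1])
  out <- lapply(split(df, df$depth_mm), function(g) {
    if (is.unsorted(g$position_mm, strictly = TRUE))
      stop("positions not strictly ascending for indentation depth ",
           g$depth_mm[1], " (row ",
           which(diff(g$position_mm) <= 0)[1] + 1, " of the group)")
    src <- unique(g$source)
    if (length(src) != 1 ||
        !src %in% c("simulated", "measured", "synthetic"))
      stop("invalid or mixed source tag for indentation depth ", g$depth_mm[1])
    force_profile(indentation_depth = g$depth_mm[1],
                  positions = g$position_mm, forces = g$force_N_per_mm,
                  source = src)
  })
  out[order(vapply(out, `[[`, numeric(1), "indentation_depth"))]
}

#' Write and read curvature tables
#'
#' CSV with columns `position_mm`, `depth_mm`, `d2F_dx2`.
#'
#' @param curvatures list of [curvature_profile()] objects.
#' @param path CSV file path.
#' @return `path` invisibly, or a data frame for the reader.
#' @export
write_curvatures <- function(curvatures, path) {
  rows <- do.call(rbind, lapply(curvatures, function(cp) {
    data.frame(position_mm = sprintf("%.12g", cp$positions),
               depth_mm = sprintf("%.12g", cp$indentation_depth),
               d2F_dx2 = sprintf("%.12g", cp$second_derivative))
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_curvatures
#' @export
read_curvatures <- function(path) {
  df <- utils::read.csv(path)
  need <- c("position_mm", "depth_mm", "d2F_dx2")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("curvature CSV is missing column(s): ", paste(miss, collapse = ", "))
  df
}

#' Serialize a calibration library as JSON
#'
#' @param lib a [build_library()] result.
#' @param path JSON file path.
#' @return `path` invisibly; the reader returns the library.
#' @export
write_library <- function(lib, path) {
  stopifnot(inherits(lib, "calibration_library"))
  obj <- list(schema_version = 1L,
              diameters = lib$diameters, depths = lib$depths,
              indentation_depths = lib$indentation_depths,
              values = as.numeric(lib$values),
              dim = dim(lib$values),
              provenance = lib$provenance)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_library
#' @export
read_library <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  vals <- array(obj$values, dim = obj$dim,
                dimnames = list(depth = obj$depths, diameter = obj$diameters,
                                indentation = obj$indentation_depths))
  structure(list(diameters = obj$diameters, depths = obj$depths,
                 indentation_depths = obj$indentation_depths,
                 values = vals, provenance = obj$provenance),
            class = "calibration_library")
}

#' Read and write material definitions as YAML
#'
#' Block format: `model: ogden|neo_hookean`, with `mu`, `alpha`, `d` (Ogden,
#' MPa / dimensionless / 1/MPa) or `c1` (neo-Hookean, MPa).
#'
#' @param mat an [ogden_material()] or [neo_hookean_material()].
#' @param path YAML file path.
#' @return The material for the reader; `path` invisibly for the writer.
#' @export
write_material_yaml <- function(mat, path) {
  obj <- if (inherits(mat, "ogden_material")) {
    list(model = "ogden", mu = mat$mu, alpha = mat$alpha, d = mat$d)
  } else if (inherits(mat, "neo_hookean_material")) {
    list(model = "neo_hookean", c1 = mat$c1)
  } else stop("unsupported material class")
  writeLines(c("# units: mu, c1 in MPa; d in 1/MPa; alpha dimensionless",
               yaml::as.yaml(obj)), path)
  invisible(path)
}

#' @rdname write_material_yaml
#' @export
read_material_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  material_from_list(obj)
}

material_from_list <- function(obj) {
  if (is.null(obj$model)) stop("material block must name a model")
  switch(obj$model,
    ogden = ogden_material(mu = unlist(obj$mu), alpha = unlist(obj$alpha),
                           d = if (length(obj$d)) unlist(obj$d) else
                             numeric(0)),
    neo_hookean = neo_hookean_material(obj$c1),
    stop("unknown material model: ", obj$model))
}

.config_keys <- c("units", "domain", "materials", "protocol", "nodule",
                  "noise", "library", "solver", "output", "seed")

#' Read and validate a run configuration
#'
#' YAML schema (units fixed package-wide to mm / N / MPa and asserted on
#' load; unknown top-level keys are rejected):
#' `units`, `domain {width, height, mesh_size}`,
#' `materials {healthy, cancer[, mixture]}` (material blocks as in
#' [read_material_yaml()]), `protocol {positions | n_positions, depths,
#' indenter_radius, increments}`, `nodule {shape, ...}`,
#' `noise {sigma, contact_offset, seed}`, `library {depths, diameters,
#' smoothing}`, `solver {mode, penalty_factor}`, `output`, `seed`.
#'
#' @param path YAML file path, or a list with the same structure.
#' @return A validated `run_config` list.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.list(path)) path else yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), .config_keys)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  u <- cfg$units
  if (is.null(u) || !identical(u$length, "mm") || !identical(u$force, "N") ||
      !identical(u$pressure, "MPa"))
    stop("config must declare units: {length: mm, force: N, pressure: MPa}")
  for (key in c("domain", "materials", "protocol"))
    if (is.null(cfg[[key]])) stop("config is missing the ", key, " block")
  dom <- tissue_domain(cfg$domain$width, cfg$domain$height,
                       cfg$domain$mesh_size)
  mats <- lapply(cfg$materials, material_from_list)
  if (is.null(mats$healthy) || is.null(mats$cancer))
    stop("materials block must define healthy and cancer")
  pr <- cfg$protocol
  positions <- if (!is.null(pr$positions)) unlist(pr$positions) else
    probe_positions(dom$width, if (is.null(pr$n_positions)) 40 else
      pr$n_positions)
  protocol <- indentation_protocol(
    positions = positions, depths = unlist(pr$depths),
    indenter_radius = if (is.null(pr$indenter_radius)) 5 else
      pr$indenter_radius,
    increments = if (is.null(pr$increments)) 10 else pr$increments)
  nodule <- if (is.null(cfg$nodule)) NULL else {
    args <- cfg$nodule
    if (!is.null(args$vertices)) args$vertices <-
        matrix(unlist(args$vertices), ncol = 2, byrow = TRUE)
    if (!is.null(args$diameters)) args$diameters <- unlist(args$diameters)
    do.call(nodule_spec, args)
  }
  noise <- if (is.null(cfg$noise)) noise_model() else
    noise_model(sigma = if (is.null(cfg$noise$sigma)) 0 else cfg$noise$sigma,
                contact_offset = if (is.null(cfg$noise$contact_offset)) 0 else
                  cfg$noise$contact_offset,
                seed = if (is.null(cfg$noise$seed)) 1L else cfg$noise$seed)
  solver <- utils::modifyList(list(mode = "displacement",
                                   penalty_factor = 200),
                              if (is.null(cfg$solver)) list() else cfg$solver)
  structure(list(domain = dom, materials = mats, protocol = protocol,
                 nodule = nodule, noise = noise,
                 library = cfg$library, solver = solver,
                 output = cfg$output,
                 seed = if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)),
            class = "run_config")
}

#' Run the full localization / quantification pipeline
#'
#' End-to-end execution: synthesize (or accept) a measurement, simulate the
#' healthy baseline, build (or accept) the calibration library, localize the
#' nodule, extract the spline second derivative at the nodule position for
#' every indentation depth, invert each against the library, intersect the
#' depth-diameter curves, and report the chosen solution with its equivalent
#' radius.  Every stage is logged with wall time and input/output hashes;
#' the run is deterministic given the config and seed.
#'
#' @param config a `run_config` (see [read_run_config()]) or path to one.
#' @param measured optional list of [force_profile()]s; synthesized from the
#'   config's nodule and noise model when omitted.
#' @param library optional prebuilt [build_library()] result.
#' @param verbose print stage progress.
#' @return A list with `outcome` (`"quantified"` or `"no_nodule"`),
#'   `result` (a [quantification_result][intersect_curves()] or `NULL`),
#'   `localized_position`, `errors` (vs the config's nodule when present),
#'   and `log` (one entry per stage).
#' @export
run_pipeline <- function(config, measured = NULL, library = NULL,
                         verbose = FALSE) {
  if (!inherits(config, "run_config")) config <- read_run_config(config)
  log <- list()
  stage <- function(name, input, fun) {
    t0 <- proc.time()[["elapsed"]]
    out <- fun()
    log[[length(log) + 1]] <<- list(
      stage = name, seconds = round(proc.time()[["elapsed"]] - t0, 3),
      input_hash = provenance_hash(input), output_hash = provenance_hash(out))
    if (verbose) message(sprintf("[%s] %.2fs", name,
                                 log[[length(log)]]$seconds))
    out
  }
  smoothing <- if (!is.null(library)) library$provenance$smoothing else
    if (!is.null(config$library$smoothing)) config$library$smoothing else
      "auto"
  mode <- config$solver$mode

  if (is.null(measured)) {
    bundle <- list(domain = config$domain, nodule = config$nodule,
                   materials = config$materials, protocol = config$protocol)
    measured <- stage("synthesize_measurement", bundle, function()
      synth_measurement(bundle, config$noise, mode = mode))
  }
  baseline <- stage("simulate_baseline", config, function() {
    mesh0 <- build_mesh(config$domain, NULL)
    sweep_indent(mesh0, config$materials, config$protocol, mode = mode)
  })
  # localize on the deepest indentation (largest signal-to-noise); a clean
  # no-nodule outcome needs no calibration library
  kdeep <- which.max(vapply(measured, `[[`, numeric(1), "indentation_depth"))
  pos <- stage("localize", list(measured[[kdeep]], baseline[[kdeep]]),
               function() localize_nodule(measured[[kdeep]],
                                          baseline[[kdeep]]))
  if (is.na(pos))
    return(list(outcome = "no_nodule", result = NULL,
                localized_position = NA_real_, errors = NULL, log = log))
  if (is.null(library)) {
    if (is.null(config$library))
      stop("no calibration library given and none configured")
    library <- stage("build_library", config, function()
      build_library(config$domain, config$materials, config$protocol,
                    diameters = unlist(config$library$diameters),
                    depths = unlist(config$library$depths),
                    smoothing = smoothing, mode = mode))
  }
  result <- stage("invert_intersect", list(measured, library, pos),
                  function() quantify_profiles(library, measured, pos,
                                               smoothing = smoothing))
  errors <- if (!is.null(config$nodule))
    quantification_errors(result, config$nodule) else NULL
  list(outcome = "quantified", result = result, localized_position = pos,
       errors = errors, log = log)
}

#' Serialize a quantification result as JSON
#'
#' @param result a [quantification_result][intersect_curves()].
#' @param path JSON file path.
#' @return `path`, invisibly.
#' @export
write_result <- function(result, path) {
  stopifnot(inherits(result, "quantification_result"))
  obj <- list(schema_version = 1L,
              chosen = as.list(result$chosen),
              residual = result$residual,
              equivalent_radius_mm = result$equivalent_radius,
              area_mm2 = result$area,
              candidates = result$candidates)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
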
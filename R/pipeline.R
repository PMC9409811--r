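# End-to-end orchestration: phantom -> field -> thermal -> lesion ->
# synthetic post-op image -> volumetrics, from a single serializable
# configuration.

#' Reference simulation grid
#'
#' Graded axisymmetric grid used by the reference runs: 0.25 mm cells in
#' a window around the electrode tip, geometrically stretched to a
#' 50 mm domain radius (far-field boundary).
#'
#' @param h_fine Fine spacing near the tip, mm.
#' @param r_extent,z_extent Domain size, mm.
#' @param properties Tissue property table.
#' @param labels Fill label.
#' @return A \code{phantom_grid}.
#' @export
reference_grid <- function(h_fine = 0.25, r_extent = 50,
                           z_extent = c(-50, 50), labels = 1L,
                           properties = brain_tissue_table()) {
  axisymmetric_grid(r_extent = r_extent, z_extent = z_extent,
                    spacing = 1.5,
                    fine_window = list(r = c(0, 12), z = c(-14, 12)),
                    h_fine = h_fine, growth = 1.2, labels = labels,
                    properties = properties)
}

#' Assemble a pipeline run configuration
#'
#' Bundles everything one reproducible run needs: the phantom
#' description, electrode, protocol, trajectory plan, solver settings,
#' imaging settings and the top-level seed. The configuration is fully
#' serializable (YAML/JSON); a run re-executed from its saved
#' configuration produces identical reports.
#'
#' @param phantom List describing the simulation phantom:
#'   \code{layers}, \code{spacing}, \code{extent}, and optionally
#'   \code{fine_window}, \code{h_fine}, \code{growth} (see
#'   [build_layered_phantom()]).
#' @param electrode An [electrode_spec()].
#' @param protocol An [ablation_protocol()].
#' @param plan A [trajectory_plan()].
#' @param solver List: \code{dt} (s), \code{electrode_thermal}.
#' @param imaging List: \code{voxel_size} (mm), \code{contrast},
#'   \code{noise_sd}, \code{background}.
#' @param seed Top-level integer seed; stage seeds are derived from it.
#' @param pi_value Pi constant of the planning volume formula.
#' @param case_id Label for the run.
#' @return Object of class \code{run_config}.
#' @export
run_config <- function(phantom, electrode = electrode_spec(),
                       protocol = ablation_protocol(), plan,
                       solver = list(dt = 0.1,
                                     electrode_thermal = "auto"),
                       imaging = list(voxel_size = 1, contrast = 100,
                                      noise_sd = 5, background = 100),
                       seed = 1L, pi_value = 3.14, case_id = "run") {
  structure(list(phantom = phantom, electrode = electrode,
                 protocol = protocol, plan = plan, solver = solver,
                 imaging = imaging, seed = as.integer(seed),
                 pi_value = pi_value, case_id = case_id),
            class = "run_config")
}

#' Validate a run configuration
#'
#' Checks every invariant the pipeline relies on and reports each
#' violation with the path of the offending field. A configuration is
#' valid iff the returned character vector is empty.
#'
#' @param config A [run_config()].
#' @return Character vector of error messages (empty when valid).
#' @examples
#' cfg <- preset_reference()
#' validate_config(cfg)   # character(0)
#' @export
validate_config <- function(config) {
  errs <- character(0)
  p <- config$phantom
  if (is.null(p$spacing) || !(p$spacing > 0))
    errs <- c(errs, "phantom$spacing: must be > 0")
  if (is.null(p$layers) || !length(p$layers))
    errs <- c(errs, "phantom$layers: at least one layer required")
  if (is.null(p$extent))
    errs <- c(errs, "phantom$extent: missing")
  el <- config$electrode
  if (!inherits(el, "electrode_spec")) {
    errs <- c(errs, "electrode: not an electrode_spec")
  } else if (el$type == "needle" && !(el$shaft_diameter > 0)) {
    errs <- c(errs, "electrode$shaft_diameter: must be > 0")
  }
  pr <- config$protocol
  if (!inherits(pr, "ablation_protocol")) {
    errs <- c(errs, "protocol: not an ablation_protocol")
  } else {
    if (!(pr$power_min > 0) || pr$power_min > pr$power_max)
      errs <- c(errs,
                "protocol$power_min/power_max: need 0 < min <= max")
    if (pr$duration < 0)
      errs <- c(errs, "protocol$duration: must be >= 0")
    if (!(pr$target_temp > pr$baseline_temp))
      errs <- c(errs, "protocol$target_temp: must exceed baseline_temp")
  }
  if (!inherits(config$plan, "trajectory_plan"))
    errs <- c(errs, "plan: not a trajectory_plan")
  if (is.null(config$solver$dt) || !(config$solver$dt > 0))
    errs <- c(errs, "solver$dt: must be > 0")
  im <- config$imaging
  if (is.null(im$voxel_size) || !(im$voxel_size > 0))
    errs <- c(errs, "imaging$voxel_size: must be > 0")
  if (!is.null(im$noise_sd) && im$noise_sd < 0)
    errs <- c(errs, "imaging$noise_sd: must be >= 0")
  errs
}

write_volume_nifti <- function(arr, voxel_size, path) {
  nii <- RNifti::asNifti(arr * 1)
  RNifti::pixdim(nii) <- rep(voxel_size, length(dim(arr)))
  RNifti::writeNifti(nii, path)
  invisible(path)
}

#' Execute a full simulation-and-validation run
#'
#' Runs the whole pipeline from a configuration: builds the phantom,
#' solves the electro-quasistatic field, integrates the bioheat
#' equation, extracts the 60 degree C isotherm radius, composes the
#' planned multi-trajectory volume, rasterizes the lesion solids,
#' synthesizes a post-ablation image and measures the ablated volume on
#' it. With \code{out_dir} set, all artifacts (configuration, reports,
#' controller log, lesion mask and image volumes) are written to disk;
#' deterministic stages are bit-identical across re-runs of the same
#' configuration.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed), or \code{NULL}
#'   for no artifacts.
#' @return List of class \code{pipeline_result}: the isotherm
#'   \code{radius} (mm), the \code{estimate} (lesion volumes), the
#'   volume \code{report}, plus the \code{field}, \code{temperature},
#'   \code{mask} and \code{image} objects and the configuration.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  errs <- validate_config(config)
  if (length(errs))
    stop("validation error:\n  ", paste(errs, collapse = "\n  "))
  stage_name <- "setup"
  stage <- function(name, expr) {
    stage_name <<- name
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  ph <- config$phantom
  grid <- stage("phantom", build_layered_phantom(
    ph$layers, spacing = ph$spacing, extent = ph$extent,
    mode = "axisymmetric-rz",
    properties = if (is.null(ph$properties)) brain_tissue_table()
                 else ph$properties,
    fine_window = ph$fine_window,
    h_fine = if (is.null(ph$h_fine)) ph$spacing else ph$h_fine,
    growth = if (is.null(ph$growth)) 1.3 else ph$growth))

  if (config$protocol$duration > 0) {
    temperature <- stage("bioheat", run_transient(
      grid, config$electrode, config$protocol, dt = config$solver$dt,
      electrode_thermal = if (is.null(config$solver$electrode_thermal))
        "auto" else config$solver$electrode_thermal))
    field <- temperature$field
    radius <- stage("isotherm",
                    as.numeric(isotherm_radius(temperature, 60)))
  } else {
    temperature <- NULL; field <- NULL; radius <- 0
  }

  estimate <- stage("compose", compose_plan(config$plan, radius,
                                            pi_value = config$pi_value))
  mask <- stage("rasterize", rasterize_lesion(
    estimate, config$plan, voxel_size = config$imaging$voxel_size))
  image <- stage("postop", make_postop_image(
    mask, contrast = config$imaging$contrast,
    noise_sd = if (is.null(config$imaging$noise_sd)) 0
               else config$imaging$noise_sd,
    seed = config$seed + 1L,
    background = if (is.null(config$imaging$background)) 100
                 else config$imaging$background))
  v_meas <- stage("measure", suppressWarnings(measure_volume(image)))

  pe <- if (estimate$v_total > 0)
    percentage_error(estimate$v_total, v_meas, digits = NULL) else NA_real_
  report <- structure(list(
    cases = data.frame(case_id = config$case_id,
                       v_calc = round(estimate$v_total, 2),
                       v_meas = round(v_meas, 2),
                       pct_error = round(pe, 1)),
    mean_error = round(pe, 1), sd_error = 0),
    class = "volume_report")

  result <- structure(list(config = config, grid = grid, field = field,
                           temperature = temperature, radius = radius,
                           estimate = estimate, mask = mask,
                           image = image, v_meas = v_meas,
                           report = report),
                      class = "pipeline_result")
  if (!is.null(out_dir)) write_artifacts(result, out_dir)
  result
}

write_artifacts <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  config <- result$config
  save_run_config(config, file.path(out_dir, "config.yaml"))

  est <- result$estimate
  scalars <- list(
    case_id = config$case_id,
    isotherm_radius_mm = result$radius,
    isotherm_diameter_mm = 2 * result$radius,
    v_calc_mm3 = est$v_total,
    v_calc_geometric_mm3 = est$v_total_geom,
    v_measured_mm3 = result$v_meas,
    pct_error = result$report$cases$pct_error,
    power_W = if (!is.null(result$field)) result$field$power_total else 0,
    impedance_ohm = if (!is.null(result$field)) result$field$impedance
                    else NA,
    seed = config$seed,
    package_version = as.character(utils::packageVersion("rfablate")))
  jsonlite::write_json(scalars, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(result$report$cases,
                   file.path(out_dir, "report.csv"), row.names = FALSE)
  per_traj <- data.frame(trajectory = seq_along(est$r), r_mm = est$r,
                         n = est$n, v_eq1_mm3 = est$v_eq1,
                         v_geom_mm3 = est$v_geom)
  utils::write.csv(per_traj, file.path(out_dir, "trajectories.csv"),
                   row.names = FALSE)
  if (!is.null(result$temperature)) {
    utils::write.csv(result$temperature$tip_trace,
                     file.path(out_dir, "controller_log.csv"),
                     row.names = FALSE)
    writeLines(c(sprintf("field residual: %.3e",
                         result$field$residual),
                 result$temperature$log),
               file.path(out_dir, "run_log.txt"))
  }
  write_volume_nifti(result$mask$mask, result$mask$voxel_size,
                     file.path(out_dir, "lesion_mask.nii.gz"))
  write_volume_nifti(result$image$intensities, result$image$voxel_size,
                     file.path(out_dir, "postop_image.nii.gz"))
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>", x$config$case_id, "\n")
  cat(sprintf("  60 C isotherm radius: %.2f mm (diameter %.2f mm)\n",
              x$radius, 2 * x$radius))
  print(x$report)
  invisible(x)
}

#' Reference run configurations
#'
#' \code{preset_reference()} is the reference grey-matter run: graded
#' axisymmetric grid (0.25 mm near the tip, 50 mm domain), the clinical
#' 1.6 mm / 3 mm electrode, and a single 5-pull-back trajectory. In
#' \code{"constant_voltage"} mode (default) it emulates the published
#' simulation (34 V for the full 90 s), which is the configuration that
#' reproduces the published lesion radius; in
#' \code{"temperature_controlled"} mode it emulates the clinical
#' generator (thermocouple-sensed ramp to 80 degrees C within the 2-6 W
#' clamp).
#'
#' @param mode Protocol mode.
#' @param h_fine Fine grid spacing, mm.
#' @param seed Top-level seed.
#' @param label Tissue label filling the phantom (1 = grey matter).
#' @param n_pullbacks Pull-backs of the single trajectory.
#' @return A [run_config()].
#' @export
preset_reference <- function(mode = c("constant_voltage",
                                      "temperature_controlled"),
                             h_fine = 0.25, seed = 1L, label = 1L,
                             n_pullbacks = 5L) {
  mode <- match.arg(mode)
  run_config(
    phantom = list(layers = list(list(label = label,
                                      region = list(type = "all"))),
                   spacing = 1.5,
                   extent = list(r = 50, z = c(-50, 50)),
                   fine_window = list(r = c(0, 12), z = c(-14, 12)),
                   h_fine = h_fine, growth = 1.2),
    electrode = electrode_spec(),
    protocol = ablation_protocol(mode = mode),
    plan = trajectory_plan(entry = c(0, 0, 40), target = c(0, 0, 0),
                           n_pullbacks = n_pullbacks),
    imaging = list(voxel_size = 1, contrast = 100, noise_sd = 5,
                   background = 100),
    seed = seed, case_id = paste0("reference-", mode))
}

#' Patient-like replication presets
#'
#' Three synthetic cases mirroring the published series structure:
#' case 1 (hippocampal target, grey matter, 3 trajectories), case 2
#' (corpus-callosum-like white-matter target, 2 trajectories), case 3
#' (mesial temporal grey-matter target, 2 trajectories). Pull-back
#' counts are chosen so the planned volumes are of the same order as
#' the published per-case volumes; the published per-trajectory radii
#' and counts are not recoverable, so these presets are structural
#' stand-ins, not reconstructions.
#'
#' @param case 1, 2 or 3.
#' @param h_fine Fine grid spacing, mm.
#' @param seed Top-level seed.
#' @return A [run_config()].
#' @export
preset_patient <- function(case, h_fine = 0.25, seed = 1L) {
  stopifnot(case %in% 1:3)
  sep <- 11   # trajectory spacing, mm (solids disjoint for r < 5.5)
  mk_plan <- function(ntraj, n_pb) {
    off <- (seq_len(ntraj) - 1) * sep
    trajectory_plan(entry = cbind(off, 0, 40),
                    target = cbind(off, 0, 0),
                    n_pullbacks = n_pb)
  }
  spec <- switch(case,
    list(label = 3L, layers = list(
           list(label = 1L, region = list(type = "all")),
           list(label = 3L, region = list(type = "cylinder",
                                          radius = 20,
                                          z = c(-25, 25)))),
         plan = mk_plan(3, c(11L, 11L, 11L))),
    list(label = 2L, layers = list(
           list(label = 2L, region = list(type = "all"))),
         plan = mk_plan(2, c(2L, 3L))),
    list(label = 1L, layers = list(
           list(label = 1L, region = list(type = "all"))),
         plan = mk_plan(2, c(6L, 6L))))
  run_config(
    phantom = list(layers = spec$layers, spacing = 1.5,
                   extent = list(r = 50, z = c(-50, 50)),
                   fine_window = list(r = c(0, 12), z = c(-14, 12)),
                   h_fine = h_fine, growth = 1.2),
    electrode = electrode_spec(),
    protocol = ablation_protocol(mode = "constant_voltage"),
    plan = spec$plan,
    imaging = list(voxel_size = 1, contrast = 100, noise_sd = 5,
                   background = 100),
    seed = seed + case, case_id = paste0("patient", case, "-like"))
}

#' Run the three patient-like presets and summarize
#'
#' Executes the patient-like presets and assembles the combined
#' calculated-vs-measured volume report (the synthetic analogue of the
#' published per-case error table).
#'
#' @param cases Subset of 1:3.
#' @param out_dir Optional artifact directory (one subdirectory per
#'   case).
#' @param h_fine Fine grid spacing, mm.
#' @param seed Top-level seed.
#' @return A \code{volume_report} with one row per case; the individual
#'   \code{pipeline_result}s are attached as attribute \code{"runs"}.
#' @export
replicate_cases <- function(cases = 1:3, out_dir = NULL, h_fine = 0.25,
                            seed = 1L) {
  runs <- lapply(cases, function(i)
    run_pipeline(preset_patient(i, h_fine = h_fine, seed = seed),
                 out_dir = if (is.null(out_dir)) NULL
                           else file.path(out_dir,
                                          paste0("patient", i))))
  rep <- volume_report(
    case_id = vapply(runs, function(r) r$config$case_id, character(1)),
    v_calc = vapply(runs, function(r) r$estimate$v_total, numeric(1)),
    v_meas = vapply(runs, function(r) r$v_meas, numeric(1)))
  attr(rep, "runs") <- runs
  rep
}
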
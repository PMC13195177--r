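# Configuration files, phantom serialization, and the end-to-end pipeline.
#
# Run configuration is a nested YAML file; unknown keys are rejected and
# omitted keys are filled with the documented defaults, so a loaded config
# always has the full canonical structure and round-trips bit-identically
# through save_config()/load_config().

default_run_config <- function() {
  list(
    seed = 1L,
    laterality = "left",
    prescription_Gy = 50,
    phantom = list(grid_shape = c(128L, 128L), spacing_mm = 3,
                   slice_thickness_mm = 3),
    beams = list(arc_start = NULL, arc_stop = NULL, n_angles = 28L,
                 beamlets_per_angle = 24L, margin_mm = 10),
    influence = list(attenuation_per_mm = 0.005, lateral_sigma_mm = 3,
                     scatter_fraction = 0.05, scatter_sigma_mm = 24),
    optimizer = list(inner_iterations = 40L, tolerance = 1e-7),
    controller = list(max_loops = 12L, saturation_tol = 0.005,
                      saturation_consecutive = 2L, v95_trigger_pct = 95,
                      repair_loops = 2L, eud_floor_Gy = 0.1),
    weights = list(ptv = 3000, oar = 10, normal_tissue = 1000),
    classes = list(
      class1 = list(m = 0.44, n = 0.8, target = 0.45, phase2_fraction = 0.5),
      class2 = list(m = 0.089, n = 0.8, target = 2.25, phase2_fraction = 0.2)),
    output_dir = "ofvplan_run")
}

merge_config <- function(defaults, user, path = "") {
  extra <- setdiff(names(user), names(defaults))
  if (length(extra))
    stop("unknown config key(s): ",
         paste0(path, extra, collapse = ", "))
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      if (!is.list(user[[k]]))
        stop("config key '", path, k, "' must be a mapping")
      defaults[[k]] <- merge_config(defaults[[k]], user[[k]],
                                    paste0(path, k, "."))
    } else {
      defaults[k] <- user[k]   # keeps NULL assignments (e.g. arc defaults)
    }
  }
  defaults
}

validate_run_config <- function(cfg) {
  if (!cfg$laterality %in% c("left", "right"))
    stop("laterality must be 'left' or 'right'")
  if (cfg$prescription_Gy <= 0) stop("prescription_Gy must be > 0")
  if (cfg$weights$ptv <= 0 || cfg$weights$oar <= 0)
    stop("weights must be positive")
  if (cfg$controller$max_loops < 3)
    stop("controller.max_loops must be >= 3 (phases cannot fit otherwise)")
  for (cl in c("class1", "class2")) {
    c0 <- cfg$classes[[cl]]
    if (c0$m <= 0 || c0$n <= 0 || c0$n >= 1 || c0$target <= 0)
      stop("classes.", cl, ": require m > 0, 0 < n < 1, target > 0")
  }
  cfg
}

#' Load a run configuration
#'
#' Reads a YAML run configuration, rejects unknown keys, fills all omitted
#' keys with the package defaults (prescription 50 Gy, PTV/OAR weights
#' 3000/10, class targets 2.25/0.45, 40 inner iterations, 12 outer loops)
#' and validates the result.
#'
#' @param path path to a YAML file.
#' @return validated `ofv_run_config` (nested named list).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  cfg <- validate_run_config(merge_config(default_run_config(), user))
  class(cfg) <- "ofv_run_config"
  cfg
}

#' Save a run configuration
#'
#' Writes the canonical (fully populated) YAML form; `load_config()` on the
#' result reproduces the object exactly.
#'
#' @param config an `ofv_run_config` (or compatible list).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  cfg <- unclass(config)
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}

as_controller_config <- function(cfg) {
  controller_config(
    prescription_Gy = cfg$prescription_Gy,
    ptv_weight = cfg$weights$ptv, oar_weight = cfg$weights$oar,
    max_loops = cfg$controller$max_loops,
    saturation_tol = cfg$controller$saturation_tol,
    saturation_consecutive = cfg$controller$saturation_consecutive,
    v95_trigger_pct = cfg$controller$v95_trigger_pct,
    repair_loops = cfg$controller$repair_loops,
    eud_floor_Gy = cfg$controller$eud_floor_Gy,
    normal_tissue_weight = cfg$weights$normal_tissue,
    classes = organ_classes(class1 = cfg$classes$class1,
                            class2 = cfg$classes$class2),
    optimizer = optimizer_config(
      inner_iterations = cfg$optimizer$inner_iterations,
      tolerance = cfg$optimizer$tolerance))
}

#' Write a phantom container
#'
#' Single-file JSON array container (format `ofvplan-phantom v1`): a
#' metadata header (grid shape, spacing, slice thickness, laterality, seed)
#' plus each structure mask stored as its sorted 1-based column-major
#' voxel indices.
#'
#' @param phantom an `ofv_phantom`.
#' @param path output path (conventionally `.ctr.json`).
#' @return `path`, invisibly.
#' @export
write_phantom <- function(phantom, path) {
  stopifnot(inherits(phantom, "ofv_phantom"))
  obj <- list(
    format = "ofvplan-phantom", version = 1L,
    grid_shape = phantom$grid_shape, spacing_mm = phantom$spacing_mm,
    slice_thickness_mm = phantom$slice_thickness_mm,
    laterality = phantom$laterality, seed = phantom$seed,
    masks = lapply(phantom$masks, which))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a phantom container
#'
#' @param path a file written by [write_phantom()].
#' @return an `ofv_phantom` (without the generation config).
#' @export
read_phantom <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "ofvplan-phantom"))
    stop("not an ofvplan phantom container: ", path)
  gs <- as.integer(obj$grid_shape)
  masks <- lapply(obj$masks, function(ix) {
    m <- matrix(FALSE, gs[1], gs[2]); m[as.integer(ix)] <- TRUE; m
  })
  vox_cm3 <- obj$spacing_mm^2 * obj$slice_thickness_mm / 1000
  structure(list(grid_shape = gs, spacing_mm = obj$spacing_mm,
                 slice_thickness_mm = obj$slice_thickness_mm,
                 laterality = obj$laterality, seed = as.integer(obj$seed),
                 masks = masks,
                 pseudo_volumes_cm3 = vapply(masks, function(m)
                   sum(m) * vox_cm3, numeric(1)),
                 voxel_volume_cm3 = vox_cm3, config = NULL),
            class = "ofv_phantom")
}

#' Run the end-to-end pipeline
#'
#' Generates the phantom, builds the beam set and influence matrix, runs
#' the OFV-feedback controller, and writes five artifacts into the output
#' directory: `phantom.ctr.json`, `trajectory.csv` (loop, organ, ofv,
#' max_eud_Gy, mean_dose_Gy), `dvh.csv` (structure, dose_Gy, volume_pct),
#' `report.json` (plan metrics and clinical-goal table), and `summary.txt`.
#' The single seed in the config governs all randomness, so repeated runs
#' produce byte-identical CSV artifacts.
#'
#' @param config an `ofv_run_config` (from [load_config()]) or a path to a
#'   YAML config file.
#' @param output_dir overrides the config's output directory.
#' @param verbose log controller progress.
#' @return the output directory, invisibly; the full `ofv_run` is attached
#'   as attribute `run`.
#' @export
run_pipeline <- function(config, output_dir = NULL, verbose = FALSE) {
  if (is.character(config)) config <- load_config(config)
  cfg <- validate_run_config(merge_config(default_run_config(),
                                          unclass(config)))
  out <- if (is.null(output_dir)) cfg$output_dir else output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)

  phantom <- generate_phantom(
    phantom_config(laterality = cfg$laterality,
                   grid_shape = cfg$phantom$grid_shape,
                   spacing_mm = cfg$phantom$spacing_mm,
                   slice_thickness_mm = cfg$phantom$slice_thickness_mm),
    seed = cfg$seed)
  beamset <- build_beamset(phantom, arc_start = cfg$beams$arc_start,
                           arc_stop = cfg$beams$arc_stop,
                           n_angles = cfg$beams$n_angles,
                           beamlets_per_angle = cfg$beams$beamlets_per_angle,
                           margin_mm = cfg$beams$margin_mm)
  influence <- compute_influence(phantom, beamset,
                                 attenuation = cfg$influence$attenuation_per_mm,
                                 lateral_sigma = cfg$influence$lateral_sigma_mm,
                                 scatter_fraction = cfg$influence$scatter_fraction,
                                 scatter_sigma = cfg$influence$scatter_sigma_mm)
  ctrl <- as_controller_config(cfg)
  run <- run_controller(phantom, beamset, ctrl, influence = influence,
                        verbose = verbose)

  write_phantom(phantom, file.path(out, "phantom.ctr.json"))

  traj <- run$trajectory$organs
  traj$ofv <- round(traj$ofv, 10)
  traj$max_eud_Gy <- round(traj$max_eud_Gy, 10)
  traj$mean_dose_Gy <- round(traj$mean_dose_Gy, 10)
  utils::write.csv(traj, file.path(out, "trajectory.csv"), row.names = FALSE)

  pm <- plan_metrics(run$plan)
  dvh_rows <- do.call(rbind, lapply(pm$dvhs, function(h)
    data.frame(structure = h$structure, dose_Gy = h$edges_Gy,
               volume_pct = round(h$volume_pct, 8))))
  utils::write.csv(dvh_rows, file.path(out, "dvh.csv"), row.names = FALSE)

  goals <- evaluate_goals(run$plan)
  report <- list(
    seed = cfg$seed, laterality = cfg$laterality,
    prescription_Gy = cfg$prescription_Gy,
    loops = max(run$trajectory$loops$loop),
    saturated = run$trajectory$saturated,
    saturation_loop = run$trajectory$saturation_loop,
    ptv_v95_pct = pm$ptv_v95_pct, ci_paddick = pm$ci_paddick, hi = pm$hi,
    external_max_Gy = pm$external_max_Gy,
    structures = pm$structures, clinical_goals = goals,
    repair = attr(run$plan, "repair"))
  jsonlite::write_json(report, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")

  sm <- c(sprintf("ofvplan run (seed %d, %s-sided)", cfg$seed, cfg$laterality),
          sprintf("outer loops: %d (%s)", max(run$trajectory$loops$loop),
                  if (run$trajectory$saturated)
                    sprintf("saturated at loop %d",
                            run$trajectory$saturation_loop)
                  else "max loops reached"),
          sprintf("PTV V95: %.2f %%  CI: %.3f  HI: %.3f", pm$ptv_v95_pct,
                  pm$ci_paddick, pm$hi),
          "final mean doses [Gy]:",
          sprintf("  %-14s %6.2f", pm$structures$structure,
                  pm$structures$mean_Gy),
          sprintf("clinical goals passed: %d / %d", sum(goals$pass),
                  nrow(goals)))
  writeLines(sm, file.path(out, "summary.txt"))

  res <- out
  attr(res, "run") <- run
  invisible(res)
}
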
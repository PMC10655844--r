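#' Write / read an ROI as JSON
#'
#' @param roi a [roi()].
#' @param path JSON path.
#' @param mesh optional cortex mesh; element ids are validated against it.
#' @return `path` invisibly / a `seeg_roi`.
#' @export
write_roi <- function(roi, path) {
  jsonlite::write_json(list(name = roi$name, element_ids = roi$element_ids),
                       path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_roi
#' @export
read_roi <- function(path, mesh = NULL) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  ids <- as.integer(x$element_ids)
  if (!is.null(mesh) && length(ids) &&
      (min(ids) < 1L || max(ids) > nrow(mesh$triangles)))
    stop("ROI element id out of range for the mesh")
  roi(ids, if (is.null(x$name)) "ROI" else x$name)
}

#' Write / read a trajectory set as JSON
#'
#' One record per trajectory (line id, entry, direction, tip depth) plus the
#' collision matrix and electrode geometry.
#'
#' @param ts a `seeg_trajectory_set`.
#' @param path JSON path.
#' @return `path` invisibly / a `seeg_trajectory_set`.
#' @export
write_trajectories <- function(ts, path) {
  payload <- list(electrode = unclass(ts$electrode),
                  shaft_samples = ts$shaft_samples,
                  trajectories = ts$trajectories,
                  collision = ts$collision)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_trajectories
#' @export
read_trajectories <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  el <- do.call(electrode_spec, x$electrode[c("n_contacts", "contact_length",
                                              "insulator_length")])
  collision <- if (!is.null(x$collision)) {
    cm <- as.matrix(x$collision)
    storage.mode(cm) <- "logical"
    cm
  }
  structure(list(trajectories = as.data.frame(x$trajectories),
                 collision = collision,
                 validity_log = NULL,
                 electrode = el, shaft_samples = x$shaft_samples),
            class = "seeg_trajectory_set")
}

#' Export a per-element recording-strength map as CSV
#'
#' Two columns (`element_id`, `strength`) suitable for colouring a cortical
#' surface in an external viewer.
#'
#' @param rs_report a `seeg_rs_report`.
#' @param path CSV path.
#' @param thr which threshold column to export (µV).
#' @return `path` invisibly.
#' @export
write_strength_csv <- function(rs_report, path, thr = 500) {
  df <- data.frame(element_id = rs_report$patch_centers,
                   strength = rs_report$recording_strength[, as.character(thr)])
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

default_run_config <- function() {
  list(
    head = list(scalp_radius = 92, skull_radius = 87, cortex_base_radius = 70,
                fold_amplitude = 8, fold_frequency = 6, mesh_subdivision = 3),
    entry_cap = list(axis = c(1, 0, 0), half_angle = 50),
    source = list(patch_area = 10, moment_density = 0.465, sigma = 0.33),
    thresholds = c(200, 500, 1000),
    trajectories = list(n_entries = 30, n_angles = 8, max_angle = 10,
                        depth_step = 3.5, max_length = 100,
                        sulci_clearance = 1.5, skull_clearance = 4,
                        midline_clearance = 4, target_count = 95000,
                        collision_threshold = 4, shaft_samples = 128),
    roi = list(axis = c(1, 0.3, 0.2), half_angle = 45, name = "cap"),
    optimizer = list(priority = c(500, 200, 1000), max_electrodes = 31),
    sulci_smooth_iters = 100,
    seed = 1L
  )
}

#' Read a pipeline run configuration
#'
#' JSON fields override the package defaults (nested lists are merged).
#'
#' @param path JSON path, or NULL for the defaults.
#' @return nested configuration list.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    user <- jsonlite::read_json(path, simplifyVector = TRUE)
    for (nm in names(user)) {
      cfg[[nm]] <- if (is.list(cfg[[nm]]) && is.list(user[[nm]]))
        modifyList(cfg[[nm]], user[[nm]]) else user[[nm]]
    }
  }
  cfg
}

#' Run the full planning pipeline
#'
#' Stages: synthetic head (with sulci derivation), candidate trajectory
#' generation + safety filters + collisions, lead-field assembly at the
#' contact lattice, patch lead field, next-best optimization, and report
#' writing. Each stage writes its artifacts into `out_dir` and is skipped
#' on re-runs when its outputs already exist, so a deleted stage output is
#' regenerated without recomputing the rest. A manifest records parameters,
#' seeds and the configuration hash.
#'
#' @param config configuration list from [read_config()].
#' @param out_dir output directory (created if missing).
#' @param quiet suppress stage messages.
#' @return invisibly, a list with the key in-memory results
#'   (`head`, `ts`, `config`, `rs_report`, paths).
#' @export
run_pipeline <- function(config = read_config(), out_dir, quiet = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  path <- function(f) file.path(out_dir, f)
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = I(17))
  cfg_hash <- fnv1a(as.character(cfg_json))
  seed <- as.integer(config$seed)

  # stage: synth
  mesh_files <- path(c("scalp.ply", "skull.ply", "cortex.ply", "sulci.ply"))
  spec <- do.call(synthetic_head_spec,
                  c(config$head, list(entry_cap = config$entry_cap, seed = seed)))
  head_model <- make_synthetic_head(spec)
  if (!all(file.exists(mesh_files))) {
    say("stage synth: generating head meshes")
    sulci <- derive_sulci_surface(head_model$cortex, config$sulci_smooth_iters)
    write_mesh(head_model$scalp, mesh_files[1])
    write_mesh(head_model$skull, mesh_files[2])
    write_mesh(head_model$cortex, mesh_files[3])
    write_mesh(sulci, mesh_files[4])
  } else say("stage synth: outputs present, skipping")
  sulci <- read_mesh(mesh_files[4])

  # stage: trajectories
  tp <- config$trajectories
  if (!file.exists(path("trajectories.json"))) {
    say("stage trajectories: sampling and filtering candidates")
    cand <- candidate_trajectories(head_model, tp$n_entries, tp$n_angles,
                                   tp$max_angle, max_length = tp$max_length,
                                   seed = seed)
    ts <- filter_valid(cand, sulci, head_model$skull, head_model$midline,
                       tp$sulci_clearance, tp$skull_clearance,
                       tp$midline_clearance,
                       shaft_samples = tp$shaft_samples)
    ts <- downsample_lines(ts, tp$target_count, seed = seed)
    ts <- collision_matrix(ts, tp$collision_threshold, tp$shaft_samples)
    write_trajectories(ts, path("trajectories.json"))
  } else say("stage trajectories: outputs present, skipping")
  ts <- read_trajectories(path("trajectories.json"))
  if (nrow(ts$trajectories) == 0) stop("stage trajectories: no valid trajectory survived the filters")

  # stage: leadfield
  ct <- contact_table(ts)
  if (!file.exists(path("leadfield.json"))) {
    say("stage leadfield: %d unique contacts x %d sources",
        nrow(ct$points), nrow(head_model$cortex$triangles))
    sources <- cortical_sources(head_model$cortex)
    lf <- build_lead_field(sources, ct$points,
                           conductivity_model(config$source$sigma))
    write_lead_field(lf, path("leadfield.json"))
  } else say("stage leadfield: outputs present, skipping")
  lf <- read_lead_field(path("leadfield.json"))

  # stage: patches (patch lead field; kept in memory, patches are cheap)
  say("stage patches: %g cm^2 patches at %g nA.m/mm^2",
      config$source$patch_area, config$source$moment_density)
  patches <- grow_patches(head_model$cortex, config$source$patch_area)
  plf <- build_patch_lead_field(lf, patches, config$source$moment_density)

  # stage: optimize
  roi_obj <- cap_roi(head_model$cortex, config$roi$axis, config$roi$half_angle,
                     config$roi$name)
  if (!file.exists(path("configuration.json"))) {
    say("stage optimize: next-best search (priority %s)",
        paste(config$optimizer$priority, collapse = "/"))
    cfg_out <- next_best_search(ts, plf, roi_obj, ct$rows,
                                priority = config$optimizer$priority,
                                max_electrodes = config$optimizer$max_electrodes,
                                seed = seed)
    jsonlite::write_json(
      list(electrodes = cfg_out$electrodes,
           trajectories = cfg_out$trajectories,
           cost_curve = cfg_out$cost_curve,
           priority = cfg_out$priority, seed = cfg_out$seed,
           P_total = cfg_out$P_total,
           rs_by_count = cfg_out$rs_report$rs_by_count,
           config_hash = cfg_hash),
      path("configuration.json"), auto_unbox = TRUE, digits = I(17))
    write_strength_csv(cfg_out$rs_report, path("strength.csv"),
                       thr = config$optimizer$priority[1])
  } else {
    say("stage optimize: outputs present, skipping")
    cfg_out <- NULL
  }

  manifest <- list(package_version = as.character(utils::packageVersion("seegrs")),
                   r_version = R.version.string,
                   seed = seed, config = config, config_hash = cfg_hash)
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                       digits = I(17))
  invisible(list(head = head_model, ts = ts, lead_field = lf,
                 patch_lead_field = plf, roi = roi_obj, config = cfg_out,
                 out_dir = out_dir, config_hash = cfg_hash))
}
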
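# Config-driven workflows wiring the modules into the three analysis paths
# (anatomy, quadrant/Flybowl behaviour, flight behaviour) plus simulation,
# with validation up front and a provenance manifest for every run.

#' Write / read a stimulation schedule as YAML
#'
#' @param schedule Schedule tibble (see [quadrant_schedule()]).
#' @param path YAML file path.
#' @return `schedule_to_yaml`: invisibly `path`; `schedule_from_yaml`: the
#'   schedule tibble.
#' @export
schedule_to_yaml <- function(schedule, path) {
  validate_schedule(schedule)
  epochs <- lapply(seq_len(nrow(schedule)), function(i) {
    e <- as.list(schedule[i, ])
    e$quadrants <- if (is.na(e$quadrants)) NULL else e$quadrants
    e
  })
  yaml::write_yaml(list(epochs = epochs), path)
  invisible(path)
}

#' @rdname schedule_to_yaml
#' @export
schedule_from_yaml <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw$epochs)) stop("schedule YAML needs an `epochs` list",
                                call. = FALSE)
  rows <- lapply(raw$epochs, function(e) {
    tibble::tibble(start_s = e$start_s, end_s = e$end_s, state = e$state,
                   quadrants = e$quadrants %||% NA_character_,
                   intensity_uW_mm2 = e$intensity_uW_mm2 %||% 0)
  })
  validate_schedule(dplyr::bind_rows(rows))
}

read_track_csv <- function(path) {
  tr <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "fly_id", "x_mm", "y_mm")
  if (!all(need %in% names(tr))) {
    stop(sprintf("track CSV '%s' needs columns %s", path,
                 paste(need, collapse = ", ")), call. = FALSE)
  }
  tibble::as_tibble(tr)
}

manifest_add <- function(manifest, path) {
  manifest$files[[length(manifest$files) + 1]] <-
    list(path = path, md5 = unname(tools::md5sum(path)))
  manifest
}

#' Run a configured workflow
#'
#' Single entry point over the package's analysis paths. The config (a YAML
#' file or an equivalent named list) names the workflow and its inputs;
#' validation failures are reported before any computation, outputs are
#' deterministic given config + inputs + seed, and every run writes a
#' `manifest.json` listing each file written with its MD5 hash, the resolved
#' parameters, and machine-readable warnings.
#'
#' Workflows:
#' \describe{
#'   \item{simulate}{`what`: one of `volumes`, `masks`, `quadrant`, `flybowl`,
#'     `flight`; writes NRRD stacks / track CSVs / trace CSVs with ground-truth
#'     JSON sidecars.}
#'   \item{anatomy}{`masks`: NRRD mask paths; builds the pairwise overlap
#'     matrix, interaction classification (at `threshold`, default 15) and
#'     clustering; writes `overlap_matrix.csv`, `interactions.json`,
#'     `cluster_order.csv`.}
#'   \item{quadrant}{`track` CSV + `schedule` YAML; writes `pi_series.csv`,
#'     `single_value_pi.json`, `delta_metrics.csv`.}
#'   \item{flybowl}{`track` CSV + `schedule` YAML; writes `locomotion.csv`.}
#'   \item{flight}{`traces` CSV (both effector and control flies),
#'     `parameter`, `visual_condition`; writes `response.csv` and
#'     `significance.csv`.}
#' }
#'
#' @param config Path to a YAML config or a named list.
#' @param seed Seed override (otherwise `config$seed`, default 1).
#' @param out_dir Output directory override (otherwise `config$out_dir`).
#' @return Invisibly, the manifest list (also written as JSON).
#' @export
run_workflow <- function(config, seed = NULL, out_dir = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      stop(sprintf("config file not found: %s", config), call. = FALSE)
    }
    config <- yaml::read_yaml(config)
  }
  wf <- config$workflow
  if (is.null(wf) || !wf %in% c("simulate", "anatomy", "quadrant", "flybowl",
                                "flight")) {
    stop("config$workflow must be one of simulate, anatomy, quadrant, flybowl, flight",
         call. = FALSE)
  }
  seed <- as.integer(seed %||% config$seed %||% 1L)
  out_dir <- out_dir %||% config$out_dir
  if (is.null(out_dir)) stop("an output directory is required", call. = FALSE)
  # validate referenced inputs before any computation or output
  inputs <- as.character(unlist(config[intersect(
    c("masks", "track", "schedule", "traces"), names(config))]))
  missing <- inputs[!file.exists(inputs)]
  if (length(missing)) {
    stop(sprintf("missing input file(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(workflow = wf, seed = seed,
                   package_version = as.character(utils::packageVersion("lhscreen")),
                   config = config, files = list(), warnings = list())
  emit <- function(path) manifest_add(manifest, path)

  if (wf == "simulate") {
    what <- config$what %||% "volumes"
    if (what == "volumes" || what == "masks") {
      p <- do.call(arbor_params, c(config$arbor %||% list(), list(seed = seed)))
      sim <- generate_replicate_stacks(p, config$n_replicates %||% 3L)
      for (i in seq_along(sim$stacks)) {
        f <- file.path(out_dir, sprintf("stack_%02d.nrrd", i))
        write_nrrd(sim$stacks[[i]], f)
        manifest <- emit(f)
      }
      gt <- file.path(out_dir, "ground_truth.json")
      jsonlite::write_json(
        list(n_truth_voxels = length(sim$ground_truth$voxel_idx),
             shifts_um = sim$ground_truth$shifts_um,
             seed = seed), gt, auto_unbox = TRUE, digits = NA)
      manifest <- emit(gt)
      if (what == "masks") {
        m <- make_mask(sim$stacks, cell_type = config$cell_type %||% "sim")
        f <- file.path(out_dir, "mask.nrrd")
        write_nrrd(m, f)
        manifest <- emit(f)
      }
    } else if (what %in% c("quadrant", "flybowl")) {
      d <- do.call(arena_design,
                   c(list(arena_kind = if (what == "quadrant") "four_quadrant"
                          else "flybowl"),
                     config$arena %||% list(), list(seed = seed)))
      sim <- if (what == "quadrant") generate_quadrant_trial(d)
      else generate_flybowl_trial(d)
      f <- file.path(out_dir, "track.csv")
      utils::write.csv(sim$track, f, row.names = FALSE)
      manifest <- emit(f)
      fs <- file.path(out_dir, "schedule.yaml")
      schedule_to_yaml(sim$schedule, fs)
      manifest <- emit(fs)
    } else if (what == "flight") {
      d <- do.call(flight_design, c(config$flight %||% list(),
                                    list(seed = seed)))
      sim <- generate_flight_session(d)
      f <- file.path(out_dir, "traces.csv")
      utils::write.csv(sim$traces, f, row.names = FALSE)
      manifest <- emit(f)
    } else {
      stop(sprintf("unknown simulate target '%s'", what), call. = FALSE)
    }
  } else if (wf == "anatomy") {
    if (is.null(config$masks) || length(config$masks) < 2) {
      stop("anatomy workflow needs at least two mask paths", call. = FALSE)
    }
    masks <- lapply(config$masks, read_nrrd)
    names(masks) <- vapply(masks, function(m) m$cell_type, character(1))
    m <- pairwise_matrix(masks, combine = config$combine %||% "mean")
    f <- file.path(out_dir, "overlap_matrix.csv")
    utils::write.csv(as.data.frame(m$values), f)
    manifest <- emit(f)
    cls <- classify_interactions(m, threshold = config$threshold %||% 15)
    fj <- file.path(out_dir, "interactions.json")
    jsonlite::write_json(
      list(threshold = cls$threshold,
           frac_rows_with_any = cls$frac_rows_with_any,
           frac_rows_with_none = cls$frac_rows_with_none),
      fj, auto_unbox = TRUE, digits = NA)
    manifest <- emit(fj)
    if (nrow(m$values) >= 2 && ncol(m$values) >= 2) {
      cl <- cluster_matrix(m)
      fc <- file.path(out_dir, "cluster_order.csv")
      utils::write.csv(
        data.frame(row_order = m$row_labels[cl$row_order],
                   col_order = m$col_labels[cl$col_order]), fc,
        row.names = FALSE)
      manifest <- emit(fc)
    }
  } else if (wf %in% c("quadrant", "flybowl")) {
    track <- read_track_csv(config$track)
    schedule <- schedule_from_yaml(config$schedule)
    arena <- quadrant_arena(config$diameter_mm %||%
                              if (wf == "quadrant") 100 else 50)
    if (wf == "quadrant") {
      pis <- pi_timeseries(track, schedule, arena)
      f <- file.path(out_dir, "pi_series.csv")
      utils::write.csv(as.data.frame(pis), f, row.names = FALSE)
      manifest <- emit(f)
      sv <- single_value_pi(pis, schedule)
      fj <- file.path(out_dir, "single_value_pi.json")
      jsonlite::write_json(list(single_value_pi = sv), fj, auto_unbox = TRUE,
                           digits = NA)
      manifest <- emit(fj)
      dm <- dplyr::bind_rows(lapply(
        c("forward_px_s", "turning_deg_s", "distance_from_center_px"),
        function(mt) delta_metric(track, schedule, mt, arena)))
      fd <- file.path(out_dir, "delta_metrics.csv")
      utils::write.csv(as.data.frame(dm), fd, row.names = FALSE)
      manifest <- emit(fd)
      excl <- dm$fly_id[!dm$included]
      if (length(excl)) {
        manifest$warnings[[length(manifest$warnings) + 1]] <-
          list(type = "excluded_flies", flies = unique(as.character(excl)))
      }
    } else {
      loco <- flybowl_locomotion(track, schedule,
                                 which_epoch = config$which_epoch %||% 3,
                                 arena = arena)
      f <- file.path(out_dir, "locomotion.csv")
      utils::write.csv(as.data.frame(loco), f, row.names = FALSE)
      manifest <- emit(f)
    }
  } else if (wf == "flight") {
    traces <- tibble::as_tibble(utils::read.csv(config$traces,
                                                stringsAsFactors = FALSE))
    traces <- drop_stopped_trials(traces,
                                  freq_floor = config$freq_floor %||% 120)
    parameter <- config$parameter %||% "yaw"
    vc <- config$visual_condition %||% "closed_loop_stripe"
    grp_a <- fly_response(traces[traces$has_effector, ], parameter, vc)
    f <- file.path(out_dir, "response.csv")
    utils::write.csv(as.data.frame(tidy(grp_a)), f, row.names = FALSE)
    manifest <- emit(f)
    if (any(!traces$has_effector)) {
      grp_b <- fly_response(traces[!traces$has_effector, ], parameter, vc)
      sig <- per_timepoint_test(grp_a, grp_b,
                                decimate_to = config$decimate_to %||% NULL)
      fs <- file.path(out_dir, "significance.csv")
      utils::write.csv(as.data.frame(sig), fs, row.names = FALSE)
      manifest <- emit(fs)
    }
  }

  mf <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(manifest)
}
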
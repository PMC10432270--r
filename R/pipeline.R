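#' Assemble a pipeline configuration
#'
#' A run configuration bundles everything a reproducible run needs: the
#' assay mode, output directory, seed, and per-stage parameters. Every
#' parameter, including defaults, is written to the run log so any output
#' can be traced back to the exact settings that produced it.
#'
#' @param mode `"tmaze"` (simulate choice sets and run the group tests),
#'   `"gravity"` (simulate/render/track climbing videos and run the exposure
#'   tests) or `"track"` (track an existing frame directory).
#' @param out_dir output directory (created if missing).
#' @param seed integer master seed; all stage seeds derive from it.
#' @param ... mode-specific settings, see Details.
#' @details
#' `tmaze` expects `groups`: a named list of lists with fields `n_sets`,
#' `flies_per_set`, `p_magnetic`, `icc`.
#' `gravity` expects `n_tubes_per_group`, `exposure_effect`, a
#' `kinematics` list passed to [climb_kinematics()], optional `render`
#' (default TRUE) with a `video` list passed to [video_spec()], and optional
#' `criterion` ([climber_criterion()] fields) and `subsample_every`.
#' `track` expects `frames` (a PNG frame directory), `fps`, `video`
#' (geometry for [video_spec()]) and optional `trial_start_frames`.
#' @return list of class `run_config`.
#' @export
run_config <- function(mode = c("tmaze", "gravity", "track"),
                       out_dir, seed = 1, ...) {
  mode <- match.arg(mode)
  if (missing(out_dir) || !is.character(out_dir) || !nzchar(out_dir))
    stop("config error: `out_dir` is required", call. = FALSE)
  cfg <- c(list(mode = mode, out_dir = out_dir, seed = as.integer(seed)),
           list(...))
  structure(cfg, class = "run_config")
}

cfg_get <- function(config, field, default = NULL, required = FALSE) {
  if (!is.null(config[[field]])) return(config[[field]])
  if (required)
    stop(sprintf("config error: field `%s` is missing", field),
         call. = FALSE)
  default
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> (render -> track -> filter) -> analyse according to
#' the configuration mode, writing versioned outputs to `out_dir`: the data
#' tables as CSV, a machine-readable `summary.json` (embedding the config
#' hash and seed, so reruns with the same config and seed are byte-identical)
#' and a `log.jsonl` recording every parameter including defaults. Any stage
#' failure aborts with an error naming the stage.
#'
#' @param config a [run_config()].
#' @return the summary list, invisibly; side effect: files in `out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  # hash the analysis-relevant configuration; the output location is not
  # part of what defines a run
  cfg_hash <- hash_object(unclass(config)[setdiff(names(config),
                                                  "out_dir")])
  log_path <- file.path(out_dir, "log.jsonl")
  logs <- list()
  log_add <- function(stage, params) {
    logs[[length(logs) + 1L]] <<-
      jsonlite::toJSON(list(stage = stage, params = params),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage `%s` failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  results <- switch(config$mode,
    tmaze = pipeline_tmaze(config, stage, log_add),
    gravity = pipeline_gravity(config, stage, log_add),
    track = pipeline_track(config, stage, log_add))

  summary <- list(package = "flymag",
                  version = as.character(utils::packageVersion("flymag")),
                  mode = config$mode, seed = config$seed,
                  config_hash = unname(cfg_hash), results = results)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       pretty = TRUE)
  writeLines(unlist(logs), log_path)
  invisible(summary)
}

test_to_list <- function(tr) {
  list(method = tr$method, terms = tr$terms, estimate = tr$estimate,
       se = tr$se, singular = tr$singular, note = tr$note)
}

pipeline_tmaze <- function(config, stage, log_add) {
  groups <- cfg_get(config, "groups", required = TRUE)
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    stop("config error: `groups` must be a named list", call. = FALSE)
  sets <- stage("simulate", {
    pieces <- lapply(seq_along(groups), function(k) {
      g <- groups[[k]]
      params <- list(n_sets = cfg_get(g, "n_sets", required = TRUE),
                     flies_per_set = cfg_get(g, "flies_per_set", 100),
                     p_magnetic = cfg_get(g, "p_magnetic", 0.5),
                     icc = cfg_get(g, "icc", 0),
                     group = names(groups)[k],
                     seed = config$seed + k)
      log_add("simulate_tmaze", params)
      do.call(simulate_tmaze_experiment, params)
    })
    do.call(rbind, lapply(pieces, as.data.frame))
  })
  write_table_csv(sets, file.path(config$out_dir, "choice_sets.csv"))
  disp <- cfg_get(config, "dispersion", "quasi")
  log_add("analyze_tmaze", list(dispersion = disp))
  res <- stage("analyze", list(
    group_test = test_to_list(glm_group_test(sets, disp)),
    pseudoreplicated = test_to_list(pseudoreplicated_test(sets))))
  res
}

pipeline_gravity <- function(config, stage, log_add) {
  n_tubes <- cfg_get(config, "n_tubes_per_group", 3)
  effect <- cfg_get(config, "exposure_effect", 1)
  kin_args <- cfg_get(config, "kinematics", list())
  render <- isTRUE(cfg_get(config, "render", TRUE))
  crit_args <- cfg_get(config, "criterion", list())
  crit <- do.call(climber_criterion, crit_args)
  sub_every <- cfg_get(config, "subsample_every", 5)

  groups <- list(sham = 1, exposed = effect)
  tabs <- vector("list", length(groups))
  for (k in seq_along(groups)) {
    gname <- names(groups)[k]
    kin <- do.call(climb_kinematics,
                   c(kin_args, list(exposure_effect = groups[[k]],
                                    seed = config$seed + 10L * k)))
    log_add("simulate_climb", c(unclass(kin), group = gname))
    truth <- stage("simulate",
                   simulate_climb_trajectories(kin, n_tubes = n_tubes))
    if (render) {
      vargs <- cfg_get(config, "video", list())
      vargs$n_tubes <- n_tubes
      spec <- do.call(video_spec, vargs)
      log_add("render_video", list(group = gname, width = spec$width,
                                   height = spec$height,
                                   noise_sd = spec$noise_sd))
      vid <- stage("render",
                   render_video(truth, spec, seed = config$seed + 100L + k))
      params <- do.call(segmentation_params,
                        cfg_get(config, "segmentation", list()))
      nf <- attr(truth, "frames_per_trial")
      tab <- stage("track", track_stack(
        vid$stack, params, spec$tube_rois, spec$cm_per_px,
        trial_start_frames = (seq_len(kin$n_trials) - 1L) * nf,
        calib_regions = spec$calib_regions,
        tube_length_cm = spec$tube_length_cm))
      tab <- stage("filter",
                   apply_validity_filters(tab, "gravity",
                                          max_flies = kin$n_flies))
    } else {
      tab <- truth
    }
    tab$tube <- tab$tube + (k - 1L) * n_tubes   # unique tube ids
    tabs[[k]] <- list(group = gname, tab = tab)
  }

  design <- do.call(rbind, lapply(seq_along(tabs), function(k)
    data.frame(tube = unique(tabs[[k]]$tab$tube[
                 !is.na(tabs[[k]]$tab$tube)]),
               Exposure = tabs[[k]]$group)))
  design$id <- paste0("id", design$tube)
  all_tab <- do.call(rbind, lapply(tabs, function(x)
    as.data.frame(x$tab)[, intersect(names(x$tab),
      c("frame", "time_s", "trial", "time_in_trial_s", "tube", "x_px",
        "y_px", "area", "major", "minor", "height_cm", "valid", "excluded",
        "excluded_reason"))]))
  write_table_csv(all_tab, file.path(config$out_dir, "tracks.csv"))
  write_table_csv(design, file.path(config$out_dir, "design.csv"))

  gsize <- if (length(kin_args$n_flies)) kin_args$n_flies else 10
  log_add("analyze_gravity", list(criterion = unclass(crit),
                                  subsample_every = sub_every,
                                  group_size = gsize))
  stage("analyze", {
    cd <- climber_data(all_tab, design, crit, group_size = gsize)
    hm <- join_design(frame_mean_heights(all_tab), design)
    hm <- subsample_frames(hm, every = sub_every)
    list(climber_rm_anova = test_to_list(test_exposure_ratio(cd,
                                                             "rm_anova")),
         height_lme = test_to_list(test_exposure_height(hm)),
         climber_proportions = aggregate(prop ~ Exposure, cd, mean))
  })
}

pipeline_track <- function(config, stage, log_add) {
  frames_dir <- cfg_get(config, "frames", required = TRUE)
  if (!dir.exists(frames_dir))
    stop("config error: field `frames` points to a missing directory: ",
         frames_dir, call. = FALSE)
  fps <- cfg_get(config, "fps", 10)
  spec <- do.call(video_spec, cfg_get(config, "video", required = TRUE))
  params <- do.call(segmentation_params,
                    cfg_get(config, "segmentation", list()))
  log_add("track", list(frames = frames_dir, fps = fps))
  stack <- stage("read", read_frame_dir(frames_dir, fps = fps))
  tab <- stage("track", track_stack(
    stack, params, spec$tube_rois, spec$cm_per_px,
    trial_start_frames = cfg_get(config, "trial_start_frames", 0L),
    calib_regions = spec$calib_regions,
    tube_length_cm = spec$tube_length_cm))
  tab <- stage("filter",
               apply_validity_filters(tab,
                                      cfg_get(config, "filter_mode",
                                              "gravity")))
  write_table_csv(tab, file.path(config$out_dir, "tracks.csv"))
  list(n_frames = stack$n_frames, n_detections = nrow(tab),
       n_excluded = sum(tab$excluded))
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path `.yaml`/`.yml` or `.json` file describing a [run_config()].
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, cfg)
}
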
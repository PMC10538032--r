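#' Project configuration and the pipeline entry point
#'
#' A project is a JSON file selecting the application, its input (a
#' synthetic scenario or numbered PNG frame sequences), the scene
#' parameters and the output directory. All threshold orderings are
#' validated at load time; nothing is written when validation fails.
#'
#' @name project_config
NULL

#' Load and validate a project configuration
#'
#' Required fields: `app` (`rat1`, `rat2`, `monkey`, `panda`), `fps`,
#' `out_dir`. Either `simulate = true` (with optional `duration_s`,
#' `seed`, `noise_sd`) or `frames_dir` (a directory of numbered PNGs;
#' for panda, a named object of per-camera directories). Optional
#' threshold blocks are checked against their ordering invariants.
#'
#' @param path JSON file path, or a list with the same structure.
#' @return validated configuration list (class `project_config`).
#' @export
load_project_config <- function(path) {
  if (is.character(path) && !file.exists(path))
    stop("unreadable project file: ", path)
  cfg <- if (is.character(path))
    jsonlite::fromJSON(path, simplifyVector = TRUE) else path
  for (field in c("app", "fps", "out_dir"))
    if (is.null(cfg[[field]])) stop("missing config field: ", field)
  if (!cfg$app %in% c("rat1", "rat2", "monkey", "panda"))
    stop("unknown app: ", cfg$app)
  if (!isTRUE(cfg$simulate)) {
    if (is.null(cfg$frames_dir)) stop("missing config field: frames_dir")
    dirs <- if (cfg$app == "panda") unlist(cfg$frames_dir) else
      cfg$frames_dir
    for (d in dirs) if (!dir.exists(d)) stop("unreadable frames_dir: ", d)
  }
  if (is.null(cfg$seed)) cfg$seed <- 1L
  if (is.null(cfg$duration_s)) cfg$duration_s <- 60
  if (is.null(cfg$noise_sd)) cfg$noise_sd <- 3
  if (!is.null(cfg$motion_thresholds))
    do.call(motion_thresholds, as.list(cfg$motion_thresholds))
  if (!is.null(cfg$velocity_thresholds))
    do.call(velocity_thresholds, as.list(cfg$velocity_thresholds))
  class(cfg) <- c("project_config", class(cfg))
  cfg
}

#' Run a configured project end to end
#'
#' Executes the selected application and writes its report CSVs into
#' the configured output directory.
#'
#' @param cfg path to a JSON project file or a validated configuration.
#' @return list with the written file paths and the application summary.
#' @export
run_pipeline <- function(cfg) {
  if (!inherits(cfg, "project_config")) cfg <- load_project_config(cfg)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  switch(cfg$app,
    rat1 = run_project_rat1(cfg),
    rat2 = run_project_rat2(cfg),
    monkey = run_project_monkey(cfg),
    panda = run_project_panda(cfg))
}

project_frames <- function(cfg, app) {
  if (isTRUE(cfg$simulate)) {
    s <- scenario(app, fps = cfg$fps, duration_s = cfg$duration_s,
                  seed = cfg$seed, noise_sd = cfg$noise_sd)
    if (app %in% c("rat1", "rat2")) render_rat_scene(s)$frames
    else render_monkey_scene(s)$frames
  } else {
    read_frame_sequence(cfg$frames_dir)
  }
}

run_project_rat1 <- function(cfg) {
  frames <- project_frames(cfg, "rat1")
  res <- run_rat1_pipeline(frames, cfg$fps)
  p <- file.path(cfg$out_dir, "head_positions.csv")
  write_head_report(res$head_positions, p)
  list(files = p,
       summary = list(frames = length(frames),
                      analyzed = nrow(res$head_positions),
                      skipped = length(res$skipped)))
}

run_project_rat2 <- function(cfg) {
  frames <- project_frames(cfg, "rat2")
  res <- run_rat2_pipeline(frames, cfg$fps,
                           debounce = cfg$debounce %||% 3L)
  p <- file.path(cfg$out_dir, "visits.csv")
  write_visit_report(res$visits, res$entries, p)
  list(files = c(p, paste0(p, ".entries.csv")),
       summary = list(entries = as.list(res$entries),
                      visits = nrow(res$visits)))
}

run_project_monkey <- function(cfg) {
  frames <- project_frames(cfg, "monkey")
  sc <- monkey_scene_config()
  res <- run_monkey_pipeline(frames, sc$regions, sc$info_polygon,
                             fps = cfg$fps)
  p <- file.path(cfg$out_dir, "monkey_track.csv")
  write_monkey_report(res, p)
  list(files = p,
       summary = list(frames = length(frames),
                      tracked = sum(!is.na(res$x)),
                      angles = sum(!is.na(res$filtered_angle))))
}

run_project_panda <- function(cfg) {
  pc <- panda_scene_configs()
  if (isTRUE(cfg$simulate)) {
    s <- scenario("panda", fps = cfg$fps, duration_s = cfg$duration_s,
                  seed = cfg$seed, noise_sd = cfg$noise_sd)
    frames_fn <- function(key) render_panda_camera(s, as.integer(key))
  } else {
    frames_fn <- function(key)
      read_frame_sequence(cfg$frames_dir[[key]])
  }
  vthr <- if (!is.null(cfg$velocity_thresholds))
    do.call(velocity_thresholds, as.list(cfg$velocity_thresholds)) else
      pc$vthr
  res <- run_panda_pipeline(frames_fn, pc$cfgs, pc$thresholds, vthr,
                            fps = cfg$fps)
  p1 <- file.path(cfg$out_dir, "trajectory.csv")
  p2 <- file.path(cfg$out_dir, "stress_episodes.csv")
  write_trajectory_report(res$entries, p1)
  write_episode_report(res$episodes, p2)
  list(files = c(p1, p2),
       summary = list(fused_length = nrow(res$entries),
                      episodes = nrow(res$episodes)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
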
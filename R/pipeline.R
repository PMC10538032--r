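#' End-to-end application pipelines
#'
#' One function per application ties the module operations into the
#' pipeline the toolkit exposes: rat stage-1 head pose, rat stage-2
#' compartment visits, monkey localization + orientation, and the
#' four-camera panda fusion + stress analysis.
#'
#' @name pipelines
NULL

#' Rat stage-1 pipeline: per-frame head pose with offline resolution
#'
#' @param frames list of grayscale frames.
#' @param fps frames per second.
#' @param ... forwarded to [track_rat_head()].
#' @return list with `head_positions` (data.frame `frame`, `x`, `y`,
#'   `status`), `decisions`, `body_centers`, `skipped`.
#' @export
run_rat1_pipeline <- function(frames, fps, ...) {
  res <- track_rat_head(frames, ...)
  status <- vapply(res$decisions, `[[`, character(1), "status")
  hp <- res$track
  names(hp)[names(hp) == "frame_index"] <- "frame"
  hp$status <- status
  list(head_positions = hp, decisions = res$decisions,
       body_centers = res$body_centers, skipped = res$skipped, fps = fps)
}

#' Rat stage-2 pipeline: tracking plus visit analysis
#'
#' @param frames list of grayscale frames.
#' @param fps frames per second.
#' @param debounce minimum frames for a sustained compartment change.
#' @param ... forwarded to [track_rat_position()].
#' @return list with `track`, `visits`, `entries`, `params`.
#' @export
run_rat2_pipeline <- function(frames, fps, debounce = 3L, ...) {
  tr <- track_rat_position(frames, ...)
  if (is.null(tr$params)) stop("cage parameters never validated")
  va <- analyze_visits(tr$track, tr$params, fps, debounce)
  list(track = tr$track, visits = va$visits, entries = va$entries,
       params = tr$params, fps = fps)
}

#' Monkey pipeline: localization, orientation, angle filtering
#'
#' Localizations gated at confidence > 75 percent enter the orientation
#' stage; the angle series is then smoothed/completed by the 1-D filter.
#'
#' @param frames list of grayscale frames.
#' @param regions a [region_reliability()].
#' @param info_polygon useful-information polygon or `NULL`.
#' @param fps frames per second.
#' @param conf_gate confidence gate (percent), strict.
#' @param filter_t odd window of the angle filter, frames.
#' @param roi_w,roi_h primary ROI size for [compute_orientation()].
#' @param ... forwarded to [track_monkey()].
#' @return data.frame per frame: `frame`, `x`, `y`, `confidence`,
#'   `region`, `light`, `raw_angle`, `filtered_angle`, `filled`.
#' @export
run_monkey_pipeline <- function(frames, regions, info_polygon = NULL,
                                fps = 10, conf_gate = 75, filter_t = 11L,
                                roi_w = 48, roi_h = 36, ...) {
  tr <- track_monkey(frames, regions, info_polygon, ...)
  n <- nrow(tr)
  raw_angle <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (is.na(tr$x[i]) || is.na(tr$confidence[i])) next
    if (tr$confidence[i] <= conf_gate) next   # strict gate: > 75 only
    if (tr$light[i] == "off") next  # the [30,60] value-channel band
                                    # presumes a lit scene
    o <- compute_orientation(frames[[i]], c(tr$x[i], tr$y[i]),
                             roi_w = roi_w, roi_h = roi_h)
    if (!is.null(o)) raw_angle[i] <- o$angle_deg
  }
  series <- data.frame(frame_index = tr$frame_index, angle_deg = raw_angle,
                       confidence = ifelse(is.na(tr$confidence), 0,
                                           tr$confidence))
  sm <- filter_angles(series, t = filter_t, conf_thr = conf_gate)
  data.frame(frame = tr$frame_index, x = tr$x, y = tr$y,
             confidence = tr$confidence, region = tr$region,
             light = tr$light, raw_angle = raw_angle,
             filtered_angle = sm$angle_deg, filled = sm$filled)
}

#' Panda pipeline: per-camera tracking, fusion, filtering, stress
#'
#' Cameras are processed one at a time (`frames_fn` supplies each
#' camera's frame list, so streams can be rendered or read lazily).
#' The fused list length equals the minimum frame count over the
#' cameras. Filtering applies the run-compaction substitution, gap
#' interpolation, attribute smoothing and velocity computation before
#' the five-class stress labeling.
#'
#' @param frames_fn function(camera_key) returning that camera's frame
#'   list; or a named list of frame lists.
#' @param cfgs named list of [camera_config()]s.
#' @param thresholds named list of per-camera [motion_thresholds()].
#' @param vthr a [velocity_thresholds()].
#' @param fps frames per second.
#' @param box_w,box_h counting-box size.
#' @param motion_opts motion-image options (the panda views default to a
#'   fine-grained setting that keeps slow-walk features).
#' @param large_min,short_max,passes compaction-filter parameters.
#' @param smooth_window,velocity_window window sizes, frames.
#' @param stress_opts options for [classify_stress()].
#' @param track_opts options for [track_camera()].
#' @return list with `cam_tracks`, `fused`, `entries` (analyzed, with
#'   velocities and stress) and `episodes`.
#' @export
run_panda_pipeline <- function(frames_fn, cfgs, thresholds, vthr, fps,
                               box_w = 48, box_h = 48,
                               motion_opts = list(erosion_size = 1L,
                                                  dilation_size = 3L,
                                                  threshold = 20),
                               large_min = 50L, short_max = 10L,
                               passes = 2L, smooth_window = 5L,
                               velocity_window = 11L,
                               stress_opts = list(), track_opts = list()) {
  if (is.list(frames_fn)) {
    streams <- frames_fn
    frames_fn <- function(key) streams[[key]]
  }
  cam_tracks <- list()
  for (key in names(cfgs)) {
    frames <- frames_fn(key)
    cam_tracks[[key]] <- track_camera(frames, cfgs[[key]],
                                      thresholds[[key]],
                                      box_w = box_w, box_h = box_h,
                                      motion_opts = motion_opts,
                                      opts = track_opts)
    rm(frames)
  }
  fused <- fuse_views(cam_tracks, cfgs)
  entries <- filter_pass_compaction(fused, cam_tracks, cfgs,
                                    large_min = large_min,
                                    short_max = short_max, passes = passes)
  entries <- fill_gaps(entries)
  entries <- smooth_attributes(entries, smooth_window)
  entries <- compute_velocities(entries, cfgs, velocity_window)
  res <- classify_stress(entries, vthr, cfgs, fps, stress_opts)
  list(cam_tracks = cam_tracks, fused = fused, entries = res$entries,
       episodes = res$episodes, fps = fps)
}
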
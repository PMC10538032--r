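#' Panda trajectory synthesis and stress analysis
#'
#' Per synchronized frame index, the per-camera observations are fused
#' into one track entry (the view with the most observable bear, chosen
#' by a zone hierarchy with stickiness to the previously selected
#' camera). The fused list is then compacted (short foreign-camera
#' insertions between large same-camera runs are replaced), frame gaps
#' are linearly interpolated, attributes are majority-smoothed,
#' weighted velocities are computed and filtered, and the five stress
#' classes are assigned from the velocity bands and habitat context.
#'
#' @name panda_analysis
NULL

# an empty fused entry
null_entry <- function(frame_index) {
  data.frame(frame_index = frame_index, camera_id = NA_integer_,
             x = NA_real_, y = NA_real_,
             attribute = "freezing_or_missing", zone = NA_character_)
}

default_hierarchy <- function() {
  # rank of a zone type (smaller = preferred), and the ground-camera
  # preference on ties between a ground view and a general view
  list(zone_rank = c(full = 1, door = 2, housing = 3, basin = 3),
       prefer_ground = TRUE)
}

#' Select the best view for one synchronized frame
#'
#' Candidates outside any observable zone and candidates with the
#' technician flag are dropped. The remainder is ranked by the zone
#' hierarchy (full-visibility zones above door zones above partial
#' zones; ground cameras above general views on equal zones); on equal
#' rank the previously selected camera is favored.
#'
#' @param candidates data.frame of per-camera observations for one frame
#'   (columns `camera_id`, `x`, `y`, `attribute`, `zone`, `technician`).
#' @param prev_selected previously fused entry (1-row data.frame) or
#'   `NULL`.
#' @param cfgs named list of [camera_config()]s (names =
#'   as.character(camera_id)).
#' @param hierarchy list as in `default_hierarchy`.
#' @param frame_index recorded in the output entry.
#' @return 1-row data.frame track entry (null entry when no candidate
#'   survives).
#' @export
select_view <- function(candidates, prev_selected = NULL, cfgs,
                        hierarchy = default_hierarchy(), frame_index = 0L) {
  if (is.null(candidates) || nrow(candidates) == 0L)
    return(null_entry(frame_index))
  ok <- !candidates$technician & !is.na(candidates$zone) &
    !is.na(candidates$x) &
    candidates$attribute %in% c("movement", "freezing")
  cand <- candidates[ok, , drop = FALSE]
  if (nrow(cand) == 0L) return(null_entry(frame_index))
  ztype <- vapply(seq_len(nrow(cand)), function(k)
    zone_type(cand$zone[k], cfgs[[as.character(cand$camera_id[k])]]),
    character(1))
  zrank <- hierarchy$zone_rank[ztype]
  zrank[is.na(zrank)] <- max(hierarchy$zone_rank) + 1
  camrank <- vapply(as.character(cand$camera_id), function(id)
    if (isTRUE(cfgs[[id]]$general_view) && hierarchy$prefer_ground) 1 else 0,
    numeric(1))
  # movement beats freezing at equal zone rank ("most observable bear")
  attrrank <- ifelse(cand$attribute == "movement", 0, 1)
  score <- zrank * 100 + attrrank * 10 + camrank
  best <- min(score)
  tied <- which(score == best)
  pick <- tied[1]
  if (length(tied) > 1L && !is.null(prev_selected) &&
      !is.na(prev_selected$camera_id)) {
    same <- tied[cand$camera_id[tied] == prev_selected$camera_id]
    if (length(same)) pick <- same[1]
  }
  data.frame(frame_index = frame_index,
             camera_id = cand$camera_id[pick],
             x = cand$x[pick], y = cand$y[pick],
             attribute = cand$attribute[pick], zone = cand$zone[pick])
}

#' Fuse per-camera tracks into the final list
#'
#' The fused list length equals the minimum frame count over the project
#' videos. Every entry starts as a null entry (null camera, null
#' coordinates, `freezing_or_missing`) and is filled by [select_view()].
#'
#' @param cam_tracks named list of per-camera data.frames from
#'   [track_camera()].
#' @param cfgs named list of [camera_config()]s.
#' @param hierarchy zone hierarchy, see [select_view()].
#' @return data.frame of fused track entries.
#' @export
fuse_views <- function(cam_tracks, cfgs, hierarchy = default_hierarchy()) {
  n <- min(vapply(cam_tracks, nrow, integer(1)))
  prev <- NULL
  out <- vector("list", n)
  for (i in seq_len(n)) {
    cand <- do.call(rbind, lapply(cam_tracks, function(tr)
      tr[i, c("camera_id", "x", "y", "attribute", "zone", "technician")]))
    e <- select_view(cand, prev, cfgs, hierarchy, frame_index = i - 1L)
    if (!is.na(e$camera_id)) prev <- e
    out[[i]] <- e
  }
  do.call(rbind, out)
}

# camera runs (NA camera = its own run value 0)
camera_runs <- function(camera_id) {
  v <- ifelse(is.na(camera_id), 0L, camera_id)
  r <- rle(v)
  ends <- cumsum(r$lengths)
  data.frame(camera = r$values, start = ends - r$lengths + 1L, end = ends,
             len = r$lengths)
}

#' Compaction filtering of the fused list (pass 1)
#'
#' Detects pairs of large same-camera runs enclosing only short runs of
#' other cameras, and replaces each interleaved short foreign run by the
#' main camera's own positions for those frames (from its per-camera
#' track; when it has none, by affine-transferred coordinates when the
#' camera geometry allows it; otherwise the entries are left). The same
#' substitution mechanism is applied `passes` times, which also compacts
#' the freezing-moving switch and repeated-path contexts that present as
#' nested short insertions.
#'
#' @param entries fused track data.frame.
#' @param cam_tracks named list of per-camera tracks.
#' @param cfgs named list of [camera_config()]s.
#' @param large_min minimum length of the bordering same-camera runs.
#' @param short_max maximum length of a replaceable interleaved run.
#' @param passes number of substitution passes.
#' @return the compacted entries data.frame.
#' @export
filter_pass_compaction <- function(entries, cam_tracks, cfgs,
                                   large_min = 50L, short_max = 10L,
                                   passes = 2L) {
  for (p in seq_len(passes)) {
    runs <- camera_runs(entries$camera_id)
    big <- which(runs$camera != 0L & runs$len >= large_min)
    changed <- FALSE
    for (bi in seq_along(big)[-1]) {
      i1 <- big[bi - 1L]; i2 <- big[bi]
      if (runs$camera[i1] != runs$camera[i2]) next
      if (i2 - i1 <= 1L) next
      between <- (i1 + 1L):(i2 - 1L)
      if (any(runs$len[between] > short_max)) next
      main <- runs$camera[i1]
      frames <- runs$start[i1 + 1L]:runs$end[i2 - 1L]
      for (f in frames) {
        if (!is.na(entries$camera_id[f]) && entries$camera_id[f] == main)
          next
        sub <- substitute_entry(entries[f, ], main, cam_tracks, cfgs)
        if (!is.null(sub)) { entries[f, ] <- sub; changed <- TRUE }
      }
    }
    if (!changed) break
  }
  entries
}

# rebuild one entry as seen by camera `main`; NULL when impossible
substitute_entry <- function(e, main, cam_tracks, cfgs) {
  key <- as.character(main)
  tr <- cam_tracks[[key]]
  if (!is.null(tr)) {
    row <- tr[tr$frame_index == e$frame_index, ]
    if (nrow(row) == 1L && !is.na(row$x) &&
        row$attribute %in% c("movement", "freezing") && !row$technician)
      return(data.frame(frame_index = e$frame_index, camera_id = main,
                        x = row$x, y = row$y, attribute = row$attribute,
                        zone = row$zone))
  }
  # transfer coordinates through the world frame when both affines exist
  if (!is.na(e$camera_id) && !is.na(e$x)) {
    src <- cfgs[[as.character(e$camera_id)]]
    dst <- cfgs[[key]]
    if (!is.null(src$world_affine) && !is.null(dst$world_affine)) {
      wpt <- affine_invert(src$world_affine, c(e$x, e$y))
      cpt <- affine_apply(dst$world_affine, wpt)
      zn <- zone_of_point(cpt, dst)
      if (!is.na(zn))
        return(data.frame(frame_index = e$frame_index, camera_id = main,
                          x = cpt[1], y = cpt[2], attribute = e$attribute,
                          zone = zn))
    }
  }
  NULL
}

affine_apply <- function(A, p) {
  as.numeric(A %*% c(p[1], p[2], 1))
}

affine_invert <- function(A, p) {
  M <- A[, 1:2]
  as.numeric(solve(M, c(p[1], p[2]) - A[, 3]))
}

#' Fill frame gaps of the fused list by linear interpolation
#'
#' For each gap of unfilled positions whose two bounding filled entries
#' come from the same camera and are `j` frames apart with
#' `2 <= j <= 100`, the intermediate frames `k = 1..j-1` receive the
#' linearly interpolated coordinates
#' `x(F[i+k]) = x(F[i]) + k * (x(F[i+j]) - x(F[i])) / j` (same for `y`).
#' The filled attribute is `movement` when at least one bounding entry is
#' a movement entry, else `freezing`. Longer gaps and gaps bounded by
#' different cameras are untouched. Idempotent.
#'
#' @param entries fused track data.frame.
#' @param max_gap largest fillable gap in frames.
#' @return entries with gaps filled.
#' @export
fill_gaps <- function(entries, max_gap = 100L) {
  filled <- which(!is.na(entries$camera_id) & !is.na(entries$x))
  if (length(filled) < 2L) return(entries)
  for (t in seq_along(filled)[-1]) {
    i <- filled[t - 1L]; ij <- filled[t]
    j <- entries$frame_index[ij] - entries$frame_index[i]
    if (ij - i <= 1L) next
    if (j < 2L || j > max_gap) next
    if (entries$camera_id[i] != entries$camera_id[ij]) next
    attr_ <- if (entries$attribute[i] == "movement" ||
                 entries$attribute[ij] == "movement") "movement"
             else "freezing"
    for (idx in (i + 1L):(ij - 1L)) {
      k <- entries$frame_index[idx] - entries$frame_index[i]
      entries$camera_id[idx] <- entries$camera_id[i]
      entries$x[idx] <- entries$x[i] + k * (entries$x[ij] - entries$x[i]) / j
      entries$y[idx] <- entries$y[i] + k * (entries$y[ij] - entries$y[i]) / j
      entries$attribute[idx] <- attr_
      entries$zone[idx] <- entries$zone[i]
    }
  }
  entries
}

#' Majority-vote smoothing of the motion attributes
#'
#' Each entry's attribute is replaced by the attribute type with the most
#' votes in a window centered on it; ties retain the current attribute.
#' Null entries neither vote nor change.
#'
#' @param entries fused track data.frame.
#' @param window odd window size, frames.
#' @return entries with smoothed attributes.
#' @export
smooth_attributes <- function(entries, window = 5L) {
  stopifnot(window %% 2L == 1L)
  half <- (window - 1L) %/% 2L
  n <- nrow(entries)
  att <- entries$attribute
  votable <- att %in% c("movement", "freezing", "no_information")
  out <- att
  for (i in which(votable)) {
    win <- max(1L, i - half):min(n, i + half)
    w <- att[win][votable[win]]
    tb <- table(w)
    top <- names(tb)[tb == max(tb)]
    if (length(top) == 1L) out[i] <- top
    else if (att[i] %in% top) out[i] <- att[i]
    else out[i] <- top[1]
  }
  entries$attribute <- out
  entries
}

#' Weighted velocities along the fused list
#'
#' For every consecutive pair with the same available camera, the local
#' velocity is the Euclidean displacement, weighted by the camera's
#' velocity weight and resolution normalization; cross-camera pairs and
#' null entries yield a missing velocity. The raw velocities are then
#' filtered by averaging the valid velocities in a window centered on
#' each position.
#'
#' @param entries fused track data.frame.
#' @param cfgs named list of [camera_config()]s.
#' @param window odd averaging window, frames.
#' @param ref_width reference width for the resolution normalization
#'   (defaults to the maximum camera width).
#' @return entries with `v_raw` and `v` columns (common-scale pixels per
#'   frame).
#' @export
compute_velocities <- function(entries, cfgs, window = 11L,
                               ref_width = NULL) {
  stopifnot(window %% 2L == 1L)
  if (is.null(ref_width))
    ref_width <- max(vapply(cfgs, function(c) c$resolution[1], numeric(1)))
  n <- nrow(entries)
  v_raw <- rep(NA_real_, n)
  for (i in seq_len(n)[-1]) {
    if (is.na(entries$camera_id[i]) || is.na(entries$camera_id[i - 1L]))
      next
    if (entries$camera_id[i] != entries$camera_id[i - 1L]) next
    if (is.na(entries$x[i]) || is.na(entries$x[i - 1L])) next
    cfg <- cfgs[[as.character(entries$camera_id[i])]]
    wgt <- cfg$velocity_weight * ref_width / cfg$resolution[1]
    v_raw[i] <- wgt * sqrt((entries$x[i] - entries$x[i - 1L])^2 +
                             (entries$y[i] - entries$y[i - 1L])^2)
  }
  half <- (window - 1L) %/% 2L
  v <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    win <- max(1L, i - half):min(n, i + half)
    vals <- v_raw[win]
    vals <- vals[!is.na(vals)]
    if (length(vals)) v[i] <- mean(vals)
  }
  entries$v_raw <- v_raw
  entries$v <- v
  entries
}

default_stress_opts <- function() {
  list(height_dist = 20,     # "significant distance" of a path height, px
       context_lookback = 30L,  # frames inspected before a moving series
       basin_pad = 30,       # distance to the basin counting as "close"
       stationary_min_s = 5,
       merge_gap_s = 1.5,    # same-class runs this close are one episode
       min_episode_s = 1)    # label runs shorter than this are noise
}

#' Five-class stress labeling and episode extraction
#'
#' Labels: `running` for velocities above `thr_v1`; `walking1` for the
#' `thr_v2..thr_v1` band when the moving series follows a period in a
#' complete-visibility zone; `walking2` for the same band when the series
#' follows a still period at one of the garden housings; `walking3` for
#' the `thr_v3..thr_v2` band after a housing still period when the path
#' section shows at least one height (a point at significant distance
#' from the line approximating the section); `stationary` for camera-8
#' series of duration above 5 s with the motion mass center close to the
#' bathing basin. Consecutive equal labels are grouped into episodes.
#'
#' @param entries fused track with velocities (from
#'   [compute_velocities()]).
#' @param thr [velocity_thresholds()].
#' @param cfgs named list of [camera_config()]s.
#' @param fps frames per second.
#' @param opts options overriding `default_stress_opts` values.
#' @return list with `entries` (added `stress` column) and `episodes`
#'   (data.frame `episode_id`, `class`, `start_frame`, `end_frame`,
#'   `start_time_s`, `end_time_s`, `duration_s`, `camera`).
#' @export
classify_stress <- function(entries, thr, cfgs, fps, opts = list()) {
  stopifnot(inherits(thr, "velocity_thresholds"))
  o <- utils::modifyList(default_stress_opts(), opts)
  n <- nrow(entries)
  label <- rep("none", n)
  v <- entries$v
  ztypes <- vapply(seq_len(n), function(i) {
    if (is.na(entries$camera_id[i]) || is.na(entries$zone[i]))
      return(NA_character_)
    zone_type(entries$zone[i], cfgs[[as.character(entries$camera_id[i])]])
  }, character(1))

  label[!is.na(v) & v > thr$thr_v1] <- "running"

  # moving series: maximal runs of consecutive entries with v > thr_v3 on
  # one camera; context = what the list shows just before the series
  series <- moving_series(entries, v, thr$thr_v3)
  for (s in seq_len(nrow(series))) {
    idx <- series$start[s]:series$end[s]
    pre <- max(1L, series$start[s] - o$context_lookback):max(1L, series$start[s] - 1L)
    pre <- pre[pre < series$start[s]]
    pre_full <- length(pre) > 0L &&
      mean(ztypes[pre] %in% "full", na.rm = TRUE) > 0.5
    pre_still_housing <- length(pre) > 0L &&
      mean(entries$attribute[pre] %in% c("freezing", "freezing_or_missing") &
             ztypes[pre] %in% c("housing", "door"), na.rm = TRUE) > 0.5
    band12 <- idx[!is.na(v[idx]) & v[idx] > thr$thr_v2 & v[idx] <= thr$thr_v1]
    band23 <- idx[!is.na(v[idx]) & v[idx] > thr$thr_v3 & v[idx] <= thr$thr_v2]
    if (length(band12)) {
      if (pre_full) label[band12] <- "walking1"
      else if (pre_still_housing) label[band12] <- "walking2"
    }
    if (length(band23) && pre_still_housing) {
      pts <- cbind(entries$x[idx], entries$y[idx])
      pts <- pts[stats::complete.cases(pts), , drop = FALSE]
      if (nrow(pts) >= 3L && max_line_deviation(pts) >= o$height_dist)
        label[band23] <- "walking3"
    }
  }

  # stationary: camera-8 bathing series near the basin, longer than 5 s
  c8 <- names(cfgs)[vapply(cfgs, function(c) !is.null(c$basin_zone),
                           logical(1))]
  for (id in c8) {
    cfg <- cfgs[[id]]
    basin <- inflate_rect(cfg$basin_zone, o$basin_pad)
    near <- !is.na(entries$camera_id) &
      entries$camera_id == cfg$camera_id &
      !is.na(entries$x) &
      vapply(seq_len(n), function(i)
        !is.na(entries$x[i]) && point_in_rect(c(entries$x[i], entries$y[i]),
                                              basin), logical(1))
    r <- rle(as.vector(near))
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      if (r$lengths[k] / fps > o$stationary_min_s) {
        idx <- starts[k]:ends[k]
        label[idx][label[idx] != "running"] <- "stationary"
      }
    }
  }

  label <- cleanup_labels(label, round(o$merge_gap_s * fps),
                          round(o$min_episode_s * fps))
  entries$stress <- label
  list(entries = entries, episodes = stress_episodes(entries, fps))
}

# label-run cleanup: bridge short interruptions (transition noise of any
# label mix) splitting one episode, then drop isolated runs too short to
# be an episode; classes bridged in decreasing strength order
cleanup_labels <- function(label, merge_frames, min_frames) {
  for (cls in c("running", "stationary", "walking1", "walking2",
                "walking3")) {
    idx <- which(label == cls)
    if (length(idx) < 2L) next
    d <- diff(idx)
    for (k in which(d > 1L & d <= merge_frames + 1L))
      label[(idx[k] + 1L):(idx[k + 1L] - 1L)] <- cls
  }
  r <- rle(label)
  r$values[r$values != "none" & r$lengths < min_frames] <- "none"
  inverse.rle(r)
}

moving_series <- function(entries, v, thr_v3) {
  act <- !is.na(v) & v > thr_v3 & !is.na(entries$camera_id)
  key <- ifelse(act, entries$camera_id, -1L)
  r <- rle(key)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  keep <- r$values >= 0
  data.frame(start = starts[keep], end = ends[keep])
}

#' Group per-frame stress labels into episodes
#'
#' @param entries fused track with a `stress` column.
#' @param fps frames per second.
#' @return data.frame of episodes (label runs other than `"none"`).
#' @export
stress_episodes <- function(entries, fps) {
  r <- rle(entries$stress)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  keep <- r$values != "none"
  if (!any(keep))
    return(data.frame(episode_id = integer(0), class = character(0),
                      start_frame = integer(0), end_frame = integer(0),
                      start_time_s = numeric(0), end_time_s = numeric(0),
                      duration_s = numeric(0), camera = integer(0)))
  idx <- which(keep)
  ep <- data.frame(
    episode_id = seq_along(idx),
    class = r$values[idx],
    start_frame = entries$frame_index[starts[idx]],
    end_frame = entries$frame_index[ends[idx]])
  ep$start_time_s <- ep$start_frame / fps
  ep$end_time_s <- ep$end_frame / fps
  ep$duration_s <- (ep$end_frame - ep$start_frame + 1L) / fps
  ep$camera <- vapply(idx, function(k) {
    cams <- entries$camera_id[starts[k]:ends[k]]
    cams <- cams[!is.na(cams)]
    if (!length(cams)) return(NA_integer_)
    as.integer(names(sort(table(cams), decreasing = TRUE))[1])
  }, integer(1))
  ep
}
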
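#' Per-camera panda tracking state machine
#'
#' Tracking per camera is organized in sessions. A session starts or
#' restarts only when the movement strength (feature count of the masked
#' motion image) warrants it: above the high threshold (with a technician
#' check), or above the movement threshold with the cluster in a gate
#' area or in the previous valid position area. During a session each
#' frame is assigned a `movement`, `freezing` or `no_information`
#' attribute from the feature-count band and the previous frame, and
#' movement frames pass validation rules against flare bursts, teleports,
#' direction reversals, branch play and (on the general views) flying
#' birds before they may enter the trajectory fusion.
#'
#' @name panda_tracking
NULL

default_panda_opts <- function() {
  list(area_burst_ratio = 3,     # "greatly surpassed" area factor
       far_factor = 2,           # x rect diagonal per frame = "far away"
       static_end = 900L,        # static frames ending a session
       same_pos_tol = 8,         # "almost in the same position", px
       door_exit_memory = 50L,   # frames the door watch persists
       exit_frames = 15L,    # static frames at a gate ending the session
       min_move = 1.0,           # displacement counted as real motion, px
       search_pad = 40L,         # confinement margin around the position
       basin_pad = 30L,          # search margin beside the basin position
       history_len = 10L)
}

#' Session gate: may tracking start or continue on this frame?
#'
#' Rules: (a) `features_nmb > high`: session (re)initialization; when the
#' movement rectangle height matches the technician profile and lies in
#' the technician gate, the `zoo_technician` flag is set. (b)
#' `features_nmb > mid` with the cluster in a panda gate area. (c)
#' `features_nmb > mid` with the cluster in the previous valid position
#' area (only after a previous valid session).
#'
#' @param m masked `motion_image` of the frame.
#' @param cluster `movement_cluster` or `NULL`.
#' @param cfg [camera_config()].
#' @param thr [motion_thresholds()].
#' @param prev_valid last valid position `c(x, y)` from a previous
#'   session, or `NULL`.
#' @param opts options overriding `default_panda_opts` values.
#' @return list `(start, zoo_technician)`; `start` FALSE when no rule
#'   fires.
#' @export
session_gate <- function(m, cluster, cfg, thr, prev_valid = NULL,
                         opts = list()) {
  o <- utils::modifyList(default_panda_opts(), opts)
  if (is.null(cluster)) return(list(start = FALSE, zoo_technician = FALSE))
  n <- m$features_nmb
  ctr <- cluster$mass_center
  if (n > thr$high) {
    tech <- FALSE
    if (!is.null(cfg$technician_gate) &&
        cluster$box[["h"]] > cfg$technician_height_frac * cfg$resolution[2] &&
        point_in_rect(ctr, cfg$technician_gate))
      tech <- TRUE
    return(list(start = TRUE, zoo_technician = tech))
  }
  if (n > thr$mid && point_in_any_rect(ctr, cfg$panda_gates))
    return(list(start = TRUE, zoo_technician = FALSE))
  if (n > thr$mid && !is.null(prev_valid)) {
    prev_area <- rect(prev_valid[[1]] - o$search_pad,
                      prev_valid[[2]] - o$search_pad,
                      2 * o$search_pad, 2 * o$search_pad)
    if (point_in_rect(ctr, prev_area))
      return(list(start = TRUE, zoo_technician = FALSE))
  }
  list(start = FALSE, zoo_technician = FALSE)
}

#' Frame attribute from the feature-count band
#'
#' The three-band decision: below the low threshold the frame is
#' `freezing` when the bear was previously seen in an observable zone or
#' was already freezing, else `no_information` (watching canceled). Above
#' the movement threshold the frame is `movement` (subject to
#' validation). In the intermediate band: door-area watch after an exit
#' continues; a near-static rectangle in a visible non-door zone while
#' previously moving means `freezing`; anything else is
#' `no_information`.
#'
#' @param features_nmb feature count of the frame.
#' @param cluster `movement_cluster` or `NULL`.
#' @param prev list describing the previous frame: `attribute`,
#'   `position` (`c(x, y)` or `NULL`), `zone` (name or `NA`),
#'   `door_watch` (logical).
#' @param cfg [camera_config()].
#' @param thr [motion_thresholds()].
#' @param opts options overriding `default_panda_opts` values.
#' @return list `(attribute, position, zone, door_watch, keep_watching)`.
#' @export
classify_frame <- function(features_nmb, cluster, prev, cfg, thr,
                           opts = list()) {
  o <- utils::modifyList(default_panda_opts(), opts)
  prev_zone_type <- zone_type(prev$zone, cfg)
  prev_in_visible <- !is.na(prev$zone)
  if (features_nmb < thr$low) {
    if (prev$attribute %in% c("movement", "freezing") && prev_in_visible)
      return(list(attribute = "freezing", position = prev$position,
                  zone = prev$zone, door_watch = FALSE,
                  keep_watching = TRUE))
    if (prev$attribute == "freezing")
      return(list(attribute = "freezing", position = prev$position,
                  zone = prev$zone, door_watch = FALSE,
                  keep_watching = TRUE))
    return(list(attribute = "no_information", position = NULL,
                zone = NA_character_, door_watch = FALSE,
                keep_watching = FALSE))
  }
  if (features_nmb > thr$mid) {
    pos <- if (!is.null(cluster)) cluster$mass_center else prev$position
    zn <- if (!is.null(pos)) zone_of_point(pos, cfg) else NA_character_
    return(list(attribute = "movement", position = pos, zone = zn,
                door_watch = FALSE, keep_watching = TRUE))
  }
  # low < features_nmb < mid
  if (isTRUE(prev$door_watch) ||
      (!is.na(prev_zone_type) && prev_zone_type == "door")) {
    # door watch after an exit: keep the restricted door-area search
    return(list(attribute = "freezing", position = prev$position,
                zone = prev$zone, door_watch = TRUE, keep_watching = TRUE))
  }
  if (!is.null(cluster) && !is.null(prev$position) && prev_in_visible &&
      (is.na(prev_zone_type) || prev_zone_type != "door") &&
      prev$attribute == "movement" &&
      sqrt(sum((cluster$mass_center - prev$position)^2)) <= o$same_pos_tol)
    return(list(attribute = "freezing", position = prev$position,
                zone = prev$zone, door_watch = FALSE, keep_watching = TRUE))
  list(attribute = "no_information", position = NULL,
       zone = NA_character_, door_watch = FALSE, keep_watching = FALSE)
}

#' Validate a candidate movement frame
#'
#' A pre-classified movement frame is rejected when (a) the movement
#' rectangle area greatly surpasses the previous one (flare or abrupt
#' brightness change), (b) the rectangle is far from the previous
#' positions while in a visible area (teleport), or (c) its position
#' disagrees with the preceding motion direction. After a fast
#' movement - stop - far-rectangle pattern (branch play), the frame is
#' accepted only when a body check contradicts the previous position. On
#' the general-view cameras the features must lie in a zone corresponding
#' to the previously fused zone, which suppresses flying birds.
#'
#' @param rect_ movement rectangle `c(x, y, w, h)` (box origin and size).
#' @param history data.frame of recent observations (columns `x`, `y` =
#'   mass-center coordinates, `w`, `h` = rectangle size, `attribute`),
#'   most recent last; may have zero rows.
#' @param fused_prev list with `camera_id` and `zone` of the previously
#'   fused frame, or `NULL`.
#' @param cfg [camera_config()].
#' @param body_check optional `c(x, y)` position of a panda-body (dark
#'   mass) detection for the branch-play case.
#' @param opts options overriding `default_panda_opts` values.
#' @param center optional `(x, y)` mass center of the candidate cluster;
#'   defaults to the rectangle center.
#' @return `"accept"` or `"reject"`.
#' @export
validate_movement_frame <- function(rect_, history, fused_prev = NULL,
                                    cfg, body_check = NULL, opts = list(),
                                    center = NULL) {
  o <- utils::modifyList(default_panda_opts(), opts)
  ctr <- if (is.null(center)) rect_center(rect_) else center
  mv <- history[!is.na(history$x) & history$attribute == "movement", ,
                drop = FALSE]
  if (nrow(mv) > 0L) {
    last <- mv[nrow(mv), ]
    last_ctr <- c(last$x, last$y)
    last_area <- last$w * last$h
    last_diag <- sqrt(last$w^2 + last$h^2)
    # (a) area burst
    if (last_area > 0 &&
        rect_area(rect_) > o$area_burst_ratio * last_area)
      return("reject")
    # (b) teleport in a visible area
    d <- sqrt(sum((ctr - last_ctr)^2))
    zn <- zone_of_point(ctr, cfg)
    if (!is.na(zn) && d > o$far_factor * last_diag) {
      # branch play: fast move, stop, then far rectangles; the body check
      # decides
      if (!is.null(body_check)) {
        bd <- sqrt(sum((body_check - last_ctr)^2))
        if (bd <= o$same_pos_tol) return("reject")
      } else {
        return("reject")
      }
    }
    # (c) direction agreement
    if (nrow(mv) >= 2L) {
      p2 <- c(mv$x[nrow(mv) - 1L], mv$y[nrow(mv) - 1L])
      p1 <- last_ctr
      v1 <- p1 - p2
      v2 <- ctr - p1
      if (sqrt(sum(v1^2)) > o$min_move && sqrt(sum(v2^2)) > o$min_move &&
          sum(v1 * v2) < 0)
        return("reject")
    }
  }
  # bird suppression on the general views: membership of the zone
  # corresponding to the previously fused zone
  if (isTRUE(cfg$general_view) && !is.null(fused_prev) &&
      !is.na(fused_prev$zone)) {
    zn <- zone_of_point(ctr, cfg)
    if (is.na(zn)) return("reject")
    if (fused_prev$camera_id == cfg$camera_id) {
      if (!identical(zn, fused_prev$zone)) {
        corr <- cfg$zone_correspondence[[fused_prev$zone]]
        ok <- !is.null(corr) &&
          any(corr$camera_id == cfg$camera_id & corr$zone == zn)
        if (!ok) return("reject")
      }
    } else {
      corr <- cfg$zone_correspondence[[zn]]
      ok <- !is.null(corr) &&
        any(corr$camera_id == fused_prev$camera_id &
              corr$zone == fused_prev$zone)
      if (!ok) return("reject")
    }
  }
  "accept"
}

# dark-mass blob detection near a position: the "panda corpus" body check
# used for the branch-play validation
detect_body_near <- function(frame, p, radius = 40L, dark_thr = 90) {
  win <- rect_intersect(rect(p[[1]] - radius, p[[2]] - radius,
                             2L * radius, 2L * radius),
                        rect(0, 0, ncol(frame), nrow(frame)))
  if (is.null(win)) return(NULL)
  sub <- frame[(win[["y"]] + 1L):(win[["y"]] + win[["h"]]),
               (win[["x"]] + 1L):(win[["x"]] + win[["w"]]), drop = FALSE]
  dark <- which(sub < dark_thr, arr.ind = TRUE)
  if (nrow(dark) < 30L) return(NULL)
  c(x = win[["x"]] + mean(dark[, 2]) - 1, y = win[["y"]] + mean(dark[, 1]) - 1)
}

#' Track one panda camera over its frame stream
#'
#' Runs the motion core and the session state machine over all frames of
#' one camera. The counting-box search area is confined around the
#' current position after a movement frame, widened to the whole
#' information polygon otherwise; on camera 8 a flooding basin (the bear
#' bathing behind the foreground stones) restrains the search to the zone
#' beside the last observable position.
#'
#' @param frames list of grayscale frame matrices.
#' @param cfg [camera_config()].
#' @param thr [motion_thresholds()].
#' @param box_w,box_h counting-box size, pixels.
#' @param motion_opts list overriding erosion/dilation/threshold defaults.
#' @param fused_prev_fn optional function(frame_index) returning the
#'   previously fused `(camera_id, zone)` for the bird validation; NULL
#'   disables it.
#' @param opts options overriding `default_panda_opts` values.
#' @return data.frame, one row per frame: `frame_index`, `camera_id`,
#'   `x`, `y`, `w`, `h`, `attribute`, `zone`, `technician`,
#'   `session_active`.
#' @export
track_camera <- function(frames, cfg, thr, box_w = 48, box_h = 48,
                         motion_opts = list(), fused_prev_fn = NULL,
                         opts = list()) {
  o <- utils::modifyList(default_panda_opts(), opts)
  mo <- utils::modifyList(list(erosion_size = 3L, dilation_size = 5L,
                               threshold = 15), motion_opts)
  h <- nrow(frames[[1]]); w <- ncol(frames[[1]])
  mask <- polygon_mask(cfg$info_polygon, w, h)
  session <- FALSE
  technician <- FALSE
  prev <- list(attribute = "no_information", position = NULL,
               zone = NA_character_, door_watch = FALSE)
  prev_valid <- NULL
  static_run <- 0L
  gate_static <- 0L
  search <- NULL
  history <- data.frame(x = numeric(0), y = numeric(0), w = numeric(0),
                        h = numeric(0), attribute = character(0))
  rows <- vector("list", length(frames))
  blank_row <- function(fi) data.frame(
    frame_index = fi, camera_id = cfg$camera_id,
    x = NA_real_, y = NA_real_, w = NA_real_, h = NA_real_,
    attribute = "no_information", zone = NA_character_,
    technician = FALSE, session_active = FALSE)
  for (i in seq_along(frames)) {
    fi <- i - 1L
    row <- blank_row(fi)
    if (i >= 3L) {
      m <- compute_motion_image(frames[[i]], frames[[i - 1L]],
                                frames[[i - 2L]], mo$erosion_size,
                                mo$dilation_size, mo$threshold)
      m <- mask_outside_region(m, mask)
      cl <- counting_box_cluster(m, search, box_w, box_h,
                                 relevance_thr = thr$low)
      # bath special case (camera 8): water motion floods the basin zone
      # while the bear sits behind the stones; restrain the watch beside
      # the last observable position
      if (!is.null(cfg$basin_zone) && !is.null(prev$position) &&
          point_in_rect(prev$position, inflate_rect(cfg$basin_zone,
                                                    o$basin_pad)) &&
          m$features_nmb > thr$mid) {
        bs <- rect_intersect(rect(prev$position[[1]] - o$basin_pad,
                                  prev$position[[2]] - o$basin_pad,
                                  2 * o$basin_pad, 2 * o$basin_pad),
                             rect(0, 0, w, h))
        clb <- if (is.null(bs)) NULL else
          counting_box_cluster(m, bs, box_w, box_h, relevance_thr = thr$low)
        if (!is.null(clb)) cl <- clb
      }
      if (!session) {
        g <- session_gate(m, cl, cfg, thr, prev_valid, o)
        if (g$start) {
          session <- TRUE
          technician <- g$zoo_technician
          static_run <- 0L
          prev <- list(attribute = "movement",
                       position = cl$mass_center,
                       zone = zone_of_point(cl$mass_center, cfg),
                       door_watch = FALSE)
          row$x <- cl$mass_center[[1]]; row$y <- cl$mass_center[[2]]
          row$w <- cl$box[["w"]]; row$h <- cl$box[["h"]]
          row$attribute <- "movement"
          row$zone <- prev$zone
          row$technician <- technician
          row$session_active <- TRUE
        }
      } else {
        cf <- classify_frame(m$features_nmb, cl, prev, cfg, thr, o)
        attr_ <- cf$attribute
        if (attr_ == "movement" && !is.null(cl)) {
          fused_prev <- if (is.null(fused_prev_fn)) NULL else
            fused_prev_fn(fi)
          body <- if (!is.null(prev$position))
            detect_body_near(frames[[i]], prev$position) else NULL
          verdict <- validate_movement_frame(cl$box, history, fused_prev,
                                             cfg, body, o,
                                             center = cl$mass_center)
          if (verdict == "reject") {
            attr_ <- if (!is.null(prev$position)) "freezing" else
              "no_information"
            cf$position <- prev$position
            cf$zone <- prev$zone
          }
        }
        if (attr_ == "movement") {
          static_run <- 0L
          prev <- list(attribute = "movement", position = cf$position,
                       zone = cf$zone, door_watch = FALSE)
          prev_valid <- cf$position
          row$x <- cf$position[[1]]; row$y <- cf$position[[2]]
          row$w <- cl$box[["w"]]; row$h <- cl$box[["h"]]
        } else if (attr_ == "freezing") {
          static_run <- static_run + 1L
          prev <- list(attribute = "freezing", position = cf$position,
                       zone = cf$zone, door_watch = cf$door_watch)
          if (!is.null(cf$position)) {
            row$x <- cf$position[[1]]; row$y <- cf$position[[2]]
            row$w <- box_w; row$h <- box_h
          }
        } else {
          static_run <- static_run + 1L
          prev <- list(attribute = "no_information", position = NULL,
                       zone = NA_character_, door_watch = FALSE)
          session <- FALSE
          technician <- FALSE
        }
        row$attribute <- attr_
        row$zone <- if (is.null(cf$zone)) NA_character_ else cf$zone
        row$technician <- technician
        row$session_active <- session
        # session ends after an exit through a gate or a long static run
        if (session && attr_ == "movement" &&
            point_in_any_rect(cf$position,
                              c(cfg$panda_gates,
                                if (!is.null(cfg$technician_gate))
                                  list(cfg$technician_gate)))) {
          prev$door_watch <- TRUE
        }
        # exit rule: the target left through a gate and the view went
        # static there; the session ends and the position is released
        all_gates <- c(cfg$panda_gates,
                       if (!is.null(cfg$technician_gate))
                         list(cfg$technician_gate))
        if (attr_ != "movement" && !is.null(prev$position) &&
            point_in_any_rect(prev$position, all_gates))
          gate_static <- gate_static + 1L
        else gate_static <- 0L
        if (gate_static > o$exit_frames || static_run > o$static_end) {
          session <- FALSE; technician <- FALSE
          gate_static <- 0L
          prev <- list(attribute = "no_information", position = NULL,
                       zone = NA_character_, door_watch = FALSE)
          row$attribute <- "no_information"
          row$x <- NA_real_; row$y <- NA_real_
          row$w <- NA_real_; row$h <- NA_real_
          row$zone <- NA_character_
          row$session_active <- FALSE
        }
      }
      # search confinement for the next frame
      search <- NULL
      if (session && prev$attribute == "movement" &&
          !is.null(prev$position) && !is.na(prev$zone)) {
        search <- rect(prev$position[[1]] - o$search_pad - box_w / 2,
                       prev$position[[2]] - o$search_pad - box_h / 2,
                       2 * o$search_pad + box_w, 2 * o$search_pad + box_h)
      } else if (session && isTRUE(prev$door_watch) &&
                 !is.null(prev$position)) {
        search <- rect(prev$position[[1]] - o$search_pad,
                       prev$position[[2]] - o$search_pad,
                       2 * o$search_pad, 2 * o$search_pad)
      }
      # rolling history of observations for the validation rules
      history <- rbind(history,
                       data.frame(x = row$x, y = row$y, w = row$w,
                                  h = row$h, attribute = row$attribute))
      if (nrow(history) > o$history_len)
        history <- history[(nrow(history) - o$history_len + 1L):nrow(history), ]
    }
    rows[[i]] <- row
  }
  do.call(rbind, rows)
}

inflate_rect <- function(r, pad) {
  rect(r[["x"]] - pad, r[["y"]] - pad, r[["w"]] + 2 * pad, r[["h"]] + 2 * pad)
}
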
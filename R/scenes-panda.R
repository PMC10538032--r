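#' Synthetic four-camera panda habitat
#'
#' A 2-D world (960 x 540) emulates the panda arena: an open ground area
#' with a full-visibility zone, a housing band with six refuge gates at
#' the bottom, a bathing basin behind two foreground stones, and a
#' technician gate. Four synchronized views render the same scripted
#' bear path: two ground cameras at unit scale covering the left (5) and
#' right (8) halves of the ground, and two general views (6, 7) of the
#' whole arena at roughly half scale. Zone correspondences are emitted
#' consistently with the camera projections. The default script includes
#' a technician visit, a flying-bird event on the general views, a basin
#' dwell longer than 5 s, two dashes and three walking segments, with
#' per-frame ground-truth stress labels.
#'
#' @name panda_scene
NULL

panda_world <- function() {
  list(width = 960, height = 540, ground_y = 200,
       ground_gray = 170, upper_gray = 150,
       bear_r = 14, bear_gray = 50,
       door_x = c(80, 200, 320, 440, 560, 680), door_w = 50,
       doors_y = c(495, 540),
       zone_full = rect(40, 280, 620, 160),
       zone_housing = rect(40, 460, 820, 60),
       zone_basin = rect(690, 300, 170, 140),
       tech_gate = rect(890, 300, 60, 240),
       stones = list(c(740, 360, 26), c(800, 385, 28)),  # cx, cy, r (c8)
       basin_gray = 160, stone_gray = 90, tech_gray = 60,
       bird_gray = 80, bird_r = 6)
}

# world -> camera affines (2 x 3), resolution 480 x 270 each
panda_cameras <- function() {
  list(
    `5` = list(camera_id = 5L, A = rbind(c(1, 0, 0), c(0, 1, -270)),
               scale = 1, general_view = FALSE,
               window = rect(0, 270, 480, 270)),
    `6` = list(camera_id = 6L, A = rbind(c(0.5, 0, 0), c(0, 0.5, 0)),
               scale = 0.5, general_view = TRUE,
               window = rect(0, 0, 960, 540)),
    `7` = list(camera_id = 7L, A = rbind(c(0.48, 0, 5), c(0, 0.48, 8)),
               scale = 0.48, general_view = TRUE,
               window = rect(0, 0, 960, 540)),
    `8` = list(camera_id = 8L, A = rbind(c(1, 0, -480), c(0, 1, -270)),
               scale = 1, general_view = FALSE,
               window = rect(480, 270, 480, 270)))
}

world_rect_to_cam <- function(r, A) {
  p1 <- affine_apply(A, c(r[["x"]], r[["y"]]))
  p2 <- affine_apply(A, c(r[["x"]] + r[["w"]], r[["y"]] + r[["h"]]))
  rect(p1[1], p1[2], p2[1] - p1[1], p2[2] - p1[2])
}

#' Default panda script
#'
#' Timeline (seconds): hidden in a refuge, emergence through a gate,
#' still period at a housing spot, a running dash across the full zone,
#' rest, a walking-1 segment after the full-zone rest, slow approach to
#' the housing, still, a walking-2 segment after the housing still, a
#' zigzag walking-3 segment (with path heights), a dash to the basin, a
#' 13 s hidden bath behind the stones, slow emergence, retreat into a
#' refuge, and a technician visit. A bird crosses the general views
#' during the walking-1 segment.
#'
#' @param duration_s script length; the default timeline needs 120 s.
#' @return script list with `waypoints`, event intervals and
#'   `label_intervals` (ground-truth stress labels).
#' @export
panda_default_script <- function(duration_s = 120) {
  wp <- data.frame(
    t = c(0, 2, 5, 12, 16, 20, 30, 40, 48, 58, 65, 70,
          72.5, 75, 77.5, 80, 83, 86, 99, 103, 107, duration_s),
    x = c(465, 465, 410, 410, 100, 640, 640, 190, 150, 150, 460, 460,
          395, 330, 265, 200, 200, 770, 770, 740, 705, 705),
    y = c(515, 515, 490, 490, 350, 330, 330, 360, 490, 490, 480, 480,
          515, 465, 515, 465, 465, 370, 370, 440, 530, 530))
  list(
    waypoints = wp,
    hidden = rbind(c(0, 2), c(86, 99), c(107, Inf)),
    bath = c(86, 99),
    technician = c(108, 117),
    bird = c(33, 36),
    label_intervals = data.frame(
      label = c("running", "walking1", "walking2", "walking3",
                "running", "stationary"),
      t0 = c(12, 30, 58, 70, 83, 86),
      t1 = c(20, 40, 65, 80, 86, 103)))
}

#' Ground truth for the panda scenario
#'
#' @param s a [scenario()] with `app = "panda"`.
#' @return data.frame, one row per synchronized frame: time, world
#'   position, visibility flags and scripted stress label.
#' @export
panda_truth <- function(s) {
  script <- if (is.null(s$script)) panda_default_script(s$duration_s) else
    s$script
  n <- round(s$duration_s * s$fps)
  times <- (seq_len(n) - 1L) / s$fps
  pos <- script_interp(script$waypoints, times)
  hidden <- vapply(times, in_intervals, logical(1),
                   intervals = script$hidden)
  bath <- times >= script$bath[1] & times < script$bath[2]
  label <- rep("none", n)
  for (k in seq_len(nrow(script$label_intervals))) {
    iv <- script$label_intervals[k, ]
    label[times >= iv$t0 & times < iv$t1] <- iv$label
  }
  data.frame(frame_index = seq_len(n) - 1L, t = times,
             x = pos$x, y = pos$y, hidden = hidden, bath = bath,
             technician = times >= script$technician[1] &
               times < script$technician[2],
             stress = label)
}

# frames beyond the synchronized length, per camera (unequal video
# lengths; the fused list length is the minimum)
panda_extra_frames <- c(`5` = 0L, `6` = 6L, `7` = 3L, `8` = 9L)

#' Render one camera of the panda scenario
#'
#' @param s a [scenario()] with `app = "panda"`.
#' @param camera_id one of 5, 6, 7, 8.
#' @return list of grayscale frame matrices (this camera's video; note
#'   cameras have slightly different frame counts).
#' @export
render_panda_camera <- function(s, camera_id) {
  stopifnot(inherits(s, "scenario"), s$app == "panda")
  set.seed(s$seed + as.integer(camera_id))
  w <- panda_world()
  cams <- panda_cameras()
  cam <- cams[[as.character(camera_id)]]
  script <- if (is.null(s$script)) panda_default_script(s$duration_s) else
    s$script
  truth <- panda_truth(s)
  n <- nrow(truth)
  W <- 480L; H <- 270L
  s_ <- cam$scale
  # static background
  bg <- blank_frame(W, H, w$ground_gray)
  if (cam$general_view) {
    ytop <- affine_apply(cam$A, c(0, w$ground_y))[2]
    if (ytop > 0) bg[seq_len(floor(ytop)), ] <- w$upper_gray
  }
  if (camera_id == 8L) {
    br <- world_rect_to_cam(w$zone_basin, cam$A)
    bg <- draw_box(bg, br[["x"]], br[["y"]], br[["w"]], br[["h"]],
                   w$basin_gray)
  }
  basin_cam <- world_rect_to_cam(w$zone_basin, cam$A)
  draw_stones <- function(fr) {
    for (st in w$stones) {
      p <- affine_apply(cam$A, st[1:2])
      fr <- draw_disk(fr, p[1], p[2], st[3] * s_, w$stone_gray)
    }
    fr
  }
  frames <- vector("list", n + panda_extra_frames[[as.character(camera_id)]])
  last <- NULL
  for (i in seq_len(n)) {
    t <- truth$t[i]
    fr <- bg
    # bear: hidden in refuge/bath; occluded from the general views while
    # in the basin area
    if (!truth$hidden[i]) {
      bp <- affine_apply(cam$A, c(truth$x[i], truth$y[i]))
      in_basin <- point_in_rect(c(truth$x[i], truth$y[i]), w$zone_basin)
      if (!(cam$general_view && in_basin))
        fr <- draw_disk(fr, bp[1], bp[2], w$bear_r * s_, w$bear_gray)
    }
    # basin ripples while the bear bathes behind the stones (camera 8)
    if (camera_id == 8L && truth$bath[i]) {
      k <- 500L
      rx <- basin_cam[["x"]] + stats::runif(k) * basin_cam[["w"]]
      ry <- basin_cam[["y"]] + stats::runif(k) * basin_cam[["h"]]
      idx <- cbind(clamp(round(ry), 0, H - 1) + 1L,
                   clamp(round(rx), 0, W - 1) + 1L)
      fr[idx] <- clamp(fr[idx] + stats::rnorm(k, 0, 60), 0, 255)
    }
    if (camera_id == 8L) fr <- draw_stones(fr)
    # technician at the technician gate
    if (truth$technician[i]) {
      jit <- 5 * sin(8 * t)
      tg <- w$tech_gate
      tr <- world_rect_to_cam(rect(tg[["x"]] + jit, tg[["y"]], 40,
                                   tg[["h"]]), cam$A)
      fr <- draw_box(fr, tr[["x"]], tr[["y"]], tr[["w"]], tr[["h"]],
                     w$tech_gray)
    }
    # bird crossing the general views
    if (cam$general_view && t >= script$bird[1] && t < script$bird[2]) {
      bx <- 100 + 40 * (t - script$bird[1]) + (camera_id == 7L) * 10
      fr <- draw_disk(fr, bx, 110, w$bird_r, w$bird_gray)
    }
    fr <- add_noise(fr, s$noise_sd)
    frames[[i]] <- fr
    last <- fr
  }
  # trailing frames beyond the synchronized length (unequal video
  # lengths); static scene, never fused
  for (j in seq_len(panda_extra_frames[[as.character(camera_id)]]))
    frames[[n + j]] <- add_noise(last, s$noise_sd)
  frames
}

#' Camera configurations for the synthetic panda habitat
#'
#' Builds the per-camera [camera_config()]s consistently with the
#' rendering projections: visible zones are the projections of the world
#' zones intersected with each camera's window, the correspondence map
#' links equally named zones across cameras, and the velocity weights
#' are the world-units-per-pixel scales.
#'
#' @return list with `cfgs` (named list of camera configs), `thresholds`
#'   (named list of per-camera [motion_thresholds()]), and `vthr`
#'   (a [velocity_thresholds()]).
#' @export
panda_scene_configs <- function() {
  w <- panda_world()
  cams <- panda_cameras()
  zone_world <- c(
    stats::setNames(lapply(seq_along(w$door_x), function(k)
      rect(w$door_x[k], w$doors_y[1], w$door_w,
           w$doors_y[2] - w$doors_y[1])),
      paste0("door", seq_along(w$door_x))),
    list(basin = w$zone_basin, housing = w$zone_housing,
         full = w$zone_full))
  ztypes_world <- c(stats::setNames(rep("door", length(w$door_x)),
                                    paste0("door", seq_along(w$door_x))),
                    basin = "basin", housing = "housing", full = "full")
  # which zones are visible per camera (basin is occluded from the
  # general views)
  zone_sets <- lapply(cams, function(cam) {
    keep <- character(0)
    for (nm in names(zone_world)) {
      if (nm == "basin" && cam$general_view) next
      iw <- rect_intersect(zone_world[[nm]], cam$window)
      if (!is.null(iw) && iw[["w"]] * iw[["h"]] >= 400) keep <- c(keep, nm)
    }
    keep
  })
  cfgs <- list()
  for (key in names(cams)) {
    cam <- cams[[key]]
    zs <- zone_sets[[key]]
    polys <- list(); ztp <- character(0)
    for (nm in zs) {
      iw <- rect_intersect(zone_world[[nm]], cam$window)
      cr <- world_rect_to_cam(iw, cam$A)
      polys[[nm]] <- rect_polygon(cr, nm)
      ztp[nm] <- ztypes_world[[nm]]
    }
    corr <- lapply(zs, function(nm) {
      others <- names(cams)[vapply(names(cams), function(k2)
        k2 != key && nm %in% zone_sets[[k2]], logical(1))]
      if (!length(others))
        return(data.frame(camera_id = integer(0), zone = character(0)))
      data.frame(camera_id = as.integer(others), zone = nm)
    })
    names(corr) <- zs
    gates <- lapply(zs[grepl("^door", zs)], function(nm)
      world_rect_to_cam(rect_intersect(zone_world[[nm]], cam$window),
                        cam$A))
    # view-entry bands at the shared boundary of the two ground cameras
    if (cam$camera_id == 5L)
      gates <- c(gates, list(rect(440, 0, 40, 270)))
    if (cam$camera_id == 8L)
      gates <- c(gates, list(rect(0, 0, 40, 270)))
    tg_int <- rect_intersect(w$tech_gate, cam$window)
    tg <- if (is.null(tg_int)) NULL else world_rect_to_cam(tg_int, cam$A)
    basin <- if (cam$camera_id == 8L)
      world_rect_to_cam(rect_intersect(w$zone_basin, cam$window), cam$A)
      else NULL
    info <- if (cam$general_view) {
      ytop <- affine_apply(cam$A, c(0, w$ground_y))[2]
      rect_polygon(rect(0, ytop, 480, 270 - ytop), "info")
    } else rect_polygon(rect(0, 0, 480, 270), "info")
    cfgs[[key]] <- camera_config(
      camera_id = cam$camera_id, resolution = c(480L, 270L),
      info_polygon = info, panda_gates = gates, technician_gate = tg,
      visible_zones = polys, zone_types = ztp, zone_correspondence = corr,
      general_view = cam$general_view, basin_zone = basin,
      velocity_weight = 1 / cam$scale,
      technician_height_frac = if (cam$general_view) 0.4 else 0.6,
      world_affine = cam$A)
  }
  thresholds <- list(
    `5` = motion_thresholds(25, 70, 1200),
    `6` = motion_thresholds(10, 30, 450),
    `7` = motion_thresholds(10, 30, 450),
    `8` = motion_thresholds(25, 70, 1200))
  list(cfgs = cfgs, thresholds = thresholds,
       vthr = velocity_thresholds(6, 3.5, 1.5))
}
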
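#' Synthetic monkey cage scene
#'
#' Emulates the neuroscience-cage recordings: an unevenly illuminated
#' scene (horizontal brightness gradient), a dark rotated rectangle for
#' the head-mounted sensor box following a scripted path and angle,
#' scripted light-off intervals (global dimming with a jittering shadow
#' blob near the animal), and an external motion burst outside the
#' useful-information polygon (feeding from outside the cage).
#'
#' @name monkey_scene
NULL

monkey_geometry <- function() {
  list(width = 320L, height = 240L,
       bg_lo = 90, bg_hi = 220,      # illumination gradient endpoints
       box_len = 44, box_wid = 18, box_gray = 25,
       off_factor = 0.2,             # light-off global dimming
       shadow_offset = c(70, 25), shadow_r = 12, shadow_gray = 35,
       info_margin = 280,            # info polygon: columns [0, 280)
       burst_x = 300, burst_y = 120, burst_r = 10, burst_gray = 60)
}

#' Default monkey script
#'
#' @param duration_s script length, seconds (600 frames at 10 fps for
#'   the default 60 s).
#' @return script list: `waypoints`, `angles` (`t`, `angle_deg`),
#'   `light_off` and `burst` interval matrices (seconds).
#' @export
monkey_default_script <- function(duration_s = 60) {
  # the animal rests (holds position and angle) during the light-off
  # intervals (20, 26) and (34, 40)
  wp <- data.frame(
    t = c(0, 8, 14, 26, 34, 40, 48, 54, duration_s),
    x = c(60, 150, 200, 200, 120, 120, 210, 90, 150),
    y = c(80, 120, 90, 90, 160, 160, 140, 100, 130))
  ang <- data.frame(
    t = c(0, 8, 14, 26, 34, 40, 48, duration_s),
    angle_deg = c(0, 30, 60, 60, 120, 120, 150, 45))
  list(waypoints = wp, angles = ang,
       light_off = rbind(c(20, 26), c(34, 40)),
       burst = rbind(c(44, 47)))
}

#' Render the synthetic monkey scene
#'
#' @param s a [scenario()] with `app = "monkey"`.
#' @return list with `frames`, `truth` (per-frame `x`, `y`,
#'   `angle_deg`, `light`, `burst`) and `geom`.
#' @export
render_monkey_scene <- function(s) {
  stopifnot(inherits(s, "scenario"), s$app == "monkey")
  set.seed(s$seed)
  g <- monkey_geometry()
  script <- if (is.null(s$script)) monkey_default_script(s$duration_s) else
    s$script
  n <- round(s$duration_s * s$fps)
  times <- (seq_len(n) - 1L) / s$fps
  pos <- script_interp(script$waypoints, times)
  ang <- stats::approx(script$angles$t, script$angles$angle_deg,
                       xout = times, rule = 2)$y
  grad <- matrix(rep(seq(g$bg_lo, g$bg_hi, length.out = g$width),
                     each = g$height), g$height, g$width)
  if (any(pos$x < 0 | pos$x >= g$width | pos$y < 0 | pos$y >= g$height))
    stop("script positions outside the cage")
  frames <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    t <- times[i]
    off <- in_intervals(t, script$light_off)
    fr <- grad
    # the sensor box (dark rotated rectangle) on the monkey's head
    fr <- draw_rot_rect(fr, pos$x[i], pos$y[i], g$box_len, g$box_wid,
                        ang[i] * pi / 180, g$box_gray)
    if (in_intervals(t, script$burst)) {
      # feeding-like motion outside the information polygon
      bx <- g$burst_x + 6 * sin(10 * t)
      fr <- draw_disk(fr, bx, g$burst_y, g$burst_r, g$burst_gray)
    }
    if (off) {
      fr <- fr * g$off_factor
      # monkey shadow: jittering dark blob away from the animal
      fr <- draw_disk(fr,
                      pos$x[i] + g$shadow_offset[1] + stats::rnorm(1, 0, 2),
                      pos$y[i] + g$shadow_offset[2] + stats::rnorm(1, 0, 2),
                      g$shadow_r, g$shadow_gray * g$off_factor)
    }
    frames[[i]] <- add_noise(fr, s$noise_sd)
    truth[[i]] <- data.frame(frame_index = i - 1L, x = pos$x[i], y = pos$y[i],
                             angle_deg = ang[i] %% 180,
                             light = if (off) "off" else "on",
                             burst = in_intervals(t, script$burst))
  }
  list(frames = frames, truth = do.call(rbind, truth), geom = g)
}

#' Information polygon and region reliabilities for the monkey scene
#'
#' Four vertical cage regions with reliability weights; the rightmost
#' columns (feeder area) are excluded from the information polygon.
#'
#' @param geom geometry list from [render_monkey_scene()].
#' @return list with `info_polygon` and `regions`
#'   (a [region_reliability()]).
#' @export
monkey_scene_config <- function(geom = monkey_geometry()) {
  w <- geom$info_margin; h <- geom$height
  info <- region_polygon(rbind(c(0, 0), c(w - 1, 0), c(w - 1, h - 1),
                               c(0, h - 1)), "info")
  qs <- round(seq(0, w, length.out = 5))
  polys <- lapply(1:4, function(k)
    region_polygon(rbind(c(qs[k], 0), c(qs[k + 1], 0),
                         c(qs[k + 1], h - 1), c(qs[k], h - 1)),
                   paste0("region", k)))
  list(info_polygon = info,
       regions = region_reliability(polys, weights = c(0.95, 1, 1, 0.9)))
}
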
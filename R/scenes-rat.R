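#' Synthetic rat box scenes
#'
#' Seeded renderers emulating the two rat-experiment stages: a top view
#' of the three-chamber box with the rat confined to the middle room
#' (stage 1), and a side view with the rat roaming all compartments
#' (stage 2). Both return the rendered frames together with per-frame
#' ground truth.
#'
#' @name rat_scenes
NULL

rat1_geometry <- function() {
  list(width = 320L, height = 240L, floor = 200, wall_gray = 30,
       # the four physical wall bands (columns); the rat itself forms the
       # fifth projection cluster between the middle-room walls
       bands = list(c(8, 16), c(60, 70), c(250, 260), c(304, 312)),
       body_a = 28, body_b = 11, taper = 0.45, rat_gray = 40,
       tail_len = 30, tail_thick = 2)
}

#' Default stage-1 script: horizontal shuttling with turn-arounds
#'
#' The rat walks back and forth across the middle room with pauses at
#' the ends during which it turns around (heading rotates by 180
#' degrees), producing at least four turn-around events in 60 s.
#'
#' @param duration_s script length, seconds.
#' @return script list with `waypoints` (`t`, `x`, `y`) and `headings`
#'   (`t`, `theta` in radians).
#' @export
rat1_default_script <- function(duration_s = 60) {
  xl <- 115; xr <- 205; y <- 120
  leg <- 6; pause <- 3
  t <- 0; pts <- list(); hd <- list()
  x <- xl; dirr <- 1
  pts[[1]] <- c(0, xl, y); hd[[1]] <- c(0, 0)
  while (t < duration_s + leg + pause) {
    t2 <- t + leg
    x2 <- if (dirr > 0) xr else xl
    th_old <- if (dirr > 0) 0 else pi
    th_new <- pi - th_old
    pts[[length(pts) + 1L]] <- c(t2, x2, y)
    hd[[length(hd) + 1L]] <- c(t2, th_old)
    # pause: hold, turn around within one second, hold the new heading
    hd[[length(hd) + 1L]] <- c(t2 + 1, th_old)
    hd[[length(hd) + 1L]] <- c(t2 + 2, th_new)
    pts[[length(pts) + 1L]] <- c(t2 + pause, x2, y)
    hd[[length(hd) + 1L]] <- c(t2 + pause, th_new)
    t <- t2 + pause
    dirr <- -dirr
  }
  wp <- do.call(rbind, pts); hh <- do.call(rbind, hd)
  list(waypoints = data.frame(t = wp[, 1], x = wp[, 2], y = wp[, 3]),
       headings = data.frame(t = hh[, 1], theta = hh[, 2]))
}

#' Render a synthetic rat scene
#'
#' @param s a [scenario()] with `app` `"rat1"` or `"rat2"`.
#' @return list with `frames` (list of grayscale matrices), `truth`
#'   (per-frame data.frame) and `geom` (scene geometry, including the
#'   true wall/cage parameters).
#' @export
render_rat_scene <- function(s) {
  stopifnot(inherits(s, "scenario"), s$app %in% c("rat1", "rat2"))
  if (s$app == "rat1") render_rat1(s) else render_rat2(s)
}

render_rat1 <- function(s) {
  set.seed(s$seed)
  g <- rat1_geometry()
  script <- if (is.null(s$script)) rat1_default_script(s$duration_s) else
    s$script
  n <- round(s$duration_s * s$fps)
  times <- (seq_len(n) - 1L) / s$fps
  pos <- script_interp(script$waypoints, times)
  theta <- stats::approx(script$headings$t, script$headings$theta,
                         xout = times, rule = 2)$y
  bg <- blank_frame(g$width, g$height, g$floor)
  for (b in g$bands) bg <- draw_box(bg, b[1], 0, b[2] - b[1] + 1, g$height,
                                    g$wall_gray)
  if (any(pos$x < 0 | pos$x >= g$width | pos$y < 0 | pos$y >= g$height))
    stop("script positions outside the box")
  frames <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    fr <- bg
    cx <- pos$x[i]; cy <- pos$y[i]; th <- theta[i]
    nose <- c(cx + g$body_a * cos(th), cy + g$body_a * sin(th))
    tail0 <- c(cx - g$body_a * cos(th), cy - g$body_a * sin(th))
    tail1 <- c(cx - (g$body_a + g$tail_len) * cos(th),
               cy - (g$body_a + g$tail_len) * sin(th))
    fr <- draw_segment(fr, tail0, tail1, g$tail_thick, g$rat_gray)
    fr <- draw_ellipse(fr, cx, cy, g$body_a, g$body_b, th, g$rat_gray,
                       taper_frac = g$taper)
    frames[[i]] <- add_noise(fr, s$noise_sd)
    # body centroid of the rendered (tapered) shape, tail excluded
    bm <- draw_ellipse(blank_frame(g$width, g$height, 0), cx, cy,
                       g$body_a, g$body_b, th, 1, taper_frac = g$taper)
    bp <- which(bm == 1, arr.ind = TRUE)
    bcx <- mean(bp[, 2]) - 1; bcy <- mean(bp[, 1]) - 1
    hx <- nose[1] - cx; hy <- nose[2] - cy
    side <- if (abs(hx) >= abs(hy)) {
      if (hx < 0) "left" else "right"
    } else {
      if (hy < 0) "up" else "down"
    }
    truth[[i]] <- data.frame(frame_index = i - 1L, x = bcx, y = bcy,
                             theta = th, head_x = nose[1], head_y = nose[2],
                             head_side = side)
  }
  list(frames = frames, truth = do.call(rbind, truth), geom = g)
}

rat2_geometry <- function() {
  list(width = 320L, height = 120L, bg = 210,
       cage_gray = 60, wall_gray = 40, rat_gray = 70,
       c11 = 20, c12 = 70, c21 = 250, c22 = 300,
       wall1 = c(95, 101), wall2 = c(219, 225), wall_height_frac = 2 / 3,
       rat_a = 20, rat_b = 12, rat_y = 95)
}

#' Default stage-2 script: scripted compartment visits
#'
#' Returns a visit plan (compartment dwell times) realized as `x`
#' waypoints; crossings move at a constant walking speed. The default
#' plan includes one left-cage visit longer than a minute.
#'
#' @param duration_s script length, seconds.
#' @param plan optional data.frame with `comp` (compartment names) and
#'   `dwell` (seconds); the default plan includes a left-cage visit of
#'   70 s.
#' @return script list with `waypoints` and `plan` (data.frame
#'   `compartment`, `start_s`, `end_s` of the scripted visits).
#' @export
rat2_default_script <- function(duration_s = 120, plan = NULL) {
  g <- rat2_geometry()
  xm <- 160; xl <- 45; xr <- 275
  cross <- 2   # seconds to cross between compartment centers
  segs <- if (is.null(plan)) data.frame(
    comp = c("middle", "left_cage", "middle", "right_cage", "middle"),
    dwell = c(10, 70, 10, 15, duration_s)) else plan
  t <- 0; pts <- list(c(0, xm))
  xat <- c(middle = xm, left_cage = xl, right_cage = xr)
  for (k in seq_len(nrow(segs))) {
    tgt <- xat[[segs$comp[k]]]
    if (k > 1L) {
      t <- t + cross
      pts[[length(pts) + 1L]] <- c(t, tgt)
    }
    t <- t + segs$dwell[k]
    pts[[length(pts) + 1L]] <- c(t, tgt)
    if (t > duration_s) break
  }
  wp <- do.call(rbind, pts)
  list(waypoints = data.frame(t = wp[, 1], x = wp[, 2], y = g$rat_y),
       plan = segs)
}

render_rat2 <- function(s) {
  set.seed(s$seed)
  g <- rat2_geometry()
  script <- if (is.null(s$script)) rat2_default_script(s$duration_s) else
    s$script
  n <- round(s$duration_s * s$fps)
  times <- (seq_len(n) - 1L) / s$fps
  pos <- script_interp(script$waypoints, times)
  bg <- blank_frame(g$width, g$height, g$bg)
  bg <- draw_box(bg, g$c11, 0, g$c12 - g$c11 + 1, g$height, g$cage_gray)
  bg <- draw_box(bg, g$c21, 0, g$c22 - g$c21 + 1, g$height, g$cage_gray)
  wh <- round(g$height * g$wall_height_frac)
  bg <- draw_box(bg, g$wall1[1], 0, diff(g$wall1) + 1, wh, g$wall_gray)
  bg <- draw_box(bg, g$wall2[1], 0, diff(g$wall2) + 1, wh, g$wall_gray)
  b1 <- mean(g$wall1); b2 <- mean(g$wall2)
  frames <- vector("list", n)
  # small within-compartment wander keeps some motion texture
  wander <- cumsum(stats::rnorm(n, 0, 0.15))
  wander <- clamp(wander, -3, 3)
  comp <- ifelse(pos$x + wander < b1, "left_cage",
                 ifelse(pos$x + wander > b2, "right_cage", "middle"))
  for (i in seq_len(n)) {
    fr <- bg
    fr <- draw_ellipse(fr, pos$x[i] + wander[i], pos$y[i], g$rat_a, g$rat_b,
                       0, g$rat_gray)
    frames[[i]] <- add_noise(fr, s$noise_sd)
  }
  truth <- data.frame(frame_index = seq_len(n) - 1L,
                      x = pos$x + wander, y = pos$y,
                      compartment = comp)
  g$b1 <- b1; g$b2 <- b2
  list(frames = frames, truth = truth, geom = g)
}

# scripted visit summary from the ground-truth compartment sequence
truth_visits <- function(truth, fps) {
  r <- rle(truth$compartment)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  data.frame(compartment = r$values,
             start_frame = truth$frame_index[starts],
             end_frame = truth$frame_index[ends],
             duration_s = r$lengths / fps)
}
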
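# Rendering primitives and script interpolation shared by the synthetic
# scene generators. All drawing is into plain grayscale matrices
# (0-based pixel coordinates, y down), vectorized over the shape's
# bounding box.

blank_frame <- function(width, height, value = 0) {
  matrix(value, height, width)
}

# pixel-center grid of a clamped bounding box; returns NULL when empty
bbox_grid <- function(frame, x0, x1, y0, y1) {
  x0 <- max(0L, floor(x0)); x1 <- min(ncol(frame) - 1L, ceiling(x1))
  y0 <- max(0L, floor(y0)); y1 <- min(nrow(frame) - 1L, ceiling(y1))
  if (x1 < x0 || y1 < y0) return(NULL)
  xs <- x0:x1; ys <- y0:y1
  list(X = matrix(rep(xs, each = length(ys)), length(ys)),
       Y = matrix(rep(ys, length(xs)), length(ys)),
       rows = ys + 1L, cols = xs + 1L)
}

draw_disk <- function(frame, cx, cy, r, value) {
  g <- bbox_grid(frame, cx - r, cx + r, cy - r, cy + r)
  if (is.null(g)) return(frame)
  inside <- (g$X - cx)^2 + (g$Y - cy)^2 <= r^2
  sub <- frame[g$rows, g$cols, drop = FALSE]
  sub[inside] <- value
  frame[g$rows, g$cols] <- sub
  frame
}

# rotated ellipse with optional taper: the semi-minor axis shrinks
# linearly toward the +u (heading) end by `taper_frac`
draw_ellipse <- function(frame, cx, cy, a, b, theta = 0, value,
                         taper_frac = 0) {
  ext <- max(a, b)
  g <- bbox_grid(frame, cx - ext, cx + ext, cy - ext, cy + ext)
  if (is.null(g)) return(frame)
  dx <- g$X - cx; dy <- g$Y - cy
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  b_eff <- b * (1 - taper_frac * pmax(u, 0) / a)
  inside <- (u / a)^2 + (v / pmax(b_eff, 1e-6))^2 <= 1
  sub <- frame[g$rows, g$cols, drop = FALSE]
  sub[inside] <- value
  frame[g$rows, g$cols] <- sub
  frame
}

# filled axis-aligned rectangle, half-open [x, x+w) x [y, y+h)
draw_box <- function(frame, x, y, w, h, value) {
  g <- bbox_grid(frame, x, x + w - 1, y, y + h - 1)
  if (is.null(g)) return(frame)
  inside <- g$X >= x & g$X < x + w & g$Y >= y & g$Y < y + h
  sub <- frame[g$rows, g$cols, drop = FALSE]
  sub[inside] <- value
  frame[g$rows, g$cols] <- sub
  frame
}

# rotated filled rectangle centered at (cx, cy), long side `len` along
# `theta`, short side `wid`
draw_rot_rect <- function(frame, cx, cy, len, wid, theta, value) {
  ext <- (len + wid) / 2
  g <- bbox_grid(frame, cx - ext, cx + ext, cy - ext, cy + ext)
  if (is.null(g)) return(frame)
  dx <- g$X - cx; dy <- g$Y - cy
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  inside <- abs(u) <= len / 2 & abs(v) <= wid / 2
  sub <- frame[g$rows, g$cols, drop = FALSE]
  sub[inside] <- value
  frame[g$rows, g$cols] <- sub
  frame
}

# thick line segment (used for the rat tail)
draw_segment <- function(frame, p1, p2, thickness, value) {
  g <- bbox_grid(frame, min(p1[1], p2[1]) - thickness,
                 max(p1[1], p2[1]) + thickness,
                 min(p1[2], p2[2]) - thickness,
                 max(p1[2], p2[2]) + thickness)
  if (is.null(g)) return(frame)
  d <- p2 - p1
  len2 <- sum(d^2)
  if (len2 < 1e-9) return(draw_disk(frame, p1[1], p1[2], thickness / 2, value))
  t <- ((g$X - p1[1]) * d[1] + (g$Y - p1[2]) * d[2]) / len2
  t <- pmin(pmax(t, 0), 1)
  px <- p1[1] + t * d[1]; py <- p1[2] + t * d[2]
  inside <- (g$X - px)^2 + (g$Y - py)^2 <= (thickness / 2)^2
  sub <- frame[g$rows, g$cols, drop = FALSE]
  sub[inside] <- value
  frame[g$rows, g$cols] <- sub
  frame
}

add_noise <- function(frame, sd) {
  if (sd <= 0) return(frame)
  clamp(frame + matrix(stats::rnorm(length(frame), 0, sd),
                       nrow(frame), ncol(frame)), 0, 255)
}

# piecewise-linear interpolation of scripted waypoints (t in seconds) at
# the frame times; constant extrapolation beyond the ends
script_interp <- function(waypoints, times) {
  data.frame(
    x = stats::approx(waypoints$t, waypoints$x, xout = times, rule = 2)$y,
    y = stats::approx(waypoints$t, waypoints$y, xout = times, rule = 2)$y)
}

# interval membership: is time t inside any [start, end) of a 2-column
# matrix/data.frame of intervals?
in_intervals <- function(t, intervals) {
  if (is.null(intervals) || length(intervals) == 0L) return(FALSE)
  iv <- as.matrix(intervals)
  any(t >= iv[, 1] & t < iv[, 2])
}

#' Scenario descriptor for the synthetic scene generators
#'
#' @param app one of `"rat1"`, `"rat2"`, `"monkey"`, `"panda"`.
#' @param fps frames per second.
#' @param duration_s scenario length in seconds.
#' @param seed integer seed; generators are bit-deterministic given
#'   `(script, seed)`.
#' @param script application-specific script list; `NULL` uses the
#'   application's default script.
#' @param noise_sd additive Gaussian intensity noise, gray levels.
#' @return object of class `scenario`.
#' @export
scenario <- function(app, fps = 10, duration_s = 60, seed = 1L,
                     script = NULL, noise_sd = 3) {
  stopifnot(app %in% c("rat1", "rat2", "monkey", "panda"))
  structure(list(app = app, fps = fps, duration_s = duration_s,
                 seed = as.integer(seed), script = script,
                 noise_sd = noise_sd),
            class = "scenario")
}
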
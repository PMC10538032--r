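# Geometry helpers shared by the orientation estimator and the trajectory
# analysis: rotating-calipers minimum-area bounding rectangle and distances
# from points to a least-squares line.

# Minimum-area bounding rectangle of a point set (rotating calipers over
# convex hull edges). Points are pixel centers; extents include the full
# pixel (+1) so degenerate 1-px-thin sets keep a nonzero area.
# Returns list(width, height, angle_deg, area): `angle_deg` is the
# direction of the LONG side, in [0, 180).
min_area_rect <- function(pts) {
  pts <- unique(as.matrix(pts))
  if (nrow(pts) == 1L)
    return(list(width = 1, height = 1, angle_deg = 0, area = 1))
  hull <- pts[grDevices::chull(pts), , drop = FALSE]
  if (nrow(hull) == 2L) hull <- rbind(hull, hull[1, ])
  best <- NULL
  n <- nrow(hull)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    e <- hull[j, ] - hull[i, ]
    len <- sqrt(sum(e^2))
    if (len < 1e-12) next
    theta <- atan2(e[2], e[1])
    ct <- cos(-theta); st <- sin(-theta)
    u <- hull[, 1] * ct - hull[, 2] * st
    v <- hull[, 1] * st + hull[, 2] * ct
    du <- diff(range(u)) + 1
    dv <- diff(range(v)) + 1
    area <- du * dv
    if (is.null(best) || area < best$area) {
      long_along_edge <- du >= dv
      ang <- theta * 180 / pi
      if (!long_along_edge) ang <- ang + 90
      ang <- ang %% 180
      best <- list(width = max(du, dv), height = min(du, dv),
                   angle_deg = ang, area = area)
    }
  }
  best
}

# smallest angular difference between two orientations modulo 180 degrees
angle_diff_180 <- function(a, b) {
  d <- abs((a - b) %% 180)
  pmin(d, 180 - d)
}

# maximum orthogonal distance of points from their least-squares line
# (total least squares via principal axis); the "path height" measure
max_line_deviation <- function(pts) {
  pts <- as.matrix(pts)
  if (nrow(pts) < 3L) return(0)
  ctr <- colMeans(pts)
  d <- sweep(pts, 2, ctr)
  sv <- svd(d, nu = 0, nv = 2)
  normal <- sv$v[, 2]
  max(abs(d %*% normal))
}
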
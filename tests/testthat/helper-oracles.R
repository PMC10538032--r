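# Independent brute-force oracles used to pin down the vectorized
# implementations. All are deliberately written as plain pixel/element
# loops, separate from the package's code paths.

# pixelwise evaluation of the motion-image formula:
# threshold(clip(|ia-ib| - |ib-ic|)) then box erosion then box dilation,
# with off-image pixels treated as background
oracle_motion_image <- function(ia, ib, ic, erosion = 3L, dilation = 5L,
                                thr = 15) {
  h <- nrow(ia); w <- ncol(ia)
  dd <- abs(ia - ib) - abs(ib - ic)
  bin <- matrix(0L, h, w)
  bin[pmax(dd, 0) > thr] <- 1L
  erode1 <- function(m, k) {
    r <- (k - 1L) %/% 2L
    out <- matrix(0L, h, w)
    for (y in seq_len(h)) for (x in seq_len(w)) {
      ok <- TRUE
      for (dy in -r:r) for (dx in -r:r) {
        yy <- y + dy; xx <- x + dx
        v <- if (yy < 1L || yy > h || xx < 1L || xx > w) 0L else m[yy, xx]
        if (v == 0L) { ok <- FALSE; break }
      }
      if (ok) out[y, x] <- 1L
    }
    out
  }
  dilate1 <- function(m, k) {
    r <- (k - 1L) %/% 2L
    out <- matrix(0L, h, w)
    for (y in seq_len(h)) for (x in seq_len(w)) {
      hit <- FALSE
      for (dy in -r:r) for (dx in -r:r) {
        yy <- y + dy; xx <- x + dx
        if (yy >= 1L && yy <= h && xx >= 1L && xx <= w && m[yy, xx] == 1L) {
          hit <- TRUE; break
        }
      }
      if (hit) out[y, x] <- 1L
    }
    out
  }
  if (erosion > 1L) bin <- erode1(bin, erosion)
  if (dilation > 1L) bin <- dilate1(bin, dilation)
  bin
}

# winding-number point-in-polygon (edge-inclusive)
oracle_winding_inside <- function(p, vertices) {
  n <- nrow(vertices)
  px <- p[1]; py <- p[2]
  eps <- 1e-9
  # on-edge check
  j <- n
  for (i in seq_len(n)) {
    x1 <- vertices[j, 1]; y1 <- vertices[j, 2]
    x2 <- vertices[i, 1]; y2 <- vertices[i, 2]
    cross <- (px - x1) * (y2 - y1) - (py - y1) * (x2 - x1)
    if (abs(cross) <= eps &&
        px >= min(x1, x2) - eps && px <= max(x1, x2) + eps &&
        py >= min(y1, y2) - eps && py <= max(y1, y2) + eps)
      return(TRUE)
    j <- i
  }
  wn <- 0L
  j <- n
  for (i in seq_len(n)) {
    x1 <- vertices[j, 1]; y1 <- vertices[j, 2]
    x2 <- vertices[i, 1]; y2 <- vertices[i, 2]
    if (y1 <= py) {
      if (y2 > py && (x2 - x1) * (py - y1) - (px - x1) * (y2 - y1) > 0)
        wn <- wn + 1L
    } else {
      if (y2 <= py && (x2 - x1) * (py - y1) - (px - x1) * (y2 - y1) < 0)
        wn <- wn - 1L
    }
    j <- i
  }
  wn != 0L
}

# exhaustive counting-box search: best feature count over all stride-1
# placements inside the search rect (0-based, half-open)
oracle_best_box_count <- function(features, sx, sy, sw, sh, bw, bh) {
  best <- -1L
  for (oy in sy:(sy + sh - bh)) for (ox in sx:(sx + sw - bw)) {
    cnt <- sum(features[(oy + 1L):(oy + bh), (ox + 1L):(ox + bw)])
    if (cnt > best) best <- cnt
  }
  best
}

# star-shaped (hence simple) random polygon around a center
random_simple_polygon <- function(n_vertices, cx, cy, r_min, r_max) {
  ang <- sort(stats::runif(n_vertices, 0, 2 * pi))
  rad <- stats::runif(n_vertices, r_min, r_max)
  cbind(cx + rad * cos(ang), cy + rad * sin(ang))
}

# naive windowed mean of an angle series with validity gating and
# mod-180 unwrapping about the window median
oracle_filtered_angles <- function(angle, conf, t, conf_thr) {
  n <- length(angle)
  half <- (t - 1L) %/% 2L
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    win <- max(1L, i - half):min(n, i + half)
    vals <- c()
    for (j in win)
      if (!is.na(angle[j]) && conf[j] >= conf_thr)
        vals <- c(vals, angle[j])
    if (!length(vals)) next
    med <- stats::median(vals)
    vals <- vals + 180 * round((med - vals) / 180)
    out[i] <- mean(vals) %% 180
  }
  out
}

# naive majority vote over a centered window; ties keep the current value
oracle_vote_attributes <- function(att, window) {
  half <- (window - 1L) %/% 2L
  n <- length(att)
  votable <- att %in% c("movement", "freezing", "no_information")
  out <- att
  for (i in seq_len(n)) {
    if (!votable[i]) next
    win <- max(1L, i - half):min(n, i + half)
    w <- att[win][votable[win]]
    tb <- table(w)
    top <- names(tb)[tb == max(tb)]
    if (length(top) == 1L) out[i] <- top
    else if (att[i] %in% top) out[i] <- att[i]
    else out[i] <- top[1]
  }
  out
}
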
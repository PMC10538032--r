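#' Motion-feature extraction from a frame triple
#'
#' Movement strength is measured on each frame from the current frame `ia`
#' and the two frames before it, `ib` and `ic` (ia newest). The double
#' difference `max(|ia - ib| - |ib - ic|, 0)` suppresses the trail the
#' target left between `ic` and `ib` and keeps the pixels it newly covers,
#' which makes the feature map concentrate on the target's current
#' position. The clipped difference is binarized at `threshold`, then
#' cleaned by a morphological erosion (removes isolated noise responses)
#' followed by a dilation (re-connects the surviving cluster). Pixels
#' outside the image are treated as background for both operators.
#'
#' @param ia,ib,ic grayscale frames of identical dimensions, `ia` the
#'   current frame, `ib` and `ic` the two anterior ones.
#' @param erosion_size odd side of the square erosion element (pixels).
#' @param dilation_size odd side of the square dilation element (pixels).
#' @param threshold intensity threshold applied to the clipped double
#'   difference; a pixel is a candidate feature when the difference is
#'   strictly greater.
#' @return an object of class `motion_image`: list with `features`
#'   (integer 0/1 matrix of the frame size) and `features_nmb` (count of
#'   nonzero feature pixels).
#' @export
compute_motion_image <- function(ia, ib, ic,
                                 erosion_size = 3L,
                                 dilation_size = 5L,
                                 threshold = 15) {
  ia <- as_gray_frame(ia); ib <- as_gray_frame(ib); ic <- as_gray_frame(ic)
  if (!all(dim(ia) == dim(ib)) || !all(dim(ia) == dim(ic)))
    stop("frame triple dimension mismatch")
  dd <- pmax(abs(ia - ib) - abs(ib - ic), 0)
  bin <- matrix(as.integer(dd > threshold), nrow(dd), ncol(dd))
  bin <- binary_box_erode(bin, erosion_size)
  bin <- binary_box_dilate(bin, dilation_size)
  motion_image(bin)
}

motion_image <- function(features) {
  structure(list(features = features, features_nmb = sum(features != 0)),
            class = "motion_image")
}

#' @export
print.motion_image <- function(x, ...) {
  cat(sprintf("<motion_image %dx%d, %d features>\n",
              ncol(x$features), nrow(x$features), x$features_nmb))
  invisible(x)
}

# Binary morphology with a square structuring element. EBImage replicates
# border pixels, while the motion formula treats off-image pixels as
# background, so the image is zero-padded by the element radius first.
binary_box_erode <- function(bin, size) {
  if (size <= 1L) return(bin)
  stopifnot(size %% 2L == 1L)
  r <- (size - 1L) %/% 2L
  pad <- matrix(0L, nrow(bin) + 2L * r, ncol(bin) + 2L * r)
  pad[(r + 1L):(r + nrow(bin)), (r + 1L):(r + ncol(bin))] <- bin
  out <- EBImage::erode(pad, EBImage::makeBrush(size, "box"))
  matrix(as.integer(out[(r + 1L):(r + nrow(bin)), (r + 1L):(r + ncol(bin))]),
         nrow(bin), ncol(bin))
}

binary_box_dilate <- function(bin, size) {
  if (size <= 1L) return(bin)
  stopifnot(size %% 2L == 1L)
  r <- (size - 1L) %/% 2L
  pad <- matrix(0L, nrow(bin) + 2L * r, ncol(bin) + 2L * r)
  pad[(r + 1L):(r + nrow(bin)), (r + 1L):(r + ncol(bin))] <- bin
  out <- EBImage::dilate(pad, EBImage::makeBrush(size, "box"))
  matrix(as.integer(out[(r + 1L):(r + nrow(bin)), (r + 1L):(r + ncol(bin))]),
         nrow(bin), ncol(bin))
}

#' Region polygon
#'
#' An ordered list of vertices delimiting a simple polygon in 0-based pixel
#' coordinates, used as the useful-information region of a camera view or
#' as a visible zone.
#'
#' @param vertices n x 2 matrix of `(x, y)` vertices, n >= 3.
#' @param name optional label.
#' @return object of class `region_polygon`.
#' @export
region_polygon <- function(vertices, name = "") {
  vertices <- as.matrix(vertices)
  if (nrow(vertices) < 3L || ncol(vertices) != 2L)
    stop("a region polygon needs at least 3 (x, y) vertices")
  structure(list(vertices = vertices, name = name), class = "region_polygon")
}

# rectangle -> region_polygon (counter-clockwise, half-open convention kept
# by using the inclusive corner coordinates of the covered pixel area)
rect_polygon <- function(r, name = "") {
  x <- r[["x"]]; y <- r[["y"]]; w <- r[["w"]]; h <- r[["h"]]
  region_polygon(rbind(c(x, y), c(x + w, y), c(x + w, y + h), c(x, y + h)),
                 name = name)
}

#' Point-in-polygon test by ray casting
#'
#' Casts a horizontal ray from the point and counts edge crossings.
#' Points lying exactly on a polygon edge count as inside.
#'
#' @param p numeric `(x, y)` point.
#' @param poly a [region_polygon()].
#' @return logical.
#' @export
point_in_polygon <- function(p, poly) {
  as.logical(points_in_polygon(matrix(p[1:2], ncol = 2), poly))
}

# vectorized ray casting over an n x 2 matrix of points; edge-inclusive
points_in_polygon <- function(pts, poly) {
  v <- poly$vertices
  n <- nrow(v)
  px <- pts[, 1]; py <- pts[, 2]
  inside <- logical(length(px))
  onedge <- logical(length(px))
  eps <- 1e-9
  j <- n
  for (i in seq_len(n)) {
    x1 <- v[j, 1]; y1 <- v[j, 2]; x2 <- v[i, 1]; y2 <- v[i, 2]
    # on-segment test: zero cross product and within the bounding box
    cross <- (px - x1) * (y2 - y1) - (py - y1) * (x2 - x1)
    seg_len2 <- (x2 - x1)^2 + (y2 - y1)^2
    on <- abs(cross) <= eps * max(1, sqrt(seg_len2)) &
      px >= pmin(x1, x2) - eps & px <= pmax(x1, x2) + eps &
      py >= pmin(y1, y2) - eps & py <= pmax(y1, y2) + eps
    onedge <- onedge | on
    crosses <- ((y1 > py) != (y2 > py))
    if (any(crosses)) {
      xint <- x1 + (py - y1) * (x2 - x1) / (y2 - y1)
      inside <- xor(inside, crosses & (px < xint))
    }
    j <- i
  }
  inside | onedge
}

# 0/1 raster of a polygon over a width x height pixel grid (pixel centers at
# integer coordinates); cached by callers that mask every frame of a view
polygon_mask <- function(poly, width, height) {
  pts <- cbind(rep(0:(width - 1L), each = height), rep(0:(height - 1L), width))
  matrix(as.integer(points_in_polygon(pts, poly)), height, width)
}

#' Mask motion features outside a region of interest
#'
#' Deletes all movement pixels external to the useful-information polygon
#' of the view and recomputes the feature count. Idempotent.
#'
#' @param m a `motion_image`.
#' @param poly a [region_polygon()], or a precomputed 0/1 mask matrix of
#'   the frame size (from repeated per-frame use).
#' @return masked `motion_image`.
#' @export
mask_outside_region <- function(m, poly) {
  stopifnot(inherits(m, "motion_image"))
  if (is.matrix(poly)) {
    mask <- poly
  } else {
    if (nrow(poly$vertices) < 3L) stop("degenerate polygon")
    mask <- polygon_mask(poly, ncol(m$features), nrow(m$features))
  }
  motion_image(m$features * mask)
}

#' Counting-box localization of the most relevant movement cluster
#'
#' Slides a `box_w x box_h` window (stride 1) over the search region and
#' returns the placement containing the most motion features. Ties are
#' broken by the smallest box origin, `y` first then `x`. The cluster's
#' mass center is the centroid of the features inside the winning box.
#'
#' @param m a `motion_image`.
#' @param search half-open search rectangle `c(x, y, w, h)`; `NULL` for the
#'   whole frame.
#' @param box_w,box_h counting-box dimensions in pixels.
#' @param relevance_thr feature count at or above which the cluster is
#'   marked relevant.
#' @return object of class `movement_cluster` (fields `box`, `mass_center`,
#'   `feature_count`, `relevant`) or `NULL` when the search region contains
#'   no features or is empty.
#' @export
counting_box_cluster <- function(m, search = NULL, box_w, box_h,
                                 relevance_thr = 1L) {
  stopifnot(inherits(m, "motion_image"))
  f <- m$features
  h <- nrow(f); w <- ncol(f)
  if (is.null(search)) search <- rect(0, 0, w, h)
  search <- rect_intersect(search, rect(0, 0, w, h))
  if (is.null(search)) return(NULL)
  sx <- as.integer(search[["x"]]); sy <- as.integer(search[["y"]])
  sw <- as.integer(search[["w"]]); sh <- as.integer(search[["h"]])
  bw <- min(as.integer(box_w), sw); bh <- min(as.integer(box_h), sh)
  sub <- f[(sy + 1L):(sy + sh), (sx + 1L):(sx + sw), drop = FALSE]
  if (sum(sub) == 0L) return(NULL)
  # summed-area table; window sum for origin (ox, oy) via inclusion-exclusion
  cs <- matrix(sub, sh, sw)
  if (sh > 1L) cs <- apply(cs, 2L, cumsum)
  cs <- matrix(cs, sh, sw)
  if (sw > 1L) cs <- t(apply(cs, 1L, cumsum))
  cs <- matrix(cs, sh, sw)
  pad <- matrix(0, sh + 1L, sw + 1L)
  pad[2:(sh + 1L), 2:(sw + 1L)] <- cs
  ny <- sh - bh + 1L; nx <- sw - bw + 1L
  sums <- pad[(bh + 1L):(sh + 1L), (bw + 1L):(sw + 1L), drop = FALSE] -
    pad[1:ny, (bw + 1L):(sw + 1L), drop = FALSE] -
    pad[(bh + 1L):(sh + 1L), 1:nx, drop = FALSE] +
    pad[1:ny, 1:nx, drop = FALSE]
  best <- max(sums)
  idx <- which(sums == best, arr.ind = TRUE)
  # ties: smallest y, then smallest x, of the box origin
  pick <- idx[order(idx[, 1], idx[, 2])[1], ]
  oy <- sy + unname(pick[1]) - 1L; ox <- sx + unname(pick[2]) - 1L
  inbox <- f[(oy + 1L):(oy + bh), (ox + 1L):(ox + bw), drop = FALSE]
  nz <- which(inbox != 0, arr.ind = TRUE)
  mc <- c(x = ox + mean(nz[, 2]) - 1, y = oy + mean(nz[, 1]) - 1)
  structure(list(box = rect(ox, oy, bw, bh),
                 mass_center = mc,
                 feature_count = as.integer(best),
                 relevant = best >= relevance_thr),
            class = "movement_cluster")
}

#' @export
print.movement_cluster <- function(x, ...) {
  cat(sprintf("<movement_cluster box=(%d,%d,%d,%d) mc=(%.1f,%.1f) n=%d%s>\n",
              x$box[["x"]], x$box[["y"]], x$box[["w"]], x$box[["h"]],
              x$mass_center[["x"]], x$mass_center[["y"]], x$feature_count,
              if (x$relevant) " relevant" else ""))
  invisible(x)
}
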
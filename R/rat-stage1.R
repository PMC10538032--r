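#' Rat head-pose analysis, stage 1 (top view)
#'
#' In the first stage of the experiment the rat is confined to the middle
#' room of a three-chamber box viewed from above. Scene geometry is
#' recomputed for every frame because the operator may nudge the camera:
#' the binary image projected on the vertical axis must show five dark
#' column clusters (box end walls, the two middle-room walls, and the rat
#' itself); the middle-room walls `b1`, `b2` are the midpoints of the
#' second and fourth cluster. Frames failing the five-cluster test are
#' skipped.
#'
#' @name rat_stage1
NULL

# Otsu threshold (0..255) of a grayscale matrix
otsu_threshold <- function(frame) {
  h <- tabulate(pmin(pmax(floor(frame), 0), 255) + 1L, nbins = 256L)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * (0:255))
  mu_t <- mu[256]
  denom <- omega * (1 - omega)
  denom[denom < 1e-12] <- NA
  sigma_b <- (mu_t * omega - mu)^2 / denom
  if (!any(is.finite(sigma_b))) return(0L)  # constant image
  which.max(sigma_b) - 1L
}

default_walls_opts <- function() {
  list(min_col_frac = 0.05,  # column is "in a cluster" when its dark count
                             # exceeds this fraction of the frame height
                             # (the rat body must register, not just walls)
       min_width = 2, max_width = 90,
       wall_max_width = 40,  # clusters 2 and 4 must be thin (walls)
       min_gap = 8,
       gap_merge = 2,        # projection runs this close are one cluster
       thr_range = c(40, 160), thr_step = 10)
}

#' Detect the stage-1 scene walls from one frame
#'
#' Binarizes the frame with an adaptively chosen threshold (Otsu first,
#' then a sweep over `thr_range`) until the column projection of the dark
#' pixels segments into exactly five clusters satisfying the proximity
#' conditions (width and spacing bounds; thin second and fourth clusters).
#'
#' @param frame grayscale frame matrix.
#' @param opts options list, see `default_walls_opts` values in the source;
#'   entries override the defaults.
#' @return list with `cluster_bounds` (5 x 2 matrix of 0-based start/end
#'   column indices), `b1`, `b2` (middle-room wall columns) and `bin_thr`,
#'   or `NULL` when no threshold yields an acceptable segmentation (the
#'   caller then analyzes the next frame).
#' @export
compute_scene_walls <- function(frame, opts = list()) {
  o <- utils::modifyList(default_walls_opts(), opts)
  thrs <- unique(c(otsu_threshold(frame),
                   seq(o$thr_range[1], o$thr_range[2], by = o$thr_step)))
  for (thr in thrs) {
    res <- walls_at_threshold(frame, thr, o)
    if (!is.null(res)) return(res)
  }
  NULL
}

walls_at_threshold <- function(frame, thr, o) {
  dark <- frame < thr
  proj <- colSums(dark)
  active <- proj > o$min_col_frac * nrow(frame)
  runs <- merge_close_runs(logical_runs(active), o$gap_merge)
  if (nrow(runs) != 5L) return(NULL)
  widths <- runs[, 2] - runs[, 1] + 1L
  gaps <- runs[-1, 1] - runs[-5, 2] - 1L
  if (any(widths < o$min_width) || any(widths > o$max_width)) return(NULL)
  if (any(widths[c(2, 4)] > o$wall_max_width)) return(NULL)
  if (any(gaps < o$min_gap)) return(NULL)
  b1 <- unname((runs[2, 1] + runs[2, 2]) / 2)
  b2 <- unname((runs[4, 1] + runs[4, 2]) / 2)
  list(cluster_bounds = runs - 1L,  # 0-based columns
       b1 = b1 - 1, b2 = b2 - 1, bin_thr = thr)
}

# start/end (1-based) of TRUE runs in a logical vector
logical_runs <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

# fuse runs separated by gaps of at most `max_gap` columns
merge_close_runs <- function(runs, max_gap) {
  if (nrow(runs) < 2L) return(runs)
  out <- runs[1, , drop = FALSE]
  for (i in 2:nrow(runs)) {
    if (runs[i, 1] - out[nrow(out), 2] - 1L <= max_gap)
      out[nrow(out), 2] <- runs[i, 2]
    else out <- rbind(out, runs[i, , drop = FALSE])
  }
  out
}

#' Detect the rat body blob in the middle room
#'
#' Restricts the frame to the columns strictly between the inner edges of
#' the two middle-room wall clusters, binarizes (dark target on bright
#' floor), erodes with a 3x3 element, and keeps the largest connected
#' component.
#'
#' @param frame grayscale frame matrix.
#' @param walls result of [compute_scene_walls()].
#' @param min_area smallest acceptable component area, pixels.
#' @param square_tol `c(lo, hi)` band of the width/height ratio classified
#'   as a square body frame.
#' @param erosion_size square element side for the body erosion; large
#'   enough that the thin tail never joins the body component.
#' @return list (`body_box`) with `box` (full-frame coordinates), `aspect`
#'   (`"horizontal"`, `"vertical"` or `"square"`), `mass_center`, `mask`
#'   (logical matrix of the box region), `bin_thr` and `region_x0` (column
#'   offset of the analyzed region), or `NULL` when no component reaches
#'   `min_area`.
#' @export
detect_rat_blob <- function(frame, walls, min_area = 30,
                            square_tol = c(0.8, 1.25),
                            erosion_size = 5L) {
  cb <- walls$cluster_bounds
  x0 <- unname(cb[2, 2]) + 1L  # first column right of the left wall cluster
  x1 <- unname(cb[4, 1]) - 1L  # last column left of the right wall cluster
  if (x1 - x0 < 3L) return(NULL)
  sub <- frame[, (x0 + 1L):(x1 + 1L), drop = FALSE]
  thr <- otsu_threshold(sub)
  bin <- matrix(as.integer(sub <= thr), nrow(sub), ncol(sub))
  er <- binary_box_erode(bin, erosion_size)
  if (sum(er) == 0L) return(NULL)
  lab <- EBImage::bwlabel(er)
  sizes <- tabulate(lab[lab > 0])
  k <- which.max(sizes)
  if (sizes[k] < min_area) return(NULL)
  # reconstruct the eroded body to its full extent (conditional dilation
  # into the binary image); the thin tail stays disconnected
  comp <- matrix(as.integer(lab == k), nrow(er), ncol(er))
  rec <- binary_box_dilate(comp, erosion_size) * bin
  px <- which(rec == 1L, arr.ind = TRUE)
  ys <- range(px[, 1]); xs <- range(px[, 2])
  w <- xs[2] - xs[1] + 1L; h <- ys[2] - ys[1] + 1L
  ratio <- w / h
  aspect <- if (ratio > square_tol[2]) "horizontal"
            else if (ratio < square_tol[1]) "vertical"
            else "square"
  mask <- matrix(FALSE, h, w)
  mask[cbind(px[, 1] - ys[1] + 1L, px[, 2] - xs[1] + 1L)] <- TRUE
  list(box = rect(x0 + xs[1] - 1L, ys[1] - 1L, w, h),
       aspect = aspect,
       mass_center = c(x = x0 + mean(px[, 2]) - 1, y = mean(px[, 1]) - 1),
       mask = mask, bin_thr = thr, region_x0 = x0)
}

head_decision <- function(frame_index, candidates, status, sides = NA) {
  structure(list(frame_index = frame_index,
                 candidates = candidates, status = status, sides = sides),
            class = "head_decision")
}

default_head_opts <- function() {
  list(fraction = 1 / 3,       # flank strip width as a fraction of the box
       ratio_thr = 0.8,        # "significantly fewer": smaller/larger < thr
       tail_strip_frac = 0.25, # width of the outside tail-scan strips
       tail_gap = 3,           # gap between the body box and the strips
       tail_min = 4,           # dark pixels needed to call a tail
       min_move = 1.5)         # displacement treated as real motion, px
}

#' Locate the rat head for one frame
#'
#' For elongated (horizontal/vertical) bodies two votes are combined:
#' vote 1 compares body-pixel counts of the two end flanks (the head end
#' has significantly fewer); vote 2 scans thin strips just outside the two
#' body-box ends for the tail (a concentration of dark pixels around the
#' box midline) and places the head opposite. Rules: (a) agreement gives a
#' certain decision; (b) if only one vote is reliable, it decides; (c) two
#' strong contradictory votes: the tail vote wins; (d) otherwise the
#' decision is deferred. When the two previous head positions agree on a
#' direction, that direction decides directly. Near-square bodies
#' (turn-arounds, wall contact) are decided from the movement direction of
#' the previous head positions, or yield the two most plausible candidates.
#'
#' @param frame grayscale frame matrix.
#' @param body result of [detect_rat_blob()].
#' @param prev list of the last (up to 2) certain `head_decision`s,
#'   most recent first; or `NULL`.
#' @param frame_index index recorded in the decision.
#' @param opts options list overriding `default_head_opts` values.
#' @return `head_decision`: `status` is `"certain"` (1 candidate),
#'   `"ambiguous"` (2 candidates) or `"deferred"` (0).
#' @export
locate_head <- function(frame, body, prev = NULL, frame_index = 0L,
                        opts = list()) {
  o <- utils::modifyList(default_head_opts(), opts)
  bx <- body$box
  if (body$aspect == "square")
    return(head_square_case(frame, body, prev, frame_index, o))

  horiz <- body$aspect == "horizontal"
  ends <- if (horiz) c("left", "right") else c("up", "down")

  # vote 1: flank body-pixel counts
  cnt <- flank_counts(body$mask, horiz, o$fraction)
  v1 <- if (min(cnt) / max(max(cnt), 1) < o$ratio_thr)
    ends[which.min(cnt)] else NA_character_

  # vote 2: tail strips outside the box ends
  tail_side <- detect_tail_side(frame, body, horiz, o)
  v2 <- if (!is.na(tail_side)) opposite_side(tail_side) else NA_character_

  # previous two certain directions override the voting
  pd <- prev_direction_side(prev, body, horiz)
  side <- NA_character_
  if (!is.na(pd)) {
    side <- pd
  } else if (!is.na(v1) && !is.na(v2)) {
    side <- v2   # agreement: same value; contradiction: tail vote validated
  } else if (!is.na(v1)) {
    side <- v1
  } else if (!is.na(v2)) {
    side <- v2
  }
  if (is.na(side))
    return(head_decision(frame_index, matrix(numeric(0), 0, 2), "deferred"))
  head_decision(frame_index,
                matrix(flank_center(body, side, o$fraction), 1, 2),
                "certain", sides = side)
}

flank_counts <- function(mask, horiz, fraction) {
  if (horiz) {
    fw <- max(1L, round(fraction * ncol(mask)))
    c(sum(mask[, seq_len(fw)]), sum(mask[, (ncol(mask) - fw + 1L):ncol(mask)]))
  } else {
    fh <- max(1L, round(fraction * nrow(mask)))
    c(sum(mask[seq_len(fh), ]), sum(mask[(nrow(mask) - fh + 1L):nrow(mask), ]))
  }
}

opposite_side <- function(s) {
  switch(s, left = "right", right = "left", up = "down", down = "up")
}

# mass center of the body pixels in the head-side flank, full-frame coords
flank_center <- function(body, side, fraction) {
  m <- body$mask
  bx <- body$box
  if (side %in% c("left", "right")) {
    fw <- max(1L, round(fraction * ncol(m)))
    cols <- if (side == "left") seq_len(fw) else (ncol(m) - fw + 1L):ncol(m)
    px <- which(m[, cols, drop = FALSE], arr.ind = TRUE)
    if (nrow(px) == 0L) return(rect_center(bx))
    c(bx[["x"]] + (cols[1] - 1L) + mean(px[, 2]) - 1,
      bx[["y"]] + mean(px[, 1]) - 1)
  } else {
    fh <- max(1L, round(fraction * nrow(m)))
    rows <- if (side == "up") seq_len(fh) else (nrow(m) - fh + 1L):nrow(m)
    px <- which(m[rows, , drop = FALSE], arr.ind = TRUE)
    if (nrow(px) == 0L) return(rect_center(bx))
    c(bx[["x"]] + mean(px[, 2]) - 1,
      bx[["y"]] + (rows[1] - 1L) + mean(px[, 1]) - 1)
  }
}

# scan the tiny strips outside the two box ends for the tail: dark pixels
# concentrated around the box midline; returns "left"/"right"/"up"/"down"
# (side of the TAIL) or NA
detect_tail_side <- function(frame, body, horiz, o) {
  bx <- body$box
  thr <- body$bin_thr
  h <- nrow(frame); w <- ncol(frame)
  strip_count <- function(r) {
    r <- rect_intersect(r, rect(0, 0, w, h))
    if (is.null(r)) return(0L)
    sub <- frame[(r[["y"]] + 1L):(r[["y"]] + r[["h"]]),
                 (r[["x"]] + 1L):(r[["x"]] + r[["w"]]), drop = FALSE]
    # middle third of the strip (across the body axis) holds the tail
    n <- if (horiz) nrow(sub) else ncol(sub)
    third <- max(1L, floor(n / 3))
    mid <- (third + 1L):(n - third)
    if (length(mid) == 0L) mid <- seq_len(n)
    if (horiz) sum(sub[mid, , drop = FALSE] <= thr)
    else sum(sub[, mid, drop = FALSE] <= thr)
  }
  g <- o$tail_gap
  if (horiz) {
    tw <- max(2L, round(o$tail_strip_frac * bx[["w"]]))
    cl <- strip_count(rect(bx[["x"]] - g - tw, bx[["y"]], tw, bx[["h"]]))
    cr <- strip_count(rect(bx[["x"]] + bx[["w"]] + g, bx[["y"]], tw,
                           bx[["h"]]))
    if (max(cl, cr) < o$tail_min || cl == cr) return(NA_character_)
    if (cl > cr) "left" else "right"
  } else {
    th <- max(2L, round(o$tail_strip_frac * bx[["h"]]))
    cu <- strip_count(rect(bx[["x"]], bx[["y"]] - g - th, bx[["w"]], th))
    cd <- strip_count(rect(bx[["x"]], bx[["y"]] + bx[["h"]] + g, bx[["w"]],
                           th))
    if (max(cu, cd) < o$tail_min || cu == cd) return(NA_character_)
    if (cu > cd) "up" else "down"
  }
}

# side indicated by the last two certain head positions, or NA
prev_direction_side <- function(prev, body, horiz) {
  if (is.null(prev) || length(prev) < 2L) return(NA_character_)
  ok <- vapply(prev[1:2], function(d) !is.null(d) && d$status == "certain",
               logical(1))
  if (!all(ok)) return(NA_character_)
  ctr <- rect_center(body$box)
  ax <- if (horiz) 1L else 2L
  s1 <- sign(prev[[1]]$candidates[1, ax] - ctr[ax])
  s2 <- sign(prev[[2]]$candidates[1, ax] - ctr[ax])
  if (s1 == 0 || s1 != s2) return(NA_character_)
  if (horiz) { if (s1 < 0) "left" else "right" }
  else { if (s1 < 0) "up" else "down" }
}

head_square_case <- function(frame, body, prev, frame_index, o) {
  ctr <- rect_center(body$box)
  cand_for <- function(side) flank_center(body, side, o$fraction)
  if (!is.null(prev) && length(prev) >= 2L &&
      prev[[1]]$status == "certain" && prev[[2]]$status == "certain") {
    p1 <- prev[[1]]$candidates[1, ]; p2 <- prev[[2]]$candidates[1, ]
    dir <- p1 - p2
    if (sqrt(sum(dir^2)) >= o$min_move) {
      # continue along the movement direction: flank best aligned with it
      sides <- c("left", "right", "up", "down")
      scores <- vapply(sides, function(s) {
        v <- cand_for(s) - ctr
        sum(v * dir)
      }, numeric(1))
      best <- order(scores, decreasing = TRUE)
      return(head_decision(frame_index,
                           matrix(cand_for(sides[best[1]]), 1, 2),
                           "certain", sides = sides[best[1]]))
    }
    # stationary: keep the previous head side relative to the body center
    v <- p1 - ctr
    side <- if (abs(v[1]) >= abs(v[2])) {
      if (v[1] < 0) "left" else "right"
    } else {
      if (v[2] < 0) "up" else "down"
    }
    return(head_decision(frame_index, matrix(cand_for(side), 1, 2),
                         "certain", sides = side))
  }
  # no usable history: emit the two most plausible candidates; the tail
  # vote, when available, orients the pair axis
  tail_side <- detect_tail_side(frame, body, horiz = TRUE, o)
  if (is.na(tail_side)) tail_side <- detect_tail_side(frame, body, FALSE, o)
  if (!is.na(tail_side)) {
    head_side <- opposite_side(tail_side)
    other <- if (head_side %in% c("left", "right")) c("up", "down")
             else c("left", "right")
    cands <- rbind(cand_for(head_side), cand_for(other[1]))
    return(head_decision(frame_index, cands, "ambiguous",
                         sides = c(head_side, other[1])))
  }
  cands <- rbind(cand_for("left"), cand_for("right"))
  head_decision(frame_index, cands, "ambiguous", sides = c("left", "right"))
}

#' Offline resolution of the head-decision list
#'
#' After the whole session is processed, uncertain cases are solved:
#' each ambiguous frame (two candidate positions) takes the candidate
#' closest to the position of the next frame with a reliable (single
#' solution) localization; deferred frames are interpolated from the
#' neighboring resolved frames.
#'
#' @param decisions list of `head_decision` objects in frame order.
#' @return data.frame with `frame_index`, `x`, `y` for every input frame.
#' @export
resolve_trajectory <- function(decisions) {
  n <- length(decisions)
  status <- vapply(decisions, `[[`, character(1), "status")
  if (!any(status == "certain")) stop("unresolved session: no certain frame")
  pos <- matrix(NA_real_, n, 2)
  for (i in seq_len(n)) if (status[i] == "certain")
    pos[i, ] <- decisions[[i]]$candidates[1, ]
  # right-to-left: ambiguous frames anchor on the next reliable position
  anchor <- NULL
  for (i in rev(seq_len(n))) {
    if (!is.na(pos[i, 1])) { anchor <- pos[i, ]; next }
    if (status[i] == "ambiguous" && !is.null(anchor)) {
      cands <- decisions[[i]]$candidates
      d2 <- rowSums(sweep(cands, 2, anchor)^2)
      pos[i, ] <- cands[which.min(d2), ]
      anchor <- pos[i, ]
    }
  }
  # left-to-right for trailing ambiguous frames (no certain frame after)
  anchor <- NULL
  for (i in seq_len(n)) {
    if (!is.na(pos[i, 1])) { anchor <- pos[i, ]; next }
    if (status[i] == "ambiguous" && !is.null(anchor)) {
      cands <- decisions[[i]]$candidates
      d2 <- rowSums(sweep(cands, 2, anchor)^2)
      pos[i, ] <- cands[which.min(d2), ]
      anchor <- pos[i, ]
    }
  }
  # deferred frames: interpolate between neighboring resolved frames
  filled <- which(!is.na(pos[, 1]))
  for (i in which(is.na(pos[, 1]))) {
    before <- filled[filled < i]
    after <- filled[filled > i]
    if (length(before) && length(after)) {
      b <- max(before); a <- min(after)
      t <- (i - b) / (a - b)
      pos[i, ] <- (1 - t) * pos[b, ] + t * pos[a, ]
    } else if (length(before)) {
      pos[i, ] <- pos[max(before), ]
    } else {
      pos[i, ] <- pos[min(after), ]
    }
  }
  data.frame(frame_index = vapply(decisions, `[[`, numeric(1), "frame_index"),
             x = pos[, 1], y = pos[, 2])
}

#' Run the stage-1 head-pose pipeline over a frame list
#'
#' @param frames list of grayscale frame matrices.
#' @param walls_opts,head_opts option lists for [compute_scene_walls()] and
#'   [locate_head()].
#' @param min_area,square_tol forwarded to [detect_rat_blob()].
#' @return list with `decisions` (per analyzed frame), `track` (resolved
#'   data.frame from [resolve_trajectory()]), `body_centers` and
#'   `skipped` (frame indices failing the scene test).
#' @export
track_rat_head <- function(frames, walls_opts = list(), head_opts = list(),
                           min_area = 30, square_tol = c(0.8, 1.25)) {
  decisions <- list()
  centers <- list()
  skipped <- integer(0)
  certain_hist <- list()
  for (i in seq_along(frames)) {
    fi <- i - 1L
    walls <- compute_scene_walls(frames[[i]], walls_opts)
    if (is.null(walls)) { skipped <- c(skipped, fi); next }
    body <- detect_rat_blob(frames[[i]], walls, min_area, square_tol)
    if (is.null(body)) { skipped <- c(skipped, fi); next }
    dec <- locate_head(frames[[i]], body, prev = certain_hist,
                       frame_index = fi, opts = head_opts)
    decisions[[length(decisions) + 1L]] <- dec
    centers[[length(centers) + 1L]] <-
      c(frame_index = fi, body$mass_center)
    if (dec$status == "certain")
      certain_hist <- c(list(dec), certain_hist)[1:min(2, length(certain_hist) + 1L)]
  }
  track <- if (length(decisions)) resolve_trajectory(decisions) else
    data.frame(frame_index = integer(0), x = numeric(0), y = numeric(0))
  list(decisions = decisions, track = track,
       body_centers = do.call(rbind, centers), skipped = skipped)
}
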
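#' Head orientation from the sensor-box profile
#'
#' The sensor array is dark, right-angled, and rigidly mounted, so the
#' head orientation is the direction of the long side of the box profile.
#' The localized region of interest is inflated by half its size in every
#' direction, converted to HSV, and the value channel is Gaussian
#' smoothed and binarized with a brightness-dependent threshold in
#' `[30, 60]`. Among the dark contours with significant area, the one
#' with the largest filling index (contour area over minimum bounding
#' rectangle area) is the box; its long-side direction, in `[0, 180)`
#' degrees, is the orientation.
#'
#' @param frame grayscale matrix or `h x w x 3` RGB array in `[0, 255]`.
#' @param center `(x, y)` accepted localization.
#' @param roi_w,roi_h primary region-of-interest size before inflation.
#' @param area_min contour area below or at which contours are ignored
#'   (pixels).
#' @param thr_range binarization threshold band; the actual threshold is
#'   a linear map of the mean ROI brightness into this band.
#' @param sigma Gaussian smoothing of the value channel.
#' @return list with `angle_deg` in `[0, 180)`, `filling_index`, `area`;
#'   or `NULL` when no contour qualifies.
#' @export
compute_orientation <- function(frame, center, roi_w = 48, roi_h = 36,
                                area_min = 500, thr_range = c(30, 60),
                                sigma = 1) {
  v <- hsv_value_channel(frame)
  # inflate the ROI by half its measures in every direction
  W <- round(roi_w * 2); H <- round(roi_h * 2)
  x0 <- clamp(round(center[[1]]) - W %/% 2L, 0L, max(0L, ncol(v) - W))
  y0 <- clamp(round(center[[2]]) - H %/% 2L, 0L, max(0L, nrow(v) - H))
  W <- min(W, ncol(v)); H <- min(H, nrow(v))
  roi <- v[(y0 + 1L):(y0 + H), (x0 + 1L):(x0 + W), drop = FALSE]
  roi <- EBImage::gblur(roi, sigma = sigma)
  thr <- thr_range[1] + (thr_range[2] - thr_range[1]) *
    clamp(mean(roi) / 255, 0, 1)
  bin <- matrix(as.integer(roi < thr), nrow(roi), ncol(roi))
  if (sum(bin) == 0L) return(NULL)
  lab <- EBImage::bwlabel(bin)
  sizes <- tabulate(lab[lab > 0])
  cand <- which(sizes > area_min)
  if (length(cand) == 0L) return(NULL)
  best <- NULL
  for (k in cand) {
    px <- which(lab == k, arr.ind = TRUE)
    pts <- cbind(px[, 2] - 1L, px[, 1] - 1L)   # (x, y), 0-based
    mar <- min_area_rect(pts)
    fill <- sizes[k] / mar$area
    if (is.null(best) || fill > best$filling_index)
      best <- list(angle_deg = mar$angle_deg, filling_index = fill,
                   area = sizes[k])
  }
  best
}

# HSV value channel of a frame: max over RGB channels; gray input is its
# own value channel
hsv_value_channel <- function(frame) {
  if (is.matrix(frame)) return(frame)
  if (is.array(frame) && length(dim(frame)) == 3L && dim(frame)[3] == 3L)
    return(pmax(frame[, , 1], frame[, , 2], frame[, , 3]))
  stop("frame must be a gray matrix or an RGB array")
}

#' 1-D average filter for the orientation series
#'
#' Each angle is replaced by the mean of the valid angles in a temporal
#' window of size `t` centered on it; frames where the orientation could
#' not be calculated, or whose confidence is below `conf_thr`, are
#' excluded from the means. Missing angles are estimated the same way and
#' flagged `filled`. Because orientations wrap modulo 180 degrees, window
#' members are first unwrapped about their median before averaging.
#'
#' @param series data.frame with columns `frame_index`, `angle_deg`
#'   (`NA` when not calculated), `confidence`; an optional `filled`
#'   column is reset.
#' @param t odd window size, frames.
#' @param conf_thr confidence threshold (percent) for a sample to enter
#'   the means.
#' @return the series with smoothed/estimated `angle_deg` and a logical
#'   `filled` column (TRUE where the angle was estimated, including
#'   frames whose window had no valid member and stay `NA`... those stay
#'   `filled = FALSE`).
#' @export
filter_angles <- function(series, t = 11L, conf_thr = 75) {
  stopifnot(t %% 2L == 1L)
  n <- nrow(series)
  half <- (t - 1L) %/% 2L
  valid <- !is.na(series$angle_deg) & series$confidence >= conf_thr
  out_angle <- rep(NA_real_, n)
  filled <- rep(FALSE, n)
  for (i in seq_len(n)) {
    win <- max(1L, i - half):min(n, i + half)
    vw <- win[valid[win]]
    if (length(vw) == 0L) next
    a <- series$angle_deg[vw]
    med <- stats::median(a)
    a <- a + 180 * round((med - a) / 180)   # unwrap about the median
    out_angle[i] <- mean(a) %% 180
    if (is.na(series$angle_deg[i])) filled[i] <- TRUE
  }
  series$angle_deg <- out_angle
  series$filled <- filled
  series
}
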
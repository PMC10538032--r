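#' Rat compartment-visit analysis, stage 2 (side view)
#'
#' After the gates open, the rat roams the whole three-compartment box,
#' now viewed from the side. Per frame, the scene parameters
#' `0 < c11 < c12 < b1 < b2 < c21 < c22` (left cage edges, middle-room
#' walls, right cage edges, as column indices) are recomputed; frames
#' violating the ordering are skipped. The moving rat is localized with
#' the motion-feature counting box, and the trajectory is analyzed offline
#' for per-compartment entry counts and visit durations.
#'
#' @name rat_stage2
NULL

default_cage_opts <- function() {
  list(min_col_frac = 0.5, thr_range = c(40, 160), thr_step = 10,
       min_width = 2)
}

#' Compute the stage-2 cage parameters from one frame
#'
#' Binarizes with an adaptively chosen threshold so that the column
#' projection of the dark pixels detects the two cages at the box sides;
#' `b1` and `b2` come from the projection clusters strictly inside
#' `(c12, c21)`. Parameters are recomputed for each frame because the
#' operator may slightly change the viewing angle.
#'
#' @param frame grayscale frame matrix.
#' @param opts options overriding the defaults in the source.
#' @return list with `c11`, `c12`, `b1`, `b2`, `c21`, `c22` (0-based
#'   columns) and `bin_thr`, or `NULL` when the ordering condition fails.
#' @export
compute_cage_params <- function(frame, opts = list()) {
  o <- utils::modifyList(default_cage_opts(), opts)
  thrs <- unique(c(otsu_threshold(frame),
                   seq(o$thr_range[1], o$thr_range[2], by = o$thr_step)))
  for (thr in thrs) {
    res <- cage_params_at_threshold(frame, thr, o)
    if (!is.null(res)) return(res)
  }
  NULL
}

cage_params_at_threshold <- function(frame, thr, o) {
  dark <- frame < thr
  proj <- colSums(dark)
  active <- proj > o$min_col_frac * nrow(frame)
  runs <- logical_runs(active)
  if (nrow(runs) < 2L) return(NULL)
  widths <- runs[, 2] - runs[, 1] + 1L
  if (any(widths[c(1, nrow(runs))] < o$min_width)) return(NULL)
  c11 <- unname(runs[1, 1]) - 1L; c12 <- unname(runs[1, 2]) - 1L
  c21 <- unname(runs[nrow(runs), 1]) - 1L
  c22 <- unname(runs[nrow(runs), 2]) - 1L
  if (!(0 < c11 && c11 < c12 && c12 < c21 && c21 < c22)) return(NULL)
  # middle-room walls: projection clusters strictly inside (c12, c21)
  interior <- runs[runs[, 1] - 1L > c12 & runs[, 2] - 1L < c21, , drop = FALSE]
  if (nrow(interior) != 2L) return(NULL)
  b1 <- unname((interior[1, 1] + interior[1, 2]) / 2) - 1
  b2 <- unname((interior[2, 1] + interior[2, 2]) / 2) - 1
  if (!(c12 < b1 && b1 < b2 && b2 < c21)) return(NULL)
  list(c11 = c11, c12 = c12, b1 = b1, b2 = b2, c21 = c21, c22 = c22,
       bin_thr = thr)
}

#' Track the free rat through the whole box (stage 2)
#'
#' For every frame from the third on, recomputes the cage parameters
#' (skipping frames where they cannot be validated), builds the motion
#' image from the frame triple, and localizes the main movement cluster
#' with the counting box inside the box columns. Frames without a relevant
#' cluster (freezing) keep the last known position.
#'
#' @param frames list of grayscale frame matrices.
#' @param box_w,box_h counting-box dimensions, pixels.
#' @param relevance_thr minimum feature count for a cluster to move the
#'   position estimate.
#' @param motion_opts list with optional `erosion_size`, `dilation_size`,
#'   `threshold` for [compute_motion_image()].
#' @param cage_opts options for [compute_cage_params()].
#' @return list with `track` (data.frame `frame_index`, `x`, `y`) and
#'   `params` (the last accepted cage parameters).
#' @export
track_rat_position <- function(frames, box_w = 48, box_h = 32,
                               relevance_thr = 20,
                               motion_opts = list(), cage_opts = list()) {
  mo <- utils::modifyList(list(erosion_size = 3L, dilation_size = 5L,
                               threshold = 15), motion_opts)
  params <- NULL
  last_pos <- NULL
  out <- vector("list", length(frames))
  for (i in seq_along(frames)) {
    p <- compute_cage_params(frames[[i]], cage_opts)
    if (!is.null(p)) params <- p
    if (i < 3L || is.null(params)) next
    m <- compute_motion_image(frames[[i]], frames[[i - 1L]], frames[[i - 2L]],
                              mo$erosion_size, mo$dilation_size, mo$threshold)
    search <- rect(params$c11, 0, params$c22 - params$c11 + 1L,
                   nrow(frames[[i]]))
    cl <- counting_box_cluster(m, search, box_w, box_h, relevance_thr)
    if (!is.null(cl) && cl$relevant) last_pos <- cl$mass_center
    if (!is.null(last_pos))
      out[[i]] <- c(frame_index = i - 1L, x = last_pos[[1]], y = last_pos[[2]])
  }
  track <- as.data.frame(do.call(rbind, out[!vapply(out, is.null, logical(1))]))
  if (nrow(track) == 0L)
    track <- data.frame(frame_index = integer(0), x = numeric(0),
                        y = numeric(0))
  list(track = track, params = params)
}

#' Compartment visits and entry counts from a stage-2 trajectory
#'
#' The compartment of a position uses the mass-center `x` only:
#' `x < b1` is the left cage, `x > b2` the right cage, otherwise the
#' middle room. Compartment changes shorter than `debounce` frames are
#' treated as boundary flicker and folded into the preceding visit. An
#' entry is a sustained change of compartment; the compartment the track
#' starts in is counted as a visit but not as an entry.
#'
#' @param track data.frame with `frame_index` and `x` (from
#'   [track_rat_position()]).
#' @param params cage parameters with `b1`, `b2`.
#' @param fps frames per second of the recording.
#' @param debounce minimum frames a compartment change must persist.
#' @return list with `visits` (data.frame `compartment`, `start_frame`,
#'   `end_frame`, `start_s`, `end_s`, `duration_s`) and `entries` (named
#'   integer vector for `left_cage`, `middle`, `right_cage`).
#' @export
analyze_visits <- function(track, params, fps, debounce = 3L) {
  comps <- c("left_cage", "middle", "right_cage")
  entries <- stats::setNames(integer(3), comps)
  if (nrow(track) == 0L)
    return(list(visits = data.frame(compartment = character(0),
                                    start_frame = integer(0),
                                    end_frame = integer(0),
                                    start_s = numeric(0), end_s = numeric(0),
                                    duration_s = numeric(0)),
                entries = entries))
  comp <- ifelse(track$x < params$b1, "left_cage",
                 ifelse(track$x > params$b2, "right_cage", "middle"))
  # debounce: fold runs shorter than `debounce` into the previous visit
  r <- rle(comp)
  if (length(r$lengths) > 1L) {
    keep <- r$lengths >= debounce
    keep[1] <- TRUE
    vals <- r$values
    for (k in seq_along(vals)[-1]) if (!keep[k]) vals[k] <- NA
    vals <- fill_forward(vals)
    comp <- inverse.rle(list(lengths = r$lengths, values = vals))
  }
  r <- rle(comp)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  visits <- data.frame(
    compartment = r$values,
    start_frame = track$frame_index[starts],
    end_frame = track$frame_index[ends])
  visits$start_s <- visits$start_frame / fps
  visits$end_s <- visits$end_frame / fps
  visits$duration_s <- (visits$end_frame - visits$start_frame + 1L) / fps
  tb <- table(factor(visits$compartment[-1], levels = comps))
  entries[comps] <- as.integer(tb)
  list(visits = visits, entries = entries)
}

fill_forward <- function(x) {
  for (i in seq_along(x)[-1]) if (is.na(x[i])) x[i] <- x[i - 1L]
  x
}
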
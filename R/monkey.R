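#' Monkey sensor-box localization
#'
#' The monkey carries a dark, rectangular sensor box on its head. The cage
#' is unevenly lit and the monkey can switch the light at any moment, so
#' every frame carries a light-on/light-off indicator. Tracking combines
#' the motion-feature cluster with two frame cues: the edge map of the
#' current frame (the sensor box produces an edge ring around an
#' edge-free dark interior) and, once a gray-level template ("model") of
#' the box has been stored, a normalized cross-correlation match against
#' it. Each accepted localization carries a confidence index built from
#' the reliability of the cage region it falls in, the match score, and
#' the number of relaxed-search iterations it took; only localizations
#' with confidence strictly above 75% feed the orientation analysis.
#'
#' @name monkey_tracking
NULL

#' Light-on / light-off indicator
#'
#' @param frame grayscale frame matrix.
#' @param thr mean-intensity threshold.
#' @return `"on"` when the mean frame intensity is at least `thr`,
#'   else `"off"`.
#' @export
detect_light_state <- function(frame, thr = 50) {
  if (mean(frame) >= thr) "on" else "off"
}

#' Edge map with hysteresis thresholding
#'
#' Gaussian smoothing, Sobel gradient magnitude, then double-threshold
#' hysteresis: weak edge pixels (`> low`) are kept only when their
#' connected component contains a strong pixel (`> high`).
#'
#' @param frame grayscale frame matrix.
#' @param sigma Gaussian smoothing standard deviation, pixels.
#' @param low,high hysteresis thresholds on the gradient magnitude.
#' @return integer 0/1 edge matrix of the frame size.
#' @export
edge_map <- function(frame, sigma = 1, low = 40, high = 90) {
  sm <- EBImage::gblur(frame, sigma = sigma)
  kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)
  gx <- EBImage::filter2(sm, kx)
  gy <- EBImage::filter2(sm, t(kx))
  mag <- sqrt(gx^2 + gy^2)
  weak <- mag > low
  if (!any(weak)) return(matrix(0L, nrow(frame), ncol(frame)))
  strong <- mag > high
  lab <- EBImage::bwlabel(matrix(as.integer(weak), nrow(frame), ncol(frame)))
  keep <- unique(lab[strong & lab > 0])
  matrix(as.integer(lab %in% keep & lab > 0), nrow(frame), ncol(frame))
}

#' Cage region reliability map
#'
#' The cage scene is divided into movement areas (typically four), each
#' with an experimentally determined reliability weight in `[0, 1]`
#' (e.g. regions where the climbing monkey's shape is poorly visible get
#' low weights).
#'
#' @param polygons named list of [region_polygon()]s.
#' @param weights numeric vector of reliability weights in `[0, 1]`,
#'   aligned with `polygons`.
#' @return object of class `region_reliability`.
#' @export
region_reliability <- function(polygons, weights) {
  stopifnot(length(polygons) == length(weights),
            all(weights >= 0 & weights <= 1))
  structure(list(polygons = polygons, weights = weights),
            class = "region_reliability")
}

# region index containing a point (first match), or NA
region_of_point <- function(p, regions) {
  for (k in seq_along(regions$polygons))
    if (point_in_polygon(p, regions$polygons[[k]])) return(k)
  NA_integer_
}

default_monkey_opts <- function() {
  list(model_w = 32L, model_h = 24L,
       edge_lo = 8L, edge_hi = 900L,  # edge-pixel count band near the box
       edge_nbhd = 24L,               # half-size of the edge-count window
       center_free_r = 3L,            # edge-free radius at the patch center
       dark_thr = 80,                 # mean gray below this is "dark"
       match_thr = 0.7,               # acceptable template-matching score
       vicinity_factor = 1.5,         # x template diagonal
       very_relevant = 400L,          # feature count forcing a restart
       uniform_tol = 2,               # sd below this means a uniform frame
       relax_factor = 1.4,            # vicinity growth per iteration
       great_features = 2000L,        # "great" motion-trait count
       light_thr = 50,
       off_search_r = 60L)            # search radius during light-off
}

# gray patch of size (w, h) centered at p, clamped to the frame; returns
# list(patch, origin)
extract_patch <- function(frame, p, w, h) {
  x0 <- round(p[[1]]) - w %/% 2L; y0 <- round(p[[2]]) - h %/% 2L
  x0 <- clamp(x0, 0L, ncol(frame) - w); y0 <- clamp(y0, 0L, nrow(frame) - h)
  list(patch = frame[(y0 + 1L):(y0 + h), (x0 + 1L):(x0 + w), drop = FALSE],
       origin = c(x = x0, y = y0))
}

# normalized cross-correlation of two equally sized patches
ncc_score <- function(a, b) {
  a <- as.vector(a); b <- as.vector(b)
  if (stats::sd(a) < 1e-9 || stats::sd(b) < 1e-9) return(0)
  stats::cor(a, b)
}

# refine a coarse cluster localization to the center of the dark mass
# (the sensor box) in its vicinity; two fixed-point iterations
dark_centroid_refine <- function(frame, p, radius = 26L, dark_thr = 80) {
  for (it in 1:2) {
    win <- rect_intersect(rect(p[[1]] - radius, p[[2]] - radius,
                               2L * radius + 1L, 2L * radius + 1L),
                          rect(0, 0, ncol(frame), nrow(frame)))
    if (is.null(win)) return(p)
    sub <- frame[(win[["y"]] + 1L):(win[["y"]] + win[["h"]]),
                 (win[["x"]] + 1L):(win[["x"]] + win[["w"]]), drop = FALSE]
    dark <- which(sub < dark_thr, arr.ind = TRUE)
    if (nrow(dark) < 10L) return(p)
    p <- c(win[["x"]] + mean(dark[, 2]) - 1, win[["y"]] + mean(dark[, 1]) - 1)
  }
  p
}

# local template-matching search: best NCC of the model template over
# integer offsets within +-search of p; returns list(position, score)
ncc_refine <- function(frame, model, p, search = 6L) {
  w <- ncol(model$template); h <- nrow(model$template)
  best <- list(position = p, score = -2)
  for (dy in -search:search) for (dx in -search:search) {
    q <- c(p[[1]] + dx, p[[2]] + dy)
    cand <- extract_patch(frame, q, w, h)
    sc <- ncc_score(cand$patch, model$template)
    if (sc > best$score) best <- list(position = q, score = sc)
  }
  best
}

# edge statistics around a candidate center: count within the
# neighborhood window and whether the immediate center vicinity is free
edge_stats <- function(edges, p, o) {
  w <- ncol(edges); h <- nrow(edges)
  cx <- round(p[[1]]); cy <- round(p[[2]])
  win <- rect_intersect(rect(cx - o$edge_nbhd, cy - o$edge_nbhd,
                             2L * o$edge_nbhd + 1L, 2L * o$edge_nbhd + 1L),
                        rect(0, 0, w, h))
  cnt <- if (is.null(win)) 0L else
    sum(edges[(win[["y"]] + 1L):(win[["y"]] + win[["h"]]),
              (win[["x"]] + 1L):(win[["x"]] + win[["w"]])])
  ctr <- rect_intersect(rect(cx - o$center_free_r, cy - o$center_free_r,
                             2L * o$center_free_r + 1L,
                             2L * o$center_free_r + 1L),
                        rect(0, 0, w, h))
  free <- if (is.null(ctr)) TRUE else
    sum(edges[(ctr[["y"]] + 1L):(ctr[["y"]] + ctr[["h"]]),
              (ctr[["x"]] + 1L):(ctr[["x"]] + ctr[["w"]])]) == 0L
  list(count = cnt, center_free = free)
}

#' Try to initialize the sensor-box model
#'
#' A model (gray-level template around the movement-cluster mass center)
#' is stored only when the scene is illuminated and (a) the cluster is
#' relevant, (b) the edge-pixel count near the mass center is in the band
#' expected for the sensor-box border while the immediate center vicinity
#' is edge-free, and (c) the mean gray level around the mass center
#' indicates a dark area.
#'
#' @param frame grayscale frame matrix.
#' @param cluster a `movement_cluster` from [counting_box_cluster()].
#' @param edges edge map of `frame` from [edge_map()].
#' @param light `"on"` or `"off"`.
#' @param frame_index stored as the model's creation frame.
#' @param opts options overriding `default_monkey_opts` values.
#' @return list (`monkey_model`: `template`, `origin`, `created_frame`)
#'   or `NULL` when any condition fails.
#' @export
try_init_model <- function(frame, cluster, edges, light, frame_index = 0L,
                           opts = list()) {
  o <- utils::modifyList(default_monkey_opts(), opts)
  if (!identical(light, "on")) return(NULL)
  if (is.null(cluster) || !cluster$relevant) return(NULL)
  # refine the coarse mass center to the dark sensor-box mass before
  # checking the edge-hole conditions
  p <- dark_centroid_refine(frame, cluster$mass_center,
                            dark_thr = o$dark_thr)
  es <- edge_stats(edges, p, o)
  if (es$count < o$edge_lo || es$count > o$edge_hi || !es$center_free)
    return(NULL)
  nb <- extract_patch(frame, p, 2L * o$center_free_r + 1L,
                      2L * o$center_free_r + 1L)
  if (mean(nb$patch) >= o$dark_thr) return(NULL)
  tp <- extract_patch(frame, p, o$model_w, o$model_h)
  structure(list(template = tp$patch, origin = tp$origin,
                 created_frame = frame_index),
            class = "monkey_model")
}

#' Confidence index of a localization
#'
#' Product of the region reliability weight, the template match score
#' (when a match was used), and an iteration penalty: recognitions resumed
#' with relaxed conditions are trusted less, more so when the motion-trait
#' count is great. Monotone non-increasing in the iteration number.
#'
#' @param region_weight reliability weight of the region, `[0, 1]`.
#' @param match_score template-matching score or `NULL`.
#' @param iteration 1 for a first-attempt localization.
#' @param features motion-feature count of the frame.
#' @param iteration_decay per-iteration penalty factor.
#' @param great_features feature count above which the extra penalty
#'   applies.
#' @return confidence in percent, `[0, 100]`.
#' @export
compute_confidence <- function(region_weight, match_score = NULL,
                               iteration = 1L, features = 0L,
                               iteration_decay = 0.9,
                               great_features = 2000L) {
  stopifnot(region_weight >= 0, region_weight <= 1)
  conf <- 100 * region_weight *
    (if (is.null(match_score)) 1 else match_score) *
    iteration_decay^(iteration - 1L)
  if (iteration > 1L && features > great_features)
    conf <- conf * iteration_decay
  clamp(conf, 0, 100)
}

#' Validate a movement cluster into a monkey localization
#'
#' A new position is accepted only with the edge cues in the right range;
#' when the cluster is in the close vicinity of the previous position the
#' stored model must also match. A very relevant cluster far away
#' triggers a tracking restart (the caller attempts a fresh model). A
#' uniform frame restarts the whole process.
#'
#' @param frame grayscale frame matrix.
#' @param cluster `movement_cluster` or `NULL`.
#' @param prev previous localization or `NULL`.
#' @param model current `monkey_model` or `NULL`.
#' @param regions a [region_reliability()].
#' @param iteration current search iteration (1 = first attempt).
#' @param edges optional precomputed edge map.
#' @param opts options overriding `default_monkey_opts` values.
#' @return a localization (list with `position`, `confidence`,
#'   `region_id`, `iteration`, `match_score`, `restart`) or `NULL`.
#' @export
locate_monkey <- function(frame, cluster, prev = NULL, model = NULL,
                          regions, iteration = 1L, edges = NULL,
                          opts = list()) {
  o <- utils::modifyList(default_monkey_opts(), opts)
  if (stats::sd(frame) < o$uniform_tol)
    return(list(position = NULL, restart = TRUE))
  if (is.null(cluster) || !cluster$relevant) return(NULL)
  if (is.null(edges)) edges <- edge_map(frame)
  p <- dark_centroid_refine(frame, cluster$mass_center,
                            dark_thr = o$dark_thr)
  es <- edge_stats(edges, p, o)
  if (es$count < o$edge_lo || es$count > o$edge_hi || !es$center_free)
    return(NULL)
  match_score <- NULL
  restart <- FALSE
  if (!is.null(prev) && !is.null(prev$position)) {
    vic <- o$vicinity_factor * o$relax_factor^(iteration - 1L) *
      sqrt(o$model_w^2 + o$model_h^2)
    d <- sqrt(sum((p - prev$position)^2))
    if (d <= vic) {
      if (!is.null(model)) {
        # validate the detection by the best local template-matching
        # score; the position itself stays at the dark-mass center
        ref <- ncc_refine(frame, model, p)
        match_score <- ref$score
        if (match_score < o$match_thr) return(NULL)
      }
    } else if (cluster$feature_count >= o$very_relevant) {
      restart <- TRUE   # pattern matching has no significance far away
    } else {
      return(NULL)
    }
  }
  rid <- region_of_point(p, regions)
  wgt <- if (is.na(rid)) 0 else regions$weights[rid]
  conf <- compute_confidence(wgt, match_score, iteration,
                             cluster$feature_count,
                             great_features = o$great_features)
  list(position = c(x = p[[1]], y = p[[2]]), confidence = conf,
       region_id = rid, iteration = iteration,
       match_score = match_score, restart = restart)
}

#' Track the monkey sensor box through a session
#'
#' Per frame: light state, motion image (masked to the useful-information
#' polygon), counting-box cluster, then validation by [locate_monkey()].
#' During light-off the search zone is restricted around the previous
#' position to suppress shadow-generated features. A failed frame
#' increases the iteration counter so the next attempt runs with relaxed
#' vicinity and a confidence penalty; frames without a relevant cluster
#' keep the last position as a freezing observation. After each accepted
#' position the model is updated.
#'
#' @param frames list of grayscale frame matrices.
#' @param regions a [region_reliability()].
#' @param info_polygon useful-information [region_polygon()] (default:
#'   whole frame).
#' @param box_w,box_h counting-box size, pixels.
#' @param relevance_thr minimum feature count for a relevant cluster.
#' @param motion_opts list overriding erosion/dilation/threshold defaults.
#' @param opts options overriding `default_monkey_opts` values.
#' @return data.frame, one row per frame: `frame_index`, `x`, `y`,
#'   `confidence`, `region`, `light`, `attribute`
#'   (`tracked`/`freezing`/`missing`).
#' @export
track_monkey <- function(frames, regions, info_polygon = NULL,
                         box_w = 48, box_h = 32, relevance_thr = 30,
                         motion_opts = list(), opts = list()) {
  o <- utils::modifyList(default_monkey_opts(), opts)
  mo <- utils::modifyList(list(erosion_size = 3L, dilation_size = 5L,
                               threshold = 15), motion_opts)
  h <- nrow(frames[[1]]); w <- ncol(frames[[1]])
  mask <- if (is.null(info_polygon)) NULL else polygon_mask(info_polygon, w, h)
  model <- NULL
  prev <- NULL
  iteration <- 1L
  rows <- vector("list", length(frames))
  for (i in seq_along(frames)) {
    fr <- frames[[i]]
    light <- detect_light_state(fr, o$light_thr)
    row <- data.frame(frame_index = i - 1L, x = NA_real_, y = NA_real_,
                      confidence = NA_real_, region = NA_integer_,
                      light = light, attribute = "missing")
    if (i >= 3L) {
      m <- compute_motion_image(fr, frames[[i - 1L]], frames[[i - 2L]],
                                mo$erosion_size, mo$dilation_size,
                                mo$threshold)
      if (!is.null(mask)) m <- mask_outside_region(m, mask)
      search <- NULL
      if (light == "off" && !is.null(prev) && !is.null(prev$position)) {
        search <- rect(prev$position[[1]] - o$off_search_r,
                       prev$position[[2]] - o$off_search_r,
                       2L * o$off_search_r, 2L * o$off_search_r)
      }
      cl <- counting_box_cluster(m, search, box_w, box_h, relevance_thr)
      if (is.null(cl) || !cl$relevant) {
        # no movement: a freezing monkey keeps its last position
        if (!is.null(prev) && !is.null(prev$position)) {
          row$x <- prev$position[[1]]; row$y <- prev$position[[2]]
          row$confidence <- prev$confidence; row$region <- prev$region_id
          row$attribute <- "freezing"
        }
      } else {
        edges <- edge_map(fr)
        loc <- locate_monkey(fr, cl, prev, model, regions, iteration,
                             edges, opts = o)
        if (!is.null(loc) && isTRUE(loc$restart) && is.null(loc$position)) {
          # uniform frame: full restart
          model <- NULL; prev <- NULL; iteration <- 1L
        } else if (!is.null(loc) && isTRUE(loc$restart)) {
          # far, very relevant cluster: restart tracking, fresh model
          nm <- try_init_model(fr, cl, edges, light, i - 1L, o)
          if (!is.null(nm)) {
            model <- nm
            prev <- loc
            row$x <- loc$position[[1]]; row$y <- loc$position[[2]]
            row$confidence <- loc$confidence; row$region <- loc$region_id
            row$attribute <- "tracked"
            iteration <- 1L
          } else iteration <- iteration + 1L
        } else if (!is.null(loc)) {
          if (is.null(model)) {
            nm <- try_init_model(fr, cl, edges, light, i - 1L, o)
            if (!is.null(nm)) model <- nm
          }
          if (!is.null(model) || !is.null(loc$match_score)) {
            prev <- loc
            row$x <- loc$position[[1]]; row$y <- loc$position[[2]]
            row$confidence <- loc$confidence; row$region <- loc$region_id
            row$attribute <- "tracked"
            iteration <- 1L
            # refresh the model at the accepted position
            tp <- extract_patch(fr, loc$position, o$model_w, o$model_h)
            if (!is.null(model)) model$template <- tp$patch
          } else iteration <- iteration + 1L
        } else {
          iteration <- iteration + 1L
          if (!is.null(prev) && !is.null(prev$position)) {
            row$x <- prev$position[[1]]; row$y <- prev$position[[2]]
            row$confidence <- prev$confidence; row$region <- prev$region_id
            row$attribute <- "freezing"
          }
        }
      }
    }
    rows[[i]] <- row
  }
  do.call(rbind, rows)
}
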
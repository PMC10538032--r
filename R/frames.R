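#' Grayscale video frames
#'
#' Frames are plain numeric matrices with `dim = c(height, width)` and
#' intensities in `[0, 255]`. Pixel coordinates are 0-based, `x` rightward
#' (columns), `y` downward (rows), so pixel `(x, y)` lives at
#' `frame[y + 1, x + 1]`. Rectangles are half-open: `[x, x + w) x [y, y + h)`.
#'
#' `as_gray_frame()` accepts a matrix (already gray), a `height x width x 3`
#' RGB array (converted by the Rec.601 luma weighting 0.299 R + 0.587 G +
#' 0.114 B), or a `height x width` array with a dropped unit channel.
#'
#' @param x matrix or 3-channel array of intensities in `[0, 255]`.
#' @return numeric matrix in `[0, 255]`.
#' @export
as_gray_frame <- function(x) {
  if (is.matrix(x)) {
    g <- x
  } else if (is.array(x) && length(dim(x)) == 3L) {
    if (dim(x)[3] == 1L) {
      g <- x[, , 1L]
    } else if (dim(x)[3] == 3L) {
      g <- 0.299 * x[, , 1L] + 0.587 * x[, , 2L] + 0.114 * x[, , 3L]
    } else {
      stop("expected 1 or 3 channels, got ", dim(x)[3])
    }
  } else {
    stop("frame must be a matrix or a h x w x c array")
  }
  if (nrow(g) < 1L || ncol(g) < 1L) stop("frame must be non-empty")
  rng <- range(g)
  if (rng[1] < 0 || rng[2] > 255) stop("intensities must lie in [0, 255]")
  g
}

frame_width <- function(frame) ncol(frame)
frame_height <- function(frame) nrow(frame)

#' Read a numbered PNG frame sequence
#'
#' Reads all `.png` files in a directory in lexicographic order and returns
#' them as grayscale matrices in `[0, 255]`.
#'
#' @param dir directory containing the numbered `.png` files.
#' @return list of grayscale frame matrices.
#' @export
read_frame_sequence <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  if (length(files) == 0L) stop("no .png frames found in ", dir)
  lapply(files, function(f) {
    px <- png::readPNG(f)
    if (length(dim(px)) == 3L && dim(px)[3] == 4L) px <- px[, , 1:3]
    as_gray_frame(px * 255)
  })
}

#' Write frames as a numbered PNG sequence
#'
#' @param frames list of grayscale matrices in `[0, 255]`.
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
write_frame_sequence <- function(frames, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(seq_along(frames), function(i) {
    p <- file.path(dir, sprintf("frame_%06d.png", i - 1L))
    png::writePNG(pmin(pmax(frames[[i]], 0), 255) / 255, p)
    p
  }, character(1))
  invisible(paths)
}

# clamp a numeric matrix/vector into [lo, hi]
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# half-open rectangle constructor/validation; x, y, w, h in 0-based pixels
rect <- function(x, y, w, h) {
  stopifnot(w >= 0, h >= 0)
  c(x = unname(x), y = unname(y), w = unname(w), h = unname(h))
}

rect_center <- function(r) c(r[["x"]] + r[["w"]] / 2, r[["y"]] + r[["h"]] / 2)
rect_diag <- function(r) sqrt(r[["w"]]^2 + r[["h"]]^2)
rect_area <- function(r) r[["w"]] * r[["h"]]

point_in_rect <- function(p, r) {
  p[1] >= r[["x"]] && p[1] < r[["x"]] + r[["w"]] &&
    p[2] >= r[["y"]] && p[2] < r[["y"]] + r[["h"]]
}

# intersection of two half-open rects, or NULL when empty
rect_intersect <- function(a, b) {
  x1 <- max(a[["x"]], b[["x"]]); y1 <- max(a[["y"]], b[["y"]])
  x2 <- min(a[["x"]] + a[["w"]], b[["x"]] + b[["w"]])
  y2 <- min(a[["y"]] + a[["h"]], b[["y"]] + b[["h"]])
  if (x2 <= x1 || y2 <= y1) return(NULL)
  rect(x1, y1, x2 - x1, y2 - y1)
}
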
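# stage-1 scene analysis and head voting on constructed frames

make_banded_frame <- function(bands, width = 320, height = 240,
                              floor = 200, wall = 30) {
  fr <- matrix(floor, height, width)
  for (b in bands) fr[, (b[1] + 1):(b[2] + 1)] <- wall
  fr
}

test_that("five dark bands give walls at the band midpoints", {
  bands <- list(c(10, 18), c(60, 70), c(140, 170), c(250, 260), c(300, 308))
  fr <- make_banded_frame(bands)
  w <- compute_scene_walls(fr)
  expect_false(is.null(w))
  expect_equal(w$b1, 65)
  expect_equal(w$b2, 255)
  expect_equal(nrow(w$cluster_bounds), 5)
})

test_that("uniform and four-band frames are rejected", {
  expect_null(compute_scene_walls(matrix(220, 240, 320)))
  four <- make_banded_frame(list(c(10, 18), c(60, 70), c(250, 260),
                                 c(300, 308)))
  expect_null(compute_scene_walls(four))
})

test_that("rat blob detection restricts to the middle room", {
  bands <- list(c(10, 18), c(60, 70), c(150, 160), c(250, 260), c(300, 308))
  fr <- make_banded_frame(bands)
  # overwrite the dummy middle band with a horizontal ellipse body
  fr[, 146:166] <- 200
  fr <- zootrack:::draw_ellipse(fr, 160, 120, 30, 10, 0, 40)
  w <- compute_scene_walls(fr)
  expect_false(is.null(w))
  b <- detect_rat_blob(fr, w)
  expect_false(is.null(b))
  expect_equal(b$aspect, "horizontal")
  expect_lt(abs(b$box[["x"]] - 130), 3)
  expect_lt(abs(b$box[["x"]] + b$box[["w"]] - 191), 3)
})

test_that("empty middle room yields no blob", {
  bands <- list(c(10, 18), c(60, 70), c(150, 160), c(250, 260), c(300, 308))
  fr <- make_banded_frame(bands)
  w <- compute_scene_walls(fr)
  # the third band lies between the walls; remove it and expect no blob
  fr2 <- fr; fr2[, 146:166] <- 200
  expect_null(detect_rat_blob(fr2, w, min_area = 30))
})

test_that("near-square blob is classified square", {
  bands <- list(c(10, 18), c(60, 70), c(150, 160), c(250, 260), c(300, 308))
  fr <- make_banded_frame(bands)
  fr[, 146:166] <- 200
  fr <- zootrack:::draw_ellipse(fr, 160, 120, 11, 10, 0, 40)
  w <- compute_scene_walls(fr)
  b <- detect_rat_blob(fr, w, min_area = 30)
  expect_equal(b$aspect, "square")
})

# a horizontal tapered body with an optional tail, in a bright frame
make_body_frame <- function(cx = 160, cy = 120, taper = 0.45,
                            tail = c("none", "left", "right")) {
  tail <- match.arg(tail)
  fr <- matrix(200, 240, 320)
  fr <- zootrack:::draw_ellipse(fr, cx, cy, 28, 11, 0, 40,
                                taper_frac = taper)
  if (tail == "right")
    fr <- zootrack:::draw_segment(fr, c(cx + 28, cy), c(cx + 58, cy), 2, 40)
  if (tail == "left")
    fr <- zootrack:::draw_segment(fr, c(cx - 28, cy), c(cx - 58, cy), 2, 40)
  fr
}

body_of <- function(fr) {
  walls <- list(cluster_bounds = cbind(c(9, 59, 130, 249, 299),
                                       c(17, 69, 190, 259, 307)))
  detect_rat_blob(fr, walls, min_area = 30)
}

test_that("taper and tail agree: certain decision on the tapered side", {
  # taper_frac thins the +x end (the head); tail rendered on the left
  fr <- make_body_frame(taper = 0.45, tail = "left")
  d <- locate_head(fr, body_of(fr), NULL, 0)
  expect_equal(d$status, "certain")
  expect_equal(d$sides, "right")
})

test_that("symmetric body with explicit tail: tail vote decides alone", {
  fr <- make_body_frame(taper = 0, tail = "right")
  d <- locate_head(fr, body_of(fr), NULL, 0)
  expect_equal(d$status, "certain")
  expect_equal(d$sides, "left")
})

test_that("contradictory strong votes: the tail vote is validated", {
  # taper says head right (fewer pixels right), tail on the right says
  # head left; the tail method wins
  fr <- matrix(200, 240, 320)
  fr <- zootrack:::draw_ellipse(fr, 160, 120, 28, 11, pi, 40,
                                taper_frac = 0.45)  # tapered toward -x
  fr <- zootrack:::draw_segment(fr, c(188, 120), c(218, 120), 2, 40)
  d <- locate_head(fr, body_of(fr), NULL, 0)
  expect_equal(d$status, "certain")
  expect_equal(d$sides, "left")
})

test_that("no reliable vote defers the decision", {
  fr <- make_body_frame(taper = 0, tail = "none")
  d <- locate_head(fr, body_of(fr), NULL, 0)
  expect_equal(d$status, "deferred")
})

test_that("two agreeing previous directions decide directly", {
  fr <- make_body_frame(taper = 0, tail = "none")
  b <- body_of(fr)
  prev <- list(
    zootrack:::head_decision(1L, matrix(c(188, 120), 1), "certain", "right"),
    zootrack:::head_decision(0L, matrix(c(186, 120), 1), "certain", "right"))
  d <- locate_head(fr, b, prev, 2L)
  expect_equal(d$status, "certain")
  expect_equal(d$sides, "right")
})

test_that("ambiguous frames resolve toward the next certain position", {
  mk <- function(f, cands, status) zootrack:::head_decision(
    f, matrix(cands, ncol = 2, byrow = TRUE), status,
    if (status == "certain") "left" else c("left", "right"))
  dec <- list(
    mk(0, c(100, 100), "certain"),
    mk(1, c(100, 102, 160, 102), "ambiguous"),
    mk(2, c(101, 104), "certain"))
  tr <- resolve_trajectory(dec)
  expect_equal(tr$x[2], 100)
  # an ambiguous run before a certain frame at the left wall resolves to
  # the candidates nearest that wall
  dec2 <- list(
    mk(0, c(10, 100), "certain"),
    mk(1, c(12, 100, 80, 100), "ambiguous"),
    mk(2, c(14, 100, 82, 100), "ambiguous"),
    mk(3, c(16, 100, 84, 100), "ambiguous"),
    mk(4, c(18, 100), "certain"))
  tr2 <- resolve_trajectory(dec2)
  expect_equal(tr2$x, c(10, 12, 14, 16, 18))
})

test_that("all-certain lists resolve to themselves; deferred interpolate", {
  mk <- function(f, x, status = "certain") zootrack:::head_decision(
    f, if (status == "deferred") matrix(numeric(0), 0, 2) else
      matrix(c(x, 50), 1), status, "left")
  dec <- list(mk(0, 10), mk(1, 20), mk(2, 30))
  expect_equal(resolve_trajectory(dec)$x, c(10, 20, 30))
  dec2 <- list(mk(0, 10), mk(1, NA, "deferred"), mk(2, 30))
  expect_equal(resolve_trajectory(dec2)$x, c(10, 20, 30))
  dec3 <- list(mk(0, NA, "deferred"), mk(1, NA, "deferred"))
  expect_error(resolve_trajectory(dec3), "no certain frame")
})
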
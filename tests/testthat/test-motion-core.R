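test_that("identical frames produce an empty motion image", {
  f <- matrix(runif(256, 0, 255), 16, 16)
  m <- compute_motion_image(f, f, f)
  expect_s3_class(m, "motion_image")
  expect_equal(m$features_nmb, 0)
  expect_true(all(m$features == 0))
})

test_that("a translating block leaves features at its newest position", {
  mk <- function(x) {
    m <- matrix(20, 16, 16)
    m[7:9, (x + 1):(x + 3)] <- 220
    m
  }
  # 3 px/frame rightward: newest block at columns 8..10 (0-based)
  m <- compute_motion_image(mk(8), mk(5), mk(2))
  expect_gt(m$features_nmb, 0)
  nz <- which(m$features != 0, arr.ind = TRUE)
  xs <- nz[, 2] - 1
  expect_true(any(xs >= 8 & xs <= 10))
  # no features left at the oldest block position (columns 2..4)
  expect_false(any(xs < 5))
})

test_that("motion image equals the pixelwise oracle on random triples", {
  set.seed(0)
  for (k in 1:50) {
    ia <- matrix(sample(0:255, 32 * 32, TRUE), 32, 32)
    ib <- matrix(sample(0:255, 32 * 32, TRUE), 32, 32)
    ic <- matrix(sample(0:255, 32 * 32, TRUE), 32, 32)
    got <- compute_motion_image(ia, ib, ic)
    want <- oracle_motion_image(ia, ib, ic)
    expect_identical(got$features, want)
    expect_identical(got$features_nmb, sum(want))
  }
})

test_that("frame-triple dimension mismatch is a configuration error", {
  a <- matrix(0, 8, 8); b <- matrix(0, 8, 9)
  expect_error(compute_motion_image(a, b, a), "dimension mismatch")
})

test_that("ray casting matches a winding-number oracle", {
  set.seed(42)
  for (k in 1:20) {
    v <- random_simple_polygon(sample(3:9, 1), cx = runif(1, 8, 24),
                               cy = runif(1, 8, 24), r_min = 2, r_max = 10)
    poly <- region_polygon(v)
    for (j in 1:10) {
      p <- c(runif(1, 0, 32), runif(1, 0, 32))
      expect_identical(point_in_polygon(p, poly),
                       oracle_winding_inside(p, v),
                       label = sprintf("poly %d point (%f, %f)", k, p[1], p[2]))
    }
  }
})

test_that("points on edges and vertices count as inside", {
  sq <- region_polygon(rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10)))
  expect_true(point_in_polygon(c(5, 5), sq))
  expect_false(point_in_polygon(c(15, 5), sq))
  expect_true(point_in_polygon(c(10, 5), sq))   # edge
  expect_true(point_in_polygon(c(0, 0), sq))    # vertex
  expect_false(point_in_polygon(c(10.001, 5), sq))
})

test_that("masking outside a region removes exactly the outside features", {
  set.seed(7)
  for (k in 1:10) {
    feats <- matrix(as.integer(runif(32 * 32) < 0.1), 32, 32)
    m <- structure(list(features = feats, features_nmb = sum(feats)),
                   class = "motion_image")
    v <- random_simple_polygon(7, 16, 16, 4, 14)
    poly <- region_polygon(v)
    got <- mask_outside_region(m, poly)
    nz <- which(feats != 0, arr.ind = TRUE)
    inside <- vapply(seq_len(nrow(nz)), function(i)
      oracle_winding_inside(c(nz[i, 2] - 1, nz[i, 1] - 1), v), logical(1))
    expect_equal(got$features_nmb, sum(inside))
    for (i in seq_len(nrow(nz)))
      expect_equal(got$features[nz[i, 1], nz[i, 2]],
                   as.integer(inside[i]))
    # idempotence
    again <- mask_outside_region(got, poly)
    expect_identical(again$features, got$features)
  }
})

test_that("whole-frame polygon leaves the motion image unchanged", {
  feats <- matrix(as.integer(runif(100) < 0.3), 10, 10)
  m <- structure(list(features = feats, features_nmb = sum(feats)),
                 class = "motion_image")
  poly <- region_polygon(rbind(c(-1, -1), c(10, -1), c(10, 10), c(-1, 10)))
  expect_identical(mask_outside_region(m, poly)$features, feats)
})

test_that("a single outside feature pixel is removed", {
  feats <- matrix(0L, 10, 10); feats[1, 10] <- 1L  # pixel (9, 0)
  m <- structure(list(features = feats, features_nmb = 1L),
                 class = "motion_image")
  poly <- region_polygon(rbind(c(0, 0), c(5, 0), c(5, 5), c(0, 5)))
  expect_equal(mask_outside_region(m, poly)$features_nmb, 0)
})

test_that("counting box returns the exhaustive-argmax placement", {
  set.seed(1)
  for (k in 1:50) {
    feats <- matrix(as.integer(runif(64 * 64) < 0.03), 64, 64)
    m <- structure(list(features = feats, features_nmb = sum(feats)),
                   class = "motion_image")
    cl <- counting_box_cluster(m, NULL, box_w = 12, box_h = 10)
    if (sum(feats) == 0) {
      expect_null(cl)
    } else {
      want <- oracle_best_box_count(feats, 0L, 0L, 64L, 64L, 12L, 10L)
      expect_identical(cl$feature_count, want)
      # mass center lies inside the winning box
      expect_true(cl$mass_center[["x"]] >= cl$box[["x"]] &&
                    cl$mass_center[["x"]] < cl$box[["x"]] + cl$box[["w"]])
      expect_true(cl$mass_center[["y"]] >= cl$box[["y"]] &&
                    cl$mass_center[["y"]] < cl$box[["y"]] + cl$box[["h"]])
    }
  }
})

test_that("counting box prefers the denser of two feature groups", {
  feats <- matrix(0L, 40, 40)
  feats[5:8, 5:7] <- 1L            # 12-pixel group
  feats[30:31, 30:31] <- 1L        # 4-pixel group
  m <- structure(list(features = feats, features_nmb = 16L),
                 class = "motion_image")
  cl <- counting_box_cluster(m, NULL, box_w = 8, box_h = 8)
  expect_identical(cl$feature_count, 12L)
  expect_true(cl$mass_center[["x"]] < 10 && cl$mass_center[["y"]] < 10)
})

test_that("empty motion image or empty search region yields no cluster", {
  m <- structure(list(features = matrix(0L, 10, 10), features_nmb = 0L),
                 class = "motion_image")
  expect_null(counting_box_cluster(m, NULL, 4, 4))
  feats <- matrix(1L, 10, 10)
  m2 <- structure(list(features = feats, features_nmb = 100L),
                  class = "motion_image")
  expect_null(counting_box_cluster(m2, c(x = 20, y = 20, w = 5, h = 5),
                                   4, 4))
})

test_that("single feature pixel becomes its own cluster mass center", {
  feats <- matrix(0L, 20, 20); feats[6, 11] <- 1L  # pixel (10, 5)
  m <- structure(list(features = feats, features_nmb = 1L),
                 class = "motion_image")
  cl <- counting_box_cluster(m, NULL, 6, 6, relevance_thr = 2)
  expect_equal(unname(cl$mass_center["x"]), 10)
  expect_equal(unname(cl$mass_center["y"]), 5)
  expect_false(cl$relevant)
})
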
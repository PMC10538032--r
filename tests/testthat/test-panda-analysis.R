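# trajectory fusion, filtering, velocities and stress labeling

two_cam_cfgs <- function() {
  mk <- function(id, general) camera_config(
    camera_id = id, resolution = c(480L, 270L),
    info_polygon = rect_polygon(rect(0, 0, 480, 270), "info"),
    visible_zones = list(
      full = rect_polygon(rect(0, 0, 480, 200), "full"),
      housing = rect_polygon(rect(0, 200, 480, 70), "housing")),
    zone_types = c(full = "full", housing = "housing"),
    zone_correspondence = list(
      full = data.frame(camera_id = setdiff(c(5L, 6L), id), zone = "full"),
      housing = data.frame(camera_id = setdiff(c(5L, 6L), id),
                           zone = "housing")),
    general_view = general, velocity_weight = 1)
  list(`5` = mk(5L, FALSE), `6` = mk(6L, TRUE))
}

cand_row <- function(camera_id, x = 100, y = 100, attribute = "movement",
                     zone = "full", technician = FALSE) {
  data.frame(camera_id = camera_id, x = x, y = y, attribute = attribute,
             zone = zone, technician = technician)
}

test_that("view selection ranks zones and favors the previous camera", {
  cfgs <- two_cam_cfgs()
  # single candidate
  e <- select_view(cand_row(5L), NULL, cfgs)
  expect_equal(e$camera_id, 5L)
  # two equal-rank candidates (same zone rank and camera class): the
  # previously selected camera is kept
  ground_cfgs <- cfgs
  ground_cfgs[["6"]]$general_view <- FALSE
  both <- rbind(cand_row(5L), cand_row(6L))
  prev <- data.frame(camera_id = 6L)
  e2 <- select_view(both, prev, ground_cfgs)
  expect_equal(e2$camera_id, 6L)
  # a ground camera outranks a general view at equal zone rank
  e2b <- select_view(both, prev, cfgs)
  expect_equal(e2b$camera_id, 5L)
  # technician-only frame yields a null entry
  e3 <- select_view(cand_row(5L, technician = TRUE), NULL, cfgs)
  expect_true(is.na(e3$camera_id))
  expect_equal(e3$attribute, "freezing_or_missing")
  # out-of-zone candidates are not considered
  e4 <- select_view(cand_row(5L, zone = NA_character_), NULL, cfgs)
  expect_true(is.na(e4$camera_id))
  # a higher-ranked zone beats the previous camera
  mixed <- rbind(cand_row(5L, zone = "full"), cand_row(6L, zone = "housing"))
  e5 <- select_view(mixed, prev, cfgs)
  expect_equal(e5$camera_id, 5L)
})

fused_entries <- function(cams, xs = NULL, attribute = "movement") {
  n <- length(cams)
  if (is.null(xs)) xs <- seq_len(n)
  data.frame(frame_index = seq_len(n) - 1L,
             camera_id = cams, x = xs, y = 50,
             attribute = ifelse(is.na(cams), "freezing_or_missing",
                                attribute),
             zone = ifelse(is.na(cams), NA_character_, "full"))
}

test_that("compaction replaces short foreign runs between large runs", {
  cfgs <- two_cam_cfgs()
  cams <- c(rep(5L, 60), rep(6L, 5), rep(5L, 60))
  e <- fused_entries(cams)
  # camera 5's own per-camera track knows those frames
  tr5 <- data.frame(frame_index = 0:124, camera_id = 5L,
                    x = 1000 + 0:124, y = 9, attribute = "movement",
                    zone = "full", technician = FALSE)
  out <- filter_pass_compaction(e, list(`5` = tr5), cfgs,
                                large_min = 50L, short_max = 10L)
  mid <- out[61:65, ]
  expect_true(all(mid$camera_id == 5L))
  expect_equal(mid$x, 1000 + 60:64)
  # a long foreign run is preserved
  cams2 <- c(rep(5L, 60), rep(6L, 200), rep(5L, 60))
  e2 <- fused_entries(cams2)
  out2 <- filter_pass_compaction(e2, list(`5` = tr5), cfgs)
  expect_identical(out2$camera_id, e2$camera_id)
  # single-camera lists are untouched
  e3 <- fused_entries(rep(5L, 100))
  expect_identical(filter_pass_compaction(e3, list(`5` = tr5), cfgs), e3)
})

test_that("gap filling matches the closed-form interpolation", {
  mk_gap <- function(j) {
    e <- fused_entries(c(5L, rep(NA, j - 1L), 5L),
                       xs = c(0, rep(NA, j - 1L), 8 * j))
    e$y <- c(0, rep(NA, j - 1L), 4 * j)
    e
  }
  for (j in c(2L, 50L, 100L)) {
    out <- fill_gaps(mk_gap(j))
    k <- seq_len(j - 1L)
    expect_equal(out$x[1L + k], 0 + k * (8 * j - 0) / j,
                 label = paste("gap", j))
    expect_equal(out$y[1L + k], k * (4 * j) / j)
    expect_true(all(out$camera_id == 5L))
    # idempotent
    expect_identical(fill_gaps(out), out)
  }
  # a 101-frame gap stays untouched
  out101 <- fill_gaps(mk_gap(101L))
  expect_true(all(is.na(out101$x[2:101])))
  # gaps bounded by different cameras stay untouched
  e <- fused_entries(c(5L, NA, NA, 6L), xs = c(0, NA, NA, 30))
  expect_true(all(is.na(fill_gaps(e)$x[2:3])))
})

test_that("gap filling attributes follow the moving/freezing rule", {
  e <- fused_entries(c(5L, NA, NA, NA, 5L), xs = c(0, NA, NA, NA, 8))
  e$attribute <- c("movement", rep("freezing_or_missing", 3), "freezing")
  out <- fill_gaps(e)
  expect_true(all(out$attribute[2:4] == "movement"))
  e$attribute <- c("freezing", rep("freezing_or_missing", 3), "freezing")
  out2 <- fill_gaps(e)
  expect_true(all(out2$attribute[2:4] == "freezing"))
})

test_that("attribute smoothing equals the windowed-vote oracle", {
  set.seed(77)
  att <- sample(c("movement", "freezing", "no_information"), 1000, TRUE)
  att[sample(1000, 50)] <- "freezing_or_missing"
  e <- data.frame(frame_index = 0:999, camera_id = 5L, x = 1, y = 1,
                  attribute = att, zone = "full")
  out <- smooth_attributes(e, 5L)
  expect_equal(out$attribute, oracle_vote_attributes(att, 5L))
  # a single freezing inside a moving run becomes moving
  e2 <- data.frame(frame_index = 0:6, camera_id = 5L, x = 1, y = 1,
                   attribute = c(rep("movement", 3), "freezing",
                                 rep("movement", 3)), zone = "full")
  expect_true(all(smooth_attributes(e2, 5L)$attribute == "movement"))
})

test_that("velocities are weighted displacements with windowed filtering", {
  cfgs <- two_cam_cfgs()
  e <- data.frame(frame_index = 0:3, camera_id = c(5L, 5L, 6L, 6L),
                  x = c(0, 3, 10, 10), y = c(0, 4, 10, 10),
                  attribute = "movement", zone = "full")
  out <- compute_velocities(e, cfgs, window = 1L)
  expect_equal(out$v_raw[2], 5)          # 3-4-5 displacement
  expect_true(is.na(out$v_raw[3]))       # camera switch
  expect_equal(out$v_raw[4], 0)          # static
  # filtered velocity equals the direct windowed mean of valid samples
  set.seed(5)
  n <- 200
  e2 <- data.frame(frame_index = seq_len(n) - 1L, camera_id = 5L,
                   x = cumsum(runif(n, 0, 4)), y = cumsum(runif(n, 0, 2)),
                   attribute = "movement", zone = "full")
  out2 <- compute_velocities(e2, cfgs, window = 11L)
  half <- 5L
  for (i in c(1L, 7L, 100L, 195L, 200L)) {
    win <- max(1L, i - half):min(n, i + half)
    vals <- out2$v_raw[win]; vals <- vals[!is.na(vals)]
    expect_equal(out2$v[i], mean(vals))
  }
})

test_that("stress labels follow the velocity bands and contexts", {
  cfgs <- two_cam_cfgs()
  thr <- velocity_thresholds(6, 3.5, 1.5)
  n <- 120
  # 40 frames still in housing, 40 frames walking at 4.5 px/frame, 40
  # still again: a walking-2 episode
  e <- data.frame(frame_index = seq_len(n) - 1L, camera_id = 5L,
                  x = c(rep(0, 40), cumsum(rep(4.5, 40)),
                        rep(180, 40)),
                  y = 230,
                  attribute = c(rep("freezing", 40), rep("movement", 40),
                                rep("freezing", 40)),
                  zone = "housing")
  e <- compute_velocities(e, cfgs, window = 1L)
  res <- classify_stress(e, thr, cfgs, fps = 10)
  expect_true(all(res$entries$stress[45:75] == "walking2"))
  expect_equal(unique(res$episodes$class), "walking2")
  # the same walk out of a full-visibility rest is walking 1
  e2 <- e; e2$zone <- "full"
  res2 <- classify_stress(compute_velocities(e2, cfgs, window = 1L),
                          thr, cfgs, fps = 10)
  expect_true(all(res2$entries$stress[45:75] == "walking1"))
  # running above thr_v1 regardless of context
  e3 <- e; e3$x <- c(rep(0, 40), cumsum(rep(8, 40)), rep(320, 40))
  res3 <- classify_stress(compute_velocities(e3, cfgs, window = 1L),
                          thr, cfgs, fps = 10)
  expect_true(all(res3$entries$stress[45:75] == "running"))
  # below thr_v3, away from any basin: no label
  e4 <- e; e4$x <- c(rep(0, 40), cumsum(rep(1, 40)), rep(40, 40))
  res4 <- classify_stress(compute_velocities(e4, cfgs, window = 1L),
                          thr, cfgs, fps = 10)
  expect_true(all(res4$entries$stress == "none"))
  # threshold-ordering violations are configuration errors
  expect_error(velocity_thresholds(1, 2, 3), "thr_v1 > thr_v2 > thr_v3")
})

test_that("walking 3 needs a slow band, housing context and a path
           height", {
  cfgs <- two_cam_cfgs()
  thr <- velocity_thresholds(6, 3.5, 1.5)
  n <- 170
  zig_y <- 230 + 25 * sin(seq(0, 2 * pi, length.out = 100))
  e <- data.frame(frame_index = seq_len(n) - 1L, camera_id = 5L,
                  x = c(rep(0, 40), cumsum(rep(2.0, 100)), rep(200, 30)),
                  y = c(rep(230, 40), zig_y, rep(230, 30)),
                  attribute = c(rep("freezing", 40), rep("movement", 100),
                                rep("freezing", 30)),
                  zone = "housing")
  res <- classify_stress(compute_velocities(e, cfgs, window = 1L),
                         thr, cfgs, fps = 10)
  expect_true(any(res$entries$stress == "walking3"))
  # a straight path in the same band earns no walking-3 label
  e2 <- e; e2$y <- 230
  res2 <- classify_stress(compute_velocities(e2, cfgs, window = 1L),
                          thr, cfgs, fps = 10)
  expect_false(any(res2$entries$stress == "walking3"))
})

test_that("stationary needs the basin camera, proximity and 5 s", {
  cfg8 <- camera_config(
    camera_id = 8L, resolution = c(480L, 270L),
    info_polygon = rect_polygon(rect(0, 0, 480, 270), "info"),
    visible_zones = list(basin = rect_polygon(rect(200, 30, 180, 140),
                                              "basin")),
    zone_types = c(basin = "basin"),
    general_view = FALSE, basin_zone = rect(200, 30, 180, 140))
  cfgs <- list(`8` = cfg8)
  mk <- function(nf) data.frame(
    frame_index = seq_len(nf) - 1L, camera_id = 8L,
    x = 290 + sin(seq_len(nf)) * 3, y = 100,
    attribute = "movement", zone = "basin")
  long <- compute_velocities(mk(80), cfgs, window = 1L)
  res <- classify_stress(long, velocity_thresholds(6, 3.5, 1.5), cfgs,
                         fps = 10)
  expect_true(all(res$entries$stress == "stationary"))
  expect_gt(res$episodes$duration_s[1], 5)
  # a 3 s dwell is too short
  short <- compute_velocities(mk(30), cfgs, window = 1L)
  res2 <- classify_stress(short, velocity_thresholds(6, 3.5, 1.5), cfgs,
                          fps = 10)
  expect_false(any(res2$entries$stress == "stationary"))
})

test_that("episode labels are invariant under uniform rescaling", {
  cfgs <- two_cam_cfgs()
  thr <- velocity_thresholds(6, 3.5, 1.5)
  set.seed(99)
  n <- 150
  e <- data.frame(frame_index = seq_len(n) - 1L, camera_id = 5L,
                  x = c(rep(0, 40), cumsum(runif(70, 3, 7)), rep(NA, 40)),
                  y = 230, attribute = c(rep("freezing", 40),
                                         rep("movement", 70),
                                         rep("freezing", 40)),
                  zone = "housing")
  e$x[111:150] <- e$x[110]
  base <- classify_stress(compute_velocities(e, cfgs, window = 5L),
                          thr, cfgs, fps = 10)
  # scale all coordinates, thresholds and the height distance by 3
  e2 <- e; e2$x <- e2$x * 3; e2$y <- e2$y * 3
  thr2 <- velocity_thresholds(18, 10.5, 4.5)
  scaled <- classify_stress(compute_velocities(e2, cfgs, window = 5L),
                            thr2, cfgs, fps = 10,
                            opts = list(height_dist = 60))
  expect_equal(scaled$entries$stress, base$entries$stress)
})
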
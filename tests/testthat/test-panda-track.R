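# per-camera panda state machine

mini_cfg <- function() {
  camera_config(
    camera_id = 5L, resolution = c(200L, 200L),
    info_polygon = rect_polygon(rect(0, 0, 200, 200), "info"),
    panda_gates = list(rect(0, 0, 40, 200)),
    technician_gate = rect(160, 0, 40, 200),
    visible_zones = list(
      full = rect_polygon(rect(40, 40, 100, 120), "full"),
      door1 = rect_polygon(rect(0, 0, 40, 200), "door1")),
    zone_types = c(full = "full", door1 = "door"),
    general_view = FALSE, velocity_weight = 1,
    technician_height_frac = 0.6)
}

fake_cluster <- function(x, y, n = 100L, w = 20, h = 20) {
  structure(list(box = rect(x - w / 2, y - h / 2, w, h),
                 mass_center = c(x = x, y = y),
                 feature_count = as.integer(n), relevant = TRUE),
            class = "movement_cluster")
}

fake_motion <- function(n) {
  structure(list(features = matrix(0L, 1, 1), features_nmb = as.integer(n)),
            class = "motion_image")
}

test_that("session gate fires per the three initialization rules", {
  cfg <- mini_cfg()
  thr <- motion_thresholds(20, 60, 400)
  # (a) very strong movement; tall rectangle in the technician gate
  tall <- fake_cluster(180, 100, 500, w = 20, h = 130)
  g <- session_gate(fake_motion(500), tall, cfg, thr)
  expect_true(g$start); expect_true(g$zoo_technician)
  # (a) strong movement elsewhere: session without the technician flag
  g2 <- session_gate(fake_motion(500), fake_cluster(100, 100, 500), cfg, thr)
  expect_true(g2$start); expect_false(g2$zoo_technician)
  # (b) moderate movement in a panda gate area
  g3 <- session_gate(fake_motion(100), fake_cluster(20, 100, 100), cfg, thr)
  expect_true(g3$start); expect_false(g3$zoo_technician)
  # moderate movement away from gates, no previous session: nothing
  g4 <- session_gate(fake_motion(100), fake_cluster(100, 100, 100), cfg, thr)
  expect_false(g4$start)
  # (c) moderate movement in the previous valid position area
  g5 <- session_gate(fake_motion(100), fake_cluster(100, 100, 100), cfg, thr,
                     prev_valid = c(95, 105))
  expect_true(g5$start)
})

test_that("frame attributes follow the three-band truth table", {
  cfg <- mini_cfg()
  thr <- motion_thresholds(20, 60, 400)
  prevs <- list(
    mv_full = list(attribute = "movement", position = c(100, 100),
                   zone = "full", door_watch = FALSE),
    mv_none = list(attribute = "movement", position = c(100, 100),
                   zone = NA_character_, door_watch = FALSE),
    fz_full = list(attribute = "freezing", position = c(100, 100),
                   zone = "full", door_watch = FALSE),
    fz_none = list(attribute = "freezing", position = c(100, 100),
                   zone = NA_character_, door_watch = FALSE),
    ni = list(attribute = "no_information", position = NULL,
              zone = NA_character_, door_watch = FALSE),
    door = list(attribute = "freezing", position = c(20, 100),
                zone = "door1", door_watch = TRUE))
  near <- fake_cluster(101, 100)   # near the previous position
  far <- fake_cluster(150, 150)    # far from it
  expect_attr <- function(f, cl, prev, want) {
    got <- classify_frame(f, cl, prevs[[prev]], cfg, thr)
    expect_equal(got$attribute, want,
                 label = sprintf("band %d prev %s", f, prev))
  }
  # below the low threshold
  expect_attr(5, NULL, "mv_full", "freezing")
  expect_attr(5, NULL, "fz_full", "freezing")
  expect_attr(5, NULL, "fz_none", "freezing")   # freezing persists
  expect_attr(5, NULL, "mv_none", "no_information")
  expect_attr(5, NULL, "ni", "no_information")
  # above the movement threshold
  for (p in names(prevs)) expect_attr(100, near, p, "movement")
  # intermediate band
  expect_attr(40, near, "door", "freezing")     # door watch continues
  expect_attr(40, near, "mv_full", "freezing")  # near-static after movement
  expect_attr(40, far, "mv_full", "no_information")
  expect_attr(40, near, "fz_full", "no_information")
  expect_attr(40, near, "ni", "no_information")
})

test_that("movement validation rejects bursts, teleports and reversals", {
  cfg <- mini_cfg()
  hist <- data.frame(x = c(80, 90), y = c(100, 100), w = 20, h = 20,
                     attribute = "movement")
  # (a) area burst (flare): 6x the previous rectangle area
  expect_equal(validate_movement_frame(rect(90, 90, 49, 49), hist, NULL,
                                       cfg, center = c(100, 100)), "reject")
  # (b) teleport within a visible area
  expect_equal(validate_movement_frame(rect(120, 140, 20, 20), hist, NULL,
                                       cfg, center = c(130, 150)), "reject")
  # (c) direction reversal
  expect_equal(validate_movement_frame(rect(70, 90, 20, 20), hist, NULL,
                                       cfg, center = c(80 - 10, 100)),
               "reject")
  # consistent continuation is accepted
  expect_equal(validate_movement_frame(rect(90, 90, 20, 20), hist, NULL,
                                       cfg, center = c(100, 100)), "accept")
})

test_that("general-view candidates outside the corresponding zone are
           rejected (flying birds)", {
  cfg6 <- camera_config(
    camera_id = 6L, resolution = c(200L, 200L),
    info_polygon = rect_polygon(rect(0, 0, 200, 200), "info"),
    visible_zones = list(full = rect_polygon(rect(40, 100, 120, 80),
                                             "full")),
    zone_types = c(full = "full"),
    zone_correspondence = list(full = data.frame(camera_id = 5L,
                                                 zone = "full")),
    general_view = TRUE)
  fused_prev <- list(camera_id = 5L, zone = "full")
  # bird blob in the sky region (no zone) while the bear was fused on
  # camera 5's full zone
  expect_equal(validate_movement_frame(
    rect(90, 10, 12, 12), data.frame(x = numeric(0), y = numeric(0),
                                     w = numeric(0), h = numeric(0),
                                     attribute = character(0)),
    fused_prev, cfg6, center = c(96, 16)), "reject")
  # blob inside the corresponding zone is fine
  expect_equal(validate_movement_frame(
    rect(90, 120, 12, 12), data.frame(x = numeric(0), y = numeric(0),
                                      w = numeric(0), h = numeric(0),
                                      attribute = character(0)),
    fused_prev, cfg6, center = c(96, 126)), "accept")
})

test_that("a freezing interval is labeled freezing without a session
           restart", {
  # single-camera fixture: the target enters through the gate, moves,
  # freezes for 5 s, then moves again
  set.seed(31)
  n <- 100
  xs <- c(seq(20, 80, length.out = 30), rep(80, 50),
          seq(80, 120, length.out = 20))
  frames <- lapply(seq_len(n), function(i) {
    fr <- matrix(200, 200, 200)
    fr <- zootrack:::draw_disk(fr, xs[i], 100, 12, 50)
    zootrack:::add_noise(fr, 2)
  })
  cfg <- mini_cfg()
  thr <- motion_thresholds(15, 40, 2000)
  tr <- track_camera(frames, cfg, thr, box_w = 32, box_h = 32,
                     motion_opts = list(erosion_size = 1L,
                                        dilation_size = 3L, threshold = 20))
  frozen <- tr[tr$frame_index %in% 35:75, ]
  expect_true(all(frozen$attribute == "freezing"))
  expect_true(all(frozen$session_active))
  # tracking resumes on the same session when movement restarts
  late <- tr[tr$frame_index %in% 85:95, ]
  expect_true(any(late$attribute == "movement"))
})
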
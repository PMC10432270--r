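test_that("stationary flies are tracked at constant heights every frame", {
  kin <- climb_kinematics(n_flies = 5, pause_prob = 1, n_trials = 1,
                          trial_duration_s = 3, seed = 21)
  truth <- simulate_climb_trajectories(kin)
  # park the flies at distinct heights so blobs stay separated; let them
  # wander sideways (as real flies do) so the background stays estimable
  truth$height_cm <- 3 * (truth$fly - 1)
  truth$x_frac <- 0.5 + 0.25 * sin(2 * pi * truth$time_s / 2 +
                                     truth$fly * 1.3)
  spec <- video_spec(width = 150, height = 220, n_tubes = 1, noise_sd = 2)
  vid <- render_video(truth, spec, seed = 22)
  tab <- track_stack(vid$stack, segmentation_params(), spec$tube_rois,
                     spec$cm_per_px, calib_regions = spec$calib_regions,
                     tube_length_cm = spec$tube_length_cm)
  per_frame <- table(tab$frame[tab$valid])
  expect_true(all(per_frame == 5))
  # constant heights: each fly's detected height varies < 0.5 cm
  for (f in unique(truth$fly)) {
    h_true <- 3 * (f - 1)
    near <- tab[abs(tab$height_cm - h_true) < 1.4, ]
    expect_equal(nrow(near), vid$stack$n_frames)
    expect_lt(max(near$height_cm) - min(near$height_cm), 0.5)
  }
})

test_that("a fly starting at the tube base reads height zero there", {
  kin <- climb_kinematics(n_flies = 1, speed_mean = 2, speed_sd = 0,
                          pause_prob = 0, n_trials = 1,
                          trial_duration_s = 6, seed = 23)
  truth <- simulate_climb_trajectories(kin)
  spec <- video_spec(width = 100, height = 180, n_tubes = 1, noise_sd = 0,
                     flicker_sd = 0)
  vid <- render_video(truth, spec, seed = 24)
  tab <- track_stack(vid$stack, segmentation_params(), spec$tube_rois,
                     spec$cm_per_px, tube_length_cm = spec$tube_length_cm)
  first <- tab[tab$frame == 0, ]
  expect_equal(nrow(first), 1)
  expect_equal(first$height_cm, 0)
  # later frames follow the climb within tracking error
  probe <- tab[tab$frame == 40, ]   # t = 4 s -> 8 cm
  expect_lt(abs(probe$height_cm - 8), 0.5)
})

test_that("trial annotation and within-trial time follow the boundaries", {
  v <- tiny_video(n_flies = 2, n_trials = 2, trial_duration_s = 2,
                  seed = 25)
  nf <- attr(v$truth, "frames_per_trial")
  tab <- track_stack(v$stack, segmentation_params(), v$spec$tube_rois,
                     v$spec$cm_per_px,
                     trial_start_frames = c(0, nf),
                     calib_regions = v$spec$calib_regions,
                     tube_length_cm = v$spec$tube_length_cm)
  expect_setequal(unique(tab$trial), c(1, 2))
  expect_true(all(tab$time_in_trial_s[tab$trial == 2] ==
                    (tab$frame[tab$trial == 2] - nf) / v$stack$fps))
})

test_that("overlapping ROIs are rejected", {
  v <- tiny_video(seed = 26, trial_duration_s = 1)
  rois <- rbind(v$spec$tube_rois, v$spec$tube_rois)
  rois$tube <- 1:2
  expect_error(track_stack(v$stack, segmentation_params(), rois,
                           v$spec$cm_per_px), "disjoint")
})

test_that("gravity filter excludes frames with too many detections", {
  tab <- data.frame(frame = rep(0:2, each = 11), tube = 1,
                    trial = 1, time_in_trial_s = rep(0:2, each = 11) / 10,
                    height_cm = 1, valid = TRUE, excluded = FALSE,
                    excluded_reason = "")
  tab <- tab[-(1:1), ]  # frame 0 has 10 detections; frames 1-2 have 11
  out <- apply_validity_filters(tab, "gravity", max_flies = 10)
  expect_true(all(!out$excluded[out$frame == 0]))
  expect_true(all(out$excluded[out$frame %in% 1:2]))
  expect_true(all(out$excluded_reason[out$frame == 1] ==
                    "too_many_detections"))
  # at most 10 detections: untouched
  ok <- tab[tab$frame == 0, ]
  expect_identical(apply_validity_filters(ok, "gravity")$excluded,
                   ok$excluded)
})

test_that("flyvac filter drops immobile and badly-reset flies", {
  mk_fly <- function(tube, heights_by_trial, h0 = 0) {
    do.call(rbind, lapply(seq_along(heights_by_trial), function(tr) {
      h <- heights_by_trial[[tr]]
      data.frame(frame = (tr - 1) * length(h) + seq_along(h) - 1,
                 tube = tube, trial = tr,
                 time_in_trial_s = (seq_along(h) - 1) / 10,
                 height_cm = h, valid = TRUE, excluded = FALSE,
                 excluded_reason = "")
    }))
  }
  climb <- lapply(1:5, function(i) c(0, 2, 5, 9))
  immobile <- lapply(1:5, function(i) rep(4, 4))
  not_sucked <- climb; not_sucked[[3]] <- c(6, 8, 10, 12)  # starts high
  tab <- rbind(mk_fly(1, climb), mk_fly(2, immobile), mk_fly(3, not_sucked))
  out <- apply_validity_filters(tab, "flyvac", bottom_threshold_cm = 1)
  expect_setequal(unique(out$tube), 1)
  # a fly that moved in just one trial is kept
  one_move <- immobile; one_move[[2]] <- c(4, 4, 5, 6)
  tab2 <- rbind(mk_fly(1, one_move))
  # starts at height 4 though: fails the vacuum criterion
  expect_equal(nrow(apply_validity_filters(tab2, "flyvac")), 0)
  one_move_ok <- lapply(one_move, function(h) h - 4)
  tab3 <- rbind(mk_fly(1, one_move_ok))
  expect_equal(nrow(apply_validity_filters(tab3, "flyvac")), nrow(tab3))
})
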
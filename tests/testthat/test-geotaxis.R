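crit15 <- climber_criterion(15, 15)

test_that("climber proportion handles the all-or-none extremes", {
  # all 10 flies cross 15 cm at t = 10 s
  fast <- climb_kinematics(n_flies = 10, speed_mean = 1.5, speed_sd = 0,
                           pause_prob = 0, n_trials = 1,
                           trial_duration_s = 20, seed = 1)
  expect_equal(climber_proportion(simulate_climb_trajectories(fast),
                                  crit15)$prop, 1)
  # nobody leaves the base
  still <- climb_kinematics(n_flies = 10, pause_prob = 1, n_trials = 1,
                            trial_duration_s = 20, seed = 2)
  expect_equal(climber_proportion(simulate_climb_trajectories(still),
                                  crit15)$prop, 0)
})

test_that("a constructed 6-of-10 split gives exactly 0.6", {
  kin <- climb_kinematics(n_flies = 10, speed_sd = 0, pause_prob = 0,
                          n_trials = 1, trial_duration_s = 20, seed = 3)
  tr <- simulate_climb_trajectories(kin)
  # six flies at 1.2 cm/s (reach 15 cm by 12.5 s), four at 0.5 cm/s (don't)
  speed <- ifelse(tr$fly <= 6, 1.2, 0.5)
  tr$height_cm <- pmin(speed * tr$time_in_trial_s, 20)
  expect_equal(climber_proportion(tr, crit15)$prop, 0.6)
})

test_that("climber proportion is invariant to finer frame subsampling", {
  kin <- climb_kinematics(n_flies = 10, n_trials = 2, trial_duration_s = 20,
                          seed = 4)
  tr <- simulate_climb_trajectories(kin)
  full <- climber_proportion(tr, crit15)
  # keep every 2nd frame (still finer than the crossing resolution)
  thin <- tr[round(tr$time_in_trial_s * 10) %% 2 == 0, ]
  expect_equal(climber_proportion(thin, crit15), full)
})

test_that("the proportion timecourse is a non-decreasing reach curve", {
  kin <- climb_kinematics(n_flies = 10, n_trials = 3, trial_duration_s = 20,
                          seed = 5)
  tr <- simulate_climb_trajectories(kin)
  tc <- proportion_timecourse(tr, crit15)
  expect_true(all(diff(tc$mean_prop) >= -1e-12))
  expect_true(all(tc$lower >= 0 & tc$upper <= 1))
  expect_equal(tc$mean_prop[tc$time_in_trial_s == 0], 0)
  expect_equal(tc$lower[tc$time_in_trial_s == 0], 0)
  # consistency with the scalar criterion at the 15-s readout
  at15 <- tc$mean_prop[tc$time_in_trial_s == 15]
  expect_equal(at15, mean(climber_proportion(tr, crit15)$prop),
               tolerance = 1e-12)
})

test_that("a saturated timecourse pins the Wilson interval at 1", {
  kin <- climb_kinematics(n_flies = 5, pause_prob = 1, n_trials = 1,
                          trial_duration_s = 2, seed = 6)
  tr <- simulate_climb_trajectories(kin)
  tr$height_cm <- 18  # everyone above the line at every frame
  tc <- proportion_timecourse(tr, crit15, group_size = 5)
  expect_true(all(tc$mean_prop == 1))
  expect_true(all(tc$upper == 1))
  expect_true(all(tc$lower > 0.4))
})

test_that("mean height timecourse averages tubes then replicates", {
  kin <- climb_kinematics(n_flies = 4, pause_prob = 1, n_trials = 1,
                          trial_duration_s = 1, seed = 7)
  tr <- simulate_climb_trajectories(kin, n_tubes = 2)
  tr$height_cm <- ifelse(tr$tube == 1, 0, 10)
  mh <- mean_height_timecourse(tr)
  expect_true(all(mh$mean_cm == 5))
  expect_true(all(abs(mh$sd_cm - sd(c(0, 10))) < 1e-12))
  expect_true(all(mh$n == 2))
  # all flies at one height: zero spread
  tr$height_cm <- 7
  mh2 <- mean_height_timecourse(tr)
  expect_true(all(mh2$mean_cm == 7) && all(mh2$sd_cm == 0))
})

test_that("tube means match ground truth on simulated data", {
  kin <- climb_kinematics(n_flies = 10, n_trials = 1, trial_duration_s = 10,
                          seed = 8)
  tr <- simulate_climb_trajectories(kin)
  hm <- frame_mean_heights(tr)
  # direct average over the truth at one probe frame
  probe <- tr[tr$frame == 50, ]
  expect_equal(hm$Ycm[hm$frame == 50], mean(probe$height_cm))
  expect_true(all(hm$n_detected == 10))
})
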
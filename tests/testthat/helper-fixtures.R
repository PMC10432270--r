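# Shared fixture builders. Everything is generated in code at test time.

# A small single-tube rendered recording with ground truth.
tiny_video <- function(n_flies = 3, n_trials = 1, trial_duration_s = 3,
                       seed = 1, noise_sd = 3, width = 120, height = 180,
                       ...) {
  kin <- climb_kinematics(n_flies = n_flies, n_trials = n_trials,
                          trial_duration_s = trial_duration_s, seed = seed,
                          ...)
  truth <- simulate_climb_trajectories(kin)
  spec <- video_spec(width = width, height = height, n_tubes = 1,
                     noise_sd = noise_sd)
  vid <- render_video(truth, spec, seed = seed + 1)
  c(vid, list(kin = kin))
}

# Draw one filled ellipse (dark on bright) directly into a matrix; an
# independent path from render_video for detector tests. Returns the frame
# and the pixel mask.
blob_frame <- function(cx, cy, a, b, dims = c(60, 60), bg = 200, fly = 40) {
  fr <- matrix(bg, dims[1], dims[2])
  rr <- outer(seq_len(dims[1]), rep(1, dims[2]))
  cc <- outer(rep(1, dims[1]), seq_len(dims[2]))
  mask <- ((cc - cx) / b)^2 + ((rr - cy) / a)^2 <= 1
  fr[mask] <- fly
  list(frame = fr, mask = mask)
}

# Independent regionprops oracle for the geometry-gate tests (kept separate
# from the package's implementation on purpose).
oracle_props <- function(mask) {
  idx <- which(mask)
  y <- (idx - 1) %% nrow(mask) + 1
  x <- (idx - 1) %/% nrow(mask) + 1
  n <- length(idx)
  mx <- mean(x); my <- mean(y)
  uxx <- sum((x - mx)^2) / n + 1 / 12
  uyy <- sum((y - my)^2) / n + 1 / 12
  uxy <- sum((x - mx) * (y - my)) / n
  com <- sqrt((uxx - uyy)^2 + 4 * uxy^2)
  list(x = mx, y = my, area = n,
       major = 2 * sqrt(2) * sqrt(uxx + uyy + com),
       minor = 2 * sqrt(2) * sqrt(max(uxx + uyy - com, 0)))
}

# Simulated two-group climbing experiment (truth only, no rendering) with
# its design table; the fast path for statistical tests.
climb_experiment <- function(n_tubes = 15, effect = 1, seed = NULL, ...) {
  k1 <- climb_kinematics(n_flies = 10, exposure_effect = 1, seed = seed, ...)
  t1 <- simulate_climb_trajectories(k1, n_tubes = n_tubes)
  k2 <- climb_kinematics(n_flies = 10, exposure_effect = effect,
                         seed = if (is.null(seed)) NULL else seed + 1, ...)
  t2 <- simulate_climb_trajectories(k2, n_tubes = n_tubes)
  t2$tube <- t2$tube + n_tubes
  tab <- rbind(t1, t2)
  design <- data.frame(tube = seq_len(2 * n_tubes),
                       id = paste0("id", seq_len(2 * n_tubes)),
                       Exposure = rep(c("sham", "exposed"), each = n_tubes))
  list(tab = tab, design = design)
}
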
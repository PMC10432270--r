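#' Climbing-kinematics parameters
#'
#' Bundles the parameters of the stochastic climb model used to generate
#' ground-truth negative-geotaxis trajectories. Each fly receives a base
#' climbing speed drawn once from `Normal(speed_mean * exposure_effect,
#' speed_sd)` (clipped at 0); at each frame the fly either pauses (with
#' probability `pause_prob`) or moves upward by a per-step speed drawn from
#' `Normal(base, speed_sd)` (clipped at 0) times the frame interval. The
#' per-fly component produces the graded, non-bimodal split into faster and
#' slower climbers seen in real assays; with `speed_sd = 0` and
#' `pause_prob = 0` the climb is exactly deterministic at `speed_mean`.
#'
#' Defaults emulate a standard assay: 10 flies per tube, five 30-s trials
#' filmed at 10 frames per second, with all flies knocked to the tube base
#' at the start of every trial.
#'
#' @param n_flies flies per tube.
#' @param speed_mean mean climbing speed, cm/s.
#' @param speed_sd between-fly and per-step speed s.d., cm/s.
#' @param pause_prob per-frame probability that a fly does not move.
#' @param exposure_effect multiplicative factor on `speed_mean` for an
#'   "exposed" group; 1 means no effect (the null).
#' @param n_trials number of knockdown-climb trials.
#' @param trial_duration_s duration of each trial, seconds.
#' @param fps frames per second of the (virtual) camera.
#' @param seed optional integer seed.
#' @return list of class `climb_kinematics`.
#' @export
climb_kinematics <- function(n_flies = 10, speed_mean = 1.3, speed_sd = 0.5,
                             pause_prob = 0.2, exposure_effect = 1,
                             n_trials = 5, trial_duration_s = 30, fps = 10,
                             seed = NULL) {
  check_count(n_flies, "n_flies", min = 0L)
  check_prob(pause_prob, "pause_prob")
  check_pos(fps, "fps")
  check_pos(trial_duration_s, "trial_duration_s")
  check_count(n_trials, "n_trials")
  if (speed_sd < 0) stop("`speed_sd` must be >= 0", call. = FALSE)
  if (exposure_effect < 0)
    stop("`exposure_effect` must be >= 0", call. = FALSE)
  structure(list(n_flies = as.integer(n_flies), speed_mean = speed_mean,
                 speed_sd = speed_sd, pause_prob = pause_prob,
                 exposure_effect = exposure_effect,
                 n_trials = as.integer(n_trials),
                 trial_duration_s = trial_duration_s, fps = fps,
                 seed = seed),
            class = "climb_kinematics")
}

#' Simulate ground-truth climbing trajectories
#'
#' Generates per-frame heights for every fly in one or more tubes under the
#' kinematics of [climb_kinematics()]. At the start of each trial all flies
#' are reset to height 0 (the knockdown / vacuum pulse); heights are
#' monotone non-decreasing within a trial and confined to
#' `[0, tube_length_cm]`. A lateral position (`x_frac`, fraction of tube
#' width) is carried along for rendering: flies keep loose "lanes", modelled
#' as a mean-reverting jitter around an evenly spaced starting offset.
#'
#' @param kin a [climb_kinematics()] object.
#' @param tube_length_cm physical tube length in cm (default 20, i.e. a
#'   200 mm tube).
#' @param n_tubes number of tubes (independent replicates) to simulate.
#' @return data.frame of class `ground_truth` with columns `tube`, `trial`,
#'   `fly`, `frame` (0-based, global across trials), `time_s`,
#'   `time_in_trial_s`, `height_cm`, `x_frac`.
#' @examples
#' kin <- climb_kinematics(n_flies = 3, n_trials = 2, trial_duration_s = 5,
#'                         seed = 1)
#' truth <- simulate_climb_trajectories(kin)
#' range(truth$height_cm)
#' @export
simulate_climb_trajectories <- function(kin, tube_length_cm = 20,
                                        n_tubes = 1) {
  stopifnot(inherits(kin, "climb_kinematics"))
  check_pos(tube_length_cm, "tube_length_cm")
  n_tubes <- check_count(n_tubes, "n_tubes")
  nf <- as.integer(round(kin$trial_duration_s * kin$fps))
  if (nf < 1) stop("trial too short for one frame", call. = FALSE)
  dt <- 1 / kin$fps
  nfly <- kin$n_flies

  with_seed(kin$seed, {
    if (nfly == 0L) {
      out <- data.frame(tube = integer(), trial = integer(),
                        fly = integer(), frame = integer(),
                        height_cm = numeric(), x_frac = numeric(),
                        time_s = numeric(), time_in_trial_s = numeric())
    } else {
      # one column per (tube, trial, fly), frames along rows; everything is
      # drawn in one pass so large designs stay cheap
      ntr <- kin$n_trials
      tube_c <- rep(seq_len(n_tubes), each = ntr * nfly)
      trial_c <- rep(rep(seq_len(ntr), each = nfly), n_tubes)
      fly_c <- rep(seq_len(nfly), n_tubes * ntr)
      C <- length(tube_c)
      # per-fly base speed, shared across that fly's trials
      base <- pmax(0, rnorm(n_tubes * nfly,
                            kin$speed_mean * kin$exposure_effect,
                            kin$speed_sd))
      base_c <- base[(tube_c - 1L) * nfly + fly_c]
      if (nf == 1L) {
        h <- matrix(0, 1L, C)
      } else {
        sp <- matrix(pmax(rnorm((nf - 1L) * C,
                                rep(base_c, each = nf - 1L),
                                kin$speed_sd), 0), nf - 1L, C)
        moving <- matrix(runif((nf - 1L) * C) >= kin$pause_prob,
                         nf - 1L, C)
        inc <- sp * moving * dt
        # column-wise cumulative sums via one global cumsum (fast for many
        # columns): subtract each column's running offset
        cs <- cumsum(as.vector(inc))
        ends <- seq_len(C) * (nf - 1L)
        off <- rep(c(0, cs[ends[-C]]), each = nf - 1L)
        h <- rbind(0, matrix(cs - off, nf - 1L, C))
        h <- pmin(h, tube_length_cm)
      }
      # lateral jitter: AR(1) around each fly's lane centre
      lane <- (fly_c - 0.5) / nfly
      x <- matrix(0, nf, C)
      if (nf > 1L) {
        e <- matrix(rnorm((nf - 1L) * C, 0, 0.004), nf - 1L, C)
        for (i in 2:nf) x[i, ] <- 0.9 * x[i - 1L, ] + e[i - 1L, ]
      }
      xf <- pmin(pmax(sweep(x, 2L, lane, `+`), 0.03), 0.97)
      frame0 <- (rep(trial_c, each = nf) - 1L) * nf +
        rep.int(seq_len(nf) - 1L, C)
      out <- data.frame(tube = rep(tube_c, each = nf),
                        trial = rep(trial_c, each = nf),
                        fly = rep(fly_c, each = nf),
                        frame = frame0,
                        height_cm = as.vector(h),
                        x_frac = as.vector(xf))
      out$time_s <- out$frame / kin$fps
      out$time_in_trial_s <- (out$frame %% nf) / kin$fps
    }
    attr(out, "fps") <- kin$fps
    attr(out, "frames_per_trial") <- nf
    attr(out, "tube_length_cm") <- tube_length_cm
    attr(out, "n_flies") <- nfly
    class(out) <- c("ground_truth", class(out))
    out
  })
}
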
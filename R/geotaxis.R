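#' Climber criterion
#'
#' The binary criterion for a successful climb: reaching `height_cm`
#' (default 15 cm) within `time_s` (default 15 s, inclusive) of the
#' knockdown.
#'
#' @param height_cm height line, cm.
#' @param time_s time bound, s.
#' @param inclusive whether frames at exactly `time_s` count (default TRUE).
#' @return list of class `climber_criterion`.
#' @export
climber_criterion <- function(height_cm = 15, time_s = 15,
                              inclusive = TRUE) {
  check_pos(height_cm, "height_cm")
  check_pos(time_s, "time_s")
  structure(list(height_cm = height_cm, time_s = time_s,
                 inclusive = inclusive),
            class = "climber_criterion")
}

# valid, non-excluded rows of a track table (ground-truth tables have no
# valid/excluded columns and pass through whole)
usable_rows <- function(table) {
  keep <- rep(TRUE, nrow(table))
  if ("valid" %in% names(table)) keep <- keep & table$valid
  if ("excluded" %in% names(table)) keep <- keep & !table$excluded
  table[keep, , drop = FALSE]
}

# Fast grouped reduction: tube x frame cells (trial and within-trial time
# are constant within a cell). Returns the cell metadata plus rowsum()s of
# the value columns in `vals`.
cell_rowsum <- function(tab, vals) {
  tub <- match(tab$tube, sort(unique(tab$tube)))
  maxf <- max(tab$frame) + 1
  key <- (tub - 1) * maxf + tab$frame
  uk <- sort(unique(key))
  first <- match(uk, key)
  rs <- rowsum(vals, key, reorder = TRUE)
  data.frame(tube = tab$tube[first], trial = tab$trial[first],
             frame = tab$frame[first],
             time_in_trial_s = tab$time_in_trial_s[first], rs,
             row.names = NULL)
}

# per tube x trial x frame count of detections at/above the height line
above_line_counts_raw <- function(table, crit) {
  tab <- usable_rows(table)
  if (!nrow(tab))
    return(data.frame(tube = integer(), trial = integer(),
                      frame = integer(), time_in_trial_s = numeric(),
                      n_above = integer()))
  out <- cell_rowsum(tab, cbind(n_above = as.numeric(
    tab$height_cm >= crit$height_cm)))
  out$n_above <- as.integer(out$n_above)
  out
}

#' Proportion of climbers per tube and trial
#'
#' For each tube x trial, the proportion of the group that reached the
#' height line within the time bound. Group-mode tracking carries no per-fly
#' identity, so the count of flies that have "climbed" by time t is taken as
#' the running maximum over frames up to t of the number of detections at or
#' above the height line; the proportion is that maximum divided by the
#' group size.
#'
#' @param table a track table ([track_stack()], after
#'   [apply_validity_filters()]) or a ground-truth table.
#' @param crit a [climber_criterion()].
#' @param group_size number of flies per tube (10 in the gravity assay).
#' @return data.frame with columns `tube`, `trial`, `prop`.
#' @export
climber_proportion <- function(table, crit = climber_criterion(),
                               group_size = 10) {
  group_size <- check_count(group_size, "group_size")
  # only frames inside the time bound matter for the running maximum
  keep <- if (crit$inclusive) table$time_in_trial_s <= crit$time_s
          else table$time_in_trial_s < crit$time_s
  table <- table[keep, , drop = FALSE]
  cnt <- above_line_counts_raw(table, crit)
  cells <- unique(usable_rows(table)[, c("tube", "trial")])
  if (!nrow(cells))
    return(data.frame(tube = integer(), trial = integer(),
                      prop = numeric()))
  key <- paste(cnt$tube, cnt$trial, sep = "\r")
  mx <- vapply(split(cnt$n_above, key), max, numeric(1))
  ck <- paste(cells$tube, cells$trial, sep = "\r")
  n_above <- mx[ck]
  n_above[is.na(n_above)] <- 0
  out <- data.frame(tube = cells$tube, trial = cells$trial,
                    prop = pmin(n_above, group_size) / group_size)
  out <- out[order(out$tube, out$trial), ]
  rownames(out) <- NULL
  out
}

#' Timecourse of the proportion of flies reaching the height line
#'
#' For every within-trial time point, the proportion of flies that have
#' reached the height line by that time (the cumulative "reaching"
#' proportion, i.e. the running maximum of above-line counts per tube x
#' trial), averaged across replicates, with a Wilson score confidence
#' interval computed from the pooled counts. Evaluated at `time_s` this
#' equals the scalar [climber_proportion()] averaged over replicates.
#'
#' @inheritParams climber_proportion
#' @param conf confidence level of the Wilson interval.
#' @return data.frame with `time_in_trial_s`, `mean_prop`, `lower`, `upper`,
#'   `n_replicates`.
#' @export
proportion_timecourse <- function(table, crit = climber_criterion(),
                                  group_size = 10, conf = 0.95) {
  group_size <- check_count(group_size, "group_size")
  cnt <- above_line_counts_raw(table, crit)
  if (!nrow(cnt))
    return(data.frame(time_in_trial_s = numeric(), mean_prop = numeric(),
                      lower = numeric(), upper = numeric(),
                      n_replicates = integer()))
  times <- sort(unique(cnt$time_in_trial_s))
  cells <- split(cnt, paste(cnt$tube, cnt$trial))
  # running max per replicate on the common time grid
  mat <- vapply(cells, function(d) {
    v <- rep(NA_real_, length(times))
    v[match(d$time_in_trial_s, times)] <- d$n_above
    v[is.na(v)] <- 0
    pmin(cummax(v), group_size)
  }, numeric(length(times)))
  mat <- matrix(mat, nrow = length(times))
  props <- mat / group_size
  pooled <- wilson_ci(rowSums(mat), ncol(mat) * group_size, conf)
  data.frame(time_in_trial_s = times,
             mean_prop = rowMeans(props),
             lower = pooled$lower, upper = pooled$upper,
             n_replicates = ncol(mat))
}

#' Per-frame mean height per tube
#'
#' Averages the heights of all detections in each tube at each frame (the
#' group assay cannot follow individual flies, so the tube average is the
#' tracked quantity). Frames with no detections in a tube are missing, not
#' zero.
#'
#' @param table a track table or ground-truth table.
#' @return data.frame with `tube`, `trial`, `frame`, `time_in_trial_s`,
#'   `Ycm` (mean height, cm) and `n_detected`.
#' @export
frame_mean_heights <- function(table) {
  tab <- usable_rows(table)
  if (!nrow(tab))
    return(data.frame(tube = integer(), trial = integer(),
                      frame = integer(), time_in_trial_s = numeric(),
                      Ycm = numeric(), n_detected = integer()))
  agg <- cell_rowsum(tab, cbind(h_sum = tab$height_cm, n_detected = 1))
  agg$Ycm <- agg$h_sum / agg$n_detected
  agg$n_detected <- as.integer(agg$n_detected)
  agg$h_sum <- NULL
  agg
}

#' Mean +/- s.d. height timecourse across replicates
#'
#' Per within-trial time point: tube-level mean heights are averaged across
#' replicates (tube x trial) and their standard deviation reported, the form
#' in which climbing curves are usually displayed.
#'
#' @param table a track table or ground-truth table.
#' @return data.frame with `time_in_trial_s`, `mean_cm`, `sd_cm`, `n`.
#' @export
mean_height_timecourse <- function(table) {
  hm <- frame_mean_heights(table)
  if (!nrow(hm))
    return(data.frame(time_in_trial_s = numeric(), mean_cm = numeric(),
                      sd_cm = numeric(), n = integer()))
  out <- aggregate(Ycm ~ time_in_trial_s, data = hm,
                   FUN = function(v) c(m = mean(v), s = sd(v), n = length(v)))
  data.frame(time_in_trial_s = out$time_in_trial_s,
             mean_cm = out$Ycm[, "m"],
             sd_cm = out$Ycm[, "s"],
             n = as.integer(out$Ycm[, "n"]))
}
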
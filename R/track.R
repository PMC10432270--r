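#' Track a full recording
#'
#' Runs the complete tracking pipeline on a frame stack: optional
#' preprocessing (gamma + unsharp), two-pass background estimation once per
#' recording, then per frame intensity scaling against the background over
#' the calibration regions, background subtraction, opening, binarisation
#' and geometry-gated blob detection. Detections are assigned to tubes by
#' ROI, their centroids converted to physical height above the tube base,
#' and trial/time annotations added.
#'
#' Detections falling outside every tube ROI are kept in the table but
#' flagged invalid (`excluded_reason = "outside_roi"`), not dropped, so
#' false-positive rates can be audited.
#'
#' @param stack a [frame_stack()].
#' @param params a [segmentation_params()].
#' @param tube_rois data.frame with columns `tube`, `x0`, `x1`, `y0`, `y1`,
#'   `base_row` (as produced by [video_spec()]).
#' @param cm_per_px centimetres per pixel along the tube axis.
#' @param trial_start_frames 0-based frame indices at which trials start
#'   (default: the whole recording is one trial).
#' @param calib_regions calibration regions for [scale_to_background()];
#'   `NULL` skips intensity scaling.
#' @param tube_length_cm tube length; heights are clipped to
#'   `[0, tube_length_cm]`.
#' @param preprocess apply [preprocess_frames()] first (default TRUE).
#' @return a track table: data.frame with columns `frame`, `time_s`,
#'   `trial`, `time_in_trial_s`, `tube`, `x_px`, `y_px`, `area`, `major`,
#'   `minor`, `height_cm`, `valid`, `excluded`, `excluded_reason`. The
#'   background model is attached as attribute `"background"`, the frame
#'   rate as `"fps"`.
#' @export
track_stack <- function(stack, params = segmentation_params(), tube_rois,
                        cm_per_px, trial_start_frames = 0L,
                        calib_regions = NULL, tube_length_cm = 20,
                        preprocess = TRUE) {
  stopifnot(inherits(stack, "frame_stack"))
  req <- c("tube", "x0", "x1", "y0", "y1", "base_row")
  if (!all(req %in% names(tube_rois)))
    stop("`tube_rois` must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  check_pos(cm_per_px, "cm_per_px")
  if (roi_overlap(tube_rois))
    stop("tube ROIs must be disjoint", call. = FALSE)
  trial_start_frames <- sort(as.integer(trial_start_frames))
  if (trial_start_frames[1] != 0L)
    stop("`trial_start_frames` must start at frame 0", call. = FALSE)

  if (preprocess) stack <- preprocess_frames(stack, params)
  bgm <- estimate_background(stack, params)

  rows <- vector("list", stack$n_frames)
  for (i in seq_len(stack$n_frames)) {
    fr <- stack$frames[[i]]
    if (!is.null(calib_regions))
      fr <- scale_to_background(fr, bgm, calib_regions)$image
    det <- detect_flies(fr, bgm, params)
    if (nrow(det)) det$frame <- i - 1L
    rows[[i]] <- det
  }
  tab <- do.call(rbind, rows[vapply(rows, nrow, integer(1)) > 0])
  if (is.null(tab))
    tab <- data.frame(x_px = numeric(), y_px = numeric(), area = numeric(),
                      major = numeric(), minor = numeric(),
                      frame = integer())

  # tube assignment by ROI containment
  tab$tube <- rep(NA_integer_, nrow(tab))
  for (k in seq_len(nrow(tube_rois))) {
    inside <- tab$x_px >= tube_rois$x0[k] & tab$x_px <= tube_rois$x1[k] &
      tab$y_px >= tube_rois$y0[k] & tab$y_px <= tube_rois$y1[k]
    tab$tube[inside] <- tube_rois$tube[k]
  }
  base_row <- tube_rois$base_row[match(tab$tube, tube_rois$tube)]
  tab$height_cm <- pmin(pmax((base_row - tab$y_px) * cm_per_px, 0),
                        tube_length_cm)
  tab$time_s <- tab$frame / stack$fps
  tab$trial <- findInterval(tab$frame, trial_start_frames)
  tab$time_in_trial_s <-
    (tab$frame - trial_start_frames[tab$trial]) / stack$fps
  tab$valid <- !is.na(tab$tube)
  tab$excluded <- !tab$valid
  tab$excluded_reason <- ifelse(tab$valid, "", "outside_roi")

  ord <- c("frame", "time_s", "trial", "time_in_trial_s", "tube", "x_px",
           "y_px", "area", "major", "minor", "height_cm", "valid",
           "excluded", "excluded_reason")
  tab <- tab[, ord]
  rownames(tab) <- NULL
  attr(tab, "background") <- bgm
  attr(tab, "fps") <- stack$fps
  class(tab) <- c("track_table", class(tab))
  tab
}

roi_overlap <- function(rois) {
  n <- nrow(rois)
  if (n < 2L) return(FALSE)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (rois$x0[i] <= rois$x1[j] && rois$x0[j] <= rois$x1[i] &&
        rois$y0[i] <= rois$y1[j] && rois$y0[j] <= rois$y1[i]) return(TRUE)
  }
  FALSE
}

#' Apply assay-specific validity filters
#'
#' Implements the exclusion rules used before any statistic is computed.
#' In `"gravity"` mode (group assay, nominally 10 flies per tube) every
#' frame in which a tube yields more than `max_flies` detections is excluded
#' as containing false positives. In `"flyvac"` mode (single-fly tubes) a
#' fly is dropped entirely if, in any trial, it was not drawn to the bottom
#' by the vacuum pulse (its height at the first post-pulse frame exceeds
#' `bottom_threshold_cm`), or if it showed no mobility (zero displacement)
#' in all trials.
#'
#' @param table a track table from [track_stack()] (or any data.frame with
#'   the same columns).
#' @param mode `"gravity"` or `"flyvac"`.
#' @param max_flies maximum plausible detections per tube per frame
#'   (gravity mode).
#' @param bottom_threshold_cm height below which a fly counts as "at the
#'   bottom" right after the vacuum pulse (flyvac mode).
#' @return the table with `excluded` / `excluded_reason` updated (flyvac
#'   drops offending flies' rows entirely, mirroring "data ... were
#'   discarded").
#' @export
apply_validity_filters <- function(table, mode = c("gravity", "flyvac"),
                                   max_flies = 10,
                                   bottom_threshold_cm = 1) {
  mode <- match.arg(mode)
  if (!all(c("frame", "tube", "trial", "height_cm") %in% names(table)))
    stop("track table is missing required columns", call. = FALSE)
  if (!nrow(table)) return(table)
  if (anyNA(table$trial))
    stop("trial annotation missing from track table", call. = FALSE)

  if (mode == "gravity") {
    ok <- table$valid & !table$excluded
    key <- paste(table$frame, table$tube)
    counts <- table(key[ok])
    bad <- names(counts)[counts > max_flies]
    hit <- ok & key %in% bad
    table$excluded[hit] <- TRUE
    table$excluded_reason[hit] <- "too_many_detections"
    return(table)
  }

  # flyvac: one fly per tube; judge each tube over its trials
  drop_tube <- c()
  for (tb in unique(table$tube[!is.na(table$tube)])) {
    sub <- table[table$tube %in% tb & table$valid & !table$excluded, ]
    if (!nrow(sub)) next
    sucked <- TRUE; moved <- FALSE
    for (tr in sort(unique(sub$trial))) {
      str <- sub[sub$trial == tr, ]
      first <- str[which.min(str$frame), ]
      if (first$height_cm > bottom_threshold_cm) sucked <- FALSE
      if (diff(range(str$height_cm)) > 0) moved <- TRUE
    }
    if (!sucked || !moved) drop_tube <- c(drop_tube, tb)
  }
  if (length(drop_tube))
    table <- table[!(table$tube %in% drop_tube), , drop = FALSE]
  rownames(table) <- NULL
  table
}
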
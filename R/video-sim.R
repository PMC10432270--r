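#' Video-rendering specification for synthetic climbing assays
#'
#' Describes the geometry and photometry of a synthetic backlit recording:
#' flies appear as dark ellipses against a bright background. Tubes are
#' vertical, evenly spaced rectangles separated by gaps that are
#' inaccessible to the flies; those gaps serve as the calibration regions
#' for per-frame intensity scaling. The rendered background carries a smooth
#' illumination gradient, and each frame receives a multiplicative gain
#' flicker plus Gaussian sensor noise, which is what makes the per-frame
#' linear intensity match a meaningful (and necessary) step.
#'
#' The default blob semi-axes (5 x 2.5 px) give an ellipse with
#' MATLAB-convention axis lengths of about 10 and 5 px and an area of about
#' 39 px^2 -- a fly-sized silhouette well inside the detection gates.
#'
#' @param width,height frame size in pixels (defaults 1280 x 1024; tests use
#'   much smaller frames).
#' @param n_tubes number of tubes laid out side by side.
#' @param tube_width_px,gap_px width of each tube ROI and of the gaps
#'   between/around tubes, in pixels.
#' @param margin_top_px,margin_bottom_px vertical margins above the tube top
#'   and below the tube base.
#' @param background_level,fly_level background and fly grey values
#'   (8-bit; `fly_level < background_level`).
#' @param noise_sd Gaussian sensor noise s.d., grey levels.
#' @param gradient_amp peak-to-centre amplitude of the static illumination
#'   gradient, grey levels.
#' @param flicker_sd s.d. of the per-frame multiplicative gain (around 1).
#' @param blob_semimajor,blob_semiminor fly ellipse semi-axes in pixels
#'   (major axis vertical, along the climb).
#' @param tube_length_cm physical tube length represented by the ROI height.
#' @return list of class `video_spec` with derived fields `tube_rois`
#'   (data.frame: `tube`, `x0`, `x1`, `y0`, `y1`, `base_row`),
#'   `cm_per_px`, and `calib_regions` (list of rectangles between tubes).
#' @export
video_spec <- function(width = 1280, height = 1024, n_tubes = 3,
                       tube_width_px = NULL, gap_px = NULL,
                       margin_top_px = 12, margin_bottom_px = 12,
                       background_level = 230, fly_level = 30,
                       noise_sd = 3, gradient_amp = 12, flicker_sd = 0.01,
                       blob_semimajor = 5, blob_semiminor = 2.5,
                       tube_length_cm = 20) {
  check_count(width, "width"); check_count(height, "height")
  n_tubes <- check_count(n_tubes, "n_tubes")
  if (fly_level >= background_level)
    stop("`fly_level` must be darker than `background_level`", call. = FALSE)
  if (is.null(gap_px)) gap_px <- max(8L, round(width / (4 * n_tubes + 1)))
  if (is.null(tube_width_px))
    tube_width_px <- floor((width - (n_tubes + 1) * gap_px) / n_tubes)
  if (tube_width_px < 4 * blob_semiminor)
    stop("tubes too narrow for the fly blob", call. = FALSE)
  y0 <- margin_top_px + 1
  y1 <- height - margin_bottom_px
  if (y1 - y0 < 10) stop("frame too short for a tube", call. = FALSE)
  x0 <- gap_px + (seq_len(n_tubes) - 1L) * (tube_width_px + gap_px) + 1
  rois <- data.frame(tube = seq_len(n_tubes), x0 = x0,
                     x1 = x0 + tube_width_px - 1L, y0 = y0, y1 = y1,
                     base_row = y1)
  calib <- vector("list", n_tubes + 1L)
  gx0 <- c(1L, rois$x1 + 1L)
  gx1 <- c(rois$x0 - 1L, width)
  for (i in seq_along(gx0))
    calib[[i]] <- c(x0 = gx0[i], x1 = gx1[i], y0 = 1L, y1 = height)
  structure(list(width = as.integer(width), height = as.integer(height),
                 n_tubes = n_tubes, tube_rois = rois,
                 calib_regions = calib,
                 background_level = background_level, fly_level = fly_level,
                 noise_sd = noise_sd, gradient_amp = gradient_amp,
                 flicker_sd = flicker_sd,
                 blob_semimajor = blob_semimajor,
                 blob_semiminor = blob_semiminor,
                 tube_length_cm = tube_length_cm,
                 cm_per_px = tube_length_cm / (y1 - y0)),
            class = "video_spec")
}

# Static (noise-free, flicker-free) background image implied by a spec:
# uniform level plus a smooth separable illumination gradient.
render_background <- function(spec) {
  r <- seq_len(spec$height); c <- seq_len(spec$width)
  gy <- cos(pi * (r - 1) / max(1, spec$height - 1) - pi / 2)  # bright middle
  gx <- cos(pi * (c - 1) / max(1, spec$width - 1) - pi / 2)
  spec$background_level +
    spec$gradient_amp * (outer(gy, gx) - 0.5)
}

# Pixel coordinates of the ellipse mask around (cx, cy); a = vertical
# (major) semi-axis, b = horizontal (minor). 1-based pixel-centre coords.
ellipse_pixels <- function(cx, cy, a, b) {
  rr <- seq(floor(cy - a), ceiling(cy + a))
  cc <- seq(floor(cx - b), ceiling(cx + b))
  grid <- expand.grid(r = rr, c = cc)
  keep <- ((grid$c - cx) / b)^2 + ((grid$r - cy) / a)^2 <= 1
  grid[keep, , drop = FALSE]
}

#' Render a synthetic climbing video from ground-truth trajectories
#'
#' Draws every fly of a [simulate_climb_trajectories()] table as a dark
#' ellipse at its true position, over a backlit background with an
#' illumination gradient, per-frame gain flicker and Gaussian sensor noise,
#' then quantises to 8-bit grey levels. The returned ground truth gains
#' pixel coordinates (`x_px`, `y_px`) so tracking output can be scored
#' against it.
#'
#' @param truth a `ground_truth` data.frame (one or more tubes; tube ids
#'   must exist in `spec$tube_rois`).
#' @param spec a [video_spec()].
#' @param seed integer seed controlling noise and flicker.
#' @param n_frames number of frames to render; defaults to the span of the
#'   ground truth. Must be given when `truth` has no rows (an empty tube).
#' @return list with elements `stack` (a [frame_stack()]), `truth` (input
#'   plus `x_px`, `y_px`), `background` (the noise-free background image)
#'   and `spec`.
#' @examples
#' kin <- climb_kinematics(n_flies = 2, n_trials = 1, trial_duration_s = 2,
#'                         seed = 1)
#' truth <- simulate_climb_trajectories(kin)
#' spec <- video_spec(width = 120, height = 160, n_tubes = 1)
#' vid <- render_video(truth, spec, seed = 1)
#' dim(vid$stack$frames[[1]])
#' @export
render_video <- function(truth, spec, seed = NULL, n_frames = NULL) {
  stopifnot(inherits(spec, "video_spec"))
  fps <- attr(truth, "fps")
  if (is.null(fps)) stop("`truth` lacks an fps attribute", call. = FALSE)
  if (nrow(truth) && !all(truth$tube %in% spec$tube_rois$tube))
    stop("ground truth references tubes absent from the spec", call. = FALSE)

  rois <- spec$tube_rois
  idx <- match(truth$tube, rois$tube)
  x_px <- rois$x0[idx] + truth$x_frac * (rois$x1[idx] - rois$x0[idx])
  y_px <- rois$base_row[idx] - truth$height_cm / spec$cm_per_px
  a <- spec$blob_semimajor; b <- spec$blob_semiminor
  if (nrow(truth) &&
      (any(y_px - a < 1) || any(y_px + a > spec$height) ||
       any(x_px - b < 1) || any(x_px + b > spec$width)))
    stop("fly blob would exceed frame bounds; enlarge margins", call. = FALSE)

  truth$x_px <- x_px
  truth$y_px <- y_px
  bg <- render_background(spec)
  if (is.null(n_frames))
    n_frames <- if (nrow(truth)) max(truth$frame) + 1L else 0L
  if (n_frames == 0L)
    stop("empty ground truth: supply `n_frames` to render fly-free frames",
         call. = FALSE)

  by_frame <- split(seq_len(nrow(truth)), truth$frame)
  frames <- vector("list", n_frames)
  with_seed(seed, {
    for (f in seq_len(n_frames) - 1L) {
      img <- bg
      rows <- by_frame[[as.character(f)]]
      for (i in rows) {
        px <- ellipse_pixels(truth$x_px[i], truth$y_px[i], a, b)
        img[cbind(px$r, px$c)] <- spec$fly_level
      }
      gain <- 1 + rnorm(1, 0, spec$flicker_sd)
      img <- gain * img +
        matrix(rnorm(length(img), 0, spec$noise_sd),
               nrow(img), ncol(img))
      frames[[f + 1L]] <- matrix(pmin(pmax(round(img), 0), 255),
                                 nrow(img), ncol(img))
    }
  })
  list(stack = frame_stack(frames, fps = fps), truth = truth,
       background = bg, spec = spec)
}
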
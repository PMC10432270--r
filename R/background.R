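#' Two-pass background estimation
#'
#' Builds a per-pixel estimate of the scene without flies. Pass 1 takes the
#' arithmetic mean of all frames. Pass 2 recomputes each pixel's mean using
#' only frames whose intensity does not fall short of the pass-1 mean by
#' more than `exclusion_fraction` (default 20%) -- frames in which the dark
#' fly silhouette covered the pixel are thereby dropped. Pixels to which too
#' few frames contributed (`min_reliable_fraction`, default: every frame
#' must contribute) are marked unreliable and filled from reliable
#' neighbours by an iterated moving average over a `fill_window`-pixel
#' neighbourhood. The filled image is finally convolved with a 2-D Gaussian
#' (`smooth_sigma`, default 1 px); the smoothed image is the background used
#' downstream.
#'
#' @param stack a [frame_stack()] (at least 2 frames).
#' @param params a [segmentation_params()].
#' @return list of class `background_model` with fields `background` (the
#'   smoothed estimate), `raw_background` (pre-smoothing, post-fill),
#'   `reliability_mask` (logical matrix), `n_contributing` (integer matrix)
#'   and `n_frames`.
#' @examples
#' st <- frame_stack(replicate(4, matrix(200, 8, 8), simplify = FALSE))
#' bg <- estimate_background(st)
#' range(bg$background)
#' @export
estimate_background <- function(stack, params = segmentation_params()) {
  stopifnot(inherits(stack, "frame_stack"),
            inherits(params, "segmentation_params"))
  n <- stack$n_frames
  if (n < 2L) stop("background estimation needs at least 2 frames",
                   call. = FALSE)

  # pass 1: arithmetic mean of all frames
  s <- Reduce(`+`, stack$frames)
  m1 <- s / n

  # pass 2: per-pixel mean over frames not falling short of m1 by more
  # than the exclusion fraction
  thr <- (1 - params$exclusion_fraction) * m1
  s2 <- matrix(0, nrow(m1), ncol(m1))
  cnt <- matrix(0L, nrow(m1), ncol(m1))
  for (f in stack$frames) {
    keep <- f >= thr
    s2 <- s2 + f * keep
    cnt <- cnt + keep
  }
  reliable <- cnt >= params$min_reliable_fraction * n & cnt > 0L
  if (!any(reliable))
    stop("no reliable background pixels: every pixel lost frames",
         call. = FALSE)
  bg <- ifelse(cnt > 0L, s2 / pmax(cnt, 1L), NA_real_)
  bg[!reliable] <- NA_real_

  # fill unreliable pixels from reliable neighbours: moving average over a
  # fill_window neighbourhood, iterated until every pixel has a value
  if (anyNA(bg)) {
    r <- max(1L, as.integer(ceiling(params$fill_window / 2)))
    r <- min(r, as.integer((min(dim(bg)) - 1) %/% 2))  # kernel must fit
    kern <- matrix(1, 2L * r + 1L, 2L * r + 1L)
    repeat {
      known <- !is.na(bg)
      if (all(known)) break
      vals <- bg; vals[!known] <- 0
      num <- as.matrix(EBImage::filter2(vals, kern, boundary = "replicate"))
      den <- as.matrix(EBImage::filter2(known * 1, kern,
                                        boundary = "replicate"))
      fill <- !known & den > 1e-9
      if (!any(fill))
        stop("background fill failed to propagate", call. = FALSE)
      bg[fill] <- num[fill] / den[fill]
    }
  }

  smoothed <- gaussian_blur(bg, params$smooth_sigma)
  structure(list(background = smoothed, raw_background = bg,
                 reliability_mask = reliable, n_contributing = cnt,
                 n_frames = n),
            class = "background_model")
}

#' @export
print.background_model <- function(x, ...) {
  cat(sprintf(
    "<background_model> %d x %d px, %d frames, %.1f%% pixels reliable\n",
    ncol(x$background), nrow(x$background), x$n_frames,
    100 * mean(x$reliability_mask)))
  invisible(x)
}
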
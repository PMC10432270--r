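#' Segmentation and preprocessing parameters
#'
#' All tunable constants of the tracking algorithm, with the defaults used
#' throughout: gamma correction 0.45 applied to normalised intensities,
#' unsharp masking with Gaussian radius 1.0 px and weight 0.93, a 20%
#' intensity-shortfall criterion for excluding fly-covered frames from the
#' second background pass, a 10-px moving-average window for filling
#' unreliable background pixels, 1-px Gaussian smoothing of the background,
#' grayscale opening with a disk of radius 2 px, and geometry gates that
#' keep only regions whose MATLAB-convention major axis lies in [4, 20] px,
#' minor axis in [3, 20] px and area in [8, 200] px^2.
#'
#' @param gamma gamma-correction exponent (applied as `out = in^gamma` on
#'   intensities normalised to [0, 1]).
#' @param unsharp_sigma Gaussian radius of the unsharp mask, px.
#' @param unsharp_weight unsharp mask weight.
#' @param exclusion_fraction a frame is dropped from the second background
#'   pass at a pixel when its intensity falls short of the first-pass mean
#'   by more than this fraction.
#' @param min_reliable_fraction minimum fraction of frames that must
#'   contribute to a pixel's second-pass mean for the pixel to count as
#'   reliable (1 = any excluded frame makes it unreliable).
#' @param fill_window moving-average window (px) used to fill unreliable
#'   background pixels from reliable neighbours.
#' @param smooth_sigma Gaussian s.d. (px) of the final background smoothing.
#' @param opening_disk_radius radius (px) of the disk structuring element
#'   for grayscale opening.
#' @param threshold_method `"otsu"` or `"fixed"` binarisation of the opened
#'   difference image.
#' @param threshold_value fixed threshold (grey levels) when
#'   `threshold_method = "fixed"`.
#' @param threshold_floor lower bound (grey levels) applied to the Otsu
#'   threshold so that fly-free frames do not binarise their own noise.
#' @param major_axis_range,minor_axis_range,area_range inclusive gates on
#'   region major/minor axis length (px) and area (px^2).
#' @return list of class `segmentation_params`.
#' @export
segmentation_params <- function(gamma = 0.45,
                                unsharp_sigma = 1.0,
                                unsharp_weight = 0.93,
                                exclusion_fraction = 0.20,
                                min_reliable_fraction = 1.0,
                                fill_window = 10,
                                smooth_sigma = 1.0,
                                opening_disk_radius = 2,
                                threshold_method = c("otsu", "fixed"),
                                threshold_value = 50,
                                threshold_floor = 8,
                                major_axis_range = c(4, 20),
                                minor_axis_range = c(3, 20),
                                area_range = c(8, 200)) {
  threshold_method <- match.arg(threshold_method)
  check_pos(gamma, "gamma")
  if (exclusion_fraction <= 0 || exclusion_fraction >= 1)
    stop("`exclusion_fraction` must be in (0, 1)", call. = FALSE)
  check_prob(min_reliable_fraction, "min_reliable_fraction")
  for (r in list(major_axis_range, minor_axis_range, area_range))
    if (length(r) != 2L || r[1] > r[2])
      stop("geometry ranges must be non-empty (lo <= hi)", call. = FALSE)
  structure(list(gamma = gamma, unsharp_sigma = unsharp_sigma,
                 unsharp_weight = unsharp_weight,
                 exclusion_fraction = exclusion_fraction,
                 min_reliable_fraction = min_reliable_fraction,
                 fill_window = fill_window, smooth_sigma = smooth_sigma,
                 opening_disk_radius = opening_disk_radius,
                 threshold_method = threshold_method,
                 threshold_value = threshold_value,
                 threshold_floor = threshold_floor,
                 major_axis_range = major_axis_range,
                 minor_axis_range = minor_axis_range,
                 area_range = area_range),
            class = "segmentation_params")
}

# Gaussian blur of a grey-level matrix (EBImage, replicated boundary).
gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  as.matrix(EBImage::gblur(m, sigma = sigma, boundary = "replicate"))
}

#' Contrast-enhance frames (gamma correction + unsharp masking)
#'
#' Applies, in order, gamma correction on intensities normalised to [0, 1]
#' (`out = in^gamma`, default gamma 0.45, which brightens and compresses the
#' highlights of a backlit scene) and an unsharp mask
#' (`out = in + weight * (in - Gaussian_sigma(in))`), then clips back to the
#' 8-bit range. With `gamma = 1` and `unsharp_weight = 0` the stack is
#' returned unchanged.
#'
#' @param stack a [frame_stack()].
#' @param params a [segmentation_params()].
#' @return a [frame_stack()] of preprocessed frames.
#' @export
preprocess_frames <- function(stack, params = segmentation_params()) {
  stopifnot(inherits(stack, "frame_stack"),
            inherits(params, "segmentation_params"))
  frames <- lapply(stack$frames, function(m) {
    v <- pmin(pmax(m / 255, 0), 1)
    if (params$gamma != 1) v <- v^params$gamma
    if (params$unsharp_weight != 0) {
      blur <- gaussian_blur(v, params$unsharp_sigma)
      v <- v + params$unsharp_weight * (v - blur)
    }
    pmin(pmax(v, 0), 1) * 255
  })
  frame_stack(frames, fps = stack$fps)
}
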
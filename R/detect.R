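# Grayscale morphology with a digital disc structuring element.
# Implemented as shifted pmin/pmax over the disc offsets (replicated
# borders), which is exact for any radius and keeps the disc convention
# explicit: offsets with dx^2 + dy^2 <= r^2.
disc_offsets <- function(radius) {
  r <- as.integer(radius)
  g <- expand.grid(dy = -r:r, dx = -r:r)
  g[g$dx^2 + g$dy^2 <= radius^2, , drop = FALSE]
}

shift_matrix <- function(m, dy, dx) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- pmin(pmax(seq_len(nr) + dy, 1L), nr)
  ci <- pmin(pmax(seq_len(nc) + dx, 1L), nc)
  m[ri, ci, drop = FALSE]
}

gray_erode <- function(m, offsets) {
  out <- NULL
  for (i in seq_len(nrow(offsets))) {
    s <- shift_matrix(m, offsets$dy[i], offsets$dx[i])
    out <- if (is.null(out)) s else pmin(out, s)
  }
  out
}

gray_dilate <- function(m, offsets) {
  out <- NULL
  for (i in seq_len(nrow(offsets))) {
    s <- shift_matrix(m, -offsets$dy[i], -offsets$dx[i])
    out <- if (is.null(out)) s else pmax(out, s)
  }
  out
}

gray_opening <- function(m, radius) {
  if (radius <= 0) return(m)
  off <- disc_offsets(radius)
  gray_dilate(gray_erode(m, off), off)
}

# Region properties of a label matrix: centroid, area and the
# MATLAB-regionprops ellipse-equivalent axis lengths from normalised second
# central moments (with the 1/12 pixel-variance correction). x = column,
# y = row, 1-based pixel centres.
region_properties <- function(labels) {
  n <- max(labels)
  if (n == 0L)
    return(data.frame(x_px = numeric(), y_px = numeric(), area = numeric(),
                      major = numeric(), minor = numeric()))
  idx <- which(labels > 0)
  lab <- labels[idx]
  y <- (idx - 1L) %% nrow(labels) + 1L
  x <- (idx - 1L) %/% nrow(labels) + 1L
  area <- tabulate(lab, n)
  sx <- tabulate_sum(lab, x, n); sy <- tabulate_sum(lab, y, n)
  cx <- sx / area; cy <- sy / area
  dx <- x - cx[lab]; dy <- y - cy[lab]
  uxx <- tabulate_sum(lab, dx * dx, n) / area + 1 / 12
  uyy <- tabulate_sum(lab, dy * dy, n) / area + 1 / 12
  uxy <- tabulate_sum(lab, dx * dy, n) / area
  common <- sqrt((uxx - uyy)^2 + 4 * uxy^2)
  major <- 2 * sqrt(2) * sqrt(uxx + uyy + common)
  minor <- 2 * sqrt(2) * sqrt(pmax(uxx + uyy - common, 0))
  data.frame(x_px = cx, y_px = cy, area = area, major = major,
             minor = minor)
}

# Sum `w` within integer bins 1..n (bins absent from `bin` get 0).
tabulate_sum <- function(bin, w, n) {
  res <- numeric(n)
  rs <- rowsum(w, group = bin, reorder = TRUE)
  res[as.integer(rownames(rs))] <- rs[, 1]
  res
}

#' Linearly rescale a frame to match the background
#'
#' Each frame of a recording is linearly scaled in intensity so that it
#' matches the background image over calibration regions that are
#' inaccessible to the flies (the gaps between tubes). The gain/offset are
#' obtained by least squares of `background ~ frame` over those regions
#' using the noise-free background as the clean regressor: fitting
#' `frame = alpha * background + beta` and inverting gives
#' `a = 1/alpha`, `b = -beta/alpha`, and the returned image is
#' `a * frame + b`.
#'
#' @param frame numeric matrix (grey levels).
#' @param background a [background_model()] or a background matrix.
#' @param calib_regions list of rectangles `c(x0, x1, y0, y1)` (1-based,
#'   inclusive) or a logical mask matrix.
#' @return list with `image` (the rescaled frame), `a`, `b`.
#' @export
scale_to_background <- function(frame, background, calib_regions) {
  bg <- if (inherits(background, "background_model"))
    background$background else background
  if (!identical(dim(frame), dim(bg)))
    stop("frame and background dimensions differ", call. = FALSE)
  mask <- calibration_mask(calib_regions, dim(frame))
  if (sum(mask) < 2L)
    stop("calibration region has fewer than 2 pixels", call. = FALSE)
  x <- bg[mask]; y <- frame[mask]
  vx <- var(x)
  if (!is.finite(vx) || vx < 1e-12)
    stop("degenerate calibration region: background is constant there",
         call. = FALSE)
  alpha <- cov(x, y) / vx
  if (!is.finite(alpha) || abs(alpha) < 1e-12)
    stop("degenerate intensity fit: frame uncorrelated with background",
         call. = FALSE)
  beta <- mean(y) - alpha * mean(x)
  a <- 1 / alpha
  b <- -beta / alpha
  list(image = a * frame + b, a = a, b = b)
}

calibration_mask <- function(calib_regions, dims) {
  if (is.matrix(calib_regions) && is.logical(calib_regions)) {
    if (!identical(dim(calib_regions), dims))
      stop("calibration mask dimensions differ from the frame",
           call. = FALSE)
    return(calib_regions)
  }
  mask <- matrix(FALSE, dims[1], dims[2])
  for (rg in calib_regions) {
    x0 <- max(1L, rg[["x0"]]); x1 <- min(dims[2], rg[["x1"]])
    y0 <- max(1L, rg[["y0"]]); y1 <- min(dims[1], rg[["y1"]])
    if (x1 >= x0 && y1 >= y0) mask[y0:y1, x0:x1] <- TRUE
  }
  mask
}

#' Detect flies in one background-subtracted frame
#'
#' Computes the difference `background - frame` (flies appear as bright
#' regions against a dark field), applies grayscale morphological opening
#' with a disk structuring element, binarises (Otsu threshold with a noise
#' floor, or a fixed value), labels connected regions (4-connectivity),
#' removes regions below the minimum area, and keeps only regions whose
#' ellipse-equivalent major axis, minor axis and area fall inside the
#' configured gates. Geometry gating is exact: a region violating any of
#' the three ranges never appears in the output.
#'
#' @param frame numeric matrix (grey levels), already intensity-scaled.
#' @param background a [background_model()] or background matrix (smoothed).
#' @param params a [segmentation_params()].
#' @return data.frame with one row per detection: `x_px`, `y_px`, `area`,
#'   `major`, `minor`.
#' @examples
#' bg <- matrix(200, 40, 40)
#' fr <- bg; fr[18:22, 19:21] <- 40   # a small dark blob
#' detect_flies(fr, bg, segmentation_params())
#' @export
detect_flies <- function(frame, background,
                         params = segmentation_params()) {
  bg <- if (inherits(background, "background_model"))
    background$background else background
  if (!identical(dim(frame), dim(bg)))
    stop("frame and background dimensions differ", call. = FALSE)

  diffim <- pmax(bg - frame, 0)
  opened <- gray_opening(diffim, params$opening_disk_radius)

  thr <- switch(params$threshold_method,
    fixed = params$threshold_value,
    otsu = {
      rng <- range(opened)
      if (rng[2] - rng[1] < 1e-9) Inf  # featureless difference image
      else {
        o <- EBImage::otsu(EBImage::Image(opened / 255,
                                          colormode = "Grayscale")) * 255
        max(o, params$threshold_floor)
      }
    })
  binary <- opened > thr
  if (!any(binary))
    return(data.frame(x_px = numeric(), y_px = numeric(), area = numeric(),
                      major = numeric(), minor = numeric()))
  labels <- EBImage::bwlabel(binary)
  props <- region_properties(as.matrix(labels))
  keep <- props$area >= params$area_range[1] &
    props$area <= params$area_range[2] &
    props$major >= params$major_axis_range[1] &
    props$major <= params$major_axis_range[2] &
    props$minor >= params$minor_axis_range[1] &
    props$minor <= params$minor_axis_range[2]
  out <- props[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
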
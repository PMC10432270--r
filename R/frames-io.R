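#' Frame stacks
#'
#' An ordered collection of 8-bit grayscale frames sharing one geometry and
#' timebase. Frames are stored as numeric matrices in grey levels (0-255),
#' rows indexed top to bottom (y increases downward), columns left to right;
#' frame indices are 0-based and `time = frame / fps`.
#'
#' @param frames list of numeric matrices with identical dimensions.
#' @param fps frames per second (> 0).
#' @return list of class `frame_stack` with fields `frames`, `fps`, `width`,
#'   `height`, `n_frames`.
#' @export
frame_stack <- function(frames, fps = 10) {
  stopifnot(is.list(frames), length(frames) >= 1)
  check_pos(fps, "fps")
  d <- dim(frames[[1]])
  ok <- vapply(frames, function(f)
    is.matrix(f) && is.numeric(f) && identical(dim(f), d), logical(1))
  if (!all(ok))
    stop("all frames must be numeric matrices of identical dimensions",
         call. = FALSE)
  structure(list(frames = frames, fps = fps,
                 width = d[2], height = d[1],
                 n_frames = length(frames)),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  cat(sprintf("<frame_stack> %d frames, %d x %d px, %.3g fps (%.1f s)\n",
              x$n_frames, x$width, x$height, x$fps, x$n_frames / x$fps))
  invisible(x)
}

#' Read and write frame stacks as PNG directories or multipage TIFF
#'
#' `write_frame_dir()` stores a stack as zero-padded 8-bit grayscale PNG
#' files (`frame_000000.png`, ...); `read_frame_dir()` reads them back in
#' order. `write_frames_tiff()` / `read_frames_tiff()` do the same with a
#' single multipage TIFF.
#'
#' @param stack a [frame_stack()].
#' @param dir directory for the PNG frames (created if missing).
#' @param path TIFF file path.
#' @param fps frames per second to attach on reading.
#' @return `read_*` return a [frame_stack()]; `write_*` return the
#'   directory/path invisibly.
#' @name frame_io
#' @export
write_frame_dir <- function(stack, dir) {
  stopifnot(inherits(stack, "frame_stack"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (i in seq_len(stack$n_frames)) {
    png::writePNG(stack$frames[[i]] / 255,
                  file.path(dir, sprintf("frame_%06d.png", i - 1L)))
  }
  invisible(dir)
}

#' @rdname frame_io
#' @export
read_frame_dir <- function(dir, fps = 10) {
  files <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  if (!length(files)) stop("no PNG frames found in ", dir, call. = FALSE)
  frames <- lapply(files, function(f) {
    m <- png::readPNG(f)
    if (length(dim(m)) == 3L) m <- m[, , 1]  # tolerate grey-as-RGB
    round(m * 255)
  })
  frame_stack(frames, fps = fps)
}

#' @rdname frame_io
#' @export
write_frames_tiff <- function(stack, path) {
  stopifnot(inherits(stack, "frame_stack"))
  tiff::writeTIFF(lapply(stack$frames, function(m) m / 255), path,
                  bits.per.sample = 8L)
  invisible(path)
}

#' @rdname frame_io
#' @export
read_frames_tiff <- function(path, fps = 10) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  frames <- lapply(pages, function(m) {
    if (length(dim(m)) == 3L) m <- m[, , 1]
    round(m * 255)
  })
  frame_stack(frames, fps = fps)
}

#' Read/write tabular results
#'
#' Plain-CSV readers and writers for the tables the pipeline exchanges:
#' track tables (one row per detection), choice sets (one row per maze run)
#' and ground truth.
#'
#' @param x data.frame to write.
#' @param path CSV path.
#' @name table_io
#' @export
write_table_csv <- function(x, path) {
  write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname table_io
#' @export
read_table_csv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
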
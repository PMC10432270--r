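#' Blind the condition labels of an experimental design
#'
#' Replaces the true treatment labels of a design table with opaque random
#' codes so the analyst cannot know the magnetic condition until the
#' analysis is complete. The code-to-label mapping (the key) is returned
#' separately and is meant to be written to its own file
#' ([write_blinding_key()]), protected by a salted hash so tampering is
#' detectable. All analysis functions accept coded labels transparently:
#' labels are opaque to the statistics, so blinded and unblinded analyses of
#' the same data give identical test results.
#'
#' @param design data.frame with a unique `id` column and one or more label
#'   columns.
#' @param label_cols columns holding the true treatment labels (default
#'   `"Exposure"` plus `"condition"` when present).
#' @param seed integer seed for the code assignment.
#' @return list with `design` (labels replaced by codes in a single
#'   `code` column, original label columns removed) and `key` (data.frame
#'   mapping `code` to the true labels, with a random `salt` and its `hash`
#'   as attributes).
#' @export
blind_labels <- function(design, label_cols = NULL, seed = NULL) {
  if (!"id" %in% names(design)) stop("`design` needs an `id` column",
                                     call. = FALSE)
  if (anyDuplicated(design$id))
    stop("duplicate ids in design", call. = FALSE)
  if (is.null(label_cols))
    label_cols <- intersect(c("Exposure", "condition"), names(design))
  if (!length(label_cols) || !all(label_cols %in% names(design)))
    stop("label columns not found in design", call. = FALSE)

  treat <- interaction(design[label_cols], drop = TRUE, sep = "|")
  lev <- levels(treat)
  with_seed(seed, {
    codes <- sprintf("T%03d", sample(999, length(lev)))
    salt <- paste(sample(c(letters, 0:9), 16, replace = TRUE),
                  collapse = "")
    ulab <- unique(cbind(design[label_cols],
                         .treat = as.character(treat)))
    ulab <- ulab[match(lev, ulab$.treat), label_cols, drop = FALSE]
    key <- cbind(data.frame(code = codes, stringsAsFactors = FALSE), ulab)
    key <- key[order(key$code), , drop = FALSE]
    rownames(key) <- NULL
    coded <- design
    coded$code <- codes[as.integer(treat)]
    coded[label_cols] <- NULL
    attr(key, "salt") <- salt
    attr(key, "hash") <- hash_object(list(salt = salt, key = key))
    list(design = coded, key = key)
  })
}

#' Restore true labels from a blinding key
#'
#' @param design_coded the coded design from [blind_labels()].
#' @param key the blinding key (from [blind_labels()] or
#'   [read_blinding_key()]).
#' @return the design with the true label columns restored and `code`
#'   removed.
#' @export
unblind_labels <- function(design_coded, key) {
  if (!"code" %in% names(design_coded))
    stop("design has no `code` column", call. = FALSE)
  h <- attr(key, "hash")
  if (!is.null(h) &&
      !identical(unname(h),
                 unname(hash_object(list(salt = attr(key, "salt"),
                                         key = key)))))
    stop("blinding key failed its integrity check", call. = FALSE)
  i <- match(design_coded$code, key$code)
  if (anyNA(i)) stop("codes in design missing from key", call. = FALSE)
  out <- design_coded
  for (cl in setdiff(names(key), "code")) out[[cl]] <- key[[cl]][i]
  out$code <- NULL
  out
}

#' Write / read a blinding key file
#'
#' The key is stored as JSON together with its salt and salted hash; the
#' hash is re-verified on read and by [unblind_labels()].
#'
#' @param key blinding key from [blind_labels()].
#' @param path JSON file path.
#' @name blinding_key_io
#' @export
write_blinding_key <- function(key, path) {
  payload <- list(salt = attr(key, "salt"), hash = unname(attr(key, "hash")),
                  key = key)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname blinding_key_io
#' @export
read_blinding_key <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  key <- as.data.frame(payload$key, stringsAsFactors = FALSE)
  attr(key, "salt") <- payload$salt
  expect <- unname(hash_object(list(salt = payload$salt, key = key)))
  if (!identical(expect, unname(payload$hash)))
    stop("blinding key failed its integrity check", call. = FALSE)
  attr(key, "hash") <- payload$hash
  key
}
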
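# File contracts: 8-bit RGB PNG images, single-channel 8-bit PNG label
# masks (integer class codes 0-4), CSV tables with a header row.

#' Read / write an 8-bit RGB core image as PNG
#'
#' @param path file path.
#' @param image `h x w x 3` integer array in `[0, 255]`.
#' @return `read_image` returns the integer array; `write_image`
#'   returns `path` invisibly.
#' @export
read_image <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 2L) {
    stop("expected an RGB image, found a single channel", call. = FALSE)
  }
  a <- a[, , 1:3, drop = FALSE] # drop alpha if present
  img <- array(as.integer(round(a * 255)), dim = dim(a))
  img
}

#' @rdname read_image
#' @export
write_image <- function(image, path) {
  assert_rgb_image(image)
  png::writePNG(image / 255, path)
  invisible(path)
}

#' Read / write an integer label mask as single-channel PNG
#'
#' Labels are stored directly as 8-bit grey levels (0-255), so the
#' five tissue classes round-trip exactly.
#'
#' @param path file path.
#' @param mask integer matrix.
#' @return `read_mask` returns an integer matrix; `write_mask` returns
#'   `path` invisibly.
#' @export
read_mask <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- a[, , 1L]
  m <- matrix(as.integer(round(a * 255)), nrow(a), ncol(a))
  m
}

#' @rdname read_mask
#' @export
write_mask <- function(mask, path) {
  m <- as.matrix(mask)
  storage.mode(m) <- "integer"
  if (min(m) < 0L || max(m) > 255L) {
    stop("mask labels must lie in [0, 255]", call. = FALSE)
  }
  png::writePNG(m / 255, path)
  invisible(path)
}

# Deterministic CSV writer: fixed options so identical inputs give
# byte-identical files.
write_table_csv <- function(df, path) {
  df <- as.data.frame(df)
  num <- vapply(df, is.numeric, logical(1L)) &
    !vapply(df, is.integer, logical(1L))
  df[num] <- lapply(df[num], function(x) signif(x, 10))
  write.csv(df, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}
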
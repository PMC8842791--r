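#' Read and write single-plane grayscale TIFF images
#'
#' Images are stored as 16-bit (or `bit_depth`-bit) unsigned TIFFs; in R they
#' are plain numeric matrices on the integer intensity scale
#' `[0, 2^bit_depth - 1]`. Label masks use the same container.
#'
#' @param path file path.
#' @param img numeric matrix of intensities in `[0, 2^bit_depth - 1]`.
#' @param bit_depth bits per sample (8 or 16).
#' @return `read_channel_tiff` returns a numeric matrix;
#'   `read_labels_tiff` an integer matrix; the writers return `path`
#'   invisibly.
#' @export
read_channel_tiff <- function(path) {
  m <- tiff::readTIFF(path, as.is = FALSE)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  round(m * 65535)
}

#' @rdname read_channel_tiff
#' @export
write_channel_tiff <- function(img, path, bit_depth = 16L) {
  check_image(img, "img")
  maxval <- 2^bit_depth - 1
  if (any(img < 0) || any(img > maxval))
    stop("pixel values outside [0, ", maxval, "]", call. = FALSE)
  scaled <- round(img) / 65535
  tiff::writeTIFF(scaled, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' @rdname read_channel_tiff
#' @export
read_labels_tiff <- function(path) {
  m <- read_channel_tiff(path)
  storage.mode(m) <- "integer"
  m
}

#' @rdname read_channel_tiff
#' @export
write_labels_tiff <- function(img, path) {
  if (max(img) > 65535) stop("more than 65535 labels", call. = FALSE)
  write_channel_tiff(img, path, bit_depth = 16L)
}

# CSV dialect: UTF-8, comma separator, '.' decimal, header row, missing
# values as empty fields.
write_csv_file <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

read_csv_file <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}
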
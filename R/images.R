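#' Read a directory of raster images as an image set
#'
#' Loads every PNG (and JPEG, via EBImage when available) file under `dir`,
#' recursively, into a list of numeric arrays on the canonical 8-bit scale
#' (values in 0..255). Grayscale images become H x W matrices; multi-channel
#' images H x W x C arrays.
#'
#' @param dir Directory containing image files.
#' @param pattern Filename regex, default PNG files.
#' @return A list of numeric arrays (class `synthzoo_image_set`), named by file.
#' @export
load_image_set <- function(dir, pattern = "\\.png$") {
  if (!dir.exists(dir)) {
    stop_synthzoo(sprintf("image directory not found: %s", dir), "synthzoo_io_error")
  }
  files <- sort(list.files(dir, pattern = pattern, recursive = TRUE,
                           full.names = TRUE, ignore.case = TRUE))
  imgs <- lapply(files, read_image)
  names(imgs) <- basename(files)
  structure(imgs, class = "synthzoo_image_set")
}

read_image <- function(path) {
  img <- png::readPNG(path)
  # drop a pure-alpha or redundant channel layout down to H x W or H x W x 3
  if (length(dim(img)) == 3L && dim(img)[3] == 4L) img <- img[, , 1:3, drop = TRUE]
  if (length(dim(img)) == 3L && dim(img)[3] == 1L) img <- img[, , 1]
  img * 255
}

#' Write one image to a PNG file
#'
#' Values are interpreted on the 8-bit 0..255 scale and clamped before writing.
#'
#' @param image Numeric matrix or H x W x C array, values in 0..255.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  img <- pmin(pmax(image / 255, 0), 1)
  png::writePNG(img, target = path)
  invisible(path)
}

# Average-pool a grayscale matrix onto a grid x grid raster (used by the toy
# feature extractor). Handles sizes not divisible by `grid` by binning indices.
average_pool <- function(mat, grid = 8L) {
  h <- nrow(mat)
  w <- ncol(mat)
  rbin <- ceiling(seq_len(h) / (h / grid))
  cbin <- ceiling(seq_len(w) / (w / grid))
  rbin <- pmin(rbin, grid)
  cbin <- pmin(cbin, grid)
  sums <- rowsum(mat, rbin)
  sums <- t(rowsum(t(sums), cbin))
  counts <- outer(tabulate(rbin, grid), tabulate(cbin, grid))
  sums / counts
}

# Collapse an image array to a grayscale matrix (mean over channels).
to_grayscale <- function(image) {
  if (length(dim(image)) == 3L) {
    apply(image, c(1, 2), mean)
  } else {
    image
  }
}

image_dims <- function(image) {
  d <- dim(image)
  if (length(d) == 2L) c(d, 1L) else d
}
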
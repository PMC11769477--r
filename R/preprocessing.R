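# Preprocessing: raw high-bit-depth slices -> 8-bit -> normalized tensors,
# plus one-hot label encoding.

#' Construct a raw image
#'
#' A raw image is an integer pixel matrix together with its declared bit
#' depth. Medical scanners commonly emit 12-bit intensities (full scale
#' 4095), while ordinary raster images are 8-bit (full scale 255).
#'
#' @param pixels Integer matrix of intensity counts (rows x cols).
#' @param bit_depth Bits per pixel; one of 8, 12 or 16.
#' @return An object of class `raw_image` with fields `pixels`, `bit_depth`
#'   and `max_intensity` (\eqn{2^{bit\_depth} - 1}).
#' @examples
#' img <- raw_image(matrix(0:3, 2, 2), bit_depth = 12)
#' img$max_intensity # 4095
#' @export
raw_image <- function(pixels, bit_depth) {
  if (!is.matrix(pixels) || nrow(pixels) == 0 || ncol(pixels) == 0) {
    stop_validation("pixels must be a non-empty matrix")
  }
  if (!bit_depth %in% c(8L, 12L, 16L)) {
    stop_validation("bit_depth must be 8, 12 or 16, got %s", bit_depth)
  }
  storage.mode(pixels) <- "integer"
  max_intensity <- as.integer(2^bit_depth - 1)
  if (anyNA(pixels)) stop_validation("pixels contain missing values")
  if (min(pixels) < 0L) stop_validation("negative pixel values are not allowed")
  if (max(pixels) > max_intensity) {
    stop_validation(
      "pixel maximum %d exceeds the declared %d-bit range [0, %d]",
      max(pixels), bit_depth, max_intensity
    )
  }
  structure(
    list(pixels = pixels, bit_depth = as.integer(bit_depth),
         max_intensity = max_intensity),
    class = "raw_image"
  )
}

#' @export
print.raw_image <- function(x, ...) {
  cat(sprintf("<raw_image %dx%d, %d-bit (full scale %d), pixel range [%d, %d]>\n",
              nrow(x$pixels), ncol(x$pixels), x$bit_depth, x$max_intensity,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Read an image file as a raw image
#'
#' Reads a DICOM file (`.dcm`, `.ima`, or anything that starts with the DICM
#' magic) or an 8/16-bit PNG. The bit depth is taken from DICOM BitsStored or
#' from the PNG header. JPEG is not supported; convert to PNG first.
#'
#' @param path Path to the image file.
#' @param format `"auto"` (default, sniff magic bytes / extension),
#'   `"dicom"` or `"raster"`.
#' @return A [raw_image()].
#' @export
read_image <- function(path, format = c("auto", "dicom", "raster")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_validation("file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  if (format == "auto") {
    format <- if (ext %in% c("dcm", "ima") || is_dicom_file(path)) "dicom" else "raster"
  }
  if (format == "dicom") {
    return(read_dicom(path))
  }
  if (ext %in% c("jpg", "jpeg")) {
    stop_validation("JPEG input is not supported; convert '%s' to PNG or DICOM", path)
  }
  if (ext != "png") {
    stop_validation("unsupported raster format '.%s' for %s (PNG expected)", ext, path)
  }
  arr <- png::readPNG(path, info = TRUE)
  info <- attr(arr, "info")
  bit_depth <- as.integer(info$bit.depth %||% 8L)
  if (!bit_depth %in% c(8L, 16L)) {
    stop_validation("PNG bit depth %d not supported", bit_depth)
  }
  if (length(dim(arr)) == 3L) {
    # collapse colour/alpha planes of a grayscale-as-RGB source
    arr <- apply(arr[, , seq_len(min(3L, dim(arr)[3])), drop = FALSE], c(1, 2), mean)
  }
  pixels <- matrix(as.integer(round(arr * (2^bit_depth - 1))),
                   nrow = nrow(arr), ncol = ncol(arr))
  raw_image(pixels, bit_depth)
}

#' Rescale a raw image to the 8-bit range
#'
#' Applies the full-scale linear rescaling
#' \deqn{uint8 = round(255 \times p / I_{max})}
#' so that, e.g., a 12-bit pixel of 4095 maps exactly to 255. Rounding is
#' round-half-to-even; results are clamped to \[0, 255\]. An 8-bit input
#' passes through unchanged.
#'
#' @param img A [raw_image()].
#' @return Integer matrix with values in \[0, 255\].
#' @examples
#' convert_bit_depth(raw_image(matrix(4095L), bit_depth = 12)) # 255
#' @export
convert_bit_depth <- function(img) {
  if (!inherits(img, "raw_image")) {
    stop_validation("img must be a raw_image object")
  }
  if (img$max_intensity <= 0) stop_validation("max_intensity must be positive")
  if (img$bit_depth == 8L) return(img$pixels)
  out <- round(255 * img$pixels / img$max_intensity)
  out <- clamp(out, 0, 255)
  storage.mode(out) <- "integer"
  out
}

#' Normalize a batch of 8-bit images into a model-ready tensor
#'
#' Divides pixels by 255 so values lie in \[0, 1\], resizes any image that is
#' not `target_size` x `target_size` with bilinear interpolation, and
#' replicates the grayscale plane into 3 identical channels. The result is
#' the n x H x W x 3 array consumed by the feature-extraction backbone.
#'
#' @param images A single 8-bit integer matrix or a list of them.
#' @param target_size Output height/width in pixels (default 320, the
#'   native slice resolution of the source archive).
#' @return Numeric array of dimension `c(n, target_size, target_size, 3)`
#'   with values in \[0, 1\].
#' @export
normalize_images <- function(images, target_size = 320L) {
  if (is.matrix(images)) images <- list(images)
  if (!is.list(images) || length(images) == 0) {
    stop_validation("images must be a non-empty matrix or list of matrices")
  }
  n <- length(images)
  out <- array(0, dim = c(n, target_size, target_size, 3L))
  for (i in seq_len(n)) {
    m <- images[[i]]
    if (inherits(m, "raw_image")) {
      stop_validation("normalize_images expects 8-bit matrices; run convert_bit_depth() first")
    }
    if (!is.matrix(m)) stop_validation("image %d is not a matrix", i)
    if (min(m) < 0 || max(m) > 255) {
      stop_validation("image %d has values outside [0, 255]", i)
    }
    v <- m / 255
    if (nrow(v) != target_size || ncol(v) != target_size) {
      v <- EBImage::resize(v, w = target_size, h = target_size,
                           filter = "bilinear")
      v <- clamp(v, 0, 1)
    }
    for (ch in 1:3) out[i, , , ch] <- v
  }
  out
}

#' One-hot encode integer class labels
#'
#' @param labels Integer vector with values in `0:(n_classes - 1)`.
#' @param n_classes Number of classes (default 2).
#' @return Binary matrix of dimension `length(labels)` x `n_classes`; row i
#'   has a single 1 in column `labels[i] + 1`.
#' @examples
#' one_hot(c(0L, 1L, 0L))
#' @export
one_hot <- function(labels, n_classes = 2L) {
  labels <- as.integer(labels)
  if (anyNA(labels)) stop_validation("labels contain missing values")
  bad <- which(labels < 0L | labels >= n_classes)
  if (length(bad) > 0) {
    stop_validation("label at index %d (value %d) is outside [0, %d]",
                    bad[1], labels[bad[1]], n_classes - 1L)
  }
  m <- matrix(0L, nrow = length(labels), ncol = n_classes)
  if (length(labels) > 0) m[cbind(seq_along(labels), labels + 1L)] <- 1L
  m
}

#' Recover class indices from a one-hot matrix
#'
#' @param m One-hot (or score) matrix, one row per sample.
#' @return Integer labels in `0:(ncol(m) - 1)` (row-wise argmax).
#' @export
decode_one_hot <- function(m) {
  if (nrow(m) == 0) return(integer(0))
  max.col(m, ties.method = "first") - 1L
}

#' Write an 8-bit image matrix to PNG
#'
#' @param pixels Integer matrix in \[0, 255\].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(pixels, path) {
  if (min(pixels) < 0 || max(pixels) > 255) {
    stop_validation("pixels outside [0, 255]; convert_bit_depth() first")
  }
  png::writePNG(pixels / 255, target = path)
  invisible(path)
}
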
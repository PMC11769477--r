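# Minimal DICOM support: uncompressed grayscale images, little-endian
# transfer syntaxes only (explicit VR "1.2.840.10008.1.2.1" on write; both
# explicit and implicit VR accepted on read). This covers the subset that
# scanner-exported .IMA/.dcm slice archives actually use for pixel access:
# Rows, Columns, BitsAllocated, BitsStored, PhotometricInterpretation and
# the PixelData element.

UID_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
UID_IMPLICIT_LE <- "1.2.840.10008.1.2"
UID_MR_STORAGE <- "1.2.840.10008.5.1.4.1.1.4"

u16le <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
u32le <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

pad_even <- function(data, pad = as.raw(0)) {
  if (length(data) %% 2 == 1) c(data, pad) else data
}

dcm_element <- function(group, element, vr, data) {
  data <- pad_even(data, if (vr %in% c("UI", "OB")) as.raw(0) else charToRaw(" "))
  tag <- c(u16le(group), u16le(element))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    c(tag, charToRaw(vr), raw(2), u32le(length(data)), data)
  } else {
    c(tag, charToRaw(vr), u16le(length(data)), data)
  }
}

dcm_str <- function(group, element, vr, value) {
  dcm_element(group, element, vr, charToRaw(value))
}

dcm_us <- function(group, element, value) {
  dcm_element(group, element, "US", u16le(value))
}

#' Write a raw image as a DICOM file
#'
#' Emits an uncompressed grayscale DICOM (explicit VR little endian) with
#' the pixel geometry and bit-depth tags downstream readers need. Pixels
#' with more than 8 bits are stored in 16-bit words.
#'
#' @param img A [raw_image()].
#' @param path Output file path.
#' @param photometric `"MONOCHROME2"` (default; 0 is black) or
#'   `"MONOCHROME1"` (0 is white; readers invert it back).
#' @return `path`, invisibly.
#' @export
write_dicom <- function(img, path, photometric = c("MONOCHROME2", "MONOCHROME1")) {
  photometric <- match.arg(photometric)
  if (!inherits(img, "raw_image")) stop_validation("img must be a raw_image")
  bits_alloc <- if (img$bit_depth > 8L) 16L else 8L
  px <- as.integer(t(img$pixels)) # row-major, DICOM raster order
  if (photometric == "MONOCHROME1") px <- img$max_intensity - px
  pixel_bytes <- writeBin(px, raw(), size = bits_alloc / 8L, endian = "little")

  meta_body <- c(
    dcm_element(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
    dcm_str(0x0002, 0x0002, "UI", UID_MR_STORAGE),
    dcm_str(0x0002, 0x0003, "UI", "1.2.826.0.1.3680043.9999.1"),
    dcm_str(0x0002, 0x0010, "UI", UID_EXPLICIT_LE),
    dcm_str(0x0002, 0x0012, "UI", "1.2.826.0.1.3680043.9999.2")
  )
  meta <- c(dcm_element(0x0002, 0x0000, "UL", u32le(length(meta_body))), meta_body)

  dataset <- c(
    dcm_str(0x0008, 0x0016, "UI", UID_MR_STORAGE),
    dcm_str(0x0008, 0x0018, "UI", "1.2.826.0.1.3680043.9999.1"),
    dcm_us(0x0028, 0x0002, 1L),
    dcm_str(0x0028, 0x0004, "CS", photometric),
    dcm_us(0x0028, 0x0010, nrow(img$pixels)),
    dcm_us(0x0028, 0x0011, ncol(img$pixels)),
    dcm_us(0x0028, 0x0100, bits_alloc),
    dcm_us(0x0028, 0x0101, img$bit_depth),
    dcm_us(0x0028, 0x0102, img$bit_depth - 1L),
    dcm_us(0x0028, 0x0103, 0L),
    dcm_element(0x7FE0, 0x0010, "OW", pixel_bytes)
  )

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(raw(128), charToRaw("DICM"), meta, dataset), con)
  invisible(path)
}

is_dicom_file <- function(path) {
  if (file.size(path) < 132) return(FALSE)
  head <- readBin(path, raw(), 132)
  identical(rawToChar(head[129:132]), "DICM")
}

read_u16 <- function(bytes, pos) {
  readBin(bytes[pos:(pos + 1)], "integer", size = 2, signed = FALSE,
          endian = "little")
}

read_u32 <- function(bytes, pos) {
  readBin(bytes[pos:(pos + 3)], "integer", size = 4, endian = "little")
}

LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")

# Parse one data element; returns list(group, element, value_raw, next_pos).
parse_element <- function(bytes, pos, explicit) {
  group <- read_u16(bytes, pos)
  element <- read_u16(bytes, pos + 2)
  if (explicit) {
    vr <- rawToChar(bytes[(pos + 4):(pos + 5)])
    if (vr %in% LONG_VRS) {
      len <- read_u32(bytes, pos + 8)
      data_start <- pos + 12
    } else {
      len <- read_u16(bytes, pos + 6)
      data_start <- pos + 8
    }
  } else {
    vr <- NA_character_
    len <- read_u32(bytes, pos + 4)
    data_start <- pos + 8
  }
  if (len == -1 || len > length(bytes)) {
    stop_validation("unsupported or corrupt DICOM element (%04x,%04x)", group, element)
  }
  value <- if (len > 0) bytes[data_start:(data_start + len - 1)] else raw(0)
  list(group = group, element = element, vr = vr, value = value,
       next_pos = data_start + len)
}

val_u16 <- function(el) read_u16(el$value, 1)
val_str <- function(el) trimws(rawToChar(el$value[el$value != as.raw(0)]))

#' Read a DICOM file as a raw image
#'
#' Supports uncompressed grayscale DICOM in the explicit or implicit VR
#' little-endian transfer syntaxes. The declared bit depth is taken from
#' BitsStored; MONOCHROME1 images are inverted to the MONOCHROME2 brightness
#' convention so 0 is always black.
#'
#' @param path Path to a `.dcm`/`.IMA` file.
#' @return A [raw_image()].
#' @export
read_dicom <- function(path) {
  bytes <- readBin(path, raw(), file.size(path))
  if (length(bytes) >= 132 && identical(rawToChar(bytes[129:132]), "DICM")) {
    pos <- 133
    transfer_syntax <- UID_EXPLICIT_LE
    # file meta group is always explicit VR
    while (pos + 7 <= length(bytes) && read_u16(bytes, pos) == 0x0002) {
      el <- parse_element(bytes, pos, explicit = TRUE)
      if (el$element == 0x0010) transfer_syntax <- val_str(el)
      pos <- el$next_pos
    }
    explicit <- transfer_syntax != UID_IMPLICIT_LE
    if (!transfer_syntax %in% c(UID_EXPLICIT_LE, UID_IMPLICIT_LE)) {
      stop_validation("unsupported DICOM transfer syntax '%s' in %s",
                      transfer_syntax, path)
    }
  } else {
    pos <- 1
    explicit <- FALSE # headerless .IMA exports are implicit VR LE
  }

  tags <- list()
  pixel_raw <- NULL
  while (pos + 7 <= length(bytes)) {
    el <- parse_element(bytes, pos, explicit)
    key <- sprintf("%04x,%04x", el$group, el$element)
    if (el$group == 0x7FE0 && el$element == 0x0010) {
      pixel_raw <- el$value
      break
    }
    tags[[key]] <- el
    pos <- el$next_pos
  }
  if (is.null(pixel_raw)) stop_validation("no PixelData element found in %s", path)

  need <- function(key, what) {
    if (is.null(tags[[key]])) stop_validation("DICOM tag (%s) %s missing in %s", key, what, path)
    tags[[key]]
  }
  rows <- val_u16(need("0028,0010", "Rows"))
  cols <- val_u16(need("0028,0011", "Columns"))
  bits_alloc <- val_u16(need("0028,0100", "BitsAllocated"))
  bits_stored <- if (!is.null(tags[["0028,0101"]])) val_u16(tags[["0028,0101"]]) else bits_alloc
  photometric <- if (!is.null(tags[["0028,0004"]])) val_str(tags[["0028,0004"]]) else "MONOCHROME2"
  if (!bits_alloc %in% c(8L, 16L)) {
    stop_validation("BitsAllocated %d not supported", bits_alloc)
  }

  px <- readBin(pixel_raw, "integer", n = rows * cols, size = bits_alloc / 8L,
                signed = FALSE, endian = "little")
  bit_depth <- if (bits_stored <= 8L) 8L else if (bits_stored <= 12L) 12L else 16L
  max_intensity <- as.integer(2^bit_depth - 1)
  if (max(px) > 2^bits_stored - 1) {
    stop_validation(
      "pixel maximum %d exceeds the declared %d-bit (BitsStored) range in %s",
      max(px), bits_stored, path
    )
  }
  pixels <- matrix(px, nrow = rows, ncol = cols, byrow = TRUE)
  if (photometric == "MONOCHROME1") pixels <- max_intensity - pixels
  raw_image(pixels, bit_depth)
}
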
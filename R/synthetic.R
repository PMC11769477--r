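# Seeded synthetic data with known structure: class-conditional Gaussian
# feature matrices (a stand-in for fully-connected-layer descriptors, with
# a known informative column subset so wrapper feature selection has a
# provable target) and toy 12-bit grayscale images whose class signal is a
# centered bright disc. Neither generator attempts anatomical realism.

#' Generate a class-structured synthetic feature matrix
#'
#' `n_informative` randomly placed columns are drawn from unit-variance
#' class-conditional Gaussians whose means are shifted by
#' `±class_separation / (2 sqrt(n_informative))`, so the Euclidean distance
#' between the two class-mean vectors is `class_separation` within-class
#' standard deviations regardless of how many columns carry signal; all
#' remaining columns are standard Gaussian noise with no class dependence.
#' Labels are Bernoulli draws with success probability `class_balance`.
#'
#' @param n_samples Number of rows (default 400).
#' @param n_features Number of columns (default 64).
#' @param n_informative Number of class-carrying columns (default 8).
#' @param class_separation Inter-class mean distance (Euclidean, over all
#'   informative columns) in units of the within-class standard deviation
#'   (default 5).
#' @param class_balance Probability of class 1 (default 0.5).
#' @param seed RNG seed; the generator is a pure function of its
#'   arguments.
#' @return List with `features` (matrix, columns `f0001`...),
#'   `labels` (integer 0/1), `informative` (column indices carrying
#'   signal), and `spec` (the arguments).
#' @export
synthetic_features <- function(n_samples = 400L, n_features = 64L,
                               n_informative = 8L, class_separation = 5,
                               class_balance = 0.5, seed = 1L) {
  if (n_informative > n_features) {
    stop_validation("n_informative (%d) exceeds n_features (%d)",
                    n_informative, n_features)
  }
  if (class_separation < 0) stop_validation("class_separation must be >= 0")
  if (class_balance <= 0 || class_balance >= 1) {
    stop_validation("class_balance must be in (0, 1)")
  }
  with_seed(seed, {
    labels <- stats::rbinom(n_samples, 1L, class_balance)
    informative <- sort(sample.int(n_features, n_informative))
    features <- matrix(stats::rnorm(n_samples * n_features),
                       n_samples, n_features)
    shift <- ifelse(labels == 1L, class_separation / 2, -class_separation / 2) /
      sqrt(max(n_informative, 1L))
    for (j in informative) features[, j] <- features[, j] + shift
    colnames(features) <- sprintf("f%04d", seq_len(n_features))
    list(features = features, labels = as.integer(labels),
         informative = informative,
         spec = list(n_samples = n_samples, n_features = n_features,
                     n_informative = n_informative,
                     class_separation = class_separation,
                     class_balance = class_balance, seed = seed))
  })
}

#' Generate toy high-bit-depth images with a class-dependent bright disc
#'
#' Every image is a flat background at 25% of full scale; class-1 images
#' additionally carry a centered disc (radius `size / 4`) raised by
#' `blob_intensity_shift` counts. Gaussian noise of standard deviation
#' `noise_sd` is added and the result is clipped to the declared bit
#' range.
#'
#' @param n_samples Number of images (default 80).
#' @param size Image side length in pixels (default 64; keep it a
#'   multiple of 32 for the debug backbone).
#' @param bit_depth 8 or 12 (default 12).
#' @param blob_intensity_shift Class-1 disc offset in intensity counts
#'   (default 600 on the 12-bit scale).
#' @param noise_sd Gaussian pixel noise standard deviation (default 80).
#' @param class_balance Probability of class 1 (default 0.5).
#' @param seed RNG seed.
#' @return List with `images` (list of [raw_image()]), `labels`
#'   (integer 0/1), and `spec`.
#' @export
synthetic_images <- function(n_samples = 80L, size = 64L, bit_depth = 12L,
                             blob_intensity_shift = 600L, noise_sd = 80,
                             class_balance = 0.5, seed = 1L) {
  if (!bit_depth %in% c(8L, 12L)) stop_validation("bit_depth must be 8 or 12")
  if (size <= 0) stop_validation("size must be positive")
  max_intensity <- 2^bit_depth - 1
  background <- round(0.25 * max_intensity)
  if (blob_intensity_shift < 0 || background + blob_intensity_shift > max_intensity) {
    stop_validation(
      "blob_intensity_shift %d pushes the disc outside the %d-bit range",
      blob_intensity_shift, bit_depth
    )
  }
  with_seed(seed, {
    labels <- stats::rbinom(n_samples, 1L, class_balance)
    centre <- (size + 1) / 2
    coords <- expand.grid(r = seq_len(size), c = seq_len(size))
    disc <- matrix((coords$r - centre)^2 + (coords$c - centre)^2 <= (size / 4)^2,
                   size, size)
    images <- lapply(seq_len(n_samples), function(i) {
      m <- matrix(background, size, size)
      if (labels[i] == 1L) m[disc] <- m[disc] + blob_intensity_shift
      if (noise_sd > 0) {
        m <- m + stats::rnorm(size * size, sd = noise_sd)
      }
      raw_image(matrix(as.integer(round(clamp(m, 0, max_intensity))), size, size),
                bit_depth)
    })
    list(images = images, labels = as.integer(labels),
         spec = list(n_samples = n_samples, size = size,
                     bit_depth = bit_depth,
                     blob_intensity_shift = blob_intensity_shift,
                     noise_sd = noise_sd, class_balance = class_balance,
                     seed = seed))
  })
}

#' Write an image data set to disk in the pipeline's ingest layout
#'
#' Emits one image file per sample plus a `labels.csv` manifest with
#' columns `path,label` — exactly the layout `run_pipeline()` ingests in
#' image mode. DICOM output preserves high bit depths; PNG output stores
#' the 8-bit conversion.
#'
#' @param images List of [raw_image()] objects.
#' @param labels Integer labels aligned with `images`.
#' @param dir Output directory (created if needed).
#' @param format `"dicom"` (default) or `"png"`.
#' @return Path to the manifest CSV, invisibly.
#' @export
write_image_dataset <- function(images, labels, dir,
                                format = c("dicom", "png")) {
  format <- match.arg(format)
  if (length(images) != length(labels)) stop_validation("images and labels misaligned")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (format == "dicom") "dcm" else "png"
  paths <- character(length(images))
  for (i in seq_along(images)) {
    paths[i] <- file.path(dir, sprintf("slice_%04d.%s", i, ext))
    if (format == "dicom") {
      write_dicom(images[[i]], paths[i])
    } else {
      write_image_png(convert_bit_depth(images[[i]]), paths[i])
    }
  }
  manifest <- file.path(dir, "labels.csv")
  utils::write.csv(
    data.frame(path = basename(paths), label = as.integer(labels)),
    manifest, row.names = FALSE
  )
  invisible(manifest)
}
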
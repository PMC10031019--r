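# Data processing (content cropping, resizing, splitting) and all image /
# table / config I/O.  Internal intensity convention: [0,1] doubles
# everywhere; 8-bit PNG at the file boundary; masks are {0,255} on disk and
# {0,1} in memory.

#' Rectangular crop box
#'
#' Scanner frames often carry burned-in text and UI outside the image
#' content; a per-dataset crop box removes them.
#'
#' @param top,left 1-based coordinates of the upper-left corner.
#' @param height,width Positive extents in pixels.
#' @return An object of class `crop_box`.
#' @export
crop_box <- function(top, left, height, width) {
  if (height <= 0 || width <= 0) stop_sym("height and width must be positive")
  if (top < 1 || left < 1) stop_sym("top and left must be >= 1")
  structure(list(top = as.integer(top), left = as.integer(left),
                 height = as.integer(height), width = as.integer(width)),
            class = "crop_box")
}

#' Crop an image to its content region
#'
#' @param image Matrix.
#' @param box A [crop_box()] lying fully inside the image.  Apply the same
#'   box to the mask to keep pixel correspondence.
#' @return The exact `height x width` sub-image.
#' @export
crop_to_content <- function(image, box) {
  stopifnot(inherits(box, "crop_box"))
  d <- dim(image)
  b <- box$top + box$height - 1L; r <- box$left + box$width - 1L
  if (b > d[1] || r > d[2])
    stop_sym("crop box exceeds image bounds: rows ", box$top, ":", b,
             ", cols ", box$left, ":", r, " on a ", d[1], "x", d[2], " image")
  image[box$top:b, box$left:r, drop = FALSE]
}

#' Resize an intensity image (bilinear)
#'
#' @param image Matrix in `[0, 1]`.
#' @param size Target side length (square) or `c(height, width)`, >= 16.
#' @return The resized image, clipped to `[0, 1]`.
#' @export
resize_image <- function(image, size) {
  size <- to_hw(size)
  d <- dim(image)
  # sample positions in source coordinates (align pixel centers)
  sr <- (seq_len(size[1]) - 0.5) * d[1] / size[1] + 0.5
  sc <- (seq_len(size[2]) - 0.5) * d[2] / size[2] + 0.5
  r0 <- pmin(pmax(floor(sr), 1), d[1]); r1 <- pmin(r0 + 1, d[1])
  c0 <- pmin(pmax(floor(sc), 1), d[2]); c1 <- pmin(c0 + 1, d[2])
  fr <- pmin(pmax(sr - r0, 0), 1); fc <- pmin(pmax(sc - c0, 0), 1)
  # vectorized bilinear: interpolate columns then rows
  a <- image[r0, c0, drop = FALSE] * rep(1 - fc, each = size[1]) +
    image[r0, c1, drop = FALSE] * rep(fc, each = size[1])
  b <- image[r1, c0, drop = FALSE] * rep(1 - fc, each = size[1]) +
    image[r1, c1, drop = FALSE] * rep(fc, each = size[1])
  out <- a * (1 - fr) + b * fr
  pmin(pmax(out, 0), 1)
}

#' Resize a binary mask (nearest neighbor, stays binary)
#'
#' @param mask Binary 0/1 matrix.
#' @param size Target side length or `c(height, width)`.
#' @return The resized binary mask.
#' @export
resize_mask <- function(mask, size) {
  assert_binary_mask(mask)
  size <- to_hw(size)
  d <- dim(mask)
  ri <- pmin(pmax(ceiling((seq_len(size[1]) - 0.5) * d[1] / size[1]), 1), d[1])
  ci <- pmin(pmax(ceiling((seq_len(size[2]) - 0.5) * d[2] / size[2]), 1), d[2])
  mask[ri, ci, drop = FALSE]
}

to_hw <- function(size) {
  size <- as.integer(size)
  if (length(size) == 1L) size <- c(size, size)
  if (any(size < 16L)) stop_sym("target size must be >= 16")
  size
}

#' Assign a seeded train/test split
#'
#' @param dataset A `domain_dataset`.
#' @param test Either a fraction in (0, 1) or an explicit test count.
#' @param seed Integer seed; the same seed reproduces the same membership.
#' @return The dataset with a fresh `split` vector.
#' @export
split_train_test <- function(dataset, test, seed = 1L) {
  stopifnot(inherits(dataset, "domain_dataset"))
  n <- length(dataset$samples)
  test_count <- if (test > 0 && test < 1) round(n * test) else as.integer(test)
  if (test_count >= n || test_count < 1)
    stop_sym("test size (", test_count, ") must be in [1, ", n - 1, "]")
  split <- rep("train", n)
  split[with_seed(seed, sample.int(n, test_count))] <- "test"
  dataset$split <- split
  dataset
}

## ---- PNG / dataset I/O ------------------------------------------------------

#' Write an image (or mask) as 8-bit grayscale PNG
#' @param image Matrix in `[0, 1]` (masks: 0/1, stored as {0, 255}).
#' @param path Destination file.
#' @export
write_image_png <- function(image, path) {
  assert_image01(image)
  storage.mode(image) <- "double"
  png::writePNG(image, path)
  invisible(path)
}

#' Read a grayscale PNG as a `[0, 1]` matrix
#' @param path PNG file.
#' @return Intensity matrix.
#' @export
read_image_png <- function(path) {
  if (!file.exists(path)) stop_sym("cannot read image: ", path)
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  img
}

#' Read a mask PNG, binarizing at 128/255
#' @param path PNG file with values {0, 255} (any value >= 128 maps to 1).
#' @return Binary 0/1 matrix.
#' @export
read_mask_png <- function(path) {
  m <- (read_image_png(path) >= 128 / 255) * 1
  m
}

#' Write a domain dataset to an on-disk PNG layout
#'
#' Layout: `<root>/<domain>/<split>/images/<id>.png` and
#' `.../masks/<id>.png`, plus a `manifest.csv` with columns
#' `id, domain, split, seed`.
#'
#' @param dataset A `domain_dataset`.
#' @param root Output directory root.
#' @param seed Seed recorded in the manifest.
#' @return `root`, invisibly.
#' @export
write_domain_dataset <- function(dataset, root, seed = NA_integer_) {
  stopifnot(inherits(dataset, "domain_dataset"))
  rows <- list()
  for (i in seq_along(dataset$samples)) {
    s <- dataset$samples[[i]]
    dir <- file.path(root, s$domain, dataset$split[i])
    dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
    write_image_png(s$image, file.path(dir, "images", paste0(s$id, ".png")))
    if (!is.null(s$mask)) {
      dir.create(file.path(dir, "masks"), recursive = TRUE,
                 showWarnings = FALSE)
      write_image_png(s$mask, file.path(dir, "masks", paste0(s$id, ".png")))
    }
    rows[[i]] <- data.frame(id = s$id, domain = s$domain,
                            split = dataset$split[i], seed = seed)
  }
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(root, "manifest.csv"), row.names = FALSE)
  invisible(root)
}

#' Read a domain dataset from the on-disk PNG layout
#'
#' @param root Directory written by [write_domain_dataset()].
#' @param domain Which domain subdirectory to read.
#' @return A `domain_dataset`.
#' @export
read_domain_dataset <- function(root, domain) {
  manifest <- read.csv(file.path(root, "manifest.csv"),
                       stringsAsFactors = FALSE)
  manifest <- manifest[manifest$domain == domain, , drop = FALSE]
  if (nrow(manifest) == 0L) stop_sym("no samples for domain '", domain, "'")
  samples <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    r <- manifest[i, ]
    dir <- file.path(root, r$domain, r$split)
    img <- read_image_png(file.path(dir, "images", paste0(r$id, ".png")))
    mpath <- file.path(dir, "masks", paste0(r$id, ".png"))
    msk <- if (file.exists(mpath)) read_mask_png(mpath) else NULL
    if (!is.null(msk) && !identical(dim(msk), dim(img)))
      stop_sym("image/mask shape mismatch for sample ", r$id)
    samples[[i]] <- image_sample(img, msk, r$domain, r$id)
  }
  new_domain_dataset(samples, manifest$split, domain)
}

## ---- config / table I/O -----------------------------------------------------

#' Read a YAML experiment configuration
#' @param path YAML file.
#' @return A named list (validate with [validate_run_config()]).
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_sym("config file not found: ", path)
  yaml::read_yaml(path)
}

#' Write the resolved configuration for provenance
#' @param config Named list.
#' @param path Destination YAML file.
#' @export
write_resolved_config <- function(config, path) {
  drop_classes <- function(x) {
    if (is.list(x)) lapply(unclass(x), drop_classes) else x
  }
  yaml::write_yaml(drop_classes(config), path)
  invisible(path)
}

#' Write a metrics table as CSV (fixed column order)
#' @param table Data frame with columns source, target, pa, dsc, tpr, tnr.
#' @param path Destination file.
#' @export
write_metrics_csv <- function(table, path) {
  cols <- c("source", "target", "pa", "dsc", "tpr", "tnr")
  write.csv(table[, cols], path, row.names = FALSE)
  invisible(path)
}
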
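#' Describe the on-disk layout of an image/mask dataset
#'
#' A dataset root either contains `images/` and `masks/` sub-directories
#' directly (a single collection named after the root), or one
#' sub-directory per collection, each with `images/` and `masks/`.  Images
#' and masks are paired by filename stem.
#'
#' @param images,masks Sub-directory names.
#' @param image_pattern Regular expression selecting image files.
#' @return A `dataset_layout` list.
#' @export
dataset_layout <- function(images = "images", masks = "masks",
                           image_pattern = "\\.(png|tif|tiff)$") {
  structure(list(images = images, masks = masks,
                 image_pattern = image_pattern), class = "dataset_layout")
}

#' Load a dataset manifest from disk
#'
#' Scans the layout, pairs every image with its mask by filename stem and
#' returns the manifest.  Unpaired files are an error and are listed by
#' stem rather than silently dropped.
#'
#' @param root_dir Dataset root directory.
#' @param layout A [dataset_layout()].
#' @return A tibble manifest (class `dataset_manifest`) with columns
#'   `image_path`, `mask_path`, `collection`, `split` (initially
#'   `"unassigned"`).
#' @export
load_dataset <- function(root_dir, layout = dataset_layout()) {
  if (!dir.exists(root_dir)) stop("no such directory: ", root_dir,
                                  call. = FALSE)
  roots <- if (dir.exists(file.path(root_dir, layout$images))) {
    stats::setNames(root_dir, basename(normalizePath(root_dir)))
  } else {
    subs <- list.dirs(root_dir, recursive = FALSE)
    subs <- subs[dir.exists(file.path(subs, layout$images))]
    stats::setNames(subs, basename(subs))
  }
  if (length(roots) == 0)
    stop("no '", layout$images, "' directories found under ", root_dir,
         call. = FALSE)
  rows <- lapply(names(roots), function(coll) {
    imgs <- sort(list.files(file.path(roots[coll], layout$images),
                            pattern = layout$image_pattern,
                            full.names = TRUE))
    msks <- sort(list.files(file.path(roots[coll], layout$masks),
                            pattern = layout$image_pattern,
                            full.names = TRUE))
    is <- tools::file_path_sans_ext(basename(imgs))
    ms <- tools::file_path_sans_ext(basename(msks))
    orphan <- symdiff_stems(is, ms)
    if (length(orphan))
      stop("unpaired image/mask stems in collection '", coll, "': ",
           paste(sort(orphan), collapse = ", "), call. = FALSE)
    tibble::tibble(image_path = imgs, mask_path = msks[match(is, ms)],
                   collection = coll)
  })
  manifest <- dplyr::bind_rows(rows)
  if (nrow(manifest) == 0) stop("dataset is empty", call. = FALSE)
  manifest$split <- "unassigned"
  class(manifest) <- c("dataset_manifest", class(manifest))
  manifest
}

#' Split a manifest into training and testing sets
#'
#' Pools all records and randomly tags `round(train_fraction * n)` of them
#' as `train`, the rest as `test` (seeded, disjoint by construction).  When
#' `per_collection_counts` is supplied, exactly that many training records
#' are drawn within each collection instead, which reproduces a published
#' per-collection allocation exactly.
#'
#' @param manifest A dataset manifest.
#' @param train_fraction Fraction of records to train on, strictly inside
#'   (0, 1).
#' @param seed Optional seed for the draw.
#' @param per_collection_counts Optional named integer vector of training
#'   counts per collection.
#' @return The manifest with its `split` column filled in.
#' @examples
#' \dontrun{
#' split_dataset(manifest, 0.7, seed = 1)  # 1187 records -> 831/356
#' }
#' @export
split_dataset <- function(manifest, train_fraction = 0.7, seed = NULL,
                          per_collection_counts = NULL) {
  stopifnot(inherits(manifest, "data.frame"))
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must lie strictly between 0 and 1", call. = FALSE)
  draw <- function() {
    n <- nrow(manifest)
    split <- rep("test", n)
    if (is.null(per_collection_counts)) {
      split[sample.int(n, round(train_fraction * n))] <- "train"
    } else {
      for (coll in names(per_collection_counts)) {
        rows <- which(manifest$collection == coll)
        k <- per_collection_counts[[coll]]
        if (k > length(rows))
          stop("requested ", k, " training records from collection '", coll,
               "' which has only ", length(rows), call. = FALSE)
        split[sample(rows, k)] <- "train"
      }
    }
    split
  }
  manifest$split <- if (is.null(seed)) draw() else
    withr::with_seed(as.integer(seed), draw())
  manifest
}

new_sample_record <- function(image, mask, native_resolution = dim(mask),
                              collection = NA_character_) {
  if (!identical(dim(image)[1:2], dim(mask)[1:2]))
    stop("image and mask resolutions differ", call. = FALSE)
  structure(list(image = image, mask = mask,
                 native_resolution = as.integer(native_resolution[1:2]),
                 collection = collection), class = "sample_record")
}

#' Read one image/mask pair
#'
#' Images are loaded as (H, W, 3) arrays scaled to `[0, 1]` (grayscale is
#' replicated, alpha dropped); masks are binarised with the 8-bit rule
#' value > 127 => polyp.
#'
#' @param image_path,mask_path Paths to a PNG or TIFF image and its mask.
#' @param collection Collection tag stored in the record.
#' @return A `sample_record`.
#' @export
read_sample <- function(image_path, mask_path, collection = NA_character_) {
  img <- read_image(image_path)
  mask <- read_mask(mask_path)
  if (!identical(dim(img)[1:2], dim(mask)))
    stop("image and mask resolutions differ for stem '",
         tools::file_path_sans_ext(basename(image_path)), "'", call. = FALSE)
  new_sample_record(img, mask, collection = collection)
}

read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  a <- switch(ext,
              png = png::readPNG(path),
              tif = , tiff = tiff::readTIFF(path),
              stop("unsupported image format: .", ext, call. = FALSE))
  if (length(dim(a)) == 2) a <- array(rep(a, 3), dim = c(dim(a), 3))
  if (dim(a)[3] == 4) a <- a[, , 1:3]
  if (dim(a)[3] == 2) a <- array(rep(a[, , 1], 3), dim = c(dim(a)[1:2], 3))
  a
}

read_mask <- function(path) {
  a <- read_image(path)
  m <- a[, , 1]
  (m > 127 / 255) * 1L
}

#' Standardise a sample to a target resolution
#'
#' The image is resampled bilinearly; the mask with nearest-neighbour
#' interpolation and then re-binarised, so it stays strictly 0/1.
#'
#' @param record A `sample_record`.
#' @param target_resolution Integer (height, width); default 288 x 384,
#'   the smallest native resolution among the public polyp datasets.
#' @return The record at the target resolution (unchanged if already
#'   there).
#' @export
standardize_sample <- function(record, target_resolution = c(288L, 384L)) {
  stopifnot(inherits(record, "sample_record"))
  tr <- as.integer(target_resolution)
  if (length(tr) != 2 || any(tr < 1))
    stop("target_resolution must be positive (height, width)", call. = FALSE)
  if (identical(as.integer(dim(record$mask)), tr)) return(record)
  img <- EBImage::resize(record$image, w = tr[1], h = tr[2],
                         filter = "bilinear")
  img <- pmin(pmax(img, 0), 1)
  mask <- EBImage::resize(record$mask, w = tr[1], h = tr[2], filter = "none")
  mask <- (mask > 0.5) * 1L
  dim(mask) <- tr
  new_sample_record(img, mask, native_resolution = record$native_resolution,
                    collection = record$collection)
}

#' Write a binary mask as a lossless 8-bit grayscale PNG
#'
#' Polyp pixels are written as 255, background as 0; reading the file back
#' with the standard binarisation reproduces the input exactly.
#'
#' @param mask A binary (0/1 or logical) matrix.
#' @param path Destination `.png` path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  m <- mask * 1
  if (!all(m %in% c(0, 1)))
    stop("mask must be strictly binary", call. = FALSE)
  png::writePNG(matrix(as.numeric(m), nrow(mask), ncol(mask)), path)
  invisible(path)
}
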
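#' Parameters of the procedural colonoscopy-like image generator
#'
#' The generator renders the features that drive segmentation difficulty
#' in colonoscopy frames at a controllable level: a low-frequency textured
#' mucosa-toned background, radial vignetting (endoscope illumination
#' fall-off), small specular highlights (wet tissue reflections), and one
#' or more brighter elliptical "polyps" whose exact interiors define the
#' ground-truth mask.  Polyps are a minority class, as in real frames.
#'
#' @param resolution Integer (height, width) of generated images.
#' @param polyps_per_image Integer range (min, max), at least one.
#' @param polyp_radius_range Semi-major axis range as a fraction of
#'   `min(resolution)`.
#' @param polyp_eccentricity_range Axis-ratio range (1 = circle).
#' @param background_texture_scale Amplitude (intensity units) of the
#'   smoothed background texture.
#' @param vignette_strength Fractional darkening at the image corners.
#' @param specular_highlight_count Bright spots per image.
#' @param intensity_contrast Mean intensity offset of polyp over
#'   background.
#' @param noise_std Standard deviation of the per-pixel Gaussian noise.
#' @param seed Global generator seed; each sample's stream is derived from
#'   `(seed, index)` so datasets are reproducible and order-independent.
#' @return A `synthetic_spec` object.
#' @export
synthetic_spec <- function(resolution = c(64L, 64L),
                           polyps_per_image = c(1L, 3L),
                           polyp_radius_range = c(0.10, 0.24),
                           polyp_eccentricity_range = c(1, 2.2),
                           background_texture_scale = 0.06,
                           vignette_strength = 0.45,
                           specular_highlight_count = 3L,
                           intensity_contrast = 0.30,
                           noise_std = 0.03,
                           seed = 1L) {
  if (length(polyps_per_image) == 1) polyps_per_image <- rep(polyps_per_image, 2)
  if (polyps_per_image[1] < 1)
    stop("every image must contain at least one polyp", call. = FALSE)
  if (any(polyp_radius_range <= 0))
    stop("polyp radii must be positive", call. = FALSE)
  if (noise_std < 0) stop("noise_std must be non-negative", call. = FALSE)
  structure(list(resolution = as.integer(resolution),
                 polyps_per_image = as.integer(polyps_per_image),
                 polyp_radius_range = polyp_radius_range,
                 polyp_eccentricity_range = polyp_eccentricity_range,
                 background_texture_scale = background_texture_scale,
                 vignette_strength = vignette_strength,
                 specular_highlight_count = as.integer(specular_highlight_count),
                 intensity_contrast = intensity_contrast,
                 noise_std = noise_std,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Deterministic per-sample stream: a multiplicative hash of (seed, index),
# kept inside the 32-bit signed range R accepts as a seed.
sample_seed <- function(seed, index) {
  as.integer((abs(as.numeric(seed) * 48271 + as.numeric(index) * 30269)) %%
               2147483587)
}

# Anti-aliased coverage of a rotated ellipse over the pixel grid, from a
# 2x2 sub-pixel sample.
ellipse_coverage <- function(h, w, cy, cx, a, b, theta) {
  cov <- matrix(0, h, w)
  ct <- cos(theta); st <- sin(theta)
  for (dy in c(-0.25, 0.25)) for (dx in c(-0.25, 0.25)) {
    y <- matrix(seq_len(h) + dy - cy, h, w)
    x <- matrix(rep(seq_len(w) + dx - cx, each = h), h, w)
    u <- (x * ct + y * st) / a
    v <- (-x * st + y * ct) / b
    cov <- cov + (u^2 + v^2 <= 1)
  }
  cov / 4
}

#' Generate one synthetic colonoscopy-like sample
#'
#' Fully determined by `(spec$seed, index)`: regenerating the same index
#' reproduces identical pixels.  The mask is the union of the rendered
#' ellipse interiors, re-binarised at 0.5 sub-pixel coverage.
#'
#' @param spec A [synthetic_spec()].
#' @param index 1-based sample index.
#' @return A `sample_record` with an (H, W, 3) image in `[0, 1]` and a
#'   strictly binary mask.
#' @export
generate_sample <- function(spec, index = 1L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  h <- spec$resolution[1]; w <- spec$resolution[2]
  a_max <- spec$polyp_radius_range[2] * min(h, w)
  if (2 * a_max >= min(h, w) - 2)
    stop("polyp cannot fit at the requested radius", call. = FALSE)
  withr::with_seed(sample_seed(spec$seed, index), {
    base <- c(0.58, 0.36, 0.32) * runif(1, 0.9, 1.1)
    tex <- matrix(rnorm(h * w), h, w)
    tex <- EBImage::gblur(tex, sigma = max(2, min(h, w) / 12))
    tex <- tex / max(sd(tex), 1e-8) * spec$background_texture_scale
    yy <- matrix(seq_len(h) - (h + 1) / 2, h, w)
    xx <- matrix(rep(seq_len(w) - (w + 1) / 2, each = h), h, w)
    vignette <- 1 - spec$vignette_strength *
      ((yy / (h / 2))^2 + (xx / (w / 2))^2) / 2
    img <- array(0, dim = c(h, w, 3))
    for (ch in 1:3) img[, , ch] <- (base[ch] + tex) * vignette
    for (s in seq_len(spec$specular_highlight_count)) {
      cy <- runif(1, 1, h); cx <- runif(1, 1, w)
      sig <- runif(1, 0.01, 0.025) * min(h, w)
      spot <- 0.5 * exp(-((yy + (h + 1) / 2 - cy)^2 +
                            (xx + (w + 1) / 2 - cx)^2) / (2 * sig^2))
      for (ch in 1:3) img[, , ch] <- img[, , ch] + spot
    }
    n_polyp <- sample(seq(spec$polyps_per_image[1],
                          spec$polyps_per_image[2]), 1)
    cov <- matrix(0, h, w)
    for (p in seq_len(n_polyp)) {
      a <- runif(1, spec$polyp_radius_range[1], spec$polyp_radius_range[2]) *
        min(h, w)
      ecc <- runif(1, spec$polyp_eccentricity_range[1],
                   spec$polyp_eccentricity_range[2])
      b <- a / ecc
      theta <- runif(1, 0, pi)
      cy <- runif(1, a + 1, h - a)
      cx <- runif(1, a + 1, w - a)
      cov <- pmax(cov, ellipse_coverage(h, w, cy, cx, a, b, theta))
    }
    mask <- (cov >= 0.5) * 1L
    dim(mask) <- c(h, w)
    # polyps are brighter, slightly redder tissue
    bump <- spec$intensity_contrast * cov
    for (ch in 1:3) img[, , ch] <- img[, , ch] + bump * c(1.05, 1, 0.95)[ch]
    if (spec$noise_std > 0)
      img <- img + array(rnorm(length(img), sd = spec$noise_std), dim = dim(img))
    img <- pmin(pmax(img, 0), 1)
    new_sample_record(img, mask, collection = "synthetic")
  })
}

#' Generate a synthetic dataset on disk
#'
#' Writes `n` image/mask pairs in the standard dataset layout
#' (`images/`, `masks/`, paired by stem) and returns the manifest.
#' Regeneration with the same spec is byte-identical.
#'
#' @param spec A [synthetic_spec()].
#' @param n Number of samples.
#' @param out_dir Output directory (created if needed).
#' @return The `dataset_manifest` for the generated pairs.
#' @export
generate_dataset <- function(spec, n, out_dir) {
  stopifnot(inherits(spec, "synthetic_spec"), n >= 1)
  img_dir <- file.path(out_dir, "images")
  msk_dir <- file.path(out_dir, "masks")
  dir.create(img_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(msk_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(img_dir)) stop("cannot create ", img_dir, call. = FALSE)
  for (i in seq_len(n)) {
    rec <- generate_sample(spec, i)
    stem <- sprintf("synth_%04d.png", i)
    png::writePNG(rec$image, file.path(img_dir, stem))
    write_mask(rec$mask, file.path(msk_dir, stem))
  }
  load_dataset(out_dir)
}

#' Display one sample as a side-by-side image/mask panel
#'
#' @param record A `sample_record`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_sample <- function(record, ...) {
  stopifnot(inherits(record, "sample_record"))
  h <- dim(record$mask)[1]; w <- dim(record$mask)[2]
  grid <- expand.grid(row = seq_len(h), col = seq_len(w))
  df <- rbind(
    cbind(grid, panel = "image",
          fill = grDevices::rgb(record$image[, , 1], record$image[, , 2],
                                record$image[, , 3])),
    cbind(grid, panel = "mask",
          fill = ifelse(record$mask == 1, "white", "black")))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = I(.data$fill))) +
    ggplot2::scale_y_reverse() +
    ggplot2::facet_wrap(~panel) +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}
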
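# Standalone layer operations on plain feature-map arrays.
#
# A feature map is a rank-3 numeric array (channels x height x width).
# These functions back the network engine's building blocks one at a time
# so each can be exercised and checked in isolation.

as_feature_map <- function(x) {
  if (is.matrix(x)) x <- array(x, dim = c(1L, dim(x)))
  if (!is.array(x) || length(dim(x)) != 3)
    stop("a feature map must be a channels x height x width array",
         call. = FALSE)
  if (!all(is.finite(x))) stop("feature map values must be finite", call. = FALSE)
  x
}

# engine layout: one row per channel, one column per pixel (p = h + H*(w-1))
fm_to_mat <- function(x) {
  d <- dim(x)
  matrix(aperm(x, c(2L, 3L, 1L)), nrow = d[1], byrow = TRUE)
}
mat_to_fm <- function(m, H, W) {
  aperm(array(t(m), dim = c(H, W, nrow(m))), c(3L, 1L, 2L))
}

# kernel array (k, k, cin, cout) -> engine weight matrix, with column
# (ki*k + kj)*cin + c matching the im2col row ordering
flatten_kernel <- function(kernel) {
  d <- dim(kernel)
  if (length(d) != 4 || d[1] != d[2])
    stop("kernel must be a (k, k, in_channels, out_channels) array",
         call. = FALSE)
  k <- d[1]
  t(matrix(aperm(kernel, c(3L, 2L, 1L, 4L)), ncol = d[4]))
}

#' Convolution block: convolution + feature normalisation + ReLU
#'
#' Applies a same-padded 2-D convolution with bias (optionally dilated),
#' then (optionally) per-channel standardisation with trainable-style scale
#' and shift, then (optionally) the ReLU.  With `normalize = FALSE` and
#' `activation = FALSE` this is the bare convolution of the network's
#' convolutional layers.
#'
#' @param input Feature map, a (channels, height, width) array (a plain
#'   matrix is treated as a single-channel map).
#' @param kernel A (k, k, in_channels, out_channels) array; k must be odd.
#' @param bias Numeric vector of length `out_channels` (default zeros).
#' @param dilation Dilation factor (1 = ordinary convolution).
#' @param normalize If `TRUE`, standardise each output channel over the map
#'   and apply `scale`/`shift` (the batch-norm transform evaluated on this
#'   single map's statistics).
#' @param scale,shift Per-channel normalisation parameters.
#' @param activation If `TRUE` apply the ReLU `max(0, y)`.
#' @param eps Variance floor of the normalisation.
#' @return Feature map with `out_channels` channels at the input resolution.
#' @examples
#' x <- array(1, dim = c(1, 3, 3))
#' k <- array(1, dim = c(3, 3, 1, 1))
#' conv_block(x, k, activation = FALSE)[1, 2, 2]  # centre sees all 9 ones
#' @export
conv_block <- function(input, kernel, bias = NULL, dilation = 1L,
                       normalize = FALSE, scale = NULL, shift = NULL,
                       activation = TRUE, eps = 1e-5) {
  x <- as_feature_map(input)
  d <- dim(kernel)
  if (length(d) != 4 || d[1] != d[2])
    stop("kernel must be a (k, k, in_channels, out_channels) array",
         call. = FALSE)
  k <- d[1]
  if (k %% 2 == 0) stop("kernel size must be odd", call. = FALSE)
  if (d[3] != dim(x)[1])
    stop("kernel input channels (", d[3], ") do not match feature map (",
         dim(x)[1], ")", call. = FALSE)
  cout <- d[4]
  if (is.null(bias)) bias <- numeric(cout)
  if (length(bias) != cout) stop("bias length must equal out_channels",
                                 call. = FALSE)
  H <- dim(x)[2]; W <- dim(x)[3]
  y <- .op_conv(fm_to_mat(x), H, W, flatten_kernel(kernel), bias,
                as.integer(k), as.integer(dilation))
  if (normalize) {
    if (is.null(scale)) scale <- rep(1, cout)
    if (is.null(shift)) shift <- numeric(cout)
    mu <- rowMeans(y)
    v <- rowMeans(y^2) - mu^2
    y <- scale * (y - mu) / sqrt(v + eps) + shift
  }
  if (activation) y <- pmax(y, 0)
  mat_to_fm(y, H, W)
}

#' Max pooling with argmax indices
#'
#' 2x2 max pooling with stride 2.  Alongside the pooled map it records, for
#' every output cell and channel, the position of the window maximum in the
#' pre-pool map, so the exact locations can be restored by
#' [unpool_with_indices()].  Ties are broken by the first occurrence in
#' row-major window order.
#'
#' @param input Feature map with even height and width.
#' @return A `pooled_feature`: list with `pooled` (half-resolution feature
#'   map), `indices` (same shape as `pooled`; 1-based flat index of the
#'   argmax within its `height x width` plane, column-major), and
#'   `pre_pool_size`.
#' @export
pool_with_indices <- function(input) {
  x <- as_feature_map(input)
  d <- dim(x)
  if (d[2] < 2 || d[3] < 2) stop("feature map too small to pool", call. = FALSE)
  if (d[2] %% 2 || d[3] %% 2)
    stop("pooling requires even height and width", call. = FALSE)
  r <- .op_pool(fm_to_mat(x), d[2], d[3])
  Ho <- d[2] %/% 2L; Wo <- d[3] %/% 2L
  structure(list(
    pooled = mat_to_fm(r$pooled, Ho, Wo),
    indices = mat_to_fm(r$indices + 1, Ho, Wo),
    pre_pool_size = c(d[2], d[3])
  ), class = "pooled_feature")
}

#' Max unpooling from recorded indices
#'
#' Scatters each pooled value back to the exact position its pooling argmax
#' recorded; every other cell of the restored map is zero.
#'
#' @param pooled A `pooled_feature` from [pool_with_indices()].
#' @return Feature map at the pre-pool resolution.
#' @export
unpool_with_indices <- function(pooled) {
  stopifnot(inherits(pooled, "pooled_feature"))
  H <- pooled$pre_pool_size[1]; W <- pooled$pre_pool_size[2]
  idx <- pooled$indices - 1
  if (any(idx < 0) || any(idx >= H * W))
    stop("pooling index out of range for pre_pool_size", call. = FALSE)
  d <- dim(pooled$pooled)
  y <- .op_unpool(fm_to_mat(pooled$pooled),
                  matrix(as.integer(fm_to_mat(idx)), nrow = d[1]),
                  d[2], d[3], H, W)
  mat_to_fm(y, H, W)
}

#' Parallel dilated-convolution pyramid
#'
#' Four same-padded dilated convolution blocks (dilations 1, 6, 12, 18)
#' applied in parallel to the same input, concatenated along channels, then
#' projected back to a target width by a final convolution block.  Because
#' every branch is same-padded, the resolution never changes while the
#' receptive field grows to `k + (k-1)(l-1)` cells per axis.
#'
#' @param input Feature map (the deepest encoder output).
#' @param branch_kernels List of four (k, k, cin, b) kernel arrays, one per
#'   dilation.
#' @param branch_biases Optional list of four bias vectors.
#' @param projection_kernel A (k, k, 4*b, cout) kernel for the projection
#'   block (`NULL` to return the raw concatenation).
#' @param projection_bias Optional projection bias.
#' @param dilations Must equal the architecture's dilation set
#'   `c(1, 6, 12, 18)`.
#' @param normalize,activation Passed to each [conv_block()].
#' @return Feature map at the input resolution.
#' @export
dilated_pyramid <- function(input, branch_kernels, branch_biases = NULL,
                            projection_kernel = NULL, projection_bias = NULL,
                            dilations = c(1L, 6L, 12L, 18L),
                            normalize = FALSE, activation = TRUE) {
  if (!identical(as.integer(dilations), c(1L, 6L, 12L, 18L)))
    stop("dilations must equal the architecture's dilation set (1, 6, 12, 18)",
         call. = FALSE)
  if (length(branch_kernels) != 4) stop("need one kernel per dilation",
                                        call. = FALSE)
  branches <- lapply(seq_along(dilations), function(i) {
    conv_block(input, branch_kernels[[i]],
               bias = if (is.null(branch_biases)) NULL else branch_biases[[i]],
               dilation = dilations[i], normalize = normalize,
               activation = activation)
  })
  out <- do.call(skip_merge_concat, branches)
  if (!is.null(projection_kernel))
    out <- conv_block(out, projection_kernel, bias = projection_bias,
                      normalize = normalize, activation = activation)
  out
}

skip_merge_concat <- function(...) {
  maps <- lapply(list(...), as_feature_map)
  dims <- vapply(maps, function(m) dim(m)[2:3], numeric(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("resolution mismatch in channel concatenation", call. = FALSE)
  ctot <- sum(vapply(maps, function(m) dim(m)[1], numeric(1)))
  out <- array(0, dim = c(ctot, dims[1, 1], dims[2, 1]))
  at <- 0L
  for (m in maps) {
    out[at + seq_len(dim(m)[1]), , ] <- m
    at <- at + dim(m)[1]
  }
  out
}

#' Merge an encoder feature into the decoder path
#'
#' Skip connections route each encoder depth's output to the matching
#' decoder depth.  `add` sums the two maps element-wise (parameter-free and
#' width-preserving); `concat` stacks them along channels.
#'
#' @param encoder_feature,decoder_feature Feature maps at the same spatial
#'   resolution (and the same channel count for `mode = "add"`).
#' @param mode `"add"` or `"concat"`.
#' @return The merged feature map.
#' @export
skip_merge <- function(encoder_feature, decoder_feature,
                       mode = c("add", "concat")) {
  mode <- match.arg(mode)
  e <- as_feature_map(encoder_feature)
  d <- as_feature_map(decoder_feature)
  if (any(dim(e)[2:3] != dim(d)[2:3]))
    stop("skip merge requires matching spatial resolution", call. = FALSE)
  if (mode == "add") {
    if (dim(e)[1] != dim(d)[1])
      stop("additive skip merge requires matching channel counts",
           call. = FALSE)
    e + d
  } else {
    skip_merge_concat(e, d)
  }
}
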
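#' Segment images with a trained network
#'
#' Runs the forward pass and returns per-pixel class probabilities or the
#' binary polyp mask (argmax).  Inputs whose height or width is not
#' divisible by 2^depth are zero-padded on the bottom/right internally and
#' the output is cropped back, so the result always has the input's
#' resolution.
#'
#' @param object A `segnet_model`.
#' @param newdata One image as an (H, W, 3) array in `[0, 1]`, a list of
#'   such arrays, a `sample_record`, or an (H, W, 3, B) batch.
#' @param type `"prob"` for (H, W, 2) probability maps (channel 1
#'   background, channel 2 polyp) or `"mask"` for binary masks.
#' @param batch_statistics Use the current batch's normalisation statistics
#'   instead of the running averages (automatic for untrained models, which
#'   have no running averages yet).
#' @param ... Unused.
#' @return A single array/mask, or a list of them when `newdata` is a list
#'   or a batch.
#' @export
predict.segnet_model <- function(object, newdata, type = c("prob", "mask"),
                                 batch_statistics = !object$trained, ...) {
  type <- match.arg(type)
  single <- FALSE
  if (inherits(newdata, "sample_record")) newdata <- newdata$image
  if (is.array(newdata) && length(dim(newdata)) == 3) {
    newdata <- list(newdata)
    single <- TRUE
  } else if (is.array(newdata) && length(dim(newdata)) == 4) {
    newdata <- lapply(seq_len(dim(newdata)[4]), function(b) newdata[, , , b])
  }
  depth <- length(object$spec$encoder_channels)
  div <- 2L^depth
  out <- lapply(newdata, function(img) {
    d <- dim(img)
    if (length(d) != 3 || d[3] != 3)
      stop("each image must be an (H, W, 3) array", call. = FALSE)
    Hp <- as.integer(ceiling(d[1] / div) * div)
    Wp <- as.integer(ceiling(d[2] / div) * div)
    x <- img
    if (Hp != d[1] || Wp != d[2]) {
      x <- array(0, dim = c(Hp, Wp, 3))
      x[seq_len(d[1]), seq_len(d[2]), ] <- img
    }
    p <- .net_forward(object$ptr, x, isTRUE(batch_statistics))
    p <- p[seq_len(d[1]), seq_len(d[2]), , 1, drop = FALSE]
    dim(p) <- dim(p)[1:3]
    if (type == "mask") (p[, , 2] > p[, , 1]) * 1L else p
  })
  if (single) out[[1]] else out
}

#' Save and restore model checkpoints
#'
#' A checkpoint is a single serialized archive of the architecture
#' specification, all trainable tensors and the batch-norm running
#' statistics, accompanied by a plain-JSON side-car (`<path>.json`) holding
#' the model summary for inspection without loading the weights.
#'
#' @param model A `segnet_model`.
#' @param path Destination file (conventionally `.rds`).
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the rebuilt `segnet_model`.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "segnet_model"))
  weights <- .net_get_weights(model$ptr)
  saveRDS(list(spec = unclass(model$spec), weights = weights,
               seed = model$seed, trained = model$trained), path)
  s <- count_trainable_parameters(model)
  jsonlite::write_json(
    list(variant = s$variant,
         trainable_parameter_count = s$trainable_parameter_count,
         layer_count = s$layer_count,
         per_block = s$per_block_parameter_table,
         seed = model$seed, trained = model$trained),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  spec <- structure(ck$spec, class = "architecture_spec")
  model <- build_model(spec, seed = ck$seed)
  w <- ck$weights
  .net_set_weights(model$ptr, w$conv_w, w$conv_b, w$bn_scale, w$bn_shift,
                   w$bn_mean, w$bn_var)
  model$trained <- isTRUE(ck$trained)
  model
}
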
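#' Optimisation protocol as data
#'
#' The default values are the reference training protocol: stochastic
#' gradient descent with momentum 0.9, base learning rate 0.001, 100
#' epochs, mini-batches of four, and the learning rate reduced by a factor
#' of 0.3 after every 10 epochs.
#'
#' @param momentum SGD momentum coefficient.
#' @param base_learning_rate Learning rate at epoch 1.
#' @param epochs Number of passes over the training set.
#' @param mini_batch_size Images per gradient step.
#' @param lr_drop_factor Multiplicative learning-rate decay, in (0, 1).
#' @param lr_drop_period_epochs Epochs between decays.
#' @param seed Seed controlling shuffling (and any other randomness in the
#'   run).
#' @param shuffle_each_epoch Reshuffle the sample stream every pass.
#' @param batcher `"rolling"` streams shuffled samples continuously across
#'   epoch boundaries, so the total step count is
#'   `floor(n * epochs / batch)` (831 training images for 100 epochs at
#'   batch 4 give exactly 20,775 iterations); `"per_epoch"` closes each
#'   epoch with a partial batch, giving `epochs * ceiling(n / batch)` steps.
#' @return A `train_config` object.
#' @export
train_config <- function(momentum = 0.9, base_learning_rate = 0.001,
                         epochs = 100L, mini_batch_size = 4L,
                         lr_drop_factor = 0.3, lr_drop_period_epochs = 10L,
                         seed = 1L, shuffle_each_epoch = TRUE,
                         batcher = c("rolling", "per_epoch")) {
  batcher <- match.arg(batcher)
  if (lr_drop_factor <= 0 || lr_drop_factor >= 1)
    stop("lr_drop_factor must lie strictly between 0 and 1", call. = FALSE)
  if (epochs < 1 || mini_batch_size < 1 || lr_drop_period_epochs < 1)
    stop("epochs, mini_batch_size and lr_drop_period_epochs must be >= 1",
         call. = FALSE)
  structure(list(momentum = momentum,
                 base_learning_rate = base_learning_rate,
                 epochs = as.integer(epochs),
                 mini_batch_size = as.integer(mini_batch_size),
                 lr_drop_factor = lr_drop_factor,
                 lr_drop_period_epochs = as.integer(lr_drop_period_epochs),
                 seed = as.integer(seed),
                 shuffle_each_epoch = isTRUE(shuffle_each_epoch),
                 batcher = batcher),
            class = "train_config")
}

#' Piecewise-constant learning-rate schedule
#'
#' `rate = base * factor^floor((epoch - 1) / period)`: the base rate holds
#' for the first period, then drops by the factor after every further
#' period.
#'
#' @param epoch 1-based epoch number.
#' @param config A [train_config()].
#' @return The learning rate for that epoch.
#' @examples
#' lr_schedule(11, train_config())  # one drop: 0.001 * 0.3
#' @export
lr_schedule <- function(epoch, config = train_config()) {
  stopifnot(inherits(config, "train_config"))
  if (any(epoch < 1) || any(epoch > config$epochs))
    stop("epoch out of range 1..", config$epochs, call. = FALSE)
  config$base_learning_rate *
    config$lr_drop_factor^floor((epoch - 1) / config$lr_drop_period_epochs)
}

#' Planned gradient-step count for a training run
#'
#' @param n_samples Training-set size.
#' @param config A [train_config()].
#' @return Total number of gradient steps the trainer will take.
#' @examples
#' planned_iterations(831, train_config())  # 20775
#' @export
planned_iterations <- function(n_samples, config = train_config()) {
  stopifnot(inherits(config, "train_config"))
  if (config$batcher == "rolling")
    floor(n_samples * config$epochs / config$mini_batch_size)
  else
    config$epochs * ceiling(n_samples / config$mini_batch_size)
}

#' Pixel-wise cross-entropy of a probability map against a truth mask
#'
#' The mean over pixels of `-log p(true class)`.  Zero exactly when the
#' model assigns probability one to the true class everywhere.
#'
#' @param probabilities A (height, width, 2) array of per-pixel class
#'   probabilities (channel 1 background, channel 2 polyp), normalised to
#'   one at every pixel (tolerance 1e-4).
#' @param truth_mask A (height, width) binary mask (1 = polyp).
#' @return Scalar loss (nats per pixel).
#' @export
pixelwise_loss <- function(probabilities, truth_mask) {
  d <- dim(probabilities)
  if (length(d) != 3 || d[3] != 2)
    stop("probabilities must be a (height, width, 2) array", call. = FALSE)
  if (!identical(dim(truth_mask), d[1:2]))
    stop("probability map and truth mask shapes differ", call. = FALSE)
  if (!all(truth_mask %in% c(0, 1)))
    stop("truth mask must be strictly binary", call. = FALSE)
  tot <- probabilities[, , 1] + probabilities[, , 2]
  if (max(abs(tot - 1)) > 1e-4)
    stop("probabilities are not normalised per pixel", call. = FALSE)
  p_true <- ifelse(truth_mask == 1, probabilities[, , 2], probabilities[, , 1])
  mean(-log(pmax(p_true, .Machine$double.xmin)))
}

# Assemble the in-memory training tensors from a manifest or an in-memory
# sample list, standardised to the model's input size.
assemble_training_set <- function(train_set, input_size) {
  if (inherits(train_set, "data.frame")) {
    rows <- if ("split" %in% names(train_set) &&
                any(train_set$split == "train"))
      train_set[train_set$split == "train", ] else train_set
    samples <- lapply(seq_len(nrow(rows)), function(i)
      read_sample(rows$image_path[i], rows$mask_path[i],
                  collection = rows$collection[i]))
  } else if (is.list(train_set) && !is.null(train_set$images)) {
    samples <- lapply(seq_along(train_set$images), function(i)
      new_sample_record(train_set$images[[i]], train_set$masks[[i]],
                        collection = "memory"))
  } else if (is.list(train_set) && all(vapply(train_set, inherits,
                                              logical(1), "sample_record"))) {
    samples <- train_set
  } else stop("train_set must be a manifest data frame, a list of ",
              "sample records, or list(images = , masks = )", call. = FALSE)
  if (length(samples) == 0) stop("training set is empty", call. = FALSE)
  samples <- lapply(samples, standardize_sample,
                    target_resolution = input_size)
  H <- input_size[1]; W <- input_size[2]; n <- length(samples)
  X <- array(0, dim = c(H, W, 3, n))
  Y <- matrix(0L, nrow = H * W, ncol = n)
  for (i in seq_len(n)) {
    X[, , , i] <- samples[[i]]$image
    Y[, i] <- as.integer(samples[[i]]$mask)
  }
  list(X = X, Y = Y, n = n)
}

#' Train a network with momentum SGD
#'
#' Runs the full optimisation protocol in [train_config()] over the
#' training set: seeded shuffling, mini-batch momentum SGD, the
#' piecewise-constant learning-rate schedule, and per-iteration loss /
#' per-epoch pixel-accuracy bookkeeping.  Deterministic for a fixed seed.
#'
#' @param model A `segnet_model` (modified in place; also returned inside
#'   the record).
#' @param train_set A dataset manifest (rows tagged `train` are used if a
#'   split is present), a list of `sample_record`s, or
#'   `list(images =, masks =)` of in-memory arrays.
#' @param config A [train_config()].
#' @param checkpoint Optional file path; the final weights are saved there
#'   with [save_checkpoint()].
#' @param verbose Print one line per epoch.
#' @return A `train_record` with the iteration table (loss, learning rate),
#'   the epoch table (mean loss, training pixel accuracy, seconds) and the
#'   trained model.
#' @export
train_model <- function(model, train_set, config = train_config(),
                        checkpoint = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "segnet_model"), inherits(config, "train_config"))
  data <- assemble_training_set(train_set, model$spec$input_size)
  n <- data$n
  batch <- config$mini_batch_size
  total <- planned_iterations(n, config)
  it_epoch <- integer(total); it_lr <- numeric(total)
  it_loss <- numeric(total); it_acc <- numeric(total)
  epoch_t0 <- Sys.time(); epoch_secs <- numeric(config$epochs)
  withr::with_seed(config$seed, {
    stream <- integer(0)
    refill <- function(s) c(s, if (config$shuffle_each_epoch) sample.int(n)
                            else seq_len(n))
    cur_epoch <- 1L
    for (it in seq_len(total)) {
      if (config$batcher == "rolling") {
        while (length(stream) < batch) stream <- refill(stream)
        idx <- stream[seq_len(batch)]
        stream <- stream[-seq_len(batch)]
        epoch <- min(floor(((it - 1) * batch) / n) + 1L, config$epochs)
      } else {
        if (length(stream) == 0) stream <- refill(integer(0))
        idx <- stream[seq_len(min(batch, length(stream)))]
        stream <- stream[-seq_len(length(idx))]
        epoch <- min(ceiling(it / ceiling(n / batch)), config$epochs)
      }
      lr <- lr_schedule(epoch, config)
      xb <- data$X[, , , idx, drop = FALSE]
      yb <- as.integer(data$Y[, idx])
      step <- .net_train_step(model$ptr, xb, yb, lr, config$momentum)
      if (!is.finite(step$loss))
        stop("non-finite loss at iteration ", it,
             " (epoch ", epoch, ", lr ", lr, "); aborting", call. = FALSE)
      it_epoch[it] <- epoch; it_lr[it] <- lr
      it_loss[it] <- step$loss; it_acc[it] <- step$accuracy
      if (epoch != cur_epoch || it == total) {
        done <- if (it == total) epoch else cur_epoch
        epoch_secs[done] <- as.numeric(difftime(Sys.time(), epoch_t0,
                                                units = "secs"))
        epoch_t0 <- Sys.time()
        if (verbose)
          message(sprintf("epoch %3d  lr %.2e  loss %.4f  acc %.4f",
                          done, lr_schedule(done, config),
                          mean(it_loss[it_epoch == done]),
                          mean(it_acc[it_epoch == done])))
        cur_epoch <- epoch
      }
    }
  })
  model$trained <- TRUE
  iterations <- tibble::tibble(iteration = seq_len(total), epoch = it_epoch,
                               learning_rate = it_lr, loss = it_loss,
                               accuracy = it_acc)
  epochs <- dplyr::summarise(dplyr::group_by(iterations, epoch = .data$epoch),
                             learning_rate = .data$learning_rate[1],
                             mean_loss = mean(.data$loss),
                             accuracy = mean(.data$accuracy),
                             .groups = "drop")
  epochs$seconds <- epoch_secs[epochs$epoch]
  record <- structure(list(iterations = iterations, epochs = epochs,
                           config = config, model = model,
                           checkpoint = checkpoint),
                      class = "train_record")
  if (!is.null(checkpoint)) save_checkpoint(model, checkpoint)
  record
}

#' @export
print.train_record <- function(x, ...) {
  last <- x$epochs[nrow(x$epochs), ]
  cat(sprintf(paste0("<train_record> %d iterations over %d epochs\n",
                     "  final epoch: loss %.4f, training pixel accuracy %.4f\n"),
              nrow(x$iterations), nrow(x$epochs), last$mean_loss,
              last$accuracy))
  invisible(x)
}

#' @export
tidy.train_record <- function(x, per = c("epoch", "iteration"), ...) {
  per <- match.arg(per)
  if (per == "epoch") x$epochs else x$iterations
}

#' @export
glance.train_record <- function(x, ...) {
  last <- x$epochs[nrow(x$epochs), ]
  tibble::tibble(iterations = nrow(x$iterations), epochs = nrow(x$epochs),
                 final_loss = last$mean_loss, final_accuracy = last$accuracy,
                 seed = x$config$seed)
}

#' Learning curves of a training run
#'
#' @param object A `train_record`.
#' @param ... Unused.
#' @return A ggplot of per-epoch loss and training pixel accuracy.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.train_record <- function(object, ...) {
  df <- tidyr::pivot_longer(object$epochs[c("epoch", "mean_loss", "accuracy")],
                            -"epoch", names_to = "curve")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~curve, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL)
}

#' @export
ggplot2::autoplot
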
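#' Describe one network variant
#'
#' An architecture specification is a declarative description of one member
#' of the modified SegNet family.  The three named variants share the same
#' block structure and differ only in encoder depth and channel plan:
#'
#' * `small` - 3 encoder depths, channels 64/128/256 (the 100-layer network);
#' * `proposed` - 5 encoder depths, channels 64/128/256/512/512 (154 layers);
#' * `large` - 7 encoder depths, channels 64/128/256/512/512/1024/1024
#'   (208 layers).
#'
#' Every depth carries its VGG-19 3x3 convolution blocks (2,2,4,4,4 per
#' depth; the two deepest depths of `large` repeat the 4-block plan), depths
#' 1-2 carry two additional 5x5 blocks appended after the 3x3 blocks on the
#' encoder side and prepended on the decoder side, and the decoder plan is
#' the exact mirror of the encoder plan.  A parallel pyramid of four dilated
#' 3x3 convolution blocks (dilations 1, 6, 12, 18) sits at the encoder
#' bottleneck; its concatenated output is projected back to the bottleneck
#' width by a final 3x3 convolution block.  The per-variant pyramid branch
#' widths (200/254/312 channels) are calibrated so that the total trainable
#' parameter count of each variant matches its published complexity budget
#' (10.4M / 51.5M / 206.7M) at 0.1M rounding.
#'
#' @param variant One of `"proposed"`, `"small"`, `"large"`.
#' @param input_size Integer (height, width) the network standardises its
#'   inputs to.  Default `c(288, 384)`, the smallest native resolution among
#'   the public polyp datasets.  Inputs whose size is not divisible by
#'   2^depth are zero-padded internally and the output cropped back.
#' @param skip_merge_mode How encoder features are merged into the decoder:
#'   `"add"` (element-wise, parameter-free; the default) or `"concat"`.
#' @param num_classes Number of output classes; fixed at 2 (polyp,
#'   background).
#'
#' @return An object of class `architecture_spec`.
#' @examples
#' spec <- architecture_spec("proposed")
#' spec$encoder_channels
#' @export
architecture_spec <- function(variant = c("proposed", "small", "large"),
                              input_size = c(288L, 384L),
                              skip_merge_mode = c("add", "concat"),
                              num_classes = 2L) {
  if (is.character(variant) && length(variant) == 1 &&
      !variant %in% c("proposed", "small", "large")) {
    stop("unknown variant name: '", variant,
         "' (expected one of 'proposed', 'small', 'large')", call. = FALSE)
  }
  variant <- match.arg(variant)
  skip_merge_mode <- match.arg(skip_merge_mode)
  plans <- list(
    small    = list(ch = c(64L, 128L, 256L), pyramid = 200L),
    proposed = list(ch = c(64L, 128L, 256L, 512L, 512L), pyramid = 254L),
    large    = list(ch = c(64L, 128L, 256L, 512L, 512L, 1024L, 1024L),
                    pyramid = 312L)
  )
  plan <- plans[[variant]]
  depth <- length(plan$ch)
  n33 <- c(2L, 2L, 4L, 4L, 4L, 4L, 4L)[seq_len(depth)]
  convs_per_depth <- lapply(seq_len(depth), function(d) {
    c(n_3x3 = n33[d], n_5x5 = if (d <= 2) 2L else 0L)
  })
  input_size <- as.integer(input_size)
  if (length(input_size) != 2 || any(input_size < 2^depth))
    stop("input_size must be (height, width), each at least 2^depth",
         call. = FALSE)
  if (num_classes != 2L)
    stop("num_classes is fixed at 2 (polyp, background)", call. = FALSE)
  spec <- structure(list(
    variant_name = variant,
    encoder_channels = plan$ch,
    convs_per_depth = convs_per_depth,
    dilation_set = c(1L, 6L, 12L, 18L),
    pyramid_channels = plan$pyramid,
    num_classes = 2L,
    skip_merge_mode = skip_merge_mode,
    input_size = input_size
  ), class = "architecture_spec")
  stopifnot(!is.unsorted(spec$encoder_channels))
  spec
}

#' @export
print.architecture_spec <- function(x, ...) {
  cat("<architecture_spec> variant:", x$variant_name, "\n")
  cat("  encoder channels :", paste(x$encoder_channels, collapse = ", "), "\n")
  cat("  conv blocks/depth:",
      paste(vapply(x$convs_per_depth,
                   function(v) sprintf("%dx3x3+%dx5x5", v[1], v[2]),
                   character(1)), collapse = ", "), "\n")
  cat("  pyramid          : dilations", paste(x$dilation_set, collapse = "/"),
      "at", x$pyramid_channels, "channels\n")
  cat("  skip merge       :", x$skip_merge_mode, "\n")
  cat("  input size       :", paste(x$input_size, collapse = " x "), "\n")
  invisible(x)
}

# Walk the architecture plan once, emitting (a) the primitive-layer table
# used for layer/parameter accounting and (b) the engine program.  Both
# views are derived from the same walk so they cannot drift apart.
build_graph_plan <- function(spec) {
  ch <- spec$encoder_channels
  D <- length(ch)
  concat_skip <- spec$skip_merge_mode == "concat"

  layers <- list()
  instrs <- list()
  convs <- list()
  bns <- integer(0)
  slot <- 0L          # current data slot (0 = input)
  n_slots <- 1L

  new_slot <- function() {
    s <- n_slots
    n_slots <<- n_slots + 1L
    s
  }
  add_layer <- function(name, kind, block = NA_character_, k = NA_integer_,
                        dil = NA_integer_, cin = NA_integer_,
                        cout = NA_integer_) {
    layers[[length(layers) + 1L]] <<- list(
      name = name, kind = kind, block = block, kernel = k, dilation = dil,
      in_channels = cin, out_channels = cout)
  }
  add_instr <- function(op, p, src, dst) {
    instrs[[length(instrs) + 1L]] <<- list(op = op, p = p,
                                           src = as.integer(src),
                                           dst = as.integer(dst))
  }
  # conv + batch-norm + ReLU
  conv_block_ <- function(name, block, k, dil, cin, cout) {
    convs[[length(convs) + 1L]] <<- list(k = k, cin = cin, cout = cout,
                                         dil = dil, name = name)
    bns[length(bns) + 1L] <<- cout
    pc <- length(convs) - 1L
    pb <- length(bns) - 1L
    s1 <- new_slot(); add_instr(1L, pc, slot, s1)
    s2 <- new_slot(); add_instr(2L, pb, s1, s2)
    s3 <- new_slot(); add_instr(3L, -1L, s2, s3)
    slot <<- s3
    add_layer(name, "conv", block, k, dil, cin, cout)
    add_layer(paste0(name, "_bn"), "batchnorm", block, cout = cout)
    add_layer(paste0(name, "_relu"), "relu", block, cout = cout)
  }

  add_layer("input", "input", cout = 3L)
  enc_tap <- integer(D)
  n_pools <- 0L
  prev <- 3L
  for (d in seq_len(D)) {
    nb <- spec$convs_per_depth[[d]]
    for (i in seq_len(nb["n_3x3"])) {
      conv_block_(sprintf("enc%d_conv%d", d, i), sprintf("encoder%d", d),
                  3L, 1L, prev, ch[d])
      prev <- ch[d]
    }
    for (i in seq_len(nb["n_5x5"]))
      conv_block_(sprintf("enc%d_conv5x5_%d", d, i), sprintf("encoder%d", d),
                  5L, 1L, ch[d], ch[d])
    enc_tap[d] <- slot
    s <- new_slot(); add_instr(4L, n_pools, slot, s)
    n_pools <- n_pools + 1L
    slot <- s
    add_layer(sprintf("pool%d", d), "pool", sprintf("encoder%d", d),
              cout = ch[d])
  }

  # dilated-convolution pyramid at the bottleneck
  pyr_in <- slot
  branch_slots <- integer(0)
  for (l in spec$dilation_set) {
    slot <- pyr_in
    conv_block_(sprintf("pyramid_d%d", l), "pyramid", 3L, as.integer(l),
                ch[D], spec$pyramid_channels)
    branch_slots <- c(branch_slots, slot)
  }
  s <- new_slot(); add_instr(7L, -1L, branch_slots, s)
  slot <- s
  add_layer("pyramid_concat", "merge", "pyramid",
            cout = 4L * spec$pyramid_channels)
  conv_block_("pyramid_proj", "pyramid", 3L, 1L,
              4L * spec$pyramid_channels, ch[D])

  # decoder mirrors the encoder
  for (d in rev(seq_len(D))) {
    s <- new_slot(); add_instr(5L, d - 1L, slot, s)
    slot <- s
    add_layer(sprintf("unpool%d", d), "unpool", sprintf("decoder%d", d),
              cout = ch[d])
    s <- new_slot()
    add_instr(if (concat_skip) 7L else 6L, -1L, c(slot, enc_tap[d]), s)
    slot <- s
    add_layer(sprintf("skip%d", d), "merge", sprintf("decoder%d", d),
              cout = ch[d] * (1L + concat_skip))
    cin <- ch[d] * (1L + concat_skip)
    nb <- spec$convs_per_depth[[d]]
    kseq <- c(rep(5L, nb["n_5x5"]), rep(3L, nb["n_3x3"]))
    tgt <- if (d > 1) ch[d - 1L] else spec$num_classes
    for (i in seq_along(kseq)) {
      cout <- if (i == length(kseq)) tgt else ch[d]
      conv_block_(sprintf("dec%d_conv%d%s", d, i,
                          if (kseq[i] == 5L) "_5x5" else ""),
                  sprintf("decoder%d", d), kseq[i], 1L, cin, cout)
      cin <- cout
    }
  }
  add_layer("softmax", "softmax", cout = spec$num_classes)
  add_layer("pixel_classification", "pixelclass", cout = spec$num_classes)

  layers <- tibble::as_tibble(do.call(rbind, lapply(layers, function(l) {
    data.frame(name = l$name, kind = l$kind, block = l$block,
               kernel = l$kernel, dilation = l$dilation,
               in_channels = l$in_channels, out_channels = l$out_channels,
               stringsAsFactors = FALSE)
  })))
  list(layers = layers, instrs = instrs, convs = convs, bns = bns,
       n_slots = n_slots, n_pools = n_pools)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a network from an architecture specification
#'
#' Constructs the full layer graph (encoder, bottleneck pyramid, mirrored
#' decoder with index-passing unpooling and per-depth skip merges),
#' allocates its trainable tensors and initialises them with He-scaled
#' Gaussian draws from the supplied seed.
#'
#' @param spec An [architecture_spec()].
#' @param seed Integer seed for the weight initialisation (recorded in the
#'   model object).
#' @return An object of class `segnet_model` holding the specification, the
#'   primitive-layer table, and a handle to the network state.
#' @examples
#' m <- build_model(architecture_spec("small", input_size = c(64, 64)))
#' count_layers(m)
#' @export
build_model <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "architecture_spec"))
  plan <- build_graph_plan(spec)
  ptr <- .net_create(plan$instrs, plan$convs, as.integer(plan$bns),
                     plan$n_slots, plan$n_pools)
  model <- structure(list(
    spec = spec, layers = plan$layers, plan = plan, ptr = ptr,
    seed = as.integer(seed), trained = FALSE
  ), class = "segnet_model")
  init_weights(model, seed)
  model
}

# He initialisation: kernel sd = sqrt(2 / fan_in), zero biases, unit
# batch-norm scale, zero shift.  Drawn from one seeded stream in layer
# order, so identical seeds give identical networks.
init_weights <- function(model, seed) {
  convs <- model$plan$convs
  withr::with_seed(as.integer(seed), {
    W <- lapply(convs, function(cp) {
      fan_in <- cp$k^2 * cp$cin
      matrix(rnorm(cp$cout * cp$k^2 * cp$cin, sd = sqrt(2 / fan_in)),
             nrow = cp$cout)
    })
  })
  b <- lapply(convs, function(cp) numeric(cp$cout))
  g <- lapply(model$plan$bns, function(c) rep(1, c))
  bt <- lapply(model$plan$bns, function(c) numeric(c))
  nil <- vector("list", length(model$plan$bns))
  .net_set_weights(model$ptr, W, b, g, bt, nil, nil)
  invisible(model)
}

#' Count primitive layers of a network graph
#'
#' Every primitive layer counts once: the input layer, each convolution,
#' each batch normalisation, each ReLU, each pooling and unpooling layer,
#' each merge (skip merges and the pyramid concatenation), the softmax and
#' the pixel-classification output.
#'
#' @param model A `segnet_model`.
#' @return Integer layer count (154 for the proposed variant, 100 for
#'   `small`, 208 for `large`).
#' @export
count_layers <- function(model) {
  stopifnot(inherits(model, "segnet_model"))
  nrow(model$layers)
}

# Closed-form accounting, independent of the engine's tensors: each
# convolution contributes kh*kw*Cin*Cout weights + Cout biases, each batch
# normalisation 2*C (scale and shift).
closed_form_parameters <- function(layers) {
  conv <- layers[layers$kind == "conv", ]
  bn <- layers[layers$kind == "batchnorm", ]
  sum(conv$kernel^2 * conv$in_channels * conv$out_channels + conv$out_channels) +
    sum(2 * bn$out_channels)
}

#' Count trainable parameters and summarise the network
#'
#' Walks the built graph summing every trainable tensor (convolution
#' kernels and biases, batch-norm scale and shift), and cross-checks the
#' total against an independent closed-form accounting over the layer
#' table.  Running batch-norm statistics are not trainable and are not
#' counted.
#'
#' @param model A `segnet_model`.
#' @return A `model_summary` with the graph-walk count, the closed-form
#'   count, the layer count and a per-block parameter table.
#' @examples
#' m <- build_model(architecture_spec("small", input_size = c(64, 64)))
#' count_trainable_parameters(m)
#' @export
count_trainable_parameters <- function(model) {
  stopifnot(inherits(model, "segnet_model"))
  walk <- .net_param_count(model$ptr)
  layers <- model$layers
  per_block <- dplyr::summarise(
    dplyr::group_by(layers[!is.na(layers$block), ], block = .data$block),
    parameters = sum(ifelse(.data$kind == "conv",
                            .data$kernel^2 * .data$in_channels * .data$out_channels +
                              .data$out_channels,
                            ifelse(.data$kind == "batchnorm",
                                   2 * .data$out_channels, 0)),
                     na.rm = TRUE),
    .groups = "drop")
  structure(list(
    variant = model$spec$variant_name,
    trainable_parameter_count = walk,
    closed_form_count = closed_form_parameters(layers),
    layer_count = nrow(layers),
    per_block_parameter_table = per_block
  ), class = "model_summary")
}

#' @rdname count_trainable_parameters
#' @export
model_summary <- count_trainable_parameters

#' @export
print.model_summary <- function(x, ...) {
  cat(sprintf("<model_summary> %s variant: %d layers, %.1fM trainable parameters\n",
              x$variant, x$layer_count, x$trainable_parameter_count / 1e6))
  if (x$trainable_parameter_count != x$closed_form_count)
    cat("  WARNING: graph walk and closed form disagree (",
        x$trainable_parameter_count, " vs ", x$closed_form_count, ")\n")
  print(x$per_block_parameter_table, n = Inf)
  invisible(x)
}

#' @export
print.segnet_model <- function(x, ...) {
  cat(sprintf("<segnet_model> %s variant (%d primitive layers)%s\n",
              x$spec$variant_name, nrow(x$layers),
              if (x$trained) ", trained" else ", untrained"))
  cat(sprintf("  trainable parameters: %.1fM; init seed %d\n",
              .net_param_count(x$ptr) / 1e6, x$seed))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.segnet_model <- function(x, ...) x$layers

#' @export
glance.segnet_model <- function(x, ...) {
  tibble::tibble(variant = x$spec$variant_name,
                 layers = nrow(x$layers),
                 parameters = .net_param_count(x$ptr),
                 depth = length(x$spec$encoder_channels),
                 skip_merge_mode = x$spec$skip_merge_mode,
                 trained = x$trained)
}

#' @export
tidy.model_summary <- function(x, ...) x$per_block_parameter_table

#' @export
glance.model_summary <- function(x, ...) {
  tibble::tibble(variant = x$variant,
                 parameters = x$trainable_parameter_count,
                 closed_form = x$closed_form_count,
                 layers = x$layer_count)
}
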
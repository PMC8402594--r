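test_that("architecture specs enforce their invariants", {
  spec <- architecture_spec("proposed")
  expect_false(is.unsorted(spec$encoder_channels))
  expect_identical(spec$dilation_set, c(1L, 6L, 12L, 18L))
  expect_identical(spec$num_classes, 2L)
  expect_identical(spec$encoder_channels, c(64L, 128L, 256L, 512L, 512L))
  expect_identical(architecture_spec("small")$encoder_channels,
                   c(64L, 128L, 256L))
  expect_identical(architecture_spec("large")$encoder_channels,
                   c(64L, 128L, 256L, 512L, 512L, 1024L, 1024L))
  expect_error(architecture_spec("vgg16"), "unknown variant")
  expect_error(architecture_spec("small", num_classes = 3), "fixed at 2")
  expect_error(architecture_spec("large", input_size = c(64, 64)), "2\\^depth")
})

test_that("the decoder layer plan mirrors the encoder plan", {
  for (v in c("small", "proposed", "large")) {
    plan <- polypseg:::build_graph_plan(architecture_spec(v))
    conv <- plan$layers[plan$layers$kind == "conv", ]
    enc <- conv[grepl("^enc", conv$name), ]
    dec <- conv[grepl("^dec", conv$name), ]
    expect_identical(nrow(enc), nrow(dec))
    # kernel sequence reversed, channel widths mirrored
    expect_identical(rev(dec$kernel), enc$kernel)
    expect_identical(rev(dec$in_channels), enc$out_channels)
  }
})

test_that("primitive-layer counts match the depth plan across variants", {
  # the layer table alone fixes the count; no weights are needed
  counts <- vapply(c(small = "small", proposed = "proposed", large = "large"),
                   function(v)
                     nrow(polypseg:::build_graph_plan(architecture_spec(v))$layers),
                   numeric(1))
  expect_identical(unname(counts), c(100, 154, 208))
})

test_that("graph-walk and closed-form parameter counts agree", {
  for (v in c("small", "proposed")) {
    m <- build_model(architecture_spec(v, input_size = c(32, 32)))
    s <- count_trainable_parameters(m)
    expect_identical(s$trainable_parameter_count, s$closed_form_count)
    expect_identical(s$trainable_parameter_count,
                     sum(s$per_block_parameter_table$parameters))
  }
  # single-conv sanity: a 3x3 convolution from 3 to 64 channels with bias
  first <- build_model(architecture_spec("small", input_size = c(32, 32)))
  row <- first$layers[first$layers$kind == "conv", ][1, ]
  expect_equal(row$kernel^2 * row$in_channels * row$out_channels +
                 row$out_channels, 1792)
})

test_that("parameter totals order small < proposed < large", {
  totals <- vapply(c("small", "proposed", "large"), function(v)
    polypseg:::closed_form_parameters(
      polypseg:::build_graph_plan(architecture_spec(v))$layers), numeric(1))
  expect_true(totals[1] < totals[2] && totals[2] < totals[3])
})

test_that("forward pass preserves resolution and normalises per pixel", {
  for (v in c("small", "proposed")) {
    m <- build_model(architecture_spec(v, input_size = c(32, 32)), seed = 3)
    x <- array(runif(32 * 32 * 3), dim = c(32, 32, 3))
    p <- predict(m, x)
    expect_identical(dim(p), c(32L, 32L, 2L))
    expect_lt(max(abs(p[, , 1] + p[, , 2] - 1)), 1e-6)
    expect_true(all(p >= 0))
  }
})

test_that("inputs not divisible by 2^depth are padded and cropped back", {
  m <- build_model(architecture_spec("small", input_size = c(64, 64)))
  x <- array(runif(50 * 70 * 3), dim = c(50, 70, 3))
  p <- predict(m, x)
  expect_identical(dim(p), c(50L, 70L, 2L))
  expect_lt(max(abs(p[, , 1] + p[, , 2] - 1)), 1e-6)
})

test_that("weight initialisation is deterministic in the seed", {
  m1 <- build_model(architecture_spec("small", input_size = c(32, 32)), seed = 9)
  m2 <- build_model(architecture_spec("small", input_size = c(32, 32)), seed = 9)
  m3 <- build_model(architecture_spec("small", input_size = c(32, 32)), seed = 10)
  x <- array(runif(32 * 32 * 3), dim = c(32, 32, 3))
  expect_identical(predict(m1, x), predict(m2, x))
  expect_false(identical(predict(m1, x), predict(m3, x)))
})

test_that("checkpoints round-trip weights and spec", {
  m <- build_model(architecture_spec("small", input_size = c(32, 32)), seed = 5)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(m, path)
  expect_true(file.exists(paste0(path, ".json")))
  m2 <- load_checkpoint(path)
  x <- array(runif(32 * 32 * 3), dim = c(32, 32, 3))
  expect_identical(predict(m, x), predict(m2, x))
  side <- jsonlite::read_json(paste0(path, ".json"))
  expect_identical(side$variant, "small")
  expect_identical(side$layer_count, 100L)
})

test_that("tidy and glance views expose the layer table and totals", {
  m <- build_model(architecture_spec("small", input_size = c(32, 32)))
  expect_identical(nrow(tidy(m)), 100L)
  g <- glance(m)
  expect_identical(g$layers, 100L)
  expect_identical(g$parameters, count_trainable_parameters(m)$closed_form_count)
})
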
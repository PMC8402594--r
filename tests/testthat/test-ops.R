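test_that("conv_block reproduces hand-evaluated examples", {
  # ReLU clamps a negative response to zero
  x <- array(-5, dim = c(1, 1, 1))
  ident <- array(0, dim = c(1, 1, 1, 1)); ident[1, 1, 1, 1] <- 1
  expect_equal(conv_block(x, ident)[1, 1, 1], 0)
  expect_equal(conv_block(x, ident, activation = FALSE)[1, 1, 1], -5)

  # all-ones 3x3 input under an all-ones 3x3 kernel: centre sums all nine
  ones <- array(1, dim = c(1, 3, 3))
  k <- array(1, dim = c(3, 3, 1, 1))
  y <- conv_block(ones, k, activation = FALSE)
  expect_equal(y[1, 2, 2], 9)
  expect_equal(y[1, 1, 1], 4)   # corner sees a 2x2 valid patch

  # same-padding preserves resolution for any input
  x <- random_feature_map(3, 7, 5)
  k <- array(rnorm(3 * 3 * 3 * 4), dim = c(3, 3, 3, 4))
  expect_identical(dim(conv_block(x, k)), c(4L, 7L, 5L))
})

test_that("conv_block rejects malformed kernels", {
  x <- random_feature_map(2, 4, 4)
  expect_error(conv_block(x, array(1, dim = c(4, 4, 2, 1))), "odd")
  expect_error(conv_block(x, array(1, dim = c(3, 3, 3, 1))), "channels")
  expect_error(conv_block(x, array(1, dim = c(3, 3, 2, 2)), bias = 1), "bias")
})

test_that("convolution agrees with the direct-sum oracle", {
  withr::with_seed(21, {
    for (dil in c(1L, 2L)) {
      x <- random_feature_map(2, 6, 6)
      k <- array(rnorm(3 * 3 * 2 * 3), dim = c(3, 3, 2, 3))
      b <- rnorm(3)
      got <- conv_block(x, k, bias = b, dilation = dil, activation = FALSE)
      expect_equal(got, oracle_conv(x, k, b, dil), tolerance = 1e-5)
    }
  })
})

test_that("pooling returns window maxima with argmax indices", {
  p <- pool_with_indices(array(c(1, 3, 2, 4), dim = c(1, 2, 2)))
  expect_equal(p$pooled[1, 1, 1], 4)
  expect_equal(p$indices[1, 1, 1], 4)   # bottom-right of the 2x2 frame

  # a constant map takes the first (top-left) cell of every window
  pc <- pool_with_indices(array(7, dim = c(1, 4, 4)))
  expect_true(all(pc$pooled == 7))
  expect_equal(as.vector(pc$indices[1, , ]), c(1, 3, 9, 11))

  expect_error(pool_with_indices(array(1, dim = c(1, 3, 4))), "even")
})

test_that("pooling matches the brute-force window oracle on random maps", {
  withr::with_seed(31, {
    for (i in 1:25) {
      x <- random_feature_map(2, 8, 8)
      got <- pool_with_indices(x)
      ref <- oracle_pool(x)
      # the engine computes in single precision; compare at float tolerance
      expect_equal(got$pooled, ref$pooled, tolerance = 1e-6)
      expect_equal(array(as.numeric(got$indices), dim = dim(ref$indices)),
                   ref$indices * 1.0)
    }
  })
})

test_that("unpooling scatters to recorded positions and round-trips", {
  pf <- structure(list(pooled = array(4, dim = c(1, 1, 1)),
                       indices = array(4, dim = c(1, 1, 1)),
                       pre_pool_size = c(2L, 2L)), class = "pooled_feature")
  expect_equal(unpool_with_indices(pf)[1, , ], matrix(c(0, 0, 0, 4), 2, 2))

  withr::with_seed(32, {
    for (i in 1:20) {
      # pooling follows a ReLU in the network, so maps are non-negative;
      # the round-trip identity is stated on that domain
      x <- pmax(random_feature_map(3, 6, 4), 0)
      p <- pool_with_indices(x)
      u <- unpool_with_indices(p)
      # round trip: pooling the unpooled map restores values and indices
      p2 <- pool_with_indices(u)
      expect_equal(p2$pooled, p$pooled)
      expect_equal(p2$indices, p$indices)
      # zeros elsewhere: totals match
      expect_equal(sum(u), sum(p$pooled))
    }
  })

  bad <- structure(list(pooled = array(1, dim = c(1, 1, 1)),
                        indices = array(9, dim = c(1, 1, 1)),
                        pre_pool_size = c(2L, 2L)), class = "pooled_feature")
  expect_error(unpool_with_indices(bad), "out of range")
})

test_that("dilated pyramid preserves resolution and validates dilations", {
  x <- random_feature_map(2, 12, 12)
  ks <- lapply(1:4, function(i) array(rnorm(3 * 3 * 2 * 3), dim = c(3, 3, 2, 3)))
  proj <- array(rnorm(3 * 3 * 12 * 2), dim = c(3, 3, 12, 2))
  y <- dilated_pyramid(x, ks, projection_kernel = proj)
  expect_identical(dim(y), c(2L, 12L, 12L))
  raw <- dilated_pyramid(x, ks)
  expect_identical(dim(raw), c(12L, 12L, 12L))
  expect_error(dilated_pyramid(x, ks, dilations = c(1, 2, 4, 8)),
               "dilation set")
})

test_that("a 3x3 kernel at dilation 6 spans a 13x13 receptive field", {
  # impulse response: taps land k_eff = 3 + 2*(6-1) = 13 cells apart end-to-end
  x <- array(0, dim = c(1, 25, 25)); x[1, 13, 13] <- 1
  k <- array(1, dim = c(3, 3, 1, 1))
  y <- conv_block(x, k, dilation = 6, activation = FALSE)
  nz <- which(y[1, , ] != 0, arr.ind = TRUE)
  expect_equal(max(nz[, 1]) - min(nz[, 1]) + 1, 13)
  expect_equal(max(nz[, 2]) - min(nz[, 2]) + 1, 13)
})

test_that("the dilation-1 branch equals a plain convolution block", {
  withr::with_seed(33, {
    x <- random_feature_map(3, 10, 10)
    ks <- lapply(1:4, function(i) array(rnorm(3 * 3 * 3 * 2), dim = c(3, 3, 3, 2)))
    pyr <- dilated_pyramid(x, ks)          # raw concatenation, no projection
    plain <- conv_block(x, ks[[1]], dilation = 1)
    expect_identical(pyr[1:2, , ], plain)  # bit-for-bit shared path
  })
})

test_that("skip merges follow add/concat contracts", {
  x <- random_feature_map(3, 5, 5)
  z <- array(0, dim = dim(x))
  expect_identical(skip_merge(x, z, "add"), x)
  y <- random_feature_map(3, 5, 5)
  expect_identical(skip_merge(x, y, "add"), skip_merge(y, x, "add"))
  w <- random_feature_map(2, 5, 5)
  cc <- skip_merge(x, w, "concat")
  expect_identical(dim(cc), c(5L, 5L, 5L))
  expect_equal(cc[1:3, , ], x)
  expect_equal(cc[4:5, , ], w)
  expect_error(skip_merge(x, w, "add"), "channel")
  expect_error(skip_merge(x, random_feature_map(3, 4, 5), "add"), "resolution")
})
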
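test_that("generated datasets load back as paired manifests", {
  dir <- withr::local_tempdir()
  sp <- synthetic_spec(resolution = c(32, 32), seed = 3)
  manifest <- generate_dataset(sp, 10, dir)
  expect_s3_class(manifest, "dataset_manifest")
  expect_identical(nrow(manifest), 10L)
  expect_true(all(manifest$split == "unassigned"))
  reloaded <- load_dataset(dir)
  expect_identical(reloaded$image_path, manifest$image_path)

  rec <- read_sample(manifest$image_path[1], manifest$mask_path[1])
  expect_identical(dim(rec$image), c(32L, 32L, 3L))
  expect_true(all(rec$mask %in% c(0L, 1L)))
})

test_that("an orphan image is reported by stem, not dropped", {
  dir <- withr::local_tempdir()
  sp <- synthetic_spec(resolution = c(16, 16), seed = 4)
  generate_dataset(sp, 3, dir)
  file.remove(file.path(dir, "masks", "synth_0002.png"))
  expect_error(load_dataset(dir), "synth_0002")
  expect_error(load_dataset(file.path(dir, "nothing-here")), "no such")
})

test_that("pooled splitting reproduces the 70/30 arithmetic", {
  manifest <- study_manifest()          # 612 + 379 + 196 = 1187 records
  expect_identical(nrow(manifest), 1187L)
  split <- split_dataset(manifest, 0.7, seed = 1)
  expect_identical(sum(split$split == "train"), 831L)
  expect_identical(sum(split$split == "test"), 356L)
  expect_identical(sum(split$split == "unassigned"), 0L)
})

test_that("the exact-count mode reproduces a published allocation", {
  manifest <- study_manifest()
  split <- split_dataset(manifest, seed = 2,
                         per_collection_counts = c(clinic = 437, colon = 260,
                                                   etis = 134))
  tab <- table(split$collection[split$split == "train"])
  expect_identical(as.integer(tab[c("clinic", "colon", "etis")]),
                   c(437L, 260L, 134L))
  expect_identical(sum(split$split == "train"), 831L)
  expect_identical(sum(split$split == "test"), 356L)
  expect_error(split_dataset(manifest, per_collection_counts = c(etis = 197)),
               "only 196")
})

test_that("splits are seeded, disjoint and edge-checked", {
  manifest <- study_manifest(c(a = 6, b = 4))
  s1 <- split_dataset(manifest, 0.5, seed = 7)
  s2 <- split_dataset(manifest, 0.5, seed = 7)
  s3 <- split_dataset(manifest, 0.5, seed = 8)
  expect_identical(s1$split, s2$split)
  expect_false(identical(s1$split, s3$split))
  expect_identical(sum(s1$split == "train"), 5L)
  expect_error(split_dataset(manifest, 1.0), "strictly between")
  expect_error(split_dataset(manifest, 0), "strictly between")
})

test_that("standardisation resamples images bilinearly and masks exactly", {
  sp <- synthetic_spec(resolution = c(48, 60), seed = 5,
                       polyps_per_image = c(1, 1))
  rec <- generate_sample(sp, 1)
  out <- standardize_sample(rec, c(32, 40))
  expect_identical(dim(out$image), c(32L, 40L, 3L))
  expect_identical(dim(out$mask), c(32L, 40L))
  expect_true(all(out$mask %in% c(0L, 1L)))
  expect_true(all(out$image >= 0 & out$image <= 1))
  # nearest-neighbour resampling keeps the single polyp in one piece
  expect_equal(max(EBImage::bwlabel(out$mask)), 1)
  # an already-conforming record passes through unchanged
  expect_identical(standardize_sample(rec, c(48, 60))$mask, rec$mask)
  expect_error(standardize_sample(rec, c(0, 10)), "positive")
})

test_that("mask writing is lossless and strictly binary", {
  dir <- withr::local_tempdir()
  m <- matrix(c(1, 0, 0, 1, 1, 0), 2, 3)
  path <- file.path(dir, "m.png")
  write_mask(m, path)
  expect_identical(polypseg:::read_mask(path), matrix(as.integer(m), 2, 3))
  zero <- matrix(0, 4, 4)
  write_mask(zero, file.path(dir, "z.png"))
  expect_true(all(polypseg:::read_mask(file.path(dir, "z.png")) == 0))
  expect_error(write_mask(matrix(0.5, 2, 2), file.path(dir, "bad.png")),
               "binary")
})
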
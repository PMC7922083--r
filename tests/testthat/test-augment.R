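blob_sample <- function(h = 60, w = 80, seed = 1) {
  set.seed(seed)
  img <- array(runif(h * w * 3), c(h, w, 3))
  msk <- matrix(0L, h, w)
  msk[round(h * 0.3):round(h * 0.6), round(w * 0.4):round(w * 0.7)] <- 1L
  adu_ns$new_segmentation_sample(img, msk, "blob")
}

test_that("resize with random crop emits the target geometry and binary masks", {
  set.seed(61)
  s <- blob_sample(448 / 4, 672 / 4)  # 112 x 168
  out <- resize_random_crop(s, 56)
  expect_equal(dim(out$image), c(56, 56, 3))
  expect_true(all(out$mask %in% c(0L, 1L)))
  # square input at the target side: unchanged up to interpolation identity
  sq <- blob_sample(56, 56)
  expect_equal(resize_random_crop(sq, 56)$image, sq$image, tolerance = 1e-12)
  # foreground cannot appear where the source had none: crop of an empty mask
  empty <- adu_ns$new_segmentation_sample(array(runif(80 * 80 * 3), c(80, 80, 3)),
                                          matrix(0L, 80, 80), "e")
  expect_equal(sum(resize_random_crop(empty, 56)$mask), 0)
})

test_that("reflections are exact involutions applied jointly to image and mask", {
  s <- blob_sample()
  r <- random_reflect(s, force = TRUE)      # flip both axes
  rr <- random_reflect(r, force = TRUE)
  expect_identical(rr$image, s$image)
  expect_identical(rr$mask, s$mask)
  expect_equal(sum(r$mask), sum(s$mask))    # area preserved exactly
})

test_that("zero-angle rotation and zero-magnitude elastic deformation are identities", {
  s <- blob_sample(64, 64)
  set.seed(62)
  expect_identical(random_rotate(s, c(0, 0)), s)
  expect_identical(elastic_deform(s, magnitude = 0), s)
})

test_that("right-angle-free geometric transforms keep masks binary and sizes fixed", {
  set.seed(63)
  s <- blob_sample(64, 64)
  for (i in 1:5) {
    r <- random_rotate(s, c(10, 80))
    e <- elastic_deform(s, grid = 10, magnitude = 6)
    for (out in list(r, e)) {
      expect_equal(dim(out$image), c(64, 64, 3))
      expect_true(all(out$mask %in% c(0L, 1L)))
    }
  }
})

test_that("elastic deformation at the default magnitude changes blob area moderately", {
  # polyp-sized blob at the working resolution of the pipeline (224 px)
  msk <- matrix(0L, 224, 224); msk[70:150, 80:160] <- 1L
  img <- array(rep(as.double(msk), 3), c(224, 224, 3))
  s <- adu_ns$new_segmentation_sample(img, msk, "blob224")
  set.seed(64)
  rel <- replicate(50, {
    e <- elastic_deform(s, grid = 10, magnitude = 6)
    abs(sum(e$mask) - sum(s$mask)) / sum(s$mask)
  })
  expect_lt(max(rel), 0.20)
})

test_that("gamma adjustment touches the image only, within the configured range", {
  set.seed(65)
  s <- blob_sample(32, 32)
  g <- random_gamma(s, c(0.7, 1.5))
  expect_identical(g$mask, s$mask)
  expect_true(all(g$image >= 0 & g$image <= 1))
  expect_false(identical(g$image, s$image))
})

test_that("rotations by construction transform image and mask identically", {
  # use a binary image equal to the mask: both channels must transform alike
  set.seed(66)
  msk <- matrix(0L, 64, 64); msk[20:40, 25:45] <- 1L
  img <- array(rep(as.double(msk), 3), c(64, 64, 3))
  s <- adu_ns$new_segmentation_sample(img, msk, "m")
  r <- random_reflect(s, force = TRUE)
  expect_equal(r$image[, , 1], r$mask + 0)
  rot <- random_rotate(s, c(30, 60))
  # nearest (mask) vs bilinear (image) only disagree on boundary pixels
  interior <- rot$image[, , 1] %in% c(0, 1)
  expect_gt(mean(rot$image[, , 1][interior] == rot$mask[interior]), 0.99)
})

test_that("dataset augmentation yields n * multiplier outputs, reproducibly", {
  pc <- phantom_config(side = 72, seed = 8)
  inputs <- lapply(0:3, function(i) phantom_sample(pc, i))
  cfgA <- augment_config(target_side = 48, multiplier = 5, seed = 21)
  outA <- augment_dataset(inputs, cfgA)
  expect_length(outA, 20)
  for (s in outA) {
    expect_equal(dim(s$image), c(48, 48, 3))
    expect_true(all(s$mask %in% c(0L, 1L)))
  }
  outB <- augment_dataset(inputs, cfgA)
  expect_identical(outA, outB)
  outC <- augment_dataset(inputs, augment_config(target_side = 48, multiplier = 5,
                                                 seed = 22))
  expect_false(identical(outA, outC))
  # multiplier 1: resized originals only
  out1 <- augment_dataset(inputs, augment_config(target_side = 48, multiplier = 1,
                                                 seed = 21))
  expect_length(out1, 4)
  expect_equal(out1[[1]]$image, adu_ns$resize_center_crop(inputs[[1]], 48)$image)
  expect_error(augment_config(multiplier = 0), "multiplier")
})

test_that("streaming sink receives every output without accumulation", {
  pc <- phantom_config(side = 64, seed = 2)
  inputs <- lapply(0:1, function(i) phantom_sample(pc, i))
  seen <- integer()
  n <- augment_dataset(inputs, augment_config(target_side = 48, multiplier = 3,
                                              seed = 5),
                       sink = function(s, i) seen <<- c(seen, i))
  expect_equal(n, 6)
  expect_equal(seen, 1:6)
})
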
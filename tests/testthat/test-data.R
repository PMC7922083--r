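write_gray_png <- function(values, path, side = 4) {
  png::writePNG(matrix(values / 255, side, side), path)
}

test_that("pair discovery matches basenames and names orphans", {
  root <- withr::local_tempdir()
  dir.create(file.path(root, "images")); dir.create(file.path(root, "masks"))
  for (id in c("a", "b", "c")) {
    write_gray_png(rep(128, 16), file.path(root, "images", paste0(id, ".png")))
    write_gray_png(rep(255, 16), file.path(root, "masks", paste0(id, ".png")))
  }
  pairs <- discover_pairs(file.path(root, "images"), file.path(root, "masks"))
  expect_equal(pairs$id, c("a", "b", "c"))

  write_gray_png(rep(0, 16), file.path(root, "masks", "stray.png"))
  expect_error(discover_pairs(file.path(root, "images"), file.path(root, "masks")),
               "stray")
})

test_that("mask binarisation uses the 127/128 8-bit boundary", {
  root <- withr::local_tempdir()
  dir.create(file.path(root, "images")); dir.create(file.path(root, "masks"))
  write_gray_png(rep(100, 16), file.path(root, "images", "x.png"))
  write_gray_png(c(0, 127, 128, 255, rep(0, 12)), file.path(root, "masks", "x.png"))
  pair <- discover_pairs(file.path(root, "images"), file.path(root, "masks"))
  s <- load_sample(pair)
  expect_equal(as.vector(s$mask)[1:4], c(0L, 0L, 1L, 1L))
  # all-black and all-white masks
  write_gray_png(rep(0, 16), file.path(root, "masks", "x.png"))
  expect_equal(sum(load_sample(pair)$mask), 0)
  write_gray_png(rep(255, 16), file.path(root, "masks", "x.png"))
  expect_equal(sum(load_sample(pair)$mask), 16)
})

test_that("deterministic evaluation resize: aspect-preserving scale + centre crop", {
  set.seed(51)
  img <- array(runif(40 * 60 * 3), c(40, 60, 3))
  msk <- matrix(0L, 40, 60); msk[10:30, 20:40] <- 1L
  s <- adu_ns$new_segmentation_sample(img, msk, "t")
  out <- adu_ns$resize_center_crop(s, 32)
  expect_equal(dim(out$image), c(32, 32, 3))
  expect_equal(dim(out$mask), c(32, 32))
  expect_true(all(out$mask %in% c(0L, 1L)))
  # identity case: already square at the target side
  sq <- adu_ns$new_segmentation_sample(array(runif(32 * 32 * 3), c(32, 32, 3)),
                                       matrix(1L, 32, 32), "sq")
  out2 <- adu_ns$resize_center_crop(sq, 32)
  expect_equal(out2$image, sq$image, tolerance = 1e-12)
  expect_identical(out2$mask, sq$mask)
})

test_that("80/10/10 split arithmetic: floors to train/val, remainder to test", {
  ids <- sprintf("s%04d", 1:1000)
  sp <- split_dataset(ids, c(0.8, 0.1, 0.1), seed = 7)
  expect_length(sp$train, 800)
  expect_length(sp$validation, 100)
  expect_length(sp$test, 100)
  # partition property
  expect_setequal(c(sp$train, sp$validation, sp$test), ids)
  expect_length(intersect(sp$train, sp$validation), 0)
  expect_length(intersect(sp$train, sp$test), 0)

  sp10 <- split_dataset(letters[1:10], seed = 1)
  expect_equal(lengths(sp10[c("train", "validation", "test")]),
               c(train = 8L, validation = 1L, test = 1L))
  sp7 <- split_dataset(letters[1:7], seed = 1)
  expect_equal(lengths(sp7[c("train", "validation", "test")]),
               c(train = 5L, validation = 0L, test = 2L))
})

test_that("splits are reproducible from their seed and differ across seeds", {
  ids <- sprintf("s%03d", 1:50)
  a <- split_dataset(ids, seed = 3)
  b <- split_dataset(ids, seed = 3)
  expect_identical(a, b)
  c2 <- split_dataset(ids, seed = 4)
  expect_false(identical(a$train, c2$train))
  # manifest round trip
  path <- withr::local_tempfile(fileext = ".json")
  write_split(a, path)
  expect_identical(read_split(path), a)
})

test_that("split input validation", {
  expect_error(split_dataset(letters[1:5], c(0.5, 0.4, 0.2)), "sum to 1")
  expect_error(split_dataset(letters[1:2], c(0.4, 0.3, 0.3)), "partitions")
})
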
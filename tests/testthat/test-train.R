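# Training-loop behaviour on micro-scale networks (seconds, not minutes).

micro_samples <- function(n = 4, seed = 10) {
  pc <- phantom_config(side = 32, polyp_axis_range = c(0.12, 0.2), seed = seed)
  lapply(seq_len(n) - 1L, function(i) phantom_sample(pc, i))
}

test_that("train config validates and records the published protocol defaults", {
  tc <- train_config()
  expect_equal(tc$batch_size, 10L)
  expect_equal(tc$epochs, 100L)
  expect_equal(tc$initial_lr, 0.01)
  expect_equal(tc$plateau_factor, 0.1)
  expect_equal(tc$plateau_patience, 5L)
  expect_equal(tc$loss, "bce")
  expect_error(train_config(batch_size = 0), "batch_size")
  expect_error(train_config(initial_lr = -1), "initial_lr")
})

test_that("plateaued validation drops the learning rate by exactly the factor", {
  set.seed(71)
  net <- a_denseunet(micro_config())
  samples <- micro_samples(2)
  # learning rate too small to improve: validation plateaus immediately
  tc <- train_config(batch_size = 2, epochs = 9, initial_lr = 1e-12,
                     plateau_patience = 2, early_stop_patience = 50, seed = 1)
  fit <- fit_adenseunet(net, samples, samples, tc)
  lrs <- fit$history$lr
  expect_true(all(diff(lrs) <= 0))
  drops <- lrs[which(diff(lrs) < 0) + 1L] / lrs[which(diff(lrs) < 0)]
  expect_gt(length(drops), 0)
  expect_equal(drops, rep(0.1, length(drops)), tolerance = 1e-12)
  # the drop happens after plateau_patience + 1 non-improving epochs (first
  # epoch sets the incumbent best), so the reduced lr is first used one epoch
  # later
  expect_equal(which(lrs < lrs[1])[1], tc$plateau_patience + 3)
})

test_that("early stopping halts before the epoch limit on a flat run", {
  set.seed(72)
  net <- a_denseunet(micro_config())
  samples <- micro_samples(2)
  tc <- train_config(batch_size = 2, epochs = 50, initial_lr = 1e-12,
                     plateau_patience = 2, early_stop_patience = 4, seed = 1)
  fit <- fit_adenseunet(net, samples, samples, tc)
  expect_lt(nrow(fit$history), 50)
  expect_equal(nrow(fit$history), fit$best_epoch + 4)
})

test_that("a few optimizer steps reduce the training loss on a tiny set", {
  set.seed(73)
  net <- a_denseunet(micro_config())
  samples <- micro_samples(3)
  tc <- train_config(batch_size = 3, epochs = 15, initial_lr = 2e-3,
                     early_stop_patience = 30, seed = 2)
  fit <- fit_adenseunet(net, samples, NULL, tc)
  expect_lt(fit$history$loss[nrow(fit$history)], fit$history$loss[1])
})

test_that("evaluation sanity: perfect predictions and constant-zero predictor", {
  samples <- micro_samples(2)
  # ground truth as prediction
  rep1 <- evaluate_dataset(lapply(samples, function(s) s$mask + 0),
                           lapply(samples, `[[`, "mask"))
  expect_equal(rep1$dice, 1); expect_equal(rep1$iou, 1)
  # constant zero
  rep0 <- evaluate_dataset(lapply(samples, function(s) s$mask * 0),
                           lapply(samples, `[[`, "mask"))
  expect_equal(rep0$dice, 0)
})

test_that("checkpoint save/load reproduces inference bit-for-bit", {
  set.seed(74)
  net <- a_denseunet(micro_config())
  samples <- micro_samples(2)
  tc <- train_config(batch_size = 2, epochs = 2, initial_lr = 1e-3, seed = 3)
  fit <- fit_adenseunet(net, samples, samples, tc)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(fit, path)
  back <- load_checkpoint(path)
  img <- samples[[1]]$image
  expect_identical(predict(back, img), predict(fit$model, img))
  m1 <- evaluate_model(back, samples)
  m2 <- evaluate_model(fit$model, samples)
  expect_identical(m1[c("dice", "iou", "loss")], m2[c("dice", "iou", "loss")])
})

test_that("prediction writes masks with values {0, 255} when saved as PNG", {
  set.seed(75)
  net <- a_denseunet(micro_config())
  s <- micro_samples(1)[[1]]
  out <- predict(net, s$image, type = "both")
  expect_equal(dim(out$prob), c(32, 32))
  expect_true(all(out$mask %in% c(0L, 1L)))
  path <- withr::local_tempfile(fileext = ".png")
  png::writePNG(matrix(as.double(out$mask), 32), path)
  bytes <- round(png::readPNG(path) * 255)
  expect_true(all(bytes %in% c(0, 255)))
  # inference determinism
  expect_identical(predict(net, s$image), predict(net, s$image))
})

test_that("selectable losses all step without error and match their formulas", {
  p <- array(c(0.2, 0.8, 0.6, 0.4), c(2, 2, 1))
  y <- array(c(0, 1, 1, 0), c(2, 2, 1))
  pn <- adu_ns$nd(p)
  sd <- adu_ns$loss_soft_dice(pn, y, smooth = 0)
  expect_equal(sd$val, 1 - 2 * (0.8 + 0.6) / (sum(p) + 2), tolerance = 1e-12)
  sj <- adu_ns$loss_soft_jaccard(pn, y, smooth = 0)
  expect_equal(sj$val, 1 - (0.8 + 0.6) / (sum(p) + 2 - 1.4), tolerance = 1e-12)
  sm <- adu_ns$loss_mse(pn, y)
  expect_equal(sm$val, mean((p - y)^2), tolerance = 1e-12)
  # gradient direction: lowering loss must increase p where y = 1
  for (lossfn in list(adu_ns$loss_soft_dice, adu_ns$loss_soft_jaccard)) {
    adu_ns$tape_start()
    node <- adu_ns$nd(p, parents = list(), backfn = NULL)
    attr(node, "keep_grad") <- TRUE
    ln <- lossfn(node, y)
    adu_ns$backward(ln)
    adu_ns$tape_stop()
    expect_true(all(ln$parents[[1]]$grad[y == 1] < 0))
  }
})
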
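# Structural and numerical tests of the network building blocks. Forward
# passes here run on small random inputs through the tape-node interface.

as_node <- function(x) adu_ns$nd_const(x)

test_that("encoder shape inference reproduces the published layout", {
  shp <- infer_encoder_shapes(model_config())
  expect_equal(shp$spatial_side, c(112, 56, 28, 14, 7))
  expect_equal(shp$channels, c(96, 384, 768, 2112, 2208))
  shp96 <- infer_encoder_shapes(model_config(input_side = 96))
  expect_equal(shp96$spatial_side, c(48, 24, 12, 6, 3))
})

test_that("dense block channel growth is linear: out = in + n * k", {
  set.seed(21)
  for (n in 0:6) {
    blk <- dense_block(5L, n, 3L, rate = 1L)
    expect_equal(blk$out_channels, 5L + n * 3L)
    x <- as_node(array(rnorm(8 * 8 * 5), c(8, 8, 5)))
    y <- blk$forward(x, training = TRUE)
    expect_equal(dim(y$val), c(8, 8, 5 + n * 3))
  }
  # published arithmetic: dense block 1 and 2 of the default encoder
  expect_equal(dense_block(96L, 6L, 48L)$out_channels, 384L)
  expect_equal(dense_block(192L, 12L, 48L)$out_channels, 768L)
  expect_error(dense_block(4L, -1L, 2L), "invalid argument")
})

test_that("a zero-layer dense block is the identity", {
  blk <- dense_block(3L, 0L, 4L)
  x <- as_node(array(rnorm(6 * 6 * 3), c(6, 6, 3)))
  expect_identical(blk$forward(x)$val, x$val)
})

test_that("transition compresses channels by floor(theta*c) and halves space", {
  set.seed(22)
  expect_equal(transition_block(384L, 0.5)$out_channels, 192L)
  expect_equal(transition_block(2112L, 0.5)$out_channels, 1056L)
  expect_equal(transition_block(7L, 1)$out_channels, 7L)
  tb <- transition_block(6L, 0.5)
  x <- as_node(array(rnorm(10 * 10 * 6), c(10, 10, 6)))
  expect_equal(dim(tb$forward(x, training = TRUE)$val), c(5, 5, 3))
  expect_error(transition_block(8L, 0), "invalid argument")
  expect_error(transition_block(8L, 1.5), "invalid argument")
})

test_that("attention gate: shape contract, bounded coefficients, zero-weight closed form", {
  set.seed(23)
  g <- attention_gate(5L, 7L, 4L)
  skip <- as_node(array(rnorm(8 * 8 * 5), c(8, 8, 5)))
  gate <- as_node(array(rnorm(8 * 8 * 7), c(8, 8, 7)))
  out <- g$forward(skip, gate)
  expect_equal(dim(out$val), dim(skip$val))
  expect_true(all(abs(out$val) <= abs(skip$val) + 1e-12))

  # gating signal at half resolution is resampled up; other sizes error
  gate_half <- as_node(array(rnorm(4 * 4 * 7), c(4, 4, 7)))
  expect_equal(dim(g$forward(skip, gate_half)$val), dim(skip$val))
  gate_bad <- as_node(array(rnorm(3 * 3 * 7), c(3, 3, 7)))
  expect_error(g$forward(skip, gate_bad), "shape contract")

  # zeroed weights: every pre-sigmoid activation is 0, coefficients 0.5
  for (p in c(g$params$wx, g$params$wg, g$params$psi)) p$val[] <- 0
  out0 <- g$forward(skip, gate)
  expect_equal(out0$val, skip$val * 0.5, tolerance = 1e-12)
})

test_that("decoder node: residual refinement collapses to the projected shortcut", {
  set.seed(24)
  cfg <- micro_config()
  node <- decoder_node(1L, 1L, cfg)
  skip <- as_node(array(rnorm(16 * 16 * 4), c(16, 16, 4)))
  deeper <- as_node(array(rnorm(8 * 8 * 6), c(8, 8, 6)))
  out <- node$forward(list(skip), deeper)
  expect_equal(dim(out$val)[1:2], c(16, 16))

  # zero the residual branch conv: output must equal the 1x1 projection
  rf <- node$params$refine
  rf$conv$w$val[] <- 0; rf$conv$b$val[] <- 0
  out0 <- node$forward(list(skip), deeper)
  # recompute the projection by hand on the same fused input
  gate_out <- if (!is.null(node$params$gate)) {
    node$params$gate$forward(deeper, deeper)
  } else deeper
  up <- adu_ns$op_convt2(gate_out, node$params$up$w, node$params$up$b)
  fused <- adu_ns$op_concat(list(skip, up))
  proj <- adu_ns$op_conv2d(fused, rf$proj$w, rf$proj$b)
  expect_equal(out0$val, proj$val, tolerance = 1e-10)
})

test_that("decoder topology rejects out-of-range nodes and degenerates without dense links", {
  cfg <- micro_config()
  expect_error(decoder_node(5L, 1L, cfg), "topology")
  expect_error(decoder_node(1L, 5L, cfg), "topology")
  plain <- ablate(cfg, "no_dense_links")
  expect_error(decoder_node(1L, 1L, plain), "topology")  # only column 4 exists
  expect_s3_class(decoder_node(1L, 4L, plain), "adu_block")
  # single-column decoder: exactly depth-1 nodes
  expect_length(adu_ns$decoder_grid(plain), 4L)
  expect_length(adu_ns$decoder_grid(cfg), 10L)  # nested grid: 4+3+2+1
})

test_that("parameter counting matches per-layer hand tallies and grows with k", {
  # single 1x1 conv, 3 -> 1 channels with bias
  cv <- adu_ns$conv_make(1L, 1L, 3L, 1L)
  expect_equal(count_parameters(cv), 4)
  # dense block hand count: n layers of (bn + 1x1 conv + bn + 3x3 conv)
  blk <- dense_block(5L, 2L, 3L, factor = 2L)
  hand <- 0
  cin <- 5
  for (t in 1:2) {
    mid <- 2 * 3
    hand <- hand + 2 * cin +                 # bn1 gamma+beta
      (1 * 1 * cin * mid + mid) +            # conv1 w+b
      2 * mid +                              # bn2
      (3 * 3 * mid * 3 + 3)                  # conv2 w+b
    cin <- cin + 3
  }
  expect_equal(count_parameters(blk), hand)
  # monotone in growth rate
  counts <- vapply(c(2L, 4L, 8L), function(k) {
    count_parameters(a_denseunet(micro_config(growth_rate_k = k)))
  }, numeric(1))
  expect_true(all(diff(counts) > 0))
})

test_that("built model obeys the forward contract on a reduced configuration", {
  cfg <- reduced_model_config()
  net <- a_denseunet(cfg)
  img <- array(runif(96 * 96 * 3), c(96, 96, 3))
  p <- predict(net, img)
  expect_equal(dim(p), c(96, 96))
  expect_true(all(p >= 0 & p <= 1))
  expect_error(predict(net, array(0, c(64, 64, 3))), "input must be")
  expect_error(a_denseunet(model_config(input_side = 60)), "divisible")
  # forward-pass encoder shapes match the inferred contract
  out <- adu_ns$forward_adenseunet(net, img)
  expect_equal(attr(out, "encoder_shapes")[c("spatial_side", "channels")],
               infer_encoder_shapes(cfg)[c("spatial_side", "channels")])
})

test_that("model output stays in [0,1] for extreme inputs", {
  net <- a_denseunet(micro_config())
  for (scale in c(0, 1, 100)) {
    img <- array(rnorm(32 * 32 * 3, sd = max(scale, 1e-9)), c(32, 32, 3))
    p <- predict(net, img)
    expect_true(all(p >= 0 & p <= 1))
  }
})
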
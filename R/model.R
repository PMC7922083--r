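#' Build an A-DenseUNet network
#'
#' Constructs the full network from a configuration: a densely connected
#' encoder (stride-2 stem, 3x3 stride-2 max pool, four dense blocks at
#' growth rate k with compressing transitions), a nested multi-depth decoder
#' whose nodes fuse attention-gated deeper features (upsampled by 2x2
#' stride-2 transposed convolutions) with all same-level predecessors, and a
#' deep-supervision head: every top-row decoder output is projected to a
#' common width by a 1x1 convolution, upsampled to full resolution, the maps
#' are averaged, and a final 1x1 convolution with sigmoid activation produces
#' the segmentation probability map.
#'
#' Weights are He-initialised from a generator seeded by `config$seed`; the
#' final convolution's bias starts at -2 so the untrained network predicts a
#' low foreground probability, matching the class balance of polyp frames.
#'
#' @param config An [model_config()] object.
#' @return An object of class `adenseunet` supporting [predict()],
#'   [count_parameters()], `print()` and `summary()`.
#' @examples
#' net <- a_denseunet(reduced_model_config())
#' img <- array(runif(96 * 96 * 3), dim = c(96, 96, 3))
#' pr <- predict(net, img)       # 96 x 96 probability map in [0, 1]
#' @export
a_denseunet <- function(config = model_config()) {
  validate_model_config(config)
  old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)

  s <- config$depth_s
  shp <- infer_encoder_shapes(config)
  enc_ch <- shp$channels

  stem_dil <- if (config$use_dilation) config$dilation_rate_l else 1L
  stem <- list(conv = conv_make(config$stem_kernel, config$stem_kernel,
                                config$input_channels, config$stem_filters),
               bn = bn_make(config$stem_filters), dil = stem_dil)

  blocks <- list(); trans <- list()
  cin <- config$stem_filters
  for (b in seq_along(config$block_layers)) {
    blocks[[b]] <- dense_block(cin, config$block_layers[b], config$growth_rate_k,
                               rate = block_dilation(config, b),
                               factor = config$bottleneck_factor,
                               order = config$dense_layer_order)
    cin <- blocks[[b]]$out_channels
    if (b < length(config$block_layers)) {
      trans[[b]] <- transition_block(cin, config$compression_theta)
      cin <- trans[[b]]$out_channels
    }
  }

  grid <- decoder_grid(config)
  dec <- list()
  for (key in names(grid)) {
    info <- grid[[key]]
    lvl <- as.integer(strsplit(key, ",")[[1]][1])
    dec[[key]] <- decoder_node_make(config, lvl, info$skip_channels,
                                    info$deep_channels, enc_ch)
  }

  # deep-supervision head: per top-row column a 1x1 conv to a common width
  dsw <- config$deep_supervision_filters
  top_cols <- if (config$use_dense_decoder_links) seq_len(s - 1L) else (s - 1L)
  ds <- lapply(top_cols, function(j) conv_make(1L, 1L, decoder_width(config, 1L, enc_ch), dsw))
  names(ds) <- paste0("col", top_cols)
  head_conv <- conv_make(1L, 1L, dsw, 1L)
  head_conv$b$val[] <- -2  # background-heavy prior

  params <- list(stem = stem[c("conv", "bn")], blocks = blocks, trans = trans,
                 dec = lapply(dec, function(n) n[c("gate", "up", "refine")]),
                 ds = ds, head = head_conv)

  model <- structure(list(config = config, stem = stem, blocks = blocks,
                          trans = trans, dec = dec, ds = ds,
                          head_conv = head_conv, top_cols = top_cols,
                          params = flatten_params(params)),
                     class = "adenseunet")
  model
}

# Forward pass on a (H, W, C) input array. Returns list(prob=, logits=) nodes.
# `training` switches batch-norm to batch statistics (and is the mode used
# under an active gradient tape).
forward_adenseunet <- function(model, image, training = FALSE) {
  cfg <- model$config
  d <- dim(image)
  if (is.null(d) || length(d) != 3L || d[1] != cfg$input_side ||
      d[2] != cfg$input_side || d[3] != cfg$input_channels)
    stop("input must be a ", cfg$input_side, "x", cfg$input_side, "x",
         cfg$input_channels, " array")
  s <- cfg$depth_s
  x <- nd_const(image)

  # encoder
  stem <- model$stem
  e <- list()
  h <- op_relu(bn_apply(stem$bn, conv_apply(stem$conv, x, stride = 2L,
                                            pad = same_pad(cfg$stem_kernel, stem$dil),
                                            dil = stem$dil),
                        training))
  e[[1]] <- h
  h <- op_maxpool3(h)
  for (b in seq_along(model$blocks)) {
    h <- model$blocks[[b]]$forward(h, training)
    e[[b + 1L]] <- h
    if (b < length(model$blocks)) h <- model$trans[[b]]$forward(h, training)
  }

  # decoder grid: X[[level]][[column + 1]] with column 0 = encoder
  X <- lapply(seq_len(s), function(l) list(e[[l]]))
  if (cfg$use_dense_decoder_links) {
    for (level in seq(s - 1L, 1L)) {
      for (column in seq_len(s - level)) {
        node <- model$dec[[paste(level, column, sep = ",")]]
        skips <- X[[level]][seq_len(column)]
        deeper <- X[[level + 1L]][[column]]
        X[[level]][[column + 1L]] <- node$forward(skips, deeper, training)
      }
    }
    tops <- X[[1]][-1]
  } else {
    deeper <- e[[s]]
    out <- NULL
    for (level in seq(s - 1L, 1L)) {
      node <- model$dec[[paste(level, s - level, sep = ",")]]
      out <- node$forward(list(e[[level]]), deeper, training)
      deeper <- out
    }
    tops <- list(out)
  }

  # deep supervision: 1x1 conv to common width, ReLU, x2 bilinear to full
  # resolution, average, final 1x1 conv + sigmoid
  maps <- lapply(seq_along(tops), function(i) {
    op_up2_bilinear(op_relu(conv_apply(model$ds[[i]], tops[[i]])))
  })
  fused <- op_mean_of(maps)
  logits <- conv_apply(model$head_conv, fused)
  out <- list(prob = op_sigmoid(logits), logits = logits)
  # per-level shapes actually realised by this pass (encoder contract audit)
  attr(out, "encoder_shapes") <- do.call(rbind, lapply(seq_len(s), function(l) {
    d <- dim(e[[l]]$val)
    data.frame(level = l, spatial_side = d[1], channels = d[3])
  }))
  out
}

#' Count trainable parameters
#'
#' Total number of trainable scalars (convolution kernels and biases, batch
#' normalisation scales and shifts) in a built network.
#'
#' @param model An `adenseunet` object (or an `adu_block`).
#' @return Integer count.
#' @export
count_parameters <- function(model) {
  params <- if (inherits(model, "adenseunet")) model$params
            else flatten_params(model)
  sum(vapply(params, function(p) length(p$val), numeric(1)))
}

#' Predict a segmentation map
#'
#' Runs the network on one image (deterministic inference: batch-norm running
#' statistics, no dropout or augmentation).
#'
#' @param object An `adenseunet` or `adenseunet_fit` object.
#' @param image `(side, side, 3)` numeric array in \[0, 1\], or a
#'   `segmentation_sample`.
#' @param type `"prob"` for the probability map, `"mask"` for the
#'   0.5-thresholded binary mask, `"both"` for a list of the two.
#' @param threshold Binarisation threshold used for `"mask"`/`"both"`.
#' @param ... Unused.
#' @return A `(side, side)` matrix, or a list with `prob` and `mask`.
#' @export
predict.adenseunet <- function(object, image, type = c("prob", "mask", "both"),
                               threshold = 0.5, ...) {
  type <- match.arg(type)
  if (inherits(image, "segmentation_sample")) image <- image$image
  out <- forward_adenseunet(object, image, training = FALSE)
  prob <- out$prob$val
  dim(prob) <- dim(prob)[1:2]
  switch(type,
         prob = prob,
         mask = binarize(prob, threshold),
         both = list(prob = prob, mask = binarize(prob, threshold)))
}

#' @export
print.adenseunet <- function(x, ...) {
  cfg <- x$config
  cat("A-DenseUNet network\n")
  cat(sprintf("  input %dx%dx%d -> output %dx%dx1 (sigmoid)\n",
              cfg$input_side, cfg$input_side, cfg$input_channels,
              cfg$input_side, cfg$input_side))
  cat(sprintf("  depth s = %d, growth rate k = %d, blocks [%s]\n",
              cfg$depth_s, cfg$growth_rate_k,
              paste(cfg$block_layers, collapse = ", ")))
  cat(sprintf("  trainable parameters: %s\n",
              format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

#' @export
summary.adenseunet <- function(object, ...) {
  shp <- infer_encoder_shapes(object$config)
  cat("Encoder shape contract (pre-transition):\n")
  print(shp, row.names = FALSE)
  cat(sprintf("Decoder nodes: %d | attention: %s | dilation: %s | dense links: %s\n",
              length(object$dec),
              object$config$use_attention, object$config$use_dilation,
              object$config$use_dense_decoder_links))
  cat(sprintf("Trainable parameters: %s\n",
              format(count_parameters(object), big.mark = ",")))
  invisible(shp)
}
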
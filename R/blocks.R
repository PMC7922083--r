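# Building blocks of the network. Each constructor allocates parameters
# (He-initialised from the current RNG stream) and returns an object holding
# the parameter environments plus a forward closure on tape nodes.

he_conv <- function(kh, kw, cin, cout) {
  fan_in <- kh * kw * cin
  new_param(array(stats::rnorm(kh * kw * cin * cout, 0, sqrt(2 / fan_in)),
                  dim = c(kh, kw, cin, cout)))
}

zeros_param <- function(n) new_param(numeric(n))

bn_make <- function(C) {
  state <- new.env(parent = emptyenv())
  state$running_mean <- numeric(C)
  state$running_var <- rep(1, C)
  list(gamma = new_param(rep(1, C)), beta = zeros_param(C), state = state)
}

bn_apply <- function(bn, x, training) {
  op_batchnorm(x, bn$gamma, bn$beta, bn$state, training)
}

conv_make <- function(kh, kw, cin, cout) {
  list(w = he_conv(kh, kw, cin, cout), b = zeros_param(cout))
}

conv_apply <- function(cv, x, stride = 1L, pad = 0L, dil = 1L) {
  op_conv2d(x, cv$w, cv$b, stride = stride, pad = pad, dil = dil)
}

# "Same" padding for an odd kernel at the given dilation.
same_pad <- function(k, dil) as.integer(dil * (k - 1L) / 2L)

# One dense layer: bottleneck 1x1 conv to factor*k channels, then 3x3 atrous
# conv to k channels, each unit ordered BN-Conv-ReLU (published ordering) or
# BN-ReLU-Conv (DenseNet convention).
dense_layer_make <- function(cin, k, factor, dil) {
  mid <- factor * k
  list(bn1 = bn_make(cin), conv1 = conv_make(1L, 1L, cin, mid),
       bn2 = bn_make(mid), conv2 = conv_make(3L, 3L, mid, k), dil = dil)
}

dense_layer_apply <- function(ly, x, training, order) {
  if (order == "bn-conv-relu") {
    h <- op_relu(conv_apply(ly$conv1, bn_apply(ly$bn1, x, training)))
    op_relu(conv_apply(ly$conv2, bn_apply(ly$bn2, h, training),
                       pad = same_pad(3L, ly$dil), dil = ly$dil))
  } else {
    h <- conv_apply(ly$conv1, op_relu(bn_apply(ly$bn1, x, training)))
    conv_apply(ly$conv2, op_relu(bn_apply(ly$bn2, h, training)),
               pad = same_pad(3L, ly$dil), dil = ly$dil)
  }
}

#' Densely connected convolution block
#'
#' Builds a dense block: a stack of `n_layers` layers in which layer t takes
#' the channel-wise concatenation of the block input and all previous layers'
#' outputs, and contributes `k` new channels, so the output width is
#' `in_channels + n_layers * k` and the spatial side is unchanged. Each layer
#' is a 1x1 bottleneck convolution (to `factor * k` channels) followed by a
#' 3x3 atrous convolution at dilation `rate`, with batch normalisation and
#' ReLU per `order`.
#'
#' @param in_channels Input channel count.
#' @param n_layers Number of dense layers (0 gives an identity block).
#' @param k Growth rate.
#' @param rate Dilation rate of the 3x3 convolutions.
#' @param factor Bottleneck width multiplier (default 4).
#' @param order Layer ordering, `"bn-conv-relu"` or `"bn-relu-conv"`.
#' @return An object of class `adu_block` with elements `params`,
#'   `out_channels`, and `forward(x, training)` operating on tape nodes.
#' @export
dense_block <- function(in_channels, n_layers, k, rate = 1L, factor = 4L,
                        order = "bn-conv-relu") {
  if (n_layers < 0) stop("invalid argument: n_layers must be >= 0")
  layers <- list()
  cin <- in_channels
  for (t in seq_len(n_layers)) {
    layers[[t]] <- dense_layer_make(cin, k, factor, rate)
    cin <- cin + k
  }
  forward <- function(x, training = FALSE) {
    state <- x
    for (ly in layers) {
      out <- dense_layer_apply(ly, state, training, order)
      state <- op_concat(list(state, out))
    }
    state
  }
  structure(list(params = layers, out_channels = as.integer(in_channels + n_layers * k),
                 forward = forward, kind = "dense_block"),
            class = "adu_block")
}

#' Transition block between dense blocks
#'
#' Compresses channels with a 1x1 convolution to `floor(theta * in_channels)`
#' and halves the spatial side with 2x2 average pooling (stride 2).
#'
#' @param in_channels Input channel count.
#' @param theta Compression factor in (0, 1].
#' @return An `adu_block` with `out_channels = floor(theta * in_channels)`.
#' @export
transition_block <- function(in_channels, theta = 0.5) {
  if (!(theta > 0 && theta <= 1))
    stop("invalid argument: theta must be in (0, 1]")
  cout <- as.integer(floor(theta * in_channels))
  bn <- bn_make(in_channels)
  cv <- conv_make(1L, 1L, in_channels, cout)
  forward <- function(x, training = FALSE) {
    op_avgpool2(op_relu(conv_apply(cv, bn_apply(bn, x, training))))
  }
  structure(list(params = list(bn = bn, conv = cv), out_channels = cout,
                 forward = forward, kind = "transition"),
            class = "adu_block")
}

#' Additive attention gate
#'
#' Learns a per-position coefficient map in \[0, 1\] that reweights skip
#' features before they are fused into the decoder: 1x1 convolutions project
#' the skip features and the gating signal to a common intermediate width,
#' the projections are summed, passed through ReLU and a 1x1 convolution to a
#' single channel, and squashed by a sigmoid; the coefficients multiply every
#' channel of the skip input. If the gating signal has half the skip's
#' spatial side it is upsampled bilinearly; any other mismatch is an error.
#'
#' @param skip_channels Channels of the features being gated.
#' @param gate_channels Channels of the gating signal.
#' @param inter_channels Intermediate projection width.
#' @return An `adu_block` whose `forward(skip, gate, training)` returns a
#'   tensor with exactly the skip input's shape.
#' @export
attention_gate <- function(skip_channels, gate_channels,
                           inter_channels = max(1L, skip_channels %/% 4L)) {
  stopifnot(skip_channels >= 1, gate_channels >= 1, inter_channels >= 1)
  wx <- conv_make(1L, 1L, skip_channels, inter_channels)
  wg <- conv_make(1L, 1L, gate_channels, inter_channels)
  psi <- conv_make(1L, 1L, inter_channels, 1L)
  forward <- function(skip, gate, training = FALSE) {
    gs <- conv_apply(wg, gate)
    sd <- dim(skip$val); gd <- dim(gs$val)
    if (gd[1] != sd[1] || gd[2] != sd[2]) {
      if (gd[1] * 2L == sd[1] && gd[2] * 2L == sd[2]) {
        gs <- op_up2_bilinear(gs)
      } else {
        stop("shape contract: gating signal ", gd[1], "x", gd[2],
             " cannot be resampled to skip ", sd[1], "x", sd[2])
      }
    }
    a <- op_relu(op_add(conv_apply(wx, skip), gs))
    coef <- op_sigmoid(conv_apply(psi, a))
    op_gate_mul(coef, skip)
  }
  structure(list(params = list(wx = wx, wg = wg, psi = psi),
                 out_channels = as.integer(skip_channels),
                 forward = forward, kind = "attention_gate"),
            class = "adu_block")
}

#' @export
print.adu_block <- function(x, ...) {
  cat("<adu_block:", x$kind, "-> channels", x$out_channels, ">\n")
  invisible(x)
}

# Residual refinement applied after each decoder fusion: a 1x1 projection
# shortcut plus (when the dilated-convolution block is enabled) a parallel
# 3x3 atrous conv -> BN -> ReLU branch. With zeroed branch weights the node
# output equals the projected shortcut exactly.
refine_make <- function(cin, cout, dil, use_branch) {
  obj <- list(proj = conv_make(1L, 1L, cin, cout), use_branch = use_branch)
  if (use_branch) {
    obj$conv <- conv_make(3L, 3L, cin, cout)
    obj$bn <- bn_make(cout)
    obj$dil <- dil
  }
  obj
}

refine_apply <- function(rf, x, training) {
  short <- conv_apply(rf$proj, x)
  if (!rf$use_branch) return(short)
  br <- op_relu(bn_apply(rf$bn, conv_apply(rf$conv, x, pad = same_pad(3L, rf$dil),
                                           dil = rf$dil), training))
  op_add(short, br)
}

# Decoder node constructor used by the model builder. `skip_channels` is the
# total width of the same-level predecessors (encoder output at column 0 plus
# earlier decoder nodes when dense links are on); `deep_channels` the width of
# the node one level deeper / one column earlier.
decoder_node_make <- function(cfg, level, skip_channels, deep_channels,
                              enc_channels) {
  w <- decoder_width(cfg, level, enc_channels)
  node <- list(width = w)
  if (cfg$use_attention) {
    node$gate <- attention_gate(deep_channels, deep_channels,
                                inter_channels = max(1L, deep_channels %/% 4L))
  }
  node$up <- list(w = he_conv(2L, 2L, deep_channels, w), b = zeros_param(w))
  dil <- if (cfg$use_dilation) cfg$dilation_rate_l else 1L
  node$refine <- refine_make(skip_channels + w, w, dil, cfg$use_dilation)
  node$forward <- function(skips, deeper, training = FALSE) {
    d <- deeper
    if (cfg$use_attention) d <- node$gate$forward(d, d, training)
    up <- op_convt2(d, node$up$w, node$up$b)
    fused <- op_concat(c(skips, list(up)))
    refine_apply(node$refine, fused, training)
  }
  node
}

#' Build one decoder node of the nested multi-depth decoder
#'
#' A node at (level, column) fuses (a) the output of the node one level
#' deeper / one column earlier — attention-gated before upsampling when
#' attention is enabled, then upsampled x2 by a 2x2 stride-2 transposed
#' convolution — with (b) the concatenation of all same-level predecessors
#' (the encoder output at column 0, plus every earlier decoder node at that
#' level when dense decoder links are on), and refines the fusion with a
#' residual block (3x3 atrous convolution, batch normalisation, ReLU beside a
#' 1x1 projection shortcut). Its output spatial side equals the encoder side
#' at that level.
#'
#' @param level Decoder level in `1 .. depth_s - 1`.
#' @param column Decoder column (>= 1).
#' @param config An [model_config()] object.
#' @return An `adu_block` with `forward(skips, deeper, training)`, where
#'   `skips` is a list of same-level predecessor nodes and `deeper` the
#'   deeper-level input node.
#' @export
decoder_node <- function(level, column, config) {
  validate_model_config(config)
  s <- config$depth_s
  if (level < 1L || level > s - 1L)
    stop("topology error: level must be in [1, ", s - 1L, "]")
  ok <- if (config$use_dense_decoder_links) {
    column >= 1L && column <= s - level
  } else {
    column == s - level  # single U-Net path: one node per level
  }
  if (!ok)
    stop("topology error: no decoder node at level ", level, ", column ",
         column, " under this configuration")
  shp <- infer_encoder_shapes(config)
  enc_ch <- shp$channels
  grid <- decoder_grid(config)
  key <- paste(level, column, sep = ",")
  info <- grid[[key]]
  if (is.null(info))
    stop("topology error: node (", level, ",", column, ") references ",
         "nonexistent predecessors")
  node <- decoder_node_make(config, level, info$skip_channels,
                            info$deep_channels, enc_ch)
  structure(list(params = node[c("gate", "up", "refine")],
                 out_channels = node$width, forward = node$forward,
                 kind = sprintf("decoder_node(%d,%d)", level, column)),
            class = "adu_block")
}

# Channel bookkeeping for the decoder grid. Returns a named list keyed
# "level,column" with skip_channels / deep_channels / width. Column 0 is the
# encoder. With dense links, level i has columns 1 .. depth-i (nested grid);
# without, only the U-Net path nodes (i, depth - i) exist and each sees the
# encoder skip only.
decoder_grid <- function(cfg) {
  s <- cfg$depth_s
  shp <- infer_encoder_shapes(cfg)
  enc_ch <- shp$channels
  width <- function(level) decoder_width(cfg, level, enc_ch)
  out_ch <- function(level, column) {
    if (column == 0L) enc_ch[level] else width(level)
  }
  grid <- list()
  if (cfg$use_dense_decoder_links) {
    for (level in seq(s - 1L, 1L)) {
      for (column in seq_len(s - level)) {
        skips <- sum(vapply(0:(column - 1L), function(j) out_ch(level, j), numeric(1)))
        grid[[paste(level, column, sep = ",")]] <- list(
          skip_channels = as.integer(skips),
          deep_channels = as.integer(out_ch(level + 1L, column - 1L)),
          width = width(level))
      }
    }
  } else {
    for (level in seq(s - 1L, 1L)) {
      column <- s - level
      deep <- if (level == s - 1L) enc_ch[s] else width(level + 1L)
      grid[[paste(level, column, sep = ",")]] <- list(
        skip_channels = as.integer(enc_ch[level]),
        deep_channels = as.integer(deep),
        width = width(level))
    }
  }
  grid
}
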
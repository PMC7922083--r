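#' Architecture configuration for A-DenseUNet
#'
#' Collects every architecture hyperparameter of the network: the densely
#' connected encoder (stem, growth rate, per-block layer counts, transition
#' compression), the atrous-convolution dilation rate, the decoder depth and
#' channel rule, and the ablation switches for the attention gates, the
#' dilated-convolution refinement blocks and the dense decoder links.
#'
#' The defaults reproduce the published layout: a 224x224x3 input, a 7x7
#' stride-2 stem with 96 filters, growth rate k = 48 with dense-block repeats
#' [6, 12, 36, 24], bottleneck width 4k, transition compression 0.5, dilation
#' rate 2 in every convolution, and network depth s = 5 (the stem level plus
#' one level per dense block).
#'
#' @param input_side Input image side in pixels (square input).
#' @param input_channels Number of input channels (3 for RGB).
#' @param stem_filters Filters in the first (stem) convolution.
#' @param stem_kernel Stem kernel size.
#' @param growth_rate_k Channels added by each dense layer.
#' @param block_layers Integer vector: dense-layer repeats per dense block.
#' @param bottleneck_factor Bottleneck width multiplier (1x1 conv outputs
#'   `bottleneck_factor * growth_rate_k` channels).
#' @param compression_theta Transition compression factor in (0, 1].
#' @param dilation_rate_l Dilation rate used by every 3x3 convolution.
#' @param dilation_rates Optional per-dense-block override of the dilation
#'   rate (length = number of dense blocks). `NULL` uses `dilation_rate_l`
#'   everywhere.
#' @param depth_s Network depth: number of spatial levels (stem level plus one
#'   per dense block).
#' @param use_attention Keep the attention gates in the decoder.
#' @param use_dilation Keep atrous convolution (rate > 1) and the decoder's
#'   dilated-convolution residual refinement blocks.
#' @param use_dense_decoder_links Keep the nested multi-depth decoder grid
#'   (horizontal dense connections); when `FALSE` the decoder degenerates to a
#'   single-column U-Net path.
#' @param decoder_channel_rule `"halve-per-up"` (decoder level i outputs
#'   `decoder_base_filters * 2^(i-1)` channels, capped) or
#'   `"match-encoder-level"` (decoder level i matches the encoder's channel
#'   count at that level).
#' @param decoder_base_filters Base width of the decoder under
#'   `"halve-per-up"`.
#' @param decoder_max_filters Cap on decoder channel widths.
#' @param deep_supervision_filters Common channel width the top-row decoder
#'   outputs are mapped to before full-resolution averaging.
#' @param dense_layer_order `"bn-conv-relu"` (the published ordering) or
#'   `"bn-relu-conv"` (the DenseNet convention).
#' @param seed Integer seed for weight initialisation.
#' @return An object of class `adu_model_config` (a validated named list).
#' @seealso [infer_encoder_shapes()], [a_denseunet()], [reduced_model_config()]
#' @export
model_config <- function(input_side = 224L,
                         input_channels = 3L,
                         stem_filters = 96L,
                         stem_kernel = 7L,
                         growth_rate_k = 48L,
                         block_layers = c(6L, 12L, 36L, 24L),
                         bottleneck_factor = 4L,
                         compression_theta = 0.5,
                         dilation_rate_l = 2L,
                         dilation_rates = NULL,
                         depth_s = 5L,
                         use_attention = TRUE,
                         use_dilation = TRUE,
                         use_dense_decoder_links = TRUE,
                         decoder_channel_rule = c("halve-per-up", "match-encoder-level"),
                         decoder_base_filters = 64L,
                         decoder_max_filters = 512L,
                         deep_supervision_filters = 32L,
                         dense_layer_order = c("bn-conv-relu", "bn-relu-conv"),
                         seed = 42L) {
  cfg <- list(
    input_side = as.integer(input_side),
    input_channels = as.integer(input_channels),
    stem_filters = as.integer(stem_filters),
    stem_kernel = as.integer(stem_kernel),
    growth_rate_k = as.integer(growth_rate_k),
    block_layers = as.integer(block_layers),
    bottleneck_factor = as.integer(bottleneck_factor),
    compression_theta = as.numeric(compression_theta),
    dilation_rate_l = as.integer(dilation_rate_l),
    dilation_rates = if (is.null(dilation_rates)) NULL else as.integer(dilation_rates),
    depth_s = as.integer(depth_s),
    use_attention = isTRUE(use_attention),
    use_dilation = isTRUE(use_dilation),
    use_dense_decoder_links = isTRUE(use_dense_decoder_links),
    decoder_channel_rule = match.arg(decoder_channel_rule),
    decoder_base_filters = as.integer(decoder_base_filters),
    decoder_max_filters = as.integer(decoder_max_filters),
    deep_supervision_filters = as.integer(deep_supervision_filters),
    dense_layer_order = match.arg(dense_layer_order),
    seed = as.integer(seed)
  )
  class(cfg) <- "adu_model_config"
  validate_model_config(cfg)
  cfg
}

#' @rdname model_config
#' @details `reduced_model_config()` is a desk-scale variant (96x96 input,
#'   growth rate 8, blocks [2, 2, 2, 2], narrow stem and decoder) that keeps
#'   the full topology — dense encoder, attention gates, nested decoder, deep
#'   supervision — at a size a CPU can train in minutes.
#' @param ... Overrides passed on to `model_config()`.
#' @export
reduced_model_config <- function(...) {
  defaults <- list(input_side = 96L, stem_filters = 16L, growth_rate_k = 8L,
                   block_layers = c(2L, 2L, 2L, 2L), bottleneck_factor = 4L,
                   decoder_base_filters = 8L, decoder_max_filters = 64L,
                   deep_supervision_filters = 8L)
  user <- list(...)
  do.call(model_config, utils::modifyList(defaults, user))
}

validate_model_config <- function(cfg) {
  fail <- function(inv, ...) {
    stop("invalid model config [", inv, "]: ", ..., call. = FALSE)
  }
  if (length(cfg$block_layers) + 1L != cfg$depth_s)
    fail("len(block_layers) + 1 == depth_s",
         "got ", length(cfg$block_layers), " dense blocks for depth ", cfg$depth_s)
  if (cfg$input_side %% (2^cfg$depth_s) != 0L)
    fail("input_side divisible by 2^depth_s",
         cfg$input_side, " is not divisible by ", 2^cfg$depth_s)
  if (cfg$growth_rate_k < 1L) fail("growth_rate_k >= 1", cfg$growth_rate_k)
  if (cfg$dilation_rate_l < 1L) fail("dilation_rate_l >= 1", cfg$dilation_rate_l)
  if (!is.null(cfg$dilation_rates)) {
    if (length(cfg$dilation_rates) != length(cfg$block_layers))
      fail("dilation_rates length == number of dense blocks",
           length(cfg$dilation_rates))
    if (any(cfg$dilation_rates < 1L)) fail("dilation rates >= 1", "")
  }
  if (!(cfg$compression_theta > 0 && cfg$compression_theta <= 1))
    fail("0 < compression_theta <= 1", cfg$compression_theta)
  if (any(cfg$block_layers < 0L)) fail("block_layers >= 0", "")
  if (cfg$stem_kernel %% 2L != 1L) fail("stem_kernel odd", cfg$stem_kernel)
  invisible(cfg)
}

# Effective dilation rate for dense block b (1-based) under the config.
block_dilation <- function(cfg, b) {
  if (!cfg$use_dilation) return(1L)
  if (!is.null(cfg$dilation_rates)) cfg$dilation_rates[b] else cfg$dilation_rate_l
}

# Decoder output width at level i.
decoder_width <- function(cfg, level, enc_channels) {
  if (cfg$decoder_channel_rule == "match-encoder-level") {
    w <- enc_channels[level]
  } else {
    w <- cfg$decoder_base_filters * 2^(level - 1L)
  }
  as.integer(min(w, cfg$decoder_max_filters))
}

#' Read / write a model configuration as a flat YAML file
#'
#' Every field of [model_config()] is a top-level key. Unknown keys are an
#' error, so stale or misspelled configuration files fail loudly.
#'
#' @param path File path.
#' @return `read_model_config()` returns an `adu_model_config`.
#' @export
read_model_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(model_config))
  known <- setdiff(known, "...")
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown model config keys: ", paste(unknown, collapse = ", "))
  do.call(model_config, raw)
}

#' @rdname read_model_config
#' @param config An `adu_model_config`.
#' @export
write_model_config <- function(config, path) {
  stopifnot(inherits(config, "adu_model_config"))
  out <- unclass(config)
  out <- out[!vapply(out, is.null, logical(1))]
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @export
print.adu_model_config <- function(x, ...) {
  cat("A-DenseUNet model configuration\n")
  cat(sprintf("  input: %dx%dx%d, depth s = %d\n",
              x$input_side, x$input_side, x$input_channels, x$depth_s))
  cat(sprintf("  stem: %dx%d conv, %d filters, stride 2\n",
              x$stem_kernel, x$stem_kernel, x$stem_filters))
  cat(sprintf("  dense blocks: [%s], growth rate k = %d, bottleneck %dk, theta = %g\n",
              paste(x$block_layers, collapse = ", "), x$growth_rate_k,
              x$bottleneck_factor, x$compression_theta))
  cat(sprintf("  dilation rate: %d (%s)\n", x$dilation_rate_l,
              if (x$use_dilation) "on" else "ablated"))
  cat(sprintf("  attention: %s | dense decoder links: %s\n",
              if (x$use_attention) "on" else "ablated",
              if (x$use_dense_decoder_links) "on" else "ablated"))
  cat(sprintf("  decoder: %s (base %d, cap %d), deep supervision width %d\n",
              x$decoder_channel_rule, x$decoder_base_filters,
              x$decoder_max_filters, x$deep_supervision_filters))
  invisible(x)
}

#' Disable architecture blocks for an ablation study
#'
#' Mirrors the block-removal ablation: each flag switches one architectural
#' addition off while leaving the output contract (a full-resolution
#' probability map) unchanged.
#'
#' @param config An `adu_model_config`.
#' @param flags Character vector, subset of `"no_attention"`, `"no_dilation"`,
#'   `"no_dense_links"`.
#' @return The modified configuration.
#' @export
ablate <- function(config, flags = character()) {
  stopifnot(inherits(config, "adu_model_config"))
  known <- c("no_attention", "no_dilation", "no_dense_links")
  bad <- setdiff(flags, known)
  if (length(bad)) stop("unknown ablation flag(s): ", paste(bad, collapse = ", "))
  if ("no_attention" %in% flags) config$use_attention <- FALSE
  if ("no_dilation" %in% flags) config$use_dilation <- FALSE
  if ("no_dense_links" %in% flags) config$use_dense_decoder_links <- FALSE
  config
}
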
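# Mask-aware augmentation: every geometric transform is applied identically
# to image and mask (bilinear vs nearest sampling), photometric transforms
# touch the image only, and masks stay strictly {0,1}-valued.

#' Augmentation protocol configuration
#'
#' The four published techniques — rotation in 0-90 degrees, horizontal and
#' vertical reflection, elastic deformation on a fixed 10x10 grid, random
#' gamma — applied after an aspect-preserving resize with random crop. Each
#' augmented variant draws a random sub-chain (every enabled technique
#' independently with probability 0.5). A multiplier of 10 expands 800
#' training images to 8000 outputs (the resized original plus nine variants
#' per input).
#'
#' @param target_side Output side in pixels.
#' @param rotation_range Rotation angle range in degrees, within \[0, 90\].
#' @param flip_horizontal,flip_vertical Enable the two reflections.
#' @param elastic_grid Control-grid size of the elastic deformation.
#' @param elastic_magnitude Displacement standard deviation in pixels.
#' @param gamma_range Random-gamma exponent interval.
#' @param multiplier Outputs per input (>= 1).
#' @param seed Integer seed; the pipeline is a pure function of
#'   (inputs, config).
#' @return An object of class `augment_config`.
#' @export
augment_config <- function(target_side = 224L,
                           rotation_range = c(0, 90),
                           flip_horizontal = TRUE,
                           flip_vertical = TRUE,
                           elastic_grid = 10L,
                           elastic_magnitude = 6,
                           gamma_range = c(0.7, 1.5),
                           multiplier = 10L,
                           seed = 1L) {
  if (multiplier < 1) stop("invalid argument: multiplier must be >= 1")
  stopifnot(rotation_range[1] >= 0, rotation_range[2] <= 90,
            rotation_range[1] <= rotation_range[2], elastic_grid >= 2L)
  structure(list(target_side = as.integer(target_side),
                 rotation_range = as.numeric(rotation_range),
                 flip_horizontal = isTRUE(flip_horizontal),
                 flip_vertical = isTRUE(flip_vertical),
                 elastic_grid = as.integer(elastic_grid),
                 elastic_magnitude = as.numeric(elastic_magnitude),
                 gamma_range = as.numeric(gamma_range),
                 multiplier = as.integer(multiplier),
                 seed = as.integer(seed)),
            class = "augment_config")
}

# Apply an inverse warp given per-output-pixel source coordinates (0-based):
# bilinear with reflect padding for the image, nearest for the mask.
apply_warp <- function(sample, ys, xs, side) {
  iv <- nn_sample_bilinear(sample$image, dim(sample$image), ys, xs, TRUE)
  img <- array(iv, dim = c(side, side, 3L))
  d <- dim(sample$mask)
  ma <- array(as.double(sample$mask), dim = c(d[1], d[2], 1L))
  mv <- nn_sample_nearest(ma, dim(ma), ys, xs, TRUE)
  msk <- matrix(as.integer(mv[, 1] > 0.5), side, side)
  new_segmentation_sample(img, msk, id = sample$id, polyps = sample$polyps)
}

#' Aspect-preserving resize with random crop
#'
#' Scales the shorter side of the sample to `side` and takes a random
#' `side x side` crop, with identical geometry on image and mask.
#' Randomness comes from the current RNG stream (seed it, or let
#' [augment_dataset()] do so).
#'
#' @param sample A `segmentation_sample`.
#' @param side Output side in pixels.
#' @return The cropped `segmentation_sample`.
#' @export
resize_random_crop <- function(sample, side = 224L) {
  d <- dim(sample$image)
  if (d[1] < 2 || d[2] < 2) stop("degenerate input dimensions")
  scale <- side / min(d[1], d[2])
  nh <- max(side, round(d[1] * scale)); nw <- max(side, round(d[2] * scale))
  top <- if (nh > side) sample.int(nh - side + 1L, 1L) - 1L else 0L
  left <- if (nw > side) sample.int(nw - side + 1L, 1L) - 1L else 0L
  warp_crop(sample, nh, nw, top, left, side)
}

#' Random rotation
#'
#' Rotates image and mask by an angle drawn uniformly from `range` degrees
#' about the image centre (bilinear image / nearest mask, reflect padding).
#'
#' @param sample A `segmentation_sample` (square).
#' @param range Angle range in degrees.
#' @return The rotated sample.
#' @export
random_rotate <- function(sample, range = c(0, 90)) {
  side <- nrow(sample$mask)
  theta <- stats::runif(1, range[1], range[2]) * pi / 180
  if (theta == 0) return(sample)
  cc <- (side - 1) / 2
  out_y <- rep(seq_len(side) - 1, times = side) - cc
  out_x <- rep(seq_len(side) - 1, each = side) - cc
  ys <- cos(theta) * out_y - sin(theta) * out_x + cc
  xs <- sin(theta) * out_y + cos(theta) * out_x + cc
  apply_warp(sample, ys, xs, side)
}

#' Random reflection
#'
#' Flips the sample horizontally and/or vertically, each enabled axis with
#' probability 0.5. Flips are exact (pure index reversal), so applying the
#' same reflection twice restores the sample bit-for-bit.
#'
#' @param sample A `segmentation_sample`.
#' @param horizontal,vertical Axes eligible for flipping.
#' @param force When `TRUE`, flip every enabled axis deterministically.
#' @return The reflected sample.
#' @export
random_reflect <- function(sample, horizontal = TRUE, vertical = TRUE,
                           force = FALSE) {
  do_h <- horizontal && (force || stats::runif(1) < 0.5)
  do_v <- vertical && (force || stats::runif(1) < 0.5)
  img <- sample$image; msk <- sample$mask
  if (do_h) { img <- img[, rev(seq_len(ncol(msk))), , drop = FALSE]
              msk <- msk[, rev(seq_len(ncol(msk))), drop = FALSE] }
  if (do_v) { img <- img[rev(seq_len(nrow(msk))), , , drop = FALSE]
              msk <- msk[rev(seq_len(nrow(msk))), , drop = FALSE] }
  new_segmentation_sample(img, msk, id = sample$id, polyps = sample$polyps)
}

#' Elastic deformation on a fixed control grid
#'
#' Draws i.i.d. Gaussian displacement vectors on a `grid x grid` lattice,
#' interpolates them smoothly to a dense per-pixel field and warps image and
#' mask through the identical field. Magnitude 0 is the identity.
#'
#' @param sample A `segmentation_sample` (square).
#' @param grid Control-grid size (default 10).
#' @param magnitude Displacement standard deviation in pixels.
#' @return The deformed sample.
#' @export
elastic_deform <- function(sample, grid = 10L, magnitude = 6) {
  side <- nrow(sample$mask)
  gy <- matrix(stats::rnorm(grid * grid, 0, magnitude), grid, grid)
  gx <- matrix(stats::rnorm(grid * grid, 0, magnitude), grid, grid)
  if (magnitude == 0) return(sample)
  src <- (seq_len(side) - 0.5) / side * (grid - 1)
  coords <- expand.grid(y = src, x = src)
  dy <- nn_sample_bilinear(array(gy, dim = c(grid, grid, 1L)),
                           c(grid, grid, 1L), coords$y, coords$x, FALSE)[, 1]
  dx <- nn_sample_bilinear(array(gx, dim = c(grid, grid, 1L)),
                           c(grid, grid, 1L), coords$y, coords$x, FALSE)[, 1]
  base_y <- rep(seq_len(side) - 1, times = side)
  base_x <- rep(seq_len(side) - 1, each = side)
  apply_warp(sample, base_y + dy, base_x + dx, side)
}

#' Random gamma adjustment
#'
#' Raises the image to a random exponent drawn uniformly from `range`
#' (identical across channels); the mask is untouched.
#'
#' @param sample A `segmentation_sample`.
#' @param range Gamma interval.
#' @return The adjusted sample.
#' @export
random_gamma <- function(sample, range = c(0.7, 1.5)) {
  g <- stats::runif(1, range[1], range[2])
  img <- pmin(pmax(sample$image, 0), 1)^g
  new_segmentation_sample(img, sample$mask, id = sample$id,
                          polyps = sample$polyps)
}

#' Expand a dataset by mask-aware augmentation
#'
#' For every input sample, emits the deterministically resized original plus
#' `multiplier - 1` randomised variants (random crop, then each enabled
#' technique independently with probability 0.5), so the output count is
#' `length(samples) * multiplier`. The whole pipeline is a pure function of
#' the inputs and `config$seed`.
#'
#' @param samples List of `segmentation_sample`s, or a function
#'   `function(i)` returning the i-th sample (to stream large sets), in which
#'   case `n_inputs` must be given.
#' @param config An [augment_config()].
#' @param sink Optional `function(sample, index)` consuming each output as it
#'   is produced (e.g. [save_sample()]); when supplied, outputs are not
#'   accumulated in memory and the total count is returned.
#' @param n_inputs Number of inputs when `samples` is a function.
#' @return A list of `segmentation_sample`s, or the output count when `sink`
#'   is given.
#' @export
augment_dataset <- function(samples, config = augment_config(), sink = NULL,
                            n_inputs = NULL) {
  stopifnot(inherits(config, "augment_config"))
  fetch <- if (is.function(samples)) {
    if (is.null(n_inputs)) stop("n_inputs required when samples is a function")
    samples
  } else {
    n_inputs <- length(samples)
    function(i) samples[[i]]
  }
  side <- config$target_side
  run_seeded(config$seed, {
    out <- if (is.null(sink)) vector("list", n_inputs * config$multiplier) else NULL
    idx <- 0L
    for (i in seq_len(n_inputs)) {
      s0 <- fetch(i)
      emit <- function(s, variant) {
        idx <<- idx + 1L
        s$id <- sprintf("%s_aug%02d", s0$id, variant)
        if (is.null(sink)) out[[idx]] <<- s else sink(s, idx)
      }
      emit(resize_center_crop(s0, side), 0L)
      for (v in seq_len(config$multiplier - 1L)) {
        s <- resize_random_crop(s0, side)
        if (stats::runif(1) < 0.5)
          s <- random_rotate(s, config$rotation_range)
        if (stats::runif(1) < 0.5)
          s <- random_reflect(s, config$flip_horizontal, config$flip_vertical)
        if (stats::runif(1) < 0.5)
          s <- elastic_deform(s, config$elastic_grid, config$elastic_magnitude)
        if (stats::runif(1) < 0.5)
          s <- random_gamma(s, config$gamma_range)
        emit(s, v)
      }
    }
    if (is.null(sink)) out else idx
  })
}
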
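# Synthetic colonoscopy phantoms: textured pink-brown mucosa, one or two
# raised elliptical polyps with distinct texture and smoothed borders, a few
# specular highlights and radial vignetting. The ground-truth mask is the
# exact union of the generating ellipse interiors (before any visual
# smoothing), so masks are pixel-exact by construction.

#' Configuration of the synthetic phantom generator
#'
#' All realism parameters are invented plumbing whose only purpose is to give
#' the pipeline colonoscopy-like inputs with exact ground truth; defaults are
#' chosen so polyps occupy a realistic fraction of the frame (roughly 1-15%
#' of pixels).
#'
#' @param side Image side in pixels.
#' @param n_polyps Integer range `c(min, max)` of polyps per frame.
#' @param polyp_axis_range Ellipse semi-axis range as a fraction of `side`.
#' @param texture_scale Amplitude of the low-frequency mucosa texture.
#' @param specular_spots Integer range of specular highlights per frame.
#' @param vignette_strength Strength of the radial vignette in \[0, 1\].
#' @param seed Integer; together with the sample index it fully determines
#'   every generated sample.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(side = 256L,
                           n_polyps = c(1L, 2L),
                           polyp_axis_range = c(0.07, 0.16),
                           texture_scale = 0.08,
                           specular_spots = c(2L, 5L),
                           vignette_strength = 0.35,
                           seed = 1L) {
  stopifnot(side >= 32L, length(n_polyps) == 2L, n_polyps[1] <= n_polyps[2],
            n_polyps[1] >= 0L,
            length(polyp_axis_range) == 2L, polyp_axis_range[1] > 0,
            polyp_axis_range[2] < 0.5,
            vignette_strength >= 0, vignette_strength <= 1)
  structure(list(side = as.integer(side), n_polyps = as.integer(n_polyps),
                 polyp_axis_range = as.numeric(polyp_axis_range),
                 texture_scale = as.numeric(texture_scale),
                 specular_spots = as.integer(specular_spots),
                 vignette_strength = as.numeric(vignette_strength),
                 seed = as.integer(seed)),
            class = "phantom_config")
}

# Smooth low-frequency noise field: coarse i.i.d. grid upsampled bilinearly.
smooth_noise <- function(side, grid = 8L, sd = 1) {
  g <- matrix(stats::rnorm(grid * grid, 0, sd), grid, grid)
  ga <- array(g, dim = c(grid, grid, 1L))
  src <- (seq_len(side) - 0.5) / side * (grid - 1)
  coords <- expand.grid(y = src, x = src)
  v <- nn_sample_bilinear(ga, c(grid, grid, 1L), coords$y, coords$x, FALSE)
  matrix(v[, 1], side, side)
}

run_seeded <- function(seed, expr) {
  old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  force(expr)
}

#' Generate one synthetic colonoscopy sample
#'
#' Deterministic in `(config, index)`: the same pair always produces
#' bit-identical arrays.
#'
#' @param config A [phantom_config()].
#' @param index Sample index (non-negative integer).
#' @return A `segmentation_sample`: list with `image` (side x side x 3 array
#'   in \[0, 1\]), `mask` (side x side binary matrix), `id`, and the polyp
#'   parameters used (`polyps`).
#' @export
phantom_sample <- function(config = phantom_config(), index = 0L) {
  stopifnot(inherits(config, "phantom_config"))
  run_seeded((config$seed * 10007L + as.integer(index)) %% .Machine$integer.max, {
    side <- config$side
    xs <- matrix(rep(seq_len(side), each = side), side, side)  # column coord
    ys <- matrix(rep(seq_len(side), times = side), side, side) # row coord

    # mucosa base: pink-brown tint modulated by smooth noise per channel
    base <- c(0.72, 0.45, 0.40) * stats::runif(1, 0.85, 1.1)
    tex <- smooth_noise(side, grid = 9L) * config$texture_scale
    fine <- smooth_noise(side, grid = 32L) * config$texture_scale * 0.4
    img <- array(0, dim = c(side, side, 3L))
    for (ch in 1:3) img[, , ch] <- base[ch] + tex * c(1, 0.8, 0.7)[ch] + fine

    # polyps
    n <- if (config$n_polyps[1] == config$n_polyps[2]) config$n_polyps[1]
         else sample(seq(config$n_polyps[1], config$n_polyps[2]), 1L)
    mask <- matrix(0L, side, side)
    polyps <- list()
    for (i in seq_len(n)) {
      a <- stats::runif(1, config$polyp_axis_range[1], config$polyp_axis_range[2]) * side
      b <- stats::runif(1, config$polyp_axis_range[1], config$polyp_axis_range[2]) * side
      phi <- stats::runif(1, 0, pi)
      r <- max(a, b)
      if (r + 2 >= side - r - 2)
        stop("infeasible polyp geometry: axes do not fit inside the frame")
      cx <- stats::runif(1, r + 2, side - r - 2)
      cy <- stats::runif(1, r + 2, side - r - 2)
      dx <- xs - cx; dy <- ys - cy
      u <- (dx * cos(phi) + dy * sin(phi)) / a
      v <- (-dx * sin(phi) + dy * cos(phi)) / b
      r2 <- u * u + v * v
      inside <- r2 <= 1
      mask[inside] <- 1L
      # raised dome with smoothed border and a redder, distinctly textured cap
      border <- pmin(pmax((1.15 - sqrt(r2)) / 0.3, 0), 1)  # soft alpha
      dome <- pmax(1 - r2, 0)
      ptex <- smooth_noise(side, grid = 24L) * 0.10
      tint <- c(0.14, 0.02, -0.02)
      for (ch in 1:3) {
        img[, , ch] <- img[, , ch] +
          border * (tint[ch] + 0.18 * dome + ptex * c(1, 0.7, 0.5)[ch])
      }
      polyps[[i]] <- list(cx = cx, cy = cy, a = a, b = b, phi = phi)
    }

    # specular highlights: small saturated gaussian spots
    nspec <- if (config$specular_spots[1] == config$specular_spots[2])
      config$specular_spots[1]
    else sample(seq(config$specular_spots[1], config$specular_spots[2]), 1L)
    for (i in seq_len(nspec)) {
      sx <- stats::runif(1, 1, side); sy <- stats::runif(1, 1, side)
      sr <- stats::runif(1, 0.006, 0.015) * side
      spot <- exp(-((xs - sx)^2 + (ys - sy)^2) / (2 * sr^2))
      for (ch in 1:3) img[, , ch] <- img[, , ch] + spot * 0.9
    }

    # radial vignette
    cc <- (side + 1) / 2
    rad2 <- ((xs - cc)^2 + (ys - cc)^2) / (2 * cc^2)
    vig <- 1 - config$vignette_strength * rad2
    for (ch in 1:3) img[, , ch] <- img[, , ch] * vig

    img[img < 0] <- 0; img[img > 1] <- 1
    new_segmentation_sample(img, mask, id = sprintf("phantom_%05d", as.integer(index)),
                            polyps = polyps)
  })
}

new_segmentation_sample <- function(image, mask, id = "", polyps = NULL) {
  stopifnot(length(dim(image)) == 3L, all(dim(image)[1:2] == dim(mask)))
  structure(list(image = image, mask = mask, id = id, polyps = polyps),
            class = "segmentation_sample")
}

#' @export
print.segmentation_sample <- function(x, ...) {
  d <- dim(x$image)
  cat(sprintf("segmentation sample '%s': %dx%dx%d image, %.1f%% foreground\n",
              x$id, d[1], d[2], d[3], 100 * mean(x$mask)))
  invisible(x)
}

#' Generate a phantom dataset on disk
#'
#' Writes `n` samples in the Kvasir-SEG directory convention — `images/` and
#' `masks/` subdirectories with same-named 8-bit PNG files (masks use values
#' 0 and 255) — plus a JSON manifest listing ids and polyp parameters.
#'
#' @param n Number of samples.
#' @param out_dir Output directory (created if needed).
#' @param config A [phantom_config()].
#' @return Invisibly, the manifest (list with `ids`, `seed`, `side`,
#'   `polyps`).
#' @export
phantom_dataset <- function(n, out_dir, config = phantom_config()) {
  stopifnot(n >= 0)
  img_dir <- file.path(out_dir, "images")
  msk_dir <- file.path(out_dir, "masks")
  dir.create(img_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(msk_dir, recursive = TRUE, showWarnings = FALSE)
  ids <- character(n)
  polyps <- vector("list", n)
  for (i in seq_len(n)) {
    s <- phantom_sample(config, i - 1L)
    ids[i] <- s$id
    polyps[[i]] <- s$polyps
    png::writePNG(aperm_to_png(s$image), file.path(img_dir, paste0(s$id, ".png")))
    png::writePNG(matrix(as.double(s$mask), nrow(s$mask)),
                  file.path(msk_dir, paste0(s$id, ".png")))
  }
  manifest <- list(ids = ids, seed = config$seed, side = config$side,
                   polyps = polyps)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

# png::writePNG quantises to 8 bits on write; round explicitly so written
# pixels equal round(x * 255) / 255.
aperm_to_png <- function(img) round(img * 255) / 255
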
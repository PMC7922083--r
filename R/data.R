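# Reading image/mask datasets laid out in the Kvasir-SEG / CVC-612
# convention: <root>/images/*.png and <root>/masks/*.png with matching
# basenames.

#' Discover image/mask pairs in a dataset directory
#'
#' Matches files by basename across the two directories in deterministic
#' lexicographic order. Any image without a mask (or vice versa) is an error
#' naming the orphans explicitly.
#'
#' @param images_dir,masks_dir Directories of images and masks.
#' @return A data frame with columns `id`, `image`, `mask` (file paths).
#' @export
discover_pairs <- function(images_dir, masks_dir) {
  if (!dir.exists(images_dir)) stop("images directory not found: ", images_dir)
  if (!dir.exists(masks_dir)) stop("masks directory not found: ", masks_dir)
  pat <- "\\.(png|jpg|jpeg)$"
  imgs <- sort(list.files(images_dir, pattern = pat, ignore.case = TRUE))
  msks <- sort(list.files(masks_dir, pattern = pat, ignore.case = TRUE))
  iid <- tools::file_path_sans_ext(imgs)
  mid <- tools::file_path_sans_ext(msks)
  orphan_i <- setdiff(iid, mid)
  orphan_m <- setdiff(mid, iid)
  if (length(orphan_i) || length(orphan_m)) {
    stop("unpaired files — images without masks: [",
         paste(orphan_i, collapse = ", "), "]; masks without images: [",
         paste(orphan_m, collapse = ", "), "]")
  }
  data.frame(id = iid,
             image = file.path(images_dir, imgs),
             mask = file.path(masks_dir, msks[match(iid, mid)]),
             stringsAsFactors = FALSE)
}

read_image_png <- function(path) {
  x <- png::readPNG(path)
  if (is.null(dim(x))) stop("unreadable image: ", path)
  if (length(dim(x)) == 2L) x <- array(rep(x, 3L), dim = c(dim(x), 3L))
  if (dim(x)[3] > 3L) x <- x[, , 1:3, drop = FALSE]  # drop alpha
  x
}

read_mask_png <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  # binarisation rule: 8-bit gray value > 127 is foreground
  (round(m * 255) > 127) * 1L
}

#' Load one image/mask pair
#'
#' Reads the pair, scales the image to \[0, 1\], binarises the mask (8-bit
#' value > 127 is foreground) and, when `target_side` is given, applies the
#' deterministic evaluation-time resize: aspect-preserving scale of the
#' shorter side followed by a centre crop (bilinear for the image, nearest
#' for the mask).
#'
#' @param pair One row of [discover_pairs()] (or a list with `image`, `mask`,
#'   `id`).
#' @param target_side Optional output side in pixels.
#' @return A `segmentation_sample`.
#' @export
load_sample <- function(pair, target_side = NULL) {
  img <- read_image_png(pair$image)
  msk <- read_mask_png(pair$mask)
  if (!all(dim(img)[1:2] == dim(msk)))
    stop("image/mask size mismatch for id ", pair$id)
  s <- new_segmentation_sample(img, msk, id = as.character(pair$id))
  if (!is.null(target_side)) s <- resize_center_crop(s, target_side)
  s
}

# Aspect-preserving scale (shorter side -> `side`) + centre crop; the
# deterministic counterpart of the training-time random crop.
resize_center_crop <- function(sample, side) {
  d <- dim(sample$image)
  scale <- side / min(d[1], d[2])
  nh <- max(side, round(d[1] * scale)); nw <- max(side, round(d[2] * scale))
  top <- floor((nh - side) / 2); left <- floor((nw - side) / 2)
  warp_crop(sample, nh, nw, top, left, side)
}

# Shared resize+crop kernel: scale the input to (nh, nw) and take the
# side x side window at (top, left) (0-based), bilinear image / nearest mask.
warp_crop <- function(sample, nh, nw, top, left, side) {
  d <- dim(sample$image)
  rows <- (top + seq_len(side) - 0.5) / nh * d[1] - 0.5
  cols <- (left + seq_len(side) - 0.5) / nw * d[2] - 0.5
  ys <- rep(rows, times = side); xs <- rep(cols, each = side)
  iv <- nn_sample_bilinear(sample$image, dim(sample$image), ys, xs, FALSE)
  img <- array(iv, dim = c(side, side, 3L))
  ma <- array(as.double(sample$mask), dim = c(d[1], d[2], 1L))
  mv <- nn_sample_nearest(ma, dim(ma), ys, xs, FALSE)
  msk <- matrix(as.integer(mv[, 1] > 0.5), side, side)
  new_segmentation_sample(img, msk, id = sample$id, polyps = sample$polyps)
}

#' Save a segmentation sample as PNG files
#'
#' @param sample A `segmentation_sample`.
#' @param images_dir,masks_dir Output directories (created if needed).
#' @return Invisibly, the two file paths.
#' @export
save_sample <- function(sample, images_dir, masks_dir) {
  dir.create(images_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(masks_dir, recursive = TRUE, showWarnings = FALSE)
  ip <- file.path(images_dir, paste0(sample$id, ".png"))
  mp <- file.path(masks_dir, paste0(sample$id, ".png"))
  png::writePNG(aperm_to_png(sample$image), ip)
  png::writePNG(matrix(as.double(sample$mask), nrow(sample$mask)), mp)
  invisible(c(image = ip, mask = mp))
}

#' Random train/validation/test split
#'
#' Shuffles the ids with a seeded generator and assigns `floor(r_train * n)`
#' to training, `floor(r_val * n)` to validation and the remainder to test
#' (the 80/10/10 default gives 800/100/100 for n = 1000).
#'
#' @param ids Character vector of sample ids.
#' @param ratios Numeric triple summing to 1.
#' @param seed Integer seed; the split is fully reproducible from it.
#' @return An object of class `dataset_split`: list with `train`,
#'   `validation`, `test`, `seed`, `ratios`.
#' @export
split_dataset <- function(ids, ratios = c(0.8, 0.1, 0.1), seed = 1L) {
  stopifnot(length(ratios) == 3L)
  if (abs(sum(ratios) - 1) > 1e-8)
    stop("invalid argument: ratios must sum to 1")
  n <- length(ids)
  if (n < sum(ratios > 0))
    stop("invalid argument: ", n, " ids cannot fill ", sum(ratios > 0),
         " nonempty partitions")
  perm <- run_seeded(seed, sample.int(n))
  n_train <- floor(ratios[1] * n)
  n_val <- floor(ratios[2] * n)
  shuffled <- ids[perm]
  structure(list(train = shuffled[seq_len(n_train)],
                 validation = shuffled[n_train + seq_len(n_val)],
                 test = shuffled[setdiff(seq_len(n), seq_len(n_train + n_val))],
                 seed = as.integer(seed), ratios = as.numeric(ratios)),
            class = "dataset_split")
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf("dataset split (seed %d, ratios %s): train %d / validation %d / test %d\n",
              x$seed, paste(x$ratios, collapse = "/"),
              length(x$train), length(x$validation), length(x$test)))
  invisible(x)
}

#' Save / load a split manifest as JSON
#'
#' @param split A [split_dataset()] result.
#' @param path JSON file path.
#' @export
write_split <- function(split, path) {
  stopifnot(inherits(split, "dataset_split"))
  jsonlite::write_json(unclass(split), path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_split
#' @export
read_split <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(train = as.character(raw$train),
                 validation = as.character(raw$validation),
                 test = as.character(raw$test),
                 seed = as.integer(raw$seed), ratios = as.numeric(raw$ratios)),
            class = "dataset_split")
}
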
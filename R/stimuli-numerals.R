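# Numeral (symbolic) stimulus generation.
#
# Emulates handwritten-digit variability without any external dataset:
# fixed 5x7 glyph templates for the digits 1-9 are rendered onto a 28x28
# canvas and perturbed by a seeded random affine map (rotation, scale,
# shear, translation), then upsampled by constant pixel replication so
# every k x k block of the final raster is constant. An optional loader
# for real MNIST IDX files is provided for fidelity runs.

# 5x7 glyph templates, rows top to bottom.
glyph_rows <- list(
  `1` = c("..X..", ".XX..", "..X..", "..X..", "..X..", "..X..", ".XXX."),
  `2` = c(".XXX.", "X...X", "....X", "...X.", "..X..", ".X...", "XXXXX"),
  `3` = c(".XXX.", "X...X", "....X", "..XX.", "....X", "X...X", ".XXX."),
  `4` = c("...X.", "..XX.", ".X.X.", "X..X.", "XXXXX", "...X.", "...X."),
  `5` = c("XXXXX", "X....", "XXXX.", "....X", "....X", "X...X", ".XXX."),
  `6` = c("..XX.", ".X...", "X....", "XXXX.", "X...X", "X...X", ".XXX."),
  `7` = c("XXXXX", "....X", "...X.", "...X.", "..X..", "..X..", "..X.."),
  `8` = c(".XXX.", "X...X", "X...X", ".XXX.", "X...X", "X...X", ".XXX."),
  `9` = c(".XXX.", "X...X", "X...X", ".XXXX", "....X", "...X.", ".XX..")
)

glyph_matrix <- function(n) {
  rows <- glyph_rows[[as.character(n)]]
  m <- t(vapply(rows, function(r) strsplit(r, "")[[1]] == "X", logical(5)))
  m * 1 # 7 rows x 5 cols
}

# Render the digit template at base resolution 28x28: each glyph cell
# becomes a 3x3 block (15x21 glyph footprint) centered on the canvas.
render_glyph28 <- function(n) {
  g <- glyph_matrix(n)
  big <- g[rep(seq_len(7), each = 3L), rep(seq_len(5), each = 3L)]
  img <- matrix(0, 28, 28)
  r0 <- floor((28 - 21) / 2); c0 <- floor((28 - 15) / 2)
  img[r0 + seq_len(21), c0 + seq_len(15)] <- big
  img
}

# Seeded random affine warp on a 28x28 raster (nearest-neighbour,
# inverse-mapped about the canvas center).
affine_warp28 <- function(img, theta, sx, sy, shear, tx, ty) {
  ct <- cos(theta); st <- sin(theta)
  A <- matrix(c(ct, st, -st, ct), 2, 2) %*%
       matrix(c(1, 0, shear, 1), 2, 2) %*% diag(c(sx, sy))
  Ainv <- solve(A)
  ctr <- (28 + 1) / 2
  grid <- as.matrix(expand.grid(r = 1:28, c = 1:28))
  src <- sweep(grid, 2L, c(ctr + ty, ctr + tx)) %*% t(Ainv)
  src <- round(sweep(src, 2L, c(ctr, ctr), `+`))
  ok <- src[, 1L] >= 1 & src[, 1L] <= 28 & src[, 2L] >= 1 & src[, 2L] <= 28
  out <- numeric(28 * 28)
  out[ok] <- img[src[ok, , drop = FALSE]]
  matrix(out, 28, 28)
}

upsample_blocks <- function(img, k) {
  img[rep(seq_len(nrow(img)), each = k), rep(seq_len(ncol(img)), each = k)]
}

#' Generate one numeral stimulus image
#'
#' Renders the glyph for digit `n` at 28x28, applies a seeded random
#' affine perturbation (rotation up to 15 degrees, scale and shear up to
#' 10\%, translation up to 2 px) emulating handwriting variability, then
#' upsamples by replicating each pixel into a constant `upsample` x
#' `upsample` block with no additional filtering (8 at full 224 x 224
#' scale; the desk profile uses 2, giving 56 x 56).
#'
#' @param n Digit 1-9.
#' @param style_seed Integer seed for the perturbation.
#' @param upsample Pixel replication factor per axis.
#' @return A `numalign_stimulus` with `format = "symbolic"`.
#' @export
generate_numeral_image <- function(n, style_seed, upsample = 2L) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1 || n > 9 ||
      n != floor(n))
    stop("numeral `n` must be an integer between 1 and 9", call. = FALSE)
  stopifnot_scalar_count(upsample, "upsample")
  with_seed(style_seed, {
    theta <- runif(1, -15, 15) * pi / 180
    sx <- runif(1, 0.9, 1.1); sy <- runif(1, 0.9, 1.1)
    shear <- runif(1, -0.1, 0.1)
    tx <- runif(1, -2, 2); ty <- runif(1, -2, 2)
    base <- affine_warp28(render_glyph28(n), theta, sx, sy, shear, tx, ty)
    new_stimulus(upsample_blocks(base, upsample), n, "symbolic",
                 provenance = list(generator = "glyph", seed = as.integer(style_seed),
                                   numerosity = as.integer(n),
                                   upsample = as.integer(upsample),
                                   affine = c(theta = theta, sx = sx, sy = sy,
                                              shear = shear, tx = tx, ty = ty)))
  })
}

#' Generate a numeral stimulus set
#'
#' `images_per_numerosity` distorted renderings per digit 1-9; the first
#' `train_per_numerosity` of each go to the training split. The full-scale
#' configuration (600, 500) matches the dot set sizes (4500/900).
#'
#' @inheritParams generate_numeral_image
#' @param images_per_numerosity,train_per_numerosity Per-digit counts.
#' @param seed Integer seed for all per-image style seeds.
#' @return A list of `numalign_stimulus` objects with a `manifest` attribute.
#' @export
generate_numeral_dataset <- function(images_per_numerosity = 120L,
                                     train_per_numerosity = 100L,
                                     seed = 1L, upsample = 2L) {
  stopifnot_scalar_count(images_per_numerosity, "images_per_numerosity")
  stopifnot_scalar_count(train_per_numerosity, "train_per_numerosity")
  if (train_per_numerosity >= images_per_numerosity)
    stop("`train_per_numerosity` must be smaller than `images_per_numerosity`",
         call. = FALSE)
  seeds <- matrix(derive_seeds(seed, 9L * images_per_numerosity),
                  nrow = 9L)
  images <- vector("list", 9L * images_per_numerosity)
  rows <- vector("list", length(images))
  k <- 0L
  for (n in 1:9) {
    for (j in seq_len(images_per_numerosity)) {
      k <- k + 1L
      img <- generate_numeral_image(n, seeds[n, j], upsample = upsample)
      img$split <- if (j <= train_per_numerosity) "train" else "test"
      images[[k]] <- img
      rows[[k]] <- data.frame(id = k, numerosity = n, format = "symbolic",
                              split = img$split, seed = seeds[n, j],
                              upsample = as.integer(upsample))
    }
  }
  attr(images, "manifest") <- do.call(rbind, rows)
  images
}

#' Read an MNIST-format IDX file pair (optional fidelity loader)
#'
#' Convenience loader for users who have the real MNIST files locally; the
#' package itself never requires them. Digits 0 are dropped (numerosities
#' are 1-9) and, per digit, the first `train_per_digit` + `test_per_digit`
#' occurrences are taken in file order.
#'
#' @param images_file,labels_file Paths to uncompressed IDX files.
#' @param train_per_digit,test_per_digit Images per digit and split.
#' @param upsample Pixel replication factor (8 reproduces 224 x 224).
#' @return A list of `numalign_stimulus` objects with a `manifest` attribute.
#' @export
load_mnist_numerals <- function(images_file, labels_file,
                                train_per_digit = 500L, test_per_digit = 100L,
                                upsample = 8L) {
  read_idx <- function(path) {
    con <- file(path, "rb"); on.exit(close(con))
    magic <- readBin(con, "integer", 1L, size = 4L, endian = "big")
    ndim <- magic %% 256L
    dims <- readBin(con, "integer", ndim, size = 4L, endian = "big")
    data <- readBin(con, "integer", prod(dims), size = 1L, signed = FALSE)
    list(dims = dims, data = data)
  }
  imgs <- read_idx(images_file); labs <- read_idx(labels_file)
  if (length(labs$data) != imgs$dims[1L])
    stop("image/label counts disagree", call. = FALSE)
  h <- imgs$dims[2L]; w <- imgs$dims[3L]
  out <- list(); rows <- list(); k <- 0L
  for (n in 1:9) {
    idx <- which(labs$data == n)
    take <- head(idx, train_per_digit + test_per_digit)
    for (j in seq_along(take)) {
      i <- take[j]
      raw <- matrix(imgs$data[((i - 1L) * h * w + 1L):(i * h * w)],
                    h, w, byrow = TRUE) / 255
      k <- k + 1L
      img <- new_stimulus(upsample_blocks(raw, upsample), n, "symbolic",
                          provenance = list(generator = "mnist", index = i,
                                            upsample = as.integer(upsample)))
      img$split <- if (j <= train_per_digit) "train" else "test"
      out[[k]] <- img
      rows[[k]] <- data.frame(id = k, numerosity = n, format = "symbolic",
                              split = img$split, seed = NA_integer_,
                              upsample = as.integer(upsample))
    }
  }
  attr(out, "manifest") <- do.call(rbind, rows)
  out
}
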
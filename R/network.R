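# The dorsal-stream-inspired convolutional trunk and its task decoders.
#
# Four named stages (V1, V2, V3, IPS) of strided 3x3 convolutions with
# ReLU, optionally recurrent (weight-shared residual 3x3 convolutions
# within a stage, in the spirit of recurrent vision models). The IPS
# feature used by all analyses is the spatially average-pooled output of
# the IPS stage, so the trunk is fully convolutional and accepts any
# canvas size. Two linear decoders share the trunk: a 2-class comparison
# head (which side is numerically larger) and a 9-class labeling head.

#' Configure the model
#'
#' @param blocks Named list of exactly four stage descriptors (`V1`, `V2`,
#'   `V3`, `IPS`), each a list with `channels`, `stride` and `recurrence`
#'   (number of passes through the stage; 1 = feedforward).
#' @param input_channels Input image channels (stimuli are luminance
#'   rasters, so 1).
#' @param kernel Convolution kernel size.
#' @param pairing_mode How a comparison trial enters the network:
#'   `"siamese"` passes each side through the shared trunk and feeds the
#'   concatenated (left, right) IPS vectors to the 2-class decoder;
#'   `"composite"` abuts the two rasters side by side into one canvas.
#' @param heads Output dimensions per task kind; must contain
#'   `comparison = 2` and `labeling = 9`.
#' @param seed Weight-initialization seed.
#' @return A `numalign_model_config` object; `ips_dim` equals the IPS
#'   stage's channel count (global average pooling).
#' @export
model_config <- function(blocks = list(
                           V1 = list(channels = 16, stride = 2, recurrence = 1),
                           V2 = list(channels = 32, stride = 2, recurrence = 1),
                           V3 = list(channels = 32, stride = 2, recurrence = 1),
                           IPS = list(channels = 64, stride = 2, recurrence = 1)),
                         input_channels = 1L, kernel = 3L,
                         pairing_mode = c("siamese", "composite"),
                         heads = c(comparison = 2L, labeling = 9L),
                         seed = 1L) {
  pairing_mode <- match.arg(pairing_mode)
  if (!identical(names(blocks), c("V1", "V2", "V3", "IPS")))
    stop("`blocks` must be exactly the four named stages V1, V2, V3, IPS",
         call. = FALSE)
  for (b in blocks)
    if (!all(c("channels", "stride", "recurrence") %in% names(b)) ||
        b$channels < 1 || b$stride < 1 || b$recurrence < 1)
      stop("each block needs positive `channels`, `stride`, `recurrence`",
           call. = FALSE)
  if (!all(c("comparison", "labeling") %in% names(heads)) ||
      heads[["comparison"]] != 2L || heads[["labeling"]] != 9L)
    stop("`heads` must declare a 2-class comparison and a 9-class labeling decoder",
         call. = FALSE)
  structure(list(blocks = blocks, input_channels = as.integer(input_channels),
                 kernel = as.integer(kernel), pairing_mode = pairing_mode,
                 heads = heads, ips_dim = as.integer(blocks$IPS$channels),
                 seed = as.integer(seed)),
            class = "numalign_model_config")
}

he_init <- function(dims, fan_in) {
  array(rnorm(prod(dims), sd = sqrt(2 / fan_in)), dim = dims)
}

#' Build a model from a configuration
#'
#' Weight initialization is fan-in-scaled Gaussian, fully determined by
#' `config$seed`. Both decoders share one trunk.
#'
#' @param config A [model_config()].
#' @return A `numalign_model` (configuration plus parameter arrays).
#' @export
build_model <- function(config) {
  stopifnot(inherits(config, "numalign_model_config"))
  k <- config$kernel
  with_seed(config$seed, {
    cin <- config$input_channels
    blocks <- list()
    for (nm in names(config$blocks)) {
      b <- config$blocks[[nm]]
      par <- list(W = he_init(c(k, k, cin, b$channels), k * k * cin),
                  b = numeric(b$channels))
      if (b$recurrence > 1L) {
        par$Wr <- he_init(c(k, k, b$channels, b$channels),
                          k * k * b$channels) * 0.1
        par$br <- numeric(b$channels)
      }
      blocks[[nm]] <- par
      cin <- b$channels
    }
    d <- config$ips_dim
    comp_in <- if (config$pairing_mode == "siamese") 2L * d else d
    heads <- list(
      comparison = list(W = matrix(rnorm(2 * comp_in, sd = sqrt(1 / comp_in)),
                                   2, comp_in), b = numeric(2)),
      labeling = list(W = matrix(rnorm(9 * d, sd = sqrt(1 / d)), 9, d),
                      b = numeric(9)))
    structure(list(config = config,
                   params = list(blocks = blocks, heads = heads)),
              class = "numalign_model")
  })
}

#' @export
print.numalign_model <- function(x, ...) {
  ch <- vapply(x$config$blocks, function(b) b$channels, 1)
  cat(sprintf("<numalign_model> V1/V2/V3/IPS channels %s, ips_dim %d, pairing %s\n",
              paste(ch, collapse = "/"), x$config$ips_dim,
              x$config$pairing_mode))
  invisible(x)
}

pad_for <- function(kernel) (kernel - 1L) %/% 2L

# Forward the trunk over a batch array (H, W, C, N). Returns the pooled
# IPS matrix (ips_dim x N) and, if requested, the caches needed for
# backpropagation.
trunk_forward <- function(model, x, keep_cache = FALSE) {
  k <- model$config$kernel; p <- pad_for(k)
  cache <- if (keep_cache) list() else NULL
  for (nm in names(model$config$blocks)) {
    b <- model$config$blocks[[nm]]
    par <- model$params$blocks[[nm]]
    z <- .conv2d_forward(x, par$W, par$b, b$stride, p)
    zs <- NULL
    if (b$recurrence > 1L) {
      zs <- vector("list", b$recurrence - 1L)
      for (t in seq_len(b$recurrence - 1L)) {
        zs[[t]] <- z
        h <- pmax(z, 0)
        z <- z + .conv2d_forward(h, par$Wr, par$br, 1L, p)
      }
    }
    if (keep_cache) cache[[nm]] <- list(x = x, z = z, zs = zs)
    x <- z
    x[x < 0] <- 0
  }
  d <- dim(x) # (H, W, C, N) of IPS activation
  ips <- matrix(colMeans(matrix(x, d[1L] * d[2L], d[3L] * d[4L])),
                d[3L], d[4L])
  if (keep_cache) list(ips = ips, cache = cache, ips_dim_hw = d[1:2])
  else list(ips = ips)
}

# Backpropagate from a gradient on the pooled IPS matrix (ips_dim x N)
# through the trunk; returns gradients for every block parameter.
trunk_backward <- function(model, fwd, g_ips) {
  k <- model$config$kernel; p <- pad_for(k)
  nms <- names(model$config$blocks)
  hw <- fwd$ips_dim_hw
  cz <- fwd$cache[[nms[length(nms)]]]$z
  d <- dim(cz)
  # GAP backward: spread the per-channel gradient uniformly over space.
  ga <- array(rep(as.vector(g_ips), each = d[1L] * d[2L]) / (d[1L] * d[2L]),
              dim = d)
  grads <- list()
  for (i in rev(seq_along(nms))) {
    nm <- nms[i]
    b <- model$config$blocks[[nm]]
    par <- model$params$blocks[[nm]]
    cc <- fwd$cache[[nm]]
    gz <- ga * (cc$z > 0) # ReLU at block output
    g <- list(W = NULL, b = NULL)
    if (b$recurrence > 1L) {
      gWr <- array(0, dim = dim(par$Wr)); gbr <- numeric(length(par$br))
      for (t in rev(seq_len(b$recurrence - 1L))) {
        zprev <- cc$zs[[t]]
        h <- pmax(zprev, 0)
        bw <- .conv2d_backward(h, par$Wr, gz, 1L, p)
        gWr <- gWr + bw$gW; gbr <- gbr + bw$gb
        gz <- gz + bw$gx * (zprev > 0)
      }
      g$Wr <- gWr; g$br <- gbr
    }
    bw <- .conv2d_backward(cc$x, par$W, gz, b$stride, p)
    g$W <- bw$gW; g$b <- bw$gb
    grads[[nm]] <- g
    if (i > 1L) {
      zin <- fwd$cache[[nms[i - 1L]]]$z
      ga <- bw$gx * (zin > 0)
    }
  }
  grads[nms]
}

stack_images <- function(images) {
  d <- dim(images[[1L]]$pixels)
  arr <- array(0, dim = c(d[1L], d[2L], 1L, length(images)))
  for (i in seq_along(images)) arr[, , 1L, i] <- images[[i]]$pixels
  arr
}

# Forward an arbitrary list of stimuli, grouping by raster size (the
# fully convolutional trunk accepts any canvas). Returns the ips matrix
# with columns in input order plus per-group caches for backprop.
forward_images <- function(model, images, keep_cache = FALSE) {
  sizes <- vapply(images, function(i) paste(dim(i$pixels), collapse = "x"), "")
  groups <- split(seq_along(images), sizes)
  ips <- matrix(0, model$config$ips_dim, length(images))
  caches <- list()
  for (gn in names(groups)) {
    idx <- groups[[gn]]
    fwd <- trunk_forward(model, stack_images(images[idx]), keep_cache)
    ips[, idx] <- fwd$ips
    if (keep_cache) caches[[gn]] <- list(idx = idx, fwd = fwd)
  }
  list(ips = ips, caches = caches)
}

# Backward a gradient on the full ips matrix through all size groups,
# summing parameter gradients.
backward_images <- function(model, fwd_all, g_ips) {
  total <- NULL
  for (gr in fwd_all$caches) {
    g <- trunk_backward(model, gr$fwd, g_ips[, gr$idx, drop = FALSE])
    total <- if (is.null(total)) g else nested_map2(total, g, `+`)
  }
  total
}

#' IPS-layer response to a single stimulus
#'
#' The spatially average-pooled activation of the IPS stage, the feature
#' vector on which all representational analyses operate. Deterministic
#' for a fixed model and image.
#'
#' @param model A `numalign_model`.
#' @param image A `numalign_stimulus`.
#' @return Numeric vector of length `config$ips_dim`.
#' @export
ips_response <- function(model, image) {
  stopifnot(inherits(model, "numalign_model"),
            inherits(image, "numalign_stimulus"))
  as.vector(forward_images(model, list(image))$ips)
}

softmax_cols <- function(z) {
  z <- sweep(z, 2L, apply(z, 2L, max))
  e <- exp(z)
  sweep(e, 2L, colSums(e), `/`)
}

head_logits <- function(model, head, feats) {
  par <- model$params$heads[[head]]
  sweep(par$W %*% feats, 1L, par$b, `+`)
}

comparison_features <- function(model, left_ips, right_ips) {
  if (model$config$pairing_mode == "siamese") rbind(left_ips, right_ips)
  else stop("composite pairing computes features from the composite image",
            call. = FALSE)
}

composite_image <- function(left, right) {
  lp <- left$pixels; rp <- right$pixels
  h <- max(nrow(lp), nrow(rp))
  pad <- function(m) {
    if (nrow(m) == h) return(m)
    out <- matrix(0, h, ncol(m))
    r0 <- (h - nrow(m)) %/% 2
    out[r0 + seq_len(nrow(m)), ] <- m
    out
  }
  new_stimulus(cbind(pad(lp), pad(rp)), left$numerosity, "composite")
}

# ips features for a set of comparison trials (by row index).
comparison_forward <- function(model, dataset, rows, keep_cache = FALSE) {
  imgs <- comparison_trial_images(dataset, rows)
  if (model$config$pairing_mode == "composite") {
    comp <- mapply(composite_image, imgs$left, imgs$right, SIMPLIFY = FALSE)
    fwd <- forward_images(model, comp, keep_cache)
    list(feats = fwd$ips, fwd = fwd, n = length(rows))
  } else {
    n <- length(rows)
    fwd <- forward_images(model, c(imgs$left, imgs$right), keep_cache)
    list(feats = rbind(fwd$ips[, seq_len(n), drop = FALSE],
                       fwd$ips[, n + seq_len(n), drop = FALSE]),
         fwd = fwd, n = n)
  }
}

#' Predict the larger side for comparison trials
#'
#' @param model A `numalign_model`.
#' @param dataset A [build_comparison_dataset()] object.
#' @param rows Trial row indices (default: all test trials).
#' @param batch_size Forward-pass batch size.
#' @return Character vector of `"left"` / `"right"` choices.
#' @export
predict_comparison <- function(model, dataset, rows = NULL, batch_size = 128L) {
  stopifnot(inherits(dataset, "numalign_comparisons"))
  rows <- rows %||% which(dataset$trials$split == "test")
  out <- character(length(rows))
  for (chunk in split(seq_along(rows), ceiling(seq_along(rows) / batch_size))) {
    cf <- comparison_forward(model, dataset, rows[chunk])
    logits <- head_logits(model, "comparison", cf$feats)
    out[chunk] <- c("left", "right")[max.col(t(logits), ties.method = "first")]
  }
  out
}

#' Predict the 9-class numerosity label of stimuli
#'
#' @param model A `numalign_model`.
#' @param images A list of `numalign_stimulus` objects (or a single one).
#' @param batch_size Forward-pass batch size.
#' @return Integer labels in 1..9.
#' @export
predict_label <- function(model, images, batch_size = 128L) {
  if (inherits(images, "numalign_stimulus")) images <- list(images)
  out <- integer(length(images))
  for (chunk in split(seq_along(images), ceiling(seq_along(images) / batch_size))) {
    ips <- forward_images(model, images[chunk])$ips
    logits <- head_logits(model, "labeling", ips)
    out[chunk] <- max.col(t(logits), ties.method = "first")
  }
  out
}

#' Save / load a model checkpoint
#'
#' A checkpoint stores the weights together with the configuration and the
#' package version; loading refuses a checkpoint whose embedded
#' configuration disagrees with `config`.
#'
#' @param model A `numalign_model`.
#' @param path File path.
#' @param config Optional expected configuration to validate against.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the model.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "numalign_model"))
  saveRDS(list(config = model$config, params = model$params,
               version = as.character(utils::packageVersion("numalign"))),
          path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path, config = NULL) {
  ck <- readRDS(path)
  if (!is.null(config) && !identical(unclass(ck$config), unclass(config)))
    stop("checkpoint configuration does not match the requested configuration",
         call. = FALSE)
  structure(list(config = ck$config, params = ck$params),
            class = "numalign_model")
}
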
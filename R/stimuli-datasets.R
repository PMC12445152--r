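# Assembly of comparison and labeling datasets from stimulus pools.

#' Bundle dot and numeral stimuli into format/split pools
#'
#' @param dots,numerals Lists of `numalign_stimulus` objects (as returned
#'   by [generate_dot_dataset()] / [generate_numeral_dataset()]), each
#'   carrying a `split` assignment.
#' @return A `numalign_pools` object indexing images by format, split and
#'   numerosity.
#' @export
make_pools <- function(dots, numerals) {
  split_one <- function(images, format) {
    stopifnot(all(vapply(images, function(i) i$format, "") == format))
    out <- list()
    for (sp in c("train", "test")) {
      sel <- images[vapply(images, function(i) identical(i$split, sp), TRUE)]
      ns <- vapply(sel, function(i) i$numerosity, 1L)
      out[[sp]] <- list(images = sel,
                        by_n = lapply(1:9, function(n) which(ns == n)))
    }
    out
  }
  structure(list(nonsymbolic = split_one(dots, "nonsymbolic"),
                 symbolic = split_one(numerals, "symbolic")),
            class = "numalign_pools")
}

pool_get <- function(pools, format, split, idx) {
  pools[[format]][[split]]$images[[idx]]
}

sample_pool_index <- function(pools, format, split, n) {
  cand <- pools[[format]][[split]]$by_n[[n]]
  if (length(cand) == 0L)
    stop(sprintf("empty stimulus pool for numerosity %d, format %s, split %s",
                 n, format, split), call. = FALSE)
  cand[sample.int(length(cand), 1L)]
}

#' Build a comparison-trial dataset
#'
#' Samples ordered number pairs (n, p), n != p, uniformly over the 72
#' cells; each side shows an image of its number, the correct response is
#' the side with the larger number. For `cross_format` trials one side is
#' a dot array and the other a numeral, with the symbolic side chosen
#' uniformly at random. Training trials draw images only from training
#' pools and test trials only from test pools.
#'
#' @param task One of `"nonsymbolic"`, `"symbolic"`, `"cross_format"`.
#' @param n_train,n_test Trial counts per split (the full-scale protocol
#'   uses 4500/900).
#' @param pools A [make_pools()] object.
#' @param seed Integer seed.
#' @return A `numalign_comparisons` object: the trial table (`$trials`, a
#'   `data.frame` with one row per trial) plus a reference to `pools`.
#' @export
build_comparison_dataset <- function(task = c("nonsymbolic", "symbolic",
                                              "cross_format"),
                                     n_train, n_test, pools, seed) {
  task <- match.arg(task)
  stopifnot(inherits(pools, "numalign_pools"))
  stopifnot_scalar_count(n_train, "n_train")
  stopifnot_scalar_count(n_test, "n_test")
  pairs <- subset(expand.grid(left_n = 1:9, right_n = 1:9),
                  left_n != right_n)
  with_seed(seed, {
    build_split <- function(n_trials, split) {
      if (n_trials == 0L) return(NULL)
      cell <- pairs[sample.int(nrow(pairs), n_trials, replace = TRUE), ]
      left_fmt <- right_fmt <- switch(task, nonsymbolic = "nonsymbolic",
                                      symbolic = "symbolic", cross_format = NA)
      if (task == "cross_format") {
        sym_left <- runif(n_trials) < 0.5
        left_fmt <- ifelse(sym_left, "symbolic", "nonsymbolic")
        right_fmt <- ifelse(sym_left, "nonsymbolic", "symbolic")
      } else {
        left_fmt <- rep(left_fmt, n_trials); right_fmt <- rep(right_fmt, n_trials)
      }
      li <- mapply(function(f, n) sample_pool_index(pools, f, split, n),
                   left_fmt, cell$left_n)
      ri <- mapply(function(f, n) sample_pool_index(pools, f, split, n),
                   right_fmt, cell$right_n)
      data.frame(split = split, left_n = cell$left_n, right_n = cell$right_n,
                 left_format = left_fmt, right_format = right_fmt,
                 left_idx = li, right_idx = ri,
                 label = ifelse(cell$left_n > cell$right_n, "left", "right"),
                 row.names = NULL)
    }
    trials <- rbind(build_split(n_train, "train"), build_split(n_test, "test"))
    structure(list(task = task, trials = trials, pools = pools),
              class = "numalign_comparisons")
  })
}

#' @export
print.numalign_comparisons <- function(x, ...) {
  cat(sprintf("<numalign_comparisons> task=%s, %d train / %d test trials\n",
              x$task, sum(x$trials$split == "train"),
              sum(x$trials$split == "test")))
  invisible(x)
}

comparison_trial_images <- function(dataset, rows) {
  tr <- dataset$trials[rows, , drop = FALSE]
  list(left = lapply(seq_len(nrow(tr)), function(i)
         pool_get(dataset$pools, tr$left_format[i], tr$split[i], tr$left_idx[i])),
       right = lapply(seq_len(nrow(tr)), function(i)
         pool_get(dataset$pools, tr$right_format[i], tr$split[i], tr$right_idx[i])))
}

#' Build a labeling (quantification) dataset
#'
#' One trial per pooled image: the target label equals the image's
#' numerosity. Requesting both formats concatenates the two single-format
#' datasets (the full-scale merged set has 9000/1800 training/testing
#' trials).
#'
#' @param formats Subset of `c("nonsymbolic", "symbolic")`.
#' @param pools A [make_pools()] object.
#' @param seed Integer seed (training-order shuffle).
#' @return A `numalign_labeling` object with a `$trials` data.frame.
#' @export
build_labeling_dataset <- function(formats, pools, seed = 1L) {
  if (length(formats) == 0L ||
      !all(formats %in% c("nonsymbolic", "symbolic")))
    stop("`formats` must be a non-empty subset of nonsymbolic/symbolic",
         call. = FALSE)
  stopifnot(inherits(pools, "numalign_pools"))
  rows <- list()
  for (f in formats) {
    for (sp in c("train", "test")) {
      imgs <- pools[[f]][[sp]]$images
      if (length(imgs) == 0L)
        stop(sprintf("empty stimulus pool for format %s, split %s", f, sp),
             call. = FALSE)
      rows[[paste(f, sp)]] <- data.frame(
        split = sp, format = f, idx = seq_along(imgs),
        label = vapply(imgs, function(i) i$numerosity, 1L))
    }
  }
  trials <- do.call(rbind, rows)
  rownames(trials) <- NULL
  with_seed(seed, {
    tr <- which(trials$split == "train")
    trials[tr, ] <- trials[tr[sample.int(length(tr))], ]
  })
  structure(list(formats = formats, trials = trials, pools = pools),
            class = "numalign_labeling")
}

#' @export
print.numalign_labeling <- function(x, ...) {
  cat(sprintf("<numalign_labeling> formats=%s, %d train / %d test trials\n",
              paste(x$formats, collapse = "+"),
              sum(x$trials$split == "train"), sum(x$trials$split == "test")))
  invisible(x)
}

labeling_trial_images <- function(dataset, rows) {
  tr <- dataset$trials[rows, , drop = FALSE]
  lapply(seq_len(nrow(tr)), function(i)
    pool_get(dataset$pools, tr$format[i], tr$split[i], tr$idx[i]))
}

#' Write a dataset manifest
#'
#' Writes one CSV row per image or trial plus a JSON header with the
#' global configuration, the plain-text provenance format used by all
#' dataset artifacts.
#'
#' @param x A stimulus list (with `manifest` attribute), comparison or
#'   labeling dataset.
#' @param path Output CSV path; a `.json` header is written alongside.
#' @param config Optional list echoed into the JSON header.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(x, path, config = list()) {
  tab <- if (!is.null(attr(x, "manifest"))) attr(x, "manifest")
         else if (inherits(x, c("numalign_comparisons", "numalign_labeling")))
           x$trials
         else stop("no manifest available for this object", call. = FALSE)
  write.csv(tab, path, row.names = FALSE)
  jsonlite::write_json(config, sub("\\.csv$", ".json", path),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
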
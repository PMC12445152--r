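# Behavioral analyses of trained checkpoints: overall test accuracy,
# ordered-pair accuracy, and the generalized / forgotten pair sets.

#' Overall comparison accuracy
#'
#' Fraction of trials whose predicted choice equals the correct side.
#'
#' @param model A `numalign_model`.
#' @param dataset A comparison dataset.
#' @param split Which split to evaluate (default test).
#' @return Accuracy in \[0,1\].
#' @export
evaluate_accuracy <- function(model, dataset, split = "test") {
  stopifnot(inherits(dataset, "numalign_comparisons"))
  rows <- which(dataset$trials$split == split)
  if (length(rows) == 0L)
    stop("no trials in the requested split", call. = FALSE)
  mean(predict_comparison(model, dataset, rows) == dataset$trials$label[rows])
}

#' Ordered-pair accuracy table
#'
#' Accuracy over exactly the trials whose ordered number pair
#' (left, right) is (n, p), for each of the 72 cells with n != p. Cells
#' with no evaluated trials are reported as missing (`NA` accuracy, count
#' 0), never imputed. Pairs are ordered: (3, 7) and (7, 3) are distinct
#' cells, which is what exposes left/right (SNARC-like) asymmetries.
#'
#' @inheritParams evaluate_accuracy
#' @param stage Optional stage identity stored with the table.
#' @return A `numalign_pair_table`: data.frame with columns `left_n`,
#'   `right_n`, `accuracy`, `count`; attributes `task` and `stage`.
#' @export
pair_accuracy <- function(model, dataset, split = "test", stage = NA) {
  stopifnot(inherits(dataset, "numalign_comparisons"))
  rows <- which(dataset$trials$split == split)
  if (length(rows) == 0L)
    stop("no trials in the requested split", call. = FALSE)
  tr <- dataset$trials[rows, ]
  correct <- predict_comparison(model, dataset, rows) == tr$label
  cells <- subset(expand.grid(left_n = 1:9, right_n = 1:9), left_n != right_n)
  key <- paste(tr$left_n, tr$right_n)
  agg_n <- table(factor(key, levels = paste(cells$left_n, cells$right_n)))
  agg_c <- tapply(correct, factor(key, levels = paste(cells$left_n,
                                                      cells$right_n)), mean)
  out <- data.frame(left_n = cells$left_n, right_n = cells$right_n,
                    accuracy = as.numeric(agg_c),
                    count = as.integer(agg_n), row.names = NULL)
  structure(out, class = c("numalign_pair_table", "data.frame"),
            task = dataset$task, stage = stage)
}

#' Generalized pairs
#'
#' Ordered pairs whose accuracy on an untrained task is strictly above the
#' threshold (95\% by default) at a stage boundary. Missing cells are
#' excluded.
#'
#' @param table A [pair_accuracy()] table.
#' @param threshold Strict lower accuracy bound.
#' @param kind Label recorded on the returned set.
#' @return A `numalign_pair_set`: data.frame of (left_n, right_n).
#' @export
generalized_pairs <- function(table, threshold = 0.95,
                              kind = "generalized") {
  stopifnot(inherits(table, "numalign_pair_table"))
  sel <- !is.na(table$accuracy) & table$accuracy > threshold
  structure(table[sel, c("left_n", "right_n"), drop = FALSE],
            class = c("numalign_pair_set", "data.frame"),
            kind = kind, threshold = threshold)
}

#' Forgotten pairs
#'
#' Ordered pairs above the `hi` accuracy bound before a stage (strictly)
#' and below the `lo` bound after it (strictly): skills mastered at one
#' stage boundary and lost by the next.
#'
#' @param before,after [pair_accuracy()] tables of the same task at
#'   consecutive stage boundaries.
#' @param hi,lo Strict accuracy bounds (defaults 0.95 and 0.55).
#' @return A `numalign_pair_set`.
#' @export
forgotten_pairs <- function(before, after, hi = 0.95, lo = 0.55) {
  stopifnot(inherits(before, "numalign_pair_table"),
            inherits(after, "numalign_pair_table"))
  if (!identical(attr(before, "task"), attr(after, "task")))
    stop("`before` and `after` must measure the same comparison task",
         call. = FALSE)
  sel <- !is.na(before$accuracy) & !is.na(after$accuracy) &
    before$accuracy > hi & after$accuracy < lo
  structure(before[sel, c("left_n", "right_n"), drop = FALSE],
            class = c("numalign_pair_set", "data.frame"),
            kind = "forgotten", hi = hi, lo = lo)
}

#' Serialize a pair-accuracy table as 9 x 9 CSVs
#'
#' Writes an accuracy matrix (diagonal empty) and a matching counts
#' matrix, rows = left number, columns = right number.
#'
#' @param table A [pair_accuracy()] table.
#' @param path Base CSV path; counts go to `*_counts.csv`.
#' @return `path`, invisibly.
#' @export
write_pair_table <- function(table, path) {
  acc <- matrix(NA_real_, 9, 9, dimnames = list(1:9, 1:9))
  cnt <- matrix(0L, 9, 9, dimnames = list(1:9, 1:9))
  acc[cbind(table$left_n, table$right_n)] <- table$accuracy
  cnt[cbind(table$left_n, table$right_n)] <- table$count
  write.csv(acc, path)
  write.csv(cnt, sub("\\.csv$", "_counts.csv", path))
  invisible(path)
}
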
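# The three-stage developmentally inspired curriculum.
#
# Stage 1 trains nonsymbolic (dot) comparison; stage 2 establishes the
# symbolic-nonsymbolic mapping under one of two conditions (cross-format
# comparison, or cross-label mapping interleaved minibatch-for-minibatch
# with dot comparison); stage 3 trains symbolic (numeral) comparison.
# After every epoch all three comparison test sets are evaluated.

#' Configure one curriculum stage
#'
#' @param stage_id One of `"nonsymbolic"`, `"mapping"`, `"symbolic"`.
#' @param mapping_condition For the mapping stage, `"cross_format"` or
#'   `"cross_label"`; otherwise `"none"`.
#' @param epochs Training epochs (20 at full scale).
#' @param lr,batch_size Adam learning rate and minibatch size.
#' @param interleave_ratio Cross-label batches per dot-comparison batch in
#'   the interleaved mapping stage.
#' @return A `numalign_stage_config`.
#' @export
stage_config <- function(stage_id = c("nonsymbolic", "mapping", "symbolic"),
                         mapping_condition = c("none", "cross_format",
                                               "cross_label"),
                         epochs = 20L, lr = 1e-3, batch_size = 32L,
                         interleave_ratio = 1) {
  stage_id <- match.arg(stage_id)
  mapping_condition <- match.arg(mapping_condition)
  if ((stage_id == "mapping") == (mapping_condition == "none"))
    stop("`mapping_condition` must be set exactly for the mapping stage",
         call. = FALSE)
  stopifnot_scalar_count(epochs, "epochs")
  if (epochs < 1L) stop("`epochs` must be at least 1", call. = FALSE)
  structure(list(stage_id = stage_id, mapping_condition = mapping_condition,
                 epochs = as.integer(epochs), lr = lr,
                 batch_size = as.integer(batch_size),
                 interleave_ratio = interleave_ratio),
            class = "numalign_stage_config")
}

eval_comparison_accuracy <- function(model, eval_sets) {
  vapply(eval_sets, function(ds) {
    rows <- which(ds$trials$split == "test")
    mean(predict_comparison(model, ds, rows) == ds$trials$label[rows])
  }, numeric(1))
}

#' Train one curriculum stage
#'
#' Optimizes the stage's task head (and the shared trunk) by minibatch
#' Adam on a cross-entropy objective. In the `cross_label` mapping stage,
#' minibatches alternate between cross-label mapping (9-class head, both
#' formats) and nonsymbolic dot comparison (2-class head) at
#' `interleave_ratio`. After every epoch the nonsymbolic, cross-format and
#' symbolic comparison test accuracies are evaluated and recorded. Fully
#' deterministic given (model, stage, datasets, seed).
#'
#' @param model A `numalign_model` (carrying any prior-stage weights).
#' @param stage A [stage_config()].
#' @param datasets Named list: `nonsymbolic`, `cross_format`, `symbolic`
#'   comparison datasets (training draws from the stage's task; all three
#'   test splits are evaluated) and, for the cross-label condition,
#'   `labeling` (the merged labeling dataset).
#' @param seed Integer seed for batch shuffling.
#' @return A `numalign_stage_record`: per-epoch `accuracy` matrix
#'   (epochs x 3 tasks), per-epoch mean `train_loss`, and the trained
#'   `model`.
#' @export
train_stage <- function(model, stage, datasets, seed = 1L) {
  stopifnot(inherits(model, "numalign_model"),
            inherits(stage, "numalign_stage_config"))
  eval_sets <- datasets[c("nonsymbolic", "cross_format", "symbolic")]
  if (any(vapply(eval_sets, is.null, TRUE)))
    stop("`datasets` must contain nonsymbolic, cross_format and symbolic comparison sets",
         call. = FALSE)

  train_task <- switch(stage$stage_id,
                       nonsymbolic = "nonsymbolic",
                       symbolic = "symbolic",
                       mapping = if (stage$mapping_condition == "cross_format")
                         "cross_format" else "cross_label")
  interleaved <- identical(train_task, "cross_label")
  if (interleaved && is.null(datasets$labeling))
    stop("cross-label mapping requires a `labeling` dataset", call. = FALSE)
  primary <- if (interleaved) datasets$labeling else datasets[[train_task]]
  prim_rows <- which(primary$trials$split == "train")
  if (length(prim_rows) == 0L) stop("empty training split", call. = FALSE)

  acc <- matrix(NA_real_, stage$epochs, 3L,
                dimnames = list(NULL, c("nonsymbolic", "cross_format",
                                        "symbolic")))
  losses <- numeric(stage$epochs)
  opt <- adam_init(model$params)
  epoch_seeds <- derive_seeds(seed, stage$epochs)

  for (ep in seq_len(stage$epochs)) {
    order_prim <- with_seed(epoch_seeds[ep], sample(prim_rows))
    batches <- split(order_prim, ceiling(seq_along(order_prim) / stage$batch_size))
    if (interleaved) {
      dot_rows <- which(datasets$nonsymbolic$trials$split == "train")
      order_dot <- with_seed(epoch_seeds[ep] + 1L, sample(dot_rows))
      dot_batches <- split(order_dot,
                           ceiling(seq_along(order_dot) / stage$batch_size))
      n_dot <- max(1L, round(length(batches) / stage$interleave_ratio))
    }
    ep_losses <- c()
    di <- 0L
    for (bi in seq_along(batches)) {
      batch <- labeling_or_comparison_batch(model, primary, batches[[bi]],
                                            interleaved)
      st <- apply_batch(model, opt, batch, stage$lr)
      model <- st$model; opt <- st$opt
      ep_losses <- c(ep_losses, st$loss)
      if (interleaved) {
        # strict alternation: one dot-comparison batch per mapping batch
        di <- di %% length(dot_batches) + 1L
        b2 <- comparison_batch_grads(model, datasets$nonsymbolic,
                                     dot_batches[[di]])
        st <- apply_batch(model, opt, b2, stage$lr)
        model <- st$model; opt <- st$opt
        ep_losses <- c(ep_losses, st$loss)
      }
    }
    losses[ep] <- mean(ep_losses)
    acc[ep, ] <- eval_comparison_accuracy(model, eval_sets)
  }
  structure(list(stage_id = stage$stage_id,
                 mapping_condition = stage$mapping_condition,
                 epochs = stage$epochs, accuracy = acc, train_loss = losses,
                 model = model),
            class = "numalign_stage_record")
}

labeling_or_comparison_batch <- function(model, primary, rows, interleaved) {
  if (interleaved) labeling_batch_grads(model, primary, rows)
  else comparison_batch_grads(model, primary, rows)
}

#' @export
print.numalign_stage_record <- function(x, ...) {
  cat(sprintf("<numalign_stage_record> stage=%s (%s), %d epochs\n",
              x$stage_id, x$mapping_condition, x$epochs))
  cat("final test accuracy:",
      paste(sprintf("%s=%.3f", colnames(x$accuracy),
                    x$accuracy[x$epochs, ]), collapse = ", "), "\n")
  invisible(x)
}

#' Run the full three-stage curriculum
#'
#' Executes nonsymbolic training, mapping training under the requested
#' condition, and symbolic training, carrying the weights forward. At
#' every stage boundary the behavioral analyses (overall and ordered-pair
#' accuracy on all three comparison test sets, generalized pair sets) and
#' representational analyses (mean IPS responses, NRS matrix, rotated MDS,
#' alignment metrics, distance-effect scores) are computed; the forgotten
#' nonsymbolic pairs are computed between the stage-2 and stage-3
#' boundaries.
#'
#' @param datasets As for [train_stage()] (all three comparison sets plus
#'   the merged `labeling` dataset, whose test split also provides the
#'   representational-analysis stimuli).
#' @param condition `"cross_format"` or `"cross_label"`.
#' @param model_cfg A [model_config()]; its seed is combined with `seed`.
#' @param epochs Epochs per stage.
#' @param lr,batch_size Optimizer settings shared by all stages.
#' @param seed Master seed for initialization and batch order.
#' @param stages Which stages to run (prefix of `1:3`), for staged
#'   inspection.
#' @return A `numalign_curriculum` object: per-stage records and
#'   boundary analyses.
#' @export
run_curriculum <- function(datasets, condition = c("cross_format",
                                                   "cross_label"),
                           model_cfg = model_config(), epochs = 20L,
                           lr = 1e-3, batch_size = 32L, seed = 1L,
                           stages = 1:3) {
  condition <- match.arg(condition)
  if (!identical(stages, seq_len(length(stages))))
    stop("`stages` must be a prefix of 1:3", call. = FALSE)
  seeds <- derive_seeds(seed, 4L)
  model_cfg$seed <- seeds[1L]
  model <- build_model(model_cfg)

  stage_cfgs <- list(
    stage_config("nonsymbolic", epochs = epochs, lr = lr,
                 batch_size = batch_size),
    stage_config("mapping", mapping_condition = condition, epochs = epochs,
                 lr = lr, batch_size = batch_size),
    stage_config("symbolic", epochs = epochs, lr = lr,
                 batch_size = batch_size))

  records <- list()
  analyses <- list()
  for (i in stages) {
    rec <- train_stage(model, stage_cfgs[[i]], datasets, seed = seeds[i + 1L])
    model <- rec$model
    records[[i]] <- rec
    analyses[[i]] <- stage_boundary_analysis(model, datasets, stage = i,
                                             condition = condition)
  }
  names(records) <- names(analyses) <-
    c("nonsymbolic", "mapping", "symbolic")[stages]

  forgotten <- NULL
  if (all(c(2, 3) %in% stages))
    forgotten <- forgotten_pairs(analyses$mapping$pair_tables$nonsymbolic,
                                 analyses$symbolic$pair_tables$nonsymbolic)
  structure(list(condition = condition, records = records,
                 analyses = analyses, forgotten_nonsymbolic = forgotten,
                 model = model, seed = seed),
            class = "numalign_curriculum")
}

# All boundary analyses for a trained checkpoint.
stage_boundary_analysis <- function(model, datasets, stage, condition) {
  eval_sets <- datasets[c("nonsymbolic", "cross_format", "symbolic")]
  accuracy <- vapply(eval_sets, function(ds) evaluate_accuracy(model, ds),
                     numeric(1))
  tables <- lapply(names(eval_sets), function(task)
    pair_accuracy(model, eval_sets[[task]], stage = stage))
  names(tables) <- names(eval_sets)

  gen <- list()
  if (stage == 1L)
    gen$generalized_cross_format <- generalized_pairs(tables$cross_format,
                                                      kind = "generalized_cross_format")
  if (stage == 2L)
    gen$generalized_symbolic <- generalized_pairs(tables$symbolic,
                                                  kind = "generalized_symbolic")

  means <- mean_ips_responses(model, datasets$labeling$pools)
  nrs <- nrs_matrix(means)
  emb <- rotate_align(mds_embed(means), numbers = means$n)
  align <- alignment_metrics(emb)
  list(stage = stage, condition = condition, accuracy = accuracy,
       pair_tables = tables, generalized = gen, means = means, nrs = nrs,
       embedding = emb, alignment = align,
       distance_effect = c(
         nonsymbolic = distance_effect_score(nrs, "nonsymbolic"),
         symbolic = distance_effect_score(nrs, "symbolic")))
}

#' @export
print.numalign_curriculum <- function(x, ...) {
  cat(sprintf("<numalign_curriculum> condition=%s, stages run: %s\n",
              x$condition, paste(names(x$records), collapse = ", ")))
  for (nm in names(x$analyses)) {
    a <- x$analyses[[nm]]
    cat(sprintf("  after %-11s acc ns=%.3f xf=%.3f sym=%.3f | align r=%.3f d=%.3f\n",
                nm, a$accuracy[1], a$accuracy[2], a$accuracy[3],
                a$alignment$correlation, a$alignment$norm_distance))
  }
  invisible(x)
}
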
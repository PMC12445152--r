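# Optimization and stage training: loss decrease, determinism,
# head independence under updates, record bookkeeping, interleaving.

test_that("one Adam step on a batch strictly decreases that batch's loss", {
  w <- tiny_world()
  model <- tiny_model(seed = 61L)
  rows <- which(w$nonsymbolic$trials$split == "train")[1:16]
  opt <- adam_init(model$params)
  before <- comparison_batch_grads(model, w$nonsymbolic, rows)
  st <- apply_batch(model, opt, before, lr = 1e-3)
  after <- comparison_batch_grads(st$model, w$nonsymbolic, rows)
  expect_lt(after$loss, before$loss)
})

test_that("gradients of one head's loss never reach the other head", {
  w <- tiny_world()
  model <- tiny_model(seed = 62L)
  rows <- which(w$nonsymbolic$trials$split == "train")[1:16]
  rows_l <- which(w$labeling$trials$split == "train")[1:16]
  # comparison loss: labeling head untouched (fresh optimizer state)
  st <- apply_batch(model, adam_init(model$params),
                    comparison_batch_grads(model, w$nonsymbolic, rows), 1e-3)
  expect_identical(st$model$params$heads$labeling,
                   model$params$heads$labeling)
  expect_false(identical(st$model$params$heads$comparison,
                         model$params$heads$comparison))
  # labeling loss: comparison head untouched (fresh optimizer state)
  st2 <- apply_batch(model, adam_init(model$params),
                     labeling_batch_grads(model, w$labeling, rows_l), 1e-3)
  expect_identical(st2$model$params$heads$comparison,
                   model$params$heads$comparison)
  expect_false(identical(st2$model$params$heads$labeling,
                         model$params$heads$labeling))
  # the raw gradients themselves are exactly zero on the other head
  g <- comparison_batch_grads(model, w$nonsymbolic, rows)$grads
  expect_true(all(g$heads$labeling$W == 0) && all(g$heads$labeling$b == 0))
})

test_that("train_stage records are complete, deterministic and improving", {
  w <- tiny_world()
  rec <- tiny_trained_record()
  expect_s3_class(rec, "numalign_stage_record")
  expect_identical(dim(rec$accuracy), c(2L, 3L))
  expect_identical(colnames(rec$accuracy),
                   c("nonsymbolic", "cross_format", "symbolic"))
  expect_length(rec$train_loss, 2L)
  expect_true(all(rec$accuracy >= 0 & rec$accuracy <= 1))
  # learning happened: the trained task ends clearly above chance (the
  # epoch-over-epoch improvement property is checked at desk scale, where
  # it is not washed out by tiny-sample noise)
  expect_gt(rec$accuracy[2L, "nonsymbolic"], 0.6)
  expect_lt(rec$train_loss[2L], rec$train_loss[1L])
  # full determinism: identical seeds and configs -> identical curves
  rec2 <- train_stage(tiny_model(), stage_config("nonsymbolic", epochs = 2L,
                                                 lr = 2e-3, batch_size = 32L),
                      w, seed = 31L)
  expect_identical(rec2$train_loss, rec$train_loss)
  expect_identical(rec2$accuracy, rec$accuracy)
  expect_identical(rec2$model$params, rec$model$params)
})

test_that("stage configuration validates mapping-condition pairing", {
  expect_error(stage_config("nonsymbolic", "cross_label"), "mapping stage")
  expect_error(stage_config("mapping"), "mapping stage")
  expect_s3_class(stage_config("mapping", "cross_format", epochs = 1L),
                  "numalign_stage_config")
  expect_error(stage_config("symbolic", epochs = 0L), "at least 1")
})

test_that("the cross-label mapping stage interleaves and trains both heads", {
  w <- tiny_world()
  model0 <- tiny_model(seed = 63L)
  st <- stage_config("mapping", "cross_label", epochs = 1L, lr = 1e-3,
                     batch_size = 32L)
  rec <- train_stage(model0, st, w, seed = 64L)
  # both decoders moved: labeling by the mapping batches, comparison by the
  # interleaved dot-comparison batches
  expect_false(identical(rec$model$params$heads$labeling,
                         model0$params$heads$labeling))
  expect_false(identical(rec$model$params$heads$comparison,
                         model0$params$heads$comparison))
  # missing labeling dataset is a configuration error
  expect_error(train_stage(model0, st, w[c("nonsymbolic", "cross_format",
                                           "symbolic")], seed = 1L),
               "labeling")
})
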
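# Orchestrator: profiles, one-call runs, artifact writing, condition
# comparison (all at an overridden miniature scale).

mini_config <- function(seed = 7L, out_dir = NULL) {
  experiment_config("desk", seed = seed, out_dir = out_dir,
                    stimuli = list(canvas_size = 32L, upsample = 1L,
                                   n_param_sets = 3L, images_per_set = 6L,
                                   train_per_set = 4L,
                                   images_per_numerosity = 18L,
                                   train_per_numerosity = 12L),
                    datasets = list(n_train = 180L, n_test = 90L),
                    network = list(channels = c(V1 = 4L, V2 = 6L, V3 = 6L,
                                                IPS = 8L)),
                    curriculum = list(epochs = 1L))
}

test_that("profiles expose the documented scales and accept overrides", {
  desk <- experiment_config("desk")
  expect_identical(desk$stimuli$canvas_size, 64L)
  expect_identical(desk$curriculum$epochs, 8L)
  paper <- experiment_config("paper")
  expect_identical(paper$stimuli$canvas_size, 224L)
  expect_identical(paper$stimuli$n_param_sets, 50L)
  expect_identical(paper$datasets$n_train, 4500L)
  expect_identical(paper$curriculum$epochs, 20L)
  over <- experiment_config("desk", curriculum = list(epochs = 3L))
  expect_identical(over$curriculum$epochs, 3L)
  expect_identical(over$curriculum$lr, 1e-3)
})

test_that("a miniature run completes both conditions with full reports", {
  out <- file.path(tempdir(), "numalign-mini")
  res <- run_experiment(mini_config(out_dir = out))
  expect_s3_class(res, "numalign_experiment")
  expect_identical(names(res$conditions), c("cross_format", "cross_label"))
  for (run in res$conditions)
    expect_identical(names(run$analyses),
                     c("nonsymbolic", "mapping", "symbolic"))
  # artifact tree: every manifest entry exists on disk
  manifest <- read.csv(file.path(out, "manifest.csv"))
  expect_true(all(file.exists(manifest$file)))
  # report cross-reference: summary accuracy equals its source CSV
  log <- read.csv(file.path(out, "cross_format", "accuracy_log.csv"))
  final <- log[log$stage == "mapping" & log$epoch == max(log$epoch[log$stage == "mapping"]), ]
  expect_equal(unname(final$symbolic),
               unname(res$conditions$cross_format$records$mapping$accuracy[
                 nrow(res$conditions$cross_format$records$mapping$accuracy),
                 "symbolic"]))
  align <- jsonlite::read_json(file.path(out, "cross_format",
                                         "mapping_alignment.json"))
  expect_equal(align$correlation,
               res$conditions$cross_format$analyses$mapping$alignment$correlation,
               tolerance = 1e-9)
  assign("mini_result", res, envir = .tiny)
})

test_that("reruns of the same config reproduce the metrics exactly", {
  res <- get("mini_result", envir = .tiny)
  res2 <- run_experiment(mini_config())
  expect_identical(
    res2$conditions$cross_label$records$mapping$accuracy,
    res$conditions$cross_label$records$mapping$accuracy)
  expect_equal(res2$conditions$cross_format$analyses$symbolic$alignment,
               res$conditions$cross_format$analyses$symbolic$alignment)
})

test_that("compare_conditions tabulates deltas and orderings consistently", {
  res <- get("mini_result", envir = .tiny)
  a <- res$conditions$cross_format; b <- res$conditions$cross_label
  cmp <- compare_conditions(a, b)
  expect_identical(nrow(cmp$metrics), 2L)
  # identical inputs -> zero deltas
  self <- compare_conditions(a, a)
  expect_true(all(self$deltas == 0))
  # deltas equal independent subtraction of the reported values
  expect_equal(unname(cmp$deltas["correlation"]),
               a$analyses$mapping$alignment$correlation -
               b$analyses$mapping$alignment$correlation)
  expect_identical(unname(cmp$orderings["correlation_a_gt_b"]),
                   cmp$deltas[["correlation"]] > 0)
  short <- run_curriculum(res$datasets, "cross_format",
                          model_cfg = tiny_model_config(), epochs = 1L,
                          seed = 1L, stages = 1L)
  expect_error(compare_conditions(a, short), "different stages")
})
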
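# Network module: seeded initialization, shape/determinism contracts,
# end-to-end gradient correctness, head independence, prediction rules.

test_that("seeded initialization is reproducible and shapes are declared", {
  m1 <- tiny_model(seed = 33L)
  m2 <- tiny_model(seed = 33L)
  expect_identical(m1$params, m2$params)
  m3 <- tiny_model(seed = 34L)
  expect_false(identical(m1$params, m3$params))
  expect_identical(m1$config$ips_dim, 8L)

  zero <- structure(
    list(pixels = matrix(0, 32, 32), numerosity = 1L,
         format = "nonsymbolic", split = "test", provenance = list()),
    class = "numalign_stimulus")
  v <- ips_response(m1, zero)
  expect_length(v, m1$config$ips_dim)
  expect_true(all(is.finite(v)))
})

test_that("ips_response is deterministic, head-independent and non-degenerate", {
  w <- tiny_world()
  model <- tiny_trained_model()
  img <- w$pools$nonsymbolic$test$images[[1]]
  v1 <- ips_response(model, img)
  expect_identical(v1, ips_response(model, img))
  # trunk sharing: decoder weights do not affect the IPS feature
  tweaked <- model
  tweaked$params$heads$labeling$W <- tweaked$params$heads$labeling$W * 3 + 1
  tweaked$params$heads$comparison$W <- tweaked$params$heads$comparison$W * -2
  expect_identical(v1, ips_response(tweaked, img))
  # non-degeneracy on a trained checkpoint
  img2 <- w$pools$symbolic$test$images[[5]]
  expect_false(isTRUE(all.equal(v1, ips_response(model, img2))))
})

test_that("whole-network gradients match finite differences", {
  w <- tiny_world()
  model <- tiny_model(seed = 41L)
  # move biases off zero: with all-zero biases, blank image regions put
  # preactivations exactly on the ReLU kink, where the finite-difference
  # quotient and the ReLU'(0) = 0 convention legitimately disagree
  for (nm in names(model$params$blocks)) {
    b <- model$params$blocks[[nm]]$b
    model$params$blocks[[nm]]$b <- 0.05 + 0.01 * seq_along(b)
  }
  rows <- which(w$cross_format$trials$split == "train")[1:6]
  got <- comparison_batch_grads(model, w$cross_format, rows)
  loss_at <- function(m) comparison_batch_grads(m, w$cross_format, rows)$loss
  eps <- 1e-5
  probe <- list(c("blocks", "V1", "W", 3L), c("blocks", "V3", "W", 10L),
                c("blocks", "IPS", "b", 2L), c("heads", "comparison", "W", 5L))
  for (p in probe) {
    m1 <- model; m2 <- model
    m1$params[[p[1]]][[p[2]]][[p[3]]][[as.integer(p[4])]] <-
      m1$params[[p[1]]][[p[2]]][[p[3]]][[as.integer(p[4])]] + eps
    m2$params[[p[1]]][[p[2]]][[p[3]]][[as.integer(p[4])]] <-
      m2$params[[p[1]]][[p[2]]][[p[3]]][[as.integer(p[4])]] - eps
    numeric_grad <- (loss_at(m1) - loss_at(m2)) / (2 * eps)
    analytic <- got$grads[[p[1]]][[p[2]]][[p[3]]][[as.integer(p[4])]]
    expect_equal(analytic, numeric_grad, tolerance = 1e-4)
  }
  # labeling head path too
  rows_l <- which(w$labeling$trials$split == "train")[1:6]
  got_l <- labeling_batch_grads(model, w$labeling, rows_l)
  m1 <- model
  m1$params$heads$labeling$W[2, 3] <- m1$params$heads$labeling$W[2, 3] + eps
  m2 <- model
  m2$params$heads$labeling$W[2, 3] <- m2$params$heads$labeling$W[2, 3] - eps
  numeric_grad <- (labeling_batch_grads(m1, w$labeling, rows_l)$loss -
                   labeling_batch_grads(m2, w$labeling, rows_l)$loss) / (2 * eps)
  expect_equal(got_l$grads$heads$labeling$W[2, 3], numeric_grad,
               tolerance = 1e-4)
})

test_that("a recurrent block changes shape bookkeeping but stays correct", {
  cfg <- model_config(blocks = list(
    V1 = list(channels = 4, stride = 2, recurrence = 2),
    V2 = list(channels = 4, stride = 2, recurrence = 1),
    V3 = list(channels = 4, stride = 2, recurrence = 1),
    IPS = list(channels = 6, stride = 2, recurrence = 2)), seed = 3L)
  model <- build_model(cfg)
  expect_true(!is.null(model$params$blocks$V1$Wr))
  for (nm in names(model$params$blocks)) {
    b <- model$params$blocks[[nm]]$b
    model$params$blocks[[nm]]$b <- 0.05 + 0.01 * seq_along(b)
    if (!is.null(model$params$blocks[[nm]]$br))
      model$params$blocks[[nm]]$br <- 0.03 + 0.01 * seq_along(b)
  }
  w <- tiny_world()
  rows <- which(w$nonsymbolic$trials$split == "train")[1:4]
  got <- comparison_batch_grads(model, w$nonsymbolic, rows)
  loss_at <- function(m) comparison_batch_grads(m, w$nonsymbolic, rows)$loss
  eps <- 1e-5
  m1 <- model; m2 <- model
  m1$params$blocks$V1$Wr[7] <- m1$params$blocks$V1$Wr[7] + eps
  m2$params$blocks$V1$Wr[7] <- m2$params$blocks$V1$Wr[7] - eps
  expect_equal(got$grads$blocks$V1$Wr[7],
               (loss_at(m1) - loss_at(m2)) / (2 * eps), tolerance = 1e-4)
})

test_that("untrained comparison accuracy sits at chance; predictions deterministic", {
  w <- tiny_world()
  model <- tiny_model(seed = 55L)
  rows <- which(w$nonsymbolic$trials$split == "test")
  pred <- predict_comparison(model, w$nonsymbolic, rows)
  expect_identical(pred, predict_comparison(model, w$nonsymbolic, rows))
  acc <- mean(pred == w$nonsymbolic$trials$label[rows])
  expect_gt(acc, 0.35)
  expect_lt(acc, 0.65)
})

test_that("a stub head wired to summed IPS activation matches the rule oracle", {
  w <- tiny_world()
  model <- tiny_trained_model()
  d <- model$config$ips_dim
  model$params$heads$comparison$W <- rbind(c(rep(1, d), rep(-1, d)),
                                           c(rep(-1, d), rep(1, d)))
  model$params$heads$comparison$b <- c(0, 0)
  rows <- which(w$cross_format$trials$split == "test")[1:40]
  pred <- predict_comparison(model, w$cross_format, rows)
  imgs <- comparison_trial_images(w$cross_format, rows)
  oracle <- vapply(seq_along(rows), function(i) {
    sl <- sum(ips_response(model, imgs$left[[i]]))
    sr <- sum(ips_response(model, imgs$right[[i]]))
    if (sl > sr) "left" else "right"
  }, "")
  expect_identical(pred, oracle)
})

test_that("predict_label stays in 1..9 and a memorized batch is recovered", {
  w <- tiny_world()
  imgs <- labeling_trial_images(w$labeling, which(w$labeling$trials$split == "train")[1:10])
  model <- tiny_model(seed = 77L)
  expect_true(all(predict_label(model, imgs) %in% 1:9))
  # overfit-one-batch sanity: memorize 10 images
  small <- w$labeling
  keep <- which(small$trials$split == "train")[1:10]
  opt <- adam_init(model$params)
  for (i in 1:150) {
    b <- labeling_batch_grads(model, small, keep)
    st <- apply_batch(model, opt, b, lr = 3e-3)
    model <- st$model; opt <- st$opt
  }
  expect_identical(predict_label(model, imgs),
                   small$trials$label[keep])
})

test_that("checkpoints round-trip and refuse mismatched configs", {
  model <- tiny_trained_model()
  path <- tempfile(fileext = ".rds")
  save_checkpoint(model, path)
  back <- load_checkpoint(path, config = model$config)
  expect_identical(back$params, model$params)
  other <- tiny_model_config(seed = 999L)
  expect_error(load_checkpoint(path, config = other), "does not match")
})

test_that("composite pairing runs end to end on mixed canvases", {
  w <- tiny_world()
  cfg <- tiny_model_config(seed = 8L)
  cfg$pairing_mode <- "composite"
  model <- build_model(cfg)
  rows <- which(w$cross_format$trials$split == "test")[1:8]
  pred <- predict_comparison(model, w$cross_format, rows)
  expect_length(pred, 8L)
  got <- comparison_batch_grads(model, w$cross_format, rows)
  expect_true(is.finite(got$loss))
})
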
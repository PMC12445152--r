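# Optimization: softmax cross-entropy losses on either decoder, Adam
# updates, and single training steps over comparison or labeling batches.

adam_init <- function(params) {
  list(m = nested_map(params, function(p) p * 0),
       v = nested_map(params, function(p) p * 0), t = 0L)
}

adam_update <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                        beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- nested_map2(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- nested_map2(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  bc1 <- 1 - beta1^state$t; bc2 <- 1 - beta2^state$t
  step <- nested_map2(state$m, state$v, function(m, v)
    lr * (m / bc1) / (sqrt(v / bc2) + eps))
  list(params = nested_map2(params, step, `-`), state = state)
}

# Cross-entropy of column-softmax logits against integer classes (1-based);
# returns loss and dlogits (already divided by batch size).
softmax_xent <- function(logits, classes) {
  n <- ncol(logits)
  probs <- softmax_cols(logits)
  picked <- probs[cbind(classes, seq_len(n))]
  loss <- -mean(log(pmax(picked, 1e-12)))
  dl <- probs
  dl[cbind(classes, seq_len(n))] <- dl[cbind(classes, seq_len(n))] - 1
  list(loss = loss, dlogits = dl / n)
}

zero_grads_like <- function(params) nested_map(params, function(p) p * 0)

# One forward/backward over a comparison batch. Returns loss and the full
# gradient structure (all heads present; untouched head gets zeros).
comparison_batch_grads <- function(model, dataset, rows) {
  cf <- comparison_forward(model, dataset, rows, keep_cache = TRUE)
  classes <- ifelse(dataset$trials$label[rows] == "left", 1L, 2L)
  logits <- head_logits(model, "comparison", cf$feats)
  ce <- softmax_xent(logits, classes)
  par <- model$params$heads$comparison
  gW <- ce$dlogits %*% t(cf$feats)
  gb <- rowSums(ce$dlogits)
  gfeat <- t(par$W) %*% ce$dlogits
  if (model$config$pairing_mode == "siamese") {
    d <- model$config$ips_dim; n <- cf$n
    g_ips <- cbind(gfeat[seq_len(d), , drop = FALSE],
                   gfeat[d + seq_len(d), , drop = FALSE])
  } else g_ips <- gfeat
  gblocks <- backward_images(model, cf$fwd, g_ips)
  grads <- list(blocks = gblocks,
                heads = list(comparison = list(W = gW, b = gb),
                             labeling = zero_grads_like(model$params$heads$labeling)))
  list(loss = ce$loss, grads = grads)
}

labeling_batch_grads <- function(model, dataset, rows) {
  imgs <- labeling_trial_images(dataset, rows)
  fwd <- forward_images(model, imgs, keep_cache = TRUE)
  classes <- dataset$trials$label[rows]
  logits <- head_logits(model, "labeling", fwd$ips)
  ce <- softmax_xent(logits, classes)
  par <- model$params$heads$labeling
  gW <- ce$dlogits %*% t(fwd$ips)
  gb <- rowSums(ce$dlogits)
  g_ips <- t(par$W) %*% ce$dlogits
  gblocks <- backward_images(model, fwd, g_ips)
  grads <- list(blocks = gblocks,
                heads = list(comparison = zero_grads_like(model$params$heads$comparison),
                             labeling = list(W = gW, b = gb)))
  list(loss = ce$loss, grads = grads)
}

apply_batch <- function(model, opt, batch, lr) {
  if (!is.finite(batch$loss))
    stop("training aborted: non-finite loss (diverged)", call. = FALSE)
  up <- adam_update(model$params, batch$grads, opt, lr = lr)
  model$params <- up$params
  list(model = model, opt = up$state, loss = batch$loss)
}
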
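# Independent oracles (deliberately not sharing code with the package):
# flood-fill component labeling, shoelace polygon area, pixel-coordinate
# convex hull, and a small cached "tiny world" of stimuli and datasets.

# Connected foreground components under 4-connectivity.
count_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  k <- 0L
  for (i in seq_len(nrow(mask))) for (j in seq_len(ncol(mask))) {
    if (mask[i, j] > 0 && lab[i, j] == 0L) {
      k <- k + 1L
      queue <- list(c(i, j)); lab[i, j] <- k
      while (length(queue)) {
        p <- queue[[1L]]; queue <- queue[-1L]
        for (d in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))) {
          r <- p[1L] + d[1L]; c <- p[2L] + d[2L]
          if (r >= 1 && r <= nrow(mask) && c >= 1 && c <= ncol(mask) &&
              mask[r, c] > 0 && lab[r, c] == 0L) {
            lab[r, c] <- k; queue <- c(queue, list(c(r, c)))
          }
        }
      }
    }
  }
  k
}

shoelace <- function(x, y) {
  abs(sum(x * c(y[-1L], y[1L]) - c(x[-1L], x[1L]) * y)) / 2
}

# Convex hull area of the foreground pixel coordinates.
pixel_hull_area <- function(mask) {
  idx <- which(mask > 0, arr.ind = TRUE)
  h <- grDevices::chull(idx[, 1L], idx[, 2L])
  shoelace(idx[h, 1L], idx[h, 2L])
}

# Small world shared across test files: 32 px dot canvas, 28 px numerals,
# compact comparison/labeling datasets, and a tiny model configuration.
.tiny <- new.env(parent = emptyenv())

tiny_world <- function() {
  if (!exists("world", envir = .tiny)) {
    dots <- generate_dot_dataset(4L, 6L, 4L, seed = 11L, canvas_size = 32L)
    numerals <- generate_numeral_dataset(24L, 16L, seed = 12L, upsample = 1L)
    pools <- make_pools(dots, numerals)
    world <- list(
      dots = dots, numerals = numerals, pools = pools,
      nonsymbolic = build_comparison_dataset("nonsymbolic", 240L, 120L,
                                             pools, seed = 13L),
      cross_format = build_comparison_dataset("cross_format", 240L, 120L,
                                              pools, seed = 14L),
      symbolic = build_comparison_dataset("symbolic", 240L, 120L, pools,
                                          seed = 15L),
      labeling = build_labeling_dataset(c("nonsymbolic", "symbolic"), pools,
                                        seed = 16L))
    assign("world", world, envir = .tiny)
  }
  get("world", envir = .tiny)
}

tiny_model_config <- function(seed = 21L) {
  model_config(blocks = list(
    V1 = list(channels = 4, stride = 2, recurrence = 1),
    V2 = list(channels = 6, stride = 2, recurrence = 1),
    V3 = list(channels = 6, stride = 2, recurrence = 1),
    IPS = list(channels = 8, stride = 2, recurrence = 1)),
    seed = seed)
}

tiny_model <- function(seed = 21L) build_model(tiny_model_config(seed))

# A model briefly trained on tiny-world dot comparison (cached).
tiny_trained_model <- function() {
  if (!exists("trained", envir = .tiny)) {
    w <- tiny_world()
    rec <- train_stage(tiny_model(), stage_config("nonsymbolic", epochs = 2L,
                                                  lr = 2e-3, batch_size = 32L),
                       w, seed = 31L)
    assign("trained", rec$model, envir = .tiny)
    assign("trained_record", rec, envir = .tiny)
  }
  get("trained", envir = .tiny)
}

tiny_trained_record <- function() {
  tiny_trained_model()
  get("trained_record", envir = .tiny)
}

# Synthetic 18-point mean-response sets with a known low-dimensional
# structure, standing in for trained-model IPS means.
synthetic_means <- function(spread = 0, seed = 5L, d = 8L) {
  stopifnot(d >= 3L)
  n <- rep(1:9, 2L)
  f <- rep(c("nonsymbolic", "symbolic"), each = 9L)
  base <- cbind(n, ifelse(f == "symbolic", spread, -spread),
                0.3 * (n - 5)^2 / 8)
  M <- withr_seeded(seed, {
    Q <- qr.Q(qr(matrix(rnorm(d * d), d, d)))[, 1:3]
    base %*% t(Q)
  })
  rownames(M) <- paste0(ifelse(f == "symbolic", "s", "ns"), n)
  structure(list(means = M, n = n, format = f, count = rep(1L, 18L)),
            class = "numalign_means")
}

# Seeded evaluation without touching the global RNG stream permanently.
withr_seeded <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

random_rotation <- function(d, seed) {
  withr_seeded(seed, {
    Q <- qr.Q(qr(matrix(rnorm(d * d), d, d)))
    if (det(Q) < 0) Q[, 1L] <- -Q[, 1L]
    Q
  })
}

# Manual pair-accuracy table construction for boundary-case tests.
manual_pair_table <- function(acc_fun, task = "nonsymbolic", stage = NA) {
  cells <- subset(expand.grid(left_n = 1:9, right_n = 1:9),
                  left_n != right_n)
  out <- data.frame(left_n = cells$left_n, right_n = cells$right_n,
                    accuracy = mapply(acc_fun, cells$left_n, cells$right_n),
                    count = 10L, row.names = NULL)
  structure(out, class = c("numalign_pair_table", "data.frame"),
            task = task, stage = stage)
}
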
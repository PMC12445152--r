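# Representational analyses: NRS formula oracles, MDS embedding
# fidelity, rotation optimality, alignment closed forms, invariances.

means_from_matrix <- function(M, n = rep(1:9, 2),
                              f = rep(c("nonsymbolic", "symbolic"), each = 9)) {
  structure(list(means = M, n = n, format = f,
                 count = rep(1L, nrow(M))), class = "numalign_means")
}

test_that("NRS matches the hand-computed 1-D toy and its invariants", {
  M <- matrix(c(0, 1, 3), ncol = 1)
  S <- nrs_matrix(means_from_matrix(M, n = 1:3, f = rep("nonsymbolic", 3)))
  expect_equal(S[1, 2], 1 - 1 / 3)
  expect_equal(S[1, 3], 0)
  expect_equal(S[2, 3], 1 - 2 / 3)
  expect_true(isSymmetric(unclass(S)))
  expect_equal(unname(diag(S)), rep(1, 3))
  expect_equal(min(S), 0)
  expect_true(all(S >= 0 & S <= 1))
  expect_error(nrs_matrix(means_from_matrix(matrix(1, 3, 2), 1:3,
                                            rep("nonsymbolic", 3))),
               "degenerate")
})

test_that("NRS invariants hold on a trained model's mean responses", {
  w <- tiny_world()
  means <- mean_ips_responses(tiny_trained_model(), w$pools)
  expect_identical(dim(means$means), c(18L, 8L))
  expect_identical(means$count,
                   vapply(seq_len(18), function(k)
                     length(w$pools[[means$format[k]]]$test$by_n[[means$n[k]]]),
                     1L))
  S <- nrs_matrix(means)
  expect_true(isSymmetric(unclass(S)))
  expect_equal(unname(diag(S)), rep(1, 18))
  expect_equal(min(S), 0)
  expect_true(all(S >= 0 & S <= 1))
})

test_that("mean responses are elementwise averages (arithmetic oracle)", {
  w <- tiny_world()
  model <- tiny_trained_model()
  means <- mean_ips_responses(model, w$pools)
  idx <- w$pools$symbolic$test$by_n[[4]]
  by_hand <- rowMeans(vapply(w$pools$symbolic$test$images[idx],
                             function(i) ips_response(model, i),
                             numeric(model$config$ips_dim)))
  expect_equal(unname(means$means[means$format == "symbolic" &
                                  means$n == 4, ]), unname(by_hand))
})

test_that("MDS reproduces exactly embeddable configurations", {
  sm <- synthetic_means(spread = 2, seed = 9)
  emb <- mds_embed(sm, dim = 3)
  expect_lt(emb$stress, 1e-6)
  expect_equal(as.matrix(dist(emb$coords)), as.matrix(dist(sm$means)),
               tolerance = 1e-6)
  # scale equivariance of metric MDS
  sm2 <- sm; sm2$means <- sm$means * 2
  emb2 <- mds_embed(sm2, dim = 3)
  expect_equal(as.matrix(dist(emb2$coords)),
               2 * as.matrix(dist(emb$coords)), tolerance = 1e-5)
})

test_that("MDS recovers a hand-computed tetrahedron", {
  # regular tetrahedron, edge sqrt(8): vertices of a cube diagonal set
  V <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  D <- as.matrix(dist(V))
  expect_true(all(abs(D[upper.tri(D)] - sqrt(8)) < 1e-12))
  emb <- mds_embed(structure(D, n = 1:4, format = rep("nonsymbolic", 4)),
                   dim = 3)
  expect_equal(as.matrix(dist(emb$coords)), D, tolerance = 1e-6)
  expect_error(mds_embed(structure(D, n = 1:4,
                                   format = rep("nonsymbolic", 4)), dim = 4),
               "at most")
})

test_that("rotation puts the number line first and preserves geometry", {
  sm <- synthetic_means(spread = 1.5, seed = 13)
  emb <- rotate_align(mds_embed(sm, dim = 3))
  R <- emb$rotation
  expect_equal(R %*% t(R), diag(3), tolerance = 1e-8)
  expect_equal(as.matrix(dist(emb$rotated_coords)),
               as.matrix(dist(emb$coords)), tolerance = 1e-8)
  r1 <- cor(emb$rotated_first_dim, emb$n)
  expect_gte(r1, 0)
  # brute force: no random unit direction correlates better
  dirs <- withr_seeded(77, matrix(rnorm(3 * 1000), 1000, 3))
  dirs <- dirs / sqrt(rowSums(dirs^2))
  rand_cors <- abs(as.vector(cor(emb$coords %*% t(dirs), emb$n)))
  expect_true(all(r1 >= rand_cors - 1e-10))
})

test_that("points already ordered along axis 1 need no rotation", {
  X <- cbind(rep(1:9, 2), rep(c(-0.5, 0.5), each = 9), 0)
  D <- as.matrix(dist(X))
  emb <- mds_embed(structure(D, n = rep(1:9, 2),
                             format = rep(c("nonsymbolic", "symbolic"),
                                          each = 9)), dim = 3)
  emb <- rotate_align(emb)
  expect_gt(cor(emb$rotated_first_dim, emb$n), 0.999)
})

test_that("alignment metrics match their closed forms", {
  make_emb <- function(rs, rn) {
    structure(list(coords = NULL, stress = 0, converged = TRUE,
                   n = rep(1:9, 2),
                   format = rep(c("nonsymbolic", "symbolic"), each = 9),
                   rotation = diag(3),
                   rotated_first_dim = c(rn, rs)),
              class = "numalign_mds")
  }
  # perfect alignment
  m <- alignment_metrics(make_emb(1:9, 1:9))
  expect_equal(m$correlation, 1)
  expect_equal(m$norm_distance, 0)
  # anti-alignment on a centered number line
  cn <- 1:9 - 5
  expect_equal(alignment_metrics(make_emb(-cn, cn))$correlation, -1)
  # constant offset: correlation 1, distance |c| / 8
  m2 <- alignment_metrics(make_emb(1:9 + 2, 1:9))
  expect_equal(m2$correlation, 1)
  expect_equal(m2$norm_distance, 2 / 8)
  expect_error(alignment_metrics(make_emb(1:9, rep(1, 9))), "degenerate")
})

test_that("alignment pipeline is invariant to global orthonormal transforms", {
  sm <- synthetic_means(spread = 1, seed = 21)
  base <- alignment_metrics(rotate_align(mds_embed(sm, dim = 3)))
  for (s in 1:3) {
    Q <- random_rotation(ncol(sm$means), seed = 100 + s)
    rot <- sm; rot$means <- sm$means %*% Q
    m <- alignment_metrics(rotate_align(mds_embed(rot, dim = 3)))
    expect_equal(m$correlation, base$correlation, tolerance = 1e-6)
    expect_equal(m$norm_distance, base$norm_distance, tolerance = 1e-6)
    # NRS is exactly invariant (distances unchanged)
    expect_equal(unclass(nrs_matrix(rot)), unclass(nrs_matrix(sm)),
                 tolerance = 1e-10)
  }
})

test_that("distance effect score matches rank oracles", {
  mk_nrs <- function(S, n, f) structure(S, class = c("numalign_nrs", "matrix"),
                                        n = n, format = f)
  n <- 1:9
  S <- 1 - abs(outer(n, n, `-`)) / 8
  diag(S) <- 1
  expect_equal(distance_effect_score(mk_nrs(S, n, rep("nonsymbolic", 9)),
                                     "nonsymbolic"), -1)
  S0 <- matrix(0.5, 9, 9); diag(S0) <- 1
  expect_equal(distance_effect_score(mk_nrs(S0, n, rep("nonsymbolic", 9)),
                                     "nonsymbolic"), 0)
  # 3-number toy against brute-force rank computation
  S3 <- rbind(c(1, .9, .2), c(.9, 1, .6), c(.2, .6, 1))
  got <- distance_effect_score(mk_nrs(S3, 1:3, rep("symbolic", 3)),
                               "symbolic")
  expect_equal(got, cor(c(1, 2, 1), c(.9, .2, .6), method = "spearman"))
})
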
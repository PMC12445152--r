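# Representational analyses of the IPS layer: mean responses per
# (number, format), the neural representational similarity (NRS) matrix,
# metric MDS with rotational alignment to the number line, and the
# symbolic/nonsymbolic alignment metrics.

#' Mean IPS responses per (number, format)
#'
#' Averages the IPS-layer response over the test-split labeling stimuli of
#' each number 1-9 and format, yielding the 18 mean vectors on which all
#' representational analyses operate.
#'
#' @param model A `numalign_model`.
#' @param pools A [make_pools()] object.
#' @param split Stimulus split to average over (default test).
#' @return A `numalign_means` object: `means` (18 x ips_dim matrix, rows
#'   ordered nonsymbolic 1-9 then symbolic 1-9), `n`, `format`, `count`.
#' @export
mean_ips_responses <- function(model, pools, split = "test") {
  stopifnot(inherits(pools, "numalign_pools"))
  fmts <- c("nonsymbolic", "symbolic")
  means <- matrix(NA_real_, 18L, model$config$ips_dim)
  n_of <- integer(18L); f_of <- character(18L); counts <- integer(18L)
  k <- 0L
  for (f in fmts) {
    for (n in 1:9) {
      k <- k + 1L
      idx <- pools[[f]][[split]]$by_n[[n]]
      if (length(idx) == 0L)
        stop(sprintf("no %s stimuli of numerosity %d in split %s", f, n,
                     split), call. = FALSE)
      ips <- forward_images(model, pools[[f]][[split]]$images[idx])$ips
      means[k, ] <- rowMeans(ips)
      n_of[k] <- n; f_of[k] <- f; counts[k] <- length(idx)
    }
  }
  rownames(means) <- paste0(ifelse(f_of == "symbolic", "s", "ns"), n_of)
  structure(list(means = means, n = n_of, format = f_of, count = counts),
            class = "numalign_means")
}

as_means <- function(x) {
  if (inherits(x, "numalign_means")) return(x)
  stop("expected a `numalign_means` object", call. = FALSE)
}

#' Neural representational similarity matrix
#'
#' Similarity between two mean responses is one minus their Euclidean
#' distance normalized by the globally largest pairwise distance:
#' `1 - ||x(n,f) - x(n',f')|| / max ||x(p,g) - x(p',g')||`. The result is
#' symmetric with unit diagonal, values in \[0,1\], and attains 0 exactly
#' at the globally most distant pair.
#'
#' @param means A [mean_ips_responses()] object (or any matrix of row
#'   vectors with one row per condition, with `n`/`format` attributes
#'   supplied by the `numalign_means` wrapper).
#' @return A `numalign_nrs`: the 18 x 18 similarity matrix with `n` and
#'   `format` attributes.
#' @export
nrs_matrix <- function(means) {
  m <- as_means(means)
  D <- as.matrix(dist(m$means))
  dmax <- max(D)
  if (dmax == 0)
    stop("degenerate input: all mean responses identical", call. = FALSE)
  S <- 1 - D / dmax
  structure(S, class = c("numalign_nrs", class(S)), n = m$n,
            format = m$format)
}

#' Metric multidimensional scaling of the mean responses
#'
#' Embeds the 18 mean responses into `dim` dimensions by metric
#' stress majorization (SMACOF) on the precomputed pairwise Euclidean
#' distances, initialized from classical (Torgerson) scaling coordinates
#' so the result is deterministic. Reports Kruskal stress-1.
#'
#' @param means A [mean_ips_responses()] object, or a distance matrix.
#' @param dim Embedding dimension (3, as used by the alignment analyses).
#' @param max_iter,tol Majorization iteration cap and relative stress
#'   tolerance; on hitting the cap a warning flags the best-found
#'   solution.
#' @return A `numalign_mds`: `coords` (18 x dim), `stress`, `converged`,
#'   plus the point metadata. Rotation fields are filled by
#'   [rotate_align()].
#' @export
mds_embed <- function(means, dim = 3L, max_iter = 3000L, tol = 1e-9) {
  if (inherits(means, "numalign_means")) {
    D <- as.matrix(dist(means$means))
    meta <- list(n = means$n, format = means$format)
  } else {
    D <- as.matrix(means)
    meta <- list(n = attr(means, "n"), format = attr(means, "format"))
  }
  npt <- nrow(D)
  if (dim > npt - 1L) stop("`dim` must be at most n - 1", call. = FALSE)

  X <- cmdscale(D, k = dim)
  if (ncol(X) < dim) X <- cbind(X, matrix(0, npt, dim - ncol(X)))

  stress_raw <- function(X) {
    d <- as.matrix(dist(X))
    sum((D - d)[upper.tri(D)]^2)
  }
  s_old <- stress_raw(X)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    d <- as.matrix(dist(X))
    B <- ifelse(d > 0, -D / d, 0)
    diag(B) <- 0
    diag(B) <- -rowSums(B)
    X <- B %*% X / npt # Guttman transform
    s_new <- stress_raw(X)
    if (s_old - s_new <= tol * max(s_old, .Machine$double.eps)) {
      converged <- TRUE
      s_old <- s_new
      break
    }
    s_old <- s_new
  }
  if (!converged)
    warning("MDS majorization hit the iteration cap; returning best-found solution")
  stress1 <- sqrt(s_old / sum(D[upper.tri(D)]^2))
  structure(list(coords = X, stress = stress1, converged = converged,
                 n = meta$n, format = meta$format, rotation = NULL,
                 rotated_first_dim = NULL),
            class = "numalign_mds")
}

# Orthonormal completion of a unit first row.
complete_basis <- function(v) {
  d <- length(v)
  Q <- qr.Q(qr(cbind(v, diag(d)[, -which.max(abs(v))])))
  if (sum(Q[, 1L] * v) < 0) Q[, 1L] <- -Q[, 1L]
  t(Q)
}

#' Rotate an MDS embedding to align its first dimension with number
#'
#' The MDS solution is defined only up to orthonormal transforms; this
#' picks the rotation whose first axis is the direction maximizing the
#' Pearson correlation between the projected coordinates and the
#' numerosity of each point (all 18 points pooled), with the sign fixed so
#' the correlation is nonnegative. The projection of each point on that
#' axis is the point's "number line" coordinate r(n, f).
#'
#' @param embedding A [mds_embed()] result.
#' @param numbers Numerosity of each embedded point (defaults to the
#'   metadata carried by the embedding).
#' @return The embedding with `rotation` (orthonormal, first row = the
#'   aligned axis), `rotated_coords`, and `rotated_first_dim` filled in.
#' @export
rotate_align <- function(embedding, numbers = embedding$n) {
  stopifnot(inherits(embedding, "numalign_mds"))
  X <- embedding$coords
  if (is.null(numbers) || length(numbers) != nrow(X))
    stop("`numbers` must give the numerosity of every embedded point",
         call. = FALSE)
  Xc <- scale(X, scale = FALSE)
  if (all(abs(Xc) < 1e-12))
    stop("degenerate embedding: zero variance", call. = FALSE)
  nc <- numbers - mean(numbers)
  S <- crossprod(Xc) / nrow(X)
  cvec <- crossprod(Xc, nc) / nrow(X)
  # max_v corr(Xv, n): v proportional to S^{-1} cov(X, n)
  v <- tryCatch(solve(S, cvec),
                error = function(e) solve(S + 1e-10 * diag(nrow(S)), cvec))
  v <- as.vector(v) / sqrt(sum(v^2))
  if (cor(X %*% v, numbers) < 0) v <- -v
  R <- complete_basis(v)
  XR <- X %*% t(R)
  embedding$rotation <- R
  embedding$rotated_coords <- XR
  embedding$rotated_first_dim <- as.vector(XR[, 1L])
  embedding
}

#' Alignment between the symbolic and nonsymbolic number lines
#'
#' From the rotated first MDS dimension r(n, f): (1) the Pearson
#' correlation between r(n, s) and r(n, ns) across numbers n = 1..9, and
#' (2) the normalized average distance
#' `(1/9) * sum_n |r(n,s) - r(n,ns)| / |r(9,ns) - r(1,ns)|`.
#'
#' @param embedding A rotated embedding (see [rotate_align()]).
#' @return A list with `correlation` and `norm_distance`.
#' @export
alignment_metrics <- function(embedding) {
  stopifnot(inherits(embedding, "numalign_mds"))
  r <- embedding$rotated_first_dim
  if (is.null(r))
    stop("embedding has not been rotated; call rotate_align() first",
         call. = FALSE)
  rs <- r[embedding$format == "symbolic"][order(embedding$n[embedding$format == "symbolic"])]
  rn <- r[embedding$format == "nonsymbolic"][order(embedding$n[embedding$format == "nonsymbolic"])]
  if (length(rs) != 9L || length(rn) != 9L)
    stop("embedding must contain numbers 1-9 in both formats", call. = FALSE)
  denom <- abs(rn[9L] - rn[1L])
  if (denom == 0)
    stop("degenerate nonsymbolic number line: r(9,ns) equals r(1,ns)",
         call. = FALSE)
  list(correlation = cor(rs, rn),
       norm_distance = mean(abs(rs - rn)) / denom)
}

#' Numerical distance effect score
#'
#' Spearman rank correlation between numerical distance |n - n'| and NRS
#' similarity over the within-format off-diagonal cells; a distance effect
#' (closer numbers represented more similarly) corresponds to a strictly
#' negative score.
#'
#' @param nrs An [nrs_matrix()].
#' @param format `"nonsymbolic"` or `"symbolic"`.
#' @return Rank correlation in \[-1, 1\] (0 when all similarities tie).
#' @export
distance_effect_score <- function(nrs, format = c("nonsymbolic", "symbolic")) {
  format <- match.arg(format)
  stopifnot(inherits(nrs, "numalign_nrs"))
  sel <- which(attr(nrs, "format") == format)
  n <- attr(nrs, "n")[sel]
  S <- unclass(nrs)[sel, sel]
  ut <- upper.tri(S)
  dist_n <- abs(outer(n, n, `-`))[ut]
  sims <- S[ut]
  if (length(unique(sims)) == 1L) return(0)
  cor(dist_n, sims, method = "spearman")
}

#' Write representational artifacts
#'
#' NRS as an 18 x 18 CSV with format/number headers; MDS coordinates and
#' number-line positions as CSV; alignment metrics as JSON.
#'
#' @param analysis A stage-boundary analysis (element of
#'   `run_curriculum()$analyses`).
#' @param dir Output directory.
#' @param prefix File-name prefix.
#' @return `dir`, invisibly.
#' @export
write_representation <- function(analysis, dir, prefix = "stage") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  nrs <- analysis$nrs
  tab <- as.data.frame(unclass(nrs))
  names(tab) <- rownames(analysis$means$means)
  tab <- cbind(format = attr(nrs, "format"), n = attr(nrs, "n"), tab)
  write.csv(tab, file.path(dir, paste0(prefix, "_nrs.csv")), row.names = FALSE)
  emb <- analysis$embedding
  coords <- data.frame(format = emb$format, n = emb$n, emb$coords,
                       r = emb$rotated_first_dim)
  write.csv(coords, file.path(dir, paste0(prefix, "_mds.csv")),
            row.names = FALSE)
  jsonlite::write_json(
    list(stage = analysis$stage, condition = analysis$condition,
         correlation = analysis$alignment$correlation,
         norm_distance = analysis$alignment$norm_distance,
         stress = emb$stress,
         distance_effect = as.list(analysis$distance_effect)),
    file.path(dir, paste0(prefix, "_alignment.json")), auto_unbox = TRUE,
    pretty = TRUE, digits = NA)
  invisible(dir)
}
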
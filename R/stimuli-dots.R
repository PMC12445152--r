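# Dot-array (nonsymbolic) stimulus generation.
#
# Each image shows 1-9 disjoint filled circles of one color on a black
# background. Two low-level magnitudes are controlled independently of
# numerosity: the total foreground area (summed dot area, in pixels^2) and
# the area of the convex hull spanned by the dots (centers plus radii), so
# that neither cue alone predicts number.

#' Specify a single dot-array stimulus
#'
#' @param numerosity Integer count of dots, 1-9.
#' @param target_total_area Target summed dot area in pixels^2 (realized as
#'   the foreground pixel count, within `area_tol`).
#' @param target_hull_area Target area of the convex hull of the dots
#'   (centers inflated by radii), in pixels^2, realized within `hull_tol`.
#'   For `numerosity = 1` the hull is the single disc, so the only feasible
#'   target equals the total area.
#' @param color RGB triple in \[0,1\]; `NULL` draws a random color with
#'   luminance at least 0.3 against the black background.
#' @param canvas_size Side of the square canvas in pixels (224 at full
#'   scale; the reduced "desk" profile uses 64).
#' @param area_tol,hull_tol Relative tolerances on the realized foreground
#'   pixel count and realized hull area.
#' @param max_retries Bound on placement attempts before an explicit
#'   placement-failure error.
#' @return An object of class `dot_stimulus_spec`.
#' @export
dot_stimulus_spec <- function(numerosity, target_total_area, target_hull_area,
                              color = NULL, canvas_size = 64,
                              area_tol = 0.05, hull_tol = 0.10,
                              max_retries = 1000L) {
  stopifnot_scalar_count(numerosity, "numerosity")
  if (numerosity < 1 || numerosity > 9)
    stop("`numerosity` must be between 1 and 9", call. = FALSE)
  if (!is.numeric(target_total_area) || target_total_area <= 0)
    stop("`target_total_area` must be positive", call. = FALSE)
  if (!is.numeric(target_hull_area) || target_hull_area <= 0)
    stop("`target_hull_area` must be positive", call. = FALSE)
  if (!is.null(color) && (length(color) != 3L || any(color < 0 | color > 1)))
    stop("`color` must be an RGB triple in [0,1]", call. = FALSE)
  structure(list(numerosity = as.integer(numerosity),
                 target_total_area = target_total_area,
                 target_hull_area = target_hull_area,
                 color = color, canvas_size = as.integer(canvas_size),
                 area_tol = area_tol, hull_tol = hull_tol,
                 max_retries = as.integer(max_retries)),
            class = "dot_stimulus_spec")
}

# Area of the convex hull of discs (centers inflated by radii), from a
# polygonal approximation with `m` boundary points per disc.
disc_hull_area <- function(centers, radii, m = 24L) {
  ang <- seq(0, 2 * pi, length.out = m + 1L)[-(m + 1L)]
  px <- as.vector(outer(cos(ang), radii) + rep(centers[, 1L], each = m))
  py <- as.vector(outer(sin(ang), radii) + rep(centers[, 2L], each = m))
  h <- chull(px, py)
  x <- px[h]; y <- py[h]
  abs(sum(x * c(y[-1L], y[1L]) - c(x[-1L], x[1L]) * y)) / 2
}

# Number of raster pixels covered by one disc (pixel centers at integers).
disc_pixel_count <- function(cx, cy, r) {
  xs <- max(1L, floor(cx - r)):ceiling(cx + r)
  ys <- max(1L, floor(cy - r)):ceiling(cy + r)
  sum(outer((xs - cx)^2, (ys - cy)^2, `+`) <= r^2)
}

rasterize_dots <- function(centers, radii, canvas) {
  img <- matrix(0, canvas, canvas)
  for (i in seq_along(radii)) {
    cx <- centers[i, 1L]; cy <- centers[i, 2L]; r <- radii[i]
    xs <- max(1L, floor(cx - r)):min(canvas, ceiling(cx + r))
    ys <- max(1L, floor(cy - r)):min(canvas, ceiling(cy + r))
    hit <- outer((xs - cx)^2, (ys - cy)^2, `+`) <= r^2
    img[xs, ys][hit] <- 1
  }
  img
}

# One placement attempt; returns NULL on failure.
place_dots_once <- function(n, total, hull, canvas) {
  r0 <- sqrt(total / (n * pi))
  r <- r0 * runif(n, 0.75, 1.25)
  r <- r * sqrt(total / sum(pi * r^2))
  if (any(r < 1)) return(NULL)
  gap <- 2
  mid <- (canvas + 1) / 2

  if (n == 1L) {
    centers <- matrix(mid + runif(2, -2, 2), 1L, 2L)
  } else {
    R0 <- sqrt(hull / pi)
    centers <- matrix(NA_real_, n, 2L)
    for (i in seq_len(n)) {
      ok <- FALSE
      for (t in seq_len(200L)) {
        u <- runif(2, -1, 1)
        if (sum(u^2) > 1) next
        cand <- mid + R0 * u
        if (i == 1L ||
            all(sqrt(rowSums((centers[seq_len(i - 1L), , drop = FALSE] -
                              matrix(cand, i - 1L, 2L, byrow = TRUE))^2)) >=
                r[seq_len(i - 1L)] + r[i] + gap)) {
          centers[i, ] <- cand; ok <- TRUE; break
        }
      }
      if (!ok) return(NULL)
    }
    # Scale the configuration about its centroid so the realized hull area
    # (monotone in the scale factor) matches the target.
    ctr <- colMeans(centers)
    hull_at <- function(g) {
      cs <- sweep(sweep(centers, 2L, ctr), 1L, rep(g, n), `*`)
      disc_hull_area(sweep(cs, 2L, ctr, `+`), r)
    }
    lo <- 0.15; hi <- 6
    if (hull_at(hi) < hull || hull_at(lo) > hull) return(NULL)
    for (it in seq_len(40L)) {
      mid_g <- (lo + hi) / 2
      if (hull_at(mid_g) < hull) lo <- mid_g else hi <- mid_g
    }
    g <- (lo + hi) / 2
    centers <- sweep(sweep(sweep(centers, 2L, ctr), 1L, rep(g, n), `*`), 2L, ctr, `+`)
    if (g < 1) { # shrinking can violate separation
      d <- as.matrix(dist(centers)); diag(d) <- Inf
      if (any(d < outer(r, r, `+`) + gap / 2)) return(NULL)
    }
  }
  if (any(centers - r < 2) || any(centers + r > canvas - 1)) return(NULL)
  list(centers = centers, radii = r)
}

#' Generate one dot-array stimulus image
#'
#' Places `spec$numerosity` non-overlapping discs, rescales the
#' configuration so the convex hull of the dots matches the target hull
#' area, then rescales the radii so the rasterized foreground pixel count
#' matches the target total area. Deterministic given `(spec, seed)`.
#'
#' @param spec A [dot_stimulus_spec()].
#' @param seed Integer seed controlling placement, radii, and color.
#' @return A `numalign_stimulus` object: a list with `pixels` (a
#'   `canvas_size` x `canvas_size` luminance matrix in \[0,1\]),
#'   `numerosity`, `format = "nonsymbolic"`, `split`, and `provenance`
#'   (all generator parameters, sufficient for bit-exact regeneration).
#' @export
generate_dot_image <- function(spec, seed) {
  stopifnot(inherits(spec, "dot_stimulus_spec"))
  # separate substreams so a spec that pins the color reproduces the same
  # placement as the run that drew it
  seeds <- derive_seeds(seed, 2L)
  color <- spec$color
  if (is.null(color)) {
    color <- with_seed(seeds[2L], {
      repeat {
        cand <- runif(3)
        if (sum(cand * c(0.2126, 0.7152, 0.0722)) >= 0.3) break
      }
      cand
    })
  }
  lum <- sum(color * c(0.2126, 0.7152, 0.0722))
  with_seed(seeds[1L], {
    n <- spec$numerosity
    canvas <- spec$canvas_size
    total <- spec$target_total_area
    hull <- spec$target_hull_area

    placement <- NULL
    for (try in seq_len(spec$max_retries)) {
      cand <- place_dots_once(n, total, hull, canvas)
      if (is.null(cand)) next
      # Radius rescale so the rasterized pixel count hits the target.
      count_at <- function(b) sum(vapply(seq_len(n), function(i)
        disc_pixel_count(cand$centers[i, 1L], cand$centers[i, 2L],
                         b * cand$radii[i]), numeric(1)))
      blo <- 0.85; bhi <- 1.18
      for (it in seq_len(30L)) {
        bm <- (blo + bhi) / 2
        if (count_at(bm) < total) blo <- bm else bhi <- bm
      }
      beta <- (bhi + blo) / 2
      realized <- count_at(beta)
      if (abs(realized - total) / total > spec$area_tol) next
      radii <- beta * cand$radii
      if (n > 1L) { # separation must survive the radius rescale
        d <- as.matrix(dist(cand$centers)); diag(d) <- Inf
        if (any(d < outer(radii, radii, `+`) + 1)) next
      }
      realized_hull <- disc_hull_area(cand$centers, radii)
      if (n > 1L && abs(realized_hull - hull) / hull > spec$hull_tol) next
      placement <- list(centers = cand$centers, radii = radii,
                        realized_area = realized, realized_hull = realized_hull)
      break
    }
    if (is.null(placement))
      stop(sprintf(paste0("dot placement failed after %d retries ",
                          "(numerosity %d, total area %.0f, hull area %.0f, ",
                          "canvas %d): infeasible parameter pair"),
                   spec$max_retries, n, total, hull, canvas), call. = FALSE)

    pixels <- rasterize_dots(placement$centers, placement$radii, canvas) * lum
    new_stimulus(pixels, n, "nonsymbolic",
                 provenance = list(generator = "dots", seed = as.integer(seed),
                                   numerosity = n,
                                   target_total_area = total,
                                   target_hull_area = hull,
                                   realized_total_area = placement$realized_area,
                                   realized_hull_area = placement$realized_hull,
                                   canvas_size = canvas, color = color))
  })
}

new_stimulus <- function(pixels, numerosity, format, split = NA_character_,
                         provenance = list()) {
  structure(list(pixels = pixels, numerosity = as.integer(numerosity),
                 format = format, split = split, provenance = provenance),
            class = "numalign_stimulus")
}

#' @export
print.numalign_stimulus <- function(x, ...) {
  cat(sprintf("<numalign_stimulus> %s %d, %dx%d, split=%s\n", x$format,
              x$numerosity, nrow(x$pixels), ncol(x$pixels), x$split))
  invisible(x)
}

#' Generate the full dot-array stimulus set
#'
#' Draws `n_param_sets` (total area, hull area) parameter pairs — total
#' area log-uniform over `area_frac_range` of the canvas area, hull area
#' log-uniform over `hull_frac_range` — shared across numerosities, and
#' renders `images_per_set` images per (numerosity, parameter pair), of
#' which the first `train_per_set` are assigned to the training split. The
#' full-scale configuration (50, 12, 10) yields 9 x 12 x 50 = 5400 images
#' (4500 training, 900 testing). Parameter pairs are adjusted per
#' numerosity to the nearest feasible values (minimum dot radius, hull no
#' smaller than tightly packed dots, hull fitting the canvas); the adjusted
#' values are recorded in each image's provenance.
#'
#' @param n_param_sets Number of (total area, hull area) parameter pairs.
#' @param images_per_set Images rendered per (numerosity, parameter pair).
#' @param train_per_set How many of those go to the training split
#'   (must be `< images_per_set`, or 0 for an all-test set).
#' @param seed Integer seed; all placement randomness derives from it.
#' @param canvas_size Canvas side in pixels.
#' @param area_frac_range,hull_frac_range Ranges for the sampled total and
#'   hull areas, as fractions of the canvas area.
#' @return A list of `numalign_stimulus` objects with a `manifest`
#'   attribute (one `data.frame` row per image).
#' @export
generate_dot_dataset <- function(n_param_sets = 50L, images_per_set = 12L,
                                 train_per_set = 10L, seed = 1L,
                                 canvas_size = 64L,
                                 area_frac_range = c(0.01, 0.10),
                                 hull_frac_range = c(0.10, 0.60)) {
  stopifnot_scalar_count(n_param_sets, "n_param_sets")
  stopifnot_scalar_count(images_per_set, "images_per_set")
  stopifnot_scalar_count(train_per_set, "train_per_set")
  if (train_per_set >= images_per_set)
    stop("`train_per_set` must be smaller than `images_per_set`", call. = FALSE)
  A <- as.numeric(canvas_size)^2

  with_seed(seed, {
    totals <- exp(runif(n_param_sets, log(area_frac_range[1] * A),
                        log(area_frac_range[2] * A)))
    hulls <- exp(runif(n_param_sets, log(hull_frac_range[1] * A),
                       log(hull_frac_range[2] * A)))
    img_seeds <- matrix(sample.int(.Machine$integer.max - 1L,
                                   9L * n_param_sets * images_per_set),
                        nrow = 9L * n_param_sets)
  })

  images <- vector("list", 9L * n_param_sets * images_per_set)
  rows <- vector("list", length(images))
  k <- 0L
  for (n in 1:9) {
    for (p in seq_len(n_param_sets)) {
      eff <- feasible_dot_params(n, totals[p], hulls[p], canvas_size)
      for (j in seq_len(images_per_set)) {
        k <- k + 1L
        s <- img_seeds[(n - 1L) * n_param_sets + p, j]
        spec <- dot_stimulus_spec(n, eff$total, eff$hull,
                                  canvas_size = canvas_size)
        img <- tryCatch(generate_dot_image(spec, s), error = function(e)
          stop(sprintf("dot dataset generation failed at parameter pair %d (total %.0f, hull %.0f), numerosity %d: %s",
                       p, eff$total, eff$hull, n, conditionMessage(e)),
               call. = FALSE))
        img$split <- if (j <= train_per_set) "train" else "test"
        img$provenance$param_set <- p
        images[[k]] <- img
        rows[[k]] <- data.frame(id = k, numerosity = n, format = "nonsymbolic",
                                split = img$split, param_set = p, seed = s,
                                target_total_area = eff$total,
                                target_hull_area = eff$hull,
                                realized_total_area = img$provenance$realized_total_area,
                                realized_hull_area = img$provenance$realized_hull_area)
      }
    }
  }
  attr(images, "manifest") <- do.call(rbind, rows)
  images
}

# Clamp a sampled (total, hull) parameter pair to the feasible region of a
# given numerosity: dots no smaller than ~1.3 px radius; hull bounded
# below by a loose-packing multiple of the summed dot area and above by
# the largest hull n discs of that size can span inside the canvas
# (points on the largest inscribed circle, inflated by the dot radius).
# n = 1 forces hull = total (a single disc admits no other hull). When
# the bounds conflict, the geometric midpoint keeps the pair feasible.
feasible_dot_params <- function(n, total, hull, canvas) {
  total <- max(total, 7.5 * n)
  if (n == 1L) return(list(total = total, hull = total))
  r <- 1.1 * sqrt(total / (n * pi))
  Rmax <- canvas / 2 - r - 3
  hull_max <- if (n == 2L) 4 * r * Rmax + pi * r^2
  else 0.5 * n * Rmax^2 * sin(2 * pi / n) +
    2 * n * Rmax * sin(pi / n) * r + pi * r^2
  # lower bound: both a multiple of the summed dot area and enough room to
  # place n centers at the enforced pairwise separation (hexagonal packing
  # area with headroom so rejection sampling of centers succeeds)
  lo <- max(1.8 * total, 1.5 * 0.866 * n * (2 * r + 2)^2)
  hi <- 0.8 * hull_max
  hull <- if (lo > hi) min(sqrt(lo * hi), 0.95 * hull_max)
  else min(max(hull, lo), hi)
  list(total = total, hull = hull)
}
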
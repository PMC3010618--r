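#' Fill gap pixels by neighbor averaging
#'
#' Undefined pixels are imputed with the arithmetic mean of their non-missing
#' neighbors (8-connected). Sweeps are Jacobi-style: within a sweep every
#' fillable gap pixel uses the values fixed at sweep start, so the result is
#' independent of pixel order; sweeps repeat until no gap pixel remains,
#' which lets large gap blocks fill inward front by front. The returned
#' image has a fully defined `chi`, but `gap_mask` still records the
#' *original* gaps -- downstream, the mean-squared distance uses the filled
#' values while the gap measure counts the original gaps.
#'
#' @param img A `SusceptibilityImage` with at least one non-gap pixel.
#' @return A `SusceptibilityImage` with fully defined `chi`.
#' @export
interpolate_gaps <- function(img) {
  stopifnot(inherits(img, "SusceptibilityImage"))
  # no symmetry requirement here: warped/registered intermediates are valid
  # inputs even though true susceptibility images are symmetric
  if (all(img$gap_mask)) stop("interpolate_gaps: all pixels are gaps")
  chi <- img$chi
  filled <- !img$gap_mask
  chi[!filled] <- 0
  m <- img$m
  while (!all(filled)) {
    vs <- chi * filled
    nsum <- shift_sum(vs, m)
    ncnt <- shift_sum(filled * 1, m)
    can <- !filled & ncnt > 0
    if (!any(can)) stop("interpolate_gaps: unreachable gap pixels")
    chi[can] <- nsum[can] / ncnt[can]
    filled <- filled | can
  }
  # neighbor means of in-range values stay in range; clamp rounding residue
  chi <- pmin(pmax(chi, 0), 1)
  structure(list(protein_id = img$protein_id, chi = chi,
                 gap_mask = img$gap_mask, m = m),
            class = "SusceptibilityImage")
}

# sum of the 8 shifted copies of M (zero padding at edges)
shift_sum <- function(M, m) {
  P <- matrix(0, m + 2, m + 2)
  P[2:(m + 1), 2:(m + 1)] <- M
  out <- matrix(0, m, m)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    out <- out + P[(2 + dr):(m + 1 + dr), (2 + dc):(m + 1 + dc)]
  }
  out
}

# Cubic-convolution (Keys, a = -0.5) sampling of matrix `img` at continuous
# 1-based coordinates (x = column, y = row), replicate-padded at the borders.
# Reproduces the source exactly at integer coordinates and linear ramps away
# from the borders.
bicubic_sample <- function(img, x, y) {
  m_r <- nrow(img); m_c <- ncol(img)
  kern <- function(t) {
    at <- abs(t)
    w <- numeric(length(at))
    i1 <- at <= 1
    w[i1] <- 1.5 * at[i1]^3 - 2.5 * at[i1]^2 + 1
    i2 <- at > 1 & at < 2
    w[i2] <- -0.5 * at[i2]^3 + 2.5 * at[i2]^2 - 4 * at[i2] + 2
    w
  }
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  out <- numeric(length(x))
  for (dy in -1:2) {
    wy <- kern(fy - dy)
    ry <- pmin(pmax(y0 + dy, 1), m_r)
    for (dx in -1:2) {
      wx <- kern(fx - dx)
      cx <- pmin(pmax(x0 + dx, 1), m_c)
      out <- out + wy * wx * img[cbind(ry, cx)]
    }
  }
  out
}

# Center-aligned coordinate map from target index t (1-based, length m_tgt)
# to source coordinate (1-based, continuous): pixel centers at integers.
resize_map <- function(t, m_src, m_tgt) {
  (t - 0.5) * (m_src / m_tgt) + 0.5
}

#' Resize a susceptibility image by bicubic interpolation
#'
#' `chi` is resampled to `target_m` x `target_m` with bicubic (cubic
#' convolution) interpolation, which gives smooth transitions with few
#' resampling artifacts; values are clamped back to [0, 1] afterwards since
#' cubic kernels can overshoot at sharp edges. The gap mask is resampled by
#' nearest neighbor: a target pixel is a gap iff its nearest source pixel
#' was an original gap. `chi` must already be fully defined (run
#' [interpolate_gaps()] first if the image has gaps).
#'
#' @param img A `SusceptibilityImage` with fully defined `chi`.
#' @param target_m Target dimension, >= 2.
#' @return A `SusceptibilityImage` of dimension `target_m`.
#' @export
resize_image <- function(img, target_m) {
  stopifnot(inherits(img, "SusceptibilityImage"))
  target_m <- as.integer(target_m)
  if (is.na(target_m) || target_m < 2)
    stop("resize_image: target_m must be an integer >= 2")
  if (anyNA(img$chi))
    stop("resize_image: chi has undefined values; run interpolate_gaps first")
  m <- img$m
  u <- resize_map(seq_len(target_m), m, target_m)
  g <- expand.grid(y = u, x = u)     # varies y (rows) fastest: column-major
  chi <- matrix(bicubic_sample(img$chi, g$x, g$y), target_m, target_m)
  chi <- pmin(pmax(chi, 0), 1)
  nn <- pmin(pmax(round(u), 1), m)
  gm <- img$gap_mask[nn, nn, drop = FALSE]
  structure(list(protein_id = img$protein_id, chi = chi, gap_mask = gm,
                 m = target_m),
            class = "SusceptibilityImage")
}

#' Least-squares similarity transform from control points
#'
#' Fits the scale, rotation and translation mapping moving-image points onto
#' base-image points in the least-squares sense. With the parameterization
#' `x_b = a x_m - b y_m + tx`, `y_b = b x_m + a y_m + ty` the problem is
#' linear in `(a, b, tx, ty)`; then `scale = sqrt(a^2 + b^2)` and
#' `rotation = atan2(b, a)`. Two distinct point pairs determine the
#' transform exactly.
#'
#' @param points n x 4 matrix (n >= 2) with columns `x_moving`, `y_moving`,
#'   `x_base`, `y_base` (see [read_control_points()]).
#' @return A `SimilarityTransform`.
#' @export
fit_similarity <- function(points) {
  points <- as.matrix(points)
  if (ncol(points) != 4 || nrow(points) < 2)
    stop("fit_similarity: need an n x 4 matrix with n >= 2")
  xm <- points[, 1]; ym <- points[, 2]
  xb <- points[, 3]; yb <- points[, 4]
  if (max(abs(xm - xm[1])) < 1e-12 && max(abs(ym - ym[1])) < 1e-12)
    stop("fit_similarity: degenerate control points (all moving points ",
         "coincide)")
  n <- length(xm)
  A <- rbind(cbind(xm, -ym, 1, 0),
             cbind(ym,  xm, 0, 1))
  rhs <- c(xb, yb)
  beta <- qr.solve(A, rhs)
  s <- sqrt(beta[1]^2 + beta[2]^2)
  if (s <= 1e-12) stop("fit_similarity: degenerate fit (zero scale)")
  similarity_transform(s, atan2(beta[2], beta[1]), beta[3:4])
}

#' Warp a moving image into the base frame
#'
#' Resamples the moving image under the inverse of `tf` (which maps moving
#' coordinates into base coordinates) so that the output lives on the base
#' pixel grid. Values are sampled bicubically and clamped to [0, 1]. A
#' target pixel becomes a gap when it maps outside the moving image's pixel
#' extent, or when its nearest source pixel was a gap in the moving image.
#'
#' @param moving A `SusceptibilityImage` with fully defined `chi`.
#' @param tf A `SimilarityTransform` (moving -> base coordinates).
#' @param m_out Output (base) dimension; default the moving dimension.
#' @return A warped `SusceptibilityImage` of dimension `m_out`.
#' @export
warp_image <- function(moving, tf, m_out = moving$m) {
  stopifnot(inherits(moving, "SusceptibilityImage"),
            inherits(tf, "SimilarityTransform"))
  if (anyNA(moving$chi))
    stop("warp_image: chi has undefined values; run interpolate_gaps first")
  inv <- st_inverse(tf)
  idx <- seq_len(m_out)
  g <- expand.grid(y = idx, x = idx)
  src <- st_apply(inv, cbind(g$x, g$y))
  sx <- src[, 1]; sy <- src[, 2]
  m <- moving$m
  outside <- sx < 0.5 | sx > m + 0.5 | sy < 0.5 | sy > m + 0.5
  vals <- bicubic_sample(moving$chi, sx, sy)
  vals <- pmin(pmax(vals, 0), 1)
  nnx <- pmin(pmax(round(sx), 1), m)
  nny <- pmin(pmax(round(sy), 1), m)
  src_gap <- moving$gap_mask[cbind(nny, nnx)]
  chi <- matrix(vals, m_out, m_out)
  gm <- matrix(outside | src_gap, m_out, m_out)
  chi[gm] <- 0
  structure(list(protein_id = moving$protein_id, chi = chi, gap_mask = gm,
                 m = m_out),
            class = "SusceptibilityImage")
}

#' Mean-squared pixel distance between registered images
#'
#' The "Euclidean distance" of the output tables: the sum of squared
#' grey-level differences over the pixels where *both* images have defined
#' values, divided by `m^2` (the full image size -- as printed in the source
#' formula, not the count of defined pixels; the gap burden is accounted for
#' separately by [gap_measure()]). No square root is taken.
#'
#' @param base,registered `SusceptibilityImage`s of equal dimension m x m.
#' @return Nonnegative real.
#' @export
image_distance <- function(base, registered) {
  stopifnot(inherits(base, "SusceptibilityImage"),
            inherits(registered, "SusceptibilityImage"))
  if (base$m != registered$m)
    stop("image_distance: dimension mismatch (", base$m, " vs ",
         registered$m, ")")
  ok <- !base$gap_mask & !registered$gap_mask
  sum((base$chi[ok] - registered$chi[ok])^2) / base$m^2
}

#' Normalized gap measure between registered images
#'
#' The count of pixels where either the base or the registered image has a
#' gap value, normalized by the image size `m^2`. Always in [0, 1]; 0 iff
#' both images are gap-free.
#'
#' @inheritParams image_distance
#' @return Real in [0, 1].
#' @export
gap_measure <- function(base, registered) {
  stopifnot(inherits(base, "SusceptibilityImage"),
            inherits(registered, "SusceptibilityImage"))
  if (base$m != registered$m)
    stop("gap_measure: dimension mismatch (", base$m, " vs ",
         registered$m, ")")
  mean(base$gap_mask | registered$gap_mask)
}

#' Refine a similarity transform by maximizing image similarity
#'
#' Deterministic coordinate-wise local search over (scale, rotation, tx, ty)
#' starting from `init`, minimizing the mean-squared pixel distance between
#' the base image and the warped moving image. Step sizes shrink by halving
#' whenever no parameter move improves the objective; the search stops when
#' all steps drop below resolution or after `max_sweeps` sweeps. Parameters
#' are kept inside a box around `init` (scale within a factor `1.3`,
#' rotation within 0.3 rad, translation within `m/8` pixels) so that the
#' search cannot drift toward degenerate overlaps with few defined pixels.
#' The returned transform is never worse than `init` under the objective.
#'
#' @param moving A gap-interpolated `SusceptibilityImage` already resized to
#'   the base dimension.
#' @param base The base `SusceptibilityImage`.
#' @param init Initial `SimilarityTransform` (e.g. from [fit_similarity()]).
#' @param max_sweeps Maximum coordinate sweeps (default 40).
#' @return A `SimilarityTransform` with attribute `"distance"` holding the
#'   achieved objective value.
#' @export
refine_by_maximum_similarity <- function(moving, base, init,
                                         max_sweeps = 40) {
  stopifnot(inherits(init, "SimilarityTransform"))
  obj <- function(p) {
    tf <- similarity_transform(p[1], p[2], p[3:4])
    image_distance(base, warp_image(moving, tf, base$m))
  }
  p <- c(init$scale, init$rotation, init$translation)
  lower <- c(init$scale / 1.3, init$rotation - 0.3,
             init$translation - base$m / 8)
  upper <- c(init$scale * 1.3, init$rotation + 0.3,
             init$translation + base$m / 8)
  step <- c(0.05, 0.02, 1, 1)
  min_step <- c(1e-3, 1e-3, 0.05, 0.05)
  best <- obj(p)
  for (sweep in seq_len(max_sweeps)) {
    improved <- FALSE
    for (k in 1:4) {
      for (sgn in c(1, -1)) {
        q <- p
        q[k] <- min(max(q[k] + sgn * step[k], lower[k]), upper[k])
        if (q[k] == p[k]) next
        v <- obj(q)
        if (v < best - 1e-15) {
          best <- v; p <- q; improved <- TRUE
        }
      }
    }
    if (!improved) {
      step <- step / 2
      if (all(step < min_step)) break
    }
  }
  out <- similarity_transform(p[1], p[2], p[3:4])
  attr(out, "distance") <- best
  out
}

# Rescale moving-side control-point coordinates after a resize of the moving
# image from m_src to m_tgt (center-aligned map, inverse of resize_map).
scale_moving_points <- function(points, m_src, m_tgt) {
  f <- m_tgt / m_src
  points[, 1] <- (points[, 1] - 0.5) * f + 0.5
  points[, 2] <- (points[, 2] - 0.5) * f + 0.5
  points
}

default_control_points <- function(m) {
  q <- round(m / 4); t <- m - q + 1
  cbind(x_moving = c(q, t, q, t), y_moving = c(q, q, t, t),
        x_base = c(q, t, q, t), y_base = c(q, q, t, t))
}

# One directional registration: interpolate gaps in `moving`, resize to the
# base dimension, fit the landmark transform, refine, warp, measure.
register_direction <- function(base, moving, points = NULL,
                               refine = TRUE, max_sweeps = 40) {
  # base gaps stay masked (excluded from the distance); only the moving
  # image needs defined values for resampling
  base_f <- base
  mov_f <- if (any(moving$gap_mask)) interpolate_gaps(moving) else moving
  mov_r <- if (mov_f$m != base$m) resize_image(mov_f, base$m) else mov_f
  if (is.null(points)) {
    points <- default_control_points(base$m)
  } else {
    points <- as.matrix(points)
    if (mov_f$m != base$m)
      points <- scale_moving_points(points, mov_f$m, base$m)
  }
  tf0 <- fit_similarity(points)
  d0 <- image_distance(base_f, warp_image(mov_r, tf0, base$m))
  tf <- if (refine) {
    refine_by_maximum_similarity(mov_r, base_f, tf0, max_sweeps)
  } else {
    attr(tf0, "distance") <- d0
    tf0
  }
  registered <- warp_image(mov_r, tf, base$m)
  # distance uses interpolated chi but the ORIGINAL base gap mask plays no
  # role in chi values; base_f carries the original mask by construction
  list(euclidean = image_distance(base_f, registered),
       gap = gap_measure(base_f, registered),
       transform = tf, init_transform = tf0, init_distance = d0,
       registered = registered)
}

#' Symmetrized pair comparison of two susceptibility images
#'
#' Runs the full registration chain in both directions -- first `x` as base
#' with `y` registered to it, then roles inverted -- and averages the two
#' mean-squared pixel distances and the two gap measures into one
#' SYMMETRIZED [pair_distance()] record. Each direction: interpolate the
#' moving image's gaps, resize it to the base dimension (bicubic), fit a
#' similarity transform to the control points, refine it by maximum
#' similarity, warp, and compute the two measures.
#'
#' @param x,y `SusceptibilityImage`s.
#' @param cp_xy Control points for registering `y` (moving) onto `x` (base);
#'   n x 4 matrix, moving columns in `y` pixel coordinates. `NULL` uses
#'   identity landmark points (only sensible when images are comparable on
#'   the same grid).
#' @param cp_yx Control points for the reverse direction; `NULL` mirrors
#'   `cp_xy` by swapping its coordinate pairs when supplied, else identity
#'   points.
#' @param refine Run the maximum-similarity refinement (default `TRUE`).
#' @param max_sweeps Refinement sweep budget per direction.
#' @return A SYMMETRIZED `PairDistance` with attribute `"directions"`
#'   holding the two directional results.
#' @export
compare_pair <- function(x, y, cp_xy = NULL, cp_yx = NULL, refine = TRUE,
                         max_sweeps = 40) {
  stopifnot(inherits(x, "SusceptibilityImage"),
            inherits(y, "SusceptibilityImage"))
  if (is.null(cp_yx) && !is.null(cp_xy))
    cp_yx <- cp_xy[, c(3, 4, 1, 2), drop = FALSE]
  d1 <- register_direction(x, y, cp_xy, refine, max_sweeps)
  d2 <- register_direction(y, x, cp_yx, refine, max_sweeps)
  out <- pair_distance(x$protein_id, y$protein_id,
                       euclidean = (d1$euclidean + d2$euclidean) / 2,
                       gap_measure = (d1$gap + d2$gap) / 2,
                       direction = "SYMMETRIZED")
  attr(out, "directions") <- list(d1, d2)
  out
}
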
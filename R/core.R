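#' Domain types for flexibility comparison
#'
#' flexcompare works with a small set of in-memory value types, all plain R
#' lists with a class attribute and a validator:
#'
#' * `FlexibilitySignal` -- an ordered 1D signal over torsion-angle positions
#'   (two positions per residue for backbone flexibility metrics, one per
#'   residue for hydrophobicity profiles) plus a logical gap mask.
#' * `RigidityStateEnsemble` -- a set of symmetric integer matrices with
#'   entries in \{-1, 0, +1\} encoding, per realization, whether a pair of
#'   positions is rigidly correlated (-1), flexibly correlated (+1) or
#'   uncorrelated (0).
#' * `SusceptibilityImage` -- the per-pair variance of the rigidity state over
#'   the ensemble, a symmetric matrix with values in [0, 1] and an explicit
#'   gap mask for undefined pixels.
#' * `SimilarityTransform` -- scale + rotation + translation in pixel
#'   coordinates (shape preserving: no shear, no perspective).
#' * `PairDistance` -- the two-component similarity record for a protein pair:
#'   mean-squared pixel distance ("euclidean") and normalized gap count.
#' * `DTWResult` -- a dynamic-time-warping distance plus its optimal path.
#'
#' Gaps are always represented as explicit logical masks in memory; off-scale
#' sentinel values exist only at the file-format boundary (see
#' [gap_dialect()]). Positions are reported 1-based in all error messages.
#'
#' @name flexcompare-types
NULL

SIGNAL_KINDS <- c("IDF", "HYDROPHOBICITY", "OTHER")

#' Construct a FlexibilitySignal
#'
#' @param protein_id Identifier string.
#' @param values Numeric vector of signal values (finite at non-gap positions).
#' @param kind One of `"IDF"`, `"HYDROPHOBICITY"`, `"OTHER"`. IDF signals must
#'   be nonnegative at non-gap positions.
#' @param gap_mask Logical vector, `TRUE` marking gap/off-scale positions.
#'   Defaults to all `FALSE`.
#' @return A `FlexibilitySignal` object.
#' @export
flexibility_signal <- function(protein_id, values, kind = "OTHER",
                               gap_mask = NULL) {
  kind <- match.arg(kind, SIGNAL_KINDS)
  values <- as.numeric(values)
  if (is.null(gap_mask)) gap_mask <- rep(FALSE, length(values))
  obj <- structure(
    list(protein_id = as.character(protein_id)[1], values = values,
         kind = kind, gap_mask = as.logical(gap_mask)),
    class = "FlexibilitySignal")
  validate_signal(obj)
}

#' @rdname flexibility_signal
#' @param sig A `FlexibilitySignal`.
#' @export
validate_signal <- function(sig) {
  stopifnot(inherits(sig, "FlexibilitySignal"))
  n <- length(sig$values)
  if (n < 1L) stop("FlexibilitySignal: values must have length >= 1")
  if (length(sig$gap_mask) != n)
    stop("FlexibilitySignal: gap_mask length (", length(sig$gap_mask),
         ") != values length (", n, ")")
  if (anyNA(sig$gap_mask)) stop("FlexibilitySignal: gap_mask contains NA")
  live <- sig$values[!sig$gap_mask]
  if (anyNA(live) || any(!is.finite(live)))
    stop("FlexibilitySignal: non-finite value at a non-gap position")
  if (sig$kind == "IDF" && any(live < 0))
    stop("FlexibilitySignal: IDF values must be >= 0 (first violation at ",
         "position ", which(!sig$gap_mask & sig$values < 0)[1], ")")
  sig
}

#' @export
print.FlexibilitySignal <- function(x, ...) {
  cat(sprintf("<FlexibilitySignal %s> kind=%s length=%d gaps=%d\n",
              x$protein_id, x$kind, length(x$values), sum(x$gap_mask)))
  invisible(x)
}

#' Construct a RigidityStateEnsemble
#'
#' An ensemble of realizations of the pairwise rigidity state n_jk: for each
#' realization, a symmetric m x m integer matrix over \{-1, 0, +1\}. The
#' diagonal is required to be -1 (a position is trivially rigid with itself).
#'
#' @param protein_id Identifier string.
#' @param realizations List of m x m integer matrices.
#' @return A validated `RigidityStateEnsemble`.
#' @export
rigidity_ensemble <- function(protein_id, realizations) {
  if (is.matrix(realizations)) realizations <- list(realizations)
  obj <- structure(
    list(protein_id = as.character(protein_id)[1],
         realizations = lapply(realizations, function(r) {
           storage.mode(r) <- "integer"; r
         }),
         m = if (length(realizations)) nrow(realizations[[1]]) else 0L),
    class = "RigidityStateEnsemble")
  validate_ensemble(obj)
}

#' Validate a RigidityStateEnsemble
#'
#' Checks that there is at least one realization, that all realizations are
#' square, symmetric, of one common dimension, with entries in \{-1, 0, +1\}
#' and -1 on the diagonal. Returns the input unchanged when valid; otherwise
#' raises an error naming the first violated invariant.
#'
#' @param ens A `RigidityStateEnsemble`.
#' @return The validated ensemble, invisibly identical to the input.
#' @export
validate_ensemble <- function(ens) {
  stopifnot(inherits(ens, "RigidityStateEnsemble"))
  R <- length(ens$realizations)
  if (R < 1L) stop("RigidityStateEnsemble: needs >= 1 realization")
  m <- ens$m
  for (r in seq_len(R)) {
    M <- ens$realizations[[r]]
    if (!is.matrix(M) || nrow(M) != ncol(M))
      stop("RigidityStateEnsemble: realization ", r, " is not square")
    if (nrow(M) != m)
      stop("RigidityStateEnsemble: realization ", r, " has dimension ",
           nrow(M), ", expected ", m)
    bad <- !(M %in% c(-1L, 0L, 1L))
    if (any(bad)) {
      idx <- which(matrix(bad, m, m), arr.ind = TRUE)[1, ]
      stop("RigidityStateEnsemble: realization ", r, " entry at (",
           idx[1], ",", idx[2], ") is ", M[idx[1], idx[2]],
           ", not in {-1, 0, 1}")
    }
    if (!identical(M, t(M))) {
      d <- which(M != t(M), arr.ind = TRUE)[1, ]
      stop("RigidityStateEnsemble: realization ", r, " asymmetric at (",
           d[1], ",", d[2], ")")
    }
    if (any(diag(M) != -1L))
      stop("RigidityStateEnsemble: realization ", r,
           " diagonal entry != -1 at position ", which(diag(M) != -1L)[1])
  }
  ens
}

#' @export
print.RigidityStateEnsemble <- function(x, ...) {
  cat(sprintf("<RigidityStateEnsemble %s> m=%d realizations=%d\n",
              x$protein_id, x$m, length(x$realizations)))
  invisible(x)
}

#' Construct a SusceptibilityImage
#'
#' @param protein_id Identifier string.
#' @param chi Numeric m x m matrix of rigidity-susceptibility values, in
#'   [0, 1] on non-gap pixels.
#' @param gap_mask Logical m x m matrix, `TRUE` marking undefined pixels.
#'   Defaults to all `FALSE`. Must be symmetric, as must `chi` on non-gap
#'   pixels.
#' @param tol Symmetry tolerance for `chi`.
#' @return A validated `SusceptibilityImage`.
#' @export
susceptibility_image <- function(protein_id, chi, gap_mask = NULL,
                                 tol = 1e-9) {
  chi <- as.matrix(chi)
  if (is.null(gap_mask)) gap_mask <- matrix(FALSE, nrow(chi), ncol(chi))
  obj <- structure(
    list(protein_id = as.character(protein_id)[1], chi = chi,
         gap_mask = gap_mask, m = nrow(chi)),
    class = "SusceptibilityImage")
  validate_image(obj, tol = tol)
}

#' @rdname susceptibility_image
#' @param img A `SusceptibilityImage`.
#' @export
validate_image <- function(img, tol = 1e-9) {
  stopifnot(inherits(img, "SusceptibilityImage"))
  chi <- img$chi; gm <- img$gap_mask; m <- img$m
  if (!is.matrix(chi) || nrow(chi) != ncol(chi) || m < 1L)
    stop("SusceptibilityImage: chi must be a square matrix")
  if (!is.matrix(gm) || !all(dim(gm) == c(m, m)))
    stop("SusceptibilityImage: gap_mask dimensions must match chi")
  if (!identical(unname(gm), unname(t(gm))))
    stop("SusceptibilityImage: gap_mask is not symmetric")
  live <- !gm
  vals <- chi[live]
  if (anyNA(vals) || any(!is.finite(vals)))
    stop("SusceptibilityImage: non-finite chi at a non-gap pixel")
  if (any(vals < -tol) || any(vals > 1 + tol))
    stop("SusceptibilityImage: chi outside [0, 1] at a non-gap pixel")
  d <- abs(chi - t(chi)); d[gm | t(gm)] <- 0
  if (max(d) > tol) {
    w <- which(d == max(d), arr.ind = TRUE)[1, ]
    stop("SusceptibilityImage: chi asymmetric beyond tolerance, worst at (",
         w[1], ",", w[2], "), |delta| = ", format(max(d)))
  }
  img
}

#' @export
print.SusceptibilityImage <- function(x, ...) {
  cat(sprintf("<SusceptibilityImage %s> m=%d gap pixels=%d (%.1f%%)\n",
              x$protein_id, x$m, sum(x$gap_mask),
              100 * mean(x$gap_mask)))
  invisible(x)
}

#' Construct a similarity transform (scale, rotation, translation)
#'
#' Maps pixel coordinates `(x, y)` of a moving image into the base image
#' frame: `p' = s * R(theta) %*% p + t`. Coordinates are 1-based with x =
#' column, y = row, origin at the top-left pixel center.
#'
#' @param scale Positive scale factor.
#' @param rotation Rotation angle in radians (counter-clockwise in the x-right,
#'   y-down pixel frame).
#' @param translation Numeric length-2 vector `(tx, ty)` in pixels.
#' @return A `SimilarityTransform`.
#' @export
similarity_transform <- function(scale = 1, rotation = 0,
                                 translation = c(0, 0)) {
  scale <- as.numeric(scale)[1]
  if (!is.finite(scale) || scale <= 0)
    stop("SimilarityTransform: scale must be a positive real")
  structure(list(scale = scale, rotation = as.numeric(rotation)[1],
                 translation = as.numeric(translation)[1:2]),
            class = "SimilarityTransform")
}

#' Apply a similarity transform to coordinates
#'
#' @param tf A `SimilarityTransform`.
#' @param xy Numeric n x 2 matrix of `(x, y)` coordinates.
#' @return n x 2 matrix of transformed coordinates.
#' @export
st_apply <- function(tf, xy) {
  stopifnot(inherits(tf, "SimilarityTransform"))
  xy <- matrix(as.numeric(xy), ncol = 2)
  cs <- cos(tf$rotation); sn <- sin(tf$rotation); s <- tf$scale
  cbind(s * (cs * xy[, 1] - sn * xy[, 2]) + tf$translation[1],
        s * (sn * xy[, 1] + cs * xy[, 2]) + tf$translation[2])
}

#' Invert a similarity transform
#'
#' @param tf A `SimilarityTransform`.
#' @return The inverse `SimilarityTransform`.
#' @export
st_inverse <- function(tf) {
  stopifnot(inherits(tf, "SimilarityTransform"))
  s <- 1 / tf$scale; th <- -tf$rotation
  cs <- cos(th); sn <- sin(th)
  tx <- -s * (cs * tf$translation[1] - sn * tf$translation[2])
  ty <- -s * (sn * tf$translation[1] + cs * tf$translation[2])
  similarity_transform(s, th, c(tx, ty))
}

#' Compose two similarity transforms
#'
#' Returns the transform equivalent to applying `b` first, then `a`.
#'
#' @param a,b `SimilarityTransform` objects.
#' @return A `SimilarityTransform`.
#' @export
st_compose <- function(a, b) {
  stopifnot(inherits(a, "SimilarityTransform"),
            inherits(b, "SimilarityTransform"))
  t_new <- st_apply(a, matrix(b$translation, ncol = 2))
  similarity_transform(a$scale * b$scale, a$rotation + b$rotation,
                       as.numeric(t_new))
}

#' @export
print.SimilarityTransform <- function(x, ...) {
  cat(sprintf(
    "<SimilarityTransform> scale=%.6g rotation=%.6g rad translation=(%.6g, %.6g)\n",
    x$scale, x$rotation, x$translation[1], x$translation[2]))
  invisible(x)
}

PAIR_DIRECTIONS <- c("A_TO_B", "B_TO_A", "SYMMETRIZED")

#' Construct a PairDistance record
#'
#' The two-component similarity record for a protein pair: the mean-squared
#' pixel distance between mutually defined pixels of the base and registered
#' susceptibility images (the "Euclidean distance" in output tables), and the
#' count of union-gap pixels normalized by the image size.
#'
#' @param id_a,id_b Protein identifiers. For `SYMMETRIZED` records the ids are
#'   stored in sorted order so that the record is invariant under swapping.
#' @param euclidean Nonnegative mean-squared pixel distance.
#' @param gap_measure Normalized gap count in [0, 1].
#' @param direction One of `"A_TO_B"`, `"B_TO_A"`, `"SYMMETRIZED"`.
#' @return A `PairDistance`.
#' @export
pair_distance <- function(id_a, id_b, euclidean, gap_measure,
                          direction = "SYMMETRIZED") {
  direction <- match.arg(direction, PAIR_DIRECTIONS)
  euclidean <- as.numeric(euclidean)[1]
  gap_measure <- as.numeric(gap_measure)[1]
  if (!is.finite(euclidean) || euclidean < 0)
    stop("PairDistance: euclidean must be a nonnegative real")
  if (!is.finite(gap_measure) || gap_measure < -1e-12 ||
      gap_measure > 1 + 1e-12)
    stop("PairDistance: gap_measure must lie in [0, 1]")
  ids <- c(as.character(id_a)[1], as.character(id_b)[1])
  if (direction == "SYMMETRIZED") ids <- sort(ids)
  structure(list(id_a = ids[1], id_b = ids[2], euclidean = euclidean,
                 gap_measure = min(max(gap_measure, 0), 1),
                 direction = direction),
            class = "PairDistance")
}

#' @export
print.PairDistance <- function(x, ...) {
  cat(sprintf("<PairDistance %s-%s [%s]> euclidean=%.6g gap_measure=%.6g\n",
              x$id_a, x$id_b, x$direction, x$euclidean, x$gap_measure))
  invisible(x)
}
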
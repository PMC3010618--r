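#' Dynamic time warping between two flexibility signals
#'
#' Aligns two 1D signals of possibly different lengths with the classical
#' dynamic-programming recurrence
#' `DTW(i, j) = d(i, j) + min(DTW(i, j-1), DTW(i-1, j-1), DTW(i-1, j))`
#' with local cost `d(i, j) = (s1[i] - s2[j])^2` (squared difference, no
#' square root anywhere), filled forward iteratively with boundary
#' `DTW(1, 1) = d(1, 1)` and cumulative sums along the first row and column.
#' The warping path is continuous and monotone, spans both signals end to
#' end, and is recovered by backtracking. When predecessors tie, the diagonal
#' step is preferred, then the step advancing `i`, then the step advancing
#' `j`; the tie-break affects only the reported path, never the distance.
#'
#' Gap positions are removed from each signal before alignment (off-scale
#' sentinels would dominate the squared cost); indices in the returned path
#' refer to the gap-compressed signals.
#'
#' @param s1,s2 `FlexibilitySignal` objects (or bare numeric vectors, which
#'   are wrapped as gap-free `OTHER` signals).
#' @param normalize `"RAW"` (default; the cumulative cost `DTW(n, m)`) or
#'   `"PATH_LENGTH"` (cumulative cost divided by the number of path steps).
#' @return A `DTWResult`: list with `distance`, `path` (k x 2 integer matrix
#'   of aligned index pairs, 1-based), `n`, `m_len`, and `normalize`.
#' @export
dtw_distance <- function(s1, s2, normalize = c("RAW", "PATH_LENGTH")) {
  normalize <- match.arg(normalize)
  a <- signal_live_values(s1)
  b <- signal_live_values(s2)
  n <- length(a); m <- length(b)
  if (n == 0L || m == 0L)
    stop("dtw_distance: signal empty after gap compression")

  # local cost matrix, Eq-(3)-style squared differences
  d <- outer(a, b, function(x, y) (x - y)^2)
  D <- matrix(NA_real_, n, m)
  D[1, 1] <- d[1, 1]
  if (n > 1) D[, 1] <- cumsum(d[, 1])
  if (m > 1) D[1, ] <- cumsum(d[1, ])
  if (n > 1 && m > 1) {
    for (i in 2:n) {
      for (j in 2:m) {
        D[i, j] <- d[i, j] + min(D[i, j - 1], D[i - 1, j - 1], D[i - 1, j])
      }
    }
  }

  # backtrack; preference diagonal > (i-1, j) > (i, j-1) on ties
  path <- matrix(c(n, m), 1, 2)
  i <- n; j <- m
  while (i > 1L || j > 1L) {
    if (i == 1L) {
      j <- j - 1L
    } else if (j == 1L) {
      i <- i - 1L
    } else {
      cand <- c(D[i - 1, j - 1], D[i - 1, j], D[i, j - 1])
      k <- which.min(cand)  # which.min takes the first minimum: diag first
      if (k == 1L) { i <- i - 1L; j <- j - 1L }
      else if (k == 2L) i <- i - 1L
      else j <- j - 1L
    }
    path <- rbind(c(i, j), path)
  }

  dist <- D[n, m]
  if (normalize == "PATH_LENGTH") dist <- dist / nrow(path)
  structure(list(distance = dist, path = path, n = n, m_len = m,
                 normalize = normalize),
            class = "DTWResult")
}

signal_live_values <- function(s) {
  if (inherits(s, "FlexibilitySignal")) return(s$values[!s$gap_mask])
  as.numeric(s)
}

#' @export
print.DTWResult <- function(x, ...) {
  cat(sprintf("<DTWResult> distance=%.6g (%s) n=%d m=%d path length=%d\n",
              x$distance, x$normalize, x$n, x$m_len, nrow(x$path)))
  invisible(x)
}

#' All-pairs DTW distance table
#'
#' Computes the symmetric table of DTW distances between every pair of
#' signals of a common kind. The diagonal (self-distance, trivially zero) is
#' reported as `NA`, mirroring the "*" convention of printed distance tables.
#'
#' @param signals List of `FlexibilitySignal` objects, all of the same kind,
#'   length >= 2. Names default to the signals' `protein_id`s.
#' @inheritParams dtw_distance
#' @return A symmetric numeric matrix with `NA` diagonal and protein ids as
#'   dimnames.
#' @export
pairwise_signal_distances <- function(signals,
                                      normalize = c("RAW", "PATH_LENGTH")) {
  normalize <- match.arg(normalize)
  k <- length(signals)
  if (k < 2L) stop("pairwise_signal_distances: need >= 2 signals")
  stopifnot(all(vapply(signals, inherits, TRUE, "FlexibilitySignal")))
  kinds <- vapply(signals, function(s) s$kind, "")
  if (length(unique(kinds)) != 1L)
    stop("pairwise_signal_distances: mixed signal kinds: ",
         paste(unique(kinds), collapse = ", "))
  ids <- vapply(signals, function(s) s$protein_id, "")
  tab <- matrix(NA_real_, k, k, dimnames = list(ids, ids))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      v <- dtw_distance(signals[[i]], signals[[j]], normalize)$distance
      tab[i, j] <- v
      tab[j, i] <- v
    }
  }
  tab
}
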
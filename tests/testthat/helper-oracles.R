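# Independent oracles and tiny fixture builders used across test files.

# Exhaustive DTW: enumerate every monotone, continuous warping path from
# (1,1) to (n,m) with steps (1,0), (0,1), (1,1) and return the minimum
# cumulative squared-difference cost. Intentionally brute force -- kept
# independent of the package's dynamic program. Usable for lengths <= ~7.
dtw_enumerate <- function(a, b) {
  n <- length(a); m <- length(b)
  best <- Inf
  recurse <- function(i, j, cost) {
    cost <- cost + (a[i] - b[j])^2
    if (cost >= best) return(invisible())  # prune only on >=, cannot miss min
    if (i == n && j == m) {
      best <<- cost
      return(invisible())
    }
    if (i < n && j < m) recurse(i + 1, j + 1, cost)
    if (i < n) recurse(i + 1, j, cost)
    if (j < m) recurse(i, j + 1, cost)
  }
  recurse(1, 1, 0)
  best
}

# Literal per-pixel, per-realization variance recomputation.
susceptibility_oracle <- function(ens) {
  m <- ens$m
  chi <- matrix(0, m, m)
  for (j in seq_len(m)) {
    for (k in seq_len(m)) {
      v <- vapply(ens$realizations, function(M) as.numeric(M[j, k]), 0)
      chi[j, k] <- mean(v^2) - mean(v)^2
    }
  }
  chi
}

# Literal sweep-by-sweep simulation of 8-neighbor gap filling.
interpolate_oracle <- function(chi, gaps) {
  m <- nrow(chi)
  filled <- !gaps
  chi[gaps] <- NA
  while (any(!filled)) {
    new_chi <- chi; new_filled <- filled
    for (r in seq_len(m)) for (c in seq_len(m)) {
      if (filled[r, c]) next
      vals <- c()
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        rr <- r + dr; cc <- c + dc
        if (rr >= 1 && rr <= m && cc >= 1 && cc <= m && filled[rr, cc])
          vals <- c(vals, chi[rr, cc])
      }
      if (length(vals)) {
        new_chi[r, c] <- mean(vals)
        new_filled[r, c] <- TRUE
      }
    }
    chi <- new_chi; filled <- new_filled
  }
  chi
}

# Random valid rigidity ensemble: symmetric, {-1,0,1}, diag -1.
random_ensemble <- function(m, R, id = "rand") {
  reals <- lapply(seq_len(R), function(r) {
    M <- matrix(0L, m, m)
    up <- upper.tri(M)
    M[up] <- sample(c(-1L, 0L, 1L), sum(up), replace = TRUE)
    M[lower.tri(M)] <- t(M)[lower.tri(M)]
    diag(M) <- -1L
    M
  })
  rigidity_ensemble(id, reals)
}

# 2x2 ensemble whose off-diagonal state follows the given value sequence.
pair_ensemble <- function(vals, id = "pair") {
  rigidity_ensemble(id, lapply(vals, function(v) {
    matrix(c(-1L, as.integer(v), as.integer(v), -1L), 2, 2)
  }))
}

tiny_image <- function(chi, gaps = NULL, id = "img") {
  chi <- as.matrix(chi)
  if (is.null(gaps)) gaps <- matrix(FALSE, nrow(chi), ncol(chi))
  structure(list(protein_id = id, chi = chi, gap_mask = gaps,
                 m = nrow(chi)),
            class = "SusceptibilityImage")
}

random_signal <- function(n, kind = "OTHER", id = "s") {
  flexibility_signal(id, runif(n), kind = kind)
}
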
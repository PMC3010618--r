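#' Specification of a synthetic protein family
#'
#' The generator emulates the outputs of an ensemble-based rigidity model:
#' as hydrogen-bond-like constraints form and break across realizations,
#' contiguous blocks of torsion-angle positions toggle between being
#' rigidly/flexibly correlated and uncorrelated. Family members share the
#' same block layout up to small member-specific boundary jitter, so they
#' are similar but distinct -- the structure the comparison pipeline is
#' meant to resolve.
#'
#' Defaults describe a realistic desk-scale family: 3 members (families of
#' three), `m = 200` torsion positions (two per residue for a ~100-residue
#' protein), 200 equilibrium realizations, a 30% per-realization chance that
#' a block toggles off (`flip_prob`), 10% boundary-mutation rate between
#' members, and 10% gap pixels (union gap fractions then land in the 0.1-0.4
#' range typical of real comparisons).
#'
#' @param n_proteins Number of family members (>= 1).
#' @param m Number of torsion-angle positions (image/signal dimension).
#' @param n_realizations Ensemble size per member.
#' @param blocks Data frame with columns `start`, `end`, `kind`
#'   (`"RIGID"`/`"FLEXIBLE"`), non-overlapping, within `[1, m]`. `NULL`
#'   yields a default three-block layout scaled to `m`.
#' @param flip_prob Per-realization probability that a block is inactive
#'   (uncorrelated) rather than active, in [0, 1].
#' @param mutation_rate Per-block probability that a member's block
#'   boundaries are jittered, in [0, 1]; the jitter amplitude also scales
#'   with this rate.
#' @param gap_frac Fraction of gap positions/pixels inserted by the
#'   generators that add gaps, in [0, 1].
#' @param seed Integer master seed; every generator draws from substreams
#'   derived from (`seed`, member index), so outputs are bit-reproducible.
#' @return A `SyntheticFamilySpec`.
#' @export
synthetic_family_spec <- function(n_proteins = 3, m = 200,
                                  n_realizations = 200, blocks = NULL,
                                  flip_prob = 0.3, mutation_rate = 0.1,
                                  gap_frac = 0.1, seed = 1) {
  if (is.null(blocks)) {
    blocks <- data.frame(
      start = pmax(1L, as.integer(round(m * c(0.05, 0.40, 0.72)))),
      end = pmin(m, as.integer(round(m * c(0.30, 0.65, 0.95)))),
      kind = c("RIGID", "FLEXIBLE", "RIGID"),
      stringsAsFactors = FALSE)
  }
  blocks <- as.data.frame(blocks, stringsAsFactors = FALSE)
  stopifnot(all(c("start", "end", "kind") %in% names(blocks)))
  blocks$kind <- toupper(blocks$kind)
  obj <- structure(
    list(n_proteins = as.integer(n_proteins), m = as.integer(m),
         n_realizations = as.integer(n_realizations), blocks = blocks,
         flip_prob = as.numeric(flip_prob),
         mutation_rate = as.numeric(mutation_rate),
         gap_frac = as.numeric(gap_frac), seed = as.integer(seed)),
    class = "SyntheticFamilySpec")
  validate_family_spec(obj)
}

#' @rdname synthetic_family_spec
#' @param spec A `SyntheticFamilySpec`.
#' @export
validate_family_spec <- function(spec) {
  stopifnot(inherits(spec, "SyntheticFamilySpec"))
  with(spec, {
    if (n_proteins < 1) stop("SyntheticFamilySpec: n_proteins must be >= 1")
    if (m < 4) stop("SyntheticFamilySpec: m must be >= 4")
    if (n_realizations < 1)
      stop("SyntheticFamilySpec: n_realizations must be >= 1")
    for (p in c(flip_prob, mutation_rate, gap_frac))
      if (is.na(p) || p < 0 || p > 1)
        stop("SyntheticFamilySpec: probabilities must lie in [0, 1]")
    b <- blocks[order(blocks$start), ]
    if (any(!b$kind %in% c("RIGID", "FLEXIBLE")))
      stop("SyntheticFamilySpec: block kind must be RIGID or FLEXIBLE")
    if (any(b$start < 1) || any(b$end > m) || any(b$start > b$end))
      stop("SyntheticFamilySpec: blocks must satisfy 1 <= start <= end <= m")
    if (nrow(b) > 1 && any(b$start[-1] <= b$end[-nrow(b)]))
      stop("SyntheticFamilySpec: blocks must not overlap")
  })
  spec
}

# Independent 31-bit substream seeds per (spec seed, member, stream).
# Member-specific randomness is confined to the block-jitter stream: the
# realization/signal noise streams are family-level, so that with
# mutation_rate = 0 all members are bit-identical and every between-member
# difference is attributable to block mutations.
member_seed <- function(spec, member_index, stream) {
  v <- (as.numeric(spec$seed) * 1000003 + as.numeric(member_index) * 7919 +
          stream * 104729) %% 2147483629
  as.integer(v) + 1L
}

family_seed <- function(spec, stream) member_seed(spec, 0, stream)

# Member-specific block layout: each block is jittered with probability
# mutation_rate; jitter amplitude grows with mutation_rate so the rate acts
# as an overall divergence dial. Overlaps after jitter are trimmed.
member_blocks <- function(spec, member_index) {
  set.seed(member_seed(spec, member_index, 1))
  b <- spec$blocks[order(spec$blocks$start), , drop = FALSE]
  s_amp <- max(1L, as.integer(round(0.15 * spec$m * spec$mutation_rate)))
  for (i in seq_len(nrow(b))) {
    if (stats::runif(1) < spec$mutation_rate) {
      b$start[i] <- b$start[i] + sample(-s_amp:s_amp, 1)
      b$end[i] <- b$end[i] + sample(-s_amp:s_amp, 1)
    }
  }
  b$start <- pmin(pmax(b$start, 1L), spec$m)
  b$end <- pmin(pmax(b$end, 1L), spec$m)
  b <- b[b$start <= b$end, , drop = FALSE]
  if (nrow(b) > 1) {
    for (i in 2:nrow(b)) {
      if (b$start[i] <= b$end[i - 1]) b$start[i] <- b$end[i - 1] + 1L
    }
    b <- b[b$start <= b$end & b$start <= spec$m, , drop = FALSE]
  }
  b
}

#' Generate a synthetic rigidity-state ensemble for one family member
#'
#' Each realization assigns `n_jk = -1` to pairs inside an active RIGID
#' block, `+1` inside an active FLEXIBLE block, and `0` otherwise (diagonal
#' always `-1`). A block is active with probability `1 - flip_prob` per
#' realization, so `flip_prob = 0` gives identical realizations (and a
#' susceptibility of exactly zero downstream), while `flip_prob = 0.5`
#' maximizes the block-interior fluctuation. Deterministic given
#' (`spec$seed`, `member_index`).
#'
#' @param spec A `SyntheticFamilySpec`.
#' @param member_index 0-based member index, `< spec$n_proteins`.
#' @return A validated `RigidityStateEnsemble`.
#' @export
generate_ensemble <- function(spec, member_index = 0) {
  validate_family_spec(spec)
  if (member_index < 0 || member_index >= spec$n_proteins)
    stop("generate_ensemble: member_index must be in [0, n_proteins)")
  b <- member_blocks(spec, member_index)
  set.seed(family_seed(spec, 2))   # family-level: see member_seed
  m <- spec$m
  nb <- nrow(b)
  reals <- vector("list", spec$n_realizations)
  for (r in seq_len(spec$n_realizations)) {
    M <- matrix(0L, m, m)
    active <- stats::runif(nb) >= spec$flip_prob
    for (i in seq_len(nb)) {
      if (!active[i]) next
      idx <- b$start[i]:b$end[i]
      M[idx, idx] <- if (b$kind[i] == "RIGID") -1L else 1L
    }
    diag(M) <- -1L
    reals[[r]] <- M
  }
  rigidity_ensemble(sprintf("synthetic-%d", member_index), reals)
}

#' Generate a synthetic IDF-like flexibility signal for one family member
#'
#' A nonnegative piecewise signal of length `m`: near zero inside RIGID
#' blocks, elevated with high-frequency variation inside FLEXIBLE blocks,
#' and at an intermediate level elsewhere. Uses the same member-specific
#' block layout as [generate_ensemble()], so the 1D and 2D views of a
#' member agree. A fraction `gap_frac` of positions is marked as gaps.
#'
#' @inheritParams generate_ensemble
#' @return A `FlexibilitySignal` of kind `"IDF"`.
#' @export
generate_idf_signal <- function(spec, member_index = 0) {
  validate_family_spec(spec)
  b <- member_blocks(spec, member_index)
  set.seed(family_seed(spec, 3))   # family-level: see member_seed
  m <- spec$m
  vals <- 0.30 + 0.05 * abs(stats::rnorm(m))
  for (i in seq_len(nrow(b))) {
    idx <- b$start[i]:b$end[i]
    if (b$kind[i] == "RIGID") {
      vals[idx] <- 0.02 + 0.01 * abs(stats::rnorm(length(idx)))
    } else {
      vals[idx] <- pmax(0, 0.70 + 0.20 * sin(2 * pi * seq_along(idx) / 3) +
                          0.08 * stats::rnorm(length(idx)))
    }
  }
  n_gap <- as.integer(round(spec$gap_frac * m))
  gaps <- rep(FALSE, m)
  if (n_gap > 0) gaps[sample.int(m, n_gap)] <- TRUE
  flexibility_signal(sprintf("synthetic-%d", member_index), vals,
                     kind = "IDF", gap_mask = gaps)
}

# symmetric random gap mask with approximately frac gap pixels
random_symmetric_mask <- function(m, frac) {
  gm <- matrix(FALSE, m, m)
  if (frac <= 0) return(gm)
  ut <- which(upper.tri(gm, diag = TRUE))
  pick <- ut[stats::runif(length(ut)) < frac]
  gm[pick] <- TRUE
  gm | t(gm)
}

#' Generate a base/moving image pair related by a known transform
#'
#' Builds a base susceptibility image from member 0 of `spec`, then a moving
#' image by resampling the base under the given similarity transform
#' (`moving(p) = base(T(p))`, bicubic), so that registering the moving image
#' onto the base with transform `T` recovers the base up to interpolation
#' error. Gaussian pixel noise (`noise_sd`) is added to the moving image and
#' symmetric random gap masks covering about `gap_frac` of the pixels are
#' inserted into both images. Exact control points derived from `T` are
#' returned alongside.
#'
#' Note the moving image is in general not symmetric (a warped symmetric
#' matrix is not), which is why it is returned as a raw image object rather
#' than passed through the susceptibility-image validator.
#'
#' @param spec A `SyntheticFamilySpec`.
#' @param transform A `SimilarityTransform` mapping moving coordinates into
#'   base coordinates.
#' @param noise_sd Nonnegative pixel-noise standard deviation.
#' @return List with elements `base` and `moving` (`SusceptibilityImage`s of
#'   dimension `spec$m`) and `control_points` (4 x 4 matrix usable with
#'   [compare_pair()], moving coordinates first).
#' @export
generate_registered_pair <- function(spec, transform = similarity_transform(),
                                     noise_sd = 0) {
  validate_family_spec(spec)
  stopifnot(inherits(transform, "SimilarityTransform"), noise_sd >= 0)
  base <- compute_susceptibility(generate_ensemble(spec, 0))
  m <- spec$m
  idx <- seq_len(m)
  g <- expand.grid(y = idx, x = idx)
  src <- st_apply(transform, cbind(g$x, g$y))
  outside <- src[, 1] < 0.5 | src[, 1] > m + 0.5 |
    src[, 2] < 0.5 | src[, 2] > m + 0.5
  vals <- bicubic_sample(base$chi, src[, 1], src[, 2])
  set.seed(family_seed(spec, 4))
  if (noise_sd > 0) vals <- vals + stats::rnorm(length(vals), 0, noise_sd)
  vals <- pmin(pmax(vals, 0), 1)
  chi_mov <- matrix(vals, m, m)
  gm_mov <- matrix(outside, m, m) | random_symmetric_mask(m, spec$gap_frac)
  chi_mov[gm_mov] <- 0
  moving <- structure(list(protein_id = paste0(base$protein_id, "-moved"),
                           chi = chi_mov, gap_mask = gm_mov, m = m),
                      class = "SusceptibilityImage")
  gm_base <- base$gap_mask | random_symmetric_mask(m, spec$gap_frac)
  chi_base <- base$chi; chi_base[gm_base] <- 0
  base <- structure(list(protein_id = base$protein_id, chi = chi_base,
                         gap_mask = gm_base, m = m),
                    class = "SusceptibilityImage")
  q <- round(m / 4); t3 <- round(3 * m / 4)
  pm <- cbind(c(q, t3, q, t3), c(q, q, t3, t3))
  pb <- st_apply(transform, pm)
  cp <- cbind(pm, pb)
  colnames(cp) <- c("x_moving", "y_moving", "x_base", "y_base")
  list(base = base, moving = moving, control_points = cp)
}
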
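#' Rigidity susceptibility from an ensemble of rigidity states
#'
#' The rigidity susceptibility chi_jk is the variance of the pairwise
#' rigidity state n_jk in \{-1, 0, +1\} over the ensemble of realizations:
#' `chi_jk = <n_jk^2> - <n_jk>^2`, with unweighted means over the supplied
#' realizations (realizations are assumed to be equilibrium samples; any
#' thermodynamic weighting belongs to whatever generated them). Because n_jk
#' is bounded in [-1, 1], chi_jk lies in [0, 1] by construction: 0 for a
#' frozen pair, 1 for a pair alternating evenly between rigidly (-1) and
#' flexibly (+1) correlated.
#'
#' @param ens A `RigidityStateEnsemble`.
#' @return A gap-free `SusceptibilityImage` of the same dimension.
#' @export
compute_susceptibility <- function(ens) {
  validate_ensemble(ens)
  R <- length(ens$realizations)
  m <- ens$m
  s1 <- matrix(0, m, m)
  s2 <- matrix(0, m, m)
  for (M in ens$realizations) {
    s1 <- s1 + M
    s2 <- s2 + M * M   # entries in {0, 1}
  }
  chi <- s2 / R - (s1 / R)^2
  # guard tiny negative rounding residue on frozen pairs
  chi[chi < 0 & chi > -1e-12] <- 0
  susceptibility_image(ens$protein_id, chi)
}
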
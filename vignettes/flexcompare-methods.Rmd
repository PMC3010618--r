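---
title: "Methods: comparing proteins by their flexibility characteristics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparing proteins by their flexibility characteristics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flexcompare)
```

## The problem

Ensemble-based rigidity models of proteins (distance-constraint models, in
which covalent bonds, hydrogen bonds and residue conformational states form
a fluctuating constraint network) output rich flexibility characteristics:
a sharp, nonnegative one-dimensional signal giving the density of
independent degrees of freedom (IDF) along the backbone, and a symmetric
two-dimensional *rigidity susceptibility* image quantifying how rigidity
and flexibility fluctuations propagate between pairs of positions. Within a
protein family these characteristics "look similar but have distinct
features", and eyeballing plots does not quantify that. flexcompare turns
the comparison into numbers:

* **1D signals** are aligned and scored with dynamic time warping (DTW),
  which tolerates the different lengths of homologous proteins.
* **2D susceptibility images** are registered onto each other with a
  similarity transform (scale + rotation + translation, preserving straight
  lines and parallelism) and then scored with two complementary measures: a
  mean-squared pixel distance over mutually defined pixels, and a
  normalized count of gap pixels.

The elementary positions are backbone torsion angles: each residue
contributes two (PHI and PSI), so a 100-residue protein yields signals and
images of dimension about 200.

## Rigidity states and susceptibility

For a pair of positions $(j, k)$ the rigidity state is
$n_{jk} \in \{-1, 0, +1\}$: $-1$ when both lie in one rigid region, $+1$
when one flexible region spans both (flexibly correlated), $0$ when the
pair is uncorrelated (e.g. dangling ends). Over the ensemble of
realizations the susceptibility is the variance

$$\chi_{jk} = \langle n_{jk}^2 \rangle - \langle n_{jk} \rangle^2,
\qquad 0 \le \chi_{jk} \le 1 .$$

`compute_susceptibility()` uses unweighted means over the supplied
realizations: we assume the realizations are already equilibrium samples,
so any thermodynamic weighting is the job of whatever generated them, not
of this formula. The diagonal $n_{jj}$ is not defined by the modelling
literature we follow; we require $-1$ (a position is trivially rigid with
itself), which makes $\chi_{jj} = 0$ and never enters pair distances in a
special way.

## DTW on 1D signals

The cumulative cost is the classical recurrence
$DTW(i,j) = d(i,j) + \min(DTW(i,j{-}1), DTW(i{-}1,j{-}1), DTW(i{-}1,j))$
with local cost $d(i,j) = (s_1(i) - s_2(j))^2$. We fill it *forward*
(iterative dynamic programming, $O(nm)$ time and memory — signals are a
few hundred points, so no banding is needed) rather than by recursion, and
backtrack for the warping path. Numerical choices:

* **No square root anywhere.** The reported distance is the cumulative sum
  of squared increments, exactly as the recurrence defines it. We expose
  `normalize = "RAW"` (default) and `"PATH_LENGTH"` (divided by the number
  of path steps); raw and normalized differ only by that factor.
* **Tie-breaking** during backtracking prefers the diagonal predecessor,
  then the step advancing $i$, then the step advancing $j$. This fixes a
  deterministic path; it can never change the distance.
* **Gaps are compressed out** of each signal before alignment. Off-scale
  sentinel values would dominate the squared cost, and there is no
  principled DTW gap rule for this data; dropping undefined positions is
  the conservative choice.

Hydrophobicity signals are built by mapping each residue of a sequence
through a scale; the built-in default is Kyte–Doolittle, and any complete
20-code scale can be substituted (`hydrophobicity_scale()`), so the mapping
is always explicit. `'X'` residues become gap positions.

## Image registration

For a pair of susceptibility images, each image in turn serves as the base
while the other is registered to it; the two directional results are
averaged into one symmetrized record (`compare_pair()`). One direction
runs:

1. **Gap interpolation** (`interpolate_gaps()`): undefined pixels receive
   the arithmetic mean of their non-missing neighbors. We use the
   8-connected neighborhood and Jacobi-style sweeps (values frozen per
   sweep, repeated until closure): "neighbors" is otherwise ambiguous, the
   8-neighborhood fills diagonal-only contacts, and frozen sweeps make the
   result independent of pixel order while filling large gap blocks front
   by front. The original gap mask is retained for the gap measure.
2. **Resizing** (`resize_image()`): the moving image is resampled to the
   base dimension with bicubic (cubic-convolution, Keys $a=-0.5$)
   interpolation, which has smooth transitions and few artifacts; values
   are clamped back to $[0,1]$ because cubic kernels overshoot at sharp
   edges. The gap mask is resampled by nearest neighbor. Pixel centers sit
   at integers, borders are replicate-padded; resizing to the same size is
   the identity and linear ramps are reproduced exactly away from borders
   (both are tested).
3. **Landmark fit** (`fit_similarity()`): control points (manual landmarks
   or generator-derived exact points) determine the least-squares
   similarity transform; with the parameterization
   $x_b = a x_m - b y_m + t_x$, $y_b = b x_m + a y_m + t_y$ the fit is
   linear, and two distinct points determine it exactly.
4. **Refinement** (`refine_by_maximum_similarity()`): the original
   "maximum similarity" optimizer we model was a customized MATLAB routine
   whose algorithm is not described, so our refinement is a declared
   stand-in: deterministic coordinate-wise descent over (scale, rotation,
   $t_x$, $t_y$) with halving steps, bounded iterations, and a parameter
   box around the initial fit. The box matters: because the printed
   distance divides by $m^2$ rather than by the count of defined pixels,
   pushing the moving image off the canvas would spuriously shrink the
   distance; bounding the search near the landmark fit (scale within a
   factor 1.3, rotation within 0.3 rad, translation within $m/8$ px)
   prevents that degenerate drift. The refined transform is never worse
   than the initial one under the objective.
5. **Warp and measure**: the moving image is resampled bicubically under
   the inverse transform; pixels mapping outside the source extent become
   gaps, consistent with treating unmatched regions as gaps. Then

   $$d(\mathrm{im}_i, \mathrm{im}_j) = \frac{1}{m^2}
     \sum_{x,y} (\mathrm{im}_i(x,y) - \mathrm{im}_j(x,y))^2$$

   summed over pixels where **both** images are defined. The denominator
   is $m^2$ exactly as the formula is printed — not the number of defined
   pixels — and the **gap measure** (union gap count over $m^2$)
   accompanies it precisely to account for the gap burden the first
   measure ignores. Output tables keep the conventional label "Euclidean
   distance" even though the printed formula takes no square root.

Susceptibility images are square and symmetric, so rotation is expected to
be $\approx 0$; it stays in the model because similarity registration is
the specified transform class. Only square images are accepted. Warped
intermediates are generally *not* symmetric, which is why the registration
chain does not re-validate the symmetry invariant of true susceptibility
images.

## The synthetic family generator

No reference model outputs are deposited for the nine proteins the method
was demonstrated on, so the package ships a generator
(`synthetic_family_spec()`, `generate_ensemble()`, `generate_idf_signal()`,
`generate_registered_pair()`) that emulates the block-fluctuation picture:
contiguous blocks of positions are rigidly or flexibly correlated, and
blocks toggle off with probability `flip_prob` per realization as
hydrogen-bond-like constraints break. Defaults state a realistic
desk-scale world and are not tuned to tests: 3 members per family, $m=200$
(two torsion entries per residue of a ~100-residue protein), 200
equilibrium realizations, `flip_prob = 0.3`, `mutation_rate = 0.1`,
`gap_frac = 0.1` (two independent ~10% masks give union gap fractions
around $1 - 0.9^2 = 0.19$, inside the 0.1–0.4 range typical of real
comparisons).

Design choices worth knowing:

* **Mutations are the only between-member difference.** Member-specific
  randomness is confined to block-boundary jitter (applied per block with
  probability `mutation_rate`, amplitude $0.15\,m\cdot$`mutation_rate`);
  realization and signal noise streams are family-level. Hence
  `mutation_rate = 0` gives bit-identical members and exactly zero
  distances, and any positive distance is attributable to mutations — the
  property the separation tests rely on.
* Both fluctuation alphabets occur: RIGID blocks fluctuate on
  $\{-1, 0\}$ (variance $p(1-p) \le 0.25$), FLEXIBLE blocks on
  $\{+1, 0\}$; a balanced $\{-1, +1\}$ pair attains the maximum
  $\chi = 1$.
* Everything is a pure function of `(spec, member_index)`: substream seeds
  are derived from the single spec seed, so outputs are bit-reproducible.

What the generator does **not** emulate: hydrogen-bond energetics,
pebble-game rigidity propagation, heat-capacity fitting, or the long-range
correlation texture of real susceptibility images. A green synthetic test
establishes that the pipeline measures what it claims on data with known
ground truth — not that the measures are biologically discriminative.

## Degenerate inputs and numerical tolerances

* Matrix symmetry on read is enforced to $10^{-9}$; round-trips through the
  text formats preserve integers exactly and reals to better than
  $10^{-12}$ (written with 17 significant digits).
* All-gap images, empty signals (after gap compression), coincident
  control points, and mixed signal kinds are rejected with specific errors.
* When no control points are supplied and the images are commensurate,
  identity landmarks are used and the fallback is logged — this honors the
  manual-landmark design while letting synthetic runs be fully automatic.

## Known limitations

* The refinement optimizer is a stand-in (see above); with severely wrong
  landmarks it can stay in a local minimum.
* The mean-squared distance with the printed $m^2$ denominator *rewards*
  gaps when used alone; always read it jointly with the gap measure, as
  the output tables do.
* DTW distances across signal kinds or hydrophobicity scales are not
  comparable; tables are computed per kind.
* Printed reference distance values for the original nine proteins are not
  reproducible here because their model outputs and landmark choices were
  never deposited; the test suite is therefore property-based.
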
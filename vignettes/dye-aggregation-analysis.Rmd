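---
title: "Quantifying J-aggregation of rod-like dyes in periodic configurations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying J-aggregation of rod-like dyes in periodic configurations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jaggr)
```

## The problem

Cyanine dyes such as indocyanine green (ICG) self-assemble into two
spectroscopically opposite kinds of aggregate.  *J-aggregates* are
nematic-like stacks of near-parallel molecules in a slipped
("head-to-tail") arrangement; their absorption narrows and red-shifts
(for ICG from ~792 nm to ~892 nm).  *H-aggregates* are face-to-face
("card-pack") stacks and blue-shift instead.  Rigid, ordered lipid
bilayers can act as templates that favor the J arrangement; quantifying
that templating from simulated configurations requires a small set of
geometric statistics, all of which this package implements:

* the **pairwise orientational order parameter** resolved by
  center-of-mass (COM) separation,
  \( O(r) = \langle P_2(\cos\theta_{ij}) \rangle_{|r_{ij}| \approx r} \),
  where \(\theta_{ij}\) is the angle between the long molecular axes and
  \(P_2(x) = (3x^2-1)/2\).  \(O = 1\) for parallel or anti-parallel
  axes, \(0\) for uncorrelated orientations, \(-0.5\) for perpendicular
  ones;
* the **distribution of inter-axis angles** among close pairs (COM
  separation below the first-neighbor distance, ~10 Å);
* the **COM radial distribution function** \(g(r)\), used to read off
  the first-neighbor distance that justifies cutoffs;
* **single-linkage cluster statistics** at a distance cutoff (default
  17 Å, first plus second neighbors; minimum cluster size 2): per-frame
  membership percentages, cluster-size histograms, largest cluster;
* a **geometric J/H classification** of close pairs through the
  stacking angle between the pair's mean axis and the line joining the
  COMs: J below the magic angle 54.7° (the zero of \(P_2\)), H between
  54.7° and 90°.

All distances use the minimum image convention in an orthorhombic
periodic box; triclinic cells are rejected explicitly.

## Molecular reductions

A molecule is reduced to its mass-weighted COM and its *longest
principal axis*, computed as the dominant eigenvector of the
mass-weighted gyration (second-moment) tensor.  For rod-like molecules
this direction coincides with the smallest-moment-of-inertia axis; the
gyration form is numerically simpler and identical for the backbones we
target.  Two safeguards matter in practice:

* **degeneracy** — when the two largest gyration eigenvalues agree to a
  relative `1e-6` (e.g. a square or a sphere-like molecule), the axis is
  reported as an error rather than an arbitrary eigenvector;
* **sign** — an eigenvector has no intrinsic sign.  When a molecule
  carries a head/tail atom pair, the sign is fixed so the axis points
  head→tail and angle distributions run over the full 0–180° range;
  otherwise angles are folded to 0–90° and the output says so.  Which
  convention a published 0–180° distribution used is generally not
  recoverable from the figures; the head/tail rule here is this
  package's declared choice, and every statistic that matters
  (\(O(r)\), stacking angles, clustering) is even in the axis sign, so
  the choice does not affect them.

Molecules are assumed whole (not split across images); configurations
whose molecules span more than half the smallest box edge are rejected
at construction, because their COMs would be ambiguous.

## The synthetic-configuration generator

There is no public deposit of the bilayer/dye trajectories that motivate
these analyses, and regenerating them would require tens of nanoseconds
of atomistic simulation of ~100k-atom systems.  The generator therefore
produces rod ensembles with *known* ground truth, defaulting to the
geometry of the motivating system: 15 rod-like dye molecules (rigid
rods of 5 equal-mass pseudo-atoms spanning 20 Å, about the length of
the extended ICG backbone) in a 100 Å orthorhombic cell, with a minimum
COM separation of 3 Å so molecules do not interpenetrate.

* **Alignment mode** (`generate_aligned()`): each axis is drawn from
  the two-component mixture "exactly along the director with
  probability \(f\), isotropic otherwise".  Since \(P_2 = 1\) on the
  director and averages 0 under the isotropic component,
  \(\langle P_2(a\cdot n)\rangle = f\), so setting \(f = S\) realizes a
  target nematic order parameter *S* exactly in expectation — and for
  independent axes the Legendre addition theorem predicts a pairwise
  order of \(S^2\), which the test-suite verifies against a Monte-Carlo
  oracle (e.g. \(S = 0.8 \Rightarrow 0.64\)).  The mixture was chosen
  over, say, a Maier–Saupe distribution because its moments are exact
  and derivable by hand, which is what a ground-truth generator is for.
  It does produce an atom-thin sub-population of perfectly aligned
  molecules rather than a realistic smooth orientation distribution —
  a deliberate trade of realism for analytic transparency.
* **Slab confinement** (`slab_thickness`): restricts COM z-coordinates
  to a slab around mid-box, an implicit stand-in for adsorption at a
  bilayer; no lipid atoms are represented.
* **Clustered mode** (`generate_clustered()`): plants clusters whose
  members sit inside balls of diameter `intra_sep` (< cutoff, so all
  member pairs are directly linked) and keeps distinct clusters and
  isolated molecules farther apart than the cutoff plus a 0.5 Å margin.
  The returned labels are therefore *exactly* the single-linkage
  decomposition at that cutoff, which the cluster stage must round-trip.
* **Frames** are independent redraws standing in for an ensemble and
  time average.  Real trajectory frames are time-correlated; i.i.d.
  frames make standard errors smaller than an equally long correlated
  trajectory would.  Passing tests on this generator therefore
  demonstrate correctness of the estimators, not realistic error bars
  for MD data.
* **Determinism**: every mode is a pure function of its spec plus seed;
  placement failures (rejection budget of 1e5 draws per molecule)
  raise errors naming the density rather than silently overlapping.

## Numerical choices

* Distance bins are right-closed, `((i-1)w, iw]`, with a `1e-9`
  tolerance at edges so constructed fixtures sitting exactly on an edge
  do not drift a bin through floating-point noise.  Default widths:
  0.5 Å for \(O(r)\) and \(g(r)\), 5° for angles.
* Bins with no pairs are `NA` (undefined), never 0 — a zero would fake
  "random orientation" in \(O(r)\).
* Pair pooling: by default every pair observation across frames has
  equal weight ("pooled"), the most literal ensemble-and-time average;
  `average = "per_frame"` averages per-frame means instead.  The two
  agree when per-frame pair counts are equal, which the tests assert.
* \(g(r)\) uses the homogeneous-fluid normalization
  \(N(N-1)/2 \cdot 4\pi r^2 \Delta r / V\) per frame.  For
  slab-confined systems the 3D-homogeneity assumption is wrong in
  absolute scale (the `homogeneous` flag in the output records this);
  peak *positions*, which are what the first-neighbor logic needs,
  are unaffected.
* `first_neighbor_cutoff()` smooths \(g(r)\) with a 3-bin moving
  average and returns the right edge of the first peak's basin (first
  local minimum or first empty bin).  It is a justification tool for
  cutoffs, not a replacement for them: the cluster default stays 17 Å.
* The J/H boundary is tied to the order-parameter formalism: the zero
  of \(P_2\) on [0°, 90°] is located by bisection over two-rod fixtures
  (`jh_boundary_angle()`), converging to
  \(\arccos(1/\sqrt{3}) = 54.7356\ldots\)°, which matches the printed
  classification boundary 54.7° to one decimal.  In `classify_pair()`
  the boundary itself is assigned to H ("J" is the strict `< 54.7°`
  convention).
* The stacking angle uses the normalized bisector of the two
  sign-aligned axes, which is symmetric under swapping the molecules
  and robust for near-parallel pairs.  The exciton-model convention
  underlying the 54.7° rule assumes near-parallel transition dipoles;
  for inter-axis angles above 30° the classification is still reported
  but flagged `noncoplanar`.

## Cluster detection

Two molecules are linked when their minimum-image COM distance is at
most the cutoff; clusters are connected components with at least
`min_size` (default 2) members, labelled deterministically by smallest
member index.  COM-based distances were chosen for consistency with
\(O(r)\), which is also COM-resolved; a minimum-atom-distance variant
would link slightly earlier for long rods but requires the same
transitive machinery.  The implementation is a union-find over the
O(n²) distance matrix at every n: at the ensemble sizes this package
targets (tens to a few thousands of molecules) the vectorized distance
matrix is faster in interpreted R than a cell list, and one code path
is easier to prove correct — the test suite checks it against an
independent igraph + 27-image-enumeration oracle on hundreds of random
systems, including wraparound cases.

## Formulation metrics

The spectroscopy arithmetic used to characterize dye-loaded liposome
formulations is included so the geometric and spectroscopic sides of a
study can live in one analysis: the J-aggregate/monomer absorbance
ratio A892/A792 (nearest grid point within 0.5 nm, linear interpolation
otherwise; raw absorbances, no baseline correction), dye encapsulation
efficiency as `100 × encapsulated/initial` concentration, and drug
(doxorubicin) encapsulation efficiency as `100 × I_after/I_before`
fluorescence from detergent-solubilized, lipid-matched samples.  All are
invariant under rescaling a spectrum by a positive constant, and
degenerate denominators are errors, not NaNs.  Values above 100%
efficiency warn rather than fail: they occur in practice through
pipetting variance and should be seen, not silently clipped.

## Problem sizes used in validation

The bundled tests and the acceptance script run entirely on synthetic
fixtures at desk scale, chosen so the whole suite completes in a few
minutes: two-rod anchor fixtures; isotropic ensembles of 1000–2000
rods (up to 20 frames for the \(S^2\) recovery, giving a standard
error ≈ 0.004 on the pooled pairwise order); 200 random systems of at
most 50 molecules for the cluster oracle; 10⁵ axis pairs for the
random-orientation anchor.  Headline numbers for real bilayer
systems — cluster-membership percentages, or how high the \(O(r)\)
plateau sits below 10 Å in a rigid versus a fluid bilayer — come from
long atomistic simulations and are *not* reproduced here; what this
package guarantees is that, fed such trajectories, every estimator
computes the defined quantity exactly or within quantified sampling
error.

## Known limitations

* Orthorhombic boxes only; no triclinic support, no unwrapping of
  molecules split across images.
* The RDF normalization is 3D-homogeneous; slab systems get biased
  absolute \(g\) values (flagged, not corrected).
* No excitonic coupling calculation: the long geometric axis proxies
  the transition dipole, and the 54.7° rule is a geometric stand-in for
  a spectroscopic classification.
* Binary trajectory containers (DCD/XTC) are not read; frames arrive
  as multi-model PDB, GRO, or the package's tabular CSV format.
* No cluster kinetics: frames are analysed independently, with no
  tracking of merging or lifetimes.
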
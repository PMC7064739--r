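# jaggr

Geometric analysis of dye aggregation in periodic molecular
configurations: orientational order, cluster statistics, and J-/H-
aggregate classification, with a ground-truth synthetic generator.

## Why

Near-infrared cyanine dyes such as indocyanine green (ICG) form two
kinds of aggregate with opposite optical signatures: slipped,
nematic-like **J-aggregates** (red-shifted, for ICG 792 → 892 nm) and
face-to-face **H-aggregates** (blue-shifted).  Rigid lipid bilayers can
template the J arrangement.  Deciding which arrangement a simulated or
modelled ensemble adopted is a geometry problem, and `jaggr` provides
the standard statistics for it:

* **O(r)** — the pairwise orientational order parameter
  `O(r) = ⟨P₂(cos θᵢⱼ)⟩` over molecule pairs at center-of-mass (COM)
  separation *r*, with `P₂(x) = (3x² − 1)/2`: 1 for parallel or
  anti-parallel long axes, 0 for random orientation, −0.5 for
  perpendicular;
* **angle distributions** of close pairs (COM separation ≤ 10 Å by
  default), over 0–180° when a head/tail axis convention is available;
* **g(r)** — the COM radial distribution function, plus a data-driven
  first-neighbor cutoff from its first minimum;
* **cluster statistics** — single-linkage components at a distance
  cutoff (default 17 Å, minimum size 2): per-frame membership
  percentages, size histograms, largest cluster;
* **J/H classification** — per pair, by the stacking angle between the
  mean molecular axis and the inter-COM direction: J below the magic
  angle 54.7° (the zero of P₂), H between 54.7° and 90°;
* **formulation metrics** — the A892/A792 absorbance ratio and the two
  encapsulation-efficiency formulas used for dye/drug-loaded liposomes.

Everything runs under the minimum image convention in orthorhombic
periodic boxes.  Because the motivating bilayer trajectories are not
publicly deposited, the package ships a synthetic rod-configuration
generator with controllable nematic order *S*, slab confinement, and
planted clusters whose ground truth is exact by construction — every
analysis stage is validated against it and against independent oracles
(brute-force enumeration, SVD, igraph graph traversal).

## Worked example

```r
library(jaggr)

# 15 dye rods in a 150 A box: a planted 5-cluster, a dimer, 8 isolated
spec <- generator_spec(n_molecules = 15, order_target = 0.9,
                       planted_clusters = list(c(5, 12), c(2, 10)),
                       n_isolated = 8, box = c(150, 150, 150),
                       seed = 1, frames = 5)
gen <- generate_clustered(spec, cutoff = 17)

find_clusters(gen$trajectory[[1]], cluster_params(cutoff = 17, min_size = 2))
#> clusters at cutoff 17 Angstrom (min size 2): 2 cluster(s) of sizes {5, 2};
#>   46.7% of 15 molecules in clusters

op <- order_profile(gen$trajectory, bin_width = 0.5, r_max = 20)
occ <- which(op$pair_counts > 0 & op$bin_edges[-1] <= 10)
mean(op$o_values[occ])
#> [1] 0.847

s <- read_spectrum_csv(system.file("extdata", "icg_spectrum_synthetic.csv",
                                   package = "jaggr"))
ija_icg_ratio(s)   # A892 / A792
#> [1] 3.3
icg_ee(46.4, 180)  # percent dye encapsulated
#> [1] 25.78
```

Reading: at the planting cutoff the detector recovers exactly the
planted 5-cluster and dimer (7/15 = 46.7% membership); the strongly
aligned ensemble (S = 0.9) shows a high orientational order plateau
(0.85) below 10 Å, the nematic-stack signature; the synthetic ICG-like
spectrum has 3.3× more absorbance at the J-band than the monomer band;
and 46.4 µM encapsulated from a 180 µM input is a 25.78% encapsulation
efficiency.

Real structure files work the same way: `read_trajectory("sys.pdb",
selection = "ICG")` (PDB needs a CRYST1 record; GRO and a tabular CSV
format are also read), then the same analysis calls.  `run_pipeline()`
chains all stages and writes tidy CSVs plus a `summary.json`;
`inst/cli/jaggr.R` exposes the same steps as shell subcommands.

## Layout

* `R/` — generators, geometry primitives, order/cluster/classification
  analyses, spectra metrics, IO, pipeline
* `tests/testthat/` — unit, property and end-to-end tests with
  independent oracles
* `vignettes/dye-aggregation-analysis.Rmd` — the model, its
  assumptions, and the design decisions
* `inst/extdata/` — small synthetic text fixtures (GRO configuration,
  ICG-like spectrum)
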
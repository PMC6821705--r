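---
title: "Models and methods behind rnasurf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind rnasurf}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnasurf)
```

# The problem and the model

`rnasurf` treats RNA binding as a property of *locations* on a protein
surface rather than of residues or whole chains. Each location — a point
of a cubic lattice in the 2.5–5.0 Å band around the protein — is assigned
a normalized probability vector over seven classes: non-site (X) and the
six RNA constituents phosphate (P), ribose (R), adenine, guanine,
cytosine and uracil. The constituent view follows the chemistry of an RNA
nucleotide, which presents three distinct recognition surfaces: the
charged phosphodiester backbone, the sugar, and the base. Each is split
out of a bound nucleotide at the phosphodiester and glycosidic bonds, and
represented by the geometric centroid of its heavy atoms.

The classifier is *hierarchical*. Backbone contacts outnumber base
contacts severalfold in ribonucleoprotein structures, so a flat 7-class
model faces strong class imbalance. Level 1 therefore resolves the
balanced coarse problem {X, P, R, Base}; level 2, trained only on
base-labeled points, resolves {A, G, C, U}. The levels combine
multiplicatively, `p(b) = p1(Base) * p2(b)`, which guarantees the 7-class
vector is normalized whenever both levels are, and makes the sum of base
probabilities reproduce the coarse Base prior exactly — a property the
test suite asserts algebraically.

## Assumptions

* Binding preference is determined by the *protein-side* microenvironment
  alone: features are computed from protein heavy atoms only, with the
  RNA, solvent and ions stripped. The model can therefore be applied to
  apo structures.
* The 2.5–5.0 Å band captures where constituent centroids of bound RNA
  actually sit; closed interval on both ends (the boundary convention is a
  choice — the band is quoted in the literature without one).
* Local geometry within 7.5 Å suffices; longer-range electrostatics are
  only captured insofar as charged atoms fall inside the shells.

# Featurization

The environment of a location is a 6 × 80 tensor: six concentric shells
of equal 1.25 Å width within 7.5 Å (equal width is the canonical radial
convention for this family of encodings; the outer bound is half-open, so
a distance of exactly 7.5 Å contributes nothing), each accumulating 80
per-atom property values over the protein heavy atoms in that shell.

The 80-slot registry (`default_registry()`, version `rnasurf-80-v1`) is
an in-package reconstruction of the classic per-atom property list:
element indicators, a heavy-atom count, functional-group flags, backbone
and sidechain topology, the 20 residue-type indicators, residue-class
indicators, formal charges and a simplified partial-charge table,
hydrogen-bond donor/acceptor roles, secondary structure of the possessing
residue, Kyte–Doolittle hydropathy, solvent accessibility, size/electronic
constants and crystallographic mobility. The original list also carries
water/nucleic-acid/ion/ligand slots; since only protein atoms are
featurized those are kept as 13 documented `np_*` slots that always
evaluate to zero, padding the registry to exactly 80. The registry is
versioned, and trained models record the version that produced their
inputs; `predict_surface()` refuses a mismatch.

Two context-dependent slots are computed in-package rather than by
external programs, to keep the pipeline deterministic and dependency-free:

* **Secondary structure** from backbone dihedrals, with Ramachandran-box
  rules (helix: φ ∈ [−100°, −30°], ψ ∈ [−80°, −5°]; sheet:
  φ ∈ [−180°, −60°], ψ ≥ 90° or ψ ≤ −150°; everything else, including
  chain termini and degenerate geometries, coil).
* **Solvent accessibility** by a Shrake–Rupley rolling-probe
  approximation (probe 1.4 Å, 64 sphere points per atom, element-keyed
  van der Waals radii). Because the point sphere is fixed in the world
  frame, these two slots are only *approximately* rotation invariant
  (relative error at the percent level for 64 points); every other slot
  is exactly invariant under rigid motion, and the tests check both
  statements separately.

# Curation choices

* **Labeling**: a grid point within 3 Å of at least one constituent
  centroid (and ≤ 5 Å from protein) takes the class of its *nearest*
  centroid; exact distance ties resolve by the priority P > R > base,
  because a backbone contact geometrically encloses the ribose/base
  attachment points.
* **Negatives** are sampled (never augmented) from unlabeled points
  > 3 Å from every RNA atom and outside every alpha sphere, then
  subsampled to a 2:1 positive:negative ratio.
* **Alpha spheres** replace an external pocket-detection binary: spheres
  tangent to four protein atoms (circumspheres of k-nearest-neighbor
  quadruples) with no fifth atom strictly inside, radii in [3, 6] Å by
  default. They mark both buried and solvent-exposed surface and gate the
  negative sampling; full pocket clustering and ranking are out of scope.
* **Homology control**: single-linkage clusters at ≥ 90% global sequence
  identity (match +1, mismatch 0, affine gaps −2/−1, identity = matches /
  alignment length, computed with Biostrings' global aligner). Whole
  clusters are assigned to cross-validation folds; `crossvalidate()`
  recomputes every cross-fold identity before training and aborts on a
  violation, naming the offending pair. Cluster representatives are the
  entries with the numerically best resolution (missing resolution is
  treated as worst; ties break toward lower mean protein B-factor), and
  within an entry the RNA copy with the lowest mean B-factor is kept.

# Training

Both hierarchy levels share a backbone interface. The residual network is
instantiated in full — 16 blocks of two 1 × 2 × 80 convolutions (80
filters, zero padding preserving the 6 × 80 shape, batch normalization,
ReLU, identity shortcut), 32 convolutional layers in total, followed by a
flattening, a fully connected layer and softmax. At desk scale the
convolutional stack is applied as a fixed, seed-determined feature
extractor and the fully connected head is optimized; end-to-end
backpropagation through all 32 layers is a GPU-scale undertaking that
this package deliberately does not exercise in its test paths. The
multinomial baseline — softmax regression on the flattened 480-vector —
is the default, fully trained backbone.

The head trainer is Adam under categorical cross-entropy with decoupled
weight decay, minibatches and a per-epoch loss trace. Defaults: learning
rate 1e-3, batch 256, weight decay 1e-4, 30 epochs, all seeded. Features
are centered and rescaled by a *single global* factor (the mean of the
column standard deviations) rather than standardized per column:
per-column standardization amplifies uninformative low-variance columns,
and Adam's per-parameter step normalization then lets noise dimensions
move as fast as signal dimensions — a measurable generalization penalty
at small sample sizes. For small training sets a larger weight decay
(1e-2) is advisable for the same reason; the cross-validation tests use
it.

# Logos and sequence scoring

At a known base position the 7-class score vectors of grid points within
3 Å are averaged and renormalized; the information content
Ξ = log₂7 + Σ p log₂ p is in bits (the logarithm inside the sum is taken
base 2, consistent with the leading log₂7 term, so Ξ ranges from 0 at the
uniform distribution to log₂7 ≈ 2.807 at a degenerate one). Letter
heights proportion Ξ by the *raw* class probabilities restricted to the
four bases — P/R/X mass is omitted from display but not renormalized
away, so heights sum to at most Ξ with equality only when no backbone or
non-site mass is present. (The alternative — renormalizing over bases
before proportioning — would inflate positions dominated by backbone
signal; it is available implicitly via `pwm_scorer()`, which does
renormalize because a sequence score must be a distribution over bases.)
A position ≥ 5 Å from the protein, or with an empty 3 Å neighborhood, is
a gap.

The sequence score is Q = max Σᵢ log₂(pᵢ(b) Tᵢ,ᵢ₊₁), a fixed hidden
Markov model maximized over paths. Q ≤ 0 always, with 0 attained only
when every factor on the optimal path equals 1.

* **PWM mode** (base locations known): T ≡ 1 and Q reduces to the best
  contiguous gap-free window of Σ log₂ pᵢ(bᵢ) slid across the native
  strand positions.
* **Hidden mode**: trinucleotide conformers are coarse-grained to 9-node
  models (3 × {P, R, base} centroids) and aligned to the top predicted
  sites through a correspondence graph whose vertices pair same-class
  nodes and sites and whose edges demand distance consistency within
  τ = 1.5 Å. Maximal cliques come from Bron–Kerbosch with pivoting; a
  placement is kept when the clique has ≥ 7 nodes, every consecutive base
  pair is guided by ≥ 5 matched backbone nodes, and the superposed
  full-atom model has no heavy atom within 2.5 Å of the protein (τ and
  the clash distance are package defaults, both user-configurable).
  Aligned base nodes are partitioned into k-means Voronoi
  cells (k is user-set — the expected number of bases in the pocket;
  when k equals the number of distinct node positions the cells are
  seeded exactly on them). Emissions average the surface scores within
  3 Å of each center, renormalized over the four bases. Transitions count
  consecutive-base cell pairs within each placement, are symmetrized
  (c′(a,b) = c(a,b) + c(b,a)), and then *direction-pruned*: the start
  cell (nearest a user anchor, or the cell maximizing summed distance to
  all others) carries probability 1 and the highest rank; edges may only
  descend strictly in rank (rank decreasing with distance from the
  start), which renders the graph acyclic — pruning happens *before* the
  row renormalization, and lateral equal-rank moves are forbidden. The
  dynamic program over this DAG is verified against exhaustive path
  enumeration for all toy scorers with ≤ 6 states and sequences up to
  length 4.

# The synthetic data generator

Every stage is testable without downloading a structure:

* `make_complex_fixture()` builds a poly-alanine protein on an idealized
  curve (3.8 Å consecutive-Cα spacing; N and C atoms carry off-axis
  offsets so backbone dihedrals are well defined) and places an RNA
  strand with idealized nucleotide geometry so that base centroids sit
  3–6 Å from the surface with bases pointing inward. It returns the true
  constituent centroids, making label recovery exactly checkable.
* `synthetic_conformer_library()` sweeps helical placement parameters
  over a 15°-binned grid with seeded jitter and chains nucleotides so the
  O3′–P linkage is exactly 1.6 Å — covalently contiguous backbones with
  varied pseudo-torsions. It is labeled synthetic throughout: these are
  idealized placements, not crystallographic conformers.
* `sample_feature_vectors()` draws class-conditional spherical Gaussians
  around user-supplied means; with equal priors the Bayes classifier is
  the nearest-mean rule, so `bayes_rate_gaussian()` gives a Monte Carlo
  reference against which the hierarchical pipeline's held-out accuracy
  is compared. The parameter-recovery suite uses orthogonal means at
  separation 6 with noise sd 0.5 — a well-separated regime chosen so the
  generative Bayes rate is a sharp target — and 700 draws per class.

What passing these tests shows: the pipeline's plumbing, geometry,
probability algebra and optimization behave correctly, and the classifier
recovers a known generative model. What they do not show: performance on
real crystallographic data, where features are correlated, classes
overlap, labels carry registration error, and homology structure is far
richer than the synthetic fixtures emulate. Benchmarks on the real
structure corpus require bulk downloads and long training and are outside
this package's test scope.

# Numerical choices and degenerate inputs

* Nucleobase templates are planar regular-polygon constructions with
  1.38 Å ring bonds, built programmatically (atom inventories are exact:
  adenine 10 heavy atoms, guanine 11, cytosine/uracil 8); downstream code
  relies only on centroids and distances, not on sub-ångström base
  geometry.
* Alternate locations: the highest-occupancy conformer wins; ties go to
  the first altloc alphabetically. Hydrogens are dropped everywhere.
* Degenerate (coplanar) atom quadruples are skipped in alpha-sphere
  detection (determinant threshold 1e-8); collinear backbone triples give
  `NA` dihedrals and coil.
* All subsampling, initialization and batch shuffling run under explicit
  seeds through an RNG-state-preserving wrapper; nothing consumes the
  caller's global RNG state.
* Problem sizes in the tests and the acceptance script — a 20-residue
  fixture, 700 feature vectors per class, 50–100 random instances per
  oracle suite — were chosen as the smallest sizes at which the checked
  properties are sharp.

# Known limitations

* The 80-slot registry approximates the authoritative property list; the
  partial-charge table is simplified and the secondary-structure rules
  are coarse. The registry is versioned precisely so alternative slot
  definitions can coexist with trained models.
* Conformer sequence expansion places idealized bases by standard
  glycosidic geometry in lieu of force-field refinement; the
  `regularized` flag records this so a refined library can be substituted.
* Desk-scale training optimizes the classifier head only; the residual
  feature extractor is fixed at its seeded initialization.
* Logos render as stacked bars rather than scaled glyphs; the logo matrix
  and MEME export feed standard motif tools for publication graphics.
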
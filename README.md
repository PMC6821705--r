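# rnasurf

Structure-based prediction of RNA-binding preferences on protein surfaces.

Proteins recognize RNA through local physicochemical complementarity: a
pocket lined with positive charge and hydrogen-bond donors attracts the
phosphate backbone, an aromatic shelf stacks a nucleobase, and so on.
`rnasurf` asks, for every point of a lattice placed around a protein
surface, *what would bind here?* — and answers with a normalized score
vector over seven classes: non-site (X), phosphate (P), ribose (R),
adenine (A), guanine (G), cytosine (C) and uracil (U).

The pipeline:

1. **Curation.** Grid points on a 1 Å cubic lattice, kept in the
   2.5–5.0 Å surface band. In a ribonucleoprotein complex, each RNA
   nucleotide is decomposed into its constituent centroids (phosphate,
   ribose, base); grid points within 3 Å of a centroid (and ≤ 5 Å from
   protein) inherit its class. Non-sites are sampled from space away from
   RNA atoms and outside alpha spheres, then balanced to positives at 2:1.
   Homology-aware clustering (single linkage at ≥ 90% identity) keeps folds
   disjoint for cross-validation.
2. **Featurization.** Each location is encoded as a 6-shell × 80-property
   tensor (480 scalars): per-atom physicochemical properties of protein
   heavy atoms within 7.5 Å, accumulated into six concentric 1.25 Å shells.
3. **Hierarchical classification.** A first 4-class model resolves
   {X, P, R, Base}; a second resolves {A, G, C, U}; the 7-class vector is
   the product of the level-2 output with the Base prior,
   `p(b) = p1(Base) · p2(b)`. Backbones: a 16-block residual network
   (two 1×2×80 convolutions per block with batch normalization, ReLU and
   identity shortcuts — 32 convolutional layers in total) and a multinomial
   baseline; both train their softmax head with Adam under categorical
   cross-entropy and weight decay.
4. **Logos.** At known base positions, score vectors within 3 Å are
   averaged; the information content per position `i` is
   `Ξᵢ = log₂7 + Σ_c pᵢ(c) log₂ pᵢ(c)` (bits), and letter heights are
   `Ξᵢ · pᵢ(b)` for the four bases. Positions ≥ 5 Å from protein are gaps.
5. **Sequence scoring.** A query RNA string is scored by a fixed hidden
   Markov model, `Q = max Σᵢ log₂(pᵢ(b) Tᵢ,ᵢ₊₁)`. With predetermined base
   locations the transitions are certain (T = 1) and Q reduces to a sliding
   PWM score. Without them, trinucleotide conformers (a backbone library
   expanded over all 4³ base assignments; 296 conformers yield 18,944
   variants) are coarse-grained to 9-node models and aligned to top
   predicted sites by Bron–Kerbosch clique search; k-means Voronoi cells
   over the aligned base nodes become hidden states with symmetrized,
   direction-pruned transitions, and Q is computed by dynamic programming.

## Worked example

A desk-scale run on a synthetic ribonucleoprotein complex with a known
A–G–C strand:

```r
library(rnasurf)
library(dplyr)

fx <- make_complex_fixture(fixture_spec(n_protein_residues = 20,
                                        n_nucleotides = 3, rng_seed = 11,
                                        sequence = c("A", "G", "C")))
fx$structure
#> <complex_structure> 165 heavy atoms, 2 chain(s): A (protein, 20 res), B (rna, 3 res)

labeled <- generate_lattice(fx$structure) |>
  filter_surface_band() |>
  label_positives(fx$centroids)
table(labeled$label)
#>  X  P  R  A  G  C  U
#>  0  0  0 43 61 60  0

spheres <- detect_alpha_spheres(fx$structure)
labeled <- sample_negatives(labeled,
                            with(fx$structure$atoms[fx$structure$atoms$molecule_class == "rna", ],
                                 cbind(x, y, z)),
                            spheres, n = sum(!is.na(labeled$label)), seed = 11)
train_set <- balance_classes(labeled, 2, seed = 11) |> filter(!is.na(label))

feats <- featurize_grid(train_set, fx$structure)
model <- train_hierarchical(feats, train_set$label,
                            backbone_spec("baseline", epochs = 60,
                                          learning_rate = 1e-2,
                                          weight_decay = 1e-2, seed = 11))
scored <- predict_surface(model, fx$structure, train_set)
scored |> select(x, y, z, starts_with("prob_")) |> head(3)
#>       x     y     z prob_X prob_P prob_R prob_A  prob_G prob_C prob_U
#> 1  6.17 -1.78 -4.02  0.203      0      0  0.574 0.00982  0.214      0
#> 2  4.17  1.22 -4.02  0.184      0      0  0.432 0.0528   0.330      0
#> 3  3.17 -3.78 -3.02  0.177      0      0  0.676 0.0179   0.129      0

logo <- build_logo(scored, train_set,
                   filter(fx$centroids, kind %in% c("A", "G", "C", "U")),
                   fx$structure)
logo |> select(position, kind, info_bits, gap)
#>   position kind  info_bits gap
#> 1        1 A          0    TRUE
#> 2        2 G          1.64 FALSE
#> 3        3 C          1.85 FALSE

score_sequence(pwm_scorer(logo), "GC", mode = "pwm")$Q   # native dinucleotide
#> [1] -0.16
score_sequence(pwm_scorer(logo), "CG", mode = "pwm")$Q   # swapped
#> [1] -12.72
```

The surface points near the guanine and cytosine centroids carry 1.6–1.9
bits of information; the 5′ adenine sits ≥ 5 Å from the protein and renders
as a gap. The native `GC` dinucleotide scores near the 0-bit ceiling while
the swapped `CG` is penalized by ~12.6 bits — the predicted surface
preferences recover the planted strand.

`plot_surface_scores(scored)` and `autoplot(logo)` draw the top-class
surface map and the logo; `write_pseudoatom_scores()` exports the top 10%
of sites per class as PDB pseudo-atoms for molecular viewers. A thin
command-line wrapper over the same functions lives in `inst/cli/rnasurf`
(subcommands `simulate`, `curate`, `featurize`, `train`, `predict`,
`logo`, `score`, `evaluate`).

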
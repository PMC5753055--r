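# strandscope

Beta-strand propensity analysis of short peptide conformational ensembles.

## What it is for

Short hydrophobic peptides of the form Ala-Val-**X**-Val-Leu (X = Ser, Thr,
(2S,3R)- or (2S,3S)-4,4,4-trifluorothreonine; Boc-protected or free amine,
C-terminal methyl ester) are candidate **beta-strand mimics** — extended
backbones that can engage beta-sheet edges, e.g. to interfere with amyloid
aggregation. Deciding whether a central residue biases the chain toward
extended structure is an ensemble question, answered jointly from
simulation-style ensembles and NMR descriptors. `strandscope` implements
both halves for structural biologists and peptide chemists working on such
systems:

* a **two-basin wrapped-Gaussian sampler** for backbone dihedrals, with
  per-residue beta weights (`sample_dihedrals()`, `basin_model()`), and an
  idealized-geometry coordinate builder (`build_coordinates()`);
* **strand metrics**: per-residue psi-basin probabilities
  (beta = [90°, 180°], alpha = [−70°, 40°]) and the **global extension
  probability** — the probability that all three central residues are
  simultaneously extended,

  P = p(Val2) x p(X3) x p(Val4),

  plus end-to-end distance distributions (N of residue 1 to the ester
  carbonyl carbon);
* **Karplus back-calculation** of 3J(HN-HA) from phi,
  J = A cos²θ + B cos θ + C with θ = φ − 60° (default A = 6.51,
  B = −1.76, C = 1.60 Hz), and comparison of observed couplings to the
  coil library (Ala 6.1, Leu 7.0, Val 7.5 Hz);
* **neighbor-count ("gromos"/Daura) clustering** at an RMSD cutoff
  (default 0.2 nm) over Kabsch-superposed backbone atoms;
* **NMR descriptor rules**: chemical shift deviations with terminal /
  no-reference exclusions, amide temperature coefficients
  (> −4.5 ppb/K → H-bond candidate, < −6 ppb/K → exposed), chi1 rotamer
  calls from 3J(HA-HB) (< 5 Hz gauche, > 10 Hz anti), and an i/i+2
  periodicity scan of temperature coefficients.

The package ships the characterization dataset of the eight studied
pentapeptides (CSD, coupling, temperature-coefficient and beta-probability
tables; see `beta_probability_table()` and friends) as its reference
inputs.

## Worked example

Score a synthetic ensemble of the free-amine (2S,3S)-CF3-Thr pentapeptide
whose central residues target their characterized beta weights:

```r
library(strandscope)

sp  <- study_peptides()[["4b"]]           # H2N-Ala-Val-TFS-Val-Leu-OMe
bm  <- basin_model(beta_weight = c(0.6, 0.779, 0.856, 0.748, 0.6))
ens <- sample_dihedrals(sp, bm, n_frames = 20000, seed = 1)

propensity_report(ens)
#> Peptide 4b: p_beta = VAL2 78.0%, TFS3 84.8%, VAL4 74.6%; P = 49.4%

xyz <- build_coordinates(ens)
mean(end_to_end_distances(xyz)$distances)
#> [1] 13.83            # Angstrom; extended chains push this up

ensemble_mean_j(ens, 3)
#> [1] 8.97             # Hz, well above the 7.5 Hz Val coil mean

sub <- xyz; sub$xyz <- xyz$xyz[seq(1, 20000, by = 400), ]
cluster_ensemble(sub, cutoff = 0.2)
#> Daura clustering at 0.2 nm: 3 clusters over 50 frames; sizes 44, 5, 1
```

Reading: about 78%, 85% and 75% of frames place Val2, CF3-Thr3 and Val4 in
the beta basin; the product says ~49% of conformers are globally extended
— the hallmark of a good strand mimic (the Ser analogue scores ~25% under
its own characterized weights). The back-calculated coupling and the
dominant extended cluster agree with that reading.

`run_pipeline(run_config())` runs all eight systems (sampling, metrics,
couplings, clustering, NMR descriptor tables) and writes provenance-stamped
CSVs.

## Layout

* `R/` — implementation; `tests/testthat/` — unit, property and
  end-to-end suites (oracle-based: numerical integration, brute-force
  greedy clustering, random-rotation search, independent torsion formula).
* `vignettes/strand-propensity-methods.Rmd` — the model, its assumptions,
  defaults, and what the synthetic generator does and does not emulate.
* `scripts/acceptance.R` — see above.
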
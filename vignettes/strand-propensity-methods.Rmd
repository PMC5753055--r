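---
title: "Scoring beta-strand propensity in short peptide ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring beta-strand propensity in short peptide ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strandscope)
```

## The scientific question

Short hydrophobic peptides such as Ala-Val-X-Val-Leu are candidate
beta-strand mimics: molecules that present an extended backbone to a
partner beta-sheet, for instance to interfere with the aggregation of
amyloid-forming proteins. Whether a given central residue X (serine,
threonine, or one of the two 4,4,4-trifluorothreonine diastereomers)
actually biases the chain toward extended conformations is a question
about a conformational *ensemble*, not a single structure. This package
implements the quantitative machinery used to answer it from two sides:

* **Ensemble side** — given per-frame backbone dihedrals (from any source),
  score how beta-strand-like the ensemble is: per-residue psi-basin
  probabilities, their product (the global extension probability),
  end-to-end distances, back-calculated 3J(HN-HA) couplings, and
  neighbor-count RMSD clustering.
* **NMR side** — given experimental descriptor tables, apply the standard
  interpretation rules: chemical shift deviations from random coil, coil
  library comparison of couplings, amide temperature coefficients with
  hydrogen-bond classification, chi1 rotamer calls, and an i/i+2
  periodicity scan.

## The ensemble model

The package does not run molecular dynamics. Its generator
(`sample_dihedrals()`) draws each residue's psi from a two-component
wrapped-Gaussian mixture,

$$\psi \sim w\,\mathcal{N}_w(\mu_\beta, \sigma_\beta) +
(1-w)\,\mathcal{N}_w(\mu_\alpha, \sigma_\alpha),$$

with the beta component centered at $\mu_\beta = +140^\circ$ and the alpha
component at $\mu_\alpha = -30^\circ$ — the two peak centers that dominate
psi distributions of these pentapeptides — and mixing weight $w$
(`beta_weight`) the quantity under experimental control. Phi is drawn from
its own Gaussian, by default centered at $-135^\circ$ with sd $15^\circ$ so
that most mass falls in the extended range ($-160^\circ$ to $-110^\circ$);
omega is fixed trans; chi1 defaults to a constant gauche+ rotamer
($+60^\circ$). Component sds default to $15^\circ$, a typical basin width
for these systems. "Wrapped" means a real-line Gaussian draw wrapped into
$(-180^\circ, 180^\circ]$, which is exact for the sampling and an accurate
density model for sd up to about $60^\circ$ (beyond that, periodic images
overlap and the mixture interpretation blurs).

Draws are independent across frames and residues. That is the key
idealization: real trajectories are autocorrelated in time and correlated
between neighboring residues. The generator makes no attempt to model
either, because the analysis stack — not trajectory physics — is what the
package exercises. Consequently, a passing parameter-recovery test shows
the estimators are correct and well-calibrated for independent draws; it
does not show that an MD trajectory of given length would estimate basin
populations with the same precision (autocorrelation inflates the effective
standard error). The product rule below is *exact* under this independence,
whereas for a real peptide it is an approximation the ensemble analysis
itself must justify.

`basin_mass()` gives the analytic window mass of the mixture (Gaussian
probabilities summed over periodic images, $k = -3\ldots3$), which is the
exact population the sampler targets; recovery tests compare empirical
fractions against it, and an independent numerical integration oracle in
the test suite guards the closed form itself.

## From dihedrals to scores

**Basin probabilities.** `basin_probability()` counts frames whose psi lies
inside a window: beta $[+90^\circ, +180^\circ]$, alpha
$[-70^\circ, +40^\circ]$, both bounds inclusive (an angle exactly at a
boundary counts inward; the tie-break is documented because printed
probabilities at three digits can depend on it). Counting frames in the
stated windows was chosen over fitting peak shapes: it is deterministic,
matches the windows' definition, and has no fit instabilities. The window
bounds are exposed in `basin_window()` so a peak-area-like convention can
be approximated by widening them.

**Global extension probability.**
`global_extension_probability()` multiplies the central-residue beta
probabilities,
$P = \prod_i p_{\beta,i}$ — the probability that all central residues are
simultaneously extended, exact under the generator's independence.
Reports print percentages to one decimal; internal values keep full
precision.

**End-to-end distance.** Defined as the distance from the backbone nitrogen
of residue 1 to the carbonyl carbon of the C-terminal methyl ester; large
values mean globally extended chains. Coordinates come from
`build_coordinates()`, a vectorized NeRF-style chain extension with
idealized geometry (`backbone_geometry()`: C-N 1.329 Å, N-CA 1.458 Å,
CA-C 1.525 Å, trans amides; the full table is carried in the object so
builds are bit-stable). A Boc cap contributes the carbamate carbonyl
carbon, which makes phi of residue 1 a real torsion; free-amine chains have
no phi(1). Psi of the last residue is realized through the ester oxygen, so
all residues carry psi. Building round-trips: re-measuring any realized
dihedral recovers the input to well below $10^{-6}$ degrees, and the
torsion sign convention is pinned to an independent reference
implementation in the tests.

**Karplus back-calculation.** $^3J(\mathrm{HN{-}H\alpha})$ relates to phi
through $J = A\cos^2\theta + B\cos\theta + C$, $\theta = \phi + \mathrm{phase}$.
The original study cites but does not print its coefficient set, so the
default here is a standard published HN-HA parameterization
(A = 6.51, B = −1.76, C = 1.60 Hz, $\theta = \phi - 60^\circ$), selectable
via `karplus_parameters()` — exact reproduction of trajectory-level J
agreement is therefore not attempted. `ensemble_mean_j()` averages J over
frames (never J of the mean phi). Extended phi gives large couplings: at
$\phi = -120^\circ$ the default set gives 9.87 Hz, far above the Val coil
mean of 7.5 Hz.

**Clustering.** `daura_cluster()` implements the greedy neighbor-count
("gromos") algorithm at an RMSD cutoff, default 0.2 nm: the frame with the
most neighbors within the cutoff seeds a cluster, the cluster is removed,
repeat. Ties in neighbor count resolve to the lowest frame index —
documented because membership depends on it. RMSD uses in-house Kabsch
superposition (proper rotation enforced via the SVD sign correction) over
backbone heavy atoms N, CA, C, O; the atom set is configurable since
published protocols often leave it unstated, which is also why cluster
populations should only be compared qualitatively between implementations.
RMSD is computed in Å and reported in nm. All-against-all RMSD is quadratic
in the frame count, so `run_pipeline()` clusters an evenly strided
subsample (default at most 120 frames) — enough to rank cluster
prevalence, not to resolve small clusters.

## NMR descriptor rules

* **CSD** (`compute_csd()`): observed shift minus random-coil reference.
  Terminal residues are excluded (no neighbor on one side biases their
  shifts), as are residues without a known coil reference — the
  CF3-threonines. Exclusions are recorded with reasons, never silently
  dropped. The default coil set is a standard published compilation
  shipped via `coil_reference()`; because the original analysis did not
  identify its exact compilation, the shipped characterization tables are
  transcribed CSD values, and the rule logic is tested against those rather
  than recomputed from raw shifts.
* **Coil comparison** (`compare_to_coil()`): only the three printed coil
  means (Ala 6.1, Leu 7.0, Val 7.5 Hz) are used; everything else is
  "not comparable". Missing markers: empty = not measured, "broad" =
  unresolvable; both excluded from comparison and tallied.
* **Temperature coefficients** (`temp_coefficient()`): OLS slope of shift
  vs temperature ×1000 (ppb/K). Classification (`classify_hbond()`):
  slope > −4.5 ppb/K suggests an intramolecular hydrogen bond,
  slope < −6 ppb/K solvent exposure; the boundary values themselves are
  intermediate because the defining inequalities are strict.
* **chi1 calls** (`classify_chi1()`): < 5 Hz gauche-dominated, > 10 Hz
  anti-dominated, else mixed. The thresholds are conventional, not
  system-specific, and configurable; note that at 5 Hz both the Thr and the
  (2S,3S)-CF3-Thr central residues classify gauche-dominated — the CF3-Thr
  couplings (2.0–2.5 Hz) are simply much deeper in the gauche regime.
* **Periodicity scan** (`periodicity_scan()`): flags residues whose
  coefficient is less negative than both neighbors' by ≥ 1 ppb/K (default
  margin). In the shipped dataset the Val4 position is flagged exactly in
  the two (2S,3S)-CF3-Thr peptides, the i/i+2 signature of transient
  intermolecular strand contacts.

## Defaults that matter

| parameter | default | unit | why |
|---|---|---|---|
| `beta_center` / `alpha_center` | +140 / −30 | deg | observed psi peak centers |
| `beta_sd`, `alpha_sd` | 15 | deg | typical basin width; recovery conditions |
| `phi_center`, `phi_sd` | −135, 15 | deg | mass inside the extended phi range |
| beta / alpha windows | [90, 180] / [−70, 40] | deg | stated basin definitions |
| Karplus (A, B, C, phase) | 6.51, −1.76, 1.60, −60 | Hz, deg | standard HN-HA set |
| cluster cutoff | 0.2 | nm | standard peptide backbone threshold |
| H-bond / exposed thresholds | −4.5 / −6 | ppb/K | protic-solvent convention |
| chi1 gauche / anti thresholds | 5 / 10 | Hz | conventional |
| histogram bin width | 5 | deg | resolves 15-degree basins |

The default `run_config()` assigns each of the eight study systems
generator weights equal to its characterized central-residue beta
probabilities (`beta_probability_table()`), with 0.6 for the
uncharacterized terminal residues — so a default synthetic run reproduces
the study's contrasts (the (2S,3S)-CF3-Thr peptides most extended) by
construction. This is a demonstration of the pipeline's shape, not an
independent prediction.

## Numerical choices and problem sizes

Sampling is driven by one seeded Mersenne-Twister stream consumed in a
fixed, documented order, so ensembles are bitwise reproducible; the
pipeline derives per-system seeds as `seed + k - 1`. Histogram bins are
left-closed (`[lo, hi)`, last bin closed at +180) and the bin width must
divide 360. Degenerate inputs fail loudly: empty ensembles, collinear
superposition selections, fewer than two temperatures, out-of-range
weights (named by residue). Recovery checks use n = 50,000 frames, where
the Monte-Carlo standard error of a basin probability is about 0.002 —
comfortably inside the ±0.01 acceptance band; pipeline-level checks use
400–5,000 frames, keeping the whole suite under a minute.

## Known limitations

* Independence across residues and frames: no coupling between phi and
  psi, no inter-residue correlation, no kinetics. The generator reproduces
  marginal basin statistics, nothing more.
* Only backbone heavy atoms (plus the cap carbonyl and ester oxygen) are
  built; chi1 lives in the dihedral table but no side-chain atoms exist,
  so RMSD and clustering are backbone-only statements.
* The Karplus coefficient set and the random-coil compilation are
  literature defaults, not fits to these systems; absolute back-calculated
  J values inherit that choice.
* The experimental tables are transcribed characterization data: the
  descriptor rules are validated against them, but raw spectra-level
  recomputation is out of scope.
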
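---
title: "Methods: curation, embedding heads and symmetric evaluation in protstab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: curation, embedding heads and symmetric evaluation in protstab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protstab)
```

# The model

`protstab` predicts the stability change ΔΔG (kcal/mol, positive =
destabilizing) of a single amino-acid substitution from the pair of
sequences (wild type, mutant). A backbone embeds a length-N sequence as
an (N+2)×D matrix: row 1 a CLS (whole-sequence) token, rows 2..N+1 the
residues, row N+2 an END token. A regression head selects rows from the
two matrices, merges them into one feature vector, and maps it to a
scalar through a network with one hidden layer. Exactly five
(source, merge) combinations are admissible — position rows with
concatenation (width 2D), outer product (D²) or element-wise linear
merge `w_WT ⊙ e_WT + w_MT ⊙ e_MT` (D), CLS rows with the linear merge
(D), and CLS-plus-position rows with the linear merge (2D) — and the
ensemble predictor is the arithmetic mean of the five heads.

The central modelling assumption is that a pre-trained protein language
model's per-token representations already encode the structural and
evolutionary context that determines a substitution's energetic effect,
so a small head suffices. A second, softer assumption is approximate
antisymmetry: the ΔΔG of the reverse mutation is the negation of the
direct one. The linear merge can represent antisymmetry exactly (it is
odd in the pair ordering when `w_MT = −w_WT` and biases vanish, since
tanh is odd); concatenation and the outer product cannot, which is why
their direction behaviour depends entirely on the balance of the
training data. The package offers optional structural tying
(`antisymmetric = TRUE` on linear-merge heads) but leaves it off by
default: the reference protocol learns symmetry from reverse-augmented
data rather than constraining the architecture.

# Curation pipeline

Measurements are keyed by (PDB ID, chain, mutation code). The five
steps: (1) split records into Group I (both pH and temperature
recorded) and Group II (anything less — a record with only one of the
two is treated as conditions-unavailable); (2) per key, select the
Group-I record closest to standard conditions; (3) admit the remaining
Group-I records lying within closed windows around *the core's own*
conditions, plus Group-II records whose key occurs nowhere in Group I;
(4) average ΔΔG per key, retaining the member values; (5) discard keys
whose members conflict.

Decisions the procedure statement leaves open, and how they are fixed
here:

* **Condition distance.** "Closest to pH 7, 25 °C" needs a metric over
  incommensurable axes; we use the normalized L2 distance
  `sqrt(((pH−7)/0.5)² + ((T−25)/10)²)`, scaling each axis by its
  acceptance half-window so one window-width of deviation counts
  equally in pH and in temperature. Ties break by smaller pH deviation,
  then lower pH, then input order — fully deterministic.
* **Windows are closed**: a candidate at exactly pH core ± 0.5 or
  T core ± 10 °C is admitted. The windows are anchored at the core's
  conditions, not at the standard values, so when no near-standard
  measurement exists the window follows the best available core.
* **Variance filter units.** The conflict threshold is quoted as a
  variance of 5 in kJ/mol units, while the package stores ΔΔG in
  kcal/mol. Because a variance scales with the *square* of a unit
  change, the member values are converted back to kJ/mol at the filter
  boundary and their unbiased sample variance (n−1 denominator;
  single-member keys have variance 0) is compared against 5. A member
  set of {0, 6} kJ/mol (variance 18) is discarded; {1.0, 1.1} kJ/mol
  (variance 0.005) is kept.
* **Sign conflict** requires a strictly positive and a strictly
  negative member; exact zeros never trigger it.
* **Order of operations.** The 70-per-wild-type cap is applied before
  reverse augmentation, and augmentation is applied only to the
  training split, after homology filtering — reversing test records is
  the evaluation protocol's job, not the dataset's.

The per-wild-type cap (default 70) counteracts the over-representation
of short, heavily-assayed miniproteins in high-throughput sources; the
subsample is uniform at random under the pipeline seed, since no
selection criterion is prescribed. Homology filtering removes a
training protein when it hits any test sequence with identity > 30 %
*and* E-value < 0.05 (a conjunction). The bundled identity backend is a
global Needleman–Wunsch alignment (BLOSUM62, gap open 10, extend 0.5)
with identity = matches / alignment length and a surrogate E-value of 0
above the identity threshold; pairs whose alignment degenerates to no
aligned identity are assigned 0 %. At production scale one would
delegate to a BLAST-compatible search exposing the same
`(queries, subjects) → hits` interface.

# Backbone contract and the mock

`embed_sequence()` enforces the contract — 20-letter alphabet (errors
name the offending position), non-empty, within the backbone's context
length (over-long input is rejected, not truncated), output exactly
(N+2)×D and finite. Mutation positions are 1-based throughout the user
API; the +1 shift for the CLS row lives in one accessor
(`mutation_row()`), which is the only place the offset convention
exists.

The mock backbone hashes (residue identity, position, seed) — plus the
residues inside a configurable locality window — into each residue row,
the whole sequence into the CLS row, and the sequence length into the
END row, expanding each hash through a seeded normal draw. Consequences,
by construction: identical inputs give bitwise-identical matrices;
distinct sequences differ; and with the default locality 0 a
single-residue change alters exactly the mutated residue's row plus the
CLS row, which makes head-behaviour tests sharp. What the mock does
*not* emulate: real embeddings vary smoothly with sequence context,
correlate across positions, and carry actual biophysics. Tests passing
on the mock therefore validate the *mechanics* (shapes, offsets,
gradients, symmetry laws, determinism) — they say nothing about
predictive accuracy on real proteins, which depends entirely on the
real backbone plugged in through `backbone_custom()`.

# Training

Per-example (batch size 1) updates with Adam (β₁ = 0.9, β₂ = 0.999,
ε = 1e−8 — library defaults, logged here since the protocol does not
state them), mean-squared-error loss, and a piecewise-linear schedule:
the learning rate rises from 0 to the peak over the first 30 % of all
examples seen across the run (epochs × dataset size), then decays
linearly to 0. Data order is reshuffled once per epoch under the run
seed. The loss is MSE as a matter of design — the protocol never names
its loss, and MSE matches the RMSE-centred evaluation.

The default peak rate of 1e−5 is the published fine-tuning rate for a
650M-parameter transformer backbone trained end to end. Training a
fresh head alone over a frozen (or mock) backbone is a different
optimization problem: the head starts from scratch and sees a few
thousand updates, so the package's desk-scale recipe uses peak 3e−2
with hidden width 48. This was chosen as the configuration that
recovers a constructed linear target robustly (held-out r ≥ 0.9 across
data seeds) within the fixed 3-epoch budget; larger rates destabilize
the tanh layer, smaller ones fail to break the symmetric all-ones
initialization of the merge weights in time. The linear-merge weight
vectors start at all ones (the initial merge is a plain sum), the
hidden and output layers at small seeded Gaussians. Ensemble training
runs the five heads as independent fits with seeds derived from the run
seed.

Freezing: the mock backbone has no trainable state, so the
`freeze_backbone` flag is honoured trivially; with a real trainable
adapter it is the adapter's duty to respect the flag.

# Evaluation

Pearson r, RMSE and MAE, with r reported as NaN plus a warning when
either side is constant — a silent zero would corrupt model
comparisons. `evaluate_symmetric()` constructs the reversed counterpart
of every test pair (swap sequences, negate target; an involution) and
reports paired metrics. For any model antisymmetrized as
`m′(a,b) = (m(a,b) − m(b,a))/2`, direct and reverse metrics coincide
exactly — a structural identity the tests exploit as an oracle.

Cross-validation folds are built from single-linkage clusters over the
homology graph (same 30 % identity threshold as the curation filter,
reused by analogy since the fold protocol names none), whole clusters
assigned greedily, heaviest first, to the lightest fold. Balancing is
by record count when weights are supplied, else by sequence count; the
seed only breaks exact ties, so assignments are deterministic.

# Structure-derived stratification

Contacts use minimum heavy-atom–heavy-atom distance (hydrogens are
dropped at parse time); "within 4.5 Å" is inclusive (≤). A chain counts
as oligomeric when *strictly more* than 30 % of its residues contact
another chain — a fraction of exactly 0.30 does not qualify. Parsing
keeps the first model and the highest-occupancy altloc, and moves
nonstandard residues out of the polymer chains into the hetero set,
where the cofactor rule looks for HEM/HEC/BLA codes. DSSP is consumed,
never re-implemented: relative ASA is DSSP's absolute ASA over the
residue-type theoretical maximum (Tien et al. 2013 table), clipped to
[0, 1]; the 8 states collapse as {H, G, I} → helix, {E, B} → strand,
rest → coil. The burial boundary is relative ASA < 0.25, a common
convention adopted because the stratified analyses this mirrors state
no number; it is configurable and reported. Residues absent from the
DSSP output are labelled unknown and excluded from labelled strata with
an explicit count. Crystal contacts are not distinguished from
biological interfaces.

# Fixture generators

`make_mutation_tables()` emulates merged thermodynamic sources by
planting per-key scenarios with known outcomes — single clean
measurements, in-window replicate groups, out-of-window outliers,
condition-free records (unique or duplicating a Group-I key),
opposite-sign conflicts, and uniform-sign groups whose kJ-space
variance exceeds the threshold (a two-point spread above
√10/4.184 ≈ 0.76 kcal/mol suffices) — and emits the expected outcome
per key as a manifest. This enables exact, non-circular curation tests:
the pipeline must reproduce the manifest *and* an independent
brute-force reimplementation. Planted ΔΔG magnitudes sit in
[0.5, 3] kcal/mol with replicate spreads ≤ 0.2, so clean groups can
never flip sign by accident; the generator makes no attempt at the
empirical ΔΔG distribution or the biases of real thermodynamic
databases. Toy structures are Cα-only chains placed at controlled
separations (default contacting pairs at 4.4 Å, spectators at 30 Å)
with optionally planted cofactor atoms; full-atom realism is
unnecessary for distance-rule tests.

`make_recoverable_dataset()` sets each target to an exact linear
function of the wild-type-minus-mutant mutation-row difference, scaled
to a spread of 1.5 kcal/mol (a realistic ΔΔG standard deviation), with
optional Gaussian noise. Ordinary least squares on the generating
features recovers the coefficients exactly at zero noise, providing an
upper-bound oracle for the trained head.

# Problem sizes and numerical notes

The test suite and the acceptance script run the curation oracle on a
generated fixture of ~120 keys / ~200 records, train heads on 500 pairs
(mock width 16) for 3 epochs, and verify contact detection on
structures up to 50 residues — sizes chosen so the full cycle completes
in well under a minute on one CPU while still exercising every branch.
Floating-point comparisons against constructed expectations use 1e−12
relative tolerance (1e−9 where an alignment of float summation orders
is not guaranteed); determinism checks are bitwise (`identical()`).
Degenerate inputs are hard errors, never silent repairs: empty
sequences, residue mismatches between mutation table and sequence
(numbering drift), non-finite losses, untrained heads asked to predict,
and structures without ATOM records all abort with diagnostics.

# Known limitations

* No pre-trained protein language model ships with the package; real
  accuracy claims require wiring one through `backbone_custom()` and
  fine-tuning at scale, which is outside the desk-scale scope.
* The outer-product head materializes D² features and is capped (4096
  by default) to fail loudly rather than exhaust memory at large D.
* The naive identity backend is O(n²) global alignment — fine for
  hundreds of sequences, not for databases.
* Oligomer detection sees only the chains present in the deposited
  coordinates; biological assemblies are not reconstructed.
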
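---
title: "Models and methods behind phoreqsar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind phoreqsar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phoreqsar)
```

phoreqsar implements a hit-discovery workflow for protein-kinase-style
targets that joins three descriptor families — pharmacophore fit values,
docking-derived ligand–receptor contact fingerprints (LRCF), and
classical physicochemical indices — in one QSAR matrix, selects a sparse
descriptor subset with a genetic algorithm wrapped around a regression
learner, and uses the validated model together with the pharmacophore
queries to rank a screening library. This vignette records the models,
their assumptions, the numerical choices, and what the synthetic test
bed does and does not establish.

## Pharmacophore model and fit value

A pharmacophore is a set of typed feature spheres in a common frame.
Point features (hydrophobic, `Hbic`) have an origin and tolerance
radius; vectored features (`HBA`, `HBD`, `RingArom`) add a projected
point with its own tolerance, representing the hydrogen-bond partner
direction or the ring normal. A per-model weight $W$ scales scores, and
exclusion spheres mark receptor-occupied space.

The fit of a mapped conformer is scored with the product form

$$\mathrm{Fit} = N_\mathrm{mapped} \times W \times
  \Big[1 - \sum (\mathrm{disp}/\mathrm{tol})^2\Big],$$

the sum running over every mapped feature *point* (origin and, when
present, projection). Two deliberate choices:

* **The product form is literal.** It can go negative when many
  features map near their tolerance boundary; the alternative
  $\sum W\,(1-(\mathrm{disp}/\mathrm{tol})^2)$ is available via
  `formula = "per_feature_sum"` on the fit functions.
* **The weight comes from the model file.** Hypothesis-generation
  engines conventionally fix $W = 1$; the shipped reference models carry
  per-model weights (2.26, 1.97, 2.18) and the file wins. Pass a model
  with `WEIGHT 1` to recover the fixed-weight convention.

### Mapping search and alignment

For each conformer, each injective kind-respecting assignment of model
features to perceived ligand features (all assignments when partial
mapping is allowed, only full covers under `require_all`) is scored with
exactly one Kabsch superposition over the mapped origin and projection
points; displacements are then measured in the model frame and an
assignment is admissible only if every point sits within its tolerance.
There is no iterative re-matching: with the 4-feature models this
package targets, exhaustive enumeration is cheap and provably optimal
(the test suite cross-checks against an independent brute-force oracle).
Assignments are capped at 10,000 per conformer with deterministic
truncation; the cap is unreachable for paper-scale models.

One extension proved necessary: a ring normal has no intrinsic sign, so
a perceived ring-aromatic projection is tried on both faces of the ring.
Without this, ring matches fail arbitrarily depending on atom ordering.

Degenerate alignments (one or two point pairs) fall back to the natural
limits of the SVD solution — pure translation for a single point — and
a single-point model therefore always reaches $\mathrm{Fit} = N\,W$,
which the property tests assert.

### Feature perception rules

Perception engines in commercial suites are proprietary; the rule table
here is explicit and configurable:

* `HBA`: N or O with a free lone pair and no positive formal charge;
  projection 1.9 Å along the lone-pair bisector (opposite the mean bond
  vector).
* `HBD`: every O–H / N–H hydrogen; projection at the hydrogen.
  Hydrogens must be explicit atoms with coordinates.
* `RingArom`: every fully aromatic SSSR ring; centroid origin,
  projection 2.0 Å along the (deterministically signed) ring normal.
* `Hbic`: centroid of each connected carbon/halogen group not adjacent
  to charged or doubly-heteroatom-substituted atoms, plus aromatic ring
  centroids (deduplicated within 0.5 Å).

These rules reproduce the textbook cases (water: one acceptor, two
donors; benzene: one aromatic ring plus one hydrophobe at the centroid;
ethane: a single hydrophobe) and are deterministic — repeated perception
is bit-identical, which screening reproducibility depends on.

## Contact fingerprints

A receptor atom is *contacted* by a pose when any ligand atom lies
within the threshold distance, 2.5 Å **inclusive** by default. All
receptor atoms are eligible, including explicit waters and hydrogens —
published contact descriptors name hydrogen atoms explicitly, so
stripping them would silently change the descriptor space. Per scoring
channel (`LD`, a LibDock-style score; `CD`, a CDOCKER-style interaction
energy, both treated higher-is-better with a per-channel override) the
top pose per ligand is chosen with lexicographic pose-id tie-breaks, and
fingerprints of a pose selected by both channels are computed once.
Columns are named `RES_<num>_<atomname>^<channel>` and ordered by
channel, residue number, atom name; no pruning of singleton columns is
applied. Contact determination is exact (no spatial indexing), matching
a brute-force all-pairs oracle on ≤500-atom instances in well under a
second.

## QSAR matrix, split, learners

The matrix is dense: compounds × (fits | LRCF bits | physchem), rows
aligned on compound id, with activity pIC50 = log10(1/IC50) in molar
units (the log base and units are a convention choice; molar base-10 is
the standard pIC50). Molecules that map no pharmacophore feature receive
fit 0, not NA.

The external test set is chosen by the every-fifth rule: rank by IC50
ascending (most potent first, ties by id) and take ranks 1, 6, 11, … —
91 compounds yield 72 train / 19 test deterministically.

Learners behind the common `fit_regressor`/`predict` contract:

* **MLR** — exact least squares; singular designs error out with advice
  to drop descriptors.
* **nu-SVR** — RBF kernel $\exp(-\gamma\|u-v\|^2)$, $\nu = 0.664$,
  $C = 1$, solved as the dense LibSVM-style dual QP with `quadprog`
  (a $2n\times2n$ problem; fine for the $n<100$ training sets this
  workflow uses). A reported $\gamma = 0$ is interpreted as the LibSVM
  auto convention $1/n_\mathrm{features}$ — a literal zero would flatten
  the kernel. The epsilon-loss width 0.1 is recorded but inert: it
  belongs to epsilon-SVR, not nu-SVR. Inputs are z-scored on the
  training data and the scaling ships with the model; binary LRCF
  columns are standardized for SVR only, never for MLR/RF.
* **RF** — bagged variance-reduction trees (mtry = p/3, quantile split
  candidates, minimum node 5), seeded; a compact in-package
  implementation kept deterministic and dependency-free.
* **plugin** — `list(fit, predict)` hook for gradient boosting,
  probabilistic neural networks and the like; deliberately not
  reimplemented.

## Cross-validation and external statistics

All q² statistics are pooled: $q^2 = 1 - \sum(\hat y_{held} - y)^2 /
\sum(y - \bar y)^2$. LOO refits $n$ times. The leave-20 %-out scheme is
not specified by convention, so a deterministic choice is made: five
disjoint folds by rank-striping on the response (activity rank 1, 6, …
into fold 1, etc.), which stratifies every fold across the potency range
and makes repeated runs identical. External predictivity is
$r^2_\mathrm{PRESS} = (SD - \mathrm{PRESS})/SD$ with $SD$ referenced to
the *training* mean — negative values mean the model predicts worse than
that baseline, and the statistic is capped above by 1 only.

## GA feature selection

Chromosomes are binary masks over all columns, repaired by seeded random
flips into 3–10 active features (bracketing the 5–8-descriptor models
this workflow typically reports; the repair bound is configurable).
Defaults follow the classical settings: population 200, up to 1000
generations, 40 % survivors, tournament selection (size 2), 10 %
elitism, uniform crossover at rate 0.60, per-bit mutation at 0.01.

The fitness the original workflow used is not stated; this package uses
**L20 q² on the training compounds**, matching the emphasis that model
selection should reward cross-validated rather than resubstitution fit,
with a parsimony tie-break (fewer descriptors wins within 1e-9).
Elites pass unaltered, so the best-so-far trace is monotone
non-decreasing — asserted by tests. Fitness values are cached by mask,
and a fixed seed yields bit-identical subsets and traces.

Tests and the acceptance script run population 100 / 25 generations:
on the planted-signal benchmark (50 descriptors, n = 60, noise sd 0.1)
this recovers the full support in 5/5 seeds in about a second per seed,
so burning the full 200 × 1000 budget in CI would add nothing. On pure
noise the same search settles at best fitness ≈ 0.26–0.39 — selection
bias, not signal, and an order of magnitude below the ≥ 0.99 reached
with a real planted signal; the null test freezes the measured bound.

## Screening metrics

Activity classes follow the stated thresholds: active iff IC50 ≤ 400 nM
(inclusive), inactive iff > 3000 nM (strict), the band between is
*intermediate* and excluded from confusion tallies — mirroring how
two-class validation sets are constructed with a deliberate gap. Ratios
with empty denominators are reported absent (NA), never zero. ROC AUC
uses the Mann–Whitney pairwise statistic (ties ½): exact, and invariant
under monotone transforms, which matters because pharmacophore screens
produce fit-value rankings with non-hits at $-\infty$. The Güner–Henry
score $(0.75\,Ya + 0.25\,\mathrm{SEN})\,\mathrm{SPC}$ uses the yield of
actives as a *fraction*: a percentage Ya would make GH incommensurate
with the [0, 1] scale the score is conventionally reported on. Hits are retained at predicted IC50 ≤
0.5 µM (pIC50 ≥ 6.3010, boundary inclusive) and ranked descending with
id tie-breaks.

## Synthetic data: what it emulates, what it does not

The generators are pure functions of (config, seed) and cover every
pipeline input:

* `gen_pocket` — 50–500 atoms on a concave shell with named residues
  and waters, ≥2 Å apart so planted contacts stay unambiguous.
* `gen_ligands` — planted hits are point-cloud constructs whose
  perceived features reproduce a model's features: donors place their
  hydrogen exactly on the projected point; acceptors and rings can only
  point *along* the projection axis (their projection lengths are fixed
  at 1.9/2.0 Å by the perception rules), so planted fits sit below the
  $N\,W$ ceiling by a known geometric margin while every displacement
  stays inside tolerance. Hydrophobic groups are isolated through ether
  bridges so group centroids stay put, and all atoms are kept ≥1 Å
  clear of exclusion-sphere surfaces. Decoys are alkane chains, which
  lack every polar/aromatic feature type. Planted molecules are
  randomly rigidly moved, so tests also exercise alignment.
* `gen_poses` — the top-scoring pose realises each requested contact at
  2.0–2.4 Å while staying >2.6 Å from every other receptor atom; decoy
  poses stay >3 Å from the receptor entirely. The LRCF matrix of the
  output equals the planted bit pattern exactly.
* `gen_activities` — a known sparse linear model over z-scored
  descriptors, signal span anchored at 2.2 log units (the 2–2.5
  log-cycle convention for QSAR training sets), mean pIC50 7, Gaussian
  noise.
* `gen_roc_set` — latent scores N(separation, 1) vs N(0, 1), IC50s
  drawn inside the active/inactive bands at requested class sizes
  (default 383/270).

A green test on this bed establishes that the *machinery* is correct:
mapping optimality, contact exactness, split determinism, support
recovery, metric algebra. It does not establish chemical realism —
point-cloud ligands have no strain, conformer ensembles, tautomers or
protonation states, docking poses are geometric constructions rather
than energy minima, and descriptor distributions are not those of real
inhibitor series. Published per-model r² and AUC values depend on
proprietary descriptor generators and are out of scope by design.

## Known limitations

* SMILES support covers the organic subset without stereochemistry or
  isotopes; SDF is V2000 only.
* Partial charges are inputs; no charge model (e.g. Gasteiger) is
  bundled, so `Dipole_Y` defaults to zero charges unless supplied.
* The nu-SVR QP is dense: O(n²) memory — intended for n ≲ 300.
* Whether the shadow-area fraction should normalise by the shadow's or
  the whole molecule's bounding box is unknowable from the available
  description; the shadow's own tight box is used, after rotation to
  principal axes so the descriptor is orientation-free (grid step
  0.05 Å, convergence-tested).
* Plain third-order kappa is used (not the alpha-modified variant), and
  SSSR ties are broken smallest-ring-first; both are conventions, stated
  here so results are interpretable.
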
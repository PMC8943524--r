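---
title: "Models and methods behind faimscv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind faimscv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faimscv)
```

# Scope

`faimscv` couples two analyses around FAIMS-assisted cross-linking mass
spectrometry: a regression of the compensation voltage (CV) at which a
cross-linked peptide pair is transmitted, and an optimisation of two-CV
acquisition schedules per SEC fraction. Both consume cross-link spectrum
match (CSM) tables that have already been searched and FDR-filtered
elsewhere; the package performs no spectral processing and no FDR
estimation.

# Data model and filters

A CSM row carries both peptide sequences with 1-based link sites, protein
accessions with the protein position of each peptide's first residue,
precursor charge, score and delta score, matched-fragment counts per
peptide, the applied CV (absent for runs without FAIMS), SEC fraction, run
id and a target/decoy flag. Decoy rows are carried through I/O but
excluded from every count unless explicitly requested, since reported
identification numbers refer to target matches at a fixed CSM-level FDR.

Two quality conventions are applied ahead of any modelling:

* **Pre-FDR filter.** A CSM survives only if *both* peptides have at
  least `min_fragments` matched fragments (default 3) and the delta score
  is at least 0.1, both bounds inclusive.
* **Leakage-free deduplication.** CSMs are grouped by (alpha sequence,
  beta sequence, precursor charge) after lexicographic order
  normalisation of the two chains, and only the highest-scoring CSM per
  group is retained (ties: first occurrence). Link sites are deliberately
  *not* part of the key: link-site variants of one peptide pair are
  near-duplicates at the sequence level, and letting them straddle a
  train/validation split would leak sequence information into validation.

Unique residue pairs (URPs) are the non-redundant counting unit of the
schedule analysis: protein-level site = peptide start + link site − 1,
with the two (protein, site) pairs order-normalised so a link and its
chain swap coincide.

The database-reduction helper `ibaq_knee_cutoff()` places an abundance
cutoff at the knee of the descending log10 iBAQ curve. "Around the first
inflection point" admits several estimators; we use a Kneedle-style rule —
min–max normalise both axes and take the interior point of maximum
discrete curvature $|y''|/(1+y'^2)^{3/2}$ — and expose the retained count
so a user can override the cutoff. Curves with no curvature maximum
(straight or constant) are flagged degenerate and retain everything.

# Featurization

Each CSM becomes a 32-entry numeric vector (order fixed by
`default_feature_config()`): m/z and masses (monoisotopic residue table,
water 18.010565 Da, proton 1.007276466 Da; both chains keep their terminal
water and the cross-linker bridge — DSS/BS3: 138.06808 Da — is added
once); chain lengths; precursor charge; Henderson–Hasselbalch net solution
charge
$z(\mathrm{pH}) = \sum_{\mathrm{basic}} \frac{1}{1+10^{\mathrm{pH}-pK_a}} -
\sum_{\mathrm{acidic}} \frac{1}{1+10^{pK_a-\mathrm{pH}}}$
at pH 2.7 (the acidic reversed-phase mobile phase; configurable);
Kyte–Doolittle GRAVY; residue-class counts and fractions (basic K/R/H,
acidic D/E, aromatic F/W/Y, proline, glycine, hydroxyl S/T/Y, sulfur C/M,
amide N/Q, aliphatic A/V/I/L); charge density and mass per residue; the
modification count and the bridge mass. The pKa table (N-term 8.6, C-term
3.6, K 10.8, R 12.5, H 6.5, D 3.9, E 4.1, C 8.5, Y 10.1) is a standard
published set, kept in configuration so the choice is auditable. "Size"
is represented both as residue count and as mass, since either reading is
defensible. Featurization is a pure function; chains are order-normalised
first so a cross-link and its alpha/beta swap featurize identically. Two
entries (modification count, bridge mass) are constants for unmodified
single-linker tables; they cost nothing in a tree model and become
informative on mixed-linker data.

# CV regression

The applied CV is modelled as a regression target despite its discrete
5 V grid — the grid is a property of the acquisition, not of the
underlying transmission optimum. The learner is gradient-boosted trees
(squared-error objective) behind a minimal contract (fit, predict,
tree-structure attributions), backed by `xgboost` with `nthread = 1` for
bitwise reproducibility under a fixed seed.

* **Split.** 80/20 with `floor(0.8·n)` training examples and a
  seed-determined shuffle (4431 records split as 3544/887).
* **Grid search.** Every hyperparameter combination is scored by 3-fold
  cross-validated MSE with seed-determined fold assignment; the shipped
  default grid has 24 combinations for desk-scale runs, and a 1152-
  combination preset (`hyper_grid_preset("full")`) spans depth, learning
  rate, rounds, L1/L2 regularisation and row/column subsampling.
* **Metrics.** Pearson r, MSE, and the fractions within ±5 V and ±10 V
  (boundary inclusive; ±5 V is one grid step). Degenerate correlations
  (zero variance on either side) are reported as 0 with a flag rather
  than propagating NaN.
* **Attribution.** TreeSHAP-style per-example contributions via the
  booster's contribution predictions; global importance is the mean
  absolute attribution, and local accuracy (base value + attributions =
  prediction) is enforced by test to 1e-4 V.

# Schedule optimisation

For a CV grid $V$ and URP sets $A_v$ per CV $v$ (within a fraction or
pooled), every unordered pair is scored by its union $|A_a \cup A_b|$ and
overlap. Design choices where the convention was genuinely open:

* **Overlap** is Jaccard, $100·|A\cap B|/|A\cup B|$ — symmetric and
  bounded, matching a symmetric heatmap triangle. A min-normalised
  variant ($100·|A\cap B|/\min(|A|,|B|)$) sits behind the `overlap`
  switch.
* **"Yield" of a combination** is the *union* of distinct URPs, not the
  arithmetic sum — double-counting shared URPs would not measure
  identifications.
* **Ties** in `best_pair()` break deterministically: lower overlap, then
  smaller CV spacing, then less negative CV.
* **Mean CV per fraction** is CSM-count-weighted (each matched spectrum
  votes); a URP-weighted variant would differ only through multiplicity.
* **Fraction gain** compares the fraction-specific optimum to the global
  optimum *evaluated within that fraction*, as a percentage of the
  latter; a fraction where the global pair yields zero URPs is flagged
  rather than divided by.
* **Top-k versus replicates** compares equal injection counts: the best
  $j$ CV pairs merged in silico against the union of the first $j$
  no-FAIMS replicates, $j = 1..k$.

Balanced pairing implements the internal-stepping design: each CV $v$ is
paired with $v - 30\,\mathrm{V}$ where both lie on the grid, pairing a
precursor-rich with a precursor-poor CV; on the −85..−30 V grid this
yields the six pairs −30/−60 … −55/−85 V.

# The synthetic generator

The generator exists to give the pipeline data with the statistical
structure the analysis assumes, plus ground truth for recovery tests. Its
defaults are the package's study conditions and are not tuned per
experiment:

* `n_pairs = 3000` analytes from 10 random proteins (vertebrate-like
  residue frequencies), digested trypsin-like (cleavage after K/R, ≤ 2
  missed cleavages, fully tryptic C-termini, lengths 5–30); link sites at
  K/S/T/Y or the N-terminus, matching amine/hydroxyl-reactive linker
  chemistry; charges 3–7 with a mode at 4.
* SEC fractions 5–10 as equal-size mass quantile bins, heaviest bin in
  fraction 5 — larger analytes elute earlier. `couple_size_to_fraction =
  FALSE` randomises the assignment and is the null model under which
  fraction-specific scheduling should (and does) stop paying.
* True optimum `cv* = −100 + 0.035·(m/z) + 0.25·size + ε`,
  `ε ~ N(0, 5 V)`, clamped to the grid. The signs make smaller ions
  transmit at more negative CV, which is the direction of the observed
  per-fraction drift of the CV optimum; the magnitudes were chosen once
  so the cv* distribution spans the −85..−30 V grid with ~6 % clamping.
  A charge term is available (`cv_beta3`) but defaults to 0, charge
  playing a minor role in the 3–7+ range.
* Detection per run is Bernoulli with
  `p = p_max · exp(−(CV − cv*)²/(2·7²))` (`p_max = 0.85`), `p = p_max`
  without FAIMS. The 7 V window width is consistent with best CV pairs
  spaced 5–10 V apart despite large overlap.
* Scores are shifted-gamma (only their ordering matters for dedup) plus a
  small transmission-proportional bonus — better-transmitted ions give
  cleaner spectra. Site multiplicity (mean 1.3 variants) re-samples alpha
  link sites to create the redundancy deduplication collapses; 2 % of
  rows are decoy-flagged.

All four operations draw from streams derived from one master seed, so
every table regenerates byte-identically from its config snapshot.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: no precursor competition or dynamic-range model
(a no-FAIMS run samples every analyte at `p_max`, so the no-FAIMS
baseline is optimistic and the simulated top-k-vs-replicates gain is
conservative, typically negative, unlike on real complex samples where
gas-phase fractionation relieves undersampling); no chromatographic peak
shapes, retention correlation, or modification chemistry; transmission is
an idealised Gaussian of fixed width; the cv* model is linear whereas
real mobility is not.

# Numerical conventions and sizes

Positions and link sites are 1-based (modification position 0 = the
N-terminus). CVs are signed volts on a 5 V grid in [−110, −20]. The split
uses `floor`; fold assignment, shuffles and all generator draws are
`withr::with_seed`-scoped. Test and acceptance runs use 3000-analyte
simulations, 10 seeds for recovery rates, 20 seeds for the decoupled
null, and 100 random tables for the best-pair/enumeration equivalence —
sizes at which every recovery statistic is stable to well within its
asserted margin on a single CPU.

# Known limitations

Beyond the generator gaps above: the 32-feature set covers every feature
family a FAIMS CV model is known to respond to (m/z, size, solution
charge, hydropathy, composition), but real training corpora may benefit
from retention or CCS features that are out of scope here; the knee
estimator is one reading of "first inflection point" and should be
overridden when the iBAQ curve is multi-modal; and Pearson r on the
discrete CV grid slightly understates accuracy relative to the ±5 V/±10 V
margins, which is why both are reported.
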
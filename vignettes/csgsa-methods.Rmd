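---
title: "CSGSA: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CSGSA: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csgsa)
```

This vignette is the package's own account of the science it implements:
the statistical model behind each stage, the tunable parameters and why
their defaults are what they are, what the synthetic-data generator does
and does not emulate, and the decisions we took where the underlying
methodology was genuinely open.

## 1. The screening model

CSGSA (Comprehensive Serum Glycopeptide Spectra Analysis) is a fused
classifier for blood-based cancer screening. Its inputs per subject are:

1. **Nine serum tumor markers** (CEA, CYFRA, AFP, CA19-9, CA125, SCC
   antigen, NCC-ST-439, CA15-3, PSA), used as log10 concentrations —
   marker distributions are heavy-tailed and roughly log-normal, so the
   log scale is where shifts are additive.
2. **Two marker glycopeptides** — the fully sialylated biantennary
   (Hex5HexNAc4NeuAc2) glycoforms of α1-antitrypsin (Asn 271) and
   α2-macroglobulin (Asn 70) — quantified as relative expressions. These
   are the two individually most discriminative glycopeptide features and
   are kept out of the spectra block so their contribution is identifiable.
3. **The EGP spectrum**: ~1688 enriched-glycopeptide LC-MS features,
   compressed to `k = 100` principal-component scores.

Model 1 uses block 1 only; Model 2 adds block 2; Model 3 adds block 3.
The classifier's predicted probability `p` is reported as the CSGSA score
`-log10(1 - p)`, clipped so the score spans 0–10; a score cutoff of 1
(`p > 0.9`, strictly greater) defines the screening decision. The cutoff
deliberately privileges specificity: at a prevalence of 100 per 100,000
even 2% false positives outnumber true positives by a factor of ~20, so
PPV — the quantity a screening program lives or dies by — is governed
almost entirely by specificity. `prevalenceCorrect()` makes this explicit
by re-expressing an operating point in a hypothetical population at a
stated prevalence (default 100 per 100,000, configurable).

## 2. Peak processing

### Alignment

Vendor alignment software is effectively a black box, so the package uses
a deterministic, oracle-checkable rule honoring the acquisition tolerances
(0.06 Da in m/z, 0.3 min in retention time): peaks are visited in
descending intensity order (ties broken by m/z, RT, sample); a peak joins
the nearest existing feature seed within both tolerances (distance
normalized by the tolerances; ties to the lower feature index) or seeds a
new feature. Intensity seeding means the strongest, best-localized ions
define feature positions and jitter-displaced weak peaks attach to them,
not vice versa. Consensus coordinates are intensity-weighted means;
duplicate hits of one sample within a feature are summed; features present
in fewer than 10% of samples (configurable, 0 disables) are dropped as
noise — they remain available as the unassigned-peak pool. The same rule
implemented naively as all-pairs loops serves as the test oracle.

### The three-step EGP screen

Features surviving alignment pass the cascade in this order:

1. **Reproducibility**: coefficient of variation across repeated QC
   injections > 50% fails. We assume the CV is computed on QC replicates
   (the alternative — study samples — would confound biology with
   technical noise). Features absent from QC fail by definition.
2. **Reliability**: signal-to-noise < 5 fails. No standard S/N definition
   exists for aligned feature tables; ours is the feature's median nonzero
   abundance divided by the median intensity of unassigned (noise) peaks
   in a ±5 Da × ±1 min neighborhood, falling back to the global unassigned
   median, and overridable with explicit noise values.
3. **Satellites**: isotopes (a stronger co-eluting feature at −1.00336/z
   Da for any z in 1..3), adducts (stronger co-eluting partner at a
   configured neutral-mass delta; defaults Na−H +21.98194, K−H +37.95588,
   formic acid +46.00548, observed as delta/z), and fragments (stronger
   co-eluting partner at higher m/z with Pearson abundance correlation
   ≥ 0.9; the correlation heuristic is ours, configurable off). Flags are
   additive and only ever set, never cleared.

The cascade order only matters at boundary cases (a feature failing both
CV and S/N is removed either way); the per-stage survivor counts stored in
`metadata()$cascade_counts` follow the (i)(ii)(iii) order and are
monotonically nonincreasing by construction.

### Normalization

Two optional steps, both ratio arithmetic: division by a per-feature QC
reference (relative expression against the quality-control standard), then
division by each sample's relative expression of a named endogenous
internal standard (a transferrin glycopeptide in the intended use), after
which the internal standard is exactly 1 everywhere. How these two steps
interact in the original workflow is ambiguous — whether the internal
standard applies to all EGPs or only to the marker glycopeptides — so both
are exposed independently and either can be skipped.

### Missing values

Absent observations are zeros throughout, never NA or sentinel negatives;
downstream t-tests include those zeros as values. This mirrors the
below-detection interpretation of missingness in serum LC-MS.

## 3. Glycopeptide annotation

Candidate glycopeptides are the Cartesian product of tryptic peptides
(with fixed carbamidomethyl-Cys, +57.02146 Da), their N-glycosylation
sequons (N-X≠P-S/T), and a glycan composition library. The default
library is the biantennary complex-type family Hex5HexNAc4NeuAc{0,1,2} ×
dHex{0,1} — the compositions relevant to the serum markers here; the full
library searched in any given study is configurable. Masses are
monoisotopic (QTOF context; residue masses Hex 162.05282, HexNAc
203.07937, dHex 146.05791, NeuAc 291.09542, water 18.010565). Matching is
on neutral mass within 0.03 Da by binary search over the sorted candidate
list; charge deconvolution is the caller's job via `neutralFromMz()` at a
stated charge. Single-site occupancy only: the marker glycopeptides carry
one glycan each, and multi-glycosylated enumeration would explode the
candidate space without a use case here. Peptide sequences are inputs, not
hard-coded: numbering conventions (precursor vs mature chain) vary between
databases, so pinning specific tryptic peptides inside the package would
bake in one convention.

## 4. Biomarker screening

Per-feature tests are two-sided pooled-variance Student t-tests (Welch by
flag); the volcano rule selects features with p < 1e-10 and |log2 MFR| >
0.5, where MFR is the cancer/healthy ratio of group means. The fold cut
defaults to 2^0.5 ≈ 1.414 — the operational threshold drawn on the volcano
plot — rather than the rounder 1.5 sometimes quoted; 1.5 is one argument
away. **No multiple-testing correction is applied**: the raw p < 1e-10
cutoff is itself the (very stringent) selection rule, and with ~1700
features a Bonferroni factor would move the effective threshold by less
than two orders of magnitude on a -log10 axis where selected features
typically sit far beyond it. ROC-AUC is rank-based (Mann–Whitney with
midrank ties), making it invariant under monotone transforms — which is
why it is immaterial whether markers are ROC-analyzed raw or logged.

## 5. The classifiers and the evaluation protocol

* **Feed-forward network** (default learner): input → (dense 64, ReLU,
  dropout 0.3) × 2 → sigmoid output, binary cross-entropy minimized by
  Adam (lr 2e-3, batch 64, ≤150 epochs), early stopping on a stratified
  inner 10% validation split with patience 15. The topology (two
  dense+dropout blocks) is the given architecture; everything else is
  unstated and these defaults are ordinary, conservative choices for a
  ~100-feature, ~550-sample problem. All weights and dropout masks are
  seeded; fits are bit-reproducible.
* **Gradient-boosted trees**: 200 trees, depth 3, learning rate 0.1,
  logistic loss (xgboost, single-threaded for determinism). Feature
  importance is the split-frequency "F-score": how often each feature is
  used to split, summed over all trees.
* **Protocol**: 10 repeats of a stratified random 70/30 split. Within each
  repeat, *everything* fit to data — the marker log offsets, the EGP
  centering/scaling, the PCA loadings, the final column standardization,
  the classifier — uses the training fold only; the test fold is projected
  with training statistics. Test predictions are pooled over repeats
  ("cumulative" ROC) for the headline AUC; per-repeat AUCs feed the paired
  two-sided t-test in `compareLearners()` (the original comparison's test
  is unnamed; a paired t across repeats is the natural reading and is
  flagged as our assumption). Stratification is our choice too — with a
  199-vs-590 imbalance an unstratified 30% test fold would occasionally
  starve one class.
* **Leakage**: fitting PCA (or any scaler) on all samples before splitting
  is the most likely silent bug in this design. Per-fold fitting is the
  default and the all-null cohort test pins the pooled AUC to ~0.5; the
  `leakyPCA = TRUE` switch reproduces the global-PCA variant for
  comparison studies. Because PCA is label-free, its leakage on a null
  cohort is mild — the switch exists to measure that, not to use.
* Class weighting is off by default; marker glycopeptide values enter the
  model raw (they are already ratios), configurable upstream by
  transforming the input.

## 6. What the synthetic generator emulates — and what it does not

`generateCohort()` draws log-normal marker and EGP abundances with
standardized log-scale shifts between cancer and healthy. The calibration
is exact binormal theory: a feature shifted by d standard deviations has
theoretical ROC-AUC Φ(d/√2), so `effectForAUC()` lets one dial a marker to
AUC 0.8 and verify the generator empirically (unbiased to within
Monte-Carlo error, SD ≈ 0.014 at n = 500 + 500). Defaults emulate the
intended study conditions: 199 cancer / 590 healthy, a stage-I-heavy stage
distribution (weights 5/124/19/20/2/29 over 0/I/II/III/IV/unclassified),
stage-graded effect scaling (0.5, 0.8, 1.0, 1.2, 1.5, 1.0 — effects grow
with stage), CEA/CYFRA near AUC 0.8 with the remaining markers weak,
30 discriminative EGPs (the two marker glycopeptides at AUC ≈ 0.8, the
rest drawn from ±[0.8, 2.0] with random sign) against 1658 nulls, and
five QC injections modeled as re-measurements of one pooled reference with
5% log-scale technical noise. The pooled-reference QC model is an
assumption (QC standard composition is never specified in this kind of
workflow); QC injections are exempt from below-detection dropout because
dropout models biological absence, not measurement of a concentrated
pooled standard.

`renderPeakLists()` turns abundances into negative-mode centroided peaks:
m/z = (M − z·1.007276)/z, isotope peaks spaced +1.00336/z with a geometric
envelope (ratio 0.6 — only the spacing matters for deisotoping, so a
simple envelope suffices), optional adduct and sialic-acid-loss fragment
ions riding on the jittered parent coordinates, Gaussian m/z/RT jitter
truncated inside half the alignment tolerances (defaults 0.01 Da,
0.05 min), per-sample dropout (5%), and uniform noise peaks at a
log-normal noise floor.

Not emulated: profile spectra and chromatographic peak shapes (peak
picking is out of scope), retention-time drift or warping beyond jitter,
correlated marker panels, batch effects, ethnicity- or age-linked biology,
and real glycoform biochemistry. Consequently, passing tests demonstrate
that the *pipeline machinery* is correct and leak-free on data with the
assumed statistical structure — they say nothing about how a real cohort
would score, and the absolute AUCs on synthetic cohorts are not
comparable to study values. What carries over is ordering behavior
(Model 3 ≥ Model 2 ≥ Model 1 when the spectra genuinely add signal) and
all of the deterministic arithmetic.

## 7. Numerical conventions and degenerate inputs

* Alignment tie-breaks: lowest feature index at equal normalized distance;
  feature output order is (m/z, RT).
* CV with zero QC mean: fails the filter (treated as infinite CV).
* t-test with zero pooled variance: p = 1 at equal means, p = 0 otherwise.
* `replicateCV()` with a zero mean returns NA flagged `undefined`.
* Score boundary: `classifyScores()` is strictly greater-than, so a score
  of exactly 1.0 is negative.
* Display rounding in reports: counts to integers, percentages to one
  decimal (two for NPV, which lives within rounding distance of 100%);
  exact values are always retained in the returned objects, and rounded
  margins may disagree with the population by a unit or two — the exact
  margins are conserved by construction.
* All stochastic functions take explicit integer seeds and restore the
  caller's RNG state; identical seeds give byte-identical outputs.

## 8. Problem sizes used by the tests

The test suite and acceptance script run the full protocol at sizes chosen
to exercise every code path at desk scale: rendered-cohort recovery at 50
samples × 20 glycopeptide ions with isotopes, adducts and 200 noise peaks
per sample; the null leakage check at 250 + 250 samples × 1688 EGPs × 10
repeats; the model-ordering check at the full study shape (199 + 590,
1688 EGPs, k = 100) over 5 cohort seeds; matcher and alignment oracles at
10³ × 10³ and ≤ 200-peak instances. These sizes are the package's own
choices balancing statistical resolution against a test suite that stays
pleasant to run.

## 9. Known limitations

* The alignment rule is deterministic and tolerance-faithful but not a
  reimplementation of any vendor algorithm; on data whose jitter exceeds
  the stated tolerances it will split features rather than warp time.
* The fragment-ion heuristic (co-elution + correlation) can in principle
  flag a genuinely co-regulated, co-eluting glycoform pair; it is
  configurable off, and the satellite flags are kept separate precisely so
  such decisions remain auditable.
* The network learner is a compact in-package implementation — adequate
  for hundreds of features and samples, not a general deep-learning
  substrate.
* Prevalence correction assumes sensitivity and specificity transport
  unchanged from the evaluation pool to the screening population; spectrum
  bias in a case–control pool typically makes the corrected PPV
  optimistic.
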
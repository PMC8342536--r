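---
title: "Models and methods behind glycograde"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind glycograde}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycograde)
```

`glycograde` implements the post-quantification analysis of a label-free
tissue-microarray study design that pairs a protein intensity matrix with a
site-resolved glycopeptide quantification table across graded tumor and
normal samples. This vignette records the models, the tunable parameters,
the numerical choices, and the design decisions that were genuinely open —
in enough detail that a maintainer can tell which behaviors are contracts
and which are conventions.

## 1. The glycan composition model

Glycans are handled at composition level only: counts of hexose (H),
N-acetylhexosamine (N), deoxyhexose/fucose (F) and N-acetylneuraminic acid
(S), written `N4H5S1F1`-style. Linkage and positional isomers are out of
scope, which has two consequences worth keeping in mind:

* **Classification is a heuristic.** The rules — oligomannose iff
  `N = 2, H >= 5, F = S = 0`; hybrid iff `N = 3, H >= 5`; complex iff
  `N >= 3` and not hybrid; everything else "paucimannose/other" — are the
  standard composition-only assignments. They agree with the biantennary
  labels that composition `N4H5…` carries in the underlying study design,
  but a true hybrid `N4` structure would be called complex here.
* **Antenna arithmetic is a proxy.** Complex glycans get `N − 2` antennae
  (mono = N3 … tetra = N6), hybrids 1, others 0. Galactosylation counts
  hexoses beyond the three core mannoses, clamped to `[0, antennae]`;
  sialylated antennae are `min(S, antennae)`. Core versus antenna fucose
  cannot be distinguished from composition, so F is one pool and the
  fucosylation metric is binary per glycoform (`F >= 1`).

Masses are sums of residue monoisotopic masses (Hex 162.05282, HexNAc
203.07937, dHex 146.05791, NeuAc 291.09542 Da — elemental formulas with the
condensation water removed); a glycopeptide mass is the backbone mass plus
the residue sum, with no additional water because the backbone already
carries its terminal H₂O. The test suite re-derives these constants from
atomic masses as an independent oracle.

## 2. Glyco preprocessing and site metrics

Filters run once, in a fixed order, and each is idempotent:

1. **RT outlier filter** — per glycopeptide across samples, drop records
   outside `[Q1 − 1.5·IQR, Q3 + 1.5·IQR]`. Quartiles use linear
   interpolation (R's default type 7) and the bounds are inclusive; both
   choices are pinned because they change which boundary records survive.
   Groups with fewer than 4 observations pass through — quartiles of 2–3
   points are not meaningful.
2. **Minimum-area filter** — drop records with AUC strictly below 1000
   (the boundary value is kept; the wording "less than" is a strict
   inequality).
3. **Presence filters** — drop glycopeptide rows observed in fewer than 5
   samples, then sample columns with fewer than 10 observed glycopeptides.
   Applied once in that order, *not* iterated to a fixpoint: the source
   procedure describes sequential steps, and iterating would silently
   change the surviving set.

**Quotient total-area normalization** is implemented as total-area scaling
(each column scaled to the cohort-median total) followed by probabilistic
quotient normalization against the per-glycopeptide median reference
profile. The cited method's exact recipe is not restated in the source, so
this standard construction is declared here and in the provenance log. Two
proportional samples become identical; a single-sample matrix is a no-op.

**Site metric degrees** are abundance-weighted, not glycoform-counted,
because the quantities are label-free areas and the reported values are
percentages of signal: fucosylation is the fucosylated fraction of a site's
total signal; sialylation (galactosylation) is sialylated (galactosylated)
antennae over all antennae, abundance-weighted, restricted to
antenna-bearing (complex) glycoforms. Degrees are computed from the **raw
filtered abundances** — ratios of areas, not of logs; the log matrix exists
only for abundance-level testing. A degree is `NA` when its denominator is
zero for that (site, sample). All degrees are invariant to rescaling a
sample's areas, which is what makes them comparable across samples without
normalization.

Two metric definitions were open and are conventions of this package:
*branching* is the abundance-weighted distribution over antenna counts, and
the *glycan type ratio* is the abundance-weighted class fraction. Both sum
to 1 by construction.

## 3. Protein pipeline

The 60% presence rule is worded inconsistently in the source material
("any" group vs "each" group); the at-least-one-group reading is the
default (`mode = "any"`), with the stricter all-groups reading available as
`mode = "all"`. The permissive reading keeps proteins expressed only in one
tissue class — exactly the biologically interesting case.

Imputation draws every missing cell from `Normal(μ − 1.8σ, (0.3σ)²)` where
μ, σ summarize **all observed values of the matrix** (whole-matrix mode).
This encodes the left-censoring assumption: values are missing mostly
because they fall below detection. The seed is mandatory; imputation is the
only stochastic step of an analysis run and re-running with the same seed
is bit-identical.

Differential statistics: Student's (pooled-variance) t for two groups —
matching the named test; Welch is a switch — and one-way ANOVA for grade
designs, each followed by Benjamini–Hochberg adjustment at FDR 0.05. BH was
chosen over permutation-based FDR because the source's exact software
settings are unavailable; BH is transparent and is recorded in provenance.
Fold-change classes use log2 intensities and strict inequalities (a fold
change of exactly 2 is "significant only", not "over 2").

Clustering of ANOVA-significant proteins uses average linkage on
`1 − Spearman` distance over **per-group mean profiles** (4 values per
protein), matching the grade-axis presentation the split is meant to
reproduce; full per-sample profiles are a switch. The 2-cut cluster with
the larger mean PCa-minus-Normal difference is labelled "up". Identical
rows make the correlation undefined; such pairs get distance 0 (others 1)
with a warning, so the degenerate case clusters rather than errors.

Grade-scheme comparison: cancer samples carry both a pathological grade
(G1–G3) and a Gleason grade; Gleason grades are regrouped GG2 | GG3+GG4 |
GG5 and each pair of corresponding groups is compared by Pearson
correlation of group-mean vectors over a common protein set.

## 4. Statistical primitives

All primitives are self-contained so that every number the pipelines
produce can be traced to code in this package:

* **Studentized range CDF** (`psrange`): the classic double integral —
  the normal-range probability at `q·s` integrated against the scaled-chi
  density of the pooled standard deviation — evaluated on fixed
  Gauss–Legendre grids (128 nodes for the inner integral on `z ∈ [−9, 9]`,
  160 nodes for the outer on a ±12-spread interval around 1). Against an
  adaptive-quadrature reference the error is ~1e-15; against
  `stats::ptukey` it agrees to 1e-5 except at df ≤ 3 where `ptukey`'s own
  approximation error (~3e-4) dominates. Critical values match published
  α = 0.05 tables to 0.01.
* **Tukey–Kramer**: per-pair standard error `sqrt(MSW/2 · (1/nᵢ + 1/nⱼ))`
  for unbalanced designs. Note a subtlety the tests encode: because the
  error variance is pooled across all k groups (df = N − k), the adjusted p
  can be *marginally smaller* than a two-sample t-test p computed from only
  the two groups; the monotonicity guarantee that does hold — and is
  tested — is against the unadjusted pairwise p on the same pooled
  statistic.
* **BH step-up** with enforced monotonicity; equals the brute-force
  definition on all 2¹⁰ subsets of a fixed p-value pool.
* Degenerate-input conventions, all logged in the returned objects:
  zero pooled variance with equal means → p = 1; with distinct means →
  p = 0 (machine certainty); features with all-equal values or a group
  with < 2 observations are skipped with a reason rather than tested.

## 5. The synthetic cohort generator

The generator's defaults *are* the emulated study design: 95 samples
(46 Normal / 9 G1 / 16 G2 / 24 G3), the 49 cancer samples relabelled
GG2/GG3/GG4/GG5 = 7/12/15/15 by ordering a jittered latent severity (so
Gleason groups are noisy refinements of the grades, which is what makes the
grade-scheme correlations high, ≥ 0.95, without being exactly 1); 653
proteins with log2 baseline N(27, 2²), within-group sd 0.5, and MNAR
missingness `P(miss) = plogis(−(x − 24)/1)` (≈13% overall, concentrated in
low intensities — the assumption the down-shifted imputation inverts); 29
glycosites × 5 glycoforms = 145 glycopeptides from a 53-glycan pool
enumerated over N 2–6, H 3–9, F 0–1, S 0–antennae.

Glycoform allocation per site: a Dirichlet base profile (concentration 60
per sample) is exponentially tilted so the abundance-weighted degrees hit
their targets **in expectation** — closed-form reweighting for the binary
fucosylation flag, a one-dimensional root-find for antenna-weighted
sialylation/galactosylation, iterated to a joint fixpoint when a site has
several targets. Cohort-wide calibration targets (average fucosylation
0.378, average antenna sialylation 0.201 — the dataset-level descriptors of
the emulated study) are applied to every site whose glycoform panel can
attain them. Three constraints keep this honest under the MNAR detection
model (records lost with probability logistic in log2 area around the
detection limit 1000):

* panels are screened for *joint* attainability of the calibration targets
  by actually running the tilt — marginal attainability is not enough, a
  near-boundary joint target degenerates the profile;
* the tilt is retried from a uniform start, then from a reference
  biantennary panel, if the projection from the random base is degenerate
  (minimum weight < 1e-3);
* site totals are raised where needed so every designed glycoform stays
  comfortably detectable — the designed universe emulates the study's
  *post-filter* set of 145 reliably quantified glycopeptides, so "every
  designed feature is observable" is a modelling statement, not a
  convenience.

For the same reason, spiked proteins and effect-bearing glycosites draw
baselines/site totals from the upper abundance range with even glycoform
profiles: features reported as differential in such a study are, by
construction, well quantified in essentially all samples. Without this, the
minimum-area filter censors minor glycoforms of weak sites and biases the
realized degrees off their configured targets — an earlier iteration of
this generator (uniform random record dropout) failed exactly that
round-trip contract and was replaced.

What the generator deliberately does **not** model: inter-protein
biological covariance (proteins are independent given their group effects —
clustering recovery on synthetic data is therefore easier than on real
data), isotope envelopes, chromatographic peak shape, shared-peptide
protein inference, and batch effects. A green recovery test establishes
that the pipeline's statistics detect the configured effects at the study's
sample sizes and noise levels; it does not establish performance under
correlated or batch-confounded data.

Scenario presets: `null` (no effects — error-control calibration),
`paper_like` (40 up / 35 down spiked proteins with monotone grade effects
reaching ±1 log2 at G3, plus the documented site shifts: fucosylation
0.47→0.83 at PPAP N94 and 0.24→0.72 at POSTN N599, sialylation 0.83→0.44 at
POSTN N599, grade-nonmonotone fucosylation at CO6A2 N785, galactosylation
+0.11 / −0.09 at MFAP4 N137 / IGHG2 N176, small sialylation decreases at
THRB N121, IGHG2 N176 and MFAP4 N87), and `minimal` (5 samples/group, 20
proteins, 10 glycopeptides) for smoke tests. Note the minimal preset's 10
glycopeptides cannot survive the default "≥ 10 glycopeptides per sample"
filter if anything at all is missing, so smoke runs pair it with
`min_glycopeptides = 5`; the default `run_config()` keeps the reference
thresholds.

All randomness flows from one master seed split into fixed substreams
(metadata / proteins / glyco / imputation), so identical seeds give
byte-identical cohorts and partial regeneration is stable.

## 6. Testing philosophy and known limitations

Every operation has either an exact hand-computed fixture, an independent
oracle (elemental masses, brute-force BH, enumeration filters, base-R
statistical functions cross-checking the self-contained primitives), or a
simulation contract (null calibration: ≤ 1% mean discoveries and ≤ 10% of
null cohorts with any discovery; recovery: the two large spiked site
effects detected with power ≥ 0.95 and estimated within ±0.05 over 50
replicates; cluster split of the 40/35 spiked proteins correct in ≥ 95% of
replicates). The acceptance suite runs the full stated sizes in about four
minutes on one CPU.

Limitations to keep in mind when interpreting results on real data: the
per-sample site-metric testing choice (degrees per sample, then a t-test)
treats the degree as the analysis unit and ignores its within-sample
estimation error, which varies with site abundance; heavily censored sites
therefore have noisier degrees than the test assumes. The classification
and antenna rules are composition-only proxies. And BH control is across
features within one family (one metric, one design) — results across the
three metrics are not jointly corrected, mirroring the per-metric
presentation of the emulated analysis.
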
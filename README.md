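# glycograde

Site-specific N-glycosylation and protein-expression analysis for graded
tissue cohorts.

## The problem

Label-free LC-MS studies of tumor tissue microarrays produce two linked
datasets per cohort: a wide protein log-intensity matrix (with
intensity-dependent missingness) and a long glycopeptide quantification
table — one row per (sample, protein, glycosite, glycan composition)
observation with a retention time and a peak area (AUC). The scientific
questions are (i) which proteins change expression between normal and
cancerous tissue and across tumor grades, and (ii) which *glycosites*
change their glycosylation state — sialylation, fucosylation,
galactosylation, branching — even when total protein abundance does not.

`glycograde` packages the complete post-quantification analysis for this
design, for proteomics/glycoproteomics analysts who start from quant tables
rather than raw spectra:

* **Glycan model** — parsing of compact composition strings (`N4H5S1F1`:
  H hexose, N HexNAc, F fucose, S sialic acid), monoisotopic glycan and
  glycopeptide masses, maturation-class assignment (oligomannose / hybrid /
  complex / other), antenna counts and derived metric features.
* **Glyco pipeline** — retention-time IQR outlier removal, minimum-area
  filter (AUC < 1000), presence filters (glycopeptides in ≥ 5 samples,
  samples with ≥ 10 glycopeptides), quotient total-area normalization with
  log transform, and abundance-weighted glycosite metric degrees, e.g. the
  sialylation degree of site *s* in sample *j*

  ```
  sial(s, j) = Σ_g a_gj · sialic_antennae(g) / Σ_g a_gj · antennae(g)
  ```

  over the site's antenna-bearing glycoforms *g* with areas `a_gj`.
* **Proteomics pipeline** — 60% group-presence filter, left-censored
  imputation from `Normal(μ − 1.8σ, (0.3σ)²)` of the observed value
  distribution, two-group volcano statistics (Student's t, BH-FDR at 0.05,
  fold-change classes >2 / <0.5), one-way ANOVA with Tukey HSD post-hoc,
  Spearman-distance hierarchical clustering of significant proteins into
  up/down groups, and Pearson correlation of group means between the
  pathological (G1–G3) and Gleason (GG2–GG5) grading schemes.
* **Stats core** — self-contained Student's t, one-way ANOVA,
  Benjamini–Hochberg step-up, and Tukey–Kramer p-values from a
  studentized-range CDF computed by 2-D Gauss–Legendre quadrature (verified
  against published tables and against `stats::ptukey`).
* **Synthetic cohorts** — a generator that emulates the study design
  (95 samples: 46 Normal / 9 G1 / 16 G2 / 24 G3; 653 proteins; 145
  glycopeptides over 29 glycosites of 22 glycoproteins) with configurable
  spiked protein fold changes and site-metric shifts plus a ground-truth
  record, so every stage has parameter-recovery and null-calibration tests.

## Worked example

```r
library(glycograde)

comp <- parse_glycan("N4H5S1F1")
glycan_mass(comp)          # 2059.735 Da
classify_glycan(comp)      # "complex"  (biantennary, sialylated, fucosylated)

cohort <- generate_cohort(scenario_presets()$paper_like)
rec <- auc_filter(rt_outlier_filter(cohort$glyco)$kept)
gm  <- presence_filter(glyco_matrix(rec))
gm
#> glyco_matrix: 145 glycopeptides x 95 samples (raw scale)
#>   29 glycosites, 45 glycans, 2 provenance steps

d <- dataset_descriptors(gm)
sprintf("avg fucosylation: %.3f | avg antenna sialylation: %.3f",
        d$avg_fucosylation, d$avg_antenna_sialylation)
#> "avg fucosylation: 0.369 | avg antenna sialylation: 0.219"

smt <- site_metric_degrees(gm)
fm  <- site_metric_matrix(smt, "fucosylation")
grade <- setNames(cohort$metadata$grade, cohort$metadata$sample_id)
res <- glyco_differential(fm, grade[colnames(fm)], "two_group")
head(res[order(res$q), c("feature", "mean_Normal", "mean_PCa", "q")], 3)
#>       feature mean_Normal mean_PCa        q
#> 22 POSTN|N599       0.235    0.734 1.82e-52
#> 25   PPAP|N94       0.464    0.832 6.05e-39
#> 2  CO6A2|N785       0.279    0.519 1.93e-16
```

The three top sites are exactly the generator's spiked fucosylation effects
(POSTN N599 0.24→0.72, PPAP N94 0.47→0.83, CO6A2 N785 grade-dependent); the
recovered group means land on the configured targets and the q-values flag
them at the 0.05 FDR.

The full two-arm analysis, including all output tables and a provenance
JSON, runs from the command line:

```sh
Rscript -e 'glycograde::glycograde_cli()' simulate --preset paper_like --seed 1 --out cohort/
Rscript -e 'glycograde::glycograde_cli()' run --dir cohort/ --out results/
```

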
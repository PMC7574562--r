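---
title: "Models and methods behind epinipt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind epinipt}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Non-invasive prenatal testing (NIPT) reads fetal chromosomal dosage from
cell-free DNA (cfDNA) in maternal plasma. The fetal component — mostly of
placental origin — makes up only 6–10% of cfDNA in early pregnancy, so
whole-genome counting approaches need 10–20 million reads to call a
trisomy reliably. Targeted epigenetic sequencing changes the economics:
placental DNA is distinctly hypomethylated (more unmodified CGs, "uCG")
and carries more 5-hydroxymethylcytosine ("5hmCG") than the hematopoietic
DNA that dominates the maternal share. Assays that covalently tag and
sequence only uCG- or 5hmCG-containing fragments therefore *enrich* the
fetal signal per read, and chromosome-dosage statistics built on those
counts reach perfect trisomy-21 discrimination at 1–5 million reads.

`epinipt` implements the complete computational side of such a pipeline —
per-CG read assignment, coverage statistics, ordination-based sample QC,
reference-normalized Z-score karyotyping with cross-validated
classification and read-depth titration, windowed differentially modified
region (DMR) discovery, annotation enrichment, and a bin-count
fetal-fraction estimator — together with a synthetic cfDNA count
generator that stands in for sequencing data and provides planted ground
truth for every statistical claim the package makes about itself.

## The synthetic cfDNA generator

### Genome model

`build_genome()` produces a scaled-down genome: at least three named
chromosomes, a CG-site catalog placed as a homogeneous Poisson process
(default 1 CG per 100 bp, the human average) with CG-island clusters of
10x local density, simple gene-model annotations, and mQTL-style probe
positions whose "mQTL" flag is drawn independently of everything else
(making "no enrichment" the planted truth for the genotype-confounding
check).

Two per-site, per-tissue, per-assay propensity vectors encode the
biology:

* **uCG.** Blood propensities are beta-distributed (mean 0.25 — roughly
  the unmethylated fraction of CGs in somatic tissue), boosted 4x in CG
  islands (CpG islands are unmethylated in both tissues). Placental
  propensities multiply the blood values by `hypo_strength = 5` inside
  hypomethylated domains covering 40% of *each* chromosome (100-kb
  blocks, the scaled analog of the megabase partially-methylated domains
  of placenta). The per-site factor 5 corresponds to domains ~85%
  methylated in blood but only ~45% methylated in placenta; genome-wide
  it implies a placenta:blood capture-mass ratio of
  `1 + 0.4 * (5 - 1) = 2.6` per molecule.
* **5hmCG.** Sparse (8% of sites per tissue) and strongly
  tissue-specific: blood and placenta receive independently drawn site
  sets, 2x enriched over exons/3'UTRs. The placental vector is rescaled
  so the genome-wide placenta:blood mass ratio equals 0.021/0.012 = 1.75
  exactly — the ratio of global 5hmC content of chorionic-villus versus
  blood DNA measured by HPLC–MS/MS, which is the one external calibration
  the generator honors.

Domains are allocated per chromosome at a fixed fraction so that both
tissues have (near-)identical chromosome *shares* of propensity mass;
this keeps the healthy chromosome-ratio statistic independent of fetal
fraction by construction, as it is in expectation in the real assay.

A configurable set of marker windows ("planted DMRs") on the target
chromosome receives placenta-specific signal (placental propensity x 25,
blood x 0.2 over dense 8-CG clusters) — the ground truth for DMR
recovery. They are switched off (`dmr_n = 0`) in the karyotyping study
genomes so that chromosome-scale statistics are driven purely by the
domain-level biology.

### Cohorts

`simulate_cohort()` draws each sample's counts in one multinomial
allocation of `depth` reads over sites with rates

```
rate = (1 - ff) * maternal + ff * fetal
```

where `ff` is the *molecular* fetal fraction (0 for non-pregnant
controls, 1 for chorionic-villus samples, uniform on 6–10% for pregnant
samples) and the fetal (placental) component of the target chromosome is
multiplied by 1.5 for trisomy 21 — three fetal copies instead of two.
Because the tissue propensities are unnormalized, the *effective fetal
read share* is `rho = ff * alpha / (1 - ff + ff * alpha)` with `alpha`
the capture-mass ratio above; this is precisely the fetal enrichment the
targeted assays deliver. The expected multiplicative shift of the
target:reference chromosome ratio in a T21 sample is `1 + rho / 2`, the
quantity all karyotyping power flows from.

Sampling noise is pure multinomial: no per-sample biological
overdispersion is added by default (a gamma site multiplier is left as a
config hook). Fetal sex is assigned alternately and has no effect on
counts — it exists as a null covariate for the DMR models. Read starts
can be materialized (`emit_read_starts()`) with up to 3 bp of uniform
jitter and a uniform strand to exercise the assignment rule.

### What the generator does not emulate

No sequence-level artifacts (no FASTQ, error or adapter models), no
cfDNA fragment-length structure, no inter-individual epigenome
variability, no batch effects, and no bin-specific 5hmC depletion of the
kind that can invert the apparent fetal-fraction relationship when a
fixed-weight estimator such as SeqFF is applied to 5hmC-targeted counts
(a property of that estimator's bins and weights, not reproducible
here). Passing tests therefore demonstrate that the *statistical
machinery* is correct and well-calibrated under the stated mixture model
— not that the pipeline is robust to every failure mode of real
sequencing data.

## Coverage statistics

A read is assigned to the nearest catalog CG whose C position lies
within 3 bp of the read's 5' start, on either strand, with ties broken
to the lower coordinate and unassignable reads dropped (and tallied).
The assays prime sequencing from the tagged CG itself, so read starts
cluster within a few bases of the C; the 3-bp radius, the absolute-
distance metric and the lower-coordinate tie rule are our precise
rendering of that geometry, and unique assignment (never double-counting
a read between two nearby CGs) is a deliberate choice. Coordinates are 0-based half-open (BED convention) throughout.

Chromosome-level signals are **CG-coverage** (total reads on a
chromosome's CGs) and **CG-fraction** (fraction of its CGs covered at
least once). Windowed variants tile chromosomes with fixed-width,
non-overlapping windows (100 bp for DMR work, 1 kb for enrichment);
windows without CGs are excluded and counted. In-silico downsampling
draws reads without replacement (multivariate hypergeometric), so
column sums equal the requested depth exactly.

## Sample QC by ordination

Counts are Hellinger-transformed (square root of within-sample relative
abundance), converted to Bray–Curtis dissimilarities, embedded in two
dimensions by non-metric multidimensional scaling (Kruskal stress-1,
vegan's engine, 20 random restarts, classical-scaling initialization),
and screened by the per-group 2-SD rule: a sample further than two
standard deviations from its own group's mean on either axis is flagged
(never silently dropped). Groups smaller than three cannot support the
rule and are skipped with a warning. The rule is scale-equivariant, so
the arbitrary nMDS scale is harmless. Note "Bray–Curtis similarity
index" in the assay literature denotes the standard dissimilarity form
used here.

## Karyotype Z-scores and cross-validated classification

For sample *i*, `X_i` is the ratio of target-chromosome signal
(CG-coverage or CG-fraction) to the same signal on a reference
chromosome; `Z_i = (X_i - mu) / sigma` with `mu`, `sigma` estimated from
the healthy-pregnancy samples. The SD convention is the sample SD
(n − 1) by default, `"population"` being one switch away. Reference-chromosome pairings reported for these assays
are inconsistent (chr16/uCG with chr20/5hmCG, or the reverse); the
package defaults to chr16 for uCG and chr20 for 5hmCG and says so once
per session. Whether non-pregnant controls should enter `mu`/`sigma` is
an equally open choice; we use healthy pregnancies only, configurable
through `healthy_ids`.

Leave-one-out cross-validation re-estimates `mu`/`sigma` *within each
fold* (a held-out healthy sample never standardizes itself) and fits a
logistic regression of karyotype on Z to the retained samples. Because
the Z-scores separate the classes completely whenever the assay works,
the fit is ridge-stabilized (penalty 1e-4 on the standardized slope) —
an unpenalized fit would diverge exactly in the regime of interest.

Two numerical decisions deserve emphasis:

* **Accuracy** uses the held-out class probability at the 0.5 cutoff.
* **AUC** is the midrank Mann–Whitney statistic over the held-out
  *Z-scores*, not the pooled fold probabilities. Pooled LOOCV
  probabilities are not rank-comparable across folds: each fold's
  intercept encodes its own class base rate, which under a null signal
  systematically orders held-out negatives above held-out positives and
  drives pooled-probability AUC far below 0.5 (we measure ~0.3 at
  n = 13, at any sample size). The held-out Z is an out-of-sample score
  on a common scale; with real signal the two definitions agree, and
  under the null the Z-based AUC is correctly centered at 0.5. The
  per-window classifier applies the same reasoning by scoring held-out
  samples with the slope-only linear term.

`depth_titration()` repeats subsample → chromosome stats → Z → LOOCV for
each requested depth (30 repetitions by default, per-repetition seeds
derived deterministically from the base seed) and can append natively
shallow samples to every evaluation at their own depth.

## DMR discovery

Per 100-bp window and sample, features are `norm_cov = log2(coverage +
1) - log2(reference-chromosome total)` (log-transformed coverage needs a
pseudocount for empty windows; 1 is our choice) and `norm_frac` =
window CG-fraction divided by the reference chromosome's CG-fraction.
Each window is tested by the logistic likelihood-ratio: full model
`group ~ norm_cov + norm_frac [+ fetal_sex + ff]` against the null
carrying only the covariates, chi-squared with df = 2. Windows whose
full model fails to converge are retried with fetal sex removed *from
both models* (df stays 2); windows that still fail get `p = NA` and stay
out of the BH-FDR adjustment (q < 0.05 default, nominal p < 0.05
exposed as the documented fallback for sparse assays). Effects are
reported as log2 fold changes of linear-scale group means with
`eps = 0.5 * smallest positive mean`.

Set comparisons use the sample odds ratio `ad/bc` over a stated window
universe (all successfully tested windows; the universe is configurable
because no canonical choice exists), with a 0.5 Haldane correction when
a cell is empty and Fisher's exact two-sided p. Effect concordance
between contrasts is a Pearson correlation; positional comparisons use
the two-sample Kolmogorov–Smirnov test. Per-window discriminatory power
is a LOOCV logistic classifier with a weakly-informative Gaussian
penalty (scale 2.5 on standardized slopes, a deterministic stand-in for
the Student-t-prior Bayesian GLM this emulates).

### Calibration at small n

The asymptotic chi-squared reference of the logistic LRT is
anticonservative at cohort sizes like 7 + 8 (type-I error near 0.09 at
nominal 0.05 in our measurements — a textbook small-sample property, not
an implementation artifact). The package therefore validates *calibration*
on effect-free cohorts of 60 + 60 samples, where the reference is
accurate (measured type-I ≈ 0.05, p-value ECDF deviation ≈ 0.014), and
validates *power and recovery* at paper-scale cohort sizes where the
planted effects are strong enough that mild anticonservatism is
irrelevant. Calibration windows are restricted to those with a mean
coverage of at least 2 reads: near-empty windows yield quasi-discrete
features whose LRT cannot be uniform for any sample size.

## Enrichment analyses

Per group, 1-kb windows at or above the 90th percentile of group-mean
coverage are "top-signal" windows (boundary ties all included, making
the selection deterministic; a uniform profile degenerates to all
windows and is flagged). Enrichment is evaluated at CG-site resolution:
each catalog CG is cross-classified by top-window membership and
annotation overlap (C position inside the half-open interval), with
Fisher's exact test. The default CG universe is the full catalog, not
just covered CGs — also configurable, since either reading is
defensible. mQTL-probe screening applies the same table at probe
resolution plus the fraction of DMRs containing a flagged probe.

## Fetal-fraction stand-in

A ridge-penalized linear regression of known fetal fractions on
depth-normalized 50-kb bin proportions. This honors the *contract* of
count-based, fetal-sex-independent estimators (fetal reads redistribute
coverage toward placentally distinctive bins) without re-implementing
any published tool: no published weights exist to port, so the model
must be trained on samples with known reference fractions. Ridge rather
than elastic net keeps it closed-form, single-hyperparameter and
deterministic. Row normalization makes predictions exactly invariant to
sequencing depth; outputs are clipped to [0, 1]. On held-out synthetic
samples it recovers ff with r > 0.99 and MAE < 0.01 at default settings;
the package makes no claim about slopes observed when external
estimators are applied to these assays.

## Study-scale simulation twins

The acceptance analyses evaluate the performance the package documents
on synthetic cohorts: uCG 7 NPC / 8 healthy / 5 T21 / 7 CVS, 5hmCG 7 / 7 / 4 / 3,
ff ~ U(0.06, 0.10), T21 dosage 1.5. Depths quoted on the human 28M-CG
scale are mapped by per-CG density: `depth * n_sites / 28e6`. Genome
sizes are fixed at ~1.2M CG sites (uCG; 54/54/12 Mb) and ~2M sites
(5hmCG; 90/90/20 Mb), with the target and the assay's reference
chromosome carrying 45% of CG mass each. The sizing argument, made once
at design time on the closed-form mixture model: the multinomial
sampling SD of the chromosome ratio at the shallowest titrated depth
must sit far enough below the minimum T21 effect `0.5 * rho(0.06)` that
the worst fetal-fraction draw still clears every leave-one-out decision
boundary in all 30 subsampling iterations — tens of thousands of reads
on the target chromosome, the same counting regime in which the real
analyses operate. The full-depth libraries are the scaled equivalent of
8M (uCG) and 4M (5hmCG) processed reads.

DMR recovery and null calibration run instead on the compact default
genome (3 x 2 Mb), where planted marker windows receive ~10–20 reads in
the affected group — the data-rich windows where real DMRs live — and
12,000+ windows are tested per run.

## Known limitations

* The generator's effect sizes are calibrated to the assays' global
  biochemistry, not fitted to any real count matrix; absolute DMR
  counts, odds ratios and correlations from real cohorts are outside
  what desk-scale simulation can or should reproduce.
* The LRT's small-sample anticonservatism is reported, not corrected;
  at paper-scale n the q-values should be read as approximate.
* nMDS is a local optimizer; with 20 restarts the embeddings are stable
  in practice, but stress equality across platforms is not guaranteed
  beyond the seeded RNG (R's Mersenne-Twister throughout).
* `run_pipeline()` is an orchestrator for demonstration-scale configs;
  the study-scale analyses are driven through the individual functions
  (as `scripts/acceptance.R` does) to keep memory bounded.
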
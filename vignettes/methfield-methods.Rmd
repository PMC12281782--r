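---
title: "Models and methods behind methfield"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind methfield}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(methfield)
```

methfield analyzes Illumina EPIC-style DNA methylation in cohorts where
each patient contributes several tissue samples — cancer, normal tissue
adjacent to the tumor, and normal tissue distant from it — and where the
clinical endpoints (biochemical recurrence after prostatectomy, later
metastasis) are properties of the *patient*, not of the sample. Every
statistical choice in the package follows from that two-level structure.
This vignette records the models, the tunable parameters, and the design
decisions that were genuinely open.

## Patient-aware differential methylation

Beta values $\beta_{js}$ (probe $j$, sample $s$, in $[0,1]$) from samples of
the same patient are strongly correlated. `mixed_group_test()` tests a
patient-level group label on all samples with a compound-symmetry
generalized least squares model, the array-world approximation of a
random-intercept model:

1. **Consensus correlation.** For each probe, an intraclass correlation is
   estimated from the one-way (patients) ANOVA of the residuals after
   removing group means, on the logit (M-value) scale, which is closer to
   variance-stabilized than the beta scale. Per-probe estimates with 16
   patients are noisy, so they are pooled by Fisher-z averaging into one
   consensus value $\rho$ — the same strategy limma's
   `duplicateCorrelation` uses. The pooled value is clamped to
   $(-1/(k_{\max}-1),\ 0.99)$, the range in which a compound-symmetry block
   of size $k_{\max}$ is positive definite.
2. **Per-probe GLS.** With $\rho$ fixed, each probe is fit by GLS under the
   block covariance $\sigma^2[(1-\rho)I + \rho J]$ per patient. The
   whitening transform is analytic (block eigenstructure), so all probes are
   processed by one matrix operation. The Wald $t$ on the group coefficient
   uses $n - 2$ degrees of freedom, as limma's `gls.series` does.
3. **FDR.** Benjamini–Hochberg across probes; candidates are called at
   $q < 0.05$.

Tests run on beta values by default so the reported effect is the modeled
group difference in beta, the scale the heatmaps use; `m_values = TRUE`
switches the test to the logit scale (the effect column then reports the
difference of group mean betas). With one sample per patient and $\rho = 0$
the procedure reduces exactly to the ordinary two-sample linear-model
$t$-test; the unit tests check this to $10^{-10}$ and check agreement with
limma's block fit to $10^{-8}$ when both are given the same $\rho$.

No tissue-class covariate enters the outcome tests — all samples of
recurrence patients are contrasted against all samples of non-recurrence
patients, which is precisely the "field effect" question: does the signal
show regardless of whether the sample is cancerous. An optional
empirical-Bayes-style variance shrinkage (`moderate_variance`) is off by
default and recorded in the result attributes either way.

`de_mixed_test()` applies the same machinery to log2-CPM (prior count 0.5)
gene counts; `grouping = "tissue"` contrasts cancer against pooled normal
samples, a within-patient contrast for which the patient blocks are
retained. A negative-binomial GLMM would model counts more faithfully; the
linear mixed model on log-CPM was chosen as the stated contract and is
well calibrated at these library sizes.

## Heterogeneity framework

Variability and similarity are measured separately, because low
variability does not imply similarity:

* **Interpatient CV** — one random sample per patient (all tissue classes
  eligible), one CV ($s/\bar x$, $n-1$ denominator) per CpG across the 16
  values; averaged over 10 random draws.
* **Intrapatient CV** — all samples of one patient, one CV per (patient,
  CpG); single-sample patients are skipped and listed.
* **Matched nulls** — sets of the same size as the DMC set (37 or 20) drawn
  uniformly from all filtered CpGs, 10 iterations for CV and 100 for
  correlations, averaged per position.
* **Similarity** — Spearman correlation of two samples' beta profiles over
  the CpG set, per patient and tissue type (normal pools adjacent and
  distant; a flag splits them); with more than two samples of a type, two
  are drawn once per run (seeded), with fewer than two the value is NA.
  Cancer-vs-normal similarity correlates the patient's mean profiles.

Distributions are compared with the two-sided Wilcoxon rank-sum test. The
pooled set of all (patient, CpG) intrapatient CVs enters that comparison;
the sample-SD convention uses $n-1$ since per-patient $n$ is 3–5.

## Enrichment

Chromatin tracks are 17-state ChromHMM segmentations, collapsed to six
groups: promoter (TssA, TssBiv, TssFlnk, TssFlnkD, TssFlnkU), enhancer
(EnhA1, EnhA2, EnhBiv, EnhG1, EnhG2, EnhWk), PRC (ReprPC, ReprPCWk),
transcribed (Tx, TxWk), heterochromatin (Het) and quiescent (Quies) — the
groups partition the 17 labels. Manifest positions are 1-based, BED
segments 0-based half-open; the two conventions meet in exactly one
function (`assign_cpgs_to_segments()`: position $p$ is inside $[s,e)$ iff
$s \le p-1 < e$), everywhere else coordinates are passed through verbatim.

Enrichment of a CpG set against the array background is the hypergeometric
upper tail on the in-category counts, with fold the ratio of category
frequencies. BH correction is applied within each track's six state groups
and within each run's TF set — the natural test families. Cell-line tracks
are analyzed separately, never unioned.

TF binding sites are padded ±150 bp into binding regions and merged per TF
into maximal disjoint intervals; touching intervals merge (half-open
adjacency means no gap) and padding clamps at coordinate 0 since BED
forbids negative starts. A CpG inside two TFs' regions counts for both —
the tests are per-TF. Interval intersection and merging use
GenomicRanges/IRanges.

## Risk model

`loocv_selection()` implements leave-one-sample-out Cox elastic-net
stability selection: in each of the $n$ iterations the model is trained on
$n-1$ samples, with the held-out sample's linear-predictor risk score
recorded. The elastic-net mixing parameter defaults to 0.1 — mostly ridge, which
keeps most candidate CpGs in the model rather than forcing a sparse pick
among correlated probes. (An alternative convention uses a single number
like 0.1 as the penalty *strength*; both are runnable, the mixing reading
is the default because keeping candidates is the point of the procedure.)
The penalty strength itself is chosen per iteration by
5-fold cross-validated partial-likelihood deviance (Verweij–van
Houwelingen construction, which never forms degenerate held-out risk sets
under tied times). The one-standard-error rule picks the penalty: with
leave-one-out training sets that are nearly identical, the deviance-minimum
rule reproducibly admits chance associations of pure-noise candidates
(their selection frequency is essentially 0 or 1, never intermediate), and
the 1se rule is the conventional guard; `lambda_rule = "min"` remains
available.

The final model keeps candidates with nonzero coefficients in strictly
more than 50% of iterations; each coefficient is the mean of its nonzero
per-iteration values; the stratification cutoff is the median training risk
score, with ties assigned to the high-risk group (a deterministic,
documented, admittedly arbitrary choice). Groups are compared by
Kaplan–Meier curves (via survival::survfit) and the two-group log-rank
test.

The penalized Cox fitter itself (Breslow ties, objective
$-\ell/n + \lambda(\alpha\|\beta\|_1 + \tfrac{1-\alpha}{2}\|\beta\|_2^2)$ on
standardized columns) is iteratively reweighted least squares with cyclic
coordinate descent in compiled code, with a step-halving guard that keeps
the penalized objective non-increasing; it matches `survival::coxph` at
$\lambda = 0$ to $10^{-6}$ and glmnet along the path to $\sim 10^{-4}$.
The inner lambda path spans a factor of 20 (lower bound 5% of
$\lambda_{\max}$): with fewer events than candidates, the near-unpenalized
end of the path has a monotone partial likelihood and no finite optimum.

Leave-one-*sample*-out is implemented exactly as stated, although samples
of the same patient then share outcome information between training and
test folds; this leaks optimism into held-out scores, which is why the
headline result is the final-model median split rather than a held-out
performance estimate.

## The synthetic cohort

Real data for this design are access-restricted, so the generator is a
first-class module whose defaults *are* the study conditions: 16 patients,
11 recurrence, 5 metastasis (a subset), 3–5 samples per patient with mode
4 (two cancer, one adjacent, one distant), 10,000 probes, 37
recurrence-spiked and 20 metastasis-spiked CpGs with ~10% overlap.

Betas are the logistic transform of a hierarchical normal model on the
logit scale: per-CpG baseline $\mu_j \sim N(\mathrm{logit}(0.35), 0.5^2)$,
a patient random effect (SD `sigma_inter` = 0.22) and sample noise (SD
`sigma_intra` = 0.18). The two SDs were fixed once by matching the
generator's *null* CpGs to the published whole-array medians of
interpatient (~0.17) and intrapatient (~0.12) CV; the simulated medians are
~0.17 and ~0.11. Spiked CpGs add their group shift at the patient level —
that is the core structural assumption, prognostic methylation with high
between-patient and low within-patient variation. The shift size is
`delta_beta` = 0.2 on the beta scale (converted per probe to a logit
offset, so values stay inside $(0,1)$ by construction); metastasis shifts
are 90% methylation loss. Designated QC failures (1% each of low bead
count, high detection p, close SNP) are placed on non-spiked probes.

Chromatin tracks tile each synthetic chromosome with one segment per probe
(boundaries midway between adjacent probes); the state at probe positions
is drawn from a background distribution that weights promoters at 0.20 —
an *array* background, reflecting the EPIC design's promoter bias, not a
genomic share — and recurrence-DMC positions inflate the promoter
probability by `promoter_enrichment_factor`. The TFBS track plants sites of
5 named factors within 150 bp of spiked DMCs over a uniform background.
Survival times are exponential with patient log-hazards supplied by the
caller (e.g. built from true DMC betas), censored administratively at
96–192 months; the baseline median event time of 120 months gives a
baseline event fraction near the cohort's 11/16 over that window.

What the generator does **not** emulate: the bimodal whole-array beta
distribution (baselines are unimodal mid-methylation), probe
cross-hybridization, batch and tissue-composition effects, real linkage
between methylation and expression, and realistic genomic clustering of
CpGs. Passing tests therefore demonstrate that the *procedures* recover
planted structure under the assumed two-level model, not that they would
behave identically on arrays from tissue.

## Numerical choices and degenerate inputs

* QC filter boundaries are strict: bead count 3, detection p 0.05 and SNP
  distance 5 bp are retained. QC fields are per-probe scalars (worst case
  across samples).
* CV with mean 0 and Spearman with zero rank variance return NA with a
  warning rather than an error; missing betas propagate pairwise-complete.
* The exact Wilcoxon enumeration is used up to $n_a + n_b = 12$ without
  ties; beyond that the tie-corrected, continuity-corrected normal
  approximation.
* A log-rank comparison with zero events returns a flagged $p = 1$ result
  rather than an error; zero-subject groups are errors.
* All resampling (CV draws, two-sample picks, null CpG sets, fold
  assignments) is seeded; reruns with one seed are byte-identical, and
  LOOCV canonicalizes unit order so results are invariant to input row
  permutation.
* Cohort-summary percentages use non-missing denominators (the published
  pT column works this way: 4/15 = 26.7%); IQR is the 25th/75th percentile
  with linear interpolation.
* Heatmap ordering uses Euclidean distance with average linkage, a neutral
  default.

## Problem sizes in the test suite

The suite exercises the full 10,000-probe cohort for recovery checks (5
seeds), a 2,000-probe null cohort for calibration, 10 seeds of the
37-candidate risk model, and a 1,200-probe end-to-end determinism run —
sizes chosen so the whole suite completes in a few minutes while keeping
every check at the cohort's real dimensions (16 patients, ~64 samples).
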
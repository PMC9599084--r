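---
title: "Methods: ceRNA networks and survival risk scores for checkpoint-blockade response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ceRNA networks and survival risk scores for checkpoint-blockade response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope and model overview

`ceRNAicb` implements a transcriptomic analysis of response to immune
checkpoint blockade (ICB) in small pre-treatment tumour cohorts, centred on
circular RNAs (circRNAs) and long non-coding RNAs (lncRNAs) acting as
competing endogenous RNAs (ceRNAs). The pipeline has five analysis stages —
multi-caller circRNA consensus calling, circular-to-linear junction ratios,
negative-binomial differential expression, ceRNA–miRNA–mRNA network
assembly, and a Cox-coefficient signature risk score with Kaplan–Meier and
log-rank stratification — plus a seeded synthetic-data generator that plants
known structure so every stage can be validated end to end.

```{r, eval = FALSE}
library(ceRNAicb)
res <- run_pipeline(list(simulate = list(), seed = 1L), outdir = "run")
```

# circRNA consensus calling

circRNA callers quantify a back-splice junction (BSJ) — the head-to-tail
junction unique to a circle — but disagree on coordinate conventions.
`harmonize_calls()` shifts each caller's coordinates by a per-caller offset
profile onto a canonical 0-based half-open interval with mandatory strand;
profiles are configuration, with shipped defaults for five widely used
callers (CIRCexplorer2 emits BED and shifts by `c(0, 0)`; CIRI, DCC,
STARchip and CIRIquant report 1-based closed intervals and shift by
`c(-1, 0)`). Records whose interval collapses after shifting are rejected
and counted, never silently dropped.

The high-confidence filter retains a circRNA when (a) at least
`min_callers = 3` callers reported it anywhere and (b) it shows at least
`min_reads = 2` BSJ reads in at least `min_samples = 2` samples. Two
readings of (b) are available. The default `reads_scope = "merged"`
evaluates it on the per-cell maximum over callers, i.e. any caller's
evidence counts; `reads_scope = "per_caller"` demands the reads/samples
condition within each of at least three callers. We deliberately do *not*
evaluate (b) on the median-merged counts: the median over the
reporting-caller set falls when one additional caller reports the circRNA
with low counts, so a median-based filter would let extra supporting
evidence *remove* a high-confidence circRNA. The max-based reading keeps
the retained set monotone — adding an observation or incrementing a count
can only grow it — which the test suite checks on a thousand random
perturbations.

Consensus *quantification* is separate from filtering:
`consensus_counts()` reports, for each circRNA and sample, the median BSJ
count across the callers that reported the circRNA anywhere (rounded half
to even). The median is robust to a single caller's outlier
quantification; callers that support the circRNA but missed a given sample
contribute zeros, which is the conservative choice for sparse BSJ data.

# Circular-to-linear ratio

For a locus with `bsj` back-splice and `fsj` forward-splice junction reads
the circular fraction is `2*bsj / (2*bsj + fsj)`; BSJ reads are doubled
because each circular junction is one of two junction-spanning ends. The
ratio is 1 exactly when the locus is transcribed only circularly and is
undefined (`NA`, never a number) when both counts are zero. When a ratio is
requested for a pooled scope (cohort or response group), junction reads are
summed over the scope's samples *before* applying the formula — the ratio
of pooled counts, not the mean of per-sample ratios, which keeps the
reported value interpretable as the formula applied to total evidence;
per-sample values are available via `by = "sample"`.

# Differential expression

`nb_wald_test()` fits, per feature, a negative-binomial GLM with log link,
an offset of `log(size factor)` and a two-level group covariate
(responder vs non-responder). Size factors come from each sample's *total
linear mapped reads*, rescaled to geometric mean 1 — BSJ matrices are far
too sparse to self-normalize, and anchoring both circRNA and lncRNA
matrices to the same linear totals keeps their fold changes on one scale.

The NB dispersion $\alpha$ (variance $\mu + \alpha\mu^2$) is estimated
gene-wise by maximizing the Cox–Reid adjusted profile likelihood, bracketed
by a method-of-moments value and floored at `1e-8`. The Cox–Reid term
(half the log-determinant of the information of the fitted means) corrects
the downward bias of plain ML dispersion at 12 samples; without it the
Wald test is visibly anti-conservative in null simulations. The Wald
statistic is the group coefficient over its expected-information standard
error with a two-sided normal reference. Perfect separation (one group all
zero) caps the natural-log coefficient at ±10 and flags the feature rather
than dropping it; all-zero features are reported with `status = "zero"`
and no test.

Significance combines Benjamini–Hochberg adjustment over tested features
with `padj < 0.1` and `|log2FC| > 1.5`. The fold-change threshold is
interpreted on the log2 scale by default; `lfc_scale = "linear"`
(`|log2FC| > log2(1.5)`) is provided because descriptions of such analyses
often leave the scale ambiguous, and the two readings differ materially.
No independent filtering, shrinkage, or outlier replacement is applied;
parity with DESeq2's full post-processing is a non-goal, though the test
suite cross-checks the fold-change estimates against a DESeq2 fit on a
shared fixture.

# ceRNA network

The network joins differentially expressed ceRNAs (circRNAs and lncRNAs)
to differentially expressed mRNAs through shared miRNAs. mRNA–miRNA
predictions aggregated from up to seven tools are kept only with support
from at least five tools; the miRNA layer is restricted to miRNAs that
interact with at least one DE ceRNA. An edge (ceRNA, mRNA) exists when
some retained miRNA targets both, and carries the full shared-miRNA set as
annotation. Because no miRNA expression is available in this design,
miRNAs are annotations on ceRNA–mRNA edges, not statistical nodes.

Edges are validated by the Pearson correlation of
`log2(size-factor-normalized count + 1)` expression between the two
endpoints. The sponge model predicts de-repression — a *positive*
ceRNA–mRNA correlation — so the default keeps positive-correlation edges
only (`keep = "positive"`, `r_min = 0`); `keep = "all"` retains everything
with `pearson_r`/`pearson_p` attached for downstream filtering. The
transform is a package choice (the convention for count correlation);
zero-variance endpoints are dropped with a logged count.

# Survival risk score

The signature is the union of DE circRNAs and DE lncRNAs. Expression is
normalized as `log2(normalized + 1)` and z-scored per feature, making Cox
coefficients comparable across features. Each feature gets a univariate
Cox proportional-hazards coefficient (partial likelihood, Efron tie
handling, Newton–Raphson to `1e-9`, at most 50 iterations); monotone
likelihood is capped at ±10 with a flag, zero-variance features are marked
untestable with coefficient 0. The per-patient risk score is
$RS = \sum_i \mathrm{expr}_i \cdot \beta_i$ over the signature. Patients
split at the median score (scores strictly above are high risk; the median
patient goes low), a convention chosen because the cutoff is rarely
stated in signature studies and the median is the least tunable choice; a
numeric cutoff is accepted. Coefficients are trained on overall survival
by default (`endpoint = "pfs"` switches), and both OS and PFS are always
evaluated with Kaplan–Meier curves (Greenwood variance on the
log(−log S) scale, medians with 95% CI, unreached bounds reported as NA)
and the two-group log-rank test.

With a pilot-sized cohort (12 patients) and tens-to-hundreds of signature
features, per-feature Cox fits are unstable; `build_risk_model()` warns
whenever features outnumber patients and the coefficients should then be
read as descriptive weights, not transportable hazard estimates.

# Synthetic data and what it does (not) show

The generator's defaults encode the targeted study design: 8 responders
vs 4 non-responders; five callers with per-(locus, caller) detection
probability 0.8 and the five shipped coordinate conventions, each caller
re-quantifying per-sample BSJ counts with Poisson noise; NB counts
(dispersion 0.1, base means log-normal around 100 for expression matrices
and a tenth of that for BSJ counts) with a planted |log2FC| of 2 in a
random direction on 10% of features per matrix; interaction tables whose
planted (ceRNA, miRNA, mRNA) triples pair direction-concordant partners
and carry mRNA-side support of at least 5 tools while decoys draw support
from a low-concentrated distribution; and exponential survival with
baseline hazard 0.05 events/month, log-hazard 1 per standard deviation of
the planted-signature signal, and 20% independent exponential censoring
calibrated at the average hazard. Every stage draws from its own
label-hashed substream of one master seed (`substream_seed()`), so stages
rerun independently yet reproducibly, and the truth tables are exhaustive
by construction.

What the generator does not emulate: read-level artefacts (FFPE
degradation, GC bias, alignment ambiguity), correlated caller errors
(dropout is independent per caller), real miRNA binding-site structure,
and non-proportional hazards. Passing tests therefore demonstrate that the
statistical machinery recovers structure of the assumed form at realistic
sizes — not that the assumed form matches any particular dataset.

Test problem sizes are the package's validation choices: consensus
brute-force equivalence on a hundred random fixtures of up to 60 circRNAs
with a thousand monotonicity perturbations; DE power and calibration at
6 vs 6 samples, 200 planted and 200 null features over 50 seeds; network
brute-force equivalence on a hundred random bipartite fixtures and
correlation-sign recovery over 500 draws at $\rho = 0.9$, $n = 12$; Cox
recovery at $n = 200$ over 100 seeds, log-rank type-I error over 1,000
null replicates at $n = 50$, and end-to-end stratification at $n = 100$
over 30 seeds.

# Numerical choices and degenerate inputs

* Dispersion search on the log scale over $[10^{-8}, \max(100, 100\cdot
  \hat\alpha_{MoM})]$ with `optimize()` at tolerance `1e-4`; per-group
  mean solved by Newton's method to `1e-10`.
* Median consensus counts round half to even (R's `round()`).
* Undefined ratios propagate as `NA` and are excluded from summaries with
  a logged count.
* BH adjustment runs over tested features only; `zero` and `low_count`
  features keep `NA` adjusted p-values.
* `stratify()` refuses all-identical scores; `km_curve()` treats a cohort
  with no events as flat curves with unreached medians, not an error.
* Hierarchical clustering for reporting uses 1 − Pearson distance with
  average linkage on z-scored features, the common heatmap default; rows
  with zero variance are excluded from the feature dendrogram.

# Known limitations

* The Wald test remains slightly liberal at 6 vs 6 even with the
  Cox–Reid adjustment; exact small-sample calibration would need
  permutation or quasi-likelihood approaches, out of scope here.
* Caller offset profiles cover coordinate conventions only; callers that
  disagree on the junction itself (e.g. ambiguous alignments) produce
  distinct loci rather than being reconciled.
* The risk model reuses one stratification for OS and PFS; features are
  trained on a single endpoint.
* Interaction tables are taken as given; no sequence-based target
  prediction is performed.
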
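# ceRNAicb

circRNA/lncRNA ceRNA-network analysis and survival risk scoring for
immune-checkpoint-blockade (ICB) response.

## The problem

Response to PD-1/CTLA-4 blockade in metastatic melanoma is hard to predict
from pre-treatment biopsies, and small pilot cohorts (here the design is
12 samples: 8 responders vs 4 non-responders) are the norm. Circular RNAs
(circRNAs) and long non-coding RNAs (lncRNAs) can act as competing
endogenous RNAs (ceRNAs) — miRNA sponges that de-repress the miRNAs' mRNA
targets — and their pre-treatment expression may carry a response signal.
`ceRNAicb` packages that analysis as tested, reusable stages for anyone
working with multi-caller circRNA quantifications, count matrices and
survival endpoints:

1. **Consensus calling.** Per-caller back-splice junction (BSJ) calls are
   harmonized onto canonical 0-based half-open coordinates via per-caller
   offset profiles, then filtered to high confidence: ≥ 2 BSJ reads in
   ≥ 2 samples and support from ≥ 3 of the callers. The consensus count is
   the per-cell median across reporting callers.
2. **Circular-to-linear ratio.** For BSJ and forward-splice (FSJ) reads,
   the circular fraction of a locus is `2·bsj / (2·bsj + fsj)` ∈ [0, 1],
   pooled over samples before the formula is applied.
3. **Differential expression.** Per-feature negative-binomial Wald GLM
   (log link, group covariate), size factors anchored to total *linear*
   mapped reads, Cox–Reid adjusted ML dispersion; significance at
   BH-adjusted p < 0.1 and |log2FC| > 1.5.
4. **ceRNA network.** DE ceRNAs are joined to DE mRNAs through shared
   miRNAs; mRNA–miRNA predictions must be supported by ≥ 5 of 7 tools, and
   edges are validated by a positive Pearson correlation of normalized
   expression.
5. **Risk score.** For the DE ceRNA signature, per-feature univariate Cox
   coefficients β_i weight normalized expression into a per-patient risk
   score `RS = Σ_i expr_i · β_i`; a median split defines high/low risk,
   evaluated with Kaplan–Meier curves and the log-rank test on overall and
   progression-free survival.

A seeded synthetic-data generator with exhaustive planted truth (caller
dropout and coordinate dialects, NB counts with planted effects,
consensus-supported interaction triples, survival hazard tied to a planted
signature) backs the whole validation suite.

## Worked example

```r
library(ceRNAicb)
res <- run_pipeline(list(simulate = list(), seed = 1L), outdir = "run")

length(res$consensus$retained)
#> [1] 280
lengths(res$de$circ[c("up", "down")])
#>   up down
#>   18   11
head(res$network$edges[, c("cerna_id", "mrna_id", "n_shared", "pearson_r")], 3)
#>                   cerna_id   mrna_id n_shared pearson_r
#> 1 chr1:69422781-69424738:- mrna_0116        1 0.7953893
#> 2 chr1:91598977-91600649:+ mrna_0021        1 0.6743699
#> 3 chr1:91598977-91600649:+ mrna_0186        1 0.7933493
res$risk
#> risk_model: 49-feature signature, 12 patients (6 high / 6 low risk)
#>   trained on OS; log-rank p: OS = 0.0119, PFS = 0.00247
res$risk$os$km$medians
#>   group n events median    lcl ucl
#> 1  high 6      6  19.06  9.514  NA
#> 2   low 6      3  33.89 22.278  NA
```

Reading this output: of 300 simulated circRNA loci, 280 pass the
multi-caller high-confidence filter; 29 circRNAs and 20 lncRNAs are
differentially expressed between responders and non-responders; 77
positive-correlation ceRNA–mRNA edges form the network; and the
49-feature ceRNA risk score splits the 12 patients into high- and
low-risk halves whose overall survival separates (log-rank p = 0.012,
median OS 19.1 vs 33.9 months; `NA` upper bounds mean the confidence
limit was not reached). Every artifact is also written under `outdir`
(consensus matrix, BED of retained loci, DE tables, edge list + GraphML,
KM tables, run manifest with content hashes).

The same stages run from files: give `run_pipeline()` an `inputs:` block
with paths to call tables, count matrices, metadata and interaction
tables (see `?run_pipeline`), or use the thin CLI at
`inst/scripts/cerna-icb.R` (`simulate` / `run` subcommands).

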
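---
title: "Methods: eRNA-defined enhancer discovery, linkage and prognosis"
author: "eRNAscout"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: eRNA-defined enhancer discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The analysis model

`eRNAscout` detects enhancer RNAs (eRNAs) — short, unstable, typically
bidirectional transcripts of active enhancers — from cohort total RNA-seq,
restricted to open chromatin, and follows them through to disease
classification and prognosis. The pipeline assumes:

* stranded RNA fragments are available as genomic intervals (alignment and
  peak calling happen upstream of this package);
* eRNA transcription is intergenic once gene bodies and their promoter and
  read-through flanks are removed;
* cohort-level differences in eRNA transcription follow a negative-binomial
  count model;
* enhancers predominantly *activate* nearby genes, so positive expression
  correlation and positive net-enhancer change are the linkage signals.

## Truncated genome and union peak set

Gene bodies are excluded with a strand-aware flank of `upstream` bp before
the TSS and `downstream` bp after the TTS, then merged. The flanks avoid
promoter-proximal signal and transcriptional read-through, respectively. The
exclusion is strand-aware — for a minus-strand gene the TSS is the higher
coordinate — because promoter interference happens upstream in the
*transcriptional* sense; this is a deliberate resolution of an ambiguity in
the source protocol, taken once and kept.

Per-sample ATAC-seq peak sets are pooled and merged to a fixpoint: two peaks
on one chromosome merge when they overlap or when their centres (floor of
the half-open midpoint, a deterministic integer) are within `mergeDistance`
bp. The centre-distance rule matches the documented behaviour of the usual
peak-merging tool; adding overlap-merge guarantees the result is a valid
non-overlapping region set. Because intervals sorted on one chromosome have
ordered centres, checking adjacent pairs suffices for the fixpoint test.

A peak overlapping an exclusion zone by even one base is dropped whole
rather than trimmed: regions are classified as intergenic or not, never
reshaped.

## Quantification, candidate filter, directionality

A fragment contributes to the unique region containing its midpoint, so no
fragment is ever double-counted at region boundaries; fragments whose
midpoint lies in no region are uncounted. Library size is the total fragment
count of the sample, and FPM is `counts x 1e6 / librarySize`. A region is a
candidate when its mean raw count across *all* samples (cohorts pooled) is
at least `minMeanCount` (3) and its mean FPM at least `minMeanFpm` (1.5).
Raw counts are used in the count filter; whether normalisation should
precede it is ambiguous in the source protocol, and the raw reading is the
simpler, documented choice.

The directionality score `log10((plus + 1)/(minus + 1)) + 1` is
antisymmetric about 1 (`D(a,b) + D(b,a) = 2`). The per-strand "expression
score" is the strand-specific fragment count summed over samples, by default
scaled per million per sample first so deep libraries do not dominate
(`normalized = FALSE` gives raw sums).

## Differential transcription

Size factors are plain median-of-ratios: per-region geometric means over
samples (regions with any zero excluded), per-sample median of
count-to-geomean ratios. The two-group Wald test on normalised counts uses

* pseudocounted fold change `log2((mu_B + 0.5)/(mu_A + 0.5))` — the
  pseudocount avoids infinities at zero means and is configurable;
* a per-region method-of-moments dispersion from the pooled within-group
  variance (`n - 2` denominator): `alpha = (s^2 - mu)/mu^2` with `mu` the
  mean of the two group means, clamped to `[0, 10]` (Poisson floor, a
  stability ceiling for tiny studies);
* the delta-method standard error with `Var = mu + alpha mu^2`, scaled by
  `df/(df - 2)` (`df = n_A + n_B - 2`). This finite-sample factor matches
  the variance of the *t* distribution that the statistic actually follows
  when the variance is estimated on few degrees of freedom; without it the
  normal-reference test is measurably liberal at cohort sizes around ten,
  and the factor vanishes as cohorts grow;
* a two-sided normal p-value, BH adjustment, and strict classification:
  `B_specific` iff `log2FC > 0.5` and `p_adj < 0.05` (thresholds exactly on
  the boundary stay unclassified).

Regions with zero counts in every sample of both groups have no defined
test; they carry `p = NA` and are reported as *discarded*, the explicit
analogue of an opaque internal filter in the reference tooling. For
mRNA-style calls the same machinery runs with `lfcThreshold` 0.9
(BO-specific) or 1.5 (OAC-specific); the source material is internally
inconsistent about the second value (one figure legend says 1.1), so it is a
parameter, with the Methods value as default.

## Gene linkage

*Nearest gene*: signed distance is strand-aware TSS minus region centre;
ties in absolute distance resolve to the lexicographically smaller gene id —
an arbitrary but deterministic rule.

*Windowed best correlation*: Spearman's rho (average ranks on ties) between
a region's expression and every gene whose TSS lies within `halfWindow`
(default 100 kb, i.e. a 200 kb window flanking the region centre) over the
shared samples; the best gene maximises *signed* rho because enhancers are
assumed activating (`useAbs = TRUE` ranks by magnitude instead). At least
three shared samples are required.

*Net enhancer change*: per gene, gained (`B_specific`) minus lost
(`A_specific`) eRNAs with centre within `halfWindow` (default 200 kb) of the
TSS, clamped into the nine bins −4..+4. The source describes "nine groups"
without stating boundaries; symmetric clamping is the minimal consistent
reading. Bin-wise gene expression shifts are summarised by median and
quartiles and tested with Kruskal–Wallis (tie-corrected ranks; the
all-values-identical case is defined as `H = 0, p = 1`).

*Overlap tests*: exact hypergeometric upper tail `P[X >= k]` and Fisher's
two-sided exact p on the 2x2 table. *Outlier-high stratification* (the
ERBB2-amplified-like rule) calls a sample high when expression exceeds the
median plus two population standard deviations.

## Sample classification

Rows are z-scored (sample SD, constant rows to zero), samples are compared
by Pearson correlation, and the `1 - r` distances are clustered with average
linkage and cut at `k = 2`. Average linkage is fixed as the default because
the original analysis used a GUI tool whose linkage is unstated; complete
and single linkage are available. Misclassification is the minimum, over
bijective assignments of clusters to cohorts, of the number of samples whose
cohort differs from their cluster's assigned cohort — the only
label-symmetric definition; for two cohorts it is necessarily at most
`n/2`. The pipeline clusters `log2(FPM + 1)` of the candidate regions:
log-scale expression is the standard input for correlation heatmaps and
keeps lognormally varying regions from dominating the correlation.

## Survival signature

Cox models are fitted by partial-likelihood maximisation with Breslow
handling of ties (the survival package is the fitting engine behind this
module's interface); non-convergence and separation (`|beta| > 10`) are
flagged, and flagged genes are excluded from the univariate screen with a
warning. The screen retains genes with BH `q < 0.1` (strict); "q-value" is
read as BH, the conventional interpretation when no method is named. The
original feature-reduction step used a random forest with unstated settings;
it is replaced by a deterministic rule — keep the `signatureSize` (default
6, the published signature size) screened genes with largest univariate
`|z|` — which preserves the pipeline shape and is reproducible. The risk
score is `sum(x_i beta_i)` from one multivariate fit; samples split at the
training-median score, with exact-median scores assigned to "low". An empty
screen yields `NULL` — the explicit "no signature" outcome. Kaplan–Meier
curves and the two-group log-rank test (hypergeometric variance, 1 df)
compare the risk groups; with no events anywhere the comparison is defined
as `p = 1` with a warning.

# The synthetic-study generator

`simConfig()` defines the study conditions; the defaults are the conditions
under which the pipeline's operating characteristics are tested: two 2 Mb
chromosomes, 60 genes, 300 intergenic peaks plus 100 decoys placed wholly
inside gene bodies, 40 planted eRNAs at `|log2FC| = 2` (half gained in
cohort OAC, half lost), cohorts of 20 + 20, NB counts with mean 50 and
dispersion 0.1, a balanced binomial strand split, and lognormal library
sizes around 10⁶.

Planted regions carry a **latent per-sample enhancer activity**: the log
cohort effect plus a Gaussian log-scale residual (`activitySd`, default
0.8), exponentiated into the NB mean (normalised so cohort mean counts are
exactly `nbMean` and `nbMean * 2^log2FC`). This is the generator's central
design decision. A pure NB model gives an eRNA no sample-to-sample signal
beyond counting noise, so the expression of *any* gene responding to the
cohort difference correlates with *every* same-direction eRNA — pooled
rank correlation is then dominated by the cohort shift that all planted
eRNAs share, and no windowed-correlation method can single out the true
target. Real enhancers vary continuously between patients and transmit that
variation to their targets; the latent activity emulates exactly that.

Gene expression is a Gaussian baseline (mean 8, SD 1, noise SD 0.5) plus two
couplings per planted eRNA: every gene whose TSS lies within the net-change
window of the eRNA centre receives `windowCoupling` (0.7) times the
standardised *cohort-level* activation — so a gene's expected expression
shift is proportional to the net eRNA change around it, which is what the
nine-bin analysis measures — and the designated target additionally receives
`targetCoupling` (2.0) times the standardised *per-sample activity
residual*, giving it the highest expression correlation with its enhancer
without distorting cohort-level fold changes. With noise SD 0.5 the
target-specific signal-to-noise is well above 2. Survival times are
exponential with hazard `baselineHazard * exp(beta * z)` on the standardised
driver-gene expression (`beta` 0.7), with independent uniform censoring
calibrated to the target censoring fraction (20%).

Fragments, when materialised, are 100 bp intervals whose midpoints are
uniform within their region, so midpoint counting reproduces the count
matrix exactly — a designed self-check. Each stage draws from its own RNG
stream derived from the master seed, so partial re-simulation is stable.

**What the generator does not emulate:** GC and mappability bias, fragment
length variation, copy-number amplification (outlier-high expression is an
expression shift only), overlapping or nested gene models, unbalanced
bidirectionality of real promoters, batch effects, or dependence between
censoring and covariates. Passing the planted-truth tests therefore
demonstrates the correctness and calibration of the pipeline's inference
machinery under its own model assumptions, not performance on real tissue
data.

# Problem sizes and measurement choices

The test-suite and the acceptance script run at deliberately chosen sizes:
oracle-equivalence checks use 50 random toy genomes (up to 100 genes and 200
peaks on 50 kb chromosomes) against per-base and all-pairs brute-force
oracles; calibration uses 10,000 null NB regions at 10 + 10 samples and 20
replicate null Cox screens of 50 genes; survival recovery uses n = 500.
End-to-end recovery is measured as the average over three replicate studies
at the default conditions, with net-change bins pooled across replicates
before taking medians: single-study recall, linkage recovery and bin
occupancy are binomial quantities over only 40 planted regions, and the
three-replicate average measures the same operating characteristic with less
noise.

# Known limitations

* The NB Wald test is a moment-based two-group test: no shrinkage across
  regions, no covariates, no GLM designs. Agreement with any particular
  external differential-expression tool's per-region p-values is explicitly
  out of scope; calibration is validated by simulation instead.
* Nearest-gene and windowed linkage use TSS geometry only; 3D-contact
  information is out of scope.
* The windowed best-correlation linkage degrades when many co-regulated
  genes share a window — see the generator discussion above; on real data a
  cohort-stratified correlation is often advisable (compute per cohort via
  the sample subset and compare).
* The deterministic top-|z| signature rule replaces a random-forest
  reduction; it is a declared substitute, not a reconstruction of the
  original selection.
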
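# eRNAscout

Discovery of enhancer-RNA (eRNA)-defined enhancers from cohort total RNA-seq
combined with ATAC-seq open-chromatin maps.

Active enhancers produce short, unstable, typically *bidirectional*
transcripts (eRNAs). They are hard to see in any single RNA-seq library, but
pooling hundreds of patient samples makes intergenic enhancer transcription
detectable — and differentially transcribed eRNA regions turn out to separate
disease states (e.g. Barrett's oesophagus, "BO", from oesophageal
adenocarcinoma, "OAC") and to point at the genes the enhancers regulate.
`eRNAscout` implements that analysis as a tested, reusable Bioconductor-style
pipeline, together with a seeded synthetic-study generator with planted
ground truth so that every stage can be validated without controlled-access
patient data.

## The method

1. **Truncated genome.** Gene bodies are excluded together with a
   strand-aware 2 kb flank upstream of each TSS and 500 bp downstream of each
   TTS; only what remains can host intergenic eRNAs
   (`buildExclusionZones()`, `filterIntergenicPeaks()`).
2. **Union peak set.** Per-sample ATAC-seq peak sets are pooled and merged to
   a fixpoint: two peaks merge when they overlap or their centres lie within
   250 bp (`mergePeakSets()`).
3. **Quantification and candidate filter.** Stranded RNA fragments are
   assigned to regions by their midpoint; a region is a candidate eRNA
   region when its mean raw count is ≥ 3 **and** its mean FPM
   (`counts × 10⁶ / library size`) is ≥ 1.5 (`quantifyRegions()`,
   `filterCandidates()`). Bidirectionality is scored as

   `D = log10((plus + 1) / (minus + 1)) + 1`

   so balanced enhancer-like transcription sits near `D = 1`
   (`regionDirectionality()`).
4. **Differential transcription.** A two-group negative-binomial Wald test on
   median-of-ratios–normalised counts (method-of-moments dispersion,
   `Var = μ + αμ²`, finite-sample SE correction), BH adjustment, and
   classification as cohort-specific when `|log2FC| > 0.5` and
   `p_adj < 0.05` (strict; `ernaDifferential()`). mRNA-style thresholds
   (0.9 / 1.5) are parameters.
5. **Gene linkage.** Nearest-gene annotation by signed TSS-to-centre
   distance; windowed best-correlation linkage (Spearman ρ against every
   gene with TSS within ±100 kb); per-gene *net enhancer change* (gained −
   lost eRNAs within ±200 kb of the TSS, clamped into nine bins −4..+4)
   compared against the gene expression shift with a Kruskal–Wallis test;
   hypergeometric/Fisher gene-set overlap tests (`nearestGeneTss()`,
   `windowedBestCorrelation()`, `netEnhancerChange()`, `overlapTest()`).
6. **Sample classification.** Row z-scoring, 1 − Pearson distance, average
   linkage, 2-cluster cut, and a bijective-minimum misclassification count
   against the cohort labels (`correlationCluster()`,
   `misclassificationCount()`).
7. **Survival signature.** Univariate Cox screen (BH q < 0.1), deterministic
   top-|z| feature reduction to a six-gene signature, one multivariate Cox
   fit, risk score `Σ xᵢβᵢ`, median split, Kaplan–Meier curves and log-rank
   test (`univariateScreen()`, `buildRiskModel()`, `kmLogrank()`).

## Worked example

Simulate a small two-cohort study (1 Mb genome, 12 genes, 60 intergenic +
20 decoy peaks, 10 planted eRNAs, 8 + 8 samples), write it to disk in
standard formats (GTF, BED, TSV), and run the full pipeline:

```r
library(eRNAscout)

cfg <- simConfig(seed = 1, nChroms = 1L, chromLength = 1e6, nGenes = 12L,
                 nIntergenicPeaks = 60L, nDecoyPeaks = 20L,
                 nPlantedErnas = 10L, nA = 8L, nB = 8L)
study <- simulateStudy(cfg)
paths <- writeSimulation(cfg, study, "sim-demo")

res <- runPipeline(list(
  gtf = paths$gtf, chromSizes = paths$chromSizes, peakBeds = paths$peakBeds,
  fragmentBeds = paths$fragmentBeds, geneExpr = paths$geneExpr,
  meta = paths$meta, survival = paths$survival, outDir = "sim-demo/out"))

round(res$summary, 4)
#>        unionPeaks intergenicRegions  candidateRegions         aSpecific
#>           77.0000           60.0000           60.0000            5.0000
#>         bSpecific         discarded     misclassified netChangeKruskalP
#>            5.0000            0.0000            0.0000            0.1002
#>    overlapFisherP          logrankP
#>            0.5152            0.0032
```

The funnel mirrors the discovery strategy: 77 merged union peaks, of which
60 are intergenic (all 20 decoys inside gene bodies were dropped), all 60
pass the count/FPM filter, and 5 + 5 are called cohort-specific — exactly
the 10 planted eRNAs, as `sim-demo/truth.json` confirms. No sample is
misclassified by eRNA-based clustering, and the planted survival driver
yields a risk-score split with log-rank p = 0.003.

The strongest differential calls show the planted |log2FC| ≈ 2 signal:

```r
de <- as.data.frame(res$de)
head(round(de[order(de$padj), c("baseMeanA", "baseMeanB", "log2FC", "padj")], 3), 4)
#>              baseMeanA baseMeanB log2FC  padj
#> region_00051    45.903   220.278  2.250 0.004
#> region_00006   329.938    43.222 -2.918 0.005
#> region_00022    55.709   155.630  1.474 0.005
#> region_00014   148.163    28.096 -2.378 0.006
```

`res$linkage` holds, per region, the most correlated gene within the ±100 kb
window and its Spearman ρ; `res$net` and `res$binShift` hold the net
enhancer-change bins and their expression-shift summary.

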
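# blastomics

Tools for comparing the transcriptomes of the two cell lineages of the
mammalian blastocyst — the inner cell mass (ICM), which forms the embryo
proper, and the trophectoderm (TE), which forms the placenta — starting
from gene-level read counts, and for characterizing the promoters of the
genes that distinguish them.

The package is aimed at developmental biologists and bioinformaticians
working with small-replicate two-group RNA-seq designs (typically three
pooled replicates per lineage) who also want the classical promoter
follow-ups: CpG-island classification, transcription-factor binding-site
(TFBS) enrichment, over-representation analysis and ΔΔCt qPCR
confirmation. A synthetic-data module generates every input with known
ground truth, so the entire pipeline can be exercised and validated
offline.

## What it computes

**Differential expression.** Counts $k_{ij}$ are modelled as negative
binomial. Sample depths are normalized with median-of-ratios size
factors $s_j$ (rescaled to geometric mean 1). The per-gene variance of
normalized counts is pooled within conditions and regressed on the mean
by loess on the log–log scale, giving a fitted variance function $v(q)$
with $v(q) \ge q$ (Poisson floor). For each gene the test conditions on
the observed total $K = K_A + K_B$ of the two per-condition count sums
and enumerates all splits $(a, K-a)$, with each condition sum NB
distributed with mean $q_0 \sum_j s_j$ and variance
$q_0 \sum_j s_j + (v(q_0) - q_0)\sum_j s_j^2$; the p-value is the total
probability of splits no more likely than the one observed. Calls use
two cut-offs jointly: Benjamini–Hochberg adjusted $P \le 0.05$ and
$\max(\mathrm{FC}, 1/\mathrm{FC}) \ge 1.5$, where
$\mathrm{FC} = \bar q_B / \bar q_A$ on normalized condition means.

**Clustering.** Significant-gene profiles ($\log_2$ of normalized
counts + 1) are clustered by k-means (k-means++ initialization,
best-of-restarts Lloyd) for every $k$ in a scan range; the per-$k$ best
sum of squared errors (SSE) is guaranteed non-increasing in $k$, and the
elbow is the smallest $k$ whose relative SSE drop falls below a
threshold (default 3%).

**Promoter CpG islands.** For each gene the strand-aware window 100 bp
either side of the TSS is scored by GC content $([C]+[G])/L$ and the
CpG observed/expected ratio $[CG]\cdot L/([C]\cdot[G])$; a promoter is
CpG-positive when GC $> 0.5$ **and** the ratio $> 0.6$. Group
proportions are compared by Pearson chi-square.

**TFBS enrichment.** JASPAR-format count matrices become log-odds PWMs
(pseudocount 0.8 distributed by background). Windows −200/+50 around
the TSS are scanned on both strands; a site counts when its
min–max-rescaled relative score reaches 0.8, and per-motif gene sets are
tested against a universe by the hypergeometric upper tail with BH
adjustment. The same machinery drives a generic over-representation
analysis over a gene→term mapping.

**qPCR.** ΔΔCt with a multi-gene reference (arithmetic mean of
reference Ct values, i.e. the geometric mean of expression levels),
fold $= 2^{-\Delta\Delta Ct}$, plus a Welch t-test between groups.

## Worked example

```r
library(blastomics)

sim <- simulate_counts(n_genes = 1000, de_fraction = 0.1, seed = 1)
res <- dge_test(sim$counts, sim$condition)
res
#> Negative-binomial differential expression (exact conditional test)
#>   conditions: A = ICM, B = TE (fold change = B/A)
#>   genes tested: 1000
#>   significant (padj <= 0.05, fold >= 1.5): 43  [up-in-ICM: 22, up-in-TE: 21]

head(res$table[order(res$table$padj), ], 3)
#>          gene mean_A mean_B fold_change   pvalue     padj direction
#> 472 gene00472 5590.3  59056     10.5640 2.96e-26 2.96e-23   up-in-B
#> 867 gene00867   76.2   1480     19.4240 9.34e-22 4.67e-19   up-in-B
#> 854 gene00854 5902.8    403      0.0683 3.82e-20 1.27e-17   up-in-A
```

Of the 1000 simulated genes, 100 carry a planted fold change; 43 clear
both cut-offs here (weak planted effects are intentionally kept below
the fold gate). `gene00472` is expressed ~10.6-fold higher in TE than
ICM with adjusted $P = 3\times10^{-23}$.

A qPCR confirmation with a known 2.7-fold planted difference:

```r
ct <- simulate_ct(6, targets = "GATA3", refs = c("GAPDH", "SDHA", "YWHAZ"),
                  true_fold = 2.7, noise_sd = 0.2, seed = 2)
ddct(ct$ct, "GATA3", c("GAPDH", "SDHA", "YWHAZ"), calibrator = "ICM")
#> ddCt quantification of GATA3 (refs: GAPDH, SDHA, YWHAZ; calibrator: ICM)
#>  group n mean_ddct  fold mean_fold
#>    ICM 6     0.000 1.000     1.006
#>     TE 6    -1.704 3.258     3.292
#> Welch t-test on ddCt: t = 15.027, df = 9.58, p = 5.592e-08
```

The recovered fold (3.26) sits within measurement noise of the planted
2.7; the calibrator group's mean ΔΔCt is 0 by construction.

The whole pipeline — counts → DE lists → clustering → CpG/TFBS/ORA →
qPCR → `report.json` — runs on generated inputs with one call:

```r
report <- demo_pipeline(seed = 42, out_dir = "demo_out")
```

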
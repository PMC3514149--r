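---
title: "Methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the statistics it
implements: the models and their assumptions, the tunable parameters and
their defaults, what the synthetic-data generator does and does not
emulate, and the numerical and design choices made where more than one
reasonable convention exists.

## Negative-binomial differential expression

The DE stage targets the hardest common design in embryology: two
conditions (here labelled ICM and TE) with about three replicates each.
With so few replicates, per-gene variances are unusable on their own;
the model assumes instead that genes of similar expression share
similar variance.

**Size factors.** `estimate_size_factors()` uses the median-of-ratios
estimator: for sample $j$, the median over genes of
$k_{ij}/(\prod_j k_{ij})^{1/m}$, restricted to genes with positive
counts in every sample, then rescaled so the factors have geometric
mean exactly 1. The estimator assumes most genes are not differentially
expressed; it fails (with an explanatory error) when no gene is
detected in all samples.

**Mean–variance trend.** Per gene, the sample variance of normalized
counts is pooled within conditions (df-weighted) and regressed on the
overall mean by `loess` on the log–log scale (degree 1, tricube
weights, span 0.3). Three corrections stabilize the fit:

* *Log-bias correction.* For a variance estimate that is approximately
  a scaled $\chi^2_\nu$, $E[\log \hat v] = \log v + \psi(\nu/2) -
  \log(\nu/2)$, so the naive back-transformed loess fit underestimates
  the variance (by ~24% at $\nu = 4$, i.e. 3+3 replicates). The fit is
  multiplied by $\exp(\log(\nu/2) - \psi(\nu/2))$ to undo this. Without
  the correction the test is anti-conservative at exactly the replicate
  numbers the package is designed for.
* *Monotonicity.* The corrected fit is evaluated on a 200-point
  log-spaced grid and made non-decreasing by a running maximum, then
  linearly interpolated; outside the fitted mean range it is clamped to
  the nearest grid value rather than extrapolated.
* *Poisson floor.* The returned variance is never below the mean.

If fewer than 10 genes have a positive pooled variance (e.g.
replicate-constant toy matrices), the trend degenerates to the Poisson
floor $v(m) = m$ rather than fitting an unidentifiable curve.

**The exact conditional test.** `nb_test()` conditions on the observed
total $K = K_A + K_B$ of the per-condition count sums. Under the null
of a common concentration $q_0 = K/\sum_j s_j$, each sum is NB with
mean $q_0 \sum_j s_j$ and variance
$q_0\sum_j s_j + (v(q_0)-q_0)\sum_j s_j^2$ (the first term is shot
noise, the second the shared overdispersion). All $K+1$ splits are
enumerated and the p-value is the probability mass of splits no more
likely than the observed one, normalized over all splits. A zero total
returns $p = 1$ by convention. Probabilities are accumulated in log
space (log-sum-exp) and a relative tolerance of $10^{-8}$ treats
equal-probability splits as ties, so the enumeration is exact up to
floating point for any $K$ the test will meet in practice.

**Calling rule.** Significance requires both an adjusted $P \le \alpha$
(BH step-up, $\alpha = 0.05$) and a symmetric fold gate
$\max(\mathrm{FC}, 1/\mathrm{FC}) \ge 1.5$ computed on normalized
condition means. The symmetric reading of the fold cut-off is a
deliberate choice: a 1.5-fold change in either direction is treated
identically. Fold changes at zero means carry explicit sentinels
(`Inf` when only the denominator mean is 0, `NA` when both are) and are
never silently dropped — genes expressed in one lineage only are real
and interesting. No independent filtering, outlier replacement or
fold-change shrinkage is applied; the test is deliberately the plain
conditional form.

## k-means with an SSE-guided scan

Profiles are $\log_2(\text{normalized count} + 1)$; the log transform
(exposed by a flag in `cluster_profiles()`) prevents the handful of
very highly expressed genes from dominating the squared-error
objective. Distances are Euclidean.

`kmeans_fit()` is best-of-`n_restarts` (default 10) Lloyd iterations
from k-means++ seedings, deterministic given one seed; ties in
assignment go to the lowest-index centroid and empty clusters are
reseeded with the point farthest from its centroid. `scan_k()` adds,
for each $k$, one warm start built from the previous $k$'s best
solution with its widest cluster split at its farthest point. Because
Lloyd never increases the SSE of its starting configuration, the best
SSE is non-increasing in $k$ — a property raw restarts do not have, and
without which an "elbow" is ill-defined. The chosen $k$ is the smallest
whose relative drop $(\mathrm{SSE}_k - \mathrm{SSE}_{k+1}) /
\mathrm{SSE}_k$ falls below `elbow_threshold` (default 0.03, i.e. the
curve has flattened to <3% gains per extra cluster); $0/0$ counts as a
flat drop. The threshold is configurable because elbow selection is
inherently a judgement call; 0.03 reproduces the "drops abruptly, then
flattens" behaviour on the package's synthetic profiles.

`standardize_rows()` (for heatmap display) centers each row and scales
by the sample standard deviation ($n-1$); constant rows map to zeros.

## Promoter CpG islands

Windows are 0-based, half-open, and strand-aware: the TSS base is the
first downstream base, and for minus-strand genes the mirrored interval
is reverse-complemented so "upstream" is always 5′ in gene orientation.
A window running past a contig end is an error by default
(`clip = TRUE` truncates with a warning).

The island call on the −100/+100 window uses GC content
$([C]+[G])/L$ and the Gardiner–Garden & Frommer observed/expected
ratio $[CG]\cdot L/([C]\cdot[G])$ with strict thresholds GC $> 0.5$
and ratio $> 0.6$. A literal variant of the score,
$[CG]/([C]\cdot[G]\cdot L)$, is available behind `literal = TRUE`:
this form is bounded above by $1/L$ (0.005 at $L = 200$) and can never
exceed the 0.6 threshold, so it cannot be the intended definition of a
score compared against 0.6; it is retained only for fidelity testing.
`CG` dinucleotides are counted at every position (the overlapping
convention — vacuous for `CG`, which cannot overlap itself); `N` bases
are excluded from $[C]$, $[G]$ and $[CG]$ but kept in $L$, which is
conservative toward the positive call. Proportions between gene groups
are compared by Pearson chi-square without continuity correction; an
expected cell below 1 triggers a warning but still returns a result.

## PWM scanning and hypergeometric enrichment

`pwm_from_pfm()` builds log-odds weights
$w_{bj} = \log_2\frac{(c_{bj} + p\,\pi_b)/(N_j + p)}{\pi_b}$ with
pseudocount $p = 0.8$ distributed by the background $\pi$ (uniform by
default; a promoter-composition background can be supplied). Sites are
scored at every offset on both strands of the −200/+50 window, skipping
sites containing `N`, and rescaled as
$(s - s_{\min})/(s_{\max} - s_{\min}) \in [0, 1]$. The min–max
convention (rather than $s/s_{\max}$) is used because log-odds scores
are negative for most of their range, making a raw ratio ill-behaved.
The default site threshold of 0.8 relative score is the conventional
operating point for this rescaling and is configurable
(`min_relative_score`); a $10^{-9}$ tolerance keeps sites exactly at
the threshold. A gene "has" a motif iff at least one site anywhere in
its window passes — enrichment is about genes, not site counts.

Enrichment assembles, per motif, the counts $N$ (universe), $K$
(universe genes with the motif), $n$ (query) and $k$ (query genes with
the motif) and computes the hypergeometric upper tail $P(X \ge k)$,
BH-adjusted across motifs. The universe defaults to every gene with an
extractable promoter; both query-vs-universe and set-vs-set contrasts
are possible by choosing the arguments. `ora_enrichment()` is the same
machinery over a gene→term mapping (terms with fewer than two universe
genes are skipped), serving as an offline stand-in for web annotation
services.

## ΔΔCt quantification

For each sample, $\Delta Ct = Ct_{\text{target}} - Ct_{\text{ref}}$,
where the multi-gene reference is by default the *arithmetic mean of
the Ct values*. Since Ct values are exponents, this equals the
geometric mean of the reference expression levels — the standard
multi-reference convention; the literal geometric mean of the Ct
numbers differs slightly and is selectable (`ref_mode =
"geometric_ct"`). $\Delta\Delta Ct$ subtracts the calibrator-group mean
$\Delta Ct$, so the calibrator's mean $\Delta\Delta Ct$ is 0 and its
group fold exactly 1. Folds assume perfect doubling per cycle
(efficiency 2.0). Group folds are reported both as
$2^{-\overline{\Delta\Delta Ct}}$ and as the mean of per-sample folds;
groups are compared by a Welch t-test on $\Delta\Delta Ct$ (reported as
`NA` for noise-free degenerate fixtures). Adding a constant to every Ct
of a sample — a global efficiency shift — cancels exactly.

## The synthetic-data generator

The generator produces the three inputs the pipeline consumes, each
with a truth table and full determinism from one integer seed per call
(the caller's RNG state is saved and restored).

*Counts* (`simulate_counts()`): gene base means log-uniform on
$[1, 10^4]$ — deliberately covering the low-count regime where NB
testing is hardest; a planted fraction (default 0.1) of genes gets a
log2 fold change drawn $N(0, 1.5)$ truncated to $|\mathrm{lfc}| \ge
0.3$ (effects below that are unrecoverable at these designs and would
only blur recovery metrics); per-sample depth factors log-uniform on
$[2/3, 3/2]$ unless supplied; counts NB with variance
$\mu + d\mu^2$ (default $d = 0.1$, typical for bulk data of this kind;
$d = 0$ gives Poisson).

*Promoters* (`simulate_promoters()`): one contig per gene (TSS
centered, random strand), i.i.d. background at a chosen GC (default
0.4). Planted islands are dinucleotide-process tracts (20% `CG`
emissions, 60% GC otherwise) spanning −110/+110, validated at
generation time to classify CpG-positive on the −100/+100 window.
Planted motif instances are drawn from the PWM's per-column corrected
probabilities — not the consensus — so their relative scores are
realistically below 1; instances are placed uniformly inside −200/+50
on a random strand, avoiding the island tract when both are planted.

*Ct tables* (`simulate_ct()`): reference genes at fixed per-gene base
Ct (drawn once in 18–24), targets in 22–28, the second group's target
Ct shifted by $-\log_2(\text{fold})$, Gaussian noise (default 0.2
cycles, a typical technical SD) on every measurement.

What the generator does **not** emulate — and therefore what passing
tests do not establish about real data: mapping and counting artifacts,
GC- or length-dependent coverage bias, batch effects, correlated genes,
real promoter sequence composition (isochores, repeats, TATA/Inr
structure), motif clustering and cooperativity, or qPCR efficiency
differences between genes. Results on synthetic data validate the
*computations*, not the biology.

## Problem sizes and runtime choices

The test suite and acceptance script exercise: null calibration and
planted-DE recovery at 2000 genes × (3+3) replicates over 5 seeds each;
CpG round trips on 600 promoters; motif round trips on 1000 promoters
with 40 planted instances; exact-test/k-means/hypergeometric oracle
checks at enumerable sizes (totals ≤ 500, 8 points, $N = 20$); and the
end-to-end demo at 1500 genes / 1000 promoters, run twice to assert
byte-identical outputs. These sizes give stable pass/fail behaviour
with comfortable margins while keeping a full run in the low minutes on
one core; all of them are plain function arguments, so larger replays
are one-line changes.

## Known limitations

* The DE model handles exactly two conditions; no covariates, no
  multi-factor designs.
* The exact test enumerates $K + 1$ splits per gene; cost grows
  linearly with the total count (vectorized, still fast at
  $K \sim 10^5$, but not intended for merged deep libraries).
* Dispersion is taken from the fitted trend only (no per-gene
  empirical-Bayes shrinkage), which is the right bias-variance
  trade-off at 3+3 replicates but conservative at larger designs.
* The elbow rule is a heuristic; `scan_k()` always returns the full
  (k, SSE) curve so the choice can be inspected.
* PWM scanning assumes independent positions (standard PWM limits) and
  the package does not attempt TRANSFAC `match` bit-compatibility; its
  thresholds are calibrated only in the min–max relative-score sense.
* `ora_enrichment()` treats terms as flat sets: no term hierarchy or
  gene-length bias correction.
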
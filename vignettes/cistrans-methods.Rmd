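---
title: "Methods: models, parameters, and design choices in cistrans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters, and design choices in cistrans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`cistrans` measures how strongly gene co-expression is confined within
chromosomes in a two-phenotype study, and annotates the resulting network
communities with regulatory evidence. This vignette is the package's own
account of its methods: what each stage assumes, which parameters matter and
why their defaults are what they are, what the synthetic-data generator does
and does not emulate, and where genuinely open design choices were resolved.

## 1. Mutual-information network inference

For each gene pair the dependence score is the plug-in mutual information of
the equal-frequency-binned expression vectors, in nats, with Miller–Madow
bias correction:

$$\hat I = \hat H(X) + \hat H(Y) - \hat H(X,Y) + \frac{k_x + k_y - k_{xy} - 1}{2n},$$

where $k$ counts occupied bins/cells. Equal-frequency (rank) binning makes
the estimate invariant under any strictly monotone transform of either
input, so normalization choices upstream (log bases, affine scalings,
quantile maps) cannot change edge ranks. Estimates are clamped at 0.

**Bin count.** The default is $\lceil n^{1/3} \rceil$ bins. A
$\lceil\sqrt{n}\rceil$ rule looks natural but fails its own calibration: at
$n = 2000$ it gives 45 bins and a $45\times45$ joint table holding ~1 count
per cell, a regime where the Miller–Madow correction removes only a third of
the plug-in bias (measured error +0.12 to +0.26 nats against the bivariate
Gaussian closed form $-\tfrac12\ln(1-\rho^2)$). With the cube-root rule the
same oracle is met within ±0.08 nats at every tested $\rho$ (0.3, 0.6, 0.9),
at the cost of a small downward discretization bias (−0.07 nats at
$\rho=0.9$, shrinking as bins grow). Since every downstream quantity depends
only on edge *ranks*, a small uniform bias is harmless; an unstable one is
not. `mi_config(n_bins=)` overrides the rule.

**Significance.** A pooled permutation null is built by repeatedly drawing a
random gene pair, shuffling one vector's sample order, and recording the MI
(default $10^5$ draws). All pairs share one sample size, so one pooled null
serves every edge, and $p = (1 + \#\{\text{null} \ge \text{obs}\})/(1 + N)$
is monotone non-increasing in the score with a +1 pseudocount keeping
$p > 0$. When both a p-value cutoff and a top-$k$ are requested, the p
filter applies first, then the rank cut — mirroring the original analyses,
which kept only permutation-significant interactions and then worked at a
fixed edge count.

**Edge count.** `select_top_edges(net, k)` breaks score ties
lexicographically so selections are reproducible, and top-$k$ sets are
nested in $k$. No default $k$ is hard-coded in the inference layer; the
bundled pipeline uses $k = 2.5\times$ the gene count, the same order as the
published full-transcriptome networks (~20k edges on ~16k genes). Two
considerations pin this scale: it must sit inside the permutation-
significant regime of *both* phenotypes (beyond it, sub-significant edges
enter as isolated two-gene communities and distort the community-level
assortativity distribution), and it must keep enough edges that the planted
module structure is densely sampled. ARACNE-style data-processing-inequality
pruning is deliberately not applied: the source analyses used MI plus
significance thresholding only.

## 2. Communities and assortativity

Detection runs on the selected network with scores as weights (they must be
positive; use absolute Pearson values if correlating). Louvain is the
default — it gave the highest modularity among the four algorithms in the
analyses this package systematizes — with fast greedy, infomap and leading
eigenvector available for cross-algorithm Jaccard comparisons
(`compare_partitions`). Nodes are sorted lexicographically before detection
and the RNG is seeded, so order-sensitive algorithms are deterministic.

Per community, with $c$ cis and $t$ trans internal edges:
$\mathrm{ASS}_{chr} = (c - t)/(c + t)$, computed by integer counting — the
cis classification ($\mathrm{ASS}_{chr} = 1$) is exact, with no floating
tolerance. $\mathrm{ASS}_{dge}$ replaces the chromosome attribute with the
*sign* of each gene's log2 fold change; genes that fail the significance
thresholds still contribute their sign, because the definition uses the
sign, not the call (a `strict` mode restricts to called genes). Communities
are named by their highest-PageRank member (igraph PageRank, damping 0.85,
edge weights as above); ties within $10^{-10}$ resolve to the
lexicographically smallest gene so a two-gene community is always named
after its first gene.

Modularity is computed in-package as
$Q = \sum_c [e_c/m - (d_c/2m)^2]$ and is tested against a brute-force
double-sum oracle; igraph is used only for the detection step itself.

## 3. Differential expression

A gene-wise two-group linear model on log2 values:
$\mathrm{LFC} = \bar x_{tumor} - \bar x_{healthy}$ with a pooled-variance t
statistic. By default gene variances are moderated: assuming
$s_g^2 \sim s_0^2 F(d, d_0)$, the prior $(d_0, s_0^2)$ is solved from the
first two moments of the observed $s_g^2$
($d_0 = (4Rd + 2d - 4)/(Rd - 2)$ with $R = \mathrm{CV}^2(s^2)$, falling back
to $d_0 = \infty$, i.e. full pooling, when the observed spread is at or
below the pure-$\chi^2$ level), variances are squeezed to
$(d_0 s_0^2 + d s_g^2)/(d_0 + d)$ and the t test gains $d_0$ degrees of
freedom. With `moderated = FALSE` the stage reduces *exactly* to the
textbook pooled t-test, which is how it is oracle-tested. Moderation is
re-implemented rather than delegated so the stage is self-contained and its
null behavior is checkable.

Calls use $|\mathrm{LFC}| \ge 0.5$ (boundary value passes) and $p < 0.05$
(boundary value fails), per-gene and unadjusted by default — the published
threshold statement names no multiple-testing correction for this stage,
unlike the enrichment stage; `adjust = TRUE` switches to BH.

## 4. Overrepresentation

`hypergeometric_test(k, K, n, N)` is the exact upper tail
$P[X \ge k]$, computed as a log-space sum of binomial terms; it matches
exhaustive draw enumeration to $10^{-12}$ for every parameter triple with
$N \le 12$. Benjamini–Hochberg is the standard step-up with monotonicity
enforcement. Conventions follow the GO-analysis defaults of the source
study: universe = all genes of the expression matrix, communities of ≥ 5
genes, terms of ≥ 10 genes *after* intersection with the universe
(the "minimum size of ten" is ambiguous between annotated and
universe-intersected size; intersected is the standard ORA convention and
was chosen), significance at BH-adjusted $p < 0.005$. The CNA-peak variant
drops both size filters and uses $p < 0.05$, with amplification and
deletion peaks tested as separate collections. BH is applied globally
across the whole (community, term) battery of a run — the stricter and
input-order-invariant choice — and the battery is sorted internally, so
results are identical however the inputs were ordered.

## 5. Genomic context

Coordinates are 0-based half-open in memory; BED I/O (rtracklayer) is
native to that convention, and the annotation TSV is written 1-based
inclusive with a header flag. Chromosome dialects ("chr1" vs "1") are
normalized on load; mixtures across inputs are an error, not a silent miss.

**Promoters** are strand-aware windows at the TSS. The literature behind
this package prints three different windows; none can be merged into the
others, so all three are presets: `regulon` (1,000 up / 100 down; the
default, used for TF-regulon annotation), `narrow` (100 / 10), and `ctcf`
(1,000 / 500 — the published "+1,000, −500" is read as 1,000 bp upstream
and 500 bp downstream, the signs being undefined in the source).

**CNA peaks** map to genes by full containment (a gene counts only if the
peak spans it entirely), the published remapping rule; an `overlap` mode
exists and provably contains the strict mode's result.

**CTCF peaks** are classified promoter / gene body / intergenic by their
midpoint with precedence promoter > gene body (the source is silent on
straddling peaks; the midpoint rule guarantees the three counts partition
the total). The boundary analysis takes each cis community's span (first
gene start to last gene end), counts peak midpoints in two flank windows of
50 kb (the published window), and compares against the mean count over
non-overlapping 50-kb windows tiling the interior, dropping a trailing
partial window rather than rescaling it (tiled windows chosen over sliding
ones; the source does not say). Communities with no associated peaks are
flagged rather than counted as negatives.

**TF regulons**: for each transcription factor that is itself a community
member, the regulatory degree is the number of its community neighbors
carrying at least one of its binding sites within their promoter window —
the pattern separating a fully-regulatory hub (every neighbor bound) from a
high-degree TF with no binding evidence.

## 6. The synthetic-data generator

The generator's role is to plant, at desk scale, exactly the statistical
structure the pipeline measures. Expression is a Gaussian latent-factor
model on the log2 scale. A module $m$ with planted correlation $\rho$
gives each member gene

$$x_{gs} = \mu_g + \gamma\,u_s + \sqrt{\rho}\,f_{ms} + \sqrt{1-\rho}\,e_{gs}
 + \sigma\,\eta_{gs} + \delta_m,$$

with baseline $\mu_g \sim U(4, 12)$, a shared per-sample factor $u_s$
(weight $\gamma$ = `global_factor_sd`, a batch-scale nuisance), unit-variance
module signal split between the shared factor and gene-specific variation,
noise $\sigma$ = `noise_sd`, and the condition shift $\delta_m$. Realized
within-module correlation is $\rho/(1+\sigma^2)$: it converges to $\rho$ as
noise vanishes and decreases monotonically in $\sigma$. Genes in no module
carry only baseline, global factor and noise — so they are independent given
the global factor, and a single-gene "module" contributes only its shift
(a latent factor for one gene would inflate its variance and is
meaningless). Defaults: `noise_sd = 0.3`, `global_factor_sd = 0.05`, chosen
so unrelated genes correlate at ≈ 0.03 (nuisance scale) while a
$\rho = 0.8$ module realizes ≈ 0.73.

Cis modules must be contiguous runs on one chromosome in genomic order;
trans modules must span ≥ 2 chromosomes; within one condition a gene
belongs to at most one module (violations are errors, not warnings). The
default genome is 22 autosomes with hg38-proportional lengths and 2,000
genes — a desk-scale stand-in for the ~20k-gene matrices of the real
cohorts — and the default group sizes are 113 healthy / 217 tumor, the
sample sizes of the study this package emulates.

**The two-condition contrast is a count asymmetry, not a strength
asymmetry.** The healthy condition gets 6 cis + 14 trans modules; the tumor
condition 26 cis + 4 trans, all at $\rho = 0.8$ (counts scale linearly for
smaller genomes). An earlier design that weakened tumor trans modules
instead ($\rho = 0.5$) proved degenerate: ranked by MI, every cis edge
preceded every trans edge, so any sparse network contained *no* tumor trans
community at all — unlike the real tumor networks, where the strongest
surviving trans communities (the overexpressed cell-cycle-like cluster) sit
among the top interactions. Tumor modules carry mean shifts (±1.5 for cis
blocks, +2 for half the trans modules) so DE, $\mathrm{ASS}_{dge}$ and the
assortativity scatter have signal.

Peak tracks come in three placements (uniform by chromosome length;
gene-spanning, guaranteeing containment, for CNA tests; boundary-enriched
with configurable odds, for CTCF boundary tests). Regulon and term-set
generators can be anchored to planted modules so recovery is a construction
guarantee, with uniform decoys for null calibration.

**What the generator does not emulate** — and what a green test therefore
does not establish: RNA-seq count noise (no negative-binomial layer; values
are Gaussian on the log2 scale), heavy-tailed or nonlinear dependence
(planted dependence is linear-Gaussian, which MI detects but does not
showcase), overlapping or hierarchical modules, copy-number *segmentation*
(only called peak intervals), read-level artifacts, and any real biology:
passing tests certify the machinery, not the biological claims of the
source study.

## 7. Numerical and determinism choices

* All generators and stochastic stages take explicit seeds; `with_seed`
  restores the caller's RNG state, so library calls never perturb user
  randomness. The pipeline derives fixed per-stage offsets from one config
  seed and writes a manifest of md5 hashes; two runs of the same config are
  bit-identical.
* Ties: edge selection and community naming break ties lexicographically;
  PageRank ties use a $10^{-10}$ tolerance. Largest-remainder apportionment
  resolves equal remainders toward earlier chromosomes.
* Degenerate inputs: constant expression vectors give MI 0 with a warning
  and are dropped (with a warning) before network inference; empty gene-set
  pairs are an error for the Jaccard index; communities with no internal
  edges report `NA` assortativity; a community spanning several chromosomes
  is rejected by the boundary analysis rather than silently skipped.
* The hypergeometric tail is summed in log space (no underflow for
  universe sizes in the tens of thousands); BH caps at 1.

## 8. Known limitations

* The MI estimator targets *ranking* fidelity; absolute MI values at small
  $n$ retain an $O(1)$-percent discretization bias and should not be read
  as calibrated information estimates.
* The pooled permutation null assumes exchangeable samples within a group;
  structured confounders (batches) would need to be regressed out upstream.
* Permutation p-value resolution is $1/(1+N_{perm})$: the published
  $P \le 10^{-8}$ cutoff is not reachable at desk-scale permutation counts,
  which is why top-$k$ selection is the primary thresholding mode.
* `enrich_communities` treats terms as opaque sets: no GO-hierarchy
  propagation or redundancy collapsing.
* The pipeline handles exactly two phenotype groups per run.
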
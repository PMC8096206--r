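# cistrans

Cis/trans gene co-expression network analysis for two-phenotype expression
studies.

## The problem

In several cancers, the strongest gene co-expression links collapse onto
single chromosomes: when a co-expression network (GCN) is built from the
top-ranked mutual-information (MI) values of a tumor expression matrix, most
edges join genes on the *same* chromosome (*cis*), whereas healthy-tissue
networks are dominated by inter-chromosomal (*trans*) edges. This "loss of
trans- co-expression" reshapes the network's community structure and, with
it, which biological functions the communities carry. `cistrans` packages
the full analysis chain needed to measure this phenomenon and to dissect
candidate mechanisms behind it — transcription-factor regulons, copy-number
alteration (CNA) peaks, and CTCF binding-site positioning — together with a
seeded synthetic-data generator that plants the same statistical structure,
so every stage is testable without access to controlled tumor data.

It is aimed at computational biologists studying co-expression topology in
bulk RNA-seq cohorts (two phenotype groups, log2-normalized expression).

## The statistics at the core

* **Network inference** — for each gene pair, binned mutual information
  `I(X;Y) = H(X) + H(Y) − H(X,Y)` in nats (equal-frequency bins,
  Miller–Madow bias correction), or Pearson correlation; significance from
  a pooled permutation null, `p = (1 + #{null ≥ obs}) / (1 + N_perm)`;
  edges kept by significance filter and/or top-*k* score rank.
* **Communities** — weighted Louvain (plus fast greedy, infomap, leading
  eigenvector), weighted Newman–Girvan modularity
  `Q = Σ_c [e_c/m − (d_c/2m)²]`, partitions compared by best-match Jaccard
  `J = |A∩B| / |A∪B|`, communities named by their highest-PageRank gene.
* **Assortativity** — per community,
  `ASS_chr = (cis links − trans links) / total links`; a community is *cis*
  iff `ASS_chr = 1`. `ASS_dge` is the analogue over the sign of each gene's
  log2 fold change.
* **Differential expression** — gene-wise linear model on log2 values,
  `LFC = mean(tumor) − mean(healthy)`, pooled t-test with optional
  empirical-Bayes variance moderation; calls at `|LFC| ≥ 0.5`, `p < 0.05`.
* **Overrepresentation** — exact hypergeometric upper tail per
  (community, term) pair with global Benjamini–Hochberg correction
  (GO-like GMT terms: communities ≥ 5 genes, terms ≥ 10, BH `p < 0.005`;
  CNA peak gene sets: no size filters, BH `p < 0.05`).
* **Genomic context** — CNA peaks mapped to the genes they span entirely;
  TF regulatory degree inside communities via promoter binding sites
  (window 1,000 bp upstream / 100 bp downstream of the TSS, strand-aware);
  CTCF peaks classified promoter / gene body / intergenic by midpoint; cis-
  community boundary analysis comparing 50-kb flank windows against the
  tiled community interior.

## Worked example

Simulate a two-phenotype study with the bundled healthy/tumor module
layout, infer both networks, and compare their cis fractions:

```r
library(cistrans)

genome <- default_genome(800)                 # 22 autosomes, 800 genes
ann    <- generate_annotation(genome, seed = 1)
layout <- default_module_layout(ann, seed = 1)
cfg    <- synthetic_study_config(genome, layout,
                                 n_samples_per_group = c(healthy = 40, tumor = 60),
                                 seed = 1)
study  <- generate_expression(cfg, ann)
study
#> <expression_study> 800 genes x 100 samples (healthy=40, tumor=60)

micfg <- mi_config(n_permutations = 1000, seed = 7)
net_h <- build_coexpression_network(study, ann, "healthy", "mi", micfg, top_k = 1500)
net_t <- build_coexpression_network(study, ann, "tumor",   "mi", micfg, top_k = 1500)
net_t
#> <coexpression_network> 1500 edges (mi), 271 genes, n=60 samples
#>   cis fraction: 0.845
net_t$edges[1:2]
#>    gene_a gene_b     score     p_value   cis
#> 1:  g0161  g0172 0.6193107 0.000999001  TRUE
#> 2:  g0367  g0371 0.5975126 0.000999001  TRUE

part <- detect_communities(net_t, "louvain", seed = 13)
prof <- community_profiles(part, net_t, ann,
                           de = differential_expression(study))
head(prof[order(-prof$size), c("community_id", "name", "size", "n_cis",
                               "n_trans", "ass_chr", "ass_dge")], 3)
#>   community_id  name size n_cis n_trans    ass_chr  ass_dge
#> 1            1 g0620   25     5      80 -0.8823529 1.000000
#> 2            2 g0796   25     6     136 -0.9154930 1.000000
#> 6            6 g0263   21   127       1  0.9843750 0.796875
```

The tumor network's cis fraction (0.845) sits far above the healthy one
(0.139 on the same run): the planted loss of trans- co-expression. The
largest tumor communities split into trans-dominated modules
(`ass_chr ≈ −0.9`, the surviving strongly co-expressed inter-chromosomal
blocks, here also uniformly overexpressed, `ass_dge = 1`) and cis blocks
(`ass_chr ≈ 1`). The full chain — enrichment, CNA peaks, CTCF boundaries,
TF regulons, report and manifest — runs from one config:

```r
cfg <- read_pipeline_config(system.file("extdata", "config-synthetic.yaml",
                                        package = "cistrans"))
report <- run_pipeline(cfg, "out_dir")
report
#> <run_report>
#>   healthy: 5000 edges (cis 0.172), 20 communities (6 cis / 14 trans), Q=0.923, 1 enriched
#>   tumor: 5000 edges (cis 0.795), 30 communities (26 cis / 4 trans), Q=0.963, 30 enriched
```

A command-line launcher is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts", "cistrans", package = "cistrans"))')" \
    run --config run.yaml --out out_dir
```

with stage-wise subcommands `simulate`, `infer`, `communities`, `de`,
`enrich`, and `context`.

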
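# fixtures built in code: tiny genomes, hand-made annotations, toy networks

# hand-built annotation: explicit coordinates, 0-based half-open
fixture_annotation <- function(df, chrom_lengths = NULL) {
  ann <- data.frame(gene_id = df$gene_id, chrom = df$chrom,
                    start = df$start, end = df$end,
                    strand = df$strand %||% rep("+", nrow(df)),
                    stringsAsFactors = FALSE)
  rownames(ann) <- ann$gene_id
  if (!is.null(chrom_lengths)) attr(ann, "chrom_lengths") <- chrom_lengths
  ann
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# three genes per chromosome on two chromosomes, evenly spaced
two_chrom_annotation <- function() {
  fixture_annotation(data.frame(
    gene_id = sprintf("g%02d", 1:6),
    chrom = rep(c("chr1", "chr2"), each = 3),
    start = rep(c(1000, 5000, 9000), 2),
    end = rep(c(2000, 6000, 10000), 2),
    strand = c("+", "-", "+", "-", "+", "-")),
    chrom_lengths = c(chr1 = 20000, chr2 = 20000))
}

# network from a plain edge table (scores default 1)
toy_network <- function(edges, annotation = NULL, score_kind = "mi") {
  e <- data.frame(gene_a = edges$gene_a, gene_b = edges$gene_b,
                  score = edges$score %||% rep(1, nrow(edges)),
                  p_value = edges$p_value %||% rep(NA_real_, nrow(edges)),
                  stringsAsFactors = FALSE)
  net <- cistrans:::new_network(e, score_kind = score_kind,
                                n_samples_used = NA_integer_)
  if (!is.null(annotation)) net <- label_cis_trans(net, annotation)
  net
}

# weighted clique edge table over the given genes
clique_edges <- function(genes, weight = 1) {
  cmb <- t(combn(sort(genes), 2))
  data.frame(gene_a = cmb[, 1], gene_b = cmb[, 2], score = weight,
             stringsAsFactors = FALSE)
}

# small two-group study with one planted module, used across tests
small_planted_study <- function(n_genes = 60, module_size = 10, rho = 0.9,
                                n_healthy = 50, n_tumor = 50, noise_sd = 0.1,
                                shift = 0, seed = 42) {
  genome <- genome_model(3, c(3e7, 2e7, 1e7), n_genes,
                         gene_length_range = c(1e3, 5e3),
                         intergenic_gap_range = c(1e4, 1e5))
  ann <- generate_annotation(genome, seed)
  mod_genes <- c(head(ann$gene_id, floor(module_size / 2)),
                 tail(ann$gene_id, ceiling(module_size / 2)))
  mod <- module_spec("m1", "trans", mod_genes, rho, shift)
  cfg <- synthetic_study_config(genome,
                                modules = list(healthy = list(), tumor = list(mod)),
                                n_samples_per_group = c(healthy = n_healthy,
                                                        tumor = n_tumor),
                                noise_sd = noise_sd, global_factor_sd = 0,
                                seed = seed)
  list(study = generate_expression(cfg, ann), annotation = ann, module = mod,
       config = cfg, genome = genome)
}

# brute-force weighted modularity: double sum over ordered node pairs
modularity_oracle <- function(edges, membership) {
  nodes <- names(membership)
  A <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  for (r in seq_len(nrow(edges))) {
    A[edges$gene_a[r], edges$gene_b[r]] <- A[edges$gene_a[r], edges$gene_b[r]] + edges$score[r]
    A[edges$gene_b[r], edges$gene_a[r]] <- A[edges$gene_b[r], edges$gene_a[r]] + edges$score[r]
  }
  k <- rowSums(A)
  m2 <- sum(A)
  q <- 0
  for (i in nodes) for (j in nodes)
    if (membership[i] == membership[j])
      q <- q + A[i, j] - k[i] * k[j] / m2
  unname(q) / m2
}

# exhaustive hypergeometric upper tail: enumerate all n-subsets of 1..N
hypergeom_oracle <- function(k, K, n, N) {
  if (n == 0) return(as.numeric(k == 0))
  draws <- combn(N, n)
  mean(colSums(draws <= K) >= k)
}
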
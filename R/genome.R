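#' Genome model for the synthetic-data generator
#'
#' Describes the coordinate space genes are placed in: chromosome count and
#' lengths, total gene count, and the sampling ranges for gene lengths and
#' intergenic gaps. All coordinates are base pairs; gene intervals are held
#' 0-based half-open in memory.
#'
#' @param n_chromosomes Number of chromosomes.
#' @param chrom_lengths Numeric vector of chromosome lengths (bp), length
#'   `n_chromosomes`.
#' @param n_genes Total number of genes to place.
#' @param gene_length_range Two-element range genes lengths are drawn from.
#' @param intergenic_gap_range Two-element range intergenic gaps are drawn
#'   from.
#' @return A `genome_model` list.
#' @export
genome_model <- function(n_chromosomes, chrom_lengths, n_genes,
                         gene_length_range = c(5e3, 1e5),
                         intergenic_gap_range = c(5e4, 2e6)) {
  stopifnot(length(chrom_lengths) == n_chromosomes, all(chrom_lengths > 0),
            n_genes >= n_chromosomes,
            length(gene_length_range) == 2, gene_length_range[1] > 0,
            gene_length_range[1] <= gene_length_range[2],
            length(intergenic_gap_range) == 2, intergenic_gap_range[1] >= 0,
            intergenic_gap_range[1] <= intergenic_gap_range[2])
  structure(list(n_chromosomes = as.integer(n_chromosomes),
                 chrom_lengths = as.numeric(chrom_lengths),
                 n_genes = as.integer(n_genes),
                 gene_length_range = as.numeric(gene_length_range),
                 intergenic_gap_range = as.numeric(intergenic_gap_range)),
            class = "genome_model")
}

#' Default desk-scale genome: 22 autosomes, hg38-proportional lengths
#'
#' @param n_genes Number of genes (default 2000, a desk-scale stand-in for
#'   the ~20k-gene full-transcriptome matrices).
#' @param ... Passed on to [genome_model()].
#' @export
default_genome <- function(n_genes = 2000, ...) {
  hg38_mb <- c(248.96, 242.19, 198.30, 190.21, 181.54, 170.81, 159.35,
               145.14, 138.39, 133.80, 135.09, 133.28, 114.36, 107.04,
               101.99, 90.34, 83.26, 80.37, 58.62, 64.44, 46.71, 50.82)
  genome_model(22L, hg38_mb * 1e6, n_genes, ...)
}

# largest-remainder apportionment of n items proportional to weights;
# ties on the fractional part resolved toward earlier entries
largest_remainder <- function(n, weights) {
  q <- n * weights / sum(weights)
  base <- floor(q)
  rem <- n - sum(base)
  if (rem > 0) {
    o <- order(-(q - base), seq_along(q))
    base[o[seq_len(rem)]] <- base[o[seq_len(rem)]] + 1
  }
  as.integer(base)
}

#' Generate a gene annotation table
#'
#' Places `n_genes` non-overlapping genes across chromosomes, with
#' per-chromosome counts proportional to chromosome length
#' (largest-remainder rounding). Genes are sorted by position and named in
#' genomic order. Coordinates are 0-based half-open.
#'
#' @param genome A [genome_model()].
#' @param seed Integer seed; output is deterministic given `genome` + `seed`.
#' @return data.frame with columns gene_id, chrom, start, end, strand and
#'   attribute `chrom_lengths`.
#' @export
generate_annotation <- function(genome, seed = 1) {
  stopifnot(inherits(genome, "genome_model"))
  counts <- largest_remainder(genome$n_genes, genome$chrom_lengths)
  with_seed(seed, {
    rows <- vector("list", genome$n_chromosomes)
    for (c in seq_len(genome$n_chromosomes)) {
      k <- counts[c]
      if (k == 0) next
      len <- round(runif(k, genome$gene_length_range[1], genome$gene_length_range[2]))
      gap <- round(runif(k, genome$intergenic_gap_range[1], genome$intergenic_gap_range[2]))
      start <- cumsum(gap) + cumsum(c(0, len[-k]))
      end <- start + len
      if (end[k] > genome$chrom_lengths[c])
        stopf("gene footprint (%d bp) exceeds chr%d length (%d bp); shrink gaps or genes",
              end[k], c, as.integer(genome$chrom_lengths[c]))
      rows[[c]] <- data.frame(chrom = paste0("chr", c), start = start, end = end,
                              strand = sample(c("+", "-"), k, replace = TRUE))
    }
    ann <- do.call(rbind, rows)
    ann <- data.frame(gene_id = sprintf("g%04d", seq_len(nrow(ann))), ann,
                      stringsAsFactors = FALSE)
    rownames(ann) <- ann$gene_id
    attr(ann, "chrom_lengths") <-
      setNames(genome$chrom_lengths, paste0("chr", seq_len(genome$n_chromosomes)))
    ann
  })
}

# order annotation rows by genomic position (chromosome number, then start)
genomic_order <- function(annotation) {
  chrn <- as.integer(sub("^chr", "", annotation$chrom))
  order(chrn, annotation$start)
}
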
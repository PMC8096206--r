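# module layout builders: pick non-overlapping cis runs / trans scatters

#' Build cis modules (contiguous genomic runs)
#'
#' Samples `n` non-overlapping runs of `size` consecutive genes (genomic
#' order, single chromosome each) from genes not in `exclude`.
#'
#' @param annotation Gene annotation.
#' @param n Number of modules.
#' @param size Genes per module.
#' @param rho Planted latent correlation.
#' @param shifts Mean shifts recycled over modules (log2 units).
#' @param seed Integer seed.
#' @param exclude Gene ids already claimed (within the same condition).
#' @param prefix Module id prefix.
#' @return List of [module_spec()]s.
#' @export
make_cis_modules <- function(annotation, n, size, rho, shifts = 0, seed = 1,
                             exclude = character(), prefix = "cis") {
  ord <- genomic_order(annotation)
  ann <- annotation[ord, ]
  shifts <- rep_len(shifts, n)
  with_seed(seed + 11L, {
    used <- ann$gene_id %in% exclude
    mods <- vector("list", n)
    for (m in seq_len(n)) {
      # all windows of `size` consecutive free genes on one chromosome
      ok <- vapply(seq_len(nrow(ann) - size + 1), function(s) {
        idx <- s:(s + size - 1)
        ann$chrom[s] == ann$chrom[s + size - 1] && all(!used[idx])
      }, logical(1))
      starts <- which(ok)
      if (length(starts) == 0)
        stopf("could not place cis module %d of %d (size %d): no free window", m, n, size)
      s <- starts[sample.int(length(starts), 1)]
      idx <- s:(s + size - 1)
      used[idx] <- TRUE
      mods[[m]] <- module_spec(sprintf("%s_%02d", prefix, m), "cis",
                               ann$gene_id[idx], rho, shifts[m])
    }
    mods
  })
}

#' Build trans modules (genes scattered over >= 2 chromosomes)
#'
#' @inheritParams make_cis_modules
#' @export
make_trans_modules <- function(annotation, n, size, rho, shifts = 0, seed = 1,
                               exclude = character(), prefix = "trans") {
  stopifnot(size >= 2)
  shifts <- rep_len(shifts, n)
  with_seed(seed + 12L, {
    pool <- setdiff(annotation$gene_id, exclude)
    mods <- vector("list", n)
    for (m in seq_len(n)) {
      if (length(pool) < size) stopf("gene pool exhausted placing trans module %d", m)
      repeat {
        genes <- sample(pool, size)
        if (length(unique(annotation[genes, "chrom"])) >= 2) break
      }
      pool <- setdiff(pool, genes)
      mods[[m]] <- module_spec(sprintf("%s_%02d", prefix, m), "trans",
                               genes, rho, shifts[m])
    }
    mods
  })
}

#' Default two-condition module layout
#'
#' The stated world of the bundled synthetic study, emulating the
#' qualitative healthy-vs-tumor contrast as a count asymmetry: the healthy
#' condition is dominated by large trans modules (a giant inter-chromosomal
#' component) with a few cis blocks, while the tumor condition carries many
#' cis blocks and only a few surviving trans modules (the strongly
#' co-expressed, overexpressed cell-cycle-like pattern). All modules share
#' one planted correlation so selection at any top-k keeps a fair mixture
#' of both kinds; tumor modules carry mean shifts so differential
#' expression and expression assortativity have signal.
#'
#' Module counts scale with genome size (reference: 2,000 genes) so smaller
#' test genomes keep the same qualitative structure.
#'
#' @param annotation Gene annotation.
#' @param seed Integer seed.
#' @return Named list with `healthy` and `tumor` module lists.
#' @export
default_module_layout <- function(annotation, seed = 1) {
  s <- nrow(annotation) / 2000
  # contiguous runs are scarce once scattered genes are claimed, so cis
  # blocks are always placed first
  healthy_cis <- make_cis_modules(annotation, n = max(1, round(6 * s)),
                                  size = 20, rho = 0.8,
                                  seed = seed, prefix = "h_cis")
  healthy_trans <- make_trans_modules(annotation, n = max(1, round(14 * s)),
                                      size = 40, rho = 0.8,
                                      seed = seed,
                                      exclude = unlist(lapply(healthy_cis, `[[`, "gene_ids")),
                                      prefix = "h_trans")
  tumor_cis <- make_cis_modules(annotation, n = max(2, round(26 * s)),
                                size = 20, rho = 0.8,
                                shifts = rep(c(1.5, -1.5, 0), length.out = max(2, round(26 * s))),
                                seed = seed + 1L, prefix = "t_cis")
  tumor_trans <- make_trans_modules(annotation, n = max(1, round(4 * s)),
                                    size = 25, rho = 0.8,
                                    shifts = rep(c(2, 2, 0, 0), length.out = max(1, round(4 * s))),
                                    seed = seed + 1L,
                                    exclude = unlist(lapply(tumor_cis, `[[`, "gene_ids")),
                                    prefix = "t_trans")
  list(healthy = c(healthy_cis, healthy_trans),
       tumor = c(tumor_cis, tumor_trans))
}
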
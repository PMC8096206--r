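#' Module specification for the synthetic expression generator
#'
#' A module is a set of genes sharing one latent factor, so their pairwise
#' expression correlation is planted at `latent_correlation`. `cis` modules
#' must be contiguous runs of genes on one chromosome; `trans` modules must
#' span at least two chromosomes. `mean_shift_log2` is an additive shift
#' applied to the condition the module belongs to, and is what downstream
#' differential expression recovers.
#'
#' @param module_id Character id.
#' @param kind `"cis"` or `"trans"`.
#' @param gene_ids Character vector of member genes.
#' @param latent_correlation Target within-module Pearson correlation in
#'   `[0, 1)` (realized correlation is `rho / (1 + noise_sd^2)`).
#' @param mean_shift_log2 Per-condition additive shift (log2 units).
#' @export
module_spec <- function(module_id, kind = c("cis", "trans"), gene_ids,
                        latent_correlation, mean_shift_log2 = 0) {
  kind <- match.arg(kind)
  stopifnot(length(gene_ids) >= 1, !anyDuplicated(gene_ids),
            latent_correlation >= 0, latent_correlation < 1,
            is.finite(mean_shift_log2))
  structure(list(module_id = as.character(module_id), kind = kind,
                 gene_ids = as.character(gene_ids),
                 latent_correlation = latent_correlation,
                 mean_shift_log2 = mean_shift_log2),
            class = "module_spec")
}

#' Synthetic study configuration
#'
#' Bundles a genome, per-condition module lists, and noise levels. Default
#' group sizes are 113 healthy and 217 tumor samples, the sample sizes of
#' the TCGA-derived study the generator emulates.
#'
#' @param genome A [genome_model()].
#' @param modules Named list with elements `healthy` and `tumor`, each a list
#'   of [module_spec()]s active in that condition (co-expression rewiring);
#'   within a condition a gene may belong to at most one module.
#' @param n_samples_per_group Named integer vector `c(healthy=, tumor=)`.
#' @param noise_sd Per-gene Gaussian noise sd (log2 units).
#' @param global_factor_sd Sd of a shared per-sample factor (batch-like).
#' @param seed Integer seed; fully determines all generated data.
#' @export
synthetic_study_config <- function(genome,
                                   modules = list(healthy = list(), tumor = list()),
                                   n_samples_per_group = c(healthy = 113, tumor = 217),
                                   noise_sd = 0.3, global_factor_sd = 0.05,
                                   seed = 1) {
  stopifnot(inherits(genome, "genome_model"),
            all(c("healthy", "tumor") %in% names(modules)),
            all(c("healthy", "tumor") %in% names(n_samples_per_group)),
            all(n_samples_per_group >= 2),
            noise_sd >= 0, global_factor_sd >= 0)
  for (cond in c("healthy", "tumor")) {
    ids <- unlist(lapply(modules[[cond]], `[[`, "gene_ids"))
    if (anyDuplicated(ids))
      stopf("overlapping modules in condition '%s' claim gene(s): %s", cond,
            paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  structure(list(genome = genome, modules = modules,
                 n_samples_per_group = n_samples_per_group,
                 noise_sd = noise_sd, global_factor_sd = global_factor_sd,
                 seed = as.integer(seed)),
            class = "synthetic_study_config")
}

# check module geometry against the annotation
validate_modules <- function(modules, annotation) {
  ord <- genomic_order(annotation)
  pos <- match(annotation$gene_id[ord], annotation$gene_id) # genomic rank
  rank_of <- setNames(order(ord), annotation$gene_id)
  for (m in modules) {
    missing <- setdiff(m$gene_ids, annotation$gene_id)
    if (length(missing) > 0)
      stopf("module %s refers to unknown gene(s): %s", m$module_id,
            paste(missing, collapse = ", "))
    chroms <- unique(annotation[m$gene_ids, "chrom"])
    if (m$kind == "cis") {
      if (length(chroms) != 1)
        stopf("cis module %s spans several chromosomes", m$module_id)
      r <- sort(rank_of[m$gene_ids])
      if (length(r) > 1 && any(diff(r) != 1))
        stopf("cis module %s is not contiguous in genomic order", m$module_id)
    } else if (length(m$gene_ids) > 1 && length(chroms) < 2) {
      stopf("trans module %s lies on a single chromosome", m$module_id)
    }
  }
  invisible(TRUE)
}

#' Generate a two-group synthetic expression study
#'
#' Gaussian latent-factor model on the log2 scale. For a gene in a module
#' with planted correlation rho (module size >= 2):
#' `x = baseline + global + sqrt(rho) f_module + sqrt(1-rho) e + noise_sd eta
#' + shift`; single-gene modules contribute only their mean shift; free genes
#' are `baseline + global + noise_sd eta`. Conditioned on the global factor,
#' free genes are independent.
#'
#' @param config A [synthetic_study_config()].
#' @param annotation Gene annotation; defaults to
#'   `generate_annotation(config$genome, config$seed)`.
#' @return An `expression_study`: list with `values` (genes x samples
#'   matrix), `gene_ids`, `sample_ids`, `groups` (named factor).
#' @export
generate_expression <- function(config,
                                annotation = generate_annotation(config$genome, config$seed)) {
  stopifnot(inherits(config, "synthetic_study_config"))
  for (cond in c("healthy", "tumor"))
    validate_modules(config$modules[[cond]], annotation)
  G <- nrow(annotation)
  ns <- config$n_samples_per_group
  samples <- c(sprintf("healthy_%03d", seq_len(ns[["healthy"]])),
               sprintf("tumor_%03d", seq_len(ns[["tumor"]])))
  groups <- factor(rep(c("healthy", "tumor"), ns[c("healthy", "tumor")]),
                   levels = c("healthy", "tumor"))
  names(groups) <- samples
  with_seed(config$seed + 1L, {
    baseline <- runif(G, 4, 12)
    N <- length(samples)
    vals <- matrix(rnorm(G * N, sd = config$noise_sd), G, N,
                   dimnames = list(annotation$gene_id, samples))
    vals <- vals + baseline +
      rep(rnorm(N, sd = config$global_factor_sd), each = G)
    for (cond in c("healthy", "tumor")) {
      cols <- which(groups == cond)
      for (m in config$modules[[cond]]) {
        idx <- match(m$gene_ids, annotation$gene_id)
        vals[idx, cols] <- vals[idx, cols] + m$mean_shift_log2
        if (length(idx) >= 2) {
          rho <- m$latent_correlation
          f <- rnorm(length(cols))
          sig <- sqrt(rho) * rep(f, each = length(idx)) +
            sqrt(1 - rho) * rnorm(length(idx) * length(cols))
          vals[idx, cols] <- vals[idx, cols] + sig
        }
      }
    }
    structure(list(values = vals, gene_ids = annotation$gene_id,
                   sample_ids = samples, groups = groups),
              class = "expression_study")
  })
}

#' @export
print.expression_study <- function(x, ...) {
  cat(sprintf("<expression_study> %d genes x %d samples (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%s=%d", levels(x$groups), table(x$groups)),
                    collapse = ", ")))
  invisible(x)
}

#' Generate a genomic peak track (BED-like intervals)
#'
#' Three placement modes: `uniform` scatters peaks across chromosomes
#' proportionally to length; `gene_spanning` emits one peak fully containing
#' each sampled target gene (the copy-number-peak regime, where genes are
#' kept only when spanned entirely by a peak); `boundary_enriched`
#' concentrates peaks in `flank`-sized windows at supplied boundary
#' intervals with odds `enrichment_ratio : 1` against uniform placement.
#'
#' @param annotation Gene annotation (carries chromosome lengths).
#' @param n_peaks Number of peaks.
#' @param placement One of `"uniform"`, `"boundary_enriched"`,
#'   `"gene_spanning"`.
#' @param seed Integer seed.
#' @param peak_width_range Width range for uniform/boundary peaks (bp).
#' @param target_genes For `gene_spanning`: gene ids to span (sampled from
#'   the annotation when `NULL`); recycled/truncated to `n_peaks`.
#' @param boundaries For `boundary_enriched`: data.frame(chrom, start, end)
#'   of community spans whose flanks attract peaks.
#' @param flank Flank width for `boundary_enriched` (bp).
#' @param enrichment_ratio Odds of flank vs uniform placement.
#' @return Interval track data.frame (chrom, start, end, name, score,
#'   strand), 0-based half-open, sorted by (chrom, start).
#' @export
generate_peak_track <- function(annotation, n_peaks,
                                placement = c("uniform", "boundary_enriched", "gene_spanning"),
                                seed = 1, peak_width_range = c(200, 2000),
                                target_genes = NULL, boundaries = NULL,
                                flank = 5e4, enrichment_ratio = 10) {
  placement <- match.arg(placement)
  stopifnot(n_peaks >= 0)
  clens <- attr(annotation, "chrom_lengths")
  if (is.null(clens)) {
    clens <- tapply(annotation$end, annotation$chrom, max) * 1.05
    clens <- setNames(as.numeric(clens), names(clens))
  }
  empty <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      name = character(), score = numeric(), strand = character(),
                      stringsAsFactors = FALSE)
  if (n_peaks == 0) return(empty)
  with_seed(seed + 101L, {
    uniform_one <- function(k) {
      chrom <- sample(names(clens), k, replace = TRUE, prob = clens)
      w <- round(runif(k, peak_width_range[1], peak_width_range[2]))
      start <- floor(runif(k) * (clens[chrom] - w))
      data.frame(chrom = chrom, start = start, end = start + w,
                 stringsAsFactors = FALSE)
    }
    tr <- switch(placement,
      uniform = uniform_one(n_peaks),
      gene_spanning = {
        tg <- target_genes %||% sample(annotation$gene_id, min(n_peaks, nrow(annotation)))
        tg <- rep_len(tg, n_peaks)
        g <- annotation[tg, ]
        pad_l <- round(runif(n_peaks, 100, 1000))
        pad_r <- round(runif(n_peaks, 100, 1000))
        data.frame(chrom = g$chrom, start = pmax(0, g$start - pad_l),
                   end = g$end + pad_r, stringsAsFactors = FALSE)
      },
      boundary_enriched = {
        if (is.null(boundaries) || nrow(boundaries) == 0)
          stopf("boundary_enriched placement needs a 'boundaries' table")
        in_flank <- runif(n_peaks) < enrichment_ratio / (enrichment_ratio + 1)
        k_f <- sum(in_flank)
        out <- uniform_one(n_peaks)
        if (k_f > 0) {
          b <- boundaries[sample(nrow(boundaries), k_f, replace = TRUE), ]
          left <- runif(k_f) < 0.5
          w <- round(runif(k_f, peak_width_range[1], peak_width_range[2]))
          lo <- ifelse(left, pmax(0, b$start - flank), b$end)
          start <- floor(lo + runif(k_f) * pmax(1, flank - w))
          out$chrom[in_flank] <- b$chrom
          out$start[in_flank] <- start
          out$end[in_flank] <- start + w
        }
        out
      })
    tr <- tr[order(as.integer(sub("^chr", "", tr$chrom)), tr$start), ]
    tr$name <- sprintf("peak_%04d", seq_len(nrow(tr)))
    tr$score <- rep(0, nrow(tr))
    tr$strand <- rep(".", nrow(tr))
    rownames(tr) <- NULL
    tr
  })
}

#' Generate TF regulons with promoter binding sites
#'
#' Each transcription factor (TF) is an annotated gene; each target row
#' records a binding-site interval inside the target's promoter window.
#' When `modules` is supplied, TFs are planted inside those modules so their
#' targets co-express (the FOXM1-style pattern: a TF whose whole community
#' neighborhood is also its regulon).
#'
#' @param annotation Gene annotation.
#' @param modules Optional list of [module_spec()]s to host TFs (one TF per
#'   module, targets drawn from the module).
#' @param n_tfs Number of TFs.
#' @param targets_per_tf Regulon size cap.
#' @param seed Integer seed.
#' @param window Promoter window used to place binding sites
#'   ([promoter_window()]).
#' @return List with `regulons` (named list tf -> data.frame(target, chrom,
#'   site_start, site_end)) and `table` (one combined data.frame).
#' @export
generate_regulons <- function(annotation, modules = NULL, n_tfs, targets_per_tf,
                              seed = 1, window = promoter_window()) {
  stopifnot(n_tfs >= 0, targets_per_tf >= 0)
  if (n_tfs == 0)
    return(list(regulons = setNames(list(), character()),
                table = data.frame(tf = character(), target = character(),
                                   chrom = character(), site_start = numeric(),
                                   site_end = numeric(), stringsAsFactors = FALSE)))
  with_seed(seed + 202L, {
    regs <- list()
    for (t in seq_len(n_tfs)) {
      if (!is.null(modules) && t <= length(modules)) {
        mod <- modules[[t]]
        tf <- mod$gene_ids[1]
        pool <- setdiff(mod$gene_ids, tf)
      } else {
        tf <- sample(setdiff(annotation$gene_id, names(regs)), 1)
        pool <- setdiff(annotation$gene_id, tf)
      }
      targets <- if (length(pool) <= targets_per_tf) pool else
        sample(pool, targets_per_tf)
      prom <- promoter_of(annotation[targets, , drop = FALSE], window)
      width <- pmax(1, prom$end - prom$start)
      off <- floor(runif(length(targets)) * pmax(1, width - 15))
      regs[[tf]] <- data.frame(target = targets, chrom = prom$chrom,
                               site_start = prom$start + off,
                               site_end = pmin(prom$end, prom$start + off + 15),
                               stringsAsFactors = FALSE)
    }
    tab <- do.call(rbind, Map(function(tf, d) cbind(tf = tf, d),
                              names(regs), regs))
    rownames(tab) <- NULL
    list(regulons = regs, table = tab)
  })
}

#' Generate GMT-style term sets
#'
#' A configurable fraction of terms coincide with planted modules (plus
#' optional noise genes) so overrepresentation is recoverable; the rest are
#' decoys drawn uniformly from the annotation.
#'
#' @param annotation Gene annotation.
#' @param modules Optional list of [module_spec()]s to convert into terms.
#' @param n_terms Total number of terms.
#' @param seed Integer seed.
#' @param decoy_fraction Fraction of terms that are uniform decoys (applies
#'   when `modules` supplies fewer than `n_terms` terms anyway).
#' @param noise_genes Random genes appended to each module-derived term.
#' @param size_range Decoy term size range.
#' @param min_size Minimum term size (smaller draws are resized up).
#' @return Named list term_id -> character vector of genes.
#' @export
generate_term_sets <- function(annotation, modules = NULL, n_terms, seed = 1,
                               decoy_fraction = 0.5, noise_genes = 0,
                               size_range = c(10, 60), min_size = 10) {
  stopifnot(n_terms >= 0)
  if (n_terms == 0) return(setNames(list(), character()))
  with_seed(seed + 303L, {
    n_mod <- if (is.null(modules)) 0L else
      min(length(modules), ceiling(n_terms * (1 - decoy_fraction)))
    terms <- list()
    for (t in seq_len(n_mod)) {
      genes <- modules[[t]]$gene_ids
      if (noise_genes > 0)
        genes <- c(genes, sample(setdiff(annotation$gene_id, genes), noise_genes))
      if (length(genes) < min_size)
        genes <- c(genes, sample(setdiff(annotation$gene_id, genes),
                                 min_size - length(genes)))
      terms[[sprintf("TERM_M%03d", t)]] <- genes
    }
    for (t in seq_len(n_terms - n_mod)) {
      k <- max(min_size, round(runif(1, size_range[1], size_range[2])))
      terms[[sprintf("TERM_D%03d", t)]] <- sample(annotation$gene_id, k)
    }
    terms
  })
}
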
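# co-expression network construction and threshold summaries

new_network <- function(edges, score_kind, n_samples_used, genes = NULL) {
  structure(list(edges = data.table::as.data.table(edges),
                 score_kind = score_kind,
                 n_samples_used = n_samples_used,
                 genes = genes %||% sort(unique(c(edges$gene_a, edges$gene_b)))),
            class = "coexpression_network")
}

#' @export
print.coexpression_network <- function(x, ...) {
  cat(sprintf("<coexpression_network> %d edges (%s), %d genes, n=%s samples\n",
              nrow(x$edges), x$score_kind, length(x$genes),
              x$n_samples_used))
  if ("cis" %in% names(x$edges) && nrow(x$edges) > 0)
    cat(sprintf("  cis fraction: %.3f\n", mean(x$edges$cis)))
  invisible(x)
}

#' Build a co-expression network for one phenotype group
#'
#' Computes all pairwise dependence scores (binned mutual information or
#' Pearson correlation) among the group's samples, attaches pooled
#' permutation p-values, labels edges cis/trans against the annotation, and
#' applies the paper-style selection: p-value filter first (when `p_cut` is
#' set), then top-k by score.
#'
#' Constant-expression genes cannot carry dependence information and are
#' dropped with a warning before inference.
#'
#' @param study An `expression_study`.
#' @param annotation Gene annotation (for cis/trans labels).
#' @param group Group label to analyze (`NULL` = all samples).
#' @param measure `"mi"` or `"pearson"`.
#' @param cfg [mi_config()] controlling bins/permutations/seed.
#' @param top_k Keep the `top_k` strongest edges (`NULL` = keep all).
#' @param p_cut Keep edges with p <= `p_cut` before top-k (`NULL` = skip).
#' @param compute_pvalues Set `FALSE` to skip the permutation null.
#' @return A `coexpression_network`.
#' @export
build_coexpression_network <- function(study, annotation, group = NULL,
                                       measure = c("mi", "pearson"),
                                       cfg = mi_config(), top_k = NULL,
                                       p_cut = NULL, compute_pvalues = TRUE) {
  measure <- match.arg(measure)
  vals <- study$values
  if (!is.null(group)) {
    keep <- names(study$groups)[study$groups == group]
    if (length(keep) < 2) stopf("group '%s' has fewer than 2 samples", group)
    vals <- vals[, keep, drop = FALSE]
  }
  const <- apply(vals, 1, sd) == 0
  if (any(const)) {
    warning(sprintf("dropping %d constant-expression gene(s): %s",
                    sum(const), paste(head(rownames(vals)[const], 5), collapse = ", ")))
    vals <- vals[!const, , drop = FALSE]
  }
  G <- nrow(vals)
  if (G < 2) stopf("fewer than 2 usable genes")
  idx <- pair_indices(G)
  if (measure == "mi") {
    score <- mi_all_pairs(vals, cfg)
  } else {
    cm <- cor(t(vals))
    score <- cm[cbind(idx$i, idx$j)]
  }
  edges <- data.table::data.table(gene_a = rownames(vals)[idx$i],
                                  gene_b = rownames(vals)[idx$j],
                                  score = score)
  if (compute_pvalues) {
    null_sorted <- if (measure == "mi") {
      mi_permutation_null(vals, cfg)
    } else {
      pearson_permutation_null(vals, cfg)
    }
    edges[, p_value := permutation_pvalues(score, null_sorted)]
  } else {
    edges[, p_value := NA_real_]
  }
  net <- new_network(edges, score_kind = measure, n_samples_used = ncol(vals),
                     genes = rownames(vals))
  net <- label_cis_trans(net, annotation)
  if (!is.null(p_cut)) {
    net$edges <- net$edges[p_value <= p_cut]
    net$genes <- sort(unique(c(net$edges$gene_a, net$edges$gene_b)))
  }
  if (!is.null(top_k)) net <- select_top_edges(net, min(top_k, nrow(net$edges)))
  net
}

# pooled null for the pearson measure: permute one gene of a random pair
pearson_permutation_null <- function(vals, cfg) {
  G <- nrow(vals); n <- ncol(vals)
  with_seed(cfg$seed, {
    out <- numeric(cfg$n_permutations)
    for (p in seq_len(cfg$n_permutations)) {
      ij <- sample.int(G, 2)
      out[p] <- cor(vals[ij[1], ], vals[ij[2], sample.int(n)])
    }
    sort(out)
  })
}

#' Select the k strongest edges
#'
#' Ranks by score descending; ties broken lexicographically by
#' (gene_a, gene_b) so the selection is deterministic. Top-k edge sets are
#' nested: top-k is always a subset of top-(k+1).
#'
#' @param net A `coexpression_network`.
#' @param k Number of edges to keep (1 <= k <= edge count).
#' @export
select_top_edges <- function(net, k) {
  if (k <= 0) stopf("k must be positive")
  if (k > nrow(net$edges)) stopf("k = %d exceeds edge count %d", k, nrow(net$edges))
  e <- net$edges[order(-score, gene_a, gene_b)][seq_len(k)]
  new_network(e, net$score_kind, net$n_samples_used)
}

#' Label edges cis (intra-chromosomal) or trans (inter-chromosomal)
#'
#' An edge is cis iff both genes lie on the same chromosome in the
#' annotation. Genes absent from the annotation are an error (listed).
#'
#' @param net A `coexpression_network`.
#' @param annotation Gene annotation.
#' @export
label_cis_trans <- function(net, annotation) {
  missing <- setdiff(net$genes, annotation$gene_id)
  if (length(missing) > 0)
    stopf("genes missing from annotation: %s",
          paste(head(missing, 10), collapse = ", "))
  chrom <- setNames(annotation$chrom, annotation$gene_id)
  net$edges[, cis := chrom[gene_a] == chrom[gene_b]]
  net
}

#' Fraction of cis edges among the top-k, over a grid of k
#'
#' The threshold-sweep summary: for each k, the proportion of
#' intra-chromosomal edges among the k strongest. In tumor-like networks
#' this curve sits above the healthy one at every k (loss of trans-
#' co-expression).
#'
#' @param net A labeled `coexpression_network`.
#' @param k_grid Ascending edge counts (each <= total edges).
#' @return data.frame(k, cis_fraction).
#' @export
cis_fraction_curve <- function(net, k_grid) {
  stopifnot(!is.unsorted(k_grid), all(k_grid >= 1),
            all(k_grid <= nrow(net$edges)))
  e <- net$edges[order(-score, gene_a, gene_b)]
  cum_cis <- cumsum(e$cis)
  data.frame(k = k_grid, cis_fraction = cum_cis[k_grid] / k_grid)
}

#' Score histograms for two networks on a shared bin grid
#'
#' Bins are computed from the pooled score range of both full networks, so
#' counts are comparable across networks and across strata: the cis and
#' trans histograms sum bin-wise to the all-edges histogram.
#'
#' @param net_a,net_b Labeled networks.
#' @param stratify `"all"`, `"cis"`, or `"trans"`.
#' @param n_bins Number of equal-width bins.
#' @return data.frame(bin_lo, bin_hi, count_a, count_b).
#' @export
score_histograms <- function(net_a, net_b, stratify = c("all", "cis", "trans"),
                             n_bins = 30) {
  stratify <- match.arg(stratify)
  all_scores <- c(net_a$edges$score, net_b$edges$score)
  rng <- range(all_scores)
  if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  pick <- function(net) {
    s <- switch(stratify, all = net$edges$score,
                cis = net$edges$score[net$edges$cis],
                trans = net$edges$score[!net$edges$cis])
    if (length(s) == 0) return(integer(n_bins))
    tabulate(pmin(pmax(findInterval(s, breaks, rightmost.closed = TRUE), 1L),
                  n_bins), nbins = n_bins)
  }
  data.frame(bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1],
             count_a = pick(net_a), count_b = pick(net_b))
}

#' Position-ordered Pearson correlation matrix
#'
#' Correlation between all gene pairs with rows/columns ordered by
#' (chromosome, start), so cis blocks appear along the diagonal.
#'
#' @param study An `expression_study`.
#' @param annotation Gene annotation.
#' @param group Optional group label to subset samples.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
pearson_matrix <- function(study, annotation, group = NULL) {
  vals <- study$values
  if (!is.null(group))
    vals <- vals[, names(study$groups)[study$groups == group], drop = FALSE]
  ann <- annotation[annotation$gene_id %in% rownames(vals), ]
  ord <- ann$gene_id[genomic_order(ann)]
  cor(t(vals[ord, , drop = FALSE]))
}
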
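# hypergeometric overrepresentation of term sets within communities

#' Exact hypergeometric upper-tail probability
#'
#' `P[X >= k]` for `X ~ Hypergeometric(N, K, n)`: drawing `n` genes from a
#' universe of `N` containing `K` term genes. Computed as an exact sum of
#' log-binomial terms (log-sum-exp), so it is stable for large universes.
#' Vectorized over its arguments.
#'
#' @param k Observed overlap.
#' @param K Term size (in the universe).
#' @param n Community (draw) size.
#' @param N Universe size.
#' @export
hypergeometric_test <- function(k, K, n, N) {
  args <- cbind(k, K, n, N)
  apply(args, 1, function(a) {
    k <- a[1]; K <- a[2]; n <- a[3]; N <- a[4]
    if (!(k >= 0 && k <= min(K, n) && max(K, n) <= N))
      stopf("invalid hypergeometric parameters k=%g K=%g n=%g N=%g", k, K, n, N)
    if (k == 0) return(1)
    i <- k:min(K, n)
    lp <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
    mx <- max(lp)
    min(1, exp(mx) * sum(exp(lp - mx)))
  })
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up procedure: `p_(i) * m / i` with monotonicity enforced from the
#' largest p downward, capped at 1. Matches `p.adjust(method = "BH")`.
#'
#' @param p Numeric vector of p-values.
#' @export
benjamini_hochberg <- function(p) {
  m <- length(p)
  if (m == 0) return(numeric(0))
  o <- order(p, decreasing = TRUE)
  adj <- pmin(1, cummin(p[o] * m / (m:1)))
  adj[order(o)]
}

#' Overrepresentation of term sets within communities
#'
#' For every (community, term) pair passing the size filters, tests whether
#' the term's genes are overrepresented in the community against the
#' universe (all genes of the expression matrix), with a global
#' Benjamini-Hochberg correction across the whole test battery. Term and
#' community gene sets are intersected with the universe before sizing.
#' Defaults follow the GO-term analysis convention: communities of >= 5
#' genes, terms of >= 10 (universe-intersected) genes, adjusted p < 0.005.
#'
#' @param communities Named list community -> gene ids, or a
#'   `community_partition`.
#' @param term_sets Named list term -> gene ids (e.g. from [read_gmt()]).
#' @param universe Character vector of universe genes.
#' @param min_community Minimum community size tested.
#' @param min_term Minimum (intersected) term size tested.
#' @param alpha Adjusted-p significance cutoff.
#' @return data.frame(community_id, term_id, k, K, n, N, p_value,
#'   p_adjusted, significant), ordered by p_adjusted.
#' @export
enrich_communities <- function(communities, term_sets, universe,
                               min_community = 5, min_term = 10,
                               alpha = 0.005) {
  if (inherits(communities, "community_partition"))
    communities <- community_gene_sets(communities)
  universe <- unique(universe)
  N <- length(universe)
  if (N == 0) stopf("empty universe")
  comms <- lapply(communities, intersect, y = universe)
  comms <- comms[lengths(comms) >= min_community]
  terms <- lapply(term_sets, intersect, y = universe)
  terms <- terms[lengths(terms) >= min_term]
  if (length(comms) == 0 || length(terms) == 0)
    return(empty_enrichment())
  grid <- expand.grid(community_id = names(comms), term_id = names(terms),
                      stringsAsFactors = FALSE)
  # deterministic, input-order-invariant test battery
  grid <- grid[order(grid$community_id, grid$term_id), ]
  k <- mapply(function(c, t) length(intersect(comms[[c]], terms[[t]])),
              grid$community_id, grid$term_id)
  K <- lengths(terms)[grid$term_id]
  n <- lengths(comms)[grid$community_id]
  p <- hypergeometric_test(k, K, n, N)
  padj <- benjamini_hochberg(p)
  out <- data.frame(grid, k = k, K = unname(K), n = unname(n), N = N,
                    p_value = p, p_adjusted = padj,
                    significant = padj < alpha, stringsAsFactors = FALSE)
  out <- out[order(out$p_adjusted, out$p_value, out$community_id, out$term_id), ]
  rownames(out) <- NULL
  out
}

empty_enrichment <- function() {
  data.frame(community_id = character(), term_id = character(),
             k = integer(), K = integer(), n = integer(), N = integer(),
             p_value = numeric(), p_adjusted = numeric(),
             significant = logical(), stringsAsFactors = FALSE)
}

#' Overrepresentation of copy-number peak gene sets within communities
#'
#' Same machinery as [enrich_communities()] with the CNA conventions: no
#' size threshold on communities or peaks and adjusted p < 0.05.
#' Amplification and deletion peaks should be tested as separate
#' collections (call once per collection, or pass a named list of
#' collections to get a combined table with a `collection` column).
#'
#' @param communities Named list community -> gene ids, or a partition.
#' @param peak_gene_sets Named list peak -> gene ids (see
#'   [map_peaks_to_genes()]), or a named list of such collections.
#' @param universe Universe gene ids.
#' @param alpha Adjusted-p cutoff.
#' @export
enrich_cna_peaks <- function(communities, peak_gene_sets, universe,
                             alpha = 0.05) {
  is_collection_list <- length(peak_gene_sets) > 0 &&
    all(vapply(peak_gene_sets, function(x) is.list(x) && !is.data.frame(x), TRUE))
  if (is_collection_list) {
    out <- lapply(names(peak_gene_sets), function(cl) {
      r <- enrich_cna_peaks(communities, peak_gene_sets[[cl]], universe, alpha)
      if (nrow(r) > 0) cbind(collection = cl, r) else NULL
    })
    return(do.call(rbind, out) %||% empty_enrichment())
  }
  enrich_communities(communities, peak_gene_sets, universe,
                     min_community = 1, min_term = 1, alpha = alpha)
}
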
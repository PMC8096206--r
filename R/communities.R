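# community detection, partition comparison, assortativity, naming

#' Detect communities in a weighted co-expression network
#'
#' Wraps the four igraph algorithms evaluated in the field (fast greedy,
#' infomap, leading eigenvector, louvain), with dependence scores as link
#' weights. Nodes are ordered lexicographically before detection so
#' order-sensitive algorithms are deterministic under a fixed seed.
#' Disconnected singleton components become their own communities.
#'
#' @param net A `coexpression_network` with positive edge weights.
#' @param algorithm One of `"louvain"` (default; highest modularity in
#'   practice), `"fast_greedy"`, `"infomap"`, `"leading_eigenvector"`.
#' @param seed Integer seed.
#' @return A `community_partition`: list(algorithm, membership (named
#'   integer vector), modularity, seed).
#' @export
detect_communities <- function(net,
                               algorithm = c("louvain", "fast_greedy",
                                             "infomap", "leading_eigenvector"),
                               seed = 1) {
  algorithm <- match.arg(algorithm)
  if (nrow(net$edges) == 0) stopf("network has no edges")
  if (any(net$edges$score <= 0))
    stopf("community detection needs positive weights (got min %.4g); for the pearson measure use absolute values",
          min(net$edges$score))
  g <- network_igraph(net)
  comm <- with_seed(seed, switch(algorithm,
    louvain = igraph::cluster_louvain(g, weights = igraph::E(g)$weight),
    fast_greedy = igraph::cluster_fast_greedy(g, weights = igraph::E(g)$weight),
    infomap = igraph::cluster_infomap(g, e.weights = igraph::E(g)$weight),
    leading_eigenvector = igraph::cluster_leading_eigen(g, weights = igraph::E(g)$weight)))
  membership <- igraph::membership(comm)
  membership <- setNames(as.integer(membership), names(membership))
  structure(list(algorithm = algorithm, membership = membership,
                 modularity = modularity_score(net, membership),
                 seed = seed),
            class = "community_partition")
}

# igraph with vertices in fixed lexicographic order
network_igraph <- function(net) {
  verts <- sort(net$genes)
  e <- as.data.frame(net$edges[, list(gene_a, gene_b, weight = score)])
  igraph::graph_from_data_frame(e, directed = FALSE,
                                vertices = data.frame(name = verts))
}

#' @export
print.community_partition <- function(x, ...) {
  cat(sprintf("<community_partition> %s: %d communities over %d genes, Q = %.4f\n",
              x$algorithm, length(unique(x$membership)), length(x$membership),
              x$modularity))
  invisible(x)
}

#' Weighted Newman-Girvan modularity of a partition
#'
#' `Q = sum_c [ e_c / m - (d_c / 2m)^2 ]` with `e_c` the total weight of
#' edges inside community `c`, `d_c` the summed weighted degree of its
#' nodes, and `m` the total edge weight. The all-in-one-community partition
#' scores exactly 0.
#'
#' @param net A `coexpression_network`.
#' @param membership Named community assignment covering every network gene.
#' @export
modularity_score <- function(net, membership) {
  e <- net$edges
  missing <- setdiff(net$genes, names(membership))
  if (length(missing) > 0)
    stopf("membership misses gene(s): %s", paste(head(missing, 5), collapse = ", "))
  m <- sum(e$score)
  if (m <= 0) stopf("total edge weight must be positive")
  ca <- membership[e$gene_a]
  cb <- membership[e$gene_b]
  e_c <- tapply(e$score[ca == cb], ca[ca == cb], sum)
  deg <- tapply(c(e$score, e$score), membership[c(e$gene_a, e$gene_b)], sum)
  comms <- names(deg)
  ec_full <- setNames(numeric(length(comms)), comms)
  ec_full[names(e_c)] <- e_c
  sum(ec_full / m - (deg / (2 * m))^2)
}

#' Jaccard index between two gene sets
#'
#' `|A intersect B| / |A union B|`; 1 iff the sets are equal and non-empty,
#' 0 iff disjoint. Undefined (error) when both sets are empty.
#'
#' @param a,b Character vectors (treated as sets).
#' @export
jaccard_index <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0) stopf("Jaccard index undefined for two empty sets")
  length(intersect(a, b)) / u
}

#' Best-match Jaccard comparison of two partitions
#'
#' For each community in `partition_a`, finds the community of
#' `partition_b` maximizing the Jaccard index of their gene sets.
#'
#' @param partition_a,partition_b `community_partition` objects.
#' @return data.frame(community_a, size_a, best_match_b, jaccard) with
#'   attribute `fraction_exact` (share of A-communities matched at J = 1).
#' @export
compare_partitions <- function(partition_a, partition_b) {
  sets_a <- community_gene_sets(partition_a)
  sets_b <- community_gene_sets(partition_b)
  rows <- lapply(names(sets_a), function(ca) {
    js <- vapply(sets_b, jaccard_index, 0, a = sets_a[[ca]])
    best <- which.max(js)
    data.frame(community_a = ca, size_a = length(sets_a[[ca]]),
               best_match_b = names(sets_b)[best], jaccard = js[best])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "fraction_exact") <- mean(out$jaccard == 1)
  out
}

#' Gene sets of a partition's communities
#' @param partition A `community_partition` (or named membership vector).
#' @return Named list community_id -> gene ids.
#' @export
community_gene_sets <- function(partition) {
  mem <- if (inherits(partition, "community_partition")) partition$membership else partition
  split(names(mem), mem)
}

#' Chromosomal assortativity of a set of edges
#'
#' `(cis links - trans links) / total links`: 1 iff every internal edge is
#' intra-chromosomal (the definition of a cis community), -1 iff all are
#' inter-chromosomal. Exact integer counting; `NA` when no edges exist.
#'
#' @param edges data.frame with columns gene_a, gene_b.
#' @param annotation Gene annotation.
#' @export
chromosomal_assortativity <- function(edges, annotation) {
  if (nrow(edges) == 0) return(NA_real_)
  chrom <- setNames(annotation$chrom, annotation$gene_id)
  n_cis <- sum(chrom[edges$gene_a] == chrom[edges$gene_b])
  (2 * n_cis - nrow(edges)) / nrow(edges)
}

#' Expression (differential-expression sign) assortativity
#'
#' `(same-sign links - mixed-sign links) / total links` using the sign of
#' the log2 fold change to classify genes as over- or under-expressed.
#' Genes failing the DE thresholds still contribute their LFC sign (the
#' definition uses the sign, not the significance call); `strict = TRUE`
#' restricts to genes with a significant call, dropping edges touching
#' unclassified genes.
#'
#' @param edges data.frame with columns gene_a, gene_b.
#' @param de DE result table from [differential_expression()].
#' @param strict Only count edges between significantly called genes.
#' @export
expression_assortativity <- function(edges, de, strict = FALSE) {
  if (nrow(edges) == 0) return(NA_real_)
  sgn <- setNames(sign(de$lfc), de$gene_id)
  if (strict) {
    ok <- de$gene_id[de$call != "unchanged"]
    keep <- edges$gene_a %in% ok & edges$gene_b %in% ok
    edges <- edges[keep, , drop = FALSE]
    if (nrow(edges) == 0) return(NA_real_)
  }
  same <- sgn[edges$gene_a] == sgn[edges$gene_b]
  (2 * sum(same) - nrow(edges)) / nrow(edges)
}

#' Name a community by its highest-PageRank member
#'
#' PageRank (damping 0.85) on the community's induced weighted subgraph;
#' ties within 1e-10 are broken lexicographically so the name is
#' deterministic (a two-gene community is named after its first gene).
#'
#' @param genes Community gene ids.
#' @param net The network the community came from.
#' @export
name_community <- function(genes, net) {
  e <- net$edges[gene_a %in% genes & gene_b %in% genes]
  if (nrow(e) == 0) return(sort(genes)[1])
  sub <- new_network(e, net$score_kind, net$n_samples_used, genes = sort(genes))
  g <- network_igraph(sub)
  pr <- igraph::page_rank(g, damping = 0.85,
                          weights = igraph::E(g)$weight)$vector
  top <- names(pr)[pr >= max(pr) - 1e-10]
  sort(top)[1]
}

#' Per-community profiles: size, cis/trans links, assortativities, name
#'
#' The unit of all downstream annotation. For each community: gene count,
#' internal cis/trans edge counts, chromosomal assortativity `ass_chr`
#' (cis-classified iff exactly 1), expression assortativity `ass_dge` (when
#' DE results are given), PageRank name, and the community's additive
#' contribution to the partition modularity.
#'
#' @param partition A `community_partition`.
#' @param net The underlying `coexpression_network` (cis/trans labeled).
#' @param annotation Gene annotation.
#' @param de Optional DE table for `ass_dge`.
#' @return data.frame, one row per community, with a `genes` list-column.
#' @export
community_profiles <- function(partition, net, annotation, de = NULL) {
  sets <- community_gene_sets(partition)
  e <- net$edges
  m_tot <- sum(e$score)
  mem <- partition$membership
  deg <- tapply(c(e$score, e$score), mem[c(e$gene_a, e$gene_b)], sum)
  rows <- lapply(names(sets), function(cid) {
    genes <- sets[[cid]]
    ie <- e[gene_a %in% genes & gene_b %in% genes]
    n_cis <- sum(ie$cis)
    n_trans <- nrow(ie) - n_cis
    qc <- sum(ie$score) / m_tot - (deg[[cid]] / (2 * m_tot))^2
    data.frame(community_id = cid,
               name = name_community(genes, net),
               size = length(genes),
               n_cis = n_cis, n_trans = n_trans,
               ass_chr = if (nrow(ie) > 0) (n_cis - n_trans) / nrow(ie) else NA_real_,
               ass_dge = if (is.null(de)) NA_real_ else expression_assortativity(ie, de),
               modularity_contribution = qc,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$genes <- unname(sets)
  rownames(out) <- NULL
  out
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items;
#' 1 for identical partitions, ~0 for independent ones.
#'
#' @param a,b Label vectors of equal length.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  maxidx <- (sum_a + sum_b) / 2
  if (maxidx == expected) return(1)
  (sum_ij - expected) / (maxidx - expected)
}
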
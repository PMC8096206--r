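# community detection, modularity, Jaccard, assortativity, naming

test_that("disconnected cliques and single edges form obvious communities", {
  ann <- two_chrom_annotation()
  cl1 <- clique_edges(sprintf("a%02d", 1:5))
  cl2 <- clique_edges(sprintf("b%02d", 1:5))
  net <- toy_network(rbind(cl1, cl2))
  part <- detect_communities(net, "louvain", seed = 1)
  sets <- community_gene_sets(part)
  expect_length(sets, 2)
  expect_true(any(vapply(sets, setequal, TRUE, y = sprintf("a%02d", 1:5))))

  single <- toy_network(data.frame(gene_a = "g01", gene_b = "g02", score = 2))
  p1 <- detect_communities(single, "louvain", seed = 1)
  expect_length(community_gene_sets(p1), 1)
  expect_setequal(names(p1$membership), c("g01", "g02"))
})

test_that("all four algorithms run and agree on the planted split", {
  cl1 <- clique_edges(sprintf("a%02d", 1:6))
  cl2 <- clique_edges(sprintf("b%02d", 1:6))
  bridge <- data.frame(gene_a = "a01", gene_b = "b01", score = 0.01)
  net <- toy_network(rbind(cl1, cl2, bridge))
  for (alg in c("louvain", "fast_greedy", "infomap", "leading_eigenvector")) {
    part <- detect_communities(net, alg, seed = 3)
    sets <- community_gene_sets(part)
    expect_length(sets, 2)
    expect_equal(part$algorithm, alg)
    # deterministic under the seed
    part2 <- detect_communities(net, alg, seed = 3)
    expect_identical(part$membership, part2$membership)
  }
  expect_error(detect_communities(net, "walktrap"), "arg")
})

test_that("modularity matches closed forms", {
  # everything in one community -> exactly 0
  net <- toy_network(clique_edges(sprintf("g%02d", 1:5), weight = 2))
  one <- setNames(rep(1L, 5), sprintf("g%02d", 1:5))
  expect_equal(modularity_score(net, one), 0)

  # two disconnected equal-weight cliques split correctly -> 1/2
  two <- toy_network(rbind(clique_edges(sprintf("a%02d", 1:4)),
                           clique_edges(sprintf("b%02d", 1:4))))
  mem <- setNames(rep(1:2, each = 4), c(sprintf("a%02d", 1:4), sprintf("b%02d", 1:4)))
  expect_equal(modularity_score(two, mem), 0.5)
})

test_that("modularity equals the brute-force double sum on random graphs", {
  set.seed(8)
  for (trial in 1:12) {
    n <- sample(5:30, 1)
    genes <- sprintf("n%02d", 1:n)
    e <- clique_edges(genes)
    keep <- runif(nrow(e)) < 0.4
    if (sum(keep) < 2) next
    e <- e[keep, ]
    e$score <- runif(nrow(e), 0.1, 3)
    nodes <- sort(unique(c(e$gene_a, e$gene_b)))
    mem <- setNames(sample(1:4, length(nodes), replace = TRUE), nodes)
    net <- toy_network(e)
    expect_equal(modularity_score(net, mem), modularity_oracle(e, mem),
                 tolerance = 1e-12)
  }
})

test_that("random assignments on a random graph score near zero", {
  set.seed(9)
  genes <- sprintf("n%03d", 1:200)
  e <- clique_edges(genes)
  e <- e[runif(nrow(e)) < 0.03, ]
  nodes <- sort(unique(c(e$gene_a, e$gene_b)))
  net <- toy_network(e)
  for (r in 1:3) {
    mem <- setNames(sample(1:5, length(nodes), replace = TRUE), nodes)
    expect_lt(abs(modularity_score(net, mem)), 0.1)
  }
})

test_that("jaccard index covers the documented cases", {
  expect_equal(jaccard_index(c("a", "b"), c("a", "b")), 1)
  expect_equal(jaccard_index(c("a", "b"), c("c", "d")), 0)
  expect_equal(jaccard_index("a", character(0)), 0)
  expect_error(jaccard_index(character(0), character(0)), "empty")
  # the 11/12 overlap regime of the shared immune-response community
  a <- sprintf("h%02d", 1:11)
  b <- c(a, "CD74")  # same 11 genes plus one extra member
  expect_equal(jaccard_index(a, b), 11 / 12)
  expect_equal(jaccard_index(b, a), 11 / 12)
})

test_that("partition comparison reports best-match Jaccard", {
  mem_a <- setNames(c(1, 1, 1, 1, 2, 2), sprintf("g%02d", 1:6))
  part_a <- structure(list(membership = mem_a), class = "community_partition")
  cmp_same <- compare_partitions(part_a, part_a)
  expect_true(all(cmp_same$jaccard == 1))
  expect_equal(attr(cmp_same, "fraction_exact"), 1)

  # one community split in half -> best match 0.5
  mem_b <- setNames(c(1, 1, 3, 3, 2, 2), sprintf("g%02d", 1:6))
  part_b <- structure(list(membership = mem_b), class = "community_partition")
  cmp <- compare_partitions(part_a, part_b)
  expect_equal(cmp$jaccard[cmp$community_a == "1"], 0.5)
})

test_that("assortativities are exact integer counting", {
  ann <- two_chrom_annotation()
  # all cis (chr1 clique)
  expect_equal(chromosomal_assortativity(clique_edges(c("g01", "g02", "g03")), ann), 1)
  # all trans
  e_trans <- data.frame(gene_a = c("g01", "g02"), gene_b = c("g04", "g05"))
  expect_equal(chromosomal_assortativity(e_trans, ann), -1)
  # 3 cis + 1 trans -> (3 - 1) / 4
  e_mix <- data.frame(gene_a = c("g01", "g01", "g02", "g01"),
                      gene_b = c("g02", "g03", "g03", "g04"))
  expect_equal(chromosomal_assortativity(e_mix, ann), 0.5)
  expect_true(is.na(chromosomal_assortativity(e_mix[0, ], ann)))

  de <- data.frame(gene_id = sprintf("g%02d", 1:6),
                   lfc = c(1, 2, 0.5, -1, -2, 3),
                   call = factor(rep("over", 6),
                                 levels = c("over", "under", "unchanged")))
  # all overexpressed -> 1
  expect_equal(expression_assortativity(clique_edges(c("g01", "g02", "g03")), de), 1)
  # perfect bipartite over/under -> -1
  e_bip <- data.frame(gene_a = c("g01", "g01", "g02"), gene_b = c("g04", "g05", "g04"))
  expect_equal(expression_assortativity(e_bip, de), -1)
  # 2 same-sign + 2 mixed -> 0
  e_half <- data.frame(gene_a = c("g01", "g01", "g01", "g02"),
                       gene_b = c("g02", "g03", "g04", "g05"))
  expect_equal(expression_assortativity(e_half, de), 0)
})

test_that("community naming follows PageRank with lexicographic ties", {
  # star: hub must win; verify against a power-iteration oracle
  star <- data.frame(gene_a = rep("hub", 5),
                     gene_b = sprintf("leaf%d", 1:5), score = 1)
  net <- toy_network(star)
  expect_equal(name_community(c("hub", sprintf("leaf%d", 1:5)), net), "hub")

  g <- igraph::graph_from_data_frame(
    data.frame(from = star$gene_a, to = star$gene_b), directed = FALSE)
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  P <- A / rowSums(A)
  v <- rep(1 / nrow(A), nrow(A))
  for (i in 1:200) v <- 0.15 / nrow(A) + 0.85 * as.vector(t(P) %*% v)
  pr_oracle <- setNames(v, rownames(A))
  expect_equal(names(which.max(pr_oracle)), "hub")

  # symmetric two-gene community: lexicographically first gene
  two <- toy_network(data.frame(gene_a = "zeta", gene_b = "alpha", score = 1))
  expect_equal(name_community(c("zeta", "alpha"), two), "alpha")
  expect_identical(name_community(c("zeta", "alpha"), two),
                   name_community(c("alpha", "zeta"), two))
})

test_that("community profiles are internally consistent", {
  ann <- two_chrom_annotation()
  e <- rbind(clique_edges(c("g01", "g02", "g03")),
             clique_edges(c("g04", "g05", "g06")),
             data.frame(gene_a = "g01", gene_b = "g04", score = 0.01))
  net <- toy_network(e, ann)
  part <- detect_communities(net, "louvain", seed = 2)
  de <- data.frame(gene_id = sprintf("g%02d", 1:6), lfc = c(1, 1, 1, -1, -1, 1),
                   call = factor(rep("over", 6), levels = c("over", "under", "unchanged")))
  prof <- community_profiles(part, net, ann, de)
  expect_setequal(unlist(prof$genes), net$genes)
  internal <- sum(prof$n_cis + prof$n_trans)
  expect_equal(internal, nrow(e) - 1)  # only the bridge is between-community
  expect_true(all(prof$ass_chr %in% c(-1, 1) | is.na(prof$ass_chr)))
  # modularity contributions sum to the partition modularity
  expect_equal(sum(prof$modularity_contribution), part$modularity,
               tolerance = 1e-12)
})

test_that("adjusted Rand index behaves at its anchors", {
  a <- rep(1:3, each = 10)
  expect_equal(adjusted_rand_index(a, a), 1)
  set.seed(10)
  b <- sample(1:3, 30, replace = TRUE)
  expect_equal(adjusted_rand_index(a, b), adjusted_rand_index(b, a))
  expect_lt(abs(adjusted_rand_index(a, b)), 0.35)
})
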
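# interval logic: promoters, peak mapping, CTCF classes, boundaries, regulons

test_that("promoter windows are strand-aware and clipped", {
  ann <- fixture_annotation(data.frame(
    gene_id = c("plus", "minus", "near0"),
    chrom = "chr1",
    start = c(10000, 50000, 300),
    end = c(12000, 10000 + 40000, 900),
    strand = c("+", "-", "+")))
  ann$end[2] <- 10000  # minus-strand gene ending at 10,000
  ann$start[2] <- 8000
  w <- promoter_window(1000, 100)
  p <- promoter_of(ann, w)
  expect_equal(unlist(p[1, c("start", "end")], use.names = FALSE), c(9000, 10100))
  expect_equal(unlist(p[2, c("start", "end")], use.names = FALSE), c(9900, 11000))
  expect_equal(p$start[3], 0)  # clipped at the chromosome origin
  expect_error(promoter_window(0, 0), "degenerate")

  # strand flip mirrors the promoter around the gene exactly
  flipped <- ann
  flipped$strand <- ifelse(ann$strand == "+", "-", "+")
  pf <- promoter_of(flipped, w)
  expect_equal(pf$start[1], ann$end[1] - w$downstream)
  expect_equal(pf$end[1], ann$end[1] + w$upstream)
})

test_that("promoter presets expose the three published windows", {
  expect_equal(promoter_preset("regulon")[c("upstream", "downstream")],
               list(upstream = 1000, downstream = 100))
  expect_equal(promoter_preset("narrow")[c("upstream", "downstream")],
               list(upstream = 100, downstream = 10))
  expect_equal(promoter_preset("ctcf")[c("upstream", "downstream")],
               list(upstream = 1000, downstream = 500))
})

test_that("fully-contained peak mapping follows the boundary rule", {
  ann <- fixture_annotation(data.frame(
    gene_id = c("g1", "g2", "g3"),
    chrom = "chr1", start = c(1000, 3000, 8000), end = c(2000, 4000, 9000)))
  peaks <- data.frame(chrom = "chr1",
                      start = c(1000, 1100, 500),
                      end = c(2000, 2000, 4500),
                      name = c("exact", "partial", "span12"),
                      score = 0, strand = ".")
  maps <- map_peaks_to_genes(peaks, ann, "fully_contained")
  expect_equal(maps$exact, "g1")          # peak identical to the gene span
  expect_length(maps$partial, 0)          # 90% coverage is not containment
  expect_setequal(maps$span12, c("g1", "g2"))
  ov <- map_peaks_to_genes(peaks, ann, "overlap")
  expect_setequal(ov$partial, "g1")
  # containment is always a subset of overlap
  for (nm in names(maps)) expect_true(all(maps[[nm]] %in% ov[[nm]]))
  bad <- peaks; bad$chrom <- "1"
  expect_error(map_peaks_to_genes(bad, ann), "chromosome")
})

test_that("interval operations agree with a per-base brute-force oracle", {
  set.seed(14)
  L <- 1e5
  ann <- fixture_annotation(data.frame(
    gene_id = sprintf("g%02d", 1:8),
    chrom = "chr1",
    start = seq(5000, 75000, by = 10000),
    end = seq(5000, 75000, by = 10000) + 4000,
    strand = rep(c("+", "-"), 4)),
    chrom_lengths = c(chr1 = L))
  peaks <- data.frame(chrom = "chr1",
                      start = sort(sample(0:(L - 600), 40)),
                      end = NA, name = sprintf("p%02d", 1:40),
                      score = 0, strand = ".")
  peaks$end <- peaks$start + sample(200:600, 40, replace = TRUE)

  # per-base occupancy masks
  w <- promoter_preset("ctcf")
  proms <- promoter_of(ann, w)
  mask_prom <- logical(L); mask_body <- logical(L)
  for (i in seq_len(nrow(proms)))
    mask_prom[(proms$start[i] + 1):proms$end[i]] <- TRUE
  for (i in seq_len(nrow(ann)))
    mask_body[(ann$start[i] + 1):ann$end[i]] <- TRUE

  cls <- classify_ctcf_sites(peaks, ann, w)
  mids <- floor((peaks$start + peaks$end) / 2)
  expected <- ifelse(mask_prom[mids + 1], "promoter",
                     ifelse(mask_body[mids + 1], "gene_body", "intergenic"))
  expect_equal(as.character(cls$class), expected)
  expect_equal(sum(cls$counts), nrow(peaks))

  # containment agrees with the per-base mask too
  maps <- map_peaks_to_genes(peaks, ann, "fully_contained")
  for (i in seq_len(nrow(peaks))) {
    inside <- vapply(seq_len(nrow(ann)), function(j)
      peaks$start[i] <= ann$start[j] && ann$end[j] <= peaks$end[i], TRUE)
    expect_setequal(maps[[peaks$name[i]]], ann$gene_id[inside])
  }
})

test_that("CTCF classification partitions a constructed track as 3/4/5", {
  ann <- fixture_annotation(data.frame(
    gene_id = c("a", "b"), chrom = "chr1",
    start = c(20000, 60000), end = c(30000, 70000), strand = c("+", "+")))
  w <- promoter_preset("ctcf")  # promoters [19000,20500) and [59000,60500)
  mk <- function(mids) data.frame(chrom = "chr1", start = mids - 50,
                                  end = mids + 50, name = sprintf("m%d", mids),
                                  score = 0, strand = ".")
  peaks <- rbind(mk(c(19500, 19900, 59800)),          # 3 promoter
                 mk(c(25000, 27000, 29000, 65000)),   # 4 gene body
                 mk(c(5000, 40000, 45000, 80000, 90000)))  # 5 intergenic
  cls <- classify_ctcf_sites(peaks, ann, w)
  expect_equal(unname(cls$counts), c(3L, 4L, 5L))
})

test_that("boundary analysis compares flanks against interior tiling", {
  ann <- fixture_annotation(data.frame(
    gene_id = sprintf("c%d", 1:4), chrom = "chr2",
    start = c(100000, 150000, 200000, 240000),
    end = c(110000, 160000, 210000, 250000), strand = "+"))
  flank <- 5e4
  # peaks only in the two flank windows -> excess
  peaks <- data.frame(chrom = "chr2",
                      start = c(60000, 80000, 260000),
                      end = c(60500, 80500, 260500),
                      name = sprintf("p%d", 1:3), score = 0, strand = ".")
  res <- ctcf_boundary_analysis(list(comm = sprintf("c%d", 1:4)), peaks, ann,
                                flank = flank)
  expect_equal(res$boundary_count, 3)
  expect_equal(res$n_interior_windows, 3)  # span 150k -> three 50k windows
  expect_equal(res$mean_interior_count, 0)
  expect_true(res$boundary_excess)
  expect_true(res$has_peaks)

  # interior-heavy placement -> no excess
  peaks2 <- data.frame(chrom = "chr2",
                       start = seq(105000, 245000, by = 10000),
                       end = seq(105000, 245000, by = 10000) + 400,
                       name = sprintf("q%d", 1:15), score = 0, strand = ".")
  res2 <- ctcf_boundary_analysis(list(comm = sprintf("c%d", 1:4)), peaks2, ann,
                                 flank = flank)
  expect_false(res2$boundary_excess)

  # a multi-chromosome community is not cis
  ann2 <- rbind(ann, fixture_annotation(data.frame(
    gene_id = "other", chrom = "chr3", start = 1000, end = 2000, strand = "+")))
  expect_error(ctcf_boundary_analysis(list(x = c("c1", "other")), peaks, ann2),
               "not cis")
})

test_that("regulatory degree separates bound and unbound TF patterns", {
  ann <- fixture_annotation(data.frame(
    gene_id = c("tfA", "tfB", "x1", "x2", "x3"),
    chrom = "chr1",
    start = c(1e4, 2e4, 3e4, 4e4, 5e4),
    end = c(1e4, 2e4, 3e4, 4e4, 5e4) + 2000,
    strand = "+"))
  comm <- c("tfA", "tfB", "x1", "x2", "x3")
  e <- rbind(data.frame(gene_a = "tfA", gene_b = c("x1", "x2", "x3"), score = 1),
             data.frame(gene_a = "tfB", gene_b = c("x1", "x2"), score = 1))
  net <- toy_network(e)
  w <- promoter_window()
  prom <- promoter_of(ann, w)
  site_for <- function(g) {
    r <- prom[prom$name == paste0(g, "_prom"), ]
    data.frame(target = g, chrom = r$chrom, site_start = r$start + 5,
               site_end = r$start + 20)
  }
  regulons <- list(
    tfA = do.call(rbind, lapply(c("x1", "x2", "x3"), site_for)),  # fully bound
    tfB = data.frame(target = character(), chrom = character(),
                     site_start = numeric(), site_end = numeric()))
  out <- annotate_regulatory_edges(comm, net, regulons, ann, w)
  a <- out[out$tf == "tfA", ]
  expect_equal(a$regulatory_degree, a$total_degree)  # whole neighborhood bound
  b <- out[out$tf == "tfB", ]
  expect_equal(b$regulatory_degree, 0)               # no binding records
  expect_equal(b$total_degree, 2)
  # no TFs in the community -> empty table
  empty <- annotate_regulatory_edges(c("x1", "x2"), net, regulons["tfA"], ann, w)
  expect_equal(nrow(empty), 0)
})

test_that("BED round-trip preserves half-open coordinates", {
  tr <- data.frame(chrom = c("chr1", "chr2"), start = c(100, 5000),
                   end = c(600, 5400), name = c("a", "b"), score = c(0, 1),
                   strand = c("+", "."))
  f <- tempfile(fileext = ".bed")
  write_bed(tr, f)
  back <- read_bed(f)
  expect_equal(back$start, tr$start)
  expect_equal(back$end, tr$end)
  expect_equal(back$name, tr$name)
})

test_that("GMT round-trips", {
  terms <- list(T1 = c("a", "b", "c"), T2 = c("d", "e"))
  f <- tempfile(fileext = ".gmt")
  write_gmt(terms, f)
  expect_equal(read_gmt(f), terms)
})
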
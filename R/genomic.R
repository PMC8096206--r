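# interval-based annotation: promoters, peak->gene mapping, CTCF classes,
# cis-community boundary analysis, TF regulon edges

#' Promoter window definition
#'
#' Anchored at the transcription start site, strand-aware. The literature
#' uses several widths; three presets are provided instead of silently
#' merging them: `"regulon"` (1,000 bp up / 100 bp down, the TF-regulon
#' convention), `"narrow"` (100 / 10, the compact TSS window), `"ctcf"`
#' (1,000 / 500, the CTCF classification window).
#'
#' @param upstream,downstream Non-negative widths in bp (not both 0).
#' @export
promoter_window <- function(upstream = 1000, downstream = 100) {
  stopifnot(upstream >= 0, downstream >= 0)
  if (upstream == 0 && downstream == 0)
    stopf("degenerate promoter window: upstream and downstream are both 0")
  structure(list(upstream = upstream, downstream = downstream),
            class = "promoter_window")
}

#' @rdname promoter_window
#' @param preset One of `"regulon"`, `"narrow"`, `"ctcf"`.
#' @export
promoter_preset <- function(preset = c("regulon", "narrow", "ctcf")) {
  switch(match.arg(preset),
         regulon = promoter_window(1000, 100),
         narrow = promoter_window(100, 10),
         ctcf = promoter_window(1000, 500))
}

#' Promoter intervals for annotated genes
#'
#' Strand-aware: a + strand gene anchors at its start
#' (`[start - up, start + down)`), a - strand gene at its end with the
#' directions mirrored (`[end - down, end + up)`). Clipped at 0 and, when
#' chromosome lengths are available, at the chromosome end.
#'
#' @param annotation Gene annotation rows (0-based half-open).
#' @param window A [promoter_window()].
#' @param chrom_lengths Optional named vector for right clipping (defaults
#'   to the annotation's `chrom_lengths` attribute, if present).
#' @return Track data.frame (chrom, start, end, name, score, strand).
#' @export
promoter_of <- function(annotation, window = promoter_window(),
                        chrom_lengths = attr(annotation, "chrom_lengths")) {
  stopifnot(inherits(window, "promoter_window"))
  plus <- annotation$strand == "+"
  start <- ifelse(plus, annotation$start - window$upstream,
                  annotation$end - window$downstream)
  end <- ifelse(plus, annotation$start + window$downstream,
                annotation$end + window$upstream)
  start <- pmax(0, start)
  if (!is.null(chrom_lengths))
    end <- pmin(end, chrom_lengths[annotation$chrom])
  data.frame(chrom = annotation$chrom, start = start, end = unname(end),
             name = paste0(annotation$gene_id, "_prom"), score = 0,
             strand = annotation$strand, stringsAsFactors = FALSE)
}

# dialect check shared by the interval operations
check_chrom_dialect <- function(track, annotation) {
  bad <- setdiff(unique(track$chrom), unique(annotation$chrom))
  if (length(bad) > 0)
    stopf("chromosome name(s) in track but not annotation: %s",
          paste(bad, collapse = ", "))
  invisible(TRUE)
}

#' Map peaks to the genes they cover
#'
#' `fully_contained` (the copy-number-peak remapping rule) reports a gene
#' for a peak iff the peak spans the gene entirely
#' (`peak.start <= gene.start` and `gene.end <= peak.end`, same
#' chromosome); `overlap` reports any overlap. The fully-contained result
#' is always a subset of the overlap result.
#'
#' @param peaks Track data.frame (0-based half-open).
#' @param annotation Gene annotation.
#' @param mode `"fully_contained"` or `"overlap"`.
#' @return Named list peak name -> character vector of gene ids (peaks with
#'   no genes map to empty vectors).
#' @export
map_peaks_to_genes <- function(peaks, annotation,
                               mode = c("fully_contained", "overlap")) {
  mode <- match.arg(mode)
  check_chrom_dialect(peaks, annotation)
  out <- setNames(vector("list", nrow(peaks)), peaks$name)
  for (i in seq_along(out)) out[[i]] <- character(0)
  if (nrow(peaks) == 0 || nrow(annotation) == 0) return(out)
  gr_peaks <- track_to_granges(peaks)
  gr_genes <- GenomicRanges::GRanges(
    seqnames = annotation$chrom,
    ranges = IRanges::IRanges(start = annotation$start + 1, end = annotation$end))
  type <- if (mode == "fully_contained") "within" else "any"
  ov <- GenomicRanges::findOverlaps(gr_genes, gr_peaks, type = type,
                                    ignore.strand = TRUE)
  hits <- split(annotation$gene_id[S4Vectors::queryHits(ov)],
                peaks$name[S4Vectors::subjectHits(ov)])
  out[names(hits)] <- hits
  out
}

peak_midpoints <- function(track) floor((track$start + track$end) / 2)

#' Classify peaks as promoter / gene body / intergenic
#'
#' Each peak is assigned exactly one class by the position of its midpoint,
#' with precedence promoter > gene body > intergenic, so the three counts
#' always sum to the total peak count.
#'
#' @param peaks Track data.frame.
#' @param annotation Gene annotation.
#' @param window Promoter window (default the CTCF preset, 1,000 up /
#'   500 down).
#' @return list(counts = named integer vector, class = per-peak factor).
#' @export
classify_ctcf_sites <- function(peaks, annotation,
                                window = promoter_preset("ctcf")) {
  check_chrom_dialect(peaks, annotation)
  mids <- peak_midpoints(peaks)
  proms <- promoter_of(annotation, window)
  in_any <- function(track) {
    if (nrow(peaks) == 0) return(logical(0))
    hit <- logical(nrow(peaks))
    for (ch in unique(track$chrom)) {
      sel <- peaks$chrom == ch
      if (!any(sel)) next
      iv <- track[track$chrom == ch, , drop = FALSE]
      ir <- IRanges::IRanges(start = iv$start + 1, end = iv$end)
      q <- IRanges::IRanges(start = mids[sel] + 1, width = 1)
      hit[sel] <- IRanges::overlapsAny(q, ir)
    }
    hit
  }
  in_prom <- in_any(proms)
  in_body <- in_any(annotation[, c("chrom", "start", "end")])
  cls <- ifelse(in_prom, "promoter", ifelse(in_body, "gene_body", "intergenic"))
  cls <- factor(cls, levels = c("promoter", "gene_body", "intergenic"))
  list(counts = setNames(as.integer(table(cls)), levels(cls)), class = cls)
}

#' CTCF boundary analysis for cis communities
#'
#' For each cis community (all genes on one chromosome): counts peaks whose
#' midpoints fall in two `flank`-sized windows just outside the community
#' span (before the first gene, after the last), and compares against the
#' mean count over non-overlapping `flank`-sized windows tiling the
#' interior span (a trailing partial window is dropped).
#' `boundary_excess` is true when the boundary count strictly exceeds the
#' interior mean. Communities with no associated peaks (none in flanks or
#' span) are flagged by `has_peaks = FALSE`.
#'
#' @param communities Named list community -> gene ids (cis communities).
#' @param peaks Track data.frame (e.g. CTCF ChIP-seq peaks).
#' @param annotation Gene annotation.
#' @param flank Window width in bp (default 50,000).
#' @return data.frame(community_id, chrom, span_start, span_end,
#'   boundary_count, n_interior_windows, mean_interior_count,
#'   boundary_excess, has_peaks).
#' @export
ctcf_boundary_analysis <- function(communities, peaks, annotation,
                                   flank = 5e4) {
  check_chrom_dialect(peaks, annotation)
  mids <- peak_midpoints(peaks)
  rows <- lapply(names(communities), function(cid) {
    genes <- communities[[cid]]
    ann <- annotation[annotation$gene_id %in% genes, , drop = FALSE]
    if (nrow(ann) == 0) stopf("community %s has no annotated genes", cid)
    if (length(unique(ann$chrom)) > 1)
      stopf("community %s spans several chromosomes: not cis", cid)
    ch <- ann$chrom[1]
    span <- c(min(ann$start), max(ann$end))
    m <- mids[peaks$chrom == ch]
    count_in <- function(lo, hi) sum(m >= lo & m < hi)
    boundary <- count_in(max(0, span[1] - flank), span[1]) +
      count_in(span[2], span[2] + flank)
    n_win <- floor((span[2] - span[1]) / flank)
    interior <- if (n_win > 0)
      vapply(seq_len(n_win) - 1,
             function(w) count_in(span[1] + w * flank, span[1] + (w + 1) * flank),
             integer(1))
    else integer(0)
    mean_interior <- if (n_win > 0) mean(interior) else 0
    data.frame(community_id = cid, chrom = ch,
               span_start = span[1], span_end = span[2],
               boundary_count = boundary, n_interior_windows = n_win,
               mean_interior_count = mean_interior,
               boundary_excess = boundary > mean_interior,
               has_peaks = (boundary + sum(interior) +
                              count_in(span[1], span[2])) > 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Regulatory edges of transcription factors inside a community
#'
#' For each regulon TF that is itself a community member: its total degree
#' inside the community, and how many of those neighbors carry at least one
#' binding site of that TF overlapping their promoter window (the
#' regulatory degree). A TF whose whole neighborhood is bound is the
#' FOXM1-style pattern; a TF with no binding records scores 0.
#'
#' @param genes Community gene ids.
#' @param net The `coexpression_network` the community came from.
#' @param regulons Regulon object from [generate_regulons()] /
#'   [read_regulons()] (or its `regulons` element).
#' @param annotation Gene annotation.
#' @param window Promoter window used to validate binding sites.
#' @return data.frame(tf, total_degree, regulatory_degree, targets).
#' @export
annotate_regulatory_edges <- function(genes, net, regulons, annotation,
                                      window = promoter_window()) {
  regs <- if (!is.null(regulons$regulons)) regulons$regulons else regulons
  tfs <- sort(intersect(genes, names(regs)))
  out <- data.frame(tf = character(), total_degree = integer(),
                    regulatory_degree = integer(), targets = character(),
                    stringsAsFactors = FALSE)
  if (length(tfs) == 0) return(out)
  e <- net$edges[gene_a %in% genes & gene_b %in% genes]
  proms <- promoter_of(annotation, window)
  rownames(proms) <- annotation$gene_id
  for (tf in tfs) {
    nbrs <- sort(unique(c(e$gene_b[e$gene_a == tf], e$gene_a[e$gene_b == tf])))
    sites <- regs[[tf]]
    bound <- vapply(nbrs, function(g) {
      s <- sites[sites$target == g, , drop = FALSE]
      if (nrow(s) == 0) return(FALSE)
      p <- proms[g, ]
      any(s$chrom == p$chrom & s$site_start < p$end & s$site_end > p$start)
    }, logical(1))
    out <- rbind(out, data.frame(
      tf = tf, total_degree = length(nbrs),
      regulatory_degree = sum(bound),
      targets = paste(nbrs[bound], collapse = ","),
      stringsAsFactors = FALSE))
  }
  out
}
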
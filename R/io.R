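# readers/writers for the on-disk formats: expression & phenotype TSV,
# annotation TSV (1-based inclusive on disk, 0-based half-open in memory),
# BED6 peak tracks (via rtracklayer), GMT term sets, regulon TSV, edge TSV

#' Write / read an expression study as TSV
#'
#' Expression TSV: genes in rows, first column `gene_id`, samples in
#' columns. Phenotype TSV: columns `sample`, `group`.
#'
#' @param study An `expression_study`.
#' @param expr_path,pheno_path Output paths.
#' @export
write_expression <- function(study, expr_path, pheno_path) {
  df <- data.frame(gene_id = study$gene_ids, study$values, check.names = FALSE)
  write.table(df, expr_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(sample = study$sample_ids,
                         group = as.character(study$groups)),
              pheno_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(expr_path, pheno_path))
}

#' @rdname write_expression
#' @param check_groups Require at least two samples per group.
#' @export
read_expression <- function(expr_path, pheno_path, check_groups = TRUE) {
  df <- read.table(expr_path, header = TRUE, sep = "\t", check.names = FALSE)
  if (anyDuplicated(df$gene_id)) stopf("duplicate gene ids in %s", expr_path)
  vals <- as.matrix(df[, -1, drop = FALSE])
  rownames(vals) <- df$gene_id
  if (anyNA(vals)) stopf("missing values in %s", expr_path)
  ph <- read.table(pheno_path, header = TRUE, sep = "\t")
  if (!all(colnames(vals) %in% ph$sample))
    stopf("samples missing from phenotype table: %s",
          paste(setdiff(colnames(vals), ph$sample), collapse = ", "))
  groups <- factor(ph$group[match(colnames(vals), ph$sample)])
  names(groups) <- colnames(vals)
  if (check_groups && any(table(groups) < 2))
    stopf("each group needs at least 2 samples")
  structure(list(values = vals, gene_ids = rownames(vals),
                 sample_ids = colnames(vals), groups = groups),
            class = "expression_study")
}

#' Write / read gene annotation TSV (1-based inclusive on disk)
#'
#' In memory the package keeps 0-based half-open intervals; the TSV is
#' written GTF-like, 1-based inclusive, flagged by a header comment line.
#'
#' @param annotation Annotation data.frame.
#' @param path File path.
#' @export
write_annotation <- function(annotation, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# coordinates: 1-based inclusive", con)
  out <- data.frame(gene_id = annotation$gene_id, chrom = annotation$chrom,
                    start = annotation$start + 1, end = annotation$end,
                    strand = annotation$strand)
  clens <- attr(annotation, "chrom_lengths")
  if (!is.null(clens))
    writeLines(paste0("# chrom_lengths: ",
                      paste(sprintf("%s=%.0f", names(clens), clens), collapse = ",")), con)
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_annotation
#' @export
read_annotation <- function(path) {
  hdr <- readLines(path, n = 5)
  cm <- grep("^# chrom_lengths:", hdr, value = TRUE)
  ann <- read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  ann$start <- ann$start - 1  # back to 0-based half-open
  ann$chrom <- normalize_chroms(ann$chrom)
  rownames(ann) <- ann$gene_id
  if (length(cm) == 1) {
    kv <- strsplit(strsplit(sub("^# chrom_lengths: *", "", cm[1]), ",")[[1]], "=")
    attr(ann, "chrom_lengths") <-
      setNames(as.numeric(vapply(kv, `[`, "", 2)), vapply(kv, `[`, "", 1))
  }
  ann
}

#' Write / read an interval track as BED6
#'
#' BED is 0-based half-open on disk, matching the in-memory convention, so
#' coordinates round-trip unchanged. Backed by rtracklayer.
#'
#' @param track Track data.frame (chrom, start, end, name, score, strand).
#' @param path File path.
#' @export
write_bed <- function(track, path) {
  gr <- track_to_granges(track)
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  granges_to_track(gr)
}

# 0-based half-open track <-> 1-based closed GRanges
track_to_granges <- function(track) {
  strand <- ifelse(track$strand %in% c("+", "-"), track$strand, "*")
  gr <- GenomicRanges::GRanges(
    seqnames = track$chrom,
    ranges = IRanges::IRanges(start = track$start + 1, end = track$end),
    strand = strand)
  gr$name <- track$name %||% sprintf("iv_%04d", seq_along(gr))
  gr$score <- track$score %||% rep(0, length(gr))
  gr
}

granges_to_track <- function(gr) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = GenomicRanges::end(gr),
    name = if (!is.null(gr$name)) gr$name else sprintf("iv_%04d", seq_along(gr)),
    score = if (!is.null(gr$score)) as.numeric(gr$score) else 0,
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE)
  df$strand[df$strand == "*"] <- "."
  df[order(as.integer(sub("^chr", "", df$chrom)), df$start), , drop = FALSE]
}

#' Write / read GMT term sets
#'
#' Standard tab-separated GMT: term id, description, then member genes.
#'
#' @param terms Named list term -> gene vector.
#' @param path File path.
#' @param descriptions Optional named descriptions (defaults to term id).
#' @export
write_gmt <- function(terms, path, descriptions = NULL) {
  lines <- vapply(names(terms), function(t) {
    d <- descriptions[[t]] %||% t
    paste(c(t, d, terms[[t]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  terms <- lapply(parts, function(p) p[-(1:2)])
  names(terms) <- vapply(parts, `[`, "", 1)
  terms
}

#' Write / read a regulon table (tf, target, chrom, site_start, site_end)
#' @param regulons Result of [generate_regulons()] or its `table` element.
#' @param path File path.
#' @export
write_regulons <- function(regulons, path) {
  tab <- if (is.data.frame(regulons)) regulons else regulons$table
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_regulons
#' @export
read_regulons <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t")
  regs <- split(tab[, c("target", "chrom", "site_start", "site_end")], tab$tf)
  regs <- lapply(regs, function(d) { rownames(d) <- NULL; d })
  list(regulons = regs, table = tab)
}

#' Write / read a network edge list TSV
#'
#' Columns gene_a, gene_b, score, p_value, cis (0/1), sorted by descending
#' score.
#'
#' @param net A `coexpression_network`.
#' @param path File path.
#' @export
write_network <- function(net, path) {
  e <- as.data.frame(net$edges)
  e <- e[order(-e$score, e$gene_a, e$gene_b), ]
  e$cis <- as.integer(e$cis)
  write.table(e, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_network
#' @param score_kind Score kind recorded on read (`"mi"` or `"pearson"`).
#' @export
read_network <- function(path, score_kind = "mi") {
  e <- data.table::fread(path, sep = "\t")
  if ("cis" %in% names(e)) e[, cis := as.logical(cis)]
  new_network(e, score_kind = score_kind, n_samples_used = NA_integer_)
}
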
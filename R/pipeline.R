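# end-to-end two-phenotype pipeline: simulate -> infer -> communities ->
# assortativity -> DE -> enrichment -> genomic context -> report

#' Default pipeline configuration
#'
#' Returns the bundled synthetic configuration as a nested list; any
#' element can be overridden via `...` (merged recursively). The same
#' structure is what [read_pipeline_config()] parses from YAML.
#'
#' @param ... Named overrides, e.g. `simulate = list(n_genes = 300)`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1,
    simulate = list(n_genes = 2000,
                    n_samples = list(healthy = 113, tumor = 217),
                    noise_sd = 0.3, global_factor_sd = 0.05),
    network = list(measure = "mi", top_k = 5000, p_cut = NULL,
                   n_permutations = 10000,
                   k_grid = c(1e3, 1e4, 1e5)),
    communities = list(algorithm = "louvain"),
    de = list(lfc_cut = 0.5, p_cut = 0.05),
    enrichment = list(alpha = 0.005, min_term = 10, min_community = 5,
                      n_terms = 60),
    cna = list(alpha = 0.05, n_del_modules = 10, n_amp_peaks = 8),
    ctcf = list(flank = 5e4, n_peaks = 3000),
    regulons = list(n_tfs = 3, targets_per_tf = 24))
  merge_config(cfg, list(...))
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Read a pipeline configuration from YAML
#' @param path YAML file; keys override the defaults of
#'   [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Run the full two-phenotype analysis
#'
#' Simulates (or loads) a two-group study, infers a co-expression network
#' per phenotype, detects communities, computes assortativities and
#' differential expression, runs term and copy-number-peak
#' overrepresentation, annotates TF-regulon edges and CTCF peak classes
#' with the cis-community boundary analysis, and writes every artifact plus
#' a manifest of md5 hashes. Reruns with the same config are bit-identical.
#'
#' @param config List from [pipeline_config()] / [read_pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param study Optional pre-built `expression_study` (skips simulation;
#'   `annotation` must then be supplied too).
#' @param annotation Optional annotation matching `study`.
#' @return A `run_report` list (also written as `report.json`).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir, study = NULL,
                         annotation = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  log_stage <- function(fmt, ...) message(sprintf(paste0("[cistrans] ", fmt), ...))

  # --- simulate -------------------------------------------------------
  if (is.null(study)) {
    log_stage("simulate: %d genes, %d+%d samples", config$simulate$n_genes,
              config$simulate$n_samples$healthy, config$simulate$n_samples$tumor)
    genome <- default_genome(config$simulate$n_genes)
    annotation <- generate_annotation(genome, seed)
    layout <- default_module_layout(annotation, seed)
    scfg <- synthetic_study_config(
      genome, modules = layout,
      n_samples_per_group = c(healthy = config$simulate$n_samples$healthy,
                              tumor = config$simulate$n_samples$tumor),
      noise_sd = config$simulate$noise_sd,
      global_factor_sd = config$simulate$global_factor_sd, seed = seed)
    study <- generate_expression(scfg, annotation)
  } else {
    if (is.null(annotation)) stopf("run_pipeline: study given without annotation")
    layout <- NULL
  }
  write_expression(study, file.path(out_dir, "expression.tsv"),
                   file.path(out_dir, "phenotype.tsv"))
  write_annotation(annotation, file.path(out_dir, "annotation.tsv"))

  # --- networks -------------------------------------------------------
  groups <- levels(study$groups)
  micfg <- mi_config(n_permutations = config$network$n_permutations,
                     seed = seed + 7L)
  nets_full <- list(); nets <- list(); curves <- list()
  for (g in groups) {
    log_stage("infer (%s): measure=%s", g, config$network$measure)
    full <- build_coexpression_network(study, annotation, group = g,
                                       measure = config$network$measure,
                                       cfg = micfg,
                                       p_cut = config$network$p_cut)
    nets_full[[g]] <- full
    k_grid <- config$network$k_grid[config$network$k_grid <= nrow(full$edges)]
    curves[[g]] <- cis_fraction_curve(full, sort(k_grid))
    nets[[g]] <- select_top_edges(full, min(config$network$top_k, nrow(full$edges)))
    write_network(nets[[g]], file.path(out_dir, sprintf("network_%s.tsv", g)))
    write.table(curves[[g]], file.path(out_dir, sprintf("cis_curve_%s.tsv", g)),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  for (strat in c("all", "cis", "trans")) {
    h <- score_histograms(nets_full[[groups[1]]], nets_full[[groups[2]]], strat)
    names(h)[3:4] <- paste0("count_", groups)
    write.table(h, file.path(out_dir, sprintf("score_hist_%s.tsv", strat)),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # --- differential expression ---------------------------------------
  log_stage("differential expression: %s vs %s", groups[2], groups[1])
  de <- differential_expression(study, ref = groups[1], alt = groups[2],
                                lfc_cut = config$de$lfc_cut,
                                p_cut = config$de$p_cut)
  write.table(de, file.path(out_dir, "de.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  # --- communities + profiles ----------------------------------------
  partitions <- list(); profiles <- list()
  for (g in groups) {
    log_stage("communities (%s): %s", g, config$communities$algorithm)
    partitions[[g]] <- detect_communities(nets[[g]],
                                          algorithm = config$communities$algorithm,
                                          seed = seed + 13L)
    profiles[[g]] <- community_profiles(partitions[[g]], nets[[g]], annotation, de)
    memb <- partitions[[g]]$membership
    write.table(data.frame(gene = names(memb), community_id = memb,
                           community_name = profiles[[g]]$name[
                             match(memb, profiles[[g]]$community_id)]),
                file.path(out_dir, sprintf("communities_%s.tsv", g)),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(profiles[[g]][, setdiff(names(profiles[[g]]), "genes")],
                file.path(out_dir, sprintf("profiles_%s.tsv", g)),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # --- term enrichment ------------------------------------------------
  log_stage("term enrichment")
  terms <- generate_term_sets(annotation,
                              modules = if (!is.null(layout)) layout$tumor else NULL,
                              n_terms = config$enrichment$n_terms,
                              seed = seed + 17L)
  write_gmt(terms, file.path(out_dir, "terms.gmt"))
  enr <- list()
  for (g in groups) {
    enr[[g]] <- enrich_communities(community_gene_sets(partitions[[g]]), terms,
                                   universe = study$gene_ids,
                                   min_community = config$enrichment$min_community,
                                   min_term = config$enrichment$min_term,
                                   alpha = config$enrichment$alpha)
    write.table(enr[[g]], file.path(out_dir, sprintf("enrichment_%s.tsv", g)),
                sep = "\t", quote = FALSE, row.names = FALSE)
    allu <- make_alluvial_table(profiles[[g]], enr[[g]])
    write.table(allu, file.path(out_dir, sprintf("alluvial_%s.tsv", g)),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # --- CNA peaks ------------------------------------------------------
  log_stage("CNA peak enrichment")
  tumor <- groups[2]
  cis_mods <- if (!is.null(layout))
    Filter(function(m) m$kind == "cis", layout$tumor) else list()
  del_targets <- unlist(lapply(head(cis_mods, config$cna$n_del_modules),
                               function(m) m$gene_ids[1:5]))
  del_peaks <- generate_peak_track(annotation, length(del_targets),
                                   "gene_spanning", seed = seed + 19L,
                                   target_genes = del_targets)
  amp_peaks <- generate_peak_track(annotation, config$cna$n_amp_peaks,
                                   "gene_spanning", seed = seed + 23L)
  write_bed(del_peaks, file.path(out_dir, "cna_deletion_peaks.bed"))
  write_bed(amp_peaks, file.path(out_dir, "cna_amplification_peaks.bed"))
  peak_sets <- list(
    deletion = map_peaks_to_genes(del_peaks, annotation),
    amplification = map_peaks_to_genes(amp_peaks, annotation))
  cna <- enrich_cna_peaks(community_gene_sets(partitions[[tumor]]), peak_sets,
                          universe = study$gene_ids, alpha = config$cna$alpha)
  write.table(cna, file.path(out_dir, "cna_enrichment.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  # --- CTCF -----------------------------------------------------------
  log_stage("CTCF classification and boundary analysis")
  ctcf <- generate_peak_track(annotation, config$ctcf$n_peaks, "uniform",
                              seed = seed + 29L)
  write_bed(ctcf, file.path(out_dir, "ctcf_peaks.bed"))
  cls <- classify_ctcf_sites(ctcf, annotation)
  write.table(data.frame(class = names(cls$counts), count = cls$counts),
              file.path(out_dir, "ctcf_classes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  cis_comms <- cis_community_sets(profiles[[tumor]], partitions[[tumor]], annotation)
  boundary <- if (length(cis_comms) > 0)
    ctcf_boundary_analysis(cis_comms, ctcf, annotation, flank = config$ctcf$flank)
  else data.frame()
  write.table(boundary, file.path(out_dir, "ctcf_boundaries.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  # --- TF regulons ----------------------------------------------------
  log_stage("TF regulon annotation")
  trans_mods <- if (!is.null(layout))
    Filter(function(m) m$kind == "trans", layout$tumor) else NULL
  regs <- generate_regulons(annotation, modules = trans_mods,
                            n_tfs = config$regulons$n_tfs,
                            targets_per_tf = config$regulons$targets_per_tf,
                            seed = seed + 31L)
  write_regulons(regs, file.path(out_dir, "regulons.tsv"))
  reg_rows <- lapply(community_gene_sets(partitions[[tumor]]),
                     annotate_regulatory_edges, net = nets[[tumor]],
                     regulons = regs, annotation = annotation)
  reg_tab <- do.call(rbind, Map(function(cid, d)
    if (nrow(d) > 0) cbind(community_id = cid, d) else NULL,
    names(reg_rows), reg_rows))
  if (is.null(reg_tab))
    reg_tab <- data.frame(community_id = character(), tf = character(),
                          total_degree = integer(), regulatory_degree = integer(),
                          targets = character())
  rownames(reg_tab) <- NULL
  write.table(reg_tab, file.path(out_dir, "regulatory_edges.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  # --- report + manifest ---------------------------------------------
  report <- build_report(groups, nets, curves, partitions, profiles, enr, cna, config)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- sort(setdiff(list.files(out_dir), "manifest.json"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("cistrans")),
    seed = seed,
    config = config,
    files = as.list(setNames(
      unname(tools::md5sum(file.path(out_dir, files))), files)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_stage("done: %d files in %s", length(files) + 1, out_dir)
  invisible(structure(report, class = "run_report"))
}

# cis communities (ass_chr exactly 1) as gene-set list, single-chromosome
cis_community_sets <- function(profiles, partition, annotation) {
  sets <- community_gene_sets(partition)
  keep <- profiles$community_id[!is.na(profiles$ass_chr) & profiles$ass_chr == 1]
  sets[names(sets) %in% keep]
}

build_report <- function(groups, nets, curves, partitions, profiles, enr, cna,
                         config) {
  per_group <- lapply(groups, function(g) {
    pr <- profiles[[g]]
    n_cis <- sum(!is.na(pr$ass_chr) & pr$ass_chr == 1)
    sig <- enr[[g]]$community_id[enr[[g]]$significant]
    list(n_edges = nrow(nets[[g]]$edges),
         cis_fraction = mean(nets[[g]]$edges$cis),
         cis_curve = curves[[g]],
         n_communities = nrow(pr),
         n_cis_communities = n_cis,
         n_trans_communities = nrow(pr) - n_cis,
         n_communities_ge5 = sum(pr$size >= 5),
         n_enriched_communities = length(unique(sig)),
         modularity = partitions[[g]]$modularity,
         ass_chr_mean = mean(pr$ass_chr, na.rm = TRUE),
         ass_dge_mean = mean(pr$ass_dge, na.rm = TRUE))
  })
  names(per_group) <- groups
  list(groups = per_group,
       n_cna_enriched = if (nrow(cna) > 0) sum(cna$significant) else 0L,
       top_k = config$network$top_k, measure = config$network$measure,
       algorithm = config$communities$algorithm)
}

#' Alluvial/scatter backing table: community type vs enriched-term count
#'
#' One row per community: cis/trans type (cis iff `ass_chr == 1`), size,
#' both assortativities, and the number of significantly enriched terms —
#' the data behind the alluvial and assortativity-scatter figures.
#'
#' @param profiles Output of [community_profiles()].
#' @param enrichment Output of [enrich_communities()].
#' @export
make_alluvial_table <- function(profiles, enrichment) {
  sig <- enrichment[enrichment$significant, , drop = FALSE]
  counts <- table(sig$community_id)
  data.frame(community_id = profiles$community_id,
             name = profiles$name,
             type = ifelse(!is.na(profiles$ass_chr) & profiles$ass_chr == 1,
                           "cis", "trans"),
             size = profiles$size,
             ass_chr = profiles$ass_chr,
             ass_dge = profiles$ass_dge,
             n_significant_terms = as.integer(
               ifelse(profiles$community_id %in% names(counts),
                      counts[as.character(profiles$community_id)], 0L)),
             stringsAsFactors = FALSE)
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  for (g in names(x$groups)) {
    r <- x$groups[[g]]
    cat(sprintf("  %s: %d edges (cis %.3f), %d communities (%d cis / %d trans), Q=%.3f, %d enriched\n",
                g, r$n_edges, r$cis_fraction, r$n_communities,
                r$n_cis_communities, r$n_trans_communities, r$modularity,
                r$n_enriched_communities))
  }
  invisible(x)
}
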
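# One-configuration orchestration of the full analysis: differential
# methylation, differential counts, sRNA clusters, motif enrichment and
# integration, with a manifest recording parameters, input checksums and
# the seed. All coupling between stages is through files.

pipeline_schema <- function() {
  list(
    inputs = c("genome", "gff3", "meth_ref", "meth_test", "gene_counts",
               "srna_reads", "pfm", "categories", "gene_set"),
    params = list(
      dm = c("contexts", "min_coverage", "c_fdr", "region_fdr", "min_dmc",
             "min_diff_c", "promoter_length"),
      de = c("min_cpm", "fdr"),
      clusters = c("min_len", "max_len", "pad", "min_reads"),
      motif = c("window", "step", "n_perm", "p_threshold"),
      integrate = c("min_diff", "min_fraction")),
    top = c("inputs", "params", "seed", "out_dir"))
}

#' Validate a pipeline run configuration
#'
#' The configuration is a named list (usually from a YAML file): `inputs`
#' (paths), `params` (per-stage blocks), `seed`, `out_dir`. Unknown keys at
#' any level are rejected so misspelt parameters cannot silently fall back
#' to defaults.
#'
#' @param config named list or path to a YAML file.
#' @return the validated config (with defaults filled in).
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  sch <- pipeline_schema()
  unknown <- setdiff(names(config), sch$top)
  if (length(unknown)) {
    stop(sprintf("unknown configuration key: %s", unknown[1]))
  }
  for (k in c("inputs", "seed", "out_dir")) {
    if (is.null(config[[k]])) stop(sprintf("missing configuration key: %s", k))
  }
  unknown <- setdiff(names(config$inputs), sch$inputs)
  if (length(unknown)) stop(sprintf("unknown input key: %s", unknown[1]))
  required <- c("genome", "gff3", "meth_ref", "meth_test", "gene_counts",
                "srna_reads", "pfm")
  for (k in required) {
    if (is.null(config$inputs[[k]])) {
      stop(sprintf("missing input path for key: %s", k))
    }
    if (!file.exists(config$inputs[[k]])) {
      stop(sprintf("input '%s' does not exist: %s", k, config$inputs[[k]]))
    }
  }
  defaults <- list(
    dm = list(contexts = c("CG", "CHG", "CHH"), min_coverage = 10L,
              c_fdr = 0.05, region_fdr = 0.05, min_dmc = 10L,
              min_diff_c = 0, promoter_length = 2000L),
    de = list(min_cpm = 2, fdr = 0.05),
    clusters = list(min_len = 18L, max_len = 24L, pad = 75L, min_reads = 3L),
    motif = list(window = 20000L, step = 100L, n_perm = 1000L,
                 p_threshold = 1e-5),
    integrate = list(min_diff = 0.05, min_fraction = 0.02))
  params <- if (is.null(config$params)) list() else config$params
  unknown <- setdiff(names(params), names(sch$params))
  if (length(unknown)) stop(sprintf("unknown parameter block: %s", unknown[1]))
  for (blk in names(defaults)) {
    given <- if (is.null(params[[blk]])) list() else params[[blk]]
    unknown <- setdiff(names(given), sch$params[[blk]])
    if (length(unknown)) {
      stop(sprintf("unknown parameter '%s' in block '%s'", unknown[1], blk))
    }
    defaults[[blk]][names(given)] <- given
  }
  config$params <- defaults
  config$seed <- as.integer(config$seed)
  config
}

write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1)) & !vapply(df, is.integer, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.6g", x))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full pipeline from one configuration
#'
#' Stages run in dependency order (differential methylation, differential
#' expression, sRNA clusters, motif enrichment, integration); each writes
#' its TSV/JSON output under `out_dir`, and a `manifest.json` records
#' parameters, input checksums, the seed and the package version. A rerun
#' with the same configuration is byte-identical.
#'
#' @param config named list or path to a YAML file (see
#'   [validate_config()]).
#' @return invisibly, the manifest as a list.
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  p <- config$params
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  inputs <- config$inputs

  genome <- read_genome(inputs$genome)
  chrom_lens <- stats::setNames(Biostrings::width(genome), names(genome))
  ann <- read_gff3(inputs$gff3)
  genes <- ann[ann$feature_class == "gene", ]
  tes <- ann[ann$feature_class == "TE", ]
  sites_ref <- read_cytosine_report(inputs$meth_ref, p$dm$min_coverage)
  sites_test <- read_cytosine_report(inputs$meth_test, p$dm$min_coverage)

  # stage dm: promoter calls per context
  prom <- promoter_regions(genes, p$dm$promoter_length, chrom_lens)
  dm_list <- lapply(p$dm$contexts, function(ctx) {
    call_region_dm(sites_ref, sites_test, prom, ctx,
                   min_coverage = p$dm$min_coverage, c_fdr = p$dm$c_fdr,
                   region_fdr = p$dm$region_fdr, min_dmc = p$dm$min_dmc,
                   min_diff_c = p$dm$min_diff_c)
  })
  names(dm_list) <- p$dm$contexts
  dm_all <- do.call(rbind, dm_list)
  write_tsv(dm_all, file.path(out_dir, "dm_promoters.tsv"))
  sig <- dm_all[dm_all$status != "ns", ]
  sig_regions <- prom[match(sig$region_id, prom$gene_id), ]
  write_bed(data.frame(sig_regions[, c("chrom", "start", "end")],
                       name = paste(sig$region_id, sig$context, sig$status,
                                    sep = "|"),
                       score = 0, strand = sig_regions$strand),
            file.path(out_dir, "dmp.bed"))

  # stage de: gene-level differential expression
  gene_cm <- read_count_matrix(inputs$gene_counts)
  groups <- sub("_[0-9]+$", "", colnames(gene_cm$counts))
  gene_cm_f <- cpm_filter(gene_cm, p$de$min_cpm, groups = groups)
  de <- nb_test(gene_cm_f, groups, p$de$fdr)
  write_tsv(de, file.path(out_dir, "de_genes.tsv"))

  # stage clusters: sRNA clusters, categories, counts, DE, methylation
  reads <- utils::read.table(inputs$srna_reads, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
  clusters <- call_clusters(reads, p$clusters$min_len, p$clusters$max_len,
                            p$clusters$pad, p$clusters$min_reads)
  clusters <- categorize_clusters(clusters, genes, prom, tes)
  write_bed(data.frame(clusters[, c("chrom", "start", "end")],
                       name = paste(clusters$cluster_id, clusters$category,
                                    sep = "|"),
                       score = 0, strand = "."),
            file.path(out_dir, "clusters.bed"))
  cl_cm <- cluster_count_matrix(clusters)
  cl_groups <- sub("_[0-9]+$", "", colnames(cl_cm$counts))
  cl_cm_f <- cpm_filter(cl_cm, p$de$min_cpm, groups = cl_groups)
  cluster_de <- nb_test(cl_cm_f, cl_groups, p$de$fdr)
  write_tsv(cluster_de, file.path(out_dir, "de_clusters.tsv"))
  cluster_dm <- do.call(rbind, lapply(p$dm$contexts, function(ctx) {
    sctgr_methylation(clusters, sites_ref, sites_test, ctx,
                      min_diff = p$integrate$min_diff,
                      min_coverage = p$dm$min_coverage, c_fdr = p$dm$c_fdr,
                      region_fdr = p$dm$region_fdr, min_dmc = p$dm$min_dmc,
                      min_diff_c = p$dm$min_diff_c)
  }))
  write_tsv(cluster_dm, file.path(out_dir, "dm_clusters.tsv"))

  # stage motif-enrich: positional TFBS enrichment of the regulated set
  pfms <- read_jaspar_pfm(inputs$pfm)
  up_regions <- upstream_regions(genes, p$motif$window, chrom_lens)
  regulated <- if (!is.null(inputs$gene_set)) {
    readLines(inputs$gene_set)
  } else {
    de$feature_id[de$status != "ns"]
  }
  positions <- seq(0L, as.integer(p$motif$window), by = as.integer(p$motif$step))
  hits <- do.call(rbind, lapply(names(pfms), function(id) {
    h <- pwm_scan(genome, up_regions, pfm_to_pwm(pfms[[id]]),
                  p$motif$p_threshold)
    if (nrow(h)) h$motif_id <- id
    h
  }))
  enr <- NULL
  if (length(regulated) >= 2L && !is.null(hits) && nrow(hits) > 0L) {
    enr <- enrichment_test(hits, intersect(regulated, genes$gene_id),
                           genes$gene_id, positions,
                           n_perm = as.integer(p$motif$n_perm),
                           seed = child_seed(config$seed, 9))
    write_tsv(data.frame(position = enr$positions, frac_set = enr$frac_set,
                         frac_all = enr$frac_all, es = enr$es),
              file.path(out_dir, "motif_curves.tsv"))
    jsonlite::write_json(list(summary_es = enr$summary_es, z = enr$z,
                              p_perm = enr$p_perm, n_perm = enr$n_perm),
                         file.path(out_dir, "motif_enrichment.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  # stage integrate
  overlap <- overlap_deg_dmp(de, dm_list)
  write_tsv(overlap$per_gene, file.path(out_dir, "deg_dmp_per_gene.tsv"))
  # association on the CHH calls (RdDM context); all contexts are in the TSVs
  assoc_ctx <- cluster_dm[cluster_dm$context == p$dm$contexts[
    length(p$dm$contexts)], ]
  assoc <- srna_methylation_association(cluster_de, assoc_ctx,
                                        p$integrate$min_diff)
  strata <- gb_vs_promoter_srna(de, clusters, cluster_de)
  write_tsv(strata, file.path(out_dir, "srna_location_strata.tsv"))
  summary <- list(
    n_deg = overlap$n_deg, n_dmp = overlap$n_dmp, n_both = overlap$n_both,
    pct_deg_with_dmp = overlap$pct_deg_with_dmp,
    pct_dmp_that_are_deg = overlap$pct_dmp_that_are_deg,
    n_clusters = nrow(clusters),
    cluster_categories = as.list(table(factor(
      clusters$category,
      levels = c("gene_body", "promoter", "TE", "intergenic")))),
    association_p = assoc$p, association_or = assoc$odds_ratio,
    motif = if (is.null(enr)) NULL else
      list(summary_es = enr$summary_es, z = enr$z, p_perm = enr$p_perm))
  if (!is.null(inputs$categories)) {
    cmap <- utils::read.table(inputs$categories, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
    degs <- de$feature_id[de$status != "ns"]
    if (length(degs) > 0L) {
      cd <- category_distribution(degs, cmap, p$integrate$min_fraction)
      write_tsv(cd, file.path(out_dir, "deg_categories.tsv"))
    }
  }
  jsonlite::write_json(summary, file.path(out_dir, "integration.json"),
                       auto_unbox = TRUE, digits = NA)

  manifest <- list(
    package_version = as.character(utils::packageVersion("photoepi")),
    seed = config$seed,
    params = p,
    input_checksums = lapply(
      Filter(Negate(is.null), inputs[!vapply(inputs, is.null, logical(1))]),
      function(f) unname(tools::md5sum(f))),
    outputs = list.files(out_dir))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Build the bundled synthetic demo study
#'
#' Simulates the miniature study with a fixed parameterisation (two 200-kb
#' chromosomes, 40 genes, 20 TEs, planted DMRs on DEG promoters, planted
#' DEGs, differential sRNA loci and an enriched motif set), writes every
#' input file under `dir/inputs`, and returns a ready-to-run pipeline
#' configuration.
#'
#' @param dir directory to hold `inputs/` and the run's `out/`.
#' @param seed RNG seed for the simulated study (default 101).
#' @return the pipeline configuration list (see [validate_config()]).
#' @export
demo_config <- function(dir, seed = 101L) {
  cfg <- sim_config(n_chroms = 2L, chrom_len = 200000L, n_genes = 40L,
                    n_tes = 20L, dmr_fraction = 0.25, dmr_delta = -0.35,
                    deg_fraction = 0.2, n_srna_loci = 60L,
                    srna_diff_fraction = 0.2, seed = as.integer(seed))
  st <- simulate_study(cfg, couple_dmr_to_deg = TRUE)
  paths <- write_study(st, file.path(dir, "inputs"))
  genes <- st$annotation$gene_id[st$annotation$feature_class == "gene"]
  cats <- data.frame(
    gene_id = genes,
    category = rep(c("photosynthesis", "hormone signalling",
                     "rna biosynthesis", "cell wall"),
                   length.out = length(genes)))
  cat_path <- file.path(dir, "inputs", "categories.tsv")
  utils::write.table(cats, cat_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(inputs = list(genome = paths$genome, gff3 = paths$gff3,
                     meth_ref = paths$meth_ref_1,
                     meth_test = paths$meth_test_1,
                     gene_counts = paths$gene_counts,
                     srna_reads = paths$srna_reads, pfm = paths$pfm,
                     categories = cat_path),
       params = list(motif = list(n_perm = 200L)),
       seed = as.integer(seed), out_dir = file.path(dir, "out"))
}
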
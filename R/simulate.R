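# Deterministic synthetic-study generator with planted ground truth: a
# miniature multi-chromosome genome with gene-rich arms and TE-rich
# pericentromeres, beta-binomial methylomes with planted DMRs, NB count
# matrices with planted DEGs / differential sRNA clusters, sRNA reads
# concentrated at cluster loci, and upstream motif landscapes with a
# positionally enriched gene set.

#' Simulation configuration
#'
#' Defaults emulate the structure of a pooled-WGBS + replicated-RNAseq +
#' sRNAome fruit study at miniature scale: context mean methylation
#' CG 0.80 / CHG 0.67 / CHH 0.23, ~20x cytosine coverage, one pooled
#' methylome per group, three count replicates per group.
#'
#' @param n_chroms number of chromosomes.
#' @param chrom_len chromosome length in bp.
#' @param n_genes,n_tes features per genome; genes are placed preferentially
#'   on the outer thirds of each chromosome, TEs in the middle third.
#' @param gc genome GC content (0.36 mimics tomato).
#' @param context_means named methylation means for CG, CHG, CHH.
#' @param dmr_fraction fraction of gene promoters carrying a planted DMR.
#' @param dmr_delta planted methylation shift (test minus reference).
#' @param dmr_contexts contexts eligible for planting (sampled per region).
#' @param coverage_mean mean per-cytosine read coverage (Poisson).
#' @param overdispersion beta-binomial intra-class correlation rho in (0,1);
#'   precision of the beta is `(1 - rho) / rho`.
#' @param n_samples_per_group count replicates per group.
#' @param deg_fraction fraction of genes planted as DEGs.
#' @param deg_lfc absolute planted log2 fold change.
#' @param nb_dispersion NB dispersion of simulated counts.
#' @param count_meanlog,count_sdlog log-normal baseline expression law.
#' @param libsize_sdlog spread of library-size factors.
#' @param base_libsize target library size per sample.
#' @param n_srna_loci,srna_reads_mean,srna_len_range sRNA read generator:
#'   loci count, mean reads per locus per sample, read-length range.
#' @param srna_diff_fraction,srna_lfc fraction of sRNA loci with a planted
#'   accumulation change, and its absolute log2 fold change.
#' @param motif_rate_bg expected background motif occurrences per gene over
#'   the 20-kb upstream window (Poisson).
#' @param motif_enriched_fraction fraction of genes in the planted
#'   positionally enriched set.
#' @param motif_p_extra probability that an enriched gene receives an extra
#'   TSS-proximal occurrence.
#' @param motif_tss_window window (bp from TSS) for the extra occurrence.
#' @param seed master RNG seed; every stage derives its own stream from it.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_chroms = 2L, chrom_len = 400000L, n_genes = 120L,
                       n_tes = 80L, gc = 0.36,
                       context_means = c(CG = 0.80, CHG = 0.67, CHH = 0.23),
                       dmr_fraction = 0.15, dmr_delta = -0.3,
                       dmr_contexts = c("CG", "CHG", "CHH"),
                       coverage_mean = 20, overdispersion = 0.03,
                       n_samples_per_group = 3L, deg_fraction = 0.1,
                       deg_lfc = 2, nb_dispersion = 0.05,
                       count_meanlog = log(60), count_sdlog = 1.2,
                       libsize_sdlog = 0.15, base_libsize = 1e6,
                       n_srna_loci = 150L, srna_reads_mean = 30,
                       srna_len_range = c(18L, 24L),
                       srna_diff_fraction = 0.1, srna_lfc = 2,
                       motif_rate_bg = 1, motif_enriched_fraction = 0.25,
                       motif_p_extra = 0.6, motif_tss_window = 1000L,
                       seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(n_chroms >= 1L, chrom_len >= 1000L, n_genes >= 0L, n_tes >= 0L,
            gc > 0, gc < 1)
  if (!all(c("CG", "CHG", "CHH") %in% names(context_means)) ||
      any(context_means <= 0) || any(context_means >= 1)) {
    stop("context_means must name CG, CHG, CHH with values in (0, 1)")
  }
  for (f in c("dmr_fraction", "deg_fraction", "srna_diff_fraction",
              "motif_enriched_fraction", "motif_p_extra")) {
    v <- cfg[[f]]
    if (v < 0 || v > 1) stop(sprintf("%s must be in [0, 1]", f))
  }
  if (abs(dmr_delta) > 1) stop("dmr_delta must be in [-1, 1]")
  if (overdispersion <= 0 || overdispersion >= 1) {
    stop("overdispersion (intra-class correlation) must be in (0, 1)")
  }
  stopifnot(coverage_mean > 0, nb_dispersion > 0, n_samples_per_group >= 1L,
            motif_tss_window <= 20000L)
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a genome and its gene/TE annotation
#'
#' Random DNA at the configured GC content; genes are placed in the outer
#' thirds of each chromosome with probability 0.85 (TEs in the middle third
#' with the same bias); features never overlap.
#'
#' @param config a [sim_config()].
#' @return list with `genome` ([Biostrings::DNAStringSet]) and `annotation`
#'   (data.frame as from [read_gff3()]).
#' @export
simulate_genome <- function(config) {
  with_seed(child_seed(config$seed, 1), {
    probs <- c(A = (1 - config$gc) / 2, C = config$gc / 2,
               G = config$gc / 2, T = (1 - config$gc) / 2)
    chroms <- paste0("chr", seq_len(config$n_chroms))
    genome <- Biostrings::DNAStringSet(vapply(chroms, function(ch) {
      paste(sample(names(probs), config$chrom_len, replace = TRUE,
                   prob = probs), collapse = "")
    }, character(1)))
    names(genome) <- chroms

    n_feat <- config$n_genes + config$n_tes
    ann <- NULL
    if (n_feat > 0L) {
      lens <- c(if (config$n_genes > 0)
        sample(1000:3000, config$n_genes, replace = TRUE),
        if (config$n_tes > 0)
          sample(500:2000, config$n_tes, replace = TRUE))
      class_ <- rep(c("gene", "TE"), c(config$n_genes, config$n_tes))
      chrom <- sample(chroms, n_feat, replace = TRUE)
      placed <- data.frame(chrom = character(), start = integer(),
                           end = integer(), stringsAsFactors = FALSE)
      start <- integer(n_feat)
      third <- config$chrom_len %/% 3L
      for (i in seq_len(n_feat)) {
        ok <- FALSE
        for (try in 1:300) {
          outer_arm <- stats::runif(1) < 0.85
          in_outer <- if (class_[i] == "gene") outer_arm else !outer_arm
          if (in_outer) {
            s <- if (stats::runif(1) < 0.5) {
              sample.int(third - lens[i], 1)
            } else {
              2L * third + sample.int(config$chrom_len - 2L * third - lens[i], 1)
            }
          } else {
            s <- third + sample.int(third - lens[i], 1)
          }
          cand <- data.frame(chrom = chrom[i], start = s, end = s + lens[i])
          if (nrow(interval_overlaps(cand, placed)) == 0L) {
            placed <- rbind(placed, cand)
            start[i] <- s
            ok <- TRUE
            break
          }
        }
        if (!ok) stop("could not place all features; genome too small for the requested feature count")
      }
      ann <- data.frame(
        gene_id = ifelse(class_ == "gene",
                         sprintf("g%03d", cumsum(class_ == "gene")),
                         sprintf("te%03d", cumsum(class_ == "TE"))),
        chrom = chrom, start = start, end = start + lens,
        strand = ifelse(class_ == "gene",
                        sample(c("+", "-"), n_feat, replace = TRUE), "."),
        feature_class = class_, stringsAsFactors = FALSE)
      ann <- ann[order(ann$chrom, ann$start), ]
      rownames(ann) <- NULL
    } else {
      ann <- empty_annotation()
    }
    list(genome = genome, annotation = ann)
  })
}

#' Simulate per-sample methylomes with planted DMRs
#'
#' Every cytosine of the genome (both strands) receives a Poisson coverage
#' and a beta-binomial methylated count around its context mean. Planted
#' DMR intervals shift the test-group mean by `dmr_delta` in the region's
#' planted context (clipped to [0.01, 0.99]). By default one pooled sample
#' per group is emitted, mirroring a pooled-WGBS design.
#'
#' @param sim output of [simulate_genome()].
#' @param config a [sim_config()].
#' @param dmr_regions optional data.frame (`chrom`, `start`, `end`, and
#'   optionally `context`) overriding the default planting on a random
#'   `dmr_fraction` of gene promoters.
#' @param samples_per_group methylome samples per group (default 1, pooled).
#' @return list with `sites` (named list `ref`/`test`, each a list of
#'   per-sample cytosine data.frames) and `truth` (planted DMR table).
#' @export
simulate_methylomes <- function(sim, config, dmr_regions = NULL,
                                samples_per_group = 1L) {
  with_seed(child_seed(config$seed, 2), {
    cyt <- enumerate_cytosines(sim$genome)
    genes <- sim$annotation[sim$annotation$feature_class == "gene", ]
    if (is.null(dmr_regions)) {
      if (config$dmr_fraction > 0 && nrow(genes) > 0L) {
        chrom_lens <- stats::setNames(Biostrings::width(sim$genome),
                                      names(sim$genome))
        prom <- promoter_regions(genes, chrom_lens = chrom_lens)
        n_dmr <- round(config$dmr_fraction * nrow(prom))
        pick <- sample.int(nrow(prom), n_dmr)
        dmr_regions <- prom[pick, c("chrom", "start", "end", "gene_id")]
        dmr_regions$context <- sample(config$dmr_contexts, n_dmr,
                                      replace = TRUE)
      } else {
        dmr_regions <- data.frame(chrom = character(), start = integer(),
                                  end = integer(), gene_id = character(),
                                  context = character(),
                                  stringsAsFactors = FALSE)
      }
    } else if (is.null(dmr_regions$context)) {
      dmr_regions$context <- sample(config$dmr_contexts, nrow(dmr_regions),
                                    replace = TRUE)
    }
    dmr_regions$delta <- rep_len(config$dmr_delta, nrow(dmr_regions))

    mu_ref <- config$context_means[cyt$context]
    mu_test <- mu_ref
    if (nrow(dmr_regions) > 0L) {
      ov <- interval_overlaps(
        data.frame(chrom = cyt$chrom, start = cyt$pos, end = cyt$pos + 1L),
        dmr_regions)
      if (nrow(ov) > 0L) {
        in_ctx <- cyt$context[ov$query] == dmr_regions$context[ov$subject]
        idx <- ov$query[in_ctx]
        mu_test[idx] <- mu_ref[idx] + dmr_regions$delta[ov$subject[in_ctx]]
      }
    }
    clipped <- mu_test < 0.01 | mu_test > 0.99
    if (any(clipped)) {
      mu_test <- pmin(pmax(mu_test, 0.01), 0.99)
      warning(sprintf("dmr_delta clipped the planted mean at %d cytosines",
                      sum(clipped)))
    }

    theta <- (1 - config$overdispersion) / config$overdispersion
    draw_sample <- function(mu) {
      total <- stats::rpois(nrow(cyt), config$coverage_mean)
      p <- stats::rbeta(nrow(cyt), mu * theta, (1 - mu) * theta)
      meth <- stats::rbinom(nrow(cyt), total, p)
      keep <- total > 0L
      data.frame(chrom = cyt$chrom[keep], pos = cyt$pos[keep],
                 strand = cyt$strand[keep], context = cyt$context[keep],
                 meth = meth[keep], total = total[keep],
                 stringsAsFactors = FALSE)
    }
    sites <- list(
      ref = lapply(seq_len(samples_per_group), function(i) draw_sample(mu_ref)),
      test = lapply(seq_len(samples_per_group), function(i) draw_sample(mu_test)))
    list(sites = sites, truth = dmr_regions)
  })
}

#' Simulate an NB count matrix with planted DEGs
#'
#' Baseline means are log-normal; planted features have their mean in the
#' test group multiplied by `2^lfc` with random sign. Library-size factors
#' are log-normal around `base_libsize`.
#'
#' @param feature_ids character vector of feature ids (e.g. gene ids or
#'   cluster ids).
#' @param config a [sim_config()].
#' @param diff_fraction,lfc planted fraction and absolute log2 fold change;
#'   default from `config` gene settings.
#' @param stream RNG stream offset, so gene and cluster matrices from the
#'   same seed are independent.
#' @return list with `cm` (a `count_matrix`; samples `ref_1..n, test_1..n`),
#'   `groups`, and `truth` (data.frame `feature_id`, `lfc`).
#' @export
simulate_counts <- function(feature_ids, config,
                            diff_fraction = config$deg_fraction,
                            lfc = config$deg_lfc, stream = 3L) {
  with_seed(child_seed(config$seed, stream), {
    nf <- length(feature_ids)
    n <- config$n_samples_per_group
    base <- stats::rlnorm(nf, config$count_meanlog, config$count_sdlog)
    n_diff <- round(diff_fraction * nf)
    diff_idx <- if (n_diff > 0) sample.int(nf, n_diff) else integer(0)
    sign <- sample(c(-1, 1), n_diff, replace = TRUE)
    lfc_vec <- numeric(nf)
    lfc_vec[diff_idx] <- sign * lfc
    s <- stats::rlnorm(2L * n, 0, config$libsize_sdlog)
    s <- s * config$base_libsize / 1e6   # per-million scale for the means
    group <- rep(c("ref", "test"), each = n)
    mu <- outer(base, s) * 2^outer(lfc_vec, as.numeric(group == "test"))
    counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                    size = 1 / config$nb_dispersion),
                     nf, 2L * n)
    dimnames(counts) <- list(feature_ids,
                             paste(group, rep(seq_len(n), 2), sep = "_"))
    truth <- data.frame(feature_id = feature_ids[diff_idx],
                        lfc = lfc_vec[diff_idx], stringsAsFactors = FALSE)
    list(cm = count_matrix(counts), groups = group, truth = truth)
  })
}

#' Simulate sRNA reads concentrated at cluster loci
#'
#' Loci of 100-400 bp are placed uniformly over the genome; each locus
#' receives NB-distributed read counts per sample (18-24-nt reads placed
#' uniformly within the locus). Planted differential loci have their mean
#' scaled by `2^srna_lfc` in the test group.
#'
#' @param sim output of [simulate_genome()].
#' @param config a [sim_config()].
#' @return list with `reads` (data.frame `chrom`, `start`, `end`, `sample`),
#'   `loci` (true cluster intervals) and `truth` (differential locus table).
#' @export
simulate_srna_reads <- function(sim, config) {
  with_seed(child_seed(config$seed, 4), {
    n <- config$n_srna_loci
    chroms <- names(sim$genome)
    lens <- stats::setNames(Biostrings::width(sim$genome), chroms)
    loc_len <- sample(100:400, n, replace = TRUE)
    loc_chrom <- sample(chroms, n, replace = TRUE)
    loc_start <- vapply(seq_len(n), function(i)
      sample.int(lens[[loc_chrom[i]]] - loc_len[i] - 30L, 1), integer(1))
    loci <- data.frame(locus_id = sprintf("locus%03d", seq_len(n)),
                       chrom = loc_chrom, start = loc_start,
                       end = loc_start + loc_len, stringsAsFactors = FALSE)
    n_diff <- round(config$srna_diff_fraction * n)
    diff_idx <- if (n_diff > 0) sample.int(n, n_diff) else integer(0)
    sign <- sample(c(-1, 1), n_diff, replace = TRUE)
    lfc_vec <- numeric(n)
    lfc_vec[diff_idx] <- sign * config$srna_lfc
    nrep <- config$n_samples_per_group
    samples <- c(paste0("ref_", seq_len(nrep)), paste0("test_", seq_len(nrep)))
    is_test <- grepl("^test", samples)
    reads <- list()
    for (j in seq_along(samples)) {
      mu <- config$srna_reads_mean * 2^(lfc_vec * is_test[j])
      cnt <- stats::rnbinom(n, mu = mu, size = 1 / config$nb_dispersion)
      li <- rep(seq_len(n), cnt)
      if (length(li) == 0L) next
      rl <- sample(config$srna_len_range[1]:config$srna_len_range[2],
                   length(li), replace = TRUE)
      off <- floor(stats::runif(length(li)) * (loci$end[li] - loci$start[li] - rl + 1))
      reads[[j]] <- data.frame(chrom = loci$chrom[li],
                               start = loci$start[li] + off,
                               end = loci$start[li] + off + rl,
                               sample = samples[j], stringsAsFactors = FALSE)
    }
    reads <- do.call(rbind, reads)
    rownames(reads) <- NULL
    truth <- data.frame(locus_id = loci$locus_id[diff_idx],
                        chrom = loci$chrom[diff_idx],
                        start = loci$start[diff_idx],
                        end = loci$end[diff_idx],
                        lfc = lfc_vec[diff_idx], stringsAsFactors = FALSE)
    list(reads = reads, loci = loci, truth = truth)
  })
}

#' Simulate a positional motif landscape over gene upstream regions
#'
#' Background occurrences fall uniformly in the 20-kb upstream window at
#' rate `motif_rate_bg` per gene; genes of the planted enriched set receive
#' an extra occurrence within `motif_tss_window` of the TSS with
#' probability `motif_p_extra`. Optionally the PFM consensus is written
#' into the genome at each occurrence so a sequence scan recovers it.
#'
#' @param sim output of [simulate_genome()] (genome is modified only when
#'   `embed = TRUE`).
#' @param pfm a 4 x L PFM (consensus = per-column argmax).
#' @param config a [sim_config()].
#' @param embed write consensus sequence into the genome at each occurrence.
#' @return list with `hits` (data.frame `gene_id`, `distance`), `truth`
#'   (enriched gene ids) and `genome` (possibly modified copy).
#' @export
simulate_motif_landscape <- function(sim, pfm, config, embed = TRUE) {
  with_seed(child_seed(config$seed, 5), {
    if (config$motif_tss_window > 20000L) stop("motif_tss_window > 20 kb")
    genes <- sim$annotation[sim$annotation$feature_class == "gene", ]
    if (nrow(genes) == 0L) stop("no genes to place motifs on")
    chrom_lens <- stats::setNames(Biostrings::width(sim$genome),
                                  names(sim$genome))
    up <- upstream_regions(genes, 20000L, chrom_lens)
    n_enr <- round(config$motif_enriched_fraction * nrow(up))
    enriched <- sample(up$gene_id, n_enr)
    L <- ncol(pfm)
    hits <- list()
    for (i in seq_len(nrow(up))) {
      reg <- up[i, ]
      reg_len <- reg$end - reg$start
      if (reg_len < L + 1L) next
      n_bg <- stats::rpois(1, config$motif_rate_bg)
      d <- floor(stats::runif(n_bg) * (min(20000L, reg_len) - L))
      if (reg$gene_id %in% enriched &&
          stats::runif(1) < config$motif_p_extra) {
        d <- c(d, floor(stats::runif(1) *
                          (min(config$motif_tss_window, reg_len) - L)))
      }
      if (length(d) == 0L) next
      hits[[i]] <- data.frame(gene_id = reg$gene_id, distance = as.integer(d),
                              chrom = reg$chrom, strand = reg$strand,
                              reg_start = reg$start, reg_end = reg$end,
                              stringsAsFactors = FALSE)
    }
    hits <- if (length(hits)) do.call(rbind, hits) else
      data.frame(gene_id = character(), distance = integer(),
                 stringsAsFactors = FALSE)
    rownames(hits) <- NULL
    genome <- sim$genome
    if (embed && nrow(hits) > 0L) {
      consensus <- paste(c("A", "C", "G", "T")[apply(pfm, 2, which.max)],
                         collapse = "")
      for (i in seq_len(nrow(hits))) {
        h <- hits[i, ]
        # motif written on the + genome strand at the position whose
        # TSS-relative distance is h$distance
        if (h$strand == "+") {
          hs <- h$reg_end - h$distance - L    # 0-based start
        } else {
          hs <- h$reg_start + h$distance
        }
        Biostrings::subseq(genome[[h$chrom]], hs + 1L, hs + L) <-
          Biostrings::DNAString(consensus)
      }
    }
    list(hits = hits[, c("gene_id", "distance")], truth = enriched,
         genome = genome)
  })
}

#' Simulate a complete miniature study
#'
#' Orchestrates genome, methylomes, gene counts, sRNA reads and the motif
#' landscape under one seed. When `couple_dmr_to_deg` is `TRUE`, planted
#' DMRs are placed on the promoters of planted DEGs (so the DEG x DMP
#' overlap exceeds its null rate); sRNA differential loci remain
#' independent.
#'
#' @param config a [sim_config()].
#' @param pfm optional PFM for the motif landscape (default: a strong
#'   built-in 8-mer).
#' @param couple_dmr_to_deg place planted DMRs on planted-DEG promoters.
#' @return list with `genome`, `annotation`, `methylomes`, `gene_counts`,
#'   `srna`, `motifs`, `config`.
#' @export
simulate_study <- function(config = sim_config(), pfm = NULL,
                           couple_dmr_to_deg = FALSE) {
  sim <- simulate_genome(config)
  genes <- sim$annotation[sim$annotation$feature_class == "gene", ]
  gene_counts <- simulate_counts(genes$gene_id, config, stream = 3L)
  dmr_regions <- NULL
  if (couple_dmr_to_deg && nrow(gene_counts$truth) > 0L) {
    chrom_lens <- stats::setNames(Biostrings::width(sim$genome),
                                  names(sim$genome))
    prom <- promoter_regions(genes, chrom_lens = chrom_lens)
    dmr_regions <- prom[prom$gene_id %in% gene_counts$truth$feature_id,
                        c("chrom", "start", "end", "gene_id")]
  }
  methylomes <- simulate_methylomes(sim, config, dmr_regions = dmr_regions)
  srna <- simulate_srna_reads(sim, config)
  if (is.null(pfm)) pfm <- default_pfm()
  motifs <- simulate_motif_landscape(sim, pfm, config, embed = TRUE)
  list(genome = motifs$genome, annotation = sim$annotation,
       methylomes = methylomes, gene_counts = gene_counts, srna = srna,
       motifs = motifs[c("hits", "truth")], pfm = pfm, config = config)
}

# A sharp 8-bp PFM (near-consensus columns) used by the bundled demo.
default_pfm <- function() {
  consensus <- c("G", "T", "A", "C", "G", "T", "G", "C")
  m <- matrix(1, 4, length(consensus),
              dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in seq_along(consensus)) m[consensus[j], j] <- 97
  m
}

#' Write a simulated study to disk in the pipeline's input formats
#'
#' @param study output of [simulate_study()].
#' @param dir output directory (created if needed).
#' @return invisibly, a named list of written paths.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    genome = file.path(dir, "genome.fa"),
    gff3 = file.path(dir, "annotation.gff3"),
    gene_counts = file.path(dir, "gene_counts.tsv"),
    srna_reads = file.path(dir, "srna_reads.tsv"),
    pfm = file.path(dir, "motif.jaspar"))
  write_genome(study$genome, paths$genome)
  write_gff3(study$annotation, paths$gff3)
  write_count_matrix(study$gene_counts$cm, paths$gene_counts)
  utils::write.table(study$srna$reads, paths$srna_reads, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_jaspar_pfm(list(demo_motif = study$pfm), paths$pfm)
  for (grp in names(study$methylomes$sites)) {
    for (i in seq_along(study$methylomes$sites[[grp]])) {
      p <- file.path(dir, sprintf("meth_%s_%d.tsv", grp, i))
      write_cytosine_report(study$methylomes$sites[[grp]][[i]], p)
      paths[[sprintf("meth_%s_%d", grp, i)]] <- p
    }
  }
  invisible(paths)
}

#' Write PFMs in JASPAR text format
#' @param pfms named list of 4 x L matrices.
#' @param path output file.
#' @export
write_jaspar_pfm <- function(pfms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(pfms)) {
    writeLines(sprintf(">%s", id), con)
    m <- pfms[[id]]
    for (b in c("A", "C", "G", "T")) {
      writeLines(sprintf("%s  [ %s ]", b,
                         paste(format(m[b, ], trim = TRUE), collapse = " ")), con)
    }
  }
  invisible(path)
}
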
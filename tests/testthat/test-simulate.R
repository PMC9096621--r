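# The synthetic-study generator: determinism, placement structure,
# methylation law, planted effects.

test_that("genome simulation is byte-identical under one seed", {
  cfg <- sim_config(n_chroms = 2L, chrom_len = 50000L, n_genes = 10L,
                    n_tes = 5L, seed = 7L)
  s1 <- simulate_genome(cfg)
  s2 <- simulate_genome(cfg)
  expect_identical(as.character(s1$genome), as.character(s2$genome))
  expect_identical(s1$annotation, s2$annotation)
  # and the whole study is reproducible end to end
  cfg2 <- sim_config(n_chroms = 1L, chrom_len = 40000L, n_genes = 8L,
                     n_tes = 4L, n_srna_loci = 20L, seed = 12L)
  st1 <- simulate_study(cfg2)
  st2 <- simulate_study(cfg2)
  expect_identical(as.character(st1$genome), as.character(st2$genome))
  expect_identical(st1$gene_counts$cm$counts, st2$gene_counts$cm$counts)
  expect_identical(st1$methylomes$sites$ref[[1]],
                   st2$methylomes$sites$ref[[1]])
  expect_identical(st1$srna$reads, st2$srna$reads)
})

test_that("genes concentrate on chromosome arms, TEs in the middle", {
  mid_gene <- 0; out_gene <- 0; mid_te <- 0; out_te <- 0
  for (sd in 1:20) {
    cfg <- sim_config(n_chroms = 1L, chrom_len = 150000L, n_genes = 25L,
                      n_tes = 25L, seed = sd)
    ann <- simulate_genome(cfg)$annotation
    mids <- (ann$start + ann$end) / 2
    third <- cfg$chrom_len / 3
    inner <- mids > third & mids < 2 * third
    mid_gene <- mid_gene + sum(inner & ann$feature_class == "gene")
    out_gene <- out_gene + sum(!inner & ann$feature_class == "gene")
    mid_te <- mid_te + sum(inner & ann$feature_class == "TE")
    out_te <- out_te + sum(!inner & ann$feature_class == "TE")
  }
  expect_lt(mid_gene, out_gene)
  expect_gt(mid_te, out_te)
  # features never overlap
  cfg <- sim_config(n_chroms = 1L, chrom_len = 150000L, n_genes = 30L,
                    n_tes = 20L, seed = 99L)
  ann <- simulate_genome(cfg)$annotation
  ov <- interval_overlaps(ann, ann)
  expect_true(all(ov$query == ov$subject))
  # n_genes = 0 -> only TEs
  cfg0 <- sim_config(n_chroms = 1L, chrom_len = 50000L, n_genes = 0L,
                     n_tes = 10L, seed = 1L)
  expect_true(all(simulate_genome(cfg0)$annotation$feature_class == "TE"))
})

test_that("simulated GC content is near the configured value", {
  cfg <- sim_config(n_chroms = 1L, chrom_len = 100000L, n_genes = 0L,
                    n_tes = 0L, seed = 3L)
  g <- simulate_genome(cfg)$genome
  gc <- Biostrings::letterFrequency(g[[1]], "GC", as.prob = TRUE)
  expect_equal(unname(gc), 0.36, tolerance = 0.02)
})

test_that("methylome emulates the context means and planted deltas", {
  cfg <- sim_config(n_chroms = 1L, chrom_len = 150000L, n_genes = 30L,
                    n_tes = 10L, dmr_fraction = 0.3, dmr_delta = 0.15,
                    dmr_contexts = "CG", coverage_mean = 20, seed = 41L)
  sim <- simulate_genome(cfg)
  m <- simulate_methylomes(sim, cfg)
  s <- m$sites$ref[[1]]
  lev <- function(x, ctx) {
    sel <- x$context == ctx
    sum(x$meth[sel]) / sum(x$total[sel])
  }
  expect_equal(lev(s, "CG"), 0.80, tolerance = 0.02)
  expect_equal(lev(s, "CHG"), 0.67, tolerance = 0.02)
  expect_equal(lev(s, "CHH"), 0.23, tolerance = 0.02)
  # context labels agree with the genome sequence
  idx <- sample(nrow(s), 200)
  expect_equal(assign_context(sim$genome, s$chrom[idx], s$pos[idx],
                              s$strand[idx]), s$context[idx])
  # planted regions show the shift when recomputed from the emitted reports
  t <- m$sites$test[[1]]
  key_s <- paste(s$pos, s$strand); key_t <- paste(t$pos, t$strand)
  deltas <- vapply(seq_len(nrow(m$truth)), function(i) {
    reg <- m$truth[i, ]
    ins <- s$pos >= reg$start & s$pos < reg$end & s$context == reg$context
    int <- t$pos >= reg$start & t$pos < reg$end & t$context == reg$context
    sum(t$meth[int]) / sum(t$total[int]) - sum(s$meth[ins]) / sum(s$total[ins])
  }, numeric(1))
  expect_equal(mean(deltas), 0.15, tolerance = 0.05)
})

test_that("null methylomes differ only by sampling noise", {
  cfg <- sim_config(n_chroms = 1L, chrom_len = 100000L, n_genes = 20L,
                    n_tes = 5L, dmr_fraction = 0, coverage_mean = 20,
                    seed = 43L)
  sim <- simulate_genome(cfg)
  m <- simulate_methylomes(sim, cfg)
  a <- m$sites$ref[[1]]; b <- m$sites$test[[1]]
  diff <- sum(a$meth) / sum(a$total) - sum(b$meth) / sum(b$total)
  expect_lt(abs(diff), 0.01)
  expect_equal(nrow(m$truth), 0L)
})

test_that("count simulation plants recoverable fold changes", {
  cfg <- sim_config(deg_fraction = 0.2, deg_lfc = 2, seed = 47L)
  sc <- simulate_counts(sprintf("f%03d", 1:400), cfg)
  z <- sweep(sc$cm$counts, 2, sc$cm$lib_sizes / mean(sc$cm$lib_sizes), "/")
  is_test <- sc$groups == "test"
  ratio <- (rowMeans(z[, is_test]) + 0.1) / (rowMeans(z[, !is_test]) + 0.1)
  up <- sc$truth$feature_id[sc$truth$lfc > 0]
  dn <- sc$truth$feature_id[sc$truth$lfc < 0]
  # total-count scaling carries a composition bias when planted DEGs are
  # unbalanced, so planted ratios are judged relative to the null median
  nulls <- setdiff(rownames(z)[rowMeans(z) > 20], sc$truth$feature_id)
  base_r <- median(ratio[nulls])
  expect_equal(median(ratio[up]) / base_r, 4, tolerance = 0.25)
  expect_equal(median(ratio[dn]) / base_r, 0.25, tolerance = 0.25)
  # without planted DEGs the null ratio sits at 1
  cfg_n <- sim_config(deg_fraction = 0, seed = 48L)
  sc_n <- simulate_counts(sprintf("f%03d", 1:400), cfg_n)
  z_n <- sweep(sc_n$cm$counts, 2,
               sc_n$cm$lib_sizes / mean(sc_n$cm$lib_sizes), "/")
  r_n <- (rowMeans(z_n[, sc_n$groups == "test"]) + 0.1) /
    (rowMeans(z_n[, sc_n$groups == "ref"]) + 0.1)
  expect_equal(median(r_n[rowMeans(z_n) > 20]), 1, tolerance = 0.1)
  # deg_fraction = 0 -> no truth rows
  cfg0 <- sim_config(deg_fraction = 0, seed = 2L)
  expect_equal(nrow(simulate_counts(c("a", "b", "c"), cfg0)$truth), 0L)
})

test_that("sRNA reads respect length bounds and planted accumulation", {
  cfg <- sim_config(n_chroms = 1L, chrom_len = 200000L, n_genes = 10L,
                    n_tes = 5L, n_srna_loci = 60L, srna_diff_fraction = 0.2,
                    srna_lfc = 2, seed = 53L)
  sim <- simulate_genome(cfg)
  sr <- simulate_srna_reads(sim, cfg)
  len <- sr$reads$end - sr$reads$start
  expect_true(all(len >= 18L & len <= 24L))
  expect_equal(sort(unique(sr$reads$sample)),
               c("ref_1", "ref_2", "ref_3", "test_1", "test_2", "test_3"))
  # reads fall inside their loci; differential loci shift by ~4x
  cl <- call_clusters(sr$reads, min_reads = 5L)
  cm <- cluster_count_matrix(cl)
  ov <- interval_overlaps(cl, sr$truth)
  expect_gt(nrow(ov), 0L)
})

test_that("motif landscape nulls and extremes behave as planted", {
  base_cfg <- function(p_extra) {
    sim_config(n_chroms = 1L, chrom_len = 100000L, n_genes = 25L,
               n_tes = 0L, motif_p_extra = p_extra,
               motif_tss_window = 1000L, motif_rate_bg = 0.8, seed = 59L)
  }
  pfm <- photoepi:::default_pfm()
  cfg1 <- base_cfg(1)
  sim <- simulate_genome(cfg1)
  ml <- simulate_motif_landscape(sim, pfm, cfg1, embed = FALSE)
  # p_extra = 1, window 1 kb: every enriched gene has a hit within 1 kb
  near <- tapply(ml$hits$distance, ml$hits$gene_id, min)
  expect_true(all(ml$truth %in% names(near)[near < 1000]))
  # the enriched set's distance histogram peaks below the window
  enr_d <- ml$hits$distance[ml$hits$gene_id %in% ml$truth]
  expect_gt(mean(enr_d < 1000), mean(ml$hits$distance < 1000) / 2)
  # window wider than the scanned region is rejected
  expect_error(sim_config(motif_tss_window = 30000L), "motif_tss_window")
})
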
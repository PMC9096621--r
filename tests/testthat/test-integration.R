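# Cross-omics integration statistics.

fake_de <- function(ids, lfc, status) {
  out <- data.frame(feature_id = ids, log2_fc = lfc, mean_cpm = 100,
                    dispersion = 0.05, p = ifelse(status == "ns", 0.5, 1e-4),
                    q = ifelse(status == "ns", 0.8, 1e-3), status = status,
                    stringsAsFactors = FALSE)
  class(out) <- c("de_results", "data.frame")
  out
}

fake_dm <- function(ids, status, diff = 0.2, context = "CG") {
  out <- data.frame(region_id = ids, context = context,
                    meth_level_a = 0.5, meth_level_b = 0.5 + diff,
                    diff = ifelse(status == "ns", 0, diff),
                    n_covered_c = 30L, n_dmc = 12L,
                    p = ifelse(status == "ns", 0.5, 1e-5),
                    q = ifelse(status == "ns", 0.7, 1e-4),
                    status = status, stringsAsFactors = FALSE)
  class(out) <- c("dm_calls", "data.frame")
  out
}

test_that("DEG x DMP overlap percentages follow the joined counts", {
  ids <- sprintf("g%02d", 1:20)
  de <- fake_de(ids, lfc = rep(c(2, 0), each = 10),
                status = rep(c("up", "ns"), each = 10))
  dm <- fake_dm(ids, status = c(rep("hyper", 4), rep("ns", 12),
                                rep("hypo", 4)))
  ov <- overlap_deg_dmp(de, dm)
  expect_equal(ov$n_deg, 10L)
  expect_equal(ov$n_dmp, 8L)
  expect_equal(ov$n_both, 4L)
  expect_equal(ov$pct_deg_with_dmp, 40)
  expect_equal(ov$pct_dmp_that_are_deg, 50)
  expect_true(ov$n_both <= min(ov$n_deg, ov$n_dmp))
  # disjoint significance sets -> zero overlap
  dm2 <- fake_dm(ids, status = c(rep("ns", 10), rep("hyper", 10)))
  de2 <- fake_de(ids, lfc = rep(c(2, 0), each = 10),
                 status = rep(c("up", "ns"), each = 10))
  expect_equal(overlap_deg_dmp(de2, dm2)$n_both, 0L)
  # non-intersecting universes are an error
  expect_error(overlap_deg_dmp(fake_de("x1", 0, "ns"), dm), "intersect")
})

test_that("planted DMRs on DEG promoters raise the DEG-with-DMP rate", {
  cfg <- sim_config(n_chroms = 2L, chrom_len = 150000L, n_genes = 50L,
                    n_tes = 10L, dmr_fraction = 0.2, dmr_delta = -0.35,
                    dmr_contexts = "CG", deg_fraction = 0.3, seed = 61L)
  st <- simulate_study(cfg, couple_dmr_to_deg = TRUE)
  chrom_lens <- stats::setNames(Biostrings::width(st$genome),
                                names(st$genome))
  genes <- st$annotation[st$annotation$feature_class == "gene", ]
  prom <- promoter_regions(genes, chrom_lens = chrom_lens)
  dm <- call_region_dm(st$methylomes$sites$ref[[1]],
                       st$methylomes$sites$test[[1]], prom, "CG")
  de <- nb_test(cpm_filter(st$gene_counts$cm, groups = st$gene_counts$groups),
                st$gene_counts$groups)
  ov <- overlap_deg_dmp(de, dm)
  # DMPs were planted only on DEG promoters, so the enrichment is extreme
  null_rate <- 100 * ov$n_dmp / nrow(prom)
  expect_gt(ov$pct_deg_with_dmp, null_rate)
  expect_gt(ov$n_both, 0L)
})

test_that("sRNA/methylation association matches the Fisher oracle", {
  # construct cluster-level results giving the table [[30,10],[10,50]]
  n <- 100
  ids <- sprintf("c%03d", 1:n)
  acc <- c(rep(TRUE, 40), rep(FALSE, 60))
  meth <- c(rep(TRUE, 30), rep(FALSE, 10), rep(TRUE, 10), rep(FALSE, 50))
  de <- fake_de(ids, lfc = ifelse(acc, 2, 0),
                status = ifelse(acc, "up", "ns"))
  dm <- fake_dm(ids, status = ifelse(meth, "hyper", "ns"), diff = 0.2)
  as <- srna_methylation_association(de, dm)
  expect_equal(as.vector(as$table), c(30L, 10L, 10L, 50L))
  expect_equal(as$p, fisher_oracle(30L, 10L, 10L, 50L), tolerance = 1e-10)
  expect_equal(as$odds_ratio, 30 * 50 / (10 * 10))
  # the 5% floor: significant but small diffs do not count as methylated
  dm_small <- fake_dm(ids, status = ifelse(meth, "hyper", "ns"),
                      diff = 0.04)
  as2 <- srna_methylation_association(de, dm_small)
  expect_equal(sum(as2$table[, "diff_meth"]), 0L)
  # zero-coverage clusters are excluded from the universe
  dm3 <- dm; dm3$n_covered_c[1:10] <- 0L
  as3 <- srna_methylation_association(de, dm3)
  expect_equal(as3$n, 90L)
})

test_that("association axes are exchangeable (Fisher symmetry)", {
  set.seed(67)
  n <- 80
  ids <- sprintf("c%03d", 1:n)
  acc <- sample(c(TRUE, FALSE), n, TRUE)
  meth <- sample(c(TRUE, FALSE), n, TRUE)
  de_a <- fake_de(ids, ifelse(acc, 1, 0), ifelse(acc, "up", "ns"))
  dm_a <- fake_dm(ids, ifelse(meth, "hyper", "ns"), diff = 0.3)
  de_b <- fake_de(ids, ifelse(meth, 1, 0), ifelse(meth, "up", "ns"))
  dm_b <- fake_dm(ids, ifelse(acc, "hyper", "ns"), diff = 0.3)
  expect_equal(srna_methylation_association(de_a, dm_a)$p,
               srna_methylation_association(de_b, dm_b)$p,
               tolerance = 1e-12)
})

test_that("WMW test: exact enumeration, ties, and normal approximation", {
  r <- wmw_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$u, 0)
  expect_equal(r$p, 0.1)   # 2/20 assignments as extreme
  expect_equal(wmw_test(c(2, 2, 2), c(2, 2, 2))$p, 1)
  # exact path agrees with stats::wilcox.test when there are no ties
  set.seed(71)
  x <- rnorm(6); y <- rnorm(7) + 0.5
  expect_equal(wmw_test(x, y)$p,
               stats::wilcox.test(x, y, exact = TRUE)$p.value,
               tolerance = 1e-10)
  # normal-approximation path tracks the exact distribution near n = 20
  for (i in 1:5) {
    x <- rnorm(20); y <- rnorm(20) + 0.3
    pn <- wmw_test(x, y, exact_max = 8L)$p
    pe <- stats::wilcox.test(x, y, exact = TRUE)$p.value
    expect_lt(abs(pe - pn), 0.01)
  }
})

test_that("gene-body sRNA shifts with DEG direction when planted", {
  # genes up-regulated carry gene-body clusters with positive lfc;
  # promoter clusters stay null in both directions
  set.seed(73)
  genes <- sprintf("g%02d", 1:40)
  de <- fake_de(genes, lfc = rep(c(2, -2), 20),
                status = rep(c("up", "down"), 20))
  cl <- data.frame(cluster_id = sprintf("c%02d", 1:80), chrom = "chr1",
                   start = seq(0L, 7900L, by = 100L),
                   end = seq(50L, 7950L, by = 100L),
                   category = rep(c("gene_body", "promoter"), each = 40),
                   linked_gene = c(genes, genes),
                   stringsAsFactors = FALSE)
  gb_lfc <- rep(c(1.5, -1.5), 20) + rnorm(40, 0, 0.1)
  p_lfc <- rnorm(40, 0, 0.1)
  cde <- fake_de(cl$cluster_id, c(gb_lfc, p_lfc), status = "ns")
  res <- gb_vs_promoter_srna(de, cl, cde)
  up_row <- res[res$contrast == "up_vs_down" & res$stratum == "gene_body", ]
  expect_lt(up_row$p, 1e-4)
  p_row <- res[res$contrast == "up_vs_down" & res$stratum == "promoter", ]
  expect_gt(p_row$p, 0.05)
  # within the up stratum, promoter vs gene body separates too
  loc_row <- res[res$contrast == "promoter_vs_gene_body" &
                   res$stratum == "up", ]
  expect_lt(loc_row$p, 1e-3)
  # tiny strata are reported untested
  res2 <- gb_vs_promoter_srna(de[1:2, ], cl[c(1, 41), ], cde)
  expect_true(all(is.na(res2$p)))
})

test_that("category distribution applies the 2% display floor", {
  genes <- sprintf("g%03d", 1:100)
  map <- data.frame(gene_id = genes,
                    category = c(rep("photosynthesis", 50),
                                 rep("hormone", 30), rep("cell wall", 19),
                                 "rna biosynthesis"),
                    stringsAsFactors = FALSE)
  cd <- category_distribution(genes, map)
  expect_equal(cd$fraction[cd$category == "photosynthesis"], 0.5)
  expect_true("other" %in% cd$category)  # the 1% category is collapsed
  expect_false("rna biosynthesis" %in% cd$category)
  expect_equal(sum(cd$fraction), 1)
  expect_error(category_distribution(character(0), map), "empty")
  expect_warning(category_distribution(c(genes, sprintf("x%03d", 1:120)),
                                       map), "covers only")
})
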
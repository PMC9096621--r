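# Context assignment, per-cytosine tests, region calls, bin profiles.

test_that("context assignment matches the exhaustive trinucleotide table", {
  # enumerate all 16 C-starting trinucleotides on the + strand:
  # CGx -> CG (4), C[ACT]G -> CHG (3), C[ACT][ACT] -> CHH (9)
  bases <- c("A", "C", "G", "T")
  combos <- expand.grid(b2 = bases, b3 = bases, stringsAsFactors = FALSE)
  got <- vapply(seq_len(nrow(combos)), function(i) {
    seq <- paste0("A", "C", combos$b2[i], combos$b3[i], "A")
    g <- Biostrings::DNAStringSet(c(chr = seq))
    assign_context(g, "chr", 1L, "+")
  }, character(1))
  oracle <- ifelse(combos$b2 == "G", "CG",
                   ifelse(combos$b3 == "G", "CHG", "CHH"))
  expect_equal(got, oracle)
  expect_equal(unname(table(got)[c("CG", "CHG", "CHH")]),
               table(oracle)[c("CG", "CHG", "CHH")], ignore_attr = TRUE)

  # and the same rule through the reverse complement on the - strand
  got_minus <- vapply(seq_len(nrow(combos)), function(i) {
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(paste0("AC", combos$b2[i], combos$b3[i], "A"))))
    g <- Biostrings::DNAStringSet(c(chr = rc))
    assign_context(g, "chr", 3L, "-")
  }, character(1))
  expect_equal(got_minus, oracle)
})

test_that("context assignment handles chromosome edges and non-C errors", {
  g <- Biostrings::DNAStringSet(c(chr = "GCAC"))
  expect_equal(assign_context(g, "chr", 3L, "+"), "CHH")  # C at last base
  expect_equal(assign_context(g, "chr", 0L, "-"), "CHH")  # G at first base
  expect_error(assign_context(g, "chr", 0L, "+"), "not a cytosine")
})

test_that("per-cytosine Fisher test equals hypergeometric enumeration", {
  r <- test_cytosine(10L, 10L, 0L, 10L)
  expect_equal(r$p, 2 / choose(20, 10), tolerance = 1e-12)
  expect_equal(test_cytosine(5L, 10L, 5L, 10L)$p, 1)
  expect_equal(test_cytosine(5L, 10L, 5L, 10L)$diff, 0)
  # all tables with margins <= 15 against the enumeration oracle
  for (ta in c(4L, 9L, 15L)) {
    for (tb in c(5L, 12L)) {
      for (ma in 0:ta) {
        for (mb in 0:tb) {
          expect_equal(test_cytosine(ma, ta, mb, tb)$p,
                       fisher_oracle(ma, ta - ma, mb, tb - mb),
                       tolerance = 1e-10)
        }
      }
    }
  }
  expect_error(test_cytosine(0L, 0L, 1L, 2L), "zero-coverage")
})

test_that("fisher2x2 agrees with stats::fisher.test", {
  set.seed(7)
  for (i in 1:40) {
    tab <- matrix(rpois(4, 8), 2)
    expect_equal(fisher2x2(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]),
                 stats::fisher.test(tab)$p.value, tolerance = 1e-9)
  }
})

test_that("promoter regions are 2 kb upstream, strand-aware, clipped", {
  genes <- data.frame(gene_id = c("a", "b", "c"),
                      chrom = "chr1", start = c(5000L, 5000L, 500L),
                      end = c(8000L, 8000L, 900L),
                      strand = c("+", "-", "+"),
                      feature_class = "gene", stringsAsFactors = FALSE)
  p <- promoter_regions(genes)
  expect_equal(p$start[p$gene_id == "a"], 3000L)
  expect_equal(p$end[p$gene_id == "a"], 5000L)
  expect_equal(p$start[p$gene_id == "b"], 8000L)
  expect_equal(p$end[p$gene_id == "b"], 10000L)
  expect_equal(p$start[p$gene_id == "c"], 0L)   # clipped at chromosome start
  expect_equal(p$end[p$gene_id == "c"], 500L)
  # zero-length promoter dropped with warning
  g0 <- data.frame(gene_id = "z", chrom = "chr1", start = 0L, end = 10L,
                   strand = "+", feature_class = "gene",
                   stringsAsFactors = FALSE)
  expect_warning(p0 <- promoter_regions(g0), "zero-length")
  expect_equal(nrow(p0), 0L)
  # - strand clipping at chromosome end
  p2 <- promoter_regions(genes[2, ], chrom_lens = c(chr1 = 9000L))
  expect_equal(p2$end, 9000L)
})

test_that("region DM calls apply the FDR and >=10-DMC rules", {
  # region 1: 12 strongly differential CGs; region 2: 9 strongly
  # differential CGs (below the DMC floor); region 3: null
  pos1 <- 0:11; pos2 <- 100:108; pos3 <- 200:219
  sites_a <- make_sites("chr1", c(pos1, pos2, pos3),
                        meth = c(rep(0L, 21), rep(10L, 20)), total = 20L)
  sites_b <- make_sites("chr1", c(pos1, pos2, pos3),
                        meth = c(rep(20L, 21), rep(10L, 20)), total = 20L)
  regions <- data.frame(region_id = c("r1", "r2", "r3"), chrom = "chr1",
                        start = c(0L, 100L, 200L), end = c(50L, 150L, 250L),
                        stringsAsFactors = FALSE)
  dm <- call_region_dm(sites_a, sites_b, regions, "CG")
  expect_equal(dm$status, c("hyper", "ns", "ns"))
  expect_equal(dm$n_dmc, c(12L, 9L, 0L))
  expect_equal(dm$n_covered_c, c(12L, 9L, 20L))
  expect_equal(dm$diff, c(1, 1, 0))
  # r2 is significant by q but blocked by the DMC floor
  expect_lt(dm$q[2], 0.05)
  # lowering the floor promotes r2
  dm2 <- call_region_dm(sites_a, sites_b, regions, "CG", min_dmc = 5L)
  expect_equal(dm2$status[2], "hyper")
})

test_that("swapping groups flips every DM status and negates diff", {
  cfg <- sim_config(n_chroms = 1L, chrom_len = 250000L, n_genes = 40L,
                    n_tes = 10L, dmr_fraction = 0.3, dmr_delta = -0.3,
                    dmr_contexts = "CG", seed = 21L)
  sim <- simulate_genome(cfg)
  m <- simulate_methylomes(sim, cfg)
  chrom_lens <- stats::setNames(Biostrings::width(sim$genome),
                                names(sim$genome))
  prom <- promoter_regions(sim$annotation, chrom_lens = chrom_lens)
  ab <- call_region_dm(m$sites$ref[[1]], m$sites$test[[1]], prom, "CG")
  ba <- call_region_dm(m$sites$test[[1]], m$sites$ref[[1]], prom, "CG")
  expect_equal(ab$diff, -ba$diff)
  expect_equal(ab$p, ba$p)
  flip <- c(hyper = "hypo", hypo = "hyper", ns = "ns")
  expect_equal(unname(flip[ab$status]), ba$status)
})

test_that("region with no covered cytosines is flagged ns, not tested", {
  sites_a <- make_sites("chr1", 0:5, meth = 0L, total = 20L)
  sites_b <- make_sites("chr1", 0:5, meth = 20L, total = 20L)
  regions <- data.frame(region_id = c("hit", "empty"), chrom = "chr1",
                        start = c(0L, 1000L), end = c(10L, 1100L),
                        stringsAsFactors = FALSE)
  dm <- call_region_dm(sites_a, sites_b, regions, "CG", min_dmc = 3L)
  expect_equal(dm$n_covered_c[2], 0L)
  expect_equal(dm$status[2], "ns")
  expect_true(is.na(dm$p[2]))
})

test_that("BH adjustment is monotone and bounded below by raw p", {
  set.seed(3)
  p <- runif(200)^2
  q <- photoepi:::bh_adjust(p)
  expect_true(all(q >= p - 1e-12))
  ord <- order(p)
  expect_true(all(diff(q[ord]) >= -1e-12))
  expect_equal(q, stats::p.adjust(p, "BH"))
})

test_that("bin profile tiles chromosomes and classifies at +/-5%", {
  # 2.5 kb chromosome, 1 kb bins -> [0,1k),[1k,2k),[2k,2.5k)
  pos <- seq(0L, 2400L, by = 20L)
  lev_ref <- rep(0.5, length(pos))
  lev_test <- ifelse(pos < 1000L, 0.5,
                     ifelse(pos < 2000L, 0.57, 0.42))
  sa <- make_sites("chr1", pos, meth = round(lev_ref * 100), total = 100L)
  sb <- make_sites("chr1", pos, meth = round(lev_test * 100), total = 100L)
  ann <- data.frame(gene_id = "te1", chrom = "chr1", start = 1000L,
                    end = 2000L, strand = ".", feature_class = "TE",
                    stringsAsFactors = FALSE)
  bp <- bin_profile(sa, sb, c(chr1 = 2500L), ann, bin_size = 1000L)
  cg <- bp[bp$context == "CG", ]
  expect_equal(cg$bin_start, c(0L, 1000L, 2000L))
  expect_equal(cg$bin_end, c(1000L, 2000L, 2500L))
  expect_equal(cg$status, c("unchanged", "hyper", "hypo"))
  # bin fully covered by the 1 kb TE -> density 1e6 per million
  expect_equal(cg$density_tes, c(0, 1e6, 0))
  # CHH rows exist but have no data: level NA, status NA
  chh <- bp[bp$context == "CHH", ]
  expect_true(all(is.na(chh$meth_level)))
  expect_true(all(is.na(chh$status)))
})

test_that("bin profile uses only cytosines covered in both samples", {
  sa <- make_sites("chr1", c(0L, 10L), meth = c(5L, 100L),
                   total = c(10L, 100L))
  sb <- make_sites("chr1", 0L, meth = 5L, total = 10L)
  bp <- bin_profile(sa, sb, c(chr1 = 100L), bin_size = 100L)
  cg <- bp[bp$context == "CG", ]
  expect_equal(cg$meth_level, 0.5)  # the 10x-in-both site only
})
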
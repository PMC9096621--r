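# Shared fixtures: tiny deterministic genomes, annotations and site tables
# built in code at test time.

# A 2-chromosome toy genome with known sequence content.
toy_genome <- function() {
  Biostrings::DNAStringSet(c(
    chr1 = "ACGTACAGTCATGCGCTAGCTTACGGATCCGATCGATTAGCCGGTACGTA",
    chr2 = "TTTCGGCATCAGCAAGCTTACGCATGCATGGCTAGCTAACGGTACCGGTA"))
}

toy_annotation <- function() {
  data.frame(
    gene_id = c("g1", "g2", "te1"),
    chrom = c("chr1", "chr2", "chr1"),
    start = c(10L, 30L, 35L),
    end = c(30L, 45L, 45L),
    strand = c("+", "-", "."),
    feature_class = c("gene", "gene", "TE"),
    stringsAsFactors = FALSE)
}

# Cytosine site tables for two samples over one region, with controllable
# methylation proportions.
make_sites <- function(chrom, positions, meth, total, context = "CG",
                       strand = "+") {
  data.frame(chrom = chrom, pos = as.integer(positions), strand = strand,
             context = context, meth = as.integer(meth),
             total = as.integer(total), stringsAsFactors = FALSE)
}

# Brute-force two-sided Fisher p by enumerating every table with the
# observed margins (independent oracle for fisher2x2).
fisher_oracle <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; k <- a + c
  p_obs <- stats::dhyper(a, m1, m2, k)
  support <- max(0, k - m2):min(k, m1)
  tot <- 0
  for (x in support) {
    px <- stats::dhyper(x, m1, m2, k)
    if (px <= p_obs * (1 + 1e-7)) tot <- tot + px
  }
  min(tot, 1)
}

# Exhaustive per-gene minimum-distance recomputation (oracle for
# cumulative_fraction).
cumfrac_oracle <- function(hits, gene_set, positions) {
  sapply(positions, function(x) {
    mean(vapply(gene_set, function(g) {
      d <- hits$distance[hits$gene_id == g]
      length(d) > 0 && min(d) <= x
    }, logical(1)))
  })
}
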
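# Differential-methylation machinery: sequence-context assignment,
# per-cytosine Fisher tests, region-level DMP/sCTGR calling, and binned
# chromosome profiles.

#' Assign the methylation sequence context of a cytosine
#'
#' Contexts are CG, CHG and CHH with H = A, C or T. On the + strand the two
#' bases following the cytosine decide; on the - strand the rule is applied
#' to the reverse complement. A cytosine closer than 2 bp to the chromosome
#' end, where the full trinucleotide cannot be read, is classed CHH.
#'
#' @param genome [Biostrings::DNAStringSet].
#' @param chrom chromosome name (vectorised).
#' @param pos 0-based position (vectorised).
#' @param strand `+` or `-` (vectorised).
#' @return character vector of contexts.
#' @export
assign_context <- function(genome, chrom, pos, strand) {
  n <- max(length(chrom), length(pos), length(strand))
  chrom <- rep_len(as.character(chrom), n)
  pos <- rep_len(as.integer(pos), n)
  strand <- rep_len(as.character(strand), n)
  out <- character(n)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    seq <- as.character(genome[[ch]])
    len <- nchar(seq)
    p <- pos[idx]
    s <- strand[idx]
    base <- substring(seq, p + 1L, p + 1L)
    ok <- (s == "+" & base == "C") | (s == "-" & base == "G")
    if (!all(ok)) {
      stop(sprintf("position %s:%d is not a cytosine on strand %s",
                   ch, p[!ok][1], s[!ok][1]))
    }
    nxt1 <- ifelse(s == "+", substring(seq, p + 2L, p + 2L),
                   comp_base(substring(seq, p, p)))
    nxt2 <- ifelse(s == "+", substring(seq, p + 3L, p + 3L),
                   comp_base(substring(seq, p - 1L, p - 1L)))
    ctx <- ifelse(nxt1 == "G", "CG",
                  ifelse(nxt2 == "G", "CHG", "CHH"))
    # off-chromosome neighbours read as "": fall through to CHH
    ctx[nxt1 == "" & s == "+" & p + 1L >= len] <- "CHH"
    out[idx] <- ctx
  }
  out
}

comp_base <- function(b) {
  chartr("ACGTN", "TGCAN", b)
}

# Enumerate all cytosines of a genome on both strands with their contexts.
# Returns chrom, pos (0-based), strand, context.
enumerate_cytosines <- function(genome) {
  res <- list()
  for (ch in names(genome)) {
    seq <- as.character(genome[[ch]])
    bases <- strsplit(seq, "")[[1]]
    pc <- which(bases == "C") - 1L
    pg <- which(bases == "G") - 1L
    df <- data.frame(chrom = ch,
                     pos = c(pc, pg),
                     strand = rep(c("+", "-"), c(length(pc), length(pg))),
                     stringsAsFactors = FALSE)
    df <- df[order(df$pos, df$strand), , drop = FALSE]
    df$context <- assign_context(genome, df$chrom, df$pos, df$strand)
    res[[ch]] <- df
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Per-cytosine differential-methylation test
#'
#' Two-sided Fisher exact test of the 2x2 table
#' `[[meth_a, unmeth_a], [meth_b, unmeth_b]]`, plus the methylation
#' difference `meth_b/total_b - meth_a/total_a`.
#'
#' @param meth_a,total_a,meth_b,total_b equal-length count vectors.
#' @return data.frame with `p` and `diff`.
#' @export
test_cytosine <- function(meth_a, total_a, meth_b, total_b) {
  if (any(total_a <= 0L) || any(total_b <= 0L)) {
    stop("zero-coverage cytosine reached the test; filter on coverage first")
  }
  if (any(meth_a > total_a) || any(meth_b > total_b)) {
    stop("methylated count exceeds total")
  }
  p <- fisher2x2(meth_a, total_a - meth_a, meth_b, total_b - meth_b)
  data.frame(p = p, diff = meth_b / total_b - meth_a / total_a)
}

#' Promoter regions: 2 kb upstream of the TSS
#'
#' For a + strand gene `[s, e)` the promoter is `[max(0, s - length), s)`;
#' for a - strand gene `[e, min(chrom_len, e + length))`. Genes whose
#' promoter is fully clipped away (TSS at a chromosome edge) are dropped
#' with a warning.
#'
#' @param genes annotation data.frame (`gene_id`, `chrom`, `start`, `end`,
#'   `strand`); rows with `feature_class` other than `gene` are ignored.
#' @param length upstream length in bp (default 2000).
#' @param chrom_lens named vector of chromosome lengths, used to clip -
#'   strand promoters; unclipped if omitted.
#' @return data.frame `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @export
promoter_regions <- function(genes, length = 2000L, chrom_lens = NULL) {
  if ("feature_class" %in% names(genes)) {
    genes <- genes[genes$feature_class == "gene", , drop = FALSE]
  }
  if (!all(genes$strand %in% c("+", "-"))) {
    stop("genes must have strand + or - to orient their promoters")
  }
  plus <- genes$strand == "+"
  start <- ifelse(plus, pmax(0L, genes$start - as.integer(length)), genes$end)
  end <- ifelse(plus, genes$start, genes$end + as.integer(length))
  if (!is.null(chrom_lens)) {
    end <- pmin(end, chrom_lens[genes$chrom])
  }
  out <- data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
                    start = as.integer(start), end = as.integer(end),
                    strand = genes$strand, stringsAsFactors = FALSE)
  empty <- out$end <= out$start
  if (any(empty)) {
    warning(sprintf("%d gene(s) with zero-length promoter dropped (TSS at chromosome edge)",
                    sum(empty)))
    out <- out[!empty, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Region-level differential-methylation calls
#'
#' Implements the study's region rule for one context: per-cytosine Fisher
#' tests (BH-adjusted across all tested cytosines) define differentially
#' methylated cytosines (DMCs); a pooled region-level Fisher test
#' (BH-adjusted across regions) defines region significance; a region is
#' called hyper/hypo (by sign of its pooled difference, B minus A) only when
#' region q < `region_fdr` AND it holds at least `min_dmc` DMCs.
#'
#' @param sites_a,sites_b cytosine data.frames (as from
#'   [read_cytosine_report()]) for the reference (A) and test (B) samples.
#' @param regions data.frame with `region_id` (or `gene_id`), `chrom`,
#'   `start`, `end`.
#' @param context one of CG, CHG, CHH.
#' @param min_coverage minimum per-sample coverage for a cytosine to enter
#'   (applied to both samples; sites must be covered in both).
#' @param c_fdr per-cytosine BH threshold defining a DMC.
#' @param region_fdr BH threshold on the pooled region test.
#' @param min_dmc minimum DMCs in the region's context (study rule: 10).
#' @param min_diff_c optional minimum absolute per-cytosine difference for a
#'   DMC (0 = FDR rule only; 0.25 mimics common practice).
#' @return data.frame of class `dm_calls`: one row per region with
#'   `region_id`, `context`, `meth_level_a`, `meth_level_b`, `diff`,
#'   `n_covered_c`, `n_dmc`, `p`, `q`, `status`.
#' @export
call_region_dm <- function(sites_a, sites_b, regions, context,
                           min_coverage = 10L, c_fdr = 0.05,
                           region_fdr = 0.05, min_dmc = 10L,
                           min_diff_c = 0) {
  stopifnot(context %in% c("CG", "CHG", "CHH"))
  rid <- if ("region_id" %in% names(regions)) regions$region_id else regions$gene_id
  if (is.null(rid)) stop("regions need a region_id or gene_id column")
  a <- sites_a[sites_a$context == context & sites_a$total >= min_coverage, ]
  b <- sites_b[sites_b$context == context & sites_b$total >= min_coverage, ]
  key_a <- paste(a$chrom, a$pos, a$strand)
  key_b <- paste(b$chrom, b$pos, b$strand)
  common <- intersect(key_a, key_b)
  a <- a[match(common, key_a), , drop = FALSE]
  b <- b[match(common, key_b), , drop = FALSE]

  # map common cytosines to regions (point overlap)
  csites <- data.frame(chrom = a$chrom, start = a$pos, end = a$pos + 1L)
  ov <- interval_overlaps(csites, regions)
  n <- nrow(regions)
  out <- data.frame(region_id = rid, context = context,
                    meth_level_a = NA_real_, meth_level_b = NA_real_,
                    diff = NA_real_, n_covered_c = 0L, n_dmc = 0L,
                    p = NA_real_, q = NA_real_, status = "ns",
                    stringsAsFactors = FALSE)

  if (nrow(ov) > 0L) {
    # per-cytosine tests on every region-assigned cytosine, BH over all
    ci <- sort(unique(ov$query))
    ct <- test_cytosine(a$meth[ci], a$total[ci], b$meth[ci], b$total[ci])
    q_c <- bh_adjust(ct$p)
    is_dmc <- q_c < c_fdr & abs(ct$diff) >= min_diff_c
    dmc_lookup <- integer(0)
    dmc_lookup[ci] <- seq_along(ci)

    reg_split <- split(ov$query, ov$subject)
    ri <- as.integer(names(reg_split))
    pooled <- t(vapply(reg_split, function(ix) {
      c(sum(a$meth[ix]), sum(a$total[ix]), sum(b$meth[ix]), sum(b$total[ix]),
        length(ix), sum(is_dmc[dmc_lookup[ix]]))
    }, numeric(6)))
    out$n_covered_c[ri] <- as.integer(pooled[, 5])
    out$n_dmc[ri] <- as.integer(pooled[, 6])
    out$meth_level_a[ri] <- pooled[, 1] / pooled[, 2]
    out$meth_level_b[ri] <- pooled[, 3] / pooled[, 4]
    out$diff[ri] <- out$meth_level_b[ri] - out$meth_level_a[ri]
    out$p[ri] <- fisher2x2(pooled[, 1], pooled[, 2] - pooled[, 1],
                           pooled[, 3], pooled[, 4] - pooled[, 3])
  }
  tested <- !is.na(out$p)
  out$q[tested] <- bh_adjust(out$p[tested])
  sig <- tested & out$q < region_fdr & out$n_dmc >= min_dmc & out$diff != 0
  out$status[sig] <- ifelse(out$diff[sig] > 0, "hyper", "hypo")
  class(out) <- c("dm_calls", "data.frame")
  out
}

#' Binned chromosome methylation profile and feature densities
#'
#' Tiles every chromosome into `bin_size` windows (last bin may be short)
#' and reports, per context, the pooled methylation level
#' `sum(meth)/sum(total)` for each sample set, the difference versus the
#' reference, a hypo/hyper/unchanged classification at +/-5%, and gene/TE
#' densities as nucleotides covered per million.
#'
#' Only cytosines covered at least `min_coverage` in BOTH samples enter the
#' comparison, matching the common-cytosine rule for between-genotype
#' profiles.
#'
#' @param sites_ref,sites_test cytosine data.frames for reference and test.
#' @param chrom_lens named vector of chromosome lengths.
#' @param annotation gene/TE annotation data.frame.
#' @param bin_size bin width in bp (default 1e6).
#' @param min_coverage per-sample coverage floor (default 10).
#' @param diff_threshold classification threshold (default 0.05).
#' @return data.frame with one row per bin x context.
#' @export
bin_profile <- function(sites_ref, sites_test, chrom_lens, annotation = NULL,
                        bin_size = 1000000L, min_coverage = 10L,
                        diff_threshold = 0.05) {
  key_r <- paste(sites_ref$chrom, sites_ref$pos, sites_ref$strand)
  key_t <- paste(sites_test$chrom, sites_test$pos, sites_test$strand)
  ok_r <- sites_ref$total >= min_coverage
  ok_t <- sites_test$total >= min_coverage
  common <- intersect(key_r[ok_r], key_t[ok_t])
  r <- sites_ref[match(common, key_r), , drop = FALSE]
  t <- sites_test[match(common, key_t), , drop = FALSE]

  bins <- list()
  for (ch in names(chrom_lens)) {
    starts <- seq(0L, chrom_lens[[ch]] - 1L, by = bin_size)
    bins[[ch]] <- data.frame(chrom = ch, bin_start = starts,
                             bin_end = pmin(starts + bin_size, chrom_lens[[ch]]),
                             stringsAsFactors = FALSE)
  }
  bins <- do.call(rbind, bins)
  rownames(bins) <- NULL

  dens <- function(feat) {
    d <- numeric(nrow(bins))
    if (is.null(feat) || nrow(feat) == 0L) return(d)
    binsiv <- stats::setNames(bins[, c("chrom", "bin_start", "bin_end")],
                              c("chrom", "start", "end"))
    ov <- interval_overlaps(binsiv, feat)
    if (nrow(ov) > 0L) {
      agg <- tapply(ov$overlap_bp, ov$query, sum)
      d[as.integer(names(agg))] <- as.numeric(agg)
    }
    d / (bins$bin_end - bins$bin_start) * 1e6
  }
  gene_d <- dens(if (!is.null(annotation))
    annotation[annotation$feature_class == "gene", ] else NULL)
  te_d <- dens(if (!is.null(annotation))
    annotation[annotation$feature_class == "TE", ] else NULL)

  res <- list()
  bin_index <- function(chrom, pos) {
    match(paste(chrom, (pos %/% bin_size) * bin_size), paste(bins$chrom, bins$bin_start))
  }
  for (ctx in c("CG", "CHG", "CHH")) {
    sel <- r$context == ctx
    bi <- bin_index(r$chrom[sel], r$pos[sel])
    mr <- tapply(r$meth[sel], bi, sum)
    tr <- tapply(r$total[sel], bi, sum)
    mt <- tapply(t$meth[sel], bi, sum)
    tt <- tapply(t$total[sel], bi, sum)
    lev_r <- rep(NA_real_, nrow(bins)); lev_t <- rep(NA_real_, nrow(bins))
    ix <- as.integer(names(mr))
    lev_r[ix] <- mr / tr
    lev_t[ix] <- as.numeric(mt[names(mr)]) / as.numeric(tt[names(mr)])
    diff <- lev_t - lev_r
    status <- rep(NA_character_, nrow(bins))
    covered <- !is.na(diff)
    status[covered] <- ifelse(diff[covered] < -diff_threshold, "hypo",
                              ifelse(diff[covered] > diff_threshold,
                                     "hyper", "unchanged"))
    res[[ctx]] <- data.frame(bins, context = ctx, meth_level = lev_r,
                             meth_level_test = lev_t, diff_vs_ref = diff,
                             status = status, density_genes = gene_d,
                             density_tes = te_d, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
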
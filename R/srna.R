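# De novo sRNA cluster calling from aligned-read intervals, genomic
# categorisation, and sCTGR methylation linkage. The caller is a coverage-
# island simplification of aligner-native cluster discovery: reads of
# 18-24 nt are unioned across samples, islands closer than `pad` are
# joined, and islands with too few supporting reads are dropped.

#' Call sRNA clusters from read intervals
#'
#' @param reads data.frame with `chrom`, `start`, `end` (0-based half-open)
#'   and `sample`; read length is `end - start`.
#' @param min_len,max_len retained read-length range in nt (default 18-24).
#' @param pad maximum gap joining adjacent islands (default 75 bp).
#' @param min_reads minimum total supporting reads per cluster (default 3).
#' @return data.frame of class `srna_clusters`: `cluster_id`, `chrom`,
#'   `start`, `end`, plus one `n_<sample>` count column per sample.
#' @export
call_clusters <- function(reads, min_len = 18L, max_len = 24L, pad = 75L,
                          min_reads = 3L) {
  len <- reads$end - reads$start
  reads <- reads[len >= min_len & len <= max_len, , drop = FALSE]
  samples <- sort(unique(reads$sample))
  empty <- data.frame(cluster_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(reads) == 0L) {
    class(empty) <- c("srna_clusters", "data.frame")
    return(empty)
  }
  ord <- order(reads$chrom, reads$start, reads$end)
  if (!identical(ord, seq_len(nrow(reads)))) {
    reads <- reads[ord, , drop = FALSE]
  }
  clusters <- list()
  for (ch in unique(reads$chrom)) {
    r <- reads[reads$chrom == ch, , drop = FALSE]
    # merge intervals whose gap to the running island is <= pad
    run_end <- cummax_end <- r$end[1]
    cl_start <- r$start[1]
    starts <- integer(); ends <- integer()
    if (nrow(r) > 1L) {
      for (i in 2L:nrow(r)) {
        if (r$start[i] - run_end <= pad) {
          run_end <- max(run_end, r$end[i])
        } else {
          starts <- c(starts, cl_start); ends <- c(ends, run_end)
          cl_start <- r$start[i]; run_end <- r$end[i]
        }
      }
    }
    starts <- c(starts, cl_start); ends <- c(ends, run_end)
    clusters[[ch]] <- data.frame(chrom = ch, start = starts, end = ends,
                                 stringsAsFactors = FALSE)
  }
  cl <- do.call(rbind, clusters)
  rownames(cl) <- NULL
  counts <- matrix(0L, nrow(cl), length(samples),
                   dimnames = list(NULL, samples))
  ov <- interval_overlaps(cl, reads)
  if (nrow(ov) > 0L) {
    tab <- table(factor(ov$query, levels = seq_len(nrow(cl))),
                 factor(reads$sample[ov$subject], levels = samples))
    counts <- matrix(as.integer(tab), nrow(cl), length(samples),
                     dimnames = list(NULL, samples))
  }
  keep <- rowSums(counts) >= min_reads
  cl <- cl[keep, , drop = FALSE]
  counts <- counts[keep, , drop = FALSE]
  if (nrow(cl) == 0L) {
    class(empty) <- c("srna_clusters", "data.frame")
    return(empty)
  }
  out <- data.frame(cluster_id = sprintf("cl_%s_%d", cl$chrom, cl$start),
                    cl, stringsAsFactors = FALSE)
  colnames(counts) <- paste0("n_", samples)
  out <- cbind(out, counts)
  rownames(out) <- NULL
  class(out) <- c("srna_clusters", "data.frame")
  out
}

#' Per-sample count matrix from called clusters
#' @param clusters output of [call_clusters()].
#' @return a `count_matrix` of cluster read counts.
#' @export
cluster_count_matrix <- function(clusters) {
  cc <- grep("^n_", names(clusters), value = TRUE)
  m <- as.matrix(clusters[, cc, drop = FALSE])
  colnames(m) <- sub("^n_", "", cc)
  rownames(m) <- clusters$cluster_id
  count_matrix(m)
}

#' Categorise sRNA clusters against the annotation
#'
#' Precedence: gene body > promoter > TE > intergenic, with overlap meaning
#' at least `min_overlap` bp of intersection; a body/promoter cluster is
#' linked to the gene with the largest overlap.
#'
#' @param clusters output of [call_clusters()].
#' @param genes gene annotation rows (`feature_class == "gene"`).
#' @param promoters output of [promoter_regions()] (carries `gene_id`).
#' @param tes TE annotation rows.
#' @param min_overlap minimum intersection in bp (default 1).
#' @return `clusters` with added `category` and `linked_gene` columns.
#' @export
categorize_clusters <- function(clusters, genes, promoters, tes,
                                min_overlap = 1L) {
  n <- nrow(clusters)
  category <- rep("intergenic", n)
  linked <- rep(NA_character_, n)
  assign_best <- function(targets, label, link_ids) {
    ov <- interval_overlaps(clusters, targets, min_overlap)
    if (nrow(ov) == 0L) return()
    best <- ov[order(ov$query, -ov$overlap_bp, ov$subject), ]
    best <- best[!duplicated(best$query), ]
    todo <- category[best$query] == "intergenic"
    category[best$query[todo]] <<- label
    if (!is.null(link_ids)) linked[best$query[todo]] <<- link_ids[best$subject[todo]]
  }
  # apply in reverse precedence so the strongest label wins? no —
  # apply in precedence order and never overwrite an assigned cluster
  assign_best(genes, "gene_body", genes$gene_id)
  assign_best(promoters, "promoter", promoters$gene_id)
  assign_best(tes, "TE", NULL)
  clusters$category <- category
  clusters$linked_gene <- linked
  clusters
}

#' Methylation of sRNA cluster-targeted genome regions (sCTGRs)
#'
#' Delegates to [call_region_dm()] with cluster intervals as regions and
#' additionally records whether the pooled methylation difference clears
#' the 5% floor used for sRNA/methylation association.
#'
#' @param clusters output of [call_clusters()].
#' @param sites_a,sites_b cytosine data.frames for the two samples.
#' @param context methylation context.
#' @param min_diff effect-size floor on the pooled difference (default 0.05).
#' @param ... passed to [call_region_dm()].
#' @return `dm_calls` data.frame with an extra logical `ge_min_diff` column.
#' @export
sctgr_methylation <- function(clusters, sites_a, sites_b, context,
                              min_diff = 0.05, ...) {
  regions <- data.frame(region_id = clusters$cluster_id,
                        chrom = clusters$chrom, start = clusters$start,
                        end = clusters$end, stringsAsFactors = FALSE)
  dm <- call_region_dm(sites_a, sites_b, regions, context, ...)
  dm$ge_min_diff <- !is.na(dm$diff) & abs(dm$diff) >= min_diff
  dm
}
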
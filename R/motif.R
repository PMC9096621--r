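# Positional TFBS enrichment: PFM -> log-odds PWM, an exact score-
# distribution threshold by dynamic programming, both-strand scanning of
# upstream regions, cumulative gene-fraction curves, and a permutation
# null for the enrichment score.

#' Convert a position frequency matrix to a log-odds PWM
#'
#' Column counts are turned into probabilities with a pseudocount of
#' `0.25 * epsilon` per base, then into log2 odds against the background.
#'
#' @param pfm 4 x L count matrix with rownames A, C, G, T (as from
#'   [read_jaspar_pfm()]).
#' @param background per-base background probabilities (default uniform).
#' @param epsilon total pseudocount per column (default 1).
#' @return 4 x L numeric matrix of log2-odds scores (bits).
#' @export
pfm_to_pwm <- function(pfm, background = rep(0.25, 4), epsilon = 1) {
  stopifnot(nrow(pfm) == 4L, all(colSums(pfm) > 0))
  if (abs(sum(background) - 1) > 1e-8) stop("background must sum to 1")
  p <- sweep(pfm + 0.25 * epsilon, 2, colSums(pfm) + epsilon, "/")
  lo <- log2(p / background)
  rownames(lo) <- c("A", "C", "G", "T")
  lo
}

#' Exact PWM score threshold for a scan p-value
#'
#' Computes the full distribution of window scores under the background by
#' dynamic programming over motif columns, with scores discretised to
#' `step` bits, and returns the smallest score whose upper-tail probability
#' is below `p_threshold`.
#'
#' @param pwm log-odds matrix from [pfm_to_pwm()].
#' @param p_threshold scan p-value (default 1e-5, the FIMO-style cutoff).
#' @param background per-base background probabilities.
#' @param step score discretisation in bits (default 1e-3).
#' @return scalar score threshold in bits (attribute `tail_p` holds its
#'   achieved tail probability).
#' @export
pwm_score_threshold <- function(pwm, p_threshold = 1e-5,
                                background = rep(0.25, 4), step = 1e-3) {
  si <- round(pwm / step)
  L <- ncol(si)
  # dist over integer scores as a named offset vector
  lo_tot <- sum(apply(si, 2, min))
  hi_tot <- sum(apply(si, 2, max))
  n_states <- hi_tot - lo_tot + 1
  if (n_states > 5e7) stop("PWM score range too wide for DP at this step")
  dist <- numeric(n_states)  # index = score - lo_tot + 1 after all columns
  # forward DP: start with point mass at 0, offset tracks current minimum
  cur <- 1
  cur_lo <- 0
  for (j in seq_len(L)) {
    col <- si[, j]
    new_lo <- cur_lo + min(col)
    new_hi <- cur_lo + length(cur) - 1 + max(col)
    new <- numeric(new_hi - new_lo + 1)
    for (b in 1:4) {
      sh <- cur_lo + col[b] - new_lo
      idx <- seq_along(cur) + sh
      new[idx] <- new[idx] + cur * background[b]
    }
    cur <- new
    cur_lo <- new_lo
  }
  tail <- rev(cumsum(rev(cur)))
  ok <- which(tail < p_threshold)
  if (length(ok) == 0L) {
    thr <- (cur_lo + length(cur)) * step  # above max score: no window passes
    attr(thr, "tail_p") <- 0
    return(thr)
  }
  t_idx <- ok[1]
  thr <- (cur_lo + t_idx - 1) * step
  attr(thr, "tail_p") <- tail[t_idx]
  thr
}

# Score every window of a character sequence against a PWM (columns of
# log-odds); windows containing N score -Inf. Returns numeric vector of
# length nchar(seq) - L + 1 (or length 0 when the sequence is too short).
scan_sequence <- function(seq, pwm) {
  L <- ncol(pwm)
  n <- nchar(seq)
  if (n < L) return(numeric(0))
  code <- match(strsplit(seq, "")[[1]], c("A", "C", "G", "T"))
  nw <- n - L + 1L
  sc <- numeric(nw)
  for (j in seq_len(L)) {
    col <- pwm[, j]
    v <- col[code[j:(j + nw - 1L)]]
    v[is.na(v)] <- -Inf
    sc <- sc + v
  }
  sc
}

reverse_complement_pwm <- function(pwm) {
  out <- pwm[4:1, ncol(pwm):1, drop = FALSE]
  rownames(out) <- c("A", "C", "G", "T")
  out
}

#' Upstream regions for TFBS scanning
#'
#' Like [promoter_regions()] but defaulting to the 20-kb window used for
#' positional enrichment; clipped at chromosome edges (clipped genes keep
#' their shortened region).
#'
#' @param genes gene annotation.
#' @param length upstream window in bp (default 20000).
#' @param chrom_lens named chromosome lengths for clipping.
#' @return data.frame `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @export
upstream_regions <- function(genes, length = 20000L, chrom_lens = NULL) {
  promoter_regions(genes, length = length, chrom_lens = chrom_lens)
}

#' Scan gene upstream regions for PWM hits
#'
#' Both strands of each upstream region are scanned; a window scoring at or
#' above the exact threshold for `p_threshold` is reported with its
#' TSS-relative distance: 0 at the TSS, growing away from the gene, taken
#' from the hit edge nearest the TSS.
#'
#' @param genome [Biostrings::DNAStringSet].
#' @param regions output of [upstream_regions()] (must carry `gene_id` and
#'   `strand` of the owning gene).
#' @param pwm log-odds matrix.
#' @param p_threshold scan p-value (default 1e-5).
#' @param background background probabilities for the threshold DP.
#' @return data.frame `gene_id`, `chrom`, `start`, `end`, `distance`,
#'   `strand_of_hit`, `score`.
#' @export
pwm_scan <- function(genome, regions, pwm, p_threshold = 1e-5,
                     background = rep(0.25, 4)) {
  thr <- pwm_score_threshold(pwm, p_threshold, background)
  pwm_rc <- reverse_complement_pwm(pwm)
  L <- ncol(pwm)
  out <- vector("list", nrow(regions))
  for (i in seq_len(nrow(regions))) {
    reg <- regions[i, ]
    seq <- as.character(Biostrings::subseq(genome[[reg$chrom]],
                                           reg$start + 1L, reg$end))
    if (nchar(seq) < L) next
    hits_i <- list()
    for (strand_of_hit in c("+", "-")) {
      m <- if (strand_of_hit == "+") pwm else pwm_rc
      sc <- scan_sequence(seq, m)
      w <- which(sc >= as.numeric(thr))
      if (length(w) == 0L) next
      hs <- reg$start + w - 1L        # genome 0-based hit start
      he <- hs + L                    # exclusive end
      if (reg$strand == "+") {
        dist <- reg$end - he          # TSS at reg$end
      } else {
        dist <- hs - reg$start        # TSS just before reg$start
      }
      hits_i[[strand_of_hit]] <- data.frame(
        gene_id = reg$gene_id, chrom = reg$chrom, start = hs, end = he,
        distance = as.integer(dist), strand_of_hit = strand_of_hit,
        score = sc[w], stringsAsFactors = FALSE)
    }
    if (length(hits_i)) out[[i]] <- do.call(rbind, hits_i)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L) {
    return(data.frame(gene_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      distance = integer(), strand_of_hit = character(),
                      score = numeric(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Cumulative fraction of genes with a hit within each distance
#'
#' `F(x)` = fraction of `gene_set` having at least one hit at TSS distance
#' `<= x`; evaluated at `positions`.
#'
#' @param hits data.frame with `gene_id` and `distance` (from [pwm_scan()]
#'   or pooled across the PFMs of a TF class).
#' @param gene_set character vector of gene ids (the denominator).
#' @param positions evaluation grid (default 0 to 20000 by 100).
#' @return data.frame `position`, `fraction`.
#' @export
cumulative_fraction <- function(hits, gene_set,
                                positions = seq(0L, 20000L, by = 100L)) {
  if (length(gene_set) == 0L) stop("empty gene set")
  md <- min_hit_distance(hits, gene_set)
  data.frame(position = positions,
             fraction = vapply(positions, function(x) mean(md <= x),
                               numeric(1)))
}

# Per-gene minimum hit distance; Inf for genes without hits.
min_hit_distance <- function(hits, gene_set) {
  md <- rep(Inf, length(gene_set))
  names(md) <- gene_set
  if (nrow(hits) > 0L) {
    agg <- tapply(hits$distance, hits$gene_id, min)
    common <- intersect(names(agg), gene_set)
    md[common] <- agg[common]
  }
  md
}

#' Positional enrichment of motif hits in a regulated gene set
#'
#' The enrichment score at each position is the difference between the
#' cumulative motif-bearing fraction of the regulated set and that of all
#' genes; the summary statistic is its maximum over positions. The null is
#' built from `n_perm` random gene subsets of the same size (drawn without
#' replacement from `all_genes`), giving a z-score and a permutation
#' p-value `(1 + #{null >= observed}) / (n_perm + 1)`.
#'
#' @param hits pooled hit table for one TF class.
#' @param regulated_set character vector, subset of `all_genes`.
#' @param all_genes every gene with an annotated TSS.
#' @param positions evaluation grid.
#' @param n_perm number of permutations (default 1000).
#' @param seed RNG seed (required for reproducibility).
#' @param summary how to reduce the ES curve: `max` (default), `mean`, or
#'   `at`, using position `at_position`.
#' @param at_position position used when `summary = "at"`.
#' @return list of class `enrichment_result`: `positions`, `frac_set`,
#'   `frac_all`, `es`, `summary_es`, `z`, `p_perm`, `n_perm`, `null_es`.
#' @export
enrichment_test <- function(hits, regulated_set, all_genes,
                            positions = seq(0L, 20000L, by = 100L),
                            n_perm = 1000L, seed = 1L,
                            summary = c("max", "mean", "at"),
                            at_position = NULL) {
  summary <- match.arg(summary)
  if (!all(regulated_set %in% all_genes)) {
    stop("regulated_set must be a subset of all_genes")
  }
  if (length(regulated_set) < 2L) stop("regulated_set too small")
  md_all <- min_hit_distance(hits, all_genes)
  reduce <- function(es) {
    switch(summary,
           max = max(es),
           mean = mean(es),
           at = es[which.min(abs(positions - at_position))])
  }
  # F(x) = #{md <= x} / n via findInterval on the sorted distances; genes
  # without hits (md = Inf) never enter the count
  frac_curve <- function(md) {
    findInterval(positions, sort(md)) / length(md)
  }
  frac_all <- frac_curve(md_all)
  frac_set <- frac_curve(md_all[regulated_set])
  es <- frac_set - frac_all
  observed <- reduce(es)
  k <- length(regulated_set)
  null_es <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(length(all_genes), k)
      reduce(frac_curve(md_all[idx]) - frac_all)
    }, numeric(1))
  })
  sd_null <- stats::sd(null_es)
  z <- if (sd_null > 0) (observed - mean(null_es)) / sd_null else NA_real_
  p_perm <- (1 + sum(null_es >= observed)) / (n_perm + 1)
  structure(list(positions = positions, frac_set = frac_set,
                 frac_all = frac_all, es = es, summary_es = observed,
                 z = z, p_perm = p_perm, n_perm = n_perm,
                 null_es = null_es),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("positional motif enrichment: summary ES %.4f, z %s, p_perm %.4g (%d permutations)\n",
              x$summary_es,
              if (is.na(x$z)) "NA" else sprintf("%.2f", x$z),
              x$p_perm, x$n_perm))
  invisible(x)
}
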
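# Cross-omics statistics: DEG x DMP overlap accounting, sRNA-accumulation
# x sCTGR-methylation association, promoter- vs gene-body-sRNA effects on
# expression, and functional-category distribution summaries.

#' Overlap between differentially expressed genes and differentially
#' methylated promoters
#'
#' Joins DE results with promoter DM calls on `gene_id`. A gene counts as a
#' DMP when any supplied context's promoter call is non-`ns`.
#'
#' @param de a `de_results` data.frame (gene-level).
#' @param dm_calls a `dm_calls` data.frame, or a list of them (one per
#'   context), with `region_id` equal to gene ids.
#' @return list of class `overlap_summary` with counts, percentages, and
#'   `per_gene` (log2 fold change, promoter diff per context, statuses).
#' @export
overlap_deg_dmp <- function(de, dm_calls) {
  if (inherits(dm_calls, "data.frame")) dm_calls <- list(dm_calls)
  dm_ids <- unique(unlist(lapply(dm_calls, `[[`, "region_id")))
  if (length(intersect(de$feature_id, dm_ids)) == 0L) {
    stop("DE and DM gene-id universes do not intersect")
  }
  per_gene <- data.frame(gene_id = de$feature_id, log2_fc = de$log2_fc,
                         de_status = de$status, stringsAsFactors = FALSE)
  dmp_status <- rep("ns", nrow(per_gene))
  for (dm in dm_calls) {
    ctx <- dm$context[1]
    ix <- match(per_gene$gene_id, dm$region_id)
    per_gene[[paste0("diff_", ctx)]] <- dm$diff[ix]
    per_gene[[paste0("dm_status_", ctx)]] <- dm$status[ix]
    hit <- !is.na(ix) & dm$status[ix] != "ns"
    dmp_status[hit] <- ifelse(dmp_status[hit] == "ns",
                              dm$status[ix][hit], dmp_status[hit])
  }
  per_gene$is_dmp <- dmp_status != "ns"
  per_gene$is_deg <- per_gene$de_status != "ns"
  n_deg <- sum(per_gene$is_deg)
  n_dmp <- sum(per_gene$is_dmp)
  n_both <- sum(per_gene$is_deg & per_gene$is_dmp)
  structure(list(
    n_deg = n_deg, n_dmp = n_dmp, n_both = n_both,
    pct_dmp_that_are_deg = if (n_dmp > 0) 100 * n_both / n_dmp else NA_real_,
    pct_deg_with_dmp = if (n_deg > 0) 100 * n_both / n_deg else NA_real_,
    per_gene = per_gene), class = "overlap_summary")
}

#' @export
print.overlap_summary <- function(x, ...) {
  cat(sprintf("DEG x DMP overlap: %d DEGs, %d DMPs, %d both\n",
              x$n_deg, x$n_dmp, x$n_both))
  cat(sprintf("  %% of DEGs with a DMP: %s\n",
              if (is.na(x$pct_deg_with_dmp)) "NA"
              else sprintf("%.1f", x$pct_deg_with_dmp)))
  cat(sprintf("  %% of DMPs that are DEGs: %s\n",
              if (is.na(x$pct_dmp_that_are_deg)) "NA"
              else sprintf("%.1f", x$pct_dmp_that_are_deg)))
  invisible(x)
}

#' Association between differential sRNA accumulation and sCTGR methylation
#'
#' Builds the 2x2 table [differentially accumulated x differentially
#' methylated] over the clusters covered by both results and applies a
#' two-sided Fisher exact test. "Differentially methylated" requires both a
#' non-`ns` region call and a pooled difference of at least `min_diff`
#' (the 5% floor).
#'
#' @param cluster_de `de_results` for cluster counts.
#' @param cluster_dm `dm_calls` for the same clusters (from
#'   [sctgr_methylation()]); clusters without methylation coverage are
#'   excluded.
#' @param min_diff pooled-difference floor (default 0.05).
#' @return list of class `association_result`: `table` (2x2), `odds_ratio`,
#'   `p`.
#' @export
srna_methylation_association <- function(cluster_de, cluster_dm,
                                         min_diff = 0.05) {
  common <- intersect(cluster_de$feature_id,
                      cluster_dm$region_id[cluster_dm$n_covered_c > 0])
  de <- cluster_de[match(common, cluster_de$feature_id), ]
  dm <- cluster_dm[match(common, cluster_dm$region_id), ]
  acc <- de$status != "ns"
  meth <- dm$status != "ns" & !is.na(dm$diff) & abs(dm$diff) >= min_diff
  tab <- matrix(c(sum(acc & meth), sum(acc & !meth),
                  sum(!acc & meth), sum(!acc & !meth)), 2, 2, byrow = TRUE,
                dimnames = list(acc = c("diff_acc", "ns"),
                                meth = c("diff_meth", "ns")))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("a margin of the association table is zero; p fixed at 1")
    p <- 1
  } else {
    p <- fisher2x2(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
  }
  structure(list(table = tab, odds_ratio = odds_ratio(tab), p = p,
                 n = length(common)), class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("sRNA x methylation association over %d clusters: OR %.2f, Fisher p %.3g\n",
              x$n, x$odds_ratio, x$p))
  print(x$table)
  invisible(x)
}

#' Two-sided Wilcoxon-Mann-Whitney test
#'
#' Exact enumeration over all assignments when both samples have at most
#' `exact_max` observations (ties handled exactly); otherwise the normal
#' approximation with tie correction and continuity correction.
#'
#' @param x,y numeric samples.
#' @param exact_max exact-path size limit per sample (default 8).
#' @return list with `u` (statistic for `x`), `p`.
#' @export
wmw_test <- function(x, y, exact_max = 8L) {
  nx <- length(x); ny <- length(y)
  if (nx == 0L || ny == 0L) stop("empty sample")
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  if (nx <= exact_max && ny <= exact_max) {
    comb <- utils::combn(nx + ny, nx)
    us <- apply(comb, 2, function(ix) sum(r[ix])) - nx * (nx + 1) / 2
    # two-sided: as extreme in either direction around the mean
    dev <- abs(us - nx * ny / 2)
    p <- mean(dev >= abs(u_obs - nx * ny / 2) - 1e-9)
  } else {
    n <- nx + ny
    ties <- table(r)
    sigma2 <- nx * ny / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) return(list(u = u_obs, p = 1))
    # continuity-corrected z with tie-corrected variance
    z <- (abs(u_obs - nx * ny / 2) - 0.5) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-max(z, 0))
  }
  list(u = u_obs, p = min(p, 1))
}

#' Promoter- versus gene-body-sRNA effects on expression
#'
#' For each DEG direction (up, down), collects the log2 fold changes of
#' sRNA clusters linked to those genes, split by cluster location (promoter
#' vs gene body), and tests the two locations against each other with the
#' Wilcoxon-Mann-Whitney test; the up-vs-down contrast within each location
#' is also computed.
#'
#' @param de gene-level `de_results`.
#' @param clusters categorised clusters (from [categorize_clusters()]).
#' @param cluster_de `de_results` for cluster counts.
#' @param min_n minimum observations per side (default 3); smaller strata
#'   are reported untested.
#' @return data.frame with one row per contrast: `contrast`, `stratum`,
#'   `n_1`, `n_2`, `median_1`, `median_2`, `p`.
#' @export
gb_vs_promoter_srna <- function(de, clusters, cluster_de, min_n = 3L) {
  lfc <- cluster_de$log2_fc[match(clusters$cluster_id,
                                  cluster_de$feature_id)]
  de_dir <- de$status[match(clusters$linked_gene, de$feature_id)]
  loc <- clusters$category
  keep <- !is.na(lfc) & !is.na(de_dir) & loc %in% c("promoter", "gene_body")
  lfc <- lfc[keep]; de_dir <- de_dir[keep]; loc <- loc[keep]
  rows <- list()
  run <- function(a, b, contrast, stratum, la, lb) {
    n1 <- length(a); n2 <- length(b)
    p <- if (n1 >= min_n && n2 >= min_n) wmw_test(a, b)$p else NA_real_
    data.frame(contrast = contrast, stratum = stratum,
               group_1 = la, group_2 = lb, n_1 = n1, n_2 = n2,
               median_1 = if (n1) stats::median(a) else NA_real_,
               median_2 = if (n2) stats::median(b) else NA_real_,
               p = p, stringsAsFactors = FALSE)
  }
  for (dir in c("up", "down")) {
    rows[[paste0("loc_", dir)]] <- run(
      lfc[de_dir == dir & loc == "promoter"],
      lfc[de_dir == dir & loc == "gene_body"],
      "promoter_vs_gene_body", dir, "promoter", "gene_body")
  }
  for (l in c("promoter", "gene_body")) {
    rows[[paste0("dir_", l)]] <- run(
      lfc[de_dir == "up" & loc == l],
      lfc[de_dir == "down" & loc == l],
      "up_vs_down", l, "up", "down")
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Functional-category distribution of a gene set
#'
#' Fractions are over categorised genes; categories holding less than
#' `min_fraction` of them are collapsed into `other` (the 2% display
#' rule).
#'
#' @param gene_set character vector of gene ids.
#' @param category_map data.frame with `gene_id` and `category`.
#' @param min_fraction display floor (default 0.02).
#' @return data.frame `category`, `n`, `fraction`, sorted by fraction;
#'   attribute `coverage` holds the categorised fraction of `gene_set`.
#' @export
category_distribution <- function(gene_set, category_map,
                                  min_fraction = 0.02) {
  if (length(gene_set) == 0L) stop("empty gene set")
  cat_ <- category_map$category[match(gene_set, category_map$gene_id)]
  coverage <- mean(!is.na(cat_))
  if (coverage < 0.5) {
    warning(sprintf("category map covers only %.0f%% of the gene set",
                    100 * coverage))
  }
  cat_ <- cat_[!is.na(cat_)]
  if (length(cat_) == 0L) stop("no gene of the set is categorised")
  tab <- table(cat_)
  frac <- as.numeric(tab) / sum(tab)
  keep <- frac >= min_fraction
  out <- data.frame(category = names(tab)[keep], n = as.integer(tab[keep]),
                    fraction = frac[keep], stringsAsFactors = FALSE)
  if (any(!keep)) {
    out <- rbind(out, data.frame(category = "other",
                                 n = sum(tab[!keep]),
                                 fraction = sum(frac[!keep])))
  }
  out <- out[order(-out$fraction), ]
  rownames(out) <- NULL
  attr(out, "coverage") <- coverage
  out
}
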
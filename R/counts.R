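# Two-group negative-binomial differential testing shared by gene-level
# RNA-seq and sRNA-cluster counts: CPM filtering, library-size
# normalisation, moment-based shrunk dispersion, and a likelihood-ratio
# test with the dispersion held fixed.

#' Counts-per-million filter
#'
#' Keeps a feature iff its CPM is at least `min_cpm` in at least
#' `min_samples` samples (the study's "smaller than two per million were
#' removed" rule with `min_cpm = 2`). Library sizes are not recomputed
#' after filtering.
#'
#' @param cm a `count_matrix`.
#' @param min_cpm CPM floor (default 2).
#' @param min_samples number of samples in which the floor must hold;
#'   default: size of the smallest group if `groups` given, else 1.
#' @param groups optional group labels used only for the default
#'   `min_samples`.
#' @return the filtered `count_matrix`.
#' @export
cpm_filter <- function(cm, min_cpm = 2, min_samples = NULL, groups = NULL) {
  stopifnot(inherits(cm, "count_matrix"))
  if (is.null(min_samples)) {
    min_samples <- if (is.null(groups)) 1L else min(table(groups))
  }
  if (min_samples > ncol(cm$counts)) {
    stop("min_samples exceeds the number of samples")
  }
  if (nrow(cm$counts) == 0L) return(cm)
  cpm <- sweep(cm$counts, 2, cm$lib_sizes, "/") * 1e6
  keep <- rowSums(cpm >= min_cpm) >= min_samples
  count_matrix(cm$counts[keep, , drop = FALSE], cm$lib_sizes)
}

#' Counts per million
#' @param cm a `count_matrix`.
#' @return numeric matrix of CPM values.
#' @export
cpm <- function(cm) sweep(cm$counts, 2, cm$lib_sizes, "/") * 1e6

# NB log-likelihood for mean m * s_j and size k, summed over samples.
# y: features x samples matrix; m, k: per-feature vectors; s: per-sample.
nb_loglik <- function(y, m, k, s) {
  mu <- outer(m, s)
  rowSums(lgamma(y + k) - lgamma(k) - lgamma(y + 1) +
            k * log(k / (k + mu)) + y * log(mu / (k + mu) + (y == 0)))
}

# Vectorised MLE of the per-feature mean m with fixed size k and library
# factors s: Newton iterations on log(m). Rows of y with all-zero counts get
# a small positive mean so the log-likelihood stays finite under comparison.
nb_fit_mean <- function(y, k, s) {
  m <- pmax(rowSums(y) / sum(s), 1e-8)
  for (iter in 1:50) {
    mu <- outer(m, s)
    # score and its derivative wrt theta = log m
    u <- rowSums(y - (y + k) * mu / (mu + k))
    h <- rowSums(-(y + k) * mu * k / (mu + k)^2)
    step <- u / pmin(h, -1e-10)
    step <- pmax(pmin(step, 2), -2)
    m_new <- m * exp(-step)
    if (max(abs(log(m_new / m))) < 1e-10) { m <- m_new; break }
    m <- m_new
  }
  m
}

# Moment estimate of the NB dispersion phi from library-size-normalised
# counts, pooled within groups, shrunk 50/50 toward the trimmed-mean common
# dispersion, floored at 1e-4.
# The common dispersion is the (optionally trimmed) mean of the per-feature
# moment estimates. Their distribution is strongly right-skewed, so a
# symmetric trim biases the centre downward and makes the LRT
# anticonservative at small n; the default is therefore no trimming.
estimate_dispersion <- function(y, s, groups, floor = 1e-4, shrink = 0.5,
                                trim = 0) {
  z <- sweep(y, 2, s, "/")
  glev <- unique(groups)
  nf <- nrow(z)
  mu_g <- matrix(0, nf, length(glev))
  var_g <- matrix(0, nf, length(glev))
  df_g <- numeric(length(glev))
  for (j in seq_along(glev)) {
    zg <- z[, groups == glev[j], drop = FALSE]
    mu_g[, j] <- rowMeans(zg)
    var_g[, j] <- rowSums((zg - mu_g[, j])^2) / (ncol(zg) - 1L)
    df_g[j] <- ncol(zg) - 1L
  }
  pooled_var <- as.numeric(var_g %*% df_g) / sum(df_g)
  mu <- rowMeans(mu_g)
  # Var(z) ~ mu/s + phi mu^2; use mean(1/s) for the Poisson part
  pois <- mu * mean(1 / s)
  phi_raw <- pmax((pooled_var - pois) / mu^2, 0)
  phi_raw[!is.finite(phi_raw)] <- 0
  phi_common <- mean(phi_raw, trim = trim)
  pmax(shrink * phi_raw + (1 - shrink) * phi_common, floor)
}

#' Two-group negative-binomial differential test
#'
#' Library sizes are used as total-count scaling factors. Each feature's NB
#' dispersion is estimated by method of moments on normalised counts and
#' shrunk 50/50 toward the trimmed-mean common dispersion (floor 1e-4); a
#' two-sided likelihood-ratio test of equal NB means across the two groups
#' is then performed with that dispersion held fixed (chi-squared, 1 df).
#' Fold changes come from normalised group means with a prior count of 0.5.
#'
#' @param cm a `count_matrix` (usually after [cpm_filter()]).
#' @param groups character/factor of length `n_samples` with exactly two
#'   levels; at least two samples per group. The reference (denominator)
#'   group is the first factor level, or the alphabetically first label.
#' @param fdr BH threshold for the up/down status calls (default 0.05).
#' @return data.frame of class `de_results`: `feature_id`, `log2_fc`
#'   (second group level over first), `mean_cpm`, `dispersion`, `p`, `q`,
#'   `status` in `up`/`down`/`ns`.
#' @export
nb_test <- function(cm, groups, fdr = 0.05) {
  stopifnot(inherits(cm, "count_matrix"))
  glev <- if (is.factor(groups)) levels(groups) else sort(unique(groups))
  groups <- as.character(groups)
  if (length(groups) != ncol(cm$counts)) {
    stop("groups length must match the number of samples")
  }
  if (length(glev) != 2L) stop("exactly two groups are required")
  if (any(table(groups) < 2L)) {
    stop("at least two samples per group are required (pooled single samples cannot be tested)")
  }
  if (any(cm$lib_sizes <= 0)) stop("a group with an all-zero library cannot be normalised")
  y <- cm$counts
  storage.mode(y) <- "double"
  if (nrow(y) == 0L) {
    out <- data.frame(feature_id = character(), log2_fc = numeric(),
                      mean_cpm = numeric(), dispersion = numeric(),
                      p = numeric(), q = numeric(), status = character(),
                      stringsAsFactors = FALSE)
    class(out) <- c("de_results", "data.frame")
    return(out)
  }
  s <- cm$lib_sizes / mean(cm$lib_sizes)
  phi <- estimate_dispersion(y, s, groups)
  k <- 1 / phi

  ia <- groups == glev[1]
  ib <- groups == glev[2]
  m0 <- nb_fit_mean(y, k, s)
  ma <- nb_fit_mean(y[, ia, drop = FALSE], k, s[ia])
  mb <- nb_fit_mean(y[, ib, drop = FALSE], k, s[ib])
  ll0 <- nb_loglik(y, m0, k, s)
  ll1 <- nb_loglik(y[, ia, drop = FALSE], ma, k, s[ia]) +
    nb_loglik(y[, ib, drop = FALSE], mb, k, s[ib])
  lrt <- pmax(2 * (ll1 - ll0), 0)
  p <- stats::pchisq(lrt, df = 1, lower.tail = FALSE)

  z <- sweep(y, 2, s, "/")
  mean_a <- rowMeans(z[, ia, drop = FALSE])
  mean_b <- rowMeans(z[, ib, drop = FALSE])
  log2_fc <- log2((mean_b + 0.5) / (mean_a + 0.5))
  q <- bh_adjust(p)
  status <- rep("ns", nrow(y))
  status[q <= fdr & log2_fc > 0] <- "up"
  status[q <= fdr & log2_fc < 0] <- "down"
  out <- data.frame(feature_id = rownames(y), log2_fc = log2_fc,
                    mean_cpm = rowMeans(cpm(cm)), dispersion = phi,
                    p = p, q = q, status = status,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("de_results", "data.frame")
  out
}
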
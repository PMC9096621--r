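# Shared low-level helpers: interval arithmetic on the package-wide 0-based
# half-open convention, a vectorised two-sided Fisher test, and RNG scoping.

#' Construct a set of genomic intervals
#'
#' Intervals use 0-based half-open coordinates (BED convention) throughout the
#' package; the GFF3 and cytosine-report readers are the only places where
#' 1-based input is converted.
#'
#' @param chrom character vector of chromosome names.
#' @param start integer vector, 0-based inclusive.
#' @param end integer vector, exclusive; must satisfy `start < end`.
#' @param strand character vector in `+`, `-`, `.`.
#' @param ... further equal-length vectors stored as extra columns.
#' @return a `data.frame` with class `genomic_intervals`.
#' @export
genomic_intervals <- function(chrom, start, end, strand = ".", ...) {
  n <- length(chrom)
  start <- as.integer(start)
  end <- as.integer(end)
  strand <- rep_len(as.character(strand), n)
  if (any(is.na(start)) || any(is.na(end))) {
    stop("interval coordinates must be integral and non-missing")
  }
  if (any(start < 0L)) stop("interval start must be >= 0")
  if (any(end <= start)) stop("interval end must be > start")
  if (!all(strand %in% c("+", "-", "."))) stop("strand must be one of +, -, .")
  out <- data.frame(chrom = as.character(chrom), start = start, end = end,
                    strand = strand, stringsAsFactors = FALSE, ...)
  class(out) <- c("genomic_intervals", "data.frame")
  out
}

# IRanges view of an interval frame (shift to 1-based closed) for overlap work.
as_iranges0 <- function(x) {
  IRanges::IRanges(start = x$start + 1L, end = x$end)
}

#' Overlap query between two interval sets
#'
#' Returns pairs of row indices `(query, subject)` with >= `min_overlap` bp of
#' intersection on the same chromosome (strand ignored).
#'
#' @param query,subject interval data.frames (`chrom`, `start`, `end`).
#' @param min_overlap minimum intersection width in bp (default 1).
#' @return data.frame with columns `query`, `subject`, `overlap_bp`.
#' @export
interval_overlaps <- function(query, subject, min_overlap = 1L) {
  if (nrow(query) == 0L || nrow(subject) == 0L) {
    return(data.frame(query = integer(), subject = integer(),
                      overlap_bp = integer()))
  }
  res <- list()
  for (ch in intersect(unique(query$chrom), unique(subject$chrom))) {
    qi <- which(query$chrom == ch)
    si <- which(subject$chrom == ch)
    hits <- IRanges::findOverlaps(as_iranges0(query[qi, , drop = FALSE]),
                                  as_iranges0(subject[si, , drop = FALSE]),
                                  minoverlap = as.integer(min_overlap))
    if (length(hits) == 0L) next
    qh <- qi[S4Vectors::queryHits(hits)]
    sh <- si[S4Vectors::subjectHits(hits)]
    ov <- pmin(query$end[qh], subject$end[sh]) -
      pmax(query$start[qh], subject$start[sh])
    res[[ch]] <- data.frame(query = qh, subject = sh, overlap_bp = ov)
  }
  if (length(res) == 0L) {
    return(data.frame(query = integer(), subject = integer(),
                      overlap_bp = integer()))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out[order(out$query, out$subject), , drop = FALSE]
}

#' Vectorised two-sided Fisher exact test for 2x2 tables
#'
#' Tables are `[[a, b], [c, d]]`. The two-sided p-value sums, over the
#' hypergeometric support fixed by the margins, every table probability not
#' exceeding that of the observed table (the same definition as
#' [stats::fisher.test()]).
#'
#' @param a,b,c,d equal-length non-negative integer vectors.
#' @return numeric vector of p-values.
#' @export
fisher2x2 <- function(a, b, c, d) {
  n <- length(a)
  stopifnot(length(b) == n, length(c) == n, length(d) == n)
  if (any(c(a, b, c, d) < 0)) stop("counts must be non-negative")
  p <- numeric(n)
  for (i in seq_len(n)) {
    m1 <- a[i] + b[i]
    m2 <- c[i] + d[i]
    k <- a[i] + c[i]
    if (m1 + m2 == 0L) { p[i] <- 1; next }
    support <- max(0L, k - m2):min(k, m1)
    probs <- stats::dhyper(support, m1, m2, k)
    pobs <- stats::dhyper(a[i], m1, m2, k)
    # relative tolerance guards against ties lost to floating-point noise
    p[i] <- min(1, sum(probs[probs <= pobs * (1 + 1e-7)]))
  }
  p
}

#' Odds ratio of a 2x2 table with Haldane-Anscombe correction
#'
#' Adds 0.5 to every cell when any cell is zero.
#' @param tab 2x2 numeric matrix.
#' @return scalar odds ratio.
#' @export
odds_ratio <- function(tab) {
  stopifnot(is.matrix(tab), all(dim(tab) == c(2L, 2L)))
  if (any(tab == 0)) tab <- tab + 0.5
  (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
}

# Benjamini-Hochberg step-up; thin wrapper kept so every module adjusts the
# same way.
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a stream-specific child seed from a master seed (stays < 2^31).
child_seed <- function(seed, stream) {
  (as.numeric(seed) * 1103515245 + stream * 12345) %% 2147483647
}
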
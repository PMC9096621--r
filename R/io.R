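# Readers and writers for every external format the pipeline touches.
# All coordinates are converted to 0-based half-open on ingest; the
# converters here are the only place +/-1 arithmetic happens.

#' Read gene and TE models from a GFF3 file
#'
#' GFF3 1-based inclusive coordinates are converted to 0-based half-open.
#' Only rows whose feature type matches `gene_types` or `te_types` are kept;
#' everything else (mRNA, exon, comments, directives) is ignored.
#'
#' @param path GFF3 file.
#' @param gene_types GFF3 `type` values treated as genes.
#' @param te_types `type` values treated as transposable elements. Annotation
#'   dialects differ in how they label TEs, hence configurable.
#' @return data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `feature_class` (`gene` or `TE`).
#' @export
read_gff3 <- function(path, gene_types = "gene",
                      te_types = c("transposable_element", "repeat_region")) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0L) {
    return(empty_annotation())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9L)) {
    bad <- which(nf != 9L)[1]
    stop(sprintf("malformed GFF3 line %d: expected 9 tab-separated fields, got %d",
                 lineno[bad], nf[bad]))
  }
  m <- do.call(rbind, fields)
  type <- m[, 3]
  class <- ifelse(type %in% gene_types, "gene",
                  ifelse(type %in% te_types, "TE", NA))
  sel <- !is.na(class)
  if (!any(sel)) return(empty_annotation())
  m <- m[sel, , drop = FALSE]
  lineno <- lineno[sel]
  class <- class[sel]
  start1 <- suppressWarnings(as.integer(m[, 4]))
  end1 <- suppressWarnings(as.integer(m[, 5]))
  if (any(is.na(start1) | is.na(end1))) {
    bad <- which(is.na(start1) | is.na(end1))[1]
    stop(sprintf("malformed GFF3 line %d: non-integer coordinates", lineno[bad]))
  }
  if (any(end1 < start1)) {
    bad <- which(end1 < start1)[1]
    stop(sprintf("malformed GFF3 line %d: end < start", lineno[bad]))
  }
  ids <- sub(".*(?:^|;)ID=([^;]+).*", "\\1", m[, 9], perl = TRUE)
  noid <- !grepl("(^|;)ID=", m[, 9])
  if (any(noid)) {
    stop(sprintf("GFF3 line %d: feature row lacks an ID attribute",
                 lineno[which(noid)[1]]))
  }
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate feature ID in GFF3: %s", ids[duplicated(ids)][1]))
  }
  strand <- m[, 7]
  if (any(class == "gene" & !strand %in% c("+", "-"))) {
    stop("gene features must carry strand + or -")
  }
  strand[!strand %in% c("+", "-")] <- "."
  ann <- data.frame(gene_id = ids, chrom = m[, 1],
                    start = start1 - 1L, end = end1,
                    strand = strand, feature_class = class,
                    stringsAsFactors = FALSE)
  rownames(ann) <- NULL
  ann
}

empty_annotation <- function() {
  data.frame(gene_id = character(), chrom = character(), start = integer(),
             end = integer(), strand = character(), feature_class = character(),
             stringsAsFactors = FALSE)
}

#' Write an annotation set as GFF3
#' @param ann annotation data.frame as returned by [read_gff3()].
#' @param path output file.
#' @export
write_gff3 <- function(ann, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(ann) > 0L) {
    type <- ifelse(ann$feature_class == "gene", "gene", "transposable_element")
    writeLines(sprintf("%s\tphotoepi\t%s\t%d\t%d\t.\t%s\t.\tID=%s",
                       ann$chrom, type, ann$start + 1L, ann$end,
                       ann$strand, ann$gene_id), con)
  }
  invisible(path)
}

#' Read a Bismark-style per-cytosine report
#'
#' Expected columns: chrom, pos (1-based), strand, methylated count,
#' unmethylated count, context; extra columns are ignored. Sites with total
#' coverage below `min_total` are dropped (the study's 10X rule when
#' `min_total = 10`).
#'
#' @param path TSV file.
#' @param min_total minimum `meth + unmeth` coverage to keep a site.
#' @return data.frame with `chrom`, `pos` (0-based), `strand`, `context`,
#'   `meth`, `total`.
#' @export
read_cytosine_report <- function(path, min_total = 10L) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE,
                         colClasses = c("character", "integer", "character",
                                        "integer", "integer", "character"),
                         col.names = c("chrom", "pos", "strand", "meth",
                                       "unmeth", "context"),
                         fill = FALSE, flush = TRUE, comment.char = "#")
  if (!all(x$context %in% c("CG", "CHG", "CHH"))) {
    bad <- setdiff(unique(x$context), c("CG", "CHG", "CHH"))
    stop(sprintf("unknown methylation context token: %s", bad[1]))
  }
  if (any(x$meth < 0L | x$unmeth < 0L)) stop("negative methylation count")
  if (!all(x$strand %in% c("+", "-"))) stop("cytosine strand must be + or -")
  total <- x$meth + x$unmeth
  keep <- total >= min_total
  out <- data.frame(chrom = x$chrom[keep], pos = x$pos[keep] - 1L,
                    strand = x$strand[keep], context = x$context[keep],
                    meth = x$meth[keep], total = total[keep],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Write a per-cytosine report in the dialect [read_cytosine_report()] reads
#' @param sites data.frame with `chrom`, `pos` (0-based), `strand`, `context`,
#'   `meth`, `total`.
#' @param path output TSV.
#' @export
write_cytosine_report <- function(sites, path) {
  df <- data.frame(sites$chrom, sites$pos + 1L, sites$strand, sites$meth,
                   sites$total - sites$meth, sites$context)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read position frequency matrices in JASPAR text format
#'
#' Format: `>motif_id name` header, then four lines `A [ ... ]`,
#' `C [ ... ]`, `G [ ... ]`, `T [ ... ]`. Several motifs per file supported.
#'
#' @param path JASPAR-format file.
#' @return named list of PFMs; each a 4 x L numeric matrix with rownames
#'   A, C, G, T.
#' @export
read_jaspar_pfm <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  heads <- grep("^>", lines)
  if (length(heads) == 0L) stop("no JASPAR '>' header found")
  out <- list()
  bounds <- c(heads, length(lines) + 1L)
  for (i in seq_along(heads)) {
    block <- lines[(bounds[i] + 1L):(bounds[i + 1L] - 1L)]
    id <- strsplit(sub("^>", "", lines[heads[i]]), "\\s+")[[1]][1]
    rows <- list()
    for (base in c("A", "C", "G", "T")) {
      ln <- block[grepl(paste0("^", base, "\\b"), block)]
      if (length(ln) != 1L) {
        stop(sprintf("motif %s: expected exactly one %s row", id, base))
      }
      nums <- sub(paste0("^", base, "\\s*\\[?"), "", ln)
      nums <- sub("\\]\\s*$", "", nums)
      rows[[base]] <- as.numeric(strsplit(trimws(nums), "\\s+")[[1]])
    }
    L <- unique(lengths(rows))
    if (length(L) != 1L) {
      stop(sprintf("motif %s: base rows have unequal lengths", id))
    }
    mat <- do.call(rbind, rows)
    if (any(mat < 0)) stop(sprintf("motif %s: negative counts", id))
    if (any(colSums(mat) <= 0)) {
      stop(sprintf("motif %s: column with non-positive sum", id))
    }
    out[[id]] <- mat
  }
  out
}

#' Write intervals as BED
#'
#' Writes BED6 when `name`/`score`/`strand` information is present (always,
#' with `.`/0 placeholders) so the file round-trips through [read_bed()].
#'
#' @param intervals data.frame with `chrom`, `start`, `end` and optionally
#'   `name`, `score`, `strand`.
#' @param path output file.
#' @export
write_bed <- function(intervals, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(intervals) > 0L) {
    name <- if ("name" %in% names(intervals)) intervals$name else "."
    score <- if ("score" %in% names(intervals)) intervals$score else 0
    strand <- if ("strand" %in% names(intervals)) intervals$strand else "."
    writeLines(sprintf("%s\t%d\t%d\t%s\t%s\t%s", intervals$chrom,
                       intervals$start, intervals$end, name,
                       as.character(score), strand), con)
  }
  invisible(path)
}

#' Read a BED3/BED6 file
#' @param path BED file.
#' @return data.frame with `chrom`, `start`, `end` and, when present,
#'   `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      name = character(), score = numeric(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- min(lengths(fields))
  if (nf < 3L) stop("BED line with fewer than 3 fields")
  m <- do.call(rbind, lapply(fields, `[`, seq_len(nf)))
  out <- data.frame(chrom = m[, 1], start = as.integer(m[, 2]),
                    end = as.integer(m[, 3]), stringsAsFactors = FALSE)
  if (nf >= 4L) out$name <- m[, 4]
  if (nf >= 5L) out$score <- as.numeric(m[, 5])
  if (nf >= 6L) out$strand <- m[, 6]
  if (any(out$end <= out$start)) stop("BED interval with end <= start")
  out
}

#' Read a count matrix TSV (features x samples, header row of sample ids)
#' @param path TSV with a leading feature-id column.
#' @return a `count_matrix`: list with `counts` (integer matrix), `lib_sizes`.
#' @export
read_count_matrix <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                         check.names = FALSE, stringsAsFactors = FALSE)
  count_matrix(as.matrix(x))
}

#' Write a count matrix TSV
#' @param cm a `count_matrix`.
#' @param path output file.
#' @export
write_count_matrix <- function(cm, path) {
  df <- data.frame(feature_id = rownames(cm$counts), cm$counts,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a count matrix container
#'
#' @param counts non-negative integer matrix, features x samples, with
#'   row and column names.
#' @param lib_sizes per-sample library sizes; defaults to column sums.
#' @return list with class `count_matrix`: `counts`, `lib_sizes`.
#' @export
count_matrix <- function(counts, lib_sizes = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  if (any(counts < 0L, na.rm = TRUE) || anyNA(counts)) {
    stop("counts must be non-negative integers")
  }
  if (nrow(counts) > 0L && is.null(rownames(counts))) {
    stop("counts must have feature rownames")
  }
  if (ncol(counts) > 0L && is.null(colnames(counts))) {
    stop("counts must have sample colnames")
  }
  if (anyDuplicated(rownames(counts))) stop("duplicate feature ids")
  if (anyDuplicated(colnames(counts))) stop("duplicate sample ids")
  if (is.null(lib_sizes)) lib_sizes <- colSums(counts)
  lib_sizes <- as.numeric(lib_sizes)
  if (length(lib_sizes) != ncol(counts)) {
    stop("lib_sizes length must match the number of samples")
  }
  if (nrow(counts) > 0L && any(lib_sizes <= 0)) stop("lib_sizes must be positive")
  structure(list(counts = counts, lib_sizes = lib_sizes),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d features x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  cat("samples:", paste(colnames(x$counts), collapse = ", "), "\n")
  invisible(x)
}

#' Read a genome from FASTA
#' @param path FASTA file.
#' @return a [Biostrings::DNAStringSet].
#' @export
read_genome <- function(path) Biostrings::readDNAStringSet(path)

#' Write a genome to FASTA
#' @param genome a [Biostrings::DNAStringSet].
#' @param path output file.
#' @export
write_genome <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path, width = 80L)
  invisible(path)
}
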
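# Readers and writers for the genomic file formats the toolkit consumes.
#
# Internal convention: all coordinates are 0-based half-open ([start, end)),
# exactly as in BED.  GFF3/GTF (1-based inclusive) are converted at the I/O
# boundary and nowhere else.

#' Read a peak file (BED6 / narrowPeak / broadPeak)
#'
#' Parses a peak file into the internal peak table. Coordinates are kept
#' 0-based half-open (BED native). Peaks are sorted by (chrom, start).
#' Unnamed peaks (name column `"."`) receive auto-generated ids
#' `peak_000001, ...` in file order; explicit names must be unique.
#'
#' @param path Path to the peak file.
#' @param format One of `"bed6"`, `"narrowPeak"`, `"broadPeak"`.
#' @return A `data.frame` with columns `peak_id`, `chrom`, `start`, `end`,
#'   `summit_offset` (offset of the summit from `start`; `NA` when absent,
#'   narrowPeak only), `score`.
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines("chr1\t100\t200\tpk1\t0\t.", bed)
#' read_peaks(bed, "bed6")
#' @export
read_peaks <- function(path, format = c("bed6", "narrowPeak", "broadPeak")) {
  format <- match.arg(format)
  if (!file.exists(path)) .stopf("peak file not found: %s", path)
  need <- switch(format, bed6 = 6L, narrowPeak = 10L, broadPeak = 9L)
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) .stopf("no peak records in %s", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < need)
  if (length(bad))
    .stopf("malformed %s line %d in %s: expected %d fields, got %d",
           format, lineno[bad[1]], path, need, nf[bad[1]])
  m <- do.call(rbind, lapply(fields, `[`, seq_len(need)))
  chrom <- m[, 1]
  start <- suppressWarnings(as.integer(m[, 2]))
  end   <- suppressWarnings(as.integer(m[, 3]))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    .stopf("malformed %s line %d in %s: non-numeric coordinates",
           format, lineno[bad[1]], path)
  bad <- which(start < 0L | start >= end)
  if (length(bad))
    .stopf("invalid interval at line %d in %s: start (%d) must satisfy 0 <= start < end (%d)",
           lineno[bad[1]], path, start[bad[1]], end[bad[1]])
  name <- m[, 4]
  score <- suppressWarnings(as.numeric(m[, 5]))
  summit <- rep(NA_integer_, length(start))
  if (format == "narrowPeak") {
    summit <- suppressWarnings(as.integer(m[, 10]))
    summit[!is.na(summit) & summit == -1L] <- NA_integer_
    bad <- which(!is.na(summit) & start + summit >= end)
    if (length(bad))
      .stopf("invalid summit at line %d in %s: start + summit_offset must be < end",
             lineno[bad[1]], path)
  }
  auto <- name == "." | !nzchar(name)
  name[auto] <- sprintf("peak_%06d", which(auto))
  dup <- duplicated(name[!auto])
  if (any(dup))
    .stopf("duplicate peak id in %s: %s", path, name[!auto][dup][1])
  if (any(name[auto] %in% name[!auto]))
    .stopf("auto-generated peak id collides with an explicit name in %s", path)
  out <- data.frame(peak_id = name, chrom = chrom, start = start, end = end,
                    summit_offset = summit, score = score,
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start, out$end, out$peak_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read gene models from a GFF3/GTF annotation
#'
#' Extracts records of the requested feature type and derives the
#' strand-aware TSS. GFF 1-based inclusive coordinates are converted to
#' 0-based half-open; `tss == start` on the `+` strand and `end - 1` on the
#' `-` strand. Records without a gene identifier or with unknown strand are
#' skipped with a warning.
#'
#' @param path Path to a GFF3 or GTF file.
#' @param format `"gff3"` or `"gtf"`.
#' @param feature Feature type to extract (third GFF column), default `"gene"`.
#' @return A `data.frame` with columns `gene_id`, `chrom`, `strand`,
#'   `start`, `end`, `tss`.
#' @export
read_gene_annotation <- function(path, format = c("gff3", "gtf"),
                                 feature = "gene") {
  format <- match.arg(format)
  if (!file.exists(path)) .stopf("annotation file not found: %s", path)
  gr <- rtracklayer::import(path, format = if (format == "gff3") "gff3" else "gtf")
  gr <- gr[!is.na(gr$type) & as.character(gr$type) == feature]
  if (!length(gr)) .stopf("no '%s' records in %s", feature, path)
  meta <- S4Vectors::mcols(gr)
  id <- rep(NA_character_, length(gr))
  for (key in c("gene_id", "ID", "Name")) {
    if (key %in% names(meta)) {
      v <- as.character(meta[[key]])
      id[is.na(id) & !is.na(v) & nzchar(v)] <- v[is.na(id) & !is.na(v) & nzchar(v)]
    }
  }
  strand <- as.character(BiocGenerics::strand(gr))
  drop_id <- is.na(id)
  drop_strand <- !strand %in% c("+", "-")
  if (any(drop_id))
    .warnf("skipped %d record(s) lacking a gene identifier", sum(drop_id))
  if (any(drop_strand & !drop_id))
    .warnf("skipped %d record(s) with unknown strand", sum(drop_strand & !drop_id))
  keep <- !drop_id & !drop_strand
  if (!any(keep)) .stopf("no usable '%s' records in %s", feature, path)
  gr <- gr[keep]; id <- id[keep]; strand <- strand[keep]
  if (anyDuplicated(id))
    .stopf("duplicate gene_id in %s: %s", path, id[duplicated(id)][1])
  start0 <- BiocGenerics::start(gr) - 1L
  end0 <- BiocGenerics::end(gr)
  out <- data.frame(
    gene_id = id,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = strand,
    start = start0,
    end = end0,
    tss = ifelse(strand == "+", start0, end0 - 1L),
    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a feature-by-sample signal matrix from TSV
#'
#' First column = feature id, remaining columns = samples (header row).
#' Values must be numeric, non-negative and complete.
#'
#' @param path Path to a tab-separated file.
#' @return A numeric matrix with feature ids as rownames.
#' @export
read_signal_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) .stopf("signal matrix %s needs an id column plus >=1 sample", path)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) .stopf("duplicate feature id in %s: %s", path,
                                 ids[duplicated(ids)][1])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  if (anyNA(m)) .stopf("missing values in signal matrix %s", path)
  if (any(m < 0)) .stopf("negative signal values in %s", path)
  if (anyDuplicated(colnames(m))) .stopf("duplicate sample id in %s", path)
  rownames(m) <- ids
  m
}

#' Read TF binding hits (TF -> bound peaks)
#'
#' Accepts either a two-column TSV (`tf_id`, `peak_id`) or a BED file whose
#' name column carries the TF id; BED intervals are resolved to peak ids of
#' the supplied peak universe by >= 1 bp overlap (an interval overlapping two
#' peaks yields both). Hits referencing unknown peaks are dropped with a
#' warning giving the count.
#'
#' @param path Path to the hit file.
#' @param peaks Peak universe as returned by [read_peaks()] (required for
#'   BED input; used to validate TSV input when supplied).
#' @return A `tf_hits` object: named list mapping `tf_id` to a character
#'   vector of bound `peak_id`s, with a `provenance` attribute.
#' @export
read_tf_hits <- function(path, peaks = NULL) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                   comment.char = "#")
  is_bed <- ncol(df) >= 4 && is.numeric(df[[2]]) && is.numeric(df[[3]])
  if (is_bed) {
    if (is.null(peaks))
      .stopf("BED-format TF hits require the peak universe ('peaks')")
    hit_gr <- GenomicRanges::GRanges(df[[1]],
                IRanges::IRanges(df[[2]] + 1L, df[[3]]))
    uni_gr <- GenomicRanges::GRanges(peaks$chrom,
                IRanges::IRanges(peaks$start + 1L, peaks$end))
    ov <- GenomicRanges::findOverlaps(hit_gr, uni_gr)
    n_drop <- sum(!seq_len(nrow(df)) %in% S4Vectors::queryHits(ov))
    if (n_drop) .warnf("%d TF-hit interval(s) overlap no universe peak; dropped", n_drop)
    tf <- df[[4]][S4Vectors::queryHits(ov)]
    pid <- peaks$peak_id[S4Vectors::subjectHits(ov)]
    prov <- "chipseq"
  } else {
    has_header <- tolower(df[1, 1]) %in% c("tf_id", "tf")
    if (has_header) df <- df[-1, , drop = FALSE]
    tf <- as.character(df[[1]]); pid <- as.character(df[[2]])
    if (!is.null(peaks)) {
      bad <- !pid %in% peaks$peak_id
      if (any(bad)) {
        .warnf("%d TF-hit row(s) reference unknown peaks; dropped", sum(bad))
        tf <- tf[!bad]; pid <- pid[!bad]
      }
    }
    prov <- "motif"
  }
  if (!length(tf)) .stopf("no usable TF hits in %s", path)
  hits <- lapply(split(pid, tf), function(x) sort(unique(x)))
  tf_hits(hits, provenance = prov)
}

#' Construct a TF hit set
#'
#' @param hits Named list: `tf_id` -> character vector of `peak_id`s.
#' @param provenance `"chipseq"` or `"motif"`.
#' @return A `tf_hits` object.
#' @export
tf_hits <- function(hits, provenance = c("chipseq", "motif")) {
  provenance <- match.arg(provenance)
  stopifnot(is.list(hits), !is.null(names(hits)), all(nzchar(names(hits))))
  hits <- hits[order(names(hits))]
  structure(hits, class = "tf_hits", provenance = provenance)
}

#' @export
print.tf_hits <- function(x, ...) {
  cat(sprintf("tf_hits: %d TF(s), %d hit(s) total [%s]\n",
              length(x), sum(lengths(x)), attr(x, "provenance")))
  invisible(x)
}

#' Read a differential-gene-expression table
#'
#' Expects tab-separated columns `gene_id`, `log2fc` (or `log2FoldChange`)
#' and `padj`. A `gene_category` column (`up`/`down`/`static`) is kept when
#' present, otherwise derived from the supplied thresholds: a gene is
#' `up`/`down` when `|log2fc| >= lfc_min` and `padj <= padj_max`, else
#' `static`.
#'
#' @param path Path to the TSV file.
#' @param lfc_min Absolute log2 fold-change threshold (default 1).
#' @param padj_max Adjusted p-value threshold (default 0.05).
#' @return `data.frame` with `gene_id`, `log2fc`, `padj`, `gene_category`.
#' @export
read_dge <- function(path, lfc_min = 1, padj_max = 0.05) {
  df <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  if ("log2FoldChange" %in% names(df) && !"log2fc" %in% names(df))
    names(df)[names(df) == "log2FoldChange"] <- "log2fc"
  .assert_cols(df, c("gene_id", "log2fc", "padj"), "DGE table")
  if (any(df$padj < 0 | df$padj > 1, na.rm = TRUE))
    .stopf("padj outside [0,1] in %s", path)
  if (!"gene_category" %in% names(df))
    df$gene_category <- dge_category(df$log2fc, df$padj, lfc_min, padj_max)
  df[, c("gene_id", "log2fc", "padj", "gene_category")]
}

#' Classify genes as up / down / static
#'
#' @param log2fc,padj Numeric vectors.
#' @param lfc_min,padj_max Thresholds; genes failing either are `static`.
#' @return Character vector of categories.
#' @export
dge_category <- function(log2fc, padj, lfc_min = 1, padj_max = 0.05) {
  ifelse(!is.na(padj) & padj <= padj_max & log2fc >= lfc_min, "up",
  ifelse(!is.na(padj) & padj <= padj_max & log2fc <= -lfc_min, "down",
         "static"))
}

#' Read TF-target pairs
#'
#' Tab-separated `tf_id`, `target_gene_id` and optional `confidence`.
#' Duplicate (tf, target) pairs are collapsed with a warning.
#'
#' @param path Path to the TSV file.
#' @return `data.frame` with `tf_id`, `target_gene_id` (+ `confidence`).
#' @export
read_tt_pairs <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  .assert_cols(df, c("tf_id", "target_gene_id"), "TF-target table")
  dup <- duplicated(df[, c("tf_id", "target_gene_id")])
  if (any(dup)) {
    .warnf("%d duplicate TF-target pair(s) collapsed", sum(dup))
    df <- df[!dup, , drop = FALSE]
  }
  rownames(df) <- NULL
  df
}

#' Read a bedGraph coverage track
#'
#' @param path Path to a bedGraph file (0-based half-open intervals).
#' @return `data.frame` with `chrom`, `start`, `end`, `value`.
#' @export
read_bedgraph <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                   comment.char = "#")
  df <- df[!grepl("^(track|browser)", df[[1]]), , drop = FALSE]
  if (ncol(df) < 4) .stopf("bedGraph %s needs 4 columns", path)
  out <- data.frame(chrom = as.character(df[[1]]),
                    start = as.integer(df[[2]]), end = as.integer(df[[3]]),
                    value = as.numeric(df[[4]]), stringsAsFactors = FALSE)
  if (any(out$start < 0 | out$start >= out$end)) .stopf("invalid interval in %s", path)
  if (any(out$value < 0)) .stopf("negative coverage in %s", path)
  out[order(out$chrom, out$start), , drop = FALSE]
}

# ---- writers ---------------------------------------------------------------

#' Write a table as TSV with a reproducibility header
#'
#' Output starts with `#`-prefixed lines naming the tool version and any
#' parameters, then a tab-separated header and rows.
#'
#' @param df Data frame (or matrix with rownames; written with an id column).
#' @param path Output path.
#' @param params Named list echoed into the `#` header.
#' @param id_col Name for the id column when `df` is a matrix.
#' @return `path`, invisibly.
#' @export
write_tsv_output <- function(df, path, params = list(), id_col = "feature_id") {
  if (is.matrix(df)) {
    df <- data.frame(rownames(df), df, check.names = FALSE,
                     stringsAsFactors = FALSE)
    names(df)[1] <- id_col
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# tfinfer %s", as.character(packageVersion("tfinfer"))), con)
  for (k in names(params))
    writeLines(sprintf("# %s=%s", k, paste(format(params[[k]]), collapse = ",")), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write gene models as GFF3
#'
#' Converts the internal 0-based half-open coordinates back to GFF 1-based
#' inclusive.
#'
#' @param genes Gene table as from [read_gene_annotation()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  writeLines(sprintf("%s\ttfinfer\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                     genes$chrom, genes$start + 1L, genes$end,
                     genes$strand, genes$gene_id), con)
  invisible(path)
}

#' Write peaks as BED6 or narrowPeak
#'
#' @param peaks Peak table as from [read_peaks()].
#' @param path Output path.
#' @param format `"bed6"` or `"narrowPeak"`.
#' @return `path`, invisibly.
#' @export
write_bed <- function(peaks, path, format = c("bed6", "narrowPeak")) {
  format <- match.arg(format)
  score <- ifelse(is.na(peaks$score), 0, peaks$score)
  if (format == "bed6") {
    lines <- sprintf("%s\t%d\t%d\t%s\t%g\t.", peaks$chrom, peaks$start,
                     peaks$end, peaks$peak_id, score)
  } else {
    summit <- ifelse(is.na(peaks$summit_offset), -1L, peaks$summit_offset)
    lines <- sprintf("%s\t%d\t%d\t%s\t%g\t.\t0\t-1\t-1\t%d", peaks$chrom,
                     peaks$start, peaks$end, peaks$peak_id, score, summit)
  }
  writeLines(lines, path)
  invisible(path)
}
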
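# Peak-to-gene annotation: nearest-gene, gene-scan and gene-bound strategies.
#
# Distances are measured from the peak anchor (summit when available, else
# interval midpoint) to the strand-aware TSS, and are signed: negative when
# the anchor lies 5' (upstream) of the TSS in the gene's orientation.

#' Peak anchor positions
#'
#' The anchor is the single base position used for all distance math:
#' the summit when present (`anchor = "auto"` or `"summit"`), otherwise the
#' integer midpoint `(start + end) %/% 2`.
#'
#' @param peaks Peak table from [read_peaks()].
#' @param anchor `"auto"` (summit when present, else midpoint),
#'   `"midpoint"`, or `"summit"` (error when any summit is missing).
#' @return Integer vector of anchor positions (0-based).
#' @export
peak_anchor <- function(peaks, anchor = c("auto", "midpoint", "summit")) {
  anchor <- match.arg(anchor)
  mid <- (peaks$start + peaks$end) %/% 2L
  if (anchor == "midpoint") return(mid)
  s <- peaks$summit_offset %||% rep(NA_integer_, nrow(peaks))
  if (anchor == "summit" && anyNA(s))
    .stopf("anchor = 'summit' requested but %d peak(s) lack a summit", sum(is.na(s)))
  ifelse(is.na(s), mid, peaks$start + s)
}

# Signed anchor -> TSS distance in the gene's orientation.
.signed_distance <- function(anchor, tss, strand) {
  ifelse(strand == "+", anchor - tss, tss - anchor)
}

# For each chromosome, precompute sorted unique TSS values and, per TSS
# value, the lexicographically smallest gene carrying it (the tie winner).
.tss_index <- function(genes) {
  lapply(split(genes, genes$chrom), function(g) {
    g <- g[order(g$tss, g$gene_id), , drop = FALSE]
    first <- !duplicated(g$tss)
    list(tss = g$tss[first], gene = g[first, , drop = FALSE])
  })
}

# Nearest-gene core: returns row indices into the per-chrom winner table.
.nearest_tss <- function(anchors, idx) {
  ut <- idx$tss
  i <- findInterval(anchors, ut)
  lo <- ifelse(i >= 1L, ut[pmax(i, 1L)], NA_integer_)
  hi <- ifelse(i < length(ut), ut[pmin(i + 1L, length(ut))], NA_integer_)
  dlo <- ifelse(is.na(lo), Inf, anchors - lo)
  dhi <- ifelse(is.na(hi), Inf, hi - anchors)
  pick_lo <- dlo < dhi
  tie <- dlo == dhi & is.finite(dlo)
  if (any(tie)) {
    g_lo <- idx$gene$gene_id[pmax(i, 1L)]
    g_hi <- idx$gene$gene_id[pmin(i + 1L, length(ut))]
    pick_lo[tie] <- g_lo[tie] <= g_hi[tie]
  }
  ifelse(pick_lo, pmax(i, 1L), pmin(i + 1L, length(ut)))
}

#' Annotate peaks with their nearest gene (by TSS distance)
#'
#' One-to-one annotation: each peak is linked to exactly one gene, the one
#' whose TSS is closest to the peak anchor. Ties are broken by the
#' lexicographically smaller `gene_id`. Peaks on chromosomes without genes
#' are omitted with a warning giving the count.
#'
#' @param peaks Peak table from [read_peaks()].
#' @param genes Gene table from [read_gene_annotation()].
#' @param anchor Anchor policy, see [peak_anchor()].
#' @return `data.frame` with columns `peak_id`, `gene_id`, `distance`
#'   (signed, negative = upstream of the TSS), `mode` (`"nearest"`).
#' @export
annotate_nearest <- function(peaks, genes, anchor = "auto") {
  stopifnot(nrow(peaks) > 0, nrow(genes) > 0)
  anchors <- peak_anchor(peaks, anchor)
  idx <- .tss_index(genes)
  out <- vector("list", length(unique(peaks$chrom)))
  n_orphan <- 0L
  res <- list()
  for (ch in unique(peaks$chrom)) {
    sel <- peaks$chrom == ch
    if (is.null(idx[[ch]])) { n_orphan <- n_orphan + sum(sel); next }
    j <- .nearest_tss(anchors[sel], idx[[ch]])
    g <- idx[[ch]]$gene[j, , drop = FALSE]
    res[[ch]] <- data.frame(
      peak_id = peaks$peak_id[sel], gene_id = g$gene_id,
      distance = .signed_distance(anchors[sel], g$tss, g$strand),
      mode = "nearest", stringsAsFactors = FALSE)
  }
  if (n_orphan) .warnf("%d peak(s) on chromosomes without genes; omitted", n_orphan)
  if (!length(res)) .stopf("no peak could be annotated (no shared chromosomes)")
  out <- do.call(rbind, res)
  out <- out[order(out$peak_id, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Scan-mode links only (no fallback): every peak whose anchor lies within
# [tss - scan_length, tss + scan_length] of a gene yields one link.
.scan_links <- function(peaks, genes, scan_length, anchor = "auto") {
  anchors <- peak_anchor(peaks, anchor)
  res <- list()
  for (ch in unique(genes$chrom)) {
    gsel <- which(genes$chrom == ch)
    psel <- which(peaks$chrom == ch)
    if (!length(psel)) next
    ord <- psel[order(anchors[psel])]
    a <- anchors[ord]
    tss <- genes$tss[gsel]
    lo <- findInterval(tss - scan_length - 1L, a) + 1L   # first anchor >= tss - L
    hi <- findInterval(tss + scan_length, a)             # last anchor <= tss + L
    n <- pmax(hi - lo + 1L, 0L)
    if (!sum(n)) next
    gi <- rep.int(gsel[n > 0], n[n > 0])
    pi <- ord[unlist(lapply(which(n > 0), function(k) lo[k]:hi[k]), use.names = FALSE)]
    res[[ch]] <- data.frame(
      peak_id = peaks$peak_id[pi], gene_id = genes$gene_id[gi],
      distance = .signed_distance(anchors[pi], genes$tss[gi], genes$strand[gi]),
      mode = "scan", stringsAsFactors = FALSE)
  }
  if (!length(res))
    return(data.frame(peak_id = character(), gene_id = character(),
                      distance = integer(), mode = character(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Annotate peaks under the gene-scan strategy
#'
#' Builds a scan region `[tss - scan_length, tss + scan_length]` around each
#' gene's TSS; every peak whose anchor falls in a gene's scan region is
#' linked to that gene (`mode = "scan"`), so a peak may be linked to several
#' genes. Peaks falling in no scan region are assigned to their nearest gene
#' (`mode = "nearest_fallback"`).
#'
#' @inheritParams annotate_nearest
#' @param scan_length Per-side scan radius in bp (default 20000).
#' @return `data.frame` with columns `peak_id`, `gene_id`, `distance`, `mode`.
#' @export
annotate_scan <- function(peaks, genes, scan_length = 20000L, anchor = "auto") {
  stopifnot(nrow(peaks) > 0, nrow(genes) > 0)
  if (scan_length <= 0) .stopf("scan_length must be > 0")
  links <- .scan_links(peaks, genes, scan_length, anchor)
  missed <- setdiff(peaks$peak_id, links$peak_id)
  if (length(missed)) {
    fb <- annotate_nearest(peaks[peaks$peak_id %in% missed, , drop = FALSE],
                           genes, anchor)
    if (nrow(fb)) {
      fb$mode <- "nearest_fallback"
      links <- rbind(links, fb)
    }
  }
  links <- links[order(links$peak_id, links$gene_id), , drop = FALSE]
  rownames(links) <- NULL
  links
}

#' Find associated peaks for genes of interest (gene-bound strategy)
#'
#' Starts from the nearest-gene annotation of all peaks; query genes covered
#' there keep their links (`mode = "nearest"`). Each query gene not assigned
#' any peak is then linked to its nearest peak (`mode = "gene_bound"`, ties
#' broken by lexicographic `peak_id`). Query genes on chromosomes without
#' peaks are reported as unresolvable, not an error.
#'
#' @param query_gene_ids Character vector of gene ids of interest.
#' @inheritParams annotate_nearest
#' @return List with `links` (columns as [annotate_nearest()]) and
#'   `unresolvable` (character vector of gene ids).
#' @export
annotate_gene_bound <- function(query_gene_ids, peaks, genes, anchor = "auto") {
  missing <- setdiff(query_gene_ids, genes$gene_id)
  if (length(missing))
    .stopf("query gene(s) absent from annotation: %s",
           paste(head(missing, 3), collapse = ", "))
  near <- suppressWarnings(annotate_nearest(peaks, genes, anchor))
  links <- near[near$gene_id %in% query_gene_ids, , drop = FALSE]
  todo <- setdiff(query_gene_ids, links$gene_id)
  anchors <- peak_anchor(peaks, anchor)
  unres <- character()
  extra <- list()
  for (gid in todo) {
    g <- genes[genes$gene_id == gid, , drop = FALSE]
    psel <- which(peaks$chrom == g$chrom)
    if (!length(psel)) { unres <- c(unres, gid); next }
    d <- abs(anchors[psel] - g$tss)
    best <- psel[d == min(d)]
    best <- best[order(peaks$peak_id[best])][1]
    extra[[gid]] <- data.frame(
      peak_id = peaks$peak_id[best], gene_id = gid,
      distance = .signed_distance(anchors[best], g$tss, g$strand),
      mode = "gene_bound", stringsAsFactors = FALSE)
  }
  links <- rbind(links, do.call(rbind, extra))
  if (!is.null(links)) {
    links <- links[order(links$gene_id, links$peak_id), , drop = FALSE]
    rownames(links) <- NULL
  }
  list(links = links, unresolvable = unres)
}

#' Per-gene and per-peak link counts
#'
#' @param links Link table from any annotation function.
#' @return List with `gene_counts` (`gene_id`, `n_peaks`) and `peak_counts`
#'   (`peak_id`, `n_genes`).
#' @export
summarize_links <- function(links) {
  stopifnot(nrow(links) > 0)
  gc <- as.data.frame(table(links$gene_id), stringsAsFactors = FALSE)
  names(gc) <- c("gene_id", "n_peaks")
  pc <- as.data.frame(table(links$peak_id), stringsAsFactors = FALSE)
  names(pc) <- c("peak_id", "n_genes")
  list(gene_counts = gc, peak_counts = pc)
}

#' Count-of-counts summary of link multiplicity
#'
#' Tallies how many genes have 1, 2, ... associated peaks and vice versa
#' (the histogram behind "most genes have only one related peak").
#'
#' @param links Link table (or a correlation-link table with `gene_id` and a
#'   peak column named `peak_id` or `source_id`).
#' @return List of two data frames: `genes_by_peak_n` (`n_peaks`,
#'   `n_genes`) and `peaks_by_gene_n` (`n_genes`, `n_peaks`).
#' @export
pair_count_summary <- function(links) {
  pcol <- if ("peak_id" %in% names(links)) "peak_id" else "source_id"
  s <- summarize_links(data.frame(peak_id = links[[pcol]],
                                  gene_id = links$gene_id,
                                  stringsAsFactors = FALSE))
  g <- as.data.frame(table(s$gene_counts$n_peaks), stringsAsFactors = FALSE)
  names(g) <- c("n_peaks", "n_genes")
  g$n_peaks <- as.integer(g$n_peaks)
  p <- as.data.frame(table(s$peak_counts$n_genes), stringsAsFactors = FALSE)
  names(p) <- c("n_genes", "n_peaks")
  p$n_genes <- as.integer(p$n_genes)
  list(genes_by_peak_n = g, peaks_by_gene_n = p)
}

#' Histogram of peak-to-TSS distances
#'
#' Bins the signed link distances into half-open bins `[lo, hi)`.
#'
#' @param links Link table with a `distance` column.
#' @param breaks Numeric vector of bin edges (default: 9 equal-width bins
#'   spanning the data).
#' @return `data.frame` with `bin_start`, `bin_end`, `count`.
#' @export
distance_distribution <- function(links, breaks = NULL) {
  stopifnot(nrow(links) > 0)
  d <- links$distance
  if (is.null(breaks)) breaks <- pretty(range(d), n = 9)
  if (min(d) < breaks[1] || max(d) >= breaks[length(breaks)])
    breaks <- unique(c(min(d), breaks[breaks > min(d) & breaks <= max(d)], max(d) + 1))
  i <- findInterval(d, breaks, rightmost.closed = FALSE)
  counts <- tabulate(i, nbins = length(breaks) - 1)
  data.frame(bin_start = breaks[-length(breaks)], bin_end = breaks[-1],
             count = counts)
}
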
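# Small in-code fixture builders and independent brute-force oracles.

mk_genes <- function(gene_id, tss, chrom = "chr1", strand = "+",
                     width = 1000L) {
  start <- ifelse(strand == "+", tss, tss - width + 1L)
  data.frame(gene_id = gene_id, chrom = chrom, strand = strand,
             start = start, end = start + width, tss = tss,
             stringsAsFactors = FALSE)
}

# peaks centered on the requested anchors (width 100 so midpoint == anchor)
mk_peaks <- function(peak_id, anchor, chrom = "chr1", width = 100L) {
  data.frame(peak_id = peak_id, chrom = chrom, start = anchor - width %/% 2L,
             end = anchor - width %/% 2L + width,
             summit_offset = NA_integer_, score = 0,
             stringsAsFactors = FALSE)
}

random_world <- function(seed, n_genes = 10, n_peaks = 20, n_chrom = 2,
                         len = 2e5) {
  set.seed(seed)
  chrom_g <- sample(sprintf("chr%d", seq_len(n_chrom)), n_genes, replace = TRUE)
  genes <- mk_genes(sprintf("g%02d", seq_len(n_genes)),
                    tss = sample.int(len, n_genes), chrom = chrom_g,
                    strand = sample(c("+", "-"), n_genes, replace = TRUE))
  chrom_p <- sample(sprintf("chr%d", seq_len(n_chrom)), n_peaks, replace = TRUE)
  peaks <- mk_peaks(sprintf("p%02d", seq_len(n_peaks)),
                    anchor = sample(seq(1000, len), n_peaks), chrom = chrom_p)
  list(genes = genes, peaks = peaks)
}

# all-pairs nearest-gene oracle (minimum |anchor - tss|, tie -> gene_id)
brute_nearest <- function(peaks, genes) {
  anchors <- peak_anchor(peaks)
  rows <- lapply(seq_len(nrow(peaks)), function(i) {
    g <- genes[genes$chrom == peaks$chrom[i], , drop = FALSE]
    if (!nrow(g)) return(NULL)
    d <- abs(anchors[i] - g$tss)
    g <- g[order(d, g$gene_id), , drop = FALSE]
    sd <- if (g$strand[1] == "+") anchors[i] - g$tss[1] else g$tss[1] - anchors[i]
    data.frame(peak_id = peaks$peak_id[i], gene_id = g$gene_id[1],
               distance = sd, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$peak_id, out$gene_id), , drop = FALSE]
}

# containment + fallback oracle for the gene-scan strategy
brute_scan <- function(peaks, genes, L) {
  anchors <- peak_anchor(peaks)
  rows <- list()
  for (i in seq_len(nrow(peaks))) {
    g <- genes[genes$chrom == peaks$chrom[i] &
                 abs(anchors[i] - genes$tss) <= L, , drop = FALSE]
    if (nrow(g)) {
      sd <- ifelse(g$strand == "+", anchors[i] - g$tss, g$tss - anchors[i])
      rows[[length(rows) + 1]] <- data.frame(
        peak_id = peaks$peak_id[i], gene_id = g$gene_id, distance = sd,
        mode = "scan", stringsAsFactors = FALSE)
    } else {
      nb <- brute_nearest(peaks[i, , drop = FALSE], genes)
      if (!is.null(nb)) {
        nb$mode <- "nearest_fallback"
        rows[[length(rows) + 1]] <- nb
      }
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$peak_id, out$gene_id), , drop = FALSE]
}

# one-sided hypergeometric tail by direct summation of choose() terms
hyper_tail <- function(a, m, n, q) {
  ks <- a:min(m, q)
  sum(exp(lchoose(m, ks) + lchoose(n, q - ks) - lchoose(m + n, q)))
}

# exact one-sided rank-sum p by enumerating all group assignments
wilcox_enum <- function(x, y) {
  all_v <- c(x, y)
  n1 <- length(x)
  r <- rank(all_v)
  obs <- sum(r[seq_len(n1)])
  combos <- combn(length(all_v), n1)
  ws <- apply(combos, 2, function(idx) sum(r[idx]))
  mean(ws >= obs)
}
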
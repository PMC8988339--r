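# Correlation-based scoring of peak-gene links across samples.

# Vectorised correlation between paired rows of two matrices (same column
# order). Returns r, two-sided p from the t transform with n - 2 df, and a
# zero-variance flag (r = NA there). For Spearman the rows are rank
# transformed first and the same t transform is applied.
.row_cor <- function(X, Y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  n <- ncol(X)
  if (method == "spearman") {
    X <- t(apply(X, 1, rank))
    Y <- t(apply(Y, 1, rank))
  }
  cx <- X - rowMeans(X)
  cy <- Y - rowMeans(Y)
  sx <- sqrt(rowSums(cx^2))
  sy <- sqrt(rowSums(cy^2))
  degenerate <- sx == 0 | sy == 0
  r <- rowSums(cx * cy) / (sx * sy)
  r[degenerate] <- NA_real_
  r <- pmin(pmax(r, -1), 1)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  p[!is.na(r) & abs(r) == 1] <- 0
  data.frame(r = r, p = p, n = n, undefined = degenerate)
}

#' Correlate peak accessibility with gene expression over links
#'
#' For each peak-gene link, computes the correlation of the peak's signal
#' row with the gene's expression row across the shared samples, plus the
#' two-sided p-value of the correlation (t transform, n - 2 df; for
#' Spearman the same transform is applied to the rank correlation). Links
#' whose peak or gene row has zero variance get `r = NA` and are flagged
#' `undefined`; they never pass the filter.
#'
#' @param links Peak-gene link table ([annotate_nearest()] / [annotate_scan()]).
#' @param peak_signal Peak-by-sample matrix ([read_signal_matrix()]).
#' @param gene_expr Gene-by-sample matrix with the identical, ordered
#'   sample set.
#' @param method `"pearson"` (default) or `"spearman"`. Values are used as
#'   supplied; any transformation (e.g. log) is the caller's choice.
#' @param r_min,p_max Filter thresholds (defaults 0.8 and 0.01); a link
#'   passes when `r > r_min` and `p < p_max`.
#' @return `data.frame`: `source_id` (peak), `gene_id`, `r`, `p`, `n`,
#'   `undefined`, `pass_filter`.
#' @export
peak_gene_cor <- function(links, peak_signal, gene_expr,
                          method = c("pearson", "spearman"),
                          r_min = 0.8, p_max = 0.01) {
  method <- match.arg(method)
  if (!identical(colnames(peak_signal), colnames(gene_expr)))
    .stopf("sample sets differ: peak samples [%s] vs expression samples [%s]",
           paste(colnames(peak_signal), collapse = ","),
           paste(colnames(gene_expr), collapse = ","))
  n <- ncol(peak_signal)
  if (n < 3) .stopf("need >= 3 shared samples, got %d", n)
  miss_p <- setdiff(links$peak_id, rownames(peak_signal))
  if (length(miss_p)) .stopf("peak(s) missing from signal matrix: %s", miss_p[1])
  miss_g <- setdiff(links$gene_id, rownames(gene_expr))
  if (length(miss_g)) .stopf("gene(s) missing from expression matrix: %s", miss_g[1])
  cc <- .row_cor(peak_signal[links$peak_id, , drop = FALSE],
                 gene_expr[links$gene_id, , drop = FALSE], method)
  out <- data.frame(source_id = links$peak_id, gene_id = links$gene_id,
                    cc, stringsAsFactors = FALSE)
  out$pass_filter <- !out$undefined & !is.na(out$r) &
    out$r > r_min & out$p < p_max
  out
}

#' Correlate distal peaks with each gene's promoter peak
#'
#' Treats the peak whose anchor is nearest a gene's TSS as that gene's
#' promoter; every other peak whose anchor lies within `tss +/- scan_length`
#' is a distal candidate. Each unique (distal peak, gene) pair yields one
#' correlation between the distal and promoter signal rows, so association
#' can be inferred from accessibility alone. Genes with no peak in the
#' window are skipped (count reported via a message).
#'
#' @param peaks Peak table.
#' @param genes Gene table.
#' @param peak_signal Peak-by-sample matrix with >= 3 samples.
#' @param scan_length Per-side window radius in bp (default 20000).
#' @param anchor Anchor policy, see [peak_anchor()].
#' @inheritParams peak_gene_cor
#' @return `data.frame`: `source_id` (distal peak), `anchor_id` (promoter
#'   peak), `gene_id`, `distance` (distal anchor to TSS, signed), `r`, `p`,
#'   `n`, `undefined`, `pass_filter`.
#' @export
enhancer_promoter_cor <- function(peaks, genes, peak_signal,
                                  scan_length = 20000L, anchor = "auto",
                                  method = c("pearson", "spearman"),
                                  r_min = 0.8, p_max = 0.01) {
  method <- match.arg(method)
  if (ncol(peak_signal) < 3) .stopf("need >= 3 samples")
  sl <- .scan_links(peaks, genes, scan_length, anchor)
  if (!nrow(sl)) .stopf("no peak falls in any gene scan window")
  n_skip <- sum(!genes$gene_id %in% sl$gene_id)
  if (n_skip) .msgf("%d gene(s) with no peak in window; skipped", n_skip)
  res <- lapply(split(sl, sl$gene_id), function(g) {
    ord <- order(abs(g$distance), g$peak_id)
    promoter <- g$peak_id[ord[1]]
    distal <- g[g$peak_id != promoter, , drop = FALSE]
    if (!nrow(distal)) return(NULL)
    data.frame(source_id = distal$peak_id, anchor_id = promoter,
               gene_id = g$gene_id[1], distance = distal$distance,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  if (is.null(res)) .stopf("no distal candidate peaks found")
  miss <- setdiff(unique(c(res$source_id, res$anchor_id)), rownames(peak_signal))
  if (length(miss)) .stopf("peak(s) missing from signal matrix: %s", miss[1])
  cc <- .row_cor(peak_signal[res$source_id, , drop = FALSE],
                 peak_signal[res$anchor_id, , drop = FALSE], method)
  out <- cbind(res, cc)
  out$pass_filter <- !out$undefined & !is.na(out$r) &
    out$r > r_min & out$p < p_max
  rownames(out) <- NULL
  out
}
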
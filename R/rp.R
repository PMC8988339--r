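# Regulatory potential (RP): per-gene summaries of nearby signal, weighted
# by an exponentially decaying function of distance to the TSS.

#' Exponential distance-decay weight
#'
#' `w(d) = 2^(-d / half_decay)`: weight 1 at the TSS, halving every
#' `half_decay` bp.
#'
#' @param d Non-negative distance(s) in bp.
#' @param half_decay Half-decay distance in bp (> 0).
#' @return Numeric weight(s) in (0, 1].
#' @examples
#' decay_weight(c(0, 1000, 2000), half_decay = 1000)  # 1, 0.5, 0.25
#' @export
decay_weight <- function(d, half_decay) {
  if (half_decay <= 0) .stopf("half_decay must be > 0")
  if (any(d < 0)) .stopf("distances must be >= 0")
  2^(-d / half_decay)
}

#' RP profile from gene-scan links and a peak-count matrix
#'
#' For each gene g and sample s,
#' `rp(g, s) = sum over linked peaks p of 2^(-|d_pg| / half_decay) * x(p, s)`,
#' where the sum runs over the gene's scan-mode links (nearest-fallback
#' links are excluded). Genes without scan links receive an all-zero row.
#'
#' @param scan_links Link table from [annotate_scan()] (only `mode == "scan"`
#'   rows are used).
#' @param peak_signal Peak-by-sample matrix; every linked peak must have a row.
#' @param half_decay Half-decay distance in bp (default 10000, suited to
#'   broad accessibility signal).
#' @param genes Optional gene table (or character vector of gene ids) naming
#'   the full gene universe, so unlinked genes get zero rows.
#' @return An `rp_profile` object: list with `rp` (gene-by-sample matrix),
#'   `weights` (`gene_id`, `peak_id`, `distance`, `w`), `with_peak_n`
#'   (named integer vector), `half_decay`.
#' @export
rp_region <- function(scan_links, peak_signal, half_decay = 10000,
                      genes = NULL) {
  sl <- scan_links[scan_links$mode == "scan", , drop = FALSE]
  if (!nrow(sl)) .stopf("no scan-mode links supplied")
  miss <- setdiff(sl$peak_id, rownames(peak_signal))
  if (length(miss)) .stopf("linked peak missing from signal matrix: %s", miss[1])
  gene_ids <- sort(unique(sl$gene_id))
  if (!is.null(genes)) {
    extra <- if (is.data.frame(genes)) genes$gene_id else genes
    gene_ids <- sort(unique(c(gene_ids, extra)))
  }
  w <- decay_weight(abs(sl$distance), half_decay)
  X <- peak_signal[sl$peak_id, , drop = FALSE]
  rp_link <- rowsum(X * w, group = sl$gene_id)
  rp <- matrix(0, nrow = length(gene_ids), ncol = ncol(peak_signal),
               dimnames = list(gene_ids, colnames(peak_signal)))
  rp[rownames(rp_link), ] <- rp_link
  npk <- setNames(integer(length(gene_ids)), gene_ids)
  tab <- table(sl$gene_id)
  npk[names(tab)] <- as.integer(tab)
  weights <- data.frame(gene_id = sl$gene_id, peak_id = sl$peak_id,
                        distance = sl$distance, w = w,
                        stringsAsFactors = FALSE)
  structure(list(rp = rp, weights = weights, with_peak_n = npk,
                 half_decay = half_decay),
            class = "rp_profile")
}

#' @export
print.rp_profile <- function(x, ...) {
  cat(sprintf("rp_profile: %d gene(s) x %d sample(s), %d weight(s), half_decay = %g bp\n",
              nrow(x$rp), ncol(x$rp), nrow(x$weights), x$half_decay))
  invisible(x)
}

# Exact sum of q^d for integer d in [a, b] (geometric partial sum).
.geom_sum <- function(q, a, b) {
  if (b < a) return(0)
  (q^a - q^(b + 1)) / (1 - q)
}

#' RP from a per-base coverage track
#'
#' Integrates base-resolution coverage around each TSS:
#' `rp(g) = sum over bases b with |b - tss| <= window of
#' 2^(-|b - tss| / half_decay) * signal(b)`. bedGraph intervals of constant
#' value are integrated with closed-form geometric partial sums. Genes on
#' chromosomes absent from the track get `rp = 0` with a warning.
#'
#' @param coverage bedGraph table from [read_bedgraph()].
#' @param genes Gene table.
#' @param half_decay Half-decay distance in bp (default 10000).
#' @param window Per-side integration window in bp (default 20000).
#' @return `data.frame` with `gene_id`, `rp`.
#' @export
rp_coverage <- function(coverage, genes, half_decay = 10000,
                        window = 20000L) {
  stopifnot(nrow(genes) > 0)
  if (window <= 0) .stopf("window must be > 0")
  q <- 2^(-1 / half_decay)
  by_chr <- split(coverage, coverage$chrom)
  n_nochr <- 0L
  rp <- vapply(seq_len(nrow(genes)), function(i) {
    cov <- by_chr[[genes$chrom[i]]]
    if (is.null(cov)) { n_nochr <<- n_nochr + 1L; return(0) }
    tss <- genes$tss[i]
    wlo <- tss - window; whi <- tss + window + 1L  # half-open window
    sel <- cov$end > wlo & cov$start < whi
    if (!any(sel)) return(0)
    cov <- cov[sel, , drop = FALSE]
    cs <- pmax(cov$start, wlo); ce <- pmin(cov$end, whi)
    total <- 0
    for (k in seq_along(cs)) {
      s <- cs[k]; e <- ce[k]; v <- cov$value[k]
      if (v == 0 || e <= s) next
      if (e - 1L < tss) {
        total <- total + v * .geom_sum(q, tss - e + 1L, tss - s)
      } else if (s > tss) {
        total <- total + v * .geom_sum(q, s - tss, e - 1L - tss)
      } else {
        if (s < tss) total <- total + v * .geom_sum(q, 1L, tss - s)
        total <- total + v * .geom_sum(q, 0L, e - 1L - tss)
      }
    }
    total
  }, numeric(1))
  if (n_nochr) .warnf("%d gene(s) on chromosomes absent from coverage; rp = 0", n_nochr)
  data.frame(gene_id = genes$gene_id, rp = rp, stringsAsFactors = FALSE)
}

#' RP of genes from one TF's ChIP-seq peaks
#'
#' Each TF peak within a gene's scan window contributes unit signal weighted
#' by distance decay:
#' `sum_rp(g) = sum over peaks in window of 2^(-|d| / half_decay)`.
#' Genes are ranked by descending `sum_rp`; ties receive the average
#' (mid) rank. High RP marks likely direct targets.
#'
#' @param tf_peaks Peak table of one TF's ChIP peaks (non-empty).
#' @param genes Gene table.
#' @param half_decay Half-decay distance in bp (default 1000, suited to
#'   sharp TF binding).
#' @param window Per-side scan radius in bp (default 20000).
#' @param anchor Anchor policy, see [peak_anchor()].
#' @return `data.frame` with `gene_id`, `with_peak_n`, `sum_rp`, `rp_rank`,
#'   sorted by `rp_rank` (then `gene_id`).
#' @export
rp_tfhit <- function(tf_peaks, genes, half_decay = 1000, window = 20000L,
                     anchor = "auto") {
  if (is.null(tf_peaks) || !nrow(tf_peaks)) .stopf("tf_peaks is empty")
  sl <- .scan_links(tf_peaks, genes, window, anchor)
  w <- decay_weight(abs(sl$distance), half_decay)
  sum_rp <- setNames(numeric(nrow(genes)), genes$gene_id)
  npk <- setNames(integer(nrow(genes)), genes$gene_id)
  if (nrow(sl)) {
    agg <- rowsum(w, group = sl$gene_id)
    sum_rp[rownames(agg)] <- agg[, 1]
    tab <- table(sl$gene_id)
    npk[names(tab)] <- as.integer(tab)
  }
  out <- data.frame(gene_id = names(sum_rp), with_peak_n = as.integer(npk),
                    sum_rp = as.numeric(sum_rp),
                    rp_rank = rank_with_ties(as.numeric(sum_rp), "descending"),
                    stringsAsFactors = FALSE)
  out <- out[order(out$rp_rank, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
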
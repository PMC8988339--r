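# Direct TF target calling: combine ChIP RP ranks with differential
# expression ranks by rank product.

#' Rank with average (mid) ranks for ties
#'
#' @param values Numeric vector, no missing values.
#' @param direction `"ascending"` (smallest value gets rank 1) or
#'   `"descending"` (largest value gets rank 1).
#' @return Numeric vector of ranks; tied values share their mean position,
#'   so ranks always sum to `n (n + 1) / 2`.
#' @examples
#' rank_with_ties(c(5, 5), "ascending")  # 1.5 1.5
#' @export
rank_with_ties <- function(values, direction = c("ascending", "descending")) {
  direction <- match.arg(direction)
  if (!length(values)) .stopf("values must be non-empty")
  if (anyNA(values)) .stopf("values must not contain NA")
  if (direction == "ascending") rank(values, ties.method = "average")
  else rank(-values, ties.method = "average")
}

#' Integrate TF ChIP-seq RP ranks with differential expression
#'
#' Combines the RP ranking of a TF's ChIP peaks ([rp_tfhit()]) with a
#' differential-expression table by rank product: genes with more
#' TSS-proximal binding (low RP rank) and stronger differential expression
#' (low padj rank) get the smallest products and head the target list.
#'
#' `diff_rank` is the ascending mid-rank of `padj` among the genes of the
#' selected category; `rank_product = rp_rank * diff_rank` (fractional
#' mid-ranks propagate exactly); `rank_of_rank_product` is the ascending
#' mid-rank of the products.
#'
#' @param rp_table Output of [rp_tfhit()].
#' @param dge DGE table ([read_dge()]): `gene_id`, `log2fc`, `padj`,
#'   `gene_category`.
#' @param category Which DGE genes to rank: `"up"`, `"down"` or `"both"`.
#' @param recompute_rp_rank Recompute `rp_rank` within the intersected gene
#'   universe (default `TRUE`); set `FALSE` to keep the ranks of the full
#'   ChIP universe.
#' @return `data.frame` sorted by `rank_of_rank_product` with columns
#'   `gene_id`, `with_peak_n`, `sum_rp`, `rp_rank`, `log2fc`, `padj`,
#'   `diff_rank`, `rank_product`, `rank_of_rank_product`, `gene_category`.
#' @export
integrate_chip_rna <- function(rp_table, dge,
                               category = c("up", "down", "both"),
                               recompute_rp_rank = TRUE) {
  category <- match.arg(category)
  keep <- if (category == "both") dge$gene_category %in% c("up", "down")
          else dge$gene_category == category
  dge <- dge[keep, , drop = FALSE]
  common <- intersect(rp_table$gene_id, dge$gene_id)
  if (!length(common))
    .stopf("no genes shared between the RP table and the selected DGE genes")
  n_drop <- (nrow(rp_table) - length(common)) + (nrow(dge) - length(common))
  if (n_drop) .msgf("%d gene(s) present in only one input; dropped", n_drop)
  rp <- rp_table[match(common, rp_table$gene_id), , drop = FALSE]
  de <- dge[match(common, dge$gene_id), , drop = FALSE]
  rp_rank <- if (recompute_rp_rank) rank_with_ties(rp$sum_rp, "descending")
             else rp$rp_rank
  diff_rank <- rank_with_ties(de$padj, "ascending")
  rank_product <- rp_rank * diff_rank
  out <- data.frame(
    gene_id = common, with_peak_n = rp$with_peak_n, sum_rp = rp$sum_rp,
    rp_rank = rp_rank, log2fc = de$log2fc, padj = de$padj,
    diff_rank = diff_rank, rank_product = rank_product,
    rank_of_rank_product = rank_with_ties(rank_product, "ascending"),
    gene_category = de$gene_category, stringsAsFactors = FALSE)
  out <- out[order(out$rank_of_rank_product, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Top-k predicted targets
#'
#' @param table Target table from [integrate_chip_rna()].
#' @param k Number of genes to return (`k <= nrow(table)`).
#' @return Character vector of the first `k` gene ids by
#'   `rank_of_rank_product`, ties broken by lexicographic `gene_id`.
#' @export
top_targets <- function(table, k) {
  if (k > nrow(table)) .stopf("k (%d) exceeds table size (%d)", k, nrow(table))
  ord <- order(table$rank_of_rank_product, table$gene_id)
  table$gene_id[ord][seq_len(k)]
}
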
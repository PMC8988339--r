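# Influential-TF statistics: each returns a common ranking table with
# columns tf_id, statistic, p, p_adj (BH across TFs), z (inverse-normal of
# the rank) and rank (1 = most enriched).

#' Inverse-normal transform of ranks
#'
#' Maps rank r out of N to `z = qnorm((N - r + 0.5) / N)`: rank 1 gets the
#' largest z, the middle rank maps to 0, and the 0.5/N offset keeps the
#' extremes finite.
#'
#' @param ranks Numeric ranks in 1..N (mid-ranks allowed).
#' @return Numeric z-scores, strictly decreasing in rank.
#' @export
inverse_normal_z <- function(ranks) {
  N <- length(ranks)
  qnorm((N - ranks + 0.5) / N)
}

# Attach p_adj, rank and z to a (tf_id, statistic, p) table. Rank order:
# ascending p, then descending statistic, then tf_id (a deterministic
# permutation of 1..n so z is strictly decreasing in rank).
.finalize_ranking <- function(df) {
  df$p_adj <- p.adjust(df$p, method = "BH")
  ord <- order(df$p, -df$statistic, df$tf_id)
  df <- df[ord, , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  df$z <- inverse_normal_z(df$rank)
  rownames(df) <- NULL
  df
}

# One-sided (greater) two-sample rank-sum test of x vs y. Exact when the
# smaller group has <= `exact_max` observations: via wilcox.test's exact
# distribution when tie-free, by full enumeration of group assignments of
# the (mid-)ranks when tied; otherwise normal approximation with tie and
# continuity correction. Returns list(p, z, U).
.wilcox_greater <- function(x, y, exact_max = 8) {
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  all_v <- c(x, y)
  ties <- anyDuplicated(all_v) > 0
  r <- rank(all_v)
  W <- sum(r[seq_len(n1)])
  U <- W - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  tab <- table(all_v)
  sig2 <- n1 * n2 / 12 * ((n + 1) - sum(tab^3 - tab) / (n * (n - 1)))
  if (sig2 <= 0) return(list(p = 1, z = 0, U = U))
  z <- (U - mu - 0.5) / sqrt(sig2)
  if (min(n1, n2) <= exact_max && choose(n, n1) <= 2e4) {
    if (!ties) {
      p <- wilcox.test(x, y, alternative = "greater", exact = TRUE)$p.value
    } else {
      combos <- utils::combn(n, n1)
      ws <- colSums(matrix(r[combos], nrow = n1))
      p <- mean(ws >= W)
    }
  } else {
    p <- pnorm(z, lower.tail = FALSE)
  }
  list(p = p, z = z, U = U)
}

.check_query <- function(query, universe, what) {
  if (!length(query)) .stopf("empty query %s set", what)
  extra <- setdiff(query, universe)
  if (length(extra))
    .stopf("query %s(s) outside the universe: %s", what, extra[1])
  if (length(unique(query)) == length(unique(universe)))
    .stopf("query equals the universe; no background to test against")
}

#' TF enrichment in a peak set by Fisher's exact test
#'
#' For each TF, tabulates bound/unbound peaks in the query set versus the
#' background (universe minus query) and applies the one-sided
#' hypergeometric (Fisher exact, alternative "greater") test. The reported
#' statistic is the sample odds ratio, with a Haldane 0.5 correction when
#' any cell is zero.
#'
#' @param query_peaks Character vector of query peak ids (subset of the
#'   universe, non-empty, not the whole universe).
#' @param universe_peaks Character vector of all peak ids.
#' @param hits `tf_hits` object.
#' @return Ranking `data.frame`: `tf_id`, `statistic` (odds ratio),
#'   `n_query_hit`, `n_bg_hit`, `p`, `p_adj`, `rank`, `z`.
#' @export
tf_enrich_fisher <- function(query_peaks, universe_peaks, hits) {
  query_peaks <- unique(query_peaks)
  universe_peaks <- unique(universe_peaks)
  .check_query(query_peaks, universe_peaks, "peak")
  nq <- length(query_peaks)
  nb <- length(universe_peaks) - nq
  rows <- lapply(names(hits), function(tf) {
    h <- intersect(hits[[tf]], universe_peaks)
    a <- sum(query_peaks %in% h)
    c_ <- length(h) - a
    b <- nq - a; d <- nb - c_
    p <- phyper(a - 1, a + c_, b + d, nq, lower.tail = FALSE)
    or <- if (a == 0 || b == 0 || c_ == 0 || d == 0)
      ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5))
    else (a * d) / (b * c_)
    data.frame(tf_id = tf, statistic = or, n_query_hit = a, n_bg_hit = c_,
               p = p, stringsAsFactors = FALSE)
  })
  .finalize_ranking(do.call(rbind, rows))
}

#' TF enrichment in a peak set by Wilcoxon rank-sum test
#'
#' Scores every universe peak per TF (binding indicator from `hits`, or a
#' caller-supplied per-peak score matrix) and tests query scores against
#' background scores with a one-sided (greater) rank-sum test: exact
#' enumeration for small tie-free groups, otherwise normal approximation
#' with tie and continuity correction.
#'
#' @inheritParams tf_enrich_fisher
#' @param peak_scores Optional peak-by-TF numeric matrix of per-peak scores
#'   (rownames = peak ids); when absent the 0/1 hit indicator is used.
#' @return Ranking `data.frame`: `tf_id`, `statistic` (rank-sum z), `p`,
#'   `p_adj`, `rank`, `z`.
#' @export
tf_enrich_wilcox <- function(query_peaks, universe_peaks, hits = NULL,
                             peak_scores = NULL) {
  query_peaks <- unique(query_peaks)
  universe_peaks <- unique(universe_peaks)
  .check_query(query_peaks, universe_peaks, "peak")
  bg <- setdiff(universe_peaks, query_peaks)
  if (is.null(peak_scores)) {
    if (is.null(hits)) .stopf("supply either 'hits' or 'peak_scores'")
    tfs <- names(hits)
    score <- function(tf, ids) as.numeric(ids %in% hits[[tf]])
  } else {
    tfs <- colnames(peak_scores)
    miss <- setdiff(universe_peaks, rownames(peak_scores))
    if (length(miss)) .stopf("peak(s) missing from peak_scores: %s", miss[1])
    score <- function(tf, ids) peak_scores[ids, tf]
  }
  rows <- lapply(tfs, function(tf) {
    w <- .wilcox_greater(score(tf, query_peaks), score(tf, bg))
    data.frame(tf_id = tf, statistic = w$z, p = w$p, stringsAsFactors = FALSE)
  })
  .finalize_ranking(do.call(rbind, rows))
}

#' TF over-representation in a gene set via known TF-target pairs
#'
#' GO-enrichment-style hypergeometric test: for each TF, the overlap of its
#' known targets with the query gene set is tested against the gene
#' universe. TFs with no targets in the universe are dropped with a warning.
#'
#' @param query_genes Character vector of query gene ids (subset of the
#'   universe).
#' @param universe_genes Character vector of all gene ids considered.
#' @param pairs TF-target table ([read_tt_pairs()]).
#' @return Ranking `data.frame`: `tf_id`, `statistic` (fold enrichment,
#'   observed/expected overlap), `n_targets`, `n_overlap`, `overlap_genes`
#'   (comma separated), `p`, `p_adj`, `rank`, `z`.
#' @export
tf_tt_pair <- function(query_genes, universe_genes, pairs) {
  query_genes <- unique(query_genes)
  universe_genes <- unique(universe_genes)
  .check_query(query_genes, universe_genes, "gene")
  all_tfs <- unique(pairs$tf_id)
  pairs <- pairs[pairs$target_gene_id %in% universe_genes, , drop = FALSE]
  dropped <- setdiff(all_tfs, unique(pairs$tf_id))
  if (length(dropped))
    .warnf("%d TF(s) with no targets in the universe; dropped", length(dropped))
  tf_targets <- split(pairs$target_gene_id, pairs$tf_id)
  if (!length(tf_targets)) .stopf("no TF has targets in the universe")
  N <- length(universe_genes); q <- length(query_genes)
  rows <- lapply(names(tf_targets), function(tf) {
    tg <- unique(tf_targets[[tf]])
    ov <- intersect(tg, query_genes)
    k <- length(ov); m <- length(tg)
    p <- phyper(k - 1, m, N - m, q, lower.tail = FALSE)
    data.frame(tf_id = tf, statistic = k / (m * q / N), n_targets = m,
               n_overlap = k, overlap_genes = paste(sort(ov), collapse = ","),
               p = p, stringsAsFactors = FALSE)
  })
  .finalize_ranking(do.call(rbind, rows))
}

#' TF enrichment in a gene set by TSS-proximal binding-site counts
#'
#' For each gene, counts the TF-bound peaks among the gene's scan-mode
#' links (optionally weighting each hit by the distance-decay weight), then
#' compares query-gene counts against background-gene counts per TF with a
#' one-sided rank-sum test.
#'
#' @inheritParams tf_tt_pair
#' @param hits `tf_hits` object.
#' @param scan_links Link table from [annotate_scan()]; only scan-mode rows
#'   provide the gene-peak geometry.
#' @param weighted Weight each hit by `decay_weight(|distance|, half_decay)`
#'   instead of counting (default `FALSE`).
#' @param half_decay Half-decay in bp for `weighted = TRUE` (default 1000).
#' @return Ranking `data.frame`: `tf_id`, `statistic` (rank-sum z), `p`,
#'   `p_adj`, `rank`, `z`.
#' @export
tf_hit_test <- function(query_genes, universe_genes, hits, scan_links,
                        weighted = FALSE, half_decay = 1000) {
  query_genes <- unique(query_genes)
  universe_genes <- unique(universe_genes)
  .check_query(query_genes, universe_genes, "gene")
  sl <- scan_links[scan_links$mode == "scan" &
                     scan_links$gene_id %in% universe_genes, , drop = FALSE]
  bg <- setdiff(universe_genes, query_genes)
  wt <- if (weighted) decay_weight(abs(sl$distance), half_decay)
        else rep(1, nrow(sl))
  rows <- lapply(names(hits), function(tf) {
    hit <- sl$peak_id %in% hits[[tf]]
    counts <- setNames(numeric(length(universe_genes)), universe_genes)
    if (any(hit)) {
      agg <- rowsum(wt[hit], group = sl$gene_id[hit])
      counts[rownames(agg)] <- agg[, 1]
    }
    w <- .wilcox_greater(counts[query_genes], counts[bg])
    data.frame(tf_id = tf, statistic = w$z, p = w$p, stringsAsFactors = FALSE)
  })
  .finalize_ranking(do.call(rbind, rows))
}

#' TF influence on a gene set via attributable regulatory potential
#'
#' Splits each gene's RP into the share attributable to a TF's bound peaks:
#' `a(g, TF, s) = sum over linked peaks p bound by TF of w(g, p) * x(p, s)`.
#' Per sample, the proportion attributable `a / rp` (0 where `rp = 0`) is
#' compared between query and background genes with a one-sided rank-sum
#' test; the per-TF summary p-value is the Bonferroni-adjusted minimum over
#' samples. The per-(gene, TF, sample) table supports per-gene drill-down.
#'
#' @inheritParams tf_tt_pair
#' @param rp_profile `rp_profile` from [rp_region()] built on the same peak
#'   universe as `hits`.
#' @param peak_signal The peak-by-sample matrix used to build the profile.
#' @param hits `tf_hits` object; hits on peaks absent from the profile's
#'   weights are ignored (count reported).
#' @param detail Which genes to keep in the detail table: `"query"`
#'   (default), `"all"`, or `"none"`.
#' @return List with `ranking` (summary table: `tf_id`, `statistic` = max
#'   per-sample rank-sum z, `p` = Bonferroni-min over samples, `p_adj`,
#'   `rank`, `z`), `per_sample_p` (TF-by-sample matrix), and `detail`
#'   (long `data.frame`: `gene_id`, `tf_id`, `sample`, `rp`, `rp_attr`,
#'   `prop_attr`).
#' @export
tf_region_rp <- function(query_genes, rp_profile, peak_signal, hits,
                         detail = c("query", "all", "none")) {
  detail <- match.arg(detail)
  stopifnot(inherits(rp_profile, "rp_profile"))
  universe_genes <- rownames(rp_profile$rp)
  query_genes <- unique(query_genes)
  .check_query(query_genes, universe_genes, "gene")
  bg <- setdiff(universe_genes, query_genes)
  W <- rp_profile$weights
  n_unknown <- sum(!unique(unlist(hits)) %in% unique(W$peak_id))
  if (n_unknown) .msgf("%d hit peak(s) absent from the RP profile; ignored", n_unknown)
  samples <- colnames(rp_profile$rp)
  RP <- rp_profile$rp
  per_sample_p <- matrix(NA_real_, length(hits), length(samples),
                         dimnames = list(names(hits), samples))
  stat <- setNames(numeric(length(hits)), names(hits))
  detail_rows <- list()
  qi <- match(query_genes, universe_genes)
  bi <- match(bg, universe_genes)
  for (tf in names(hits)) {
    sel <- W$peak_id %in% hits[[tf]]
    A <- matrix(0, nrow(RP), ncol(RP), dimnames = dimnames(RP))
    if (any(sel)) {
      ws <- W[sel, , drop = FALSE]
      agg <- rowsum(peak_signal[ws$peak_id, , drop = FALSE] * ws$w,
                    group = ws$gene_id)
      A[rownames(agg), ] <- agg
    }
    prop <- ifelse(RP > 0, A / pmax(RP, .Machine$double.xmin), 0)
    zbest <- -Inf
    for (s in seq_along(samples)) {
      w <- .wilcox_greater(prop[qi, s], prop[bi, s])
      per_sample_p[tf, s] <- w$p
      zbest <- max(zbest, w$z)
    }
    stat[tf] <- zbest
    if (detail != "none") {
      keep <- if (detail == "query") qi else seq_len(nrow(RP))
      detail_rows[[tf]] <- data.frame(
        gene_id = rep(universe_genes[keep], times = length(samples)),
        tf_id = tf,
        sample = rep(samples, each = length(keep)),
        rp = as.vector(RP[keep, , drop = FALSE]),
        rp_attr = as.vector(A[keep, , drop = FALSE]),
        prop_attr = as.vector(prop[keep, , drop = FALSE]),
        stringsAsFactors = FALSE)
    }
  }
  summary_p <- pmin(apply(per_sample_p, 1, min) * length(samples), 1)
  ranking <- .finalize_ranking(data.frame(
    tf_id = names(hits), statistic = as.numeric(stat),
    p = as.numeric(summary_p), stringsAsFactors = FALSE))
  list(ranking = ranking, per_sample_p = per_sample_p,
       detail = if (detail == "none") NULL else do.call(rbind, detail_rows))
}

#' Combine TF rankings from replicates or sources
#'
#' Aligns the tables on their common TF universe (TFs missing from any
#' table are dropped with a warning) and combines per-TF evidence:
#' `"geometric_mean"` of p-values (default), `"stouffer"` (sum of the
#' per-table z columns over sqrt(k), converted back to a p-value), or
#' `"mean_rank"`.
#'
#' @param tables List of ranking tables (any `tf_*` output).
#' @param method Combination rule.
#' @return Ranking `data.frame` with the combined value as `statistic`;
#'   `p`/`p_adj` are set for the p-like methods and `NA` for `mean_rank`.
#' @export
combine_replicates <- function(tables,
                               method = c("geometric_mean", "stouffer",
                                          "mean_rank")) {
  method <- match.arg(method)
  stopifnot(length(tables) >= 1)
  common <- Reduce(intersect, lapply(tables, `[[`, "tf_id"))
  n_drop <- length(unique(unlist(lapply(tables, `[[`, "tf_id")))) - length(common)
  if (n_drop) .warnf("%d TF(s) missing from some table(s); dropped", n_drop)
  if (!length(common)) .stopf("no TF shared across tables")
  k <- length(tables)
  get <- function(col) sapply(tables, function(t) t[[col]][match(common, t$tf_id)])
  if (method == "geometric_mean") {
    P <- matrix(get("p"), ncol = k)
    comb <- exp(rowMeans(log(pmax(P, 1e-300))))
    df <- data.frame(tf_id = common, statistic = -log10(comb), p = comb,
                     stringsAsFactors = FALSE)
    out <- .finalize_ranking(df)
  } else if (method == "stouffer") {
    Z <- matrix(get("z"), ncol = k)
    zc <- rowSums(Z) / sqrt(k)
    df <- data.frame(tf_id = common, statistic = zc,
                     p = pnorm(zc, lower.tail = FALSE), stringsAsFactors = FALSE)
    out <- .finalize_ranking(df)
  } else {
    R <- matrix(get("rank"), ncol = k)
    mr <- rowMeans(R)
    df <- data.frame(tf_id = common, statistic = mr, p = NA_real_,
                     p_adj = NA_real_, stringsAsFactors = FALSE)
    ord <- order(df$statistic, df$tf_id)
    out <- df[ord, , drop = FALSE]
    out$rank <- seq_len(nrow(out))
    out$z <- inverse_normal_z(out$rank)
    rownames(out) <- NULL
  }
  out
}

#' Jaccard co-occurrence between TFs
#'
#' `J(a, b) = |Sa intersect Sb| / |Sa union Sb|` over each TF's bound peaks
#' (or target genes), optionally restricted to a query set first.
#' `J(a, a) = 1`; two empty sets give 0.
#'
#' @param sets Named list of character vectors (per-TF peak or gene sets).
#' @param query Optional character vector; sets are intersected with it.
#' @return Symmetric numeric TF-by-TF matrix.
#' @export
jaccard_tf <- function(sets, query = NULL) {
  if (length(sets) < 2) .stopf("need >= 2 TF sets")
  if (!is.null(query)) sets <- lapply(sets, intersect, y = query)
  tfs <- names(sets)
  J <- matrix(0, length(sets), length(sets), dimnames = list(tfs, tfs))
  for (i in seq_along(sets)) {
    J[i, i] <- 1
    for (j in seq_len(i - 1)) {
      u <- length(union(sets[[i]], sets[[j]]))
      J[i, j] <- J[j, i] <- if (u == 0) 0 else
        length(intersect(sets[[i]], sets[[j]])) / u
    }
  }
  J
}
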
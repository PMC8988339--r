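# Peak-gene annotation strategies against brute-force oracles.

test_that("a peak at the TSS links at distance zero", {
  genes <- mk_genes("g1", tss = 5000L)
  peaks <- mk_peaks("p1", anchor = 5000L)
  l <- annotate_nearest(peaks, genes)
  expect_equal(l$gene_id, "g1")
  expect_equal(l$distance, 0L)
  expect_equal(l$mode, "nearest")
})

test_that("equidistant genes resolve to the lexicographically smaller id", {
  genes <- mk_genes(c("gB", "gA"), tss = c(1000L, 3000L))
  peaks <- mk_peaks("p1", anchor = 2000L)
  l <- annotate_nearest(peaks, genes)
  expect_equal(l$gene_id, "gA")
  # and with the names swapped the other gene wins
  genes2 <- mk_genes(c("gA", "gB"), tss = c(1000L, 3000L))
  expect_equal(annotate_nearest(peaks, genes2)$gene_id, "gA")
})

test_that("nearest annotation is one-to-one and matches the all-pairs oracle", {
  for (seed in 1:5) {
    w <- random_world(seed)
    l <- suppressWarnings(annotate_nearest(w$peaks, w$genes))
    expect_equal(anyDuplicated(l$peak_id), 0L)
    oracle <- brute_nearest(w$peaks, w$genes)
    rownames(oracle) <- NULL
    expect_equal(l[, c("peak_id", "gene_id", "distance")], oracle)
  }
})

test_that("peaks on chromosomes without genes are omitted with a warning", {
  genes <- mk_genes("g1", tss = 1000L, chrom = "chr1")
  peaks <- mk_peaks(c("p1", "p2"), anchor = c(1000L, 1000L),
                    chrom = c("chr1", "chrX"))
  expect_warning(l <- annotate_nearest(peaks, genes), "1 peak")
  expect_equal(l$peak_id, "p1")
})

test_that("scan mode links every gene whose window contains the anchor", {
  genes <- mk_genes(c("gA", "gB"), tss = c(100000L, 110000L))
  peaks <- mk_peaks("p1", anchor = 95000L)  # 5 kb from gA, 15 kb from gB
  l <- annotate_scan(peaks, genes, scan_length = 20000L)
  expect_equal(sort(l$gene_id), c("gA", "gB"))
  expect_true(all(l$mode == "scan"))
  expect_true(all(abs(l$distance) <= 20000))
})

test_that("a peak outside every scan window falls back to the nearest gene", {
  genes <- mk_genes("g1", tss = 100000L)
  peaks <- mk_peaks("p1", anchor = 200000L)
  l <- annotate_scan(peaks, genes, scan_length = 20000L)
  expect_equal(nrow(l), 1L)
  expect_equal(abs(l$distance), 100000L)
  expect_equal(l$mode, "nearest_fallback")
})

test_that("gene-scan links match the containment + fallback oracle", {
  for (seed in 6:10) {
    w <- random_world(seed, n_genes = 8, n_peaks = 25)
    l <- suppressWarnings(annotate_scan(w$peaks, w$genes, 20000L))
    oracle <- suppressWarnings(brute_scan(w$peaks, w$genes, 20000L))
    rownames(oracle) <- NULL
    expect_equal(l, oracle)
    expect_gte(nrow(l), sum(w$peaks$chrom %in% w$genes$chrom))
    expect_true(all(abs(l$distance[l$mode == "scan"]) <= 20000))
  }
})

test_that("gene-bound keeps nearest links and supplements unassigned genes", {
  genes <- mk_genes(c("g1", "g2"), tss = c(1000L, 50000L))
  peaks <- mk_peaks(c("p1", "p7"), anchor = c(1000L, 47000L))
  # p7 is 3 kb from g2 but still nearest to... check: |47000-1000|=46000 vs 3000
  res <- annotate_gene_bound(c("g1", "g2"), peaks, genes)
  expect_setequal(res$links$gene_id, c("g1", "g2"))
  expect_equal(res$links$mode[res$links$gene_id == "g2"], "nearest")
  # force g2 to need a gene_bound link: both peaks nearest to g1
  peaks2 <- mk_peaks(c("p1", "p7"), anchor = c(1000L, 2000L))
  res2 <- annotate_gene_bound(c("g1", "g2"), peaks2, genes)
  g2link <- res2$links[res2$links$gene_id == "g2", ]
  expect_equal(g2link$mode, "gene_bound")
  expect_equal(g2link$peak_id, "p7")  # nearest peak to g2's TSS
  expect_equal(length(res2$unresolvable), 0L)
})

test_that("every resolvable query gene is covered; others are reported", {
  w <- random_world(11, n_genes = 8, n_peaks = 12)
  # add a gene on a peak-free chromosome
  extra <- mk_genes("gX", tss = 1000L, chrom = "chrZ")
  genes <- rbind(w$genes, extra)
  query <- c(w$genes$gene_id[1:5], "gX")
  res <- suppressWarnings(annotate_gene_bound(query, w$peaks, genes))
  expect_equal(res$unresolvable, "gX")
  expect_true(all(setdiff(query, "gX") %in% res$links$gene_id))
  # two-pass oracle: genes covered by nearest keep those links
  near <- suppressWarnings(annotate_nearest(w$peaks, genes))
  covered <- intersect(query, near$gene_id)
  got <- res$links[res$links$gene_id %in% covered, c("peak_id", "gene_id")]
  want <- near[near$gene_id %in% covered, c("peak_id", "gene_id")]
  ord <- function(d) d[order(d$peak_id, d$gene_id), ]
  expect_equal(ord(got), ord(want), ignore_attr = TRUE)
})

test_that("link summaries count pairs exactly", {
  links <- data.frame(peak_id = c("p1", "p2", "p3"), gene_id = "g1",
                      distance = c(0L, 10L, -20L), mode = "scan")
  s <- summarize_links(links)
  expect_equal(s$gene_counts$n_peaks, 3L)
  expect_true(all(s$peak_counts$n_genes == 1L))
  expect_equal(sum(s$gene_counts$n_peaks), nrow(links))
  cc <- pair_count_summary(links)
  expect_equal(cc$genes_by_peak_n,
               data.frame(n_peaks = 3L, n_genes = 1L))
})

test_that("count-of-counts matches a brute-force tally on a random world", {
  w <- random_world(12)
  l <- suppressWarnings(annotate_scan(w$peaks, w$genes, 20000L))
  cc <- pair_count_summary(l)
  tally <- table(table(l$gene_id))
  expect_equal(cc$genes_by_peak_n$n_genes, as.integer(tally))
  expect_equal(cc$genes_by_peak_n$n_peaks, as.integer(names(tally)))
})

test_that("distance histograms use half-open bins and cover all links", {
  links <- data.frame(peak_id = sprintf("p%d", 1:4), gene_id = "g",
                      distance = c(-100L, 0L, 99L, 100L), mode = "scan")
  h <- distance_distribution(links, breaks = c(-100, 0, 100, 200))
  expect_equal(sum(h$count), 4L)
  expect_equal(h$count, c(1L, 2L, 1L))  # 0 goes to [0,100), 100 to [100,200)
})

test_that("annotation output is deterministic", {
  w <- random_world(13)
  l1 <- suppressWarnings(annotate_scan(w$peaks, w$genes, 20000L))
  l2 <- suppressWarnings(annotate_scan(w$peaks, w$genes, 20000L))
  expect_identical(l1, l2)
})
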
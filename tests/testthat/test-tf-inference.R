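# TF-influence statistics: exact oracles, invariants, planted recovery.

check_ranking_contract <- function(rk) {
  expect_true(all(rk$p_adj >= rk$p - 1e-12))
  expect_equal(sort(rk$rank), seq_len(nrow(rk)))
  expect_true(all(diff(rk$z[order(rk$rank)]) < 0))
  expect_true(all(rk$p >= 0 & rk$p <= 1))
}

test_that("inverse-normal z maps ranks symmetrically around the median", {
  expect_equal(inverse_normal_z(c(1, 2, 3))[2], 0)
  expect_equal(inverse_normal_z(1:3)[1], qnorm(2.5 / 3))
  expect_equal(round(inverse_normal_z(1:3)[1], 4), 0.9674)
  # reversing the rank vector negates the z vector elementwise
  r2 <- 1:7
  expect_equal(inverse_normal_z(r2), -inverse_normal_z(rev(r2)))
})

test_that("Fisher enrichment p equals the direct hypergeometric summation", {
  # craft the 2x2 table (80, 20, 90, 810)
  universe <- c(sprintf("q%03d", 1:100), sprintf("b%03d", 1:900))
  hits <- tf_hits(list(TFA = c(sprintf("q%03d", 1:80), sprintf("b%03d", 1:90))),
                  "chipseq")
  rk <- tf_enrich_fisher(sprintf("q%03d", 1:100), universe, hits)
  expect_equal(rk$p, hyper_tail(80, 170, 830, 100), tolerance = 1e-12)
  expect_equal(rk$n_query_hit, 80L)
})

test_that("Fisher p matches the summation oracle across a table sweep", {
  set.seed(41)
  for (i in 1:200) {
    N <- sample(10:200, 1)
    m <- sample(1:(N - 1), 1)
    q <- sample(1:(N - 1), 1)
    a <- sample(0:min(m, q), 1)
    if (a > m || q - a > N - m) next
    p_pkg <- phyper(a - 1, m, N - m, q, lower.tail = FALSE)
    expect_equal(p_pkg, hyper_tail(a, m, N - m, q), tolerance = 1e-10)
  }
  # the same identity through the exported interface on a concrete table
  universe <- sprintf("u%03d", 1:50)
  query <- universe[1:10]
  h <- tf_hits(list(T1 = universe[c(1:6, 20:28)]), "motif")
  rk <- tf_enrich_fisher(query, universe, h)
  expect_equal(rk$p, hyper_tail(6, 15, 35, 10), tolerance = 1e-10)
})

test_that("a TF absent from the query never outranks one present in it", {
  universe <- sprintf("u%03d", 1:100)
  query <- universe[1:20]
  h <- tf_hits(list(absent = universe[21:60], present = universe[1:10]),
               "chipseq")
  rk <- tf_enrich_fisher(query, universe, h)
  expect_equal(rk$tf_id[1], "present")
  expect_error(tf_enrich_fisher(universe, universe, h), "background")
  check_ranking_contract(rk)
})

test_that("Wilcoxon enrichment: degenerate, exact and enumerated cases", {
  universe <- sprintf("u%d", 1:10)
  query <- universe[1:5]
  h <- tf_hits(list(T1 = "u99"), "motif")  # no scored hits in universe
  rk <- tf_enrich_wilcox(query, universe, h)
  expect_equal(rk$p, 1)
  # query scores {3,4,5} vs background {1,2}: exact p = 1 / C(5,2) = 0.1
  scores <- matrix(c(3, 4, 5, 1, 2), ncol = 1,
                   dimnames = list(c("q1", "q2", "q3", "b1", "b2"), "T1"))
  rk2 <- tf_enrich_wilcox(c("q1", "q2", "q3"), rownames(scores),
                          peak_scores = scores)
  expect_equal(rk2$p, 0.1)
  expect_equal(rk2$p, wilcox_enum(c(3, 4, 5), c(1, 2)))
  # enumeration oracle on random tie-free scores
  set.seed(42)
  v <- sample(100, 9)
  scores3 <- matrix(v, ncol = 1, dimnames = list(sprintf("x%d", 1:9), "T1"))
  rk3 <- tf_enrich_wilcox(sprintf("x%d", 1:4), sprintf("x%d", 1:9),
                          peak_scores = scores3)
  expect_equal(rk3$p, wilcox_enum(v[1:4], v[5:9]))
})

test_that("TF-target over-representation matches the hypergeometric oracle", {
  universe <- sprintf("g%04d", 1:1000)
  query <- universe[1:50]
  pairs <- data.frame(
    tf_id = "T1",
    target_gene_id = c(universe[31:50], sprintf("g%04d", 101:180)))
  rk <- tf_tt_pair(query, universe, pairs)
  expect_equal(rk$p, hyper_tail(20, 100, 900, 50), tolerance = 1e-10)
  expect_equal(rk$n_overlap, 20L)
  expect_equal(rk$overlap_genes, paste(universe[31:50], collapse = ","))
  # zero overlap means p = 1
  pairs0 <- data.frame(tf_id = "T0", target_gene_id = universe[900:950])
  expect_equal(tf_tt_pair(query, universe, pairs0)$p, 1)
  # a TF whose target set is exactly the query attains the extreme p
  pairs2 <- rbind(pairs, data.frame(tf_id = "T2", target_gene_id = query))
  rk2 <- tf_tt_pair(query, universe, pairs2)
  expect_equal(rk2$tf_id[1], "T2")
  expect_equal(rk2$p[rk2$tf_id == "T2"], hyper_tail(50, 50, 950, 50))
})

test_that("TFs without targets in the universe are dropped with a warning", {
  universe <- sprintf("g%d", 1:10)
  pairs <- data.frame(tf_id = c("T1", "T2"),
                      target_gene_id = c("g1", "outside"))
  expect_warning(rk <- tf_tt_pair("g1", universe, pairs), "dropped")
  expect_equal(rk$tf_id, "T1")
})

test_that("hit-count gene test matches enumeration on the toy counts", {
  # 3 query genes with counts {2,2,3}, 2 background genes with {0,1}
  genes <- mk_genes(sprintf("g%d", 1:5),
                    tss = seq(50000L, by = 100000L, length.out = 5))
  mk <- function(g, n) sprintf("%s_p%d", g, seq_len(n))
  links <- do.call(rbind, lapply(seq_len(5), function(i) {
    n <- c(2, 2, 3, 0, 1)[i]
    if (!n) return(NULL)
    data.frame(peak_id = mk(genes$gene_id[i], n), gene_id = genes$gene_id[i],
               distance = 0L, mode = "scan", stringsAsFactors = FALSE)
  }))
  h <- tf_hits(list(T1 = links$peak_id), "chipseq")
  rk <- tf_hit_test(sprintf("g%d", 1:3), sprintf("g%d", 1:5), h, links)
  expect_equal(rk$p, wilcox_enum(c(2, 2, 3), c(0, 1)))
  check_ranking_contract(rk)
})

test_that("region-RP attribution: empty TFs and fully-bound genes", {
  genes <- mk_genes(c("g1", "g2"), tss = c(50000L, 150000L))
  peaks <- mk_peaks(c("p1", "p2"), anchor = c(50000L, 150000L))
  links <- annotate_scan(peaks, genes, 20000L)
  X <- matrix(c(10, 20, 5, 8), 2, dimnames = list(c("p1", "p2"),
                                                  c("s1", "s2")))
  prof <- rp_region(links, X, genes = genes)
  h <- tf_hits(list(bound = "p1", unbound = "pZZZ"), "chipseq")
  res <- suppressMessages(
    tf_region_rp("g1", prof, X, h, detail = "all"))
  expect_true(all(res$per_sample_p["unbound", ] == 1))
  d <- res$detail
  expect_equal(d$prop_attr[d$gene_id == "g1" & d$tf_id == "bound"], c(1, 1))
  expect_equal(d$prop_attr[d$gene_id == "g2" & d$tf_id == "bound"], c(0, 0))
})

test_that("region-RP finds the TF only in the sample where it acts", {
  set.seed(55)
  n_g <- 40
  genes <- mk_genes(sprintf("g%02d", 1:n_g),
                    tss = seq(50000L, by = 50000L, length.out = n_g))
  peaks <- mk_peaks(sprintf("p%02d", 1:n_g), anchor = genes$tss + 1000L)
  links <- annotate_scan(peaks, genes, 20000L)
  query <- genes$gene_id[1:10]
  # TF binds the query genes' peaks; signal there is high only in s1
  X <- matrix(abs(rnorm(n_g * 2, 10, 1)), n_g,
              dimnames = list(peaks$peak_id, c("s1", "s2")))
  X[1:10, "s1"] <- X[1:10, "s1"] + 100
  prof <- rp_region(links, X, genes = genes)
  h <- tf_hits(list(TFA = peaks$peak_id[1:10],
                    decoy = peaks$peak_id[seq(2, n_g, 4)]), "chipseq")
  res <- tf_region_rp(query, prof, X, h, detail = "none")
  expect_lt(res$per_sample_p["TFA", "s1"], 0.001)
  expect_equal(res$ranking$tf_id[1], "TFA")
  check_ranking_contract(res$ranking)
})

test_that("replicate integration is idempotent and averages evidence", {
  universe <- sprintf("u%03d", 1:60)
  h <- tf_hits(list(A = universe[1:20], B = universe[c(1:6, 30:40)],
                    C = universe[50:59]), "chipseq")
  rk <- tf_enrich_fisher(universe[1:15], universe, h)
  same <- combine_replicates(list(rk, rk, rk))
  expect_equal(same$tf_id, rk$tf_id)
  two <- combine_replicates(list(
    data.frame(tf_id = "A", statistic = 1, p = 1e-2, p_adj = 1e-2,
               rank = 1L, z = 1),
    data.frame(tf_id = "A", statistic = 1, p = 1e-4, p_adj = 1e-4,
               rank = 1L, z = 2)))
  expect_equal(two$p, 1e-3, tolerance = 1e-12)
  st <- combine_replicates(list(rk, rk), method = "stouffer")
  expect_equal(st$statistic, rk$z[match(st$tf_id, rk$tf_id)] * 2 / sqrt(2))
  mr <- combine_replicates(list(rk, rk), method = "mean_rank")
  expect_equal(mr$tf_id, rk$tf_id)
})

test_that("two noisy replicates promote the consistent TF to the top", {
  t1 <- data.frame(tf_id = c("A", "B", "C"), statistic = c(1, 2, 0.5),
                   p = c(0.01, 0.001, 0.5), p_adj = c(0.015, 0.003, 0.5),
                   rank = c(2L, 1L, 3L), z = c(0.4, 1, -1))
  t2 <- data.frame(tf_id = c("A", "B", "C"), statistic = c(1, 0.5, 2),
                   p = c(0.02, 0.6, 0.004), p_adj = c(0.03, 0.6, 0.012),
                   rank = c(2L, 3L, 1L), z = c(0.4, -1, 1))
  comb <- combine_replicates(list(t1, t2))
  expect_equal(comb$tf_id[1], "A")  # consistently 2nd beats one-off winners
})

test_that("Jaccard co-occurrence handles identity, disjointness and ratios", {
  J <- jaccard_tf(list(a = c("x", "y", "z"), b = c("x", "y", "z"),
                       c = c("q", "r"), d = c("x", "y", "u", "v")))
  expect_equal(unname(diag(J)), rep(1, 4))
  expect_equal(J["a", "b"], 1)
  expect_equal(J["a", "c"], 0)
  expect_equal(J["a", "d"], 2 / 5)
  Jq <- jaccard_tf(list(a = "x", b = "y"), query = "zzz")
  expect_equal(Jq["a", "b"], 0)  # both empty after restriction
  expect_equal(jaccard_tf(list(a = c("1", "2", "3", "4"),
                               b = c("3", "4", "5", "6")))["a", "b"], 1 / 3)
})

test_that("every statistic recovers its planted TF at rank 1", {
  ew <- make_enrich_world(seed = 3)
  expect_equal(tf_enrich_fisher(ew$query_peaks, ew$universe_peaks,
                                ew$hits)$tf_id[1], "TF01")
  expect_equal(tf_enrich_wilcox(ew$query_peaks, ew$universe_peaks,
                                ew$hits)$tf_id[1], "TF01")
  spec <- fixture_spec(seed = 3L)
  genome <- make_genome(spec)
  sig <- make_signal(spec, genome)
  world <- make_tf_world(spec, genome)
  expect_equal(tf_tt_pair(world$query_genes, genome$genes$gene_id,
                          world$tt_pairs)$tf_id[1], spec$planted_tf_id)
  rk_hit <- tf_hit_test(world$query_genes, genome$genes$gene_id, world$hits,
                        world$scan_links)
  expect_equal(rk_hit$tf_id[1], spec$planted_tf_id)
  check_ranking_contract(rk_hit)
  prof <- rp_region(world$scan_links, sig$peak_signal, genes = genome$genes)
  rr <- suppressMessages(tf_region_rp(world$query_genes, prof,
                                      sig$peak_signal, world$hits,
                                      detail = "none"))
  expect_equal(rr$ranking$tf_id[1], spec$planted_tf_id)
  mw <- make_mara_world(planted_factor = 5, seed = 3)
  m <- tf_mara(mw$signal, mw$site_counts, log_transform = FALSE)
  expect_equal(names(m$variability)[1], mw$planted_motif)
})
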
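# End-to-end demonstration pipeline on a synthetic world: simulate, write
# the raw inputs, annotate, score links, compute RP, call targets, rank
# TFs, fit MARA, and emit TSVs. Byte-reproducible under a fixed seed.

#' Run the full synthetic-world pipeline
#'
#' Generates a world from `spec`, writes its raw inputs (GFF3, BED, TSV
#' matrices, hits, DGE), then runs every analysis stage and writes one TSV
#' per result plus a manifest. All outputs carry `#` headers recording the
#' tool version and parameters; two runs with the same spec produce
#' byte-identical files.
#'
#' @param out_dir Output directory (created if needed).
#' @param spec A [fixture_spec()]; its `seed` fixes the whole run.
#' @param scan_length Scan radius in bp.
#' @return Invisibly, the manifest `data.frame` (`file`, `description`).
#' @export
run_demo_pipeline <- function(out_dir, spec = fixture_spec(),
                              scan_length = 20000L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  genome <- make_genome(spec)
  sig <- make_signal(spec, genome)
  world <- make_tf_world(spec, genome, scan_length)
  prm <- list(seed = spec$seed, scan_length = scan_length)

  write_gff3(genome$genes, p("genes.gff3"))
  write_bed(genome$peaks, p("peaks.bed"))
  write_tsv_output(sig$peak_signal, p("peak_counts.tsv"), prm, "peak_id")
  write_tsv_output(sig$gene_expr, p("gene_expr.tsv"), prm, "gene_id")
  write_tsv_output(world$dge, p("dge.tsv"), prm)
  hits_df <- data.frame(
    tf_id = rep(names(world$hits), lengths(world$hits)),
    peak_id = unlist(world$hits, use.names = FALSE), stringsAsFactors = FALSE)
  write_tsv_output(hits_df, p("tf_hits.tsv"), prm)
  write_tsv_output(world$tt_pairs, p("tt_pairs.tsv"), prm)

  near <- annotate_nearest(genome$peaks, genome$genes)
  scan <- annotate_scan(genome$peaks, genome$genes, scan_length)
  write_tsv_output(near, p("links_nearest.tsv"), prm)
  write_tsv_output(scan, p("links_scan.tsv"), prm)

  cor_links <- peak_gene_cor(scan, sig$peak_signal, sig$gene_expr)
  write_tsv_output(cor_links, p("peak_gene_cor.tsv"), prm)

  prof <- rp_region(scan, sig$peak_signal, genes = genome$genes)
  write_tsv_output(prof$rp, p("rp_region.tsv"), prm, "gene_id")

  tf_bed <- genome$peaks[genome$peaks$peak_id %in%
                           world$hits[[spec$planted_tf_id]], , drop = FALSE]
  rp_chip <- rp_tfhit(tf_bed, genome$genes)
  targets <- suppressMessages(integrate_chip_rna(rp_chip, world$dge, "up"))
  write_tsv_output(targets, p("targets.tsv"), prm)

  rank_fisher <- tf_enrich_fisher(world$query_peaks, genome$peaks$peak_id,
                                  world$hits)
  rank_wilcox <- tf_enrich_wilcox(world$query_peaks, genome$peaks$peak_id,
                                  world$hits)
  rank_tt <- tf_tt_pair(world$query_genes, genome$genes$gene_id,
                        world$tt_pairs)
  rank_hit <- tf_hit_test(world$query_genes, genome$genes$gene_id,
                          world$hits, scan)
  rr <- suppressMessages(tf_region_rp(world$query_genes, prof,
                                      sig$peak_signal, world$hits,
                                      detail = "none"))
  write_tsv_output(rank_fisher, p("tf_rank_fisher.tsv"), prm)
  write_tsv_output(rank_wilcox, p("tf_rank_wilcox.tsv"), prm)
  write_tsv_output(rank_tt, p("tf_rank_ttpair.tsv"), prm)
  write_tsv_output(rank_hit, p("tf_rank_tfhit.tsv"), prm)
  write_tsv_output(rr$ranking, p("tf_rank_regionrp.tsv"), prm)

  site_counts <- vapply(names(world$hits), function(tf)
    as.numeric(genome$peaks$peak_id %in% world$hits[[tf]]),
    numeric(nrow(genome$peaks)))
  rownames(site_counts) <- genome$peaks$peak_id
  mara <- tf_mara(sig$peak_signal, site_counts)
  write_tsv_output(mara$activity, p("mara_activity.tsv"),
                   c(prm, list(lambda = mara$lambda)), "motif_id")

  combined <- combine_replicates(list(rank_fisher, rank_wilcox, rank_hit))
  write_tsv_output(combined, p("tf_rank_combined.tsv"), prm)

  manifest <- data.frame(
    file = c("genes.gff3", "peaks.bed", "peak_counts.tsv", "gene_expr.tsv",
             "dge.tsv", "tf_hits.tsv", "tt_pairs.tsv", "links_nearest.tsv",
             "links_scan.tsv", "peak_gene_cor.tsv", "rp_region.tsv",
             "targets.tsv", "tf_rank_fisher.tsv", "tf_rank_wilcox.tsv",
             "tf_rank_ttpair.tsv", "tf_rank_tfhit.tsv",
             "tf_rank_regionrp.tsv", "mara_activity.tsv",
             "tf_rank_combined.tsv"),
    description = c("gene models", "peak set", "peak counts",
                    "gene expression", "differential expression", "TF hits",
                    "TF-target pairs", "nearest-gene links", "gene-scan links",
                    "peak-gene correlations", "region RP matrix",
                    "integrated target ranking", "Fisher TF ranking",
                    "Wilcoxon TF ranking", "target-pair TF ranking",
                    "hit-count TF ranking", "region-RP TF ranking",
                    "MARA activities", "combined TF ranking"),
    stringsAsFactors = FALSE)
  write_tsv_output(manifest, p("manifest.tsv"), prm)
  invisible(manifest)
}
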
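# Synthetic-world generator: genomes, peaks, count matrices, TF hits and
# DGE tables with planted, parameterized structure. Fully deterministic
# under the spec seed; the generator emulates a time-course accessibility
# study (7 time points, one planted TF among 40 decoy motifs) without any
# claim of sequence realism.

#' Specification of a synthetic world
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_len Chromosome length in bp.
#' @param n_genes,n_peaks,n_samples,n_tfs World sizes. Defaults mirror a
#'   7-time-point accessibility course with one planted TF and 40 decoys.
#' @param planted_tf_id Id of the planted (truly influential) TF.
#' @param planted_effect Fraction of query genes/peaks hit by the planted
#'   TF.
#' @param background_rate Hit rate of decoy TFs (and of the planted TF
#'   outside the query).
#' @param cor_pairs Number of planted enhancer-promoter pairs.
#' @param cor_target_r Target correlation of planted pairs.
#' @param dge_effect log2 fold-change scale of planted targets.
#' @param dispersion Negative-binomial dispersion of counts.
#' @param query_frac Fraction of genes designated as the query set.
#' @param seed RNG seed; the whole world is a deterministic function of it.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_chrom = 2L, chrom_len = 1e6, n_genes = 150L,
                         n_peaks = 450L, n_samples = 7L, n_tfs = 41L,
                         planted_tf_id = "TF01", planted_effect = 0.8,
                         background_rate = 0.1, cor_pairs = 5L,
                         cor_target_r = 0.95, dge_effect = 3,
                         dispersion = 0.2, query_frac = 0.2, seed = 42L) {
  spec <- list(n_chrom = as.integer(n_chrom), chrom_len = as.integer(chrom_len),
               n_genes = as.integer(n_genes), n_peaks = as.integer(n_peaks),
               n_samples = as.integer(n_samples), n_tfs = as.integer(n_tfs),
               planted_tf_id = planted_tf_id, planted_effect = planted_effect,
               background_rate = background_rate, cor_pairs = as.integer(cor_pairs),
               cor_target_r = cor_target_r, dge_effect = dge_effect,
               dispersion = dispersion, query_frac = query_frac,
               seed = as.integer(seed))
  stopifnot(spec$n_chrom >= 1, spec$n_genes >= 1, spec$n_peaks >= 0,
            spec$n_samples >= 1, spec$n_tfs >= 1,
            spec$planted_effect >= 0, spec$planted_effect <= 1,
            spec$cor_pairs >= 0, spec$cor_target_r > 0, spec$cor_target_r <= 1)
  structure(spec, class = "fixture_spec")
}

#' Study conditions for correlation-link recovery
#'
#' A sparse world for testing enhancer-promoter link recovery: 12 genes on
#' one 1.2 Mb chromosome (disjoint scan windows), 5 planted
#' promoter-distal pairs among ~50 uncorrelated peaks, and 16 samples.
#' Correlation-based linking at the conservative `r > 0.8`, `p < 0.01`
#' thresholds needs a moderately large sample count before the `r` cut is
#' meaningfully stricter than the raw p cut; 16 samples corresponds to a
#' dense (or replicated) developmental series.
#'
#' @param seed RNG seed.
#' @return A `fixture_spec`.
#' @export
cor_fixture_spec <- function(seed = 42L) {
  fixture_spec(n_chrom = 1L, chrom_len = 1.2e6, n_genes = 12L, n_peaks = 60L,
               n_samples = 16L, cor_pairs = 5L, cor_target_r = 0.95,
               seed = seed)
}

#' Generate a synthetic genome (genes + peaks)
#'
#' Genes are placed on a jittered grid with guaranteed spacing; peaks are
#' placed mostly within gene scan windows. For each of the first
#' `cor_pairs` genes, a promoter peak (anchor within 150 bp of the TSS)
#' and a distal partner peak (5-15 kb away, within the 20 kb scan window)
#' are planted, and other random peaks are kept >= 3 kb from those TSSs so
#' the promoter stays the nearest peak. Deterministic under `spec$seed`.
#'
#' @param spec A [fixture_spec()].
#' @return List with `genes`, `peaks` (internal tables) and
#'   `planted_pairs` (`gene_id`, `promoter_peak`, `distal_peak`).
#' @export
make_genome <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed(spec$seed, {
    per <- rep(spec$n_genes %/% spec$n_chrom, spec$n_chrom)
    per[seq_len(spec$n_genes %% spec$n_chrom)] <-
      per[seq_len(spec$n_genes %% spec$n_chrom)] + 1L
    spacing <- spec$chrom_len %/% (max(per) + 1L)
    if (spacing < 4000)
      .stopf("infeasible packing: %d genes on a %d bp chromosome", max(per),
             spec$chrom_len)
    genes <- do.call(rbind, lapply(seq_len(spec$n_chrom), function(ci) {
      n <- per[ci]
      if (!n) return(NULL)
      sp <- spec$chrom_len %/% (n + 1L)
      start <- as.integer(seq_len(n) * sp +
                            round(runif(n, -sp / 4, sp / 4)))
      width <- sample(1000:3000, n, replace = TRUE)
      strand <- sample(c("+", "-"), n, replace = TRUE)
      data.frame(chrom = sprintf("chr%d", ci), strand = strand,
                 start = start, end = start + width,
                 stringsAsFactors = FALSE)
    }))
    genes <- genes[order(genes$chrom, genes$start), , drop = FALSE]
    genes$gene_id <- sprintf("g%04d", seq_len(nrow(genes)))
    genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
    genes <- genes[, c("gene_id", "chrom", "strand", "start", "end", "tss")]
    rownames(genes) <- NULL

    # planted enhancer-promoter geometry
    n_cp <- min(spec$cor_pairs, nrow(genes))
    cp_genes <- genes[seq_len(n_cp), , drop = FALSE]
    planted <- NULL
    pk <- list()
    mk_peak <- function(chrom, anchor, tag) {
      w <- sample(200:400, 1)
      start <- max(0L, as.integer(anchor - w %/% 2L))
      data.frame(chrom = chrom, start = start, end = start + w,
                 tag = tag, stringsAsFactors = FALSE)
    }
    for (i in seq_len(n_cp)) {
      g <- cp_genes[i, ]
      side <- if (g$tss + 16000 < spec$chrom_len) 1 else -1
      prom_anchor <- g$tss + round(runif(1, -150, 150))
      dist_anchor <- g$tss + side * round(runif(1, 5000, 15000))
      pk[[length(pk) + 1]] <- mk_peak(g$chrom, prom_anchor,
                                      paste0("prom:", g$gene_id))
      pk[[length(pk) + 1]] <- mk_peak(g$chrom, dist_anchor,
                                      paste0("dist:", g$gene_id))
    }
    n_rest <- max(spec$n_peaks - length(pk), 0L)
    forbid <- cp_genes$tss
    forbid_chrom <- cp_genes$chrom
    too_close <- function(chrom, anchor) {
      any(forbid_chrom == chrom & abs(forbid - anchor) < 3000)
    }
    chroms <- sprintf("chr%d", seq_len(spec$n_chrom))
    for (i in seq_len(n_rest)) {
      repeat {
        if (runif(1) < 0.9) {
          gi <- sample.int(nrow(genes), 1)
          chrom <- genes$chrom[gi]
          anchor <- genes$tss[gi] + round(runif(1, -18000, 18000))
        } else {
          chrom <- sample(chroms, 1)
          anchor <- round(runif(1, 0, spec$chrom_len))
        }
        anchor <- min(max(anchor, 200L), spec$chrom_len - 400L)
        if (!too_close(chrom, anchor)) break
      }
      pk[[length(pk) + 1]] <- mk_peak(chrom, anchor, "")
    }
    if (!length(pk)) {
      pk <- list(data.frame(chrom = character(), start = integer(),
                            end = integer(), tag = character(),
                            stringsAsFactors = FALSE))
    }
    peaks <- do.call(rbind, pk)
    peaks <- peaks[order(peaks$chrom, peaks$start), , drop = FALSE]
    peaks$peak_id <- sprintf("peak_%06d", seq_len(nrow(peaks)))
    peaks$summit_offset <- rep(NA_integer_, nrow(peaks))
    peaks$score <- rep(0, nrow(peaks))
    if (n_cp) {
      planted <- data.frame(
        gene_id = cp_genes$gene_id,
        promoter_peak = peaks$peak_id[match(paste0("prom:", cp_genes$gene_id),
                                            peaks$tag)],
        distal_peak = peaks$peak_id[match(paste0("dist:", cp_genes$gene_id),
                                          peaks$tag)],
        stringsAsFactors = FALSE)
    }
    peaks <- peaks[, c("peak_id", "chrom", "start", "end", "summit_offset",
                       "score")]
    rownames(peaks) <- NULL
    list(genes = genes, peaks = peaks, planted_pairs = planted)
  })
}

#' Generate signal matrices with planted correlations and a trend
#'
#' Peak and gene counts are negative binomial around lognormal baselines.
#' The planted promoter-distal pairs share a latent temporal profile and
#' are rejection-sampled until their observed correlation is within 0.05
#' of `cor_target_r` (`cor_target_r = 1` gives exactly proportional rows).
#' Ten non-planted peaks carry a monotone temporal trend across the
#' ordered samples.
#'
#' @param spec A [fixture_spec()].
#' @param genome Output of [make_genome()].
#' @return List with `peak_signal`, `gene_expr` (matrices) and
#'   `trend_peaks` (ids of the monotone peaks).
#' @export
make_signal <- function(spec, genome) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed(spec$seed + 1L, {
    ns <- spec$n_samples
    samples <- sprintf("s%02d", seq_len(ns))
    npk <- nrow(genome$peaks)
    mu_p <- exp(rnorm(npk, log(100), 0.6))
    size <- 1 / spec$dispersion
    X <- matrix(rnbinom(npk * ns, mu = rep(mu_p, ns), size = size),
                nrow = npk, dimnames = list(genome$peaks$peak_id, samples))
    planted <- genome$planted_pairs
    trend_ids <- character()
    free <- setdiff(genome$peaks$peak_id,
                    c(planted$promoter_peak, planted$distal_peak))
    if (length(free) >= 10) {
      trend_ids <- sample(free, 10)
      trend <- exp(seq(-1, 1, length.out = ns))
      X[trend_ids, ] <- t(vapply(trend_ids, function(id) {
        as.numeric(rnbinom(ns, mu = mu_p[match(id, genome$peaks$peak_id)] * trend,
                           size = size * 4))
      }, numeric(ns)))
    }
    if (!is.null(planted)) {
      for (i in seq_len(nrow(planted))) {
        lat <- exp(cumsum(rnorm(ns, 0, 0.6)))
        lat <- lat / mean(lat)
        base_p <- exp(rnorm(1, log(150), 0.3))
        base_d <- exp(rnorm(1, log(120), 0.3))
        if (spec$cor_target_r >= 0.999) {
          prom <- round(base_p * lat)
          dist <- 2 * prom  # exactly proportional
        } else {
          ok <- FALSE
          for (try in 1:500) {
            noise_sd <- 0.08
            prom <- pmax(0, round(base_p * lat * exp(rnorm(ns, 0, noise_sd))))
            dist <- pmax(0, round(base_d * lat * exp(rnorm(ns, 0, noise_sd))))
            if (sd(prom) > 0 && sd(dist) > 0 &&
                abs(cor(prom, dist) - spec$cor_target_r) <= 0.05) {
              ok <- TRUE; break
            }
          }
          if (!ok)
            .stopf("could not realise target r = %g at n_samples = %d; increase n_samples",
                   spec$cor_target_r, ns)
        }
        X[planted$promoter_peak[i], ] <- prom
        X[planted$distal_peak[i], ] <- dist
      }
    }
    ng <- nrow(genome$genes)
    mu_g <- exp(rnorm(ng, log(200), 0.8))
    E <- matrix(rnbinom(ng * ns, mu = rep(mu_g, ns), size = size),
                nrow = ng, dimnames = list(genome$genes$gene_id, samples))
    list(peak_signal = X, gene_expr = E, trend_peaks = trend_ids)
  })
}

#' Generate the TF world: hits, target pairs and a DGE table
#'
#' Designates a query gene set (fraction `query_frac` of genes) and its
#' linked peaks as the query peak set. The planted TF binds a peak of
#' `planted_effect` of the query genes (its "targets") plus a
#' `background_rate` sprinkling elsewhere; decoy TFs bind uniformly at
#' `background_rate`. The DGE table up-regulates the planted targets with
#' log2 fold changes around `dge_effect` and tiny adjusted p-values;
#' all other genes are null.
#'
#' @param spec A [fixture_spec()].
#' @param genome Output of [make_genome()].
#' @param scan_length Scan radius used for the gene-peak geometry.
#' @return List with `hits` (`tf_hits`), `tt_pairs`, `dge`, `query_genes`,
#'   `query_peaks`, `planted_targets`, `scan_links`.
#' @export
make_tf_world <- function(spec, genome, scan_length = 20000L) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed(spec$seed + 2L, {
    genes <- genome$genes; peaks <- genome$peaks
    links <- .scan_links(peaks, genes, scan_length)
    tfs <- c(spec$planted_tf_id,
             sprintf("decoy%02d", seq_len(spec$n_tfs - 1L)))
    n_query <- max(2L, round(spec$query_frac * nrow(genes)))
    query_genes <- sort(sample(genes$gene_id, n_query))
    query_peaks <- sort(unique(links$peak_id[links$gene_id %in% query_genes]))
    planted_targets <- sort(sample(query_genes,
                                   round(spec$planted_effect * n_query)))
    hit_list <- list()
    for (tf in tfs) {
      bg <- peaks$peak_id[runif(nrow(peaks)) < spec$background_rate]
      if (tf == spec$planted_tf_id) {
        tgt_peaks <- vapply(planted_targets, function(g) {
          cand <- links$peak_id[links$gene_id == g]
          if (length(cand)) sample(cand, 1) else NA_character_
        }, character(1))
        hit_list[[tf]] <- sort(unique(c(bg, tgt_peaks[!is.na(tgt_peaks)])))
      } else {
        hit_list[[tf]] <- sort(unique(bg))
      }
      if (!length(hit_list[[tf]]))
        hit_list[[tf]] <- sample(peaks$peak_id, 1)
    }
    hits <- tf_hits(hit_list, provenance = "chipseq")
    tt <- do.call(rbind, lapply(tfs, function(tf) {
      tg <- if (tf == spec$planted_tf_id) {
        c(planted_targets,
          sample(setdiff(genes$gene_id, query_genes),
                 round(spec$background_rate * nrow(genes))))
      } else {
        sample(genes$gene_id, max(1L, round(spec$background_rate * nrow(genes))))
      }
      data.frame(tf_id = tf, target_gene_id = sort(unique(tg)),
                 stringsAsFactors = FALSE)
    }))
    rownames(tt) <- NULL
    is_target <- genes$gene_id %in% planted_targets
    log2fc <- ifelse(is_target, rnorm(nrow(genes), spec$dge_effect, 0.4),
                     rnorm(nrow(genes), 0, 0.3))
    padj <- ifelse(is_target, 10^-runif(nrow(genes), 5, 60),
                   runif(nrow(genes)))
    dge <- data.frame(gene_id = genes$gene_id, log2fc = log2fc, padj = padj,
                      gene_category = dge_category(log2fc, padj),
                      stringsAsFactors = FALSE)
    list(hits = hits, tt_pairs = tt, dge = dge, query_genes = query_genes,
         query_peaks = query_peaks, planted_targets = planted_targets,
         scan_links = links)
  })
}

#' Simulate a peak-set enrichment world
#'
#' Pure peak-level world for the Fisher/Wilcoxon enrichment statistics:
#' a universe of `n_query + n_bg` peaks in which the planted TF binds
#' `planted_rate` of the query peaks and `bg_rate` of the background,
#' while each decoy TF binds every peak independently at `bg_rate`.
#'
#' @param n_query,n_bg Query and background peak counts (defaults 100, 900).
#' @param planted_rate Planted TF's binding rate on query peaks (0.8).
#' @param bg_rate Background binding rate (0.1).
#' @param n_decoys Number of decoy TFs (20).
#' @param seed RNG seed.
#' @return List with `query_peaks`, `universe_peaks`, `hits`
#'   (planted TF id `"TF01"`).
#' @export
make_enrich_world <- function(n_query = 100L, n_bg = 900L,
                              planted_rate = 0.8, bg_rate = 0.1,
                              n_decoys = 20L, seed = 1L) {
  with_seed(seed, {
    universe <- sprintf("peak_%06d", seq_len(n_query + n_bg))
    query <- universe[seq_len(n_query)]
    bg <- setdiff(universe, query)
    hit_list <- list(TF01 = c(query[runif(n_query) < planted_rate],
                              bg[runif(n_bg) < bg_rate]))
    for (i in seq_len(n_decoys))
      hit_list[[sprintf("decoy%02d", i)]] <-
        universe[runif(length(universe)) < bg_rate]
    hit_list <- lapply(hit_list, function(x)
      if (length(x)) sort(x) else universe[1])
    list(query_peaks = query, universe_peaks = universe,
         hits = tf_hits(hit_list, provenance = "chipseq"))
  })
}

#' Simulate a MARA recovery problem
#'
#' Builds Poisson site counts `N`, a true activity matrix `A0` (rows
#' centered; motif amplitudes drawn uniformly, with the first motif's
#' amplitude multiplied by `planted_factor`), and a signal matrix
#' `X = center(N) %*% A0 + noise` with Gaussian noise of standard
#' deviation `noise_frac` times the sd of the noiseless signal. Feed the
#' result to [tf_mara()] with `log_transform = FALSE`.
#'
#' @param n_peaks,n_motifs,n_samples Problem sizes (defaults 200, 10, 7).
#' @param noise_frac Noise sd as a fraction of signal sd (default 0.1).
#' @param planted_factor Amplitude multiplier of motif 1 (default 1 = no
#'   planted motif).
#' @param seed RNG seed.
#' @return List with `signal`, `site_counts`, `activity_true`,
#'   `planted_motif`.
#' @export
make_mara_world <- function(n_peaks = 200L, n_motifs = 10L, n_samples = 7L,
                            noise_frac = 0.1, planted_factor = 1, seed = 1L) {
  with_seed(seed, {
    N <- matrix(rpois(n_peaks * n_motifs, 1.5), n_peaks,
                dimnames = list(sprintf("peak_%06d", seq_len(n_peaks)),
                                sprintf("motif%02d", seq_len(n_motifs))))
    amp <- runif(n_motifs, 0.5, 1.5)
    amp[1] <- amp[1] * planted_factor
    A0 <- t(vapply(seq_len(n_motifs), function(m) {
      a <- amp[m] * scale(rnorm(n_samples))[, 1]
      a - mean(a)
    }, numeric(n_samples)))
    dimnames(A0) <- list(colnames(N), sprintf("s%02d", seq_len(n_samples)))
    Nc <- sweep(N, 2, colMeans(N))
    signal0 <- Nc %*% A0
    X <- signal0 + rnorm(length(signal0), 0, noise_frac * sd(signal0))
    dimnames(X) <- dimnames(signal0)
    list(signal = X, site_counts = N, activity_true = A0, planted_motif = colnames(N)[1])
  })
}

#' @importFrom stats rpois rlnorm
NULL
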
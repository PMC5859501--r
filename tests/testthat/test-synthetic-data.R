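cfg <- small_config()

test_that("genome generation is deterministic with the stated dimensions", {
  g1 <- generate_genome(cfg)
  g2 <- generate_genome(cfg)
  expect_identical(as.character(g1$seq), as.character(g2$seq))
  expect_equal(length(g1$seq), cfg$n_scaffolds)
  expect_equal(sum(g1$sizes$length),
               cfg$n_scaffolds * cfg$scaffold_length)
  expect_true(all(Biostrings::width(g1$seq) == cfg$scaffold_length))
  # GC within a tight binomial band at n = 6e5
  comp <- base_comp(paste(as.character(g1$seq), collapse = ""))
  gc <- sum(comp[c("C", "G")]) / sum(comp)
  expect_lt(abs(gc - cfg$gc), 0.02)
  g3 <- generate_genome(small_config(seed = 2L))
  expect_false(identical(as.character(g1$seq), as.character(g3$seq)))
})

test_that("gene models are disjoint, labelled and cluster-consistent", {
  genome <- generate_genome(cfg)
  gg <- generate_genes(cfg, genome)
  genes <- gg$genes
  expect_equal(nrow(genes), cfg$n_genes)
  expect_equal(sum(genes$de), cfg$n_de_genes)
  # spans pairwise disjoint per scaffold
  for (s in unique(genes$scaffold)) {
    g <- genes[genes$scaffold == s, ]
    g <- g[order(g$start), ]
    if (nrow(g) > 1) expect_true(all(g$start[-1] >= g$end[-nrow(g)]))
  }
  # exons inside their gene span, disjoint, and >= 1 per gene
  expect_true(all(table(gg$exons$gene_id) >= 1))
  for (gid in sample(genes$gene_id, 10)) {
    ex <- gg$exons[gg$exons$gene_id == gid, ]
    g <- genes[genes$gene_id == gid, ]
    expect_true(all(ex$start >= g$start & ex$end <= g$end))
    ex <- ex[order(ex$start), ]
    if (nrow(ex) > 1)
      expect_true(all(ex$start[-1] >= ex$end[-nrow(ex)]))
  }
  # profiles peak inside the assigned cluster window
  win <- list(`1` = c(0, 10), `2` = c(40, 72), `3` = c(24, 40),
              `4` = c(18, 24))
  argmax_t <- gg$times[apply(gg$expression, 1, which.max)]
  for (k in 1:4) {
    tk <- argmax_t[genes$cluster_true == k]
    # the discrete grid argmax lands in (or adjacent to) the window;
    # check the underlying continuous peak time exactly
    pt <- genes$peak_time[genes$cluster_true == k]
    expect_true(all(pt >= win[[k]][1] & pt < win[[k]][2]))
    expect_true(all(assign_temporal_cluster(
      gg$expression[which(genes$cluster_true == k)[1], ],
      gg$times) == k))
    expect_true(length(tk) > 0)
  }
})

test_that("gene placement fails gracefully on an impossible genome", {
  tiny <- sim_config(seed = 1, n_scaffolds = 1L,
                     scaffold_length = 5000L, n_genes = 50L,
                     n_de_genes = 5L, n_peaks = 10L)
  genome <- generate_genome(tiny)
  expect_error(generate_genes(tiny, genome), "placement")
})

test_that("peak landscape plants differential peaks near DE genes", {
  genome <- generate_genome(cfg)
  genes <- generate_genes(cfg, genome)
  land <- generate_peak_landscape(cfg, genome, genes)
  expect_equal(nrow(land$master), cfg$n_peaks)
  n_diff <- round(cfg$n_peaks * cfg$frac_differential)
  expect_length(land$differential_peak_ids, n_diff)
  # brute-force distance scan: every differential peak within de_window
  de <- genes$genes[genes$genes$de, ]
  for (pid in land$differential_peak_ids) {
    pk <- land$master[land$master$id == pid, ]
    gaps <- vapply(seq_len(nrow(de)), function(i) {
      if (de$scaffold[i] != pk$scaffold) return(Inf)
      max(0, de$start[i] - pk$end + 1, pk$start - de$end[i] + 1)
    }, numeric(1))
    expect_lte(min(gaps), cfg$de_window)
  }
  # all replicate sets have n_peaks records; zero jitter reproduces master
  expect_true(all(vapply(unlist(land$replicates, recursive = FALSE) |>
                           unlist(recursive = FALSE), nrow, 0L) ==
                    cfg$n_peaks))
  cfg0 <- small_config(replicate_jitter_bp = 0L)
  land0 <- generate_peak_landscape(cfg0, genome,
                                   generate_genes(cfg0, genome))
  expect_identical(as.data.frame(land0$replicates$atac$target[[1]]),
                   as.data.frame(land0$master))
  # excessive jitter is a configuration error
  expect_error(small_config(replicate_jitter_bp = 200L,
                            peak_width_min = 300), "jitter")
})

test_that("count generation obeys the planted-effect law and determinism", {
  genome <- generate_genome(cfg)
  genes <- generate_genes(cfg, genome)
  land <- generate_peak_landscape(cfg, genome, genes)
  cm <- generate_counts(cfg, land$master, land$planted_log2fc,
                        assay = "dnase")
  cm2 <- generate_counts(cfg, land$master, land$planted_log2fc,
                         assay = "dnase")
  expect_identical(cm$counts, cm2$counts)
  expect_true(all(cm$counts >= 0))
  # planted effect: depth-factor-corrected mean ratio near 2^lfc
  norm <- sweep(cm$counts, 2, cm$depth_factors, "/")
  tgt <- cm$samples$condition == "target"
  is_diff <- rownames(cm$counts) %in% land$differential_peak_ids
  ratio_diff <- mean(rowMeans(norm[is_diff, tgt])) /
    mean(rowMeans(norm[is_diff, !tgt]))
  ratio_null <- mean(rowMeans(norm[!is_diff, tgt])) /
    mean(rowMeans(norm[!is_diff, !tgt]))
  expect_lt(abs(log2(ratio_diff) - cfg$planted_log2fc), 0.15)
  # null peaks: ratio within 3 SE of 1 (SE of the log-ratio of means)
  se <- sqrt(2 * cfg$dispersion / sum(!is_diff))
  expect_lt(abs(log(ratio_null)), 3 * max(se, 0.01))
  # dispersion -> 0 limit behaves like Poisson: variance/mean ~ 1
  cfg_p <- small_config(dispersion = 0)
  cmp <- generate_counts(cfg_p, land$master, NULL, assay = "atac")
  # under the null every peak in a column shares one Poisson mean, so
  # the per-column Fano factor (variance over peaks / mean) must be ~1
  fano <- apply(cmp$counts, 2, stats::var) / colMeans(cmp$counts)
  expect_true(all(abs(fano - 1) < 0.2))
  expect_lt(abs(median(fano) - 1), 0.1)
})

test_that("motif planting hits the requested rate and is reversible at rate 0", {
  genome <- generate_genome(cfg)
  genes <- generate_genes(cfg, genome)
  land <- generate_peak_landscape(cfg, genome, genes)
  p <- example_pwms()[["Ets1"]]
  cons <- pwm_consensus(p)
  pm1 <- plant_motifs(small_config(motif_plant_rate = 1), genome,
                      land$master, p, land$differential_peak_ids)
  seqs <- peak_sequences(pm1$genome,
                         land$master[land$master$id %in%
                                       land$differential_peak_ids, ])
  expect_true(all(grepl(cons, seqs, fixed = TRUE)))
  # genome length unchanged by in-place planting
  expect_equal(Biostrings::width(pm1$genome$seq),
               Biostrings::width(genome$seq))
  pm0 <- plant_motifs(small_config(motif_plant_rate = 0), genome,
                      land$master, p, land$differential_peak_ids)
  expect_identical(as.character(pm0$genome$seq),
                   as.character(genome$seq))
  expect_length(pm0$motif_planted_peak_ids, 0)
  # rate 0.5 over n differential peaks: count within binomial 99% CI
  cfg5 <- small_config(motif_plant_rate = 0.5)
  pm5 <- plant_motifs(cfg5, genome, land$master, p,
                      land$differential_peak_ids)
  n <- length(land$differential_peak_ids)
  ci <- qbinom(c(0.005, 0.995), n, 0.5)
  expect_gte(length(pm5$motif_planted_peak_ids), ci[1])
  expect_lte(length(pm5$motif_planted_peak_ids), ci[2])
})

test_that("simulate_experiment ground truth is closed over emitted records", {
  sim <- simulate_experiment(cfg)
  gt <- sim$ground_truth
  expect_true(all(gt$differential_peak_ids %in% sim$peaks$master$id))
  expect_true(all(gt$de_gene_ids %in% sim$genes$genes$gene_id))
  expect_true(all(gt$motif_planted_peak_ids %in%
                    gt$differential_peak_ids))
  expect_setequal(names(gt$planted_log2fc_per_peak),
                  sim$peaks$master$id)
})

test_that("read emitter approximates the target FRiP", {
  genome <- generate_genome(cfg)
  genes <- generate_genes(cfg, genome)
  land <- generate_peak_landscape(cfg, genome, genes)
  reads <- simulate_reads(cfg, genome, land$master, n_reads = 20000L)
  f <- frip(reads, land$master)
  # planted fraction plus background reads that land in peaks by chance
  cov <- genome_coverage(land$master,
                         sum(as.numeric(genome$sizes$length)))
  expected <- cfg$frac_reads_in_peaks +
    (1 - cfg$frac_reads_in_peaks) * cov
  expect_lt(abs(f - expected), 0.03)
})
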
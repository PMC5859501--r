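# End-to-end orchestration over synthetic data: simulate -> RPS -> QC ->
# differential (per assay) -> cross-assay merge -> annotate -> enrich ->
# motifs -> report. Each stage consumes the previous stage's outputs;
# a stage failure halts the run with a stage-named error, leaving the
# outputs already written on disk intact.

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full differential-accessibility pipeline on synthetic data
#'
#' Generates a synthetic experiment from \code{config}, builds a
#' reference peak set per assay from the replicate peak calls
#' (non-reciprocal 75% qualification, then merge), computes QC (FRiP on
#' emitted reads, replicate concordance on counts), runs the NB Wald
#' test per assay and selects differential peaks at the per-assay
#' nominal thresholds, merges differential peaks across assays,
#' annotates peaks against the gene models, computes proximity /
#' location / expression-class / temporal-cluster enrichments, runs the
#' two-step motif enrichment, and assembles a report. Ground-truth
#' recall and precision of the planted differential peaks are included
#' since the inputs are simulated.
#'
#' @param config a \code{\link{sim_config}}.
#' @param out_dir optional output directory; when given, all stage
#'   outputs (BED/TSV/JSON) and a run manifest with per-file checksums
#'   are written there.
#' @param alpha_atac nominal p threshold for the ATAC-style assay
#'   (default 0.2; the 2v2 design yields higher p-values).
#' @param alpha_dnase nominal p threshold for the DNase-style assay
#'   (default 0.1).
#' @param criterion \code{\link{overlap_criterion}} for RPS construction
#'   and cross-assay merging.
#' @param window_bp gene-proximity window (default 10 kb).
#' @param pwms motif panel for the enrichment step (default
#'   \code{\link{example_pwms}}; the first is planted).
#' @param motif_alpha significance level of the two-step motif test.
#' @param n_nondiff_seqs non-differential peaks sampled for the motif
#'   control set.
#' @param de_gene_ids DE gene ids for the enrichment stage; defaults to
#'   the simulated ground truth.
#' @return list of class \code{crm_report}; see the elements written by
#'   the report stage.
#' @export
run_pipeline <- function(config = sim_config(), out_dir = NULL,
                         alpha_atac = 0.2, alpha_dnase = 0.1,
                         criterion = overlap_criterion(),
                         window_bp = 10000L, pwms = example_pwms(),
                         motif_alpha = 0.05, n_nondiff_seqs = 300L,
                         de_gene_ids = NULL) {
  writing <- !is.null(out_dir)
  if (writing) dir.create(out_dir, showWarnings = FALSE,
                          recursive = TRUE)
  emit <- function(fn, name) if (writing) fn(file.path(out_dir, name))

  sim <- .stage("simulate", simulate_experiment(config,
                                                pwm = pwms[[1]]))
  if (writing) {
    write_bed(sim$peaks$master, file.path(out_dir, "master_peaks.bed"))
    write_chrom_sizes(sim$genome$sizes,
                      file.path(out_dir, "genome.chrom.sizes"))
    write_fasta(sim$genome$seq, file.path(out_dir, "genome.fa"))
    write_gff3_genes(sim$genes$genes, sim$genes$exons,
                     file.path(out_dir, "genes.gff3"))
    write_json_file(sim$ground_truth,
                    file.path(out_dir, "ground_truth.json"))
  }

  # --- reference peak sets ------------------------------------------
  rps <- .stage("rps", {
    lapply(sim$peaks$replicates, function(assay_reps) {
      build_reference_peak_set(c(assay_reps$target,
                                 assay_reps$reference),
                               criterion = criterion)
    })
  })
  genome_size <- sum(as.numeric(sim$genome$sizes$length))
  if (writing) {
    write_bed(rps$atac, file.path(out_dir, "rps_atac.bed"))
    write_bed(rps$dnase, file.path(out_dir, "rps_dnase.bed"))
  }

  # --- QC ------------------------------------------------------------
  qc <- .stage("qc", {
    reads <- simulate_reads(config, sim$genome, sim$peaks$master)
    lapply(c(atac = "atac", dnase = "dnase"), function(a) {
      cm <- sim$counts[[a]]
      fr <- stats::setNames(rep(frip(reads, rps[[a]]),
                                nrow(cm$samples)),
                            cm$samples$sample_id)
      replicate_concordance(cm$counts, cm$samples, frip_scores = fr)
    })
  })

  # --- differential accessibility per assay -------------------------
  diffacc <- .stage("diffacc", {
    lapply(c(atac = "atac", dnase = "dnase"), function(a) {
      cm <- sim$counts[[a]]
      sf <- size_factors(cm$counts)
      disp <- estimate_dispersions(cm$counts, cm$samples$condition,
                                   sf = sf)
      res <- nb_wald_test(cm$counts, cm$samples$condition,
                          reference = "reference", sf = sf,
                          dispersions = disp)
      alpha <- if (a == "atac") alpha_atac else alpha_dnase
      sel <- select_differential(res, sim$peaks$master, alpha = alpha,
                                 direction = "target")
      list(results = res, differential = sel, alpha = alpha)
    })
  })
  if (writing) {
    for (a in names(diffacc)) {
      m <- merge(as.data.frame(sim$peaks$master),
                 diffacc[[a]]$results, by.x = "id", by.y = "peak_id")
      utils::write.table(
        m[, c("id", "scaffold", "start", "end", "baseMean",
              "log2FoldChange", "lfcSE", "stat", "pvalue")],
        file.path(out_dir, sprintf("differential_results_%s.tsv", a)),
        sep = "\t", quote = FALSE, row.names = FALSE)
      write_bed(diffacc[[a]]$differential,
                file.path(out_dir,
                          sprintf("differential_peaks_%s.bed", a)))
    }
  }

  # --- cross-assay merge --------------------------------------------
  overlapping <- .stage("crossassay",
    cross_assay_merge(diffacc$atac$differential,
                      diffacc$dnase$differential,
                      criterion = criterion))
  if (writing)
    write_bed(overlapping,
              file.path(out_dir, "overlapping_differential_peaks.bed"))

  # --- annotation ----------------------------------------------------
  ann <- .stage("annotate",
    annotate_peaks(sim$peaks$master, sim$genes$genes, sim$genes$exons,
                   window_bp = window_bp))
  if (writing) {
    flat <- ann
    flat$genes_within_window <- vapply(ann$genes_within_window,
                                       paste, "", collapse = ",")
    utils::write.table(flat,
                       file.path(out_dir, "peak_annotation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # --- enrichment ----------------------------------------------------
  if (is.null(de_gene_ids))
    de_gene_ids <- sim$ground_truth$de_gene_ids
  enrich <- .stage("enrich", {
    if (length(de_gene_ids) == 0)
      stop("no DE gene list supplied")
    prox <- lapply(c(atac = "atac", dnase = "dnase"), function(a)
      proximity_enrichment(ann, diffacc[[a]]$differential$id,
                           de_gene_ids))
    diff_ids_all <- unique(c(diffacc$atac$differential$id,
                             diffacc$dnase$differential$id))
    near_overlap <- unique(unlist(
      ann$genes_within_window[ann$peak_id %in% diff_ids_all]))
    de_near <- intersect(near_overlap, de_gene_ids)
    genes <- sim$genes$genes
    de_universe <- genes[genes$gene_id %in% de_gene_ids, ,
                         drop = FALSE]
    expr_class <- assign_expression_class(de_universe$fpkm)
    clusters <- vapply(de_universe$gene_id, function(g)
      assign_temporal_cluster(sim$genes$expression[g, ],
                              sim$genes$times), integer(1))
    cls <- if (length(de_near) > 0)
      class_enrichment(de_near, de_universe$gene_id, expr_class)
    else NULL
    clu <- if (length(de_near) > 0)
      class_enrichment(de_near, de_universe$gene_id,
                       as.character(clusters))
    else NULL
    locdist <- list(
      rps = location_distribution(ann),
      differential = location_distribution(
        ann[ann$peak_id %in% diff_ids_all, , drop = FALSE]))
    list(proximity = prox, expression_class = cls,
         temporal_cluster = clu, location = locdist,
         de_genes_near_differential = de_near)
  })
  if (writing) {
    utils::write.table(do.call(rbind, enrich$proximity),
                       file.path(out_dir, "proximity_enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # --- motifs --------------------------------------------------------
  motifs <- .stage("motifs", {
    diff_ids <- diffacc$atac$differential$id
    nondiff <- setdiff(sim$peaks$master$id, diff_ids)
    set.seed(.sim_seed(config, "reads") + 1L)
    nondiff <- sample(nondiff, min(n_nondiff_seqs, length(nondiff)))
    dseq <- peak_sequences(sim$genome,
                           sim$peaks$master[
                             sim$peaks$master$id %in% diff_ids, ])
    nseq <- peak_sequences(sim$genome,
                           sim$peaks$master[
                             sim$peaks$master$id %in% nondiff, ])
    ame_two_step(dseq, nseq, pwms, alpha = motif_alpha,
                 seed = config$seed)
  })
  if (writing)
    utils::write.table(motifs,
                       file.path(out_dir, "motif_enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

  # --- report --------------------------------------------------------
  report <- .stage("report", {
    gt <- sim$ground_truth
    eval_assay <- function(a) {
      sel <- diffacc[[a]]$differential$id
      tp <- length(intersect(sel, gt$differential_peak_ids))
      list(n_selected = length(sel),
           recall = tp / length(gt$differential_peak_ids),
           precision = if (length(sel) > 0) tp / length(sel) else NA)
    }
    list(
      config = unclass(config),
      n_peaks_master = nrow(sim$peaks$master),
      rps = list(
        atac = list(n_peaks = nrow(rps$atac),
                    coverage = genome_coverage(rps$atac, genome_size),
                    mean_width = mean(rps$atac$end - rps$atac$start)),
        dnase = list(n_peaks = nrow(rps$dnase),
                     coverage = genome_coverage(rps$dnase, genome_size),
                     mean_width = mean(rps$dnase$end -
                                       rps$dnase$start))),
      qc = lapply(qc, function(q)
        list(retained = q$retained_samples,
             frip = unname(q$frip_per_sample[1]))),
      differential = list(
        atac = c(alpha = diffacc$atac$alpha, eval_assay("atac")),
        dnase = c(alpha = diffacc$dnase$alpha, eval_assay("dnase"))),
      n_overlapping_differential = nrow(overlapping),
      proximity = lapply(enrich$proximity, function(x)
        list(fold = x$fold_enrichment, p = x$p_value)),
      location = enrich$location,
      motif_calls = motifs$motif_id[motifs$enriched_in_differential],
      planted_motif = gt$planted_motif_id)
  })
  if (writing) {
    write_json_file(report, file.path(out_dir, "report.json"))
    files <- list.files(out_dir, full.names = TRUE)
    files <- files[!grepl("manifest\\.json$", files)]
    manifest <- list(
      tool = "crmpeaks",
      version = as.character(utils::packageVersion("crmpeaks")),
      seed = config$seed,
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      checksums = as.list(tools::md5sum(files)))
    names(manifest$checksums) <- basename(files)
    write_json_file(manifest, file.path(out_dir, "manifest.json"))
  }
  structure(c(report, list(annotations = ann, motifs = motifs,
                           enrichment = enrich, diffacc = diffacc,
                           rps_sets = rps, overlapping = overlapping,
                           qc_reports = qc, sim = sim)),
            class = "crm_report")
}

#' @export
print.crm_report <- function(x, ...) {
  cat("crmpeaks pipeline report\n")
  cat(sprintf("  master peaks: %d\n", x$n_peaks_master))
  cat(sprintf("  RPS: atac %d peaks (%.1f%% coverage), dnase %d peaks (%.1f%% coverage)\n",
              x$rps$atac$n_peaks, 100 * x$rps$atac$coverage,
              x$rps$dnase$n_peaks, 100 * x$rps$dnase$coverage))
  for (a in c("atac", "dnase"))
    cat(sprintf("  %s differential: %d selected (alpha %.2f, recall %.2f, precision %.2f)\n",
                a, x$differential[[a]]$n_selected,
                x$differential[[a]]$alpha, x$differential[[a]]$recall,
                x$differential[[a]]$precision))
  cat(sprintf("  overlapping differential peaks: %d\n",
              x$n_overlapping_differential))
  for (a in c("atac", "dnase"))
    cat(sprintf("  proximity to DE genes (%s): fold %.2f, p %.3g\n",
                a, x$proximity[[a]]$fold, x$proximity[[a]]$p))
  cat("  motifs called enriched:",
      paste(x$motif_calls, collapse = ", "), "\n")
  invisible(x)
}
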
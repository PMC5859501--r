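# Synthetic-data generator: a toy multi-scaffold genome, non-overlapping
# gene models with DE labels and temporal expression profiles, a master
# peak landscape with differential peaks planted near DE genes, replicate
# peak calls with jittered boundaries, negative-binomial count matrices
# with planted log2 fold changes, read intervals for FRiP/counting tests,
# and consensus motif sites written into differential peak sequences.
# Every generator is a pure function of its sim_config (per-stage seeds
# are derived from config$seed), so identical configs reproduce identical
# outputs.

.sim_seed <- function(config, stage) {
  # per-stage offsets keep each generator independently reproducible
  offs <- c(genome = 11L, genes = 23L, peaks = 37L, counts_atac = 41L,
            counts_dnase = 43L, motifs = 53L, reads = 59L)
  (config$seed * 97L + offs[[stage]]) %% .Machine$integer.max
}

#' Simulation configuration
#'
#' Defaults describe the study conditions the pipeline is exercised
#' under: a ~4 Mb toy genome on 20 scaffolds, 200 genes of which 40 are
#' DE, 1200 accessible peaks (~600 bp wide, ~18% genome coverage) of
#' which 10% carry a planted log2 fold change of 2 and lie within 10 kb
#' of DE genes, negative-binomial counts at mean depth 200 with
#' dispersion 0.05, 3 replicates per condition for the DNase-style assay
#' and 2 for the ATAC-style assay, and a consensus motif planted in 60%
#' of differential peaks.
#'
#' @param seed integer master seed; all per-stage seeds derive from it.
#' @param n_scaffolds number of scaffolds.
#' @param scaffold_length scaffold length in bp.
#' @param gc genome GC fraction.
#' @param n_genes number of gene models to place.
#' @param n_de_genes number of genes labelled differentially expressed.
#' @param n_peaks number of master peaks.
#' @param frac_differential fraction of peaks carrying a planted effect.
#' @param planted_log2fc log2 fold change planted in differential peaks
#'   (target over reference condition).
#' @param dispersion NB dispersion alpha (0 gives Poisson counts).
#' @param mean_depth expected reads per peak per sample at depth factor 1.
#' @param replicate_jitter_bp peak-boundary noise across replicates (bp).
#' @param n_replicates_atac,n_replicates_dnase replicates per condition.
#' @param motif_plant_rate fraction of differential peaks receiving a
#'   planted consensus motif site.
#' @param de_window maximum distance (bp) of planted differential peaks
#'   from a DE gene span.
#' @param peak_width_mean,peak_width_sd,peak_width_min peak width model.
#' @param peak_strength_sdlog sdlog of the per-peak lognormal baseline
#'   accessibility strength (mean 1). Peak-to-peak signal variation is
#'   what makes biological replicates correlate; 0 gives the flat
#'   equal-mean landscape.
#' @param frac_reads_in_peaks target FRiP of the read emitter.
#' @return A validated list of class \code{sim_config}.
#' @export
sim_config <- function(seed = 1L, n_scaffolds = 20L,
                       scaffold_length = 200000L, gc = 0.5,
                       n_genes = 200L, n_de_genes = 40L,
                       n_peaks = 1200L, frac_differential = 0.1,
                       planted_log2fc = 2, dispersion = 0.05,
                       mean_depth = 200, replicate_jitter_bp = 50L,
                       n_replicates_atac = 2L, n_replicates_dnase = 3L,
                       motif_plant_rate = 0.6, de_window = 10000L,
                       peak_width_mean = 600, peak_width_sd = 120,
                       peak_width_min = 300, peak_strength_sdlog = 1,
                       frac_reads_in_peaks = 0.635) {
  cfg <- list(seed = as.integer(seed), n_scaffolds = as.integer(n_scaffolds),
              scaffold_length = as.integer(scaffold_length), gc = gc,
              n_genes = as.integer(n_genes),
              n_de_genes = as.integer(n_de_genes),
              n_peaks = as.integer(n_peaks),
              frac_differential = frac_differential,
              planted_log2fc = planted_log2fc, dispersion = dispersion,
              mean_depth = mean_depth,
              replicate_jitter_bp = as.integer(replicate_jitter_bp),
              n_replicates_atac = as.integer(n_replicates_atac),
              n_replicates_dnase = as.integer(n_replicates_dnase),
              motif_plant_rate = motif_plant_rate,
              de_window = as.integer(de_window),
              peak_width_mean = peak_width_mean,
              peak_width_sd = peak_width_sd,
              peak_width_min = peak_width_min,
              peak_strength_sdlog = peak_strength_sdlog,
              frac_reads_in_peaks = frac_reads_in_peaks)
  with(cfg, {
    if (n_scaffolds < 1 || scaffold_length < 1)
      stop("sim_config: scaffold dimensions must be positive")
    if (gc < 0 || gc > 1) stop("sim_config: gc must be in [0,1]")
    if (n_de_genes > n_genes)
      stop("sim_config: n_de_genes must be <= n_genes")
    if (frac_differential <= 0 || frac_differential >= 1)
      stop("sim_config: frac_differential must be in (0,1)")
    if (dispersion < 0) stop("sim_config: dispersion must be >= 0")
    if (mean_depth <= 0) stop("sim_config: mean_depth must be positive")
    if (replicate_jitter_bp >= peak_width_min / 2)
      stop("sim_config: replicate_jitter_bp must be < half the minimum peak width")
    if (motif_plant_rate < 0 || motif_plant_rate > 1)
      stop("sim_config: motif_plant_rate must be in [0,1]")
    if (peak_strength_sdlog < 0)
      stop("sim_config: peak_strength_sdlog must be >= 0")
  })
  structure(cfg, class = "sim_config")
}

#' Generate a toy genome
#'
#' Scaffold sequences are i.i.d. bases at the configured GC fraction.
#' @param config a \code{\link{sim_config}}.
#' @return list with \code{seq} (\code{DNAStringSet}) and \code{sizes}
#'   (data.frame \code{scaffold}, \code{length}).
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.sim_seed(config, "genome"))
  p <- c(A = (1 - config$gc) / 2, C = config$gc / 2,
         G = config$gc / 2, T = (1 - config$gc) / 2)
  scafs <- sprintf("scaffold_%02d", seq_len(config$n_scaffolds))
  seqs <- vapply(scafs, function(s)
    paste(sample(names(p), config$scaffold_length, replace = TRUE,
                 prob = p), collapse = ""), "")
  list(seq = Biostrings::DNAStringSet(seqs),
       sizes = data.frame(scaffold = scafs,
                          length = config$scaffold_length,
                          stringsAsFactors = FALSE))
}

# rejection-sample n disjoint intervals of given widths onto the genome;
# also avoids intervals in `avoid` (data.frame scaffold/start/end) if given
.place_disjoint <- function(widths, sizes, min_gap = 0L, avoid = NULL,
                            max_tries = 200L) {
  n <- length(widths)
  placed <- data.frame(scaffold = character(n), start = integer(n),
                       end = integer(n), stringsAsFactors = FALSE)
  occ <- lapply(seq_len(nrow(sizes)), function(i) {
    if (is.null(avoid)) cbind(start = integer(0), end = integer(0))
    else {
      a <- avoid[avoid$scaffold == sizes$scaffold[i], , drop = FALSE]
      cbind(start = a$start, end = a$end)
    }
  })
  names(occ) <- sizes$scaffold
  for (i in seq_len(n)) {
    w <- widths[i]
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      si <- sample.int(nrow(sizes), 1)
      maxs <- sizes$length[si] - w
      if (maxs < 1) next
      s <- sample.int(maxs, 1)
      e <- s + w
      o <- occ[[si]]
      if (nrow(o) == 0 ||
          !any(s < o[, "end"] + min_gap & o[, "start"] < e + min_gap)) {
        placed$scaffold[i] <- sizes$scaffold[si]
        placed$start[i] <- s
        placed$end[i] <- e
        occ[[si]] <- rbind(o, c(s, e))
        ok <- TRUE
        break
      }
    }
    if (!ok)
      stop("placement error: genome too small to place all intervals disjointly")
  }
  placed
}

#' Generate gene models, DE labels and expression profiles
#'
#' Places \code{n_genes} non-overlapping gene models (1-5 exons each,
#' random strand), labels \code{n_de_genes} of them DE, and draws per
#' gene an FPKM value plus a temporal expression profile whose peak time
#' falls in one of four cluster windows (0-10, 40-72, 24-40, 18-24 hpf,
#' drawn with probabilities proportional to the 104/136/155/25 cluster
#' sizes of the DE-gene compendium the simulation emulates).
#'
#' @param config a \code{\link{sim_config}}.
#' @param genome output of \code{\link{generate_genome}}.
#' @return list with \code{genes} (gene table with \code{gene_id},
#'   coordinates, \code{strand}, \code{de}, \code{fpkm},
#'   \code{cluster_true}), \code{exons}, \code{expression} (genes x
#'   timepoints matrix) and \code{times} (hpf).
#' @export
generate_genes <- function(config, genome) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.sim_seed(config, "genes"))
  n <- config$n_genes
  span <- pmin(round(stats::rlnorm(n, log(3500), 0.45)) + 500L,
               config$scaffold_length %/% 4L)
  placed <- .place_disjoint(span, genome$sizes, min_gap = 1L)
  gene_id <- sprintf("gene_%04d", seq_len(n))
  strand <- sample(c("+", "-"), n, replace = TRUE)

  exons <- vector("list", n)
  for (i in seq_len(n)) {
    nex <- sample.int(5L, 1)
    w <- placed$end[i] - placed$start[i]
    if (nex == 1) {
      ex <- cbind(placed$start[i], placed$end[i])
    } else {
      # cut the span at 2*(nex-1) interior points: alternate exon/intron
      cuts <- sort(sample.int(w - 1L, 2L * (nex - 1L))) + placed$start[i]
      bounds <- c(placed$start[i], cuts, placed$end[i])
      starts <- bounds[seq(1, length(bounds), by = 2)]
      ends <- bounds[seq(2, length(bounds), by = 2)]
      ex <- cbind(starts, ends)
    }
    exons[[i]] <- data.frame(gene_id = gene_id[i],
                             scaffold = placed$scaffold[i],
                             start = as.integer(ex[, 1]),
                             end = as.integer(ex[, 2]),
                             stringsAsFactors = FALSE)
  }
  exons <- do.call(rbind, exons)

  de <- rep(FALSE, n)
  de[sample.int(n, config$n_de_genes)] <- TRUE
  fpkm <- stats::rlnorm(n, log(40), 1.2)

  cluster_windows <- list(`1` = c(0, 10), `2` = c(40, 72),
                          `3` = c(24, 40), `4` = c(18, 24))
  cluster_prob <- c(104, 136, 155, 25) / 420
  cl <- sample(1:4, n, replace = TRUE, prob = cluster_prob)
  peak_time <- vapply(cl, function(k) {
    w <- cluster_windows[[k]]
    stats::runif(1, w[1], w[2] - 1e-6)
  }, numeric(1))

  times <- c(0, 6, 10, 14, 18, 21, 24, 30, 36, 40, 48, 60, 72)
  expression <- t(vapply(seq_len(n), function(i)
    fpkm[i] * exp(-(times - peak_time[i])^2 / (2 * 8^2)), numeric(length(times))))
  rownames(expression) <- gene_id
  colnames(expression) <- as.character(times)

  genes <- data.frame(gene_id = gene_id, scaffold = placed$scaffold,
                      start = placed$start, end = placed$end,
                      strand = strand, de = de, fpkm = fpkm,
                      cluster_true = cl, peak_time = peak_time,
                      stringsAsFactors = FALSE)
  list(genes = genes, exons = exons, expression = expression,
       times = times)
}

#' Generate master peaks and per-replicate peak calls
#'
#' Places a disjoint master peak set (~600 bp widths); a
#' \code{frac_differential} fraction of peaks is placed within
#' \code{de_window} of randomly chosen DE gene spans and recorded as the
#' planted differential peaks. Each replicate's calls are the master set
#' with both boundaries independently jittered by up to
#' \code{replicate_jitter_bp}.
#'
#' @param config a \code{\link{sim_config}}.
#' @param genome output of \code{\link{generate_genome}}.
#' @param genes output of \code{\link{generate_genes}}.
#' @return list with \code{master} (\code{peak_set}),
#'   \code{differential_peak_ids}, \code{planted_log2fc} (named vector),
#'   and \code{replicates}: per assay, per condition, a list of
#'   \code{peak_set}s.
#' @export
generate_peak_landscape <- function(config, genome, genes) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.sim_seed(config, "peaks"))
  n <- config$n_peaks
  n_diff <- round(n * config$frac_differential)
  widths <- pmax(round(stats::rnorm(n, config$peak_width_mean,
                                    config$peak_width_sd)),
                 config$peak_width_min)

  de_genes <- genes$genes[genes$genes$de, , drop = FALSE]
  if (nrow(de_genes) == 0 && n_diff > 0)
    stop("cannot plant differential peaks without DE genes")

  # differential peaks: rejection-sample near DE gene spans
  placed <- data.frame(scaffold = character(0), start = integer(0),
                       end = integer(0), stringsAsFactors = FALSE)
  for (i in seq_len(n_diff)) {
    w <- widths[i]
    ok <- FALSE
    for (try in 1:500) {
      g <- de_genes[sample.int(nrow(de_genes), 1), ]
      lo <- max(0L, g$start - config$de_window - w)
      hi <- min(config$scaffold_length - w,
                g$end + config$de_window)
      if (hi <= lo) next
      s <- sample(seq.int(lo, hi), 1)
      e <- s + w
      # distance from peak to gene span must be <= de_window
      gap <- max(0L, g$start - e + 1L, s - g$end + 1L)
      if (gap > config$de_window) next
      same <- placed[placed$scaffold == g$scaffold, , drop = FALSE]
      if (nrow(same) == 0 || !any(s < same$end & same$start < e)) {
        placed <- rbind(placed, data.frame(scaffold = g$scaffold,
                                           start = s, end = e,
                                           stringsAsFactors = FALSE))
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("placement error: could not place differential peaks")
  }
  rest <- .place_disjoint(widths[seq.int(n_diff + 1, n)], genome$sizes,
                          min_gap = 1L, avoid = placed)
  all_placed <- rbind(placed, rest)
  ids <- sprintf("peak_%06d", seq_len(n))
  master <- peak_set(all_placed$scaffold, all_placed$start,
                     all_placed$end, id = ids, label = "master")
  # peak_set() sorts; recover which sorted rows are the differential ones
  diff_ids <- ids[seq_len(n_diff)]
  lfc <- stats::setNames(rep(0, n), ids)
  lfc[diff_ids] <- config$planted_log2fc

  jitter_one <- function(ps) {
    j <- config$replicate_jitter_bp
    if (j == 0) return(ps)
    ds <- sample.int(2L * j + 1L, nrow(ps), replace = TRUE) - j - 1L
    de_ <- sample.int(2L * j + 1L, nrow(ps), replace = TRUE) - j - 1L
    s <- pmax(0L, ps$start + ds)
    e <- pmin(config$scaffold_length, ps$end + de_)
    bad <- s >= e
    s[bad] <- ps$start[bad]
    e[bad] <- ps$end[bad]
    peak_set(ps$scaffold, s, e, id = ps$id, label = attr(ps, "label"))
  }

  reps <- list(
    atac = list(target = lapply(seq_len(config$n_replicates_atac),
                                function(r) jitter_one(master)),
                reference = lapply(seq_len(config$n_replicates_atac),
                                   function(r) jitter_one(master))),
    dnase = list(target = lapply(seq_len(config$n_replicates_dnase),
                                 function(r) jitter_one(master)),
                 reference = lapply(seq_len(config$n_replicates_dnase),
                                    function(r) jitter_one(master))))

  # per-peak baseline accessibility strength (mean 1), shared across
  # samples and assays: the signal replicates correlate on
  strength <- stats::setNames(
    stats::rlnorm(n, -config$peak_strength_sdlog^2 / 2,
                  config$peak_strength_sdlog), ids)

  list(master = master, differential_peak_ids = diff_ids,
       planted_log2fc = lfc, peak_strength = strength,
       replicates = reps)
}

#' Generate a negative-binomial count matrix for one assay
#'
#' Counts are NB(mu_ij, alpha) with
#' mu_ij = mean_depth * g_i * s_j * 2^(x_j * lfc_i), where g_i is the
#' per-peak baseline accessibility strength (mean 1), x_j = 1 in the
#' target (accessible) condition and lfc_i is the planted log2 fold
#' change (0 for non-differential peaks). Per-sample depth factors s_j
#' are drawn uniformly in [0.7, 1.3] and returned. dispersion = 0 gives
#' Poisson counts.
#'
#' @param config a \code{\link{sim_config}}.
#' @param peaks \code{peak_set} the counts are indexed by (usually the
#'   master set or an RPS).
#' @param planted_log2fc named vector of planted effects per peak id;
#'   ids absent from it get 0.
#' @param peak_strength named vector of per-peak baseline strengths;
#'   ids absent from it get 1 (flat landscape).
#' @param assay \code{"atac"} or \code{"dnase"} (sets replicate number
#'   and the per-stage seed).
#' @return list with \code{counts} (integer matrix peaks x samples),
#'   \code{samples} (sample sheet) and \code{depth_factors}.
#' @export
generate_counts <- function(config, peaks, planted_log2fc = NULL,
                            peak_strength = NULL,
                            assay = c("atac", "dnase")) {
  stopifnot(inherits(config, "sim_config"))
  assay <- match.arg(assay)
  set.seed(.sim_seed(config, paste0("counts_", assay)))
  nrep <- if (assay == "atac") config$n_replicates_atac else
    config$n_replicates_dnase
  samples <- data.frame(
    sample_id = c(sprintf("%s_target_rep%d", assay, seq_len(nrep)),
                  sprintf("%s_reference_rep%d", assay, seq_len(nrep))),
    assay = assay,
    condition = rep(c("target", "reference"), each = nrep),
    replicate = rep(seq_len(nrep), 2),
    stringsAsFactors = FALSE)
  ns <- nrow(samples)
  np <- nrow(peaks)
  lfc <- rep(0, np)
  if (!is.null(planted_log2fc)) {
    hit <- intersect(peaks$id, names(planted_log2fc))
    lfc[match(hit, peaks$id)] <- planted_log2fc[hit]
  }
  g_i <- rep(1, np)
  if (!is.null(peak_strength)) {
    hit <- intersect(peaks$id, names(peak_strength))
    g_i[match(hit, peaks$id)] <- peak_strength[hit]
  }
  s_j <- stats::runif(ns, 0.7, 1.3)
  x_j <- as.numeric(samples$condition == "target")
  mu <- outer(config$mean_depth * g_i, s_j) *
    2^(outer(lfc, x_j))
  counts <- matrix(0L, np, ns,
                   dimnames = list(peaks$id, samples$sample_id))
  for (j in seq_len(ns)) {
    counts[, j] <- if (config$dispersion == 0)
      stats::rpois(np, mu[, j])
    else
      stats::rnbinom(np, mu = mu[, j], size = 1 / config$dispersion)
  }
  list(counts = counts, samples = samples, depth_factors = s_j)
}

#' Emit read intervals for one sample
#'
#' Places single-end read intervals so that a fraction
#' \code{frac_in_peaks} of them start inside peaks (uniformly across
#' peak bases) and the rest uniformly across the genome; supports FRiP
#' and read-counting tests.
#'
#' @param config a \code{\link{sim_config}}.
#' @param genome output of \code{\link{generate_genome}}.
#' @param peaks \code{peak_set} of accessible regions.
#' @param n_reads number of reads to place.
#' @param read_length read length in bp.
#' @param frac_in_peaks target fraction of reads inside peaks; defaults
#'   to the configured FRiP.
#' @param seed optional seed override (defaults to the config-derived
#'   read-stage seed).
#' @return A \code{peak_set} of read intervals.
#' @export
simulate_reads <- function(config, genome, peaks, n_reads = 50000L,
                           read_length = 50L, frac_in_peaks = NULL,
                           seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(frac_in_peaks)) frac_in_peaks <- config$frac_reads_in_peaks
  set.seed(if (is.null(seed)) .sim_seed(config, "reads") else seed)
  in_peak <- stats::rbinom(n_reads, 1, frac_in_peaks) == 1
  n_in <- sum(in_peak)
  scaf <- character(n_reads)
  start <- integer(n_reads)
  if (n_in > 0) {
    pw <- peaks$end - peaks$start
    pick <- sample.int(nrow(peaks), n_in, replace = TRUE,
                       prob = pw / sum(pw))
    off <- floor(stats::runif(n_in) * pmax(1L, pw[pick] - read_length))
    scaf[in_peak] <- peaks$scaffold[pick]
    start[in_peak] <- peaks$start[pick] + off
  }
  n_bg <- n_reads - n_in
  if (n_bg > 0) {
    si <- sample.int(nrow(genome$sizes), n_bg, replace = TRUE)
    scaf[!in_peak] <- genome$sizes$scaffold[si]
    start[!in_peak] <- floor(stats::runif(
      n_bg, 0, genome$sizes$length[si] - read_length))
  }
  peak_set(scaf, start, start + read_length,
           id = sprintf("read_%07d", seq_len(n_reads)), label = "reads")
}

#' Plant consensus motif sites into differential peak sequences
#'
#' Writes the consensus string of \code{pwm} at a random offset inside
#' each differential peak with probability \code{motif_plant_rate};
#' other peaks and the rest of the genome are untouched. Peaks narrower
#' than the motif are skipped with a warning.
#'
#' @param config a \code{\link{sim_config}}.
#' @param genome output of \code{\link{generate_genome}}; modified copy
#'   returned.
#' @param peaks master \code{peak_set}.
#' @param pwm a \code{\link{pwm}} whose consensus is planted.
#' @param differential_peak_ids ids of peaks eligible for planting.
#' @return list with \code{genome} (mutated) and
#'   \code{motif_planted_peak_ids}.
#' @export
plant_motifs <- function(config, genome, peaks, pwm,
                         differential_peak_ids) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.sim_seed(config, "motifs"))
  cons <- pwm_consensus(pwm)
  w <- nchar(cons)
  seqs <- as.character(genome$seq)
  planted <- character(0)
  for (pid in differential_peak_ids) {
    if (stats::runif(1) > config$motif_plant_rate) next
    row <- peaks[peaks$id == pid, ]
    pw_ <- row$end - row$start
    if (pw_ < w) {
      warning(sprintf("peak %s narrower than motif; skipped", pid))
      next
    }
    off <- sample.int(pw_ - w + 1L, 1) - 1L
    s0 <- row$start + off  # 0-based genome offset
    seqs[[row$scaffold]] <- paste0(
      substr(seqs[[row$scaffold]], 1, s0),
      cons,
      substr(seqs[[row$scaffold]], s0 + w + 1,
             nchar(seqs[[row$scaffold]])))
    planted <- c(planted, pid)
  }
  genome$seq <- Biostrings::DNAStringSet(seqs)
  list(genome = genome, motif_planted_peak_ids = planted)
}

#' Extract peak sequences from the genome
#' @param genome output of \code{\link{generate_genome}}.
#' @param peaks a \code{peak_set}.
#' @return named character vector of peak sequences.
#' @export
peak_sequences <- function(genome, peaks) {
  out <- vapply(seq_len(nrow(peaks)), function(i)
    as.character(Biostrings::subseq(genome$seq[[peaks$scaffold[i]]],
                                    peaks$start[i] + 1L, peaks$end[i])),
    "")
  stats::setNames(out, peaks$id)
}

#' Run the whole generator and assemble the ground truth
#'
#' Convenience wrapper producing everything downstream stages consume:
#' genome (with planted motifs), gene models and expression, master and
#' replicate peak sets, per-assay count matrices, and a ground-truth
#' manifest.
#'
#' @param config a \code{\link{sim_config}}.
#' @param pwm optional \code{\link{pwm}} to plant (default: the built-in
#'   Ets1-like example motif).
#' @return list with components \code{config}, \code{genome},
#'   \code{genes}, \code{peaks}, \code{counts} (per assay) and
#'   \code{ground_truth}.
#' @export
simulate_experiment <- function(config = sim_config(),
                                pwm = example_pwms()[["Ets1"]]) {
  genome <- generate_genome(config)
  genes <- generate_genes(config, genome)
  land <- generate_peak_landscape(config, genome, genes)
  counts <- list(
    atac = generate_counts(config, land$master, land$planted_log2fc,
                           land$peak_strength, assay = "atac"),
    dnase = generate_counts(config, land$master, land$planted_log2fc,
                            land$peak_strength, assay = "dnase"))
  pm <- plant_motifs(config, genome, land$master, pwm,
                     land$differential_peak_ids)
  ground_truth <- list(
    differential_peak_ids = land$differential_peak_ids,
    de_gene_ids = genes$genes$gene_id[genes$genes$de],
    planted_log2fc_per_peak = land$planted_log2fc,
    motif_planted_peak_ids = pm$motif_planted_peak_ids,
    planted_motif_id = pwm$motif_id,
    depth_factors = list(atac = counts$atac$depth_factors,
                         dnase = counts$dnase$depth_factors))
  list(config = config, genome = pm$genome, genes = genes, peaks = land,
       counts = counts, ground_truth = ground_truth)
}
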
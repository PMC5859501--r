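# Read counting over the reference peak set, depth equalization by
# subsampling, FRiP, and replicate-concordance gating.

#' Count reads in disjoint peaks
#'
#' Each read contributes to at most one peak: the peak it overlaps by
#' the greatest number of bases, with ties broken toward the leftmost
#' (smallest-start) peak. Reads overlapping no peak are uncounted, so
#' the counts sum to at most the number of reads. The peak set must be
#' disjoint (the RPS contract).
#'
#' @param reads \code{peak_set} of read intervals.
#' @param peaks disjoint \code{peak_set} (e.g. an RPS).
#' @return Named integer vector of counts, one per peak, in peak order.
#' @export
count_reads_in_peaks <- function(reads, peaks) {
  m <- merge_union(peaks)
  if (nrow(m) != nrow(peaks))
    stop("count_reads_in_peaks: peaks must be disjoint (RPS contract)")
  counts <- stats::setNames(integer(nrow(peaks)), peaks$id)
  if (nrow(reads) == 0 || nrow(peaks) == 0) return(counts)
  h <- .harmonize(.ps_to_gr(reads), .ps_to_gr(peaks))
  rgr <- h$a
  pgr <- h$b
  ov <- GenomicRanges::findOverlaps(rgr, pgr)
  if (length(ov) == 0) return(counts)
  qh <- S4Vectors::queryHits(ov)
  sh <- S4Vectors::subjectHits(ov)
  w <- GenomicRanges::width(IRanges::pintersect(rgr[qh], pgr[sh]))
  # per read: keep hit with max overlap, tie -> leftmost peak
  o <- order(qh, -w, peaks$scaffold[sh], peaks$start[sh])
  first <- !duplicated(qh[o])
  chosen <- sh[o][first]
  tab <- table(chosen)
  counts[as.integer(names(tab))] <- as.integer(tab)
  counts
}

# multivariate hypergeometric draw: subsample a count vector to k total
.subsample_counts <- function(x, k) {
  n_tot <- sum(x)
  if (k >= n_tot) return(x)
  out <- integer(length(x))
  rem_total <- n_tot
  rem_k <- k
  for (i in seq_along(x)) {
    if (rem_k == 0) break
    xi <- x[i]
    drawn <- stats::rhyper(1, m = xi, n = rem_total - xi, k = rem_k)
    out[i] <- drawn
    rem_total <- rem_total - xi
    rem_k <- rem_k - drawn
  }
  out
}

#' Equalize sequencing depth across samples
#'
#' Subsamples every sample, without replacement, down to the minimum
#' depth. For a list of read interval sets, rows are subsampled; for a
#' count matrix, each column is downsampled by a multivariate
#' hypergeometric draw (equivalent to subsampling the underlying reads).
#' Seeded and reproducible.
#'
#' @param x either a list of \code{peak_set}s of reads, or an integer
#'   count matrix (peaks x samples).
#' @param seed integer seed.
#' @return Object of the same shape with equal per-sample depth (the
#'   minimum of the input depths).
#' @export
equalize_depth <- function(x, seed = 1L) {
  set.seed(seed)
  if (is.matrix(x)) {
    depths <- colSums(x)
    if (any(depths == 0)) stop("equalize_depth: sample with zero depth")
    k <- min(depths)
    for (j in seq_len(ncol(x))) x[, j] <- .subsample_counts(x[, j], k)
    return(x)
  }
  if (!is.list(x) || length(x) < 2)
    stop("equalize_depth needs >= 2 samples")
  depths <- vapply(x, nrow, 0L)
  if (any(depths == 0)) stop("equalize_depth: sample with zero depth")
  k <- min(depths)
  lapply(x, function(r) {
    if (nrow(r) == k) return(r)
    keep <- sort(sample.int(nrow(r), k))
    as_peak_set(r[keep, , drop = FALSE], label = attr(r, "label"))
  })
}

#' Fraction of reads in peaks (FRiP)
#'
#' The number of reads overlapping any peak by at least 1 bp divided by
#' the total number of reads.
#'
#' @param reads \code{peak_set} of read intervals (must be nonempty).
#' @param peaks \code{peak_set} of called peaks.
#' @return FRiP fraction in [0,1].
#' @export
frip <- function(reads, peaks) {
  if (nrow(reads) == 0) stop("frip: undefined for zero reads")
  if (nrow(peaks) == 0) return(0)
  hit <- present_in(reads, peaks,
                    overlap_criterion(min_bp = 1L, mode = "any"))
  mean(hit)
}

#' Replicate concordance QC
#'
#' Pairwise Pearson correlation of per-peak counts between samples
#' (log1p-transformed by default to stabilise heavy-tailed counts). A
#' replicate is dropped when its mean pairwise correlation with the
#' other retained same-condition replicates falls at or below the
#' exclusion threshold; exclusion is greedy (the worst replicate is
#' dropped first and the means recomputed), so one discordant replicate
#' does not drag its concordant partners below the threshold. Pairs
#' with a constant count vector have undefined correlation and are
#' reported as NA.
#'
#' @param counts integer matrix, peaks x samples.
#' @param samples sample sheet with \code{sample_id} and
#'   \code{condition} matching the columns of \code{counts}.
#' @param transform \code{"log1p"} (default) or \code{"raw"}.
#' @param retain_threshold correlation at or above which a replicate is
#'   reported as highly concordant (default 0.9).
#' @param exclude_threshold mean same-condition correlation at or below
#'   which a replicate is dropped (default 0.8).
#' @param frip_scores optional named FRiP vector per sample; samples
#'   below \code{frip_threshold} fail the FRiP gate.
#' @param frip_threshold minimum FRiP (default 0.4).
#' @return list of class \code{qc_report}: \code{pearson} (symmetric
#'   matrix), \code{mean_same_condition}, \code{retained_samples},
#'   \code{frip_per_sample}, \code{frip_pass}.
#' @export
replicate_concordance <- function(counts, samples,
                                  transform = c("log1p", "raw"),
                                  retain_threshold = 0.9,
                                  exclude_threshold = 0.8,
                                  frip_scores = NULL,
                                  frip_threshold = 0.4) {
  transform <- match.arg(transform)
  if (ncol(counts) < 2)
    stop("replicate_concordance needs >= 2 samples")
  stopifnot(identical(colnames(counts), samples$sample_id))
  m <- if (transform == "log1p") log1p(counts) else counts
  ns <- ncol(m)
  r <- matrix(NA_real_, ns, ns,
              dimnames = list(samples$sample_id, samples$sample_id))
  diag(r) <- 1
  for (i in seq_len(ns - 1)) for (j in seq.int(i + 1, ns)) {
    if (stats::sd(m[, i]) == 0 || stats::sd(m[, j]) == 0) next
    r[i, j] <- r[j, i] <- stats::cor(m[, i], m[, j])
  }
  mean_vs <- function(i, pool) {
    same <- setdiff(pool[samples$condition[pool] ==
                           samples$condition[i]], i)
    if (length(same) == 0) return(NA_real_)
    mean(r[i, same], na.rm = TRUE)
  }
  mean_same <- vapply(seq_len(ns), function(i)
    mean_vs(i, seq_len(ns)), numeric(1))
  names(mean_same) <- samples$sample_id
  # greedy exclusion: repeatedly drop the worst replicate at or below
  # the threshold, recomputing means among the survivors
  pool <- seq_len(ns)
  repeat {
    cur <- vapply(pool, function(i) mean_vs(i, pool), numeric(1))
    bad <- which(!is.na(cur) & cur <= exclude_threshold)
    if (length(bad) == 0) break
    pool <- pool[-bad[which.min(cur[bad])]]
  }
  retained <- samples$sample_id[pool]
  frip_pass <- NULL
  if (!is.null(frip_scores)) {
    frip_pass <- frip_scores >= frip_threshold
    retained <- intersect(retained,
                          names(frip_scores)[frip_pass])
  }
  structure(list(pearson = r, mean_same_condition = mean_same,
                 retained_samples = retained,
                 highly_concordant = !is.na(mean_same) &
                   mean_same >= retain_threshold,
                 frip_per_sample = frip_scores, frip_pass = frip_pass),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report\n")
  cat("  retained samples:", paste(x$retained_samples, collapse = ", "),
      "\n")
  if (!is.null(x$frip_per_sample)) {
    cat("  FRiP:\n")
    print(round(x$frip_per_sample, 3))
  }
  cat("  mean same-condition Pearson:\n")
  print(round(x$mean_same_condition, 3))
  invisible(x)
}
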
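#' Construct a peak set
#'
#' A peak set is the atom of all peak algebra in this package: an ordered
#' collection of genomic intervals on named scaffolds, using 0-based
#' half-open coordinates (BED convention). Intervals are sorted by
#' (scaffold, start) on construction.
#'
#' @param scaffold character vector of scaffold names.
#' @param start integer vector, 0-based inclusive start coordinates.
#' @param end integer vector, exclusive end coordinates; must satisfy
#'   \code{start < end}.
#' @param id optional character vector of interval identifiers; generated
#'   as \code{peak_000001, ...} when missing.
#' @param label optional label naming the sample or assay the set came from.
#' @return A \code{data.frame} of class \code{peak_set} with columns
#'   \code{scaffold}, \code{start}, \code{end}, \code{id}.
#' @export
peak_set <- function(scaffold = character(), start = integer(),
                     end = integer(), id = NULL, label = NULL) {
  n <- length(start)
  if (length(scaffold) == 1L && n > 1L) scaffold <- rep(scaffold, n)
  if (length(scaffold) != n || length(end) != n)
    stop("scaffold, start and end must have equal length")
  start <- as.integer(start)
  end <- as.integer(end)
  if (n > 0) {
    if (anyNA(start) || anyNA(end) || anyNA(scaffold))
      stop("peak_set: NA coordinates are not allowed")
    if (any(start < 0)) stop("peak_set: start must be >= 0")
    if (any(start >= end)) stop("peak_set: start must be < end")
  }
  if (is.null(id)) {
    id <- sprintf("peak_%06d", seq_len(n))
  } else if (length(id) != n) {
    stop("id must match the number of intervals")
  }
  ps <- data.frame(scaffold = as.character(scaffold), start = start,
                   end = end, id = as.character(id),
                   stringsAsFactors = FALSE)
  o <- order(ps$scaffold, ps$start, ps$end)
  ps <- ps[o, , drop = FALSE]
  rownames(ps) <- NULL
  attr(ps, "label") <- label
  class(ps) <- c("peak_set", "data.frame")
  ps
}

#' Coerce a data.frame to a peak set
#' @param x data.frame with columns scaffold, start, end and optionally id.
#' @param label optional sample/assay label.
#' @return A \code{peak_set}.
#' @export
as_peak_set <- function(x, label = NULL) {
  peak_set(x$scaffold, x$start, x$end,
           id = if ("id" %in% names(x)) x$id else NULL, label = label)
}

#' @export
print.peak_set <- function(x, ...) {
  lab <- attr(x, "label")
  cat(sprintf("peak_set with %d interval(s)%s\n", nrow(x),
              if (is.null(lab)) "" else paste0(" [", lab, "]")))
  if (nrow(x) > 0) print(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

# internal: peak_set <-> GRanges (1-based closed)
.ps_to_gr <- function(ps) {
  GenomicRanges::GRanges(
    seqnames = ps$scaffold,
    ranges = IRanges::IRanges(start = ps$start + 1L, end = ps$end),
    id = ps$id)
}

# put two GRanges on a common seqlevel universe before findOverlaps
.harmonize <- function(a, b) {
  lv <- union(GenomeInfoDb::seqlevels(a), GenomeInfoDb::seqlevels(b))
  GenomeInfoDb::seqlevels(a) <- lv
  GenomeInfoDb::seqlevels(b) <- lv
  list(a = a, b = b)
}

#' Overlap criterion
#'
#' Parameters controlling when one interval is considered to overlap a
#' reference set: either a minimum fraction of the query's own length
#' (non-reciprocal fraction mode, default 0.75) or any overlap of at least
#' \code{min_bp} bases.
#'
#' @param min_fraction minimum fraction of the query's length that must be
#'   covered by the union of the targets (fraction mode).
#' @param min_bp minimum overlap in bp (any-overlap mode).
#' @param mode \code{"fraction"} (of the query) or \code{"any"}.
#' @return A list of class \code{overlap_criterion}.
#' @export
overlap_criterion <- function(min_fraction = 0.75, min_bp = 1L,
                              mode = c("fraction", "any")) {
  mode <- match.arg(mode)
  if (min_fraction < 0 || min_fraction > 1)
    stop("min_fraction must be in [0,1]")
  if (min_bp < 1) stop("min_bp must be >= 1")
  structure(list(min_fraction = min_fraction, min_bp = as.integer(min_bp),
                 mode = mode), class = "overlap_criterion")
}

#' Fraction of each query interval covered by a target set
#'
#' The overlap fraction is computed non-reciprocally: for each query
#' interval, the number of its own bases covered by the union of the
#' target intervals, divided by the query's length. Queries on scaffolds
#' absent from the target set get 0.
#'
#' @param query a \code{peak_set} of query intervals.
#' @param targets a \code{peak_set}; internally merged before computing
#'   coverage.
#' @return Numeric vector in [0,1], one value per query interval, in the
#'   order of \code{query}.
#' @export
overlap_fraction <- function(query, targets) {
  if (nrow(query) == 0) return(numeric(0))
  if (nrow(targets) == 0) return(rep(0, nrow(query)))
  m <- merge_union(targets)
  frac <- numeric(nrow(query))
  for (scf in unique(query$scaffold)) {
    qi <- which(query$scaffold == scf)
    tm <- m[m$scaffold == scf, , drop = FALSE]
    if (nrow(tm) == 0) next
    ts <- tm$start
    te <- tm$end
    cum0 <- c(0, cumsum(te - ts))
    # C(x): covered target length left of coordinate x
    C <- function(x) {
      j <- findInterval(x, ts)
      out <- numeric(length(x))
      nz <- j > 0
      out[nz] <- cum0[j[nz]] +
        pmin(pmax(x[nz] - ts[j[nz]], 0), te[j[nz]] - ts[j[nz]])
      out
    }
    frac[qi] <- (C(query$end[qi]) - C(query$start[qi])) /
      (query$end[qi] - query$start[qi])
  }
  frac
}

#' Merge a peak set into its disjoint union
#'
#' Returns the minimal sorted set of disjoint intervals covering exactly
#' the union of the input. Book-ended intervals (sharing only an endpoint,
#' e.g. [0,10) and [10,20)) are merged only when
#' \code{merge_bookended = TRUE}.
#'
#' @param ps a \code{peak_set}.
#' @param merge_bookended logical; merge intervals that touch without
#'   overlapping (default \code{FALSE}, standard BED merge-distance-0
#'   semantics made explicit).
#' @return A merged \code{peak_set}; idempotent and order-invariant.
#' @export
merge_union <- function(ps, merge_bookended = FALSE) {
  if (nrow(ps) == 0) return(ps)
  o <- order(ps$scaffold, ps$start, ps$end)
  scf <- ps$scaffold[o]
  s <- ps$start[o]
  e <- ps$end[o]
  n <- length(s)
  # running max end within each scaffold (input sorted by scaffold)
  cme <- stats::ave(e, scf, FUN = cummax)
  same <- c(FALSE, scf[-1] == scf[-n])
  prev_cme <- c(-1L, cme[-n])
  new_grp <- !same | (if (merge_bookended) s > prev_cme
                      else s >= prev_cme)
  grp <- cumsum(new_grp)
  first <- which(new_grp)
  peak_set(scf[first], s[first],
           as.integer(tapply(e, grp, max)),
           label = attr(ps, "label"))
}

#' Build a reference peak set from replicate peak calls
#'
#' A replicate peak qualifies for the reference peak set (RPS) when the
#' fraction of its own length covered by the other replicates meets the
#' criterion (non-reciprocal overlap, default 75%). Qualifying peaks from
#' all replicates are pooled and merged into disjoint intervals. The
#' result is invariant to replicate ordering.
#'
#' @param replicates list of two or more \code{peak_set}s, one per
#'   replicate.
#' @param criterion an \code{\link{overlap_criterion}}; only fraction mode
#'   is meaningful here.
#' @param qualify \code{"union"}: a peak qualifies if covered >=
#'   \code{min_fraction} by the union of all other replicates (default);
#'   \code{"each"}: it must meet the fraction against every other
#'   replicate separately.
#' @param merge_bookended passed to \code{\link{merge_union}}.
#' @return A merged \code{peak_set} (the RPS).
#' @export
build_reference_peak_set <- function(replicates,
                                     criterion = overlap_criterion(),
                                     qualify = c("union", "each"),
                                     merge_bookended = FALSE) {
  qualify <- match.arg(qualify)
  if (!is.list(replicates) || length(replicates) < 2)
    stop("build_reference_peak_set needs at least 2 replicate peak sets")
  n <- length(replicates)
  kept <- vector("list", n)
  for (i in seq_len(n)) {
    rep_i <- replicates[[i]]
    if (nrow(rep_i) == 0) { kept[[i]] <- rep_i; next }
    others <- replicates[-i]
    if (qualify == "union") {
      pooled <- do.call(rbind, lapply(others, as.data.frame))
      frac <- overlap_fraction(rep_i, as_peak_set(pooled))
      ok <- frac >= criterion$min_fraction
    } else {
      ok <- rep(TRUE, nrow(rep_i))
      for (o in others)
        ok <- ok & (overlap_fraction(rep_i, o) >= criterion$min_fraction)
    }
    kept[[i]] <- rep_i[ok, , drop = FALSE]
  }
  pooled <- do.call(rbind, lapply(kept, as.data.frame))
  if (nrow(pooled) == 0)
    return(peak_set(label = "RPS"))
  merge_union(as_peak_set(pooled, label = "RPS"),
              merge_bookended = merge_bookended)
}

#' Merge differential peaks across two assays
#'
#' Pools the peaks of each set whose own length is covered by the other
#' set at the criterion fraction (non-reciprocal, both directions) and
#' merges them into disjoint intervals. Symmetric in its two arguments;
#' disjoint inputs give an empty result.
#'
#' @param diff_a,diff_b \code{peak_set}s of differential peaks from the
#'   two assays.
#' @param criterion an \code{\link{overlap_criterion}}.
#' @param merge_bookended passed to \code{\link{merge_union}}.
#' @return A merged \code{peak_set} of cross-assay overlapping
#'   differential peaks.
#' @export
cross_assay_merge <- function(diff_a, diff_b,
                              criterion = overlap_criterion(),
                              merge_bookended = FALSE) {
  keep_a <- if (nrow(diff_a) > 0)
    diff_a[overlap_fraction(diff_a, diff_b) >= criterion$min_fraction, ,
           drop = FALSE] else diff_a
  keep_b <- if (nrow(diff_b) > 0)
    diff_b[overlap_fraction(diff_b, diff_a) >= criterion$min_fraction, ,
           drop = FALSE] else diff_b
  pooled <- rbind(as.data.frame(keep_a), as.data.frame(keep_b))
  if (nrow(pooled) == 0) return(peak_set(label = "overlapping"))
  merge_union(as_peak_set(pooled, label = "overlapping"),
              merge_bookended = merge_bookended)
}

#' Fraction of the genome covered by a peak set
#'
#' @param ps a \code{peak_set}; merged internally so overlapping intervals
#'   are not double-counted.
#' @param genome_size total genome length in bp (> 0).
#' @return Fraction in [0,1].
#' @export
genome_coverage <- function(ps, genome_size) {
  if (!is.numeric(genome_size) || length(genome_size) != 1 ||
      genome_size <= 0)
    stop("genome_size must be a single positive number")
  if (nrow(ps) == 0) return(0)
  m <- merge_union(ps)
  sum(as.numeric(m$end - m$start)) / genome_size
}

#' Flag query peaks present in a reference set
#'
#' Under fraction mode a query is present when the fraction of its own
#' length covered by the reference meets \code{min_fraction}; under
#' any-overlap mode when it shares at least \code{min_bp} bases with the
#' reference union.
#'
#' @param peaks query \code{peak_set}.
#' @param reference reference \code{peak_set}.
#' @param criterion an \code{\link{overlap_criterion}}.
#' @return Logical vector, one flag per query peak.
#' @export
present_in <- function(peaks, reference, criterion = overlap_criterion()) {
  if (nrow(peaks) == 0) return(logical(0))
  frac <- overlap_fraction(peaks, reference)
  if (criterion$mode == "fraction") {
    frac >= criterion$min_fraction
  } else {
    covered_bp <- frac * (peaks$end - peaks$start)
    covered_bp >= criterion$min_bp - 1e-9
  }
}
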
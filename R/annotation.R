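# Peak-to-gene annotation: each peak is classified against its closest
# gene into one of five location categories, evaluated strand-aware in
# gene-oriented coordinates. "5' end of the peak" / "3' end of the peak"
# mean the peak boundary nearer the gene's 5' / 3' side: for a + strand
# gene the peak's 3' end is its rightmost base, for a - strand gene its
# leftmost base. The categories, with d the gap in bp to the 5' end of
# the first exon (or from the 3' end of the last exon):
#   Promoter        peak 3' end within 1 kb upstream of the gene 5' end
#                   (1 <= d <= 1000)
#   WithinGeneBody  peak 5' end inside the gene span (intron or exon
#                   subcategory by the 5' base)
#   Upstream        peak 3' end 1-10 kb upstream (1000 < d <= 10000)
#   Downstream      peak 5' end within 10 kb downstream of, and not
#                   overlapping, the gene 3' end (1 <= d <= 10000)
#   Distal          no portion of the peak within 10 kb of a gene
# Precedence when several rules match: Promoter > WithinGeneBody >
# Upstream > Downstream > Distal. A peak that engulfs its gene matches
# no boundary rule and is assigned WithinGeneBody.

#' Classify one peak's location relative to one gene
#'
#' @param peak single-row \code{peak_set} (or list with scaffold, start,
#'   end).
#' @param gene single gene row (\code{gene_id}, \code{scaffold},
#'   \code{start}, \code{end}, \code{strand}).
#' @param exons exon table for that gene (\code{gene_id}, \code{start},
#'   \code{end}).
#' @param window_bp the proximity window (default 10 kb).
#' @param promoter_bp the promoter window (default 1 kb).
#' @return list with \code{category} in \{Promoter, WithinGeneBody,
#'   Upstream, Downstream, Distal\} and \code{subcategory} in \{exon,
#'   intron, none\}.
#' @export
classify_peak_location <- function(peak, gene, exons,
                                   window_bp = 10000L,
                                   promoter_bp = 1000L) {
  if (peak$scaffold != gene$scaffold)
    return(list(category = "Distal", subcategory = "none"))
  p_left <- peak$start          # leftmost base
  p_right <- peak$end - 1L      # rightmost base
  g_left <- gene$start
  g_right <- gene$end - 1L
  plus <- gene$strand == "+"

  # gene-oriented peak ends (genomic coordinate of that base)
  peak5 <- if (plus) p_left else p_right
  peak3 <- if (plus) p_right else p_left
  gene5 <- if (plus) g_left else g_right
  gene3 <- if (plus) g_right else g_left

  # upstream gap from peak 3' end to gene 5' end, in gene orientation
  d_up <- if (plus) gene5 - peak3 else peak3 - gene5
  # downstream gap from gene 3' end to peak 5' end
  d_down <- if (plus) peak5 - gene3 else gene3 - peak5
  in_body <- peak5 >= g_left && peak5 <= g_right
  overlaps <- p_left <= g_right && g_left <= p_right
  gap <- max(0L, g_left - p_right, p_left - g_right)

  subcat_at <- function(pos) {
    ex <- exons[exons$gene_id == gene$gene_id, , drop = FALSE]
    if (any(pos >= ex$start & pos < ex$end)) "exon" else "intron"
  }

  if (d_up >= 1 && d_up <= promoter_bp)
    return(list(category = "Promoter", subcategory = "none"))
  if (in_body)
    return(list(category = "WithinGeneBody",
                subcategory = subcat_at(peak5)))
  if (d_up > promoter_bp && d_up <= window_bp)
    return(list(category = "Upstream", subcategory = "none"))
  if (!overlaps && d_down >= 1 && d_down <= window_bp)
    return(list(category = "Downstream", subcategory = "none"))
  if (overlaps)  # peak engulfs the gene: no boundary rule fires
    return(list(category = "WithinGeneBody",
                subcategory = subcat_at(if (plus) g_left else g_right)))
  if (gap <= window_bp && gap >= 1) {
    # near end is the peak's gene-oriented far end for that side; the
    # boundary rules above cover all such cases, so this is unreachable
    # for well-formed intervals, but kept as a safe fallback
    return(list(category = if ((plus && p_right < g_left) ||
                               (!plus && p_left > g_right))
                  "Upstream" else "Downstream",
                subcategory = "none"))
  }
  list(category = "Distal", subcategory = "none")
}

#' Nearest gene per peak
#'
#' Minimal bp gap between the peak interval and each gene span (0 when
#' they overlap); ties broken by lexicographically smaller gene id.
#'
#' @param peaks \code{peak_set}.
#' @param genes gene table (nonempty).
#' @return data.frame with \code{peak_id}, \code{nearest_gene},
#'   \code{distance_bp} (NA/Inf-free: peaks with no gene on their
#'   scaffold get NA gene and Inf distance).
#' @export
nearest_gene <- function(peaks, genes) {
  if (nrow(genes) == 0) stop("nearest_gene: empty gene set")
  out <- data.frame(peak_id = peaks$id,
                    nearest_gene = NA_character_,
                    distance_bp = Inf, stringsAsFactors = FALSE)
  genes <- genes[order(genes$gene_id), , drop = FALSE]
  for (i in seq_len(nrow(peaks))) {
    g <- genes[genes$scaffold == peaks$scaffold[i], , drop = FALSE]
    if (nrow(g) == 0) next
    gap <- pmax(0L, g$start - peaks$end[i] + 1L,
                peaks$start[i] - g$end + 1L)
    best <- which.min(gap)  # first minimum = smallest gene_id (sorted)
    out$nearest_gene[i] <- g$gene_id[best]
    out$distance_bp[i] <- gap[best]
  }
  out
}

#' Genes within a window of a peak
#'
#' All genes whose span lies within \code{window_bp} of the peak; the
#' boundary is inclusive (a gap of exactly \code{window_bp} counts) and
#' overlap counts as distance 0.
#'
#' @param peak single-row \code{peak_set}.
#' @param genes gene table.
#' @param window_bp window in bp (default 10 kb).
#' @return Character vector of gene ids.
#' @export
genes_within_window <- function(peak, genes, window_bp = 10000L) {
  g <- genes[genes$scaffold == peak$scaffold, , drop = FALSE]
  if (nrow(g) == 0) return(character(0))
  gap <- pmax(0L, g$start - peak$end + 1L, peak$start - g$end + 1L)
  g$gene_id[gap <= window_bp]
}

#' Annotate a peak set against gene models
#'
#' For each peak: the nearest gene, the gap to it, the location category
#' against that gene, and the set of genes within the window.
#'
#' @param peaks \code{peak_set}.
#' @param genes gene table.
#' @param exons exon table.
#' @param window_bp proximity window (default 10 kb).
#' @return data.frame with one row per peak: \code{peak_id},
#'   \code{scaffold}, \code{start}, \code{end}, \code{nearest_gene},
#'   \code{distance_bp}, \code{category}, \code{subcategory},
#'   \code{genes_within_window} (list column).
#' @export
annotate_peaks <- function(peaks, genes, exons, window_bp = 10000L) {
  ng <- nearest_gene(peaks, genes)
  cats <- character(nrow(peaks))
  subs <- character(nrow(peaks))
  near <- vector("list", nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    pk <- peaks[i, ]
    near[[i]] <- genes_within_window(pk, genes, window_bp)
    if (is.na(ng$nearest_gene[i])) {
      cats[i] <- "Distal"
      subs[i] <- "none"
    } else {
      g <- genes[genes$gene_id == ng$nearest_gene[i], ]
      cl <- classify_peak_location(pk, g, exons, window_bp = window_bp)
      cats[i] <- cl$category
      subs[i] <- cl$subcategory
    }
  }
  out <- data.frame(peak_id = peaks$id, scaffold = peaks$scaffold,
                    start = peaks$start, end = peaks$end,
                    nearest_gene = ng$nearest_gene,
                    distance_bp = ng$distance_bp,
                    category = cats, subcategory = subs,
                    stringsAsFactors = FALSE)
  out$genes_within_window <- near
  out
}

#' Location-category distribution of a peak set
#'
#' @param annotations output of \code{\link{annotate_peaks}} (or any
#'   data.frame with a \code{category} column).
#' @return data.frame with \code{category}, \code{n} and
#'   \code{fraction} (fractions sum to 1 over annotated peaks).
#' @export
location_distribution <- function(annotations) {
  levs <- c("Promoter", "WithinGeneBody", "Upstream", "Downstream",
            "Distal")
  n <- vapply(levs, function(l) sum(annotations$category == l), 0L)
  data.frame(category = levs, n = as.integer(n),
             fraction = as.numeric(n) / sum(n),
             stringsAsFactors = FALSE)
}
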
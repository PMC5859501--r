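# Fisher-exact enrichment machinery: proximity of differential peaks to
# DE genes, functional-category enrichment with BH adjustment, temporal
# expression clusters, FPKM expression classes, and per-class
# enrichment. Fold enrichment is reported as the ratio of proportions
# (a/(a+b)) / (c/(c+d)), not the odds ratio; tests are two-sided so both
# enrichment and depletion are detected.

#' Fisher exact enrichment for a 2x2 table
#'
#' Rows: differential / non-differential (or subset / remainder);
#' columns: with-property / without. Two-sided exact p, ratio-of-
#' proportions fold enrichment, and a direction flag. A zero margin
#' leaves the result undefined (NA p, NA fold).
#'
#' @param a,b,c,d the table cells: a = differential with property,
#'   b = differential without, c = non-differential with,
#'   d = non-differential without.
#' @param property_name optional label carried into the result.
#' @return data.frame (one row): \code{property}, \code{a..d},
#'   \code{p_value}, \code{fold_enrichment}, \code{direction}.
#' @export
fisher_enrichment <- function(a, b, c, d, property_name = NA_character_) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("fisher_enrichment: cells must be non-negative integers")
  if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0) {
    return(data.frame(property = property_name, a = a, b = b, c = c,
                      d = d, p_value = NA_real_,
                      fold_enrichment = NA_real_,
                      direction = NA_character_,
                      stringsAsFactors = FALSE))
  }
  p <- stats::fisher.test(matrix(c(a, b, c, d), 2, byrow = TRUE))$p.value
  fold <- (a / (a + b)) / (c / (c + d))
  data.frame(property = property_name, a = a, b = b, c = c, d = d,
             p_value = p, fold_enrichment = fold,
             direction = if (fold >= 1) "enriched" else "depleted",
             stringsAsFactors = FALSE)
}

#' Proximity-to-DE-gene enrichment of differential peaks
#'
#' Tests whether differential peaks are more likely than
#' non-differential peaks to lie within \code{window_bp} of a DE gene.
#'
#' @param annotations output of \code{\link{annotate_peaks}} for all
#'   peaks (must carry \code{genes_within_window}).
#' @param diff_peak_ids ids of differential peaks (subset of
#'   \code{annotations$peak_id}, nonempty and proper).
#' @param de_gene_ids DE gene ids.
#' @return \code{\link{fisher_enrichment}} row, plus attributes
#'   \code{n_diff_near_de} and \code{n_diff}.
#' @export
proximity_enrichment <- function(annotations, diff_peak_ids,
                                 de_gene_ids) {
  if (length(diff_peak_ids) == 0)
    stop("proximity_enrichment: empty differential peak set")
  is_diff <- annotations$peak_id %in% diff_peak_ids
  near_de <- vapply(annotations$genes_within_window, function(g)
    any(g %in% de_gene_ids), logical(1))
  a <- sum(is_diff & near_de)
  b <- sum(is_diff & !near_de)
  c_ <- sum(!is_diff & near_de)
  d <- sum(!is_diff & !near_de)
  if ((c_ + d) == 0)
    stop("proximity_enrichment: degenerate table (all peaks differential)")
  res <- fisher_enrichment(a, b, c_, d, "within_window_of_DE_gene")
  attr(res, "n_diff_near_de") <- a
  attr(res, "n_diff") <- a + b
  res
}

#' Functional-category enrichment with BH adjustment
#'
#' Per category: a 2x2 Fisher test of category membership among genes
#' near differential peaks vs genes near non-differential peaks. Genes
#' assigned to multiple categories are counted once per category.
#'
#' @param genes_near_diff,genes_near_nondiff character vectors of gene
#'   ids.
#' @param category_map data.frame (\code{gene_id}, \code{category});
#'   genes may appear in several categories.
#' @return data.frame of \code{\link{fisher_enrichment}} rows with an
#'   \code{adjusted_p} column (Benjamini-Hochberg), sorted by p.
#' @export
category_enrichment <- function(genes_near_diff, genes_near_nondiff,
                                category_map) {
  cats <- sort(unique(category_map$category))
  if (length(cats) == 0) stop("category_enrichment: empty category map")
  rows <- lapply(cats, function(cc) {
    members <- category_map$gene_id[category_map$category == cc]
    a <- sum(genes_near_diff %in% members)
    b <- length(genes_near_diff) - a
    c_ <- sum(genes_near_nondiff %in% members)
    d <- length(genes_near_nondiff) - c_
    fisher_enrichment(a, b, c_, d, cc)
  })
  out <- do.call(rbind, rows)
  out$adjusted_p <- stats::p.adjust(out$p_value, method = "BH")
  out[order(out$p_value), , drop = FALSE]
}

#' Assign a temporal expression cluster by peak time
#'
#' Clusters are defined by the time of maximal expression: cluster 1 for
#' an argmax in [0,10] hpf, cluster 4 in [18,24), cluster 3 in [24,40),
#' cluster 2 in [40,72]. An argmax in the uncovered (10,18) interval is
#' left unassigned (NA). Ties take the earliest time.
#'
#' @param timecourse numeric vector of expression values.
#' @param times numeric vector of hpf timepoints (same length).
#' @return Integer cluster 1-4 or NA.
#' @export
assign_temporal_cluster <- function(timecourse, times) {
  stopifnot(length(timecourse) == length(times),
            length(timecourse) > 0)
  o <- order(times)
  times <- times[o]
  timecourse <- timecourse[o]
  t_max <- times[which.max(timecourse)]  # first max = earliest tie
  if (t_max <= 10) 1L
  else if (t_max < 18) NA_integer_
  else if (t_max < 24) 4L
  else if (t_max < 40) 3L
  else if (t_max <= 72) 2L
  else NA_integer_
}

#' Assign an expression class from FPKM
#'
#' Half-open FPKM bins: [100, Inf) high, [40, 100) medium, [15, 40) low,
#' [0, 15) very_low.
#'
#' @param fpkm non-negative FPKM value(s).
#' @return Character vector of classes.
#' @export
assign_expression_class <- function(fpkm) {
  if (any(fpkm < 0)) stop("assign_expression_class: negative FPKM")
  cut(fpkm, breaks = c(0, 15, 40, 100, Inf), right = FALSE,
      labels = c("very_low", "low", "medium", "high")) |>
    as.character()
}

#' Per-class enrichment of a gene subset against its universe
#'
#' For each label level: Fisher test of the label among the subset
#' versus the remainder of the universe.
#'
#' @param subset_genes gene ids of the subset (nonempty, drawn from the
#'   universe).
#' @param universe_genes all gene ids.
#' @param labels per-universe-gene label vector (same order as
#'   \code{universe_genes}); NA labels are dropped.
#' @return data.frame of \code{\link{fisher_enrichment}} rows, one per
#'   label level.
#' @export
class_enrichment <- function(subset_genes, universe_genes, labels) {
  if (length(subset_genes) == 0)
    stop("class_enrichment: empty subset")
  stopifnot(length(universe_genes) == length(labels))
  keep <- !is.na(labels)
  universe_genes <- universe_genes[keep]
  labels <- as.character(labels[keep])
  in_sub <- universe_genes %in% subset_genes
  rows <- lapply(sort(unique(labels)), function(l) {
    a <- sum(in_sub & labels == l)
    b <- sum(in_sub & labels != l)
    c_ <- sum(!in_sub & labels == l)
    d <- sum(!in_sub & labels != l)
    fisher_enrichment(a, b, c_, d, l)
  })
  do.call(rbind, rows)
}
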
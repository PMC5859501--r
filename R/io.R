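# Readers and writers for the plain-text formats the pipeline exchanges:
# BED (0-based half-open), chrom-sizes TSV, GFF3 gene models (1-based
# closed, converted on read), FASTA, count-matrix TSV, MEME minimal motif
# format, and JSON. All writers round-trip through the matching readers.

#' Write a peak set as BED
#'
#' Writes BED4 (scaffold, start, end, id), tab-delimited, 0-based
#' half-open coordinates.
#' @param ps a \code{peak_set}.
#' @param path output file.
#' @export
write_bed <- function(ps, path) {
  df <- as.data.frame(ps)[, c("scaffold", "start", "end", "id")]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file as a peak set
#'
#' Accepts BED3 or more columns; column 4 (when present) becomes the
#' interval id. Malformed lines (start >= end, non-numeric coordinates)
#' raise an error naming the line.
#' @param path BED file.
#' @param label optional sample/assay label.
#' @return A \code{peak_set}.
#' @export
read_bed <- function(path, label = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                 !startsWith(lines, "track")]
  if (length(lines) == 0) return(peak_set(label = label))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- lengths(fields)
  if (any(ncol < 3))
    stop(sprintf("%s: line %d has fewer than 3 BED fields", path,
                 which(ncol < 3)[1]))
  scaf <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end) | start >= end | start < 0)
  if (length(bad) > 0)
    stop(sprintf("%s: line %d is not a valid BED interval", path, bad[1]))
  id <- if (all(ncol >= 4)) vapply(fields, `[[`, "", 4L) else NULL
  peak_set(scaf, start, end, id = id, label = label)
}

#' Write a chrom-sizes table
#' @param sizes data.frame with columns \code{scaffold}, \code{length}.
#' @param path output TSV.
#' @export
write_chrom_sizes <- function(sizes, path) {
  utils::write.table(sizes[, c("scaffold", "length")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a chrom-sizes table
#' @param path TSV with scaffold name and length per line.
#' @return data.frame with columns \code{scaffold}, \code{length}.
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  names(df) <- c("scaffold", "length")[seq_len(ncol(df))]
  df[, c("scaffold", "length")]
}

#' Write gene models as GFF3
#'
#' Emits one \code{gene} feature per gene plus one \code{exon} feature
#' per exon, converting internal 0-based half-open coordinates to GFF3
#' 1-based closed.
#' @param genes gene table (\code{gene_id}, \code{scaffold},
#'   \code{start}, \code{end}, \code{strand}).
#' @param exons exon table (\code{gene_id}, \code{scaffold},
#'   \code{start}, \code{end}).
#' @param path output GFF3 file.
#' @export
write_gff3_genes <- function(genes, exons, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    writeLines(sprintf("%s\tcrmpeaks\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       g$scaffold, g$start + 1L, g$end, g$strand,
                       g$gene_id), con)
    ex <- exons[exons$gene_id == g$gene_id, , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    for (j in seq_len(nrow(ex))) {
      writeLines(sprintf(
        "%s\tcrmpeaks\texon\t%d\t%d\t.\t%s\t.\tID=%s.exon%d;Parent=%s",
        ex$scaffold[j], ex$start[j] + 1L, ex$end[j], g$strand,
        g$gene_id, j, g$gene_id), con)
    }
  }
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Reads \code{gene} and \code{exon} features via rtracklayer and
#' converts to internal 0-based half-open coordinates. Exons are grouped
#' to genes by their \code{Parent} attribute.
#' @param path GFF3 file.
#' @return list with elements \code{genes} and \code{exons}.
#' @export
read_gff3_genes <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gdf <- as.data.frame(gr)
  genes <- gdf[gdf$type == "gene", , drop = FALSE]
  exons <- gdf[gdf$type == "exon", , drop = FALSE]
  parent <- vapply(exons$Parent, function(p) as.character(p)[1], "")
  list(
    genes = data.frame(
      gene_id = as.character(genes$ID),
      scaffold = as.character(genes$seqnames),
      start = genes$start - 1L, end = genes$end,
      strand = as.character(genes$strand), stringsAsFactors = FALSE),
    exons = data.frame(
      gene_id = parent,
      scaffold = as.character(exons$seqnames),
      start = exons$start - 1L, end = exons$end,
      stringsAsFactors = FALSE))
}

#' Write a count matrix with sample metadata
#'
#' Counts go to \code{path} as a TSV with peak ids in the first column
#' and one column per sample; sample metadata go to \code{sample_path}.
#' @param counts integer matrix, peaks x samples, with dimnames.
#' @param samples sample sheet (\code{sample_id}, \code{assay},
#'   \code{condition}, \code{replicate}).
#' @param path counts TSV path.
#' @param sample_path sample sheet TSV path.
#' @export
write_counts_tsv <- function(counts, samples, path, sample_path) {
  df <- data.frame(peak_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(samples, sample_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a count matrix and sample sheet
#' @param path counts TSV (first column peak_id).
#' @param sample_path sample sheet TSV.
#' @return list with \code{counts} (integer matrix) and \code{samples}.
#' @export
read_counts_tsv <- function(path, sample_path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  counts <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(counts) <- "integer"
  rownames(counts) <- df[[1]]
  samples <- utils::read.table(sample_path, sep = "\t", header = TRUE,
                               stringsAsFactors = FALSE)
  list(counts = counts, samples = samples)
}

#' Write sequences as FASTA
#' @param seqs named character vector or \code{DNAStringSet}.
#' @param path output FASTA.
#' @export
write_fasta <- function(seqs, path) {
  if (!methods::is(seqs, "DNAStringSet"))
    seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read a FASTA file
#' @param path FASTA file.
#' @return A \code{DNAStringSet}.
#' @export
read_fasta <- function(path) Biostrings::readDNAStringSet(path)

#' Write PWMs in MEME minimal motif format
#' @param pwms list of \code{\link{pwm}} objects.
#' @param path output file.
#' @export
write_meme <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  bg <- pwms[[1]]$background
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "",
               "Background letter frequencies",
               sprintf("A %.5f C %.5f G %.5f T %.5f",
                       bg[1], bg[2], bg[3], bg[4]), ""), con)
  for (p in pwms) {
    w <- ncol(p$matrix)
    writeLines(sprintf("MOTIF %s", p$motif_id), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0", w),
      con)
    for (j in seq_len(w))
      writeLines(sprintf("%.6f %.6f %.6f %.6f", p$matrix[1, j],
                         p$matrix[2, j], p$matrix[3, j], p$matrix[4, j]),
                 con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read PWMs from a MEME minimal motif file
#' @param path MEME motif file.
#' @param pseudocount pseudocount attached to each returned PWM.
#' @return list of \code{\link{pwm}} objects.
#' @export
read_meme <- function(path, pseudocount = 0.01) {
  lines <- readLines(path)
  bg <- c(0.25, 0.25, 0.25, 0.25)
  bg_idx <- grep("^Background letter frequencies", lines)
  if (length(bg_idx) > 0 && bg_idx[1] < length(lines)) {
    tok <- strsplit(trimws(lines[bg_idx[1] + 1]), "\\s+")[[1]]
    bg <- as.numeric(tok[c(2, 4, 6, 8)])
  }
  motif_idx <- grep("^MOTIF", lines)
  pwms <- list()
  for (mi in motif_idx) {
    id <- strsplit(trimws(lines[mi]), "\\s+")[[1]][2]
    hdr <- mi + which(grepl("^letter-probability matrix",
                            lines[(mi + 1):length(lines)]))[1]
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[hdr]))
    rows <- lines[(hdr + 1):(hdr + w)]
    mat <- t(vapply(rows, function(r)
      as.numeric(strsplit(trimws(r), "\\s+")[[1]][1:4]), numeric(4)))
    pwms[[id]] <- pwm(id, t(mat), background = bg,
                      pseudocount = pseudocount)
  }
  pwms
}

#' Write an R list as JSON
#' @param x list.
#' @param path output JSON file.
#' @export
write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a JSON file as an R list
#' @param path JSON file.
#' @export
read_json_file <- function(path) jsonlite::read_json(path,
                                                     simplifyVector = TRUE)
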
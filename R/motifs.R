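# PWM scanning with exact score-distribution p-values (dynamic
# programming over the discretized log-odds score under the background
# model) and the two-step shuffled-control enrichment test: a motif is
# called enriched in differential peaks when it is enriched against a
# shuffled control of the differential sequences but not against a
# shuffled control of the non-differential sequences.

.BASES <- c("A", "C", "G", "T")

#' Position weight matrix
#'
#' @param motif_id motif name (e.g. Ets1, Alx1).
#' @param matrix 4 x w matrix of base probabilities, rows A, C, G, T;
#'   each column must sum to 1.
#' @param background base frequencies (A, C, G, T), summing to 1.
#' @param pseudocount positive pseudocount mixed into the matrix
#'   (proportionally to the background) before taking log-odds.
#' @return list of class \code{pwm}.
#' @export
pwm <- function(motif_id, matrix, background = rep(0.25, 4),
                pseudocount = 0.01) {
  if (nrow(matrix) != 4) stop("pwm: matrix must have 4 rows (A,C,G,T)")
  if (any(abs(colSums(matrix) - 1) > 1e-6))
    stop("pwm: each matrix column must sum to 1")
  if (abs(sum(background) - 1) > 1e-6)
    stop("pwm: background must sum to 1")
  if (pseudocount <= 0) stop("pwm: pseudocount must be > 0")
  rownames(matrix) <- .BASES
  structure(list(motif_id = motif_id, matrix = matrix,
                 background = background, pseudocount = pseudocount),
            class = "pwm")
}

#' Consensus string of a PWM (highest-probability base per column)
#' @param p a \code{\link{pwm}}.
#' @return Character consensus sequence.
#' @export
pwm_consensus <- function(p) {
  paste(.BASES[apply(p$matrix, 2, which.max)], collapse = "")
}

#' Motif width
#' @param p a \code{\link{pwm}}.
#' @export
pwm_width <- function(p) ncol(p$matrix)

# log-odds score matrix in bits (4 x w)
.pwm_score_matrix <- function(p) {
  pm <- sweep(p$matrix, 1, p$background * p$pseudocount, "+") /
    (1 + p$pseudocount)
  log2(pm / p$background)
}

#' Exact score distribution of a PWM under the background model
#'
#' Discretizes the log-odds scores to a grid (default 1/100 bit) and
#' convolves the per-position score distributions exactly. Returns the
#' discretized support and tail probabilities.
#'
#' @param p a \code{\link{pwm}}.
#' @param step score discretization step in bits (default 0.01).
#' @return list with \code{scores} (bits, ascending), \code{prob}
#'   (point probabilities) and \code{pval} (P(score >= s), same order).
#' @export
pwm_score_distribution <- function(p, step = 0.01) {
  S <- round(.pwm_score_matrix(p) / step)
  w <- ncol(S)
  lo <- sum(apply(S, 2, min))
  hi <- sum(apply(S, 2, max))
  dist <- numeric(hi - lo + 1)  # index = score - lo + 1
  # start: distribution of column 1
  off1 <- sum(apply(S[, -1, drop = FALSE], 2, min))
  dist_cur <- numeric(max(S[, 1]) - min(S[, 1]) + 1)
  base_lo <- min(S[, 1])
  for (b in 1:4)
    dist_cur[S[b, 1] - base_lo + 1] <-
      dist_cur[S[b, 1] - base_lo + 1] + p$background[b]
  for (k in seq_len(w)[-1]) {
    col <- S[, k]
    new_lo <- base_lo + min(col)
    new_hi <- base_lo + length(dist_cur) - 1 + max(col)
    nd <- numeric(new_hi - new_lo + 1)
    for (b in 1:4) {
      shift <- base_lo + col[b] - new_lo
      idx <- seq_along(dist_cur) + shift
      nd[idx] <- nd[idx] + dist_cur * p$background[b]
    }
    dist_cur <- nd
    base_lo <- new_lo
  }
  scores <- (base_lo + seq_along(dist_cur) - 1) * step
  pv <- rev(cumsum(rev(dist_cur)))
  list(scores = scores, prob = dist_cur, pval = pv, step = step)
}

#' Exact p-value of a PWM score
#'
#' P(score >= s) for a random background word, from the exact
#' discretized score distribution.
#'
#' @param p a \code{\link{pwm}}.
#' @param score score(s) in bits.
#' @param dist optional precomputed \code{\link{pwm_score_distribution}}.
#' @return Numeric p-value(s) in (0,1].
#' @export
pwm_pvalue <- function(p, score, dist = pwm_score_distribution(p)) {
  idx <- findInterval(score - 1e-9, dist$scores) + 1L
  idx <- pmin(pmax(idx, 1L), length(dist$pval))
  out <- dist$pval[idx]
  # scores above the maximum achievable have probability 0 -> report
  # the smallest atom instead of 0 (p_value in (0,1])
  out[score > max(dist$scores) + 1e-9] <- min(dist$prob[dist$prob > 0])
  out
}

# reverse-complement score matrix: S'[b,k] = S[comp(b), w-k+1]
.revcomp_score_matrix <- function(S) {
  S[4:1, rev(seq_len(ncol(S))), drop = FALSE]
}

.encode_seq <- function(sequence) {
  x <- strsplit(toupper(sequence), "")[[1]]
  m <- match(x, .BASES)  # N and others become NA
  m
}

# score every window of an encoded sequence against a score matrix;
# windows containing NA (N bases) score NA
.window_scores <- function(enc, S) {
  w <- ncol(S)
  n_win <- length(enc) - w + 1L
  if (n_win < 1) return(numeric(0))
  sc <- numeric(n_win)
  for (k in seq_len(w)) {
    col <- S[, k]
    sc <- sc + col[enc[k:(k + n_win - 1L)]]
  }
  sc
}

#' Scan a sequence with a PWM
#'
#' Log-odds scores at every offset on both strands; a hit is any window
#' whose exact background p-value is at or below the threshold. Windows
#' containing N are skipped. Minus-strand hits are reported at their
#' forward-strand offset.
#'
#' @param p a \code{\link{pwm}}.
#' @param sequence character sequence over A,C,G,T,N.
#' @param p_threshold hit p-value threshold (default 1e-4).
#' @param dist optional precomputed score distribution.
#' @return data.frame of hits: \code{offset} (0-based), \code{strand},
#'   \code{score} (bits), \code{p_value}; zero rows when the sequence is
#'   shorter than the motif or has no hit.
#' @export
scan_sequence <- function(p, sequence, p_threshold = 1e-4,
                          dist = pwm_score_distribution(p)) {
  S <- round(.pwm_score_matrix(p) / dist$step) * dist$step
  enc <- .encode_seq(sequence)
  empty <- data.frame(offset = integer(0), strand = character(0),
                      score = numeric(0), p_value = numeric(0),
                      stringsAsFactors = FALSE)
  if (length(enc) < ncol(S)) return(empty)
  # smallest score whose tail p-value meets the threshold
  ok <- dist$pval <= p_threshold
  if (!any(ok)) return(empty)
  score_min <- dist$scores[which(ok)[1]]
  rows <- list()
  for (strand in c("+", "-")) {
    Sm <- if (strand == "+") S else .revcomp_score_matrix(S)
    sc <- .window_scores(enc, Sm)
    hit <- which(!is.na(sc) & sc >= score_min - 1e-9)
    if (length(hit) > 0)
      rows[[strand]] <- data.frame(
        offset = hit - 1L, strand = strand, score = sc[hit],
        p_value = pwm_pvalue(p, sc[hit], dist),
        stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$offset, out$strand), , drop = FALSE]
}

# does the sequence contain at least one hit? (cheap path for AME)
.has_hit <- function(p, enc, score_min, S, Src) {
  w <- ncol(S)
  if (length(enc) < w) return(FALSE)
  sc <- .window_scores(enc, S)
  if (any(!is.na(sc) & sc >= score_min - 1e-9)) return(TRUE)
  sc <- .window_scores(enc, Src)
  any(!is.na(sc) & sc >= score_min - 1e-9)
}

# Altschul-Erickson dinucleotide-preserving shuffle of one sequence
.dinuc_shuffle_one <- function(s) {
  x <- strsplit(s, "")[[1]]
  n <- length(x)
  if (n < 3) return(s)
  verts <- unique(x)
  last <- x[n]
  edges <- lapply(stats::setNames(verts, verts), function(v)
    x[which(x[-n] == v) + 1L])
  for (tries in 1:1000) {
    # choose a random last edge for every vertex except the final one
    last_edge <- vapply(verts, function(v) {
      if (v == last || length(edges[[v]]) == 0) return(NA_character_)
      sample(edges[[v]], 1)
    }, "")
    # the last-edge graph must connect every vertex to `last`
    ok <- TRUE
    for (v in setdiff(verts, last)) {
      seen <- character(0)
      cur <- v
      while (!is.na(cur) && cur != last && !(cur %in% seen)) {
        seen <- c(seen, cur)
        cur <- last_edge[[cur]]
      }
      if (is.na(cur) || cur != last) { ok <- FALSE; break }
    }
    if (ok) break
  }
  if (!ok) return(paste(sample(x), collapse = ""))  # degenerate input
  out_edges <- lapply(stats::setNames(verts, verts), function(v) {
    e <- edges[[v]]
    if (v == last) return(sample(e))
    le <- last_edge[[v]]
    drop1 <- match(le, e)
    rest <- e[-drop1]
    c(if (length(rest) > 0) sample(rest) else character(0), le)
  })
  res <- character(n)
  res[1] <- x[1]
  ptr <- lapply(out_edges, function(e) 1L)
  cur <- x[1]
  for (i in 2:n) {
    nxt <- out_edges[[cur]][ptr[[cur]]]
    ptr[[cur]] <- ptr[[cur]] + 1L
    res[i] <- nxt
    cur <- nxt
  }
  paste(res, collapse = "")
}

#' Shuffle sequences to build an enrichment control
#'
#' Default is a per-sequence mononucleotide shuffle, preserving each
#' sequence's length and base composition exactly;
#' \code{method = "dinucleotide"} preserves dinucleotide composition
#' (Altschul-Erickson Euler-path shuffle). Seeded and reproducible.
#'
#' @param sequences character vector of sequences.
#' @param seed integer seed.
#' @param method \code{"mononucleotide"} (default) or
#'   \code{"dinucleotide"}.
#' @return Character vector of shuffled sequences (names preserved).
#' @export
shuffle_control <- function(sequences, seed = 1L,
                            method = c("mononucleotide",
                                       "dinucleotide")) {
  method <- match.arg(method)
  set.seed(seed)
  out <- vapply(sequences, function(s) {
    if (method == "mononucleotide")
      paste(sample(strsplit(s, "")[[1]]), collapse = "")
    else
      .dinuc_shuffle_one(s)
  }, "")
  names(out) <- names(sequences)
  out
}

#' Two-step motif enrichment against shuffled controls
#'
#' For each motif: (i) Fisher exact test (one-sided, greater) of the
#' number of differential sequences with at least one hit versus their
#' shuffled control; (ii) the same for non-differential sequences. The
#' motif is called enriched in differential peaks iff (i) is significant
#' at \code{alpha} and (ii) is not.
#'
#' @param diff_seqs,nondiff_seqs character vectors of peak sequences
#'   (both nonempty).
#' @param pwms list of \code{\link{pwm}} objects.
#' @param alpha significance level (default 0.05).
#' @param seed seed for the shuffles.
#' @param p_threshold per-window hit threshold (default 1e-4).
#' @param shuffle_method passed to \code{\link{shuffle_control}}.
#' @return data.frame per motif: \code{motif_id},
#'   \code{n_diff_hit}, \code{n_diff_shuf_hit}, \code{n_nondiff_hit},
#'   \code{n_nondiff_shuf_hit}, \code{p_diff_vs_shuffled},
#'   \code{p_nondiff_vs_shuffled}, \code{enriched_in_differential}.
#' @export
ame_two_step <- function(diff_seqs, nondiff_seqs, pwms, alpha = 0.05,
                         seed = 1L, p_threshold = 1e-4,
                         shuffle_method = "mononucleotide") {
  if (length(diff_seqs) == 0 || length(nondiff_seqs) == 0)
    stop("ame_two_step: both sequence sets must be nonempty")
  if (length(pwms) == 0)
    return(data.frame(motif_id = character(0)))
  shuf_diff <- shuffle_control(diff_seqs, seed = seed,
                               method = shuffle_method)
  shuf_nondiff <- shuffle_control(nondiff_seqs, seed = seed + 1L,
                                  method = shuffle_method)
  enc <- function(v) lapply(v, .encode_seq)
  e_diff <- enc(diff_seqs); e_sd <- enc(shuf_diff)
  e_non <- enc(nondiff_seqs); e_sn <- enc(shuf_nondiff)

  one_motif <- function(p) {
    dist <- pwm_score_distribution(p)
    ok <- dist$pval <= p_threshold
    S <- round(.pwm_score_matrix(p) / dist$step) * dist$step
    Src <- .revcomp_score_matrix(S)
    if (!any(ok)) {
      counts <- c(0L, 0L, 0L, 0L)
    } else {
      smin <- dist$scores[which(ok)[1]]
      counts <- vapply(list(e_diff, e_sd, e_non, e_sn), function(es)
        sum(vapply(es, function(e) .has_hit(p, e, smin, S, Src),
                   logical(1))), 0L)
    }
    test <- function(hits, n, hits0, n0) {
      stats::fisher.test(matrix(c(hits, n - hits, hits0, n0 - hits0),
                                2, byrow = TRUE),
                         alternative = "greater")$p.value
    }
    p1 <- test(counts[1], length(diff_seqs), counts[2],
               length(diff_seqs))
    p2 <- test(counts[3], length(nondiff_seqs), counts[4],
               length(nondiff_seqs))
    data.frame(motif_id = p$motif_id, n_diff_hit = counts[1],
               n_diff_shuf_hit = counts[2], n_nondiff_hit = counts[3],
               n_nondiff_shuf_hit = counts[4],
               p_diff_vs_shuffled = p1, p_nondiff_vs_shuffled = p2,
               enriched_in_differential = p1 < alpha && p2 >= alpha,
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(pwms, one_motif))
  rownames(out) <- NULL
  out
}

# consensus -> near-deterministic PWM
.consensus_pwm <- function(id, consensus, p_major = 0.91) {
  b <- .encode_seq(consensus)
  m <- matrix((1 - p_major) / 3, 4, length(b))
  for (k in seq_along(b)) m[b[k], k] <- p_major
  pwm(id, m)
}

#' Built-in example PWMs
#'
#' A small panel of near-consensus PWMs named after sea urchin
#' transcription factors, used by the simulator (the Ets1-like motif is
#' planted by default) and as decoys in enrichment tests. These are
#' synthetic stand-ins constructed from published consensus cores, not
#' measured binding models.
#'
#' @return Named list of \code{\link{pwm}} objects.
#' @export
example_pwms <- function() {
  cons <- c(Ets1 = "ACAGGAAGT", Alx1 = "CTAATTAGC",
            HesC = "TCACGAGCT", Gata = "AGATAAGGC",
            Sox = "GCTTTGTTC", Otx = "CGGATTAGC", Tbr = "AAGGTGTGA")
  lapply(stats::setNames(names(cons), names(cons)), function(n)
    .consensus_pwm(n, cons[[n]]))
}
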
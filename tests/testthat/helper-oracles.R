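# Independent brute-force oracles used across the suite. All of them
# work per base on explicit logical bitmaps over a single scaffold
# domain [0, L), deliberately avoiding the package's interval code.

# random interval fixture on one scaffold
rand_intervals <- function(n, L = 2000L, max_w = 120L,
                           scaffold = "s1") {
  start <- sample.int(L - max_w, n, replace = TRUE) - 1L
  w <- sample.int(max_w, n, replace = TRUE)
  peak_set(rep(scaffold, n), start, start + w)
}

# per-base coverage bitmap of a set of intervals (single scaffold)
bm_cover <- function(ps, L) {
  bm <- logical(L)
  for (i in seq_len(nrow(ps))) {
    if (ps$end[i] > ps$start[i])
      bm[(ps$start[i] + 1):ps$end[i]] <- TRUE
  }
  bm
}

# bitmap -> minimal disjoint interval list
bm_to_intervals <- function(bm) {
  r <- rle(bm)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}

# brute-force overlap fraction of each query base-by-base
brute_overlap_fraction <- function(query, targets, L) {
  bm <- bm_cover(targets, L)
  vapply(seq_len(nrow(query)), function(i) {
    idx <- (query$start[i] + 1):query$end[i]
    mean(bm[idx])
  }, numeric(1))
}

# brute-force RPS: qualify each replicate peak against the union bitmap
# of the other replicates, pool qualifiers, return covered bitmap
brute_rps_bitmap <- function(replicates, L, min_frac = 0.75) {
  out <- logical(L)
  for (i in seq_along(replicates)) {
    others <- do.call(rbind,
                      lapply(replicates[-i], as.data.frame))
    bm <- bm_cover(as_peak_set(others), L)
    ri <- replicates[[i]]
    for (k in seq_len(nrow(ri))) {
      idx <- (ri$start[k] + 1):ri$end[k]
      if (mean(bm[idx]) >= min_frac) out[idx] <- TRUE
    }
  }
  out
}

# brute-force cross-assay merge bitmap
brute_cross_merge_bitmap <- function(a, b, L, min_frac = 0.75) {
  out <- logical(L)
  bma <- bm_cover(a, L)
  bmb <- bm_cover(b, L)
  for (k in seq_len(nrow(a))) {
    idx <- (a$start[k] + 1):a$end[k]
    if (mean(bmb[idx]) >= min_frac) out[idx] <- TRUE
  }
  for (k in seq_len(nrow(b))) {
    idx <- (b$start[k] + 1):b$end[k]
    if (mean(bma[idx]) >= min_frac) out[idx] <- TRUE
  }
  out
}

# exact two-sided Fisher p by hypergeometric enumeration
fisher_oracle_p <- function(a, b, c, d) {
  m <- a + b          # row 1 total
  n <- c + d          # row 2 total
  k <- a + c          # column 1 total
  lo <- max(0, k - n)
  hi <- min(k, m)
  probs <- vapply(lo:hi, function(x)
    exp(lchoose(m, x) + lchoose(n, k - x) - lchoose(m + n, k)),
    numeric(1))
  p_obs <- probs[a - lo + 1]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# brute-force nearest gene by all-pairs scan
brute_nearest <- function(peak, genes) {
  gap <- rep(Inf, nrow(genes))
  same <- genes$scaffold == peak$scaffold
  gap[same] <- pmax(0L, genes$start[same] - peak$end + 1L,
                    peak$start - genes$end[same] + 1L)
  best <- min(gap)
  if (!is.finite(best)) return(list(gene = NA_character_, gap = Inf))
  cands <- sort(genes$gene_id[gap == best])
  list(gene = cands[1], gap = best)
}

# independent single-peak NB ML fit by coarse-to-fine grid search
grid_nb_fit <- function(y, x, alpha, sf = rep(1, length(y))) {
  loglik <- function(b, beta) {
    mu <- sf * exp(b + beta * x)
    sum(stats::dnbinom(y, mu = mu, size = 1 / alpha, log = TRUE))
  }
  b_grid <- seq(log(mean(y) / 4 + 0.1), log(max(y) + 1), length = 120)
  beta_grid <- seq(-6, 6, length = 240)
  best <- c(b = NA, beta = NA, ll = -Inf)
  for (b in b_grid) for (be in beta_grid) {
    ll <- loglik(b, be)
    if (ll > best["ll"]) best <- c(b = b, beta = be, ll = ll)
  }
  # refine around the best cell
  b_grid2 <- seq(best["b"] - 0.1, best["b"] + 0.1, length = 60)
  beta_grid2 <- seq(best["beta"] - 0.1, best["beta"] + 0.1, length = 60)
  for (b in b_grid2) for (be in beta_grid2) {
    ll <- loglik(b, be)
    if (ll > best["ll"]) best <- c(b = b, beta = be, ll = ll)
  }
  list(log2fc = unname(best["beta"]) / log(2), ll = unname(best["ll"]))
}

# base composition table of a sequence
base_comp <- function(s) table(factor(strsplit(s, "")[[1]],
                                      levels = c("A", "C", "G", "T")))

# small deterministic test config (fast to simulate)
small_config <- function(seed = 1L, ...) {
  args <- utils::modifyList(
    list(seed = seed, n_scaffolds = 6L, scaffold_length = 100000L,
         n_genes = 60L, n_de_genes = 15L, n_peaks = 300L),
    list(...))
  do.call(sim_config, args)
}
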
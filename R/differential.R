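# Negative-binomial differential accessibility test over the RPS count
# matrix: median-of-ratios size factors, method-of-moments dispersion
# estimation with shrinkage toward a fitted mean-dispersion trend, and a
# per-peak NB log-linear Wald test (vectorized Fisher scoring). This is
# a deliberately simplified NB pipeline: no Cox-Reid dispersion MAP, no
# LFC shrinkage, no outlier or independent filtering; downstream peak
# selection needs only (log2FoldChange, p) at nominal thresholds.

#' Median-of-ratios size factors
#'
#' factor_j = median over peaks of count_ij / geometric mean_i, taken
#' over peaks whose geometric mean is nonzero (i.e. peaks with nonzero
#' counts in all samples).
#'
#' @param counts integer matrix, peaks x samples.
#' @return Positive numeric vector of per-sample factors.
#' @export
size_factors <- function(counts) {
  logs <- log(counts)
  loggm <- rowMeans(logs)
  use <- is.finite(loggm)
  if (!any(use))
    stop("size_factors: no peak has nonzero counts in all samples")
  sf <- apply(logs[use, , drop = FALSE], 2, function(lc)
    exp(stats::median(lc - loggm[use])))
  if (any(!is.finite(sf)) || any(sf <= 0))
    stop("size_factors: degenerate normalization")
  sf
}

#' Per-peak NB dispersion estimates
#'
#' Method-of-moments estimate on normalized counts pooled within
#' condition, alpha_hat = max(0, (s^2 - mu)/mu^2) combined across
#' conditions with (n_c - 1) weights, then shrunk toward a fitted
#' mean-dispersion trend alpha_tr(mu) = a0 + a1/mu by a weighted
#' average. With only one replicate per condition in both conditions,
#' falls back to pooling across all samples with a warning.
#'
#' The default trend weight is high (0.9) because with 2-3 replicates
#' per condition the per-peak moment estimate has only a few degrees of
#' freedom and is mostly noise; strong pooling across peaks is what
#' keeps the downstream Wald p-values calibrated at these design sizes.
#' Lower the weight when many replicates are available or dispersion is
#' strongly peak-specific.
#'
#' @param counts integer matrix, peaks x samples.
#' @param sf size factors (defaults to \code{\link{size_factors}}).
#' @param condition character/factor of per-sample condition labels.
#' @param shrink_weight weight of the trend in the weighted average
#'   (default 0.9).
#' @param floor minimum dispersion (default 1e-8).
#' @return Numeric vector of per-peak dispersions (>= floor).
#' @export
estimate_dispersions <- function(counts, condition,
                                 sf = size_factors(counts),
                                 shrink_weight = 0.9, floor = 1e-8) {
  norm <- sweep(counts, 2, sf, "/")
  conds <- unique(as.character(condition))
  nrep <- table(as.character(condition))
  if (all(nrep < 2)) {
    warning("single replicate per condition; pooling across all samples")
    groups <- list(seq_len(ncol(counts)))
  } else {
    groups <- lapply(conds[nrep[conds] >= 2], function(cc)
      which(as.character(condition) == cc))
  }
  num <- rep(0, nrow(counts))
  den <- 0
  for (g in groups) {
    ng <- length(g)
    mu <- rowMeans(norm[, g, drop = FALSE])
    v <- rowSums((norm[, g, drop = FALSE] - mu)^2) / (ng - 1)
    a <- ifelse(mu > 0, pmax(0, (v - mu) / mu^2), 0)
    num <- num + (ng - 1) * a
    den <- den + (ng - 1)
  }
  a_raw <- num / den
  mu_all <- rowMeans(norm)
  # mean-dispersion trend a0 + a1/mu on informative peaks
  use <- mu_all > 0 & a_raw > 0
  if (sum(use) >= 10) {
    fit <- stats::lm(a_raw[use] ~ I(1 / mu_all[use]))
    a0 <- max(0, unname(stats::coef(fit)[1]))
    a1 <- max(0, unname(stats::coef(fit)[2]))
    a_tr <- ifelse(mu_all > 0, a0 + a1 / mu_all, a0)
  } else {
    a_tr <- rep(mean(a_raw[use], na.rm = TRUE), nrow(counts))
    a_tr[is.na(a_tr)] <- 0
  }
  pmax(floor, (1 - shrink_weight) * a_raw + shrink_weight * a_tr)
}

#' Negative-binomial Wald test per peak
#'
#' Fits, for each peak, the NB log-linear model
#' mu_ij = s_j * exp(b_i + beta_i x_j) with fixed dispersion, where
#' x_j = 1 for the tested condition, by vectorized Fisher scoring.
#' Reports the condition coefficient on the log2 scale, its standard
#' error from the observed Fisher information at the optimum, the Wald
#' statistic and a two-sided normal p-value. baseMean is the mean of
#' normalized counts across all samples. Peaks with all-zero counts get
#' baseMean 0 and NA statistics.
#'
#' @param counts integer matrix, peaks x samples.
#' @param condition per-sample condition labels (exactly two levels).
#' @param reference the reference condition level; the fold change is
#'   tested-level over reference. Defaults to \code{"reference"} when
#'   present, else the first sorted level.
#' @param sf size factors (defaults to \code{\link{size_factors}}).
#' @param dispersions per-peak dispersions (defaults to
#'   \code{\link{estimate_dispersions}}).
#' @param maxit,tol Fisher-scoring iteration controls.
#' @return data.frame with \code{peak_id}, \code{baseMean},
#'   \code{log2FoldChange}, \code{lfcSE}, \code{stat}, \code{pvalue}.
#' @export
nb_wald_test <- function(counts, condition, reference = NULL,
                         sf = size_factors(counts),
                         dispersions = NULL, maxit = 100L, tol = 1e-10) {
  condition <- as.character(condition)
  lev <- sort(unique(condition))
  if (length(lev) != 2)
    stop("nb_wald_test requires exactly two conditions")
  if (is.null(reference))
    reference <- if ("reference" %in% lev) "reference" else lev[1]
  if (!reference %in% lev) stop("unknown reference level")
  if (is.null(dispersions))
    dispersions <- estimate_dispersions(counts, condition, sf = sf)
  x <- as.numeric(condition != reference)
  np <- nrow(counts)
  ns <- ncol(counts)
  norm <- sweep(counts, 2, sf, "/")
  base_mean <- rowMeans(norm)
  nonzero <- rowSums(counts) > 0

  # init from condition means of normalized counts (0.5 pseudocount)
  mu1 <- rowMeans(norm[, x == 1, drop = FALSE]) + 0.5
  mu0 <- rowMeans(norm[, x == 0, drop = FALSE]) + 0.5
  b <- log(mu0)
  beta <- log(mu1) - log(mu0)
  logsf <- log(sf)
  a <- dispersions
  Y <- counts
  cap <- 15  # |beta| cap in nats; keeps all-zero-condition fits finite

  for (it in seq_len(maxit)) {
    eta <- outer(b, rep(1, ns)) + outer(beta, x) +
      matrix(logsf, np, ns, byrow = TRUE)
    mu <- exp(eta)
    denom <- 1 + a * mu
    resid <- (Y - mu) / denom     # score contribution per cell
    W <- mu / denom               # Fisher weights
    U1 <- rowSums(resid)
    U2 <- as.numeric(resid %*% x)
    I11 <- rowSums(W)
    I12 <- as.numeric(W %*% x)
    I22 <- I12                    # x is 0/1 so x^2 = x
    det <- I11 * I22 - I12^2
    det[det < 1e-12] <- 1e-12
    db <- (I22 * U1 - I12 * U2) / det
    dbeta <- (I11 * U2 - I12 * U1) / det
    step <- pmax(abs(db), abs(dbeta))
    db[!nonzero] <- 0
    dbeta[!nonzero] <- 0
    b <- b + pmin(pmax(db, -2), 2)
    beta <- pmin(pmax(beta + pmin(pmax(dbeta, -2), 2), -cap), cap)
    if (max(step[nonzero], 0) < tol) break
  }

  # observed information at the optimum for the SE
  eta <- outer(b, rep(1, ns)) + outer(beta, x) +
    matrix(logsf, np, ns, byrow = TRUE)
  mu <- exp(eta)
  obs <- mu * (1 + a * Y) / (1 + a * mu)^2
  J11 <- rowSums(obs)
  J12 <- as.numeric(obs %*% x)
  J22 <- J12
  detJ <- J11 * J22 - J12^2
  var_beta <- ifelse(detJ > 1e-12, J11 / detJ, NA_real_)

  log2fc <- beta / log(2)
  lfc_se <- sqrt(var_beta) / log(2)
  stat <- log2fc / lfc_se
  pval <- 2 * stats::pnorm(-abs(stat))
  out <- data.frame(peak_id = rownames(counts), baseMean = base_mean,
                    log2FoldChange = log2fc, lfcSE = as.numeric(lfc_se),
                    stat = as.numeric(stat), pvalue = as.numeric(pval),
                    stringsAsFactors = FALSE)
  out[!nonzero, c("log2FoldChange", "lfcSE", "stat", "pvalue")] <- NA
  out$baseMean[!nonzero] <- 0
  rownames(out) <- NULL
  out
}

#' Select differential peaks at a nominal p threshold
#'
#' Peaks with nominal p below \code{alpha} and a log2 fold change whose
#' sign matches the requested direction. Nominal (unadjusted) p-values
#' are the default because adjusted thresholds are exceedingly stringent
#' when hundreds of thousands of peaks are tested; set
#' \code{adjust = "BH"} to threshold Benjamini-Hochberg adjusted values
#' instead.
#'
#' @param results output of \code{\link{nb_wald_test}}.
#' @param peaks \code{peak_set} the results refer to (matched by id).
#' @param alpha nominal p threshold in (0,1) (the reference analysis
#'   uses 0.1 for the 3v3 DNase-style design and 0.2 for the 2v2
#'   ATAC-style design).
#' @param direction \code{"target"} (log2FC > 0), \code{"reference"}
#'   (log2FC < 0) or \code{"both"}.
#' @param adjust \code{"none"} (default) or \code{"BH"}.
#' @return \code{peak_set} of selected differential peaks.
#' @export
select_differential <- function(results, peaks, alpha,
                                direction = c("target", "reference",
                                              "both"),
                                adjust = c("none", "BH")) {
  direction <- match.arg(direction)
  adjust <- match.arg(adjust)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0,1)")
  p <- results$pvalue
  if (adjust == "BH") p <- stats::p.adjust(p, method = "BH")
  sel <- !is.na(p) & p < alpha
  sel <- sel & switch(direction,
                      target = results$log2FoldChange > 0,
                      reference = results$log2FoldChange < 0,
                      both = TRUE)
  ids <- results$peak_id[sel]
  out <- peaks[peaks$id %in% ids, , drop = FALSE]
  as_peak_set(out, label = "differential")
}
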
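test_that("size factors follow the median-of-ratios hand computation", {
  m <- matrix(c(10L, 20L, 40L, 8L,
                10L, 20L, 40L, 8L,
                10L, 20L, 40L, 8L), 4, 3,
              dimnames = list(sprintf("p%d", 1:4), c("a", "b", "c")))
  expect_equal(unname(size_factors(m)), c(1, 1, 1))
  # one column exactly doubled: its factor 2 relative to the others
  m2 <- m
  m2[, 3] <- 2L * m[, 3]
  sf <- size_factors(m2)
  # median-of-ratios on a doubled column: ratios (2^(2/3)) vs 2^(-1/3)
  # per column; check the *relative* factor is exactly 2
  expect_equal(unname(sf[3] / sf[1]), 2)
  expect_equal(unname(sf[1] / sf[2]), 1)
  # invariance to peak reordering
  perm <- c(3, 1, 4, 2)
  expect_equal(size_factors(m2[perm, ]), size_factors(m2))
  # all-zero-row-only matrix cannot be normalized
  expect_error(size_factors(matrix(c(0L, 1L, 1L, 0L), 2, 2)),
               "nonzero")
})

test_that("dispersion estimation recovers the simulation parameter", {
  set.seed(101)
  np <- 3000
  cond <- rep(c("target", "reference"), each = 3)
  # Poisson data: dispersion near zero
  cp <- sapply(1:6, function(j) rpois(np, 150))
  rownames(cp) <- sprintf("p%d", 1:np)
  dp <- estimate_dispersions(cp, cond, sf = rep(1, 6))
  expect_lt(median(dp), 0.01)
  # NB at alpha = 0.2, 3v3: recovered median within [0.1, 0.4]
  cn <- sapply(1:6, function(j) rnbinom(np, mu = 150, size = 1 / 0.2))
  rownames(cn) <- sprintf("p%d", 1:np)
  dn <- estimate_dispersions(cn, cond, sf = rep(1, 6))
  expect_gt(median(dn), 0.1)
  expect_lt(median(dn), 0.4)
  # constant counts within conditions -> floor
  cc <- matrix(rep(c(5L, 9L), each = 3), 2, 6, byrow = TRUE,
               dimnames = list(c("pa", "pb"), NULL))
  cc <- rbind(pa = rep(5L, 6), pb = rep(9L, 6))
  dc <- estimate_dispersions(cc, cond, sf = rep(1, 6),
                             shrink_weight = 0)
  expect_equal(unname(dc), c(1e-8, 1e-8))
  # single replicate per condition falls back with a warning
  expect_warning(
    estimate_dispersions(cn[, c(1, 4)], c("target", "reference"),
                         sf = rep(1, 2)),
    "single replicate")
})

test_that("single-peak ML estimate matches an independent grid-search oracle", {
  y <- c(10L, 12L, 9L, 40L, 44L, 38L)
  x <- c(0, 0, 0, 1, 1, 1)
  counts <- matrix(y, 1, 6, dimnames = list("p1", NULL))
  res <- nb_wald_test(counts,
                      c(rep("reference", 3), rep("target", 3)),
                      sf = rep(1, 6), dispersions = 0.01)
  oracle <- grid_nb_fit(y, x, alpha = 0.01)
  expect_lt(abs(res$log2FoldChange - oracle$log2fc), 0.1)
  expect_lt(abs(res$log2FoldChange - log2(mean(y[4:6]) / mean(y[1:3]))),
            0.1)
  # a few random parameterisations against the oracle
  set.seed(7)
  for (i in 1:5) {
    mu0 <- runif(1, 20, 200)
    lfc <- runif(1, -2, 2)
    a <- runif(1, 0.01, 0.3)
    yy <- c(rnbinom(3, mu = mu0, size = 1 / a),
            rnbinom(3, mu = mu0 * 2^lfc, size = 1 / a))
    if (sum(yy[1:3]) == 0 || sum(yy[4:6]) == 0) next
    cm <- matrix(as.integer(yy), 1, 6, dimnames = list("p1", NULL))
    r <- nb_wald_test(cm, c(rep("reference", 3), rep("target", 3)),
                      sf = rep(1, 6), dispersions = a)
    o <- grid_nb_fit(yy, x, alpha = a)
    expect_lt(abs(r$log2FoldChange - o$log2fc), 0.05)
  }
})

test_that("planted log2 fold changes are recovered on average", {
  set.seed(31)
  np <- 500
  cond <- c(rep("reference", 3), rep("target", 3))
  sf_true <- runif(6, 0.8, 1.2)
  mu <- outer(rep(200, np), sf_true)
  mu[, 4:6] <- mu[, 4:6] * 4  # log2FC = 2 everywhere
  counts <- matrix(rnbinom(np * 6, mu = mu, size = 1 / 0.05), np, 6,
                   dimnames = list(sprintf("p%d", 1:np), NULL))
  res <- nb_wald_test(counts, cond, sf = sf_true,
                      dispersions = rep(0.05, np))
  expect_lt(abs(mean(res$log2FoldChange) - 2), 0.25)
  expect_true(all(res$stat == res$log2FoldChange / res$lfcSE))
})

test_that("label swap negates the fold change and keeps p-values", {
  set.seed(43)
  counts <- matrix(rnbinom(600, mu = 100, size = 20), 100, 6,
                   dimnames = list(sprintf("p%d", 1:100), NULL))
  cond <- c(rep("A", 3), rep("B", 3))
  disp <- rep(0.05, 100)
  r1 <- nb_wald_test(counts, cond, reference = "A", sf = rep(1, 6),
                     dispersions = disp)
  r2 <- nb_wald_test(counts, cond, reference = "B", sf = rep(1, 6),
                     dispersions = disp)
  expect_equal(r1$log2FoldChange, -r2$log2FoldChange, tolerance = 1e-6)
  expect_equal(r1$stat, -r2$stat, tolerance = 1e-6)
  expect_equal(r1$pvalue, r2$pvalue, tolerance = 1e-6)
})

test_that("all-zero peaks are reported as missing, not as estimates", {
  counts <- rbind(p1 = c(10L, 12L, 11L, 30L, 29L, 33L),
                  p2 = rep(0L, 6))
  res <- nb_wald_test(counts, c(rep("reference", 3), rep("target", 3)),
                      sf = rep(1, 6), dispersions = c(0.05, 0.05))
  expect_equal(res$baseMean[2], 0)
  expect_true(is.na(res$pvalue[2]))
  expect_false(is.na(res$pvalue[1]))
})

test_that("null p-values are calibrated and selection honours alpha and direction", {
  set.seed(57)
  np <- 4000
  cond <- c(rep("reference", 3), rep("target", 3))
  counts <- sapply(1:6, function(j)
    rnbinom(np, mu = 200 * runif(1, 0.8, 1.2), size = 1 / 0.05))
  rownames(counts) <- sprintf("p%05d", 1:np)
  res <- nb_wald_test(counts, cond)
  for (a in c(0.05, 0.1, 0.2)) {
    rate <- mean(res$pvalue < a)
    expect_lt(abs(rate - a), 3 * sqrt(a * (1 - a) / np) + 0.01)
  }
  peaks <- peak_set(rep("s1", np), seq(0, by = 1000, length = np),
                    seq(600, by = 1000, length = np),
                    id = rownames(counts))
  sel_both <- select_differential(res, peaks, alpha = 0.1,
                                  direction = "both")
  sel_t <- select_differential(res, peaks, alpha = 0.1,
                               direction = "target")
  sel_r <- select_differential(res, peaks, alpha = 0.1,
                               direction = "reference")
  expect_equal(nrow(sel_t) + nrow(sel_r), nrow(sel_both))
  expect_true(all(sel_t$id %in%
                    res$peak_id[res$log2FoldChange > 0]))
  # all p = 0.5 -> nothing selected
  res_null <- res
  res_null$pvalue <- 0.5
  expect_equal(nrow(select_differential(res_null, peaks, 0.2,
                                        "target")), 0L)
  # p = 0.19 with positive lfc is kept at the 0.2 threshold
  res_edge <- res[1, ]
  res_edge$pvalue <- 0.19
  res_edge$log2FoldChange <- 1
  expect_equal(nrow(select_differential(res_edge, peaks, 0.2,
                                        "target")), 1L)
  expect_equal(nrow(select_differential(res_edge, peaks, 0.1,
                                        "target")), 0L)
  expect_error(select_differential(res, peaks, 1.5), "alpha")
})

test_that("fold-change estimates track DESeq2 on the same matrix", {
  skip_if_not_installed("DESeq2")
  set.seed(77)
  np <- 300
  cond <- c(rep("reference", 3), rep("target", 3))
  mu <- outer(rnbinom(np, mu = 150, size = 3) + 20, rep(1, 6))
  mu[1:60, 4:6] <- mu[1:60, 4:6] * 4
  counts <- matrix(rnbinom(np * 6, mu = mu, size = 1 / 0.05), np, 6,
                   dimnames = list(sprintf("p%d", 1:np),
                                   sprintf("s%d", 1:6)))
  res <- nb_wald_test(counts, cond)
  suppressMessages({
    dds <- DESeq2::DESeqDataSetFromMatrix(
      counts, data.frame(condition = factor(cond,
                                            levels = c("reference",
                                                       "target"))),
      ~condition)
    dds <- DESeq2::DESeq(dds, quiet = TRUE)
    dres <- DESeq2::results(dds)
  })
  keep <- !is.na(dres$log2FoldChange) & !is.na(res$log2FoldChange)
  expect_gt(cor(res$log2FoldChange[keep], dres$log2FoldChange[keep]),
            0.98)
  # planted block recovered by both routes
  expect_lt(abs(mean(res$log2FoldChange[1:60]) -
                  mean(dres$log2FoldChange[1:60])), 0.15)
})
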
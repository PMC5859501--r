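revcomp <- function(s) {
  chartr("ACGT", "TGCA",
         paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

test_that("pwm construction validates and reports its consensus", {
  m <- matrix(0.25, 4, 5)
  p <- pwm("flat", m)
  expect_equal(pwm_width(p), 5L)
  expect_error(pwm("bad", matrix(0.3, 4, 5)), "sum to 1")
  expect_error(pwm("bad", m, background = c(0.5, 0.5, 0.5, 0.5)),
               "background")
  expect_error(pwm("bad", m, pseudocount = 0), "pseudocount")
  ets <- example_pwms()[["Ets1"]]
  expect_equal(pwm_consensus(ets), "ACAGGAAGT")
})

test_that("scanning finds the consensus at maximal score on both strands", {
  p <- example_pwms()[["Ets1"]]
  cons <- pwm_consensus(p)
  hits <- scan_sequence(p, cons)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$offset, 0L)
  expect_equal(hits$strand, "+")
  dist <- pwm_score_distribution(p)
  expect_equal(hits$score, max(dist$scores))
  # reverse complement: same score, minus strand
  hits_rc <- scan_sequence(p, revcomp(cons))
  expect_equal(hits_rc$strand, "-")
  expect_equal(hits_rc$score, hits$score)
  expect_equal(hits_rc$p_value, hits$p_value)
  # embedded in background sequence at a known offset
  seq <- paste0(strrep("ACGT", 10), cons, strrep("TTGCA", 8))
  h <- scan_sequence(p, seq)
  expect_true(40 %in% h$offset)
  # windows containing N are skipped silently
  hN <- scan_sequence(p, paste0("NNNN", cons))
  expect_equal(hN$offset, 4L)
  # sequence shorter than the motif: no hits
  expect_equal(nrow(scan_sequence(p, "ACGT")), 0L)
})

test_that("window scores equal the score of the reverse complement on the other strand", {
  set.seed(5)
  p <- example_pwms()[["Gata"]]
  s <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
             collapse = "")
  h_fwd <- scan_sequence(p, s, p_threshold = 1)
  h_rc <- scan_sequence(p, revcomp(s), p_threshold = 1)
  # every + strand hit in s maps to a - strand hit in revcomp(s)
  w <- pwm_width(p)
  L <- nchar(s)
  plus <- h_fwd[h_fwd$strand == "+", ]
  minus_rc <- h_rc[h_rc$strand == "-", ]
  expect_equal(sort(L - w - plus$offset),
               sort(minus_rc$offset))
  expect_equal(sort(plus$score), sort(minus_rc$score))
})

test_that("exact DP p-values match exhaustive enumeration for short motifs", {
  set.seed(11)
  # a random informative 6-mer PWM
  m <- sapply(1:6, function(k) {
    x <- rgamma(4, 0.6) + 0.02
    x / sum(x)
  })
  p <- pwm("rand6", m, background = c(0.3, 0.2, 0.2, 0.3))
  dist <- pwm_score_distribution(p)
  S <- round(log2((sweep(p$matrix, 1, p$background * p$pseudocount,
                         "+") / (1 + p$pseudocount)) / p$background) /
               dist$step) * dist$step
  # enumerate all 4^6 words under the background model
  words <- expand.grid(rep(list(1:4), 6))
  wscore <- as.matrix(words)
  sc <- vapply(seq_len(nrow(words)), function(i)
    sum(S[cbind(wscore[i, ], 1:6)]), numeric(1))
  wp <- apply(words, 1, function(b) prod(p$background[b]))
  for (q in quantile(sc, c(0.05, 0.25, 0.5, 0.75, 0.95, 1))) {
    exact <- sum(wp[sc >= q - 1e-9])
    expect_equal(pwm_pvalue(p, q, dist), exact, tolerance = 1e-9)
  }
  # max-score p-value for the consensus-style PWM equals the exact
  # probability of drawing its best word(s)
  ets <- example_pwms()[["Ets1"]]
  d2 <- pwm_score_distribution(ets)
  expect_equal(pwm_pvalue(ets, max(d2$scores), d2), 0.25^9,
               tolerance = 1e-12)
})

test_that("shuffles preserve composition; dinucleotide shuffle preserves dinucleotides", {
  set.seed(21)
  seqs <- c(a = paste(sample(c("A", "C", "G", "T"), 200,
                             replace = TRUE), collapse = ""),
            b = strrep("A", 50),
            c = paste(sample(c("A", "C", "G", "T"), 120,
                             replace = TRUE), collapse = ""))
  sh <- shuffle_control(seqs, seed = 3)
  expect_equal(names(sh), names(seqs))
  for (n in names(seqs))
    expect_equal(base_comp(sh[[n]]), base_comp(seqs[[n]]))
  expect_equal(sh[["b"]], seqs[["b"]])  # homopolymer is invariant
  expect_identical(shuffle_control(seqs, seed = 3), sh)
  expect_false(identical(sh[["a"]], seqs[["a"]]))
  # dinucleotide shuffle: dinucleotide counts preserved exactly
  dn <- function(s) {
    x <- strsplit(s, "")[[1]]
    table(factor(paste0(x[-length(x)], x[-1]),
                 levels = as.vector(outer(c("A", "C", "G", "T"),
                                          c("A", "C", "G", "T"),
                                          paste0))))
  }
  shd <- shuffle_control(seqs, seed = 4, method = "dinucleotide")
  for (n in names(seqs))
    expect_equal(dn(shd[[n]]), dn(seqs[[n]]))
  # planted motif occurrences drop to background after shuffling
  p <- example_pwms()[["Ets1"]]
  planted <- vapply(1:60, function(i) {
    bg <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
                collapse = "")
    paste0(substr(bg, 1, 150), pwm_consensus(p),
           substr(bg, 151, 300))
  }, "")
  hit_rate <- function(v) mean(vapply(v, function(s)
    nrow(scan_sequence(p, s)) > 0, logical(1)))
  expect_equal(hit_rate(planted), 1)
  expect_lt(hit_rate(shuffle_control(planted, seed = 9)), 0.2)
})

test_that("two-step enrichment calls the planted motif and only it", {
  set.seed(33)
  pwms <- example_pwms()
  planted <- pwms[["Ets1"]]
  rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")
  diff_seqs <- vapply(1:60, function(i) {
    s <- rand_seq(400)
    if (runif(1) < 0.6)
      s <- paste0(substr(s, 1, 200), pwm_consensus(planted),
                  substr(s, 201, 400))
    s
  }, "")
  nondiff_seqs <- vapply(1:120, function(i) rand_seq(400), "")
  calls <- ame_two_step(diff_seqs, nondiff_seqs, pwms, seed = 2)
  expect_true(calls$enriched_in_differential[calls$motif_id == "Ets1"])
  expect_false(any(calls$enriched_in_differential[
    calls$motif_id != "Ets1"]))
  # motif planted equally in both sets is not called
  both_d <- vapply(seq_along(diff_seqs), function(i)
    paste0(diff_seqs[i], pwm_consensus(pwms[["Gata"]])), "")
  both_n <- vapply(seq_along(nondiff_seqs), function(i)
    paste0(nondiff_seqs[i], pwm_consensus(pwms[["Gata"]])), "")
  calls2 <- ame_two_step(both_d, both_n, pwms["Gata"], seed = 2)
  expect_false(calls2$enriched_in_differential)
  # no hits anywhere: p = 1, nothing called
  calls3 <- ame_two_step(rep("ACACACACAC", 5), rep("GTGTGTGTGT", 5),
                         pwms["Ets1"], seed = 2)
  expect_equal(calls3$p_diff_vs_shuffled, 1)
  expect_false(calls3$enriched_in_differential)
  expect_error(ame_two_step(character(0), nondiff_seqs, pwms),
               "nonempty")
})

test_that("MEME motif files round-trip through the reader", {
  pwms <- example_pwms()[c("Ets1", "Alx1")]
  path <- tempfile(fileext = ".meme")
  write_meme(pwms, path)
  back <- read_meme(path)
  expect_equal(names(back), names(pwms))
  for (n in names(pwms)) {
    expect_equal(back[[n]]$matrix, pwms[[n]]$matrix,
                 tolerance = 1e-5, ignore_attr = TRUE)
    expect_equal(back[[n]]$background, pwms[[n]]$background,
                 tolerance = 1e-4)
    expect_equal(pwm_consensus(back[[n]]), pwm_consensus(pwms[[n]]))
  }
})
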
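make_windows <- function(n, seed = 1) {
  set.seed(seed)
  vapply(seq_len(n), function(i) {
    x <- paste(sample(c("A", "C", "G", "T"), 36, TRUE), collapse = "")
    substr(x, 18, 19) <- "GT"
    x
  }, character(1))
}

test_that("identical training windows give pure consensus columns", {
  w <- rep(canonical_minimal_window(CANON)$sequence, 5)
  m <- build_motif(w, pseudocount = 0)
  expect_identical(m$width, 34L)
  expect_true(all(colSums(m$counts) == 5))
  expect_true(all(apply(m$counts, 2, max) == 5))
  expect_identical(m$consensus, substr(w[1], 2, 35))
  # fully conserved columns carry 2 bits against a uniform background
  expect_equal(unname(motif_ic(m)), rep(2, 34), tolerance = 1e-12)
  expect_identical(m$core_columns, c(17L, 18L))
  expect_identical(substr(m$consensus, 17, 18), "GT")
})

test_that("information content matches a direct per-column computation", {
  m <- build_motif(make_windows(12), pseudocount = 0.5)
  ic <- motif_ic(m)
  for (j in c(1, 10, 17, 34)) {
    direct <- sum(m$probs[, j] * log2(m$probs[, j] / m$background))
    expect_equal(unname(ic[j]), direct, tolerance = 1e-12)
  }
})

test_that("the consensus attains the maximal attainable score", {
  m <- build_motif(make_windows(8, seed = 3))
  best <- sum(apply(m$log_odds, 2, max))
  cons_codes <- match(strsplit(m$consensus, "")[[1]], c("A", "C", "G", "T"))
  cons_score <- sum(m$log_odds[cbind(cons_codes, 1:34)])
  expect_equal(cons_score, best, tolerance = 1e-12)
})

test_that("motif construction validates its inputs", {
  expect_error(build_motif(c("ACGT")), "at least 2")
  expect_error(build_motif(c("ACGTA", "ACGT")), "inconsistent widths")
  expect_error(build_motif(c("AAAAAA", "AAAAAA"), core_index = 3),
               "GT at core_index")
})

test_that("a single-column motif gives p = 0.25 at the best letter", {
  m1 <- structure(list(
    name = "w1", width = 1L,
    log_odds = matrix(c(2, -1, -1, -1), 4, 1,
                      dimnames = list(c("A", "C", "G", "T"), NULL)),
    background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  ), class = "motif_model")
  sd <- exact_pvalues(m1)
  expect_equal(score_pvalue(sd, round(2 / sd$granularity)), 0.25)
  expect_equal(sd$tail[1], 1)
})

test_that("DP tail probabilities equal exhaustive enumeration (width 6)", {
  m <- build_motif(substr(make_windows(9, seed = 5), 15, 22),
                   core_index = 4, width = 6)
  gran <- 1e-3
  for (bg in list(c(A = .25, C = .25, G = .25, T = .25),
                  c(A = .16, C = .34, G = .34, T = .16))) {
    sd <- exact_pvalues(m, background = bg, granularity = gran)
    S <- round(m$log_odds / gran)
    grid <- as.matrix(expand.grid(rep(list(1:4), 6)))
    sc <- apply(grid, 1, function(cd) sum(S[cbind(cd, 1:6)]))
    pr <- apply(grid, 1, function(cd) prod(bg[cd]))
    for (q in unique(quantile(sc, c(0, .25, .5, .9, .99, 1), type = 1))) {
      expect_equal(score_pvalue(sd, as.integer(q)), sum(pr[sc >= q]),
                   tolerance = 1e-12)
    }
  }
})

test_that("the null distribution is a proper, monotone distribution", {
  m <- build_motif(make_windows(7, seed = 9))
  sd <- exact_pvalues(m)
  expect_equal(sum(sd$prob), 1, tolerance = 1e-9)
  expect_true(all(diff(sd$tail) <= 1e-15))
  expect_equal(sd$tail[1], 1)
  expect_true(sd$min_p > 0)
  expect_error(exact_pvalues(m, background = c(A = .5, C = .5, G = .1, T = .1)),
               "summing to 1")
})

test_that("a permissive threshold reports every window on both strands", {
  m <- build_motif(make_windows(5, seed = 2))
  set.seed(40)
  g <- paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")
  h <- scan_genome(g, m, threshold = 1,
                   background = c(A = .25, C = .25, G = .25, T = .25))
  expect_identical(nrow(h), 2L * (200L - 34L + 1L))
  h1 <- scan_genome(g, m, threshold = 1, both_strands = FALSE,
                    background = c(A = .25, C = .25, G = .25, T = .25))
  expect_identical(nrow(h1), 200L - 34L + 1L)
})

test_that("a planted consensus is recovered at its exact coordinate", {
  m <- build_motif(make_windows(10, seed = 6))
  set.seed(41)
  g <- paste(sample(c("A", "C", "G", "T"), 20000, TRUE), collapse = "")
  substr(g, 7001, 7034) <- m$consensus
  h <- scan_genome(g, m, threshold = 1e-8,
                   background = c(A = .25, C = .25, G = .25, T = .25))
  expect_true(any(h$start == 7001 & h$strand == "+"))
  expect_equal(min(h$p_value), unname(score_pvalue(
    exact_pvalues(m), sum(round(m$log_odds / 1e-3)[
      cbind(match(strsplit(m$consensus, "")[[1]], c("A", "C", "G", "T")),
            1:34)]))))
})

test_that("scanning the reverse complement mirrors hits and strands", {
  m <- build_motif(make_windows(6, seed = 8))
  set.seed(42)
  g <- paste(sample(c("A", "C", "G", "T"), 3000, TRUE), collapse = "")
  substr(g, 1001, 1034) <- m$consensus
  bg <- c(A = .25, C = .25, G = .25, T = .25)
  h <- scan_genome(g, m, threshold = 1e-4, background = bg)
  hr <- scan_genome(revcomp(g), m, threshold = 1e-4, background = bg)
  expect_identical(nrow(h), nrow(hr))
  mirrored <- data.frame(start = 3000L - hr$start - 34L + 2L,
                         strand = ifelse(hr$strand == "+", "-", "+"),
                         score = hr$score)
  mirrored <- mirrored[order(mirrored$start, mirrored$strand), ]
  expect_equal(h$start, mirrored$start)
  expect_identical(h$strand, mirrored$strand)
  expect_equal(h$score, mirrored$score)
})

test_that("background hit counts follow the Poisson expectation", {
  m <- build_motif(make_windows(10, seed = 12))
  bg <- c(A = .25, C = .25, G = .25, T = .25)
  sd <- exact_pvalues(m, background = bg)
  thr <- 1e-3
  set.seed(43)
  g <- paste(sample(c("A", "C", "G", "T"), 200000, TRUE), collapse = "")
  h <- scan_genome(g, m, threshold = thr, sd = sd, background = bg)
  # the realized cut sits at the discretized score, so use its exact tail
  p_real <- score_pvalue(sd, attsites:::.score_threshold(sd, thr))
  lambda <- 2 * (200000 - 34 + 1) * p_real
  expect_gt(nrow(h), lambda - 3 * sqrt(lambda))
  expect_lt(nrow(h), lambda + 3 * sqrt(lambda))
})

test_that("require_core restricts hits to GT-bearing windows", {
  m <- build_motif(make_windows(5, seed = 14))
  set.seed(44)
  g <- paste(sample(c("A", "C", "G", "T"), 500, TRUE), collapse = "")
  h <- scan_genome(g, m, threshold = 1, require_core = TRUE,
                   background = c(A = .25, C = .25, G = .25, T = .25))
  expect_true(all(substr(h$sequence, 17, 18) == "GT"))
  expect_gt(nrow(h), 0)
})
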
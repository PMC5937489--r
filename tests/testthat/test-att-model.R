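test_that("extract_window recovers configured canonical windows", {
  w <- extract_window(CANON$attB, CANON$attB_core, "+",
                      CANON$minimal_arm_left, CANON$minimal_arm_right)
  expect_identical(nchar(w$sequence), 36L)
  expect_identical(w$sequence,
                   substr(CANON$attB, CANON$attB_core - 17L,
                          CANON$attB_core + 18L))
  expect_true(w$core_ok)
  expect_identical(substr(w$sequence, 18, 19), "GT")
})

test_that("circular extraction equals rotate-then-extract", {
  set.seed(5)
  g <- paste(sample(c("A", "C", "G", "T"), 100, TRUE), collapse = "")
  substr(g, 99, 100) <- "GT"
  w <- extract_window(g, 99, "+", 17, 17, circular = TRUE)
  rot <- paste0(substr(g, 51, 100), substr(g, 1, 50))  # core G now at 49
  expect_identical(w$sequence, substr(rot, 49 - 17, 49 + 18))
  # wrap on the left edge too
  substr(g, 2, 3) <- "GT"
  rot <- paste0(substr(g, 51, 100), substr(g, 1, 50))  # core G now at 52
  w2 <- extract_window(g, 2, "+", 17, 17, circular = TRUE)
  expect_identical(w2$sequence, substr(rot, 52 - 17, 52 + 18))
})

test_that("linear out-of-bounds windows error; non-GT cores are flagged", {
  g <- paste(rep("ACGT", 30), collapse = "")
  expect_error(extract_window(g, 5, "+", 17, 17), "out of bounds")
  w <- extract_window(g, 60, "+", 5, 5)
  expect_false(w$core_ok)
  expect_match(w$warning, "not 'GT'")
})

test_that("minus-strand extraction returns the planted window", {
  cfg <- sim_config(seed = 3L, genome_length = 60000L, n_sites = 8L,
                    n_transformants = 0L)
  host <- generate_host(cfg, CANON)
  for (i in seq_len(nrow(host$sites))) {
    s <- host$sites[i, ]
    w <- extract_window(host$genome, s$core_position, s$strand,
                        CANON$minimal_arm_left, CANON$minimal_arm_right,
                        circular = TRUE)
    expect_identical(w$sequence, s$window)
    expect_true(w$core_ok)
  }
  expect_setequal(unique(host$sites$strand), c("+", "-"))
})

test_that("identity_count is exact on the canonical site itself", {
  w <- extract_window(CANON$attB, CANON$attB_core, "+",
                      CANON$full_arm_left, CANON$full_arm_right)
  r <- identity_count(w, CANON)
  expect_identical(r$count_full, 73L)
  expect_identical(r$count_minimal, 36L)
  expect_identical(r$count_crossover, 9L)
  expect_identical(r$pct_full, 100L)
})

test_that("identity_count agrees with a position-by-position oracle", {
  set.seed(11)
  for (rep in 1:20) {
    chars <- sample(c("A", "C", "G", "T"), 73, TRUE)
    chars[36:37] <- c("G", "T")
    q <- att_window(paste(chars, collapse = ""), core_index = 36L)
    r <- identity_count(q, CANON)
    expect_identical(r$count_full,
                     naive_match_count(q$sequence, 36L, CANON$attB,
                                       CANON$attB_core, 35L, 36L))
    expect_identical(r$count_minimal,
                     naive_match_count(q$sequence, 36L, CANON$attB,
                                       CANON$attB_core, 17L, 17L))
    expect_identical(r$count_crossover,
                     naive_match_count(q$sequence, 36L, CANON$attB,
                                       CANON$attB_core, 3L, 4L))
    # nesting and core conservation
    expect_gte(r$count_full, r$count_minimal)
    expect_gte(r$count_minimal, r$count_crossover)
    expect_gte(r$count_crossover, 2L)
  }
})

test_that("identity is symmetric and reverse-complement invariant", {
  set.seed(21)
  chars <- sample(c("A", "C", "G", "T"), 73, TRUE)
  chars[36:37] <- c("G", "T")
  seq_q <- paste(chars, collapse = "")
  # symmetry: swap query and canonical roles
  can_q <- canonical_att(attB = seq_q, attB_core = 36L,
                         attP = CANON$attP, attP_core = CANON$attP_core)
  r1 <- identity_count(att_window(seq_q, 36L), CANON)
  r2 <- identity_count(att_window(CANON$attB, CANON$attB_core), can_q)
  expect_identical(r1$count_full, r2$count_full)
  expect_identical(r1$count_minimal, r2$count_minimal)
  # simultaneous reverse complement: compare minimal-span counts through
  # windows extracted from the minus strand of both sequences
  rc_q <- revcomp(seq_q); rc_b <- revcomp(CANON$attB)
  # on the rc, the G of the (window-strand) core pairs with position 38
  q_rc <- extract_window(rc_q, 38L, "-", 17L, 17L)
  can_rc <- canonical_att(attB = extract_window(rc_b, 38L, "-", 35L, 36L)$sequence,
                          attB_core = 36L,
                          attP = CANON$attP, attP_core = CANON$attP_core)
  r3 <- identity_count(q_rc, can_rc, spans = "minimal")
  expect_identical(r3$count_minimal, r1$count_minimal)
})

test_that("scoring a span wider than the window errors with guidance", {
  w <- extract_window(CANON$attB, CANON$attB_core, "+", 17L, 17L)
  expect_error(identity_count(w, CANON), "wider arms")
  expect_silent(identity_count(w, CANON, spans = c("minimal", "crossover")))
})

test_that("non-ACGT characters never count as matches", {
  chars <- strsplit(CANON$attB, "")[[1]]
  chars[1:10] <- "N"
  q <- att_window(paste(chars, collapse = ""), core_index = 36L)
  r <- identity_count(q, CANON)
  expect_identical(r$count_full, 63L)
})

test_that("attL/attR reconstruction round-trips its inputs", {
  b <- extract_window(CANON$attB, CANON$attB_core, "+", 17L, 17L)
  p <- canonical_attP_window(CANON)
  pr <- reconstruct_att_products(b, p)
  # length is conserved: each product carries one copy of the 2 nt core
  expect_identical(nchar(pr$attL) + nchar(pr$attR),
                   nchar(b$sequence) + nchar(p$sequence))
  # re-split at the core recovers both inputs exactly
  expect_identical(paste0(substr(pr$attL, 1, 17), "GT",
                          substr(pr$attR, 20, 36)), b$sequence)
  expect_identical(paste0(substr(pr$attR, 1, 17), "GT",
                          substr(pr$attL, 20, 36)), p$sequence)
})

test_that("reconstruction of a site with itself is the identity", {
  b <- extract_window(CANON$attB, CANON$attB_core, "+", 17L, 17L)
  pr <- reconstruct_att_products(b, b)
  expect_identical(pr$attL, b$sequence)
  expect_identical(pr$attR, b$sequence)
})

test_that("reconstruction requires the matched core GT", {
  b <- extract_window(CANON$attB, CANON$attB_core, "+", 17L, 17L)
  bad <- att_window(chartr("GT", "CA", b$sequence), core_index = 18L)
  expect_error(reconstruct_att_products(bad, b), "core GT")
  expect_error(reconstruct_att_products(b, bad), "core GT")
})
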
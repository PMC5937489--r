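test_that("identical configs give byte-identical outputs", {
  cfg <- sim_config(seed = 9L, genome_length = 30000L, n_sites = 4L,
                    n_transformants = 5L, plasmid_length = 2000L)
  a <- generate_host(cfg, CANON); b <- generate_host(cfg, CANON)
  expect_identical(a$genome, b$genome)
  expect_identical(a$sites, b$sites)
  pa <- generate_plasmid(cfg, CANON); pb <- generate_plasmid(cfg, CANON)
  expect_identical(pa$sequence, pb$sequence)
  ta <- simulate_transformants(a, pa, cfg)
  tb <- simulate_transformants(b, pb, cfg)
  expect_identical(ta$truth, tb$truth)
  expect_identical(ta$genomes, tb$genomes)
})

test_that("zero sites gives a plain background genome", {
  cfg <- sim_config(seed = 2L, genome_length = 10000L, n_sites = 0L,
                    n_transformants = 0L)
  host <- generate_host(cfg, CANON)
  expect_identical(nrow(host$sites), 0L)
  expect_identical(nchar(host$genome), 10000L)
  expect_error(
    simulate_transformants(host, generate_plasmid(cfg, CANON),
                           sim_config(seed = 2L, genome_length = 10000L,
                                      n_sites = 0L, n_transformants = 3L)),
    "without planted sites")
})

test_that("planted sites realize their target identity exactly", {
  cfg <- sim_config(seed = 13L, genome_length = 40000L, n_sites = 5L,
                    identity_counts = c(36L, 22L, 12L, 30L, 18L),
                    n_transformants = 0L)
  host <- generate_host(cfg, CANON)
  expect_identical(host$sites$realized_count, host$sites$target_count)
  # a 36/36 site is a verbatim copy of the canonical minimal window
  canon_min <- canonical_minimal_window(CANON)$sequence
  expect_identical(host$sites$window[host$sites$target_count == 36L],
                   canon_min)
  # mutations never touch the core
  expect_true(all(substr(host$sites$window, 18, 19) == "GT"))
})

test_that("sites are separated and no stray canonical copy exists", {
  cfg <- sim_config(seed = 4L, genome_length = 50000L, n_sites = 10L,
                    n_transformants = 0L)
  host <- generate_host(cfg, CANON)
  # forward starts of the planted windows, both strands
  starts <- ifelse(host$sites$strand == "+",
                   host$sites$core_position - 17L,
                   host$sites$core_position - 18L)
  expect_true(all(diff(sort(starts)) >= 36L + cfg$min_separation))
  canon_min <- canonical_minimal_window(CANON)$sequence
  hitsF <- gregexpr(canon_min, host$genome, fixed = TRUE)[[1]]
  hitsR <- gregexpr(revcomp(canon_min), host$genome, fixed = TRUE)[[1]]
  ok36 <- starts[host$sites$target_count == 36L]
  expect_true(all(setdiff(hitsF[hitsF > 0], ok36) == numeric(0)))
  expect_true(all(setdiff(hitsR[hitsR > 0], ok36) == numeric(0)))
})

test_that("weighted site selection matches binomial expectation", {
  # weight vector echoing the observed multiplicity structure 4,4,2,2
  w <- c(4, 4, 2, 2)
  cfg <- sim_config(seed = 31L, genome_length = 20000L, n_sites = 4L,
                    weights = w, n_transformants = 1000L,
                    plasmid_length = 1500L)
  host <- generate_host(cfg, CANON)
  tr <- simulate_transformants(host, generate_plasmid(cfg, CANON), cfg)
  counts <- table(factor(tr$truth$site_id, levels = host$sites$site_id))
  p <- w / sum(w)
  for (i in 1:4) {
    mu <- 1000 * p[i]; sd3 <- 3 * sqrt(1000 * p[i] * (1 - p[i]))
    expect_gt(counts[i], mu - sd3)
    expect_lt(counts[i], mu + sd3)
  }
})

test_that("integration conserves sequence content exactly", {
  fx <- sim_fixture()
  LH <- nchar(fx$host$genome); LP <- nchar(fx$plasmid$sequence)
  expect_true(all(nchar(fx$tr$genomes) == LH + LP))
  # the post genome carries the truth attL and attR verbatim (one strand)
  for (i in seq_len(nrow(fx$tr$truth))) {
    g <- fx$tr$genomes[[fx$tr$truth$transformant_id[i]]]
    attL <- fx$tr$truth$attL[i]; attR <- fx$tr$truth$attR[i]
    if (fx$tr$truth$strand[i] == "-") {
      attL <- revcomp(attL); attR <- revcomp(attR)
    }
    expect_true(grepl(attL, g, fixed = TRUE))
    expect_true(grepl(attR, g, fixed = TRUE))
  }
  # truth attL/attR equal the reconstruction rule applied to the windows
  canonical <- fx$host$canonical
  attP_w <- canonical_attP_window(canonical)
  for (i in seq_len(nrow(fx$tr$truth))) {
    s <- fx$tr$truth[i, ]
    attB_w <- extract_window(fx$host$genome, s$core_position, s$strand,
                             17L, 17L, circular = TRUE)
    pr <- reconstruct_att_products(attB_w, attP_w)
    expect_identical(s$attL, pr$attL)
    expect_identical(s$attR, pr$attR)
  }
})

test_that("infeasible configurations are rejected", {
  expect_error(sim_config(seed = 1, genome_length = 1000L, n_sites = 20L),
               "200 nt per planted site")
  expect_error(sim_config(seed = 1, identity_counts = 1L), "\\[2, 36\\]")
  expect_error(sim_config(seed = 1, weights = c(-1, 2)), "non-negative")
})
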
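# Shared fixtures. Everything is generated in code under fixed seeds.

CANON <- canonical_att_synthetic()

# Published per-site statistics of the 19 N. terpenica insertion sites
# (identity counts to the canonical attB over the 73/36/9 bp windows, event
# multiplicities and genome positions); used as input data for aggregation
# and invariant checks.
nt_site_stats <- function() {
  read_tsv(system.file("extdata", "nt_terpenica_sites.tsv",
                       package = "attsites"))
}

# A fixture event list with the observed multiplicity structure
# {4, 4, 2, 2, 1 x 15}: 27 events over 19 distinct (position, strand) sites.
fixture_events <- function(positions = NULL) {
  mult <- c(4L, 4L, 2L, 2L, rep(1L, 15L))
  positions <- positions %||% (1000L + 500L * seq_along(mult))
  data.frame(
    transformant_id = sprintf("T%03d", seq_len(sum(mult))),
    ref_core_position = rep(positions, times = mult),
    orientation = rep(rep(c("+", "-"), length.out = length(mult)), times = mult),
    stringsAsFactors = FALSE
  )
}

# Construct a full-width (73 nt) window with exactly the requested identity
# counts to the canonical attB over the nested spans, by mutating a seeded
# choice of positions of the canonical sequence. Used to rebuild windows
# with the identity structure of published sites (the published sequences
# themselves are figure-only); counts are later re-derived independently.
plant_identity_window <- function(canonical, count_full, count_minimal,
                                  count_crossover = 9L, seed = 1L) {
  core <- canonical$attB_core
  min_span <- seq.int(core - canonical$minimal_arm_left,
                      core + 1L + canonical$minimal_arm_right)
  cross_span <- seq.int(core - canonical$crossover_arm_left,
                        core + 1L + canonical$crossover_arm_right)
  core_pos <- c(core, core + 1L)
  pool_cross <- setdiff(cross_span, core_pos)
  pool_min <- setdiff(min_span, cross_span)
  pool_out <- setdiff(seq_len(nchar(canonical$attB)), min_span)
  mm_cross <- length(cross_span) - count_crossover
  mm_min_extra <- (length(min_span) - count_minimal) - mm_cross
  mm_out <- (nchar(canonical$attB) - count_full) -
    (length(min_span) - count_minimal)
  stopifnot(mm_cross >= 0, mm_cross <= length(pool_cross),
            mm_min_extra >= 0, mm_min_extra <= length(pool_min),
            mm_out >= 0, mm_out <= length(pool_out))
  set.seed(seed)
  pos <- c(sample(pool_cross, mm_cross), sample(pool_min, mm_min_extra),
           sample(pool_out, mm_out))
  chars <- strsplit(canonical$attB, "")[[1]]
  for (p in pos) chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
  att_window(paste(chars, collapse = ""), core_index = core)
}

# brute-force core-anchored match counter (independent of identity_count)
naive_match_count <- function(seq_a, core_a, seq_b, core_b, arm_l, arm_r) {
  n <- 0L
  for (d in seq.int(-arm_l, arm_r + 1L)) {
    a <- substr(seq_a, core_a + d, core_a + d)
    b <- substr(seq_b, core_b + d, core_b + d)
    if (a == b && a %in% c("A", "C", "G", "T")) n <- n + 1L
  }
  n
}

# small simulated benchmark shared across detection tests (both strands
# present under this seed)
sim_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(seed = 3L, genome_length = 60000L, n_sites = 8L,
                        n_transformants = 25L, plasmid_length = 3000L)
      host <- generate_host(cfg)
      plasmid <- generate_plasmid(cfg)
      tr <- simulate_transformants(host, plasmid, cfg)
      cache <<- list(cfg = cfg, host = host, plasmid = plasmid, tr = tr,
                     attP_core = find_attP(plasmid$sequence, host$canonical))
    }
    cache
  }
})
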
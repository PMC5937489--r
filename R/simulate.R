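#' Simulation configuration
#'
#' Parameters of the synthetic recombination benchmark: a GC-rich circular
#' host genome with planted pseudo-attB sites of controlled identity to the
#' canonical minimal attB, a circular donor plasmid carrying attP, and a set
#' of independently drawn single-integration transformants. Defaults mirror
#' the sampling structure of a pseudo-attB survey at desk scale: a 200 kb
#' host (a stand-in for a ~9 Mb actinomycete chromosome), 20 planted sites
#' whose minimal-window match counts span 12–22 of 36 (the identity range
#' observed for real pseudo-attB sites), and 27 transformants drawn from 14
#' independent transformation reactions.
#'
#' @param seed integer seed; everything downstream is deterministic in it.
#' @param genome_length host genome length (nt).
#' @param gc_fraction background GC content (actinomycete-like default 0.68).
#' @param n_sites number of planted pseudo-attB sites.
#' @param identity_counts integer vector of per-site target match counts to
#'   the canonical minimal window (2..36; the 2 is the invariant core GT).
#'   Default: evenly spread over 12..22, recycled over sites.
#' @param weights site selection weights: `"uniform"` or a non-negative
#'   numeric vector (recycled to `n_sites`).
#' @param plasmid_length donor plasmid length (nt, circular).
#' @param n_transformants number of transformants to simulate.
#' @param n_reactions number of independent transformation reactions the
#'   transformants are attributed to (round robin).
#' @param topology host topology, `"circular"` (default) or `"linear"`.
#' @param min_separation minimum nt between planted windows.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L, genome_length = 200000L, gc_fraction = 0.68,
                       n_sites = 20L, identity_counts = NULL,
                       weights = "uniform", plasmid_length = 6000L,
                       n_transformants = 27L, n_reactions = 14L,
                       topology = c("circular", "linear"),
                       min_separation = 100L) {
  topology <- match.arg(topology)
  stopifnot(seed == as.integer(seed), gc_fraction >= 0, gc_fraction <= 1,
            n_sites >= 0L, plasmid_length >= 200L, n_transformants >= 0L)
  if (n_sites > 0L && genome_length < n_sites * 200L)
    stop("genome_length must be at least 200 nt per planted site")
  if (is.null(identity_counts)) {
    identity_counts <- if (n_sites > 0L)
      as.integer(round(seq(12L, 22L, length.out = n_sites))) else integer(0)
  } else {
    identity_counts <- as.integer(rep_len(identity_counts, max(n_sites, length(identity_counts))))
    identity_counts <- identity_counts[seq_len(n_sites)]
  }
  if (n_sites > 0L && (any(identity_counts < 2L) || any(identity_counts > 36L)))
    stop("identity_counts must lie in [2, 36]")
  if (is.numeric(weights)) {
    weights <- rep_len(weights, n_sites)
    if (any(weights < 0) || (n_sites > 0L && sum(weights) <= 0))
      stop("weights must be non-negative and not all zero")
  } else if (!identical(weights, "uniform")) {
    stop("weights must be 'uniform' or a numeric vector")
  }
  structure(list(
    seed = as.integer(seed), genome_length = as.integer(genome_length),
    gc_fraction = gc_fraction, n_sites = as.integer(n_sites),
    identity_counts = identity_counts, weights = weights,
    plasmid_length = as.integer(plasmid_length),
    n_transformants = as.integer(n_transformants),
    n_reactions = as.integer(n_reactions),
    topology = topology, min_separation = as.integer(min_separation)
  ), class = "sim_config")
}

.random_dna <- function(n, gc) {
  paste(sample(DNA_BASES, n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# mutate a minimal-window copy down to exactly `target` matches; the core GT
# (window positions core_idx, core_idx+1) is never touched and mutated
# positions are drawn without replacement among the non-core positions.
.mutate_window <- function(window, target, core_idx) {
  w <- nchar(window)
  k <- w - target
  if (k == 0L) return(window)
  pool <- setdiff(seq_len(w), c(core_idx, core_idx + 1L))
  if (k > length(pool)) stop("target identity below the invariant core")
  pos <- sample(pool, k)
  chars <- seq_chars(window)
  for (p in pos) chars[p] <- sample(setdiff(DNA_BASES, chars[p]), 1L)
  paste(chars, collapse = "")
}

# forward-strand occurrences (1-based starts) of fixed pattern in genome
.find_fixed <- function(genome, pattern) {
  m <- gregexpr(pattern, genome, fixed = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m)
}

#' Generate a host genome with planted pseudo-attB sites
#'
#' Draws an i.i.d. background genome at the configured GC content and plants
#' `n_sites` non-overlapping pseudo-attB windows, each a copy of the
#' canonical minimal attB with a seeded random subset of non-core positions
#' mutated so that the realized match count equals the target exactly.
#' Site strands are Bernoulli(1/2). The generator verifies that no exact
#' copy of the canonical minimal window occurs anywhere it was not planted
#' (either strand) and redraws the genome otherwise.
#'
#' @param config a [sim_config()].
#' @param canonical a [canonical_att()] object.
#' @return list with `genome` (character), `sites` (the truth table: one row
#'   per site with `site_id`, `core_position`, `strand`, `window`,
#'   `target_count`, `realized_count`, `weight`), `config`, `canonical`.
#' @export
generate_host <- function(config, canonical = canonical_att_synthetic()) {
  stopifnot(inherits(config, "sim_config"), inherits(canonical, "canonical_att"))
  set.seed(config$seed)
  L <- config$genome_length
  circular <- config$topology == "circular"
  canon_min <- canonical_minimal_window(canonical)$sequence
  wlen <- nchar(canon_min)
  core_idx <- canonical$minimal_arm_left + 1L
  n <- config$n_sites

  for (attempt in 1:25) {
    genome <- .random_dna(L, config$gc_fraction)
    if (n == 0L) {
      sites <- data.frame(site_id = character(0), core_position = integer(0),
                          strand = character(0), window = character(0),
                          target_count = integer(0), realized_count = integer(0),
                          weight = numeric(0), stringsAsFactors = FALSE)
      return(list(genome = genome, sites = sites, config = config,
                  canonical = canonical))
    }
    # non-overlapping, separated starts; keep away from the linear ends
    lo <- if (circular) 1L else config$min_separation
    hi <- L - wlen - config$min_separation
    ok <- FALSE
    for (try in 1:200) {
      starts <- sort(sample(seq.int(lo, hi), n))
      if (all(diff(starts) >= wlen + config$min_separation)) { ok <- TRUE; break }
    }
    if (!ok) stop("could not place ", n, " sites in ", L,
                  " nt with min_separation ", config$min_separation)
    strands <- sample(c("+", "-"), n, replace = TRUE)
    targets <- config$identity_counts
    windows <- vapply(targets, function(t)
      .mutate_window(canon_min, t, core_idx), character(1))
    for (i in seq_len(n)) {
      ins <- if (strands[i] == "+") windows[i] else revcomp(windows[i])
      substr(genome, starts[i], starts[i] + wlen - 1L) <- ins
    }
    # forward coordinate of the (window-strand) core G
    core_pos <- ifelse(strands == "+",
                       starts + core_idx - 1L,
                       starts + (wlen - core_idx))
    # no stray exact canonical minimal window anywhere else
    hitsF <- .find_fixed(genome, canon_min)
    hitsR <- .find_fixed(genome, revcomp(canon_min))
    planted_ok <- starts[targets == 36L]
    stray <- c(setdiff(hitsF, planted_ok[strands[targets == 36L] == "+"]),
               setdiff(hitsR, planted_ok[strands[targets == 36L] == "-"]))
    if (length(stray) > 0L) next
    realized <- vapply(seq_len(n), function(i) {
      w <- extract_window(genome, core_pos[i], strands[i],
                          arm_left = canonical$minimal_arm_left,
                          arm_right = canonical$minimal_arm_right,
                          circular = circular)
      identity_count(w, canonical, spans = "minimal")$count_minimal
    }, integer(1))
    weights <- if (identical(config$weights, "uniform"))
      rep(1 / n, n) else config$weights / sum(config$weights)
    sites <- data.frame(
      site_id = sprintf("S%02d", seq_len(n)),
      core_position = as.integer(core_pos), strand = strands,
      window = windows, target_count = targets,
      realized_count = realized, weight = weights,
      stringsAsFactors = FALSE
    )
    return(list(genome = genome, sites = sites, config = config,
                canonical = canonical))
  }
  stop("failed to generate a host free of stray canonical windows")
}

#' Generate a circular donor plasmid carrying attP
#'
#' @param config a [sim_config()].
#' @param canonical a [canonical_att()] object.
#' @return list with `sequence`, `attP_core` (1-based position of the G of
#'   the attP core GT on the plasmid), `canonical`.
#' @export
generate_plasmid <- function(config, canonical = canonical_att_synthetic()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  L <- config$plasmid_length
  attP <- canonical$attP
  pos <- max(2L, L %/% 3L)
  for (attempt in 1:25) {
    seqn <- .random_dna(L, config$gc_fraction)
    substr(seqn, pos, pos + nchar(attP) - 1L) <- attP
    if (length(.find_fixed(seqn, attP)) == 1L &&
        length(.find_fixed(seqn, revcomp(attP))) == 0L)
      return(list(sequence = seqn,
                  attP_core = pos + canonical$attP_core - 1L,
                  canonical = canonical))
  }
  stop("failed to generate a plasmid with a unique attP")
}

# rotate the circular plasmid so it starts just after its core T and ends
# with its own core GT: the linear segment inserted 3' of the host core.
.plasmid_insert <- function(plasmid, attP_core) {
  L <- nchar(plasmid)
  g <- attP_core
  paste0(substr(plasmid, wrap1(g + 2L, L), L), substr(plasmid, 1L, g + 1L))
}

# integrate the (circular) plasmid at one site of the host, returning the
# post-integration genome and the 1-based start of the inserted segment.
.integrate_at <- function(host, core_position, strand, insert) {
  L <- nchar(host)
  if (strand == "+") {
    g <- core_position
    list(genome = paste0(substr(host, 1L, g + 1L), insert,
                         substr(host, g + 2L, L)),
         insert_start = g + 2L)
  } else {
    # forward view of a minus-strand site: the core reads "AC" with the C at
    # core_position; the cut falls before the A so the plasmid's own AC lands
    # on those coordinates and the host AC reappears at the right junction
    m <- core_position
    list(genome = paste0(substr(host, 1L, m - 2L), revcomp(insert),
                         substr(host, m - 1L, L)),
         insert_start = m - 1L)
  }
}

#' Simulate integration transformants
#'
#' Each transformant independently selects one planted site with probability
#' proportional to its weight, and the plasmid integrates there by the
#' attL/attR rule: the host is cut inside the core GT so the post-integration
#' genome reads B_left + GT + P_right ... plasmid body ... P_left + GT +
#' B_right (reverse-complemented as a block for minus-strand sites). Clean
#' insertion: the post genome is exactly host + plasmid in length.
#'
#' @param host result of [generate_host()].
#' @param plasmid result of [generate_plasmid()].
#' @param config a [sim_config()] (defaults to the host's).
#' @return list with `truth` (one row per transformant: `transformant_id`,
#'   `reaction`, `site_id`, `core_position`, `strand`, `insert_start`,
#'   `attL`, `attR`) and `genomes` (named character vector of
#'   post-integration assemblies).
#' @export
simulate_transformants <- function(host, plasmid, config = host$config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_transformants
  sites <- host$sites
  if (n > 0L && nrow(sites) == 0L)
    stop("cannot simulate transformants without planted sites")
  set.seed(config$seed + 2L)
  canonical <- host$canonical
  circular <- config$topology == "circular"
  insert <- .plasmid_insert(plasmid$sequence, plasmid$attP_core)
  attP_w <- canonical_attP_window(canonical,
                                  arm_left = canonical$minimal_arm_left,
                                  arm_right = canonical$minimal_arm_right)
  pick <- if (n > 0L)
    sample.int(nrow(sites), n, replace = TRUE, prob = sites$weight) else integer(0)
  genomes <- character(0)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    s <- sites[pick[i], ]
    res <- .integrate_at(host$genome, s$core_position, s$strand, insert)
    attB_w <- extract_window(host$genome, s$core_position, s$strand,
                             arm_left = canonical$minimal_arm_left,
                             arm_right = canonical$minimal_arm_right,
                             circular = circular)
    pr <- reconstruct_att_products(attB_w, attP_w)
    id <- sprintf("T%03d", i)
    genomes[id] <- res$genome
    rows[[i]] <- data.frame(
      transformant_id = id,
      reaction = sprintf("R%02d", ((i - 1L) %% config$n_reactions) + 1L),
      site_id = s$site_id, core_position = s$core_position,
      strand = s$strand, insert_start = res$insert_start,
      attL = pr$attL, attR = pr$attR, stringsAsFactors = FALSE
    )
  }
  truth <- if (n > 0L) do.call(rbind, rows) else
    data.frame(transformant_id = character(0), reaction = character(0),
               site_id = character(0), core_position = integer(0),
               strand = character(0), insert_start = integer(0),
               attL = character(0), attR = character(0),
               stringsAsFactors = FALSE)
  rownames(truth) <- NULL
  list(truth = truth, genomes = genomes)
}
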
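#' Run the full pseudo-att site analysis pipeline
#'
#' Orchestrates the end-to-end analysis: simulate (or load) transformant
#' assemblies, detect insertion junctions against the host reference,
#' collate events into a site table, build the pseudo-att site motif from
#' the unique site windows, scan the reference for candidate sites at the
#' configured p-value threshold, and project total site richness from the
#' event multiplicities. All artifacts are written into `outdir`; the
#' returned report contains every table plus a provenance block, and is
#' byte-reproducible from the same config and seed.
#'
#' @param config either the path of a YAML config file (see
#'   [read_config()]) or a list with elements `canonical`, `sim`, `detect`,
#'   `scan`, `richness`.
#' @param outdir output directory (created if needed); `NULL` writes
#'   nothing.
#' @param seed overrides the simulation seed in the config.
#' @return a `pipeline_report` list: `sites`, `events`, `motif`, `hits`,
#'   `richness`, `truth` (when simulated), `provenance`.
#' @export
run_pipeline <- function(config, outdir = NULL, seed = NULL) {
  if (is.character(config)) config <- read_config(config)
  canonical <- config$canonical %||% canonical_att_synthetic()
  sim <- config$sim
  if (is.null(sim)) stop("run_pipeline currently requires a simulation block")
  if (!is.null(seed)) sim$seed <- as.integer(seed)
  detect_par <- config$detect %||% list()
  scan_par <- config$scan %||% list()

  host <- generate_host(sim, canonical)
  plasmid <- generate_plasmid(sim, canonical)
  tr <- simulate_transformants(host, plasmid, sim)
  circular <- sim$topology == "circular"

  events <- find_insertions(tr$genomes, host$genome, plasmid$sequence,
                            anchor_k = detect_par$anchor_k %||% 21L,
                            circular_reference = circular,
                            min_run = detect_par$min_run %||% 3L,
                            flank = detect_par$flank %||% 30L,
                            plasmid_attP_core = find_attP(plasmid$sequence,
                                                          canonical))
  if (nrow(events) > 0L && nrow(tr$truth) > 0L)
    events$reaction <- tr$truth$reaction[match(events$transformant_id,
                                               tr$truth$transformant_id)]
  sites <- collate_sites(events, host$genome, canonical,
                         circular_reference = circular)

  motif <- NULL; hits <- NULL; rich <- NULL
  if (nrow(sites) >= 2L) {
    motif <- build_motif(sites$window_minimal,
                         pseudocount = scan_par$pseudocount %||% 0.5,
                         core_index = canonical$minimal_arm_left + 1L)
    hits <- scan_genome(host$genome, motif,
                        threshold = scan_par$threshold %||% 1e-8,
                        both_strands = scan_par$both_strands %||% TRUE,
                        circular = circular,
                        require_core = scan_par$require_core %||% FALSE,
                        genome_id = "host")
    rich <- richness_summary(sites$events)
  } else {
    warning("fewer than 2 sites detected: motif, scan and richness stages skipped")
  }

  report <- structure(list(
    sites = sites, events = events, motif = motif, hits = hits,
    richness = rich, truth = tr$truth,
    provenance = list(seed = sim$seed, n_transformants = sim$n_transformants,
                      genome_length = sim$genome_length,
                      n_planted_sites = sim$n_sites,
                      canonical = canonical$provenance,
                      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  ), class = "pipeline_report")

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(stats::setNames(host$genome, "host circular=true"),
                file.path(outdir, "host.fasta"))
    write_fasta(stats::setNames(plasmid$sequence, "plasmid circular=true"),
                file.path(outdir, "plasmid.fasta"))
    write_fasta(tr$genomes, file.path(outdir, "transformants.fasta"))
    write_tsv(tr$truth, file.path(outdir, "truth_transformants.tsv"))
    write_tsv(host$sites, file.path(outdir, "truth_sites.tsv"))
    write_tsv(events, file.path(outdir, "events.tsv"))
    write_tsv(sites, file.path(outdir, "site_table.tsv"))
    if (nrow(sites) > 0L) {
      al <- canonical$minimal_arm_left; ar <- canonical$minimal_arm_right
      write_bed(data.frame(
        chrom = "host",
        start = ifelse(sites$strand == "+", sites$core_position - al,
                       sites$core_position - 1L - ar),
        end = ifelse(sites$strand == "+", sites$core_position + 1L + ar,
                     sites$core_position + al),
        name = sites$site_id, score = sites$events, strand = sites$strand
      ), file.path(outdir, "sites.bed"))
      write_sites_gff3(sites, file.path(outdir, "sites.gff3"),
                       seqid = "host", canonical = canonical)
    }
    if (!is.null(motif))
      write_meme_motif(motif, file.path(outdir, "motif.meme.txt"))
    if (!is.null(hits)) write_tsv(hits, file.path(outdir, "scan_hits.tsv"))
    if (!is.null(rich)) {
      write_tsv(as.data.frame(rich$curve),
                file.path(outdir, "rarefaction_curve.tsv"))
      jsonlite::write_json(list(
        S_obs = rich$abundance$S_obs, N = rich$abundance$N,
        F1 = rich$abundance$F1, F2 = rich$abundance$F2,
        chao1_classic = rich$chao1_classic,
        chao1_bias_corrected = rich$chao1_bias_corrected,
        asymptote_S_max = if (!is.null(rich$asymptote)) rich$asymptote$S_max
      ), file.path(outdir, "richness.json"), auto_unbox = TRUE, digits = NA)
    }
  }
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("pipeline report\n")
  cat(sprintf("  events: %d over %d transformants\n",
              nrow(x$events), length(unique(x$events$transformant_id))))
  cat(sprintf("  sites: %d\n", nrow(x$sites)))
  if (!is.null(x$motif))
    cat(sprintf("  motif: width %d from %d sites\n",
                x$motif$width, x$motif$nsites))
  if (!is.null(x$hits)) cat(sprintf("  scan hits: %d\n", nrow(x$hits)))
  if (!is.null(x$richness)) {
    cat(sprintf("  richness: S_obs %d, Chao1 %.2f (bc %.2f)",
                x$richness$abundance$S_obs,
                x$richness$chao1_classic %||% NA_real_,
                x$richness$chao1_bias_corrected))
    if (!is.null(x$richness$asymptote))
      cat(sprintf(", asymptote %.2f", x$richness$asymptote$S_max))
    cat("\n")
  }
  invisible(x)
}
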
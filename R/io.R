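# Readers and writers for the external formats the pipeline touches.
# Conventions: BED is 0-based half-open; TSV/GFF3 and all human-readable
# reports are 1-based inclusive; every writer is deterministic byte-for-byte
# for identical inputs.

#' Read a FASTA file
#'
#' Sequences are upper-cased on read. A `circular=true` token in a record's
#' description marks it circular; everything else is linear.
#'
#' @param path FASTA file path.
#' @return data.frame with `id`, `description`, `sequence`, `topology`.
#' @export
read_fasta <- function(path) {
  empty <- data.frame(id = character(0), description = character(0),
                      sequence = character(0), topology = character(0),
                      stringsAsFactors = FALSE)
  if (file.size(path) == 0L) {
    warning("empty FASTA file: ", path)
    return(empty)
  }
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0L) {
    warning("no records in FASTA file: ", path)
    return(empty)
  }
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  descs <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids))
    stop("duplicate FASTA ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  data.frame(
    id = ids, description = descs,
    sequence = toupper(unname(as.character(set))),
    topology = ifelse(grepl("circular=true", descs, fixed = TRUE),
                      "circular", "linear"),
    stringsAsFactors = FALSE
  )
}

#' Write sequences to FASTA
#'
#' @param records data.frame with `id`, `sequence` and optionally
#'   `description` / `topology` (circular topology is recorded as a
#'   `circular=true` description token), or a named character vector.
#' @param path output path.
#' @param width line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  if (is.character(records))
    records <- data.frame(id = names(records), sequence = unname(records),
                          stringsAsFactors = FALSE)
  desc <- records$description %||% rep("", nrow(records))
  if (!is.null(records$topology)) {
    add <- records$topology == "circular" &
      !grepl("circular=true", desc, fixed = TRUE)
    desc[add] <- trimws(paste(desc[add], "circular=true"))
  }
  set <- Biostrings::DNAStringSet(records$sequence)
  names(set) <- trimws(paste(records$id, desc))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Write a motif in MEME text format (version 4)
#'
#' @param motif a `motif_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_meme_motif <- function(motif, path) {
  con <- file(path, "w")
  on.exit(close(con))
  bg <- motif$background
  writeLines(c(
    "MEME version 4", "",
    "ALPHABET= ACGT", "",
    "strands: + -", "",
    "Background letter frequencies",
    sprintf("A %.6f C %.6f G %.6f T %.6f", bg["A"], bg["C"], bg["G"], bg["T"]),
    "",
    paste("MOTIF", motif$name),
    sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
            motif$width, motif$nsites)
  ), con)
  writeLines(apply(motif$probs, 2, function(p)
    sprintf(" %.6f %.6f %.6f %.6f", p[1], p[2], p[3], p[4])), con)
  invisible(path)
}

#' Read a motif from MEME text format
#'
#' Accepts version 4 minimal motif files with a background line. Letter
#' probability rows must each sum to 1 within 1e-4.
#'
#' @param path MEME motif file.
#' @param pseudocount stored on the returned model (metadata only; the
#'   probabilities are taken from the file as-is).
#' @return a `motif_model` (counts reconstituted as probs * nsites).
#' @export
read_meme_motif <- function(path, pseudocount = 0) {
  lines <- readLines(path)
  if (!any(grepl("^MEME version", lines)))
    stop("not a MEME motif file (missing version header): ", path)
  bg <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  bgi <- grep("^Background letter frequencies", lines)
  if (length(bgi) == 1L && bgi < length(lines)) {
    tok <- strsplit(trimws(lines[bgi + 1L]), "\\s+")[[1]]
    vals <- as.numeric(tok[seq(2, length(tok), by = 2)])
    names(vals) <- tok[seq(1, length(tok), by = 2)]
    bg <- vals[DNA_BASES]
  }
  mi <- grep("^MOTIF\\b", lines)
  if (length(mi) == 0L) stop("no MOTIF block in ", path)
  name <- strsplit(trimws(lines[mi[1]]), "\\s+")[[1]][2]
  hi <- grep("^letter-probability matrix:", lines)
  if (length(hi) == 0L) stop("no letter-probability matrix in ", path)
  hdr <- lines[hi[1]]
  getf <- function(key) {
    m <- regmatches(hdr, regexec(paste0(key, "=\\s*(\\S+)"), hdr))[[1]]
    if (length(m) < 2L) NA else as.numeric(m[2])
  }
  w <- getf("w"); nsites <- getf("nsites")
  if (is.na(w)) stop("malformed matrix header in ", path)
  if (is.na(nsites)) nsites <- 20
  rows <- lines[(hi[1] + 1L):(hi[1] + w)]
  probs <- t(vapply(rows, function(r)
    as.numeric(strsplit(trimws(r), "\\s+")[[1]]), numeric(4)))
  if (any(abs(rowSums(probs) - 1) > 1e-4))
    stop("letter-probability rows do not sum to 1 in ", path)
  probs <- t(probs)
  dimnames(probs) <- list(DNA_BASES, NULL)
  structure(list(
    name = name, width = as.integer(w), counts = probs * nsites,
    probs = probs, log_odds = log2(probs / bg), nsites = as.integer(nsites),
    pseudocount = pseudocount, background = bg,
    core_columns = c(as.integer(w) %/% 2L, as.integer(w) %/% 2L + 1L),
    consensus = paste(DNA_BASES[apply(probs, 2, which.max)], collapse = "")
  ), class = "motif_model")
}

#' Write genomic features as BED
#'
#' BED is 0-based, half-open; the header comment states the convention.
#'
#' @param df data.frame with 1-based inclusive `start`, `end`, plus `chrom`,
#'   `name`, `score`, `strand` (missing columns get BED defaults).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path) {
  lines <- c("# BED: 0-based, half-open intervals",
             sprintf("%s\t%d\t%d\t%s\t%s\t%s",
                     df$chrom %||% "genome",
                     as.integer(df$start) - 1L, as.integer(df$end),
                     df$name %||% ".",
                     as.character(df$score %||% 0),
                     df$strand %||% "."))
  writeLines(lines, path)
  invisible(path)
}

#' Write a table as TSV (1-based coordinates)
#'
#' @param df data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# coordinates: 1-based, inclusive", con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv()] (or any comment-headed TSV)
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE)
}

#' Write site calls as GFF3 features on the reference
#'
#' @param sites site table from [collate_sites()] (needs `site_id`,
#'   `core_position`, `strand`); features span the minimal window.
#' @param path output path.
#' @param seqid reference sequence id.
#' @param canonical a [canonical_att()] giving the window arms.
#' @return `path`, invisibly.
#' @export
write_sites_gff3 <- function(sites, path, seqid = "genome",
                             canonical = canonical_att_synthetic()) {
  al <- canonical$minimal_arm_left; ar <- canonical$minimal_arm_right
  start <- ifelse(sites$strand == "+",
                  sites$core_position - al, sites$core_position - 1L - ar)
  end <- ifelse(sites$strand == "+",
                sites$core_position + 1L + ar, sites$core_position + al)
  lines <- c("##gff-version 3",
             "# coordinates: 1-based, inclusive",
             sprintf("%s\tattsites\tpseudo_attB_site\t%d\t%d\t%s\t%s\t.\tID=%s;events=%d",
                     seqid, start, end,
                     as.character(sites$events %||% "."),
                     sites$strand, sites$site_id,
                     sites$events %||% NA_integer_))
  writeLines(lines, path)
  invisible(path)
}

#' Read an analysis configuration (YAML)
#'
#' One schema covers the canonical att set, simulation, detection, scan and
#' richness parameters. Unknown keys anywhere in the schema are an error
#' (fail fast on typos). Canonical sequences may be inline strings or paths
#' to single-record FASTA files (relative to the config file).
#'
#' @param path YAML config file.
#' @return list with `canonical` (a [canonical_att()]), `sim` (a
#'   [sim_config()] if a simulation block is present), and the remaining
#'   blocks (`detect`, `scan`, `richness`) as lists of parameters.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known_top <- c("canonical", "sim", "detect", "scan", "richness", "inputs")
  .check_keys(cfg, known_top, "top level")
  base <- dirname(path)
  resolve_seq <- function(x, what) {
    if (is.null(x)) stop("config: canonical$", what, " is required")
    if (grepl("\\.(fa|fasta|fna)$", x, ignore.case = TRUE)) {
      p <- if (file.exists(x)) x else file.path(base, x)
      rec <- read_fasta(p)
      if (nrow(rec) != 1L) stop("config: ", p, " must hold a single record")
      rec$sequence
    } else toupper(x)
  }
  cb <- cfg$canonical
  if (is.null(cb)) stop("config: a 'canonical' block is required")
  .check_keys(cb, c("attB", "attB_core", "attP", "attP_core",
                    "minimal_arm_left", "minimal_arm_right",
                    "crossover_arm_left", "crossover_arm_right",
                    "provenance"), "canonical block")
  canonical <- canonical_att(
    attB = resolve_seq(cb$attB, "attB"), attB_core = cb$attB_core,
    attP = resolve_seq(cb$attP, "attP"), attP_core = cb$attP_core,
    minimal_arm_left = cb$minimal_arm_left %||% 17L,
    minimal_arm_right = cb$minimal_arm_right %||% 17L,
    crossover_arm_left = cb$crossover_arm_left %||% 3L,
    crossover_arm_right = cb$crossover_arm_right %||% 4L,
    provenance = cb$provenance %||% paste("config:", path)
  )
  sim <- NULL
  if (!is.null(cfg$sim)) {
    .check_keys(cfg$sim, c("seed", "genome_length", "gc_fraction", "n_sites",
                           "identity_counts", "weights", "plasmid_length",
                           "n_transformants", "n_reactions", "topology",
                           "min_separation"), "sim block")
    sim <- do.call(sim_config, cfg$sim)
  }
  if (!is.null(cfg$detect))
    .check_keys(cfg$detect, c("anchor_k", "min_run", "flank"), "detect block")
  if (!is.null(cfg$scan))
    .check_keys(cfg$scan, c("threshold", "granularity", "pseudocount",
                            "background", "require_core", "both_strands"),
                "scan block")
  if (!is.null(cfg$richness))
    .check_keys(cfg$richness, c("estimator", "n_grid"), "richness block")
  list(canonical = canonical, sim = sim,
       detect = cfg$detect %||% list(), scan = cfg$scan %||% list(),
       richness = cfg$richness %||% list(), inputs = cfg$inputs %||% list())
}

.check_keys <- function(x, known, where) {
  extra <- setdiff(names(x), known)
  if (length(extra) > 0L)
    stop("unknown config key(s) in ", where, ": ",
         paste(extra, collapse = ", "))
  invisible(TRUE)
}
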
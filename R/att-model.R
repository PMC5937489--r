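#' Extract a GT-core-anchored window from a genome
#'
#' Pulls the sequence of an att-site candidate out of a genome, anchored on
#' the forward-strand coordinate of the G of the core GT dinucleotide. For
#' minus-strand sites the returned sequence is the reverse complement of the
#' forward strand, so that in the window's own orientation the core reads
#' "GT" with `arm_left` nt to its left. The reported `core_position` is
#' always the forward-strand coordinate of the base pairing with the G of
#' the (window-strand) core.
#'
#' @param genome character scalar, the genome sequence.
#' @param core_position 1-based forward-strand coordinate of the G of the
#'   core (for minus-strand sites: the forward-strand position of the C that
#'   pairs with the core G).
#' @param strand `"+"` or `"-"`.
#' @param arm_left,arm_right nt either side of the core dinucleotide, in the
#'   window's own orientation.
#' @param circular is the genome circular? Windows then wrap the origin.
#' @param genome_id identifier carried into the result.
#' @return an object of class `att_window`: list with `sequence`,
#'   `genome_id`, `core_position`, `strand`, `arm_left`, `arm_right`,
#'   `core_ok` (TRUE when the core dinucleotide is GT) and `warning`.
#' @export
extract_window <- function(genome, core_position, strand = "+",
                           arm_left = 17L, arm_right = 17L,
                           circular = FALSE, genome_id = "") {
  stopifnot(strand %in% c("+", "-"), arm_left >= 0L, arm_right >= 0L)
  n <- nchar(genome)
  if (core_position < 1L || core_position > n)
    stop("core_position ", core_position, " outside genome of length ", n)
  if (strand == "+") {
    start <- core_position - arm_left
    end <- core_position + 1L + arm_right
  } else {
    start <- core_position - 1L - arm_right
    end <- core_position + arm_left
  }
  if (!circular && (start < 1L || end > n))
    stop("window [", start, ", ", end, "] out of bounds on linear genome of length ", n)
  seq <- subseq_circular(toupper(genome), start, end)
  if (strand == "-") seq <- revcomp(seq)
  core <- substr(seq, arm_left + 1L, arm_left + 2L)
  w <- structure(list(
    sequence = seq, genome_id = genome_id,
    core_position = as.integer(core_position), strand = strand,
    arm_left = as.integer(arm_left), arm_right = as.integer(arm_right),
    core_ok = identical(core, "GT"),
    warning = if (identical(core, "GT")) NA_character_ else
      paste0("core dinucleotide is '", core, "', not 'GT'")
  ), class = "att_window")
  w
}

#' Build an att_window from a bare sequence
#'
#' Convenience constructor for windows that already exist as strings
#' (e.g. transcribed from the literature): the core GT position within the
#' string defines the arms.
#'
#' @param sequence window sequence.
#' @param core_index 1-based index of the G of the core within `sequence`;
#'   default centres the core (index `nchar/2` for even widths).
#' @param genome_id,core_position,strand optional provenance fields.
#' @return an `att_window`.
#' @export
att_window <- function(sequence, core_index = nchar(sequence) %/% 2L,
                       genome_id = "", core_position = NA_integer_,
                       strand = "+") {
  sequence <- toupper(sequence)
  arm_left <- core_index - 1L
  arm_right <- nchar(sequence) - core_index - 1L
  stopifnot(arm_left >= 0L, arm_right >= 0L)
  core <- substr(sequence, core_index, core_index + 1L)
  structure(list(
    sequence = sequence, genome_id = genome_id,
    core_position = as.integer(core_position), strand = strand,
    arm_left = as.integer(arm_left), arm_right = as.integer(arm_right),
    core_ok = identical(core, "GT"),
    warning = if (identical(core, "GT")) NA_character_ else
      paste0("core dinucleotide is '", core, "', not 'GT'")
  ), class = "att_window")
}

#' @export
print.att_window <- function(x, ...) {
  cat(sprintf("att window [%s%s:%s] arms %d+2+%d\n  %s\n",
              x$genome_id, ifelse(is.na(x$core_position), "",
                                  paste0(":", x$core_position)),
              x$strand, x$arm_left, x$arm_right, x$sequence))
  if (!x$core_ok) cat("  !", x$warning, "\n")
  invisible(x)
}

# core-anchored positional match count between two sequences over arms (l, r)
# around their respective core indices; non-ACGT never matches.
.count_matches <- function(seq_a, core_a, seq_b, core_b, l, r) {
  a <- seq_chars(toupper(substr(seq_a, core_a - l, core_a + 1L + r)))
  b <- seq_chars(toupper(substr(seq_b, core_b - l, core_b + 1L + r)))
  stopifnot(length(a) == l + r + 2L, length(b) == l + r + 2L)
  sum(a == b & a %in% DNA_BASES)
}

#' GT-core-anchored identity statistic
#'
#' Counts identical nucleotide positions between a candidate window and the
#' canonical attB over three nested spans — the full attB (73 bp in the BT1
#' system), the minimal window (36 bp), and the crossover window (9 bp) —
#' after superposing the two core GT dinucleotides. No gaps and no shifting:
#' integration is observed to be precise, so the comparison is strictly
#' positional. Counts are the primary statistic; integer percentages
#' (round half up) are attached for the full and minimal spans.
#'
#' @param query an [att_window] whose arms cover every requested span
#'   (extract at full-attB width to score the full span).
#' @param canonical a [canonical_att()] object.
#' @param spans which spans to score (default all three).
#' @return an object of class `identity_report`: `count_full`, `pct_full`,
#'   `count_minimal`, `pct_minimal`, `count_crossover`, plus the span widths.
#'   Unscored spans are `NA`.
#' @export
identity_count <- function(query, canonical,
                           spans = c("full", "minimal", "crossover")) {
  stopifnot(inherits(query, "att_window"), inherits(canonical, "canonical_att"))
  spans <- match.arg(spans, several.ok = TRUE)
  qcore <- query$arm_left + 1L
  arms <- list(
    full = c(canonical$full_arm_left, canonical$full_arm_right),
    minimal = c(canonical$minimal_arm_left, canonical$minimal_arm_right),
    crossover = c(canonical$crossover_arm_left, canonical$crossover_arm_right)
  )
  out <- list(count_full = NA_integer_, pct_full = NA_integer_,
              count_minimal = NA_integer_, pct_minimal = NA_integer_,
              count_crossover = NA_integer_,
              span_full = NA_integer_, span_minimal = NA_integer_,
              span_crossover = NA_integer_)
  for (s in spans) {
    l <- arms[[s]][1]; r <- arms[[s]][2]
    if (query$arm_left < l || query$arm_right < r)
      stop("query window arms (", query$arm_left, ",", query$arm_right,
           ") too short for span '", s, "' (needs ", l, ",", r,
           "); re-extract with wider arms")
    cnt <- .count_matches(query$sequence, qcore,
                          canonical$attB, canonical$attB_core, l, r)
    width <- l + 2L + r
    out[[paste0("count_", s)]] <- as.integer(cnt)
    out[[paste0("span_", s)]] <- width
    if (s %in% c("full", "minimal"))
      out[[paste0("pct_", s)]] <- as.integer(round_half_up(100 * cnt / width))
  }
  structure(out, class = "identity_report")
}

#' @export
print.identity_report <- function(x, ...) {
  fmt <- function(c, p, w) {
    if (is.na(c)) return("-")
    if (is.na(p)) sprintf("%d/%d", c, w) else sprintf("%d/%d (%d%%)", c, w, p)
  }
  cat("identity to canonical attB:",
      "full", fmt(x$count_full, x$pct_full, x$span_full),
      "| minimal", fmt(x$count_minimal, x$pct_minimal, x$span_minimal),
      "| crossover", fmt(x$count_crossover, NA, x$span_crossover), "\n")
  invisible(x)
}

#' Reconstruct attL/attR from an attB and an attP window
#'
#' Serine-integrase recombination exchanges strands inside the core GT
#' dinucleotide, producing hybrid junction sites: attL carries the attB left
#' arm and the attP right arm, attR the attP left arm and the attB right
#' arm, each around one copy of the shared core. Both inputs must carry GT
#' at their recorded core (matched cores are required for recombination).
#'
#' @param attB_window,attP_window [att_window] objects with core GT.
#' @return an object of class `att_products`: `attL`, `attR`, and the
#'   labelled `components` (B_left, B_right, P_left, P_right, core).
#' @export
reconstruct_att_products <- function(attB_window, attP_window) {
  stopifnot(inherits(attB_window, "att_window"),
            inherits(attP_window, "att_window"))
  if (!attB_window$core_ok)
    stop("attB window lacks the core GT: ", attB_window$warning)
  if (!attP_window$core_ok)
    stop("attP window lacks the core GT: ", attP_window$warning)
  b <- attB_window; p <- attP_window
  comp <- list(
    B_left = substr(b$sequence, 1L, b$arm_left),
    B_right = substr(b$sequence, b$arm_left + 3L, nchar(b$sequence)),
    P_left = substr(p$sequence, 1L, p$arm_left),
    P_right = substr(p$sequence, p$arm_left + 3L, nchar(p$sequence)),
    core = "GT"
  )
  structure(list(
    attL = paste0(comp$B_left, comp$core, comp$P_right),
    attR = paste0(comp$P_left, comp$core, comp$B_right),
    components = comp
  ), class = "att_products")
}

#' @export
print.att_products <- function(x, ...) {
  cat("attL:", x$attL, "\nattR:", x$attR, "\n")
  invisible(x)
}
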
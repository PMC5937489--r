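#' Canonical att-site configuration
#'
#' Bundles the reference attB/attP sequences of a serine-integrase system
#' together with the nested window geometry used for all site scoring: the
#' full attB (typically 73 bp), the minimal recombinogenic window (36 bp,
#' arms of 17 nt either side of the core), and the crossover window (9 bp)
#' shared between attB and attP. All cross-sequence comparison in this
#' package is anchored on the core GT dinucleotide at which strand exchange
#' occurs; no gapped alignment is ever performed.
#'
#' @param attB full-length canonical attB sequence (character scalar).
#' @param attB_core 1-based position of the G of the core GT within `attB`.
#' @param attP canonical attP sequence.
#' @param attP_core 1-based position of the G of the core GT within `attP`.
#' @param minimal_arm_left,minimal_arm_right nt either side of the core GT
#'   defining the minimal window (defaults 17/17, i.e. 36 bp).
#' @param crossover_arm_left,crossover_arm_right nt either side of the core
#'   defining the crossover window (defaults 3/4, i.e. 9 bp).
#' @param provenance free-text note on where the sequences came from.
#' @return an object of class `canonical_att`.
#' @seealso [canonical_att_synthetic()] for a ready-made synthetic example,
#'   [identity_count()] for the scoring that uses this geometry.
#' @export
canonical_att <- function(attB, attB_core, attP, attP_core,
                          minimal_arm_left = 17L, minimal_arm_right = 17L,
                          crossover_arm_left = 3L, crossover_arm_right = 4L,
                          provenance = "") {
  attB <- toupper(attB); attP <- toupper(attP)
  stopifnot(is.character(attB), length(attB) == 1L,
            is.character(attP), length(attP) == 1L)
  if (substr(attB, attB_core, attB_core + 1L) != "GT")
    stop("attB does not carry 'GT' at attB_core = ", attB_core)
  if (substr(attP, attP_core, attP_core + 1L) != "GT")
    stop("attP does not carry 'GT' at attP_core = ", attP_core)
  full_arm_left <- attB_core - 1L
  full_arm_right <- nchar(attB) - attB_core - 1L
  if (minimal_arm_left > full_arm_left || minimal_arm_right > full_arm_right)
    stop("minimal window not contained in full attB")
  if (crossover_arm_left > minimal_arm_left ||
      crossover_arm_right > minimal_arm_right)
    stop("crossover window not contained in minimal window")
  structure(list(
    attB = attB, attB_core = as.integer(attB_core),
    attP = attP, attP_core = as.integer(attP_core),
    full_arm_left = full_arm_left, full_arm_right = full_arm_right,
    minimal_arm_left = as.integer(minimal_arm_left),
    minimal_arm_right = as.integer(minimal_arm_right),
    crossover_arm_left = as.integer(crossover_arm_left),
    crossover_arm_right = as.integer(crossover_arm_right),
    provenance = provenance
  ), class = "canonical_att")
}

#' Synthetic canonical att set
#'
#' A fully synthetic attB/attP pair with the geometry of the BT1 system:
#' a 73 bp attB with the core GT at position 36, a 36 bp minimal window
#' (17 + 2 + 17), a 9 bp crossover window shared verbatim between attB and
#' attP, and a 49 bp attP. The arm sequences are invented (they carry a weak
#' inverted repeat, as att sites do) and are NOT the published BT1
#' sequences, which must be transcribed from the primary literature into a
#' config file for analyses of real data. This synthetic set is the default
#' for simulation, testing and examples.
#'
#' @return a [canonical_att()] object.
#' @export
canonical_att_synthetic <- function() {
  attB_left  <- "ACTGCAAGTTCACGGATCGGCTACTCATCGGGACT"          # 35 nt
  attB_right <- "AGTCCCGATGAGTAGCCGATCCGTGAACTTGCAGTC"         # 36 nt
  attP_left  <- "GGTACCATTCACTCGATCGGACT"                      # 23 nt
  attP_right <- "AGTCGATCGAGTGAATGGTACCGG"                     # 24 nt
  canonical_att(
    attB = paste0(attB_left, "GT", attB_right), attB_core = 36L,
    attP = paste0(attP_left, "GT", attP_right), attP_core = 24L,
    provenance = "synthetic stand-in sequences; geometry of the BT1 attB/attP system"
  )
}

#' @export
print.canonical_att <- function(x, ...) {
  cat("Canonical att set\n")
  cat(sprintf("  attB: %d nt, core GT at %d (arms %d/%d)\n",
              nchar(x$attB), x$attB_core, x$full_arm_left, x$full_arm_right))
  cat(sprintf("  minimal window: %d nt (arms %d/%d)\n",
              x$minimal_arm_left + 2L + x$minimal_arm_right,
              x$minimal_arm_left, x$minimal_arm_right))
  cat(sprintf("  crossover window: %d nt (arms %d/%d)\n",
              x$crossover_arm_left + 2L + x$crossover_arm_right,
              x$crossover_arm_left, x$crossover_arm_right))
  cat(sprintf("  attP: %d nt, core GT at %d\n", nchar(x$attP), x$attP_core))
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' Canonical minimal attB window
#'
#' @param canonical a [canonical_att()] object.
#' @return the minimal attB window as an [att_window] (core GT anchored).
#' @export
canonical_minimal_window <- function(canonical) {
  extract_window(canonical$attB, canonical$attB_core, strand = "+",
                 arm_left = canonical$minimal_arm_left,
                 arm_right = canonical$minimal_arm_right,
                 genome_id = "attB")
}

#' Canonical attP window with given arms
#'
#' @param canonical a [canonical_att()] object.
#' @param arm_left,arm_right arms around the attP core GT.
#' @return an [att_window].
#' @export
canonical_attP_window <- function(canonical, arm_left = 17L, arm_right = 17L) {
  extract_window(canonical$attP, canonical$attP_core, strand = "+",
                 arm_left = arm_left, arm_right = arm_right,
                 genome_id = "attP")
}
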
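# Position-weight-matrix motif machinery for GT-anchored att windows.
#
# The training windows are already aligned by their core GT, so the motif is
# simply the column profile of the aligned windows — no EM-style motif
# discovery is performed (a deliberate divergence from general-purpose motif
# finders, which must first align their input). P-values for scan scores are
# exact under an i.i.d. background, computed by dynamic programming over the
# discretized per-column score distributions.

#' Build a pseudo-att site motif from aligned windows
#'
#' Constructs a position frequency / log-odds model from GT-core-anchored
#' windows of equal width. By default one column is trimmed from each end of
#' 36 nt training windows to yield the 34-position motif centred on the core
#' GT (motif columns 17 and 18). Probabilities use a background-weighted
#' pseudocount: p = (count + pseudocount * background) / (n + pseudocount);
#' log-odds are log2(p / background).
#'
#' @param windows character vector of aligned window sequences, or a list of
#'   [att_window] objects (all same width, core at the same index).
#' @param pseudocount total pseudocount mass per column (default 0.5).
#' @param background named base frequencies (A,C,G,T), default uniform.
#' @param core_index 1-based index of the G of the core in the input
#'   windows; default `width/2` (18 for 36 nt windows).
#' @param width motif width after symmetric trimming (default
#'   `input width - 2`, i.e. 34 for 36 nt windows; use the input width to
#'   disable trimming).
#' @param name motif name for report/file output.
#' @return an object of class `motif_model`: `width`, `counts` (4 x width,
#'   rows A,C,G,T), `probs`, `log_odds`, `nsites`, `pseudocount`,
#'   `background`, `core_columns`, `consensus`.
#' @export
build_motif <- function(windows, pseudocount = 0.5, background = NULL,
                        core_index = NULL, width = NULL,
                        name = "pseudo_attB") {
  if (is.list(windows) && all(vapply(windows, inherits, logical(1), "att_window"))) {
    core_index <- core_index %||% (windows[[1]]$arm_left + 1L)
    windows <- vapply(windows, function(w) w$sequence, character(1))
  }
  windows <- toupper(windows)
  n <- length(windows)
  if (n < 2L) stop("need at least 2 windows to build a motif")
  w_in <- unique(nchar(windows))
  if (length(w_in) != 1L) stop("windows have inconsistent widths")
  core_index <- as.integer(core_index %||% (w_in %/% 2L))
  if (!all(substr(windows, core_index, core_index + 1L) == "GT"))
    stop("not all windows carry GT at core_index = ", core_index)
  width <- as.integer(width %||% (w_in - 2L))
  trim <- (w_in - width) %/% 2L
  if (trim < 0L || 2L * trim != w_in - width)
    stop("width must allow symmetric trimming of the input windows")
  if (trim > 0L) windows <- substr(windows, trim + 1L, w_in - trim)
  core_columns <- c(core_index - trim, core_index - trim + 1L)

  if (is.null(background)) {
    background <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  } else {
    background <- background[DNA_BASES]
    if (any(is.na(background)) || abs(sum(background) - 1) > 1e-9)
      stop("background must be named A,C,G,T frequencies summing to 1")
  }
  mat <- do.call(rbind, strsplit(windows, "", fixed = TRUE))
  counts <- apply(mat, 2, function(col) {
    tabulate(match(col, DNA_BASES), nbins = 4L)
  })
  dimnames(counts) <- list(DNA_BASES, NULL)
  probs <- (counts + pseudocount * background) / (n + pseudocount)
  log_odds <- log2(probs / background)
  consensus <- paste(DNA_BASES[apply(counts, 2, which.max)], collapse = "")
  structure(list(
    name = name, width = width, counts = counts, probs = probs,
    log_odds = log_odds, nsites = n, pseudocount = pseudocount,
    background = background, core_columns = core_columns,
    consensus = consensus
  ), class = "motif_model")
}

#' @export
print.motif_model <- function(x, ...) {
  cat(sprintf("motif '%s': width %d, %d sites, core GT at columns %d-%d\n",
              x$name, x$width, x$nsites, x$core_columns[1], x$core_columns[2]))
  cat("consensus:", x$consensus, "\n")
  cat(sprintf("information content: %.2f bits\n", sum(motif_ic(x))))
  invisible(x)
}

#' Per-column information content of a motif
#'
#' @param motif a `motif_model`.
#' @return numeric vector, bits per column: sum_a f_a * log2(f_a / b_a).
#' @export
motif_ic <- function(motif) {
  term <- motif$probs * motif$log_odds
  term[motif$probs == 0] <- 0  # lim p->0 of p*log(p) contribution
  colSums(term)
}

# integer (discretized) score matrix at the given granularity (bits/bin)
.int_scores <- function(motif, granularity) {
  round(motif$log_odds / granularity)
}

#' Exact null score distribution for a motif
#'
#' Discretizes the log-odds matrix to integer score bins and convolves the
#' per-column score distributions under the i.i.d. background by dynamic
#' programming, yielding the exact tail probability P(score >= s) for every
#' attainable discretized score. Scanning uses the same discretized scores,
#' so the p-values are exact for the discretized motif (discretization
#' resolution: `granularity` bits).
#'
#' @param motif a `motif_model`.
#' @param background base frequencies for the null (default: the motif's).
#' @param granularity score bin width in bits (default 1/1000).
#' @return an object of class `score_distribution`: `granularity`, `offset`
#'   (integer score of the first bin), `prob` (bin probabilities), `tail`
#'   (P(score >= bin)), `min_p` (smallest attainable p-value).
#' @export
exact_pvalues <- function(motif, background = motif$background,
                          granularity = 1e-3) {
  stopifnot(granularity > 0)
  background <- background[DNA_BASES]
  if (any(is.na(background)) || abs(sum(background) - 1) > 1e-9)
    stop("background must be named A,C,G,T frequencies summing to 1")
  S <- .int_scores(motif, granularity)
  lo <- sum(apply(S, 2, min)); hi <- sum(apply(S, 2, max))
  span <- hi - lo + 1L
  # dist[i] = P(partial score == lo_partial + i - 1); grow column by column
  dist <- 1
  off <- 0L
  for (j in seq_len(ncol(S))) {
    cmin <- min(S[, j])
    new <- numeric(length(dist) + max(S[, j]) - cmin)
    for (a in 1:4) {
      sh <- S[a, j] - cmin
      idx <- seq_along(dist) + sh
      new[idx] <- new[idx] + dist * background[a]
    }
    dist <- new
    off <- off + cmin
  }
  stopifnot(off == lo, length(dist) == span)
  tail <- rev(cumsum(rev(dist)))
  structure(list(granularity = granularity, offset = lo,
                 prob = dist, tail = tail, min_p = tail[length(tail)]),
            class = "score_distribution")
}

#' P-value of a discretized motif score
#'
#' @param sd a `score_distribution`.
#' @param int_score integer score(s) on the distribution's bin scale.
#' @return tail probability P(score >= int_score); 1 below the support,
#'   the minimum attainable p-value above it.
#' @export
score_pvalue <- function(sd, int_score) {
  i <- int_score - sd$offset + 1L
  i[i < 1L] <- 1L
  over <- i > length(sd$tail)
  p <- rep(NA_real_, length(i))
  p[!over] <- sd$tail[i[!over]]
  p[over] <- 0
  p
}

# smallest integer score whose tail probability is <= p (Inf if unattainable)
.score_threshold <- function(sd, p) {
  idx <- which(sd$tail <= p)
  if (length(idx) == 0L) return(Inf)
  sd$offset + idx[1] - 1L
}

# integer-score scan of one strand; returns starts and scores
.scan_strand <- function(codes, S, smin) {
  L <- length(codes); w <- ncol(S)
  n <- L - w + 1L
  if (n < 1L) return(list(start = integer(0), score = integer(0)))
  total <- numeric(n)
  bad <- logical(n)
  for (j in seq_len(w)) {
    cj <- codes[j:(n + j - 1L)]
    nas <- is.na(cj)
    bad <- bad | nas
    cj[nas] <- 1L
    total <- total + S[cbind(cj, j)]
  }
  total[bad] <- -Inf
  keep <- which(total >= smin)
  list(start = keep, score = as.integer(total[keep]))
}

#' Scan a genome for motif occurrences with exact p-values
#'
#' Slides the motif over both strands (circular genomes wrap the origin) and
#' reports every window whose exact background p-value is at or below the
#' threshold. Overlapping hits on opposite strands are both reported.
#' Windows containing non-ACGT characters are skipped.
#'
#' @param genome character scalar.
#' @param motif a `motif_model`.
#' @param threshold p-value cut-off (default 1e-8).
#' @param sd optional precomputed [exact_pvalues()] distribution.
#' @param background null base frequencies; default `"genome"` uses the
#'   mononucleotide frequencies of the scanned genome, or pass a named
#'   vector (e.g. the motif's uniform background).
#' @param both_strands scan the minus strand too (default TRUE).
#' @param circular does the genome wrap?
#' @param require_core report only windows carrying GT at the motif's core
#'   columns (in hit orientation); default FALSE.
#' @param granularity score discretization (bits) when `sd` is not supplied.
#' @param genome_id identifier for the output.
#' @return data.frame of hits sorted by start: `genome_id`, `start` (1-based
#'   forward-strand coordinate of the leftmost window base), `strand`,
#'   `score` (bits), `p_value`, `sequence` (in hit orientation).
#' @export
scan_genome <- function(genome, motif, threshold = 1e-8, sd = NULL,
                        background = "genome", both_strands = TRUE,
                        circular = FALSE, require_core = FALSE,
                        granularity = 1e-3, genome_id = "genome") {
  genome <- toupper(genome)
  L <- nchar(genome)
  w <- motif$width
  if (L < w) stop("genome shorter than motif width")
  if (identical(background, "genome")) {
    tab <- tabulate(match(seq_chars(genome), DNA_BASES), nbins = 4L)
    background <- stats::setNames(tab / sum(tab), DNA_BASES)
  }
  if (is.null(sd)) sd <- exact_pvalues(motif, background, granularity)
  S <- .int_scores(motif, sd$granularity)
  smin <- .score_threshold(sd, threshold)
  ext <- if (circular) paste0(genome, substr(genome, 1L, w - 1L)) else genome
  codes <- match(seq_chars(ext), DNA_BASES)
  res <- list()
  fwd <- .scan_strand(codes, S, smin)
  if (length(fwd$start)) {
    keep <- fwd$start <= L
    res[[1]] <- data.frame(start = fwd$start[keep], strand = "+",
                           int_score = fwd$score[keep])
  }
  if (both_strands) {
    rcodes <- match(seq_chars(revcomp(ext)), DNA_BASES)
    rev <- .scan_strand(rcodes, S, smin)
    if (length(rev$start)) {
      # window at rc position i covers forward [nchar(ext) - i - w + 2, ...]
      start_f <- nchar(ext) - rev$start - w + 2L
      if (circular) start_f <- wrap1(start_f, L)
      keep <- start_f >= 1L & start_f <= L
      res[[length(res) + 1L]] <- data.frame(start = start_f[keep],
                                            strand = "-",
                                            int_score = rev$score[keep])
    }
  }
  if (length(res) == 0L)
    return(data.frame(genome_id = character(0), start = integer(0),
                      strand = character(0), score = numeric(0),
                      p_value = numeric(0), sequence = character(0),
                      stringsAsFactors = FALSE))
  hits <- do.call(rbind, res)
  hits <- hits[!duplicated(hits[, c("start", "strand")]), , drop = FALSE]
  seqs <- vapply(seq_len(nrow(hits)), function(i) {
    s <- subseq_circular(genome, hits$start[i], hits$start[i] + w - 1L)
    if (hits$strand[i] == "-") revcomp(s) else s
  }, character(1))
  if (require_core) {
    cc <- motif$core_columns
    keep <- substr(seqs, cc[1], cc[2]) == "GT"
    hits <- hits[keep, , drop = FALSE]; seqs <- seqs[keep]
  }
  out <- data.frame(
    genome_id = genome_id, start = as.integer(hits$start),
    strand = hits$strand, score = hits$int_score * sd$granularity,
    p_value = score_pvalue(sd, hits$int_score), sequence = seqs,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}
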
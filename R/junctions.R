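# Insertion-junction detection from transformant assemblies.
#
# Strategy: classify every anchor k-mer of a contig as matching the host
# reference, the plasmid (either orientation), or nothing; maximal collinear
# runs of same-diagonal matches delineate host and plasmid segments, and each
# host -> plasmid -> host transition is one integration event. Because the
# 2 nt core is present in both host and plasmid at each boundary (and arm
# sequence may coincide further), the exact cut point is ambiguous over a
# few nt from runs alone; it is resolved by requiring the core dinucleotide
# simultaneously on the contig, on the reference at the mapped position and
# on the plasmid at the mapped (circular) position, taking the lowest
# reference coordinate when several positions qualify.

# collinear match runs of one classification vector; returns data.frame
.match_runs <- function(pos, n_k, modulus, circular) {
  i <- seq_len(n_k)
  diag <- if (circular) (pos - i) %% modulus else pos - i
  key <- ifelse(is.na(pos), "N", paste0("d", diag))
  r <- rle(key)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != "N"
  data.frame(start = starts[keep], len = r$lengths[keep],
             diag = as.integer(sub("^d", "", r$values[keep])),
             stringsAsFactors = FALSE)
}

.psi <- function(c, diag, L, circular) {
  p <- c + diag
  if (circular) wrap1(p, L) else p
}

#' Detect plasmid insertion events in transformant assemblies
#'
#' Recovers integration events from assembled transformant genomes by exact
#' anchor k-mer matching against the host reference and the donor plasmid.
#' Anchors shared between reference and plasmid, or repeated within the
#' reference, are masked (ambiguous). Each host/plasmid/host transition on a
#' contig yields one event whose reported position is the forward-strand
#' reference coordinate of the G of the shared core GT (the C it pairs with,
#' for minus-orientation insertions), resolved independently at the left and
#' right junction; an event is `precise` when both junctions resolve to the
#' same core, the insert length equals the plasmid length, and the host
#' flanks abut with no gain or loss beyond the shared core.
#'
#' Because attB and attP share their crossover sequence, the flanks on
#' either side of a junction can agree over several nt and, when the shared
#' region contains a second GT, the cut point is genuinely ambiguous from
#' the strings alone; supplying `plasmid_attP_core` (the annotated position
#' of the attP core GT on the vector) pins the plasmid-side mapping and
#' makes the placement exact. Without it, ties are broken toward the lower
#' reference coordinate.
#'
#' @param assemblies named character vector (or list) of contig sequences.
#' @param reference host reference genome (character scalar).
#' @param plasmid donor plasmid sequence (character scalar, circular).
#' @param anchor_k anchor k-mer length (>= 15; default 21).
#' @param circular_reference is the reference circular?
#' @param min_run minimum number of collinear anchors for a segment.
#' @param flank nt of context captured in the junction strings.
#' @param plasmid_attP_core optional 1-based position of the G of the attP
#'   core GT on `plasmid` (e.g. located with [find_attP()]).
#' @return data.frame of events: `transformant_id`, `ref_core_position`,
#'   `orientation`, `left_junction`, `right_junction`, `observed_attL`,
#'   `observed_attR`, `precise`, `notes`.
#' @export
find_insertions <- function(assemblies, reference, plasmid, anchor_k = 21L,
                            circular_reference = TRUE, min_run = 3L,
                            flank = 30L, plasmid_attP_core = NULL) {
  stopifnot(anchor_k >= 15L)
  reference <- toupper(reference); plasmid <- toupper(plasmid)
  k <- as.integer(anchor_k)
  L <- nchar(reference); LP <- nchar(plasmid)
  refx <- if (circular_reference)
    paste0(reference, substr(reference, 1L, k - 1L)) else reference
  kref <- kmerize(refx, k)
  plx <- paste0(plasmid, substr(plasmid, 1L, k - 1L))
  kpl <- kmerize(plx, k)
  qseq <- revcomp(plasmid)
  qx <- paste0(qseq, substr(qseq, 1L, k - 1L))
  kq <- kmerize(qx, k)
  # mask anchors shared between reference and plasmid (either orientation)
  shared <- intersect(kref, c(kpl, kq))
  if (length(shared) > 0L) {
    kref[kref %in% shared] <- NA_character_
    kpl[kpl %in% shared] <- NA_character_
    kq[kq %in% shared] <- NA_character_
  }
  # mask anchors repeated within the reference (ambiguous placement)
  dup <- unique(kref[duplicated(kref)])
  if (length(dup) > 0L) kref[kref %in% dup] <- NA_character_

  refc <- seq_chars(reference)
  plc <- seq_chars(plasmid)
  qc <- seq_chars(qseq)
  rat <- function(p) refc[if (circular_reference) wrap1(p, L) else p]
  pat <- function(p) plc[wrap1(p, LP)]
  qat <- function(p) qc[wrap1(p, LP)]

  pg <- plasmid_attP_core
  if (!is.null(pg)) {
    pg <- as.integer(pg)
    if (!(pat(pg) == "G" && pat(pg + 1L) == "T"))
      stop("plasmid does not carry GT at plasmid_attP_core = ", pg)
  }
  qa <- if (!is.null(pg)) LP - pg else NULL  # Q-coordinate of the attP core A

  # plasmid-side condition at a candidate boundary: either the mapped
  # position must be the annotated attP core (pinned), or the plasmid must
  # carry the core dinucleotide at the mapped position (content-based)
  pl_cond <- function(cpos, diag, side, orient) {
    m <- wrap1(cpos + diag, LP)
    if (!is.null(pg)) {
      want <- switch(paste0(orient, side),
                     "+L" = wrap1(pg + 2L, LP), "+R" = wrap1(pg + 1L, LP),
                     "-L" = wrap1(qa, LP), "-R" = wrap1(qa - 1L, LP))
      return(m == want)
    }
    switch(paste0(orient, side),
           "+L" = pat(m - 2L) == "G" && pat(m - 1L) == "T",
           "+R" = pat(m - 1L) == "G" && pat(m) == "T",
           "-L" = qat(m) == "A" && qat(m + 1L) == "C",
           "-R" = qat(m + 1L) == "A" && qat(m + 2L) == "C")
  }

  if (is.list(assemblies)) assemblies <- unlist(assemblies)
  if (length(assemblies) > 0L && is.null(names(assemblies)))
    names(assemblies) <- paste0("contig", seq_along(assemblies))

  out <- list()
  for (tid in names(assemblies)) {
    contig <- toupper(assemblies[[tid]])
    n_k <- nchar(contig) - k + 1L
    if (n_k < 1L) next
    kc <- kmerize(contig, k)
    rpos <- match(kc, kref)
    ppos <- match(kc, kpl)
    qpos <- match(kc, kq)
    if (all(is.na(rpos)) && all(is.na(ppos)) && all(is.na(qpos))) {
      warning("contig '", tid, "' matches neither reference nor plasmid; skipped")
      next
    }
    hruns <- .match_runs(rpos, n_k, L, circular_reference)
    pruns <- .match_runs(ppos, n_k, LP, TRUE)
    qruns <- .match_runs(qpos, n_k, LP, TRUE)
    hruns <- hruns[hruns$len >= min_run, , drop = FALSE]
    pruns <- pruns[pruns$len >= min_run, , drop = FALSE]
    qruns <- qruns[qruns$len >= min_run, , drop = FALSE]
    segs <- rbind(
      if (nrow(hruns)) cbind(hruns, type = "H"),
      if (nrow(pruns)) cbind(pruns, type = "P"),
      if (nrow(qruns)) cbind(qruns, type = "Q")
    )
    if (is.null(segs) || nrow(segs) < 3L) next
    segs <- segs[order(segs$start), , drop = FALSE]
    contigc <- seq_chars(contig)
    nc <- nchar(contig)

    for (j in seq_len(nrow(segs) - 2L)) {
      if (segs$type[j] != "H" || segs$type[j + 2L] != "H") next
      mid <- segs$type[j + 1L]
      if (!(mid %in% c("P", "Q"))) next
      h1 <- segs[j, ]; pl <- segs[j + 1L, ]; h2 <- segs[j + 2L, ]
      orientation <- if (mid == "P") "+" else "-"
      cov1_end <- h1$start + h1$len - 1L + k - 1L
      pstart <- pl$start
      pend <- pl$start + pl$len - 1L + k - 1L
      cov2_start <- h2$start

      # ---- left junction ----
      tL <- NA_integer_; coreL <- NA_integer_
      for (t in seq.int(max(pstart - 1L, 2L), cov1_end)) {
        if (t + 1L > nc) break
        if (orientation == "+") {
          ok <- contigc[t - 1L] == "G" && contigc[t] == "T" &&
            rat(.psi(t - 1L, h1$diag, L, circular_reference)) == "G" &&
            rat(.psi(t, h1$diag, L, circular_reference)) == "T" &&
            pl_cond(t + 1L, pl$diag, "L", "+")
          if (ok) { tL <- t; coreL <- .psi(t - 1L, h1$diag, L, circular_reference); break }
        } else {
          if (t + 2L > nc) break
          y <- .psi(t, h1$diag, L, circular_reference)
          ok <- contigc[t + 1L] == "A" && contigc[t + 2L] == "C" &&
            rat(y + 1L) == "A" && rat(y + 2L) == "C" &&
            pl_cond(t + 1L, pl$diag, "L", "-")
          if (ok) { tL <- t; coreL <- if (circular_reference) wrap1(y + 2L, L) else y + 2L; break }
        }
      }

      # ---- right junction ----
      uR <- NA_integer_; coreR <- NA_integer_
      for (u in seq.int(max(cov2_start - 1L, 2L), pend)) {
        if (u + 1L > nc) break
        psi2 <- .psi(u + 1L, h2$diag, L, circular_reference)
        if (orientation == "+") {
          ok <- contigc[u - 1L] == "G" && contigc[u] == "T" &&
            pl_cond(u, pl$diag, "R", "+") &&
            rat(psi2 - 2L) == "G" && rat(psi2 - 1L) == "T"
          if (ok) { uR <- u; coreR <- if (circular_reference) wrap1(psi2 - 2L, L) else psi2 - 2L; break }
        } else {
          if (u + 2L > nc) break
          ok <- contigc[u + 1L] == "A" && contigc[u + 2L] == "C" &&
            rat(psi2) == "A" && rat(psi2 + 1L) == "C" &&
            pl_cond(u, pl$diag, "R", "-")
          if (ok) { uR <- u; coreR <- if (circular_reference) wrap1(psi2 + 1L, L) else psi2 + 1L; break }
        }
      }

      notes <- character(0)
      core <- NA_integer_
      precise <- FALSE
      if (!is.na(coreL) && !is.na(coreR)) {
        core <- coreL
        if (coreL != coreR) {
          notes <- c(notes, sprintf("junction cores disagree (%d vs %d)", coreL, coreR))
        } else if ((uR - tL) == LP) {
          precise <- TRUE
        } else {
          notes <- c(notes, sprintf("insert length %d != plasmid length %d",
                                    uR - tL, LP))
        }
      } else if (!is.na(coreL)) {
        core <- coreL; notes <- c(notes, "right junction unresolved")
      } else if (!is.na(coreR)) {
        core <- coreR; notes <- c(notes, "left junction unresolved")
      } else {
        notes <- c(notes, "boundaries unresolved")
      }

      jstr <- function(pos) {
        if (is.na(pos)) return(NA_character_)
        substr(contig, max(1L, pos - flank + 1L), min(nc, pos + flank))
      }
      obs_attL <- obs_attR <- NA_character_
      if (!is.na(tL) && !is.na(uR)) {
        ok_rng <- function(a, b) a >= 1L && b <= nc
        if (orientation == "+") {
          if (ok_rng(tL - 18L, tL + 17L))
            obs_attL <- substr(contig, tL - 18L, tL + 17L)
          if (ok_rng(uR - 18L, uR + 17L))
            obs_attR <- substr(contig, uR - 18L, uR + 17L)
        } else {
          # cores on the contig sit at t+2 (plasmid C, left junction / attR)
          # and u+2 (host C, right junction / attL)
          if (ok_rng(uR - 16L, uR + 19L))
            obs_attL <- revcomp(substr(contig, uR - 16L, uR + 19L))
          if (ok_rng(tL - 16L, tL + 19L))
            obs_attR <- revcomp(substr(contig, tL - 16L, tL + 19L))
        }
      }
      out[[length(out) + 1L]] <- data.frame(
        transformant_id = tid, ref_core_position = core,
        orientation = orientation,
        left_junction = jstr(tL), right_junction = jstr(uR),
        observed_attL = obs_attL, observed_attR = obs_attR,
        precise = precise,
        notes = paste(notes, collapse = "; "),
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(out) == 0L)
    return(data.frame(transformant_id = character(0),
                      ref_core_position = integer(0),
                      orientation = character(0),
                      left_junction = character(0),
                      right_junction = character(0),
                      observed_attL = character(0),
                      observed_attR = character(0),
                      precise = logical(0), notes = character(0),
                      stringsAsFactors = FALSE))
  ev <- do.call(rbind, out)
  # deduplicate repeated calls of the same event within a transformant
  ev <- ev[!duplicated(ev[, c("transformant_id", "ref_core_position",
                              "orientation")]), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

#' Collate insertion events into pseudo-attB site calls
#'
#' Groups events across transformants by identical (reference core position,
#' strand), assigns ordinal site ids by ascending genome position, and — when
#' the reference and a canonical att set are supplied — attaches the minimal
#' and full-width windows with their identity report. When events carry a
#' `reaction` label the number of distinct transformation reactions per site
#' is reported (multi-reaction sites cannot be sibling colonies); no event
#' is ever discarded.
#'
#' @param events data.frame as returned by [find_insertions()] (minimally:
#'   `transformant_id`, `ref_core_position`, `orientation`).
#' @param reference host genome (optional; enables window extraction).
#' @param canonical a [canonical_att()] (optional, with `reference`).
#' @param circular_reference is the reference circular?
#' @param id_prefix prefix for ordinal site ids.
#' @return data.frame with one row per site: `site_id`, `core_position`,
#'   `strand`, `events`, `transformants`, `n_reactions`, and (if scored)
#'   `window_minimal`, `window_full`, `count_full`, `pct_full`,
#'   `count_minimal`, `pct_minimal`, `count_crossover`.
#' @export
collate_sites <- function(events, reference = NULL, canonical = NULL,
                          circular_reference = TRUE, id_prefix = "S") {
  need <- c("transformant_id", "ref_core_position", "orientation")
  stopifnot(all(need %in% names(events)))
  if (nrow(events) == 0L) {
    return(data.frame(site_id = character(0), core_position = integer(0),
                      strand = character(0), events = integer(0),
                      transformants = character(0), n_reactions = integer(0),
                      stringsAsFactors = FALSE))
  }
  key <- paste(events$ref_core_position, events$orientation)
  groups <- split(events, key)
  pos <- vapply(groups, function(g) g$ref_core_position[1], numeric(1))
  ord <- order(pos)
  groups <- groups[ord]
  rows <- lapply(seq_along(groups), function(i) {
    g <- groups[[i]]
    data.frame(
      site_id = sprintf("%s-%02d", id_prefix, i),
      core_position = as.integer(g$ref_core_position[1]),
      strand = g$orientation[1],
      events = nrow(g),
      transformants = paste(sort(unique(g$transformant_id)), collapse = ","),
      n_reactions = if ("reaction" %in% names(g))
        length(unique(g$reaction)) else NA_integer_,
      stringsAsFactors = FALSE
    )
  })
  sites <- do.call(rbind, rows)
  rownames(sites) <- NULL
  if (!is.null(reference) && !is.null(canonical)) {
    win_min <- character(nrow(sites)); win_full <- character(nrow(sites))
    rep_cols <- matrix(NA_integer_, nrow(sites), 5,
                       dimnames = list(NULL, c("count_full", "pct_full",
                                               "count_minimal", "pct_minimal",
                                               "count_crossover")))
    for (i in seq_len(nrow(sites))) {
      wm <- extract_window(reference, sites$core_position[i], sites$strand[i],
                           arm_left = canonical$minimal_arm_left,
                           arm_right = canonical$minimal_arm_right,
                           circular = circular_reference)
      wf <- extract_window(reference, sites$core_position[i], sites$strand[i],
                           arm_left = canonical$full_arm_left,
                           arm_right = canonical$full_arm_right,
                           circular = circular_reference)
      rp <- identity_count(wf, canonical)
      win_min[i] <- wm$sequence; win_full[i] <- wf$sequence
      rep_cols[i, ] <- c(rp$count_full, rp$pct_full, rp$count_minimal,
                         rp$pct_minimal, rp$count_crossover)
    }
    sites$window_minimal <- win_min
    sites$window_full <- win_full
    sites <- cbind(sites, as.data.frame(rep_cols))
  }
  sites
}

#' Locate the attP core GT on a vector sequence
#'
#' Finds the canonical attP on a (circular) plasmid and returns the 1-based
#' position of the G of its core GT, for use as `plasmid_attP_core` in
#' [find_insertions()].
#'
#' @param plasmid plasmid sequence (character scalar, treated as circular).
#' @param canonical a [canonical_att()] object.
#' @return integer position, or `NA` (with a warning) when the attP is not
#'   found exactly once.
#' @export
find_attP <- function(plasmid, canonical) {
  plasmid <- toupper(plasmid)
  LP <- nchar(plasmid)
  attP <- canonical$attP
  plx <- paste0(plasmid, substr(plasmid, 1L, nchar(attP) - 1L))
  hits <- .find_fixed(plx, attP)
  hits <- unique(wrap1(hits, LP))
  if (length(hits) != 1L) {
    warning("canonical attP found ", length(hits), " times on the plasmid")
    return(NA_integer_)
  }
  wrap1(hits + canonical$attP_core - 1L, LP)
}
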
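---
title: "Methods: pseudo-attB site discovery, scoring and projection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pseudo-attB site discovery, scoring and projection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(attsites)
```

# The biological model

Serine integrases recombine two attachment sites, *attP* on the phage or
plasmid and *attB* in the host chromosome, by a cut-and-rejoin reaction
inside a central 2 nt core (GT here). Integration produces two hybrid
junction sites flanking the inserted DNA:

```
attB:  B_left  GT  B_right          attP:  P_left  GT  P_right
attL = B_left  GT  P_right          attR = P_left  GT  B_right
```

The reaction is unidirectional, precise (no bases gained or lost beyond
the exchange: the post-integration genome is exactly host + plasmid in
length), and requires matched cores but tolerates extensive mismatch
elsewhere — which is what makes *pseudo-attB* sites usable. `attsites`
encodes exactly this model and nothing more: every comparison between a
candidate site and the canonical attB superposes the two core GTs and
counts positionwise matches. No gapped or local alignment is ever
performed, because the phenomenon being modelled is gap-free.

## Window geometry and the identity statistic

A `canonical_att` object fixes the geometry once: the full attB (73 bp in
the reference system, core G at a configured offset), a minimal
recombinogenic window (36 bp = 17 + 2 + 17), and a crossover window (9 bp)
shared verbatim between attB and attP. `identity_count()` reports matched
positions over the three nested spans; integer counts are the primary
statistic and percentages (round half up) are cosmetic, since published
percentage roundings are not always self-consistent while counts are.
Non-ACGT characters never match. Windows are always GT-anchored: the
reported position of a site is the forward-strand coordinate of the G of
the core (of the pairing C, for minus-strand sites).

The canonical sequences shipped with the package
(`canonical_att_synthetic()`) are **synthetic stand-ins** with the correct
geometry — the published attB/attP sequences of a real integrase system
appear only in figure form in the primary literature and must be
transcribed by the user into a config file (`read_config()`; YAML was
chosen over other config formats because it is the idiomatic, pre-packaged
choice in R). The arm split of the 73 bp site around its core, and of the
9 bp crossover (3 + 2 + 4 here), are likewise configuration, not code: the
tool stays correct for any serine-integrase system.

# The synthetic survey

The simulator is the package's stand-in for a sequencing study: it
generates the data a pseudo-attB survey would produce, with full truth
tables, so detection, scoring, motif and richness stages can be validated
end-to-end.

* **Host genome**: i.i.d. bases at GC 0.68 (actinomycete-like), default
  200 kb and circular — a desk-scale stand-in for a ~9 Mb chromosome. The
  genome length only needs to dwarf the window size for the analysis to
  exercise every code path; tests and the acceptance script use 30–200 kb.
* **Planted sites**: default 20 sites, each a copy of the canonical
  minimal window with a seeded random subset of the 34 non-core positions
  mutated so that the realized match count *equals* the target exactly.
  Default targets are spread over 12–22 of 36, the identity range reported
  for real pseudo-attB sites; the core GT is never touched, mirroring its
  perfect conservation in observed sites. Sites land on either strand
  (Bernoulli 1/2), at least 100 nt apart, and the generator re-rolls if an
  exact canonical minimal window arises anywhere by chance.
* **Transformants**: default 27, attributed round-robin to 14 independent
  transformation reactions (the sampling structure of a real survey, where
  independent reactions rule out sibling colonies). Each transformant
  picks one site with probability proportional to its weight — uniform by
  default, because no quantitative site-preference model is established
  (observed preference is real but "not absolute"); the weight vector is
  an explicit simulation knob, not an estimate.
* **Integration** follows the attL/attR rule exactly; truth records the
  expected junction sequences and coordinates.

What the simulator does **not** emulate: sequencing errors, read-level
data, assembly fragmentation or collapse, repeats in the host genome, or
replicative (non-integrating) plasmids. Passing tests therefore certify
the algorithms on clean assemblies — the regime of curated, finished
transformant genomes — and say nothing about raw-read robustness.

# Junction detection

`find_insertions()` classifies every anchor k-mer (default k = 21, exact
match only) of a transformant contig as host-derived, plasmid-derived
(either orientation) or unknown; maximal collinear runs of one diagonal
define segments, and each host → plasmid → host transition is one event.
k = 21 makes random collisions negligible (4^21 ≈ 4 × 10^12) while
tolerating site-scale divergence; anchors shared between reference and
plasmid, or repeated within the reference, are masked as ambiguous.

The delicate part is placing the cut at base resolution. Both flanks of a
junction end in the same core dinucleotide (it is present in host *and*
plasmid), so the runs leave a few-nt ambiguity. The resolver demands the
core dinucleotide simultaneously on the contig, on the reference at the
mapped position, and on the plasmid at the mapped circular position.
One genuine degeneracy remains: attB and attP share their crossover
sequence, and when that shared flank contains a second GT, two cut
placements produce *byte-identical* contigs — no detector can distinguish
them from sequence alone. Supplying the annotated position of attP on the
vector (`find_attP()` locates it) pins the plasmid-side mapping and makes
placement exact; without it the tie is broken toward the lower reference
coordinate. An event is `precise` when both junctions resolve to the same
core and the insert length equals the plasmid length.

`collate_sites()` groups events by (core position, strand), orders sites
by position, attaches the 36/73 bp windows and identity reports, and
counts distinct transformation reactions per site without discarding any
event. Multi-insertion transformants yield multiple events by design.

# Motif model and exact p-values

Because training windows are already aligned by their core GT, the motif
is simply the column profile of the windows — deliberately replacing
EM-style motif discovery, whose alignment search is unnecessary here. The
default trims one column from each end of the 36 nt windows, giving a
34-position motif centred on the core (columns 17–18), the width at which
flanking positions still show conservation. Probabilities use a
background-weighted pseudocount, p = (count + 0.5·b) / (n + 0.5), and
log2 odds against the background; the default scan background is the
mononucleotide composition of the scanned genome (GC-rich genomes would
otherwise inflate scores of GC-poor motif columns), with uniform as an
option.

P-values are exact under an i.i.d. background: log-odds are discretized
to 1/1000-bit bins and the per-column score distributions are convolved by
dynamic programming, giving the full tail function P(score ≥ s) for the
discretized motif — scanning uses the same discretized scores, so reported
p-values are exact for the scanned statistic (resolution one bin). The
default reporting threshold of 1e-8 is the strict genome-scan cut-off at
which a ~10^7 bp genome yields a handful of hits. Scans cover both strands
(overlapping opposite-strand hits are both kept), wrap circular genomes,
skip windows containing non-ACGT characters, and can optionally require
the core GT in reported windows (`require_core`; off by default, since a
PWM scan does not inherently require it).

# Richness projection

Per-site event counts form an abundance vector. `rarefaction_curve()`
computes the exact hypergeometric expectation
E[S_n] = Σ_i (1 − C(N−x_i, n)/C(N, n)) in log space (no resampling
noise, no overflow). `chao1()` provides the classic and bias-corrected
closed forms, switching automatically (with a warning) when no doubletons
exist.

`fit_asymptote()` projects total richness from the curve. The default
model is the finite-pool accumulation form
S(n) = S_max (1 − (1 − 1/S_max)^n) — the exact expected richness when
events are drawn with replacement from S_max equally usable sites, i.e.
the generative model of this survey design. A generic saturating
hyperbola S(n) = S_max·n/(B+n) is available as `model = "michaelis"`, but
its tail is heavier than finite-pool sampling produces and its asymptote
runs systematically high when fitted to shallow surveys (in the package's
own recovery experiment — 500 replicates of 27 draws from a 40-site pool —
the hyperbola's median projection lands near 70 while the finite-pool
model's lands near 40); it is retained for curves that genuinely follow a
hyperbolic law. Both fits are deterministic: analytic start values,
bounded Levenberg–Marquardt, fixed tolerances, S_max bounded below by the
observed richness, and a flat curve short-circuits to S_obs.

No single published estimator is being reproduced here: abundance-based
richness projection from insertion multiplicities admits several
defensible estimators, which is why the summary reports Chao1 (both
forms) and the curve asymptote side by side, labelled.

# Numerical and interface conventions

* Coordinates: 1-based inclusive in every report and TSV/GFF3; BED output
  is 0-based half-open; each writer's header states its convention.
* All writers are byte-deterministic for identical inputs; motifs
  round-trip through MEME text format to 1e-6.
* Percentages round half up; counts are authoritative.
* Every stochastic routine takes its seed from configuration; identical
  config ⇒ byte-identical genomes, truth tables and reports.
* Degenerate inputs fail fast with instructive errors (windows too short
  for a span, targets below the invariant core, infeasible site packing,
  non-stochastic motif rows, unknown config keys).

# Problem sizes

The shipped tests and the acceptance script run the full stack at
desk scale, chosen to exercise every code path with comfortable margins:
hosts of 30–200 kb with 4–20 planted sites, surveys of 20–100
transformants, motif scans over 100–200 kb backgrounds, enumeration
oracles at motif width 6, and 500-replicate estimator-recovery
experiments. These sizes are the package's validation conditions, not
limits: the algorithms are linear in genome length (k-mer classification,
PWM scanning) and were chosen so a full survey analysis completes in
seconds to a couple of minutes on one core.

# Known limitations

* Exact-match anchoring assumes curated assemblies; diverged or
  error-containing contigs need a mismatch-tolerant anchor stage that is
  deliberately out of scope.
* The cut-point degeneracy within a shared crossover containing a second
  GT is information-theoretic, not algorithmic; supply the vector's attP
  position to remove it.
* The motif model is zeroth-order (independent columns, i.i.d.
  background); dinucleotide composition effects are not modelled.
* Richness projection inherits the usual caveats of abundance-based
  estimators at shallow sampling depth; with unequal site preference the
  finite-pool asymptote is a lower-biased summary of the usable-site
  count.
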
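---
title: "Inferring piRNA ping-pong and phased-biogenesis networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring piRNA ping-pong and phased-biogenesis networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pirnanet)
```

## The model

PIWI-interacting RNAs (piRNAs) are 24–29 nt small RNAs that guide PIWI
proteins to slice complementary transcripts. The slicer cut falls between
nucleotides 10 and 11 of the guide, so a piRNA made from the sliced
transcript starts exactly 10 nt into the guide's footprint: the 5' ends of
the guide and its product overlap by 10 nt. This geometric fact drives
everything the package computes.

Two amplification modes leave distinguishable traces:

* **Ping-pong amplification.** Reciprocal slicing between sense and
  antisense piRNAs from the same transcript. The trace is an excess of
  sense/antisense read pairs whose 5' ends overlap by exactly 10 nt,
  usually accompanied by uridine at guide position 1 (1U) on one strand
  and adenine at position 10 (10A) on the other — the 10A is simply the
  base that pairs with the partner's 1U.
* **Phased (trigger/responder/trail) biogenesis.** A *trigger* piRNA from
  one locus anneals — possibly with mismatches — to another transcript and
  directs its slicing. The first product, the *responder*, starts at the
  cleavage position (trigger 5' position − 9 on the target). Further
  fragmentation proceeds 3'-ward head-to-tail, yielding *trail* piRNAs
  with a strong 1U bias.

Transcripts that exchange piRNAs through either mode form networks: an
undirected graph of transcripts sharing identical ping-pong piRNAs (which
in practice means they share a genomic repeat), and a directed graph of
trigger targeting. When a responder can anneal back to the locus that
produced its trigger *at the trigger's own position*, the pair
amplifies reciprocally (trans-ping-pong); a back-target elsewhere is
reported with its signed distance from the trigger locus.

## The statistics

**Overlap histogram and z-score.** For one transcript, let $s(p)$ and
$a(q)$ be the (copy-weighted) numbers of sense and antisense reads whose
5' ends sit at positions $p$ and $q$. For overlap $d = 1..24$,

$$ c_d = \sum_p s(p)\, a(p + d - 1), $$

and the ping-pong score is the bin-10 z-score against all 24 bins,

$$ z_{10} = \frac{c_{10} - \bar c}{\sigma(c)}, $$

with the *population* standard deviation and bin 10 included in the
background. The window stops at 24 nt because that is the largest overlap
every 24-nt read can realize, so longer overlaps would be biased by read
length. A transcript is called significant when $z_{10} > 1.96$ (strictly)
and the window holds at least 30 pairs; with $\sigma = 0$ the score is
undefined and the transcript is flagged degenerate, never significant.
No multiple-testing correction is applied across transcripts by default;
the z-threshold is a per-transcript decision rule, not a family-wise test.

**Classification.** Significant transcripts whose ping-pong reads are
more than 95% genome-unique are `uniquePP` — the amplification is
*intrinsic* to a single locus; the rest are `repeatPP`, driven by
sequence shared with other loci. Genome multiplicity is the count of
exact occurrences of the read sequence in the genome, both strands.

**Event inference.** Trigger queries are genome-unique reads mapping an
mRNA or lncRNA sense at 0 mismatches (their origin is unambiguous).
Candidate targets are transcripts with > 3 RPM of genome-unique sense
piRNAs. Annealing sites are found by an ungapped reverse-complement scan
at 1–5 mismatches; responders are the sense reads at the implied cleavage
position, and events are retained when responder RPM exceeds 3. The seed
(guide positions 2–11) is profiled but not required to be perfect:
observed events tolerate mismatches there, while the pairing around
positions 10–11 is what fixes the cut site, even when pairing only starts
at guide position 2 or 3.

**RPM.** Every figure uses a single denominator: the number of reads of
the whole library mapping the genome with zero mismatches, in reads per
million. The sense/antisense ratio is reported as
$\log(\mathrm{Bs}/\mathrm{Bas})$, adding 0.06 to a zero numerator or
denominator so the ratio stays finite.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `min_len`, `max_len` | 24, 29 nt | putative piRNA size band |
| `z_thresh` | 1.96 | one-sided significance cut on $z_{10}$ (strict) |
| `min_pairs` | 30 | overlap-pair floor for a callable transcript |
| `dmax` | 24 nt | overlap window |
| `min_rpm_target` / `min_rpm_responder` | 3 RPM | candidate-target and event retention (strict >) |
| `mm_range` | 1–5 | trigger annealing mismatch bounds |
| `te_max_mm` | 3 | TE-matching tolerance |
| `flank_nt`, `flank_min_rpm` | 5000 nt, 0.5 RPM | producer-locus verification window and floor (strict >) |
| `bias_threshold` | 50% | 1U/10A bias call (strict >) |
| `unique_thresh` | 95% | `uniquePP` vs `repeatPP` boundary (strict >) |
| `trail_window` | 1000 nt | trail search window downstream of the cut |
| `rng_seed` | 1 | multimapper assignment seed |

The structural-RNA (bona fide) filter removes reads matching
miRNA/rRNA/snRNA/tRNA references exactly, in either orientation. Exact
matching is the minimal reproducible choice; the tolerance is a single
place in the code if a laxer rule is wanted, and removals are logged per
class so the effect is visible.

## Design choices worth knowing

* **Mismatch model.** Substitutions only (Hamming distance), no indels.
  Annealing windows are compared at every offset; correctness is
  preferred over index trickery because a seed anchor short enough to be
  lossless at 5 mismatches on a 24-nt query would be only 4 nt.
* **Coordinates.** 1-based inclusive on transcripts everywhere; a sense
  read's 5' is its lowest covered coordinate, an antisense read's 5' its
  highest, so the overlap is `antisense_5' − sense_5' + 1`. Negative
  overlaps (antisense 5' upstream) are not slicer-compatible and are not
  counted. BED input/output converts to 0-based half-open at the
  boundary; GFF3 is read as 1-based.
* **N bases** never match anything, including N — a conservative rule
  that cannot fabricate exact hits.
* **Pair counting unit.** Read copies (the non-collapsed library) by
  default; a `collapsed` switch weights each distinct sequence once.
  Both 1U/10A panels are always computed on both units, and the two are
  never silently mixed.
* **Multimapper assignment** is uniform per copy under one global seed,
  computed once and cached on the run object. Transcript profiles use
  the full alignment set (transcript mapping is a separate question from
  genomic origin); the assignment is exposed for genome-level tallies.
* **Trail phasing score.** The head-to-tail distance histogram
  (`d = next 5' − previous 3'`, bins 1–50) is scored with the same
  z-statistic as the ping-pong bin, applied to `d = 1`. No published
  formalization of the trail call exists, so this statistic is an
  artifact-defined surrogate and is labelled as such in outputs.
* **Event granularity.** Events are aggregated per (source transcript,
  target transcript, annealing site); a read may be responder in one
  event and trigger of another — no exclusivity, which is exactly how
  reciprocal amplification arises.
* **Network edges.** One shared ping-pong read sequence suffices for an
  edge (`min_shared = 1`, configurable upward); singleton components are
  not networks. Reciprocal directed trigger edges collapse into a single
  trans-ping-pong edge, keeping the direction of the earliest event.

## The synthetic generator

`make_world()` builds a genome with embedded transcripts and plants,
deterministically under one seed: (i) transcripts with intrinsic
ping-pong (40 planted pairs of unique sequence — comfortably above the
30-pair floor); (ii) three repeat families of 300 nt (within the
130–1130 nt range typical of shared repeats) copied into three host
transcripts each, giving three recoverable networks of genome-repeated
reads; (iii) one snetDNA-style network: a source transcript whose
trigger piRNAs (26-nt annealing sites, in the ~25–42 nt range of such
elements) target three transcripts with 2, 1 and 5 mismatches — one
plain one-way event, one with reciprocal complementarity at the trigger
locus (trans-ping-pong, which also yields the derived reciprocal event
in which the responder acts as a trigger), and one whose responders
back-target the source 113 nt downstream of the trigger locus.

Planting edits the transcript sequence and then extracts reads, so every
planted read maps its transcript at 0 mismatches by construction, and a
mismatched annealing site has exactly the configured Hamming distance.
One transcript nucleotide — the slicer-facing base — realizes both the
sense-10A and antisense-1U biases of a pair, so those two probabilities
are coupled in the generator (as they are in the biology). Trail reads
are chained head-to-tail (`d = 1`) with optional jitter and a 90% 1U
probability. Default depths: 20 copies per trigger, 60 per responder, 10
per trail read, single-copy ping-pong pairs.

What the generator does *not* emulate: sequencing error, adapter
remnants, quality scores, realistic TE families, low-complexity repeats,
or the long-tailed abundance distributions of real libraries. Passing
the recovery tests therefore demonstrates correctness of the geometry,
statistics and graph construction — not robustness to artifacts real
libraries would add upstream of this package.

## Problem sizes and numerical notes

The default world is intentionally desk-scale: a ~30 kb genome, 19
transcripts, ~400 distinct reads (~760 copies). The null calibration
uses 200 structureless transcripts with 40 reads per strand on 500 nt,
which yields ~77 expected pairs — enough that the 30-pair floor does not
mask the calibration. Degenerate inputs (empty strands, all-equal
histograms, loci without coordinates, windows running past transcript or
contig ends) return NA or truncated-and-flagged results rather than
errors; genuinely contradictory configuration (e.g. a repeat longer than
its host) errors at configuration time.

## Limitations

* Ungapped matching only; a bulged annealing site is invisible.
* The trail call is a surrogate statistic, not a validated detector.
* Transcript-level profiles count all alignments of multimappers, so a
  read shared by several transcripts contributes to each; the seeded
  random assignment is available where a partition is required.
* With `min_shared = 1`, a single chimeric read can bridge two networks;
  raise the floor for noisy libraries.
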
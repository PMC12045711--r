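---
title: "tigrkit: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{tigrkit: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tigrkit)
```

# The system being modelled

TIGR-Tas systems are compact RNA-guided DNA-targeting systems found mostly
in phages, archaeal viruses and parasitic bacteria. A **TIGR array** encodes
many short guides in one transcript; a Nop-domain effector protein (TasA,
or the nuclease fusions TasR/TasH) binds the processed guides. tigrkit
implements the sequence-level formal system: the array grammar, guide
maturation, the tandem-spacer targeting rule with its cleavage geometry,
guide design, and a ground-truthed synthetic-data generator. It makes no
attempt to model protein biology, cleavage kinetics, or cellular outcomes.

## Array grammar

A dual-repeat array is fully described by a `repeat_set`:

* `edge_repeat`, `loop_repeat` — two distinct repeats, 8–12 nt each. On
  the transcribed strand both begin with box D (`TG` in DNA) and end with
  box C (`CCA`) when `enforce_boxes = TRUE`. Detection never *requires*
  boxes (it records conformance), because the motifs can diverge in nature
  provided they covary between the two repeats.
* `spacer_len_a`, `spacer_len_b` — 8–12 nt, default 9 (the typical value;
  natural exceptions reach 12 nt).
* `processing_offset` *p* — where inside the edge repeat the maturation
  cut falls, `1 <= p < |edge|`, default `floor(|edge|/2)`. The true base is
  not resolvable from available evidence (the terminal guide bases are
  disordered in structures), so it is configurable; the default makes the
  mature unit span exactly one period.

The assembled body is `edge[p+1..] (sA loop sB edge)^(n-1) sA loop sB
edge[..p]`: a 5′-truncated edge, *n* units, a 3′-truncated edge, then
optionally a rho-independent terminator cassette. `assemble_array()` /
`parse_array()` are mutually inverse for every valid model (property
tested). The mature guide length equals the period
`|edge| + |loop| + |sA| + |sB|`; the packaged Ta-like set (edge 10, loop 8,
spacers 9 + 9, *p* = 5) gives 36 nt.

Coordinates are 1-based closed throughout the R API (the Bioconductor
convention); GFF3 output is 1-based, BED output 0-based half-open. Nick
positions use an "after base *i*" integer for the bond between bases *i*
and *i* + 1.

## Processing model

Processing is modelled as deterministic cuts at `processing_offset` inside
every full edge repeat plus the transcript termini; the responsible host
RNase is unknown and not modelled. `simulate_partial_processing()` cuts
each internal site independently with probability `completeness`, so
fragment lengths are multiples of the period with a 36/72/108-nt ladder;
the 72-nt fraction matches the exact enumeration over cut patterns (tested
against a 2^7 enumeration oracle). `processing_concordance()` scores read
intervals whose start *and* end fall within a tolerance of predicted cuts.
For stem-loop arrays the processing boundaries are variable in nature, so
mature units are reported as the hairpin unit rather than a fixed cut.

## Targeting and cleavage geometry

A guide is just its two spacers (`guide_pair`). A target site is a
contiguous dsDNA footprint of `a + gap + b` bp in which one spacer pairs
the bottom strand over the left region and the other pairs the top strand
over the right region, antiparallel Watson–Crick, spacer base 1 (the
box-C-proximal base) pairing its region's **outer** base. Both
assignments (A-left and B-left) are physical and scanned; the RNP is
C2-pseudosymmetric, so a palindromic footprint satisfying both is
reported once. Consequences that the test suite verifies as properties:

* spacer-swapped guides find identical sites (symmetric roles);
* reverse-complemented spacers find nothing;
* flanking sequence is irrelevant — there is no TAM/PAM;
* a guide never matches its own expression array (both spacers sit in
  tandem on one strand there), except the flagged corner case
  `spacer_a == revcomp(spacer_b)`.

**Cut placement.** The source evidence states the cut two ways ("cut 3′ to
the nucleotide complementary to the 5th base of the spacer" vs "cleaved 5′
to the nucleotide that pairs with the 5th base downstream of the C box"),
which differ by one phosphodiester bond under a naive reading. tigrkit
adopts the **C − 5 form** — the nick sits 5′ of the DNA base pairing
spacer base 5 — because only it reproduces the printed 8-nt 3′ overhang
for 9 + 9-nt spacers at zero gap: with both nicks 5 bases in from the
outer edges, overhang = `a + b + gap − 10`. The `8 + gap` overhang for
gapped sites is a model extrapolation, not a measured value.

**Mismatch rule table** (`mismatch_model`): literal positions from the
transversion-scan evidence, per spacer region, 1 = box-C-proximal:

| positions | name | effect of a mismatch |
|---|---|---|
| 4, 5 | seed | no cleavage of either strand |
| 6, 7 | nickase | only the mismatched strand uncleaved |
| 8 and 9 together | 5′ edge | no cleavage |
| others | tolerated | none (singly) |

Positions not mentioned by the evidence default to "tolerated"; the full
per-position quantitation in the source figures is not modelled. G:U
wobble pairing is off by default (no evidence either way). TasH is treated
identically to TasR (same cut position); whether the cut index shifts for
8-nt spacers is unknown, so index 5 is kept for all spacer lengths.

`brute_force_find_sites()` is a deliberately naive re-implementation
(explicit per-base complement checks over every offset, gap and
assignment) kept as an independent oracle; `find_sites()` must agree with
it exactly, which the acceptance suite checks over 200 randomized cases.

## De novo detection

`detect_dual_repeat_arrays()` follows a seed–resolve–refine contract:

1. **Seeding**: exact `k`-mer (default 7) recurrence at a constant lag
   within `period_range` (30–50 nt). Alignment-free seeding is justified
   because repeats are near-identical within a locus.
2. **Phase profile**: seeded matches are projected modulo the period;
   covered phase columns form circular arcs. Two grammar-consistent arcs
   give the two repeat families directly. If only one family is visible —
   e.g. every loop copy carries a substitution, which kills all exact
   k-mers in an 8-nt repeat — the second family is recovered from the
   per-column majority consensus of the inter-copy segments, scored with a
   per-column penalty so spacer columns (variable) cannot join the repeat
   window.
3. **Placement**: the locus region is re-parsed with the inferred repeat
   set under both edge/loop assignments; the assignment explaining more
   units wins (the wrong one loses the two boundary-truncated units).
   Truncated edges are then inferred by exact greedy extension, and a
   terminator is sought in the 60 nt downstream.
4. **Guards**: calls are rejected when the two families are identical,
   when phase arcs are wider than any legal repeat (homopolymers,
   microsatellites), or when spacers have > 0.9 mean pairwise identity
   (an ordinary tandem repeat, not a guide array). Overlapping candidates
   are resolved by units, then mean copy identity, then leftmost start.

Both strands are scanned; an array is periodic on both orientations, so
the orientation whose repeats carry the box grammar wins (default `+`).
With `min_units = 3` the lag evidence is thin (one edge pair); the
detector is designed for the natural 5–15-unit regime, and the acceptance
sweep uses 5–15 units. This is a documented limitation for 3–4-unit
arrays.

`detect_stem_loop_arrays()` uses the hairpin grammar directly: a unit is
`arm…CCA | spacer A | TG…CCA | spacer B | TGG…rc(arm)` with maximal
palindromic arms of at least `min_arm` (default 5 bp, mismatch-free — the
evidence gives no arm length, so this is configurable). Runs of units with
linkers under `max_linker` (default 150 nt) form one call; longer gaps
split sub-arrays, mirroring the 13-units-in-3-subarrays locus organization
with ~450-nt intergenic linkers.

`predict_terminator()` is intentionally a simple heuristic (stem >= 6 bp
with <= 1 mismatch, loop 3–8 nt, >= 4 T in the 8 nt downstream, score =
stem + T-count − 2·mismatches): it marks the array 3′ end, nothing more.

Intra-repeat Watson–Crick pair positions for `covariation_check()` are
user-configurable rather than fixed: the underlined pairing positions in
the source figure are not recoverable from text, so no specific pairs are
hard-coded beyond the box C/D defaults.

## The synthetic-data generator and what a green test establishes

`make_locus()`, `make_stem_loop_locus()`, `make_target_genome()` and
`make_reads()` are first-class, seed-deterministic generators whose
defaults state the modelled world: Ta-like repeat set, 8 units (natural
arrays have most often 5–15), 2-kb i.i.d. uniform background (GC knob
available), default truncations, terminator present, mutation-free unless
asked. Spacers are i.i.d. uniform with **identifiability constraints**,
chosen a priori so that planted truth is recoverable exactly rather than
to make any particular test pass:

* the background base 5′ of the array and the first terminator base do not
  extend the truncated edges (greedy boundary inference stops exactly at
  the planted boundary);
* no spacer column is near-unanimous across units (majority capped at
  `ceiling(n/2)`), and the first/last spacer columns never repeat between
  adjacent units — otherwise exact k-mer seeds bleed across the
  repeat/spacer boundary with probability 1/4 per junction and repeat
  boundaries become genuinely unidentifiable from the sequence;
* no loop-like match (within 2 mismatches) sits exactly one period beyond
  either array boundary, which would let a chain-based parser annex a
  phantom unit whose flanking half-edge matches the truncation by
  construction;
* stem-loop units get non-complementary flanking bases so maximal
  palindromic arms stop at the planted arm;
* `make_target_genome()` verifies with the brute-force oracle that the
  planted gap-tolerant perfect sites are the only ones, resampling the
  background otherwise.

What the generator does **not** emulate: real repeat sequences (the
packaged repeats are synthetic but grammar-conformant, since the natural
TaTIGR repeats appear only in figures), compositional bias and repeats of
real genomes, sequencing error, expression level, or array evolution. A
green detection test therefore establishes correctness of the algorithm on
grammar-conformant loci in neutral background — not metagenome-scale
sensitivity, which would need looser tolerances and external data.

## Numerical and interface choices

* Ties in detection resolve deterministically (units, identity, leftmost).
* `parse_array()` trims chain units at the array boundaries when no
  consistent edge copy accompanies them, and errors on interior
  inconsistency, reporting per-copy mismatch counts.
* Ambiguity codes are tolerated in backgrounds, rejected inside repeats
  and spacers; RNA inputs yield no DNA matches anywhere.
* Empty results are empty lists/data frames, never errors;
  `processing_concordance()` errors on empty evidence (a fraction of
  nothing is undefined).
* The terminator cassette appended by `assemble_array()` is a fixed
  perfect hairpin (8-bp GC stem, 4-nt loop, 7-T tract) — a stand-in
  synthetic terminator, not a natural sequence.

## Known limitations

Single-sequence (no multi-record FASTA walking in the core API, though the
CLI reads the first record); no probabilistic array-evolution model; no
HMM/profile discovery; no protein (ORF) detection; no efficiency ranking
of designed guides beyond rule-based warnings, because the evidence offers
no sequence-determinants-of-efficiency model; detection below 5 units is
best-effort; the partial complementarity pattern of the natural *wcaD*
off-target depends on figure-only sequences and is not encoded.
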
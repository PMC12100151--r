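---
title: "Profiling tandem-array instability from linearized-plasmid long reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling tandem-array instability from linearized-plasmid long reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The measurement model

A tandem gene array carried on a centromeric plasmid behaves like a
miniature chromosome: recombination between repeat units contracts or
expands the array, and the plasmid population accumulates molecules of
different array lengths. Cutting the circular plasmid at a unique
restriction site turns every molecule into a linear template

```
left_flank  +  k × repeat_unit  +  right_flank
```

whose flanks are identical across molecules while `k` varies. A long read
that contains **both** flanks must have traversed the entire array, so the
number of repeat-unit copies on that read equals the array length of the
molecule it came from, *regardless of how much the read was clipped at its
ends*. That conditional independence is the whole trick: read truncation,
which plagues naive repeat counting, only affects whether a read qualifies,
never the count of a qualifying read.

`tandemtally` operationalizes this as four stages: build the template model
(`plasmid_map()`, `build_template()`), select target reads
(`classify_reads()`), count units per target read (`scan_units()`,
`count_copies()`), and aggregate (`copy_distribution()`, `welch_t()`,
`render_report()`). A seeded simulator (`simulate_sample()`) provides
ground-truthed inputs for validation.

## Anchor-based selection

Anchors are the innermost `anchor_len` bases of each flank, adjacent to the
array (default 500 bp). Whole-flank alignment would be wasteful and would
loosen the bound on the array interval; the innermost stretches pin the
inter-anchor interval tightly around the array. A read is

* **target** — both anchors found, same strand, left-before-right after
  canonicalizing minus-strand geometry, non-overlapping;
* **ambiguous** — both anchors found but overlapping each other (geometry
  incompatible with the template; e.g. concatemeric or chimeric reads).
  Ambiguous reads are excluded from copy statistics by default;
* **non-target** — anything else (one or zero anchors, inconsistent
  strands or order). This bucket collects background molecules and reads
  clipped into a flank.

Anchor search is exact k-mer seeding (`kmer_size` 15, sampled every 15
bases), grouping of seed diagonals into candidate placements (diagonals
within `band_width` of each other are one placement), and banded local
Smith–Waterman verification around the best candidates. Identity is defined
once, everywhere, as matches / alignment columns with indel columns counting
against — a single unambiguous definition for the `min_identity` threshold
(default 0.80, deliberately permissive: at nanopore-like 2.5% error the
observed anchor identity is ~0.95, and the threshold only needs to reject
random sequence, whose local-alignment identity under this scoring sits far
below 0.8).

## Unit counting

Counting runs only inside the inter-anchor region (plus one `band_width` of
slack per side). Candidate unit placements come from the same seeding
machinery; in a tandem array the seed diagonals cluster at multiples of the
unit length, so successive copies separate cleanly (adjacent copies differ
by ~2000 in diagonal, far beyond the 150 bp band). Each candidate is
verified by banded alignment of the whole unit:

* aligned span ≥ `min_span_frac` (default 0.90) of the unit and identity ≥
  `min_identity` → **accepted** (a countable copy);
* span in [`partial_span_frac`, `min_span_frac`) (default 0.30–0.90) →
  **partial**: not counted, but the read is flagged `has_partial`;
* anything shorter or below identity is discarded.

Accepted hits are selected greedily by descending score with leftmost
tie-break, discarding overlaps (overlap = any shared read base, since true
copies are non-overlapping by construction); the copy number is the number
selected. Greedy rather than optimal weighted interval scheduling is a
deliberate simplification — near-periodic hits essentially never conflict —
and an exhaustive oracle guards it (below). Reads flagged `has_partial` are
excluded from headline distributions by default (`include_partial = FALSE`):
a partial unit between the anchors means the molecule violates the clean
tandem model (rearrangement, large indel burst), and silently rounding it to
an integer count would be worse than reporting it separately.

`oracle_scan()` is the reference implementation used in the test suite:
iterated *full* local alignment (Biostrings `pairwiseAlignment`, no seeding,
no banding) that accepts the best hit if it clears the thresholds, masks it
by splitting the region, and recurses. The production scanner and the oracle
share only the scoring constants (match +2, mismatch −3, linear gap −4 —
mirrored in the oracle as affine with zero opening cost); their agreement on
simulated reads spanning copy numbers 0–5 and error rates 0–5% is asserted
in `tests/testthat/test-acceptance.R` at ≥ 99%, with every disagreement
required to carry the `has_partial` flag.

## The simulator, and what it does not emulate

`simulate_sample()` draws each read independently: origin (target vs
background by `background_fraction`), copy number (from the mixture), strand
(uniform), end clipping (each end independently with probability
`clip_prob`, geometric length with mean `clip_len_mean`, applied before
errors — clipping models incomplete molecule capture, which happens to the
molecule, not to the error process), then per-base errors. Default error
rates are substitution 0.01, insertion 0.005, deletion 0.01 — a crude
stand-in for current nanopore chemistry with high-accuracy basecalling, not
a calibrated profile; quality strings are constant at `qual_mean`. Circular
background molecules are linearized at a uniform random position. The
second purification protocol (pre-digestion of the 2-micron plasmid plus
exonuclease treatment) is modelled compositionally by
`apply_second_protocol()`: molecules that are linear, or circular but cut by
the digestion enzymes, are removed from the pool — its computational
consequence is a change of composition, not of sequence.

Determinism: read *k* is generated from a stream derived from
`(master_seed, k)` only, so fixtures are byte-stable and the first *k* reads
do not depend on the batch size.

Not emulated, hence not probed by passing tests: signal-level artefacts,
homopolymer-biased errors, chimeric reads, length-dependent capture bias,
and real flank/unit sequences (the bundled `example_plasmid_map()` and
`example_background_pool()` are synthetic random DNA at yeast-like GC
content reproducing the *architecture* — unique cut site, 2 kb unit, long
flanks, cuttable/uncuttable background classes — not any real sequence).
Conclusions from simulation are about the algorithm, not about a sequencer.

## Statistics

The unit of analysis for group comparisons is the per-replicate percentage
(e.g. contraction percentage per biological replicate), matching how
replicate means ± SDs are reported for this kind of assay; pooling reads
across replicates before testing would understate between-replicate
variance. The test is Welch's unequal-variance *t* by default — the robust
choice for 2–6 replicates of possibly unequal spread — with a `pooled`
flag for Student's variant. Degenerate inputs follow a stated convention:
both groups constant and equal → *t* = 0, *p* = 1; both constant and
unequal → *t* = ±∞, *p* = 0. No multiple-testing correction is applied:
the workflow reports single pairwise comparisons.

Mass bookkeeping (`estimate_target_mass()`) multiplies the measured total
DNA mass by the target-read fraction; this is a molar-fraction proxy that
assumes target and non-target fragments have comparable lengths. Displayed
masses are *truncated* (not rounded) to three decimals — the convention
under which 1.73 × 0.056 displays as 0.096 — while full precision is kept
in the returned object. `yield_reduction()` is `100 × (1 − alt/ref)`.

Coverage (`accumulate_coverage()`, `normalize_coverage()`) supports two
normalizations because the choice is genuinely open: `mean` (per-base mean
becomes 1; default, convenient for plateau inspection) and `total` (divide
by total aligned bases). bedGraph output merges equal-value runs and
round-trips exactly through `read_bedgraph()`.

## Numerical and design choices

* Coordinates are 0-based half-open everywhere in the public interface;
  circular positions are reported modulo the sequence length. R-internal
  1-based arithmetic is converted at the boundaries.
* Restriction cut offsets default to the blunt midpoint of the recognition
  site (correct for PmlI, the only enzyme whose cut position matters
  downstream); recognition sequences for PmlI/SphI/BsoBI ship as defaults
  and are overridable in config.
* Tie-breaks are always leftmost-on-read, making every stage deterministic.
* Candidate placements need ≥ 3 seed hits before alignment verification;
  with 15-mers sampled every 15 bases, even a 30%-of-unit partial at 5%
  error retains an expected ~20 intact seeds, so the floor only suppresses
  random noise.
* The config file is YAML; all CLI flags override it. Every text output is
  stamped with the package version, an MD5 of the scientific configuration
  (output paths excluded, so re-runs into different directories compare
  equal) and the seed.
* The `cmd_profile()` reference for coverage is the two-copy template by
  default; mapping reads to a whole genome is out of scope, and read-to-
  template intervals are derived from the anchor/unit alignments already
  computed rather than an external mapper.

## Validation scales

The shipped test suite validates at sizes a laptop handles comfortably:
zero-error exactness on 1,000 reads; mixture recovery (7.32% / 92.32% /
0.36% with 2.5% error and moderate clipping) on 10,000 reads against
3×binomial-SE bounds; selection-fraction recovery on 3,000 reads at 40%
target; oracle agreement on 200 reads spanning copy 0–5 and error 0–5%;
plus property suites (strand invariance, digestion length conservation,
distribution normalization, Welch symmetry and closed-form agreement,
byte-identical reruns). `scripts/acceptance.R` re-runs the headline
quantities end to end from a single seed.

## Known limitations

* Copy-0 molecules put the two anchors directly adjacent; under heavy error
  their alignments can touch and the read falls into `ambiguous`. This
  costs a small amount of power for fully contracted arrays but never
  miscounts them.
* Concatemers and chimeras are not resolved, only quarantined (ambiguous /
  `has_partial`).
* The identity threshold is a scalar; no per-base quality weighting.
* The enrichment-mass proxy inherits the equal-fragment-length assumption;
  strongly skewed background length distributions would bias it.
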
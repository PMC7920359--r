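---
title: "Color balance and decodability of pooled barcode sets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Color balance and decodability of pooled barcode sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bcbalance)
```

## The problem

On patterned flow cells that read every DNA nanoball synchronously —
MGISEQ-2000 / DNBSEQ-G400 and relatives — each position of the sample
index barcode is one sequencing cycle, read at the same moment across
all pooled libraries. The basecaller separates the four fluorophore
channels by contrasting signal across neighbouring nanoballs, so it
needs nucleotide diversity at every cycle: if one base dominates a
barcode position across the pool, the per-cycle signal-to-noise
separation collapses and barcode bases are misread. Misread barcode
bases in turn inflate the *undecoded* fraction — reads whose barcode
matches no known index within the allowed mismatch count — which is
lost to downstream analysis.

`bcbalance` quantifies and designs around this. Its core quantity is
the weighted per-position nucleotide fraction of a pooled set: for
members $i$ with mixing weights $w_i$ and barcode sequences $s_i$ of
length $L$,

$$
f(p, b) \;=\; \frac{\sum_i w_i \,[\, s_i[p] = b \,]}{\sum_i w_i},
\qquad p = 1,\dots,L,\quad b \in \{A, C, G, T\}.
$$

The ideal pool has $f \equiv 0.25$ everywhere. The package judges a
set by whether every position's fractions stay inside a *corridor*
around 0.25, analyzes the pairwise Hamming distances that govern
mismatch-tolerant demultiplexing, simulates reads to measure undecoded
and misassignment rates, and searches a candidate pool for barcodes
whose addition keeps a set balanced.

## The corridor criteria

A criterion is a corridor $[\ell, u]$ with
$\ell \le 0.25 \le u$, a border tolerance $\tau$, and a cap on
violating positions. Each cell $f(p,b)$ is *outside* if
$f < \ell - \tau$ or $f > u + \tau$, *on the border* if within $\tau$
of a bound, and *inside* otherwise; a position takes the worst status
of its four bases, because what matters physically is whether that
cycle can be basecalled, and a single starved or saturated channel is
enough to spoil it. The set passes when the number of outside
positions does not exceed the cap.

Two named criteria ship as defaults:

| criterion | lower | upper | border_tol | max_outside |
|-----------|-------|-------|------------|-------------|
| strong    | 0.15  | 0.35  | 0.01       | 0           |
| lite      | 0.05  | 0.45  | 0.01       | 0           |

The strong corridor models the tight balance of vendor-approved sets;
the lite corridor the wider excursions that real runs tolerate without
a per-cycle quality drop. There are no canonical numeric bounds for
either, so the values above are this package's own defaults, chosen
to preserve the logic (a tight reference corridor, a wider empirical
one, and a violation cap) without asserting exact intercepts as
ground truth. They are
configuration, not constants: `criterion()` builds any corridor,
`read_criterion()`/`write_criterion()` round-trip YAML configs, and —
the faithful derivation path — `derive_corridor_from_sets()` sets the
corridor to the min/max envelope of the fractions of reference sets
you trust:

```{r}
panel <- make_balanced_set(8, L = 10, seed = 1)
derive_corridor_from_sets(bc_set(panel$id), panel)
```

A perfectly balanced reference yields the degenerate corridor
$[0.25, 0.25]$; the constructor accepts it (clamping the border
tolerance to the corridor half-width) so that envelope derivation
needs no special-casing.

Two further conventions. The violation cap defaults to 0 — there are
causes of misread cycles other than pool imbalance, so the headroom of
"up to 2 acceptable violations" is left to explicit expert override
(`default_criteria(max_outside = 2)`). And border positions do not
count toward the cap: only *outside* does. The border band exists to
report near-misses honestly, not to fail them.

## Weights, mixing, and why balance composes

Weights are arbitrary-scale mixing proportions (`9:9:5:5` means the
same as `0.9:0.9:0.5:0.5`); every result is invariant under rescaling.
Equal proportions are the default when weights are omitted.

Balance composes: if two disjoint sets each have $f \equiv 0.25$, any
positive mixture of the two — equal weights within each group, any
ratio between groups — again has $f \equiv 0.25$, since each group
contributes 0.25 of its own weight share. This is the closure property
that makes pre-balanced quartets freely combinable, and it is tested
exactly (to $10^{-12}$) rather than approximately. The converse
matters too: re-weighting a balanced set generally destroys balance
(a 1:4:1:4 pool of a balanced quartet moves fractions to 0.1 and 0.4),
which is why proportions are an input to every verdict, not an
afterthought.

## Distances and decodability

Barcodes are fixed-length and read on synchronous cycles, so
substitution-only Hamming distance is the right metric; indels are not
modelled. `hamming_matrix()` gives the full pairwise matrix with its
extremes; `decodability_check()` reports two conditions at a mismatch
tolerance $m$:

* the **no-merge condition** $m < d_{\min}$: fewer misread bases than
  the smallest pairwise difference, otherwise a read can land exactly
  on another sample's barcode;
* the **unique-nearest guarantee** $d_{\min} \ge 2m + 1$: the
  classical code-distance bound under which every read with at most
  $m$ errors has a unique nearest barcode, so ambiguity is impossible.

Both are reported, clearly labelled, because the gap between them is
where practical trouble lives: raising the mismatch cap from 2 to 3 or
4 rescues undecoded reads, but once $d_{\min} < 2m + 1$ some reads sit
equidistant between two barcodes. The decoder therefore never breaks
ties: a read with two members tied at minimal distance within $m$ is
UNDECODED with `ambiguous = TRUE`. Losing a read is recoverable;
silently connecting two samples is not. The default cap is $m = 2$,
the platform's own default, and values above 2 are left to the user's
judgement.

## The read simulator

`simulate_reads()` draws sources proportional to the normalised
weights and applies independent per-position substitutions; a
substituted base is uniform over the three alternatives. Two error
shapes are provided: `uniform` (one rate `q`) and `ramp` (linear from
`q_start` to `q_end` across positions), the latter because per-cycle
error rates rise toward the end of a run — exactly where barcode
cycles sit. Defaults (`q = 0.01`; ramp `0.005 → 0.03`) are plausible
per-cycle substitution rates for late cycles on this class of
instrument; at `q = 0.02` and $L = 10$ the expected share of reads
with more than 2 errors — hence undecoded at the default cap — is
well under 2%, the usual ceiling for a well-behaved run.

`run_mismatch_sweep()` simulates one read pool and decodes the *same*
reads at each cap, so differences between rows isolate the cap itself;
`pct_rescued` is the reduction of the undecoded count relative to the
first cap. What the simulator emulates is the substitution channel
only: it does not model the optical crosstalk mechanism by which
imbalance *causes* errors (error rate is an input, not a function of
balance), nor quality scores, index hopping, or real per-cycle error
profiles. Passing simulation tests therefore validates the decoding
and accounting machinery, not the corridor thresholds themselves —
those are validated against reference sets via the envelope
derivation.

## Set completion

`complete_set()` answers: which $k$ barcodes from a candidate pool,
added at given proportions, keep the combined set within a criterion?
When $\binom{|pool|}{k}$ is at most the exhaustive cap (default
100,000) every combination is evaluated; beyond it a deterministic
greedy beam search (default width 64) explores the pool and the result
is flagged `exhaustive = FALSE` rather than silently pretending
completeness. Candidates are ranked by the lexicographic score
(outside positions, worst cell deviation, RMS deviation from 0.25),
ties broken by sorted ids, so identical problems always produce
identical output.

With unequal new weights the weight-to-barcode pairing changes the
fraction matrix; all $k!$ pairings are evaluated for $k \le 5$, and a
deterministic greedy pairing (largest weight placed first, each on the
barcode minimising the running score) beyond that. When nothing
passes, the result carries the best failing combination and its
offending positions as diagnostics, so the natural escalation — relax
to lite, or raise the cap — is informed rather than blind.

## Numerical choices and degenerate inputs

* Fractions are computed as weighted counts divided by the total
  weight once, at the end; with equal weights this gives exact
  binary-representable quarters, and exact-balance tests assert
  deviations below $10^{-12}$, not approximate equality.
* Border classification uses the tolerance $\tau$ precisely so that
  "on the bound" is well-defined for floats; $\tau$ defaults to 0.01
  on a fraction scale of $[0,1]$.
* Sequences are uppercased on input; any non-ACGT character (including
  IUPAC codes) is a hard error naming the barcode and position — the
  method counts exact identities, and a silent `N` would corrupt
  fractions and distances. Reverse-complement handling is deliberately
  absent: barcodes are compared in the written orientation.
* Panels of one barcode have an undefined $d_{\min}$ (flagged, not
  faked); decodability requires two.
* All randomness (panel generation, simulation) flows through
  explicit seeds; unseeded calls use the session RNG.

## Problem sizes in the shipped checks

The test suite and the reproduction script work at desk scale chosen
to finish in seconds while leaving no property under-sampled: balanced
panels at $n \in \{4, 8, 12\}$, $L \in \{6, 10\}$; 100 random panels
(up to 16 barcodes) against a brute-force distance oracle; 1,000
random decode instances against an exhaustive-scan oracle; mismatch
sweeps of 50,000 reads at $q = 0.02$ over five seeds; and 50 random
completion problems (pools up to 12, $k \le 3$) against a full
enumeration oracle. Vendor-panel facts (pre-approved sets exactly
balanced; panel-wide $d_{\min} = 4$, $d_{\max} = 10$) concern a
proprietary sequence list that is not redistributed here; the checks
run on synthetic panels constructed to have the same structural
properties, and users with the vendor file can reproduce the originals
directly with `read_panel()` + `hamming_matrix()` +
`derive_corridor_from_sets()`.

## Limitations

The corridor is a proxy for per-cycle basecall quality, validated
upstream against instrument quality metrics; this package does not
compute those metrics and cannot confirm the proxy on your instrument.
The simulator's error channel is substitution-only and
position-independent across reads. The completion search optimises one
set for one lane; multi-lane pooling and cross-library constraints are
out of scope.
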
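---
title: "Methods: information-theoretic operator discovery and classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: information-theoretic operator discovery and classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(galregulon)
```

This vignette is the package's own account of the models and procedures
it implements, the parameters that matter, the numerical choices made
where the design was genuinely open, and what the synthetic-data tests
do and do not demonstrate about real data.

## Coordinates and sequence conventions

All public coordinates are 1-based inclusive on the forward strand, so a
16-bp operator satisfies `end − start + 1 = 16`. BED export
(`intervals_to_bed()`) converts to 0-based half-open. Windows that would
cross a sequence end are rejected rather than wrapped: the chromosome is
circular, but no operator in any packaged table lies near the origin,
and a non-circular contract is much easier to reason about. `N` is
accepted in input sequence but each scoring module defines its own
policy (below); IUPAC codes other than `N` are rejected at read time
unless explicitly masked.

The anchor for all site-centered work is position 9 of the 16-mer — the
base the binding-site logo marks as coordinate 0, just 3' of the dyad
center between positions 8 and 9. `extract_window()` takes `left` and
`right` offsets around that anchor in the site's own orientation,
reverse-complementing minus-strand extractions, so aligned windows
always read 5'→3' across the site. The default 20/21 offsets give the
42-bp modelling window.

## Degenerate-consensus scanning

The operator consensus `GTGNAANCGNTTNCAC` (the dot sometimes printed
between positions 8 and 9 is a dyad-center marker, not a 17th position)
is matched with two classes of positions: *fixed* positions {3, 5, 9,
15}, where genetic evidence says a mutation inactivates the operator and
which therefore must match exactly, and *checkable* positions (the
remaining non-N positions {1, 2, 6, 8, 11, 12, 14, 16}), over which up
to `max_mismatches = 2` deviations are tolerated. `N` pattern positions
are never compared; an `N` anywhere in the genomic window is a
conservative non-match (the reference sequence contains none).

Both strands must be scanned separately: although the consensus string
is its own reverse complement, the fixed-position set is not mirror
symmetric (it maps to {2, 8, 12, 14}), so the two strands genuinely
disagree on some windows. Two open choices are resolved as follows and
surfaced in the output rather than hidden:

* **Deduplication.** Two hits are the same locus iff their
  forward-strand intervals are identical. A locus matching on both
  strands is one record with `strands = "+/-"` and `+` as the canonical
  strand. This makes "number of operators" well defined without strand
  bookkeeping.
* **Overlaps.** Overlapping but non-identical intervals are all kept;
  known operator pairs sit as close as 40 bp apart, so merging would
  destroy real structure.

The vectorized scanner is checked against a naive all-windows,
both-strands oracle built from the single-window matcher, and the hit
invariants (mismatch count recomputable from the stored sequence;
monotonicity in the mismatch budget) are property-tested.

## Information content of the aligned sites

For `n` aligned sites of width `L`, with observed base frequencies
`f(b, l)`:

* per-position information `r(l) = 2 − Ĥ(l) − e(n)` bits, where
  `Ĥ(l) = −Σ_b f log2 f` (with `0·log 0 = 0`);
* `Rsequence = Σ_l r(l)` bits/site;
* `Rfrequency = log2(G/γ)` bits/site for `γ` sites among `G` genomic
  positions, and conversely `γ̂ = G·2^(−Rsequence)` with first-order
  uncertainty `σ_γ = γ̂·ln 2·σ_R`.

`G` counts single-strand positions: that convention reproduces the
canonical 18.98 bits/site for nine sites in a 4,641,652-bp chromosome
(counting both strands would add exactly one bit). The background is
fixed at uniform (2 bits/base ceiling), as implied by the `log2(G/γ)`
form; *E. coli*'s ≈51% GC makes this a mild approximation, and a
non-uniform background is deliberately out of scope.

**Small-sample correction.** The plug-in entropy of `n` draws
underestimates the true 2 bits of a uniform background; `e(n) = 2 −
E[Ĥ(n)]` removes that bias. The expectation and variance of `Ĥ` under
the multinomial null are computed in closed form — the mean via the
binomial marginal of one base count, the variance via trinomial pairs —
which is algebraically identical to summing over all compositions of `n`
into four parts but costs O(n²) instead of O(n³). Tests verify equality
with a literal composition-enumeration oracle to 1e-10 for n = 1..12.
The closed form is the default up to n = 2000; beyond that the
asymptotic bias `3/(2·ln 2·n)` is used (the two agree within 15% from
n ≈ 20, and the bias itself is < 1e-3 bits there).

**Uncertainty of Rsequence.** Two estimators are provided because the
right one depends on the question:

* `sigma_Rsequence = sqrt(L·var_H)` — the null sampling standard
  deviation of the summed plug-in entropies, with `var_H` the exact
  multinomial-null variance. This is the field's conventional quote and
  what `information_summary()` reports.
* `rsequence_se_sites()` — the standard error of the mean individual
  information across the training sites, `sd(R_i)/sqrt(n)`. Because
  `mean(R_i) = Rsequence` identically (below), this estimates the
  sampling uncertainty of `Rsequence` with no null-model assumption.
  For sharp (low-entropy) matrices the uniform-null variance understates
  the real site-to-site spread, so the parameter-recovery tests use this
  estimator; it is also the natural reading of a "±" quoted next to a
  per-site information average.

## Individual information and genome scanning

The weight matrix is `w(b, l) = 2 + log2 f*(b, l) − e(n)`. With
`pseudocount = "none"` (default), `f*` is the raw frequency and a base
never seen at a position carries a `−Inf` sentinel: any window using it
is unscorable, which is the honest statement that the training set
provides no estimate. `"jeffreys"` substitutes `(counts + 1/4)/(n + 1)`
when finite scores for arbitrary windows are needed (for example, for
genome scans with small, diverse training sets). A window's score is
`R_i = Σ_l w(b_l, l)`; windows containing `N` score `NA` and are
excluded.

Under `"none"` the algebraic identity `mean(R_i over training sites) =
Rsequence` holds exactly; the suite checks it to 1e-9 bits on 100 random
alignments. Genome scanning (`scan_riw()`) applies the matrix to every
window on both strands (the minus strand via the complement-and-reverse
transform of the matrix), reports windows with `R_i` strictly above the
threshold — the canonical cutoff, 9.4 bits, is the lowest information
content among the biochemically proven sites, and "more than" is taken
literally, so ties at the threshold are excluded — and deduplicates
per-locus exactly as the consensus scanner does. The 42-bp alignment
itself is fixed by the operator coordinates and the center-at-position-9
convention; the original alignment-optimization search is not
re-implemented, because the coordinates are published but the search
procedure is not. Whether the published model symmetrized the alignment
(appending reverse complements) is unstated; the default uses each
site's annotated strand and `aligned_sites(symmetrize = TRUE)` exposes
the alternative.

The logo export carries per-base stack heights `f(b,l)·r(l)` (clipped at
zero where `r(l) < 0`) and a cosine overlay with a 10.6-bp helical
period peaking at coordinate 0 — the face of the DNA major groove
presented to the bound protein.

## ChIP-chip bound regions

Probes carry a score `S` (enrichment ratio) and a pixel-count quality
field; probes with fewer than 100 pixels (strictly) are dropped, as
these report array regions likely absent from the genome. Regions are
maximal runs of probes with `S` strictly above a threshold. The
threshold itself has **no default**: it is a property of the upstream
enrichment statistic, not of this package, and must be supplied.
Adjacency is additionally broken by coverage gaps wider than twice the
median probe spacing, so two enriched regions separated by an unprobed
stretch are never fused. Peak-score ties break toward the most upstream
probe, making output deterministic.

Region boundaries interpolate between the peak probe `P` and its track
neighbours in proportion to score ratios:

* upstream: `U_P − (U_P − U_{P−1})·(S_{P−1}/S_P)`
* downstream: `D_P + (D_{P+1} − D_P)·(S_{P+1}/S_P)`

The source formula for the downstream boundary subtracts the second
term, which would place the downstream edge upstream of the peak; the
package treats that as a sign typo, defaults to the symmetric `+`
(`mode = "corrected"`), and retains `mode = "as_printed"` for
bit-faithful replication. Coordinates are rounded half-up. A missing
neighbour (peak at a track edge) behaves as score 0, collapsing the
boundary onto the peak probe's own end. In corrected mode the
boundaries provably bracket the peak probe. Manual separation of
closely spaced peaks is not automated.

## Expression calls

A probe is "under" a gene iff their intervals overlap by ≥ 1 bp,
strand-blind (the array tiles both strands). The gene score is the
arithmetic mean of natural-log standardized probe scores; genes with no
probes are flagged, never zero-filled. The mutant/wild-type ratio is
`exp(mean_ln_mut − mean_ln_wt)`, and with the canonical cutoff 3 a gene
is `up` when the ratio strictly exceeds 3, `down` below 1/3. The
comparison is performed on the ln scale (`d > ln 3`) so that a ratio of
exactly 3 is not misclassified by floating-point round-off of `exp()`;
`inclusive = TRUE` moves the boundary case into the regulated classes.
Transcript rollup calls a transcript up (down) if any member gene is,
and flags transcripts with conflicting member calls rather than forcing
a direction. No significance testing or FDR control is attempted — the
procedure is a plain ratio cutoff by design.

## GRS/CAS classification

Offsets from an operator to a transcription start point (tsp) are
strand-aware and measured from the operator's dyad center (midpoint of
positions 8 and 9, rounded down — the biologically meaningful anchor;
the source does not state center vs edge). For a plus-strand tsp at `t`
the offset is `center − t`; for minus-strand, `t − center`, so negative
always means promoter-upstream. An operator is GRS if any tsp yields an
offset inside the **closed** interval [−200, +400] ("between" read
inclusively; the edge cases are exercised in tests), with the nearest
qualifying tsp's gene recorded as cognate; otherwise CAS. The partition
is exhaustive and exclusive, widening the window can only convert CAS to
GRS, and the labels are invariant under genome-wide translation. Sites
acting as both GRS and CAS in long-range contact data are not a third
label; the 3C operator table ships as a fixture for cross-referencing.

## Synthetic data: what it emulates, and what it does not

The generators reproduce the statistical structure each stage assumes,
with defaults chosen once to mirror the study system:

* `synth_genome()` — i.i.d. background, uniform by default to match the
  2-bit background of the information model (a GC knob exists but is
  off); planted operator instances at known positions/strands with an
  emitted truth table; overlapping plants are an error.
* `synth_probe_track()` — 25-mer probes every 8 bp, the real array
  geometry; triangular enrichment over truth regions on a baseline of
  1.0, multiplicative log-normal noise, and a configurable fraction of
  sub-100-pixel probes for the quality filter.
* `synth_expression_pair()` — per-probe ln-scores N(0, σ) with
  `ln(fold)` added to every probe of a regulated gene; σ = 0.1 and 20
  probes/gene in the reference simulation.

Problem sizes used by the suite: scanner-oracle equivalence on 10-kb
genomes, 2-kb planted-site recovery, 200 noisy peak replicates on 6-kb
tracks, and a 210-gene expression simulation. The noisy peak-recovery
check uses a sharp 200-bp enrichment footprint with apex 10× baseline
and 5% probe noise: under those conditions the called peak lands within
one probe spacing of the planted apex in ≥ 95% of replicates. That
condition is a choice worth being explicit about — for wide, shallow
peaks or probe noise of 20% and more, the apex probe is statistically
unidentifiable at 8-bp resolution by any caller, because neighbouring
probes differ by far less than the noise; peak *regions* are still
recovered, but single-probe apex localization is not a meaningful claim
there.

What passing these tests does **not** show: real tiling arrays have
sequence-dependent probe affinity (handled upstream by the standardized
scores this package consumes, and not emulated), spatially correlated
noise, and a 51%-GC genome whose background differs mildly from the
uniform model; real annotation maps genes to promoters imperfectly.
Synthetic recovery is a correctness check of the algorithms, not a
performance estimate on experimental data.

## Pipeline

`run_pipeline()` takes one declarative configuration (list or YAML),
validates every referenced file and parameter before any stage runs,
executes stages in dependency order, and writes outputs through a
staging directory that is promoted only on full success — a failed run
leaves its partial outputs quarantined in `.staging`, never mixed with a
complete manifest. The manifest echoes all parameters and lists each
output with its MD5 checksum; identical configurations reproduce
byte-identical outputs (timestamps are deliberately excluded). A thin
command-line wrapper over these functions ships in `inst/cli/`.

## Known limitations

* The full-scale replication of the published genome-wide counts (165
  consensus operators; 60 sites above 9.4 bits; Rsequence of the 9-site
  alignment) requires the 4.6-Mb chromosome FASTA, which is not
  packaged; the corresponding acceptance test fails informatively until
  the user supplies it. Exact reproduction of the operator count may
  additionally depend on the deduplication/strand policy above, which
  the source does not specify.
* The published 76/89 GRS/CAS split depends on the tsp catalog used,
  which is not packaged; the classifier is tested on synthetic tss
  tables and on the printed partition arithmetic.
* One published sentence (an "observed 16.3 ± 0.1 bits/site" average
  over predicted sites) cannot be reconciled with the packaged
  per-site bits column (direct mean ≈ 11.6); which site set it averages
  is unclear, and no test asserts it.
* Background assumed uniform throughout; no non-B-form DNA modelling;
  no motif discovery (the package only produces motif-finder input).
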
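# galregulon

Tools for mapping the regulon of the *Escherichia coli* transcription
factor GalR — a repressor of D-galactose metabolism that also acts as a
nucleoid-structuring protein — from genome sequence and tiling-array
data. The package is aimed at bacterial regulatory genomicists who want
to reproduce, or apply to other factors, the combination of
degenerate-consensus scanning, information-theoretic site modelling,
ChIP-chip bound-region geometry and expression-ratio classification that
defines an extended regulon.

## What it computes

**Consensus scanning.** The GalR operator is a 16-bp hyphenated dyad,
`GTGNAANC·GNTTNCAC`, whose positions 3, 5, 9 and 15 are critical:
mutating any of them inactivates the operator. `scan_consensus()` slides
this pattern over both strands of a genome, requiring exact matches at
the fixed positions and allowing a budget of ≤ 2 mismatches over the
remaining non-N positions. Loci hit on both strands at the same forward
interval are collapsed to one record.

**Information analysis.** For an alignment of n binding sites of width
L, the per-position information is

    r(l) = 2 − Ĥ(l) − e(n)   [bits],

where Ĥ(l) is the plug-in entropy of the observed base frequencies and
e(n) = 2 − E[Ĥ] is the small-sample bias of the entropy estimator under
a uniform base background, evaluated exactly from the multinomial null
(`small_sample_correction()`). The total R_sequence = Σ_l r(l) bits/site
is compared with R_frequency = log2(G/γ), the information needed to pick
out γ sites among G genomic positions; their ratio says whether the
sites carry enough information to be found, and γ̂ = G·2^(−R_sequence)
predicts how many sites the genome can support. An individual-information
weight matrix w(b,l) = 2 + log2 f(b,l) − e(n) scores any window as
R_i = Σ_l w(b_l, l); the mean R_i over the training sites equals
R_sequence exactly, and `scan_riw()` reports every genomic window above
a bits threshold.

**ChIP-chip geometry.** `call_regions()` merges runs of above-threshold
tiling probes into bound regions, picks the highest-scoring probe as the
peak, and interpolates region boundaries from the peak's flanking probes
in proportion to their score ratios; `export_region_sequences()` writes
the spanned DNA as FASTA for external motif discovery.

**Expression and classification.** `gene_scores()` averages natural-log
standardized probe scores under each gene, `regulation_calls()` applies
a linear ratio cutoff (default 3) to call genes up/down-regulated
between a deletion mutant and wild type, and `rollup_transcripts()`
aggregates calls to operon/promoter level. `classify_operators()`
labels each operator a Gene Regulatory Site (GRS) if it lies within
−200..+400 bp of some transcription start point (strand-aware, measured
from the dyad center) and a Chromosome Anchoring Site (CAS) otherwise.

A seeded synthetic-data module (`synth_genome()`, `sample_sites()`,
`synth_probe_track()`, `synth_expression_pair()`) generates inputs with
known ground truth for every stage, and `run_pipeline()` orchestrates
end-to-end runs from one declarative (YAML) configuration with a
checksummed output manifest.

## Worked example

```r
library(galregulon)

# how many operator-like sites can a 4.64-Mb genome support,
# given sites carrying 16.1 +/- 0.7 bits each?
rfrequency(4641652, 9)
#> [1] 18.97764
pred <- predict_site_count(4641652, 16.1, 0.7)
round(c(pred$gamma_predicted, pred$sigma_gamma))
#> [1] 66 32

# scan a synthetic genome carrying one planted operator
g <- synth_genome(5000,
                  planted = data.frame(sequence = "GTGAAAACGATTACAC",
                                       position = 2001),
                  seed = 1)
hits <- scan_consensus(g$genome)
hits[, c("start", "end", "strand", "strands", "mismatches", "sequence")]
#>   start  end strand strands mismatches         sequence
#> 1  2001 2016      +     +/-          0 GTGAAAACGATTACAC
```

The first block says: locating the nine known operators in the genome
needs 18.98 bits/site, the sites only carry 16.1 ± 0.7 bits, and that
information content is consistent with roughly 66 ± 32 operator-like
sites genome-wide. The second block recovers the planted operator at
its exact coordinates, matching the consensus on both strands with zero
mismatches.

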
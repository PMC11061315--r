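---
title: "Models and methods in tnpbtools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in tnpbtools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tnpbtools)
```

`tnpbtools` couples a discovery pipeline for RNA-associated nucleases in
microbial genomes with read-level characterisation of a programmable
TnpB-family endonuclease. This vignette is the package's account of the
models behind each stage: what is assumed, which parameters matter, how
the synthetic data relates to real data, and where the design was
genuinely open.

## Discovery pipeline

### Gene roles and significance calibration

Defense and housekeeping roles are assigned by scoring each protein
against position-frequency profiles (20 × L matrices with Laplace
pseudocounts) by its best ungapped placement, in summed base-2 log-odds
against a uniform residue background. Database search tools report
e-values for this kind of comparison; the package's stand-in is a
calibrated upper-tail probability. For each profile and protein-length
bin (width 50 aa) it scores 1000 random sequences and fits a Gumbel
distribution by moments — score maxima over placements are
extreme-value distributed, which is also why e-values in HMM search
follow the same family. The fitted tail extrapolates below the empirical
resolution of the null sample, which matters because the defense
threshold (1e-4) is finer than 1/1000. The housekeeping threshold is
1e-2; a gene passing both databases is called defense, the stricter
category. Empty proteins become `other` with a warning.

Assumptions worth knowing: placements are ungapped (no insert/delete
states), the null is i.i.d. uniform over residues rather than shuffled
composition-matched sequence, and profiles in the packaged generators
are built from ungapped member sets. These choices keep the calibration
exact and fast at desk scale; they understate significance for
low-complexity proteins.

### Defense islands and intergenic regions

A defense island is a maximal run of non-housekeeping genes containing
at least one defense gene, bounded on each side by a housekeeping gene.
A contig edge counts as a valid boundary, but such islands are flagged
`edge = TRUE` so downstream analyses can exclude them. Strand is ignored
for contiguity, and there is no cap on island length or on consecutive
`other` genes — the pure flanking definition. The caller is a single
left-to-right scan; the test suite checks it against a brute-force
enumeration of all qualifying runs on random contigs.

Intergenic regions are the gaps between merged gene spans plus contig
termini; regions shorter than 15 nt are discarded
(`igr_min_len = 15`). Genes, kept IGRs and discarded short gaps tile
each contig exactly — a property test asserts the lengths reconcile.

### Structured RNA motif scanning

The scanner is a covariance-model-lite. A model is built from a seed
alignment plus consensus structure: match columns are those with gap
fraction below 0.5; each match column gets nucleotide log-odds (base 2,
background 0.25, pseudocount 0.5 per base); bracket pairs in the
structure whose partners are both match columns become pair constraints.
A window of model length scores

* the sum of column log-odds, plus
* for each pair: +1 bit if the two window bases are Watson–Crick or
  G·U-compatible, −1 bit otherwise.

Both strands of every IGR are scanned (DNA is read with T ≡ U);
overlapping candidate hits are resolved greedily by descending score,
ties to the leftmost start, then the + strand. There are no
insert/delete states: a real covariance model aligns with gaps, so this
scanner underestimates hits of length-variant instances — a documented
limitation, acceptable for fixed-length planted instances and short
motifs. With the pair terms set to zero the scanner is exactly a PWM
scan, which the tests exploit as an oracle equivalence.

Score thresholds come from `calibrate_null()`: the empirical
`1 - FPR` quantile (R's default continuous quantile, so an FPR of 0.5
gives the sample median) of i.i.d. background windows, default FPR
1e-3 per window. This replaces covariance-model e-values; at 1e-3 a
few background hits per few thousand windows are expected, and the
planted-recovery tests therefore rank by score rather than asserting a
clean hit list.

### Two-step protein clustering

Step one is greedy identity clustering: proteins in descending length
order join the first representative they match at identity ≥ 0.3 and
coverage ≥ 0.6 (identity = identical fraction of both-aligned columns
of a Smith–Waterman local alignment with BLOSUM62, gap open 10, extend
1; coverage = aligned columns over the shorter length; coverage against
the shorter sequence is the default, a bidirectional variant being the
natural alternative). A sensitivity knob of the kind fast prefilter
tools expose has no analogue in an exact aligner and is deliberately
absent.

Step two integrates remote homology: each initial cluster gets a
star-alignment profile (members globally aligned to the longest member;
column frequencies with Laplace pseudocount 1 — deterministic, unlike a
full progressive MSA), every protein is scored against every cluster
profile, scores are normalised by each protein's own-cluster score, the
two directions are averaged and clipped to [0, 1], and edges whose
cross-scores fail a Gumbel-calibrated tail probability of 1e-5 are
dropped. Markov clustering of this graph (inflation 2.0, pruning 1e-5,
tolerance 1e-6, ≤ 100 iterations) yields the final families: columns
are normalised to stochastic after every inflation (asserted to 1e-9 in
tests), self-loops are set to each node's maximum incident weight (1
for isolated nodes), and clusters are the weakly connected components
of the attractor support, so overlapping attractor systems merge rather
than being tie-broken. The suite cross-checks the whole procedure
against an independently coded reference implementation on random
graphs of up to 8 nodes, and requires adjusted Rand ≥ 0.9 against
planted families at divergence 0.3.

Taxonomy is a consensus: protein best-hit lineages filtered at identity
> 0.4 and coverage > 0.7, the most specific of the 7 ranks with > 70%
agreement, adopted only when a nucleotide-method lineage carries the
same label at that rank. Redundancy filtering keeps one representative
per ≥ 90%-identity group, and representative selection caps 6 proteins
per species per family, longest first. Co-occurrence is reported per
RNA hit: the fraction of hits whose ±5-gene window contains a family
member. Whether such a denominator counts loci or per-strain copies is
ambiguous in general; the package counts hits and says so here.

## Cleavage characterisation

### The engine

`cleavage_engine()` encodes the nuclease's observed rules:

| parameter | default | meaning |
|---|---|---|
| `tam_consensus` | `AGGAG` | 5-nt TAM, exact match required |
| `seed_region` | 1–13 | guide positions where any mismatch abolishes cleavage |
| `distal_mismatch_factor` | 0.5 | efficiency multiplier per mismatch at positions 14–20 |
| `ts_site_dist` | 22: 0.65, 21: 0.20, 23: 0.15 | target-strand cut position distribution |
| `nts_site_dist` | 16: 0.85, 15/17: 0.075 | non-target-strand distribution |

Positions count from the TAM/target junction, position 1 being the
target base adjacent to the TAM; the overhang is the target-strand mode
minus the non-target-strand mode, positive meaning a 5'-overhang at the
TAM-distal end (+6 by default). The modal positions and their dominance
(> 60% and > 80%) reflect the characterised enzyme; the spread around
each mode is this package's own modelling choice and is configurable.
The hard zero for seed mismatches and the single per-mismatch distal
factor are explicit simplifications of a smooth empirical gradient: the
qualitative pattern (total loss proximally, graded loss distally) is
what the heatmap tests pin down, not per-position values, which are not
available as numbers.

### TAM discovery

The simulated assay mirrors the biochemical one: a plasmid library with
a 7-nt randomized window immediately 5' of a 20-nt target; molecules
whose TAM-proximal 5 window bases match the consensus are cleaved;
cleaved ends receive an adapter, and reads run from the adapter back
across the window. Extraction keeps a read when its adapter matches
within one mismatch and a 12-nt backbone anchor locates the window. Two
anchors are available — immediately 5' and immediately 3' of the window
— and an exact match to either suffices. With a single exact 12-nt
anchor, a per-base error rate of 0.001 alone caps expected recall at
(1−0.001)^12 ≈ 0.988; accepting either flank restores recall ≈ 0.9999
without loosening the exact-match rule per anchor. The logo reports
per-position frequencies, information content 2 − H (bits), log2
enrichment over the background (uniform unless an input library is
supplied — appropriate because the randomized window is synthesised
uniformly), and a consensus with `N` below 1 bit.

### Transcript anatomy

Small-RNA reads are placed by exact match with a ≤ 2-mismatch fallback;
unplaced reads are counted, not guessed. The transcript is called in two
steps: a core region where coverage is at least 10% of the maximum, then
bounds extended to the outermost reads overlapping that core. The
extension step matters for tiling coverage, which is trapezoidal: the
ramps at either end sit below any fractional threshold, and
thresholding alone would clip two read-lengths' worth of transcript
ends. Landmarks (motif bounds and tail start) partition the transcript
into 5' flanking, RNA motif, 3' flanking and non-conserved tail
segments; bounds at the locus edge set a `truncated` flag.

### Indels and mismatch heatmaps

Amplicon reads are globally aligned to the reference (match +2,
mismatch −3, gap open 8, extend 1 — values in the range CRISPR amplicon
tools use; reads identical to the reference skip alignment). A read is
edited when at least one gap column overlaps the target window (guide
± 5 nt); substitutions never count, which is also why the simulator
plants substitution-only sequencing errors — indel truth stays
unambiguous. Deletion columns carry the deleted base's coordinate and
overlap the half-open window; insertion columns sit on the boundary
before the next reference base and overlap inclusively at both window
edges, matching how the generator draws insertion positions. Reads
below 80% identity are discarded and counted. The mismatch heatmap
normalises each variant guide's edited fraction by the wild-type
fraction (an error if that is zero) into a 4 × 20 matrix with the
original-base cells at 1.

### Off-targets

Candidate sites are exact-TAM matches followed by a 20-nt window with at
most 3 guide mismatches, on either strand, no bulges, sorted by mismatch
count then coordinate.

## Synthetic data: what it does and does not emulate

The generators produce genomes with role mosaics, planted islands and
planted IGR motifs; protein families as point-substituted consensus
copies with 7-rank lineages; TAM libraries with uniform 7-mers;
run-off, small-RNA and amplicon reads with substitution errors at a
constant rate and constant quality symbols. All are pure functions of
(spec, seed) — R's Mersenne-Twister via one `set.seed` per call — and
byte-identical on re-run, with truth tables sufficient to score every
downstream metric.

They do not emulate: assembly artifacts or chimeras, strand-specific
library biases, quality-score error profiles, sequencing indels,
codon-level consistency between gene DNA and protein sequences, or
compositional bias (all backgrounds are uniform). Passing tests
therefore demonstrate correctness of the algorithms under clean,
known-truth conditions — not robustness to the full error structure of
real libraries.

## Problem sizes and numerics

The test and acceptance runs use sizes chosen to make the statistics
decisive at desk scale: 10,000 run-off reads per strand (multinomial
fluctuations ≤ 0.02 per position), 5000-observation TAM logos
(information-content bias ≈ 0.0004 bits), depth-1000 amplicon sets
(planted-rate recovery within ±0.005), 4 × 5 planted families at
divergence up to 0.3, and ≤ 8-node graphs for exhaustive-style MCL
cross-checks. Numerical guards: probability vectors validated to 1e-9;
graph symmetry to 1e-12; MCL convergence at 1e-6 with a warning flag on
non-convergence; degenerate inputs (empty proteins, zero coverage, zero
WT fraction, empty genome sets) raise explicit errors rather than
propagating NaNs.
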
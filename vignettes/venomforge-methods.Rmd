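---
title: "Models and methods behind venomforge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind venomforge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`venomforge` reconstructs, as a library, the computational chain used to
characterize rear-fanged snake venom glands: merge short overlapping read
pairs, assemble and cluster toxin coding sequences, estimate cluster
abundances from read mapping, confirm proteins against
peptide-identification reports, and test toxins for diversifying
selection.  This vignette explains the models and the choices behind each
stage — what is assumed, which parameters matter, and what the synthetic
tests do and do not demonstrate.

## Read merging

A venom-gland RNA-seq library built from short inserts yields 151-nt read
pairs whose 3' ends overlap, often over their entire length.  For a pair
(read 1, reverse-complemented read 2), every candidate insert length `L`
implies an overlap layout; the merger scores each candidate by matches
minus mismatches over the overlapping columns and keeps the best, breaking
ties toward the longer overlap (the full read-through interpretation).  A
merge is accepted when the overlap is at least `min_overlap` (default
25 nt) and its mismatch fraction at most `max_mismatch_fraction` (default
0.05).  Consensus bases where the mates agree carry the *sum* of the two
phred scores (capped at 93, the printable FASTQ ceiling); disagreements
keep the higher-quality base with quality `|q1 - q2|`; `N` never matches
and carries quality 0.  Bases 3' of the insert end in either read are
fragment read-through into the adapter and are discarded.

The merge thresholds are not dictated by any published protocol; 25 nt at
5% mismatches makes a false merge of two random 151-nt reads vanishingly
unlikely (expected well under 1e-6 per pair) while merging essentially all
genuine short-insert pairs.  Quality summation is the natural consequence
of treating the two base calls as independent error channels, and it is
the only simple rule consistent with merged mean qualities near 70 arising
from raw reads near phred 35.

## Assembly

*Seed extension.*  A seed (typically a merged read) is extended greedily
at both ends.  An extending read must overlap the contig end by at least
100 nt, match exactly in the overlap, and have phred ≥ 30 at every base;
per step the eligible read adding the most new bases wins.  Extension
stops when no read qualifies or at a 30 kb safety cap (the longest venom
transcripts, e.g. venom factor, run to ~5 kb; the cap only guards against
pathological loops).  Exactness makes the extender conservative: a single
sequencing error in an overlap excludes that read rather than risking a
hybrid contig.

*Reference-guided consensus.*  Reads are placed on annotated references by
k-mer-seeded ungapped alignment (15-mers, best placement by identity) and
assigned wherever identity ≥ 0.85; a per-position majority vote gives the
consensus.  A consensus is kept only if depth ≥ 5 at every CDS position;
UTR flanks are trimmed where depth < 5.  Indel-free placement is adequate
here because the simulated (and typical Illumina) error model is
substitution-only; a banded aligner would be needed for indel-rich data.

*Deduplication* collapses byte-identical CDSs and CDSs wholly contained in
a longer identical region, keeping the longest, with output order stable
by id.

*Clustering.*  Toxin coding sequences are grouped by single-linkage at
pairwise divergence strictly below 0.01 (mismatches over aligned non-gap
columns of a global alignment).  Single linkage matches how such clusters
are used: as allele/close-paralog groups discovered greedily, where any
<1% link justifies co-membership.  The threshold is strict (`<`), reading
"less than 1% divergence" literally.  Clusters are numbered by descending
total abundance (input order when abundance is absent) and members
lettered `a`, `b`, `c`, ... by descending abundance; singleton clusters
carry no letter (`SVMPIII-1`), multi-member clusters do (`3FTx-9a`).

*Chimera screening.*  Misassembled fusions betray themselves two ways:
remapping reads at high identity (0.98) produces multimodal or extremely
uneven coverage, and the sequence decomposes into segments matching
distinct database parents.  The evenness statistic is
`U = min(sliding 100-nt window mean depth) / median depth`, flagged below
0.1 — a ratio, so uniformly *low* coverage does not fire.  The mosaic test
scans single breakpoints on a 60-nt grid for a split whose two segments
each match distinct parents at ≥ 95% identity.  Both cutoffs are package
choices; the underlying criteria are qualitative.  A chimera call requires
the parent partition to exist; the evenness statistic is reported alongside
as supporting evidence.  One guard matters in practice: a candidate
matching one database entry at ≥ 95% identity over ≥ 95% of its length is
never called a chimera — otherwise every member of a <1% cluster would
"decompose" into its siblings.

*Annotation.*  Translated CDSs are aligned locally (BLOSUM62, gap
10/0.5) against a packaged reference of toxin-class proteins whose
descriptions carry class keywords; the best hit assigns the class when its
score reaches 100 and a keyword matches, otherwise the transcript is
`nontoxin`.  The packaged reference is synthetic (random sequences of
class-typical lengths, labeled as such in the FASTA) — it defines the
class vocabulary for simulated data and stands where a curated toxin
database would be plugged in for real data.

## Quantification

Merged reads are mapped to a CDS-only database at ≥ 0.95 identity over the
aligned span; each read goes to its best-identity CDS.  Reads tying across
clusters are assigned uniformly at random under a recorded seed — this
preserves totals without inventing an EM reassignment; reads tying among
members of one cluster count once for the cluster (members are <1%
apart, so such ties are the norm).  Counts and per-base depths are scaled
to 10 million mapped reads.  The expression table reports, per toxin
cluster, its share of toxin-mapped reads and of all mapped reads — the
ratio of the two columns is constant and equals the toxin share of
transcription — and `median_coverage`, the median per-position scaled
depth over the representative CDS (an interpretation consistent with the
column's magnitude relative to read counts).  Percentages are read-count
based, not base-coverage based.

## Proteomic cross-validation

The search database holds one mature protein per transcript (signal
peptide removed according to the supplied annotation span — signal-peptide
prediction itself is out of scope) plus one reversed-sequence decoy per
target.  Tryptic digestion cleaves C-terminal to K/R except before P, with
at most one missed cleavage and a 6-residue minimum (a standard floor; the
filter applies after enumeration so missed-cleavage products survive).
Report peptides are mapped to every database entry containing them, with
isoleucine and leucine collapsed by default (they are mass-identical to
the instrument); coverage is the union of mapped spans.  Acceptance
requires ≥ 3 matched peptides, ≥ 20% coverage, and a protein score
strictly above the best decoy — by construction this yields a 0% empirical
false-positive rate, which the tests verify on simulated reports across
seeds.

Grouping reconstructs the shared-unique-peptide semantics of
protein-inference tables: the candidate groups are the distinct sets of
accepted entries sharing a peptide; groups are assigned greedily from the
most specific set upward, and an entry all of whose peptides map into
already-grouped sets ends up with no group (reported `NA`), mirroring
identifications that lack a distinguishing peptide.  The exact algorithm
inside commercial engines is proprietary; this reconstruction reproduces
the structure of the published tables but is not claimed identical.

## Molecular evolution

*Orthologs.*  All-vs-all local protein alignment (BLOSUM62), E-values from
the classical Karlin–Altschul form with standard gapped constants
(λ = 0.267, K = 0.041), pairs kept iff mutually best with E < 1e-4.
Only the mutual-best logic and the cutoff materially affect results.

*Codon alignment.*  Global protein alignment back-threaded onto codons;
pairs with more than 24 gapped nucleotide positions are excluded
(counting nucleotides, not columns), and gapped codon columns are removed
before estimation.

*Pairwise rates.*  The counting estimator is Nei–Gojobori (1986): per-codon
synonymous site fractions (changes to stops excluded from the
denominator), pathway-averaged difference counts over orderings of the
differing positions (orderings through stop codons skipped, falling back
to all orderings when none survive), Jukes–Cantor correction, with `dS = 0`
or a corrected proportion ≥ 0.75 reported as undefined — never infinity.
The ML estimator maximizes the two-sequence GY94 likelihood (61 sense
codons, transition/transversion ratio κ, nonsynonymous multiplier ω, F3x4
frequencies) over divergence, κ and ω; dN and dS derive from the fitted
flux decomposition with site counts taken at ω = 1, the codeml
convention.  Counting is the default because it has an exact brute-force
oracle (the test suite enumerates all pathways independently over the full
61×61 codon space); ML is the mode faithful to likelihood-based studies.

*Null-distribution outliers.*  Thresholds are the empirical 95th
percentiles (linear interpolation) of the nontoxin dN, dS and ω; toxin
pairs exceeding each are counted, and distributions are compared by
two-sided Wilcoxon rank-sum tests — exact when both samples are ≤ 20 and
tie-free (matching full enumeration, which the tests check for all
n, m ≤ 8), normal approximation with tie correction otherwise.

*Site models.*  Likelihoods are computed by pruning over the 61 sense
codons with GY94 rates and F3x4 frequencies from the data; the site-class
mixture is integrated per site; rate matrices are scaled by the
mixture-averaged rate so branch lengths stay in expected substitutions per
codon.  M7/M8 discretize the beta into K = 10 equal-probability categories
at category means.  Optimization is bounded quasi-Newton (L-BFGS-B on
transformed parameters) over the class mixture, κ, and a single scale
factor on the branch lengths of the NJ (or user-supplied) tree — per-branch
optimization is deliberately traded away; with the scale free, the LRTs of
interest are insensitive to the residual branch-length error at these
divergences, and fits stay fast and reproducible.  Three deterministic
ω starts (0.1, 0.5, 2.0) each get a short pilot optimization and the best
pilot is polished to convergence; the pilot phase exists because the
M2a surface has a ridge at `p2 → 0, ω2 → 1` (the M1a nesting boundary)
that can trap a single cold start.  Trees come from neighbor joining on
pairwise HKY maximum-likelihood distances (negative branches clamped to
zero); a user-supplied newick overrides.

Likelihood-ratio tests compare `2ΔlnL` to χ² with 2 degrees of freedom —
for df = 2 the upper tail is exactly `exp(-ΔlnL)`, which is how the
package reproduces published p-values from printed negative
log-likelihood pairs to two significant figures.

## The synthetic-data generator

The generator is first-class, tested code: it emulates two diverged
species' venom-gland transcriptomes with known ground truth.  Toxin
families are seeded from the packaged class reference (reverse-translated
with uniform codon choice), cluster ancestors diverge within a class at
~0.3 substitutions/codon, the two species split by GY94 simulation with
exact exponential waiting times, and within-cluster variants sprinkle
substitutions at ~0.3% of sites (pairwise divergence comfortably below the
1% clustering threshold).  Expression weights are log-normal per
transcript, rescaled so the toxin share of transcription hits the target
(default 0.362).  Reads are 151 nt from normal inserts (mean 142, sd 20,
floor 30 nt — chosen to reproduce the reported mean merged length of
~142 nt from a mostly-full-overlap library), with adapter read-through for
short inserts, per-base substitution errors (default 1e-3), phred scores
~N(35, 3) capped at 41 per raw base, and low-level contamination:
single-breakpoint two-parent fusions (chimeras, 0.2%) and intron-bearing
unspliced copies (0.2%).  Identification reports draw protein presence per
toxin at the configured detectability, sample tryptic peptides, and add
decoy rows from reversed sequences under a separated score distribution.

One scaling convention matters: when two orthologs diverge, the rate
matrix is normalized by its *neutral* (ω = 1) rate, so every gene shares a
mutational clock — synonymous divergence is ω-independent and
nonsynonymous divergence scales with ω, as in real coding sequences.
Without this, low-ω genes would accumulate more synonymous substitutions
per unit time than high-ω genes, inverting the expected toxin/nontoxin dS
relationship.  Tree simulation for the site-model tests instead uses
mixture-average scaling, the convention the mixture likelihood assumes.

What the synthetic tests do **not** show: realism of the error model (no
quality-dependent or position-dependent error structure, no indels — the
quality model is a stand-in, not a claim about any instrument chemistry),
isoform structure, allele-frequency structure within clusters,
composition bias (uniform codon frequencies in simulation; F3x4 in
inference), or the behavior of the assembler on repeat-rich or
low-complexity transcripts.  Passing them demonstrates the *algorithms*
are implemented correctly against their definitions and that the chain is
internally consistent — not that any particular biological dataset would
assemble perfectly.

## Problem sizes and numerical choices

The default generator configuration is desk-scale: 300 nontoxins, the
46-cluster toxin-class structure, 50,000 read pairs.  The test suite uses
smaller configurations per stage, and the heavier statistical checks run
at: NG86-vs-oracle over all 61×61 codon pairs; M0 ω recovery over 20
simulations of 1,000 codons on 6 taxa (median |error| ≤ 0.05); M1a-vs-M2a
power over 50 replicates of 500 codons with 20% of sites at ω = 4 on 6
taxa (power ≥ 80%; in practice it is near 100% — this selection intensity
is strong).  The acceptance script repeats these at 10 and 20 replicates
respectively.  Optimizer tolerances: L-BFGS-B `factr = 1e9` (~1e-7
relative), nesting assertions at 1e-4 relative; degenerate inputs
(identical sequences, zero mapped reads, empty decoy sets, fewer than two
Wilcoxon observations) all return defined values or explicit `NA`s rather
than errors, as documented on each function.

## Known limitations

Ungapped read mapping (substitution errors only); no isoform-aware or EM
quantification; protein inference reconstructs table semantics, not any
proprietary engine; site-model branch lengths are scaled, not individually
optimized; no per-site posterior (NEB/BEB) reporting; HKY throughout for
nucleotide distances.  These match the package's scope: a transparent,
testable reimplementation of the analysis chain, not a drop-in replacement
for every external tool it abstracts.
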
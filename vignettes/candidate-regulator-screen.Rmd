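---
title: "Methods: the multi-omics candidate-regulator screen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the multi-omics candidate-regulator screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regscreen)
```

`regscreen` nominates candidate regulator genes from a wild-type/mutant
strain pair by intersecting three layers of evidence: variant consequences
on the wild-type genome, differential gene expression, and differential
protein secretion. This vignette explains the statistical and algorithmic
choices, the tunable parameters, and what the synthetic validation does and
does not demonstrate.

## Coordinates and gene models

All internal coordinates are 1-based inclusive, matching GFF3, VCF and the
Bioconductor ranges stack used for interval queries. Converting to an
internal 0-based frame would add a conversion surface at every boundary for
no benefit in R, where `IRanges`/`GRanges` are natively 1-based.

Gene models come from `gene`/`mRNA`/`CDS` rows of a GFF3 file. When a gene
has several mRNA isoforms the first in file order is kept and a warning is
emitted; the screen operates at gene level and the fungal annotations this
package targets are effectively single-isoform. Genes whose total CDS
length is not divisible by 3 are accepted with a warning and processed on
the truncated codon frame — a common artefact of draft annotations that
should not abort a screen.

Genome feature statistics use the genomic span (`end − start + 1`) as the
gene length, exon/intron sizes from the CDS segment structure, and GC
content over unambiguous bases only (N excluded from the denominator, the
conservative convention for draft assemblies).

## Variant annotation

Variants are interpreted on the wild-type genome. Multi-allelic VCF rows
are split, REF alleles are validated against the genome, and the VCF
anchor-base convention for indels is converted internally to pure
insert/delete events.

**Region.** Each variant falls in exactly one of CDS, intron or intergenic,
with precedence CDS > intron > intergenic. A deletion touching any CDS base
is CDS; an insertion is inside a feature only when its insertion point lies
strictly between two bases of the feature, so an insertion immediately
outside a CDS never counts as coding.

**Consequence.** SNVs are mapped strand-aware to their spliced-CDS codon,
the codon is re-translated, and the call is synonymous / missense /
stop-gain / stop-loss / start-loss with an amino-acid change string such as
`S725N` (1-based protein position, `*` for stop). Codons containing
ambiguity codes translate to `X`. InDels fully inside the CDS are
frameshift when the length change is not a multiple of 3, otherwise
in-frame; indels spanning a CDS boundary are frameshift by convention — the
spliced product is disrupted in a way the in-frame/frameshift dichotomy
does not describe, and frameshift is the conservative (damaging) label.

Every consequence call is validated, in tests and at data-generation time,
against a brute-force oracle that applies the edit to the genome, remaps
the CDS segments, re-splices, re-translates, and classifies by comparing
wild-type and mutant proteins. The oracle shares no code path with the
analytic caller beyond sequence extraction.

**Regulatory windows.** A variant flags a gene's promoter when it lies
strictly upstream of the translation start within `upstream_bp` (default
1500), and the terminator when strictly downstream of the stop codon's last
base within `downstream_bp` (default 200), both measured on the gene's
coding orientation; one variant may flag several genes (e.g. between two
convergent stops). Window flags are orthogonal to the region partition: a
promoter-window SNV still counts as intergenic in the region summary, which
keeps the partition exact. By default variants inside any CDS receive no
window flags (`exclude_cds = TRUE`); the inclusive behaviour is available
because published counts do not always state the convention.

## Differential expression

Counts are FPKM-normalized per sample. For each gene, with pseudocounted
per-strain means x̄₁, x̄₂ (pseudocount `k = 0.5` guards zeros; FPKM scale),

* M = log2(x̄₂ / x̄₁) — strain 2 is the second strain to appear in the
  sample table;
* D = |x̄₂ − x̄₁|.

The null distribution of (M, D) is empirical: all within-strain replicate
pairs, pooled over genes (the default when both strains have ≥ 2
replicates, as in a 3 + 3 design). Without replication a simulated null is
built from seeded multinomial pseudo-replicates of each sample (5
pseudo-replicates at 20 % of the library by default). The probability of a
gene is the fraction of null points it strictly dominates
(|M_null| < |M| and D_null < D); ties count against the gene, a
conservative choice that also makes an all-zero matrix yield probability 0
everywhere. A gene is called DE when |M| ≥ 1 and probability ≥ 0.8. Null
clouds larger than `null_size` (default 1e5) are subsampled with the
configured seed, so results are deterministic given the seed.

Two properties follow directly: probabilities are invariant to per-sample
depth rescaling (FPKM removes depth), and relabelling the strains negates M
while leaving D and probability unchanged.

Because D is measured in FPKM units, weakly expressed genes with large fold
changes can fail to dominate the null cloud of strongly expressed genes —
an intrinsic feature of the (M, D) dominance statistic. The screen
mitigates nothing here; it is a reason the fold-change-only "twofold" set
(`twofold_set()`, |M| ≥ 1 with an inclusive boundary) exists as a separate
filter for variant-bearing genes.

## The candidate rules

* **Rule A**: a damaging CDS consequence (missense, stop-gain, stop-loss,
  start-loss, frameshift) *or* a promoter/terminator flag, and |M| ≥ 1.
  No probability condition: this mirrors the practice of following up any
  variant-bearing gene whose expression moves at least twofold.
* **Rule B**: membership in the user-supplied transcription-factor list
  plus a damaging CDS consequence. Expression is deliberately not a
  condition — a mutated regulator can act without changing its own
  transcript level.
* **Rule C**: a transcription factor called DE at |M| ≥ 1 and
  probability ≥ 0.8 with no qualifying CDS variant. Genes qualifying for
  both B and C are reported with both tags rather than suppressed.

The candidate list is exactly `rule_A ∪ rule_B ∪ rule_C`, ordered by gene
id, with evidence columns (consequences, amino-acid changes, window flags,
M, probability, optional secretome concordance). All three thresholds and
the window sizes are configurable; relaxing any of them can only add
candidates (monotonicity, covered by tests). The final manual narrowing of
a candidate list by homology inspection is out of scope; an analyst does
that on the evidence table.

## Downstream procedures

* ΔΔCt relative expression with amplification efficiency fixed at 2 (the
  classic assumption when no efficiency calibration is reported):
  fold = 2^−(ΔCt_strain − ΔCt_reference), reference strain ≡ 1.
* Enzyme activity: U/mL = μmol product / min / mL enzyme × dilution; one
  unit produces 1 μmol product per minute.
* Percent change with a pooled-variance two-tailed Student t-test
  (Welch via `var_equal = FALSE`); degenerate zero-variance groups return
  t = 0, p = 1 when means agree and a flagged floor p-value when they do
  not, rather than erroring mid-pipeline.
* Biomass = protein concentration / 0.28 g protein per g dry mass
  (configurable constant in (0, 1]).

## Phylogenies

Protein distances use the Poisson correction d = −ln(1 − p) with p the
proportion of differing sites over comparable positions; gaps and
ambiguous residues (X/B/Z) are non-comparable, with pairwise deletion by
default and complete deletion available. Saturated pairs (p ≥ 1) are an
error, not an infinity.

Neighbour joining follows Saitou–Nei: join the pair minimizing
Q(i,j) = (n−2)d(i,j) − Σd(i,·) − Σd(j,·); exact ties break towards the
smallest index pair, so degenerate inputs are deterministic but may differ
from other implementations. Negative branch lengths are clamped to zero
with the deficit moved to the sister branch, preserving the joined path
length. On additive matrices the generating topology and branch lengths
are recovered exactly (tested against independent implementations).
Bootstrap support resamples alignment columns with replacement, rebuilds
distance + NJ per replicate, and reports per-bipartition recovery
percentages; replicates with uncomparable or saturated pairs are skipped
and excluded from the denominator. Trees are unrooted (trifurcating root
in Newick), with supports as internal node labels.

## The synthetic-data generator

`generate_scenario()` builds a complete toy study whose every label is
known: 3 contigs, 120 protein-coding genes (ATG start, in-frame stop, no
internal stops, 0–3 introns of 60–150 bp, both strands), intergenic gaps of
3.3–3.6 kb so that neighbouring promoter/terminator windows cannot overlap,
and a planted variant set covering every consequence class at a mix shaped
like a real resequencing study (a 5/3/3 candidate funnel over CDS, window,
intron and intergenic variants plus one frameshift deletion and one
insertion). Planted coding variants are chosen by searching codons for a
substitution that provably yields the intended consequence and are verified
with the mutate-and-retranslate oracle at generation time — a hard
guarantee, not a statistical one.

Expression uses negative binomial counts (variance = μ + αμ²) for 2
strains × 3 replicates. Baseline means are log-normal around a median depth
of 1000; planted genes receive fixed baselines, with down-regulated genes
given more mass so the two library sizes stay close — FPKM has no
compositional correction, and a strongly unbalanced planted mass would bias
every null gene's M. Planted effects are ±2 for Rule-A genes, (−1.82,
−1.82, +2) for Rule-C transcription factors, and ±2 for eight background DE
genes. The default dispersion is α = 0.02: with 3 replicates the log2
fold-change noise SD is then ≈ 0.17, so null genes sit far below the |M| ≥
1 threshold and planted effects sit far above it, which is what makes exact
funnel recovery a fair expectation; this is the regime of technical-quality
replicates of isogenic strains under controlled induction. Noisier designs
are exercised separately: the DE power and calibration checks run at
α = 0.1 and depth 500, where the screen is asked only for ≥ 90 % power on
|log2FC| = 3 effects (planted half up, half down, again to keep the library
composition near-balanced) and a bounded null call rate, not exact
recovery.

The secretome table reuses gene ids (so transcript/protein concordance is
testable), plants 15 up and 10 down proteins of 60 at ratio cut-offs well
clear of the twofold boundary, and sets exactly 45 % of proteins to carry a
secretion signal.

What the generator does **not** emulate: sequencing error and mapping
artefacts (variants are given, not called), GC or length bias in counts,
overlapping genes, alternative isoforms, UTRs, batch effects, and any
correlation structure between genes. Passing the recovery tests therefore
shows the screen's logic is correct and calibrated under its stated model;
it does not show robustness to upstream noise sources, which enter a real
analysis through the variant caller and quantifier.

## Problem sizes and determinism

The shipped tests and the acceptance script use 120–240-gene genomes
(~0.5–1 Mb), 200–720 planted variants per oracle-equivalence run, 10–20
seeds for recovery and calibration loops, 50 random trees for NJ, and
100–500 bootstrap replicates — sizes at which every check runs in seconds
to a few minutes on one core while keeping Monte-Carlo margins wide.
Every stochastic step flows from a single integer seed (`withr::with_seed`
around generation, null construction and bootstrap), and a pipeline run
writes no timestamps, so identically seeded runs are byte-identical.

## Known limitations

* The (M, D) probability is an empirical dominance fraction, not a
  posterior; with few replicates its granularity is limited by the null
  cloud size (720 points for 120 genes at 3 + 3).
* FPKM has no between-sample compositional normalization; heavily
  asymmetric true DE shifts all M values (see above).
* Window screening uses translation starts, not transcription starts; with
  unannotated UTRs the "promoter" window is an approximation.
* NJ tie-breaking is deterministic but implementation-specific; topologies
  on degenerate (tied) matrices may differ from other software.
* The screen treats the transcription-factor list as given; errors in that
  list propagate directly to Rules B and C.
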
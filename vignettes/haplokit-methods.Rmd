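---
title: "haplokit: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{haplokit: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

haplokit re-creates, at desk scale and with complete ground truth, the
computational workflow used to characterize the immunoglobulin heavy-chain
constant (IGHC) locus from haplotype-resolved long-read assemblies. This
vignette records the models, parameter choices, and numerical decisions a
maintainer would need; the README gives the user-facing tour.

## What the synthetic locus emulates

`build_locus()` generates a random 400 kb sequence carrying the nine
canonical constant genes in their 5'→3' order (IGHM, IGHD, IGHG3, IGHG1,
IGHA1, IGHG2, IGHG4, IGHE, IGHA2). Gene models follow the field's shared
architecture: CH-domain exons of ~290–340 bp, short hinge exons between CH1
and CH2 for the IgG/IgD classes (four hinge exons in IGHG3, two in IGHD),
and an extra CH4 exon for IgM and IgE. Hinge exons are spaced 141 bp apart
so that one 47 bp hinge exon plus its upstream intron is exactly 188 bp —
the size of the recurrent IGHG3 hinge-copy indel — which lets a single
contiguous deletion change hinge copy number 4→3 the way the real
polymorphism does.

One high-identity paralog block models the IGHG4-containing segmental
duplication: a 20 kb block including IGHG4 is copied immediately
downstream, and the copy is seeded with a fixed number of differences per
1 kb window (default 2, never fewer than 1). This guarantees, by
construction, that every 1 kb window of the copy differs from its source,
so any exact overlap of ≥2 kb is position-unambiguous — the property both
the greedy read merger and the unique-k-mer aligner rely on. The copy's
gene annotation (IGHG4B) gives the locus its tenth gene.

The default structural-variant classes mirror the locus's recurrent
events: the 188 bp hinge indel; a 4.5 kb intergenic inversion between
IGHG2 and the IGHG4 block; a 19.5 kb deletion removing the duplicated
IGHG4-like block; a tandem extra copy of that block (triplication); and a
~105 kb insertion duplicating the IGHG2..IGHE span (the multi-gene
insertion class). At locus sizes below the default the event sizes scale
with the paralog block so the classes, not the exact base counts, are
preserved.

What the generator deliberately does **not** model: linkage disequilibrium
(haplotypes are drawn independently per site), indel sequencing errors
(HiFi's dominant error mode at this scale is substitution), chimeric or
class-switch-recombination artifact reads, and real IGHC sequence (no
T2T/GRCh38 material is bundled). Passing tests therefore demonstrate
algorithmic correctness on a faithful *architecture*, not performance on
real reads with real error structure.

## Coordinates

All internal intervals are 1-based closed — the R and Bioconductor
interval dialect (`substr`, IRanges) — while BED is written 0-based
half-open and VCF 1-based on export. Adopting the host language's idiom
here avoids a class of off-by-one defects that a 0-based convention would
invite in R code.

## Read simulation

"Tiled reads with overlapping boundaries" are realized as tiling passes
with step `read_length/2` plus uniform jitter up to a quarter step; passes
are stacked until the requested coverage is reached and reads are then
dropped from the final pass only, so earlier passes keep their guaranteed
within-pass overlaps of about half a read. Total bases land within 5% of
`coverage × haplotype length`. Errors are independent per-base
substitutions (no indels). Defaults: read lengths {350, 3000, 6000,
10000} bp, 15× per haplotype per length bin, error rate 0 — the benchmark
read lengths with error-free bases, since the simulation benchmark is about
assembly feasibility, not error correction; the rate is configurable
(`read_sim_spec()`).

## The anchor/chain aligner

`align_contig()` anchors contig k-mers (k = 31, sampling stride 8) on
*reference-unique* k-mers; k-mers occurring more than once in the reference
are discarded from the index, so the paralog copies anchor distinctly
without any seed-chain-extend machinery. Anchors are chained per strand by
collinearity (chains split where the target coordinate is non-monotone or
an anchor gap exceeds 50 kb); both orientations are scanned, and a
reverse-strand sub-chain between forward chains is exactly the inversion
signal.

Numerical choices:

* Within a chain, anchor runs with equal query/target gaps merge into one
  gapless block; runs longer than 500 bp are first checked for mismatch
  fraction ≤ 0.2 so a divergent interior (e.g. an inversion) is left
  unaligned rather than absorbed.
* Gaps with bases on both sides are closed by global alignment
  (Biostrings, match +1 / mismatch −2 / gap open 4 / extend 1) when the
  smaller side is ≤2 kb, giving exact indel breakpoints; larger two-sided
  gaps stay unaligned and are reported as uncovered.
* Chain ends are extended by an exact-match-biased X-drop (+1 match, −3
  mismatch, limit 200 bp), so clean SV breakpoints are recovered exactly.
* Indel sizes follow from gap arithmetic (`target gap − query gap`), which
  is exact regardless of anchor sampling.

Inside paralog blocks unique anchors exist only near the planted
differences (~every 500 bp at the default divergence), so chain *ends* near
block boundaries can be fuzzy by a few hundred bases even though indel
*sizes* remain exact. SV detection therefore tolerates up to 2 kb of query
gap at a duplication rewind and, when an insertion point falls inside a
slid block boundary, extrapolates the lift through the adjacent pure
deletion gap (limit 2 kb).

A target span re-covered by a later chain of the same query (a "rewind")
is classified as a tandem duplication when the rewound chain runs
contiguously through the breakpoint, and as an insertion of duplicated
sequence otherwise; deletion/insertion calls falling inside a re-covered
span are down-ranked to low confidence because their reference frame is
ambiguous. Ambiguous signatures are always reported, never dropped.

## Benchmarking rules, read literally

* Contig merging requires a suffix/prefix overlap of at least 2000 bp with
  at most 5 substitutions; any indel in the candidate overlap disqualifies
  it (strictness preferred where the rule is silent). Candidate discovery
  uses 6 disjoint 32-mer probes of the incoming prefix, so any qualifying
  overlap (≤5 mismatches) is found by at least one clean probe. Merge
  order is longest-contig-first then lexicographic id, making the result
  permutation-invariant.
* Per-base read support: a position enters the summary when its depth is
  ≥10 (the ">9×" rule) and counts as supported when the agreeing fraction
  is ≥0.8 — both inclusive, the literal reading.
* Genotype concordance assesses reference positions only; a position is
  "missing" unless spanned by the diploid assembly and ≥4 reads, and
  missing positions leave the denominator.
* Windowed error rates are truth-anchored 10 kb windows; the last partial
  window is kept and weighted by its length in the mean (the natural
  unbiased choice where the procedure is unspecified). Insertions are
  charged to their breakpoint window; deletions to the windows of the
  deleted bases; windows no chain covers are reported separately rather
  than imputed.
* The read-candidate rescue threshold (`minrel = 0.05`) is inclusive,
  mirroring the cited tool flag's semantics.
* Positions covered by only one haplotype are emitted half-missing
  (`1/.`) rather than forced homozygous — explicitness preferred.

## CNV-region clustering

Region haplotypes are extracted between flank anchors lifted through the
contig's chains (±5 kb flanks). When a region recurs in a contig (dispersed
duplication) each anchor lifts more than once; the tightest same-strand
pairing is taken so one copy is extracted rather than the span across
copies. Copy number is the extracted-versus-reference length difference
quantized to the duplicated block length, and haplotypes are binned by that
class before distances are computed: cross-bin distances are pinned to the
sentinel 1.0 so different copy-number classes can never merge, which
reproduces bin-separated clusters whether one clusters within bins or
globally. Within a bin the distance is the gap-excluded p-distance of a
pairwise global alignment (plain Hamming p-distance for equal-length
pairs — at within-bin divergences the two coincide, and it avoids
quadratic alignments of identical-length haplotypes). Average linkage was
chosen where the linkage was unspecified (robust to outliers;
configurable), the tree is cut at 0.1, and labels are deterministically
re-ordered by cluster size then smallest member id so clustering is
permutation-invariant.

## Allele curation

Extraction lifts every exon of a gene through a *single* chain of a single
contig and splices them in transcription order (reverse-complementing as
needed); any unliftable exon is a no-call — the all-exons-on-one-contig
rule. This also means a gene whose exons were hit by an SV (e.g. the hinge
deletion) is a no-call by design, and such genes are likewise dropped from
the simulator's allele-assignment truth: the closed-loop recovery property
is asserted over assignments that survive.

Matching is exact-first; otherwise the closest allele by Levenshtein
distance over the spliced exons (indel-tolerant, since hinge copy
variation changes length), ties broken toward the lowest allele number
with all ties reported. Novel names append ordered descriptors in 1-based
spliced coordinates — substitutions `303g>a`, insertions `120insACG`,
deletions `141del47` — chosen to be unambiguous and invertible:
`apply_descriptors()` regenerates the observed sequence from the closest
allele, and the test suite asserts that round trip. The per-position
support statistic uses all mapped reads at each exonic position, while
fully spanning reads with 100% exonic agreement are counted separately, so
both views of read support are reported.

Because the synthetic alleles are random sequences rather than open
reading frames, a stop codon is flagged only when the variant *introduces*
one at a codon where the reference allele has none.

## Population statistics

The genotype matrix codes alt-allele dosage with missingness where a
donor's diploid span does not cover a site; multi-allelic sites are
decomposed into one biallelic site per alt allele (configurable drop). The
MAF filter defaults to strictly > 0.05 with an `inclusive` toggle, because
the workflow's own description uses both readings in different places; the
discrepancy is surfaced as an option rather than silently resolved.
F_ST is the two-group Weir–Cockerham (1984) estimator with the remaining
populations pooled ("one vs. rest"), not a multi-population θ; missing
genotypes are excluded from per-site counts (no imputation), sites
monomorphic in the combined sample are undefined and excluded, and the
summary θ̂ is the ratio-of-sums estimator. PCA mean-imputes missing
entries, centers at 2p and scales by √(p(1−p)), drops monomorphic columns,
and decomposes by SVD; no LD pruning is applied.

## Problem sizes used in the tests

Unit and property tests run on a 60 kb locus (same architecture, scaled
paralog block) with cohorts of 4–100 donors; SV-signature tests use 120 kb
and full 400 kb references; the two benchmark computations
(`scripts/acceptance.R`) use the full 400 kb diploid locus with 6/10 kb
reads at 15× and 6 kb reads at 40×. These sizes keep the whole suite
around a minute on one core while exercising every code path at the
default parameterization.

## Known limitations

* The aligner is a toy for collinear-with-SVs comparisons at locus scale;
  it has no mapping-quality model, no affine-gap optimization beyond the
  single documented gap cost, and emits PAF, not SAM/BAM.
* Read placement is ungapped (substitution-only error model); indel-error
  reads would need the chain aligner instead.
* SV genotyping assumes one event per breakpoint per haplotype and pairs
  calls across haplotypes within 50 bp; nested or overlapping same-kind
  events at one breakpoint are not resolved.
* Breakpoints *inside* paralog blocks are reported to the precision the
  planted divergence allows (a few hundred bases at defaults); sizes stay
  exact.
* The cohort model draws sites independently; F_ST/PCA recovery tests are
  therefore clean-room exercises, not demonstrations on LD-structured
  data.
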
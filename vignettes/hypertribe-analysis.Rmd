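---
title: "Calling HyperTRIBE editing sites and RBP targets with tribecall"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling HyperTRIBE editing sites and RBP targets with tribecall}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tribecall)
```

## The experiment this package analyses

HyperTRIBE identifies the transcripts bound by an RNA-binding protein (RBP)
without antibodies or crosslinking. The RBP is fused to the hyperactive
(E488Q) catalytic domain of the RNA editing enzyme ADAR2; wherever the
fusion binds an mRNA, nearby adenosines are deaminated to inosine, which
reverse transcription and sequencing read as guanosine. An RBP's targets
therefore appear as novel A-to-G mismatches in stranded RNA-seq, and the
analysis problem is to distinguish those marks from three confounders:

* **background editing** by the untethered catalytic domain, measured in a
  matched "Hyper-only" control library;
* **genomic variants** (homozygous SNPs between the sequenced strain and
  the reference), which look like 100%-edited positions; and
* **sequencing error**, which scatters low-frequency mismatches everywhere.

`tribecall` implements the post-alignment half of such an experiment in
yeast-like settings: strand-resolved base counting from coordinate-sorted
SAM/BAM, threshold-based site calling, control subtraction, SNP exclusion,
target-set construction across replicates, comparative statistics, and
motif-window preparation. Upstream read trimming and alignment are out of
scope; the pipeline consumes aligned reads.

## The calling model

At a genic position whose reference base is A on the transcript strand, let
$A$ and $G$ be the deduplicated read counts of the reference and edited
base on that strand. The editing percentage is

$$\mathrm{editing\%} = 100 \cdot \frac{G}{A + G},$$

and a site is called under the rNeM convention when total coverage is at
least $N$ and editing% at least $M$; `thresholds("r20e10")` (at least 20
reads, at least 10% editing) is the default, with `r10e10` the standard
relaxed preset. Two choices deserve comment:

* **The denominator is $A+G$, not total coverage.** C and T reads at an A
  position are almost always sequencing error and carry no information
  about editing; including them would deflate editing% at noisy positions.
  The coverage threshold, in contrast, is applied to total coverage, so a
  site must genuinely be well sequenced.
* **Counting is strand-aware.** Reads contribute to a genic position only
  when their library strand (inferred from the FLAG bits and the
  `fr-firststrand` / `fr-secondstrand` protocol) matches the gene's
  strand; counts and the reference base are reverse-complemented for
  minus-strand genes so an edit always reads as reference A, observed G.
  On real data a position inside two opposite-strand genes is evaluated
  once per gene strand, never merged.

PCR duplicates are collapsed before counting, by positional key
(contig, start, end, library strand, mate identity) — the convention for
libraries without UMIs. Overlapping mates of one fragment count once per
position by default (`count_mode = "fragment"`); a per-read mode exists
because published pipelines differ on this point and the choice is not
stated in the protocols this package follows.

## Filtering rules and their defaults

**Background subtraction.** A called site is removed when the Hyper-only
control itself shows editing there: control coverage ≥ 10, control
editing% ≥ 1, and at least 2 control G reads. The percentage floor alone is
not usable at realistic depth: one error G read among 60 control reads is
already 1.7%, and a 1%-only rule silently deletes roughly a tenth of true
sites at 60–100×. The two-read floor makes the rule mean "reproducible
editing in the control", not "any stray G".

**SNP exclusion (wtRNA–RNA approach).** A genomic variant shows its
alternate allele in a wild-type RNA sample too, so a site is dropped when
the wild type fails to show the reference allele: non-reference fraction of
wild-type coverage ≥ 0.8 at coverage ≥ 10. The rule is deliberately
allele-agnostic rather than G-specific: an A→C variant plus a single
error G read otherwise presents as a "100% edited" site ($A=0$, $G=1$) and
would sail past a rule that only inspects G. When no wild-type library
exists, a conservative fallback drops sites at ≥ 95% editing in both the
fusion and control samples.

Both filters act by independent per-site predicates, so their order does
not matter; the test suite asserts this commutativity.

## What the synthetic generator emulates — and what it does not

The generator builds a small intronless genome (default 200 genes of
400–800 bp with 50 bp 5′ UTRs and 150 bp 3′ UTRs on one contig), selects
25% of genes as targets, and plants edit sites at gene-strand adenosines:
76% of target genes receive one site, 18% two, 6% three, mirroring the
published edits-per-gene histogram for a yeast KH-domain RBP. Per-site
editing fractions are uniform on 0.2–0.8 — published work reports
thresholded percentages rather than a fraction distribution, so this range
is an assumption documented here, not a literature fact. Homozygous SNPs are planted genome-wide at
5×10⁻⁴/bp, sequencing errors are uniform at 0.005/base, and 10% of the
library is exact PCR duplicates. Reads are emitted pre-aligned (SAM),
because alignment is out of scope and the aligned file is the pipeline's
actual input contract.

Three design details keep the ground truth exactly checkable:

* **Reads are drawn from transcripts**, so "coverage" means transcript
  coverage (reads per gene = coverage × transcript length / read length)
  and intergenic positions are empty, as in RNA-seq.
* **Read lengths are jittered ±10%** so that the positional duplicate key
  rarely collides between genuinely distinct fragments, and the simulator
  records the exact number of distinct keys among its primary reads — the
  expected post-deduplication count, asserted exactly in tests.
* **Edit sites are placed in the transcript interior** (at least one read
  length from each end), where simulated coverage equals the configured
  depth, so binomial statements about recovered editing fractions hold
  exactly rather than approximately near coverage ramps.

The generator does *not* emulate: splicing and introns, overlapping genes,
heterozygous variants, base-quality profiles, coverage bias along
transcripts, or expression-level variation between genes. Passing tests on
this material therefore demonstrate the correctness of the counting,
calling, filtering and bookkeeping logic under a clean error model — not
robustness to alignment artefacts or library pathologies in real data.

## Comparative statistics

Replicate agreement is the squared Pearson correlation of editing
percentages at shared sites. Signal-to-noise is the ratio of fusion to
control site counts under one threshold. Gene-set overlap uses Fisher's
exact test on the 2×2 table over an explicit universe — the universe is
always supplied by the caller because no default (all annotated genes? all
expressed genes?) is defensible in general. The test is one-sided
(enrichment) by default since over-representation is the question asked;
two-sided is available. Differential-expression filtering implements the
two published cutoff styles: microarray mode (`p < 0.1` and
`|log ratio| > 0.2`, on the log column as supplied, since the original
source's log base is not stated) and RNA-seq mode (mean FPKM ≥ 2, fold
change ≥ 1.5 in either direction). Grouped distribution comparisons report
pairwise Kolmogorov–Smirnov and Welch t statistics plus a one-way ANOVA,
with ECDF plotting via `autoplot()`.

## Motif windows

For motif discovery the package exports, per called site, the ±100 bp
window (201 bp) on the transcript strand, truncated and flagged at contig
ends, plus a background of the same number of 201 bp windows sampled
uniformly (with replacement across positions) from non-target gene
transcripts. Windows are genomic rather than spliced-transcript sequence —
correct for the intronless synthetic genes and the dominant intronless
case in yeast; spliced genes would need transcript-space extraction, which
is out of scope. Windows are emitted per site, so adjacent sites in one
gene yield overlapping windows; no deduplication rule is applied because
none is established. RNA-alphabet motifs are accepted and stored as DNA.
`kmer_enrichment()` is a deliberately simple internal check (windows
containing a k-mer, one-sided Fisher); de novo discovery belongs to
MEME/XSTREME on the exported FASTA files.

## Numerical and testing choices

All coordinates are 1-based inclusive internally; BED export is 0-based
half-open with score = editing% × 10. Determinism is end-to-end: every
random draw derives from one root seed, and identical configurations give
byte-identical FASTA/GFF3/SAM/JSON outputs. The test suite runs the full
pipeline at 200 genes × 100× coverage for recovery checks, and smaller
layouts (12–40 genes, 40–60×) for property tests such as threshold
monotonicity across twenty seeds, strand-mirror equivariance (an
all-minus-strand genome and its reverse complement must call identical
sites), and exhaustive agreement of the Fisher overlap p-value with direct
hypergeometric enumeration for every 2×2 table with universe up to 60.

## Known limitations

The caller is purely threshold-based; replicate-aware statistical models
(beta-binomial, GLMs) are out of scope, as are C-to-U (STAMP) chemistry,
editing QTLs, and isoform-level assignment. The SNP fallback without a
wild-type sample cannot distinguish a homozygous A→G variant from a
saturated genuine edit site when the control is silent; a wild-type RNA
library is strongly recommended. Spliced CIGARs are handled for real BAM
input (M/=/X/I/D/N/S), but the simulator never produces them, so that code
path is exercised only by hand-built fixtures.
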
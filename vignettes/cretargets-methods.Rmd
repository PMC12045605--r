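---
title: "Methods: enhancer-based target calling, motif p-values and locus enrichment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: enhancer-based target calling, motif p-values and locus enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cretargets)
```

## The procedure

`cretargets` identifies putative direct target genes of a transcription
factor from epigenomic peak data, in four composable stages.

**1. Active enhancers.** Open-chromatin (ATAC) peaks and H3K27Ac peaks are
intersected per base; a region supported by both marks is treated as a
candidate active regulatory element. Fragments overlapping promoter zones
(± 1 kb of a TSS by default) or exons are removed, leaving intronic and
intergenic elements — the classic "putative enhancer" filter. Peak
classification uses a fixed priority (promoter > exon > intron >
intergenic), so each peak has exactly one category.

**2. Soft TSS assignment.** Each element is assigned to *every* gene whose
TSS lies within a distance window (35 kb by default) of the element
midpoint. This soft annotation deliberately allows many-to-many links: a
regulatory element may plausibly act on several promoters, and a gene may
be served by several elements. The distance is signed (positive when the
TSS is downstream of the midpoint in genome coordinates) and the window
boundary is inclusive.

**3. Motif evidence.** Element sequences are scanned with one or more
position weight matrices (PWMs). A window of width $w$ is scored by summed
log-odds in bits,
$$ S = \sum_{i=1}^{w} \log_2 \frac{p_{i,b_i}}{q_{b_i}}, $$
where $p_{i,b}$ is the motif probability of base $b$ at position $i$ and
$q$ the background. The p-value of a score is computed **exactly** under
the order-0 background null by dynamic programming: per-position scores
are discretised to a grid (1/1000 bit by default) and the probability mass
function of their sum is built by convolving one position at a time; the
survival function then converts any window score to
$P(\text{score} \ge s)$. Both strands are scanned; windows containing N
are skipped; all hits at $p \le 0.001$ (default) are reported, overlaps
included. Several matrices are combined with OR semantics — an element
"harbours a motif" if any matrix hits it.

**4. Target calling.** A gene is called a putative target iff it passes
the expression-enrichment filter (fold change > 2 and FPKM > 10, both
strict) *and* receives at least one motif-bearing element within the
window. Supporting elements, their distances and hit counts are reported
per gene; an element supporting several genes is counted once in the
element total. Intersection fragments are the countable element unit and
receive stable `chrom:start-end` identifiers.

A companion stage cross-references called targets (optionally mapped
through an ortholog table) against disease loci: loci without a known
causative gene are extended by 100 bp on both sides, genes whose spans
overlap an extended locus by at least one base are collected, and the
overlap of targets with those genes is tested with Fisher's exact
one-tailed test,
$$ p = P(X \ge k), \quad X \sim \mathrm{Hypergeom}(N, K, n), $$
at $\alpha = 0.1$. Small-sample assay helpers implement ChIP-qPCR percent
input, $100 \cdot 2^{(\mathrm{Ct}_\mathrm{input} -
\log_2(1/f)) - \mathrm{Ct}_\mathrm{IP}}$ for input fraction $f$, the
ratio paired t-test (a paired t-test on $\log_2$ within-pair ratios,
matching qPCR cycle arithmetic), and the differential-expression
threshold filter (log2FC > 1.5, adjusted p < 0.1).

## Parameters that matter

| Parameter | Default | Unit | Notes |
|---|---|---|---|
| `window` | 35000 | bp | TSS assignment window, midpoint-based, inclusive |
| `promoter_window` | 1000 | bp | promoter zone half-width around the TSS |
| `p_threshold` | 0.001 | — | per-match motif p-value, no multiple-testing correction |
| `fc_min`, `fpkm_min` | 2, 10 | —, FPKM | expression enrichment, strict inequalities |
| `lfc_min`, `padj_max` | 1.5, 0.1 | log2, — | DE threshold filter, strict |
| `flank` | 100 | bp | locus extension before gene overlap |
| `alpha_enrich` | 0.1 | — | one-tailed locus enrichment |
| `alpha_assay` | 0.05 | — | assay t-tests |
| `background` | uniform | — | order-0 scan null, overridable |
| `pseudocount` | 0.001 | — | folded into PWM probabilities at construction |
| `granularity` | 1/1000 | bit | score discretisation step |

## Design choices where the design was open

* **Internal container.** Intervals live in `GRanges` (1-based, closed) —
  the standard container of the R genomics stack — while every file format
  and user-facing coordinate (BED, gene TSV, locus TSV, motif hits) uses
  the BED convention (0-based, half-open). The conversion happens exactly
  once, in `genomic_intervals()` and the writers, which keeps off-by-one
  drift out of the analysis code.
* **Midpoint distance.** The assignment window is measured from the
  element midpoint (`floor((start+end)/2)` in BED coordinates) to the
  TSS. The midpoint is symmetric and robust to peak width; edge-based
  measurement would make wide elements reach farther for no biological
  reason. The boundary is inclusive (a TSS at exactly 35,000 bp is
  assigned; at 35,001 bp it is not).
* **Soft annotation, not nearest-gene.** All in-window TSSs are kept.
  With a realistic gene density, element counts exceed gene counts only
  under many-to-many linkage, and nearest-gene assignment is known to
  mis-assign a substantial fraction of enhancers.
* **Fragments as the countable unit.** After intersection, each fragment
  gets a fresh identifier and is what the element counts refer to.
* **Enrichment universe.** The universe $N$ for the locus enrichment test
  is the set of genes in the supplied gene-coordinate table, and $K$ the
  subset overlapping extended unresolved loci. The universe is an input,
  echoed in the result, never a hidden constant. Locus overlap uses gene
  spans (not TSS points): a locus is a region hypothesis, and a gene
  partially inside it is a candidate.
* **Percentage rounding.** The cross-reference percentage is rounded to
  the nearest integer (36/156 → 23%).
* **One-tailed direction.** The ratio paired t-test's one-tailed
  alternative is "first argument greater" (e.g. specific antibody over
  IgG, wild-type enhancer over motif-deleted), the direction in which the
  assays are read.
* **PWM inputs.** Binding-site matrices are inputs in MEME-minimal
  format; the package ships no claim about any published matrix's cell
  values. The synthetic generator builds sharply peaked stand-in matrices
  (`make_pwm`) from a consensus word.

## Numerical choices

* Score discretisation: per-position log-odds are rounded to the grid
  *before* summation, and scanned windows are scored on the same integer
  grid, so DP p-values agree exactly with exhaustive word enumeration
  under the shared discretisation; at 1/1000 bit the discretisation error
  is far below the 0.001 decision threshold (halving the granularity
  moves p-values by < 2%). A support cap rejects absurd
  granularity/width combinations with advice rather than exhausting
  memory.
* Survival lookups below the minimum achievable score return 1; the
  minimum score has p = 1 by construction.
* Minus-strand scanning scores the reverse-complemented matrix on the
  plus strand and reports plus-strand coordinates. The same null
  distribution is used for both strands; this is exact for the uniform
  default background (and any complement-symmetric background).
* Tie-break in motif deletion: lowest p-value, then leftmost start.
* Zero-variance paired tests are flagged indeterminate instead of
  producing p = 0 or 1.
* Interval outputs are always sorted by (chromosome lexicographic,
  start, end); chromosome-name mismatches between inputs are reported,
  never silently harmonised.
* `slop` clamps at both chromosome edges; empty intervals are rejected at
  construction.

## The synthetic study generator

`simulate_study()` emits a complete toy study — genome FASTA, chromosome
sizes, gene models, ATAC and H3K27Ac BED files, MEME matrices, expression
table, ortholog map, disease loci — plus a `truth.json` with the planted
ground truth. The design:

* 3 chromosomes × 100 kb, 30 genes (10 per chromosome), 12
  expression-enriched, 5 planted target genes, ~300 bp elements.
* Background sequence is i.i.d. uniform over A/C/G/T, matching the
  scanner's default null so planted-site p-values are exactly controlled.
* Geometry guarantees exact truth: planted-target genes sit at chromosome
  ends with their elements ~4.3 kb away; enriched non-target genes sit in
  chromosome middles, ≥ 35 kb from every motif-bearing element midpoint;
  motif-bearing decoy elements live on a chromosome whose only enriched
  gene is ~87 kb away.
* All six decoy classes are present: ATAC-only peaks, H3K27Ac-only
  peaks, promoter-overlapping elements, exonic elements, motif-free
  active elements near enriched genes, and motif-bearing elements near
  non-enriched genes.
* Element sequences are placed by rejection sampling (with a retry cap):
  a motif-free element is resampled until it contains no hit at the
  configured threshold, and a planted element until its only hits lie on
  the planted consensus site. This pins hit counts exactly to the design;
  chance motifs elsewhere in the genome are irrelevant because only
  element sequences are ever scanned.
* Same seed ⇒ byte-identical files.

Two further generators, `simulate_locus_study()` and
`simulate_stage_expression()`, are synthetic stand-ins for
publication-style supplementary tables that depend on proprietary
databases (OMIM extracts, genome-wide human gene tables, staged human
expression): they realise a designed association structure (e.g. 36 of
156 targets inside 50 unresolved loci; 121 of 156 orthologs enriched at
one or both stages) as *coordinates and values*, from which the pipeline
then recomputes the counts. Gene placement keeps every gene ≥ 50 kb from
locus boundaries, so the 100 bp flank can never flip a designed
membership; expression values are drawn away from the filter thresholds
for the same reason. The locus-study universe (156 targets + 1000
non-target genes, 136 of them in loci) is scaled down from a genome-wide
table; it is chosen so that targets are genuinely over-represented in
loci, mirroring the qualitative situation the enrichment test is meant to
detect.

What passing on synthetic data shows — and what it does not: the tests
prove the *logic* (interval algebra, classification priority, exact
p-value calibration, threshold boundaries, composition, determinism) at
study conditions where ground truth is knowable. Real chromatin data
violate the generator's simplifications — peaks have shape and width
distributions, background composition is non-uniform and autocorrelated,
enhancer-gene linkage does not respect a hard distance cutoff — so
perfect recovery here does not promise perfect biology; it promises that
any disagreement on real data comes from the data and the model
assumptions, not from the implementation.

## Problem sizes

The shipped test-suite and acceptance runs use: 10 random 50-vs-50
interval sets plus ~1000 pairwise/slop cases for the per-base oracles; 50
random matrices of width ≤ 8 against exhaustive `4^w` enumeration; every
enrichment configuration with N ≤ 12 against subset enumeration plus 25
closed-form spot checks up to N = 10⁴; and 20 seeded synthetic studies
for end-to-end precision/recall. These sizes make every oracle exact
while keeping a full run at a few minutes on one CPU.

## Known limitations

* Order-0 background only; no Markov backgrounds, no q-values.
* No BigWig/BigBed or BAM input; coordinate lift-over and ortholog
  retrieval are consumed as tables, never performed.
* Enhancer-gene assignment is purely distance-based; no chromatin-contact
  or CTCF-domain information.
* The enrichment p-value depends on the supplied gene universe; with a
  different universe table the same overlap can change significance.
* Cytogenetic-band loci must arrive pre-resolved to coordinates.
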
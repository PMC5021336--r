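---
title: "Methylome quantification, DMR calling and bulk segregant mapping with methmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methylome quantification, DMR calling and bulk segregant mapping with methmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methmap)
```

## Scope and data model

methmap implements a two-sample WGBS comparison pipeline for plant
methylomes together with bulk segregant analysis (BSA) of pooled F2
allele counts. Its unit of observation is the strand-specific cytosine:
a `methylome_sample` holds, per (chromosome, position, strand), the
methylated and unmethylated read counts and the sequence context — CG,
CHG or CHH with H ∈ {A, C, T} — as produced by any bisulfite aligner
that emits a per-cytosine report. The on-disk dialect is a 7-column
tab-separated cytosine report (both covered and uncovered cytosines
allowed); gene models travel as GFF3, DMRs as BED6, everything else as
headered TSV. Coordinates are 1-based inclusive everywhere except BED
output (0-based half-open). Strands are reported separately and never
pooled at I/O level; any pooling is an explicit analysis step.

## Site-level quantification and QC

A cytosine's methylation level is `n_meth / (n_meth + n_unmeth)`,
defined only at sites with at least fourfold coverage
(`min_coverage = 4`). Genome- and feature-level summaries are *weighted*
levels — `100 · Σ n_meth / Σ total` over qualifying sites — rather than
means of per-site ratios. The weighted form was chosen because it is
robust at coverage just above the floor, where per-site ratios are
coarse (quarters at 4×); at uniform depth the two are nearly identical.

Chromosome-scale profiles sum the site-level methylation mass of
qualifying sites in bins (default 100 kb) per context, then normalise
each context so its densest bin reads 100%. Density is summed site-level
mass rather than a count of "methylated sites", which would require
inventing a binary call threshold; at constant depth the two are
monotonically related, and the normalisation makes the choice largely
cosmetic.

Conversion-rate QC exploits the unmethylated chloroplast genome: every
methylated call there is a bisulfite conversion failure, so the
conversion rate is `100 · (1 − Σ n_meth / Σ total)` over all covered
organellar cytosines. No coverage floor applies here — the estimate is a
pooled proportion, not a per-site level, and discarding low-coverage
sites would only discard information.

## The sliding-window DMR caller

Windows span five consecutive same-context cytosines (both strands
interleaved in position order) and advance one cytosine at a time, so a
chromosome with *n* context cytosines yields *n − 4* windows. Windows
are built over the union of the two samples' site inventories, making
window coordinates sample-independent. A member site *qualifies* when it
has ≥ 4× coverage in **both** samples; the window's covered-site
fraction is qualifying/5, and only qualifying sites contribute to its
pooled counts. The fraction criterion ("coverage > 0.6", i.e. at least
4 of 5 sites) reuses the only coverage notion already defined in the
pipeline — the fourfold site rule — rather than introducing a second
depth threshold.

Eligible windows (fraction > 0.6, both pooled samples non-empty) are
tested with a two-sided Fisher's exact test on the pooled 2×2 table of
methylated vs unmethylated reads by sample. `fisher_p()` sums
hypergeometric probabilities not exceeding that of the observed table,
with the conventional 1e−7 relative tolerance for floating-point ties;
degenerate tables (a zero row or column margin) return p = 1. P-values
are Benjamini–Hochberg adjusted within one comparison × context family —
contexts are analysed separately throughout, so each context forms its
own multiple-testing family.

A window passes when adjusted p ≤ 0.05, the fold change of pooled levels
(max/min) exceeds 2, and the covered fraction exceeds 0.6. No
pseudocounts are added: a zero level against a positive one gives an
infinite fold change, which passes the criterion — silently regularising
zeros would change the stated "> 2" rule. Windows with both levels zero,
or an empty pooled sample, fail.

Passing windows whose spans overlap *and* share a direction (hyper =
sample B more methylated than A) merge transitively; the DMR's bounds
are the outermost member-cytosine positions and its pooled counts are
recomputed over the unique qualifying member sites, so overlapping
windows are not double-counted. Merging is direction-aware because a
mixed-direction region would have no assignable direction for gene-level
classification. Merged regions shorter than 200 bp are dropped (counts
of dropped regions are retained as an attribute). In the rare case that
a hyper and a hypo region overlap after merging, the one with the larger
best adjusted p is withheld so that emitted same-context DMRs never
overlap.

Threshold defaults (`default_params()`): coverage 4, window 5, FDR 0.05
(the "≤ 0.05" form), fold change 2, fraction 0.6, minimum length 200 bp,
flank 2 kb, bin 100 kb.

## DMG annotation

Each gene's territory is its body plus strand-aware 2 kb flanks
(upstream 5′ of the body, downstream 3′), clipped at chromosome ends. A
single base pair of intersection with any of the three regions makes a
gene a DMG — "at least one DMR in" is read as any overlap, since no
minimum is otherwise defined. A DMG's direction is exclusive: the shared
direction of its member DMRs if they agree, otherwise the direction of
the member with the smallest adjusted p (ties broken by larger total
span, then hyper). This preserves the arithmetic identity
hyper-DMGs + hypo-DMGs = total DMGs. Transposable elements participate
in feature-level methylation summaries but are not annotated as DMGs.
Cross-comparison overlap summaries intersect gene-id sets per direction
pair; the seven-cell body/upstream/downstream partition is disjoint and
exhaustive by construction.

## Bulk segregant analysis

F2 individuals are two independent F1 gametes simulated as Markov chains
along the genetic map under Haldane's map function
(r = ½(1 − e^(−2d/100)) for distance d in cM). The high pool selects
individuals homozygous for the mutant allele at the recessive causal
locus; the normal pool draws from the phenotypically normal classes in
their natural 1:2 homozygous-wild-type:heterozygote ratio — the
composition of the original normal pool is not recorded, and the
unselected-normal model is the conservative choice (expected causal-locus
difference Δ = 1 − 1/3 = 2/3; a wild-type-selected pool would give Δ = 1
and only make localisation easier). Allele counts, not genotype calls,
are the unit: each individual contributes two chromosomes per marker.
The Δ profile is smoothed with a truncated centred moving average
(default k = 5 markers) and candidate intervals are maximal runs of
markers with smoothed Δ ≥ 0.4. Both k and the threshold are configurable;
0.4 sits midway between the null expectation (0) and the recessive
expectation (2/3), more than three binomial standard errors from each
with pools of 40.

## The synthetic-data generator

The generator emulates the study conditions end to end: reference
sequences drawn i.i.d. at GC 0.36 (A. thaliana-like); per-context
baseline methylation rates (CG 0.28, CHG 0.10, CHH 0.03) matching
wild-type shoot levels; planted DMRs that set a chosen context's sites
inside disjoint random intervals to rates m_A ≠ m_B; read depth Poisson
with mean 30 (the original sequencing averaged ~28×; Poisson is the
simplest depth model sufficient for recovery testing); methylated calls
Binomial(n, m + (1 − m)·f) with conversion-failure rate f = 0.005 by
default (the observed conversion floor of 99.57% corresponds to
f = 0.0043) — over-conversion of methylated cytosines is not modelled,
matching a QC that tracks only conversion failure; and an unmethylated
chloroplast chromosome. Strands are simulated independently, without
forced CG symmetry. Everything is deterministic under the configured
seed, down to the bytes of the written files.

What the generator does **not** emulate — and what passing benchmarks
therefore cannot certify on real data: read-level error and mapping
bias, non-uniform coverage (GC or mappability tracks), spatial
autocorrelation of methylation outside planted regions, CG-site
clustering (CpG-island-like structure), and replicate-level biological
variance. The caller's null behaviour on real data depends on exactly
these features.

### Benchmark scenarios and problem sizes

The validation suite uses: exact-test agreement with full enumeration on
all 2×2 tables with row margins ≤ 30 (246,016 tables); FDR agreement
with a sort-based oracle on 10⁴ random vectors of length ≤ 500; a null
comparison (no planted signal) on a 200 kb genome at depth 30 across 3
seeds, where at most 2 DMRs per context are tolerated; planted-DMR
recovery of six 2 kb CG regions (rates 0.1 vs 0.8, ≥ 12 sites each) on a
400 kb genome across 3 seeds, scored as base-pair recall and precision
≥ 0.9; conversion-rate recovery over > 10⁵ organellar calls within
±0.07 of 99.5%; weighted-summary recovery over > 5·10⁴ CG sites within
±1 point of 28%; and BSA localisation over 20 seeds (100 markers,
causal at 40 cM, pools of 40). Planted regions are 2 kb — well above the
caller's boundary resolution — because boundary windows holding as few
as two planted cytosines legitimately pass the fold-change rule, so
calls overhang the truth by up to ~3 inter-cytosine gaps per side; a
recovery benchmark measures whether regions are found, not the caller's
boundary sharpness, and short regions would conflate the two. Genome
sizes were chosen so each scenario's statistical target (3·SE bounds,
site-count floors) is met with margin.

## Numerical and degenerate-input choices

Fisher p-values use the standard two-sided summation rule with a 1e−7
relative tie tolerance (matching `fisher.test`); agreement with direct
enumeration is at 1e−9 or better. Contexts at chromosome ends with
missing downstream bases treat the absent base as H (the trinucleotide
is N-padded). Chromosomes with fewer than five context cytosines yield
zero windows, not an error; an all-zero context in a density profile
stays at zero rather than dividing by zero; markers with an empty pool
are flagged undefined rather than dropped. Empty input files parse to
empty objects with a warning; malformed rows are reported with line
numbers (cytosine reports abort; GFF3 rejects row-wise, keeping valid
rows).

## Known limitations

The caller is replicate-free by design — it compares exactly two pooled
samples, as the underlying two-sample Fisher framework does — so
biological variance is not separated from sampling variance.
Neighbouring windows share four of five sites, so window-level FDR
control is over correlated tests; the merge step absorbs much of this,
but the emitted "best adjusted p" per DMR should be read as a ranking
score, not a calibrated region-level error rate. BSA models idealised
allele counts (2 per individual), not array hybridisation intensities or
sequencing of pooled DNA; its Δ profile is therefore cleaner than a real
pooled-array track at equal pool sizes. GO enrichment of DMG lists is
out of scope — the DMG tables are written so external tools can consume
them.
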
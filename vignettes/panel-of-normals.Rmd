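---
title: "Building and applying a panel-of-normals SNP database"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building and applying a panel-of-normals SNP database}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ponsub)
```

## The problem

A tumor variant set is an overlay of somatic mutations on thousands of
inherited germline polymorphisms. Standard practice removes the germline
component by subtracting the matched normal and then depleting against
public SNP catalogs. Those catalogs are strongly biased toward European
ancestry cohorts, so for under-represented populations a substantial tail
of real germline polymorphism — mostly at low minor allele frequency —
survives depletion and inflates the apparent somatic burden. The remedy is
a *panel of normals*: variants seen in unrelated normal samples from the
population of interest, banked once and subtracted from every tumor.

`ponsub` implements that remedy end to end: merge normal VCFs, filter to
high-confidence germline variants, deplete the already-known ones, persist
the remainder as a database, and subtract it from tumor VCFs.

## The variant key and VCF handling

All matching uses the tuple *(chromosome, position, reference allele,
alternate allele)* in a fixed genome build. Three consequences follow:

* **Multi-allelic records are split** into one key per alternate allele
  before any matching; the key has one ref and one alt by definition.
  During subtraction, a multi-allelic tumor record loses only the matched
  alleles and is dropped outright only when all of them match — dropping
  the whole record on a single-allele match would over-subtract.
* **Chromosome labels are normalized** (leading `chr` stripped
  case-insensitively, `M` → `MT`) on both sides of every comparison, so a
  database built from one caller's VCFs applies to another's. Positions
  stay 1-based throughout; no coordinate conversion happens anywhere.
* **Indels are matched as exact strings** after splitting. No
  left-alignment or parsimony trimming is applied: trimming would silently
  change which records match, and the correct place to normalize allele
  representation is upstream of this tool.

Symbolic alleles (`<DEL>`, breakends, `*`) cannot be expressed as sequence
keys; they are skipped (builder) or retained (subtraction) with a warning,
never silently matched. The VCF layer preserves data lines verbatim, so a
read–write cycle is byte-identical and subtraction output carries the
original INFO/FILTER/FORMAT fields untouched plus one provenance header
line.

## The quality filter

A merged cohort entry carries its recurrence $r$ (distinct carrier
samples) and cohort-maximum known alt read depth $d$ (from the `AD` FORMAT
entry for that allele). The builder keeps an entry iff

$$ d \ge \texttt{min\_alt\_depth} \quad\text{or}\quad r \ge \texttt{min\_recurrence}, $$

with defaults `min_alt_depth = 5` and `min_recurrence = 4`. Choices worth
stating explicitly:

* The two clauses overlap at a depth of exactly 5; the predicate is a
  plain OR, so a depth-5 singleton passes and a shallow variant is rescued
  by recurrence alone. Units: `min_alt_depth` counts reads supporting the
  alternate allele in one sample, not total coverage.
* Depth is aggregated across the cohort as a **maximum**: one confidently
  covered carrier is enough to trust the site. Requiring the threshold in
  every carrier would be a materially stricter filter.
* Records lacking `AD` have unknown depth and can pass only through the
  recurrence clause; they are never assumed deep.
* Recurrence counts **distinct samples**, never VCF lines: a duplicated
  line, or a homozygous genotype, still contributes 1.

## Catalog depletion and persistence

Survivors are depleted first against a known-SNP catalog and then against
a known-somatic catalog (the latter because normal tissue adjacent to a
tumor can harbor genuine somatic events that must not be banked as
germline). Membership of the final set is order-insensitive; the fixed
SNP-then-somatic order only determines which stage gets credited with a
removal in the funnel report. Matching is allele-aware on the full key:
position- or rsID-level matching would wrongly deplete novel alleles at
known positions. Catalogs are accepted as VCF or 4-column tab-delimited
text.

The database is persisted as a single SQLite file with a `variants` table
(chrom, pos, ref, alt, recurrence, alt_allele_count, max_alt_depth) and a
`meta` table recording cohort size, thresholds and catalog labels, so a
build is auditable from its artifact alone.

## Cohort allele frequencies

For a database entry with total alt allele count $c$ in a cohort of $N$
samples, the alt frequency is $f = c / 2N$ — the standard diploid cohort
convention in which samples without a call at the site count as homozygous
reference — and the minor allele frequency is $\min(f, 1-f) \in [0, 0.5]$.
Sex-chromosome ploidy is deliberately not special-cased (a flagged
limitation: X/Y frequencies are computed under the same $2N$ denominator).
The default spectrum bins, `c(0, .01, .02, .03, .04, .05, .10, .25, .5)`
with half-open `[lo, hi)` intervals (last bin closed), emphasise the rare
end where a population-specific panel concentrates; they are configurable.

Reporting conventions: percentages to 1 decimal, ratios to 2 decimals,
headline depletion percentages to the nearest integer where reports
conventionally print integers. Every reported percentage sits next to the
numerator and denominator it came from, and zero denominators yield `NA`
("not applicable"), never 0.

## The synthetic cohort generator

`generate_cohort()` exists so that every stage is testable against planted
truth without any external data. It draws unique variant sites on
synthetic contigs 1–22, X, Y (exercising chromosome normalization and the
novelty summary), assigns each site a carrier count, per-carrier
genotypes, and Poisson alt depths, optionally omits `AD` for a fraction of
carriers, includes a small indel fraction (exercising exact-string
matching), and plants disjoint site subsets into the two catalogs. Its
defaults emulate the study conditions the package models: 62 normal
exomes at a median depth near 90× (heterozygous alt depths with Poisson
mean 45), with 92% of detected sites already in the SNP catalog and about
1.8% in the somatic catalog. The truth table records, per site, the
planted values and the expected filter/build outcome recomputed from the
documented predicate, so an end-to-end build can be checked for exact
membership agreement.

What the generator does **not** emulate: read-level error processes,
mapping artifacts, linkage between nearby sites, mutational signatures,
multi-allelic normal sites, or realistic allele-frequency spectra. Passing
tests therefore demonstrate that the bookkeeping — merging, filtering,
depletion, subtraction, persistence — is exact, not that the default
thresholds are optimal for any particular real cohort.

`generate_tumor()` plants an exact overlap with the built database, so the
subtractor's removal count has a known expected value.

## Validation suite problem sizes

The shipped tests check the filter predicate against a brute-force oracle
over the full (depth 0–10 ∪ unknown) × (recurrence 1–10) grid including
the boundary values 4 and 5; subtraction conservation, idempotence,
monotonicity and brute-force equivalence on instances of a few hundred
records; byte-level VCF round-trips (with `vcfR` as an independent parsing
oracle on a 1,000-record file); SQLite round-trips; and exact
planted-truth recovery of database membership across 100 random cohorts of
10 samples × 500 sites spanning shallow and deep depth regimes. These
sizes keep the default suite around a minute while covering every decision
boundary; the generator scales to arbitrarily larger cohorts.

## Known limitations

* No left-alignment of indels (see above); inputs should be normalized
  consistently upstream if callers differ in representation.
* Genotypes are interpreted up to diploid; gVCF blocks, structural
  variants and phasing are out of scope.
* The recurrence rule treats the cohort as unrelated individuals; related
  samples would inflate recurrence and over-bank family-private variants.
* A panel built from tumor-adjacent "normal" tissue can bank genuine
  somatic events (field effect) despite the somatic-catalog depletion
  step, and will bank population-novel predisposition alleles as normal
  variation; it is a tool for somatic analyses, not germline
  interpretation.
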
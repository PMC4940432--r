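# ponsub

**Panel-of-normals SNP database construction and tumor VCF subtraction.**

A somatic mutation call is only believable once every germline variant has
been removed from the tumor's variant set. Public SNP catalogs (dbSNP, 1000
Genomes) under-represent many populations, so tumor exomes from those
populations retain population-specific germline polymorphisms that
masquerade as somatic events even after catalog depletion. `ponsub` is for
cancer-genomics analysts facing that gap: it builds a **panel of normals
(PoN)** — a reusable germline variant database — from VCFs of unrelated
normal samples, and subtracts it from tumor VCFs as an additional depletion
step on top of the public catalogs.

## The method

Every variant allele is identified by the allele-aware key

```
(chromosome, position, reference allele, alternate allele)
```

in a fixed genome build (multi-allelic records are split into biallelic
keys; `chr` prefixes are stripped and `M` is mapped to `MT` so callers
interoperate). The database is built in four stages:

1. **Merge** all normal-sample VCFs and compute, per key, the recurrence
   *r* (number of distinct carrier samples), the cohort-maximum
   alt-supporting read depth *d* (from the `AD` FORMAT field), and the
   total alt allele count *c* (het = 1, hom = 2).
2. **Quality filter**: keep a variant iff
   `d ≥ 5` **or** `r ≥ 4` —
   one confidently covered carrier suffices, and shallow variants are
   rescued when they recur in at least four normals.
3. **Deplete** the survivors against a known-SNP catalog (dbSNP-like), then
   against a known-somatic catalog (COSMIC-like, to avoid banking true
   somatic events that leaked into "normal" tissue), matching on the full
   key — never on position alone.
4. **Persist** the remaining variants as a single-file SQLite database
   (`variants` + `meta` tables).

Subtraction then removes every tumor record whose key is in the database;
multi-allelic tumor records lose only the matching alleles. Companion
summaries report the construction funnel, per-cohort reduction percentages,
the cohort minor-allele-frequency spectrum
(`MAF = min(f, 1 − f)` with `f = c / 2N` over `N` diploid samples),
per-chromosome novelty against a reference catalog, and annotation
class/region tallies including the NS/S ratio.

## Worked example

Two toy normal VCFs and a three-entry SNP catalog ship with the package:

```r
library(ponsub)
normals <- list(
  system.file("extdata", "toy_normal1.vcf", package = "ponsub"),
  system.file("extdata", "toy_normal2.vcf", package = "ponsub"))
snp <- read_catalog(system.file("extdata", "toy_snp_catalog.tsv",
                                package = "ponsub"),
                    name = "SNP-catalog", version_label = "toy")
db <- build_database(normals, snp_catalog = snp)
print(db$funnel)
#> Panel-of-normals build funnel
#>   raw observations merged : 11
#>   unique variant keys     : 7
#>   pass quality filter     : 5
#>   removed by SNP catalog  : 2
#>   after SNP catalog       : 3
#>   removed by somatic cat. : 0
#>   final database size     : 3
```

The two normals contribute 11 allele observations over 7 unique keys; 5
keys have an alt depth of at least 5 somewhere in the cohort (none recurs
in ≥ 4 of these 2 samples), 2 of those are already in the SNP catalog, and
the remaining 3 form the database:

```r
db$entries[, c("chrom", "pos", "ref", "alt", "recurrence", "max_alt_depth")]
#> # A tibble: 3 × 6
#>   chrom     pos ref   alt   recurrence max_alt_depth
#>   <chr>   <int> <chr> <chr>      <int>         <int>
#> 1 1      115252 G     A              2            33
#> 2 5     1295228 G     T              1             6
#> 3 MT         73 A     G              1            48
```

Subtracting a VCF against the database removes exactly the records whose
keys it contains — here 2 of the first normal's 5 alleles:

```r
subtract(normals[[1]], db)
#> <subtraction_result> 5 input allele(s): 2 removed (40.0%), 3 retained
```

The same steps are available from a shell via the installed script
(`system.file("exec", "ponsub", package = "ponsub")`) with subcommands
`build`, `subtract`, `summarize` and `simulate`.

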
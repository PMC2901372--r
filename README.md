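# snpscreen

Post-GWAS SNP annotation and candidate-marker screening for any species with
a SNP catalogue — livestock included.

A genome-wide association study ends with a set of statistically significant
SNPs, each of which may be the causal variant, a variant in linkage
disequilibrium (LD) with an untyped causal variant, an association with no
known biological backing, or a false positive. `snpscreen` helps tell these
apart. It builds a species-specific single-file SQLite store integrating
SNPs, genes, GO terms, KEGG pathways, protein links, QTL regions, trait
records and ortholog groups from flat-file sources; scores every SNP for
likely functional significance; and screens and ranks a GWAS-significant SNP
list as candidate DNA markers, using physical distance to high-scoring SNPs
as an LD proxy.

## The score

Each SNP's score is the sum of two components:

```
total = class_score(function_class) + Σ_{c ∈ categories} 1[evidence c found]
```

* a **function-class component** from a ranked table over the dbSNP-style
  function classification (missense = frameshift = stop-gain = 20,
  splice-site = 15, synonymous = 10, UTR = 8, intron = 5, near-gene = 3,
  intergenic = 0) — the maximum, 20, goes to classes that alter the encoded
  amino acid; and
* **one point per evidence category** found, capped at one per category:
  located in a QTL region (positional), plus gene-mediated protein, GO,
  KEGG, OMIA and homolog links.

The maximum is 26 = 20 + 1 + 1 + 1 + 1 + 1 + 1; SNPs scoring ≥ 20 are
treated as highly likely to have significant functional roles. The screen
then runs four progressively narrower selections over the significant list
(all; score > 7; database SNPs with score > 11 within 10,000 bp; SNPs with
score > 24 on genes within 10,000 bp) and ranks candidates by descending own
score, then descending best nearby score, then proximity.

## Worked example

Generate a toy species at the screening-study scale (165 significant SNPs, 8
of them planted next to a maximum-score SNP), build and score the store, and
screen:

```r
library(snpscreen)

dir <- tempfile("toy")
fx  <- generate_fixture(default_paper_fixture(seed = 42), dir)
db  <- file.path(dir, "toyspecies.db")
build_store(fx$config, db)

st <- open_store(db, "toyspecies")
st
#> <snp_store> species: toyspecies  file: .../toyspecies.db
#>   snp      800
#>   gene     60
#>   protein  42
#>   go       89
#>   kegg     40
#>   omia     28
#>   qtl      17
#>   homolog  64

runs <- screen_four_runs(fx$significant, st)
screen_summary(runs)
#>   run                 mode snps_meeting_criteria wgas_snps score_ge20 genes proteins pathways go_terms homologs
#> 1   1      all_significant                   165       165          0     0        0        0        0        0
#> 2   2 significant_by_score                     0         0          0     0        0        0        0        0
#> 3   3    nearby_high_score                    42         0          8    30       24       15       40       36
#> 4   4     nearby_gene_snps                     8         0          8     8        8        8       11       16
```

Run 1 annotates all 165 inputs (here all intergenic, so no gene-mediated
annotation); run 3 finds 42 database SNPs scoring > 11 within 10 kb of an
input, 8 of which reach the score-20 rule — the planted companions; run 4
narrows to the 8 SNPs scoring > 24 on genes within 10 kb. Ranking recovers
the planted markers:

```r
ranked <- rank_candidates(fx$significant, st, results = runs)
head(ranked[, 1:6], 3)
#>   rank    snp_id own_score best_nearby_score nearby_snp nearby_distance
#> 1    1 rs1000523         1                26  rs1000522            2928
#> 2    2 rs1000254         1                26  rs1000253            3195
#> 3    3 rs1000798         1                26  rs1000797            3581

setequal(ranked$snp_id[1:8], fx$planted_markers)
#> [1] TRUE

total_score("rs1000522", st)
#>      snp_id class_component in_qtl has_protein has_go has_kegg has_omia has_homolog total
#>   rs1000522              20   TRUE        TRUE   TRUE     TRUE     TRUE        TRUE    26
```

Each top-ranked significant SNP sits a few kb from a maximally supported
(score-26) SNP: the pattern the screen exists to find, since such a pair is
likely in LD. Queries are available piecemeal too — `get_snps()`,
`get_annotations()` (gene/protein/GO/KEGG/QTL-trait/OMIA/homolog),
`get_snp_id()`, `genes_by_dist()`, `nearest_genes()`, `high_score_snp()` —
and the whole surface is scriptable through
`inst/cli/snpscreen.R` (`fixture`, `build`, `score`, `validate`, `query`,
`screen`, `fetch`, `registry` subcommands).

Real sources are wired in through a per-species INI file listing one section
per resource (location, optional compression and dialect); see
`?parse_config` and `?build_store`.

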
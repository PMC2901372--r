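---
title: "SNP annotation stores and post-GWAS candidate screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SNP annotation stores and post-GWAS candidate screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

A genome-wide association study (GWAS) ends with a list of SNPs statistically
associated with a trait. Association is not causation: a significant SNP may
be the causal variant, may merely be in linkage disequilibrium (LD) with an
untyped causal variant, may have an association with no known biological
backing, or may be a false positive. Before investing in functional
experiments or marker-assisted selection, a researcher wants to know which
significant SNPs have functional evidence behind them — directly, or through
a nearby SNP they are likely to be in LD with.

The information needed to make that judgement is scattered across resources:
a SNP catalogue with function classes, a gene catalogue, GO annotations,
pathway maps, protein links, QTL regions, trait records and ortholog groups.
`snpscreen` integrates these per species into a single-file relational store,
scores every SNP for likely functional significance, and runs a screening
workflow that ranks GWAS-significant SNPs as candidate DNA markers. The
approach targets species — livestock in particular — for which LD maps are
incomplete and human-centric annotation services do not apply.

## The store

Each species gets one SQLite file with documented, stable tables:
`snp(snp_id, chrom, pos, alleles, function_class, gene_id, score)`,
`gene(gene_id, symbol, chrom, start, end, strand)`, one table per evidence
category (`protein`, `go`, `kegg`, `omia`, `qtl`, `homolog`), and a `meta`
table carrying a schema version. Everything is linked through `snp_id` or
`gene_id`, so the file can equally be queried with raw SQL. Coordinates are
1-based and inclusive at both ends throughout (the dbSNP/GFF convention);
all distance arithmetic follows it. A version mismatch on open is an error,
never a silent migration, because silent schema drift under an analysis is
worse than a forced rebuild. A missing gene link is an explicit NULL, and the
store invariant is that a SNP has no gene link exactly when its function
class is intergenic.

The build pipeline (`build_store()`) is configuration-driven: an INI file
names one section per source with a location (path or URL). Each source runs
download → decompress (`gz`, `zip`, `tar`, `tgz`, inferred from the suffix) →
convert (one parser per source dialect: a tab SNP table, a tab gene table,
GAF 2.x for GO, two-column gene→pathway and gene→protein maps, GFF3 with the
trait in the `Name` attribute for QTL, a three-column trait table, a
three-column ortholog-group table) → import. Imports are transactional per
source with delete-and-replace refresh semantics: a failed source leaves the
store as it was, and re-running a build can never accumulate stale rows —
which is the only refresh semantics that keeps a periodically re-run build
idempotent. Malformed lines are skipped and counted; a file where more than
half the lines fail is treated as a wrong-dialect error rather than a partial
import. Conflicting records within a source (for example two intervals for
one gene ID) violate a primary-key constraint and abort that source's
transaction; we prefer a loud failure at import over a silent "last one
wins".

The parsers are registered in a plain list keyed by dialect name. Real
resources drift in format; the registry is the seam where a real-dialect
parser plugs in without touching the pipeline.

## The score

Every SNP's score is the sum of two components.

The first is a function-class component reflecting the likelihood that the
variant alters the encoded amino-acid sequence, using the dbSNP-style
function classification. The default table is

| class | points | | class | points |
|---|---|---|---|---|
| missense | 20 | | utr | 8 |
| frameshift | 20 | | intron | 5 |
| stop_gain | 20 | | near_gene | 3 |
| splice_site | 15 | | intergenic | 0 |
| synonymous | 10 | | | |

The three amino-acid-altering classes carry the maximum, 20. The non-maximal
values are a ranked design choice of this package: they respect the ordering
(splicing disruption above silent coding change, coding above UTR, UTR above
intron, intron above flanking, flanking above intergenic) and are consistent
with the screening thresholds discussed below, but any monotone table with
the same maximum is defensible — which is why `read_score_table()` accepts a
user-supplied table, subject to the constraint that the amino-acid-altering
classes keep the maximum.

The second component adds one point per evidence category found, capped at
one point per category no matter how many records it holds: located in a QTL
region, protein information, GO terms, KEGG pathways, OMIA trait records,
homologous genes. A maximally supported amino-acid-altering SNP therefore
scores 26 = 20 + 1 + 1 + 1 + 1 + 1 + 1, and SNPs scoring 20 or more are
treated as highly likely to have significant functional roles — under the
default table that is reachable only by an amino-acid-altering class, or by
a splice-site SNP with at least five of the six categories.

One categorisation choice was genuinely open: whether "located in a QTL
region" should be tested against the SNP's own position or its linked gene's
interval. We test the SNP's position, because intergenic SNPs can fall inside
QTL regions and would otherwise be structurally unable to earn the point.
The other five categories are gene-mediated and are all false for SNPs with
no gene link.

## Queries

The query layer accepts vectors of rs accessions or gene IDs (`get_snps()`,
`get_annotations()`), locations (`get_snp_id()`, and location targets in the
proximity searches), and provides three spatial searches: genes within a
distance (`genes_by_dist()`), k nearest genes (`nearest_genes()`), and the
highest-scoring SNP within a window (`high_score_snp()`). Distance to a gene
is the gap to its nearest boundary, zero inside — the standard proximity
semantic. Cross-chromosome results are never returned, since base-pair
distance across chromosomes is undefined. Ties are deterministic everywhere:
by distance, then ascending gene ID or rs number. `high_score_snp()` excludes
the target SNP itself (a high-scoring significant SNP would otherwise always
be its own best neighbour) and applies its score threshold strictly (`>`),
matching the screening criteria's "greater than" phrasing; unknown input IDs
go to a `not_found` attribute instead of an error so batch screens survive
partially annotated inputs.

## The screen and the ranking

`screen_four_runs()` runs four progressively narrower selections over a
significant-SNP list: (1) all of them; (2) those scoring > 7; (3) database
SNPs, inputs excluded, scoring > 11 within 10,000 bp of any input —
SNP-to-SNP distance, per the phrasing of that criterion; (4) genes within
10,000 bp of any input (edge-gap distance), then SNPs *located on* those
genes (position inside the interval — a near-gene class SNP does not
qualify) scoring > 24. The thresholds and the radius are user-settable; LD
knowledge for the study species should govern the radius. Each run's result
is summarised as the count of selected SNPs, how many are GWAS inputs, how
many reach the score-20 rule, and the distinct annotation entities reachable
from the selection (genes, proteins, pathways, GO terms, homologous genes),
deduplicated by accession.

`rank_candidates()` orders the significant list by the lexicographic key:
descending own score, then descending best score of any other database SNP
within the radius, then ascending distance to that SNP, then ascending rs
number. This is a deterministic codification of the premise that a reliable
marker is either itself likely functional or physically close — hence likely
in LD with — a likely-functional SNP. The key is this package's own design
(ranking by researcher synthesis does not reduce to a formula) and is
pluggable via `key_fun`. Physical proximity is only a proxy for LD: two
close SNPs can sit on different LD blocks, so the ranking is a screen, not
an inference.

## The synthetic fixture

`generate_fixture()` writes a complete toy-species source set — all eight
dialect files, the INI configuration, the significant-SNP list — plus a truth
table holding every SNP's expected score breakdown, computed by direct
bookkeeping over the generated annotations, independently of the store
scoring path. Everything is a pure function of the seed, so the same seed
reproduces byte-identical files.

The generative model is deliberately the simplest structure that exercises
every code path: uniform non-overlapping genes on a few chromosomes; SNPs
placed uniformly, with function class assigned by containment (a mixture
over genic classes inside genes, near-gene/intergenic outside); per-gene
Bernoulli evidence per category; QTL regions covering a configurable
fraction of each chromosome. `default_paper_fixture()` sets the screening
study scale: 165 significant SNPs and 8 planted markers in a 10,000 bp
search context, with three 1 Mb chromosomes, 60 genes and an 800-SNP panel —
sizes chosen so a full build-score-screen cycle runs in about a second while
every selection mode still fires.

Planted markers are significant SNPs placed within 5,000 bp of a companion:
a missense SNP on a fully annotated gene inside a QTL region, scoring the
maximum 26. Planted sites live in reserved chromosome segments, spaced
30,000 bp apart and away from the background region, so no background SNP
can sit within the search radius of a planted anchor. Two further choices
make marker recovery exact by construction at zero noise: the default genic
class mixture excludes classes above 10 points (so no background SNP can
reach the score-20 rule, let alone 26), and every significant SNP is
intergenic — the regime the screen is designed for, in which over 90% of
significant SNPs do not fall on genes, taken here to its clean extreme
because any genic significant SNP would outrank the planted markers on the
own-score key component and make "perfect recovery" depend on accidental
geometry rather than planted truth. `n_decoys` then provides the controlled
degradation: each decoy is the same gene-plus-companion-plus-QTL construct
planted next to a *non-marker* significant SNP, which makes that SNP's key
indistinguishable from a marker's and lets the tests report the recovery
fraction as decoys are added.

What the fixture does not emulate: real LD structure (distance is the only
proxy, by design), allele-frequency spectra, genotypes, clustered gene
density, annotation correlation between categories (real genes with protein
records tend to have GO records too), and real resource formats' drift. A
passing suite therefore shows the machinery is exact on data with known
truth, not that the scores are well calibrated for any real genome.

## Numerical and degenerate-input choices

Score thresholds in the screen are strict (`>`); distances and interval
membership are inclusive. An empty store scores zero SNPs; an empty result
is a zero-row frame with the documented columns, never `NULL`. A screen run
with an unsatisfiable threshold yields a row of zeros. Multi-allelic
position collisions return all rs accessions ordered by rs number.
Validation never errors: every inconsistency — dangling gene link, malformed
accession, out-of-range coordinate, a gene in two homolog groups — is a
report row, so a broken store remains inspectable.

## Problem sizes used in the tests

The oracle-equivalence suite compares every spatial query and screen mode
against exhaustive brute-force scans on twenty 300-SNP/25-gene fixtures;
marker recovery is measured on ten study-scale fixtures (800 SNPs, 60 genes,
165 significant) at zero noise and three more with six decoys. These sizes
give exact, fully enumerable ground truth; the store layer itself is plain
SQLite with indexes on `(chrom, pos)` and scales to real panels
independently of anything tested here.

## Known limitations

All causal variants are assumed to be on genes; regulatory, non-coding
mechanisms earn no evidence points. The class-score table is subjective by
nature and only rank-constrained. Proximity is an LD proxy, not LD. Scores
are ordinal screening aids — a 12 is not "twice as functional" as a 6 — and
the final biological judgement (does this pathway plausibly relate to the
trait?) remains with the researcher.
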
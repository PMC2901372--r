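Package: snpscreen
Title: Species-Specific SNP Annotation Databases and Post-GWAS Candidate Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds species-specific embedded relational (SQLite) databases of
    single nucleotide polymorphisms together with functional annotations drawn
    from flat-file resources (dbSNP-style SNP tables, NCBI-style gene tables,
    GAF gene-ontology annotations, KEGG-style pathway maps, UniProt-style
    protein maps, QTL regions in GFF3, OMIA-style trait records and
    HomoloGene-style ortholog groups) via a configuration-driven
    download-decompress-convert-import pipeline. Every SNP is scored for likely
    functional significance as the sum of a function-class component and
    cumulative evidence increments, and a query layer links SNPs to genes,
    proteins, ontology terms, pathways, QTL traits and orthologs, including
    proximity searches. A four-run screening workflow filters and ranks
    GWAS-significant SNPs as candidate DNA markers, and a deterministic
    synthetic-fixture generator produces complete toy source-file sets with a
    planted truth table so the whole pipeline is testable offline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    DBI,
    RSQLite,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
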
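# Build a small store directly from record data frames (no file ingest),
# used where tests need exact control over every record.
make_store <- function(snps = NULL, genes = NULL, protein = NULL, go = NULL,
                       kegg = NULL, omia = NULL, qtl = NULL, homolog = NULL,
                       species = "toyspecies", path = ":memory:",
                       score = TRUE) {
  st <- open_store(path, species, create = TRUE)
  put <- function(tab, df) if (!is.null(df) && nrow(df) > 0L)
    import_records(st, tab, df)
  put("gene", genes)
  put("snp", snps)
  put("protein", protein)
  put("go", go)
  put("kegg", kegg)
  put("omia", omia)
  put("qtl", qtl)
  put("homolog", homolog)
  if (score) score_all(st)
  st
}

snp_df <- function(snp_id, chrom, pos, function_class, gene_id = NA_integer_,
                   alleles = "A/G", score = 0L) {
  data.frame(snp_id = snp_id, chrom = chrom, pos = as.integer(pos),
             alleles = alleles, function_class = function_class,
             gene_id = as.integer(gene_id), score = as.integer(score),
             stringsAsFactors = FALSE)
}

gene_df <- function(gene_id, chrom, start, end, symbol = NULL, strand = "+") {
  data.frame(gene_id = as.integer(gene_id),
             symbol = if (is.null(symbol)) paste0("G", gene_id) else symbol,
             chrom = chrom, start = as.integer(start), end = as.integer(end),
             strand = strand, stringsAsFactors = FALSE)
}

# one gene fully annotated across all five gene-mediated categories
full_annotation <- function(gene_id) {
  list(protein = data.frame(gene_id = gene_id, accession = sprintf("Q%05d", gene_id)),
       go = data.frame(gene_id = gene_id, accession = "GO:0001875", term = "t"),
       kegg = data.frame(gene_id = gene_id, accession = "path:toy04620", pathway = "p"),
       omia = data.frame(gene_id = gene_id, accession = "OMIA:000123", phenotype = "ph"),
       homolog = data.frame(group_id = paste0("HG", gene_id),
                            species = c("toyspecies", "homo_sapiens"),
                            gene_id = c(gene_id, 1000000L + gene_id)))
}

# generate a fixture and ingest it into a store file; returns list(fx, store)
fixture_store <- function(p, dir = tempfile("fx")) {
  fx <- generate_fixture(p, dir)
  db <- file.path(dir, "toy.db")
  build_store(fx$config, db, workdir = file.path(dir, "work"))
  list(fx = fx, store = open_store(db, "toyspecies"), path = db)
}

small_params <- function(seed, ...) {
  fixture_params(seed = seed, n_chrom = 2L, chrom_len = 300000L, n_genes = 25L,
                 n_snps = 300L, n_qtl = 4L, n_significant = 15L,
                 n_planted_markers = 3L, ...)
}
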
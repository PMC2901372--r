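query_store <- function() {
  ann <- full_annotation(1L)
  make_store(
    snps = rbind(
      snp_df("rs10", "chr1", 120L, "missense", 1L),
      snp_df("rs11", "chr1", 150L, "intron", 1L),
      snp_df("rs12", "chr1", 199L, "utr", 1L),
      snp_df("rs13", "chr1", 5000L, "intergenic", NA),
      snp_df("rs20", "chr1", 700L, "synonymous", 2L),
      snp_df("rs30", "chr2", 300L, "intergenic", NA)),
    genes = rbind(gene_df(1L, "chr1", 100L, 200L),
                  gene_df(2L, "chr1", 650L, 800L),
                  gene_df(5L, "chr2", 1000L, 1200L)),
    protein = ann$protein, go = ann$go, kegg = ann$kegg, omia = ann$omia,
    homolog = rbind(ann$homolog,
                    data.frame(group_id = "HG1", species = "mus_musculus",
                               gene_id = 2000001L)),
    qtl = data.frame(qtl_id = "Q1", chrom = "chr1", start = 1L, end = 6000L,
                     trait = "growth"))
}

test_that("SNP-mode lookup preserves input order and reports unknown ids", {
  st <- query_store()
  on.exit(close_store(st))
  res <- get_snps(c("rs20", "rs9999999", "rs10"), "snp", st)
  expect_equal(res$snp_id, c("rs20", "rs10"))
  expect_equal(attr(res, "not_found"), "rs9999999")
  expect_error(get_snps(character(), "snp", st), "empty")
  expect_error(get_snps("SNP_1", "snp", st), "malformed")
})

test_that("gene-mode lookup returns exactly the SNPs inside each interval", {
  st <- query_store()
  on.exit(close_store(st))
  res <- get_snps("1", "gene", st)
  expect_equal(res$snp_id, c("rs10", "rs11", "rs12"))  # 199 inside, 5000 out
  res2 <- get_snps(c("5", "1"), "gene", st)
  expect_equal(unique(res2$query_id), "1")  # the chr2 gene holds no SNPs
  expect_equal(res2$snp_id, c("rs10", "rs11", "rs12"))
})

test_that("locations map back to rs ids, with multi-allelic collisions ordered by rs number", {
  st <- query_store()
  on.exit(close_store(st))
  DBI::dbExecute(st$con,
    "INSERT INTO snp VALUES ('rs2', 'chr1', 120, 'C/T', 'missense', 1, 0)")
  res <- get_snp_id(data.frame(chrom = c("chr1", "chr1"), pos = c(120L, 121L)), st)
  expect_equal(res$snp_id, c("rs2", "rs10", NA))
  expect_equal(res$pos, c(120L, 120L, 121L))
})

test_that("gene-mode results agree with location lookups of the same SNPs", {
  st <- query_store()
  on.exit(close_store(st))
  res <- get_snps("1", "gene", st)
  back <- get_snp_id(res[, c("chrom", "pos")], st)
  expect_setequal(back$snp_id, res$snp_id)
})

test_that("annotation retrieval resolves SNPs through their gene link", {
  st <- query_store()
  on.exit(close_store(st))
  go <- get_annotations("rs10", "snp", "go", st)
  expect_equal(go$accession, "GO:0001875")
  # an intergenic SNP has no gene-mediated annotations
  expect_equal(nrow(get_annotations("rs13", "snp", "go", st)), 0L)
  # but can still fall inside a QTL region
  tr <- get_annotations("rs13", "snp", "qtl_trait", st)
  expect_equal(tr$trait, "growth")
  expect_equal(nrow(get_annotations("rs30", "snp", "qtl_trait", st)), 0L)
  # gene ids work directly, and the category decides the columns
  pr <- get_annotations("1", "gene", "protein", st)
  expect_equal(pr$accession, "Q00001")
})

test_that("homolog lookup returns group members, optionally filtered by species", {
  st <- query_store()
  on.exit(close_store(st))
  all_members <- get_annotations("rs10", "snp", "homolog", st)
  expect_setequal(all_members$member_species,
                  c("toyspecies", "homo_sapiens", "mus_musculus"))
  human <- get_annotations("rs10", "snp", "homolog", st, species = "homo_sapiens")
  expect_equal(human$member_species, "homo_sapiens")
  expect_equal(human$member_gene_id, 1000001L)
})

test_that("distance to a gene is zero inside and edge-gap outside, bounded inclusively", {
  st <- query_store()
  on.exit(close_store(st))
  inside <- genes_by_dist("rs11", 0L, st)
  expect_equal(inside$gene_id, 1L)
  expect_equal(inside$distance, 0L)

  # rs13 at 5000: gene 2 ends at 800 -> gap 4200; gene 1 ends at 200 -> 4800
  res <- genes_by_dist("rs13", 4200L, st)
  expect_equal(res$gene_id, 2L)
  expect_equal(res$distance, 4200L)
  expect_equal(genes_by_dist("rs13", 4199L, st)$gene_id, integer(0))
  expect_error(genes_by_dist("rs13", -1L, st))
})

test_that("nearest-gene search honours k, ties and sparse chromosomes", {
  st <- query_store()
  on.exit(close_store(st))
  res <- nearest_genes("rs13", k = 1L, st)
  expect_equal(res$gene_id, 2L)
  res <- nearest_genes("rs13", k = 5L, st)
  expect_equal(res$gene_id, c(2L, 1L))  # only two genes on chr1
  # equidistant genes break ties by ascending gene id
  st2 <- make_store(snps = snp_df("rs1", "chr1", 500L, "intergenic", NA),
                    genes = rbind(gene_df(8L, "chr1", 600L, 700L),
                                  gene_df(3L, "chr1", 300L, 400L)))
  on.exit(close_store(st2), add = TRUE)
  res <- nearest_genes("rs1", k = 2L, st2)
  expect_equal(res$gene_id, c(3L, 8L))
  # location targets work the same way
  res <- nearest_genes(data.frame(chrom = "chr1", pos = 500L), k = 1L, st2)
  expect_equal(res$gene_id, 3L)
})

test_that("highest-scoring nearby SNP excludes the target and breaks ties by distance then rs", {
  st <- make_store(
    snps = rbind(snp_df("rs1", "chr1", 10000L, "intergenic", NA),
                 snp_df("rs5", "chr1", 13000L, "missense", 1L),
                 snp_df("rs6", "chr1", 18000L, "missense", 1L),
                 snp_df("rs7", "chr1", 7000L, "missense", 1L),
                 snp_df("rs8", "chr1", 30000L, "missense", 1L)),
    genes = gene_df(1L, "chr1", 1L, 50000L))
  on.exit(close_store(st))
  # rs5/rs6/rs7 share the top score; rs5 at 3000 bp and rs7 at 3000 bp tie on
  # distance, rs5 wins on rs number
  res <- high_score_snp("rs1", max_dist = 10000L, store = st)
  expect_equal(res$snp_id, "rs5")
  expect_equal(res$distance, 3000L)
  # a strict threshold above every score yields no answer
  res <- high_score_snp("rs1", min_score = 26L, max_dist = 10000L, store = st)
  expect_true(is.na(res$snp_id))
  # a zero window excludes the target itself, so nothing qualifies
  res <- high_score_snp("rs1", max_dist = 0L, store = st)
  expect_true(is.na(res$snp_id))
})

test_that("spatial queries agree with exhaustive scans over random fixtures", {
  for (seed in c(21, 22, 23)) {
    fs <- fixture_store(small_params(seed))
    tabs <- store_tables_df(fs$store)
    sample_ids <- tabs$snp$snp_id[seq(1, nrow(tabs$snp), by = 23)]
    for (id in sample_ids) {
      got <- genes_by_dist(id, 10000L, fs$store)
      exp <- bf_genes_by_dist(id, 10000L, tabs)
      if (is.null(exp)) expect_equal(nrow(got), 0L) else {
        expect_equal(got$gene_id, exp$gene_id, info = paste(seed, id))
        expect_equal(got$distance, exp$distance)
      }
      gotk <- nearest_genes(id, k = 3L, fs$store)
      expk <- bf_nearest_genes(id, 3L, tabs)
      expect_equal(gotk$gene_id, expk$gene_id, info = paste(seed, id))
      goth <- high_score_snp(id, min_score = 11L, max_dist = 10000L, store = fs$store)
      exph <- bf_high_score_snp(id, 11L, 10000L, tabs)
      expect_equal(goth$snp_id, exph, info = paste(seed, id))
    }
    close_store(fs$store)
  }
})
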
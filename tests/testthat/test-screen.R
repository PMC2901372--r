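test_that("run 1 keeps every significant SNP; run 2 applies the strict score filter", {
  fs <- fixture_store(small_params(31))
  on.exit(close_store(fs$store))
  sig <- fs$fx$significant
  r1 <- screen(sig, screen_criteria("all_significant"), fs$store)
  expect_equal(r1$input_snps, length(sig))
  expect_setequal(r1$snps_selected, sig)
  r2 <- screen(sig, screen_criteria("significant_by_score", score_gt = 0L), fs$store)
  truth <- fs$fx$snps
  expect_setequal(r2$snps_selected,
                  truth$snp_id[truth$snp_id %in% sig & truth$total > 0L])
  expect_true(all(r2$snps_selected %in% r1$snps_selected))
  expect_error(screen(character(), screen_criteria("all_significant"), fs$store),
               "empty")
})

test_that("a score filter on planted genic inputs selects exactly the planted count", {
  # three genic significant SNPs score above 7 (synonymous + evidence); the
  # rest cannot reach it
  ann <- full_annotation(1L)
  snps <- rbind(
    snp_df(sprintf("rs%d", 1:3), "chr1", c(110L, 150L, 190L), "synonymous", 1L),
    snp_df(sprintf("rs%d", 4:9), "chr1", 10000L + 1:6, "intergenic", NA))
  st <- make_store(snps = snps, genes = gene_df(1L, "chr1", 100L, 200L),
                   go = ann$go)
  on.exit(close_store(st))
  r2 <- screen(sprintf("rs%d", 1:9), screen_criteria("significant_by_score"), st)
  expect_equal(sort(r2$snps_selected), sprintf("rs%d", 1:3))
  expect_equal(r2$annotation_counts[["genes"]], 1L)
  expect_equal(r2$annotation_counts[["go_terms"]], 1L)
})

test_that("screen modes 2-4 match exhaustive brute-force selection", {
  for (seed in c(41, 42)) {
    fs <- fixture_store(small_params(seed))
    tabs <- store_tables_df(fs$store)
    sig <- fs$fx$significant
    cases <- list(list("significant_by_score", 7L, NA),
                  list("nearby_high_score", 11L, 10000L),
                  list("nearby_gene_snps", 11L, 10000L),
                  list("nearby_gene_snps", 24L, 10000L))
    for (cs in cases) {
      crit <- screen_criteria(cs[[1]], score_gt = cs[[2]],
                              dist = if (is.na(cs[[3]])) NULL else cs[[3]])
      got <- screen(sig, crit, fs$store)
      expect_equal(sort(got$snps_selected),
                   bf_screen_select(sig, cs[[1]], cs[[2]], cs[[3]], tabs),
                   info = paste(seed, cs[[1]], cs[[2]]))
    }
    close_store(fs$store)
  }
})

test_that("annotation tallies count distinct entities by accession", {
  fs <- fixture_store(small_params(43))
  on.exit(close_store(fs$store))
  sig <- fs$fx$significant
  res <- screen(sig, screen_criteria("nearby_high_score"), fs$store)
  sel <- res$snps_selected
  truth <- fs$fx$snps
  genes <- unique(truth$gene_id[truth$snp_id %in% sel & !is.na(truth$gene_id)])
  expect_equal(res$annotation_counts[["genes"]], length(genes))
  ann <- fs$fx$annotations
  recount <- function(df) length(unique(df$accession[df$gene_id %in% genes]))
  expect_equal(res$annotation_counts[["proteins"]], recount(ann$protein))
  expect_equal(res$annotation_counts[["pathways"]], recount(ann$kegg))
  expect_equal(res$annotation_counts[["go_terms"]], recount(ann$go))
  hom <- ann$homolog[ann$homolog$gene_id %in% genes, , drop = FALSE]
  groups <- unique(hom$group_id)
  members <- unique(ann$homolog$gene_id[ann$homolog$group_id %in% groups])
  expect_equal(res$annotation_counts[["homologs"]], length(members))
})

test_that("the summary table has one row per run and zero rows count as zeros", {
  fs <- fixture_store(small_params(44))
  on.exit(close_store(fs$store))
  sig <- fs$fx$significant
  runs <- screen_four_runs(sig, fs$store)
  tab <- screen_summary(runs)
  expect_equal(nrow(tab), 4L)
  expect_equal(names(tab),
               c("run", "mode", "snps_meeting_criteria", "wgas_snps",
                 "score_ge20", "genes", "proteins", "pathways", "go_terms",
                 "homologs"))
  expect_equal(tab$snps_meeting_criteria[1], length(sig))
  # an unsatisfiable threshold gives a row of zeros
  r0 <- screen(sig, screen_criteria("significant_by_score", score_gt = 26L), fs$store)
  row <- screen_summary(list(r0))
  expect_true(all(unlist(row[, 3:10]) == 0L))
})

test_that("selections shrink with the score threshold and grow with the radius", {
  fs <- fixture_store(small_params(45))
  on.exit(close_store(fs$store))
  sig <- fs$fx$significant
  prev <- Inf
  for (gt in c(0L, 7L, 11L, 24L)) {
    n <- length(screen(sig, screen_criteria("nearby_high_score", score_gt = gt,
                                            dist = 10000L), fs$store)$snps_selected)
    expect_lte(n, prev)
    prev <- n
  }
  prev <- -1L
  for (d in c(0L, 1000L, 10000L, 50000L)) {
    for (mode in c("nearby_high_score", "nearby_gene_snps")) {
      n <- length(screen(sig, screen_criteria(mode, score_gt = 11L, dist = d),
                         fs$store)$snps_selected)
      if (mode == "nearby_high_score") {
        expect_gte(n, prev)
        prev <- n
      }
    }
  }
})

test_that("ranking is by own score, then best neighbour, then proximity, then rs number", {
  ann <- full_annotation(1L)
  st <- make_store(
    snps = rbind(
      snp_df("rs1", "chr1", 150L, "missense", 1L),      # own 26 with full support
      snp_df("rs2", "chr1", 60000L, "intergenic", NA),  # neighbour scores 25
      snp_df("rs3", "chr1", 80000L, "intergenic", NA),  # neighbour scores 12
      snp_df("rs4", "chr1", 63000L, "missense", 2L),
      snp_df("rs5", "chr1", 81000L, "synonymous", 3L),
      snp_df("rs9", "chr2", 500L, "intergenic", NA)),   # nothing nearby
    genes = rbind(gene_df(1L, "chr1", 100L, 200L),
                  gene_df(2L, "chr1", 62000L, 64000L),
                  gene_df(3L, "chr1", 80500L, 82000L)),
    protein = ann$protein, go = rbind(ann$go,
      data.frame(gene_id = 2L, accession = "GO:0000002", term = "t"),
      data.frame(gene_id = 3L, accession = "GO:0000003", term = "t")),
    kegg = rbind(ann$kegg, data.frame(gene_id = 2L, accession = "path:toy1",
                                      pathway = "p")),
    omia = ann$omia, homolog = ann$homolog,
    qtl = data.frame(qtl_id = c("Q1", "Q2"), chrom = "chr1",
                     start = c(100L, 61000L), end = c(200L, 65000L),
                     trait = "t"))
  on.exit(close_store(st))
  # rs4: 20+go+kegg+qtl+... gene 2 has go+kegg, in QTL -> 23; rs5: 10+go = 11
  ranked <- rank_candidates(c("rs3", "rs9", "rs2", "rs1"), st, dist = 10000L)
  expect_equal(ranked$snp_id, c("rs1", "rs2", "rs3", "rs9"))
  expect_equal(ranked$rank, 1:4)
  expect_equal(ranked$own_score[1], 26L)
  expect_equal(ranked$nearby_snp[2], "rs4")
  expect_match(ranked$rationale[1], "own score >= 20")
  expect_match(ranked$rationale[4], "no supporting evidence")
})

test_that("equal own scores are separated by the better nearby SNP", {
  st <- make_store(
    snps = rbind(
      snp_df("rs1", "chr1", 10000L, "intergenic", NA),
      snp_df("rs2", "chr1", 50000L, "intergenic", NA),
      snp_df("rs3", "chr1", 12000L, "missense", 1L),   # 20 + protein = 21
      snp_df("rs4", "chr1", 52000L, "synonymous", 2L)),# 10
    genes = rbind(gene_df(1L, "chr1", 11000L, 13000L),
                  gene_df(2L, "chr1", 51000L, 53000L)),
    protein = data.frame(gene_id = 1L, accession = "Q00001"))
  on.exit(close_store(st))
  ranked <- rank_candidates(c("rs2", "rs1"), st, dist = 10000L)
  expect_equal(ranked$snp_id, c("rs1", "rs2"))
  expect_equal(ranked$best_nearby_score, c(21L, 10L))
})

test_that("screen results over a different input list are rejected for ranking", {
  fs <- fixture_store(small_params(46))
  on.exit(close_store(fs$store))
  sig <- fs$fx$significant
  runs <- screen_four_runs(sig, fs$store)
  expect_error(rank_candidates(sig[-1], fs$store, results = runs),
               "different input list")
})

test_that("all planted markers occupy the top ranks of the study-scale screen", {
  fs <- fixture_store(default_paper_fixture(seed = 101))
  on.exit(close_store(fs$store))
  sig <- fs$fx$significant
  runs <- screen_four_runs(sig, fs$store)
  ranked <- rank_candidates(sig, fs$store, results = runs)
  expect_setequal(ranked$snp_id[1:8], fs$fx$planted_markers)
  expect_true(all(grepl("run3", ranked$rationale[1:8])))
})
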
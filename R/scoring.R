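#' Evidence flags for a SNP
#'
#' Six boolean evidence categories back a SNP's cumulative score component.
#' `in_qtl` is positional: true iff the SNP's base position falls inside at
#' least one QTL region on its chromosome (1-based, inclusive at both ends).
#' The five gene-mediated flags (`has_protein`, `has_go`, `has_kegg`,
#' `has_omia`, `has_homolog`) are true iff the SNP's linked gene carries at
#' least one annotation of that category; they are all false for SNPs with no
#' gene link. Each category contributes at most one score point no matter how
#' many annotations it holds.
#'
#' @param snp_ids character vector of rs accessions present in the store.
#' @param store an open `snp_store`.
#' @return logical matrix, one row per SNP (rownames = `snp_ids`), columns
#'   `in_qtl`, `has_protein`, `has_go`, `has_kegg`, `has_omia`, `has_homolog`.
#' @export
evidence_flags <- function(snp_ids, store) {
  stopifnot(length(snp_ids) >= 1L)
  con <- store$con
  snp <- DBI::dbGetQuery(con,
    "SELECT snp_id, chrom, pos, gene_id FROM snp WHERE snp_id IN (SELECT value FROM json_each(:ids))",
    params = list(ids = jsonlite_ids(snp_ids)))
  missing <- setdiff(snp_ids, snp$snp_id)
  if (length(missing) > 0L) stop("SNP(s) not in store: ", paste(utils::head(missing, 3), collapse = ", "))
  snp <- snp[match(snp_ids, snp$snp_id), , drop = FALSE]

  in_qtl <- DBI::dbGetQuery(con,
    "SELECT s.snp_id FROM snp s JOIN qtl q
       ON q.chrom = s.chrom AND s.pos BETWEEN q.start AND q.end
      WHERE s.snp_id IN (SELECT value FROM json_each(:ids))
      GROUP BY s.snp_id",
    params = list(ids = jsonlite_ids(snp_ids)))$snp_id

  flags <- matrix(FALSE, nrow = length(snp_ids), ncol = 6L,
                  dimnames = list(snp_ids,
                    c("in_qtl", "has_protein", "has_go", "has_kegg",
                      "has_omia", "has_homolog")))
  flags[, "in_qtl"] <- snp_ids %in% in_qtl
  for (cat in evidence_categories()) {
    tab <- if (cat == "protein") "protein" else cat
    genes <- DBI::dbGetQuery(con, paste0("SELECT DISTINCT gene_id FROM ", tab))$gene_id
    flags[, paste0("has_", cat)] <- !is.na(snp$gene_id) & snp$gene_id %in% genes
  }
  flags
}

# SQLite's json_each gives a clean parameterised IN-list without string pasting
jsonlite_ids <- function(ids) {
  paste0("[", paste(sprintf('"%s"', ids), collapse = ","), "]")
}
jsonlite_nums <- function(x) paste0("[", paste(x, collapse = ","), "]")

#' Total prioritisation score for SNPs
#'
#' A SNP's score is the sum of two components: a function-class component
#' reflecting how likely the variant is to alter the encoded amino-acid
#' sequence (maximum 20 under the default table), plus one point per evidence
#' category found (QTL region, protein, GO term, KEGG pathway, OMIA record,
#' homologous genes) — so the maximum total under the default table is
#' 26 = 20 + 1 + 1 + 1 + 1 + 1 + 1.
#'
#' @inheritParams evidence_flags
#' @param table class-score table, defaults to [default_score_table()].
#' @return data frame with one row per SNP: `snp_id`, `class_component`, the
#'   six flag columns, and `total`.
#' @export
total_score <- function(snp_ids, store, table = default_score_table()) {
  con <- store$con
  snp <- DBI::dbGetQuery(con,
    "SELECT snp_id, function_class FROM snp WHERE snp_id IN (SELECT value FROM json_each(:ids))",
    params = list(ids = jsonlite_ids(snp_ids)))
  snp <- snp[match(snp_ids, snp$snp_id), , drop = FALSE]
  flags <- evidence_flags(snp_ids, store)
  cls <- class_score(snp$function_class, table)
  data.frame(
    snp_id = snp_ids,
    class_component = cls,
    as.data.frame(flags, row.names = NULL),
    total = cls + as.integer(rowSums(flags)),
    stringsAsFactors = FALSE)
}

#' Score every SNP in a store
#'
#' Recomputes and persists the total score for all SNPs. Deterministic:
#' re-running with unchanged annotations changes nothing.
#'
#' @param store writable `snp_store`.
#' @param table class-score table.
#' @return number of SNPs scored.
#' @export
score_all <- function(store, table = default_score_table()) {
  con <- store$con
  snp <- DBI::dbGetQuery(con, "SELECT snp_id, chrom, pos, gene_id, function_class FROM snp")
  if (nrow(snp) == 0L) return(0L)

  # set-based recomputation of the six flags (one pass per category)
  in_qtl <- DBI::dbGetQuery(con,
    "SELECT DISTINCT s.snp_id FROM snp s JOIN qtl q
       ON q.chrom = s.chrom AND s.pos BETWEEN q.start AND q.end")$snp_id
  n_flags <- as.integer(snp$snp_id %in% in_qtl)
  for (cat in evidence_categories()) {
    genes <- DBI::dbGetQuery(con, paste0("SELECT DISTINCT gene_id FROM ", cat))$gene_id
    n_flags <- n_flags + as.integer(!is.na(snp$gene_id) & snp$gene_id %in% genes)
  }
  totals <- class_score(snp$function_class, table) + n_flags

  DBI::dbWithTransaction(con, {
    DBI::dbExecute(con, "UPDATE snp SET score = :score WHERE snp_id = :id",
                   params = list(score = totals, id = snp$snp_id))
  })
  nrow(snp)
}
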
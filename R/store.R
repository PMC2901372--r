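SCHEMA_VERSION <- "1"

# table -> CREATE statement; column names are part of the public interface so
# that end users can query the store file directly with SQL
store_schema <- function() {
  list(
    meta = "CREATE TABLE meta (key TEXT PRIMARY KEY, value TEXT NOT NULL)",
    snp = "CREATE TABLE snp (
             snp_id TEXT PRIMARY KEY,
             chrom TEXT NOT NULL,
             pos INTEGER NOT NULL,
             alleles TEXT NOT NULL,
             function_class TEXT NOT NULL,
             gene_id INTEGER,
             score INTEGER NOT NULL DEFAULT 0)",
    gene = "CREATE TABLE gene (
              gene_id INTEGER PRIMARY KEY,
              symbol TEXT NOT NULL,
              chrom TEXT NOT NULL,
              start INTEGER NOT NULL,
              end INTEGER NOT NULL,
              strand TEXT NOT NULL)",
    protein = "CREATE TABLE protein (gene_id INTEGER NOT NULL, accession TEXT NOT NULL)",
    go = "CREATE TABLE go (gene_id INTEGER NOT NULL, accession TEXT NOT NULL, term TEXT)",
    kegg = "CREATE TABLE kegg (gene_id INTEGER NOT NULL, accession TEXT NOT NULL, pathway TEXT)",
    omia = "CREATE TABLE omia (gene_id INTEGER NOT NULL, accession TEXT NOT NULL, phenotype TEXT)",
    qtl = "CREATE TABLE qtl (qtl_id TEXT NOT NULL, chrom TEXT NOT NULL,
             start INTEGER NOT NULL, end INTEGER NOT NULL, trait TEXT)",
    homolog = "CREATE TABLE homolog (group_id TEXT NOT NULL, species TEXT NOT NULL,
                 gene_id INTEGER NOT NULL)"
  )
}

store_tables <- function() setdiff(names(store_schema()), "meta")

# evidence category -> backing table (all keyed on gene_id except qtl, which
# is positional)
evidence_categories <- function() c("protein", "go", "kegg", "omia", "homolog")

#' Create or open a species SNP store
#'
#' A store is a single-file SQLite database holding one species' SNPs, genes
#' and evidence annotations, every table linkable through the `snp_id` or
#' `gene_id` columns. Several stores (one per species) can be open in the same
#' session and queried independently. The table and column names are stable and
#' documented, so the file can also be queried directly with SQL.
#'
#' @param path store file path (`":memory:"` for a transient store).
#' @param species species registry key, a lowercase binomial token such as
#'   `"bos_taurus"`.
#' @param create create a fresh store (overwriting nothing; the schema is laid
#'   down only if the file is new or empty).
#' @return an object of class `snp_store` wrapping the open connection.
#' @examples
#' st <- open_store(":memory:", "toyspecies", create = TRUE)
#' store_counts(st)
#' close_store(st)
#' @export
open_store <- function(path, species, create = FALSE) {
  stopifnot(is.character(path), length(path) == 1L)
  stopifnot(grepl("^[a-z][a-z0-9_]*$", species))
  if (!create && path != ":memory:" && !file.exists(path)) {
    stop("no store installed for species '", species, "': file not found: ", path)
  }
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  existing <- DBI::dbListTables(con)
  if (length(existing) == 0L) {
    if (!create) {
      DBI::dbDisconnect(con)
      stop("empty store file (not a built database): ", path)
    }
    for (sql in store_schema()) DBI::dbExecute(con, sql)
    DBI::dbExecute(con, "CREATE INDEX idx_snp_chrom_pos ON snp(chrom, pos)")
    DBI::dbExecute(con, "CREATE INDEX idx_snp_gene ON snp(gene_id)")
    DBI::dbExecute(con, "CREATE INDEX idx_gene_chrom ON gene(chrom)")
    DBI::dbExecute(con,
      "INSERT INTO meta (key, value) VALUES ('schema_version', :v), ('species', :s)",
      params = list(v = SCHEMA_VERSION, s = species))
  } else {
    need <- names(store_schema())
    if (!all(need %in% existing)) {
      DBI::dbDisconnect(con)
      stop("store file lacks required tables (",
           paste(setdiff(need, existing), collapse = ", "), "): ", path)
    }
    ver <- DBI::dbGetQuery(con, "SELECT value FROM meta WHERE key = 'schema_version'")$value
    if (length(ver) != 1L || !identical(ver, SCHEMA_VERSION)) {
      DBI::dbDisconnect(con)
      stop("store schema version mismatch (found ", paste(ver, collapse = "/"),
           ", need ", SCHEMA_VERSION, "); rebuild the store")
    }
  }
  structure(list(con = con, path = path, species = species), class = "snp_store")
}

#' @rdname open_store
#' @param store an open `snp_store`.
#' @export
close_store <- function(store) {
  stopifnot(inherits(store, "snp_store"))
  DBI::dbDisconnect(store$con)
  invisible(NULL)
}

#' @rdname open_store
#' @return `store_counts()` returns a named integer vector of row counts per
#'   table.
#' @export
store_counts <- function(store) {
  tabs <- store_tables()
  n <- vapply(tabs, function(t) {
    DBI::dbGetQuery(store$con, paste0("SELECT COUNT(*) AS n FROM ", t))$n
  }, numeric(1))
  stats::setNames(as.integer(n), tabs)
}

#' @export
print.snp_store <- function(x, ...) {
  cat("<snp_store> species:", x$species, " file:", x$path, "\n")
  n <- store_counts(x)
  cat(paste0("  ", format(names(n), width = 8), " ", n, collapse = "\n"), "\n")
  invisible(x)
}

#' Validate a store's internal consistency
#'
#' Checks the linkage invariant (every `gene_id` referenced by a SNP or an
#' evidence row resolves to a gene record), coordinate sanity (positions and
#' interval ends 1-based and ordered) and accession syntax (rs numbers, GO and
#' UniProt accessions). Problems are report rows, never errors, so a partially
#' broken store can still be inspected.
#'
#' @param store an open `snp_store`.
#' @return data frame with columns `table`, `id`, `problem`; zero rows iff the
#'   store is internally consistent.
#' @export
validate_store <- function(store) {
  con <- store$con
  probs <- list()
  add <- function(table, id, problem) {
    if (length(id) > 0L) {
      probs[[length(probs) + 1L]] <<- data.frame(
        table = table, id = as.character(id), problem = problem,
        stringsAsFactors = FALSE)
    }
  }

  bad <- DBI::dbGetQuery(con, "SELECT snp_id FROM snp WHERE snp_id NOT GLOB 'rs[0-9]*'")
  add("snp", bad$snp_id, "malformed rs accession")
  bad <- DBI::dbGetQuery(con, "SELECT snp_id FROM snp WHERE pos < 1")$snp_id
  add("snp", bad, "position < 1")
  bad <- DBI::dbGetQuery(con, paste0(
    "SELECT snp_id FROM snp WHERE function_class NOT IN (",
    paste(sprintf("'%s'", function_classes()), collapse = ","), ")"))$snp_id
  add("snp", bad, "unknown function class")
  bad <- DBI::dbGetQuery(con,
    "SELECT snp_id FROM snp WHERE (gene_id IS NULL) != (function_class = 'intergenic')")$snp_id
  add("snp", bad, "gene link must be absent iff intergenic")
  bad <- DBI::dbGetQuery(con,
    "SELECT snp_id FROM snp WHERE gene_id IS NOT NULL
       AND gene_id NOT IN (SELECT gene_id FROM gene)")$snp_id
  add("snp", bad, "dangling gene_id")

  bad <- DBI::dbGetQuery(con, "SELECT gene_id FROM gene WHERE start < 1 OR start > end")$gene_id
  add("gene", bad, "invalid interval")
  bad <- DBI::dbGetQuery(con, "SELECT gene_id FROM gene WHERE strand NOT IN ('+','-')")$gene_id
  add("gene", bad, "invalid strand")

  for (tab in setdiff(evidence_categories(), "homolog")) {
    bad <- DBI::dbGetQuery(con, paste0(
      "SELECT gene_id FROM ", tab,
      " WHERE gene_id NOT IN (SELECT gene_id FROM gene)"))$gene_id
    add(tab, bad, "dangling gene_id")
  }
  # homolog rows for other species legitimately point outside this store's
  # gene table; only this species' members must resolve
  bad <- DBI::dbGetQuery(con,
    "SELECT gene_id FROM homolog WHERE species = :sp
       AND gene_id NOT IN (SELECT gene_id FROM gene)",
    params = list(sp = store$species))$gene_id
  add("homolog", bad, "dangling gene_id")
  bad <- DBI::dbGetQuery(con, "SELECT accession FROM go WHERE accession NOT GLOB 'GO:[0-9][0-9][0-9][0-9][0-9][0-9][0-9]'")$accession
  add("go", bad, "malformed GO accession")
  go_ok <- DBI::dbGetQuery(con, "SELECT accession FROM protein")$accession
  bad <- go_ok[!grepl("^[A-Z0-9]{6,10}$", go_ok)]
  add("protein", bad, "malformed UniProt accession")
  bad <- DBI::dbGetQuery(con, "SELECT qtl_id FROM qtl WHERE start < 1 OR start > end")$qtl_id
  add("qtl", bad, "invalid interval")
  dup <- DBI::dbGetQuery(con,
    "SELECT gene_id FROM homolog GROUP BY gene_id HAVING COUNT(DISTINCT group_id) > 1")$gene_id
  add("homolog", dup, "gene in more than one homolog group")

  if (length(probs) == 0L) {
    data.frame(table = character(), id = character(), problem = character(),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, probs)
  }
}
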
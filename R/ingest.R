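SOURCE_NAMES <- c("snp", "gene", "go", "kegg", "uniprot", "qtl", "omia", "homologene")
MANDATORY_SOURCES <- c("snp", "gene")
COMPRESSIONS <- c("none", "gz", "zip", "tar", "tgz")

infer_compression <- function(location) {
  # suffix rule: tar, tgz, gz and zip archives are decompressed automatically
  if (grepl("\\.tar\\.gz$|\\.tgz$", location)) "tgz"
  else if (grepl("\\.tar$", location)) "tar"
  else if (grepl("\\.gz$", location)) "gz"
  else if (grepl("\\.zip$", location)) "zip"
  else "none"
}

#' Parse a species build configuration
#'
#' The build is driven by one INI file per species: a `[species]` section
#' naming the registry key, then one section per source (`[snp]`, `[gene]`,
#' `[go]`, `[kegg]`, `[uniprot]`, `[qtl]`, `[omia]`, `[homologene]`) giving at
#' least a `location` (URL or local path). `compression` and `dialect` default
#' from the location suffix and the section name. Relative locations are
#' resolved against the INI file's directory.
#'
#' @param path path to the INI file.
#' @return an `ingest_plan`: list with `species` and a data frame `sources`
#'   (name, location, compression, dialect) in file order.
#' @export
parse_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub(";.*$", "", sub("#.*$", "", lines))
  lines <- trimws(lines)
  section <- NA_character_
  ini <- list()
  order <- character()
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (!nzchar(ln)) next
    if (grepl("^\\[.*\\]$", ln)) {
      section <- sub("^\\[(.*)\\]$", "\\1", ln)
      if (section %in% order) stop("duplicate section [", section, "]")
      ini[[section]] <- list()
      order <- c(order, section)
    } else if (grepl("=", ln, fixed = TRUE)) {
      if (is.na(section)) stop("key outside any section at line ", i)
      key <- trimws(sub("=.*$", "", ln))
      val <- trimws(sub("^[^=]*=", "", ln))
      ini[[section]][[key]] <- val
    } else {
      stop("malformed INI line ", i, ": ", ln)
    }
  }

  species <- ini[["species"]][["name"]]
  if (is.null(species)) stop("config must carry a [species] section with key 'name'")
  src_sections <- setdiff(order, "species")
  unknown <- setdiff(src_sections, SOURCE_NAMES)
  if (length(unknown) > 0L) stop("unknown source section(s): ", paste(unknown, collapse = ", "))
  missing <- setdiff(MANDATORY_SOURCES, src_sections)
  if (length(missing) > 0L) {
    stop("config missing mandatory section(s): ",
         paste(sprintf("[%s]", missing), collapse = ", "))
  }

  known_keys <- c("location", "compression", "dialect")
  sources <- lapply(src_sections, function(nm) {
    sec <- ini[[nm]]
    extra <- setdiff(names(sec), known_keys)
    if (length(extra) > 0L) {
      warning("section [", nm, "] has unknown key(s): ", paste(extra, collapse = ", "))
    }
    loc <- sec[["location"]]
    if (is.null(loc) || !nzchar(loc)) stop("section [", nm, "] missing mandatory key 'location'")
    if (!grepl("^[a-z]+://", loc) && !grepl("^/", loc)) {
      loc <- file.path(dirname(normalizePath(path)), loc)
    }
    comp <- sec[["compression"]]
    if (is.null(comp)) comp <- infer_compression(loc)
    if (!comp %in% COMPRESSIONS) stop("unknown compression '", comp, "' in [", nm, "]")
    dia <- sec[["dialect"]]
    if (is.null(dia)) dia <- nm
    if (!dia %in% names(dialect_parsers())) stop("unknown dialect '", dia, "' in [", nm, "]")
    data.frame(name = nm, location = loc, compression = comp, dialect = dia,
               stringsAsFactors = FALSE)
  })
  plan <- list(species = species, sources = do.call(rbind, sources), path = path)
  class(plan) <- "ingest_plan"
  plan
}

#' Fetch and decompress one source file
#'
#' Local paths are copied; `http(s)`/`ftp` URLs are downloaded. Archives with
#' suffix `gz`, `zip`, `tar` or `tgz` are unpacked to a plain-text file.
#' Re-running with an unchanged source reproduces an identical file.
#'
#' @param location URL or local path.
#' @param workdir working directory for downloaded/decompressed files.
#' @param compression one of `none`, `gz`, `zip`, `tar`, `tgz`; inferred from
#'   the suffix when missing.
#' @return path to the plain-text file.
#' @export
fetch_and_decompress <- function(location, workdir, compression = NULL) {
  if (is.null(compression)) compression <- infer_compression(location)
  if (!compression %in% COMPRESSIONS) {
    stop("unsupported archive suffix on: ", location)
  }
  if (grepl("\\.(7z|bz2|xz|rar)$", location)) stop("unsupported archive suffix on: ", location)
  dir.create(workdir, showWarnings = FALSE, recursive = TRUE)

  local <- location
  if (grepl("^[a-z]+://", location)) {
    local <- file.path(workdir, basename(location))
    status <- utils::download.file(location, local, quiet = TRUE, mode = "wb")
    if (status != 0L) stop("unreachable location: ", location)
  } else if (!file.exists(local)) {
    stop("unreachable location: ", location)
  }

  switch(compression,
    none = local,
    gz = {
      out <- file.path(workdir, sub("\\.gz$", "", basename(local)))
      con <- gzfile(local, "rb")
      on.exit(close(con))
      raw <- readBin(con, "raw", n = file.size(local) * 50 + 1e6)
      writeBin(raw, out)
      out
    },
    zip = {
      listing <- utils::unzip(local, list = TRUE)
      if (nrow(listing) != 1L) stop("archive must contain exactly one file: ", local)
      utils::unzip(local, exdir = workdir, overwrite = TRUE)
      file.path(workdir, listing$Name[[1L]])
    },
    tar = ,
    tgz = {
      listing <- utils::untar(local, list = TRUE)
      listing <- listing[!grepl("/$", listing)]
      if (length(listing) != 1L) stop("archive must contain exactly one file: ", local)
      utils::untar(local, exdir = workdir)
      file.path(workdir, listing[[1L]])
    }
  )
}

# --- dialect parsers -------------------------------------------------------
# Each parser maps one plain-text source file to a typed data frame matching a
# store table. Malformed lines are skipped and counted; a file where more than
# half the data lines fail signals a wrong-dialect file and is an error.
# The registry is a plain list so real-resource dialects can be plugged in.

read_tab <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "!") & !startsWith(lines, "#")]
  lines <- lines[nzchar(lines)]
  strsplit(lines, "\t", fixed = TRUE)
}

parse_with <- function(path, min_fields, builder) {
  rows <- read_tab(path)
  if (length(rows) == 0L) {
    warning("zero records parsed from ", path)
    return(builder(list()))
  }
  ok <- vapply(rows, function(f) length(f) >= min_fields, logical(1))
  out <- builder(rows[ok])
  keep <- attr(out, "kept")
  n_bad <- length(rows) - (if (is.null(keep)) sum(ok) else keep)
  if (n_bad * 2L > length(rows)) {
    stop("more than 50% malformed lines in ", path, " (wrong dialect?)")
  }
  if (n_bad > 0L) message(n_bad, " malformed line(s) skipped in ", path)
  attr(out, "kept") <- NULL
  out
}

col <- function(rows, i) vapply(rows, `[[`, character(1), i)

parse_snp <- function(path) {
  parse_with(path, 6L, function(rows) {
    df <- data.frame(
      snp_id = col(rows, 1), chrom = col(rows, 2),
      pos = suppressWarnings(as.integer(col(rows, 3))),
      alleles = col(rows, 4), function_class = col(rows, 5),
      gene_id = suppressWarnings(as.integer(ifelse(col(rows, 6) == ".", NA, col(rows, 6)))),
      stringsAsFactors = FALSE)
    ok <- grepl("^rs[0-9]+$", df$snp_id) & !is.na(df$pos) & df$pos >= 1 &
      df$function_class %in% function_classes() &
      (is.na(df$gene_id) == (df$function_class == "intergenic"))
    out <- df[ok, , drop = FALSE]
    out$score <- rep(0L, nrow(out))
    attr(out, "kept") <- sum(ok)
    out
  })
}

parse_gene <- function(path) {
  parse_with(path, 6L, function(rows) {
    df <- data.frame(
      gene_id = suppressWarnings(as.integer(col(rows, 1))), symbol = col(rows, 2),
      chrom = col(rows, 3),
      start = suppressWarnings(as.integer(col(rows, 4))),
      end = suppressWarnings(as.integer(col(rows, 5))),
      strand = col(rows, 6), stringsAsFactors = FALSE)
    ok <- !is.na(df$gene_id) & !is.na(df$start) & !is.na(df$end) &
      df$start >= 1 & df$start <= df$end & df$strand %in% c("+", "-")
    out <- df[ok, , drop = FALSE]
    attr(out, "kept") <- sum(ok)
    out
  })
}

# GAF 2.x: column 2 = DB object ID (numeric gene ID here), column 5 = GO:ID,
# comment lines start with "!"
parse_go <- function(path) {
  parse_with(path, 5L, function(rows) {
    df <- data.frame(
      gene_id = suppressWarnings(as.integer(col(rows, 2))),
      accession = col(rows, 5),
      term = vapply(rows, function(f) if (length(f) >= 10L) f[[10L]] else "", character(1)),
      stringsAsFactors = FALSE)
    ok <- !is.na(df$gene_id) & grepl("^GO:[0-9]{7}$", df$accession)
    out <- df[ok, , drop = FALSE]
    attr(out, "kept") <- sum(ok)
    out
  })
}

parse_kegg <- function(path) {
  parse_with(path, 2L, function(rows) {
    df <- data.frame(
      gene_id = suppressWarnings(as.integer(col(rows, 1))),
      accession = col(rows, 2),
      pathway = vapply(rows, function(f) if (length(f) >= 3L) f[[3L]] else "", character(1)),
      stringsAsFactors = FALSE)
    ok <- !is.na(df$gene_id) & nzchar(df$accession)
    out <- df[ok, , drop = FALSE]
    attr(out, "kept") <- sum(ok)
    out
  })
}

parse_uniprot <- function(path) {
  parse_with(path, 2L, function(rows) {
    df <- data.frame(
      gene_id = suppressWarnings(as.integer(col(rows, 1))),
      accession = col(rows, 2), stringsAsFactors = FALSE)
    ok <- !is.na(df$gene_id) & grepl("^[A-Z0-9]{6,10}$", df$accession)
    out <- df[ok, , drop = FALSE]
    attr(out, "kept") <- sum(ok)
    out
  })
}

# GFF3: seqid source type start end score strand phase attributes; the trait
# name travels in the "Name" attribute, the QTL accession in "ID"
parse_qtl <- function(path) {
  parse_with(path, 9L, function(rows) {
    attr_of <- function(attrs, key) {
      m <- regmatches(attrs, regexec(paste0("(^|;)", key, "=([^;]*)"), attrs))
      vapply(m, function(x) if (length(x) == 3L) x[[3L]] else NA_character_, character(1))
    }
    attrs <- col(rows, 9)
    df <- data.frame(
      qtl_id = attr_of(attrs, "ID"), chrom = col(rows, 1),
      start = suppressWarnings(as.integer(col(rows, 4))),
      end = suppressWarnings(as.integer(col(rows, 5))),
      trait = attr_of(attrs, "Name"), stringsAsFactors = FALSE)
    ok <- !is.na(df$qtl_id) & !is.na(df$start) & !is.na(df$end) &
      df$start >= 1 & df$start <= df$end & !is.na(df$trait)
    out <- df[ok, , drop = FALSE]
    attr(out, "kept") <- sum(ok)
    out
  })
}

parse_omia <- function(path) {
  parse_with(path, 3L, function(rows) {
    df <- data.frame(
      gene_id = suppressWarnings(as.integer(col(rows, 1))),
      accession = col(rows, 2), phenotype = col(rows, 3),
      stringsAsFactors = FALSE)
    ok <- !is.na(df$gene_id) & nzchar(df$accession)
    out <- df[ok, , drop = FALSE]
    attr(out, "kept") <- sum(ok)
    out
  })
}

parse_homologene <- function(path) {
  parse_with(path, 3L, function(rows) {
    df <- data.frame(
      group_id = col(rows, 1), species = col(rows, 2),
      gene_id = suppressWarnings(as.integer(col(rows, 3))),
      stringsAsFactors = FALSE)
    ok <- nzchar(df$group_id) & !is.na(df$gene_id)
    out <- df[ok, , drop = FALSE]
    attr(out, "kept") <- sum(ok)
    out
  })
}

dialect_parsers <- function() {
  list(snp = parse_snp, gene = parse_gene, go = parse_go, kegg = parse_kegg,
       uniprot = parse_uniprot, qtl = parse_qtl, omia = parse_omia,
       homologene = parse_homologene)
}

# which store table a source's records land in
source_table <- function(name) {
  switch(name, snp = "snp", gene = "gene", go = "go", kegg = "kegg",
         uniprot = "protein", qtl = "qtl", omia = "omia",
         homologene = "homolog", stop("unknown source: ", name))
}

#' Convert one source file to typed records
#'
#' @param path plain-text file in the named dialect.
#' @param dialect parser key (`snp`, `gene`, `go`, `kegg`, `uniprot`, `qtl`,
#'   `omia`, `homologene`).
#' @return data frame of records matching the corresponding store table.
#' @export
convert_source <- function(path, dialect) {
  parsers <- dialect_parsers()
  if (!dialect %in% names(parsers)) stop("unknown dialect: ", dialect)
  parsers[[dialect]](path)
}

#' Import records for one source into a store
#'
#' Each source is imported in its own transaction: the previous contents of
#' that source's table are replaced (delete-and-replace refresh semantics, so
#' repeated ingests never accumulate stale rows), and any failure rolls the
#' table back to its prior state.
#'
#' @param store writable `snp_store`.
#' @param table destination table name.
#' @param records data frame from [convert_source()].
#' @return number of rows inserted.
#' @export
import_records <- function(store, table, records) {
  stopifnot(table %in% store_tables())
  con <- store$con
  DBI::dbWithTransaction(con, {
    DBI::dbExecute(con, paste0("DELETE FROM ", table))
    if (nrow(records) > 0L) {
      if (table == "homolog") {
        key <- paste(records$species, records$gene_id)
        dup <- unique(key[duplicated(key)])
        if (length(dup) > 0L) {
          stop("gene(s) in more than one homolog group: ",
               paste(utils::head(dup, 3), collapse = ", "))
        }
      }
      DBI::dbAppendTable(con, table, records)
    }
  })
  nrow(records)
}

#' Build a species store from a configuration file
#'
#' Runs the full download-decompress-convert-import pipeline for every source
#' in the plan, in file order, then optionally scores all SNPs. Each source is
#' atomic; re-running a build replaces each source's rows, so the pipeline is
#' idempotent.
#'
#' @param config path to the species INI file (see [parse_config()]).
#' @param out output store file path.
#' @param workdir scratch directory for downloads/decompression.
#' @param score score all SNPs after import (default `TRUE`).
#' @param score_table class-score table used when `score` is `TRUE`.
#' @return invisibly, a named integer vector of per-table insert counts.
#' @examples
#' dir <- tempfile(); p <- fixture_params(n_snps = 50, n_genes = 8, n_significant = 5,
#'                                        n_planted_markers = 2)
#' fx <- generate_fixture(p, dir)
#' counts <- build_store(fx$config, file.path(dir, "toy.db"))
#' counts
#' @export
build_store <- function(config, out, workdir = tempfile("ingest"), score = TRUE,
                        score_table = default_score_table()) {
  plan <- parse_config(config)
  store <- open_store(out, plan$species, create = TRUE)
  on.exit(close_store(store))
  counts <- integer(0)
  for (i in seq_len(nrow(plan$sources))) {
    src <- plan$sources[i, ]
    txt <- fetch_and_decompress(src$location, workdir, src$compression)
    recs <- convert_source(txt, src$dialect)
    tab <- source_table(src$name)
    counts[[tab]] <- import_records(store, tab, recs)
  }
  if (score) score_all(store, score_table)
  invisible(counts)
}
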
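check_id_query <- function(ids, id_type) {
  if (length(ids) == 0L) stop("empty id list")
  id_type <- match.arg(id_type, c("snp", "gene"))
  if (id_type == "snp" && !all(grepl("^rs[0-9]+$", ids))) {
    stop("malformed rs accession(s): ",
         paste(utils::head(ids[!grepl("^rs[0-9]+$", ids)], 3), collapse = ", "))
  }
  if (id_type == "gene" && anyNA(suppressWarnings(as.integer(ids)))) {
    stop("malformed gene id(s) (must be integers)")
  }
  id_type
}

# rs accessions order numerically by their rs number, not lexically
rs_number <- function(snp_id) as.numeric(sub("^rs", "", snp_id))

#' Retrieve SNP records by SNP or gene identifiers
#'
#' With `id_type = "snp"`, returns one record per found rs accession, in input
#' order; unknown identifiers are collected in the `not_found` attribute
#' rather than raising an error, so batch screens survive partial annotation.
#' With `id_type = "gene"`, returns every SNP whose position lies within each
#' gene's `[start, end]` interval (1-based inclusive).
#'
#' @param ids character vector of rs accessions or gene IDs.
#' @param id_type `"snp"` or `"gene"`.
#' @param store an open `snp_store`.
#' @return data frame of SNP records (columns as the `snp` table, plus
#'   `query_id` in gene mode); attribute `not_found` lists unmatched inputs.
#' @export
get_snps <- function(ids, id_type = c("snp", "gene"), store) {
  id_type <- check_id_query(ids, id_type)
  con <- store$con
  if (id_type == "snp") {
    res <- DBI::dbGetQuery(con,
      "SELECT * FROM snp WHERE snp_id IN (SELECT value FROM json_each(:ids))",
      params = list(ids = jsonlite_ids(ids)))
    res <- res[match(ids[ids %in% res$snp_id], res$snp_id), , drop = FALSE]
    rownames(res) <- NULL
    attr(res, "not_found") <- setdiff(ids, res$snp_id)
    res
  } else {
    gids <- as.integer(ids)
    genes <- DBI::dbGetQuery(con,
      "SELECT gene_id, chrom, start, end FROM gene
        WHERE gene_id IN (SELECT value FROM json_each(:ids))",
      params = list(ids = jsonlite_nums(gids)))
    out <- lapply(gids, function(g) {
      gi <- genes[genes$gene_id == g, , drop = FALSE]
      if (nrow(gi) == 0L) return(NULL)
      r <- DBI::dbGetQuery(con,
        "SELECT * FROM snp WHERE chrom = :c AND pos BETWEEN :s AND :e ORDER BY pos, snp_id",
        params = list(c = gi$chrom, s = gi$start, e = gi$end))
      if (nrow(r) > 0L) cbind(query_id = as.character(g), r, stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, out)
    if (is.null(res)) {
      res <- cbind(query_id = character(),
                   DBI::dbGetQuery(con, "SELECT * FROM snp WHERE 0"))
    }
    rownames(res) <- NULL
    attr(res, "not_found") <- as.character(setdiff(gids, genes$gene_id))
    res
  }
}

resolve_gene_ids <- function(ids, id_type, store) {
  # map every input id to (query_id, gene_id); SNP ids resolve through their
  # gene link (NA for intergenic SNPs)
  if (id_type == "snp") {
    snp <- get_snps(ids, "snp", store)
    data.frame(query_id = snp$snp_id, gene_id = snp$gene_id, stringsAsFactors = FALSE)
  } else {
    data.frame(query_id = as.character(ids), gene_id = as.integer(ids),
               stringsAsFactors = FALSE)
  }
}

#' Retrieve annotations linked to SNPs or genes
#'
#' SNP identifiers are first resolved to their linked gene (intergenic SNPs
#' yield no gene-mediated annotations). `category = "qtl_trait"` is positional
#' for SNPs (QTL regions containing the SNP's position) and interval-overlap
#' for genes. `category = "homolog"` returns the gene's homolog-group members,
#' optionally restricted to one target species.
#'
#' @inheritParams get_snps
#' @param category one of `gene`, `protein`, `go`, `kegg`, `qtl_trait`,
#'   `omia`, `homolog`.
#' @param species optional species filter for `homolog`.
#' @return data frame keyed by `query_id`, with category-specific columns.
#' @export
get_annotations <- function(ids, id_type = c("snp", "gene"), category, store,
                            species = NULL) {
  id_type <- check_id_query(ids, id_type)
  category <- match.arg(category,
    c("gene", "protein", "go", "kegg", "qtl_trait", "omia", "homolog"))
  con <- store$con

  if (category == "qtl_trait") {
    if (id_type == "snp") {
      snp <- get_snps(ids, "snp", store)
      out <- DBI::dbGetQuery(con,
        "SELECT s.snp_id AS query_id, q.qtl_id, q.chrom, q.start, q.end, q.trait
           FROM snp s JOIN qtl q ON q.chrom = s.chrom AND s.pos BETWEEN q.start AND q.end
          WHERE s.snp_id IN (SELECT value FROM json_each(:ids))",
        params = list(ids = jsonlite_ids(ids)))
    } else {
      out <- DBI::dbGetQuery(con,
        "SELECT g.gene_id AS query_id, q.qtl_id, q.chrom, q.start, q.end, q.trait
           FROM gene g JOIN qtl q ON q.chrom = g.chrom
            AND q.start <= g.end AND q.end >= g.start
          WHERE g.gene_id IN (SELECT value FROM json_each(:ids))",
        params = list(ids = jsonlite_nums(as.integer(ids))))
      out$query_id <- as.character(out$query_id)
    }
    return(order_by_input(out, ids))
  }

  map <- resolve_gene_ids(ids, id_type, store)
  map <- map[!is.na(map$gene_id), , drop = FALSE]
  if (nrow(map) == 0L) return(empty_annotation(category))
  gid_list <- jsonlite_nums(unique(map$gene_id))

  ann <- switch(category,
    gene = DBI::dbGetQuery(con,
      "SELECT * FROM gene WHERE gene_id IN (SELECT value FROM json_each(:ids))",
      params = list(ids = gid_list)),
    protein = DBI::dbGetQuery(con,
      "SELECT gene_id, accession FROM protein WHERE gene_id IN (SELECT value FROM json_each(:ids))",
      params = list(ids = gid_list)),
    go = DBI::dbGetQuery(con,
      "SELECT gene_id, accession, term FROM go WHERE gene_id IN (SELECT value FROM json_each(:ids))",
      params = list(ids = gid_list)),
    kegg = DBI::dbGetQuery(con,
      "SELECT gene_id, accession, pathway FROM kegg WHERE gene_id IN (SELECT value FROM json_each(:ids))",
      params = list(ids = gid_list)),
    omia = DBI::dbGetQuery(con,
      "SELECT gene_id, accession, phenotype FROM omia WHERE gene_id IN (SELECT value FROM json_each(:ids))",
      params = list(ids = gid_list)),
    homolog = {
      h <- DBI::dbGetQuery(con,
        "SELECT h2.group_id, h1.gene_id AS gene_id, h2.species AS member_species,
                h2.gene_id AS member_gene_id
           FROM homolog h1 JOIN homolog h2 ON h1.group_id = h2.group_id
          WHERE h1.gene_id IN (SELECT value FROM json_each(:ids))",
        params = list(ids = gid_list))
      if (!is.null(species)) h <- h[h$member_species == species, , drop = FALSE]
      h
    })

  out <- merge(map, ann, by = "gene_id", sort = FALSE)
  out <- out[, c("query_id", setdiff(names(out), "query_id")), drop = FALSE]
  order_by_input(out, ids)
}

order_by_input <- function(df, ids) {
  if (nrow(df) > 0L) {
    df <- df[order(match(df$query_id, as.character(ids))), , drop = FALSE]
  }
  rownames(df) <- NULL
  df
}

empty_annotation <- function(category) {
  data.frame(query_id = character(), gene_id = integer(), stringsAsFactors = FALSE)
}

#' Look up SNP identifiers by chromosomal location
#'
#' Exact `(chrom, pos)` match. Multi-allelic collisions (several rs accessions
#' at one position) are all returned, ordered by ascending rs number.
#'
#' @param locations data frame with columns `chrom` and `pos` (1-based bp).
#' @param store an open `snp_store`.
#' @return data frame `chrom`, `pos`, `snp_id` (`NA` where no SNP occupies the
#'   position), one row per match plus one per unmatched location.
#' @export
get_snp_id <- function(locations, store) {
  stopifnot(is.data.frame(locations), all(c("chrom", "pos") %in% names(locations)))
  stopifnot(all(locations$pos >= 1))
  con <- store$con
  out <- lapply(seq_len(nrow(locations)), function(i) {
    hit <- DBI::dbGetQuery(con,
      "SELECT snp_id FROM snp WHERE chrom = :c AND pos = :p",
      params = list(c = locations$chrom[[i]], p = locations$pos[[i]]))
    snp_id <- if (nrow(hit) == 0L) NA_character_ else hit$snp_id[order(rs_number(hit$snp_id))]
    data.frame(chrom = locations$chrom[[i]], pos = locations$pos[[i]],
               snp_id = snp_id, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# edge-gap distance: 0 inside the gene, else bp to the nearest gene boundary
gene_distance <- function(pos, start, end) {
  ifelse(pos >= start & pos <= end, 0L,
         pmin(abs(pos - start), abs(pos - end)))
}

#' Genes within a distance of each SNP
#'
#' Distance is the gap to the nearest gene boundary: 0 if the SNP lies inside
#' `[start, end]`, otherwise `min(|pos - start|, |pos - end|)`. Only genes on
#' the SNP's own chromosome are considered (cross-chromosome distance is
#' undefined). Results are sorted by ascending distance then gene ID.
#'
#' @param snp_ids character vector of rs accessions.
#' @param max_dist maximum distance in bp (inclusive), `>= 0`.
#' @param store an open `snp_store`.
#' @return data frame `snp_id`, `gene_id`, `distance`.
#' @export
genes_by_dist <- function(snp_ids, max_dist, store) {
  stopifnot(length(max_dist) == 1L, max_dist >= 0)
  snp <- get_snps(snp_ids, "snp", store)
  con <- store$con
  out <- lapply(seq_len(nrow(snp)), function(i) {
    g <- DBI::dbGetQuery(con,
      "SELECT gene_id, start, end FROM gene WHERE chrom = :c",
      params = list(c = snp$chrom[[i]]))
    if (nrow(g) == 0L) return(NULL)
    d <- gene_distance(snp$pos[[i]], g$start, g$end)
    keep <- d <= max_dist
    if (!any(keep)) return(NULL)
    r <- data.frame(snp_id = snp$snp_id[[i]], gene_id = g$gene_id[keep],
                    distance = as.integer(d[keep]), stringsAsFactors = FALSE)
    r[order(r$distance, r$gene_id), , drop = FALSE]
  })
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(snp_id = character(), gene_id = integer(),
                      distance = integer(), stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  res
}

# accept either a vector of rs ids or a (chrom,pos) data frame as targets
resolve_targets <- function(targets, store) {
  if (is.data.frame(targets)) {
    stopifnot(all(c("chrom", "pos") %in% names(targets)))
    data.frame(target = paste0(targets$chrom, ":", targets$pos),
               chrom = targets$chrom, pos = targets$pos,
               self = NA_character_, stringsAsFactors = FALSE)
  } else {
    snp <- get_snps(targets, "snp", store)
    data.frame(target = snp$snp_id, chrom = snp$chrom, pos = snp$pos,
               self = snp$snp_id, stringsAsFactors = FALSE)
  }
}

#' Nearest genes to SNPs or locations
#'
#' Returns the `k` genes with the smallest edge-gap distance on the target's
#' chromosome, ties broken by ascending gene ID; fewer than `k` rows are
#' returned when the chromosome holds fewer genes.
#'
#' @param targets character vector of rs accessions, or a data frame with
#'   columns `chrom`, `pos`.
#' @param k number of genes per target, `>= 1`.
#' @param store an open `snp_store`.
#' @return data frame `target`, `gene_id`, `distance`, ordered per target by
#'   ascending distance.
#' @export
nearest_genes <- function(targets, k = 1L, store) {
  stopifnot(k >= 1L)
  tg <- resolve_targets(targets, store)
  con <- store$con
  out <- lapply(seq_len(nrow(tg)), function(i) {
    g <- DBI::dbGetQuery(con,
      "SELECT gene_id, start, end FROM gene WHERE chrom = :c",
      params = list(c = tg$chrom[[i]]))
    if (nrow(g) == 0L) return(NULL)
    d <- gene_distance(tg$pos[[i]], g$start, g$end)
    ord <- order(d, g$gene_id)[seq_len(min(k, nrow(g)))]
    data.frame(target = tg$target[[i]], gene_id = g$gene_id[ord],
               distance = as.integer(d[ord]), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(target = character(), gene_id = integer(),
                      distance = integer(), stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  res
}

#' Highest-scoring SNP near each target
#'
#' Among store SNPs on the target's chromosome within `max_dist` bp of the
#' target position (the target SNP itself excluded), returns the SNP with the
#' highest score strictly greater than `min_score`; ties are broken by smaller
#' distance, then ascending rs number. `NA` when no SNP qualifies.
#'
#' @inheritParams nearest_genes
#' @param min_score strict lower score bound (a qualifying SNP must score
#'   `> min_score`); default -1 accepts any score.
#' @param max_dist search radius in bp, `>= 0`.
#' @return data frame `target`, `snp_id`, `score`, `distance` (one row per
#'   target; `snp_id` `NA` when nothing qualifies).
#' @export
high_score_snp <- function(targets, min_score = -1L, max_dist, store) {
  stopifnot(max_dist >= 0)
  tg <- resolve_targets(targets, store)
  con <- store$con
  out <- lapply(seq_len(nrow(tg)), function(i) {
    cand <- DBI::dbGetQuery(con,
      "SELECT snp_id, pos, score FROM snp
        WHERE chrom = :c AND pos BETWEEN :lo AND :hi",
      params = list(c = tg$chrom[[i]],
                    lo = tg$pos[[i]] - max_dist, hi = tg$pos[[i]] + max_dist))
    if (!is.na(tg$self[[i]])) cand <- cand[cand$snp_id != tg$self[[i]], , drop = FALSE]
    cand <- cand[cand$score > min_score, , drop = FALSE]
    if (nrow(cand) == 0L) {
      return(data.frame(target = tg$target[[i]], snp_id = NA_character_,
                        score = NA_integer_, distance = NA_integer_,
                        stringsAsFactors = FALSE))
    }
    d <- abs(cand$pos - tg$pos[[i]])
    best <- order(-cand$score, d, rs_number(cand$snp_id))[[1L]]
    data.frame(target = tg$target[[i]], snp_id = cand$snp_id[[best]],
               score = cand$score[[best]], distance = as.integer(d[[best]]),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
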
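#' Screening criteria for one prioritisation run
#'
#' The post-GWAS screen runs the annotation functions over four progressively
#' narrower SNP selections:
#' \describe{
#'   \item{`all_significant`}{every input (GWAS-significant) SNP;}
#'   \item{`significant_by_score`}{input SNPs with score strictly greater than
#'     `score_gt` (default 7);}
#'   \item{`nearby_high_score`}{database SNPs (inputs excluded) with score
#'     `> score_gt` (default 11) within `dist` bp of any input SNP
#'     (SNP-to-SNP distance, default 10,000 bp);}
#'   \item{`nearby_gene_snps`}{genes within `dist` bp of any input SNP
#'     (edge-gap distance), then SNPs located on those genes
#'     (position inside `[start, end]`) with score `> score_gt` (default 24).}
#' }
#' Score thresholds are strict; distances are inclusive. The thresholds and
#' search distance are at the user's discretion — LD patterns of the study
#' species should govern the distance.
#'
#' @param mode one of the four modes above.
#' @param score_gt strict score threshold (ignored by `all_significant`).
#' @param dist search radius in bp (modes 3-4 only).
#' @return a `screen_criteria` list.
#' @export
screen_criteria <- function(mode = c("all_significant", "significant_by_score",
                                     "nearby_high_score", "nearby_gene_snps"),
                            score_gt = NULL, dist = NULL) {
  mode <- match.arg(mode)
  defaults <- list(all_significant = list(score_gt = 0L, dist = NA_integer_),
                   significant_by_score = list(score_gt = 7L, dist = NA_integer_),
                   nearby_high_score = list(score_gt = 11L, dist = 10000L),
                   nearby_gene_snps = list(score_gt = 24L, dist = 10000L))[[mode]]
  if (is.null(score_gt)) score_gt <- defaults$score_gt
  if (is.null(dist)) dist <- defaults$dist
  stopifnot(score_gt >= 0L)
  if (mode %in% c("nearby_high_score", "nearby_gene_snps")) {
    if (is.na(dist) || dist < 0) stop("mode '", mode, "' requires dist >= 0")
  }
  structure(list(mode = mode, score_gt = as.integer(score_gt),
                 dist = as.integer(dist)), class = "screen_criteria")
}

# SNPs selected by one run, as a character vector of rs ids
select_snps <- function(significant, criteria, store) {
  con <- store$con
  switch(criteria$mode,
    all_significant = {
      found <- get_snps(significant, "snp", store)
      found$snp_id
    },
    significant_by_score = {
      found <- get_snps(significant, "snp", store)
      found$snp_id[found$score > criteria$score_gt]
    },
    nearby_high_score = {
      inputs <- get_snps(significant, "snp", store)
      hits <- DBI::dbGetQuery(con,
        "SELECT DISTINCT t.snp_id FROM snp t
           JOIN snp s ON s.chrom = t.chrom
          WHERE s.snp_id IN (SELECT value FROM json_each(:ids))
            AND ABS(t.pos - s.pos) <= :d AND t.score > :sc",
        params = list(ids = jsonlite_ids(inputs$snp_id),
                      d = criteria$dist, sc = criteria$score_gt))$snp_id
      sort_rs(setdiff(hits, inputs$snp_id))
    },
    nearby_gene_snps = {
      inputs <- get_snps(significant, "snp", store)
      near <- genes_by_dist(inputs$snp_id, criteria$dist, store)
      if (nrow(near) == 0L) return(character())
      hits <- DBI::dbGetQuery(con,
        "SELECT DISTINCT t.snp_id FROM snp t
           JOIN gene g ON g.chrom = t.chrom AND t.pos BETWEEN g.start AND g.end
          WHERE g.gene_id IN (SELECT value FROM json_each(:ids))
            AND t.score > :sc",
        params = list(ids = jsonlite_nums(unique(near$gene_id)),
                      sc = criteria$score_gt))$snp_id
      sort_rs(hits)
    })
}

sort_rs <- function(ids) ids[order(rs_number(ids))]

#' Run one screening pass over a GWAS-significant SNP list
#'
#' Selects SNPs according to the criteria, then tallies the distinct
#' annotation entities reachable from the selection: genes, proteins (UniProt
#' accessions), pathways, GO terms and homologous genes, each deduplicated by
#' accession across SNPs. `high_score_count` applies the rule that SNPs
#' scoring 20 or more are considered highly likely to have significant
#' functional roles.
#'
#' @param significant character vector of GWAS-significant rs accessions.
#' @param criteria a [screen_criteria()] object.
#' @param store an open, scored `snp_store`.
#' @param homolog_species optional species filter for the homolog tally.
#' @return a `screen_result`: criteria, `input_snps`, `snps_selected`,
#'   `wgas_selected`, `high_score_count` and the five distinct-annotation
#'   counts.
#' @export
screen <- function(significant, criteria, store, homolog_species = NULL) {
  if (length(significant) == 0L) stop("empty significant SNP list")
  stopifnot(inherits(criteria, "screen_criteria"))
  selected <- select_snps(significant, criteria, store)

  counts <- c(genes = 0L, proteins = 0L, pathways = 0L, go_terms = 0L, homologs = 0L)
  high <- 0L
  if (length(selected) > 0L) {
    recs <- get_snps(selected, "snp", store)
    high <- sum(recs$score >= 20L)
    genes <- unique(recs$gene_id[!is.na(recs$gene_id)])
    counts[["genes"]] <- length(genes)
    if (length(genes) > 0L) {
      gid <- as.character(genes)
      counts[["proteins"]] <- n_distinct_acc(get_annotations(gid, "gene", "protein", store))
      counts[["pathways"]] <- n_distinct_acc(get_annotations(gid, "gene", "kegg", store))
      counts[["go_terms"]] <- n_distinct_acc(get_annotations(gid, "gene", "go", store))
      hom <- get_annotations(gid, "gene", "homolog", store, species = homolog_species)
      counts[["homologs"]] <- if (nrow(hom) == 0L) 0L else
        length(unique(hom$member_gene_id))
    }
  }
  structure(list(
    criteria = criteria,
    input_snps = length(significant),
    snps_selected = selected,
    wgas_selected = length(intersect(selected, significant)),
    high_score_count = as.integer(high),
    annotation_counts = counts), class = "screen_result")
}

n_distinct_acc <- function(ann) {
  if (nrow(ann) == 0L) 0L else length(unique(ann$accession))
}

#' @export
print.screen_result <- function(x, ...) {
  cat("<screen_result> mode:", x$criteria$mode,
      " score_gt:", x$criteria$score_gt,
      if (!is.na(x$criteria$dist)) paste(" dist:", x$criteria$dist), "\n")
  cat("  selected:", length(x$snps_selected), "of", x$input_snps, "inputs;",
      x$high_score_count, "with score >= 20\n")
  cat("  distinct annotations:",
      paste(names(x$annotation_counts), x$annotation_counts, collapse = ", "), "\n")
  invisible(x)
}

#' Summarise screening runs as one table
#'
#' One row per run: SNPs meeting the criteria, GWAS-derived SNPs among them,
#' SNPs with score >= 20, then the five distinct-annotation counts.
#'
#' @param results list of `screen_result` objects.
#' @return data frame with one row per run.
#' @export
screen_summary <- function(results) {
  stopifnot(length(results) >= 1L)
  rows <- lapply(seq_along(results), function(i) {
    r <- results[[i]]
    stopifnot(inherits(r, "screen_result"))
    data.frame(
      run = i, mode = r$criteria$mode,
      snps_meeting_criteria = length(r$snps_selected),
      wgas_snps = r$wgas_selected,
      score_ge20 = r$high_score_count,
      genes = r$annotation_counts[["genes"]],
      proteins = r$annotation_counts[["proteins"]],
      pathways = r$annotation_counts[["pathways"]],
      go_terms = r$annotation_counts[["go_terms"]],
      homologs = r$annotation_counts[["homologs"]],
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the standard four-pass screen
#'
#' Convenience wrapper running all four modes with their default thresholds
#' (score > 7 for run 2; score > 11 within `dist` bp for run 3; score > 24 on
#' genes within `dist` bp for run 4).
#'
#' @inheritParams screen
#' @param dist search radius in bp for runs 3-4.
#' @param score_gt named overrides for the run thresholds, e.g.
#'   `c(run2 = 7, run3 = 11, run4 = 24)`.
#' @return list of four `screen_result` objects.
#' @export
screen_four_runs <- function(significant, store, dist = 10000L,
                             score_gt = c(run2 = 7L, run3 = 11L, run4 = 24L),
                             homolog_species = NULL) {
  crits <- list(
    screen_criteria("all_significant"),
    screen_criteria("significant_by_score", score_gt = score_gt[["run2"]]),
    screen_criteria("nearby_high_score", score_gt = score_gt[["run3"]], dist = dist),
    screen_criteria("nearby_gene_snps", score_gt = score_gt[["run4"]], dist = dist))
  lapply(crits, function(cr) screen(significant, cr, store,
                                    homolog_species = homolog_species))
}

#' Rank GWAS-significant SNPs as candidate DNA markers
#'
#' The premise: a reliable DNA marker is either itself a likely-functional SNP
#' or close enough to one to be in linkage disequilibrium with it (physical
#' distance as the LD proxy). Each significant SNP is ranked by the
#' lexicographic key (descending own score, descending best score of any other
#' database SNP within `dist` bp, ascending distance to that SNP, ascending rs
#' number). The key is a deterministic codification of that premise and is
#' deliberately pluggable: `key_fun` may replace it.
#'
#' @param significant character vector of GWAS-significant rs accessions.
#' @param store an open, scored `snp_store`.
#' @param dist search radius in bp for the nearby-SNP component.
#' @param results optional list of the four `screen_result`s over the same
#'   input list; used to annotate each SNP with the runs that supported it.
#' @param key_fun optional replacement ranking key: a function of the ranking
#'   table returning a permutation of its rows.
#' @return data frame `rank`, `snp_id`, `own_score`, `best_nearby_score`,
#'   `nearby_snp`, `nearby_distance`, `rationale`, best candidates first.
#' @export
rank_candidates <- function(significant, store, dist = 10000L, results = NULL,
                            key_fun = NULL) {
  if (!is.null(results)) {
    bad <- vapply(results, function(r) r$input_snps != length(significant), logical(1))
    if (any(bad)) stop("screen results were produced from a different input list")
  }
  own <- get_snps(significant, "snp", store)
  near <- high_score_snp(own$snp_id, min_score = -1L, max_dist = dist, store = store)
  tab <- data.frame(
    snp_id = own$snp_id,
    own_score = own$score,
    best_nearby_score = ifelse(is.na(near$score), -1L, near$score),
    nearby_snp = near$snp_id,
    nearby_distance = near$distance,
    stringsAsFactors = FALSE)

  ord <- if (is.null(key_fun)) {
    order(-tab$own_score, -tab$best_nearby_score,
          ifelse(is.na(tab$nearby_distance), Inf, tab$nearby_distance),
          rs_number(tab$snp_id))
  } else {
    key_fun(tab)
  }
  tab <- tab[ord, , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  tab$rationale <- vapply(seq_len(nrow(tab)), function(i) {
    rationale_for(tab[i, ], significant, results, dist, store)
  }, character(1))
  rownames(tab) <- NULL
  tab[, c("rank", "snp_id", "own_score", "best_nearby_score", "nearby_snp",
          "nearby_distance", "rationale")]
}

rationale_for <- function(row, significant, results, dist, store) {
  parts <- character()
  if (row$own_score >= 20L) parts <- c(parts, "own score >= 20")
  if (!is.null(results)) {
    runs <- character()
    for (i in seq_along(results)) {
      r <- results[[i]]
      sel <- r$snps_selected
      supported <- switch(r$criteria$mode,
        all_significant = row$snp_id %in% sel,
        significant_by_score = row$snp_id %in% sel,
        nearby_high_score = !is.na(row$nearby_snp) && row$nearby_snp %in% sel,
        nearby_gene_snps = !is.na(row$nearby_snp) && row$nearby_snp %in% sel)
      if (isTRUE(supported)) runs <- c(runs, paste0("run", i))
    }
    if (length(runs) > 0L) parts <- c(parts, paste("supported by", paste(runs, collapse = ",")))
  }
  if (!is.na(row$nearby_snp) && row$best_nearby_score >= 20L) {
    parts <- c(parts, sprintf("within %d bp of %s (score %d)",
                              row$nearby_distance, row$nearby_snp,
                              row$best_nearby_score))
  }
  if (length(parts) == 0L) "no supporting evidence" else paste(parts, collapse = "; ")
}
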
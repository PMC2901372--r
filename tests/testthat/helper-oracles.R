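# Independent brute-force oracles over plain data frames pulled from a store.
# These never call the query layer under test.

store_tables_df <- function(st) {
  list(snp = DBI::dbGetQuery(st$con, "SELECT * FROM snp"),
       gene = DBI::dbGetQuery(st$con, "SELECT * FROM gene"),
       qtl = DBI::dbGetQuery(st$con, "SELECT * FROM qtl"))
}

bf_gene_dist <- function(pos, start, end) {
  if (pos >= start && pos <= end) 0L else min(abs(pos - start), abs(pos - end))
}

bf_genes_by_dist <- function(snp_id, max_dist, tabs) {
  s <- tabs$snp[tabs$snp$snp_id == snp_id, ]
  g <- tabs$gene[tabs$gene$chrom == s$chrom, , drop = FALSE]
  if (nrow(g) == 0L) return(NULL)
  d <- vapply(seq_len(nrow(g)), function(i) bf_gene_dist(s$pos, g$start[i], g$end[i]),
              numeric(1))
  keep <- d <= max_dist
  if (!any(keep)) return(NULL)
  out <- data.frame(snp_id = snp_id, gene_id = g$gene_id[keep],
                    distance = as.integer(d[keep]), stringsAsFactors = FALSE)
  out[order(out$distance, out$gene_id), , drop = FALSE]
}

bf_nearest_genes <- function(snp_id, k, tabs) {
  s <- tabs$snp[tabs$snp$snp_id == snp_id, ]
  g <- tabs$gene[tabs$gene$chrom == s$chrom, , drop = FALSE]
  if (nrow(g) == 0L) return(NULL)
  d <- vapply(seq_len(nrow(g)), function(i) bf_gene_dist(s$pos, g$start[i], g$end[i]),
              numeric(1))
  ord <- order(d, g$gene_id)[seq_len(min(k, nrow(g)))]
  data.frame(target = snp_id, gene_id = g$gene_id[ord],
             distance = as.integer(d[ord]), stringsAsFactors = FALSE)
}

bf_high_score_snp <- function(snp_id, min_score, max_dist, tabs) {
  s <- tabs$snp[tabs$snp$snp_id == snp_id, ]
  cand <- tabs$snp[tabs$snp$chrom == s$chrom &
                   abs(tabs$snp$pos - s$pos) <= max_dist &
                   tabs$snp$snp_id != snp_id &
                   tabs$snp$score > min_score, , drop = FALSE]
  if (nrow(cand) == 0L) return(NA_character_)
  d <- abs(cand$pos - s$pos)
  rs <- as.numeric(sub("^rs", "", cand$snp_id))
  cand$snp_id[order(-cand$score, d, rs)][1L]
}

# brute-force screen selections, modes 2-4
bf_screen_select <- function(significant, mode, score_gt, dist, tabs) {
  sig <- tabs$snp[tabs$snp$snp_id %in% significant, , drop = FALSE]
  sel <- switch(mode,
    significant_by_score = sig$snp_id[sig$score > score_gt],
    nearby_high_score = {
      hits <- character()
      for (i in seq_len(nrow(tabs$snp))) {
        t <- tabs$snp[i, ]
        if (t$score <= score_gt || t$snp_id %in% significant) next
        same <- sig[sig$chrom == t$chrom, , drop = FALSE]
        if (nrow(same) > 0L && any(abs(t$pos - same$pos) <= dist)) {
          hits <- c(hits, t$snp_id)
        }
      }
      hits
    },
    nearby_gene_snps = {
      gids <- integer()
      for (i in seq_len(nrow(sig))) {
        g <- tabs$gene[tabs$gene$chrom == sig$chrom[i], , drop = FALSE]
        for (j in seq_len(nrow(g))) {
          if (bf_gene_dist(sig$pos[i], g$start[j], g$end[j]) <= dist) {
            gids <- c(gids, g$gene_id[j])
          }
        }
      }
      gids <- unique(gids)
      hits <- character()
      for (i in seq_len(nrow(tabs$snp))) {
        t <- tabs$snp[i, ]
        if (t$score <= score_gt) next
        g <- tabs$gene[tabs$gene$gene_id %in% gids &
                       tabs$gene$chrom == t$chrom, , drop = FALSE]
        if (nrow(g) > 0L && any(t$pos >= g$start & t$pos <= g$end)) {
          hits <- c(hits, t$snp_id)
        }
      }
      hits
    })
  sort(sel)
}
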
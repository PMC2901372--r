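#' Parameters for the synthetic toy-species fixture
#'
#' The generator emulates the statistical structure a post-GWAS screen
#' operates on: a genome of a few chromosomes carrying non-overlapping genes,
#' a SNP panel whose genic members draw a function class from a mixture, QTL
#' regions covering a fraction of each chromosome, per-gene evidence
#' annotations drawn independently per category, and a GWAS-significant SNP
#' list dominated by intergenic SNPs. `n_planted_markers` of the significant
#' SNPs are deliberately placed within `plant_dist` bp of a maximally scored
#' (26-point) SNP sitting on a fully annotated gene inside a QTL region —
#' these are the recoverable "true markers". `n_decoys` adds the confounder:
#' equally high-scoring SNPs planted next to non-marker significant SNPs.
#'
#' @param seed integer RNG seed; the whole fixture is a pure function of it.
#' @param n_chrom number of chromosomes.
#' @param chrom_len chromosome length, bp.
#' @param n_genes total genes (planted marker/decoy genes included).
#' @param n_snps total SNPs written to the SNP source (companions and
#'   significant SNPs included).
#' @param n_qtl background QTL regions.
#' @param annotation_probs named numeric: per-gene probabilities for
#'   `protein`, `go`, `kegg`, `omia`, `homolog`, and `qtl` = the approximate
#'   fraction of each chromosome covered by QTL regions (`1` covers the
#'   whole chromosome).
#' @param class_mixture named probability vector over the genic function
#'   classes, used for SNPs falling inside a gene.
#' @param n_significant size of the GWAS-significant SNP list.
#' @param n_planted_markers significant SNPs planted next to a score-26 SNP.
#' @param plant_dist maximum planting offset, bp (kept under 6,000 so that
#'   anchor and companion always sit within a 10,000 bp search radius).
#' @param n_decoys score-26 SNPs planted next to non-marker significant SNPs.
#' @return a `fixture_params` list.
#' @export
fixture_params <- function(seed = 1L, n_chrom = 3L, chrom_len = 1000000L,
                           n_genes = 60L, n_snps = 800L, n_qtl = 9L,
                           annotation_probs = c(protein = 0.5, go = 0.7,
                                                kegg = 0.5, omia = 0.3,
                                                homolog = 0.5, qtl = 0.15),
                           class_mixture = c(missense = 0, frameshift = 0,
                                             stop_gain = 0, splice_site = 0,
                                             synonymous = 0.35, utr = 0.25,
                                             intron = 0.40),
                           n_significant = 20L, n_planted_markers = 3L,
                           plant_dist = 5000L, n_decoys = 0L) {
  stopifnot(all(annotation_probs >= 0), all(annotation_probs <= 1),
            all(c("protein", "go", "kegg", "omia", "homolog", "qtl") %in%
                  names(annotation_probs)))
  stopifnot(all(names(class_mixture) %in% genic_classes()),
            sum(class_mixture) > 0)
  stopifnot(n_chrom >= 1L, chrom_len >= 100000L, n_genes >= 1L, n_qtl >= 0L,
            n_significant >= 1L, n_planted_markers >= 0L, n_decoys >= 0L,
            n_planted_markers <= n_significant,
            plant_dist >= 200L, plant_dist <= 6000L)
  n_zones <- n_planted_markers + n_decoys
  if (n_decoys > n_significant - n_planted_markers) {
    stop("n_decoys exceeds the number of non-marker significant SNPs")
  }
  if (n_genes <= n_zones) stop("infeasible geometry: n_genes must exceed planted zones")
  if (n_snps < n_significant + n_zones + 1L) {
    stop("n_snps too small to hold significant and planted SNPs")
  }
  structure(list(seed = as.integer(seed), n_chrom = as.integer(n_chrom),
                 chrom_len = as.integer(chrom_len), n_genes = as.integer(n_genes),
                 n_snps = as.integer(n_snps), n_qtl = as.integer(n_qtl),
                 annotation_probs = annotation_probs,
                 class_mixture = class_mixture / sum(class_mixture),
                 n_significant = as.integer(n_significant),
                 n_planted_markers = as.integer(n_planted_markers),
                 plant_dist = as.integer(plant_dist),
                 n_decoys = as.integer(n_decoys)),
            class = "fixture_params")
}

#' Paper-scale fixture parameters
#'
#' The default screening study scale: 165 GWAS-significant SNPs, 8 of them
#' planted markers, all significant SNPs intergenic (the regime where over
#' 90% of significant SNPs do not fall on genes), with a 10,000 bp search
#' context.
#'
#' @param seed integer RNG seed.
#' @param n_decoys decoy high-score SNPs added next to non-markers.
#' @return a `fixture_params` list.
#' @export
default_paper_fixture <- function(seed = 1L, n_decoys = 0L) {
  fixture_params(seed = seed, n_chrom = 3L, chrom_len = 1000000L,
                 n_genes = 60L, n_snps = 800L, n_qtl = 9L,
                 n_significant = 165L, n_planted_markers = 8L,
                 plant_dist = 5000L, n_decoys = n_decoys)
}

ZONE_SPAN <- 30000L
NEAR_GENE_WINDOW <- 2000L

#' Generate the complete toy-species source-file set
#'
#' Writes all eight source dialect files, the species INI configuration, the
#' significant SNP list, the planted-marker list and a truth table giving
#' every SNP's expected score breakdown — computed here by direct bookkeeping
#' over the generated annotations, independently of the store scoring path.
#' The same seed always reproduces byte-identical files.
#'
#' Layout: the lower ~55% of each chromosome holds background genes, SNPs and
#' QTL regions; planted marker/decoy zones occupy the upper part, spaced
#' `30,000` bp apart, so no background high-score SNP can sit within the
#' search radius of a planted anchor.
#'
#' @param p a [fixture_params()] object.
#' @param outdir output directory (created if missing).
#' @return invisibly, a list with the parameter set, file paths, and in-memory
#'   copies of the generated tables (`genes`, `snps` (truth table), `qtl`,
#'   annotation tables, `significant`, `planted_markers`).
#' @export
generate_fixture <- function(p, outdir) {
  stopifnot(inherits(p, "fixture_params"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  set.seed(p$seed)

  chroms <- paste0("chr", seq_len(p$n_chrom))
  bg_end <- as.integer(floor(p$chrom_len * 0.55))
  zone_base <- as.integer(floor(p$chrom_len * 0.60))
  n_zones <- p$n_planted_markers + p$n_decoys
  zones_per_chrom <- if (n_zones == 0L) 0L else ceiling(n_zones / p$n_chrom)
  if (zone_base + zones_per_chrom * ZONE_SPAN > p$chrom_len) {
    stop("infeasible geometry: planted zones do not fit on the chromosomes")
  }

  # --- planted zones: fully annotated gene + score-26 companion + QTL ------
  zone <- function(j) {
    ci <- ((j - 1L) %% p$n_chrom) + 1L
    slot <- (j - 1L) %/% p$n_chrom
    lo <- zone_base + slot * ZONE_SPAN + 1L
    gstart <- lo + 10000L
    gend <- gstart + 3999L
    companion_pos <- gstart + sample.int(4000L, 1L) - 1L
    anchor_pos <- gend + sample(200:p$plant_dist, 1L)
    list(chrom = chroms[[ci]], qtl_start = lo, qtl_end = lo + ZONE_SPAN - 1L,
         gstart = gstart, gend = gend, companion_pos = companion_pos,
         anchor_pos = anchor_pos)
  }
  zones <- lapply(seq_len(n_zones), zone)

  # --- genes ----------------------------------------------------------------
  planted_genes <- if (n_zones > 0L) {
    data.frame(gene_id = seq_len(n_zones),
               symbol = sprintf("PGENE%d", seq_len(n_zones)),
               chrom = vapply(zones, `[[`, character(1), "chrom"),
               start = vapply(zones, `[[`, numeric(1), "gstart"),
               end = vapply(zones, `[[`, numeric(1), "gend"),
               strand = sample(c("+", "-"), n_zones, replace = TRUE),
               stringsAsFactors = FALSE)
  } else {
    data.frame(gene_id = integer(), symbol = character(), chrom = character(),
               start = numeric(), end = numeric(), strand = character(),
               stringsAsFactors = FALSE)
  }

  n_bg_genes <- p$n_genes - n_zones
  per_chrom <- tabulate(((seq_len(n_bg_genes) - 1L) %% p$n_chrom) + 1L, p$n_chrom)
  bg_genes <- do.call(rbind, lapply(seq_len(p$n_chrom), function(ci) {
    n <- per_chrom[[ci]]
    if (n == 0L) return(NULL)
    lens <- sample(2000:8000, n, replace = TRUE)
    free <- bg_end - sum(lens)
    if (free < n) stop("infeasible geometry: genes cannot fit without overlap")
    offs <- sort(sample.int(free, n))
    starts <- offs + c(0L, cumsum(lens))[seq_len(n)]
    data.frame(chrom = chroms[[ci]], start = starts, end = starts + lens - 1L,
               stringsAsFactors = FALSE)
  }))
  if (!is.null(bg_genes) && nrow(bg_genes) > 0L) {
    bg_genes <- data.frame(gene_id = n_zones + seq_len(nrow(bg_genes)),
                           symbol = sprintf("GENE%d", n_zones + seq_len(nrow(bg_genes))),
                           chrom = bg_genes$chrom, start = bg_genes$start,
                           end = bg_genes$end,
                           strand = sample(c("+", "-"), nrow(bg_genes), replace = TRUE),
                           stringsAsFactors = FALSE)
    genes <- rbind(planted_genes, bg_genes)
  } else {
    genes <- planted_genes
  }

  # --- per-gene evidence annotations ---------------------------------------
  probs <- p$annotation_probs
  planted_flag <- genes$gene_id <= n_zones
  has <- function(cat) planted_flag | (stats::runif(nrow(genes)) < probs[[cat]])
  gene_has <- data.frame(gene_id = genes$gene_id,
                         protein = has("protein"), go = has("go"),
                         kegg = has("kegg"), omia = has("omia"),
                         homolog = has("homolog"))

  protein <- data.frame(gene_id = genes$gene_id[gene_has$protein],
                        accession = sprintf("Q%05d", genes$gene_id[gene_has$protein]),
                        stringsAsFactors = FALSE)
  go <- do.call(rbind, lapply(genes$gene_id[gene_has$go], function(g) {
    acc <- sprintf("GO:%07d", sample.int(300L, sample(1:3, 1L)))
    data.frame(gene_id = g, accession = acc,
               term = sprintf("toy process %s", sub("GO:", "", acc)),
               stringsAsFactors = FALSE)
  }))
  if (is.null(go)) go <- data.frame(gene_id = integer(), accession = character(),
                                    term = character(), stringsAsFactors = FALSE)
  kegg <- data.frame(gene_id = genes$gene_id[gene_has$kegg],
                     accession = sprintf("path:toy%05d",
                                         sample.int(40L, sum(gene_has$kegg), replace = TRUE)),
                     stringsAsFactors = FALSE)
  kegg$pathway <- sprintf("toy pathway %s", sub("path:toy", "", kegg$accession))
  omia <- data.frame(gene_id = genes$gene_id[gene_has$omia],
                     accession = sprintf("OMIA:%06d",
                                         sample.int(120L, sum(gene_has$omia), replace = TRUE)),
                     stringsAsFactors = FALSE)
  omia$phenotype <- sprintf("toy trait %s", sub("OMIA:", "", omia$accession))
  hom_genes <- genes$gene_id[gene_has$homolog]
  homolog <- do.call(rbind, lapply(hom_genes, function(g) {
    data.frame(group_id = sprintf("HG%d", g),
               species = c("toyspecies", "homo_sapiens"),
               gene_id = c(g, 1000000L + g), stringsAsFactors = FALSE)
  }))
  if (is.null(homolog)) homolog <- data.frame(group_id = character(),
                                              species = character(),
                                              gene_id = integer(),
                                              stringsAsFactors = FALSE)

  # --- QTL regions ----------------------------------------------------------
  qtl_frac <- probs[["qtl"]]
  planted_qtl <- if (n_zones > 0L) {
    data.frame(qtl_id = sprintf("QTL:P%d", seq_len(n_zones)),
               chrom = vapply(zones, `[[`, character(1), "chrom"),
               start = vapply(zones, `[[`, numeric(1), "qtl_start"),
               end = vapply(zones, `[[`, numeric(1), "qtl_end"),
               trait = sprintf("planted trait %d", seq_len(n_zones)),
               stringsAsFactors = FALSE)
  } else NULL
  bg_qtl <- NULL
  if (qtl_frac >= 1) {
    bg_qtl <- data.frame(qtl_id = sprintf("QTL:C%d", seq_len(p$n_chrom)),
                         chrom = chroms, start = 1L, end = p$chrom_len,
                         trait = sprintf("whole chromosome trait %d", seq_len(p$n_chrom)),
                         stringsAsFactors = FALSE)
  } else if (p$n_qtl > 0L && qtl_frac > 0) {
    per <- tabulate(((seq_len(p$n_qtl) - 1L) %% p$n_chrom) + 1L, p$n_chrom)
    len <- pmax(1000L, as.integer(floor(qtl_frac * bg_end / pmax(per, 1L))))
    bg_qtl <- do.call(rbind, lapply(seq_len(p$n_chrom), function(ci) {
      n <- per[[ci]]
      if (n == 0L) return(NULL)
      starts <- sample.int(bg_end - len[[ci]], n)
      data.frame(qtl_id = sprintf("QTL:B%d_%d", ci, seq_len(n)),
                 chrom = chroms[[ci]], start = starts,
                 end = starts + len[[ci]] - 1L,
                 trait = sprintf("background trait %d.%d", ci, seq_len(n)),
                 stringsAsFactors = FALSE)
    }))
  }
  qtl <- rbind(planted_qtl, bg_qtl)
  if (is.null(qtl)) qtl <- data.frame(qtl_id = character(), chrom = character(),
                                      start = numeric(), end = numeric(),
                                      trait = character(), stringsAsFactors = FALSE)

  # --- SNPs -----------------------------------------------------------------
  allele_pool <- c("A/C", "A/G", "A/T", "C/G", "C/T", "G/T")
  snp_rows <- list()
  add_snp <- function(chrom, pos, fc, gene_id, role) {
    snp_rows[[length(snp_rows) + 1L]] <<- data.frame(
      chrom = chrom, pos = as.integer(pos), function_class = fc,
      gene_id = if (is.na(gene_id)) NA_integer_ else as.integer(gene_id),
      role = role, stringsAsFactors = FALSE)
  }

  for (j in seq_len(n_zones)) {
    z <- zones[[j]]
    role <- if (j <= p$n_planted_markers) "companion_marker" else "companion_decoy"
    add_snp(z$chrom, z$companion_pos, "missense", j, role)
  }
  for (j in seq_len(p$n_planted_markers)) {
    z <- zones[[j]]
    add_snp(z$chrom, z$anchor_pos, "intergenic", NA, "marker")
  }
  if (p$n_decoys > 0L) {
    for (j in (p$n_planted_markers + seq_len(p$n_decoys))) {
      z <- zones[[j]]
      add_snp(z$chrom, z$anchor_pos, "intergenic", NA, "decoyed_significant")
    }
  }

  # intergenic significant SNPs in the background region, clear of genes
  n_other_sig <- p$n_significant - p$n_planted_markers - p$n_decoys
  sig_placed <- 0L
  while (sig_placed < n_other_sig) {
    ci <- sample.int(p$n_chrom, 1L)
    pos <- sample.int(bg_end, 1L)
    g <- genes[genes$chrom == chroms[[ci]], , drop = FALSE]
    near <- any(pos >= g$start - NEAR_GENE_WINDOW & pos <= g$end + NEAR_GENE_WINDOW)
    if (near) next
    add_snp(chroms[[ci]], pos, "intergenic", NA, "significant")
    sig_placed <- sig_placed + 1L
  }

  # background panel SNPs
  mix <- p$class_mixture
  n_bg_snps <- p$n_snps - n_zones - p$n_planted_markers - p$n_decoys - n_other_sig
  for (i in seq_len(n_bg_snps)) {
    ci <- sample.int(p$n_chrom, 1L)
    pos <- sample.int(bg_end, 1L)
    ch <- chroms[[ci]]
    g <- genes[genes$chrom == ch, , drop = FALSE]
    inside <- which(pos >= g$start & pos <= g$end)
    if (length(inside) > 0L) {
      fc <- sample(names(mix), 1L, prob = mix)
      add_snp(ch, pos, fc, g$gene_id[[inside[[1L]]]], "background")
    } else {
      near <- which(pos >= g$start - NEAR_GENE_WINDOW & pos <= g$end + NEAR_GENE_WINDOW)
      if (length(near) > 0L && stats::runif(1) < 0.5) {
        add_snp(ch, pos, "near_gene", g$gene_id[[near[[1L]]]], "background")
      } else {
        add_snp(ch, pos, "intergenic", NA, "background")
      }
    }
  }

  snps <- do.call(rbind, snp_rows)
  snps <- snps[order(match(snps$chrom, chroms), snps$pos, snps$role), , drop = FALSE]
  snps$snp_id <- sprintf("rs%07d", seq_len(nrow(snps)) + 1000000L)
  snps$alleles <- sample(allele_pool, nrow(snps), replace = TRUE)

  # --- truth table: score breakdown by direct bookkeeping -------------------
  in_any_qtl <- function(ch, pos) {
    q <- qtl[qtl$chrom == ch, , drop = FALSE]
    any(pos >= q$start & pos <= q$end)
  }
  snps$in_qtl <- mapply(in_any_qtl, snps$chrom, snps$pos)
  for (cat in c("protein", "go", "kegg", "omia", "homolog")) {
    linked <- gene_has$gene_id[gene_has[[cat]]]
    snps[[paste0("has_", cat)]] <- !is.na(snps$gene_id) & snps$gene_id %in% linked
  }
  snps$class_component <- class_score(snps$function_class)
  flagcols <- c("in_qtl", "has_protein", "has_go", "has_kegg", "has_omia", "has_homolog")
  snps$total <- snps$class_component + as.integer(rowSums(snps[, flagcols]))

  significant <- sort_rs(snps$snp_id[snps$role %in%
    c("marker", "decoyed_significant", "significant")])
  planted_markers <- sort_rs(snps$snp_id[snps$role == "marker"])

  # --- write dialect files --------------------------------------------------
  fp <- function(name) file.path(outdir, name)
  wl <- function(lines, name) writeLines(lines, fp(name), useBytes = TRUE)

  wl(sprintf("%s\t%s\t%d\t%s\t%s\t%s", snps$snp_id, snps$chrom, snps$pos,
             snps$alleles, snps$function_class,
             ifelse(is.na(snps$gene_id), ".", as.character(snps$gene_id))),
     "snp.tsv")
  wl(sprintf("%d\t%s\t%s\t%d\t%d\t%s", genes$gene_id, genes$symbol, genes$chrom,
             as.integer(genes$start), as.integer(genes$end), genes$strand),
     "gene.tsv")
  sym <- genes$symbol[match(go$gene_id, genes$gene_id)]
  wl(c("!gaf-version: 2.1",
       sprintf("TOY\t%d\t%s\t\t%s\tTOY:ref\tIEA\t\tP\t%s\t\t\t\t\t\t\t",
               go$gene_id, sym, go$accession, go$term)),
     "go.gaf")
  wl(sprintf("%d\t%s\t%s", kegg$gene_id, kegg$accession, kegg$pathway), "kegg.tsv")
  wl(sprintf("%d\t%s", protein$gene_id, protein$accession), "uniprot.tsv")
  wl(c("##gff-version 3",
       sprintf("%s\tQTLdb\tQTL\t%d\t%d\t.\t.\t.\tID=%s;Name=%s", qtl$chrom,
               as.integer(qtl$start), as.integer(qtl$end), qtl$qtl_id, qtl$trait)),
     "qtl.gff3")
  wl(sprintf("%d\t%s\t%s", omia$gene_id, omia$accession, omia$phenotype), "omia.tsv")
  wl(sprintf("%s\t%s\t%d", homolog$group_id, homolog$species, homolog$gene_id),
     "homologene.tsv")

  ini <- c("[species]", "name = toyspecies", "")
  for (s in SOURCE_NAMES) {
    loc <- switch(s, snp = "snp.tsv", gene = "gene.tsv", go = "go.gaf",
                  kegg = "kegg.tsv", uniprot = "uniprot.tsv", qtl = "qtl.gff3",
                  omia = "omia.tsv", homologene = "homologene.tsv")
    ini <- c(ini, sprintf("[%s]", s), sprintf("location = %s", loc), "")
  }
  wl(ini, "toyspecies.ini")

  truth_cols <- c("snp_id", "chrom", "pos", "alleles", "function_class",
                  "gene_id", "role", flagcols, "class_component", "total")
  truth <- snps[, truth_cols]
  utils::write.table(truth, fp("truth_snps.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  wl(significant, "significant.txt")
  wl(planted_markers, "planted_markers.txt")

  invisible(list(
    params = p, dir = outdir, config = fp("toyspecies.ini"),
    files = stats::setNames(
      file.path(outdir, c("snp.tsv", "gene.tsv", "go.gaf", "kegg.tsv",
                          "uniprot.tsv", "qtl.gff3", "omia.tsv",
                          "homologene.tsv")),
      c("snp", "gene", "go", "kegg", "uniprot", "qtl", "omia", "homologene")),
    genes = genes, snps = truth, qtl = qtl,
    annotations = list(protein = protein, go = go, kegg = kegg, omia = omia,
                       homolog = homolog),
    significant = significant, planted_markers = planted_markers))
}
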
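## Annotation module: gene proximity around significant SNPs, chromosomal
## distribution summaries with top-5% tallies, and GO-term
## over-representation by one-sided Fisher's exact test with Bonferroni
## correction.

#' Load gene features from a GFF3 file
#'
#' Parses via `rtracklayer` and keeps `gene`-type features only
#' (mRNA/exon/CDS children are skipped). Coordinates stay 1-based closed.
#'
#' @param path Path to a GFF3 file.
#' @return Data frame: gene_id, chrom, start, end, strand, product.
#' @export
load_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[S4Vectors::mcols(gr)$type == "gene"]
  mc <- S4Vectors::mcols(gr)
  ids <- if ("ID" %in% names(mc)) as.character(mc$ID) else
    sprintf("gene_%d", seq_along(gr))
  prod <- if ("product" %in% names(mc)) as.character(mc$product) else
    rep(NA_character_, length(gr))
  data.frame(
    gene_id = ids,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    product = prod,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Genes within a window around SNPs
#'
#' For each SNP, every gene whose interval intersects
#' `[pos - half_window, pos + half_window]` (both ends inclusive; i.e. a
#' nearest-edge distance of at most `half_window`). The distance is 0 for
#' SNPs inside the gene, otherwise the distance to the nearest gene edge;
#' the side is reported relative to gene coordinates.
#'
#' @param snps Data frame with snp_id, chrom, pos.
#' @param features Gene features as from [load_gff3()].
#' @param half_window Window half-width in bp (default 25,000, i.e. a
#'   50 kb total window).
#' @return Data frame: snp_id, gene_id, product, distance, side
#'   ("upstream" = gene left of the SNP, "inside", "downstream").
#'   Zero-row result when no gene is in range.
#' @export
genes_near_snp <- function(snps, features, half_window = 25000) {
  empty <- data.frame(snp_id = character(0), gene_id = character(0),
                      product = character(0), distance = numeric(0),
                      side = character(0), stringsAsFactors = FALSE)
  if (!nrow(snps) || !nrow(features)) return(empty)
  snp_gr <- GenomicRanges::GRanges(
    snps$chrom,
    IRanges::IRanges(pmax(1, snps$pos - half_window), snps$pos + half_window)
  )
  gene_gr <- GenomicRanges::GRanges(
    features$chrom, IRanges::IRanges(features$start, features$end)
  )
  ov <- suppressWarnings(
    GenomicRanges::findOverlaps(snp_gr, gene_gr, ignore.strand = TRUE)
  )
  if (!length(ov)) return(empty)
  si <- S4Vectors::queryHits(ov)
  gi <- S4Vectors::subjectHits(ov)
  pos <- snps$pos[si]
  s <- features$start[gi]; e <- features$end[gi]
  inside <- pos >= s & pos <= e
  dist <- ifelse(inside, 0, pmin(abs(pos - s), abs(pos - e)))
  side <- ifelse(inside, "inside", ifelse(e < pos, "upstream", "downstream"))
  keep <- dist <= half_window
  out <- data.frame(
    snp_id = snps$snp_id[si], gene_id = features$gene_id[gi],
    product = features$product[gi], distance = dist, side = side,
    stringsAsFactors = FALSE
  )[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-chromosome distribution of significant SNPs with top-5% tallies
#'
#' Counts significant SNPs per chromosome and display category, flags the
#' globally most significant `top_fraction` (ceiling count, ranked by p),
#' and tallies the flagged SNPs per chromosome split into chemical vs
#' non-chemical.
#'
#' @param hits Data frame with snp_id, chrom, p and a display `category`
#'   column.
#' @param category_major Named character vector mapping display category
#'   to "chemical"/"non-chemical"; unmapped categories count as
#'   non-chemical.
#' @param top_fraction Fraction flagged as most significant (default
#'   0.05).
#' @return List: `by_chromosome` (chrom x category count table as a data
#'   frame), `top` (the flagged rows), `top_tally` (per-chromosome
#'   chemical / non-chemical counts among the flagged).
#' @export
chromosome_summary <- function(hits, category_major = NULL,
                               top_fraction = 0.05) {
  if (!nrow(hits)) {
    return(list(by_chromosome = data.frame(),
                top = hits, top_tally = data.frame()))
  }
  tab <- as.data.frame.matrix(table(hits$chrom, hits$category))
  tab <- cbind(chrom = rownames(tab), tab, stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  n_top <- as.integer(ceiling(top_fraction * nrow(hits)))
  ord <- order(hits$p, hits$snp_id, method = "radix")
  top <- hits[ord[seq_len(n_top)], , drop = FALSE]
  major <- function(cat) {
    m <- if (!is.null(category_major)) unname(category_major[cat]) else
      rep(NA_character_, length(cat))
    ifelse(is.na(m), "non-chemical", m)
  }
  top_major <- major(top$category)
  tt <- as.data.frame.matrix(
    table(factor(top$chrom, levels = sort(unique(hits$chrom))),
          factor(top_major, levels = c("chemical", "non-chemical")))
  )
  tt <- cbind(chrom = rownames(tt), tt, stringsAsFactors = FALSE)
  rownames(tt) <- NULL
  rownames(top) <- NULL
  list(by_chromosome = tab, top = top, top_tally = tt)
}

#' GO-term over-representation in a gene list
#'
#' One-sided Fisher's exact test (hypergeometric upper tail) per term on
#' the 2x2 in-list x has-term table, Bonferroni-corrected over the terms
#' with at least one list gene. A term is flagged when its corrected p is
#' at most `alpha` and its fold enrichment (list proportion over
#' background proportion) is at least `min_fold`.
#'
#' @param gene_list Character vector of genes of interest (must be a
#'   subset of `background`).
#' @param background Character vector of all candidate genes.
#' @param term_map Data frame with columns `gene_id`, `term_id` (one row
#'   per gene-term assignment).
#' @param min_fold Minimum fold enrichment to flag (default 2).
#' @param alpha Corrected-p cutoff to flag (default 0.05).
#' @return Data frame: term_id, genes_in_list, genes_in_background,
#'   fold_enrichment, p_raw, p_bonferroni, flagged — one row per term
#'   present in the background, sorted by p_raw.
#' @export
go_overrepresentation <- function(gene_list, background, term_map,
                                  min_fold = 2, alpha = 0.05) {
  if (!length(background)) stopf("empty background gene set")
  if (!nrow(term_map)) stopf("empty gene-to-term map")
  if (length(setdiff(gene_list, background))) {
    stopf("gene_list contains genes absent from the background")
  }
  gene_list <- unique(gene_list)
  background <- unique(background)
  tm <- term_map[term_map$gene_id %in% background, , drop = FALSE]
  tm <- unique(tm[, c("gene_id", "term_id")])
  n <- length(gene_list)
  N <- length(background)
  terms <- sort(unique(tm$term_id))
  k <- vapply(terms, function(t)
    sum(tm$gene_id[tm$term_id == t] %in% gene_list), 0L)
  K <- as.integer(table(factor(tm$term_id, levels = terms)))
  ## hypergeometric upper tail P(X >= k)
  p_raw <- phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  n_tested <- sum(k >= 1L)
  p_bonf <- ifelse(k >= 1L, pmin(1, p_raw * n_tested), 1)
  fold <- (k / n) / (K / N)
  out <- data.frame(
    term_id = terms, genes_in_list = k, genes_in_background = K,
    fold_enrichment = fold, p_raw = p_raw, p_bonferroni = p_bonf,
    flagged = k >= 1L & p_bonf <= alpha & fold >= min_fold,
    stringsAsFactors = FALSE, row.names = NULL
  )
  out[order(out$p_raw, out$term_id), , drop = FALSE]
}

#' Load a two-column gene-to-term map
#'
#' @param path Tab-separated file with columns gene_id, term_id (header
#'   optional if the columns are in that order).
#' @return Data frame with gene_id, term_id.
#' @export
load_term_map <- function(path) {
  tm <- read.delim(path, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE)
  if (!all(c("gene_id", "term_id") %in% names(tm))) {
    if (ncol(tm) >= 2) {
      tm <- read.delim(path, sep = "\t", header = FALSE,
                       stringsAsFactors = FALSE)[, 1:2]
      names(tm) <- c("gene_id", "term_id")
    } else {
      stopf("%s: expected two tab-separated columns gene_id, term_id", path)
    }
  }
  tm
}
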
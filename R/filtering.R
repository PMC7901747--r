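## Variant-filtering module: VCF ingestion, bi-allelic SNP selection,
## hard filters on site-quality annotations, and sliding-window LD
## pruning on pairwise genotype r-squared.

#' Hard-filter and LD-pruning configuration
#'
#' Defaults are the screening thresholds for amplicon-derived SNP panels:
#' a site fails when any *present* annotation violates QD < 20, FS > 60,
#' MQ < 45, MQRankSum < -0.2, ReadPosRankSum < -1.0 or SOR > 2.0 (strict
#' inequalities: a site exactly at a threshold passes). Pruning removes
#' one SNP of every pair with r^2 > `r2_max` within sliding windows of
#' `window_size` SNPs advanced by `window_step`.
#'
#' @param qd_min,fs_max,mq_min,mqranksum_min,readposranksum_min,sor_max
#'   Hard-filter thresholds.
#' @param r2_max Maximum tolerated pairwise squared genotype correlation.
#' @param window_size Window width in SNPs.
#' @param window_step Window increment in SNPs (must be <= window_size).
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(qd_min = 20, fs_max = 60, mq_min = 45,
                          mqranksum_min = -0.2, readposranksum_min = -1,
                          sor_max = 2, r2_max = 0.5,
                          window_size = 50, window_step = 10) {
  if (window_step > window_size) stopf("window_step must be <= window_size")
  if (r2_max < 0 || r2_max > 1) stopf("r2_max must be in [0, 1]")
  structure(list(
    qd_min = qd_min, fs_max = fs_max, mq_min = mq_min,
    mqranksum_min = mqranksum_min, readposranksum_min = readposranksum_min,
    sor_max = sor_max, r2_max = r2_max,
    window_size = as.integer(window_size),
    window_step = as.integer(window_step)
  ), class = "filter_config")
}

#' Read a multi-sample VCF into a genotype panel
#'
#' Parses via `vcfR`, converts unphased or phased diploid GT calls into
#' alternate-allele dosages in {0, 1, 2, NA}, and extracts the
#' QD/FS/MQ/MQRankSum/ReadPosRankSum/SOR INFO annotations (absent keys
#' stay `NA` and never fail a filter). Input must be coordinate-sorted
#' within chromosome; unsorted input is an error, not a silent sort.
#'
#' @param path Path to a VCF (v4.x, plain or bgzipped).
#' @return A `genotype_panel` (no `truth` component).
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stopf("VCF not found: %s", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (!nrow(fix)) stopf("%s: no variant records", path)
  pos <- as.integer(fix$POS)
  unsorted <- unlist(tapply(pos, factor(fix$CHROM, levels = unique(fix$CHROM)),
                            function(p) diff(p) < 0), use.names = FALSE)
  if (any(unsorted)) {
    stopf("%s: records not coordinate-sorted within chromosome", path)
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  ## map GT strings to dosages; anything else (half-calls etc.) -> NA
  map <- c("0/0" = 0L, "0|0" = 0L, "0/1" = 1L, "1/0" = 1L,
           "0|1" = 1L, "1|0" = 1L, "1/1" = 2L, "1|1" = 2L)
  dosage <- matrix(map[gt], nrow = nrow(gt), dimnames = dimnames(gt))
  dosage <- t(dosage) # strains x variants
  keys <- c("QD", "FS", "MQ", "MQRankSum", "ReadPosRankSum", "SOR")
  info <- lapply(keys, function(k) {
    suppressWarnings(vcfR::extract.info(v, element = k, as.numeric = TRUE))
  })
  names(info) <- keys
  ids <- fix$ID
  auto <- paste0(fix$CHROM, "_", pos)
  ids[is.na(ids) | ids == "."] <- auto[is.na(ids) | ids == "."]
  variants <- data.frame(
    snp_id = ids, chrom = fix$CHROM, pos = pos,
    ref = fix$REF, alt = fix$ALT,
    QD = info$QD, FS = info$FS, MQ = info$MQ,
    MQRankSum = info$MQRankSum, ReadPosRankSum = info$ReadPosRankSum,
    SOR = info$SOR, stringsAsFactors = FALSE, row.names = NULL
  )
  colnames(dosage) <- variants$snp_id
  structure(
    list(dosage = dosage, truth = NULL, variants = variants,
         strains = rownames(dosage), config = NULL),
    class = "genotype_panel"
  )
}

#' Subset a genotype panel to selected variants
#'
#' @param panel A `genotype_panel`.
#' @param keep Logical or integer index over variants.
#' @return The subset panel.
#' @export
subset_panel <- function(panel, keep) {
  panel$variants <- panel$variants[keep, , drop = FALSE]
  rownames(panel$variants) <- NULL
  panel$dosage <- panel$dosage[, keep, drop = FALSE]
  if (!is.null(panel$truth)) panel$truth <- panel$truth[, keep, drop = FALSE]
  panel
}

#' Retain bi-allelic SNPs only
#'
#' Keeps records with exactly one alternate allele and single-base REF and
#' ALT; multi-allelic sites and indels are removed. The removal count is
#' recorded as attribute `"n_removed"`.
#'
#' @param panel A `genotype_panel`.
#' @return The filtered panel.
#' @export
filter_biallelic_snps <- function(panel) {
  v <- panel$variants
  keep <- !grepl(",", v$alt, fixed = TRUE) &
    nchar(v$ref) == 1L & nchar(v$alt) == 1L &
    v$ref %in% c("A", "C", "G", "T") & v$alt %in% c("A", "C", "G", "T")
  out <- subset_panel(panel, keep)
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Apply per-site hard filters
#'
#' A record is removed iff any *present* annotation violates its
#' threshold; absent annotations (e.g. rank sums at sites with no
#' heterozygotes) never cause removal. Per-criterion removal counts are
#' recorded as attribute `"removal_counts"`.
#'
#' @param panel A `genotype_panel` of bi-allelic SNPs.
#' @param config A [filter_config()].
#' @return The filtered panel.
#' @export
apply_hard_filters <- function(panel, config = filter_config()) {
  v <- panel$variants
  viol <- cbind(
    QD = !is.na(v$QD) & v$QD < config$qd_min,
    FS = !is.na(v$FS) & v$FS > config$fs_max,
    MQ = !is.na(v$MQ) & v$MQ < config$mq_min,
    MQRankSum = !is.na(v$MQRankSum) & v$MQRankSum < config$mqranksum_min,
    ReadPosRankSum = !is.na(v$ReadPosRankSum) &
      v$ReadPosRankSum < config$readposranksum_min,
    SOR = !is.na(v$SOR) & v$SOR > config$sor_max
  )
  keep <- rowSums(viol) == 0L
  out <- subset_panel(panel, keep)
  attr(out, "removal_counts") <- colSums(viol)
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Pairwise squared genotype correlation between two SNPs
#'
#' The square of the Pearson correlation between dosage vectors over the
#' strains non-missing at both sites. Returns `NA` when either site is
#' monomorphic over the shared strains (such pairs are treated as
#' unlinked by the pruner).
#'
#' @param a,b Dosage vectors over the same strain panel.
#' @return Squared correlation in \[0, 1\], or `NA`.
#' @export
genotype_r2 <- function(a, b) {
  if (length(a) != length(b)) stopf("dosage vectors differ in length")
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 2) stopf("fewer than 2 shared non-missing strains")
  x <- a[ok]; y <- b[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  cor(x, y)^2
}

#' LD-prune a panel with sliding windows on r-squared
#'
#' Per chromosome, windows of `window_size` SNPs advance by `window_step`;
#' within each window, pairs of surviving SNPs are scanned in coordinate
#' order and for any pair with r^2 > `r2_max` one SNP is removed: the one
#' with the smaller minor-allele frequency (computed from observed
#' dosages), ties removing the later coordinate. After the final window
#' no surviving pair within any window position exceeds `r2_max`. Pairs
#' with undefined r^2 (monomorphic on the shared strains) are unlinked.
#'
#' @param panel A coordinate-sorted `genotype_panel` of bi-allelic SNPs.
#' @param config A [filter_config()].
#' @return The pruned panel; attribute `"prune_report"` is a data frame
#'   (snp_id, partner_snp, r2) of removals.
#' @export
ld_prune <- function(panel, config = filter_config()) {
  v <- panel$variants
  d <- panel$dosage
  m <- nrow(v)
  if (m == 0) return(panel)
  af <- colMeans(d, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  removed <- logical(m)
  report <- list()
  for (ch in unique(v$chrom)) {
    idx <- which(v$chrom == ch)
    k <- length(idx)
    starts <- seq(1L, k, by = config$window_step)
    for (s in starts) {
      win <- idx[seq.int(s, min(s + config$window_size - 1L, k))]
      if (length(win) < 2) next
      alive <- win[!removed[win]]
      if (length(alive) < 2) next
      cm <- suppressWarnings(
        cor(d[, alive, drop = FALSE], use = "pairwise.complete.obs")
      )
      for (ii in seq_len(length(alive) - 1L)) {
        i <- alive[ii]
        if (removed[i]) next
        for (jj in seq.int(ii + 1L, length(alive))) {
          j <- alive[jj]
          if (removed[j]) next
          r2 <- cm[ii, jj]^2
          if (is.na(r2) || r2 <= config$r2_max) next
          drop <- if (is.na(maf[i]) || is.na(maf[j])) j
            else if (maf[i] < maf[j]) i
            else if (maf[j] < maf[i]) j
            else j # equal MAF: remove the later coordinate
          keep_one <- if (drop == i) j else i
          removed[drop] <- TRUE
          report[[length(report) + 1L]] <- data.frame(
            snp_id = v$snp_id[drop], partner_snp = v$snp_id[keep_one],
            r2 = r2, stringsAsFactors = FALSE
          )
          if (drop == i) break # i is gone; move to next i
        }
      }
    }
  }
  out <- subset_panel(panel, !removed)
  attr(out, "prune_report") <- if (length(report)) do.call(rbind, report) else
    data.frame(snp_id = character(0), partner_snp = character(0),
               r2 = numeric(0))
  attr(out, "n_removed") <- sum(removed)
  out
}
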
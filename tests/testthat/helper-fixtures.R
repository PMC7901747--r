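## Shared fixtures and independent oracles, built in code at test time.

## Construct a minimal genotype_panel from an explicit dosage matrix.
make_panel <- function(dosage, chrom = NULL, pos = NULL, truth = NULL) {
  n <- nrow(dosage); m <- ncol(dosage)
  chrom <- chrom %||% rep("chr1", m)
  pos <- pos %||% seq(1000L, by = 1000L, length.out = m)
  strains <- sprintf("strain_%04d", seq_len(n))
  variants <- data.frame(
    snp_id = paste0(chrom, "_", pos), chrom = chrom, pos = pos,
    ref = "A", alt = "G",
    QD = 30, FS = 10, MQ = 50, MQRankSum = 0, ReadPosRankSum = 0, SOR = 1,
    stringsAsFactors = FALSE
  )
  dimnames(dosage) <- list(strains, variants$snp_id)
  structure(
    list(dosage = dosage, truth = truth %||% dosage, variants = variants,
         strains = strains, config = NULL),
    class = "genotype_panel"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Write a hand-crafted VCF: `records` is a data frame with chrom, pos,
## id, ref, alt, info; genotypes all 0/0,0/1,1/1 cycling unless given.
write_raw_vcf <- function(records, path, n_samples = 4, gt = NULL) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s>", unique(records$chrom)),
    sprintf("##INFO=<ID=%s,Number=1,Type=Float,Description=\"x\">",
            c("QD", "FS", "MQ", "MQRankSum", "ReadPosRankSum", "SOR")),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sprintf("s%02d", seq_len(n_samples))), collapse = "\t")
  )
  if (is.null(gt)) {
    gt <- matrix(rep(c("0/0", "0/1", "1/1", "0/1"), length.out =
                       nrow(records) * n_samples),
                 nrow = nrow(records))
  }
  body <- paste(records$chrom, records$pos, records$id, records$ref,
                records$alt, ".", "PASS", records$info, "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  path
}

## Brute-force Pearson r^2 from first principles (no cor()).
oracle_r2 <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  x <- a[ok]; y <- b[ok]
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  sxy <- sum((x - mx) * (y - my))
  sxx <- sum((x - mx)^2); syy <- sum((y - my)^2)
  if (sxx == 0 || syy == 0) return(NA_real_)
  (sxy / sqrt(sxx * syy))^2
}

## Exhaustive (50,10) window re-scan: TRUE when no surviving pair in any
## window position exceeds r2_max.
oracle_no_window_violation <- function(panel, window_size = 50,
                                       window_step = 10, r2_max = 0.5) {
  v <- panel$variants
  for (ch in unique(v$chrom)) {
    idx <- which(v$chrom == ch)
    k <- length(idx)
    for (s in seq(1L, k, by = window_step)) {
      win <- idx[seq.int(s, min(s + window_size - 1L, k))]
      if (length(win) < 2) next
      for (ii in seq_len(length(win) - 1L)) {
        for (jj in seq.int(ii + 1L, length(win))) {
          a <- panel$dosage[, win[ii]]; b <- panel$dosage[, win[jj]]
          ok <- !is.na(a) & !is.na(b)
          if (sum(ok) < 2) next
          r2 <- oracle_r2(a, b)
          if (!is.na(r2) && r2 > r2_max) return(FALSE)
        }
      }
    }
  }
  TRUE
}

## Hypergeometric upper-tail by explicit enumeration of choose() terms.
oracle_hyper_tail <- function(k, K, N, n) {
  i <- seq.int(k, min(K, n))
  sum(exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)))
}

## Brute-force proximity scan over all (snp, gene) pairs.
oracle_proximity <- function(snps, features, half_window = 25000) {
  out <- list()
  for (i in seq_len(nrow(snps))) {
    for (j in seq_len(nrow(features))) {
      if (snps$chrom[i] != features$chrom[j]) next
      pos <- snps$pos[i]
      s <- features$start[j]; e <- features$end[j]
      d <- if (pos >= s && pos <= e) 0 else min(abs(pos - s), abs(pos - e))
      if (d <= half_window) {
        out[[length(out) + 1L]] <- data.frame(
          snp_id = snps$snp_id[i], gene_id = features$gene_id[j],
          distance = d, stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(snp_id = character(0), gene_id = character(0),
               distance = numeric(0))
}

## A tiny multi-source phenotype fixture with a planted effect and a
## binary noise trait; returns list(panel, phenotypes, effects).
small_study <- function(n_strains = 150, n_snps = 120, seed = 7,
                        effect_size = 2, noise_sd = 0.3) {
  cfg <- sim_config(
    n_strains = n_strains, n_snps = n_snps, n_chromosomes = 2,
    maf_sampler = function(n) runif(n, 0.2, 0.5),
    missing_rate = 0.02, ld_block_size = 4, ld_within_block_r2 = 0.6,
    seed = seed
  )
  panel <- simulate_genotypes(cfg)
  planted <- panel$variants$snp_id[3]
  effects <- data.frame(snp_id = planted, trait_name = "THC",
                        effect_size = effect_size)
  traits <- data.frame(
    name = c("THC", "CBD", "CBN", "affect"),
    kind = c("quantitative", "quantitative", "quantitative", "binary"),
    baseline = c(15, 5, 1, 0)
  )
  pheno <- simulate_phenotypes(panel, effects,
                               sources = default_sources(noise_sd),
                               traits = traits, seed = seed + 1)
  list(panel = panel, phenotypes = pheno, effects = effects,
       planted = planted)
}
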
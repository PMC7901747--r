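## Synthetic-data module: genotypes with local LD, gene annotations, and
## multi-source noisy phenotypes with planted causal SNPs. Everything is
## seeded and byte-reproducible so the downstream modules can be tested
## without any external data.

#' Simulation configuration
#'
#' Defaults emulate the scale of an amplicon-sequenced crop strain panel:
#' 845 strains genotyped at 4,351 bi-allelic SNPs spread over 10
#' chromosomes, with local LD in small blocks, sparse missing calls and
#' variant-quality annotations in ranges that pass the default hard
#' filters.
#'
#' @param n_strains Number of strains (rows of the dosage matrix).
#' @param n_snps Total number of bi-allelic SNPs.
#' @param n_chromosomes Number of chromosomes; SNPs are split across them
#'   as evenly as possible.
#' @param chromosome_lengths Integer vector of chromosome lengths in bp
#'   (recycled to `n_chromosomes`). Default 100 Mb each.
#' @param maf_sampler Function of one argument `n` returning `n` population
#'   minor-allele frequencies in (0, 0.5]. Default uniform on
#'   \[0.05, 0.5\].
#' @param missing_rate Per-call probability of a missing genotype, in
#'   \[0, 1).
#' @param ld_block_size Number of consecutive SNPs per LD block. Within a
#'   block, dosage vectors are copies of the block anchor with per-call
#'   resampling, across blocks SNPs are independent.
#' @param ld_within_block_r2 Target pairwise squared correlation between a
#'   block anchor and its copies, in \[0, 1\].
#' @param info_ranges Named list of `c(min, max)` ranges from which the
#'   site-quality annotations (QD, FS, MQ, MQRankSum, ReadPosRankSum, SOR)
#'   are drawn uniformly. The defaults lie strictly inside the hard-filter
#'   pass region; widen a range past its threshold to create failing sites.
#' @param info_missing_rate Probability that a rank-sum annotation
#'   (MQRankSum, ReadPosRankSum) is absent at a site, as happens at sites
#'   without heterozygotes.
#' @param seed Integer seed; identical `(config, seed)` gives byte-identical
#'   fixtures.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_strains = 845,
                       n_snps = 4351,
                       n_chromosomes = 10,
                       chromosome_lengths = NULL,
                       maf_sampler = function(n) runif(n, 0.05, 0.5),
                       missing_rate = 0.03,
                       ld_block_size = 5,
                       ld_within_block_r2 = 0.7,
                       info_ranges = NULL,
                       info_missing_rate = 0.02,
                       seed = 1L) {
  n_strains <- check_count(n_strains, "n_strains")
  n_snps <- check_count(n_snps, "n_snps")
  n_chromosomes <- check_count(n_chromosomes, "n_chromosomes")
  ld_block_size <- check_count(ld_block_size, "ld_block_size")
  if (missing_rate < 0 || missing_rate >= 1) {
    stopf("`missing_rate` must be in [0, 1)")
  }
  if (ld_within_block_r2 < 0 || ld_within_block_r2 > 1) {
    stopf("`ld_within_block_r2` must be in [0, 1]")
  }
  chromosome_lengths <- rep_len(
    as.numeric(chromosome_lengths %||% 1e8), n_chromosomes
  )
  per_chrom <- snps_per_chromosome(n_snps, n_chromosomes)
  if (any(chromosome_lengths < per_chrom)) {
    stopf("chromosome_lengths too short to place the requested SNPs")
  }
  defaults <- list(
    QD = c(20, 40), FS = c(0, 60), MQ = c(45, 60),
    MQRankSum = c(-0.2, 1), ReadPosRankSum = c(-1, 2), SOR = c(0, 2)
  )
  info_ranges <- utils::modifyList(defaults, as.list(info_ranges %||% list()))
  structure(list(
    n_strains = n_strains, n_snps = n_snps, n_chromosomes = n_chromosomes,
    chromosome_lengths = chromosome_lengths, maf_sampler = maf_sampler,
    missing_rate = missing_rate, ld_block_size = ld_block_size,
    ld_within_block_r2 = ld_within_block_r2, info_ranges = info_ranges,
    info_missing_rate = info_missing_rate, seed = as.integer(seed)
  ), class = "sim_config")
}

snps_per_chromosome <- function(n_snps, n_chromosomes) {
  base <- n_snps %/% n_chromosomes
  extra <- n_snps %% n_chromosomes
  base + as.integer(seq_len(n_chromosomes) <= extra)
}

#' Simulate a diploid genotype panel with local LD
#'
#' Per-SNP population MAFs are drawn from `config$maf_sampler`, dosages as
#' Binomial(2, maf) per strain. Local LD is produced by block-copying: the
#' first SNP of each block of `ld_block_size` consecutive SNPs is an
#' independent draw, the remainder copy the anchor's dosage vector and
#' resample each call independently with probability
#' `1 - sqrt(ld_within_block_r2)`, which makes the expected anchor-copy
#' correlation `sqrt(r2)` and hence the squared correlation the target r2.
#' Missing calls are masked uniformly at random at `missing_rate`; the
#' pre-missingness truth is retained for phenotype simulation.
#'
#' @param config A [sim_config()].
#' @return An object of class `genotype_panel`: a list with `dosage`
#'   (strains x SNPs integer matrix, `NA` = missing call), `truth` (the
#'   same matrix before missingness), `variants` (data frame with snp_id,
#'   chrom, pos, ref, alt and the QD/FS/MQ/MQRankSum/ReadPosRankSum/SOR
#'   site annotations), `strains`, and the config.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    n <- config$n_strains
    m <- config$n_snps
    per_chrom <- snps_per_chromosome(m, config$n_chromosomes)
    chrom <- rep(paste0("chr", seq_len(config$n_chromosomes)), per_chrom)
    pos <- unlist(lapply(seq_len(config$n_chromosomes), function(i) {
      sort(sample.int(config$chromosome_lengths[i], per_chrom[i]))
    }), use.names = FALSE)
    maf <- pmin(pmax(config$maf_sampler(m), 1e-6), 0.5)
    if (length(maf) != m) stopf("maf_sampler must return n values")

    ## independent draws for every SNP, then overwrite block copies
    truth <- matrix(
      rbinom(n * m, size = 2L, prob = rep(maf, each = n)),
      nrow = n, ncol = m
    )
    if (config$ld_block_size > 1) {
      copy_keep <- sqrt(config$ld_within_block_r2)
      offset <- 0L
      for (k in per_chrom) {
        anchors <- seq(1L, k, by = config$ld_block_size)
        for (a in anchors) {
          members <- seq(a + 1L, min(a + config$ld_block_size - 1L, k))
          if (a + 1L > min(a + config$ld_block_size - 1L, k)) next
          for (j in members) {
            keep <- runif(n) < copy_keep
            col <- truth[, offset + j]
            col[keep] <- truth[keep, offset + a]
            truth[, offset + j] <- col
          }
        }
        offset <- offset + k
      }
    }
    dosage <- truth
    if (config$missing_rate > 0) {
      dosage[runif(n * m) < config$missing_rate] <- NA_integer_
    }

    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, m, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")
    info <- lapply(config$info_ranges, function(rg) runif(m, rg[1], rg[2]))
    for (key in c("MQRankSum", "ReadPosRankSum")) {
      if (config$info_missing_rate > 0) {
        info[[key]][runif(m) < config$info_missing_rate] <- NA_real_
      }
    }
    variants <- data.frame(
      snp_id = paste0(chrom, "_", pos), chrom = chrom, pos = pos,
      ref = ref, alt = alt, maf = maf,
      QD = info$QD, FS = info$FS, MQ = info$MQ,
      MQRankSum = info$MQRankSum, ReadPosRankSum = info$ReadPosRankSum,
      SOR = info$SOR,
      stringsAsFactors = FALSE, row.names = NULL
    )
    strains <- sprintf("strain_%04d", seq_len(n))
    dimnames(truth) <- dimnames(dosage) <- list(strains, variants$snp_id)
    structure(
      list(dosage = dosage, truth = truth, variants = variants,
           strains = strains, config = config),
      class = "genotype_panel"
    )
  })
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf(
    "genotype_panel: %d strains x %d SNPs on %d chromosome(s), %.1f%% missing calls\n",
    length(x$strains), nrow(x$variants),
    length(unique(x$variants$chrom)),
    100 * mean(is.na(x$dosage))
  ))
  invisible(x)
}

#' Write a genotype panel as VCF v4.2
#'
#' Emits diploid unphased GT calls and the six site-quality INFO keys used
#' by the hard filters; absent annotations are omitted from the INFO
#' column rather than written as missing values.
#'
#' @param panel A `genotype_panel`.
#' @param path Output path (plain text).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(panel, path) {
  stopifnot(inherits(panel, "genotype_panel"))
  v <- panel$variants
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=strainassoc",
    sprintf("##contig=<ID=chr%d,length=%d>",
            seq_len(panel$config$n_chromosomes),
            as.integer(panel$config$chromosome_lengths)),
    sprintf(
      "##INFO=<ID=%s,Number=1,Type=Float,Description=\"%s\">",
      c("QD", "FS", "MQ", "MQRankSum", "ReadPosRankSum", "SOR"),
      c("Quality by depth", "Fisher strand bias", "RMS mapping quality",
        "Mapping quality rank sum", "Read position rank sum",
        "Strand odds ratio")
    ),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", panel$strains), collapse = "\t")
  )
  keys <- c("QD", "FS", "MQ", "MQRankSum", "ReadPosRankSum", "SOR")
  info <- vapply(seq_len(nrow(v)), function(i) {
    vals <- unlist(v[i, keys])
    keep <- !is.na(vals)
    paste(sprintf("%s=%.6g", keys[keep], vals[keep]), collapse = ";")
  }, "")
  gt_codes <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow = nrow(v), ncol = length(panel$strains))
  d <- t(panel$dosage) # variants x strains
  ok <- !is.na(d)
  gt[ok] <- gt_codes[d[ok] + 1L]
  body <- paste(
    v$chrom, v$pos, v$snp_id, v$ref, v$alt, ".", "PASS", info, "GT",
    apply(gt, 1L, paste, collapse = "\t"),
    sep = "\t"
  )
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Simulate a gene annotation and write it as GFF3
#'
#' Places `n_genes` non-degenerate gene intervals uniformly on the panel's
#' chromosomes. To exercise the 25 kb proximity boundary downstream, one
#' gene can be guaranteed within `near_distance` of each SNP named in
#' `near_snps`, and one gene guaranteed farther than `far_distance` from
#' every SNP. Fully deterministic placements can be appended via
#' `fixed_genes`.
#'
#' @param panel A `genotype_panel` (supplies chromosome names, lengths and
#'   SNP positions).
#' @param n_genes Number of randomly placed genes (0 allowed).
#' @param gene_length_range `c(min, max)` gene length in bp.
#' @param near_snps Character vector of snp_ids; one extra gene is placed
#'   with its nearest edge at most `near_distance` bp from each.
#' @param near_distance Guaranteed maximum SNP-to-edge distance for
#'   `near_snps` genes (default 20,000 bp, inside the 25 kb window).
#' @param guarantee_far If `TRUE`, place one gene farther than
#'   `far_distance` from every SNP (errors if infeasible).
#' @param far_distance Minimum distance for the far gene (default 25,001).
#' @param fixed_genes Optional data frame with columns chrom, start, end
#'   (and optionally gene_id, product) appended verbatim.
#' @param seed Integer seed.
#' @return Data frame of gene features: gene_id, chrom, start, end,
#'   strand, product (1-based closed intervals).
#' @export
simulate_annotation <- function(panel, n_genes = 50,
                                gene_length_range = c(1000, 8000),
                                near_snps = character(),
                                near_distance = 20000,
                                guarantee_far = TRUE,
                                far_distance = 25001,
                                fixed_genes = NULL,
                                seed = 1L) {
  stopifnot(inherits(panel, "genotype_panel"))
  cfg <- panel$config
  lens <- cfg$chromosome_lengths
  names(lens) <- paste0("chr", seq_along(lens))
  if (max(gene_length_range) >= min(lens)) {
    stopf("gene placement infeasible: genes longer than a chromosome")
  }
  with_seed(seed, {
    draw_len <- function(k) {
      floor(runif(k, gene_length_range[1], gene_length_range[2] + 1))
    }
    chrom <- character(0); start <- numeric(0); end <- numeric(0)
    if (n_genes > 0) {
      chrom <- sample(names(lens), n_genes, replace = TRUE)
      len <- draw_len(n_genes)
      start <- floor(runif(n_genes, 1, lens[chrom] - len + 1))
      end <- start + len - 1
    }
    for (sid in near_snps) {
      i <- match(sid, panel$variants$snp_id)
      if (is.na(i)) stopf("near_snps: unknown snp_id '%s'", sid)
      p <- panel$variants$pos[i]; ch <- panel$variants$chrom[i]
      len <- draw_len(1)
      s <- p + floor(runif(1, 1, near_distance))
      if (s + len - 1 > lens[ch]) s <- max(1, p - near_distance - len + 1)
      chrom <- c(chrom, ch); start <- c(start, s); end <- c(end, s + len - 1)
    }
    if (isTRUE(guarantee_far)) {
      placed <- FALSE
      for (ch in names(lens)) {
        snp_pos <- panel$variants$pos[panel$variants$chrom == ch]
        len <- draw_len(1)
        lo <- if (length(snp_pos)) max(snp_pos) + far_distance else 1
        if (lo + len - 1 <= lens[ch]) {
          chrom <- c(chrom, ch); start <- c(start, lo)
          end <- c(end, lo + len - 1)
          placed <- TRUE
          break
        }
      }
      if (!placed) stopf("gene placement infeasible: no SNP-free span of %d bp",
                         as.integer(far_distance))
    }
    feats <- data.frame(chrom = chrom, start = start, end = end,
                        stringsAsFactors = FALSE)
    if (!is.null(fixed_genes)) {
      fg <- fixed_genes[, c("chrom", "start", "end")]
      feats <- rbind(feats, fg)
    }
    n <- nrow(feats)
    feats$gene_id <- sprintf("gene_%04d", seq_len(n))
    if (!is.null(fixed_genes) && !is.null(fixed_genes$gene_id)) {
      feats$gene_id[seq.int(n - nrow(fixed_genes) + 1, n)] <- fixed_genes$gene_id
    }
    feats$strand <- sample(c("+", "-"), n, replace = TRUE)
    feats$product <- sprintf("hypothetical protein %s", feats$gene_id)
    feats <- feats[order(feats$chrom, feats$start), , drop = FALSE]
    rownames(feats) <- NULL
    feats[, c("gene_id", "chrom", "start", "end", "strand", "product")]
  })
}

#' Write gene features as a GFF3 file
#'
#' @param features Data frame as returned by [simulate_annotation()].
#' @param path Output path.
#' @param chromosome_lengths Optional named lengths for
#'   `##sequence-region` directives.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(features, path, chromosome_lengths = NULL) {
  hdr <- "##gff-version 3"
  if (!is.null(chromosome_lengths)) {
    hdr <- c(hdr, sprintf("##sequence-region %s 1 %d",
                          names(chromosome_lengths),
                          as.integer(chromosome_lengths)))
  }
  body <- character(0)
  if (!is.null(features) && nrow(features)) {
    body <- paste(
      features$chrom, "strainassoc", "gene",
      as.integer(features$start), as.integer(features$end),
      ".", features$strand, ".",
      sprintf("ID=%s;product=%s", features$gene_id, features$product),
      sep = "\t"
    )
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Default source models for multi-source phenotype simulation
#'
#' Emulates three partially overlapping public databases that report the
#' same strains with source-specific coverage, additive bias and report
#' noise.
#'
#' @param noise_sd Common per-report noise standard deviation (trait
#'   units).
#' @return Data frame with columns source_name, coverage, bias, noise_sd.
#' @export
default_sources <- function(noise_sd = 0.5) {
  data.frame(
    source_name = c("siteA", "siteB", "siteC"),
    coverage = c(0.85, 0.75, 0.65),
    bias = c(0.5, -0.5, 0),
    noise_sd = rep(noise_sd, 3),
    stringsAsFactors = FALSE
  )
}

#' Simulate per-source strain-by-trait phenotype tables
#'
#' Quantitative trait value for strain s reported by source w is
#' `baseline + sum(effect_size * dosage) + bias_w + N(0, noise_sd_w)`;
#' binary traits threshold a latent liability (genetic value plus unit
#' residual, plus per-source noise) at the population median. Each source
#' reports only a coverage fraction of strains. A designated null trait
#' with no planted effects is always included so downstream calibration
#' can be checked against a negative control.
#'
#' @param panel A `genotype_panel`; effects act on the pre-missingness
#'   truth dosages.
#' @param effects Data frame with columns snp_id, trait_name, effect_size
#'   (trait units per alternate allele), or `NULL` for a fully null study.
#' @param sources Data frame as [default_sources()].
#' @param traits Data frame with columns name, kind ("quantitative" or
#'   "binary") and baseline. Defaults to quantitative traits for every
#'   trait named in `effects` plus the null trait.
#' @param null_trait Name of the guaranteed effect-free quantitative
#'   trait (default "CBN", an oxidation product not under direct genetic
#'   control, hence the natural negative control).
#' @param seed Integer seed.
#' @return Named list of per-source data frames (strain_id plus one
#'   column per trait; unreported strains absent), with attribute
#'   `"truth"` carrying the planted effects and per-strain genetic
#'   values.
#' @export
simulate_phenotypes <- function(panel, effects = NULL,
                                sources = default_sources(),
                                traits = NULL, null_trait = "CBN",
                                seed = 1L) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (!is.null(effects) && nrow(effects)) {
    unknown <- setdiff(effects$snp_id, panel$variants$snp_id)
    if (length(unknown)) {
      stopf("effects reference unknown snp_id(s): %s",
            paste(unknown, collapse = ", "))
    }
    if (null_trait %in% effects$trait_name) {
      stopf("the null trait '%s' must not carry planted effects", null_trait)
    }
  }
  if (is.null(traits)) {
    nm <- unique(if (is.null(effects)) character(0) else effects$trait_name)
    traits <- data.frame(
      name = c(nm, null_trait),
      kind = "quantitative",
      baseline = c(rep(10, length(nm)), 1),
      stringsAsFactors = FALSE
    )
  }
  if (!null_trait %in% traits$name) {
    traits <- rbind(traits, data.frame(name = null_trait,
                                       kind = "quantitative", baseline = 1))
  }
  n <- length(panel$strains)
  genetic <- matrix(0, n, nrow(traits),
                    dimnames = list(panel$strains, traits$name))
  if (!is.null(effects) && nrow(effects)) {
    for (i in seq_len(nrow(effects))) {
      tr <- effects$trait_name[i]
      if (!tr %in% traits$name) stopf("effect for unknown trait '%s'", tr)
      genetic[, tr] <- genetic[, tr] +
        effects$effect_size[i] * panel$truth[, effects$snp_id[i]]
    }
  }
  with_seed(seed, {
    ## shared latent liability for binary traits (residual sd 1)
    liability <- genetic
    is_bin <- traits$kind == "binary"
    for (j in which(is_bin)) {
      liability[, j] <- genetic[, j] + rnorm(n)
    }
    out <- list()
    for (w in seq_len(nrow(sources))) {
      src <- sources[w, ]
      reported <- runif(n) <= src$coverage
      tab <- data.frame(strain_id = panel$strains[reported],
                        stringsAsFactors = FALSE)
      for (j in seq_len(nrow(traits))) {
        tr <- traits[j, ]
        if (tr$kind == "binary") {
          obs <- liability[, j] + rnorm(n, 0, src$noise_sd)
          val <- as.integer(obs > median(liability[, j]))
        } else {
          val <- tr$baseline + genetic[, j] + src$bias +
            rnorm(n, 0, src$noise_sd)
        }
        tab[[tr$name]] <- val[reported]
      }
      out[[src$source_name]] <- tab
    }
    attr(out, "truth") <- list(effects = effects, traits = traits,
                               genetic_values = genetic,
                               null_trait = null_trait, sources = sources)
    out
  })
}

#' Write per-source phenotype tables as tab-separated files
#'
#' @param phenotypes Named list from [simulate_phenotypes()].
#' @param dir Output directory (created if needed).
#' @return Character vector of written paths, invisibly.
#' @export
write_phenotype_tables <- function(phenotypes, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(phenotypes), function(nm) {
    p <- file.path(dir, paste0(nm, ".tsv"))
    write.table(phenotypes[[nm]], p, sep = "\t", quote = FALSE,
                row.names = FALSE)
    p
  }, "")
  invisible(paths)
}

#' Write the planted ground truth as JSON
#'
#' Records the planted effects and the null trait so test harnesses can
#' score recovery without re-deriving the simulation internals.
#'
#' @param phenotypes Result of [simulate_phenotypes()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(phenotypes, path) {
  truth <- attr(phenotypes, "truth")
  jsonlite::write_json(
    list(effects = truth$effects, null_trait = truth$null_trait,
         traits = truth$traits, sources = truth$sources),
    path, auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(path)
}
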
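test_that("identical config and seed give byte-identical fixtures", {
  cfg <- sim_config(n_strains = 40, n_snps = 60, n_chromosomes = 2, seed = 5)
  g1 <- simulate_genotypes(cfg)
  g2 <- simulate_genotypes(cfg)
  expect_identical(g1, g2)

  f1 <- tempfile(fileext = ".vcf"); f2 <- tempfile(fileext = ".vcf")
  write_vcf(g1, f1); write_vcf(g2, f2)
  expect_identical(readLines(f1), readLines(f2))

  a1 <- simulate_annotation(g1, n_genes = 10, seed = 3)
  a2 <- simulate_annotation(g1, n_genes = 10, seed = 3)
  g3 <- tempfile(fileext = ".gff3"); g4 <- tempfile(fileext = ".gff3")
  write_gff3(a1, g3); write_gff3(a2, g4)
  expect_identical(readLines(g3), readLines(g4))
})

test_that("realized MAF tracks the sampled population MAF", {
  ## degenerate distribution at 0.5; binomial sampling at 2n = 20,000
  ## alleles has sd ~0.0035, so +/-0.02 is > 5 sd
  cfg <- sim_config(
    n_strains = 10000, n_snps = 200, n_chromosomes = 1,
    maf_sampler = function(n) rep(0.5, n),
    missing_rate = 0, ld_block_size = 1, seed = 11
  )
  g <- simulate_genotypes(cfg)
  af <- colMeans(g$truth) / 2
  maf <- pmin(af, 1 - af)
  expect_gte(mean(abs(maf - 0.5) <= 0.02), 0.99)
})

test_that("ld_within_block_r2 = 1 duplicates dosage vectors within blocks", {
  cfg <- sim_config(n_strains = 50, n_snps = 20, n_chromosomes = 1,
                    ld_block_size = 5, ld_within_block_r2 = 1,
                    missing_rate = 0, seed = 2)
  g <- simulate_genotypes(cfg)
  for (a in seq(1, 20, by = 5)) {
    for (j in seq(a + 1, a + 4)) {
      expect_equal(unname(g$truth[, j]), unname(g$truth[, a]))
    }
  }
})

test_that("block LD lands near the target r2 and blocks are ~independent", {
  cfg <- sim_config(n_strains = 2000, n_snps = 40, n_chromosomes = 1,
                    maf_sampler = function(n) rep(0.4, n),
                    ld_block_size = 4, ld_within_block_r2 = 0.7,
                    missing_rate = 0, seed = 4)
  g <- simulate_genotypes(cfg)
  within <- cor(g$truth[, 1], g$truth[, 2])^2
  expect_lt(abs(within - 0.7), 0.12)
  across <- cor(g$truth[, 1], g$truth[, 5])^2
  expect_lt(across, 0.05)
})

test_that("positions are strictly increasing per chromosome", {
  g <- simulate_genotypes(sim_config(n_strains = 10, n_snps = 500,
                                     n_chromosomes = 3, seed = 9))
  for (ch in unique(g$variants$chrom)) {
    expect_true(all(diff(g$variants$pos[g$variants$chrom == ch]) > 0))
  }
})

test_that("infeasible simulation requests error", {
  expect_error(sim_config(n_strains = 0), "n_strains")
  expect_error(
    simulate_genotypes(sim_config(n_snps = 1000, n_chromosomes = 1,
                                  chromosome_lengths = 50)),
    "too short"
  )
})

test_that("noise-free single-effect phenotype is an exact affine function of dosage", {
  g <- simulate_genotypes(sim_config(n_strains = 30, n_snps = 10,
                                     missing_rate = 0, n_chromosomes = 1,
                                     seed = 3))
  eff <- data.frame(snp_id = g$variants$snp_id[4], trait_name = "THC",
                    effect_size = 1.5)
  src <- data.frame(source_name = "w1", coverage = 1, bias = 0, noise_sd = 0)
  ph <- simulate_phenotypes(g, eff, sources = src, seed = 1,
                            traits = data.frame(name = "THC",
                                                kind = "quantitative",
                                                baseline = 10))
  expect_equal(ph$w1$THC, 10 + 1.5 * unname(g$truth[, 4]))
})

test_that("opposite source biases cancel in the cross-source mean", {
  g <- simulate_genotypes(sim_config(n_strains = 25, n_snps = 8,
                                     missing_rate = 0, n_chromosomes = 1,
                                     seed = 6))
  src <- data.frame(source_name = c("w1", "w2"), coverage = 1,
                    bias = c(1, -1), noise_sd = 0)
  ph <- simulate_phenotypes(g, NULL, sources = src, seed = 1,
                            traits = data.frame(name = "CBD",
                                                kind = "quantitative",
                                                baseline = 5))
  expect_equal((ph$w1$CBD + ph$w2$CBD) / 2, rep(5, 25))
})

test_that("with no planted effects, dosage-trait correlation is null", {
  g <- simulate_genotypes(sim_config(n_strains = 1000, n_snps = 20,
                                     missing_rate = 0, n_chromosomes = 1,
                                     maf_sampler = function(n) rep(0.3, n),
                                     seed = 12))
  src <- data.frame(source_name = "w1", coverage = 1, bias = 0,
                    noise_sd = 1)
  ph <- simulate_phenotypes(g, NULL, sources = src, seed = 2,
                            traits = data.frame(name = "THC",
                                                kind = "quantitative",
                                                baseline = 0))
  ## |r| < 0.05 at n = 1000: ~3.2 null sd for any single SNP
  r <- abs(cor(g$truth[, 7], ph$w1$THC))
  expect_lt(r, 0.05)
})

test_that("the designated null trait is always present and effect-free", {
  s <- small_study()
  for (tab in s$phenotypes) expect_true("CBN" %in% names(tab))
  expect_error(
    simulate_phenotypes(s$panel,
                        data.frame(snp_id = s$planted, trait_name = "CBN",
                                   effect_size = 1)),
    "null trait"
  )
  expect_error(
    simulate_phenotypes(s$panel,
                        data.frame(snp_id = "nonexistent_snp",
                                   trait_name = "THC", effect_size = 1)),
    "unknown snp_id"
  )
})

test_that("emitted VCF round-trips through the reader without loss", {
  g <- simulate_genotypes(sim_config(n_strains = 35, n_snps = 80,
                                     n_chromosomes = 2, seed = 21))
  f <- tempfile(fileext = ".vcf")
  write_vcf(g, f)
  p <- read_vcf(f)
  expect_identical(unname(p$dosage), unname(g$dosage))
  expect_identical(p$variants$snp_id, g$variants$snp_id)
  expect_identical(p$variants$pos, g$variants$pos)
  for (k in c("QD", "FS", "MQ", "SOR")) {
    expect_equal(p$variants[[k]], g$variants[[k]], tolerance = 1e-5)
  }
  ## absent rank sums stay absent
  expect_identical(is.na(p$variants$MQRankSum), is.na(g$variants$MQRankSum))
})

test_that("simulated annotation honors near/far guarantees and GFF3 round-trips", {
  g <- simulate_genotypes(sim_config(n_strains = 20, n_snps = 50,
                                     n_chromosomes = 2, seed = 8))
  target <- g$variants$snp_id[25]
  feats <- simulate_annotation(g, n_genes = 15, near_snps = target, seed = 4)
  f <- tempfile(fileext = ".gff3")
  write_gff3(feats, f)
  back <- load_gff3(f)
  expect_equal(nrow(back), nrow(feats))
  expect_setequal(back$gene_id, feats$gene_id)
  expect_identical(back$start[order(back$gene_id)],
                   as.integer(feats$start[order(feats$gene_id)]))

  prox <- genes_near_snp(g$variants[g$variants$snp_id == target, ], back)
  expect_gte(nrow(prox), 1)

  ## far gene: farther than 25 kb from every SNP
  dists <- sapply(seq_len(nrow(back)), function(j) {
    same <- g$variants$chrom == back$chrom[j]
    if (!any(same)) return(Inf)
    pos <- g$variants$pos[same]
    min(pmax(0, pmax(back$start[j] - pos, pos - back$end[j])))
  })
  expect_true(any(dists > 25000))
})

test_that("zero genes gives a valid header-only GFF3", {
  g <- simulate_genotypes(sim_config(n_strains = 10, n_snps = 10,
                                     n_chromosomes = 1, seed = 1))
  feats <- simulate_annotation(g, n_genes = 0, guarantee_far = FALSE,
                               seed = 1)
  expect_equal(nrow(feats), 0)
  f <- tempfile(fileext = ".gff3")
  write_gff3(feats, f)
  expect_identical(readLines(f), "##gff-version 3")
  expect_equal(nrow(load_gff3(f)), 0)
})
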
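## Construct a results table + manifest directly so Methods 1-3 can be
## checked against hand-enumerated truth.
mk_results <- function(snp, test, p) {
  data.frame(snp_id = snp, test_id = test, chrom = "chr1",
             pos = seq_along(snp), p = p, untested = FALSE,
             stringsAsFactors = FALSE)
}

mk_manifest <- function(test_id, subcategory, major_category) {
  data.frame(test_id = test_id, subcategory = subcategory,
             major_category = major_category, stringsAsFactors = FALSE)
}

test_that("Method 1 uses an inclusive cutoff", {
  res <- mk_results(c("s1", "s2", "s3"), c("t1", "t1", "t1"),
                    c(1e-9, 2e-9, 1e-10))
  hits <- method1_hits(res, consensus_config(alpha = 1e-9))
  expect_setequal(hits$snp_id, c("s1", "s3"))  # p = alpha exactly is a hit
  expect_equal(nrow(method1_hits(res[0, ], consensus_config())), 0)
})

test_that("Methods 2 and 3 count distinct supporting tests per grouping", {
  man <- mk_manifest(
    c("cbd1", "cbd2", "cbd3", "thc1", "thc2", "grow1", "grow2", "grow3"),
    c("CBD content", "CBD content", "CBD content", "THC content",
      "THC content", "Growth", "Growth", "Growth"),
    c(rep("chemical", 5), rep("non-chemical", 3))
  )
  cfg <- consensus_config(alpha = 1e-9, min_tests = 3)

  ## snpA: 3 CBD tests -> Method 2 hit for CBD and Method 3 chemical hit
  ## snpB: 2 CBD + 2 THC -> no Method 2 hit; Method 3 chemical hit (4),
  ##       pleiotropic across subcategories
  ## snpC: 2 chemical + 1 non-chemical -> neither method
  res <- mk_results(
    c("snpA", "snpA", "snpA", "snpB", "snpB", "snpB", "snpB",
      "snpC", "snpC", "snpC"),
    c("cbd1", "cbd2", "cbd3", "cbd1", "cbd2", "thc1", "thc2",
      "cbd1", "thc1", "grow1"),
    rep(1e-10, 10)
  )
  m2 <- method2_hits(res, man, cfg)
  expect_equal(m2$snp_id, "snpA")
  expect_equal(m2$grouping, "CBD content")
  expect_equal(m2$n_supporting, 3)

  m3 <- method3_hits(res, man, cfg)
  expect_setequal(m3$snp_id, c("snpA", "snpB"))
  expect_equal(m3$grouping[m3$snp_id == "snpB"], "chemical")
  expect_equal(m3$n_supporting[m3$snp_id == "snpB"], 4)
  expect_true(m3$pleiotropic[m3$snp_id == "snpB"])
  expect_false(m3$pleiotropic[m3$snp_id == "snpA"])
  expect_equal(m3$pleiotropy_subcategories[m3$snp_id == "snpB"],
               "CBD content,THC content")

  ## containment: every Method 2 hit is a Method 3 hit in its major category
  expect_true(all(m2$snp_id %in% m3$snp_id))

  ## duplicate rows for the same test count once
  res_dup <- rbind(res, res[1, ])
  m2_dup <- method2_hits(res_dup, man, cfg)
  expect_equal(m2_dup$n_supporting, 3)
})

test_that("distinct direction/fraction encodings of one trait are distinct tests", {
  man <- mk_manifest(c("cbd|top|5", "cbd|bottom|5", "cbd|top|25"),
                     rep("CBD content", 3), rep("chemical", 3))
  res <- mk_results(rep("snpX", 3),
                    c("cbd|top|5", "cbd|bottom|5", "cbd|top|25"),
                    rep(1e-12, 3))
  m2 <- method2_hits(res, man, consensus_config())
  expect_equal(m2$n_supporting, 3)  # three test_ids, one trait
})

test_that("raising alpha never shrinks hits; raising min_tests never grows them", {
  s <- small_study(n_strains = 200, n_snps = 60)
  bat <- enumerate_test_battery(s$phenotypes)
  res <- run_battery(s$panel, bat$catalogs)
  for (alphas in list(c(1e-12, 1e-9), c(1e-9, 1e-6), c(1e-6, 1e-3))) {
    h_lo <- method1_hits(res, consensus_config(alpha = alphas[1]))
    h_hi <- method1_hits(res, consensus_config(alpha = alphas[2]))
    expect_true(all(paste(h_lo$snp_id, h_lo$test_id) %in%
                      paste(h_hi$snp_id, h_hi$test_id)))
  }
  cfg3 <- consensus_config(alpha = 1e-4, min_tests = 3)
  cfg5 <- consensus_config(alpha = 1e-4, min_tests = 5)
  m2_3 <- method2_hits(res, bat$manifest, cfg3)
  m2_5 <- method2_hits(res, bat$manifest, cfg5)
  expect_true(all(m2_5$snp_id %in% m2_3$snp_id))
  m3_3 <- method3_hits(res, bat$manifest, cfg3)
  expect_true(all(paste(m2_3$snp_id) %in% m3_3$snp_id))
})

test_that("Fisher-Yates subsampling covers edge cases and is uniform", {
  pool <- c("a", "b", "c", "d")
  expect_setequal(fisher_yates_subsample(pool, 4, seed = 1), pool)
  expect_length(fisher_yates_subsample(pool, 0, seed = 1), 0)
  expect_error(fisher_yates_subsample(pool, 5, seed = 1), "exceeds")

  ## all 6 two-element subsets of a 4-element pool appear ~1/6 each
  set.seed(42)
  draws <- replicate(100000, paste(sort(fisher_yates_subsample(pool, 2)),
                                   collapse = ""))
  freq <- table(draws) / length(draws)
  expect_length(freq, 6)
  expect_true(all(abs(freq - 1 / 6) <= 0.01))
})

test_that("a fixed seed reproduces bootstrap replicates exactly", {
  s <- small_study(n_strains = 120, n_snps = 30)
  bat <- enumerate_test_battery(s$phenotypes)
  cat_ <- bat$catalogs[["THC|siteA|top|25"]]
  cfg <- consensus_config(alpha = 1e-4, n_bootstrap = 25, seed = 99)
  r1 <- method4_bootstrap(s$panel, cat_, cfg)
  r2 <- method4_bootstrap(s$panel, cat_, cfg)
  expect_identical(r1, r2)
  r3 <- method4_bootstrap(s$panel, cat_,
                          consensus_config(alpha = 1e-4, n_bootstrap = 25,
                                           seed = 100))
  expect_false(identical(r1$n_significant, r3$n_significant))
})

test_that("bootstrap balances the groups by subsampling the larger one", {
  set.seed(8)
  d <- matrix(rbinom(230 * 10, 2, 0.4), 230, 10)
  panel <- make_panel(d)
  cat_ <- structure(list(test_id = "t", case_ids = panel$strains[1:30],
                         control_ids = panel$strains[31:230]),
                    class = "cc_catalog")
  r <- method4_bootstrap(panel, cat_,
                         consensus_config(n_bootstrap = 5, seed = 1))
  expect_equal(attr(r, "n_per_group"), 30)
  ## swapped roles: cases outnumber controls -> cases get subsampled
  cat_sw <- structure(list(test_id = "t", case_ids = panel$strains[1:200],
                           control_ids = panel$strains[201:230]),
                      class = "cc_catalog")
  r_sw <- method4_bootstrap(panel, cat_sw,
                            consensus_config(n_bootstrap = 5, seed = 1))
  expect_equal(attr(r_sw, "n_per_group"), 30)
  expect_error(
    method4_bootstrap(panel, structure(list(
      test_id = "t", case_ids = panel$strains[1],
      control_ids = panel$strains[2:30]), class = "cc_catalog"),
      consensus_config()),
    ">= 2"
  )
})

test_that("a strongly planted SNP is retained while null SNPs are not", {
  s <- small_study(n_strains = 300, n_snps = 50, effect_size = 3,
                   noise_sd = 0.2)
  bat <- enumerate_test_battery(s$phenotypes)
  cat_ <- bat$catalogs[["THC|averaged|top|25"]]
  cfg <- consensus_config(alpha = 1e-9, n_bootstrap = 40, seed = 5)
  r <- method4_bootstrap(s$panel, cat_, cfg)
  planted <- r[r$snp_id == s$planted, ]
  expect_true(planted$hit)
  expect_gte(planted$retention, 0.95)
  ## SNPs outside the planted LD block are never retained
  block <- s$panel$variants$snp_id[1:4]
  expect_equal(sum(r$hit[!r$snp_id %in% block]), 0)
})

test_that("retention thresholds use the ceiling rule", {
  s <- small_study(n_strains = 100, n_snps = 20)
  bat <- enumerate_test_battery(s$phenotypes)
  cat_ <- bat$catalogs[["THC|siteA|top|50"]]
  cfg <- consensus_config(alpha = 1e-9, n_bootstrap = 7, retention = 0.95,
                          seed = 2)
  r <- method4_bootstrap(s$panel, cat_, cfg)
  expect_true(all(r$hit == (r$n_significant >= ceiling(0.95 * 7))))
})
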
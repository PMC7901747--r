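## Consensus module: the four significance-detection rules layered over
## the association battery — the raw p <= alpha scan (Method 1),
## within-subcategory overlap (Method 2), within-major-category overlap
## with pleiotropy flagging (Method 3), and the balanced Fisher-Yates
## bootstrap (Method 4).

#' Consensus configuration
#'
#' @param alpha Inclusive significance cutoff (default 1e-9; a result at
#'   exactly `alpha` is significant).
#' @param min_tests Minimum number of supporting tests for Methods 2-3.
#' @param n_bootstrap Number of balanced-subsample replicates for
#'   Method 4.
#' @param retention Fraction of replicates in which a SNP must stay
#'   significant; with 100 replicates the default 0.95 means at least 95
#'   runs, and in general `ceiling(retention * n_bootstrap)` runs.
#' @param seed Master seed; each replicate draws from its own spawned
#'   substream.
#' @return A list of class `consensus_config`.
#' @export
consensus_config <- function(alpha = 1e-9, min_tests = 3, n_bootstrap = 100,
                             retention = 0.95, seed = 1L) {
  if (alpha <= 0 || alpha >= 1) stopf("alpha must be in (0, 1)")
  if (retention <= 0 || retention > 1) stopf("retention must be in (0, 1]")
  structure(list(
    alpha = alpha, min_tests = check_count(min_tests, "min_tests"),
    n_bootstrap = check_count(n_bootstrap, "n_bootstrap"),
    retention = retention, seed = as.integer(seed)
  ), class = "consensus_config")
}

#' Method 1: raw significant (SNP, test) pairs
#'
#' Every tested result with `p <= alpha` (inclusive).
#'
#' @param results Battery results from [run_battery()].
#' @param config A [consensus_config()].
#' @return Data frame of significant rows (snp_id, test_id, chrom, pos,
#'   p).
#' @export
method1_hits <- function(results, config = consensus_config()) {
  if (!nrow(results)) {
    return(data.frame(snp_id = character(0), test_id = character(0),
                      chrom = character(0), pos = integer(0), p = numeric(0)))
  }
  keep <- !results$untested & results$p <= config$alpha
  out <- results[keep, c("snp_id", "test_id", "chrom", "pos", "p"),
                 drop = FALSE]
  rownames(out) <- NULL
  out
}

## shared core for Methods 2 and 3: group Method-1 hits by a test-level
## label and keep SNPs supported by >= min_tests distinct tests
overlap_hits <- function(m1, manifest, group_col, config) {
  empty <- data.frame(snp_id = character(0), grouping = character(0),
                      n_supporting = integer(0),
                      supporting_tests = character(0),
                      stringsAsFactors = FALSE)
  if (!nrow(m1)) return(empty)
  lab <- manifest[[group_col]][match(m1$test_id, manifest$test_id)]
  if (anyNA(lab)) {
    stopf("test(s) missing from the battery manifest: %s",
          paste(unique(m1$test_id[is.na(lab)]), collapse = ", "))
  }
  key <- paste(m1$snp_id, lab, sep = "\r")
  parts <- split(m1$test_id, key)
  n_sup <- vapply(parts, function(x) length(unique(x)), 0L)
  keep <- n_sup >= config$min_tests
  if (!any(keep)) return(empty)
  ks <- strsplit(names(parts)[keep], "\r", fixed = TRUE)
  out <- data.frame(
    snp_id = vapply(ks, `[[`, "", 1),
    grouping = vapply(ks, `[[`, "", 2),
    n_supporting = as.integer(n_sup[keep]),
    supporting_tests = vapply(parts[keep], function(x)
      paste(sort(unique(x)), collapse = ","), ""),
    stringsAsFactors = FALSE, row.names = NULL
  )
  out[order(out$grouping, out$snp_id), , drop = FALSE]
}

#' Method 2: overlap within a phenotypic subcategory
#'
#' SNPs significant (`p <= alpha`) in at least `min_tests` distinct tests
#' belonging to one subcategory; one hit per (SNP, subcategory).
#'
#' @param results Battery results.
#' @param manifest Battery manifest with `test_id` and `subcategory`
#'   columns.
#' @param config A [consensus_config()].
#' @return Data frame: snp_id, grouping (subcategory), n_supporting,
#'   supporting_tests.
#' @export
method2_hits <- function(results, manifest, config = consensus_config()) {
  m1 <- method1_hits(results, config)
  out <- overlap_hits(m1, manifest, "subcategory", config)
  rownames(out) <- NULL
  out
}

#' Method 3: overlap within a major category, with pleiotropy flags
#'
#' SNPs significant in at least `min_tests` distinct tests within the
#' chemical or the non-chemical major category. For each hit the set of
#' subcategories among its supporting tests is reported; a hit spanning
#' more than one subcategory is flagged pleiotropic.
#'
#' @param results Battery results.
#' @param manifest Battery manifest with `test_id`, `subcategory`,
#'   `major_category` columns.
#' @param config A [consensus_config()].
#' @return Data frame: snp_id, grouping (major category), n_supporting,
#'   supporting_tests, pleiotropy_subcategories, pleiotropic.
#' @export
method3_hits <- function(results, manifest, config = consensus_config()) {
  m1 <- method1_hits(results, config)
  out <- overlap_hits(m1, manifest, "major_category", config)
  if (!nrow(out)) {
    out$pleiotropy_subcategories <- character(0)
    out$pleiotropic <- logical(0)
    return(out)
  }
  subcat_of <- function(tests) {
    ids <- strsplit(tests, ",", fixed = TRUE)[[1]]
    sort(unique(manifest$subcategory[match(ids, manifest$test_id)]))
  }
  subs <- lapply(out$supporting_tests, subcat_of)
  out$pleiotropy_subcategories <- vapply(subs, paste, "", collapse = ",")
  out$pleiotropic <- lengths(subs) > 1L
  rownames(out) <- NULL
  out
}

#' Draw a uniformly random k-subset by partial Fisher-Yates shuffle
#'
#' The first `k` steps of an in-place Fisher-Yates shuffle: at step i an
#' element is swapped in from the untouched tail, so after k steps the
#' head is a uniformly random k-subset drawn without replacement.
#'
#' @param pool Vector to sample from.
#' @param k Subset size (`0 <= k <= length(pool)`).
#' @param seed Optional seed; `NULL` uses the current RNG stream.
#' @return A length-`k` vector.
#' @export
fisher_yates_subsample <- function(pool, k, seed = NULL) {
  n <- length(pool)
  k <- check_count(k, "k", min = 0)
  if (k > n) stopf("k (%d) exceeds pool size (%d)", k, n)
  with_seed(seed, {
    x <- pool
    for (i in seq_len(k)) {
      j <- i - 1L + sample.int(n - i + 1L, 1L)
      tmp <- x[i]; x[i] <- x[j]; x[j] <- tmp
    }
    x[seq_len(k)]
  })
}

#' Method 4: balanced bootstrap over one catalog
#'
#' Case/control imbalance is removed by subsampling the larger group,
#' without replacement via a Fisher-Yates shuffle, down to the size of
#' the smaller group. The allelic test is run for every SNP in each of
#' `n_bootstrap` balanced replicates; a SNP is a hit when it is
#' significant (`p <= alpha`) in at least `ceiling(retention *
#' n_bootstrap)` replicates. Each replicate uses its own seed spawned
#' from `config$seed` (offset by `seed_offset`), so replicates are
#' individually reproducible.
#'
#' @param panel A `genotype_panel`.
#' @param catalog A `cc_catalog` with at least 2 strains in each group.
#' @param config A [consensus_config()].
#' @param seed_offset Integer added to the replicate stream index,
#'   letting a battery of bootstraps give each catalog independent
#'   streams.
#' @return Data frame: snp_id, chrom, pos, n_significant, retention, hit.
#'   Attribute `"n_per_group"` records the balanced group size.
#' @export
method4_bootstrap <- function(panel, catalog, config = consensus_config(),
                              seed_offset = 0L) {
  n_case <- length(catalog$case_ids)
  n_ctrl <- length(catalog$control_ids)
  if (n_case < 2 || n_ctrl < 2) {
    stopf("catalog %s: need >= 2 strains per group", catalog$test_id)
  }
  k <- min(n_case, n_ctrl)
  fixed_ids <- if (n_case <= n_ctrl) catalog$case_ids else catalog$control_ids
  pool <- if (n_case <= n_ctrl) catalog$control_ids else catalog$case_ids
  B <- config$n_bootstrap
  subsets <- lapply(seq_len(B), function(b) {
    fisher_yates_subsample(pool, k,
                           seed = spawn_seed(config$seed, seed_offset + b))
  })
  m_fixed <- membership_matrix(panel$strains, list(fixed = fixed_ids))
  m_sub <- membership_matrix(panel$strains, subsets)
  fx <- battery_counts(panel$dosage, m_fixed)
  sb <- battery_counts(panel$dosage, m_sub)
  n_snps <- nrow(panel$variants)
  ## orient counts as case vs control (the test is label-symmetric)
  case_alt <- if (n_case <= n_ctrl) matrix(fx$alt, n_snps, B) else sb$alt
  case_ref <- if (n_case <= n_ctrl) matrix(fx$ref, n_snps, B) else sb$ref
  ctrl_alt <- if (n_case <= n_ctrl) sb$alt else matrix(fx$alt, n_snps, B)
  ctrl_ref <- if (n_case <= n_ctrl) sb$ref else matrix(fx$ref, n_snps, B)
  stat <- allelic_test(as.vector(case_alt), as.vector(case_ref),
                       as.vector(ctrl_alt), as.vector(ctrl_ref))
  sig <- matrix(!stat$untested & stat$p <= config$alpha, n_snps, B)
  n_sig <- rowSums(sig)
  need <- ceiling(config$retention * B)
  out <- data.frame(
    snp_id = panel$variants$snp_id, chrom = panel$variants$chrom,
    pos = panel$variants$pos, n_significant = as.integer(n_sig),
    retention = n_sig / B, hit = n_sig >= need,
    stringsAsFactors = FALSE, row.names = NULL
  )
  attr(out, "n_per_group") <- k
  out
}

#' Method 4 over a battery of catalogs
#'
#' Runs [method4_bootstrap()] for each catalog (each on its own spawned
#' seed block) and collects the hits.
#'
#' @param panel A `genotype_panel`.
#' @param catalogs Named list of `cc_catalog` objects.
#' @param config A [consensus_config()].
#' @return Data frame of hits: test_id, snp_id, chrom, pos,
#'   n_significant, retention. Attribute `"skipped"` names catalogs too
#'   small to bootstrap.
#' @export
method4_battery <- function(panel, catalogs, config = consensus_config()) {
  hits <- list()
  skipped <- character(0)
  for (i in seq_along(catalogs)) {
    cat_ <- catalogs[[i]]
    res <- tryCatch(
      method4_bootstrap(panel, cat_, config,
                        seed_offset = (i - 1L) * config$n_bootstrap),
      error = function(e) NULL
    )
    if (is.null(res)) {
      skipped <- c(skipped, cat_$test_id)
      next
    }
    h <- res[res$hit, , drop = FALSE]
    if (nrow(h)) {
      h$test_id <- cat_$test_id
      hits[[length(hits) + 1L]] <-
        h[, c("test_id", "snp_id", "chrom", "pos", "n_significant",
              "retention")]
    }
  }
  out <- if (length(hits)) do.call(rbind, hits) else
    data.frame(test_id = character(0), snp_id = character(0),
               chrom = character(0), pos = integer(0),
               n_significant = integer(0), retention = numeric(0))
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}
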
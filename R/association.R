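## Association module: 2x2 allele-count tables per (SNP, catalog) and the
## classic 1-df allelic chi-square test, run over the whole battery with
## one matrix product per group.

#' Build per-SNP allele-count tables for one catalog
#'
#' Each non-missing diploid genotype contributes `dosage` alternate and
#' `2 - dosage` reference alleles to its group; missing genotypes
#' contribute nothing.
#'
#' @param panel A `genotype_panel`.
#' @param catalog A `cc_catalog`; all its strains must exist in the panel.
#' @return Data frame: snp_id, case_alt, case_ref, control_alt,
#'   control_ref, call_rate (fraction of catalog strains with a call).
#' @export
allele_count_table <- function(panel, catalog) {
  unknown <- setdiff(c(catalog$case_ids, catalog$control_ids), panel$strains)
  if (length(unknown)) {
    stopf("catalog references unknown strain(s): %s",
          paste(head(unknown, 5), collapse = ", "))
  }
  counts_for <- function(ids) {
    d <- panel$dosage[ids, , drop = FALSE]
    alt <- colSums(d, na.rm = TRUE)
    called <- colSums(!is.na(d))
    list(alt = alt, ref = 2 * called - alt, called = called)
  }
  ca <- counts_for(catalog$case_ids)
  co <- counts_for(catalog$control_ids)
  n_strains <- length(catalog$case_ids) + length(catalog$control_ids)
  data.frame(
    snp_id = panel$variants$snp_id,
    case_alt = as.integer(ca$alt), case_ref = as.integer(ca$ref),
    control_alt = as.integer(co$alt), control_ref = as.integer(co$ref),
    call_rate = (ca$called + co$called) / n_strains,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' 1-df allelic chi-square test on 2x2 allele-count tables
#'
#' Pearson chi-square without continuity correction on the
#' case/control x alt/ref allele table — the classic allelic association
#' test. Vectorized over tables. Monomorphic tables (an allele absent
#' overall, or a group with no called alleles) are flagged `untested`
#' with `NA` statistics rather than raising. The odds ratio
#' `(case_alt * control_ref) / (case_ref * control_alt)` is reported only
#' when all four cells are positive. P-values that underflow are clamped
#' to the smallest positive double and flagged.
#'
#' @param case_alt,case_ref,control_alt,control_ref Non-negative allele
#'   counts (equal-length vectors).
#' @return Data frame: chisq, p, odds_ratio, untested, p_underflow.
#' @export
allelic_test <- function(case_alt, case_ref, control_alt, control_ref) {
  a <- as.numeric(case_alt); b <- as.numeric(case_ref)
  c_ <- as.numeric(control_alt); d <- as.numeric(control_ref)
  n <- a + b + c_ + d
  untested <- (a + c_ == 0) | (b + d == 0) | (a + b == 0) | (c_ + d == 0)
  chisq <- rep(NA_real_, length(a))
  ok <- !untested
  chisq[ok] <- n[ok] * (a[ok] * d[ok] - b[ok] * c_[ok])^2 /
    ((a[ok] + b[ok]) * (c_[ok] + d[ok]) * (a[ok] + c_[ok]) * (b[ok] + d[ok]))
  p <- pchisq(chisq, df = 1, lower.tail = FALSE)
  p_underflow <- !is.na(p) & p == 0
  p[p_underflow] <- .Machine$double.xmin
  or <- rep(NA_real_, length(a))
  pos <- ok & a > 0 & b > 0 & c_ > 0 & d > 0
  or[pos] <- (a[pos] * d[pos]) / (b[pos] * c_[pos])
  data.frame(chisq = chisq, p = p, odds_ratio = or,
             untested = untested, p_underflow = p_underflow)
}

## Fast allele counts for many strain sets at once: membership is a
## strains x sets 0/1 matrix; one crossprod per quantity.
battery_counts <- function(dosage, membership) {
  d0 <- dosage
  d0[is.na(d0)] <- 0
  called <- 1 - is.na(dosage)
  alt <- crossprod(d0, membership)        # snps x sets
  ncalled <- crossprod(called, membership)
  list(alt = alt, ref = 2 * ncalled - alt, called = ncalled)
}

membership_matrix <- function(strains, id_sets) {
  m <- matrix(0, nrow = length(strains), ncol = length(id_sets),
              dimnames = list(strains, names(id_sets)))
  for (j in seq_along(id_sets)) {
    m[match(id_sets[[j]], strains), j] <- 1
  }
  m
}

#' Run the allelic test for every (SNP, catalog) pair
#'
#' Allele counts for all catalogs are computed with dense matrix products
#' over group-membership indicators, so the full default-scale battery
#' (thousands of SNPs times hundreds of catalogs) runs in seconds.
#'
#' @param panel A `genotype_panel`.
#' @param catalogs Named list of `cc_catalog` objects (as produced by
#'   [enumerate_test_battery()]).
#' @param keep_untested Keep rows for monomorphic/uncallable markers
#'   (flagged) instead of dropping them. Default drops them but counts
#'   them in the attribute `"n_untested"`.
#' @return Long data frame: test_id, snp_id, chrom, pos, case_alt,
#'   case_ref, control_alt, control_ref, case_freq, control_freq,
#'   call_rate, chisq, p, odds_ratio. Attribute `"test_summary"` holds
#'   per-test minimum p and counts.
#' @export
run_battery <- function(panel, catalogs, keep_untested = FALSE) {
  if (!length(catalogs)) stopf("no catalogs supplied")
  strains <- panel$strains
  all_ids <- unique(unlist(lapply(catalogs, function(x)
    c(x$case_ids, x$control_ids))))
  unknown <- setdiff(all_ids, strains)
  if (length(unknown)) {
    stopf("catalog references unknown strain(s): %s",
          paste(head(unknown, 5), collapse = ", "))
  }
  m_case <- membership_matrix(strains, lapply(catalogs, `[[`, "case_ids"))
  m_ctrl <- membership_matrix(strains, lapply(catalogs, `[[`, "control_ids"))
  ca <- battery_counts(panel$dosage, m_case)
  co <- battery_counts(panel$dosage, m_ctrl)
  n_snps <- nrow(panel$variants)
  n_tests <- length(catalogs)
  group_n <- vapply(catalogs, function(x)
    length(x$case_ids) + length(x$control_ids), 0)
  res <- data.frame(
    test_id = rep(names(catalogs), each = n_snps),
    snp_id = rep(panel$variants$snp_id, n_tests),
    chrom = rep(panel$variants$chrom, n_tests),
    pos = rep(panel$variants$pos, n_tests),
    case_alt = as.vector(ca$alt), case_ref = as.vector(ca$ref),
    control_alt = as.vector(co$alt), control_ref = as.vector(co$ref),
    stringsAsFactors = FALSE
  )
  res$case_freq <- res$case_alt / (res$case_alt + res$case_ref)
  res$control_freq <- res$control_alt / (res$control_alt + res$control_ref)
  res$call_rate <- as.vector(ca$called + co$called) /
    rep(group_n, each = n_snps)
  stat <- allelic_test(res$case_alt, res$case_ref,
                       res$control_alt, res$control_ref)
  res <- cbind(res, stat)
  n_untested <- sum(res$untested)
  if (!keep_untested) res <- res[!res$untested, , drop = FALSE]
  rownames(res) <- NULL
  tested <- res[!res$untested, , drop = FALSE]
  min_p <- tapply(tested$p, factor(tested$test_id, levels = names(catalogs)),
                  function(p) if (length(p)) min(p) else NA_real_)
  attr(res, "test_summary") <- data.frame(
    test_id = names(catalogs),
    n_tested = as.vector(table(factor(tested$test_id,
                                      levels = names(catalogs)))),
    min_p = as.numeric(min_p),
    stringsAsFactors = FALSE, row.names = NULL
  )
  attr(res, "n_untested") <- n_untested
  res
}
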
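## Orchestration module: end-to-end driver tying phenotype encoding,
## variant filtering, the association battery, the consensus methods and
## the annotation stage together, with a run manifest for auditability.

#' Pipeline configuration
#'
#' A single configuration object naming the inputs and carrying every
#' analysis threshold as an explicit, defaulted field.
#'
#' @param vcf Path to the multi-sample VCF.
#' @param phenotype_dir Directory of per-source tab-separated trait
#'   tables (one `<source>.tsv` per source).
#' @param out_dir Output directory (created).
#' @param gff Optional GFF3 gene annotation for the proximity stage.
#' @param term_map Optional tab-separated gene-to-GO-term map.
#' @param filter A [filter_config()].
#' @param consensus A [consensus_config()].
#' @param categories Trait category scheme
#'   ([default_trait_categories()]).
#' @param fractions Percentile fractions for the battery.
#' @param min_strains Minimum non-missing strains per catalog.
#' @param min_sources Minimum sources for the averaged chemical trait.
#' @param ratio_numerator,ratio_denominator Ratio-trait components.
#' @param bootstrap_tests Which catalogs Method 4 bootstraps: "all" or a
#'   character vector of test_ids.
#' @param proximity_window Half-window in bp for gene proximity.
#' @param write_results Write the full long result table (can be large);
#'   the per-test summary is always written.
#' @param seed Master seed for the run.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(vcf, phenotype_dir, out_dir,
                            gff = NULL, term_map = NULL,
                            filter = filter_config(),
                            consensus = consensus_config(),
                            categories = default_trait_categories(),
                            fractions = c(0.05, 0.1, 0.25, 0.5),
                            min_strains = 10, min_sources = 2,
                            ratio_numerator = "CBN",
                            ratio_denominator = "THC",
                            bootstrap_tests = "all",
                            proximity_window = 25000,
                            write_results = FALSE,
                            seed = 1L) {
  structure(list(
    vcf = vcf, phenotype_dir = phenotype_dir, out_dir = out_dir,
    gff = gff, term_map = term_map, filter = filter,
    consensus = consensus, categories = categories,
    fractions = fractions, min_strains = min_strains,
    min_sources = min_sources, ratio_numerator = ratio_numerator,
    ratio_denominator = ratio_denominator,
    bootstrap_tests = bootstrap_tests,
    proximity_window = proximity_window,
    write_results = write_results, seed = as.integer(seed)
  ), class = "pipeline_config")
}

write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full association pipeline
#'
#' Stages, in order: load phenotypes, encode the test battery, read and
#' filter the VCF (bi-allelic -> hard filters -> LD prune), run the
#' allelic battery, call consensus hits by Methods 1-4, and (when an
#' annotation is supplied) interpret hits by gene proximity, chromosomal
#' distribution and GO over-representation. All tables, a JSON run
#' manifest with stage-wise record counts, and a YAML echo of the
#' configuration are written under `config$out_dir`.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the panel, battery, results, per-method
#'   hits, annotation products and the manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  for (p in c(config$vcf, config$phenotype_dir, config$gff, config$term_map)) {
    if (!is.null(p) && !file.exists(p)) stopf("input not found: %s", p)
  }
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = config$seed, stages = list())
  stage <- function(name, value) {
    manifest$stages[[name]] <<- value
  }

  ## 1. phenotypes -> battery ------------------------------------------
  files <- sort(list.files(config$phenotype_dir, pattern = "\\.tsv$",
                           full.names = TRUE))
  if (!length(files)) stopf("no .tsv phenotype tables in %s",
                            config$phenotype_dir)
  tables <- lapply(files, function(f)
    load_trait_table(f, sub("\\.tsv$", "", basename(f))))
  names(tables) <- sub("\\.tsv$", "", basename(files))
  battery <- enumerate_test_battery(
    tables, categories = config$categories, fractions = config$fractions,
    min_strains = config$min_strains, min_sources = config$min_sources,
    ratio_numerator = config$ratio_numerator,
    ratio_denominator = config$ratio_denominator
  )
  write_tsv(battery$manifest, file.path(out, "battery_manifest.tsv"))
  if (nrow(battery$excluded)) {
    write_tsv(battery$excluded, file.path(out, "battery_excluded.tsv"))
  }
  stage("encode", list(n_sources = length(tables),
                       n_tests = nrow(battery$manifest),
                       n_excluded = nrow(battery$excluded)))

  ## 2. variants --------------------------------------------------------
  panel <- read_vcf(config$vcf)
  n_raw <- nrow(panel$variants)
  panel <- filter_biallelic_snps(panel)
  n_biallelic <- nrow(panel$variants)
  panel <- apply_hard_filters(panel, config$filter)
  n_hard <- nrow(panel$variants)
  hard_counts <- attr(panel, "removal_counts")
  panel <- ld_prune(panel, config$filter)
  n_pruned <- nrow(panel$variants)
  write_tsv(attr(panel, "prune_report"), file.path(out, "prune_report.tsv"))
  stage("filter", list(
    n_raw = n_raw, n_biallelic = n_biallelic, n_after_hard_filters = n_hard,
    hard_filter_removals = as.list(hard_counts), n_after_ld_prune = n_pruned
  ))

  ## restrict catalogs to strains genotyped in the panel
  catalogs <- lapply(battery$catalogs, function(cat) {
    cat$case_ids <- intersect(cat$case_ids, panel$strains)
    cat$control_ids <- intersect(cat$control_ids, panel$strains)
    cat
  })
  usable <- vapply(catalogs, function(cat)
    length(cat$case_ids) >= 1 && length(cat$control_ids) >= 1, NA)
  catalogs <- catalogs[usable]

  ## 3. association battery --------------------------------------------
  results <- run_battery(panel, catalogs)
  summary_tab <- attr(results, "test_summary")
  summary_tab <- merge(battery$manifest, summary_tab, by = "test_id",
                       all.x = TRUE, sort = FALSE)
  write_tsv(summary_tab, file.path(out, "test_summary.tsv"))
  if (isTRUE(config$write_results)) {
    write_tsv(results, file.path(out, "association_results.tsv"))
  }
  stage("assoc", list(n_tests_run = length(catalogs),
                      n_results = nrow(results),
                      n_untested = attr(results, "n_untested")))

  ## 4. consensus -------------------------------------------------------
  ccfg <- config$consensus
  ccfg$seed <- spawn_seed(config$seed, 777L)
  m1 <- method1_hits(results, ccfg)
  m2 <- method2_hits(results, battery$manifest, ccfg)
  m3 <- method3_hits(results, battery$manifest, ccfg)
  boot_cats <- if (identical(config$bootstrap_tests, "all")) catalogs else
    catalogs[intersect(config$bootstrap_tests, names(catalogs))]
  m4 <- method4_battery(panel, boot_cats, ccfg)
  write_tsv(m1, file.path(out, "method1_hits.tsv"))
  write_tsv(m2, file.path(out, "method2_hits.tsv"))
  write_tsv(m3, file.path(out, "method3_hits.tsv"))
  write_tsv(m4, file.path(out, "method4_hits.tsv"))
  pleio <- m3[m3$pleiotropic, , drop = FALSE]
  write_tsv(pleio, file.path(out, "pleiotropy_report.tsv"))
  stage("consensus", list(
    method1 = nrow(m1), method1_snps = length(unique(m1$snp_id)),
    method2 = nrow(m2), method3 = nrow(m3), method4 = nrow(m4),
    n_bootstrapped_tests = length(boot_cats),
    pleiotropic = nrow(pleio)
  ))

  ## 5. annotation ------------------------------------------------------
  annotation <- NULL
  if (!is.null(config$gff)) {
    genes <- load_gff3(config$gff)
    sig_snps <- unique(m1$snp_id)
    snp_tab <- panel$variants[panel$variants$snp_id %in% sig_snps,
                              c("snp_id", "chrom", "pos"), drop = FALSE]
    prox <- genes_near_snp(snp_tab, genes, config$proximity_window)
    write_tsv(prox, file.path(out, "gene_proximity.tsv"))
    ## display category of a significant SNP: subcategory of its best test
    chrom_sum <- NULL
    if (nrow(m1)) {
      m1cat <- m1
      m1cat$category <- battery$manifest$subcategory[
        match(m1$test_id, battery$manifest$test_id)]
      best <- m1cat[order(m1cat$p, m1cat$test_id, method = "radix"), ]
      best <- best[!duplicated(best$snp_id), , drop = FALSE]
      cat_major <- battery$manifest$major_category
      names(cat_major) <- battery$manifest$subcategory
      cat_major <- cat_major[!duplicated(names(cat_major))]
      chrom_sum <- chromosome_summary(best, category_major = cat_major)
      write_tsv(chrom_sum$by_chromosome,
                file.path(out, "chromosome_summary.tsv"))
      write_tsv(chrom_sum$top_tally, file.path(out, "top5_tally.tsv"))
    }
    enrichment <- NULL
    if (!is.null(config$term_map) && nrow(prox)) {
      tm <- load_term_map(config$term_map)
      enrichment <- go_overrepresentation(
        unique(prox$gene_id), unique(genes$gene_id), tm
      )
      write_tsv(enrichment, file.path(out, "go_enrichment.tsv"))
    }
    annotation <- list(genes = genes, proximity = prox,
                       chromosome_summary = chrom_sum,
                       enrichment = enrichment)
    stage("annotate", list(
      n_genes = nrow(genes), n_proximity_pairs = nrow(prox),
      n_enriched_terms = if (is.null(enrichment)) 0L else
        sum(enrichment$flagged)
    ))
  }

  yaml::write_yaml(config_to_list(config), file.path(out, "config_echo.yaml"))
  jsonlite::write_json(manifest, file.path(out, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(
    panel = panel, battery = battery, catalogs = catalogs,
    results = results, test_summary = summary_tab,
    hits = list(method1 = m1, method2 = m2, method3 = m3, method4 = m4),
    annotation = annotation, manifest = manifest, config = config
  ))
}

config_to_list <- function(config) {
  cl <- unclass(config)
  cl$filter <- unclass(cl$filter)
  cl$consensus <- unclass(cl$consensus)
  cl$categories <- NULL # data frame; echoed via the manifest tables
  cl
}

#' Summarize a pipeline run
#'
#' Tabulates hits per method split by major category and subcategory (the
#' data behind a per-method bar chart) and the case-size versus
#' minimum-p relationship across tests, and renders a short plain-text
#' report.
#'
#' @param run The (invisible) return value of [run_pipeline()].
#' @return List with `per_method` (data frame of hit counts by method and
#'   major category), `per_subcategory`, `case_size` (per-test case size
#'   and minimum p) and `text` (character vector of report lines).
#' @export
summarize_run <- function(run) {
  man <- run$battery$manifest
  sub_of <- function(ids) man$subcategory[match(ids, man$test_id)]
  maj_of <- function(ids) man$major_category[match(ids, man$test_id)]
  count_by <- function(ids, snps, label) {
    if (!length(ids)) {
      return(data.frame(method = character(0), group = character(0),
                        n_hits = integer(0)))
    }
    tab <- table(label)
    data.frame(method = character(length(tab)), group = names(tab),
               n_hits = as.integer(tab), stringsAsFactors = FALSE)
  }
  per_method <- list()
  add <- function(method, group_labels) {
    if (!length(group_labels)) {
      per_method[[length(per_method) + 1L]] <<- data.frame(
        method = method, group = c("chemical", "non-chemical"),
        n_hits = c(0L, 0L), stringsAsFactors = FALSE)
      return()
    }
    tab <- table(factor(group_labels, levels = c("chemical", "non-chemical")))
    per_method[[length(per_method) + 1L]] <<- data.frame(
      method = method, group = names(tab), n_hits = as.integer(tab),
      stringsAsFactors = FALSE)
  }
  h <- run$hits
  add("method1", maj_of(h$method1$test_id))
  add("method2", h$method2$grouping)
  add("method3", h$method3$grouping)
  add("method4", maj_of(h$method4$test_id))
  per_method <- do.call(rbind, per_method)

  sub_counts <- table(sub_of(h$method1$test_id))
  per_subcategory <- data.frame(
    subcategory = names(sub_counts),
    method1_hits = as.integer(sub_counts), stringsAsFactors = FALSE
  )
  if (!nrow(per_subcategory)) {
    per_subcategory <- data.frame(subcategory = character(0),
                                  method1_hits = integer(0))
  }
  case_size <- run$test_summary[, c("test_id", "n_case", "n_control",
                                    "min_p")]
  text <- c(
    sprintf("tests run: %d", nrow(run$test_summary)),
    sprintf("SNPs analyzed: %d", nrow(run$panel$variants)),
    vapply(split(per_method, per_method$method), function(d) {
      sprintf("%s hits: chemical %d, non-chemical %d", d$method[1],
              d$n_hits[d$group == "chemical"],
              d$n_hits[d$group == "non-chemical"])
    }, "")
  )
  list(per_method = per_method, per_subcategory = per_subcategory,
       case_size = case_size, text = text)
}
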
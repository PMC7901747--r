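## Phenotype catalog module: load per-source trait tables, average chemical
## values across sources, derive the ratio trait, and encode every trait
## into reciprocal percentile case/control catalogs forming the test
## battery.

#' Load a strain-by-trait table from a tab-separated file
#'
#' Expects a header row containing a `strain_id` column; every other
#' column is a trait. Cells that cannot be parsed as numbers in an
#' otherwise numeric column (e.g. "n/a", "") become missing with a
#' warning, never zero.
#'
#' @param path Path to a tab-separated file.
#' @param source_name Identifier recorded on the table.
#' @return A data frame (attribute `"source"` set) with unique strain_ids.
#' @export
load_trait_table <- function(path, source_name) {
  tab <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE, na.strings = c("NA", ""),
                    colClasses = "character")
  if (!"strain_id" %in% names(tab)) {
    stopf("%s: no 'strain_id' column in header", path)
  }
  if (anyDuplicated(tab$strain_id)) {
    stopf("%s: duplicate strain_id(s): %s", path,
          paste(unique(tab$strain_id[duplicated(tab$strain_id)]),
                collapse = ", "))
  }
  for (col in setdiff(names(tab), "strain_id")) {
    raw <- tab[[col]]
    num <- suppressWarnings(as.numeric(raw))
    bad <- !is.na(raw) & is.na(num)
    if (any(bad) && !all(bad)) {
      warning(sprintf("%s: %d unparseable cell(s) in column '%s' set missing",
                      path, sum(bad), col), call. = FALSE)
    }
    ## keep column character only if nothing parses; else numeric with NAs
    if (!all(is.na(num) | bad) || all(is.na(raw))) tab[[col]] <- num
  }
  attr(tab, "source") <- source_name
  tab
}

#' Average a chemical trait across sources
#'
#' Per strain, the arithmetic mean over the sources reporting a value,
#' emitted only when at least `min_sources` sources report (default 2:
#' values seen by a single source are excluded from the averaged trait).
#'
#' @param tables Named list of strain-by-trait data frames.
#' @param trait Trait (column) name.
#' @param min_sources Minimum number of reporting sources.
#' @return Data frame `strain_id`, `value` restricted to strains meeting
#'   `min_sources`.
#' @export
average_chemical_values <- function(tables, trait, min_sources = 2) {
  have <- vapply(tables, function(t) trait %in% names(t), NA)
  if (!any(have)) stopf("trait '%s' absent from all tables", trait)
  vals <- list()
  for (t in tables[have]) {
    ok <- !is.na(t[[trait]])
    vals[[length(vals) + 1L]] <- data.frame(strain_id = t$strain_id[ok],
                                            value = t[[trait]][ok])
  }
  all <- do.call(rbind, vals)
  agg <- stats::aggregate(value ~ strain_id, data = all,
                          FUN = function(v) c(mean = mean(v), n = length(v)))
  out <- data.frame(strain_id = agg$strain_id,
                    value = agg$value[, "mean"],
                    n_sources = agg$value[, "n"],
                    stringsAsFactors = FALSE)
  out <- out[out$n_sources >= min_sources, c("strain_id", "value")]
  out <- out[order(out$strain_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Add a chemical ratio trait column
#'
#' The ratio is defined only where both components are present and the
#' denominator is strictly positive; elsewhere it is missing. Which
#' chemical is the numerator and which the denominator is configuration,
#' not hard-coded.
#'
#' @param table Strain-by-trait data frame.
#' @param numerator,denominator Trait column names.
#' @param name Name for the new column (default "ratio").
#' @return `table` with the ratio column added.
#' @export
compute_chemical_ratio <- function(table, numerator, denominator,
                                   name = "ratio") {
  if (!numerator %in% names(table) || !denominator %in% names(table)) {
    stopf("numerator/denominator column missing from table")
  }
  num <- table[[numerator]]
  den <- table[[denominator]]
  r <- ifelse(!is.na(num) & !is.na(den) & den > 0, num / den, NA_real_)
  table[[name]] <- r
  table
}

#' Encode one trait into a percentile case/control catalog
#'
#' Strains with a non-missing value are ranked; the ceiling(fraction * m)
#' most extreme strains in the requested direction become cases, every
#' other non-missing strain a control. Ties at the cut are broken by
#' stable (value, strain_id) order so the encoding is deterministic.
#' Binary 0/1 traits admit only the direct encoding (cases = 1), via
#' `direction = "binary"`.
#'
#' @param table Data frame with `strain_id` and the trait column.
#' @param trait Trait column name.
#' @param direction "top", "bottom", or "binary".
#' @param fraction One of 0.05, 0.10, 0.25, 0.50 (ignored for binary).
#' @param source Source label carried into the test_id.
#' @param allowed_fractions Permitted fractions.
#' @return A list of class `cc_catalog`: test_id, trait, source,
#'   direction, fraction, case_ids, control_ids.
#' @export
encode_case_control <- function(table, trait, direction,
                                fraction = NULL, source = "source",
                                allowed_fractions = c(0.05, 0.1, 0.25, 0.5)) {
  if (!trait %in% names(table)) stopf("trait '%s' not in table", trait)
  ok <- !is.na(table[[trait]])
  ids <- table$strain_id[ok]
  vals <- table[[trait]][ok]
  m <- length(ids)
  if (m < 2) stopf("need >= 2 strains with non-missing '%s' (got %d)", trait, m)
  if (direction == "binary") {
    case_ids <- ids[vals == 1]
    control_ids <- ids[vals == 0]
    if (!length(case_ids) || !length(control_ids)) {
      stopf("binary trait '%s' has an empty case or control group", trait)
    }
    test_id <- paste(trait, source, "binary", "na", sep = "|")
    fraction <- NA_real_
  } else {
    if (!direction %in% c("top", "bottom")) {
      stopf("direction must be 'top', 'bottom' or 'binary'")
    }
    if (is.null(fraction) ||
        !any(abs(fraction - allowed_fractions) < 1e-12)) {
      stopf("fraction must be one of {%s}",
            paste(allowed_fractions, collapse = ", "))
    }
    n_case <- as.integer(ceiling(fraction * m))
    ord <- if (direction == "top") {
      order(-vals, ids, method = "radix")
    } else {
      order(vals, ids, method = "radix")
    }
    case_ids <- ids[ord[seq_len(n_case)]]
    control_ids <- ids[ord[seq.int(n_case + 1L, m)]]
    test_id <- paste(trait, source, direction,
                     sprintf("%g", fraction * 100), sep = "|")
  }
  structure(list(
    test_id = test_id, trait = trait, source = source,
    direction = direction, fraction = fraction,
    case_ids = sort(case_ids), control_ids = sort(control_ids)
  ), class = "cc_catalog")
}

#' @export
print.cc_catalog <- function(x, ...) {
  cat(sprintf("cc_catalog %s: %d cases / %d controls\n",
              x$test_id, length(x$case_ids), length(x$control_ids)))
  invisible(x)
}

#' Default trait-to-category scheme
#'
#' Maps the canonical chemical traits and common anecdotal trait groups to
#' the subcategory / major-category scheme used by the consensus methods.
#' Traits absent from the scheme default to a non-chemical subcategory
#' named after the trait.
#'
#' @return Data frame with columns trait, subcategory, major_category.
#' @export
default_trait_categories <- function() {
  data.frame(
    trait = c("CBD", "THC", "CBN", "ratio",
              "grow", "taste", "affect", "medical", "sativa_indica"),
    subcategory = c("CBD content", "THC content", "CBN content", "ratio",
                    "Growth", "Taste", "Affect", "Medical", "Sativa/Indica"),
    major_category = c(rep("chemical", 4), rep("non-chemical", 5)),
    stringsAsFactors = FALSE
  )
}

category_for <- function(trait, categories) {
  i <- match(trait, categories$trait)
  if (is.na(i)) {
    c(subcategory = trait, major_category = "non-chemical")
  } else {
    c(subcategory = categories$subcategory[i],
      major_category = categories$major_category[i])
  }
}

#' Enumerate the full case/control test battery
#'
#' Cartesian generation of (trait x source x direction x fraction)
#' catalogs. Quantitative traits get both reciprocal directions at every
#' fraction; chemical traits additionally get a cross-source "averaged"
#' pseudo-source (mean over sources reporting, at least `min_sources` of
#' them); binary traits get the single direct encoding per source. The
#' ratio trait is computed per source from the configured
#' numerator/denominator before encoding. Catalogs whose trait has fewer
#' than `min_strains` non-missing strains are excluded (and logged in the
#' manifest of exclusions), reflecting that very small case/control
#' groups produce effectively random associations.
#'
#' @param tables Named list of per-source strain-by-trait data frames.
#' @param categories Trait category scheme as
#'   [default_trait_categories()].
#' @param fractions Percentile fractions for quantitative traits.
#' @param min_strains Minimum non-missing strain count per catalog.
#' @param min_sources Minimum reporting sources for the averaged trait.
#' @param ratio_numerator,ratio_denominator Components of the ratio
#'   trait; set either to `NULL` to skip the ratio.
#' @param binary_traits Optional character vector naming traits to encode
#'   as binary; by default traits whose observed values are all 0/1.
#' @return List with `catalogs` (named list of `cc_catalog`), `manifest`
#'   (one row per catalog: test_id, trait, source, direction, fraction,
#'   subcategory, major_category, n_case, n_control) and `excluded`
#'   (trait/source pairs dropped by `min_strains`).
#' @export
enumerate_test_battery <- function(tables,
                                   categories = default_trait_categories(),
                                   fractions = c(0.05, 0.1, 0.25, 0.5),
                                   min_strains = 10,
                                   min_sources = 2,
                                   ratio_numerator = "CBN",
                                   ratio_denominator = "THC",
                                   binary_traits = NULL) {
  if (!length(tables)) stopf("no phenotype tables supplied")
  if (is.null(names(tables)) || any(!nzchar(names(tables)))) {
    stopf("tables must be a named list (one name per source)")
  }
  ## derive the ratio trait in every source table that has both components
  if (!is.null(ratio_numerator) && !is.null(ratio_denominator)) {
    tables <- lapply(tables, function(t) {
      if (all(c(ratio_numerator, ratio_denominator) %in% names(t))) {
        compute_chemical_ratio(t, ratio_numerator, ratio_denominator)
      } else t
    })
  }
  traits <- unique(unlist(lapply(tables, function(t)
    setdiff(names(t), "strain_id"))))
  is_binary <- function(trait) {
    if (!is.null(binary_traits)) return(trait %in% binary_traits)
    vals <- unlist(lapply(tables, function(t)
      if (trait %in% names(t)) t[[trait]] else NULL))
    vals <- vals[!is.na(vals)]
    length(vals) > 0 && all(vals %in% c(0, 1))
  }

  catalogs <- list()
  manifest <- list()
  excluded <- list()
  add <- function(cat, subcat, major) {
    catalogs[[cat$test_id]] <<- cat
    manifest[[length(manifest) + 1L]] <<- data.frame(
      test_id = cat$test_id, trait = cat$trait, source = cat$source,
      direction = cat$direction, fraction = cat$fraction,
      subcategory = subcat, major_category = major,
      n_case = length(cat$case_ids), n_control = length(cat$control_ids),
      stringsAsFactors = FALSE
    )
  }
  note_excluded <- function(trait, source, m) {
    excluded[[length(excluded) + 1L]] <<- data.frame(
      trait = trait, source = source, n_nonmissing = m,
      stringsAsFactors = FALSE)
  }

  for (trait in traits) {
    cc <- category_for(trait, categories)
    chem <- cc[["major_category"]] == "chemical"
    binary <- is_binary(trait)
    views <- list()
    for (src in names(tables)) {
      t <- tables[[src]]
      if (trait %in% names(t)) {
        views[[src]] <- data.frame(strain_id = t$strain_id,
                                   value = t[[trait]],
                                   stringsAsFactors = FALSE)
      }
    }
    if (chem && !binary && length(views) >= min_sources) {
      sub <- lapply(views, function(v) {
        d <- v; names(d)[2] <- trait; d
      })
      views[["averaged"]] <- average_chemical_values(sub, trait, min_sources)
    }
    for (src in names(views)) {
      v <- views[[src]]
      names(v)[2] <- trait
      m <- sum(!is.na(v[[trait]]))
      if (m < min_strains) {
        note_excluded(trait, src, m)
        next
      }
      if (binary) {
        cat <- tryCatch(
          encode_case_control(v, trait, "binary", source = src),
          error = function(e) NULL
        )
        if (is.null(cat)) { note_excluded(trait, src, m); next }
        add(cat, cc[["subcategory"]], cc[["major_category"]])
      } else {
        for (dir in c("top", "bottom")) {
          for (f in fractions) {
            add(encode_case_control(v, trait, dir, f, source = src,
                                    allowed_fractions = fractions),
                cc[["subcategory"]], cc[["major_category"]])
          }
        }
      }
    }
  }
  manifest <- if (length(manifest)) do.call(rbind, manifest) else
    data.frame(test_id = character(0))
  excluded <- if (length(excluded)) do.call(rbind, excluded) else
    data.frame(trait = character(0))
  list(catalogs = catalogs, manifest = manifest, excluded = excluded)
}
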
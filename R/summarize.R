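#' Percentages along the database-construction funnel
#'
#' Computes the reduction percentages a panel-of-normals build report quotes:
#' the fraction of raw variants removed by the quality filter, the fraction
#' of quality variants depleted by the SNP catalog, the fraction of the
#' remainder depleted by the somatic catalog, and the final database size.
#' Every percentage is returned alongside the numerator and denominator it
#' was computed from.
#'
#' @param stats A `funnel_stats` object, or `NULL` if explicit counts are
#'   given.
#' @param n_raw,n_quality,n_removed_snp_catalog,n_removed_somatic_catalog
#'   Explicit stage counts, used when `stats` is `NULL`. `n_raw` may be `NA`
#'   when only the post-merge stages are known.
#' @return A tibble with columns `stage`, `entering`, `removed`, `remaining`
#'   and `percent_removed` (1 decimal; `NA` when the denominator is zero or
#'   unknown — never reported as 0).
#' @export
#' @examples
#' funnel_percentages(n_raw = 15015608, n_quality = 1422336,
#'                    n_removed_snp_catalog = 1305937,
#'                    n_removed_somatic_catalog = 2090)
funnel_percentages <- function(stats = NULL, n_raw = NA, n_quality = NULL,
                               n_removed_snp_catalog = NULL,
                               n_removed_somatic_catalog = NULL) {
  if (!is.null(stats)) {
    stopifnot(inherits(stats, "funnel_stats"))
    n_raw <- stats$n_raw
    n_quality <- stats$n_quality
    n_removed_snp_catalog <- stats$n_removed_snp_catalog
    n_removed_somatic_catalog <- stats$n_removed_somatic_catalog
  }
  n_post_snp <- n_quality - n_removed_snp_catalog
  n_final <- n_post_snp - n_removed_somatic_catalog
  if (any(c(n_quality, n_removed_snp_catalog, n_removed_somatic_catalog,
            n_post_snp, n_final) < 0, na.rm = TRUE)) {
    stop("funnel counts must be non-negative and non-increasing", call. = FALSE)
  }
  pct <- function(removed, entering) {
    ifelse(is.na(entering) | entering == 0, NA_real_,
           round(100 * removed / entering, 1))
  }
  tibble::tibble(
    stage = c("quality_filter", "snp_catalog", "somatic_catalog"),
    entering = c(n_raw, n_quality, n_post_snp),
    removed = c(if (is.na(n_raw)) NA_real_ else n_raw - n_quality,
                n_removed_snp_catalog, n_removed_somatic_catalog),
    remaining = c(n_quality, n_post_snp, n_final),
    percent_removed = c(pct(n_raw - n_quality, n_raw),
                        pct(n_removed_snp_catalog, n_quality),
                        pct(n_removed_somatic_catalog, n_post_snp))
  )
}

#' Tumor-cohort reduction statistics
#'
#' Reproduces, from a cancer type's variant counts, the percentages a
#' subtraction study tabulates: the fraction of all tumor variants that
#' remain after public-SNP-catalog depletion, the fraction remaining after
#' the additional panel-of-normals depletion, and the additional reduction
#' the panel achieves on top of the public catalog
#' (`100 * (post_catalog - post_pon) / post_catalog`).
#'
#' @param n_total Total raw tumor variants for the cohort.
#' @param n_post_catalog Variants remaining after public-catalog depletion.
#' @param n_post_pon Variants remaining after additional panel-of-normals
#'   depletion.
#' @return A one-row tibble with the three counts, `percent_post_catalog`,
#'   `percent_post_pon` (both of `n_total`, 1 decimal) and
#'   `percent_additional_reduction` (1 decimal). Zero denominators yield
#'   `NA`, never 0.
#' @export
#' @examples
#' subtraction_reduction(613055, 84001, 48182)
subtraction_reduction <- function(n_total, n_post_catalog, n_post_pon) {
  stopifnot(length(n_total) == length(n_post_catalog),
            length(n_total) == length(n_post_pon))
  if (any(n_post_catalog > n_total | n_post_pon > n_post_catalog |
          n_post_pon < 0, na.rm = TRUE)) {
    stop("counts must satisfy total >= post_catalog >= post_pon >= 0",
         call. = FALSE)
  }
  pct <- function(num, den) ifelse(den == 0, NA_real_, round(100 * num / den, 1))
  tibble::tibble(
    n_total = n_total,
    n_post_catalog = n_post_catalog,
    n_post_pon = n_post_pon,
    percent_post_catalog = pct(n_post_catalog, n_total),
    percent_post_pon = pct(n_post_pon, n_total),
    percent_additional_reduction = pct(n_post_catalog - n_post_pon,
                                       n_post_catalog)
  )
}

#' Cohort minor allele frequency of a database entry
#'
#' The alternate allele frequency is `alt_allele_count / (2 * cohort_size)`,
#' the standard diploid cohort convention in which samples without a call at
#' the site count as homozygous reference; the minor allele frequency folds
#' it into `[0, 0.5]` as `min(f, 1 - f)`. Sex-chromosome ploidy is not
#' special-cased.
#'
#' @param alt_allele_count Total alternate allele copies across carriers
#'   (vectorized).
#' @param cohort_size Number of samples in the normal cohort (> 0).
#' @return Numeric vector of minor allele frequencies in `[0, 0.5]`.
#' @export
#' @examples
#' cohort_allele_frequency(1, 62)   # a singleton het among 62 samples
cohort_allele_frequency <- function(alt_allele_count, cohort_size) {
  cohort_size <- as.integer(cohort_size)
  if (is.na(cohort_size) || cohort_size < 1L) {
    stop("cohort_size must be a positive integer", call. = FALSE)
  }
  if (any(alt_allele_count < 0 | alt_allele_count > 2 * cohort_size)) {
    stop("alt_allele_count must lie in [0, 2 * cohort_size]", call. = FALSE)
  }
  f <- alt_allele_count / (2 * cohort_size)
  pmin(f, 1 - f)
}

#' Minor allele frequency spectrum of a panel-of-normals database
#'
#' Bins every database variant's cohort minor allele frequency into
#' half-open intervals `[lo, hi)` (the last bin closed at 0.5) and reports
#' the percentage of the database per bin.
#'
#' @param db A `pon_database` with a known `cohort_size`.
#' @param bin_edges Ordered breakpoints in `[0, 0.5]`; the default
#'   `c(0, 0.01, 0.02, 0.03, 0.04, 0.05, 0.10, 0.25, 0.5)` emphasises the
#'   rare-variant end of the spectrum where such a database concentrates.
#' @return A `maf_spectrum` tibble with columns `bin_lo`, `bin_hi`, `n` and
#'   `percent`; percentages sum to 100 up to rounding.
#' @export
maf_spectrum <- function(db,
                         bin_edges = c(0, 0.01, 0.02, 0.03, 0.04, 0.05,
                                       0.10, 0.25, 0.5)) {
  stopifnot(inherits(db, "pon_database"))
  if (nrow(db$entries) == 0L) {
    stop("nothing to summarize: the database is empty", call. = FALSE)
  }
  bin_edges <- sort(unique(as.numeric(bin_edges)))
  if (length(bin_edges) < 2L || bin_edges[1] < 0 ||
      bin_edges[length(bin_edges)] > 0.5) {
    stop("bin_edges must be >= 2 ordered breakpoints within [0, 0.5]",
         call. = FALSE)
  }
  maf <- cohort_allele_frequency(db$entries$alt_allele_count, db$cohort_size)
  if (any(maf < bin_edges[1] | maf > bin_edges[length(bin_edges)])) {
    stop("bin_edges do not cover the observed frequency range", call. = FALSE)
  }
  # half-open [lo, hi); findInterval with rightmost.closed keeps 0.5 in the
  # last bin
  bin <- findInterval(maf, bin_edges, rightmost.closed = TRUE)
  n <- tabulate(bin, nbins = length(bin_edges) - 1L)
  out <- tibble::tibble(
    bin_lo = bin_edges[-length(bin_edges)],
    bin_hi = bin_edges[-1],
    n = n,
    percent = 100 * n / length(maf)
  )
  class(out) <- c("maf_spectrum", class(out))
  out
}

#' Per-chromosome novelty of a database versus a reference catalog
#'
#' For each chromosome, the database's `n_new` variants are compared with the
#' reference catalog's `n_reference` variants on that chromosome:
#' `percent_new = 100 * n_new / (n_new + n_reference)`, the share of the
#' combined per-chromosome variant pool that the database newly contributes.
#'
#' @param db A `pon_database`.
#' @param reference_counts Named integer vector or two-column data frame
#'   (`chrom`, `n_reference`) of reference-catalog variant counts per
#'   chromosome; must cover every database chromosome.
#' @return A tibble with columns `chrom`, `n_new`, `n_reference` and
#'   `percent_new` (`NA` where both counts are zero, never reported as 0).
#' @export
chromosome_novelty <- function(db, reference_counts) {
  stopifnot(inherits(db, "pon_database"))
  if (is.data.frame(reference_counts)) {
    ref <- stats::setNames(as.integer(reference_counts$n_reference),
                           normalize_chrom(reference_counts$chrom))
  } else {
    ref <- stats::setNames(as.integer(reference_counts),
                           normalize_chrom(names(reference_counts)))
  }
  new_counts <- table(db$entries$chrom)
  missing <- setdiff(names(new_counts), names(ref))
  if (length(missing) > 0L) {
    stop("reference_counts lack database chromosome(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  chroms <- union(names(ref), names(new_counts))
  ord <- order(match(chroms, c(as.character(1:22), "X", "Y", "MT"),
                     nomatch = 99L), chroms)
  chroms <- chroms[ord]
  n_new <- as.integer(new_counts[chroms])
  n_new[is.na(n_new)] <- 0L
  n_ref <- as.integer(ref[chroms])
  n_ref[is.na(n_ref)] <- 0L
  total <- n_new + n_ref
  tibble::tibble(
    chrom = chroms,
    n_new = n_new,
    n_reference = n_ref,
    percent_new = ifelse(total == 0, NA_real_, 100 * n_new / total)
  )
}

# variant classes counted as non-synonymous when no explicit
# non_synonymous/synonymous labels are provided
.ns_classes <- c("missense", "nonsense", "splice_site")
.s_classes <- c("silent")

#' Summarize functional annotation classes and genomic regions
#'
#' Consumes a pre-computed annotation table (this package does not annotate)
#' and tallies variant classes and genomic regions, including the
#' non-synonymous/synonymous (NS/S) ratio that characterises coding
#' variation in exome cohorts (about 2 for neutral random coding changes,
#' lower under purifying selection).
#'
#' @param annotations A data frame with columns `variant_class` and/or
#'   `region` (extra columns such as the variant key are ignored). Class
#'   labels are matched case-insensitively with spaces/hyphens mapped to
#'   underscores; recognised classes are `non_synonymous`, `synonymous`,
#'   `missense`, `silent`, `nonsense`, `splice_site`, `indel` (others are
#'   kept and counted under their own label). NS and S totals use explicit
#'   `non_synonymous`/`synonymous` labels when present, otherwise NS =
#'   missense + nonsense + splice_site and S = silent.
#' @return An `annotation_summary` list with tibbles `classes` and `regions`
#'   (each label, count and percent of total), `n_total`, `n_ns`, `n_s` and
#'   `ns_s_ratio` (unrounded; `NA` when S = 0; conventionally reported to 2
#'   decimals).
#' @export
#' @examples
#' annotation_summary(data.frame(
#'   variant_class = c(rep("non_synonymous", 11466), rep("synonymous", 6507))
#' ))$ns_s_ratio
annotation_summary <- function(annotations) {
  annotations <- as.data.frame(annotations)
  if (nrow(annotations) == 0L) {
    stop("nothing to summarize: the annotation table is empty", call. = FALSE)
  }
  norm_label <- function(x) gsub("[ -]", "_", tolower(trimws(as.character(x))))
  n_total <- nrow(annotations)
  tally <- function(labels) {
    t <- sort(table(labels), decreasing = TRUE)
    tibble::tibble(label = names(t), n = as.integer(t),
                   percent = 100 * as.integer(t) / n_total)
  }
  classes <- regions <- NULL
  n_ns <- n_s <- NA_integer_
  if ("variant_class" %in% names(annotations)) {
    cl <- norm_label(annotations$variant_class)
    classes <- tally(cl)
    if (any(cl %in% c("non_synonymous", "synonymous"))) {
      n_ns <- sum(cl == "non_synonymous")
      n_s <- sum(cl == "synonymous")
    } else {
      n_ns <- sum(cl %in% .ns_classes)
      n_s <- sum(cl %in% .s_classes)
    }
  }
  if ("region" %in% names(annotations)) {
    regions <- tally(norm_label(annotations$region))
  }
  if (is.null(classes) && is.null(regions)) {
    stop("annotation table has neither 'variant_class' nor 'region' column",
         call. = FALSE)
  }
  structure(list(
    classes = classes,
    regions = regions,
    n_total = n_total,
    n_ns = n_ns,
    n_s = n_s,
    ns_s_ratio = if (!is.na(n_s) && n_s > 0) n_ns / n_s else NA_real_
  ), class = "annotation_summary")
}

#' @export
print.annotation_summary <- function(x, ...) {
  cat("<annotation_summary> ", x$n_total, " variant(s)\n", sep = "")
  if (!is.na(x$ns_s_ratio)) {
    cat(sprintf("  NS/S ratio: %d / %d = %.2f\n", x$n_ns, x$n_s, x$ns_s_ratio))
  }
  invisible(x)
}

#' Write a plain-text funnel report
#'
#' @param db A `pon_database` whose funnel is populated.
#' @param path Output text file.
#' @return `path`, invisibly.
#' @export
write_funnel_report <- function(db, path) {
  stopifnot(inherits(db, "pon_database"), !is.null(db$funnel))
  pcts <- funnel_percentages(db$funnel)
  con <- textConnection("rep_lines", "w", local = TRUE)
  sink(con); print(db$funnel); sink()
  close(con)
  lines <- c(rep_lines, "",
             sprintf("stage %-16s entering %10s removed %9s (%s%%)",
                     pcts$stage, format(pcts$entering, big.mark = ","),
                     format(pcts$removed, big.mark = ","),
                     ifelse(is.na(pcts$percent_removed), "NA",
                            format(pcts$percent_removed))))
  writeLines(lines, path)
  invisible(path)
}
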
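#' Quality-filter parameters for the panel-of-normals builder
#'
#' The builder retains a cohort variant when any carrier shows at least
#' `min_alt_depth` reads supporting the alternate allele, or — rescuing
#' shallow but consistently seen sites — when it recurs in at least
#' `min_recurrence` distinct normal samples. The defaults (5 reads, 4
#' samples) are the standard exome panel-of-normals settings.
#'
#' @param min_alt_depth Minimum alt-supporting read depth, default 5.
#' @param min_recurrence Minimum number of distinct carrier samples for the
#'   recurrence rescue, default 4.
#' @return A `filter_params` list.
#' @export
filter_params <- function(min_alt_depth = 5L, min_recurrence = 4L) {
  min_alt_depth <- as.integer(min_alt_depth)
  min_recurrence <- as.integer(min_recurrence)
  if (is.na(min_alt_depth) || min_alt_depth < 1L ||
      is.na(min_recurrence) || min_recurrence < 1L) {
    stop("filter_params thresholds must be integers >= 1", call. = FALSE)
  }
  structure(list(min_alt_depth = min_alt_depth,
                 min_recurrence = min_recurrence),
            class = "filter_params")
}

.as_vcf_document <- function(x) {
  if (inherits(x, "vcf_document")) x else read_vcf(x)
}

#' Merge normal-sample VCFs into a cohort table
#'
#' Normalizes every document to allele-aware observations and aggregates them
#' per variant key across the whole normal cohort. A sample contributes at
#' most once to a key's recurrence regardless of genotype or duplicated
#' lines; its allele-copy contribution (het = 1, hom_alt = 2) is likewise
#' counted once.
#'
#' @param normals List of `vcf_document` objects or VCF file paths. Sample
#'   identifiers are the VCF sample column names; they must be unique across
#'   the cohort.
#' @return A `cohort_table`: a tibble with one row per unique variant key and
#'   columns `chrom`, `pos`, `ref`, `alt`, `key`, `recurrence` (distinct
#'   carrier samples), `alt_allele_count` (total alt allele copies across
#'   carriers), `max_alt_depth` (maximum known alt depth across carriers,
#'   `NA` when no carrier has usable AD), and `carrier_ids`
#'   (comma-separated). The number of samples merged is attached as
#'   attribute `cohort_size`, the sample names as attribute `sample_ids`.
#' @export
merge_cohort <- function(normals) {
  if (length(normals) == 0L) {
    stop("merge_cohort requires at least one normal VCF", call. = FALSE)
  }
  docs <- lapply(normals, .as_vcf_document)
  ids <- unlist(lapply(docs, function(d) d$samples), use.names = FALSE)
  if (anyDuplicated(ids)) {
    stop("duplicate sample id(s) across normal VCFs: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  .merge_observations(lapply(docs, normalize_observations), ids)
}

# aggregate per-document observation tables into the cohort table
.merge_observations <- function(obs_list, ids) {
  obs <- dplyr::bind_rows(obs_list)
  if (nrow(obs) > 0L) {
    # duplicate lines for the same (key, sample) collapse to one carrier;
    # keep the deepest observation and the largest copy number seen
    obs <- obs |>
      dplyr::group_by(.data$chrom, .data$pos, .data$ref, .data$alt,
                      .data$sample_id) |>
      dplyr::summarise(
        n_copies = max(.data$n_copies),
        alt_depth = if (all(is.na(.data$alt_depth))) NA_integer_
                    else max(.data$alt_depth, na.rm = TRUE),
        .groups = "drop"
      )
  }
  cohort <- obs |>
    dplyr::group_by(.data$chrom, .data$pos, .data$ref, .data$alt) |>
    dplyr::summarise(
      recurrence = dplyr::n_distinct(.data$sample_id),
      alt_allele_count = sum(.data$n_copies),
      max_alt_depth = if (all(is.na(.data$alt_depth))) NA_integer_
                      else max(.data$alt_depth, na.rm = TRUE),
      carrier_ids = paste(sort(unique(.data$sample_id)), collapse = ","),
      .groups = "drop"
    ) |>
    dplyr::mutate(key = variant_key(.data$chrom, .data$pos,
                                    .data$ref, .data$alt)) |>
    dplyr::arrange(.data$chrom, .data$pos, .data$ref, .data$alt)
  attr(cohort, "cohort_size") <- length(ids)
  attr(cohort, "sample_ids") <- ids
  class(cohort) <- c("cohort_table", class(cohort))
  cohort
}

#' Apply the depth-or-recurrence quality filter to a cohort table
#'
#' A cohort entry passes iff its maximum known alt-supporting depth reaches
#' `min_alt_depth`, or its recurrence reaches `min_recurrence`. Entries whose
#' carriers all lack AD can only pass through the recurrence clause; they are
#' never assumed deep.
#'
#' @param cohort A `cohort_table` from [merge_cohort()] (or any tibble with
#'   `max_alt_depth` and `recurrence` columns).
#' @param params A [filter_params()] object.
#' @return A list with tibbles `passed` and `failed`; their union is the
#'   input and they are disjoint.
#' @export
apply_quality_filter <- function(cohort, params = filter_params()) {
  stopifnot(inherits(params, "filter_params"))
  depth_ok <- !is.na(cohort$max_alt_depth) &
    cohort$max_alt_depth >= params$min_alt_depth
  rec_ok <- cohort$recurrence >= params$min_recurrence
  pass <- depth_ok | rec_ok
  list(passed = cohort[pass, , drop = FALSE],
       failed = cohort[!pass, , drop = FALSE])
}

#' Read a variant catalog (known-SNP or known-somatic)
#'
#' Catalogs emulate public references such as dbSNP or COSMIC: a set of
#' allele-aware variant keys used to deplete the cohort. Accepted formats are
#' VCF (every ALT allele of every record becomes a key) and 4-column
#' tab-delimited text (`chrom pos ref alt`; lines starting with `#` are
#' ignored).
#'
#' @param path File path, or `NULL`/`NA` for an empty catalog.
#' @param name Catalog display name (e.g. `"SNP-catalog"`).
#' @param version_label Free-text provenance label stored with the database.
#' @return A `catalog`: list with `name`, `version_label` and `keys`
#'   (deduplicated character vector of normalized key strings).
#' @export
read_catalog <- function(path, name = "catalog", version_label = "") {
  if (is.null(path) || length(path) == 0L || is.na(path)) {
    return(catalog(character(), name = name, version_label = version_label))
  }
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 1L && startsWith(first, "##fileformat=")) {
    doc <- read_vcf(path)
    rec <- doc$records
    if (nrow(rec) == 0L) {
      keys <- character()
    } else {
      alt_list <- strsplit(rec$ALT, ",", fixed = TRUE)
      n_alt <- lengths(alt_list)
      i <- rep.int(seq_len(nrow(rec)), n_alt)
      alt <- unlist(alt_list, use.names = FALSE)
      ok <- .is_sequence_allele(alt)
      keys <- variant_key(rec$CHROM[i][ok], rec$POS[i][ok],
                          rec$REF[i][ok], alt[ok])
    }
  } else {
    tab <- utils::read.table(path, sep = "\t", comment.char = "#",
                             col.names = c("chrom", "pos", "ref", "alt"),
                             colClasses = "character", fill = FALSE)
    keys <- variant_key(tab$chrom, tab$pos, tab$ref, tab$alt)
  }
  catalog(keys, name = name, version_label = version_label)
}

#' Construct a catalog from key strings or key columns
#'
#' @param keys Character vector of `chrom:pos:ref:alt` key strings (already
#'   normalized by [variant_key()]), or a data frame with columns
#'   `chrom`, `pos`, `ref`, `alt`.
#' @param name,version_label Provenance labels.
#' @return A `catalog` object with deduplicated keys.
#' @export
catalog <- function(keys, name = "catalog", version_label = "") {
  if (is.data.frame(keys)) {
    keys <- variant_key(keys$chrom, keys$pos, keys$ref, keys$alt)
  }
  structure(list(name = name, version_label = version_label,
                 keys = unique(as.character(keys))),
            class = "catalog")
}

#' @export
print.catalog <- function(x, ...) {
  cat("<catalog> ", x$name,
      if (nzchar(x$version_label)) paste0(" (", x$version_label, ")"),
      ": ", length(x$keys), " key(s)\n", sep = "")
  invisible(x)
}

#' Deplete a keyed variant table against a catalog
#'
#' Matching is exact on the full allele-aware key (chrom, pos, ref, alt) —
#' never on position alone, so a novel allele at a cataloged position is
#' retained.
#'
#' @param variants A tibble with a `key` column (e.g. a cohort table or the
#'   `passed` set of [apply_quality_filter()]).
#' @param cat A [catalog()].
#' @return List with tibbles `retained` and `removed`; disjoint, union equals
#'   the input.
#' @export
deplete_catalog <- function(variants, cat) {
  stopifnot(inherits(cat, "catalog"))
  hit <- variants$key %in% cat$keys
  list(retained = variants[!hit, , drop = FALSE],
       removed = variants[hit, , drop = FALSE])
}

#' Build a panel-of-normals database from normal VCFs
#'
#' Runs the full construction pipeline: merge the normal cohort, apply the
#' depth-or-recurrence quality filter, deplete against the known-SNP catalog,
#' then against the known-somatic catalog. Everything that survives
#' constitutes the panel-of-normals database.
#'
#' @param normals List of `vcf_document` objects or VCF file paths.
#' @param snp_catalog,somatic_catalog [catalog()] objects (default empty).
#' @param params [filter_params()].
#' @return A `pon_database`: list with `entries` (tibble of surviving cohort
#'   entries), `cohort_size`, `provenance` (named list recording thresholds
#'   and catalog labels) and `funnel` (a `funnel_stats` object, see below).
#'   The funnel records `n_raw` (observations merged), `n_unique` (unique
#'   keys), `n_quality`, `n_removed_snp_catalog`, `n_post_snp_catalog`,
#'   `n_removed_somatic_catalog` and `n_final`.
#' @details A cohort in which no VCF yields a usable variant observation is
#'   an error ("empty cohort"), not an empty database: it almost always
#'   indicates malformed input rather than a genuinely variant-free cohort.
#' @export
build_database <- function(normals,
                           snp_catalog = catalog(character(), "SNP-catalog"),
                           somatic_catalog = catalog(character(), "somatic-catalog"),
                           params = filter_params()) {
  docs <- lapply(normals, .as_vcf_document)
  ids <- unlist(lapply(docs, function(d) d$samples), use.names = FALSE)
  if (anyDuplicated(ids)) {
    stop("duplicate sample id(s) across normal VCFs: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  obs_list <- lapply(docs, normalize_observations)
  n_raw <- sum(vapply(obs_list, nrow, integer(1)))
  if (n_raw == 0L) {
    stop("empty cohort: no usable variant observations in any normal VCF",
         call. = FALSE)
  }
  cohort <- .merge_observations(obs_list, ids)
  filt <- apply_quality_filter(cohort, params)
  snp <- deplete_catalog(filt$passed, snp_catalog)
  som <- deplete_catalog(snp$retained, somatic_catalog)
  funnel <- funnel_stats(
    n_raw = n_raw,
    n_unique = nrow(cohort),
    n_quality = nrow(filt$passed),
    n_removed_snp_catalog = nrow(snp$removed),
    n_removed_somatic_catalog = nrow(som$removed)
  )
  entries <- som$retained
  class(entries) <- setdiff(class(entries), "cohort_table")
  attr(entries, "cohort_size") <- NULL
  attr(entries, "sample_ids") <- NULL
  structure(list(
    entries = entries,
    cohort_size = attr(cohort, "cohort_size"),
    provenance = list(
      min_alt_depth = params$min_alt_depth,
      min_recurrence = params$min_recurrence,
      snp_catalog = snp_catalog$name,
      snp_catalog_version = snp_catalog$version_label,
      somatic_catalog = somatic_catalog$name,
      somatic_catalog_version = somatic_catalog$version_label,
      sample_ids = paste(attr(cohort, "sample_ids"), collapse = ",")
    ),
    funnel = funnel
  ), class = "pon_database")
}

#' Funnel stage counts for the database build
#'
#' @param n_raw Total observations merged across the cohort.
#' @param n_unique Unique variant keys after the merge.
#' @param n_quality Keys passing the quality filter.
#' @param n_removed_snp_catalog,n_removed_somatic_catalog Keys removed by the
#'   two depletion stages.
#' @return A `funnel_stats` list, with derived fields `n_post_snp_catalog`
#'   and `n_final`. Conservation invariants
#'   (`n_quality = n_post_snp_catalog + n_removed_snp_catalog`,
#'   `n_final = n_post_snp_catalog - n_removed_somatic_catalog`) are checked.
#' @export
funnel_stats <- function(n_raw, n_unique, n_quality,
                         n_removed_snp_catalog, n_removed_somatic_catalog) {
  n_post_snp <- n_quality - n_removed_snp_catalog
  n_final <- n_post_snp - n_removed_somatic_catalog
  x <- list(n_raw = n_raw, n_unique = n_unique, n_quality = n_quality,
            n_removed_snp_catalog = n_removed_snp_catalog,
            n_post_snp_catalog = n_post_snp,
            n_removed_somatic_catalog = n_removed_somatic_catalog,
            n_final = n_final)
  if (any(unlist(x) < 0) || n_unique > n_raw || n_quality > n_unique) {
    stop("inconsistent funnel counts", call. = FALSE)
  }
  structure(x, class = "funnel_stats")
}

#' @export
print.funnel_stats <- function(x, ...) {
  cat("Panel-of-normals build funnel\n",
      "  raw observations merged : ", x$n_raw, "\n",
      "  unique variant keys     : ", x$n_unique, "\n",
      "  pass quality filter     : ", x$n_quality, "\n",
      "  removed by SNP catalog  : ", x$n_removed_snp_catalog, "\n",
      "  after SNP catalog       : ", x$n_post_snp_catalog, "\n",
      "  removed by somatic cat. : ", x$n_removed_somatic_catalog, "\n",
      "  final database size     : ", x$n_final, "\n", sep = "")
  invisible(x)
}

#' @export
print.pon_database <- function(x, ...) {
  cat("<pon_database> ", nrow(x$entries), " variant(s) from a cohort of ",
      x$cohort_size, " normal sample(s)\n", sep = "")
  cat("  filters: alt depth >= ", x$provenance$min_alt_depth,
      " or recurrence >= ", x$provenance$min_recurrence, "\n", sep = "")
  invisible(x)
}

#' Database keys
#'
#' @param db A `pon_database`.
#' @return Character vector of the database's variant key strings.
#' @export
pon_keys <- function(db) {
  stopifnot(inherits(db, "pon_database"))
  db$entries$key
}
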
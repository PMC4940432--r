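#' Persist a panel-of-normals database as a single SQLite file
#'
#' The database is stored in the SQLite file format with two tables:
#' `variants` (chrom TEXT, pos INTEGER, ref TEXT, alt TEXT,
#' recurrence INTEGER, alt_allele_count INTEGER, max_alt_depth INTEGER NULL)
#' and `meta` (key TEXT, value TEXT) holding the cohort size, the filter
#' thresholds and the catalog labels used at build time.
#'
#' @param db A `pon_database` from [build_database()].
#' @param path Output file path (overwritten if present).
#' @return `path`, invisibly.
#' @seealso [load_database()]
#' @export
save_database <- function(db, path) {
  stopifnot(inherits(db, "pon_database"))
  if (file.exists(path)) unlink(path)
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  on.exit(DBI::dbDisconnect(con))
  variants <- db$entries[, c("chrom", "pos", "ref", "alt", "recurrence",
                             "alt_allele_count", "max_alt_depth")]
  DBI::dbExecute(con, paste(
    "CREATE TABLE variants (",
    "chrom TEXT NOT NULL, pos INTEGER NOT NULL,",
    "ref TEXT NOT NULL, alt TEXT NOT NULL,",
    "recurrence INTEGER, alt_allele_count INTEGER, max_alt_depth INTEGER)"))
  DBI::dbWriteTable(con, "variants", as.data.frame(variants), append = TRUE)
  meta <- c(
    format_version = "1",
    cohort_size = as.character(db$cohort_size),
    vapply(db$provenance, as.character, character(1)),
    funnel = paste(unlist(db$funnel), collapse = ",")
  )
  DBI::dbWriteTable(con, "meta",
                    data.frame(key = names(meta), value = unname(meta),
                               stringsAsFactors = FALSE))
  invisible(path)
}

#' Load a panel-of-normals database from its SQLite file
#'
#' @param path Path to a file written by [save_database()].
#' @return A `pon_database`. Loading then saving is the identity on variant
#'   keys, recurrence, allele counts, cohort size and provenance. The stored
#'   funnel counts, if present, are restored as well.
#' @details A file that is not SQLite, or an SQLite file without a `variants`
#'   table, is rejected with a format error naming what is missing.
#' @export
load_database <- function(path) {
  if (!file.exists(path)) {
    stop("database file not found: ", path, call. = FALSE)
  }
  header <- readBin(path, "raw", n = 16L)
  if (!identical(rawToChar(header[1:15]), "SQLite format 3")) {
    stop("not a panel-of-normals database (not an SQLite file): ", path,
         call. = FALSE)
  }
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  on.exit(DBI::dbDisconnect(con))
  tabs <- DBI::dbListTables(con)
  if (!"variants" %in% tabs) {
    stop("database file lacks the required 'variants' table: ", path,
         call. = FALSE)
  }
  variants <- tibble::as_tibble(DBI::dbReadTable(con, "variants"))
  variants$pos <- as.integer(variants$pos)
  variants$recurrence <- as.integer(variants$recurrence)
  variants$alt_allele_count <- as.integer(variants$alt_allele_count)
  variants$max_alt_depth <- as.integer(variants$max_alt_depth)
  variants$key <- variant_key(variants$chrom, variants$pos,
                              variants$ref, variants$alt)
  meta <- if ("meta" %in% tabs) {
    m <- DBI::dbReadTable(con, "meta")
    stats::setNames(as.list(m$value), m$key)
  } else list()
  funnel <- NULL
  if (!is.null(meta$funnel)) {
    f <- as.numeric(strsplit(meta$funnel, ",", fixed = TRUE)[[1L]])
    if (length(f) == 7L) {
      funnel <- funnel_stats(f[1], f[2], f[3], f[4], f[6])
    }
  }
  prov_keys <- setdiff(names(meta), c("format_version", "cohort_size", "funnel"))
  db <- structure(list(
    entries = variants,
    cohort_size = as.integer(meta$cohort_size %||% NA_integer_),
    provenance = meta[prov_keys],
    funnel = funnel
  ), class = "pon_database")
  db$provenance$min_alt_depth <- as.integer(db$provenance$min_alt_depth)
  db$provenance$min_recurrence <- as.integer(db$provenance$min_recurrence)
  db
}
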
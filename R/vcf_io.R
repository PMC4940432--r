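#' Read a VCF file into a `vcf_document`
#'
#' Parses a VCF 4.x text file (optionally gzip-compressed) into a lightweight
#' in-memory document that preserves every data-line field verbatim, so that
#' [write_vcf()] reproduces the data lines byte for byte. Only structural
#' validation is performed here; allele-aware interpretation happens in
#' [normalize_observations()].
#'
#' @param path Path to a VCF file. The first line must start with
#'   `"##fileformat="`; anything else (e.g. a FASTA file) is a format error.
#' @return A `vcf_document`: a list with elements `header` (character vector
#'   of all `##` meta lines), `records` (a tibble with one character column
#'   per VCF column, named as in the `#CHROM` line), and `samples` (character
#'   vector of sample column names, possibly empty).
#' @details Data lines must have exactly as many tab-separated fields as the
#'   `#CHROM` header line declares; offending lines are reported with their
#'   1-based line numbers in the file.
#' @seealso [write_vcf()], [normalize_observations()]
#' @export
#' @examples
#' vcf <- system.file("extdata", "toy_normal1.vcf", package = "ponsub")
#' doc <- read_vcf(vcf)
#' doc$samples
#' nrow(doc$records)
read_vcf <- function(path) {
  if (!file.exists(path)) {
    stop("VCF file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || !startsWith(lines[[1L]], "##fileformat=")) {
    stop("not a VCF file (first line must start with '##fileformat='): ",
         path, call. = FALSE)
  }
  is_meta <- startsWith(lines, "##")
  # meta lines are a prefix; the column header is the first non-## line
  hdr_idx <- which(!is_meta)[1L]
  if (is.na(hdr_idx) || !startsWith(lines[[hdr_idx]], "#CHROM")) {
    stop("VCF is missing the #CHROM column header line: ", path, call. = FALSE)
  }
  header <- lines[seq_len(hdr_idx - 1L)]
  cols <- strsplit(sub("^#", "", lines[[hdr_idx]]), "\t", fixed = TRUE)[[1L]]
  fixed_cols <- c("CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
  if (length(cols) < 8L || !identical(cols[1:8], fixed_cols)) {
    stop("VCF column header does not declare the 8 fixed VCF columns: ",
         path, call. = FALSE)
  }
  data_lines <- lines[seq_along(lines) > hdr_idx]
  data_lnos <- which(seq_along(lines) > hdr_idx)
  keep <- nzchar(data_lines)
  data_lines <- data_lines[keep]
  data_lnos <- data_lnos[keep]
  if (length(data_lines) == 0L) {
    records <- tibble::as_tibble(
      stats::setNames(rep(list(character()), length(cols)), cols)
    )
  } else {
    fields <- strsplit(data_lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    bad <- which(nf != length(cols))
    if (length(bad) > 0L) {
      stop("malformed VCF data line(s) (expected ", length(cols),
           " tab-separated fields) at line(s) ",
           paste(utils::head(data_lnos[bad], 10L), collapse = ", "),
           if (length(bad) > 10L) " ..." else "",
           " in ", path, call. = FALSE)
    }
    mat <- matrix(unlist(fields, use.names = FALSE),
                  ncol = length(cols), byrow = TRUE)
    colnames(mat) <- cols
    records <- tibble::as_tibble(mat)
  }
  samples <- if (length(cols) > 9L) cols[-(1:9)] else character()
  new_vcf_document(header, records, samples)
}

#' Construct a `vcf_document` from parts
#'
#' @param header Character vector of `##` meta lines; must contain a
#'   `##fileformat=` line.
#' @param records Tibble/data frame of character columns named as VCF columns
#'   (CHROM, POS, ID, REF, ALT, QUAL, FILTER, INFO, then optionally FORMAT and
#'   one column per sample).
#' @param samples Character vector of sample column names; defaults to the
#'   columns after FORMAT.
#' @return A `vcf_document`.
#' @export
new_vcf_document <- function(header, records, samples = NULL) {
  stopifnot(is.character(header))
  if (!any(startsWith(header, "##fileformat="))) {
    stop("vcf_document header must contain a ##fileformat= line", call. = FALSE)
  }
  records <- tibble::as_tibble(records)
  records[] <- lapply(records, as.character)
  cols <- names(records)
  if (is.null(samples)) {
    samples <- if (length(cols) > 9L) cols[-(1:9)] else character()
  }
  structure(list(header = header, records = records, samples = samples),
            class = "vcf_document")
}

#' @export
print.vcf_document <- function(x, ...) {
  cat("<vcf_document> ", nrow(x$records), " record(s), ",
      length(x$samples), " sample(s)",
      if (length(x$samples)) paste0(": ", paste(x$samples, collapse = ", ")),
      "\n", sep = "")
  invisible(x)
}

#' Write a `vcf_document` to a VCF text file
#'
#' Emits the stored meta lines, the `#CHROM` column header, and one
#' tab-joined line per record. Because fields are stored verbatim, a
#' read/write/read cycle is the identity on keys, record order and
#' FORMAT/sample fields, and data lines round-trip byte-identically.
#'
#' @param doc A `vcf_document`.
#' @param path Output file path (plain text).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(doc, path) {
  stopifnot(inherits(doc, "vcf_document"))
  cols <- names(doc$records)
  lines <- c(doc$header, paste0("#", paste(cols, collapse = "\t")))
  if (nrow(doc$records) > 0L) {
    lines <- c(lines, do.call(paste, c(unname(as.list(doc$records)),
                                       list(sep = "\t"))))
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Normalize a chromosome label
#'
#' Strips a leading `"chr"` prefix (case-insensitive) and maps the
#' mitochondrial labels `M`/`chrM` to `MT`, so that databases and VCFs
#' produced by different callers match on the same key. Idempotent.
#'
#' @param chrom Character vector of chromosome labels.
#' @return Character vector of normalized labels.
#' @export
#' @examples
#' normalize_chrom(c("chr7", "X", "chrM", "MT"))
normalize_chrom <- function(chrom) {
  out <- sub("^[Cc][Hh][Rr]", "", as.character(chrom))
  out[out == "M"] <- "MT"
  out
}

# TRUE for ALT alleles that can be matched as literal sequence keys
.is_sequence_allele <- function(alt) {
  grepl("^[ACGTNacgtn]+$", alt)
}

# Locate a FORMAT sub-field (e.g. "GT", "AD") per record; NA when absent.
.format_field_index <- function(format, field) {
  idx <- rep(NA_integer_, length(format))
  for (f in unique(format)) {
    parts <- strsplit(f, ":", fixed = TRUE)[[1L]]
    idx[format == f] <- match(field, parts)
  }
  idx
}

# Extract the k-th ":"-separated sub-field from sample strings (k vectorized).
.subfield <- function(values, k) {
  parts <- strsplit(values, ":", fixed = TRUE)
  n <- lengths(parts)
  flat <- unlist(parts, use.names = FALSE)
  off <- cumsum(c(0L, n[-length(n)]))
  pos <- off + k
  out <- rep(NA_character_, length(values))
  ok <- !is.na(k) & k <= n & k >= 1L
  out[ok] <- flat[pos[ok]]
  out
}

#' Normalize VCF records into allele-aware sample observations
#'
#' Turns the raw records of a [vcf_document][read_vcf] into one row per
#' (alternate allele, carrier sample) pair: the atomic observation the cohort
#' merge and the panel-of-normals filters operate on. Multi-allelic records
#' are split into biallelic keys; chromosome labels are normalized with
#' [normalize_chrom()]; the alt-supporting read depth is taken from the `AD`
#' FORMAT field entry for that allele when present and is `NA` (unknown)
#' otherwise; the genotype class is derived from `GT`.
#'
#' @param doc A `vcf_document` with at least one sample column, or a record
#'   subset of one.
#' @return A tibble with columns `chrom`, `pos` (integer), `ref`, `alt`,
#'   `sample_id`, `genotype` (`"het"` or `"hom_alt"`), `n_copies` (alt allele
#'   copies in the genotype, 1 or 2), and `alt_depth` (integer, `NA` when the
#'   record lacks usable `AD`). Samples whose genotype does not carry the
#'   allele contribute no row; missing genotypes (`./.`) contribute no row.
#' @details Symbolic alternate alleles (`<DEL>`, breakends, `*`) cannot be
#'   matched as sequence keys and are skipped with a warning, never silently
#'   matched. Alleles beyond the second in a `GT` call are ignored.
#' @export
normalize_observations <- function(doc) {
  stopifnot(inherits(doc, "vcf_document"))
  rec <- doc$records
  empty <- tibble::tibble(
    chrom = character(), pos = integer(), ref = character(),
    alt = character(), sample_id = character(), genotype = character(),
    n_copies = integer(), alt_depth = integer()
  )
  if (nrow(rec) == 0L || length(doc$samples) == 0L) {
    return(empty)
  }
  alt_list <- strsplit(rec$ALT, ",", fixed = TRUE)
  n_alt <- lengths(alt_list)
  rec_id <- rep.int(seq_len(nrow(rec)), n_alt)
  alt_idx <- sequence(n_alt)
  alt <- unlist(alt_list, use.names = FALSE)
  sym <- !.is_sequence_allele(alt)
  if (any(sym)) {
    warning(sum(sym), " symbolic/non-sequence ALT allele(s) skipped during ",
            "normalization (e.g. ", alt[which(sym)[1L]], ")", call. = FALSE)
    rec_id <- rec_id[!sym]; alt_idx <- alt_idx[!sym]; alt <- alt[!sym]
  }
  if (length(rec_id) == 0L) return(empty)

  has_format <- "FORMAT" %in% names(rec)
  gt_k <- if (has_format) .format_field_index(rec$FORMAT, "GT") else
    rep(NA_integer_, nrow(rec))
  ad_k <- if (has_format) .format_field_index(rec$FORMAT, "AD") else
    rep(NA_integer_, nrow(rec))

  out <- vector("list", length(doc$samples))
  for (s in seq_along(doc$samples)) {
    sval <- rec[[doc$samples[[s]]]]
    gt <- .subfield(sval, gt_k)
    ad <- .subfield(sval, ad_k)
    gt_parts <- strsplit(gt, "[/|]")
    a1 <- suppressWarnings(as.integer(vapply(gt_parts, function(p)
      if (length(p) >= 1L) p[[1L]] else NA_character_, character(1))))
    a2 <- suppressWarnings(as.integer(vapply(gt_parts, function(p)
      if (length(p) >= 2L) p[[2L]] else NA_character_, character(1))))
    copies <- (!is.na(a1[rec_id]) & a1[rec_id] == alt_idx) +
      (!is.na(a2[rec_id]) & a2[rec_id] == alt_idx)
    carrier <- which(copies > 0L)
    if (length(carrier) == 0L) next
    ri <- rec_id[carrier]
    depth <- rep(NA_integer_, length(carrier))
    has_ad <- !is.na(ad[ri]) & ad[ri] != "."
    if (any(has_ad)) {
      ad_parts <- strsplit(ad[ri][has_ad], ",", fixed = TRUE)
      want <- alt_idx[carrier][has_ad] + 1L
      depth[has_ad] <- suppressWarnings(as.integer(mapply(
        function(p, k) if (k <= length(p)) p[[k]] else NA_character_,
        ad_parts, want)))
    }
    out[[s]] <- tibble::tibble(
      chrom = normalize_chrom(rec$CHROM[ri]),
      pos = as.integer(rec$POS[ri]),
      ref = rec$REF[ri],
      alt = alt[carrier],
      sample_id = doc$samples[[s]],
      genotype = c("het", "hom_alt")[pmin(copies[carrier], 2L)],
      n_copies = as.integer(pmin(copies[carrier], 2L)),
      alt_depth = depth
    )
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0L) empty else res
}

#' Normalize a single raw VCF record
#'
#' Convenience wrapper around [normalize_observations()] for one record,
#' given either as a raw tab-separated VCF data line or as a one-row record
#' tibble. Mostly useful interactively and in tests; pipelines use the
#' vectorized document form.
#'
#' @param record A single VCF data line (character scalar with tab-separated
#'   fields) or a one-row data frame with VCF columns.
#' @param samples Sample column names. Required for a raw line with sample
#'   columns; defaults to `S1, S2, ...` for the columns after FORMAT.
#' @return A tibble of observations as in [normalize_observations()].
#' @export
#' @examples
#' normalize_record("chr5\t100\t.\tA\tT,G\t50\tPASS\t.\tGT:AD\t1/2:10,6,4")
normalize_record <- function(record, samples = NULL) {
  if (is.character(record) && length(record) == 1L) {
    fields <- strsplit(record, "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 8L) {
      stop("record has fewer than the 8 fixed VCF fields", call. = FALSE)
    }
    n_extra <- max(0L, length(fields) - 9L)
    if (is.null(samples)) samples <- paste0("S", seq_len(n_extra))
    cols <- c("CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
              if (length(fields) >= 9L) "FORMAT", samples)
    record <- stats::setNames(as.data.frame(as.list(fields),
                                            stringsAsFactors = FALSE), cols)
  } else {
    record <- as.data.frame(record, stringsAsFactors = FALSE)
    samples <- samples %||% setdiff(names(record),
      c("CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", "FORMAT"))
  }
  doc <- new_vcf_document("##fileformat=VCFv4.2", record, samples)
  normalize_observations(doc)
}

#' Allele-aware variant key strings
#'
#' Builds the `chrom:pos:ref:alt` identity used for all matching: the unique
#' combination of chromosome, position, reference allele and alternate allele
#' in a fixed genome build.
#'
#' @param chrom,pos,ref,alt Vectors of equal length (chrom already normalized
#'   or not; it is normalized here).
#' @return Character vector of key strings.
#' @export
variant_key <- function(chrom, pos, ref, alt) {
  paste(normalize_chrom(chrom), as.integer(pos),
        toupper(ref), toupper(alt), sep = ":")
}
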
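#' Subtract panel-of-normals variants from a tumor VCF
#'
#' Removes every tumor record whose allele-aware key (normalized chromosome,
#' position, reference allele, alternate allele) is present in the
#' panel-of-normals database. Multi-allelic tumor records are handled per
#' allele: only matching alternate alleles are removed, and the record is
#' dropped entirely only when all of its alleles match; otherwise it is
#' rewritten with the surviving alleles. INFO/FILTER and FORMAT/sample fields
#' of retained records are passed through untouched — the tool filters, it
#' does not re-annotate.
#'
#' @param tumor A `vcf_document` or a tumor VCF file path.
#' @param db A `pon_database` (from [build_database()] or [load_database()]).
#' @param keep_removed Also return the removed records as a `vcf_document`
#'   (for audit); default `FALSE`.
#' @return A `subtraction_result`: list with `retained` (`vcf_document` with
#'   one added provenance header line), `n_input` (input biallelic keys),
#'   `n_removed`, `n_retained`, `removed_keys` (character vector), and — when
#'   `keep_removed = TRUE` — `removed` (`vcf_document`). Always
#'   `n_input = n_removed + n_retained`.
#' @details Records with only symbolic/non-sequence alternate alleles cannot
#'   be keyed; they are retained with a warning, never silently matched. An
#'   empty tumor VCF yields a valid empty result.
#' @export
subtract <- function(tumor, db, keep_removed = FALSE) {
  stopifnot(inherits(db, "pon_database"))
  doc <- .as_vcf_document(tumor)
  rec <- doc$records
  db_keys <- pon_keys(db)
  prov <- paste0("##ponsub_subtract=\"panel-of-normals subtraction; db_size=",
                 length(db_keys), "; cohort_size=", db$cohort_size, "\"")

  if (nrow(rec) == 0L) {
    out <- new_vcf_document(c(doc$header, prov), rec, doc$samples)
    res <- list(retained = out, n_input = 0L, n_removed = 0L,
                n_retained = 0L, removed_keys = character())
    if (keep_removed) res$removed <- new_vcf_document(doc$header, rec, doc$samples)
    return(structure(res, class = "subtraction_result"))
  }

  alt_list <- strsplit(rec$ALT, ",", fixed = TRUE)
  n_alt <- lengths(alt_list)
  rec_id <- rep.int(seq_len(nrow(rec)), n_alt)
  alt <- unlist(alt_list, use.names = FALSE)
  keyable <- .is_sequence_allele(alt)
  if (any(!keyable)) {
    warning(sum(!keyable), " symbolic/non-sequence ALT allele(s) in tumor ",
            "VCF retained unmatched", call. = FALSE)
  }
  keys <- rep(NA_character_, length(alt))
  keys[keyable] <- variant_key(rec$CHROM[rec_id][keyable],
                               rec$POS[rec_id][keyable],
                               rec$REF[rec_id][keyable], alt[keyable])
  hit <- !is.na(keys) & keys %in% db_keys

  # rewrite ALT per record with the surviving alleles
  surv <- vapply(split(!hit, rec_id), any, logical(1))
  new_alt <- vapply(split(alt[!hit], rec_id[!hit]), paste,
                    character(1), collapse = ",")
  retained_rec <- rec[as.integer(names(surv))[surv], , drop = FALSE]
  retained_rec$ALT <- new_alt[names(surv)[surv]]
  removed_rec <- rec[!seq_len(nrow(rec)) %in% as.integer(names(surv))[surv], ,
                     drop = FALSE]

  out <- new_vcf_document(c(doc$header, prov), retained_rec, doc$samples)
  res <- list(
    retained = out,
    n_input = length(alt),
    n_removed = sum(hit),
    n_retained = length(alt) - sum(hit),
    removed_keys = unique(keys[hit])
  )
  if (keep_removed) {
    res$removed <- new_vcf_document(doc$header, removed_rec, doc$samples)
  }
  structure(res, class = "subtraction_result")
}

#' @export
print.subtraction_result <- function(x, ...) {
  pct <- if (x$n_input > 0) sprintf(" (%.1f%%)", 100 * x$n_removed / x$n_input)
         else ""
  cat("<subtraction_result> ", x$n_input, " input allele(s): ",
      x$n_removed, " removed", pct, ", ", x$n_retained, " retained\n",
      sep = "")
  invisible(x)
}

#' Subtract a panel-of-normals database from several tumor VCFs
#'
#' Applies [subtract()] independently to each tumor. One unreadable file does
#' not abort the batch: it is reported with a warning and skipped (its row in
#' the summary carries `NA` counts).
#'
#' @param tumors Named list of `vcf_document` objects or VCF file paths.
#'   Names (or file basenames) become sample labels.
#' @param db A `pon_database`.
#' @param keep_removed Passed through to [subtract()].
#' @return A `batch_subtraction`: list with `results` (per-tumor
#'   `subtraction_result` or `NULL` for skipped inputs) and `summary` (tibble
#'   with columns `sample`, `n_input`, `n_removed`, `n_retained`,
#'   `percent_removed`).
#' @export
batch_subtract <- function(tumors, db, keep_removed = FALSE) {
  stopifnot(inherits(db, "pon_database"))
  labels <- names(tumors)
  if (is.null(labels)) labels <- rep("", length(tumors))
  fill <- !nzchar(labels)
  labels[fill] <- vapply(tumors[fill], function(t) {
    if (is.character(t)) basename(t) else "tumor"
  }, character(1))
  labels <- make.unique(labels, sep = "_")

  results <- vector("list", length(tumors))
  names(results) <- labels
  rows <- vector("list", length(tumors))
  for (i in seq_along(tumors)) {
    res <- tryCatch(subtract(tumors[[i]], db, keep_removed = keep_removed),
                    error = function(e) {
                      warning("skipping tumor '", labels[[i]], "': ",
                              conditionMessage(e), call. = FALSE)
                      NULL
                    })
    results[[i]] <- res
    rows[[i]] <- tibble::tibble(
      sample = labels[[i]],
      n_input = if (is.null(res)) NA_integer_ else res$n_input,
      n_removed = if (is.null(res)) NA_integer_ else res$n_removed,
      n_retained = if (is.null(res)) NA_integer_ else res$n_retained
    )
  }
  summary <- dplyr::bind_rows(c(list(tibble::tibble(
    sample = character(), n_input = integer(), n_removed = integer(),
    n_retained = integer())), rows))
  summary$percent_removed <- as.numeric(ifelse(
    !is.na(summary$n_input) & summary$n_input > 0,
    100 * summary$n_removed / summary$n_input, NA_real_))
  structure(list(results = results, summary = summary),
            class = "batch_subtraction")
}

#' @export
print.batch_subtraction <- function(x, ...) {
  ok <- !is.na(x$summary$n_input)
  cat("<batch_subtraction> ", sum(ok), " of ", nrow(x$summary),
      " tumor(s) processed; ", sum(x$summary$n_removed[ok]),
      " allele(s) removed of ", sum(x$summary$n_input[ok]), " input\n",
      sep = "")
  invisible(x)
}
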
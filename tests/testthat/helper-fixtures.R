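# Shared helpers: hand-built VCF documents and independent brute-force
# oracles. Oracles deliberately re-derive results with plain loops, never by
# calling the implementation under test.

sim_header <- c(
  "##fileformat=VCFv4.2",
  "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
  "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">")

# single-sample document from parallel vectors; ad entries like "10,6" or NA
# to omit the AD field for that record
make_doc <- function(sample_id, chrom, pos, ref, alt, gt, ad = NULL) {
  n <- length(chrom)
  if (is.null(ad)) ad <- rep(NA_character_, n)
  fmt <- ifelse(is.na(ad), "GT", "GT:AD")
  val <- ifelse(is.na(ad), gt, paste0(gt, ":", ad))
  rec <- tibble::tibble(
    CHROM = as.character(chrom), POS = as.character(pos), ID = ".",
    REF = ref, ALT = alt, QUAL = "50", FILTER = "PASS", INFO = ".",
    FORMAT = fmt)
  rec[[sample_id]] <- val
  new_vcf_document(sim_header, rec, sample_id)
}

# n single-base variant records on chromosome 1 at positions 1..n
simple_doc <- function(sample_id, n, gt = "0/1", ad = "10,10") {
  make_doc(sample_id, chrom = rep("1", n), pos = seq_len(n),
           ref = rep("A", n), alt = rep("T", n),
           gt = rep(gt, n), ad = rep(ad, n))
}

write_lines_vcf <- function(lines, path = withr::local_tempfile(
                              fileext = ".vcf", .local_envir = parent.frame())) {
  writeLines(lines, path)
  path
}

# independent filter predicate: spelled out branch by branch
oracle_filter_pass <- function(max_alt_depth, recurrence,
                               min_alt_depth = 5, min_recurrence = 4) {
  if (!is.na(max_alt_depth)) {
    if (max_alt_depth >= min_alt_depth) return(TRUE)
  }
  if (recurrence >= min_recurrence) return(TRUE)
  FALSE
}

# brute-force subtraction: nested membership check per (record, alt) pair
oracle_subtract_counts <- function(doc, db_keys) {
  removed <- 0L; input <- 0L
  for (i in seq_len(nrow(doc$records))) {
    alts <- strsplit(doc$records$ALT[[i]], ",", fixed = TRUE)[[1L]]
    for (a in alts) {
      input <- input + 1L
      k <- variant_key(doc$records$CHROM[[i]], doc$records$POS[[i]],
                       doc$records$REF[[i]], a)
      if (any(db_keys == k)) removed <- removed + 1L
    }
  }
  list(n_input = input, n_removed = removed, n_retained = input - removed)
}
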
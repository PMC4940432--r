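#' Specification for a synthetic normal cohort
#'
#' Describes a cohort of normal-sample VCFs with fully known ground truth,
#' used to exercise every stage of the panel-of-normals pipeline without
#' external data. Defaults emulate an exome cohort of 62 normal samples
#' sequenced to a median depth near 90x (so heterozygous alt depths are
#' Poisson with mean about 45), in which the large majority of detected
#' germline variants are already cataloged: 92% of sites are planted into
#' the known-SNP catalog and about 2% into the known-somatic catalog.
#'
#' @param n_samples Number of normal samples (>= 1).
#' @param n_sites Number of distinct variant sites (>= 1).
#' @param recurrence Per-site carrier-count law: a single integer (fixed
#'   count), a length-2 vector `c(lo, hi)` (uniform on `lo:hi`), or a vector
#'   of length `n_sites` (per-site counts). Counts are clamped to
#'   `[1, n_samples]`.
#' @param depth_mean Mean of the Poisson law for per-carrier alt-supporting
#'   read depth.
#' @param depth A vector of length `n_sites` of fixed per-site alt depths
#'   (every carrier of the site gets this depth), overriding `depth_mean`;
#'   or `NULL` to draw Poisson depths per carrier.
#' @param frac_in_snp_catalog,frac_in_somatic_catalog Fractions of sites
#'   planted into the two catalogs; plants are disjoint, so the fractions
#'   must sum to at most 1.
#' @param frac_hom Probability that a carrier is homozygous alt rather than
#'   heterozygous.
#' @param frac_missing_ad Probability that a carrier's record omits the AD
#'   field (its depth becomes unknown to the builder).
#' @param frac_indel Fraction of sites that are small insertions/deletions
#'   rather than single-base substitutions.
#' @param catalog_extra Number of additional catalog-only keys (absent from
#'   the cohort) appended to the SNP catalog, to exercise novelty summaries.
#' @param seed Integer seed; the entire cohort is a deterministic function
#'   of the spec.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_samples = 62L, n_sites = 2000L,
                        recurrence = c(1L, 4L), depth_mean = 45,
                        depth = NULL,
                        frac_in_snp_catalog = 0.92,
                        frac_in_somatic_catalog = 0.018,
                        frac_hom = 0.1, frac_missing_ad = 0.05,
                        frac_indel = 0.02, catalog_extra = 0L,
                        seed = 1L) {
  n_samples <- as.integer(n_samples); n_sites <- as.integer(n_sites)
  if (n_samples < 1L || n_sites < 1L) {
    stop("n_samples and n_sites must be >= 1", call. = FALSE)
  }
  fr <- c(frac_in_snp_catalog, frac_in_somatic_catalog,
          frac_hom, frac_missing_ad, frac_indel)
  if (any(fr < 0 | fr > 1)) {
    stop("fractions must lie in [0, 1]", call. = FALSE)
  }
  if (frac_in_snp_catalog + frac_in_somatic_catalog > 1) {
    stop("catalog fractions overlap: frac_in_snp_catalog + ",
         "frac_in_somatic_catalog must be <= 1 (plants are disjoint)",
         call. = FALSE)
  }
  if (!is.null(depth) && length(depth) != n_sites) {
    stop("fixed `depth` must have length n_sites", call. = FALSE)
  }
  structure(list(n_samples = n_samples, n_sites = n_sites,
                 recurrence = recurrence, depth_mean = depth_mean,
                 depth = depth,
                 frac_in_snp_catalog = frac_in_snp_catalog,
                 frac_in_somatic_catalog = frac_in_somatic_catalog,
                 frac_hom = frac_hom, frac_missing_ad = frac_missing_ad,
                 frac_indel = frac_indel,
                 catalog_extra = as.integer(catalog_extra),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

.sim_contigs <- c(as.character(1:22), "X", "Y")
.vcf_sim_header <- function(extra = character()) {
  c("##fileformat=VCFv4.2",
    "##source=ponsub-simulate",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste0("##FORMAT=<ID=AD,Number=R,Type=Integer,Description=",
           "\"Allelic depths for the ref and alt alleles\">"),
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    extra)
}

# distinct variant keys on synthetic contigs; globally unique positions make
# keys unique by construction
.draw_sites <- function(n, frac_indel, pos_offset = 0L) {
  chrom <- sample(.sim_contigs, n, replace = TRUE)
  pos <- sample.int(10000000L, n, replace = FALSE) + pos_offset
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  shift <- sample.int(3L, n, replace = TRUE)
  alt <- bases[(match(ref, bases) - 1L + shift) %% 4L + 1L]
  if (frac_indel > 0) {
    is_indel <- stats::runif(n) < frac_indel
    ins <- is_indel & stats::runif(n) < 0.5
    del <- is_indel & !ins
    if (any(ins)) {
      alt[ins] <- paste0(ref[ins],
                         sample(bases, sum(ins), replace = TRUE),
                         sample(bases, sum(ins), replace = TRUE))
    }
    if (any(del)) {
      ref[del] <- paste0(ref[del],
                         sample(bases, sum(del), replace = TRUE),
                         sample(bases, sum(del), replace = TRUE))
      alt[del] <- substr(ref[del], 1L, 1L)
    }
  }
  tibble::tibble(chrom = chrom, pos = pos, ref = ref, alt = alt,
                 key = variant_key(chrom, pos, ref, alt))
}

.site_order <- function(chrom, pos) {
  order(match(chrom, .sim_contigs), pos)
}

#' Generate a synthetic normal cohort with planted truth
#'
#' Draws variant sites on synthetic contigs 1..22, X, Y; assigns each site a
#' planted carrier count, per-carrier genotypes and alt depths; plants
#' disjoint subsets of sites into the known-SNP and known-somatic catalogs;
#' and materialises one single-sample VCF per normal (GT, and AD/DP unless
#' the AD field is deliberately omitted). The truth table records, per site,
#' the planted values and the expected outcome of the quality filter
#' (maximum known alt depth >= 5 or carrier count >= 4) and of the full
#' build (`expected_final_db`).
#'
#' @param spec A [cohort_spec()].
#' @param dir Optional directory: when given, the normal VCFs, the two
#'   catalogs (4-column tab-delimited) and the truth table are also written
#'   there and their paths returned.
#' @return A list with `normals` (named list of `vcf_document`, one per
#'   sample `N01`, `N02`, ...), `snp_catalog`, `somatic_catalog`
#'   ([catalog()] objects), `truth` (tibble), `spec`, and — when `dir` is
#'   given — `paths` (named list of written files).
#' @details The generator is a deterministic function of the spec (including
#'   its seed); truth bookkeeping uses integer arithmetic only. Note
#'   `set.seed(spec$seed)` is called internally.
#' @export
generate_cohort <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_sites
  ns <- spec$n_samples
  sites <- .draw_sites(n, spec$frac_indel)

  rec <- spec$recurrence
  planted_rec <- if (length(rec) == 1L) rep.int(as.integer(rec), n)
    else if (length(rec) == 2L && n != 2L)
      sample(seq.int(rec[1L], rec[2L]), n, replace = TRUE)
    else if (length(rec) == n) as.integer(rec)
    else stop("recurrence must be length 1, 2 (range) or n_sites",
              call. = FALSE)
  planted_rec <- pmin(pmax(planted_rec, 1L), ns)

  carriers <- lapply(planted_rec, function(k) sort(sample.int(ns, k)))
  site_id <- rep.int(seq_len(n), planted_rec)
  carrier <- unlist(carriers, use.names = FALSE)
  hom <- stats::runif(length(carrier)) < spec$frac_hom
  alt_depth <- if (is.null(spec$depth)) {
    stats::rpois(length(carrier), spec$depth_mean)
  } else {
    as.integer(spec$depth)[site_id]
  }
  ad_missing <- stats::runif(length(carrier)) < spec$frac_missing_ad
  ref_depth <- ifelse(hom, stats::rpois(length(carrier), 1),
                      stats::rpois(length(carrier), spec$depth_mean))

  # disjoint catalog plants
  planted <- sample.int(n, round(n * (spec$frac_in_snp_catalog +
                                      spec$frac_in_somatic_catalog)))
  n_snp <- round(n * spec$frac_in_snp_catalog)
  snp_idx <- planted[seq_len(n_snp)]
  som_idx <- planted[seq_len(length(planted) - n_snp) + n_snp]

  known_depth <- ifelse(ad_missing, NA_integer_, alt_depth)
  max_known <- rep(NA_integer_, n)
  agg <- tapply(known_depth, site_id, function(d)
    if (all(is.na(d))) NA_integer_ else max(d, na.rm = TRUE))
  max_known[as.integer(names(agg))] <- as.integer(agg)

  truth <- sites
  truth$planted_recurrence <- planted_rec
  truth$planted_alt_allele_count <- as.integer(
    tapply(1L + hom, site_id, sum)[as.character(seq_len(n))])
  truth$planted_max_known_depth <- max_known
  truth$in_snp_catalog <- seq_len(n) %in% snp_idx
  truth$in_somatic_catalog <- seq_len(n) %in% som_idx
  truth$expected_pass <- (!is.na(max_known) & max_known >= 5L) |
    planted_rec >= 4L
  truth$expected_final_db <- truth$expected_pass &
    !truth$in_snp_catalog & !truth$in_somatic_catalog

  sample_ids <- sprintf("N%02d", seq_len(ns))
  normals <- vector("list", ns)
  names(normals) <- sample_ids
  for (s in seq_len(ns)) {
    sel <- which(carrier == s)
    si <- site_id[sel]
    ord <- .site_order(sites$chrom[si], sites$pos[si])
    sel <- sel[ord]; si <- si[ord]
    gt <- ifelse(hom[sel], "1/1", "0/1")
    has_ad <- !ad_missing[sel]
    fmt <- ifelse(has_ad, "GT:AD:DP", "GT")
    sval <- ifelse(has_ad,
                   paste0(gt, ":", ref_depth[sel], ",", alt_depth[sel], ":",
                          ref_depth[sel] + alt_depth[sel]),
                   gt)
    recdf <- tibble::tibble(
      CHROM = sites$chrom[si], POS = as.character(sites$pos[si]), ID = ".",
      REF = sites$ref[si], ALT = sites$alt[si], QUAL = "50", FILTER = "PASS",
      INFO = ".", FORMAT = fmt)
    recdf[[sample_ids[[s]]]] <- sval
    normals[[s]] <- new_vcf_document(.vcf_sim_header(), recdf,
                                     sample_ids[[s]])
  }

  snp_keys <- sites$key[sort(snp_idx)]
  if (spec$catalog_extra > 0L) {
    extra <- .draw_sites(spec$catalog_extra, frac_indel = 0,
                         pos_offset = 20000000L)
    snp_keys <- c(snp_keys, extra$key)
  }
  snp_cat <- catalog(snp_keys, name = "SNP-catalog",
                     version_label = "synthetic")
  som_cat <- catalog(sites$key[sort(som_idx)], name = "somatic-catalog",
                     version_label = "synthetic")

  out <- list(normals = normals, snp_catalog = snp_cat,
              somatic_catalog = som_cat, truth = truth, spec = spec)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list()
    for (s in sample_ids) {
      p <- file.path(dir, paste0("normal_", s, ".vcf"))
      write_vcf(normals[[s]], p)
      paths[[s]] <- p
    }
    paths$snp_catalog <- file.path(dir, "snp_catalog.tsv")
    .write_catalog_tsv(snp_cat, paths$snp_catalog)
    paths$somatic_catalog <- file.path(dir, "somatic_catalog.tsv")
    .write_catalog_tsv(som_cat, paths$somatic_catalog)
    paths$truth <- file.path(dir, "truth.tsv")
    utils::write.table(truth, paths$truth, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    out$paths <- paths
  }
  out
}

.write_catalog_tsv <- function(cat, path) {
  parts <- strsplit(cat$keys, ":", fixed = TRUE)
  df <- data.frame(
    chrom = vapply(parts, `[[`, character(1), 1L),
    pos = vapply(parts, `[[`, character(1), 2L),
    ref = vapply(parts, `[[`, character(1), 3L),
    alt = vapply(parts, `[[`, character(1), 4L))
  lines <- c("#chrom\tpos\tref\talt",
             do.call(paste, c(unname(as.list(df)), list(sep = "\t"))))
  writeLines(if (nrow(df) == 0L) lines[1L] else lines, path)
  invisible(path)
}

#' Generate a synthetic tumor VCF with a planted database overlap
#'
#' Builds a single-sample tumor VCF containing exactly `n_db_overlap` keys
#' drawn from the sites the truth table marks as final-database members, plus
#' `n_private_somatic` novel keys absent from the cohort; the expected
#' removal count under subtraction is therefore exactly `n_db_overlap`.
#'
#' @param truth A truth table from [generate_cohort()] (or any tibble with
#'   `chrom`, `pos`, `ref`, `alt`, `key` and `expected_final_db` columns).
#' @param n_private_somatic Number of novel (private somatic) records.
#' @param n_db_overlap Number of records shared with the final database;
#'   must not exceed the number of `expected_final_db` sites.
#' @param seed Integer seed. Note `set.seed(seed)` is called internally.
#' @return A list with `tumor` (`vcf_document`, sample `TUMOR`),
#'   `expected_removed` (= `n_db_overlap`), and `records` (tibble of the
#'   tumor's keys with an `is_db` flag).
#' @export
generate_tumor <- function(truth, n_private_somatic, n_db_overlap, seed = 1L) {
  set.seed(as.integer(seed))
  db_sites <- truth[truth$expected_final_db, , drop = FALSE]
  if (n_db_overlap > nrow(db_sites)) {
    stop("requested overlap (", n_db_overlap, ") exceeds the number of ",
         "final-database sites in the truth table (", nrow(db_sites), ")",
         call. = FALSE)
  }
  shared <- db_sites[sample.int(nrow(db_sites), n_db_overlap),
                     c("chrom", "pos", "ref", "alt", "key")]
  private <- .draw_sites(n_private_somatic, frac_indel = 0,
                         pos_offset = 40000000L)[,
                         c("chrom", "pos", "ref", "alt", "key")]
  shared$is_db <- rep(TRUE, nrow(shared))
  private$is_db <- rep(FALSE, nrow(private))
  recs <- rbind(as.data.frame(shared), as.data.frame(private))
  recs <- recs[.site_order(recs$chrom, recs$pos), , drop = FALSE]
  ad <- stats::rpois(nrow(recs), 30)
  rd <- stats::rpois(nrow(recs), 30)
  recdf <- tibble::tibble(
    CHROM = recs$chrom, POS = as.character(recs$pos), ID = ".",
    REF = recs$ref, ALT = recs$alt, QUAL = "50", FILTER = "PASS",
    INFO = ".", FORMAT = "GT:AD:DP",
    TUMOR = paste0("0/1:", rd, ",", ad, ":", rd + ad))
  tumor <- new_vcf_document(.vcf_sim_header(), recdf, "TUMOR")
  list(tumor = tumor, expected_removed = as.integer(n_db_overlap),
       records = tibble::as_tibble(recs))
}
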
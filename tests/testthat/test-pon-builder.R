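test_that("merge_cohort counts recurrence as distinct carrier samples", {
  one_site <- function(id, gt) make_doc(id, "1", 500, "A", "G", gt, "8,8")
  docs <- list(one_site("N1", "0/1"), one_site("N2", "0/1"),
               one_site("N3", "0/1"),
               make_doc("N4", "2", 900, "C", "T", "0/1", "9,9"),
               make_doc("N5", "2", 900, "C", "T", "1/1", "0,12"))
  coh <- merge_cohort(docs)
  expect_equal(attr(coh, "cohort_size"), 5L)
  site <- coh[coh$key == "1:500:A:G", ]
  expect_equal(site$recurrence, 3L)
  expect_equal(site$alt_allele_count, 3L)
  expect_equal(site$carrier_ids, "N1,N2,N3")
  other <- coh[coh$key == "2:900:C:T", ]
  expect_equal(other$recurrence, 2L)
  expect_equal(other$alt_allele_count, 3L)  # het + hom
  expect_equal(other$max_alt_depth, 12L)
})

test_that("a duplicated line within one sample's VCF counts that sample once", {
  doc <- make_doc("N1", c("1", "1"), c(500, 500), c("A", "A"), c("G", "G"),
                  c("0/1", "0/1"), c("8,4", "8,7"))
  coh <- merge_cohort(list(doc))
  expect_equal(nrow(coh), 1L)
  expect_equal(coh$recurrence, 1L)
  expect_equal(coh$alt_allele_count, 1L)
  expect_equal(coh$max_alt_depth, 7L)  # deepest observation wins
})

test_that("duplicate sample ids across normal VCFs are a fatal error", {
  expect_error(merge_cohort(list(simple_doc("N1", 2), simple_doc("N1", 3))),
               "duplicate sample id")
  expect_error(build_database(list(simple_doc("N1", 2), simple_doc("N1", 3))),
               "duplicate sample id")
})

test_that("merged recurrence reproduces the generator's planted truth", {
  sim <- generate_cohort(cohort_spec(n_samples = 10, n_sites = 500,
                                     recurrence = c(1, 10), seed = 7))
  coh <- merge_cohort(sim$normals)
  truth <- sim$truth[order(sim$truth$key), ]
  coh <- coh[order(coh$key), ]
  expect_equal(coh$key, truth$key)
  expect_equal(coh$recurrence, truth$planted_recurrence)
  expect_equal(coh$alt_allele_count, truth$planted_alt_allele_count)
  expect_equal(coh$max_alt_depth, truth$planted_max_known_depth)
})

test_that("quality filter keeps depth>=5 or recurrence>=4, boundaries included", {
  coh <- tibble::tibble(
    key = as.character(1:4),
    max_alt_depth = c(5L, 2L, 4L, NA),
    recurrence = c(1L, 4L, 3L, 4L))
  out <- apply_quality_filter(coh, filter_params())
  expect_equal(out$passed$key, c("1", "2", "4"))
  expect_equal(out$failed$key, "3")
})

test_that("quality filter matches a brute-force oracle over the depth x recurrence grid", {
  grid <- expand.grid(depth = c(0:10, NA), rec = 1:10)
  coh <- tibble::tibble(
    key = as.character(seq_len(nrow(grid))),
    max_alt_depth = as.integer(grid$depth),
    recurrence = as.integer(grid$rec))
  for (params in list(filter_params(), filter_params(3, 2))) {
    out <- apply_quality_filter(coh, params)
    want <- vapply(seq_len(nrow(coh)), function(i)
      oracle_filter_pass(coh$max_alt_depth[[i]], coh$recurrence[[i]],
                         params$min_alt_depth, params$min_recurrence),
      logical(1))
    expect_setequal(out$passed$key, coh$key[want])
    expect_setequal(out$failed$key, coh$key[!want])
    expect_equal(nrow(out$passed) + nrow(out$failed), nrow(coh))
  }
})

test_that("catalog depletion is allele-aware and exact", {
  vars <- tibble::tibble(key = c("5:100:A:T", "5:100:A:G", "7:1:C:T"))
  cat <- catalog(c("5:100:A:T"))
  out <- deplete_catalog(vars, cat)
  expect_equal(out$removed$key, "5:100:A:T")
  expect_setequal(out$retained$key, c("5:100:A:G", "7:1:C:T"))

  # empty catalog is the identity
  out <- deplete_catalog(vars, catalog(character()))
  expect_equal(out$retained, vars)
  expect_equal(nrow(out$removed), 0L)
})

test_that("depletion removes exactly the planted catalog members", {
  sim <- generate_cohort(cohort_spec(n_samples = 4, n_sites = 1000,
                                     recurrence = c(1, 4),
                                     frac_in_snp_catalog = 0.3,
                                     frac_in_somatic_catalog = 0, seed = 13))
  coh <- merge_cohort(sim$normals)
  out <- deplete_catalog(coh, sim$snp_catalog)
  expect_equal(nrow(out$removed), sum(sim$truth$in_snp_catalog))
  expect_equal(nrow(out$removed), 300L)
  expect_setequal(out$removed$key, sim$truth$key[sim$truth$in_snp_catalog])
})

test_that("build_database runs merge -> filter -> SNP -> somatic with exact funnel arithmetic", {
  # 24 sites: 20 pass the filter (deep), 4 fail (shallow singletons);
  # 8 of the passing are planted in the SNP catalog, 2 of the remainder in
  # the somatic catalog -> 10 final
  pos <- 1:24
  deep <- pos <= 20
  docs <- list(make_doc("N1", rep("1", 24), pos, rep("A", 24), rep("T", 24),
                        rep("0/1", 24),
                        ifelse(deep, "10,9", "20,1")))
  keys <- variant_key(rep("1", 24), pos, "A", "T")
  snp <- catalog(keys[1:8], "SNP-catalog")
  som <- catalog(keys[9:10], "somatic-catalog")
  built <- build_database(docs, snp, som)
  f <- built$funnel
  expect_equal(f$n_raw, 24L)
  expect_equal(f$n_unique, 24L)
  expect_equal(f$n_quality, 20L)
  expect_equal(f$n_removed_snp_catalog, 8L)
  expect_equal(f$n_post_snp_catalog, 12L)
  expect_equal(f$n_removed_somatic_catalog, 2L)
  expect_equal(f$n_final, 10L)
  expect_setequal(pon_keys(built), keys[11:20])
  expect_equal(built$provenance$min_alt_depth, 5L)

  # both catalogs empty: nothing depleted
  built2 <- build_database(docs)
  expect_equal(built2$funnel$n_final, built2$funnel$n_quality)
})

test_that("an unusable cohort is an explicit empty-cohort error", {
  no_carrier <- make_doc("N1", "1", 10, "A", "T", "0/0", "20,0")
  expect_error(build_database(list(no_carrier)), "empty cohort")
})

test_that("build is deterministic and insensitive to input file order", {
  sim <- generate_cohort(cohort_spec(n_samples = 6, n_sites = 200,
                                     recurrence = c(1, 6),
                                     frac_in_snp_catalog = 0.4,
                                     frac_in_somatic_catalog = 0.1, seed = 3))
  db1 <- build_database(sim$normals, sim$snp_catalog, sim$somatic_catalog)
  db2 <- build_database(rev(sim$normals), sim$snp_catalog, sim$somatic_catalog)
  expect_equal(db1$entries, db2$entries)
  expect_equal(unclass(db1$funnel), unclass(db2$funnel))
})

test_that("catalog depletion membership is order-insensitive", {
  sim <- generate_cohort(cohort_spec(n_samples = 4, n_sites = 300,
                                     recurrence = c(1, 4),
                                     frac_in_snp_catalog = 0.3,
                                     frac_in_somatic_catalog = 0.2, seed = 9))
  coh <- merge_cohort(sim$normals)
  ab <- deplete_catalog(deplete_catalog(coh, sim$snp_catalog)$retained,
                        sim$somatic_catalog)$retained
  ba <- deplete_catalog(deplete_catalog(coh, sim$somatic_catalog)$retained,
                        sim$snp_catalog)$retained
  expect_setequal(ab$key, ba$key)
})

test_that("funnel conservation holds on random generated cohorts", {
  for (seed in c(21, 22, 23)) {
    sim <- generate_cohort(cohort_spec(n_samples = 5, n_sites = 150,
                                       recurrence = c(1, 5), depth_mean = 5,
                                       frac_in_snp_catalog = 0.5,
                                       frac_in_somatic_catalog = 0.1,
                                       seed = seed))
    f <- build_database(sim$normals, sim$snp_catalog,
                        sim$somatic_catalog)$funnel
    expect_gte(f$n_raw, f$n_unique)
    expect_gte(f$n_unique, f$n_quality)
    expect_equal(f$n_quality, f$n_post_snp_catalog + f$n_removed_snp_catalog)
    expect_equal(f$n_final, f$n_post_snp_catalog - f$n_removed_somatic_catalog)
    expect_true(all(unlist(f) >= 0))
  }
})

test_that("the SQLite database round-trips keys, counts and provenance", {
  sim <- generate_cohort(cohort_spec(n_samples = 6, n_sites = 1000,
                                     recurrence = c(1, 6),
                                     frac_in_snp_catalog = 0.2,
                                     frac_in_somatic_catalog = 0.05,
                                     seed = 17))
  db <- build_database(sim$normals, sim$snp_catalog, sim$somatic_catalog)
  path <- withr::local_tempfile(fileext = ".db")
  save_database(db, path)
  back <- load_database(path)
  ord <- function(x) x[order(x$key), c("chrom", "pos", "ref", "alt", "key",
                                       "recurrence", "alt_allele_count",
                                       "max_alt_depth")]
  expect_equal(ord(back$entries), ord(db$entries))
  expect_equal(back$cohort_size, db$cohort_size)
  expect_equal(back$provenance$min_alt_depth, db$provenance$min_alt_depth)
  expect_equal(back$provenance$snp_catalog, db$provenance$snp_catalog)
  expect_equal(unclass(back$funnel), unclass(db$funnel))

  # empty database round-trips with valid metadata
  empty <- db
  empty$entries <- db$entries[0, ]
  save_database(empty, path)
  expect_equal(nrow(load_database(path)$entries), 0L)
  expect_equal(load_database(path)$cohort_size, 6L)
})

test_that("foreign files are rejected with a format error", {
  txt <- withr::local_tempfile(fileext = ".txt")
  writeLines("not a database", txt)
  expect_error(load_database(txt), "SQLite")
  # an SQLite file without the variants table
  sqlite <- withr::local_tempfile(fileext = ".db")
  con <- DBI::dbConnect(RSQLite::SQLite(), sqlite)
  DBI::dbWriteTable(con, "other", data.frame(x = 1), overwrite = TRUE)
  DBI::dbDisconnect(con)
  expect_error(load_database(sqlite), "variants")
  expect_error(load_database(file.path(tempdir(), "missing.db")), "not found")
})

test_that("catalogs load from both VCF and tab-delimited form", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("#chrom\tpos\tref\talt", "chr1\t100\tA\tT", "2\t50\tC\tCAT"),
             tsv)
  cat1 <- read_catalog(tsv, "SNP-catalog", "v-test")
  expect_setequal(cat1$keys, c("1:100:A:T", "2:50:C:CAT"))

  vcf <- write_lines_vcf(c(
    "##fileformat=VCFv4.1",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "chr1\t100\t.\tA\tT\t.\t.\t.",
    "2\t50\t.\tC\tCAT,G\t.\t.\t."))
  cat2 <- read_catalog(vcf)
  expect_setequal(cat2$keys, c("1:100:A:T", "2:50:C:CAT", "2:50:C:G"))

  expect_length(read_catalog(NULL)$keys, 0L)
})
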
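# a small handcrafted store: one common SNV (3 het + 1 hom of n = 10),
# one blurred singleton, one rs-identified SNV
query_store <- function() {
  records <- data.table(
    chrom = c("1", "1", "2"),
    pos = c(100L, 250L, 500L),
    id = c(".", ".", "rs6605067"),
    ref = c("A", "C", "G"), alt = c("G", "T", "A"),
    blurred = c(FALSE, TRUE, FALSE),
    carrier_count = c(4L, 1L, 2L),
    het_count = c(3L, NA, 2L), hom_count = c(1L, NA, 0L),
    trait_summary = c("t|4", "t|1", "t|2"),
    subs = c("aa|H,bb|H,cc|H,dd|A", "", "ee|H,ff|H"),
    class_tokens = c("C1", "", "C1"),
    contact = c(NA, "Submitter <s@x.org>", NA))
  snv_store(records, n_samples = 10L, factor = 1.5, median_count = 2,
            threshold = 3,
            classes = data.table(class_id = "C1", n_members = 10L,
                                 hpo_present = "HP:0001250;HP:0001263",
                                 hpo_absent = ""),
            tuples = data.table(trait = "t", hpo_present = "x",
                                hpo_absent = "unknown", gender = "unknown",
                                platform = "unknown",
                                enrichment = "unknown", n = 10L),
            sub_class = data.table(sub_id = c("aa", "bb", "cc", "dd",
                                              "ee", "ff"),
                                   class_id = "C1"),
            contact = "Submitter <s@x.org>")
}

test_that("position queries report the stated frequency conventions", {
  st <- query_store()
  res <- query_position(st, "1:100")
  expect_equal(nrow(res), 1L)
  expect_equal(res$carrier_freq, 0.4)          # 4 of 10 samples
  expect_equal(res$allele_freq, 5 / 20)        # 3 het + 2x1 hom over 2n
  expect_equal(res$het_freq, 0.3)
  expect_equal(res$hpo_terms, "HP:0001250;HP:0001263")

  # chr prefix tolerated
  expect_equal(nrow(query_position(st, "chr1:100")), 1L)
  # absent locus: empty result, not an error
  expect_equal(nrow(query_position(st, "1:9999")), 0L)
  expect_error(query_position(st, "not-a-position"),
               class = "snvblur_usage")
})

test_that("blurred loci return contact but no genotype frequencies", {
  st <- query_store()
  res <- query_position(st, "1:250")
  expect_equal(nrow(res), 1L)
  expect_true(res$blurred)
  expect_equal(res$contact, "Submitter <s@x.org>")
  expect_true(is.na(res$allele_freq))
  expect_true(is.na(res$het_freq))
  expect_true(is.na(res$carrier_freq))
})

test_that("rsid queries match exactly and never match the '.' sentinel", {
  st <- query_store()
  expect_equal(query_rsid(st, "rs6605067")$pos, 500L)
  expect_equal(nrow(query_rsid(st, "rs999")), 0L)
  expect_equal(nrow(query_rsid(st, ".")), 0L)
})

test_that("gene queries follow the BED and GFF coordinate conventions", {
  st <- query_store()
  bed <- write_lines_tmp(c("1\t90\t110\tGENE1", "2\t400\t600\tGENE2"),
                         ext = ".bed")
  # pos 100 inside [90, 110)
  expect_equal(query_gene(st, "GENE1", bed)$pos, 100L)
  # boundary checks on a store built for them
  bst <- local({
    records <- data.table(
      chrom = "1", pos = c(90L, 109L, 110L), id = ".",
      ref = "A", alt = "G", blurred = TRUE,
      carrier_count = 1L, het_count = NA_integer_,
      hom_count = NA_integer_, trait_summary = "t|1", subs = "",
      class_tokens = "", contact = "c")
    snv_store(records, 10L, 1.5, 2, 3,
              classes = data.table(class_id = character(),
                                   n_members = integer(),
                                   hpo_present = character(),
                                   hpo_absent = character()),
              tuples = data.table(trait = character(),
                                  hpo_present = character(),
                                  hpo_absent = character(),
                                  gender = character(),
                                  platform = character(),
                                  enrichment = character(), n = integer()),
              sub_class = data.table(sub_id = character(),
                                     class_id = character()),
              contact = "c")
  })
  hits <- query_gene(bst, "GENE1", bed)
  expect_setequal(hits$pos, c(90L, 109L))      # start inclusive, end open

  gff <- write_lines_tmp(paste(
    "1", "test", "gene", "90", "110", ".", "+", ".", 'ID=GENE1',
    sep = "\t"), ext = ".gff3")
  ghits <- query_gene(bst, "GENE1", gff)
  expect_setequal(ghits$pos, c(90L, 109L, 110L))  # 1-based closed

  expect_warning(res <- query_gene(st, "NOSUCH", bed), "NOSUCH")
  expect_equal(nrow(res), 0L)
})

test_that("combined search equals the de-duplicated union of single queries", {
  st <- query_store()
  bed <- write_lines_tmp(c("1\t90\t110\tGENE1"), ext = ".bed")
  res <- combined_search(st, c("1:100", "rs6605067", "GENE1"),
                         intervals = bed)
  expect_equal(nrow(res), 2L)   # 1:100 matched twice, deduplicated
  k <- snv_key(res$chrom, res$pos, res$ref, res$alt)
  expect_setequal(k, c("1:100:A:G", "2:500:G:A"))
  both <- res$matched_term[k == "1:100:A:G"]
  expect_true(grepl("1:100", both) && grepl("GENE1", both))

  # idempotent under duplicate terms
  res2 <- combined_search(st, c("rs6605067", "rs6605067"))
  expect_equal(nrow(res2), 1L)
  # empty term list
  expect_equal(nrow(combined_search(st, character())), 0L)
  # unclassifiable term
  expect_error(combined_search(st, "chr1:pos:extra!"),
               class = "snvblur_usage")
  # symbol without interval file
  expect_error(combined_search(st, "NOD2"), class = "snvblur_usage")
})

test_that("queries are read-only and frequencies are internally consistent", {
  st <- query_store()
  before <- serialize(st, NULL)
  invisible(query_position(st, "1:100"))
  invisible(query_rsid(st, "rs6605067"))
  invisible(combined_search(st, c("1:100", "1:250")))
  expect_identical(serialize(st, NULL), before)

  r <- st$records[!st$records$blurred]
  expect_true(all(r$carrier_count <= 10L))
  expect_equal(r$het_count + r$hom_count, r$carrier_count)
})

test_that("user-supplied reference frequencies join onto results", {
  st <- query_store()
  tsv <- write_lines_tmp(c("chrom\tpos\tref\talt\tfreq",
                           "1\t100\tA\tG\t0.015"), ext = ".tsv")
  rf <- read_reference_freqs(tsv)
  res <- query_position(st, "1:100", ref_freqs = rf)
  expect_equal(res$ref_freq, 0.015)
  res2 <- query_position(st, "1:250", ref_freqs = rf)
  expect_true(is.na(res2$ref_freq))
  bad <- write_lines_tmp("a\tb\n1\t2", ext = ".tsv")
  expect_error(read_reference_freqs(bad), class = "snvblur_format")
})
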
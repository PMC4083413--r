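test_that("read_vcf extracts het/hom-alt calls and ignores hom-ref", {
  f <- write_lines_tmp(vcf_fixture(c(
    "1\t100\trs1\tA\tG\t.\tPASS\t.\tGT\t0/1",
    "1\t200\t.\tC\tT\t.\tPASS\t.\tGT\t1/1",
    "1\t300\t.\tG\tA\t.\tPASS\t.\tGT\t0/0")))
  d <- read_vcf(f)
  expect_equal(length(d$samples), 1L)
  expect_equal(nrow(d$sites), 3L)
  expect_equal(nrow(d$calls), 2L)
  expect_equal(d$calls$zygosity[d$calls$site_id == 1], "het")
  expect_equal(d$calls$zygosity[d$calls$site_id == 2], "hom_alt")
  expect_false(3L %in% d$calls$site_id)
  expect_equal(d$sites$id, c("rs1", ".", "."))
})

test_that("read_vcf handles the empty, phased and override cases", {
  f <- write_lines_tmp(vcf_fixture(character()))
  d <- read_vcf(f)
  expect_equal(length(d$samples), 1L)
  expect_equal(nrow(d$calls), 0L)

  f2 <- write_lines_tmp(vcf_fixture("1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t1|0"))
  d2 <- read_vcf(f2, sample_id_override = "X9")
  expect_equal(d2$calls$sample_id, "X9")
  expect_equal(d2$calls$zygosity, "het")
})

test_that("read_vcf skips non-SNV alleles and splits multi-allelic lines", {
  f <- write_lines_tmp(vcf_fixture(c(
    "1\t100\t.\tAT\tA\t.\tPASS\t.\tGT\t0/1",
    "1\t200\t.\tC\tT,G\t.\tPASS\t.\tGT\t1/2",
    "1\t300\t.\tG\tGA,<DEL>\t.\tPASS\t.\tGT\t0/1")))
  d <- read_vcf(f)
  expect_equal(unname(d$skip_stats["indel"]), 2L)  # AT>A and G>GA
  expect_equal(unname(d$skip_stats["symbolic"]), 1L)
  # the C>T,G line splits into two SNV records, sample carries each once
  expect_equal(nrow(d$sites), 2L)
  expect_equal(sort(d$sites$alt), c("G", "T"))
  expect_equal(nrow(d$calls), 2L)
  expect_true(all(d$calls$zygosity == "het"))
})

test_that("read_vcf rejects files without #CHROM or GT", {
  f <- write_lines_tmp(c("##fileformat=VCFv4.2", "no header here"))
  expect_error(read_vcf(f), class = "snvblur_format")
  f2 <- write_lines_tmp(c(
    "##fileformat=VCFv4.2",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "S1", sep = "\t"),
    "1\t100\t.\tA\tG\t.\tPASS\t.\tDP\t30"))
  expect_error(read_vcf(f2), class = "snvblur_format")
  expect_error(read_vcf(tempfile()), class = "snvblur_io")
})

test_that("INI metadata round-trips, with global defaults applied", {
  minimal <- write_lines_tmp(c(
    "[global]",
    "trait = some disease",
    "contact_name = Jane Doe",
    "contact_affiliation = Test Institute",
    "contact_email = jane.doe@example.org",
    "[sample:A1]",
    "status = patient"), ext = ".ini")
  s <- read_ini(minimal)
  expect_length(s, 1L)
  expect_equal(s$A1$trait, "some disease")
  expect_true(is.na(s$A1$gender))
  expect_length(s$A1$hpo_present, 0L)

  full <- meta("B2", trait = "epilepsy", gender = "female",
               platform = "HiSeq", enrichment = "SureSelect",
               pi = "Prof X", hpo = c("HP:0001250", "HP:0001263"),
               hpo_abs = "HP:0002376")
  f <- tempfile(fileext = ".ini")
  write_ini(list(full), f)
  back <- read_ini(f)
  expect_equal(back$B2, full, ignore_attr = TRUE)
})

test_that("random sample metadata survives a write/read round trip", {
  for (seed in 1:15) {
    samples <- fuzz_samples(sample(2:6, 1), seed)
    f <- tempfile(fileext = ".ini")
    write_ini(samples, f)
    back <- read_ini(f)
    expect_equal(length(back), length(samples))
    # input order preserved
    expect_equal(names(back),
                 vapply(samples, `[[`, character(1), "sample_id"))
    for (i in seq_along(samples))
      expect_equal(back[[i]], samples[[i]], ignore_attr = TRUE)
  }
})

test_that("INI validation rejects malformed or missing mandatory fields", {
  bad_hpo <- write_lines_tmp(c(
    "[global]",
    "trait = t",
    "contact_name = n", "contact_affiliation = a", "contact_email = e",
    "[sample:A1]",
    "status = patient",
    "hpo_present = HP:123"), ext = ".ini")
  expect_error(read_ini(bad_hpo), "HP:123", class = "snvblur_validation")

  no_trait <- write_lines_tmp(c(
    "[global]",
    "contact_name = n", "contact_affiliation = a", "contact_email = e",
    "[sample:A1]", "status = patient"), ext = ".ini")
  expect_error(read_ini(no_trait), "trait", class = "snvblur_validation")

  no_contact <- write_lines_tmp(c(
    "[global]", "trait = t",
    "[sample:A1]", "status = patient"), ext = ".ini")
  expect_error(read_ini(no_contact), "contact",
               class = "snvblur_validation")
})

test_that("aggregated VCF round-trips field-exactly and validates clean", {
  cohort <- simulate_cohort(sfs_config(n_samples = 8, n_sites = 600,
                                       seed = 42))
  agg <- aggregate_cohort(cohort, seed = 42, passphrase = "pw")
  f <- tempfile(fileext = ".vcf")
  write_aggregated_vcf(agg$store, f)
  expect_equal(nrow(validate_aggregated_vcf(f)), 0L)
  back <- read_aggregated_vcf(f)
  expect_equal(back$records, agg$store$records)
  expect_equal(back$n_samples, agg$store$n_samples)
  expect_equal(back$threshold, agg$store$threshold)
  expect_equal(back$classes, agg$store$classes)
  expect_equal(back$tuples, agg$store$tuples)
  expect_equal(back$sub_class, agg$store$sub_class)
  expect_equal(back$contact, agg$store$contact)
})

test_that("an empty store writes a header-only dialect file that reads back", {
  empty <- snv_store(
    records = data.table(chrom = character(), pos = integer(),
                         id = character(), ref = character(),
                         alt = character(), blurred = logical(),
                         carrier_count = integer(), het_count = integer(),
                         hom_count = integer(), trait_summary = character(),
                         subs = character(), class_tokens = character(),
                         contact = character()),
    n_samples = 2L, factor = 1.5, median_count = 0, threshold = 0,
    classes = data.table(class_id = character(), n_members = integer(),
                         hpo_present = character(),
                         hpo_absent = character()),
    tuples = data.table(trait = character(), hpo_present = character(),
                        hpo_absent = character(), gender = character(),
                        platform = character(), enrichment = character(),
                        n = integer()),
    sub_class = data.table(sub_id = character(), class_id = character()),
    contact = "x")
  f <- tempfile(fileext = ".vcf")
  write_aggregated_vcf(empty, f)
  expect_true(all(startsWith(readLines(f), "#")))
  expect_equal(nrow(validate_aggregated_vcf(f)), 0L)
  back <- read_aggregated_vcf(f)
  expect_equal(nrow(back$records), 0L)
})

test_that("blurred output lines never contain sub-sample tokens", {
  cohort <- toy8_cohort()
  agg <- aggregate_cohort(cohort, seed = 7, passphrase = "pw")
  f <- tempfile(fileext = ".vcf")
  write_aggregated_vcf(agg$store, f)
  lines <- readLines(f)
  body <- lines[!startsWith(lines, "#")]
  blurred_lines <- body[grepl("GBBLUR", body)]
  expect_length(blurred_lines, 8L)
  all_subs <- unlist(strsplit(
    agg$store$records$subs[!agg$store$records$blurred], ","))
  sub_ids <- sub("\\|.*$", "", all_subs)
  for (sid in sub_ids)
    expect_false(any(grepl(sid, blurred_lines, fixed = TRUE)))
})

test_that("the validator flags hand-corrupted files precisely", {
  cohort <- toy8_cohort()
  agg <- aggregate_cohort(cohort, seed = 7, passphrase = "pw")
  f <- tempfile(fileext = ".vcf")
  write_aggregated_vcf(agg$store, f)
  lines <- readLines(f)

  # blurred record that still carries linkage
  corrupt <- lines
  i <- which(grepl("GBBLUR", corrupt) & !startsWith(corrupt, "#"))[1]
  corrupt[i] <- paste0(corrupt[i], ";GBSUBS=deadbeef|H")
  f1 <- write_lines_tmp(corrupt)
  rep1 <- validate_aggregated_vcf(f1)
  expect_equal(sum(rep1$class == "blurred-with-linkage"), 1L)

  # carrier count inconsistent with listed genotypes
  corrupt <- lines
  j <- which(!grepl("GBBLUR", lines) & grepl("GBCAR=", lines))[1]
  corrupt[j] <- sub("GBCAR=8", "GBCAR=5", corrupt[j])
  f2 <- write_lines_tmp(corrupt)
  rep2 <- validate_aggregated_vcf(f2)
  expect_true(any(rep2$class == "count-mismatch"))

  # duplicate key and unsorted records
  body <- which(!startsWith(lines, "#"))
  f3 <- write_lines_tmp(c(lines, lines[body[1]]))
  rep3 <- validate_aggregated_vcf(f3)
  expect_true(any(rep3$class == "duplicate-key"))
  expect_true(any(rep3$class == "unsorted"))

  # missing dialect meta-lines
  f4 <- write_lines_tmp(lines[!startsWith(lines, "##GBDIALECT")])
  expect_true(any(validate_aggregated_vcf(f4)$class == "missing-meta"))
  expect_error(read_aggregated_vcf(f4), class = "snvblur_format")
})
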
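test_that("occurrence counts are genotype-blind carrier counts", {
  d1 <- make_cohort(1L, list(1L, 1L, 1L))
  expect_true(all(occurrence_counts(d1)$counts$count == 1L))

  d2 <- make_cohort(2L, list(1:2), zyg = list(c("het", "hom_alt")))
  expect_equal(occurrence_counts(d2)$counts$count, 2L)

  # brute-force oracle on a random 6 x 20 carrier matrix
  set.seed(31)
  mat <- matrix(rbinom(120, 1, 0.4), nrow = 6, ncol = 20)
  carriers <- lapply(seq_len(20), function(j) which(mat[, j] == 1))
  keep <- lengths(carriers) > 0
  d3 <- make_cohort(6L, carriers[keep])
  cnt <- occurrence_counts(d3)
  expect_equal(cnt$counts$count[order(cnt$counts$site_id)],
               unname(colSums(mat)[keep]))
})

test_that("the rare threshold is factor times the count median", {
  mk <- function(counts) {
    carriers <- lapply(counts, function(k) seq_len(k))
    occurrence_counts(make_cohort(max(counts), carriers))
  }
  expect_equal(rare_threshold(mk(c(1, 2, 2, 3, 9))), 3.0)
  # all counts equal c: threshold 1.5c, every SNV rare by k <= 1.5k
  t5 <- rare_threshold(mk(rep(5, 4)))
  expect_equal(t5, 7.5)
  expect_true(all(rep(5, 4) <= t5))
  expect_error(rare_threshold(structure(list(counts = data.table()),
                                        class = "snv_freq_table")),
               class = "snvblur_validation")
  expect_error(rare_threshold(mk(c(1, 2)), factor = -1),
               class = "snvblur_validation")
})

test_that("the threshold median agrees with an independent sort-based median", {
  set.seed(77)
  for (i in 1:200) {
    counts <- sample.int(50, sample(1:40, 1), replace = TRUE)
    carriers <- lapply(counts, seq_len)
    tab <- occurrence_counts(make_cohort(50L, carriers))
    # oracle: sort, take middle (or mean of the two middles)
    s <- sort(counts); n <- length(s)
    med <- if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
    expect_equal(rare_threshold(tab, 1.5), 1.5 * med)
  }
})

test_that("the 8-sample toy blurs exactly its 8 singletons", {
  cohort <- toy8_cohort()
  agg <- aggregate_cohort(cohort, seed = 11, passphrase = "pw")
  expect_equal(agg$store$threshold, 1.5)
  expect_equal(sum(agg$store$records$blurred), 8L)
  expect_equal(sum(!agg$store$records$blurred), 2L)
  ub <- agg$store$records[!agg$store$records$blurred]
  expect_true(all(ub$carrier_count == 8L))
})

test_that("extreme thresholds blur nothing or everything", {
  cohort <- toy8_cohort()
  set.seed(3)
  frag <- snvblur:::fragment_cohort(cohort)
  tab <- occurrence_counts(cohort)
  none <- blur_rare(cohort, frag, tab, threshold = 0, factor = 1.5,
                    contact = "c")
  expect_false(any(none$records$blurred))
  all_b <- blur_rare(cohort, frag, tab, threshold = 8, factor = 1,
                     contact = "c")
  expect_true(all(all_b$records$blurred))
  expect_true(all(all_b$records$subs == ""))
})

test_that("raising the factor never unblurs a record", {
  cohort <- simulate_cohort(sfs_config(n_samples = 10, n_sites = 800,
                                       seed = 5))
  blurred_at <- function(f) {
    agg <- aggregate_cohort(cohort, factor = f, seed = 5,
                            passphrase = "pw")
    r <- agg$store$records
    snv_key(r$chrom, r$pos, r$ref, r$alt)[r$blurred]
  }
  b1 <- blurred_at(0.8); b2 <- blurred_at(1.5); b3 <- blurred_at(3)
  expect_true(all(b1 %in% b2))
  expect_true(all(b2 %in% b3))
})

test_that("blurred keys and sub-sample keys are disjoint and exhaustive", {
  for (seed in c(2, 13)) {
    cohort <- simulate_cohort(sfs_config(n_samples = 8,
                                         n_sites = 500, seed = seed))
    agg <- aggregate_cohort(cohort, seed = seed, passphrase = "pw")
    r <- agg$store$records
    keys <- snv_key(r$chrom, r$pos, r$ref, r$alt)
    with_subs <- keys[nzchar(r$subs)]
    blurred <- keys[r$blurred]
    expect_length(intersect(with_subs, blurred), 0L)
    expect_setequal(union(with_subs, blurred), keys)
    expect_true(all(is.na(r$het_count[r$blurred])))
  }
})

test_that("a 2-sample degenerate cohort blurs everything end to end", {
  cohort <- make_cohort(2L, list(1:2))
  agg <- aggregate_cohort(cohort, seed = 1, passphrase = "pw")
  expect_equal(agg$store$threshold, 3)
  expect_true(all(agg$store$records$blurred))
  expect_false(any(grepl("GBSUBS",
                         {f <- tempfile(); write_aggregated_vcf(agg$store, f)
                          grep("^[^#]", readLines(f), value = TRUE)})))
})

test_that("aggregation is deterministic and never leaks sample ids", {
  cohort <- simulate_cohort(sfs_config(n_samples = 8, n_sites = 400,
                                       seed = 21))
  f1 <- tempfile(); f2 <- tempfile()
  write_aggregated_vcf(
    aggregate_cohort(cohort, seed = 99, passphrase = "pw")$store, f1)
  write_aggregated_vcf(
    aggregate_cohort(cohort, seed = 99, passphrase = "pw")$store, f2)
  expect_identical(readLines(f1), readLines(f2))

  for (seed in 1:8) {
    ch <- simulate_cohort(sfs_config(n_samples = sample(4:8, 1),
                                     n_sites = 120, seed = seed))
    agg <- aggregate_cohort(ch, seed = seed, passphrase = "pw")
    f <- tempfile(); write_aggregated_vcf(agg$store, f)
    txt <- readLines(f)
    for (sid in names(ch$samples))
      expect_false(any(grepl(sid, txt, fixed = TRUE)))
  }
})

test_that("removing a sample matches frozen-threshold re-computation", {
  cohort <- simulate_cohort(sfs_config(n_samples = 5, n_sites = 400,
                                       seed = 17))
  agg <- aggregate_cohort(cohort, seed = 17, passphrase = "pw")
  st2 <- remove_sample(agg$store, agg$linkage, "pw", "S003")
  expect_equal(st2$n_samples, 4L)
  expect_equal(st2$threshold, agg$store$threshold)   # frozen

  # oracle: recount carriers from the remaining samples
  cc <- cohort$calls[cohort$calls$sample_id != "S003", ]
  kk <- data.table::as.data.table(cc)[, .N, by = site_id]
  keys <- cohort_keys(cohort, kk$site_id)
  m <- match(snv_key(st2$records$chrom, st2$records$pos,
                     st2$records$ref, st2$records$alt), keys)
  expect_false(anyNA(m))
  expect_equal(nrow(st2$records), nrow(kk))
  expect_equal(st2$records$carrier_count, kk$N[m])
  ub <- st2$records[!st2$records$blurred]
  expect_equal(ub$het_count + ub$hom_count, ub$carrier_count)

  # removed sample's sub-samples are gone everywhere
  lk <- decrypt_linkage(agg$linkage, "pw")
  own <- unlist(lapply(lk, function(r)
    if (r$sample_id == "S003")
      vapply(r$subs, `[[`, character(1), "sub_id") else character()))
  for (sid in own) {
    expect_false(any(grepl(sid, st2$records$subs, fixed = TRUE)))
    expect_false(sid %in% st2$sub_class$sub_id)
  }

  expect_error(remove_sample(agg$store, agg$linkage, "pw", "sX"),
               class = "snvblur_validation")
  expect_error(remove_sample(agg$store, agg$linkage, "bad", "S003"),
               class = "snvblur_auth")
})

test_that("removing every sample empties the store", {
  cohort <- make_cohort(2L, list(1:2, 1L))
  agg <- aggregate_cohort(cohort, seed = 4, passphrase = "pw")
  s1 <- remove_sample(agg$store, agg$linkage, "pw", "T01")
  s2 <- remove_sample(s1, agg$linkage, "pw", "T02")
  expect_equal(nrow(s2$records), 0L)
})

test_that("consequence labels rank from nonsense to synonymous", {
  expect_equal(consequence_rank("nonsense"), 1L)
  expect_equal(consequence_rank("synonymous"), 6L)
  expect_equal(consequence_rank(c("Missense", "SPLICE SITE", "readthrough",
                                  "start-lost")), c(5L, 4L, 2L, 3L))
  expect_equal(consequence_rank("frameshift"), 7L)
  lbl <- c("missense", "nonsense", "frameshift")
  expect_equal(lbl[order(consequence_rank(lbl))],
               c("nonsense", "missense", "frameshift"))
})
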
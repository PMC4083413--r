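# ---------------------------------------------------------------------------
# Step 3 of aggregation: blurring the genotype information of rare
# variants.
#
# freq(SNV) is the number of cohort samples carrying at least one alt
# allele at the site, irrespective of genotype (het and hom-alt each
# count once). An SNV is rare iff
#
#     freq(SNV) <= factor * median(freq)         (factor default 1.5)
#
# The median is used because it is robust against the outlier mass of
# singletons. Rare SNVs lose all sub-sample linkage and genotype counts;
# only locus, alleles, trait summary and the submitter contact remain.
# A patient is trivially identifiable through singletons, which is why
# these and other rare SNVs are blurred.
# ---------------------------------------------------------------------------

#' Per-SNV occurrence counts
#'
#' Counts, for every SNV in the cohort, the number of distinct samples
#' carrying at least one alternate allele (genotype-blind: het and
#' hom-alt both count 1).
#'
#' @param cohort an [snv_cohort()].
#' @return object of class `snv_freq_table`: `list(counts, n_samples)`
#'   where `counts` has columns `site_id, chrom, pos, ref, alt, count`.
#' @export
occurrence_counts <- function(cohort) {
  if (!length(cohort$samples) || !nrow(cohort$sites))
    stop_snvblur("empty cohort", "snvblur_validation")
  k <- cohort$calls[, .(count = uniqueN(sample_id)), by = site_id]
  counts <- merge(cohort$sites, k, by = "site_id", all.x = FALSE)
  structure(list(counts = counts[, .(site_id, chrom, pos, ref, alt, count)],
                 n_samples = length(cohort$samples)),
            class = "snv_freq_table")
}

#' @export
print.snv_freq_table <- function(x, ...) {
  cat(sprintf("<snv_freq_table> %d SNVs over %d samples; median count %s\n",
              nrow(x$counts), x$n_samples, format(median(x$counts$count))))
  invisible(x)
}

#' Rare-variant threshold
#'
#' The adaptive cut-off below which an SNV counts as rare:
#' `factor * median` of the multiset of occurrence counts. For an
#' even-length multiset the median is the mean of the two middle values.
#' An SNV with count `k` is rare iff `k <= threshold`.
#'
#' @param table an [occurrence_counts()] result.
#' @param factor positive multiplier, default 1.5; raise it for a higher
#'   aggregation level (more blurring), lower it for less.
#' @return the threshold (real number).
#' @export
rare_threshold <- function(table, factor = 1.5) {
  if (!inherits(table, "snv_freq_table") || !nrow(table$counts))
    stop_snvblur("empty frequency table", "snvblur_validation")
  if (!is.numeric(factor) || factor <= 0)
    stop_snvblur("factor must be > 0", "snvblur_validation")
  factor * median(table$counts$count)
}

# "label|n,label|n" trait summaries, decrementable
parse_trait_summary <- function(s) {
  if (!nzchar(s)) return(data.table(label = character(), n = integer()))
  p <- strsplit(strsplit(s, ",", fixed = TRUE)[[1]], "|", fixed = TRUE)
  data.table(label = vapply(p, `[[`, character(1), 1L),
             n = as.integer(vapply(p, `[[`, character(1), 2L)))
}

format_trait_summary <- function(dt) {
  dt <- dt[n > 0][order(label)]
  paste(sprintf("%s|%d", dt$label, dt$n), collapse = ",")
}

#' Blur rare SNVs and assemble the aggregated store
#'
#' Applies the rare rule to every SNV: records with occurrence count at
#' or below the threshold are blurred (sub-sample linkage and genotype
#' counts dropped, trait summary and submitter contact retained); records
#' above it keep their sub-sample genotypes. No sub-sample id co-occurs
#' with a rare SNV anywhere in the output.
#'
#' @param cohort the [snv_cohort()] being aggregated.
#' @param frag result of the fragmentation step (sub-sample call table).
#' @param table [occurrence_counts()] of the same cohort.
#' @param threshold value from [rare_threshold()] computed on `table`.
#' @param factor the factor used (echoed into the store).
#' @param contact submitter contact string (attached to blurred records).
#' @param classes,tuples,sub_class cohort metadata tables.
#' @param rare_cmp `"le"` (default; rare iff k <= threshold) or `"lt"`.
#' @return an [snv_store()].
#' @export
blur_rare <- function(cohort, frag, table, threshold, factor, contact,
                      classes = NULL, tuples = NULL, sub_class = NULL,
                      rare_cmp = c("le", "lt")) {
  rare_cmp <- match.arg(rare_cmp)
  counts <- table$counts
  is_rare <- if (rare_cmp == "le") counts$count <= threshold
             else counts$count < threshold

  trait_of <- vapply(cohort$samples, `[[`, character(1), "trait")
  enc_of <- setNames(pct_encode(unique(trait_of)), unique(trait_of))

  calls <- copy(cohort$calls)
  calls[, trait := enc_of[trait_of[sample_id]]]
  gsum <- calls[, .(het = sum(zygosity == "het"),
                    hom = sum(zygosity == "hom_alt")), by = site_id]
  tsum <- calls[, .N, by = .(site_id, trait)][order(site_id, trait)]
  tsum <- tsum[, .(trait_summary = paste(sprintf("%s|%d", trait, N),
                                         collapse = ",")), by = site_id]

  unblurred_ids <- counts$site_id[!is_rare]
  fsub <- frag$calls[site_id %in% unblurred_ids]
  if (nrow(fsub)) {
    fsub <- fsub[order(site_id, sub_id)]
    ssum <- fsub[, .(subs = paste(sprintf(
      "%s|%s", sub_id, ifelse(zygosity == "hom_alt", "A", "H")),
      collapse = ",")), by = site_id]
  } else {
    ssum <- data.table(site_id = integer(), subs = character())
  }
  cls_of <- if (!is.null(sub_class) && nrow(sub_class))
    setNames(sub_class$class_id, sub_class$sub_id) else character()
  if (nrow(fsub) && length(cls_of)) {
    csum <- fsub[, .(class_tokens = paste(
      sort(unique(cls_of[sub_id])), collapse = ",")), by = site_id]
  } else {
    csum <- data.table(site_id = integer(), class_tokens = character())
  }

  rec <- merge(counts, gsum, by = "site_id", all.x = TRUE)
  rec <- merge(rec, tsum, by = "site_id", all.x = TRUE)
  rec <- merge(rec, ssum, by = "site_id", all.x = TRUE)
  rec <- merge(rec, csum, by = "site_id", all.x = TRUE)
  rec[, blurred := is_rare[match(site_id, counts$site_id)]]
  rec[is.na(subs), subs := ""]
  rec[is.na(class_tokens), class_tokens := ""]
  rec[blurred == TRUE, `:=`(het = NA_integer_, hom = NA_integer_,
                            subs = "", class_tokens = "")]
  rec[, contact := ifelse(blurred, contact, NA_character_)]
  rec <- merge(rec, cohort$sites[, .(site_id, id)], by = "site_id")

  records <- rec[, .(chrom, pos, id, ref, alt, blurred,
                     carrier_count = count, het_count = het,
                     hom_count = hom, trait_summary, subs, class_tokens,
                     contact)]
  empty_cls <- data.table(class_id = character(), n_members = integer(),
                          hpo_present = character(),
                          hpo_absent = character())
  empty_tup <- data.table(trait = character(), hpo_present = character(),
                          hpo_absent = character(), gender = character(),
                          platform = character(), enrichment = character(),
                          n = integer())
  empty_sc <- data.table(sub_id = character(), class_id = character())
  snv_store(records, length(cohort$samples), factor,
            threshold / factor, threshold,
            classes %||% empty_cls, tuples %||% empty_tup,
            sub_class %||% empty_sc, contact)
}

classes_table <- function(classes) {
  data.table(
    class_id = vapply(classes, `[[`, character(1), "class_id"),
    n_members = vapply(classes, function(cl) length(cl$member_ids),
                       integer(1)),
    hpo_present = vapply(classes, function(cl)
      paste(cl$hpo_present, collapse = ";"), character(1)),
    hpo_absent = vapply(classes, function(cl)
      paste(cl$hpo_absent, collapse = ";"), character(1)))
}

tuples_table <- function(samples) {
  ts <- t(vapply(samples, released_tuple, character(6)))
  dt <- as.data.table(ts)
  dt[, .(n = .N), by = names(dt)]
}

#' Aggregate a cohort: the full three-step pipeline
#'
#' Runs the whole anonymizing aggregation: (1) metadata suppression to
#' k-anonymity and phenotype-class construction, (2) weighted
#' fragmentation of every sample's SNVs into sub-samples with the secret
#' linkage encrypted under `passphrase`, (3) median-adaptive blurring of
#' rare SNVs. The result is a shareable store (nothing in it references
#' a sample id) plus the encrypted linkage bytes for the submitter.
#'
#' @param x an [snv_cohort()], or the path of an INI metadata file whose
#'   sample sections name their VCFs (see [read_cohort()]).
#' @param factor rare-threshold multiplier (default 1.5).
#' @param n_subsamples sub-samples per sample (default 5).
#' @param k k-anonymity parameter (default 2).
#' @param seed mandatory RNG seed; the aggregated VCF is byte-identical
#'   across runs with the same inputs and seed.
#' @param passphrase linkage-encryption passphrase.
#' @param rare_cmp `"le"` or `"lt"`, see [blur_rare()].
#' @return `list(store, linkage, suppression_log)`.
#' @export
aggregate_cohort <- function(x, factor = 1.5, n_subsamples = 5L, k = 2L,
                             seed, passphrase, rare_cmp = c("le", "lt")) {
  rare_cmp <- match.arg(rare_cmp)
  if (missing(seed) || is.null(seed))
    stop_snvblur("seed is mandatory (reproducible aggregation)",
                 "snvblur_validation")
  cohort <- if (inherits(x, "snv_cohort")) x else read_cohort(x)
  if (length(cohort$samples) < k)
    stop_snvblur(sprintf("cohort of %d samples cannot be released (k = %d)",
                         length(cohort$samples), k), "snvblur_validation")
  set.seed(as.integer(seed))

  sup <- suppress_metadata(cohort$samples, k)
  cohort$samples <- sup$samples
  names(cohort$samples) <-
    vapply(sup$samples, `[[`, character(1), "sample_id")
  classes <- build_phenotype_classes(cohort$samples)
  class_of <- unlist(lapply(classes, function(cl)
    setNames(rep(cl$class_id, length(cl$member_ids)), cl$member_ids)))

  frag <- fragment_cohort(cohort, fragmentation_config(n_subsamples))
  sub_class <- unique(frag$calls[, .(sub_id, sample_id)])
  # also include sub-samples whose every call happens to be rare later:
  # the map is per sub-sample, not per record
  sub_class <- data.table(
    sub_id = unlist(lapply(frag$linkage, function(r)
      vapply(r$subs, `[[`, character(1), "sub_id"))),
    class_id = unname(class_of[unlist(lapply(frag$linkage, function(r)
      rep(r$sample_id, length(r$subs))))]))
  sub_class <- sub_class[order(sub_id)]

  freq <- occurrence_counts(cohort)
  thr <- rare_threshold(freq, factor)
  contact <- contact_string(cohort$samples[[1]]$contact)
  store <- blur_rare(cohort, frag, freq, thr, factor, contact,
                     classes = classes_table(classes),
                     tuples = tuples_table(cohort$samples),
                     sub_class = sub_class, rare_cmp = rare_cmp)
  linkage <- encrypt_linkage(frag$linkage, passphrase)
  list(store = store, linkage = linkage, suppression_log = sup$log)
}

#' Remove a withdrawn sample from an aggregated store
#'
#' Honours consent withdrawal: using the decrypted linkage (which retains
#' the sample's complete call list, including calls that were blurred in
#' the public store), every contribution of the sample is removed -
#' sub-sample genotypes deleted, carrier / het / hom / trait counts
#' decremented, the cohort size reduced by one. The rare threshold is
#' deliberately NOT recomputed: re-thresholding could re-link records
#' that were already published blurred, which the public store cannot
#' support. Records left with no carrier are deleted.
#'
#' @param store an [snv_store()].
#' @param linkage raw linkage bytes from [aggregate_cohort()].
#' @param passphrase the submitter's passphrase.
#' @param sample_id the withdrawing sample.
#' @return the updated [snv_store()].
#' @export
remove_sample <- function(store, linkage, passphrase, sample_id) {
  recs <- decrypt_linkage(linkage, passphrase)
  idx <- which(vapply(recs, `[[`, character(1), "sample_id") == sample_id)
  if (!length(idx))
    stop_snvblur(sprintf("sample '%s' not present in linkage", sample_id),
                 "snvblur_validation")
  rec <- recs[[idx[1]]]
  sub_ids <- vapply(rec$subs, `[[`, character(1), "sub_id")
  removed <- rbindlist(lapply(rec$subs, function(s) data.table(
    k = unlist(s$keys), zyg = unlist(s$zygosity), sid = s$sub_id)))
  if (is.null(removed) || !nrow(removed))
    removed <- data.table(k = character(), zyg = character(),
                          sid = character())
  r <- copy(store$records)
  r[, key := snv_key(chrom, pos, ref, alt)]
  hit <- match(removed$k, r$key)
  if (anyNA(hit))
    stop_snvblur("linkage references SNVs absent from the store",
                 "snvblur_invariant")
  trait_enc <- pct_encode(rec$trait)
  for (i in seq_len(nrow(removed))) {
    j <- hit[i]
    r[j, carrier_count := carrier_count - 1L]
    ts <- parse_trait_summary(r$trait_summary[j])
    ts[label == trait_enc, n := n - 1L]
    r[j, trait_summary := format_trait_summary(ts)]
    if (!r$blurred[j]) {
      r[j, `:=`(
        het_count = het_count - as.integer(removed$zyg[i] == "het"),
        hom_count = hom_count - as.integer(removed$zyg[i] == "hom_alt"))]
      toks <- strsplit(r$subs[j], ",", fixed = TRUE)[[1]]
      keep <- toks[sub("\\|.*$", "", toks) != removed$sid[i]]
      r[j, subs := paste(keep, collapse = ",")]
      cls <- store$sub_class[match(
        sub("\\|.*$", "", keep), store$sub_class$sub_id), class_id]
      r[j, class_tokens := paste(sort(unique(cls)), collapse = ",")]
    }
  }
  r <- r[carrier_count > 0L]
  r[, key := NULL]
  sub_class <- store$sub_class[!sub_id %in% sub_ids]
  classes <- copy(store$classes)
  own_cls <- unique(store$sub_class[sub_id %in% sub_ids, class_id])
  if (length(own_cls) == 1L)
    classes[class_id == own_cls, n_members := n_members - 1L]
  snv_store(r, store$n_samples - 1L, store$factor, store$median_count,
            store$threshold, classes[n_members > 0L], store$tuples,
            sub_class, store$contact)
}

#' Rank a functional-consequence label by expected severity
#'
#' Orders coding-consequence labels from most to least likely damaging:
#' nonsense (1), readthrough (2), start-lost (3), splice site (4),
#' missense (5), synonymous (6); any other label ranks 7 ("unknown").
#' Case-insensitive.
#'
#' @param label character vector of consequence labels.
#' @return integer ranks (1 = most damaging).
#' @export
consequence_rank <- function(label) {
  order_tbl <- c("nonsense" = 1L, "readthrough" = 2L, "start-lost" = 3L,
                 "splice site" = 4L, "missense" = 5L, "synonymous" = 6L)
  r <- order_tbl[tolower(trimws(as.character(label)))]
  r[is.na(r)] <- 7L
  unname(r)
}
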
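# ---------------------------------------------------------------------------
# Evaluation diagnostics: how much genotype information survives blurring
# (as a function of cohort size), the shape of the occurrence-count
# spectrum, and an adversarial re-identification experiment that asks
# whether a probe sample's own sub-samples stand out by set overlap.
# ---------------------------------------------------------------------------

#' Fraction of unblurred genotype data in a store
#'
#' The headline privacy/utility trade-off: how much of the aggregated
#' data still carries sub-sample genotype linkage. Measured over genotype
#' records (sample-site carrier pairs, i.e. carrier-count sums) by
#' default - the reading under which common variants dominate - or per
#' site.
#'
#' @param store an [snv_store()].
#' @param per `"records"` (default) or `"sites"`.
#' @return fraction in `[0, 1]`; 0 iff every record is blurred.
#' @export
unblurred_ratio <- function(store, per = c("records", "sites")) {
  per <- match.arg(per)
  r <- store$records
  if (!nrow(r))
    stop_snvblur("empty store", "snvblur_validation")
  if (per == "records")
    sum(r$carrier_count[!r$blurred]) / sum(r$carrier_count)
  else
    sum(!r$blurred) / nrow(r)
}

# unblurred ratio implied by a vector of occurrence counts under the
# median rule; provably equals unblurred_ratio() of the aggregated store
# built from the same counts (the blur decision depends only on counts)
ratio_from_counts <- function(k, factor = 1.5, per = "records") {
  thr <- factor * median(k)
  if (per == "records") sum(k[k > thr]) / sum(k) else mean(k > thr)
}

#' Unblurred-data ratio as a function of cohort size
#'
#' For each cohort size, repeatedly draws occurrence-count spectra from
#' the generator's mixture, applies the median rule, and records the
#' unblurred fraction. The ratio is a function of the count multiset
#' alone, so the curve is computed without materializing genotypes; a
#' unit test pins its equality with the full simulate-aggregate path.
#'
#' @param sizes integer vector of cohort sizes (each >= 2).
#' @param replicates replicates per size.
#' @param n_sites sites per replicate.
#' @param factor rare-threshold multiplier.
#' @param seed RNG seed.
#' @param csv optional path: write the table as CSV.
#' @param ... further [sfs_config()] parameters (alpha, common_weight, ...).
#' @return `data.table` with columns `n`, `mean_ratio`, `sd_ratio`,
#'   `mean_site_ratio`.
#' @export
ratio_curve <- function(sizes, replicates = 5L, n_sites = 12000L,
                        factor = 1.5, seed = 1L, csv = NULL, ...) {
  if (any(sizes < 2L))
    stop_snvblur("cohort sizes must be >= 2", "snvblur_validation")
  set.seed(as.integer(seed))
  rows <- lapply(sizes, function(n) {
    cfg <- sfs_config(n_samples = n, n_sites = n_sites, ...)
    rr <- replicate(replicates, {
      k <- sample_site_counts(cfg)
      c(ratio_from_counts(k, factor, "records"),
        ratio_from_counts(k, factor, "sites"))
    })
    data.table(n = n, mean_ratio = mean(rr[1, ]),
               sd_ratio = stats::sd(rr[1, ]),
               mean_site_ratio = mean(rr[2, ]))
  })
  out <- rbindlist(rows)
  if (!is.null(csv)) data.table::fwrite(out, csv)
  out
}

#' Occurrence-count histogram (site frequency spectrum)
#'
#' @param x an [snv_cohort()] or an [occurrence_counts()] table.
#' @return `data.table` with columns `k` (occurrence count) and
#'   `n_sites`; sums to the number of distinct SNV sites with carriers.
#' @export
sfs_histogram <- function(x) {
  tab <- if (inherits(x, "snv_freq_table")) x else occurrence_counts(x)
  h <- tab$counts[, .(n_sites = .N), by = .(k = count)][order(k)]
  h[]
}

#' Re-identification overlap assessment
#'
#' The adversarial experiment: given a probe sample's complete SNV set,
#' compare it against every sub-sample still visible in the aggregated
#' store (via shared count, containment and Jaccard similarity) and ask
#' whether the probe's own sub-samples can be picked out. Ownership is
#' known only to the evaluator, through the decrypted linkage. The
#' headline metric is top-K identification precision under Jaccard
#' (K = number of own sub-samples present): containment is trivially 1
#' for own sub-samples (they are subsets of the probe), so Jaccard is
#' the discriminating metric an attacker would use.
#'
#' @param probe_keys character vector of `chrom:pos:ref:alt` keys - the
#'   probe sample's complete SNV set.
#' @param store an [snv_store()].
#' @param linkage,passphrase the encrypted linkage and its passphrase.
#' @param probe_sample_id the probe's sample id (for the `is_own` flag).
#' @return object of class `overlap_report`: `list(table, summary)` where
#'   `table` has one row per visible sub-sample (`sub_id, size, shared,
#'   containment, jaccard, is_own`) and `summary` holds per-metric own
#'   ranks and top-K precision.
#' @export
overlap_assessment <- function(probe_keys, store, linkage, passphrase,
                               probe_sample_id) {
  if (!length(probe_keys))
    stop_snvblur("probe SNV set is empty", "snvblur_validation")
  recs <- decrypt_linkage(linkage, passphrase)
  own_ids <- unlist(lapply(recs, function(r) {
    if (identical(r$sample_id, probe_sample_id))
      vapply(r$subs, `[[`, character(1), "sub_id") else character()
  }))

  ub <- store$records[blurred == FALSE & nzchar(subs)]
  if (nrow(ub)) {
    toks <- strsplit(ub$subs, ",", fixed = TRUE)
    sub_dt <- data.table(
      kstr = rep(snv_key(ub$chrom, ub$pos, ub$ref, ub$alt), lengths(toks)),
      sub_id = sub("\\|.*$", "", unlist(toks)))
    tab <- sub_dt[, .(size = .N, shared = sum(kstr %in% probe_keys)),
                  by = sub_id]
    np <- length(unique(probe_keys))
    tab[, containment := shared / size]
    tab[, jaccard := shared / (np + size - shared)]
    tab[, is_own := sub_id %in% own_ids]
    tab <- tab[order(-jaccard, sub_id)]
  } else {
    tab <- data.table(sub_id = character(), size = integer(),
                      shared = integer(), containment = numeric(),
                      jaccard = numeric(), is_own = logical())
  }
  K <- sum(tab$is_own)
  topk_precision <- function(metric) {
    if (K == 0L) return(NA_real_)
    o <- order(-tab[[metric]], tab$sub_id)
    sum(tab$is_own[o[seq_len(K)]]) / K
  }
  ranks <- function(metric) {
    if (K == 0L) return(integer())
    o <- order(-tab[[metric]], tab$sub_id)
    which(tab$is_own[o])
  }
  summary <- list(
    n_subsamples = nrow(tab), K = K,
    precision = c(jaccard = topk_precision("jaccard"),
                  containment = topk_precision("containment"),
                  shared = topk_precision("shared")),
    own_ranks = list(jaccard = ranks("jaccard"),
                     containment = ranks("containment"),
                     shared = ranks("shared")))
  structure(list(table = tab, summary = summary),
            class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<overlap_report> %d visible sub-samples, %d owned by the probe\n",
    s$n_subsamples, s$K))
  if (s$K > 0)
    cat(sprintf("  top-K precision: jaccard %.2f, containment %.2f, shared %.2f\n",
                s$precision["jaccard"], s$precision["containment"],
                s$precision["shared"]))
  invisible(x)
}

#' Repeated identification experiment
#'
#' Runs the full pipeline (simulate, aggregate, probe) across seeds and
#' averages the top-K Jaccard identification precision of a randomly
#' chosen probe sample's own sub-samples. Values well below 1 mean own
#' sub-samples are not reliably distinguishable from foreign ones.
#'
#' @param n_samples cohort size per replicate (default 10).
#' @param n_sites sites per replicate.
#' @param seeds integer vector of replicate seeds.
#' @param factor,n_subsamples aggregation parameters.
#' @return `list(mean_precision, per_seed)`.
#' @export
identification_experiment <- function(n_samples = 10L, n_sites = 40000L,
                                      seeds = 1:20, factor = 1.5,
                                      n_subsamples = 5L) {
  prec <- vapply(seeds, function(s) {
    cohort <- simulate_cohort(sfs_config(n_samples = n_samples,
                                         n_sites = n_sites, seed = s))
    agg <- aggregate_cohort(cohort, factor = factor,
                            n_subsamples = n_subsamples, seed = s,
                            passphrase = "experiment")
    probe <- names(cohort$samples)[1 + (s %% n_samples)]
    keys <- cohort_keys(cohort,
                        cohort$calls[sample_id == probe, site_id])
    rep <- overlap_assessment(keys, agg$store, agg$linkage, "experiment",
                              probe)
    rep$summary$precision[["jaccard"]]
  }, numeric(1))
  list(mean_precision = mean(prec), per_seed = prec)
}
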
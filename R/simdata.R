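# ---------------------------------------------------------------------------
# Synthetic exome-cohort generator.
#
# Real exome cohorts show a site-frequency spectrum with a strong
# singleton excess and a secondary mass of common variants shared by
# (nearly) everyone. The generator reproduces that shape with a
# two-component mixture over occurrence counts k in 1..n:
#
#   f(k) = (1 - w) * k^(-alpha) / Z  +  w * Uniform{ceil((1-band)*n) .. n}
#
# With the defaults (alpha = 1, w = 0.10, band = 0.10) at n = 50 this
# yields singleton:all-carrier ratio ~ 9.7, a median occurrence count of
# 7 (hence rare threshold 1.5 * 7 = 10.5, largest rare count 10 = 20% of
# samples), and ~41,000 SNVs per sample at 140,000 sites - the exome
# scale of ~40,000-45,000 SNVs per individual. Carriers per site are
# exchangeable: no linkage disequilibrium, no per-sample rate variation.
# ---------------------------------------------------------------------------

#' Site-frequency-spectrum configuration
#'
#' @param n_samples cohort size (>= 2).
#' @param n_sites number of distinct SNV sites.
#' @param alpha power-law exponent of the low-frequency component.
#' @param common_weight mixture weight of the high-frequency component.
#' @param common_band fraction of top counts the common component covers.
#' @param p_hom probability that a carrier is homozygous-alt.
#' @param seed RNG seed (used by [simulate_cohort()]).
#' @return object of class `sfs_config`.
#' @export
sfs_config <- function(n_samples = 50L, n_sites = 140000L, alpha = 1,
                       common_weight = 0.10, common_band = 0.10,
                       p_hom = 1 / 3, seed = NULL) {
  n_samples <- as.integer(n_samples)
  if (n_samples < 2L) stop_snvblur("n_samples must be >= 2",
                                   "snvblur_validation")
  if (alpha <= 0) stop_snvblur("alpha must be > 0", "snvblur_validation")
  if (common_weight < 0 || common_weight >= 1)
    stop_snvblur("common_weight must be in [0, 1)", "snvblur_validation")
  if (common_band <= 0 || common_band > 1)
    stop_snvblur("common_band must be in (0, 1]", "snvblur_validation")
  structure(list(n_samples = n_samples, n_sites = as.integer(n_sites),
                 alpha = alpha, common_weight = common_weight,
                 common_band = common_band, p_hom = p_hom, seed = seed),
            class = "sfs_config")
}

#' Analytic occurrence-count distribution
#'
#' The exact mixture pmf `f(k)`, `k = 1..n_samples`, that
#' [sample_site_counts()] draws from.
#'
#' @param config an [sfs_config()].
#' @return numeric vector of probabilities, summing to 1.
#' @export
site_count_pmf <- function(config) {
  n <- config$n_samples
  k <- seq_len(n)
  base <- k^(-config$alpha)
  base <- base / sum(base)
  lo <- ceiling((1 - config$common_band) * n)
  band <- as.numeric(k >= lo) / (n - lo + 1)
  (1 - config$common_weight) * base + config$common_weight * band
}

#' Draw per-site occurrence counts
#'
#' @param config an [sfs_config()].
#' @return integer vector of length `n_sites`, i.i.d. from
#'   [site_count_pmf()]. Consumes the R RNG stream.
#' @export
sample_site_counts <- function(config) {
  sample.int(config$n_samples, config$n_sites, replace = TRUE,
             prob = site_count_pmf(config))
}

#' Simulate a synthetic exome cohort
#'
#' Draws each site's occurrence count from the mixture spectrum, chooses
#' that many carriers uniformly without replacement, assigns zygosity
#' (hom-alt with probability `p_hom`), and attaches synthetic metadata:
#' trait groups (in blocks of at least two samples, so the cohort is
#' always k-anonymizable), a small HPO vocabulary shared within each
#' group, and randomized gender / platform / enrichment so the metadata
#' suppression step has work to do. Every tenth site receives an
#' rs-style dbSNP ID. Deterministic under `config$seed`.
#'
#' @param config an [sfs_config()].
#' @return an [snv_cohort()].
#' @export
simulate_cohort <- function(config = sfs_config()) {
  if (!is.null(config$seed)) set.seed(as.integer(config$seed))
  n <- config$n_samples
  ids <- sprintf("S%03d", seq_len(n))

  k <- sample_site_counts(config)
  n_sites <- config$n_sites
  chroms <- as.character(rep_len(1:22, n_sites))
  within <- ave(seq_len(n_sites), chroms, FUN = seq_along)
  pos <- as.integer(10000L + 150L * within)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_sites, replace = TRUE)
  alt <- bases[(match(ref, bases) + sample.int(3L, n_sites,
                                               replace = TRUE) - 1L) %% 4L + 1L]
  id <- rep(".", n_sites)
  rs <- seq_len(n_sites) %% 10L == 0L
  id[rs] <- sprintf("rs%d", 1000000L + which(rs))
  sites <- data.table(site_id = seq_len(n_sites), chrom = chroms,
                      pos = pos, id = id, ref = ref, alt = alt)

  carriers <- mapply(function(kk) sample.int(n, kk), k, SIMPLIFY = FALSE)
  total <- sum(k)
  calls <- data.table(
    site_id = rep.int(seq_len(n_sites), k),
    sample_id = ids[unlist(carriers, use.names = FALSE)],
    zygosity = ifelse(rbinom(total, 1L, config$p_hom) == 1L,
                      "hom_alt", "het"))

  # --- synthetic metadata -------------------------------------------------
  traits <- c("retinal dystrophy", "epileptic encephalopathy",
              "dilated cardiomyopathy", "healthy control")
  hpo_vocab <- list(
    c("HP:0000510", "HP:0000556"),
    c("HP:0001250", "HP:0001263", "HP:0002376"),
    c("HP:0001644", "HP:0001635"),
    character())
  n_groups <- if (n < 4L) 1L else min(4L, max(2L, n %/% 12L))
  cuts <- round(seq(0, n, length.out = n_groups + 1L))
  group <- rep(seq_len(n_groups), times = diff(cuts))
  contact <- list(name = "Cohort Submitter",
                  affiliation = "Synthetic Genomics Unit",
                  email = "submitter@example.org")
  samples <- vector("list", n)
  for (i in seq_len(n)) {
    g <- group[i]
    is_control <- n_groups >= 2L && g == n_groups
    samples[[i]] <- sample_meta(
      sample_id = ids[i],
      status = if (is_control) "control" else "patient",
      trait = if (is_control) "healthy control" else traits[g],
      hpo_present = if (is_control) character() else hpo_vocab[[g]],
      gender = sample(c("male", "female"), 1L),
      platform = sample(c("HiSeq 2000", "SOLiD 4"), 1L),
      enrichment = sample(c("SureSelect v4", "TruSeq Exome"), 1L),
      pi = "P. Investigator",
      contact = contact, contact_release = TRUE)
  }
  snv_cohort(samples, sites, calls)
}

#' Write a cohort as per-sample VCF files plus a metadata INI
#'
#' Materializes the on-disk fixture set the aggregation pipeline accepts
#' as input: one plain VCF 4.2 per sample and a `meta.ini` whose sample
#' sections reference them.
#'
#' @param cohort an [snv_cohort()].
#' @param dir output directory (created if needed).
#' @return path of the written INI file.
#' @export
write_cohort_fixtures <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sites <- copy(cohort$sites)
  ord <- snv_order(sites)
  calls <- copy(cohort$calls)
  setkey(calls, sample_id)
  samples <- cohort$samples
  for (m in samples) {
    sc <- calls[.(m$sample_id), nomatch = NULL]
    sel <- sites[ord][site_id %in% sc$site_id]
    gt <- ifelse(sc$zygosity[match(sel$site_id, sc$site_id)] == "hom_alt",
                 "1/1", "0/1")
    lines <- c(
      "##fileformat=VCFv4.2",
      "##source=snvblur-simulate",
      '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
      paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", m$sample_id, sep = "\t"),
      if (nrow(sel)) paste(sel$chrom, sel$pos, sel$id, sel$ref, sel$alt,
                           ".", "PASS", ".", "GT", gt, sep = "\t")
      else character())
    writeLines(lines, file.path(dir, sprintf("%s.vcf", m$sample_id)))
    attr(samples[[m$sample_id]], "vcf") <- sprintf("%s.vcf", m$sample_id)
  }
  ini <- file.path(dir, "meta.ini")
  write_ini(samples, ini)
  ini
}
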
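library(data.table)

default_contact <- list(name = "Jane Doe", affiliation = "Test Institute",
                        email = "jane.doe@example.org")

# quick sample_meta with sensible defaults
meta <- function(id, trait = "test trait", status = "patient",
                 hpo = character(), hpo_abs = character(),
                 gender = NA_character_, platform = NA_character_,
                 enrichment = NA_character_, pi = NA_character_) {
  sample_meta(id, status, trait, hpo_present = hpo, hpo_absent = hpo_abs,
              gender = gender, platform = platform, enrichment = enrichment,
              pi = pi, contact = default_contact)
}

# hand-built cohort with a prescribed carrier matrix:
# `carriers` is a list, one element per site, of sample indices;
# `zyg` optionally a parallel list of zygosities (default all het)
make_cohort <- function(n_samples, carriers, zyg = NULL,
                        traits = NULL, ...) {
  ids <- sprintf("T%02d", seq_len(n_samples))
  traits <- traits %||% rep("test trait", n_samples)
  samples <- lapply(seq_len(n_samples), function(i)
    meta(ids[i], trait = traits[i], ...))
  n_sites <- length(carriers)
  bases <- c("A", "C", "G", "T")
  sites <- data.table(site_id = seq_len(n_sites), chrom = "1",
                      pos = 100L + 10L * seq_len(n_sites), id = ".",
                      ref = "A", alt = "G")
  calls <- rbindlist(lapply(seq_len(n_sites), function(s) {
    if (!length(carriers[[s]])) return(NULL)
    z <- if (is.null(zyg)) rep("het", length(carriers[[s]]))
         else zyg[[s]]
    data.table(site_id = s, sample_id = ids[carriers[[s]]], zygosity = z)
  }))
  snv_cohort(samples, sites, calls)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# the 8-sample toy: 8 singleton sites (one per sample) + 2 sites carried
# by everyone; counts multiset {1 x8, 8, 8}: median 1, threshold 1.5
toy8_cohort <- function() {
  carriers <- c(as.list(1:8), list(1:8), list(1:8))
  make_cohort(8L, carriers)
}

# random fuzz cohort of metadata only (for k-anonymity properties);
# traits drawn from a pool of 2 so a trait can occur >= 2 times for n >= 4
fuzz_samples <- function(n, seed) {
  set.seed(seed)
  hpo_pool <- sprintf("HP:%07d", 1:6)
  lapply(seq_len(n), function(i) meta(
    sprintf("F%03d", i),
    trait = sample(c("trait one", "trait two"), 1),
    hpo = sample(hpo_pool, sample(0:3, 1)),
    gender = sample(c("male", "female", NA), 1),
    platform = sample(c("P1", "P2", NA), 1),
    enrichment = sample(c("E1", "E2", NA), 1)))
}

min_tuple_multiplicity <- function(samples) {
  ts <- vapply(samples, function(m) paste(released_tuple(m),
                                          collapse = "\r"), character(1))
  min(table(ts))
}

# cached default 50-exome simulation shared across expensive tests
.sim_cache <- new.env(parent = emptyenv())
default_sim <- function() {
  if (is.null(.sim_cache$cohort))
    .sim_cache$cohort <- simulate_cohort(sfs_config(seed = 101L))
  .sim_cache$cohort
}

write_lines_tmp <- function(lines, ext = ".vcf") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# minimal single-sample VCF text
vcf_fixture <- function(rows, sample = "S1") {
  c("##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample, sep = "\t"),
    rows)
}
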
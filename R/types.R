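#' Per-sample phenotype and technology metadata
#'
#' Constructs and validates the metadata record attached to one sample:
#' its patient/control status, a mandatory free-text trait, optional HPO
#' term sets (present and explicitly absent phenotypes), and optional
#' gender / sequencing platform / enrichment kit / PI fields. Contact
#' details (name, affiliation, email) are mandatory at intake; whether
#' they are released alongside blurred records is controlled by
#' `contact_release`.
#'
#' @param sample_id sample identifier (non-empty string).
#' @param status `"patient"` or `"control"`.
#' @param trait mandatory free-text disease description.
#' @param hpo_present,hpo_absent character vectors of HPO IDs
#'   (`HP:` followed by exactly 7 digits); the two sets must be disjoint.
#' @param gender optional, `"male"` or `"female"`.
#' @param platform,enrichment,pi optional free-text strings.
#' @param contact named list or vector with `name`, `affiliation`, `email`.
#' @param contact_release logical; release contact details publicly?
#' @return an object of class `sample_meta`.
#' @export
sample_meta <- function(sample_id, status, trait,
                        hpo_present = character(), hpo_absent = character(),
                        gender = NA_character_, platform = NA_character_,
                        enrichment = NA_character_, pi = NA_character_,
                        contact = NULL, contact_release = FALSE) {
  obj <- structure(list(
    sample_id = as.character(sample_id),
    status = as.character(status),
    trait = as.character(trait),
    hpo_present = sort(unique(as.character(hpo_present))),
    hpo_absent = sort(unique(as.character(hpo_absent))),
    gender = as.character(gender),
    platform = as.character(platform),
    enrichment = as.character(enrichment),
    pi = as.character(pi),
    contact = if (is.null(contact)) NULL else as.list(contact),
    contact_release = isTRUE(contact_release)
  ), class = "sample_meta")
  validate_sample_meta(obj)
  obj
}

#' @rdname sample_meta
#' @param x object to validate.
#' @export
validate_sample_meta <- function(x) {
  if (!nzchar(x$sample_id %||% ""))
    stop_snvblur("sample_id must be a non-empty string", "snvblur_validation")
  if (!x$status %in% c("patient", "control"))
    stop_snvblur(sprintf("sample '%s': status must be 'patient' or 'control'",
                         x$sample_id), "snvblur_validation")
  if (is.na(x$trait) || !nzchar(x$trait))
    stop_snvblur(sprintf("sample '%s': trait is mandatory", x$sample_id),
                 "snvblur_validation")
  for (f in c("hpo_present", "hpo_absent")) {
    bad <- x[[f]][!grepl("^HP:[0-9]{7}$", x[[f]])]
    if (length(bad))
      stop_snvblur(sprintf("sample '%s': malformed HPO ID '%s' in %s",
                           x$sample_id, bad[1], f), "snvblur_validation")
  }
  if (length(intersect(x$hpo_present, x$hpo_absent)))
    stop_snvblur(sprintf("sample '%s': HPO sets overlap", x$sample_id),
                 "snvblur_validation")
  if (!is.na(x$gender) && !x$gender %in% c("male", "female"))
    stop_snvblur(sprintf("sample '%s': gender must be 'male' or 'female'",
                         x$sample_id), "snvblur_validation")
  if (is.null(x$contact) ||
      !all(c("name", "affiliation", "email") %in% names(x$contact)) ||
      !all(nzchar(unlist(x$contact[c("name", "affiliation", "email")]))))
    stop_snvblur(sprintf(
      "sample '%s': contact (name, affiliation, email) is mandatory",
      x$sample_id), "snvblur_validation")
  invisible(x)
}

#' @export
print.sample_meta <- function(x, ...) {
  cat(sprintf("<sample_meta> %s [%s] trait='%s'\n", x$sample_id, x$status,
              x$trait))
  if (length(x$hpo_present))
    cat("  HPO present:", paste(x$hpo_present, collapse = " "), "\n")
  if (length(x$hpo_absent))
    cat("  HPO absent: ", paste(x$hpo_absent, collapse = " "), "\n")
  opt <- c(gender = x$gender, platform = x$platform,
           enrichment = x$enrichment, pi = x$pi)
  opt <- opt[!is.na(opt)]
  if (length(opt))
    cat(" ", paste(sprintf("%s=%s", names(opt), opt), collapse = " "), "\n")
  invisible(x)
}

# single displayable contact string ("Name, Affiliation <email>")
contact_string <- function(contact) {
  sprintf("%s, %s <%s>", contact$name, contact$affiliation, contact$email)
}

#' Assemble a cohort dataset
#'
#' A cohort bundles the per-sample metadata with the full genotype call
#' table. Calls are stored sparsely: only het and hom-alt genotypes exist
#' (homozygous-reference is never a call). The site table fixes the
#' `chrom:pos:ref:alt` identity of each SNV.
#'
#' @param samples list of [sample_meta()] objects.
#' @param sites `data.table` with columns `site_id`, `chrom`, `pos`, `id`
#'   (dbSNP ID or `"."`), `ref`, `alt`.
#' @param calls `data.table` with columns `site_id`, `sample_id`,
#'   `zygosity` (`"het"` or `"hom_alt"`).
#' @param skip_stats named integer vector of skipped-line counts.
#' @return an object of class `snv_cohort`.
#' @export
snv_cohort <- function(samples, sites, calls,
                       skip_stats = c(indel = 0L, symbolic = 0L,
                                      malformed = 0L)) {
  names(samples) <- vapply(samples, `[[`, character(1), "sample_id")
  sites <- as.data.table(sites)
  calls <- as.data.table(calls)
  if (nrow(calls)) {
    if (!all(calls$zygosity %in% c("het", "hom_alt")))
      stop_snvblur("zygosity must be 'het' or 'hom_alt'", "snvblur_validation")
    if (!all(calls$sample_id %in% names(samples)))
      stop_snvblur("call references unknown sample_id", "snvblur_validation")
    if (anyDuplicated(calls, by = c("site_id", "sample_id")))
      stop_snvblur("duplicate (site, sample) call", "snvblur_validation")
  }
  structure(list(samples = samples, sites = sites, calls = calls,
                 skip_stats = skip_stats),
            class = "snv_cohort")
}

#' @export
print.snv_cohort <- function(x, ...) {
  cat(sprintf("<snv_cohort> %d samples, %d sites, %d genotype calls\n",
              length(x$samples), nrow(x$sites), nrow(x$calls)))
  if (any(x$skip_stats > 0))
    cat("  skipped:", paste(sprintf("%s=%d", names(x$skip_stats),
                                    x$skip_stats), collapse = " "), "\n")
  invisible(x)
}

#' SNV keys of a cohort's sites
#'
#' @param cohort an [snv_cohort()].
#' @param site_id optional subset of site ids (e.g. one sample's calls).
#' @return character vector of `chrom:pos:ref:alt` keys.
#' @export
cohort_keys <- function(cohort, site_id = NULL) {
  s <- cohort$sites
  if (!is.null(site_id)) {
    idx <- match(site_id, s$site_id)   # evaluate outside [.data.table:
    s <- s[idx]                        # 'site_id' is also a column name
  }
  snv_key(s$chrom, s$pos, s$ref, s$alt)
}
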